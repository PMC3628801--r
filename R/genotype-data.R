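#' Construct a genotype dataset
#'
#' The container consumed by marker QC, association testing and
#' shared-homozygosity mapping: a marker map, sample identifiers with
#' case/control phenotype labels, and a samples-by-markers dosage matrix.
#'
#' Markers are sorted by (chromosome, position) on construction, stable by
#' marker id on position ties, so downstream window operations can assume
#' non-decreasing coordinates. Genotypes are coded as alt-allele dosage:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing.
#'
#' @param map data.frame with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based), and optionally `ref_allele` / `alt_allele`
#'   (single bases, used when writing PED files).
#' @param samples character vector of sample ids.
#' @param phenotype character vector, one of `"case"`, `"control"`,
#'   `"unknown"` per sample.
#' @param geno integer matrix, `length(samples)` rows by `nrow(map)` columns,
#'   values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(map, samples, phenotype, geno) {
  stopifnot(is.data.frame(map),
            all(c("marker_id", "chromosome", "position_bp") %in% names(map)))
  if (anyDuplicated(map$marker_id))
    stop("marker ids must be unique", call. = FALSE)
  if (any(map$position_bp < 1))
    stop("marker positions must be >= 1", call. = FALSE)
  geno <- as.matrix(geno)
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(map))
    stop("genotype matrix must be n_samples x n_markers", call. = FALSE)
  if (length(phenotype) != length(samples))
    stop("one phenotype label per sample required", call. = FALSE)
  if (!all(phenotype %in% c("case", "control", "unknown")))
    stop("phenotype labels must be case/control/unknown", call. = FALSE)
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotypes must be in {0, 1, 2, NA}", call. = FALSE)

  ord <- order(map$chromosome, map$position_bp, map$marker_id)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  geno <- geno[, ord, drop = FALSE]
  dimnames(geno) <- list(samples, map$marker_id)

  structure(list(map = map, samples = samples,
                 phenotype = phenotype, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases, %d controls) x %d markers\n",
              length(x$samples), sum(x$phenotype == "case"),
              sum(x$phenotype == "control"), nrow(x$map)))
  chroms <- unique(x$map$chromosome)
  cat(sprintf("  chromosomes: %s\n", paste(chroms, collapse = ", ")))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype rate: %.3f\n", miss))
  invisible(x)
}

n_cases <- function(ds) sum(ds$phenotype == "case")
n_controls <- function(ds) sum(ds$phenotype == "control")

case_rows <- function(ds) which(ds$phenotype == "case")
control_rows <- function(ds) which(ds$phenotype == "control")

#' Restrict a dataset to a subset of markers and/or samples
#' @param ds a `genotype_dataset`.
#' @param markers logical or integer index into the marker map.
#' @param samples logical or integer index into the sample list.
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(ds, markers = NULL, samples = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  mi <- if (is.null(markers)) seq_len(nrow(ds$map)) else markers
  si <- if (is.null(samples)) seq_along(ds$samples) else samples
  genotype_dataset(ds$map[mi, , drop = FALSE],
                   ds$samples[si],
                   ds$phenotype[si],
                   ds$geno[si, mi, drop = FALSE])
}

## ---- PLINK-text ingestion -------------------------------------------------

#' Read PLINK-text genotypes (PED/MAP)
#'
#' Reads a whitespace-delimited PED file (six leading columns, then two
#' allele columns per marker) together with its four-column MAP file.
#' Alleles are recoded to alt-dosage with the minor allele *among controls*
#' taken as the alternate allele; if the controls are monomorphic at a
#' marker the overall minor allele is used, and an exact frequency tie is
#' broken toward the alphabetically later allele. The pair `0 0` (or any
#' half-missing pair) codes a missing genotype. Phenotype column six is
#' mapped 1 = control, 2 = case, anything else = unknown.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (chromosome, marker id, genetic
#'   distance, position).
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path, call. = FALSE)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nt <- lengths(map_tok)
  if (any(nt != 4L))
    format_error(map_path, which(nt != 4L)[1L], "expected 4 columns")
  map <- data.frame(
    marker_id   = vapply(map_tok, `[`, "", 2L),
    chromosome  = vapply(map_tok, `[`, "", 1L),
    position_bp = as.integer(vapply(map_tok, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(map$position_bp))
    format_error(map_path, which(is.na(map$position_bp))[1L],
                 "non-numeric position")
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  tok <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * m
  nt <- lengths(tok)
  if (any(nt != want))
    format_error(ped_path, which(nt != want)[1L],
                 sprintf("expected %d fields (6 + 2 per marker), found %d",
                         want, nt[which(nt != want)[1L]]))
  n <- length(tok)
  samples <- vapply(tok, `[`, "", 2L)
  pheno_code <- vapply(tok, `[`, "", 6L)
  phenotype <- ifelse(pheno_code == "2", "case",
               ifelse(pheno_code == "1", "control", "unknown"))

  al <- matrix("", nrow = n, ncol = 2L * m)
  for (i in seq_len(n)) al[i, ] <- tok[[i]][-(1:6)]
  ok <- matrix(al %in% c("A", "C", "G", "T", "0"), nrow = n)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    format_error(ped_path, bad[["row"]],
                 sprintf("allele symbol '%s' outside {A,C,G,T,0}",
                         al[bad[["row"]], bad[["col"]]]))
  }

  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  is_ctrl <- phenotype == "control"

  geno <- matrix(NA_integer_, n, m)
  ref_allele <- alt_allele <- character(m)
  for (j in seq_len(m)) {
    p1 <- a1[, j]; p2 <- a2[, j]
    miss <- p1 == "0" | p2 == "0"
    obs <- c(p1[!miss], p2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      format_error(ped_path, 1L,
                   sprintf("marker %s has >2 alleles", map$marker_id[j]))
    if (length(alleles) == 0L) alleles <- c("A", "A")
    if (length(alleles) == 1L) {
      ref_allele[j] <- alleles; alt_allele[j] <- alleles
      geno[!miss, j] <- 0L
      next
    }
    ctrl_obs <- c(p1[is_ctrl & !miss], p2[is_ctrl & !miss])
    counts <- if (length(unique(ctrl_obs)) >= 2L)
      table(factor(ctrl_obs, levels = alleles))
    else
      table(factor(obs, levels = alleles))
    # minor allele becomes alt; ties fall to the alphabetically later allele
    alt <- if (counts[[1L]] < counts[[2L]]) alleles[1L] else alleles[2L]
    ref <- setdiff(alleles, alt)
    alt_allele[j] <- alt; ref_allele[j] <- ref
    g <- (p1 == alt) + (p2 == alt)
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  map$ref_allele <- ref_allele
  map$alt_allele <- alt_allele
  genotype_dataset(map, samples, phenotype, geno)
}

#' Write a genotype dataset as PED/MAP
#'
#' Inverse of [read_genotypes()]: emits the four-column MAP and a PED file
#' with dummy family/parent/sex columns. Allele letters are taken from the
#' map's `ref_allele`/`alt_allele` columns (defaulting to A/G).
#'
#' @param ds a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, `ds`.
#' @export
write_genotypes <- function(ds, ped_path, map_path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  map <- ds$map
  ref <- map$ref_allele %||% rep("A", nrow(map))
  alt <- map$alt_allele %||% rep("G", nrow(map))
  writeLines(sprintf("%s\t%s\t0\t%d", map$chromosome, map$marker_id,
                     map$position_bp), map_path)

  pheno_code <- c(case = "2", control = "1", unknown = "0")[ds$phenotype]
  lines <- character(length(ds$samples))
  for (i in seq_along(ds$samples)) {
    g <- ds$geno[i, ]
    p1 <- ifelse(is.na(g), "0", ifelse(g >= 1, alt, ref))
    p2 <- ifelse(is.na(g), "0", ifelse(g == 2, alt, ref))
    lines[i] <- paste(c("FAM", ds$samples[i], "0", "0", "0", pheno_code[i],
                        as.vector(rbind(p1, p2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(ds)
}
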