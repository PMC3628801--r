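#' Construct a variant table
#'
#' One row per called ALT allele of the sequenced proband, carrying the QC
#' annotations (QUAL, QD, MQ0, DP, HRun, SB) consumed by the hard-filter
#' engine. Annotations absent from the source VCF are assigned neutral
#' values that cannot trigger a filter (`qd = Inf`, `mq0 = 0`, `dp = 1`,
#' `hrun = 0`, `sb = -1`): the filters label positive evidence of a bad
#' call, so absence of evidence must not fail a record.
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype` (`"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`), and
#'   optionally `id`, `qual`, `qd`, `mq0`, `dp`, `hrun`, `sb`.
#' @return data.frame of class `variant_table`, sorted by (chrom, pos).
#' @export
variant_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "genotype")
  if (!all(need %in% names(df)))
    stop("variant table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$pos <- as.integer(df$pos)
  if (anyNA(df$pos) || any(df$pos < 1))
    stop("positions must be positive integers", call. = FALSE)
  df$id <- df$id %||% sprintf("%s:%d:%s>%s", df$chrom, df$pos, df$ref, df$alt)
  fill <- function(x, default) {
    if (is.null(x)) x <- rep(default, nrow(df))
    x
  }
  df$qual <- as.numeric(fill(df$qual, Inf))
  df$qd   <- as.numeric(fill(df$qd, Inf))
  df$mq0  <- as.integer(fill(df$mq0, 0L))
  df$dp   <- as.integer(fill(df$dp, 1L))
  df$hrun <- as.integer(fill(df$hrun, 0L))
  df$sb   <- as.numeric(fill(df$sb, -1))
  df$qual[is.na(df$qual)] <- Inf
  df$qd[is.na(df$qd)] <- Inf
  df$mq0[is.na(df$mq0)] <- 0L
  df$dp[is.na(df$dp)] <- 1L
  df$hrun[is.na(df$hrun)] <- 0L
  df$sb[is.na(df$sb)] <- -1

  if (!all(grepl("^[ACGT]+$", df$ref)) || !all(grepl("^[ACGT]+$", df$alt)))
    stop("ref/alt alleles must be non-empty DNA strings over ACGT",
         call. = FALSE)
  if (!all(df$genotype %in% c("hom_ref", "het", "hom_alt", "missing")))
    stop("genotype must be hom_ref/het/hom_alt/missing", call. = FALSE)
  if (any(df$mq0 < 0) || any(df$dp < 0) || any(df$hrun < 0))
    stop("MQ0, DP and HRun must be non-negative", call. = FALSE)

  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Classify a variant row as SNV / deletion / insertion / other
#' @param vt a `variant_table` (or compatible data.frame).
#' @return character vector.
#' @export
variant_class <- function(vt) {
  ifelse(nchar(vt$ref) == 1L & nchar(vt$alt) == 1L, "snv",
  ifelse(nchar(vt$ref) > nchar(vt$alt), "deletion",
  ifelse(nchar(vt$ref) < nchar(vt$alt), "insertion", "other")))
}

gt_string_to_code <- function(gt, alt_index = 1L) {
  # "0/1", "1|1", "./." etc -> hom_ref / het / hom_alt / missing
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    a <- strsplit(g, "[/|]")[[1L]]
    if (any(a == ".")) return("missing")
    dose <- sum(a == as.character(alt_index))
    c("hom_ref", "het", "hom_alt")[dose + 1L]
  }, "", USE.NAMES = FALSE)
}

#' Read proband variant calls from a VCF
#'
#' Reads a VCF v4.x via `vcfR` and returns one [variant_table()] row per ALT
#' allele (multi-allelic sites are split, order preserved within the file
#' ordering). The INFO keys QD, MQ0, DP, HRun and SB populate the QC
#' annotations; absent keys receive the neutral defaults described in
#' [variant_table()].
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF.
#' @param sample sample name whose GT column supplies the proband genotype;
#'   default first sample. VCFs without genotype columns yield
#'   `genotype = "missing"`.
#' @return A [variant_table()].
#' @export
read_variants <- function(vcf_path, sample = NULL) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  v <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    genotype = character())))
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    format_error(vcf_path, which(is.na(pos))[1L], "malformed POS field")
  if (!all(grepl("^[ACGT]+$", fix$REF)))
    format_error(vcf_path, which(!grepl("^[ACGT]+$", fix$REF))[1L],
                 "malformed REF allele")

  info_num <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, nrow(fix)) else x
  }
  qd <- info_num("QD"); mq0 <- info_num("MQ0"); dp <- info_num("DP")
  hrun <- info_num("HRun"); sb <- info_num("SB")
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  gts <- NULL
  if (ncol(v@gt) >= 2L) {
    g <- vcfR::extract.gt(v, element = "GT")
    col <- if (is.null(sample)) 1L else match(sample, colnames(g))
    if (is.na(col)) stop("sample not found in VCF: ", sample, call. = FALSE)
    gts <- g[, col]
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    if (!all(grepl("^[ACGT]+$", alts)))
      format_error(vcf_path, i, "malformed ALT allele")
    geno <- if (is.null(gts)) rep("missing", length(alts))
            else vapply(seq_along(alts),
                        function(k) gt_string_to_code(gts[i], k), "")
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts,
      genotype = geno, qual = qual[i], qd = qd[i], mq0 = mq0[i],
      dp = dp[i], hrun = hrun[i], sb = sb[i], stringsAsFactors = FALSE)
  }
  variant_table(do.call(rbind, rows))
}

#' Write a variant table as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with the QC annotations in INFO and a
#' single genotype column. Used by the simulator; [read_variants()] is its
#' inverse.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @param sample genotype column name.
#' @return Invisibly, `path`.
#' @export
write_variants_vcf <- function(vt, path, sample = "PROBAND") {
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
          missing = "./.")[vt$genotype]
  info <- sprintf("DP=%d;QD=%s;MQ0=%d;HRun=%d;SB=%s",
                  vt$dp, format(vt$qd, trim = TRUE, digits = 6),
                  vt$mq0, vt$hrun, format(vt$sb, trim = TRUE, digits = 6))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Reads with MQ 0\">",
           "##INFO=<ID=HRun,Number=1,Type=Integer,Description=\"Homopolymer run\">",
           "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- paste(vt$chrom, vt$pos, vt$id, vt$ref, vt$alt,
                format(vt$qual, trim = TRUE, digits = 8), ".", info, "GT", gt,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct panel genotypes for the absence-from-panel step
#'
#' @param geno matrix of codes (`"hom_ref"`, `"het"`, `"hom_alt"`,
#'   `"missing"`), variants in rows (rownames = variant ids), panel samples
#'   in columns.
#' @return Object of class `panel_genotypes`.
#' @export
panel_genotypes <- function(geno) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c("hom_ref", "het", "hom_alt", "missing")))
    stop("panel genotypes must be hom_ref/het/hom_alt/missing", call. = FALSE)
  if (is.null(rownames(geno)))
    stop("panel genotype matrix needs variant ids as rownames", call. = FALSE)
  structure(list(geno = geno, panel_size = ncol(geno)),
            class = "panel_genotypes")
}
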