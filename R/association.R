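#' Allelic chi-square test on a 2x2 allele-count table
#'
#' Pearson chi-square with 1 df and no continuity correction on the table
#' of alt/ref allele counts in cases versus controls (the classic allelic
#' association test). A table with a zero margin is returned as
#' `chi2 = 0, p = 1` with `degenerate = TRUE` rather than an error, since
#' monomorphic markers can survive QC only in edge cases.
#'
#' @param case_alt,case_ref,control_alt,control_ref allele counts.
#' @return list with `chi2`, `p`, `degenerate`.
#' @export
allelic_chi2 <- function(case_alt, case_ref, control_alt, control_ref) {
  a <- case_alt; b <- case_ref; c <- control_alt; d <- control_ref
  if (any(c(a, b, c, d) < 0)) stop("allele counts must be non-negative",
                                   call. = FALSE)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

## Allele counts per marker for a given case index set; missing genotypes
## drop both of a sample's alleles at that marker.
allele_counts <- function(geno, rows) {
  g <- geno[rows, , drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  called <- colSums(!is.na(g))
  cbind(alt = alt, ref = 2 * called - alt)
}

## Vectorized chi-square over matrices of counts (rows = units).
chi2_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  x <- a * d - b * c
  chi2 <- n * x * x / denom
  chi2[denom <= 0] <- 0       # zero margin: degenerate table
  chi2
}

#' Per-marker allelic association scan
#'
#' Runs [allelic_chi2()] at every marker of a (QC-passed) dataset, cases
#' versus controls, excluding missing genotypes marker-wise. Results are
#' ordered as the marker map.
#'
#' @param ds a [genotype_dataset()] with at least one case and one control.
#' @return data.frame of class `gwas_scan` with columns `marker_id`,
#'   `chromosome`, `position_bp`, `case_alt`, `case_ref`, `control_alt`,
#'   `control_ref`, `chi2`, `p_raw` (and `p_corrected` once
#'   [max_t_permutation()] has been applied).
#' @seealso [max_t_permutation()], [genomic_inflation()]
#' @export
run_gwas <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (nrow(ds$map) == 0L) stop("empty dataset", call. = FALSE)
  if (n_cases(ds) == 0 || n_controls(ds) == 0)
    stop("association requires at least one case and one control",
         call. = FALSE)
  cc <- allele_counts(ds$geno, case_rows(ds))
  kk <- allele_counts(ds$geno, control_rows(ds))
  chi2 <- chi2_vec(cc[, "alt"], cc[, "ref"], kk[, "alt"], kk[, "ref"])
  res <- data.frame(marker_id = ds$map$marker_id,
                    chromosome = ds$map$chromosome,
                    position_bp = ds$map$position_bp,
                    case_alt = cc[, "alt"], case_ref = cc[, "ref"],
                    control_alt = kk[, "alt"], control_ref = kk[, "ref"],
                    chi2 = chi2,
                    p_raw = stats::pchisq(chi2, 1, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gwas_scan", "data.frame")
  res
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan: %d markers, min p_raw = %.3g (%s)\n",
              nrow(x), min(x$p_raw), x$marker_id[which.min(x$p_raw)]))
  cat(sprintf("  genomic inflation lambda = %.3f\n", genomic_inflation(x$chi2)))
  if (!is.null(x$p_corrected))
    cat(sprintf("  min corrected p = %.3g\n", min(x$p_corrected)))
  invisible(x)
}

#' Manhattan-style plot of a scan
#' @param x a `gwas_scan`.
#' @param ... passed to [plot()].
#' @export
plot.gwas_scan <- function(x, ...) {
  plot(x$position_bp / 1e6, -log10(x$p_raw), pch = 20, cex = 0.4,
       xlab = "position (Mb)", ylab = expression(-log[10](p)), ...)
  invisible(x)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)`; the null median of a 1-df
#' chi-square is 0.4549364. Values well above 1 indicate stratification or
#' cryptic relatedness.
#'
#' @param chi2_values numeric vector of per-marker 1-df chi-square values.
#' @return lambda.
#' @export
genomic_inflation <- function(chi2_values) {
  if (length(chi2_values) == 0L) stop("empty chi-square vector", call. = FALSE)
  stats::median(chi2_values) / stats::qchisq(0.5, df = 1)
}

#' Family-wise (max-T) permutation correction
#'
#' Permutes the phenotype labels (genotypes fixed), recomputes the allelic
#' chi-square at every marker, and records the genome-wide maximum per
#' permutation. Each marker's corrected p-value is
#' `(1 + #\{permutation maxima >= observed chi2\}) / (1 + n_perm)`, the
#' add-one estimator that avoids reporting zero.
#'
#' The permutation stream depends only on (`seed`, `n_perm`, number of
#' samples), so the output is reproducible bit-for-bit.
#'
#' @param ds a [genotype_dataset()].
#' @param n_perm number of permutations (default 100000).
#' @param seed RNG seed (required).
#' @param scan optional precomputed [run_gwas()] result for `ds`.
#' @param block permutations per vectorized block (memory/time trade-off).
#' @return The `gwas_scan` with a `p_corrected` column appended, plus
#'   attribute `perm_max` holding the permutation maxima.
#' @export
max_t_permutation <- function(ds, n_perm = 100000, seed, scan = NULL,
                              block = 2000L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!is_count(n_perm) || n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required for permutation", call. = FALSE)
  if (is.null(scan)) scan <- run_gwas(ds)

  cc <- ds$phenotype %in% c("case", "control")
  idx <- which(cc)
  nk <- length(idx)
  ncase <- n_cases(ds)
  D <- ds$geno[idx, , drop = FALSE]
  M <- 1 * !is.na(D)
  D[is.na(D)] <- 0L
  tot_alt <- colSums(D)
  tot_n <- colSums(M)

  set.seed(seed)
  perm_max <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    P <- matrix(0, nb, nk)
    for (i in seq_len(nb)) P[i, sample.int(nk, ncase)] <- 1
    case_alt <- P %*% D
    case_n <- P %*% M
    case_ref <- 2 * case_n - case_alt
    ctrl_alt <- rep(tot_alt, each = nb) - case_alt
    ctrl_ref <- 2 * (rep(tot_n, each = nb) - case_n) - ctrl_alt
    chi2 <- chi2_vec(case_alt, case_ref, ctrl_alt, ctrl_ref)
    dim(chi2) <- c(nb, ncol(D))
    jmax <- max.col(chi2, ties.method = "first")
    perm_max[done + seq_len(nb)] <- chi2[cbind(seq_len(nb), jmax)]
    done <- done + nb
  }

  counts <- vapply(scan$chi2,
                   function(x) sum(perm_max >= x - 1e-12), 0)
  scan$p_corrected <- (1 + counts) / (1 + n_perm)
  attr(scan, "perm_max") <- perm_max
  scan
}
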