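#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test on one biallelic marker's genotype
#' counts: given the observed allele counts, the probability of each
#' possible heterozygote count is computed under random mating, and the
#' p-value is the sum of the probabilities of all configurations no more
#' probable than the observed one (the convention of PLINK's `--hwe`; no
#' mid-p correction). A monomorphic marker returns 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, total
#'   > 0).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (!is_count(n_hom_ref) || !is_count(n_het) || !is_count(n_hom_alt))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)

  rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  if (rare == 0L || rare == 2L * n) return(1.0)

  # heterozygote counts share the parity of the rare-allele count
  h_max <- min(rare, 2L * n - rare)
  h_vals <- seq.int(rare %% 2L, h_max, by = 2L)

  # unnormalized probabilities via the ratio recurrence, anchored mid-range
  k <- length(h_vals)
  logp <- numeric(k)
  mid <- which.min(abs(h_vals - rare * (2 * n - rare) / (2 * n)))
  for (i in seq.int(mid + 1L, length.out = max(0L, k - mid))) {
    h <- h_vals[i - 1L]
    hr <- (rare - h) / 2         # rare homozygotes at h
    hc <- (2L * n - rare - h) / 2
    # P(h+2)/P(h) = 4*hr*hc / ((h+1)(h+2))
    logp[i] <- logp[i - 1L] + log(4 * hr * hc) - log((h + 1) * (h + 2))
  }
  for (i in seq.int(mid - 1L, length.out = max(0L, mid - 1L), by = -1L)) {
    h <- h_vals[i + 1L]
    hr <- (rare - h) / 2
    hc <- (2L * n - rare - h) / 2
    # P(h-2)/P(h) = h(h-1) / (4*(hr+1)(hc+1))
    logp[i] <- logp[i + 1L] + log(h * (h - 1)) - log(4 * (hr + 1) * (hc + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, h_vals)]
  min(1.0, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Marker quality control
#'
#' Applies the pre-association exclusion rules: samples with call rate
#' below `call_rate_min` are dropped first, then markers are excluded when
#' (computed on the remaining samples) their call rate is below
#' `call_rate_min`, their minor allele frequency over all samples is below
#' `maf_min`, or the exact Hardy-Weinberg test in the controls falls below
#' `hwe_alpha`. The fixed order makes the per-marker audit trail
#' deterministic; a marker can carry several exclusion reasons.
#'
#' @param ds a [genotype_dataset()]; must contain at least one control.
#' @param call_rate_min minimum call rate (default 0.90), applied to both
#'   samples and markers.
#' @param maf_min minimum minor allele frequency (default 0.05), computed
#'   over non-missing genotypes of all retained samples.
#' @param hwe_alpha Hardy-Weinberg exclusion threshold in controls
#'   (default 1e-5).
#' @return list with `dataset` (retained markers/samples), `qc` (per-marker
#'   audit data.frame: `marker_id`, `call_rate`, `maf`, `hwe_p_controls`,
#'   `excluded`, `exclusion_reasons`), and `samples_removed`.
#' @export
qc_filter <- function(ds, call_rate_min = 0.90, maf_min = 0.05,
                      hwe_alpha = 1e-5) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_controls(ds) == 0)
    stop("marker QC requires at least one control (for the HWE term)",
         call. = FALSE)

  sample_cr <- rowMeans(!is.na(ds$geno))
  keep_s <- sample_cr >= call_rate_min
  removed_samples <- ds$samples[!keep_s]
  if (!all(keep_s)) ds <- subset_dataset(ds, samples = keep_s)
  if (n_controls(ds) == 0)
    stop("all controls removed by the sample call-rate filter", call. = FALSE)

  g <- ds$geno
  ctrl <- control_rows(ds)
  m <- ncol(g)

  call_rate <- colMeans(!is.na(g))
  alt_count <- colSums(g, na.rm = TRUE)
  n_called <- colSums(!is.na(g))
  alt_freq <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  maf[is.na(maf)] <- 0

  hwe_p <- vapply(seq_len(m), function(j) {
    gc <- g[ctrl, j]
    gc <- gc[!is.na(gc)]
    if (length(gc) == 0L) return(1.0)
    hwe_exact_test(sum(gc == 0L), sum(gc == 1L), sum(gc == 2L))
  }, 0)

  reasons <- lapply(seq_len(m), function(j) {
    r <- character()
    if (call_rate[j] < call_rate_min) r <- c(r, "low_call_rate")
    if (maf[j] < maf_min) r <- c(r, "low_maf")
    if (hwe_p[j] < hwe_alpha) r <- c(r, "hwe_deviation")
    r
  })
  excluded <- lengths(reasons) > 0L

  qc <- data.frame(marker_id = ds$map$marker_id, call_rate = call_rate,
                   maf = maf, hwe_p_controls = hwe_p, excluded = excluded,
                   stringsAsFactors = FALSE)
  qc$exclusion_reasons <- reasons

  list(dataset = subset_dataset(ds, markers = !excluded),
       qc = qc,
       samples_removed = removed_samples)
}
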