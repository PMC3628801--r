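#' Construct a cohort genotype table
#'
#' Genotype counts for one candidate variant across the validation cohort
#' groups (affected cases, controls of the mapped breed, dogs of other
#' breeds). Individuals with failed genotyping assays are tracked in
#' `n_failed` and excluded from every denominator.
#'
#' @param variant_id identifier.
#' @param counts 3x3 numeric matrix (or data.frame), rows `cases`,
#'   `breed_controls`, `other_breeds`; columns `hom_ref`, `het`, `hom_alt`.
#' @param n_failed count of failed assays.
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(variant_id, counts, n_failed = 0L) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(c("cases", "breed_controls", "other_breeds"),
                           c("hom_ref", "het", "hom_alt"))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(variant_id = variant_id, counts = counts,
                 n_failed = as.integer(n_failed)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table %s (n_failed = %d)\n", x$variant_id, x$n_failed))
  print(x$counts)
  invisible(x)
}

#' Recessive full-penetrance concordance
#'
#' A variant is perfectly associated under a fully penetrant recessive
#' model iff every case is homozygous-alt and no control (breed or other)
#' is homozygous-alt. Carrier (heterozygous) controls are expected for a
#' recessive allele and do not count as violations.
#'
#' @param gt a [genotype_table()] with at least one case.
#' @return list with `concordant` and `n_violations` (cases not hom-alt
#'   plus hom-alt controls).
#' @export
recessive_concordance <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  cs <- gt$counts["cases", ]
  if (sum(cs) == 0) stop("at least one case required", call. = FALSE)
  bad_cases <- cs[["hom_ref"]] + cs[["het"]]
  bad_controls <- gt$counts["breed_controls", "hom_alt"] +
    gt$counts["other_breeds", "hom_alt"]
  n_viol <- bad_cases + bad_controls
  list(concordant = n_viol == 0, n_violations = as.integer(n_viol))
}

#' Carrier frequency in a cohort group
#'
#' Proportion of heterozygotes among successfully genotyped individuals of
#' the group: `n_het / (n_hom_ref + n_het + n_hom_alt)`.
#'
#' @param gt a [genotype_table()].
#' @param group `"breed_controls"` or `"other_breeds"`.
#' @return fraction in \[0, 1\].
#' @export
carrier_frequency <- function(gt, group = c("breed_controls",
                                            "other_breeds")) {
  stopifnot(inherits(gt, "genotype_table"))
  group <- match.arg(group)
  g <- gt$counts[group, ]
  tot <- sum(g)
  if (tot == 0) stop("no genotyped individuals in group ", group,
                     call. = FALSE)
  g[["het"]] / tot
}

#' Format a carrier frequency as the conventional percentage
#' @param f fraction from [carrier_frequency()].
#' @return string, one decimal (e.g. `"6.2%"`).
#' @export
format_carrier_frequency <- function(f) {
  sprintf("%.1f%%", round_half_up(100 * f, 1))
}

#' Squared genotype correlation (LD) between two variants
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors over the samples
#' non-missing at both loci — the standard genotype r-squared measure of
#' linkage disequilibrium. Two variants carried by exactly the same
#' individuals (perfect LD) give r-squared 1.
#'
#' @param geno_a,geno_b equal-length dosage vectors (0/1/2, `NA` missing).
#' @return r-squared in \[0, 1\].
#' @export
genotype_r2 <- function(geno_a, geno_b) {
  if (length(geno_a) != length(geno_b))
    stop("dosage vectors must have equal length", call. = FALSE)
  ok <- !is.na(geno_a) & !is.na(geno_b)
  if (sum(ok) < 2)
    stop("need at least two samples genotyped at both loci", call. = FALSE)
  a <- geno_a[ok]; b <- geno_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD is undefined at a monomorphic locus", call. = FALSE)
  stats::cor(a, b)^2
}
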