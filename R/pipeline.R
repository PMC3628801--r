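#' Run the full mapping pipeline on a simulated cohort
#'
#' End-to-end orchestration of the recessive-trait mapping workflow on
#' synthetic data with planted ground truth: simulate the cohort, apply
#' marker QC, run the allelic association scan with max-T permutation
#' correction, find the shared-homozygosity run and delineate the critical
#' interval, run the variant prioritization cascade, annotate the surviving
#' candidates, and compute the segregation report on the validation cohort.
#'
#' @param cfg a [sim_config()] (its seed drives every stochastic step).
#' @param n_perm permutations for the max-T correction (default 10000; the
#'   permutation correction is the one genuinely expensive step and scales
#'   linearly).
#' @param min_markers minimum shared-run length considered a mapping signal
#'   (default 10).
#' @param out_dir optional directory; when given, PED/MAP, the proband VCF,
#'   the interval BED and the per-stage TSV reports are written there.
#' @return list of class `recessmap_pipeline` with elements `config`,
#'   `qc`, `scan`, `lambda`, `run`, `interval`, `cascade`, `consequences`
#'   (calls for the surviving candidates), `segregation`, `truth`.
#' @export
run_pipeline <- function(cfg, n_perm = 10000L, min_markers = 10L,
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))

  sim <- simulate_cohort(cfg)
  qc <- qc_filter(sim$dataset)
  ds <- qc$dataset

  scan <- run_gwas(ds)
  scan <- max_t_permutation(ds, n_perm = n_perm, seed = cfg$seed + 3L,
                            scan = scan)
  lambda <- genomic_inflation(scan$chi2)

  mapping <- map_critical_interval(ds, min_markers = min_markers)
  if (is.null(mapping))
    stop("pipeline stage 'autozygosity' failed: no shared run of >= ",
         min_markers, " markers", call. = FALSE)

  vars <- simulate_variants(cfg, sim$truth)
  cascade <- run_cascade(vars$variants, mapping$interval, vars$panel,
                         vars$consequences)

  cons <- vars$consequences[cascade$surviving]
  cohort <- simulate_validation_cohort(cfg, vars$truth)
  seg <- list(
    concordance = lapply(cohort$tables, recessive_concordance),
    carrier_frequency = vapply(cohort$tables, carrier_frequency, 0,
                               group = "breed_controls"),
    r2 = genotype_r2(cohort$dosages$causal, cohort$dosages$passenger))

  out <- structure(list(config = cfg, qc = qc$qc, scan = scan,
                        lambda = lambda, run = mapping$run,
                        interval = mapping$interval, cascade = cascade,
                        consequences = cons, segregation = seg,
                        truth = vars$truth),
                   class = "recessmap_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(ds, file.path(out_dir, "cohort.ped"),
                    file.path(out_dir, "cohort.map"))
    write_variants_vcf(vars$variants, file.path(out_dir, "proband.vcf"))
    write_interval_bed(mapping$interval,
                       file.path(out_dir, "critical_interval.bed"))
    utils::write.table(as.data.frame(scan),
                       file.path(out_dir, "gwas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cascade$steps, file.path(out_dir, "cascade.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(interval_report(list(mapping$interval)),
                       file.path(out_dir, "intervals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.recessmap_pipeline <- function(x, ...) {
  cat("recessive-trait mapping pipeline (synthetic cohort)\n")
  cat(sprintf("  seed %d | %d cases / %d controls | %d markers pre-QC\n",
              x$config$seed, x$config$n_cases, x$config$n_controls,
              x$config$n_markers))
  cat(sprintf("  markers retained after QC: %d\n", nrow(x$qc) - sum(x$qc$excluded)))
  cat(sprintf("  best raw p = %.3g, corrected p = %.3g, lambda = %.2f\n",
              min(x$scan$p_raw), min(x$scan$p_corrected), x$lambda))
  print(x$interval)
  print(x$cascade)
  for (id in names(x$consequences)) {
    cq <- x$consequences[[id]]
    if (inherits(cq, "consequence_call"))
      cat(sprintf("  %s: %s %s [%s]\n", id, cq$hgvs_c, cq$hgvs_p, cq$effect))
  }
  cat(sprintf("  carrier frequency (breed controls): %s | candidate r2 = %.2f\n",
              format_carrier_frequency(x$segregation$carrier_frequency[["causal"]]),
              x$segregation$r2))
  invisible(x)
}
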