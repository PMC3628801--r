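#' Hard-filter labels for variant calls
#'
#' Applies the rule-based call filters used on raw whole-genome variant
#' calls, returning per-variant label sets; an empty set means PASS.
#'
#' * `HardToValidate`: `MQ0 >= 4 & (MQ0 / DP) > 0.1` (with `DP == 0` and
#'   `MQ0 > 0` treated as failing, the ratio being unbounded).
#' * `LowQual`: `QUAL < 30 | QD < 5 | HRun > 5 | SB > 0` (strict: SB
#'   exactly 0 passes).
#' * `SnpCluster`: assigned by [flag_snp_clusters()] and merged by
#'   [run_cascade()].
#'
#' @param vt a [variant_table()] (or a single-row compatible data.frame).
#' @return list of character vectors, one per variant.
#' @export
hard_filter_label <- function(vt) {
  ratio_bad <- ifelse(vt$dp > 0, vt$mq0 / vt$dp > 0.1, vt$mq0 > 0)
  hard <- vt$mq0 >= 4 & ratio_bad
  lowq <- vt$qual < 30.0 | vt$qd < 5.0 | vt$hrun > 5L | vt$sb > 0.00
  lapply(seq_len(nrow(vt)), function(i) {
    c(character(0), if (hard[i]) "HardToValidate", if (lowq[i]) "LowQual")
  })
}

#' Flag SNV clusters
#'
#' A variant is flagged when it belongs to any window of at least
#' `cluster_size` SNVs spanning at most `window_bp` base pairs on one
#' chromosome. Indels neither count toward clusters nor get flagged.
#'
#' @param vt a [variant_table()] sorted by (chromosome, position); unsorted
#'   input is an error.
#' @param window_bp window span in bp (default 10).
#' @param cluster_size minimum SNVs per window (default 3).
#' @return logical vector, one per variant.
#' @export
flag_snp_clusters <- function(vt, window_bp = 10L, cluster_size = 3L) {
  n <- nrow(vt)
  if (n == 0L) return(logical(0))
  ord_ok <- all(vapply(split(seq_len(n), vt$chrom), function(i)
    !is.unsorted(vt$pos[i]), TRUE)) &&
    !is.unsorted(match(vt$chrom, unique(vt$chrom)))
  if (!ord_ok) stop("variants must be sorted by (chromosome, position)",
                    call. = FALSE)
  flagged <- logical(n)
  is_snv <- variant_class(vt) == "snv"
  for (chr in unique(vt$chrom)) {
    idx <- which(vt$chrom == chr & is_snv)
    k <- length(idx)
    if (k < cluster_size) next
    pos <- vt$pos[idx]
    for (i in seq_len(k - cluster_size + 1L)) {
      j <- i + cluster_size - 1L
      if (pos[j] - pos[i] <= window_bp)
        flagged[idx[i:j]] <- TRUE
    }
  }
  flagged
}

#' Run the variant prioritization cascade
#'
#' The positional-candidate funnel for a recessive trait, applied to the
#' proband's variant calls:
#'
#' 1. `filter_pass` — drop calls with any hard-filter or SNV-cluster label;
#' 2. `total_homozygous` — keep homozygous-alt calls (the affected
#'    individual must be homozygous for a recessive causal allele);
#' 3. `in_interval` — keep calls inside the critical interval (closed
#'    bounds, matching chromosome);
#' 4. `absent_from_panel` — keep calls whose alt allele is absent from
#'    every panel genome (any het or hom-alt panel genotype excludes;
#'    missing panel genotypes do not exclude, but are counted for audit);
#' 5. `nonsynonymous` — keep calls whose coding consequence is missense,
#'    nonsense or frameshift.
#'
#' Steps 2-5 are pure intersections, so their order does not change the
#' surviving set; the fixed order reproduces the conventional funnel
#' report. Counts are checked to be non-increasing on every run.
#'
#' @param vt a [variant_table()].
#' @param interval a [critical_interval()].
#' @param panel a [panel_genotypes()] covering (at least) the in-interval
#'   variants; variants absent from the panel matrix are treated as
#'   panel-missing.
#' @param consequences named list of [consequence_call()] objects (or a
#'   character vector of effect classes), keyed by variant id; required for
#'   coding variants reaching step 5, others default to `"other"`.
#' @return Object of class `cascade_report`: `steps` (data.frame of
#'   step/n_variants), `surviving` (character ids after the last step),
#'   `survivors_by_step` (list), `n_panel_missing` (named count of missing
#'   panel genotypes among step-4 survivors).
#' @export
run_cascade <- function(vt, interval, panel, consequences = list()) {
  stopifnot(inherits(interval, "critical_interval"))
  n <- nrow(vt)
  if (n > 0 && !any(vt$chrom == interval$chromosome))
    stop("no variant shares the interval's chromosome name '",
         interval$chromosome, "': naming-convention mismatch?",
         call. = FALSE)

  labels <- hard_filter_label(vt)
  clustered <- flag_snp_clusters(vt)
  pass <- lengths(labels) == 0L & !clustered

  effect_of <- function(ids) {
    vapply(ids, function(id) {
      cq <- consequences[[id]]
      if (is.null(cq)) "other"
      else if (is.character(cq)) cq
      else cq$effect
    }, "")
  }

  s0 <- vt$id[pass]
  s1 <- vt$id[pass & vt$genotype == "hom_alt"]
  in_iv <- vt$chrom == interval$chromosome &
    vt$pos >= interval$start_bp & vt$pos <= interval$end_bp
  s2 <- intersect(s1, vt$id[in_iv])

  panel_absent <- function(id) {
    if (!id %in% rownames(panel$geno)) return(TRUE)  # uncovered = missing
    g <- panel$geno[id, ]
    !any(g %in% c("het", "hom_alt"))
  }
  s3 <- s2[vapply(s2, panel_absent, TRUE)]
  n_panel_missing <- vapply(s3, function(id) {
    if (!id %in% rownames(panel$geno)) return(panel$panel_size)
    sum(panel$geno[id, ] == "missing")
  }, 0)

  s4 <- s3[effect_of(s3) %in% c("missense", "nonsense", "frameshift")]

  steps <- data.frame(
    step = c("filter_pass", "total_homozygous", "in_interval",
             "absent_from_panel", "nonsynonymous"),
    n_variants = c(length(s0), length(s1), length(s2), length(s3),
                   length(s4)),
    stringsAsFactors = FALSE)
  if (is.unsorted(rev(steps$n_variants)))
    stop("internal error: cascade counts increased", call. = FALSE)

  structure(list(steps = steps, surviving = s4,
                 survivors_by_step = list(filter_pass = s0,
                                          total_homozygous = s1,
                                          in_interval = s2,
                                          absent_from_panel = s3,
                                          nonsynonymous = s4),
                 n_panel_missing = n_panel_missing),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("variant prioritization cascade\n")
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  %-18s %6d\n", x$steps$step[i], x$steps$n_variants[i]))
  if (length(x$surviving))
    cat("  candidates:", paste(x$surviving, collapse = ", "), "\n")
  invisible(x)
}
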