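#' Find runs of shared homozygosity across cases
#'
#' Scans each chromosome for maximal runs of consecutive markers at which
#' every case is homozygous for the same allele. A marker is compatible
#' with a run iff no case is heterozygous and all non-missing case
#' genotypes are the same homozygote; markers where every case is missing
#' break a run (a run cannot be carried by missing data alone), while
#' individual missing genotypes are treated as compatible, so routine array
#' missingness does not shatter true identical-by-descent segments.
#'
#' Under a fully penetrant recessive model all affected individuals are
#' identical by descent for the causal allele and its flanking haplotype,
#' so the causal mutation must lie inside one such run.
#'
#' @param ds a [genotype_dataset()] with at least two cases.
#' @param min_markers minimum run length in markers (shorter runs dropped).
#' @return list of `shared_run` objects, each with `chromosome`,
#'   `first_marker_index` / `last_marker_index` (into the full marker map),
#'   `n_markers` and `shared_allele_per_marker` (`"ref"`/`"alt"`, `NA`
#'   where all cases are missing is impossible by construction).
#' @export
find_shared_runs <- function(ds, min_markers = 1L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_cases(ds) == 0) stop("no cases in dataset", call. = FALSE)
  m <- ncol(ds$geno)
  if (m == 0L) return(list())
  comp <- case_compatibility(ds)
  compatible <- comp$compatible
  shared <- comp$shared

  runs <- list()
  chroms <- ds$map$chromosome
  r <- rle(paste(chroms, compatible))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    i1 <- starts[k]; i2 <- ends[k]
    if (!compatible[i1]) next
    if (i2 - i1 + 1L < min_markers) next
    runs[[length(runs) + 1L]] <- structure(
      list(chromosome = chroms[i1],
           first_marker_index = i1, last_marker_index = i2,
           n_markers = i2 - i1 + 1L,
           shared_allele_per_marker = shared[i1:i2]),
      class = "shared_run")
  }
  runs
}

## per-marker shared-homozygosity state of the cases: a marker is
## compatible iff no case is heterozygous, all non-missing case genotypes
## are the same homozygote, and at least one case is non-missing
case_compatibility <- function(ds) {
  g <- ds$geno[case_rows(ds), , drop = FALSE]
  any_het <- colSums(g == 1L, na.rm = TRUE) > 0L
  any_ref <- colSums(g == 0L, na.rm = TRUE) > 0L
  any_alt <- colSums(g == 2L, na.rm = TRUE) > 0L
  all_missing <- colSums(!is.na(g)) == 0L
  list(compatible = unname(!any_het & !(any_ref & any_alt) & !all_missing),
       shared = unname(ifelse(any_alt, "alt",
                              ifelse(any_ref, "ref", NA_character_))))
}

#' @export
print.shared_run <- function(x, ...) {
  cat(sprintf("shared_run %s: markers %d-%d (%d markers)\n", x$chromosome,
              x$first_marker_index, x$last_marker_index, x$n_markers))
  invisible(x)
}

#' Delineate the critical interval around a shared run
#'
#' The critical interval is bounded by the closest markers violating the
#' shared-homozygosity criterion on either side of the run (in an
#' association study these are the nearest heterozygous/discordant
#' markers). Where the run touches a chromosome end, the terminal run
#' marker's position is used and the corresponding truncation flag is set.
#'
#' @param run a `shared_run` from [find_shared_runs()].
#' @param ds the [genotype_dataset()] the run was found in.
#' @return A [critical_interval()].
#' @export
delineate_interval <- function(run, ds) {
  stopifnot(inherits(run, "shared_run"), inherits(ds, "genotype_dataset"))
  map <- ds$map
  i1 <- run$first_marker_index; i2 <- run$last_marker_index
  if (i1 < 1L || i2 > nrow(map) || i1 > i2)
    stop("run indices out of range", call. = FALSE)
  chrom <- run$chromosome
  left_ok <- i1 > 1L && map$chromosome[i1 - 1L] == chrom
  right_ok <- i2 < nrow(map) && map$chromosome[i2 + 1L] == chrom
  start_bp <- if (left_ok) map$position_bp[i1 - 1L] else map$position_bp[i1]
  end_bp <- if (right_ok) map$position_bp[i2 + 1L] else map$position_bp[i2]
  critical_interval(chrom, start_bp, end_bp, n_core_markers = run$n_markers,
                    truncated_left = !left_ok, truncated_right = !right_ok)
}

#' Map the critical interval from the longest shared run
#'
#' The mapping step of the pipeline: finds the longest run of shared case
#' homozygosity and delineates its critical interval. By default, isolated
#' discordant markers — a single marker violating the sharing criterion,
#' flanked by at least `bridge_flank` compatible markers on each side —
#' are bridged before the longest run is selected. A single genotyping
#' error in one case is enough to break a true identical-by-descent
#' segment under the strict criterion, and standard
#' runs-of-homozygosity callers tolerate such isolated discordances for
#' exactly this reason; a genuine segment boundary is followed by a dense
#' stretch of discordant markers and is never bridged. Set
#' `max_bridge = 0` for the strict behaviour of [find_shared_runs()].
#'
#' Interval bounds come from the nearest *unbridged* discordant marker on
#' either side (or the chromosome-end marker, with a truncation flag).
#'
#' @inheritParams find_shared_runs
#' @param max_bridge maximum width (markers) of a discordant gap to bridge
#'   (default 1: isolated single markers only).
#' @param bridge_flank compatible markers required on each side of a
#'   bridged marker (default 5).
#' @return list with `run` (a `shared_run`; bridged markers counted in
#'   `n_markers`, ids of bridged markers in attribute `bridged`) and
#'   `interval`, or `NULL` if no run passes `min_markers`.
#' @export
map_critical_interval <- function(ds, min_markers = 1L, max_bridge = 1L,
                                  bridge_flank = 5L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_cases(ds) == 0) stop("no cases in dataset", call. = FALSE)
  m <- ncol(ds$geno)
  if (m == 0L) return(NULL)
  comp <- case_compatibility(ds)
  compatible <- comp$compatible
  chroms <- ds$map$chromosome

  bridged <- logical(m)
  if (max_bridge >= 1L) {
    r0 <- rle(paste(chroms, compatible))
    e0 <- cumsum(r0$lengths)
    s0 <- e0 - r0$lengths + 1L
    gap <- which(!compatible[s0] & r0$lengths <= max_bridge)
    for (k in gap) {
      i1 <- s0[k]; i2 <- e0[k]
      lo <- i1 - bridge_flank; hi <- i2 + bridge_flank
      if (lo < 1L || hi > m) next
      if (any(chroms[lo:hi] != chroms[i1])) next
      if (all(compatible[lo:(i1 - 1L)]) && all(compatible[(i2 + 1L):hi]))
        bridged[i1:i2] <- TRUE
    }
  }
  eff <- compatible | bridged

  r <- rle(paste(chroms, eff))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  for (k in seq_along(r$lengths)) {
    i1 <- starts[k]; i2 <- ends[k]
    if (!eff[i1]) next
    if (i2 - i1 + 1L < min_markers) next
    if (is.null(best) || i2 - i1 > best[2L] - best[1L]) best <- c(i1, i2)
  }
  if (is.null(best)) return(NULL)
  i1 <- best[1L]; i2 <- best[2L]
  # a bridged marker at a run edge is not evidence of sharing: trim
  while (i1 < i2 && bridged[i1]) i1 <- i1 + 1L
  while (i2 > i1 && bridged[i2]) i2 <- i2 - 1L
  run <- structure(
    list(chromosome = chroms[i1], first_marker_index = i1,
         last_marker_index = i2, n_markers = i2 - i1 + 1L,
         shared_allele_per_marker = ifelse(bridged[i1:i2], NA,
                                           comp$shared[i1:i2])),
    class = "shared_run")
  attr(run, "bridged") <- ds$map$marker_id[seq(i1, i2)][bridged[i1:i2]]
  list(run = run, interval = delineate_interval(run, ds))
}
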