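#' Construct a critical interval
#'
#' The mapping result: a closed 1-based interval bounded by the nearest
#' markers violating the shared-homozygosity criterion on either side of a
#' shared run (or by the terminal marker where the run touches a chromosome
#' end, in which case the corresponding truncation flag is set).
#'
#' @param chromosome chromosome name.
#' @param start_bp,end_bp closed 1-based bounds, `start_bp < end_bp`.
#' @param n_core_markers number of markers inside the shared run.
#' @param truncated_left,truncated_right whether a bound is a chromosome-end
#'   marker rather than a discordant flanking marker.
#' @return Object of class `critical_interval`.
#' @export
critical_interval <- function(chromosome, start_bp, end_bp,
                              n_core_markers = NA_integer_,
                              truncated_left = FALSE,
                              truncated_right = FALSE) {
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (!(start_bp < end_bp))
    stop("interval requires start_bp < end_bp", call. = FALSE)
  structure(list(chromosome = as.character(chromosome),
                 start_bp = start_bp, end_bp = end_bp,
                 n_core_markers = as.integer(n_core_markers),
                 truncated_left = isTRUE(truncated_left),
                 truncated_right = isTRUE(truncated_right)),
            class = "critical_interval")
}

#' @export
print.critical_interval <- function(x, ...) {
  cat(sprintf("critical interval %s:%s-%s (%s Mb, %s core markers)%s\n",
              x$chromosome, format(x$start_bp, big.mark = ","),
              format(x$end_bp, big.mark = ","),
              format_mb(x$end_bp - x$start_bp),
              ifelse(is.na(x$n_core_markers), "?", x$n_core_markers),
              if (x$truncated_left || x$truncated_right) " [truncated]" else ""))
  invisible(x)
}

format_mb <- function(bp) sprintf("%.2f", round_half_up(bp / 1e6, 2))

#' Write a critical interval as BED
#'
#' BED is 0-based half-open, so the closed 1-based interval
#' `[start_bp, end_bp]` is written as `start_bp - 1` / `end_bp`.
#'
#' @param interval a [critical_interval()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_interval_bed <- function(interval, path) {
  stopifnot(inherits(interval, "critical_interval"))
  writeLines(sprintf("%s\t%.0f\t%.0f", interval$chromosome,
                     interval$start_bp - 1, interval$end_bp), path)
  invisible(path)
}

#' Read a single-interval BED file back to 1-based closed coordinates
#' @param path BED path (first line used).
#' @return A [critical_interval()].
#' @export
read_interval_bed <- function(path) {
  ln <- strsplit(readLines(path)[1L], "\t")[[1L]]
  critical_interval(ln[1L], as.numeric(ln[2L]) + 1, as.numeric(ln[3L]))
}

#' Tabulate critical intervals with sizes in Mb
#'
#' Deterministic text table; sizes are `end_bp - start_bp` in Mb, rounded
#' half-up to two decimals (so the canonical 17,283,880-20,818,258 interval
#' prints as "3.53 Mb").
#'
#' @param intervals list of [critical_interval()] objects.
#' @return data.frame with columns `chromosome`, `start_bp`, `end_bp`,
#'   `size_mb` (formatted, e.g. `"3.53 Mb"`), `n_core_markers`.
#' @export
interval_report <- function(intervals) {
  if (inherits(intervals, "critical_interval")) intervals <- list(intervals)
  out <- data.frame(chromosome = character(), start_bp = numeric(),
                    end_bp = numeric(), size_mb = character(),
                    n_core_markers = integer(), stringsAsFactors = FALSE)
  for (iv in intervals) {
    out <- rbind(out, data.frame(
      chromosome = iv$chromosome, start_bp = iv$start_bp, end_bp = iv$end_bp,
      size_mb = paste(format_mb(iv$end_bp - iv$start_bp), "Mb"),
      n_core_markers = iv$n_core_markers, stringsAsFactors = FALSE))
  }
  out
}
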