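#' DZ-to-LZ ratio time series
#'
#' The ratio of centroblasts to non-apoptotic centrocytes at every sample
#' time, with \code{Inf} marking samples where no live centrocyte exists.
#' Optional smoothing applies a centered 24-h running median to the finite
#' part of the series (infinite samples stay infinite and are flagged).
#'
#' @param record A \code{\link{gc_run}}.
#' @param smooth Logical; apply the centered 24-h running median.
#' @return Data frame with \code{time_h}, \code{ratio}, \code{infinite}
#'   (logical) and, when \code{smooth}, \code{ratio_smooth}.
#' @export
dz_lz_series <- function(record, smooth = FALSE) {
  stopifnot(inherits(record, "gc_run"))
  ts <- record$timeseries
  out <- data.frame(time_h = ts$time_h, ratio = ts$dz_lz_ratio,
                    infinite = is.infinite(ts$dz_lz_ratio))
  if (smooth) {
    cad <- stats::median(diff(ts$time_h))
    half <- max(1L, as.integer(round(12 / cad)))
    n <- nrow(out)
    sm <- vapply(seq_len(n), function(i) {
      w <- out$ratio[max(1L, i - half):min(n, i + half)]
      w <- w[is.finite(w)]
      if (length(w)) stats::median(w) else Inf
    }, numeric(1))
    sm[out$infinite] <- Inf
    out$ratio_smooth <- sm
  }
  out
}

#' Temporal-switch metrics of plasma-cell output
#'
#' Splits plasma-cell exits at the GC peak (default day 6 = 144 h; exit times
#' strictly greater than the boundary count as "after") and summarizes memory
#' B-cell production. The switch flag operationalizes the experimentally
#' described memory-to-plasma-cell transition: at least 80 percent of PCs
#' exiting after the peak while MBC production starts before it.
#'
#' @param record A \code{\link{gc_run}}.
#' @param peak_day Day of the GC peak (boundary = \code{peak_day * 24} h).
#' @return List with \code{n_pc}, \code{n_mbc}, \code{frac_pc_before},
#'   \code{frac_pc_after} (NA and \code{defined = FALSE} when no PC exists),
#'   \code{mbc_production_span} and \code{switch_flag}.
#' @export
switch_metrics <- function(record, peak_day = 6) {
  stopifnot(inherits(record, "gc_run"))
  boundary <- peak_day * 24
  ocs <- record$output_cells
  pc_t <- ocs$exit_time_h[ocs$type == 1]
  mbc_t <- ocs$exit_time_h[ocs$type == 2]
  n_pc <- length(pc_t); n_mbc <- length(mbc_t)
  if (n_pc) {
    after <- mean(pc_t > boundary)
    before <- 1 - after
  } else {
    after <- NA_real_; before <- NA_real_
  }
  span <- if (n_mbc) range(mbc_t) else c(NA_real_, NA_real_)
  flag <- isTRUE(!is.na(after) && after >= 0.8 && n_mbc > 0 &&
                   span[1] < boundary)
  list(n_pc = n_pc, n_mbc = n_mbc,
       frac_pc_before = before, frac_pc_after = after,
       mbc_production_span = span, switch_flag = flag,
       defined = n_pc > 0)
}

#' Fold change of cumulative output between two runs
#'
#' Ratio of end-of-run cumulative counts (record_a over record_b).
#'
#' @param record_a,record_b \code{\link{gc_run}} objects.
#' @param quantity One of \code{"MBC"}, \code{"PC"}, \code{"OC"}.
#' @return List with \code{value} (\code{Inf} when b is 0 and a > 0;
#'   \code{NA} with \code{defined = FALSE} when both are 0), \code{count_a},
#'   \code{count_b}.
#' @export
fold_change <- function(record_a, record_b,
                        quantity = c("MBC", "PC", "OC")) {
  quantity <- match.arg(quantity)
  cnt <- function(r) switch(quantity,
                            MBC = r$counters$mbc,
                            PC = r$counters$pc,
                            OC = r$counters$pc + r$counters$mbc)
  a <- cnt(record_a); b <- cnt(record_b)
  value <- if (a == 0 && b == 0) NA_real_
  else if (b == 0) Inf
  else a / b
  list(value = value, count_a = a, count_b = b, defined = !(a == 0 && b == 0))
}

#' Median DZ-to-LZ ratio over an observation window
#'
#' Convenience metric: per-run median of the ratio over samples from
#' \code{from_h} onward (infinite samples participate; a run whose window is
#' entirely infinite yields \code{Inf}), then the median across runs.
#'
#' @param records List of \code{\link{gc_run}} objects.
#' @param from_h Window start (h), default 96 (day 4).
#' @return List with \code{per_run} medians and the cross-run \code{median}.
#' @export
dz_lz_window_median <- function(records, from_h = 96) {
  per <- vapply(records, function(r) {
    ts <- r$timeseries
    stats::median(ts$dz_lz_ratio[ts$time_h >= from_h])
  }, numeric(1))
  list(per_run = per, median = stats::median(per))
}
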