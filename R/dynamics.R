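#' Apical-area time series for one cell
#'
#' Holds the segmented apical area of a single cell over a time-lapse movie.
#' Summary statistics (time mean, max, min, range) are always recomputed from
#' the series via [trace_stats()], never stored.
#'
#' @param cell_id identifier.
#' @param times numeric vector, minutes, strictly increasing, length >= 2.
#' @param areas numeric vector, um^2, all > 0, same length as `times`.
#' @return object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, times, areas) {
  times <- as.numeric(times); areas <- as.numeric(areas)
  if (length(times) < 2L)
    stopf("cell_trace '%s': need at least 2 time points", cell_id)
  if (length(times) != length(areas))
    stopf("cell_trace '%s': times and areas differ in length", cell_id)
  if (any(diff(times) <= 0))
    stopf("cell_trace '%s': times must be strictly increasing", cell_id)
  if (any(!is.finite(areas)) || any(areas <= 0))
    stopf("cell_trace '%s': areas must be finite and > 0", cell_id)
  structure(list(cell_id = as.character(cell_id), times = times, areas = areas),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  s <- trace_stats(x)
  cat(sprintf("<cell_trace %s: %d frames, %.0f-%.0f min, area %.1f-%.1f um^2 (delta %.1f)>\n",
              x$cell_id, length(x$times), min(x$times), max(x$times),
              s$a_min, s$a_max, s$delta))
  invisible(x)
}

#' Per-trace summary statistics
#'
#' @param trace a [cell_trace()].
#' @return list with `a_avg` (time mean), `a_max`, `a_min`, and
#'   `delta` = a_max - a_min (um^2).
#' @export
trace_stats <- function(trace) {
  a <- trace$areas
  list(a_avg = mean(a), a_max = max(a), a_min = min(a),
       delta = max(a) - min(a))
}

#' Thresholds for apical-area dynamics classification
#'
#' Defaults follow the established cutoffs for apically constricting
#' epithelia: a cell is *decreasing* if its initial apical area lies in
#' 20-40 um^2 and its final area falls below 10 um^2; otherwise *fluctuating*
#' if its area range (delta = max - min) is >= 10 um^2; otherwise *constant*.
#' Initial/final areas are means over the first/last `edge_window` frames to
#' resist single-frame segmentation noise.
#'
#' @param fluct_delta fluctuation range cutoff, um^2.
#' @param decr_start_lo,decr_start_hi admissible initial-area range for the
#'   decreasing group, um^2.
#' @param decr_final final-area cutoff for the decreasing group, um^2.
#' @param edge_window frames averaged to estimate initial/final area.
#' @return object of class `dynamics_thresholds`.
#' @export
dynamics_thresholds <- function(fluct_delta = 10, decr_start_lo = 20,
                                decr_start_hi = 40, decr_final = 10,
                                edge_window = 3L) {
  if (!(0 < decr_final && decr_final < decr_start_lo &&
        decr_start_lo < decr_start_hi))
    stopf("need 0 < decr_final < decr_start_lo < decr_start_hi")
  assert_scalar_num(fluct_delta, "fluct_delta", lo = 0)
  if (edge_window < 1L) stopf("edge_window must be >= 1")
  structure(list(fluct_delta = fluct_delta, decr_start_lo = decr_start_lo,
                 decr_start_hi = decr_start_hi, decr_final = decr_final,
                 edge_window = as.integer(edge_window)),
            class = "dynamics_thresholds")
}

trace_edges <- function(trace, window) {
  n <- length(trace$areas)
  w <- min(as.integer(window), n)
  list(initial = mean(trace$areas[seq_len(w)]),
       final = mean(trace$areas[seq.int(n - w + 1L, n)]))
}

#' Classify one apical-area trace
#'
#' Exactly one label per trace. The decreasing predicate is evaluated first
#' (a constricting cell necessarily also has a large range); the remaining
#' cells split on the range cutoff, with the fluctuating cutoff inclusive
#' (delta exactly at the cutoff is fluctuating).
#'
#' @param trace a [cell_trace()].
#' @param thr a [dynamics_thresholds()].
#' @return one of `"constant"`, `"fluctuating"`, `"decreasing"`.
#' @export
classify_trace <- function(trace, thr = dynamics_thresholds()) {
  if (!inherits(trace, "cell_trace")) stopf("'trace' must be a cell_trace")
  s <- trace_stats(trace)
  e <- trace_edges(trace, thr$edge_window)
  if (e$initial >= thr$decr_start_lo && e$initial <= thr$decr_start_hi &&
      e$final < thr$decr_final) return("decreasing")
  if (s$delta >= thr$fluct_delta) return("fluctuating")
  "constant"
}

#' Classify a collection of traces
#'
#' @param traces list of [cell_trace()] objects.
#' @param thr a [dynamics_thresholds()].
#' @return data.frame with `cell_id` and `group`.
#' @export
classify_traces <- function(traces, thr = dynamics_thresholds()) {
  data.frame(
    cell_id = vapply(traces, function(tr) tr$cell_id, character(1)),
    group = vapply(traces, classify_trace, character(1), thr = thr),
    stringsAsFactors = FALSE)
}

#' Proportional change in apical area
#'
#' (A_t - A_avg) / A_avg per frame; dimensionless, zero time-mean by
#' construction.
#'
#' @param trace a [cell_trace()].
#' @return numeric vector, same length as the trace.
#' @export
proportional_change <- function(trace) {
  a_avg <- mean(trace$areas)
  if (!is.finite(a_avg) || a_avg <= 0)
    stopf("cell '%s': non-positive mean area, cannot normalize", trace$cell_id)
  (trace$areas - a_avg) / a_avg
}

resample_trace <- function(trace, grid) {
  if (min(grid) < min(trace$times) || max(grid) > max(trace$times))
    stopf("cell '%s': resampling grid extends beyond the trace (extrapolation forbidden)",
          trace$cell_id)
  cell_trace(trace$cell_id, grid,
             stats::approx(trace$times, trace$areas, xout = grid)$y)
}

common_grid <- function(traces) {
  g <- traces[[1L]]$times
  same <- all(vapply(traces, function(tr)
    length(tr$times) == length(g) && all(tr$times == g), logical(1)))
  if (!same) stopf("traces are not on a common time grid; resample first")
  g
}

#' Group summary of proportional-change curves
#'
#' Per classified group: cell count, proportion of all cells, and mean +/-
#' stdev curves of proportional change over the common time grid. Groups with
#' no cells are reported with count 0 and `NA` curves.
#'
#' @param traces list of [cell_trace()] on a common time grid (or pass `grid`
#'   to resample by linear interpolation; extrapolation is an error).
#' @param labels character vector of group labels, one per trace (e.g. from
#'   [classify_traces()]).
#' @param grid optional numeric time grid to resample onto.
#' @param groups group labels to summarize, in reporting order.
#' @return list with `counts`, `proportions` (percent), `curves` (data.frame:
#'   time, group, mean, sd), and `sd_range` (per-group range of the stdev
#'   curve).
#' @export
group_summary <- function(traces, labels,
                          grid = NULL,
                          groups = c("constant", "fluctuating", "decreasing")) {
  if (length(labels) != length(traces))
    stopf("one label per trace required")
  if (!is.null(grid)) traces <- lapply(traces, resample_trace, grid = grid)
  tg <- common_grid(traces)
  pc <- t(vapply(traces, proportional_change, numeric(length(tg))))
  counts <- vapply(groups, function(g) sum(labels == g), integer(1))
  curves <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(labels == g)
    if (length(idx) == 0L)
      return(data.frame(time = tg, group = g, mean = NA_real_, sd = NA_real_))
    m <- pc[idx, , drop = FALSE]
    data.frame(time = tg, group = g,
               mean = colMeans(m),
               sd = apply(m, 2L, stats::sd))
  }))
  sd_range <- lapply(groups, function(g) {
    s <- curves$sd[curves$group == g]
    if (all(is.na(s))) c(NA_real_, NA_real_) else range(s, na.rm = TRUE)
  })
  names(sd_range) <- groups
  list(counts = counts,
       proportions = 100 * counts / length(traces),
       curves = curves,
       sd_range = sd_range)
}

#' Onset of significant apical constriction
#'
#' Finds the earliest frame at which the mean apical area of fold cells is
#' significantly different from non-fold cells (Welch two-tailed t-test,
#' per frame) and remains significant at every later frame.
#'
#' @param fold_traces,nonfold_traces lists of [cell_trace()] on a common
#'   shared time grid, >= 2 cells per group.
#' @param alpha per-frame significance level (default 0.05).
#' @return list with `onset_time` (min; `NA` if never sustained),
#'   `onset_index`, and the per-frame `p_values`.
#' @export
constriction_onset <- function(fold_traces, nonfold_traces, alpha = 0.05) {
  if (length(fold_traces) < 2L || length(nonfold_traces) < 2L)
    stopf("need >= 2 cells per group")
  g1 <- common_grid(fold_traces)
  g2 <- common_grid(nonfold_traces)
  if (length(g1) != length(g2) || any(g1 != g2))
    stopf("fold and non-fold traces are on different time grids")
  m_fold <- t(vapply(fold_traces, function(tr) tr$areas, numeric(length(g1))))
  m_non <- t(vapply(nonfold_traces, function(tr) tr$areas, numeric(length(g1))))
  p <- vapply(seq_along(g1), function(j) {
    x <- m_fold[, j]; y <- m_non[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y)$p.value
  }, numeric(1))
  sig <- p < alpha
  # last FALSE, then everything after is TRUE
  sustained_from <- if (all(sig)) 1L else {
    lastF <- max(which(!sig))
    if (lastF == length(sig)) NA_integer_ else lastF + 1L
  }
  if (is.na(sustained_from))
    return(list(onset_time = NA_real_, onset_index = NA_integer_, p_values = p))
  list(onset_time = g1[sustained_from], onset_index = sustained_from,
       p_values = p)
}
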