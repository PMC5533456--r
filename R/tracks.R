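#' Cell trajectory
#'
#' Time-stamped 2D positions of one tracked cell, plus an optional group label
#' (e.g. CALI vs non-CALI region) and epithelial-layer tag for filtering out
#' peripodial cells.
#'
#' @param track_id identifier.
#' @param t numeric times (minutes), strictly increasing, length >= 2.
#' @param x,y positions (um), same length as `t`.
#' @param group optional group label.
#' @param layer optional layer tag (e.g. "disc-proper", "peripodial").
#' @return object of class `cell_track`.
#' @export
cell_track <- function(track_id, t, x, y, group = NA_character_,
                       layer = NA_character_) {
  t <- as.numeric(t)
  if (length(t) < 2L) stopf("track '%s': needs >= 2 samples", track_id)
  if (any(diff(t) <= 0)) stopf("track '%s': times must increase", track_id)
  if (length(x) != length(t) || length(y) != length(t))
    stopf("track '%s': x/y and t differ in length", track_id)
  structure(list(track_id = as.character(track_id), t = t,
                 x = as.numeric(x), y = as.numeric(y),
                 group = group, layer = layer),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track %s: %d samples over %.0f min%s>\n", x$track_id,
              length(x$t), max(x$t) - min(x$t),
              if (is.na(x$group)) "" else paste0(", group ", x$group)))
  invisible(x)
}

#' Displacement summary of a track
#'
#' Net displacement from the first position, total path length, and net
#' orientation angle.
#'
#' @param track a [cell_track()].
#' @return list with `dx`, `dy`, `net_length` (um), `path_length` (um),
#'   `orientation_deg` in (-180, 180] (NA with `orientation_defined = FALSE`
#'   for a net-stationary track).
#' @export
displacement_summary <- function(track) {
  n <- length(track$t)
  dx <- track$x[n] - track$x[1L]
  dy <- track$y[n] - track$y[1L]
  net <- sqrt(dx^2 + dy^2)
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  defined <- net > .Machine$double.eps
  list(dx = dx, dy = dy, net_length = net, path_length = path,
       orientation_deg = if (defined) atan2(dy, dx) * 180 / pi else NA_real_,
       orientation_defined = defined)
}

#' Detect persistent fold crossings in a track
#'
#' The track's side of the fold is evaluated at every sample; a crossing is a
#' change of side that is maintained for at least `persistence` consecutive
#' samples. Brief touch-and-return excursions shorter than the persistence
#' window are ignored.
#'
#' @param track a [cell_track()].
#' @param fold a [fold_line()].
#' @param persistence minimum run length (samples) for a side to count,
#'   >= 1; must not exceed the track length.
#' @return list with `crossed` (logical), `times` (crossing times, min), and
#'   `sides` (per-sample side sign, +1/-1).
#' @export
crossing_events <- function(track, fold, persistence = 3L) {
  if (persistence < 1L) stopf("persistence must be >= 1")
  n <- length(track$t)
  if (n < persistence)
    stopf("track '%s' shorter than the persistence window", track$track_id)
  d <- signed_distance(cbind(track$x, track$y), fold)
  s <- sign(d)
  # carry the previous side across exact on-line samples
  for (i in seq_len(n)) if (s[i] == 0) s[i] <- if (i > 1L) s[i - 1L] else 1
  r <- rle(s)
  keep <- r$lengths >= persistence | seq_along(r$lengths) == 1L
  vals <- r$values[keep]
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)[keep]
  times <- numeric(0)
  if (length(vals) > 1L) {
    for (i in seq_along(vals)[-1L]) {
      if (vals[i] != vals[i - 1L]) times <- c(times, track$t[starts[i]])
    }
  }
  list(crossed = length(times) > 0L, times = times, sides = s)
}

#' Compare displacement and orientation between two track groups
#'
#' Welch two-tailed unpaired t-tests on x displacement, y displacement, and
#' the orientation's cosine and sine components (component-wise rather than a
#' circular test).
#'
#' @param tracks_a,tracks_b lists of [cell_track()], >= 2 tracks per group.
#' @return data.frame with one row per tested quantity (`dx`, `dy`,
#'   `orientation_cos`, `orientation_sin`) and its p-value.
#' @export
group_displacement_test <- function(tracks_a, tracks_b) {
  if (length(tracks_a) < 2L || length(tracks_b) < 2L)
    stopf("need >= 2 tracks per group")
  summ <- function(trs) {
    s <- lapply(trs, displacement_summary)
    data.frame(dx = vapply(s, `[[`, numeric(1), "dx"),
               dy = vapply(s, `[[`, numeric(1), "dy"),
               ocos = cos(vapply(s, `[[`, numeric(1), "orientation_deg") * pi / 180),
               osin = sin(vapply(s, `[[`, numeric(1), "orientation_deg") * pi / 180))
  }
  a <- summ(tracks_a); b <- summ(tracks_b)
  one <- function(col) {
    xa <- a[[col]]; xb <- b[[col]]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (length(xa) < 2L || length(xb) < 2L) return(NA_real_)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    stats::t.test(xa, xb)$p.value
  }
  data.frame(quantity = c("dx", "dy", "orientation_cos", "orientation_sin"),
             p_value = c(one("dx"), one("dy"), one("ocos"), one("osin")),
             stringsAsFactors = FALSE)
}

#' Partition crossing events around a fold-reformation time
#'
#' After acute actomyosin inactivation the fold reforms once the target
#' protein recovers; crossings are only expected before that.
#'
#' @param event_times numeric vector of crossing times (minutes).
#' @param reform_time fold-reformation time (minutes), >= 0.
#' @return list with `within_window` / `outside_window` event times and
#'   counts.
#' @export
crossing_window <- function(event_times, reform_time) {
  assert_scalar_num(reform_time, "reform_time", lo = 0)
  within <- event_times[event_times < reform_time]
  outside <- event_times[event_times >= reform_time]
  list(within_window = within, outside_window = outside,
       n_within = length(within), n_outside = length(outside))
}
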