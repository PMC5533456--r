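#' 1D intensity profile across a fold
#'
#' Raw multichannel pixel-intensity profile along a line crossing the
#' expression border, with position 0 at the fold (or the overlap midpoint in
#' earlier discs) and a per-channel background level taken as the mean over a
#' designated non-expressing region.
#'
#' @param positions numeric vector, um, centered on the border.
#' @param intensities numeric matrix, one column per channel, rownames free.
#' @param background named numeric vector of per-channel background levels.
#' @return object of class `profile_line`.
#' @export
profile_line <- function(positions, intensities, background) {
  intensities <- as.matrix(intensities)
  if (length(positions) != nrow(intensities))
    stopf("positions and intensity rows differ in length")
  if (is.null(colnames(intensities)))
    stopf("intensity columns must be named by channel")
  missing_bg <- setdiff(colnames(intensities), names(background))
  if (length(missing_bg))
    stopf("no background level for channel(s): %s",
          paste(missing_bg, collapse = ", "))
  structure(list(positions = as.numeric(positions),
                 intensities = intensities,
                 background = background[colnames(intensities)]),
            class = "profile_line")
}

#' @export
print.profile_line <- function(x, ...) {
  cat(sprintf("<profile_line: %d positions (%.0f to %.0f um), channels: %s>\n",
              length(x$positions), min(x$positions), max(x$positions),
              paste(colnames(x$intensities), collapse = ", ")))
  invisible(x)
}

#' Background-normalize an intensity profile
#'
#' Each channel is divided by its own background level (fold-over-background),
#' so a non-expressing region sits at 1. A subtractive mode
#' (`method = "subtract"`) is available; division is the default.
#'
#' @param p a [profile_line()].
#' @param method `"divide"` (default) or `"subtract"`.
#' @return matrix of normalized intensities, same shape as the raw channels.
#' @export
normalize_profile <- function(p, method = c("divide", "subtract")) {
  method <- match.arg(method)
  bad <- names(p$background)[!is.finite(p$background) | p$background <= 0]
  if (length(bad))
    stopf("non-positive background for channel(s): %s",
          paste(bad, collapse = ", "))
  if (method == "divide") sweep(p$intensities, 2L, p$background, `/`)
  else sweep(p$intensities, 2L, p$background, `-`)
}

#' Border-segregation metrics from two normalized channels
#'
#' Overlap width is the extent of positions at which both channels exceed half
#' their own maximum; the crossing position is where the two curves intersect
#' (linear interpolation between grid points).
#'
#' @param positions numeric grid (um) shared by both channels.
#' @param a,b normalized intensity vectors for the two channels.
#' @return list with `overlap_width_um`, `crossing_um` (NA if none), and
#'   `defined` (FALSE when a channel is flat and the metrics are undefined).
#' @export
segregation_metrics <- function(positions, a, b) {
  if (length(a) != length(positions) || length(b) != length(positions))
    stopf("profiles must share the position grid")
  flat <- function(v) (max(v) - min(v)) < 1e-12
  if (flat(a) || flat(b))
    return(list(overlap_width_um = NA_real_, crossing_um = NA_real_,
                defined = FALSE))
  both <- (a > max(a) / 2) & (b > max(b) / 2)
  dx <- diff(positions)
  # measure covered extent as the sum of step widths whose midpoint is in the
  # overlap (half-step at region edges)
  w <- sum(((both[-length(both)] + both[-1L]) / 2) * dx)
  d <- a - b
  s <- which(d[-length(d)] * d[-1L] < 0)
  crossing <- if (any(d == 0)) positions[which(d == 0)[1L]]
  else if (length(s)) {
    i <- s[1L]
    positions[i] + (positions[i + 1L] - positions[i]) * d[i] / (d[i] - d[i + 1L])
  } else NA_real_
  list(overlap_width_um = w, crossing_um = crossing, defined = TRUE)
}

#' Percentage of cells co-expressing two channels
#'
#' A cell is called positive for a channel when its mean intensity exceeds the
#' channel threshold; the default threshold convention is background mean +
#' 2 background sd.
#'
#' @param cells data.frame with one intensity column per channel.
#' @param thresholds named numeric vector, one threshold per channel to call;
#'   exactly two channels define co-expression.
#' @return list with `percent` (0-100), and `calls`, the per-cell logical
#'   co-expression vector.
#' @export
coexpression_percent <- function(cells, thresholds) {
  if (nrow(cells) == 0L) stopf("empty cell set")
  ch <- names(thresholds)
  if (length(ch) != 2L) stopf("exactly two channel thresholds required")
  if (any(thresholds < 0)) stopf("thresholds must be >= 0")
  missing <- setdiff(ch, names(cells))
  if (length(missing))
    stopf("cells table lacks channel column(s): %s", paste(missing, collapse = ", "))
  calls <- cells[[ch[1L]]] > thresholds[[1L]] & cells[[ch[2L]]] > thresholds[[2L]]
  list(percent = 100 * mean(calls), calls = calls)
}

#' Disc staging model from disc-area groups
#'
#' Developmental staging by total disc area: the three late-L2 size groups
#' have mean +/- sd areas of 4835 +/- 328, 6058 +/- 231 and 7065 +/- 309 um^2.
#'
#' @param means,sds numeric vectors of group means and sds (um^2), means
#'   strictly increasing.
#' @return object of class `staging_model`.
#' @export
staging_model <- function(means = c(4835, 6058, 7065),
                          sds = c(328, 231, 309)) {
  if (length(means) != length(sds)) stopf("means and sds differ in length")
  if (any(diff(means) <= 0)) stopf("group means must be strictly increasing")
  structure(list(means = means, sds = sds), class = "staging_model")
}

#' Assign a disc to a size group
#'
#' Nearest group mean wins; exact ties go to the lower group.
#'
#' @param disc_area disc area in um^2, > 0.
#' @param model a [staging_model()].
#' @return integer group index (1-based).
#' @export
assign_stage <- function(disc_area, model = staging_model()) {
  assert_scalar_num(disc_area, "disc_area", lo = .Machine$double.eps)
  d <- abs(disc_area - model$means)
  which(d <= min(d))[1L]
}

#' Single-cell selector/ligand ratio regression
#'
#' Ordinary least squares of the per-cell Delta/Serrate intensity ratio on the
#' Dll/Lim1 intensity ratio. Cells with a non-positive denominator channel are
#' excluded (and counted), never imputed.
#'
#' @param cells data.frame with columns named by `num_x`, `den_x`, `num_y`,
#'   `den_y` (defaults Dll, Lim1, Dl, Ser).
#' @param num_x,den_x,num_y,den_y channel column names: x = num_x/den_x,
#'   y = num_y/den_y.
#' @param log_ratios if TRUE regress log ratios instead of raw ratios.
#' @return list with `slope`, `intercept`, `r_squared`, `n_used`,
#'   `n_excluded`, and the `fit` (an `lm` object).
#' @export
ratio_regression <- function(cells, num_x = "Dll", den_x = "Lim1",
                             num_y = "Dl", den_y = "Ser",
                             log_ratios = FALSE) {
  need <- c(num_x, den_x, num_y, den_y)
  missing <- setdiff(need, names(cells))
  if (length(missing))
    stopf("cells table lacks column(s): %s", paste(missing, collapse = ", "))
  ok <- cells[[den_x]] > 0 & cells[[den_y]] > 0
  n_excluded <- sum(!ok)
  d <- cells[ok, , drop = FALSE]
  if (nrow(d) < 3L)
    stopf("fewer than 3 usable cells after excluding zero denominators")
  x <- d[[num_x]] / d[[den_x]]
  y <- d[[num_y]] / d[[den_y]]
  if (log_ratios) { x <- log(x); y <- log(y) }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n_used = nrow(d), n_excluded = n_excluded, fit = fit)
}

#' Reporter level as a ratio over a reference region
#'
#' Mean pixel intensity of the expressing region divided by the mean of a
#' non-expressing reference region in the same disc.
#'
#' @param region_mean mean intensity of the region of interest.
#' @param reference_mean mean intensity of the reference region, > 0.
#' @return dimensionless ratio.
#' @export
reporter_ratio <- function(region_mean, reference_mean) {
  assert_scalar_num(region_mean, "region_mean", lo = 0)
  if (!is.numeric(reference_mean) || reference_mean <= 0)
    stopf("reference_mean must be > 0")
  region_mean / reference_mean
}
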