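#' z-indexed contour stack for one cell domain
#'
#' Serial optical sections of one cell's apical (aPKC-defined) or basolateral
#' (FasIII-defined) domain, each section a simple polygon in the XY plane.
#' Default optical intervals follow the acquisition settings for each domain:
#' 0.27 um (apical) and 0.47 um (basolateral).
#'
#' @param cell_id identifier.
#' @param domain `"apical"` or `"basolateral"`.
#' @param z numeric vector of slice depths (um), strictly increasing.
#' @param polygons list of two-column vertex matrices (um), one per slice,
#'   each simple (non-self-intersecting) with >= 3 vertices.
#' @return object of class `contour_stack`.
#' @export
contour_stack <- function(cell_id, domain = c("apical", "basolateral"),
                          z, polygons) {
  domain <- match.arg(domain)
  if (length(z) != length(polygons))
    stopf("cell '%s': z and polygons differ in length", cell_id)
  if (length(z) < 1L) stopf("cell '%s': needs >= 1 slice", cell_id)
  if (any(diff(z) <= 0))
    stopf("cell '%s': z must be strictly increasing", cell_id)
  for (i in seq_along(polygons)) {
    pg <- as.matrix(polygons[[i]])
    if (nrow(pg) < 3L)
      stopf("cell '%s': degenerate polygon (<3 vertices) at slice %d",
            cell_id, i)
    if (polyline_self_intersects(pg, closed = TRUE))
      stopf("cell '%s': self-intersecting polygon at slice %d", cell_id, i)
    polygons[[i]] <- unname(pg)
  }
  structure(list(cell_id = as.character(cell_id), domain = domain,
                 z = as.numeric(z), polygons = polygons),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack %s [%s]: %d slices, z %.2f-%.2f um>\n",
              x$cell_id, x$domain, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Default optical slice interval per domain (um)
#' @param domain `"apical"` or `"basolateral"`.
#' @return numeric interval in um.
#' @export
slice_interval <- function(domain = c("apical", "basolateral")) {
  switch(match.arg(domain), apical = 0.27, basolateral = 0.47)
}

polygon_perimeter <- function(pg) {
  v <- rbind(pg, pg[1L, ])
  sum(sqrt(rowSums(diff(v)^2)))
}

polygon_area <- function(pg) {
  abs(pracma::polyarea(pg[, 1L], pg[, 2L]))
}

#' Measure a contour stack
#'
#' Volume is the trapezoidal integral of slice polygon area over z (a single
#' slice contributes area x nominal interval). Height is the z extent plus
#' one slice interval, so that a one-slice domain has a nonzero height
#' (`height = "extent"` gives the bare z range). Maximal circumference is the
#' maximum polygon perimeter over slices.
#'
#' @param s a [contour_stack()].
#' @param interval nominal slice interval (um); defaults to the per-domain
#'   acquisition interval from [slice_interval()].
#' @param height `"extent_plus_interval"` (default) or `"extent"`.
#' @return data.frame (one row) with cell_id, domain, height_um, volume_um3,
#'   max_circumference_um, n_slices.
#' @export
measure_stack <- function(s, interval = slice_interval(s$domain),
                          height = c("extent_plus_interval", "extent")) {
  height <- match.arg(height)
  areas <- vapply(s$polygons, polygon_area, numeric(1))
  vol <- if (length(s$z) == 1L) areas[1L] * interval
         else pracma::trapz(s$z, areas)
  extent <- max(s$z) - min(s$z)
  h <- if (height == "extent") extent else extent + interval
  data.frame(cell_id = s$cell_id, domain = s$domain,
             height_um = h, volume_um3 = vol,
             max_circumference_um = max(vapply(s$polygons, polygon_perimeter,
                                               numeric(1))),
             n_slices = length(s$z),
             stringsAsFactors = FALSE)
}

#' Measure a list of contour stacks
#'
#' @param stacks list of [contour_stack()] objects.
#' @param ... passed to [measure_stack()].
#' @return data.frame, one row per stack.
#' @export
measure_stacks <- function(stacks, ...) {
  do.call(rbind, lapply(stacks, measure_stack, ...))
}

#' Volume ratio between two cell groups
#'
#' Per shared domain: 100 x mean(volume in A) / mean(volume in B), plus group
#' means and sds.
#'
#' @param measures_a,measures_b data.frames from [measure_stacks()] (e.g.
#'   fold cells vs non-fold cells).
#' @return data.frame per domain with `ratio_percent`, group means/sds and
#'   counts.
#' @export
volume_ratio <- function(measures_a, measures_b) {
  if (nrow(measures_a) == 0L || nrow(measures_b) == 0L)
    stopf("both groups must be non-empty")
  domains <- intersect(unique(measures_a$domain), unique(measures_b$domain))
  if (length(domains) == 0L) stopf("groups share no domain")
  do.call(rbind, lapply(domains, function(dm) {
    va <- measures_a$volume_um3[measures_a$domain == dm]
    vb <- measures_b$volume_um3[measures_b$domain == dm]
    if (mean(vb) == 0) stopf("zero mean volume in denominator group (%s)", dm)
    data.frame(domain = dm, ratio_percent = 100 * mean(va) / mean(vb),
               mean_a = mean(va), sd_a = stats::sd(va), n_a = length(va),
               mean_b = mean(vb), sd_b = stats::sd(vb), n_b = length(vb),
               stringsAsFactors = FALSE)
  }))
}

#' Fraction of positive cells
#'
#' @param n_positive,n_total counts; `n_total >= 1`,
#'   `0 <= n_positive <= n_total`.
#' @return fraction in 0..1.
#' @export
positive_fraction <- function(n_positive, n_total) {
  if (n_total < 1L) stopf("n_total must be >= 1")
  if (n_positive < 0L || n_positive > n_total)
    stopf("n_positive must be in 0..n_total")
  n_positive / n_total
}

#' Group comparison with the appropriate test family
#'
#' Two groups: Welch two-tailed unpaired t-test. More than two groups:
#' one-way ANOVA followed by either Tukey all-pairs or Dunnett
#' many-to-one (one-vs-control) multiple comparisons, with adjusted p-values.
#'
#' @param values numeric vector of measurements.
#' @param group factor/character of group membership (>= 2 observations per
#'   group).
#' @param design `"two-sample"`, `"all-pairs"` (Tukey) or `"one-vs-control"`
#'   (Dunnett).
#' @param control control-group level for the Dunnett design (default: first
#'   factor level).
#' @return data.frame with one row per comparison: `comparison`, `estimate`
#'   (difference in means), `p_value` (adjusted for the ANOVA designs).
#' @export
group_compare <- function(values, group,
                          design = c("two-sample", "all-pairs",
                                     "one-vs-control"),
                          control = NULL) {
  design <- match.arg(design)
  group <- factor(group)
  if (any(table(group) < 2L)) stopf("every group needs >= 2 observations")
  if (design == "two-sample") {
    if (nlevels(group) != 2L) stopf("two-sample design needs exactly 2 groups")
    lv <- levels(group)
    tt <- stats::t.test(values[group == lv[1L]], values[group == lv[2L]])
    return(data.frame(comparison = paste(lv[1L], "-", lv[2L]),
                      estimate = unname(diff(rev(tt$estimate))),
                      p_value = tt$p.value, stringsAsFactors = FALSE))
  }
  if (nlevels(group) < 2L) stopf("need >= 2 groups")
  fit <- stats::aov(values ~ group, data = data.frame(values = values,
                                                      group = group))
  if (design == "all-pairs") {
    tk <- stats::TukeyHSD(fit)$group
    return(data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                      p_value = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  if (!is.null(control)) group <- stats::relevel(group, ref = control)
  fit <- stats::aov(values ~ group, data = data.frame(values = values,
                                                      group = group))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl)
  data.frame(comparison = names(sm$test$coefficients),
             estimate = unname(sm$test$coefficients),
             p_value = unname(sm$test$pvalues), stringsAsFactors = FALSE)
}
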