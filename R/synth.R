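#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of the study's
#' microscopy-derived tables: 5-hour apical-area movies with three dynamic
#' behaviours, sharpening two-selector expression gradients with
#' progressively correlated ligand gradients, clone growth against a
#' stage-dependent fold barrier, fold vs non-fold contour stacks with
#' prescribed volume effect sizes, and trajectories that do or do not cross
#' the fold. Defaults are the study conditions: 17/31/17 control trace
#' composition, 300 min movies, constriction onset 180 min, decreasing cells
#' starting at 20-40 um^2 and ending below 10 um^2, apical/basolateral
#' fold-to-non-fold volume ratios 0.2/0.5, and disc-size staging groups
#' 4835/6058/7065 um^2.
#'
#' Noise terms are bounded (uniform) with guard bands of 2 um^2 around the
#' 10 um^2 classification threshold, so generated group labels are
#' recoverable exactly; threshold-exact behaviour is exercised separately in
#' the classifier tests.
#'
#' @param seed integer; fixes every stochastic output bit-for-bit.
#' @param n_cells_per_group named integer vector: constant / fluctuating /
#'   decreasing cell counts.
#' @param trace_duration movie length, minutes.
#' @param frame_interval frame spacing, minutes.
#' @param constriction_onset time (min) at which decreasing cells start
#'   constricting.
#' @param area_start_range initial-area range (um^2) for decreasing cells.
#' @param area_end_max final-area bound (um^2) for decreasing cells.
#' @param constant_baseline_range baseline-area range (um^2) for constant
#'   cells.
#' @param pulse_period,pulse_amplitude period (min) and transient dip depth
#'   (um^2) of the pulsatile medial actomyosin ratchet.
#' @param profile_length intensity-profile window (um).
#' @param profile_step profile grid spacing (um).
#' @param sharpening_schedule list with `width` (um, strictly decreasing over
#'   stages) and `amplitude` (strictly increasing) of the selector gradients.
#' @param ligand_correlation per-stage correlation of the ligand log-ratio
#'   with the selector log-ratio, strictly increasing.
#' @param n_cells_profile cells per disc in the single-cell expression table.
#' @param n_coexpr per-stage count of truly co-expressing cells.
#' @param background_mean,background_sd per-channel background intensity.
#' @param group_area_means,group_area_sds disc-size staging groups (um^2).
#' @param clone_barrier_strength per-stage probability that a clone at the
#'   fold is stopped by it (used for sampling restricted counts when they are
#'   not given explicitly).
#' @param clone_margin minimum cell distance from the fold line (um), > 0.
#' @param volume_ratio_apical,volume_ratio_basolateral fold/non-fold true
#'   volume ratios.
#' @param track_duration,track_interval track length and sampling (min).
#' @param persistence_window frames a side change must persist.
#' @param noise_amplitude bound of the uniform area noise (um^2).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_cells_per_group = c(constant = 17L,
                                               fluctuating = 31L,
                                               decreasing = 17L),
                         trace_duration = 300,
                         frame_interval = 6,
                         constriction_onset = 180,
                         area_start_range = c(20, 40),
                         area_end_max = 10,
                         constant_baseline_range = c(18, 45),
                         pulse_period = 12,
                         pulse_amplitude = 1.5,
                         profile_length = 60,
                         profile_step = 0.5,
                         sharpening_schedule = list(width = c(8, 4, 2),
                                                    amplitude = c(2, 3, 4)),
                         ligand_correlation = c(0.3, 0.6, 0.85),
                         n_cells_profile = 200L,
                         n_coexpr = c(4L, 2L, 0L),
                         background_mean = 100,
                         background_sd = 5,
                         group_area_means = c(4835, 6058, 7065),
                         group_area_sds = c(328, 231, 309),
                         clone_barrier_strength = c(`m-L2` = 0.03,
                                                    `l-L2` = 0.19,
                                                    `e-L3` = 0.86),
                         clone_margin = 1,
                         volume_ratio_apical = 0.2,
                         volume_ratio_basolateral = 0.5,
                         track_duration = 720,
                         track_interval = 6,
                         persistence_window = 3L,
                         noise_amplitude = 0.4) {
  cfg <- as.list(environment())
  with(cfg, {
    if (trace_duration <= 0 || frame_interval <= 0 || track_duration <= 0 ||
        track_interval <= 0 || pulse_period <= 0 || profile_length <= 0)
      stopf("all durations and lengths must be > 0")
    if (any(clone_barrier_strength < 0) || any(clone_barrier_strength > 1))
      stopf("clone_barrier_strength must be probabilities in [0, 1]")
    if (clone_margin <= 0) stopf("clone_margin must be > 0")
    if (constriction_onset < 0 || constriction_onset >= trace_duration)
      stopf("constriction_onset must lie within the movie")
    if (any(diff(sharpening_schedule$width) >= 0) ||
        any(diff(sharpening_schedule$amplitude) <= 0))
      stopf("sharpening schedule must be monotone: widths decreasing, amplitudes increasing")
    if (any(diff(ligand_correlation) <= 0))
      stopf("ligand_correlation must be strictly increasing over stages")
    if (volume_ratio_apical <= 0 || volume_ratio_basolateral <= 0)
      stopf("volume ratios must be > 0")
    if (persistence_window * track_interval > track_duration)
      stopf("persistence window longer than the track")
  })
  cfg$seed <- as.integer(seed)
  g <- cfg$n_cells_per_group
  if (length(g) != 3L || any(g < 0))
    stopf("n_cells_per_group needs 3 non-negative counts")
  if (is.null(names(g)))
    names(g) <- c("constant", "fluctuating", "decreasing")
  cfg$n_cells_per_group <- as.integer(g)
  names(cfg$n_cells_per_group) <- names(g)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config: seed %d, traces %s, %g min @ %g min/frame>\n",
              x$seed, paste(x$n_cells_per_group, collapse = "/"),
              x$trace_duration, x$frame_interval))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

runif_b <- function(n, amp) stats::runif(n, -amp, amp)

#' Generate apical-area traces with known group labels
#'
#' Constant cells wobble within a < 10 um^2 total range around a stable
#' baseline; fluctuating cells oscillate with a >= 12 um^2 range but a stable
#' mean and a final area well above 10 um^2; decreasing cells hold their
#' starting area until the constriction onset and then ratchet down in
#' pulses (area drops during a pulse's active phase and holds between
#' pulses) to below `area_end_max`. Guard bands around the classification
#' thresholds make the generated labels exactly recoverable.
#'
#' @param config a [synth_config()].
#' @return list with `traces` (list of [cell_trace()]), `labels` (true group
#'   per trace), and `table` (long data.frame: cell_id, t_min, area_um2,
#'   true_group).
#' @export
generate_traces <- function(config = synth_config()) {
  n <- config$n_cells_per_group
  if (sum(n) == 0L) stopf("zero cells requested in every group")
  tgrid <- seq(0, config$trace_duration, by = config$frame_interval)
  na <- config$noise_amplitude
  with_seed(config$seed, {
    traces <- list(); labels <- character(0)
    id <- 0L
    mk <- function(areas) {
      id <<- id + 1L
      cell_trace(sprintf("cell_%03d", id), tgrid, areas)
    }
    for (i in seq_len(n[["constant"]])) {
      base <- stats::runif(1, config$constant_baseline_range[1],
                           config$constant_baseline_range[2])
      amp <- stats::runif(1, 1, 3.5)
      phase <- stats::runif(1, 0, 2 * pi)
      areas <- base + amp * sin(2 * pi * tgrid / 90 + phase) +
        runif_b(length(tgrid), na)
      traces[[length(traces) + 1L]] <- mk(areas)
      labels <- c(labels, "constant")
    }
    for (i in seq_len(n[["fluctuating"]])) {
      base <- stats::runif(1, 18, 35)
      amp <- stats::runif(1, 7, 9.5)
      # keep the closing frames near or above baseline so the final area
      # stays clear of the decreasing cutoff
      repeat {
        phase <- stats::runif(1, 0, 2 * pi)
        tail_idx <- seq.int(length(tgrid) - 2L, length(tgrid))
        if (mean(sin(2 * pi * tgrid[tail_idx] / 60 + phase)) >= -0.15) break
      }
      areas <- base + amp * sin(2 * pi * tgrid / 60 + phase) +
        runif_b(length(tgrid), na)
      traces[[length(traces) + 1L]] <- mk(areas)
      labels <- c(labels, "fluctuating")
    }
    for (i in seq_len(n[["decreasing"]])) {
      s <- stats::runif(1, config$area_start_range[1] + 2,
                        config$area_start_range[2] - 2)
      f <- stats::runif(1, 4, config$area_end_max - 2)
      areas <- decreasing_profile(tgrid, s, f, config) +
        runif_b(length(tgrid), min(na, 0.3))
      traces[[length(traces) + 1L]] <- mk(areas)
      labels <- c(labels, "decreasing")
    }
    tab <- do.call(rbind, Map(function(tr, lab) {
      data.frame(cell_id = tr$cell_id, t_min = tr$times,
                 area_um2 = tr$areas, true_group = lab,
                 stringsAsFactors = FALSE)
    }, traces, labels))
    list(traces = traces, labels = labels, table = tab)
  })
}

# stepwise pulsatile ratchet from start area s to final f after the onset
decreasing_profile <- function(tgrid, s, f, config) {
  onset <- config$constriction_onset
  P <- config$pulse_period
  dur <- config$trace_duration
  n_pulses <- max(1L, floor((dur - onset) / P))
  step <- (s - f) / n_pulses
  vapply(tgrid, function(t) {
    if (t <= onset) return(s)
    k <- min(n_pulses, floor((t - onset) / P) + 1)     # pulse index
    t0 <- onset + (k - 1) * P
    frac <- min(1, (t - t0) / (0.6 * P))               # active 60% of period
    lvl <- s - (k - 1) * step - frac * step
    # transient medial dip during the active phase
    dip <- if (frac < 1) config$pulse_amplitude * sin(pi * frac) * 0.3 else 0
    max(lvl - dip, f * 0.5)
  }, numeric(1))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Generate expression profiles and a single-cell expression table
#'
#' Two opposing sigmoid selector gradients (Dll high on the negative-x
#' central side, Lim1 high peripherally) whose transition width shrinks and
#' amplitude grows with the disc-size stage, plus ligand channels (Dl
#' tracking Dll, Ser tracking Lim1) whose per-cell log-ratio correlation with
#' the selector log-ratio increases with stage. Per-cell intensities are
#' guard-banded around the background + 2 sd co-expression threshold so the
#' generated `true_coexpr` flags are exactly recoverable.
#'
#' @param config a [synth_config()].
#' @param stage disc-size group, 1..3.
#' @param noise_sd profile noise sd as a fraction of background (0 for
#'   noise-free profiles).
#' @return list with `profile` (a [profile_line()]), `cells` (data.frame:
#'   cell_id, x_um, y_um, Dll, Lim1, Dl, Ser, true_coexpr), `disc_area_um2`,
#'   and `threshold` (the per-channel positivity cut).
#' @export
generate_profiles <- function(config = synth_config(), stage,
                              noise_sd = 0.02) {
  if (!stage %in% 1:3) stopf("stage must be 1, 2 or 3")
  w <- config$sharpening_schedule$width[stage]
  amp <- config$sharpening_schedule$amplitude[stage]
  rho <- config$ligand_correlation[stage]
  bg <- config$background_mean
  half <- config$profile_length / 2
  pos <- seq(-half, half, by = config$profile_step)
  with_seed(config$seed + 1000L * stage, {
    noise <- function() stats::rnorm(length(pos), 0, noise_sd * bg)
    lig_amp <- c(0.4, 1.5, 3)[stage]
    raw <- cbind(
      Dll = bg * (1 + amp * sigmoid(-pos / w)) + noise(),
      Lim1 = bg * (1 + amp * sigmoid(pos / w)) + noise(),
      Dl = bg * (1 + lig_amp * sigmoid(-pos / w)) + noise(),
      Ser = bg * (1 + lig_amp * sigmoid(pos / w)) + noise())
    background <- c(Dll = bg, Lim1 = bg, Dl = bg, Ser = bg)
    prof <- profile_line(pos, raw, background)

    n <- config$n_cells_profile
    n_co <- config$n_coexpr[stage]
    if (n_co > n) stopf("more co-expressing cells than cells")
    x <- stats::runif(n, -half, half)
    y <- stats::runif(n, -10, 10)
    thr <- config$background_mean + 2 * config$background_sd
    hi <- function(m) stats::runif(m, 2.5 * thr, 4 * thr)
    lo <- function(m) stats::runif(m, 0.6 * thr, 0.9 * thr)
    co <- rep(FALSE, n)
    co[sample.int(n, n_co)] <- TRUE
    dll_side <- x < 0
    Dll <- ifelse(co, hi(n), ifelse(dll_side, hi(n), lo(n)))
    Lim1 <- ifelse(co, hi(n), ifelse(dll_side, lo(n), hi(n)))
    z1 <- as.numeric(scale(log(Dll / Lim1)))
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    Dl <- 1.5 * bg * exp(z2 / 4)
    Ser <- 1.5 * bg * exp(-z2 / 4)
    cells <- data.frame(cell_id = sprintf("pc_%03d", seq_len(n)),
                        x_um = x, y_um = y, Dll = Dll, Lim1 = Lim1,
                        Dl = Dl, Ser = Ser, true_coexpr = co,
                        stringsAsFactors = FALSE)
    disc_area <- stats::rnorm(1, config$group_area_means[stage],
                              config$group_area_sds[stage])
    list(profile = prof, cells = cells, disc_area_um2 = disc_area,
         threshold = thr)
  })
}

default_fold <- function() {
  x <- seq(-40, 40, by = 10)
  fold_line(cbind(x, 8 * sin(x / 25)))
}

# place a point at |signed distance| >= margin on the requested side
place_cell <- function(fold, anchor, want_positive, margin) {
  for (attempt in 1:200) {
    p <- anchor + stats::rnorm(2, 0, 4)
    d <- signed_distance(p, fold)
    if (abs(d) >= margin && (d > 0) == want_positive) return(p)
  }
  # deterministic fallback: step along the local normal until on the side
  for (off in seq(margin + 0.5, 40, by = 0.5)) {
    for (sgn in c(1, -1)) {
      p <- anchor + c(0, sgn * off)
      d <- signed_distance(p, fold)
      if (abs(d) >= margin && (d > 0) == want_positive) return(p)
    }
  }
  stopf("could not place a cell at margin %g from the fold", margin)
}

#' Generate clones against a fold line
#'
#' Exactly `n_restricted` clones have all member cells strictly on one side
#' of the fold; the remaining clones have at least one cell on each side.
#' Every cell is at least `clone_margin` um from the line, so side calls are
#' unambiguous.
#'
#' @param config a [synth_config()].
#' @param stage induction-stage tag (see [clone_stages()]).
#' @param n_clones total clone count.
#' @param n_restricted number of fully one-sided clones
#'   (`<= n_clones`); if `NULL`, drawn from the per-stage
#'   `clone_barrier_strength`.
#' @param fold optional [fold_line()]; default is a gently curved open
#'   polyline.
#' @return list with `clones` (list of [clone()]), `fold`, and `truth`
#'   (data.frame: clone_id, restricted).
#' @export
generate_clones <- function(config = synth_config(), stage = "m-L2",
                            n_clones, n_restricted = NULL, fold = NULL) {
  margin <- config$clone_margin
  if (margin <= 0) stopf("clone_margin must be > 0")
  if (n_clones < 1L) stopf("need at least one clone")
  fold <- fold %||% default_fold()
  with_seed(config$seed + 7L, {
    if (is.null(n_restricted)) {
      p <- config$clone_barrier_strength[[stage]]
      n_restricted <- stats::rbinom(1L, n_clones, p)
    }
    if (n_restricted > n_clones) stopf("n_restricted must be <= n_clones")
    restricted <- rep(c(TRUE, FALSE),
                      c(n_restricted, n_clones - n_restricted))
    clones <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      n_cells <- sample(3:12, 1L)
      u <- stats::runif(1, -35, 35)
      anchor <- c(u, 8 * sin(u / 25))
      if (restricted[i]) {
        side <- stats::runif(1) < 0.5
        pts <- t(vapply(seq_len(n_cells), function(j)
          place_cell(fold, anchor, side, margin), numeric(2)))
      } else {
        # at least one cell per side
        sides <- c(TRUE, FALSE,
                   stats::runif(max(0L, n_cells - 2L)) < 0.5)[seq_len(max(2L, n_cells))]
        pts <- t(vapply(sides, function(sd_) place_cell(fold, anchor, sd_, margin),
                        numeric(2)))
      }
      clones[[i]] <- clone(sprintf("%s_clone_%03d", stage, i), stage,
                           data.frame(x = pts[, 1L], y = pts[, 2L]))
    }
    ord <- sample.int(n_clones)   # shuffle so truth order carries no signal
    list(clones = clones[ord], fold = fold,
         truth = data.frame(
           clone_id = vapply(clones[ord], function(cl) cl$clone_id, character(1)),
           restricted = restricted[ord], stringsAsFactors = FALSE))
  })
}

regular_polygon <- function(radii, center = c(0, 0)) {
  k <- length(radii)
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(center[1] + radii * cos(th), center[2] + radii * sin(th))
}

#' Generate contour stacks with known true volumes
#'
#' Non-fold cells are right generalized cylinders: one simple (star-convex,
#' irregular) polygon extruded over z at the per-domain optical interval, so
#' the true volume is polygon area x z extent in closed form. Each fold cell
#' is the same shape as one non-fold cell with its XY cross-section scaled so
#' its volume is exactly `volume_ratio_apical` (apical domain) or
#' `volume_ratio_basolateral` (basolateral) times its partner's.
#'
#' @param config a [synth_config()].
#' @param n_fold,n_nonfold cell counts, >= 0.
#' @return list with `stacks` (list of [contour_stack()]), and `truth`
#'   (data.frame: cell_id, domain, fold flag, true volume um^3).
#' @export
generate_contour_stacks <- function(config = synth_config(), n_fold = 10L,
                                    n_nonfold = 10L) {
  if (n_fold < 0L || n_nonfold < 0L) stopf("counts must be >= 0")
  if (n_fold + n_nonfold == 0L) stopf("no cells requested")
  n_base <- max(n_fold, n_nonfold)
  ratios <- c(apical = config$volume_ratio_apical,
              basolateral = config$volume_ratio_basolateral)
  with_seed(config$seed + 13L, {
    stacks <- list(); truth <- NULL
    base_polys <- list()
    for (i in seq_len(n_base)) {
      base_polys[[i]] <- list(
        apical = regular_polygon(stats::runif(12, 0.8, 1.2) *
                                   sqrt(stats::runif(1, 20, 40) / pi)),
        basolateral = regular_polygon(stats::runif(12, 0.8, 1.2) *
                                        sqrt(stats::runif(1, 30, 55) / pi)),
        z_apical = stats::runif(1, 4, 7),
        z_baso = stats::runif(1, 30, 40))
    }
    add <- function(cell_id, domain, poly, extent, is_fold) {
      dz <- slice_interval(domain)
      z <- seq(0, extent, by = dz)
      if (length(z) < 2L) z <- c(0, extent)
      st <- contour_stack(cell_id, domain, z,
                          rep(list(poly), length(z)))
      stacks[[length(stacks) + 1L]] <<- st
      truth <<- rbind(truth, data.frame(
        cell_id = cell_id, domain = domain, fold = is_fold,
        true_volume_um3 = polygon_area(poly) * (max(z) - min(z)),
        stringsAsFactors = FALSE))
    }
    for (i in seq_len(n_nonfold)) {
      b <- base_polys[[i]]
      add(sprintf("nonfold_%02d", i), "apical", b$apical, b$z_apical, FALSE)
      add(sprintf("nonfold_%02d", i), "basolateral", b$basolateral,
          b$z_baso, FALSE)
    }
    for (j in seq_len(n_fold)) {
      b <- base_polys[[(j - 1L) %% n_base + 1L]]
      add(sprintf("fold_%02d", j), "apical",
          b$apical * sqrt(ratios[["apical"]]), b$z_apical, TRUE)
      add(sprintf("fold_%02d", j), "basolateral",
          b$basolateral * sqrt(ratios[["basolateral"]]), b$z_baso, TRUE)
    }
    list(stacks = stacks, truth = truth)
  })
}

#' Generate tracks with known crossing labels
#'
#' Crossing tracks change fold side exactly once (a jump between consecutive
#' frames, with bounded jitter smaller than the standoff distance) and stay
#' on the new side; confined tracks never change side. Crossing tracks start
#' alternately on either side, so per-axis displacement means are zero in
#' both groups and the two sets are matched in displacement scale.
#'
#' @param config a [synth_config()].
#' @param n_crossing,n_confined track counts, >= 0.
#' @param fold optional [fold_line()]; default is the straight line y = 0.
#' @return list with `tracks` (list of [cell_track()]), `fold`, and `truth`
#'   (data.frame: track_id, crosses).
#' @export
generate_tracks <- function(config = synth_config(), n_crossing = 5L,
                            n_confined = 13L, fold = NULL) {
  if (n_crossing < 0L || n_confined < 0L) stopf("counts must be >= 0")
  fold <- fold %||% fold_line(cbind(c(-60, 0, 60), c(0, 0, 0)))
  tgrid <- seq(0, config$track_duration, by = config$track_interval)
  nfr <- length(tgrid)
  if (config$persistence_window > nfr)
    stopf("persistence window longer than the track")
  with_seed(config$seed + 29L, {
    tracks <- list(); truth <- NULL
    mk <- function(id, d, group, crosses) {
      x <- stats::runif(1, -20, 20) + cumsum(c(0, stats::rnorm(nfr - 1L, 0, 1.2)))
      tracks[[length(tracks) + 1L]] <<- cell_track(id, tgrid, x, d,
                                                   group = group)
      truth <<- rbind(truth, data.frame(track_id = id, crosses = crosses,
                                        stringsAsFactors = FALSE))
    }
    for (i in seq_len(n_crossing)) {
      s <- if (i %% 2L == 0L) 1 else -1
      d0 <- stats::runif(1, 8, 15); d1 <- stats::runif(1, 8, 15)
      kc <- floor(stats::runif(1, 0.3, 0.7) * nfr)   # crossing frame
      base <- numeric(nfr)
      base[1:kc] <- seq(d0, 1.5, length.out = kc)
      base[(kc + 1L):nfr] <- seq(-1.5, -d1, length.out = nfr - kc)
      d <- s * base + runif_b(nfr, config$noise_amplitude)
      mk(sprintf("crossing_%02d", i), d, "CALI", TRUE)
    }
    for (i in seq_len(n_confined)) {
      s <- if (i %% 2L == 0L) 1 else -1
      d0 <- stats::runif(1, 8, 15)
      walk <- cumsum(c(0, stats::rnorm(nfr - 1L, 0, 1.2)))
      d <- s * (2 + abs(d0 + walk - 2)) + runif_b(nfr, config$noise_amplitude)
      mk(sprintf("confined_%02d", i), d, "non-CALI", FALSE)
    }
    list(tracks = tracks, fold = fold, truth = truth)
  })
}
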