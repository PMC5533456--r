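#' Default clone study design
#'
#' Stage-wise clone totals and restricted counts matching the published
#' twin-spot clonal analysis: 34 mid-L2 clones (1 restricted), 37 late-L2
#' clones (7 restricted), 35 early-L3 clones (30 restricted).
#'
#' @return data.frame with `stage`, `n_clones`, `n_restricted`.
#' @export
default_clone_design <- function() {
  data.frame(stage = clone_stages(),
             n_clones = c(34L, 37L, 35L),
             n_restricted = c(1L, 7L, 30L),
             stringsAsFactors = FALSE)
}

stage_step <- function(stage, fn) {
  tryCatch(fn(), error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates every input with the configured seed, writes the interchange
#' files into `out_dir`, runs every analysis module on the written files, and
#' aggregates the results into a single report (also written as JSON).
#' Deterministic given the config.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if absent).
#' @param clone_design data.frame of stage/n_clones/n_restricted rows
#'   (default [default_clone_design()]).
#' @param n_fold,n_nonfold contour-stack counts per group.
#' @param n_crossing,n_confined track counts per group.
#' @return the report, an invisible list; see `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         clone_design = default_clone_design(),
                         n_fold = 10L, n_nonfold = 10L,
                         n_crossing = 5L, n_confined = 13L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  # --- simulate -------------------------------------------------------------
  sim_traces <- stage_step("simulate", function() generate_traces(config))
  write_traces_csv(sim_traces$table, p("traces.csv"))
  sim_profiles <- stage_step("simulate", function()
    lapply(1:3, function(sg) generate_profiles(config, sg)))
  sim_clones <- stage_step("simulate", function() {
    out <- lapply(seq_len(nrow(clone_design)), function(i)
      generate_clones(synth_config(seed = config$seed + i),
                      stage = clone_design$stage[i],
                      n_clones = clone_design$n_clones[i],
                      n_restricted = clone_design$n_restricted[i]))
    names(out) <- clone_design$stage
    out
  })
  all_clones <- unlist(lapply(sim_clones, `[[`, "clones"), recursive = FALSE)
  write_clones_csv(all_clones, p("clones.csv"))
  write_fold_json(sim_clones[[1L]]$fold, p("fold.json"))
  sim_stacks <- stage_step("simulate", function()
    generate_contour_stacks(config, n_fold, n_nonfold))
  write_contours_json(sim_stacks$stacks, p("contours.json"))
  sim_tracks <- stage_step("simulate", function()
    generate_tracks(config, n_crossing, n_confined))
  write_tracks_csv(sim_tracks$tracks, p("tracks.csv"))

  # --- classify -------------------------------------------------------------
  dynamics <- stage_step("classify", function() {
    traces <- read_traces_csv(p("traces.csv"))$traces
    cls <- classify_traces(traces)
    utils::write.csv(cls, p("classified.csv"), row.names = FALSE)
    gs <- group_summary(traces, cls$group)
    list(classified = cls, counts = as.list(gs$counts),
         proportions = as.list(gs$proportions), sd_range = gs$sd_range)
  })

  # --- profile --------------------------------------------------------------
  profiles <- stage_step("profile", function() {
    lapply(seq_along(sim_profiles), function(sg) {
      sp <- sim_profiles[[sg]]
      norm <- normalize_profile(sp$profile)
      seg <- segregation_metrics(sp$profile$positions,
                                 norm[, "Dll"], norm[, "Lim1"])
      thr <- c(Dll = sp$threshold, Lim1 = sp$threshold)
      co <- coexpression_percent(sp$cells, thr)
      reg <- ratio_regression(sp$cells)
      list(stage = sg,
           assigned_stage = assign_stage(sp$disc_area_um2),
           disc_area_um2 = sp$disc_area_um2,
           overlap_width_um = seg$overlap_width_um,
           crossing_um = seg$crossing_um,
           coexpression_percent = co$percent,
           regression = reg[c("slope", "intercept", "r_squared",
                              "n_used", "n_excluded")])
    })
  })

  # --- clones ---------------------------------------------------------------
  restriction <- stage_step("clones", function() {
    if (!file.exists(p("fold.json")))
      stopf("missing input 'fold.json'")
    do.call(rbind, lapply(names(sim_clones), function(sg) {
      sc <- sim_clones[[sg]]
      calls <- vapply(sc$clones, score_clone, character(1), fold = sc$fold)
      rf <- restriction_fraction(calls)
      data.frame(stage = sg, n_clones = rf$n_total,
                 n_restricted = rf$n_restricted,
                 percent_restricted = rf$percent,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(restriction, p("restriction_by_stage.csv"),
                   row.names = FALSE)

  # --- volumes --------------------------------------------------------------
  volumes <- stage_step("volumes", function() {
    stacks <- read_contours_json(p("contours.json"))
    meas <- measure_stacks(stacks)
    utils::write.csv(meas, p("measures.csv"), row.names = FALSE)
    is_fold <- grepl("^fold_", meas$cell_id)
    vr <- volume_ratio(meas[is_fold, ], meas[!is_fold, ])
    list(measures = meas, ratios = vr)
  })

  # --- tracks ---------------------------------------------------------------
  track_report <- stage_step("tracks", function() {
    trks <- read_tracks_csv(p("tracks.csv"))
    ev <- lapply(trks, crossing_events, fold = sim_tracks$fold,
                 persistence = config$persistence_window)
    data.frame(track_id = vapply(trks, function(tr) tr$track_id, character(1)),
               crossed = vapply(ev, `[[`, logical(1), "crossed"),
               n_events = vapply(ev, function(e) length(e$times), integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  utils::write.csv(track_report, p("crossings.csv"), row.names = FALSE)

  report <- list(
    version = as.character(utils::packageVersion("foldquant")),
    seed = config$seed,
    config = config[setdiff(names(config), "sharpening_schedule")],
    sharpening_schedule = config$sharpening_schedule,
    dynamics = dynamics[c("counts", "proportions", "sd_range")],
    profiles = profiles,
    restriction_by_stage = restriction,
    volume_ratios = volumes$ratios,
    crossings = track_report)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(report)
}
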