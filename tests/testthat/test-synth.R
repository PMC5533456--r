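test_that("config validation enforces the generator invariants", {
  expect_error(synth_config(trace_duration = 0), "durations")
  expect_error(synth_config(clone_barrier_strength = c(1.2, 0, 0)),
               "probabilities")
  expect_error(synth_config(clone_margin = 0), "margin")
  expect_error(synth_config(sharpening_schedule = list(width = c(2, 4, 8),
                                                       amplitude = c(2, 3, 4))),
               "monotone")
  expect_error(synth_config(n_cells_per_group = c(1, 2)), "3 non-negative")
  expect_error(generate_traces(synth_config(n_cells_per_group = c(0, 0, 0))),
               "zero cells")
})

test_that("identical config gives byte-identical outputs", {
  cfg <- synth_config(seed = 99)
  a <- generate_traces(cfg); b <- generate_traces(cfg)
  expect_identical(a$table, b$table)
  expect_identical(generate_profiles(cfg, 2), generate_profiles(cfg, 2))
  expect_identical(generate_clones(cfg, "l-L2", 10, 4),
                   generate_clones(cfg, "l-L2", 10, 4))
  expect_identical(generate_contour_stacks(cfg, 3, 3),
                   generate_contour_stacks(cfg, 3, 3))
  expect_identical(generate_tracks(cfg, 2, 2), generate_tracks(cfg, 2, 2))
  # and a different seed actually changes the draw
  expect_false(identical(a$table,
                         generate_traces(synth_config(seed = 100))$table))
})

test_that("trace generation hits the requested composition and margins", {
  cfg <- synth_config(seed = 1, n_cells_per_group = c(17, 31, 17))
  gen <- generate_traces(cfg)
  expect_length(gen$traces, 65)
  expect_equal(unname(table(gen$labels)[c("constant", "fluctuating",
                                          "decreasing")]),
               c(17, 31, 17), ignore_attr = TRUE)
  # one constant cell: total range strictly below 10
  solo <- generate_traces(synth_config(seed = 4,
                                       n_cells_per_group = c(1, 0, 0)))
  expect_lt(trace_stats(solo$traces[[1]])$delta, 10)
  # one decreasing cell: starts in range, ends below 10, trend monotone
  dec <- generate_traces(synth_config(seed = 4,
                                      n_cells_per_group = c(0, 0, 1)))
  tr <- dec$traces[[1]]
  expect_true(tr$areas[1] >= 20 && tr$areas[1] <= 40)
  expect_lt(mean(tail(tr$areas, 3)), 10)
  fit <- coef(lm(tr$areas ~ tr$times))[2]
  expect_lt(fit, 0)
})

test_that("generated labels are recovered exactly across 10 seeds", {
  for (s in 1:10) {
    gen <- generate_traces(synth_config(seed = s))
    expect_identical(classify_traces(gen$traces)$group, gen$labels)
  }
})

test_that("profile sharpening narrows the overlap and raises ligand coupling", {
  cfg <- synth_config(seed = 6)
  widths <- r_log <- numeric(3)
  for (sg in 1:3) {
    gp <- generate_profiles(cfg, sg, noise_sd = 0)
    nm <- normalize_profile(gp$profile)
    seg <- segregation_metrics(gp$profile$positions, nm[, "Dll"], nm[, "Lim1"])
    widths[sg] <- seg$overlap_width_um
    # noise-free opposing sigmoids cross exactly once: the difference is
    # strictly monotone with a single zero at the border
    d <- nm[, "Dll"] - nm[, "Lim1"]
    expect_true(all(diff(d) < 0))
    expect_equal(seg$crossing_um, 0, tolerance = 1e-8)
    r_log[sg] <- cor(log(gp$cells$Dll / gp$cells$Lim1),
                     log(gp$cells$Dl / gp$cells$Ser))
  }
  expect_true(all(diff(widths) < 0))
  expect_true(all(diff(r_log) > 0))
})

test_that("sample ligand correlation tracks the configured coefficients at n=50 per draw", {
  # pooled over draws, the sample Pearson r of the log-ratios rises from the
  # stage-1 to the stage-3 configuration
  cfg0 <- synth_config()
  rs <- sapply(1:6, function(s) {
    cfg <- synth_config(seed = 200 + s, n_cells_profile = 50)
    sapply(c(1, 3), function(sg) {
      d <- generate_profiles(cfg, sg)$cells
      cor(log(d$Dll / d$Lim1), log(d$Dl / d$Ser))
    })
  })
  expect_lt(mean(rs[1, ]), mean(rs[2, ]))
  expect_lt(abs(mean(rs[1, ]) - cfg0$ligand_correlation[1]), 0.15)
  expect_lt(abs(mean(rs[2, ]) - cfg0$ligand_correlation[3]), 0.1)
})

test_that("co-expression flags are exact generator inputs", {
  cfg <- synth_config(seed = 8, n_cells_profile = 100,
                      n_coexpr = c(3L, 1L, 0L))
  gp <- generate_profiles(cfg, 1)
  expect_equal(sum(gp$cells$true_coexpr), 3)
  co <- coexpression_percent(gp$cells,
                             c(Dll = gp$threshold, Lim1 = gp$threshold))
  expect_equal(co$percent, 3)
  expect_identical(co$calls, gp$cells$true_coexpr)
})

test_that("clone generation honors sidedness counts and the margin", {
  cfg <- synth_config(seed = 10)
  for (args in list(list(n = 5, k = 5), list(n = 5, k = 0),
                    list(n = 12, k = 4))) {
    gen <- generate_clones(cfg, "m-L2", args$n, args$k)
    calls <- vapply(gen$clones, score_clone, character(1), fold = gen$fold)
    expect_equal(sum(calls == "restricted"), args$k)
    ids <- vapply(gen$clones, function(cl) cl$clone_id, character(1))
    expect_identical(calls == "restricted",
                     gen$truth$restricted[match(ids, gen$truth$clone_id)])
    for (cl in gen$clones) {
      d <- signed_distance(as.matrix(cl$cells[, c("x", "y")]), gen$fold)
      expect_true(all(abs(d) >= cfg$clone_margin))
    }
  }
  expect_error(generate_clones(synth_config(seed = 1, clone_margin = -1)),
               "margin")
  expect_error(generate_clones(cfg, "m-L2", 4, 9), "<= n_clones")
})

test_that("contour stacks carry closed-form volumes at the configured ratios", {
  cfg <- synth_config(seed = 12)
  gen <- generate_contour_stacks(cfg, 6, 6)
  meas <- measure_stacks(gen$stacks)
  chk <- merge(meas, gen$truth, by = c("cell_id", "domain"))
  expect_equal(chk$volume_um3, chk$true_volume_um3, tolerance = 1e-10)
  for (dm in c("apical", "basolateral")) {
    tr <- gen$truth[gen$truth$domain == dm, ]
    want <- if (dm == "apical") cfg$volume_ratio_apical else
      cfg$volume_ratio_basolateral
    expect_equal(mean(tr$true_volume_um3[tr$fold]) /
                   mean(tr$true_volume_um3[!tr$fold]), want)
  }
  # z spacing follows the per-domain optical interval
  ap <- gen$stacks[[1]]
  expect_equal(unique(round(diff(ap$z), 10)), slice_interval(ap$domain))
  # fold-free request yields only non-fold stacks
  nf <- generate_contour_stacks(cfg, 0, 4)
  expect_true(all(grepl("^nonfold_", vapply(nf$stacks, function(s) s$cell_id,
                                            character(1)))))
})

test_that("track generation yields exact crossing labels across 10 seeds", {
  for (s in 1:10) {
    gen <- generate_tracks(synth_config(seed = s), 4, 6)
    for (i in seq_along(gen$tracks)) {
      ev <- crossing_events(gen$tracks[[i]], gen$fold)
      id <- gen$tracks[[i]]$track_id
      expect_equal(ev$crossed, gen$truth$crosses[gen$truth$track_id == id])
      if (ev$crossed) expect_length(ev$times, 1)
    }
  }
})

test_that("confined-only sets cross nowhere and matched groups are comparable", {
  gen <- generate_tracks(synth_config(seed = 21), 0, 13)
  expect_length(gen$tracks, 13)
  crossed <- vapply(gen$tracks, function(tr)
    crossing_events(tr, gen$fold)$crossed, logical(1))
  expect_false(any(crossed))
  # displacement scale matched between groups at n = 50 per group
  big <- generate_tracks(synth_config(seed = 22), 50, 50)
  grp <- vapply(big$tracks, function(tr) tr$group, character(1))
  tst <- group_displacement_test(big$tracks[grp == "CALI"],
                                 big$tracks[grp == "non-CALI"])
  expect_gt(min(tst$p_value[tst$quantity %in% c("dx", "dy")]), 0.05)
})
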