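test_that("mineralization_series tracks substrate-derived DIC", {
  th <- seq(0, 24, 4)

  # everything at background: identically zero
  f_bg <- 0.0110
  d13_bg <- atom_fraction_to_delta(f_bg)
  ser <- mineralization_series(th, rep(2000, 7), rep(d13_bg, 7))
  expect_equal(ser$tracer_mmol_m2, rep(0, 7))

  # constant DIC, atom fraction rising linearly by 0.001 over the day
  cst <- conversion_constants(label_atom_pct = 49.4)
  f <- f_bg + 0.001 * th / 24
  ser <- mineralization_series(th, rep(2000, 7), atom_fraction_to_delta(f),
                               constants = cst, background = f_bg)
  pool_final <- 2000 * POOL_PER_UM              # 967.66 mmol m^-2
  expect_equal(ser$tracer_mmol_m2[7], pool_final * 0.001 / 0.483,
               tolerance = 1e-6)
  # and the whole series is linear in time
  expect_equal(ser$tracer_mmol_m2, pool_final * 0.001 * th / 24 / 0.483,
               tolerance = 1e-6)

  expect_error(
    mineralization_series(th, rep(2000, 7),
                          c(d13_bg, NA, rep(d13_bg, 5))),
    "missing delta-13C")
})

test_that("mineralization_rate recovers noiseless slopes", {
  th <- seq(0, 24, 4)
  ser <- data.frame(time_h = th, tracer_mmol_m2 = 0.143 * th / 24)
  expect_equal(mineralization_rate(ser), 0.143, tolerance = 1e-9)
  expect_equal(mineralization_rate(ser, include_t0 = TRUE), 0.143,
               tolerance = 1e-9)
  ser$tracer_mmol_m2 <- 0
  expect_equal(mineralization_rate(ser), 0)
  expect_error(mineralization_rate(ser[1:3, ]), "3 timepoints")
})

test_that("bacterial_uptake scales biomarker tracer carbon to biomass carbon", {
  cst <- conversion_constants()
  f_bg <- delta_to_atom_fraction(-25)
  mk <- function(tracer) {
    pools <- c("i15:0" = 0.55, "ai15:0" = 0.50, "i16:0" = 0.35)
    f <- f_bg + tracer * (cst$f_label - f_bg) / pools
    data.frame(plfa = names(pools), carbon_mmol_m2 = unname(pools),
               atom_pct_13C = 100 * unname(f))
  }
  # unlabelled
  expect_equal(bacterial_uptake(mk(c(0, 0, 0)), f_bg, cst), 0,
               tolerance = 1e-9)
  # total biomarker tracer 0.01 mmol -> 0.01 / (0.10 * 0.056)
  i_b <- bacterial_uptake(mk(c(0.004, 0.004, 0.002)), f_bg, cst)
  expect_equal(i_b, 1.7857, tolerance = 1e-4)

  expect_error(bacterial_uptake(mk(c(0, 0, 0))[1:2, ], f_bg, cst), "i16:0")
  dup <- rbind(mk(c(0, 0, 0)), mk(c(0, 0, 0))[1, ])
  expect_error(bacterial_uptake(dup, f_bg, cst), "duplicate")
})

test_that("bge and percent_of_added reproduce their defining arithmetic", {
  expect_equal(bge(1, 1), 0.5)
  expect_true(is.na(bge(0, 0)))
  # scale invariance
  expect_equal(bge(0.096, 0.143), bge(9.6, 14.3))
  # strictly increasing in uptake at fixed respiration
  i <- seq(0.01, 2, length.out = 30)
  expect_true(all(diff(bge(i, 0.7)) > 0))

  expect_equal(percent_of_added(0, 4.16), 0)
  expect_equal(percent_of_added(2.08, 4.16, duration_d = 0.5), 25)
  expect_error(percent_of_added(1, 0), "positive")
})

test_that("budget closure: noiseless generator truths are recovered to < 0.5%", {
  ex <- generate_experiment(generator_config(seed = 3, noise = "none"))
  bud <- tracer_budget_table(ex$water, ex$plfa, ex$design)
  tr <- ex$truth
  for (i in seq_len(nrow(bud))) {
    cid <- bud$core_id[i]
    expect_equal(bud$R_B[i], tr$mineralization_per_core[[cid]],
                 tolerance = 5e-3)
    expect_equal(bud$I_B[i], tr$uptake_per_core[[cid]], tolerance = 5e-3)
  }
  # mass sanity: substrate-derived DIC pool never exceeds the added carbon
  added <- ex$design$added_mmol_m2[match(bud$core_id, ex$design$core_id)]
  dic <- ex$water[ex$water$solute == "DIC" &
                    ex$water$core_id %in% bud$core_id, ]
  for (i in seq_len(nrow(bud))) {
    d <- dic[dic$core_id == bud$core_id[i], ]
    ser <- mineralization_series(d$time_h, d$conc_uM, d$delta13C)
    expect_true(all(ser$tracer_mmol_m2 <= added[i]))
  }
})

test_that("noisy budgets are unbiased around the generator truths", {
  # across seeds the across-core treatment means scatter around Table-level truths
  est <- t(vapply(1:40, function(s) {
    ex <- generate_experiment(generator_config(seed = s))
    bud <- tracer_budget_table(ex$water, ex$plfa, ex$design)
    c(mean(bud$R_B[bud$treatment == "medium"]),
      mean(bud$I_B[bud$treatment == "medium"]))
  }, numeric(2)))
  expect_equal(mean(est[, 1]), 1.149, tolerance = 0.03)
  expect_equal(mean(est[, 2]), 1.314, tolerance = 0.05)
})

test_that("budget_report renders treatment columns and is order-invariant", {
  ex <- generate_experiment(generator_config(seed = 8, noise = "none"))
  bud <- tracer_budget_table(ex$water, ex$plfa, ex$design)
  rep1 <- budget_report(bud, c("low", "medium", "high"))
  expect_equal(unique(rep1$summary$quantity),
               c("Mineralization", "Bacterial uptake", "BGE"))
  expect_equal(round(rep1$summary$mean[rep1$summary$quantity == "BGE"], 2),
               c(0.40, 0.53, 0.55))
  expect_equal(rep1$summary$pct[rep1$summary$quantity == "Mineralization"],
               c(3.4, 2.8, 1.6), tolerance = 0.05)

  # permuting core rows leaves the report unchanged
  rep2 <- budget_report(bud[sample(nrow(bud)), ], c("low", "medium", "high"))
  expect_equal(rep1$summary, rep2$summary)
  expect_equal(rep1$text, rep2$text)

  # single-treatment input gives a single column
  rep3 <- budget_report(bud[bud$treatment == "low", ], "low")
  expect_equal(unique(rep3$summary$treatment), "low")
})
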