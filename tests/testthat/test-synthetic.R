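test_that("generated experiments have the design's structure", {
  ex <- generate_experiment(generator_config(seed = 1))
  expect_equal(nrow(ex$design), 12)
  expect_equal(unname(table(ex$design$treatment)[c("control", "low",
                                                   "medium", "high")]),
               rep(3L, 4), ignore_attr = TRUE)
  # 12 cores x 7 timepoints per solute
  expect_equal(unname(table(ex$water$solute)), rep(84L, 4),
               ignore_attr = TRUE)
  # PLFA table covers all 12 cores, 9 of them labelled
  expect_equal(length(unique(ex$plfa$core_id)), 12)
  labelled <- ex$design$core_id[ex$design$treatment != "control"]
  expect_equal(length(labelled), 9)
  # only DIC carries isotope values
  expect_true(all(is.na(ex$water$delta13C[ex$water$solute != "DIC"])))
  expect_true(all(!is.na(ex$water$delta13C[ex$water$solute == "DIC"])))
})

test_that("the generator is deterministic in its seed", {
  e1 <- generate_experiment(generator_config(seed = 42))
  e2 <- generate_experiment(generator_config(seed = 42))
  expect_identical(e1$water, e2$water)
  expect_identical(e1$plfa, e2$plfa)
  expect_identical(e1$truth, e2$truth)
  e3 <- generate_experiment(generator_config(seed = 43))
  expect_false(identical(e1$water, e3$water))
})

test_that("control cores show no isotope labelling", {
  ex <- generate_experiment(generator_config(seed = 4))
  ctrl <- ex$design$core_id[ex$design$treatment == "control"]
  f_bg <- delta_to_atom_fraction(-25)
  f_ctrl <- ex$plfa$atom_pct_13C[ex$plfa$core_id %in% ctrl] / 100
  expect_lt(max(abs(excess_atom_fraction(f_ctrl, f_bg))), 5e-5)
  dic <- ex$water[ex$water$solute == "DIC" & ex$water$core_id %in% ctrl, ]
  expect_lt(max(abs(dic$delta13C)), 25)  # stays near the 0 per-mil background
})

test_that("label mass balance holds: tracer in DIC + PLFA never exceeds the dose", {
  for (s in c(2, 9)) {
    ex <- generate_experiment(generator_config(seed = s))
    lab <- ex$design[ex$design$treatment != "control", ]
    for (i in seq_len(nrow(lab))) {
      dic_final <- ex$truth$dic_tracer[match(lab$core_id[i],
                                             ex$design$core_id),
                                       length(ex$config$times_h)]
      cst <- conversion_constants()
      plfa_total <- ex$truth$uptake_per_core[[lab$core_id[i]]] *
        cst$biomarker_fraction * cst$plfa_c_per_biomass_c /
        sum(ex$truth$allocation[[lab$core_id[i]]][cst$biomarkers])
      expect_lt(dic_final + plfa_total, lab$added_mmol_m2[i])
    }
  }
})

test_that("the noiseless generator and the analysis pipeline are inverse maps", {
  ex <- generate_experiment(generator_config(seed = 5, noise = "none"))
  bud <- tracer_budget_table(ex$water, ex$plfa, ex$design)
  means <- aggregate(cbind(R_B, I_B, BGE) ~ treatment, bud, mean)
  means <- means[match(c("low", "medium", "high"), means$treatment), ]
  expect_equal(means$R_B, c(0.143, 1.149, 6.589), tolerance = 5e-3)
  expect_equal(means$I_B, c(0.096, 1.314, 8.201), tolerance = 5e-3)
  expect_equal(round(means$BGE, 2), c(0.40, 0.53, 0.55))

  # proportional-uptake fingerprint reproduces the allocation vectors
  bg <- plfa_background(ex$plfa, ex$design)
  cst <- conversion_constants()
  cid <- bud$core_id[bud$treatment == "medium"][1]
  tc <- plfa_tracer_carbon(ex$plfa[ex$plfa$core_id == cid, ], bg, cst)
  alloc <- ex$truth$allocation[[cid]]
  expect_equal(unname(tc / sum(tc)), unname(alloc[names(tc)]),
               tolerance = 1e-6)

  # solute slopes recovered exactly per core
  pc <- per_core_rates(ex$water)
  for (s in c("NH4", "TOx", "O2")) {
    expect_equal(unique(round(pc$slope[pc$solute == s], 9)),
                 ex$config$solutes[[s]]$slope, tolerance = 1e-6)
  }
})

test_that("fixtures are canned deterministic datasets", {
  tiny <- make_fixture("tiny")
  expect_equal(nrow(tiny$design), 4)
  expect_equal(length(unique(tiny$water$time_h)), 3)
  expect_equal(length(unique(tiny$plfa$plfa)), 5)

  pd1 <- make_fixture("paper_defaults")
  pd2 <- make_fixture("paper_defaults")
  expect_identical(pd1$water, pd2$water)

  ne <- make_fixture("null_effect")
  expect_equal(unname(ne$config$mineralization),
               rep(1.149, 3), ignore_attr = TRUE)
  expect_error(make_fixture("bogus"))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(mineralization = c(low = 0.1)),
               "missing mineralization")
  expect_error(generator_config(plfa_profile = c("16:0" = 1)),
               "biomarker")
  expect_error(generator_config(times_h = c(4, 0)))
})
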