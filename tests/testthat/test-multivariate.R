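test_that("the default exclusion list removes diatom-type compounds and keeps 10-Me18:0", {
  nm <- plfa_vocabulary()
  ex <- default_plfa_exclusions(nm)
  expect_true(all(c("14:0", "16:1(n-7)", "16:1(n-5)", "16:0", "18:0",
                    "18:1(n-7)", "18:1(n-9)", "18:2(n-6)") %in% ex))
  expect_false("10-Me18:0" %in% ex)
  expect_false("i15:0" %in% ex)
  # widened rule also takes the methyl-branched C18
  expect_true("10-Me18:0" %in% default_plfa_exclusions(
    nm, exclude_methyl_c18 = TRUE))
})

test_that("proportional_uptake renormalizes rows and is scale invariant", {
  tr <- expand.grid(core_id = c("A", "B"),
                    plfa = c("i15:0", "ai15:0", "17:0cy", "16:0"),
                    stringsAsFactors = FALSE)
  tr$tracer_mmol_m2 <- c(1, 2, 2, 4, 1, 2, 10, 20)
  m <- proportional_uptake(tr)  # 16:0 excluded by default
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-12)

  # doubling one core's tracer leaves its row unchanged
  tr2 <- tr
  tr2$tracer_mmol_m2[tr2$core_id == "A"] <-
    2 * tr2$tracer_mmol_m2[tr2$core_id == "A"]
  expect_equal(proportional_uptake(tr2), m)

  # a single included compound gives a column of ones
  m1 <- proportional_uptake(tr, exclude = c("ai15:0", "17:0cy", "16:0"))
  expect_equal(unname(m1[, 1]), c(1, 1))

  tr$tracer_mmol_m2[tr$plfa != "16:0"] <- 0
  expect_error(proportional_uptake(tr), "<= 0")
})

test_that("correlation_pca matches the SVD oracle and its algebraic identities", {
  set.seed(31)
  x <- matrix(rnorm(9 * 6), 9, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  pc <- correlation_pca(x)

  # oracle: singular values of the standardized matrix
  z <- scale(x)
  sv <- svd(z / sqrt(nrow(x) - 1))
  expect_equal(pc$eigenvalues, sv$d^2, tolerance = 1e-8)
  for (j in 1:6) {
    expect_equal(abs(pc$loadings[, j]), abs(sv$v[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # eigenvalue sum equals the number of columns
  expect_equal(sum(pc$eigenvalues), ncol(x), tolerance = 1e-9)

  # orthonormal loadings, uncorrelated scores
  expect_equal(crossprod(pc$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  cv <- crossprod(pc$scores) / (nrow(x) - 1)
  expect_equal(cv, diag(pc$eigenvalues), tolerance = 1e-8,
               ignore_attr = TRUE)

  # sign convention: each component's largest-magnitude loading is positive
  for (j in 1:6) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }

  # scores reproduce inter-sample distances of the standardized data
  expect_equal(dist(pc$scores), dist(z), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("two perfectly correlated columns load entirely on PC1", {
  x <- cbind(a = 1:8, b = 2 * (1:8) + 3)
  pc <- suppressWarnings(correlation_pca(x))
  expect_equal(pc$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(pc$prop_variance[1], 1, tolerance = 1e-9)
  expect_error(correlation_pca(x[1, , drop = FALSE]), "2 rows")
  expect_warning(correlation_pca(cbind(x, c = rep(1, 8))), "zero-variance")
})

test_that("treatment fingerprints separate on the first two components", {
  ex <- generate_experiment(generator_config(seed = 77))
  bud <- tracer_budget_table(ex$water, ex$plfa, ex$design)
  bg <- plfa_background(ex$plfa, ex$design)
  cst <- conversion_constants()
  tr <- do.call(rbind, lapply(bud$core_id, function(cid) {
    tc <- plfa_tracer_carbon(ex$plfa[ex$plfa$core_id == cid, ], bg, cst)
    data.frame(core_id = cid, plfa = names(tc),
               tracer_mmol_m2 = unname(tc), stringsAsFactors = FALSE)
  }))
  pc <- correlation_pca(proportional_uptake(tr))
  sc <- pc$scores[, 1:2]
  grp <- ex$design$treatment[match(rownames(sc), ex$design$core_id)]
  D <- as.matrix(dist(sc))
  same <- outer(grp, grp, "==") & upper.tri(D)
  diff <- !outer(grp, grp, "==") & upper.tri(D)
  expect_gt(mean(D[diff]), mean(D[same]))
})
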