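test_that("markov fit: identity for unchanged rasters, rows sum to 1", {
  cfg <- small_cfg(40, seed = 21)
  lu <- gen_landuse(cfg, gen_drivers(cfg))
  fit <- fit_markov(lu, lu)
  expect_equal(unname(fit$P), diag(6))
  expect_equal(unname(rowSums(fit$P)), rep(1, 6))
  expect_error(fit_markov(lu, land_raster(matrix(1L, 10, 10))), "geometry")
})

test_that("markov fit recovers the injected matrix within binomial error", {
  cfg <- synth_config(grid_shape = c(500, 500), seed = 22)
  d <- gen_drivers(cfg)
  lu1 <- gen_landuse(cfg, d)
  lu2 <- evolve_landuse(lu1, cfg$true_transition, cfg, d)
  fit <- fit_markov(lu1, lu2, interval = 15)
  P <- cfg$true_transition
  n_row <- class_counts(lu1)
  for (a in 1:6) {
    se <- sqrt(P[a, ] * (1 - P[a, ]) / n_row[a])
    expect_true(all(abs(fit$P[a, ] - P[a, ]) <= pmax(3 * se, 1 / n_row[a])),
                info = paste("row", a))
  }
  td <- tidy(fit)
  expect_equal(nrow(td), 36)
  expect_equal(sum(td$n_cells), 500 * 500)
})

test_that("demand projection follows the matrix power and conserves total", {
  P <- rbind(c(0.9, 0.1), c(0, 1))
  expect_equal(unname(project_demand(P, c(100, 0), steps = 2)), c(81, 19))
  expect_equal(unname(project_demand(P, c(100, 0), steps = 1)),
               drop(t(P) %*% c(100, 0)))
  expect_equal(project_demand(diag(3), c(5, 2, 9), steps = 7), c(5, 2, 9))
  S <- project_demand(default_transition(), c(100, 10, 1, 20, 30, 2),
                      horizon = 30, interval = 15)
  expect_equal(sum(S), 163)
  expect_error(project_demand(P, c(1, 1), horizon = 7, interval = 15),
               "multiple")
})

test_that("demand-to-cells rounding conserves totals exactly", {
  d <- demand_to_cells(c(a = 1453.65, b = 37.67, c = 0.15, d = 225.29,
                         e = 297.63, f = 2.24), 40000)
  expect_equal(sum(d), 40000L)
  expect_true(all(d >= 0))
  expect_error(demand_to_cells(c(-1, 2), 10), "negative")
})

test_that("suitability model learns the generated landscape", {
  cfg <- small_cfg(100, seed = 23)
  d <- gen_drivers(cfg)
  lu <- gen_landuse(cfg, d)
  fit <- train_suitability(lu, d, seed = 31)
  pr <- fit$prob
  # per-cell probabilities sum to 1
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0 & pr <= 1))
  # held-out accuracy: cells not sampled for training
  hold <- setdiff(seq_along(lu$values), fit$sample_idx)
  pred <- max.col(pr[hold, ], ties.method = "first")
  expect_gt(mean(pred == as.vector(lu$values)[hold]), 0.7)
  # determinism under fixed seed
  fit2 <- train_suitability(lu, d, seed = 31)
  expect_identical(fit$prob, fit2$prob)
})

test_that("stratified resampling keeps rare classes in the training set", {
  cfg <- small_cfg(60, seed = 24,
                   class_proportions = c(0.989, 0, 0.001, 0, 0.01, 0))
  d <- gen_drivers(cfg)
  lu <- gen_landuse(cfg, d)  # grassland: ~4 cells of 3600
  fit <- train_suitability(lu, d, sample_frac = 0.05, seed = 32)
  expect_true(all(sort(unique(as.vector(lu$values))) %in%
                    as.vector(lu$values)[fit$sample_idx]))
})

test_that("neighborhood effect matches the window definition", {
  uni <- land_raster(matrix(2L, 10, 10))
  om <- neighborhood_effect(uni, 2L, N = 3, weight = 1)
  expect_equal(om[2:9, 2:9], matrix(1, 8, 8))  # 8/8 at interior cells
  # truncated edge window keeps the N^2 - 1 denominator
  expect_equal(om[1, 1], 3 / 8)
  expect_true(all(neighborhood_effect(uni, 5L, N = 3) == 0))
  expect_error(neighborhood_effect(uni, 2L, N = 4), "odd")
  # brute-force window count at 100 random cells
  set.seed(33)
  m <- matrix(sample(1:6, 900, replace = TRUE), 30, 30)
  om5 <- neighborhood_effect(land_raster(m), 4L, N = 5, weight = 0.43)
  cells <- cbind(sample(30, 100, TRUE), sample(30, 100, TRUE))
  for (i in seq_len(100)) {
    ri <- max(1, cells[i, 1] - 2):min(30, cells[i, 1] + 2)
    ci <- max(1, cells[i, 2] - 2):min(30, cells[i, 2] + 2)
    cnt <- sum(m[ri, ci] == 4L) - (m[cells[i, 1], cells[i, 2]] == 4L)
    expect_equal(om5[cells[i, 1], cells[i, 2]], cnt / 24 * 0.43)
  }
})

test_that("adaptive inertia follows the printed three-case rule", {
  # equal gaps: unchanged
  expect_equal(update_inertia(1, D_prev1 = -10, D_prev2 = -10), 1)
  expect_equal(update_inertia(2.5, D_prev1 = 5, D_prev2 = 5), 2.5)
  # overshoot worsening: 0 > D(t-2) > D(t-1) -> multiply by D(t-2)/D(t-1)
  expect_equal(update_inertia(1, D_prev1 = -20, D_prev2 = -10), 0.5)
  # shortfall worsening: D(t-1) > D(t-2) > 0 -> multiply by D(t-1)/D(t-2)
  expect_equal(update_inertia(1, D_prev1 = 20, D_prev2 = 10), 2)
  # first case of the printed rule: D(t-2) <= D(t-1) -> unchanged
  expect_equal(update_inertia(1, D_prev1 = -10, D_prev2 = -20), 1)
  expect_equal(update_inertia(1, D_prev1 = 10, D_prev2 = 20), 1)
  # zero gap treated as converged for the class
  expect_equal(update_inertia(3, D_prev1 = 0, D_prev2 = 10), 3)
  # absolute-gap convention damps overshoot symmetrically
  expect_equal(update_inertia(1, -20, -10, convention = "absolute"), 0.5)
  expect_equal(update_inertia(1, -10, -20, convention = "absolute"), 1)
  expect_equal(update_inertia(1, 20, 10, convention = "absolute"), 2)
  # vectorized over classes
  expect_equal(update_inertia(c(1, 1), c(-20, 20), c(-10, 10)), c(0.5, 2))
})

test_that("allocation converges immediately when demand equals counts", {
  cfg <- small_cfg(40, seed = 25)
  d <- gen_drivers(cfg)
  lu <- gen_landuse(cfg, d)
  suit <- train_suitability(lu, d, seed = 34)
  run <- allocate_landuse(lu, suit, class_counts(lu), seed = 35)
  expect_true(run$converged)
  expect_equal(run$iterations, 1L)
  expect_identical(run$raster$values, lu$values)
})

test_that("a fully restrictive source row is never converted away", {
  cfg <- small_cfg(50, seed = 26)
  d <- gen_drivers(cfg)
  lu <- gen_landuse(cfg, d)
  S <- class_counts(lu)
  # move 5% of cultivated land to construction, but forbid leaving cultivated
  demand <- S
  shift <- round(0.05 * S[["cultivated"]])
  demand[["cultivated"]] <- S[["cultivated"]] - shift
  demand[["construction"]] <- S[["construction"]] + shift
  allow <- matrix(1, 6, 6)
  allow[1, ] <- 0; allow[1, 1] <- 1
  suit <- train_suitability(lu, d, seed = 36)
  expect_warning(
    run <- allocate_landuse(lu, suit, demand, allowance = allow,
                            max_iter = 30, seed = 37),
    "residual")
  expect_gte(class_counts(run$raster)[["cultivated"]], S[["cultivated"]])
  # and no cultivated cell changed at all
  expect_equal(sum(lu$values == 1 & run$raster$values != 1), 0)
})

test_that("allocation meets demand, honors restrictions and allowances", {
  cfg <- small_cfg(100, seed = 27)
  d <- gen_drivers(cfg)
  lu <- gen_landuse(cfg, d)
  suit <- train_suitability(lu, d, seed = 38)
  S <- class_counts(lu)
  nd <- builtin_scenarios()$ND
  demand <- feasible_demand(
    demand_to_cells(project_demand(default_transition(), S), sum(S)),
    S, nd$allowance)
  restr <- gen_restriction(cfg, d, fraction = 0.1)
  run <- allocate_landuse(lu, suit, demand, allowance = nd$allowance,
                          weights = nd$weights, restriction = restr,
                          seed = 39)
  got <- class_counts(run$raster)
  # total cell count conserved exactly
  expect_equal(sum(got), sum(S))
  # per-class gap within the convergence contract
  expect_true(all(abs(got - demand) <= pmax(0.005 * demand, 10)))
  # large classes within the bare 0.5% band
  big <- demand >= 5000
  expect_true(all(abs(got[big] - demand[big]) <= 0.005 * demand[big]))
  # restricted cells never change
  expect_identical(run$raster$values[restr], lu$values[restr])
  # no forbidden transition occurred anywhere in the run
  moved <- which(run$raster$values != lu$values)
  expect_true(all(nd$allowance[cbind(lu$values[moved],
                                     run$raster$values[moved])] == 1))
  # run log is consistent
  g <- glance(run)
  expect_true(g$converged)
  # converged at the check of the final iteration: one log row block per
  # completed conversion pass
  expect_equal(nrow(tidy(run)), 6 * (run$iterations - 1))
})

test_that("degenerate uniform inputs allocate exactly to demand", {
  lu <- land_raster(matrix(rep(1:2, each = 50), 10, 10))
  sp <- matrix(1 / 6, 100, 6)
  demand <- c(30L, 70L, 0L, 0L, 0L, 0L)
  run <- allocate_landuse(lu, sp, demand, tol_cells = 0, seed = 40)
  expect_equal(unname(class_counts(run$raster)[1:2]), c(30L, 70L))
})

test_that("kappa: identity, symmetry, hand example and library oracle", {
  cfg <- small_cfg(40, seed = 28)
  d <- gen_drivers(cfg)
  lu <- gen_landuse(cfg, d)
  expect_equal(kappa_coefficient(lu, lu), 1)
  # hand example: confusion [[40,10],[10,40]] -> (0.8 - 0.5)/0.5 = 0.6
  a <- land_raster(matrix(rep(c(1L, 2L), each = 50), 10, 10))
  b_vals <- c(rep(1L, 40), rep(2L, 10), rep(2L, 40), rep(1L, 10))
  b <- land_raster(matrix(b_vals, 10, 10))
  expect_equal(kappa_coefficient(a, b), 0.6)
  expect_equal(kappa_coefficient(b, a), 0.6)
  # independent random rasters: near zero at 10^5 cells
  set.seed(41)
  r1 <- land_raster(matrix(sample(1:4, 1e5, TRUE), 400, 250))
  r2 <- land_raster(matrix(sample(1:4, 1e5, TRUE), 400, 250))
  expect_lt(abs(kappa_coefficient(r1, r2)), 0.02)
  # cross-check against e1071's agreement statistics
  cm <- table(factor(r1$values, 1:4), factor(r2$values, 1:4))
  expect_equal(kappa_coefficient(r1, r2),
               e1071::classAgreement(cm)$kappa)
})
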