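# Shared small fixtures for the maxent tests
stack_small <- gen_landscape(n_rows = 30, n_cols = 30, seed = 71)
truth_small <- truth_model(linear = c(bio1 = 3, bio16 = -2))
occ_small <- gen_occurrences(stack_small, truth_small, n = 200, seed = 72)
bg_small <- sample_background(stack_small, n = 600, seed = 73)

test_that("background sampling is masked, seeded, and exhaustive at the cap", {
  st <- gen_landscape(n_rows = 24, n_cols = 24, mask_fraction = 0.5,
                      seed = 61)
  vc <- valid_cells(st)
  bg <- sample_background(st, n = 100, seed = 1)
  expect_true(all(bg$cell %in% vc))
  expect_identical(bg, sample_background(st, n = 100, seed = 1))
  all_bg <- sample_background(st, n = 1e6, seed = 1)
  expect_equal(sort(all_bg$cell), sort(vc))
})

test_that("train/test splits are disjoint, exhaustive, and sized by the ratio", {
  pts <- data.frame(x = runif(100), y = runif(100))
  sp <- split_train_test(pts, 0.75, seed = 2)
  expect_equal(nrow(sp$train), 75L)
  expect_equal(nrow(sp$test), 25L)
  expect_equal(sort(c(as.numeric(rownames(sp$train)),
                      as.numeric(rownames(sp$test)))), 1:100)
  sp4 <- split_train_test(pts[1:4, ], 0.75, seed = 3)
  expect_equal(nrow(sp4$train), 3L)
  expect_equal(nrow(sp4$test), 1L)
})

test_that("rank-based AUC matches brute-force pair counting", {
  expect_equal(auc_scores(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(auc_scores(c(1, 2), c(5, 6)), 0)
  # single presence: fraction of background below it, ties at half
  set.seed(4)
  bg <- round(runif(200, 0, 10))
  p <- 5
  brute <- (sum(bg < p) + 0.5 * sum(bg == p)) / length(bg)
  expect_equal(auc_scores(p, bg), brute)
  # shuffled labels at large n sit near one half
  set.seed(5)
  s <- rnorm(4000)
  lab <- sample(rep(c(TRUE, FALSE), 2000))
  expect_equal(auc_scores(s[lab], s[!lab]), 0.5, tolerance = 0.03)
})

test_that("zero usable features yield the uniform distribution", {
  constant <- env_stack(list(flat = matrix(1, 20, 20)))
  occc <- data.frame(x = runif(10, 0, 20), y = runif(10, 0, 20))
  bgc <- sample_background(constant, 150, seed = 1)
  m <- fit_maxent(occc, bgc, stack = constant)
  expect_equal(length(m$lambda), 0L)
  raw <- predict(m, extract_env(constant, cells = bgc$cell),
                 transform = "raw")
  expect_equal(raw, rep(1 / 150, 150), tolerance = 1e-12)
})

test_that("raw Gibbs probabilities over the background sum to one after every fit", {
  for (reg in c(0.25, 1, 4)) {
    for (fs in list("linear", c("linear", "quadratic"),
                    c("linear", "quadratic", "hinge"))) {
      m <- fit_maxent(occ_small, bg_small, stack = stack_small,
                      variables = c("bio1", "bio16", "bio6"),
                      features = fs, reg_multiplier = reg)
      raw <- predict(m, extract_env(stack_small, cells = bg_small$cell,
                                    layers = m$variables),
                     transform = "raw")
      expect_equal(sum(raw), 1, tolerance = 1e-6)
      expect_true(all(m$trace$gain >= 0))  # monotone objective
    }
  }
})

test_that("Gibbs parameter recovery within 15 percent at n = 2000", {
  st <- make_contrast_stack(seed = 42)
  tr <- truth_model(linear = c(bio1 = 1.5, bio16 = -0.8))
  occ <- gen_occurrences(st, tr, n = 2000, seed = 43)
  bg <- sample_background(st, n = 10000, seed = 44)
  m <- fit_maxent(occ, bg, stack = st, features = "linear",
                  reg_multiplier = 0.01, dedupe = FALSE)
  expect_lt(abs(m$lambda[["bio1"]] - 1.5) / 1.5, 0.15)
  expect_lt(abs(m$lambda[["bio16"]] + 0.8) / 0.8, 0.15)
})

test_that("stronger penalties shrink weights toward zero, to uniformity", {
  Fp <- invascape:::feature_matrix(
    defs <- invascape:::build_feature_defs(
      bge <- extract_env(stack_small, cells = bg_small$cell,
                         layers = c("bio1", "bio16")),
      classes = c("linear", "quadratic")),
    extract_env(stack_small, cells = occ_small$cell,
                layers = c("bio1", "bio16")))
  Fb <- invascape:::feature_matrix(defs, bge)
  beta1 <- rep(0.005, ncol(Fb))
  fit1 <- invascape:::maxent_core(Fp, Fb, beta1)
  beta2 <- beta1
  beta2[1] <- beta1[1] * 50
  fit2 <- invascape:::maxent_core(Fp, Fb, beta2)
  expect_lte(abs(fit2$lambda[1]), abs(fit1$lambda[1]) + 1e-8)

  # effectively infinite penalty: all weights zero, prediction uniform
  m_inf <- fit_maxent(occ_small, bg_small, stack = stack_small,
                      variables = c("bio1", "bio16"),
                      reg_multiplier = 1e6)
  expect_true(all(abs(m_inf$lambda) < 1e-10))
})

test_that("suitability predictions stay in [0,1] and respect monotone features", {
  m <- fit_maxent(occ_small, bg_small, stack = stack_small,
                  variables = c("bio1", "bio16"), features = "linear")
  s <- predict(m, stack_small)
  expect_true(all(s[!is.na(s)] >= 0 & s[!is.na(s)] <= 1))
  rc <- response_curve(m, "bio1")
  if (m$lambda[["bio1"]] > 0) {
    expect_true(all(diff(rc$suitability) >= -1e-12))
  }
  # the fitted surface separates presences from background decently
  expect_gt(model_auc(m, occ_small, bg_small, stack_small), 0.6)
})

test_that("the true generating model is not outranked by fitted ones", {
  # evaluate on an independent presence draw from the same truth, so a
  # flexible fit cannot beat the oracle by memorizing training points
  occ_eval <- gen_occurrences(stack_small, truth_small, n = 300,
                              seed = 74)
  eta_true <- invascape:::truth_eta(stack_small, truth_small,
                                    occ_eval$cell)
  eta_bg <- invascape:::truth_eta(stack_small, truth_small,
                                  bg_small$cell)
  auc_oracle <- auc_scores(eta_true, eta_bg)
  m <- fit_maxent(occ_small, bg_small, stack = stack_small,
                  features = c("linear", "quadratic", "hinge"))
  expect_gte(auc_oracle,
             model_auc(m, occ_eval, bg_small, stack_small) - 0.02)
})

test_that("spearman screening drops the weaker of a correlated pair", {
  st <- gen_landscape(n_rows = 30, n_cols = 30, seed = 81)
  st$layers$bio1_dup <- st$layers$bio1
  occ <- gen_occurrences(st, truth_model(linear = c(bio1 = 2)),
                         n = 100, seed = 82)
  sc <- spearman_screen(st, occ, threshold = 0.75, n_background = 500,
                        seed = 83)
  expect_true(xor("bio1" %in% sc$retained, "bio1_dup" %in% sc$retained))
  # planted 0.9 pair: exactly one member survives
  expect_true(xor("bio12" %in% sc$retained, "bio16" %in% sc$retained))
  # categorical layer is never screened out
  expect_true("landcover" %in% sc$retained)

  # independent rough layers both survive
  st2 <- env_stack(list(u = matrix(runif(900), 30),
                        v = matrix(runif(900), 30)))
  occ2 <- data.frame(x = runif(50, 0, 30), y = runif(50, 0, 30))
  sc2 <- spearman_screen(st2, occ2, n_background = 400, seed = 84)
  expect_setequal(sc2$retained, c("u", "v"))

  # constant layers are flagged and excluded
  st3 <- env_stack(list(u = matrix(runif(900), 30),
                        k = matrix(2, 30, 30)))
  expect_warning(sc3 <- spearman_screen(st3, occ2, n_background = 400,
                                        seed = 85), "constant")
  expect_false("k" %in% sc3$retained)
})

test_that("percent contribution credits the informative variable", {
  m <- fit_maxent(occ_small, bg_small, stack = stack_small,
                  variables = c("bio1", "bio16", "bio14"),
                  features = "linear")
  pc <- percent_contribution(m)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-9)
  expect_true(all(pc$percent >= 0))
  expect_equal(pc$variable[1], "bio1")  # the dominant planted signal

  # single-variable model takes all the credit
  m1 <- fit_maxent(occ_small, bg_small, stack = stack_small,
                   variables = "bio1", features = "linear")
  pc1 <- percent_contribution(m1)
  expect_equal(pc1$percent, 100)

  # symmetric duplicated signal splits the credit roughly in half
  st_sym <- make_contrast_stack(seed = 55, n = 50)
  st_sym$layers$bio16 <- st_sym$layers$bio1  # identical twin layers
  occ_sym <- gen_occurrences(st_sym,
                             truth_model(linear = c(bio1 = 1, bio16 = 1)),
                             n = 500, seed = 56)
  bg_sym <- sample_background(st_sym, 1500, seed = 57)
  m_sym <- fit_maxent(occ_sym, bg_sym, stack = st_sym,
                      features = "linear", dedupe = FALSE)
  pc_sym <- percent_contribution(m_sym)
  expect_equal(pc_sym$percent[1], 50, tolerance = 5)
})

test_that("permutation importance vanishes for unused variables and sums to 100", {
  m <- fit_maxent(occ_small, bg_small, stack = stack_small,
                  variables = c("bio1", "bio16", "bio14"),
                  features = "linear", reg_multiplier = 2)
  pi <- permutation_importance(m, occ_small, bg_small,
                               stack = stack_small, seed = 6)
  expect_equal(sum(pi$percent), 100, tolerance = 0.1)
  expect_true(all(pi$percent >= 0))
  expect_equal(pi$variable[1], "bio1")
  unused <- pi[vapply(pi$variable, function(v) {
    all(abs(m$lambda[grep(paste0("^", v), names(m$lambda))]) < 1e-12)
  }, logical(1)), ]
  if (nrow(unused) > 0) expect_true(all(unused$percent == 0))
})

test_that("jackknife gains isolate signal and redundancy", {
  st <- make_contrast_stack(seed = 91, n = 60)
  st$layers$noise <- invascape:::with_seed(92, matrix(rbeta(3600, 0.3, 0.3), 60, 60))
  occ <- gen_occurrences(st, truth_model(linear = c(bio1 = 2.5)),
                         n = 400, seed = 93)
  bg <- sample_background(st, 1200, seed = 94)
  m <- fit_maxent(occ, bg, stack = st, features = "linear",
                  dedupe = FALSE)
  jk <- jackknife_gains(m, occ, bg, stack = st, features = "linear")
  expect_true(all(jk$gain_only >= -1e-9))
  g <- stats::setNames(jk$gain_only, jk$variable)
  expect_gt(g[["bio1"]], g[["noise"]])
  expect_lt(g[["noise"]], 0.05)

  # a duplicated variable is redundant: dropping it barely costs gain
  st2 <- make_contrast_stack(seed = 95, n = 60)
  st2$layers$bio16 <- st2$layers$bio1
  occ2 <- gen_occurrences(st2, truth_model(linear = c(bio1 = 2)),
                          n = 400, seed = 96)
  bg2 <- sample_background(st2, 1200, seed = 97)
  m2 <- fit_maxent(occ2, bg2, stack = st2, features = "linear",
                   dedupe = FALSE)
  jk2 <- jackknife_gains(m2, occ2, bg2, stack = st2, features = "linear")
  full <- attr(jk2, "full_gain")
  without_b16 <- jk2$gain_without[jk2$variable == "bio16"]
  expect_equal(without_b16, full, tolerance = 0.05)
})

test_that("response curves reflect the model's feature shapes", {
  # flat for a variable the model never uses
  m <- fit_maxent(occ_small, bg_small, stack = stack_small,
                  variables = c("bio1", "bio14"), features = "linear",
                  reg_multiplier = 2)
  if (all(abs(m$lambda[grep("bio14", names(m$lambda))]) < 1e-12)) {
    rc <- response_curve(m, "bio14")
    expect_lt(diff(range(rc$suitability)), 1e-9)
  }
  # a concave quadratic fit to mid-range presences peaks inside the range
  st <- make_contrast_stack(seed = 98, n = 60)
  tru <- truth_model(linear = c(bio1 = 8), quadratic = c(bio1 = -8))
  occ <- gen_occurrences(st, tru, n = 600, seed = 99)
  bg <- sample_background(st, 1500, seed = 100)
  mq <- fit_maxent(occ, bg, stack = st, variables = "bio1",
                   features = c("linear", "quadratic"), dedupe = FALSE)
  rc <- response_curve(mq, "bio1", n_points = 101)
  peak <- which.max(rc$suitability)
  expect_gt(peak, 10)
  expect_lt(peak, 92)
})

test_that("model tuning prefers regularized fits on small samples by AICc", {
  st <- make_contrast_stack(seed = 111, n = 40)
  occ <- gen_occurrences(st, truth_model(linear = c(bio1 = 1.5)),
                         n = 25, seed = 112)
  bg <- sample_background(st, 800, seed = 113)
  tuned <- tune_model(occ, bg, stack = st,
                      reg_multipliers = c(0.05, 2),
                      feature_sets = list(c("linear", "quadratic",
                                            "hinge")),
                      n_hinge_knots = 8L, seed = 114)
  expect_equal(nrow(tuned$results), 2L)
  expect_equal(tuned$best$reg_multiplier, 2)

  single <- tune_model(occ, bg, stack = st, reg_multipliers = 1,
                       feature_sets = list("linear"), seed = 115)
  expect_equal(nrow(single$results), 1L)
  expect_equal(single$best$reg_multiplier, 1)
})

test_that("model fits are deterministic given identical inputs", {
  m1 <- fit_maxent(occ_small, bg_small, stack = stack_small,
                   variables = c("bio1", "bio16"), seed = 7)
  m2 <- fit_maxent(occ_small, bg_small, stack = stack_small,
                   variables = c("bio1", "bio16"), seed = 7)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$log_z, m2$log_z)
})
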