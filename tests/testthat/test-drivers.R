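test_that("driver table samples layers at plot cells and drops nodata", {
  st <- make_gradient_stack(20)
  sv <- make_plot("p1", c("Solidago canadensis", "x"),
                  abundance = c(5, 5), height = c(50, 50),
                  cover = c(0.3, 0.3), lon = 10.5, lat = 10.5)
  tab <- build_driver_table(sv, st, "Solidago canadensis",
                            env_vars = c("a", "b"))
  cell <- cell_index(st, 10.5, 10.5)
  expect_equal(tab$a, st$layers$a[cell])
  expect_equal(tab$response, 0.5)  # equal shares in a 2-species plot

  # plot on nodata gets dropped (and counted)
  st2 <- st
  st2$layers$a[cell] <- NA
  st2$layers$b[cell] <- NA
  sv2 <- bind_survey(sv, make_plot("p2", "y", 3, 20, 0.2,
                                   lon = 5.5, lat = 5.5))
  expect_message(tab2 <- build_driver_table(sv2, st2,
                                            "Solidago canadensis",
                                            env_vars = c("a", "b")),
                 "dropped")
  expect_equal(nrow(tab2), 1L)
  expect_equal(attr(tab2, "n_dropped"), 1L)

  # everything outside the extent is an error
  sv3 <- make_plot("p1", "y", 3, 20, 0.2, lon = 999, lat = 999)
  expect_error(build_driver_table(sv3, st, "Solidago canadensis",
                                  env_vars = c("a", "b")), "outside")
})

test_that("standardization is a population z-score and rejects constants", {
  tab <- data.frame(x = c(1, 2, 3), response = c(0, 0, 0))
  z <- standardize(tab, "x")
  expect_equal(z$x, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(standardize(z, "x")$x, z$x, tolerance = 1e-12)
  expect_error(standardize(data.frame(x = rep(1, 3)), "x"), "constant")
})

test_that("collinearity screen drops the weaker member of correlated pairs", {
  set.seed(5)
  n <- 200
  x1 <- rnorm(n)
  tab <- data.frame(response = x1 + rnorm(n, 0, 0.5),
                    a = x1, a_dup = x1, b = rnorm(n), c = rnorm(n))
  sc <- collinearity_screen(tab, c("a", "a_dup", "b", "c"))
  expect_equal(length(sc$retained), 3L)
  expect_equal(nrow(sc$dropped), 1L)
  expect_true(sc$dropped$dropped %in% c("a", "a_dup"))

  # independent noise columns all survive
  tab2 <- data.frame(response = rnorm(n), u = rnorm(n), v = rnorm(n),
                     w = rnorm(n))
  expect_setequal(collinearity_screen(tab2, c("u", "v", "w"))$retained,
                  c("u", "v", "w"))
})

test_that("GLM fit matches the normal-equation oracle", {
  set.seed(9)
  n <- 120
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tab$response <- 0.3 - 0.5 * tab$x1 + 0.2 * tab$x2 + rnorm(n, 0, 0.3)
  fit <- fit_glm(tab, predictors = c("x1", "x2"),
                 standardize_predictors = FALSE)
  X <- cbind(1, tab$x1, tab$x2)
  beta_hat <- solve(t(X) %*% X, t(X) %*% tab$response)
  expect_equal(fit$coefficients$estimate, as.numeric(beta_hat),
               tolerance = 1e-8)
  r2_direct <- 1 - sum((tab$response - X %*% beta_hat)^2) /
    sum((tab$response - mean(tab$response))^2)
  expect_equal(fit$r_squared, r2_direct, tolerance = 1e-10)

  # exact fit
  tab0 <- data.frame(x = 1:10, response = 2 * (1:10))
  f0 <- fit_glm(tab0, "x", standardize_predictors = FALSE)
  expect_equal(f0$coefficients$estimate[2], 2, tolerance = 1e-10)
  expect_equal(f0$r_squared, 1, tolerance = 1e-10)

  # null model: coefficient near zero, not significant
  set.seed(10)
  tabn <- data.frame(x = rnorm(500), response = rnorm(500))
  fn <- fit_glm(tabn, "x")
  expect_lt(abs(fn$coefficients$estimate[2]), 0.15)

  # singular designs are refused with the culprit named
  tabs <- data.frame(x = 1:10, y = 2 * (1:10), response = rnorm(10))
  expect_error(fit_glm(tabs, c("x", "y")), "singular")
})

test_that("fit is invariant to row order and predictor scaling", {
  st <- gen_landscape(n_rows = 30, n_cols = 30, seed = 21)
  sv <- gen_survey(st, n_plots = 150, seed = 22)
  tab <- build_driver_table(sv, st, "Solidago canadensis")
  fit <- fit_glm(tab)
  perm <- tab[sample.int(nrow(tab)), ]
  fit_p <- fit_glm(perm)
  expect_equal(fit$coefficients$estimate, fit_p$coefficients$estimate,
               tolerance = 1e-10)
  scaled <- tab
  scaled$bio1 <- scaled$bio1 * 1000
  fit_s <- fit_glm(scaled)
  expect_equal(fit$coefficients$estimate, fit_s$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("driver model recovers the planted diversity effect", {
  st <- gen_landscape(n_rows = 40, n_cols = 40, seed = 31)
  sv <- gen_survey(st, n_plots = 595, seed = 32)
  tab <- build_driver_table(sv, st, "Solidago canadensis")
  expect_equal(nrow(tab), 595L)
  fit <- fit_glm(tab)
  co <- fit$coefficients
  sh <- co[co$term == "shannon", ]
  expect_lt(sh$estimate, 0)
  expect_lt(sh$p_value, 0.001)
  expect_equal(sh$tier, "***")
  expect_gt(fit$r_squared, 0.3)
  expect_lt(fit$r_squared, 0.6)
})

test_that("the planted five-variable sign structure is recovered", {
  st <- gen_landscape(n_rows = 40, n_cols = 40, seed = 41)
  env_beta <- c(bio1 = 0.06, bio6 = -0.06, bio17 = 0.05, bio18 = -0.05)
  sv <- gen_survey(st, n_plots = 595, env_beta = env_beta, seed = 42)
  fit <- fit_glm(build_driver_table(sv, st, "Solidago canadensis"))
  co <- fit$coefficients
  est <- stats::setNames(co$estimate, co$term)
  expect_lt(est["shannon"], 0)
  expect_lt(est["bio6"], 0)
  expect_lt(est["bio18"], 0)
  expect_gt(est["bio1"], 0)
  expect_gt(est["bio17"], 0)
})
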