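test_that("analytic waiting times match the closed form and its symmetries", {
  p <- model_params(s = 0.01, c = 2)
  expect_equal(analytic_T_super(0, p), 0)
  expect_equal(analytic_T_driver(0, p), 0)
  # direct evaluation of the closed form (independent arithmetic)
  expect_equal(analytic_T_super(1, p),
               log(0.02 / (1e-8 * 10))^2 / (0.02 * log(1e9 * 1e6)))
  expect_equal(analytic_T_driver(3, p),
               3 * log(0.01 / (1e-8 * 100))^2 / (0.01 * log(1e9 * 1e6)))
  # linear in the number of mutations waited for
  expect_equal(analytic_T_super(4, p), 2 * analytic_T_super(2, p))
  # c = 1 with n = m collapses the two classes
  p1 <- model_params(n = 10, m = 10, s = 0.01, c = 1)
  expect_equal(analytic_T_super(3, p1), analytic_T_driver(3, p1))
  # ratio variant of the population-size term
  expect_equal(analytic_T_super(1, p, "ratio"),
               log(0.02 / 1e-7)^2 / (0.02 * log(1e3)))
  expect_error(analytic_T_super(1, model_params(s = 0, c = 1)), "advantage")
})

test_that("tau_approx is additive and monotone decreasing in c", {
  p <- model_params(s = 0.01, c = 2)
  expect_equal(tau_approx(0, 0, p), 0)
  expect_equal(tau_approx(2, 3, p),
               tau_approx(2, 0, p) + tau_approx(0, 3, p))
  taus <- vapply(c(1.1, 1.5, 2, 2.5, 3), function(cc)
    tau_approx(2, 3, model_params(s = 0.01, c = cc)), 0)
  expect_true(all(diff(taus) < 0))
})

test_that("empirical waiting times handle the trivial and censored cases", {
  p <- tiny_oracle_params()
  ens <- run_ensemble(p, 3, master_seed = 5)
  w00 <- empirical_waiting_time(ens, 0, 0)
  expect_equal(w00$mean, 0)
  expect_equal(w00$censored, 0)

  p0 <- model_params(n = 1, m = 2, mu = 0, s = 0.1, c = 2,
                     N0 = 200, NT = 200, T = 10)
  e0 <- run_ensemble(p0, 3, master_seed = 5)
  w10 <- empirical_waiting_time(e0, 1, 0)
  expect_true(is.nan(w10$mean))
  expect_equal(w10$censored, 3)

  # at-least definition is never later than the exact-clone definition
  pm <- model_params(n = 1, m = 2, mu = 0.02, s = 0.05, c = 2,
                     N0 = 500, NT = 500, T = 20)
  em <- run_ensemble(pm, 5, master_seed = 5)
  ex <- empirical_waiting_time(em, 1, 0)$times
  al <- empirical_waiting_time(em, 1, 0, at_least = TRUE)$times
  expect_true(all(is.na(ex) | al <= ex))
})

test_that("empirical waiting time agrees with the per-cell oracle simulator", {
  # small constant population where the brute-force per-cell model is exact
  p <- model_params(n = 1, m = 1, mu = 1e-3, s = 0.1, c = 2,
                    N0 = 1e4, NT = 1e4, T = 10)
  R <- 60
  sim_times <- vapply(seq_len(R), function(i) {
    set.seed(300 + i)
    tr <- simulate_trajectory(p, 300 + i)
    tr$first_hit[2, 1]
  }, 0)
  set.seed(99)
  orc_times <- vapply(seq_len(R), function(i) oracle_first_hit(p, 1, 0), 0)
  expect_true(all(!is.na(sim_times)) && all(!is.na(orc_times)))
  se <- sqrt(var(sim_times) / R + var(orc_times) / R)
  expect_lt(abs(mean(sim_times) - mean(orc_times)), 4 * se + 1e-9)
})

test_that("residual table rows satisfy the defining arithmetic", {
  p <- tiny_oracle_params()
  g <- run_grid(grid_spec(s_values = c(0.02, 0.05), c_values = c(1, 2),
                          replicates = 3, master_seed = 21), p)
  tab <- build_residual_table(g, k_range = 1, l_range = 1:2)
  expect_equal(nrow(tab), 4 * 2)
  expect_equal(tab$tau_approx, tab$T_super + tab$T_driver)
  ok <- !is.na(tab$residual)
  expect_equal(tab$residual[ok], tab$tau_sim[ok] - tab$tau_approx[ok])
  expect_equal(tab$r, tab$c * tab$s)
  # requested clones beyond the genotype space are dropped, not fabricated
  tab2 <- build_residual_table(g, k_range = 1:6, l_range = 1:10)
  expect_equal(nrow(tab2), 4 * 1 * 2)   # n = 1, m = 2 caps the ranges
})

test_that("error model recovers exact linear data and the OLS solution", {
  # exact linear residuals: residual = 2 + 3 s
  set.seed(31)
  tab <- data.frame(s = rep(c(0.01, 0.02, 0.03, 0.05), 3),
                    c = rep(c(1, 2, 3), each = 4),
                    k = rep(1:3, 4), l = rep(1:4, 3),
                    regression_ok = TRUE)
  tab$r <- tab$c * tab$s
  tab$residual <- 2 + 3 * tab$s
  fit <- suppressWarnings(fit_error_model(tab, "s,r,k,l"))  # exact fit
  expect_equal(unname(fit$beta), c(2, 3, 0, 0, 0), tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-8)

  # random table: coefficients equal the normal-equations solution
  tab$residual <- rnorm(nrow(tab))
  fit2 <- fit_error_model(tab, "s,c,k,l")
  X <- cbind(1, tab$s, tab$c, tab$k, tab$l)
  expect_equal(unname(fit2$beta), ols_normal_equations(X, tab$residual),
               tolerance = 1e-10)
  expect_equal(fit2$n_obs, nrow(tab))

  # the c covariate is r / s row by row
  expect_equal(tab$c, tab$r / tab$s)
})

test_that("rank-deficient designs are rejected with the offending columns named", {
  tab <- data.frame(s = 0.01, c = seq(1, 3, length.out = 10),
                    k = rep(1:2, 5), l = rep(1:5, 2),
                    regression_ok = TRUE)
  tab$r <- tab$c * tab$s
  tab$residual <- rnorm(10)
  # single s value: r = c * s is collinear with c, and s with the intercept
  expect_error(fit_error_model(tab, "s,r,k,l"), "rank-deficient")
  expect_error(fit_error_model(tab[1:4, ], "s,c,k,l"), "at least 6")
})

test_that("adding the fitted residual correction reduces squared error", {
  p <- model_params(n = 2, m = 4, mu = 5e-4, s = 0.02, c = 2,
                    N0 = 2000, NT = 2000, T = 60)
  g <- run_grid(grid_spec(s_values = c(0.02, 0.05), c_values = c(1, 1.5, 3),
                          replicates = 4, master_seed = 77), p)
  tab <- build_residual_table(g, k_range = 1:2, l_range = 1:2)
  fit <- fit_error_model(tab, "s,c,k,l")
  dat <- tab[tab$regression_ok & !is.na(tab$residual), ]
  mse_plain <- mean((dat$tau_sim - dat$tau_approx)^2)
  corr <- predict(fit$fit, newdata = dat)
  mse_corr <- mean((dat$tau_sim - (dat$tau_approx + corr))^2)
  expect_lt(mse_corr, mse_plain)
})
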