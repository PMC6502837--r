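test_that("quantile_grid validates and default_grids match the protocol", {
  expect_error(quantile_grid(c(0.2, 0.1)), class = "cqrmr_validation_error")
  expect_error(quantile_grid(c(0, 0.5)), class = "cqrmr_validation_error")
  expect_error(quantile_grid(c(0.5, 1)), class = "cqrmr_validation_error")
  g <- default_grids()
  expect_equal(as.numeric(g[["9"]]), seq(0.1, 0.9, by = 0.1))
  expect_equal(as.numeric(g[["19"]]), seq(0.05, 0.95, by = 0.05))
  expect_equal(as.numeric(g[["10"]]), seq(0.05, 0.95, by = 0.1))
  expect_equal(as.numeric(g[["5"]]), seq(0.1, 0.9, by = 0.2))
})

test_that("fit_ols recovers an exact linear relationship", {
  ph <- data.frame(individual_id = sprintf("i%d", 1:20),
                   trait = 2 * rep(0:2, length.out = 20))
  res <- fit_ols(ph, rep(0:2, length.out = 20), covariates = character(0))
  expect_equal(res$beta, 2, tolerance = 1e-12)
  expect_equal(res$se, 0, tolerance = 1e-8)
})

test_that("fit_ols matches the normal-equations oracle on a small fixture", {
  # 8-row fixture solved independently via solve(X'X, X'y)
  g <- c(0, 1, 2, 1, 0, 2, 1, 0)
  age <- c(45, 52, 60, 48, 63, 55, 41, 67)
  y <- c(-0.8, 0.3, -1.9, 0.2, 1.1, -2.4, 0.5, 0.9)
  ph <- data.frame(individual_id = sprintf("i%d", 1:8), trait = y, age = age)
  res <- fit_ols(ph, g, covariates = "age")
  X <- cbind(1, g, scale(age))
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$beta, oracle[2], tolerance = 1e-10)
  r <- y - X %*% oracle
  s2 <- sum(r^2) / (8 - 3)
  se_oracle <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(res$se, se_oracle, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(oracle[2] / se_oracle), 5),
               tolerance = 1e-10)
  expect_true(res$ci_low <= res$beta && res$beta <= res$ci_high)
})

test_that("fit_ols rejects degenerate designs", {
  ph <- data.frame(individual_id = sprintf("i%d", 1:10), trait = rnorm(10))
  expect_error(fit_ols(ph, rep(1, 10), covariates = character(0)),
               class = "cqrmr_degenerate_design")
})

test_that("CQR solver matches an independent reference on the 60-row fixture", {
  fit <- .cqr_fit_cpp(fix60$X, fix60$y, c(0.25, 0.5, 0.75))
  for (k in 1:3) {
    tau <- c(0.25, 0.5, 0.75)[k]
    # our objective is never worse than the reference solution's
    expect_lte(check_loss_of(fix60$X, fix60$y, fit[, k], tau),
               check_loss_of(fix60$X, fix60$y, fix60$qr_ref[k, ], tau) + 1e-6)
  }
  # away from the degenerate median solution the coefficients agree
  expect_equal(fit[, 1], fix60$qr_ref[1, ], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit[, 3], fix60$qr_ref[3, ], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("fitted CQR coefficients satisfy check-loss optimality", {
  # perturbing any coefficient by +-delta never decreases the objective
  co <- make_cohort(800, null_panel(1), seed = 31)
  eff <- fit_cqr(co$pheno, co$genos$dosages[, 1], grid = quantile_grid(),
                 n_boot = 0)
  d <- cqrmr:::build_design(co$pheno, co$genos$dosages[, 1])
  coefs <- attr(eff, "coef")
  delta <- 1e-3 * sd(d$y)
  for (k in seq_along(eff$q)) {
    base <- check_loss_of(d$X, d$y, coefs[, k], eff$q[k])
    for (j in seq_len(nrow(coefs))) for (s in c(-1, 1)) {
      pert <- coefs[, k]
      pert[j] <- pert[j] + s * delta
      expect_gte(check_loss_of(d$X, d$y, pert, eff$q[k]), base - 1e-8)
    }
  }
})

test_that("location model yields a flat profile; median tracks OLS", {
  vars <- variant_panel(variant_spec("loc", 0.3, "location", beta = -0.4))
  co <- make_cohort(50000, vars, seed = 8)
  g <- co$genos$dosages[, 1]
  eff <- fit_cqr(co$pheno, g, grid = quantile_grid(), n_boot = 0)
  expect_lt(diff(range(eff$beta)), 0.15)        # flat up to noise
  ols <- fit_ols(co$pheno, g)
  expect_lt(abs(eff$beta[eff$q == 0.5] - ols$beta), 3 * ols$se)
})

test_that("CQR is scale-equivariant and flip-antisymmetric", {
  co <- make_cohort(600, null_panel(1), seed = 17)
  g <- co$genos$dosages[, 1]
  grid <- quantile_grid(c(0.25, 0.5, 0.75))
  eff <- fit_cqr(co$pheno, g, grid = grid, n_boot = 0)
  ph_scaled <- co$pheno
  ph_scaled$trait <- 3 * ph_scaled$trait
  eff_scaled <- fit_cqr(ph_scaled, g, grid = grid, n_boot = 0)
  expect_equal(eff_scaled$beta, 3 * eff$beta, tolerance = 1e-5)
  ols <- fit_ols(co$pheno, g); ols_s <- fit_ols(ph_scaled, g)
  expect_equal(ols_s$beta, 3 * ols$beta, tolerance = 1e-10)
  # g -> 2 - g negates every quantile slope: the flipped fit at quantile q
  # is the reparametrised fit of the same problem
  eff_flip <- fit_cqr(co$pheno, 2 - g, grid = grid, n_boot = 0)
  expect_equal(eff_flip$beta, -eff$beta, tolerance = 1e-5)
})

test_that("bootstrap SEs are reproducible under seed and sane in magnitude", {
  co <- make_cohort(1000, null_panel(1), seed = 23)
  g <- co$genos$dosages[, 1]
  e1 <- fit_cqr(co$pheno, g, n_boot = 100, seed = 77)
  e2 <- fit_cqr(co$pheno, g, n_boot = 100, seed = 77)
  expect_identical(e1$beta, e2$beta)
  expect_identical(e1$se, e2$se)
  expect_true(all(e1$se > 0))
  expect_true(all(e1$n_boot == 100L))
  # roughly n^{-1/2} scale: SEs for a diopter-scale trait at n = 1000
  expect_true(all(e1$se > 0.02 & e1$se < 1))
  e3 <- fit_cqr(co$pheno, g, n_boot = 100, seed = 78)
  expect_false(identical(e1$se, e3$se))
})

test_that("fit_cqr validates inputs", {
  co <- make_cohort(200, null_panel(1), seed = 1)
  expect_error(fit_cqr(co$pheno, co$genos$dosages[, 1], n_boot = 10),
               class = "cqrmr_validation_error")
  expect_error(fit_cqr(co$pheno, rep(1, 200), n_boot = 0),
               class = "cqrmr_degenerate_design")
  expect_error(fit_cqr(co$pheno, co$genos$dosages[1:100, 1], n_boot = 0),
               class = "cqrmr_validation_error")
})
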