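test_that("single-site fit recovers noiseless parameters exactly", {
  d <- generate_titration(true_kd = 2.9, hill_n = 1, n_points = 12,
                          noise_sd = 0, seed = 1)
  fit <- fit_single_site(d)
  kd <- tidy(fit)$estimate[tidy(fit)$term == "Kd"]
  expect_equal(kd, 2.9, tolerance = 1e-6)
  # y at x = Kd is exactly one half
  expect_equal(as.numeric(predict(fit, tibble::tibble(x = kd))), 0.5,
               tolerance = 1e-6)
  expect_equal(attr(d, "basis"), "monomer")
})

test_that("flat titrations refuse to fit", {
  flat <- data.frame(x = 1:10, y = rep(0.4, 10))
  expect_error(fit_single_site(flat), "curvature")
  expect_error(fit_exponential(data.frame(t = 1:20, y = rep(1, 20))),
               "curvature")
})

test_that("Hill fit recovers noiseless parameters and reduces to the
           single-site isotherm at n = 1", {
  d <- generate_titration(true_kd = 117, hill_n = 1.2, n_points = 14,
                          noise_sd = 0, seed = 2, unit = "nM",
                          basis = "hexamer")
  fit <- fit_hill(d)
  expect_equal(coef(fit$fit)[["Kd"]], 117, tolerance = 1e-6)
  expect_equal(coef(fit$fit)[["n"]], 1.2, tolerance = 1e-6)
  # midpoint property holds for any n
  expect_equal(as.numeric(predict(fit, tibble::tibble(x = 117))), 0.5,
               tolerance = 1e-6)

  d1 <- generate_titration(true_kd = 5, hill_n = 1, noise_sd = 0.01,
                           seed = 3)
  ss <- fit_single_site(d1)
  hf <- fit_hill(d1, fix_n = 1)
  kd_ss <- tidy(ss)$estimate[tidy(ss)$term == "Kd"]
  kd_h <- tidy(hf)$estimate[tidy(hf)$term == "Kd"]
  expect_equal(kd_h, kd_ss, tolerance = 1e-6)
})

test_that("IC50 fit recovers noiseless parameters and rejects rising data", {
  d <- generate_competition(true_ic50 = 1.0, n = 1.5, minY = 0.1,
                            maxY = 0.9, noise_sd = 0, seed = 4)
  fit <- fit_ic50(d)
  expect_equal(coef(fit$fit)[["IC50"]], 1.0, tolerance = 1e-6)
  expect_equal(coef(fit$fit)[["n"]], 1.5, tolerance = 1e-6)
  # midpoint and limits of the fitted curve
  expect_equal(as.numeric(predict(fit, tibble::tibble(x = 1.0))),
               (0.1 + 0.9) / 2, tolerance = 1e-6)
  expect_equal(as.numeric(predict(fit, tibble::tibble(x = 1e-9))), 0.9,
               tolerance = 1e-4)
  expect_equal(as.numeric(predict(fit, tibble::tibble(x = 1e9))), 0.1,
               tolerance = 1e-4)

  rising <- data.frame(x = 10^seq(-2, 2, length.out = 10),
                       y = seq(0.1, 0.9, length.out = 10))
  expect_error(fit_ic50(rising), "increase")
})

test_that("exponential fits recover rates; dominant rate reported for
           double fits", {
  d <- generate_progress_curve(k = 0.5, A = 2, c = 0.1, noise_sd = 0,
                               seed = 5)
  fit <- fit_exponential(d)
  expect_equal(fit$extra$k_obs, 0.5, tolerance = 1e-6)
  # e^-1 point: y(1/k) - c = 0.632 A
  y_tau <- as.numeric(predict(fit, tibble::tibble(t = 1 / 0.5)))
  expect_equal(y_tau - 0.1, (1 - exp(-1)) * 2, tolerance = 1e-6)

  withr::with_seed(6, {
    t <- seq(0, 30, length.out = 120)
    y <- 1.5 * (1 - exp(-0.8 * t)) + 0.4 * (1 - exp(-0.05 * t)) + 0.2 +
      rnorm(120, 0, 0.002)
    fit2 <- fit_exponential(data.frame(t = t, y = y), order = "double")
    expect_equal(fit2$extra$k_obs, 0.8, tolerance = 0.05)
  })
})

test_that("noisy-replicate medians recover truth within tolerance", {
  kds <- vapply(1:60, function(s) {
    d <- generate_titration(2.9, n_points = 12, noise_sd = 0.03, seed = s)
    fit <- fit_single_site(d)
    tidy(fit)$estimate[tidy(fit)$term == "Kd"]
  }, numeric(1))
  expect_lt(abs(median(kds) - 2.9) / 2.9, 0.10)

  ks <- vapply(1:60, function(s) {
    d <- generate_progress_curve(0.5, A = 1, noise_sd = 0.02, seed = s)
    fit_exponential(d)$extra$k_obs
  }, numeric(1))
  expect_lt(abs(median(ks) - 0.5) / 0.5, 0.05)
})

test_that("linear_fit matches closed-form OLS and flags degenerate input", {
  exact <- data.frame(x = c(1, 2, 3, 4), y = c(3, 5, 7, 9)) # y = 2x + 1
  lf <- suppressWarnings(linear_fit(exact)) # lm warns on a perfect fit
  expect_equal(lf$slope, 2, tolerance = 1e-12)
  expect_equal(lf$intercept, 1, tolerance = 1e-12)
  expect_equal(lf$adj_r_squared, 1, tolerance = 1e-12)

  withr::with_seed(9, {
    d <- data.frame(x = rnorm(12), y = rnorm(12))
    lf2 <- linear_fit(d)
    o <- oracle_ols(d$x, d$y)
    expect_equal(lf2$slope, o$slope, tolerance = 1e-10)
    expect_equal(lf2$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(lf2$adj_r_squared, o$adj_r_squared, tolerance = 1e-10)
    expect_equal(lf2$p_value, o$p_value, tolerance = 1e-10)
  })
  expect_error(linear_fit(data.frame(x = c(1, 1, 1), y = 1:3)), "variance")
  expect_error(linear_fit(data.frame(x = 1:2, y = 1:2)), "3")
})

test_that("tidy and glance expose fit results as tibbles", {
  d <- generate_titration(2.9, noise_sd = 0.02, seed = 10)
  fit <- fit_single_site(d)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "std_error",
                    "conf_low", "conf_high") %in% names(td)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 12)
})
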