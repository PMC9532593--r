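test_that("Pearson correlation matches hand computation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  pc <- pearson_cor(x, c(2, 1, 4, 3))  # product-moment by hand: 3/sqrt(5*5)
  expect_equal(pc$r, 0.6)
  expect_equal(pc$n, 4)
  # p from t = r*sqrt((n-2)/(1-r^2)) on n-2 df
  t_stat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(pc$p_value, 2 * pt(-t_stat, df = 2))
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("OLS recovers exact and hand-solved fits", {
  x <- c(1, 2, 3, 4)
  exact <- ols_fit(3 * x, data.frame(x = x))
  expect_equal(exact$coefficients$estimate[exact$coefficients$term == "x"], 3)
  expect_equal(exact$r_squared, 1)

  f <- ols_fit(c(1, 2, 2, 3), data.frame(x = x))  # normal equations by hand
  expect_equal(f$coefficients$estimate[f$coefficients$term == "(Intercept)"], 0.5)
  expect_equal(f$coefficients$estimate[f$coefficients$term == "x"], 0.6)
  expect_equal(f$df_residual, 2)

  y <- c(4, 7, 1, 9, 3)
  icept <- ols_fit(y, data.frame(row.names = seq_along(y)))
  expect_equal(icept$coefficients$estimate, mean(y))

  expect_error(ols_fit(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "collinear")
})

test_that("single-predictor OLS reproduces the Pearson test", {
  set.seed(41)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  f <- ols_fit(y, data.frame(z = (x - mean(x)) / sd(x)))
  pc <- pearson_cor(x, y)
  slope <- f$coefficients[f$coefficients$term == "z", ]
  # standardized predictor: slope = r * sd(y); the t tests coincide
  expect_equal(slope$estimate, pc$r * sd(y), tolerance = 1e-10)
  expect_equal(slope$p_value, pc$p_value, tolerance = 1e-12)
})

test_that("R-squared never decreases when predictors are added", {
  set.seed(42)
  for (rep in 1:10) {
    X <- as.data.frame(matrix(rnorm(40 * 4), 40, 4))
    names(X) <- paste0("v", 1:4)
    y <- rnorm(40)
    r2 <- vapply(1:4, function(k) ols_fit(y, X[, 1:k, drop = FALSE])$r_squared,
                 numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("quadratic fits recover exact parabolas and flag shapes", {
  x <- 0:4
  hump <- quadratic_fit(-(x - 2)^2 + 5, x)
  expect_equal(hump$c, -1, tolerance = 1e-10)
  expect_equal(hump$vertex_x, 2, tolerance = 1e-10)
  expect_equal(hump$shape, "HUMP")

  lin <- quadratic_fit(as.numeric(x), x)
  expect_equal(lin$c, 0)
  expect_equal(lin$shape, "NONE")

  ushape <- quadratic_fit((x - 2)^2 + 1, x)
  expect_equal(ushape$shape, "U")

  # vertex outside the observed range: monotone arm, not a hump
  arm <- quadratic_fit(-(x - 10)^2 + rnorm(5, 0, 1e-6), x)
  expect_equal(arm$shape, "NONE")

  # near-noise-free recovery of a known parabola to <= 1e-8 relative error
  set.seed(43)
  xx <- runif(50, -2, 3)
  yy <- 1.5 - 0.7 * xx - 2.2 * xx^2 + rnorm(50, 0, 1e-10)
  q <- quadratic_fit(yy, xx)
  expect_equal(q$a, 1.5, tolerance = 1e-8)
  expect_equal(q$b, -0.7, tolerance = 1e-8)
  expect_equal(q$c, -2.2, tolerance = 1e-8)
})

test_that("quadratic pH response in the generator is recovered at its optimum", {
  cfg <- survey_config(n_sites = 100, seed = 7, beta_salinity_c = 0,
                       beta_tpsed_c = 0, beta_tnwater_n = 0,
                       gamma_ph = -0.3, sigma_eps = 1e-9)
  chem <- generate_environment(cfg)
  enz <- generate_enzyme_activities(chem, cfg)
  q <- quadratic_fit(log(enz$bg), chem$sed_ph)
  expect_equal(q$shape, "HUMP")
  expect_equal(q$vertex_x, cfg$ph_opt, tolerance = 1e-4)
  expect_equal(q$c, -0.3, tolerance = 1e-4)
})

test_that("stepwise selection finds an exact single dependence", {
  set.seed(44)
  cand <- as.data.frame(matrix(rnorm(50 * 4), 50, 4))
  names(cand) <- c("a", "b", "c", "d")
  y <- 2 * cand$c
  for (crit in c("AIC", "p")) {
    sw <- stepwise_select(y, cand, criterion = crit)
    expect_identical(sw$selected, "c")
    expect_gt(sw$fit$r_squared, 0.999)
  }
  empty <- stepwise_select(y, data.frame(row.names = 1:50))
  expect_identical(empty$selected, character(0))
  expect_equal(empty$fit$coefficients$estimate, mean(y))
})

test_that("stepwise selection on pure noise stays near the null model", {
  set.seed(45)
  n_selected_p <- 0
  r2 <- numeric(50)
  for (s in 1:50) {
    cand <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
    names(cand) <- c("a", "b", "c", "d")
    y <- rnorm(200)
    sw_aic <- stepwise_select(y, cand, criterion = "AIC")
    r2[s] <- sw_aic$fit$r_squared
    sw_p <- stepwise_select(y, cand, criterion = "p")
    if (length(sw_p$selected) > 0) n_selected_p <- n_selected_p + 1
  }
  # p-entry mode: P(any of 4 independent candidates enters) ~ 1 - 0.95^4 ~ 0.19
  expect_lt(n_selected_p / 50, 0.5)
  expect_lt(mean(r2), 0.05)
})

test_that("stepwise screening recovers the generating salinity effect", {
  hits <- 0
  for (s in 1:40) {
    cfg <- survey_config(n_sites = 50, seed = s)
    chem <- generate_environment(cfg)
    enz <- generate_enzyme_activities(chem, cfg)
    vl <- vector_limitation(acquisition_sums(enz))
    cand <- chem[, c("water_salinity", "sed_tp", "water_temp", "sed_tc", "water_tn")]
    sw <- stepwise_select(vl$vector_length, cand)
    if ("water_salinity" %in% sw$selected) hits <- hits + 1
  }
  expect_gte(hits, 36)  # >= 90% of seeds
})
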