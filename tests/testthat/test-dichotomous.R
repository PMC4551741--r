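test_that("binomial log-likelihood matches a term-by-term oracle", {
  ds <- dichotomous_dataset(c(0, 2, 4, 8), c(1, 5, 12, 30), rep(50, 4))
  fit <- fit_dichotomous(ds, "quantal_linear")
  expect_true(fit$converged)
  p <- predict(fit)
  ll_oracle <- sum(dbinom(ds$affected, ds$denominator, p, log = TRUE))
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-9)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("zero-background quantal-linear data are recovered", {
  d <- c(0, 0.5, 1, 2, 4)
  n <- rep(10000L, 5)
  y <- round(n * (1 - exp(-d)))
  ds <- dichotomous_dataset(d, y, n)
  fit <- fit_dichotomous(ds, "quantal_linear")
  expect_equal(unname(fit$params[["beta"]]), 1, tolerance = 0.01)
  expect_lt(unname(fit$params[["g"]]), 1e-3)
  expect_equal(predict(fit, d), 1 - exp(-d), tolerance = 0.01)
})

test_that("all-zero incidence gives a background-only fit with undefined BMD", {
  ds <- dichotomous_dataset(c(0, 2, 4, 8), rep(0L, 4), rep(50, 4))
  fit <- fit_dichotomous(ds, "quantal_linear")
  expect_true(fit$converged)
  expect_true(is.na(bmd_extra_risk(fit)))
})

test_that("extra-risk inversion has its closed forms and matches a grid oracle", {
  ql <- make_dich_fit("quantal_linear", c(g = 0, beta = 1))
  expect_equal(bmd_extra_risk(ql, 0.10), -log(0.9), tolerance = 1e-12)
  expect_true(is.na(bmd_extra_risk(ql, 0)))
  fits <- list(
    make_dich_fit("logistic", c(alpha = -3, beta = 0.6)),
    make_dich_fit("probit", c(alpha = -2, beta = 0.4)),
    make_dich_fit("log_logistic", c(g = 0.05, alpha = -2, beta = 1.5)),
    make_dich_fit("quantal_linear", c(g = 0.02, beta = 0.3)),
    make_dich_fit("multistage2", c(g = 0.01, b1 = 0.05, b2 = 0.02)),
    make_dich_fit("multistage3", c(g = 0, b1 = 0.02, b2 = 0.01, b3 = 0.004)),
    make_dich_fit("weibull", c(g = 0.02, a = 1.6, beta = 0.08)),
    make_dich_fit("gamma", c(g = 0.02, a = 2, beta = 0.5)))
  for (fit in fits) {
    b <- bmd_extra_risk(fit, 0.10)
    P <- txpod:::.quantal_models[[fit$model_name]]$P
    grid <- seq(1e-6, 40, length.out = 1e6)
    er <- (P(fit$params, grid) - P(fit$params, 0)) / (1 - P(fit$params, 0))
    oracle <- grid[which(er >= 0.10)[1]]
    expect_lt(abs(b - oracle) / oracle, 1e-3)
  }
})

test_that("profile BMDL stays below the BMD and tightens with information", {
  set.seed(19)
  d <- c(0, 2, 4, 8)
  p <- plogis(-3 + 0.5 * d)
  ds <- dichotomous_dataset(d, rbinom(4, 100, p), rep(100, 4))
  fit <- fit_dichotomous(ds, "logistic")
  b <- bmd_extra_risk(fit)
  bl <- bmdl_profile_dichotomous(fit, b)
  expect_true(is.finite(bl))
  expect_lte(bl, b)
  # near-asymptotic regime: the bound hugs the estimate
  ds2 <- dichotomous_dataset(d, round(1e5 * p), rep(1e5, 4))
  fit2 <- fit_dichotomous(ds2, "logistic")
  b2 <- bmd_extra_risk(fit2)
  bl2 <- bmdl_profile_dichotomous(fit2, b2)
  expect_lt((b2 - bl2) / b2, 0.05)
})

test_that("one-sided 95% profile bounds cover the true BMD at the nominal rate", {
  set.seed(13)
  d <- c(0, 2, 4, 8); a <- -3; b <- 0.5; n <- 500
  p <- plogis(a + b * d); p0 <- p[1]
  true_bmd <- (qlogis(p0 + 0.1 * (1 - p0)) - a) / b
  cover <- replicate(500, {
    ds <- dichotomous_dataset(d, rbinom(4, n, p), rep(n, 4))
    fit <- fit_dichotomous(ds, "logistic")
    if (!fit$converged) return(NA)
    bmd <- bmd_extra_risk(fit)
    bmdl <- bmdl_profile_dichotomous(fit, bmd)
    is.finite(bmdl) && bmdl <= true_bmd
  })
  rate <- mean(cover, na.rm = TRUE)
  expect_gte(rate, 0.93)
  expect_lte(rate, 0.99)
})

test_that("model selection gates on GOF, ranks by AIC and flags 3-fold divergence", {
  f1 <- make_dich_fit("quantal_linear", c(g = 0, beta = -log(0.9) / 0.5),
                      aic = 10.1, gof_p = 0.5)
  f2 <- make_dich_fit("multistage2", c(g = 0, b1 = -log(0.9) / 2, b2 = 0),
                      aic = 12.3, gof_p = 0.4)
  sel <- select_dichotomous(list(f1, f2))
  expect_equal(sel$fit$model_name, "quantal_linear")   # lower AIC
  expect_true(sel$bmd_divergent)                       # BMDs 0.5 vs 2.0: 4-fold
  # single passing model
  sel1 <- select_dichotomous(list(f1))
  expect_equal(sel1$fit$model_name, "quantal_linear")
  expect_false(sel1$bmd_divergent)
  # GOF failures are not candidates
  f3 <- make_dich_fit("logistic", c(alpha = -3, beta = 1), aic = 1, gof_p = 0.01)
  sel3 <- select_dichotomous(list(f3))
  expect_null(sel3$fit)
  expect_match(sel3$reason, "adequate fit")
})

test_that("deg_count_bmd runs the full suite and reports a selection", {
  ds <- simulate_deg_count_profile(88, c(0, 23, 32, 71))
  res <- deg_count_bmd(ds)
  expect_s3_class(res, "deg_count_bmd")
  expect_equal(nrow(res$table), length(quantal_model_names()))
  expect_true(is.finite(res$bmd))
  expect_true(is.finite(res$bmdl))
  expect_lte(res$bmdl, res$bmd)
})

test_that("dataset construction enforces the quantal invariants", {
  expect_error(dichotomous_dataset(c(2, 4, 8), c(1, 2, 3), rep(10, 3)),
               "control")
  expect_error(dichotomous_dataset(c(0, 2, 4), c(1, 11, 3), rep(10, 3)),
               "denominator")
  expect_error(fit_dichotomous(dichotomous_dataset(c(0, 2), c(0, 5),
                                                   c(10, 10)), "logistic"),
               "3 dose groups")
})

test_that("quantal fit methods: simulate regenerates datasets, plot draws", {
  ds <- dichotomous_dataset(c(0, 2, 4, 8), c(1, 5, 12, 30), rep(50, 4))
  fit <- fit_dichotomous(ds, "logistic")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "dichotomous_dataset")
  expect_equal(sims[[1]]$denominator, ds$denominator)
  grDevices::pdf(NULL)
  expect_no_error(plot(fit, bmd = bmd_extra_risk(fit)))
  grDevices::dev.off()
})
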