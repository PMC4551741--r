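test_that("zero-noise Hill data are recovered exactly", {
  d <- rep(c(0, 1, 2, 4, 8), each = 2)
  y <- 2 * d^2 / (3^2 + d^2)
  fit <- fit_continuous(d, y, "hill")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[["gamma"]]), 0, tolerance = 1e-4)
  expect_equal(unname(fit$params[["nu"]]), 2, tolerance = 1e-4)
  expect_equal(unname(fit$params[["k"]]), 3, tolerance = 1e-4)
  expect_equal(unname(fit$params[["n"]]), 2, tolerance = 1e-4)
  expect_lt(fit$sigma_hat, 1e-6)
})

test_that("the log-likelihood equals its closed form in the SSE", {
  set.seed(8)
  d <- rep(c(0, 2, 4, 8), each = 5)
  y <- 1 + 0.25 * d + rnorm(20, 0, 0.3)
  for (m in c("linear", "poly2", "power", "hill")) {
    fit <- fit_continuous(d, y, m)
    mu <- predict(fit, d)
    sse <- sum((y - mu)^2)
    n <- length(y)
    expect_equal(fit$sigma_hat, sqrt(sse / n), tolerance = 1e-6)
    expect_equal(fit$loglik, -n / 2 * (log(2 * pi * sse / n) + 1),
                 tolerance = 1e-6)
    expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  }
})

test_that("constant data collapse every model to the same likelihood", {
  d <- rep(c(0, 2, 4, 8), each = 3)
  y <- rep(5, 12) + rep(c(-0.1, 0, 0.1), 4)
  lls <- vapply(c("linear", "poly2", "poly3", "power", "hill"), function(m)
    fit_continuous(d, y, m)$loglik, 0)
  expect_true(all(abs(lls - lls[1]) < 1e-6))
})

test_that("lack-of-fit test: interpolating fits get p = 1, gross misfit p < 0.1", {
  d <- rep(c(0, 2, 4, 8), each = 5)
  set.seed(5)
  y <- 1 + 0.3 * d + rnorm(20, 0, 0.2)
  # poly3 has 4 mean parameters = 4 dose groups: saturated, p = 1
  expect_equal(fit_continuous(d, y, "poly3")$gof_p, 1)
  expect_equal(fit_continuous(d, y, "hill")$gof_p, 1)
  # strongly sigmoidal zero-noise data: linear cannot fit
  ys <- 3 / (1 + exp(-4 * (d - 4)))
  expect_lt(fit_continuous(d, ys, "linear")$gof_p, 0.1)
})

test_that("lack-of-fit p-values are calibrated against a parametric null", {
  # at n = 100/dose the chi-square approximation holds; rejection at 0.1
  # should match the nominal rate within binomial error
  set.seed(11)
  d <- rep(c(0, 2, 4, 8), each = 100)
  rej <- replicate(400, {
    y <- 1 + 0.2 * d + rnorm(400, 0, 0.3)
    fit_continuous(d, y, "linear")$gof_p < 0.1
  })
  expect_lt(abs(mean(rej) - 0.10), 0.045)
})

test_that("the nested polynomial test matches hand-computed LR decisions", {
  d <- rep(c(0, 2, 4, 8), each = 5)
  # zero-noise linear: stay linear
  y_lin <- 1 + 0.5 * d
  f1 <- fit_continuous(d, y_lin, "linear")
  f2 <- fit_continuous(d, y_lin, "poly2")
  f3 <- fit_continuous(d, y_lin, "poly3")
  expect_equal(nested_linear_vs_poly(f1, f2, f3)$model_name, "linear")
  # cubic signal with small noise: escalate to poly3
  set.seed(2)
  y_cub <- 1 + 0.05 * d - 0.2 * d^2 + 0.04 * d^3 + rnorm(20, 0, 0.05)
  g1 <- fit_continuous(d, y_cub, "linear")
  g2 <- fit_continuous(d, y_cub, "poly2")
  g3 <- fit_continuous(d, y_cub, "poly3")
  chosen <- nested_linear_vs_poly(g1, g2, g3)
  # independent check: replay the step-up rule from the stored logliks
  crit <- qchisq(0.95, 1)
  step1 <- if (2 * (g2$loglik - g1$loglik) > crit) g2 else g1
  step2 <- if (step1$model_name == "poly2" &&
               2 * (g3$loglik - step1$loglik) > crit) g3 else step1
  expect_equal(chosen$model_name, step2$model_name)
  expect_equal(chosen$model_name, "poly3")
})

test_that("the linear-model BMD has its closed form", {
  fit <- make_cont_fit("linear", c(gamma = 0, b1 = 1.349), sigma_hat = 1)
  expect_equal(compute_bmd(fit, bmr_sd = 1.349), 1, tolerance = 1e-9)
  # generic closed form bmr * sigma / |slope|
  fit2 <- make_cont_fit("linear", c(gamma = 2, b1 = -0.5), sigma_hat = 0.25)
  expect_equal(compute_bmd(fit2), 1.349 * 0.25 / 0.5, tolerance = 1e-9)
})

test_that("BMD roots agree with a dense grid-search oracle for all forms", {
  fits <- list(
    make_cont_fit("linear", c(gamma = 1, b1 = 0.4), 0.5),
    make_cont_fit("poly2", c(gamma = 1, b1 = 0.1, b2 = 0.05), 0.5),
    make_cont_fit("poly3", c(gamma = 0, b1 = 0.2, b2 = -0.04, b3 = 0.01), 0.3),
    make_cont_fit("power", c(gamma = 0, beta = 0.12, delta = 1.7), 0.4),
    make_cont_fit("hill", c(gamma = 0, nu = 2, k = 3, n = 2), 0.5))
  for (fit in fits) {
    b <- compute_bmd(fit, bmr_sd = 1.349)
    f <- txpod:::.cont_mean_fun(fit$model_name, fit$params)
    grid <- seq(0, 80, length.out = 1e6)
    dev <- abs(f(grid) - f(0)) - 1.349 * fit$sigma_hat
    oracle <- grid[which(dev >= 0)[1]]
    expect_lt(abs(b - oracle) / oracle, 1e-3)
  }
})

test_that("an unreachable benchmark response yields an undefined BMD", {
  # Hill plateau below the BMR band: |nu| < bmr * sigma
  fit <- make_cont_fit("hill", c(gamma = 0, nu = 0.5, k = 3, n = 2), 1)
  expect_true(is.na(compute_bmd(fit, bmr_sd = 1.349)))
  fit0 <- make_cont_fit("linear", c(gamma = 0, b1 = 0.3), 0)
  expect_true(is.na(compute_bmd(fit0)))
})

test_that("model selection follows GOF gate, AIC and the deterministic tie-break", {
  mk <- function(model, aic, gof_p, n_params, params = c(k = 10)) {
    structure(list(model_name = model, aic = aic, gof_p = gof_p,
                   n_params = n_params, params = params, converged = TRUE,
                   loglik = -aic / 2 + n_params),
              class = "continuous_fit")
  }
  # only one model passes the GOF gate: it wins regardless of AIC
  fits <- list(linear = mk("linear", 50, 0.5, 3),
               power = mk("power", 10, 0.05, 4),
               hill = mk("hill", 5, 0.02, 5))
  sel <- select_best_model(fits, lowest_positive_dose = 2)
  expect_equal(sel$fit$model_name, "linear")
  expect_equal(sel$flag_action, "none")
  # exact AIC tie: fewest parameters first
  fits2 <- list(linear = mk("linear", 20, 0.5, 3),
                power = mk("power", 20, 0.5, 4),
                hill = mk("hill", 20, 0.5, 5))
  expect_equal(select_best_model(fits2, 2)$fit$model_name, "linear")
  # nothing passes: unmodeled with reason
  fits3 <- list(linear = mk("linear", 20, 0.01, 3))
  sel3 <- select_best_model(fits3, 2)
  expect_null(sel3$fit)
  expect_match(sel3$reason, "adequate fit")
})

test_that("the Hill flag rule prefers the next-best model, then the halved substitute", {
  mk <- function(model, aic, gof_p, n_params, params = numeric()) {
    structure(list(model_name = model, aic = aic, gof_p = gof_p,
                   n_params = n_params, params = params, converged = TRUE,
                   loglik = -aic / 2 + n_params),
              class = "continuous_fit")
  }
  # hill wins AIC but k < lowest_dose / 3; power has gof_p = 0.2 -> next best
  fits <- list(hill = mk("hill", 5, 0.6, 5, c(gamma = 0, nu = 2, k = 0.5, n = 2)),
               power = mk("power", 8, 0.2, 4, c(gamma = 0, beta = 1, delta = 1.5)))
  sel <- select_best_model(fits, lowest_positive_dose = 2)
  expect_true(sel$hill_flagged)
  expect_equal(sel$flag_action, "next_best")
  expect_equal(sel$fit$model_name, "power")
  # no backup with gof > 0.05: keep hill, substitute the BMD later
  fits2 <- list(hill = mk("hill", 5, 0.6, 5, c(gamma = 0, nu = 2, k = 0.5, n = 2)),
                power = mk("power", 8, 0.03, 4))
  sel2 <- select_best_model(fits2, lowest_positive_dose = 2)
  expect_true(sel2$hill_flagged)
  expect_equal(sel2$flag_action, "halved_substitute")
  expect_equal(sel2$fit$model_name, "hill")
})

test_that("BMDL lies below the BMD and approaches it at large n", {
  set.seed(14)
  d5 <- rep(c(0, 2, 4, 8), each = 5)
  for (i in 1:5) {
    y <- 1 + 0.3 * d5 + rnorm(20, 0, 0.25)
    fit <- fit_continuous(d5, y, "linear")
    b <- compute_bmd(fit)
    bl <- compute_bmdl(fit, b)
    expect_true(is.finite(bl))
    expect_lte(bl, b)
  }
  d200 <- rep(c(0, 2, 4, 8), each = 200)
  y <- 1 + 0.3 * d200 + rnorm(800, 0, 0.25)
  fit <- fit_continuous(d200, y, "linear")
  b <- compute_bmd(fit)
  bl <- compute_bmdl(fit, b)
  expect_lt((b - bl) / b, 0.05)
})

test_that("run_gene_bmd models responders, excludes high BMDs, and is deterministic", {
  cfg <- sim_config(n_genes = 60, frac_responders = 1, seed = 17)
  st <- simulate_platform_study(cfg, "microarray")
  bm <- suppressMessages(run_gene_bmd(st$dset, st$truth$gene, bmdl = FALSE))
  expect_gte(mean(is.finite(bm$bmd)), 0.9)
  expect_true(all(bm$bmd[bm$excluded_above_top] > 8, na.rm = TRUE))
  bm2 <- suppressMessages(run_gene_bmd(st$dset, st$truth$gene, bmdl = FALSE))
  expect_identical(bm, bm2)
  expect_error(suppressMessages(run_gene_bmd(st$dset, character(0))), "empty")
})

test_that("on zero-noise data the selected curve matches the generating curve", {
  d <- rep(c(0, 1, 2, 4, 8), each = 2)
  curves <- list(linear = function(x) 1 + 0.4 * x,
                 hill = function(x) 2 * x^2 / (9 + x^2),
                 power = function(x) 0.2 * x^1.6)
  for (nm in names(curves)) {
    y <- curves[[nm]](d)
    fits <- sapply(c("linear", "poly2", "poly3", "power", "hill"),
                   function(m) fit_continuous(d, y, m), simplify = FALSE)
    sel <- select_best_model(fits, lowest_positive_dose = 1)
    expect_false(is.null(sel$fit))
    grid <- seq(0, 8, length.out = 200)
    expect_lt(max(abs(predict(sel$fit, grid) - curves[[nm]](grid))), 1e-3)
  }
})

test_that("parameter recovery: median relative BMD error below 25%", {
  cfg <- sim_config(n_genes = 500, frac_responders = 1, noise_sd = 0.25,
                    n_per_dose = rep(5L, 4), compression_factor = 1, seed = 23)
  st <- simulate_platform_study(cfg, "microarray")
  bm <- suppressMessages(run_gene_bmd(st$dset, st$truth$gene, bmdl = FALSE))
  mm <- merge(as.data.frame(bm), st$truth[, c("gene", "true_bmd")], by = "gene")
  mm <- mm[mm$status == "modeled" & is.finite(mm$true_bmd), ]
  expect_gt(nrow(mm), 200)
  expect_lt(median(abs(mm$bmd - mm$true_bmd) / mm$true_bmd), 0.25)
})

test_that("fit methods: residuals, simulate and plot operate on the fit", {
  set.seed(3)
  d <- rep(c(0, 2, 4, 8), each = 5)
  y <- 1 + 0.3 * d + rnorm(20, 0, 0.2)
  fit <- fit_continuous(d, y, "linear")
  r <- residuals(fit)
  expect_length(r, 4L)
  expect_equal(unname(r), tapply(y, d, mean) - predict(fit, c(0, 2, 4, 8)),
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(20L, 3L))
  grDevices::pdf(NULL)
  expect_no_error(plot(fit, bmd = compute_bmd(fit)))
  grDevices::dev.off()
})
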