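#' @title Continuous dose-response models
#' @description Internal model registry: mean functions on the log2 scale,
#'   parameter counts and box constraints for the nonlinear forms. The mean
#'   forms are linear `g + b1*d`, quadratic and cubic polynomials, power
#'   `g + b*d^delta` with the power restricted to `delta >= 1`, and Hill
#'   `g + v*d^n / (k^n + d^n)` with shape `n >= 1` and `k > 0`.
#' @name continuous-models
#' @keywords internal
NULL

.cont_models <- c("linear", "poly2", "poly3", "power", "hill")
.cont_order <- stats::setNames(seq_along(.cont_models), .cont_models)

.cont_mean_fun <- function(model_name, params) {
  switch(model_name,
    linear = function(d) params[["gamma"]] + params[["b1"]] * d,
    poly2  = function(d) params[["gamma"]] + params[["b1"]] * d + params[["b2"]] * d^2,
    poly3  = function(d) params[["gamma"]] + params[["b1"]] * d + params[["b2"]] * d^2 +
                         params[["b3"]] * d^3,
    power  = function(d) params[["gamma"]] + params[["beta"]] * d^params[["delta"]],
    hill   = function(d) {
      x <- ifelse(d > 0,
                  d^params[["n"]] / (params[["k"]]^params[["n"]] + d^params[["n"]]),
                  0)
      params[["gamma"]] + params[["nu"]] * x
    })
}

.cont_n_mean_params <- c(linear = 2L, poly2 = 3L, poly3 = 4L, power = 3L, hill = 4L)

# sufficient statistics of a gene's replicate data under the pooled
# constant-variance normal likelihood: the weighted group means and the
# within-group sum of squares carry all information
.suff_stats <- function(doses, values) {
  stopifnot(length(doses) == length(values))
  groups <- factor(doses)
  du <- as.numeric(levels(groups))
  n_g <- as.vector(table(groups))
  m_g <- as.vector(tapply(values, groups, mean))
  ssw <- sum((values - m_g[as.integer(groups)])^2)
  list(du = du, n_g = n_g, m_g = m_g, ssw = ssw, N = length(values),
       G = length(du))
}

.ll_from_sse <- function(sse, N) {
  s2 <- sse / N
  if (s2 <= 0) return(Inf)                  # perfect fit of zero-noise data
  -N / 2 * (log(2 * pi * s2) + 1)
}

# weighted LS of group means on a design matrix; returns coef and weighted SSE
.wls <- function(X, y, w) {
  XtW <- t(X * w)
  cf <- tryCatch(solve(XtW %*% X, XtW %*% y),
                 error = function(e) qr.coef(qr(X * sqrt(w)), y * sqrt(w)))
  cf[is.na(cf)] <- 0
  r <- y - X %*% cf
  list(coef = as.vector(cf), q = sum(w * r^2))
}

# closed-form weighted simple regression y ~ 1 + x (the inner step of the
# power/hill profiles, called hundreds of times per gene)
.wls2 <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  det <- sw * sxx - swx * swx
  if (det <= 1e-14 * sw * max(sxx, 1e-300)) {
    a <- swy / sw
    return(list(coef = c(a, 0), q = sum(w * (y - a)^2)))
  }
  b <- (sw * sxy - swx * swy) / det
  a <- (swy - b * swx) / sw
  r <- y - a - b * x
  list(coef = c(a, b), q = sum(w * r^2))
}

# profile objective for hill: given (k, n), gamma and nu are weighted LS;
# du^n is 0 at the control dose since n >= 1
.hill_profile_q <- function(log_k, n, ss) {
  k <- exp(log_k)
  dn <- ss$du^n
  .wls2(dn / (k^n + dn), ss$m_g, ss$n_g)$q
}

.fit_from_ss <- function(ss, model_name, max_iterations = 250L) {
  model_name <- match.arg(model_name, .cont_models)
  need <- c(linear = 2L, poly2 = 3L, poly3 = 4L, power = 3L, hill = 4L)[model_name]
  if (ss$G < need)
    return(structure(list(model_name = model_name, converged = FALSE,
                          reason = sprintf("%d distinct doses < %d parameters",
                                           ss$G, need)),
                     class = "continuous_fit"))
  du <- ss$du; pos <- du[du > 0]
  converged <- TRUE
  if (model_name %in% c("linear", "poly2", "poly3")) {
    deg <- c(linear = 1L, poly2 = 2L, poly3 = 3L)[model_name]
    X <- stats::poly(du, degree = deg, raw = TRUE)
    X <- cbind(1, X)
    w <- .wls(X, ss$m_g, ss$n_g)
    params <- stats::setNames(w$coef, c("gamma", paste0("b", seq_len(deg))))
    q <- w$q
  } else if (model_name == "power") {
    qfun <- function(delta) .wls2(du^delta, ss$m_g, ss$n_g)$q
    grid <- seq(1, 18, length.out = 35)
    qs <- vapply(grid, qfun, 0)
    i <- which.min(qs)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(qfun, c(lo, hi))
    delta <- if (opt$objective < qs[i]) opt$minimum else grid[i]
    w <- .wls2(du^delta, ss$m_g, ss$n_g)
    params <- c(gamma = w$coef[1L], beta = w$coef[2L], delta = delta)
    q <- w$q
  } else {                                   # hill
    d_lo <- min(pos); d_hi <- max(pos); d_mid <- exp(mean(log(pos)))
    starts <- rbind(c(log(d_mid), 1.5),
                    c(log(d_lo), 3),
                    c(log(d_hi), 1.2),
                    c(log(d_lo / 2), 6),
                    c(log(d_mid), 9))
    bounds_lo <- c(log(d_lo / 100), 1)
    bounds_hi <- c(log(d_hi * 100), 18)
    best <- .ml_optim(function(p) .hill_profile_q(p[1L], p[2L], ss),
                      starts, bounds_lo, bounds_hi, max_iterations,
                      early_exit = 1e-12 * max(ss$ssw, 1e-12))
    if (is.null(best))
      return(structure(list(model_name = model_name, converged = FALSE,
                            reason = "optimizer failure"),
                       class = "continuous_fit"))
    k <- exp(best$par[1L]); n <- best$par[2L]
    dn <- du^n
    w <- .wls2(dn / (k^n + dn), ss$m_g, ss$n_g)
    params <- c(gamma = w$coef[1L], nu = w$coef[2L], k = k, n = n)
    q <- w$q
    converged <- best$convergence == 0L
  }
  sse <- ss$ssw + q
  n_params <- .cont_n_mean_params[[model_name]] + 1L   # + variance parameter
  ll <- .ll_from_sse(sse, ss$N)
  fit <- structure(list(model_name = model_name,
                        params = params,
                        sigma_hat = sqrt(sse / ss$N),
                        loglik = ll,
                        aic = 2 * n_params - 2 * ll,
                        n_params = n_params,
                        converged = converged,
                        ss = ss),
                   class = "continuous_fit")
  fit$gof_p <- if (converged) goodness_of_fit(fit) else NA_real_
  fit
}

#' Fit one continuous dose-response model to replicate data
#'
#' Maximum-likelihood fit under the pooled constant-variance normal model:
#' parameters minimize the error sum of squares, and `sigma_hat^2 = SSE/N`.
#' The polynomial forms are solved in closed form (weighted least squares on
#' the dose-group means); the power exponent is profiled over a grid plus
#' golden-section refinement on \[1, 18\]; the Hill (k, n) pair is profiled
#' by bounded quasi-Newton search from five deterministic starts, with
#' `max_iterations` applied per start. Models needing more parameters than
#' there are distinct doses are skipped (`converged = FALSE` with a reason).
#'
#' @param doses per-sample dose vector.
#' @param values per-sample response values (log2 analysis scale).
#' @param model_name one of `"linear"`, `"poly2"`, `"poly3"`, `"power"`,
#'   `"hill"`.
#' @param max_iterations optimizer cap per start (default 250).
#' @return object of class `continuous_fit` with elements `params`,
#'   `sigma_hat`, `loglik`, `aic`, `gof_p`, `n_params`, `converged`.
#' @examples
#' d <- rep(c(0, 2, 4, 8), each = 5)
#' y <- 1 + 0.3 * d + rnorm(length(d), 0, 0.2)
#' fit <- fit_continuous(d, y, "linear")
#' coef(fit); AIC(fit)
#' @export
fit_continuous <- function(doses, values, model_name, max_iterations = 250L) {
  .fit_from_ss(.suff_stats(doses, values), model_name, max_iterations)
}

#' @export
print.continuous_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("continuous_fit [%s]: not converged (%s)\n", x$model_name,
                x$reason %||% "optimizer"))
    return(invisible(x))
  }
  cat(sprintf("continuous_fit [%s]: logLik %.3f, AIC %.3f, GOF p %.4g, sigma %.4g\n",
              x$model_name, x$loglik, x$aic, x$gof_p, x$sigma_hat))
  print(signif(x$params, 5))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.continuous_fit <- function(object, ...) object$params

#' @export
logLik.continuous_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
predict.continuous_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$ss$du else newdata
  .cont_mean_fun(object$model_name, object$params)(d)
}

#' Likelihood-ratio lack-of-fit test against the saturated group-means model
#'
#' Compares the fitted mean curve with the model that gives every dose group
#' its own mean, under the same pooled-variance normal likelihood:
#' `stat = 2 * (loglik_means - loglik_model)` on
#' `df = (#dose groups) - (#mean parameters)` degrees of freedom. With
#' `df <= 0` the curve can interpolate the group means and the test is
#' vacuous (p = 1).
#'
#' @param fit a converged [fit_continuous()] object.
#' @return upper-tail chi-square p-value.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "continuous_fit"), isTRUE(fit$converged))
  ss <- fit$ss
  df <- ss$G - .cont_n_mean_params[[fit$model_name]]
  if (df <= 0L) return(1)
  sse <- fit$sigma_hat^2 * ss$N
  if (ss$ssw <= .Machine$double.eps * ss$N)   # zero-noise data: fit must interpolate
    return(if (sse <= ss$ssw + 1e-10 * max(1, sum(ss$m_g^2))) 1 else 0)
  stat <- ss$N * log(sse / ss$ssw)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Step-up likelihood-ratio choice among the nested polynomial family
#'
#' Accepts the quadratic over the linear model when twice the log-likelihood
#' gain exceeds the chi-square(1) critical value at `cutoff`, then the cubic
#' over the quadratic by the same rule. Unconverged or missing fits are
#' skipped.
#'
#' @param fit_linear,fit_poly2,fit_poly3 [fit_continuous()] objects (or
#'   `NULL`).
#' @param cutoff test size (default 0.05).
#' @return the chosen `continuous_fit`.
#' @export
nested_linear_vs_poly <- function(fit_linear, fit_poly2 = NULL, fit_poly3 = NULL,
                                  cutoff = 0.05) {
  ok <- function(f) !is.null(f) && isTRUE(f$converged)
  crit <- stats::qchisq(1 - cutoff, df = 1)
  # LR gain of the richer model; zero when both SSEs sit at the numerical
  # floor (zero-noise data fit exactly by both — rounding noise is not
  # evidence for extra terms)
  gain <- function(rich, simple) {
    sse_r <- rich$sigma_hat^2 * rich$ss$N
    sse_s <- simple$sigma_hat^2 * simple$ss$N
    scale <- simple$ss$ssw + sum(simple$ss$n_g * simple$ss$m_g^2)
    if (sse_s - sse_r <= 1e-12 * max(scale, 1e-300)) return(0)
    2 * (rich$loglik - simple$loglik)
  }
  chosen <- if (ok(fit_linear)) fit_linear else NULL
  if (ok(fit_poly2) && (is.null(chosen) || gain(fit_poly2, chosen) > crit))
    chosen <- fit_poly2
  if (ok(fit_poly3) && !is.null(chosen) && chosen$model_name == "poly2" &&
      gain(fit_poly3, chosen) > crit)
    chosen <- fit_poly3
  if (ok(fit_poly3) && is.null(chosen)) chosen <- fit_poly3
  if (is.null(chosen)) stop("no converged nested fit available")
  chosen
}

# deterministic AIC comparison: lower AIC wins; near-ties (delta < 1e-6) go
# to fewer parameters, then to the fixed model-name order
.aic_before <- function(a, b) {
  if (a$aic < b$aic - 1e-6) return(TRUE)
  if (a$aic > b$aic + 1e-6) return(FALSE)
  if (a$n_params != b$n_params) return(a$n_params < b$n_params)
  .cont_order[[a$model_name]] < .cont_order[[b$model_name]]
}

#' Select the best continuous model for one gene
#'
#' Implements the BMDExpress-style decision cascade: the nested polynomial
#' winner (see [nested_linear_vs_poly()]) competes with the power and Hill
#' fits; among candidates with goodness-of-fit p above `gof_threshold` the
#' lowest AIC wins. A winning Hill fit whose half-max dose `k` falls below
#' one third of the lowest positive dose is flagged as an unsupported
#' low-dose inflection: the next-lowest-AIC candidate with GOF p > 0.05 is
#' taken instead (`flag_action = "next_best"`); if none exists the Hill fit
#' is kept and its BMD later replaced by half the lowest positive dose
#' (`flag_action = "halved_substitute"`; set
#' `hill_flag_mode = "halve_own_bmd"` for halving the Hill fit's own BMD).
#'
#' @param fits named list of `continuous_fit` objects (any subset of the
#'   five models).
#' @param lowest_positive_dose smallest non-zero dose of the design.
#' @param gof_threshold primary goodness-of-fit gate (default 0.1).
#' @param nested_cutoff size of the nested polynomial test (default 0.05).
#' @param hill_flag_mode remediation when a flagged Hill has no backup
#'   model: `"half_lowest_dose"` (default) or `"halve_own_bmd"`.
#' @return list with elements `fit` (the selected `continuous_fit` or
#'   `NULL`), `hill_flagged`, `flag_action` (`"none"`, `"next_best"` or
#'   `"halved_substitute"`), and `reason` when unmodeled.
#' @export
select_best_model <- function(fits, lowest_positive_dose,
                              gof_threshold = 0.1, nested_cutoff = 0.05,
                              hill_flag_mode = c("half_lowest_dose",
                                                 "halve_own_bmd")) {
  hill_flag_mode <- match.arg(hill_flag_mode)
  ok <- function(f) !is.null(f) && isTRUE(f$converged)
  nested <- tryCatch(
    nested_linear_vs_poly(fits$linear, fits$poly2, fits$poly3, nested_cutoff),
    error = function(e) NULL)
  candidates <- Filter(ok, list(nested = nested, power = fits$power,
                                hill = fits$hill))
  if (length(candidates) == 0L)
    return(list(fit = NULL, hill_flagged = FALSE, flag_action = "none",
                reason = "no converged fit"))
  eligible <- Filter(function(f) f$gof_p > gof_threshold, candidates)
  if (length(eligible) == 0L)
    return(list(fit = NULL, hill_flagged = FALSE, flag_action = "none",
                reason = "no model with adequate fit"))
  srt <- eligible[order(vapply(eligible, `[[`, 0, "aic"))]
  best <- srt[[1L]]
  for (f in srt[-1L]) if (.aic_before(f, best)) best <- f
  hill_flagged <- FALSE; flag_action <- "none"
  if (best$model_name == "hill" &&
      best$params[["k"]] < lowest_positive_dose / 3) {
    hill_flagged <- TRUE
    backups <- Filter(function(f) f$model_name != "hill" && f$gof_p > 0.05,
                      candidates)
    if (length(backups) > 0L) {
      srt <- backups[order(vapply(backups, `[[`, 0, "aic"))]
      best <- srt[[1L]]
      for (f in srt[-1L]) if (.aic_before(f, best)) best <- f
      flag_action <- "next_best"
    } else {
      flag_action <- "halved_substitute"
    }
  }
  list(fit = best, hill_flagged = hill_flagged, flag_action = flag_action,
       hill_flag_mode = hill_flag_mode, reason = NULL)
}

#' Benchmark dose of a fitted continuous model
#'
#' The BMD is the smallest positive dose at which the fitted mean departs
#' from its control value by `bmr_sd * sigma_hat` log2 units. The crossing
#' is located by a sign-change scan over \[0, 10 x top dose\] (4000 cells)
#' refined by root bisection, so non-monotone polynomial fits yield their
#' *first* crossing of the benchmark band. Returns `NA` when the response
#' never reaches the benchmark within the bracket, or when `sigma_hat = 0`.
#'
#' @param fit a converged [fit_continuous()] object.
#' @param bmr_sd benchmark response in SD units (default 1.349).
#' @return dose in mkd, or `NA_real_`.
#' @export
compute_bmd <- function(fit, bmr_sd = 1.349) {
  stopifnot(inherits(fit, "continuous_fit"), isTRUE(fit$converged))
  if (fit$sigma_hat <= 0) return(NA_real_)
  a <- bmr_sd * fit$sigma_hat
  f <- .cont_mean_fun(fit$model_name, fit$params)
  f0 <- f(0)
  g <- function(d) abs(f(d) - f0) - a
  top <- 10 * max(fit$ss$du)
  grid <- seq(0, top, length.out = 4001L)
  gv <- g(grid)
  idx <- which(gv[-1L] >= 0 & gv[-length(gv)] < 0)
  if (length(idx) == 0L) {
    if (gv[1L] >= 0) return(grid[1L])
    return(NA_real_)
  }
  i <- idx[1L]
  stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-12 * top)$root
}

# profile log-likelihood of the constraint BMD = b: the constraint ties the
# residual SD to the mean curve, sigma = |f(b) - f(0)| / bmr, so the profile
# is an unconstrained search over the mean parameters only
.cont_profile_ll <- function(fit, b, bmr_sd) {
  ss <- fit$ss
  model <- fit$model_name
  theta0 <- fit$params
  lower <- rep(-Inf, length(theta0)); upper <- rep(Inf, length(theta0))
  if (model == "power") { lower[3L] <- 1; upper[3L] <- 18 }
  if (model == "hill") { lower[3L] <- 1e-6; lower[4L] <- 1; upper[4L] <- 18 }
  obj <- function(theta) {
    names(theta) <- names(theta0)
    f <- .cont_mean_fun(model, theta)
    delta <- abs(f(b) - f(0))
    if (!is.finite(delta) || delta <= 0) return(1e10)
    sigma <- delta / bmr_sd
    mu <- f(ss$du)
    sse <- ss$ssw + sum(ss$n_g * (ss$m_g - mu)^2)
    ss$N / 2 * log(2 * pi * sigma^2) + sse / (2 * sigma^2)
  }
  best <- Inf
  for (st in list(theta0, theta0 * 0.9 + 1e-3)) {
    o <- try(stats::optim(st, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500)), silent = TRUE)
    if (!inherits(o, "try-error") && o$value < best) best <- o$value
  }
  -best
}

#' Profile-likelihood lower confidence bound on the BMD
#'
#' One-sided lower bound at the given confidence: the smallest dose `b` for
#' which the maximum log-likelihood under the constraint `BMD = b` stays
#' within `qchisq(2 * confidence - 1, 1) / 2` of the unconstrained maximum.
#' The constrained maximum is profiled over the mean parameters (the
#' constraint determines the residual SD), and the bound is located by
#' geometric bisection on `(0, BMD]`.
#'
#' @param fit a converged [fit_continuous()] object.
#' @param bmd the gene's BMD from [compute_bmd()].
#' @param bmr_sd benchmark response in SD units (default 1.349).
#' @param confidence one-sided confidence level (default 0.95).
#' @return dose in mkd, or `NA_real_` if profiling fails.
#' @export
compute_bmdl <- function(fit, bmd, bmr_sd = 1.349, confidence = 0.95) {
  stopifnot(inherits(fit, "continuous_fit"), isTRUE(fit$converged))
  if (!is.finite(bmd) || bmd <= 0) return(NA_real_)
  target <- fit$loglik - stats::qchisq(2 * confidence - 1, df = 1) / 2
  prof <- function(b) .cont_profile_ll(fit, b, bmr_sd)
  lo <- bmd * 1e-3; hi <- bmd
  if (prof(hi) < target - 1e-6) return(NA_real_)     # profiling failure
  if (prof(lo) >= target) return(lo)
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    if (prof(mid) >= target) hi <- mid else lo <- mid
    if (hi / lo < 1.002) break
  }
  hi
}

#' Per-gene continuous BMD analysis
#'
#' Fits all five continuous models to every listed gene on the log2
#' analysis scale, applies the selection cascade of [select_best_model()],
#' computes BMD and (optionally) BMDL, and marks genes whose BMD exceeds
#' the top dose — such genes are excluded from pathway aggregation
#' downstream.
#'
#' @param dset a [dose_response_set()].
#' @param genes character vector of gene symbols (typically a filter tier
#'   from [select_genes()]).
#' @param config a [run_config()].
#' @param bmdl compute profile-likelihood BMDLs (default `TRUE`; the
#'   profiling is the expensive step and can be skipped for
#'   distributional analyses that only need BMDs).
#' @param hill_flag_mode see [select_best_model()].
#' @return data frame of class `bmd_result`: one row per gene with columns
#'   `gene`, `model`, `bmd`, `bmdl`, `hill_flagged`, `flag_action`,
#'   `excluded_above_top`, `gof_p`, `aic`, `status`.
#' @export
run_gene_bmd <- function(dset, genes, config = run_config(), bmdl = TRUE,
                         hill_flag_mode = c("half_lowest_dose",
                                            "halve_own_bmd")) {
  stopifnot(inherits(dset, "dose_response_set"))
  hill_flag_mode <- match.arg(hill_flag_mode)
  if (length(genes) == 0L) stop("empty gene list")
  missing <- setdiff(genes, rownames(dset$values))
  if (length(missing))
    stop("gene(s) absent from the dataset: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  mat <- analysis_matrix(dset)[genes, , drop = FALSE]
  doses <- dset$doses
  top_dose <- max(doses)
  lowest_pos <- min(doses[doses > 0])
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    ss <- .suff_stats(doses, mat[i, ])
    fits <- stats::setNames(lapply(.cont_models, function(m)
      .fit_from_ss(ss, m, config$max_iterations)), .cont_models)
    sel <- select_best_model(fits, lowest_pos, hill_flag_mode = hill_flag_mode)
    row <- data.frame(gene = genes[i], model = NA_character_,
                      bmd = NA_real_, bmdl = NA_real_,
                      hill_flagged = sel$hill_flagged,
                      flag_action = sel$flag_action,
                      excluded_above_top = FALSE,
                      gof_p = NA_real_, aic = NA_real_,
                      status = "modeled", stringsAsFactors = FALSE)
    if (is.null(sel$fit)) {
      row$status <- sel$reason
    } else {
      fit <- sel$fit
      row$model <- fit$model_name
      row$gof_p <- fit$gof_p
      row$aic <- fit$aic
      b <- compute_bmd(fit, config$bmr_sd)
      if (sel$flag_action == "halved_substitute")
        b <- if (hill_flag_mode == "half_lowest_dose") 0.5 * lowest_pos
             else 0.5 * b
      if (!is.finite(b)) {
        row$status <- "benchmark response not reached"
      } else {
        row$bmd <- b
        if (b > top_dose) {
          row$excluded_above_top <- TRUE
          row$status <- "excluded: BMD above top dose"
        } else if (bmdl) {
          row$bmdl <- compute_bmdl(fit, b, config$bmr_sd, config$confidence)
        }
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bmd_result", "data.frame")
  n_mod <- sum(out$status == "modeled")
  message(sprintf("modeled %d / %d genes (%d excluded above top dose, %d unmodeled)",
                  n_mod, nrow(out), sum(out$excluded_above_top),
                  nrow(out) - n_mod - sum(out$excluded_above_top)))
  out
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("bmd_result: %d genes, %d modeled, %d excluded above top dose\n",
              nrow(x), sum(x$status == "modeled"), sum(x$excluded_above_top)))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
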