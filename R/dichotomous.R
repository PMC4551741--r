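#' Construct a dichotomous (quantal) dose-response dataset
#'
#' @param doses dose levels in mkd; must include 0.
#' @param affected number of affected units per dose.
#' @param denominator number of trials per dose.
#' @return object of class `dichotomous_dataset`.
#' @export
dichotomous_dataset <- function(doses, affected, denominator) {
  stopifnot(length(doses) == length(affected),
            length(doses) == length(denominator))
  if (!any(doses == 0)) stop("dose 0 (control) must be present")
  if (any(affected < 0) || any(affected > denominator))
    stop("affected counts must lie in [0, denominator]")
  ord <- order(doses)
  structure(list(doses = doses[ord], affected = affected[ord],
                 denominator = denominator[ord]),
            class = "dichotomous_dataset")
}

#' @export
print.dichotomous_dataset <- function(x, ...) {
  cat("dichotomous_dataset:\n")
  print(data.frame(dose = x$doses, affected = x$affected,
                   denominator = x$denominator,
                   fraction = signif(x$affected / x$denominator, 3)))
  invisible(x)
}

# --- quantal model registry ----------------------------------------------
# Each entry: probability function P(par, d), parameter names, box bounds,
# deterministic start builder, closed-form extra-risk inversion bmd(par, bmr),
# and the BMDL substitution: free parameter layout with the constrained
# parameter expressed through the candidate bound b (returns NULL when the
# constraint is infeasible, e.g. a multistage coefficient driven negative).
.quantal_models <- local({
  clamp <- function(p) pmin(pmax(p, 0.02), 0.98)
  list(
  logistic = list(
    P = function(par, d) stats::plogis(par[1L] + par[2L] * d),
    par_names = c("alpha", "beta"),
    lower = c(-Inf, 0), upper = c(Inf, Inf),
    starts = function(dat) {
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))
      cf <- stats::coef(stats::lm(stats::qlogis(emp) ~ dat$doses))
      rbind(c(cf[1L], max(cf[2L], 1e-3)),
            c(cf[1L], max(cf[2L], 1e-3) * 2),
            c(cf[1L] - 1, max(cf[2L], 1e-3) / 2))
    },
    bmd = function(par, bmr) {
      p0 <- stats::plogis(par[1L]); pb <- p0 + bmr * (1 - p0)
      (stats::qlogis(pb) - par[1L]) / par[2L]
    },
    sub = function(b, free, bmr) {
      a <- free[1L]
      p0 <- stats::plogis(a); pb <- p0 + bmr * (1 - p0)
      beta <- (stats::qlogis(pb) - a) / b
      if (beta < 0) return(NULL)
      function(d) stats::plogis(a + beta * d)
    },
    sub_free = function(par) par[1L], sub_lower = -30, sub_upper = 10),
  probit = list(
    P = function(par, d) stats::pnorm(par[1L] + par[2L] * d),
    par_names = c("alpha", "beta"),
    lower = c(-Inf, 0), upper = c(Inf, Inf),
    starts = function(dat) {
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))
      cf <- stats::coef(stats::lm(stats::qnorm(emp) ~ dat$doses))
      rbind(c(cf[1L], max(cf[2L], 1e-3)),
            c(cf[1L], max(cf[2L], 1e-3) * 2),
            c(cf[1L] - 0.5, max(cf[2L], 1e-3) / 2))
    },
    bmd = function(par, bmr) {
      p0 <- stats::pnorm(par[1L]); pb <- p0 + bmr * (1 - p0)
      (stats::qnorm(pb) - par[1L]) / par[2L]
    },
    sub = function(b, free, bmr) {
      a <- free[1L]
      p0 <- stats::pnorm(a); pb <- p0 + bmr * (1 - p0)
      beta <- (stats::qnorm(pb) - a) / b
      if (beta < 0) return(NULL)
      function(d) stats::pnorm(a + beta * d)
    },
    sub_free = function(par) par[1L], sub_lower = -15, sub_upper = 6),
  log_logistic = list(
    P = function(par, d) par[1L] + (1 - par[1L]) *
      ifelse(d > 0, stats::plogis(par[2L] + par[3L] * log(d)), 0),
    par_names = c("g", "alpha", "beta"),
    lower = c(0, -Inf, 1), upper = c(1, Inf, 18),
    starts = function(dat) {
      pos <- dat$doses > 0
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))[pos]
      cf <- stats::coef(stats::lm(stats::qlogis(emp) ~ log(dat$doses[pos])))
      b <- min(max(cf[2L], 1), 18)
      rbind(c(1e-3, cf[1L], b), c(1e-3, cf[1L] - 1, min(b * 2, 18)),
            c(1e-3, cf[1L], 1))
    },
    bmd = function(par, bmr) exp((stats::qlogis(bmr) - par[2L]) / par[3L]),
    sub = function(b, free, bmr) {
      g <- free[1L]; beta <- free[2L]
      a <- stats::qlogis(bmr) - beta * log(b)
      function(d) g + (1 - g) * ifelse(d > 0, stats::plogis(a + beta * log(d)), 0)
    },
    sub_free = function(par) par[c(1L, 3L)],
    sub_lower = c(0, 1), sub_upper = c(1, 18)),
  quantal_linear = list(
    P = function(par, d) par[1L] + (1 - par[1L]) * (1 - exp(-par[2L] * d)),
    par_names = c("g", "beta"),
    lower = c(0, 0), upper = c(1, Inf),
    starts = function(dat) {
      pos <- dat$doses > 0
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))[pos]
      b <- mean(-log(1 - emp) / dat$doses[pos])
      rbind(c(1e-3, b), c(1e-3, b * 3), c(1e-3, b / 3))
    },
    bmd = function(par, bmr) -log(1 - bmr) / par[2L],
    sub = function(b, free, bmr) {
      g <- free[1L]; beta <- -log(1 - bmr) / b
      function(d) g + (1 - g) * (1 - exp(-beta * d))
    },
    sub_free = function(par) par[1L], sub_lower = 0, sub_upper = 1),
  multistage2 = list(
    P = function(par, d) par[1L] + (1 - par[1L]) *
      (1 - exp(-(par[2L] * d + par[3L] * d^2))),
    par_names = c("g", "b1", "b2"),
    lower = c(0, 0, 0), upper = c(1, Inf, Inf),
    starts = function(dat) {
      top <- max(dat$doses)
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))
      bt <- -log(1 - emp[length(emp)])
      rbind(c(1e-3, bt / top / 2, bt / top^2 / 2),
            c(1e-3, bt / top, 1e-4),
            c(1e-3, 1e-4, bt / top^2))
    },
    bmd = function(par, bmr) {
      a <- -log(1 - bmr); b1 <- par[2L]; b2 <- par[3L]
      if (b2 <= 0) return(a / b1)
      (-b1 + sqrt(b1^2 + 4 * b2 * a)) / (2 * b2)
    },
    sub = function(b, free, bmr) {
      g <- free[1L]; b2 <- free[2L]
      b1 <- (-log(1 - bmr) - b2 * b^2) / b
      if (b1 < -1e-9) return(NULL)
      b1 <- max(b1, 0)
      function(d) g + (1 - g) * (1 - exp(-(b1 * d + b2 * d^2)))
    },
    sub_free = function(par) par[c(1L, 3L)],
    sub_lower = c(0, 0), sub_upper = c(1, Inf)),
  multistage3 = list(
    P = function(par, d) par[1L] + (1 - par[1L]) *
      (1 - exp(-(par[2L] * d + par[3L] * d^2 + par[4L] * d^3))),
    par_names = c("g", "b1", "b2", "b3"),
    lower = c(0, 0, 0, 0), upper = c(1, Inf, Inf, Inf),
    starts = function(dat) {
      top <- max(dat$doses)
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))
      bt <- -log(1 - emp[length(emp)])
      rbind(c(1e-3, bt / top / 3, bt / top^2 / 3, bt / top^3 / 3),
            c(1e-3, bt / top, 1e-5, 1e-5),
            c(1e-3, 1e-5, 1e-5, bt / top^3))
    },
    bmd = function(par, bmr) {
      a <- -log(1 - bmr)
      rt <- polyroot(c(-a, par[2L], par[3L], par[4L]))
      rr <- Re(rt[abs(Im(rt)) < 1e-8 & Re(rt) > 0])
      if (length(rr) == 0L) return(NA_real_)
      min(rr)
    },
    sub = function(b, free, bmr) {
      g <- free[1L]; b2 <- free[2L]; b3 <- free[3L]
      b1 <- (-log(1 - bmr) - b2 * b^2 - b3 * b^3) / b
      if (b1 < -1e-9) return(NULL)
      b1 <- max(b1, 0)
      function(d) g + (1 - g) * (1 - exp(-(b1 * d + b2 * d^2 + b3 * d^3)))
    },
    sub_free = function(par) par[c(1L, 3L, 4L)],
    sub_lower = c(0, 0, 0), sub_upper = c(1, Inf, Inf)),
  weibull = list(
    P = function(par, d) par[1L] + (1 - par[1L]) *
      (1 - exp(-par[3L] * d^par[2L])),
    par_names = c("g", "a", "beta"),
    lower = c(0, 1, 0), upper = c(1, 18, Inf),
    starts = function(dat) {
      top <- max(dat$doses)
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))
      bt <- -log(1 - emp[length(emp)])
      rbind(c(1e-3, 1.5, bt / top^1.5), c(1e-3, 1, bt / top),
            c(1e-3, 3, bt / top^3))
    },
    bmd = function(par, bmr) (-log(1 - bmr) / par[3L])^(1 / par[2L]),
    sub = function(b, free, bmr) {
      g <- free[1L]; a <- free[2L]
      beta <- -log(1 - bmr) / b^a
      function(d) g + (1 - g) * (1 - exp(-beta * d^a))
    },
    sub_free = function(par) par[c(1L, 2L)],
    sub_lower = c(0, 1), sub_upper = c(1, 18)),
  gamma = list(
    P = function(par, d) par[1L] + (1 - par[1L]) *
      stats::pgamma(par[3L] * d, shape = par[2L]),
    par_names = c("g", "a", "beta"),
    lower = c(0, 1, 0), upper = c(1, 18, Inf),
    starts = function(dat) {
      top <- max(dat$doses)
      emp <- clamp((dat$affected + 0.5) / (dat$denominator + 1))
      pt <- emp[length(emp)]
      rbind(c(1e-3, 1.5, stats::qgamma(pt, 1.5) / top),
            c(1e-3, 1, stats::qgamma(pt, 1) / top),
            c(1e-3, 3, stats::qgamma(pt, 3) / top))
    },
    bmd = function(par, bmr) stats::qgamma(bmr, shape = par[2L]) / par[3L],
    sub = function(b, free, bmr) {
      g <- free[1L]; a <- free[2L]
      beta <- stats::qgamma(bmr, shape = a) / b
      function(d) g + (1 - g) * stats::pgamma(beta * d, shape = a)
    },
    sub_free = function(par) par[c(1L, 2L)],
    sub_lower = c(0, 1), sub_upper = c(1, 18))
  )
})

.quantal_order <- stats::setNames(seq_along(.quantal_models),
                                  names(.quantal_models))

.binom_nll <- function(P) {
  function(par, dat) {
    p <- pmin(pmax(P(par, dat$doses), 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(dat$affected, dat$denominator, p, log = TRUE))
  }
}

# bounded minimization with deterministic multistart: L-BFGS-B from each
# start, then a Nelder-Mead polish (bounds enforced by penalty) because the
# line search aborts with a spurious non-convergence code when the optimum
# sits on the boundary of the feasible box
.ml_optim <- function(obj, starts, lower, upper, maxit, early_exit = -Inf) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    st <- pmin(pmax(starts[s, ], lower + 1e-9),
               ifelse(is.finite(upper), upper - 1e-9, starts[s, ]))
    o <- try(stats::optim(st, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = maxit)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value <= early_exit && best$convergence == 0L) return(best)
  }
  if (is.null(best) || best$convergence == 0L) return(best)
  pen <- function(par) if (any(par < lower) || any(par > upper)) 1e10 else obj(par)
  o <- try(stats::optim(pmin(pmax(best$par, lower), upper), pen,
                        control = list(maxit = 10 * maxit, reltol = 1e-12)),
           silent = TRUE)
  if (!inherits(o, "try-error") && o$value <= best$value + 1e-8) {
    o$par <- pmin(pmax(o$par, lower), upper)
    best <- o
  }
  best
}

#' Fit one quantal dose-response model by binomial maximum likelihood
#'
#' Standard BMDS-style forms: logistic, probit, log-logistic, quantal
#' linear, multistage (degree 2 and 3, coefficients restricted to be
#' non-negative), Weibull and gamma (shape restricted to >= 1). Fits use
#' bounded quasi-Newton search from three deterministic starts derived from
#' empirical transforms of the incidence fractions. The goodness-of-fit p
#' is the Pearson chi-square on `#doses - #parameters` degrees of freedom
#' (p = 1 when the model has at least as many parameters as dose groups).
#'
#' @param data a [dichotomous_dataset()] with at least 3 dose groups.
#' @param model_name one of `names(quantal_model_names())`.
#' @param max_iterations optimizer cap per start (default 250).
#' @return object of class `dichotomous_fit`: `params`, `loglik`, `aic`,
#'   `gof_p`, `n_params`, `converged`.
#' @export
fit_dichotomous <- function(data, model_name, max_iterations = 250L) {
  stopifnot(inherits(data, "dichotomous_dataset"))
  model_name <- match.arg(model_name, names(.quantal_models))
  if (length(data$doses) < 3L) stop("at least 3 dose groups are required")
  m <- .quantal_models[[model_name]]
  if (length(m$par_names) > length(data$doses))
    return(structure(list(model_name = model_name, converged = FALSE,
                          reason = "more parameters than dose groups"),
                     class = "dichotomous_fit"))
  nll <- .binom_nll(m$P)
  best <- .ml_optim(function(par) nll(par, data), m$starts(data),
                    m$lower, m$upper, max_iterations)
  if (is.null(best))
    return(structure(list(model_name = model_name, converged = FALSE,
                          reason = "optimizer failure"),
                     class = "dichotomous_fit"))
  par <- stats::setNames(best$par, m$par_names)
  ll <- -best$value
  k <- length(par)
  p <- m$P(par, data$doses)
  ex <- data$denominator * p
  chi <- sum((data$affected - ex)^2 / pmax(ex * (1 - p), 1e-12))
  df <- length(data$doses) - k
  gof_p <- if (df <= 0L) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  structure(list(model_name = model_name, params = par,
                 loglik = ll, aic = 2 * k - 2 * ll,
                 gof_p = gof_p, pearson_chisq = chi, gof_df = df,
                 n_params = k,
                 converged = best$convergence == 0L,
                 data = data),
            class = "dichotomous_fit")
}

#' Names of the available quantal models
#' @return character vector.
#' @export
quantal_model_names <- function() names(.quantal_models)

#' @export
print.dichotomous_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("dichotomous_fit [%s]: not converged (%s)\n",
                x$model_name, x$reason %||% "optimizer"))
    return(invisible(x))
  }
  cat(sprintf("dichotomous_fit [%s]: logLik %.3f, AIC %.3f, GOF p %.4g\n",
              x$model_name, x$loglik, x$aic, x$gof_p))
  print(signif(x$params, 5))
  invisible(x)
}

#' @export
coef.dichotomous_fit <- function(object, ...) object$params

#' @export
logLik.dichotomous_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
predict.dichotomous_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$doses else newdata
  .quantal_models[[object$model_name]]$P(object$params, d)
}

#' Benchmark dose at a given extra risk
#'
#' Solves `[P(d) - P(0)] / [1 - P(0)] = bmr` for the smallest positive
#' dose, using the model's closed-form inversion.
#'
#' @param fit a converged [fit_dichotomous()] object.
#' @param bmr extra risk (default 0.10). Must be strictly positive.
#' @return dose in mkd, or `NA_real_` when the risk level is unreachable.
#' @export
bmd_extra_risk <- function(fit, bmr = 0.10) {
  stopifnot(inherits(fit, "dichotomous_fit"), isTRUE(fit$converged))
  if (bmr <= 0 || bmr >= 1) return(NA_real_)
  b <- unname(.quantal_models[[fit$model_name]]$bmd(fit$params, bmr))
  if (!is.finite(b) || b <= 0) NA_real_ else b
}

#' Profile-likelihood BMDL for a quantal fit
#'
#' One-sided lower confidence bound on the BMD: the smallest `b` whose
#' constrained maximum log-likelihood (the dose-effect parameter
#' re-expressed through `b` via the extra-risk equation, remaining
#' parameters free) lies within `qchisq(2 * confidence - 1, 1) / 2` of the
#' unconstrained maximum, located by geometric bisection on `(0, BMD]`.
#'
#' @param fit a converged [fit_dichotomous()] object.
#' @param bmd the BMD from [bmd_extra_risk()].
#' @param bmr extra risk (default 0.10).
#' @param confidence one-sided level (default 0.95).
#' @return dose in mkd, or `NA_real_` if profiling fails.
#' @export
bmdl_profile_dichotomous <- function(fit, bmd, bmr = 0.10, confidence = 0.95) {
  stopifnot(inherits(fit, "dichotomous_fit"), isTRUE(fit$converged))
  if (!is.finite(bmd) || bmd <= 0) return(NA_real_)
  m <- .quantal_models[[fit$model_name]]
  dat <- fit$data
  target <- fit$loglik - stats::qchisq(2 * confidence - 1, df = 1) / 2
  st0 <- m$sub_free(fit$params)
  prof <- function(b) {
    obj <- function(free) {
      Pf <- m$sub(b, free, bmr)
      if (is.null(Pf)) return(1e10)
      p <- pmin(pmax(Pf(dat$doses), 1e-12), 1 - 1e-12)
      -sum(stats::dbinom(dat$affected, dat$denominator, p, log = TRUE))
    }
    best <- Inf
    for (st in list(st0, pmin(pmax(st0 * 0.5, m$sub_lower + 1e-6),
                              ifelse(is.finite(m$sub_upper),
                                     m$sub_upper - 1e-6, st0 * 0.5 + 1)))) {
      o <- try(stats::optim(st, obj, method = "L-BFGS-B",
                            lower = m$sub_lower, upper = m$sub_upper,
                            control = list(maxit = 500)), silent = TRUE)
      if (!inherits(o, "try-error") && o$value < best) best <- o$value
    }
    -best
  }
  lo <- bmd * 1e-3; hi <- bmd
  if (prof(hi) < target - 1e-6) return(NA_real_)
  if (prof(lo) >= target) return(lo)
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    if (prof(mid) >= target) hi <- mid else lo <- mid
    if (hi / lo < 1.002) break
  }
  hi
}

# deterministic AIC comparison, as in the continuous module
.dich_aic_before <- function(a, b) {
  if (a$aic < b$aic - 1e-6) return(TRUE)
  if (a$aic > b$aic + 1e-6) return(FALSE)
  if (a$n_params != b$n_params) return(a$n_params < b$n_params)
  .quantal_order[[a$model_name]] < .quantal_order[[b$model_name]]
}

#' Select the best quantal model
#'
#' Candidates are the converged fits with goodness-of-fit p above
#' `gof_threshold` and a defined BMD; the lowest AIC wins (near-ties go to
#' fewer parameters, then a fixed model order). When the BMDs across *all*
#' converged fits span a factor of `divergence_fold` or more, the report
#' carries a model-divergence flag — selection still proceeds, but the
#' spread signals model dependence of the answer.
#'
#' @param fits list of [fit_dichotomous()] objects.
#' @param bmr extra risk for the divergence check (default 0.10).
#' @param gof_threshold goodness-of-fit gate (default 0.1).
#' @param divergence_fold fold-range of BMDs that triggers the flag
#'   (default 3).
#' @return list with `fit` (selected `dichotomous_fit` or `NULL`),
#'   `bmd_divergent` flag, `bmd_range`, and `reason` when unmodeled.
#' @export
select_dichotomous <- function(fits, bmr = 0.10, gof_threshold = 0.1,
                               divergence_fold = 3) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0L)
    return(list(fit = NULL, bmd_divergent = FALSE, bmd_range = c(NA, NA),
                reason = "no converged fit"))
  bmds <- vapply(conv, function(f) {
    b <- bmd_extra_risk(f, bmr); if (is.na(b)) NA_real_ else b
  }, 0)
  rng <- range(bmds, na.rm = TRUE)
  divergent <- is.finite(rng[1L]) && rng[1L] > 0 &&
    rng[2L] / rng[1L] >= divergence_fold
  eligible <- conv[!is.na(bmds) &
                     vapply(conv, function(f) f$gof_p > gof_threshold, TRUE)]
  if (length(eligible) == 0L)
    return(list(fit = NULL, bmd_divergent = divergent, bmd_range = rng,
                reason = "no model with adequate fit"))
  best <- eligible[[1L]]
  for (f in eligible[-1L]) if (.dich_aic_before(f, best)) best <- f
  list(fit = best, bmd_divergent = divergent, bmd_range = rng, reason = NULL)
}

#' Quantal BMD analysis of a DEG-count dose-response profile
#'
#' Fits the full quantal suite to the dataset, selects a model with
#' [select_dichotomous()], and computes the BMD at `bmr` extra risk with
#' its profile-likelihood BMDL.
#'
#' @param data a [dichotomous_dataset()] (e.g. from
#'   [simulate_deg_count_profile()]).
#' @param bmr extra risk (default 0.10).
#' @param confidence one-sided BMDL level (default 0.95).
#' @param max_iterations optimizer cap (default 250).
#' @return list of class `deg_count_bmd`: `selected` (model name), `bmd`,
#'   `bmdl`, `bmd_divergent`, `fits` (all fits) and `table` (per-model
#'   summary data frame).
#' @examples
#' ds <- simulate_deg_count_profile(88, c(0, 23, 32, 71))
#' res <- deg_count_bmd(ds)
#' res$table
#' @export
deg_count_bmd <- function(data, bmr = 0.10, confidence = 0.95,
                          max_iterations = 250L) {
  fits <- lapply(quantal_model_names(), function(mn)
    fit_dichotomous(data, mn, max_iterations))
  names(fits) <- quantal_model_names()
  tab <- do.call(rbind, lapply(fits, function(f) {
    if (!isTRUE(f$converged))
      return(data.frame(model = f$model_name, aic = NA_real_, gof_p = NA_real_,
                        bmd = NA_real_, stringsAsFactors = FALSE))
    data.frame(model = f$model_name, aic = f$aic, gof_p = f$gof_p,
               bmd = bmd_extra_risk(f, bmr), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  sel <- select_dichotomous(fits, bmr = bmr)
  out <- list(selected = if (is.null(sel$fit)) NA_character_ else
                sel$fit$model_name,
              bmd = NA_real_, bmdl = NA_real_,
              bmd_divergent = sel$bmd_divergent,
              reason = sel$reason, fits = fits, table = tab)
  if (!is.null(sel$fit)) {
    out$bmd <- bmd_extra_risk(sel$fit, bmr)
    out$bmdl <- bmdl_profile_dichotomous(sel$fit, out$bmd, bmr, confidence)
  }
  class(out) <- "deg_count_bmd"
  out
}

#' @export
print.deg_count_bmd <- function(x, ...) {
  cat("deg_count_bmd:\n")
  print(transform(x$table, aic = signif(aic, 5), gof_p = signif(gof_p, 3),
                  bmd = signif(bmd, 4)))
  if (is.na(x$selected)) {
    cat("no model selected:", x$reason, "\n")
  } else {
    cat(sprintf("selected %s: BMD %.3f, BMDL %.3f mkd%s\n", x$selected,
                x$bmd, x$bmdl,
                if (isTRUE(x$bmd_divergent)) "  [BMDs divergent >= 3-fold]" else ""))
  }
  invisible(x)
}
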