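#' @export
summary.continuous_fit <- function(object, ...) {
  print(object)
  if (isTRUE(object$converged)) {
    ss <- object$ss
    cat(sprintf("  %d dose groups, N = %d; group means: %s\n", ss$G, ss$N,
                paste(signif(ss$m_g, 4), collapse = ", ")))
  }
  invisible(object)
}

#' Residuals of a continuous fit at the dose-group level
#'
#' The constant-variance likelihood depends on the data only through the
#' group means and the within-group sum of squares, so residuals are
#' reported per dose group: observed group mean minus fitted value.
#'
#' @param object a [fit_continuous()] object.
#' @param ... unused.
#' @return named numeric vector, one residual per dose group.
#' @export
residuals.continuous_fit <- function(object, ...) {
  stopifnot(isTRUE(object$converged))
  ss <- object$ss
  r <- ss$m_g - predict(object, ss$du)
  names(r) <- as.character(ss$du)
  r
}

#' Simulate replicate responses from a fitted continuous model
#'
#' Draws normal replicates around the fitted mean curve with the
#' maximum-likelihood residual SD — the parametric-bootstrap generator for
#' the fit.
#'
#' @param object a converged [fit_continuous()] object.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param doses per-sample dose vector; defaults to the fitted design
#'   (each dose group at its original size).
#' @param ... unused.
#' @return a data frame with one column per simulation; the `doses`
#'   attribute carries the design.
#' @export
simulate.continuous_fit <- function(object, nsim = 1, seed = NULL,
                                    doses = NULL, ...) {
  stopifnot(isTRUE(object$converged))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(doses)) doses <- rep(object$ss$du, times = object$ss$n_g)
  mu <- predict(object, doses)
  out <- as.data.frame(replicate(nsim, stats::rnorm(length(doses), mu,
                                                    object$sigma_hat)))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "doses") <- doses
  out
}

#' Plot a continuous dose-response fit
#'
#' Dose-group means, the fitted curve, and (when supplied) the BMD/BMDL
#' locations with the benchmark-response band.
#'
#' @param x a converged [fit_continuous()] object.
#' @param bmd,bmdl optional doses to mark.
#' @param bmr_sd benchmark response used for the band (default 1.349).
#' @param ... passed to [graphics::plot()].
#' @export
plot.continuous_fit <- function(x, bmd = NULL, bmdl = NULL, bmr_sd = 1.349,
                                ...) {
  stopifnot(isTRUE(x$converged))
  ss <- x$ss
  grid <- seq(0, max(ss$du), length.out = 200)
  mu <- predict(x, grid)
  graphics::plot(ss$du, ss$m_g, pch = 19, xlab = "dose (mkd)",
                 ylab = "response (log2 scale)",
                 ylim = range(c(ss$m_g, mu)),
                 main = sprintf("%s fit", x$model_name), ...)
  graphics::lines(grid, mu, col = "steelblue", lwd = 2)
  f0 <- predict(x, 0)
  graphics::abline(h = f0 + c(-1, 1) * bmr_sd * x$sigma_hat,
                   lty = 3, col = "grey50")
  if (!is.null(bmd) && is.finite(bmd))
    graphics::abline(v = bmd, col = "firebrick", lty = 2)
  if (!is.null(bmdl) && is.finite(bmdl))
    graphics::abline(v = bmdl, col = "firebrick", lty = 3)
  invisible(x)
}

#' @export
summary.dichotomous_fit <- function(object, ...) {
  print(object)
  if (isTRUE(object$converged)) {
    d <- object$data
    cat(sprintf("  Pearson chi-square %.3f on %d df\n",
                object$pearson_chisq, object$gof_df))
    print(data.frame(dose = d$doses, observed = d$affected / d$denominator,
                     fitted = signif(predict(object), 4)))
  }
  invisible(object)
}

#' Simulate incidence data from a fitted quantal model
#'
#' Binomial draws at the fitted per-dose probabilities with the original
#' denominators.
#'
#' @param object a converged [fit_dichotomous()] object.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of [dichotomous_dataset()] objects.
#' @export
simulate.dichotomous_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(isTRUE(object$converged))
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  p <- predict(object)
  lapply(seq_len(nsim), function(i)
    dichotomous_dataset(d$doses, stats::rbinom(length(p), d$denominator, p),
                        d$denominator))
}

#' Plot a quantal dose-response fit
#'
#' Observed incidence fractions and the fitted probability curve, with
#' optional BMD/BMDL marks.
#'
#' @param x a converged [fit_dichotomous()] object.
#' @param bmd,bmdl optional doses to mark.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dichotomous_fit <- function(x, bmd = NULL, bmdl = NULL, ...) {
  stopifnot(isTRUE(x$converged))
  d <- x$data
  grid <- seq(0, max(d$doses), length.out = 200)
  graphics::plot(d$doses, d$affected / d$denominator, pch = 19,
                 xlab = "dose (mkd)", ylab = "incidence fraction",
                 ylim = c(0, 1), main = sprintf("%s fit", x$model_name), ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  if (!is.null(bmd) && is.finite(bmd))
    graphics::abline(v = bmd, col = "firebrick", lty = 2)
  if (!is.null(bmdl) && is.finite(bmdl))
    graphics::abline(v = bmdl, col = "firebrick", lty = 3)
  invisible(x)
}
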