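#' Configuration for robust errors-in-variables normalization
#'
#' Defaults follow the robust EIV estimator for dual-luciferase data:
#' Tukey's biweight loss with `c_rho = 4.7` for the slope objective, an
#' M-estimate of scale with `c_chi = 1.56` and target `kappa = 0.05`,
#' optimizer tolerance `xtol = 1e-7` with at most `max_eval = 1000`
#' objective evaluations, and 999 basic-bootstrap replicates at the 95%
#' level.
#'
#' @param c_rho Tukey constant for the slope loss.
#' @param c_chi Tukey constant for the scale equation.
#' @param kappa target value of the scale equation, in (0, 0.5).
#' @param xtol relative tolerance on the slope.
#' @param max_eval maximum objective evaluations.
#' @param n_boot bootstrap replicates.
#' @param ci_level confidence level.
#' @return a `robust_config` list.
#' @export
robust_config <- function(c_rho = 4.7, c_chi = 1.56, kappa = 0.05,
                          xtol = 1e-7, max_eval = 1000, n_boot = 999,
                          ci_level = 0.95) {
  stopifnot(c_rho > 0, c_chi > 0, kappa > 0, kappa < 0.5, xtol > 0,
            max_eval > 0, n_boot > 0, ci_level > 0, ci_level < 1)
  structure(list(c_rho = c_rho, c_chi = c_chi, kappa = kappa, xtol = xtol,
                 max_eval = as.integer(max_eval),
                 n_boot = as.integer(n_boot), ci_level = ci_level),
            class = "robust_config")
}

#' Tukey's biweight loss
#'
#' `rho(t) = t^2/6 * (3 - 3 t^2/c^2 + t^4/c^4)` for `|t| <= c` and the
#' bound `c^2/6` beyond; even and nondecreasing in `|t|`, which caps the
#' influence of gross outliers.
#'
#' @param t numeric vector.
#' @param c positive tuning constant.
#' @return loss values.
#' @export
tukey_rho <- function(t, c) {
  if (!is.numeric(c) || c <= 0) stop("`c` must be positive")
  .tukey_rho_cpp(as.numeric(t), c)
}

#' M-estimate of scale
#'
#' Solves `mean(chi(r_i / S)) = kappa` for `S` by bracketed bisection,
#' `chi` being Tukey's loss at `c_chi`.  Scale-equivariant:
#' `m_scale(k r) = k m_scale(r)`.  When too many residuals are exactly
#' zero the equation has no positive solution and `S = 0` is returned with
#' a `degenerate` attribute.
#'
#' @param residuals numeric vector (n >= 1).
#' @param config a [robust_config()].
#' @return scale estimate `S >= 0` with attribute `degenerate`.
#' @export
m_scale <- function(residuals, config = robust_config()) {
  if (length(residuals) == 0L) stop("`residuals` must be non-empty")
  if (any(!is.finite(residuals))) stop("residuals must be finite")
  s <- .m_scale_cpp(as.numeric(residuals), config$c_chi, config$kappa)
  structure(s, degenerate = s == 0)
}

#' Robust errors-in-variables slope through the origin
#'
#' Estimates the slope `beta` of `y = beta x` by minimizing
#' `sum_i rho(d_i / S(beta))` where
#' `d_i = (1 + beta^2)^(-1/2) (y_i - beta x_i)` is the orthogonal distance
#' of `(x_i, y_i)` from the line, `rho` is Tukey's loss at `c_rho`, and
#' `S(beta)` is the nested M-estimate of scale of the distances.  Both
#' variables may carry noise; the bounded loss makes the estimate robust
#' to outliers.  The optimizer is a deterministic log-spaced grid around
#' the robust start `median(y_i / x_i)` followed by golden-section
#' refinement honouring `xtol` and `max_eval`.
#'
#' @param x,y paired, finite measurements (Renilla, Firefly); n >= 3.
#' @param config a [robust_config()].
#' @return a `slope_fit`: `beta`, `scale`, `objective`, `n`, `converged`,
#'   plus the data for bootstrapping.
#' @export
eiv_slope <- function(x, y, config = robust_config()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must be paired")
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (all(x == 0)) stop("all x are 0: slope is unidentifiable")
  beta0 <- slope_start(x, y)
  res <- .eiv_slope_cpp(x, y, beta0, config$c_rho, config$c_chi,
                        config$kappa, config$xtol, config$max_eval,
                        201L, 2)
  structure(list(beta = res$beta, scale = res$scale,
                 objective = res$objective, n = length(x),
                 converged = res$converged, n_eval = res$n_eval,
                 ci = NULL, seed = NULL, x = x, y = y, config = config),
            class = "slope_fit")
}

slope_start <- function(x, y) {
  pos <- x > 0
  b0 <- if (any(pos)) median(y[pos] / x[pos]) else median(y[x != 0] / x[x != 0])
  if (!is.finite(b0) || b0 == 0) b0 <- 1
  b0
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> beta = %.6g, S = %.4g, n = %d%s\n", x$beta,
              x$scale, x$n,
              if (!is.null(x$ci))
                sprintf(", %g%% CI [%.6g, %.6g]", 100 * x$config$ci_level,
                        x$ci[1], x$ci[2]) else ""))
  invisible(x)
}

#' Basic-bootstrap confidence interval for the EIV slope
#'
#' Resamples `(x, y)` pairs with replacement `n_boot` times, refits the
#' slope on each replicate, and forms the basic bootstrap interval
#' `(2 beta_hat - q_{1-a/2}, 2 beta_hat - q_{a/2})` from the replicate
#' quantiles.  Reproducible given `seed`.
#'
#' @inheritParams eiv_slope
#' @param seed integer seed for the resampling.
#' @param fit optional pre-computed [eiv_slope()] fit on the full data.
#' @return `c(low, high)`, with the replicate slopes as attribute
#'   `replicates`.
#' @export
bootstrap_ci <- function(x, y, config = robust_config(), seed,
                         fit = NULL) {
  if (missing(seed)) stop("`seed` is required for bootstrap CIs")
  if (is.null(fit)) fit <- eiv_slope(x, y, config)
  reps <- boot_replicates(fit, config, seed)
  n_fail <- sum(!is.finite(reps))
  if (n_fail > 0.1 * config$n_boot)
    stop(n_fail, " of ", config$n_boot,
         " bootstrap replicates failed to converge")
  a <- (1 - config$ci_level) / 2
  qs <- quantile(reps[is.finite(reps)], c(1 - a, a), names = FALSE)
  ci <- c(low = 2 * fit$beta - qs[1], high = 2 * fit$beta - qs[2])
  attr(ci, "replicates") <- reps
  ci
}

# replicate slopes; narrower deterministic search centred on the full-data
# estimate
boot_replicates <- function(fit, config, seed) {
  set.seed(seed)
  .eiv_boot_cpp(fit$x, fit$y, config$n_boot, fit$beta, config$c_rho,
                config$c_chi, config$kappa, config$xtol, config$max_eval,
                61L, 1.5)
}
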