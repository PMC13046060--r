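#' Fit the power law U(k) = alpha * k^-beta + gamma to a precision curve
#'
#' Bounded nonlinear least squares on the empirical precision curve:
#' minimizes \code{sum_k (u_k - alpha * k^-beta - gamma)^2} subject to
#' \code{alpha >= 0}, \code{beta in (0, 2]}, \code{gamma >= 0}. The
#' \code{alpha * k^-beta} term captures the precision gain from averaging k
#' SVs (beta = 1/2 is ideal central-limit scaling), and the asymptote gamma
#' is the residual relative imprecision of the WKP reference itself.
#'
#' The primary solver is bounded Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}) started at \code{gamma0 = min(u)},
#' \code{alpha0 = u(min k) - gamma0}, \code{beta0 = 0.5}. If it fails, or a
#' grid candidate beats it, a fallback grid over \code{beta = 0.05, 0.10,
#' ..., 2.00} with a linear solve for (alpha, gamma) at each beta (clipped
#' to the bounds) selects the best candidate and refines it with bounded
#' BFGS. The solution never has a larger residual sum of squares than the
#' initialization point.
#'
#' @param curve A \code{\link{precision_curve}}, or any data.frame with
#'   columns \code{k} and \code{u_percent}; needs \code{>= 3} distinct k
#'   with finite, non-negative u values.
#' @param bounds Optional list overriding the default parameter bounds, with
#'   elements \code{lower} and \code{upper}, each \code{c(alpha, beta,
#'   gamma)}.
#' @param init Optional numeric \code{c(alpha, beta, gamma)} start values.
#' @param weights Optional per-point weights (e.g. \code{curve$n_samples});
#'   unweighted by default.
#' @return An object of class \code{"power_law_fit"}: a list with
#'   \code{alpha}, \code{beta}, \code{gamma} (percent / dimensionless),
#'   \code{r2}, \code{converged} (\code{"lm"} or \code{"grid"} for the path
#'   that produced the optimum, \code{NA} if neither converged),
#'   \code{residuals_percent}, \code{param_se} (from the Levenberg-Marquardt
#'   curvature when available) and the fitted \code{curve}.
#' @examples
#' u <- 10 * (1:10)^-0.5 + 5
#' fit_power_law(data.frame(k = 1:10, u_percent = u))
#' @export
fit_power_law <- function(curve, bounds = NULL, init = NULL, weights = NULL) {
  k <- as.numeric(curve$k)
  u <- as.numeric(curve$u_percent)
  keep <- is.finite(k) & is.finite(u)
  if (!all(keep)) stop("non-finite k or u values in the precision curve")
  if (length(unique(k)) < 3L)
    stop("power-law fit needs at least 3 distinct k values")
  if (any(u < 0)) stop("u values must be non-negative")
  w <- if (is.null(weights)) rep(1, length(k)) else as.numeric(weights)
  stopifnot(length(w) == length(k), all(w > 0))

  lower <- c(alpha = 0, beta = 1e-6, gamma = 0)
  upper <- c(alpha = Inf, beta = 2, gamma = Inf)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower <- bounds$lower
    if (!is.null(bounds$upper)) upper <- bounds$upper
  }
  ssr_of <- function(p) sum(w * (u - p[1] * k^-p[2] - p[3])^2)

  if (is.null(init)) {
    g0 <- min(u)
    a0 <- max(u[which.min(k)] - g0, 1e-6)
    init <- c(alpha = a0, beta = 0.5, gamma = g0)
  }
  init <- pmin(pmax(init, lower), upper)

  cand <- list()   # each: list(par, ssr, path, se)
  fit_lm <- tryCatch(
    minpack.lm::nlsLM(
      u ~ alpha * k^-beta + gamma,
      data = data.frame(k = k, u = u),
      start = as.list(init), weights = w,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w2) NULL
  )
  if (!is.null(fit_lm)) {
    p <- stats::coef(fit_lm)
    se <- tryCatch(summary(fit_lm)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 3))
    cand$lm <- list(par = p, ssr = ssr_of(p), path = "lm", se = se)
  }

  # beta grid with linear solve for (alpha, gamma), clipped to bounds
  best_grid <- NULL
  for (beta in seq(0.05, 2, by = 0.05)) {
    x <- k^-beta
    fit <- stats::lm.wfit(cbind(x, 1), u, w)
    p <- c(alpha = unname(fit$coefficients[1]), beta = beta,
           gamma = unname(fit$coefficients[2]))
    p[is.na(p)] <- 0
    p <- pmin(pmax(p, lower), upper)
    if (p[1] == 0) p[3] <- min(max(sum(w * u) / sum(w), lower[3]), upper[3])
    if (is.null(best_grid) || ssr_of(p) < best_grid$ssr)
      best_grid <- list(par = p, ssr = ssr_of(p))
  }
  ref <- stats::optim(best_grid$par, ssr_of, method = "L-BFGS-B",
                      lower = lower, upper = pmin(upper, 1e12))
  if (ref$value <= best_grid$ssr) best_grid$par <- ref$par
  best_grid$ssr <- ssr_of(best_grid$par)
  cand$grid <- c(best_grid, list(path = "grid", se = rep(NA_real_, 3)))

  # keep the init as a floor so the fit never worsens the starting SSR
  cand$init <- list(par = init, ssr = ssr_of(init), path = NA_character_,
                    se = rep(NA_real_, 3))
  best <- cand[[which.min(vapply(cand, `[[`, 0, "ssr"))]]

  p <- best$par
  pred <- p[1] * k^-p[2] + p[3]
  res <- u - pred
  sst <- sum(w * (u - sum(w * u) / sum(w))^2)
  ssr <- best$ssr
  r2 <- if (sst > 0) 1 - ssr / sst else if (ssr < 1e-12) 1 else 0

  structure(
    list(alpha = unname(p[1]), beta = unname(p[2]), gamma = unname(p[3]),
         r2 = r2, converged = best$path, residuals_percent = res,
         param_se = best$se, curve = data.frame(k = k, u_percent = u)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law precision fit: U(k) = alpha * k^-beta + gamma\n")
  cat(sprintf("  alpha = %.4f %%   beta = %.4f   gamma = %.4f %%\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  R^2 = %.5f   path = %s\n", x$r2,
              if (is.na(x$converged)) "not converged" else x$converged))
  invisible(x)
}

#' Evaluate a fitted power law at k
#'
#' @param object A \code{\link{fit_power_law}} result.
#' @param k Positive count (or positive real for extrapolation); vectorized.
#'   Values beyond the fitted grid extrapolate the model, e.g. \code{k =
#'   100} for the projected precision of a 100-SV average.
#' @param ... Unused.
#' @return Predicted U(k) in percent.
#' @export
predict.power_law_fit <- function(object, k, ...) {
  stopifnot(is.numeric(k))
  if (any(!is.finite(k)) || any(k <= 0)) stop("'k' must be positive")
  object$alpha * k^-object$beta + object$gamma
}

#' Asymptotic precision floor gamma
#'
#' Returns the fitted asymptote gamma, the model's estimate of the relative
#' imprecision of the WKP reference itself (approximately
#' \code{100 * sd(eps_wkp) / D_true}): the best achievable relative
#' precision no matter how many SVs are averaged.
#'
#' @param fit A converged \code{\link{fit_power_law}} result.
#' @return Gamma in percent.
#' @export
asymptotic_floor <- function(fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (is.na(fit$converged)) stop("fit did not converge; no reliable floor")
  fit$gamma
}

#' Coefficient of determination of a power-law fit
#'
#' \code{1 - SSR / SST} with SST about the mean of the observed u values.
#' A degenerate flat curve (SST = 0) yields 1 when the residuals are also
#' zero, else 0.
#'
#' @param fit A \code{\link{fit_power_law}} result.
#' @param curve A precision curve with columns \code{k} and \code{u_percent}
#'   (defaults to the curve the fit was computed on).
#' @return R-squared (\code{<= 1}).
#' @export
r_squared <- function(fit, curve = fit$curve) {
  stopifnot(inherits(fit, "power_law_fit"))
  k <- as.numeric(curve$k); u <- as.numeric(curve$u_percent)
  if (length(k) != length(u)) stop("mismatched curve lengths")
  ssr <- sum((u - predict(fit, k))^2)
  sst <- sum((u - mean(u))^2)
  if (sst > 0) 1 - ssr / sst else if (ssr < 1e-12) 1 else 0
}
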