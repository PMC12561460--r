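# Weighted least-squares parameter estimation with robust scaling and a
# bounded Nelder-Mead search.

# simulate at the measurement times and return the model outputs aligned
# with the measurement rows; NULL on solver failure
.ye_predict_meas <- function(p, meas, design, variant, rtol, atol) {
  times <- sort(unique(meas$time))
  sol <- tryCatch(
    .ye_solve(design, p, variant, times = times, rtol = rtol,
              atol = atol),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  m <- sol$m
  tt <- m[, "time"]
  out <- numeric(nrow(meas))
  for (v in unique(meas$variable)) {
    sel <- meas$variable == v
    col <- if (v == "DOT") "DOTm" else v
    out[sel] <- approx(tt, m[, col], xout = meas$time[sel],
                       ties = "ordered")$y
  }
  out
}

# per-point weighted scaled residuals sqrt(w_l/(sigma^2 N_l)) * r_scaled
.ye_weighted_residuals <- function(h, meas, scaler, weights) {
  r <- numeric(nrow(meas))
  for (v in unique(meas$variable)) {
    sel <- meas$variable == v
    rs <- scale_values(scaler, v, h[sel]) -
      scale_values(scaler, v, meas$value[sel])
    r[sel] <- sqrt(weights[[v]] / (meas$sigma[sel]^2 * sum(sel))) * rs
  }
  r
}

#' Weighted least-squares cost of a parameter set
#'
#' The objective minimised by [ye_fit()]: per variable l and sampling point
#' k, `w_l / (sigma_lk^2 N_l) * (h_scaled - y_scaled)^2`, summed over all
#' points, where h is the simulated output and both sides are transformed
#' by the robust scaler fitted to the measurements. A failed simulation
#' returns a large finite penalty so a derivative-free optimizer can step
#' away from pathological parameter regions.
#'
#' @param theta named numeric of (free) parameter values to evaluate.
#' @param meas a [ye_measurements()] object.
#' @param design a [ye_design()] object whose horizon covers the data.
#' @param variant model variant.
#' @param p base [ye_params()] object that `theta` overrides.
#' @param scaler a [robust_scale_fit()] transform; fitted to `meas` when
#'   `NULL`.
#' @param rtol,atol solver tolerances used during fitting.
#' @param penalty value returned when the simulation fails.
#' @return scalar cost.
#' @export
ye_cost <- function(theta, meas, design, variant = "two_yef",
                    p = ye_reference_params(variant), scaler = NULL,
                    rtol = 1e-6, atol = 1e-8, penalty = 1e10) {
  if (length(theta)) p <- ye_set_values(p, theta)
  if (is.null(scaler)) scaler <- robust_scale_fit(meas)
  h <- .ye_predict_meas(p, meas, design, variant, rtol, atol)
  if (is.null(h) || any(!is.finite(h))) return(penalty)
  r <- .ye_weighted_residuals(h, meas, scaler, attr(meas, "weights"))
  sum(r^2)
}

# sine-squashing reparameterisation for box bounds under Nelder-Mead
.to_unbounded <- function(theta, lo, hi) {
  z <- (theta - lo) / (hi - lo)
  z <- pmin(pmax(z, 0), 1)
  asin(sqrt(z))
}

.to_bounded <- function(x, lo, hi) {
  lo + (hi - lo) * sin(x)^2
}

#' Fit the growth model to measurements
#'
#' Estimates the free parameters of a model variant from weighted
#' time-series measurements by minimising [ye_cost()] with the Nelder-Mead
#' simplex. Box bounds are enforced through a smooth sine-squashing
#' reparameterisation (`theta = lo + (hi - lo) * sin^2(x)`), so the search
#' itself is unconstrained while every evaluated candidate respects the
#' bounds. The fit is deterministic given identical inputs and options.
#'
#' @param meas a [ye_measurements()] object.
#' @param design a [ye_design()] object.
#' @param variant model variant, see [ye_variant()].
#' @param start starting [ye_params()]; defaults to the packaged reference
#'   set for the variant.
#' @param free character vector of parameter names to estimate; defaults to
#'   the parameters flagged free in `start` (after the variant constraints
#'   are applied).
#' @param control passed to [stats::optim()] (`maxit`, `reltol`, ...).
#' @param rtol,atol solver tolerances used during fitting.
#' @return object of class `ye_fit` with components `params` (full
#'   parameter set at the optimum), `coefficients` (free-parameter
#'   estimates), `value` (cost at the optimum), `initial_value`, `rmse`,
#'   `counts`, `convergence` (0 = converged), `residuals`, `scaler`,
#'   `measurements`, `design`, `variant`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' sc <- ye_scenario("two_yef", t_end = 8, feed = "none",
#'                   noise = c(X = 0.02, S = 0.02, A = 0.02, DOT = 0.02))
#' gen <- ye_generate(sc, seed = 1)
#' fit <- ye_fit(gen$measurements, gen$design, "two_yef",
#'               free = c("q_S_max", "Y_XS_em"))
#' coef(fit)
#' }
#' @export
ye_fit <- function(meas, design, variant = "two_yef", start = NULL,
                   free = NULL, control = list(), rtol = 1e-6,
                   atol = 1e-8) {
  stopifnot(inherits(meas, "ye_measurements"),
            inherits(design, "ye_design"))
  v <- ye_variant(variant)
  if (is.null(start)) {
    start <- ye_reference_params(
      v, if (design$feed$kind == "none") "batch" else "fed_batch")
  }
  start <- apply_variant(start, v)
  validate_params(start)
  if (max(meas$time) > design$t_end + 1e-9) {
    stop("design horizon t_end does not cover the measurements",
         call. = FALSE)
  }
  if (is.null(free)) free <- names(start$free)[start$free]
  .check_param_names(free)
  fixed_sel <- start$lower[free] >= start$upper[free]
  if (any(fixed_sel)) {
    warning("dropping free parameter(s) with collapsed bounds: ",
            paste(free[fixed_sel], collapse = ", "))
    free <- free[!fixed_sel]
  }
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)

  scaler <- robust_scale_fit(meas)
  weights <- attr(meas, "weights")
  lo <- start$lower[free]
  hi <- start$upper[free]
  x0 <- .to_unbounded(start$value[free], lo, hi)

  fn <- function(x) {
    theta <- .to_bounded(x, lo, hi)
    names(theta) <- free
    ye_cost(theta, meas, design, v, p = start, scaler = scaler,
            rtol = rtol, atol = atol)
  }
  control <- modifyList(list(maxit = 1000, reltol = 1e-8), control)
  init_value <- fn(x0)
  opt <- optim(x0, fn, method = "Nelder-Mead", control = control)

  theta_hat <- .to_bounded(opt$par, lo, hi)
  names(theta_hat) <- free
  p_hat <- ye_set_values(start, theta_hat)
  h <- .ye_predict_meas(p_hat, meas, design, v, rtol, atol)
  if (is.null(h)) {
    stop("simulation failed at the optimizer's final parameter set",
         call. = FALSE)
  }
  res <- data.frame(time = meas$time, variable = meas$variable,
                    observed = meas$value, fitted = h,
                    residual = meas$value - h)
  res$weighted <- .ye_weighted_residuals(h, meas, scaler, weights)

  structure(list(
    coefficients = theta_hat, params = p_hat, free = free,
    value = opt$value, initial_value = init_value,
    rmse = sqrt(opt$value / nrow(meas)),
    counts = opt$counts, convergence = opt$convergence,
    residuals = res, scaler = scaler, measurements = meas,
    design = design, variant = v, start = start,
    rtol = rtol, atol = atol
  ), class = "ye_fit")
}

#' Goodness of fit of a model fit
#'
#' Root mean square of the weighted, robust-scaled residuals over all
#' measurement points: `sqrt(cost / N_total)`. With every weighted scaled
#' residual equal to r, the value is |r|.
#'
#' @param fit a [ye_fit()] object.
#' @return scalar RMSE (dimensionless, on the weighted scaled residual
#'   scale).
#' @export
ye_rmse <- function(fit) {
  stopifnot(inherits(fit, "ye_fit"))
  sqrt(mean(fit$residuals$weighted^2))
}
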