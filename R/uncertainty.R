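# Monte-Carlo parameter-uncertainty quantification: LHS restarts,
# sensitivity-based subset selection, IQR outlier filtering, Student-t
# confidence intervals.

#' Latin hypercube sample over parameter bounds
#'
#' Stratified uniform sample: each dimension is divided into `n` equal bins
#' of its bound interval and every bin contains exactly one point.
#' Degenerate bounds (lower == upper) give a constant column.
#'
#' @param lower,upper named numeric vectors of finite bounds.
#' @param n number of points.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return `n` x `length(lower)` matrix with column names from `lower`.
#' @export
ye_lhs <- function(lower, upper, n, seed = NULL) {
  stopifnot(length(lower) == length(upper), n >= 1)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("LHS requires finite bounds for every free parameter",
         call. = FALSE)
  }
  if (any(upper < lower)) stop("upper < lower bound", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, length(lower))
  m <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(m) <- names(lower)
  m
}

#' Sensitivity-based selection of an identifiable parameter subset
#'
#' Computes a finite-difference sensitivity matrix of the robust-scaled
#' model outputs with respect to log-parameters at all measurement times,
#' ranks candidate parameters by root-mean-square sensitivity, and greedily
#' grows the subset while the collinearity index of the selected
#' (unit-normalised) sensitivity columns stays at or below `threshold`.
#' The collinearity index is `1/sqrt(lambda_min)` of the normalised
#' cross-product matrix; large values mean a parameter combination is
#' nearly unidentifiable from the data.
#'
#' @param fit a [ye_fit()] reference fit.
#' @param candidates parameter names to consider; default the fit's free
#'   parameters.
#' @param threshold collinearity-index cap (default 10).
#' @param rel_step relative finite-difference step on the log scale.
#' @return list with `subset` (ordered identifiable parameter names),
#'   `ranking` (data.frame: parameter, rms sensitivity, selected,
#'   collinearity index when added) and `sensitivities` (the scaled
#'   sensitivity matrix).
#' @export
ye_subset_select <- function(fit, candidates = NULL, threshold = 10,
                             rel_step = 0.01) {
  stopifnot(inherits(fit, "ye_fit"))
  if (is.null(candidates)) candidates <- fit$free
  .check_param_names(candidates)
  meas <- fit$measurements
  p0 <- fit$params
  scaled_outputs <- function(p) {
    h <- .ye_predict_meas(p, meas, fit$design, fit$variant, fit$rtol,
                          fit$atol)
    if (is.null(h)) stop("simulation failed during sensitivity analysis",
                         call. = FALSE)
    out <- numeric(nrow(meas))
    for (v in unique(meas$variable)) {
      sel <- meas$variable == v
      out[sel] <- scale_values(fit$scaler, v, h[sel])
    }
    out
  }
  S <- matrix(0, nrow(meas), length(candidates),
              dimnames = list(NULL, candidates))
  for (j in candidates) {
    th <- p0$value[[j]]
    if (th > 0) {
      up <- ye_set_values(p0, setNames(th * exp(rel_step), j))
      dn <- ye_set_values(p0, setNames(th * exp(-rel_step), j))
      S[, j] <- (scaled_outputs(up) - scaled_outputs(dn)) / (2 * rel_step)
    } else {
      # log-perturbation undefined at zero; one-sided absolute step over
      # the bound range instead
      step <- rel_step * max(p0$upper[[j]] - p0$lower[[j]], 1e-8)
      up <- ye_set_values(p0, setNames(th + step, j))
      S[, j] <- (scaled_outputs(up) - scaled_outputs(p0)) / step
    }
  }
  rms <- sqrt(colMeans(S^2))
  ord <- order(rms, decreasing = TRUE)
  selected <- character(0)
  gamma_at <- rep(NA_real_, length(candidates))
  names(gamma_at) <- candidates
  for (j in candidates[ord]) {
    if (rms[[j]] < 1e-12) next
    trial <- c(selected, j)
    Sn <- S[, trial, drop = FALSE]
    Sn <- sweep(Sn, 2, sqrt(colSums(Sn^2)), `/`)
    ev <- eigen(crossprod(Sn), symmetric = TRUE, only.values = TRUE)$values
    lam <- min(ev)
    if (lam <= 0) next
    gamma <- 1 / sqrt(lam)
    if (gamma <= threshold) {
      selected <- trial
      gamma_at[[j]] <- gamma
    }
  }
  if (!length(selected)) {
    warning("no identifiable parameter found below the collinearity cap")
  }
  ranking <- data.frame(parameter = candidates[ord],
                        rms_sensitivity = rms[ord],
                        selected = candidates[ord] %in% selected,
                        collinearity = gamma_at[candidates[ord]])
  rownames(ranking) <- NULL
  list(subset = selected, ranking = ranking, sensitivities = S)
}

#' Keep-mask of an IQR outlier filter
#'
#' Single-pass Tukey fence: values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' (type-7 quantiles) are excluded. With fewer than 4 values the filter is
#' skipped (all kept, with a warning). Identical values are all kept: the
#' fences collapse onto the value itself.
#'
#' @param x numeric vector (e.g. per-replicate RMSE values).
#' @param k fence multiplier, default 1.5.
#' @return logical keep-mask of `length(x)`.
#' @export
iqr_keep <- function(x, k = 1.5) {
  if (length(x) < 4) {
    warning("fewer than 4 values; IQR filter skipped")
    return(rep(TRUE, length(x)))
  }
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  keep <- x >= q[1] - k * iqr & x <= q[2] + k * iqr
  keep & is.finite(x)
}

#' Student-t confidence intervals of Monte-Carlo point estimates
#'
#' Per parameter: `mean +/- t_{(1+level)/2, n-1} * sd` of the kept point
#' estimates, interpreting the estimate dispersion itself as the parameter
#' uncertainty. The standard-error variant (`sd/sqrt(n)`) is reported
#' alongside for reference.
#'
#' @param estimates numeric matrix (replicates x parameters) or vector.
#' @param level confidence level.
#' @return data.frame: parameter, n, mean, sd, lower, upper, lower_se,
#'   upper_se. With fewer than 2 estimates the interval is undefined (NA,
#'   with a warning).
#' @export
ye_confint <- function(estimates, level = 0.95) {
  if (is.null(dim(estimates))) {
    estimates <- matrix(estimates, ncol = 1,
                        dimnames = list(NULL, "theta"))
  }
  n <- nrow(estimates)
  mu <- colMeans(estimates)
  if (n < 2) {
    warning("fewer than 2 estimates; confidence interval undefined")
    s <- rep(NA_real_, ncol(estimates))
    tq <- NA_real_
  } else {
    s <- apply(estimates, 2, sd)
    tq <- qt((1 + level) / 2, df = n - 1)
  }
  data.frame(parameter = colnames(estimates), n = n, mean = mu, sd = s,
             lower = mu - tq * s, upper = mu + tq * s,
             lower_se = mu - tq * s / sqrt(n),
             upper_se = mu + tq * s / sqrt(n),
             row.names = NULL)
}

#' Monte-Carlo parameter-uncertainty quantification
#'
#' Quantifies the uncertainty of a reference fit by replication: `L`
#' replicate datasets are drawn from the fitted model (parametric bootstrap
#' with each point's measurement sigma, or residual resampling), each is
#' refit over the identifiable subset from a Latin-hypercube initial point,
#' outlier replicates are removed by the IQR rule on the per-replicate
#' RMSE, and per-parameter standard deviations and Student-t confidence
#' intervals are computed from the kept point estimates. The whole pipeline
#' is a pure function of (fit, options, seed).
#'
#' @param fit a converged [ye_fit()] reference fit.
#' @param L number of replications (250 in a full analysis; smaller values
#'   are used routinely for quick checks).
#' @param seed integer seed (mandatory).
#' @param subset identifiable parameter names; default the fit's free
#'   parameters (use [ye_subset_select()] to choose).
#' @param level confidence level.
#' @param filter apply the IQR outlier filter on replicate RMSEs.
#' @param residual use residual resampling instead of parametric noise.
#' @param control optimizer control for the replicate fits.
#' @return object of class `ye_mc`: list with `estimates` (L x p matrix,
#'   NA rows for failed fits), `rmse`, `kept` mask, `summary` (the
#'   [ye_confint()] table plus the reference estimates), `subset`, `L`,
#'   `seed`, `level`.
#' @export
ye_mc <- function(fit, L = 250, seed, subset = NULL, level = 0.95,
                  filter = TRUE, residual = FALSE, control = list()) {
  stopifnot(inherits(fit, "ye_fit"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(subset)) subset <- fit$free
  .check_param_names(subset)
  set.seed(seed)
  control <- modifyList(list(maxit = 250, reltol = 1e-7), control)

  replicates <- simulate.ye_fit(fit, nsim = L, residual = residual)
  inits <- ye_lhs(fit$start$lower[subset], fit$start$upper[subset], L)

  est <- matrix(NA_real_, L, length(subset),
                dimnames = list(NULL, subset))
  rmse <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    start_i <- ye_set_values(fit$params, inits[i, ])
    fi <- tryCatch(
      ye_fit(replicates[[i]], fit$design, fit$variant, start = start_i,
             free = subset, control = control, rtol = fit$rtol,
             atol = fit$atol),
      error = function(e) NULL)
    if (!is.null(fi)) {
      est[i, ] <- fi$coefficients
      rmse[i] <- fi$rmse
    }
  }
  ok <- !is.na(rmse)
  kept <- ok
  if (filter && sum(ok) >= 4) {
    kept[ok] <- iqr_keep(rmse[ok])
  }
  ci <- ye_confint(est[kept, , drop = FALSE], level = level)
  ci$reference <- unname(fit$params$value[subset])

  structure(list(estimates = est, rmse = rmse, kept = kept, summary = ci,
                 subset = subset, L = L, seed = seed, level = level,
                 filter = filter, fit = fit),
            class = "ye_mc")
}

#' @export
print.ye_mc <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo uncertainty: L = %d replications, %d kept after %s\n",
    x$L, sum(x$kept),
    if (x$filter) "IQR filtering" else "no filtering"))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
confint.ye_mc <- function(object, parm, level, ...) {
  ci <- object$summary
  if (!missing(level) && level != object$level) {
    ci <- ye_confint(object$estimates[object$kept, , drop = FALSE],
                     level = level)
  }
  rownames(ci) <- ci$parameter
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  as.matrix(ci[, c("lower", "upper")])
}

#' @export
plot.ye_mc <- function(x, ...) {
  est <- x$estimates[x$kept, , drop = FALSE]
  p <- ncol(est)
  op <- par(mfrow = c(1, p), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (j in seq_len(p)) {
    hist(est[, j], main = colnames(est)[j], xlab = "estimate",
         col = "grey85", border = "white", ...)
    abline(v = x$summary$reference[j], col = "firebrick", lwd = 2)
    abline(v = c(x$summary$lower[j], x$summary$upper[j]), lty = 2)
  }
  invisible(x)
}
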