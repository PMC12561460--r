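# S3 methods for ye_fit objects.

#' @export
print.ye_fit <- function(x, ...) {
  cat(sprintf("Yeast-extract growth model fit (%s variant)\n", x$variant))
  cat(sprintf("  %d measurement points, %d free parameter(s)\n",
              nrow(x$measurements), length(x$free)))
  cat(sprintf("  cost %.6g (from %.6g), RMSE %.4g, %s after %d evaluations\n",
              x$value, x$initial_value, x$rmse,
              if (x$convergence == 0) "converged" else "NOT converged",
              x$counts[["function"]]))
  cat("  estimates:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.ye_fit <- function(object, ...) object$coefficients

#' @export
residuals.ye_fit <- function(object, type = c("response", "weighted"),
                             ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals$residual
  else object$residuals$weighted
}

#' @export
fitted.ye_fit <- function(object, ...) object$residuals$fitted

#' @export
summary.ye_fit <- function(object, ...) {
  res <- object$residuals
  per_var <- do.call(rbind, lapply(split(res, res$variable), function(d) {
    data.frame(variable = d$variable[1], n = nrow(d),
               rmse_native = sqrt(mean(d$residual^2)),
               rmse_weighted = sqrt(mean(d$weighted^2)))
  }))
  rownames(per_var) <- NULL
  out <- list(fit = object, per_variable = per_var,
              bounds = data.frame(parameter = object$free,
                                  estimate = unname(object$coefficients),
                                  lower = unname(object$start$lower[object$free]),
                                  upper = unname(object$start$upper[object$free])))
  class(out) <- "summary.ye_fit"
  out
}

#' @export
print.summary.ye_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-variable residuals:\n")
  print(x$per_variable, digits = 4)
  cat("\nEstimates and bounds:\n")
  print(x$bounds, digits = 4)
  at_bound <- with(x$bounds, estimate <= lower + 1e-8 * (upper - lower) |
                     estimate >= upper - 1e-8 * (upper - lower))
  if (any(at_bound)) {
    cat("note: estimate(s) at a bound:",
        paste(x$bounds$parameter[at_bound], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict model observables from a fitted model
#'
#' Re-simulates the fitted parameter set over the design and returns the
#' noise-free model outputs at the requested times.
#'
#' @param object a [ye_fit()] object.
#' @param times times (h); default a dense grid over the design horizon.
#' @param variables subset of `c("X", "S", "A", "DOT")`.
#' @param ... unused.
#' @return data.frame `time`, `variable`, `value`.
#' @export
predict.ye_fit <- function(object, times = NULL,
                           variables = c("X", "S", "A", "DOT"), ...) {
  if (is.null(times)) {
    times <- seq(0, object$design$t_end, length.out = 200)
  }
  traj <- ye_simulate(object$design, object$params, object$variant)
  ye_observe(traj, times, variables)
}

#' @export
plot.ye_fit <- function(x, ...) {
  res <- x$residuals
  pred <- predict(x)
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  labs <- c(X = "biomass X [g/L]", S = "glucose S [g/L]",
            A = "acetate A [g/L]", DOT = "DOT [% sat.]")
  for (v in intersect(names(labs), unique(res$variable))) {
    d <- res[res$variable == v, ]
    pr <- pred[pred$variable == v, ]
    ylim <- range(d$observed, pr$value)
    plot(d$time, d$observed, xlab = "time [h]", ylab = labs[[v]],
         ylim = ylim, pch = 16, col = adjustcolor("black", 0.6), ...)
    lines(pr$time, pr$value, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Parametric-bootstrap replicate datasets from a fitted model
#'
#' Simulates the fitted model at the measurement times and adds Gaussian
#' noise with each point's own `sigma`, producing replicate measurement
#' sets of the kind used by [ye_mc()]. With `residual = TRUE`, resamples
#' the fit's raw residuals (per variable, with replacement) instead of
#' drawing parametric noise.
#'
#' @param object a [ye_fit()] object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (mandatory for reproducibility when given).
#' @param residual use residual resampling instead of parametric noise.
#' @param ... unused.
#' @return list of [ye_measurements()] objects of length `nsim`.
#' @export
simulate.ye_fit <- function(object, nsim = 1, seed = NULL,
                            residual = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  meas <- object$measurements
  h <- object$residuals$fitted
  lapply(seq_len(nsim), function(i) {
    if (residual) {
      noise <- numeric(nrow(meas))
      for (v in unique(meas$variable)) {
        sel <- meas$variable == v
        noise[sel] <- sample(object$residuals$residual[
          object$residuals$variable == v], sum(sel), replace = TRUE)
      }
    } else {
      noise <- rnorm(nrow(meas), 0, meas$sigma)
    }
    rep <- as.data.frame(meas)
    rep$value <- h + noise
    ye_measurements(rep, weights = attr(meas, "weights"))
  })
}
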