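# Weighted, sigma-annotated time-series measurements of X, S, A, DOT.

.ye_obs_vars <- c("X", "S", "A", "DOT")

#' Assemble a measurement set
#'
#' Long-format measurements of the four observables: biomass `X`, glucose
#' `S`, acetate `A` (all g L^-1) and dissolved oxygen `DOT` (% saturation,
#' the probe reading). Each point may carry its own standard deviation
#' `sigma`; where missing, a per-variable constant of
#' `sigma_rel * |median(value)|` (floored at `sigma_floor`) is imputed,
#' since the weighted cost function requires one. Per-variable weights
#' default to 10, 6, 4, 2 for X, S, A, DOT.
#'
#' @param data data.frame with columns `time`, `variable`, `value` and
#'   optionally `sigma`.
#' @param weights named numeric, cost-function weight per variable.
#' @param sigma_rel,sigma_floor imputation rule for missing sigmas.
#' @return object of class `ye_measurements`: the data sorted by variable
#'   and time, with a complete `sigma` column and a `weights` attribute.
#' @export
ye_measurements <- function(data,
                            weights = c(X = 10, S = 6, A = 4, DOT = 2),
                            sigma_rel = 0.05, sigma_floor = 1e-3) {
  stopifnot(is.data.frame(data),
            all(c("time", "variable", "value") %in% names(data)))
  data$variable <- as.character(data$variable)
  bad <- setdiff(unique(data$variable), .ye_obs_vars)
  if (length(bad)) {
    stop("unknown measurement variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(data$sigma)) data$sigma <- NA_real_
  data <- data[order(match(data$variable, .ye_obs_vars), data$time),
               c("time", "variable", "value", "sigma")]
  rownames(data) <- NULL
  for (v in unique(data$variable)) {
    sel <- data$variable == v
    miss <- sel & !is.finite(data$sigma)
    if (any(miss)) {
      s <- max(sigma_rel * abs(median(data$value[sel])), sigma_floor)
      data$sigma[miss] <- s
    }
  }
  if (any(data$sigma <= 0)) {
    stop("measurement sigma must be > 0", call. = FALSE)
  }
  w <- weights[.ye_obs_vars]
  names(w) <- .ye_obs_vars
  if (any(is.na(w[unique(data$variable)]))) {
    stop("weights must be named for every measured variable", call. = FALSE)
  }
  structure(data, weights = w, class = c("ye_measurements", "data.frame"))
}

#' @export
print.ye_measurements <- function(x, ...) {
  tab <- table(x$variable)
  cat(sprintf("Measurement set: %d points (%s), t in [%.3g, %.3g] h\n",
              nrow(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Read / write measurements as tidy delimited text
#'
#' Comma-separated with a header line; columns `time`, `variable`, `value`
#' and optionally `sigma`.
#'
#' @param path file path.
#' @param ... passed to [ye_measurements()].
#' @return for `read_measurements`, a `ye_measurements` object.
#' @export
read_measurements <- function(path, ...) {
  ye_measurements(read.table(path, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE), ...)
}

#' @rdname read_measurements
#' @param meas a `ye_measurements` object (or compatible data.frame).
#' @export
write_measurements <- function(meas, path) {
  write.table(as.data.frame(meas), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Fit a robust (median/IQR) scaling transform
#'
#' Per measured variable, centres by the median and scales by the
#' interquartile range (type-7 quantiles), the same convention as
#' scikit-learn's RobustScaler. A zero IQR (e.g. a constant series) falls
#' back to scale 1. The transform is fitted on the measurements only and
#' applied identically to measurements and simulated outputs, so the
#' weighted cost compares like with like regardless of the native units.
#'
#' @param meas a [ye_measurements()] object.
#' @return object of class `ye_scaler`: named list of `c(center, scale)`
#'   per variable.
#' @examples
#' m <- ye_measurements(data.frame(time = 1:5, variable = "X",
#'                                 value = c(1, 2, 3, 4, 5)))
#' sc <- robust_scale_fit(m)
#' scale_values(sc, "X", c(1, 3, 5))  # -1, 0, 1
#' @export
robust_scale_fit <- function(meas) {
  stopifnot(inherits(meas, "ye_measurements"))
  vars <- unique(meas$variable)
  out <- lapply(vars, function(v) {
    vals <- meas$value[meas$variable == v]
    if (length(vals) < 2) {
      stop("need at least 2 points per variable to fit the scaler",
           call. = FALSE)
    }
    q <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    c(center = q[2], scale = if (iqr > 0) iqr else 1)
  })
  names(out) <- vars
  structure(out, class = "ye_scaler")
}

#' @rdname robust_scale_fit
#' @param scaler a `ye_scaler` object.
#' @param variable variable name.
#' @param values numeric values to transform.
#' @export
scale_values <- function(scaler, variable, values) {
  stopifnot(inherits(scaler, "ye_scaler"))
  sc <- scaler[[variable]]
  if (is.null(sc)) stop("scaler has no entry for ", variable, call. = FALSE)
  (values - sc[["center"]]) / sc[["scale"]]
}
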