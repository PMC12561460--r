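# Feed profiles: none / stepwise-constant / exponential / bolus, plus
# evaporation and a cumulative-substrate stop criterion.

.new_feed <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "ye_feed")
}

#' Batch operation (no feed)
#'
#' @param evaporation evaporative volume loss (L h^-1), active over the whole
#'   run.
#' @return a `ye_feed` object of kind `"none"`.
#' @export
ye_feed_none <- function(evaporation = 0) {
  stopifnot(evaporation >= 0)
  .new_feed("none", Si = 0, t_start = Inf, evaporation = evaporation,
            stop_mass = NULL, t_stop = Inf)
}

#' Stepwise-constant feed profile
#'
#' A user-supplied table of piecewise-constant feed rates, as produced by an
#' operator-adjusted constant ("stepwise") feeding strategy. The schedule is
#' given as absolute times; the rate is 0 before the first step and holds
#' the last step's rate until the stop criterion.
#'
#' @param steps data.frame with columns `time` (h, non-decreasing) and
#'   `rate` (L h^-1, >= 0), or a path to a two-column delimited text file
#'   (header optional).
#' @param Si glucose concentration of the feed stock (g L^-1).
#' @param stop_mass stop criterion: cumulative glucose fed per initial
#'   volume (g L^-1); the feed rate is 0 once reached. `NULL` disables.
#' @param t_stop hard feed end time (h).
#' @param evaporation evaporative volume loss (L h^-1).
#' @return a `ye_feed` object of kind `"stepwise"`.
#' @export
ye_feed_stepwise <- function(steps, Si, stop_mass = NULL, t_stop = Inf,
                             evaporation = 0) {
  if (is.character(steps)) steps <- read_feed_steps(steps)
  stopifnot(is.data.frame(steps), all(c("time", "rate") %in% names(steps)))
  steps <- steps[order(steps$time), c("time", "rate")]
  if (any(steps$rate < 0) || any(steps$time < 0)) {
    stop("step times and rates must be >= 0", call. = FALSE)
  }
  if (Si < 0 || evaporation < 0) stop("Si and evaporation must be >= 0")
  .new_feed("stepwise", Si = Si, t_start = steps$time[1], steps = steps,
            stop_mass = stop_mass, t_stop = t_stop,
            evaporation = evaporation)
}

#' Exponential feed profile
#'
#' Continuous exponential feeding `F(t) = F0 * exp(mu_set * (t - t_start))`
#' designed to hold the culture at a set specific growth rate `mu_set`.
#'
#' @param F0 initial feed rate (L h^-1); see [exponential_F0()].
#' @param mu_set design specific growth rate (h^-1).
#' @param Si feed glucose concentration (g L^-1).
#' @param t_start feed start time (h).
#' @inheritParams ye_feed_stepwise
#' @return a `ye_feed` object of kind `"exponential"`.
#' @export
ye_feed_exponential <- function(F0, mu_set, Si, t_start,
                                stop_mass = NULL, t_stop = Inf,
                                evaporation = 0) {
  stopifnot(F0 >= 0, mu_set >= 0, Si >= 0, t_start >= 0, evaporation >= 0)
  .new_feed("exponential", Si = Si, t_start = t_start, F0 = F0,
            mu_set = mu_set, stop_mass = stop_mass, t_stop = t_stop,
            evaporation = evaporation)
}

#' Bolus (pulsed) feed profile
#'
#' Feed delivered as instantaneous, perfectly mixed pulses every
#' `pulse_interval` hours starting at `t_start`. Per pulse, either a fixed
#' `pulse_volume` is added or, by default, the volume that a continuous
#' exponential feed (`F0`, `mu_set`) would deliver over the coming interval,
#' so that the pulse train tracks the exponential target.
#'
#' @param pulse_interval time between pulses (h), e.g. `5/60` for 5 min.
#' @param pulse_volume fixed volume per pulse (L); `NULL` for the
#'   exponential-equivalent volume.
#' @inheritParams ye_feed_exponential
#' @return a `ye_feed` object of kind `"bolus"`.
#' @export
ye_feed_bolus <- function(F0, mu_set, Si, t_start, pulse_interval,
                          pulse_volume = NULL, stop_mass = NULL,
                          t_stop = Inf, evaporation = 0) {
  stopifnot(F0 >= 0, mu_set >= 0, Si >= 0, t_start >= 0,
            pulse_interval > 0, evaporation >= 0)
  if (!is.null(pulse_volume)) stopifnot(pulse_volume >= 0)
  .new_feed("bolus", Si = Si, t_start = t_start, F0 = F0, mu_set = mu_set,
            pulse_interval = pulse_interval, pulse_volume = pulse_volume,
            stop_mass = stop_mass, t_stop = t_stop,
            evaporation = evaporation)
}

#' @export
print.ye_feed <- function(x, ...) {
  desc <- switch(x$kind,
    none = "batch (no feed)",
    stepwise = sprintf("stepwise, %d steps from t = %g h, Si = %g g/L",
                       nrow(x$steps), x$t_start, x$Si),
    exponential = sprintf(
      "exponential, F0 = %.3g L/h, mu_set = %g 1/h from t = %g h, Si = %g g/L",
      x$F0, x$mu_set, x$t_start, x$Si),
    bolus = sprintf(
      "bolus every %.3g h from t = %g h (exp. target F0 = %.3g L/h, mu_set = %g 1/h), Si = %g g/L",
      x$pulse_interval, x$t_start, x$F0, x$mu_set, x$Si))
  cat(desc, "\n")
  if (x$evaporation > 0) {
    cat(sprintf("  evaporation %.3g L/h\n", x$evaporation))
  }
  invisible(x)
}

#' Read a stepwise feed schedule from a delimited text file
#'
#' Expects two columns, time (h) and rate (L h^-1); a header line naming
#' them is optional.
#'
#' @param path file path.
#' @return data.frame with columns `time` and `rate`.
#' @export
read_feed_steps <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- read.table(path, header = has_header, sep = "")
  names(df)[1:2] <- c("time", "rate")
  df[, c("time", "rate")]
}

#' Initial rate of an exponential feed
#'
#' `F0 = mu_set * X0 * V0 / (Si * Y_XS)`: the rate that supplies just enough
#' glucose for a culture of biomass `X0 * V0` to grow at `mu_set` with yield
#' `Y_XS`.
#'
#' @param mu_set design specific growth rate (h^-1).
#' @param Si feed glucose concentration (g L^-1).
#' @param Y_XS biomass yield on glucose (g g^-1).
#' @param X0 biomass concentration at feed start (g L^-1).
#' @param V0 broth volume at feed start (L).
#' @return initial feed rate (L h^-1).
#' @examples
#' exponential_F0(0.2, 400, 0.5, 0.5, 0.01)  # 5e-06
#' @export
exponential_F0 <- function(mu_set, Si, Y_XS, X0, V0) {
  if (Si <= 0 || Y_XS <= 0) stop("Si and Y_XS must be > 0", call. = FALSE)
  stopifnot(mu_set > 0, X0 > 0, V0 > 0)
  mu_set * X0 * V0 / (Si * Y_XS)
}

# time at which the cumulative-substrate stop criterion is met (Inf if never)
feed_stop_time <- function(profile, V0) {
  t_stop <- if (is.null(profile$t_stop)) Inf else profile$t_stop
  if (is.null(profile$stop_mass) || profile$kind == "none") return(t_stop)
  target <- profile$stop_mass * V0 # grams of glucose
  if (profile$Si <= 0) return(t_stop)
  t_mass <- Inf
  if (profile$kind == "exponential" || profile$kind == "bolus") {
    # continuous-equivalent mass Si*(F0/mu)(e^{mu*dt}-1), linear when mu = 0
    F0 <- profile$F0
    mu <- profile$mu_set
    if (profile$kind == "bolus" && !is.null(profile$pulse_volume)) {
      n_pulse <- ceiling(target / (profile$Si * profile$pulse_volume))
      t_mass <- profile$t_start + (n_pulse - 1) * profile$pulse_interval +
        profile$pulse_interval / 2
    } else if (F0 > 0) {
      dt <- if (mu > 0) {
        log(target * mu / (profile$Si * F0) + 1) / mu
      } else {
        target / (profile$Si * F0)
      }
      t_mass <- profile$t_start + dt
    }
  } else if (profile$kind == "stepwise") {
    st <- profile$steps
    times <- c(st$time, Inf)
    mass <- 0
    for (i in seq_len(nrow(st))) {
      seg <- times[i + 1] - times[i]
      add <- profile$Si * st$rate[i] * seg
      if (is.finite(add) && mass + add < target) {
        mass <- mass + add
      } else if (st$rate[i] > 0) {
        t_mass <- times[i] + (target - mass) / (profile$Si * st$rate[i])
        break
      }
    }
  }
  min(t_stop, t_mass)
}

#' Continuous feed rate at given times
#'
#' Evaluates `F(t)` for a feed profile: 0 before `t_start` and after the
#' stop criterion; the active step's rate for stepwise profiles; the
#' exponential law for exponential profiles; identically 0 for bolus
#' profiles (their delivery is event-based, see [bolus_schedule()]).
#'
#' @param t time(s), h.
#' @param profile a `ye_feed` object.
#' @param V0 initial broth volume (L); needed only when the profile carries
#'   a cumulative-substrate stop criterion.
#' @return feed rate(s), L h^-1.
#' @export
feed_rate_at <- function(t, profile, V0 = NULL) {
  stopifnot(inherits(profile, "ye_feed"))
  if (!is.null(profile$stop_mass) && is.null(V0) &&
      profile$kind != "bolus") {
    stop("V0 required to evaluate the cumulative-substrate stop criterion",
         call. = FALSE)
  }
  t_off <- feed_stop_time(profile, V0)
  F <- numeric(length(t))
  on <- t >= profile$t_start & t < t_off
  if (profile$kind == "exponential") {
    F[on] <- profile$F0 * exp(profile$mu_set * (t[on] - profile$t_start))
  } else if (profile$kind == "stepwise") {
    idx <- findInterval(t[on], profile$steps$time)
    F[on] <- ifelse(idx >= 1, profile$steps$rate[pmax(idx, 1)], 0)
  }
  F
}

#' Bolus event schedule
#'
#' Pulse times `t_start + k * pulse_interval` (k = 0, 1, ...) within the
#' half-open horizon `[t_start, horizon_end)`, with per-pulse volumes equal
#' to the fixed `pulse_volume` or to the exponential-equivalent volume
#' `(F0/mu_set) * (exp(mu_set*(t2-t_start)) - exp(mu_set*(t1-t_start)))`
#' integrated over each coming interval. Pulses stop once the cumulative
#' glucose fed reaches `stop_mass * V0`.
#'
#' @param profile a bolus `ye_feed` object.
#' @param horizon numeric of length 2, `c(t0, t_end)` (h).
#' @param V0 initial broth volume (L), for the stop criterion.
#' @return data.frame with columns `time` (h) and `volume` (L); zero rows
#'   when no pulse falls inside the horizon.
#' @export
bolus_schedule <- function(profile, horizon, V0 = NULL) {
  stopifnot(inherits(profile, "ye_feed"))
  if (profile$kind != "bolus") {
    return(data.frame(time = numeric(0), volume = numeric(0)))
  }
  t0 <- max(horizon[1], profile$t_start)
  t_end <- min(horizon[2], profile$t_stop %||% Inf)
  if (t_end <= profile$t_start) {
    return(data.frame(time = numeric(0), volume = numeric(0)))
  }
  k0 <- ceiling((t0 - profile$t_start) / profile$pulse_interval - 1e-12)
  kmax <- floor((t_end - profile$t_start) / profile$pulse_interval - 1e-12)
  if (kmax < k0) {
    return(data.frame(time = numeric(0), volume = numeric(0)))
  }
  times <- profile$t_start + (k0:kmax) * profile$pulse_interval
  times <- times[times < t_end - 1e-12]
  if (!length(times)) {
    return(data.frame(time = numeric(0), volume = numeric(0)))
  }
  if (!is.null(profile$pulse_volume)) {
    vols <- rep(profile$pulse_volume, length(times))
  } else {
    rel1 <- times - profile$t_start
    rel2 <- rel1 + profile$pulse_interval
    mu <- profile$mu_set
    vols <- if (mu > 0) {
      (profile$F0 / mu) * (exp(mu * rel2) - exp(mu * rel1))
    } else {
      profile$F0 * profile$pulse_interval + 0 * rel1
    }
  }
  if (!is.null(profile$stop_mass)) {
    if (is.null(V0)) {
      stop("V0 required for the cumulative-substrate stop criterion",
           call. = FALSE)
    }
    cum <- cumsum(vols * profile$Si)
    keep <- cum <= profile$stop_mass * V0 + 1e-12
    times <- times[keep]
    vols <- vols[keep]
  }
  data.frame(time = times, volume = vols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
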