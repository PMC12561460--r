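# Flat key-value experiment-design configs (shell/CLI interface).

#' Read an experiment design from a flat key-value config file
#'
#' Format: one `key = value` per line, `#` comments. Recognised keys are
#' the [ye_design()] arguments (`X0` or `OD0`/`od_factor`, `S0`, `YE0`,
#' `A0`, `V0`, `t_end`, `carbon_literal`, `evap_conc`), the reactor
#' constants prefixed `reactor.` (`DOT_star`, `kLa`, `H`, `tau`) and the
#' feed prefixed `feed.` (`kind` in none/stepwise/exponential/bolus, `Si`,
#' `t_start`, `F0`, `mu_set`, `pulse_interval`, `pulse_volume`,
#' `stop_mass`, `t_stop`, `evaporation`, `steps_file` for a stepwise
#' schedule table).
#'
#' @param path file path.
#' @return a [ye_design()] object.
#' @export
read_design_config <- function(path) {
  kv <- .read_kv(path)
  num <- function(key, default = NULL) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else default
  }
  rc <- ye_reactor(
    DOT_star = num("reactor.DOT_star", 100),
    kLa = num("reactor.kLa", 1000),
    H = num("reactor.H", 14000),
    tau = num("reactor.tau", 0.008))
  kind <- if ("feed.kind" %in% names(kv)) kv[["feed.kind"]] else "none"
  evap <- num("feed.evaporation", 0)
  feed <- switch(kind,
    none = ye_feed_none(evaporation = evap),
    stepwise = ye_feed_stepwise(
      steps = if ("feed.steps_file" %in% names(kv)) {
        file.path(dirname(path), kv[["feed.steps_file"]])
      } else stop("stepwise feed needs feed.steps_file", call. = FALSE),
      Si = num("feed.Si"), stop_mass = num("feed.stop_mass"),
      t_stop = num("feed.t_stop", Inf), evaporation = evap),
    exponential = ye_feed_exponential(
      F0 = num("feed.F0"), mu_set = num("feed.mu_set"),
      Si = num("feed.Si"), t_start = num("feed.t_start"),
      stop_mass = num("feed.stop_mass"), t_stop = num("feed.t_stop", Inf),
      evaporation = evap),
    bolus = ye_feed_bolus(
      F0 = num("feed.F0"), mu_set = num("feed.mu_set"),
      Si = num("feed.Si"), t_start = num("feed.t_start"),
      pulse_interval = num("feed.pulse_interval"),
      pulse_volume = num("feed.pulse_volume"),
      stop_mass = num("feed.stop_mass"), t_stop = num("feed.t_stop", Inf),
      evaporation = evap),
    stop("unknown feed.kind '", kind, "'", call. = FALSE))
  ye_design(
    X0 = num("X0"), OD0 = num("OD0"), od_factor = num("od_factor", 0.37),
    S0 = num("S0", 0), YE0 = num("YE0", 0), A0 = num("A0", 0),
    V0 = num("V0", 0.01), t_end = num("t_end", 12),
    reactor = rc, feed = feed, DOTm0 = num("DOTm0"),
    carbon_literal = isTRUE(num("carbon_literal", 0) > 0),
    evap_conc = isTRUE(num("evap_conc", 0) > 0))
}

#' Write a trajectory as tidy delimited text
#'
#' One row per (time, variable); states and rates side by side in long
#' form, the format consumed by external plotting tools.
#'
#' @param traj a [ye_simulate()] trajectory.
#' @param path file path.
#' @param rates also write the specific rates.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, rates = FALSE) {
  stopifnot(inherits(traj, "ye_trajectory"))
  s <- traj$state
  long <- do.call(rbind, lapply(setdiff(names(s), "time"), function(v) {
    data.frame(time = s$time, variable = v, value = s[[v]])
  }))
  if (rates) {
    r <- traj$rates
    long <- rbind(long, do.call(rbind, lapply(names(r), function(v) {
      data.frame(time = s$time, variable = v, value = r[[v]])
    })))
  }
  write.table(long, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
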