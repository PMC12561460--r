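# Synthetic cultivation scenarios and noisy pseudo-measurements, emulating
# online DOT sensing and at-line sampling of biomass, glucose and acetate.

#' Define a synthetic cultivation scenario
#'
#' Bundles everything [ye_generate()] needs: a model variant, a generating
#' ("truth") parameter set, an experiment design, a noise model and a
#' sampling schedule. The default design emulates a mini-bioreactor
#' experiment: 10 mL working volume inoculated at OD600 = 0.3 with
#' 9 g L^-1 glucose and 10 g L^-1 yeast extract, an 8 h batch phase, then
#' an exponential bolus feed (pulses every 5 min, feed stock 400 g L^-1,
#' set growth rate 0.2 h^-1) to 14 h. DOT is sampled densely (online
#' cadence), X, S and A sparsely (at-line cadence).
#'
#' @param variant model variant, see [ye_variant()].
#' @param params truth [ye_params()]; default the packaged reference set of
#'   the variant (`phase` column chosen by feed regime).
#' @param design a [ye_design()]; `NULL` builds the template above with the
#'   arguments below.
#' @param YE0,S0,OD0,V0,t_end design template knobs (see [ye_design()]).
#' @param feed `"bolus"` (default template), `"none"` (batch), or a
#'   ready-made `ye_feed` object.
#' @param t_feed_start feed start time (h) for the template feed.
#' @param Si,mu_set template feed stock concentration and set growth rate.
#' @param noise per-variable relative noise sd (fractions).
#' @param noise_floor per-variable absolute noise floor (native units).
#' @param n_atline number of at-line samples per variable (X, S, A), evenly
#'   spaced over the horizon.
#' @param dot_interval online DOT sampling interval (h), default 1 min.
#' @param atline_jitter half-width (h) of uniform jitter on at-line times.
#' @return object of class `ye_scenario`.
#' @export
ye_scenario <- function(variant = "two_yef", params = NULL, design = NULL,
                        YE0 = 10, S0 = 9, OD0 = 0.3, V0 = 0.01,
                        t_end = NULL, feed = "bolus", t_feed_start = 8,
                        Si = 400, mu_set = 0.2,
                        noise = c(X = 0.02, S = 0.02, A = 0.02,
                                  DOT = 0.02),
                        noise_floor = c(X = 0.01, S = 0.01, A = 0.005,
                                        DOT = 0.5),
                        n_atline = 20, dot_interval = 1 / 60,
                        atline_jitter = 0) {
  v <- ye_variant(variant)
  if (is.null(design)) {
    if (inherits(feed, "ye_feed")) {
      fd <- feed
      if (is.null(t_end)) t_end <- 14
    } else if (identical(feed, "bolus")) {
      if (is.null(t_end)) t_end <- 14
      # pulse volumes track the exponential target computed from the
      # nominal biomass expected at feed start (Eq.-style F0 rule)
      F0 <- exponential_F0(mu_set, Si, Y_XS = 0.5, X0 = 5, V0 = V0)
      fd <- ye_feed_bolus(F0 = F0, mu_set = mu_set, Si = Si,
                          t_start = t_feed_start, pulse_interval = 5 / 60)
    } else if (identical(feed, "none")) {
      if (is.null(t_end)) t_end <- 10
      fd <- ye_feed_none()
    } else {
      stop("feed must be 'bolus', 'none' or a ye_feed object",
           call. = FALSE)
    }
    design <- ye_design(OD0 = OD0, S0 = S0, YE0 = YE0, V0 = V0,
                        t_end = t_end, feed = fd)
  }
  if (is.null(params)) {
    phase <- if (design$feed$kind == "none") "batch" else "fed_batch"
    params <- ye_reference_params(v, phase)
  }
  stopifnot(all(noise >= 0), all(noise_floor >= 0), n_atline >= 1,
            dot_interval > 0, atline_jitter >= 0)
  structure(list(variant = v, params = params, design = design,
                 noise = noise, noise_floor = noise_floor,
                 n_atline = n_atline, dot_interval = dot_interval,
                 atline_jitter = atline_jitter),
            class = "ye_scenario")
}

#' @export
print.ye_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario (%s): %d at-line samples/var, DOT every %.3g min\n",
    x$variant, x$n_atline, x$dot_interval * 60))
  print(x$design)
  invisible(x)
}

#' Generate a noisy synthetic dataset
#'
#' Simulates the scenario at its truth parameters, samples the trajectory
#' at the scenario's schedule and adds Gaussian noise with standard
#' deviation `rel * |value| + floor` per point. The generator is a pure
#' function of (scenario, seed).
#'
#' @param scenario a [ye_scenario()] object.
#' @param seed integer seed (mandatory).
#' @return list with `measurements` (a [ye_measurements()] object whose
#'   `sigma` column carries the true noise sd of each point),
#'   `trajectory` (the noise-free [ye_simulate()] truth), `truth` (the
#'   generating [ye_params()]), `design` and `variant`.
#' @examples
#' sc <- ye_scenario("two_yef", feed = "none", t_end = 8)
#' gen <- ye_generate(sc, seed = 42)
#' gen$measurements
#' @export
ye_generate <- function(scenario, seed) {
  stopifnot(inherits(scenario, "ye_scenario"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  d <- scenario$design

  t_at <- seq(0, d$t_end, length.out = scenario$n_atline + 1)[-1]
  if (scenario$atline_jitter > 0) {
    t_at <- pmin(pmax(t_at + runif(length(t_at), -scenario$atline_jitter,
                                   scenario$atline_jitter), 0), d$t_end)
    t_at <- sort(t_at)
  }
  t_dot <- seq(0, d$t_end, by = scenario$dot_interval)

  # solve at the sampling times themselves so measurements carry no
  # interpolation error on top of the solver tolerance
  traj <- ye_simulate(d, scenario$params, scenario$variant,
                      times = sort(unique(c(t_at, t_dot))))
  clean <- rbind(ye_observe(traj, t_at, c("X", "S", "A")),
                 ye_observe(traj, t_dot, "DOT"))
  sd <- scenario$noise[clean$variable] * abs(clean$value) +
    scenario$noise_floor[clean$variable]
  noisy <- clean
  noisy$value <- clean$value + rnorm(nrow(clean), 0, sd)
  # zero-noise scenarios leave sigma unspecified so that the measurement
  # constructor imputes its usual default instead of a degenerate 0
  noisy$sigma <- ifelse(sd > 0, sd, NA_real_)
  list(measurements = ye_measurements(noisy), trajectory = traj,
       truth = scenario$params, design = d, variant = scenario$variant)
}
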