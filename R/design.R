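# Reactor constants and experiment designs.

#' Reactor constants
#'
#' Physical constants of the oxygen-transfer and probe model. The probe gain
#' `K_P = 1/tau` is derived and stored alongside. Defaults describe a small
#' stirred-tank configuration with oxygen-enriched gassing and a fast optical
#' DO sensor; they are package choices, not measured values, and should be
#' set to the actual reactor at hand.
#'
#' @param DOT_star oxygen saturation level (% saturation).
#' @param kLa volumetric mass-transfer coefficient (h^-1).
#' @param H Henry-type conversion constant ((% saturation) L g^-1), turning
#'   a volumetric oxygen-uptake rate (g L^-1 h^-1) into a DOT deficit.
#' @param tau probe response time (h).
#' @return object of class `ye_reactor`.
#' @examples
#' ye_reactor(tau = 30 / 3600)  # a 30-second probe
#' @export
ye_reactor <- function(DOT_star = 100, kLa = 1000, H = 14000, tau = 0.008) {
  if (any(c(DOT_star, kLa, H, tau) <= 0)) {
    stop("all reactor constants must be strictly positive", call. = FALSE)
  }
  structure(list(DOT_star = DOT_star, kLa = kLa, H = H, tau = tau,
                 K_P = 1 / tau),
            class = "ye_reactor")
}

#' @export
print.ye_reactor <- function(x, ...) {
  cat(sprintf(
    "Reactor constants: DOT* = %g %%, kLa = %g 1/h, H = %g %%.L/g, tau = %g h (K_P = %g 1/h)\n",
    x$DOT_star, x$kLa, x$H, x$tau, x$K_P))
  invisible(x)
}

#' Experiment design
#'
#' Bundles the initial state, reactor constants, feed profile and numerical
#' switches of one cultivation. The initial yeast extract `YE0` is split
#' into its kinetic fractions by [split_yeast_extract()] at simulation time
#' using the distribution parameters of the parameter set, so one design can
#' serve every model variant.
#'
#' @param X0 initial biomass (g L^-1); alternatively give `OD0` and the
#'   OD-to-dry-weight conversion `od_factor` (see [od_to_biomass()]).
#' @param S0 initial glucose (g L^-1).
#' @param YE0 initial total yeast extract (g L^-1).
#' @param V0 initial broth volume (L).
#' @param t_end simulation horizon (h).
#' @param A0 initial acetate (g L^-1), usually 0.
#' @param reactor a [ye_reactor()] object.
#' @param feed a feed profile, see [ye_feed_none()] and friends.
#' @param OD0 initial optical density (overrides `X0` when given).
#' @param od_factor g L^-1 dry weight per OD600 unit.
#' @param DOTm0 initial probe reading; default `NULL` initialises the probe
#'   at the algebraic DOT of the initial state.
#' @param carbon_literal carbon-ratio convention switch, see [oxygen_rate()].
#' @param evap_conc if `TRUE`, evaporation (water removal) also concentrates
#'   the broth, adding `+(F_evap/V) * c` to every concentration balance.
#' @param S_deplete_tol glucose threshold (g L^-1) at which the integrator
#'   registers a depletion event and restarts.
#' @return object of class `ye_design`.
#' @examples
#' d <- ye_design(OD0 = 0.3, S0 = 9, YE0 = 10, V0 = 0.01, t_end = 10)
#' @export
ye_design <- function(X0 = NULL, S0 = 0, YE0 = 0, V0 = 0.01, t_end = 12,
                      A0 = 0, reactor = ye_reactor(), feed = ye_feed_none(),
                      OD0 = NULL, od_factor = 0.37, DOTm0 = NULL,
                      carbon_literal = FALSE, evap_conc = FALSE,
                      S_deplete_tol = 1e-9) {
  if (!is.null(OD0)) X0 <- od_to_biomass(OD0, od_factor)
  if (is.null(X0)) stop("give X0 or OD0", call. = FALSE)
  if (any(c(X0, S0, YE0, A0) < 0)) {
    stop("initial concentrations must be >= 0", call. = FALSE)
  }
  if (V0 <= 0) stop("V0 must be > 0", call. = FALSE)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  stopifnot(inherits(reactor, "ye_reactor"), inherits(feed, "ye_feed"))
  structure(list(X0 = X0, S0 = S0, YE0 = YE0, A0 = A0, V0 = V0,
                 t_end = t_end, reactor = reactor, feed = feed,
                 DOTm0 = DOTm0, carbon_literal = carbon_literal,
                 evap_conc = evap_conc, S_deplete_tol = S_deplete_tol),
            class = "ye_design")
}

#' @export
print.ye_design <- function(x, ...) {
  cat(sprintf(
    "Cultivation design: X0 = %.3g, S0 = %.3g, YE0 = %.3g g/L in V0 = %g L, horizon %g h\n",
    x$X0, x$S0, x$YE0, x$V0, x$t_end))
  cat("  feed: ")
  print(x$feed)
  invisible(x)
}

#' Convert optical density to biomass dry weight
#'
#' Linear conversion `X = OD600 * factor`. The default factor of
#' 0.37 g L^-1 per OD unit is a package choice typical for *E. coli* K-12;
#' calibrate it for the strain and photometer at hand.
#'
#' @param od optical density at 600 nm.
#' @param factor g L^-1 dry weight per OD unit.
#' @return biomass concentration (g L^-1).
#' @export
od_to_biomass <- function(od, factor = 0.37) {
  if (any(od < 0) || any(factor < 0)) {
    stop("od and factor must be >= 0", call. = FALSE)
  }
  od * factor
}
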