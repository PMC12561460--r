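# Batch / fed-batch integration of the model.

.ye_state_names <- c("X", "S", "A", "YEFA", "YEFB", "YEFC", "DOTm", "V")

# parameter vector handed to the compiled right-hand side; order must match
# src/yemodel.c
.ye_parms_vector <- function(p, rc, flags, carbon_literal, evap_conc,
                             feed_mode = 0, F_const = 0, F0 = 0, mu_set = 0,
                             t_ref = 0, Si = 0, F_evap = 0,
                             S_thresh = 1e-9, pulse_interval = 0,
                             pulse_volume = -1) {
  v <- p$value
  c(v[c("q_S_max", "K_S", "q_YEFA_max", "K_YEFA", "q_YEFB_max", "K_YEFB",
        "d_YE_AB", "d_YE_BC", "Ki_YEFA_qSox", "Ki_YEFB_qSox", "K_qSox",
        "Y_AS", "q_Ac_max", "K_A", "Ki_A_S", "q_m", "Y_XS_em", "Y_X_YEFA",
        "Y_X_YEFB", "Y_XA", "Y_OS", "Y_OA", "Y_O_YE", "C_X", "C_S", "C_A",
        "C_YE")],
    rc$DOT_star, rc$kLa, rc$H, rc$tau,
    as.numeric(flags[["yefa"]]), as.numeric(flags[["yefb"]]),
    as.numeric(carbon_literal), as.numeric(evap_conc),
    feed_mode, F_const, F0, mu_set, t_ref, Si, F_evap, S_thresh,
    pulse_interval, pulse_volume)
}

#' Model state derivative
#'
#' Evaluates the full set of mass balances at one reactor state: dilution by
#' the feed, uptake and growth from the algebraic rate layer, the
#' probe ODE and the volume balance. This is the reference (pure-R)
#' formulation of the right-hand side integrated by [ye_simulate()].
#'
#' @param state named numeric with `X`, `S`, `A`, `YEFA`, `YEFB`, `YEFC`
#'   (g L^-1), `DOTm` (% saturation), `V` (L).
#' @param p a [ye_params()] object.
#' @param rc a [ye_reactor()] object.
#' @param variant model variant, see [ye_variant()].
#' @param F continuous feed rate (L h^-1).
#' @param F_evap evaporation rate (L h^-1).
#' @param Si feed glucose concentration (g L^-1).
#' @param carbon_literal,evap_conc numerical switches, see [ye_design()].
#' @return named numeric vector of time derivatives, same order as `state`.
#' @export
ye_rhs <- function(state, p, rc = ye_reactor(), variant = "two_yef",
                   F = 0, F_evap = 0, Si = 0, carbon_literal = FALSE,
                   evap_conc = FALSE) {
  if (F < 0 || F_evap < 0) stop("F and F_evap must be >= 0", call. = FALSE)
  V <- state[["V"]]
  if (V <= 0) stop("broth volume V must be > 0", call. = FALSE)
  r <- ye_rates(state, p, rc, variant, carbon_literal = carbon_literal)
  D <- F / V
  E <- if (evap_conc) F_evap / V else 0
  X <- state[["X"]]
  der <- c(
    X = -D * X + r$mu * X + E * X,
    S = D * (Si - state[["S"]]) - r$q_S * X + E * state[["S"]],
    A = -D * state[["A"]] + r$q_A * X + E * state[["A"]],
    YEFA = -D * state[["YEFA"]] - r$q_YEFA * X + E * state[["YEFA"]],
    YEFB = -D * state[["YEFB"]] - r$q_YEFB * X + E * state[["YEFB"]],
    YEFC = -D * state[["YEFC"]] + E * state[["YEFC"]],
    DOTm = rc$K_P * (r$DOT - state[["DOTm"]]),
    V = F - F_evap
  )
  der
}

# one lsodar call over seg_times, with either a glucose-depletion root
# restart or compiled bolus events (never both); returns
# list(out = matrix, depletion = time or NULL)
.integrate_segment <- function(y0, seg_times, parms, rtol, atol, use_root,
                               event_times = NULL) {
  run <- function(y, tt, root) {
    deSolve::lsodar(
      y = y, times = tt, func = "yem_derivs", parms = parms,
      dllname = "yegrowth", initfunc = "yem_initmod",
      rootfunc = if (root) "yem_root" else NULL,
      nroot = if (root) 1L else 0L,
      events = if (length(event_times)) {
        list(func = "yem_bolus", time = event_times)
      } else NULL,
      rtol = rtol, atol = atol, maxsteps = 50000L)
  }
  use_root <- use_root && !length(event_times)
  out <- run(y0, seg_times, use_root)
  depletion <- NULL
  istate <- attr(out, "istate")
  if (use_root && !is.null(istate) && istate[1] == 3) {
    # stopped at the depletion root: restart from there without the root
    t_root <- out[nrow(out), 1]
    y_root <- out[nrow(out), 1 + seq_along(y0)]
    names(y_root) <- names(y0)
    depletion <- t_root
    remaining <- seg_times[seg_times > t_root + 1e-12]
    if (length(remaining)) {
      out2 <- run(y_root, c(t_root, remaining), FALSE)
      out <- rbind(out[out[, 1] < t_root - 1e-12, , drop = FALSE],
                   out2)
    }
  }
  list(out = out, depletion = depletion)
}

# core solver: integrates and returns the raw output matrix (time + the
# eight states) plus the event log; ye_simulate() dresses this up as a
# trajectory object and the estimation layer uses it directly
.ye_solve <- function(design, p, variant = "two_yef", times = NULL,
                      n_dense = 200, rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(design, "ye_design"))
  v <- ye_variant(variant)
  p <- apply_variant(p, v)
  validate_params(p)
  fl <- variant_flags(v)
  rc <- design$reactor
  feed <- design$feed
  t_end <- design$t_end
  V0 <- design$V0

  if (is.null(atol)) {
    atol <- c(1e-10, 1e-12, 1e-12, 1e-12, 1e-12, 1e-12, 1e-8, 1e-14)
  }

  # initial state; the basic variant carries no yeast-extract mass at all
  if (fl[["yefa"]]) {
    fr0 <- split_yeast_extract(design$YE0, p$value[["d_YE_AB"]],
                               p$value[["d_YE_BC"]])
  } else {
    fr0 <- c(YEFA = 0, YEFB = 0, YEFC = 0)
  }
  y0 <- c(X = design$X0, S = design$S0, A = design$A0,
          YEFA = unname(fr0[["YEFA"]]), YEFB = unname(fr0[["YEFB"]]),
          YEFC = unname(fr0[["YEFC"]]), DOTm = 0, V = V0)
  st0 <- structure(list(X = y0[["X"]], S = y0[["S"]], A = y0[["A"]],
                        YEFA = y0[["YEFA"]], YEFB = y0[["YEFB"]]),
                   class = "data.frame", row.names = c(NA_integer_, -1L))
  r0 <- ye_rates(st0, p, rc, v, carbon_literal = design$carbon_literal)
  y0[["DOTm"]] <- design$DOTm0 %||% r0$DOT

  # continuous-feed breakpoints (bolus pulses are events, not breakpoints)
  t_off <- feed_stop_time(feed, V0)
  brk <- c(0, t_end)
  if (feed$kind != "none" && feed$t_start < t_end) {
    brk <- c(brk, feed$t_start)
    if (is.finite(t_off) && t_off < t_end) brk <- c(brk, t_off)
    if (feed$kind == "stepwise") {
      st <- feed$steps$time
      brk <- c(brk, st[st > feed$t_start & st < min(t_off, t_end)])
    }
  }
  brk <- sort(unique(pmin(pmax(brk, 0), t_end)))

  boluses <- bolus_schedule(feed, c(0, min(t_end, t_off)), V0)
  boluses <- boluses[boluses$time < t_end - 1e-12, , drop = FALSE]

  if (is.null(times)) {
    phases <- cbind(head(brk, -1), tail(brk, -1))
    times <- unlist(lapply(seq_len(nrow(phases)), function(i) {
      seq(phases[i, 1], phases[i, 2], length.out = n_dense)
    }))
  }
  # breakpoints and pulse times must appear exactly; requested times that
  # fall within a hair of them are snapped away so the solver never sees
  # two output points separated by a rounding error
  special <- sort(unique(c(0, brk, boluses$time, t_end)))
  req <- sort(unique(pmin(pmax(times, 0), t_end)))
  req <- req[c(TRUE, diff(req) > 1e-9)]
  near <- findInterval(req, special)
  dist_lo <- ifelse(near >= 1, req - special[pmax(near, 1)], Inf)
  dist_hi <- ifelse(near < length(special),
                    special[pmin(near + 1, length(special))] - req, Inf)
  times <- sort(c(special, req[pmin(dist_lo, dist_hi) > 1e-9]))

  events <- data.frame(time = numeric(0), type = character(0))
  if (feed$kind != "none" && feed$t_start < t_end) {
    events <- rbind(events,
                    data.frame(time = feed$t_start, type = "feed_start"))
    if (is.finite(t_off) && t_off < t_end) {
      events <- rbind(events, data.frame(time = t_off, type = "feed_stop"))
    }
  }
  if (nrow(boluses)) {
    events <- rbind(events, data.frame(time = boluses$time, type = "bolus"))
  }

  rows <- list()
  y <- y0
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]
    b <- brk[i + 1]
    in_feed <- feed$kind != "none" && a >= feed$t_start - 1e-12 && a < t_off
    mode <- 0
    F_const <- 0
    F0 <- 0
    mu_set <- 0
    if (in_feed) {
      if (feed$kind == "exponential") {
        mode <- 1
        F0 <- feed$F0
        mu_set <- feed$mu_set
      } else if (feed$kind == "stepwise") {
        F_const <- feed_rate_at((a + b) / 2, feed, V0)
      } else if (feed$kind == "bolus") {
        # continuous F stays 0; the compiled event function needs the
        # exponential target to size each pulse
        F0 <- feed$F0
        mu_set <- feed$mu_set
      }
    }
    parms <- .ye_parms_vector(
      p, rc, fl, design$carbon_literal, design$evap_conc,
      feed_mode = mode, F_const = F_const, F0 = F0, mu_set = mu_set,
      t_ref = feed$t_start, Si = feed$Si, F_evap = feed$evaporation,
      S_thresh = design$S_deplete_tol,
      pulse_interval = feed$pulse_interval %||% 0,
      pulse_volume = feed$pulse_volume %||% -1)

    seg_times <- times[times >= a - 1e-12 & times <= b + 1e-12]
    seg_times <- sort(unique(c(a, seg_times, b)))
    seg_bol <- boluses[boluses$time >= a - 1e-12 &
                         boluses$time < b - 1e-12, , drop = FALSE]

    # a pulse falling exactly on the segment start is applied by hand; the
    # rest are compiled integrator events
    hit <- which(abs(seg_bol$time - a) < 1e-12)
    if (length(hit)) {
      vb <- seg_bol$volume[hit[1]]
      Vold <- y[["V"]]
      Vnew <- Vold + vb
      conc <- c("X", "S", "A", "YEFA", "YEFB", "YEFC")
      y[conc] <- y[conc] * Vold / Vnew
      y[["S"]] <- y[["S"]] + vb * feed$Si / Vnew
      y[["V"]] <- Vnew
      seg_bol <- seg_bol[-hit[1], , drop = FALSE]
    }

    use_root <- y[["S"]] > design$S_deplete_tol
    res <- .integrate_segment(y, seg_times, parms, rtol, atol, use_root,
                              event_times = seg_bol$time)
    out <- res$out
    if (any(!is.finite(out))) {
      stop(sprintf(
        "integration produced non-finite state near t = %.4g h", a),
        call. = FALSE)
    }
    if (!is.null(res$depletion)) {
      events <- rbind(events, data.frame(time = res$depletion,
                                         type = "glucose_depletion"))
    }
    last <- out[nrow(out), ]
    y <- last[1 + seq_along(y0)]
    names(y) <- names(y0)
    if (y[["V"]] <= 0) {
      stop(sprintf("broth volume became non-positive at t = %.4g h",
                   last[1]), call. = FALSE)
    }
    rows[[length(rows) + 1]] <- out
  }

  m <- do.call(rbind, rows)
  # segment boundaries appear twice (pre/post restart); keep the later row,
  # which carries any impulse applied at that instant
  m <- m[order(m[, 1]), , drop = FALSE]
  m <- m[!duplicated(round(m[, 1], 12), fromLast = TRUE), , drop = FALSE]
  colnames(m) <- c("time", .ye_state_names)

  list(m = m, events = events[order(events$time), , drop = FALSE],
       p = p, variant = v)
}

#' Simulate a cultivation
#'
#' Integrates the selected model variant over the design's horizon with the
#' stiff `lsodar` solver (compiled right-hand side). The dissolved-oxygen
#' tension is treated algebraically; only the probe reading `DOTm` is
#' integrated. Integration is restarted at every feed discontinuity and
#' bolus pulse, and a root function detects glucose depletion so the solver
#' never steps across the stiff depletion transient. Bolus pulses are
#' instantaneous perfectly mixed additions: `V <- V + v`, every
#' concentration is diluted by `V/(V+v)` and glucose additionally gains
#' `v * Si / (V+v)`.
#'
#' @param design a [ye_design()] object.
#' @param p a [ye_params()] object (variant constraints are applied
#'   internally).
#' @param variant model variant, see [ye_variant()].
#' @param times output times (h); default: `n_dense` points per operating
#'   phase plus all event times.
#' @param n_dense dense-output points per phase.
#' @param rtol,atol solver tolerances (atol may be a vector over the state
#'   `X, S, A, YEFA, YEFB, YEFC, DOTm, V`).
#' @return object of class `ye_trajectory`: list with `state` (data.frame:
#'   `time`, the eight states, and the derived total `YE`), `rates`
#'   (data.frame from [ye_rates()] at every output row), and `events`
#'   (data.frame `time`, `type`).
#' @examples
#' p <- ye_reference_params("two_yef", "batch")
#' d <- ye_design(OD0 = 0.3, S0 = 9, YE0 = 10, V0 = 0.01, t_end = 8)
#' traj <- ye_simulate(d, p, "two_yef")
#' @export
ye_simulate <- function(design, p, variant = "two_yef", times = NULL,
                        n_dense = 200, rtol = 1e-8, atol = NULL) {
  sol <- .ye_solve(design, p, variant, times = times, n_dense = n_dense,
                   rtol = rtol, atol = atol)
  state <- as.data.frame(sol$m)
  state$YE <- state$YEFA + state$YEFB + state$YEFC
  rates <- ye_rates(state, sol$p, design$reactor, sol$variant,
                    carbon_literal = design$carbon_literal)
  structure(list(state = state, rates = rates, events = sol$events,
                 design = design, params = sol$p, variant = sol$variant),
            class = "ye_trajectory")
}

#' @export
print.ye_trajectory <- function(x, ...) {
  s <- x$state
  cat(sprintf(
    "Simulated %s cultivation, %d output rows over %.3g h\n",
    x$variant, nrow(s), max(s$time)))
  cat(sprintf(
    "  final state: X = %.3g, S = %.3g, A = %.3g, YE = %.3g g/L, DOTm = %.3g %%, V = %.4g L\n",
    tail(s$X, 1), tail(s$S, 1), tail(s$A, 1), tail(s$YE, 1),
    tail(s$DOTm, 1), tail(s$V, 1)))
  if (nrow(x$events)) {
    cat("  events:", paste(sprintf("%s@%.3gh", x$events$type,
                                   x$events$time), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.ye_trajectory <- function(x, which = c("X", "S", "A", "DOTm"), ...) {
  s <- x$state
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  labs <- c(X = "biomass X [g/L]", S = "glucose S [g/L]",
            A = "acetate A [g/L]", DOTm = "DOTm [% sat.]",
            YE = "yeast extract [g/L]", V = "volume [L]")
  for (v in which) {
    plot(s$time, s[[v]], type = "l", xlab = "time [h]",
         ylab = labs[[v]] %||% v, ...)
  }
  invisible(x)
}

#' Interpolate model observables from a trajectory
#'
#' Returns the noise-free model outputs for the requested measurement
#' variables at the requested times by linear interpolation of the stored
#' trajectory. The dissolved-oxygen observable `DOT` is the probe reading
#' `DOTm`, which is what a sensor measures.
#'
#' @param traj a [ye_simulate()] trajectory.
#' @param times times (h) within the trajectory span; extrapolation is an
#'   error.
#' @param variables subset of `c("X", "S", "A", "DOT")`.
#' @return data.frame `time`, `variable`, `value` in long (tidy) form.
#' @export
ye_observe <- function(traj, times, variables = c("X", "S", "A", "DOT")) {
  stopifnot(inherits(traj, "ye_trajectory"))
  variables <- match.arg(variables, c("X", "S", "A", "DOT"),
                         several.ok = TRUE)
  s <- traj$state
  if (any(times < min(s$time) - 1e-9) || any(times > max(s$time) + 1e-9)) {
    stop("requested times outside the simulated span", call. = FALSE)
  }
  out <- lapply(variables, function(v) {
    col <- if (v == "DOT") "DOTm" else v
    data.frame(time = times, variable = v,
               value = approx(s$time, s[[col]], xout = times,
                              ties = "ordered")$y)
  })
  do.call(rbind, out)
}
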