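# Independent oracles: a literal transcription of the algebraic model
# equations and a fixed-step classical Runge-Kutta integrator built on it.
# Deliberately written as plain arithmetic on a named value vector, sharing
# no code with the package's rate layer.

# v: named numeric vector of parameter values; state: named numeric
oracle_rates <- function(state, v, rc, yefa_on = TRUE, yefb_on = TRUE,
                         carbon_literal = FALSE) {
  S <- max(state[["S"]], 0)
  A <- max(state[["A"]], 0)
  X <- max(state[["X"]], 0)
  YEFA <- max(state[["YEFA"]], 0)
  YEFB <- max(state[["YEFB"]], 0)

  q_S <- v[["q_S_max"]] * S / (S + v[["K_S"]])
  q_YEFA <- if (yefa_on) {
    v[["q_YEFA_max"]] * YEFA / (YEFA + v[["K_YEFA"]])
  } else 0
  q_YEFB <- if (yefb_on) {
    v[["q_YEFB_max"]] * YEFB / (YEFB + v[["K_YEFB"]])
  } else 0

  alpha <- v[["K_qSox"]] / (v[["K_qSox"]] + q_S)
  q_S_ox <- q_S / (1 + q_YEFA / v[["Ki_YEFA_qSox"]] +
                     q_YEFB / v[["Ki_YEFB_qSox"]]) * alpha
  q_S_of <- q_S - q_S_ox

  q_Ap <- q_S_of * v[["Y_AS"]]
  q_Ac <- v[["q_Ac_max"]] / (1 + S / v[["Ki_A_S"]]) * A / (A + v[["K_A"]])
  q_A <- q_Ap - q_Ac

  mu_S <- (q_S_ox - v[["q_m"]]) * v[["Y_XS_em"]]
  mu_YE <- q_YEFA * v[["Y_X_YEFA"]] + q_YEFB * v[["Y_X_YEFB"]]
  mu_A <- q_Ac * v[["Y_XA"]]
  mu <- mu_S + mu_YE + mu_A

  if (carbon_literal) {
    rA <- v[["C_A"]] / v[["C_S"]]
    rY <- v[["C_YE"]] / v[["C_S"]]
  } else {
    rA <- v[["C_X"]] / v[["C_A"]]
    rY <- v[["C_X"]] / v[["C_YE"]]
  }
  q_O <- v[["Y_OS"]] * (q_S_ox - mu_S * v[["C_X"]] / v[["C_S"]]) +
    v[["Y_OA"]] * (q_Ac - mu_A * rA) +
    v[["Y_O_YE"]] * ((q_YEFA + q_YEFB) - mu_YE * rY)
  if (q_O < 0) q_O <- 0

  DOT <- rc$DOT_star - q_O * X * rc$H / rc$kLa

  c(q_S = q_S, alpha = alpha, q_S_ox = q_S_ox, q_S_of = q_S_of,
    q_YEFA = q_YEFA, q_YEFB = q_YEFB, q_Ap = q_Ap, q_Ac = q_Ac, q_A = q_A,
    mu_S = mu_S, mu_YE = mu_YE, mu_A = mu_A, mu = mu, q_O = q_O,
    DOT = DOT)
}

# literal mass balances at a state (same conventions as the model: clamped
# rates, raw dilution)
oracle_rhs <- function(t, y, v, rc, feed, V0, yefa_on = TRUE,
                       yefb_on = TRUE) {
  r <- oracle_rates(y, v, rc, yefa_on, yefb_on)
  F <- feed_rate_at(t, feed, V0)
  D <- F / y[["V"]]
  c(
    X = -D * y[["X"]] + r[["mu"]] * y[["X"]],
    S = D * (feed$Si - y[["S"]]) - r[["q_S"]] * y[["X"]],
    A = -D * y[["A"]] + r[["q_A"]] * y[["X"]],
    YEFA = -D * y[["YEFA"]] - r[["q_YEFA"]] * y[["X"]],
    YEFB = -D * y[["YEFB"]] - r[["q_YEFB"]] * y[["X"]],
    YEFC = -D * y[["YEFC"]],
    DOTm = (r[["DOT"]] - y[["DOTm"]]) / rc$tau,
    V = F - feed$evaporation
  )
}

# classical RK4 with steps aligned to feed discontinuities and bolus
# pulses (impulse: V += v, concentrations diluted, glucose gains v*Si/V')
oracle_rk4 <- function(design, p, variant, dt_max = 1e-3) {
  p <- apply_variant(p, variant)
  fl <- variant_flags(variant)
  v <- p$value
  rc <- design$reactor
  feed <- design$feed
  if (fl[["yefa"]]) {
    fr0 <- split_yeast_extract(design$YE0, v[["d_YE_AB"]], v[["d_YE_BC"]])
  } else {
    fr0 <- c(YEFA = 0, YEFB = 0, YEFC = 0)
  }
  y <- c(X = design$X0, S = design$S0, A = design$A0,
         YEFA = unname(fr0[["YEFA"]]), YEFB = unname(fr0[["YEFB"]]),
         YEFC = unname(fr0[["YEFC"]]), DOTm = 0, V = design$V0)
  y[["DOTm"]] <- oracle_rates(y, v, rc, fl[["yefa"]],
                              fl[["yefb"]])[["DOT"]]
  bol <- bolus_schedule(feed, c(0, design$t_end), design$V0)
  knots <- c(0, design$t_end, bol$time)
  if (feed$kind != "none" && is.finite(feed$t_start)) {
    knots <- c(knots, feed$t_start,
               min(yegrowth:::feed_stop_time(feed, design$V0),
                   design$t_end))
    if (feed$kind == "stepwise") knots <- c(knots, feed$steps$time)
  }
  knots <- sort(unique(knots[knots >= 0 & knots <= design$t_end]))
  f <- function(t, y) oracle_rhs(t, y, v, rc, feed, design$V0,
                                 fl[["yefa"]], fl[["yefb"]])
  for (k in seq_len(length(knots) - 1)) {
    a <- knots[k]
    b <- knots[k + 1]
    hit <- which(abs(bol$time - a) < 1e-12)
    if (length(hit)) {
      vb <- bol$volume[hit[1]]
      Vo <- y[["V"]]
      Vn <- Vo + vb
      y[1:6] <- y[1:6] * Vo / Vn
      y[["S"]] <- y[["S"]] + vb * feed$Si / Vn
      y[["V"]] <- Vn
    }
    n <- max(1, ceiling((b - a) / dt_max))
    h <- (b - a) / n
    for (i in seq_len(n)) {
      tt <- a + (i - 1) * h
      k1 <- f(tt, y)
      k2 <- f(tt + h / 2, y + h / 2 * k1)
      k3 <- f(tt + h / 2, y + h / 2 * k2)
      k4 <- f(tt + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  y
}

# uniform random states over physiological ranges
random_states <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    X = runif(n, 0, 15), S = runif(n, 0, 20), A = runif(n, 0, 2),
    YEFA = runif(n, 0, 8), YEFB = runif(n, 0, 8), YEFC = runif(n, 0, 3)
  )
}

rel_err <- function(a, b, floor = 1e-12) {
  abs(a - b) / pmax(abs(b), floor)
}
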