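# Algebraic layer: specific rates of the yeast-extract growth model.
#
# All specific rates are in g per g biomass per hour; alpha is dimensionless,
# growth-rate terms are h^-1, DOT is in % of air saturation. Concentration
# arguments are clamped at zero before rate evaluation so that tiny negative
# integrator excursions cannot produce negative uptake.

#' Split an initial yeast-extract concentration into kinetic fractions
#'
#' At inoculation the total yeast extract `YE0` is distributed into a rapidly
#' consumed fraction A, a slowly consumed fraction B and an unconsumed
#' fraction C by the two distribution parameters:
#' `YEFA0 = YE0 * d_AB`, `YEFB0 = (YE0 - YEFA0) * d_BC`,
#' `YEFC0 = (YE0 - YEFA0) * (1 - d_BC)`.
#'
#' @param YE0 total yeast-extract concentration at t = 0 (g L^-1).
#' @param d_AB,d_BC distribution parameters in \[0, 1\].
#' @return named numeric vector `c(YEFA, YEFB, YEFC)`; the three fractions
#'   sum to `YE0` to machine precision.
#' @examples
#' split_yeast_extract(10, 0.27, 1)   # c(2.7, 7.3, 0)
#' @export
split_yeast_extract <- function(YE0, d_AB, d_BC) {
  if (any(YE0 < 0)) stop("YE0 must be >= 0", call. = FALSE)
  if (d_AB < 0 || d_AB > 1 || d_BC < 0 || d_BC > 1) {
    stop("distribution parameters must lie in [0, 1]", call. = FALSE)
  }
  yefa <- YE0 * d_AB
  rest <- YE0 - yefa
  c(YEFA = yefa, YEFB = rest * d_BC, YEFC = rest * (1 - d_BC))
}

#' Monod uptake kinetics
#'
#' `q = q_max * c / (c + K)`, the saturating uptake law used for glucose and
#' for both consumable yeast-extract fractions.
#'
#' @param conc substrate concentration (g L^-1); clamped at 0.
#' @param q_max maximal specific uptake rate (g g^-1 h^-1).
#' @param K affinity constant (g L^-1), strictly positive.
#' @return specific uptake rate, bounded by `q_max`.
#' @export
monod_rate <- function(conc, q_max, K) {
  if (any(K <= 0)) stop("Monod affinity K must be > 0", call. = FALSE)
  if (any(q_max < 0)) stop("q_max must be >= 0", call. = FALSE)
  cc <- pmax(conc, 0)
  q_max * cc / (cc + K)
}

#' Partition glucose uptake between the oxidative and overflow routes
#'
#' The oxidative capacity is limited by a saturation function
#' `alpha = K_qSox / (K_qSox + q_S)` and non-competitively inhibited by the
#' uptake of both yeast-extract fractions:
#' `q_S_ox = q_S * alpha / (1 + q_YEFA/Ki_YEFA_qSox + q_YEFB/Ki_YEFB_qSox)`.
#' Whatever glucose flux is not oxidised overflows: `q_S_of = q_S - q_S_ox`.
#'
#' @param q_S total specific glucose uptake (g g^-1 h^-1).
#' @param q_YEFA,q_YEFB specific uptake rates of the YE fractions.
#' @param p a [ye_params()] object (uses `K_qSox`, `Ki_YEFA_qSox`,
#'   `Ki_YEFB_qSox`).
#' @return list with `alpha`, `q_S_ox`, `q_S_of`; `q_S_ox + q_S_of == q_S`
#'   exactly and `q_S_of >= 0`.
#' @export
partition_substrate <- function(q_S, q_YEFA, q_YEFB, p) {
  v <- p$value
  if ((any(q_YEFA > 0) && v[["Ki_YEFA_qSox"]] <= 0) ||
      (any(q_YEFB > 0) && v[["Ki_YEFB_qSox"]] <= 0)) {
    stop("inhibition constants Ki_*_qSox must be > 0 when the corresponding ",
         "fraction is consumed", call. = FALSE)
  }
  alpha <- v[["K_qSox"]] / (v[["K_qSox"]] + q_S)
  inhib <- 1 + q_YEFA / v[["Ki_YEFA_qSox"]] + q_YEFB / v[["Ki_YEFB_qSox"]]
  q_S_ox <- q_S * alpha / inhib
  list(alpha = alpha, q_S_ox = q_S_ox, q_S_of = q_S - q_S_ox)
}

#' Acetate production and re-assimilation rates
#'
#' Acetate is produced from the overflow flux, `q_Ap = q_S_of * Y_AS`, and
#' consumed with Monod kinetics in acetate under glucose repression,
#' `q_Ac = q_Ac_max / (1 + S/Ki_A_S) * A / (A + K_A)`. The net specific rate
#' is `q_A = q_Ap - q_Ac` (positive: net production).
#'
#' @param S glucose concentration (g L^-1).
#' @param A acetate concentration (g L^-1).
#' @param q_S_of overflow glucose flux (g g^-1 h^-1).
#' @param p a [ye_params()] object.
#' @return list with `q_Ap`, `q_Ac`, `q_A`.
#' @export
acetate_rates <- function(S, A, q_S_of, p) {
  v <- p$value
  Ss <- pmax(S, 0)
  As <- pmax(A, 0)
  q_Ap <- q_S_of * v[["Y_AS"]]
  q_Ac <- v[["q_Ac_max"]] / (1 + Ss / v[["Ki_A_S"]]) * As / (As + v[["K_A"]])
  list(q_Ap = q_Ap, q_Ac = q_Ac, q_A = q_Ap - q_Ac)
}

#' Specific growth rate and its components
#'
#' Anabolism draws on three sources: oxidised glucose net of maintenance,
#' `mu_S = (q_S_ox - q_m) * Y_XS_em`; both yeast-extract fractions,
#' `mu_YE = q_YEFA * Y_X_YEFA + q_YEFB * Y_X_YEFB`; and re-assimilated
#' acetate, `mu_A = q_Ac * Y_XA`. The total growth rate is their sum and may
#' be negative when maintenance exceeds supply (starvation decay).
#'
#' @param q_S_ox oxidative glucose flux (g g^-1 h^-1).
#' @param q_YEFA,q_YEFB yeast-extract fraction uptake rates.
#' @param q_Ac acetate consumption rate.
#' @param p a [ye_params()] object.
#' @return list with `mu_S`, `mu_YE`, `mu_A`, `mu` (h^-1).
#' @export
growth_rate <- function(q_S_ox, q_YEFA, q_YEFB, q_Ac, p) {
  v <- p$value
  mu_S <- (q_S_ox - v[["q_m"]]) * v[["Y_XS_em"]]
  mu_YE <- q_YEFA * v[["Y_X_YEFA"]] + q_YEFB * v[["Y_X_YEFB"]]
  mu_A <- q_Ac * v[["Y_XA"]]
  list(mu_S = mu_S, mu_YE = mu_YE, mu_A = mu_A, mu = mu_S + mu_YE + mu_A)
}

#' Specific oxygen consumption rate
#'
#' Energy metabolism oxidises whatever carbon is taken up but not fixed into
#' biomass. Per co-substrate j (glucose, acetate, yeast extract) the oxygen
#' demand is `Y_Oj * (q_j - mu_j * r_j)` where `r_j` converts the anabolic
#' growth term back to co-substrate units. Two carbon-ratio conventions are
#' supported (see the methods vignette): the default carbon-balance reading
#' `r_j = C_X / C_j` and the alternate literal reading `r_j = C_j / C_S`
#' (with `r_S = C_X / C_S` in both). The result is clipped at zero from
#' below: respiration cannot run backwards.
#'
#' @param q_S_ox oxidative glucose flux; `mu_S`, `mu_YE`, `mu_A` growth
#'   components; `q_YEFA`, `q_YEFB`, `q_Ac` uptake rates (all g g^-1 h^-1).
#' @param mu_S,mu_YE,mu_A growth-rate components (h^-1).
#' @param q_YEFA,q_YEFB,q_Ac uptake rates.
#' @param p a [ye_params()] object.
#' @param carbon_literal use the alternate literal carbon-ratio reading.
#' @return specific oxygen uptake `q_O` (g g^-1 h^-1), non-negative.
#' @export
oxygen_rate <- function(q_S_ox, mu_S, mu_YE, mu_A, q_YEFA, q_YEFB, q_Ac, p,
                        carbon_literal = FALSE) {
  v <- p$value
  if (any(c(v[["C_X"]], v[["C_S"]], v[["C_A"]], v[["C_YE"]]) <= 0)) {
    stop("carbon contents must be > 0", call. = FALSE)
  }
  if (carbon_literal) {
    r_A <- v[["C_A"]] / v[["C_S"]]
    r_YE <- v[["C_YE"]] / v[["C_S"]]
  } else {
    r_A <- v[["C_X"]] / v[["C_A"]]
    r_YE <- v[["C_X"]] / v[["C_YE"]]
  }
  q_O <- v[["Y_OS"]] * (q_S_ox - mu_S * v[["C_X"]] / v[["C_S"]]) +
    v[["Y_OA"]] * (q_Ac - mu_A * r_A) +
    v[["Y_O_YE"]] * ((q_YEFA + q_YEFB) - mu_YE * r_YE)
  pmax(q_O, 0)
}

#' Algebraic dissolved-oxygen tension
#'
#' Assuming the gas-liquid transfer balance is fast relative to the biology,
#' the dissolved-oxygen tension follows algebraically from the oxygen uptake
#' rate: `DOT = DOT_star - q_O * X * H / kLa`. The value is deliberately not
#' floored at zero: a negative DOT flags an infeasible oxygen-transfer
#' configuration (demand exceeding the reactor's transfer capacity).
#'
#' @param q_O specific oxygen uptake (g g^-1 h^-1).
#' @param X biomass concentration (g L^-1).
#' @param rc a [ye_reactor()] object.
#' @return DOT in % of saturation.
#' @export
dot_algebraic <- function(q_O, X, rc) {
  if (rc$kLa <= 0) stop("kLa must be > 0", call. = FALSE)
  rc$DOT_star - q_O * pmax(X, 0) * rc$H / rc$kLa
}

#' Evaluate the full set of specific rates at one or more reactor states
#'
#' Evaluates every algebraic quantity of the model (glucose and
#' yeast-extract uptake, oxidative/overflow partitioning, acetate cycling,
#' growth-rate components, oxygen uptake and algebraic DOT) at the given
#' states, applying the variant reduction first (inactive fractions
#' contribute no uptake, growth or oxygen demand).
#'
#' @param state data.frame (or named vector for a single state) with columns
#'   `X`, `S`, `A`, `YEFA`, `YEFB` (g L^-1). Missing YE columns are treated
#'   as zero.
#' @param p a [ye_params()] object.
#' @param rc a [ye_reactor()] object.
#' @param variant model variant, see [ye_variant()].
#' @param carbon_literal passed to [oxygen_rate()].
#' @return data.frame with columns `q_S`, `alpha`, `q_S_ox`, `q_S_of`,
#'   `q_YEFA`, `q_YEFB`, `q_Ap`, `q_Ac`, `q_A`, `mu_S`, `mu_YE`, `mu_A`,
#'   `mu`, `q_O`, `DOT`, one row per state.
#' @examples
#' p <- ye_reference_params("two_yef", "fed_batch")
#' ye_rates(c(X = 1, S = 2, A = 0.3, YEFA = 1, YEFB = 4), p, ye_reactor())
#' @export
ye_rates <- function(state, p, rc = ye_reactor(), variant = "two_yef",
                     carbon_literal = FALSE) {
  if (!is.data.frame(state)) state <- as.data.frame(as.list(state))
  for (col in c("YEFA", "YEFB")) if (is.null(state[[col]])) state[[col]] <- 0
  fl <- variant_flags(variant)
  v <- p$value

  q_S <- monod_rate(state$S, v[["q_S_max"]], v[["K_S"]])
  q_YEFA <- if (fl[["yefa"]]) {
    monod_rate(state$YEFA, v[["q_YEFA_max"]], v[["K_YEFA"]])
  } else {
    rep(0, nrow(state))
  }
  q_YEFB <- if (fl[["yefb"]]) {
    monod_rate(state$YEFB, v[["q_YEFB_max"]], v[["K_YEFB"]])
  } else {
    rep(0, nrow(state))
  }
  part <- partition_substrate(q_S, q_YEFA, q_YEFB, p)
  ac <- acetate_rates(state$S, state$A, part$q_S_of, p)
  gr <- growth_rate(part$q_S_ox, q_YEFA, q_YEFB, ac$q_Ac, p)
  q_O <- oxygen_rate(part$q_S_ox, gr$mu_S, gr$mu_YE, gr$mu_A,
                     q_YEFA, q_YEFB, ac$q_Ac, p,
                     carbon_literal = carbon_literal)
  n <- length(q_S)
  structure(
    list(q_S = q_S, alpha = rep_len(part$alpha, n),
         q_S_ox = part$q_S_ox, q_S_of = part$q_S_of,
         q_YEFA = q_YEFA, q_YEFB = q_YEFB,
         q_Ap = ac$q_Ap, q_Ac = rep_len(ac$q_Ac, n),
         q_A = rep_len(ac$q_A, n),
         mu_S = gr$mu_S, mu_YE = rep_len(gr$mu_YE, n),
         mu_A = rep_len(gr$mu_A, n), mu = gr$mu,
         q_O = q_O, DOT = dot_algebraic(q_O, state$X, rc)),
    class = "data.frame", row.names = c(NA_integer_, -n))
}
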