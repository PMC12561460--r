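p_ref <- ye_reference_params("two_yef", "fed_batch")
rc <- ye_reactor()

test_that("initial yeast-extract split follows the distribution parameters", {
  expect_equal(split_yeast_extract(10, 0.27, 1),
               c(YEFA = 2.7, YEFB = 7.3, YEFC = 0))
  expect_equal(split_yeast_extract(0, 0.5, 0.5),
               c(YEFA = 0, YEFB = 0, YEFC = 0))
  expect_equal(split_yeast_extract(10, 0.43, 0.71),
               c(YEFA = 4.3, YEFB = 4.047, YEFC = 1.653))
  # mass closure across random splits
  set.seed(1)
  for (i in 1:50) {
    ye0 <- runif(1, 0, 30)
    fr <- split_yeast_extract(ye0, runif(1), runif(1))
    expect_equal(sum(fr), ye0, tolerance = 1e-14)
  }
  expect_error(split_yeast_extract(10, -0.1, 0.5), "\\[0, 1\\]")
  expect_error(split_yeast_extract(10, 0.5, 1.5), "\\[0, 1\\]")
  expect_error(split_yeast_extract(-1, 0.5, 0.5), ">= 0")
})

test_that("Monod kinetics saturate and honour the half-saturation identity", {
  expect_equal(monod_rate(0, 0.62, 0.05), 0)
  expect_equal(monod_rate(0.05, 0.62, 0.05), 0.31)
  expect_equal(monod_rate(1, 2, 1), 1)
  # monotone non-decreasing and bounded by q_max
  cc <- seq(0, 50, length.out = 200)
  q <- monod_rate(cc, 0.62, 0.05)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= 0.62))
  expect_error(monod_rate(1, 0.62, 0), "K must be > 0")
})

test_that("oxidative/overflow partitioning matches the inhibition law", {
  z <- partition_substrate(0, 0, 0, p_ref)
  expect_equal(z$alpha, 1)
  expect_equal(c(z$q_S_ox, z$q_S_of), c(0, 0))

  # with no YE uptake and q_S = K_qSox the split is exactly half/half
  k <- p_ref$value[["K_qSox"]]
  z <- partition_substrate(k, 0, 0, p_ref)
  expect_equal(z$alpha, 0.5)
  expect_equal(z$q_S_ox, k / 2)
  expect_equal(z$q_S_of, k / 2)

  # frozen hand evaluation at q_S = 0.5, K_qSox = 38.11
  z <- partition_substrate(0.5, 0, 0, p_ref)
  expect_equal(z$alpha, 0.98704999, tolerance = 1e-7)
  expect_equal(z$q_S_of, 0.00647501, tolerance = 1e-6)

  pz <- ye_params(values = list(Ki_YEFA_qSox = 0))
  expect_error(partition_substrate(0.5, 0.1, 0, pz), "Ki_")
})

test_that("acetate cycling: overflow production, glucose-repressed uptake", {
  a <- acetate_rates(S = 1, A = 0, q_S_of = 0.02, p_ref)
  expect_equal(a$q_Ac, 0)
  expect_equal(a$q_A, a$q_Ap)
  expect_equal(acetate_rates(1, 0.5, 0.01, p_ref)$q_Ap, 0.0067)
  # strong glucose repression kills acetate uptake
  hi <- acetate_rates(1e6, 1, 0, p_ref)
  expect_lt(hi$q_Ac, 1e-6)
})

test_that("growth decomposition including maintenance-driven decay", {
  g <- growth_rate(0, 0, 0, 0, ye_params(values = list(q_m = 0.04,
                                                       Y_XS_em = 0.43)))
  expect_equal(g$mu, -0.0172)
  g <- growth_rate(q_S_ox = 0.04, 0, 0, 0, p_ref)   # q_S_ox = q_m
  expect_equal(g$mu_S, 0)
  g <- growth_rate(q_S_ox = p_ref$value[["q_m"]], q_YEFA = 1,
                   q_YEFB = 0, q_Ac = 0, p_ref)
  expect_equal(g$mu, 0.56)
})

test_that("oxygen rate: single-term checks and clipping", {
  expect_equal(oxygen_rate(0, 0, 0, 0, 0, 0, 0, p_ref), 0)
  q <- oxygen_rate(q_S_ox = 0.1, mu_S = 0, mu_YE = 0, mu_A = 0,
                   q_YEFA = 0, q_YEFB = 0, q_Ac = 0, p_ref)
  expect_equal(q, 0.107)
  # anabolic carbon exceeding uptake would give negative respiration;
  # the rate is clipped instead
  q <- oxygen_rate(q_S_ox = 0.01, mu_S = 0.5, mu_YE = 0, mu_A = 0,
                   0, 0, 0, p_ref)
  expect_equal(q, 0)
  # the two carbon-ratio conventions differ for the acetate/YE terms only
  a1 <- oxygen_rate(0.1, 0.02, 0.03, 0.01, 0.05, 0.02, 0.04, p_ref)
  a2 <- oxygen_rate(0.1, 0.02, 0.03, 0.01, 0.05, 0.02, 0.04, p_ref,
                    carbon_literal = TRUE)
  expect_false(isTRUE(all.equal(a1, a2)))
})

test_that("algebraic DOT is linear in the oxygen demand and not floored", {
  expect_equal(dot_algebraic(0, 5, rc), rc$DOT_star)
  # exact exhaustion: q_O * X * H / kLa = DOT_star
  qx <- rc$DOT_star * rc$kLa / rc$H
  expect_equal(dot_algebraic(qx, 1, rc), 0)
  d1 <- rc$DOT_star - dot_algebraic(0.5, 1, rc)
  d2 <- rc$DOT_star - dot_algebraic(0.5, 2, rc)
  expect_equal(d2, 2 * d1)
  expect_lt(dot_algebraic(2 * qx, 1, rc), 0)
})

test_that("rate-set evaluation matches the literal-transcription oracle", {
  st <- random_states(1000, seed = 42)
  r <- ye_rates(st, p_ref, rc, "two_yef")
  for (i in c(1, 57, 500, 1000)) {
    o <- oracle_rates(as.list(st[i, ]), p_ref$value, rc)
    expect_true(all(rel_err(unlist(r[i, names(o)]), o) < 1e-10))
  }
  # full-suite check against the oracle, all rows
  om <- t(apply(st, 1, function(s) oracle_rates(as.list(s), p_ref$value,
                                                rc)))
  expect_true(max(rel_err(as.matrix(r[, colnames(om)]), om)) < 1e-10)
})

test_that("flux, acetate and growth closures hold to near machine precision", {
  st <- random_states(500, seed = 7)
  r <- ye_rates(st, p_ref, rc, "two_yef")
  expect_lt(max(abs(r$q_S - (r$q_S_ox + r$q_S_of))), 1e-12)
  expect_lt(max(abs(r$q_A - (r$q_Ap - r$q_Ac))), 1e-12)
  expect_lt(max(abs(r$mu - (r$mu_S + r$mu_YE + r$mu_A))), 1e-12)
  expect_true(all(r$alpha > 0 & r$alpha <= 1))
  expect_true(all(r$q_S_of >= -1e-15))
})

test_that("alpha decreases strictly with glucose uptake", {
  S <- seq(0.01, 20, length.out = 100)
  r <- ye_rates(data.frame(X = 1, S = S, A = 0, YEFA = 0, YEFB = 0),
                p_ref, rc, "two_yef")
  expect_true(all(diff(r$alpha) < 0))
})

test_that("variant reductions nest exactly at the rate level", {
  st <- random_states(100, seed = 3)
  # one-fraction == two-fraction when fraction B carries no mass
  st_b0 <- st
  st_b0$YEFB <- 0
  p1 <- ye_reference_params("one_yef", "batch")
  expect_identical(ye_rates(st_b0, p1, rc, "two_yef"),
                   ye_rates(st_b0, p1, rc, "one_yef"))
  # any variant == basic when no YE mass is present
  st_ye0 <- st
  st_ye0$YEFA <- st_ye0$YEFB <- st_ye0$YEFC <- 0
  expect_identical(ye_rates(st_ye0, p_ref, rc, "three_yef"),
                   ye_rates(st_ye0, p_ref, rc, "basic"))
  # basic zeroes YE uptake even on a YE-containing state
  rb <- ye_rates(st, p_ref, rc, "basic")
  expect_true(all(rb$q_YEFA == 0 & rb$q_YEFB == 0 & rb$mu_YE == 0))
})

test_that("state derivative honours dilution, fixed points and variants", {
  state <- c(X = 0, S = 0, A = 0, YEFA = 0, YEFB = 0, YEFC = 0,
             DOTm = 100, V = 0.01)
  der <- ye_rhs(state, p_ref, rc, "two_yef")
  expect_true(all(der == 0))

  # pure dilution: all uptake switched off, F/V = 0.1 1/h, Si = 0
  p0 <- ye_params(values = list(q_S_max = 0, q_YEFA_max = 0,
                                q_YEFB_max = 0, q_Ac_max = 0, q_m = 0),
                  lower = c(K_qSox = 1))
  state <- c(X = 2, S = 3, A = 0.5, YEFA = 1, YEFB = 2, YEFC = 0.3,
             DOTm = 100, V = 1)
  der <- ye_rhs(state, p0, rc, "three_yef", F = 0.1, Si = 0)
  for (nm in c("X", "S", "A", "YEFA", "YEFB", "YEFC")) {
    expect_equal(der[[nm]], -0.1 * state[[nm]])
  }
  expect_equal(der[["V"]], 0.1)

  # basic variant: YE derivatives identically zero on a YE-laden state
  der <- ye_rhs(state, p_ref, rc, "basic")
  expect_equal(unname(der[c("YEFA", "YEFB", "YEFC")]), c(0, 0, 0))
  expect_error(ye_rhs(replace(state, 8, -1), p_ref, rc), "V must be > 0")
})
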