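# small shared fixture: quick batch scenario and a 2-parameter fit
lean_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- ye_scenario("two_yef", feed = "none", t_end = 8,
                        n_atline = 10, dot_interval = 0.5)
      gen <- ye_generate(sc, seed = 17)
      cache <<- list(
        gen = gen,
        fit = ye_fit(gen$measurements, gen$design, "two_yef",
                     free = c("q_S_max", "Y_X_YEFA"),
                     control = list(maxit = 300)))
    }
    cache
  }
})

test_that("Latin hypercube samples are stratified per dimension", {
  lo <- c(a = 0, b = 10)
  hi <- c(a = 1, b = 20)
  m <- ye_lhs(lo, hi, n = 4, seed = 1)
  expect_equal(dim(m), c(4, 2))
  # brute force: each quartile bin of each dimension holds exactly one point
  for (j in 1:2) {
    u <- (m[, j] - lo[j]) / (hi[j] - lo[j])
    bins <- findInterval(u, seq(0, 1, 0.25), rightmost.closed = TRUE)
    expect_equal(sort(bins), 1:4)
  }
  # larger n, same property
  m2 <- ye_lhs(c(x = -3), c(x = 5), n = 32, seed = 2)
  bins <- findInterval((m2[, 1] + 3) / 8, seq(0, 1, length.out = 33),
                       rightmost.closed = TRUE)
  expect_equal(sort(bins), 1:32)

  # degenerate bounds give a constant column
  md <- ye_lhs(c(a = 2, b = 0), c(a = 2, b = 1), n = 5, seed = 3)
  expect_equal(md[, "a"], rep(2, 5))

  # determinism per seed; different seeds differ
  expect_identical(ye_lhs(lo, hi, 4, seed = 9), ye_lhs(lo, hi, 4, seed = 9))
  expect_false(identical(ye_lhs(lo, hi, 4, seed = 9),
                         ye_lhs(lo, hi, 4, seed = 10)))
  expect_error(ye_lhs(c(a = 0), c(a = Inf), 4, seed = 1), "finite")
})

test_that("IQR filter matches a brute-force quantile oracle", {
  x <- c(1, 2, 3, 100)
  # type-7 oracle by hand: sorted x, h = (n-1)p + 1, linear interpolation
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  q1 <- q7(x, 0.25)
  q3 <- q7(x, 0.75)
  oracle <- x >= q1 - 1.5 * (q3 - q1) & x <= q3 + 1.5 * (q3 - q1)
  expect_equal(iqr_keep(x), oracle)
  expect_equal(iqr_keep(x), c(TRUE, TRUE, TRUE, FALSE))

  set.seed(4)
  y <- rlnorm(200)
  q1 <- q7(y, 0.25)
  q3 <- q7(y, 0.75)
  expect_equal(iqr_keep(y),
               y >= q1 - 1.5 * (q3 - q1) & y <= q3 + 1.5 * (q3 - q1))

  expect_equal(iqr_keep(rep(2, 10)), rep(TRUE, 10))
  expect_warning(k <- iqr_keep(c(1, 2, 3)), "fewer than 4")
  expect_equal(k, rep(TRUE, 3))
})

test_that("Student-t confidence intervals behave as closed forms dictate", {
  ci <- ye_confint(matrix(rep(0.5, 6), ncol = 1,
                          dimnames = list(NULL, "p")))
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$mean, 0.5)

  ci2 <- ye_confint(matrix(c(0, 2), ncol = 1,
                           dimnames = list(NULL, "p")))
  expect_equal(ci2$mean, 1)
  expect_equal(ci2$sd, sqrt(2))
  expect_equal(ci2$upper - ci2$mean, qt(0.975, 1) * sqrt(2))

  # fixed dispersion: growing n shrinks the t quantile monotonically
  hw <- sapply(c(3, 5, 10, 30), function(n) qt(0.975, n - 1))
  expect_true(all(diff(hw) < 0))

  expect_warning(ci1 <- ye_confint(matrix(1, 1, 1,
                                          dimnames = list(NULL, "p"))),
                 "fewer than 2")
  expect_true(is.na(ci1$lower))
})

test_that("subset selection drops insensitive and duplicated parameters", {
  lf <- lean_fit()
  # K_YEFB has zero sensitivity here: fraction B is exhausted slowly and
  # the fit's data barely constrain it relative to the strong parameters;
  # the truly zero-sensitivity case is a parameter of an inactive pathway
  fit <- lf$fit
  # acetate pathway inert when no acetate forms: make a basic fit with
  # overflow disabled
  sc <- ye_scenario("basic",
                    params = ye_params(values = list(
                      q_S_max = 0.5, Y_AS = 0, q_Ac_max = 0,
                      K_qSox = 100, q_m = 0)),
                    feed = "none", t_end = 6, S0 = 5, YE0 = 0,
                    n_atline = 8, dot_interval = 0.5)
  gen <- ye_generate(sc, seed = 1)
  fitb <- ye_fit(gen$measurements, gen$design, "basic",
                 start = gen$truth, free = c("q_S_max", "Y_XS_em"),
                 control = list(maxit = 50))
  ss <- ye_subset_select(fitb, candidates = c("q_S_max", "Y_XS_em", "K_A"),
                         threshold = 10)
  # K_A only enters through acetate uptake, which is switched off
  expect_false("K_A" %in% ss$subset)
  expect_equal(ss$ranking$rms_sensitivity[ss$ranking$parameter == "K_A"], 0)

  # an exactly duplicated candidate is perfectly collinear: kept once
  ss2 <- ye_subset_select(fit, candidates = c("q_S_max", "q_S_max"),
                          threshold = 10)
  expect_equal(sum(ss2$subset == "q_S_max"), 1)
})

test_that("sensitivity ranking places the strong parameters first", {
  # on informative fed-batch data the glucose uptake and biomass yield
  # outrank the weakly identifiable acetate uptake capacity
  sc <- ye_scenario("two_yef", dot_interval = 5 / 60)
  gen <- ye_generate(sc, seed = 2)
  fit <- ye_fit(gen$measurements, gen$design, "two_yef",
                start = gen$truth, free = c("q_S_max", "Y_XS_em",
                                            "q_Ac_max"),
                control = list(maxit = 5))
  ss <- ye_subset_select(fit)
  r <- ss$ranking
  rank_of <- function(p) which(r$parameter == p)
  expect_lt(rank_of("q_S_max"), rank_of("q_Ac_max"))
  expect_lt(rank_of("Y_XS_em"), rank_of("q_Ac_max"))
})

test_that("Monte-Carlo uncertainty pipeline is reproducible and sane", {
  lf <- lean_fit()
  mc1 <- ye_mc(lf$fit, L = 4, seed = 21, control = list(maxit = 120))
  mc2 <- ye_mc(lf$fit, L = 4, seed = 21, control = list(maxit = 120))
  expect_identical(mc1$estimates, mc2$estimates)
  expect_identical(mc1$summary, mc2$summary)
  expect_false(identical(
    mc1$estimates, ye_mc(lf$fit, L = 4, seed = 22,
                         control = list(maxit = 120))$estimates))
  expect_true(all(mc1$kept %in% c(TRUE, FALSE)))
  expect_true(all(mc1$summary$sd >= 0, na.rm = TRUE))
  expect_equal(mc1$summary$parameter, c("q_S_max", "Y_X_YEFA"))
  expect_equal(nrow(mc1$estimates), 4)
  # confint method agrees with the summary table
  ci <- confint(mc1)
  expect_equal(unname(ci[, "lower"]), mc1$summary$lower)
})

test_that("near-noiseless bootstrap concentrates on the reference estimate", {
  # data with tiny sigma: every replicate is almost the reference dataset,
  # so the replicate estimates cluster tightly on theta_hat
  sc <- ye_scenario("two_yef", feed = "none", t_end = 8,
                    noise = c(X = 0, S = 0, A = 0, DOT = 0),
                    noise_floor = c(X = 1e-4, S = 1e-4, A = 1e-4,
                                    DOT = 1e-3),
                    n_atline = 10, dot_interval = 0.5)
  gen <- ye_generate(sc, seed = 8)
  fit <- ye_fit(gen$measurements, gen$design, "two_yef",
                start = gen$truth, free = c("q_S_max", "Y_X_YEFA"),
                control = list(maxit = 200))
  mc <- ye_mc(fit, L = 3, seed = 31, filter = FALSE,
              control = list(maxit = 400, reltol = 1e-9))
  for (j in colnames(mc$estimates)) {
    expect_equal(unname(mc$estimates[, j]),
                 rep(unname(coef(fit)[j]), 3), tolerance = 0.02)
  }
})
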