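test_that("measurement sets sort, validate and impute sigmas", {
  df <- data.frame(time = c(3, 1, 2, 1, 2),
                   variable = c("S", "X", "X", "S", "S"),
                   value = c(0.5, 1, 2, 8, 4))
  m <- ye_measurements(df)
  expect_s3_class(m, "ye_measurements")
  expect_equal(m$variable, c("X", "X", "S", "S", "S"))
  expect_true(all(diff(m$time[m$variable == "S"]) >= 0))
  # default sigma: 5% of the per-variable median, floored
  expect_equal(unique(m$sigma[m$variable == "X"]), 0.05 * 1.5)
  expect_equal(unique(m$sigma[m$variable == "S"]), 0.05 * 4)
  tiny <- ye_measurements(data.frame(time = 1:2, variable = "A",
                                     value = c(0.001, 0.003)))
  expect_equal(unique(tiny$sigma), 1e-3)  # floor engaged
  expect_equal(unname(attr(m, "weights")),
               c(10, 6, 4, 2))
  expect_error(ye_measurements(data.frame(time = 1, variable = "pH",
                                          value = 7)), "unknown")
})

test_that("measurements round-trip through tidy delimited text", {
  df <- data.frame(time = c(1, 2), variable = "X", value = c(1, 2),
                   sigma = c(0.1, 0.1))
  path <- tempfile(fileext = ".csv")
  write_measurements(ye_measurements(df), path)
  m <- read_measurements(path)
  expect_equal(m$value, c(1, 2))
  expect_equal(m$sigma, c(0.1, 0.1))
})

test_that("robust scaling centres by median and scales by IQR", {
  m <- ye_measurements(data.frame(time = 1:5, variable = "X",
                                  value = c(1, 2, 3, 4, 5)))
  sc <- robust_scale_fit(m)
  expect_equal(scale_values(sc, "X", c(1, 2, 3, 4, 5)),
               c(-1, -0.5, 0, 0.5, 1))
  # constant series: centred to 0 with the unit-scale fallback
  mc <- ye_measurements(data.frame(time = 1:4, variable = "S",
                                   value = rep(2.5, 4)))
  scc <- robust_scale_fit(mc)
  expect_equal(scale_values(scc, "S", rep(2.5, 4)), rep(0, 4))
  expect_equal(scc$S[["scale"]], 1)
  # affine: positive scaling preserves ordering
  v <- c(3, 1, 2)
  expect_equal(order(scale_values(sc, "X", 10 * v)), order(v))
  expect_error(
    robust_scale_fit(ye_measurements(data.frame(time = c(1, 2),
                                                variable = c("X", "S"),
                                                value = c(1, 1),
                                                sigma = 1))),
    "at least 2")
})

test_that("weighted cost terms follow the per-point weighting rule", {
  # single point, w = 10, sigma = 1, N = 1, scaled residual 0.5 -> 2.5
  meas <- ye_measurements(data.frame(time = 1, variable = "X", value = 1,
                                     sigma = 1))
  scaler <- structure(list(X = c(center = 0, scale = 2)),
                      class = "ye_scaler")
  h <- 2  # (2 - 1)/2 = 0.5 scaled residual
  r <- yegrowth:::.ye_weighted_residuals(h, meas, scaler,
                                         attr(meas, "weights"))
  expect_equal(sum(r^2), 2.5)

  # doubling the weight of one variable doubles its contribution
  meas2 <- ye_measurements(
    data.frame(time = c(1, 1), variable = c("X", "S"),
               value = c(1, 1), sigma = 1),
    weights = c(X = 20, S = 6, A = 4, DOT = 2))
  scaler2 <- structure(list(X = c(center = 0, scale = 2),
                            S = c(center = 0, scale = 2)),
                       class = "ye_scaler")
  r2 <- yegrowth:::.ye_weighted_residuals(c(2, 2), meas2, scaler2,
                                          attr(meas2, "weights"))
  expect_equal(r2[1]^2, 2 * 2.5)

  # unit changes on one variable cancel (sigma is native-unit, held fixed)
  scaler10 <- structure(list(X = c(center = 0, scale = 20)),
                        class = "ye_scaler")
  meas10 <- ye_measurements(data.frame(time = 1, variable = "X",
                                       value = 10, sigma = 1))
  r10 <- yegrowth:::.ye_weighted_residuals(20, meas10, scaler10,
                                           attr(meas10, "weights"))
  expect_equal(r10^2, r^2)
})

test_that("cost is ~zero when the simulation reproduces the data", {
  sc <- ye_scenario("two_yef", feed = "none", t_end = 8,
                    noise = c(X = 0, S = 0, A = 0, DOT = 0),
                    noise_floor = c(X = 0, S = 0, A = 0, DOT = 0),
                    n_atline = 8, dot_interval = 0.5)
  gen <- ye_generate(sc, seed = 1)
  cost <- ye_cost(numeric(0), gen$measurements, gen$design, "two_yef",
                  p = gen$truth)
  expect_lt(cost, 1e-6)
  # a wrong parameter set costs visibly more
  bad <- yegrowth:::ye_set_values(gen$truth, c(q_S_max = 0.3))
  expect_gt(ye_cost(c(q_S_max = 0.3), gen$measurements, gen$design,
                    "two_yef", p = gen$truth), 1)
})

test_that("fit keeps a truth-started optimum and recovers one parameter", {
  sc <- ye_scenario("two_yef", feed = "none", t_end = 8,
                    noise = c(X = 0, S = 0, A = 0, DOT = 0),
                    noise_floor = c(X = 0, S = 0, A = 0, DOT = 0),
                    n_atline = 10, dot_interval = 0.25)
  gen <- ye_generate(sc, seed = 2)

  # starting exactly at the generating truth: cost stays ~0, theta moves
  # at most marginally
  fit0 <- ye_fit(gen$measurements, gen$design, "two_yef",
                 start = gen$truth, free = c("q_S_max", "Y_X_YEFA"),
                 control = list(maxit = 200))
  expect_lt(fit0$value, 1e-4)
  expect_equal(unname(coef(fit0)),
               unname(gen$truth$value[c("q_S_max", "Y_X_YEFA")]),
               tolerance = 1e-3)

  # single-parameter recovery from a displaced start, noise-free
  start <- yegrowth:::ye_set_values(gen$truth, c(q_S_max = 0.62))
  fit1 <- ye_fit(gen$measurements, gen$design, "two_yef", start = start,
                 free = "q_S_max")
  expect_equal(unname(coef(fit1)), 0.55, tolerance = 0.01)
  expect_lt(fit1$value, fit1$initial_value)
  # row order of the data does not change the optimum
  shuf <- ye_measurements(as.data.frame(gen$measurements)[
    sample(nrow(gen$measurements)), ])
  fit2 <- ye_fit(shuf, gen$design, "two_yef", start = start,
                 free = "q_S_max")
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-8)
})

test_that("fit object supports the standard modelling verbs", {
  sc <- ye_scenario("two_yef", feed = "none", t_end = 8, n_atline = 8,
                    dot_interval = 0.5)
  gen <- ye_generate(sc, seed = 5)
  fit <- ye_fit(gen$measurements, gen$design, "two_yef",
                free = c("q_S_max", "Y_X_YEFA"),
                control = list(maxit = 150))
  expect_named(coef(fit), c("q_S_max", "Y_X_YEFA"))
  expect_equal(length(residuals(fit)), nrow(gen$measurements))
  expect_equal(fitted(fit) + residuals(fit), gen$measurements$value)
  pr <- predict(fit, times = c(1, 2), variables = "X")
  expect_equal(nrow(pr), 2)
  s <- summary(fit)
  expect_s3_class(s, "summary.ye_fit")
  expect_equal(sort(s$per_variable$variable), sort(unique(gen$measurements$variable)))
  expect_output(print(fit), "free parameter")
  reps <- simulate(fit, nsim = 2, seed = 9)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "ye_measurements")
  expect_false(all(reps[[1]]$value == reps[[2]]$value))
  # RMSE identities
  expect_equal(ye_rmse(fit), fit$rmse, tolerance = 1e-10)
  fake <- fit
  fake$residuals$weighted <- rep(0.3, nrow(fake$residuals))
  expect_equal(ye_rmse(fake), 0.3)
  fake$residuals$weighted <- rep(0, nrow(fake$residuals))
  expect_equal(ye_rmse(fake), 0)
})
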