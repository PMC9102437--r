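test_that("regulatory function covers both modes", {
  expect_equal(regulatory_f(0), 0)
  expect_equal(regulatory_f(50), 1)
  expect_equal(regulatory_f(2, "hill", n = 1, K = 2), 0.5)
  expect_equal(regulatory_f(0, "hill", n = 2, K = 5), 0)
  expect_error(regulatory_f(-1), ">= 0")
})

test_that("core death rate follows the Hill law", {
  expect_equal(death_rate_bax(0, dth), 0)
  expect_equal(death_rate_bax(200, dth), 0.43 / 2)  # half-maximum at K_BAX
  expect_equal(death_rate_bax(400, dth), 0.43 * 6.4e7 / 7.2e7,
               tolerance = 1e-9)
  expect_error(death_rate_bax(-5, dth), ">= 0")
  # monotone and bounded by gamma over random parameters
  set.seed(11)
  for (i in 1:20) {
    d <- death_parameters(gamma = stats::runif(1, 0.1, 2),
                          K_BAX = stats::runif(1, 10, 1000))
    x <- sort(stats::runif(20, 0, 2000))
    lam <- death_rate_bax(x, d)
    expect_true(all(diff(lam) >= 0))
    expect_true(all(lam <= d$gamma))
  }
})

test_that("extended death rate reduces to the core law and hits the printed values", {
  d0 <- death_parameters(kappa = 0, beta = 0)
  x <- c(0, 50, 200, 1000)
  expect_equal(death_rate_extended(x, condition(0, 0), d0),
               death_rate_bax(x, d0))
  # saturating BAX*: Medium and APRIL+ST2 at annotated parameters
  xs <- 1e7
  expect_equal(death_rate_extended(xs, condition(0, 0), dth),
               0.43 * (1 + 1.78), tolerance = 1e-6)
  expect_equal(death_rate_extended(xs, condition(1, 1), dth),
               0.43 * (1 + 1.78 / 11) / 3.65, tolerance = 1e-6)
})

test_that("extended death rate is bounded and ordered across conditions", {
  set.seed(12)
  for (i in 1:20) {
    d <- death_parameters(gamma = stats::runif(1, 0.1, 2),
                          K_BAX = stats::runif(1, 50, 500),
                          kappa = stats::runif(1, 0, 5),
                          alpha = stats::runif(1, 1, 20),
                          beta = stats::runif(1, 0.5, 5))
    x <- sort(stats::runif(10, 0, 2000))
    for (cc in default_conditions()) {
      lam <- death_rate_extended(x, cc, d)
      expect_true(all(diff(lam) >= 0))
      expect_true(all(lam >= 0 & lam <= d$gamma * (1 + d$kappa) + 1e-12))
    }
  }
  # at the annotated values and fixed BAX*
  x <- 300
  lam <- vapply(default_conditions(), function(cc)
    death_rate_extended(x, cc, dth), numeric(1))
  expect_gt(lam[["Medium"]], lam[["APRIL"]])
  expect_gt(lam[["Medium"]], lam[["ST2"]])
  expect_gt(lam[["ST2"]], lam[["APRIL+ST2"]])
})

test_that("alpha suppresses the caspase-12 term and beta the ST2 inhibition", {
  d_inf <- death_parameters(alpha = 1e12)
  expect_equal(death_rate_extended(200, condition(1, 0), d_inf),
               death_rate_bax(200, d_inf), tolerance = 1e-9)
  d_nob <- death_parameters(beta = 0)
  expect_equal(death_rate_extended(200, condition(0, 1), d_nob),
               death_rate_extended(200, condition(0, 0), d_nob))
})

test_that("survival matches the closed form for a constant death rate", {
  tt <- seq(0, 8, 0.5)
  # frozen at the Medium steady state, the trajectory is constant
  sc <- simulate_survival(kin, dth, condition(0, 0), times = tt,
                          mode = "trajectory")
  lam <- attr(simulate_survival(kin, dth, condition(0, 0), times = tt,
                                mode = "steady"), "lambda")
  expect_equal(sc$percent_live, 100 * exp(-lam * tt), tolerance = 1e-7)
  # gamma = 0: no death at all
  d0 <- death_parameters(gamma = 0)
  sc0 <- simulate_survival(kin, d0, condition(0, 0), times = tt)
  expect_equal(sc0$percent_live, rep(100, length(tt)))
})

test_that("survival curves are monotone non-increasing", {
  for (cc in default_conditions()) {
    sc <- simulate_survival(kin, dth, cc, times = seq(0, 10, 0.25))
    expect_true(all(diff(sc$percent_live) <= 1e-10))
    expect_equal(sc$percent_live[1], 100)
  }
})

test_that("half-life extraction is exact for exponentials and interpolates otherwise", {
  tt <- seq(0, 20, 0.5)
  expect_equal(model_half_life(tt, 100 * exp(-log(2) * tt)), 1.0,
               tolerance = 1e-9)
  expect_equal(model_half_life(tt, 100 * exp(-0.1 * tt)), log(2) / 0.1,
               tolerance = 1e-9)
  # piecewise-exponential curve (per-day rates): the 50% crossing falls
  # between grid points; a dense-grid brute-force reference must agree
  rates <- c(0.1, 0.2, 0.5, 0.4, 0.3)
  hazard <- function(t) {
    full <- cumsum(c(0, rates))
    k <- pmin(floor(t), length(rates) - 1)
    full[k + 1] + rates[k + 1] * (t - k)
  }
  coarse <- 0:5
  dense <- seq(0, 5, 0.0005)
  t_coarse <- model_half_life(coarse, 100 * exp(-hazard(coarse)))
  t_dense <- model_half_life(dense, 100 * exp(-hazard(dense)))
  expect_equal(t_coarse, t_dense, tolerance = 1e-6)
  expect_gt(t_coarse, 2); expect_lt(t_coarse, 3)
  expect_error(model_half_life(0:3, c(100, 99, 98, 97)), "50%")
})

test_that("trajectory and steady-state survival agree from steady initial state", {
  for (nm in c("Medium", "APRIL+ST2")) {
    cc <- default_conditions()[[nm]]
    ss <- steady_state(kin, cc)
    tt <- seq(0, 12, 0.25)
    tr_mode <- simulate_survival(kin, dth, cc, times = tt, init = ss,
                                 mode = "trajectory")
    st_mode <- simulate_survival(kin, dth, cc, times = tt, mode = "steady")
    expect_equal(tr_mode$percent_live, st_mode$percent_live,
                 tolerance = 1e-5)
  }
})

test_that("the annotated model reproduces the printed half-life contrast", {
  hl <- model_half_lives(kin, dth, mode = "trajectory")
  expect_lt(hl[["Medium"]], 1)
  expect_gt(hl[["APRIL+ST2"]], 6)
})
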