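test_that("exponential decay fit recovers noise-free rates exactly", {
  tt <- 0:5
  f <- fit_exponential_decay(tt, 100 * exp(-0.5 * tt))
  expect_equal(f$lambda, 0.5, tolerance = 1e-12)
  expect_equal(f$t_half, log(2) / 0.5, tolerance = 1e-12)
  f2 <- fit_exponential_decay(tt, 100 * exp(-0.5 * tt), method = "nls")
  expect_equal(f2$lambda, 0.5, tolerance = 1e-6)
  expect_error(fit_exponential_decay(tt, rep(100, 6)), "decay")
  expect_error(fit_exponential_decay(0, 100), "two")
})

test_that("half-life / decay-rate conversion is exactly inverse", {
  lam <- c(0.05, 0.5, 5)
  expect_equal(log(2) / (log(2) / lam), lam)
  f <- fit_exponential_decay(0:4, 100 * exp(-1.2 * (0:4)))
  expect_equal(log(2) / f$t_half, f$lambda)
})

test_that("noisy replicate fits recover the generating rate on average", {
  d <- make_survival_dataset(c(Medium = log(2) / 0.5), times = 0:5,
                             n_replicates = 12, noise_sd = 5, seed = 7)
  lams <- vapply(split(d, d$replicate), function(r)
    fit_exponential_decay(r$time_d, r$percent_live)$lambda, numeric(1))
  expect_equal(mean(lams), 0.5, tolerance = 0.05)
})

test_that("half-life summaries aggregate per condition", {
  est <- data.frame(condition = c("A", "A", "B", "B"),
                    t_half = c(1, 3, 2, 2))
  s <- summarize_half_lives(est)
  expect_equal(s$mean_t_half[s$condition == "A"], 2)
  expect_equal(s$sd_t_half[s$condition == "A"], sqrt(2))
  expect_equal(s$sd_t_half[s$condition == "B"], 0)
  expect_error(summarize_half_lives(data.frame(condition = "A", t_half = 1)),
               ">= 2")
})

test_that("synthetic survival groups recover their generating half-lives", {
  d <- make_survival_dataset(c(Medium = 0.7, `APRIL+ST2` = 6.5),
                             times = 0:5, n_replicates = 12, noise_sd = 5,
                             seed = 21)
  # fast decays reach the clipping floor within the sampling window, so
  # use the linear-space estimator (unbiased under additive noise)
  fits <- suppressWarnings(do.call(rbind, lapply(
    split(d, interaction(d$condition, d$replicate)),
    function(r) data.frame(condition = r$condition[1],
                           t_half = fit_exponential_decay(
                             r$time_d, r$percent_live,
                             method = "nls")$t_half))))
  s <- summarize_half_lives(fits)
  expect_equal(s$mean_t_half[s$condition == "Medium"], 0.7,
               tolerance = 0.1)
  expect_equal(s$mean_t_half[s$condition == "APRIL+ST2"], 6.5,
               tolerance = 0.1)
})

test_that("normalization to Medium fixes the Medium geometric mean at 1", {
  d <- data.frame(protein = "BIM",
                  condition = rep(c("Medium", "ST2"), each = 3),
                  replicate = rep(1:3, 2),
                  value = c(1, 10, 100, 20, 20, 20))
  n <- normalize_to_medium(d)
  med <- n$value[n$condition == "Medium"]
  expect_equal(exp(mean(log(med))), 1)
  expect_equal(n$value[n$condition == "ST2"], rep(2, 3))
  expect_error(normalize_to_medium(data.frame(protein = "x",
                                              condition = "ST2",
                                              replicate = 1, value = 1)),
               "Medium")
  d$value[1] <- -1
  expect_error(normalize_to_medium(d), "> 0")
})

test_that("protein ratios behave as ratios of condition means", {
  d <- data.frame(protein = rep(c("BIM", "MCL1"), each = 4),
                  condition = rep(rep(c("Medium", "ST2"), each = 2), 2),
                  replicate = rep(1:2, 4),
                  value = c(1, 2, 2, 4,   1, 2, 0.5, 1))
  n <- normalize_to_medium(d)
  r <- protein_ratio(n, "BIM", "MCL1", n_boot = 200, seed = 5)
  expect_equal(r$ratio[r$condition == "Medium"], 1)
  expect_equal(r$ratio[r$condition == "ST2"], 4)  # pro x2, anti /2
  # identical columns give ratio 1 everywhere
  d2 <- d; d2$value[d2$protein == "MCL1"] <- d2$value[d2$protein == "BIM"]
  r2 <- protein_ratio(normalize_to_medium(d2), "BIM", "MCL1",
                      n_boot = 200, seed = 5)
  expect_equal(r2$ratio, rep(1, 2))
})

test_that("bootstrap is deterministic under seed and calibrated", {
  x <- c(rep(4, 10))
  b <- bootstrap_uncertainty(x, n_boot = 500, seed = 3)
  expect_equal(unname(b), c(4, 0))
  set.seed(99)
  y <- stats::rnorm(30)
  b1 <- bootstrap_uncertainty(y, n_boot = 2000, seed = 42)
  b2 <- bootstrap_uncertainty(y, n_boot = 2000, seed = 42)
  expect_identical(b1, b2)
  # bootstrap sd of the mean approximates sigma / sqrt(n)
  expect_equal(b1[["sd"]], 1 / sqrt(30), tolerance = 0.15)
  expect_error(bootstrap_uncertainty(1), ">= 2")
  expect_error(bootstrap_uncertainty(1:5, n_boot = 10), "100")
})

test_that("condition comparison is the classic unpaired t-test", {
  ht <- compare_conditions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(ht$statistic), -3.674, tolerance = 1e-3)
  expect_equal(ht$p.value, 0.0214, tolerance = 1e-2)
  same <- c(1, 2, 3)
  ht0 <- compare_conditions(same, same)
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
  expect_error(compare_conditions(c(1, 1), c(1, 1)), "undefined")
  expect_error(compare_conditions(1, c(1, 2)), ">= 2")
})
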