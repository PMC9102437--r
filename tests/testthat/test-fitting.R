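test_that("chi-square cost matches its definition", {
  expect_equal(chi2(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_equal(chi2(0, 2, 2), 1)               # residual equal to sigma
  expect_equal(chi2(c(0, 0), c(1, 2), c(1, 1)), 5)
  expect_error(chi2(1, 1, 0), "> 0")
})

# shared noise-free datasets generated from the annotated model
hl_truth <- model_half_lives(kin, dth, mode = "steady")
pd_clean <- make_protein_dataset(kin, noise_cv = 1e-9, seed = 1)
sv_clean <- make_survival_dataset(hl_truth, times = 0:5,
                                  n_replicates = 2, noise_sd = 0, seed = 1)

test_that("fits are self-consistent at the generating truth", {
  f <- fit_joint(pd_clean, sv_clean, seed = 2)
  expect_true(f$converged)
  expect_lt(f$chi2, 1e-6)
  expect_equal(coef(f), truth_free, tolerance = 1e-3)
  expect_equal(f$k, 8)
  expect_equal(f$N, 9 + 24)   # 3 ratios x 3 conditions + 4 x 6 survival
})

test_that("noise-free recovery works from displaced starting values", {
  set.seed(31)
  st <- as.list(truth_free * runif(8, 0.6, 1.4))
  f <- fit_joint(pd_clean, sv_clean, start = st, seed = 2)
  expect_lt(f$chi2, 1e-4)
  expect_equal(coef(f), truth_free, tolerance = 0.01)
})

test_that("the optimiser never worsens the starting cost", {
  pd <- make_protein_dataset(kin, noise_cv = 0.1, seed = 8)
  sv <- make_survival_dataset(hl_truth, times = 0:5, n_replicates = 6,
                              noise_sd = 5, seed = 9)
  set.seed(32)
  st <- truth_free * runif(8, 0.5, 1.5)
  f <- fit_joint(pd, sv, start = as.list(st), seed = 2)
  # cost at the init: pin the optimiser to the starting point
  pinned <- fit_joint(pd, sv, start = as.list(st),
                      lower = st, upper = st, seed = 2)
  expect_lte(f$chi2, pinned$chi2 + 1e-8)
})

test_that("survival-only and protein-only wrappers target their parameters", {
  fs <- fit_survival_model(sv_clean, seed = 2)
  expect_named(coef(fs), c("gamma", "kappa", "beta"))
  expect_lt(fs$chi2, 1e-6)
  fp <- fit_protein_model(pd_clean, seed = 2)
  expect_named(coef(fp), c("a_BCL2", "s_MCL1", "s_BCL2", "s_BIM", "s_NOXA"))
  expect_lt(fp$chi2, 1e-4)
})

test_that("an inflated uncertainty removes a point's influence", {
  sv <- make_survival_dataset(hl_truth, times = 0:5, n_replicates = 6,
                              noise_sd = 3, seed = 13)
  f0 <- fit_survival_model(sv, seed = 2)
  # corrupt one late Medium point but give it an enormous spread: the
  # per-point sd becomes its sigma, so the estimates barely move
  sv2 <- sv
  idx <- which(sv2$condition == "Medium" & sv2$time_d == 4)
  # shift the mean by +30 while blowing up the replicate spread (the
  # fitted sigma), so the corrupted point carries almost no weight
  sv2$percent_live[idx] <- sv2$percent_live[idx] +
    rep(c(120, -60), length.out = length(idx))
  f2 <- fit_survival_model(sv2, seed = 2)
  expect_equal(coef(f2), coef(f0), tolerance = 0.05)
})

test_that("nested models cannot beat the full model on its own data", {
  sv <- make_survival_dataset(hl_truth, times = 0:5, n_replicates = 12,
                              noise_sd = 5, seed = 17)
  f_full <- fit_survival_model(sv, seed = 2)
  dp0 <- dth; dp0$kappa <- 0
  f_red <- fit_apoptosis_model(survival_data = sv, free = c("gamma", "beta"),
                               dp = dp0, seed = 2)
  expect_gt(f_red$chi2, f_full$chi2 - 1e-8)
  # and on full-model data the caspase-12 term is clearly needed
  expect_gt(f_red$chi2, 2 * f_full$chi2)
})

test_that("multistart is deterministic under a fixed seed", {
  sv <- make_survival_dataset(hl_truth, times = 0:5, n_replicates = 4,
                              noise_sd = 5, seed = 19)
  f1 <- fit_survival_model(sv, seed = 5, multistart = 5)
  f2 <- fit_survival_model(sv, seed = 5, multistart = 5)
  expect_identical(f1$chi2, f2$chi2)
  expect_identical(coef(f1), coef(f2))
})

test_that("well-identified parameters are recovered within 10% at study noise", {
  errs <- sapply(1:6, function(i) {
    pd <- make_protein_dataset(kin, noise_cv = 0.05, seed = 400 + i)
    sv <- make_survival_dataset(hl_truth, times = 0:5, n_replicates = 12,
                                noise_sd = 5, seed = 500 + i)
    f <- fit_joint(pd, sv, protein_target = "abundances", seed = 2)
    (coef(f) - truth_free) / truth_free
  })
  med <- apply(abs(errs), 1, stats::median)
  strong <- c("s_MCL1", "s_BCL2", "s_BIM", "s_NOXA", "gamma", "kappa",
              "beta")
  expect_true(all(med[strong] <= 0.10))
  # a_BCL2 is a small effect (11% shift) measured with 5% noise: it is
  # recovered without bias but at sampling-limited precision
  expect_lte(med["a_BCL2"], 0.35)
})

test_that("fit methods expose the usual modelling interface", {
  f <- fit_survival_model(sv_clean, seed = 2)
  expect_s3_class(f, "apoptosis_fit")
  expect_output(print(f), "chi2")
  s <- summary(f)
  expect_output(print(s), "half-lives")
  expect_length(residuals(f), f$N)
  hl <- predict(f, "half_life")
  expect_named(hl, names(default_conditions()))
  sc <- predict(f, "survival", times = 0:3)
  expect_true(all(c("time_d", "percent_live", "condition") %in% names(sc)))
  pr <- predict(f, "protein")
  expect_true(all(pr$normalized[pr$condition == "Medium"] == 1))
  # a perfect (chi2 = 0) fit yields the -Inf sentinel with a warning
  expect_equal(suppressWarnings(AIC(f)),
               suppressWarnings(aic(f$chi2, f$N, f$k)))
  sim <- simulate(f, nsim = 1, seed = 4)
  expect_named(sim[[1]], c("protein", "survival"))
})
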