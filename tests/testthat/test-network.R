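test_that("production rates apply the condition modifiers", {
  expect_equal(production_rate("BIM", condition(0, 0), kin)[["BIM"]], 0.86)
  expect_equal(production_rate("BIM", condition(0, 1), kin)[["BIM"]],
               0.86 * 0.49)
  expect_equal(production_rate("BCL2", condition(1, 0), kin)[["BCL2"]],
               0.86 * (1 + 0.11))
  # ST2 + APRIL compose multiplicatively on BCL-2
  expect_equal(production_rate("BCL2", condition(1, 1), kin)[["BCL2"]],
               0.86 * 0.53 * 1.11)
  # BAX production is condition-independent
  expect_equal(production_rate("BAX", condition(1, 1), kin)[["BAX"]], 0.86)
  expect_error(production_rate("BAK", condition(0, 0), kin), "BAK")
})

test_that("network derivative has the analytic limits", {
  p0 <- apoptosis_parameters(g_p0 = 0, k_plus = 0, k1 = 0, k2 = 0)
  zero <- setNames(rep(0, 11), apoptosim:::state_names(topo))
  expect_equal(unname(network_derivative(zero, condition(0, 0), p0)),
               rep(0, 11))
  # binding-free: production only at zero concentration
  pk0 <- apoptosis_parameters(k_plus = 0)
  d <- network_derivative(zero, condition(0, 0), pk0)
  expect_equal(d[["BIM"]], 0.86)
  # binding-free steady state g/d has zero derivative
  st <- zero
  st["BIM"] <- 0.86 / 5.94
  p1 <- apoptosis_parameters(k_plus = 0, k1 = 0, k2 = 0)
  expect_equal(network_derivative(st, condition(0, 0), p1)[["BIM"]], 0,
               tolerance = 1e-12)
  st["BIM"] <- -1
  expect_error(network_derivative(st, condition(0, 0), kin), "negative")
})

test_that("simulation relaxes to the decoupled g/d levels without binding", {
  p <- apoptosis_parameters(k_plus = 0, k1 = 0, k2 = 0)
  tr <- simulate_network(p, condition(0, 0), times = seq(0, 50, 1))
  final <- unclass(tr)[nrow(tr), ]
  expect_equal(final[["BIM"]], 0.86 / 5.94, tolerance = 1e-6)
  expect_equal(final[["BCL2"]], 0.86 / 0.86, tolerance = 1e-6)
  expect_equal(final[["BAXa"]], 0, tolerance = 1e-8)
  # production-free system from zero stays at zero
  p0 <- apoptosis_parameters(g_p0 = 0, k_plus = 0, k1 = 0, k2 = 0)
  tr0 <- simulate_network(p0, condition(0, 0), times = 0:5)
  expect_true(all(unclass(tr0) == 0))
})

test_that("steady state solves the decoupled system exactly", {
  p <- apoptosis_parameters(k_plus = 0, k1 = 0, k2 = 0)
  ss <- steady_state(p, condition(0, 0))
  expect_equal(ss[["BIM"]], 0.86 / 5.94, tolerance = 1e-9)
  expect_equal(ss[["NOXA"]], 0.86 / 32.8, tolerance = 1e-9)
  expect_equal(unname(ss[topo$complex]), rep(0, 5), tolerance = 1e-12)
  p0 <- apoptosis_parameters(g_p0 = 0)
  expect_equal(max(steady_state(p0, condition(0, 0))), 0, tolerance = 1e-9)
})

test_that("steady state agrees with long-time simulation over random draws", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_kinetics()
    cc <- random_condition()
    ss <- steady_state(p, cc)
    t_relax <- 10 * max(1 / c(p$d_MCL1, p$d_BCL2, p$d_BIM, p$d_NOXA, p$d_BAX))
    tr <- simulate_network(p, cc, times = c(0, t_relax, 2 * t_relax),
                           init = ss * exp(stats::runif(11, -0.2, 0.2)),
                           rtol = 1e-10, atol = 1e-12)
    final <- unclass(tr)[nrow(tr), ]
    expect_equal(as.numeric(final), as.numeric(ss), tolerance = 1e-6)
  }
})

test_that("trajectories stay non-negative for random parameters", {
  set.seed(202)
  for (i in 1:15) {
    p <- random_kinetics()
    tr <- simulate_network(p, random_condition(), times = seq(0, 5, 0.25))
    expect_true(all(unclass(tr) >= 0))
  }
})

test_that("ST2 contact lowers free BIM, NOXA and MCL-1 at steady state", {
  ss_med <- steady_state(kin, condition(0, 0))
  ss_st2 <- steady_state(kin, condition(0, 1))
  for (sp in c("BIM", "NOXA", "MCL1"))
    expect_lt(ss_st2[[sp]], ss_med[[sp]])
})

test_that("equilibrium solver matches the single-pair closed form", {
  one <- pc_topology(data.frame(anti = "MCL1", pro = "BIM", kd = "Kd_3"))
  Kd_nM <- 100
  Kd_uM <- Kd_nM / 1000
  eq <- equilibrium_complexes(c(MCL1 = Kd_uM, BIM = Kd_uM), one,
                              c(`MCL1:BIM` = Kd_nM))
  # (Kd - C)^2 = Kd C  =>  C = Kd (3 - sqrt(5)) / 2
  expect_equal(unname(eq$complexes), Kd_uM * (3 - sqrt(5)) / 2,
               tolerance = 1e-9)
})

test_that("equilibrium limits: absent species and vanishing affinity", {
  tot <- c(BIM = 0.2, NOXA = 0, BCL2 = 1, MCL1 = 0.05, BAX = 0.1,
           BAXa = 0.3)
  eq <- equilibrium_complexes(tot, topo, kin)
  expect_equal(unname(eq$complexes["MCL1:NOXA"]), 0)
  weak <- kin
  for (nm in c("Kd_3", "Kd_4", "Kd_5", "Kd_6", "Kd_7")) weak[[nm]] <- 1e12
  eq2 <- equilibrium_complexes(tot, topo, weak)
  expect_equal(eq2$free[names(tot)], tot, tolerance = 1e-6)
  expect_true(all(eq2$complexes < 1e-9))
})

test_that("equilibrium solver conserves mass over random instances", {
  set.seed(303)
  for (i in 1:25) {
    tot <- setNames(stats::runif(6, 0, 2), species_names <-
                      c("BIM", "NOXA", "BCL2", "MCL1", "BAX", "BAXa"))
    eq <- equilibrium_complexes(tot, topo, kin)
    for (s in names(tot)) {
      bound <- sum(eq$complexes[topo$anti == s]) +
        sum(eq$complexes[topo$pro == s])
      expect_equal(eq$free[[s]] + bound, tot[[s]], tolerance = 1e-9)
    }
  }
})

test_that("mass-action complexes approach the rapid-equilibrium oracle", {
  p <- annotated_parameters()$kinetic
  errs <- vapply(c(10, 1e3, 1e5), function(kp) {
    p$k_plus <- kp
    ss <- steady_state(p, condition(0, 0))
    tot <- apoptosim:::state_totals(ss, topo)
    eq <- equilibrium_complexes(tot, topo, p)
    max(abs(eq$complexes - ss[topo$complex]) /
          pmax(abs(eq$complexes), 1e-12))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("trajectory export uses the tidy long format", {
  tr <- simulate_network(kin, condition(1, 0), times = 0:3)
  df <- as.data.frame(tr)
  expect_named(df, c("time_d", "species", "concentration_uM", "condition"))
  expect_equal(unique(df$condition), "APRIL")
  expect_equal(nrow(df), 4 * 11)
})
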