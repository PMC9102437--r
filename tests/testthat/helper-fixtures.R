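# shared fixtures: the annotated parameter point and common settings
fx <- annotated_parameters()
kin <- fx$kinetic
dth <- fx$death
topo <- fx$topology

truth_free <- c(a_BCL2 = 0.11, s_MCL1 = 0.37, s_BCL2 = 0.53,
                s_BIM = 0.49, s_NOXA = 0.40,
                gamma = 0.43, kappa = 1.78, beta = 2.65)

# random positive rescaling of the kinetic constants around the annotated
# point (log-uniform within the given fold range)
random_kinetics <- function(fold = exp(1)) {
  p <- annotated_parameters()$kinetic
  for (nm in c("g_p0", "d_MCL1", "d_BCL2", "d_BIM", "d_NOXA", "d_BAX",
               "Kd_3", "Kd_4", "Kd_5", "Kd_6", "Kd_7", "k1", "k2",
               "k_plus"))
    p[[nm]] <- p[[nm]] * exp(stats::runif(1, -log(fold), log(fold)))
  p
}

random_condition <- function() {
  condition(sample(0:1, 1), sample(0:1, 1))
}
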