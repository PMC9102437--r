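#' Kinetic parameters of the BCL-2 family network
#'
#' Constructs the set of production, decay, binding and BAX-activation
#' constants that define the mass-action network model. Defaults are the
#' literature-annotated best-fit values shipped with the package (see
#' [annotated_parameters()]).
#'
#' @details
#' Units follow the annotated parameter table: production rates in uM/d,
#' decay rates in 1/d, dissociation constants `Kd_3`..`Kd_7` in nM. The
#' printed association rate `k_plus` and the BAX (de)activation rates
#' `k1`, `k2` require a dimensional convention: `k_plus` is bimolecular and
#' is interpreted on the nM scale of the dissociation constants
#' (nM^-1 d^-1, i.e. multiplied by 1000 when applied to uM concentrations),
#' while `k1` and `k2` are first-order rates in 1/d (normalised by a 1 uM
#' reference concentration). This convention makes competitive binding
#' effective at the annotated point; see the package vignette for the
#' full rationale.
#'
#' Condition modifiers: when ST2 contact is present, production of MCL-1,
#' BCL-2, BIM and NOXA is multiplied by the factors `s_MCL1`, `s_BCL2`,
#' `s_BIM`, `s_NOXA` (all < 1: measured downregulation); when APRIL is
#' present, BCL-2 production is multiplied by `(1 + a_BCL2)` (upregulation).
#' BAX production is condition-independent.
#'
#' @param g_p0 basal production rate, uM/d, applied to all five proteins.
#' @param d_MCL1,d_BCL2,d_BIM,d_NOXA,d_BAX first-order decay rates, 1/d.
#' @param Kd_3,Kd_4,Kd_5,Kd_6,Kd_7 dissociation constants, nM (see
#'   [default_topology()] for the pair assignment).
#' @param k_plus complex association rate, nM^-1 d^-1.
#' @param k1 BAX activation rate, 1/d.
#' @param k2 BAX* deactivation rate, 1/d.
#' @param a_BCL2 APRIL effect on BCL-2 production (dimensionless, >= 0).
#' @param s_MCL1,s_BCL2,s_BIM,s_NOXA ST2 effects on production
#'   (dimensionless, in (0, 1.5]).
#' @return An object of class `"apoptosis_parameters"` (a named list).
#' @seealso [death_parameters()], [annotated_parameters()],
#'   [default_topology()]
#' @examples
#' p <- apoptosis_parameters()
#' p$g_p0
#' @export
apoptosis_parameters <- function(g_p0 = 0.86,
                                 d_MCL1 = 16.4, d_BCL2 = 0.86, d_BIM = 5.94,
                                 d_NOXA = 32.8, d_BAX = 1.38,
                                 Kd_3 = 2.0, Kd_4 = 22.0, Kd_5 = 40.0,
                                 Kd_6 = 2.5, Kd_7 = 68.0,
                                 k_plus = 0.17, k1 = 43.2, k2 = 8.64,
                                 a_BCL2 = 0.11,
                                 s_MCL1 = 0.37, s_BCL2 = 0.53,
                                 s_BIM = 0.49, s_NOXA = 0.40) {
  p <- list(g_p0 = g_p0,
            d_MCL1 = d_MCL1, d_BCL2 = d_BCL2, d_BIM = d_BIM,
            d_NOXA = d_NOXA, d_BAX = d_BAX,
            Kd_3 = Kd_3, Kd_4 = Kd_4, Kd_5 = Kd_5, Kd_6 = Kd_6, Kd_7 = Kd_7,
            k_plus = k_plus, k1 = k1, k2 = k2,
            a_BCL2 = a_BCL2,
            s_MCL1 = s_MCL1, s_BCL2 = s_BCL2, s_BIM = s_BIM, s_NOXA = s_NOXA)
  validate_apoptosis_parameters(p)
  structure(p, class = "apoptosis_parameters")
}

validate_apoptosis_parameters <- function(p) {
  problems <- character(0)
  pos <- c("d_MCL1", "d_BCL2", "d_BIM", "d_NOXA", "d_BAX",
           "Kd_3", "Kd_4", "Kd_5", "Kd_6", "Kd_7")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      problems <- c(problems, sprintf("'%s' must be a single finite positive number", nm))
  }
  # zero is a legitimate degenerate limit (production-free, binding-free)
  for (nm in c("g_p0", "k_plus", "k1", "k2")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      problems <- c(problems, sprintf("'%s' must be a single finite non-negative number", nm))
  }
  if (!is.numeric(p$a_BCL2) || p$a_BCL2 < 0)
    problems <- c(problems, "'a_BCL2' must be >= 0")
  for (nm in c("s_MCL1", "s_BCL2", "s_BIM", "s_NOXA")) {
    v <- p[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1.5)
      problems <- c(problems, sprintf("'%s' must lie in (0, 1.5]", nm))
  }
  if (length(problems))
    stop("invalid kinetic parameters:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(p)
}

#' @export
print.apoptosis_parameters <- function(x, ...) {
  cat("BCL-2 family network kinetic parameters\n")
  cat(sprintf("  basal production g_p0 = %.3g uM/d\n", x$g_p0))
  cat(sprintf("  decay rates (1/d): MCL-1 %.3g, BCL-2 %.3g, BIM %.3g, NOXA %.3g, BAX %.3g\n",
              x$d_MCL1, x$d_BCL2, x$d_BIM, x$d_NOXA, x$d_BAX))
  cat(sprintf("  Kd (nM): %s\n",
              paste(sprintf("Kd_%d=%.3g", 3:7,
                            unlist(x[c("Kd_3", "Kd_4", "Kd_5", "Kd_6", "Kd_7")])),
                    collapse = ", ")))
  cat(sprintf("  k_plus = %.3g nM^-1 d^-1, k1 = %.3g /d, k2 = %.3g /d\n",
              x$k_plus, x$k1, x$k2))
  cat(sprintf("  APRIL effect a_BCL2 = %.3g; ST2 effects s: MCL-1 %.3g, BCL-2 %.3g, BIM %.3g, NOXA %.3g\n",
              x$a_BCL2, x$s_MCL1, x$s_BCL2, x$s_BIM, x$s_NOXA))
  invisible(x)
}

#' Death-rate parameters
#'
#' Parameters of the population death-rate law. The core law is a Hill
#' function of activated BAX (BAX*),
#' \deqn{\lambda = \gamma \frac{x^3}{K_{BAX}^3 + x^3},}
#' and the extended law adds algebraic caspase regulation,
#' \deqn{\lambda = \gamma\left(H + \frac{\kappa}{1 + \alpha f(APRIL)}\right)
#'       \frac{1}{1 + \beta f(ST2)},}
#' where \eqn{H} is the Hill term, \eqn{\kappa} the relative caspase-12
#' effect (inhibited by APRIL with strength \eqn{\alpha}) and \eqn{\beta}
#' the maximal inhibitory effect of ST2 on caspase 3/7.
#'
#' @param gamma maximal BAX-driven death rate, 1/d.
#' @param K_BAX half-saturation constant of the Hill term, nM.
#' @param hill_n Hill exponent (default 3).
#' @param kappa relative caspase-12 effect (dimensionless, >= 0).
#' @param alpha APRIL inhibition strength on caspase 12 (>= 0).
#' @param beta ST2 inhibition strength on caspase 3/7 (>= 0).
#' @param fmode regulatory-function mode, `"boolean"` (indicator of
#'   stimulus presence) or `"hill"` (graded response, see [regulatory_f()]).
#' @param f_n,f_K Hill exponent and half-saturation for `fmode = "hill"`.
#' @return An object of class `"death_parameters"`.
#' @seealso [death_rate_bax()], [death_rate_extended()]
#' @export
death_parameters <- function(gamma = 0.43, K_BAX = 200, hill_n = 3,
                             kappa = 1.78, alpha = 10, beta = 2.65,
                             fmode = c("boolean", "hill"),
                             f_n = 1, f_K = 1) {
  fmode <- match.arg(fmode)
  dp <- list(gamma = gamma, K_BAX = K_BAX, hill_n = hill_n,
             kappa = kappa, alpha = alpha, beta = beta,
             fmode = fmode, f_n = f_n, f_K = f_K)
  validate_death_parameters(dp)
  structure(dp, class = "death_parameters")
}

validate_death_parameters <- function(dp) {
  problems <- character(0)
  if (!is.numeric(dp$gamma) || dp$gamma < 0)
    problems <- c(problems, "'gamma' must be >= 0")
  if (!is.numeric(dp$K_BAX) || dp$K_BAX <= 0)
    problems <- c(problems, "'K_BAX' must be > 0")
  if (!is.numeric(dp$hill_n) || dp$hill_n <= 0)
    problems <- c(problems, "'hill_n' must be > 0")
  for (nm in c("kappa", "alpha", "beta")) {
    if (!is.numeric(dp[[nm]]) || dp[[nm]] < 0)
      problems <- c(problems, sprintf("'%s' must be >= 0", nm))
  }
  if (length(problems))
    stop("invalid death parameters:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(dp)
}

#' @export
print.death_parameters <- function(x, ...) {
  cat("Death-rate parameters\n")
  cat(sprintf("  gamma = %.3g /d, K_BAX = %.3g nM, Hill n = %g\n",
              x$gamma, x$K_BAX, x$hill_n))
  cat(sprintf("  kappa = %.3g, alpha = %.3g, beta = %.3g; regulation: %s\n",
              x$kappa, x$alpha, x$beta, x$fmode))
  invisible(x)
}

#' Stimulation condition
#'
#' A culture condition given by the presence (or, in graded `"hill"`
#' regulation mode, the level) of the two survival inputs: soluble APRIL
#' and contact to ST2 stromal cells.
#'
#' @param april,st2 0/1 presence flags under Boolean regulation, or
#'   non-negative input levels under Hill-type regulation.
#' @return An object of class `"pc_condition"`.
#' @examples
#' condition(april = 1, st2 = 1)   # APRIL + ST2 co-culture
#' condition_name(condition(0, 0)) # "Medium"
#' @export
condition <- function(april = 0, st2 = 0) {
  if (!is.numeric(april) || length(april) != 1L || april < 0 ||
      !is.numeric(st2) || length(st2) != 1L || st2 < 0)
    stop("'april' and 'st2' must be single non-negative numbers", call. = FALSE)
  structure(list(april = april, st2 = st2), class = "pc_condition")
}

#' @rdname condition
#' @param cond a `pc_condition`.
#' @export
condition_name <- function(cond) {
  stopifnot(inherits(cond, "pc_condition"))
  if (cond$april > 0 && cond$st2 > 0) "APRIL+ST2"
  else if (cond$april > 0) "APRIL"
  else if (cond$st2 > 0) "ST2"
  else "Medium"
}

#' @rdname condition
#' @description `default_conditions()` returns the four study conditions
#'   Medium, APRIL, ST2, APRIL+ST2 as a named list.
#' @export
default_conditions <- function() {
  list(Medium       = condition(0, 0),
       APRIL        = condition(1, 0),
       ST2          = condition(0, 1),
       `APRIL+ST2`  = condition(1, 1))
}

#' @export
print.pc_condition <- function(x, ...) {
  cat(sprintf("condition: %s (APRIL = %g, ST2 = %g)\n",
              condition_name(x), x$april, x$st2))
  invisible(x)
}

#' Annotated best-fit parameter set
#'
#' Loads the packaged parameter fixture: the literature-annotated kinetic
#' constants and the best-fit production/death parameters of the full
#' model, together with the default binding topology.
#'
#' @return A list with elements `kinetic` ([apoptosis_parameters()]),
#'   `death` ([death_parameters()]) and `topology` ([default_topology()]).
#' @examples
#' fx <- annotated_parameters()
#' fx$death$gamma
#' @export
annotated_parameters <- function() {
  path <- system.file("extdata", "annotated_parameters.json",
                      package = "apoptosim", mustWork = TRUE)
  read_parameters(path)
}
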