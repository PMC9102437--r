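#' Fold-change perturbation of a model parameter
#'
#' Multiplies (`direction = "up"`) or divides (`"down"`) a named kinetic
#' or death parameter by a fold of 2, 5 or 10, emulating partial
#' overexpression or knockdown.
#'
#' @param params an [apoptosis_parameters()] set.
#' @param dp a [death_parameters()] set.
#' @param name parameter to perturb (any kinetic or death parameter
#'   name, e.g. `"g_p0"`, `"gamma"`, `"kappa"`).
#' @param fold one of 2, 5, 10.
#' @param direction `"up"` or `"down"`.
#' @return list with perturbed `params` and `dp`.
#' @examples
#' fx <- annotated_parameters()
#' perturb_parameter(fx$kinetic, fx$death, "gamma", 2, "up")$dp$gamma
#' @export
perturb_parameter <- function(params, dp, name, fold,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!fold %in% c(2, 5, 10))
    stop("'fold' must be one of 2, 5, 10", call. = FALSE)
  valid <- c(kinetic_par_names(), death_par_names())
  if (!name %in% valid)
    stop("unknown parameter '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  f <- if (direction == "up") fold else 1 / fold
  old <- current_values(params, dp, name)
  apply_free(params, dp, stats::setNames(list(unname(old) * f), name))
}

#' Log2 effect size between baseline and perturbed outcomes
#'
#' @param baseline,perturbed positive quantities (e.g. half-lives in
#'   days, or steady-state activated-BAX levels).
#' @return `log2(perturbed / baseline)`.
#' @examples
#' effect_size(2, 8)  # 2
#' @export
effect_size <- function(baseline, perturbed) {
  if (any(baseline <= 0) || any(perturbed <= 0))
    stop("half-lives / levels must be > 0", call. = FALSE)
  log2(perturbed / baseline)
}

# perturbation of a signaling branch: a joint scaling of every effect
# the pathway drives. NF-kB carries the APRIL inputs (a_BCL2, alpha);
# PI3K carries the ST2 inputs (the s_* production effects, scaled on the
# log scale so they remain in (0, 1], and beta).
perturb_branch <- function(params, dp, name, fold, direction) {
  f <- if (direction == "up") fold else 1 / fold
  if (name == "NFkB") {
    params$a_BCL2 <- params$a_BCL2 * f
    dp$alpha <- dp$alpha * f
  } else if (name == "PI3K") {
    for (s in c("s_MCL1", "s_BCL2", "s_BIM", "s_NOXA"))
      params[[s]] <- params[[s]]^f
    dp$beta <- dp$beta * f
  } else stop("unknown branch: ", name, call. = FALSE)
  list(params = params, dp = dp)
}

#' In-silico knockdown / overexpression scan
#'
#' For each target parameter, fold and direction, perturbs the model,
#' recomputes the population half-life and the steady-state activated
#' BAX level under a reference condition, and reports log2 fold changes
#' relative to the unperturbed model. The signaling-level targets
#' `"NFkB"` and `"PI3K"` perturb all APRIL-driven effects (`a_BCL2`,
#' `alpha`) and all ST2-driven effects (`s_*` on the log scale, `beta`)
#' jointly.
#'
#' @param params,dp,topo baseline model (defaults: annotated values).
#' @param targets parameter names and/or `"NFkB"`, `"PI3K"`.
#' @param folds subset of `c(2, 5, 10)`.
#' @param directions subset of `c("up", "down")`.
#' @param cond reference condition (default APRIL+ST2, the full-survival
#'   culture).
#' @return data.frame of class `"perturbation_scan"` with columns
#'   `parameter`, `fold`, `direction`, `log2fc_half_life`,
#'   `log2fc_bax_star`; solver failures yield `NA` rows and the scan
#'   continues.
#' @examples
#' fx <- annotated_parameters()
#' scan <- perturbation_scan(fx$kinetic, fx$death,
#'                           targets = c("gamma", "beta"), folds = 2)
#' scan
#' @export
perturbation_scan <- function(params = annotated_parameters()$kinetic,
                              dp = annotated_parameters()$death,
                              topo = default_topology(),
                              targets = c("g_p0", "gamma", "kappa", "beta",
                                          "NFkB", "PI3K"),
                              folds = c(2, 5, 10),
                              directions = c("up", "down"),
                              cond = condition(1, 1)) {
  if (!all(folds %in% c(2, 5, 10)))
    stop("'folds' must be a subset of {2, 5, 10}", call. = FALSE)
  outcome <- function(p, d) {
    ss <- steady_state(p, cond, topo, fmode = d$fmode,
                       f_n = d$f_n, f_K = d$f_K)
    bax <- ss[["BAXa"]] * 1000
    lam <- death_rate_extended(bax, cond, d)
    c(t_half = log(2) / lam, bax_star = bax)
  }
  base <- outcome(params, dp)
  grid <- expand.grid(parameter = targets, fold = folds,
                      direction = directions, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pert <- tryCatch({
      nm <- grid$parameter[i]
      mod <- if (nm %in% c("NFkB", "PI3K"))
        perturb_branch(params, dp, nm, grid$fold[i], grid$direction[i])
      else
        perturb_parameter(params, dp, nm, grid$fold[i], grid$direction[i])
      outcome(mod$params, mod$dp)
    }, error = function(e) c(t_half = NA_real_, bax_star = NA_real_))
    data.frame(parameter = grid$parameter[i], fold = grid$fold[i],
               direction = grid$direction[i],
               log2fc_half_life = if (is.na(pert["t_half"])) NA_real_
                 else effect_size(base[["t_half"]], pert[["t_half"]]),
               log2fc_bax_star = if (is.na(pert["bax_star"])) NA_real_
                 else effect_size(base[["bax_star"]], pert[["bax_star"]]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res)
    else data.frame(parameter = character(0), fold = numeric(0),
                    direction = character(0),
                    log2fc_half_life = numeric(0),
                    log2fc_bax_star = numeric(0))
  attr(out, "condition") <- condition_name(cond)
  attr(out, "baseline") <- base
  class(out) <- c("perturbation_scan", "data.frame")
  out
}

#' @export
print.perturbation_scan <- function(x, ...) {
  b <- attr(x, "baseline")
  cat(sprintf("perturbation scan under %s (baseline t1/2 = %.3g d, BAX* = %.3g nM)\n",
              attr(x, "condition"), b[["t_half"]], b[["bax_star"]]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
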