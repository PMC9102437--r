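#' Akaike information criterion for least-squares fits
#'
#' `AIC = 2k + N log(chi2 / N)`, where `k` is the number of fitted
#' parameters and `N` the number of data points. Only differences
#' between models fitted to the same data are interpretable.
#'
#' @param chi2 chi-square cost at the optimum (> 0).
#' @param N number of data points (>= 1).
#' @param k number of fit parameters (>= 0).
#' @return the AIC value; `-Inf` with a warning when `chi2 = 0`.
#' @examples
#' aic(16, 16, 8)  # 16: the log term vanishes
#' @export
aic <- function(chi2, N, k) {
  stopifnot(N >= 1, k >= 0)
  if (chi2 < 0) stop("'chi2' must be >= 0", call. = FALSE)
  if (chi2 == 0) {
    warning("chi2 = 0: AIC undefined, returning -Inf")
    return(-Inf)
  }
  2 * k + N * log(chi2 / N)
}

#' Enumerate submodel topologies
#'
#' The full model plus five reductions, each removing one or more
#' regulatory components of the caspase/input network:
#'
#' * `full` -- all components active.
#' * `no_APRIL_casp12` -- APRIL no longer inhibits caspase 12
#'   (`alpha = 0`).
#' * `no_APRIL` -- no APRIL inputs at all (`alpha = 0`, `a_BCL2 = 0`
#'   fixed; `a_BCL2` leaves the free-parameter set).
#' * `no_ST2_casp37` -- ST2 no longer inhibits caspase 3/7 (`beta = 0`
#'   fixed and not fitted).
#' * `no_casp_regulation` -- neither APRIL nor ST2 regulate caspases
#'   (`alpha = 0`, `beta = 0` fixed).
#' * `no_caspase_module` -- the caspase module is bypassed entirely
#'   (`kappa = 0`, `beta = 0` fixed): the death rate reduces to the core
#'   BAX-only Hill law.
#'
#' Free-parameter counts `k` are derived from the toggles: parameters
#' fixed at zero are not fitted.
#'
#' @param full_free free parameters of the full model fit.
#' @return list of submodel specifications (class `"submodel_spec"`):
#'   each has `label`, `fixes` (named values forced on the parameters)
#'   and `free`.
#' @export
enumerate_submodels <- function(full_free = c("a_BCL2", "s_MCL1", "s_BCL2",
                                              "s_BIM", "s_NOXA", "gamma",
                                              "kappa", "beta")) {
  spec <- function(label, fixes) {
    structure(list(label = label, fixes = fixes,
                   free = setdiff(full_free, names(fixes))),
              class = "submodel_spec")
  }
  list(
    spec("full",               list()),
    spec("no_APRIL_casp12",    list(alpha = 0)),
    spec("no_APRIL",           list(alpha = 0, a_BCL2 = 0)),
    spec("no_ST2_casp37",      list(beta = 0)),
    spec("no_casp_regulation", list(alpha = 0, beta = 0)),
    spec("no_caspase_module",  list(kappa = 0, beta = 0)))
}

#' @export
print.submodel_spec <- function(x, ...) {
  fx <- if (length(x$fixes))
    paste(names(x$fixes), unlist(x$fixes), sep = " = ", collapse = ", ")
  else "none"
  cat(sprintf("submodel '%s': fixed {%s}; k = %d free (%s)\n",
              x$label, fx, length(x$free), paste(x$free, collapse = ", ")))
  invisible(x)
}

#' Fit every submodel to the same data
#'
#' Applies each submodel's fixed values to the baseline parameters and
#' fits its free parameters by [fit_apoptosis_model()].
#'
#' @inheritParams fit_apoptosis_model
#' @param submodels list from [enumerate_submodels()].
#' @param ... passed to [fit_apoptosis_model()].
#' @return named list of `"apoptosis_fit"` objects.
#' @export
fit_submodels <- function(protein_data = NULL, survival_data = NULL,
                          submodels = enumerate_submodels(),
                          params = annotated_parameters()$kinetic,
                          dp = annotated_parameters()$death, ...) {
  fits <- lapply(submodels, function(sm) {
    upd <- apply_free(params, dp, sm$fixes)
    fit_apoptosis_model(protein_data = protein_data,
                        survival_data = survival_data,
                        free = sm$free, params = upd$params, dp = upd$dp,
                        ...)
  })
  names(fits) <- vapply(submodels, `[[`, character(1), "label")
  fits
}

#' Rank fitted models by AIC
#'
#' Computes `-dAIC` relative to the worst model (which is set to 0, so
#' larger is better), and flags models whose AIC exceeds the best
#' model's by more than 2 as significantly worse.
#'
#' @param fits named list of `"apoptosis_fit"` objects (>= 2), or a
#'   data.frame with columns `label`, `chi2`, `N`, `k`.
#' @return data.frame with columns `label`, `chi2`, `N`, `k`, `AIC`,
#'   `neg_delta_AIC`, `delta_from_best`, `significant`, ordered best
#'   first.
#' @examples
#' rank_models(data.frame(label = c("a", "b"), chi2 = c(10, 10),
#'                        N = 10, k = c(2, 4)))
#' @export
rank_models <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits
    tab$AIC <- mapply(aic, tab$chi2, tab$N, tab$k)
  } else {
    if (length(fits) < 2) stop("need >= 2 fitted models", call. = FALSE)
    tab <- data.frame(
      label = if (!is.null(names(fits))) names(fits)
              else paste0("model", seq_along(fits)),
      chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
      N = vapply(fits, `[[`, numeric(1), "N"),
      k = vapply(fits, `[[`, numeric(1), "k"),
      stringsAsFactors = FALSE)
    tab$AIC <- vapply(fits, `[[`, numeric(1), "aic")
  }
  if (nrow(tab) < 2) stop("need >= 2 fitted models", call. = FALSE)
  if (length(unique(tab$N)) > 1)
    warning("models were fitted to differing numbers of data points; ",
            "AIC differences are not interpretable")
  tab$neg_delta_AIC <- max(tab$AIC) - tab$AIC
  tab$delta_from_best <- tab$AIC - min(tab$AIC)
  tab$significant <- tab$delta_from_best > 2
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  tab
}
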