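#' Synthetic flow-cytometry protein dataset
#'
#' Emulates per-replicate geometric-mean fluorescence measurements of
#' BIM, NOXA, BCL-2 and MCL-1 under the four culture conditions:
#' replicates are drawn lognormally around the model's steady-state
#' total abundance of each protein (free plus complexed, since antibody
#' staining does not distinguish binding state), with a fixed geometric
#' noise level. Deterministic under a fixed seed; the generating model
#' is attached as the `ground_truth` attribute.
#'
#' @param params an [apoptosis_parameters()] set (the generating truth).
#' @param topo an [pc_topology()].
#' @param conditions named list of [condition()]s.
#' @param n_replicates biological replicates per condition (>= 2).
#' @param noise_cv geometric noise: sd of log-values (> 0). The default
#'   0.15 reflects typical replicate scatter of normalized
#'   flow-cytometry geometric means.
#' @param seed RNG seed.
#' @param scale arbitrary fluorescence units per uM.
#' @return data.frame with columns `protein`, `condition`, `replicate`,
#'   `value`.
#' @examples
#' d <- make_protein_dataset(seed = 1)
#' head(d)
#' @export
make_protein_dataset <- function(params = annotated_parameters()$kinetic,
                                 topo = default_topology(),
                                 conditions = default_conditions(),
                                 n_replicates = 6, noise_cv = 0.15,
                                 seed = 1L, scale = 1000) {
  if (n_replicates < 2) stop("'n_replicates' must be >= 2", call. = FALSE)
  if (!is.numeric(noise_cv) || noise_cv <= 0)
    stop("'noise_cv' must be > 0", call. = FALSE)
  proteins <- c("BIM", "NOXA", "BCL2", "MCL1")
  truth <- lapply(conditions, function(cc)
    state_totals(steady_state(params, cc, topo), topo)[proteins])
  rows <- with_seed(seed, {
    do.call(rbind, lapply(names(conditions), function(nm) {
      do.call(rbind, lapply(proteins, function(pp) {
        data.frame(protein = pp, condition = nm,
                   replicate = seq_len(n_replicates),
                   value = scale * truth[[nm]][[pp]] *
                     exp(stats::rnorm(n_replicates, 0, noise_cv)),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(rows) <- NULL
  structure(rows,
            ground_truth = list(params = params,
                                steady_totals = truth,
                                noise_cv = noise_cv, seed = seed))
}

#' Synthetic survival dataset
#'
#' Emulates per-replicate plasma cell survival time courses: exponential
#' decay at a condition-specific half-life plus additive truncated
#' Gaussian noise, clipped to \[0, 100\]%. The default half-lives
#' (Medium 0.7 d, APRIL 1.5 d, ST2 1.5 d, APRIL+ST2 6.5 d) respect the
#' observed contrast of under one day without survival signals versus
#' more than six days with both.
#'
#' @param half_lives named vector of half-lives per condition, days.
#' @param times sampling days (must include 0).
#' @param n_replicates replicates (independent time series) per
#'   condition.
#' @param noise_sd additive noise sd, percentage points.
#' @param seed RNG seed.
#' @return data.frame with columns `time_d`, `percent_live`,
#'   `condition`, `replicate`; generating half-lives in the
#'   `ground_truth` attribute.
#' @examples
#' d <- make_survival_dataset(seed = 1)
#' head(d)
#' @export
make_survival_dataset <- function(half_lives = c(Medium = 0.7, APRIL = 1.5,
                                                 ST2 = 1.5,
                                                 `APRIL+ST2` = 6.5),
                                  times = 0:5, n_replicates = 12,
                                  noise_sd = 5, seed = 1L) {
  if (any(!is.finite(half_lives)) || any(half_lives <= 0))
    stop("'half_lives' must be finite and > 0", call. = FALSE)
  if (!0 %in% times) stop("'times' must include 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  rows <- with_seed(seed, {
    do.call(rbind, lapply(names(half_lives), function(nm) {
      lam <- log(2) / half_lives[[nm]]
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        clean <- 100 * exp(-lam * times)
        noisy <- pmin(100, pmax(0, clean +
                                  stats::rnorm(length(times), 0, noise_sd)))
        data.frame(time_d = times, percent_live = noisy, condition = nm,
                   replicate = r, stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(rows) <- NULL
  structure(rows, ground_truth = list(half_lives = half_lives,
                                      noise_sd = noise_sd, seed = seed))
}
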