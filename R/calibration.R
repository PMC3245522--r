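## Data-driven choice of the power-law exponent alpha (leave-one-out
## cross-validation) and calibration of the physical scale.

#' LOOCV fitting budget
#'
#' Controls the per-fold structure fit used by [loocv_mse()]: a short
#' Metropolis-Hastings run followed by a greedy accept-only-improvement
#' polish (see [fit_structure()]).
#'
#' @param mcmc_iters,polish_iters Iteration budgets for the two phases.
#' @param radius,polish_radius Proposal radii for the two phases.
#' @param restarts Independent random initializations per fold; the best
#'   final log posterior wins (guards against misfolded local optima).
#' @param max_folds Datasets with more measured pairs than this run LOOCV
#'   on a seeded random subset of folds (recorded in the result); full
#'   LOOCV is the default up to 200 pairs.
#' @param seed Seed for the whole LOOCV experiment (fold subsampling and
#'   every fit draw from one stream, so results are reproducible).
#' @return `list` of class `loocv_config`.
#' @export
loocv_config <- function(mcmc_iters = 5e4, polish_iters = 5e4,
                         radius = 0.25, polish_radius = 0.05,
                         restarts = 2L, max_folds = 200L, seed = 1L) {
  structure(list(mcmc_iters = mcmc_iters, polish_iters = polish_iters,
                 radius = radius, polish_radius = polish_radius,
                 restarts = as.integer(restarts),
                 max_folds = as.integer(max_folds), seed = as.integer(seed)),
            class = "loocv_config")
}

#' Leave-one-out cross-validation of the distance exponent
#'
#' For each candidate `alpha` and each measured pair in turn: hold the
#' pair out, fit a maximum-posterior structure to the remaining pairs
#' (scale refit per evaluation, so exponents compete on shape rather than
#' scale), predict the held-out IF from the fitted distance via the
#' forward model, and accumulate the squared prediction error.
#' `MSE(alpha)` is the mean over folds; the best exponent is its argmin
#' ([select_alpha()]).  Folds whose removal leaves a fragment with fewer
#' than two measured pairs are skipped with a warning.
#'
#' @param data 5C [if_dataset()] (>= 10 measured pairs recommended).
#' @param alpha_grid Candidate exponents (sorted ascending internally).
#' @param fit_config [loocv_config()].
#' @return `list` of class `loocv_result`: `alpha_grid`, `mse`,
#'   `records` (one row per evaluated fold: alpha, i, j, observed,
#'   predicted, sq_error), `n_folds`, `skipped`, `subsampled`.
#' @export
loocv_mse <- function(data, alpha_grid, fit_config = loocv_config()) {
  stopifnot(inherits(data, "if_dataset"), length(alpha_grid) >= 1L)
  alpha_grid <- sort(as.numeric(alpha_grid))
  p <- data$pairs
  m <- nrow(p)
  if (m < 10L)
    warning("fewer than 10 measured pairs; LOOCV will be unstable")
  set.seed(fit_config$seed)
  folds <- seq_len(m)
  subsampled <- FALSE
  if (m > fit_config$max_folds) {
    folds <- sort(sample.int(m, fit_config$max_folds))
    subsampled <- TRUE
  }
  n <- n_fragments(data)
  counts <- tabulate(c(p$i, p$j), nbins = n)
  records <- vector("list", length(alpha_grid) * length(folds))
  skipped <- 0L
  ri <- 0L
  for (a in alpha_grid) {
    params_a <- model_params(alpha = a, psi = 1,
                             technology = data$technology)
    for (f in folds) {
      cnt <- counts
      cnt[p$i[f]] <- cnt[p$i[f]] - 1L
      cnt[p$j[f]] <- cnt[p$j[f]] - 1L
      involved <- counts > 0L          # fragments measured at all
      if (any(cnt[involved] < 2L)) {
        warning(sprintf(
          "fold (%d,%d) skipped: a fragment has < 2 measured pairs after hold-out",
          p$i[f], p$j[f]))
        skipped <- skipped + 1L
        next
      }
      train <- if_dataset(data$fragments, p[-f, , drop = FALSE],
                          technology = data$technology)
      fit <- fit_structure(train, params_a,
                           mcmc_iters = fit_config$mcmc_iters,
                           polish_iters = fit_config$polish_iters,
                           radius = fit_config$radius,
                           polish_radius = fit_config$polish_radius,
                           restarts = fit_config$restarts,
                           normalize_psi = TRUE)
      dij <- sqrt(sum((fit$conformation[p$i[f], ] -
                         fit$conformation[p$j[f], ])^2))
      pred <- fit$psi_hat * dij^(-a)
      ri <- ri + 1L
      records[[ri]] <- data.frame(alpha = a, i = p$i[f], j = p$j[f],
                                  observed = p$value[f], predicted = pred,
                                  sq_error = (pred - p$value[f])^2)
    }
  }
  records <- do.call(rbind, records[seq_len(ri)])
  mse <- vapply(alpha_grid,
                function(a) mean(records$sq_error[records$alpha == a]),
                numeric(1L))
  structure(list(alpha_grid = alpha_grid, mse = mse, records = records,
                 n_folds = length(folds) - skipped / length(alpha_grid),
                 skipped = skipped, subsampled = subsampled),
            class = "loocv_result")
}

#' Exponent selected by LOOCV
#'
#' Argmin of `MSE(alpha)` over the grid; ties go to the smaller exponent.
#'
#' @param result A [loocv_mse()] result.
#' @return Selected `alpha`.
#' @export
select_alpha <- function(result) {
  stopifnot(inherits(result, "loocv_result"), length(result$mse) >= 1L)
  result$alpha_grid[which.min(result$mse)]   # grid sorted: first min = smallest
}

#' Calibrate the physical scale of the model
#'
#' Anchors the power-law scale to chromatin-packing physics: pairs of
#' fragments closer than `max_separation_bp` along the genome are assumed
#' to sit at the distance implied by packed chromatin (1 nm per
#' `packing_bp_per_nm` base pairs, plausible range 110-150).  `psi` is
#' then chosen so that the mean short-range IF maps exactly to that
#' physical distance: `psi = mean_IF * L^alpha`.
#'
#' @param data 5C [if_dataset()].
#' @param params [model_params()] providing `alpha`.
#' @param packing_bp_per_nm Base pairs per nanometer of packed chromatin
#'   (default 130, the middle of the 110-150 range).
#' @param max_separation_bp Genomic separation cutoff defining
#'   "short-range" (default 5000 bp).
#' @return `list(psi, distance_nm, mean_short_if, n_pairs, packing)`;
#'   `distance_nm` is the calibrated short-range physical distance (the
#'   scale constant, approximately 50 nm for typical 5C designs).
#' @export
estimate_scale <- function(data, params, packing_bp_per_nm = 130,
                           max_separation_bp = 5000) {
  stopifnot(packing_bp_per_nm > 0)
  mids <- (data$fragments$start + data$fragments$end) / 2
  sep <- abs(mids[data$pairs$i] - mids[data$pairs$j])
  sel <- sep < max_separation_bp & data$pairs$value > 0
  if (!any(sel))
    stop("no measured pairs closer than ", max_separation_bp,
         " bp along the genome; set psi manually", call. = FALSE)
  l_phys <- mean(sep[sel]) / packing_bp_per_nm
  mean_if <- mean(data$pairs$value[sel])
  psi <- mean_if * l_phys^params$alpha
  list(psi = psi, distance_nm = l_phys, mean_short_if = mean_if,
       n_pairs = sum(sel), packing = packing_bp_per_nm)
}
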