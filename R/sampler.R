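## Metropolis-Hastings sampling of conformations from the posterior.
##
## The inner loop lives in C++ (src/run_chain.cpp) for speed; the pure-R
## functions here (propose_move, mh_step, delta_log_posterior) implement
## the same algorithm and are used by the test suite as an independent
## route against the compiled chain.

#' Sampler configuration
#'
#' @param radius Perturbation radius `r` (model units, nm once
#'   calibrated).  Default 0.25, the value found to work well for both
#'   5C and Hi-C data.
#' @param max_iterations Hard iteration cap per chain.  The default
#'   mirrors full-size runs (5e9); tests and examples use far smaller
#'   values.
#' @param mixing_threshold Two-chain mixing tolerance: chains are mixed
#'   when the within-run and cross-run mean structure distances agree to
#'   within this relative fraction (default 0.10).
#' @param k0 First mixing checkpoint; checks happen at `k0 * 2^j`
#'   (must be a multiple of 20 so the 11 snapshot positions
#'   `k/2 + i*k/20` are integers).
#' @param n_samples Ensemble size collected *per chain* after mixing.
#' @param n_chains Number of parallel chains (>= 2).
#' @param seed Master seed; per-chain streams are derived from it.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(radius = 0.25, max_iterations = 5e9,
                           mixing_threshold = 0.10, k0 = 1e5,
                           n_samples = 250, n_chains = 2, seed = 1) {
  stopifnot(radius > 0, mixing_threshold > 0, mixing_threshold < 1,
            n_samples >= 1, n_chains >= 2, k0 >= 20,
            max_iterations >= k0)
  if (round(k0) %% 20 != 0)
    stop("k0 must be a multiple of 20", call. = FALSE)
  structure(list(radius = radius, max_iterations = max_iterations,
                 mixing_threshold = mixing_threshold, k0 = k0,
                 n_samples = n_samples, n_chains = n_chains,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Random initial conformation
#'
#' Each point is placed uniformly at random in a cube of side
#' `L = 10 * avg(d)`, where `d` are the distances implied by the observed
#' interaction frequencies.  For 5C, `d = if_to_distance(IF)`.  For Hi-C
#' the likelihood is scale-invariant (the count normalizer absorbs any
#' global rescaling), so distances relative to the strongest contact,
#' `d = (max(r) / r)^(1/alpha)`, set the box size.
#'
#' @param data [if_dataset()] with at least one measured pair with a
#'   positive value.
#' @param params [model_params()].
#' @return n x 3 conformation matrix with coordinates in `[0, L]`.
#' @export
init_structure <- function(data, params) {
  v <- data$pairs$value
  v <- v[v > 0]
  if (length(v) == 0)
    stop("dataset has no measured pairs with positive values", call. = FALSE)
  d <- if (data$technology == "5C") if_to_distance(v, params)
       else (max(v) / v)^(1 / params$alpha)
  L <- 10 * mean(d)
  n <- n_fragments(data)
  matrix(stats::runif(3L * n, 0, L), ncol = 3L)
}

#' Distance-geometry initialization by classical MDS
#'
#' Converts measured interaction frequencies to distance estimates via
#' [if_to_distance()] (Hi-C: distances relative to the strongest
#' contact), completes unmeasured entries by shortest paths through the
#' measured graph, and embeds the resulting matrix in 3D with classical
#' multidimensional scaling.  A good starting point for
#' [fit_structure()]: for noise-free complete data at the correct
#' exponent it recovers the generating geometry up to rigid motion.
#'
#' @param data [if_dataset()] whose measured graph is connected.
#' @param params [model_params()].
#' @return n x 3 conformation matrix.
#' @export
mds_init <- function(data, params) {
  n <- n_fragments(data)
  p <- data$pairs
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  pos <- p$value > 0
  d <- if (data$technology == "5C") if_to_distance(p$value[pos], params)
       else (max(p$value[pos]) / p$value[pos])^(1 / params$alpha)
  D[cbind(p$i[pos], p$j[pos])] <- d
  D[cbind(p$j[pos], p$i[pos])] <- d
  # Floyd-Warshall completion of unmeasured pairs
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], "+")
    upd <- via < D
    D[upd] <- via[upd]
  }
  if (any(!is.finite(D)))
    stop("measured-pair graph is disconnected; cannot build an MDS init",
         call. = FALSE)
  xy <- suppressWarnings(stats::cmdscale(D, k = 3))
  if (ncol(xy) < 3) xy <- cbind(xy, matrix(0, n, 3 - ncol(xy)))
  unname(xy)
}

runif_ball <- function(radius) {
  repeat {
    v <- stats::runif(3L, -1, 1)
    if (sum(v * v) <= 1) return(v * radius)
  }
}

#' Single-point spherical proposal
#'
#' Picks a point uniformly among the n fragments and displaces it by a
#' vector uniform in the closed ball of radius `radius` (volume-uniform,
#' by rejection from the bounding cube).  The proposal is symmetric, so
#' the Metropolis rule needs no Hastings correction.
#'
#' @param conf Conformation matrix.
#' @param radius Ball radius, > 0.
#' @return `list(index, displacement, point)` where `point` is the moved
#'   coordinate.
#' @export
propose_move <- function(conf, radius) {
  stopifnot(radius > 0)
  n <- nrow(conf)
  idx <- sample.int(n, 1L)
  disp <- runif_ball(radius)
  list(index = idx, displacement = disp, point = conf[idx, ] + disp)
}

mh_accept <- function(delta) {
  if (!is.finite(delta)) return(FALSE)
  delta >= 0 || stats::runif(1L) < exp(delta)
}

#' One Metropolis-Hastings step (reference R implementation)
#'
#' Proposes a single-point move and accepts it with probability
#' `min(1, exp(delta log posterior))`, updating the per-pair cache
#' incrementally.  The compiled chain used by [sample_ensemble()] runs
#' the same algorithm; this function exists for unit-level testing and
#' for small interactive experiments.
#'
#' @param state `list(conformation, log_posterior, cache, t)`; create the
#'   cache with [make_pair_cache()].
#' @param data,params Dataset and model parameters.
#' @param config [sampler_config()] (only `radius` is used).
#' @return Updated state, with fields `accepted` and `delta` describing
#'   the step just taken.
#' @export
mh_step <- function(state, data, params, config) {
  prop <- propose_move(state$conformation, config$radius)
  upd <- delta_log_posterior(state$conformation, state$cache, prop$index,
                             prop$point, data, params)
  delta <- upd$log_posterior - state$log_posterior
  if (is.nan(delta)) delta <- -Inf       # -Inf -> -Inf proposals
  acc <- mh_accept(delta)
  if (acc) {
    state$conformation[prop$index, ] <- prop$point
    state$cache <- upd$cache
    state$log_posterior <- upd$log_posterior
  }
  state$t <- state$t + 1L
  state$accepted <- acc
  state$delta <- delta
  state
}

mixing_decision <- function(within_mean, cross_mean, threshold) {
  if (within_mean == 0) return(cross_mean == 0)
  abs(within_mean - cross_mean) / within_mean <= threshold
}

#' Two-chain mixing diagnostic
#'
#' Compares the mean pairwise structure distance among one chain's
#' snapshots (within-run) to the mean over all cross-chain snapshot
#' pairs.  Mixing is declared when the two means agree to within the
#' threshold fraction of the within-run mean (boundary inclusive).
#'
#' @param snapshots_a,snapshots_b Lists of conformations: the snapshot
#'   sets `{R_{k/2}, R_{k/2 + k/20}, ..., R_k}` of the two chains.
#' @param threshold Relative tolerance, default 0.10.
#' @return `list(mixed, within_mean, cross_mean, ratio)`.
#' @export
assess_mixing <- function(snapshots_a, snapshots_b, threshold = 0.10) {
  na <- length(snapshots_a); nb <- length(snapshots_b)
  if (na < 2L || nb < 1L)
    stop("assess_mixing needs at least two snapshots per chain",
         call. = FALSE)
  wsum <- 0; wn <- 0L
  for (a in seq_len(na - 1L)) for (b in seq.int(a + 1L, na)) {
    wsum <- wsum + structure_distance(snapshots_a[[a]], snapshots_a[[b]])
    wn <- wn + 1L
  }
  within <- wsum / wn
  csum <- 0
  for (a in seq_len(na)) for (b in seq_len(nb))
    csum <- csum + structure_distance(snapshots_a[[a]], snapshots_b[[b]])
  cross <- csum / (na * nb)
  ratio <- if (within == 0) { if (cross == 0) 0 else Inf }
           else abs(within - cross) / within
  list(mixed = mixing_decision(within, cross, threshold),
       within_mean = within, cross_mean = cross, ratio = ratio)
}

## low-level bridge to the compiled chain
run_chain_segment <- function(points, data, params, radius, from, to,
                              snap_iters = numeric(0), greedy = FALSE,
                              normalize_psi = FALSE) {
  p <- data$pairs
  mode <- if (data$technology == "HiC") 1L
          else if (normalize_psi) 2L else 0L
  sigma <- if (data$technology == "5C") p$sigma else numeric(0)
  run_chain_cpp(points, p$i, p$j, p$value, sigma,
                params$alpha, params$psi, params$kappa, mode,
                radius, from, to, snap_iters, greedy)
}

# per-chain RNG bookkeeping: each chain owns an independent stream derived
# from the master seed, saved/restored around every compiled segment
save_rng <- function() get(".Random.seed", envir = globalenv())
restore_rng <- function(s) assign(".Random.seed", s, envir = globalenv())

#' Sample an ensemble of conformations from the posterior
#'
#' Runs `n_chains` parallel Metropolis-Hastings chains from independent
#' random initial structures.  Mixing is checked at geometrically growing
#' milestones `k = k0 * 2^j` by comparing the 11 snapshots
#' `R_{k/2}, R_{k/2 + k/20}, ..., R_k` of the first two chains
#' ([assess_mixing()]).  Once mixed, `n_samples` conformations per chain
#' are collected at thinning interval `delta = k/20` starting at
#' iteration `k`.
#'
#' @param data [if_dataset()].
#' @param params [model_params()].
#' @param config [sampler_config()].
#' @return Object of class `conf_ensemble`: parallel vectors/lists
#'   `structures`, `log_posterior`, `chain`, `iteration`, plus the
#'   fragment map and a `mixing_report` data frame (one row per
#'   milestone: iteration, within_mean, cross_mean, ratio, mixed).
#'   If `max_iterations` is reached unmixed, an error of class
#'   `mixing_not_achieved` is signalled carrying the report in its
#'   `report` field.
#' @export
sample_ensemble <- function(data, params, config = sampler_config()) {
  stopifnot(inherits(data, "if_dataset"), inherits(params, "model_params"),
            inherits(config, "sampler_config"))
  if (nrow(data$pairs) == 0)
    stop("dataset has no measured pairs", call. = FALSE)
  nc <- config$n_chains
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, nc)

  chains <- vector("list", nc)
  for (c in seq_len(nc)) {
    set.seed(chain_seeds[c])
    pts <- init_structure(data, params)
    chains[[c]] <- list(points = pts, iter = 0, lp = NA_real_,
                        rng = save_rng())
  }

  run_seg <- function(c, to, snaps = numeric(0)) {
    restore_rng(chains[[c]]$rng)
    res <- run_chain_segment(chains[[c]]$points, data, params,
                             config$radius, chains[[c]]$iter, to, snaps)
    chains[[c]]$points <<- res$points
    chains[[c]]$iter <<- to
    chains[[c]]$lp <<- res$log_posterior
    chains[[c]]$rng <<- save_rng()
    res
  }

  k <- config$k0
  half <- round(k / 2)
  for (c in seq_len(nc)) run_seg(c, half)

  report <- data.frame(iteration = numeric(0), within_mean = numeric(0),
                       cross_mean = numeric(0), ratio = numeric(0),
                       mixed = logical(0))
  repeat {
    targets <- round(k / 2 + (0:10) * k / 20)
    snaps <- vector("list", nc)
    for (c in seq_len(nc)) {
      first <- list(chains[[c]]$points)        # R_{k/2} = current state
      res <- run_seg(c, k, snaps = targets[-1L])
      snaps[[c]] <- c(first, res$snapshots)
    }
    mix <- assess_mixing(snaps[[1L]], snaps[[2L]],
                         threshold = config$mixing_threshold)
    report <- rbind(report,
                    data.frame(iteration = k, within_mean = mix$within_mean,
                               cross_mean = mix$cross_mean,
                               ratio = mix$ratio, mixed = mix$mixed))
    if (mix$mixed) break
    if (2 * k > config$max_iterations) {
      cond <- structure(
        list(message = sprintf(paste0(
          "mixing not achieved after %g iterations (last within = %g,",
          " cross = %g, ratio = %g > %g); increase max_iterations or",
          " inspect the mixing report"),
          k, mix$within_mean, mix$cross_mean, mix$ratio,
          config$mixing_threshold),
          call = sys.call(-1L), report = report),
        class = c("mixing_not_achieved", "error", "condition"))
      stop(cond)
    }
    k <- 2 * k
  }

  delta <- max(1, round(k / 20))
  N <- config$n_samples
  structures <- list(); lp <- numeric(0); chain_id <- integer(0)
  iteration <- numeric(0)
  for (c in seq_len(nc)) {
    first_pts <- chains[[c]]$points
    first_lp <- chains[[c]]$lp                 # X_1 = R_k
    if (N > 1) {
      iters <- k + delta * seq_len(N - 1L)
      res <- run_seg(c, k + delta * (N - 1L), snaps = iters)
      structures <- c(structures, list(first_pts), res$snapshots)
      lp <- c(lp, first_lp, res$snapshot_lp)
      iteration <- c(iteration, k, iters)
    } else {
      structures <- c(structures, list(first_pts))
      lp <- c(lp, first_lp)
      iteration <- c(iteration, k)
    }
    chain_id <- c(chain_id, rep(c, N))
  }

  structure(list(structures = structures, log_posterior = lp,
                 chain = chain_id, iteration = iteration,
                 fragments = data$fragments, technology = data$technology,
                 thinning = delta, mixed_at = k,
                 mixing_report = report, seed = config$seed),
            class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<conf_ensemble> %d structures (%d chains), n = %d",
                     " points; mixed at %g iterations, thinning %g\n"),
              length(x$structures), length(unique(x$chain)),
              nrow(x$structures[[1L]]),
              if (is.null(x$mixed_at)) NA else x$mixed_at,
              if (is.null(x$thinning)) NA else x$thinning))
  invisible(x)
}

#' Highest-posterior structure of an ensemble
#'
#' Ties are broken by earliest (chain, iteration); ensembles are stored
#' chain-major with strictly increasing iterations, so the first maximum
#' is the earliest.
#'
#' @param ens A `conf_ensemble`.
#' @return `list(conformation, log_posterior, chain, iteration)`.
#' @export
max_posterior_structure <- function(ens) {
  if (length(ens$structures) == 0)
    stop("empty ensemble", call. = FALSE)
  i <- which.max(ens$log_posterior)
  list(conformation = ens$structures[[i]],
       log_posterior = ens$log_posterior[i],
       chain = ens$chain[i], iteration = ens$iteration[i])
}

#' Fit a maximum-posterior structure by short MCMC plus greedy polish
#'
#' A fixed-budget Metropolis-Hastings run followed by an
#' accept-only-improvement phase with a smaller step.  Used per fold by
#' [loocv_mse()]; also handy for a quick point estimate.  With
#' `normalize_psi = TRUE` (the default for 5C) the scale is refit at
#' every likelihood evaluation by matching the model IF total to the
#' observed total, so the fit is invariant to the overall structure
#' scale and exponents can be compared fairly.
#'
#' @param data,params Dataset and model parameters.
#' @param mcmc_iters,polish_iters Iteration budgets of the two phases.
#' @param radius,polish_radius Proposal radii of the two phases.
#' @param normalize_psi Refit the scale per evaluation (ignored for
#'   Hi-C, which is always scale-normalized).
#' @param restarts Number of independent initializations; the fit with
#'   the highest final log posterior wins.  Single-point proposals can
#'   trap a run in a misfolded local optimum, so the first start is the
#'   distance-geometry embedding ([mds_init()], when `init = "mds"`) and
#'   further starts are random.
#' @param init `"mds"` (default) or `"random"` for the first start.
#' @param seed Optional seed (uses the current RNG stream if `NULL`).
#' @return `list(conformation, log_posterior, psi_hat)` where `psi_hat`
#'   is the fitted scale at the final structure.
#' @export
fit_structure <- function(data, params, mcmc_iters = 5e4,
                          polish_iters = 5e4, radius = 0.25,
                          polish_radius = 0.05,
                          normalize_psi = data$technology == "5C",
                          restarts = 1L, init = c("mds", "random"),
                          seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  # the accept-only-improvement phase equilibrates at a geometry error of
  # the order of its proposal radius, so it anneals the radius downward
  polish_stages <- polish_radius * 4^-(0:3)
  stage_iters <- ceiling(polish_iters / length(polish_stages))
  for (rs in seq_len(max(1L, restarts))) {
    pts <- if (rs == 1L && init == "mds")
      tryCatch(mds_init(data, params),
               error = function(e) init_structure(data, params))
    else init_structure(data, params)
    s <- run_chain_segment(pts, data, params, radius, 0, mcmc_iters,
                           normalize_psi = normalize_psi)
    for (pr in polish_stages)
      s <- run_chain_segment(s$points, data, params, pr, 0, stage_iters,
                             greedy = TRUE, normalize_psi = normalize_psi)
    if (is.null(best) || s$log_posterior > best$log_posterior)
      best <- s
  }
  conf <- best$points
  psi_hat <- params$psi
  if (normalize_psi || data$technology == "HiC") {
    d <- pair_dists(conf, data$pairs)
    psi_hat <- sum(data$pairs$value) / sum(d^(-params$alpha))
  }
  list(conformation = conf, log_posterior = best$log_posterior,
       psi_hat = psi_hat)
}
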