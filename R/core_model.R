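#' chromconf: chromatin conformation ensembles from 5C/Hi-C data
#'
#' Probabilistic inference of 3D chromatin structure from chromosome
#' conformation capture interaction frequencies.  The chromatin fiber is
#' modeled as an ordered set of 3D points (one per restriction site or
#' Hi-C bin); interaction frequencies decay with Euclidean distance as a
#' power law, and conformations are sampled from the resulting posterior
#' by Metropolis-Hastings.
#'
#' @useDynLib chromconf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm runif rnorm sd dist cutree hclust kmeans
#'   aggregate rmultinom
#' @importFrom utils read.delim write.table combn packageVersion
#' @keywords internal
"_PACKAGE"

## ---- validation helpers -------------------------------------------------

validate_conformation <- function(conf) {
  if (is.data.frame(conf)) conf <- as.matrix(conf)
  if (!is.matrix(conf) || !is.numeric(conf) || ncol(conf) != 3L ||
      nrow(conf) < 1L)
    stop("a conformation must be a numeric n x 3 matrix", call. = FALSE)
  if (!all(is.finite(conf)))
    stop("conformation contains non-finite coordinates", call. = FALSE)
  invisible(conf)
}

## ---- model parameters ---------------------------------------------------

#' Model parameters for the distance-to-IF transformation
#'
#' The forward model is `IF = psi * d^(-alpha)`: interaction frequency is
#' inversely related to Euclidean distance through a power law with
#' exponent `alpha` and scale `psi`.  For Hi-C data the per-pair variance
#' is the expected count plus the constant `kappa`, which prevents small
#' counts from being assigned vanishing variance.
#'
#' @param alpha Power-law exponent (> 0).  The default 2 is the value
#'   selected by leave-one-out cross-validation on real 5C data (see
#'   [loocv_mse()]).
#' @param psi Power-law scale (> 0), in units of IF times
#'   distance^`alpha`.  Defaults to 1 internal unit; [estimate_scale()]
#'   calibrates it to nanometers.
#' @param kappa Hi-C variance constant (>= 0 counts), default 10.
#' @param technology `"5C"` or `"HiC"`.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' p <- model_params(alpha = 2, psi = 1)
#' expected_if(2, p)
model_params <- function(alpha = 2, psi = 1, kappa = 10,
                         technology = c("5C", "HiC")) {
  technology <- match.arg(technology)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(psi), length(psi) == 1L, psi > 0,
            is.numeric(kappa), length(kappa) == 1L, kappa >= 0)
  structure(list(alpha = alpha, psi = psi, kappa = kappa,
                 technology = technology),
            class = "model_params")
}

## ---- fragment map -------------------------------------------------------

#' Restriction-fragment / bin genomic map
#'
#' Genomic intervals (0-based half-open, BED convention) for each modeled
#' restriction site or Hi-C bin, in genomic order.
#'
#' @param chrom Chromosome name (recycled).
#' @param start,end Interval bounds in base pairs; intervals must be
#'   sorted, non-overlapping, with `end > start`.
#' @param id 1-based fragment indices (default sequential).
#' @return A `data.frame` of class `fragment_map` with columns
#'   `id`, `chrom`, `start`, `end`.
#' @export
fragment_map <- function(chrom, start, end, id = seq_along(start)) {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(end) != n || length(id) != n)
    stop("fragment_map fields must have equal length", call. = FALSE)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("fragment coordinates must be finite", call. = FALSE)
  if (any(end <= start))
    stop("fragment intervals must satisfy end > start", call. = FALSE)
  if (is.unsorted(start, strictly = TRUE))
    stop("fragments must be sorted by start", call. = FALSE)
  if (n > 1L && any(start[-1L] < end[-n]))
    stop("fragment intervals must not overlap", call. = FALSE)
  structure(data.frame(id = as.integer(id), chrom = chrom,
                       start = start, end = end),
            class = c("fragment_map", "data.frame"))
}

## ---- interaction dataset ------------------------------------------------

#' Interaction-frequency dataset
#'
#' Bundles a [fragment_map()] with the set of *measured* fragment pairs.
#' For 5C each pair carries an observed interaction frequency and a
#' per-pair standard deviation; for Hi-C the value is a read count and
#' `sigma` is unused.  Pairs absent from the table are treated as
#' unmeasured and contribute nothing to any likelihood (no imputation);
#' the even-odd 5C primer design mask is therefore purely data-driven.
#'
#' Standard deviations below `1e-6 * max(value)` are clamped to that
#' floor to avoid infinite-weight pairs from degenerate replicate
#' estimates.
#'
#' @param fragments A [fragment_map()].
#' @param pairs `data.frame` with columns `i`, `j`, `value`, and (5C)
#'   `sigma`.  `i`/`j` are 1-based fragment indices; rows with `i > j`
#'   are swapped.
#' @param technology `"5C"` or `"HiC"`.
#' @return An object of class `if_dataset`.
#' @export
if_dataset <- function(fragments, pairs, technology = c("5C", "HiC")) {
  technology <- match.arg(technology)
  if (!inherits(fragments, "fragment_map"))
    fragments <- fragment_map(fragments$chrom, fragments$start,
                              fragments$end, fragments$id)
  n <- nrow(fragments)
  i <- as.integer(pairs$i); j <- as.integer(pairs$j)
  value <- as.numeric(pairs$value)
  if (anyNA(i) || anyNA(j) || any(i < 1L) || any(j < 1L) ||
      any(i > n) || any(j > n))
    stop("pair indices must reference fragments 1..", n, call. = FALSE)
  if (any(i == j)) stop("self-pairs (i == j) are not allowed", call. = FALSE)
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  if (anyDuplicated(cbind(i, j)))
    stop("duplicate measured pair in dataset", call. = FALSE)
  if (anyNA(value) || any(!is.finite(value)))
    stop("pair values must be finite", call. = FALSE)
  if (technology == "5C") {
    sigma <- as.numeric(pairs$sigma)
    if (length(sigma) != length(i) || anyNA(sigma))
      stop("5C datasets require a sigma for every measured pair",
           call. = FALSE)
    floor_sigma <- 1e-6 * max(value)
    if (floor_sigma <= 0) floor_sigma <- 1e-12
    sigma <- pmax(sigma, floor_sigma)
  } else {
    if (any(value < 0))
      stop("Hi-C counts must be nonnegative", call. = FALSE)
    sigma <- rep(NA_real_, length(i))
  }
  ord <- order(i, j)
  pairs_df <- data.frame(i = i, j = j, value = value,
                         sigma = sigma)[ord, , drop = FALSE]
  rownames(pairs_df) <- NULL
  structure(list(fragments = fragments,
                 technology = technology,
                 pairs = pairs_df),
            class = "if_dataset")
}

#' @export
print.if_dataset <- function(x, ...) {
  cat(sprintf("<if_dataset> %s: %d fragments, %d measured pairs\n",
              x$technology, nrow(x$fragments), nrow(x$pairs)))
  invisible(x)
}

n_fragments <- function(data) nrow(data$fragments)

## ---- distances and the power-law transform ------------------------------

#' Pairwise Euclidean distance matrix of a conformation
#'
#' @param conf Numeric n x 3 matrix of 3D coordinates.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(conf) {
  validate_conformation(conf)
  m <- as.matrix(stats::dist(conf))
  dimnames(m) <- NULL
  m
}

#' Expected interaction frequency at a given distance
#'
#' `IF = psi * d^(-alpha)`, strictly decreasing in `d`.
#'
#' @param d Euclidean distance(s), > 0.
#' @param params A [model_params()].
#' @return Expected IF value(s).
#' @export
expected_if <- function(d, params) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("expected_if is defined for distances > 0 only", call. = FALSE)
  params$psi * d^(-params$alpha)
}

#' Distance implied by an interaction frequency
#'
#' Exact inverse of [expected_if()]: `d = (psi / IF)^(1/alpha)`.
#'
#' @param if_value Interaction frequency value(s), > 0.
#' @param params A [model_params()].
#' @return Distance(s).
#' @export
if_to_distance <- function(if_value, params) {
  if (any(!is.finite(if_value)) || any(if_value <= 0))
    stop("if_to_distance is defined for IF > 0 only", call. = FALSE)
  (params$psi / if_value)^(1 / params$alpha)
}

## ---- likelihoods --------------------------------------------------------

pair_dists <- function(conf, pairs) {
  dx <- conf[pairs$i, , drop = FALSE] - conf[pairs$j, , drop = FALSE]
  sqrt(rowSums(dx * dx))
}

#' 5C Gaussian log-likelihood of a conformation
#'
#' Sum over measured pairs of the log normal density of the observed IF
#' around `psi * d^(-alpha)` with the per-pair standard deviation.
#' Unmeasured pairs contribute nothing.  A measured pair with coincident
#' points (distance 0) yields `-Inf` (the sampler always rejects such
#' proposals); no error is raised.
#'
#' @param conf Conformation (n x 3 matrix).
#' @param data 5C [if_dataset()].
#' @param params [model_params()].
#' @return Log-likelihood (equals the log posterior up to an additive
#'   constant, since the prior over conformations is flat).
#' @export
log_likelihood_5c <- function(conf, data, params) {
  stopifnot(inherits(data, "if_dataset"))
  if (data$technology != "5C")
    stop("log_likelihood_5c requires a 5C dataset", call. = FALSE)
  validate_conformation(conf)
  d <- pair_dists(conf, data$pairs)
  if (any(d == 0)) return(-Inf)
  mu <- params$psi * d^(-params$alpha)
  sum(stats::dnorm(data$pairs$value, mean = mu, sd = data$pairs$sigma,
                   log = TRUE))
}

#' Hi-C log-likelihood of a conformation
#'
#' Normal approximation to multinomial read counts: expected count
#' `r(i,j) = beta * d(i,j)^(-alpha)` where `beta` is set so that the
#' model total matches the observed total over measured pairs (counts
#' are proportions of a sequencing total), and the variance is
#' `r(i,j) + kappa`.  `beta` is recomputed for every conformation, which
#' makes the Hi-C likelihood invariant under global rescaling of the
#' structure.
#'
#' @inheritParams log_likelihood_5c
#' @export
log_likelihood_hic <- function(conf, data, params) {
  stopifnot(inherits(data, "if_dataset"))
  if (data$technology != "HiC")
    stop("log_likelihood_hic requires a Hi-C dataset", call. = FALSE)
  validate_conformation(conf)
  v <- data$pairs$value
  if (all(v == 0))
    stop("all-zero Hi-C count matrix: nothing to fit", call. = FALSE)
  d <- pair_dists(conf, data$pairs)
  if (any(d == 0)) return(-Inf)
  q <- d^(-params$alpha)
  beta <- sum(v) / sum(q)
  mu <- beta * q
  sum(stats::dnorm(v, mean = mu, sd = sqrt(mu + params$kappa), log = TRUE))
}

#' Log posterior of a conformation (up to an additive constant)
#'
#' Dispatches to the 5C or Hi-C likelihood according to the dataset
#' technology.  With a flat prior over conformations the posterior is
#' proportional to the likelihood; the normalizer is never computed.
#'
#' @inheritParams log_likelihood_5c
#' @export
log_posterior <- function(conf, data, params) {
  if (data$technology == "5C") log_likelihood_5c(conf, data, params)
  else log_likelihood_hic(conf, data, params)
}

## ---- incremental evaluation ---------------------------------------------

#' Per-pair term cache for incremental posterior updates
#'
#' Stores, for every measured pair, either its log-density term (5C) or
#' its `d^(-alpha)` contribution (Hi-C), together with an adjacency index
#' from fragments to the pairs that involve them.  Used by
#' [delta_log_posterior()] so that moving one point costs time
#' proportional to the pairs involving it (5C) rather than all pairs.
#'
#' @inheritParams log_likelihood_5c
#' @return A list cache; treat as opaque.
#' @export
make_pair_cache <- function(conf, data, params) {
  validate_conformation(conf)
  n <- n_fragments(data)
  p <- data$pairs
  adj <- lapply(seq_len(n), function(k) which(p$i == k | p$j == k))
  d <- pair_dists(conf, p)
  cache <- list(adj = adj, n = n)
  if (data$technology == "5C") {
    mu <- params$psi * d^(-params$alpha)
    terms <- stats::dnorm(p$value, mean = mu, sd = p$sigma, log = TRUE)
    terms[d == 0] <- -Inf
    cache$terms <- terms
    cache$total <- sum(terms)
  } else {
    if (all(p$value == 0))
      stop("all-zero Hi-C count matrix: nothing to fit", call. = FALSE)
    q <- d^(-params$alpha)
    cache$q <- q
    cache$total <- hic_total_from_q(q, p$value, params$kappa)
  }
  cache
}

hic_total_from_q <- function(q, v, kappa) {
  if (any(!is.finite(q))) return(-Inf)
  beta <- sum(v) / sum(q)
  mu <- beta * q
  sum(stats::dnorm(v, mean = mu, sd = sqrt(mu + kappa), log = TRUE))
}

#' Incremental log-posterior after moving a single point
#'
#' Recomputes only the per-pair terms involving `moved_index` and returns
#' the updated log posterior together with the updated cache, matching a
#' full recomputation to within floating-point accumulation error.
#' For Hi-C the `d^(-alpha)` cache is updated locally but the density sum
#' is re-evaluated over all pairs because the scale normalizer `beta`
#' couples every pair mean.
#'
#' @param conf Current conformation (before the move).
#' @param cache Cache from [make_pair_cache()], consistent with `conf`.
#' @param moved_index Fragment index of the moved point.
#' @param new_point Numeric length-3 coordinate.
#' @param data,params Dataset and model parameters.
#' @param check Debug flag: verify cache consistency against a full
#'   recomputation before applying the move (slow; default `FALSE`).
#' @return `list(log_posterior = <new value>, cache = <updated cache>)`.
#'   The returned cache reflects the *moved* conformation; the caller is
#'   responsible for discarding it if the move is rejected.
#' @export
delta_log_posterior <- function(conf, cache, moved_index, new_point,
                                data, params, check = FALSE) {
  stopifnot(length(new_point) == 3L, all(is.finite(new_point)))
  moved_index <- as.integer(moved_index)
  if (moved_index < 1L || moved_index > nrow(conf))
    stop("moved_index out of range", call. = FALSE)
  if (isTRUE(check)) {
    ref <- make_pair_cache(conf, data, params)
    ok <- if (data$technology == "5C")
      isTRUE(all.equal(ref$terms, cache$terms, tolerance = 1e-9))
    else isTRUE(all.equal(ref$q, cache$q, tolerance = 1e-9))
    if (!ok)
      stop("pair cache inconsistent with conformation", call. = FALSE)
  }
  idx <- cache$adj[[moved_index]]
  p <- data$pairs
  newconf_row <- matrix(new_point, nrow = 1L)
  other <- ifelse(p$i[idx] == moved_index, p$j[idx], p$i[idx])
  dx <- conf[other, , drop = FALSE] -
    newconf_row[rep(1L, length(other)), , drop = FALSE]
  dnew <- sqrt(rowSums(dx * dx))
  if (data$technology == "5C") {
    tnew <- stats::dnorm(p$value[idx],
                         mean = params$psi * dnew^(-params$alpha),
                         sd = p$sigma[idx], log = TRUE)
    tnew[dnew == 0] <- -Inf
    old <- cache$terms[idx]
    cache$terms[idx] <- tnew
    if (any(!is.finite(tnew)) || any(!is.finite(old)) ||
        !is.finite(cache$total)) {
      cache$total <- sum(cache$terms)        # avoid -Inf - -Inf = NaN
    } else {
      cache$total <- cache$total - sum(old) + sum(tnew)
    }
  } else {
    cache$q[idx] <- dnew^(-params$alpha)
    cache$total <- hic_total_from_q(cache$q, p$value, params$kappa)
  }
  list(log_posterior = cache$total, cache = cache)
}
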