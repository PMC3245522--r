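## Gold-standard conformations and simulated 5C/Hi-C datasets for
## validation: known structures plus the observation noise models, so
## that recovery can be measured against a known truth.

#' Construct a gold-standard conformation
#'
#' @param kind One of:
#'   * `random_walk` - fixed-step random walk (steps uniform on the
#'     sphere of radius `step_length`);
#'   * `helix` - regular helix (`radius`, `pitch` per point,
#'     `turn_points` points per full turn);
#'   * `two_domain` - two Gaussian blobs of `spread` sd centered
#'     `separation` apart along x (first half / second half of the
#'     chain), for clustering and condition-separation tests;
#'   * `hairpin` - two antiparallel straight strands `separation` apart,
#'     re-entrant geometry for looping tests.
#' @param n Number of points (>= 2).
#' @param seed Optional seed (stochastic kinds only).
#' @param step_length Random-walk / hairpin step (default 1).
#' @param radius,pitch,turn_points Helix geometry.
#' @param separation Two-domain center offset or hairpin strand gap.
#' @param spread Two-domain within-cluster sd.
#' @return n x 3 conformation matrix.
#' @export
make_structure <- function(kind = c("random_walk", "helix", "two_domain",
                                    "hairpin"),
                           n, seed = NULL, step_length = 1,
                           radius = 2, pitch = 0.3, turn_points = 10,
                           separation = 1, spread = 0.5) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    random_walk = {
      v <- matrix(stats::rnorm(3L * (n - 1L)), ncol = 3L)
      v <- v / sqrt(rowSums(v * v)) * step_length
      rbind(0, apply(v, 2L, cumsum))
    },
    helix = {
      t <- seq_len(n) - 1L
      th <- 2 * pi * t / turn_points
      cbind(radius * cos(th), radius * sin(th), pitch * t)
    },
    two_domain = {
      n1 <- floor(n / 2)
      pts <- matrix(stats::rnorm(3L * n, sd = spread), ncol = 3L)
      pts[seq_len(n1), 1L] <- pts[seq_len(n1), 1L] - separation / 2
      pts[-seq_len(n1), 1L] <- pts[-seq_len(n1), 1L] + separation / 2
      pts
    },
    hairpin = {
      m1 <- ceiling(n / 2); m2 <- n - m1
      up <- cbind((seq_len(m1) - 1L) * step_length, 0, 0)
      down <- cbind((m1 - seq_len(m2)) * step_length, separation, 0)
      rbind(up, down)
    })
}

#' Regular synthetic fragment map
#'
#' Contiguous equal-length fragments, convenient as genomic metadata for
#' simulated datasets.
#'
#' @param n Number of fragments.
#' @param frag_len Fragment length in bp (default 100).
#' @param chrom Chromosome label.
#' @param start Genomic start of the first fragment.
#' @return A [fragment_map()].
#' @export
make_fragment_map <- function(n, frag_len = 100, chrom = "chrS", start = 0) {
  s <- start + (seq_len(n) - 1L) * frag_len
  fragment_map(chrom = chrom, start = s, end = s + frag_len)
}

#' 5C noise specification
#'
#' Per-pair heteroscedastic Gaussian noise mimicking replicate-derived
#' standard deviations: `sigma(i,j) = cv * IF(i,j) + sigma0`.  With
#' `mode = "none"` the data are exact and sigma is reported as a small
#' positive floor so likelihoods stay proper.
#'
#' @param mode `"per_pair_sigma"` (default) or `"none"`.
#' @param cv Coefficient of variation (default 0.1).
#' @param sigma0 Additive floor; default `0.01 * mean(IF)` computed at
#'   simulation time.
#' @return `list` of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("per_pair_sigma", "none"), cv = 0.1,
                       sigma0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(cv >= 0, is.null(sigma0) || sigma0 >= 0)
  structure(list(mode = mode, cv = cv, sigma0 = sigma0),
            class = "noise_spec")
}

#' Pairs measurable under the 5C even-odd primer design
#'
#' Forward/reverse primer assignment means only pairs of one even- and
#' one odd-numbered fragment are measured.
#'
#' @param n Number of fragments.
#' @return `data.frame(i, j)` with `i < j` and `i + j` odd.
#' @export
even_odd_pairs <- function(n) {
  all <- t(utils::combn(n, 2L))
  keep <- (all[, 1L] + all[, 2L]) %% 2L == 1L
  data.frame(i = all[keep, 1L], j = all[keep, 2L])
}

all_pairs <- function(n) {
  all <- t(utils::combn(n, 2L))
  data.frame(i = all[, 1L], j = all[, 2L])
}

#' Simulate a 5C dataset from a known conformation
#'
#' For every measurable pair, the observed IF is drawn from a normal
#' distribution centered at `expected_if(d)` with standard deviation
#' `cv * IF + sigma0`; negative draws are truncated at 0 (IFs are
#' nonnegative) and the truncation count is recorded in the
#' `"n_truncated"` attribute.  The per-pair sigma is stored in the
#' dataset, exactly as the 5C likelihood expects.
#'
#' @param conf Gold-standard conformation.
#' @param fmap [fragment_map()] (defaults to [make_fragment_map()]).
#' @param params [model_params()].
#' @param noise [noise_spec()].
#' @param even_odd_mask Restrict to even-odd measurable pairs
#'   (default TRUE, matching the 5C primer design).
#' @param seed Optional seed.
#' @return A 5C [if_dataset()].
#' @export
simulate_5c <- function(conf, fmap = NULL, params = model_params(),
                        noise = noise_spec(), even_odd_mask = TRUE,
                        seed = NULL) {
  validate_conformation(conf)
  n <- nrow(conf)
  if (is.null(fmap)) fmap <- make_fragment_map(n)
  if (!is.null(seed)) set.seed(seed)
  pr <- if (even_odd_mask) even_odd_pairs(n) else all_pairs(n)
  d <- sqrt(rowSums((conf[pr$i, , drop = FALSE] -
                       conf[pr$j, , drop = FALSE])^2))
  mu <- expected_if(d, params)
  sigma0 <- if (is.null(noise$sigma0)) 0.01 * mean(mu) else noise$sigma0
  n_trunc <- 0L
  if (noise$mode == "none") {
    value <- mu
    sigma <- rep(max(sigma0, 1e-12), length(mu))
  } else {
    sigma <- noise$cv * mu + sigma0
    value <- stats::rnorm(length(mu), mean = mu, sd = sigma)
    n_trunc <- sum(value < 0)
    value[value < 0] <- 0
  }
  out <- if_dataset(fmap, data.frame(i = pr$i, j = pr$j, value = value,
                                     sigma = sigma),
                    technology = "5C")
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Simulate a Hi-C dataset from a known conformation
#'
#' Read counts are multinomial over measurable pairs with proportions
#' `p(i,j)` proportional to `d(i,j)^(-alpha)` and a fixed sequencing
#' total, so simulated counts always sum exactly to `total_reads`.
#'
#' @param conf Gold-standard conformation.
#' @param fmap Optional [fragment_map()] (default: contiguous 1 Mb bins).
#' @param params [model_params()].
#' @param total_reads Total read count to distribute (> 0).
#' @param seed Optional seed.
#' @return A Hi-C [if_dataset()].
#' @export
simulate_hic <- function(conf, fmap = NULL, params = model_params(),
                         total_reads = 1e6, seed = NULL) {
  validate_conformation(conf)
  stopifnot(total_reads > 0)
  n <- nrow(conf)
  if (is.null(fmap)) fmap <- make_fragment_map(n, frag_len = 1e6)
  if (!is.null(seed)) set.seed(seed)
  pr <- all_pairs(n)
  d <- sqrt(rowSums((conf[pr$i, , drop = FALSE] -
                       conf[pr$j, , drop = FALSE])^2))
  w <- d^(-params$alpha)
  counts <- as.vector(stats::rmultinom(1L, size = total_reads,
                                       prob = w / sum(w)))
  if_dataset(fmap, data.frame(i = pr$i, j = pr$j, value = counts,
                              sigma = NA_real_),
             technology = "HiC")
}
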