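## Rotation/reflection-invariant comparison and clustering of sampled
## conformations, reliable-substructure detection, and superposition.

#' Distance between two conformations
#'
#' Euclidean norm of the difference between the two intra-structure
#' distance matrices over unordered pairs:
#' `sqrt(sum_{i<j} (D_S(i,j) - D_T(i,j))^2)`.  Because only internal
#' distances enter, the metric is invariant under translation, rotation
#' and reflection of either structure; in particular mirror images
#' (enantiomers, indistinguishable from interaction-frequency data) are
#' at distance zero.
#'
#' @param s,t Conformations (n x 3 matrices) with equal n.
#' @return Nonnegative scalar.
#' @export
structure_distance <- function(s, t) {
  validate_conformation(s); validate_conformation(t)
  if (nrow(s) != nrow(t))
    stop("conformations have different numbers of points", call. = FALSE)
  ds <- stats::dist(s); dt <- stats::dist(t)
  sqrt(sum((ds - dt)^2))
}

flatten_distances <- function(structures)
  t(vapply(structures, function(s) as.vector(stats::dist(s)),
           numeric(nrow(structures[[1L]]) * (nrow(structures[[1L]]) - 1L) / 2L)))

#' All pairwise structure distances of an ensemble
#'
#' @param ens A `conf_ensemble` (or plain list of conformations), N >= 2.
#' @return N x N symmetric matrix of [structure_distance()] values.
#' @export
ensemble_distance_matrix <- function(ens) {
  structures <- if (inherits(ens, "conf_ensemble")) ens$structures else ens
  if (length(structures) < 2L)
    stop("need at least two structures", call. = FALSE)
  # structure_distance(S, T) is the Euclidean distance between the
  # flattened upper triangles of D_S and D_T, so one dist() call suffices
  m <- as.matrix(stats::dist(flatten_distances(structures)))
  dimnames(m) <- NULL
  m
}

#' Ward hierarchical clustering of an ensemble
#'
#' Agglomerative Ward linkage (`hclust` method `"ward.D2"`, i.e. Ward's
#' criterion on Euclidean distances, which the structure metric is) cut
#' at the requested number of clusters.  The cluster count is a user
#' choice; inspect `$hclust$height` (merge heights) to pick one.
#'
#' @param dm Distance matrix from [ensemble_distance_matrix()].
#' @param n_clusters Number of flat clusters, between 1 and N.
#' @return `list(hclust, labels, sizes, weights)`; weights are cluster
#'   sizes divided by N and sum to 1.
#' @export
ward_cluster <- function(dm, n_clusters) {
  n <- nrow(dm)
  if (!is.numeric(n_clusters) || length(n_clusters) != 1L ||
      n_clusters < 1 || n_clusters > n)
    stop("n_clusters must be between 1 and the ensemble size", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dm), method = "ward.D2")
  labels <- stats::cutree(hc, k = n_clusters)
  sizes <- as.integer(table(labels))
  list(hclust = hc, labels = unname(labels), sizes = sizes,
       weights = sizes / n)
}

#' k-means cross-check of the Ward clustering
#'
#' Runs k-means on the flattened upper-triangle intra-structure distance
#' vectors (so the representation, like the Ward metric, is invariant to
#' rigid motions and reflections) and reports labels for cross-method
#' agreement checks via [label_agreement()].
#'
#' @param ens `conf_ensemble` or list of conformations.
#' @param n_clusters Number of clusters.
#' @param seed Seed for the k-means starts.
#' @param nstart Number of random starts (default 10).
#' @return Integer label vector.
#' @export
kmeans_check <- function(ens, n_clusters, seed = 1, nstart = 10L) {
  structures <- if (inherits(ens, "conf_ensemble")) ens$structures else ens
  x <- flatten_distances(structures)
  set.seed(seed)
  unname(stats::kmeans(x, centers = n_clusters, nstart = nstart)$cluster)
}

#' Fraction of agreement between two labelings, up to relabeling
#'
#' Cluster identities are arbitrary, so agreement is maximized over
#' permutations of the second labeling (exhaustive for <= 7 clusters,
#' greedy confusion-matrix matching beyond).
#'
#' @param a,b Integer label vectors of equal length.
#' @return Fraction in `[0, 1]` of positions agreeing after the best
#'   relabeling of `b`.
#' @export
label_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- sort(unique(a)); lb <- sort(unique(b))
  k <- max(length(la), length(lb))
  conf <- table(factor(a, levels = la), factor(b, levels = lb))
  if (k <= 7L) {
    perms <- perms_of(seq_along(lb))
    best <- 0L
    for (p in perms) {
      hits <- sum(conf[cbind(seq_along(la)[seq_len(min(length(la),
                                                       length(lb)))],
                             p[seq_len(min(length(la), length(lb)))])])
      if (hits > best) best <- hits
    }
    best / length(a)
  } else {
    cm <- as.matrix(conf); hits <- 0L
    while (any(cm >= 0) && nrow(cm) > 0 && ncol(cm) > 0) {
      w <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
      hits <- hits + cm[w[1L], w[2L]]
      cm <- cm[-w[1L], -w[2L], drop = FALSE]
    }
    hits / length(a)
  }
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(perms_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Cluster representatives and weights
#'
#' For each cluster, the member with the highest log posterior (ties:
#' earliest by chain then iteration, i.e. first occurrence) represents
#' it, weighted by the fraction of the ensemble it contains.
#'
#' @param ens A `conf_ensemble`.
#' @param labels Integer cluster labels covering the ensemble.
#' @return `data.frame(cluster, structure, chain, iteration,
#'   log_posterior, size, weight)`; weights sum to 1.
#' @export
representatives <- function(ens, labels) {
  N <- length(ens$structures)
  if (length(labels) != N || N == 0L)
    stop("labels must cover the ensemble", call. = FALSE)
  cl <- sort(unique(labels))
  rows <- lapply(cl, function(k) {
    members <- which(labels == k)
    best <- members[which.max(ens$log_posterior[members])]
    data.frame(cluster = k, structure = best,
               chain = ens$chain[best], iteration = ens$iteration[best],
               log_posterior = ens$log_posterior[best],
               size = length(members), weight = length(members) / N)
  })
  do.call(rbind, rows)
}

#' Greedy reliable-fragment subset
#'
#' Finds `k` fragments whose pairwise distances vary least across the
#' ensemble: with `s(i,j)` the standard deviation of the intra-structure
#' distance `D_X(i,j)` over members `X`, the greedy search seeds with the
#' pair minimizing `s`, then repeatedly adds the fragment that least
#' increases the subset's total pairwise `s`.  Ties are broken toward
#' lower fragment indices.  Greedy is a heuristic; for small `n` compare
#' against the exhaustive optimum.
#'
#' @param ens `conf_ensemble` or list of conformations.
#' @param k Subset size, `2 <= k <= n`.
#' @return `list(fragments, score, sd_matrix)`: fragments in the order
#'   added, total pairwise standard deviation of the subset, and the
#'   full `s(i,j)` matrix.
#' @export
reliable_subset <- function(ens, k) {
  structures <- if (inherits(ens, "conf_ensemble")) ens$structures else ens
  n <- nrow(structures[[1L]])
  if (k < 2 || k > n)
    stop("k must be between 2 and the number of fragments", call. = FALSE)
  flat <- flatten_distances(structures)       # members x pairs (col i<j)
  s_flat <- apply(flat, 2L, stats::sd)
  S <- matrix(0, n, n)
  S[lower.tri(S)] <- s_flat                    # dist() ordering is column-wise
  S <- S + t(S)
  # seed: pair with smallest s, ties toward lexicographically lowest (i, j)
  idx <- which(lower.tri(S), arr.ind = TRUE)   # idx[,1] = row > idx[,2] = col
  ord <- order(S[idx], idx[, 2L], idx[, 1L])
  best <- unname(idx[ord[1L], ])
  subset <- c(best[2L], best[1L])              # (i, j) with i < j
  while (length(subset) < k) {
    cand <- setdiff(seq_len(n), subset)
    cost <- vapply(cand, function(c) sum(S[c, subset]), numeric(1L))
    subset <- c(subset, cand[which.min(cost)]) # which.min: first = lowest id
  }
  score <- sum(S[subset, subset][upper.tri(diag(length(subset)))])
  list(fragments = subset, score = score, sd_matrix = S)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes `s` onto `t` by the optimal translation and rotation; with
#' `allow_reflection` the better of the proper and mirror alignments is
#' returned (enantiomers fit interaction data equally well, so mirroring
#' before superposition is legitimate).
#'
#' @param s,t Conformations with equal n >= 3.
#' @param allow_reflection Also try the mirror image of `s`.
#' @return `list(transformed, rmsd, reflected)`.
#' @export
superpose <- function(s, t, allow_reflection = TRUE) {
  validate_conformation(s); validate_conformation(t)
  if (nrow(s) != nrow(t)) stop("mismatched sizes", call. = FALSE)
  if (nrow(s) < 3L) stop("superposition needs n >= 3", call. = FALSE)
  fit1 <- kabsch(s, t)
  if (!allow_reflection) {
    return(list(transformed = fit1$transformed, rmsd = fit1$rmsd,
                reflected = FALSE))
  }
  sm <- s; sm[, 1L] <- -sm[, 1L]
  fit2 <- kabsch(sm, t)
  if (fit2$rmsd < fit1$rmsd)
    list(transformed = fit2$transformed, rmsd = fit2$rmsd, reflected = TRUE)
  else
    list(transformed = fit1$transformed, rmsd = fit1$rmsd, reflected = FALSE)
}

kabsch <- function(s, t) {
  cs <- colMeans(s); ct <- colMeans(t)
  sc <- sweep(s, 2L, cs); tc <- sweep(t, 2L, ct)
  h <- crossprod(sc, tc)                       # 3 x 3
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # proper rotation
  transformed <- sweep(sc %*% r, 2L, ct, "+")
  rmsd <- sqrt(mean(rowSums((transformed - t)^2)))
  list(transformed = transformed, rmsd = rmsd)
}

#' Mean interaction frequency by genomic separation
#'
#' Groups measured pairs by the linear genomic distance between fragment
#' midpoints and reports the mean observed IF per bin.  Captures the
#' decay of interaction frequency with genomic distance; bins without
#' pairs are reported as `NA`, not zero.
#'
#' @param data [if_dataset()].
#' @param bins Numeric vector of bin edges (bp), length >= 2.
#' @return `data.frame(bin_low, bin_high, n_pairs, mean_if)`.
#' @export
genomic_distance_profile <- function(data, bins) {
  stopifnot(length(bins) >= 2L, !is.unsorted(bins, strictly = TRUE))
  mids <- (data$fragments$start + data$fragments$end) / 2
  sep <- abs(mids[data$pairs$i] - mids[data$pairs$j])
  grp <- cut(sep, breaks = bins, include.lowest = TRUE, right = FALSE)
  nb <- length(bins) - 1L
  mean_if <- rep(NA_real_, nb)
  n_pairs <- integer(nb)
  tab <- tapply(data$pairs$value, grp, mean)
  cnt <- tapply(rep(1L, length(sep)), grp, sum)
  present <- !is.na(tab)
  mean_if[present] <- tab[present]
  n_pairs[!is.na(cnt)] <- cnt[!is.na(cnt)]
  data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1L],
             n_pairs = n_pairs, mean_if = mean_if)
}
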