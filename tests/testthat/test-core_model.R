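test_that("pairwise_distances matches a scalar brute-force recomputation", {
  conf <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(pairwise_distances(conf)[1, 2], 5)

  conf <- rand_conf(6, seed = 42)
  D <- pairwise_distances(conf)
  expect_equal(diag(D), rep(0, 6))
  expect_identical(D, t(D))
  for (i in 1:6) for (j in 1:6) {
    dd <- sqrt((conf[i, 1] - conf[j, 1])^2 + (conf[i, 2] - conf[j, 2])^2 +
                 (conf[i, 3] - conf[j, 3])^2)
    expect_equal(D[i, j], dd)
  }
  expect_error(pairwise_distances(rbind(c(0, 0, NA))), "non-finite")
})

test_that("expected_if and if_to_distance are exact inverses", {
  p <- model_params(alpha = 2, psi = 1)
  expect_equal(expected_if(2, p), 0.25)
  expect_equal(expected_if(1, model_params(alpha = 1.7, psi = 3.3)), 3.3)
  # strictly decreasing
  expect_gt(expected_if(2, model_params(alpha = 1)),
            expected_if(4, model_params(alpha = 1)))
  expect_equal(if_to_distance(0.25, p), 2)
  # hand-evaluated (psi/IF)^(1/alpha): nm scale anchor
  expect_equal(if_to_distance(1, model_params(alpha = 2, psi = 2500)), 50)
  # roundtrip on a grid
  for (d in c(1e-3, 0.5, 7.3, 120)) {
    pp <- model_params(alpha = 1.4, psi = 6)
    expect_equal(if_to_distance(expected_if(d, pp), pp), d,
                 tolerance = 1e-12)
  }
  expect_error(expected_if(0, p), "> 0")
  expect_error(expected_if(-1, p), "> 0")
  expect_error(if_to_distance(0, p), "> 0")
})

test_that("5C log-likelihood matches per-pair Gaussian log densities", {
  p <- model_params(alpha = 2, psi = 1)
  fmap <- make_fragment_map(2)
  conf <- rbind(c(0, 0, 0), c(2, 0, 0))
  # IF exactly at the mean, sigma = 1 -> standard normal log density at 0
  data <- if_dataset(fmap, data.frame(i = 1, j = 2, value = 0.25, sigma = 1))
  expect_equal(log_likelihood_5c(conf, data, p), -0.5 * log(2 * pi))
  expect_equal(log_likelihood_5c(conf, data, p), -0.918939,
               tolerance = 1e-6)
  # one-sigma deviation (sigma = 1)
  data1 <- if_dataset(fmap, data.frame(i = 1, j = 2, value = 0.25 + 1,
                                       sigma = 1))
  expect_equal(log_likelihood_5c(conf, data1, p), -0.5 * log(2 * pi) - 0.5)
  # general sigma: one-sigma deviation costs exactly 1/2 nat
  data2 <- if_dataset(fmap, data.frame(i = 1, j = 2, value = 0.25 + 0.3,
                                       sigma = 0.3))
  data2b <- if_dataset(fmap, data.frame(i = 1, j = 2, value = 0.25,
                                        sigma = 0.3))
  expect_equal(log_likelihood_5c(conf, data2, p),
               log_likelihood_5c(conf, data2b, p) - 0.5)

  # 10 seeded pairs vs a scalar loop
  set.seed(7)
  n <- 5
  conf <- rand_conf(n, seed = 7)
  prs <- t(combn(n, 2))
  pick <- sample(nrow(prs), 10)
  pairs <- data.frame(i = prs[pick, 1], j = prs[pick, 2],
                      value = runif(10, 0.1, 2), sigma = runif(10, 0.1, 1))
  data <- if_dataset(make_fragment_map(n), pairs)
  ref <- 0
  for (r in seq_len(10)) {
    d <- sqrt(sum((conf[pairs$i[r], ] - conf[pairs$j[r], ])^2))
    mu <- 1 * d^(-2)
    s <- max(pairs$sigma[r], 1e-6 * max(pairs$value))
    ref <- ref + (-0.5 * log(2 * pi * s^2) -
                    (pairs$value[r] - mu)^2 / (2 * s^2))
  }
  expect_equal(log_likelihood_5c(conf, data, p), ref)
  # coincident measured points -> -Inf sentinel, not an error
  conf0 <- conf; conf0[pairs$j[1], ] <- conf0[pairs$i[1], ]
  expect_identical(log_likelihood_5c(conf0, data, p), -Inf)
})

test_that("Hi-C log-likelihood uses beta-normalized means, var = mu + kappa", {
  p <- model_params(alpha = 2, psi = 1, kappa = 10, technology = "HiC")
  fmap <- make_fragment_map(2, frag_len = 1e6)
  conf <- rbind(c(0, 0, 0), c(1, 0, 0))
  # single pair: beta matches the observation exactly -> density at mean
  data <- if_dataset(fmap, data.frame(i = 1, j = 2, value = 90,
                                      sigma = NA), technology = "HiC")
  expect_equal(log_likelihood_hic(conf, data, p),
               -0.5 * log(2 * pi * 100))

  # 5x5 seeded count matrix vs scalar recomputation
  set.seed(11)
  n <- 5
  conf <- rand_conf(n, seed = 11)
  prs <- t(combn(n, 2))
  counts <- rpois(nrow(prs), 50)
  data <- if_dataset(make_fragment_map(n, 1e6),
                     data.frame(i = prs[, 1], j = prs[, 2], value = counts,
                                sigma = NA), technology = "HiC")
  d <- sqrt(rowSums((conf[prs[, 1], ] - conf[prs[, 2], ])^2))
  q <- d^(-2)
  beta <- sum(counts) / sum(q)
  ref <- 0
  for (r in seq_along(counts)) {
    mu <- beta * q[r]; v <- mu + 10
    ref <- ref + (-0.5 * log(2 * pi * v) - (counts[r] - mu)^2 / (2 * v))
  }
  expect_equal(log_likelihood_hic(conf, data, p), ref)

  # expected count -> 0 implies variance -> kappa: a far-away pair's term
  # approaches the N(count; 0, kappa) density
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(1e6, 0, 0))
  data3 <- if_dataset(make_fragment_map(3, 1e6),
                      data.frame(i = c(1, 1), j = c(2, 3),
                                 value = c(100, 0), sigma = NA),
                      technology = "HiC")
  ll <- log_likelihood_hic(far, data3, p)
  d12 <- 1
  beta3 <- 100 / (d12^(-2) + 1e6^(-2))
  mu1 <- beta3 * 1
  term1 <- dnorm(100, mu1, sqrt(mu1 + 10), log = TRUE)
  term2_limit <- dnorm(0, 0, sqrt(10), log = TRUE)
  expect_equal(ll, term1 + term2_limit, tolerance = 1e-6)

  expect_error(log_likelihood_hic(conf, if_dataset(
    make_fragment_map(5, 1e6),
    data.frame(i = prs[, 1], j = prs[, 2], value = 0, sigma = NA),
    technology = "HiC"), p), "all-zero")
})

test_that("log posterior is invariant under rigid motions and reflections", {
  for (tech in c("5C", "HiC")) {
    p <- model_params(alpha = 2, technology = tech)
    conf <- make_structure("random_walk", 8, seed = 3)
    data <- if (tech == "5C")
      simulate_5c(conf, params = p, noise = noise_spec("none"),
                  even_odd_mask = FALSE)
    else simulate_hic(conf, params = p, total_reads = 1e4, seed = 5)
    base <- log_posterior(conf, data, p)
    moved <- rigid_motion(conf, seed = 9)
    mirrored <- rigid_motion(conf, seed = 10, reflect = TRUE)
    expect_equal(log_posterior(moved, data, p), base, tolerance = 1e-10)
    expect_equal(log_posterior(mirrored, data, p), base, tolerance = 1e-10)
  }
})

test_that("noise-free data attains its likelihood maximum at the truth", {
  g <- gold_5c(n = 9, seed = 21)
  base <- log_likelihood_5c(g$conf, g$data, g$params)
  for (s in 1:20) {
    pert <- jitter_conf(g$conf, sd = runif(1, 0.01, 1), seed = s)
    expect_lte(log_likelihood_5c(pert, g$data, g$params), base)
  }
})

test_that("delta_log_posterior matches full recomputation (5C and Hi-C)", {
  for (tech in c("5C", "HiC")) {
    p <- model_params(alpha = 2, technology = tech)
    conf <- make_structure("random_walk", 12, seed = 31)
    data <- if (tech == "5C")
      simulate_5c(conf, params = p, noise = noise_spec(cv = 0.1),
                  even_odd_mask = TRUE, seed = 32)
    else simulate_hic(conf, params = p, total_reads = 5e4, seed = 32)
    cache <- make_pair_cache(conf, data, p)
    expect_equal(cache$total, log_posterior(conf, data, p))

    # no-op move: delta exactly 0
    upd <- delta_log_posterior(conf, cache, 3L, conf[3, ], data, p)
    expect_identical(upd$log_posterior, cache$total)
    # locality: terms not involving the moved fragment stay bit-identical
    upd2 <- delta_log_posterior(conf, cache, 5L, conf[5, ] + 0.2, data, p)
    untouched <- setdiff(seq_len(nrow(data$pairs)), cache$adj[[5]])
    if (tech == "5C")
      expect_identical(upd2$cache$terms[untouched], cache$terms[untouched])
    else
      expect_identical(upd2$cache$q[untouched], cache$q[untouched])

    # 500 sequential random moves tracked incrementally vs full recompute
    set.seed(33)
    cur <- conf
    for (m in 1:500) {
      idx <- sample.int(nrow(cur), 1)
      np <- cur[idx, ] + runif(3, -0.5, 0.5)
      upd <- delta_log_posterior(cur, cache, idx, np, data, p)
      cur[idx, ] <- np
      cache <- upd$cache
      expect_equal(upd$log_posterior, log_posterior(cur, data, p),
                   tolerance = 1e-8)
    }
  }
})

test_that("cache consistency check fires in debug mode", {
  g <- gold_5c(n = 6, seed = 41)
  cache <- make_pair_cache(g$conf, g$data, g$params)
  other <- jitter_conf(g$conf, sd = 1, seed = 42)
  expect_error(
    delta_log_posterior(other, cache, 1L, other[1, ] + 0.1, g$data,
                        g$params, check = TRUE),
    "inconsistent")
  expect_silent(
    delta_log_posterior(g$conf, cache, 1L, g$conf[1, ] + 0.1, g$data,
                        g$params, check = TRUE))
})

test_that("dataset validation enforces the documented invariants", {
  fmap <- make_fragment_map(4)
  expect_error(if_dataset(fmap, data.frame(i = 1, j = 5, value = 1,
                                           sigma = 1)), "1..4")
  expect_error(if_dataset(fmap, data.frame(i = c(1, 2), j = c(2, 1),
                                           value = 1, sigma = 1)),
               "duplicate")
  expect_error(if_dataset(fmap, data.frame(i = 1, j = 2, value = -3,
                                           sigma = NA), technology = "HiC"),
               "nonnegative")
  # sigma flooring
  d <- if_dataset(fmap, data.frame(i = 1, j = 2, value = 10, sigma = 0))
  expect_gt(d$pairs$sigma, 0)
  # i > j rows are swapped into canonical order
  d2 <- if_dataset(fmap, data.frame(i = 3, j = 1, value = 1, sigma = 1))
  expect_equal(unlist(d2$pairs[1, c("i", "j")], use.names = FALSE), c(1, 3))
  expect_error(fragment_map("chr1", c(0, 50), c(100, 150)), "overlap")
})
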