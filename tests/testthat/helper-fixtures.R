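# Shared fixtures: small synthetic datasets built in code.

# random conformation with finite coordinates
rand_conf <- function(n, seed = 1, scale = 5) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
}

# noise-free 5C dataset from a known structure (all pairs unless masked)
gold_5c <- function(n = 10, seed = 1, params = model_params(),
                    mask = FALSE, noise = noise_spec(mode = "none")) {
  conf <- make_structure("random_walk", n = n, seed = seed)
  data <- simulate_5c(conf, make_fragment_map(n), params,
                      noise = noise, even_odd_mask = mask,
                      seed = seed + 1000)
  list(conf = conf, data = data, params = params)
}

# jitter every point of a conformation
jitter_conf <- function(conf, sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conf + matrix(stats::rnorm(length(conf), sd = sd), ncol = 3)
}

# rigid motion: random rotation (+ optional reflection) and translation
rigid_motion <- function(conf, seed = 1, reflect = FALSE) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]           # make proper
  if (reflect) q[, 1] <- -q[, 1]
  sweep(conf %*% q, 2, stats::rnorm(3, sd = 3), "+")
}

# list of jittered copies around a base conformation (a tight "ensemble")
jitter_ensemble <- function(conf, m, sd = 0.05, seed = 1) {
  set.seed(seed)
  lapply(seq_len(m), function(i)
    conf + matrix(stats::rnorm(length(conf), sd = sd), ncol = 3))
}

# wrap a list of structures as a conf_ensemble
as_ensemble <- function(structures, lp = NULL, chain = NULL,
                        iteration = NULL, fragments = NULL) {
  N <- length(structures)
  structure(list(structures = structures,
                 log_posterior = if (is.null(lp)) rep(0, N) else lp,
                 chain = if (is.null(chain)) rep(1L, N) else chain,
                 iteration = if (is.null(iteration)) seq_len(N)
                             else iteration,
                 fragments = fragments),
            class = "conf_ensemble")
}
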