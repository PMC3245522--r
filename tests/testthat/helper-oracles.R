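# scalar enumeration oracles for the base-level structural measures,
# independent of the vectorized implementations
oracle_density <- function(pts, i, r) {
  cnt <- 0
  for (b in seq_len(nrow(pts)))
    if (sqrt(sum((pts[b, ] - pts[i, ])^2)) <= r) cnt <- cnt + 1
  cnt
}

oracle_compaction <- function(pts, i, r) {
  ins <- function(b) sqrt(sum((pts[b, ] - pts[i, ])^2)) <= r
  lo <- i; while (lo > 1 && ins(lo - 1)) lo <- lo - 1
  hi <- i; while (hi < nrow(pts) && ins(hi + 1)) hi <- hi + 1
  hi - lo + 1
}
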