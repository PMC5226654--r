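# Independent brute-force oracles used across test files.

# joint count by explicit enumeration over matched binary layers
layer_joint_oracle <- function(a, b, lag) {
  T <- length(a)
  M <- min(max(a), max(b))
  if (M == 0) return(0)
  tot <- 0
  for (al in seq_len(M)) {
    la <- as.integer(a >= al)
    lb <- as.integer(b >= al)
    for (t in seq_len(T)) {
      tb <- t + lag
      if (tb >= 1 && tb <= T) tot <- tot + la[t] * lb[tb]
    }
  }
  tot
}

# Rand index by exhaustive enumeration of unit pairs
rand_oracle <- function(p1, p2, universe) {
  lab <- function(p) {
    l <- paste0("s", seq_along(universe))
    names(l) <- universe
    for (i in seq_along(p)) l[intersect(p[[i]], universe)] <- paste0("b", i)
    l
  }
  l1 <- lab(p1); l2 <- lab(p2)
  r <- s <- 0
  n <- length(universe)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    st <- l1[i] == l1[j]; sd <- l2[i] == l2[j]
    if (st && sd) r <- r + 1
    if (!st && !sd) s <- s + 1
  }
  (r + s) / (n * (n - 1) / 2)
}

# permutation Monte-Carlo moments of the joint count at a lag, holding the
# bin contents of both series fixed and shuffling bin order
perm_moments <- function(a, b, lag, nrep = 1e5) {
  vals <- numeric(nrep)
  for (i in seq_len(nrep))
    vals[i] <- joint_count(sample(a), sample(b), lag)
  list(mean = mean(vals), variance = stats::var(vals))
}

# two-column csv on disk for io tests
write_spike_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  path
}
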