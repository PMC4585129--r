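# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Welch t-test from the textbook formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# All subsets of 1..n that form cliques in the "not significantly
# different" graph (adjacency with unit diagonal), by brute force.
all_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  for (bits in 1:(2^n - 1)) {
    members <- which(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(members) > 1) {
      for (i in members) for (j in members)
        if (i < j && !adj[i, j]) ok <- FALSE
    }
    if (ok) out <- c(out, list(members))
  }
  out
}

# The defining property of a compact letter display: two nodes share a
# letter iff they are not significantly different, and each letter class is
# a clique of the non-significance graph.
cld_valid <- function(labels, p, alpha) {
  n <- length(labels)
  sets <- strsplit(labels, "")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    share <- length(intersect(sets[[i]], sets[[j]])) > 0
    if (share != (p[i, j] > alpha)) return(FALSE)
  }
  # every letter class must be a clique
  letters_used <- unique(unlist(sets))
  adj <- p > alpha; diag(adj) <- TRUE
  for (L in letters_used) {
    members <- which(vapply(sets, function(s) L %in% s, TRUE))
    cl <- all_cliques(adj)
    if (!any(vapply(cl, function(c0) setequal(c0, members), TRUE)))
      return(FALSE)
  }
  TRUE
}

# Enumerate every symmetric significance pattern on n nodes as a p matrix
# (0.01 = significant, 0.5 = not).
all_p_matrices <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- list()
  for (bits in 0:(2^m - 1)) {
    p <- matrix(0.5, n, n); diag(p) <- 1
    for (k in seq_len(m)) {
      if (bitwAnd(bits, 2^(k - 1)) > 0) {
        p[pairs[1, k], pairs[2, k]] <- 0.01
        p[pairs[2, k], pairs[1, k]] <- 0.01
      }
    }
    out[[length(out) + 1L]] <- p
  }
  out
}

# Small deterministic study for pipeline tests (fast: shorter run).
small_study <- function(seed = 7, noise_sd = 0.05, n_days = 947) {
  generate_study(sim_params(seed = seed, noise_sd = noise_sd,
                            n_days = n_days))
}
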