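# Independent brute-force oracles. These deliberately avoid the package's
# own computational paths: summary statistics are derived by enumerating
# pairs of individuals, AMOVA follows the defining formulas with explicit
# loops, the MST oracle is Kruskal with union-find (the package uses Prim),
# and the MSN/Steiner oracles enumerate spanning trees / Steiner point
# subsets exhaustively.

# Haplotype-level statistics by pair enumeration: HMP is the probability
# that two draws with replacement match.
oracle_summary <- function(keys) {
  n <- length(keys)
  matches <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (keys[i] == keys[j]) matches <- matches + 1L
  hmp <- matches / n^2
  list(
    hmp = hmp,
    hd = n * (1 - hmp) / (n - 1),
    dc = length(unique(keys)) / n,
    unique_fraction = sum(table(keys) == 1L) / n
  )
}

# Two-level AMOVA by direct application of the defining formulas.
oracle_amova <- function(groups) {
  X <- do.call(rbind, groups)
  N <- nrow(X)
  P <- length(groups)
  n_p <- vapply(groups, nrow, 0L)
  delta <- function(a, b) sum((a - b)^2)
  ssd_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    ssd_total <- ssd_total + delta(X[i, ], X[j, ])
  ssd_total <- ssd_total / N
  ssd_within <- 0
  for (p in seq_len(P)) {
    G <- groups[[p]]
    if (nrow(G) < 2) next
    acc <- 0
    for (i in seq_len(nrow(G) - 1)) for (j in (i + 1):nrow(G))
      acc <- acc + delta(G[i, ], G[j, ])
    ssd_within <- ssd_within + acc / n_p[p]
  }
  ssd_among <- ssd_total - ssd_within
  sigma2_w <- ssd_within / (N - P)
  n_prime <- (N - sum(n_p^2) / N) / (P - 1)
  sigma2_a <- (ssd_among / (P - 1) - sigma2_w) / n_prime
  list(ssd_total = ssd_total, ssd_among = ssd_among,
       ssd_within = ssd_within, sigma2_a = sigma2_a, sigma2_w = sigma2_w,
       phi_st = sigma2_a / (sigma2_a + sigma2_w))
}

# Weighted-L1 distances for the oracle graph algorithms.
oracle_dists <- function(V, w) {
  n <- nrow(V)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(w * abs(V[i, ] - V[j, ]))
  D
}

# Kruskal MST cost with union-find.
oracle_mst_cost <- function(V, w) {
  n <- nrow(V)
  if (n < 2) return(0)
  D <- oracle_dists(V, w)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  edges <- edges[order(D[edges]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  cost <- 0
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) { parent[a] <- b; cost <- cost + D[edges[r, 1], edges[r, 2]] }
  }
  cost
}

# Union of all minimum spanning trees by exhaustive enumeration of
# spanning-tree edge subsets (feasible for <= 6 nodes).
oracle_msn <- function(V, w) {
  n <- nrow(V)
  D <- oracle_dists(V, w)
  all_edges <- which(upper.tri(D), arr.ind = TRUE)
  m <- nrow(all_edges)
  combos <- utils::combn(m, n - 1)
  best <- Inf
  trees <- list()
  for (c2 in seq_len(ncol(combos))) {
    sel <- all_edges[combos[, c2], , drop = FALSE]
    # connectivity check via flood fill
    reach <- c(TRUE, rep(FALSE, n - 1))
    repeat {
      grew <- FALSE
      for (r in seq_len(nrow(sel))) {
        a <- sel[r, 1]; b <- sel[r, 2]
        if (xor(reach[a], reach[b])) { reach[a] <- reach[b] <- TRUE; grew <- TRUE }
      }
      if (!grew) break
    }
    if (!all(reach)) next
    cost <- sum(D[sel])
    if (cost < best - 1e-9) { best <- cost; trees <- list(sel) }
    else if (cost < best + 1e-9) trees[[length(trees) + 1L]] <- sel
  }
  ed <- do.call(rbind, trees)
  unique(ed[order(ed[, 1], ed[, 2]), , drop = FALSE])
}

# Minimal spanning cost over the sampled vectors plus any subset of up to
# (n - 2) candidate Steiner points drawn from the observed state grid.
oracle_steiner_cost <- function(V, w) {
  n <- nrow(V)
  grids <- lapply(seq_len(ncol(V)), function(l) seq(min(V[, l]), max(V[, l])))
  cand <- as.matrix(expand.grid(grids))
  keys <- apply(V, 1, paste, collapse = "|")
  cand <- cand[!apply(cand, 1, paste, collapse = "|") %in% keys, , drop = FALSE]
  best <- oracle_mst_cost(V, w)
  for (k in seq_len(min(max(0, n - 2), nrow(cand)))) {
    subs <- utils::combn(nrow(cand), k)
    for (c2 in seq_len(ncol(subs))) {
      cost <- oracle_mst_cost(rbind(V, cand[subs[, c2], , drop = FALSE]), w)
      if (cost < best) best <- cost
    }
  }
  best
}
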