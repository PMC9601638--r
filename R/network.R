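# Median-joining haplotype networks with mutation-rate-derived locus
# weights.
#
# Distances here are weighted L1 (sum_l w_l |a_l - b_l|), the convention for
# STR network construction; squared differences are reserved for R_ST. The
# minimum spanning network (MSN) is the union of all minimum spanning trees,
# optionally relaxed by epsilon; median-joining augments the node set with
# majority-consensus (median) vectors of connected triplets whenever doing
# so reduces the cost of the spanning structure.

#' Locus weights from mutation rates
#'
#' Network weights are inversely proportional to the mutation rate:
#' `w_l = round(c / mu_l)` with the constant `c` chosen so that the median
#' weight is 10, clamped to `[1, 99]`. Fast loci therefore get small weights
#' (their changes are cheap) and slow loci large ones.
#'
#' @param rates named numeric vector of per-generation mutation rates, all
#'   positive.
#' @return named integer vector of weights.
#' @export
weights_from_rates <- function(rates) {
  if (any(rates <= 0)) stop("mutation rates must be positive")
  c0 <- 10 * stats::median(rates)
  w <- round(c0 / rates)
  w <- pmin(99, pmax(1, w))
  stats::setNames(as.integer(w), names(rates))
}

#' Weighted L1 distance between repeat vectors
#'
#' `sum_l w_l |a_l - b_l|`; a metric on repeat space.
#'
#' @param a,b numeric repeat vectors over the same panel.
#' @param w numeric weights, same length.
#' @return nonnegative number.
#' @export
weighted_distance <- function(a, b, w) {
  if (length(a) != length(b) || length(a) != length(w))
    stop("repeat vectors and weights differ in length")
  sum(w * abs(a - b))
}

# Full pairwise weighted-L1 distance matrix for rows of X: manhattan
# distance on weight-scaled coordinates.
weighted_dist_matrix <- function(X, w) {
  Xs <- sweep(X, 2L, w, `*`)
  as.matrix(stats::dist(Xs, method = "manhattan"))
}

#' Condense filtered haplotypes into network nodes
#'
#' Merges identical repeat vectors into one node carrying the sample
#' multiplicity, the sample ids and the multiset of tribe/population labels.
#' Nodes are ordered lexicographically by repeat vector so downstream
#' tie-breaking is deterministic.
#'
#' @param t an adjusted, network-filtered `haplotype_table`.
#' @return list of class `condensed_nodes`: `vectors` (matrix, one row per
#'   distinct haplotype), `multiplicity`, `sample_ids` (list),
#'   `populations`, `tribes` (lists of per-node label vectors).
#' @export
condense_haplotypes <- function(t) {
  if (n_samples(t) == 0L) stop("empty haplotype table")
  M <- repeat_matrix(t)
  key <- apply(M, 1L, paste, collapse = "|")
  ord <- order(key, method = "radix")
  M <- M[ord, , drop = FALSE]
  key <- key[ord]
  meta <- t$meta[ord, , drop = FALSE]
  first <- !duplicated(key)
  vecs <- M[first, , drop = FALSE]
  idx <- match(key, key[first])
  structure(list(
    vectors = vecs,
    multiplicity = as.integer(tabulate(idx, nbins = sum(first))),
    sample_ids = split(meta$sample_id, idx),
    populations = split(meta$population, idx),
    tribes = split(meta$tribe, idx)),
    class = "condensed_nodes")
}

# Minimax connection levels: M[i, j] = weight at which i and j first join
# when edges are processed in ascending order (Kruskal levels). The MSN with
# relaxation epsilon is {(i, j): D_ij <= M_ij + epsilon}; epsilon = 0 gives
# the union of all minimum spanning trees.
minimax_levels <- function(D) {
  n <- nrow(D)
  M <- matrix(0, n, n)
  comp <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  ut <- which(upper.tri(D))
  ord <- ut[order(D[ut])]
  n_comp <- n
  for (e in ord) {
    j <- ((e - 1L) %/% n) + 1L
    i <- e - (j - 1L) * n
    ci <- comp[i]; cj <- comp[j]
    if (ci == cj) next
    a <- members[[ci]]; b <- members[[cj]]
    M[a, b] <- D[i, j]; M[b, a] <- D[i, j]
    comp[b] <- ci
    members[[ci]] <- c(a, b)
    members[cj] <- list(NULL)
    n_comp <- n_comp - 1L
    if (n_comp == 1L) break
  }
  M
}

#' Minimum spanning network edge set
#'
#' Edges belonging to some minimum spanning tree of the weighted-distance
#' graph, plus (for `epsilon > 0`) edges within `epsilon` of the level at
#' which their endpoints' components first connect.
#'
#' @param vectors numeric matrix of node repeat vectors.
#' @param w locus weights.
#' @param epsilon relaxation parameter (default 0: classical MSN).
#' @return two-column integer matrix of node index pairs (i < j).
#' @export
minimum_spanning_network <- function(vectors, w, epsilon = 0) {
  n <- nrow(vectors)
  if (n == 1L) return(matrix(integer(0), 0, 2))
  D <- weighted_dist_matrix(vectors, w)
  M <- minimax_levels(D)
  sel <- which(upper.tri(D) & D <= M + epsilon + 1e-9, arr.ind = TRUE)
  sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
}

# Prim MST cost over rows of `vectors` under weighted L1 distance, given a
# precomputed distance matrix.
mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  best <- D[1, ]
  inT <- c(TRUE, rep(FALSE, n - 1L))
  cost <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!inT)
    j <- cand[which.min(best[cand])]
    cost <- cost + best[j]
    inT[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  unname(cost)
}

# Consensus median of three repeat vectors: per locus, the coordinate-wise
# median. Repeat counts are ordered numeric characters, so the median is
# always defined; whenever two of the three states agree it equals the
# majority state, and it is the L1 Fermat point of the triplet.
triplet_median <- function(u, v, x) {
  m <- numeric(length(u))
  for (l in seq_along(u))
    m[l] <- sort(c(u[l], v[l], x[l]))[2]
  m
}

#' Median-joining haplotype network
#'
#' Builds the minimum spanning network over the condensed haplotypes, then
#' iteratively adds consensus median vectors (coordinate-wise median, which
#' equals the majority state whenever two of the three agree) of
#' MSN-connected triplets whenever the added vector strictly reduces the
#' minimum spanning tree cost, until a fixed point; obsolete medians (whose
#' removal leaves the MST cost unchanged) are pruned. Ties are broken by
#' lexicographic vector order, so the result is deterministic.
#'
#' @param nodes a `condensed_nodes` object (or a plain numeric matrix of
#'   repeat vectors, each row one haplotype of multiplicity 1).
#' @param w locus weights, see [weights_from_rates()].
#' @param epsilon MSN relaxation parameter (default 0).
#' @param triplet_scope where candidate medians are drawn from: `"all"`
#'   triplets of current nodes (exhaustive), `"msn"`-connected triplets only
#'   (the classical heuristic, much faster), or `"auto"` (exhaustive up to
#'   40 nodes, MSN-restricted beyond).
#' @param max_medians safety cap on the number of inferred vectors.
#' @return object of class `haplo_network`: `vectors` (sampled + median
#'   rows), `kind` (`"sampled"`/`"median"`), `multiplicity`, label lists,
#'   `edges` (data.frame `from`, `to`, `length`), `epsilon`, `weights` and
#'   an `igraph` graph in `$graph`.
#' @export
median_joining <- function(nodes, w, epsilon = 0,
                           triplet_scope = c("auto", "all", "msn"),
                           max_medians = 512L) {
  triplet_scope <- match.arg(triplet_scope)
  if (is.matrix(nodes))
    nodes <- structure(list(vectors = nodes,
                            multiplicity = rep(1L, nrow(nodes)),
                            sample_ids = as.list(
                              if (is.null(rownames(nodes)))
                                sprintf("n%d", seq_len(nrow(nodes)))
                              else rownames(nodes)),
                            populations = rep(list(NA_character_), nrow(nodes)),
                            tribes = rep(list(NA_character_), nrow(nodes))),
                       class = "condensed_nodes")
  V <- nodes$vectors
  n_sampled <- nrow(V)
  kind <- rep("sampled", n_sampled)
  repeat {
    ## one round: regenerate the candidate median set, then add reducing
    ## candidates greedily (lazy re-validation) until none reduces the MST
    exhaustive <- triplet_scope == "all" ||
      (triplet_scope == "auto" && nrow(V) <= 40L)
    edges <- minimum_spanning_network(V, w, epsilon)
    existing <- apply(V, 1L, paste, collapse = "|")
    cand <- list()
    consider <- function(i, j, v) {
      m <- triplet_median(V[i, ], V[j, ], V[v, ])
      mk <- paste(m, collapse = "|")
      if (!mk %in% existing && is.null(cand[[mk]])) cand[[mk]] <<- m
    }
    if (exhaustive && nrow(V) >= 3L) {
      trip <- utils::combn(nrow(V), 3L)
      for (cidx in seq_len(ncol(trip)))
        consider(trip[1, cidx], trip[2, cidx], trip[3, cidx])
    } else {
      # candidate medians from triplets u - v - x adjacent in the MSN
      adj <- vector("list", nrow(V))
      for (r in seq_len(nrow(edges))) {
        adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
        adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
      }
      for (v in seq_len(nrow(V))) {
        nb <- adj[[v]]
        if (length(nb) < 2L) next
        prs <- utils::combn(sort(nb), 2L)
        for (cidx in seq_len(ncol(prs)))
          consider(prs[1, cidx], prs[2, cidx], v)
      }
    }
    if (!length(cand) || sum(kind == "median") >= max_medians) break
    # numeric-lexicographic candidate order for deterministic tie-breaking
    cmat <- do.call(rbind, cand)
    ord <- do.call(order, as.data.frame(cmat))
    cand <- cand[ord]
    D <- weighted_dist_matrix(V, w)
    cur_cost <- mst_cost(D)
    reduction_of <- function(m) {
      dm <- colSums(w * abs(t(V) - m))
      cur_cost - mst_cost(rbind(cbind(D, dm), c(dm, 0)))
    }
    red <- vapply(cand, reduction_of, 0)
    added_any <- FALSE
    while (length(cand) && sum(kind == "median") < max_medians) {
      # lazy greedy: re-validate the stale top candidate before accepting
      top <- which.max(red)
      if (red[top] <= 1e-9) break
      true_red <- reduction_of(cand[[top]])
      runner_up <- if (length(red) > 1L) max(red[-top]) else -Inf
      if (true_red <= 1e-9) {
        red[top] <- true_red
        next
      }
      if (true_red < runner_up - 1e-9) {
        red[top] <- true_red
        next
      }
      V <- rbind(V, cand[[top]])
      kind <- c(kind, "median")
      added_any <- TRUE
      D <- weighted_dist_matrix(V, w)
      cur_cost <- mst_cost(D)
      cand <- cand[-top]; red <- red[-top]
    }
    if (added_any) next
    if (!exhaustive || length(cand) < 2L) break
    # depth-2 lookahead: a cost-neutral median may enable a reduction only
    # in combination with a second median (small node sets only)
    nm <- names(cand)
    pair_pick <- NULL
    for (a in seq_len(length(nm) - 1L)) {
      for (b in (a + 1L):length(nm)) {
        m1 <- cand[[nm[a]]]; m2 <- cand[[nm[b]]]
        V2 <- rbind(V, m1, m2)
        if (cur_cost - mst_cost(weighted_dist_matrix(V2, w)) > 1e-9) {
          pair_pick <- list(m1, m2)
          break
        }
      }
      if (!is.null(pair_pick)) break
    }
    if (is.null(pair_pick)) break
    V <- rbind(V, pair_pick[[1]], pair_pick[[2]])
    kind <- c(kind, "median", "median")
  }
  # prune medians whose removal leaves the MST cost unchanged
  repeat {
    D <- weighted_dist_matrix(V, w)
    cur_cost <- mst_cost(D)
    meds <- which(kind == "median")
    dropped <- FALSE
    for (m in meds) {
      if (abs(mst_cost(D[-m, -m, drop = FALSE]) - cur_cost) < 1e-9) {
        V <- V[-m, , drop = FALSE]
        kind <- kind[-m]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  edges <- minimum_spanning_network(V, w, epsilon)
  D <- weighted_dist_matrix(V, w)
  edge_df <- data.frame(from = edges[, 1], to = edges[, 2],
                        length = D[edges])
  mult <- c(nodes$multiplicity, rep(0L, sum(kind == "median")))
  pops <- c(nodes$populations,
            rep(list(character(0)), sum(kind == "median")))
  tribes <- c(nodes$tribes, rep(list(character(0)), sum(kind == "median")))
  ids <- c(nodes$sample_ids, rep(list(character(0)), sum(kind == "median")))
  g <- igraph::graph_from_data_frame(
    edge_df, directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(V)), kind = kind,
                          multiplicity = mult))
  igraph::E(g)$weight <- edge_df$length
  structure(list(vectors = V, kind = kind, multiplicity = mult,
                 sample_ids = ids, populations = pops, tribes = tribes,
                 edges = edge_df, epsilon = epsilon, weights = w,
                 graph = g),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("median-joining network: %d sampled + %d median nodes, %d edges (epsilon = %g)\n",
              sum(x$kind == "sampled"), sum(x$kind == "median"),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

# Total edge length of the network's spanning structure (MST cost over the
# final node set).
network_cost <- function(net) {
  mst_cost(weighted_dist_matrix(net$vectors, net$weights))
}

#' Cut long links and summarise network clusters
#'
#' Partitions the sampled haplotypes by cutting, in the spanning structure
#' over sampled nodes, links whose network path length exceeds (strictly)
#' the given quantile of link lengths. Links between sampled haplotypes are
#' measured as shortest-path distances through the network, so chains of
#' inferred median vectors along a deep split still count at their full
#' length. Reports per-cluster sample counts, label composition and purity,
#' a per-sample cluster assignment, and the modal allele per network locus
#' in each cluster (the allele profile separating the clusters).
#'
#' @param net a `haplo_network`.
#' @param label `"tribe"` or `"population"` — which annotation to summarise.
#' @param cut_quantile link-length quantile above which (strictly) links are
#'   cut; with tied maximal lengths nothing is cut, so star-like networks
#'   stay in one cluster.
#' @return list of class `network_clusters`: `n_clusters`, `assignments`
#'   (data.frame `sample_id`, `label`, `cluster`), `composition` (per
#'   cluster x label counts), `purity` (per-cluster majority-label share),
#'   `modal_profile` (cluster x locus modal repeat values).
#' @export
annotate_clusters <- function(net, label = c("tribe", "population"),
                              cut_quantile = 0.95) {
  label <- match.arg(label)
  sampled <- which(net$kind == "sampled")
  # network path distances between sampled nodes; single-linkage merge
  # heights are then exactly the spanning-link lengths over sampled nodes
  if (length(sampled) > 1L) {
    pd <- igraph::distances(net$graph, v = sampled, to = sampled,
                            weights = igraph::E(net$graph)$weight)
    hc <- stats::hclust(stats::as.dist(pd), method = "single")
    cutoff <- stats::quantile(hc$height, cut_quantile, names = FALSE)
    comp <- stats::cutree(hc, h = cutoff + 1e-12)
  } else comp <- 1L
  labs_per_node <- if (label == "tribe") net$tribes else net$populations
  rows <- list()
  for (k in seq_along(sampled)) {
    v <- sampled[k]
    ids <- net$sample_ids[[v]]
    lv <- labs_per_node[[v]]
    lv[is.na(lv)] <- "unknown"
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = unname(ids), label = unname(lv),
      component = unname(comp[k]), stringsAsFactors = FALSE)
  }
  asg <- do.call(rbind, rows)
  # renumber clusters by decreasing size
  sz <- sort(table(asg$component), decreasing = TRUE)
  asg$cluster <- match(as.character(asg$component), names(sz))
  asg$component <- NULL
  composition <- as.matrix(table(asg$cluster, asg$label))
  purity <- apply(composition, 1L, function(r) max(r) / sum(r))
  # modal repeat value per network locus within each cluster
  loci <- colnames(net$vectors)
  modal <- matrix(NA_real_, length(sz), length(loci),
                  dimnames = list(seq_along(sz), loci))
  node_cluster <- match(as.character(comp), names(sz))
  for (cl in seq_along(sz)) {
    vs <- sampled[node_cluster == cl]
    if (!length(vs)) next
    reps <- net$multiplicity[vs]
    for (l in seq_along(loci)) {
      vals <- rep(net$vectors[vs, l], reps)
      tab <- table(vals)
      modal[cl, l] <- as.numeric(names(tab)[which.max(tab)])
    }
  }
  structure(list(n_clusters = length(unique(asg$cluster)),
                 assignments = asg[, c("sample_id", "label", "cluster")],
                 composition = composition, purity = purity,
                 modal_profile = modal, cut_quantile = cut_quantile),
            class = "network_clusters")
}

#' @export
print.network_clusters <- function(x, ...) {
  cat(sprintf("network clusters: %d (cut quantile %.2f)\n",
              x$n_clusters, x$cut_quantile))
  print(x$composition)
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes GraphML or DOT (node size = multiplicity, label composition as
#' attributes) via igraph, or a plain TSV edge list.
#'
#' @param net a `haplo_network`.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "dot", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    df <- net$edges
    df$from_kind <- net$kind[df$from]
    df$to_kind <- net$kind[df$to]
    return(write_report_tsv(df, path))
  }
  g <- net$graph
  igraph::V(g)$size <- pmax(1L, net$multiplicity)
  igraph::V(g)$tribes <- vapply(net$tribes, function(x)
    paste(stats::na.omit(x), collapse = ","), "")
  igraph::V(g)$populations <- vapply(net$populations, function(x)
    paste(stats::na.omit(x), collapse = ","), "")
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
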