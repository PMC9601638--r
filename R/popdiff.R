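# Population differentiation: squared repeat-count distances, two-level
# AMOVA with R_ST-style variance components, pairwise distance matrices,
# permutation significance, and classical MDS with Kruskal stress-1.

#' Repeat-count matrix for distance and network analyses
#'
#' Extracts the numeric repeat counts at the 23 network-eligible single-copy
#' loci. The table must already be DYS389-adjusted and network-filtered so
#' every cell holds exactly one numeric value (microvariants enter as their
#' decimal value, e.g. 17.2).
#'
#' @param t an adjusted, filtered `haplotype_table`.
#' @return numeric matrix, samples x network loci, rownames = sample_ids.
#' @export
repeat_matrix <- function(t) {
  if (!t$dys389_adjusted)
    stop("apply adjust_dys389() before extracting repeat vectors")
  loci <- network_loci(t$panel)
  m <- apply(t$calls[, loci, drop = FALSE], 2L, token_value)
  if (n_samples(t) == 1L) m <- matrix(m, 1L, dimnames = list(NULL, loci))
  if (anyNA(m))
    stop("non-numeric calls at network loci; apply filter_for_network() first")
  rownames(m) <- t$meta$sample_id
  m
}

#' Squared repeat distance between two haplotypes
#'
#' Sum over loci of squared repeat-count differences — the molecular
#' distance underlying R_ST for microsatellites.
#'
#' @param a,b numeric repeat vectors over the same locus panel.
#' @return nonnegative number; zero iff the vectors are equal.
#' @export
repeat_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("repeat vectors differ in length")
  sum((a - b)^2)
}

# All pairwise squared distances for the rows of X.
squared_dist_matrix <- function(X) {
  as.matrix(stats::dist(X))^2
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared repeat-count distances among and within populations:
#' `SSD_total = (1/N) sum_{i<j} d_ij` over all samples,
#' `SSD_within = sum_p (1/n_p) sum_{i<j in p} d_ij`,
#' `sigma2_w = SSD_within / (N - P)`,
#' `sigma2_a = (SSD_among / (P - 1) - sigma2_w) / n'` with
#' `n' = (N - sum n_p^2 / N) / (P - 1)`, and
#' `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)` (R_ST when distances are
#' squared repeat differences). The raw, possibly negative Phi is kept;
#' `phi_st_clamped` floors it at zero.
#'
#' @param groups list (length >= 2) of numeric matrices, one per population,
#'   rows = individual repeat vectors over a common panel.
#' @return object of class `amova_result` with the sums of squares, degrees
#'   of freedom, variance components, `n_prime`, `phi_st` and
#'   `phi_st_clamped`.
#' @export
amova_two_level <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("AMOVA requires at least two groups")
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    if (!nrow(g)) stop("AMOVA groups must be nonempty")
    g
  })
  P <- length(groups)
  n_p <- vapply(groups, nrow, 0L)
  N <- sum(n_p)
  if (N < 3L) stop("AMOVA requires at least 3 individuals in total")
  if (N == P) stop("within-group variance undefined: every group has n = 1")
  X <- do.call(rbind, groups)
  D <- squared_dist_matrix(X)
  ssd_total <- sum(D[upper.tri(D)]) / N
  idx <- rep(seq_len(P), n_p)
  ssd_within <- sum(vapply(seq_len(P), function(p) {
    Dp <- D[idx == p, idx == p, drop = FALSE]
    sum(Dp[upper.tri(Dp)]) / n_p[p]
  }, 0))
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1L
  df_within <- N - P
  sigma2_w <- ssd_within / df_within
  n_prime <- (N - sum(n_p^2) / N) / df_among
  sigma2_a <- (ssd_among / df_among - sigma2_w) / n_prime
  denom <- sigma2_a + sigma2_w
  phi <- if (denom > 0) sigma2_a / denom else 0
  structure(list(ssd_total = ssd_total, ssd_among = ssd_among,
                 ssd_within = ssd_within, df_among = df_among,
                 df_within = df_within, sigma2_a = sigma2_a,
                 sigma2_w = sigma2_w, n_prime = n_prime,
                 phi_st = phi, phi_st_clamped = max(0, phi)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Two-level AMOVA (squared repeat-count distances)\n")
  cat(sprintf("  among groups:  SSD = %.4f, df = %d, sigma2_a = %.4f\n",
              x$ssd_among, x$df_among, x$sigma2_a))
  cat(sprintf("  within groups: SSD = %.4f, df = %d, sigma2_w = %.4f\n",
              x$ssd_within, x$df_within, x$sigma2_w))
  cat(sprintf("  Phi_ST (R_ST) = %.4f (clamped %.4f)\n",
              x$phi_st, x$phi_st_clamped))
  invisible(x)
}

#' Permutation test for AMOVA Phi_ST
#'
#' Permutes individuals across groups and reports
#' `p = (1 + #{Phi_perm >= Phi_obs}) / (n_perm + 1)`.
#'
#' @param groups as in [amova_two_level()].
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return list with `phi_obs`, `p_value`, `n_perm`.
#' @export
phi_permutation_test <- function(groups, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- amova_two_level(groups)$phi_st
  n_p <- vapply(groups, nrow, 0L)
  X <- do.call(rbind, lapply(groups, as.matrix))
  N <- nrow(X)
  idx_end <- cumsum(n_p)
  idx_start <- c(1L, idx_end[-length(idx_end)] + 1L)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)
    gperm <- lapply(seq_along(n_p), function(p)
      X[perm[idx_start[p]:idx_end[p]], , drop = FALSE])
    if (amova_two_level(gperm)$phi_st >= obs - 1e-12) hits <- hits + 1L
  }
  list(phi_obs = obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Pairwise R_ST distance matrix between groups
#'
#' Applies DYS389 adjustment (if not yet applied) and network filtering,
#' then computes the clamped pairwise AMOVA Phi_ST between every pair of
#' groups.
#'
#' @param t a `haplotype_table` (raw or adjusted).
#' @param group_by metadata field defining the groups.
#' @return object of class `rst_matrix`: list with `d` (symmetric matrix,
#'   zero diagonal), `labels`, `n` (per-group retained sample sizes) and
#'   `excluded` (network-filter report).
#' @export
rst_matrix <- function(t, group_by = "population") {
  if (!t$dys389_adjusted) t <- suppressWarnings(adjust_dys389(t))
  flt <- filter_for_network(t)
  ft <- flt$table
  labels_all <- ft$meta[[group_by]]
  if (is.null(labels_all)) stop("unknown grouping field: ", group_by)
  keep <- !is.na(labels_all)
  ft <- subset_samples(ft, which(keep))
  labels_all <- labels_all[keep]
  labs <- unique(labels_all)
  if (length(labs) < 2L)
    stop("need at least two groups after filtering")
  M <- repeat_matrix(ft)
  groups <- lapply(labs, function(g) M[labels_all == g, , drop = FALSE])
  sizes <- vapply(groups, nrow, 0L)
  if (any(sizes == 0L)) {
    warning("dropping empty group(s): ",
            paste(labs[sizes == 0L], collapse = ", "))
    labs <- labs[sizes > 0L]; groups <- groups[sizes > 0L]
    sizes <- sizes[sizes > 0L]
  }
  P <- length(labs)
  d <- matrix(0, P, P, dimnames = list(labs, labs))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    d[i, j] <- d[j, i] <-
      amova_two_level(groups[c(i, j)])$phi_st_clamped
  }
  structure(list(d = d, labels = labs,
                 n = stats::setNames(sizes, labs),
                 excluded = flt$excluded),
            class = "rst_matrix")
}

#' @export
print.rst_matrix <- function(x, ...) {
  cat(sprintf("pairwise R_ST matrix over %d groups (n = %s)\n",
              length(x$labels), paste(x$n, collapse = ", ")))
  print(round(x$d, 4))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric MDS by double-centering and eigendecomposition
#' ([stats::cmdscale()]); negative eigenvalues are truncated. Kruskal
#' stress-1 between the input distances and the embedded Euclidean distances
#' is reported on the raw distance scale:
#' `stress = sqrt(sum (d - dhat)^2 / sum d^2)`.
#'
#' @param d an `rst_matrix`, `dist` or symmetric numeric matrix.
#' @param k embedding dimension (`1 <= k <` number of objects).
#' @return list of class `mds_result` with `coordinates` (matrix, labelled
#'   rows), `stress` and `eigenvalues`.
#' @export
classical_mds <- function(d, k = 2) {
  if (inherits(d, "rst_matrix")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be symmetric")
  if (k < 1 || k >= nrow(d)) stop("need 1 <= k < number of objects")
  # cmdscale warns when fewer than k positive eigenvalues exist; the missing
  # axes are padded with zeros below, so the warning carries no information
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < k) # degenerate: cmdscale drops all-zero axes
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
  rownames(coords) <- rownames(d)
  dhat <- as.matrix(stats::dist(coords))
  num <- sum((d - dhat)[upper.tri(d)]^2)
  den <- sum(d[upper.tri(d)]^2)
  stress <- if (den > 0) sqrt(num / den) else 0
  structure(list(coordinates = coords, stress = stress,
                 eigenvalues = fit$eig),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("classical MDS: %d points in %d dimensions, stress-1 = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  invisible(x)
}
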