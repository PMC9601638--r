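# Locus weights, condensation, MSN and median-joining construction,
# checked against exhaustive spanning-tree and Steiner-point oracles.

test_that("weights are inversely proportional to mutation rates", {
  eq <- weights_from_rates(stats::setNames(rep(0.002, 5), paste0("L", 1:5)))
  expect_true(all(eq == 10L))
  two <- weights_from_rates(c(a = 0.002, b = 0.004, c = 0.002))
  expect_equal(unname(two["b"]), 5L)
  rates <- yfiler_plus_rates()[network_loci()]
  w <- weights_from_rates(rates)
  expect_true(all(w >= 1L & w <= 99L))
  # fast loci weigh less than slow loci
  expect_lt(w[["DYS627"]], w[["DYS392"]])
  expect_lt(w[["DYS576"]], w[["DYS392"]])
  # weight ordering is nonincreasing in rate
  ord <- order(rates)
  expect_true(all(diff(w[ord]) <= 0))
  expect_error(weights_from_rates(c(a = 0)), "positive")
})

test_that("condensation merges identical vectors and keeps label multisets", {
  t <- make_table(DYS19 = c("15", "15", "15", "15", "15", "16", "16"),
                  tribe = c("A", "A", "A", "B", "B", "B", "B"))
  nodes <- condense_haplotypes(adjust_dys389(t))
  expect_equal(nrow(nodes$vectors), 2L)
  expect_equal(sort(nodes$multiplicity), c(2L, 5L))
  expect_equal(sum(nodes$multiplicity), 7L)
  big <- which(nodes$multiplicity == 5L)
  comp <- table(nodes$tribes[[big]])
  expect_equal(comp[["A"]], 3L)
  expect_equal(comp[["B"]], 2L)
  # all distinct -> node count equals sample count
  t2 <- adjust_dys389(make_table(DYS19 = as.character(11:15)))
  expect_equal(nrow(condense_haplotypes(t2)$vectors), 5L)
})

test_that("weighted distance equals the brute-force loop and scales linearly", {
  set.seed(31)
  for (rep in 1:10) {
    a <- sample(8:20, 6, replace = TRUE)
    b <- sample(8:20, 6, replace = TRUE)
    w <- sample(1:20, 6, replace = TRUE)
    brute <- 0
    for (l in seq_along(a)) brute <- brute + w[l] * abs(a[l] - b[l])
    expect_equal(weighted_distance(a, b, w), brute)
  }
  expect_equal(weighted_distance(c(14, 12), c(14, 12), c(10, 10)), 0)
  expect_equal(weighted_distance(c(14), c(16), c(10)), 20)
  expect_error(weighted_distance(1:3, 1:3, 1:2), "length")
})

test_that("MSN equals the union of all minimum spanning trees", {
  # two nodes -> single edge; three equidistant nodes -> all three edges
  expect_equal(nrow(minimum_spanning_network(rbind(c(10), c(12)), 1)), 1L)
  tri <- minimum_spanning_network(rbind(c(0, 0), c(2, 0), c(1, 1)), c(1, 1))
  expect_equal(nrow(tri), 3L)
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    V <- unique(matrix(sample(10:13, n * 3, replace = TRUE), n, 3))
    if (nrow(V) < 3) next
    w <- sample(1:3, 3, replace = TRUE)
    got <- minimum_spanning_network(V, w)
    want <- oracle_msn(V, w)
    expect_equal(unname(got), unname(want))
  }
})

test_that("median-joining recovers stars and the documented triplet median", {
  # star data: founder + one-step neighbours stays a star with no medians
  founder <- rep(14, 5)
  V <- rbind(founder,
             t(vapply(1:6, function(k) {
               v <- founder; l <- ((k - 1) %% 5) + 1
               v[l] <- v[l] + if (k > 5) -1 else 1; v
             }, founder)))
  rownames(V) <- NULL
  net <- median_joining(V, rep(1, 5))
  expect_equal(sum(net$kind == "median"), 0L)
  expect_equal(nrow(net$edges), 6L)
  deg <- tabulate(c(net$edges$from, net$edges$to), nrow(V))
  expect_equal(max(deg), 6L) # the founder is the hub

  # documented three-node instance: consensus median closes the triangle
  V3 <- rbind(c(14, 12, 10), c(15, 13, 10), c(15, 12, 11))
  net3 <- median_joining(V3, rep(1, 3))
  expect_equal(sum(net3$kind == "median"), 1L)
  expect_equal(unname(net3$vectors[net3$kind == "median", ]), c(15, 12, 10))
  expect_equal(ystrkit:::network_cost(net3), 3)

  # two nodes: a single edge, no medians
  net2 <- median_joining(rbind(c(10, 10), c(12, 10)), c(1, 1))
  expect_equal(sum(net2$kind == "median"), 0L)
  expect_equal(nrow(net2$edges), 1L)
})

test_that("median-joining cost matches exhaustive Steiner enumeration", {
  set.seed(42)
  checked <- 0
  for (rep in 1:15) {
    n <- sample(3:5, 1)
    V <- matrix(sample(10:12, n * 3, replace = TRUE), n, 3)
    V <- V[!duplicated(apply(V, 1, paste, collapse = "|")), , drop = FALSE]
    if (nrow(V) < 3) next
    w <- sample(1:3, 3, replace = TRUE)
    net <- median_joining(V, w)
    mst0 <- oracle_mst_cost(V, w)
    cost <- ystrkit:::network_cost(net)
    expect_lte(cost, mst0 + 1e-9)
    expect_equal(cost, oracle_steiner_cost(V, w), tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("network structure is invariant to weight scaling and stays connected", {
  set.seed(77)
  V <- unique(matrix(sample(10:13, 5 * 4, replace = TRUE), 5, 4))
  w <- sample(1:3, 4, replace = TRUE)
  n1 <- median_joining(V, w)
  n2 <- median_joining(V, w * 7)
  expect_equal(n1$vectors, n2$vectors)
  expect_equal(n1$edges[, c("from", "to")], n2$edges[, c("from", "to")])
  expect_equal(n2$edges$length, n1$edges$length * 7)
  expect_true(igraph::is_connected(n1$graph))
  # every sampled haplotype appears exactly once
  expect_equal(sum(n1$kind == "sampled"), nrow(V))
})

test_that("deep founder splits are recovered as distinct clusters", {
  founderA <- default_founder()
  founderB <- default_founder()
  founderB$DYS570 <- 14; founderB$DYS449 <- 32; founderB$DYS481 <- 19
  simA <- simulate_tribe(founderA, 25, 8, tribe = "A", id_prefix = "A",
                         seed = 101)
  simB <- simulate_tribe(founderB, 25, 8, tribe = "B", id_prefix = "B",
                         seed = 102)
  t <- bind_tables(simA$table, simB$table)
  ft <- filter_for_network(adjust_dys389(t))$table
  w <- weights_from_rates(yfiler_plus_rates()[network_loci()])
  net <- median_joining(condense_haplotypes(ft), w)
  cl <- annotate_clusters(net, label = "tribe")
  # major clusters (>= 5% of samples) = the two founders
  comp <- table(cl$assignments$cluster)
  major <- as.integer(names(comp)[comp >= 0.05 * n_samples(ft)])
  expect_equal(length(major), 2L)
  # recovery: samples whose cluster majority label matches their own label
  tab <- table(cl$assignments$cluster, cl$assignments$label)
  recovery <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(recovery, 0.95)
  # purity rows are proper proportions
  expect_true(all(cl$purity > 0 & cl$purity <= 1))

  # a single founder yields a single cluster
  net1 <- median_joining(condense_haplotypes(
    filter_for_network(adjust_dys389(simA$table))$table), w)
  cl1 <- annotate_clusters(net1, label = "tribe")
  comp1 <- table(cl1$assignments$cluster)
  expect_equal(sum(comp1 >= 0.05 * sum(comp1)), 1L)
})

test_that("network export formats are written and reloadable", {
  V <- rbind(c(14, 12, 10), c(15, 13, 10), c(15, 12, 11))
  net <- median_joining(V, c(1, 1, 1))
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, gml, "graphml")
  write_network(net, dot, "dot")
  write_network(net, tsv, "edge_tsv")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$vectors))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true(any(grepl("graph", readLines(dot))))
  ed <- utils::read.delim(tsv)
  expect_equal(nrow(ed), nrow(net$edges))
})
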