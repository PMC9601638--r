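# End-to-end orchestration: read -> forensic stats -> AMOVA / R_ST / MDS ->
# median-joining network, with per-stage accounting written to a run log.

#' Run the full Y-STR analysis pipeline
#'
#' Executes the analysis stages in order — haplotype-level forensic summary,
#' per-locus forensic parameters, abnormal-allele report, pairwise R_ST with
#' classical MDS, and the mutation-rate-weighted median-joining network with
#' cluster annotation — and writes each product to `output_dir` as TSV
#' (network additionally as GraphML and DOT). Every input sample is
#' accounted for per stage: either analysed or listed in the exclusion
#' report.
#'
#' @param input path to a wide haplotype table, or a `haplotype_table`.
#' @param output_dir directory for the report bundle (created if needed).
#' @param group_by metadata field for grouping (`"population"` or
#'   `"tribe"`).
#' @param dialect input file dialect, see [read_haplotypes()].
#' @param epsilon MSN relaxation parameter for the network stage.
#' @param network_label annotation used for network clusters.
#' @param k MDS dimension (capped at number of groups - 1).
#' @param n_perm permutations for the global AMOVA significance test
#'   (0 disables).
#' @param seed integer seed for the permutation test.
#' @param rates mutation-rate table for network weights.
#' @return invisible list with the in-memory results (`summary`,
#'   `locus_stats`, `abnormal`, `rst`, `mds`, `network`, `clusters`,
#'   `excluded`, `files`).
#' @export
run_pipeline <- function(input, output_dir, group_by = "population",
                         dialect = "wide_tsv", epsilon = 0,
                         network_label = "tribe", k = 2, n_perm = 0,
                         seed = 1L, rates = yfiler_plus_rates()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  t <- if (inherits(input, "haplotype_table")) input
       else read_haplotypes(input, dialect = dialect)
  note("read %d samples, %d locus columns", n_samples(t), ncol(t$calls))
  files <- character(0)
  out <- function(name) file.path(output_dir, name)

  ## stage 1: haplotype-level forensic summary + locus parameters
  summ <- forensic_summary(t, group_by = group_by)
  summ_fmt <- summ
  summ_fmt$unique_pct <- round_half_up(summ$unique_pct, 2)
  for (cn in c("dc", "hmp", "hd")) summ_fmt[[cn]] <- round_half_up(summ[[cn]], 4)
  write_report_tsv(summ_fmt, out("summary.tsv"))
  files <- c(files, "summary.tsv")
  note("forensic summary: %d group(s) by %s", nrow(summ), group_by)
  loc <- locus_summary(t)
  loc_fmt <- loc
  for (cn in c("gd", "rmp", "pd", "pic"))
    loc_fmt[[cn]] <- round_half_up(loc[[cn]], 4)
  write_report_tsv(loc_fmt, out("locus_stats.tsv"))
  files <- c(files, "locus_stats.tsv")
  abn <- abnormal_allele_report(t)
  write_report_tsv(abn, out("abnormal_alleles.tsv"))
  files <- c(files, "abnormal_alleles.tsv")
  note("abnormal alleles: %d locus/population cell(s) with findings", nrow(abn))

  ## stage 2: preprocessing shared by distance + network stages
  ta <- suppressWarnings(adjust_dys389(t))
  flt <- filter_for_network(ta)
  write_report_tsv(flt$excluded, out("exclusions.tsv"))
  files <- c(files, "exclusions.tsv")
  note("network filter: %d retained, %d excluded",
       n_samples(flt$table), nrow(flt$excluded))

  ## stage 3: R_ST + MDS (needs >= 2 groups)
  groups <- flt$table$meta[[group_by]]
  rst <- mds <- perm <- NULL
  if (length(unique(stats::na.omit(groups))) >= 2L) {
    rst <- rst_matrix(t, group_by = group_by)
    dm <- as.data.frame(rst$d)
    dm <- cbind(group = rownames(rst$d), dm)
    write_report_tsv(dm, out("rst_matrix.tsv"))
    files <- c(files, "rst_matrix.tsv")
    keff <- min(k, length(rst$labels) - 1L)
    mds <- classical_mds(rst, k = keff)
    co <- as.data.frame(mds$coordinates)
    names(co) <- sprintf("dim%d", seq_len(ncol(co)))
    co <- cbind(group = rownames(mds$coordinates), co)
    write_report_tsv(co, out("mds_coordinates.tsv"))
    files <- c(files, "mds_coordinates.tsv")
    note("R_ST over %d groups; MDS k = %d, stress = %.4f",
         length(rst$labels), keff, mds$stress)
    if (n_perm > 0) {
      M <- repeat_matrix(flt$table)
      gl <- lapply(unique(stats::na.omit(groups)), function(g)
        M[which(groups == g), , drop = FALSE])
      perm <- phi_permutation_test(gl, n_perm = n_perm, seed = seed)
      note("global AMOVA Phi_ST = %.4f, permutation p = %.4f (%d perms)",
           perm$phi_obs, perm$p_value, n_perm)
    }
  } else {
    note("R_ST/MDS skipped: fewer than two groups by %s", group_by)
  }

  ## stage 4: median-joining network
  net <- clusters <- NULL
  if (n_samples(flt$table) >= 2L) {
    w <- weights_from_rates(rates[network_loci(t$panel)])
    nodes <- condense_haplotypes(flt$table)
    net <- median_joining(nodes, w, epsilon = epsilon)
    write_network(net, out("network.graphml"), "graphml")
    write_network(net, out("network.dot"), "dot")
    write_network(net, out("network_edges.tsv"), "edge_tsv")
    files <- c(files, "network.graphml", "network.dot", "network_edges.tsv")
    clusters <- annotate_clusters(net, label = network_label)
    write_report_tsv(clusters$assignments, out("clusters.tsv"))
    files <- c(files, "clusters.tsv")
    note("network: %d sampled + %d median nodes, %d edges, %d cluster(s)",
         sum(net$kind == "sampled"), sum(net$kind == "median"),
         nrow(net$edges), clusters$n_clusters)
  } else {
    note("network skipped: fewer than two retained haplotypes")
  }
  writeLines(log_lines, out("run_log.txt"))
  files <- c(files, "run_log.txt")
  invisible(list(summary = summ, locus_stats = loc, abnormal = abn,
                 rst = rst, mds = mds, permutation = perm, network = net,
                 clusters = clusters, excluded = flt$excluded,
                 files = file.path(output_dir, files)))
}
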