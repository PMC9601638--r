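# Preprocessing for distance and network analyses: DYS389II adjustment,
# network filtering and abnormal-allele accounting.

#' Subtract DYS389I from DYS389II
#'
#' The DYS389II amplicon contains the DYS389I repeat stretch, so its
#' independent repeat content is DYS389II minus DYS389I. Distance and network
#' computations require the adjusted form. The adjustment is applied exactly
#' once per table: a flag on the table blocks a second application. Records
#' where either locus is null or duplicated are left unadjusted and flagged.
#'
#' @param t a `haplotype_table` with raw DYS389II.
#' @return the table with DYS389II adjusted, `dys389_adjusted = TRUE`, and
#'   unadjustable or out-of-range records listed in `$dys389_flags`.
#' @export
adjust_dys389 <- function(t) {
  if (t$dys389_adjusted)
    stop("DYS389II has already been adjusted in this table")
  flags <- list()
  for (i in seq_len(nrow(t$calls))) {
    a <- parse_allele(t$calls[i, "DYS389I"])
    b <- parse_allele(t$calls[i, "DYS389II"])
    if (a$state %in% c("null", "duplicated") ||
        b$state %in% c("null", "duplicated")) {
      flags[[length(flags) + 1L]] <- data.frame(
        sample_id = t$meta$sample_id[i],
        reason = "DYS389I/DYS389II null or duplicated; left unadjusted",
        stringsAsFactors = FALSE)
      next
    }
    adj <- b$values - a$values
    t$calls[i, "DYS389II"] <- paste(.fmt_repeat(adj))
    if (adj <= 0) {
      flags[[length(flags) + 1L]] <- data.frame(
        sample_id = t$meta$sample_id[i],
        reason = sprintf("adjusted DYS389II = %s out of range", .fmt_repeat(adj)),
        stringsAsFactors = FALSE)
      warning(sprintf("sample %s: adjusted DYS389II = %s out of range",
                      t$meta$sample_id[i], .fmt_repeat(adj)), call. = FALSE)
    }
  }
  t$dys389_adjusted <- TRUE
  t$dys389_flags <- if (length(flags)) do.call(rbind, flags) else t$dys389_flags
  t
}

#' Filter haplotypes for network and R_ST analyses
#'
#' Retains records with exactly one numeric repeat value at every
#' network-eligible locus; records with a null allele (e.g. a DYS448
#' deletion) or a duplicated allele (e.g. a DYS19 copy-number gain) at any
#' network locus are excluded and reported. Microvariant alleles are ordinary
#' numeric states and are kept.
#'
#' @param t a `haplotype_table`.
#' @return list with `table` (retained records) and `excluded` (data.frame
#'   `sample_id`, `locus`, `reason`).
#' @export
filter_for_network <- function(t) {
  loci <- network_loci(t$panel)
  excl <- list()
  keep <- rep(TRUE, nrow(t$calls))
  for (i in seq_len(nrow(t$calls))) {
    for (loc in loci) {
      st <- parse_allele(t$calls[i, loc])$state
      if (st %in% c("null", "duplicated")) {
        keep[i] <- FALSE
        excl[[length(excl) + 1L]] <- data.frame(
          sample_id = t$meta$sample_id[i], locus = loc,
          reason = if (st == "null") sprintf("%s deletion (null allele)", loc)
                   else sprintf("%s duplicated allele", loc),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl)
              else data.frame(sample_id = character(0), locus = character(0),
                              reason = character(0), stringsAsFactors = FALSE)
  list(table = subset_samples(t, keep), excluded = excluded)
}

#' Abnormal allele report
#'
#' Counts null, microvariant and duplicated allele calls per locus, grouped
#' by population. Each abnormal call is counted exactly once, under its
#' state.
#'
#' @param t a `haplotype_table`.
#' @return data.frame with columns `population`, `locus`, `nulls`,
#'   `microvariants`, `duplications` (loci with at least one abnormal call
#'   only; all-zero rows are dropped).
#' @export
abnormal_allele_report <- function(t) {
  multi <- stats::setNames(t$panel$copy_class == "multi", t$panel$locus)
  rows <- list()
  for (pop in unique(t$meta$population)) {
    sel <- t$meta$population == pop
    for (loc in t$panel$locus) {
      st <- token_state(t$calls[sel, loc], multi = multi[[loc]])
      n_null <- sum(st == "null")
      n_micro <- sum(st == "microvariant")
      n_dup <- sum(st == "duplicated")
      if (n_null + n_micro + n_dup > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          population = pop, locus = loc, nulls = n_null,
          microvariants = n_micro, duplications = n_dup,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(population = character(0), locus = character(0),
                      nulls = integer(0), microvariants = integer(0),
                      duplications = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
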