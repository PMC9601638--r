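# Haplotype-level forensic statistics by direct counting, and per-locus
# forensic parameters.
#
# Haplotype identity is exact equality of all 27 locus calls, including
# multi-copy allele sets (order-insensitive via canonical tokens), null,
# duplicated and microvariant states.

#' Haplotype spectrum by direct counting
#'
#' @param t a nonempty `haplotype_table`.
#' @return object of class `haplotype_spectrum`: list with `counts` (named
#'   integer vector, one entry per distinct haplotype) and `n` (sample size).
#' @export
haplotype_spectrum <- function(t) {
  if (n_samples(t) == 0L) stop("empty haplotype table")
  counts <- table(haplotype_keys(t))
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n = n_samples(t)),
            class = "haplotype_spectrum")
}

#' Build a spectrum directly from class counts
#'
#' Convenience for working from published summary counts, e.g. a sample of
#' 59 with one haplotype observed twice: `spectrum_from_counts(c(rep(1, 57), 2))`.
#'
#' @param counts integer vector of observation counts per distinct haplotype
#'   (all >= 1).
#' @return a `haplotype_spectrum`.
#' @export
spectrum_from_counts <- function(counts) {
  counts <- as.integer(counts)
  if (!length(counts) || any(counts < 1L))
    stop("counts must be positive integers")
  structure(list(counts = stats::setNames(counts,
                                          sprintf("h%04d", seq_along(counts))),
                 n = sum(counts)),
            class = "haplotype_spectrum")
}

#' @export
print.haplotype_spectrum <- function(x, ...) {
  cat(sprintf("haplotype spectrum: n = %d, %d distinct (max count %d)\n",
              x$n, length(x$counts), max(x$counts)))
  invisible(x)
}

#' Haplotype match probability (HMP)
#'
#' Sum of squared observed haplotype frequencies: the probability that two
#' haplotypes drawn with replacement from the sample match.
#'
#' @param s a `haplotype_spectrum`.
#' @return probability in `[1/n, 1]`.
#' @export
match_probability <- function(s) {
  sum((s$counts / s$n)^2)
}

#' Haplotype diversity (HD)
#'
#' Nei-corrected probability that two sampled haplotypes differ:
#' `HD = n (1 - sum p_i^2) / (n - 1)`.
#'
#' @param s a `haplotype_spectrum` with `n >= 2`.
#' @return diversity in `[0, 1]`; 1 iff all haplotypes are distinct, 0 iff a
#'   single haplotype.
#' @export
haplotype_diversity <- function(s) {
  if (s$n < 2L) stop("haplotype diversity requires n >= 2")
  hd_from_hmp(s$n, match_probability(s))
}

#' Haplotype diversity from a known match probability
#'
#' Applies the identity `HD = n (1 - HMP) / (n - 1)`, useful when only a
#' published HMP and sample size are available.
#'
#' @param n sample size (>= 2).
#' @param hmp haplotype match probability.
#' @return diversity value.
#' @export
hd_from_hmp <- function(n, hmp) {
  if (n < 2) stop("haplotype diversity requires n >= 2")
  n * (1 - hmp) / (n - 1)
}

#' Discrimination capacity (DC)
#'
#' Ratio of distinct haplotypes to sample size.
#'
#' @param s a `haplotype_spectrum`.
#' @return proportion in `(0, 1]`.
#' @export
discrimination_capacity <- function(s) {
  length(s$counts) / s$n
}

#' Fraction of unique haplotypes
#'
#' Number of singleton haplotypes (observed exactly once) divided by the
#' sample size.
#'
#' @param s a `haplotype_spectrum`.
#' @return proportion in `[0, 1]`.
#' @export
unique_fraction <- function(s) {
  sum(s$counts == 1L) / s$n
}

#' Per-locus forensic parameters
#'
#' Allele frequencies by direct counting plus gene diversity
#' `GD = n (1 - sum p^2) / (n - 1)`, random match probability `RMP = sum p^2`,
#' power of discrimination `PD = 1 - RMP`, and polymorphism information
#' content `PIC = 1 - sum p^2 - (sum p^2)^2 + sum p^4`. Multi-copy loci are
#' summarised as unordered allele combinations (one observation per
#' individual); null alleles are excluded from the denominator by default,
#' and duplicated calls count as their own combined allele class.
#'
#' @param t a `haplotype_table`.
#' @param locus panel locus name.
#' @param count_nulls if `TRUE`, null alleles form their own frequency class
#'   instead of being dropped from the denominator.
#' @param extended if `TRUE`, also report haploid-convention PE = GD^2 and
#'   TPI = 1 / (2 (1 - GD)); these diploid-born parameters have no canonical
#'   haploid definition and are off by default.
#' @return list of class `locus_stats`: `locus`, `n` (denominator),
#'   `allele_freqs` (named, summing to 1), `n_alleles`, `gd`, `rmp`, `pd`,
#'   `pic` (and `pe`, `tpi` when `extended`).
#' @export
locus_statistics <- function(t, locus, count_nulls = FALSE, extended = FALSE) {
  if (!locus %in% t$panel$locus) stop("unknown locus: ", locus)
  multi <- t$panel$copy_class[t$panel$locus == locus] == "multi"
  tokens <- t$calls[, locus]
  if (!count_nulls) tokens <- tokens[tokens != ""]
  else tokens[tokens == ""] <- "(null)"
  if (!length(tokens)) stop("all calls null at locus ", locus)
  n <- length(tokens)
  freq <- table(tokens) / n
  p2 <- sum(freq^2)
  p4 <- sum(freq^4)
  out <- list(locus = locus, n = n,
              allele_freqs = stats::setNames(as.numeric(freq), names(freq)),
              n_alleles = length(freq),
              gd = if (n > 1) n * (1 - p2) / (n - 1) else 0,
              rmp = p2, pd = 1 - p2,
              pic = 1 - p2 - p2^2 + p4)
  if (extended) {
    out$pe <- out$gd^2
    out$tpi <- if (out$gd < 1) 1 / (2 * (1 - out$gd)) else Inf
  }
  class(out) <- "locus_stats"
  out
}

#' @export
print.locus_stats <- function(x, ...) {
  cat(sprintf("%s: %d alleles (n = %d), GD = %.4f, RMP = %.4f, PD = %.4f, PIC = %.4f\n",
              x$locus, x$n_alleles, x$n, x$gd, x$rmp, x$pd, x$pic))
  invisible(x)
}

#' Per-locus forensic parameters for the whole panel
#'
#' @inheritParams locus_statistics
#' @return data.frame with one row per panel locus.
#' @export
locus_summary <- function(t, count_nulls = FALSE, extended = FALSE) {
  rows <- lapply(t$panel$locus, function(loc) {
    s <- locus_statistics(t, loc, count_nulls = count_nulls,
                          extended = extended)
    d <- data.frame(locus = s$locus, n = s$n, n_alleles = s$n_alleles,
                    gd = s$gd, rmp = s$rmp, pd = s$pd, pic = s$pic,
                    stringsAsFactors = FALSE)
    if (extended) { d$pe <- s$pe; d$tpi <- s$tpi }
    d
  })
  do.call(rbind, rows)
}

#' Haplotype-level forensic summary per group
#'
#' One row per group with sample size, distinct haplotype count, unique
#' haplotype fraction (as percent), discrimination capacity, haplotype match
#' probability and haplotype diversity. HD is `NA` for groups of size 1.
#'
#' @param t a `haplotype_table`.
#' @param group_by metadata field to group on (`"population"`, `"tribe"` or
#'   `"clan"`); `NULL` summarises the whole table as one group.
#' @return data.frame with columns `group`, `n`, `distinct`, `unique_pct`,
#'   `dc`, `hmp`, `hd`.
#' @export
forensic_summary <- function(t, group_by = "population") {
  groups <- if (is.null(group_by)) rep("all", n_samples(t))
            else t$meta[[group_by]]
  if (is.null(groups)) stop("unknown grouping field: ", group_by)
  labs <- unique(groups[!is.na(groups)])
  rows <- lapply(labs, function(g) {
    s <- haplotype_spectrum(subset_samples(t, which(groups %in% g)))
    data.frame(group = g, n = s$n, distinct = length(s$counts),
               unique_pct = 100 * unique_fraction(s),
               dc = discrimination_capacity(s),
               hmp = match_probability(s),
               hd = if (s$n >= 2) haplotype_diversity(s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Round half-up (the rounding used in forensic report tables; base round()
# is round-half-even).
round_half_up <- function(x, digits = 4) {
  floor(x * 10^digits + 0.5) / 10^digits
}
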