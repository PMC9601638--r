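# Locus registry for the Yfiler Plus panel.
#
# The panel stores one row per assayed locus *column*: 23 single-copy loci
# plus the two multi-copy loci DYS385 (a/b) and DYF387S1 (a/b), each of which
# contributes two allele copies, for 27 named loci in total. Network
# eligibility is restricted to the 23 single-copy loci; DYS389II enters
# distance and network computations only after subtraction of DYS389I.

.YFILER_PLUS_LOCI <- data.frame(
  locus = c("DYS576", "DYS389I", "DYS635", "DYS389II", "DYS627", "DYS460",
            "DYS458", "DYS19", "YGATAH4", "DYS448", "DYS391", "DYS456",
            "DYS390", "DYS438", "DYS392", "DYS518", "DYS570", "DYS437",
            "DYS385", "DYS449", "DYS393", "DYS439", "DYS481", "DYF387S1",
            "DYS533"),
  copy_class = "single",
  n_copies = 1L,
  stringsAsFactors = FALSE
)
.YFILER_PLUS_LOCI$copy_class[.YFILER_PLUS_LOCI$locus %in% c("DYS385", "DYF387S1")] <- "multi"
.YFILER_PLUS_LOCI$n_copies[.YFILER_PLUS_LOCI$copy_class == "multi"] <- 2L

#' Bundled consensus Y-STR mutation rates
#'
#' Reads the per-locus, per-generation mutation-rate table shipped with the
#' package (consensus estimates from published father-son pair studies).
#' Individual rates may be overridden.
#'
#' @param overrides optional named numeric vector of rates replacing the
#'   bundled values for the named loci.
#' @return named numeric vector, one rate per panel locus column.
#' @export
yfiler_plus_rates <- function(overrides = NULL) {
  path <- system.file("extdata", "yfiler_plus_mutation_rates.json",
                      package = "ystrkit", mustWork = TRUE)
  rates <- unlist(jsonlite::read_json(path)$rates)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!names(overrides) %in% names(rates)))
      stop("rate overrides must be named after panel loci")
    rates[names(overrides)] <- overrides
  }
  rates
}

#' Yfiler Plus locus panel definition
#'
#' Registry of the 27-locus Yfiler Plus panel: one row per locus column
#' (multi-copy loci DYS385a/b and DYF387S1a/b are stored as one column each
#' holding an unordered allele set). Single-copy loci are network-eligible;
#' multi-copy loci are excluded from network and R_ST analyses.
#'
#' @param rates named numeric vector of per-generation mutation rates; default
#'   is the bundled consensus table, see [yfiler_plus_rates()].
#' @return data.frame with columns `locus`, `copy_class`, `n_copies`,
#'   `mutation_rate`, `in_network_panel`.
#' @export
yfiler_plus_panel <- function(rates = yfiler_plus_rates()) {
  panel <- .YFILER_PLUS_LOCI
  missing <- setdiff(panel$locus, names(rates))
  if (length(missing))
    stop("no mutation rate for loci: ", paste(missing, collapse = ", "))
  if (any(rates <= 0 | rates >= 0.05))
    stop("mutation rates must lie in (0, 0.05)")
  panel$mutation_rate <- unname(rates[panel$locus])
  panel$in_network_panel <- panel$copy_class == "single"
  panel
}

#' Network-eligible loci of a panel
#'
#' @param panel a panel data.frame as returned by [yfiler_plus_panel()].
#' @return character vector of the single-copy network loci, in panel order.
#' @export
network_loci <- function(panel = yfiler_plus_panel()) {
  panel$locus[panel$in_network_panel]
}
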