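# The haplotype table container: a character matrix of canonical allele
# tokens (samples x locus columns) plus sample metadata and the panel
# definition. DYS389II is stored raw; distance/network code requires the
# adjusted form and the `dys389_adjusted` flag guards against double
# subtraction.

#' Construct a haplotype table
#'
#' @param calls character matrix of canonical allele tokens, one row per
#'   sample, columns named after the panel locus columns.
#' @param meta data.frame with columns `sample_id`, `population` and
#'   optionally `tribe`, `clan`; one row per sample.
#' @param panel locus registry, see [yfiler_plus_panel()].
#' @param dys389_adjusted logical; has DYS389I already been subtracted from
#'   DYS389II?
#' @return object of class `haplotype_table`.
#' @export
haplotype_table <- function(calls, meta, panel = yfiler_plus_panel(),
                            dys389_adjusted = FALSE) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls)))
    stop("calls matrix must have locus column names")
  missing <- setdiff(panel$locus, colnames(calls))
  if (length(missing))
    stop("calls do not cover panel loci: ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(calls), panel$locus)
  if (length(extra))
    stop("unknown locus column: ", paste(extra, collapse = ", "))
  calls <- calls[, panel$locus, drop = FALSE]
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(meta)))
    stop("meta must contain sample_id and population")
  for (f in c("tribe", "clan"))
    if (is.null(meta[[f]])) meta[[f]] <- NA_character_
  meta <- meta[, c("sample_id", "population", "tribe", "clan")]
  if (nrow(meta) != nrow(calls))
    stop("meta and calls disagree on the number of samples")
  if (anyDuplicated(meta$sample_id))
    stop("sample_ids must be unique")
  # canonicalize every token (sorted multi-copy sets, trimmed separators) so
  # haplotype identity is deterministic whatever the entry path
  for (k in seq_len(nrow(panel))) {
    multi <- panel$copy_class[k] == "multi"
    col <- calls[, panel$locus[k]]
    calls[, panel$locus[k]] <- vapply(col, canonical_token, "",
                                      multi = multi, USE.NAMES = FALSE)
  }
  rownames(calls) <- meta$sample_id
  structure(
    list(calls = calls, meta = meta, panel = panel,
         dys389_adjusted = isTRUE(dys389_adjusted),
         dys389_flags = data.frame(sample_id = character(0),
                                   reason = character(0),
                                   stringsAsFactors = FALSE)),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Y-STR haplotype table: %d samples, %d locus columns (%d named loci)\n",
              nrow(x$calls), ncol(x$calls), sum(x$panel$n_copies)))
  cat(sprintf("  populations: %s\n",
              paste(unique(x$meta$population), collapse = ", ")))
  if (any(!is.na(x$meta$tribe)))
    cat(sprintf("  tribes: %s\n",
                paste(unique(stats::na.omit(x$meta$tribe)), collapse = ", ")))
  cat(sprintf("  DYS389II adjusted: %s\n", x$dys389_adjusted))
  invisible(x)
}

#' Number of samples in a haplotype table
#' @param t a `haplotype_table`.
#' @return integer sample count.
#' @export
n_samples <- function(t) nrow(t$calls)

#' Subset a haplotype table by sample
#'
#' @param t a `haplotype_table`.
#' @param idx logical, integer or character (sample_id) index.
#' @return the subsetted `haplotype_table`.
#' @export
subset_samples <- function(t, idx) {
  if (is.character(idx)) idx <- match(idx, t$meta$sample_id)
  out <- t
  out$calls <- t$calls[idx, , drop = FALSE]
  out$meta <- t$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out$dys389_flags <- t$dys389_flags[
    t$dys389_flags$sample_id %in% out$meta$sample_id, , drop = FALSE]
  out
}

# Canonical haplotype key: ordered locus tokens joined with "|"; "" marks a
# null so keys are deterministic for all abnormal states.
haplotype_keys <- function(t) {
  apply(t$calls, 1L, paste, collapse = "|")
}
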