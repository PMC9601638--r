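# Wide-table I/O. One row per sample; metadata columns (sample_id,
# population, tribe, clan, case-insensitive) followed by one column per
# locus. Multi-copy loci may come as a single combined column ("DYS385" =
# "11-14") or as split columns ("DYS385a"/"DYS385b"); they are written
# combined.

.META_ALIASES <- c(sample_id = "sampleid", sample_id = "sample_id",
                   sample_id = "sample", sample_id = "id",
                   population = "population", population = "pop",
                   tribe = "tribe", clan = "clan")

#' Read a wide Y-STR haplotype table
#'
#' @param path path to the file.
#' @param dialect `"wide_tsv"` (tab-separated) or `"csv"`.
#' @param panel locus registry, see [yfiler_plus_panel()].
#' @param null_sentinel token(s) denoting a null allele (the empty cell is
#'   always accepted).
#' @return a validated [haplotype_table()].
#' @export
read_haplotypes <- function(path, dialect = c("wide_tsv", "csv"),
                            panel = yfiler_plus_panel(),
                            null_sentinel = "0") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- if (dialect == "csv")
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  else
    utils::read.delim(path, colClasses = "character", check.names = FALSE)
  cols <- names(df)
  norm <- tolower(gsub("[^A-Za-z0-9]", "", cols))

  meta <- data.frame(sample_id = rep(NA_character_, nrow(df)),
                     stringsAsFactors = FALSE)
  meta_idx <- integer(0)
  for (field in c("sample_id", "population", "tribe", "clan")) {
    aliases <- gsub("_", "", .META_ALIASES[names(.META_ALIASES) == field])
    hit <- which(norm %in% aliases)[1]
    if (!is.na(hit)) {
      meta[[field]] <- df[[hit]]
      meta_idx <- c(meta_idx, hit)
    }
  }
  if (all(is.na(meta$sample_id)))
    meta$sample_id <- sprintf("S%04d", seq_len(nrow(df)))
  if (is.null(meta$population)) meta$population <- "unknown"
  for (f in c("tribe", "clan"))
    if (!is.null(meta[[f]])) meta[[f]][meta[[f]] %in% c("", "NA")] <- NA

  locus_cols <- setdiff(seq_along(cols), meta_idx)
  panel_norm <- toupper(gsub("[^A-Za-z0-9]", "", panel$locus))
  calls <- matrix("", nrow(df), nrow(panel),
                  dimnames = list(NULL, panel$locus))
  seen <- logical(nrow(panel))
  split_ab <- list()
  for (j in locus_cols) {
    nm <- toupper(gsub("[^A-Za-z0-9]", "", cols[j]))
    k <- match(nm, panel_norm)
    if (is.na(k) && grepl("[AB]$", nm)) {
      # split multi-copy column, e.g. DYS385a / DYS385b
      base <- sub("[AB]$", "", nm)
      k <- match(base, panel_norm)
      if (!is.na(k) && panel$copy_class[k] == "multi") {
        key <- panel$locus[k]
        split_ab[[key]] <- c(split_ab[[key]], j)
        seen[k] <- TRUE
        next
      }
      k <- NA
    }
    if (is.na(k))
      stop("unknown locus column: ", cols[j])
    calls[, k] <- df[[j]]
    seen[k] <- TRUE
  }
  for (key in names(split_ab)) {
    parts <- df[split_ab[[key]]]
    joined <- apply(parts, 1L, function(v) {
      v <- v[!is.na(v) & trimws(v) != "" & !trimws(v) %in% null_sentinel]
      paste(v, collapse = "-")
    })
    calls[, key] <- joined
  }
  if (!all(seen))
    stop("missing locus column(s): ",
         paste(panel$locus[!seen], collapse = ", "))

  multi <- panel$copy_class == "multi"
  for (k in seq_len(nrow(panel))) {
    for (i in seq_len(nrow(calls))) {
      tok <- calls[i, k]
      res <- tryCatch(
        canonical_token(tok, multi = multi[k], null_sentinel = null_sentinel),
        error = function(e)
          stop(sprintf("row %d, locus %s: %s", i, panel$locus[k],
                       conditionMessage(e)), call. = FALSE))
      calls[i, k] <- res
    }
  }
  haplotype_table(calls, meta, panel)
}

#' Write a haplotype table as a wide file
#'
#' Null alleles are written as the first `null_sentinel` token; multi-copy
#' allele sets are hyphen-joined, duplicated alleles comma-joined.
#'
#' @param t a `haplotype_table`.
#' @param path output path.
#' @param dialect `"wide_tsv"` or `"csv"`.
#' @param null_sentinel token written for null alleles (default `"0"`).
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(t, path, dialect = c("wide_tsv", "csv"),
                             null_sentinel = "0") {
  dialect <- match.arg(dialect)
  out <- t$calls
  out[out == ""] <- null_sentinel[1]
  df <- cbind(t$meta, as.data.frame(out, stringsAsFactors = FALSE))
  if (dialect == "csv")
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  else
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(path)
}

#' Write a generic report data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
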