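# Allele call tokens.
#
# Calls are stored as canonical character tokens, one per locus column:
#   ""        null allele (no product, e.g. DYS448 deletion)
#   "15"      normal single-copy allele
#   "17.2"    microvariant (non-integer repeat count)
#   "15,16"   duplicated allele at a single-copy locus (ascending, comma)
#   "11-14"   multi-copy allele set (ascending, hyphen); three or more
#             values at a multi-copy locus mark a copy-number gain
# Repeat counts are validated to [5, 60] on parsing.

.REPEAT_MIN <- 5
.REPEAT_MAX <- 60

.fmt_repeat <- function(x) sub("\\.0$", "", sprintf("%.1f", x))

#' Parse one allele token
#'
#' @param token character scalar as read from a haplotype table cell.
#' @param multi logical; is the locus multi-copy (DYS385, DYF387S1)?
#' @param null_sentinel tokens to interpret as a null allele in addition to
#'   the empty cell.
#' @return list with `state` (one of `"null"`, `"normal"`, `"microvariant"`,
#'   `"duplicated"`) and `values` (ascending numeric repeat counts; empty for
#'   null).
#' @export
parse_allele <- function(token, multi = FALSE, null_sentinel = "0") {
  token <- trimws(as.character(token))
  if (is.na(token) || token == "" || token %in% null_sentinel)
    return(list(state = "null", values = numeric(0)))
  sep <- if (multi) "[-,/]" else "[,/]"
  parts <- trimws(strsplit(token, sep)[[1]])
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals)) || !length(vals))
    stop(sprintf("unparseable allele token '%s'", token), call. = FALSE)
  if (any(vals < .REPEAT_MIN | vals > .REPEAT_MAX))
    stop(sprintf("allele token '%s' outside repeat-count range [%d, %d]",
                 token, .REPEAT_MIN, .REPEAT_MAX), call. = FALSE)
  vals <- sort(vals)
  state <- if (multi) {
    if (length(vals) > 2L) "duplicated"
    else if (any(vals %% 1 != 0)) "microvariant" else "normal"
  } else {
    if (length(vals) > 1L) "duplicated"
    else if (vals %% 1 != 0) "microvariant" else "normal"
  }
  list(state = state, values = vals)
}

#' Format an allele call as its canonical token
#'
#' @param values numeric repeat counts (empty for a null allele).
#' @param multi logical; multi-copy locus?
#' @return canonical character token.
#' @export
format_allele <- function(values, multi = FALSE) {
  if (!length(values)) return("")
  paste(.fmt_repeat(sort(values)), collapse = if (multi) "-" else ",")
}

# Canonicalize a raw token (sorting values, normalising separators); errors
# propagate with the offending token named.
canonical_token <- function(token, multi = FALSE, null_sentinel = "0") {
  call <- parse_allele(token, multi = multi, null_sentinel = null_sentinel)
  format_allele(call$values, multi = multi)
}

# Vectorised state of canonical tokens (no re-validation).
token_state <- function(tokens, multi = FALSE) {
  vapply(tokens, function(tok) parse_allele(tok, multi = multi)$state, "",
         USE.NAMES = FALSE)
}

# Numeric value of a canonical single-valued token; NA for null/duplicated.
token_value <- function(tokens) {
  suppressWarnings(as.numeric(tokens))
}
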