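# In-code fixtures used across test files.

# A haplotype table with given per-sample calls at a few chosen loci; all
# other panel loci are held at the default founder haplotype. `...` are
# named character vectors, e.g. DYS19 = c("15", "15,16").
make_table <- function(..., population = "P1", tribe = NA_character_) {
  over <- list(...)
  panel <- yfiler_plus_panel()
  founder <- default_founder()
  founder$DYS389II <- founder$DYS389I + founder$DYS389II # raw form
  n <- if (length(over)) length(over[[1]]) else
    stop("give at least one locus column")
  calls <- matrix("", n, nrow(panel), dimnames = list(NULL, panel$locus))
  for (loc in panel$locus)
    calls[, loc] <- format_allele(
      founder[[loc]], multi = panel$copy_class[panel$locus == loc] == "multi")
  for (loc in names(over)) calls[, loc] <- over[[loc]]
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = rep_len(population, n),
    tribe = rep_len(tribe, n), clan = NA_character_,
    stringsAsFactors = FALSE)
  haplotype_table(calls, meta, panel)
}

# Random haplotype table varying a small set of single-copy loci (keys for
# the oracle equivalence checks); remaining loci constant.
random_table <- function(n, loci = c("DYS19", "DYS390", "DYS391", "DYS456"),
                         states = 13:16) {
  args <- lapply(loci, function(l)
    as.character(sample(states, n, replace = TRUE)))
  names(args) <- loci
  do.call(make_table, args)
}

# Combine the tables of several genealogy samples into one haplotype table.
bind_tables <- function(...) {
  parts <- list(...)
  calls <- do.call(rbind, lapply(parts, function(p) p$calls))
  meta <- do.call(rbind, lapply(parts, function(p) p$meta))
  rownames(meta) <- NULL
  haplotype_table(calls, meta, parts[[1]]$panel)
}

# Founder list derived from an adjusted 23-locus repeat vector (multi-copy
# loci taken from the default founder).
founder_from_vector <- function(v) {
  f <- default_founder()
  for (l in names(v)) f[[l]] <- unname(v[l])
  f
}
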