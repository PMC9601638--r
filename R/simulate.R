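# Stepwise-mutation-model simulator for founder-effect Y-STR populations.
#
# Lineages descend from a founder haplotype on a star genealogy: each
# sampled lineage evolves independently for g generations, mutating at each
# locus with probability mu_l per generation by +/-1 repeat (symmetric,
# single-step). Under this model the repeat-count variance at a locus after
# g generations is mu_l * g. Data artifacts (DYS448 null alleles, DYS19
# duplications, DYS458 microvariants) are injected after mutation.

#' Default founder haplotype
#'
#' A plausible modal Yfiler Plus haplotype used as the simulation ancestor.
#' Multi-copy loci carry two values; DYS389II is given in *adjusted* form
#' (the raw value written to tables is DYS389I + the adjusted value, so the
#' two loci co-vary as they do in real data).
#'
#' @return named list of numeric allele vectors, one per panel locus column.
#' @export
default_founder <- function() {
  list(DYS576 = 17, DYS389I = 13, DYS635 = 22, DYS389II = 16, DYS627 = 21,
       DYS460 = 11, DYS458 = 18, DYS19 = 16, YGATAH4 = 11, DYS448 = 19,
       DYS391 = 10, DYS456 = 15, DYS390 = 25, DYS438 = 10, DYS392 = 11,
       DYS518 = 38, DYS570 = 18, DYS437 = 14, DYS385 = c(11, 14),
       DYS449 = 28, DYS393 = 13, DYS439 = 10, DYS481 = 23,
       DYF387S1 = c(36, 38), DYS533 = 11)
}

# One SMM trajectory: net repeat change and mutation count after g
# generations at rate mu. Draws the number of mutation events
# Binomial(g, mu), then signs +/-1; steps that would leave [5, 60] are
# reflected back.
.smm_step <- function(value, g, mu) {
  m <- stats::rbinom(1L, g, mu)
  if (m == 0L) return(list(value = value, events = 0L))
  steps <- sample(c(-1, 1), m, replace = TRUE)
  for (s in steps) {
    nxt <- value + s
    if (nxt < .REPEAT_MIN || nxt > .REPEAT_MAX) nxt <- value - s
    value <- nxt
  }
  list(value = value, events = m)
}

#' Simulate one tribe on a star genealogy
#'
#' Every sampled lineage descends independently from `founder` for
#' `generations` generations under the single-step symmetric stepwise
#' mutation model with per-locus rates `rates`.
#'
#' @param founder named list of founder allele values (see
#'   [default_founder()]); DYS389II in adjusted form.
#' @param n number of sampled lineages.
#' @param generations genealogy depth in generations (>= 0).
#' @param rates named per-generation mutation rates; default bundled table.
#' @param panel locus registry.
#' @param tribe,population,clan labels attached to the samples.
#' @param id_prefix prefix for generated sample ids.
#' @param seed optional integer seed (set it for reproducibility).
#' @return list of class `genealogy_sample`: `table` (a `haplotype_table`
#'   with raw DYS389II) and `truth` (data.frame `sample_id`, `founder`,
#'   `mutation_events`, plus the per-sample adjusted repeat vectors in
#'   `truth_vectors`).
#' @export
simulate_tribe <- function(founder = default_founder(), n, generations,
                           rates = yfiler_plus_rates(),
                           panel = yfiler_plus_panel(rates),
                           tribe = NA_character_, population = "simulated",
                           clan = NA_character_, id_prefix = "SIM",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1L) stop("n must be >= 1")
  loci <- panel$locus
  calls <- matrix("", n, length(loci), dimnames = list(NULL, loci))
  events <- integer(n)
  net_loci <- network_loci(panel)
  truth_vec <- matrix(NA_real_, n, length(net_loci),
                      dimnames = list(NULL, net_loci))
  for (i in seq_len(n)) {
    vals <- founder
    for (loc in loci) {
      mu <- panel$mutation_rate[panel$locus == loc]
      v <- vals[[loc]]
      for (ci in seq_along(v)) {
        st <- .smm_step(v[ci], generations, mu)
        v[ci] <- st$value
        events[i] <- events[i] + st$events
      }
      vals[[loc]] <- v
    }
    # store raw DYS389II = DYS389I + adjusted segment
    adj2 <- vals$DYS389II
    vals$DYS389II <- vals$DYS389I + adj2
    for (loc in loci)
      calls[i, loc] <- format_allele(
        vals[[loc]], multi = panel$copy_class[panel$locus == loc] == "multi")
    truth_vec[i, ] <- vapply(net_loci, function(l)
      if (l == "DYS389II") adj2 else vals[[l]][1], 0)
  }
  meta <- data.frame(sample_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                     population = population, tribe = tribe, clan = clan,
                     stringsAsFactors = FALSE)
  tab <- haplotype_table(calls, meta, panel)
  truth <- data.frame(sample_id = meta$sample_id, founder = tribe,
                      mutation_events = events, stringsAsFactors = FALSE)
  structure(list(table = tab, truth = truth, truth_vectors = truth_vec,
                 founder_vector = vapply(net_loci, function(l)
                   if (l == "DYS389II") founder$DYS389II else founder[[l]][1], 0)),
            class = "genealogy_sample")
}

#' Simulation configuration for a multi-tribe founder-effect population
#'
#' Defaults emulate a three-tribe sample with one dominant founder lineage
#' per tribe (founder shares 0.67, 0.746 and 0.258 — the dominant-haplogroup
#' shares reported for Alimuly, Baiuly and Zhetiru), founder depth 24
#' generations, background lineages ten times deeper, and artifact rates
#' matching the observed abundance of DYS448 nulls (~0.14), DYS19
#' duplications (~0.13) and DYS458 microvariants (~0.006).
#'
#' @param n total sample size.
#' @param tribes data.frame with columns `name`, `proportion`,
#'   `founder_share`, `generations`; proportions must sum to 1.
#' @param background_factor depth multiplier for non-founder (background)
#'   lineages.
#' @param dys448_null_rate,dys19_dup_rate,microvariant_rate artifact
#'   injection probabilities per sample, in `[0, 1]`.
#' @param rates named per-generation mutation rates.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n = 464,
                              tribes = data.frame(
                                name = c("Alimuly", "Baiuly", "Zhetiru"),
                                proportion = c(103, 272, 89) / 464,
                                founder_share = c(0.67, 0.746, 0.258),
                                generations = 24,
                                stringsAsFactors = FALSE),
                              background_factor = 10,
                              dys448_null_rate = 0.14,
                              dys19_dup_rate = 0.13,
                              microvariant_rate = 0.006,
                              rates = yfiler_plus_rates(),
                              seed = 1L) {
  if (abs(sum(tribes$proportion) - 1) > 1e-9)
    stop("tribe proportions must sum to 1")
  if (any(tribes$generations < 0)) stop("generations must be >= 0")
  rates_ok <- c(dys448_null_rate, dys19_dup_rate, microvariant_rate)
  if (any(rates_ok < 0 | rates_ok > 1))
    stop("artifact rates must lie in [0, 1]")
  structure(list(n = n, tribes = tribes,
                 background_factor = background_factor,
                 dys448_null_rate = dys448_null_rate,
                 dys19_dup_rate = dys19_dup_rate,
                 microvariant_rate = microvariant_rate,
                 rates = rates, seed = seed),
            class = "simulation_config")
}

# Derive a tribe-specific founder from the ancestral haplotype: a fixed
# deterministic offset at a few discriminating loci per tribe index (deep
# split between tribal founder lineages).
.tribe_founder <- function(ancestor, k, split_loci = c("DYS570", "DYS449", "DYS481", "DYS627")) {
  f <- ancestor
  for (j in seq_along(split_loci)) {
    loc <- split_loci[j]
    f[[loc]] <- f[[loc]] + ((k + j) %% 5L) - 2L
  }
  f
}

#' Simulate a multi-tribe founder-effect population
#'
#' For each tribe, a share of the samples descends from the tribe's founder
#' haplotype (a fixed offset of the common ancestor at a few discriminating
#' loci) over the tribe's genealogy depth; the remaining (background)
#' samples descend from the common ancestor over a `background_factor`
#' times deeper genealogy, supplying the non-founder diversity. Data
#' artifacts are then injected as independent Bernoulli events per sample:
#' DYS448 null alleles, DYS19 duplications (second allele one repeat away)
#' and DYS458 microvariants (+0.2).
#'
#' @param cfg a [simulation_config()].
#' @return list of class `genealogy_sample` with the combined
#'   `haplotype_table`, per-sample `truth` (founder assignment and mutation
#'   counts) and `truth_vectors`.
#' @export
simulate_population <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  panel <- yfiler_plus_panel(cfg$rates)
  ancestor <- default_founder()
  counts <- round(cfg$n * cfg$tribes$proportion)
  counts[1] <- cfg$n - sum(counts[-1])
  parts <- list()
  for (k in seq_len(nrow(cfg$tribes))) {
    tr <- cfg$tribes[k, ]
    n_founder <- round(counts[k] * tr$founder_share)
    n_bg <- counts[k] - n_founder
    if (n_founder > 0)
      parts[[length(parts) + 1L]] <- simulate_tribe(
        .tribe_founder(ancestor, k), n_founder, tr$generations,
        rates = cfg$rates, panel = panel, tribe = tr$name,
        population = "simulated",
        id_prefix = sprintf("T%dF", k))
    if (n_bg > 0) {
      bg <- simulate_tribe(
        ancestor, n_bg, round(tr$generations * cfg$background_factor),
        rates = cfg$rates, panel = panel, tribe = tr$name,
        population = "simulated",
        id_prefix = sprintf("T%dB", k))
      bg$truth$founder <- "background"
      parts[[length(parts) + 1L]] <- bg
    }
  }
  calls <- do.call(rbind, lapply(parts, function(p) p$table$calls))
  meta <- do.call(rbind, lapply(parts, function(p) p$table$meta))
  truth <- do.call(rbind, lapply(parts, function(p) p$truth))
  truth_vectors <- do.call(rbind, lapply(parts, function(p) p$truth_vectors))
  rownames(meta) <- rownames(truth) <- NULL
  # inject artifacts after mutation
  n <- nrow(calls)
  nulls <- stats::runif(n) < cfg$dys448_null_rate
  calls[nulls, "DYS448"] <- ""
  dups <- stats::runif(n) < cfg$dys19_dup_rate
  for (i in which(dups)) {
    v <- parse_allele(calls[i, "DYS19"])$values
    if (!length(v)) next
    second <- v[1] + sample(c(-1, 1), 1L)
    calls[i, "DYS19"] <- format_allele(c(v[1], second))
  }
  micro <- stats::runif(n) < cfg$microvariant_rate
  for (i in which(micro)) {
    v <- parse_allele(calls[i, "DYS458"])$values
    if (!length(v)) next
    calls[i, "DYS458"] <- format_allele(v[1] + 0.2)
  }
  tab <- haplotype_table(calls, meta, panel)
  structure(list(table = tab, truth = truth, truth_vectors = truth_vectors,
                 config = cfg),
            class = "genealogy_sample")
}

#' Deterministic fixture: a 59-sample single-duplicate population
#'
#' A synthetic, fully deterministic 59-record haplotype table in which
#' exactly one haplotype is carried by two individuals and the other 57 are
#' singletons (58 distinct haplotypes). Each variant differs from the base
#' haplotype at a single network locus. The spectrum `{57 x 1, 1 x 2}`
#' yields DC = 58/59, a unique-haplotype fraction of 57/59, HMP = 61/59^2
#' and HD = (59/58) (1 - 61/59^2) — the regime of a small population sample
#' in which almost every haplotype is unique.
#'
#' @return a `haplotype_table` with population label
#'   `"Karakalpakstan Kazakh"`.
#' @export
fixture_karakalpakstan <- function() {
  panel <- yfiler_plus_panel()
  base <- default_founder()
  base$DYS389II <- base$DYS389I + base$DYS389II # raw form
  net <- network_loci(panel)
  make_row <- function(vals) {
    vapply(panel$locus, function(loc)
      format_allele(vals[[loc]],
                    multi = panel$copy_class[panel$locus == loc] == "multi"),
      "")
  }
  calls <- matrix("", 59, nrow(panel), dimnames = list(NULL, panel$locus))
  for (i in 1:58) {
    vals <- base
    loc <- net[((i - 1L) %% length(net)) + 1L]
    delta <- ((i - 1L) %/% length(net)) + 1L
    vals[[loc]] <- vals[[loc]] + delta
    calls[i, ] <- make_row(vals)
  }
  calls[59, ] <- calls[58, ] # the single shared haplotype
  meta <- data.frame(sample_id = sprintf("KK%03d", 1:59),
                     population = "Karakalpakstan Kazakh",
                     tribe = NA_character_, clan = NA_character_,
                     stringsAsFactors = FALSE)
  haplotype_table(calls, meta, panel)
}
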