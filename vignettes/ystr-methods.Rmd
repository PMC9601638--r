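---
title: "Methods: Y-STR forensic statistics, AMOVA/R_ST, and median-joining networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-STR forensic statistics, AMOVA/R_ST, and median-joining networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

`ystrkit` analyses Y-chromosomal STR haplotypes — the joint allele profile
of one man across a panel of Y-linked microsatellite loci. Because the Y
chromosome is haploid and does not recombine, the whole haplotype is one
patrilineally inherited unit; populations organised around patrilineal
descent groups (clans and tribes) therefore often show strong founder
effects, with one high-frequency lineage and a halo of recently derived
variants. This vignette documents the statistical machinery, the tunable
parameters and their defaults, the numerical conventions, and the design
choices made where more than one defensible convention exists.

## The data model

The panel registry (`yfiler_plus_panel()`) describes the 27-locus Yfiler
Plus set as 25 locus *columns*: 23 single-copy loci plus the multi-copy
pairs DYS385 a/b and DYF387S1 a/b, each stored as one unordered allele set.
Allele calls are kept as canonical tokens that preserve the forensically
relevant abnormal states:

* `""` — a **null allele** (no amplification product, e.g. a DYS448
  deletion); files may use a configurable sentinel (default `"0"`).
* `"17.2"` — a **microvariant** (non-integer repeat count), kept as an
  exact decimal and treated as a distinct allele state for counting.
* `"15,16"` — a **duplicated allele** at a single-copy locus (copy-number
  gain, e.g. at DYS19), stored ascending.
* `"11-14"` — a multi-copy allele set, stored ascending so haplotype
  identity is order-insensitive.

Repeat counts are validated to [5, 60] on entry. Haplotype identity is
exact equality of all locus tokens; the canonical key makes this
deterministic for every abnormal state.

DYS389 needs one special rule: the DYS389II amplicon physically contains
the DYS389I repeat stretch, so the independent repeat content of DYS389II
is obtained by subtracting DYS389I. Frequency tables conventionally report
the raw value, while repeat-based distances require the adjusted one.
`ystrkit` therefore stores DYS389II raw and applies `adjust_dys389()` only
for distance and network work; a table-level flag forbids a second
subtraction, records where either locus is null or duplicated are left
unadjusted and flagged, and a non-positive adjusted value raises a warning
and an out-of-range flag rather than silently propagating.

## Haplotype-level forensic statistics

All haplotype statistics are direct counts on the spectrum of observation
counts $(c_1, \dots, c_k)$, $n = \sum_i c_i$, $p_i = c_i / n$:

* haplotype match probability $\mathrm{HMP} = \sum_i p_i^2$ — the
  probability that two draws with replacement carry the same haplotype;
* haplotype diversity $\mathrm{HD} = \frac{n}{n-1}(1 - \sum_i p_i^2)$ —
  the Nei-corrected probability that two sampled haplotypes differ;
* discrimination capacity $\mathrm{DC} = k / n$;
* unique-haplotype fraction $=\#\{i : c_i = 1\}/n$.

Two conventions deserve a note. First, the unique-haplotype fraction is
not defined identically across the literature; the singleton-count over
sample-size reading is adopted because it reproduces published
summary-table values exactly from their printed distinct/shared counts,
whereas singletons-over-distinct does not. Second, the identity
$\mathrm{HD} = n(1-\mathrm{HMP})/(n-1)$ holds *exactly* for every
spectrum; it is enforced to machine precision in the property tests and is
exposed as `hd_from_hmp()` so a published match probability can be turned
into a diversity when the full spectrum is unavailable.

Per-locus parameters use the same allele-frequency machinery: gene
diversity $GD = \frac{n}{n-1}(1 - \sum p^2)$, random match probability
$RMP = \sum p^2$, power of discrimination $PD = 1 - RMP$, and
$\mathrm{PIC} = 1 - \sum p^2 - (\sum p^2)^2 + \sum p^4$. Null alleles are
excluded from the locus denominator by default (`count_nulls = TRUE` gives
them their own class); duplicated calls count as their own combined allele
class; multi-copy loci are summarised as unordered allele combinations,
one observation per individual. PE and TPI are diploid-born parameters
with no canonical haploid definition; they are emitted only under
`extended = TRUE`, using the haploid conventions $PE = GD^2$ and
$TPI = 1/(2(1-GD))$, and should be interpreted accordingly.

Reported tables round half-up to 4 decimals (percentages to 2), matching
forensic reporting practice; internal values keep full precision.

## AMOVA, R_ST and MDS

Differentiation between populations uses the microsatellite-specific
molecular distance $\delta_{ij} = \sum_l (a_{il} - a_{jl})^2$ — squared
repeat-count differences summed over the 23 network loci (DYS389II
adjusted, multi-copy loci excluded; microvariants enter as their numeric
value, so a 17.2 vs 17 difference contributes $0.2^2$). The two-level
analysis of molecular variance partitions

$$SSD_{total} = \tfrac{1}{N}\textstyle\sum_{i<j}\delta_{ij}, \qquad
  SSD_{within} = \sum_p \tfrac{1}{n_p}\sum_{i<j \in p}\delta_{ij},$$

with $\sigma^2_w = SSD_{within}/(N-P)$,
$\sigma^2_a = (SSD_{among}/(P-1) - \sigma^2_w)/n'$,
$n' = (N - \sum_p n_p^2/N)/(P-1)$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$, which is R_ST for this
distance. Negative variance components are *retained* in the
`amova_result` (they are informative about sampling noise) and clamped to
zero only in the pairwise `rst_matrix`, mirroring how distance matrices
are reported in practice. Degenerate inputs fail loudly: fewer than two
groups, fewer than three individuals, or all-singleton groups are errors
with explicit messages, not crashes. Significance uses a permutation test,
$p = (1 + \#\{\Phi^{perm} \ge \Phi^{obs}\})/(B + 1)$, reproducible under a
seed.

Whether R_ST pipelines adjust DYS389II or use it raw is rarely stated in
publications; the adjusted convention is used here (consistent with the
network panel) and is flagged in the documentation because the choice
changes the distance scale at that locus.

Ordination is classical (Torgerson) MDS via double-centering and
eigendecomposition (`stats::cmdscale`), chosen over iterative stress
majorisation because it is deterministic and hence testable; negative
eigenvalues are truncated and missing axes padded with zeros. Kruskal
stress-1, $\sqrt{\sum (d - \hat d)^2 / \sum d^2}$, is computed on the raw
R_ST scale and reported alongside the coordinates.

## Median-joining networks

Within a founder lineage, haplotypes differ by few mutation steps and the
genealogy is star-like; a haplotype network displays this structure
directly. The construction follows the median-joining idea: start from the
**minimum spanning network** (MSN) — the union of all minimum spanning
trees, computed exactly from minimax connection levels via a sorted-edge
union-find pass, with an `epsilon` relaxation (default 0) admitting edges
within `epsilon` of their connection level — and augment the node set with
inferred intermediate haplotypes where they shorten the spanning
structure.

Distances are weighted L1: $\sum_l w_l\,|a_l - b_l|$, the convention for
STR network construction (squared differences are reserved for R_ST, and
the two metrics intentionally differ). Locus weights are inversely
proportional to the per-generation mutation rate, $w_l =
\mathrm{round}(c/\mu_l)$ with $c$ fixed so the median weight is 10,
clamped to $[1, 99]$: a step at a slowly mutating locus is rarer, hence
more informative, hence more expensive to postulate. The bundled rate
table (`inst/extdata/yfiler_plus_mutation_rates.json`) carries consensus
per-locus estimates of the magnitude reported across father–son pair
studies; users may override any rate.

**The median rule.** For a triplet of haplotypes the inferred candidate is
the *coordinate-wise median* per locus. STR repeat counts are ordered
numeric characters, so the median is always defined, equals the majority
state whenever two of the three agree, and is the L1 Fermat point of the
triplet — the point minimising the summed weighted distance to all three.
A majority-only rule (natural for unordered multistate characters) was
considered and rejected: where a locus carries three distinct states it
produces no candidate at all, and provably cannot reach the cost-minimal
network on instances as small as three nodes, whereas the coordinate-wise
median can.

The engine iterates: candidate medians are generated from triplets of
current nodes — exhaustively for node sets up to 40 (`triplet_scope =
"auto"`), and from MSN-connected triplets beyond that (the classical
heuristic, which keeps the construction tractable at hundreds of nodes) —
and accepted greedily while they strictly reduce the minimum-spanning-tree
cost over the node set, with lazy re-validation for speed and
numeric-lexicographic tie-breaking for cross-platform determinism. For
small node sets a depth-2 lookahead also admits pairs of cost-neutral
medians that jointly reduce cost. At the fixed point, obsolete medians —
those whose removal leaves the MST cost unchanged — are pruned, and the
MSN over the final node set gives the edge set. On star data (a founder
plus one-step derivatives) no median can reduce cost, so the network is
exactly the star; on small instances the construction is validated in the
tests against exhaustive enumeration of Steiner-point subsets over the
observed state grid.

**Cluster annotation.** `annotate_clusters()` partitions the *sampled*
haplotypes by cutting, in the spanning structure over sampled nodes, links
whose length exceeds (strictly) a quantile of link lengths (default 0.95).
Links are measured as shortest network path lengths, so a deep split
subdivided by a chain of inferred medians still counts at its full length
— cutting raw edges instead is defeated by exactly that subdivision.
Operationally this is single-linkage clustering on network path distances,
whose merge heights are the spanning-link lengths. The strict inequality
means fully tied link lengths (a pure star) yield one cluster. Per
cluster, the label composition, majority-label purity and the modal allele
per network locus (the profile that separates clusters) are reported.

## The simulator: what it emulates, and what it does not

`simulate_tribe()` implements a single-step symmetric stepwise mutation
model on a **star genealogy**: each sampled lineage descends independently
from the founder for $g$ generations, mutating at each locus with
probability $\mu_l$ per generation by ±1 repeat (steps that would leave
[5, 60] are reflected). Under this model the repeat-count variance at a
locus after $g$ generations is $\mu_l g$ — the closed form used as the
calibration oracle in the tests (checked within three standard errors of
the sampling variance at $n = 2000$). Mutation events are recorded
per lineage, so the displacement bound $\sum_l |x_l - f_l| \le$
(event count) is testable, with equality when no back-mutation occurred.
DYS389 is simulated on the adjusted scale and written raw
(raw II = I + adjusted II), so the two loci co-vary as in real data.

`simulate_population()` composes tribes: within each tribe a
*founder share* of samples descends from the tribe founder over $g$
generations, and the remainder descends from the common ancestor over a
$10\times$ deeper genealogy, supplying background diversity. Defaults are
fixed once from the study system the generator emulates: three tribes in
proportions 103/272/89 of 464, founder shares 0.67 / 0.746 / 0.258 (the
reported dominant-lineage shares per tribe), founder depth $g = 24$
generations (about 600 years at ~25 years per generation — the era of the
common ancestor the tribal genealogies point to), and artifact rates
matching the reported abundance of DYS448 nulls (0.14), DYS19 duplications
(0.13) and DYS458 microvariants (0.006). Artifacts are injected after
mutation as independent Bernoulli events per sample: a DYS448 null, a
DYS19 second allele one repeat away, a +0.2 DYS458 microvariant.

What the simulator deliberately does **not** model: coalescent genealogy
within lineages (star genealogies have no shared internal branches, so
within-founder haplotype classes are somewhat more even than real data),
multi-step mutations (negligible at these depths), lineage-heritable
artifacts (real DYS448 deletions concentrate in one clan; injected nulls
are independent), and haplogroup-defining SNPs. Consequently, passing
tests demonstrate correctness of the statistical machinery under a clean
founder-effect generating process — not that real tribal data meet the
model's assumptions.

`fixture_karakalpakstan()` is a fully deterministic synthetic table — 59
records, 58 distinct haplotypes, exactly one carried by two individuals,
each variant one step from a base haplotype — reproducing the spectrum
regime of a small population sample for the summary-statistic tests.

## Numerical conventions and problem sizes

Floating-point cost comparisons in the network engine use an absolute
tolerance of $10^{-9}$; SSD additivity is exact by construction and tested
at $10^{-9}$ relative tolerance; the HD–HMP identity is tested at machine
precision. Ties are always broken deterministically (numeric-lexicographic
node order), so equal seeds give byte-identical outputs across platforms.

The test suite runs entirely on synthetic data built in code: oracle
equivalence on random tables of up to 20 samples, spanning-tree and
Steiner enumeration on up to 6 and 5 nodes, simulator calibration at
$n = 2000$, cluster recovery on $3 \times 30$ samples, and pipeline runs
at $n \le 150$ — sizes chosen to exercise every code path while keeping
the default test run in about a minute. The acceptance script additionally
simulates one $n = 405$ population, the scale of the largest published
sample it emulates.

## Known limitations

* R_ST between *published* populations cannot be recomputed without their
  deposited haplotype lists; the machinery is general, but the package
  bundles no third-party haplotypes.
* The MSN-restricted candidate scope beyond 40 nodes is a heuristic; very
  large networks may admit shorter Steiner structures than the greedy
  fixed point finds (true of median-joining implementations generally).
* Classical MDS minimises strain, not stress; the reported Kruskal
  stress-1 describes the embedding but is not the quantity optimised.
* PE/TPI for haploid data are conventions, not standards, and are off by
  default.
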