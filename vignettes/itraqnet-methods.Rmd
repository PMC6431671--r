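---
title: "Methods: iTRAQ quantification and network-based key-target screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iTRAQ quantification and network-based key-target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqnet)
```

`itraqnet` implements an integrative pharmacology workflow that joins two
evidence streams about a multi-compound herbal therapy: differentially
expressed serum proteins measured by iTRAQ 4-plex LC-MS/MS (the experimental
stream) and putative compound targets filtered through scored interaction
networks (the predicted stream). This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults, the
design choices made where the methodology was genuinely open, what the
synthetic-data generator does and does not emulate, and known limitations.

## The quantification model

A 4-plex batch labels three patient sera with reporter tags 115–117 and one
pooled healthy control with tag 114; the default design of 10 batches × 3
patients yields 30 patients. A *patient* is therefore a (batch, channel)
pair. The stage order is fixed:

1. **Isotope-overlap correction.** Each tag leaks a known fraction of its
   signal into neighbouring channels. Given a 4×4 purity matrix $M$ (row =
   observed channel, column = true channel, columns summing to 1), the true
   areas solve $Mx = \text{observed}$ per spectrum. The default is the
   identity (no correction): purity factors are reagent-lot-specific vendor
   certificates, and inventing them would be worse than abstaining. Corrected
   areas that come out negative — possible when noise exceeds the overlap
   signal — are clipped to 0 with a warning. A singular or non-column-
   stochastic matrix is rejected at load time (`rcond` below $10^{-12}$
   counts as singular).
2. **Per-spectrum ratios.** The relative amount of a peptide in each patient
   is $\text{area}_{ch}/\text{area}_{114}$, $ch \in \{115,116,117\}$. A
   spectrum with a non-positive 114 area has no usable denominator; it is
   excluded with a counted warning rather than aborting, since one saturated
   or missing control peak should not kill a run.
3. **Protein rollup.** Within a batch, a protein's channel ratio is the
   arithmetic mean of the ratios of its peptides. The arithmetic (not
   geometric) mean follows standard 4-plex practice of averaging peak-area
   ratios; distinct peptide IDs are counted as identification metadata.
4. **Normalization.** To cancel small loading differences between channels,
   each channel's ratios are divided, within each batch, by that channel's
   *overall ratio* across all proteins. The aggregate is the **median** by
   default: the planted (or real) differentially expressed tail biases a
   mean, while the median is robust as long as under half the proteome
   changes. The mean is available (`aggregate = "mean"`). Normalization is
   idempotent by construction, and multiplying all four channels of every
   spectrum by a common constant changes nothing downstream.
5. **Differential testing.** Because the control is the ratio denominator,
   every control value is identically 1 and a two-sample test would be
   degenerate. The test is the two-sided **one-sample Student t on log2
   patient ratios against 0**. Log2 puts up- and down-regulation on a
   symmetric scale and makes the multiplicative noise model approximately
   Gaussian. Fewer than two finite log-ratios, or zero variance, makes a
   protein *not testable*: it gets an `NA` p-value and can never be called.

## Differential-protein calling

`call_deps()` applies five filters, all with **strict** inequalities (a
protein at exactly 1.2, p exactly 0.05, or unused score exactly 2 is not
called — thresholds phrased as "greater than" are honoured literally):

| parameter | default | meaning |
|---|---|---|
| `up` / `down` | 1.2 / 0.8 | fold-change dead zone on the mean NPC/control ratio |
| `alpha` | 0.05 | t-test significance level |
| `min_peptides` | 2 | distinct peptides for a confident identification |
| `min_unused_score` | 2.0 | spectral-search unused score (99% confidence); carried as input metadata, never recomputed |
| `min_consensus` | 25/30 | patient-consensus fraction, strictly exceeded |

The consensus rule needed operationalizing: "a similar protein profile
across patients" is here defined as the fraction of patients whose
individual ratio lies on the **same side of 1.0** as the protein's mean
ratio (a mean of exactly 1.0 has no side and gets consensus 0). This is the
simplest definition that is monotone in effect size, scale-free, and
computable from the ratios alone. Output is sorted by $|\log_2$ mean
ratio$|$ descending with accession tie-breaks, so reruns are byte-stable
and row order of the input never matters.

## Compound screening

Compounds are binary fingerprints; similarity is the Tanimoto coefficient
$|A \cap B| / |A \cup B|$. No chemistry toolkit is involved because the
screen consumes only the score: a compound is kept iff its best similarity
over the reference-drug set **strictly exceeds** 0.8. The boundary case is
ambiguous in common usage ("higher than 0.8 kept", "lower than 0.8
redundant" — 0.8 itself unaddressed); strict-greater was chosen and is
asserted in the tests. Two all-zero fingerprints have an empty union; their
similarity is defined as 0 with a warning. The mean-targets-per-compound
statistic divides distinct (compound, target) pairs by the number of kept
compounds, so a target-less compound lowers the mean rather than vanishing.

## Network topology and hub screening

Interaction edges carry a combined confidence score in $[0,1]$. Two
screening rules operate in sequence:

- **Median edge filter**: only edges with score strictly greater than the
  median of all scores survive. Strictness means ties at the median are
  dropped and the retained fraction never exceeds one half; an all-equal
  score vector retains nothing (warned).
- **Triple-median hub screen**: on the filtered graph, a node is a *major
  hub* iff its degree, betweenness and closeness all strictly exceed the
  corresponding network-wide medians. The cut statistic is configurable
  (`median` or `mean`) with median the default: where the source
  methodology names both "the median value" and "higher than the average",
  the explicit computation of medians is taken as the operative rule and
  "average" as loose prose.

Centrality conventions (asserted against a brute-force all-shortest-paths
oracle in the test suite):

- *degree* — link count in the simple graph (self-loops dropped,
  multi-edges collapsed keeping the maximum score);
- *betweenness* — $\sum_{s<t} \sigma_{st}(v)/\sigma_{st}$ over unordered
  pairs, unnormalized: the pair-fraction convention of standard network
  software, not raw path counts;
- *closeness* — per connected component, $(n_c - 1)/\sum_u d(v,u)$
  (Wasserman–Faust normalization), so values are comparable across
  components of different sizes and bounded by 1; an isolated node scores
  0. Component-wise normalization matters because integrated networks are
  not guaranteed connected.

Edges are undirected and unweighted for shortest paths; the combined score
is only ever a filter, never a path weight, because interaction confidence
is not a distance.

## Enrichment

Overrepresentation of a query gene list in a pathway is the upper-tail
hypergeometric probability $P[X \ge k]$, $X \sim \mathrm{Hypergeom}(N, K,
n)$, with fold enrichment $(k/n)/(K/N)$. Raw p-values are reported;
Benjamini–Hochberg adjustment is available behind `adjust = TRUE` but off
by default, matching the convention of reporting unadjusted
overrepresentation p-values per pathway. The universe defaults to the union
of all pathway genes in the GMT — the only background recoverable from a
gene-set file — and can be overridden. Query genes outside the universe are
dropped with a warning and shrink $n$; results are sorted by p-value with
lexicographic pathway-id tie-breaks so output is deterministic.

## Integration and key-target nomination

The candidate set is the deduplicated union of major predicted hubs and
experimentally called proteins, with dual provenance preserved (an
accession-to-symbol mapping file may translate the experimental ids;
unmappable accessions are kept under their own id with a warning rather
than silently dropped). The interaction network induced on the candidates
is median-filtered with the median recomputed *on the induced edges* — the
filter is a property of the network being screened, not of the global
database. "Strong interaction in the network" is operationalized as the
same triple-median rule used upstream: it is the only screening rule the
workflow defines, and reusing it keeps the nomination criterion auditable.
Survivors are ranked by degree, ties broken by betweenness, closeness, then
node id, making the report deterministic. When no node clears all three
strict cuts (e.g. a cycle, where every node is topologically equivalent)
the nomination is empty with an explanatory note — an honest "no
distinguished target" answer.

## The synthetic-data generator

The generator's role is to supply every input with planted ground truth so
all stages are testable offline; its defaults *are* the study conditions
used throughout the tests.

**iTRAQ stream** (`gen_itraq_dataset`): 500 proteins, 10% planted up at
fold 2.0 and 10% down at fold 0.5, 2–6 peptides per protein, 10 batches × 3
patients, multiplicative lognormal peptide noise at CV 0.2. Fold magnitudes
sit inside the 0.5–3.3 range typical of serum iTRAQ reports, and a CV of
0.2 is a realistic reporter-ion precision for pooled serum work. Planted
counts are `round(frac × n)` with up planted first and the down count
truncated to fit, so counts are exact, not merely expected. Channel-114
areas are lognormal around a per-protein baseline with per-peptide
ionization efficiencies; patient channels are the 114 area × true fold ×
independent lognormal noise — lognormal because reporter ratios are
strictly positive and their noise is multiplicative. An optional batch
effect applies a lognormal scalar **per (batch, channel)**: a scalar common
to all four channels of a batch would cancel exactly in every ratio and
could exercise nothing, whereas per-channel loading differences are
precisely what the normalization step corrects. It defaults to off.

What the generator does *not* emulate: between-patient biological
variance (all patients of a protein share one true fold), shared peptides
between proteins, missing channels, intensity-dependent noise, and
spectral-search errors (scores are drawn to pass the filters). Passing the
parameter-recovery tests therefore demonstrates that the statistical
machinery is correct under its own model, not that real serum studies
achieve sensitivity 0.9 at FDP 0.1.

**Compound stream** (`gen_compound_library`): similar compounds are built
by copying a reference fingerprint and toggling at most
$\lceil 0.2m \rceil - 1$ bits ($m$ = reference on-bits), which bounds the
worst-case Tanimoto strictly above 0.8; dissimilar compounds are re-drawn
until below 0.8, and a fingerprint too short to separate (persistent
failure) raises a configuration error.

**Network stream** (`gen_ppi_and_pathways`): 240 putative targets, 134
disease targets, 30 shared — mirroring the shape of herb-versus-disease
target collections — with preferential-attachment topology (protein
interaction networks are heavy-tailed) and i.i.d. Beta(2,2) combined
scores; one pathway is planted among the top-degree quintile.

**Integration scenario** (`gen_key_target_scenario`): 12 hubs and 13
experimental proteins sharing 3 key targets. Core edges (incident to a key
target) score in (0.78, 0.98) and exactly as many filler edges among
non-key nodes score in (0.05, 0.65); with equal counts, the score median
falls strictly between the two ranges, so the median filter retains
exactly the key-target star and the triple-median screen nominates exactly
the planted three. This determinism is a design feature: the end-to-end
test asserts identity, not overlap.

## Numerical choices and degenerate inputs

- All threshold comparisons strict; all sorts carry deterministic
  tie-breaks (accession, node id, pathway id).
- Aggregations run on keyed tables, so input row permutations produce
  identical output bytes; normalization idempotence is asserted at
  $10^{-12}$.
- Seeding: every generator takes an explicit seed and restores the
  caller's RNG state, so generators never perturb a surrounding analysis;
  identical configurations produce identical tables.
- Oracle agreement for centralities and the hypergeometric tail is
  asserted at $10^{-12}$/$10^{-10}$ (pure floating-point noise), not at a
  statistical tolerance.
- Problem sizes in the test suite: the exhaustive centrality sweep covers
  all labelled graphs on up to 6 nodes plus 100 random graphs on up to 8;
  the hypergeometric sweep covers every $(N \le 12, K, n, k)$; recovery
  tests use the 500-protein default design and 100 enrichment replicates
  at 75 network nodes. These sizes give exhaustive coverage where
  enumeration is possible and stable Monte-Carlo rates where it is not,
  while keeping the default test run in minutes.

## Limitations

- Protein inference is out of scope: each spectrum row arrives with its
  accession, and shared peptides are not modelled.
- The purity matrix defaults to no correction; results on real data depend
  on supplying the vendor certificate.
- The enrichment background defaults to the GMT union; p-values are not
  comparable across runs with different GMT files, and annotation-database
  snapshots make externally reported enrichment scores non-reproducible by
  design.
- The hub screen is a marginal rule on three correlated centralities; it
  is auditable and matches the workflow it implements, but it is not an
  optimal detector of "importance" in any decision-theoretic sense.
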