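---
title: "Identifying Africanized honey bees: models, markers and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Africanized honey bees: models, markers and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afribee)
```

## The problem

Africanized honey bees — New World hybrids between the sub-Saharan
*Apis mellifera scutellata* and European *A. mellifera* subspecies — can be
recognised in two largely independent ways:

* **maternally**, from mitochondrial DNA, where the African (A) lineage is
  distinguished from the European and Middle Eastern lineages (C, M, O); and
* **morphologically**, from body size, because Africanized workers tend to be
  smaller than European workers.

In a hybrid zone the two assessments need not agree for an individual bee:
drones carry nuclear genes without mitochondria, so bidirectional
hybridization decouples mitotype from morphology as introgression proceeds.
afribee implements both assessments and the statistics used to compare them.

## Morphometric discriminant functions

Four lengths are measured per worker, all in millimetres: right forewing
(FWL), right hindwing (HWL), and femur (FL) and tibia (TL) of the right hind
leg. Two fixed linear discriminants are applied:

* **individual workers**:
  `2.5164 FWL + 1.2159 HWL + 16.3439 FL − 10.6356 TL − 36.4909`
* **colony means** (each measurement averaged over the sampled workers of a
  colony, conventionally ten):
  `2.7535 FWL + 2.6834 HWL + 27.9261 FL − 19.5551 TL − 46.5884`

A score strictly below a midpoint threshold classifies the worker or colony
as Africanized; a tie classifies European, the conservative direction given
the "smaller than the midpoint" convention. The midpoints themselves are
properties of the reference training populations and are **not** baked into
the package: the shipped default threshold is 0 for both formulas, because
the discriminant axes are constructed so that the African and European group
means straddle zero. Users reproducing a specific survey must supply the
midpoint derived from that survey's reference means. Scores are computed at
full floating precision and conventionally reported to four decimals.

The expected misclassification rates of these discriminants against
molecular ground truth are about 9.9% for individual workers and 3.5% for
colony means; the synthetic-data generator is calibrated around the former
(see below).

```{r}
individual_score(9.0, 6.0, 2.6, 3.2)
classify_score(individual_score(9.0, 6.0, 2.6, 3.2))
```

## The three mitochondrial assays

**Cytochrome b BglII restriction typing.** The classic gel assay: a
cytochrome b amplicon is digested with BglII (recognition site `AGATCT`,
cutting after the first base, `A^GATCT`). African mitochondria lack the site
(one band); European and Middle Eastern mitochondria carry it (two bands).
`digest()` reproduces the digest in silico and `rflp_mitotype()` applies the
band-count rule, scoring any other visible band count indeterminate. Two
numerical choices matter:

* `min_visible_bp` (default 50): fragments shorter than this are treated as
  having run off the gel. Published protocols do not state a resolution
  limit; 50 bp avoids scoring a few-bp terminal fragment as a band.
* Ambiguous bases (`N`) never match the motif: an uncertain site cannot
  create a cut, so degraded sequence biases the assay toward the uncut
  (single-band) phenotype rather than inventing European calls from noise —
  and a truly uncut amplicon is still confirmed by the other two markers.

**Diagnostic COI barcode SNP.** A single site in the standard ~650 bp COI
DNA-barcode fragment separates African from non-African mitotypes: cytosine
marks the African lineage, thymine the European lineages (position 2382 in
mitogenome reference numbering). Because barcode fragments start at
arbitrary offsets, the coordinate is stored as an annotation on the panel's
reference fragment and every query is mapped to it by pairwise alignment
(query-global within reference-local; match 2 / mismatch −3, gap open 5 /
extend 2). A call is confident only when alignment identity is at least 90%
(configurable) — below that the record is unlikely to be honey-bee COI at
all — and a gap, another base, or a query that does not cover the site
yields `indeterminate`, never an error.

**COI–COII spacer lineage.** The intergenic spacer between COI and COII
assigns mitochondria to the named lineages (A, C, M, O). Published practice
places query sequences on a phylogeny with reference haplotypes;
tree inference is out of scope here, so afribee uses deterministic
nearest-reference assignment: normalized edit distance (edits / alignment
length) from a global alignment to each exemplar, with the call going to the
unique minimum and ties scored indeterminate. At exemplar level this is
equivalent to tree placement whenever the query is closer to one exemplar
than to any other — guaranteed when its divergence from the true lineage is
under half the minimum pairwise exemplar distance.

```{r}
panel <- default_panel()
panel
sq <- make_marker_sequences("african", panel, seed = 7)
rflp_mitotype(sq$cytb, panel)
coi_snp_call(sq$COI, panel)
spacer_lineage(sq$spacer, panel)
```

The packaged panel is a clearly labelled **synthetic stand-in** with the
right structure (motif-free reference, T at the diagnostic site, four
exemplars separated by ≥ 43 edits over 220 bp) but invented sequence; real
surveys must substitute real reference haplotypes via `read_panel()`.

## Statistics

* `gof_chisq(k, n, p0)` — two-cell goodness-of-fit chi-square of an observed
  proportion against a reference proportion, no continuity correction, df = 1.
  This reproduces published hive-versus-foraging-worker comparisons exactly;
  corrected statistics do not. Expected cells below 5 warn rather than error
  because several published comparisons have small expecteds.
* `heterogeneity_chisq(counts, p_hat)` — compares the per-site counts of
  African-mitotype workers (0..k of k sampled per site) with the binomial
  expectation from drawing k workers at random from one population.
  Convention: df = k as published, even though p̂ is estimated from the same
  data; `df_convention = "conservative"` gives df = k − 1. Simulation shows
  the published convention is mildly conservative (rejection below nominal
  5%).
* `pooled_t(a, b, tails)` — equal-variance two-sample t on df = nₐ + n_b − 2,
  for comparing mean discriminant scores by mitotype. Default two-tailed;
  some published comparisons are consistent only with one-tailed p-values,
  so tails is a per-call flag. Zero pooled variance with equal means returns
  t = 0 by convention; with unequal means it is a domain error.
* `estimate_frequency(calls)` — African-mitotype frequency with a Wilson
  score interval, chosen over the Wald interval because it behaves at extreme
  frequencies; indeterminate calls are excluded and counted.

## The synthetic-data generator

`sim_config()` states a world and `sample_population()` /
`sample_sites()` / `make_marker_sequences()` draw from it, fully determined
by one seed (components use deterministically derived child streams, so
results do not depend on call order).

* **Mitotype**: Bernoulli with `p_african` (default 0.65, the frequency
  reported among foraging workers in the focal county survey).
* **Sites**: workers grouped `bees_per_site = 3` per site, the field
  protocol; site counts in `sample_sites()` are i.i.d. binomial — exactly
  the null of the heterogeneity test.
* **Nuclear class and λ**: with probability λ a bee's nuclear class equals
  its mitotype, otherwise it is an independent Bernoulli draw. λ = 1 is the
  early-introgression regime (mitotype predicts morphology); λ = 0 the fully
  admixed regime with no association. A single correlation parameter was
  chosen over an explicit mating-system model because the contrast being
  emulated is precisely a correlation statement.
* **Morphometrics**: multivariate normal per nuclear class. Published
  sources print discriminant **score** means, never raw measurement moments,
  so the measurement-level defaults are honey-bee-plausible placeholders:
  base means FWL 9.0, HWL 6.3, FL 2.6, TL 3.2 mm and a diagonal covariance
  shape (SD 0.15, 0.12, 0.06, 0.08 mm). The covariance is rescaled once so
  the individual score has unit SD, and the group means are shifted along the
  coefficient vector (`calibrate_morph_means()`) to hit the configured score
  targets exactly. The default targets ±1.2873 place the groups so that the
  midpoint-0 rule misclassifies 9.9% of workers — the documented expected
  rate — which fixes the one free parameter (covariance magnitude) the
  sources leave open.
* **Sequences**: constructed so that with zero extra mutations every assay
  recovers the generating mitotype (motif-free or single-site cytochrome b
  amplicon of 485 bp with both fragments gel-visible; reference COI with the
  diagnostic base set; the A exemplar or a random non-A exemplar as spacer).
  Extra substitutions avoid the motif and the diagnostic site and may not
  create new motif occurrences (rejection sampling, capped at 10,000 tries —
  unreachable in practice at amplicon scale).

What a green simulation-based test does establish: the pipeline's internal
consistency — assays invert the generator, estimators recover generating
parameters, the linkage contrast between λ = 1 and λ = 0 reproduces the
qualitative published pattern (a large northern t versus a non-significant
county t). What it does not establish: agreement with field measurements,
real haplotype diversity (the generator emits exemplar copies, not a
haplotype cloud), heteroplasmy, sequencing error models, or spatial
structure. Field percentages printed in surveys are therefore not asserted
anywhere; they require the original specimen-level tables.

## Degenerate inputs and tie-breaks

* Classification ties at the threshold → European (strict-inequality rule).
* Spacer distance ties → indeterminate.
* `digest` on a motif-free sequence → one fragment; `min_visible_bp` can
  legitimately produce zero visible bands, which `rflp_mitotype` scores
  indeterminate.
* Measurement tables fail fast on non-numeric rows; `skip_bad = TRUE` drops
  them loudly. Delimiter sniffing is restricted to comma and tab — anything
  else must be explicit, because a silent misparse is worse than an error.
* BOLD-style records lacking sequence or coordinates are flagged
  (`no-sequence` / `no-coordinates`) and kept; how to filter them is the
  caller's decision.

## Known limitations

Nearest-reference lineage assignment is only as good as the exemplar panel;
with closely related exemplars the half-minimum-distance guarantee shrinks.
The generator's measurement covariance is synthetic, so simulated
measurement values (as opposed to scores) should not be compared with real
bees. Colony-level misclassification calibration is not independent of the
individual-level calibration: both derive from the same measurement
covariance, and the package calibrates at the individual level.
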