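---
title: "Methods: disease-index scoring and microbiome meta-analysis in phragpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-index scoring and microbiome meta-analysis in phragpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phragpath)
```

## Scope

`phragpath` packages two linked workflows for common reed (*Phragmites
australis*) microbiology: scoring pathogenicity bioassays (seedling,
mature-leaf, saprophyte) and meta-analysing literature reports of the reed
microbiome. This vignette records the models, parameter choices, numerical
conventions and known limitations; empirical claims here are limited to what
the test suite itself computes.

## The seedling disease model

An inoculated replicate of sterile seedlings is observed repeatedly over up
to three weeks; at each visit the leaves are tallied into five ordinal
categories (0 dark green, 1 pale green, 2 yellow, 3 brown spots, 4 dead) and
summarised as the count-weighted disease index

$$\mathrm{D.I.} = \frac{\sum_{k=0}^{4} k\,N_k}{\sum_{k=0}^{4} N_k} \in [0, 4].$$

Symptom development on this scale is close to linear during the infection
phase, so each replicate reduces to the slope of a least-squares line forced
through the origin (an uninfected plant starts symptom-free):
$b = \sum_i t_i\,\mathrm{DI}_i \big/ \sum_i t_i^2$. The **standardized
10-day index** is $10\,b$, clipped to $[0, 4]$.

Two cleanup rules precede the fit:

* **Age exclusion.** Control plants slow down and develop iron-chlorosis
  symptoms in week three, so observations from plants older than 16 days are
  dropped. "Older than 16" is read strictly: day 16 itself is retained.
* **Death truncation.** Once a microbe has killed every leaf the index is
  pinned at 4.0 and no longer carries rate information; only the first two
  fully-dead observations are retained so that the plateau does not drag the
  slope toward zero.

Both rules are idempotent and order-independent for sorted days (tested).
Even with the truncation, a fast killer's retained dead points lie *below*
the extrapolated line $\mathrm{DI} = \beta t$ whenever observation days fall
after the death time $4/\beta$, so standardized indices of strong pathogens
are conservative. This is a property of the published standardization, not
of this implementation; the package therefore also reports the unclipped
`di10_raw` and per-fit bookkeeping (`n_used`, `excluded`).

The **growth rate** (leaves/day) applies the identical machinery to total
leaf count. A through-origin fit is a deliberate, literal reading of the
protocol even though a seedling starts with at least one leaf; an ordinary
least-squares alternative is available via `origin = FALSE` for sensitivity
analysis.

### Classification thresholds

All cut-points live in one `classification_thresholds()` object; nothing is
hard-coded in stage logic. Defaults:

| parameter | value | meaning |
|---|---|---|
| `symptom_floor` | 0.03 | seedling index at or below which symptoms are attributed to iron-deficiency chlorosis |
| `seedling_weak_min` | 0.1 | minor-lesion floor for the Weak Pathogen band |
| `seedling_pathogen_min` | 2.0 | Pathogen boundary (inclusive, after rounding) |
| `seedling_strong_min` | 4.1 | Strong Pathogen boundary |
| `mature_weak_min` / `mature_pathogen_min` / `mature_strong_min` | 0.2 / 0.5 / 0.8 | half-open bands on the 0–1 lesion scale |
| `max_day` | 16 | last retained plant age |

Two genuinely open points were settled as follows:

* The source material states "pathogenic = D.I. ≥ 2.0" in one place and a
  "2.1–4.0" band in another. We classify **after rounding half-up to one
  decimal** with Pathogen iff ≥ 2.0; both readings agree on every printed
  value, and this reproduces the headline count of 13 pathogenic isolates
  (asserted in the acceptance suite).
* No seedling "Weak Pathogen" band is named in the source. We label values
  between the chlorosis floor and 2.0 as Weak Pathogen when they clear the
  0.1 minor-lesion floor. This is an extension, documented as such, and can
  be disabled by raising `seedling_weak_min` above the scale maximum.
* The 0.03 chlorosis floor is applied to the **standardized** value (whether
  the original analysis applied it before or after standardization is not
  stated).
* Mature-leaf classification uses exact half-open intervals with **no
  rounding**: replicate means of scores in {0, 0.5, 1} are exact multiples
  of $1/(2n)$, so rounding would only blur the stated band edges.
* Rounding is half-up everywhere a convention is needed (`round_half_up()`),
  matching how the printed percentages (12 %, 78 %, 27 %, 85 %) are
  reproduced by integer arithmetic.

## Comparative statistics

The statistical layer is implemented from first principles — the point is a
self-contained, auditable computation — and each primitive is cross-checked
in the tests against an independent implementation (`t.test`,
`vegan::vegdist`, `vegan::adonis2`, `vegan::betadisper`, `hclust`):

* **Paired t-test** on within-pair differences, two-sided, df = n − 1;
  zero-variance differences yield t = ±∞ (p reported as the limit 0) or
  t = 0, p = 1 when all differences vanish.
* **Bonferroni**: adjusted p = min(1, m·p).
* **Bray–Curtis**: $\sum|u-v| / \sum(u+v)$, with a presence/absence mode
  because literature reports are often presence-only; both-zero vectors are
  an error, never 0/0.
* **PerMANOVA** (one-way, Anderson's direct partition):
  $SS_\mathrm{total} = \sum_{i<j} d_{ij}^2/n$,
  $SS_\mathrm{within} = \sum_g \sum_{i<j \in g} d_{ij}^2/n_g$, pseudo-F
  $=(SS_B/(g-1))/(SS_W/(n-g))$, p-value
  $(1 + \#\{F^* \ge F\})/(1 + n_\mathrm{perm})$ over seeded label
  permutations (default 999; the +1 correction keeps p ≥ 1/(n+1)). Only the
  single-factor design is implemented; that is the design the comparisons
  require. On Euclidean distances of univariate data the pseudo-F equals
  the classical ANOVA F to 1e-9 (acceptance test d), and the type-I error at
  α = 0.05 is calibrated over 500 null simulations (acceptance test c).
* **Dispersion check**: principal-coordinate embedding keeping
  negative-eigenvalue axes, distance of each sample to its group's spatial
  median (Weiszfeld iteration; centroid optional), F on those distances with
  a permutation p obtained by shuffling the distances across groups. This is
  a simplification of permuting least-squares residuals; for the one-factor
  balanced designs used here the two coincide in distribution under the
  null.

Every stochastic routine takes an explicit seed, restores the caller's RNG
state, and is bit-reproducible.

## Literature meta-analysis rules

* **Lineage assignment** is a fixed precedence: author statement → Gulf
  lineage excluded (interspecific hybrid) → central/western North America
  before 1910 = native *americanus* → Spain/Portugal/Italy/Egypt/Morocco =
  Mediterranean *altissimus* → Romania = uncertain (hybrid zone) → remaining
  Europe, Asia, Australia, Africa = *australis*. The "central/western"
  boundary is nowhere defined in the source; it is operationalized as
  longitude west of −85° when coordinates exist, else a curated
  state/province list, both configurable.
* **Tissue normalization** is dictionary-driven onto a closed vocabulary;
  roots and rhizomes merge into `root_associated`; unknown terms are a hard
  error naming the term (no silent bucket). Compartments derive as
  phyllosphere / rhizosphere / soil.
* **Community filter**: culture-dependent studies only, grouped by
  study × tissue × microbial group, groups with ≥ 10 reports become one
  community sample of taxon counts. Taxon identity is the SH
  (species-hypothesis) code when present, else the case/whitespace
  normalized name; synonymy resolution is out of scope.
* **Overlaps and coverage**: exact Venn-region cardinalities for up to three
  sets (counts only — area-proportional rendering is out of scope), pairwise
  shared fractions, and collection coverage |collection ∩ reported|/|reported|.
* Reports from dead stem tissue are excluded via the `tissue_alive` flag
  when present; unknown vitality is treated as alive.

## Trophic classification

Predicted modes come from a local guild-table snapshot (no network calls):
lookup by species binomial, then genus; matches graded "possible" or resolved
only at family rank or higher are discarded. The experimentally supported
class uses an explicit precedence — Pathogen (seedling class ≥ Pathogen or
mature class Strong Pathogen) → Saprophyte (sporulated on autoclaved leaves)
→ Endophyte (sterile hyphae only, or no saprophytic growth despite isolation
from living tissue) → Unclassified. The source never states the rule that
produced its experimental 1:1:12 ratio; this reconstruction is confined to
`experimental_trophic_class()` so alternatives can be swapped. Likewise the
denominator behind its "at least 74 % complete their life cycle on dead
tissue" is ambiguous (73/101 vs 73/98), so `saprophyte_summary()` reports the
raw numerator and denominator rather than matching a percentage.
P:E:S ratios are normalized to endophyte = 1 and rounded half-up; a zero
endophyte count flags the normalization undefined rather than dividing.

## Barcode clustering

The identification workflow consumes *precomputed* similarity data — no
alignment or database search is reimplemented. Hits are screened at 95 %
query coverage and 99.0 % identity among the top 50 by score ("length" is
read as query coverage). WPGMA agglomeration uses the weighted average
$d(A\cup B, C) = (d(A,C)+d(B,C))/2$ with ultrametric node heights (half the
merge distance) and deterministic lexicographic tie-breaking; heights are
monotone and random ultrametrics are recovered exactly (acceptance test f).
Species-hypothesis clustering at the 1.5 % threshold is single-linkage
connected components — the closest local analogue of reference-database
threshold clustering, documented as an approximation.

## The synthetic-data generator

The generator emits the *stated world* of the analysis, fixed once:

* 162 isolates with a 2 : 20 : 140 strong/weak/nonpathogen mixture (the
  published marginal counts, used as a familiar fixture, not as a claim of
  reproducing the real data);
* per-replicate latent trajectories $\mathrm{DI}(t) = \min(4, \beta t)$ with
  $\beta$ uniform in class-specific ranges — strong 0.41–0.70 (10-day index
  at or above the strong threshold), weak 0.05–0.20 (0.5–2.0), nonpathogen
  0–0.003 (at most the chlorosis floor); observation days 4, 8, 12, 16;
  4–14 plants per replicate; 0.5 leaves/day/plant;
* leaf counts split between the two categories bracketing the latent index,
  binomially (unbiased) or deterministically (`noise = FALSE`), with an
  optional beta-binomial overdispersion knob — the minimal noise model
  consistent with an ordinal count scale, since the source states none;
* mature-leaf sections drawn per class from multinomials over {0, 0.5, 1}
  with 3–7 replicates; intact (non-abraded) leaves never develop lesions,
  reflecting the cuticle barrier;
* literature tables built from continental taxon pools with an exactly
  controlled number of multi-continent taxa (default 34), 119 studies with a
  98/119 culture-dependent fraction, Poisson isolate counts, and countries/
  years consistent with the lineage rules. Continental pool sizes
  (234/278/30 private + shared) echo the printed per-continent taxon totals.

What a green round-trip test establishes is internal consistency — the
pipeline recovers the quantities the generator planted (slopes within 5 %,
overlap and community counts exactly). It does **not** establish agreement
with the original study's full dataset: the published community statistics
(t = −4.2613, r² = 0.135, p = 0.001, the 6:1:9 and 1:1:12 ratios) require an
external data release and are therefore checked structurally, never
value-matched. Real literature data also carry features the generator omits:
synonymy and misidentification, geographically clustered sampling effort,
non-Poisson study sizes, and abundance reporting heterogeneity.

## Numerical conventions and degenerate inputs

* Half-up rounding everywhere a printed convention exists; comparisons at
  band edges happen after rounding for the seedling scale only.
* A zero leaf total is an explicit "unscoreable observation" error; an
  all-excluded time course is "insufficient data"; all-zero days make the
  through-origin slope undefined and error out.
* Distance matrices are validated (symmetry, zero diagonal, non-negativity)
  with tolerance 1e-8 before any clustering or permutation test.
* WPGMA ties are broken by the lexicographically smallest pair of cluster
  representatives, so label order never changes the topology (up to
  isomorphism).
* Seeds: every generator and permutation routine takes an explicit integer
  seed and leaves the global RNG state untouched.

## Known limitations

* Single-factor PerMANOVA only; no nested or multi-factor designs, no
  ordination plots.
* Lineage rules depend on free-text geography; reports with unmappable
  countries fall back to "uncertain" with a warning.
* The dispersion check permutes distance-to-center values rather than model
  residuals; with strongly unbalanced groups the residual-permutation
  scheme would be preferable.
* The guild lookup reproduces only the genus/species matching of guild
  databases, not their internal heuristics.
* Taxon identity treats names as given; no nomenclatural review.
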