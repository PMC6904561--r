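---
title: "Models and methods behind m6ace"
author: "m6ace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind m6ace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6ace)
```

# The measurement model

m6ACE-seq converts the position of an m6A/m6Am residue into a
read-start coordinate: an anti-m6A antibody is photo-crosslinked to the
methylated base, a 5'→3' exoribonuclease digests the RNA up to the
crosslink, and the surviving fragment is sequenced. Under ideal
chemistry every captured fragment of a methylated molecule starts
exactly at the methylated adenosine; in practice a minor fraction of
fragments stops 3–4 nt short of it, and sporadic loci show diffuse
clusters of read starts unrelated to methylation. Input libraries from
the same RNA, fragmented but neither captured nor digested, provide the
coverage baseline.

Everything in this package follows from that model:

* the unit of signal is the strand-aware 5' coordinate of a
  deduplicated fragment (`start` on `+`, `end - 1` on `-`; coordinates
  are 0-based half-open internally, and reports show 1-based positions
  where oligo positions are quoted);
* a site is an adenosine whose read-start count in the m6ACE libraries
  is statistically enriched over the input libraries;
* the imperfect-stoppage and clustered-noise artifacts get dedicated
  filters rather than wider peak windows.

# Site calling

## Candidates

Candidate positions are read starts whose strand-aware reference base
is A and whose mean m6ACE count across replicates is at least 1 (the
input libraries are not thresholded: the methylation signal lives in
the m6ACE libraries). Requiring the reference base keeps the test
family small and excludes the bulk of background starts.

## Enrichment test

Counts are modelled as negative binomial. For each site the m6ACE
group sum is compared to its conditional distribution given the site's
total count — an exact conditional test in the style long established
for small-replicate RNA-seq count comparisons — one-sided, because
only enrichment of m6ACE over input is evidence of methylation.
Numerical choices, in order of appearance:

* **Size factors** are DESeq-style median-of-ratios over the candidate
  table. The median is only meaningful when most usable sites are
  unenriched, so when fewer than 10 sites have all-positive counts the
  estimate falls back to total-count ratios scaled to geometric mean 1.
  Zero library sizes are an error.
* **Dispersion** is a per-site method-of-moments estimate on
  normalised counts (with a `mean(1/s)` correction of the Poisson term
  for unequal size factors), shrunk halfway toward the 20%-trimmed
  mean across sites and capped at 10. At triplicate depth a per-site
  estimate alone is far too noisy; full shrinkage would erase genuine
  per-site overdispersion.
* **Group sums** under unequal size factors are moment-matched to
  negative binomials (`mu = sum(s) * m`, `size = sum(s)^2 / (alpha *
  sum(s^2))`), which reduces to the exact conditional distribution
  when size factors are equal.
* **Mid-p correction.** The conditional distribution is discrete; the
  plain tail is conservative at low counts. The reported p-value is
  `P(S > s) + 0.5 * P(S = s)`. With this correction the null
  false-positive fraction at α = 0.05 sits at 0.03–0.045 across count
  scales (the suite checks a 2,000-site Poisson null against the band
  0.03–0.07).
* **log2FC** is reported from normalised group means with a 0.5
  pseudocount on both sides — reporting only; the test never sees the
  pseudocount.
* A site is called when log2FC ≥ log2(`min_fold`) (default fold 2) and
  BH-adjusted p < `padj_cutoff` (default 0.05; the BH family target
  0.1 is recorded in the configuration alongside it). With a single
  tested site padj equals p.

A Wald test on a negative-binomial GLM was evaluated for this role and
rejected: with three replicates per library a normal reference is
anticonservative (≈9.5% at α = 0.05 under a Poisson null) while a
t reference with residual degrees of freedom is calibrated but cannot
produce the extreme p-values that survive BH adjustment across
thousands of candidates. The exact conditional tail does both.

## Shadow filter

An enriched site S is discarded when another enriched site T lies 1–4
nt 3' of it (strand-aware) and T sits in an R-A-C context on the
reference. This encodes the imperfect-stoppage artifact: fragments of a
genuine R-A-C site that escape full digestion start a few nucleotides
5' of it and can themselves reach significance. The context condition
is checked on the neighbour T, not on S, and the neighbour set is the
*enriched* (pre-filter) sites, which makes the shadow and cluster
filters commute — each filter only marks, never unmarks.

## Clustered-noise filter

An enriched site is discarded when its surroundings look like diffuse
noise rather than a pileup: within ±`window` nt (default 25) of the
site in the pooled m6ACE libraries, more than `max_distinct_starts`
(default 10) distinct positions carry reads *and* the site's own
read-start signature — the strand-aware offsets −4..0, i.e. the exact
stop plus the imperfect-stoppage positions — holds less than
`dominance` (default 0.5) of the pooled window counts. Two refinements
matter in practice:

* dominance is evaluated on the −4..0 signature rather than the single
  site position, because the stop profile legitimately spreads a
  genuine site's reads over those offsets (the same window the RML
  numerator sums);
* counts at *other enriched sites'* signatures inside the window are
  excluded from the total, because two genuine sites closer than the
  window would otherwise annihilate each other — methylated sites do
  occur within a few dozen nucleotides of each other.

No published constants exist for this artifact; all three values are
deliberate, exposed choices in `enrichment_config()`.

# Quantification

## RML

For site i, replicate r:

* `X = m6ACE(−4..0) / input(−51..0)` — the site's captured signal over
  its local input coverage;
* `Y = spike m6ACE(−4..0) / spike input(−21..0)` — the same ratio at
  the spike-in's methylated base;
* `RML = X / Y`.

Offset windows are inclusive on both ends (−4..0 spans 5 positions,
−51..0 spans 52, −21..0 spans 22) and strand-aware; positions off the
contig contribute zero. The spike-in, added at fixed mass to every
sample, cancels between-library differences in crosslinking, capture
and digestion efficiency, which makes RML proportional to the
methylated fraction and comparable across samples. Any zero
denominator makes the replicate's RML undefined (`NA`), never zero;
missing spike-in coverage is a hard error because nothing can be
normalised without it. On the built-in 41-nt spike-in the −51..0 and
−21..0 input windows both clip to the full oligo, so the spike-in
quantified against itself gives RML = 1 exactly — a fixed point the
tests assert.

## Differential methylation

Replicate RMLs are averaged per condition over *defined* replicates
(a site stays testable while at least two remain). The log2 fold
change is oriented by the experiment's direction so called sites
always report LFC ≥ 0: `log2(meanA/meanB)` for reductions
(writer knockout, eraser overexpression; cutoff 2.0) and
`log2(meanB/meanA)` for accumulations (eraser knockout; cutoff 1.0),
with epsilon 1e-6 guarding empty means. Significance is a one-tailed
two-sample t test in the stated direction at p < 0.05. Welch
(unequal-variance) is the default since nothing guarantees equal RML
variance across conditions; `var_equal = TRUE` switches to the pooled
form. Zero-variance ties yield p = 1 (no evidence), so identical
conditions are never called — the suite checks this property
explicitly. The test runs on replicate RMLs, the quantity the
averaging step defines, rather than on windowed counts.

## Mixing linearity

For a WT/KO mixing series, each site's RML per mixture is normalised
to its RML in the 100% WT condition and all site-level points are
pooled into one least-squares regression of normalised RML on the WT
fraction — a single fitted line, not averaged per-site slopes. A slope
near 1 with high R² demonstrates that RML responds linearly to the
underlying methylated fraction. At least three distinct fractions and
the 100% WT condition are required.

# Downstream analyses

* **Metagene.** Sites are mapped into transcript coordinates of a
  containing coding transcript (longest CDS wins when several match —
  the choice is open, and longest-CDS is the stable, annotation-driven
  one), scaled to [0,1) within their 5'UTR/CDS/3'UTR segment, and
  binned on a concatenated axis with equal bins per segment. Densities
  sum to 1; intronic and non-coding-only sites are excluded and
  counted.
* **TSS alignment.** Strand-aware offset of each site to its nearest
  same-strand TSS, histogrammed over ±`max_offset` with an overflow
  bin; translation-invariant by construction.
* **Overlap.** Upper-tail hypergeometric probability `P(X ≥ k)` for
  the observed overlap of two site sets inside an explicit universe;
  both sets must be subsets of the universe. The universe is the
  caller's choice (default in pipelines: union of the condition-wise
  candidate universes) because the published analyses do not pin it
  down.
* **ROC.** The universe — WT-called sites plus sites with significant
  RML accumulation on demethylase knockout — is ranked
  most-insignificant-first by WT padj (sites never tested in WT rank
  as padj = 1). For each LFC stratum (0.0, 0.5, 1.0, 1.5; nested
  sets), positives are sites regulated at least that strongly, and the
  AUC measures how well WT insignificance predicts regulated status.
  Tied padj values share one curve step, so the trapezoidal AUC equals
  the tie-corrected Mann–Whitney statistic (asserted against
  `wilcox.test`); site-id ordering is used only to make the output
  deterministic. Strata with no positives report an undefined AUC.
* **Consensus.** Strand-aware base frequencies at ±`flank` around the
  called sites; each column's IUPAC letter covers the bases at ≥ 0.25
  frequency. This is a descriptive summary of the sequence context,
  not a motif-discovery algorithm.

# The simulator

`simulate_scenario()` generates worlds with the statistical structure
the assay assumes, providing ground truth for every pipeline stage.
Per replicate and condition: a methylated site with stoichiometry θ
emits `Binomial(depth, θ × capture)` m6ACE reads whose starts follow
the exonuclease stop profile; nonspecific m6ACE background and input
reads start uniformly; clustered-noise loci (shared across replicates,
as a sequence-dependent artifact would be) add diffuse m6ACE starts;
N7B UMIs are drawn uniformly and PCR duplicates appended at the
configured rate. All randomness derives from the mandatory seed, so
identical seeds give byte-identical outputs.

Defaults — the study conditions of the validation suite:

| parameter | default | rationale |
|---|---|---|
| replicates | 3 | triplicate design of the assay |
| m6ace_depth | 100 reads/site | typical per-site capture at benchmark depth |
| capture_efficiency | 0.8 | efficient but imperfect antibody capture |
| stop_profile | 0.85 / 0.075 / 0.075 at 0 / −3 / −4 | dominant exact stop with the minor short-stop leak the shadow filter targets |
| stoichiometry | U(0.3, 1) | the regime in which single-site recovery is claimed |
| methylation_fraction | 0.05 of DRACH motifs | sparse methylome |
| m6ace_background | 0.3 reads/nt/replicate | faint nonspecific carryover, consistent with sharp observed pileups |
| input_depth | 2 reads/nt/replicate | smooth input baseline for the −51..0 windows |
| noise loci | ~0.5/transcript, Poisson(40) reads over ±12 nt | sporadic diffuse clusters |
| duplication_rate | 0.3 | moderate PCR duplication |
| spike-in | 41 nt, methylated A at 1-based 21, m6ACE depth 300, input 400 | synthetic stand-in oligo; the published spike sequence is not reproduced, so the stand-in is generated with a single DRACH centred on position 21 and a second adenosine at position 18 to exercise the shadow filter |

The stop-profile magnitudes, capture efficiency and background levels
are declared modelling assumptions, not published measurements.

What the simulator does **not** model: sequencing errors and quality
scores, splice-aware alignment (each transcript is its own single-exon
contig; multi-exon handling is exercised by parser-level fixtures),
mappability and alignment artifacts, isoform mixtures, antibody
sequence bias beyond the N7B constraint, and batch effects. Passing
tests therefore demonstrate correctness of the statistical machinery
under the assay's idealised generative model — not robustness to
alignment or chemistry pathologies in real libraries.

# Validation scale and stochastic checks

The suite runs at desk scale: 30–100 transcripts of 300–600 nt,
~12–280 planted sites, triplicates at the default depths; the
end-to-end scenarios take seconds to ~15 s each. Two stochastic checks
deserve a note:

* planted-methylome recovery is asserted at F1 ≥ 0.9 with ~50 sites
  (observed: perfect recovery at the tested seeds);
* in the demethylase scenario the AUC is asserted to rise across LFC
  strata with a 0.02 allowance between adjacent strata: with
  triplicates, accumulations below LFC ≈ 0.5 rarely reach t-test
  significance, so adjacent strata select nearly identical positive
  sets and their AUC difference is smaller than its own sampling
  noise. The overall increase from stratum 0.0 to 1.5 is asserted
  strictly.

# Known limitations

* The exact conditional test conditions on the site total; very low
  totals (< ~5 reads) have little power regardless of dispersion, and
  such sites survive only as uncalled candidates.
* RML is a relative quantity; absolute stoichiometry would require an
  orthogonal calibration and is out of scope.
* The shadow filter removes a genuine site that sits 1–4 nt 5' of
  another genuine R-A-C site; at m6A's clustering scale this is rare
  but not impossible.
* Metagene assignment uses the longest-CDS transcript, which can
  misplace sites whose dominant isoform is shorter.
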