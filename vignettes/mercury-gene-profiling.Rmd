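---
title: "Profiling mercury-cycling genes in MAGs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling mercury-cycling genes in MAGs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mercmags)
library(dplyr)
```

## The problem

Microbial communities both produce and destroy the neurotoxin
methylmercury. Methylation requires the *hgcA* corrinoid protein gene
acting together with the *hgcB* ferredoxin gene immediately downstream;
demethylation and detoxification run through the *mer* system, where
*merB* (alkylmercury lyase) cleaves organomercury compounds and *merA*
(mercuric reductase) reduces Hg(II) to volatile Hg(0). Genome-resolved
metagenomics can ask *who* carries these genes and metatranscriptomics
*who* expresses them — but each step is easy to get wrong: automated
annotations confuse *merA* with other pyridine-nucleotide disulfide
oxidoreductases (*pndr*, *dld*), *merA* homologs without the essential
cysteines cannot reduce mercury, and *hgcA* without a downstream *hgcB*
does not make a methylator.

`mercmags` implements this screening–curation–quantification chain as a
tested, reusable pipeline, together with a synthetic community generator
that plants every gene class (including the misannotation decoys) with
known ground truth, so that the whole chain can be validated end to end
on a laptop.

## Screening model

Candidates are found with a position-specific log-odds profile per family
(`hgcA`, `hgcB`, `merA`, `merB`, `rpoB`). A profile is built from a seed
alignment (`build_profile()`): columns gapped in at least half of the
rows are dropped; per-column frequencies are mixed with the background
by a Laplace-style pseudocount,

$$ f_{c,a} = \frac{n_{c,a} + w\,b_a}{n_c + w}, \qquad
   S_{c,a} = \log_2 \frac{f_{c,a}}{b_a}, $$

with weight $w = 1$ by default and a uniform background $b_a = 1/20$. A
protein's bit score is the maximum over all ungapped placements of the
profile along it (`score_protein()`), ties going to the smallest start;
the associated e-value is

$$ E = n_\text{targets} \cdot
  \max(\bar L - L_\text{profile} + 1,\, 1) \cdot 2^{-S}, $$

the expected number of equal-or-better placements in a search of the
given size under the base-2 bit-score convention. Profile scores of
hundreds of bits drive $E$ below the double-precision underflow limit,
so all threshold comparisons happen in log10 space; the hits table
carries `log10_evalue` next to `e_value`.

This is deliberately an ungapped position-specific scoring profile, not
a full profile HMM: it is exact, dependency-free, testable against a
brute-force oracle, and sufficient for the substitution-only divergence
the generator produces. The interface (`screen_families()` consuming a
named list of profile objects and per-family thresholds) is the contract;
an external profile-HMM engine can be slotted behind it without touching
downstream code. Full Viterbi/forward recursions and translated search
are out of scope.

**Thresholds.** `merB` uses the fixed stringent cutoff $e^{-120} \approx
7.7\times10^{-53}$, the filter conventionally applied to that family's
homology search; for `hgcA`, `merA`, `hgcB` and `rpoB` no canonical
cutoff exists, so the package defaults to 1e-10 and exposes every
threshold in `default_family_thresholds()`. On the synthetic fixture any
of these choices retains all planted homologs, because planted genes
score hundreds of bits above background.

## Curation rules

**hgcA** calls require operon context (`find_hgcB_downstream()`): the
nearest gene 3′ of *hgcA* on its own strand must be an *hgcB*, on the
same strand, within `max_intergenic` bases (default 200 bp,
configurable). The default is deliberately generous relative to the
0–50 bp the generator plants, while still excluding genes in another
part of the contig; an intervening non-*hgcB* gene or an opposite-strand
*hgcB* voids the context. Strict adjacency (no intervening gene) is
required — the canonical operon arrangement — and the intergenic
distance is `start(hgcB) − end(hgcA) − 1`, strand-mirrored on `−`.

**merA / merB** calls are checked for residue signatures
(`check_signature()`): the candidate is globally aligned to a packaged
reference, the reference-numbered signature positions are mapped through
the alignment, and the call passes iff every position carries an allowed
residue. For MerB the signature is the classical C96/D99/C117/C159 set;
for MerA it is the active-site cysteine pair plus the C-terminal
metal-binding pair. Three safeguards:

* **Truncation**: a signature position falling in a terminal unaligned
  region makes the call `indeterminate`, never `merA_like` — an
  incomplete gene cannot be declared signature-less. "Complete" is
  operationalized as all signature positions lying inside the aligned
  core (outside the leading/trailing query-gap runs).
* **Divergent homologs**: a candidate whose overall alignment identity
  to the reference falls below `min_identity` (default 0.8) is
  `indeterminate` with reason `divergent_homolog`. This is the
  desk-scale stand-in for the phylogenetic curation that field studies
  use to weed out *pndr*/*dld* misannotations (tree placement itself is
  out of scope here): planted decoys sit near 60% identity while true
  merA/merA-like genes at realistic divergence stay above 90%, so the
  floor separates the two populations with a wide margin. It is a
  parameter, not a constant, precisely because real communities may
  need a different bar.
* **Internal deletions** at a required position count as failures
  (`found = "-"`).

A complete close homolog failing the signature is classified
`merA_like` (or `merB_like`) — present, but not credited with the
catalytic capability.

**Alignment.** `global_align()` is a Needleman–Wunsch/Gotoh aligner
with BLOSUM62, gap open 11, gap extend 1 (a length-$L$ gap costs
$11 + L$), implemented in C++ with a fixed traceback tie order
(diagonal, then gap-in-query, then gap-in-reference) so results are
bit-for-bit reproducible. The DP score is verified in the test suite
against exhaustive enumeration of all alignments for every sequence
pair up to length 5 over a three-letter alphabet, and against an
independent implementation (Biostrings) on longer random proteins.

**Signature coordinates are data, not code.** The shipped
`signature_spec.tsv` lists family, reference id, position and allowed
residues; `read_signature_spec()` accepts a user TSV, so the MerA
cysteine-pair coordinates (for which no single printed consensus
exists) can be edited without touching the package.

## Reference sequences

Real curated reference proteins are not redistributable inside this
package, so it ships *synthetic* stand-ins (files and docs are labeled
accordingly): deterministic random-composition sequences carrying the
field's diagnostic residues at the canonical coordinates — MerB
C96/D99/C117/C159 on a 212-residue stand-in, MerA cysteine pairs
136/141 and 558/559 on a 561-residue stand-in, plus HgcA cap-helix-like
and HgcB ferredoxin-like motifs. Every function that takes a reference
or seed alignment accepts user-supplied sequences, so biological
references drop in directly.

## Synthetic community generator

`generate_community()` emulates the statistical structure the analysis
assumes, not the biology of any particular mat:

* **Community**: `n_mags = 24` bins, 2–4 contigs each, ~8 background
  genes per contig, completeness 55–99% and contamination 0–4.5%
  (passing the quality bar; the filter's boundary behavior is tested on
  explicit tables).
* **Planted design** (`default_planted()`): 10 hgcAB operons, 10 merA,
  10 merA-like, 2 merB, 16 pndr/dld-like decoys — the mercury-gene
  census of the two-mat study the package is modeled on. Instances
  spread round-robin over MAGs; each MAG gets exactly one *rpoB* unless
  configured otherwise.
* **Sequence divergence**: planted genes are the packaged references
  with per-residue substitutions at `mutation_rate` (default 0.02);
  signature positions are protected on intact plants and forced to
  non-required residues (Cys→Ser, Asp→Asn) on ablated ones. Decoys
  mutate 40% of positions *including* all signature positions, which
  keeps them well inside profile-detection range (hundreds of bits)
  while putting them far outside the identity floor — reproducing the
  misannotation hazard.
* **Background genes** are uniform-random proteins of 150–450 residues:
  maximally unlike any profile, so background false positives are
  absent by construction. This is a deliberate idealization — real
  proteomes contain true homologs at all identity levels.
* **Samples**: 30 labels (2 sites × 5 season/daytime periods × 3
  replicates), mirroring a two-mat, three-campaign field design with
  day/night sampling. A failed-library exclusion list is a pipeline
  parameter (`excluded_samples`), empty by default, not hard-coded.
* **Transcripts** (`simulate_transcripts()`): negative-binomial
  coverage per gene × sample, mean from per-family rates (background 1,
  mercury genes 2, rpoB 5), dispersion 2. Negative binomial rather than
  Poisson because overdispersion is the norm in metatranscriptome
  coverage; the calibration test checks the empirical mean of 10,000
  draws at rate 5 lands in [4.8, 5.2].
* **DNA coverage**: per-MAG, per-sample base depths log-uniform on
  0.5–30 reads per base (a right-skewed distribution, like real MAG
  coverage tables), with ±15% per-contig noise; MAG coverage is the
  length-weighted mean over contigs.
* **Determinism**: one user seed; each stage (community layout,
  transcript draws) derives its own 32-bit stream seed from it, so
  `generate_community()` and `simulate_transcripts()` are independently
  reproducible and identical config+seed writes byte-identical files.

What passing on this fixture does **not** show: robustness to indels
and fragmented genes (the generator substitutes, never inserts/deletes
— truncation handling is tested with explicit fragments instead), to
homologs at intermediate identity (40–90%), to read-mapping artifacts
(coverage is drawn, not mapped), or to chimeric bins. Results on real
communities depend on the references and thresholds supplied.

## Quantification conventions

* **Quality filter**: strictly over 50% completeness and strictly under
  5% contamination.
* **Abundance**: MAG coverage (reads per base, length-weighted) is the
  relative-abundance proxy; classes are strictly-above vs below the
  community *mean* (not median), with mean/median/max reported.
* **Expression**: per bin and sample, gene coverage is divided by the
  bin's *rpoB* coverage. If a bin carries several *rpoB* copies their
  coverage is summed. Categories: `not_expressed` (gene coverage 0),
  `lower`/`similar`/`higher` against a symmetric two-fold band
  (`similar_band = c(0.5, 2)`, configurable — no numeric band is
  canonical in the literature, so the package declares one), and
  `undetermined` when *rpoB* coverage is 0 but the gene is detected
  (never an infinite ratio). A gene at coverage 0 is `not_expressed`
  even when *rpoB* is also 0.
* **Summed profiles**: per bin, transcripts are summed over all
  sampling periods per gene and compared to the summed *rpoB*
  transcripts with the same band — the whole-run counterpart of the
  per-sample categories, invariant to rescaling all samples jointly.
* **Reporting**: means and percentages are rounded half-up
  (`round_half_up()`), full precision kept internally.
  `column_mean_sd()` uses the n−1 standard deviation.
  `bray_curtis_similarity()` is the percent form
  $100 \cdot 2\sum_i \min(a_i, b_i) / (\sum_i a_i + \sum_i b_i)$,
  cross-checked against vegan.

## Pipeline and evaluation

`run_pipeline()` chains quality filter → screening → curation →
quantification, returns a `mercmags_run` with broom-style `tidy()`
(validated calls) and `glance()` (one-row summary), ggplot2 `autoplot()`
/ `plot_summed_profile()` / `plot_abundance()` figures, and a stage
report in which retained + discarded always equals input.
`evaluate_against_truth()` scores validated calls against the planted
labels: per-family precision and recall plus the merA/merA-like
confusion table. A thin command-line front end
(`inst/scripts/mercmags-cli.R`, subcommands `simulate`, `run`,
`evaluate`) wraps these functions for shell use.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline on 8–24-MAG
communities (a few hundred to ~700 genes) — sizes chosen so a complete
end-to-end validation, including five robustness replicates at 2%
divergence and a 130k-pair brute-force alignment sweep, completes in
about a minute of CPU. The statistical margins involved (hundreds of
bits between planted genes and background; 30 identity points between
decoys and true homologs) do not depend on community size, so scaling
the fixture up changes runtimes, not outcomes. Other numerical choices:
e-value comparisons in log space (underflow), fixed alignment tie order
(determinism), placement floor of one per target in the e-value
(degenerate short-target searches), per-stage derived seeds below
$2^{31}$ (R's integer range).

## Known limitations

Substitution-only divergence; no translated or six-frame search; no
phylogenetic placement (the identity floor is a proxy with a single
global parameter); synthetic references rather than curated biological
ones; operon detection requires strict adjacency, which penalizes
assemblies with genes called inside the intergenic gap; expression
categories depend on a declared band rather than a fitted error model.
Each limitation marks the boundary between this package's scope —
the reusable, testable procedure — and study-specific analysis.
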