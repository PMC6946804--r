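---
title: "Methods: depth-stratified pangenome and DOM-transformation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-stratified pangenome and DOM-transformation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bathypan)
```

# The scientific question

Dark-ocean heterotrophs face a diet of dissolved organic matter (DOM) that
becomes progressively more refractory with depth. One adaptive route is
enzymatic breadth: lineages expand paralogous families of catabolic enzymes
— flavin-dependent monooxygenases (FMNOs) that insert single oxygen atoms
into otherwise inert substrates, ring-hydroxylating dioxygenases, and
enolase-superfamily racemases that collapse chiral complexity. `bathypan`
provides the statistics that connect three layers of evidence: (i) paralog
copy-number expansions in genome bins, (ii) the depth distribution of those
genomes and gene families in metagenomes, and (iii) a mass-difference
signature of oxygenase activity in FTICR-MS spectra of DOM.

# Models and procedures

## Gene-family abundance, Z-scores, expansion scores

`family_abundance()` expresses each family as percent of a genome's total
genes, `100 * n_fg / N_g`, which removes genome-size differences between
partial bins. Column sums equal 100 exactly when the annotation covers
every gene, giving a cheap integrity check. Z-scores are computed per
family **across genomes** (row-wise), with the sample (n − 1) standard
deviation; constant rows map to all zeros rather than erroring, because
subset matrices routinely contain all-zero families. Row-wise
standardization is the reading that makes a heatmap answer "which genomes
are enriched for this family"; the alternative (per genome, across
families) would instead rank families within a genome, which is not the
comparison of interest. "Top" families are ranked by mean relative
abundance across genomes — a symmetric, scale-free statistic that is not
dominated by whichever subgroup happens to have the most genomes — with
lexicographic tie-breaks for determinism.

The expansion score for a (family, subgroup) pair is
`(mean_in + ε) / (mean_out + ε)` with ε = 0.01 percentage points. The ratio
form makes "planted only in subgroup X" score maximal; the pseudocount
keeps families absent outside a subgroup finite and maps
families absent everywhere to exactly 1 (ε/ε), a neutral value. Raw maximum
copy counts per subgroup are reported alongside, since a mean-ratio score
and a copy-number ceiling answer different questions. This
operationalization is the package's own; abundance heatmaps in the
literature make the claim visually, and users who prefer a different
statistic have the full matrix.

Family–family association uses Pearson's r (the correlation the rest of the
analysis family uses), with constant families reported as missing — a zero
would assert independence that was never measured.

## Fragment recruitment

Alignments arrive in BLAST outfmt-6-like tables; subject coordinates are
converted once, at parse time, from 1-based inclusive (minus-strand hits
normalized so start ≤ end) to 0-based half-open, the representation BED
masks already use. Filtering keeps records with percent identity ≥ 80 by
default. Aligner parameter conventions differ on whether the "80" cutoff
means identity or read coverage, so a separate optional coverage filter is
provided but off by default — both readings are expressible without
conflating them. Any overlap (≥ 1 bp) with an rRNA mask interval
disqualifies a record: rRNA recruits promiscuously across taxa, and the
conservative rule is cheap to reason about and test. Multi-mapped reads can
be collapsed to the best hit per (read, genome) by bit score (first
occurrence when scores are absent), logged, and off by default since the
synthetic generator emits unique assignments.

Two normalizations are computed because the field prints both: the primary
metric `R(g, s) = Σ aligned_bases / total_bases(s)` (dimensionless, ≤ 1 per
cell under unique mapping, so per-sample column sums are a conservation
check) and a per-Mbp variant `R / size_bp × 10^6` that corrects for genome
size when comparing bins of different completeness. Callers choose
explicitly; nothing is silently divided.

## Single-copy normalization and depth correlations

Per-sample enzyme abundance is normalized as (taxon genes in family) /
(taxon genes in any single-copy marker cluster). The denominator counts
gene *occurrences*, not distinct clusters — with a fixed panel the
occurrence count is proportional to the taxon's genome equivalents in the
sample, which is the quantity that cancels sequencing depth. A zero
denominator gives a missing value with a warning: reporting 0 would claim
absence of the enzyme, and infinity would claim presence without cells,
both wrong. `single_copy_panel()` applies the defining filter (copy number
exactly 1 in every genome); selection of phylogenetically well-behaved
subsets beyond that filter is left to the user as an explicit list, since
"evidence of linear inheritance" is a judgment call, not an algorithm.

Depth correlations are Pearson on (value, depth) pairs with pairwise
deletion of missing samples and a two-sided p-value from
`t = r sqrt((n−2)/(1−r²))`. Depth enters untransformed (linear meters) by
default — no transform is standard in this literature — with a log-depth
option behind a flag. The miTAG-style sample screen `select_samples()` is
inclusive at its 1% threshold ("at least 1%").

## Mass-difference statistic

For a peak list (treated as neutral monoisotopic masses, sorted,
deduplicated within 1e-6 Da), `count_mass_differences()` counts unordered
pairs whose difference matches a transformation mass within
`tol_ppm × 1e-6 × (heavier mass)`. Exact masses are Δ(O) = 15.994915 Da and
Δ(C) = 12.000000 Da (IUPAC monoisotopic values). The default tolerance of
1 ppm, relative to the heavier peak, reflects FTICR mass accuracy; an
absolute-Da tolerance is available for lower-resolution data. The counter
is a vectorized sorted-window sweep (`findInterval` over the sorted list),
O(n log n); the test suite proves it equal to a naive all-pairs oracle on
hundreds of random instances. Counting is per sample, unweighted by
intensity (the statistic counts observations), and charge deconvolution is
out of scope — peak lists are assumed neutralized upstream. The O:C ratio
is missing when the carbon count is zero, and 0 when only the oxygen count
is zero.

## ANI and dereplication

`estimate_ani()` computes the Jaccard similarity J of canonical k-mer sets
(k = 21, odd so no k-mer is its own reverse complement; canonical = the
lexicographically smaller of a k-mer and its reverse complement, making the
estimate strand-independent) and applies the Mash relation
`ANI = 1 + ln(2J/(1+J))/k`. A k-mer-sketch ANI is used instead of an
alignment-based one because downstream decisions only compare against a
0.99 threshold, a range where the estimator is accurate — the test suite
verifies that megabase pairs generated at 1% divergence estimate in
[0.985, 0.995]. K-mer extraction is compiled (2-bit packed hashes in C++),
as in the field's sketching tools. Disjoint k-mer sets are flagged
`no_overlap` with ANI 0 rather than extrapolating the formula.

Dereplication builds a graph with edges at ANI ≥ 0.99 (inclusive, the
natural reading of "share 99% ANI") and decides per connected component:
same-station near-duplicates are flagged `merge_candidate` (coassembly is an
external step), otherwise the bin maximizing
`Q = completeness − 5 × contamination` is retained and the rest discarded,
naming the winner. The 5× contamination weight is the convention
established by dereplication tooling and is exposed as a parameter; "more
complete and less contaminated" does not define an order by itself, and a
combined score, unlike a lexicographic rule, cannot be reversed by a 0.01%
completeness difference. Ties break by size, then id, so decisions are a
deterministic function of the input *set* — permutation invariance is
tested.

QC thresholds are strict inequalities (redundancy < 1.1, contamination
< 5.0), matching "less than" exactly; the boundary cases are tested.

## Chiral-complexity enzyme model

A compound with n chiral centers has 2^n stereoisomers. A degrader without
racemases needs an enzyme per stereoisomer (2^n); with a racemase per
center, one degradative enzyme plus n racemases suffice (n + 1). For n = 3:
8 versus 4. The model is the quantitative argument for why racemase
(enolase-family) expansions pay off in chirally complex DOM: the saving
2^n − (n+1) grows exponentially, with equality only at n ∈ {0, 1}.

# The synthetic-data generators

The generators produce every input the pipeline consumes, with the planted
parameters returned as a truth record, so each stage is validated by
parameter recovery rather than against fixtures.

- **Pangenomes** (`simulate_pangenome`): per-(genome, family) copy counts
  are negative binomial (dispersion shared, default size 5) around a
  background mean of (genes per genome)/(families), with planted
  (subgroup, family) pairs at an elevated mean. The over-dispersion mimics
  the heavy-tailed paralog counts of real bins, where one genome can carry
  >100 copies of a family that averages a handful.
- **Communities** (`simulate_community`): subgroup relative abundance
  follows a Gaussian in depth (center, width, peak) — the simplest unimodal
  shape matching observed depth maxima; reads are allocated multinomially,
  and every alignment spans the full read length, so aligned bases are
  conserved by construction.
- **Peak lists** (`simulate_peaklists`): shared base peaks, a +12 Da carbon
  ladder whose per-formula lengths are drawn once and reused across samples
  (so the planted one-carbon count is depth-invariant), and
  `round(p(depth) × n_base)` one-oxygen partners. The rounding makes the
  truth-record O:C ratio non-decreasing in depth exactly, not merely in
  expectation, which keeps the monotonicity property testable without
  slack. Noise peaks add accidental pairs, as real spectra would.
- **Sequence pairs** (`simulate_sequence_pair`): i.i.d. substitutions that
  always change the base, so divergence 1 forces a full-length Hamming
  distance.
- **Gene surveys** (`simulate_gene_survey`): per-sample gene tables whose
  family/marker ratio is linear in depth plus Gaussian noise scaled so the
  generating correlation equals `target_r`; it exists as its own generator
  because the community simulator's niche curves parameterize taxon
  abundance, not within-taxon family trends, and conflating the two would
  make recovery tests circular.

Each generator seeds its own RNG locally (restoring the caller's RNG
state), so artifacts can be regenerated independently and identical
configs are byte-identical.

What the generators deliberately do not emulate: sequencing error and read
QC artifacts, assembly/binning chimeras, isotopologue patterns and charge
states, compositional correlations between gene families, and
non-Gaussian (e.g. bimodal) niche shapes. Passing recovery tests therefore
demonstrates that the statistics recover what they claim from data obeying
the stated models — not that real trench metagenomes will be as clean.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the smallest sizes at
which the planted effects are comfortably identifiable: paralog-expansion
recovery on 5 subgroups × 20 genomes × 300 families with 10× plants over
50 replicates; depth-trend recovery at n = 100 samples (generating
r = 0.9, 20 seeds) plus a 1000-replicate independence null at n = 50;
niche recovery on a 7-point depth grid with 8000 reads/sample over 50
replicates; mass-difference oracle equality on 200 instances up to 500
peaks; and ANI recovery on 50 megabase pairs at 1% divergence. The
headline real-data values the literature reports (e.g. Pearson r ≈ 0.87
for FMNO abundance versus depth across ocean metagenomes, 639 single-copy
clusters in 141 genomes, a 114-copy FMNO genome) require the original
survey data and serve here as qualitative anchors: the package reproduces
the *form* of each analysis and demonstrates recovery of known truths at
these scales.

Numerical details: sample (n − 1) standard deviations throughout; constant
vectors yield Z = 0 but missing correlations; Pearson p-values use the
exact t reference, so the null calibration is exact up to Monte-Carlo
error; mass tolerances are relative to the heavier peak, making counts
monotone in tolerance; ANI is clamped to [0, 1] and 21-mer hashes are
exact in doubles (42 bits < 2^53). Ties are always broken
deterministically (lexicographic ids, then size), so every pipeline output
is a pure function of config + seed.

# Known limitations

- The k-mer ANI estimator loses precision below ~90% identity; it is fit
  for a 99% dereplication threshold, not for distant comparisons.
- Expansion scores compare means; a family expanded in half a subgroup's
  genomes dilutes its own signal. The reported max copy counts mitigate
  this but do not model within-subgroup heterogeneity.
- Recruitment assumes uniquely assigned reads when interpreting column
  sums as fractions; competitive mapping across highly similar bins would
  require upstream disambiguation.
- The mass-difference statistic counts all pairs, including accidental
  matches from unrelated formulas; it is a relative, between-sample
  signal, not an absolute count of oxidation events.
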