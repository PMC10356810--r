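---
title: "Detecting selection of structural features in somatic missense mutations"
author: "SomaticSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection of structural features in somatic missense mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SomaticSelect)
```

# The problem

Deep sequencing of normal tissues reveals thousands of somatic mutations.
Mutations that raise a cell's competitive fitness seed expanding clones and
are over-represented among the mutations detected; mutations that lower
fitness are depleted. A gene's observed missense mutations are therefore an
in-vivo mutational scan: if mutations sharing a structural property — a
destabilising folding free-energy change (∆∆G), a position on a
ligand-binding interface, proximity to a bound substrate — occur more (or
less) often than chance predicts, that property is under selection, and the
pattern says something about how the protein's function couples to cell
fitness.

Chance, here, is not uniform. Mutagenesis is strongly context-dependent, so
the neutral expectation for *which* mutations arise must be built from the
mutational spectrum of the dataset. SomaticSelect implements the full
chain: spectrum → per-SNV neutral null → feature scoring → selection tests
→ iterative exclude-and-retest layering → a per-gene CDF-shift summary.

# The neutral null model

## Mutational spectrum

For every gene carrying at least one exonic mutation, the longest annotated
transcript is kept (ties broken by smallest transcript identifier). Every
CDS position is assigned its trinucleotide context read in the direction of
transcription; the first and last positions use a single supplied flanking
base. The spectrum has 192 strand-specific channels — 16 flanking pairs ×
4 reference bases (ref ≠ alt) × 3 alternates — and each channel's rate is

$$\hat r_{c} = \frac{\text{mutations of channel } c}{\text{occurrences of the context of } c \text{ in the included transcripts}}.$$

A mutation merged from $k$ clones contributes $k$ to the numerator by
default (`countWeighted = TRUE`); each clone is an independent origination.
The conservation identity $\sum_c \hat r_c \cdot n_c = $ total mutation
count holds exactly and is tested.

Two conventions were genuinely open and are settled as follows. Contexts at
exon junctions use the *spliced* CDS neighbours plus one supplied flank per
terminus, not genomic introns: this keeps the module genome-independent,
and transcripts arrive pre-extracted anyway. Context occurrences are
counted once per selected transcript, not weighted by sequencing coverage.
Positions whose context contains a non-ACGT base are excluded from
numerator and denominator alike.

## The SNV catalogue

`enumerateSnvs()` lists all three single-nucleotide variants of every CDS
position of a region, annotates amino-acid consequence under the standard
codon table, and `buildNull()` attaches each entry's spectrum rate,
restricted to a consequence-class filter (missense by default) and
renormalised so included probabilities sum to one. The null is deliberately
nucleotide-level: two nucleotide changes producing the same amino-acid
substitution stay distinct entries and amino-acid-level scores (∆∆G) are
copied onto each. Stop-loss changes form their own class and are excluded
from missense analyses. Entries outside the filter stay in the catalogue
with probability zero, so observed mutations of excluded classes are
recognised and tallied rather than silently lost.

# Feature scoring

Three families of scores attach to catalogue entries via
`attachFeatures()`:

* **∆∆G** (kcal/mol, positive destabilises), parsed from FoldX
  PositionScan output (`readFoldxPositionScan()`). A mutation is called
  destabilising when ∆∆G strictly exceeds 2 kcal/mol, the conventional
  threshold for highly destabilising changes; the threshold is a plain
  argument and sweeping it is one line.
* **Residue-set membership** — e.g. the ligand-binding interface and
  calcium-binding residues of the NOTCH1/NOTCH2 EGF11–12 repeats, shipped
  verbatim as a YAML fixture and guarded by a checksum test.
* **Distance to a binding partner** — minimum Euclidean distance between
  a residue's heavy atoms and a declared target selection (ligand peptide,
  DNA, substrate) in a PDB structure; hydrogens are ignored because
  crystal structures usually lack them, and the 8 Å functional-site
  cutoff is inclusive ("within 8 Å"). Structure-to-protein residue
  numbering offsets are explicit configuration, never inferred.

Entries whose residue lacks ∆∆G or structure coverage are flagged unscored
and dropped from both the null and the observed side of any test using
that feature, with a tally message.

# Selection tests

## Boolean features: exact binomial test

With null feature mass $p_0$ (the summed probability of feature-positive
entries) and $k$ of $n$ observed mutations on the feature
(recurrence-weighted), the two-tailed p-value is the minimum-likelihood
exact convention: the sum of all Binomial($n, p_0$) outcome probabilities
no greater than that of $k$. The error bar on the expected count is the
equal-tailed 95% interval of Binomial($n, p_0$). p-values are never
reported as zero.

## Continuous scores: Monte Carlo test

`monteCarloTest()` draws `nDraws` null samples of size $n$ with
replacement (probabilities = null probabilities; recurrent mutations are
independent draws), computes a summary statistic per sample, and reports

$$p = \min\!\Big(1,\; 2\min(\hat t_{\text{lo}}, \hat t_{\text{hi}})\Big),
\qquad \hat t = \frac{\#\{\text{tail}\} + 1}{n_{\text{draws}} + 1},$$

so the attainable floor is $2/(n_{\text{draws}}+1)$ — with the default
100,000 draws, $2\times10^{-5}$. The statistic is the median by default
(matching how observed-vs-expected medians are reported); the mean of
mid-CDF values is available for heavy-tailed scores. A seed is mandatory
and recorded in the result.

## The CDF-shift statistic

Raw ∆∆G values have extreme outliers, so per-gene summaries use the
mid-distribution CDF transform under the probability-weighted null,

$$F(x) = P(X < x) + \tfrac12 P(X = x),$$

which satisfies $E_{\text{null}}[F(X)] = \tfrac12$ *exactly* for any
discrete distribution. The CDF shift is the recurrence-weighted mean of
observed entries' $F$ values minus $\tfrac12$. It is bounded in
$[-0.5, 0.5]$: exactly 0 when observed matches the null, approaching
$+0.5$ ($-0.5$) when all observed mutations sit on the maximum (minimum)
possible score as that entry's null mass vanishes — the attained extremes
are $\pm(0.5 - p_{\text{ext}}/2)$, a direct consequence of the mid-CDF
convention. For genes with several solved structures the shift is computed
per structure and averaged unweighted (`aggregateGeneShift()`); shifts can
then be correlated with the logarithm of upstream truncating dN/dS
estimates (`correlateShiftDnds()`) to separate fitness-suppressors
(destabilising mutations enriched, truncating dN/dS > 1) from
fitness-enhancers.

# Exclude-and-retest layering

Strong selection of one mutation category masks weaker selection in the
same region: the strongly selected category inflates $n$ while the weaker
category's share stays near its null mass. `excludeEntries()` removes a
category (a predicate over feature columns, e.g. `"ddg > 2"`) from *both*
the null (renormalising) and the observed data; `layeredAnalysis()` runs
an ordered sequence of test-then-exclude layers and reports per-layer
results plus the residual of unexplained mutations. Entries matching
several layer predicates are excluded at the first matching layer, which
makes the analyst's ordering explicit — the canonical NOTCH1-style
ordering is destabilising first, then interface, then calcium-binding.
Layers whose post-exclusion $n$ falls below 5 are flagged "underpowered";
an exclusion that would empty the null or the observed set halts the
analysis with partial results and an explicit status rather than failing
silently.

# The synthetic-data generator

Every analysis step is testable without downloads. The generator emulates:

* transcripts (`simulateTranscript()`): random CDS, ATG start, no internal
  stops, one flanking base per side, GC bias 0.5 by default;
* mutation sets (`simulateMutations()`): draws from the null with each
  entry's weight multiplied by the enrichment factor of every matching
  scenario layer. Factors compose multiplicatively on overlapping layers —
  the canonical masking scenario uses disjoint partitions, so composition
  is this package's extension. The shipped `fig1Scenario()` plants factors
  3 and 2 on disjoint 20% residue partitions, the configuration under
  which a factor-$f$ feature of null mass $a$ is observed at proportion
  $fa/(1+(f-1)a)$;
* ∆∆G tables (`simulateDdg()`): a two-component Gaussian mixture — a
  near-zero mode (mean 0.3, sd 0.8 kcal/mol) and a destabilising tail
  (mean 4, sd 1.5 kcal/mol, weight 0.25; designated core residues draw
  the tail with weight 0.8) — mimicking the empirical spread of
  position-scan output;
* toy structures (`simulateStructure()`): an idealised α-helical Cα trace
  (2.3 Å radius, 1.5 Å rise, 100°/residue) with a single-atom
  pseudo-ligand at an analytically known distance from residue 1.

What the generator does **not** emulate: real spectra's signature
structure beyond 192 independent channels, indels and MNVs, spatial clone
dynamics, correlated ∆∆G errors, or disorder/coverage gaps in real
structures. Passing tests therefore demonstrate the statistical machinery
is correct under its stated model, not that any particular biological
dataset will show selection.

# Numerical choices

* Two-sided binomial convention: minimum-likelihood, with the customary
  $1+10^{-7}$ relative tolerance when comparing pmf values.
* Monte Carlo: $+1$ pseudo-count in both tail numerator and denominator;
  p capped at 1; constant score columns return p = 1 with a warning.
* Mid-CDF: computed by cumulative summation over the sorted unique score
  values; the null self-shift is zero to ~1e-16 and asserted below 1e-12.
* Ties: the weighted median of the null uses the lower-quantile
  convention; catalogue order is deterministic (position, then alternate
  base A<C<G<T), as is transcript tie-breaking.
* Predicates are parsed R expressions restricted by an AST whitelist to
  comparisons, Boolean operators, arithmetic and `abs`/`is.na`; `NA`
  feature values never match a predicate.
* Seeds: one top-level seed fans out to named streams (`deriveSeed`), so
  subcommands are independently reproducible; all seeds stay below
  $2^{31}$.

# Scale of the shipped checks

The test suite verifies calibration and recovery at the scales the method
is typically used at, chosen once: 10,000 neutral replicates for binomial
type-I error (n = 100, null mass 0.3); 5,000 replicates for Monte Carlo
p-value uniformity; 1,000
replicates of the masking scenario at n = 300; a 10,000-mutation
spectrum round trip over a 5,000-codon transcript; 10,000 random observed
sets for the CDF-shift bounds; exhaustive enumeration oracles for the
binomial (n ≤ 12) and Monte Carlo (≤ 5 entries, n ≤ 3) tests.

# Known limitations

* The headline results of the motivating analyses depend on external
  cohort mutation tables and full FoldX runs over crystal structures;
  this package ships the machinery and verifies it on synthetic data, and
  consumes those external tables when the user supplies them.
* dN/dS estimation, FoldX execution, metal-site database lookups and
  conservation scores are upstream inputs, by design.
* The spectrum assumes SNVs only; the catalogue is blind to splice-site
  consequences and dinucleotide events.
* Monte Carlo p-values inherit discreteness at small n; the +1-corrected
  two-tailed convention is slightly conservative near the floor.

# A minimal worked example

```{r example, eval = FALSE}
tx <- simulateTranscript(120, seed = 1)
cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
cat <- partitionFeatures(cat)                       # strong/weak partitions
cat <- attachFeatures(cat, ddg = simulateDdg(cat, seed = 2))
obs <- simulateMutations(cat, fig1Scenario(300), seed = 3)

binomialFeatureTest(obs, cat, "weak")               # masked
after <- excludeEntries(cat, obs, "strong")
binomialFeatureTest(after$observed, after$catalogue, "weak")  # unmasked

shiftValue(cdfShift(obs, cat))                      # gene-level ddG shift
```
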