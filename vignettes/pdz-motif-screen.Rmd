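---
title: "Screening variants that disrupt or create C-terminal PDZ-binding motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening variants that disrupt or create C-terminal PDZ-binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzsnp)
library(dplyr)
```

## The problem

PDZ domains are peptide-recognition modules that bind primarily the extreme
C-terminus of partner proteins. Because the binding interface is a short
linear motif — at most the last seven residues — a single amino-acid change
can abolish an interaction outright, or conjure a new one out of a previously
inert tail. Missense variants (one residue replaced) and stop-gain variants
(the protein truncated, exposing an entirely different C-terminus) are
therefore disproportionately consequential in this region, yet conventional
variant-effect predictors, which lean on conservation and structure, say
little about short, disordered, weakly conserved tails.

`pdzsnp` implements a specificity-model approach to this problem: build a
position weight matrix (PWM) per PDZ domain from peptides selected against it
(e.g. by phage display), score every protein C-terminus against every domain,
and classify each variant by how it moves those scores across a two-threshold
confidence band. Around that core it provides the enrichment statistics used
to characterise variant density in C-termini, and a synthetic-data generator
so the whole pipeline can be exercised and validated without any external
download.

## The specificity model

Peptides binding a domain are aligned at their C-terminal residue; position
*n* denotes the offset from that residue (offset 0 = last residue, up to
offset 6). The PWM entry $p_i[n, a]$ is the smoothed frequency of residue
$a$ at offset $n$ among the peptides selected for domain $i$. The score of a
C-terminus $j$ under domain $i$ is the summed log-probability

$$S_{ij} = \sum_{n} \log_{10} p_i[n,\, j(n)],$$

where $j(n)$ is the residue of $j$ at offset $n$. Higher scores mean
greater similarity to the domain's preferred ligands; the score of any
sequence under a completely uninformative model is $7\log_{10}(1/20) =
-9.10$, a useful mental baseline for the thresholds below.

Two numerical choices deserve comment.

**Log base.** Scores here are base-10 log probabilities. The working
thresholds ($S_{min} = -8.3$, $S_{max} = -6.4$) bracket the uniform-model
baseline $-9.10$ only on that scale (natural logs would put the baseline
near $-21$), so base 10 is the default and the tested contract;
`score_cterm()` is deliberately simple enough that a different convention
is a one-line wrapper away.

**Pseudocount.** Raw phage-display peptide sets under-sample residues, so a
random count is added before normalising. `build_pwm()` spreads
$\kappa\,w(IC_n)/20$ over the 20 residues at position $n$, where $IC_n$ is
the column's information content in bits and the weight $w$ is configurable:
proportional to $IC_n$ (the default), proportional to $\log_2 20 - IC_n$
(the conventional direction — smooth the degenerate columns hardest), or
flat. The proportional default follows the screen's original protocol of a
random count proportional to the information content; the exact constant is
not recoverable from that description, so $\kappa = 1$ was fixed once as the
default and the mode is exposed as configuration. All validation that
depends on exact score margins uses $\kappa = 0$ (raw frequencies), where
the estimator is exactly maximum likelihood and unobserved residues have
probability zero.

Sequences shorter than seven residues are scored over their available
offsets only, anchored at the C-terminus; PWM positions beyond the longest
training peptide hold the uniform row $1/20$, so scores stay total and
comparable.

## Classifying variants

For each variant the wild-type and mutant C-terminal windows are scored
against every domain. With the confidence band $[S_{min}, S_{max}] =
[-8.3, -6.4]$:

* domain $i$ supports **disrupts** iff $S_{ij} > S_{max}$ and
  $S_{ij'} < S_{min}$ (wild type binds, mutant clearly does not);
* domain $i$ supports **creates** under the mirrored condition;
* scores inside the band never support a call.

Both inequalities are strict, read literally from the rule's definition;
ties are practically impossible with floating-point scores but the contract
is explicit, and the test suite checks that scores exactly equal to a
threshold never support a call. The strictness also yields an exact
antisymmetry — swapping wild type and mutant exchanges the disrupt and
create domain sets — which is enforced property-style in the tests.

A variant observed on several splice isoforms is classified per isoform and
rolled up with an *any-isoform* rule: one supporting (isoform, domain) pair
suffices. A variant may in principle disrupt via one domain and create via
another; the roll-up gives disrupts precedence and retains both domain lists
in the output, a collision the verdict vocabulary otherwise hides.

Stop-gains are handled by truncating the protein at the stop position and
extracting the trailing window of the product; classification then proceeds
exactly as for missense variants. For bookkeeping, a *predicted
PDZ-mediated interaction* is a (domain, protein) pair whose wild-type
C-terminus scores above $S_{max}$, and the screen reports how many distinct
pairs are hit by at least one disrupting stop-gain — one pair can be hit by
several stops, so this count is not the number of stop-gains.

## Statistics

**C-terminal enrichment.** Whether C-termini carry more variants than the
genome-wide density predicts is tested with an exact binomial:
$k \sim \mathrm{Binom}(\text{region aa},\ N/\text{total aa})$, where $N$ is
the genome-wide variant count. A binomial rather than hypergeometric model
is used because several variants can affect the same residue. The expected
count is $\text{region aa} \cdot N/\text{total aa}$ and the default
sidedness is two-sided; this parameterisation reproduces the published
desk-scale inputs to their printed precision (see the acceptance script).
No normal approximation is used anywhere; the test-suite oracle is a
brute-force summation of the probability mass function.

**Threshold sweep.** `sweep_motif_thresholds()` varies the motif-defining
threshold over a grid (default $-12$ to $-4$ by $0.1$): per threshold it
counts the variants inside motif-containing C-termini, their amino-acid
span, the variant density, and a one-sided *less* binomial p-value against
the global C-terminal density — probing whether functional motifs are
depleted of variants.

**Randomization null.** `randomized_disruption_fraction()` compares the
observed fraction of C-terminal missense variants called disrupting (as
$S_{max}$ varies, $S_{min}$ fixed) with a null in which every variant's
alternate residue is redrawn uniformly from the 19 non-identical residues
at the same position — i.e. random non-synonymous changes at the observed
positions; a codon-aware null is out of scope because the inputs are
protein-level. The default is 1000 randomizations; the reported spread is
the population standard deviation over replicates, and the whole
computation is a pure function of its inputs and the seed. Internally the
per-replicate cost is a table lookup: for every (variant-isoform, domain)
the score with the mutated offset excluded is precomputed, so each
substitution is one addition rather than a rescoring pass.

**Gold-standard overlap.** `fisher_overlap()` is the one-sided Fisher exact
test (identical to the hypergeometric upper tail, and cross-checked against
a brute-force tail enumeration in the tests). `fisher_gold_standard()`
builds its 2x2 table from a scored screen: the universe is all (domain,
protein) pairs, hits are pairs scoring above $S_{min}$, and the sample is a
curated interaction list.

## The synthetic-data generator

The generator stands in for three external inputs — per-domain peptide
sets, a reference proteome with splice isoforms and GO compartment
annotations, and a protein-level variant table — while recording the ground
truth needed to validate every stage.

*Specificity models* (`simulate_pwm()`) are sparse: each position allows a
small support (default 3 residues at probabilities 0.75/0.125/0.125), all
other residues exactly zero. Sparsity mirrors selection data, where most
residues are never observed at a constrained position, and it is what makes
single-residue verdicts plantable at all: with dense columns a single
substitution can move a score by at most a couple of log units, which
cannot cross from above $-6.4$ to below $-8.3$; a zero-probability
substitution sends the score to $-\infty$ with certainty.

*Proteomes* (`simulate_proteome()`) draw residues uniformly, which keeps the
uninformative-model baseline exactly $-9.10$; defaults are 100 proteins of
50–200 residues, a 0.2 motif fraction (suffixes rejection-sampled from a
domain's PWM until they clear $S_{max}$ + margin), a 0.1 second-isoform
rate, and compartment annotations on 10% of the non-motif proteins,
rotating through extracellular, mitochondrial and rescued
(extracellular + plasma-membrane-part) cases so every filter branch is
exercised without ever removing planted truth.

*Variants* (`simulate_variants()`; defaults 20 disrupt / 10 create / 50
neutral / 10 stop-gain at margin 1.0) are planted by construction and then
*verified against all ground-truth PWMs* — a disrupt placement that would
accidentally create a motif under another domain is rejected and resampled;
an infeasible request (more disrupt variants than motif proteins, say)
errors naming the shortfall. Create variants are planted by overwriting a
background protein's suffix with a high-scoring draw corrupted at one
position by a zero-probability residue, so the wild type scores $-\infty$
and the variant restores binding. Neutral variants alternate between
positions outside every C-terminal window and in-window substitutions
verified to cross no threshold. Stop-gains are split half/half between
motif-truncating (disrupting) and background (neutral) placements.

What passing on this data does and does not show: recovery is exact because
margins are planted and the background is uniform; real proteomes have
biased composition, correlated positions, motif-like sequences near the
thresholds, and specificity models estimated from far fewer peptides, so
100% synthetic recovery validates the *machinery* (coordinates, window
logic, threshold rule, isoform roll-up), not the biological error rate of
the screen.

## Problem sizes and reproducibility

The validation suite runs the full pipeline at 100 proteins, 5 domains, 90
variants and 2,000 peptides per domain, with 30–200 randomization
replicates in the file-based tests and the script (1000 — the analysis
default — in the statistical calibration checks where the null spread
matters); these sizes were chosen as the smallest at which every code path
(isoforms, every filter branch, all four variant classes) is exercised with
comfortable score margins. Every simulation and randomization is seeded,
outputs are plain TSV/JSON, and a rerun under the same configuration and
seed is byte-identical — this is asserted in the tests. The run manifest
records the configuration, seed, and MD5 checksums of all inputs.

## Known limitations

* Only canonical C-terminal binding is modelled: no internal or non-
  canonical PDZ binding modes, and nothing upstream of the last seven
  residues.
* PWMs assume positional independence; correlated preferences between
  positions are invisible to the model.
* The compartment filter is literal set membership on supplied GO terms —
  no ontology-graph propagation.
* Stop-loss (read-through) variants, indels and multi-nucleotide variants
  are out of scope; inputs arrive protein-mapped.
* The classification thresholds are screen-level operating points, not
  binding-affinity estimates; scores near the band are deliberately left
  uncalled.

## A worked example

```{r example}
pwms <- lapply(1:3, function(i) simulate_pwm(paste0("DOM", i), seed = i))
sim <- simulate_proteome(n_proteins = 60, motif_fraction = 0.2,
                         pwms = pwms, seed = 1)
bundle <- simulate_variants(sim, n_disrupt = 8, n_create = 4,
                            n_neutral = 20, n_stopgain = 6, seed = 2)

scr <- screen_variants(bundle$proteome, bundle$variants, pwms)
scr
glance(scr)

tidy(scr) |>
  filter(verdict == "disrupts") |>
  select(variant_id, protein_id, wt_cterm, mut_cterm, best_domain, s_wt) |>
  head()
```

```{r logo, fig.width = 6, fig.height = 3}
autoplot(pwms[[1]])
```
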