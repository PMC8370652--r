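---
title: "Forecasting wrinkly spreader evolution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting wrinkly spreader evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When a *Pseudomonas* population grows in an unshaken well, oxygen at the
air-liquid interface creates strong selection for mutants that attach to each
other and to the surface. The dominant class of such mutants, wrinkly
spreaders (WS), arises by mutational activation of diguanylate cyclases
(DGCs), raising c-di-GMP and switching on exopolysaccharide production. In
*P. protegens*-like genomes three negatively regulated pathways dominate:

* **Wsp**: a chemosensory-like cluster (WspA receptor, WspB-D scaffold, WspE
  kinase, WspR DGC) held off by the methylesterase **WspF**. Loss of WspF
  function constitutively activates WspR.
* **Aws**: AwsO (outer-membrane sensor), **AwsX** (periplasmic inhibitor) and
  AwsR (inner-membrane DGC). AwsX loss derepresses AwsR — but only lesions
  that preserve the reading frame: *awsX* sits upstream of *awsR* in the
  operon, so frame-breaking lesions are polar and silence the DGC itself.
* **Mws**: MwsR, a fused DGC-phosphodiesterase; lesions disabling the
  phosphodiesterase/regulatory moiety activate the fused DGC, whole-gene
  loss removes it.

`wsforecast` turns this network logic plus per-gene mutational target sizes
into a multinomial forecast of where adaptive mutations will fall, simulates
the static-well experiment that tests the forecast, estimates selection
coefficients from competition platings, and scores the eight hierarchical
predictions against an observed mutant catalogue.

## The null model

For gene $g$ and mutation class $c$ the target size $T_c(g)$ is the number of
distinct events of class $c$ that produce WS in $g$ (stop-gain substitutions,
frame-breaking ±1 bp indel sites, frame-preserving direct-repeat deletions,
region-restricted missense). Class rates $r_c$ convert counts to rates and

$$P(g) = \frac{\sum_c r_c\,T_c(g)\,[g,c\ \text{WS-enabling}]}
             {\sum_{g'}\sum_c r_c\,T_c(g')\,[g',c\ \text{WS-enabling}]}$$

where WS-enabling is decided by the pathway logic (`ws_output()` must return
`"high"` for the corresponding single-component perturbation). Normalization
defaults to the three main pathways, the scale on which the predicted
fractions (54% Wsp / 30% Aws / 16% Mws) are quoted.

Counts are sequence facts; rates are model parameters. Exactly one rate ratio
is calibrated: the ±1 indel : substitution ratio, fitted once by
`uniroot` so the Wsp marginal equals 0.54 on the frozen fixtures
($\rho \approx 1.31$, recorded in
`inst/extdata/null_model_config.json`), everything else forward-predicted.
Per-event weights treat a direct-repeat deletion as one indel-class event;
hot-spot multipliers exist as a configuration hook but default to off,
because repeat-mediated hot spots are demonstrably not conserved between
close relatives and a forecast should not borrow them.

## Mutation classification conventions

* Coordinates are 1-based inclusive; the stored CDS is always the coding
  strand, so codon $k$ occupies bases $3(k-1)+1..3k$ and protein-residue
  numbering matches the field's "V271G" notation (CDS position 812 is codon
  271, offset 2).
* Bacterial code (table 11); GTG/TTG starts are rendered M. Ambiguity codes
  are rejected, never expanded — targets and spectra must be exact counts.
* Substitutions are classified by translating the affected codon before and
  after; indels purely by $|\Delta\ell| \bmod 3$. Initiator-codon
  substitutions: start-to-start changes are synonymous (still Met), anything
  else is recorded as M1x missense; the initiator contributes **no** missense
  target opportunities, since such events act through initiation loss. The
  same reasoning excludes the start and annotated stop from stop-gain
  counting.
* Positions ≤ 0 relative to the first CDS base are upstream; a configurable
  window (default 300 bp) bounds what counts as `promoter_point`, making the
  classification deterministic where the literature says only "upstream of
  the operon". Rearrangements fusing an operon to a foreign promoter carry a
  `promoter_capture` flag and are attributed to the operon's pathway, which
  reproduces the 9 + 3 + 2 = 14 decomposition of the Aws pathway count.
* "Coding disruptions of negative regulation" (the 38/43 headline) are
  missense/nonsense/indel events in *wspF*, *wspE*, *awsX*, *awsR*, *mwsR*,
  excluding promoter events.

## The microcosm simulator

`simulate_well()` uses the standard Luria–Delbrück approximation at these
population sizes: the resident doubles deterministically from $N_0 = 10^3$
to $N_f = 4\times10^8$ ($\log_2$ expansion ≈ 18.6 generations); mutants of
class $k$ arrive as Poisson($\mu_k N_i$) per generation and grow
deterministically at $2e^{s_k}$ per generation. Endpoint class frequencies
feed a colony screen with detection threshold $f_{\text{detect}} = 0.01$ and
one colony sampled per detecting well (60 wells per experiment by default).

Two sampling rules are provided: `"uniform"` over detected classes (the
package default) and `"frequency"`-weighted (closer to picking a random
divergent colony on a plate). A subtlety worth knowing: when most wells
contain several detected classes, co-detected lineages interfere through the
shared frequency denominator and the sampled spectrum acquires a small
(percentage-point scale) bias toward the largest class under either rule. In
the single-lineage regime (detection fraction ≲ 0.2) colony sampling is an
unbiased multinomial thinning and the sampled spectrum converges exactly to
$\mu_k/\sum\mu$; the convergence acceptance test therefore runs there, and
the high-multiplicity regime is checked with an absolute tolerance instead.

The default per-generation Malthusian advantage is $s = 0.5$. During the
modelled growth phase only lineages with a substantial per-generation
advantage can reach 1% from a single founder; the five-day static phase that
further amplifies surface mutants is deliberately not modelled (no
death/turnover, no frequency-dependent mat dynamics — a config hook exists),
so $s$ absorbs that amplification. `estimate_total_rate()` inverts an
analytic Poisson-approximate detection probability by bisection; it is
monotone, and because the final census is only known to order of magnitude,
its output should be read as the reported bracket, not a point.

## Selection-coefficient estimation

$s = \ln(R(t)/R(0))/t$ with $R$ the mutant:reference ratio and $t$
whole-population generations (supplied per assay; the package default derives
it from the population expansion). The estimator is exactly antisymmetric
under swapping the strains and invariant to common plating dilutions. Zeros
are never silently patched: a zero mutant count at $t_0$ is an error, at
$t_1$ a flagged censored estimate; a +0.5 pseudocount exists behind an
explicit flag because silent pseudocounts bias small-$s$ estimates. Pairwise
strain comparisons reproduce the uncorrected two-tailed *t* procedure used in
this literature, with Holm-adjusted values reported alongside.

## What the synthetic data emulate — and what they do not

Everything ships offline. The gene fixtures are **synthetic stand-ins**
(filenames and provenance columns say so): seeded random CDSs of realistic
lengths and GC content with the specific codons planted that the documented
protein changes require (Val-271 in WspF, the tryptophans that can reach
stops, an 8-bp direct repeat in *awsX* whose deletion is frame-preserving).
The 43-record and 7-record mutant tables reproduce the published gene-level
decomposition exactly (WspF 15 with 11 identical V271G, AwsX 9, AwsR 3,
WspE 1, MwsR 10, 2 promoter captures upstream of *aws*, 3 promoter points
upstream of the polysaccharide operon; triple-deletion screen 7 with 6 in
DgcH), but nucleotide-level coordinates not printed in the main text are
reconstructed placeholders, tagged per row. Region boundaries are likewise a
best-effort transcription of figure-drawn ranges. Consequently a green test
establishes that the pipeline reproduces the published *counts, fractions,
hierarchy and estimator behaviour* from inputs with the published structure —
not that the package knows the true Pf-5 sequences or the exact drawn
regions.

The competition-count generator realizes exactly the exponential-ratio model
with binomial plating noise at a chosen depth; real platings add dilution
error and colony-morphology misclassification that it does not emulate.

## Numerical choices and degenerate inputs

* Exact multinomial p-values enumerate all outcomes when
  $\binom{n+k-1}{k-1}$ is below a budget, else seeded Monte Carlo with a
  reported binomial SE; mass comparisons use a $1+10^{-9}$ relative guard
  against ties lost to floating point. G tests give zero observed cells zero
  contribution; a positive count on a zero-probability cell flags infinite G
  rather than raising.
* The repeat scanner reports all maximal exact pairs (no greedy suppression);
  nested and overlapping pairs are all retained, sorted by (left start,
  deletion length).
* Tie-breaks are alphabetical and documented wherever a ranking is produced,
  so outputs are stable across platforms.
* Degenerate spectra (all-zero rate-weighted targets) raise an explicit
  undefined-spectrum error rather than returning NaNs.

## Design choices that were genuinely open

* **Kinetics vs class logic.** The pathway model is implemented at the level
  of WS-enabling (gene, class) pairs plus rate-weighted targets, not as
  differential equations: the quantities being forecast (pathway fractions,
  gene ranking) are class/target-level, and kinetic constants for this
  genome are not available.
* **Locus tags** for the *wsp*/*aws*/*mws* genes are not published for this
  genome; fixtures key on gene names and no tags were invented.
* **Distinct mutated sites** (the 22 denominator of region coverage) are
  defined by collapsing exactly identical changes; different changes in one
  gene count separately. A stricter rule that also collapses different
  changes inside one contiguous predicted region is conceivable; the chosen
  rule is the one consistent with the published 16/22 summary and is
  documented here rather than made configurable silently.
* **Self-consistency of the forecast**: drawing 43-mutant spectra from the
  calibrated 54/30/16 multinomial recovers the full pathway order in ~84% of
  draws — a useful reminder that even a correct forecast fails an exact-order
  check one time in six at this sample size.

## Known limitations

Single-mutation trajectories only; no spatial mat mechanics or oxygen
diffusion; frequency-dependent fitness acknowledged but not modelled;
promoter-capture rates carried as counts with zero default weight (no
mechanistic rearrangement model); absolute mutation rates identifiable only
up to the uncertainty of the final census.
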