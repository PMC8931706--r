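---
title: "Models and methods behind genedecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genedecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

genedecay studies the decay of a protein-coding gene across a phylogeny:
which species carry inactivating lesions, whether selection on the gene has
relaxed on particular lineages, and — for lineages where the gene has become
a pseudogene — when along a branch the inactivation happened. The canonical
use case is a single-gene comparative screen across tens to ~150 mammalian
genomes, of the kind used to connect gene loss (for example of the
keratinocyte channel gene *TRPV3*) to phenotypic change. This vignette is
the package's own account of its models, conventions, numerical choices, and
limits.

## 1. Lesion scanning and the reading-frame convention

A coding sequence is scanned for five lesion classes: start-codon loss
(first codon not ATG), premature stop codons (any in-frame TAA/TAG/TGA
strictly before the final codon), stop-codon loss (a final codon that is not
a stop), frameshift indels (alignment-polarised indels whose length is not a
multiple of 3), and splice-site disruptions (junction dinucleotides other
than the canonical GT donor / AG acceptor, read from a per-junction
annotation table). In-frame (3n-length) indels are recorded but are *not*
inactivating by default — they do not disrupt the reading frame — and a
switch (`inframe_inactivating`) flips that policy. A GC donor can be
whitelisted. Codons or dinucleotides containing ambiguity are never called:
lesions are only reported on observed states.

Indels are polarised against a designated **reference taxon**. The codon
alignment is stored twice: the raw nucleotide matrix keeps every column, and
the model-facing codon matrix is laid out in the reference taxon's reading
frame — columns in which the reference is gapped are insertion columns,
visible to the scanner but excluded from the codon matrix (whose length must
then be divisible by 3). Codons containing gaps, ambiguity codes, or stop
codons are stored as missing for the substitution model; the raw matrix is
never modified.

Two consequences of frameshifts deserve emphasis. First, a frameshift is
annotated with whether the cumulative frame offset returns to zero
downstream (`compensated`), but compensation never rescinds the event — each
frameshift is treated as inactivating on its own. Second, every codon
downstream of an uncompensated frameshift is read out of frame, so apparent
"premature stops" called there are artifacts of the broken frame rather
than independent lesions. The scanner reports them (it reports what the
sequence says), but the simulator's truth contract — and therefore the
precision/recall checks — apply to events up to and including each species'
first uncompensated frameshift. For model fitting, `mask_lesions()` masks
everything from the first uncompensated frameshift onward, and stop codons
are already missing by construction, so pseudogenized sequences remain
analyzable by a model that has no stop states.

Gene status is three-valued: a gene is `INCOMPLETE` when its coverage of the
reference CDS falls below a completeness threshold (default 0.9),
`INACTIVATED` when it is complete enough and carries at least one
inactivating event, and `INTACT` otherwise. Incomplete genes are still
scanned — their lesion calls are reported — but they are not treated as
pseudogenization evidence, matching the mixed annotation quality of real
genome assemblies.

## 2. Ancestral placement of shared lesions

Shared lesions are grouped into signatures — identical type, aligned
position, and observed state — because an identical lesion at an identical
position in related species is most parsimoniously a single ancestral
mutation. Placement uses Dollo parsimony: a lesion arises once and does not
revert. If the carriers of a signature form exactly one clade, the origin is
the branch above their most recent common ancestor (the clade's stem);
otherwise the signature is flagged homoplasic and the minimal set of
independent gains is reported (the smallest set of branches whose subtrees
are all-carrier and jointly cover the carriers). Placement is monotone by
construction: adding a carrier outside the current clade can only move the
origin rootward.

## 3. The codon substitution model

The likelihood engine is a Goldman–Yang (GY94) codon model over the 61 sense
codons of the standard genetic code. The generator has
$q_{ij} = 0$ for multi-position changes and, for single-nucleotide changes,
$q_{ij} \propto \pi_j$, multiplied by $\kappa$ for transitions and by
$\omega$ for nonsynonymous changes. The matrix is rescaled so that branch
lengths are in expected substitutions per codon. Codon frequencies $\pi$
default to F3X4 (position-specific empirical nucleotide frequencies with a
0.5 pseudocount so every frequency is strictly positive); F1X4 and equal
frequencies are available. Frequencies are empirical and not counted as free
parameters.

Likelihoods are computed by Felsenstein pruning over site patterns
(duplicate columns are collapsed with multiplicities) with per-site scaling,
so deep trees cannot underflow and all-missing columns contribute exactly
zero information rather than NaN. Transition probabilities use the symmetric
eigendecomposition available for reversible generators,
$P(t) = \Pi^{-1/2} U e^{\Lambda t} U^{\top} \Pi^{1/2}$, with a
scaling-and-squaring fallback if the decomposition is ever numerically
unusable. The pruning core (C++) also returns analytic first derivatives of
the log-likelihood with respect to every branch length (via outside
partial vectors) and with respect to $\omega$ and $\kappa$ (via the
eigenbasis Fréchet formula $dP = A\,(D \circ V)\,B$), so optimization needs
no finite differences. All derivative code is unit-tested against central
differences, and the pruning likelihood is tested against exhaustive
enumeration over all internal-node state assignments on small trees.

**Branch models and parameter counting.** Branch classes assign one
$\omega$ per class: one-ratio (A), all-neutral $\omega = 1$ (B), two-ratio
foreground/background (C), two-ratio with the foreground fixed at 1 (D),
and free-ratio (E, one $\omega$ per branch). Trees are rooted and
bifurcating with $2n - 2$ branches for $n$ tips; the free-parameter count is
$np = (2n - 2) + 1 + (\text{free } \omega\text{'s})$, a convention chosen
because it reproduces the published parameter counts of the study this
package's worked example draws on (238/237/239/473 at 119 sequences;
226/225/227/449 at 113). Note the likelihood itself is invariant to root
placement; the rooted convention is a bookkeeping choice for np.

**Optimization.** All parameters — $\kappa$, the free $\omega$'s, and every
branch length — are co-estimated by box-bounded L-BFGS-B on log-transformed
parameters (bounds: $\kappa \in [0.05, 50]$, $\omega \in [10^{-4}, 20]$,
branch lengths $\in [10^{-7}, 10]$), with convergence tolerance `factr =
1e7` (about $10^{-9}$ relative on the log-likelihood). The model suite is
fitted along the nesting chain with warm starts (B, C from A; D, E from C),
which both speeds convergence and keeps the nesting inequalities
numerically clean. Non-convergence triggers deterministic jittered restarts;
a fit that still fails is returned flagged, never silently.

## 4. Likelihood-ratio tests and their calibration

Nested models are compared by $2\Delta\ln L$ against a $\chi^2$ with df
equal to the difference in np (1 for B/A, A/C, D/C; $2n - 4$ for C/E — the
df are taken as the np difference throughout, since that is the only
internally consistent reading of the published parameter counts). A raw
statistic that is negative by less than 0.1 is clamped to zero with a
warning (optimizer noise); a larger negative value is an error, because it
means a fit did not converge. P-values are reported at full precision and
formatted to two significant digits in scientific notation.

Calibration was checked by simulation. With a 16-taxon tree, a designated
8-tip foreground clade, and 500-codon alignments generated under a single
$\omega = 0.07$, the A-vs-C test rejects at close to the nominal 5% rate
(0.08 over 50 replicates), while the same check on 300-codon alignments is
noticeably anti-conservative (~0.15) — the usual finite-sample behaviour of
the $\chi^2$ approximation. The calibration suites therefore use 500-codon
alignments, the same size as the power simulations; users testing much
shorter alignments should expect anti-conservative p-values.

## 5. The selection-intensity (K) test

`relaxation_k_test()` is a deliberately reduced selection-intensity test,
sharing the K-exponent idea of the RELAX framework but not its full
random-effects machinery. Sites belong to one of three categories with
proportions $p_k$ (softmax-parameterised) and reference omegas $\omega_k$,
shared across the tree; on the designated *test* branches each category's
omega becomes $\omega_k^K$. $K < 1$ drags every category toward 1 —
relaxation of both purifying and positive selection — and $K > 1$
intensifies selection. The null fixes $K = 1$ (test and reference branches
become indistinguishable); the LRT has one df.

The three-category mixture surface is multimodal, so the two fits are
chained: the alternative warm-starts from the null solution, the null is
then re-polished from the alternative's $K = 1$ projection, and the better
null is kept. Without this a poorly optimized null can masquerade as a
relaxation signal. The test reports the category table (proportions,
reference and test omegas), $K$, and the LRT. It is labelled a surrogate
throughout: it is directionally comparable to full random-effects
selection-intensity tests (relaxed test branches give $K < 1$ with small
p), not numerically interchangeable with them. No multiple-testing
correction is applied; `run_pipeline()` runs at most one test per declared
clade.

## 6. Two-period inactivation dating

A branch on which the gene died is modelled as two periods: functional
(selection at the background $\omega_s$) then neutral ($\omega_n = 1$). The
branch-average omega then satisfies

$$\omega_a = \omega_s \frac{T_s}{T} + \omega_n \frac{T_n}{T}, \qquad
  T_s = T - T_n,$$

so the neutral period is $T_n = T\,(\omega_a - \omega_s)/(1 - \omega_s)$,
linear in $T$, applied to both bounds of the divergence-time interval and
reported as Ma before the recent end of the branch (the present, for
terminal branches; for internal branches the report also echoes the full
branch time window). $\omega_a$ comes from the free-ratio model on the
branch in question; $\omega_s$ defaults to the one-ratio estimate over
intact background species and is overridable. Before solving, $\omega_a$ is
clamped into $[\omega_s, 1]$: estimates below $\omega_s$ (sampling noise)
date to $T_n = 0$, estimates above 1 to $T_n = T$ with a warning.
$\omega_s \ge 1$ is an error — the equation is then undefined. $T_n$ is
strictly increasing in $\omega_a$ and in $T$, and interval order is always
preserved.

A modelling subtlety: the equations assume the synonymous clock ticks
uniformly in time across both periods. The simulator honours this — on a
two-period branch the neutral segment's generator is rescaled so its
synonymous flux matches the functional segment's (total substitution rate
is then *higher* during the neutral period, as it should be). Under that
regime the free-ratio $\hat\omega_a$ converges to the time-weighted mixture
and a simulated switchpoint at $T_n/T = 0.4$ is recovered with median
absolute error well inside 0.15 at 500 codons over 20 replicates.

## 7. The synthetic-data generator

`simulate_alignment()` draws root codons from $\pi$, evolves them along the
tree with per-branch transition matrices (branch-specific omegas, optional
two-period switchpoints), and then injects the configured lesions *post
hoc* into the designated tips — point lesions as codon replacements, indels
as gap/insertion columns, splice lesions as rewritten junction
dinucleotides, with the emitted CDS being ATG + evolved codons + stop. The
exon annotation template distributes the CDS over a configurable number of
exons with canonical GT/AG junctions except where a splice lesion is
injected; per-species exon lengths absorb indel length changes. Injection
rather than mechanistic emergence is a design choice: the analysis consumes
lesions as observed states, and injection yields exact truth labels
(`sim_expected_events()` translates them into precisely the coordinates the
scanner reports). One RNG stream keyed by the mandatory seed drives every
draw in documented order, so outputs are byte-identical across runs.

What the generator emulates: background purifying selection at
$\omega \approx 0.07$ (the magnitude seen for conserved single-copy
mammalian genes), lineages switching to neutrality partway along a branch,
shared and private lesions of every scanned class, and divergence-time
tables (branch length × a configurable Ma-per-unit scale, exact intervals
by default, widened by `time_jitter`). What it deliberately does not
emulate: alignment error, assembly/sequencing artifacts, rate variation
among sites (beyond the relax test's fitted mixture), codon usage bias
beyond $\pi$, GC-biased gene conversion, and selection on synonymous sites.
Passing tests on simulated data therefore validate the machinery, not the
robustness of any biological conclusion to those real-data complications.

`preset_study_miniature()` is the tutorial fixture: 16 taxa × 500 codons,
an eight-tip purifying background, a six-tip "whale-like" clade at
$\omega = 0.5$ whose tips additionally spend half their terminal branches
neutral and which shares a premature stop (mapping, by construction, to the
clade's stem), assorted private lesions covering all scanned classes, and
two intact "manatee/hippo-like" tips at elevated omega with no lesions —
the qualitative design of a land-to-water gene-loss study at desk scale.

## 8. Problem sizes and reproducibility

The shipped test and acceptance suites run at desk scale, chosen as the
smallest sizes at which the statistical behaviour under test is stable:
oracle equivalence on 4 taxa × 10 codons; power, recovery and size
calibration at 16 taxa × 500 codons with 20 power and 50 null replicates;
dating recovery on a 6-taxon tree at 500 codons with 20 replicates; the
miniature at 16 × 300–500. A `--scale`-style stress run (the ~140-taxon
scale of a full mammalian screen) is supported by the same code paths —
the pruning core scales linearly in taxa and patterns — but is not part of
the default suites. All simulations take explicit seeds; every reported
number is recomputed at run time by `scripts/acceptance.R`.

## 9. Known limitations

- The scanner works at CDS level on the coding strand; genomic coordinates,
  reverse strands, and exon re-annotation are out of scope.
- Ancestral placement is parsimony on presence/absence of shared signatures,
  not probabilistic ancestral sequence reconstruction; deep homoplasy will
  be reported as such rather than resolved.
- Only the standard genetic code is supported; a different code table is
  rejected loudly rather than silently mis-translated.
- The K test is a surrogate (see section 5).
- Dating inherits every caveat of $\hat\omega_a$: short branches or heavily
  masked pseudogene sequences give noisy omegas, and the clamping policy
  turns that noise into boundary dates (flagged in the output) rather than
  hiding it.
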