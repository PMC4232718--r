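---
title: "Inferring gene loss and relaxed selection from coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene loss and relaxed selection from coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedecay)
```

# The scientific problem

When a gene stops contributing to fitness — say, a taste-receptor gene in a
lineage that swallows prey whole — two molecular signatures accumulate.
First, open-reading-frame (ORF) disruptions: insertions or deletions whose
length is not a multiple of three shift the downstream reading frame, and
point mutations create premature stop codons (TAA, TAG, TGA) upstream of
the true terminus, truncating the protein. Second, the ratio of
nonsynonymous to synonymous substitution rates, $\omega = d_N/d_S$, drifts
upward from the small values typical of purifying selection toward the
neutral value of 1. `genedecay` implements both lines of evidence as a
single tested pipeline: disruption scanning against a functional reference,
parsimony mapping of shared disruptions onto a species tree, and
maximum-likelihood codon-model tests of relaxed or divergent selection,
together with protein-level conservation and physicochemical analyses and a
simulator that generates data with known truth.

# Disruption scanning and event mapping

`scan_alignment()` walks each aligned query against the in-frame reference,
classifying every gap run as an insertion (gap in the reference) or
deletion (gap in the query), with 1-based coordinates in the reference
frame and a `frameshifting` flag (`length %% 3 != 0`). Premature stops are
read in the query's *local* frame: downstream of a frameshift the query is
translated in its shifted frame, so stops created by the frameshift itself
are found and labelled `post-frameshift`, distinct from `point` stops that
exist in the unshifted frame. Truncation is summarized as
$1 - (\text{first stop codon} - 1)/L$ for a reference protein of $L$
residues.

Two conventions are worth stating because they define coordinate
comparisons everywhere downstream. Indels are reported at their
leftmost-shifted placement (the alignment post-pass moves every gap run as
far left as an equal-scoring placement exists), and shared events are
formed by exact identity of kind, length and coordinates
(`find_shared_events()`, tolerance configurable, default 0). A gap run
covering at least 95% of an annotated exon interval is additionally
summarized as a whole-exon loss.

`map_event()` places each event's origin under strict Dollo parsimony: a
derived loss arises once per origin and never reverts. Carriers forming a
clade map to the stem branch of their most recent common ancestor;
otherwise the origins are the stems of the maximal carrier-only clades.
When exactly one non-carrier tip nests inside the carrier MRCA the
alternative "single origin plus one reversal" is recorded as a note —
point stops can revert by a second substitution, indels essentially never
do, so the no-reversal mapping stays primary. The pipeline maps only
primary mutations (indels and point stops); post-frameshift stops are
consequences of their indel, and counting them as events would manufacture
spurious "shared" mutations between lineages whose independent frameshifts
happen to expose the same downstream stop.

# The codon model

Selection analyses use the Goldman–Yang codon substitution model over the
61 sense codons. For codons $i \ne j$ differing at one nucleotide,

$$q_{ij} \propto \pi_j \cdot \kappa^{\,[\text{transition}]} \cdot
\omega^{\,[\text{nonsynonymous}]},$$

zero for multi-nucleotide changes, with $\pi$ the codon frequencies,
$\kappa$ the transition/transversion rate ratio, and $\omega$ the
nonsynonymous/synonymous rate ratio. $Q$ is scaled so branch lengths are
expected substitutions per codon. Frequencies default to F3x4
(position-specific nucleotide frequencies multiplied, stops removed,
renormalized, floored at $10^{-8}$ so the reversible parameterization is
well defined); they are counted from data and not included in the free
parameter count `np`, which is `#branches + 1 (kappa) + model parameters`
— the accounting used by mainstream codon-model software.

Likelihoods are computed by Felsenstein pruning over site patterns with
per-node rescaling (the 61-state recursion is in C++), transition matrices
by the $\pi$-symmetrized eigendecomposition with negative rounding
clipped at zero. Codons containing gaps, `N`, or recoded stops are missing
states contributing all-ones partials.

Within site mixtures (M1a/M2a, M8/M8a, clade models) all classes share one
rate normalization: class $k$ runs at relative rate $r_k/\rho$ with
$\rho = \sum_k w_k r_k$, computed per branch partition. This is the
convention of the field's standard implementation, and it matters: a class
at $\omega = 3$ is faster, not merely different in kind, and normalizing
each class separately would discard most of the signal that the
positive-class tests rely on.

Pseudogenized sequences enter likelihoods only after `repair_alignment()`:
codon columns containing any alignment gap are removed (this covers all
frameshift columns) and remaining stop codons are recoded as missing. The
recipe applied is recorded on the repaired object. Codon models are defined
over sense codons only; some repair convention is unavoidable, and this one
keeps the maximal in-frame signal while refusing to let stop codons enter a
likelihood silently (`codon_states()` errors on unrepaired input).

# Fitting and the model ladder

`fit_codon_model()` maximizes the likelihood over branch lengths, $\kappa$
and model parameters jointly, on transformed scales (log for rates and
lengths, logit/stick-breaking for proportions) by L-BFGS-B with bounds
$t \in [10^{-6}, 50]$, $\kappa \in [10^{-3}, 100]$,
$\omega \in [10^{-4}, 20]$, beta shapes in $[0.05, 99]$. Starts default to
3 (first from data/defaults or a supplied warm start, the rest jittered
with a seeded RNG; default seed 1234). The M8/M8a beta is discretized into
10 equal-probability categories represented by their conditional means.
Convergence is reported honestly in the `converged` flag; an unconverged
fit is returned, never hidden, and `lrt()` records a warning for it.

`run_ladder()` fits the five branch models — A (one $\omega$), B
($\omega = 1$), C (two-ratio), D (two-ratio, foreground pinned at 1), E
(free ratios) — warm-starting each model from its nested neighbour, and if
an alternative still lands below its null (an optimizer failure mode, not
a property of the models), refits it from the null's solution. The
likelihood ordering $\ell_B \le \ell_A \le \ell_C \le \ell_E$ and
$\ell_D \le \ell_C$ is therefore structural. Verdicts follow a fixed rule:
relaxation requires A-vs-C significant *and*
$\hat\omega_{\text{fg}} > \hat\omega_{\text{bg}}$; D-vs-C significant then
distinguishes `partially_relaxed` (constraint not fully removed) from
`fully_relaxed`; otherwise C-vs-E significance yields `heterogeneous`,
else `purifying`. `run_clade_test()` compares clade model C against
M2a_rel (1 df), and `run_site_tests()` runs M1a-vs-M2a and M8a-vs-M8 with
naive empirical Bayes posteriors for the positive class. The M8a-vs-M8
p-value uses a plain $\chi^2_1$ by default — matching how such tables are
conventionally printed — with the 50:50 boundary mixture available via
`boundary_mixture = TRUE`. Raw p-values are reported throughout; no
multiple-testing correction is applied across genes, and reports say so.

The foreground set for models C and D defaults, in the pipeline, to the
mapped origin branch of the earliest loss event plus all its descendants
(so the branch on which pseudogenization arose is included); explicit tag
sets override this. Whether the transitional branch belongs in the
foreground is genuinely ambiguous — it is partly functional, partly not —
and including it follows the usual practice of tagging the stem of the
affected clade.

# Protein-level analyses

`conservation_profile()` reports per-column consensus and conservation
level over a chosen reference taxon set, in the residue numbering of a
designated reference sequence (its gap columns are skipped), with the two
conventional classes: complete (level 1.0) and partial (level $\ge$ 0.8).
`variant_scan()` then reports target taxa deviating from the consensus in
those columns, rendered as `<gene><consensus><position><observed>` labels.
`motif_check()` scans for functional motifs with `X` wildcards (defaults:
PPPXYXXL, HG, FPXXTXC — the C-terminal proline-rich, N-terminal gating and
post-M1 motifs of epithelial sodium channel subunits).

`property_zscores()` is a TreeSAAP-style analysis: amino-acid replacements
along branches (ancestral states by Fitch parsimony with a deterministic
tie-break — the root takes the alphabetically first member of its state
set, children inherit the parent state when admissible) are binned, per
property scale, into 8 equal-width categories of property-change magnitude
spanning the range attainable by single-nucleotide nonsynonymous codon
exchanges; categories 6–8 are radical. The expected distribution weights
every such exchange by source-codon usage (optionally by $\kappa$), and
each category gets $z = (O - Np)/\sqrt{Np(1-p)}$. Two numerical choices
depart from a literal z-threshold test, both because radical categories
often expect counts near zero where the normal approximation is badly
anticonservative: replacements between amino acids that no single
nucleotide change can connect (multi-hit reconstruction artifacts) are
excluded, and significance is decided by the exact binomial upper tail at
$\alpha/2$ (default $\alpha = 0.001$), with z still reported. Under
neutral simulation this brings the flag rate from ~1.9% to ~0.07%,
close to nominal. The sliding window is 15 codons, step 1; edge windows
shorter than 15 are skipped, not padded. The 31 property scales are
assembled at load time from the AAindex compilation shipped with seqinr,
under a fixed accession mapping kept as provenance on the table
(`attr(aa_property_table(), "accession")`).

# The synthetic-data generator

`simulate_alignment()` draws the root from $\pi$ and evolves each branch
under its own $\omega$ (or per-site $\omega$ vectors for site/clade
scenarios, with the shared-normalization convention above), fully
determined by an integer seed. `inject_pseudogenization()` then edits the
final alignment — deletions become gap runs, insertions add columns (gaps
in non-carriers), stops overwrite a codon — identically in every taxon
descending from the chosen branch, recording branch, kind, coordinates and
carriers in a truth manifest. Injection after simulation is deliberate:
it makes truth recovery exact, at the price of not modelling indel
evolution (a non-goal). Consequently the generator emulates the *shapes*
of real pseudogene data (shared frameshifts of 1/2/4/5/17 nt, premature
TGA/TAA/TAG stops propagated to descendants, relaxed $\omega$ on
foreground branches) but not alignment uncertainty, sequencing error,
rate variation beyond the modelled site classes, or indel placement
ambiguity in repetitive sequence — passing tests on synthetic data show
the inference machinery is correct under the model, not that real
alignments are this clean.

The bundled 13-taxon fixture tree mirrors the breadth of a cetacean
sampling design (three delphinids, a porpoise, a river dolphin, a beaked
whale, two sperm whales, two baleen whales, the hippopotamus as sister
lineage, two terrestrial outgroups) with round, plausible branch lengths.
One deliberate topology choice: the river dolphin is placed as the
earliest-diverging toothed whale, so that carrier sets of the form "all
cetaceans except the river dolphin" decompose into exactly two Dollo
origins with a recorded single-origin-plus-reversal alternative — the
configuration the mapping layer most needs to exercise.

# Problem sizes and numerical checks

The validation suite chooses sizes where each property is decidable
quickly: exhaustive-enumeration likelihood checks on 3–4 taxa and 5–10
codons (tolerance $10^{-8}$); one-ratio recovery at 2,000 codons and 8
taxa ($|\hat\omega - \omega| \le 0.05$); two-ratio ordering over 20
seeded replicates at 500 codons; type-I error of A-vs-C over 200 null
replicates at 250 codons on 6 taxa, compared to $\chi^2_1$ at the 5%
level; disruption/mapping roundtrips over 50 seeded scenarios at 120
codons. The chi-square layer is checked against a series/continued-
fraction evaluation of the regularized incomplete gamma function to
$10^{-10}$ relative accuracy.

# Known limitations

Ancestral amino acids come from Fitch parsimony, not marginal ML
reconstruction; on long branches parsimony undercounts changes.
Alignment of pseudogene sequences is global affine with leftmost gap
canonicalization; placement of indels in repetitive regions remains
convention, not truth, and shared-event identity is exact by default. The
repair recipe discards all gap-containing codon columns, which is
conservative for heavily indel-ridden sequences. Branch lengths at the
root pair of a rooted tree are only jointly identifiable under a
reversible model (their sum is); fitted trees should be read accordingly.
The free-ratio model on large trees is expensive and its per-branch
$\omega$ estimates are noisy — it is fitted for the C-vs-E heterogeneity
test, not for interpreting individual branches.

# A worked example

```{r example, eval = FALSE}
fx <- fixture_suite(seed = 1)
tg <- fx$taste_gene

## 1. scan and map
reports <- scan_alignment(tg$alignment, gene = "tasteGene")
events <- find_shared_events(reports, include_post_frameshift = FALSE)
mapped <- map_events(fixture_tree(), events)
mapped[, c("kind", "ref_nt_start", "length_nt", "origin_branch")]

## 2. repair and test for relaxation on the cetacean foreground
rep_aln <- repair_alignment(tg$alignment)
tr <- tag_branches(fixture_tree(), cetacean_taxa(), 1L)
lad <- run_ladder(rep_aln, tr, n_starts = 1)
ladder_table(lad)
```
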