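---
title: "Methods: pan-genome metabolic models, trait evolution and evolution-informed essential-gene analysis"
author: "gemevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome metabolic models and trait evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemevo)
```

# The problem

Budding yeasts span hundreds of species whose metabolic repertoires —
which sugars and nitrogen sources they can grow on, whether they ferment
in the presence of oxygen, which genes they cannot live without — have
diverged through gene loss, duplication, and occasional horizontal
acquisition. `gemevo` implements the computational chain that connects a
pan-genome to those phenotypes: a union ("pan") metabolic network is
specialised into species-specific genome-scale models (ssGEMs) through
boolean gene–protein–reaction (GPR) logic; flux balance analysis (FBA)
turns each model into predictions of substrate utilization and gene
essentiality; enzyme-constrained extensions quantify which enzymes limit
growth; and complementary sequence-level modules screen for horizontal
gene transfer, score residue conservation and spatial clustering of
selected sites on structures, and feed evolution-derived features into
essential-gene classifiers.

Every module is exercised end-to-end on synthetic data with *planted
ground truth*: the package ships a generator that fabricates all of its
own inputs — pan-network, species tree, existence matrix, trait tables,
BLAST hit tables, nucleotide sequences, alignments and Cα structures —
so that each downstream analysis has a known answer key. The tests (and
`scripts/acceptance.R`) assert that the pipeline recovers those keys at
the same thresholds it would use on real data.

# Species model derivation

## GPR semantics

A GPR rule is a boolean tree over ortholog-group identifiers: `and`
joins subunits of an enzyme complex, `or` joins isozymes. Parsing gives
`and` precedence over `or`, and trees are normalised (same-kind nodes
flattened, duplicates merged). Evaluation against a species' gene set
follows the majority-subunit convention: an `and` node is active iff
*strictly more than half* of its child subunits are satisfied — two of
three subunits keep a complex active (and the missing subunit is pruned
from the rule), two of four do not. An `or` node is active when any
child is; missing isozymes are dropped from the pruned rule. Reactions
without a GPR (exchanges, spontaneous reactions) are always retained,
and the biomass pseudo-reaction is never removed. We count subunit
*slots* (children of the `and` node after flattening) rather than
weighting by stoichiometry, since subunit stoichiometries are not part
of the rule language; rules nested deeper than complex-of-isozymes
levels are handled by the same recursive convention.

Homolog integration follows two rewrite rules: a bare reference leaf
gains the homolog as an `or`-sibling (`A or B` becomes `A or B or C`),
and each maximal `and` term containing the reference is duplicated with
the reference substituted (`A and B` becomes `(A and B) or (C and B)`).
A useful consequence, asserted as a property test, is that integration
can never deactivate a rule that was active.

## Gap-filling

A derived model that cannot reach the growth threshold (1e-6 h⁻¹) on
minimal media is repaired by adding a minimum-cardinality set of
pan-model reactions. The search is formulated with one binary indicator
per candidate reaction whose flux bounds are coupled to the indicator
(`lb·y ≤ v ≤ ub·y`), a growth constraint, and the indicator sum as the
objective. No mixed-integer solver is assumed: the package solves the
program exactly with branch-and-bound over its own LP relaxations,
branching on the most-used fractional indicator. Because the growth
threshold is small relative to the coupling bounds, relaxed indicators
rest near `v/ub`; any indicator supported above solver noise (1e-10) is
treated as fractional, which keeps the relaxation honest. Among
equal-cardinality optima the lexicographically smallest reaction-id set
is returned, obtained by greedily fixing candidates in id order — a
deterministic tie-break we chose since cardinality alone does not pin
down a unique optimum. An optional "preferred candidates" list is tried
on its own first, standing in for literature-guided filling; auxotrophs
are expected to be handled by media augmentation, not by filling.

# Flux analysis

FBA maximises an objective flux subject to steady state (`S v = 0`) and
bounds; parsimonious FBA then fixes the objective at its optimum (1e-9
relative) and minimises total absolute flux via forward/reverse
splitting. Only the objective value is contract-bound — flux vectors may
be degenerate. Substrate-utilization tests *replace* the default carbon
(or ammonia) source with the test substrate at an uptake of 10
mmol·gDW⁻¹·h⁻¹; growth at or above 1e-6 h⁻¹ counts as utilization (the
boundary goes to growth, since only rates *below* the threshold are
classified as no growth). Oxygen uptake is left free in minimal media.
Single-gene deletions re-evaluate every GPR without the gene, close
reactions whose rules become inactive, and re-solve.

The linear programs run on the package's own bounded-variable two-phase
simplex (`lp_solve()`): nonbasic variables rest at either bound,
pivoting uses a lowest-index rule with periodic refactorisation of the
basis inverse, and tolerances are 1e-9 (pivot/feasibility) with reported
fluxes rounded at 1e-10 to suppress solver noise. The suite checks it
against hand-solved programs, vertex enumeration on a tiny chain, and
feasibility/optimality certificates on random programs. The networks
this package targets stay below a few hundred reactions, well inside
the solver's comfortable range.

# Enzyme constraints and flux control

An enzyme-constrained model adds usage variables `e_i ≥ 0` with
capacity couplings `v_j ≤ Σ_i kcat_ij e_i` (isozymes additive;
reversible reactions are split before coupling, both directions sharing
the kcat) and a shared protein pool `Σ_i MW_i e_i ≤ P`. Complexes
consume pool through the sum of subunit masses at equal stoichiometry.
With no kcat entries, or infinite pool, the model reduces exactly to
its base.

The flux control coefficient of enzyme *i* over flux *j* is the scaled
finite difference obtained by multiplying all of the enzyme's kcats by
1.001: `FCC = ((v* − v)/v) / 0.001`. We normalise by the *unperturbed*
flux; the alternative perturbed-flux reading differs by O(0.1%) and is
available behind the `denominator` argument. Two classical properties
anchor the tests: a sole saturated enzyme on a linear pathway carries a
control coefficient of exactly 1, and over a fully pooled linear
pathway the coefficients sum to 1 (analytically `m_i/k_i / Σ m_j/k_j`).

kcat fold-scans multiply selected enzymes' kcats along a grid from 1 to
10, solve ec-pFBA (growth maximisation, then pool-usage minimisation at
the fixed optimum), and report fluxes also normalised per gram of
consumed carbon substrate (0.18 g/mmol for the glucose-like substrate).
In the synthetic world the kinetic parameters are set so that carbon
throughput, not uptake, limits growth at the base glycolytic kcat:
respiration (3 ATP per carbon, protein-costly) wins while carbon is
scarce, and fermentation (1 ATP per carbon, protein-cheap) takes over
once glycolytic capacity rises — the scan reproduces the overflow
(Crabtree-style) switch around threefold, with the fermentation-product
flux weakly increasing across the grid.

# Trait evolution

Reaction–trait correlation treats reaction presence as a predictor of
the trait across species (NA trait cells excluded per reaction):
high-correlated reactions must exceed accuracy 0.83 *and* sensitivity
0.92, both strict — the calibration carried over from the
galactose-pathway benchmark. Gain/loss classification compares each
species against the ancestral posterior per trait: probability ≥ 0.85
means the ancestor had the trait (a species 0 is a loss), probability
below 0.15 means it did not (a species 1 is a gain), anything between —
or an NA observation — is undetermined. The boundary convention
(`≥ 0.85`, `< 0.15`) follows the one-sided phrasing of the cutoffs.

Losses are attributed mechanistically in a fixed cascade: a missing
trait-correlated reaction; else a missing direct-pathway reaction; else,
if the whole direct pathway is present but gap-filling (under media with
the substrate as sole carbon source) restores utilization using only
reactions *outside* the direct pathway, a downstream-pathway gap — the
situation where a distantly related pathway, not the catabolic branch
itself, was lost. Anything else is unexplained; on noiseless synthetic
worlds the tests require zero unexplained losses.

# Horizontal gene transfer

The Alien Index is `AI = ln(bbhG + 1e-200) − ln(bbhO + 1e-200)` over
best (smallest) E-values in the group lineage and outside it. A lineage
with no hit enters as E-value 1.0 — BLAST's conventional "no
significant hit" ceiling; "no hit" is an absent table row, never a
sentinel value. Distant candidates require AI ≥ 45 and an out-group hit
percentage ≥ 90%, both inclusive; hit species are deduplicated when a
species column is present. Close (within-group) candidates pass three
sequential filters: best non-recipient hit in the group lineage with
bitscore ≥ 100; group-lineage share of non-recipient hits ≥ 90%; and an
HGT index (best group bitscore over best recipient bitscore) ≥ 0.5,
read as a ratio. The out-group percentage denominator counts
non-recipient hits in both screens; it is configurable, since only the
numerators are fixed by the definitions. The screens report candidates
only — phylogenetic confirmation is outside this package's scope.

# Residue-level analysis

Conservation per alignment column is the base-2 Jensen–Shannon
divergence (equal weights) between the gap-excluded residue
distribution and a background (uniform by default), linearly penalised
by the gap fraction; columns above the 0.3 gap cut-off are flagged
low-confidence but still scored rather than dropped, so downstream
consumers decide. Unique-mutation detection compares residue
frequencies between trait groups: a residue above 80% among tolerant
species that is absent from the reference set (residues above 20% among
non-tolerant species) is reported, at reference-mappable positions
only. Frequencies are computed over species with a residue at the
column; counting gaps in the denominator is available behind a flag.

The CLUMPS-style test scores a site set by the Gaussian pair potential
`Σ exp(−d²/(2t²))` with bandwidth t = 6 Å on Cα distances, against a
null built by redrawing the same number of residues uniformly without
replacement; p-values use add-one smoothing, so they lie in (0, 1] and
a planted cluster is called at p < 0.05. The synthetic structure is a
hairpin of two ideal helical segments (1.5 Å rise, 100° turn, 2.3 Å
radius) packed antiparallel about 5 Å apart: a single straight helix
cannot contain residues that are simultaneously sequence-distant and
within 6 Å, so the hairpin is the minimal geometry in which the planted
cluster can span sequence-remote positions while every member stays
within 6 Å of a neighbour (consecutive Cα steps are 3.8 Å). Annotated
"functional" columns are invariant in the alignment and placed at least
10 Å from every cluster site.

# Essential-gene features and evaluation

Dinucleotide composition divides overlapping pair counts by N−1.
Trinucleotide Kmer frequencies divide overlapping triplet counts by the
sequence length N, following the printed definition literally even
though overlapping counts total N−2 — the vector therefore sums to
(N−2)/N, an identity the tests assert; the per-window normalisation and
an in-frame (codon) counting mode are available behind flags. Ambiguous
bases are rejected with positions listed, not silently skipped.
Evolution features per ortholog group are the mean residue
conservation, dN/dS (consumed as input — site-model inference is out of
scope), occurrence across species, and the average paralog number
(sequences over unique species).

Class imbalance is handled by oversampling the minority class with
replacement, keeping all original observations; ROC/AUC uses the rank
(Mann–Whitney) formulation with half-credit for ties, cross-checked in
the tests against trapezoidal integration and an independent ROC
implementation. Chi-square feature ranking compares class-aggregated
feature mass to class priors. The classifiers themselves are consumed
through a two-method fit/score interface over standard random-forest
and SVM backends — the package's contribution is the features and
evaluation, not the learners.

# The synthetic world

`generate_pan_network()` builds a toy pan-network (24 reactions at the
default three substrates): per substrate a transporter gated by a
trait-causal ortholog and a catabolic step; a central chain with an
isozyme-pair glycolysis analogue, a three-subunit complex on a
precursor synthesis, respiration and fermentation ATP branches; and a
gluconeogenesis analogue (`GNG`) that is required for every substrate
entering below the central node but sits on no catabolic branch — the
planted "downstream pathway". A promiscuous ortholog catalyses two
catabolic steps. Species histories come from a random coalescent tree:
each trait's causal ortholog is gained on one clade and lost again on a
nested clade (so every trait has at least one gain and one loss event;
traits alternate root-present and root-absent so that both classifiable
gains and classifiable losses exist against the ancestral posteriors,
which a single posterior per trait could not otherwise provide). One
species loses only `GNG` (the pure downstream-gap case) and one species
is complete. Clade pairs are chosen, deterministically under the seed,
subject to separation constraints (trait prevalence bounded away from
the 0.83 accuracy threshold, pairwise differences of at least two
species between traits) that make the planted causal reaction the
*unique* high-correlated reaction of its trait in a noiseless table —
this is what makes exact answer-key recovery a fair test rather than an
accident of one draw.

Defaults are the study conditions throughout: 16 species, 3 substrates,
uptake 10 mmol·gDW⁻¹·h⁻¹, growth threshold 1e-6 h⁻¹, trait noise 0–10%
where exercised, 10,000 permutations for cluster calls, 500 sequences
per class at length 300 with profile shift 0.2. Tests run scaled-down
instances of the same conditions (12–16 species, 60–80 residue
structures, 100–2,000 permutations) chosen so the whole suite completes
in a few minutes.

What the generator does *not* emulate, and hence what green tests do
not show about real data: sequences do not evolve along the tree
(existence patterns do, but alignments are i.i.d. mutation sprays around
a reference); networks are two orders of magnitude smaller than genome
scale and have a single biomass route topology; BLAST statistics are
drawn from idealised log-uniform ranges with planted separations rather
than from homology search; and trait noise is independent per cell,
unlike phylogenetically correlated measurement error. Recovery of
planted signal at the published thresholds demonstrates that the
implementations apply those thresholds correctly — not that the
thresholds themselves are well calibrated for real yeast data.

# Numerical choices and limitations

* LP: pivot/feasibility tolerance 1e-9, flux rounding 1e-10, basis
  refactorisation every 64 pivots, lowest-index pivoting for
  determinism.
* Gap-fill: indicator support tolerance 1e-10, bound coupling uses the
  reactions' own (finite, ≤ 1000) bounds as big-M, lexicographic
  tie-break.
* FCC: perturbation 0.1%; halving it changes smooth-fixture
  coefficients by < 1e-3 (asserted); degenerate vertex switches can
  make the finite difference non-smooth, which is inherent to LP-based
  control analysis.
* CLUMPS: bandwidth 6 Å is configurable; add-one smoothing bounds
  p > 0.
* All seeded randomness flows through one helper that saves and
  restores the RNG state, so generators are byte-reproducible and do
  not perturb the caller's RNG.
* The derivation keeps a reaction whenever its GPR is active and never
  re-balances biomass composition per phenotype group; SBML import and
  genome annotation live outside the package.
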