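---
title: "Methods: detecting the pi-turn signature and tracing its evolutionary history"
author: "nrpiturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting the pi-turn signature and tracing its evolutionary history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpiturn)
```

## The scientific question

Most nuclear receptors (NRs) act as dimers through a conserved interface on
the ligand-binding domain (LBD). RXR/USP and HNF4 — the receptors at the base
of the NR tree — carry an unusual deformation in helix H7 of the LBD: a
**pi-turn** (also called an alpha/pi-bulge), in which the i to i+4 backbone
hydrogen bonds of a regular alpha helix are locally replaced by i to i+5
bonds, pushing one residue out of the helix axis. In sequence space the
pi-turn is flagged by an **RxxxE motif**: an arginine and a glutamate four
residues apart whose side chains form an intra-helical salt bridge. The motif
can, however, persist in sequences whose structures show a plain alpha helix
(the COUP-TFII / PNR situation), so sequence and structure evidence must be
reconciled explicitly. This package implements the full chain of analyses:
geometry-based helix classification, motif and marker scanning, interface
contact analysis, and a discrete-character evolution engine that
reconstructs where on the NR phylogeny the pi-turn was lost.

## Helix classification from hydrogen-bond patterns

Backbone amide hydrogens (absent from crystal structures) are placed at
N + 1.0 Å along the unit vector from the preceding carbonyl oxygen to its
carbon; prolines and chain-start residues get none. Hydrogen bonds are then
scored with the Kabsch–Sander electrostatic model,

$$E = 0.084 \cdot 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
      - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right)\ \mathrm{kcal/mol},$$

with a bond recorded when $E < -0.5$ kcal/mol (the community-standard
cutoff, configurable), donors and acceptors at least two residues apart, and
at most the two best acceptors kept per donor. A *k*-turn starts at residue
*i* when the donor at *i + k* bonds back to the C=O of *i* (k = 3, 4, 5 for
3₁₀, alpha and pi). Two consecutive k-turns at (i−1, i) assign residues
*i .. i+k−2*. Two conventions deserve a note:

* **Painting width.** Classic DSSP paints *i .. i+k−1*; we stop one residue
  earlier. On ideal helices built by the package's own generator this keeps
  the assignment centred on the residues whose dihedrals are actually
  helical — planted segments are recovered within one residue per junction,
  and the spans still agree with an independent DSSP implementation within
  one residue at each boundary.
* **Priority.** On overlapping patterns the precedence is
  pi > alpha > 3₁₀. Classic DSSP's alpha-first priority systematically
  absorbs short pi-bulges into the flanking alpha helix — the very object
  of interest here. The order is a function argument for users who want the
  classic behaviour.

A maximal pi-classified stretch flanked by alpha helix is reported as a
pi-turn; the bulge residue is the one whose CA lies farthest from the local
helix axis (a least-squares line through up to four flanking alpha CA atoms
per side). An isolated single i to i+5 bond inside alpha context is reported
as a *weak* candidate rather than dropped, because the biological pi-turn is
a short local bulge, not a long pi-helix. `verify_motif_conformation()`
combines motif spacing, the intra-helical salt bridge (basic N to acidic O
atoms within 4.0 Å), pi-turn overlap, and an optional 3₁₀ check in a
caller-supplied helix H10–H11 junction window into a single verdict with the
labels `pi-turn-motif`, `motif-without-pi-turn` and `no-motif`.

## Sequence side: motifs, markers, numbering

`scan_motif()` searches alignment rows for RxxxE and its degraded variants
(KxxxE, QxxxE, RxxxxxxE) with spacing counted over non-gap residues, so a
motif interrupted by gap columns is still found; at a shared anchor the
canonical motif wins. `audit_class_markers()` checks the class I /
class II dimerization markers in the Brelivet generic numbering
(class I: E5, W40, K/R55, R/K93, R105; class II: E/D42, R62, H/R/K90;
E50 and R105 universal). Two decisions were genuinely open:

* R105 is listed both as a class I marker and as universally conserved. We
  treat it as universal *and* count it toward class I audits, because the
  published SpNR2 audit counts its absence against class I.
* Positions 5, 55 and 90 have no anchored alignment column in the packaged
  residue table; they are skipped with a warning unless the user supplies a
  mapping.

The packaged anchor table ties generic alignment positions to native
(author) residue numbers per receptor in per-helix contiguity blocks, so a
single anchored cell determines a whole block:
`native = anchor_native + (position − anchor_position)`. Block ranges are
package choices wide enough to cover each helix; all mapping is exact
arithmetic and round-trips by construction.

## Interface contacts and buried surface

Interface contacts are typed by distance alone (crystal structures lack
hydrogens, and published bond schematics are reported at residue level):
salt bridges at ≤ 4.0 Å between basic side-chain nitrogens and acidic
oxygens, hydrogen bonds at ≤ 3.5 Å between N/O heavy atoms, van der Waals
contacts at ≤ 4.5 Å, with salt_bridge > hbond > vdw precedence per atom
pair and one record per residue pair. A water-mediated contact needs exactly
one bridging water oxygen within 3.5 Å of a polar atom of each chain; water
chains are out of scope. The cutoffs are config defaults, not published
values. Contacts are binned by named secondary-structure elements (H7, H8,
loop H8-H9, H9, H10, H11) supplied per structure; the signed asymmetry
score, count(H7_A, loop H8-H9_B) − count(H7_B, loop H8-H9_A), is positive
when chain A plays the RXR role in a heterodimer.

Solvent-accessible surface area uses Shrake–Rupley sampling with a
deterministic golden-spiral point set (960 points per atom, probe 1.4 Å),
so areas are exactly reproducible; buried surface area is
SASA(A) + SASA(B) − SASA(AB), symmetric in chain order by definition.

## The character-evolution engine

The pi-turn character is analysed under a continuous-time Markov model with
symmetric rates (SYM; a single rate gives ER). Transition probabilities are
$P(t) = e^{Qt}$ via the eigendecomposition of the symmetric rate matrix.
Likelihoods use Felsenstein pruning with per-node rescaling; tips coded
unknown contribute all-ones partials rather than being dropped — the
conservative treatment of missing oligomerization data. Multifurcations are
handled natively as products over children. The root prior defaults to
equal frequencies (which is also the stationary distribution of any
symmetric Q), matching the common default of the reference
stochastic-mapping implementation; a stationary-prior option exists for
future asymmetric extensions.

Rates are fitted by bounded maximisation of the pruning log-likelihood
(one-dimensional golden-section search on a log scale for ER, L-BFGS-B for
SYM; tolerance 1e-8). Invariant characters return the q = 0 boundary with a
warning instead of crashing. Marginal ancestral states come from the
standard up/down message-passing scheme and were validated against
exhaustive enumeration over all internal state assignments on trees of up
to 5 tips and 4 states (agreement to 1e-9).

Stochastic character maps are drawn in two stages: joint node states by
root-to-tip sampling over the pruning partials, then each branch path
conditional on its endpoints. Path sampling uses endpoint-conditioned
rejection first (with the first jump forced when the endpoints differ) —
exact and fast in this paper's regime of rare losses — and falls back to an
exact uniformization sampler after 1,000 rejected attempts, which
guarantees termination at high rates. Zero-length branches with differing
endpoints raise an internal assertion. Summaries report per-node state
frequencies and the distribution of transition counts, the same quantities
the usual `describe.simmap`-style summary prints.

Loss counting uses two independent parsimony views: Dollo (single origin,
irreversible losses; the count is the number of maximal all-absent clades
under a present root) and Fitch/Hartigan minimum changes as a lower bound.

## The synthetic generators and what they do not emulate

The generators exist so that every stage is testable at desk scale with
known ground truth:

* `make_ideal_helix()` builds backbones by internal-coordinate chain
  extension (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, omega 180°) with
  per-segment dihedrals: alpha (−57°, −47°), 3₁₀ (−49°, −26°), pi
  (−57°, −70°) — standard tabulated values; the pi dihedrals are a choice
  from standard tabulations and the tests assert the hydrogen-bond pattern,
  never the dihedral values themselves. No side chains are built: the
  classifier consumes only backbone geometry.
* `make_toy_dimer()` places two ideal helices at a chosen separation with
  one pseudo side-chain atom per designed bridge residue, positioned so the
  designed pair sits at exactly the target distance; construction verifies
  that every non-designed inter-chain pair clears the van der Waals cutoff
  by 1 Å, so downstream contact counts equal the design. Bridge designs
  whose pseudo-atoms would violate that margin (crossing or tightly spaced
  bridges) are rejected as contradictory rather than silently built.
* `make_planted_alignment()` draws background columns uniformly from amino
  acids outside {R, K, Q, E}, so no spurious motif can arise and planted
  hits are exactly the expected hits.
* `make_random_tree()` produces pure-birth trees rescaled to unit depth;
  `simulate_character_evolution()` runs Gillespie simulation under the same
  model family the inference assumes, making simulate-under/fit-under
  experiments exact.

Real data differ in ways these generators deliberately ignore: crystal
structures have side chains, alternate conformations, missing atoms and
non-ideal geometry; real alignments have composition bias and correlated
columns; real trees are non-ultrametric with estimated (noisy) branch
lengths. Passing tests therefore demonstrate correctness of the algorithms
under their stated models, not robustness to crystallographic pathology.

## The packaged nuclear-receptor fixture

The character fixture (`nr_fixture()`) is a 24-taxon consensus topology of
early NRs with per-taxon motif and pi-turn states transcribed from textual
statements about the family: structures fix the state where they exist
(RXR, USP, HNF4, COUP-TFII, PNR, and the derived receptors), published
homology inference covers SpNR1 and basal HNF4s, sequence evidence covers
motif presence/absence, and taxa without a quotable statement (EAR-2
structure, the divergent Trichoplax sequences) are coded unknown. Degraded
variants count as canonical-motif absent. On this fixture the equal-rates
fit gives a root posterior of 0.58 for "present" and Dollo parsimony
requires 7 independent losses (at least five, consistent with the
"pi-turn early" scenario); both numbers are recomputed by the tests and by
`analysis/04_ancestral_history.R`, never stored.

## Problem sizes and numerical choices

The test suite runs the classifier against an independent geometric
DSSP-style oracle on 100 random composite helices; the likelihood engine
against exhaustive enumeration on all tree/state combinations up to 5 tips
and 4 states; stochastic mapping at the published sample size of 10,000
histories on a 5-tip tree (node frequencies within 0.02 of the marginal
posteriors; conditioned-branch transition counts within 3 Monte-Carlo
standard errors of a numerical-integration oracle); and parameter recovery
over 20 seeded replicates of 128-tip trees. Recovery fits the ER rate
jointly from 4 independently simulated binary characters per replicate —
the standard multi-site recovery design, giving the estimator enough events
to be meaningfully compared with the truth at ±30%. All randomness is
seeded; all generators are bit-reproducible given the seed.

## Known limitations

* The classifier is helix-only: no beta-sheet or bridge assignment beyond
  what turn/coil covers.
* Side-chain hydrogen bonds at interfaces are distance-only by default; the
  optional angle filter needs placed hydrogens the typical input lacks.
* The exact residue windows delimiting helix H7 per receptor are
  configuration, not constants: the reference alignment is published only
  as an image, so the anchor table encodes the published table cells and
  nothing more.
* The four dimerization states used for the oligomerization character are
  labels with a config override; the engine itself is k-state generic.
* Dollo counting assumes the root state is "present"; it refuses data that
  violate the single-origin premise instead of guessing.
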