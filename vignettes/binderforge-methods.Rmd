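---
title: "Methods: desk-scale binder design and screening analytics"
author: "binderforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale binder design and screening analytics}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

binderforge re-creates, at desk scale, the computational skeleton of a
de novo miniprotein binder campaign against integrin α5β1: ferredoxin
(βαββαβ) scaffolds are enumerated from topology occurrence statistics,
assembled in torsion space around an RGD hotspot loop, grafted and scored
geometrically, and the downstream screening analytics (sort-seq K~D~
estimation, SSM entropy, specificity calls, combination libraries) and
binding-model fits are implemented in full. This vignette records the
models, the tunable parameters, and the design decisions that were
genuinely open, in the package's own terms.

## Blueprints from topology statistics

A blueprint fixes, per segment, the secondary structure of the fold:
strands E1–E4, helices H1–H2 and loops L1–L5 in the order
E1‑L1‑H1‑L2‑E2‑L3‑E3‑L4‑H2‑L5‑E4 (secondary-structure string "EHEEHE").
Loops carry an ABEGO string — the five-letter classification of backbone
torsion space (A helical, B extended, G and E their positive-φ mirrors, O
cis-ω). The bins are the community convention: O when |ω| < 90°; A when
φ < 0 and −75 ≤ ψ < 50; B for the remaining φ < 0; G when φ ≥ 0 and
−100 < ψ ≤ 100; E otherwise. The source material names the classification
but not the bin edges, so the standard binning was adopted as a design
decision.

`enumerate_blueprints()` forms the full Cartesian product of the most
frequent options per degree of freedom (default 5 ABEGO strings per loop,
4 lengths per helix, 5 strand-pairing combinations → 5^5 · 4² · 5 =
250,000 candidates) and scores each blueprint by

  score = Σ log(count(option) / total)

over its chosen options, treating the factors as independent. "Most
occurring" implies frequency ranking; the independent joint score is the
simplest consistent choice. Ties are broken lexicographically on the
serialized segment string, so enumeration and selection are fully
deterministic and never consume random numbers. Strand lengths are fixed
per strand (5 residues in the shipped statistics) because the surveyed
length statistics cover only the helices; strand-pairing combinations are
opaque identifiers, as their identities are not published anywhere we can
draw from.

## Backbone construction

Chains grow in internal coordinates (NeRF-style sequential placement)
under ideal covalent geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å;
N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°); the carbonyl oxygen is
placed trans to the next amide nitrogen. `measure_torsions()` inverts the
construction; the build/measure round trip reproduces interior torsions to
below 1e−6 degrees, which the test suite enforces at 1e−5 over random
chains.

Torsion sampling is per-class Gaussian with rejection back into the
requested ABEGO bin (A: μ = (−63, −42), σ = 8°; B: (−120, 130), σ = 15°;
G: (60, 35), σ = 10°; E: (120, −130), σ = 15°; helices draw at (−57, −47),
σ = 8°). Cis-ω (letter O) draws are off unless explicitly enabled. All
sampling is seeded and restores the caller's RNG state.

Assembly runs in three stages — E1+L1+H1 around the motif, then the
hairpin arm L2+E2+L3+E3 with an E1/E2 pairing check, then L4+H2+L5+E4 with
the global compactness/cavity filter — because nucleating the fold around
the binding loop and filtering early wastes far fewer draws than
constructing whole chains blind. Lineages are capped (8 out of stage 1)
and each lineage gets a bounded number of extension attempts, so surviving
counts can only shrink stage over stage.

### Filters and their defaults

* **Clash**: non-bonded backbone atom pairs (sequence separation ≥ 2
  residues) closer than 2.8 Å.
* **Strand pairing** (strict default): ≥ 2 inter-strand N···O distances
  < 3.5 Å between E1 and E2. Stochastic torsion draws without fragment
  refinement essentially never land hydrogen-bond-precision registers, so
  the end-to-end pipeline (`pipeline_filters()`) runs a proximity version
  (≥ 1 contact under 7 Å) and concentrates draws at 45% of the per-class
  spread. Both criteria are plain configuration.
* **Compactness**: CA radius of gyration below 1.3 × 2.2 N^0.38 Å, i.e.
  30% above the empirical scaling of compact folded domains (≈ 13 Å at
  N = 58). A N^0.6-type bound with an Å-scale coefficient of 0.395 was
  considered and rejected: it evaluates to ~6 Å at this size, below any
  physical chain — that coefficient belongs to nm-scale polymer scaling
  laws.
* **Cavity**: voxel scan at 1.0 Å spacing after rotating coordinates to a
  canonical principal-axes frame (making the count invariant under rigid
  motion). A voxel is occupied within atom radius + probe (1.7 + 1.4 Å) of
  any atom; an empty voxel counts as cavity when blocked along ≥ 5 of the
  6 axis directions. The strict default bound (20 Å³) is meant for
  full-atom models. Backbone-only compact folds necessarily enclose the
  volume their unbuilt side chains would fill — measured at roughly
  650–1200 Å³ for this fold — so the pipeline bound is 1500 Å³, catching
  topological holes rather than packing defects.

## Motif grafting

The hotspot loop ships as a six-residue idealized motif (H‑R‑G‑D‑F‑P built
from fixed torsions); the first and last residues are anchors, R‑G‑D‑F is
the grafted interior. Grafting superposes the motif anchor frames (N, CA,
C of both anchors, six atoms) onto the residues flanking the target loop
by Kabsch least-squares (proper rotations only; reflections are never
returned), replaces the loop interior, and reports the post-fit anchor
RMSD as the closure RMSD. A graft is accepted at closure ≤ 0.75 Å and zero
clashes. Length mismatches up to ±2 residues re-index the chain; no
loop-closure refinement is attempted (out of scope). Which loop hosts the
motif is configurable and defaults to L1, the position the final designs
use.

## Interface scoring

Rosetta-style interface metrics are replaced by documented geometric
proxies:

* **SASA** by Shrake–Rupley sampling (960 deterministic golden-spiral
  points per atom, probe 1.4 Å; radii N 1.55, C 1.70, O 1.52 Å), with
  coordinates canonicalized first so areas are exactly reproducible under
  rigid motion. Accuracy against the closed-form one- and two-sphere
  solutions is within 2%, and 960 vs 4000 points agree within 1%.
* **Buried interface area**: ΣSASA(A) + ΣSASA(B) − ΣSASA(A∪B), computed
  per atom and clamped at zero, which also yields the tight-contact
  surface (buried area restricted to atoms whose surface gap is ≤ 1.5 Å).
* **Contact energy** (`ddg_proxy`): class-compatibility weights
  (hydrophobic–hydrophobic −1, donor–acceptor −1.5, opposite charges −2,
  like charges +2) times a distance kernel that is 1 up to 3.5 Å and
  decays linearly to 0 at 5 Å. Backbone-only designs contribute one
  pseudo-atom per residue at CA, classed by sequence letter. The energy is
  additive over disjoint interface patches by construction.

Ranking sorts by contact energy, breaking ties by contact surface and then
design id; thresholds default to "accept anything clash-free" because no
numeric cutoffs are published for the original ranking.

## Sort-seq affinity estimation

The estimator models the chance that a displayed cell is collected in the
gate at ligand concentration c as proportional to the occupancy
c / (c + K~D~), with each gate's selection stringency absorbed into the
gate normalization. Counts are multinomial per gate; log10 K~D~ values are
fit by coordinate-wise maximization of the joint likelihood (the
normalization couples variants), with curvature-based standard errors.
Estimates at the edge of the probed concentration range (±2 decades beyond
the gates) are flagged `below-range`/`above-range` rather than reported as
converged values — mirroring how very stringent sorts only bound an
affinity. The exact estimator used in the original screen is described
only by citation, so the occupancy/multinomial model is our explicit,
replaceable choice; it recovers noiseless truth to a fraction of a percent
and stays within 25% median error at 10^5 reads per gate.

SSM tolerance maps convert ΔlogK~D~ into per-position weights
p ∝ exp(−Δ/T) and report Shannon entropy in bits (0 = conserved,
log2 20 ≈ 4.32 = indifferent). Specificity calls require on-target
K~D~ ≤ 100 nM and an off-target/on-target ratio ≥ 100-fold by default;
both cutoffs are configuration, as the published scatter prints none.
Combination libraries are the plain Cartesian product of parent vs
substitution at each listed position.

## Binding models

* **1:1 kinetics**: association R(t) = R_eq (1 − e^(−(k_on C + k_off) t))
  with R_eq = R_max C / (C + K_D), dissociation decaying from the
  association end point. One (k_on, k_off, R_max) triple is fit jointly
  across traces by Levenberg–Marquardt in log space with five log-spaced
  k_on starts (deterministic; best SSE wins). K_D ≡ k_off/k_on.
* **Three-parameter dose-response**: MFI(c) = bg + (max − bg) c / (c + K_D)
  (descending form for competition-style curves), with delta-method
  standard errors from the Gauss–Newton curvature.
* **Global competition**: descending logistic with Hill slope fixed at 1
  (the three-parameter family), plateaus shared across competitors, one
  EC50 each; K_D = EC50 / (1 + C_L / K_D,L) converts for the labelled
  tracer at concentration C_L. With a single competitor the fit reduces
  exactly to the descending dose-response, which the tests enforce at
  1e−6 relative.

Optimizer parity with the vendor/Prism software used on the bench data is
impossible, so parameter recovery on forward-simulated data is the
contract: all three families round-trip noiseless inputs within 1%, and
the suite checks the published operating points (0.31 nM kinetics; 1.9 and
124 nM on-cell; 0.9/612/150,000 nM competition and the 65× and 680×
ratios they imply) at 5%.

## Synthetic fixtures: what they emulate, and what they do not

Every input regenerates from a seed: topology statistics, the idealized
motif, a pseudo-target (one negative and one positive anchor 6–9 Å apart
plus a three-atom hydrophobic pocket, placed to reward RGD-like poses),
sort-seq counts and binding curves. Manifests record parameters and md5
checksums; regeneration is byte-identical.

The shipped topology statistics stand in for a structural survey of
ferredoxin-like domains. Their loop options were designed, once, by a
geometric search for connector ABEGO strings whose mean-torsion chain
closes into a compact, clash-free βαββαβ — which is exactly the property
that makes real survey loops "most occurring": observed loops are the ones
that close the fold. Counts decay geometrically with rank with
seed-controlled jitter. L1 options are four residues so the loop hosts the
RGDF motif interior.

What the fixtures do **not** emulate: real side-chain packing and
sequence–structure coupling (models are backbone-only), NGS error
profiles, gate spillover or sorting impurities, receptor conformational
change, avidity and rebinding. Passing tests therefore demonstrate that
the algorithms are correct and the estimators recover known truth under
their stated models — not that the pipeline would rediscover a real
binder against a real receptor.

## Problem sizes and determinism

Default study sizes keep every stage interactive: 250,000 enumerated
blueprints with the top 100 retained; two blueprints built per pipeline
run with 80 sampling attempts per stage and 8 lineages; 10-variant
sort-seq fixtures at 5 concentrations and 10^5 reads per gate; 12-point
dose curves and 14-point competition curves. Every stochastic function
takes an explicit seed, restores the caller's RNG state, and reproduces
byte-identical output per seed (PDB output included).

## Known limitations

* Strand pairing is asserted by distance criteria, not hydrogen-bond
  geometry with register and pleat; no fragment refinement or energy
  minimization exists, by scope.
* Scoring is backbone/pseudo-atom level; it orders poses sensibly (charge
  swaps at the anchor pair flip the sign of the preference) but is not an
  energy function.
* The sort-seq estimator assumes the occupancy model it documents;
  mean-bin style estimators from the display literature would need a
  different gate model (the module keeps that pluggable).
* Blueprint scoring assumes independence between loops, helices and sheet
  combinations; real occurrence statistics are correlated.
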