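---
title: "Triage of GPCR dimer models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of GPCR dimer models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrdimer)
```

## The problem

Chemokine receptors — class A G protein-coupled receptors (GPCRs) with
the canonical seven-transmembrane-helix (7TM) fold — dimerize with
themselves, with each other, and with highly truncated splice isoforms
that retain only two to five TM helices. Structure-prediction and
docking tools emit tens of candidate complex models per receptor pair,
most of which are physically impossible for a membrane protein (a
protomer upside down in the bilayer, the two protomers sitting in
different membrane planes). `gpcrdimer` implements the downstream
triage and interpretation layer of such a study: it filters docked
poses for membrane topology, characterises the surviving interfaces at
TM-helix resolution, selects the most stable models from binding free
energy (BFE) tables, decides whether a truncated isoform can *block* a
dimerization interface, groups models that *compete* for the same
surface, and assembles candidate higher-order oligomers with a steric
clash check.

Two classes of input are deliberately consumed, never computed: complex
coordinates (from AlphaFold-Multimer, ClusPro, or molecular-dynamics
snapshots) and energies (MMPBSA BFE means with SEMs, and per-residue
energy decompositions). Everything the package computes is geometric or
combinatorial, which is what makes it testable at desk scale.

## The membrane frame

A protomer's membrane geometry is inferred from its TM annotation
alone. Each TM helix contributes an axis; since the fold alternates
direction (odd-indexed helices run extracellular to intracellular),
odd-index axes are flipped so all axes point extracellular, and the
unit mean is the membrane normal. The midplane passes through the
centroid of the per-helix C-alpha midpoints. The sign convention is
anchored at the N-terminal end of TM1, extracellular in chemokine
receptors.

One numerical detail matters. A helix axis estimated from short end
caps inherits the helical phase: the centroid of *k* consecutive
C-alphas sits exactly on the helix axis only when *k* spans whole
turns. We therefore average 18 consecutive C-alphas — five turns at 3.6
residues per turn — at each helix end, which cancels the phase exactly;
helices shorter than 19 residues fall back to 2–4-residue end caps (an
approximation adequate for the 2-degree scale of the orientation test).

## Topology compliance

Three rules triage a docked pose:

* **(i) orientation** — the two inferred normals agree within
  `orientation_tol_deg` (default 30°). A flipped protomer scores 180°.
* **(ii) layers** — the midplane offset along the mean normal is at
  most `layer_tol_A` (default 8 Å). A pose translated out of the
  membrane plane by 15 Å fails cleanly.
* **(iii) symmetry** — for homodimers (identical protomer sequences)
  the interface composition of the two protomers, compared as TM-helix
  *sets*, must be identical. Heterodimers report this rule as not
  applicable.

The published criteria are verbal ("consistent", "basically spatially
consistent"); the two numeric tolerances are this package's own
quantification, chosen once to sit far from both the compliant poses
and the decoys the generator produces (compliant poses score ≤ ~1° and
≤ ~1 Å; flip and offset decoys score 180° and 15 Å), and both are
exposed in `screen_params()` so a screen always logs what it used.
Rule (iii) is evaluated at helix granularity, not residue granularity,
because published interface compositions are reported per helix.

## Interfaces, helix ranking, and E/M/I qualifiers

An interface residue is any residue with a heavy atom strictly within
`cutoff_A` (default 5 Å) of the other protomer — the same 5 Å rule used
when MMPBSA decompositions are printed. Helix contributions are ranked
by summed favourable per-residue energy when a decomposition table is
present, and by interface residue count otherwise; ties break toward
the lower helix index. Both metrics are available because published
rankings derive from energy decompositions, which a consumer of
third-party tables cannot always obtain; the contact-count fallback is
logged whenever it is used. Loops and Helix 8 participate in contact
computation but are excluded from the ranking, matching the convention
that only TM helices appear in interface strings.

A helix qualifier localises the contact along the membrane normal: the
helix is cut into three equal-length thirds (extracellular E, middle M,
intracellular I) and a third that holds at least `qualifier_frac`
(default 0.6) of the helix's interface residues names the qualifier;
otherwise the majority of the helix is involved and no qualifier is
printed. The 0.6 default encodes "clear dominance" while letting a 2/3
split qualify; it is configurable because the published definition is
verbal.

Per-residue significance uses the strict threshold `contribution <
-1 kcal/mol`; a residue at exactly −1 is excluded.

## Model selection, blocking, and competition

**Selection.** Within a complex group the model with the lowest mean
BFE is kept; any model within `delta_keep` (default 15 kcal/mol) of the
best whose subject helix set is distinct (Jaccard < 0.5) from every
kept model is kept too, up to three models. This operationalises
"comparably stable models with distinct interfaces are all analysed";
published groups never retain more than three.

**Blocking.** A subject-blocker model blocks a dimer model when (i)
the blocker's interface on the shared subject covers at least
`overlap_min` (default 0.25) of the dimer's subject interface, and
(ii) the blocker's mean BFE is lower than or close to the dimer's:
`bfe_blocker <= bfe_dimer + delta_close`. The `delta_close` default is
15 kcal/mol. The published worked examples include a blocker that is
13.2 kcal/mol *weaker* than its dimer yet is still called a blocker,
so a 5 kcal/mol reading of "close" is demonstrably too strict; 15
reproduces every published verdict with margin while still rejecting,
for example, a blocker 20 kcal/mol weaker. SEMs are carried through
reports but never enter the decision: at ~0.1–0.4 kcal/mol they are
two orders of magnitude below the decision scale. Overlap is measured
on the subject protomer by residue number (the two complexes share the
subject's numbering); superposition on the subject C-alphas (Kabsch,
SVD with determinant correction) supports steric inspection and
oligomer assembly but the verdict itself is a set computation —
residue sets are finer than helix sets and make the verdict monotone
in overlap.

**Competition.** Models sharing a subject compete when each one's
subject interface covers at least `overlap_min` of the other's;
connected components of that relation (size ≥ 2) are competition
groups.

## Higher-order oligomers

Assemblies grow from a seed protomer by superposing a dimer model's
subject onto an already placed protomer and adding its partner with
the induced transform; placed protomers never move. The clash check
reports residue pairs of distinct placements with heavy atoms closer
than `clash_cutoff_A` (default 2 Å), excluding the designed interface
contacts of each extension; the package detects clashes and never
repairs them (side-chain rotation or protomer translation is a
modelling step, out of scope). Chains that alternate two distinct
interfaces — the pattern the selection step surfaces when a group
retains two models with distinct helix sets — extend without clashing,
which is the structural prerequisite for linear higher-order
oligomers.

## The synthetic generator: what it emulates, and what it does not

All tests run on idealized synthetic structures, not on predicted
receptor models:

* **Bundles** (`build_ideal_bundle()`): straight alpha-helices (N, CA,
  C, O backbone plus a CB marker) with ideal geometry — 1.5 Å rise and
  100° twist per residue, C-alpha 2.3 Å from the axis — arranged on a
  12 Å circle at the seven-helix angular pitch, alternating up/down
  through a planar membrane at z = 0. Truncated `Iso_XTM`-style
  protomers (2–5 helices) are arcs of the same circle, mirroring
  C-terminal truncation. Loops occupy residue numbering but carry no
  atoms; each helix uses a distinct marker residue type so interface
  sets can be verified by sequence inspection.
* **Poses** (`place_dimer()`): the partner is rotated so designed
  facing helices oppose the subject's, then translated in-plane to a
  facing-axis separation of 10 Å by default — close enough for a dense
  5 Å interface, far enough that nothing approaches the 2 Å clash
  scale. An interpenetration guard rejects separations that produce
  sub-2 Å contacts. Compliant-pose variation preserves the C2 symmetry
  of homodimers (facing pair, separation, whole-pose in-plane
  placement); a partner-only axial twist is available as a
  perturbation and is used for heterodimer poses, because at wide
  separations it legitimately produces one-sided marginal contacts
  that rule (iii) should, and does, reject.
* **Decoys** (`make_decoy()`): flip (180° about an in-plane axis),
  offset (15 Å along the normal), tilt (compliant below the 30°
  tolerance), and asymmetric (partner rotated about its own axis by
  helix steps) — each violating exactly one targeted rule.
* **Energy tables** (`synth_energy_table()`): 90% of a stated total
  BFE spread over interface residues proportionally to contact counts,
  the rest spread evenly, plus seeded Gaussian noise (0.1 kcal/mol per
  residue by default).

What the generator does *not* emulate: side-chain rotamers, helix
kinks and bends, loop atoms, membrane deformation, and docking-score
realism. Green tests therefore certify the *logic* — rule
discrimination, ranking, overlap, selection arithmetic, assembly
geometry — on unambiguous inputs; they do not certify that the 30°/8 Å
tolerances are optimal for real docked receptor poses, where
borderline cases will occur.

## Worked-example inputs and the bundled data

The bundled `chemokine_model_table()` transcribes the published
summary of 26 most-stable models (interface strings, BFE mean ± SEM)
for the CXCR2/CXCR7/CCR2/CCR7 panel; `chemokine_blocking_claims()`
records the 13 published blocking relationships, including the
negative control (a 4TM isoform whose complex does not overlap its
receptor's homodimer interface). Feeding the printed BFEs and stated
overlap relationships through `blocking_decision()` reproduces all 13
verdicts at the default thresholds
(`evaluate_blocking_claims()`). Interface strings are stored in the
normalised `"TMk (Q)"` spelling (the published table is
typographically inconsistent about the space before the parenthesis).

`inst/extdata/chemokine_receptors.fasta` bundles transcriptions of the
UniProt entries for CCR2 (P41597), CCR5 (P51681) and CXCR4 (P61073) so
that sequence-identity computations work without network access. The
transcription could not be re-verified against the live database from
this environment; `pairwise_identity()` on the bundled copies gives
71% (CCR2 vs CCR5) and 31% (CCR2 vs CXCR4) under Needleman–Wunsch with
BLOSUM62 and gap penalties 10/0.5, versus 79% and 33% as published
with the UniProt alignment tool — a discrepancy attributable to
residual transcription errors and to the unstated parameters of that
tool, which is why the substitution matrix and gap penalties are
exposed as arguments rather than hard-coded as correct.

## Problem sizes and determinism

The test-suite and acceptance-script workloads are sized for a desk
machine: 50 compliant poses plus 50 decoys per mode for filter
discrimination, 20 random designed poses for ranking (checked against
an independent all-pairs distance scan), 100 random point sets for the
Kabsch-versus-quaternion cross-check (agreement well below 1e-6 Å),
4-protomer assemblies for the clash criterion, and the 26-row/13-claim
worked example. Every stochastic step is seeded; identical specs and
seeds give bit-identical structures, tables and screen reports.

## Known limitations

* The membrane frame is annotation-driven; it does not optimise
  hydrophobic thickness and will be wrong if the TM annotation is.
* Rule (iii) compares helix sets, so a homodimer whose two protomers
  use the same helices with very different residue footprints still
  passes; the residue-level machinery exists but is deliberately not
  used here.
* Blocking verdicts are structural statements about overlap and
  binding strength; they imply nothing kinetic or cell-biological.
* mmCIF input, hydrogen handling, and structure repair are out of
  scope; PDB files are read heavy-atom-only.
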