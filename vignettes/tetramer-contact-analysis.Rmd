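---
title: "Inferring homo-tetramer architecture from contact fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring homo-tetramer architecture from contact fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligofinger)
```

## The model

`oligofinger` analyzes conformational ensembles of `N` chemically identical
protein chains and asks three questions: *which inter-chain interfaces
exist*, *how many times does each occur in the assembled complex*, and
*what symmetry does the complex have*. The motivating system is the BCL11B
ZF0 zinc-finger domain (modeled residues 54–82, UniProt Q9C0K0 numbering),
whose tetramer is a dimer of dimers: two beta-sheet-stacked dimers
(interface `IF-beta`, clamped by the D54–K77 charge-lock salt bridge)
associate through a hydrophobic interface (`IF-alpha`: L67–I70, L67–L71,
L67–I74) and a helical cross-dimer interface (`IF-gamma`: I74–F73, I74–I74,
I74–K77, K77–R78, R78–R78). In such an architecture every interface class
appears exactly twice, and the ideal complex is self-superposable under
four chain permutations (D2-like symmetry).

The pipeline works at residue-contact level throughout. Two residues on
different chains are in contact when their sites lie within a cutoff
(default 8 Å — the common single-site/CA convention; the distance
definition is a declared choice, exposed as a parameter). Each frame is
encoded as a binary *fingerprint* over all (chain-pair slot, residue pair)
columns. Because the chains are identical, their labels carry no
information: the fingerprint is canonicalized by applying, per frame, the
chain permutation that minimizes the binary vector lexicographically (ties
broken by the lowest label sequence). This guarantees bit-identical
fingerprints under any relabeling of the input — the property the test
suite checks against brute-force permutation enumeration. The
canonicalization is exhaustive over `N!` permutations and therefore refused
beyond 8 chains.

One consequence worth knowing when reading fingerprints directly: because
the *lexicographic minimum* pushes 1-entries toward late columns, a lone
dimer is stored in the last chain-pair slot, and a two-dimer frame in the
latest slot pairing — slots (1,4) and (2,3) for four chains. Interface
classification is unaffected (it compares slot contents, not positions),
but per-slot occupancy probabilities follow these routing rules; the test
suite exploits them to compare empirical occupancies with the closed-form
stationary distribution of the assembly Markov chain.

ccPCA is ordinary PCA on the fingerprint matrix: columns are mean-centered,
never scaled, and the smallest number of components whose cumulative
explained-variance fraction reaches `variance_target` (default 0.9) is
kept. Component signs follow a fixed convention (largest-magnitude loading
positive), and the scores are verified against a direct eigendecomposition
of the covariance matrix. Frames are then clustered in score space.

## Structural states and interfaces

The clustering algorithm is deliberately deterministic: average-linkage
agglomeration on Euclidean score distances, with the number of clusters
chosen by maximum mean silhouette width over the grid 2..`max_k` (default
8). When even the best split has mean silhouette below `silhouette_floor`
(default 0.5), the ensemble is treated as a single state — this is what
makes a pure-noise, single-state ensemble come back as one cluster instead
of an arbitrary split. There is no seed dependence anywhere in the
analysis; only the synthetic generator and the crosslink simulator consume
seeds. Frames far from every medoid can optionally be flagged unassigned
(`noise_threshold`, off by default).

Within the dominant state, each contact's *persistence* is the fraction of
member frames containing it. Contacts with persistence at least
`membership_threshold` (default 0.5) define one pair set per unordered
chain pair; chain pairs whose sets agree up to swapping the two chains'
roles (Jaccard similarity at least `merge_threshold`, default 0.8) form one
interface class, whose multiplicity is the number of chain pairs carrying
it. Classes are ranked by descending total persistence and labeled `IF-1`,
`IF-2`, ...; the mapping to the published interface names is *reported* via
best pair-set overlap with `reference_interfaces()`, never assumed — which
chain pairs carry the hydrophobic versus the helical cross-dimer interface
is not identifiable from contacts alone, so the reference topology makes
that assignment configurable (`alpha_pairs`). Networks for display use the
lower `display_threshold` (default 0.25), mirroring the graded
edge-weight rendering common for contact-probability networks.

Assembly order is read per frame from the largest connected component of
the chain graph, linking chains that share at least `min_edges_per_link`
residue contacts (default 3, so a single spurious contact never fuses two
chains); the modal order resolves ties upward. Symmetry detection
superposes every chain permutation onto the original complex and keeps
those within `rmsd_tolerance`; the kept set is closed under composition (if
thresholding ever breaks closure, highest-RMSD elements are dropped with a
warning). For iid Gaussian site noise of scale sigma, the self-superposition
RMSD of a true symmetry permutation concentrates near `sigma * sqrt(6)`
(two independent noise copies, three coordinates), so the default tolerance
of 1.5 Å cleanly accepts true D2 permutations at the generator's default
sigma = 0.5 Å while rejecting wrong permutations, which sit several Å away.

## The synthetic generator

The generator emulates the statistical structure of replica-exchange
assembly ensembles of four ZF0 chains; it is a coarse model, not a physics
simulation. Its fixed ingredients:

* **Geometry.** One rigid site per residue. The chain template is a frozen
  output of `design_fold_template()`, which optimizes 29 sites under three
  penalties: every published interface contact realized within 6 Å across
  the corresponding D2 image, no two non-bonded sites of the tetramer
  closer than 3.8 Å, and consecutive sites near 3.8 Å. The four chains are
  the template's images under the identity and the three coordinate-axis
  two-fold rotations, so each axis carries one interface class twice by
  construction. The template is an idealized scaffold — it is *not* a real
  beta-beta-alpha zinc-finger fold, which is irrelevant here because all
  downstream analysis consumes contacts, not secondary structure.
* **Dynamics.** Three assembly bonds follow a discrete Markov chain: one
  per beta-dimer, plus a dimer-dimer bond that exists only while both
  dimers do (its four cross-interface placements switch together). Bonds
  switch on with probability `on_rate` and off with `off_rate` per frame
  and are initialized from the stationary distribution, so occupancies have
  no burn-in bias. Chains joined by "on" bonds keep their reference poses
  (all placed contacts realized); separate components are translated 150 Å
  apart, far beyond twice any sensible cutoff. Gaussian noise of
  `noise_sigma` is added to every coordinate.
* **Defaults as study conditions.** `n_frames = 2000`, `noise_sigma = 0.5`
  Å (sub-bond thermal jitter), `on_rate = 0.10`, `off_rate = 0.01`. The
  rate asymmetry encodes the qualitative kinetics the structural study
  reports — dimers form rapidly, and the assembled tetramer, once found,
  essentially never dissolves — while still letting monomer, single-dimer
  and two-dimer states occur so that clustering has genuine work to do.
  These sizes keep the full pipeline under a minute on one CPU; the test
  suite uses 120–1000-frame ensembles per case for the same reason, which
  is ample for contact persistences whose standard errors scale as
  `1/sqrt(n_frames)`.
* **Modes.** `dimer_only` suppresses the cross-dimer bond — the in-silico
  analogue of the I70A/I74A/K77A mutants that crosslink to dimers at most;
  `monomer_only` suppresses all bonds; `decoy` stacks two beta-dimers by
  pure translation, producing a connected tetramer whose interface
  classification *differs* from the reference — a negative control for the
  classifier.

What passing tests on these ensembles do show: the analysis chain —
canonicalization, ccPCA, clustering, persistence networks, classification,
multiplicity, assembly order, symmetry — recovers a planted dimer-of-dimers
architecture exactly, under positional noise and reversible partial
assembly, and its components match independent oracles (covariance
eigendecomposition, brute-force permutation enumeration, exhaustive mapping
search, closed-form Markov occupancies). What they do not show: that the
method would extract the same architecture from *real* all-atom ensembles,
whose contact definitions are softer, whose states are less separated, and
whose frames are exchange-correlated. The generator has no energetics, no
zinc coordination, no intermediate geometries between "assembled" and
"150 Å apart", and equal frame weights.

## Wet-lab forward models

The crosslink simulator reduces gel logic to connectivity: for each of
`n_molecules` complexes, every inter-chain linkable edge (from the
topology's placements, a structure's reactive-pair list, or the complete
graph on a bare order) is crosslinked independently with
`link_probability`; denaturation leaves the covalently connected
components, and the number of *distinct* component sizes is the band count.
Band intensities and migration are deliberately out of scope — the robust,
efficiency-independent observable is the count, which equals the assembly
order at intermediate probabilities (four bands for a tetramer) and
collapses to one band at probability 0 or 1. Reactive sites are lysines
plus each chain's N-terminus; the distance criterion is the linker span
(default 21.7 Å, the BS(PEG)5 reagent) plus a 6 Å slack for sidechain
reach beyond the one-site representation. Intra-chain pairs are reported
separately: they model the self-reaction channel that defeats crosslinking
of constructs with long disordered tails.

The SEC stoichiometric factor is the closed form
`10^(intercept + slope * V_e) / MW_monomer`, with the calibration line
user-supplied (calibration curves are instrument-specific, so the package
validates the operation analytically rather than reproducing any
particular instrument's numbers). No rounding is applied.

## Numerical choices and degenerate inputs

* A constant fingerprint matrix yields a defined ccPCA result with zero
  components and a warning, never an error; clustering then returns a
  single full-population cluster.
* Identical frames, single-frame clusters and empty contact sets all have
  defined behavior (population 1, the frame itself as medoid, an empty
  interface table for a dissociated state).
* Kabsch superposition guards against reflections (determinant forced to
  +1) and warns on rank-deficient point sets; chain mappings are exhaustive
  up to 8 chains.
* The beta-sheet interface is anchored at D54 (the published contact list
  D54–T57/C58/G59 and the charge-lock D54–K77), where the narrative
  alternative would have started it at D55; the package adopts the explicit
  list.
* Residue numbering is 1-based UniProt full-length numbering (54–82)
  everywhere; nothing is re-indexed to 1–29. Structure I/O rejects
  insertion codes and duplicated (chain, residue) keys with named errors.
* The construct sequence ships as `zf0_sequence()`; positions fixed by the
  interface lists, the mutant panel and the CCHC motif are annotation-exact,
  intervening positions follow the UniProt context.

## Limitations

The package infers architecture from contacts only: it ranks interfaces by
persistence, not energy; it assigns permutation-group order, not a
crystallographic point group; and it treats all frames as equally weighted,
which is wrong for raw replica-exchange output unless frames are already
resampled to a single ensemble. The crosslink model ignores reaction
kinetics and partial denaturation, and the SEC factor inherits all the
shape-dependence caveats of SEC calibration — for elongated or disordered
complexes the factor can overshoot the true order severely, which is
precisely why the band ladder, not SEC alone, pins the stoichiometry.
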