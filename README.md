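# oligofinger

Contact-fingerprint analysis of protein homo-oligomer assembly ensembles.

## The problem

The N-terminal atypical CCHC zinc-finger domain (ZF0) of the transcription
factor BCL11B mediates its multimerization: the domain assembles into a
symmetric homo-tetramer — a *dimer of dimers* — held together by three
distinct inter-chain interfaces, each present twice. Establishing such an
architecture from multi-chain conformational ensembles requires a chain of
inferences: the four chains are chemically identical, so their labels are
arbitrary; the ensemble mixes monomers, dimers and tetramers; and the
structural conclusion (how many interfaces, how often each occurs, what
symmetry the complex has) must ultimately square with wet-lab stoichiometry
readouts such as crosslinking band ladders and size-exclusion
chromatography (SEC).

`oligofinger` implements that inference chain as a tested, reusable R
pipeline, for structural bioinformaticians analyzing MD or docking
ensembles of self-assembling domains:

1. **Contact fingerprints** — each frame becomes a binary vector over
   (chain pair, residue pair) columns, canonicalized over all chain
   permutations so that relabeling the identical chains never changes the
   encoding.
2. **ccPCA** — PCA on the fingerprint matrix (columns mean-centered,
   components kept up to a cumulative explained-variance target), followed
   by deterministic agglomerative clustering into structural states.
3. **Persistence networks & interface classes** — for the dominant state,
   every contact is weighted by the fraction of the state's frames that
   contain it; chain pairs whose persistent contact sets coincide up to a
   chain-role swap are one interface *class*, and the number of chain pairs
   carrying a class is its *multiplicity*.
4. **Assembly order & symmetry** — per-frame largest connected chain
   component; exhaustive chain-permutation superposition (Kabsch) detects
   the point-group-like self-symmetry of the complex.
5. **Forward wet-lab models** — amine-reactive crosslinking band ladders
   (species = connected components after per-edge Bernoulli crosslinking;
   the number of distinct sizes bounds the assembly order) and the SEC
   stoichiometric factor `10^(intercept + slope * V_e) / MW_monomer`.

A coarse-grained synthetic generator (one site per residue, residues 54–82
in UniProt Q9C0K0 numbering, Markov assembly/disassembly of the
dimer-of-dimers topology) makes every stage testable without external
trajectory data; the published residue-level contact lists of the three
interfaces (`IF-beta` with its D54–K77 charge-lock, `IF-alpha`, `IF-gamma`)
ship with the package as `reference_interfaces()`.

## Worked example

```r
library(oligofinger)

topo <- build_reference_topology()       # 4 chains, 3 interfaces placed twice
traj <- generate_trajectory(topo, generator_config(n_frames = 500, seed = 1))

fp  <- traj |> extract_contacts(cutoff = 8) |> contact_fingerprints()
pca <- ccpca(fp, variance_target = 0.9)
clusters <- cluster_states(pca)
clusters
#> # A tibble: 3 × 4
#>   cluster n_frames population medoid_frame
#>     <int>    <int>      <dbl>        <int>
#> 1       1      313      0.626          217
#> 2       2      123      0.246          134
#> 3       3       64      0.128          219

classify_interfaces(fp, clusters)[, c("class", "multiplicity", "n_pairs",
                                      "mean_persistence", "best_match")]
#> # A tibble: 3 × 5
#>   class multiplicity n_pairs mean_persistence best_match
#> 1 IF-1             2      96            0.905 IF-beta
#> 2 IF-2             2      74            0.891 IF-alpha
#> 3 IF-3             2      59            0.890 IF-gamma

detect_symmetry(assembled_frame(topo))
#> <symmetry_result> order 4 over chains ABCD
#>   ABCD  (rmsd 0.000 A)
#>   BADC  (rmsd 0.000 A)
#>   CDAB  (rmsd 0.000 A)
#>   DCBA  (rmsd 0.000 A)

simulate_crosslink_ladder(topo, link_probability = 0.5, seed = 1)
#> # A tibble: 4 × 2
#>   species_size count
#> 1            1  5052
#> 2            2  1904
#> 3            3  2516
#> 4            4  5898
```

Reading the output: the dominant structural state (63% of frames) carries
exactly **three interface classes, each with multiplicity two** — the
dimer-of-dimers signature — and each class recovers the full published
contact list of one named interface (`best_match`, matched by pair-set
overlap, never assumed). The ideal complex is self-superposable under four
chain permutations (the identity and three double swaps: D2-like symmetry,
order 4), and a tetramer crosslinked at intermediate efficiency shows all
four bands (monomer–tetramer), while dimer-only systems — the in-silico
analogue of the interface mutants — give at most two.

`run_pipeline(list(seed = 1))` chains all stages (simulate → contacts →
ccPCA → cluster → network → interfaces → assembly → symmetry → crosslink
ladder) and can write every report plus a reproducibility manifest via
`out_dir`. `tidy()`, `glance()` and `autoplot()` methods cover the fitted
and result objects.

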