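# twnrencod

Compare protein binding sites through the water networks they organise,
rather than through their own atoms.

Conserved, hydrogen-bonded water clusters in a binding pocket are part of
what a ligand "sees": two kinases whose pockets shape similar hydration
networks tend to bind the same inhibitor with similar affinity, even when
their pocket residues differ. `twnrencod` implements a trajectory-based
pocket comparison built on that idea. From restrained-solvent molecular
dynamics frames (protein fixed, waters mobile) it:

1. **Detects topological water networks (TWNs)** — 3-membered rings of
   three mutually hydrogen-bonded waters. Two waters *a*, *b* count as
   hydrogen bonded when their rigid TIP3P interaction energy

   v(a,b) = Σᵢ Σⱼ kₑ qᵢqⱼ / rᵢⱼ + A/r_OO¹² − C/r_OO⁶

   (nine Coulomb terms over the (O,H,H)×(O,H,H) charge sites, one
   oxygen–oxygen Lennard-Jones term; q_O = −0.834 e, q_H = +0.417 e,
   A = 582 000 kcal·Å¹²/mol, C = 595 kcal·Å⁶/mol,
   kₑ = 332.0636 kcal·Å/(e²·mol)) is at or below **−2.25 kcal/mol**.
2. **Encodes each frame** as distances from each binding-site backbone
   atom (N, Cα, C, O of each pocket residue — 16 residues, 64 atoms by
   default) to the nearest ring centroid, then bins each distance into
   hydration-shell classes **A** (<5 Å), **B** (5–7.5 Å), **C**
   (7.5–10 Å), **D** (≥10 Å).
3. **Reorders the query protein's frames** against the reference's by
   greedy sequential minimum difference in distance values, because
   equivalent water networks need not occur in the same frames of two
   independent simulations.
4. **Scores similarity** as the fraction of matched class pairs between
   the two class-type matrices — a number in [0, 1], where 1 means
   identical encodings.

A pairwise similarity table can then be correlated
(Pearson/Kendall/Spearman) against |Δ log₁₀ Kd| inhibitory-activity
differences via `correlate()`.

The package also ships a synthetic-trajectory generator that plants
ground-truth water rings at chosen pocket locations, so the whole
pipeline is testable end to end without running MD.

## Worked example

Two synthetic "proteins" share the same two planted ring sites; the
second is perturbed by 0.5 Å coordinate jitter:

```r
library(twnrencod)

site_a <- synthetic_binding_site(n_residues = 16, radius = 8,
                                 protein_label = "kinaseA")
site_b <- synthetic_binding_site(n_residues = 16, radius = 8,
                                 protein_label = "kinaseB")

traj_a <- generate_trajectory(synthetic_spec(
  n_frames = 20, planted_sites = rbind(c(0, 0, 3), c(3, 0, -3)),
  n_noise_waters = 30, noise_box = c(60, 60, 60), seed = 101))
traj_b <- generate_trajectory(synthetic_spec(
  n_frames = 20, planted_sites = rbind(c(0, 0, 3), c(3, 0, -3)),
  jitter_sigma = 0.5, n_noise_waters = 30, noise_box = c(60, 60, 60),
  seed = 202))

rings_a <- detect_twns_trajectory(traj_a)
head(rings_a, 3)
#>   frame_index water_i water_j water_k      e_ij   centroid_x
#> 1           1       1       2       3 -3.522512 0.000000e+00
#> 2           1       4       5       6 -3.522512 3.000000e+00
#> 3           2       1       2       3 -3.522512 9.251859e-17
```

Each row is one detected 3-membered ring: the three water indices, the
three pair energies (all ≤ −2.25 kcal/mol; −3.52 is the planted-triangle
edge energy) and the ring centroid. Both planted sites are recovered in
every frame (40 rings over 20 frames).

```r
enc_a <- encode_trajectory(traj_a, site_a)
enc_a
#> encoded_trajectory 'kinaseA': 20 frames x 64 site atoms (16 residues)
#>   class occupancy: A=80 B=720 C=480 D=0

compare_trajectories(enc_a, encode_trajectory(traj_b, site_b))
#> twn_comparison: 'kinaseA' (reference) vs 'kinaseB' (query)
#>   matched class pairs: 181 / 1280
#>   similarity: 0.1414
```

A trajectory compared against itself, or against a frame-shuffled copy
of itself, scores exactly 1.0 (the greedy reordering recovers the
shuffle); 0.5 Å of jitter on an *independently generated* counterpart
drops the matched fraction to 0.14 — jitter both displaces surviving
ring centroids across class boundaries and breaks rings outright, and
the two runs realise different noise backgrounds. Similarity decreases
monotonically with jitter (see the test suite).

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "twn-rencod.R", package = "twnrencod"))')
Rscript $CLI simulate --spec spec.yaml --out traj.pdb
Rscript $CLI detect   --trajectory traj.pdb --out rings.tsv
Rscript $CLI compare  --ref-trajectory a.pdb --ref-site a.yaml \
                      --query-trajectory b.pdb --query-site b.yaml \
                      --out report.json
```

Real trajectories enter as multi-model PDB files
(`read_water_frames()`); binding sites as YAML/JSON configs listing
pocket residues with inline backbone coordinates or a reference PDB
(`read_binding_site()`).

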