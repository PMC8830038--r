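# lipidsite

Lipids and other small ligands bind membrane proteins at specific surface
sites, and molecular dynamics (MD) simulations — especially long
coarse-grained runs — sample these binding events well enough to
characterise them quantitatively. `lipidsite` turns MD trajectories of a
protein plus a named ligand species into:

- **dual-cutoff contact events** per residue and per site, with mean
  duration, occupancy (% of frames in contact) and ligand count,
- **residence times** from a survival time correlation function fitted
  with a biexponential,
- **binding sites** discovered as communities of a residue
  interaction-correlation network (Louvain modularity optimisation),
- **representative bound poses** chosen by a Gaussian kernel density score
  in relative-distance coordinates, plus k-means/DBSCAN pose clustering
  and pose RMSDs,
- **site surface areas** over time via the Shrake–Rupley algorithm,

and writes the whole analysis as a tidy output tree (master residue CSV,
B-factor-annotated PDB, PyMOL script, per-site summaries). It is aimed at
simulators of membrane proteins working at coarse-grained (e.g. Martini)
or atomistic resolution.

## The statistics at the core

**Contacts.** A ligand copy is in contact with a residue from the frame
its minimum atom–atom distance drops below a lower cutoff until the frame
it passes an upper cutoff (defaults 0.475/0.8 nm, suited to coarse-grained
sterols). The hysteresis band stops "rattling in a cage" — rapid
fluctuations of a bound ligand — from being miscounted as many short
events.

**Residence time.** For contact events with durations *d<sub>j</sub>*, the
survival function at lag *t* is the normalized count of windows
(ν, ν + *t*) over which a contact persists,

σ(t) = Σ<sub>j</sub> max(0, d<sub>j</sub> − t) / (T − t), normalized so σ(0) = 1,

which is fitted with σ(t) ≈ A e<sup>−k₁t</sup> + B e<sup>−k₂t</sup>
(A, B, k₁, k₂ ≥ 0). The slower rate with non-negligible amplitude is
reported as k<sub>off</sub>, the residence time is τ = 1/k<sub>off</sub>,
and fit quality is summarised by r². Contact durations are bootstrapped to
report the sampling spread of k<sub>off</sub>.

**Binding sites.** Each residue gets a ligand-interaction feature vector
over (ligand copy, frame, repeat); edges of the residue network are the
Pearson correlations of these vectors (negatives clamped to zero). The
network is partitioned by Louvain modularity optimisation,

Q = (1/2m) Σ<sub>ij</sub> [A<sub>ij</sub> − k<sub>i</sub>k<sub>j</sub>/2m] δ(c<sub>i</sub>, c<sub>j</sub>),

and communities of at least four residues are reported as binding sites,
ranked by residence time.

**Poses.** A bound pose is the matrix D with D<sub>ip</sub> = minimum
distance of ligand atom *i* to site residue *p* — invariant to rigid
motion, so pose analysis ignores global protein displacement. Poses are
scored by Σ<sub>i</sub> W<sub>i</sub> f̂<sub>i,H</sub>(D<sub>i</sub>)
with a Gaussian-kernel density f̂ per atom (bandwidth H = 0.15 by
default); the highest-scoring pose is the representative. Pose RMSD is
computed about the across-pose mean distance vectors.

## Worked example

The built-in generator plants binding sites with known exponential dwell
kinetics, so the full pipeline can be exercised without simulation data:

```r
library(lipidsite)

fx <- generate_fixture(
  fixture_spec(n_frames = 500, n_ligands = 4, n_repeats = 1, seed = 7)
)
cfg <- run_config(
  trajectories = fx$paths$trajectories, topology = fx$paths$topology,
  ligand = "LIG", output_dir = "analysis",
  n_boot = 5, sasa_points = 240, sasa_stride = 25, seed = 7
)
res <- run_pipeline(cfg)

res$sites[, c("site_id", "n_residues", "occupancy", "koff",
              "residence_time", "r_squared")]
#> # A tibble: 2 × 6
#>   site_id n_residues occupancy  koff residence_time r_squared
#>     <int>      <int>     <dbl> <dbl>          <dbl>     <dbl>
#> 1       1          7      81   0.235           4.26     0.998
#> 2       2          7      57.6 0.493           2.03     0.999

glance(res$site_fits[[1]])
#> # A tibble: 1 × 7
#>    koff residence_time r_squared n_events converged boot_koff_mean boot_koff_sd
#>   <dbl>          <dbl>     <dbl>    <int> <lgl>              <dbl>        <dbl>
#> 1 0.235           4.26     0.998       53 TRUE               0.267       0.0443
```

The two detected sites contain the two planted residue patches; the
fitted dissociation rates (0.235 and 0.493 ns⁻¹ from this short 250 ns
run) recover the planted rates of 0.2 and 0.5 ns⁻¹, and `occupancy` is
the percentage of frames with at least one bound ligand copy. The output
tree under `analysis/` holds `dataset.csv` (one row per residue with both
residue- and site-level metrics), `coordinates_residence_time.pdb`
(residence times in the B-factor column), `show_sites.py` (PyMOL
rendering of the sites), and per-site directories with `koff.csv`,
`surface_area.csv`, `rmsd.csv`, written poses and a plain-text summary.

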