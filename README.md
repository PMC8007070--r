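# sh2pep

Structural analysis of SH2 domain-phosphopeptide complexes in R.

SH2 domains recognize phosphotyrosine (pY) marks; for the N-terminal SH2
domain of SHP2 — the system this package's defaults annotate — binding is
held by an arginine-phosphate ion pair (R32, βB5), a hydrogen-bond network
around the phosphate (S34, K35, S36, T42), backbone H-bonds pinning an
extended peptide (H53, K89, K91), and hydrophobic insertion of peptide
positions +1/+3/+5 into a groove gated by the EF and BG loops. `sh2pep`
asks the standard quantitative questions about such complexes, uniformly
over single crystal structures and conformational ensembles:

* **Contacts** — hydrogen bonds (heavy-atom donor-acceptor ≤ 3.5 Å) and
  salt bridges (minimum charged-group distance ≤ 4.0 Å), per frame and
  aggregated: persistence (occupancy), stability at ≥ 50%, and
  published-style catalog tables (distances for crystals, integer percent
  for ensembles, `-` below 5%, `n.a.` for unresolved atoms).
* **Side-chain rigidity** — circular order parameters of χ1,
  Θ = |N⁻¹ Σᵢ (cos χᵢ, sin χᵢ)|, 1 for a frozen dihedral, → 0 for free
  rotation.
* **Mobility** — per-residue RMSF after least-squares superposition on the
  domain backbone.
* **Backbone conformation** — φ/ψ with Ramachandran region classification
  (polygons shipped as configurable data).
* **Burial** — side-chain solvent-accessible surface area (rolling-probe),
  relative to per-residue reference maxima; buried below 50%.
* **Loop/sheet geometry** — BC-loop-to-T42 opening, EF-BG gating distance,
  central-sheet interstrand distance.
* **Representative structures** — greedy neighbor-count RMSD clustering.
* **Convergence** — block-averaging SEM diagnostics.

A deterministic synthetic-ensemble generator (two-state contact switching
at prescribed occupancies, von Mises χ1 distributions, isotropic positional
noise, full ground-truth records) makes every estimator testable end to end
without external data.

## Worked example

Generate an ensemble in which the +2 Asp / K91 ion pair is formed in 70%
of frames, the +1 side chain is rigid and the +4 side chain rotates
almost freely — then recover all three facts:

```r
library(sh2pep)

# template complex: IRS-1 pY1172 core peptide (offsets -2..+5)
tmpl <- build_template_complex(list(peptide = "LNyIDLDL"))

pair <- atom_group_pair("+2 D : K91 [salt bridge]",
  data.frame(chain = "B", resno = 5, elety = c("OD1", "OD2")),
  data.frame(chain = "A", resno = 91, elety = "NZ"),
  kind = "saltbridge")
spec <- synthetic_ensemble_spec(
  tmpl, n_frames = 1000, seed = 7,
  contacts = list(contact_spec(pair, occupancy = 0.7)),
  dihedrals = list(
    list(residue = residue_ref("B", 4, "ILE"),
         dist = list(type = "vonmises", mu = -60, kappa = 12)),
    list(residue = residue_ref("B", 7, "ASP"),
         dist = list(type = "vonmises", mu = 180, kappa = 0.5))))
ens <- sample_ensemble(spec)

rec <- detect_interaction(ens$model, pair)
prof <- chi1_profile(ens$model, "B")
```

Output:

```
ion pair persistence: 68.7% (ground truth 68.7%), stable: TRUE
offset -2 (LEU): theta = 0.98
offset -1 (ASN): theta = 0.98
offset +0 (PTR): theta = 0.98
offset +1 (ILE): theta = 0.94
offset +2 (ASP): theta = 0.98
offset +3 (LEU): theta = 0.98
offset +4 (ASP): theta = 0.21
offset +5 (LEU): theta = 0.98
```

Detection recovers the realized occupancy exactly (68.7% of the 1000
Bernoulli draws at p = 0.7) and flags the contact stable (≥ 50%). The
κ = 12 side chain profiles at Θ = 0.94 and the κ = 0.5 one at 0.21 —
the von Mises population values are I₁(κ)/I₀(κ) = 0.957 and 0.242 —
while the unperturbed side chains sit at 0.98 (rigid up to the 0.1 Å
positional noise). On a real input you would start from
`load_structure()` / `load_ensemble()` instead of the generator, and
`enumerate_candidate_pairs()` builds the backbone / pY-pocket / side-chain
catalogs that `build_interaction_table()` renders.

## Analysis workflow

`analysis/` holds the numbered workflow, each script a thin driver over
the package that prints what it found and writes tables under `results/`:

1. `01_synthetic_ensembles.R` — generate the study ensembles + ground truth;
2. `02_interface_contacts.R` — contact catalogs, distance distributions,
   closed-loop persistence check (exact to machine precision);
3. `03_conformation.R` — RMSF/Θ profiles, Ramachandran, burial, loop
   metrics, representative structures, convergence diagnostics;
4. `04_pipeline_report.R` — `run_pipeline()` end to end and the stacked
   cross-run tables via `compare_runs()`.

Run them in order from the repository root with `Rscript`.

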