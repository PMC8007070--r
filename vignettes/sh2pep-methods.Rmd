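---
title: "Interface and conformation analysis of SH2 domain-phosphopeptide complexes"
author: "sh2pep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface and conformation analysis of SH2 domain-phosphopeptide complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh2pep)
```

# The problem

SH2 domains read phosphotyrosine (pY) marks: a ~100-residue module binds a
pY-containing stretch of a partner protein, with the pY buried in a charged
pocket and the residues C-terminal to it selecting among domains. For the
N-terminal SH2 domain of the phosphatase SHP2 — the system this package's
defaults describe — binding runs through a conserved arginine-phosphate ion
pair (R32, strand position βB5), a hydrogen-bond network around the
phosphate (S34, K35, S36, T42), an extended peptide backbone pinned by
H-bonds to the βD strand and the BG loop (H53, K89, K91), and hydrophobic
insertion of peptide positions +1/+3/+5 into a groove gated by the EF and
BG loops.

Analyzing such complexes means asking the same small set of quantitative
questions of very different inputs — a single crystal structure, a
multi-model ensemble, a trajectory: which contacts are formed and how
persistently; how rigid is each side chain; what backbone conformation does
each peptide position adopt; which side chains are buried; how open are the
mobile loops. `sh2pep` implements those questions once, uniformly over
single structures and ensembles, together with a ground-truth synthetic
generator so that every estimator in the package can be validated end to
end without any external data.

# Data model and conventions

A `complex_model` is an atom table plus a frames-by-3N coordinate matrix
(Angstrom), with the domain and peptide chains named explicitly. Chains
are *never* auto-detected: crystal forms exist with two peptides per
domain, or several complexes per asymmetric unit, and silent guessing is
how the wrong interface gets analyzed. For the same reason author residue
numbering is preserved exactly — nothing is renumbered.

Two annotation layers translate between structure and the field's
vocabulary:

* **pY-relative peptide numbering** (`assign_peptide_numbering()`): the
  phosphotyrosine is position 0, N-terminal residues are negative,
  C-terminal positive. Offsets follow chain order, so they remain
  consecutive across gaps in author numbering (the gap is reported).
  The pY itself is found either by the standard component name `PTR` or by
  connectivity — a tyrosine whose ring hydroxyl oxygen carries a bonded
  phosphorus — because deposited structures use `PTR` while generated or
  in-house models often phosphorylate a TYR in place.
* **SH2 secondary-structure nomenclature** (`build_sh2_annotation()`): a
  map from labels like `βB5`, `BC1`, `BG7` to residue numbers, with SHP2
  N-SH2 defaults (βB5→32, BC1→35, BC2→36, βB7→34, βC3→42, βD6→55, BG5→89,
  BG7→91, and so on), the loop ranges (BC 34–38, EF 66–69, BG 84–96) and
  the probe atoms used by the loop metrics. Every label is verified to
  resolve to a residue actually present; overrides are explicit arguments,
  and no hard-coded residue number exists outside this object. Other SH2
  domains are supported by overriding the map; no automatic alignment is
  attempted.

Alternate locations are resolved to the highest-occupancy conformer (ties
to altloc A). Waters are dropped. Hydrogens are kept when present but no
criterion depends on them (below), so X-ray and MD inputs behave
identically.

# Interaction detection and persistence

All criteria are heavy-atom distances:

* hydrogen bond — donor-acceptor distance ≤ 3.5 Å;
* salt bridge — minimum distance between charged groups ≤ 4.0 Å, where the
  groups are Lys Nζ, the Arg Nε/Nη1/Nη2 guanidinium, Asp Oδ1/Oδ2,
  Glu Oε1/Oε2 and the pY phosphate terminal oxygens O1P/O2P/O3P.

The per-frame distance of a candidate pair is the **minimum over all
cross-group atom combinations**; the minimum-heavy-atom convention is the
only one under which the 4.0 Å rule reproduces charged-group contact
classifications regardless of which oxygen or nitrogen happens to face the
partner. On an ensemble, *occupancy* (persistence) is the fraction of
evaluable frames satisfying the criterion, and a contact is *stable* at
occupancy ≥ 50%; on a single structure, stable means the distance criterion
itself. Frames in which a required atom is missing are removed from the
denominator rather than counted as non-bonded, and a record whose atoms are
absent altogether renders as `n.a.` instead of a number.

No angle term is applied by default. Distance-only criteria are the ones
the published interface tables are defined by, and they are the only ones
computable uniformly on hydrogen-free crystal structures. An optional
donor-H-acceptor ≥ 150° filter exists for hydrogen-bearing ensembles
(`hbond_min_angle`), off by default.

Candidate pairs are enumerated per catalog: peptide backbone N/O against
domain backbone N/O (donor-acceptor combinations only); the pY phosphate
against the fixed pocket probe list (S34 Oγ, K35 N, S36 N, T42 Oγ1
H-bonds; R32 guanidinium, K35 Nζ, K55 Nζ salt bridges); and peptide
side-chain polar/charged atoms against domain polar atoms. A 6 Å
any-frame prefilter keeps the candidate lists short; it is purely a
performance device, and the test suite holds detection to an exhaustive
O(n²) scan on random geometries.

Rendered tables follow the published conventions exactly: distances to one
decimal (half-up) for single structures, integer percent persistence for
ensembles, a dash for H-bonds not formed (single structure) or below 5%
persistence (ensemble), `n.a.` for non-evaluable records, and a stability
flag at the thresholds above. Salt-bridge distances are printed even when
far beyond the cutoff, since the separation of charged groups is
informative in itself.

# Conformational statistics

**χ1 order parameter.** For a side-chain dihedral sampled over N frames,
the order parameter is the modulus of the circular mean of unit vectors at
the per-frame angle:

$$\Theta_\chi = \left| \frac{1}{N} \sum_{i=1}^N
  \big(\cos\chi_i, \sin\chi_i\big) \right|$$

Θ = 1 for a dihedral frozen across frames and Θ → 0 for free rotation; it
is invariant under a global rotation of all angles, and for a von Mises
distribution with concentration κ its population value is the Bessel ratio
I₁(κ)/I₀(κ) — the oracle the recovery tests use. Only χ1 is profiled
(N–Cα–Cβ–γ heavy atom, with the standard γ-atom choice per residue type;
pY follows the tyrosine definition); glycine and alanine have no χ1 and
render as `x` in profile tables. Positional measurement noise biases a
measured Θ slightly downward (jitter of the four defining atoms widens the
apparent angle distribution), which is why the order-parameter calibration
runs on noise-free synthetic ensembles; at the generator's default noise
(0.1 Å) the bias is a few parts in a thousand.

**RMSF.** Frames are superposed by least squares on the domain backbone
(N/Cα/C) by default, for both peptide and domain profiles — peptide
mobility is then measured *relative to the binding site*, which is what a
bound-peptide fluctuation profile is meant to show. Per-atom RMSF is the
RMS deviation from the atom's mean position; per-residue values average
heavy atoms for peptides and backbone atoms for the domain. Fitting on the
peptide itself is available through `fit_selection`. Residues within 1 Å
of the profile minimum are flagged low-mobility.

**Ramachandran classification.** φ/ψ use the standard four-atom
definitions; terminal residues are skipped with a message. Region
boundaries are configuration, not code: generous published-style polygons
for three residue classes (generic, Gly, Pro) ship as a CSV
(`extdata/rama_regions.csv`) and can be replaced wholesale. Regions are
β/extended (the top-left quadrant), right-handed α, left-handed α, and
`other`; the first matching polygon in that order wins, and classification
depends on nothing but (φ, ψ, class).

**Solvent burial.** Side-chain solvent-accessible surface area uses a
rolling-probe (Shrake-Rupley) algorithm written in this package — no
installed R package provides the primitive — with Bondi-type radii, a
1.4 Å probe and a golden-spiral point lattice (242 points per atom by
default). Relative accessibility divides by a per-residue-type reference
maximum computed from the central residue of an extended Gly-X-Gly
construct built by the package's own generator with the same SASA
parameters, cached per session. Computing the reference with the same
construct and code that define the quantity keeps relative SASA exactly 1
on the defining geometry and covers phosphotyrosine uniformly; the price
is that references reflect this package's idealized side-chain geometry
rather than a literature scale, a difference of a few percent that does
not move the coarse 50% burial threshold. A residue is *buried* below 50%
relative SASA. Ensemble labels use the mean SASA over frames, not a
majority vote of per-frame labels, so they are invariant to frame order.

**Loop and sheet metrics.** Three per-frame series summarize the mobile
regions: the mean over BC-loop residues of the minimum heavy-atom distance
to the pocket probe residue (T42-equivalent), which measures pY-pocket
opening; the minimum heavy-atom distance between the EF and BG loops,
which gates the specificity groove; and the central-sheet interstrand
distance between the βC1 residue's C atom and the βD′1 residue's N atom.
Minimum-heavy-atom distances for the BC metric are robust to side-chain
composition across SH2 domains; a Cα-Cα variant is available
(`bc_mode = "ca"`).

**Representative structures.** Greedy neighbor-count clustering on the
pairwise least-squares-fitted RMSD matrix (backbone selection, 2 Å cutoff
by default): the frame with the most neighbors becomes a cluster center,
its neighborhood is removed, and the centroid of the largest cluster is
returned, with ties broken to the lowest frame number — fully
deterministic. The pairwise matrix is computed with an internal Kabsch
(3×3 SVD) implementation for speed on ensembles of hundreds of frames; the
tests pin it to `bio3d::rmsd(fit = TRUE)` pair by pair, and to exhaustive
cluster search on small ensembles.

**Convergence.** `block_average()` estimates the standard error of a
series mean from block means at several block counts. For a stationary
series whose correlation time is shorter than a block, the SEM plateaus as
blocks grow; the `converged` flag requires the relative SEM change between
the two largest block sizes to stay below 20%. The 20% threshold is this
package's choice, as is the default block list. Note the SEM estimated
from n blocks has relative sd ≈ 1/√(2(n−1)); plateau detection is only as
good as the smallest block counts used, so for long series prefer counts
of a few tens or more.

# The synthetic-ensemble generator

The MD ensembles behind published interface tables are rarely deposited,
so the generator makes the statistical structure of such data available
with known ground truth:

* a **template complex** (`build_template_complex()`): an all-heavy-atom
  peptide in an extended backbone conformation (φ, ψ = −120°, 130°, the
  bound-state geometry of type-II SH2 complexes) with idealized side
  chains, 15 Å from a rigid scaffold "domain" spanning residues 3–103
  whose annotated positions carry the true SHP2 N-SH2 residue types, so
  every nomenclature label and probe atom resolves. The scaffold is
  deliberately not a folded SH2: the downstream metrics consume geometry,
  and folding is outside the generator's claims — as are force fields,
  integrators, and any thermodynamic realism;
* **two-state contacts**: each specified contact is independently bound
  per frame with prescribed probability p, realized by rigidly translating
  the partner residue along the line of closest approach to the bound or
  unbound distance (defaults 2.9 / 6.5 Å, straddling the detection
  cutoffs). An optional two-state Markov switcher with a dwell parameter
  produces autocorrelated series for exercising the convergence
  diagnostics; the i.i.d. default is the cleanest testable condition;
* **prescribed χ1 distributions**: point mass, von Mises (sampled by
  Best-Fisher rejection), or mixtures, applied by rotating the side chain
  about the Cα-Cβ axis;
* **isotropic Gaussian positional noise**, default σ = 0.1 Å — enough to
  make every downstream estimator work for its answer while keeping
  engineered distances well clear of the cutoffs (bound 2.9 Å vs 3.5/4.0;
  distance jitter ~ σ√2).

Everything is driven by one seed; identical specifications yield
bit-identical coordinates and therefore byte-identical downstream tables.
The generator records the realized per-frame states and drawn angles, so
closed-loop tests can demand *exact* recovery of realized occupancies, not
merely statistical agreement.

What passing on synthetic data does and does not show: it validates the
estimators (detection, persistence aggregation, circular statistics,
superposition, SASA, clustering) against known truth, but synthetic
ensembles have idealized geometry, no correlated collective motions unless
asked for, and no force-field physics. Conclusions about a real system
still require real structures or trajectories as input — the point is
that when those arrive, every stage of the machinery has been verified.

# Problem sizes and numerical choices

The bundled analysis workflow (`analysis/01...04`) runs two 500-frame
ensembles of a ~570-atom complex; occupancy estimates at N = 500 carry
binomial standard errors of about 2%, and the calibration suites use
N = 2000 (occupancy grid, exact binomial 99% intervals) and N = 10⁴
(order-parameter grid, three standard errors of the Bessel-ratio oracle).
Surface area is the most expensive per-frame quantity; since burial varies
slowly, the workflow subsamples frames for it (`sas_stride`), which leaves
the mean SASA's uncertainty far below the 50% classification granularity.
Degenerate inputs are handled explicitly rather than silently: empty
analysis windows, missing chains and atoms, zero-evaluable-frame records,
peptides without (or with several) phosphotyrosines, too-short series for
a block count — each raises an informative error or an `n.a.`/skip with a
message, as exercised in the test suite.

# Known limitations

* The scaffold "domain" is rigid and unstructured; domain-side RMSF and
  loop metrics on synthetic data exercise the code paths, not SH2 physics.
* SASA references derive from this package's extended constructs, not a
  published scale; absolute relative-SASA values near the 50% threshold
  can differ by a few percent from scales computed with other reference
  geometries.
* Ramachandran polygons are deliberately coarse boxes; borderline
  conformations near region edges are classification-config dependent,
  which is why the polygons are shipped as data.
* The distance-only H-bond criterion can over-count on hydrogen-bearing
  inputs with distorted geometry; enable the angle filter there.
* Persistence values from real trajectories depend on the analysis window;
  the window is explicit configuration (`analysis_window`), echoed into
  every output for provenance.
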