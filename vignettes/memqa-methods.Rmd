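---
title: "memqa: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memqa: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the quality model, the resampling protocol, the synthetic study conditions,
the numerical choices, and — importantly — what the desk-scale results do
and do not show.

## 1. The quality model

`memqa` predicts, for every residue of an all-atom membrane-protein model,
how close that residue sits to its (possibly unknown) native position. The
per-residue target during training is the S-score of the Cα deviation $d$
after a global superposition of the model onto the native,

$$ s(d) = \frac{1}{1 + (d/d_0)^2}, \qquad d_0 = 3\,\text{Å}, $$

so a perfectly placed residue scores 1 and one $d_0$ away scores 0.5. The
global model quality is the mean of the per-residue predictions, clamped to
$[0,1]$.

The predictor itself is linear ridge regression over a windowed feature
vector. A linear model was chosen deliberately over a kernel machine: the
original method in this lineage used a linear SVM, and at this scale ridge
regression is functionally equivalent, closed-form, and exactly
reproducible — `train_scorer()` has no stochastic component at all.
Column z-normalisation constants are fitted on the training data and stored
on the scorer, so a saved model (`save_scorer()` / `load_scorer()`, plain
text with a versioned header) reproduces predictions bit-identically.

Per residue, before windowing, the 65 features are:

| block | width | source |
|---|---|---|
| PSSM log-odds | 20 | sequence profile |
| predicted secondary structure (H/E/C) | 3 | sequence profile |
| predicted burial | 1 | sequence profile |
| observed secondary structure one-hot | 3 | hydrogen-bond assignment |
| relative solvent accessibility | 1 | Shrake–Rupley SASA |
| membrane depth + region one-hot | 4 | slab geometry |
| atom–atom contact counts | 13 | 13-class atom typing |
| residue–residue contact counts | 20 | CB–CB contacts by partner type |

Rows are stacked over a symmetric window of 9 sequence positions (the
window size is a package default; the source literature does not pin one),
with zero padding and one padding-indicator column per window position
(594 columns in total). Sequence-derived features are computed once per
target; structural features are recomputed for every decoy.

Cross-validation (`cv_scorer()`) assigns folds by *target*, never splitting
a target's models or residues across folds — the standard anti-leakage
convention for quality-assessment training.

## 2. Structural features

**Solvent accessibility.** Shrake–Rupley sampling: quasi-uniform Fibonacci
points on each heavy atom's probe-inflated sphere (probe 1.4 Å), a point
being accessible when outside every neighbour's inflated sphere. Radii are
Chothia/Naccess-style per element (C 1.87, N 1.65, O 1.40, S 1.85 Å).
Relative accessibility divides residue SASA by Gly-X-Gly maxima (Tien et
al. theoretical values), capped at 1. The exported `shrake_rupley_sasa()`
defaults to 960 points per atom; the feature pipeline uses 240, where total
SASA of a test bundle is converged to well under 0.5% (asserted in the test
suite). SASA is the one feature that is only rotation-invariant up to the
sampling resolution; everything else is exactly invariant under rigid
motion.

**Secondary structure.** Three-state hydrogen-bond assignment in the
Kabsch–Sander style: amide H reconstructed 1 Å from N anti to the preceding
carbonyl, electrostatic bond energy
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, bond when $E < -0.5$. Helix requires two consecutive
$i \to i{+}4$ turns; strand uses the parallel/antiparallel bridge patterns;
everything else (and any residue with missing backbone atoms) is coil.
Three states rather than eight: that is all the feature role needs.

**Contacts.** Atom–atom: heavy atoms of other residues within 4.5 Å of any
atom of the residue, each partner atom counted once, binned into a declared
13-class typing (aliphatic/aromatic/carbonyl/carboxylate carbon;
amide/charged/aromatic nitrogen; carbonyl/carboxylate/hydroxyl oxygen;
sulfur; glycine Cα; other). Residue–residue: CB–CB (CA for glycine) within
8 Å. Both exclude sequence neighbours (same chain, residue-number
difference ≤ 1) and use half-open intervals $[0, \text{cutoff})$. The
original atom typing of this method family is not published in detail; ours
is declared, not claimed identical.

**Membrane geometry.** A flat slab: normal along z, hydrophobic core
|z| < 15 Å, a 6 Å interface shell, water beyond. Models are assumed
pre-oriented; membrane-orientation search is out of scope.

## 3. Side-chain resampling

`repack()` rebuilds side chains on the fixed backbone: every χ-bearing
residue is initialised at the most probable rotamer of its (φ,ψ) bin
(30° bins, backbone-independent fallback at chain termini), then residues
are visited in seeded random order and greedily assigned the
minimum-energy candidate among the bin's rotamers plus the residue's input
conformation, until a sweep changes nothing (cap 10 sweeps). Backbone heavy
atoms are untouched bit-for-bit, so TM-score and any Cα-based measure of
the model are exactly preserved — the point of the protocol.

The packing energy is a *declared simplification*, not a Rosetta
reproduction (explicitly a non-goal):

$$ E = w_{st} \sum_{\text{pairs}} \max(0,\; s\,(r_i + r_j) - d_{ij})^2
     + w_{rot} \sum_{\text{res}} -\ln p_{\text{rotamer}}
     + w_{mem} \sum_{\text{res}} m(\text{region}, \text{type}) $$

with defaults $w_{st} = 1$, $w_{rot} = 1$, $w_{mem} = 0.5$, clash scale
$s = 0.8$; pairs run over heavy atoms of different residues with at least
one side-chain atom; $m$ penalises Kyte–Doolittle-hydrophilic residues in
the membrane core and hydrophobic ones in water (scaled by 4.5, the
hydropathy range). Greedy acceptance makes the per-sweep energy trace
non-increasing, which the tests assert. Side chains are rebuilt with ideal
internal geometry (tabulated bond lengths/angles; measuring χ of a built
side chain returns the input to numerical precision); ring closure for
TRP/HIS is approximate at the far atoms, a known idealisation.

The built-in rotamer library is minimal and declared: dominant rotamers per
type with rounded literature-style frequencies, plus helix-bin entries
(φ, ψ near −60°, −45°) that up-weight the gauche⁻ χ1 rotamer — the dominant
backbone dependence in α-helical membrane proteins. Richer libraries load
from a documented TSV.

`generate_decoys()` produces decoy $i$ with seed `base_seed + i`,
bit-reproducibly. Because the default greedy search is deterministic and
usually converges to the same optimum from any sweep order, the decoys of
one model typically coincide — decoy count then matters only through the
first decoy. This is an honest consequence of preferring a deterministic,
testable packer; a stochastic χ-jitter around rotamer means
(`packing_params(jitter_sd = ...)`) is available when genuine decoy
diversity is wanted, and was measured at desk scale to add score noise
without improving selection.

## 4. The selection protocol and its evaluation

`resample_and_score()` scores the original model and each of its $n = 10$
repacked decoys (10 matching the saturation point of the source method's
published selection curve), and assigns the model the **maximum** over all
these scores; `rank_models()` sorts descending with lexicographic
tie-breaks. The combiner is a declared design choice: the maximum matches
the rationale of rescuing good backbones with poor packing and is monotone
non-decreasing in $n$ for a fixed seed prefix (asserted); the mean is
available behind a flag. Evaluation uses per-target Z-scores of the
first-ranked model's true TM-score (population standard deviation, no
trimming, Z = 0 for zero spread), summed over targets;
`consensus_score()` provides the Pcons-style baseline (mean pairwise
TM-score against all other models, the evaluated model as reference — note
the documented pathology that duplicated models inflate each other).
`run_benchmark()` ties it together and also reports pooled χ1/χ2-within-40°
side-chain correctness before resampling and for each model's best-scoring
decoy after, with targets partitioned by whether resampled selection picked
a higher-TM model than no-resample selection.

Two χ conventions worth noting: the correctness metric pools χ1 and χ2
counts over all comparable residues (a per-residue-averaged variant is an
option), and 180°-symmetric terminal groups (ASP/PHE/TYR χ2, GLU χ3) are
compared modulo 180°. The threshold is strict (< 40°).

## 5. Synthetic study conditions

Nothing in the package downloads data; the benchmark is generated.
`make_helix_bundle()` builds idealised α-helical bundles (φ = −57°,
ψ = −47°) on a circle, alternating up/down across a 30 Å membrane slab,
joined by schematic loops (loop realism is explicitly secondary — the
backbone path is interpolated with peptide-like bonds, not
physically minimised). The default study conditions, chosen once:

* targets: 3 helices × 14 residues (~46–50 residues with loops) — large
  enough for a hydrophobic core and windowed features, small enough that
  the full protocol runs in minutes on one CPU;
* decoys per target: backbone perturbations over the magnitude grid
  {0.5, 1, 2, 4, 8} Å (smooth low-frequency displacement fields, C–N bonds
  clamped to [1.2, 1.8] Å), each decoy's side chains additionally scrambled
  on a uniformly drawn fraction in [0.3, 1];
* profiles: PSSM as blurred one-hot log-odds, predicted secondary structure
  mixed with uniform, predicted burial as noised true accessibility,
  topology from true membrane depth — noise level 0.3;
* benchmark: 5 targets × 20 models; scorer trained on a disjoint 3 × 6 set,
  models as they come (the faithful analog of retraining on an ordinary
  model set), ridge penalty 10.

Every artifact is bit-reproducible from its seed, and within each target
the decoys are guaranteed to span ≥ 0.2 in both TM-score and χ-correctness
(regenerated with a derived seed otherwise, bounded retries).

What this emulates: graded backbone quality, poor side-chain packing, noisy
sequence profiles. What it does **not** emulate: real modeling pipelines'
*correlated* errors (here side-chain degradation is drawn independently of
backbone quality), β-barrels, realistic loops, hard decoy sets where
single-model scoring is weak.

## 6. What the desk-scale results show — and what they do not

On these conditions the package reproduces the mechanism of the source
method where the mechanism is local: repacking improves pooled χ1/χ2
correctness from ≈ 49% to ≈ 66%, and 80–100% of models improve
(`scripts/acceptance.R` prints the exact numbers for its seed) — the
desk-scale analog of the published side-chain improvement. The scorer's
global prediction correlates with true TM-score at $r \approx 0.9$.

The *selection* gain from resampling, however, is marginal here: resampled
and plain sum-Z typically differ by less than the between-seed spread, with
either sign. The reason is visible in the diagnostics above: our synthetic
scorer is already strongly backbone-informed ($r \approx 0.9$ versus the
original method's published $r \approx 0.6$ regime), and because side-chain
damage is independent of backbone quality by construction, it contributes
little systematic confounding for resampling to remove. The package's
directional test therefore asserts the weak form — resampled selection not
worse than plain selection across seeded replicates of the resampling —
and this vignette, not the test suite, is where the stronger published
effect size is discussed. Reproducing that effect would need decoy sets
whose side-chain quality is uniformly poor and whose scorer is
feature-noise-limited, i.e. the regime of the original external benchmark.

## 7. Numerical choices and degenerate inputs

* TM-score search: seed windows of lengths L, L/2, L/4 (min 4), offsets at
  stride max(1, L/20), inclusion cutoff 8 Å shrinking to max(d0, 3.5) Å,
  20-iteration cap per seed; the heuristic is asserted never to fall below
  the single all-residue superposition score. d0 floored at 0.5 Å for short
  chains.
* Kabsch superposition excludes reflections (determinant-corrected SVD);
  fewer than 3 points is an error.
* Dihedrals follow the IUPAC sign convention; degenerate (collinear or
  coincident) geometry errors out in `dihedral()` but is represented as NA
  where absence is meaningful (missing atoms, chain termini).
* Circular differences are taken modulo 360 into [0, 180]; zero-variance
  Z-scores are defined as 0; ties in ranking go to the lexicographically
  smallest model id — all chosen so that every code path is deterministic.
* Residues missing backbone atoms are labelled coil, excluded from
  repacking, and reported by `validate_model()`; unknown residue types are
  dropped at parse time with a warning; alternate locations resolve to the
  highest-occupancy copy; hydrogens are parsed but excluded from all
  features and energies.
* All randomness flows through explicit integer seeds (`with_seed`
  internally restores the RNG state), so every CLI command and every
  generator call is byte-reproducible.

## 8. Known limitations

Schematic loop geometry; minimal rotamer library (sufficient for the
protocol's claims, far coarser than a full backbone-dependent library);
simplified packing energy; no membrane-orientation search; no
sequence-alignment-based residue correspondence (numbering only); the
consensus baseline inherits the usual duplicated-model pathology; and the
selection-gain caveat of Section 6.
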