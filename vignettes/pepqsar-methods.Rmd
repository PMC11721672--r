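---
title: "Methods: potency decomposition, interface descriptors and stepwise QSAR"
author: "pepqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: potency decomposition, interface descriptors and stepwise QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter and why their defaults
were chosen, what the synthetic generators do and do not emulate, and the
numerical and design decisions taken where the problem left the design open.

## 1. The peptide series and the potency scale

The package analyses an 11-residue GLP-1 receptor agonist scaffold,
H-His¹-Aib-Glu-Gly-Thr-Phe(2-F)⁶-Thr-Ser-Asp-Bip-Bip¹¹-NH₂, together with
its Ala-scan, Aib-scan and Phe⁶-modification series. Potency is the
agonist concentration producing half-maximal cAMP response (EC50, nM);
analysis is done on pEC50 = −log₁₀ EC50[M] = 9 − log₁₀ EC50[nM], so 1 nM is
9.0 and 0.1 nM is 10.0. Right-censored measurements (EC50 out of assay
range, ">1000 nM") carry no finite EC50.

The packaged tables store the printed per-peptide pEC50 where the source
reported one, and that printed value is authoritative for analysis: for
several peptides it disagrees with the (rounded, separately assayed) EC50
column by more than printing precision, so recomputing pEC50 from EC50
would not reproduce the published decomposition. `validate_peptides()`
reports the disagreements rather than erroring on them; strict mode is
available for user-supplied tables.

### The Cα-methylation decomposition

Replacing a residue's Cα-hydrogen with a methyl group (Ala → Aib,
Phe-type → α-Me-Phe-type) biases the backbone toward helicity. The two
scan parents differ only by Cα-methylation of the position-6 side chain, so
their pEC50 difference (10.89 − 9.92 = 0.97 log units) isolates that
contribution and serves as the reference constant. At every other position

$$\mathrm{dpEC_{50}}(i) = \mathrm{pEC_{50}}(\mathrm{Aib}\,i) -
  \mathrm{pEC_{50}}(\mathrm{Ala}\,i) - 0.97 .$$

`build_methylation_table()` recomputes the constant from the parent pair
and applies it uniformly. Two table positions (1 and 9) reproduce the
printed value only to ±0.01 because the published table was evidently
computed from unrounded inputs; all other positions agree exactly.

## 2. Interface descriptors

`descriptor_vector()` maps a receptor–peptide complex (standard PDB,
peptide identified by chain) to 26 descriptors. The interaction criteria
and internal score formulas of the original modeling environment are
proprietary, so this package implements documented surrogate criteria with
every threshold exposed in `energy_model_params()`. Because any downstream
regression re-fits weights per descriptor, consistency across peptides is
what matters, not agreement with any particular program's absolute values —
which also means previously published absolute model statistics computed
with other engines are not expected to be bit-reproduced.

### Geometric detectors

All detectors consider only cross-interface participants and are exhaustive
over pairs (no spatial indexing — complexes of interest are small).

| interaction | criterion | energy constant |
|---|---|---|
| hydrogen bond | d(H⋯A) ≤ 2.5 Å and ∠D–H⋯A ≥ 120°; without hydrogens, d(D⋯A) ≤ 3.5 Å | 8 kJ/mol |
| hydrophobic | apolar, non-aromatic C⋯C ≤ 5.0 Å | 2 kJ/mol |
| cation–π | cation center to ring centroid ≤ 6.0 Å, ≤ 45° off the ring normal | 8 kJ/mol |
| π–π | stacked: centroids ≤ 5.5 Å, normals ≤ 30°; T-shaped: ≤ 7.0 Å, 60–90° | 6 kJ/mol |
| ion–ion | opposite-sign group centers ≤ 6.0 Å | 12 kJ/mol |

Each energy is the (negative) constant scaled by distance/angle ramps in
[0, 1] and capped at 0. Aromatic-ring carbons are excluded from the
hydrophobic detector so that the five interaction classes are disjoint
(stacked rings would otherwise double-count as dozens of hydrophobic
contacts). `InteractionCount` and `InteractionEnergy` are exact sums of the
five counts and five energies.

Donors, acceptors, partial charges, aromatic rings and ionized groups come
from a per-residue template registry covering the canonical residues plus
the noncanonical ones of this scaffold (Aib; biphenylalanine Bip;
ring-fluorinated Phe, which also extends the element set with F, radius
1.30 Å). `register_residue_template()` lets users add further residues.
Charges are a fixed template: unit formal charges on ionized groups and
small polar offsets on N/O/polar-H (not fitted charges) — sufficient for a
consistent, deterministic electrostatic signal.

### Energetics and solvation

Cross-interface electrostatics use Coulomb's law with the solute dielectric
(1) and a generic per-element Lennard-Jones table (Lorentz–Berthelot
combining). All nonbonded and solvation pair terms are smoothly switched
off between 10 and 12 Å; separability is exact — a complex whose halves are
beyond the cutoff has all eight binding terms identically zero.

The polar solvation term is a generalized-Born screening between
dielectrics 1 and 78 using the documented solute radii (polar H 0.32,
other H 1.017, C 1.8, O 1.344, N 1.14, S 2.0 Å; probe 1.4 Å) as effective
Born radii, which makes the isolated-ion Born limit exact. The nonpolar
(vdw-solvation) term is 0.010 kJ/mol/Å² times total solvent-accessible
surface area; the hydrophobic term is a surface tension of
0.0227 kJ/mol/Å² times the apolar SASA. SASA itself is Shrake–Rupley
quadrature with a deterministic 242-point spiral per atom.

Two numerical choices deserve note. First, the quadrature is evaluated in
the principal-axis frame of the coordinates (axis signs fixed by third
moments, right-handed), so all SASA-derived quantities are invariant under
rigid motion of the input rather than only up to quadrature error; exactly
or near-degenerate principal axes are the residual caveat, though collinear
and planar configurations remain exact. Second, `binding_terms()` evaluates
the complex and its frozen receptor/peptide parts in one shared frame, so
the binding differences cancel exactly for separated halves. The
decomposition identities `BEpot = BEelec + BEvdw`, `BS = BSelec + BSvdw`
and `BE = BEpot − BS − BShydro` hold exactly by construction.

### Packing and model-quality surrogates

`Pack3D` is the summed contact energy (−1 kJ/mol per heavy-atom pair ≤
4.5 Å between distinct residues): more packing, more negative, matching the
"lower is better" convention. `Pack1D` restricts to sequence-local pairs
(residue separation 1–2 within a chain) plus all cross-chain pairs —
sequence separation is undefined across chains, and counting cross pairs
as local makes `BindPack1D` the (negated) interface contact energy rather
than an identical zero. `MQ` is unitless contact density penalised by clash
(< 2.2 Å) density. Each score is computed for the complex and the frozen
parts; `Bind* = Comp* − Receptor* − Peptide*`.

## 3. The QSAR engine

`qsar_mlr()` is ordinary least squares with the complete validation ladder
attached to the fitted object:

* R², adjusted R², overall F-test and per-term t-tests;
* variance inflation factors, VIFⱼ = 1/(1 − Rⱼ²);
* AIC = n·ln(RSS/n) + 2k with k counting the intercept and slopes (the
  error variance is not counted; the convention is recorded on the object
  as `aic_convention`), and AICc = AIC + 2k(k+1)/(n−k−1);
* leave-one-out Q² = 1 − PRESS/TSS with TSS about the full-sample mean,
  computed through the hat-matrix identity (the explicit n-refit route is
  available and agrees to numerical precision).

`stepwise_qsar()` is forward selection with backward elimination on
partial-F (added-term t-test) p-values at α = 0.05; candidates tying are
resolved by the canonical descriptor-name order, so the result is
deterministic and independent of candidate-list order. The α = 0.05 default
follows the methods-level prescription; a conflicting 0.5 appears in some
narrative text, but 0.5 would admit nearly every term and contradicts the
one- and two-term models actually reported, so it is only available as an
explicit argument.

**Operating characteristics, honestly stated.** With 26 candidates and
per-term entry at α = 0.05, the chance that at least one null candidate
clears entry is ≈ 1 − 0.95²⁴ ≈ 0.7 at n = 31. The property tests measure
exactly that: both planted terms are recovered in well over 80% of seeded
replicates, but at least one spurious term rides along in the majority of
them. Stepwise screening over 26 descriptors at this sample size is a
hypothesis-generating device; the selection protocols below, not the raw
stepwise output, are the model-choice mechanism.

`y_randomize()` permutes the response (seeded), refits the *fixed* selected
term set each trial (a fresh per-trial stepwise is available behind
`reselect = TRUE`; refitting fixed terms is the variant consistent with
reporting per-model averages), and summarises mean random R²/Q² and
cRp² = √(R²·(R² − mean R²ᵣₐₙd)), clipped at 0. The permutation-null mean R²
is k/(n−1), which the tests verify.

### Model selection

Two protocols are provided. The bounded protocol labels a candidate
underfit/pass/overfit by its adjusted R² against a window whose lower edge
is the single-term binding-energy reference model (0.37 for the study data)
and whose upper edge is the agreement between two independent experimental
assays on the same biology (0.62) — a computational model should not
out-predict experimental repeatability; it additionally flags p(F) ≤ 0.05,
all p(t) ≤ 0.05, all VIF < 5 and Q² above the reference margin (0.24), and
ranks passes by adjusted R². The algorithmic protocol sorts candidates by
AICc and returns the first whose terms pass a physical-interpretability
gate supplied by the analyst.

## 4. Validation splits and external prediction

Three deterministic constructions on (id, pEC50) records, all sorted
ascending with ties broken lexicographically by id (the data contain
duplicate pEC50 values, so determinism requires a rule):

* **alternating**: sorted positions 1, 3, 5, … train; 2, 4, 6, … test
  (odd n puts the extra record in training: 31 → 16/15);
* **every fifth**: members 1–4 of each sorted group of five train, member 5
  test, trailing partial group to training (31 → 25/6);
* **potency-ranked**: the least potent round(f·n) records train (f = 0.6 or
  0.8), the most potent remainder test — a deliberate extrapolation
  challenge.

`assess_predictions()` reports R²_pred = 1 − SSE/SS(obs about the training
mean) — the definition that can go negative when predictions are worse
than the training-mean baseline — RMSE_pred, the least-squares line of
predicted versus observed with and without intercept, and the mean shift.

## 5. Synthetic data: what it emulates, what it does not

`gen_descriptor_table()` emulates the statistical structure the regression
assumes: standard-normal descriptors (optionally mixed to block
equicorrelation by Cholesky; infeasible blocks are rejected), a sparse
linear signal and homoscedastic Gaussian noise. Defaults mirror the study
regime — n = 31, p = 26, two true terms, noise sized for a population R² of
0.6 — so that the engine's property tests operate where the analysis
actually lives. It does not emulate the heavy-tailed, mutually dependent
distributions of real physics-based descriptors.

`gen_toy_complex()` realises each requested interaction as a minimal atom
group in its own spatial cluster (25 Å apart, beyond every cutoff), each
satisfying its detector criterion with ≥ 10% margin, with decoy atoms
violating every criterion by a margin. These are geometric unit fixtures,
not conformers: passing tests demonstrate detector and bookkeeping
correctness, not force-field realism.

`gen_scan_dataset()` builds parent/Ala/Aib records with additive
per-position effects, a constant methylation contribution and optional
Gaussian noise — by construction, the decomposition recovers the planted
Aib−Ala gaps exactly at zero noise.

All generators are bit-reproducible under a fixed seed.

## 6. Numerical choices and degenerate inputs

* Nonbonded/solvation switch 10 → 12 Å (cubic); clash guard errors below
  0.1 Å separation.
* Ring planarity enforced at load (max out-of-plane deviation 0.3 Å);
  partial residues simply contribute no ring/charged group.
* Censored potencies are excluded from conversion; conversion of a censored
  or non-positive EC50 is an error naming the record.
* Intercept-only models are legal stepwise outcomes (R² = 0, p(F)
  undefined); rank-deficient designs error naming the collinear terms;
  zero-variance candidates are skipped during selection.
* AICc is undefined (error) for n ≤ k + 1.
* Property-test problem sizes were chosen to mirror the study scale
  (n = 31, p = 26; 100–200 seeded replicates for the stochastic
  calibrations; toy complexes of tens of atoms), keeping the full suite
  in the tens of seconds.

## 7. Known limitations

* The interaction criteria, packing scores and charge model are documented
  surrogates; published absolute statistics obtained with proprietary
  engines and unpublished descriptor values are out of reach by design.
  The training-set membership of the 31-peptide study set is itself partly
  inferred (the published tables do not mark the excluded Phe⁶ analogs),
  so the packaged `in_training_31` flag reflects a documented
  reconstruction: all scan analogs, the three parents and the seven
  singly-substituted Phe⁶ analogs with replicated assays.
* Stepwise screening at α = 0.05 over 26 candidates admits spurious terms
  in most replicates at n = 31 (see §3); use the selection protocols and
  Y-randomization rather than trusting a single stepwise pass.
* The generalized-Born surrogate uses intrinsic radii as effective Born
  radii; it is exact in the isolated-ion limit but does not capture
  descreening in deeply buried interiors.
* SASA-derived descriptors are rotation-invariant through principal-axis
  canonicalisation; structures with exactly degenerate, non-collinear,
  non-planar inertia tensors may show quadrature-level frame sensitivity.
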