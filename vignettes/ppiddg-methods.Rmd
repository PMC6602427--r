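---
title: "Predicting binding-affinity changes at protein-protein interfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binding-affinity changes at protein-protein interfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiddg)
```

## The problem

Missense mutations at protein-protein interfaces can strengthen or weaken
complex formation, with consequences ranging from disease to drug
resistance.  The experimentally measurable quantity is the change in
binding free energy,

$$\Delta\Delta G = \Delta G_{\mathrm{wild\text{-}type}} - \Delta G_{\mathrm{mutant}},
\qquad \Delta G = R\,T\,\ln K_D,$$

with $R = 1.985\times10^{-3}$ kcal K$^{-1}$ mol$^{-1}$ and $K_D$ the
dissociation constant in molar.  Under this sign convention a mutation
that weakens binding ($K_D$ grows, $\Delta G_{\mathrm{mutant}}$ less
negative) has a *negative* $\Delta\Delta G$.  Several public resources use
the opposite sign; `predict_ddg(..., sign_convention = "skempi")` flips
the reported scale and warns.

`ppiddg` predicts $\Delta\Delta G$ for single-point mutations from the 3D
structure of the complex, using a supervised regressor over a structured
feature vector.  It also scores whole interfaces by alanine scanning or
saturation mutagenesis, and ships the statistics used to validate such
predictors (redundancy-aware cross-validation, correlation-comparison
tests, hotspot classification).

## Feature families

All features are computed on the **wild-type** structure; the mutant
enters only through a deterministic side-chain model used for
contact-count differences, and through residue-identity terms.

**Graph-based structural signature.**  The environment of the mutated
residue is the set of heavy atoms (any chain) within `radius` (default
10 Å) of the geometric center of the residue's heavy atoms.  Each atom
carries one or more of eight pharmacophore classes (hydrophobic,
aromatic, donor, acceptor, positive, negative, sulfur, neutral) assigned
by a shipped residue/atom lookup table
(`inst/extdata/pharmacophores.csv`).  For every unordered atom pair and
every distinct unordered class pair carried by the two atoms, the count
at the smallest cutoff of an ascending ladder (default 1.0–10.0 Å in
0.5 Å steps) covering the pair distance is incremented; a cumulative sum
along the ladder turns the counts into discrete cumulative distribution
functions.  Flattened, this yields $36 \times 19 = 684$ integer slots.
The radius and ladder are not sharp physical constants; both are exposed
in `feature_config()`.  Pairs internal to the mutated residue itself are
included by default (the residue is part of its own environment); a flag
excludes them.

**Residue environment.**  Relative solvent accessibility (Shrake–Rupley
SASA over the full complex divided by the theoretical maximum ASA of the
amino acid, Tien et al. 2013 values), the backbone $\phi$ torsion, residue
depth, and the 20-slot amino-acid composition of the mutated chain.
Values above RSA 1 can occur for termini and are left uncapped.  Residue
depth is defined here as the mean distance from the residue's heavy atoms
to the nearest *solvent-exposed atom center* (an atom with non-zero
SASA); this avoids an external molecular-surface binary while correlating
with the classical surface-distance definition.  $\phi$ is undefined at
chain starts; because `NA` is reserved for absent optional blocks, the
feature vector encodes this as `phi = 0` with a `phi_defined` indicator.

**Residue identity flags.**  Four binaries: mutation from/to glycine and
from/to proline, the two residues with exceptional backbone behaviour.

**Non-covalent interaction network.**  Contacts are typed by a distance
rule table (`contact_params()`): covalent if $d \le r_{cov,a} + r_{cov,b}
+ 0.4$ Å; hydrogen bond if one donor-capable and one acceptor-capable
heavy atom lie within 3.9 Å (no angle term — hydrogens are not required);
van der Waals if $d \le r_{vdw,a} + r_{vdw,b} + 0.5$ Å and not covalent;
aromatic as one contact per pair of *distinct* rings whose centroids are
within 5.0 Å (atom pairs inside a single ring are not contacts — a
contact relates two moieties).  Two feature sets derive from this: (i)
the per-kind difference between wild-type and mutant contact counts at
the mutated residue, the mutant being modelled by grafting an
ideal-geometry side-chain template onto the unchanged backbone
(N–CA–C frame superposition; glycine targets need no CB); and (ii)
complex-network metrics of the contact graph of the closest interface —
mean normalised closeness, Freeman central-point dominance and the graph
center cardinality, computed on the largest connected component.
A residue belongs to an interface when any of its heavy atoms is at most
5 Å (inclusive) from another chain.

**Evolutionary information.**  PSSM log-odds of the wild-type and mutant
residues at the mutated position, plus their difference.  PSSMs are
consumed as PSI-BLAST ASCII files (`read_pssm()`); the package never runs
PSI-BLAST.  For testing without a sequence database,
`pssm_from_alignment()` builds log-odds scores from a user-supplied
alignment.  This block is optional: absent means absent, never zero.

**Contact potentials.**  Symmetric lookups of the (wild-type, mutant)
cell in three 20×20 residue contact-potential matrices in AAindex matrix
format.  The shipped defaults are *synthetic substitutes* (deterministic,
clearly labelled in their filenames); real AAindex entries can be dropped
in as files without code changes.

**Energetic terms.**  An adapter reads the inter-chain interaction energy
and a predicted folding free-energy change from FoldX-style tables.  With
no files supplied the block is explicitly absent; training and prediction
work either way, and the model schema records which blocks were active.

**Atomic fluctuations.**  Elastic-network models of the mutated chain's
CA trace: the `calpha` force field (Hinsen distance-dependent springs,
$k = 8.6\times10^2 r - 2.39\times10^3$ below 4 Å and $128\times10^4
r^{-6}$ above, $r$ floored at 2.9 Å, pairs enumerated within 15 Å) and
the parameter-free `pfanm` field ($k \propto 1/d^2$, all pairs).
Fluctuations are the diagonal of the Hessian pseudo-inverse, obtained by
eigen-decomposition after discarding exactly six near-zero rigid-body
modes (tolerance $10^{-8}$ of the largest eigenvalue; any other count is
a hard error because it signals degenerate geometry).  Four slots enter
the vector: the mutated residue's own fluctuation and the chain mean,
per force field.

## The regressor

`train_model()` fits an extremely-randomised-trees regression forest
(via `ranger`): 500 trees, random single-threshold splits, and — the
classical Extra-Trees choice for regression — all predictors considered
at every split.  Training is deterministic given a seed, persists with
`save_model()`/`load_model()` to bit-identical predictions, and refuses
feature rows whose slot schema differs from the training schema
(including the set of absent optional blocks).  Columns of absent blocks
are excluded from the design matrix and recorded, so a model trained
without PSSMs happily scores structures without PSSMs, and loudly refuses
anything inconsistent.

## Dataset construction

`parse_skempi()` reads semicolon-separated affinity tables in the
SKEMPI 2.0 dialect.  Multi-point mutation rows are dropped; per-row
$\Delta\Delta G$ is computed from the wild-type and mutant $K_D$ at the
row's recorded temperature (298.15 K when missing); replicated
measurements of one variant are averaged when their spread is strictly
below 2.0 kcal/mol and the variant is discarded otherwise.
`augment_reverse()` adds the hypothetical reverse mutation for every
record with the negated $\Delta\Delta G$ — free energy is a state
function, so the mutant→wild-type change is exactly the negative of the
forward one — doubling the data and balancing the strong
destabilising/stabilising asymmetry of curated sets.

Three split generators mirror the validation designs used for such
predictors:

* `split_stratified_paired()` — repeated stratified k-fold in which
  forward/reverse twins are always co-assigned (otherwise the reverse of
  a training mutation sits in the test set — leakage by antisymmetry) and
  strata are the sign of the forward $\Delta\Delta G$ (records at exactly
  0 count as increased binding).  Fold sizes stay within one pair.
* `split_leave_one_complex_out()` — one test group per complex.
* `split_leave_one_binding_site_out()` — one group per binding site;
  when no curated site annotation exists the fallback identifier is
  pdb + chain + position.

## Evaluation statistics

`regression_metrics()` reports Pearson $r$, tie-corrected Kendall
$\tau_b$ and RMSE.  `fisher_r_to_z_test()` compares two independent
correlations through $z = (\operatorname{atanh} r_1 - \operatorname{atanh}
r_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ (two-tailed).  Comparing a rank
correlation against a Pearson correlation first maps $\tau$ through
Greiner's relation, $r = \sin(\pi\tau/2)$ (`tau_to_r()`).
`hotspot_metrics()` binarises predictions and observations at a
destabilisation threshold (default 2 kcal/mol, the conventional hotspot
cut) and reports per-class precision and recall.

## Synthetic test-beds and what they do (and do not) show

`make_toy_complex()` builds two ideal poly-alanine α-helices with a
controllable minimal inter-chain heavy-atom distance (solved numerically
to the requested gap) plus a small seeded coordinate jitter, and optional
residue substitutions.  Helical chains were chosen because an extended
strand's CA trace is nearly collinear, which degenerates the elastic
network.  `simulate_feature_table()` plants a known linear function of
five binary flag-like slots among Gaussian nuisance slots, optionally in
antisymmetric forward/reverse pairs, with noise of known standard
deviation (default 0.1 kcal/mol on the target scale).

These fixtures validate the machinery: exactness of the signature
computation against brute force, interface detection at the inclusive
boundary, split hygiene, recovery of a planted signal (held-out Pearson
≥ 0.9, RMSE near the noise floor), and the antisymmetry benefit of
reverse augmentation.  They deliberately do **not** demonstrate accuracy
on real complexes: toy helices lack packing diversity, waters, cofactors
and crystallographic noise, and the planted-function study says nothing
about how informative real features are for real $\Delta\Delta G$.
Reproducing benchmark-scale correlations requires the curated public
affinity data with its hundreds of PDB structures and sequence profiles,
which this package consumes through the same interfaces
(`parse_skempi()`, `read_structure()`, `read_pssm()`) but does not
download.

The shipped 12-row affinity fixture is hand-built to exercise every
curation rule (replicate averaging, spread-based discard, multi-point
filtering, temperature fallback); its counts are asserted row-exactly in
the tests.  Problem sizes throughout the suite (toy chains of 4–10
residues, 500-row simulations, 10 recovery seeds) were chosen as the
smallest sizes at which the checked properties are non-trivial.

## Numerical choices and edge cases

* Altloc handling keeps the highest-occupancy conformer (ties → `"A"`);
  hetero residues and waters are dropped at parse time; hydrogens are
  kept if present but ignored by heavy-atom computations.
* All distance cutoffs are inclusive; the interface comparison carries a
  $10^{-6}$ Å$^2$ slack so an exactly-at-cutoff boundary is stable
  against floating-point noise.
* Shrake–Rupley test directions are expressed in a principal-axes frame
  of the structure and the point set is symmetric under coordinate-sign
  flips, so SASA (hence RSA and depth) is exactly invariant under
  rigid-body motion rather than approximately so.
* Ideal side-chain templates (20 residues, heavy atoms) ship as a plain
  CSV of ideal coordinates; grafting uses the backbone N–CA–C frame, so
  glycine targets need no CB construction.  Identity mutations return
  the input structure unchanged.
* `dg_from_kd` rejects non-positive $K_D$; `aggregate_replicates` reads
  "varied by less than 2.0" strictly, so a spread of exactly 2.0
  discards.
* Tie-breaks: the closest interface resolves ties lexicographically by
  chain pair; altloc ties resolve to `"A"`.

## Known limitations

* The mutant side chain is an idealised template in its template
  conformation — no rotamer search, no backbone relaxation.  A hook
  accepts externally modelled mutant structures
  (`contact_delta(..., mutant = )`).
* Hydrogen-bond detection is distance-only, trading angular precision
  for independence from hydrogen placement.
* The shipped contact-potential tables are synthetic placeholders;
  quantitative use should substitute real AAindex entries.
* No network access anywhere in the core: structures, PSSMs and energy
  tables are files the caller provides.
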