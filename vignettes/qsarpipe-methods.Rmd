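---
title: "Methods: curation, descriptors and cost-sensitive substrate classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, descriptors and cost-sensitive substrate classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

ABCC2 (MRP2) is an ATP-binding-cassette efflux transporter of the hepatocyte
canalicular membrane.  Candidate substrates can be postulated at scale by
correlating, across a tumor cell-line panel, each compound's cytotoxicity
profile with the transporter's mRNA expression: a compound whose toxicity
falls where the transporter is highly expressed behaves as if it were being
pumped out.  The resulting label is operational -- a Pearson correlation
coefficient (PCC) per compound, thresholded at -0.25 or -0.30 (a compound
with PCC less than or equal to the threshold is called a substrate, the
boundary inclusive) -- and it is both noisy and strongly imbalanced: at
-0.25 roughly 13% of a curated library qualifies.

`qsarpipe` implements the full workflow from raw structure files to an
evaluated classifier: structure curation, 2D descriptor computation, three
train/test selection strategies, correlation-based feature selection,
cost-sensitive learning with bagging, imbalance-aware evaluation, and a PCA
applicability domain.  Because the original inputs (an NCI structure
archive joined to a published compound list) are external downloads, the
package ships a synthetic-library generator that emulates them with a known
generative signal, so that every stage -- and the pipeline end to end -- is
testable offline.

# Curation

`run_curation()` applies seven steps in a fixed order: (1) remove records
without a carbon atom; (2) resolve multi-component records, keeping a
record only when exactly one component contains carbon (that component
becomes the structure, stripping counter-ions such as hydrochlorides;
records with two or more organic components are deleted because the active
component is unknowable); (3) remove records containing metal atoms (the
metal list covers alkali through post-transition metals, lanthanides and
actinides); (4) remove records with elements outside the descriptor
parameterization (`H B C N O F Si P S Cl Br I`; selenium, tellurium,
arsenic and the like fall here); (5) standardize chemotypes; (6) remove
duplicate structures -- groups whose PCC values disagree by more than a
tolerance (default `1e-6`, i.e. exact after float parsing) are deleted
outright, otherwise one entry is kept; (7) remove records whose net formal
charge is non-zero.  Every step logs the removed ids with reasons, and the
report satisfies count conservation by construction.

Step order matters and is tested: a sodium carboxylate salt survives the
metal filter because step 2 strips the counter-ion first.

**Standardization details.**  Stereochemistry is cleared by construction:
the connection-table parser reads neither wedge flags nor parities, which
is appropriate for an archive whose stereo annotations are unreliable, and
only 2D descriptors are computed downstream.  Nitro and azide groups are
normalized to their charge-separated depictions.  Neutralization
protonates anions and deprotonates protic cations, but only while this
moves the net charge toward zero, so internally balanced zwitterions
(betaines, N-oxides) are preserved; non-neutralizable ions (quaternary
ammonium) survive to step 7 and are then removed, while zwitterions with
net charge zero are retained, mirroring a rule stated on the net charge
only.  Duplicate identity is the standard InChI: its mobile-hydrogen layer
canonicalizes heteroatom-H tautomers (imidazole-type), which is the
pinned, published canonicalization this package uses in place of a
proprietary tautomer scorer.  Carbon-bound (keto-enol) tautomers are not
merged; this is a documented limitation.

**Protonation variant.**  `assign_charge_states()` (curation's `"charged"`
variant) deprotonates strong acid groups -- carboxylic, sulfonic, sulfinic,
sulfate, phosphonic/phosphate, one hydroxyl per acid center (first
ionization) -- and protonates basic nitrogens: aliphatic amines with no
aromatic neighbor and no adjacent multiple-bonded heteroatom (excluding
amides and anilines), plus the imine nitrogen of amidines and guanidines.
All rules are explicit graph predicates in the source, not an external
SMARTS dictionary.

# Descriptors

All descriptors are connection-table based; hydrogens are expanded
internally so every atom carries a partial charge and a surface area.

* **Per-atom surface area.**  The exposed area of an atom's van der Waals
  sphere (Bondi radii) minus the spherical caps buried in each bonded
  neighbor, with ideal bond lengths from single-bond covalent radii
  shortened by 0.20/0.34/0.15 Å for double/triple/aromatic bonds and
  clamped so spheres neither detach nor swallow one another.  This is the
  standard connection-table approximation used by subdivided
  surface-area descriptor families; absolute parity with any particular
  commercial implementation is explicitly not a goal, and no test asserts
  it.  Conservation (bins summing to the total area) is asserted instead.
* **PEOE partial charges.**  Gasteiger-Marsili partial equalization of
  orbital electronegativities, 6 damped iterations (damping factor
  2^-n; the scheme is converged at that depth), seeded from formal
  charges, using the published 1980 electronegativity polynomials plus the
  phosphorus extension; boron and silicon fall back to sp3-carbon
  parameters (they are rare survivors of curation).  `PEOE_VSA+k` sums
  atom areas over the half-open charge bins `[0.05k, 0.05(k+1))`;
  `PEOE_VSA_FNEG`/`FPOS` are area fractions with strictly negative /
  strictly positive charge (zero-charge atoms belong to neither);
  `PEOE_VSA_POS` uses charge > 0 and `PEOE_VSA_PPOS` charge > +0.2.
* **Wildman-Crippen contributions.**  The published atom typing for
  atomic logP and molar-refractivity contributions is encoded as ordered
  graph predicates (first match wins, exactly as the published table is
  read).  `SlogP_VSA0` sums areas over atoms with logP contribution
  <= -0.40, `SlogP_VSA1` over (-0.40, -0.20].  The `SMR_VSA` bins are
  printed in the source material with impossible negative bounds
  ("(-0.11, -0.26]"); since the molar-refractivity contributions of the
  atoms concerned are positive, these are read as the conventional
  positive half-open intervals [0.11, 0.26), [0.26, 0.35), [0.39, 0.44).
  The implementation was cross-checked atom by atom against an
  independent open implementation of the same published tables on a
  17-molecule panel (exact agreement; the values are frozen in the test
  suite as oracle constants).
* **TPSA.**  The classic N/O fragment-contribution parameterization (a
  phenol hydroxyl contributes 20.23 Å^2); sulfur and phosphorus
  contributions are not included.
* **Pharmacophore-style counts and areas.**  `a_don` counts N/O atoms
  bearing hydrogen.  `vsa_base` counts basic nitrogens under the same
  rules as the protonation variant (the descriptor is a count, following
  the printed description).  `vsa_don` sums the areas of *pure donor*
  atoms -- N/O bearing hydrogen that are neither strong-acid hydroxyls nor
  basic nitrogens -- together with their attached hydrogens.  `vsa_other`
  sums areas of atoms outside the donor/acceptor/acid/base/hydrophobe
  typing: S, P, Si, B.  These typings are deliberately explicit and fixed
  in the source, because no public definition of the original
  pharmacophore typing exists.
* **MACCS keys.**  The public 166-key set, computed through OpenBabel's
  implementation; Tanimoto similarity is |A∩B|/|A∪B| with the two-empty
  convention of 1.

The core panel (`panel = "core"`) has 25 descriptors; the extended panel
adds 35 more natively defined counts and bins.  The original study's full
93-descriptor panel is not recoverable from its exclusion lists, so only
the core panel is treated as authoritative.

Z-scoring uses the population standard deviation; constant columns become
zeros and are flagged, and the fitted parameters are stored so external
compounds are always transformed with training parameters.

# Splitting

Three strategies, as in the source protocol: greedy MaxMin diversity in
MACCS space (distance = 1 - Tanimoto), MaxMin in descriptor space
(continuous Tanimoto on z-scored descriptors rescaled to [0, 1];
Euclidean available), and stratified random selection.  Diverse splits
take `ceiling(fraction * N)` training compounds (963.2 -> 964 on a
1204-compound library) deterministically -- the seed is the first member of
the most distant pair, ties broken by input order -- and ignore class
labels, which is why diverse test sets have uncontrolled class ratios.
Stratified random splits take `floor(fraction * class size)` per class
(154 substrates at 0.8 -> 123), reproducibly under a seed.  The two sizing
rules differ deliberately: they reproduce the two printed compositions.

# Feature selection

CFS merit of a k-subset is `k·rcf / sqrt(k + k(k-1)·rff)` with `rcf` the
mean absolute feature-class correlation and `rff` the mean absolute
pairwise feature-feature correlation.  Correlations are Pearson
(point-biserial against the class) on the continuous z-scored descriptors:
the historical reference implementation discretizes and uses symmetric
uncertainty, but the descriptors here are continuous and Pearson is
deterministic and parameter-free; a symmetric-uncertainty mode over
equal-frequency 10-bin discretization is available behind a flag for
comparison.  Search is forward best-first from the empty set with a stale
limit of 5 consecutive non-improving expansions, ties broken by column
order.  On panels of up to ~12 features the search provably returns the
global merit optimum (tested by exhaustive enumeration).

A property worth understanding: when two informative descriptors are
strongly correlated, CFS's redundancy penalty will keep only one.  In the
synthetic libraries, low-logP surface area and donor surface area
correlate around 0.55 (every N-H nitrogen contributes to both), so the
selected subset reliably contains the fractional-negative-charge and
donor-area descriptors while the redundant third signal descriptor is
often pruned.  The recovery tests therefore assert that at least two of
the three injected signal descriptors are selected; demanding all three
would test against CFS's design rather than its correctness.  A second,
sharper aliasing also exists: the fractional positive and negative
charge-area descriptors sum exactly to 1 whenever no atom carries a
partial charge of exactly zero, so their correlation is exactly -1 and
either name carries the identical information; recovery checks count the
complement as the same signal carrier.

# Cost-sensitive learning

Five base learners (Gaussian naive Bayes, k-NN with k = 1, a pruned
decision tree, a 100-tree random forest with sqrt(p) features per split,
and a linear SVM with C = 1 -- established implementations from `e1071`,
`class`, `rpart` and `ranger`) are wrapped in a cost layer: substrate
instances are weighted by the false-negative cost and non-substrates by
the false-positive cost, weights rescaled to sum to n.  Learners with
native case-weight support consume the weights directly; the others are
trained on a seeded weighted bootstrap of size n.  An extreme cost ratio
can resample one class away entirely; the wrapper then returns the
limiting constant classifier rather than failing, which preserves the
expected limiting behavior (sensitivity -> 1 as the FN cost grows).
Bagging draws B bootstrap replicates of the weighted distribution
(default B = 10) and aggregates by majority vote with ties going to the
substrate class.  The preset cost grid ships the studied ratios (65:2.5,
150:3.5, 81:1.20, 80:1.10), and `cost_grid_search()` selects by pooled
cross-validated G-mean -- the selection statistic is an assumption, since
the original selection criterion is not stated.

Cross-validation is stratified (members dealt into the currently smallest
eligible fold, so fold sizes differ by at most one and class ratios by at
most one member) and pooled: per-fold confusion matrices are summed before
statistics are computed.  Feature selection is performed once on the
training set before cross-validation, matching the original workflow; a
nested mode re-selecting per fold is available for leakage-aware analysis.

# Evaluation

Substrate is the positive class.  Specificity, sensitivity, precision,
G-mean, MCC and standard accuracy follow their conventional formulas;
balanced accuracy `(sensitivity + specificity)/2` is always reported as
well, because the published per-model "Accuracy" column equals it (for
every printed row) rather than the printed accuracy formula -- both are
therefore computed and the discrepancy documented here.  Zero-denominator
statistics are reported as 0 with an `undefined` flag so degenerate folds
never crash a run.  F-measure is computed and reported but is not an
acceptance surface.  The module is verified against an independent
from-scratch oracle over all confusion matrices with cells up to 6.

# Applicability domain

PCA on the training compounds in the space of the model's selected,
z-scored descriptors.  The original call was made visually on a
two-component score plot; the operational rule here is a bounding box over
the first two component score ranges (margin 0% by default; a margin of
1 doubles each range about its midpoint), with leverage (h > 3p/n) as an
alternative criterion.  In-domain sets grow monotonically with the margin,
and decisions are invariant under rigid rotations of the feature space.

# Synthetic libraries

`generate_library()` assembles molecules from a seeded fragment grammar --
benzene, naphthalene, pyridine, cyclohexane, chain and aryl-alkyl
scaffolds with up to three substituents from {Cl, Br, F, OH, NH2, COOH,
SO3H, NO2, SMe, Me, Et, OMe, CONH2} -- deduplicated by InChI so every
member is unique (a collision would otherwise be destroyed later by the
duplicate-conflict rule).  PCC values are generated as

```
PCC = b0 + b1*z(PEOE_VSA_FNEG) + b2*z(vsa_don) + b3*z(SlogP_VSA0) + e
```

with defaults `b = (-0.15, -0.10, -0.08)`, `e ~ N(0, 0.15)`, clipped to
[-1, 1].  The signal enters through descriptors reported as discriminative
for this transporter (fractional negative charge, donor area, low-logP
area), so feature-selection recovery is a meaningful desk-scale test of
that qualitative claim.  The intercept is calibrated against the empirical
quantile of the linear predictor so that the fraction at or below -0.25
matches the target (default 0.13, the substrate share of the curated
library); calibration failure beyond ±0.02 is an error, not a warning.
Dirty records (inorganics, organic-pair mixtures, strippable salts,
organometallics, selenium/arsenic compounds, permanent ions, and
conflicting-PCC duplicate pairs) are appended with machine-readable
expected fates, and the curation tests assert that exactly the annotated
records are removed.

What the generator does *not* emulate: real structural diversity (natural
products dominate the original library; the grammar is a small substituted-
scaffold space), correlated assay noise, and any derivation of PCC values
from actual cytotoxicity/expression matrices (out of scope).  Passing the
end-to-end tests therefore demonstrates that the pipeline machinery
recovers a known signal under realistic imbalance and descriptor
correlation -- not that the original biological model is reproduced.

# Problem sizes and numerical choices

The test suite runs the end-to-end recovery property at n = 2000 compounds
over 10 seeded libraries (the acceptance script repeats it from scratch),
cost-monotonicity over 25 replicates on a 600-compound library, and the
exhaustive oracles at their natural small sizes (all subsets of 10
features, all confusion matrices with cells <= 6, MaxMin on up to 20
points).  Tolerances: oracle equivalences at 1e-10 or better; surface-area
conservation at 1e-6; recovery and G-mean bounds are stochastic with seeds
fixed in the suite.  Ties everywhere break deterministically (input order
or column order), and every stochastic step takes an explicit integer
seed.

# Known limitations

* Descriptor values are not bit-exact with any commercial implementation
  (different charge parameterizations, surface approximations and
  pharmacophore typings); published-table fidelity is asserted only for
  quantities derivable from printed integers and rates.
* Keto-enol tautomers are not merged at deduplication.
* Aromaticity perception covers 5-7-membered Hückel rings per SSSR-style
  ring; exotic fused or charged aromatic systems outside that scope are
  treated as aliphatic.
* The external-validation compound set of the original study is not
  shipped (external downloads); `check_domain()` and `predict()` accept
  any user-supplied external set instead.
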