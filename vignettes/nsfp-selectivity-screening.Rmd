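---
title: "Connectivity-aware fingerprints and selectivity screening cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-aware fingerprints and selectivity screening cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsfpscreen)
```

## The problem

Aminergic GPCR subtypes share nearly identical orthosteric binding pockets,
so a ligand optimized for affinity alone tends to hit the whole subfamily.
Subtype selectivity is carried largely by the secondary binding pocket
(SBP), the extracellular vestibule near extracellular loop 2, whose
residues are poorly conserved across subtypes. `nsfpscreen` implements a
screening protocol built around that observation: a ligand-based machine
learning funnel that enriches for target-selective chemotypes, followed by
a structure-based stage that checks whether docking poses actually engage
the non-conserved SBP residues differently at target and antitarget
structures.

## The Neighbouring Substructures Fingerprint

Key-based substructure fingerprints record which members of a fixed SMARTS
vocabulary occur in a molecule. They ignore how the matched substructures
are arranged, so two very different molecules can share a bit pattern —
a known source of false positives in activity classification. The NSFP
adds the missing connectivity: its features are *pairs* (and optionally
*triples*) of key matches that are neighbours in the molecular graph.

Construction, per molecule:

1. **Matching.** Every key of the ordered set is matched against the
   molecule; each match is a `(key_id, atom set)` pair. Symmetry-equivalent
   embeddings on the same atoms collapse to one match (benzene against a
   six-membered aromatic ring key yields one match, not twelve), while
   matches of one key on different atom sets stay distinct.
2. **Adjacency.** Two matches are neighbours when their atom sets touch.
   The default definition, `bonded`, requires a shared atom or a direct
   bond between the sets — the two substructures must jointly form a
   connected fragment. `overlap` (shared atom only) and `path` with a
   maximum topological distance `d` are available; `d = 0` reduces to
   `overlap` and `d = 1` to `bonded`. The choice is exposed because the
   neighbouring notion admits several sensible readings; `bonded` is the
   default on the grounds that "constituting a larger fragment" implies
   physical contact.
3. **Features.** Each adjacent match pair contributes one count to the
   doublet feature named by its two key ids sorted lexicographically
   (`KR003|KR007`). With `order = "2+3"`, every set of three matches whose
   induced adjacency subgraph is connected (at least two of the three
   possible edges) contributes a triplet. Tuples of one key matched on
   distinct atom sets (`KR007|KR007`) are legitimate features; a switch
   (`distinct_keys_only`) removes them for users who prefer the stricter
   reading. Counts are stored; kernels consume the binarized presence view
   by default, in keeping with the binary heritage of key-based
   fingerprints.

The implementation carries its own SMILES reader and a SMARTS matcher
(backtracking subgraph search) because the fingerprint needs the *atom
sets* of every match, which no available R cheminformatics interface
exposes. The supported SMARTS subset covers the primitives key sets of
this style actually use — elements, aromaticity, `#n`, `D/X/H/h/R/r/v`,
charges, the four logical operators, all bond symbols, branches and ring
closures — and rejects recursive SMARTS and stereo primitives at compile
time with a clear error. Two caveats are documented rather than hidden:
`R<n>` with `n ≥ 1` is treated as "in at least one ring" (ring-count
semantics would require an SSSR convention), and aromaticity perception
for kekulized input upgrades only cleanly alternating 5–7-membered C/N
rings, so aromatic (lowercase) SMILES is the canonical input form. The
matcher was validated embedding-by-embedding against an independent
cheminformatics toolkit on a 30-molecule × 42-key fixture panel; those
reference atom sets are frozen in the test suite.

## Training sets

Raw affinity tables (ChEMBL-export shaped: compound, target, value, unit,
measure, relation) are normalized to Ki in nM: unit scaling, `pKi →
10^(9−pKi)`, Kd accepted as a proxy, IC50 accepted with a warning or
converted by Cheng–Prusoff when the radioligand concentration and Kd are
configured. Censored records (`<`, `>`) are kept only when the bound falls
unambiguously on one side of both labelling thresholds. Replicates are
aggregated by the geometric mean, since equilibrium constants are
log-normally distributed; a compound whose replicates put it on both sides
of the threshold band is dropped as irreconcilable rather than averaged
into a label.

Labelling uses the conventional thresholds Ki ≤ 500 nM (active) and
Ki ≥ 1000 nM (inactive), both inclusive; the 500–1000 nM band is ambiguous
and excluded. A 22-heavy-atom floor removes compounds too small to span
both the orthosteric pocket and the SBP — the selectivity hypothesis makes
no prediction for them. Seven sets result per target/antitarget pair:
actives and inactives per target, selectives per target (active at one,
inactive at the other), and nonselectives (active at both). Set-algebra
invariants (disjointness, subset relations) are asserted after every
construction.

## Classifiers and model selection

Four binary classifiers drive the cascade: two activity models (target
actives vs. inactives; antitarget likewise) and two selectivity models
(target selectives vs. nonselectives; antitarget likewise). Each is picked
from a method–kernel–hyperparameter grid by five-fold stratified
cross-validation, scored by the Matthews correlation coefficient computed
from *pooled* fold counts — pooling is more stable than averaging per-fold
coefficients when folds are small, which the selective sets often are. The
MCC denominator convention is 0 when any marginal is empty. Ties break
deterministically (naive Bayes < SVM < kernel discriminant, then smaller
cost/basis size, then grid order) so reruns are bit-identical.

The default grid (`default_model_grid()`, 35 specifications) covers SVMs
with RBF (γ ∈ {0.01, 0.1, 1}), Tanimoto and Sørensen kernels at
C ∈ {0.1, 1, 10, 100}; Bernoulli naive Bayes at Laplace α ∈ {0.5, 1, 2};
and the kernel discriminant at basis sizes m ∈ {64, 128, 256} with ridge
ε ∈ {10⁻³, 10⁻²} per kernel. It is a documented, fully overridable
stand-in for an exhaustive production search, not a canonical list.
`fast_model_grid()` (one representative per family) is the pipeline
default where four models must be selected in one run.

Implementation notes worth knowing:

- SVMs are fitted by `kernlab::ksvm` on precomputed Gram matrices. The
  SMO shrinking heuristic is disabled: on fingerprint Gram matrices with
  many near-duplicate rows it can inflate a sub-second fit to tens of
  seconds without changing the solution.
- The Bernoulli naive Bayes over sparse feature sets is implemented
  in-package (the factor-data-frame interface of general-purpose
  implementations does not scale to tuple vocabularies); it is
  cross-checked against an independent implementation on a dense fixture
  in the tests.
- The "extreme entropy machine" family is implemented as its closed-form
  core: map each example to kernel similarities against a random basis of
  m training points, then a Fisher-style discriminant
  `w = (Σ₊+Σ₋+εI)⁻¹(μ₊−μ₋)` with the threshold at the midpoint of the
  projected class means. This is a faithful summary of the family's
  decision rule, not a reimplementation of the original entropy objective;
  treat reported performance accordingly.
- Tanimoto and Sørensen set similarities are positive semi-definite
  kernels; the suite verifies symmetry, unit self-similarity and PSD of
  random Gram matrices to −10⁻⁸ eigenvalue tolerance.

## The cascade

Classification is hard-label and two-staged: stage 1 passes a compound iff
the target activity model is positive and the antitarget activity model
negative; stage 2, applied to survivors, requires the same pattern from
the two selectivity models. All other flag combinations reject — the truth
table has exactly one passing cell per stage, and the suite checks all
four combinations exhaustively. Decision scores are kept in logs for
diagnostics but never used for ranking; the structure-based stage owns
ranking. Compounds whose fingerprint is empty are classified on the
all-absent vector (with a warning) rather than silently dropped.

## Docking post-processing

The package consumes poses (SDF with a score property, or a delimited
table) and receptor residue coordinates (PDB subset plus a YAML criterion
list); it never runs docking. Interaction criteria:

- **Distance contact:** minimum ligand-atom–residue-atom distance at or
  below 5.0 Å, boundary inclusive.
- **Hydrogen bond:** a ligand donor/acceptor heavy atom within 3.5 Å of a
  complementary residue partner. No angle term by default — docking
  output frequently lacks hydrogens; an angle criterion would silently
  never fire.
- **Salt bridge extension:** a positively charged ligand nitrogen within
  4.0 Å of a carboxylate oxygen.
- **Water sites** are a single oxygen acting as both donor and acceptor.
  The water is treated as a direct hydrogen-bond partner; if the
  underlying interaction is really a ligand–water–aspartate bridge, this
  is the permissive approximation.

Two filter modes mirror the two screening arms: `obp_and_sbp` (aspartate
hydrogen bond AND at least one SBP contact) and `asp_or_water` (aspartate
hydrogen bond/salt bridge OR structural-water hydrogen bond). The default
site-to-criterion mapping assigns hydrogen bonds to the orthosteric
residues and 5.0 Å distance contacts to the SBP residues; the YAML spec
overrides any of it, because the published per-residue assignment is not
fully recoverable and receptors differ.

Ranking and consensus: a compound's score at a receptor is its best
(minimum) surviving pose score; ranks are 1-based ascending with
lexicographic tie-breaks. The consensus score is
Δ~max~ = Σ rank(target structures) − Σ rank(antitarget structures);
selection requires strictly Δ~max~ < 0, and output is sorted most-negative
first. Compounds lacking a rank at any listed receptor are excluded and
reported, never imputed. Top-fraction selection takes `floor(n·f)` of the
sorted list (10% of 181 is 18). Diversity selection is sphere-exclusion
leader clustering on Tanimoto similarity (threshold 0.6) processed in
ascending-Δ~max~ order, which makes the centroid set deterministic.

## Synthetic data: what it emulates, and what it does not

The generator builds molecules by chaining weighted fragments
(arylpiperazine, piperidine, azole, phenyl and short aliphatic linkers —
serotonergic-flavoured purely for realism), independently inserting two
planted motifs: a chlorophenyl (activity at the synthetic target "R2B")
and an arylsulfonyl (activity at the antitarget "R1B"). Molecules with
motif 1 only are therefore the planted target-selectives. Affinities are
drawn log-uniformly (actives 5–200 nM, inactives 2–50 µM), labels flip at
the configured noise rate, and records are emitted in a seeded mix of nM
Ki, µM Ki and pKi with relation `=`. Pose scenarios place a three-atom
probe ligand (protonated amine, carbon, carbonyl oxygen) at hand-checkable
distances from a toy receptor of four residue atoms.

Defaults are fixed once: 35% motif insertion probability per motif, 5%
label noise, three to six backbone fragments (spanning the 22-heavy-atom
boundary), and the reference benchmark at seed 7 with 400 examples per
class. The reference benchmark problem sizes — 800 fingerprinted molecules
for the grid search, fast-grid selection for the four cascade models —
keep a full run in single-digit minutes on one CPU.

What passing these tests shows: the fingerprint, kernels, model selection,
cascade logic, geometric filters and consensus arithmetic are correct and
reproducible, and the pipeline recovers planted structure under label
noise. What it does not show: performance on real pharmacology. The
synthetic activity signal is a deterministic motif — far cleaner than the
polypharmacology, assay heterogeneity and activity cliffs of curated
binding data — and the toy poses have no physics. Benchmark MCC near 0.9
against 5%-noisy labels is the expected ceiling for a perfect detector
(agreement is bounded by the unflipped fraction), not evidence of
real-world accuracy.

## Numerical and degenerate-input conventions

- Kernel conventions: similarity 1 for two empty fingerprints; MCC 0 on a
  zero denominator; Gram PSD asserted to −10⁻⁸.
- The kernel discriminant with ε = 0 fails loudly on singular covariance,
  instructing a positive ridge.
- Molecules: salts keep the largest organic fragment by default
  (configurable off); stereochemistry and isotopes are parsed and ignored
  (the fingerprint is connectivity-only); explicit and implicit hydrogens
  are interchangeable for every derived quantity.
- Seeds: every stochastic element (library generation, label noise, fold
  assignment, discriminant basis, pose score jitter) is driven by an
  explicit integer seed; identical seed means bit-identical results, and
  the suite asserts it.

## Known limitations

- The SMARTS subset excludes recursive patterns; full published key sets
  containing them must be pre-filtered (the loader reports exactly which
  keys fail).
- Hydrogen-bond detection is distance-only in the default configuration.
- Aromatic perception for kekulized input covers the common alternating
  rings only.
- The original 117-model grid of the protocol this package generalizes is
  not enumerable from public information; the default grid is an explicit
  stand-in and the per-run audit records every evaluated specification
  with its score.
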