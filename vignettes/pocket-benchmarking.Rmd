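---
title: "Benchmarking binding-pocket comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking binding-pocket comparison: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketbench)
```

## The problem

Proteins with globally unrelated folds often bind the same small
molecules. Tools that compare *binding pockets* rather than whole folds
must therefore be evaluated on benchmarks of pocket pairs whose parent
structures are globally dissimilar, with ground truth coming from the
bound ligands themselves. `pocketbench` implements the statistics and
the curation machinery such an evaluation needs, plus synthetic
generators that stand in for the external inputs (deposited structures,
third-party aligners, docking engines) so that every code path is
exercised offline.

## Contacts and the overlap coefficient

A *contact* is any ligand-heavy-atom/residue-heavy-atom pair within
`contact_cutoff` of each other, and a *binding residue* is a residue
with at least one contact. The default cutoff of 4.5 Å is the
conventional heavy-atom interaction range; it is a configuration value,
not a constant, because published contact assignments derive from
surface-complementarity programs whose internals are not reproducible
from distances alone. Absolute contact counts therefore differ from
surface-based tools; the downstream statistics only require that the
same rule is applied to both pockets of a pair.

Each contact is typed by the residue's physico-chemical group
(I: LVIMC, II: AG, III: ST, IV: P, V: FYW, VI: EDNQ, VII: KR, VIII: H).
Two contacts in different structures are of the same type when their
ligand atoms correspond under a chemical atom equivalence and the
residue groups match. The Szymkiewicz–Simpson coefficient is then

$$\mathrm{SSC} = \frac{|A \cap B|}{\min(|A|, |B|)}$$

over the two contact lists. The intersection is computed as a *maximum
one-to-one bipartite matching* of contacts (`igraph`), not greedily:
when one ligand atom touches several residues of the same group, greedy
pairing can undercount the overlap.

Structure input is standard PDB text (`bio3d` does the parsing). Only
the first MODEL is used; within each alternate-location group the
highest-occupancy conformer wins, with ties broken by the lowest altloc
letter; author residue numbering and insertion codes are preserved
throughout. Modified residues in the shipped alias table (MSE, SEP,
PTR, …) count as their parent amino acid for sequence, grouping and
chain length; unknown residues are excluded from profiles and logged.
Chain length is counted over polymer residues with at least one atom,
not over SEQRES, because curation length bounds should reflect the
coordinates actually present.

## Ligand chemistry

Ligands from HETATM records carry no reliable bond orders, so molecular
graphs are element-labelled only: bonds are inferred where the
interatomic distance is at most 1.15 × the sum of single-bond covalent
radii. Fingerprints are hashed linear paths of 1–7 atoms over element
symbols (1024 bits), with each path canonicalised to its
lexicographically smaller reading direction and hashed by an
arithmetic-only function, so fingerprints are bit-identical across
platforms. Absolute Tanimoto values depend on the fingerprint dialect;
this only shifts thresholds and never reorders comparisons made with a
single dialect, which is why the curation thresholds below are
configuration values.

Atom equivalences between two ligands come from a maximum *connected*
common-substructure search: backtracking over frontier atom pairs with
element matching, an optimistic-bound prune, and early exit once the
smaller molecule is fully mapped. Connectivity is the natural choice
for ligand cores shared between binding sites (and the behaviour of
common chemical-alignment tools); a disconnected variant would match
scattered fragments with no geometric meaning. The search is exact
unless the wall-clock budget (default 10 s) expires, in which case the
best mapping so far is returned with a `truncated` flag. On the ADP/ATP
pair the search maps all 27 ADP heavy atoms and terminates through the
upper bound, not the timeout.

Ligand clustering is deterministic leader clustering: molecules in
descending heavy-atom order (ties keep input order) join the first
representative at or above the Tanimoto threshold. This replaces
unspecified orderings of classic clustering utilities with a rule that
is reproducible and, when all pairwise similarities are cleanly above
or below the threshold, order-invariant.

## Geometry

Rigid superposition uses the Kabsch algorithm (SVD of the
cross-covariance with the determinant sign correction, so reflections
are never returned). Inputs of fewer than 3 points or with a second
singular value below 1e-9 (collinear sets) are rejected rather than
silently fitted.

The *reference alignment* of a pocket pair superposes complex B onto A
by the equivalenced ligand heavy atoms and then pairs binding residues
one-to-one by minimum-total-cost assignment over Cα–Cα distances
(Hungarian algorithm, written in-package because no installed library
provides dense linear assignment), admitting pairs only below
`pair_cutoff = 5.0` Å. An assignment, rather than nearest-neighbour
pairing, guarantees a one-to-one mapping; the cutoff keeps spurious
long-range pairings out of the reference. For chemically different
ligands the ligand RMSD is computed over the equivalenced atoms only —
a common-atom convention is unavoidable when, say, a di- and a
tri-phosphate nucleotide are compared. All binding residues are
eligible for pairing (no additional distance-to-ligand restriction);
this is one of the genuinely open conventions, and `pair_cutoff`
already bounds how far an admissible pair can stray.

The ligand RMSD of an *arbitrary* alignment reverses the roles:
superpose by the Cα atoms of the aligned residues, measure over the
equivalenced ligand atoms. Low values mean the alignment is
geometrically correct regardless of which method produced it.

## Ordinal association and rank statistics

Kendall τ over alignment positions uses the τ-a form
$(n_C - n_D)/(n(n-1)/2)$ with no tie correction: within a single chain
two residues cannot share a sequence position, so ties are impossible
by construction. Spearman ρ is the classic $1 - 6\sum d_i^2/(n(n^2-1))$
when ranks are unique; with ties (docking scores do tie) midranks are
assigned and the statistic is the Pearson correlation of midranks, of
which the classic formula is the tie-free special case. Rank 1 is the
best (most negative) predicted affinity. MCC is defined as 0 when any
factor of its denominator vanishes. ROC AUC uses the Mann–Whitney
identity with ties credited 0.5; the stored curve is swept over all
distinct thresholds and its trapezoidal integral equals the
Mann–Whitney value to numerical precision (asserted at 1e-10 in the
tests). Sensitivity at a fixed FPR follows the step-function
convention: the TPR at the largest achieved FPR not exceeding the
requested level. Pairs missing a score are excluded per-method and
counted, never imputed — tool failures should be visible in a
benchmark, not silently absorbed.

The meta-predictor multiplies a direct alignment score by the screening
ρ of the pair's two targets. Multiplication needs no calibration,
preserves each factor's ordering on positive ranges, and lets either
signal veto the other, which is exactly the behaviour wanted from
combining two methodologically orthogonal similarity measurements.

## Curation pipeline

Defaults (all in `curation_config()`): chains of 50–999 residues; a
single qualifying ligand per chain; drug-likeness at Tanimoto ≥ 0.5 to
at least one library fingerprint; sequence clustering at 40% global
identity (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5, via
`Biostrings`; identity = exact matches over alignment length);
within-cluster dedup keeping records whose ligand Tanimoto is < 0.5
*or* whose ligand-centroid separation is ≥ 8 Å (the disjunctive
reading; `representative_rule = "and"` switches to the conjunctive
one); predicted-pocket MCC ≥ 0.4 against the contact-derived truth;
ligand clusters at Tanimoto 0.7; and pairs only below TM-score 0.4.
TM-scores are consumed from an external lookup, never computed —
global structure alignment is outside this package's scope. The
centroid of the ligand heavy atoms stands in for "binding-site
location", the per-cluster representative for negative pairing is the
record with the most binding residues (ties alphabetical), and every
rejected record carries the rule that removed it, so
`verify_manifest()` can audit the finished product against every
constraint independently of the pipeline that built it.

## What the synthetic generators emulate — and what they do not

`make_complex_pair()` grows Cα traces as self-avoiding random walks
(3.8 Å steps, 3.5 Å exclusion radius, direction persistence) with one
side-chain pseudo-atom per residue and a connected ligand chain
threaded ~3.7 Å along the pocket face. A Positive pair shares a
congruent pocket: the pocket residues and ligand of complex A are
transplanted under a random rigid motion and the rest of the decoy
chain is regrown independently, so the chains fold differently while
the residue mapping, the contact lists and (at zero noise) an exact
ligand superposition are known by construction. Making the pocket a
sequence-contiguous N-terminal segment is a deliberate simplification:
it keeps both chains valid self-avoiding walks end to end. The cost is
that planted reference alignments are sequential (τ = 1), so ordinal
behaviour is exercised separately by `make_alignment()`, which mixes a
sorted and a shuffled correspondence (exact τ of +1/−1 at the extremes,
mean τ of 0 at order level 0) and always reports the realised τ from
direct pair counting. Negative pairs draw the two chains' residues from
disjoint group alphabets and unlike ligand elements, making the planted
contact-type overlap provably zero.

`make_rank_matrix()` draws scores from a Gaussian copula: designated
target pairs share the latent Pearson correlation $2\sin(\pi\rho_s/6)$
that yields the requested Spearman ρ under bivariate normality, and
every target loads on a synthetic molecular-weight covariate the same
way (heavier compounds score more negative), emulating the weight bias
of docking scoring functions. Infeasible combinations (latent
correlation outside [−1, 1]) are rejected rather than clipped.

None of this is physically realistic: no secondary structure, no
docking energetics, no real chemistry in the toy molecules (random
trees/rings over C, N, O, P, S). Passing tests demonstrate that the
statistics, the geometry and the pipeline logic are correct on inputs
with known ground truth — not that any particular external tool will
score well on real proteins. Conclusions about real data additionally
require the deposited structures, aligner reports and docking tables
the adapters are designed to ingest.

## Numerical choices and degenerate inputs

* Kabsch: reflection branch resolved by the determinant correction;
  collinearity threshold 1e-9 on the second singular value.
* Hungarian residue pairing: inadmissible pairs carry a large finite
  cost and are stripped from the result afterwards, which makes the
  assignment maximum-cardinality over admissible pairs first and
  minimum-distance second.
* Empty cases: two empty contact profiles are an error (no defined
  overlap), one empty profile gives SSC 0; an empty reference alignment
  is an error for MCC; single-class ROC input is an error; an
  all-ties score vector is an undefined correlation, reported as such.
* Fingerprint hashing: polynomial accumulation mod 33554393 (a prime
  below 2^25, exact in doubles), folded mod 1024 — no platform- or
  locale-dependent behaviour.
* Determinism: every generator seeds R's RNG once from its `seed`
  argument; repeated calls are byte-identical.

## Problem sizes in the shipped tests

The test suite runs entirely on generated data: toy chains of 55–60
residues with 5–6 pocket residues, molecules of up to 31 atoms,
rank matrices of 1515 compounds (the size of a non-redundant
FDA-approved drug library, kept so the null behaviour of ρ is measured
at the realistic n), ROC instances up to 10^5 scores, 100-seed
calibration runs for the planted-correlation recovery, and exhaustive
brute-force oracles confined to graphs of ≤ 6 atoms and assignments of
≤ 6 rows, where enumeration is exact and fast. These sizes were chosen
so every statistical tolerance in the tests is comfortably inside the
corresponding sampling error.

## Known limitations

* The distance-based contact rule and the path-fingerprint dialect will
  not reproduce contact lists or Tanimoto values from surface-based or
  commercial tools atom-for-atom; thresholds calibrated for one dialect
  should be re-examined under another.
* mmCIF, biological assemblies, hydrogens and resolution-based quality
  filtering are out of scope; input is single-model PDB text.
* The connected-MCS search is exponential in the worst case; the time
  budget makes it safe but a truncated mapping is a lower bound, and
  the `truncated` flag should be checked when ligands exceed a few
  dozen heavy atoms.
* Statistical significance of τ and ρ is not computed, and no
  confidence intervals are attached to AUCs.
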