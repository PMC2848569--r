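---
title: "Methods: multi-label subcellular localization with hybrid pseudo amino acid composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label subcellular localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sublocr)
```

## Problem and model

`sublocr` predicts the subcellular location *set* of a eukaryotic protein.
The problem is multi-label: a protein may legitimately reside in several of
the compartments (the package ships the standard 22-location label preset,
but any ordered label set works). The design follows the hybrid strategy of
the mPLoc family of predictors: represent a protein in several complementary
pseudo amino acid composition modes, classify with an ensemble of
evidence-theoretic K-nearest-neighbor (OET-KNN) voters, and turn the
ensemble tally into a label set with a share-band threshold.

### Feature modes

**GO mode.** The working assumption is that close homologs share both
compartments and annotations. BLAST hits of the query against an annotated
reference set are filtered into the *homology set* — subjects with percent
identity at least `identity_min` and expect value at most `evalue_max_go` —
and the union of the representatives' GO terms defines a sparse binary
indicator vector. The query never needs an accession number of its own. A
query fails this mode in two situations: the homology set is empty, or none
of its terms occurs in the training library (the vector is *unproductive* —
usefulness is always relative to a given training set). Such queries fall
through to the sequence-evolution engine.

**FunD mode.** Conserved-domain hits with expect value at most
`evalue_max_fund` set bits of a binary domain indicator. Domains encode
function, and function co-determines compartment; this mode needs no
homology at all.

**SeqEvo mode.** The PSI-BLAST position-specific scoring matrix is
row-standardized (each position's 20 scores centred and scaled by their
population standard deviation) and condensed to a fixed-length pseudo-PSSM
descriptor: the 20 column means, plus 20 lag-ξ correlation factors
$G_j(\xi) = \frac{1}{L-\xi}\sum_{i=1}^{L-\xi}(E_{i,j}-E_{i+\xi,j})^2$.
The squared-difference coupling is the standard form in this descriptor
family; the exponent is exposed (`power`, default 2, even values keep the
factors non-negative). At ξ = 0 the correlation block vanishes and the
descriptor is exactly the 20 means. The ξ range 0…49 pairs with the
fragment rule: chains under `min_length = 50` residues are rejected, so
every retained chain supports all 50 lags. For 50 ≤ L ≤ 49 + k the range is
never truncated; shorter *library* chains would simply drop out of the
affected lag spaces (with the truncation warning reserved for queries).

### Classifier and ensembles

Each OET-KNN voter works on one feature space. A neighbor of class $c$ at
distance $d$ commits the simple belief structure
$m(\{c\}) = \alpha\,e^{-\gamma_c d^2}$, remainder on the whole frame;
neighbor masses are fused with the normalized Dempster rule (an
unnormalized variant is available) and the voter returns the
maximal-belief class. The class scales are fitted from the training data:
$\gamma_c$ is the reciprocal mean squared distance from class-$c$ samples
to their nearest same-class neighbor, so that a typical within-class
neighbor commits nearly $\alpha$; degenerate classes (single sample, or
coincident points) fall back to the global mean rule, and an optional
leave-one-out grid refinement of a common multiplier is provided
(`refine_gammas`).

Distances are Jaccard on the binary spaces (empty-vs-empty defined as 0)
and Euclidean on the pseudo-PSSM block. The SEQ engine's member $(K,\xi)$
votes on the joint FunD ⊕ Pse-PSSM(ξ) space with the convex combination
$d = w\,d_{FunD} + (1-w)\,d_{Pse}/s$, where $s$ is the mean pairwise
training Pse-PSSM distance at that lag (computed over distinct proteins so
duplicated virtual copies do not deflate it). The joint space is a design
choice — the alternative, separate voters per space
(`joint_space = FALSE`), is provided because the original formulation does
not say how the two representations are joined; the joint space was chosen
because it lets domain evidence and evolutionary evidence trade off within
a single vote rather than only at the tally.

The **GO engine** fuses K = 1…10 (10 members); the **SEQ engine** fuses
K = 1…10 × ξ = 0…49 (500 members for any full-length chain). Votes are
tallied per location and the predicted set is
$\{\ell : \text{votes}(\ell) \ge 1 \text{ and } v(\ell) \ge v^* - \theta\}$
with $v(\ell)$ the vote share and $v^*$ its maximum. The rule is monotone
in θ and never reports a zero-vote location.

### Virtual samples, jackknife, scoring

A protein with $m$ locations counts as $m$ virtual samples; the virtual
total is $\sum_m m N_m$ over the multiplicity histogram. The jackknife
removes one *distinct protein* per fold — all its virtual copies leave
every library together, since leaving an identical vector behind would leak
the answer — refits every $\gamma$ on the remainder, and routes the
withheld protein normally. Reports give per-location `correct/total`
percentages plus the overall rate as summed correct over summed totals, in
two conventions: *locative* (credit 1 when the sample's location is among
the predictions) and *penalized* (credit weighted by
$|T \cap P|/|T \cup P|$, so false positives and false negatives both
shrink the score; penalized ≤ locative always).

## Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `identity_min` | 60 % | homology-set identity floor; conventional working threshold for annotation transfer |
| `evalue_max_go` | 0.001 | BLAST expect ceiling, matching the profile-search cutoff used for the PSSMs |
| `evalue_max_fund` | 0.001 | domain-hit significance ceiling |
| `alpha` | 0.95 | maximal single-neighbor commitment; < 1 keeps total conflict impossible |
| `gamma_c` | fitted | inverse mean squared same-class NN distance (see above) |
| `k_max` | 10 | neighborhood sizes 1…10; larger K is known to degrade this family of predictors |
| `xi_max` | 49 | largest pseudo-PSSM lag; bounded by the 50-residue fragment rule |
| `w` | 0.5 | FunD weight in the joint SEQ distance; equal weight absent evidence either way |
| `theta` | tuned | multi-label share band; see below |
| `min_length` | 50 | fragment threshold, in residues |

**Why θ is tuned rather than fixed.** The band exists "to control the count
of multiple location sites and optimize the predicted results", i.e. it is
an optimized quantity by construction. A fixed small band also turns out to
be structurally unable to express multiplex predictions: ensemble tallies
for a two-location protein are typically extreme splits (for instance 1/9 —
the K = 1 voter takes one true class, all others the second), because a
multi-label training protein contributes *identical* feature vectors to
each of its classes and all tie-breaks are deterministic. `tune_theta()`
therefore computes the training tallies once (they do not depend on θ),
scores every candidate θ on a 0–0.95 grid by the penalized resubstitution
rate, and keeps the smallest maximizer, so the band never grows without
measurable benefit. An explicit numeric `theta` in `loc_config()` overrides
the tuning. The tuned value is shared across jackknife folds (a global
engine parameter, like the K range), which introduces the same mild
optimism any globally tuned hyper-parameter does.

## Numerical choices and degenerate inputs

- Zero-variance PSSM rows standardize to the all-zero row (the limit
  consistent with zero-mean centring); standardization is idempotent to
  1e-9 and invariant to positive per-row affine rescaling.
- Lags with ξ ≥ L are errors, not silently capped: the averaging
  denominator L − ξ must stay positive, and capping would hide data
  problems.
- Distance ties break by ascending sample index; belief ties by the
  smallest class level; both chosen for bit-reproducible results.
- Empty binary vectors are at distance 0 from each other and 1 from any
  non-empty vector.
- Total conflict in the Dempster combination (normalization constant 0) is
  an error flagging degenerate parameters; it cannot occur for α < 1.
- The ASCII PSSM reader maps columns through the amino-acid header line
  when present (PSI-BLAST prints A R N D C …; the package's canonical
  order is alphabetical) and reads only the residue letter plus the first
  20 integer columns.

## The synthetic benchmark generator

`make_benchmark()` emulates the statistical structure the method assumes,
not biology: each location owns an exclusive block of GO terms
(8 by default), an exclusive block of domains (6), and a 20-dimensional
PSSM column-bias signature; a multi-location protein mixes its locations'
signatures. Homologs are the protein's *family* — the proteins carrying
exactly the same location set (capped at 15 subjects) — because close
relatives share both compartments and annotations; an earlier design that
made every co-located protein a homolog collapsed all GO vectors into
near-identical unions and is documented here as a cautionary note. Each
protein additionally carries a few private terms and domains, keeping
same-family vectors close but never identical. A configurable `orphan_frac`
(default 0.25) of proteins receive only sub-threshold identities, so their
homology sets are empty and they exercise the SEQ routing branch. `noise`
corrupts the data three ways: annotation dropout, cross-location
contamination, and — the dominant effect — *spurious homology*, where a hit
is redirected to a random unrelated protein at high identity so that
wrong-location annotations are transferred. The label-multiplicity
distribution defaults to the empirical histogram of the curated
22-location benchmark (proportions 6687 : 1029 : 48 : 2, capped at four
labels). Everything is a deterministic function of the configuration
including its seed; written directories are byte-identical across runs.

What the generator does **not** emulate: realistic sequence evolution
(sequences are i.i.d. residues; the PSSM signal is injected directly),
annotation incompleteness bias, GO term correlation structure, shared
domains between compartments, and class imbalance beyond what the
multiplicity distribution induces. Passing tests on generated data
therefore demonstrate the pipeline's internal correctness and its response
to controlled signal and noise — not field performance on real proteomes.

## Problem sizes used by the test suite

The suite checks the clean-recovery condition on one generated benchmark of
200 proteins over 5 locations (zero noise, separation 4, fixed seed) and
noise degradation on 60-protein, 3-location benchmarks over noise levels
{0, 0.3, 0.6} averaged across 5 seeds; property suites use 100–1000 random
instances per invariant. These sizes were chosen so the whole pipeline —
featurization, per-fold refitting, 10- and 500-member ensembles — is
exercised end-to-end many times while the suite stays comfortably
interactive.

## Known limitations

- **Exact multi-label recovery has a structural ceiling.** Because a
  multi-label training protein contributes identical vectors to each of its
  classes, a query that is closest to such copies produces exact distance
  and belief ties, which deterministic tie-breaking always resolves to the
  alphabetically-first class; when those copies dominate the neighborhood,
  the second true location receives zero votes and no θ < 1 can report it.
  On clean separable benchmarks this caps the jackknife rate a few points
  below 100 % (the residual misses are exactly these sweeps). Softening
  would require randomized tie-breaking or belief-level (rather than
  vote-level) fusion, both outside the present design's reproducibility
  constraints.
- θ is tuned by resubstitution, which is optimistic on small training sets;
  per-fold tuning would be cleaner but quadratic in cost.
- The jackknife recomputes per-lag scale factors per SEQ-routed fold;
  runtime grows roughly linearly in folds × lags × library size and
  quadratically in library size for the γ fits. Benchmarks beyond a few
  thousand virtual samples would need incremental distance updates.
- The GO mode uses flat term presence; no ontology-graph propagation is
  performed, by design.
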