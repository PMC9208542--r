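---
title: "Methods: classifying and dating the vertebrate DNase repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and dating the vertebrate DNase repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaserep)
```

## The problem

Vertebrate genomes carry two unrelated families of DNA-degrading enzymes:
the DNase1 family (cation-dependent, neutral-pH nucleases) and the DNase2
family (cation-independent, acidic lysosomal nucleases built from two
phospholipase-D-like domains). Across vertebrates these families resolve
into ten orthogroups — eight DNase1-type (DNase1, DNase1L1, DNase1L1L,
DNase1L2, DNase1L3, DNase1L4, DNase1L4-2, DNase1L5) and two DNase2-type
(DNase2, DNase2b). `dnaserep` implements the computational chain needed to
define and date such a repertoire: profile-HMM classification of proteins
into orthogroups, verification through diagnostic sequence features,
presence/absence reconstruction, Dollo parsimony dating of gains and losses
on a chronogram, and detection of conserved local gene arrangements.

## Profile HMMs and orthogroup assignment

Each orthogroup is modelled by a profile hidden Markov model built from a
curated alignment of 10–20 trusted members.

* **Architecture.** Plan7-style match/insert/delete chain in *glocal* mode:
  every path enters at the first match state and exits from the last, so a
  full-length domain is required, while background-emitting flanking insert
  states absorb N- and C-terminal overhangs (signal peptides, tails). The
  flank self-loop probability is fixed at 0.9; since flanks emit the
  background distribution, an overhang costs only the loop transitions
  (≈ 0.15 bit per residue), keeping glocal scores comparable across
  moderately different sequence lengths.
* **Match columns.** Alignment columns with residue occupancy ≥ 0.5 become
  match states. With curated, mostly ungapped input alignments this
  reproduces the intuitive core domain.
* **Emissions.** Observed counts plus a pseudocount of 1.0 times the
  Robinson–Robinson background frequencies, normalised. Insert states emit
  the background itself, so inserts are score-neutral.
* **Transitions.** Estimated from the per-row state paths with additive
  smoothing of 0.1 per allowed target. The smoothing constant is
  deliberately smaller than the emission pseudocount: with a dozen rows, a
  constant of 1.0 would impose ~7 % delete probability per column on
  alignments that contain no gaps at all, which distorts both sampling and
  Viterbi mapping; 0.1 keeps unobserved transitions possible but rare.
* **Scoring.** Forward and Viterbi run entirely in log space (with a
  log-sum-exp kernel in C++), reported as log2-odds bit scores against the
  i.i.d. background null. `X` residues are score-neutral everywhere.
* **E-values.** Each profile is calibrated by scoring 200 seeded random
  background sequences of core length and fitting a Gumbel distribution by
  maximum likelihood; then `E = dbsize * exp(-lambda * (score - mu))`. The
  database size defaults to the number of scanned records and is exposed
  explicitly, because a fixed threshold such as 1e-20 only has meaning
  relative to a search-space size. Assignment keeps the highest-scoring
  profile among those with `E <= 1e-20`, breaking ties by lexicographic
  label. True members score hundreds of bits above the null, so the
  threshold is far from the decision boundary; shuffled decoys stay
  unassigned.

Scanning is protein-only by design: six-frame translation of genomic DNA is
out of scope.

## Alignments, identity and trees

Pairwise alignment is global Needleman–Wunsch/Gotoh with BLOSUM62, gap open
11 and gap extension 1 (a gap of length *k* costs 11 + *k*). Scores
involving `X` are set to zero. Traceback ties prefer the diagonal, then the
vertical, then the horizontal predecessor, making every alignment
deterministic. Percent identity uses columns where *both* rows hold
residues as the denominator — the convention closest to alignment-viewer
identity and insensitive to terminal overhangs. Published identity figures
computed with other aligners and conventions can differ by a couple of
percentage points; comparisons at that granularity should allow ±2 points.

The multiple aligner is progressive: a UPGMA guide tree from all-pairs
identity distances, then profile–profile global alignment with
frequency-weighted column scores. Trees for monophyly sanity checks come
from standard neighbor-joining on `100 - identity` distances (exact on
additive inputs); this is an explicit stand-in for maximum-likelihood
phylogenetics, which the package does not reimplement.

## Diagnostic sequence features

Orthogroups carry features that profile similarity alone does not verify.
Residue-level features are anchored through the profile's *reference map*:
labels such as `C101` name match states (human-DNase1 numbering for the
DNase1 family), and the Viterbi path carries them onto each classified
sequence, which keeps the mapping robust to indels. A cysteine pair is
reported only when both mapped residues are literally cysteine.

The C-terminal classifier is a fixed cascade — GPI, then basic peptide,
then somatomedin-B, then "EL", else NONE — ordered so the most specific
signal wins:

* **GPI**: a small residue (S/G/A/N/D/C) within the last 40 positions,
  followed by a 6-residue spacer and a tail of ≥ 8 residues with mean
  Kyte–Doolittle hydropathy ≥ 1.0; candidate ω positions are scanned from
  the C-terminus inwards and the first valid one is reported (1-based).
* **BASIC**: net charge of the last 12 residues ≥ +4 (K/R = +1, D/E = −1,
  H = 0).
* **SMB**: ≥ 6 cysteines in the last 60 residues.
* **EL**: the final two residues are exactly "EL".

The signal-peptide detector is a deliberate heuristic: an 8-residue window
within the first 35 positions with mean hydropathy ≥ 1.6, preceded by a
non-negatively charged segment. It replaces dedicated predictors; no
accuracy claim is made for real proteins — its contract is defined (and
tested) on the synthetic fixtures. All constants live in
`feature_params()` because the underlying publications define these
signals by predictor output and visual inspection, not by thresholds.

Every call is checked against the per-orthogroup expectation table
(`orthogroup_expectations()`); mismatches produce flags but never reject a
call, since real repertoires contain genuine exceptions (a lamprey
DNase1L3 without the basic tail, for example, is a finding, not an error).

## Dollo reconstruction and dating

Presence/absence matrices are reconciled with a dated species tree under
Dollo parsimony: each orthogroup is gained exactly once and lost any number
of times. The gain is placed on the stem branch above the MRCA of the
presence leaves — not at the node — so the event gets a proper time
interval (parent age, child age); a gain at the tree root has no parent and
its older bound is reported as `NA`. Losses are the stems of the maximal
absent subtrees below the gain, which is provably the minimum-loss
labelling (verified against exhaustive search in the tests). Taxa present
in the matrix but missing from the tree are an error, never silently
dropped.

Tandem duplications are dated by the daughter orthogroup's gain interval,
tightened by the parent's own gain when the parent does not predate it. On
the bundled chronogram this yields the bony-vertebrate-stem interval
(473–435 Myr, midpoint 454) for the DNase1L1L→DNase1L1 duplication and the
amniote-stem interval (352–319 Myr, midpoint 335.5) for DNase1→DNase1L2.

The bundled 21-leaf chordate chronogram uses round TimeTree-style ages
(root at 700 Myr; gnathostome crown 473, bony-vertebrate crown 435,
tetrapod crown 352, amniote crown 319). Ages enter as input data; the
package does no divergence-time estimation.

Synteny is purely geometric on 0-based half-open coordinates:
"head-to-head" means divergent strands with the minus-strand gene upstream
(the bidirectional-promoter configuration, as in DNase2b–Uox), tandem means
same strand, and genes on different chromosomes are unlinked (distance
reported as −1).

## The synthetic generator: what it does and does not emulate

Because the real analysis rests on downloads from public databases, the
package ships a generator that reproduces the *structure* of those inputs:

* **Histories.** Presence spreads from a configurable gain branch per
  orthogroup; losses are a Poisson process on descendant branches at a
  default rate of 5e-4 events/Myr/lineage, chosen to give on the order of
  two losses per orthogroup on the bundled chronogram — the regime of the
  real repertoire. A lost lineage stays lost. Losses whose branch Dollo
  cannot pinpoint (no surviving presence beside them, or above the realised
  MRCA) are flagged non-identifiable and excluded from recovery scoring,
  because no parsimony method can see a loss inside a loss.
* **Proteomes.** Members are sampled from the orthogroup profiles; the
  diagnostic residues at reference columns are then repaired to the profile
  consensus (sampling noise and deletions would otherwise erode motifs that
  are, in reality, under strong purifying selection), and each orthogroup's
  terminal signatures are attached: a signal-peptide-like or acidic
  N-terminal peptide and a GPI / basic / SMB / "EL" / neutral C-terminal
  peptide. Decoys are residue-shuffled members — composition-matched, the
  hardest null that is still honestly negative.
* **Gene tables.** Coordinates are constructed so the planted arrangement,
  distance and intervening-gene count are recovered exactly.

The synthetic consensus sequences derive from two random family ancestors;
they carry the right motif geometry (including the fifteen-residue
DNase1-loop deletion that defines DNase1L2) but are otherwise unrelated to
real DNase sequences, and members of one orthogroup are i.i.d. draws rather
than phylogenetically correlated. Synthetic orthogroups are therefore more
separable than real ones: passing recovery tests demonstrates that the
machinery is correct and calibrated, not that real-data classification
achieves the same accuracy. Sequence evolution along the tree is
deliberately not simulated.

## Numerical and engineering choices

* Log-sum-exp with a 36-nat cutoff (below double precision) in the C++
  kernels; no probability-space accumulation anywhere.
* Profiles serialize to plain text at 6 significant digits; reading and
  rewriting a profile is byte-identical, and validation of reread profiles
  uses a correspondingly relaxed tolerance.
* Degenerate inputs are contracts, not crashes: an empty proteome scans to
  an empty table, an all-absent orthogroup warns and yields no events,
  sub-30-residue sequences get `NONE` with a warning flag, and calibration
  refuses degenerate score variance.
* Determinism: every stochastic step takes a seed; the same seed reproduces
  bundles byte-for-byte, and output tables sort by (taxon, id).

Test and verification sizes were chosen to exercise every code path while
keeping the whole suite comfortably fast on one core: exhaustive alignment
enumeration up to length 8, exhaustive HMM path sums for ≤ 5 match states
against every ≤ 6-mer over a reduced alphabet, 100 random Dollo instances
against exhaustive minimisation, 200 profile-sampled members and 1000
decoys for the recovery experiment.

## Known limitations

* No maximum-likelihood phylogenetics, bootstrap support, or substitution
  model selection; NJ monophyly checks are a stand-in.
* Protein-level scanning only; genomic tBLASTn-style searches and RNA-seq
  quantification are out of scope.
* The signal-peptide and GPI heuristics are rule-based stand-ins for
  dedicated predictors.
* Dollo parsimony by construction cannot recover nested or
  sibling-symmetric losses, and reports ambiguity only through the
  gain-branch interval.
* The E-value calibration is a Gumbel fit to a modest background sample;
  it is accurate in the regime that matters here (scores far from the
  threshold) but is not a replacement for exhaustively validated
  production calibrations.
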