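---
title: "Methods: conservation of prion-like composition and sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation of prion-like composition and sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions baked into each stage, and the design decisions taken where
more than one defensible choice existed.

## The analysis in one paragraph

For a set of reference proteins classified as known prions (KP),
prion-forming proteins (PFP ⊇ KP) or prion-like proteins (PLP), the
pipeline asks two questions at each of three nested taxonomic levels
(genus ⊆ WGD group ⊆ class): how conserved is the *sequence* of each
prion-like domain, and how conserved is its *prion-like composition*?
Sequence conservation is a per-column entropy score averaged over the
domain's alignment columns. Compositional conservation is the
evolutionarily weighted prion score (EWPS): the weighted mean of the
orthologs' prion propensity scores, weighting divergent orthologs more
heavily, so that a high score certifies that distant relatives still carry
the N/Q-biased composition.

## Orthology: exact Smith–Waterman plus bidirectional best hits

Orthologs are bidirectional best hits (BDBH) between whole proteomes:
(r, s) is kept iff s is r's best hit and r is s's, both with E ≤ 0.001.
Three choices deserve comment.

* **Exact alignment, no heuristics.** Scores come from full
  Smith–Waterman dynamic programming (BLOSUM62; a gap of length L costs
  11 + L), not from a seeded heuristic. At desk scale this is affordable
  (the kernel is compiled; a 180 × 180-protein proteome pair of
  ~140-residue sequences scores in about a second), and exactness makes
  the suite's brute-force oracle comparisons meaningful. A reader for
  12-column tabular hit files (`read_hit_table()`) exists for users who
  prefer to bring external aligner output.
* **Bitscores and E-values** use the ungapped-style conversion
  `bits = (λS − ln K)/ln 2`, `E = K·m·n·e^{−λS}` with λ = 0.267,
  K = 0.041 and m, n the two sequence lengths. Using m·n rather than a
  database-effective search space is deliberate simplicity, but it has a
  visible consequence: over N random sequence pairs, roughly N·E pairs
  clear any E-value cutoff by chance, so at E ≤ 0.001 a large decoy set
  *will* contain occasional reciprocal chance hits between unrelated
  background proteins. The analysis is insensitive to this because
  families are built only for the tracked reference proteins, whose true
  orthologs outscore chance hits by an enormous margin; the test suite
  measures BDBH precision and recall over those tracked proteins.
* **Percent identity** is identities divided by aligned columns in which
  both sequences carry a residue. The alternative denominator (full
  alignment length including gap columns) gives slightly lower
  identities; since identity only enters the PC weighting as
  1 − pid/100, either convention yields a valid weighting, and the
  aligned-columns one was fixed for determinism.
* **Ties** in best-hit bitscore are broken by higher percent identity,
  then lexicographically smaller id, purely for reproducibility.

## Multiple alignment: progressive profile aligner

Each family (reference + orthologs) is aligned progressively: pairwise
local-alignment identities give distances 1 − pid/100, a UPGMA tree
(`hclust`, average linkage) orders the merges, and each merge is a global
profile–profile Needleman–Wunsch under BLOSUM62 with the same affine
penalties. Column frequencies are counts over all rows of a profile, so
gap-rich columns are down-weighted. A two-member family reduces exactly
to global pairwise alignment, which the tests exploit.

A disorder-aware aligner would place gaps differently inside
low-complexity regions. The downstream statistics, however, consume only
column composition, and the package accepts externally computed
alignments (`read_aligned_fasta()`, or `alignment_dir` in
`run_pipeline()`) whenever fidelity to a particular aligner matters. The
alignment reader keeps all columns, including all-gap ones (they are
masked later by the gap filter rather than silently dropped).

## Per-column conservation

For column *i* with non-gap residue frequencies *p*<sub>ia</sub>
(unweighted counts; gaps excluded, not a 21st symbol), the raw score is
Σ<sub>a</sub> *p*<sub>ia</sub> ln *p*<sub>ia</sub>: 0 for a fully
conserved column, increasingly negative with diversity. Columns with gap
fraction above 0.5 are masked. Raw scores are normalized to mean 0, SD 1
over unmasked columns, which is what makes domain means comparable across
families and levels; whole-sequence means are computed over the same
unmasked set (so masked columns are excluded from whole-sequence means
too — the other convention would mix scales). Degenerate inputs are
handled explicitly: fewer than two rows is an error, an all-identical
alignment yields all-zero normalized scores with a warning, and a domain
whose columns are all masked is flagged undefined and excluded from
downstream statistics rather than contributing an NA silently.

One property of entropy conservation is worth stating because it shapes
what the simulation tests can claim: a compositionally restricted column
(e.g. 80% N/Q) retains low entropy even when every row has been
resampled, so an N/Q-rich domain can score *above* the whole-sequence
mean despite evolving faster. Rate recovery is therefore always asserted
on composition-matched comparisons (the same domain class at different
rate multipliers), never on domain-vs-flank contrasts.

## Prion propensity: two-state composition HMM

Prion-likeness is scored by a hidden Markov model with a background state
and a prion-like state whose emissions are the shipped frequency tables'
log-odds ln(prion/background). The prion state has a minimum run length
(`core_length`, default 60 residues — prion-forming domains are long)
enforced structurally by a chain of sub-states, so a Viterbi parse can
never produce a domain shorter than the core. The PRD score is the sum of
log-odds over all decoded prion-state residues, clamped at zero; clamped
zeros are retained in every downstream summation. The LLR is the best
core-length window sum, kept for comparability, with ties resolved to the
smallest start. X residues carry log-odds 0 in both states.

Transition probabilities are a single enter/exit pair; the exit
probability 1/`core_length` makes the expected prion-state run equal the
core length, and the enter probability is set equal to it for symmetry
(the decoded parse is insensitive to this value over a wide range because
the emission log-odds of a genuine N/Q tract dominate the transition
costs). One background model is applied to all species; a per-species
background would confound cross-species score comparisons, which is
exactly what the EWPS aggregates.

The shipped tables (`inst/extdata/*_synthetic.tsv`) are reconstructions:
an N/Q-dominated prion-domain composition approximating the
experimentally characterized prion-former set, and a yeast-like proteome
background. They are explicitly swappable (`frequency_tables()`,
`read_frequency_table()`); absolute PRD values depend on the tables, but
every comparative statement the pipeline makes (orderings, correlations,
EWPS ratios) is driven by the N/Q log-odds structure that any reasonable
table pair shares.

## EWPS

`EWPS = Σ w_i P_i / Σ w_i` over the orthologs of a family, under PC
weighting (w = 1 − pid/100) or BS weighting (w = bitscore /
self-bitscore). Decisions:

* **The reference is excluded from the summation.** Under PC its weight
  is 0 anyway; under BS it would dominate with weight 1, which would
  defeat the stated purpose of weighting *divergent* orthologs more.
* **The two weightings pull in opposite directions** — PC up-weights
  divergent orthologs, BS up-weights similar ones. Both formulas are
  implemented exactly as defined; the package surfaces the tension
  rather than "fixing" either formula, and `compare_schemes()` quantifies
  how much it matters (the acceptance script measures the Spearman rank
  correlation between the two scores on each simulated study; it comes
  out near 0.9, matching the expectation that the difference is minimal).
* **Degenerate families** (no orthologs, or total weight 0 because every
  ortholog is 100% identical under PC) are flagged undefined: they are
  excluded from correlations and reported as 0 in ranking tables.

## Comparison layer

Set-vs-set conservation differences use Welch's two-sided t-test (KP is
compared against PFP-minus-KP, since KP ⊂ PFP); EWPS set differences use
the Mann–Whitney U test (exact null distribution when both groups are
below 20 and tie-free, normal approximation with tie-corrected variance
otherwise); correlations are Pearson with the t-transform p-value. No
multiple-testing correction is applied; raw p-values are reported.
Thirds-consistency ranks proteins by domain mean conservation at each
level and splits them top/middle/bottom; with n = 3q + r the top third
takes the first extra member and the bottom the second, and rank ties
break on id, so the partition is deterministic. All of these are wrapped
around the corresponding base-R tests and verified in the suite against
hand-coded formula and enumeration oracles.

## What the simulator emulates — and what it does not

`simulate_family()` plants an N/Q-rich segment (default 60 residues at
80% N/Q, split 60:40 N:Q) between two 40-residue flanks of proteome-like
composition, and evolves each species independently from the ancestor at
a level-specific depth (defaults: 0.1 / 0.3 / 0.6 expected substitutions
per flank site for genus / WGD / class members; the reference keeps the
ancestral sequence). Substitutions resample sites from the stationary
composition of their region; domain sites substitute at
`domain_rate_mult` times the flank rate; indels arrive at 0.02 events per
site per unit depth with geometric lengths (mean 2). Decoys are
independent draws from the background composition with family-matched
lengths. Everything is deterministic under `seed`.

This emulates exactly the structure the analysis assumes: nested clades
with identity ordering genus > WGD > class, a compositionally biased
domain whose rate is decoupled from its flanks, and proteomes with
unrelated background proteins. It deliberately does *not* emulate:

* **Shared internal branches.** Species evolve independently from the
  ancestor (a star within each level), so covariances between same-level
  species are absent. The statistics consumed downstream depend on
  divergence from the reference, which the star reproduces.
* **Persistent per-protein rate variation within a category.** All
  families of a category share one rate multiplier, so cross-level rank
  stability beyond the category structure is pure noise; the simulated
  thirds-stability fraction is therefore near the chance level, unlike
  real proteins, whose individual rates persist across epochs. Passing
  tests certify the bookkeeping of the thirds partition, not a
  biological signal.
* **Paralogy from genome duplication and gene loss.** Decoys are
  unrelated, not paralogous; BDBH asymmetry from recent duplication is
  covered by a dedicated constructed test case instead.
* **Empirical substitution matrices.** Replacement is
  composition-conditioned uniform resampling, the simplest model that
  produces the composition/conservation structure being measured.

Problem sizes in the shipped tests were chosen for resolution at
interactive runtimes: 20 seeds of 8 species × 30 families × 5× decoys for
BDBH recovery, 100 replicates per rate multiplier for conservation
recovery, 100 constructions for domain recovery, 20 families per category
for the rate-ordering comparison, and 1000 random families for the EWPS
oracle equivalence.

## Known limitations

* Absolute PRD/EWPS values are only as faithful as the frequency tables;
  ship your own for strict comparability with a particular predictor.
* The entropy conservation measure has no sequence weighting, so heavily
  sampled subclades pull column frequencies; the sum-of-pairs and
  variance measures of the original conservation program are not
  implemented.
* E-values use m·n; for genuinely large proteome scans the external
  hit-table path is the better-calibrated route.
* The progressive aligner does no iterative refinement; for publication
  alignments of disordered regions, feed a dedicated aligner's output in
  via `alignment_dir`.
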