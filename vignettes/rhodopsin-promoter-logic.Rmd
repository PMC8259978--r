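---
title: "Dissecting the combinatorial cis-regulatory logic of rhodopsin promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the combinatorial cis-regulatory logic of rhodopsin promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhocis)
```

## The biological problem

Color vision in *Drosophila* rests on five rhodopsins expressed in
non-overlapping photoreceptor subsets: Rh1 in the outer R1–R6 cells, Rh3 in
pale R7s, Rh4 in yellow R7s, Rh5 in pale R8s and Rh6 in yellow R8s. Minimal
promoter regions of under 300 bp reproduce each pattern. Each promoter has a
bipartite layout: a distal region rich in subtype-restricting motifs, and a
proximal core that carries a promoter-specific variant of the Rhodopsin Core
Sequence I (RCSI, consensus `TAATYNRATTN`) immediately upstream of the TATA
box. Two competing models describe how these parts interact:

* **Interchangeable core**: the proximal core is a generic activation module;
  only distal motifs set subtype specificity, so proximal cores can be freely
  exchanged between rhodopsins.
* **Combinatorial core**: distal and proximal motifs are matched; exchanging
  the proximal core changes the spatial pattern.

The decisive experiment fuses the distal region of one rhodopsin to the
proximal core of another at the base immediately 5' of the RCSI, assays
reporter expression per subtype, and asks whether each hybrid reproduces the
distal donor's pattern. `rhocis` implements the full computational side of
this programme: motif scanning and scoring, cross-species motif conservation,
in-silico construct building checked against the printed mutagenesis primers,
outcome classification, and reporter-count statistics, plus generators that
manufacture all three data types with known ground truth.

## Motif scanning and the normalized PWM score

Motifs are IUPAC consensus strings (K50 `TAATCC`, Q50 `TAATTR`, the
per-rhodopsin RCSI variants) or position weight matrices. Scanning reports
every overlapping window on both strands in 0-based half-open coordinates;
minus-strand hits are reported on the forward interval they cover, which makes
the output BED-like. `N` in a sequence matches nothing. Overlaps are never
masked, because real promoter motifs nest (an ATTC repressor motif sits inside
the Rh3 and Rh5 RCSIs, an S-box overlaps an ATTC motif in Rh3).

A word's matrix score is the plain sum of its per-position weights,
\(S = \sum_i w_i(b_i)\), and similarity is reported as a percentage of the
matrix maximum, \(100 \cdot S / S_{max}\), so the strongest configuration
scores exactly 100. We deliberately normalize by the maximum rather than
min–max scaling: weights are log-odds-like, and a *negative* percentage is
informative — it flags a non-functional or random site — which min–max
scaling would hide.

```{r pwm}
store <- rh_pwm_store()
otd <- store$OTD_SYN
pwm_argmax_word(otd)
pwm_norm_score(pwm_raw_score("TAATCC", otd), otd)  # the best word: 100
pwm_norm_score(pwm_raw_score("TAATTG", otd), otd)  # a Q50 word on a K50 matrix
```

The bundled matrices are synthetic stand-ins with the documented argmax words
(`TAATCC`, `TAATTG`); real matrices, e.g. from FlyFactorSurvey, drop in via
`read_pwm_store()`. Likewise the XRE, S-box and Seq56 catalog entries are
flagged `placeholder`, because their exact consensus sequences are not
published; replace them before interpreting scans of real sequences.

## Conservation calling

`call_conservation()` lifts a reference motif occurrence through the
alignment gaps (`map_ref_interval()`) and classifies each species by the
first matching rule in a fixed order: unalignable, identical, consensus
variant, inverted, shifted, absent. Two design choices matter:

* Alignments sometimes encode "no alignable sequence here" as runs of
  dashes, which collides with genuine deletion gaps. We use a distinct
  marker character (default `=`), and `read_alignment_fasta(collapse_gap_runs
  = TRUE)` converts long dash runs for inputs that use the ambiguous
  convention.
* Published conservation analyses typically hand-adjust local misalignments
  around conserved motifs. We replace that manual step with a deterministic
  shifted-match search within a configurable window (default ±10 bp, smaller
  offsets first, upstream before downstream on ties). The window default is
  a judgment call, not a measured value, and is exposed as a parameter.

The fixed rule order (identical beats variant beats inverted) and the
deterministic tie-break make calls reproducible and stable under species
reordering. Note that a "variant" must still match the motif's consensus; for
a fully concrete consensus such as `TAATCC` only identity can match, so
variant analyses should use the degenerate class consensus (e.g. Q50
`TAATTR`). `tally_variants()` then counts the distinct words across species
and `score_variants()` attaches normalized matrix scores, reproducing the
motif-variant affinity tables.

## Construct engineering against printed primers

`build_hybrid()` splices at the first base upstream of the RCSI: the distal
part *excludes* the RCSI, the proximal part *includes* it, because the
proximal core replacement is defined to carry the RCSI along, while
`swap_element()` handles the finer-grained RCSI/RCSII swaps and insertions
with full coordinate bookkeeping (anchors and hits shift by the length
difference; hits overlapping the edit are dropped for rescanning). Hybrids
are named distal-donor-first (`Rh3-Rh4`).

The real minimal promoter sequences are not published. The bundled
`rh_synthetic_promoters()` are therefore assembled from printed fragments
only — amplification-primer cores as termini, mutagenesis-primer flanks as
the RCSI neighbourhood, the RCSI variant words — joined by a neutral C/G/A
spacer that can create no motif match at any junction. They are labelled
synthetic and exist so that every printed primer remains checkable:

```{r primers}
proms <- rh_synthetic_promoters()
swaps <- rh_primer_table("swap")
row <- swaps[swaps$construct == "Rh4-RCSIswap-Rh3", ]
built <- swap_element(proms$Rh4, proms$Rh4[["rcsi"]], rh_rcsi_words()[["Rh3"]])
validate_against_primer(built, row$forward)$match
revcomp(row$reverse) == toupper(row$forward)
```

All ten mutagenesis primer pairs are mutual reverse complements and every
swap construct rebuilt in silico contains its primer's mutagenic core; the
amplification primer pairs are *not* reverse complements of each other (they
flank the promoter), so they are validated by occurrence at the construct
termini instead.

## Expression logic and outcome classification

The transcription-factor model encodes the known regulators: broad
activators Otd (K50) and Pph13 (Q50), the yR7-specific activator Ss (XRE),
and repressors Dve (K50; high in R1–R6, low in yR7), Pros (Seq56, R7s), Sens
(S-box, R8s) and the unidentified "y" repressor (ATTC).
`predict_motif_logic()` turns a motif complement into a pattern by a
deliberately naive rule — active where some activator is expressed and no
repressor is — and its failures are the point: motif presence alone
over-predicts (for an Rh4-like complement it predicts R1–R6 and pR7
expression that the real promoter never shows, and nothing in the model
represses Rh6-like inputs in pR8). The predictor is a documented baseline,
not a fitted model. The ATTC repressor scope is configurable (`yR7`, `yR8`
or both) because both behaviours are reported depending on promoter context.

Observed outcomes are classified by a fixed rule cascade — silent,
interchangeable-consistent, partial, additive, broadened/novel — where
presence means any level other than none ("variable" and "weak" count), and
"additive" requires the presence set to equal the union of both donors'
patterns while exceeding the distal donor's alone. On the bundled table of
all fourteen hybrids this reproduces the published partition:

```{r outcomes}
tab <- rh_outcome_table()
evaluate_models(tab$hybrids, tab$wildtype)
```

## Reporter quantification

Counts are per retina, construct, layer, marker and region.
`filter_region()` drops R7-layer dorsal-third records, because dorsal-third
yR7 ommatidia co-express Rh3 and Rh4 and would masquerade as derepression;
R8-layer records are kept everywhere. `summarize_coexpression()` computes
per-retina percentages, their mean, and the SEM using the sample standard
deviation (denominator N−1) over retinas — the standard choice for
biological replicates; a single retina reports SEM 0 with a warning.

`mann_whitney()` compares two groups of per-retina percentages (the retina,
not the pooled rhabdomere, is the replication unit — an interpretation,
since the published methods do not say). With no ties and both groups of
size ≤ 12 the two-sided p-value is exact over all C(n1+n2, n1) arrangements;
otherwise a normal approximation with tie-corrected variance and continuity
correction is used. `stats::wilcox.test()` provides both computational
paths; an independent enumeration oracle in the test suite confirms the
exact path for every group size up to 7, and 2,000 null simulations put the
empirical size at α = 0.05 near 0.043 (the exact test is conservative at
n = 10 because of discreteness).

## Synthetic data: what it does and does not emulate

The generators exist so every pipeline stage is testable without downloads:

* `gen_promoter()` samples i.i.d. background at a stated GC fraction and
  plants motif words at exact, returned coordinates; `forbid_spurious`
  rejection-samples until a catalog scan finds nothing outside the planted
  intervals (nested sub-motif hits inside a plant are allowed). There is no
  dinucleotide or positional background model — sufficient for
  plant-and-recover testing, not for motif discovery benchmarks.
* `gen_alignment()` applies named per-species motif fates (identical,
  variant word, inverted in place, deleted to gaps, unalignable marker) plus
  background substitutions and single-base deletions. It is a fate
  realizer, not an evolutionary simulation: no tree, no rate matrix, no
  insertion columns. Fate recovery by `call_conservation()` is exact
  whenever background noise does not create a consensus match inside the
  shifted-search window of a species whose motif is gone.
* `gen_counts()` draws marker counts per retina (fixed or Poisson), splits
  them across retinal regions, and draws GFP-positive counts binomially at
  the recipe's co-expression probability. Real count data add observer
  effects and spatial correlation that the binomial model ignores.

All generators are bit-reproducible given (recipe, seed) and restore the
caller's RNG state. Default simulated study sizes mirror the experimental
ones: N = 10 retinas and ~80 scorable rhabdomeres per retina per marker
(published counts are 7–18 retinas and roughly 60–180 R7/R8 rhabdomeres per
retina).

## Numerical choices and limitations

* Coordinates are 0-based half-open throughout, converted only at R's
  1-based string boundaries; minus-strand hits carry forward-strand
  intervals.
* Case-insensitive input is normalized to uppercase; characters outside
  A/C/G/T/N are rejected rather than silently skipped.
* PWM argmax ties break toward the first base in A < C < G < T order;
  normalization refuses matrices with non-positive maxima as degenerate.
* The RCSI anchor is required before hybrid construction; annotation infers
  it only when the catalog's RCSI-class motifs hit exactly one interval, and
  errors on zero or several candidates rather than guessing.
* The coverage check "mean within 3 SEM of truth" at N = 10 sits at the
  edge of what the t distribution with 9 degrees of freedom allows
  (theoretical coverage ≈ 98.5% against a 99% requirement), so that
  property is intrinsically marginal at this sample size; enlarging N, not
  the band, is the principled fix.
* Tests and examples run in seconds on one CPU: property suites use 1,000
  scanner comparisons, 200 alignment recipes, 2,000 null and 1,000 recovery
  simulations — sizes chosen to make sampling error negligible relative to
  the asserted bounds.
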