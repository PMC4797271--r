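---
title: "Methods: dual-topology binding sites, empirical affinity rules, and cooperative occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-topology binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comascan)
```

`comascan` models a transcription factor that reads one hexameric
recognition element (RE, consensus `TTGCGG`) in two topologically distinct
paired arrangements: the canonical inverted repeat (IR, plus-strand
rendering `TTGCGG-N4-CCGCAA`, a dyad) and the non-canonical direct repeat
(DR, `TTGCGG-N5-TTGCGG`, a tandem).  This vignette is the package's account
of its models, defaults and design decisions.

## The motif model

A `motif_model` carries the consensus, an optional position frequency
matrix (PFM) of site counts, a pseudocount, and a background composition.
Probabilities are pseudocount-normalized counts; the default pseudocount
is 0.25 per cell (a uniform Laplace-style quarter-count — no value is
dictated by the data, so we use the common logo-tool default).  Two scoring
conventions are deliberately distinct:

* **Information content** (`information_content()`) always uses the
  uniform-background logo convention, `IC_j = 2 + sum_b p_bj log2 p_bj`,
  so letter heights are comparable to published logos regardless of the
  scan background.
* **Log-odds scores** (`log_odds_score()`) use the model's configurable
  background, because genome scans should be calibrated to genome
  composition.

The PFM is always user-supplied or synthetic.  The published motif logos
exist only as figures, not as printed count matrices, so the package never
pretends to ship "the" matrix; `build_pfm()` compiles one from whatever
aligned sites the user trusts.  The DR motif in real promoters is
considerably more degenerate than the IR motif, so a user may keep two
separate models; the API takes a model argument everywhere rather than
hard-wiring one.

## Exact score p-values

Relaxed scanning thresholds windows on the exact tail probability of the
log-odds score under the background.  `score_pvalue_table()` discretizes
each column's four scores to integer bins of width `bin_width` (default
0.01 log2-odds units) and convolves the six column distributions — the
standard dynamic program for PWM p-values.  The tail is exact for the
discretized score; any word's discretization drift is at most half a bin
per column (3 bins total at width 0.01, i.e. 0.03 score units).  The test
suite checks the DP against brute-force enumeration over all 4096
hexamers, which is feasible precisely because the motif is a hexamer — the
DP exists so the same machinery scales to user-supplied longer models and
finer bins.

Defaults for the relaxed mode: per-element p < 1e-3, both topologies, each
at its optimal and tolerated spacer.  The stringent mode implements the
published genome-scan rule instead: optimal spacer only and at most one
mismatched nucleotide per RE; DR-only by default (that is the scan that
found the isolated non-canonical sites), IR opt-in.

## Scanner geometry

Coordinates are 0-based half-open on the plus strand everywhere; GFF3
export converts to 1-based inclusive, BED stays 0-based.  `observed`
element words are always motif-local (reverse-complemented for minus-strand
matches), which is what makes one substitution table serve both
topologies.  An IR is its own reverse complement, so IR records carry
strand `"."`; reporting `+` or `-` would be arbitrary.  DRs are reported
per strand (a minus-strand DR reads `CCGCAA-N5-CCGCAA` on the plus
strand).  Pairs may share an element; all are emitted, and
`dedupe_pairs()` is a documented post-filter (best combined score, then
fewest mismatches, per overlapping cluster) rather than a silent one.
Windows containing `N` never match in either mode.

## The empirical affinity rules

`classify_pair()` encodes gel-shift measurements on a synthetic probe
panel as a deterministic rule cascade composed multiplicatively on an
apparent fold penalty (1 = optimal; 2 = roughly two-fold reduced; infinity
= no binding detected up to the 9.6 μM concentration ceiling):

* **Spacers** (tested n = 1–10 plus a full extra helical turn): DR — 5
  optimal, 4 tolerated at two-fold, everything else abolishes; IR — 4
  optimal, 5 tolerated, everything else abolishes.
* **Single substitutions**, in motif-local coordinates: a position-1
  transition (`T→C`) costs two-fold; the position-3 transversion `G→T`
  costs two-fold; the position-4 transversion `C→A` abolishes; every other
  tested transition abolishes; untested transversions default to abolished
  with an `untested` provenance flag.  Two or more substitutions in one
  element abolish.
* **Isolated single elements never bind** (`classify_single_re()`),
  regardless of score.

Reading elements motif-locally makes the central-GC asymmetry emerge
automatically: the *same* plus-strand mutation of the second element is
`G3→T` for a DR but maps to motif-local `C4→A` for an IR, so identical
chemical changes produce opposite outcomes on the two topologies, exactly
as measured.

Two recorded judgment calls: (i) the figure legend for the point-mutation
map lists a "no change" category, but the accompanying text states that
all point mutations reduced affinity, with only position-1 transitions
tolerated at about two-fold — the rule table follows the text and carries a
note; (ii) combinations of two tolerated penalties (e.g. tolerated spacer
plus a position-1 transition) were never measured jointly, so composed
finite penalties are flagged `extrapolated` in the provenance string.

`NONE` is categorical.  For simulation continuity the package also carries
the measured bound that abolished sites would need more than an 8-fold
higher concentration: `promoter_binding()` uses `8 × K0_reference` as the
numeric sentinel for sites that bind only through coupling.
`K0_reference` defaults to 1.2 μM — the lowest concentration at which
complexes with optimal probes were visible — and is documented as an
apparent scale, not a thermodynamic constant.

## Cooperative coupling

Quantitative titrations of an IR–DR core module are sigmoidal (apparent
n_H = 1.4, apparent K_d = 2.4 μM), and clusters of degenerate DRs that are
individually unbindable shift as a unit.  `promoter_binding()` captures
this with one promotion rule: a site classified `NONE` *purely through
sequence degeneracy* (its spacer is a valid topology spacer and each
element has at most `degenerate_max_mismatch = 2` mismatches) becomes
bindable when at least one other bindable-or-degenerate site lies within
`coupling_window = 60` nt.  Isolated degenerate sites stay unbindable;
spacer-violating pairs are never rescued.  The window default is a
judgment call — the span of the measured DR cluster is not printed — and
both knobs are config.  Promoters with at least two bindable sites get the
cooperative Hill coefficient (default 1.4); single-site promoters get
n_H = 1.  Whether IR+IR promoters share the same n_H was never measured;
the default applies it uniformly, flagged here.

## Hill fitting

`fit_hill()` fits θ(c) = c^n_H / (K_d^n_H + c^n_H) by bounded
Levenberg–Marquardt least squares to the per-concentration mean fraction
bound (matching the convention of averaging replicate gels; per-replicate
fitting is a flag).  The original analysis names only the software used,
so the optimization recipe is ours: K_d starts at the concentration
nearest half-occupancy by linear interpolation, n_H at 1; bounds are
n_H ∈ [0.3, 5] and K_d ∈ [0.001, 1000] μM.  All-zero or all-one data are
rejected as non-identifiable; non-convergence is reported in the fit
object, not thrown.  Noiseless round trips recover generating parameters
to 1e-6 across the bounded range (property-tested).

`bootstrap_ci()` case-resamples whole replicates and reports percentile
intervals.  A known limitation, measured during development by simulation:
with the three replicates typical of gel densitometry there are only ten
distinct resampled multisets, and percentile intervals undercover
substantially (on the order of 60% realized coverage for a 90% nominal
interval at noise SD 0.05; still modestly below nominal at 6–10
replicates).  The intervals are honest summaries of resampling spread, not
calibrated frequentist intervals at small replicate counts — treat them
accordingly.  The test suite therefore checks the bootstrap's
deterministic properties (seed reproducibility, degenerate width on
noiseless data, refusal below two replicates) rather than asserting
nominal coverage.

## Promoter architecture

`detect_core_promoter()` is deliberately simple plumbing: best-scoring
`TATAAT` (≤ 2 mismatches, extended −10 `TG` bonus) and `TTGACA` (≤ 3
mismatches) pair at 15–21 nt separation on the plus strand, with a score
floor (default 4 = at most one mismatch total without the TG bonus) below
which it reports none-found rather than guessing.  A lone perfect −10 is
reported flagged.  Users with real annotations should supply them and use
`validate_annotation()`.

`classify_architecture()` is positional: a class II site ends within
`prox_max = 5` nt of, or overlaps, the −35 hexamer; a class I site lies
wholly ≥ `dist_min = 20` nt upstream.  The published positions are
qualitative ("adjacent", "upstream"), so both thresholds are config with
these defaults.  Class III requires one of each; a core module (class II
site plus a bindable upstream partner within a 0–30 nt gap — the gap is
unconstrained by the data and configurable) with ≥ 2 further bindable DRs
upstream is `cluster_plus_core`.  Topology is recorded but not required
for the position classes, because synthetic promoter permutations showed
position and topology can be decoupled; the observation that a DR in the
class II position drives strong output is carried as the
`expected_activity` annotation, not as a hard rule.

## Synthetic data: what it does and does not emulate

Generators are pure functions of a `generator_config` (same config ⇒
byte-identical output).  Backgrounds are i.i.d. (or first-order Markov
with mild persistence) at GC 0.435, a *B. subtilis*-like composition — an
invented but realistic default, since no background model is prescribed.
`make_probe_panel()` rebuilds the 50-bp probe set: perfect DR and IR,
single element, negative control (the 12 RE nucleotides
position-randomized, then *verified* to contain zero stringent hits with
bounded reshuffling — a random shuffle can recreate a site by chance, and
a verified-or-fail fixture beats a silently flaky one), both spacer-swap
series, and the central-GC mutant quartet.  `simulate_titration()` adds
truncated-Gaussian noise on the fraction scale (simplest defensible
emulation of densitometry error; multiplicative noise is a flag); the
concentration grid defaults to a two-fold series 0.075–9.6 μM, an
emulation of the published gel series, not the exact experimental grid.
The truncation at 0 slightly inflates low-concentration means, which
biases fitted n_H a few percent low at noise SD 0.05 — visible in the
Monte-Carlo recovery tests and another reason bootstrap intervals for n_H
run below nominal coverage.

`make_promoter_fixture()` builds ~260-nt promoters with a planted core
promoter and the site layouts discussed above, redrawing the background
until a stringent scan recovers exactly the implanted truth, so fixtures
never carry accidental extra sites.

What passing tests on these fixtures shows: the scanner, rules, coupling
logic and fitter implement the stated model correctly.  What it does not
show: performance on real genomes, where backgrounds are not Markovian,
promoters are not planted, and binding is modulated by factors (DNA shape,
occupancy competition, supercoiling) outside this model.

## Problem sizes and numerical choices

The shipped test and acceptance runs use: 100 random 1-kb sequences for
scanner/oracle equivalence, the full 4096-hexamer enumeration for p-value
checks, 1000 seeded implant→scan round trips on 200-nt backgrounds, and
200 simulated titrations (noise SD 0.05, 3 replicates) for parameter
recovery, sizes chosen to exercise every code path at desk scale.
Tie-breaks are deterministic throughout: consensus derivation takes the
alphabetically first argmax; core-promoter detection keeps the first best
score; overlapping-pair deduplication orders by score then mismatch count.

## Known limitations

* The affinity table is exactly as coarse as the measurements behind it:
  three fold levels, single-substitution resolution, untested
  substitutions defaulting to no-binding.  It is a lookup model, not a
  free-energy model.
* Cooperative rescue is binary and windowed, not a partition function;
  interactions with RNAP subunits are carried only as the categorical
  class I/II labels.
* The core-promoter detector is a convenience heuristic for synthetic and
  well-behaved sequences, not a general σ-factor promoter predictor.
* Bootstrap intervals undercover at small replicate counts (above).
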