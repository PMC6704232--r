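---
title: "Methods: siRNA enumeration, strand selection, target accessibility and the HS/HE rule sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: siRNA enumeration, strand selection, target accessibility and the HS/HE rule sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaitrigger)
```

# Scope and model overview

`rnaitrigger` models the silencing potential of a long dsRNA trigger as
the joint outcome of three biophysically motivated filters applied to
every candidate siRNA it can produce: (i) does the siRNA have a
complementary site on a transcript, (ii) would RISC load the
mRNA-complementary (antisense) strand as guide, and (iii) is the target
site accessible, i.e. likely unpaired in the mRNA's secondary-structure
ensemble. The package deliberately models none of the downstream cell
biology (Dicer processing registers, 2-nt 3′ overhangs, RISC kinetics,
siRNA amplification); it ranks *candidate* siRNAs, it does not predict
absolute silencing strength.

# Candidate enumeration and matching

A trigger of length $n$ is represented by its sense strand (same
polarity as the target mRNA). All $n-k+1$ windows of length $k$
(default 21 nt, the canonical Dicer product length; 19–25 allowed) form
the candidate set; windows containing an ambiguity code are skipped and
counted, since no pairing energy is defined for them.

Matching searches both the sense k-mer and its reverse complement
against every transcript. Sense-strand occurrences (`sense-match`) are
the silencing-relevant ones — there the antisense strand can pair the
mRNA — but antisense-strand occurrences are also reported because dsRNA
triggers produce siRNAs of both polarities and constructs may be cloned
in either orientation; reports carry the orientation flag so either view
can be filtered.

Perfect matching is a hash join between query k-mers and an index of all
transcript k-mers. For 1–2 mismatches the k-mer is split into $m+1$
near-equal pieces; by pigeonhole any window within Hamming distance $m$
contains at least one exact piece, so exact piece occurrences seed
candidate placements that are then verified by full Hamming comparison
and deduplicated. Both paths are exact (no heuristics); the test suite
checks set equality against a naive sliding-window Hamming scan on
databases up to a few kilobases. Indels are intentionally out of scope:
RISC cleavage requires near-contiguous pairing, and the field's
convention for siRNA off-target screening is ungapped matching.

The default mismatch tolerance is 0. Published hit counts for this class
of tool (480 candidate siRNAs for a 500-nt self-matching trigger, 80 for
a 100-nt matching block) are consistent with perfect-match counting, and
perfect matches are the conservative choice for off-target *design*
decisions; tolerances of 1–2 are available for sensitivity analyses.

# Strand selection

Guide-strand choice is scored per duplex from two observations: RISC
favors strands with U or A at the 5′ terminus, and it favors the strand
whose 5′ end sits in the thermodynamically weaker duplex end.

End stability is the sum of the $t-1$ nearest-neighbor stacking free
energies ($\Delta G^\circ_{37}$, kcal/mol) of the terminal $t$
nucleotides read 5′→3′ into the duplex from the strand's 5′ terminus,
with $t = 3$ by default (configurable 2–5). The Watson–Crick stacking
table is the standard Xia/Turner parameter set, shipped as a plain-text
file (`extdata/rna_nn_stacks_dg37.tsv`) and overridable. Dangling ends
and terminal-AU penalties are deliberately omitted: the stack-sum is the
simplest definition that captures end asymmetry, is exactly testable,
and avoids committing to one folding engine's end corrections. The
asymmetry score is
$\Delta\mathrm{MFE} = \Delta G(\text{guide 5′ end}) -
\Delta G(\text{passenger 5′ end})$; positive values mean the guide end
is weaker, as desired.

Four flags result: the sequence rule (antisense 5′ ∈ {U, A}), the
opposite-end rule (sense 5′ ∈ {G, C}), the thermodynamic rule
($\Delta\mathrm{MFE} > 0$) and the strict rule
($\Delta\mathrm{MFE} > 1$ kcal/mol). The predicted guide is the
antisense strand if the sequence or thermodynamic rule favors it; the
sense strand if only the mirrored conditions hold; undecided otherwise.
Ties (both strands favored) resolve toward the antisense strand, the
conservative choice for off-target detection. The opposite-end G/C
condition is scored but required by neither mode by default, since it
reinforces rather than replaces the 5′-terminus rule.

# Target-site accessibility

The local accessibility probability (LAP) at position $i$ is the
Boltzmann probability that the stretch of $u = 8$ nt ending at $i$ is
completely unpaired, averaged over every folding window that contains
the stretch. Windows of length $W = 80$ nt slide by 1 nt; base pairs are
restricted to spans $\le L = 40$ nt. These defaults mirror standard
local-folding practice for mRNA accessibility screening: local windows
avoid spurious long-range pairs in ensembles of translated mRNAs, and
$u = 8$ approximates the seed-pairing footprint that must be open for
RISC to engage. A sequence shorter than $W$ folds as a single truncated
window; leading/trailing sub-$W$ windows are not added, so every
position's value averages ensembles of comparable size.

## Energy model

The ensemble is scored with a reduced nested secondary-structure model:

* pairs AU, UA, CG, GC, GU, UG; hairpin loops ≥ 3 unpaired nt;
* a pair stacked directly on its inner neighbor contributes the
  nearest-neighbor stacking $\Delta G^\circ_{37}$ (the same Watson–Crick
  table as strand selection; stacks involving a GU wobble use one
  representative constant, −1.3 kcal/mol, the approximate magnitude of
  published wobble stacks);
* a pair whose inner neighbor is unpaired closes a loop and contributes
  a constant penalty (default 4.5 kcal/mol — large enough that a 4-bp GC
  stem hairpin (≈ −10 kcal/mol of stacking) is strongly favored over the
  open chain at 37 °C while isolated lone pairs are suppressed);
* ambiguity codes cannot pair.

This is *not* the full Turner loop model: loop-length dependence,
special hairpins, coaxial stacking and dangles are collapsed into the
single closure penalty. Consequently absolute LAP values differ from
RNAplfold's, and no agreement with ViennaRNA output is claimed; the
algorithmic core — windowed McCaskill recursion, span restriction,
unpaired-stretch probability via inside/outside partition functions,
window averaging — is the faithful part, and it is verified to
$10^{-9}$ against exhaustive structure enumeration under the same
energy model for sequences up to 18 nt.

## Computation

Per window, an inside recursion computes interval partition functions
$q(i,j)$ and pair-conditioned $q_b(i,j)$; an outside recursion computes
$\hat q(i,j)$, the weight of everything outside a pair. The probability
that a stretch $[a,b]$ is unpaired decomposes exactly into the
no-enclosing-pair term $q(1,a-1)\,q(b+1,n)/Z$ plus, for every possible
innermost enclosing pair $(i,j)$, the term
$\hat q(i,j)\, e^{-P/RT}\, q(i+1,a-1)\, q(b+1,j-1)/Z$ (the enclosing
pair necessarily closes a loop). The recursions are implemented in C++
(Rcpp); a 500-nt transcript profiles in well under a second, so design
runs on typical cDNA databases are interactive.

## Stretch-to-position convention

LAP values are stored at the **3′-most position** of the $u$-stretch
(positions $< u$ are `NA`). This off-by-$u$ convention is the classic
failure mode when comparing accessibility tools; it is fixed here,
documented, and covered by tests. A target site's scalar accessibility
is the **maximum** defined LAP over the $k$ positions of the site: a
site is considered usable if it contains at least one open stretch for
nucleation, which matches the view that peak height above the threshold,
not the mean, is what matters. Mean-over-site is the plausible
alternative; max was chosen and is applied consistently.

# HS and HE modes

* **HS (high-sensitivity, off-target search)**: a duplex counts when
  the predicted guide is the antisense strand (sequence rule OR
  thermodynamic rule). No accessibility is computed in this mode — an
  inaccessible off-target site today may be accessible in another
  transcript context, so accessibility must not veto off-target
  warnings (and skipping it keeps off-target scans fast; the pipeline
  never computes profiles in HS mode).
* **HE (high-efficiency, design)**: a (siRNA, target-site) pair passes
  only the full conjunction — sequence rule AND thermodynamic rule AND
  $\Delta\mathrm{MFE} > 1$ kcal/mol AND site LAP ≥ 0.1, on a
  sense-match hit. HE ⊂ HS by construction.

The exact boolean composition of "stricter strand selection" is the one
genuinely open design point in this architecture; the conjunction above
is this package's documented choice, made because each listed rule is
individually necessary under a "stringent" reading, and it preserves the
HE ⊆ HS nesting that any two-mode design requires. Classification is
per-(siRNA, transcript): the same siRNA can be HE for one target and
not for another.

## Zoning and region recommendation

A trigger position is zoned **red** when at least one siRNA covering it
has an HS-mode hit (either orientation) on a transcript outside the
declared main-target set — HS, not raw hits, because a hit whose duplex
would not load the guide strand is not an off-target risk; either
orientation, because sensitivity is the purpose of the red zone. The
recommended region is the window of `region_length` (default 100 nt,
a practical cloning-fragment granularity) maximizing the number of HE
siRNAs fully contained in it, subject to zero red positions, ties going
to the 5′-most window; if no red-free window contains an HE siRNA there
is no recommendation.

# Synthetic validation constructs

The generator reproduces the two construct families used to validate
this class of predictor:

* **Molecular-clock constructs**: `round(p·len/100)` distinct positions
  drawn uniformly without replacement, each reassigned a uniform random
  base *including the original* — so expected identity is
  $100 - 0.75p$ percent, and a fully randomized construct retains ≈ 25%
  identity. Identity here is ungapped positional identity; published
  identity figures for heavily diverged constructs of this kind run
  higher (e.g. ≈ 34% at full randomization), consistent with
  alignment-based identity, but the positional definition is kept
  because it is analytic and seed-reproducible.
* **Window constructs**: one block of the target (default 100 nt)
  copied coordinate-true into a fully randomized backbone.

What the generator emulates: sequence divergence under neutral drift and
block-local homology, i.e. exactly the combinatorics of k-mer survival
(a single substitution kills up to $k$ overlapping siRNAs, which is why
perfect-match counts collapse long before identity does). What it does
not emulate: real transcriptome composition, codon structure, repeat
content, UTR structure, expression levels, or any phenotype. Green test
results therefore validate the combinatorial and thermodynamic machinery
on its own terms, not silencing predictions for real genes.

# Numerical and engineering choices

* All randomness flows through explicit integer seeds; reports are
  byte-deterministic given inputs and seed (numbers are written with
  fixed formatting, no timestamps).
* Coordinates are 1-based inclusive everywhere a user sees them.
* Partition-function arithmetic is done in linear (non-log) space;
  with $W \le 80$ and $L \le 40$ the Boltzmann sums stay far below
  double-precision overflow. Very large windows (≫ 200 nt) would need
  rescaling that this implementation does not include.
* Degenerate inputs: triggers shorter than $k$ give an empty report
  with a warning; sequences shorter than $u$ are an error for
  accessibility; empty databases are an error; ambiguous bases cannot
  pair and never enter siRNA windows.
* One property claimed plausible a priori — that raising the loop
  penalty raises *every* LAP value — is false in this model: penalizing
  loop closures can concentrate the ensemble on a single dominant stem
  and lower LAP at stem positions. The test suite asserts the corrected
  ensemble-level statements (mean LAP rises; a prohibitive penalty
  recovers the open chain everywhere).

Problem sizes in the shipped tests were chosen for tight feedback
cycles: oracle equivalence for the matcher runs on ~1–3 kb databases,
exhaustive-enumeration checks on ≤ 18-nt sequences, Monte-Carlo
calibrations on 100–500 seeds of 500-nt constructs; the 500-nt /
21-mer study conditions themselves are used unreduced.

# Known limitations

* The reduced energy model trades absolute accuracy for testability;
  LAP values are comparable within a run, not across tools.
* The strict-rule composition of HE mode is a documented reconstruction
  choice (see above), not a community standard.
* No weighting of off-targets by expression or tissue; every database
  transcript counts equally.
* Ungapped matching only; a bulged near-complementary off-target site
  is invisible to the matcher.
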