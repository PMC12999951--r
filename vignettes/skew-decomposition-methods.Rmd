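---
title: "Methods: skew decomposition, SkewI, div fitting and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skew decomposition, SkewI, div fitting and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, conventions and numerical choices behind
`repliskew`, and what the test suite's green results do and do not establish.

## The skew model

For a window of the reference (plus) strand, the GC skew is
$s = (G - C)/(G + C)$, where $G$ and $C$ are base counts in the window.
Windows are consecutive, non-overlapping, of fixed size (default 4,096
bases); the trailing partial window is discarded rather than rescaled, so
every value is computed from the same number of candidate positions and the
cumulative curve $S_k = \sum_{j \le k} s_j$ has homogeneous increments.
Windows whose class has no G or C at all are assigned skew 0, not `NA`:
keeping the grid dense is what makes the five class curves and the GSB curve
commensurable point by point.

Five position classes partition every position exactly once: `codon1`,
`codon2`, `codon3` for positions of coding bases (frame taken from the
annotation's phase, codons read 5′→3′ on the coding strand, so a minus-strand
CDS is labelled right to left), and `noncoding` for everything else; `total`
counts all positions. Where CDS overlap, a position belongs to the longer
feature (ties to the smaller start coordinate), and opposite-strand overlap
zeroes the position's strand cover; this is an arbitrary but deterministic
rule — annotation overlap is rare enough that any reasonable rule gives
indistinguishable curves, and determinism is what matters for
reproducibility.

**Strand convention.** Sub-skews count the *reference-strand* base at each
labelled position, not the codon string of the gene. This is deliberate: a
minus-strand gene then contributes the complement of its coding-strand
preferences, so codon-class skews respond to gene orientation — which is
exactly the coupling between gene strand bias and codon-position skew the
correlation analysis measures. Counting gene-oriented bases
(`gene_oriented = TRUE`, provided for sensitivity analysis) makes the
codon-class skews orientation-blind and destroys that coupling.

The gene strand bias (GSB) counter adds +1 at positions covered only by
plus-strand genes, −1 at positions covered only by minus-strand genes, 0
elsewhere, and is sampled at the last position of each complete window. The
sampling choice (window ends rather than means) is one of several defensible
readings; since the curve is nearly linear within a window, the Pearson
correlations it enters are insensitive to it.

## SkewI

Window-level sign agreement with an ideal two-replichore pattern:
$A(r) = \frac{1}{n}\left|\sum_i s^{\mathrm{sign}}_i p_i(r)\right|$ with
$p_i(r) = +1$ on the first $\lfloor n/2 \rfloor$ windows after circular
rotation $r$ and $-1$ otherwise, maximised over all $n$ rotations. Zero-skew
windows get sign 0 so they dilute rather than bias the score. The default
window is 20,000 bases — the convention of the skew-index test this
implements, and intentionally independent of the 4,096-base cumulative-curve
window; both sizes are recorded in the output. The equal-halves template is a
fixed design choice: unequal replichores are the business of the div fit, not
of SkewI. Because the statistic is a maximum over rotations, its null value
on random signs is well above zero and grows as the window count shrinks —
with 52 windows (1 Mb at 20 kb) the null mean is ≈ 0.22 — so SkewI values
below ≈ 0.25 should be read as "no detectable two-replichore signal", not as
small-but-real signal. The QC rule (at least 500,000 bases and
annotated-complete) flags inputs for which the index is known to mislead;
the value is still reported, flagged.

## The div fit

The cumulative total-skew curve of a circular two-replichore genome is
modelled as intercept + per-window drift $d\,x$ + a closed triangular wave:
slope $a_1 > 0$ from the origin window over an arc of $\mathrm{div}\cdot n$
windows, slope $a_2 < 0$ back, continuous at both breakpoints with
$a_1\,\mathrm{div} + a_2\,(1-\mathrm{div}) = 0$. The drift term absorbs net
genome-wide skew (global parity violation) so that replicons whose curve is
a tilted triangle still fit; `div` is read off the rising-arc length.

Numerics: for each ordered breakpoint pair the model is linear in
(intercept, drift, amplitude) and solved by least squares; the pair grid is
searched exhaustively (all pairs when `n ≤ 64` windows, otherwise 64 coarse
candidates per axis — well under the 512 cap — followed by exhaustive local
refinement one coarse step around the best pair). The objective is
piecewise-linear in the breakpoints, so the grid search is exact on its grid
and immune to local minima; the refined answer is within one window of the
continuous optimum. One genuine degeneracy exists: a breakpoint at the edge
of the linearised domain has an unobservable kink, and a one-window-shifted
triangle plus compensating drift fits equally well. Near-ties in residual sum
of squares (relative tolerance $10^{-9}$) are therefore broken toward the
smaller |drift| — among equally good fits, prefer the one explaining the most
by replication. Fits whose best `div` collapses to the grid boundary are
flagged `degenerate`. Linear replicons are refused unless forced, because the
closed-circle constraint is meaningless for them.

## Correlation and aggregation

Per replicon, the GSB curve and the five cumulative skew curves share one
window grid, and each pairing gets a Pearson correlation — computed on the
cumulative curves as plotted, not on per-window values (a flag switches, for
sensitivity analysis; per-window correlations are much noisier but reach the
same sign conclusions). A class whose curve is constant (e.g. no non-coding
positions) yields `NA`, never a fabricated 0. Class summaries report mean,
sample SD ($n-1$), CV as $100\,\mathrm{SD}/|\mathrm{mean}|$ (the absolute
value matters for near-zero means), $n$, and the fraction of replicons with
PCC > 0.5. Post-hoc multiplicity after Kruskal–Wallis or ANOVA uses Holm
adjustment — a safe dominant choice where the convention is merely
"corrected".

## The synthetic world

`simulate_replicon()` generates the *equilibrium composition* a replication-
and selection-shaped genome would have, not an evolutionary trajectory —
the analysis consumes only composition, so forward simulation would add
runtime without adding verification power. The stated world:

- a circle (default 1 Mb) with one origin; the reference strand is the
  leading strand on an arc of `leading_fraction` (default 0.5) — this is the
  ground-truth `div`;
- genes tile the circle without overlap, lengths geometric with mean 300
  codons, to a coding density of 0.85 — typical prokaryotic values;
- each gene is co-oriented with its local leading strand with probability
  `p_lead` (default 0.75, in the range observed for bacterial chromosomes);
- coding positions draw from codon-position weight vectors on the coding
  strand (defaults: position 1 G-favoured at 0.34, position 2 T/A-favoured
  with C > G, position 3 uniform — the genetic-code-level preferences in
  qualitative form); intergenic positions draw from a 50% GC background;
- strand-specific mutational bias: with probability `beta` (default 0.08) a
  leading-strand C becomes G (equivalently, on the arc where the reference
  strand lags, a reference G becomes C). At codon positions 1–2 the
  probability is attenuated by 0.25, encoding "selection resists mutation"
  without a codon-fitness model. The `beta` default is illustrative — chosen
  so the default genome sits in the strongly-skewed regime while `beta = 0`
  gives the null — not an estimate of any organism's mutation pressure.

Limitations a green test does not cover: real genomes have operons (gene
orientations are correlated, not i.i.d.), horizontally transferred islands,
inversions that scramble the skew, multiple or relocated origins, rRNA/tRNA
genes, and annotation errors. The generator also writes all genes in frame 0
and never wraps a gene across the origin. Green acceptance therefore
establishes that the estimators recover the parameters of *this* generative
model, and that the code's invariants (partition, antisymmetry, equivariance,
determinism) hold — not that any biological conclusion is correct.

## Degenerate inputs and edge rules

- `N` bases keep their position labels but are excluded from all G/C counts.
- Features shorter than one codon after the frame offset contribute no codon
  labels (but still contribute strand cover).
- A constant curve cannot be min-max normalised; `normalize_curve()` returns
  the midline with a warning.
- Zero-variance inputs to `pearson()` are an error, not `NA`: silent `NA`
  propagation through aggregation was judged worse than a loud failure.
- Batch runs isolate failures per genome and report them; a batch aborts only
  when every row fails.

## Known limitations

GenBank parsing covers the subset needed here (LOCUS topology, DEFINITION
completeness, CDS with `complement()`/`join()` and `/codon_start`); exotic
location operators are not supported — use GFF3 for anything unusual.
The div model is single-origin by construction; multi-origin chromosomes get
whatever single triangle fits best, typically with a large residual, and
should be judged by `rms_residual` and the `degenerate` flag. SkewI is
reported for QC-failing replicons but should not be compared across QC
states.
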