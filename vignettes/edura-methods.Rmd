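---
title: "Methods: axis-systematic structure and digital/analog control in bacterial regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axis-systematic structure and digital/analog control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Bacterial gene regulation operates through two logically distinct
infrastructures: the transcriptional regulatory network (TRN), a directed
graph of transcription-factor genes pointing at their targets ("digital"
control), and the spatial organization of the circular chromosome, whose
supercoiling state and nucleoid-associated proteins modulate expression of
chromosomal neighborhoods ("analog" control). This package implements a
joint structural and functional analysis of the two: a rotation statistic
that asks whether the chromosomal embedding of the TRN is systematic with
respect to the replication axis (Ori–Ter), null models to calibrate it,
connectivity z-scores that quantify digital and analog control strength in
differential-expression contrasts, and a decision-tree feature analysis
that asks which gene properties predict expression changes. A synthetic-data
module generates genomes, networks, binding sites and contrasts with known
ground truth so that every stage is testable without database downloads.

## Coordinates and graphs

All positions live on a circle of length $g$ base pairs (default
4,641,652, the *E. coli* K-12 chromosome). Coordinates are 0-based and all
arithmetic is mod $g$; distances are shortest-arc
(`circular_distance()`, always in $[0, g/2]$). A gene's center is the mean
of its start and end; genes wrapping across the origin use the midpoint of
the forward arc, reduced mod $g$ — the plain average formula silently
assumes start ≤ end, and the wrap rule is the unique continuous extension.
Centers are kept as reals (half-integers occur) and compared without
rounding.

The TRN is read from a two-column regulator/target table; duplicate edges
collapse, edges to genes missing from the annotation are dropped with a
warning, and self-loops (autoregulation) are retained at load time — each
analysis states its own exclusion rule. The gene proximity network (GPN)
links genes whose centers are within $T_\mathrm{GPN}$ (default 20 kbp,
boundary inclusive). Operon-level graphs collapse genes to operons,
dropping within-operon regulation.

## The axis-rotation statistic

Fix a candidate axis by its Ori end $a$; the Ter end is $a + g/2$. The
axis splits the circle into two arms; "right" is the semicircle of
increasing coordinates from Ori (either chirality is internally
consistent; this one is fixed and documented), and centers exactly at Ori
or Ter count as right — a measure-zero tie resolved deterministically.
Every non-self-loop edge then falls in one of six categories: along-arm
edges pointing away from (+) or towards (−) Ori on the right or left arm
($r_+, r_-, l_+, l_-$), and cross-arm edges ($rl$, $lr$). Self-loops have
no direction along an arm and are excluded from the categories but
tallied. Same-arm edges whose endpoints are equidistant from Ori count as
"+" (again measure-zero, deterministic).

Two asymmetries summarize the counts $n(\cdot)$:

$$A_\pm^r = \frac{n(r_+) - n(r_-)}{n(r_+) + n(r_-) + n(rl)},$$

with the mirrored $A_\pm^l$ using $n(lr)$ in the denominator, and

$$A_{\leftrightarrow\updownarrow} =
 \frac{n(lr) + n(rl) - n(l_+) - n(l_-) - n(r_+) - n(r_-)}
      {n(lr) + n(rl) + n(l_+) + n(l_-) + n(r_+) + n(r_-)}.$$

Zero denominators are recorded as 0 with an `undefined` flag so curves
stay aligned across positions.

As the axis rotates, categories transform smoothly into one another
($l_+ \to rl \to r_-$, and so on), so the counts — and the two arm
asymmetries — are strongly correlated along most of the scan. A
*systematic* arrangement of edges with respect to one particular axis
disrupts those correlations there; the detector therefore computes a
windowed Pearson correlation of $A_\pm^r$ and $A_\pm^l$ along the scan and
returns the position of its minimum (ties go to the smallest coordinate).

**Exact scan representation.** Edge categorization is piecewise constant
in $a$ between "breakpoints" — gene centers and their antipodes — so
scanning at the midpoints of consecutive breakpoints represents every
curve exactly; a uniform grid is available for plotting. This is tested
against brute-force categorization at uniformly spaced positions.

**Randomized baseline.** The asymmetry curves of *any* embedded graph
carry a geometry-driven component (gene density, degree structure). The
systematic part is isolated by subtracting the mean curves of
degree-preserving switch-randomized copies of the graph, evaluated at the
same positions with gene positions held fixed (default ensemble size 100).

**Windowing.** The window is the smallest odd integer covering 10% of scan
positions (minimum 11). Calibration on planted-axis networks (below)
showed that substantially narrower windows (e.g. 5%) leave so few
category transitions per window that the correlation minimum is
noise-dominated and mislocalizes in a sizable fraction of replicates;
at 10% localization is reliable without blurring the drop beyond the
detection tolerance.

**Orientation.** The correlation curve is exactly invariant under a
half-turn of the axis (the category-swap identities
$n(r_+)(a) = n(l_-)(a + g/2)$ etc. are exact), so the drop fixes only the
axis *line*. The Ori end is disambiguated as the candidate around which
the raw arm asymmetries are more positive — the end from which along-arm
edges dominantly point away, which is the arrangement the method targets.
`detect_axis(orient = FALSE)` disables this step.

Both the raw and the baseline-subtracted asymmetries can feed the
correlation; the default is baseline-subtracted when available.

## Null models

**Switch randomization** rewires directed edges by double-edge swaps
$(a\!\to\!b, c\!\to\!d) \Rightarrow (a\!\to\!d, c\!\to\!b)$, rejecting
proposals that would create a self-loop or duplicate edge; in- and
out-degrees are preserved exactly. The step count (default 5000) counts
*accepted* swaps, so mixing does not depend on the rejection rate; a cap
of 100× the step count on attempts guards against livelock (an error past
the cap). Existing self-loops are excluded from the moves entirely, which
keeps the self-loop count invariant.

**Systematic random networks** plant a known axis: $N/2$ gene positions
drawn uniformly per arm, then each of the six category counts realized by
drawing distinct ordered gene pairs uniformly among the pairs of that
category. Recounting categories at the planted axis reproduces the
request exactly (a hard postcondition, tested over random
specifications). These networks calibrate the detector: with the biased
counts 120/30/120/30/20/20 on 400 nodes the detected axis falls within
$g/50$ of the planted one in ≥ 90% of seeded replicates.

## Digital and analog control strengths

A contrast is a per-gene logFC column. Differential calls use strict
inequalities — `absdge` ($|logFC| > T_{FC}$), `posdge`, `negdge` — with
default $T_{FC} = 2.5$; missing values are never called. The *effective*
TRN (or GPN) of a contrast is the induced subgraph on its called genes.
With $N_\mathrm{connected}$ the nodes of non-zero degree in that subgraph
and $N_\mathrm{isolated}$ the rest, the control ratio is
$R = N_\mathrm{connected} / N_\mathrm{isolated}$. The denominator is
clamped at 1: the source description gives no rule for fully connected
effective networks, and the clamp is the minimal continuous completion; a
`statistic = "connected"` option exposes the raw count variant instead.

The control-type confidence (CTC) is the z-score of $R$ against a null
that places the same number of genes at random — on the TRN node set for
digital control, on the genome's gene positions for analog control
(resampling the existing gene positions preserves the empirical gene
density; a uniform-position variant of the question would change the
analog null's density profile, and resampling is the reading adopted).
Null mean and SD come from 10,000 draws by default. A zero-variance null
(e.g. a complete base graph) yields CTC 0 with a `degenerate` flag.
Calibration: for called sets themselves drawn from the null, CTC is
standard-normal to Monte-Carlo accuracy; this is checked empirically at
$n_\mathrm{null} = 10{,}000$.

`control_scan()` computes the digital/analog CTC pair per contrast and
their Spearman rank correlation (average ranks on ties) across contrasts;
`parameter_sweep()` repeats it over a $T_{FC} \times T_\mathrm{GPN}$ grid.
Operon-level calls follow the any-member rule; in the single-signed modes
an operon with members past both thresholds triggers a conflict warning
and is assigned by its largest-|logFC| member. Because that rule needs
both tails, `operon_calls()` takes the contrast matrix rather than a
finished single-mode call set.

## Decision-tree feature analysis

Each gene carries nine features: distance to Ori (`pos_oric`, unsigned —
it captures position along the Ori–Ter axis; a signed variant would break
the axis symmetry the analysis is about); crp/hns/fis binding-site counts
within ±50 kbp (boundary inclusive); the number of called GPN neighbors
(`gpn_cont`); the number of called direct TRN regulators (`trn_cont`);
and three binary flags for hns/fis/crp being a direct regulator. The
feature list's "ancestors" wording is ambiguous between direct
predecessors and the transitive closure; direct predecessors are the
default for consistency with the three factor flags, and
`ancestors = TRUE` switches to the closure.

The tree is a standard impurity-greedy binary classifier grown to purity:
at each node the (feature, threshold) pair maximizing the entropy gain
(natural log; Gini available) over all midpoints of consecutive distinct
values is chosen, with deterministic tie-breaks (lowest feature index,
then lowest threshold; `x ≤ threshold` goes left). Identical feature
vectors with different labels stop growth at an impure leaf, where
perfect classification is unattainable. Splits are verified against an
exhaustive search oracle on small datasets. Feature importance is mean
decrease in impurity: each internal node contributes its sample count
times its impurity reduction to its split feature, normalized to sum 1.
Because MDI is biased toward high-cardinality features, the reported
quantity is the *shuffle-corrected* importance: the raw importance minus
its mean over label permutations (default 100) that preserve class
counts. Corrected values can be negative; for labels independent of all
features they center at zero. Finally, each corrected-importance column is
rank-correlated with the analog and digital CTC across contrasts, with
the two CTC columns appended so their mutual anti-correlation appears in
the same table.

## The synthetic study system

The generators emulate the statistical structure the analyses consume,
not the biology that produced it:

- `generate_genome()`: distinct integer gene positions, uniform or
  clustered (wrapped-normal mixture) to mimic nonuniform gene density.
- `generate_trn()`: a hub-dominated directed graph — a few regulators
  emit most edges, giving the disassortative degree structure typical of
  regulatory networks; exact edge count, no duplicates or loops.
- `generate_binding_sites()`: uniform sites, or sites jittered around a
  factor's targets (the clustered landscapes of nucleoid-associated
  proteins).
- `generate_contrasts()`: each contrast's called set arises from seed
  events that are digital with probability $\lambda$ (a random regulator
  plus each TRN successor with probability $p_d$) and analog otherwise
  (genes within $w_a$ of a uniform focal position, each with probability
  $p_a$), plus background calls at rate $\rho$. Called genes get
  $\mathrm{sign} \cdot N(\mu_{FC}, \sigma_{FC})$ resampled above
  $T_{FC}$; uncalled genes get $N(0, \sigma_0)$ truncated below it, so
  threshold calls equal the ground truth exactly and generator tests stay
  decoupled from threshold tests.

Default sizes are desk scale: 2000 genes on 1 Mbp, 5000 TRN edges, 40
contrasts per mixture level. The contrast defaults
($n_\mathrm{events} = 2$, $w_a = 10$ kbp, $p_a = 0.3$, $p_d = 0.7$,
$\rho = 0.001$) size called sets at roughly 1–5% of genes. That scale is
deliberate: the clamped ratio statistic saturates when the expected
number of called neighbors per called gene, $k \cdot \bar d / n$,
approaches or exceeds 1 — then both observed and null effective networks
have almost no isolated nodes and the z-score degenerates. The defaults
match that dimensionless load to the regime of real gene-level analyses
(of order 0.9), at which the digital CTC rises monotonically in
$\lambda$, the analog CTC falls, and the two anti-correlate across mixed
contrasts (Spearman ≈ −0.7 at these sizes).

What the generator does **not** emulate: operon structure coupled to the
call mechanism, realistic TRN motif content beyond hubbiness, platform
noise or normalization artifacts of compendium expression data, and any
genuine axis-systematic edge placement in `generate_trn()` (only
`generate_systematic_network()` plants one). Passing tests therefore show
the *methods* behave as designed on data with known ground truth, not
that real data will show the same effect sizes.

## Numerical choices and degenerate inputs

- Inclusive boundaries throughout (GPN threshold, site window).
- Zero-denominator asymmetries → 0 with flags; zero-variance correlation
  windows → 0 with flags; zero-variance nulls → CTC 0 with a flag.
- The ratio denominator clamps at 1; empty effective networks give
  $(0, 0, 0)$.
- All randomized components take explicit seeds; generators are
  byte-stable under a fixed seed, and pipeline substreams derive from the
  single configured seed.
- Scans chunk their position × edge matrices (1024 positions per chunk)
  to bound memory on genome-scale graphs.

## Problem sizes used by the test suite

The suite exercises the statistical claims at sizes chosen to keep a full
run at desk scale: planted-axis recovery over 20 replicates with a
20-graph baseline ensemble each (the function default is 100); CTC
calibration with 200 null-drawn sets of 150 genes at 10,000 null draws on
a 500-node, mean-degree-5 graph (that subset size makes the discrete
ratio distribution near-Gaussian, so the SD of 200 z-scores is a stable
estimate); the mixture sweep with 40 contrasts per $\lambda \in \{0,
0.25, 0.5, 0.75, 1\}$ at 2000 null draws per CTC (the z-score's
Monte-Carlo error at 2000 draws is far below the between-contrast spread
that drives the sign and monotonicity conclusions, while calibration
itself is verified separately at 10,000); and 40 pure-analog plus 40
pure-digital contrasts for the importance analysis at the default 100
shuffles.

## Known limitations

- The detector reports a single global correlation minimum; multiple
  systematic axes would need the full curve (returned as an attribute).
- MDI-based importances, even shuffle-corrected, remain tree-specific;
  no ensemble averaging is performed (deliberately — the object of study
  is the single tree's feature use, not classification quality).
- The analog null resamples gene positions, so it conditions on the
  empirical gene density; `analog_ctc_uniform()` provides the
  uniform-placement variant for checking that dependence.
- Operon-level control analysis uses `operon_calls()`; feature-level operon
  aggregation (`operon_feature_table()`, member-mean features with
  any-member labels) is an extension beyond the gene-level analysis and
  is flagged as such.
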