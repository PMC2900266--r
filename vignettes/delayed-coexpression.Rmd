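---
title: "Detecting simultaneous and time-delayed co-expression with delaycor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting simultaneous and time-delayed co-expression with delaycor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaycor)
```

## The model

Two expression profiles measured over the same $N$ conditions are
*co-expressed* when their rank correlation is larger than chance.  With
an ordered condition axis (a time course or life-cycle series) the
correlation may peak not at lag zero but when one profile is shifted by
$t$ conditions relative to the other.  The co-expression score of a
shifted pair is the Spearman rank correlation of the truncated
overlap:

$$\gamma_t = 1 - \frac{6\sum_i d_i^2}{L^3 - L}, \qquad L = N - t,$$

with $d_i$ the rank differences over the overlap, computed either on
$(x_{t+1},\dots,x_N)$ vs $(y_1,\dots,y_{N-t})$ (the $x$ profile trails)
or on the mirror image (the $y$ profile trails).  With tied values we
use average (fractional) ranks and the product-moment correlation of
the ranks; this is the standard generalization and reduces exactly to
the displayed formula when ties are absent, which the test suite
verifies bit-for-bit against a naive sort-based implementation.  Rank
correlation is used instead of Pearson correlation because biological
couplings are often monotone but not linear, and because it is
invariant under any strictly increasing transformation of either
profile (a property the suite checks directly).

The *delay scan* evaluates $t = 0$ and $t = 1,\dots,t_{\max}$ in both
directions, $2 t_{\max} + 1$ scores in total, and predicts the delay as
the shift with the largest $|\gamma|$.  Negative correlation counts as
co-expression — strongly anti-correlated profiles are biologically
coupled — hence the selection on $|\gamma|$.

## The significance procedure

The null hypothesis is *no co-expression at any shift*.  Each
permutation replicate independently permutes the condition order of
both profiles (a shared permutation would preserve the pairing and
leave $\gamma_0$ unchanged, which cannot serve as a null), re-runs the
entire delay scan, and records the best $|\gamma_0|$.  Five hundred
replicates form the null distribution of the maximum, so the selection
step of the observed statistic is mirrored in the null.  The p-value
uses the add-one Monte-Carlo convention
$p = (1 + \#\{|\gamma_0| \ge |\gamma|\})/(n_{\mathrm{perm}} + 1)$,
which never reaches zero and is valid for any replicate count, and is
then Bonferroni-adjusted by $m = 2 t_{\max} + 1$, the number of shift
hypotheses examined for the pair (adjusting instead across all pairs
would make rejection impossible at any realistic permutation count,
since $p \ge 1/501$).  Significant pairs are classed `simultaneous`
or `delayed_k` by their best shift; testable non-significant pairs are
`none`.  A profile that is constant over the jointly observed
conditions has no defined rank correlation; such pairs are reported as
`untestable` and excluded from every denominator, never coerced to
$p = 1$.

Missing values are excluded pairwise (an index missing in either
profile is dropped from that comparison); no imputation is performed.
Every shift requires at least 3 overlapping conditions, which caps
$t_{\max}$ at $N - 3$ — with six conditions, delays up to three.

## Power and its limits on short courses

The maximum-statistic null has an important consequence on very short
courses.  At a 3-point overlap the Spearman score of two random
permutations is $\pm 1$ with probability $1/3$ each side combined, so
when the scan includes 3-point shifts a permuted pair reaches
$|\gamma_0| = 1$ more often than not across its seven shifts.  With
$N = 6$ and $t_{\max} = 3$ the null distribution of the maximum
therefore saturates at 1, and *no* pair — not even a perfect noiseless
coupling — can reach significance.  This is not a defect of the
implementation but a property of short time courses: six points spread
over seven shift hypotheses simply do not carry enough rank information
for a selection-corrected test.  Any procedure that does report
abundant significant delayed co-expression on a six-point design must
be comparing shifted scores against a full-length (uncorrected) null,
which is strongly anticonservative for the truncated overlaps.  We keep
the valid, conservative construction: the packaged calibration run
(1000 simulated null pairs, 500 permutations each) rejects at a rate of
zero, comfortably within the nominal 0.05 bound, and the power
demonstrations in the test suite use 12-condition courses, where all
overlaps retain at least nine points and noiseless planted couplings
are rejected with the minimum attainable p-value ($1/501$, adjusted
$0.014$).

The same geometry limits *lag identification* under noise.  A single
noise-induced transposition of adjacent ranks at a 3-point overlap
turns $|\gamma| = 0.5$ into $1.0$, so with four short-overlap shifts in
the scan a spurious shift overtakes the planted one in roughly a third
of the pairs at 25% relative noise; the acceptance run measures ~70%
joint (lag, sign) recovery at six conditions, against 100% recovery at
zero noise.  Users analysing six-stage designs should read the delay
scan as exploratory ranking; confirmatory delay classification needs
longer series.

## The synthetic data generator

`simulate_coexpression()` produces paired mRNA/protein matrices with a
known truth table so that every downstream stage is testable without
external data.  Each pair draws a class (simultaneous, delayed by
1..$t_{\max}$, or null), a direction (mRNA leads or protein leads,
equally likely), a sign (positive with probability 0.8 by default,
emulating the positive skew of observed correlation distributions), and
a strictly monotone link (identity or cubic, equally likely).  The
driver series is a smooth random walk for ordered data — rank methods
need no particular marginal, but trends make lags meaningful — and
i.i.d. Gaussian for unordered panels.  The follower row is the
lag-shifted, linked, sign-flipped driver plus additive Gaussian noise;
both rows are standardized to unit spread before noise, so `noise_sd`
is relative to the signal.  A configurable fraction of rows is rounded
to one decimal to exercise tie handling.

Coupled pairs are rejection-sampled for *identifiability*: at zero
noise the planted shift must be the unique maximizer of $|\gamma|$,
with $|\gamma| \ge 0.95$ at the planted shift (after tie rounding) and
every competitor at least 0.1 below it.  Offset windows of a short
random walk coincide in rank order often enough that, without this
constraint, the planted lag would sometimes be unidentifiable even
without noise, and "recovery" would be ill-defined.  The constraint is
a property of the ground truth, not of the analysis: the scan never
sees it.

Defaults mirror the six-stage life-cycle study shape (2502 gene pairs,
6 ordered conditions, $t_{\max} = 3$, class proportions taken from the
observed same-gene class counts); an unordered 86 × 59 configuration
emulates the cancer-panel shape.  The generator does **not** attempt to
model transcription/translation kinetics, stage-specific variance,
probe-level measurement error, or correlated noise across genes — so
green synthetic tests certify the statistical machinery, not the
biology of any real dataset.

## Group construction and summaries

Four comparison groups are analysed: (i) sampled mRNA–mRNA pairs,
(ii) the same pair set evaluated on the protein matrix — using one pair
set at both levels is what makes the transfer matrix well-defined —,
(iii) sampled cross-level pairs of different genes, and (iv) all
same-gene mRNA–protein pairs.  Sampling is uniform without
replacement, excluding self-pairs within a level and same-gene pairs
across levels; default sizes are ten within-level and twenty
cross-level pairs per gene (25020 and 50040 for 2502 genes), or all
pairs when the gene set is small.

Class-count tables report counts and percentages over testable pairs,
rounded half-up to two decimals; the composite time-delayed percentage
is the sum of the rounded per-delay cells, matching how such tables
are conventionally read.  The transfer matrix cross-tabulates each
pair's class at the transcript level against the protein level, by
default at the pooled granularity {simultaneous, time-delayed, none};
its diagonal fraction measures conservation, and the block excluding
`none` measures co-expression at both levels.  Group contrasts use the
Pearson chi-square without continuity correction on the 2 × k count
table, $df = k - 1$.

## Numerical and design choices

* **Ranking direction.** Descending and ascending ranks give identical
  $\gamma$; ascending average ranks are used.
* **Tie-break for the best shift.** Equal $|\gamma|$ resolves to the
  smaller shift, and within a shift to no-delay, then the
  $x$-trailing direction: the most parsimonious claim wins.
* **Minimum overlap 3.** The smallest window on which a rank
  correlation is non-degenerate; it fixes $t_{\max} \le N - 3$.
* **Seeding.** One user seed expands through a Lehmer-style step into
  per-stage and per-pair sub-seeds, so results are independent of
  evaluation order; two identically configured runs are byte-identical
  (checked via MD5 manifests).
* **Problem sizes in the packaged checks.** The calibration run uses
  1000 null pairs at the six-condition shape with 500 permutations;
  recovery runs use 200 coupled pairs; pipeline demonstrations use
  10–14 genes over 12 conditions with 199 permutations — large enough
  for every class of behaviour to appear while keeping the default
  check quick.

## Known limitations

* Delay resolution is one condition; no interpolation or
  continuous-time lag estimation.
* The Bonferroni correction is per pair over shifts; no FDR mode is
  provided.
* On six-point courses the test is valid but powerless (see above);
  reported class tables then collapse to `none`, which is the correct
  statistical answer at that design size.
* The identity map between levels assumes one protein row per mRNA
  row; paralog-aware or many-to-many mappings are out of scope.
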