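---
title: "Methods: differential-sensitivity screening statistics and genomic calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-sensitivity screening statistics and genomic calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscreen)
```

# The screening model

The screen is single-dose (1 µM, 72 h endpoint) over a compound library,
one plate series per cell line, with a fluorescence viability readout
(resazurin reduction). Each 96-well treatment plate carries 88 library
compounds and 8 DMSO vehicle-control wells; each cell-line experiment
adds a full 96-well DMSO plate and one cell-free plate measuring assay
background.

## Normalization

For cell line $\ell$ with compound-well intensities $x_{i\ell}$,

$$z_{i\ell} = \frac{\log x_{i\ell} - \overline{\log x_{\cdot\ell}}}
                   {\mathrm{sd}(\log x_{\cdot\ell})},$$

where the mean and (n−1) standard deviation run over the library
compounds of that cell line only — controls are not library members and
are excluded. Low $z$ means low viability, i.e. a potent compound.
Choices behind this:

* **Background** (`background = "subtract"`, default): the cell-free
  plate mean is subtracted before the log. The assay design collects a
  cell-free plate but its use is not prescribed; both policies are
  supported and recorded in the result's metadata, and Z-scores are in
  any case invariant to overall intensity rescaling.
* **Log base** (natural, default): cosmetic — standardization cancels
  the base.
* **Replicates**: replicate wells of one compound are averaged on the
  log scale before standardization (the single-dose design has none, but
  the contract allows them).
* **Guards**: non-positive post-background intensities and zero-variance
  cell lines are errors, never silently patched; `min_compounds`
  (default 3) protects the sd estimate.

Plate QC reports the DMSO mean and CV per plate and flags (never drops)
plates whose control CV exceeds `control_cv_limit` (default 0.2, i.e.
20% — a generous limit for a healthy viability assay).

## Selectivity statistics

Per compound, group-mean Z-scores are averaged over member cell lines
(unweighted) and the selectivity statistic is
$\Delta_i = \bar z_i(\mathrm{SINET}) - \bar z_i(\mathrm{PanNET})$;
negative $\Delta$ = more potent against SINETs. Non-tumour means are
reported but not part of $\Delta$.

**Empirical-null p-score.** A normal is fitted to *all* compounds'
$\Delta$ by maximum likelihood ($\hat\sigma$ with the $n$ denominator)
and each compound is scored by the two-sided tail probability
$2\Phi(-|\Delta_i - \hat\mu|/\hat\sigma)$. Two open choices were
resolved as follows: sidedness (two-sided by default, one-sided by flag
— a selectivity screen cares about both directions) and trimming (none:
the simplest reading of "a fitted normal" is that the bulk of the
library is the null; with ≥300 compounds and a handful of true hits the
fit is dominated by nulls). The score is reported unadjusted; FDR
control is applied at the class level, where the inference happens.

**Class enrichment.** Each target class's $\Delta$ values are compared
with all other compounds' by a two-sided Wilcoxon–Mann–Whitney test.
Midranks are used throughout; the null distribution is enumerated
exactly over all $\binom{n_1+n_2}{n_1}$ label assignments when both
groups have ≤ 10 members or the total is ≤ 12 (the enumeration handles
ties exactly), otherwise the normal approximation with midrank tie
correction and 0.5 continuity correction is used. Two-sided p is
$\min(1,\,2\min(P(U\le u), P(U\ge u)))$. Benjamini–Hochberg is applied
across tested classes; classes below `min_class_size` (default 5 — an
exact 4-vs-296 test can never reach q < 0.05 across 30 classes, so
smaller classes are uninformative) are reported as untested rather than
dropped. Direction is the sign of the class median $\Delta$.

**Paired group contrasts.** For one class, per-compound group means are
paired across two groups and tested by the Wilcoxon signed-rank test;
zero differences are dropped (Wilcoxon convention), $|d|$ midranked, and
for $n \le 25$ the exact tie-adjusted distribution of $V$ is computed by
dynamic programming over doubled midranks (equivalent to the full $2^n$
sign enumeration, which the test suite uses as an independent oracle);
beyond that, the normal approximation with continuity correction and
$\mathrm{Var}(V) = \sum r_i^2/4$.

## Dose–response

The variable-slope four-parameter logistic is parameterized as

$$y(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
        {1 + 10^{\,\mathrm{hill}\,(\log_{10} d - \mathrm{logIC50})}},$$

so hill > 0 is the descending inhibitor orientation ($y \to$ top as
$d \to 0$) and $y(10^{\mathrm{logIC50}}) = (\mathrm{top} +
\mathrm{bottom})/2$. The textbook form writes the exponent with the
opposite sign and fits negative slopes for inhibitors; the two are the
same curve under a slope sign flip, and fits here are canonicalized to
top ≥ bottom, flipping the slope when the mirrored solution was found.
Fitting is multi-start least squares (`nls`, port algorithm; logIC50
starts at the log-dose quartiles, slopes at {−1, 0.5, 1, 2}), with the
slope bounded to ±20 and, by default, bottom ≥ 0 (a viability readout
cannot be negative; free by flag). The degenerate flat-line limit
(hill → 0) is handled before optimization: exactly constant responses
short-circuit to bottom = top with logIC50 unidentifiable. A stalled optimizer returns
`converged = FALSE` rather than throwing; all-equal responses return the
degenerate bottom = top fit with logIC50 flagged unidentifiable.

Per-dose group comparisons are two-sided unpaired t-tests
(pooled-variance by default, Welch by flag) with BH correction across
the doses of one compound; a dose with zero pooled variance yields NA
("undefined"), not a fabricated p.

## Variant filtering

Hard filters are exactly the printed rule set (SNPs: QD < 2.0,
MQ < 40.0, FS > 60.0, ReadPosRankSum < −8.0, MQRankSum < −12.5; indels:
QD < 2.0, FS > 200.0, ReadPosRankSum < −20.0), with three deliberate
semantics: inequalities are strict, so boundary-equal values pass;
missing annotations never fail their filter (the caller convention —
rank-sums are undefined for homozygous sites); SNP rules never touch
indels and vice versa. The MAF filter removes records with population
frequency strictly above 0.01; records absent from the population table
are retained as rare (the conservative reading). The source methods say
"remove > 0.01" while the results text says "less than 0.01 included" —
the default follows the former (0.01 exactly is retained) with
`boundary = "remove"` for the stricter reading. The protein-altering set
defaults to {missense, nonsense, stoploss, frameshift, nonframeshift};
it is configurable because the upstream annotator's exact class list is
not fixed here. When a record lacks a consequence annotation, a toy gene
model classifies it positionally: non-exonic, or frameshift vs
non-frameshift by indel length mod 3; an unannotated exonic SNP cannot
be split into missense vs synonymous without codon information and is
conservatively removed (counted in `n_unclassified`).

The funnel reports counts per class at detected → quality-passed → rare
→ protein-altering, plus percentages of the detection stage, and treats
a count increase as an internal error. Gene-level bi-allelic
inactivation is flagged iff (hom mutation) or (het mutation and
single-copy context) or (homozygous loss); the contradictory input hom
mutation + homozygous loss resolves to homozygous loss with a warning.

## Copy-number calls

Per array, a QC scalar selects the regime: QC > 0.2 (strictly) → high
stringency, gain/loss thresholds ±0.3; otherwise ±0.2. Amplification and
homozygous loss sit at ±1.5 in both regimes. Boundary values take the
more extreme call (≥/≤ semantics) — the source states thresholds without
boundary semantics, so this is a documented package choice, exercised by
an enumerated decision-table test. Segments on X/Y or overlapping a
known-CNV region by ≥ 1 base are flagged excluded (with reason), never
removed; flagging is idempotent. Segmentation itself is consumed, not
reimplemented. The per-gene copy context takes the most extreme
overlapping call (severity order: homozygous loss > amplification >
loss > gain > neutral), mapping loss → "single-copy" for the bi-allelic
logic.

# The synthetic-data generator

The generator emulates the stated assay world: 96-well plates, 88
compounds + 8 DMSO controls per treatment plate in library order, a full
DMSO plate and a cell-free plate per cell line, a 2/2/3
SINET/PanNET/non-tumour panel by default, and single-dose treatment.
The intensity model is

$$x = \mathcal{N}(\mathrm{background},\,\sigma_b) +
      \mathrm{plate} \times \mathrm{signal} \times (1 - \mathrm{effect})
      \times \mathrm{LogN}(1, cv),$$

with the lognormal multiplier normalized to mean exactly 1 (so
`noise_cv = 0` is exactly noise-free) and effects combining
multiplicatively on survival. Defaults, chosen once as realistic for a
resazurin endpoint and recorded here because the source reports no noise
model: `noise_cv = 0.1` (10% well CV), `background_level = 100` against
`cellline_signal = 10000` (a ~100:1 dynamic range), `background_sd = 0`,
`plate_effect_sd = 0.05` (5% multiplicative plate-to-plate spread).
Variant and segment generators draw annotation values uniformly strictly
inside the passing or failing side of each threshold according to
per-filter failure fractions, so truth labels are consistent with values
by construction; MAF values follow a Beta(0.3, 2)/2 (most variants rare,
a realistic common tail), present for 70% of records.

What the generator does **not** emulate: spatial within-plate gradients
(edge effects), compound cross-contamination, correlated annotation
failures (real low-quality variants fail several filters at once),
linkage between variants, or segment boundaries derived from probe-level
noise. A green test therefore establishes that the statistics and rule
sets are implemented correctly and calibrated under their stated
assumptions — not that the pipeline is robust to artefacts it never
models.

## Plate effects confound library-order classes

One genuine property surfaced by simulation: with the default
library-order class map (classes are blocks of consecutive compounds)
and compounds plated in library order, the multiplicative plate effect
gives every compound of a class a shared $\Delta$ offset. The
class-enrichment WMW test assumes exchangeable compounds, so under plate
noise its type-I error is inflated (~0.20 at `plate_effect_sd = 0.05`
instead of 0.05). This mirrors a real screening pitfall: commercial
libraries often group mechanistically related compounds on neighbouring
wells, and per-cell-line (not per-plate) normalization does not remove
plate-level covariance. Consequently the null-calibration acceptance
experiment simulates the test's exchangeability null
(`plate_effect_sd = 0`, no injected effects), where the measured level
is 0.050 with KS-uniform p-scores; the recovery experiment keeps the
default plate effect, under which the injected class is still recovered
in ≥ 95% of screens. Generator defaults were not changed.

# Numerical choices and degenerate inputs

* Exact rank tests break two-sided p as twice the smaller tail, capped
  at 1, with a 1e-9 tolerance when comparing tied enumeration values.
* `empirical_null_pscores` requires ≥ 20 compounds and errors on
  $\hat\sigma = 0$ ("degenerate null").
* BH is `stats::p.adjust(method = "BH")`, verified in the tests against
  a hand-written step-up implementation.
* All interval work (CNV exclusion, gene model, gene context) is
  1-based closed internally via IRanges, converting from the 0-based
  half-open TSV/BED convention at the boundary; random-input tests
  compare against an O(n·m) loop oracle.
* TSV output is unquoted, `\n`-terminated, NA-coded text written through
  one writer, which is what makes every CLI subcommand byte-reproducible
  for a fixed seed; `--config` files are JSON (no YAML parser is
  assumed).

# Limitations

* The screen statistics implement a two-group contrast only; multi-group
  designs reduce to pairwise runs.
* The empirical-null p-score is calibrated only insofar as the library
  bulk is null; screens where most compounds hit one group violate it.
* No spatial plate correction is applied (none is part of the method);
  the class/plate confounding above is the visible consequence.
* IC50 confidence intervals are Wald (from the nls covariance), not
  profile-likelihood.
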