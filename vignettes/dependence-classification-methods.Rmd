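---
title: "Methods: classifying CAMTA1-dependent drought-responsive genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying CAMTA1-dependent drought-responsive genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtadep)
```

## The analysis problem

A loss-of-function mutant of the transcription factor CAMTA1 shows increased
drought sensitivity in *Arabidopsis thaliana*. To ask which part of the
drought transcriptional programme runs through CAMTA1, expression is
profiled in a 2 × 2 × 2 factorial: genotype (wild type Col-0 vs *camta1*
knockout) × condition (watered control vs drought) × tissue (leaf vs root),
with three biological replicates per cell. The question per gene is not
simply "is it drought-responsive?" but "does its drought response *require*
CAMTA1?" — operationalised as: significant response in the wild type whose
magnitude collapses in the mutant.

`camtadep` implements that analysis as a reusable chain:

1. **Differential expression** per genotype and tissue, drought vs control
   (`run_de()`).
2. **Dependence classification** of the wild-type responders from the ratio
   of mutant to wild-type fold changes (`classify_dependence()`).
3. **Promoter motif scanning** for the two CAMTA recognition cis-elements
   (`scan_promoters()`).
4. **Annotation cross-tabulation** against stress/hormone/TF gene sets with
   Fisher enrichment and Benjamini–Yekutieli correction
   (`crosstab_classes()`, `fisher_enrichment()`).
5. A **synthetic-data generator** with recorded ground truth
   (`simulate_expression()` and friends) so that every stage is testable
   without array data.

## Differential expression: a SAM-style permutation d-statistic

For a contrast (drought vs control within one genotype and tissue) with
log2-scale expression values, each gene gets

$$ d_g = \frac{\bar{x}_{g,\mathrm{drought}} - \bar{x}_{g,\mathrm{control}}}
             {s_g + s_0}, $$

where $s_g$ is the pooled standard error of the mean difference and $s_0$ a
fudge factor that keeps low-variance genes from dominating the ranking. The
classical procedure tunes $s_0$ over percentiles of the $s_g$ distribution;
at the scale of these designs that machinery adds little, so the default
`s0 = "auto"` uses the median of the $s_g$ — a common simplification — and
any non-negative value can be supplied instead.

Significance comes from condition-label permutations within the contrast's
six samples. With $n = 3$ vs $3$ there are only $\binom{6}{3} = 20$ distinct
assignments, far too few for per-gene nulls, so permuted $d^*$ values are
pooled across genes (standard practice for this statistic). Whenever the
number of distinct assignments is at most `n_perm`, all of them are
enumerated exactly; otherwise `n_perm` random assignments are drawn under
the run's seed. The p-value is the smoothed pooled tail

$$ p_g = \frac{1 + \#\{|d^*| \ge |d_g|\}}{1 + N_\mathrm{pool}}, $$

which can never be exactly zero. A q-value is also reported (median
permutation false-positive count over the observed count at each $|d_g|$
threshold, capped at 1 and monotonised), with $\pi_0 = 1$, i.e.
conservatively assuming no true positives. The significance *gate*, however,
is applied to p, with both thresholds inclusive:

* called UP iff linear fold change $\ge 2$ **and** $p \le 0.05$;
* called DOWN symmetrically ($\le -2$, signed "fold" convention where
  $-2$ means halved);
* otherwise NS.

Genes with zero variance in both groups and $s_0 = 0$ receive $d = \pm\infty$
(ranked most extreme) or $d = 0$ for a zero difference — never NaN.

## Dependence classification: the attenuation ratio

For every wild-type-significant gene the mutant response is compared to the
wild-type response through the ratio on the log2 scale,
$\rho_g = \mathrm{log2FC}_{\mathrm{mut}} / \mathrm{log2FC}_{\mathrm{WT}}$,
re-expressed as the **attenuation**

$$ a_g = 1 - \rho_g. $$

$a = 0$ means the mutant responds exactly like the wild type, $a = 1$ means
the response is abolished, $a > 1$ means the mutant responds in the opposite
direction. The wording of the source protocol ("ratio ... greater or equal
to threshold value (99% of confidence of interval)") leaves three things
open, which this package resolves explicitly:

* **Orientation.** The raw ratio points in opposite directions for UP and
  DOWN genes; the attenuation form gives "more dependent" a single
  orientation for both, so one threshold covers the whole column.
* **Which interval.** The column-statistics summary of the original
  toolchain computes the confidence interval *of the mean*; the threshold
  used here is therefore the upper bound of the t-interval
  $\bar{a} + t_{(1+0.99)/2,\,n-1} \cdot s/\sqrt{n}$ of the attenuation
  column, with `ci_level` configurable. A gene is DEPENDENT iff
  $a_g \ge$ that bound. Because the bound sits just above the column mean,
  it separates a bimodal attenuation column (near 1 for dependent genes,
  near 0 for unaffected ones) cleanly, and lowering `ci_level` can only
  grow the dependent set (a property the tests assert).
* **Ties and degenerate columns.** If the attenuation column has zero
  variance the interval collapses to the common value; the tie is then
  broken toward INDEPENDENT, since dependence should require strict
  evidence of attenuation. Genes oppositely regulated in the mutant
  ($\rho < 0$, so $a > 1$) classify as dependent.

Crossing the dependence call with the wild-type direction yields the four
classes — CDPRG/CDNRG (dependent, positively/negatively regulated) and
CIDIG/CIDRG (independent, drought induced/repressed) — and two partition
identities that are asserted on every run:
CDPRG + CIDIG = #WT-UP and CDNRG + CIDRG = #WT-DOWN.

A genotype × condition interaction term in a linear model would be the
statistically cleaner route to the same question; it is deliberately **not**
what this package computes, because the goal is a faithful, tested
implementation of the ratio-threshold procedure.

## Promoter motif scanning

The two recognition elements are degenerate IUPAC patterns:
`MCGCGB` = (A/C)CGCG(C/G/T), the CGCG-box bound by the CG-1 domain, and
`MCGTGT` = (A/C)CGTGT, whose `ACGTGT` expansion is the classical ABRE.
`scan_sequence()` tests every window position, reports overlapping hits
individually (the per-gene counts in the style "2-CGCG; 5-CGTG" need them),
and uses 0-based half-open coordinates on the given promoter string with
position 0 the most-upstream base. Conventions chosen where the field gives
no single answer:

* **Strands.** Default policy is `both`: the reverse complement of `MCGCGB`
  (`VCGCGK`) is not itself in the scanned set, so a forward-only scan would
  miss genuine sites on the other strand. Minus-strand hits are found by
  scanning the reverse complement and mapping coordinates back.
  `strand_policy = "forward"` reproduces a single-strand scan.
* **N bases** match no motif symbol — conservative, avoids inflating the
  per-class frequencies.

Per-class summaries report the percentage of class genes with at least one
hit, rounded half-up to one decimal (the convention of the published
percentage tables; `round_half_up(100 * 11/39, 1)` is `28.2`).

## Annotation analysis

Gene sets arrive as GMT files (stress categories, hormone classes, TF
families — stand-ins for database exports). Three views are produced:

* `venn3()`: exclusive three-set region counts of a class against e.g.
  drought/cold/salt responder sets.
* `crosstab_classes()`: per class × set counts and percentages of the
  class's set-annotated genes.
* `fisher_enrichment()`: one-sided hypergeometric over-representation
  (under-representation is not reported, matching singular-enrichment
  semantics), odds ratio from the 2×2 table with a 0.5 continuity
  correction when any cell is zero, and Benjamini–Yekutieli adjustment —
  valid under arbitrary dependence between terms. The universe defaults to
  the union of set members (or all array genes when supplied), and is
  configurable because the original toolchain does not state which
  background it used.

## The synthetic-data generator

`simulate_expression()` draws, per gene, a baseline $b_g \sim N(8, 2^2)$
log2 units and a class label, then generates

$$ x = b_g + \delta_g \cdot [\mathrm{drought}] \cdot
        (\kappa_g \text{ if MUT else } 1) + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma^2), $$

with defaults $\delta = 2$ log2 units (a 4-fold response, comfortably past
the 2-fold gate), $\sigma = 0.25$ (additive Gaussian noise on the log2
scale, the standard idealisation of normalized array intensities), three
replicates per cell, and $\kappa = 0$ for dependent genes (response
abolished) vs $\kappa = 1$ for independent ones. Class fractions default to
`dep_pos = dep_neg = 0.11`, `indep_up = indep_down = 0.04`, `null = 0.70`:
on the array this emulates, only a minority of genes responded to drought,
and roughly three quarters of the responders were classified dependent
(leaf: 796 of 1042 induced, 934 of 1225 repressed), so the defaults keep a
large null class and a ~73% dependent share among responders. Effect signs
are fixed by the class label (`dep_pos`/`indep_up` positive), keeping class
semantics unambiguous.

`simulate_promoters()` plants concrete motif expansions at recorded
positions and strands (probability 0.4 per gene and motif by default) in
1000-bp background sequence; with `clean_background = TRUE` the background
is rejection-resampled until it contains no accidental match on either
strand, so the planted table is the complete scan ground truth. Planted
words are drawn only from expansions that are unambiguous under both-strand
scanning — some CGCG-box expansions are reverse-complement palindromes
(`ACGCGT`, `CCGCGG`) or map onto other expansions, which would create a
second legitimate hit at the same position on the opposite strand.
`simulate_gene_sets()` samples set membership per truth class at
configurable rates; the defaults recruit drought-responsive classes into
the "drought" set at 0.30 against a 0.02 background, leaving flat
(uninformative) hormone and TF sets to rank against.

One seed governs all three generators through derived streams
(`seed`, `seed + 1`, `seed + 2`), so each can be regenerated independently
and the whole pipeline is bit-reproducible.

**What the generator does not emulate:** probe-level intensities and
summarisation, array batch and spatial effects, correlated noise between
genes, heavy-tailed residuals, partial attenuation mixtures, and real
promoter base composition (background is i.i.d. at a configurable GC
fraction). Passing recovery tests on this generator therefore demonstrates
the *procedure's* correctness under its own model, not performance on real
arrays.

## Numerical choices and problem sizes

* Permutation p-values are smoothed by the +1 convention and tie handling
  is exact (counts use sorted-pool rank arithmetic, not floating
  comparisons of re-derived quantities).
* Infinite d-statistics (zero variance, $s_0 = 0$) are ranked most extreme;
  a flat gene gets $p = 1$ exactly.
* The verification suite and the reproduction script run at 2000 genes,
  one tissue, three replicates — large enough that binomial error on a
  sensitivity estimated over ~440 planted dependent genes is ±2% and the
  type-I error of ~2000 null p-values is estimated to ±1%, while a full
  run stays in seconds.
* Classifier recovery at these defaults is sensitivity ≳ 0.97 and
  specificity ≈ 1.0; the noise-free limit ($\sigma = 0$) is recovered
  exactly, and on null data ($\delta = 0$) the fraction of genes at
  $p \le 0.05$ sits at 0.05 within sampling error with p-values that pass
  a KS uniformity test.

## Known limitations

* The attenuation formulation is a documented interpretation of an
  ambiguous published recipe; with real data, small wild-type fold changes
  near the gate make $\rho$ noisy even though the $|log2FC| \ge 1$ gate
  bounds the denominator away from 0.
* The pooled permutation null assumes exchangeability of genes up to the
  $s_0$ stabilisation; strongly heteroskedastic data would distort the
  pooled tail.
* With three replicates, the exhaustive null has only 20 assignments; p
  values below ~1/(20·G) are unreachable by construction.
* Enrichment treats terms as flat sets — there is no ontology structure,
  term ancestry or propagation.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(n_genes = 1000, tissues = "LEAF", seed = 1)
run <- run_pipeline(cfg, out_dir = "camta_demo")
print(run)                       # per-tissue counts, frequencies, top terms
partition_summary(run$classifications)
```

Every table printed by the report is also written as TSV under `out_dir`
and listed in `run$manifest`.
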