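---
title: "Methods: demethylation analysis of IDH-mutant glioma methylation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demethylation analysis of IDH-mutant glioma methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific setting

IDH-mutant lower-grade gliomas carry the glioma CpG-island methylator
phenotype (G-CIMP): genome-wide DNA hypermethylation driven by the
2-hydroxyglutarate block on TET-mediated demethylation. A subset of these
tumours partially loses that hypermethylation when they progress to
higher-grade disease. Two features characterise the loss: it concentrates
outside CpG islands (in "open sea" probes), and it concentrates in
late-replicating chromatin. The second feature is the signature of
*passive* demethylation — DNMT1-mediated maintenance methylation failing to
keep up with accelerated division — rather than active, enzyme-driven
demethylation. Most of the lost methylation sits in non-regulatory DNA, but
a handful of genes gain expression through genuine promoter demethylation,
which makes them candidate progression drivers.

`gcimpdemeth` implements this analysis as a reusable pipeline over
Infinium 450K beta-values, an FPKM expression matrix, a replication-timing
(Repli-seq) track and a fusion-junction table, together with a synthetic
cohort generator that plants all of those signals with known ground truth.

## Pipeline stages and their models

**Clustering.** Probes on the X/Y chromosomes or with a common SNP within
5 bp of the target CpG are excluded; the 10,000 probes with the largest
sample standard deviation of beta (denominator $n-1$, missing values
excluded pairwise) feed agglomerative clustering of samples with Euclidean
distance and the ward.D2 convention (Ward's criterion applied to unsquared
distances, as in `stats::hclust`). `k` is user-chosen; nothing in the
pipeline selects it automatically. Beta-values are clustered raw, not
mean-centred: the hyper/hypo contrast between groups *is* the signal of
interest, and centring would discard the overall methylation level that
separates the methylator phenotype from demethylated tumours.

**Differential methylation.** Per probe, an unpaired two-sided Welch
(unequal-variance) $t$-test compares the demethylated against the reference
group; $\Delta\beta$ is comparison minus reference, so demethylation is
negative. Benjamini–Hochberg adjustment runs across all testable probes
($m$ = number of non-missing $p$). Two labelling profiles are used: the
count profile ($q<0.05$ and $|\Delta\beta|>0.2$, hypo and hyper sides) and
the stricter replication-timing profile ($q<0.05$ and $\Delta\beta<-0.4$,
hypo side only). All inequalities are strict, following the printed ">"
wording. Probes untestable in either group (fewer than two values, or zero
variance in both groups) keep missing $p$/$q$ and the `ns` label rather
than disappearing.

**Replication timing.** Probe positions are 1-based, bedGraph intervals
0-based half-open; a probe at position $p$ sits in the interval with
$\mathrm{start} \le p-1 < \mathrm{end}$. Category thresholds are the
medians of the strictly negative and strictly positive replication-timing
values (zeros belong to neither); categories follow
$v \le \mathrm{late\_cut}$ (late), $\mathrm{late\_cut} < v \le
\mathrm{early\_cut}$ (intermediate), $v > \mathrm{early\_cut}$ (early),
with both boundaries inclusive downwards exactly as published. When two
Repli-seq profiles are supplied their values are averaged per probe before
thresholding — the combination rule is not stated anywhere, and averaging
is the symmetric choice. Enrichment of demethylated probes in late domains
is a Pearson chi-square without continuity correction, in two comparator
modes: `all` compares the demethylated set against *all* probes (faithful
to the published figure, though the columns overlap), `complement` against
the non-demethylated remainder (independent columns, the statistically
clean version). Both are reported; the late-membership odds ratio is always
computed on the complement partition so it is mode-invariant.

**Expression.** Per gene, the same Welch/BH machinery runs on
$\log_2(\mathrm{FPKM} + 0.1)$; the fold change is computed on the raw scale
as $(\bar{x}_{cmp}+0.1)/(\bar{x}_{ref}+0.1)$ so the published ">2 / <0.5"
semantics apply directly. The log-scale test stabilises the strong
mean–variance coupling of FPKM; a `test_scale = "raw"` option exists
because the original scale was not stated. No expression floor is applied
by default (`min_fpkm` is available but off).

**Promoter integration.** A probe belongs to a gene's promoter when
annotated TSS1500, TSS200, 5'UTR or 1stExon for that gene (the manifest's
semicolon-delimited multi-gene dialect is parsed; gene-body entries never
count). Per gene, probes are ranked by the absolute difference of group
mean betas and the top $\lceil 0.25\,n \rceil$ (at least one; ties broken
by probe id) are averaged per sample into a promoter score; Welch + BH
across genes gives promoter $q$-values. This construction — Welch on
per-sample scores — is declared here because only the existence of promoter
$q$-values, not their computation, is stated in the source material.
Absolute rather than signed ranking is the default since "most different"
does not specify a direction; a signed option exists. The starburst rule
labels a gene `up_with_demethylation` when expression $q<0.05$, fold change
$>2$, promoter $q<0.05$ and promoter $\Delta\beta<-0.2$ (mirrored for
`down_with_hypermethylation`). The per-probe scan re-examines each
upregulated gene probe by probe ($q<0.05$, $\Delta\beta<-0.2$) and is at
least as sensitive as the averaged rule at equal thresholds.

**Fusion filtering.** A junction read supports a candidate when it has at
least 12 matched bases on *each* side of the breakpoint; a candidate passes
with strictly more than four supporting reads ("more than four" is strict,
"at least 12" inclusive, read literally) and, when both partners share a
chromosome, a breakpoint distance of at least 100,000 bp (read-through
suppression). Only reads passing the match rule count toward the read
threshold — the stricter of the two possible readings; `count_all_reads`
switches to the laxer one. Failure diagnostics decompose into
`read_through`, `min_reads` (too few spanning reads at all) and
`min_match` (enough reads, too few passing), so each synthetic decoy class
violates exactly one named rule.

## The synthetic cohort generator

The generator is the test-bed for every stage, so its defaults *are* the
study conditions:

| parameter | default | why |
|---|---|---|
| samples | 20 reference / 9 demethylated | the compared groups at the published sizes (44 was the full reference cluster; 20 keeps the same imbalance at desk scale) |
| probes / genes | 10,000 / 1,000 | enough for stable BH behaviour and clustering; runs in seconds |
| context mix | Island .30, Shore .23, Shelf .10, OpenSea .37 | 450K-manifest-like proportions |
| context → early-domain placement | Island .85, Shore .70, Shelf .40, OpenSea .30 | couples open sea with late replication, as in real genomes; this is what makes hypomethylated probes concentrate in open sea |
| replication-timing track | 50 alternating ±1 domains of 1 Mb on one chromosome | clean two-level categories; a sinusoidal option exercises the intermediate class |
| planting probability | 0.30 late / 0.02 early | the late-versus-early demethylation asymmetry used by the enrichment calibration |
| planted $\Delta\beta$ | 0.5 | deep enough that planted probes clear both the 0.2 and the 0.4 profiles above the noise |
| beta noise | beta distribution, concentration 50 | bounded fraction noise, sd ≈ 0.06 at mean 0.8 — array-like |
| planted genes | 3, $\log_2$FC = 2 | a small promoter-driven set, as observed; their promoter probes are forcibly demethylated |
| expression noise | $\sigma = 0.25$ on $\log_2$ FPKM | tight biological replicates; FPKM base levels log-normal around 20 |

Reference group means are 0.80 (Island) down to 0.70 (OpenSea) —
hypermethylated everywhere, the methylator phenotype. Planted probes in the
demethylated group lose $\Delta\beta$ (floored at 0.02). A `contamination`
parameter mixes in a normal-brain-like profile (islands ~0.15) to emulate
normal-tissue admixture; it defaults to 0 because no value exists to
calibrate it. All randomness flows from `rng_seed`; fusion candidates
derive from `rng_seed + 1` so the junction table is reproducible yet
independent of the cohort draw.

What the generator does **not** emulate: probe-type (Infinium I/II) chemistry
differences, spatial autocorrelation of beta along the genome beyond the
domain structure, copy-number-driven intensity shifts, batch effects,
detection-p-value failure patterns (missingness must be injected manually),
and multi-chromosome genomes (single chromosome by default — nothing in
the analysis is cross-chromosomal). Tests passing on this generator
therefore establish correctness of the statistical machinery and the
plumbing, not robustness to those real-data artefacts.

## Numerical choices and degenerate inputs

* Missing values: token `NA`, excluded pairwise everywhere, never imputed
  (handling of failed-detection probes is not stated in the source;
  masking is this package's convention).
* Ties: probe-variance ranking and promoter-probe selection break ties by
  probe id in C-locale order, making outputs platform-independent.
* `ceil(0.25 n)` with a floor of one guarantees a non-empty promoter
  selection for any promoter size (rounding was unspecified).
* On the two-level synthetic track the early cut equals the maximum value,
  so the `early` category is empty by the inclusive-boundary rule and is
  dropped (with a warning) from enrichment tables; the test then runs on
  the remaining 2×2 table. The sinusoidal track populates all three.
* `q_max = 0` is accepted as a degenerate threshold (everything `ns`); the
  pipeline skips the enrichment test when the demethylated set is empty.
* Zero-variance features and groups with fewer than two observations are
  untestable, reported with missing statistics rather than dropped or
  errored.
* Writers emit 6 significant digits by default so results are diffable;
  round-tripping is exact for data already at that precision.

## Problem sizes used by the checks

The replicate-based calibrations run at: 20 null cohorts of 10,000 probes
(false-discovery control), 100 + 100 cohorts for the enrichment power and
null-calibration checks (10,000 probes, minimal 2+2 samples since those
checks use the planted truth, not the beta matrix; promoter planting is
disabled there to isolate the replication-timing mechanism). The oracle
comparisons use ≤10-element instances where brute force is exact.

## Known limitations

* The published cohort's headline numbers (33,695/635 probes, 116/383
  genes, 3 starburst genes) derive from controlled-access patient data and
  cannot be reproduced here; what the package reproduces is the method and
  its behaviour under planted truth.
* The published replication-timing thresholds (−0.4599, 0.80074) require
  the external NPC Repli-seq profile; `compute_rt_thresholds()` implements
  the stated median rule and reproduces them when that track is supplied.
* Variance moderation (limma-style) is deliberately out of scope; with 9
  samples in the comparison group, moderation would change borderline
  calls.
* The chi-square `all` mode uses overlapping columns; it is kept for
  fidelity with the published comparison but `complement` is the mode to
  interpret.
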