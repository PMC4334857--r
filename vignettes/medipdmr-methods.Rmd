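---
title: "Methods: differential methylation from MeDIP-Seq read densities"
author: "medipdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation from MeDIP-Seq read densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

## The measurement model

MeDIP-Seq enriches methylated DNA fragments with a 5-methylcytosine
antibody and sequences them. The number of reads falling on a locus is
therefore a joint function of (i) the local CpG density — unmethylated or
CpG-free DNA cannot be pulled down — and (ii) the methylation level of
those CpGs. `medipdmr` treats aligned read positions as draws from an
inhomogeneous Poisson process whose intensity is proportional to that
product, and every statistic in the pipeline is a statement about read
*counts*, never about absolute methylation: two samples are compared
through their counts, normalized by library size.

This has two practical consequences. First, comparisons are only
meaningful after library-size normalization; we use

$$AM = \frac{RC \times 10^6}{URC}$$

per genome segment, where $RC$ is the segment's read count and $URC$ the
sample's unique mapped reads — reads per million at segment resolution.
Second, regions with no MeDIP signal in *any* sample are invisible: a
differential call always originates from a region that is a methylation
peak in at least one sample.

## Stage by stage

### Binned coverage and sample similarity

The genome is tiled with fixed-width bins (10 kb for global maps; the
final bin of a chromosome is ragged rather than dropped, so read counts
are conserved). A read is assigned to exactly one bin by its fragment
midpoint; counting by midpoint rather than overlap keeps column sums equal
to the number of reads, which the normalization identity above relies on.
Pearson correlation of the $AM$ vectors (excluding bins that are zero
everywhere, which carry no signal) gives the between-sample similarity
matrix; a sample pair from the same methylome should correlate strongly at
10 kb resolution, and the simulated default conditions reproduce
correlations around 0.97–0.98 between case samples.

### Peak scanning with a dynamic Poisson background

Methylated regions are detected per sample by sliding a window
(`window_bp = 500`, `step_bp = 100`) along each chromosome, counting
extended-fragment midpoints (`fragment_extension_bp = 200`), and testing
the count against a locally adaptive expectation,

$$\lambda_{local} = \max(\lambda_{BG},\ \lambda_{5k},\ \lambda_{10k}),$$

where $\lambda_{BG}$ is the genome-wide rate scaled to window width and
$\lambda_{5k}$, $\lambda_{10k}$ are the counts in 5 kb and 10 kb spans
centered on the window, rescaled likewise (spans clipped at chromosome
ends are rescaled by their realized width). Taking the maximum makes the
test conservative wherever the neighbourhood is locally enriched — the
standard defence against false peaks when no input/IgG control library
exists. A window is significant when the Poisson upper tail
$P(X \ge k)$ falls below `p_threshold = 1e-5`; significant windows closer
than `merge_gap_bp = 200` merge into one peak. A merged peak records the
minimum member p-value together with that window's count and rate (so the
p-value is always recomputable from its own numbers) and the distinct read
count of the merged interval.

The window, step, extension and span constants are exposed in
`peak_params()`; the defaults are the conventional choices for
fragment-scale chromatin enrichment data. The merged-peak p-value is the
member minimum rather than a recomputed whole-peak value: it keeps peak
calling monotone in the threshold and deterministic.

### DMR testing

For one case sample against the control, candidate regions are the
coalesced union of both samples' peaks — a region methylated in either
sample can be differential. For each candidate the 2x2 table
$(a, b; c, d)$ crosses sample (control/case) with location (in-region /
elsewhere), so $a + b$ and $c + d$ are the library sizes. The test is the
Yates-corrected chi-square

$$\chi^2 = \frac{n\,\big(\max(0, |ad - bc| - n/2)\big)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with one degree of freedom. The continuity term is clamped at zero —
without the clamp a table with $|ad - bc| < n/2$ would gain a spurious
positive statistic from squaring a negative quantity. Degenerate inner
margins ($a + c = 0$ or $b + d = 0$) yield $\chi^2 = 0$, $p = 1$;
candidates with no reads in either sample are dropped before testing.
P-values are Benjamini–Hochberg adjusted across the candidates of the
comparison, and a region is a DMR when $q \le 0.05$ *and* its
library-size-corrected fold change — the ratio of in-region read
proportions $\frac{c/(c+d)}{a/(a+b)}$ — is at least 2 in either direction.
Proportions rather than raw counts are compared because raw counts
confound library size with methylation. Direction is `hyper` when the case
proportion is larger.

Two properties are worth stating because the test suite checks them: the
DMR set can only shrink when either threshold is tightened, and the
realized false-discovery proportion tracks the nominal level only to the
extent that candidate selection is unbiased — candidates that exist solely
because one sample's window fluctuated past the peak threshold carry
chi-square statistics conditioned on that selection, which is why the
planted-truth simulations measure the empirical FDP directly rather than
trusting the q-values.

### Ultra-DMR consensus

With several case samples sharing one control, per-pair DMRs are collapsed
onto a fixed 500 bp segment grid: a segment supports a sample when a
same-direction DMR overlaps it by strictly more than 250 bp (half a
segment), and a segment is an ultra DMR when more than half the samples
support it — at least 4 of 6, or 2 of 3. A segment supported in both
directions is contradictory and dropped (with a message); this is the
conservative resolution of a case the rule set does not otherwise define.

### Feature and band enrichment

Enrichment uses the same 500 bp segments as sampling units, which keeps
the 2x2 construction well defined for variable-length features: segments
in the region set vs the rest of the genome, crossed with overlapping the
feature vs not. The odds ratio is computed directly from the table (a 0.5
continuity correction is applied, and flagged, when a cell is zero), the
p-value is the two-sided Fisher exact test, and BH adjustment runs across
feature classes (or bands). "Enriched" requires $q < 0.01$ and OR > 1.
The background is the whole genome's segment grid; a narrower background
(e.g. peak-covered segments only) would answer a different question —
where differential methylation sits *given* methylation — and is not what
the enrichment tables here report.

### Promoter methylation patterns

Promoters are the TSS ± 2 kb (4 kb total), divided into forty 100 bp
windows ordered 5'→3' in gene orientation (minus-strand promoters are
reversed, so "5' of the CGI" always means upstream in the gene's sense).
A window is *methylated* when any peak overlaps it by at least 1 bp, and
*CGI* when any CpG island does; the 1 bp rule is the literal reading of
"covered" and is configurable. Classification applies five rules in a
fixed order (first match wins):

1. `NO_CGI` — the promoter has no CGI windows;
2. `CGI_CONFINED` — methylated∩CGI windows exceed half the methylated
   windows *or* half the CGI windows;
3. `SHORE_5PRIME` — all methylated windows precede the first CGI window;
4. `SHORE_3PRIME` — all follow the last CGI window;
5. `CGI_OVERLAP` — everything else.

The order encodes specificity: confinement is checked before the pure
shore patterns so that a promoter mostly methylated inside its island is
never called a shore pattern on the strength of one stray window.
Case-specific promoters are methylated (≥ 1 window) in at least
`min_case_support = 4` case samples and unmethylated in the control; their
pattern is classified on the union of the supporting case masks.
Control-specific promoters mirror this: methylated in the control and in
at most `n_case − min_case_support` cases. When a promoter holds several
CGIs the CGI mask is their union.

### Expression integration

Expression is quantified as RPKM, $10^9 C / (N L)$, with $L$ the longest
transcript of the gene. Genes are ranked by
$\log_2\frac{\bar{x}_{case} + 1}{\bar{x}_{control} + 1}$ — with a single
control sample a signal-to-noise metric is undefined, so a pseudocounted
log ratio of means is the defensible choice. The enrichment score of a
gene set is the signed maximum deviation of the weighted
Kolmogorov–Smirnov running sum (hits weighted by $|metric|^p$, $p = 1$,
normalized over the set; misses by $1/(N - N_h)$); with $p = 0$ it reduces
to the classical two-sample KS statistic, which the tests exploit as an
oracle. Significance comes from gene-set permutation — random sets of the
same size drawn from the ranked universe — because a one-control design
rules out phenotype permutation; the p-value carries +1 smoothing so it is
never zero at finite permutation counts. Pathway enrichment is the
upper-tail hypergeometric test with BH adjustment, flagged at $q < 0.05$
with at least two overlapping genes.

## The synthetic-data generator

`simulate_methylome()` exists so that every stage above can be tested
against known truth. It emulates, deliberately:

- **CpG geography**: ~1 CpG per 100 bp background with log-normal
  isochore-scale (100 kb) intensity variation (log-sd 0.5), and CpG
  islands with ~10x density and log-normal lengths. The isochore term
  gives 10 kb methylation maps their strong between-sample correlation;
  without it the toy rate field is flat at that scale and no realistic
  correlation structure exists.
- **TSS hypomethylation**: promoter-overlapping CGIs simulate at
  methylation 0.2; intergenic CGIs at 1. This is the canonical somatic
  landscape, and it is what makes "methylated only in case samples"
  detectable at CGI promoters at all.
- **Fragment-level capture**: a fragment is sampled in proportion to its
  total methylated-CpG content, so the midpoint intensity is the
  methylated CpG density box-filtered over the fragment length (200 bp),
  plus a small nonspecific-pulldown floor.
- **Planted differential regions**: pairwise non-overlapping, cycling
  through promoter-CGI, 5'-shore, 3'-shore, CGI-free promoter and
  intergenic targets. A planted region is a *methylated* region in both
  conditions: its low side runs at ~2x the background read rate
  (`planted_baseline`, expressed relative to local CpG density) and its
  high side at `effect_fold` times that, so the case/control rate ratio is
  exactly the configured fold while the low side stays below the peak
  threshold. Hypomethylated regions are therefore elevated in the
  *control* — hypomethylation presupposes a methylated reference state.
  Shore events occupy the distal 1.2 kb of the 2 kb shore, leaving an
  800 bp guard at the island edge: peak boundaries resolve only to about
  `window − step` (400 bp) at strong enrichment, fragments smear another
  ~200 bp and the 100 bp pattern windows quantize a further 100 bp, so an
  event flush against the island would bleed into it and no classifier
  could recover the pure shore pattern.
- **Coupled expression**: log-normal baseline means, Poisson counts;
  genes with planted promoter-CGI hypermethylation are repressed by
  $2^{coupling}$ and genes with planted 3'-shore hypomethylation
  overexpressed by the same factor (default coupling 1, i.e. 2-fold).
- **Determinism**: each sample draws from its own stream seeded as
  `seed + sample index`, so adding samples never perturbs existing ones,
  and a fixed seed reproduces all outputs byte-identically (RNG kinds are
  pinned).

It does **not** emulate sequencing errors, mapping bias, duplicate reads,
copy-number variation, GC amplification bias, age/sex covariates, or
biological replicate variance beyond Poisson sampling. Passing the
planted-truth tests therefore demonstrates that the statistics and the
plumbing are correct under the stated model — not that the pipeline is
robust to artefacts real libraries may carry.

Default scale: 2 chromosomes x 5 Mb, 300 genes (~60% with a promoter
CGI), 200 CGIs, 200,000 reads per sample (±20% library-size variation),
six case samples, 100 planted regions at 4-fold. The full pipeline on
these conditions runs in seconds per sample on one CPU; the test suite
runs its multi-seed simulations (20 seeds for recovery and null checks)
in a few minutes.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally (BED native);
  1-based inputs would be converted at parse time. One convention, no
  off-by-one ambiguity.
- Unstranded features are treated as + strand.
- `poisson_pvalue(k, lam)` is the survival function at `k − 1`; `k = 0`
  returns exactly 1.
- CGI length classes are type-1 quantile tertiles with boundaries to the
  lower class; all-equal lengths are all "short", and fewer than 3 CGIs
  cannot define tertiles (all "medium", with a warning).
- Promoter CpG classes follow the sliding-window scheme (500 bp windows,
  step 5 bp): HCP if some window has CpG ratio ≥ 0.75 and GC ≥ 0.55, LCP
  if no window reaches ratio 0.48, ICP otherwise; a sequence without C or
  G has ratio 0 and falls to LCP by the same rule. Thresholds are
  arguments.
- Promoters clipped at chromosome ends keep their clipped interval (with
  a warning); their pattern masks pad the missing windows as
  unmethylated and are flagged.
- Shores are derived from merged island blocks, so nested or overlapping
  CGIs can never receive shore base pairs inside another island.
- Constant normalized-coverage vectors have undefined correlation and are
  reported `NA`, never coerced to 0.
- The empty-direction, empty-peak-list, empty-repeat-track and
  zero-planted-region cases all return empty, well-typed tables.

## Known limitations

- The dynamic Poisson background cannot see rate variation *below* its
  smallest local span: a 500 bp stretch whose CpG density sits well above
  the 5 kb average can produce one-sample chance peaks, and because
  candidates are selected through exactly that fluctuation, the
  chi-square q-values of such candidates are optimistic. The planted-truth
  simulations quantify the realized false-discovery proportion directly
  (reported by `scripts/acceptance.R`), and it sits above the nominal 5%
  — the price of peak-conditioned testing with no input control.
- One control sample means no within-group variance estimate: the
  chi-square compares proportions between two libraries and attributes
  all excess to the condition. Ultra-DMR consensus across case samples is
  the paper-level mitigation, not a substitute for replicates.
- GSEA significance uses gene-set permutation, which tests set membership
  against a random-gene null, not the phenotype null of replicated
  designs.
- Enrichment odds ratios treat 500 bp segments as exchangeable units;
  long-range correlation of methylation (and of features) makes the
  Fisher p-values anti-conservative for strongly clustered region sets.
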