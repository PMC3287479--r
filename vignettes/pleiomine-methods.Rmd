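---
title: "Methods: mining multivariate phenotypes and pruning for pleiotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining multivariate phenotypes and pruning for pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Standard GWAS tests one trait at a time. When two traits are driven in part
by shared loci — pleiotropy — a single-trait design dilutes the signal: a
variant that nudges both LDL cholesterol and triglycerides upward may reach
neither trait's significance threshold alone, yet be strongly enriched in
individuals extreme on *both*. `pleiomine` implements a two-stage scheme
around this idea.

**Stage 1 — pattern discovery.** Cohort traits are discretized into quintile
items ("TG5" = top fifth of triglycerides) and individuals become
transactions. APRIORI mining with support/confidence/lift plus rule-form
constraints extracts multivariate phenotype patterns, which are visualized
as an undirected weighted trait graph (edge weight = number of rules in
which a pair of trait levels co-occurs; vertex size tracks degree).

**Stage 2 — association and pruning.** A mined pattern (optionally adjusted
to clinical guideline thresholds) defines a bivariate case/control design,
e.g. cases LDL ≥ 130 mg/dl AND TG ≥ 180 mg/dl versus controls
LDL ≤ 100 AND TG ≤ 100. Three allelic chi-square genome scans are run —
the bivariate phenotype and the two single-trait projections — and each SNP
gets

$$\mathrm{mOR}^{y_k} = \log_{10} p_{\text{single},k} - \log_{10} p_{\text{multi}},$$

the log10 ratio of its single-trait to multivariate p-value. mOR ≥ 1 means
the SNP is ten times (in p-value terms) more strongly associated with the
bivariate phenotype. A SNP survives pruning iff (1) its multivariate
p ≤ 5×10⁻⁴, (2) mOR ≥ 1 against *both* single traits (the intersection of
the two filtered sets), and (3) it has LD-clump support.

## Statistical choices

* **Allelic test.** 1-df chi-square on the 2×2 allele-count table, no
  continuity correction; a single p and OR per SNP, as in a PLINK
  case/control workflow. No covariate adjustment is offered because the
  underlying scheme describes none.
* **Odds ratio.** Oriented on allele1 (the observed minor allele; ties go
  to the alphabetically first allele). The Haldane–Anscombe 0.5 is added
  to all four cells only when some cell is zero, and only for the OR — the
  chi-square always uses the raw counts. A zero marginal yields p = 1 and
  an undefined-OR flag.
* **Sex-by-status test.** The 2×2 independence chi-square is reported both
  Yates-corrected — the value such cohort tables print (44.92 on the
  reference counts) — and uncorrected (45.70).
* **mOR degeneracies.** p-values that underflow to 0 are floored at 1e-300
  before logs, so mOR is always finite. mOR chains additively in the log
  ratio.
* **LD clumping.** Greedy: SNPs at p ≤ p_index (default 1e-5) are visited
  in ascending p (ties broken by chromosome, then position); each
  unclaimed one becomes an index and claims unclaimed SNPs with
  p ≤ p_clumped (1e-4), same chromosome, within 250 kb and dosage
  r² ≥ 0.5. r² is the squared Pearson correlation of allele dosages over
  pairwise-complete individuals; monomorphic pairs count as no LD. The
  defaults are the widely used PLINK-style settings; the clump-support
  pruning condition has two selectable readings (`index_or_clumped`,
  the default, and `index_only`) because the published wording is
  ambiguous about whether a survivor must itself be an index.
* **Discretization.** Quintiles by inverse-ECDF (type-1) quantiles, so for
  all-distinct values the level occupancies differ from N/5 by at most 1.
  Values exactly on a cut fall in the lower level — deterministic and
  order-independent. Fixed clinical cut points are available via
  `fixed_scheme()`. Nominal traits get one item per observed category.
* **Rule metrics.** Supports are exact transaction counts internally;
  confidence and lift are derived from stored supports only, so the
  identities lift·s(Y) = c and c·s(X) = s(X∪Y) hold to machine precision,
  and rules sharing a head share c/lift (= the head's support). Rule CSVs
  are written at full precision: the lossless round-trip contract takes
  precedence over table-style 4-decimal display.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_sup` | 0.01 | minimum rule support (fraction of individuals) — low, to catch rare disease-predisposing patterns |
| `min_conf` | 0.10 | minimum confidence at generation; the interestingness pass re-filters at conf ≥ 0.5, lift ≥ 1 |
| `max_len` | 5 | largest mined itemset (bodies of ≤ 4 items + single-item head) |
| `n_levels` | 5 | quintile vocabulary |
| `p_multi_max` | 5e-4 | pruning condition (1); deliberately less stringent than a Bonferroni threshold because the bivariate design shrinks the sample |
| `mor_min` | 1 | pruning condition (2): ten-fold p-ratio |
| `p_index`, `p_clumped`, `r2_threshold`, `window_kb` | 1e-5, 1e-4, 0.5, 250 | clumping |

## What the simulator emulates — and what it does not

`sim_spec()` states a world: N individuals; M SNPs with MAF ~ U(0.1, 0.5)
drawn under Hardy–Weinberg; optional LD blocks built by founder-copying
(each haplotype allele copies a block founder with probability r²^(1/4),
giving pairwise dosage r² near the target — adequate for clump testing,
far simpler than coalescent simulation); and two lipid-like traits,
LDL ~ N(115, 30) and TG ~ N(160, 70) before effects, with noise
correlation ρ = 0.3 by default (a moderate positive lipid correlation).
Planted effects are β per allele in base-trait SD units, added on centered
dosages so that carriers shift relative to the cohort rather than the
whole scale drifting — this keeps the clinical thresholds meaningful.
Binary phenotypes come from thresholding these traits exactly as the
phenotype builder does; there is no separate liability model.

Not emulated: demography and population structure, ascertainment,
genotyping error, trait transformations, and realistic genome-wide LD.
A green end-to-end test therefore establishes that the pipeline's logic
recovers planted signal under idealized sampling — not that it would
behave identically on a real cohort.

With ~30 planted loci at β = 0.25 the genetic variance is comparable to
the noise variance (trait SD ≈ 1.3 × the base SD), i.e. a strongly
heritable, polygenic-lite world; that is a consequence of the stated
effect sizes, not a calibration target.

## The honest red: end-to-end recovery

The acceptance suite simulates 20 pleiotropic SNPs (β = 0.25 SD on both
traits), 10 + 10 single-trait SNPs and 4,960 nulls in n = 8,000, and runs
the full pipeline at the published thresholds over 20 fixed seeds. Measured
outcome: pooled precision 1.00 (every survivor is truly pleiotropic; all
single-trait SNPs are removed by the mOR filter), but mean sensitivity
0.565 against a stated bar of 0.6 — the corresponding test is left failing
rather than adjusted. The binding constraint is the mOR intersection:
the single-trait designs span the whole cohort (~2,200 + 2,400) while the
bivariate design keeps only doubly-extreme individuals (~1,700 + 1,200),
so for a true pleiotropic SNP the single-trait p is often within a factor
of ten of the multivariate p, and requiring mOR ≥ 1 on *both* traits holds
only ~55–60% of the time. The filter trades sensitivity for the near-pure
specificity it was designed for. Generator parameters (ρ, MAF range) were
fixed on realism grounds before this measurement and not revisited.

## Numerical and degenerate-input conventions

* Support comparisons use a 1e-9 slack on `ceiling(min_sup * N)` so that
  exact-fraction thresholds (e.g. 0.5 of 4) are not lost to floating
  point; confidence thresholds get a 1e-12 slack likewise.
* `filter_complete()` on an all-missing table, empty transaction
  databases, zero-case/zero-control definitions, overlapping
  case/control predicates, ragged `.ped` rows and >2-allele variants are
  all hard errors naming the offending row/column/variant.
* Strata with fewer than two cases or controls are skipped with a warning
  during replication; empty survivor lists yield header-only outputs, not
  errors.
* Pipeline outputs carry a `# pleiomine config_hash=… seed=…` first line;
  identical configs reproduce byte-identical files.

## Known limitations

* Heads are single items and case/control definitions are conjunctions
  only; disjunctive phenotypes are out of scope.
* Only PLINK *text* genotypes (.ped/.map) and a dosage-matrix constructor
  are supported — no .bed, no VCF, no imputation.
* r² is dosage correlation, not haplotype-phase EM r².
* The miner is plain APRIORI over dense incidence matrices: right for
  trait-level vocabularies (≤ a few hundred items), wrong for
  market-basket scale.
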