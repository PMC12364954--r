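---
title: "Inferring competing endogenous RNA networks from multi-class expression profiles"
author: "cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring competing endogenous RNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The biological question and the model

In laying hens, one small yellow follicle (SYF, 6–8 mm) is recruited each
day into the preovulatory hierarchy as a large yellow follicle (LYF,
9–12 mm). Transcriptome studies of this *follicle selection* step profile
four RNA classes — mRNA, lncRNA, circRNA (FPKM) and miRNA (TPM) — in the
two follicle stages, typically with three pooled biological replicates per
stage, and ask which regulatory interactions distinguish them.

The competing endogenous RNA (ceRNA) hypothesis supplies the interaction
model: lncRNAs and circRNAs that carry miRNA response elements (MREs) can
sequester miRNAs and thereby derepress mRNAs carrying the same MREs. A
candidate ceRNA interaction is therefore supported by three signatures,
which `cernet` screens in sequence:

1. **Differential expression.** Only features that respond to the contrast
   enter the network. Long RNAs (mRNA/lncRNA/circRNA) require fold change
   ≥ 2 and Benjamini–Hochberg FDR < 0.05; miRNAs require fold change ≥ 2
   and raw p < 0.05. FDR is adjusted within each RNA class because the
   classes are analysed separately.
2. **miRNA–target anticorrelation.** For each predicted (miRNA, target)
   pair the Spearman rank correlation (SCC) of abundances across all
   samples must satisfy SCC < −0.7 (strict).
3. **ceRNA co-expression and shared-MRE overlap.** Every
   (lncRNA-or-circRNA, mRNA) pair that shares at least one retained miRNA
   is screened by the Pearson correlation (PCC) of log2 abundances,
   keeping PCC > 0.9 (strict), and then tested for a surprising overlap of
   targeting miRNAs: with `N` miRNAs in the universe, `K` targeting the
   ceRNA, `M` targeting the mRNA and `s` shared, the pair's p-value is the
   hypergeometric upper tail `P(X >= s)`, retained at p < 0.05 (strict,
   uncorrected — the customary raw threshold for this screen; a BH column
   is available downstream via `bh_adjust()` if a user wants it).

Significant pairs are expanded into (ceRNA, miRNA, mRNA) triads — one per
shared miRNA — and assembled into a typed network in which hubs are ranked
by degree. Separately, lncRNAs are assigned *cis* targets (protein-coding
genes whose gene bodies lie within 10 kb, inclusive, strand-agnostic) and
*trans* targets (genes with |Pearson r| ≥ 0.95, inclusive), and any gene
list can be tested for over-representation against user-supplied
annotations with the same hypergeometric core.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fc_min` | 2 | minimum fold change (linear), i.e. abs log2FC ≥ 1 |
| `de_fdr` | 0.05 | FDR bound for long RNAs (strict `<`) |
| `mirna_de_p` | 0.05 | raw p bound for miRNAs (strict `<`) |
| `scc_cutoff` | −0.7 | Spearman retention threshold (strict `<`) |
| `pcc_cutoff` | 0.9 | Pearson retention threshold (strict `>`) |
| `pair_alpha` | 0.05 | hypergeometric pair threshold (strict `<`) |
| `cis_window` | 10,000 bp | cis gap bound (inclusive `<=`) |
| `trans_r` | 0.95 | trans abs-correlation bound (inclusive `>=`) |
| `pseudocount` | 0.01 | offset on the FPKM/TPM scale before log2 |

Strictness follows the printed wording of each rule exactly: "less than
−0.7" and "greater than 0.9" are strict, "within 10 kb" and "≥ 0.95" are
inclusive. The boundary semantics are pinned by tests at representable
values (a correlation exactly equal to the configured cutoff; gaps of
exactly 10,000 and 10,001 bp).

## Design choices that were genuinely open

**The surrogate DE test.** Production RNA-seq analyses fit negative
binomial models (DESeq2/edgeR) to counts. This package consumes
FPKM/TPM-scale matrices for which count models are not identifiable, so it
uses Welch's unequal-variance t-test on `log2(x + pseudocount)` as an
explicitly labelled surrogate (`attr(de, "test")` records it). The
surrogate preserves the decision structure (class-specific thresholds,
within-class BH) while remaining honest about what it is: dispersion
estimation, shrinkage and normalisation factors are out of scope, and DE
counts from real studies are not expected to be reproduced. When both
groups have zero variance the statistic is undefined; the p-value is
defined as 1 for equal means and 0 otherwise, so constant matrices behave
sensibly.

**The miRNA universe of the pair test.** The hypergeometric p-value
depends on `N`, and the screening literature rarely states its universe.
For a pair sharing its single targeting miRNA (`K = M = s = 1`) the
p-value is exactly `1/N`, so defining the universe as only the miRNAs
that survived edge filtering makes every sparse-network pair
non-significant (`1/N_retained` is large precisely when the network is
small) — the test would refute the very structure it screens for. The
default is therefore *all expressed miRNAs* (`universe_policy =
"expressed"`), with `"de"` and `"retained"` available; the policy and `N`
are recorded in the outputs because p-values are not comparable across
policies.

**Correlation scales.** Spearman is computed on raw abundances (it is
rank-invariant, so any monotone transform gives the same value); Pearson
is computed on log2 pseudocounted abundances, where FPKM/TPM data are
closest to elliptical and where a noise-free multiplicative coupling is
exactly affine (hence PCC exactly 1 in the noise-free simulation).
Both choices are configurable at the function level.

**Connectivity.** "Connectivity" is implemented as node degree on the
deduplicated edge set — an edge supported by many triads counts once, as
it would be read off a drawn network. Ties are broken lexicographically so
hub lists are reproducible.

**Gap definition for cis targets.** The gap is measured between the
closest gene-body edges on the same chromosome, strand-agnostic, with
overlapping or adjacent bodies at distance 0. No TSS anchoring is applied
because the rule being implemented specifies none.

## The synthetic-data generator

Real follicle data (raw reads, predictor outputs) are not bundled;
instead, `simulate_dataset()` produces datasets whose *statistical
structure* matches what the analysis assumes, with a known ground truth:

* **Planted triads.** Each triad draws a latent per-sample signal
  `z = 1[group B] + Normal(0, latent_sd)`. The miRNA follows
  `a − β·z + ε`, the ceRNA and mRNA follow `c + β·z + ε` on the log2
  scale, with `β = planted_log2fc` and `ε ~ Normal(0, noise_sd²)`.
  Coupling through a latent signal (rather than copying one vector)
  makes planted correlations imperfect under noise, like biological
  coupling. With `noise_sd = 0` the coupling is exactly monotone/affine:
  SCC = −1 and log2-scale PCC = +1 exactly, which the tests assert.
* **Planted DE features** shift their group-B mean by ± `planted_log2fc`
  with no latent coupling.
* **Background features** are independent log-normal draws; all noise is
  additive on the log2 scale, i.e. multiplicative on the positive raw
  scale, matching the heavy-tailed nature of FPKM/TPM data.
* **Decoy target rows** point miRNAs at background features:
  `round(decoy_target_fraction · (2·n_triads + n_background_miRNA))`
  rows, a rule that stays positive when no triads are planted so that
  decoy-only null runs still exercise the whole pipeline.
* **Intervals** are laid on one synthetic chromosome at 50 kb spacing,
  with two background lncRNA/mRNA pairs repositioned at gaps of exactly
  10,000 and 10,001 bp to probe both sides of the cis window.

Defaults: 3 replicates per group; `planted_log2fc = 1.5`; `noise_sd =
0.1` (`0.05` in the canonical fixture); baseline log2 abundance
`Normal(4, 1.5)`, a realistic FPKM spread spanning roughly 1–200. The
canonical fixture uses 60 background features split 24/8/4/24
(mRNA/lncRNA/circRNA/miRNA): miRNA-rich, as real whole-transcriptome
universes are, and large enough (32 expressed miRNAs including planted
ones) that a pair sharing its sole miRNA reaches p = 1/32 < 0.05.

`latent_sd` defaults to 0.1, a modest fraction of the group effect. The
choice is a power calculation for the n = 3 per group design: triad
members' within-group log2 sd is `sqrt((β·latent_sd)² + noise_sd²)` ≈
0.16, giving a Welch statistic around 1.5/0.13 ≈ 11 and p-values small
enough to survive within-class BH with a comfortable margin. A larger
latent spread (≥ 0.2) makes the generator defeat its own purpose:
genuinely planted members start failing the FDR gate at this sample size,
and recovery is then limited by the DE stage rather than by the network
statistics under study.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: count-level sampling noise and library-size
effects; correlated background co-expression modules; the scale of a real
study (tens of thousands of features); sequence-based target prediction
error structure; batch effects. Recovery rates on the fixture measure the
pipeline's correctness, not its field performance.

### A sharp recovery threshold at n = 6

With six samples and distinct ranks, Spearman's coefficient takes values
in a discrete grid (steps of 6/210 ≈ 0.0286 in `1 − 6Σd²/210`), and
|SCC| > 0.7 tolerates only a few adjacent rank flips away from perfect
monotonicity. Edge retention at n = 6 is therefore nearly all-or-nothing:
planted pairs pass while their ranks stay near-perfectly anti-aligned and
fail abruptly once noise scrambles them; the exact null retention
probability P(SCC < −0.7) under independence is computed in the tests by
enumerating all 720 orderings. This is a property of the published
thresholds at this sample size, not of the implementation.

## Numerical choices

* The hypergeometric upper tail is summed in log space
  (`lchoose` + log-sum-exp), is symmetric in (K, M), and matches
  exhaustive enumeration of all `C(N, M)` draw subsets to < 1e−9 relative
  error on the full N ≤ 12 grid, and `phyper` elsewhere.
* Spearman uses average (mid-)ranks, exact under ties, implemented as
  Pearson of ranks rather than the `6Σd²` shortcut (biased under ties).
* Pairs with an undefined correlation (a constant vector) raise a typed
  condition, are dropped, and are counted in the result's attributes.
* Expression values are written at full precision; fixture emission and
  the staged pipeline are byte-reproducible from one integer seed (the
  run manifest deliberately carries no timestamp).
* BH adjustment delegates to `stats::p.adjust`, verified in the tests
  against an independent step-up implementation.

## Validation problem sizes

The test suite and the acceptance script validate on: the full N ≤ 12
hypergeometric grid against enumeration (~3,200 configurations); 1,000
random tied length-6 vectors for the Spearman/mid-rank identity; 1,000
random vectors for BH; 25-seed ensembles of the canonical fixture for
planted-triad recall (125 planted triads) and decoy-only false-positive
runs; and 100-seed null ensembles (3,600 background long-RNA features)
for FDR calibration. These sizes keep every check exact or tightly
estimated while completing in minutes on one core; they are the package's
validation design, and the same quantities can be recomputed at any other
seed with `scripts/acceptance.R`.

## Known limitations

* The Welch surrogate is not a count model; on real RNA-seq counts a
  negative-binomial tool should produce the DE table, which can then be
  fed into the downstream stages (`filter_mirna_targets()` accepts any
  table with `feature_id` and `is_de`).
* Correlations pool both groups (6 samples); with n = 3 per group,
  within-group correlation is not estimable, and pooled correlations
  conflate group shifts with coupling — exactly as in the published
  procedure this package operationalises.
* The pair test conditions on retained edges while using an expressed
  universe; as with all post-selection screens, its p-values are
  screening scores rather than calibrated error rates.
* miRNA–miRNA and ceRNA–ceRNA (non-mRNA partner) interactions are out of
  scope, as is target-site prediction itself: the prediction table is an
  input.
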