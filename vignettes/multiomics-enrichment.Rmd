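---
title: "Multi-omics pathway enrichment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics pathway enrichment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mogsea)
```

## The problem

A treatment or disease rarely perturbs a single molecular layer. Transcripts,
proteins and metabolites respond on different time scales and are measured
with different coverage, so a pathway that looks marginal in each layer alone
can carry consistent evidence across layers. `mogsea` scores pathways in each
omics layer separately with a gene set enrichment analysis (GSEA) and then
aggregates the per-layer pathway p-values into one multi-omics p-value.

The package deliberately starts *after* differential analysis: its inputs are
per-layer tables of `(feature_id, logFC, pvalue)` produced by whatever
differential-expression, -abundance or -concentration tool fits the assay.
Pathway definitions arrive as one GMT file per layer, and user-supplied
lookup tables translate between identifier namespaces (Entrez, UniProt,
symbols, Ensembl, RefSeq; HMDB, ChEBI, KEGG Compound, PubChem, CAS, DTXSID)
when the measurement platform and the pathway database disagree.

## Per-layer enrichment

### Ranking metric

Each layer's features are ordered by the signed log-transformed p-value

$$ s_i = \operatorname{sign}(\mathrm{logFC}_i)\,(-\log_{10} p_i), $$

so strong up-regulation sits at the top of the list and strong
down-regulation at the bottom. We fix base 10; the base rescales every
statistic by a constant and cannot change which running-sum extreme wins,
but fixing it makes scores reproducible across installations. Two
conventions need stating because they affect edge cases:

* `sign(0)` is treated as `+1`, so a feature with zero fold change but a
  tiny p-value still ranks by its significance rather than landing
  mid-list;
* `p = 1` gives statistic 0 regardless of sign; `p = 0` is rejected with an
  error — a p-value of exactly zero is a reporting artefact the caller must
  clamp, and accepting it would put infinities into the ranking.

Ties are broken by feature identifier in C-locale order, which makes the
ranking — and everything downstream — a pure function of the table contents,
independent of row order. Metric choice is known to matter for GSEA
outcomes (Zyla et al., *Bioinformatics* 2017), so `log_fold_change` is
exposed as an alternative (`signed_neg_log10_p` names the default
explicitly).

### Enrichment statistic

For a pathway with $N_H$ measured members in a ranked list of $N$ features,
the running sum gains $|s_i|^q / N_R$ at each member position ($N_R$ the sum
of $|s_i|^q$ over members) and loses $1/(N - N_H)$ at each non-member
position. The enrichment score (ES) is the signed extreme of this walk —
the weighted Kolmogorov–Smirnov statistic of Subramanian et al. (2005).
`exponent` $q$ defaults to 1 (weighted); $q = 0$ recovers the classical KS
form. Degenerate cases are defined, not left to chance: if every member
statistic is zero, members contribute uniformly $1/N_H$; an exact tie
between the positive and negative extreme resolves to the positive one; the
walk ends at zero by construction (total gain 1, total loss 1), which the
test suite checks to $10^{-12}$.

The hot loop is compiled (Rcpp), with the walk written as sequential
double-precision additions so the compiled batch path, the R reference
implementation and a naive re-walk agree bit-for-bit — the suite verifies
exact equality on every subset of lists up to 8 features, and
cross-checks against `fgsea::calcGseaStat` on larger random instances.

### Permutation null, p-value and NES

Only summary statistics are available, so the null is built by scoring
`n_perm` random feature sets of the same size drawn without replacement
from the ranked list (the same scheme fgsea uses; sample-label permutation
is impossible here). The p-value conditions on the sign of the observed
score and uses the add-one estimator

$$ p = \frac{1 + \#\{\text{same-sign null ES at least as extreme}\}}
            {1 + \#\{\text{same-sign null ES}\}}, $$

whose floor $1/(n_\text{perm}+1)$ guarantees $p > 0$ — necessary because the
downstream Fisher and Stouffer transforms diverge at $p = 0$. NES is the
observed ES divided by the mean magnitude of same-sign null scores, and is
missing when no same-sign nulls exist. `n_perm` defaults to 1000, putting
the floor at about $10^{-3}$; raise it if you need finer resolution at the
extreme tail (the package does not implement fgsea's adaptive multilevel
estimator for arbitrarily small p-values).

Pathways whose measured-feature overlap falls outside
`[min_size, max_size]` (defaults 5 and 500, the usual GSEA gate; the
originating method literature is silent on gating, so it is configurable)
are reported as `untestable` with missing statistics rather than dropped —
downstream layers may still test them. Within a layer, BH adjustment runs
over tested pathways only.

`share_null = TRUE` reuses one null pool per distinct overlap size across
pathways. This changes which random numbers each pathway sees (results are
statistically equivalent, not numerically identical to fresh pools) and is
the right choice for large collections; it stays off by default so that
default results never couple pathways through shared draws.

## Cross-layer combination

Per pathway, the *raw* per-layer permutation p-values (not the BH-adjusted
ones — adjusting before combining would penalise multiplicity twice) are
aggregated by one of:

* **Fisher**: $X^2 = -2\sum_i \ln p_i$ referred to the upper tail of
  $\chi^2_{2k}$ — the classical reference distribution with two degrees of
  freedom per test. Sensitive to a single small p-value: one strong layer
  can carry a pathway even when another layer's p-value is near 1.
* **Stouffer** (default): $Z_s = \sum_i Z_i / \sqrt{k}$ with
  $Z_i = \Phi^{-1}(p_i)$, combined p-value $\Phi(Z_s)$. Treats layers
  evenly; the weighted form $Z_s = \sum w_i Z_i / \sqrt{\sum w_i^2}$ takes
  user-supplied per-layer weights (weights proportional to the square root
  of per-layer sample sizes are the standard recommendation; the package
  infers nothing). Equal weights reduce to the unweighted form bitwise,
  because the weight scale cancels and the implementation routes that case
  through the unweighted formula.
* **Edgington**: with $S = \sum_i p_i$, the combined p-value is the
  alternating series $\sum_{j=0}^{\lfloor S\rfloor} (-1)^j \binom{k}{j}
  (S-j)^k / k!$ — the Irwin–Hall CDF, i.e. the probability that $k$
  independent uniforms sum to at most $S$. The series' stopping rule is
  stated in the literature as "until the numerator becomes negative",
  which is ambiguous for even powers; truncation at $j = \lfloor S\rfloor$
  is the reading that reproduces the Irwin–Hall identity and is what we
  implement and test against Monte Carlo. Conservative for small p-values,
  responsive to large ones.

All three are exactly calibrated under the null (uniform combined p for
independent uniform inputs), which the acceptance suite verifies with
$10^5$ simulated triples. A consequence worth knowing: the three methods
differ in *where* their equal-measure rejection regions sit, not in how
much they reject under the null. Fisher's region hugs the axes (hence its
asymmetric sensitivity), Edgington's is the simplex corner $p_1 + \dots +
p_k \le \sqrt[k]{\alpha\,k!}$.

Before Fisher/Stouffer, p-values are clamped to
$[10^{-15}, 1 - 10^{-15}]$ with a warning; in practice only exact $p = 1$
(an ES of zero, or every same-sign null at least as extreme) triggers
this, since the permutation floor bounds the other side.

Pathways missing from a layer (untestable or absent from that layer's GMT)
are handled by `missing_policy`: `available-layers` (default) combines over
the $k_\text{used}$ layers that tested the pathway — dropping such pathways
would systematically remove everything lacking, say, metabolite
annotation — while `require-all` leaves the combined value missing. The
per-row `k_used` column lets users filter either way. Combined p-values are
BH-adjusted across pathways by default (`adjust_combined = FALSE` to opt
out; the choice of adjustment is deliberately left to the user).

## The synthetic study generator

`simulate_study()` generates the fully self-contained reference study used
for calibration and recovery analysis: three layers
(transcriptome/proteome/metabolome) of 2000 features each, 50 pathways with
per-layer sizes uniform on [15, 60] — comfortably inside the size gate and
typical of curated pathway databases. Null features draw
$p \sim \mathrm{Uniform}(0,1)$ and $\mathrm{logFC} \sim N(0,1)$. Planted
pathway members in affected layers draw $p = U^{1+\text{shift}}$ — a family
chosen because it is exactly uniform at shift 0 (continuous with the null)
and needs no special functions — with positive fold changes $|N(1, 0.5)|$;
the default shift 4 represents a strong, clearly recoverable perturbation.
An optional background fraction of differential features (shift 2, random
sign) models nonspecific signal. All randomness derives from one seed via
per-layer derived streams, so adding a layer never perturbs another layer's
draws and identical configurations write byte-identical files.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: heteroscedastic, intensity-dependent noise;
correlation between features within a pathway; and correlation between
layers. The last two matter most: the combiners assume independent
per-layer tests, and correlated layers make all of them anticonservative.
That is a property of the method, not of this implementation, and is the
main caveat for interpreting combined p-values on real multi-omics data,
where the same underlying biology drives several layers.

## Problem sizes and numerical choices

The shipped analyses are sized to run on a laptop core: combiner
calibration uses $10^5$ replicates (standard error on a 5% rate:
$\pm 0.0007$); GSEA calibration 200 random sets at 500 permutations;
planted-pathway recovery 50 replicates of the full reference study at 1000
permutations with shared null pools (~2–3 minutes total). Recovery
replicates carry two planted pathways at once — one in all three layers
(expected to rank first by Stouffer-combined p), one in two of three
(expected to beat its best single-layer p) — which halves simulation cost
without weakening either claim, since the two signals occupy different
pathways.

Other numerical decisions, collected: GMT members are written
lexicographically sorted so output is byte-stable; pathway identity across
layers is exact string match on the GMT name field; identifier matching is
case-sensitive with no prefix normalisation (HMDB's 5- vs 7-digit forms
are distinct identifiers here — supply a mapping table that bridges them);
the one-to-many mapping policy defaults to `all`, keeping every target
identifier, which is conservative for set-based enrichment; Edgington
results are clamped into $(0, 1]$ so a degenerate all-zero input cannot
produce $p = 0$.

## Limitations

Beyond the independence caveat above: only node sets are used — pathway
topology is ignored by design (this is a set-based, not topology-based,
method); leading-edge subsets are not reported; p-values below the
permutation floor are not resolved further; and the package retrieves
nothing over the network — pathway definitions and mapping tables are
explicit inputs, which is what makes every analysis reproducible from its
manifest.
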