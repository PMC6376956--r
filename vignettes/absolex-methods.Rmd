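---
title: "Absolutist-language scoring and nested inference: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolutist-language scoring and nested inference: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absolex)
```

This vignette documents the statistical machinery in `absolex`: the scoring
model and its false-positive correction, the multilevel group comparison,
the bootstrap and sensitivity procedures, the factor-analytic tools, and —
because every design has open corners — the choices we made where the
methodology itself does not dictate one, and what the synthetic-data tests
do and do not establish about real corpora.

## 1. Scoring model

### Tokenizer dialect

Closed-vocabulary ("word count") analysis is only as well-defined as its
tokenizer. `tokenize()` fixes one dialect and the whole package is
self-consistent with respect to it:

* lowercase everything; normalize the typographic apostrophe to `'`;
* tokens are maximal runs of letters/digits, with *internal* apostrophes
  kept, so contractions ("don't") are single tokens;
* hyphens split ("well-known" is two tokens); numerals count as tokens;
* sentence boundaries fall at `. ! ? ;` and newlines. Newlines matter
  because a member's posts are concatenated with `\n`: making the join a
  sentence boundary guarantees that no multiword phrase can match across
  two posts.

Commercial word-count engines each have their own (proprietary) dialect, so
bit-exact agreement with any of them is not a goal; self-consistency — the
same rules for word counts, indices and phrase matching — is the contract,
and indices are ratios of counts under one dialect, which makes them robust
to dialect details at the margins.

### Indices and the false-positive correction

For a lexicon $D$ and a document with $N$ tokens, the raw index is
$I_{\mathrm{raw}} = 100\,\#\{t \in D\}/N$. Absolutist words generate three
systematic classes of *false positives* — the word is present but absolutism
is not expressed:

* **negation**: "not completely";
* **qualifier**: "almost completely";
* **salutation**: "hello everyone" at the top of a post.

Each false-positive pattern is a multiword phrase containing exactly one
lexicon word (a validated invariant). Matches are counted as contiguous
token subsequences, leftmost and non-overlapping, each lexicon-word token
consumed by at most one match; negation/qualifier phrases must sit inside
one sentence, and salutations only match when they start within the first
3 tokens of the document (greetings are positional; the original
methodology does not state a window, so the 3-token rule is this package's
documented choice). The false-positive index uses the *same* denominator
$N$, so $I_{\mathrm{corr}} = I_{\mathrm{raw}} - I_{\mathrm{fp}} \ge 0$ is a
subtraction on a common per-token scale. Any residual false positives are
assumed equidistributed across groups and left uncorrected.

The test suite checks the scorer against an independently coded brute-force
scan on thousands of random token fixtures (exact equality, not tolerance),
and the salutation/negation identities ("not always" repeated 50 times has
corrected index exactly 0).

### Judge-panel arithmetic

Dictionary membership is finalized by majority vote of independent judges
who may multi-label (absolute / extreme / nonabsolute). The decision of
record is binary — absolute or not — so multi-label votes resolve with the
precedence absolute > extreme > nonabsolute. Items proposed as absolutist
that fail to win a strict absolute majority are reassigned to the
nonabsolutist side; with an even panel a tie is flagged `unresolved` and
excluded rather than silently assigned (a 5-judge panel never ties on the
binary question, so this branch only matters for user-supplied panels).
"Extreme" is parsed but collapsed into nonabsolutist downstream: judge
agreement on extremeness is known to be poor, and the package keeps that
category only as an annotation.

## 2. Group comparison model

Members are nested in forums, forums in groups. The analysis model for an
index $x$ is

$$ y_{ijk} = \log_{10}(x_{ijk} + 1), \qquad
   y_{ijk} = \mu + \gamma_{g(j)} + u_j + \varepsilon_{ijk}, \quad
   u_j \sim N(0, \sigma_f^2), \quad
   \varepsilon_{ijk} \sim N(0, \sigma^2 / w_{ijk}), $$

with $w_{ijk}$ the member's word count. The pieces, and why:

* **Transform.** Indices are nonnegative and right-skewed;
  $\log_{10}(x+1)$ corrects the skew and maps 0 to 0 (identities
  $\{0, 9, 99\} \to \{0, 1, 2\}$ are asserted exactly in the tests).
* **Weights.** "Weight residuals by word count" names a target, not a
  mechanism; we implement it as analytic (inverse-variance-style) weights,
  which is the natural reading — a 3,000-word document pins down its
  member's index ten times more precisely than a 300-word one, since the
  token-sampling variance of an index scales as $1/w$.
* **Random intercepts for forums** make the forum the effective replication
  unit for group contrasts; with 4–7 forums per group, omnibus denominator
  df land in the single or low double digits, which is faithful to the
  design (members within a forum are not independent evidence about group
  differences).
* **Estimation and df.** REML by default (ML is appropriate when comparing
  nested fixed-effects models); denominator df by the Satterthwaite
  approximation via `lmerTest`. Reported F denominators are therefore
  approximation-dependent — exactly reproducing another software package's
  denominator df is a non-goal.
* **Degenerate inputs.** A singular fit (forum variance estimated at zero)
  is reported with the component pinned at 0 and a warning, never an error;
  a constant outcome returns $F = 0$, $p = 1$. With `forum_re = FALSE` the
  model reduces to a weighted one-way ANOVA/ANCOVA, and the tests assert
  equality of its omnibus F with the closed-form weighted ANOVA to 1e-6.

**Contrasts and effect size.** A pairwise contrast is the difference of
adjusted group means on the transformed scale with a model-based SE.
Cohen's $d$ is reported as a magnitude: $|\hat\Delta|$ divided by the
pooled *member-level* SD of the transformed outcome in the two groups.
Conventions for $d$ in multilevel designs vary (raw vs transformed scale,
member-level vs forum-level SD, model-based vs sample SD); the
transformed/member-level convention matches the scale on which the model,
p-values and bootstrap CIs live, and `d_scale = "raw"` provides the
raw-percentage alternative. Raw-scale group means and SDs are always
attached to contrasts for interpretability. Bonferroni correction is
$p_{\mathrm{adj}} = \min(1, m\,p)$.

**ANCOVA.** Covariate indices (e.g. certainty, negative-emotion, pronoun
prevalences) enter on the same transformed scale; constant or collinear
(|r| > 0.999) covariates are rejected by name. When covariates explain the
outcome exactly, the group effect is reported as $F = 0,\ p = 1$ rather
than NaN.

## 3. Stratified BCa bootstrap

CIs for contrasts come from a stratified nonparametric bootstrap: members
are resampled with replacement *within each forum* (forums are the strata,
preserving the design's clustering), 1,000 resamples by default, and the
interval is bias-corrected and accelerated:

* $z_0 = \Phi^{-1}(\Pr^*(\hat\theta^* < \hat\theta))$, with half-weight on
  ties and clamping to $[1/2B, 1 - 1/2B]$;
* acceleration $a$ from a jackknife over members,
  $a = \sum (\bar\theta_{(\cdot)} - \theta_{(i)})^3 / 6[\sum(\bar\theta_{(\cdot)} - \theta_{(i)})^2]^{3/2}$;
* endpoints by interpolation of order statistics on the normal-quantile
  scale (the same convention as the `boot` package, against which the BCa
  arithmetic is cross-checked on shared replicates in the tests).

With $z_0 = a = 0$ the interval reduces *exactly* to the percentile
interval (asserted to the last bit). Constant data yield a zero-width
interval at the point estimate; a statistic degenerate on more than half
the resamples is an error, not an average.

The default bootstrap statistic is the word-count-weighted difference of
transformed group means recomputed per resample. Refitting the full mixed
model per resample is available (`statistic = "model"`) but is not the
default: the mean difference matches the scale of the model contrasts,
keeps $B = 1000$ cheap, and whether the original procedure refit the model
per resample is not documented — this is an explicitly open corner, so both
are provided.

A coverage experiment in the test suite (500 simulated two-group datasets,
$n = 200$, known mean difference) checks that the nominal 95% interval
covers between 90% and 98% of the time.

## 4. Sensitivity analysis

`leave_one_forum_out()` refits the model and recomputes a contrast set with
each forum of a probed group excluded in turn — one full result set per
forum — and summarizes the min–max range of $d$ and $p$ per contrast. A
narrow range indicates results not driven by a single forum. The probed
group must have at least two forums; excluding a forum that exactly
duplicates another leaves estimates unchanged (asserted to 1e-9).

## 5. Per-word factor structure

`word_index_matrix()` gives each word its own per-member prevalence.
`efa_oblimin()` runs principal-axis extraction with iterated communalities
followed by a direct oblimin (quartimin) rotation via the gradient
projection algorithm, returning the pattern matrix, factor correlations,
and a view filtered at a loadings cutoff (default 0.55). Although the
original analysis is labeled confirmatory, rotation plus a cutoff is an
exploratory device; the package therefore exposes both the EFA and a real
confirmatory model and documents the distinction. Non-positive-definite
correlation matrices are eigenvalue-smoothed with a warning. The number of
factors is the caller's choice; two is the natural default for a combined
absolutist/nonabsolutist word list (one factor per dictionary). Sign
indeterminacy is resolved by orienting each factor so its largest loading
is positive. The rotation is verified in the tests against direct
minimization of the quartimin criterion over a rotation-angle grid.

`cfa_one_factor()` fits the one-factor measurement model by ML (loadings
and uniquenesses free, factor variance fixed at 1), giving
$\chi^2 = (n-1)F_{ML}$ with $df = p(p+1)/2 - 2p$ (14 for seven
indicators), and fit indices against the independence baseline: CFI and NFI
with the usual definitions (clipped to $[0,1]$), and GFI through the ML fit
function, $\mathrm{GFI} = 1 - \operatorname{tr}[(\Sigma^{-1}S - I)^2] /
\operatorname{tr}[(\Sigma^{-1}S)^2]$ — GFI has several circulating
definitions, so the formula is fixed here and in the docs. The discrepancy
minimum and loadings are cross-checked against `stats::factanal` (which
fits the same ML problem) to 1e-3 on a fixed fixture; non-convergence is
reported as `converged = FALSE` with no indices rather than as numbers.

## 6. The synthetic-data generator

`generate_corpus()` emulates the nested design with known truth, so the
whole pipeline — file layout, tokenization, phrase matching, model,
contrasts — can be exercised end to end:

* member level: $t_m = \log_{10}(\mu_g + 1) + u_f + e_m$ with Gaussian
  forum and member effects *on the transformed scale* (so the default
  generator matches the analysis model's assumptions; `re_scale = "raw"`
  provides a deliberate misspecification toggle), inverse-transformed and
  floored at zero to give the member's emission rate;
* tokens i.i.d. per member: an absolutist word with the member's rate, of
  which a configurable fraction `fp_rate` is emitted wrapped in a
  negation/qualifier phrase; auxiliary-lexicon words at configured rates;
  neutral filler otherwise. Documents open with a salutation phrase with
  probability `salutation_rate`. A wrapped emission occupies extra tokens,
  so the per-slot rate is solved from the target corrected index
  ($\rho = r / (1 - f - r f (\bar L - 1))$ for mean phrase length
  $\bar L$) — the *corrected* index is the quantity with mean $\mu_g$;
* word counts are lognormal truncated below at 100 (the post-selection
  floor); defaults are meanlog $\log 280$, sdlog 0.4, i.e. a median near
  280 and mean near 300 words — the scale of a corpus built from ~30,000
  words per forum and ~100 contributing members;
* default group sizes (4–7 forums per group, 100 members per forum) and
  default means (0.97–1.80%) mirror the published design's scale; default
  variance components $\sigma_f = 0.05$, $\sigma_m = 0.18$ were fixed a
  priori from the published descriptives: member-level raw SDs of
  0.85–1.04 at means of 0.97–1.80% transform to about 0.31, of which about
  0.7 percentage points of raw spread at ~300 words is token-sampling
  noise, leaving $\sigma_m \approx 0.18$; the near-null omnibus among
  control forums and contrast SEs near 0.01 imply a small between-forum
  component, $\sigma_f \approx 0.02$–0.05.

The generator excludes phrase context words ("not", "almost", "hello") from
the filler and auxiliary emission pools, so the phrase matches in the
generated text are exactly the planted ones: the truth table reconciles
with `score_corpus()` *exactly*, token for token, which the tests assert.
Filler is a fixed list of 1,000 pronounceable pseudo-words disjoint from
all lexicons, which guarantees zero accidental hits.

### Parameter recovery, and a known attenuation

`recovery_experiment()` runs generate → score → fit per replicate and
compares estimates with truth. One subtlety is documented rather than
hidden: the model estimates the group mean of the *transformed observed*
index, and since the observed index is the true rate plus token-sampling
noise, Jensen's inequality gives the transformed mean a deterministic
downward attenuation of order $1/w$ — about $-0.018$ at 300 words per
member (exact binomial computation), shrinking to $-0.005$ at 1,000 words.
No estimator of the transformed mean can avoid it at fixed document length,
it is nearly identical across groups (so contrasts are essentially
unbiased), and it is small relative to the estimator's sampling SD at the
default design size (bias/SD ≈ 0.4 in the shipped experiments). The
recovery report therefore shows, per group: bias against the generating
truth, the per-replicate SD of the estimator, and the Monte-Carlo SE of the
bias estimate, so both comparisons are visible. Recovery experiments at the
default scale (2 groups × 4 forums × 100 members, 200 replicates) and a
400-replicate null configuration (type-I error within [0.025, 0.075]) run
in the test suite and in `scripts/acceptance.R`; problem sizes were chosen
as the smallest at which the checks are statistically meaningful.

The member-level SD reported by the recovery experiment is the within-forum
SD of the transformed outcome, which includes the token-sampling component
and therefore sits slightly above $\sigma_m$ by construction (about +0.02
at the default word-count law); the forum SD comes from the fitted variance
component and is directly comparable to $\sigma_f$.

### What passing synthetic tests does not show

The generator produces i.i.d. token emissions over a neutral filler
vocabulary: no topics, no syntax, no burstiness, no member-specific style,
no correlation between word count and severity, and false positives only of
the three modeled phrase classes. Passing recovery tests therefore
validates the *pipeline arithmetic and inference machinery* under the
stated model — not the linguistic validity of any lexicon on real forums,
nor robustness to false-positive classes outside the phrase inventory.

## 7. Shipped lexicons

The shipped absolutist dictionary has 19 validated words plus the three
archetypal false-positive phrases; the phrase inventory is deliberately
minimal and user-extensible through the lexicon file format (`~phrase<TAB>tag`
lines). The shipped *nonabsolutist* lexicon is a clearly labeled synthetic
stand-in (the validated nuance dictionary is not redistributable): it keeps
the documented exemplar words and pads with generic nuance/intensifier
vocabulary to the documented size (43 words, 21 tagged extreme). It exists
so tests and examples can exercise multi-lexicon scoring and must not be
used to reproduce published nonabsolutist scores.

## 8. Reproducibility

Every stochastic operation takes an explicit integer seed (default
20180105); the bootstrap is endpoint-reproducible given its seed, the
generator is byte-identical given its config, and `run_study()` writes a
manifest (config, seed, lexicon checksums, tokenizer version) from which
the whole bundle can be regenerated. `scripts/acceptance.R` recomputes the
package's verification quantities from scratch with all randomness derived
from a single `--seed`.

## 9. Known limitations

* The tokenizer dialect is fixed; corpora scored elsewhere will differ at
  the margins (typically in the second decimal of an index).
* Members posting in several forums are treated as distinct documents —
  identity resolution across forums is unknowable from public data.
* The bootstrap default resamples members, not forums; with very few
  forums per group, forum-level uncertainty is carried by the mixed model's
  df, not by the interval.
* The EFA/CFA tools assume roughly continuous indicators; per-word indices
  of very rare words are zero-inflated, and loadings for such words should
  be read with care.
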