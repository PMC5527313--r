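---
title: "Scoring inducible SGA screens: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring inducible SGA screens: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgascore)
```

## The experiment and the model

An induction SGA screen pins an arrayed strain collection in quadruplicate
(384-format parents, 1536-format screen plates) onto otherwise identical
plates with and without an inducer, and asks which gene deletions change
the fitness cost of switching the construct on. Colony area is the fitness
proxy. Three properties shape the statistics:

1. **The treatment affects most colonies.** A global induction effect
   shifts the whole colony-size distribution, so any normalization that
   forces plates to a common scale ("plate normalization") would erase the
   signal. We therefore normalize only *within* plates (spatial surface,
   row/column medians) and model the global shift explicitly as `Wi`.
2. **Replicates are few (4) and occasionally corrupted** — a pinning
   failure can produce one wildly deviant colony in a quadruplicate, and
   colonies can be missing altogether. This motivates median-based
   statistics, a leave-one-out (jackknife) replicate filter, and
   empirical-Bayes variance moderation for the test.
3. **Interactions are defined multiplicatively.** For strain $x$ and
   query $q$, with $W_{ij}$ the observed induced/uninduced median-area
   ratio of the strain, $W_i$ the same ratio over all colonies of the
   query, and $W_j$ the strain's relative uninduced fitness across all
   queries, the interaction score is
   $$S = W_{ij} - W_i \times W_j,$$
   zero when the induction effect and the deletion's baseline effect
   combine independently, positive for alleviating and negative for
   aggravating interactions.

Calling an interaction requires **two independent gates**: a moderated
fold-change-threshold test on replicate log2 differentials (statistical
evidence the strain's response differs from the screen-wide response by
more than the threshold fold), and an effect-size gate on $S$. A third,
biological gate restricts calls to strains that are well behaved in the
control query.

## The pipeline, stage by stage

### Normalization

`spatial_normalize()` divides each colony by the median of its
window-by-window neighborhood (default 9, missing-aware, truncated at
plate edges) and rescales so the plate median is unchanged. A moving
*median* rather than mean keeps genuine biology — including strong planted
interactions — out of the estimated surface, as long as responders are a
local minority. `rowcol_normalize()` then divides each row by
(row median / plate median) and each column likewise, catching the striped
artifacts pinning robots produce. Both operators never fill missing cells
and never produce negative areas; a row or column that is entirely missing
is left unscaled.

The surface cannot distinguish artifact from biology when a large
contiguous fraction of a neighborhood truly responds; with the default
window, planted fractions up to roughly 10–20% are safely in the minority
regime. This is a fundamental limitation of within-plate normalization,
not of the implementation.

### Replicate filters

`jackknife_filter()` flags a replicate contributing more than a fraction
(default 0.9) of its set's sample variance, measured as
$(\mathrm{Var}(\text{all}) - \mathrm{Var}(\text{all} \setminus i)) /
\mathrm{Var}(\text{all})$ with the $n-1$ variance. At most one replicate —
the maximal contributor — is flagged per set: above fraction 1/2 two
replicates cannot both qualify under this definition, and the cap prevents
cascades. Sets with fewer than three usable replicates skip the filter;
zero-variance sets flag nothing.

`low_area_filter()` drops a strain when its induced + uninduced median
areas sum below `min_sum` (default 400 on the normalized area scale, i.e.
both colonies are near dead and the ratio is numerically meaningless). A
strain dropped in *any* screen of a jointly scored set is dropped from all
of them, so every screen reports the same strain universe. Note the
consequence: a truly lethal interaction in one query removes the strain
everywhere — extreme negatives are censored by design, in exchange for
cross-screen comparability.

### W statistics and medians

All W statistics are ratios of medians over *retained* colonies (jackknife
survivors of non-missing colonies, strains passing the low-area filter).
Medians of even counts are the mean of the two central order statistics —
stated explicitly so that every number in a results table can be
reproduced bit for bit from the observation table, which the fitted object
retains (`fit$observations`). `Wj` pools the uninduced plates of **all**
queries, including the control; a strain absent from some query's
uninduced plates simply contributes the colonies it has.

`usable` is false (and the record `filtered`) whenever a denominator
median is zero or a condition has no retained colonies; no score is ever
computed from a zero denominator.

### The moderated threshold test

Per strain, induced and uninduced replicates are paired **positionally**
(same quadruplicate slot on the same plate tile — they share pinning
position and local plate context), giving differentials
$d_r = \log_2 a^{\text{ind}}_r - \log_2 a^{\text{unind}}_r$. Pairs with a
missing, filtered, or zero-area side are dropped; strains with fewer than
two pairs are untestable and classified `filtered`. The log scale is used
for variance stabilization of multiplicative noise.

The null hypothesis is that a strain's differential equals the screen-wide
expected differential, estimated as the **median over strains of
per-strain median differentials** (`null_center`) — robust to the planted
minority. Per-strain sample variances $s_x^2$ (df $= n_x - 1$) are
moderated by a scaled inverse chi-square prior fit by the standard
log-variance moment equations: with $z = \log s^2$ and
$e = z - \psi(d/2) + \log(d/2)$, the mean of $e$ identifies $\log s_0^2$
and the excess of $\mathrm{Var}(e)$ over $\psi'(d/2)$ identifies
$\psi'(d_0/2)$, inverted by Newton iteration. Posterior variances are
$s^2_{\text{post}} = (d_0 s_0^2 + d_x s_x^2)/(d_0 + d_x)$; `d0_override = 0`
disables moderation, and a degenerate variance distribution collapses to
$d_0 = \infty$. The pre-installed reference implementation of this
moderation is used in the test suite as an independent cross-check, never
as the implementation.

With $\Delta$ the centered mean differential,
$\tau = \log_2(\text{fold\_threshold})$ (default fold 1.3, so
$\tau \approx 0.379$), $se = s_{\text{post}}/\sqrt{n}$ and
$T \sim t_{n - 1 + d_0}$, the p-value is the composite tail
$$p = P\!\left(T \ge \tfrac{|\Delta| - \tau}{se}\right) +
      P\!\left(T \ge \tfrac{|\Delta| + \tau}{se}\right),$$
which equals the two-sided moderated t-test at $\tau = 0$, approaches 1
for null-centered effects, and is monotone in $\tau$ and $|\Delta|$.
Degenerate $se = 0$ gives $p \in \{0, 1\}$ by comparing $|\Delta|$ with
$\tau$. Benjamini–Hochberg q-values are computed **within each query's
strain set** (each screen is its own multiple-testing family and is
presented per query; pooling across queries would let a strong screen
distort a weak one's q-values).

### Classification

A strain is eligible only if its control-query $W_{ij}$ lies in the closed
window $[0.7, 1.3]$ — outside it, the strain interacts with the control
construct or its induction machinery, and attributing its response to the
query payload would be unsound. Eligible strains are `positive` when
$q \le 0.05$ and $S > 0.3$, `negative` when $q \le 0.05$ and $S < -0.3$.
The positive gate requires $S$ strictly *above* +0.3: the thresholds are
symmetric effect-size gates, and a "positive" class that admitted negative
scores would be incoherent with the sign convention of $S$.

### Compound mode (petite / drug screens)

When the second perturbation is a strain background (petite, [rho−]) or a
medium additive (hydroxyurea) rather than an arrayed deletion, the ratios
are conditional: $W_i$ = variant untreated / parent untreated (the
variant's baseline cost), $W_j$ = parent treated / parent untreated (the
parent's induction response), $W_{ij}$ = variant treated / variant
untreated (the induction response *inside* the variant). Because $W_{ij}$
and $W_j$ are both already conditional induction responses, the product
form $W_i \times W_j$ does not predict $W_{ij}$ under independence —
$W_i$ has already cancelled out of it. `compound_w_triple()` therefore
scores the contrast
$$S = W_{ij} - W_j,$$
which is exactly 0 for independent multiplicative effects, and reports
$W_i$ alongside; scores below −0.1 are called synthetic sick. This is a
deliberate reading: applying the array-mode formula verbatim to the
conditional ratios would make $S$ track the variant's baseline cost even
with no synergy at all, contradicting the interpretation that $S \approx 0$
means no interaction.

### FD scores and profile correlation

Fitness-defect scores are $\mathrm{FD} = -\log_2 W_{ij}$: positive when
induction shrinks colonies. The sign is a convention, exposed as a setting
(`fd_score(..., sign =)`), since correlations flip coherently either way;
the default makes screens comparable with published chemogenomic FD
matrices oriented defect-positive. `correlate_fd_profiles()` computes
Pearson correlations per reference experiment over pairwise-complete
shared strains, p-values via the t-transform on $n-2$ df, and BH
correction across experiments (significance gate q ≤ 0.01). Experiments
sharing fewer than `min_overlap = 30` strains are skipped — the t-transform
is unreliable at small $n$, and the reference matrices are sparse enough
that a floor is needed. The profile uses the strains that passed the
screen's own filters.

## The synthetic screen generator

`generate_screen()` is first-class, tested code — every downstream stage
is validated against screens whose truth is known by construction.
Uninduced colonies are $B_x \cdot T(r,c) \cdot \varepsilon$ and induced
colonies $B_x \cdot W_i^{(q)} \cdot I_{x,q} \cdot T(r,c) \cdot
\varepsilon$, with:

* $B_x$ — per-strain baseline area, log-normal around 500 area units. The
  **default log-sd is 0**, so every strain's expected baseline is equal
  and the true $W_j$ is exactly 1 by construction, keeping the stored
  truth $S = W_i (I - 1)$ analytically exact. A positive
  `baseline_log_sd`, or the slow-strain option
  (`slow_strain_fraction`/`slow_strain_factor`), adds strain-specific
  uninduced fitness effects that exercise the $W_j$ term — the recovered
  $S$ then legitimately deviates from the stored truth, which is precisely
  the behavior those settings exist to study.
* $W_i^{(q)}$ — the query's global induction effect (default 1 for the
  control query, 0.8 elsewhere: induction costs ~20% colony size across
  the board, a visible but not crushing global shift).
* $I_{x,q}$ — planted interaction factors, drawn for 5% of strains per
  non-control query from the ranges (0.3, 0.5) and (1.8, 2.2) by default
  (≥ 2-fold effects in either direction). The control query is never
  planted: its role is the no-interaction eligibility gate.
* $T(r,c)$ — a smooth multiplicative bilinear log-gradient whose max/min
  ratio is exactly `1 + spatial_gradient_amplitude` (default 0.2). Real
  plate artifacts are unpublished; a smooth low-order surface reproduces
  what spatial normalization must remove without pretending to
  reconstruct any particular scanner.
* $\varepsilon$ — log-normal replicate noise with CV 0.1 and **median 1**
  (log-mean 0), so that median-based statistics are unbiased by
  construction.
* Corruption — with probability 0.01 per strain and condition plate, one
  replicate is multiplied by 4 (exactly the case the jackknife filter
  targets); colonies go missing independently with probability 0.01
  (absent records, not zeros — a zero area is a legitimate measurement of
  a dead spot and is generated separately via $I \approx 0$).

Identical configurations and seeds reproduce screens bit for bit, and the
generator restores the caller's RNG state.

What the generator does **not** emulate: agar/nutrient competition between
neighboring colonies, growth saturation, pinning-order effects, image
segmentation artifacts, or biological replicate structure beyond the
quadruplicate. Passing recovery tests on these screens therefore
demonstrates the statistical machinery is correct and calibrated under the
stated noise model — not that any particular real screen meets that model.

## Numerical conventions

* Even-count medians: mean of the two central order statistics,
  everywhere.
* Jackknife uses the sample ($n-1$) variance; the flag criterion is a
  variance ratio, so the choice only needs to be fixed and documented for
  oracle reproducibility.
* Low-area boundary: a sum exactly at `min_sum` is kept (the rule is
  strict `<`).
* The control window is the closed interval — boundary strains stay
  eligible.
* A zero local median in the spatial surface (≥ half a neighborhood dead)
  falls back to the plate median rather than dividing by zero.
* Ties in BH are handled by the step-up minimum; permuting the input
  permutes the output.
* `trigamma` inversion runs Newton steps to relative tolerance 1e-10.

## Validation scale

The bundled validation (tests and `scripts/acceptance.R`) exercises the
pipeline at the sizes where its guarantees are stated: exact W/S oracle
agreement on 4-query × 500-strain screens, jackknife brute-force
equivalence on 10,000 replicate sets, and calibration/recovery on
2,000-strain, 2-query screens over three seeds each — null screens to
bound the false-call rate, planted screens (5% interactions, ≥ 2-fold) to
bound sensitivity and empirical FDR. These sizes keep a full run in the
low tens of seconds on one core while matching the strain counts of real
arrayed collections within a small factor.

## Known limitations

* $W_j$ folds strain baseline fitness into the array-mode score: for
  strongly slow-growing strains, $S = W_{ij} - W_i W_j$ mixes baseline and
  interaction signal. The classification gates (q-value and control
  window) do not depend on $W_j$, which bounds the damage, but S-score
  rankings of very sick strains should be read with care.
* The low-area filter censors lethal interactions (see above).
* Within-plate normalization assumes responders are a local minority of
  every window, row and column.
* The threshold test assumes approximately log-normal replicate noise;
  heavy-tailed corruption beyond the single-outlier-per-set pattern the
  jackknife removes will inflate variances and cost power, not
  calibration.
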