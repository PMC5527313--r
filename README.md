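# sgascore

Interaction scoring for inducible synthetic genetic array (SGA) screens.

In a classic SGA experiment the perturbation is a second mutation
introduced by crossing. In an *induction* SGA screen the perturbation is
switched on chemically instead: every strain of an arrayed deletion
collection carries an inducible construct (for example a doxycycline-driven
bacterial nucleotide synthetase), and each array is pinned in quadruplicate
to 1536-format plates with and without the inducer. Fitness is read out as
colony area. Because induction typically shifts *most* colonies, the usual
plate-normalization assumption (colony-size changes are rare) is invalid,
and the analysis has to work from replicate medians and a screen-wide
expected response instead.

`sgascore` implements that analysis end to end:

* **Grid preparation** — missing-aware spatial normalization (moving-median
  surface division) and row/column median normalization of each plate;
  jackknife filtering of replicates contributing > 90% of their
  quadruplicate's variance; a low-area filter dropping strains whose
  induced + uninduced median areas sum below 400 (dropped strains are
  removed from *all* screens scored together). Plate-level normalization is
  deliberately absent.
* **Interaction scoring** — the median-ratio statistics
  `Wij` (induced/uninduced median-area ratio of strain *x* in query *q*),
  `Wi` (the same ratio over all colonies of the query: the expected
  induction effect) and `Wj` (strain *x*'s uninduced fitness relative to
  the array, across all queries), combined into the multiplicative
  interaction score

  ```
  S = Wij − Wi × Wj
  ```

  which is 0 under independence, positive for alleviating and negative for
  aggravating interactions. FD (fitness-defect) scores are `−log2(Wij)`.
* **Moderated threshold testing** — per-strain paired log2 differentials
  against the screen-wide expected differential, empirical-Bayes variance
  moderation (scaled inverse chi-square prior fit by log-variance moments),
  and a fold-change-threshold test (default 1.3-fold) whose p-values get
  per-query Benjamini–Hochberg correction. Interactions are called at
  q ≤ 0.05 and |S| > 0.3, restricted to strains whose control-query
  response lies in [0.7, 1.3].
* **Compound mode** — the petite [rho−] / hydroxyurea variant, where the
  score contrasts the induction response inside the variant background with
  the parent's; S < −0.1 is called synthetic sick.
* **Profile correlation** — Pearson correlation of a screen's FD profile
  against a reference chemogenomic FD matrix with BH correction (q ≤ 0.01)
  and response-signature summaries.
* **Synthetic screens** — `generate_screen()` builds complete plate sets
  with planted interactions and known ground truth, so the whole chain is
  testable without any external data.

## Worked example

```r
library(sgascore)

cfg <- screen_sim_config(n_strains = 1000, n_queries = 3, seed = 42)
sim <- generate_screen(cfg)      # 5% planted interactions in Q02 and Q03
fit <- score_screen(sim)
summary(fit)
```

```
Induction-screen interaction scoring
control query: Q01; strains dropped by low-area filter: 0

  query_id     wi null_center     d0   s0_sq positive negative none filtered
1      Q01 1.0010    0.004691 10.576 0.03044        0        0  997        3
2      Q02 0.7961   -0.329434 15.259 0.03170       29       21  946        4
3      Q03 0.7972   -0.331068  6.111 0.02602       22       25  951        2
```

`wi` is the recovered screen-wide induction effect (the simulation plants
0.8 for the non-control queries — induction costs ~20% colony size across
the board), `null_center` the expected log2 differential the test centers
on (≈ log2 0.8), and `d0`/`s0_sq` the fitted variance-moderation prior.
The control query calls nothing; the two induced screens call ~50
interactions each, matching the 5% planting. Per-strain records carry the
full chain:

```r
head(subset(fit$records, class != "none" & query_id == "Q02",
            select = c(strain_id, wij, wi, wj, s, q_value, class)))
```

```
     strain_id       wij        wi        wj           s      q_value    class
1024     S0024 1.3366549 0.7960718 0.9816716  0.55517386 3.568078e-03 positive
1049     S0049 1.5381082 0.7960718 0.9910870  0.74913180 1.223261e-04 positive
1074     S0074 1.6200350 0.7960718 0.9926200  0.82983825 5.168010e-05 positive
1128     S0128 1.5372702 0.7960718 0.9887184  0.75017944 2.591461e-04 positive
1129     S0129 0.7546658 0.7960718 1.0016549 -0.04272337           NA filtered
1146     S0146 0.2875436 0.7960718 0.9849835 -0.49657395 6.519185e-08 negative
```

S0024's colonies *grow* on induction (Wij = 1.34 against an expected 0.80):
an alleviating interaction, S ≈ +0.56. S0146 shrinks far more than
expected: aggravating, S ≈ −0.50. Overlaps between queries come from
`overlap_counts(call_sets(fit))`, and `fd_profile(fit, "Q02")` feeds
`correlate_fd_profiles()` against a reference FD matrix.

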