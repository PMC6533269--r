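# summedstates

Tools for testing the **summed-state hypothesis** of person perception:
that the brain represents a specific person as the sum of the mental
states that person habitually experiences. The package implements, in R,
the two analyses this hypothesis calls for:

1. **Direct test — pattern reconstruction.** Given group-average
   multivoxel patterns for mental states, `s_1 … s_K`, and dual-normalized
   ratings `W` of how often each of `T` target people experiences each
   state, each target's pattern is predicted as the weighted sum
   `p̂_t = Σ_k W[t,k] · s_k`. Reconstructions are scored within each
   participant by the matched/unmatched contrast: the correlation of `p̂_t`
   with the actual pattern for target `t`, minus the mean correlation with
   the other `T−1` targets. Participant means enter a one-sample t-test
   with a one-sample Cohen's d.

2. **Comparative test — summed states vs traits.** Interpersonal
   similarity, measured five ways (neural patterns, pairwise similarity
   judgments, biographical bag-of-words text, binary choices, reaction
   times), is regressed on the summed-state prediction (correlations
   between state-frequency profiles) and the trait prediction (negated
   Euclidean distances in a 3-component PCA trait space). The comparison
   reports zero-order and semi-partial coefficients, Steiger dependent-
   correlation difference tests, OLS BIC, Fisher-transformed group-level
   RSA, split-half reliability with disattenuation (share of reliable
   variance explained), and logistic / log-RT models of the triadic choice
   task with participant-cluster bootstrap contrasts.

Because the original imaging, rating, text, and behavioral datasets are
external, the package ships a first-class **synthetic-data generator**
(`generator_config()`, `generate_dataset()`) whose defaults mirror the
emulated study design (60 targets, 15 states, 29/28 imaging participants,
644 raters, 103 behavioral participants) and whose ground truth is
retained, so every pipeline stage is validated against known answers.

## Worked example

```r
library(summedstates)
report <- run_pipeline(generator_config(seed = 1))
print(report)
```

```
== summed-state pipeline report ==
<reconstruction_result> 29 participants, 60 targets
  mean matched r 0.2867, mean unmatched r 0.1699
  mean r difference 0.1168 (t = 244.361, p = 3.69e-48, d = 45.377)
neural reliability 0.803; states explain 39.6% of reliable neural variance
unfitted choice accuracy: states 0.672, traits 0.532

comparison table:
   measure  model coefficient         p semi_partial semi_partial_p
1   neural states    0.563811 4.55e-149      0.53775      3.81e-133
2   neural traits    0.192340  3.28e-16      0.09102       1.26e-04
3     text states    0.546803 1.44e-138      0.51658      2.88e-121
4     text traits    0.213191  1.22e-19      0.11538       1.14e-06
5  ratings states    0.651884 1.10e-214      0.63173      1.14e-197
6  ratings traits    0.168569  9.47e-13      0.05050       3.37e-02
7  choices states    2.646611 2.17e-157      2.63264      7.91e-152
8  choices traits    1.200225  1.14e-10      1.02765       3.81e-01
9       rt states   -0.028973  3.78e-02     -0.03003       3.47e-02
10      rt traits   -0.000383  9.78e-01      0.00545       7.01e-01
          difference    bic
1         p=3.75e-44 -14905
...
```

Reading the output: the planted summed-state structure is recovered — the
mean matched-minus-unmatched correlation difference is positive and highly
reliable across the 29 simulated participants; the states account beats
the traits account on every measure (larger coefficients, larger unique
semi-partial contributions, lower BIC, bootstrap choice-coefficient
difference interval excluding zero); and without any fitting, simulated
participants choose the option favored by the summed-state model on 67% of
triadic trials versus 50% chance. `write_dataset()` +
`run_pipeline_files()` run the identical analysis through CSV files.

Individual stages are exported for use on your own data:
`zscore_pattern()`, `average_across_participants()`,
`select_reliable_voxels()`, `normalize_weights()`,
`reconstruct_targets()`, `score_reconstruction()`, the five
`*_similarity()` constructors, `trait_pca()`, `item_correlation()`,
`semi_partial()`, `group_level_rsa()`, `paired_correlation_difference()`,
`similarity_reliability()`, `disattenuate()`, `model_bic()`,
`filter_trials()`, `choice_model()`, `rt_model()`,
`coefficient_difference_ci()`, and `unfitted_choice_accuracy()`. The
methods vignette (`vignettes/summed-states.Rmd`) documents the model,
the generator's assumptions, and the numerical choices.

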