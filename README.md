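# mirdiag

Descriptor generation and Bayesian classification for screening mature
microRNAs (miRNAs) as disease-associated biomarkers.

Circulating miRNAs are attractive non-invasive diagnostic markers: a
~22-nucleotide miRNA can be characterized entirely from its sequence and its
predicted regulatory context, without any expression assay. `mirdiag`
implements that idea as a reusable pipeline for binary screening of miRNAs
(disease-associated *positive* class vs background *negative* class):

1. **Descriptors.** Each mature miRNA is turned into a feature vector:
   - *sequence block* (12 numeric attributes): base counts `n_A..n_U`, base
     frequencies `f_A..f_U`, length, GC fraction, single-strand molecular
     weight `MW = Σ m(b) + 18.0` Da, and Watson–Crick hydrogen-bond capacity
     `3(n_G + n_C) + 2(n_A + n_U)`;
   - optional 16 dinucleotide frequencies and configurable motif-presence
     flags (substring match);
   - *annotation blocks*: binary `gene_<SYMBOL>` flags for predicted target
     genes at or above a confidence score threshold (default 80/100), and
     binary `path_<name>` flags set when any passing target falls in a
     pathway gene set.
2. **Attribute ranking** by information gain,
   `IG(A) = H(class) − H(class | A)` in bits, with numeric attributes
   discretized by the Fayyad–Irani MDL criterion.
3. **Classification.** The headline model is a discrete Bayesian-network
   classifier with the naive structure (class as sole parent): smoothed
   conditional probability tables
   `P(state | class) = (count + α) / (n_class + α·n_states)` with α = 0.5,
   log-space posteriors. Comparison learners behind the same contract:
   Gaussian naive Bayes, a Hoeffding incremental tree with naive-Bayes
   leaves, random forest, and a single random tree.
4. **Evaluation.** Stratified k-fold cross-validation with pooled
   out-of-fold scores, class-weighted accuracy/precision/recall/F-measure,
   threshold-swept ROC (trapezoidal AUC = normalized Mann–Whitney U) and
   step-integrated precision–recall curves, learning-curve experiments, and
   independent-holdout evaluation.

A seeded synthetic-data generator emulates the whole study design (miRBase-
style FASTA, miRDB-style target table, pathway gene sets, class labels) with
controllable class signal, so every stage is testable offline.

## Worked example

```r
library(mirdiag)

data     <- synth_generate(synth_config(n_pos = 40, n_neg = 40, seed = 20))
features <- synth_feature_table(data)
features
#> <feature_table> 80 instances x 74 attributes (28 numeric, 46 binary); labels: 40 negative / 40 positive

info_gain(features)
#> <attribute_ranking> 74 attributes, class entropy 1.0000 bits
#>    attribute      gain
#>  gc_fraction 0.9152186
#>          f_C 0.8037828
#>          n_C 0.7217096
#>          f_A 0.6787881
#>         f_CG 0.6786522

cross_validate(features, "bayesnet", k = 5, seed = 20)
#> <evaluation_report> bayesnet (5-fold CV, seed 20)
#>   accuracy 1.000  precision 1.000  recall 1.000  F 1.000  AUC 1.000  AUPRC 1.000
#>           predicted
#> truth      negative positive
#>   negative       40        0
#>   positive        0       40
```

The class entropy of the balanced 40/40 design is 1 bit; `gc_fraction`
recovers 0.92 of it because the generator's composition channel is its
strongest signal, and the Bayes net separates the two classes perfectly at
this effect size. On real data the interesting regime is weaker signals —
see the methods vignette (`vignettes/mirdiag-methods.Rmd`) for what the
generator does and does not emulate.

With real files the same pipeline runs from the command line via the
installed script (`system.file("cli", "mirdiag", package = "mirdiag")`):

```sh
mirdiag synth     --seed 1 --out run/
mirdiag featurize --config config.yaml --out run/
mirdiag rank      --config config.yaml --out run/
mirdiag eval      --config config.yaml --out run/
```

A commented default configuration ships in
`inst/extdata/default_config.yaml`.

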