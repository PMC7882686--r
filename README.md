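# rtcp

Protein sequence classification for ATP-binding cassette (ABC) transporter
prediction, built on a composite sequence descriptor: **reduced-alphabet
tripeptide composition (RTC)** spliced with a **sigmoid-averaged PSSM
summary**, compressed by PCA and classified with a small 1-D convolutional
network.

ABC transporters couple ATP hydrolysis to transmembrane transport of
nutrients, antibiotics and metabolites; recognising them from sequence alone
matters for annotation of newly sequenced proteomes. `rtcp` is aimed at
bioinformaticians who have protein FASTA files and PSI-BLAST profiles and
want a reproducible, cross-validated transporter-vs-other classifier — plus
a synthetic data generator so the entire pipeline can be exercised and
tested without downloading any external database.

## The method

1. **Reduced alphabets.** The 20 amino acids are partitioned into K classes
   by pairing two physicochemical properties (hydrophobicity HP, surface
   tension ST, solvent solubility SS, charged polarity CP). The six
   canonical pairings HP_ST, HP_SS, HP_CP, ST_SS, ST_CP and SS_CP have
   7, 5, 5, 7, 8 and 6 classes.
2. **RTC.** A protein's sequence is rewritten in class symbols and the
   frequencies of its overlapping tripeptides form a K³-dimensional
   probability vector — 343 dimensions for ST_SS instead of the 8000 of the
   raw tripeptide space.
3. **PSSM feature.** Every entry a<sub>ij</sub> of the L×20 PSI-BLAST
   log-odds matrix is squashed by A<sub>ij</sub> = 1/(1+e^(−a<sub>ij</sub>))
   and averaged over positions, giving a 20-vector of evolutionary
   conservation per target residue.
4. **RTCP.** The concatenation RTC ∥ PSSM-feature (e.g. 8³+20 = 532
   dimensions for ST_CP) is reduced to 80 principal components and fed to
   the classifier.
5. **Classifier.** A 1-D CNN — five stride-2 convolutions of 32 filters
   with batch normalization, two max-pools, two fully connected layers and
   a sigmoid output — trained with Adam on binary cross-entropy, learning
   rate 10⁻³ decayed ×0.1 every 100 epochs. SVM (RBF, C = 10⁵,
   γ = 1/p), naive Bayes, random forest and a feed-forward net are
   available as baselines.
6. **Evaluation.** Stratified k-fold cross-validation reporting accuracy,
   specificity, sensitivity, precision, F-score, Matthews correlation
   coefficient and ROC/AUC, plus a repeated-training analysis that flags
   proteins misclassified in a majority of independently seeded runs.

The convolutional network is implemented in-package (forward and backward
passes in vectorised base R), so no deep-learning framework is required.

## Worked example

Everything below runs in a few seconds with no external data: sequences and
PSSMs are simulated with a weak planted class difference.

```r
library(rtcp)

d     <- generate_dataset(synthetic_spec(n_per_class = 50, signal_strength = 0.08,
                                         pssm_shift = 0.2, seed = 42))
feats <- extract_features(d$sequences, d$spec$alphabet, d$pssms)
dim(feats)
#> [1] 100 366   # id, seq, label + 343 tripeptide + 20 pssm columns

cv <- cross_validate(feats, classifier = "svm", k = 5, d_out = 40, seed = 42)
cv
#> <5-fold CV of svm (pca fold, d=40, seed 42)>
#>   acc 0.8800  spec 0.9000  sens 0.8600  F 0.8788  mcc 0.7632  auc 0.9560

generics::tidy(cv)
#> # A tibble: 5 × 9
#>    fold   acc  spec  sens   pre f_score   mcc  beta   auc
#>   <int> <dbl> <dbl> <dbl> <dbl>   <dbl> <dbl> <dbl> <dbl>
#> 1     1  0.85   0.9   0.8 0.889   0.842 0.704     1  0.96
#> 2     2  0.85   0.8   0.9 0.818   0.857 0.704     1  0.95
#> 3     3  0.95   1     0.9 1       0.947 0.905     1  0.98
#> 4     4  0.95   1     0.9 1       0.947 0.905     1  1
#> 5     5  0.8    0.8   0.8 0.8     0.8   0.6       1  0.89
```

The mean row (accuracy 0.88, MCC 0.76, AUC 0.956) says the pipeline
recovers most of the weak planted signal; per-fold rows show its spread
across held-out splits. `autoplot(cv)` draws the per-fold ROC curves, and
`cross_validate(..., classifier = "dcnn", train = train_config(epochs = 60))`
swaps in the convolutional network.

With real data, replace the simulated inputs:

```r
seqs  <- read_fasta("proteins.fasta")
pssms <- read_pssm_dir("pssms/")          # psiblast -out_ascii_pssm files
labs  <- read_labels("labels.tsv")        # id <tab> 0/1
feats <- extract_features(dplyr::inner_join(seqs, labs, by = "id"),
                          canonical_alphabets()$ST_SS, pssms)
```

A thin command-line wrapper is installed at `exec/rtcp`
(`rtcp simulate|extract-features|train|evaluate|predict`, plus
`rtcp alphabets` to list the six reduced alphabets).

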