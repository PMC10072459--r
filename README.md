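# cdecg — compressed-domain classification of ECG heartbeats

`cdecg` classifies electrocardiogram (ECG) heartbeats **directly in the
compressed domain**. Ambulatory ECG monitoring produces far more data than a
wearable device can comfortably store or transmit; compressed-sensing
pipelines shrink the data but pay for it with an expensive reconstruction
step before classification. This package implements the alternative: a small
learned 1-D convolutional network compresses each R-peak-centered beat of
length *n* to a vector of length *k* = round(CR·*n*) (CR = *k*/*n* is the
compression ratio), and a lightweight parallel-branch 1-D convolutional
network classifies that vector into the AAMI arrhythmia super-classes
(N — normal and bundle-branch/escape/paced beats, S — supraventricular
ectopy, V — ventricular ectopy, F — fusion) with no reconstruction anywhere.
Compressor and classifier are trained jointly on the classification
cross-entropy alone.

The package is aimed at researchers studying compression/classification
trade-offs in biosignal pipelines: it ships the full pipeline (WFDB and
beat-table I/O, segmentation, AAMI mapping, balancing, splitting), the two
network planners with exact per-layer parameter accounting, a pure-R
training engine (Adam, batch 64, 50 epochs, reduce-on-plateau learning
rate), SVD/PCA baseline compressors, multi-class metrics (confusion matrix,
macro precision/sensitivity/F1, squared-macro-F1 score, ROC/PR curves), a
benchmark harness over CR × method × classifier variant, and a synthetic
beat generator so everything runs at desk scale with no data download.

## Worked example

Generate 1000 labelled synthetic beats (250 per class), train the
compressor + classifier jointly at CR = 0.2 for 50 epochs, and evaluate on
the held-out 20%:

```r
library(cdecg)

ds <- generate_dataset(synthetic_beat_spec(seed = 0), n_per_class = 250)
sp <- split_train_test(ds, split_config(0.8, seed = 0))

cmp_plan <- build_compressor_plan(compression_config(n = 260, cr = 0.2))
cls_plan <- build_classifier_plan(classifier_config(k = cmp_plan$output_dim))

model <- train_model(cmp_plan, cls_plan, sp$train,
                     train_config(epochs = 50, seed = 0))
evaluate_model(model, sp$test)
```

```
<ecg_eval_report> 200 beats
    predicted
true  N  S  V  F
   N 56  0  0  0
   S  0 47  0  0
   V  0  0 47  0
   F  0  0  0 50
 class precision sensitivity f1
     N         1           1  1
     S         1           1  1
     V         1           1  1
     F         1           1  1
accuracy 1.0000  macro precision 1.0000  sensitivity 1.0000  F1 1.0000  score 1.0000
```

All 200 held-out beats are classified correctly from their 52-sample
compressed representations (the four synthetic classes are strongly
separable by design; the run takes about 1.5 minutes on one CPU core).
`compress_forward(model, sp$test)` returns the 200×52 compressed matrix
itself, and `model$history` holds the per-epoch loss/accuracy/learning-rate
trajectory.

The network plans reproduce the reference architecture's layer tables
exactly — e.g. the compressor's dense bottleneck at CR = 0.2 holds
(13·16 + 1) × 52 = 10 868 parameters:

```r
cmd_inspect_plan(cr = 0.2, n = 260)
```

## Command line

A thin CLI over the same functions ships in `inst/cli/cdecg.R`:

```sh
Rscript inst/cli/cdecg.R synth --out beats.csv --n-per-class 250 --seed 0
Rscript inst/cli/cdecg.R inspect-plan --cr 0.2
Rscript inst/cli/cdecg.R train --data beats.csv --out-dir run1 --cr 0.2
Rscript inst/cli/cdecg.R segment --wfdb-dir mitdb/ --out beats.csv \
        --targets N=1000,S=1000,V=1000,F=802
Rscript inst/cli/cdecg.R benchmark --out report.csv --crs 0.5,0.2,0.05 \
        --methods cnn,pca
```

`segment` reads WFDB records (`.hea`/`.dat` formats 16 and 212 with `.atr`
beat annotations), cuts 260-sample R-centered beats, maps annotation
symbols to AAMI classes and balances them to the requested per-class
counts — with the targets above, the classic 3802-beat working set.

## Scope notes

The classifier's ablation variants (`no_parallel`, `plus_lstm`,
`plus_bilstm`) are selectable wherever a classifier is built. Laplacian
eigenmap and stacked-autoencoder compression baselines, and external
comparison classifier architectures, are out of scope; the SVD/PCA
baselines and the learned compressor are included. See the vignette
(`vignettes/compressed-domain-ecg.Rmd`) for the model, the design
decisions and the generator's limitations.
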