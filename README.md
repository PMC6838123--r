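# hicsubcomp

Inference of the five primary Hi-C subcompartments (A1, A2, B1, B2, B3) of
100 kb genomic bins from **moderate-coverage** Hi-C data, for genome-biology
groups who have a typical few-hundred-million-read-pair Hi-C experiment
rather than the multi-billion-read dataset that direct subcompartment
clustering requires.

## The method

Subcompartments are visible as block patterns in the inter-chromosomal
contact matrix (odd-numbered autosomes × even-numbered autosomes, 100 kb
bins), but at ordinary sequencing depth the matrix is too sparse to cluster.
The package therefore:

1. converts counts to contact probabilities, `P_ij = exp(-1 / C_ij)`
   (`P = 0` at `C = 0`), bounding the signal in `[0, 1)` and taming
   outliers;
2. trains a **denoising autoencoder**
   (`N_loci`–1024–512–256–128–256–512–1024–`N_loci`, ReLU hidden layers,
   linear 128-d latent, sigmoid output, 25% dropout, binary cross-entropy,
   RMSProp, 25 epochs × batch 32 × lr 0.001) that maps rows of a
   downsampled probability matrix to the corresponding dense rows;
3. classifies each bin's 128-d latent embedding with a **balanced
   multilayer perceptron** (sigmoid-squashed input, 64- and 16-unit ReLU
   hidden layers, softmax over the five classes, categorical
   cross-entropy), where the training set is balanced per class by segment
   interpolation `r = x + (y - x) u`, `u ~ U(0,1)`;
4. mirrors the whole pipeline on the transposed matrix so odd- and
   even-parity bins each get their own model pair.

It also computes cross-cell-type **conservation states**: per-bin annotation
entropy `S = Σ -p_c log p_c` over N cell types, information content
`|p_c log(p_c / 0.2)|`, and the 13-state scheme for 9 cell types (12
majority states ordered by entropy, plus a non-conserved NC state), together
with evaluation utilities (confusion matrices, one-vs-rest AUPR, stratified
10-fold CV, enrichment fold change, 400 kb boundary signal profiles,
coverage titrations) and a planted-truth Poisson block simulator.

## Worked example

```r
library(hicsubcomp)

# planted-truth fixture: 400 x 400 bins, 2e6 expected read pairs
sim   <- simulate_hic(planted_model(seed = 2))
model <- fit_subcompartments(sim$contacts, sim$truth, keep_rate = 0.1,
                             seed = 2)
print(model)
#> subcomp_model
#>   grids: 400 odd-parity x 400 even-parity bins
#>   trained at keep_rate 0.1, seed 2
#>   autoencoder: 400-1024-512-256-128-256-512-1024-400
#>   classifier:  128-64-16-5
#>   training chromosomes: odd chr1,chr3,chr5,chr7 | even chr2,chr4,chr6,chr8,chr10

sparse <- downsample_contacts(sim$contacts, 0.1, seed = 3)
ann    <- predict(model, sparse)               # per-bin labels + 5 probabilities
confusion_subcomp(ann, sim$truth)
#> subcomp_confusion over 800 bins; overall accuracy 0.968
#>          predicted
#> reference  A1  A2 B1  B2  B3
#>        A1 135   9  0   0   0
#>        A2  15 114  0   0   0
#>        B1   0   0 96   2   0
#>        B2   0   0  0 134   0
#>        B3   0   0  0   0 295
#> per-class accuracy: A1=0.938 A2=0.884 B1=0.980 B2=1.000 B3=1.000

imputed <- impute_contacts(model, sparse)      # dense probability matrix
```

The confusion matrix compares every covered bin's predicted subcompartment
with the planted truth; `impute_contacts()` returns the reconstructed dense
contact-probability matrix, whose rows correlate substantially better with
the dense truth than the sparse input rows do (row-averaged Spearman 0.79
vs 0.65 at 10% coverage in this example).

A command-line front end covering
`simulate / train / annotate / impute / conserve / evaluate /
coverage-sweep` is installed at
`system.file("scripts", "hicsubcomp.R", package = "hicsubcomp")`.

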