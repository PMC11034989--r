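# gpgcn — gapped pattern graph convolutional networks for DNA sequences

Alignment-free characterization of genome sequences — classifying phage vs
mobile-element sequences, predicting integration sites, lifestyles or hosts,
and similar labeling tasks — struggles with two things: sequences of wildly
different lengths, and genetic variation (SNPs, indels) that breaks exact
k-mer matching. `gpgcn` implements a graph answer to both. Every sequence,
whatever its length, becomes a **gapped pattern graph** (GPG): one vertex per
possible k-mer carrying its frequency, and one directed edge per ordered
k-mer pair \((s, t)\) carrying a gap-resolved frequency vector — entry
\(g\) counts the spaced word \(s\,x\,t\) with spacer length \(|x| = g \le d\).
Spaced words tolerate the variation that defeats contiguous 2k-mers, and the
fixed graph shape removes any arbitrary ordering of k-mers in the encoding.

A two-step graph convolution embeds each GPG. Edge features are reified as
*pair vertices* bipartitely wired to their two k-mer vertices; each level
updates k-mer vertices from the mean of their pair neighbors, then pair
vertices from the mean of their freshly updated endpoints:

    h_u' = sigma(B1 h_u + W1 * mean{h_v : v in N(u)})
    h_v' = sigma(B2 h_v + W2 * mean{h_u' : u in N(v)})

A small 1-D convolutional head over the concatenated pair features produces
the embedding; a softmax MLP (optionally fused with per-sequence auxiliary
features such as protein presence/absence vectors) performs the task.
Training uses mini-batch Adam (lr 1e-4) on the cross-entropy with
inverse-class-frequency batch sampling, early stopping on validation loss,
and grid search over hyperparameters. Occlusion-based contribution scores
(zero a pattern's features, measure the mean absolute probability shift,
compare to a matched random-removal baseline) attribute predictions to
individual gapped patterns or IUPAC motifs. A seeded simulator generates
labeled sequence sets with planted gapped-pattern signatures and SNP/indel
noise so the whole pipeline is testable offline. Everything — forward pass,
hand-derived gradients, Adam — is plain R (Matrix for the sparse
aggregation operators, Biostrings for FASTA).

## Worked example

The pattern graph of `ATGATGC` at k = 3 (gap length 0):

```r
library(gpgcn)
g <- build_gpg("ATGATGC", k = 3, d = 0, normalize = FALSE)
g
#> gapped pattern graph: k = 3 , d = 0 , bins = 1
#>   source length 7 ; absolute counts
#>   nonzero vertices: 4 / 64
#>   nonzero pair entries: 2 / 4096
as.data.frame(g)
#>     type kmer_s kmer_t gap_bin value
#> 1 vertex    ATG   <NA>    <NA>     2
#> 2 vertex    GAT   <NA>    <NA>     1
#> 3 vertex    TGA   <NA>    <NA>     1
#> 4 vertex    TGC   <NA>    <NA>     1
#> 5   edge    ATG    ATG       0     1
#> 6   edge    TGA    TGC       0     1
```

Four of the 64 vertices are occupied (`ATG` twice, the others once) and the
two edges are the 6-mers the sequence contains: `ATG`→`ATG` and `TGA`→`TGC`.
With normalized counts the `ATG` vertex becomes 2/5 = 0.4 (five 3-mer
windows).

End to end on simulated data — class 1 carries a planted gap-2 pattern
`ACG??TAC`, class 0 the same k-mer content unpaired:

```r
pat <- gapped_pattern("ACG", 2, "TAC")
sim <- sim_config(classes = 2, n_per_class = 100, length_range = c(1000, 1000),
                  signatures = list(
                    list(list(pattern = "ACG", copies = 10),
                         list(pattern = "TAC", copies = 10)),
                    list(list(pattern = pat, copies = 10))),
                  snp_rate = 0.01, seed = 11)
ds  <- split_dataset(generate_dataset(sim), c(0.8, 0.1, 0.1), seed = 11)
cfg <- gpgcn_config(k = 3, d = 2, layers = 2, hidden = 8,
                    conv_channels = c(16, 8), embed_dim = 32,
                    mlp_hidden = 32, n_classes = 2, seed = 11)
fit <- gpgcn(ds, cfg, train_config(epochs = 60, patience = 15, seed = 11))
summary(fit)
#> Fitted gapped-pattern GCN (gpgcn)
#>   classes: class_0, class_1
#>   k = 3 , d = 2 , layers = 2
#>   trained 60 epochs; best epoch 60 (val loss 0.0710)
#>   train accuracy: 1.000  (n = 160)
#>   val   accuracy: 1.000  (n = 20)
#>   test  accuracy: 1.000  (n = 20)
```

The trained model attributes its decisions to the planted pattern: zeroing
the single feature `(ACG, gap 2, TAC)` shifts predicted probabilities by
0.32 on average over the test graphs, while removing one random pattern
shifts them by about 1e-4:

```r
graphs <- lapply(ds$sequences[ds$split == "test"], build_gpg)
contribution_score(fit, graphs, pat)            # 0.322
baseline_score(fit, graphs, 1, R = 10, seed = 99)  # 9.97e-05
```

`score_motifs()` does the same for IUPAC consensus motifs and flags the ones
whose contribution beats the matched baseline. A command-line wrapper
(`inst/cli/gpgcn.R`, or `gpg_cli()` in-process) exposes `simulate`,
`build-graph`, `train`, `grid-search`, `predict`, `embed` and `interpret`
subcommands, each writing a JSON run manifest.

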