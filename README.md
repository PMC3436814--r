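# trnarch

Architecture analysis of tissue regulatory networks (TRNs): hub statistics,
colored three-vertex motifs, and bow-tie decomposition of motif instances.

## What problem this addresses

The same genome produces very different cell types because different
tissues run different regulatory networks. Given a genome-wide *reference*
network of predicted regulatory interactions among transcription factors
(TFs), microRNAs (miRNAs) and non-TF target genes, and binary expression
calls per tissue, each tissue's regulatory network is the subgraph induced
by its expressed genes. `trnarch` is for computational biologists who want
to compare the design of such networks across tissues at three scales:

- **Hubs.** A gene is an in-/out-hub of a TRN when its degree beats the
  same vertex in 2000 Erdős–Rényi-style random networks (empirical
  *P* < 0.01). Cross-tissue hub behaviour is summarized by the
  specificity index **SI = (N − n)/(N − 1)** (1 = hub in one tissue,
  0 = hub in all N), by active ratios (the realized fraction of a gene's
  reference connections, separating *strong* from *weak* hubs), and by
  σ_RF curves — the standardized deviation of the hub frequency at each
  SI value from degree-redistribution nulls.
- **Motifs.** Connected role-colored triads are counted exactly, compared
  against 1000 degree-preserving edge-switch randomizations, and called
  motifs when occurrence > 5, *P* < 0.05 and *Z* > 2.2; motifs significant
  in all tissues are *common* (CM), in some but not all *tissue-specific*
  (TS). Structural classes: FFL, FBL, CMPLX, non-loop.
- **Bow-tie.** Genes of CM and TS motif instances partition into core
  (both), non-core CM (output layer) and non-core TS (input layer).
  Composition and inter-layer average degrees are tested against 5000
  label permutations; layer size ratios classify each tissue as
  input-dominated, symmetric or output-dominated.

A seeded synthetic generator (heavy-tailed regulator out-degrees,
housekeeping + tissue-specific expression, plantable hubs/motifs/bow-ties)
makes the full pipeline testable without any external data.

## Worked example

Simulate a reference network with 12 TF–TF–nonTF feed-forward loops
planted into tissues 1 and 2, then run the hub and motif stages:

```r
library(trnarch)

ffl <- rbind(c(1, 2), c(1, 3), c(2, 3))
plants <- plant_spec(motifs = list(plant_motif(c("TF", "TF", "nonTF"), ffl,
                                               n_instances = 12, tissues = 1:2)))
params <- generator_params(n_tf = 60, n_mirna = 30, n_nontf = 120,
                           n_tissues = 4, seed = 7)
reference <- generate_reference(params, plants)
profile   <- generate_expression(params, reference)
trns      <- build_trns(reference, profile)
trns[[1]]
#> regulatory_network 'tissue1': 184 vertices (54 TF, 25 miRNA, 105 nonTF), 333 arcs

calls <- call_hubs_tissues(trns, n_random = 500, seed = 1)
profiles <- hub_profiles(calls, trns)
table(profiles$strength)
#>
#> non-hub  strong    weak
#>     399      11      10

stats <- lapply(trns, motif_significance, n_random = 200, seed = 2)
ms <- stats[[1]]
head(ms[order(-ms$z_score),
        c("signature", "structure", "occurrence", "z_score", "p_value", "significant")], 3)
#>                signature structure occurrence  z_score     p_value significant
#> 18    TF-TF-nonTF|011100       FFL         25 5.798446 0.004975124        TRUE
#> 26 TF-miRNA-miRNA|110001       FFL          3 4.743578 0.004975124       FALSE
#> 20 TF-miRNA-miRNA|000110  non-loop         17 3.079153 0.004975124        TRUE

catalog <- classify_cm_ts(stats)
catalog[catalog$signature == "TF-TF-nonTF|011100",
        c("signature", "n_significant", "tissues", "label")]
#>                             signature n_significant         tissues label
#> TF-TF-nonTF|011100 TF-TF-nonTF|011100             2 tissue1,tissue2    TS

specificity_index(8, 1)   # hub in 1 of 8 tissues -> maximally specific
#> [1] 1
specificity_index(8, 8)   # hub everywhere -> not specific at all
#> [1] 0
```

The hub table says 21 genes reach hub status in at least one of the four
tissues, 11 of them in every tissue where they are expressed. The planted
TF–TF–nonTF feed-forward loop (canonical signature `TF-TF-nonTF|011100`)
is recovered as over-represented in tissue 1 — 25 occurrences (12 planted
plus background) against the switch-randomized ensemble, Z ≈ 5.8,
empirical *P* ≈ 0.005 — and, being significant in exactly the two planted
tissues of four, it is catalogued as a tissue-specific (TS) motif. Note
the second row: a triad with only 3 occurrences is never called
significant regardless of its Z-score, per the occurrence > 5 criterion.

The whole pipeline — simulate (or load TSV inputs), build TRNs, hubs,
σ_RF, motifs, CM/TS catalog, bow-ties, summary report — runs from one
seeded configuration:

```r
cfg <- pipeline_config(out_dir = "out", seed = 42,
                       simulate = list(n_tf = 60, n_mirna = 30,
                                       n_nontf = 120, n_tissues = 8))
res <- run_pipeline(cfg)
```

or from a shell: `Rscript inst/scripts/trnarch-pipeline.R --config config.yaml`.

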