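# postgwas

An integrated post-GWAS analysis pipeline for complex disease, for
statistical geneticists and computational biologists who need to walk from
association summary signals to prioritized risk genes and risk variants.

A GWAS association signal names neither the gene it acts through nor the
causal variant behind it: most signals fall in non-coding sequence and tag
many variants in linkage disequilibrium. `postgwas` implements the full
downstream chain:

* **Risk regions** — each association SNP seeds an LD block (panel variants
  with dosage r² > 0.5 within 400 kb of the seed); overlapping or close
  (< 250 kb) blocks merge into risk regions.
* **Candidate genes** — *proximal* genes overlap a region after a 20 kb
  extension; *distal* genes are targeted by an enhancer or eQTL
  (FDR < 0.05) lying inside the region.
* **Gene scoring** — permutation-based network and annotation statistics
  against stringent/lenient training gene sets, combined as

  S_g = α·S_f⁽ⁿ⁾ + (1−α)·S_f⁽ᵃ⁾,  0 < α < 1,

  where S_f⁽ⁿ⁾ is the −log₁₀ empirical p-value of the gene's summed edge
  weight to training genes and S_f⁽ᵃ⁾ the −log₁₀ empirical p-value of its
  mean top-5 Jaccard term similarity to training genes. Risk genes exceed a
  threshold calibrated to cross-validated precision ≥ 0.8.
* **Risk variants** — variants in risk regions hitting the coding sequence,
  promoter window, or linked enhancers of risk genes, called at strict
  tier thresholds: pathogenicity > 0.7 (coding), |log fold change| >
  ln 1.2 (promoter), selection score > 0.9 (enhancer).
* **Characterization** — allele-level PWM motif gain/loss (± 25 bp windows,
  match score > 7.5), eQTL cross-referencing, case/control co-expression
  connectivity and hubs (Pearson r > 0.7, top-20), Ward clustering of
  tissue expression, bootstrap cell-type enrichment, and Kaplan–Meier
  median-expression survival screens with an age-trend contrast.

A first-class synthetic-data module generates every input with planted
ground truth (risk genes, tiered risk variants, motif-disrupting alleles,
prognostic genes, cell-type markers), so the whole pipeline is testable
without any external download.

## Worked example

```r
library(postgwas)

study <- simulate_study(seed = 1)   # all inputs, with planted truth
study
#> Synthetic post-GWAS study (seed 1)
#>   panel:     100 samples x 900 variants
#>   signals:   100
#>   genes:     272 (30 planted risk genes)
#>   variants:  30 planted risk variants

run <- run_pipeline(study, pipeline_config(seed = 1))
run
#> Post-GWAS pipeline run
#>   risk regions:    62 (1.54 Mb)
#>   candidates:      139 (120 proximal, 17 distal, 2 both)
#>   risk genes:      35 (thresholds: stringent 0.458, lenient 0.614)
#>   risk variants:   30 unique (30 tier records)
#>   supported:       24/30 (80%) by motif delta or eQTL
#>   prognostic hits: 1 gene(s)
```

The 100 association signals collapse into 62 LD-defined risk regions
spanning 1.54 Mb. 139 genes connect to those regions — 120 by overlap, 17
through a regulatory link only, and 2 by both routes. At the
precision-calibrated thresholds, 35 candidates are called risk genes; all
30 planted risk genes are among them. The 30 called risk variants are
exactly the planted ones (zero false discoveries at this seed), and 80% of
them carry independent functional support — a motif gain/loss or an eQTL
record for a linked gene. One risk gene splits the simulated patients into
survival groups at p < 0.05 with a significant age-trend contrast.

Every stage is also exposed directly (`build_risk_regions()`,
`map_proximal()`/`map_distal()`, `score_genes()`, `estimate_threshold()`,
`predict_risk_variants()`, `call_gain_loss()`, `build_network()`,
`celltype_enrichment()`, `km_estimate()`, `logrank_test()`, ...), and
`inst/scripts/postgwas.R` offers a thin command-line wrapper
(`Rscript postgwas.R all --seed 1 --out run_dir`) that writes the study
inputs in their standard formats (VCF, GFF3, BED, GMT, FASTA, JASPAR-style
PFM) plus the pipeline outputs and a manifest.

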