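---
title: "Methods: post-GWAS prioritization of risk genes and risk variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-GWAS prioritization of risk genes and risk variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Genome-wide association studies report thousands of disease-associated
variants, but an association signal names neither the gene it acts through
nor the causal variant behind it: most signals fall in non-coding sequence
and tag many variants in linkage disequilibrium (LD). `postgwas` implements
an integrated post-GWAS pipeline that walks from association signals to
prioritized genes and variants in five stages:

1. **Risk regions.** Each association SNP seeds an LD block: every reference
   panel variant with dosage correlation $r^2 > 0.5$ with the seed and less
   than 400 kb away joins the block. Overlapping or nearby blocks (gap
   < 250 kb) merge transitively into risk regions.
2. **Candidate genes.** *Proximal* genes overlap a region after a 20 kb
   extension of the gene body; *distal* genes lie farther away but are the
   target of a regulatory element inside the region — an enhancer interval
   or an eQTL variant at FDR < 0.05. A gene can be proximal to one region
   and distal to another ("both").
3. **Gene scoring.** Each candidate receives a network score $S^{(n)}$ and
   an annotation score $S^{(a)}$, combined as
   $S_g = \alpha S^{(n)} + (1-\alpha) S^{(a)}$ with $0 < \alpha < 1$
   (default $0.5$). Genes whose combined score strictly exceeds a
   precision-calibrated threshold are called risk genes.
4. **Risk variants.** Every panel variant inside a risk region is assigned
   the functional contexts it hits in risk genes — coding sequence, the
   strand-aware promoter window (TSS $-2000$/$+500$ bp), or a linked
   enhancer — and is called when its tier's annotation score strictly
   exceeds 0.7 (coding pathogenicity), $\ln 1.2$ (absolute promoter
   expression effect), or 0.9 (enhancer selection score).
5. **Characterization.** Risk variants are cross-referenced against eQTL
   tables (FDR < 0.05, reference- and disease-cohort-style separately) and
   against allele-level transcription-factor motif gains/losses; risk genes
   are profiled by case/control co-expression connectivity and hubs,
   tissue-expression clustering, cell-type enrichment, and a
   survival/age-trend screen.

# Permutation scores and their calibration

The upstream tool this stage emulates combines network and annotation
evidence on an unbounded score scale; its internals are not public. Here
both components are defined as empirical-permutation statistics so that they
share one interpretable scale:

* **Network score.** For gene $g$ with training set $T$,
  $T(g)=\sum_{t \in N(g)\cap T} w(g,t)$ — the summed edge weight from $g$ to
  training genes. Its null distribution comes from $N_\mathrm{perm}$ uniform
  draws of $|T|$ genes from the network nodes; $g$'s own edges stay fixed,
  so its degree is preserved. $S^{(n)} = -\log_{10} p$ with the add-one
  estimator, hence bounded by $\log_{10}(N_\mathrm{perm}+1)$.
* **Annotation score.** $A(g)$ is the mean of the top-5 Jaccard
  similarities between $g$'s term set and those of the training genes,
  against the same kind of null. Self-similarity never counts towards the
  statistic: a training gene is scored by its match with the *other*
  training genes, otherwise its trivial self-match dominates the scale and
  the calibrated threshold lands above what any non-training gene can
  reach.

Genes absent from the network or without terms are unscorable on that
component; by default a gene missing either component is reported unscored
(a `partial` option falls back to the available component).

**Threshold calibration.** The decision threshold is the smallest score
whose cross-validated precision reaches the target (default 0.8): training
genes among the scored universe are split into $K=5$ folds; held-out
training genes are positives, an equal-size uniform draw of non-training
scored genes the negatives. Three implementation choices matter and are
deliberate:

* The cross-validation is *repeated* (20 times by default) with fresh folds
  and negative draws. A single equal-size negative draw gives a precision
  estimate with standard error of several points, which makes the chosen
  threshold jump across seeds; repeated CV pools the draws.
* The negative pool always excludes the *lenient* training superset, even
  when calibrating on the stringent subset: a known disease gene is never a
  valid negative. Without this rule the stringent calibration is
  structurally infeasible whenever more than $1-\text{target}$ of the
  negative pool consists of true disease genes.
* A threshold only qualifies while it still calls at least half of the
  held-out positives (`min_recall = 0.5`). Without this support condition a
  shuffled training set can return a spuriously "precise" threshold that
  calls a single top-scoring gene.

Two thresholds are calibrated — one against the stringent training set, one
against the lenient set — on a single score vector computed with the full
(lenient) training evidence. Calls use strict inequality; a gene called by
either threshold is a risk gene.

# The synthetic study

The generators produce every input with planted ground truth. Their
defaults are the study conditions for all tests and are chosen to mirror
the scale and proportions of a typical large post-GWAS analysis at roughly
one tenth the size:

* **Panel**: 100 samples, 75 LD blocks of 12 variants over 30 kb, blocks
  290 kb apart (beyond the 250 kb merge gap, so regions stay distinct);
  haplotype copying with per-site flip probability $e$ gives expected
  within-block dosage $r^2 = (1-2e)^4$, default target 0.8. Between blocks
  variants are independent. This is deliberately not a coalescent
  simulation: block-wise copying is sufficient to exercise every $r^2$
  threshold and is fully controllable.
* **Signals**: 100 association SNPs, log-uniform p-values in
  $[10^{-12}, 10^{-5}]$, at least one per risk block (60 blocks carry
  signals; 15 are background).
* **Genes**: 30 planted risk genes — 20 proximal (inside risk blocks) and
  10 distal (> 20 kb from every block, enhancer-linked into one), a 2:1
  ratio — among ~137 candidates, i.e. a 22% risk fraction. These
  proportions match the published ratios of proximal/distal risk genes and
  of risk genes among candidates; they matter because the negative draws of
  the threshold calibration come from non-training candidates, and the
  feasible precision is bounded by the fraction of true risk genes hiding
  in that pool.
* **Training sets**: 20 stringent ⊂ 40 lenient genes drawn from background
  genes (disjoint from candidates, so recovery metrics are unambiguous).
  Favored genes (planted + training) oversample training-gene network
  partners and disease-pool terms by an `elevation` factor (default 6)
  while all other genes undersample them by $1/\text{elevation}$ — the
  clustering of disease genes that guilt-by-association methods assume.
  `elevation = 1` collapses to an exact null in which planted genes are
  generated identically to background genes.
* **Variant annotations**: background coding/enhancer scores are
  Beta(2, 8), promoter effects Normal(0, 0.05). A planted variant's tier
  score gains `risk_shift * (base_shift + noise_sd * Z)` with base shifts
  0.65/0.40/0.85, putting it above its tier threshold with probability
  ≥ 0.9; `risk_shift = 0` reproduces the background distribution exactly.
* **Cohorts**: four brain-region cohorts of 90 cases / 64 controls; one
  gene module shares a latent factor among cases only (pairwise $r \approx
  0.9$) and a second among controls only; survival times are exponential
  with log-hazard proportional to the standardized expression of planted
  prognostic genes (default $|\beta| = 0.9$, i.e. hazard ratio ≈ 2.5 per
  SD), with a 20% censoring fraction. Constant baseline hazard keeps
  closed-form sanity checks available.
* **Sequence and motifs**: motif width 7 with consensus probability 0.99 is
  chosen so a full match scores ≈ 13.9 and any single mismatch ≈ 6.0 on the
  log2-odds scale — a single substitution crosses the 7.5 calling threshold
  in exactly one direction. Windows around planted variants are locally
  resampled until no accidental full match of any library motif remains, so
  planted gains/losses are guaranteed recoverable by construction.

What the generator does *not* emulate: realistic allele-frequency spectra,
population structure, coalescent genealogies, overlapping genes, distance
decay of LD within blocks, expression count noise, or batch effects.
Passing tests therefore demonstrate that the pipeline's logic and
thresholds behave as specified and that effects of the planted size are
recovered — not that the method is calibrated on real cohort data.

# Numerical and convention choices

* Coordinates are 0-based half-open everywhere internally (BED-native);
  GFF3 and VCF convert at the I/O boundary. A gap of exactly 20 kb is not
  proximal; every printed operating point (0.5, 400 kb, 250 kb, 0.7,
  $\ln 1.2$, 0.9, 7.5, 0.7, 0.05) is strict.
* LD is the squared Pearson correlation of genotype dosages (composite LD):
  no phasing is required and the estimator is well-defined on any biallelic
  panel. Monomorphic pairs have undefined $r^2$, treated as below
  threshold; a monomorphic seed yields a single-SNP region with a warning.
* Block membership is seed-anchored (star topology) rather than chained;
  chaining happens only through the 250 kb merge. Seeds are processed in
  (chromosome, position, id) order and merging is iterated to a fixpoint,
  so output never depends on input order.
* PWM match scores are log2-odds sums against a uniform 0.25 background
  with pseudocount $10^{-3}$, maximized over offsets and both strands. The
  motif tool this stage replaces scores against a sequence-derived
  background; equivalence of the two scales is not claimed — 7.5 is
  retained as the operating point on the declared scale.
* The promoter window (TSS −2000/+500 bp, strand-aware) is a configurable
  default; the promoter tier compares the *absolute* log fold change, since
  either direction of expression change can mediate risk.
* Co-expression edges use signed $r > 0.7$ (an `absolute` option exists).
  Connectivity contrasts use Welch's two-sided t-test on the per-gene
  induced-subgraph degrees of the same gene universe in the two networks;
  full-network degrees are available via option. Hub ties break
  lexicographically for determinism.
* The survival screen uses the raw log-rank p-value at $\alpha = 0.05$
  jointly with the age-trend criterion, without multiplicity correction by
  default (a BH option exists), matching the screening character of the
  analysis. The "trend test" is implemented as the OLS age × group
  interaction; a Fisher-z correlation contrast would be an alternative.
* Cell-type enrichment draws bootstrap gene sets uniformly (no
  expression-level matching); p-values use the add-one estimator and are BH
  adjusted across cell types.
* All randomness flows from one seed; stage-local seeds are derived
  deterministically from it, so identical configurations reproduce
  identical outputs byte for byte.

# Problem sizes used by the test-suite

The unit tests run on toy fixtures (tens of variants/genes). The recovery
tests run the full default study on 10 seeds; null calibrations use 250
small replicates per statistic. These sizes were chosen as the smallest at
which the binomial noise of the recovery and calibration checks is
comfortably below the margins being asserted.

# Known limitations

* The gene-score scale is bounded by $\log_{10}(N_\mathrm{perm}+1)$;
  thresholds are therefore not comparable with tools that report unbounded
  scores, and the published threshold values of the emulated tool are not
  reproduction targets.
* Whether the emulated scorer folds association p-values into the gene
  score is not documented; this implementation does not.
* Distal-gene exclusivity is per region (a gene proximal to region A can
  still be distal to region B); whether the original analysis excluded
  genes proximal to *any* region is not stated there.
* eQTL support matching is by (variant, gene) pair; tissue is carried as
  metadata but not filtered on by default.
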