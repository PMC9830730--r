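---
title: "Methods: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paeomics)
```

`paeomics` re-implements, as a tested and reusable pipeline, the downstream
analysis of a bulk RNA-seq contrast between pulmonary-artery segments
affected by an induced embolism (PA-E, n = 6) and matched controls
(CTR, n = 5) in a porcine model. The package enters the analysis at the
aligned-feature level: gene counts, junction counts, per-site allele
depths, transcript models and sequences. Read-level processing (QC,
trimming, alignment, transcript assembly) is out of scope; those products
are the input contract. Every stage has a synthetic-data generator with
planted truth, so each statistical claim in the test suite is a recovery
or calibration statement against known ground truth.

## Differential expression

Counts are modelled as negative binomial,
$K_{gj} \sim \mathrm{NB}(\mu_{gj} = s_j q_{gi(j)}, \alpha_g)$, with $s_j$ a
per-library size factor, $q_{gi}$ the group concentration and $\alpha_g$ a
gene dispersion. The implementation is a deliberately simplified core of
the standard NB workflow:

* **Size factors** are median-of-ratios: the median over
  all-samples-positive genes of the count over the gene's geometric mean,
  computed in log space (so the estimator matches the reference
  implementation to numerical precision; the cross-check test asserts
  this against DESeq2 on a simulated matrix).
* **Dispersion** is a per-gene method-of-moments estimate on normalised
  counts, $\hat\alpha_g = (s^2_g - \bar\mu_g)/\bar\mu_g^2$, floored at
  $10^{-8}$, then shrunk 50% toward an ordinary-least-squares trend
  $\alpha_{tr}(\mu) = a_0 + a_1/\mu$. The full Cox–Reid/MAP machinery is
  not reproduced; with 11 libraries, the moment estimator plus trend
  shrinkage is mildly conservative, which the null-calibration tests
  quantify (raw p at 5% rejects ~3.5% of null genes; BH discoveries under
  a complete null are rare).
* **Testing** fits each group's concentration by Newton iteration on the
  log scale (score $\sum_j (y_j-\mu_j)/(1+\alpha\mu_j)$, expected
  information $\sum_j \mu_j/(1+\alpha\mu_j)$; steps clipped to $\pm 5$,
  25 iterations, tolerance $10^{-10}$), and Wald-tests
  $\log_2 \mathrm{FC} = (\log \hat q_{case} - \log \hat q_{ctrl})/\log 2$
  with $SE = \sqrt{1/I_{case} + 1/I_{ctrl}}/\log 2$. A gene with all-zero
  counts in either group, or an undefined dispersion, gets `NA` and is
  excluded from the Benjamini–Hochberg denominator. DEGs are called at
  adjusted p < 0.05, strictly; no independent filtering or fold-change
  shrinkage is applied. Swapping the group labels negates every log2FC
  exactly (an invariant test).

FPKM uses the exonic-union gene length and the per-library mapped total;
expression classes are binned on the FPKM sum over all libraries: high
(> 100), medium (> 10), low (otherwise), with strict inequalities.

A known property of median-of-ratios normalisation, visible in the
acceptance metrics, is a composition bias when planted fold changes are
unidirectional: with 10% of genes up-regulated 4-fold, the recovered mean
log2FC is biased by about −0.13. This is a property of the normalisation
assumption (most genes unchanged), not of the estimator, which is
unbiased when true size factors are supplied.

## lncRNA identification and trans network

A transcript is kept as lncRNA iff it is longer than 200 nt, has at least
two exons, carries neither an Rfam nor a Pfam homology flag (flags are
inputs), and **all three** internal coding-potential scorers call it
noncoding. The unanimity rule is our reading of "lack of coding potential
confirmed by three methods"; a majority rule would admit transcripts one
scorer finds coding. The three scorers emulate the published tool family
with transparent internals:

1. **ORF rule** — coding iff the longest ATG..stop ORF (three forward
   frames, stop included, ties to the 5'-most start) is at least 300 nt
   *and* covers at least 30% of the transcript.
2. **Fickett TESTCODE** — the classic position/composition statistic with
   its published lookup tables; coding iff the score reaches 0.95.
3. **Hexamer usage** — mean in-frame log-ratio of dicodon probabilities
   (coding background: products of codon-model probabilities; noncoding
   background: the same model's marginal base composition), read in the
   frame of the longest ORF; coding iff positive. The background tables
   are derived analytically from the package codon-usage model at call
   time, so nothing binary is shipped.

DELs are the intersection of the lncRNA set with the DEG calls (via the
transcript-to-gene map). Trans links are Pearson correlations across the
11 libraries on `log2(count/size factor + 1)` — the expression scale is a
package choice, as correlation is scale-dependent but affine-invariant —
retained at |r| > 0.9 together with an explicit correlation t-test
(n − 2 df) at p < 0.05; the |r| threshold alone leaves the implied test
implicit, so we state it. Zero-variance profiles are skipped with a
warning.

## Differential alternative splicing

Events are enumerated from transcript models by pairwise isoform
comparison within each gene, in the five canonical geometries (SE, RI,
A5SS, A3SS, MXE), strand-aware: a shared genomic-right junction edge with
alternative left edges is an A5SS on the plus strand and an A3SS on the
minus strand, and vice versa. Each distinct coordinate tuple is emitted
once. Quantification is junction-count only: with 120 bp reads and an
8 nt anchor overhang, each junction offers 105 countable read start
positions, giving effective lengths $l_I$ and $l_S$ per event form.

$\mathrm{PSI} = (I/l_I) / (I/l_I + S/l_S)$, `NA` when no reads support
either form. The group test is a pooled binomial likelihood-ratio test —
one shared inclusion probability versus one per group, $\chi^2_1$ — which
replaces the hierarchical model of the reference tool; with replicate
counts pooled, between-replicate overdispersion is not modelled, so the
calibration is verified by simulation instead (the null false-flag rate
at the dual threshold is far below the 1% nominal level because the
|ΔPSI| > 0.1 requirement must also be met). Because the length
adjustment is a monotone reparameterisation of the binomial proportion,
the LRT is computed on raw counts. ΔPSI is the difference of group means
of per-sample PSI (case minus control, NA dropped); an event needs at
least one sample per group with 5 junction reads to be testable, and
untestable events are excluded from the BH denominator. DAS requires
adjusted p < 0.01 *and* |ΔPSI| > 0.1, both strict. A DASG is any gene
with at least one significant event; per-type counts let one gene count
in several types.

## Allele-specific expression (ΔAAF cascade)

The cascade mirrors the filtration-then-test structure of the analysis:

1. **Coverage filter** — total depth (ref + alt) of at least 10 reads in
   *every* sample of both groups, plus alt support (alt ≥ 2 and alt
   fraction ≥ 5%) in at least one sample.
2. **Region masks** — sites inside any of four interval classes are
   removed: bidirectional-transcription regions (opposite-strand gene
   overlap, or head-to-head TSSs within 1,000 bp), intron flanks (first
   and last 10 bp of every intron), simple sequence repeats, and
   pseudogene spans. The 1,000 bp window and 10 bp flank are package
   choices recorded in the run manifest; the source analysis names the
   classes but not the widths. Mask classes commute: the surviving set
   does not depend on application order.
3. **SSR detection** — perfect tandem repeats with motif lengths 1–6 and
   minimum repeat counts 12, 6, 4, 3, 3, 3; maximal (non-extendable)
   arrays with partial trailing repeats included; motifs that are
   repetitions of a shorter unit are reported at their primitive period.
   The detector is tested for exact interval equality against a
   brute-force enumerator.
4. **Group test** — per site, a two-sided Fisher's exact test on the 2×2
   table of ref/alt counts pooled within groups, BH-corrected. The source
   analysis states the statistic (ΔAAF) and the FDR bound but not the
   test; Fisher is chosen for validity at low depth, with a chi-square
   alternative behind a config switch. ΔAAF is the difference of
   unweighted means of per-sample AAF (pooled-count fractions available
   via config). Significance needs |ΔAAF| > 0.3 and FDR < 0.001, strict.
5. **Final selection** — "smallest standard deviation between biological
   replicates" is operationalised as within-group AAF SD ≤ 0.1 in both
   groups, ranked by the larger SD; the cutoff is configurable and
   recorded in the manifest.

Consequence annotation assigns, per site and overlapping transcript
(±5 kb, the conventional upstream/downstream window), one of eight
classes — upstream, 5' UTR, missense, synonymous, intron, splice acceptor
(last two intronic bases before the next exon in transcription order),
3' UTR, downstream — and reports the most severe class per site with
severity splice_acceptor > missense > synonymous > 5'UTR > 3'UTR >
intron > upstream > downstream. CDS substitutions are translated with the
standard genetic code, reverse-complemented on the minus strand; the
caller is tested for exact agreement with a translate-the-whole-protein
oracle and for exact strand symmetry under reverse complement of the
locus. Exonic positions of non-coding transcripts fall outside the eight
classes and are not annotated against that transcript; sites near no
transcript are `intergenic` and excluded from the class tally.

## Enrichment and qPCR validation

Over-representation is the one-sided hypergeometric tail
$P(X \ge k)$ (identical to one-sided Fisher on the 2×2 table; an
enumeration oracle checks exactness for small universes), with the
universe taken as all genes annotated in the namespace — the default
behaviour of the web tool the analysis used — and BH correction within
each namespace at FDR < 0.05. The trend z-score of a term is
$(n_{up}-n_{down})/\sqrt{n_{up}+n_{down}}$ over the term's DE genes.

qPCR uses the Pfaffl efficiency-corrected ratio
$RQ = E_t^{\Delta Cq_t} / E_{ref}^{\Delta Cq_{ref}}$ with
$\Delta Cq = \bar{Cq}_{ctrl} - Cq_{sample}$; two reference genes (ACTB,
GAPDH) are combined as the geometric mean of the per-reference ratios (a
package choice; the source lists both references without stating a
combination rule, and a single-reference mode exists). Technical
replicates (four per biological sample) are averaged after dropping
replicates more than one cycle from the replicate median. Group
differences are Student's t (two-tailed) on log2 RQ — the log scale
stabilises the variance of ratios; a raw-scale option is retained — with
stars at the printed thresholds 0.0332, 0.0021, 0.0002, 0.0001. With all
efficiencies equal to 2, RQ reduces to $2^{-\Delta\Delta Cq}$ exactly.

## The synthetic-data generator

The generator emulates the study conditions — 6 vs 5 libraries, NB counts
with log-normal library sizes (sdlog 0.2) and gamma dispersions (shape 2,
rate 20, mean 0.1), planted log2 fold changes of mean magnitude 2
(sd 0.5, random sign) in 10% of genes, binomial junction reads at planted
PSI (ΔPSI 0.3 in 20% of events, Poisson coverage 100), binomial allele
counts at planted AAF (ΔAAF 0.5 in 10% of sites, Poisson depth 50,
floor 1), coding sequences drawn from a stated codon-usage model with
ORFs ≥ 300 nt versus composition-matched noncoding sequence with ORFs
< 300 nt enforced by rejection (capped at 1,000 tries), and Cq values
under $Cq = Cq_0 - \log_E(\text{conc}) + N(0, 0.1)$ with four technical
replicates. Where the study fixes a value (design shape, read length 120,
thresholds) the generator uses it; remaining scale parameters (baseline
expression log-normal, coverage and depth means, fixture sizes of 2,000
genes / 300 events / 3,000 sites / 500 transcripts / 150 modelled genes)
are desk-scale choices a simulation of this kind would typically use, set
once.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: fragment GC and positional bias,
read-level error, between-replicate overdispersion of junction counts
(the binomial model is exactly the test's H1 family), mapping artefacts,
linkage between neighbouring allele sites, and annotation error in the
transcript models. Recovery rates on this generator are upper bounds on
real-data performance; the calibration statements (null false-flag
rates) are the more transferable results.

Determinism: each generator stage derives its own seed deterministically
from the master seed, so a configuration reproduces a byte-identical
bundle, and the pipeline run on it is byte-identical too (both are
asserted in tests).

## Numerical and interface choices

* Internal coordinates are 1-based inclusive throughout (the GTF/VCF and
  GRanges convention); BED's 0-based half-open intervals are converted at
  the I/O boundary only, bijectively. An all-0-based internal convention
  was considered and rejected: in an R/Bioconductor package every
  container and neighbour API is 1-based, so a private 0-based layer
  would add a conversion surface rather than remove one.
* Multiallelic VCF records are rejected by default (the analysis treats
  biallelic substitutions); a `split` mode emits one record per
  alternative allele. Indel records are skipped and counted.
* All decision thresholds are strict inequalities; boundary cases
  (padj = 0.05, FPKM sum = 10, p = 0.0332) fall on the non-significant
  side, and tests pin this.
* Degenerate inputs: zero junction coverage yields NA PSI; a group with
  zero allele depth makes a site untestable; all-zero genes and
  untestable events/sites are excluded from the BH denominator with the
  exclusion logged; fewer than two surviving qPCR replicates yield NA
  with a warning.
* Test-suite problem sizes (2,000 genes × 20 null replicates, 1,000
  events at coverage 200, 3,000 null sites, 1,000 oracle instances for
  the SSR and consequence callers, 500 transcripts for the lncRNA
  consensus) are chosen so the whole suite runs in about a minute on one
  CPU while keeping Monte-Carlo error well inside the asserted margins.

## Known limitations

The DE core is a simplified re-implementation: no Cox–Reid adjustment,
no dispersion MAP shrinkage, no outlier replacement, single-factor
designs only. The splicing test pools replicates and so does not model
biological variability in PSI; its calibration on overdispersed real data
would be optimistic. The paper's headline counts (473 DEGs and the rest)
depend on the original sequencing data and external databases and are
not reproducible at desk scale; the package's claims are the property
and calibration statements its tests compute.
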