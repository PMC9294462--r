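---
title: "Methods: dikaryon-monokaryon phasing and population structure"
author: "karyophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dikaryon-monokaryon phasing and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The system and the model

Edible dikaryotic fungi such as *Flammulina filiformis* carry two haploid
nuclei per mycelium. When the constituent monokaryons are recovered by
protoplast regeneration they *are* the dikaryon's two nuclei — no meiosis
intervenes — so at every marker the dikaryon genotype is exactly the
multiset union of its two monokaryon haplotypes. That single identity
drives everything in this package:

* **Phasing** is deterministic, not statistical. Given one haplotype,
  every heterozygous dikaryon site donates the complementary allele to
  the second nucleus and every homozygous site forces both nuclei.
* **Geometry**: under the joint dosage encoding (monokaryon allele
  $a \mapsto 2a$, dikaryon dosage unchanged) a dikaryon's encoded row is
  the arithmetic mean of its parents' rows. Genotype PCA standardises
  each marker affinely and projects linearly, so the dikaryon's score
  equals the mean of its parents' scores on *every* component, exactly
  (to numerical precision; the test-suite asserts $10^{-8}$). Pedigree
  inference exploits this: candidate parent pairs are ranked by the
  Euclidean distance between the dikaryon's score and the pair's mean
  score, with exact genotype compatibility (fraction of markers where
  $a + b$ reproduces the dikaryon dosage) as tie-break. A lexicographic
  order is used instead of a weighted sum because geometry alone cannot
  separate mirror-symmetric pairs and any weight would be arbitrary.

# Marker construction

Raw joint-genotyped VCFs are reduced to an intrapopulation-polymorphic
marker set by five conjunctive rules: (1) bi-allelic SNPs only; (2) minor
allele frequency strictly above 0.05; (3) at least one homozygous-reference
and one homozygous-alternative sample (a monokaryon allele counts as the
homozygous class, missing calls never count); (4) missing rate strictly
below 0.2; (5) no heterozygous call in any monokaryon — a haploid nucleus
cannot be heterozygous, so such calls flag genotyping artifacts. Removal
counts are attributed to the first failing rule in the order 1–5;
retention is order-independent. MAF uses ploidy-aware allele counting
(monokaryons contribute one allele, dikaryons two); a PLINK-parity mode
that counts every sample as diploid is available for comparison with
pipelines that recode haploids as homozygous diploids.

Heterozygosity levels for sample QC are low < 5%, medium 5–30%,
high > 30%. The 30% boundary and the ~20% medium anchor follow the
levels observed in resequenced dikaryon panels; the low/medium boundary
at 5% is this package's choice. Marker density uses non-overlapping
500-kb tiles by default (a sliding step is configurable); coordinates are
1-based in VCF and 0-based half-open in all interval arithmetic.

# Assembly integration

Assemblies join the marker set without read data: each contig is chopped
into 5,000-bp segments every 200 bp (pseudo-reads). For a contig of
length $L \ge 5000$, starts run $0, 200, \dots$ while
$\mathrm{start} + 5000 \le L$, plus one final segment anchored at
$L - 5000$ when the tail is not step-aligned — this guarantees full
coverage, with interior bases covered by $\lceil 5000/200 \rceil = 25$
segments. Shorter contigs are emitted whole. At each marker the aligned
base is collected from every covering segment and the majority base is
called, mapped to allele 0/1 when it equals the reference/alternative
allele and to "other" for a third base (excluded from the strictly
bi-allelic matrix). Exact ties are called missing — conservative, in
keeping with the filter philosophy. Alignment itself is pluggable: the
module consumes SAM, and the synthetic generator emits truth alignments
whose placements are known by construction, so the chop → align →
genotype loop is testable to exactness. How a production aligner plus
pileup caller would resolve discordant overlaps is their behaviour, not
ours; majority vote is this package's defined rule.

# The admixture model

Each sample $i$ draws its $n_{ij}$ allele copies at marker $j$
binomially from a mixture of $K$ ancestral frequency profiles:

$$ L(Q, F) = \sum_{ij} \left[ g_{ij} \log \textstyle\sum_k q_{ik} f_{kj}
 + (n_{ij} - g_{ij}) \log \sum_k q_{ik} (1 - f_{kj}) \right] $$

with $n_{ij} = 1$ for monokaryons and 2 for dikaryons (missing calls get
$g = n = 0$ and vanish). Treating haploids as one draw rather than a
duplicated diploid is statistically correct and is the default; a
PLINK-parity mode sets $n = 2$ throughout. The likelihood is maximised
by block EM with a compiled inner loop. Plain EM needs thousands of
sweeps on flat likelihood directions, so each cycle applies SQUAREM
extrapolation guarded by an explicit likelihood comparison: the
accelerated point is kept only when it does not decrease the likelihood,
otherwise the plain double sweep is kept. The recorded likelihood
sequence is therefore non-decreasing by construction — the classic EM
guarantee survives the acceleration. Defaults for a standalone fit:
eight starts (one informative k-means-on-PCA initialisation plus seven
random), absolute log-likelihood tolerance $10^{-6}$, at most 2,000
sweeps per start; ancestral frequencies are clamped to
$[10^{-6}, 1 - 10^{-6}]$ and ancestry rows renormalised each sweep.

## Choosing K by cross-validation

`cv_error()` masks non-missing genotype entries in folds, refits on the
remainder, predicts the masked dosages as $n_{ij} \sum_k q_{ik} f_{kj}$,
and pools the squared deviations; `choose_K()` minimises this over a
candidate range (2–6 by default). Three numerical choices matter, all
validated on the benchmark design by comparing against slow reference
settings before freezing:

* **5 folds** (the convention of the reference ancestry-estimation
  software), not more — fold fits dominate runtime and the CV curve is
  insensitive to the fold count here.
* **Warm starts**: each fold refit starts from the full-data fit and
  runs to convergence on the masked likelihood. This only selects the
  mode — cold k-means-initialised refits reproduce the same CV values to
  four decimals — and cuts sweeps by an order of magnitude.
* **Tolerance $10^{-2}$ and a 100-sweep cap** for CV refits (vs
  $10^{-6}$ / 2,000 for standalone fits): between-K CV gaps on this
  design are $\sim 2\times10^{-3}$ in dosage-MSE units, two orders above
  the change from tightening further; warm-started refits converge in
  tens of sweeps and the cap merely bounds the flat-direction tail at
  large K. CV values under these defaults match an uncapped
  $10^{-4}$ cold-start reference to four decimals.

## A real limitation: relatedness defeats CV-based K selection

On a combined monokaryon + dikaryon panel the CV error keeps falling
past the true K. This is not overfitting noise: with extra components
the held-out error dips *below* the error of the true generating
parameters, because union dikaryons literally contain their parents'
haplotypes and any structure that captures this duplication genuinely
predicts held-out entries. The same effect is expected in real panels
containing dikaryons together with their own constituent monokaryons.
K selection should therefore run on karyotype-specific panels; the
monokaryon haplotype panel is used throughout this package's analyses
(the dikaryon-only panel behaves correctly too but is small). On the
benchmark design the monokaryon panel shows a clear CV minimum at the
true K = 3, with the K=2 gap an order larger than the K=4 gap.

# The synthetic generator

`simulate_population()` draws an ancestral minor-allele frequency
uniformly on a configurable range (default (0.05, 0.5], with random
allele polarity), population profiles from the Balding–Nichols Beta
distribution with drift $F$ per component, monokaryon haplotypes
allele-wise Bernoulli from each individual's mixture frequency, and
dikaryons as unions of named haplotype pairs. Admixed individuals get
symmetric Dirichlet(0.5) ancestry — producing both near-pure and mixed
individuals, as real panels show. Genotyping error flips haploid allele
calls with probability $e$ and perturbs dikaryon genotype classes one
step (hom→het; het→either hom) with the same probability; the truth set
keeps the pre-error haplotypes. Missingness masks entries i.i.d., with
optional per-sample inflation to spread samples in QC space. No
empirical error rate is reported for the real study; the default is 0
and the error model is a free parameter.

Benchmark defaults — 3 components, $F = 0.3$, 120 monokaryons (10%
admixed), 20 dikaryons, 5,000 markers — are the conditions used by the
test-suite and the acceptance script. What the generator does *not*
emulate: linkage (markers are independent, so LD-sensitive behaviour is
untested), strain-specific genomic regions absent from the reference,
non-random missingness, and multi-allelic error modes. Passing tests
demonstrate correctness of the algorithms under the stated generative
model, not robustness to those real-data features.

Problem sizes throughout (5,000 markers, ~140 samples, 10 replicates for
the K-selection experiment, 50 dikaryons for pedigree recovery) are the
package's benchmark choices; every experiment is seeded and reproducible.

# Degenerate inputs and tie-breaks

* All-missing markers get undefined MAF and fail the MAF rule.
* Zero-variance markers are dropped before PCA standardisation; missing
  entries are mean-imputed (zero after centring) — imputation breaks the
  exact midpoint identity only at markers where the trio has missing
  calls.
* PCA signs follow a fixed convention (largest-magnitude loading
  positive).
* Phasing conflicts (homozygous dikaryon vs mismatching monokaryon) are
  recorded and emitted missing, never overwritten — conservative, and it
  keeps downstream MAF honest. How the original study's scripts handled
  such sites is not documented; this is our definition.
* `pairing_plausibility()` accepts a monokaryon as a credible
  constituent when the conflict rate is at most 0.01 — against genuine
  parents, conflicts arise only from genotyping error, while unrelated
  haplotypes conflict at roughly the homozygous-site mismatch rate
  (orders of magnitude higher).
* Inferred haplotypes are tagged by name (`<dikaryon>.inferred`) and
  participate in downstream analysis by default, mirroring expanded
  monokaryon panels built from sequenced plus inferred haplotypes.

# What the workflow scripts do

`analysis/01_simulate.R` … `06_pedigree.R` run the stages end to end on
the benchmark population, writing artifacts under `results/run/`:
simulate → filter/QC/density → assembly integration round trip →
phasing (conflict-free on error-free input; inferred haplotypes appended)
→ IBS/PCA/cross-validated admixture → pedigree recovery. Each script
prints the quantities it checks; `run_pipeline()` packages the same
sequence behind a single configuration object with a JSON manifest
recording every seed and threshold that affects output.
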