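---
title: "Methods: cross-species conservation analysis of regulatory epigenomes"
author: "epicross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species conservation analysis of regulatory epigenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicross)
library(GenomicRanges)
```

# Scope

`epicross` implements the comparative-epigenomics toolchain used to ask
how much of a cell lineage's regulatory program — here motivated by
regulatory (Treg) versus conventional (Teff) CD4+ T cells in human and
mouse — is conserved at three levels: the DNA sequence of a regulatory
element (*genetic* conservation), its activity mark (H3K27ac;
*epigenetic* conservation), and its lineage specificity (differential
activity between cell subsets). Around that core it provides the
statistics used downstream: transcription-factor binding conservation,
motif enrichment against flanking background, polymorphism-constraint
testing at accessible sites, allele-specific histone-acetylation
calling, and disease-SNP enrichment. Every stage can be exercised on
synthetic data with planted ground truth, which is how the test suite
and the acceptance script validate the implementation.

# Coordinate mapping through alignment chains

Intervals are mapped between assemblies through UCSC-format chain
files. A query maps through a chain when at least `minMappedFraction`
of its bases fall in aligned blocks of that single chain; the default
0.95 mirrors the liftOver `-minMatch` default. The mapped interval is
the span of the mapped bases on the target assembly, reported on the
plus strand (minus-strand chain coordinates are flipped with
`size - x`). When several chains qualify, the one covering the most
query bases wins, with ties broken by score and then input order. The
implementation is validated, exactly, against a brute-force per-base
walk through the block arithmetic on randomly simulated genome pairs.

Regulatory loci often fail to map as a whole — an acetylated region
spanning several kilobases may contain only a few hundred bases of
alignable sequence, which can be all that function requires. The
iterative search therefore falls back to fixed-length sub-windows
evaluated center-outward at centers $c_0, c_0 \pm s, c_0 \pm 2s,
\dots$, returning the first window that maps, together with its signed
offset from the locus center. The increment $s$ is assay-matched:
300 bp for histone-acetylation loci (3–5 kbp), 50 bp for DNase
hypersensitive sites (200 bp) and transcription-factor binding sites
(300 bp). Two details are deliberate choices rather than given facts:
the sub-window *length* equals the increment (the smallest unit
consistent with scanning in those increments), and ties between the
two sides at distance $k s$ are broken toward the lower coordinate. An
alternative reading — progressively shrinking the window rather than
scanning a fixed one — would find strictly fewer orthologs for the
same parameters; the fixed-window scan was chosen as the more
conservative and more reproducible of the two.

# The union atlas

Peaks from both species are merged into a single locus set. Each peak
is mapped into the other assembly; a human and a mouse peak collapse
into one *genetically conserved* locus when their cross-mappings
overlap reciprocally (at least 1 bp each way; many-to-one conflicts are
resolved by largest total overlap, then lowest coordinate). A peak
whose mapping lands in a peak desert remains genetically conserved —
the mapped interval stands in for the orthologous locus, so signal can
still be quantified there and found epigenetically inactive. Only
unmappable peaks become species-only loci, and downstream analyses
treat their signal in the missing species as zero by definition.
Every input peak is represented exactly once; overlapping same-species
peaks are merged first with a warning.

# Signal quantification and peak filters

Reads enter as start positions with strand only. Each read is modelled
as a 200 nt extension from its start in the read direction, and
contributes coverage over the central 100 nt of that extension —
`[start+50, start+150)` for a plus-strand read, the mirror image for a
minus-strand read. This transform sharpens signal at protein–DNA
contact points relative to raw read overlap. Counting for a peak uses
the same footprint with a 1 bp minimum overlap, and counts are scaled
to reads per million aligned reads (RPM). Consensus peaks are dropped
when they fail to reach 1 RPM in any ChIP sample, exceed 0.5 RPM in
any input sample (the maximum across input samples — the conservative
choice where a mean would also have been defensible), or overlap a
blacklist.

# Lineage specificity and its conservation

Differential activity between subsets is summarised as
$\log_2\!\frac{\mathrm{RPM}_a + 0.5}{\mathrm{RPM}_b + 0.5}$; the
symmetric pseudocount shrinks fold changes at weakly covered loci.
Replicates are averaged per cell type before the ratio. An element is
lineage-specific (`up`/`down`) when the fold change passes a threshold
$\tau$, by default 1 (two-fold), independently per species; the
combined nine-way class drives everything downstream. Cross-species
agreement of the lineage program is tested with one-sided upper-tail
hypergeometric overlap tests over the genetically conserved universe,
and — because any fixed $\tau$ is arbitrary — with a rank-cutoff scan
that repeats the overlap test over top-$k$ sets for a range of $k$.

Elements are assigned to all genes whose body lies within 100 kbp,
falling back to the single nearest gene by TSS distance. Expression
concordance per element class is summarised as ECDFs of gene-level
expression fold changes with two-sample Kolmogorov–Smirnov tests, with
mouse gene identifiers translated through a homology map and
unmappable identifiers reported rather than silently dropped. The
mobility analysis asks, per genic locus (nearest TSS plus genes within
100 kbp), whether lineage specificity is conserved at the gene level
even where individual elements are not: (1) genes with same-direction
lineage-specific elements in both species at non-orthologous
positions, with expression concordance assessed against a
permutation-of-gene-labels null; (2) lineage-specific elements whose
orthologous interval is epigenetically inactive in the other species;
(3) a loosened variant using the maximally lineage-specific element per
locus ($|\mathrm{lfc}|$ above 0.5) restricted to genes with at least
weak differential expression ("more than 0.5-fold, or q below 0.01" —
read as $|\log_2 \mathrm{FC}| > 0.5$, with q-values computed by
Benjamini–Hochberg where needed). These question definitions are
necessarily reconstructions; they are isolated in `mobilityAnalysis()`
so alternates can be swapped.

# Binding-site conservation and motif enrichment

Binding sites at genetically conserved loci are classed `both`,
`human_only` or `mouse_only` by whether occupancy reaches a
robust-quantification floor (default 1 RPM) at orthologous positions;
sites below the floor in both species are excluded, and unmappable
sites are reported separately rather than forced into a class.
Acetylation change per class is compared against all acetylated loci by
two-sample t-tests per species. Motif enrichment compares
presence/absence of an IUPAC consensus (default `RYAAAYA`, the
forkhead core; any pattern can be supplied) between sites and their two
200 nt flanks, both strands, pooling the flanks into one background and
testing the 2×2 region-count table with Fisher's exact test. Repression
of bound genes is tested with one-sided Kolmogorov–Smirnov tests
against all expressed genes.

# Polymorphism constraint at accessible sites

Each DHS is reduced to a 150 bp window around its center; the summary
is the number of contained SNPs and the maximum MAF across SNPs and
populations, binned by the conventional edges (<0.05 → 0, 0.05–0.15 →
0.1, …, >0.45 → 0.5; upper bins left-closed, so 0.05 falls in bin
0.1). The constraint statistic works on count-exceeding-bin curves:
for each group (conserved / non-conserved), the number of DHSs whose
maximum MAF reaches each bin, with $\log_{10}$ counts regressed on the
bin value. Two reconstruction decisions matter here:

* The regression response is not stated beyond "fitting a linear
  regression"; we regress $\log_{10}$ exceed-count on bin value and
  keep the statistic behind `constraintPermutationTest()` so an
  alternative response can be swapped in.
* "Greater conserved slopes" is read as a greater *decay rate* (the
  negative of the regression coefficient): a constrained group's curve
  falls faster, so its fitted coefficient is more negative and its
  decay slope larger. With that orientation the statistic
  $\Delta = \beta_{\mathrm{cons}} - \beta_{\mathrm{non}}$ is positive
  under constraint, and the empirical p-value
  $(1 + \#\{\Delta_{\pi} \ge \Delta_{\mathrm{obs}}\})/(n_{\pi}+1)$
  (add-one convention, labels permuted) detects it. The opposite sign
  reading would make planted suppression undetectable by construction.

The synthetic DHS generator draws Poisson(3) SNPs per window with MAF
$0.5\,\mathrm{Beta}(0.3, 1.2)$, matching the observed fraction of
windows containing at least one SNP (~95%) while being more
common-variant-rich than real catalogs. Planted constraint removes a
fraction of *high-MAF* variants (MAF ≥ 0.25, the upper bins) from
conserved windows. The threshold matters: removing all common variants
(≥ 0.05) mostly shifts the curves in parallel — a weak slope signal
(measured power 0.86 at 30% suppression, 5000 DHSs) — whereas removing
upper-bin variants plants a genuine constraint gradient, which is what
the slope statistic is built to measure (power 0.93 under the same
conditions). Under a MAF spectrum thinned to match real common-variant
fractions (~53% of windows), tail counts become too noisy for the
slope statistic to reach that power at 5000 DHSs regardless of
reading; detecting constraint there requires the full ~85,000-site
scale of real data.

# Allele-specific histone acetylation

The element-level pipeline follows this chain:

1. *Deduplication.* One read is kept per (chromosome, start, strand)
   key, chosen uniformly at random under an explicit seed — avoiding
   the reference bias of score-based deduplication.
2. *SNP reliability.* A variant is testable when its calls pass QC, it
   is heterozygous in ≥ 2 donors *and* homozygous in ≥ 2 donors, and
   its input (non-ChIPed) DNA shows no allelic imbalance at nominal
   p < 0.05.
3. *Per-variant imbalance.* Exact two-tailed binomial test of pooled
   het-donor ChIP depths against 0.5, using the minimum-likelihood
   convention (the sum of outcome probabilities no larger than the
   observed one), which at 0.5 coincides with doubling the smaller
   tail. Variants with p > 0.2 provide little evidence and are removed
   (the boundary is kept).
4. *LD collapsing.* Within an element, variants with genotype
   $r^2 > 0.99$ in all five reference populations are one signal; the
   highest-depth representative is kept. Collapse-then-combine honors
   the independence assumption of the next step; joint aggregation of
   linked variants is available by passing `panel = NULL` and
   pre-grouping.
5. *Aggregation.* Fisher's statistic $-2\sum \ln p$ over the element's
   contributing variants, calibrated against an empirical null built by
   aggregating the same number of uniform draws. Because the observed
   p-values were pre-selected below 0.2, the pipeline's null draws are
   uniform on $(0, 0.2]$ — the "identical assumptions" must include
   the selection, otherwise element-level p-values cannot be uniform
   under the null. With unselected draws (`nullMax = 1`,
   the default of `aggregateElement()`), the empirical p converges to
   the $\chi^2_{2k}$ upper tail, which the tests verify to within 0.01
   absolute at $10^5$ null draws.
6. *Zygosity-combined tests.* Read counts are made comparable across
   zygosity by excluding observations with ≤ 5 supporting reads,
   doubling heterozygous per-allele RPMs, and mean-normalizing.
   Heterozygous (within-individual) and homozygous
   (between-individual, t-test) evidence are independent, so their
   p-value product estimates joint significance. The genotype
   regression extends the usual {0, 1, 2} dosage domain to
   {0, 1, 2, 3}, with heterozygous individuals contributing their two
   allelic values at codes 1 and 2; slope differences between two
   groups are tested with a pooled-variance t on $n_1 + n_2 - 4$
   degrees of freedom, each group fitted with its own intercept.

Element-level results are summarised as a QQ table of observed versus
uniform-order-statistic expected $-\log_{10}$ p-values, observed values
capped at 5 for display. No FDR is applied by default — the
deliverable is the divergence of the whole distribution, not a
significance list; Benjamini–Hochberg can be applied to the returned
p-values where a list is wanted.

One calibration subtlety is worth recording: exact binomial p-values
are discrete, so element-level uniformity under the null holds only
when read depths vary across variants and donors. The cohort generator
therefore draws per-donor depths from a negative binomial
(mean 35, size 6) rather than a constant; with constant depths the
test statistic would concentrate on a handful of atoms and no empirical
null could make it uniform.

# Disease-risk SNP enrichment

GWAS-catalog studies contribute only if they identified strictly more
than 5 independent SNPs. Around each regulatory element a broad region
of ±100 kbp is taken — extended to cover the most proximal gene body
when that body reaches beyond the window (the parenthetical "or" is
read as an augmentation, not a replacement) — and overlapping regions
are merged, which is the crude LD correction that prevents one
haplotype from being counted once per element it contains. Enrichment
of a disease set is a one-tailed upper hypergeometric test with all
catalog variants as the universe: $N$ catalog variants, $K$ in
regions, $n$ in the disease set, $k$ in both. Risk elements are
partitioned into four nested categories (genetically non-conserved;
conserved; conserved and lineage-specific in human; conserved and
lineage-specific in both species). Note the test is exact and
discrete: under a null catalog its p-values are conservative rather
than exactly uniform, and the calibration checks assert the rejection
rate and location of the p distribution rather than a KS fit.

# The synthetic-data generators

`simulationConfig()` fixes the study conditions; the defaults are the
conditions under which all planted-truth checks run:

* *Genome pair*: assembly B is derived from A by Poisson-sampled
  insertions, deletions (exponential lengths, mean 150 bp), inversions
  (mean 2 kbp, emitted as minus-strand chains) and chromosome breaks;
  the chain set encodes the relation exactly and round-trips through
  the parser bit-identically. The truth map lists every aligned
  segment, which is what the per-base oracle in the tests consumes.
* *Epigenome*: locus classes are drawn from planted proportions
  (85% conserved-active, 1.5% + 1.5% single-species lineage-specific,
  0.1% both-species, 0.05% discordant, remainder genetically
  non-conserved), the lineage fold effect is 4, and counts are
  negative binomial with mean 50 at a library size of one million over
  2 aTreg / 4 rTreg / 2 Teff / 4 Tn replicates per species — the
  replicate structure of the motivating study design. The dispersion
  default of 0.01 is derived from the reproducibility that study
  reports (replicate correlations above 0.99): at mean 50,
  $\mathrm{Var}[\log_2] \approx (1/\mu + \phi)/\ln^2 2$, and
  $r > 0.99$ on log replicates over a signal spread of
  $\mathrm{sd} = 1.5$ requires $\phi$ of order $10^{-2}$. Baseline
  log2 signal is bivariate normal across species with correlation
  $\rho = 0.5$ and spread 1.5.
* *Cohort*: donors receive Hardy–Weinberg genotypes at common variants
  (MAF uniform on 0.2–0.5 — allele-specific testing requires common
  heterozygotes), planted allele-specific elements emit ChIP reads
  with alternate-allele probability $\theta = 0.75$ while input stays
  at 0.5, and reference panels carry optional perfect-LD duplicate
  variants to exercise collapsing.
* *GWAS catalog*: background variants uniform over the genome; an
  enriched disease set's variants land inside target regions with
  probability $\min(1, f L/G)$ at fold enrichment $f$ (default 5 for
  the autoimmune set, 1 for metabolic and psychiatric); each set
  includes one undersized study of exactly 5 SNPs so the study filter
  is always exercised.

Two recovery experiments deserve their design notes. The
class-proportion experiment (20,000 loci) holds the baseline log2
spread at zero so that every locus sits at the stated count mean of 50:
it measures classification against count noise alone, and estimated
class counts are compared with exact binomial 99% intervals of the
planted conditional proportions. The correlation experiment uses the
default spread of 1.5 — correlation is undefined without cross-locus
variation — and recovers $\rho = 0.5$ to within ±0.05; the residual
count noise attenuates the observed correlation by the factor
$\sigma^2/(\sigma^2 + \mathrm{Var}_{\mathrm{count}})$, about 3% under
the defaults.

What the generators do *not* emulate: realistic sequence composition
(motif tests plant occurrences in synthetic C/G background), realistic
human LD structure (panel LD is all-or-nothing), mappability and GC
biases, fragment-length variation (reads are reduced to starts by
design), or the covariance of expression with chromatin beyond the
planted concordance. Passing tests therefore demonstrate correctness
of the statistics and plumbing under a known model, not robustness to
every artefact of real sequencing data; the headline quantities of the
motivating study (correlation 0.48 between species, tens of thousands
of elements, thousands of allele-specific enhancers) depend on its
actual libraries and are out of reach at desk scale.

# Numerical conventions and problem sizes

Randomness always flows through explicit seed arguments; permutation
and empirical p-values use the add-one convention and therefore live in
$(0, 1]$; zero p-values entering a log aggregation are clamped to the
smallest positive double with a warning; boundary conventions are
stated at each filter (prefilter keeps p = 0.2; the zygosity filter
requires *more than* 5 reads; the study filter requires *more than* 5
SNPs; MAF bins are left-closed above). The default validation sizes —
1000 oracle queries over ≤ 100 kb assemblies, 1000-element null
cohorts, 5000-DHS constraint runs with 199 permutations, 20,000-locus
recovery experiments — were chosen so the whole suite completes on a
single CPU in well under half an hour while keeping every interval
estimate comfortably away from its acceptance boundary.

# Known limitations

* The union atlas resolves many-to-one mappings greedily; a
  reciprocal-best-hit graph matching could differ on dense peak sets.
* `classifyBindingConservation()` takes the maximum occupancy over
  overlapping partner sites rather than re-quantifying reads at the
  mapped interval.
* The mobility analysis implements one defensible reading of three
  informally posed questions; its counts are not comparable across
  different gene-assignment rules.
* The constraint statistic's regression response is a reconstruction;
  its power depends strongly on the assumed MAF spectrum (see above).
* VCF support covers GT + AD fields only — enough for the
  allele-specific module, not a general-purpose variant reader.
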