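---
title: "Methods: cline, discordance and NUMT-aware analyses of a mimicry transition zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cline, discordance and NUMT-aware analyses of a mimicry transition zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

*Bombus melanopygus* carries two Müllerian-mimetic colour forms — a northern
ferruginous form and a southern black form — that meet in a narrow
transition zone in northern California and southern Oregon. Three kinds of
markers change along that zone: the colour phenotype itself (controlled by a
single locus with ferruginous dominant), the mitochondrial COI haplogroup
(a northern and a southern lineage differing by a handful of substitutions),
and genome-wide nuclear ancestry. The analytical questions are where each
marker's cline sits, how wide it is, and whether the mitochondrial and
colour/nuclear clines are displaced from one another — the signature of
mito-nuclear discordance.

`mimicline` implements that analysis as a reusable, fully tested pipeline:
specimen-table handling and transect projection, dominance-aware
allele-frequency estimation under haplodiploidy, equilibrium cline models
fitted by MCMC with AICc model selection, two chi-squared discordance
tests, COI haplotype statistics and a minimum-spanning haplotype network,
a tiered NUMT-aware SNP filter cascade, and nuclear-structure inference
(neighbour joining, LD pruning, PCA, NMF-based ancestry). A synthetic
hybrid-zone generator supplies data with the statistical structure the
methods assume, so every stage is testable without any downloads.

# The transect

Specimens are projected onto a one-dimensional south-to-north transect as
the Haversine distance from the southernmost specimen, computed along a
meridian (longitude is ignored; the zone is modelled as latitudinal).
The Earth radius is fixed at the IUGG mean, R = 6371.0088 km, so distances
are bit-reproducible; one degree of latitude is then 111.1949 km. A full
2D great-circle option (`projection = "great_circle"`) exists because the
choice is not forced by the data model; the latitudinal projection is the
default since an east–west scatter of collection sites would otherwise
bend the 1D axis unpredictably.

# Allele frequencies under dominance and haplodiploidy

Ferruginous (f) is dominant over black (b); males are haploid. For
diploid females the Hardy–Weinberg inversion gives
$\hat b = \sqrt{\text{proportion of black females}}$ because black females
are exactly the bb homozygotes. For males the phenotype proportion is the
allele frequency. The combined estimate treats individuals equally: the
female estimate is converted to an effective count of black individuals
($\hat b_\text{♀} n_\text{♀}$), added to the black male count, and divided
by the total number of individuals. Effective counts are real-valued, and
the temporal test of frequency change per locality is a Pearson chi-squared
test of independence on the 2 × P table of effective counts across P
collection periods (df = P − 1, no continuity correction). Females with a
sequenced colour genotype can instead contribute exact allele counts
(`use_known_genotypes = TRUE`); the default uses the phenotype-based
inversion for all ungenotyped females.

# Equilibrium cline models

The central cline is $p(x) = p_{min} + (p_{max}-p_{min})\, s(x)$ with
$s(x) = \left(1 + \tanh\frac{2(x-c)}{w}\right)/2$: $c$ is the centre (km),
and $w$ (km) is the width in the inverse-of-maximum-slope sense, since
$s'(c) = 1/w$. Three model classes follow the standard fixed/free-scaling,
tails-none/both taxonomy:

* **Model I** — $p_{min}, p_{max}$ fixed at the observed data extremes;
* **Model II** — $p_{min}, p_{max}$ free;
* **Model III** — free scaling plus two exponential tails fitted
  separately. For $x < x_L = c - \delta_L$ the tail is
  $s(x) = s(x_L)\exp\{\tau_L s'(x_L)(x-x_L)/s(x_L)\}$, and symmetrically on
  the right. This parameterisation is value-continuous everywhere, monotone,
  and slope-continuous at the junction when $\tau = 1$. It is this
  package's own tail form in the spirit of the classic two-tail cline
  models; bit-identity with any other implementation is a non-goal.

Because the study's specimens are scattered individuals rather than
population samples, each individual is its own locality. Binary traits
(mtDNA haplogroup, colour phenotype) use a Bernoulli likelihood with the
fitted probability clamped to $[10^{-9}, 1-10^{-9}]$ to keep a misfit
finite; continuous ancestry proportions use a Gaussian likelihood with a
free residual SD $\sigma \in (0, 1]$.

Fitting is Metropolis–Hastings MCMC under uniform priors (centre over the
data range; width in $(0, 3\times\text{range}]$; bounds in $[0,1]$ with
$p_{min} < p_{max}$; tail offsets in $[0, \text{range}]$; tail scales in
$[0,1]$). Proposals are componentwise Gaussian random walks whose scales
adapt during burn-in towards 20–40% acceptance and are then frozen, so the
post-burn-in chain is a valid fixed-kernel sampler. Defaults are 10^5
sweeps, 10% burn-in, thinning 10; the recovery analyses in the tests and
the acceptance script use 12,000 sweeps at n = 500, which the
parameter-recovery checks show is ample for a two-parameter model-I fit.
The centre is summarised two ways — a 95% equal-tailed credible interval
and the 2-log-likelihood support region — because "centre range" is
ambiguous between the two; neither is privileged. Model choice uses AICc,
$2k - 2\log L + 2k(k+1)/(n-k-1)$, with ties broken towards fewer
parameters. Width is reported both as the $w$ parameter and as
$w/(p_{max}-p_{min})$, which differ under free scaling.

# Discordance tests

Within the hybrid zone — by default the interval from the southernmost
northern-haplogroup specimen to the northernmost southern-haplogroup
specimen, overridable — two Pearson goodness-of-fit constructions are
computed on specimens whose colour allele is known (all males, since
phenotype = allele in haploids, plus females with a sequenced colour
locus):

1. **Haplotype vs colour-allele distribution**: observed (northern,
   southern) haplotype counts against expected proportions equal to the
   (ferruginous, black) allele frequencies, pairing each haplogroup with
   its ancestral colour. df = 1.
2. **Colour within one haplogroup**: the (f, b) counts within a haplogroup
   against the overall hybrid-zone colour frequencies. df = 1. Most
   informative for the rarer southern haplogroup.

Colour alleles are counted per allele (two per female) by default; a
per-individual mode (heterozygous females contribute half to each side)
matches the "individuals treated equally" convention of the
allele-frequency module. Both are exposed because the category unit
(alleles vs individuals) is a genuine modelling choice.

The type-I calibration treats the expected colour-allele frequencies as
given proportions: haplotype counts are simulated binomially at the same
frequency and tested against it, which is the regime in which a df = 1
Pearson statistic holds its nominal size. If instead the expectation were
re-estimated from an equally small sample in every replicate, the
statistic would be inflated by roughly $(1 + n_\text{hap}/n_\text{alleles})$
and no fixed reference distribution would apply; in the package the
expectation comes from the much larger allele pool, which the calibration
idealises as known.

# COI statistics and the haplotype network

Alignments are character matrices (FASTA in/out via `ape`). A site is
variable if it shows two or more states ignoring N and gaps, and
parsimony-informative if at least two states each occur in at least two
sequences. Fixed differences between haplogroups require within-group
fixation on both sides, with N/gap-bearing members ignored site-wise.
Divergence is the p-distance over pairwise-unambiguous sites, and
divergence time applies a strict clock (default 1.5% per Myr for insect
COI): 1.6% divergence dates to just over one million years.

Haplotype collapsing merges sequences identical over mutually non-N sites
(N is a wildcard; merging is greedy in input order, so it is deterministic)
and can drop sequences containing IUPAC heterozygous codes — individuals
carrying two haplotypes of unknown phase. Gaps are simple-indel-coded: each
distinct (start, end) gap run becomes one presence/absence character
weighted as a single mutational step.

The network is the union of all minimum spanning trees over haplotype
Hamming distances (substitution steps plus gap characters): an edge of
weight d is included exactly when its endpoints are not connected by
strictly lighter edges. Tied alternative connections are therefore
retained, which reproduces the reticulations a statistical-parsimony (TCS)
network shows at this divergence scale (≤ 8 steps); the 95% connection
limit of true TCS is irrelevant at such shallow depths and is not
implemented. Tests verify the edge set against exhaustive spanning-tree
enumeration on small instances.

# The NUMT filter cascade

Nuclear copies of mitochondrial DNA (NUMTs) masquerade as nuclear SNPs
fixed between mitochondrial lineages, so the filter is tiered:

1. **Quality** — non-biallelic sites dropped; calls with DP < 3 or GQ < 20
   set missing (thresholds inclusive: DP 3 and GQ 20 survive).
2. **Structural** — sites on contigs < 20 kb dropped; then any site with a
   missing call dropped.
3. **Interval exclusion** — annotation intervals, homology-scan hits, and
   the ~18 kb colour-locus interval, all 1-based closed internally (BED
   I/O converts from 0-based half-open).
4. **Fixed-SNP scan** — sites where every southern-group sample is
   homozygous for one allele and every other sample for the alternative;
   any heterozygous or missing call disqualifies the site (conservative,
   and the no-missing filter precedes the scan anyway).

The clustering diagnostic lists consecutive inter-fixed-site distances per
contig, labels each pair by whether an endpoint lies in a NUMT interval,
and summarises the fraction of close pairs (< 1 kb) involving NUMTs —
tight clusters of fixed sites are the NUMT signature, scattered fixed
sites the genuine divergence signal.

`naive_homology_scan()` is a deliberately small seed-and-extend matcher
(exact 15-mers chained on diagonals, ungapped identity ≥ 0.8, hits ≥ 60 bp,
both strands) used to locate near-identical mitochondrial insertions in
the synthetic genomes; its parameters are fixed and it makes no attempt at
the sensitivity of a full local aligner.

# Nuclear structure

Distances are allele-sharing distances (mean |dosage difference|/2).
Neighbour joining is the Saitou–Nei agglomeration with the
Studier–Keppler criterion, written here so its determinism is explicit:
ties in Q break towards the smallest index pair, and negative branch
lengths are clamped to zero with the deficit transferred to the sibling
edge. Tests require exact inversion of random additive trees and agreement
with an independent implementation.

LD pruning scans left-to-right and, for each kept site, drops later sites
within 5 kb whose dosage r² exceeds 0.5 (strictly; r² = 0.5 is kept, and a
pair 5,001 bp apart is outside the window). Keep-first is the documented,
deterministic retention rule. PCA is an eigendecomposition of the
column-centred dosage matrix with a deterministic sign convention
(largest-magnitude loading positive).

Ancestry proportions come from a simplex-constrained factorisation of the
dosage/2 matrix, X ≈ QG, fitted by multiplicative updates in the EM form
of the binomial admixture likelihood (because Q rows sum to one,
1 − QG = Q(1 − G), so allele and reference responsibilities factor
cleanly). A beta-style pseudo-count (default 0.5) keeps ancestral
frequencies off the 0/1 boundary, where a single held-out allele would
otherwise dominate the scoring. For each K a random 5% of entries is held
out; the cross-entropy of the hold-out under QG scores the fit, the best
of 10 restarts is kept per K, and the K minimising the mean restart
cross-entropy is selected. This is an "sNMF-like" stand-in delivering the
same decisions (a K choice and a Q matrix), not a reimplementation of any
specific regularised factorisation; outputs are labelled accordingly. The
full cross-entropy curve is always reported, because a most-likely K = 1
with interpretable K = 2 structure is a real possibility in weakly
differentiated data, and that interpretation belongs to the user.

# The synthetic hybrid zone

The generator's defaults are the study conditions: colour cline centred at
661.6 km (width 134.3 km), mtDNA cline at 607.0 km (width 157.6 km), and a
nuclear admixture cline at 650.6 km (width 292 km) on a 0–1300 km
transect, so that recovery tests double as plausibility checks against
the field-fitted values. Specimens (default n = 2000, 20% males) are
uniform on the transect; diploid genotypes are drawn at Hardy–Weinberg
proportions from the local black-allele frequency, haploids Bernoulli, the
phenotype follows dominance, and the haplogroup follows the mtDNA cline.
The COI alignment plants 8 fixed inter-haplogroup differences, 4
within-group variants carried by two sequences each, and 1 singleton —
13 variable sites of which 12 are parsimony-informative, the observed
structure. The SNP matrix has 20 genomic samples (3 southern-haplogroup)
drawn binomially from admixture-weighted ancestral frequencies separated
by 0.3 on average; genomic samples are placed on a 300–1000 km window
because genome-sequenced individuals were collected around the transition
zone rather than across the whole range. Planted NUMT intervals (2 × 1 kb,
15 clustered fixed sites each) and 30 scattered genuinely nuclear fixed
sites give the filter cascade a known truth; planted sites carry clean
depth/quality so truth survives the quality tiers.

What the generator does *not* emulate: coalescent noise and LD structure
within populations, recombination around the colour locus, selection,
uneven sampling effort, museum-specimen georeferencing error, and
sequencing artefacts beyond simple DP/GQ noise. Passing recovery tests
therefore shows the estimators are correct under the assumed model, not
that the model captures every feature of field data.

# Numerical choices and problem sizes

* Bernoulli cline probabilities clamped at $10^{-9}$; tail formulas switch
  to their saturation limit when the junction sigmoid is within $10^{-12}$
  of 0/1 (avoiding 0/0).
* MCMC initialisation redraws from the prior until the likelihood is
  finite (at most 100 tries).
* LD r² uses a $10^{-9}$ epsilon so r² = 0.5 is kept despite floating
  point.
* Recovery analyses use n = 500 individuals per cline, 12,000 MCMC sweeps,
  and 20 replicate seeds; the admixture analyses use 20 samples × 2000
  SNPs. These sizes were chosen as the smallest at which the recovery
  properties are stable across seeds.
* All generators and fits are pure functions of their seed.

# Known limitations

* The admixture Q estimates saturate towards 0/1 relative to the true
  admixture fraction (maximum-likelihood behaviour with thousands of
  informative sites). A Gaussian cline fitted to Q therefore recovers the
  cline *centre* well but compresses the *width* relative to the planted
  admixture gradient; width inferences from ancestry coefficients should
  be read as properties of the assignment profile, not the underlying
  gradient.
* The minimum-spanning network is an approximation to statistical
  parsimony; at divergences much deeper than ~10 steps the two can differ.
* The N-wildcard haplotype merge is order-dependent in pathological cases
  (a fully ambiguous sequence compatible with several haplotypes joins the
  first); heterozygote exclusion should precede collapsing when IUPAC
  codes are present.
* Chi-squared p-values are asymptotic; very small expected counts should
  use the Monte-Carlo route demonstrated in the tests instead.
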