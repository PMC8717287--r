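# mimicline

Analysis toolkit for the *Bombus melanopygus* mimicry transition zone —
and, more generally, for one-dimensional hybrid zones scored for a
dominant colour locus, a mitochondrial marker, and genome-wide SNPs.

The bumble bee *B. melanopygus* has a northern ferruginous and a southern
black colour form, each matching a regional Müllerian mimicry complex.
The forms meet in a narrow transition zone where three marker systems can
be compared along a south-to-north transect: the colour phenotype
(single locus, ferruginous dominant), the mitochondrial COI haplogroup
(two lineages differing by a few substitutions), and nuclear ancestry.
`mimicline` provides the full analysis chain:

* **Specimen handling** — validated specimen tables (TSV), Haversine
  projection of latitudes onto a 1D transect (R = 6371.0088 km).
* **Allele frequencies under dominance and haplodiploidy** — for diploid
  females \(\hat b = \sqrt{\text{prop. black}}\) (black = bb under
  dominance), for haploid males the phenotype proportion; combined
  estimates treat individuals equally, and a chi-squared test of
  independence compares effective counts across collection periods.
* **Equilibrium geographic clines** —
  \(p(x) = p_{min} + (p_{max}-p_{min})\,\frac{1+\tanh(2(x-c)/w)}{2}\)
  with model classes I (fixed scaling), II (free scaling) and III (free
  scaling + two exponential tails), fitted by Metropolis–Hastings MCMC at
  individual-level localities, compared by AICc, and cross-compared for
  centre shifts (mito-nuclear discordance).
* **Discordance tests** — two df = 1 Pearson goodness-of-fit
  constructions inside the hybrid zone: haplotype counts against
  colour-allele frequencies, and colour frequencies within one haplogroup
  against the overall frequencies.
* **COI statistics and haplotype networks** — variable /
  parsimony-informative site counts, fixed inter-group differences,
  p-distance divergence and clock dating (1.5%/Myr), IUPAC-aware
  haplotype collapsing, simple indel coding, and a minimum-spanning
  haplotype network that retains tied connections (TCS-style
  reticulation).
* **NUMT-aware SNP filtering** — quality (biallelic, DP ≥ 3, GQ ≥ 20),
  structural (contigs ≥ 20 kb, no missing data), tiered interval
  exclusion (annotation / homology / colour locus), a fixed-SNP scan
  between haplogroup sample groups, and clustering diagnostics that
  separate tightly clustered NUMT-derived fixed sites from scattered
  genuine ones.
* **Nuclear structure** — allele-sharing distances, neighbour joining,
  LD pruning (r² > 0.5 in 5 kb), PCA, and sNMF-like ancestry estimation
  by simplex-constrained NMF with hold-out cross-entropy K selection.
* **Synthetic hybrid zone** — a generator whose defaults plant the
  field-fitted study conditions (colour cline 661.6/134.3 km, mtDNA
  607.0/157.6 km, nuclear 650.6/292 km), so every stage is testable
  offline with known truth.

## Worked example

```r
library(mimicline)

cfg <- sim_config(n_specimens = 400)
tab <- simulate_specimens(cfg, seed = 1)
x   <- tab$transect_km

f_col <- fit_cline(x, as.integer(tab$color_phenotype == "ferruginous"),
                   "I_fixed_none", "bernoulli", iterations = 12000, seed = 1)
f_mt  <- fit_cline(x, as.integer(tab$mt_haplogroup == "northern"),
                   "I_fixed_none", "bernoulli", iterations = 12000, seed = 2)
f_col; f_mt
#> cline fit (I_fixed_none, bernoulli): center 638.6 km [95% CI 618.7-660.7], width 141.9 km, AICc 83.09
#> cline fit (I_fixed_none, bernoulli): center 575.5 km [95% CI 553.3-596.8], width 161.5 km, AICc 99.85

cmp <- compare_clines(f_col, f_mt)
#> centre shift: 63.2 km (95% CI 33.9 to 95.0)

w   <- hybrid_zone_window(tab)      # 389.2 - 642.9 km
cnt <- discordance_counts(tab, w)
haplotype_vs_colorallele_gof(cnt)   # chi2 = 46.70, p = 8.3e-12
color_within_haplotype_gof(cnt, "southern")  # chi2 = 0.10, p = 0.75

aln <- simulate_coi_alignment(tab, cfg, seed = 1)
g   <- attr(aln, "groups")
fixed_differences(aln, g, "northern", "southern")  # 8
site_summary(aln)                   # 13 variable, 12 parsimony informative
divergence_time(1.6, 1.5)           # 1.07 Myr
```

The colour cline sits north of the mtDNA cline (centre shift ≈ 63 km in
this 400-specimen simulation, planted truth 54.6 km): inside the zone the
southern mitochondrial haplotype occurs in specimens whose colour alleles
look like the overall zone (second test, n.s.), while the haplotype
*counts* deviate strongly from the colour-allele frequencies (first
test) — the mito-nuclear discordance signature. The COI statistics
recover the planted two-haplogroup structure: 8 fixed differences among
13 variable sites, dating the split to just over a million years under a
1.5%/Myr clock.

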