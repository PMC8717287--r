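#' Hybrid-zone window along the transect
#'
#' Default window spans from the southernmost northern-haplogroup specimen
#' to the northernmost southern-haplogroup specimen — the region where the
#' two mitochondrial lineages co-occur.
#'
#' @param table a `specimen_table` with known haplogroups.
#' @param override optional `c(south_km, north_km)` pair that wins if given.
#' @return km interval `c(lo, hi)`.
#' @export
hybrid_zone_window <- function(table, override = NULL) {
  if (!is.null(override)) {
    if (length(override) != 2 || override[1] > override[2]) {
      stop("override must be an increasing km pair")
    }
    return(as.numeric(override))
  }
  north <- table$transect_km[table$mt_haplogroup == "northern"]
  south <- table$transect_km[table$mt_haplogroup == "southern"]
  if (length(north) == 0 || length(south) == 0) {
    stop("need specimens of both haplogroups (or an override window)")
  }
  lo <- min(north)
  hi <- max(south)
  if (lo > hi) stop("haplogroup ranges do not overlap: empty hybrid zone")
  c(lo, hi)
}

#' Colour-allele and haplotype counts inside the hybrid zone
#'
#' Restricts a specimen table to the hybrid-zone window and to specimens
#' whose colour allele is known: all males (haploid, allele = phenotype) and
#' females with a sequenced colour genotype.  Colour alleles are counted per
#' allele (2 per female, 1 per male) by default, or per individual
#' (heterozygous females contribute 0.5 to each allele) to weight
#' individuals equally.
#'
#' @param table a `specimen_table`.
#' @param window km pair from [hybrid_zone_window()].
#' @param counting `"alleles"` or `"individuals"`.
#' @return list of haplotype counts (`n_north`, `n_south`), overall allele
#'   counts (`n_f`, `n_b`), and per-haplogroup allele counts.
#' @export
discordance_counts <- function(table, window,
                               counting = c("alleles", "individuals")) {
  counting <- match.arg(counting)
  in_zone <- table$transect_km >= window[1] & table$transect_km <= window[2] &
    table$mt_haplogroup %in% c("northern", "southern")
  t <- table[in_zone, , drop = FALSE]
  male <- t$ploidy == "haploid"
  known_female <- !male & t$color_genotype %in% c("ff", "fb", "bb")
  # males without a recorded genotype still have a known allele via phenotype
  male_allele_b <- ifelse(t$color_genotype[male] %in% c("b", "f"),
                          t$color_genotype[male] == "b",
                          t$color_phenotype[male] == "black")
  use <- male | known_female
  if (!any(use)) stop("no specimens with known colour alleles in window")

  allele_counts <- function(idx_sel) {
    sel_m <- idx_sel & male
    sel_f <- idx_sel & known_female
    gt <- t$color_genotype[sel_f]
    mb <- ifelse(t$color_genotype[sel_m] %in% c("b", "f"),
                 t$color_genotype[sel_m] == "b",
                 t$color_phenotype[sel_m] == "black")
    if (counting == "alleles") {
      b <- sum(mb) + 2 * sum(gt == "bb") + sum(gt == "fb")
      f <- sum(!mb) + 2 * sum(gt == "ff") + sum(gt == "fb")
    } else {
      b <- sum(mb) + sum(gt == "bb") + 0.5 * sum(gt == "fb")
      f <- sum(!mb) + sum(gt == "ff") + 0.5 * sum(gt == "fb")
    }
    c(f = f, b = b)
  }

  overall <- allele_counts(use)
  by_north <- allele_counts(use & t$mt_haplogroup == "northern")
  by_south <- allele_counts(use & t$mt_haplogroup == "southern")
  list(
    n_north = sum(use & t$mt_haplogroup == "northern"),
    n_south = sum(use & t$mt_haplogroup == "southern"),
    n_f = unname(overall["f"]), n_b = unname(overall["b"]),
    northern = by_north, southern = by_south,
    counting = counting, window = window
  )
}

# two-category Pearson goodness of fit, df = 1, no continuity correction
.gof2 <- function(observed, expected_freq) {
  if (any(expected_freq <= 0)) stop("zero expected cell in goodness-of-fit")
  expected <- expected_freq / sum(expected_freq) * sum(observed)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, df = 1,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = observed, expected = expected)
}

#' Are mtDNA haplotypes distributed like colour alleles?
#'
#' Goodness-of-fit of the observed (northern, southern) haplotype counts in
#' the hybrid zone against expected proportions equal to the
#' (ferruginous, black) colour-allele frequencies.  The northern haplogroup
#' is paired with the ferruginous allele, its ancestral colour; under equal
#' gene flow of mitochondria and colour the two distributions should match.
#'
#' @param counts output of [discordance_counts()], or a list with `n_north`,
#'   `n_south`, `n_f`, `n_b`.
#' @return list with `chi2`, `df = 1`, `p`, observed and expected counts.
#' @export
haplotype_vs_colorallele_gof <- function(counts) {
  observed <- c(northern = counts$n_north, southern = counts$n_south)
  .gof2(observed, c(counts$n_f, counts$n_b))
}

#' Does one haplogroup carry a skewed colour-allele distribution?
#'
#' Goodness-of-fit of the (f, b) allele counts within one haplogroup against
#' the overall hybrid-zone colour-allele frequencies.  Most informative for
#' the rarer (southern) haplogroup.
#'
#' @param counts output of [discordance_counts()].
#' @param haplogroup `"northern"` or `"southern"`.
#' @return list with `chi2`, `df = 1`, `p`, observed and expected counts.
#' @export
color_within_haplotype_gof <- function(counts,
                                       haplogroup = c("southern", "northern")) {
  haplogroup <- match.arg(haplogroup)
  observed <- counts[[haplogroup]]
  if (sum(observed) == 0) stop("haplogroup has no specimens with known alleles")
  .gof2(observed, c(counts$n_f, counts$n_b))
}
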