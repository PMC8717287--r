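#' Female colour-allele frequency under dominance
#'
#' Females are diploid and ferruginous is dominant, so black females are the
#' homozygotes `bb` and the Hardy-Weinberg inversion gives the black-allele
#' frequency as the square root of the black phenotype proportion.
#'
#' @param n_black_females number of black-phenotype females.
#' @param n_females total females (>= 1).
#' @return list with `b` and `f = 1 - b`.
#' @export
female_allele_freq <- function(n_black_females, n_females) {
  if (n_females < 1) stop("allele frequency undefined for zero females")
  if (n_black_females < 0 || n_black_females > n_females) {
    stop("black-female count out of range")
  }
  b <- sqrt(n_black_females / n_females)
  list(b = b, f = 1 - b)
}

#' Male colour-allele frequency
#'
#' Males are haploid so the phenotype proportion is the allele frequency.
#'
#' @param n_black_males black males.
#' @param n_males total males (>= 1).
#' @return list with `b` and `f`.
#' @export
male_allele_freq <- function(n_black_males, n_males) {
  if (n_males < 1) stop("allele frequency undefined for zero males")
  if (n_black_males < 0 || n_black_males > n_males) {
    stop("black-male count out of range")
  }
  b <- n_black_males / n_males
  list(b = b, f = 1 - b)
}

#' Combined colour-allele frequency, treating individuals equally
#'
#' The female estimate is converted into an effective individual count
#' (`b_female * n_females`) and added to the black male count; the combined
#' frequency divides by the total number of individuals, so a female and a
#' male carry equal weight despite their different ploidy.
#'
#' @param n_black_females,n_females female phenotype counts.
#' @param n_black_males,n_males male phenotype counts.
#' @param locality,period labels carried into the result.
#' @return an `allele_freq_estimate`: list with `b`, `f`,
#'   `effective_b_count`, `effective_f_count`, and the input counts.
#' @export
combined_allele_freq <- function(n_black_females, n_females,
                                 n_black_males, n_males,
                                 locality = NA_character_,
                                 period = NA_character_) {
  n_total <- n_females + n_males
  if (n_total < 1) stop("allele frequency undefined with no individuals")
  b_female <- if (n_females > 0) {
    female_allele_freq(n_black_females, n_females)$b
  } else 0
  eff_b <- b_female * n_females + n_black_males
  b <- eff_b / n_total
  structure(
    list(locality = locality, period = period,
         b = b, f = 1 - b,
         effective_b_count = eff_b, effective_f_count = n_total - eff_b,
         n_females = n_females, n_black_females = n_black_females,
         n_males = n_males, n_black_males = n_black_males),
    class = "allele_freq_estimate"
  )
}

#' Per-locality, per-period allele-frequency estimates from a specimen table
#'
#' Groups specimens by locality and period and applies
#' [combined_allele_freq()] to the phenotype counts.  Specimens with unknown
#' phenotype are dropped.  With `use_known_genotypes = TRUE`, females with a
#' sequenced colour genotype (`ff`/`fb`/`bb`) contribute exact allele counts
#' (two alleles each) instead of entering the Hardy-Weinberg inversion; this
#' changes only the effective counts, the reported `b` still treats
#' individuals equally (a genotyped female contributes `fb` as half an
#' effective black individual).
#'
#' @param table a `specimen_table`.
#' @param use_known_genotypes use sequenced female genotypes where present.
#' @return data.frame, one row per locality x period.
#' @export
allele_freq_table <- function(table, use_known_genotypes = FALSE) {
  keep <- table$color_phenotype %in% c("ferruginous", "black")
  t <- table[keep, , drop = FALSE]
  groups <- split(seq_len(nrow(t)),
                  list(locality = t$locality, period = t$period),
                  drop = TRUE)
  rows <- lapply(groups, function(idx) {
    g <- t[idx, , drop = FALSE]
    fem <- g$ploidy == "diploid"
    mal <- !fem
    known <- fem & use_known_genotypes & g$color_genotype %in% c("ff", "fb", "bb")
    # effective black individuals among genotyped females: bb = 1, fb = 0.5
    eff_known <- sum(g$color_genotype[known] == "bb") +
      0.5 * sum(g$color_genotype[known] == "fb")
    hw_fem <- fem & !known
    est <- combined_allele_freq(
      n_black_females = sum(g$color_phenotype[hw_fem] == "black"),
      n_females = sum(hw_fem),
      n_black_males = sum(g$color_phenotype[mal] == "black"),
      n_males = sum(mal),
      locality = g$locality[1], period = g$period[1]
    )
    eff_b <- est$effective_b_count + eff_known
    n_total <- sum(fem) + sum(mal)
    data.frame(
      locality = g$locality[1], period = g$period[1],
      n_females = sum(fem), n_black_females = sum(g$color_phenotype[fem] == "black"),
      n_males = sum(mal), n_black_males = sum(g$color_phenotype[mal] == "black"),
      effective_b_count = eff_b, effective_f_count = n_total - eff_b,
      b = eff_b / n_total, f = 1 - eff_b / n_total
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$locality, out$period), , drop = FALSE]
}

#' Chi-squared test of allele-frequency independence across periods
#'
#' Pearson chi-squared test of independence on a 2 x P table of effective
#' black/ferruginous counts across P collection periods within a locality.
#' Effective counts may be non-integer.
#'
#' @param counts 2 x P matrix (rows: b, f; columns: periods), or a
#'   data.frame from [allele_freq_table()] restricted to one locality.
#' @return list with `chi2`, `df = P - 1`, `p`.
#' @export
period_independence_test <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- rbind(b = counts$effective_b_count,
                    f = counts$effective_f_count)
  }
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two periods")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
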