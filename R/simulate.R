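#' Simulation configuration for the synthetic hybrid zone
#'
#' Defaults plant the fitted study-condition clines as simulation truth:
#' colour cline centred at 661.6 km with width 134.3 km, mtDNA cline at
#' 607.0 km with width 157.6 km, nuclear admixture cline at 650.6 km with
#' width 292 km, on a 0-1300 km south-to-north transect.  The COI alignment
#' plants 8 fixed inter-haplogroup differences plus 4 within-group variants
#' shared by two sequences and 1 singleton (13 variable sites, 12 of them
#' parsimony informative).  The SNP matrix plants 20 genomic samples
#' (3 southern-haplogroup) and NUMT intervals carrying tightly clustered
#' sites fixed between haplogroup sample groups.
#'
#' @param seed default RNG seed used by the generators.
#' @param n_specimens specimens in the simulated table.
#' @param male_fraction fraction of drones (haploid).
#' @param transect_extent km pair, south to north.
#' @param color_cline,mt_cline,nuclear_cline `c(center, width)` km pairs.
#' @param nuclear_noise_sd Gaussian observation noise on ancestry
#'   proportions.
#' @param genotyped_female_fraction fraction of females with a sequenced
#'   colour genotype recorded.
#' @param coi_length,coi_fixed_diffs,coi_shared_variants,coi_singletons COI
#'   alignment structure (bp / site counts; shared variants are carried by
#'   two sequences each, singletons by one).
#' @param n_snps,n_samples_genomic,n_southern_genomic,n_contigs,contig_length
#'   SNP matrix dimensions.
#' @param genomic_extent km pair over which genomic samples were collected
#'   (concentrated around the transition zone, unlike the full specimen
#'   transect).
#' @param numt_intervals,numt_interval_length,numt_sites_per_interval
#'   planted NUMT insertions and their clustered fixed sites.
#' @param n_fixed_nonnumt genuinely nuclear sites fixed between haplogroup
#'   sample groups, scattered across contigs.
#' @param ancestral_freq_divergence mean absolute allele-frequency
#'   difference between the two ancestral populations.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_specimens = 2000,
                       male_fraction = 0.2,
                       transect_extent = c(0, 1300),
                       color_cline = c(center = 661.6, width = 134.3),
                       mt_cline = c(center = 607.0, width = 157.6),
                       nuclear_cline = c(center = 650.6, width = 292),
                       nuclear_noise_sd = 0.1,
                       genotyped_female_fraction = 0.3,
                       coi_length = 500,
                       coi_fixed_diffs = 8,
                       coi_shared_variants = 4,
                       coi_singletons = 1,
                       n_snps = 2000,
                       n_samples_genomic = 20,
                       genomic_extent = c(300, 1000),
                       n_southern_genomic = 3,
                       n_contigs = 10,
                       contig_length = 1e5,
                       numt_intervals = 2,
                       numt_interval_length = 1000,
                       numt_sites_per_interval = 15,
                       n_fixed_nonnumt = 30,
                       ancestral_freq_divergence = 0.3) {
  cfg <- as.list(environment())
  if (cfg$color_cline[2] <= 0 || cfg$mt_cline[2] <= 0 ||
      cfg$nuclear_cline[2] <= 0) stop("cline widths must be > 0")
  rng <- cfg$transect_extent
  centers <- c(cfg$color_cline[1], cfg$mt_cline[1], cfg$nuclear_cline[1])
  if (any(centers < rng[1] | centers > rng[2])) {
    stop("cline centers must lie within the transect extent")
  }
  if (cfg$coi_fixed_diffs + cfg$coi_shared_variants + cfg$coi_singletons >
        cfg$coi_length) {
    stop("more planted COI variant sites than alignment columns")
  }
  if (cfg$numt_interval_length > cfg$contig_length) {
    stop("NUMT intervals exceed contig bounds")
  }
  class(cfg) <- "sim_config"
  cfg
}

# southern-trait probability: high south of the center, falling northward
.south_prob <- function(x, center, width) {
  1 - (1 + tanh(2 * (x - center) / width)) / 2
}

# invert a transect km back to a latitude on a fixed meridian
.km_to_lat <- function(km, ref_lat = 36) ref_lat + km / 111.194927

#' Simulate a specimen table along the transect
#'
#' Positions are uniform on the transect.  The black-allele frequency at x
#' follows the colour cline (black in the south), diploid genotypes are
#' drawn at Hardy-Weinberg proportions, haploid genotypes Bernoulli, the
#' phenotype follows dominance of ferruginous, and the mtDNA haplogroup is
#' southern with the probability given by the mtDNA cline.  Latitudes are
#' back-computed on a fixed meridian so that the table's derived
#' `transect_km` reproduces the simulated positions up to the southernmost
#' specimen's offset.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a `specimen_table`; true positions are in
#'   `attr(, "true_position_km")`.
#' @export
simulate_specimens <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  n <- config$n_specimens
  x <- stats::runif(n, config$transect_extent[1], config$transect_extent[2])
  b <- .south_prob(x, config$color_cline[1], config$color_cline[2])
  male <- stats::runif(n) < config$male_fraction
  caste <- ifelse(male, "drone",
                  ifelse(stats::runif(n) < 0.15, "queen", "worker"))
  genotype <- character(n)
  u <- stats::runif(n)
  # diploids at HW proportions b^2 : 2bf : f^2; haploids Bernoulli(b)
  genotype[!male] <- ifelse(u[!male] < b[!male]^2, "bb",
                     ifelse(u[!male] < b[!male]^2 +
                              2 * b[!male] * (1 - b[!male]), "fb", "ff"))
  genotype[male] <- ifelse(u[male] < b[male], "b", "f")
  phenotype <- ifelse(genotype %in% c("bb", "b"), "black", "ferruginous")
  mt <- ifelse(stats::runif(n) <
                 .south_prob(x, config$mt_cline[1], config$mt_cline[2]),
               "southern", "northern")
  recorded_gt <- genotype
  hide <- !male & stats::runif(n) > config$genotyped_female_fraction
  recorded_gt[hide] <- "unknown"
  records <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    caste = caste,
    latitude = .km_to_lat(x),
    longitude = -122,
    color_phenotype = phenotype,
    color_genotype = recorded_gt,
    mt_haplogroup = mt,
    period = "2014-2019",
    locality = sprintf("L%02d", floor(x / 100))
  )
  tab <- specimen_table(records)
  attr(tab, "true_position_km") <- x
  tab
}

#' Simulate a COI alignment matching specimen haplogroups
#'
#' Two haplogroup consensus sequences differ at exactly
#' `coi_fixed_diffs` sites; `coi_shared_variants` additional sites carry a
#' private variant in two sequences of one group and `coi_singletons` in a
#' single sequence.  All planted sites are disjoint, so the counts are
#' additive.
#'
#' @param table a `specimen_table` with known `mt_haplogroup`s.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return character matrix alignment with specimen ids as rownames and
#'   haplogroups in `attr(, "groups")`.
#' @export
simulate_coi_alignment <- function(table, config = sim_config(),
                                   seed = config$seed) {
  set.seed(seed)
  keep <- table$mt_haplogroup %in% c("northern", "southern")
  ids <- table$id[keep]
  groups <- table$mt_haplogroup[keep]
  if (length(ids) == 0) stop("no specimens with known haplogroup")
  L <- config$coi_length
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  n_special <- config$coi_fixed_diffs + config$coi_shared_variants +
    config$coi_singletons
  special <- sample.int(L, n_special)
  fixed_sites <- special[seq_len(config$coi_fixed_diffs)]
  shared_sites <- special[config$coi_fixed_diffs +
                            seq_len(config$coi_shared_variants)]
  singleton_sites <- special[config$coi_fixed_diffs +
                               config$coi_shared_variants +
                               seq_len(config$coi_singletons)]
  mutate <- function(base) sample(setdiff(bases, base), 1)

  south_cons <- anc
  for (s in fixed_sites) south_cons[s] <- mutate(anc[s])
  aln <- matrix(rep(anc, each = length(ids)), nrow = length(ids),
                dimnames = list(ids, NULL))
  aln[groups == "southern", ] <- matrix(rep(south_cons, each = sum(groups == "southern")),
                                        nrow = sum(groups == "southern"))
  plant <- function(aln, site, group, n_carriers) {
    members <- which(groups == group)
    if (length(members) < n_carriers) {
      stop("not enough ", group, " sequences to carry a planted variant")
    }
    carriers <- members[sample.int(length(members), n_carriers)]
    aln[carriers, site] <- mutate(aln[members[1], site])
    aln
  }
  grp_cycle <- rep(c("northern", "southern"), length.out = length(shared_sites))
  for (i in seq_along(shared_sites)) {
    aln <- plant(aln, shared_sites[i], grp_cycle[i], 2)
  }
  for (s in singleton_sites) aln <- plant(aln, s, "northern", 1)
  attr(aln, "groups") <- groups
  attr(aln, "planted") <- list(fixed = sort(fixed_sites),
                               shared = sort(shared_sites),
                               singleton = sort(singleton_sites))
  aln
}

#' Simulate a NUMT-contaminated SNP matrix
#'
#' Background sites are drawn binomially from admixture-weighted allele
#' frequencies: two ancestral frequency vectors separated on average by
#' `ancestral_freq_divergence`, mixed per sample according to a nuclear
#' admixture cline along the transect.  Planted NUMT intervals contain
#' tightly clustered sites fixed between the southern-haplogroup samples
#' and the rest; `n_fixed_nonnumt` scattered sites are fixed between the
#' same groups but genuinely nuclear.  Planted sites get clean depth and
#' quality so the truth survives the quality filters.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `matrix` (a `snp_matrix`), `truth` (NUMT intervals,
#'   per-site NUMT flag, positions of all planted fixed sites, admixture
#'   proportions, sample positions) and `sample_table` (a `specimen_table`
#'   for the genomic samples).
#' @export
simulate_snp_matrix <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  ns <- config$n_samples_genomic
  n_south <- config$n_southern_genomic
  contigs <- sprintf("contig%02d", seq_len(config$n_contigs))
  contig_lengths <- stats::setNames(rep(config$contig_length,
                                        config$n_contigs), contigs)

  # southern samples sit at the south end of the genomic sampling range
  x <- sort(stats::runif(ns, config$genomic_extent[1],
                         config$genomic_extent[2]))
  groups <- stats::setNames(
    c(rep("southern", n_south), rep("northern", ns - n_south)),
    sprintf("G%02d", seq_len(ns)))
  samples <- names(groups)
  alpha <- 1 - .south_prob(x, config$nuclear_cline[1],
                           config$nuclear_cline[2])  # northern ancestry

  # background biallelic sites
  n_bg <- config$n_snps
  p_north <- stats::runif(n_bg, 0.05, 0.95)
  p_south <- pmin(pmax(p_north + sample(c(-1, 1), n_bg, replace = TRUE) *
                         config$ancestral_freq_divergence, 0.02), 0.98)
  bg_contig <- sample(contigs, n_bg, replace = TRUE)
  bg_pos <- sample.int(config$contig_length, n_bg, replace = TRUE)

  # planted NUMT intervals with clustered fixed sites
  numt_truth <- list()
  numt_rows <- list()
  for (i in seq_len(config$numt_intervals)) {
    ctg <- contigs[(i - 1) %% config$n_contigs + 1]
    start <- round(config$contig_length * (0.25 + 0.4 * (i - 1) /
                                             max(config$numt_intervals - 1, 1)))
    end <- start + config$numt_interval_length - 1
    pos <- sort(sample(seq(start, end), config$numt_sites_per_interval))
    numt_truth[[i]] <- data.frame(contig = ctg, start = start, end = end,
                                  tier = "annotation")
    numt_rows[[i]] <- data.frame(contig = ctg, pos = pos)
  }
  numt_intervals <- if (length(numt_truth)) do.call(rbind, numt_truth) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               tier = character(0))
  numt_sites <- if (length(numt_rows)) do.call(rbind, numt_rows) else
    data.frame(contig = character(0), pos = integer(0))

  # scattered genuinely nuclear fixed sites
  nn <- config$n_fixed_nonnumt
  fx_contig <- sample(contigs, nn, replace = TRUE)
  fx_pos <- sample.int(config$contig_length, nn, replace = TRUE)

  # planted rows first so a position collision never silently drops truth
  sites <- rbind(
    data.frame(contig = numt_sites$contig, pos = numt_sites$pos,
               kind = rep("numt", nrow(numt_sites))),
    data.frame(contig = fx_contig, pos = fx_pos,
               kind = rep("fixed_nuclear", length(fx_contig))),
    data.frame(contig = bg_contig, pos = bg_pos,
               kind = rep("background", length(bg_contig)))
  )
  sites <- sites[!duplicated(sites[, c("contig", "pos")]), ]
  ord <- order(sites$contig, sites$pos)
  sites <- sites[ord, ]
  n_sites_total <- nrow(sites)

  gt <- matrix(NA_real_, n_sites_total, ns)
  bg_idx <- which(sites$kind == "background")
  bg_of <- match(paste(sites$contig[bg_idx], sites$pos[bg_idx]),
                 paste(bg_contig, bg_pos))
  for (j in seq_len(ns)) {
    p <- alpha[j] * p_north[bg_of] + (1 - alpha[j]) * p_south[bg_of]
    gt[bg_idx, j] <- stats::rbinom(length(bg_idx), 2, p)
  }
  is_south <- groups[samples] == "southern"
  planted <- sites$kind != "background"
  gt[planted, is_south] <- 2
  gt[planted, !is_south] <- 0

  dp <- matrix(stats::rpois(n_sites_total * ns, 20), n_sites_total, ns)
  gq <- matrix(ifelse(stats::runif(n_sites_total * ns) < 0.02,
                      stats::rpois(n_sites_total * ns, 10), 99),
               n_sites_total, ns)
  dp[planted, ] <- 30
  gq[planted, ] <- 99

  ref <- sample(c("A", "C", "G", "T"), n_sites_total, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  site_df <- data.frame(contig = sites$contig, pos = sites$pos,
                        ref = ref, alt = unname(alt))
  m <- snp_matrix(site_df, gt, dp, gq, samples = samples,
                  sample_groups = groups, contig_lengths = contig_lengths)

  lat <- .km_to_lat(x)
  sample_table <- specimen_table(data.frame(
    id = samples, caste = "worker", latitude = lat, longitude = -122,
    color_phenotype = "unknown", color_genotype = "unknown",
    mt_haplogroup = unname(groups), period = "2014-2019",
    locality = sprintf("L%02d", floor(x / 100))
  ))
  list(
    matrix = m,
    truth = list(
      numt_intervals = numt_intervals,
      numt_site = sites$kind == "numt",
      planted_fixed = sites$kind != "background",
      site_kind = sites$kind,
      admixture_north = alpha,
      position_km = x,
      groups = groups
    ),
    sample_table = sample_table
  )
}
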