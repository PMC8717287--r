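#' Per-call quality filter
#'
#' Drops non-biallelic sites and sets individual calls failing the depth or
#' genotype-quality thresholds to missing.  Thresholds are inclusive:
#' DP >= 3 and GQ >= 20 are retained at the defaults.
#'
#' @param m a `snp_matrix`.
#' @param min_depth,min_gq inclusive per-call thresholds.
#' @return filtered `snp_matrix`; `attr(, "removed_sites")` counts dropped
#'   sites.
#' @export
quality_filter <- function(m, min_depth = 3, min_gq = 20) {
  n0 <- n_sites(m)
  m <- snp_subset(m, m$sites$biallelic)
  fail <- (!is.na(m$dp) & m$dp < min_depth) | (!is.na(m$gq) & m$gq < min_gq)
  m$gt[fail] <- NA
  attr(m, "removed_sites") <- n0 - n_sites(m)
  m
}

#' Structural filter: short contigs and missingness
#'
#' Sites on contigs shorter than `min_contig` bp are dropped (inclusive:
#' a 20,000 bp contig is retained at the default), then sites with more
#' than `max_missing` missing calls are dropped (default 0: any missing
#' call removes the site).
#'
#' @param m a `snp_matrix` with known contig lengths.
#' @param min_contig minimum contig length, bp.
#' @param max_missing maximum missing calls per retained site.
#' @return filtered `snp_matrix` with `attr(, "removed_sites")`.
#' @export
structural_filter <- function(m, min_contig = 20000, max_missing = 0) {
  if (is.null(m$contig_lengths)) stop("contig lengths are required")
  unknown <- setdiff(unique(m$sites$contig), names(m$contig_lengths))
  if (length(unknown) > 0) {
    stop("no length recorded for contig(s): ", paste(unknown, collapse = ", "))
  }
  n0 <- n_sites(m)
  keep_contig <- m$contig_lengths[m$sites$contig] >= min_contig
  m <- snp_subset(m, keep_contig)
  n_miss <- rowSums(is.na(m$gt))
  m <- snp_subset(m, n_miss <= max_missing)
  attr(m, "removed_sites") <- n0 - n_sites(m)
  m
}

# logical index of sites falling inside any 1-based closed interval
.sites_in_intervals <- function(sites, intervals) {
  hit <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (sites$contig == intervals$contig[i] &
                    sites$pos >= intervals$start[i] &
                    sites$pos <= intervals$end[i])
  }
  hit
}

#' Exclude sites falling in annotation intervals
#'
#' Removes every site whose position lies inside any interval (1-based
#' closed, both endpoints included) and reports removals per tier.
#'
#' @param m a `snp_matrix`.
#' @param intervals data.frame with `contig`, `start`, `end`, `tier`
#'   (e.g. from [read_bed()] or [naive_homology_scan()]).
#' @return filtered `snp_matrix`; `attr(, "removed_by_tier")` is a named
#'   count per tier and `attr(, "removed_sites")` the total.
#' @export
interval_exclude <- function(m, intervals) {
  n0 <- n_sites(m)
  if (is.null(intervals) || nrow(intervals) == 0) {
    attr(m, "removed_sites") <- 0L
    attr(m, "removed_by_tier") <- integer(0)
    return(m)
  }
  tiers <- unique(intervals$tier)
  by_tier <- vapply(tiers, function(tr) {
    sum(.sites_in_intervals(m$sites, intervals[intervals$tier == tr, ]))
  }, integer(1))
  names(by_tier) <- tiers
  hit <- .sites_in_intervals(m$sites, intervals)
  m <- snp_subset(m, !hit)
  attr(m, "removed_sites") <- n0 - n_sites(m)
  attr(m, "removed_by_tier") <- by_tier
  m
}

#' Exclude the colour-locus interval
#'
#' Removes SNPs within the mapped colour-controlling interval (~18 kb
#' around the Abd-B region) so that nuclear structure is estimated without
#' the locus under divergent mimicry selection.
#'
#' @param m a `snp_matrix`.
#' @param contig,start,end the interval, 1-based closed.
#' @return filtered `snp_matrix` with `attr(, "removed_sites")`.
#' @export
region_exclude_color_locus <- function(m, contig, start, end) {
  interval_exclude(m, data.frame(contig = contig, start = start, end = end,
                                 tier = "color_locus"))
}

#' Scan for SNPs fully fixed between two sample groups
#'
#' A site is fixed when every group-A sample is homozygous for one allele
#' and every group-B sample homozygous for the other; any heterozygous or
#' missing call disqualifies the site.
#'
#' @param m a `snp_matrix`.
#' @param groupA,groupB disjoint character vectors of sample ids.
#' @return `fixed_snp_report`: data.frame of fixed sites (`contig`, `pos`)
#'   with the total per contig in `attr(, "per_contig")`.
#' @export
fixed_snp_scan <- function(m, groupA, groupB) {
  if (length(intersect(groupA, groupB)) > 0) stop("groups must be disjoint")
  if (length(groupA) == 0 || length(groupB) == 0) stop("groups must be non-empty")
  missing_ids <- setdiff(c(groupA, groupB), m$samples)
  if (length(missing_ids) > 0) {
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  }
  a <- m$gt[, groupA, drop = FALSE]
  b <- m$gt[, groupB, drop = FALSE]
  a_ref <- rowSums(a == 0, na.rm = TRUE) == length(groupA) & !rowSums(is.na(a))
  a_alt <- rowSums(a == 2, na.rm = TRUE) == length(groupA) & !rowSums(is.na(a))
  b_ref <- rowSums(b == 0, na.rm = TRUE) == length(groupB) & !rowSums(is.na(b))
  b_alt <- rowSums(b == 2, na.rm = TRUE) == length(groupB) & !rowSums(is.na(b))
  fixed <- (a_ref & b_alt) | (a_alt & b_ref)
  out <- m$sites[fixed, c("contig", "pos")]
  rownames(out) <- NULL
  per_contig <- table(factor(out$contig, levels = unique(m$sites$contig)))
  structure(out, per_contig = per_contig, class = c("fixed_snp_report", "data.frame"))
}

#' Clustering diagnostics for fixed SNPs (NUMT signature)
#'
#' NUMT-derived SNPs sit in short nuclear insertions of the mitochondrial
#' genome, so fixed sites of mitochondrial origin cluster tightly while
#' genuine nuclear fixed sites are scattered.  The report lists consecutive
#' inter-site distances within contigs, labels each pair by whether either
#' endpoint falls in a NUMT annotation interval, and summarises the
#' fraction of close pairs (< `close_bp`) that involve NUMTs.
#'
#' @param report a `fixed_snp_report` from [fixed_snp_scan()].
#' @param intervals NUMT annotation intervals (1-based closed, with `tier`),
#'   or NULL for none.
#' @param close_bp distance below which a pair counts as close.
#' @return list with `per_contig` counts, `pair_distances` (data.frame:
#'   contig, distance, numt_pair), `close_pair_numt_fraction`,
#'   `median_distance_numt`, `median_distance_non_numt`.
#' @export
numt_cluster_report <- function(report, intervals = NULL, close_bp = 1000) {
  sites <- as.data.frame(report)
  numt_flag <- if (is.null(intervals) || nrow(intervals) == 0) {
    rep(FALSE, nrow(sites))
  } else {
    .sites_in_intervals(sites, intervals)
  }
  rows <- list()
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    if (length(idx) < 2) next
    ord <- idx[order(sites$pos[idx])]
    dpos <- diff(sites$pos[ord])
    pair_numt <- numt_flag[ord[-length(ord)]] | numt_flag[ord[-1]]
    rows[[ctg]] <- data.frame(contig = ctg, distance = dpos,
                              numt_pair = pair_numt)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), distance = numeric(0),
               numt_pair = logical(0))
  rownames(pairs) <- NULL
  close <- pairs$distance < close_bp
  frac <- if (any(close)) mean(pairs$numt_pair[close]) else 0
  list(
    per_contig = attr(report, "per_contig"),
    site_numt_flag = numt_flag,
    pair_distances = pairs,
    close_pair_numt_fraction = frac,
    median_distance_numt = stats::median(pairs$distance[pairs$numt_pair]),
    median_distance_non_numt = stats::median(pairs$distance[!pairs$numt_pair])
  )
}

#' Naive seed-and-extend homology scan for NUMT regions
#'
#' Self-contained matcher locating regions of a reference genome similar to
#' mitochondrial query sequences: exact k-mer seeds (k = 15) are chained
#' along diagonals (gap tolerance `max_gap`), candidate regions are scored
#' by ungapped identity, and hits of at least `min_len` bp and
#' `min_identity` are merged into intervals.  Both strands are scanned.
#' This is a small test-support matcher with fixed parameters, suited to
#' the near-identical copies a NUMT screen targets.
#'
#' @param reference named character vector or `Biostrings::DNAStringSet` of
#'   genome contigs.
#' @param queries mitochondrial query sequences, same accepted types.
#' @param min_len minimum merged hit length, bp.
#' @param min_identity minimum ungapped identity of a candidate region.
#' @param k seed length.
#' @param max_gap maximum seed gap chained on one diagonal.
#' @return data.frame of intervals (`contig`, `start`, `end`, 1-based
#'   closed, `tier = "homology"`).
#' @export
naive_homology_scan <- function(reference, queries, min_len = 60,
                                min_identity = 0.8, k = 15, max_gap = 50) {
  ref <- if (inherits(reference, "DNAStringSet")) reference
         else Biostrings::DNAStringSet(reference)
  qry <- if (inherits(queries, "DNAStringSet")) queries
         else Biostrings::DNAStringSet(queries)
  if (length(ref) == 0 || length(qry) == 0) stop("empty sequences")
  if (is.null(names(ref))) names(ref) <- paste0("contig", seq_along(ref))

  hits <- list()
  for (qi in seq_along(qry)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qry[[qi]] else Biostrings::reverseComplement(qry[[qi]])
      qlen <- length(q)
      if (qlen < k) next
      starts <- seq_len(qlen - k + 1)
      kmers <- Biostrings::DNAStringSet(q, start = starts, width = k)
      pd <- Biostrings::PDict(kmers)
      for (ci in seq_along(ref)) {
        mm <- Biostrings::matchPDict(pd, ref[[ci]])
        qpos <- rep(starts, times = lengths(mm))
        rpos <- unlist(lapply(mm, IRanges::start), use.names = FALSE)
        if (length(rpos) == 0) next
        diag <- rpos - qpos
        for (dg in unique(diag)) {
          rp <- sort(rpos[diag == dg])
          grp <- cumsum(c(1, diff(rp) > max_gap + k))
          for (g in unique(grp)) {
            r1 <- min(rp[grp == g])
            r2 <- max(rp[grp == g]) + k - 1
            if (r2 - r1 + 1 < min_len) next
            q1 <- r1 - dg
            rs <- as.character(Biostrings::subseq(ref[[ci]], r1, r2))
            qs <- as.character(Biostrings::subseq(q, q1, q1 + (r2 - r1)))
            ident <- mean(strsplit(rs, "")[[1]] == strsplit(qs, "")[[1]])
            if (ident >= min_identity) {
              hits[[length(hits) + 1]] <-
                data.frame(contig = names(ref)[ci], start = r1, end = r2)
            }
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), tier = character(0)))
  }
  all_hits <- do.call(rbind, hits)
  merged <- lapply(split(all_hits, all_hits$contig), function(h) {
    ir <- IRanges::reduce(IRanges::IRanges(h$start, h$end))
    data.frame(contig = h$contig[1], start = IRanges::start(ir),
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out$tier <- "homology"
  out
}
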