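# small in-code fixtures shared across test files

specimen_df <- function(...) {
  base <- data.frame(
    id = c("q1", "w1", "d1"),
    caste = c("queen", "worker", "drone"),
    latitude = c(40, 42, 38),
    longitude = c(-122, -122, -122),
    color_phenotype = c("ferruginous", "black", "black"),
    color_genotype = c("fb", "bb", "b"),
    mt_haplogroup = c("northern", "northern", "southern"),
    period = "2014-2019",
    locality = c("A", "B", "C")
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# tiny snp_matrix built by hand: genotypes per site x sample
toy_snp_matrix <- function(gt, pos = seq_len(nrow(gt)) * 100,
                           contig = "c1", contig_len = 50000,
                           dp = 30, gq = 99, alt = NULL) {
  n <- nrow(gt)
  if (is.null(alt)) alt <- rep("T", n)
  snp_matrix(
    sites = data.frame(contig = rep_len(contig, n), pos = pos,
                       ref = rep("A", n), alt = alt),
    gt = gt,
    dp = matrix(dp, n, ncol(gt)),
    gq = matrix(gq, n, ncol(gt)),
    samples = paste0("s", seq_len(ncol(gt))),
    contig_lengths = stats::setNames(rep(contig_len, length(unique(rep_len(contig, n)))),
                                     unique(rep_len(contig, n)))
  )
}

# brute-force union of all minimum spanning trees by enumerating spanning
# trees on a small distance matrix (the exhaustive oracle for build_msn)
brute_force_msn_edges <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf
  in_some_mst <- rep(FALSE, m)
  combs <- utils::combn(m, n - 1)
  for (k in seq_len(ncol(combs))) {
    sel <- combs[, k]
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(pairs[sel, , drop = FALSE])))
    if (igraph::components(g)$no != 1) next
    w <- sum(d[pairs[sel, , drop = FALSE]])
    if (w < best - 1e-9) {
      best <- w
      in_some_mst <- rep(FALSE, m)
      in_some_mst[sel] <- TRUE
    } else if (abs(w - best) <= 1e-9) {
      in_some_mst[sel] <- TRUE
    }
  }
  cbind(pairs[in_some_mst, , drop = FALSE],
        w = d[pairs[in_some_mst, , drop = FALSE]])
}
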