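aln_from_strings <- function(strs) {
  m <- do.call(rbind, lapply(strs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(strs)
  m
}

test_that("haplotype collapsing merges identical sequences and honours IUPAC codes", {
  aln <- aln_from_strings(c(a = "ACGT", b = "ACGT", c = "ACTT", d = "ACRT"))
  h <- collapse_haplotypes(aln)
  expect_equal(sum(h$counts), 4)
  expect_equal(max(h$counts), 2)
  h2 <- collapse_haplotypes(aln, exclude_heterozygous = TRUE)
  expect_equal(h2$excluded, "d")
  expect_equal(sum(h2$counts), 3)
  # N acts as a wildcard when merging
  h3 <- collapse_haplotypes(aln_from_strings(c(a = "ACGT", b = "ACNT")))
  expect_equal(nrow(h3$haplotypes), 1)
  expect_error(collapse_haplotypes(matrix(character(0), 0, 0)), "empty")
})

test_that("heterozygote exclusion retains 81 of 89 colour-locus sequences", {
  set.seed(12)
  base <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  seqs <- matrix(rep(base, each = 89), nrow = 89)
  rownames(seqs) <- sprintf("s%02d", 1:89)
  het_rows <- sample(89, 8)
  for (r in het_rows) seqs[r, sample(30, 1)] <- "R"
  h <- collapse_haplotypes(seqs, exclude_heterozygous = TRUE)
  expect_equal(length(h$excluded), 8)
  expect_equal(sum(h$counts), 81)
})

test_that("site summary counts variable and parsimony-informative columns", {
  aln <- aln_from_strings(c(a = "AAAA", b = "AAAT", c = "AAAT", d = "AAAA"))
  expect_equal(site_summary(aln), list(n_variable = 1, n_parsimony_informative = 1))
  ident <- aln_from_strings(c(a = "ACGT", b = "ACGT"))
  expect_equal(site_summary(ident)$n_variable, 0)
  # singleton column is variable but not informative
  aln2 <- aln_from_strings(c(a = "AT", b = "AT", c = "CT"))
  expect_equal(site_summary(aln2), list(n_variable = 1, n_parsimony_informative = 0))
  set.seed(13)
  for (i in 1:10) {
    rnd <- matrix(sample(c("A", "C", "G", "T", "N", "-"), 60, replace = TRUE), 6)
    rownames(rnd) <- letters[1:6]
    ss <- site_summary(rnd)
    expect_lte(ss$n_parsimony_informative, ss$n_variable)
  }
})

test_that("p-distance divergence handles exclusions and symmetry", {
  a <- strsplit(paste(rep("A", 500), collapse = ""), "")[[1]]
  b <- a
  b[1:8] <- "C"
  expect_equal(pairwise_divergence(a, b), 1.6)
  expect_equal(pairwise_divergence(a, a), 0)
  expect_equal(pairwise_divergence(b, a), pairwise_divergence(a, b))
  # gaps and N removed pairwise from the denominator
  b2 <- b
  b2[9:108] <- "N"
  expect_equal(pairwise_divergence(a, b2), 100 * 8 / 400)
  expect_error(pairwise_divergence(rep("N", 5), rep("A", 5)), "comparable")
})

test_that("fixed differences require fixation in both groups", {
  aln <- aln_from_strings(c(n1 = "AAAA", n2 = "AAAA", s1 = "TTAA", s2 = "TTAA"))
  g <- c("N", "N", "S", "S")
  expect_equal(fixed_differences(aln, g, "N", "S"), 2)
  expect_equal(fixed_differences(aln, g, "N", "N"), 0)
  # one migrant copy of the other group's state breaks fixation
  aln2 <- aln_from_strings(c(n1 = "AAAA", n2 = "TAAA", s1 = "TTAA", s2 = "TTAA"))
  expect_equal(fixed_differences(aln2, g, "N", "S"), 1)
  expect_error(fixed_differences(aln, g, "N", "X"), "absent")
})

test_that("divergence time applies the molecular clock", {
  expect_equal(divergence_time(1.6, 1.5), 1.0667, tolerance = 1e-4)
  expect_gt(divergence_time(1.6, 1.5), 1)  # just over one million years
  expect_equal(divergence_time(0, 1.5), 0)
  expect_equal(divergence_time(3.0, 1.5), 2.0)
  expect_error(divergence_time(1.6, 0), "rate")
})

test_that("gap coding emits one character per distinct indel region", {
  gapfree <- aln_from_strings(c(a = "ACGT", b = "ACGT"))
  expect_equal(ncol(code_gaps(gapfree)), 0)
  one <- aln_from_strings(c(a = "A---T", b = "A---T", c = "ACGGT", d = "ACGGT"))
  g1 <- code_gaps(one)
  expect_equal(ncol(g1), 1)
  expect_equal(unname(g1[, 1]), c(1L, 1L, 0L, 0L))
  two <- aln_from_strings(c(a = "--CGGT", b = "ACCG--", c = "ACCGGT"))
  expect_equal(ncol(code_gaps(two)), 2)
})

test_that("minimum-spanning network keeps ties and drops dominated edges", {
  # chain: d(A,B)=1, d(B,C)=1, d(A,C)=2 -> AC excluded
  chain <- collapse_haplotypes(aln_from_strings(c(A = "AAA", B = "AAT", C = "ATT")))
  net <- build_msn(chain)
  expect_equal(nrow(net$edges), 2)
  expect_false(any(net$edges$d == 2))
  # equidistant triangle: all three edges retained (reticulation)
  tri <- collapse_haplotypes(aln_from_strings(c(A = "A", B = "C", C = "G")))
  expect_equal(nrow(build_msn(tri)$edges), 3)
  single <- collapse_haplotypes(aln_from_strings(c(A = "ACGT")))
  net1 <- build_msn(single)
  expect_equal(nrow(net1$edges), 0)
  expect_equal(nrow(net1$nodes), 1)
})

test_that("network edges match the exhaustive all-MST union on random instances", {
  set.seed(14)
  for (trial in 1:6) {
    n <- sample(4:7, 1)
    seqs <- matrix(sample(c("A", "C", "G", "T"), n * 12, replace = TRUE), n)
    rownames(seqs) <- paste0("h", seq_len(n))
    haps <- collapse_haplotypes(seqs)
    if (nrow(haps$haplotypes) < 3) next
    net <- build_msn(haps, include_gap_characters = FALSE)
    d <- net$distances
    oracle <- brute_force_msn_edges(d)
    got <- net$edges
    expect_equal(nrow(got), nrow(oracle))
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    idx <- match(got$from, rownames(d))
    jdx <- match(got$to, rownames(d))
    expect_setequal(key(idx, jdx), key(oracle[, 1], oracle[, 2]))
  }
})

test_that("alignment FASTA round trip preserves sequences", {
  cfg <- sim_config(n_specimens = 30)
  tab <- simulate_specimens(cfg, seed = 15)
  aln <- simulate_coi_alignment(tab, cfg, seed = 15)
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(unname(back), unname(aln[, seq_len(ncol(aln))]))
  expect_equal(rownames(back), rownames(aln))
})
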