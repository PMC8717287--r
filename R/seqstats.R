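IUPAC_HET <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read an aligned FASTA into a character matrix
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return uppercase character matrix, one row per sequence, rownames = ids.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dna)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(names(dna)))
  m
}

#' Write a character-matrix alignment as FASTA
#' @param aln character matrix as from [read_alignment()].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  ape::write.FASTA(ape::as.DNAbin(aln), path)
  invisible(path)
}

.check_alignment <- function(aln) {
  if (!is.matrix(aln) || nrow(aln) == 0) stop("empty alignment")
  if (is.null(rownames(aln))) rownames(aln) <- paste0("seq", seq_len(nrow(aln)))
  aln
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical over their mutually non-N sites are merged into one
#' haplotype (N is treated as a wildcard; each sequence joins the first
#' compatible haplotype in input order, and fills in sites the
#' representative had as N).  Sequences containing IUPAC heterozygous
#' ambiguity codes are dropped when `exclude_heterozygous` is set — these
#' are individuals with two haplotypes whose phase is unknown.
#'
#' @param aln character matrix alignment.
#' @param groups optional per-sequence group labels (haplogroup or colour
#'   form), recycled into per-haplotype composition counts.
#' @param exclude_heterozygous drop sequences with heterozygous codes.
#' @return list of class `haplotype_set`: `haplotypes` (representative
#'   matrix), `counts`, `members` (ids per haplotype), `groups` (composition
#'   tables), `excluded` (ids dropped as heterozygous).
#' @export
collapse_haplotypes <- function(aln, groups = NULL,
                                exclude_heterozygous = FALSE) {
  aln <- .check_alignment(aln)
  ids <- rownames(aln)
  if (!is.null(groups)) groups <- rep_len(groups, nrow(aln))
  excluded <- character(0)
  if (exclude_heterozygous) {
    het <- apply(aln, 1, function(s) any(s %in% IUPAC_HET))
    excluded <- ids[het]
    if (!is.null(groups)) groups <- groups[!het]
    aln <- aln[!het, , drop = FALSE]
    ids <- ids[!het]
  }
  if (nrow(aln) == 0) stop("no sequences left after heterozygote exclusion")
  reps <- list()
  members <- list()
  for (i in seq_len(nrow(aln))) {
    s <- aln[i, ]
    placed <- FALSE
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      comp <- s == "N" | r == "N" | s == r
      if (all(comp)) {
        fill <- r == "N" & s != "N"
        r[fill] <- s[fill]
        reps[[h]] <- r
        members[[h]] <- c(members[[h]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1]] <- s
      members[[length(members) + 1]] <- ids[i]
    }
  }
  hmat <- do.call(rbind, reps)
  rownames(hmat) <- paste0("H", seq_len(nrow(hmat)))
  comp <- NULL
  if (!is.null(groups)) {
    gmap <- stats::setNames(groups, ids)
    comp <- lapply(members, function(m) table(gmap[m]))
  }
  structure(
    list(haplotypes = hmat, counts = lengths(members), members = members,
         groups = comp, excluded = excluded),
    class = "haplotype_set"
  )
}

#' Variable and parsimony-informative site counts
#'
#' A site is variable if it carries at least two distinct states (gaps and
#' N excluded); parsimony-informative if at least two of those states are
#' each present in at least two sequences.
#'
#' @param aln character matrix alignment (>= 2 sequences).
#' @return list with `n_variable` and `n_parsimony_informative`.
#' @export
site_summary <- function(aln) {
  aln <- .check_alignment(aln)
  if (nrow(aln) < 2) stop("need at least two sequences")
  n_var <- 0L
  n_pi <- 0L
  for (j in seq_len(ncol(aln))) {
    states <- aln[, j]
    states <- states[!(states %in% c("N", "-"))]
    tab <- table(states)
    if (length(tab) >= 2) {
      n_var <- n_var + 1L
      if (sum(tab >= 2) >= 2) n_pi <- n_pi + 1L
    }
  }
  list(n_variable = n_var, n_parsimony_informative = n_pi)
}

#' Pairwise percent divergence (p-distance)
#'
#' Proportion of differing sites over sites where both sequences carry an
#' unambiguous base (gaps, N and ambiguity codes excluded pairwise),
#' expressed as a percentage.
#'
#' @param seqA,seqB character vectors (aligned, equal length).
#' @return percent divergence.
#' @export
pairwise_divergence <- function(seqA, seqB) {
  if (length(seqA) != length(seqB)) stop("sequences must be aligned (equal length)")
  ok <- seqA %in% c("A", "C", "G", "T") & seqB %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites between sequences")
  100 * sum(seqA[ok] != seqB[ok]) / sum(ok)
}

#' Fixed differences between two groups
#'
#' Sites where all members of group A share one state and all members of
#' group B share a different state; members with N or a gap at the site are
#' ignored there.
#'
#' @param aln character matrix alignment.
#' @param groups per-sequence group labels.
#' @param groupA,groupB the two labels to compare.
#' @return count of fixed differences.
#' @export
fixed_differences <- function(aln, groups, groupA, groupB) {
  aln <- .check_alignment(aln)
  groups <- rep_len(groups, nrow(aln))
  if (!groupA %in% groups || !groupB %in% groups) {
    stop("group label absent from alignment")
  }
  a <- aln[groups == groupA, , drop = FALSE]
  b <- aln[groups == groupB, , drop = FALSE]
  n_fixed <- 0L
  for (j in seq_len(ncol(aln))) {
    sa <- unique(a[, j]); sa <- sa[!(sa %in% c("N", "-"))]
    sb <- unique(b[, j]); sb <- sb[!(sb %in% c("N", "-"))]
    if (length(sa) == 1 && length(sb) == 1 && sa != sb) n_fixed <- n_fixed + 1L
  }
  n_fixed
}

#' Divergence time from percent divergence and a molecular clock
#'
#' @param divergence_percent pairwise divergence, percent.
#' @param rate_percent_per_myr clock rate, percent per million years
#'   (1.5 for the standard insect COI clock).
#' @return time in millions of years.
#' @export
divergence_time <- function(divergence_percent, rate_percent_per_myr = 1.5) {
  if (rate_percent_per_myr <= 0) stop("rate must be > 0")
  divergence_percent / rate_percent_per_myr
}

#' Simple indel coding of alignment gaps
#'
#' Each maximal gap run with a distinct (start, end) across the alignment
#' becomes one binary presence/absence character: a sequence scores 1 if it
#' carries a gap run with exactly those boundaries.
#'
#' @param aln character matrix alignment.
#' @return binary matrix, sequences x gap characters (0 columns if gap-free);
#'   column names encode the region as `gap<start>_<end>`.
#' @export
code_gaps <- function(aln) {
  aln <- .check_alignment(aln)
  runs_per_seq <- lapply(seq_len(nrow(aln)), function(i) {
    r <- rle(aln[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cbind(start = starts[r$values], end = ends[r$values])
  })
  all_runs <- unique(do.call(rbind, runs_per_seq))
  if (is.null(all_runs) || nrow(all_runs) == 0) {
    return(matrix(0L, nrow(aln), 0, dimnames = list(rownames(aln), NULL)))
  }
  all_runs <- all_runs[order(all_runs[, 1], all_runs[, 2]), , drop = FALSE]
  out <- matrix(0L, nrow(aln), nrow(all_runs),
                dimnames = list(rownames(aln),
                                paste0("gap", all_runs[, 1], "_", all_runs[, 2])))
  for (i in seq_len(nrow(aln))) {
    runs <- runs_per_seq[[i]]
    if (nrow(runs) == 0) next
    for (k in seq_len(nrow(runs))) {
      hit <- all_runs[, 1] == runs[k, 1] & all_runs[, 2] == runs[k, 2]
      out[i, hit] <- 1L
    }
  }
  out
}

# Hamming distance between haplotypes: differing unambiguous substitution
# sites plus differing gap characters (one indel = one step)
.haplotype_distances <- function(hmat, gap_chars) {
  n <- nrow(hmat)
  d <- matrix(0, n, n, dimnames = list(rownames(hmat), rownames(hmat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- hmat[i, ]; b <- hmat[j, ]
      ok <- a != "N" & b != "N" & a != "-" & b != "-"
      steps <- sum(a[ok] != b[ok])
      if (!is.null(gap_chars) && ncol(gap_chars) > 0) {
        steps <- steps + sum(gap_chars[i, ] != gap_chars[j, ])
      }
      d[i, j] <- d[j, i] <- steps
    }
  }
  d
}

#' Minimum-spanning haplotype network
#'
#' Builds the union of all minimum spanning trees over haplotypes under
#' Hamming distance (substitution steps plus gap-coded indel steps); tied
#' alternative connections are retained, giving the reticulations a
#' statistical-parsimony (TCS-style) network would show at low divergence.
#' An edge of weight d belongs to some minimum spanning tree exactly when
#' its endpoints are not already connected by edges of strictly smaller
#' weight.
#'
#' @param haps a `haplotype_set` from [collapse_haplotypes()].
#' @param include_gap_characters add gap-coded indel characters to the
#'   distance (one step per indel).
#' @return list of class `haplotype_network`: `nodes` (data.frame with
#'   haplotype, count), `edges` (data.frame with from, to, d,
#'   intermediate_steps = d - 1), `distances`, `groups`.
#' @export
build_msn <- function(haps, include_gap_characters = TRUE) {
  hmat <- haps$haplotypes
  n <- nrow(hmat)
  nodes <- data.frame(haplotype = rownames(hmat), count = as.integer(haps$counts))
  if (n == 1) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             d = numeric(0),
                                             intermediate_steps = numeric(0)),
                          distances = matrix(0, 1, 1), groups = haps$groups),
                     class = "haplotype_network"))
  }
  gap_chars <- if (include_gap_characters) code_gaps(hmat) else NULL
  d <- .haplotype_distances(hmat, gap_chars)

  pairs <- which(upper.tri(d), arr.ind = TRUE)
  wt <- d[pairs]
  ord <- order(wt)
  pairs <- pairs[ord, , drop = FALSE]
  wt <- wt[ord]

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  keep <- logical(nrow(pairs))
  for (w in unique(wt)) {
    idx <- which(wt == w)
    # membership in the graph of strictly smaller edges decides MST membership
    comp <- igraph::components(g)$membership
    for (k in idx) {
      keep[k] <- comp[pairs[k, 1]] != comp[pairs[k, 2]]
    }
    kept_now <- idx[keep[idx]]
    if (length(kept_now) > 0) {
      g <- igraph::add_edges(g, as.vector(t(pairs[kept_now, , drop = FALSE])))
    }
  }
  edges <- data.frame(
    from = rownames(hmat)[pairs[keep, 1]],
    to = rownames(hmat)[pairs[keep, 2]],
    d = wt[keep],
    intermediate_steps = pmax(wt[keep] - 1, 0)
  )
  structure(list(nodes = nodes, edges = edges, distances = d,
                 groups = haps$groups),
            class = "haplotype_network")
}

#' Write a haplotype network as an edge-list TSV
#' @param net a `haplotype_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
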