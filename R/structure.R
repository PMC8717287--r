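#' Allele-sharing genotype distance
#'
#' Mean over non-missing sites of |dosage_i - dosage_j| / 2, giving 0 for
#' identical samples and 1 for opposite homozygotes at every site.
#'
#' @param m a `snp_matrix`.
#' @return symmetric distance matrix with zero diagonal (class `matrix`).
#' @export
genotype_distance <- function(m) {
  if (length(m$samples) < 2) stop("need at least two samples")
  g <- m$gt
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(m$samples, m$samples))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(ok)) stop("samples ", m$samples[i], " and ", m$samples[j],
                         " share no genotyped sites")
      d[i, j] <- d[j, i] <- mean(abs(g[ok, i] - g[ok, j])) / 2
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.  Ties in
#' Q are broken towards the smallest (i, j) index pair, so input order
#' determines tie resolution deterministically.  Negative branch lengths
#' are clamped to zero with the deficit transferred to the sibling edge.
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param outgroup optional sample id to root the tree on.
#' @return an `ape::phylo` tree (unrooted unless `outgroup` given).
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbour joining needs at least 3 samples")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # active nodes: tip numbers 1..n, internal nodes numbered n+1 ...
  active <- seq_len(n)
  next_node <- 2L * n - 2L  # internal ids count down from the ape root id
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  node_id <- seq_len(n)
  Dm <- d

  while (length(active) > 2) {
    r <- length(active)
    rs <- rowSums(Dm)
    # Studier-Keppler criterion
    Q <- (r - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- Dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    # clamp-and-transfer for negative branch lengths
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_id <- next_node
    next_node <- next_node - 1L
    edges <- rbind(edges, c(new_id, node_id[i]), c(new_id, node_id[j]))
    lens <- c(lens, li, lj)
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    Dm <- Dm[-c(i, j), -c(i, j), drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    node_id <- c(node_id[-c(i, j)], new_id)
    active <- active[-1]
  }
  # connect the final two nodes
  edges <- rbind(edges, c(node_id[2], node_id[1]))
  lens <- c(lens, Dm[1, 2])

  # internal ids were assigned counting down from 2n-2, so they already
  # occupy n+1 .. 2n-2 with the final join (the root) at n+1, as ape expects
  tree <- structure(
    list(edge = matrix(as.integer(edges), ncol = 2), edge.length = lens,
         tip.label = labels, Nnode = n - 2L),
    class = "phylo"
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (!is.null(outgroup)) tree <- ape::root(tree, outgroup, resolve.root = TRUE)
  tree
}

#' Left-to-right LD pruning
#'
#' Scans sites in (contig, position) order; for each retained site, later
#' sites within `window` bp on the same contig whose squared dosage
#' correlation with it exceeds `r2_max` are dropped.  No retained pair
#' violates the bound (r-squared of exactly `r2_max` is kept: the rule is a
#' strict inequality).
#'
#' @param m a `snp_matrix` with sites sorted by contig and position.
#' @param r2_max maximum allowed squared correlation (exclusive).
#' @param window window size in bp.
#' @return pruned `snp_matrix` with `attr(, "removed_sites")`.
#' @export
ld_prune <- function(m, r2_max = 0.5, window = 5000) {
  n0 <- n_sites(m)
  keep <- rep(TRUE, n0)
  contig <- m$sites$contig
  pos <- m$sites$pos
  for (i in seq_len(n0)) {
    if (!keep[i]) next
    j <- i + 1
    while (j <= n0 && contig[j] == contig[i] && pos[j] - pos[i] <= window) {
      if (keep[j]) {
        r <- suppressWarnings(stats::cor(m$gt[i, ], m$gt[j, ],
                                         use = "pairwise.complete.obs"))
        # strict inequality with an epsilon so r2 == r2_max survives
        # floating-point noise in the correlation
        if (!is.na(r) && r^2 > r2_max + 1e-9) keep[j] <- FALSE
      }
      j <- j + 1
    }
  }
  m <- snp_subset(m, keep)
  attr(m, "removed_sites") <- n0 - n_sites(m)
  m
}

#' Principal components of the genotype matrix
#'
#' Column-centred dosage matrix (samples x sites) decomposed by
#' eigendecomposition of the sample covariance.  Scores carry a
#' deterministic sign convention: within each component the
#' largest-magnitude loading is positive.
#'
#' @param m a `snp_matrix` with no missing data (run the filters first).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained_variance`,
#'   `proportion_variance`.
#' @export
snp_pca <- function(m, n_components = 2) {
  x <- t(m$gt)
  if (any(is.na(x))) stop("PCA requires a complete matrix; filter missing data first")
  x <- scale(x, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(x, center = FALSE)
  rank <- sum(pc$sdev^2 > 1e-12)
  if (n_components > rank) stop("requested more components than matrix rank (", rank, ")")
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    if (rot[which.max(abs(rot[, k])), k] < 0) scores[, k] <- -scores[, k]
  }
  ev <- pc$sdev[seq_len(n_components)]^2
  list(scores = scores, explained_variance = ev,
       proportion_variance = ev / sum(pc$sdev^2))
}

# one weighted multiplicative-update NMF run on X (samples x sites, dosage
# fractions in [0, 1]) with observation weights Wt (0 for held-out
# entries); Q rows on the simplex.  The updates are the EM form for the
# binomial admixture likelihood: because Q rows sum to one, 1 - QG equals
# Q(1-G), and the updates multiply each factor by the ratio of its
# expected allele-count responsibilities.
.nmf_run <- function(X, K, Wt, max_iter = 500, tol = 1e-6, pseudocount = 0.5) {
  n <- nrow(X); p <- ncol(X)
  Q <- matrix(stats::runif(n * K, 0.1, 1), n, K)
  Q <- Q / rowSums(Q)
  G <- matrix(stats::runif(K * p, 0.2, 0.8), K, p)
  eps <- 1e-9
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    P <- pmin(pmax(Q %*% G, eps), 1 - eps)
    A <- Wt * X / P            # responsibility weight for the allele
    B <- Wt * (1 - X) / (1 - P)  # and for the reference allele
    Q <- Q * (A %*% t(G) + B %*% t(1 - G))
    Q <- pmax(Q, eps)
    Q <- Q / rowSums(Q)
    P <- pmin(pmax(Q %*% G, eps), 1 - eps)
    num <- G * (t(Q) %*% (Wt * X / P))
    den <- num + (1 - G) * (t(Q) %*% (Wt * (1 - X) / (1 - P)))
    # beta-style pseudo-count keeps ancestral frequencies off the 0/1
    # boundary, where a single held-out allele would dominate the
    # cross-entropy
    G <- (num + pseudocount) / pmax(den + 2 * pseudocount, eps)
    G <- pmin(pmax(G, eps), 1 - eps)
    P <- pmin(pmax(Q %*% G, eps), 1 - eps)
    obj <- -sum(Wt * (X * log(P) + (1 - X) * log(1 - P)))
    if (!is.finite(obj) || abs(obj_old - obj) < tol * (abs(obj_old) + eps)) break
    obj_old <- obj
  }
  list(Q = Q, G = G)
}

# binomial cross-entropy of held-out dosage fractions under predictions P
.masked_cross_entropy <- function(X, P, mask) {
  P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
  -mean(X[mask] * log(P[mask]) + (1 - X[mask]) * log(1 - P[mask]))
}

#' sNMF-like ancestry estimation by masked NMF
#'
#' Factorises the dosage/2 matrix (samples x sites, entries in \[0, 1\]) as
#' Q G with per-sample ancestry proportions Q on the simplex and ancestral
#' allele frequencies G in \[0, 1\], by weighted multiplicative updates.
#' For each K a random 5% of entries is held out; cross-entropy of the
#' hold-out predicted by Q G scores the fit, the best of `n_restarts`
#' random restarts is kept per K, and the K minimising the mean restart
#' cross-entropy is selected.
#'
#' @param m a `snp_matrix` with no missing data.
#' @param K_range integer vector of K values to evaluate.
#' @param n_restarts independent restarts per K.
#' @param masked_fraction fraction of entries held out for cross-entropy.
#' @param max_iter,tol multiplicative-update controls.
#' @param pseudocount beta-style prior count regularising the ancestral
#'   frequencies away from 0 and 1.
#' @param seed RNG seed.
#' @return `ancestry_result`: list with `selected_K`, `Q` (for the selected
#'   K, best restart), `cross_entropy` (data.frame K x mean/min), `runs`
#'   (per-K best Q matrices).
#' @export
nmf_admixture <- function(m, K_range = 1:10, n_restarts = 10,
                          masked_fraction = 0.05, max_iter = 500,
                          tol = 1e-6, pseudocount = 0.5, seed = 1) {
  X <- t(m$gt) / 2
  if (any(is.na(X))) stop("admixture estimation requires a complete matrix")
  n <- nrow(X)
  if (max(K_range) > n) stop("K cannot exceed the number of samples")
  set.seed(seed)
  mask <- matrix(stats::runif(length(X)) < masked_fraction, nrow(X))
  if (!any(mask)) mask[sample(length(mask), 1)] <- TRUE
  Wt <- 1 - mask

  ce_mean <- numeric(length(K_range))
  ce_min <- numeric(length(K_range))
  best_Q <- vector("list", length(K_range))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    ces <- numeric(n_restarts)
    qs <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      fit <- .nmf_run(X, K, Wt, max_iter = max_iter, tol = tol,
                      pseudocount = pseudocount)
      P <- fit$Q %*% fit$G
      ces[r] <- .masked_cross_entropy(X, P, mask)
      qs[[r]] <- fit$Q
    }
    ce_mean[ki] <- mean(ces)
    ce_min[ki] <- min(ces)
    best_Q[[ki]] <- qs[[which.min(ces)]]
    rownames(best_Q[[ki]]) <- m$samples
  }
  sel <- K_range[which.min(ce_mean)]
  structure(
    list(selected_K = sel,
         Q = best_Q[[which.min(ce_mean)]],
         cross_entropy = data.frame(K = K_range, mean = ce_mean, min = ce_min),
         runs = stats::setNames(best_Q, paste0("K", K_range)),
         seed = seed),
    class = "ancestry_result"
  )
}

#' Per-sample input for the nuclear ancestry cline
#'
#' Pairs each genomic sample's transect position with its assigned-cluster
#' ancestry proportion, for Gaussian cline fitting.
#'
#' @param result an `ancestry_result` with a K = 2 `Q` matrix (or a Q for
#'   the requested K in `runs`).
#' @param table a `specimen_table` containing every sample id.
#' @param cluster which ancestry cluster's proportion to emit (column of Q).
#' @return data.frame with `id`, `x` (transect km), `q` (proportion).
#' @export
nuclear_cline_input <- function(result, table, cluster = 2) {
  Q <- result$Q
  if (ncol(Q) < cluster) stop("requested cluster exceeds K")
  ids <- rownames(Q)
  pos <- match(ids, table$id)
  if (any(is.na(pos))) {
    stop("sample(s) not in specimen table: ",
         paste(ids[is.na(pos)], collapse = ", "))
  }
  data.frame(id = ids, x = table$transect_km[pos], q = Q[, cluster])
}
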