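#' Construct a SNP genotype matrix
#'
#' Genotypes are stored as alternate-allele dosages (0 = hom-ref, 1 = het,
#' 2 = hom-alt, NA = missing), one row per site and one column per sample,
#' with per-call depth and genotype quality alongside.
#'
#' @param sites data.frame with `contig`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multiallelic sites).
#' @param gt integer dosage matrix, sites x samples.
#' @param dp,gq depth and genotype-quality matrices, same shape as `gt`.
#' @param samples sample ids (column names).
#' @param sample_groups optional named vector of group labels per sample
#'   (e.g. mt haplogroup).
#' @param contig_lengths named vector of contig lengths in bp.
#' @return object of class `snp_matrix`.
#' @export
snp_matrix <- function(sites, gt, dp = NULL, gq = NULL, samples = colnames(gt),
                       sample_groups = NULL, contig_lengths = NULL) {
  sites <- as.data.frame(sites)
  stopifnot(nrow(sites) == nrow(gt))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(gt), ncol(gt))
  colnames(gt) <- samples
  sites$biallelic <- !grepl(",", sites$alt)
  # positions must strictly increase within each contig
  for (ctg in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ctg]
    if (any(diff(p) <= 0)) stop("positions must strictly increase within contig ", ctg)
  }
  structure(
    list(sites = sites, gt = gt, dp = dp, gq = gq, samples = samples,
         sample_groups = sample_groups, contig_lengths = contig_lengths),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d sites x %d samples on %d contig(s)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$contig))))
  invisible(x)
}

#' Subset a SNP matrix by site index
#' @param m a `snp_matrix`.
#' @param idx logical or integer site index.
#' @return the subset `snp_matrix`.
#' @export
snp_subset <- function(m, idx) {
  m$sites <- m$sites[idx, , drop = FALSE]
  m$gt <- m$gt[idx, , drop = FALSE]
  m$dp <- m$dp[idx, , drop = FALSE]
  m$gq <- m$gq[idx, , drop = FALSE]
  rownames(m$sites) <- NULL
  m
}

#' Number of sites in a SNP matrix
#' @param m a `snp_matrix`.
#' @return site count.
#' @export
n_sites <- function(m) nrow(m$sites)

.gt_string <- function(d) {
  out <- rep(".", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 1] <- "0/1"
  out[!is.na(d) & d == 2] <- "1/1"
  out
}

#' Write a SNP matrix as VCF
#'
#' Minimal VCF 4.2 with GT:DP:GQ fields and contig-length header lines,
#' written through vcfR (output is bgzip-compressed, extension `.vcf.gz`).
#'
#' @param m a `snp_matrix`.
#' @param path output path (`.vcf.gz`).
#' @export
write_snp_vcf <- function(m, path) {
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>",
            names(m$contig_lengths), as.integer(m$contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">"
  )
  fix <- cbind(
    CHROM = m$sites$contig, POS = as.character(m$sites$pos),
    ID = ".", REF = m$sites$ref, ALT = m$sites$alt,
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  gt_cols <- vapply(seq_along(m$samples), function(j) {
    paste(.gt_string(m$gt[, j]),
          ifelse(is.na(m$dp[, j]), ".", as.character(m$dp[, j])),
          ifelse(is.na(m$gq[, j]), ".", as.character(m$gq[, j])),
          sep = ":")
  }, character(nrow(m$sites)))
  if (nrow(m$sites) == 1) gt_cols <- matrix(gt_cols, nrow = 1)
  gt <- cbind(FORMAT = "GT:DP:GQ", gt_cols)
  colnames(gt) <- c("FORMAT", m$samples)
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a VCF into a SNP matrix
#'
#' @param path VCF path (plain or gzipped); contig lengths are taken from
#'   the `##contig` header lines.
#' @param sample_groups optional named group labels.
#' @return a `snp_matrix`.
#' @export
read_snp_vcf <- function(path, sample_groups = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_real_, nrow(gt_chr), ncol(gt_chr),
                   dimnames = dimnames(gt_chr))
  clean <- gsub("\\|", "/", gt_chr)
  dosage[clean %in% c("0/0")] <- 0
  dosage[clean %in% c("0/1", "1/0")] <- 1
  dosage[clean %in% c("1/1")] <- 2
  dp <- suppressWarnings(
    matrix(as.numeric(vcfR::extract.gt(v, element = "DP")),
           nrow(gt_chr), dimnames = dimnames(gt_chr)))
  gq <- suppressWarnings(
    matrix(as.numeric(vcfR::extract.gt(v, element = "GQ")),
           nrow(gt_chr), dimnames = dimnames(gt_chr)))
  contig_meta <- grep("^##contig", v@meta, value = TRUE)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contig_meta)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig_meta)))
  contig_lengths <- stats::setNames(lens, ids)
  sites <- data.frame(
    contig = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
    ref = vcfR::getREF(v), alt = vcfR::getALT(v)
  )
  snp_matrix(sites, dosage, dp, gq, samples = colnames(gt_chr),
             sample_groups = sample_groups,
             contig_lengths = if (length(contig_lengths)) contig_lengths else NULL)
}

#' Read a BED file of exclusion intervals
#'
#' BED is 0-based half-open on disk; intervals are converted to the 1-based
#' closed convention used internally (matching VCF positions).  An optional
#' fourth column is read as the tier label.
#'
#' @param path BED path.
#' @param tier default tier when the file has no name column.
#' @return data.frame with `contig`, `start`, `end` (1-based closed), `tier`.
#' @export
read_bed <- function(path, tier = "annotation") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(
    contig = bed[[1]],
    start = bed[[2]] + 1L,
    end = bed[[3]],
    tier = if (ncol(bed) >= 4) bed[[4]] else tier
  )
  if (any(out$start > out$end)) stop("invalid BED interval (start > end)")
  out
}

#' Write 1-based closed intervals as BED (0-based half-open)
#' @param intervals data.frame with `contig`, `start`, `end`, optional `tier`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(
    contig = intervals$contig,
    start = intervals$start - 1L,
    end = intervals$end,
    tier = if ("tier" %in% names(intervals)) intervals$tier else "."
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
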