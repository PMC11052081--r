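#' Construct an ASV experiment
#'
#' @param counts integer matrix, ASVs as rows and samples as columns (row and
#'   column names required).
#' @param taxonomy data.frame with columns \code{asv}, \code{domain},
#'   \code{phylum}, \code{class} covering every ASV, or \code{NULL}.
#' @param metadata data.frame with a \code{sample_id} column covering every
#'   sample, or \code{NULL}.
#' @return an \linkS4class{AsvExperiment}.
#' @export
asvExperiment <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV row names and sample column names")
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    miss <- setdiff(rownames(counts), taxonomy$asv)
    if (length(miss))
      stop("taxonomy lacks entries for ASV(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    i <- match(rownames(counts), taxonomy$asv)
    rd <- DataFrame(domain = taxonomy$domain[i], phylum = taxonomy$phylum[i],
                    class = taxonomy$class[i], row.names = rownames(counts))
  }
  cd <- DataFrame(row.names = colnames(counts))
  if (!is.null(metadata)) {
    miss <- setdiff(colnames(counts), metadata$sample_id)
    if (length(miss))
      stop("metadata lacks entries for sample(s): ",
           paste(miss, collapse = ", "))
    i <- match(colnames(counts), metadata$sample_id)
    cd <- DataFrame(metadata[i, setdiff(names(metadata), "sample_id"),
                             drop = FALSE],
                    row.names = colnames(counts))
  }
  methods::new("AsvExperiment",
               SummarizedExperiment(assays = list(counts = counts),
                                    rowData = rd, colData = cd))
}

#' Load an ASV table, taxonomy and sample metadata from disk
#'
#' The ASV table is a TSV with samples as rows and ASVs as columns (set
#' \code{transposed = TRUE} for the ASVs-as-rows dialect); taxonomy is a TSV
#' with columns \code{asv}, \code{domain}, \code{phylum}, \code{class};
#' metadata a CSV with \code{sample_id} plus arbitrary columns (typically
#' \code{trench}, \code{layer}, \code{depth_m}, temperature, salinity and
#' nutrients).
#'
#' @param path,taxonomyPath,metadataPath file paths (taxonomy and metadata
#'   optional).
#' @param transposed whether the table stores ASVs as rows.
#' @return an \linkS4class{AsvExperiment}.
#' @export
loadAsvTable <- function(path, taxonomyPath = NULL, metadataPath = NULL,
                         transposed = FALSE) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!transposed) m <- t(m)
  tax <- if (!is.null(taxonomyPath))
    utils::read.delim(taxonomyPath, stringsAsFactors = FALSE)
  meta <- if (!is.null(metadataPath))
    utils::read.csv(metadataPath, stringsAsFactors = FALSE)
  asvExperiment(m, tax, meta)
}

setMethod("show", "AsvExperiment", function(object) {
  cat("AsvExperiment:", nrow(object), "ASVs x", ncol(object), "samples\n")
  if ("domain" %in% names(rowData(object))) {
    tb <- table(rowData(object)$domain)
    cat("  domains:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

#' Relative abundance
#'
#' Scales each sample's counts to proportions (columns sum to 1).
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @return a numeric matrix, ASVs as rows, samples as columns.
#' @export
setMethod("relativeAbundance", "AsvExperiment", function(x) {
  cnt <- assay(x, "counts")
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("zero-sum sample(s): ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  sweep(cnt, 2, tot, "/")
})

#' Per-sample Shannon diversity and Pielou evenness
#'
#' \eqn{H = -\sum p \ln p} over each sample's nonzero ASV proportions, and
#' \eqn{E = H / \ln S_{obs}} with \eqn{S_{obs}} the number of ASVs observed in
#' that sample (\code{NA} when a sample holds a single ASV).
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @return a data.frame with \code{sample_id}, \code{shannon},
#'   \code{evenness}, \code{observed}.
#' @export
setMethod("shannonEvenness", "AsvExperiment", function(x) {
  p <- relativeAbundance(x)
  H <- apply(p, 2, shannonIndex)
  S <- colSums(p > 0)
  E <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(sample_id = colnames(p), shannon = unname(H),
             evenness = unname(E), observed = unname(S))
})

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})},
#' computed on relative abundances by default.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param relative compute on relative abundances (default) or raw counts.
#' @return a \code{dist} over samples.
#' @export
setMethod("brayCurtis", "AsvExperiment", function(x, relative = TRUE) {
  m <- if (relative) relativeAbundance(x) else assay(x, "counts")
  vegan::vegdist(t(m), method = "bray")
})

.allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- vector("list", 0L)
  for (i in seq_along(v))
    out <- c(out, lapply(.allPerms(v[-i]), function(p) c(v[i], p)))
  out
}

.anosimR <- function(rk, between, M) {
  (mean(rk[between]) - mean(rk[!between])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities:
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with \eqn{M = n(n-1)/2} ranked
#' dissimilarities (midranks for ties). The p-value uses the add-one
#' permutation estimator \eqn{p = (1 + \#\{R^* \ge R\}) / (1 + n_{perm})};
#' with \code{exact = TRUE} all label permutations are enumerated instead
#' (feasible for small n) and \eqn{p = \#\{R^* \ge R\} / n!}, the identity
#' permutation included.
#'
#' @param d a \code{dist} or symmetric dissimilarity matrix.
#' @param groups group labels, one per sample; at least two groups with at
#'   least two members each.
#' @param nPerm number of label permutations (ignored when exact).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all label permutations.
#' @return list with \code{statistic} (R), \code{p_value}, \code{n_perm}.
#' @export
anosimTest <- function(d, groups, nPerm = 999L, seed = NULL, exact = FALSE) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3L) stop("ANOSIM needs at least 3 samples")
  if (length(groups) != n) stop("groups must match the number of samples")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L))
    stop("singleton group(s): ",
         paste(names(which(table(groups) < 2L)), collapse = ", "))
  lower <- lower.tri(m)
  dv <- m[lower]
  rk <- rank(dv)                       # midranks
  M <- n * (n - 1) / 2
  pair_i <- row(m)[lower]
  pair_j <- col(m)[lower]
  Rstat <- function(g)
    .anosimR(rk, g[pair_i] != g[pair_j], M)
  obs <- Rstat(groups)
  if (exact) {
    if (n > 9L) stop("exact enumeration limited to n <= 9")
    perms <- .allPerms(seq_len(n))
    Rs <- vapply(perms, function(ix) Rstat(groups[ix]), 0)
    p <- sum(Rs >= obs - 1e-12) / length(Rs)
    nP <- length(Rs)
  } else {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    Rs <- vapply(seq_len(nPerm), function(b) Rstat(sample(groups)), 0)
    p <- (1 + sum(Rs >= obs - 1e-12)) / (1 + nPerm)
    nP <- nPerm
  }
  list(statistic = obs, p_value = p, n_perm = nP)
}
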