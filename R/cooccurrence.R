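#' Select the most abundant ASVs
#'
#' Ranks ASVs by their total relative abundance across samples (sum of
#' per-sample proportions) and keeps the top \code{k}; ties are broken
#' lexicographically by ASV id so the selection is deterministic. When
#' \code{k} exceeds the number of ASVs, all are kept with a warning.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param k number of ASVs to keep (default 200).
#' @return an \linkS4class{AsvExperiment} restricted to the selected ASVs.
#' @export
setMethod("selectTopAsvs", "AsvExperiment", function(x, k = 200L) {
  if (!nrow(x)) stop("empty ASV table")
  if (k > nrow(x)) {
    warning("k = ", k, " exceeds the ", nrow(x), " available ASVs; keeping all")
    k <- nrow(x)
  }
  tot <- rowSums(relativeAbundance(x))
  ord <- order(-tot, rownames(x))
  x[sort(ord[seq_len(k)]), ]
})

.spearmanP <- function(rho, n) {
  p <- matrix(0, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  off <- row(rho) != col(rho)
  r <- rho[off]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pv[abs(r) >= 1 - 1e-12] <- 0
  p[off] <- pmin(pv, 1)
  p
}

#' Pairwise Spearman correlations with p-values
#'
#' Midrank-tie Spearman \eqn{\rho} between all pairs of ASVs, computed on
#' relative abundances. Two-sided p-values come from the t-distribution
#' approximation with \eqn{n-2} degrees of freedom
#' (\code{pMethod = "exact"} enumerates all sample permutations instead;
#' feasible for \eqn{n \le 8}). Zero-variance ASVs are excluded (their rank
#' correlation is undefined) and reported in the result.
#'
#' @param x an \linkS4class{AsvExperiment} (at least 4 samples) or a numeric
#'   matrix with variables as rows.
#' @param ... passed through to the matrix method.
#' @param pMethod \code{"t"} (default) or \code{"exact"}.
#' @return list with \code{rho} and \code{p} matrices, sample size \code{n},
#'   and \code{excluded} (ids of constant ASVs).
#' @name spearmanMatrix
NULL

#' @rdname spearmanMatrix
#' @export
setMethod("spearmanMatrix", "AsvExperiment", function(x, ...) {
  spearmanMatrix(relativeAbundance(x), ...)
})

#' @rdname spearmanMatrix
#' @export
setMethod("spearmanMatrix", "matrix", function(x, pMethod = c("t", "exact"),
                                               ...) {
  pMethod <- match.arg(pMethod)
  n <- ncol(x)
  if (n < 4L) stop("need at least 4 samples for correlation")
  v <- apply(x, 1, stats::var)
  excluded <- rownames(x)[v == 0]
  x <- x[v > 0, , drop = FALSE]
  if (!nrow(x)) stop("all ASVs are constant across samples")
  rho <- stats::cor(t(x), method = "spearman")
  if (pMethod == "t") {
    p <- .spearmanP(rho, n)
  } else {
    if (n > 8L) stop("exact permutation p limited to n <= 8 samples")
    perms <- .allPerms(seq_len(n))
    p <- matrix(0, nrow(x), nrow(x), dimnames = dimnames(rho))
    for (i in seq_len(nrow(x) - 1L)) for (j in seq(i + 1L, nrow(x))) {
      robs <- rho[i, j]
      rs <- vapply(perms, function(ix)
        stats::cor(x[i, ], x[j, ix], method = "spearman"), 0)
      p[i, j] <- p[j, i] <- mean(abs(rs) >= abs(robs) - 1e-12)
    }
  }
  list(rho = rho, p = p, n = n, excluded = excluded)
})

#' Benjamini-Hochberg FDR adjustment over a p-value matrix
#'
#' Applies the step-up BH adjustment to the strict upper triangle of a
#' symmetric p-value matrix (each ASV pair tested once) and mirrors the
#' result; the vector form adjusts a plain vector. Backed by
#' \code{stats::p.adjust}.
#'
#' @param p a symmetric p-value matrix or a numeric vector, values in [0, 1].
#' @return adjusted p-values in the same shape.
#' @export
adjustFdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (is.matrix(p)) {
    up <- upper.tri(p)
    adj <- p
    adj[up] <- stats::p.adjust(p[up], method = "BH")
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    return(adj)
  }
  stats::p.adjust(p, method = "BH")
}

#' Build a co-occurrence network from correlation and significance matrices
#'
#' Keeps an undirected edge between two ASVs when both gates pass:
#' \eqn{|\rho|} strictly above \code{rThreshold} AND FDR-adjusted p strictly
#' below \code{alpha}. Edge sign is the sign of \eqn{\rho}. Isolated nodes are
#' retained (flagged by the \code{isolated} vertex attribute).
#'
#' @param rho,pAdj conformable symmetric matrices with shared ASV names.
#' @param taxonomy data.frame with columns \code{asv}, \code{domain},
#'   \code{phylum}, \code{class} covering every node.
#' @param rThreshold correlation-strength gate (default 0.6).
#' @param alpha FDR significance gate (default 0.05).
#' @return a \linkS4class{CoocNetwork} (partition and modularity unset; see
#'   [networkModularity()]).
#' @export
buildNetwork <- function(rho, pAdj, taxonomy, rThreshold = 0.6,
                         alpha = 0.05) {
  if (!identical(dim(rho), dim(pAdj)))
    stop("rho and pAdj must be conformable")
  ids <- rownames(rho)
  miss <- setdiff(ids, taxonomy$asv)
  if (length(miss))
    stop("taxonomy lacks entries for node(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  up <- which(upper.tri(rho) & abs(rho) > rThreshold & pAdj < alpha,
              arr.ind = TRUE)
  el <- data.frame(source = ids[up[, 1]], target = ids[up[, 2]],
                   rho = rho[up], sign = sign(rho[up]), p_adj = pAdj[up])
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = ids))
  ti <- match(ids, taxonomy$asv)
  igraph::V(g)$domain <- taxonomy$domain[ti]
  igraph::V(g)$phylum <- taxonomy$phylum[ti]
  igraph::V(g)$class <- taxonomy$class[ti]
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  net <- methods::new("CoocNetwork", graph = g, partition = integer(0),
                      modularityQ = NA_real_, signSummary = data.frame(),
                      params = list(rThreshold = rThreshold, alpha = alpha))
  net@signSummary <- edgeSignSummary(net)
  net
}

#' Module detection and Newman modularity
#'
#' Runs Louvain community detection on the network's unweighted, sign-agnostic
#' edge set (the default; \code{weights = "absrho"} uses \eqn{|\rho|} edge
#' weights instead) and reports the Newman-Girvan modularity Q of the
#' resulting partition. An edgeless graph gets an undefined (\code{NA}) Q with
#' every node its own module.
#'
#' @param x a \linkS4class{CoocNetwork}.
#' @param seed RNG seed for Louvain (fixed seed gives a reproducible
#'   partition).
#' @param resolution Louvain resolution parameter (1.0 default).
#' @param weights \code{"none"} (default) or \code{"absrho"}.
#' @return the network with \code{partition} and \code{modularityQ} filled in.
#' @export
networkModularity <- function(x, seed = NULL, resolution = 1.0,
                              weights = c("none", "absrho")) {
  weights <- match.arg(weights)
  g <- x@graph
  if (igraph::ecount(g) == 0) {
    x@partition <- stats::setNames(seq_len(igraph::vcount(g)),
                                   igraph::V(g)$name)
    x@modularityQ <- NA_real_
    message("edgeless network: modularity undefined")
    return(x)
  }
  w <- if (weights == "absrho") abs(igraph::E(g)$rho) else NULL
  if (!is.null(seed)) set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
  memb <- igraph::membership(cl)
  x@partition <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  x@modularityQ <- igraph::modularity(g, memb, weights = w)
  methods::validObject(x)
  x
}

#' Positive-edge proportions per taxonomy stratum
#'
#' The fraction of positive-sign edges overall, within each domain
#' (archaea-archaea, bacteria-bacteria), between domains, and per unordered
#' phylum pair. Strata without edges are omitted.
#'
#' @param x a \linkS4class{CoocNetwork}.
#' @return a data.frame with \code{stratum}, \code{n_edges},
#'   \code{prop_positive}.
#' @export
setMethod("edgeSignSummary", "CoocNetwork", function(x) {
  g <- x@graph
  empty <- data.frame(stratum = character(0), n_edges = integer(0),
                      prop_positive = numeric(0))
  if (igraph::ecount(g) == 0) return(empty)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  sgn <- igraph::E(g)$sign
  dom <- igraph::V(g)$domain
  phy <- igraph::V(g)$phylum
  d1 <- dom[ends[, 1]]; d2 <- dom[ends[, 2]]
  dom_stratum <- ifelse(d1 == d2,
                        paste0(tolower(d1), "-", tolower(d2)),
                        "archaea-bacteria")
  p1 <- phy[ends[, 1]]; p2 <- phy[ends[, 2]]
  phy_stratum <- paste0("phylum:",
                        pmin(p1, p2), "|", pmax(p1, p2))
  one <- function(name, s) data.frame(stratum = name, n_edges = length(s),
                                      prop_positive = mean(s > 0))
  rows <- list(one("overall", sgn))
  for (st in sort(unique(dom_stratum)))
    rows <- c(rows, list(one(st, sgn[dom_stratum == st])))
  for (st in sort(unique(phy_stratum)))
    rows <- c(rows, list(one(st, sgn[phy_stratum == st])))
  do.call(rbind, rows)
})

#' CoocNetwork accessors
#'
#' @param x a \linkS4class{CoocNetwork}.
#' @return \code{networkEdges}: data.frame \code{source}, \code{target},
#'   \code{rho}, \code{sign}, \code{p_adj}. \code{modulePartition}: named
#'   integer module ids. \code{modularityQ}: the Newman modularity.
#' @name CoocNetwork-accessors
NULL

#' @rdname CoocNetwork-accessors
#' @export
setMethod("networkEdges", "CoocNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(source = character(0), target = character(0),
                      rho = numeric(0), sign = numeric(0),
                      p_adj = numeric(0)))
  ends <- igraph::ends(g, igraph::E(g))
  data.frame(source = ends[, 1], target = ends[, 2],
             rho = igraph::E(g)$rho, sign = igraph::E(g)$sign,
             p_adj = igraph::E(g)$p_adj)
})

#' @rdname CoocNetwork-accessors
#' @export
setMethod("modulePartition", "CoocNetwork", function(x) x@partition)

#' @rdname CoocNetwork-accessors
#' @export
setMethod("modularityQ", "CoocNetwork", function(x) x@modularityQ)

setMethod("show", "CoocNetwork", function(object) {
  g <- object@graph
  cat("CoocNetwork:", igraph::vcount(g), "nodes,", igraph::ecount(g),
      "edges (|rho| >", object@params$rThreshold,
      ", FDR <", object@params$alpha, ")\n")
  if (length(object@partition))
    cat("  modules:", length(unique(object@partition)),
        " modularity Q:", signif(object@modularityQ, 3), "\n")
  ov <- object@signSummary[object@signSummary$stratum == "overall", ]
  if (nrow(ov))
    cat("  positive edges:", sprintf("%.1f%%", 100 * ov$prop_positive), "\n")
})

#' Run the whole co-occurrence stage
#'
#' Convenience wrapper: select the top-abundance ASVs, compute the Spearman
#' correlation and p matrices, apply the BH-FDR correction, gate edges at
#' \eqn{|\rho| >} \code{rThreshold} and FDR p \eqn{<} \code{alpha}, then run
#' Louvain and summarise edge signs.
#'
#' @param x an \linkS4class{AsvExperiment} with taxonomy in \code{rowData}.
#' @param top number of top-abundance ASVs (default 200).
#' @param rThreshold,alpha edge gates.
#' @param seed Louvain seed.
#' @return a \linkS4class{CoocNetwork} with partition and modularity set.
#' @export
cooccurrenceNetwork <- function(x, top = 200L, rThreshold = 0.6,
                                alpha = 0.05, seed = 1L) {
  if (!all(c("domain", "phylum", "class") %in% names(rowData(x))))
    stop("rowData(x) must carry domain, phylum, class taxonomy")
  xt <- suppressWarnings(selectTopAsvs(x, top))
  sp <- spearmanMatrix(xt)
  pAdj <- adjustFdr(sp$p)
  tax <- data.frame(asv = rownames(xt), domain = rowData(xt)$domain,
                    phylum = rowData(xt)$phylum, class = rowData(xt)$class)
  tax <- tax[tax$asv %in% rownames(sp$rho), ]
  net <- buildNetwork(sp$rho, pAdj, tax, rThreshold, alpha)
  networkModularity(net, seed = seed)
}

#' Export a network as edge-list and node-table TSVs
#'
#' @param x a \linkS4class{CoocNetwork}.
#' @param edgePath,nodePath output TSV paths.
#' @return invisibly, the two paths.
#' @export
writeNetwork <- function(x, edgePath, nodePath) {
  utils::write.table(networkEdges(x), edgePath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  g <- x@graph
  nodes <- data.frame(id = igraph::V(g)$name, domain = igraph::V(g)$domain,
                      phylum = igraph::V(g)$phylum,
                      class = igraph::V(g)$class,
                      module = if (length(x@partition))
                        unname(x@partition[igraph::V(g)$name]) else NA_integer_)
  utils::write.table(nodes, nodePath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(edgePath, nodePath))
}
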