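suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# Build a toy PlateSeries directly: od is a matrix with one row per
# (substrate, replicate) well and one column per timepoint.
makeSeries <- function(substrate, replicate, times, od,
                       category = NULL, sample = "toy") {
  if (is.null(category)) category <- rep("carbohydrates", length(substrate))
  key <- paste(substrate, replicate, sep = "::")
  od <- matrix(od, nrow = length(substrate), dimnames = list(key, NULL))
  se <- SummarizedExperiment(
    assays = list(corrected = od),
    rowData = S4Vectors::DataFrame(substrate = substrate,
                                   category = category,
                                   replicate = replicate, row.names = key),
    colData = S4Vectors::DataFrame(time_h = times))
  out <- new("PlateSeries", se)
  S4Vectors::metadata(out)$sample_id <- sample
  out
}

# Write a readings CSV where every well has a constant OD per
# (timepoint, wavelength); `values` is a function(well, time, wavelength).
writeReadingsCsv <- function(path, layout, times, values,
                             plate = "P1", sample = "S1") {
  w <- wells(layout)$well
  rows <- expand.grid(well = w, time_h = times, wavelength = c(590, 750),
                      stringsAsFactors = FALSE)
  rows$plate <- plate
  rows$sample <- sample
  rows$od <- mapply(values, rows$well, rows$time_h, rows$wavelength)
  write.csv(rows[c("plate", "sample", "time_h", "wavelength", "well", "od")],
            path, row.names = FALSE)
  path
}

# Independent ANOSIM oracle: recomputes the rank statistic from first
# principles and enumerates every label permutation iteratively.
anosimOracle <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  dv <- dmat[lower.tri(dmat)]
  rk <- rank(dv)
  M <- length(dv)
  stat <- function(g) {
    between <- outer(g, g, "!=")[lower.tri(dmat)]
    (mean(rk[between]) - mean(rk[!between])) / (M / 2)
  }
  # iterative permutation enumeration (heap-free, lexicographic recursion
  # unrolled via index odometer over remaining elements)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  all_p <- perms(seq_len(n))
  Rs <- vapply(all_p, function(ix) stat(groups[ix]), 0)
  obs <- stat(groups)
  list(statistic = obs, p_value = mean(Rs >= obs - 1e-12))
}

# Exhaustive maximum modularity over all partitions of a small graph,
# enumerated as restricted growth strings.
maxModularityOracle <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 10)
  best <- -Inf
  rgs <- rep(1L, n)
  repeat {
    q <- igraph::modularity(g, rgs)
    if (q > best) best <- q
    # next restricted growth string
    i <- n
    while (i >= 2) {
      if (rgs[i] <= max(rgs[1:(i - 1)])) {
        rgs[i] <- rgs[i] + 1L
        if (i < n) rgs[(i + 1):n] <- 1L
        break
      }
      i <- i - 1
    }
    if (i < 2) break
  }
  best
}

# Toy ASV experiment with explicit counts (ASVs x samples).
makeAsv <- function(counts, domain = NULL, phylum = NULL) {
  nA <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("ASV%02d", 1:nA)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  if (is.null(domain)) domain <- rep("Bacteria", nA)
  if (is.null(phylum)) phylum <- rep("Proteobacteria", nA)
  tax <- data.frame(asv = rownames(counts), domain = domain, phylum = phylum,
                    class = paste0(phylum, "_c"))
  asvExperiment(counts, tax)
}
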