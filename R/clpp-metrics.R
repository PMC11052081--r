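#' Average well colour development (AWCD)
#'
#' AWCD at a timepoint is the mean, over a set of substrates, of the
#' control-corrected absorbance \eqn{(R - C)}: replicate wells are averaged
#' per substrate first, then the substrate means are averaged, with \eqn{n}
#' equal to the number of substrates in the set (all 31 by default, or one
#' carbon category's substrates).
#'
#' @param x a \linkS4class{PlateSeries}.
#' @param time_h a timepoint on the series grid.
#' @param substrates substrate ids to average over (default: all).
#' @return \code{awcd}: a single number. \code{awcdSeries}: a data.frame with
#'   \code{time_h} and \code{awcd} for every timepoint.
#' @name awcd
NULL

#' @rdname awcd
#' @export
setMethod("awcd", "PlateSeries", function(x, time_h, substrates = NULL) {
  tt <- plateTimes(x)
  j <- match(time_h, tt)
  if (is.na(j)) stop("time ", time_h, " is not on the series grid")
  m <- .substrateMeans(x)
  if (is.null(substrates)) substrates <- rownames(m)
  if (!length(substrates)) stop("empty substrate subset")
  miss <- setdiff(substrates, rownames(m))
  if (length(miss))
    stop("unknown substrate(s): ", paste(miss, collapse = ", "))
  mean(m[substrates, j])
})

#' @rdname awcd
#' @export
setMethod("awcdSeries", "PlateSeries", function(x, substrates = NULL) {
  tt <- plateTimes(x)
  if (!length(tt)) stop("empty series")
  data.frame(time_h = tt,
             awcd = vapply(tt, function(tm) awcd(x, tm, substrates), 0))
})

#' Substrate richness
#'
#' Counts the oxidised substrates: those whose replicate-averaged corrected
#' OD reaches the threshold (default 0.5) at two consecutive measurement
#' times \eqn{t_n} and \eqn{t_{n+1}}. With \code{statistic = "sum"} the
#' index is instead the sum, over qualifying substrates, of the maximum OD
#' attained across their qualifying consecutive pairs.
#'
#' @param x a \linkS4class{PlateSeries} with at least 2 timepoints.
#' @param threshold oxidation threshold on the corrected OD.
#' @param statistic \code{"count"} (default) or \code{"sum"}.
#' @return an integer count (or a numeric sum).
#' @export
setMethod("substrateRichness", "PlateSeries",
          function(x, threshold = 0.5, statistic = c("count", "sum")) {
  statistic <- match.arg(statistic)
  m <- .substrateMeans(x)
  if (ncol(m) < 2L) stop("richness needs at least 2 timepoints")
  hit <- m >= threshold
  pair <- hit[, -ncol(hit), drop = FALSE] & hit[, -1, drop = FALSE]
  passed <- rowSums(pair) > 0
  if (statistic == "count") return(sum(passed))
  if (!any(passed)) return(0)
  sum(vapply(which(passed), function(i) {
    js <- which(pair[i, ])
    max(pmax(m[i, js], m[i, js + 1L]))
  }, 0))
})

#' Substrate proportions of colour development
#'
#' \eqn{P_i = OD_i / \sum_i OD_i} over the substrates (replicate-averaged) at
#' one timepoint: each substrate's share of the plate's total colour
#' development.
#'
#' @param x a \linkS4class{PlateSeries}.
#' @param time_h a timepoint on the series grid.
#' @return a named numeric vector summing to 1.
#' @export
setMethod("substratePi", "PlateSeries", function(x, time_h) {
  tt <- plateTimes(x)
  j <- match(time_h, tt)
  if (is.na(j)) stop("time ", time_h, " is not on the series grid")
  od <- .substrateMeans(x)[, j]
  tot <- sum(od)
  if (tot <= 0)
    stop("total colour development is zero at time ", time_h,
         "; Pi is undefined")
  od / tot
})

.checkPi <- function(pi) {
  if (!length(pi)) stop("empty Pi vector")
  if (any(pi < 0)) stop("Pi values must be non-negative")
  if (abs(sum(pi) - 1) > 1e-6) stop("Pi must sum to 1")
}

#' Functional-diversity indices from substrate proportions
#'
#' \code{simpsonIndex} follows the plate-profiling convention
#' \eqn{D = -\ln \sum_i P_i^2} (0 for a single dominant substrate,
#' \eqn{\ln N} at uniformity). \code{giniSimpson} is the classical
#' \eqn{1 - \sum_i P_i^2} variant, provided for comparison but not used by the
#' pipeline defaults. \code{shannonIndex} is \eqn{H = -\sum_i P_i \ln P_i}
#' with zero proportions contributing 0.
#'
#' @param pi a vector of proportions summing to 1.
#' @return a non-negative number.
#' @export
simpsonIndex <- function(pi) {
  .checkPi(pi)
  -log(sum(pi^2))
}

#' @rdname simpsonIndex
#' @export
giniSimpson <- function(pi) {
  .checkPi(pi)
  1 - sum(pi^2)
}

#' @rdname simpsonIndex
#' @export
shannonIndex <- function(pi) {
  .checkPi(pi)
  p <- pi[pi > 0]
  -sum(p * log(p))
}

#' Per-category carbon-source utilization
#'
#' AWCD computed per carbon category, i.e. with \eqn{n} the number of
#' substrates in that category.
#'
#' @param x a \linkS4class{PlateSeries}.
#' @param time_h a timepoint on the series grid.
#' @return a named numeric vector, one AWCD per category.
#' @export
setMethod("categoryUtilization", "PlateSeries", function(x, time_h) {
  cats <- rowData(x)$category
  subs <- rowData(x)$substrate
  by_cat <- split(subs, cats)
  vapply(by_cat, function(s) awcd(x, time_h, unique(s)), 0)
})

#' Detect exponential and stable growth phases on an AWCD curve
#'
#' Scans forward slopes computed over a window of \code{window} sampling
#' intervals. The exponential phase starts at the first time the slope
#' exceeds \code{slopeEps}; the stable phase starts at the first later time
#' from which the slope stays below \code{slopeEps} for the remainder of the
#' incubation.
#'
#' @param time_h timepoints (strictly increasing).
#' @param awcd the AWCD values at those timepoints.
#' @param window number of sampling intervals per slope estimate (default 3).
#' @param slopeEps slope threshold in OD per hour; default 2\% of the final
#'   AWCD per 24 h.
#' @return named numeric: \code{t_exp_start}, \code{t_stable_start}
#'   (hours; \code{NA} when the phase is not found).
#' @export
detectPhases <- function(time_h, awcd, window = 3L, slopeEps = NULL) {
  if (any(diff(time_h) <= 0)) stop("time grid must be strictly increasing")
  n <- length(time_h)
  out <- c(t_exp_start = NA_real_, t_stable_start = NA_real_)
  if (n < window + 1L) return(out)
  if (is.null(slopeEps)) slopeEps <- 0.02 * awcd[n] / 24
  idx <- seq_len(n - window)
  slopes <- (awcd[idx + window] - awcd[idx]) / (time_h[idx + window] - time_h[idx])
  i_exp <- which(slopes > slopeEps)
  if (!length(i_exp)) return(out)
  out["t_exp_start"] <- time_h[i_exp[1]]
  later <- idx[idx > i_exp[1]]
  for (i in later) {
    if (all(slopes[seq(i, length(slopes))] <= slopeEps)) {
      out["t_stable_start"] <- time_h[i]
      break
    }
  }
  out
}

#' Full physiological profile of one plate
#'
#' Bundles the plate statistics into a \linkS4class{ClppProfile}: the AWCD
#' time series overall and per carbon category, growth-phase boundaries, the
#' substrate proportions \eqn{P_i} at a reference timepoint, and the
#' richness, Simpson and Shannon indices. The default reference timepoint
#' (\code{refTime = "auto"}) is the detected start of the stable phase,
#' falling back to the final timepoint; a plate with no colour development at
#' the reference time gets \code{NA} indices rather than zeros.
#'
#' @param x a \linkS4class{PlateSeries}.
#' @param refTime \code{"auto"}, \code{"final"}, or a timepoint in hours.
#' @param threshold richness oxidation threshold.
#' @param window,slopeEps phase-detection controls, see [detectPhases()].
#' @return a \linkS4class{ClppProfile}.
#' @export
setMethod("clppProfile", "PlateSeries",
          function(x, refTime = "auto", threshold = 0.5, window = 3L,
                   slopeEps = NULL) {
  curve <- awcdSeries(x)
  phase <- detectPhases(curve$time_h, curve$awcd, window, slopeEps)
  tt <- plateTimes(x)
  ref <- if (identical(refTime, "auto")) {
    if (is.na(phase["t_stable_start"])) tt[length(tt)] else
      unname(phase["t_stable_start"])
  } else if (identical(refTime, "final")) tt[length(tt)] else as.numeric(refTime)
  if (is.na(match(ref, tt)))
    stop("reference time ", ref, " is not on the series grid")

  cats <- sort(unique(rowData(x)$category))
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    s <- unique(rowData(x)$substrate[rowData(x)$category == cc])
    cbind(awcdSeries(x, s), category = cc)
  }))

  pi <- tryCatch(substratePi(x, ref), error = function(e) NULL)
  if (is.null(pi)) {
    pi <- rep(NA_real_, length(substrates_of(x)))
    names(pi) <- substrates_of(x)
    D <- H <- NA_real_
  } else {
    D <- simpsonIndex(pi)
    H <- shannonIndex(pi)
  }
  methods::new("ClppProfile",
               sampleId = sampleId(x),
               awcdSeries = curve,
               awcdByCategory = by_cat[c("category", "time_h", "awcd")],
               richness = as.integer(substrateRichness(x, threshold)),
               simpson = D, shannon = H, pi = pi, refTime = ref,
               phase = phase)
})

substrates_of <- function(x) sort(unique(rowData(x)$substrate))

setMethod("show", "ClppProfile", function(object) {
  cat("ClppProfile for sample", object@sampleId, "\n")
  cat("  reference time:", object@refTime, "h; AWCD:",
      signif(object@awcdSeries$awcd[match(object@refTime,
                                          object@awcdSeries$time_h)], 4), "\n")
  cat("  richness:", object@richness,
      " Simpson D:", signif(object@simpson, 4),
      " Shannon H:", signif(object@shannon, 4), "\n")
  cat("  phases: exponential from", object@phase["t_exp_start"],
      "h, stable from", object@phase["t_stable_start"], "h\n")
})
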