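#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData rowData<- colData<-
NULL

setOldClass("igraph")

#' EcoPlate layout
#'
#' Maps the 96 wells of a Biolog EcoPlate to 31 carbon substrates (in
#' triplicate) plus 3 water-blank control wells, each substrate tagged with one
#' of six carbon categories (carbohydrates, polymers, phenolic, carboxylic,
#' amino_acids, amines).
#'
#' @slot wells a \code{data.frame} with columns \code{well}, \code{substrate}
#'   (\code{"CONTROL"} for water blanks), \code{category} and \code{replicate}.
#' @seealso [loadPlateLayout()], [ecoPlateLayout()]
#' @export
setClass("PlateLayout", representation(wells = "data.frame"))

.CATEGORIES <- c("carbohydrates", "polymers", "phenolic", "carboxylic",
                 "amino_acids", "amines")

setValidity("PlateLayout", function(object) {
  w <- object@wells
  need <- c("well", "substrate", "category", "replicate")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns", paste(need, collapse = ", ")))
  all_wells <- paste0(rep(LETTERS[1:8], times = 12), rep(1:12, each = 8))
  if (anyDuplicated(w$well))
    return(paste("duplicate well id:",
                 paste(unique(w$well[duplicated(w$well)]), collapse = ", ")))
  missing <- setdiff(all_wells, w$well)
  if (length(missing))
    return(paste("missing wells:", paste(missing, collapse = ", ")))
  if (nrow(w) != 96L) return("layout must have exactly 96 wells")
  is_ctrl <- w$substrate == "CONTROL"
  if (sum(is_ctrl) != 3L) return("layout must have exactly 3 control wells")
  if (!setequal(w$replicate[is_ctrl], 1:3))
    return("control wells must span replicates 1..3, one each")
  sub <- w[!is_ctrl, ]
  bad_cat <- setdiff(unique(sub$category), .CATEGORIES)
  if (length(bad_cat))
    return(paste("unknown category label:", paste(bad_cat, collapse = ", ")))
  tab <- table(sub$substrate)
  if (length(tab) != 31L)
    return(sprintf("expected 31 substrates, found %d", length(tab)))
  if (any(tab != 3L))
    return(paste("substrates without exactly 3 replicate wells:",
                 paste(names(tab)[tab != 3L], collapse = ", ")))
  # each substrate in exactly one category
  cat_per_sub <- tapply(sub$category, sub$substrate,
                        function(x) length(unique(x)))
  if (any(cat_per_sub != 1L))
    return("a substrate is assigned to more than one category")
  rep_per_sub <- tapply(sub$replicate, sub$substrate,
                        function(x) setequal(x, 1:3))
  if (!all(unlist(rep_per_sub)))
    return("substrate replicates must be labelled 1, 2, 3")
  TRUE
})

#' A single plate reading at one timepoint and wavelength
#'
#' @slot plateId,sampleId identifiers.
#' @slot timeH hours since inoculation.
#' @slot wavelength 590 or 750 (nm).
#' @slot od named numeric, optical density per well.
#' @export
setClass("RawReading",
         representation(plateId = "character", sampleId = "character",
                        timeH = "numeric", wavelength = "numeric",
                        od = "numeric"))

setValidity("RawReading", function(object) {
  if (!object@wavelength %in% c(590, 750))
    return("wavelength must be 590 or 750")
  if (length(object@timeH) != 1L || object@timeH < 0)
    return("timeH must be a single non-negative number")
  if (any(!is.finite(object@od))) return("od values must be finite")
  if (is.null(names(object@od))) return("od must be named by well id")
  TRUE
})

#' Turbidity- and control-corrected plate time series
#'
#' Extends \linkS4class{SummarizedExperiment}: one row per
#' (substrate, replicate) well, one column per timepoint. The
#' \code{"corrected"} assay holds the 590 nm minus 750 nm absorbance with the
#' mean control signal subtracted and negatives clipped at zero.
#' \code{rowData} carries \code{substrate}, \code{category} and
#' \code{replicate}; \code{colData} carries \code{time_h} (strictly
#' increasing).
#'
#' @seealso [correctPlateSeries()]
#' @export
setClass("PlateSeries", contains = "SummarizedExperiment")

setValidity("PlateSeries", function(object) {
  if (!"corrected" %in% SummarizedExperiment::assayNames(object))
    return("assay 'corrected' is required")
  if (!all(c("substrate", "replicate") %in% names(rowData(object))))
    return("rowData must have substrate and replicate")
  if (!"time_h" %in% names(colData(object)))
    return("colData must have time_h")
  tt <- colData(object)$time_h
  if (ncol(object) > 1 && any(diff(tt) <= 0))
    return("time_h must be strictly increasing")
  a <- assay(object, "corrected")
  if (any(!is.finite(a)) || any(a < 0))
    return("corrected values must be finite and >= 0")
  TRUE
})

#' Community-level physiological profile for one sample
#'
#' Holds the metabolic-activity statistics derived from a
#' \linkS4class{PlateSeries}: the AWCD time series (overall and per carbon
#' category), the substrate richness count, the Simpson and Shannon
#' functional-diversity indices with the underlying substrate proportions
#' \eqn{P_i}, the reference timepoint the indices were evaluated at, and the
#' detected growth-phase boundaries.
#'
#' @slot sampleId sample identifier.
#' @slot awcdSeries data.frame with \code{time_h}, \code{awcd}.
#' @slot awcdByCategory data.frame with \code{category}, \code{time_h},
#'   \code{awcd}.
#' @slot richness integer count of oxidised substrates.
#' @slot simpson,shannon functional-diversity indices (\code{NA} when the
#'   plate shows no colour development at the reference time).
#' @slot pi named numeric substrate proportions at the reference time.
#' @slot refTime reference timepoint (hours).
#' @slot phase named numeric, \code{t_exp_start} and \code{t_stable_start}
#'   in hours (\code{NA} when undetected).
#' @export
setClass("ClppProfile",
         representation(sampleId = "character", awcdSeries = "data.frame",
                        awcdByCategory = "data.frame", richness = "integer",
                        simpson = "numeric", shannon = "numeric",
                        pi = "numeric", refTime = "numeric",
                        phase = "numeric"))

setValidity("ClppProfile", function(object) {
  if (length(object@richness) &&
      (object@richness < 0L || object@richness > 31L))
    return("richness must be in 0..31")
  if (length(object@pi) && !anyNA(object@pi)) {
    if (abs(sum(object@pi) - 1) > 1e-9)
      return("pi must sum to 1")
  }
  if (!setequal(names(object@phase), c("t_exp_start", "t_stable_start")))
    return("phase must be named t_exp_start, t_stable_start")
  TRUE
})

#' ASV count table with taxonomy and sample metadata
#'
#' Extends \linkS4class{SummarizedExperiment}: ASVs as rows, samples as
#' columns, integer \code{"counts"} assay. \code{rowData} carries the taxonomy
#' (\code{domain}, \code{phylum}, \code{class}); \code{colData} carries sample
#' metadata (e.g. \code{trench}, \code{layer}, \code{depth_m}).
#'
#' @seealso [asvExperiment()], [loadAsvTable()]
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be non-negative integers")
  if (anyDuplicated(rownames(object))) return("ASV ids must be unique")
  if (anyDuplicated(colnames(object))) return("sample ids must be unique")
  if (ncol(object) && any(colSums(cnt) == 0))
    return(paste("all-zero sample(s):",
                 paste(colnames(object)[colSums(cnt) == 0], collapse = ", ")))
  TRUE
})

#' Co-occurrence network over ASVs
#'
#' A signed, weighted undirected graph whose edges are ASV pairs passing both
#' the correlation-strength gate (Spearman \eqn{|\rho| >} threshold) and the
#' FDR-significance gate, together with a module partition, its Newman
#' modularity, and positive-edge proportions overall and per taxonomy stratum.
#'
#' @slot graph an \code{igraph} object; vertices carry \code{domain},
#'   \code{phylum}, \code{class}; edges carry \code{rho}, \code{sign},
#'   \code{p_adj}.
#' @slot partition named integer, module id per node (empty until
#'   [networkModularity()] is run).
#' @slot modularityQ Newman modularity of the partition (\code{NA} when the
#'   graph has no edges).
#' @slot signSummary data.frame with \code{stratum}, \code{n_edges},
#'   \code{prop_positive}.
#' @slot params list of thresholds used to build the network.
#' @export
setClass("CoocNetwork",
         representation(graph = "igraph", partition = "integer",
                        modularityQ = "numeric", signSummary = "data.frame",
                        params = "list"))

setValidity("CoocNetwork", function(object) {
  if (length(object@modularityQ) && !is.na(object@modularityQ) &&
      (object@modularityQ < -0.5 - 1e-12 || object@modularityQ > 1 + 1e-12))
    return("modularity must lie in [-0.5, 1]")
  ss <- object@signSummary
  if (nrow(ss) && any(ss$prop_positive < 0 | ss$prop_positive > 1))
    return("sign proportions must lie in [0, 1]")
  TRUE
})
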