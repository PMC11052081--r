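#' @rdname PlateLayout-accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname PlateLayout-accessors
#' @export
setGeneric("substrates", function(x) standardGeneric("substrates"))

#' @rdname PlateLayout-accessors
#' @export
setGeneric("substrateCategories", function(x) standardGeneric("substrateCategories"))

#' @rdname PlateLayout-accessors
#' @export
setGeneric("controlWells", function(x) standardGeneric("controlWells"))

#' @rdname PlateSeries-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname PlateSeries-accessors
#' @export
setGeneric("plateTimes", function(x) standardGeneric("plateTimes"))

#' @rdname awcd
#' @export
setGeneric("awcd", function(x, time_h, substrates = NULL)
  standardGeneric("awcd"))

#' @rdname awcd
#' @export
setGeneric("awcdSeries", function(x, substrates = NULL)
  standardGeneric("awcdSeries"))

#' @rdname substrateRichness
#' @export
setGeneric("substrateRichness",
           function(x, threshold = 0.5, statistic = c("count", "sum"))
  standardGeneric("substrateRichness"))

#' @rdname substratePi
#' @export
setGeneric("substratePi", function(x, time_h) standardGeneric("substratePi"))

#' @rdname categoryUtilization
#' @export
setGeneric("categoryUtilization", function(x, time_h)
  standardGeneric("categoryUtilization"))

#' @rdname clppProfile
#' @export
setGeneric("clppProfile",
           function(x, refTime = "auto", threshold = 0.5, window = 3L,
                    slopeEps = NULL)
  standardGeneric("clppProfile"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @rdname shannonEvenness
#' @export
setGeneric("shannonEvenness", function(x) standardGeneric("shannonEvenness"))

#' @rdname brayCurtis
#' @export
setGeneric("brayCurtis", function(x, relative = TRUE)
  standardGeneric("brayCurtis"))

#' @rdname selectTopAsvs
#' @export
setGeneric("selectTopAsvs", function(x, k = 200L)
  standardGeneric("selectTopAsvs"))

#' @rdname spearmanMatrix
#' @export
setGeneric("spearmanMatrix", function(x, ...) standardGeneric("spearmanMatrix"))

#' @rdname CoocNetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CoocNetwork-accessors
#' @export
setGeneric("modulePartition", function(x) standardGeneric("modulePartition"))

#' @rdname CoocNetwork-accessors
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

#' @rdname edgeSignSummary
#' @export
setGeneric("edgeSignSummary", function(x) standardGeneric("edgeSignSummary"))
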