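#' Re-exported Bioconductor accessors
#'
#' \code{assay}, \code{rowData} and \code{colData} from SummarizedExperiment,
#' re-exported so PlateSeries and AsvExperiment objects can be inspected
#' without attaching it.
#'
#' @name reexports
#' @keywords internal
NULL

#' @rdname reexports
#' @export
SummarizedExperiment::assay

#' @rdname reexports
#' @export
SummarizedExperiment::rowData

#' @rdname reexports
#' @export
SummarizedExperiment::colData
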