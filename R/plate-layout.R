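#' Load a plate layout from CSV
#'
#' Reads a well-to-substrate map with columns \code{well}, \code{substrate},
#' \code{category}, \code{replicate} and validates the EcoPlate invariants:
#' all 96 wells present exactly once, 31 substrates in triplicate, 3 control
#' wells (substrate \code{"CONTROL"}, one per replicate block), and the six
#' carbon-category labels partitioning the substrates.
#'
#' @param path path to a layout CSV (UTF-8, header required).
#' @return a validated \linkS4class{PlateLayout}.
#' @seealso [ecoPlateLayout()] for the bundled standard EcoPlate map.
#' @export
loadPlateLayout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "substrate", "category", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("layout file lacks column(s): ", paste(missing, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  methods::new("PlateLayout", wells = df[need])
}

#' The standard Biolog EcoPlate layout
#'
#' The canonical 96-well EcoPlate map: three replicate blocks of four columns
#' each, with a water blank (A1/A5/A9) and 31 carbon substrates per block.
#' Substrates are classified into the six usual carbon categories
#' (10 carbohydrates, 7 carboxylic acids, 6 amino acids, 4 polymers,
#' 2 amines, 2 phenolic compounds).
#'
#' @return a validated \linkS4class{PlateLayout}.
#' @export
ecoPlateLayout <- function() {
  path <- system.file("extdata", "ecoplate_layout.csv", package = "hadalCLPP",
                      mustWork = TRUE)
  loadPlateLayout(path)
}

#' Plate layout accessors
#'
#' @param x a \linkS4class{PlateLayout}.
#' @return \code{wells}: the full well map as a data.frame.
#'   \code{substrates}: the 31 substrate ids. \code{substrateCategories}: a
#'   named character vector, category per substrate. \code{controlWells}: the
#'   control well ids.
#' @name PlateLayout-accessors
NULL

#' @rdname PlateLayout-accessors
#' @export
setMethod("wells", "PlateLayout", function(x) x@wells)

#' @rdname PlateLayout-accessors
#' @export
setMethod("substrates", "PlateLayout", function(x)
  sort(unique(x@wells$substrate[x@wells$substrate != "CONTROL"])))

#' @rdname PlateLayout-accessors
#' @export
setMethod("substrateCategories", "PlateLayout", function(x) {
  w <- x@wells[x@wells$substrate != "CONTROL", ]
  w <- w[!duplicated(w$substrate), ]
  stats::setNames(w$category, w$substrate)
})

#' @rdname PlateLayout-accessors
#' @export
setMethod("controlWells", "PlateLayout", function(x)
  x@wells$well[x@wells$substrate == "CONTROL"])

setMethod("show", "PlateLayout", function(object) {
  cat("PlateLayout: 96 wells,", length(substrates(object)),
      "substrates in triplicate,",
      length(controlWells(object)), "control wells\n")
  cat("categories:",
      paste(sort(unique(substrateCategories(object))), collapse = ", "), "\n")
})
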