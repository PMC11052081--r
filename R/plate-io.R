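#' Load dual-wavelength plate readings
#'
#' Reads a long-format OD file with columns \code{plate}, \code{sample},
#' \code{time_h}, \code{wavelength}, \code{well}, \code{od} and splits it into
#' one \linkS4class{RawReading} per (plate, timepoint, wavelength), validating
#' each against the layout: every layout well must be present exactly once,
#' wavelengths must be 590 or 750, and OD values numeric and finite.
#'
#' @param path path to the readings CSV.
#' @param layout a \linkS4class{PlateLayout}.
#' @return a list of \linkS4class{RawReading} objects, ordered by plate,
#'   time and wavelength.
#' @export
loadPlateReadings <- function(path, layout) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "sample", "time_h", "wavelength", "well", "od")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("readings file lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(df$od))
    stop("non-numeric od value(s) in readings file")
  if (any(!is.finite(df$od))) stop("od values must be finite")
  bad_wl <- setdiff(unique(df$wavelength), c(590, 750))
  if (length(bad_wl))
    stop("wavelength must be 590 or 750, found: ",
         paste(bad_wl, collapse = ", "))
  layout_wells <- wells(layout)$well
  key <- interaction(df$plate, df$time_h, df$wavelength, drop = TRUE)
  groups <- split(df, key)
  readings <- lapply(groups, function(g) {
    if (anyDuplicated(g$well))
      stop("duplicate well ", unique(g$well[duplicated(g$well)])[1],
           " for plate ", g$plate[1], " at time ", g$time_h[1])
    miss <- setdiff(layout_wells, g$well)
    if (length(miss))
      stop("missing well(s) ", paste(miss, collapse = ", "),
           " for plate ", g$plate[1], " at time ", g$time_h[1],
           ", wavelength ", g$wavelength[1])
    methods::new("RawReading",
                 plateId = as.character(g$plate[1]),
                 sampleId = as.character(g$sample[1]),
                 timeH = g$time_h[1],
                 wavelength = g$wavelength[1],
                 od = stats::setNames(g$od, g$well))
  })
  ord <- order(vapply(readings, function(r) r@plateId, ""),
               vapply(readings, function(r) r@timeH, 0),
               vapply(readings, function(r) r@wavelength, 0))
  unname(readings[ord])
}

#' Turbidity and control correction of plate readings
#'
#' Computes, per well and timepoint, the 590 nm absorbance minus the 750 nm
#' absorbance (removing turbidity in the 750 nm channel), then subtracts the
#' mean of the three control wells' own corrected signal at the same
#' timepoint, and clips negative results to zero. The two wavelengths must
#' have been read on identical time grids.
#'
#' @param readings a list of \linkS4class{RawReading} for one plate
#'   (both wavelengths, all timepoints).
#' @param layout a \linkS4class{PlateLayout}.
#' @return a \linkS4class{PlateSeries} keyed by (substrate, replicate).
#' @export
correctPlateSeries <- function(readings, layout) {
  if (!length(readings)) stop("no readings supplied")
  plates <- unique(vapply(readings, function(r) r@plateId, ""))
  if (length(plates) > 1L)
    stop("readings span multiple plates: ", paste(plates, collapse = ", "))
  sample_id <- readings[[1]]@sampleId
  wl <- vapply(readings, function(r) r@wavelength, 0)
  t590 <- sort(vapply(readings[wl == 590], function(r) r@timeH, 0))
  t750 <- sort(vapply(readings[wl == 750], function(r) r@timeH, 0))
  if (!identical(t590, t750))
    stop("590 and 750 nm readings are on different time grids")
  if (!length(t590)) stop("no timepoints present")
  times <- t590

  w <- wells(layout)
  layout_wells <- w$well
  ctrl <- controlWells(layout)
  sub_w <- w[w$substrate != "CONTROL", ]
  row_key <- paste(sub_w$substrate, sub_w$replicate, sep = "::")

  get_od <- function(time, wavelength) {
    i <- which(vapply(readings, function(r)
      r@timeH == time && r@wavelength == wavelength, NA))
    od <- readings[[i[1]]]@od
    miss <- setdiff(layout_wells, names(od))
    if (length(miss))
      stop("reading at time ", time, " lacks well(s): ",
           paste(miss, collapse = ", "))
    od[layout_wells]
  }

  corrected <- vapply(times, function(tm) {
    d <- get_od(tm, 590) - get_od(tm, 750)
    d <- d - mean(d[ctrl])
    pmax(d[sub_w$well], 0)
  }, numeric(nrow(sub_w)))
  corrected <- matrix(corrected, nrow = nrow(sub_w),
                      dimnames = list(row_key, NULL))

  se <- SummarizedExperiment(
    assays = list(corrected = corrected),
    rowData = DataFrame(substrate = sub_w$substrate,
                        category = sub_w$category,
                        replicate = sub_w$replicate,
                        well = sub_w$well,
                        row.names = row_key),
    colData = DataFrame(time_h = times))
  out <- methods::new("PlateSeries", se)
  metadata(out)$sample_id <- sample_id
  methods::validObject(out)
  out
}

#' PlateSeries accessors
#'
#' @param x a \linkS4class{PlateSeries}.
#' @return \code{sampleId}: the sample identifier. \code{plateTimes}: the
#'   ordered timepoints in hours.
#' @name PlateSeries-accessors
NULL

#' @rdname PlateSeries-accessors
#' @export
setMethod("sampleId", "PlateSeries", function(x) metadata(x)$sample_id)

#' @rdname PlateSeries-accessors
#' @export
setMethod("plateTimes", "PlateSeries", function(x) colData(x)$time_h)

setMethod("show", "PlateSeries", function(object) {
  cat("PlateSeries for sample", sampleId(object), "\n")
  cat(" ", length(unique(rowData(object)$substrate)), "substrates x",
      ncol(object), "timepoints (",
      min(plateTimes(object)), "-", max(plateTimes(object)), "h )\n")
})

# replicate-averaged corrected OD: substrates x times matrix
.substrateMeans <- function(x) {
  a <- assay(x, "corrected")
  sub <- rowData(x)$substrate
  m <- rowsum(a, sub) / as.vector(table(sub)[sort(unique(sub))])
  m[sort(unique(sub)), , drop = FALSE]
}

#' Serialize and reload a corrected plate series
#'
#' The CSV has columns \code{sample}, \code{substrate}, \code{replicate},
#' \code{time_h}, \code{od_corrected}; a write/read round trip reproduces the
#' series exactly.
#'
#' @param x a \linkS4class{PlateSeries}.
#' @param path output (or input) CSV path.
#' @return \code{writePlateSeries}: the path, invisibly.
#'   \code{readPlateSeries}: the reconstructed \linkS4class{PlateSeries}.
#' @export
writePlateSeries <- function(x, path) {
  rd <- rowData(x)
  tt <- plateTimes(x)
  a <- assay(x, "corrected")
  df <- data.frame(
    sample = sampleId(x),
    substrate = rep(rd$substrate, times = length(tt)),
    category = rep(rd$category, times = length(tt)),
    replicate = rep(rd$replicate, times = length(tt)),
    time_h = rep(tt, each = nrow(a)),
    od_corrected = as.vector(a))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlateSeries
#' @export
readPlateSeries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  times <- sort(unique(df$time_h))
  key <- paste(df$substrate, df$replicate, sep = "::")
  ukey <- unique(key[order(df$substrate, df$replicate)])
  m <- matrix(NA_real_, nrow = length(ukey), ncol = length(times),
              dimnames = list(ukey, NULL))
  m[cbind(match(key, ukey), match(df$time_h, times))] <- df$od_corrected
  first <- !duplicated(key)
  se <- SummarizedExperiment(
    assays = list(corrected = m),
    rowData = DataFrame(substrate = df$substrate[first][match(ukey, key[first])],
                        category = df$category[first][match(ukey, key[first])],
                        replicate = df$replicate[first][match(ukey, key[first])],
                        row.names = ukey),
    colData = DataFrame(time_h = times))
  out <- methods::new("PlateSeries", se)
  metadata(out)$sample_id <- df$sample[1]
  methods::validObject(out)
  out
}
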