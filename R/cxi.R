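## CXI-flavoured HDF5 I/O.
##
## Layout (CXI 1.4 conventions):
##   /entry_1/instrument_1/detector_1/data       frame stack (chunked by frame)
##   /entry_1/instrument_1/detector_1/distance   metres
##   /entry_1/instrument_1/detector_1/x_pixel_size, y_pixel_size   metres
##   /entry_1/instrument_1/detector_1/mask       shared mask (nonzero = bad)
##   /entry_1/instrument_1/source_1/energy       joules
##   /entry_1/experiment_identifier              per-frame id strings
## Photon data is stored as integers, ADU data as doubles.  Standalone mask
## files carry a 2-D dataset /data/data with nonzero = bad; selection files
## carry a single 1-D dataset /timestamps of fixed-width id strings compared
## lexically.

#' Handle to a CXI dataset on disk
#'
#' Lazy per-frame access to a CXI file: metadata is read eagerly, frames on
#' demand via [getFrame()].  Optional metadata missing from the file is
#' reported as \code{NA} (an explicit absent marker), never defaulted.
#'
#' @slot path file path.
#' @slot detector detector group name (e.g. "detector_1").
#' @slot dim integer(3): rows, cols, frames.
#' @slot ids frame identifiers (NA when absent).
#' @slot energyKeV photon energy (NA when absent).
#' @slot distanceMm detector distance (NA when absent).
#' @slot pixelSizeUm pixel pitch (NA when absent).
#' @slot hasMask TRUE when the file carries a shared mask dataset.
#' @export
setClass("CxiDataset",
  slots = c(path = "character", detector = "character", dim = "integer",
            ids = "character", energyKeV = "numeric", distanceMm = "numeric",
            pixelSizeUm = "numeric", hasMask = "logical"))

setMethod("show", "CxiDataset", function(object) {
  cat(sprintf("CxiDataset: %s [%s]\n", object@path, object@detector))
  cat(sprintf("  %d frames of %d x %d px\n", object@dim[3L], object@dim[1L],
              object@dim[2L]))
  cat(sprintf("  energy %s keV, distance %s mm, pixel %s um\n",
              format(object@energyKeV), format(object@distanceMm),
              format(object@pixelSizeUm)))
})

#' Number of frames in a CXI dataset
#' @param x a [CxiDataset-class].
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname nFrames
#' @export
setMethod("nFrames", "CxiDataset", function(x) x@dim[3L])

#' Frame identifiers of a CXI dataset
#' @param x a [CxiDataset-class].
#' @export
setGeneric("frameIds", function(x) standardGeneric("frameIds"))
#' @rdname frameIds
#' @export
setMethod("frameIds", "CxiDataset", function(x) x@ids)

.cxiDataPath <- function(detector)
  paste0("entry_1/instrument_1/detector_1/data") # single-detector layout

.detGroup <- function(detector) paste0("entry_1/instrument_1/", detector)

#' Write a frame stack as a CXI HDF5 file
#'
#' Creates the CXI group layout, stores the stack chunked frame-by-frame,
#' echoes the detector geometry into the metadata (distance and pixel size
#' in metres, photon energy in joules) and writes per-frame identifiers.
#' Integer stacks (photon data) are stored as integers, real stacks (ADU)
#' as doubles.  An empty stack yields a valid file with zero frames.
#'
#' @param frames 3-D array \code{[row, col, frame]} (possibly with 0
#'   frames), a matrix, or a list of matrices / frame objects.
#' @param path output path (overwritten).
#' @param geom optional [DetectorGeometry-class] echoed into metadata.
#' @param ids per-frame identifier strings; generated when NULL.
#' @param mask optional shared mask (logical or 0/1; nonzero = bad).
#' @param detector detector group name.
#' @return Invisibly, \code{path}.
#' @export
writeCxi <- function(frames, path, geom = NULL, ids = NULL, mask = NULL,
                     detector = "detector_1") {
  if (is.array(frames) && length(dim(frames)) == 3L) arr <- frames
  else arr <- .stackArray(frames)
  d <- dim(arr)
  nf <- d[3L]
  if (!is.null(ids) && length(ids) != nf)
    stop("invalid-dataset: one id per frame required")
  if (is.null(ids)) ids <- sprintf("evt-%010d", seq_len(nf))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "entry_1")
  rhdf5::h5createGroup(path, "entry_1/instrument_1")
  dg <- .detGroup(detector)
  rhdf5::h5createGroup(path, dg)
  rhdf5::h5createGroup(path, "entry_1/instrument_1/source_1")
  storMode <- if (is.integer(arr)) "integer" else "double"
  dataName <- paste0(dg, "/data")
  rhdf5::h5createDataset(path, dataName, dims = d,
                         maxdims = c(d[1L], d[2L], rhdf5::H5Sunlimited()),
                         storage.mode = storMode,
                         chunk = c(d[1L], d[2L], 1L))
  if (nf > 0L) rhdf5::h5write(arr, path, dataName)
  if (!is.null(mask)) {
    m <- matrix(as.integer(mask != 0), d[1L], d[2L])
    rhdf5::h5write(m, path, paste0(dg, "/mask"))
  }
  if (!is.null(geom)) {
    rhdf5::h5write(geom@distance / 1000, path, paste0(dg, "/distance"))
    rhdf5::h5write(geom@pixelSize * 1e-6, path, paste0(dg, "/x_pixel_size"))
    rhdf5::h5write(geom@pixelSize * 1e-6, path, paste0(dg, "/y_pixel_size"))
    rhdf5::h5write(geom@photonEnergy * .joule_per_kev, path,
                   "entry_1/instrument_1/source_1/energy")
  }
  rhdf5::h5write(ids, path, "entry_1/experiment_identifier")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Open a CXI file
#'
#' Validates the mandatory layout (\code{/entry_1} and the detector data
#' stack must exist) and returns a lazy [CxiDataset-class] handle.  Missing
#' optional metadata is reported as NA.
#'
#' @param path CXI file path.
#' @param detector detector group name.
#' @return A [CxiDataset-class].
#' @export
readCxi <- function(path, detector = "detector_1") {
  if (!file.exists(path)) stop("malformed-cxi: no such file: ", path)
  ls <- rhdf5::h5ls(path)
  full <- paste(sub("^/$", "", ls$group), ls$name, sep = "/")
  full <- sub("^/", "", full)
  if (!any(full == "entry_1"))
    stop("malformed-cxi: missing /entry_1 group")
  dg <- .detGroup(detector)
  dataName <- paste0(dg, "/data")
  i <- which(full == dataName)
  if (!length(i))
    stop("malformed-cxi: missing mandatory dataset /", dataName)
  d <- as.integer(strsplit(ls$dim[i], " x ")[[1L]])
  if (length(d) != 3L)
    stop("malformed-cxi: data stack must be 3-dimensional")
  rd <- function(name, scale = 1) {
    if (any(full == name))
      as.numeric(rhdf5::h5read(path, name)) * scale else NA_real_
  }
  ids <- if (any(full == "entry_1/experiment_identifier"))
    as.character(rhdf5::h5read(path, "entry_1/experiment_identifier"))
  else NA_character_
  out <- new("CxiDataset", path = path, detector = detector, dim = d,
             ids = ids,
             energyKeV = rd("entry_1/instrument_1/source_1/energy",
                            1 / .joule_per_kev),
             distanceMm = rd(paste0(dg, "/distance"), 1000),
             pixelSizeUm = rd(paste0(dg, "/x_pixel_size"), 1e6),
             hasMask = any(full == paste0(dg, "/mask")))
  rhdf5::h5closeAll()
  out
}

#' Read one frame from a CXI dataset
#'
#' @param x a [CxiDataset-class].
#' @param i frame index (1-based, stored order).
#' @return Numeric or integer matrix.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname getFrame
#' @export
setMethod("getFrame", "CxiDataset", function(x, i) {
  stopifnot(i >= 1L, i <= x@dim[3L])
  m <- rhdf5::h5read(x@path, paste0(.detGroup(x@detector), "/data"),
                     index = list(NULL, NULL, i))
  rhdf5::h5closeAll()
  matrix(m, x@dim[1L], x@dim[2L])
})

#' Read the whole frame stack of a CXI dataset
#'
#' @param x a [CxiDataset-class].
#' @return 3-D array \code{[row, col, frame]}.
#' @export
setGeneric("getFrames", function(x) standardGeneric("getFrames"))
#' @rdname getFrames
#' @export
setMethod("getFrames", "CxiDataset", function(x) {
  a <- rhdf5::h5read(x@path, paste0(.detGroup(x@detector), "/data"))
  rhdf5::h5closeAll()
  array(a, dim = x@dim)
})

#' Read the shared mask of a CXI dataset
#'
#' @param x a [CxiDataset-class].
#' @return Logical matrix, TRUE = bad; NULL when the file has none.
#' @export
setGeneric("getMask", function(x) standardGeneric("getMask"))
#' @rdname getMask
#' @export
setMethod("getMask", "CxiDataset", function(x) {
  if (!x@hasMask) return(NULL)
  m <- rhdf5::h5read(x@path, paste0(.detGroup(x@detector), "/mask"))
  rhdf5::h5closeAll()
  matrix(m != 0, x@dim[1L], x@dim[2L])
})

#' Write / read a hit-selection file
#'
#' A selection file holds a single 1-D dataset \code{/timestamps} of frame
#' identifier strings.  Round trips are exact; an empty selection is valid.
#'
#' @param ids character vector of selected frame identifiers.
#' @param path HDF5 file path.
#' @return \code{writeSelection}: invisibly, the path.
#'   \code{readSelection}: the identifier vector.
#' @export
writeSelection <- function(ids, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  if (length(ids) == 0L) {
    ## explicit empty 1-D string dataset
    rhdf5::h5createDataset(path, "timestamps", dims = 0L,
                           maxdims = rhdf5::H5Sunlimited(),
                           storage.mode = "character", size = 32L,
                           chunk = 1L)
  } else {
    rhdf5::h5write(as.character(ids), path, "timestamps")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname writeSelection
#' @export
readSelection <- function(path) {
  if (!file.exists(path)) stop("malformed-selection: no such file: ", path)
  ls <- rhdf5::h5ls(path)
  if (!any(ls$name == "timestamps"))
    stop("malformed-selection: missing /timestamps dataset")
  ids <- as.character(rhdf5::h5read(path, "timestamps"))
  rhdf5::h5closeAll()
  ids
}

#' Validate a selection against a CXI dataset
#'
#' Warns, listing the orphans, when the selection references identifiers not
#' present in the dataset.
#'
#' @param ids selection identifiers (from [readSelection()]).
#' @param dataset a [CxiDataset-class] or a character vector of frame ids.
#' @return Invisibly, the orphan identifiers (empty when consistent).
#' @export
validateSelection <- function(ids, dataset) {
  have <- if (is(dataset, "CxiDataset")) frameIds(dataset) else dataset
  orphans <- setdiff(ids, have)
  if (length(orphans))
    warning("selection references ids absent from the dataset: ",
            paste(orphans, collapse = ", "))
  invisible(orphans)
}

#' Read / write a standalone bad-pixel mask file
#'
#' Mask files carry a 2-D dataset \code{/data/data} with the nonzero = bad
#' convention.
#'
#' @param path HDF5 file path.
#' @param mask logical (or 0/1) matrix, TRUE/nonzero = bad.
#' @return \code{readMaskFile}: logical matrix, TRUE = bad.
#' @export
readMaskFile <- function(path) {
  if (!file.exists(path)) stop("malformed-mask: no such file: ", path)
  ls <- rhdf5::h5ls(path)
  full <- sub("^/", "", paste(sub("^/$", "", ls$group), ls$name, sep = "/"))
  if (!any(full == "data/data"))
    stop("malformed-mask: missing /data/data dataset")
  m <- rhdf5::h5read(path, "data/data")
  rhdf5::h5closeAll()
  m != 0
}

#' @rdname readMaskFile
#' @export
writeMaskFile <- function(mask, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "data")
  rhdf5::h5write(matrix(as.integer(mask != 0), nrow(mask)), path,
                 "data/data")
  rhdf5::h5closeAll()
  invisible(path)
}
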