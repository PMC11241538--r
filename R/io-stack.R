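#' Read an angiographic frame stack
#'
#' Reads a multi-page TIFF (the package's canonical on-disk format, with a
#' JSON sidecar carrying frame times and calibration) or a multi-frame DICOM
#' file. TIFF stacks written by \code{\link{writeStack}} round-trip
#' bit-exactly for 16-bit integer data. DICOM files are converted through
#' the pydicom bridge (requires a \code{python} interpreter with
#' \code{pydicom} and \code{tifffile} on the PATH); frame times come from
#' embedded frame-time tags when present, else from index / frame rate.
#'
#' @param path path to a \code{.tif}/\code{.tiff} or DICOM file.
#' @param mmPerPx calibration override (mm per pixel); used when neither the
#'   sidecar nor the DICOM metadata provides one. An error is raised if no
#'   source provides a calibration.
#' @param frameRate fallback frame rate (fps) when no timing metadata exists.
#' @return A \linkS4class{FrameStack}.
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, mmPerPx = NULL, frameRate = 30) {
    if (!file.exists(path)) stop("cannot read '", path, "': no such file")
    if (.isDicom(path)) return(.readStackDicom(path, mmPerPx, frameRate))
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) stop("unreadable TIFF '", path,
                                               "': ", conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    dims <- lapply(pages, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
        stop("inconsistent frame shapes in '", path, "'")
    frames <- simplify2array(pages)
    if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
    storage.mode(frames) <- "double"

    side <- paste0(path, ".json")
    times <- NULL
    cal <- mmPerPx
    if (file.exists(side)) {
        meta <- jsonlite::read_json(side, simplifyVector = TRUE)
        if (!is.null(meta$times)) times <- as.numeric(meta$times)
        if (!is.null(meta$frame_rate)) frameRate <- as.numeric(meta$frame_rate)
        if (!is.null(meta$mm_per_px)) cal <- as.numeric(meta$mm_per_px)
    }
    if (is.null(cal))
        stop("no calibration: neither a sidecar 'mm_per_px' nor the ",
             "'mmPerPx' override was provided")
    if (is.null(times)) times <- (seq_along(pages) - 1) / frameRate
    FrameStack(frames, times = times, mmPerPx = cal, frameRate = frameRate)
}

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are written as 16-bit grayscale TIFF pages; intensities must lie
#' in [0, 65535] and are rounded to integers (integer-valued stacks
#' round-trip bit-exactly). Times, calibration and frame rate go to
#' \code{<path>.json}.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
    stopifnot(is(stack, "FrameStack"))
    n <- nFrames(stack)
    if (n < 1L) stop("refusing to write an empty stack")
    mx <- max(stack@frames)
    if (mx > 65535)
        stop("intensities exceed the 16-bit range (max ", mx, ")")
    pages <- lapply(seq_len(n), function(k)
        round(stack@frames[, , k]) / 65535)
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                   error = function(e) stop("cannot write '", path, "': ",
                                            conditionMessage(e)))
    jsonlite::write_json(
        list(times = stack@times, mm_per_px = stack@mmPerPx,
             frame_rate = stack@frameRate),
        paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
    invisible(path)
}

.isDicom <- function(path) {
    con <- file(path, "rb"); on.exit(close(con))
    hdr <- readBin(con, "raw", 132L)
    length(hdr) == 132L && identical(hdr[129:132], charToRaw("DICM"))
}

.readStackDicom <- function(path, mmPerPx, frameRate) {
    py <- Sys.which("python")
    if (!nzchar(py))
        stop("DICOM input requires a 'python' interpreter with pydicom ",
             "on the PATH")
    script <- system.file("python", "dicom_to_tiff.py", package = "ccia",
                          mustWork = TRUE)
    out <- tempfile(fileext = ".tif")
    status <- system2(py, c(script, shQuote(path), shQuote(out)),
                      stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(status, "status")) && attr(status, "status") != 0)
        stop("DICOM conversion failed: ", paste(status, collapse = "\n"))
    on.exit(unlink(c(out, paste0(out, ".json"))), add = TRUE)
    readStack(out, mmPerPx = mmPerPx, frameRate = frameRate)
}
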