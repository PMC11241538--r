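#' Read a CSV table against a column contract
#'
#' Thin wrapper over \code{read.csv} that enforces the presence and type of
#' the expected columns, the validation layer used by every CSV reader in
#' the package.
#'
#' @param path CSV path with a header row.
#' @param numericCols character vector of columns that must parse as
#'   numbers (empty cells become NA).
#' @param requiredCols character vector of columns that must exist;
#'   defaults to \code{numericCols}.
#' @return A \code{data.frame}.
#' @export
readTable <- function(path, numericCols = character(),
                      requiredCols = numericCols) {
    if (!file.exists(path)) stop("cannot read '", path, "': no such file")
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("malformed CSV '", path, "': ",
                                            conditionMessage(e)))
    if (nrow(df) == 0L) stop("'", path, "' contains no data rows")
    miss <- setdiff(requiredCols, names(df))
    if (length(miss))
        stop("'", path, "' is missing required column(s): ",
             paste(miss, collapse = ", "))
    for (cn in numericCols) {
        raw <- df[[cn]]
        v <- suppressWarnings(as.numeric(raw))
        bad <- !is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(v)
        if (any(bad))
            stop("non-numeric value in column '", cn, "' of '", path,
                 "' (row ", which(bad)[1L], ")")
        df[[cn]] <- v
    }
    df
}

#' Path to the packaged 15-patient results table
#'
#' A CSV transcription of the published per-patient table: vessel, proximal
#' / stenotic / distal contrast intensities, CCIA, iFR (empty where not
#' measured) and FFR for 15 patients.
#'
#' @return File path of the packaged fixture.
#' @export
patientTablePath <- function()
    system.file("extdata", "patient_results.csv", package = "ccia", mustWork = TRUE)

#' Read the packaged per-patient results table
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A 15-row \code{data.frame} with columns \code{patient},
#'   \code{vessel}, \code{proximal}, \code{stenotic}, \code{distal},
#'   \code{ccia}, \code{ifr} (NA where not measured) and \code{ffr}.
#' @export
readPatientTable <- function(path = patientTablePath()) {
    df <- readTable(path,
                    numericCols = c("patient", "proximal", "stenotic",
                                    "distal", "ccia", "ifr", "ffr"),
                    requiredCols = c("patient", "vessel", "proximal",
                                     "stenotic", "distal", "ccia", "ifr",
                                     "ffr"))
    df
}

#' Read / write ECG traces as CSV (time, voltage)
#'
#' @param path CSV path.
#' @return \code{readEcg}: an \linkS4class{EcgTrace}.
#' @export
readEcg <- function(path) {
    df <- readTable(path, numericCols = c("time", "voltage"))
    EcgTrace(df$time, df$voltage)
}

#' @rdname readEcg
#' @param ecg an \linkS4class{EcgTrace}.
#' @export
writeEcg <- function(ecg, path) {
    utils::write.csv(data.frame(time = ecg@times, voltage = ecg@voltage),
                     path, row.names = FALSE)
    invisible(path)
}

#' Read / write pressure traces as CSV (time, pa, pd)
#'
#' @param path CSV path.
#' @param pv venous pressure to attach (mmHg).
#' @return \code{readPressures}: a \linkS4class{PressureTraces}.
#' @export
readPressures <- function(path, pv = 0) {
    df <- readTable(path, numericCols = c("time", "pa", "pd"))
    PressureTraces(df$time, df$pa, df$pd, pv = pv)
}

#' @rdname readPressures
#' @param traces a \linkS4class{PressureTraces}.
#' @export
writePressures <- function(traces, path) {
    utils::write.csv(data.frame(time = traces@times, pa = traces@pa,
                                pd = traces@pd), path, row.names = FALSE)
    invisible(path)
}

#' Read / write an ROI specification as JSON
#'
#' On disk the mask is run-length encoded over the column-major pixel order
#' and all pixel coordinates are 0-based (row, col); in memory everything is
#' 1-based, matching R matrix indexing.
#'
#' @param path JSON path.
#' @return \code{readRoi}: a \linkS4class{RoiSpec}.
#' @export
readRoi <- function(path) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("shape", "mask_starts", "mask_lengths", "centerline",
              "mm_per_px")
    miss <- setdiff(need, names(js))
    if (length(miss))
        stop("ROI JSON is missing field(s): ", paste(miss, collapse = ", "))
    shape <- as.integer(js$shape)
    mask <- logical(prod(shape))
    starts <- as.integer(js$mask_starts)  # 0-based flat indices
    lens <- as.integer(js$mask_lengths)
    for (i in seq_along(starts))
        mask[starts[i] + seq_len(lens[i])] <- TRUE
    dim(mask) <- shape
    cl <- js$centerline
    if (is.list(cl)) cl <- do.call(rbind, lapply(cl, unlist))
    cl <- as.matrix(cl) + 1   # 0-based on disk -> 1-based in memory
    RoiSpec(mask, cl, js$mm_per_px)
}

#' @rdname readRoi
#' @param roi a \linkS4class{RoiSpec}.
#' @export
writeRoi <- function(roi, path) {
    flat <- as.vector(roi@stenoticMask)
    r <- rle(flat)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths      # 0-based run starts
    keep <- r$values
    jsonlite::write_json(
        list(shape = dim(roi@stenoticMask),
             mask_starts = starts[keep], mask_lengths = r$lengths[keep],
             centerline = unname(roi@centerline - 1),
             mm_per_px = roi@mmPerPx),
        path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' Serialize a time-intensity curve as CSV (time, value)
#'
#' @param curve a \linkS4class{TimeIntensityCurve}.
#' @param path CSV path.
#' @export
writeCurve <- function(curve, path) {
    utils::write.csv(data.frame(time = curve@times, value = curve@values),
                     path, row.names = FALSE)
    invisible(path)
}

#' Serialize a motion track as CSV (frame, dy, dx, score, phase)
#'
#' @param track a \linkS4class{MotionTrack}.
#' @param path CSV path.
#' @export
writeMotionTrack <- function(track, path) {
    n <- nrow(track@displacements)
    ph <- if (length(track@phases)) track@phases else rep(NA_real_, n)
    utils::write.csv(data.frame(frame = seq_len(n),
                                dy = track@displacements[, 1L],
                                dx = track@displacements[, 2L],
                                score = track@scores, phase = ph),
                     path, row.names = FALSE)
    invisible(path)
}
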