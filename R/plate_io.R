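#' Construct a single-channel microscope field image
#'
#' A `field_image` is the package's in-memory representation of one grayscale
#' fluorescence image of one microscope field: a numeric pixel matrix plus
#' the metadata needed to place it in a screen (well, field index, channel,
#' acquisition time and pixel size). Pixel coordinates are 0-based
#' (row, column) with the origin at the top-left; intensities are kept in
#' native (camera) units and never rescaled on input.
#'
#' @param pixels numeric matrix of non-negative finite intensities, at least
#'   64 x 64.
#' @param channel one of `"nuclear"` (Hoechst-like DNA stain), `"ros"`
#'   (DCF-like cytosolic ROS probe), `"tmrm"` (mitochondrial potential dye)
#'   or `"secondary"` (e.g. anti-MPO immunostain).
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param well_id well identifier such as `"B03"`.
#' @param field_index 0-based field number within the well.
#' @param time acquisition time in minutes (>= 0).
#' @return an object of class `field_image`.
#' @export
field_image <- function(pixels, channel, pixel_size = 0.6, well_id = "A01",
                        field_index = 0L, time = 0) {
    if (!is.matrix(pixels) || !is.numeric(pixels))
        stop("pixels must be a numeric matrix")
    if (any(dim(pixels) < 64L))
        stop("image dimensions must be at least 64 x 64, got ",
             paste(dim(pixels), collapse = " x "))
    if (any(!is.finite(pixels)))
        stop("pixels contain non-finite values")
    if (any(pixels < 0))
        stop("pixels contain negative intensities")
    channel <- match.arg(channel, .channels)
    if (!is.numeric(pixel_size) || pixel_size <= 0)
        stop("pixel_size must be > 0 (micrometres per pixel)")
    if (field_index < 0) stop("field_index must be >= 0")
    if (time < 0) stop("time must be >= 0 minutes")
    structure(list(pixels = pixels, channel = channel,
                   pixel_size = as.numeric(pixel_size),
                   well_id = as.character(well_id),
                   field_index = as.integer(field_index),
                   time = as.numeric(time)),
              class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
    cat(sprintf("<field_image> %s field %d, channel %s, %d x %d px (%.3g um/px), t = %g min\n",
                x$well_id, x$field_index, x$channel,
                nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$time))
    invisible(x)
}

#' Read a grayscale TIFF as one or more field images
#'
#' Reads an 8- or 16-bit grayscale TIFF without any intensity rescaling.
#' Multi-plane files yield one `field_image` per plane with consecutive
#' `field_index` starting at `field_index`.
#'
#' @param path path to a TIFF file.
#' @inheritParams field_image
#' @return a single `field_image`, or a list of them for multi-plane files.
#' @export
read_image <- function(path, channel = "nuclear", pixel_size = 0.6,
                       well_id = "A01", field_index = 0L, time = 0) {
    if (!file.exists(path)) stop("file not found: ", path)
    planes <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                       error = function(e)
                           stop("unreadable TIFF '", path, "': ",
                                conditionMessage(e)))
    imgs <- lapply(seq_along(planes), function(k) {
        p <- planes[[k]]
        if (length(dim(p)) != 2L)
            stop("file '", path, "' plane ", k,
                 " is not single-channel grayscale (RGB/paletted input is not supported)")
        if (any(!is.finite(p)))
            stop("file '", path, "' plane ", k, " contains non-finite pixels")
        field_image(p, channel = channel, pixel_size = pixel_size,
                    well_id = well_id,
                    field_index = field_index + k - 1L, time = time)
    })
    if (length(imgs) == 1L) imgs[[1L]] else imgs
}

#' Write a field image to a grayscale TIFF
#'
#' Intensities are stored as unsigned integers at the requested bit depth;
#' values must already lie in `[0, 2^bits - 1]` (no rescaling is applied).
#'
#' @param img a `field_image`.
#' @param path output path.
#' @param bits bits per sample, 8 or 16 (default 16).
#' @export
write_image <- function(img, path, bits = 16L) {
    stopifnot(inherits(img, "field_image"))
    if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
    mx <- 2^bits - 1
    px <- img$pixels
    if (any(px > mx))
        stop("pixel values exceed ", mx, " (", bits, "-bit range)")
    tiff::writeTIFF(round(px) / mx, path, bits.per.sample = as.integer(bits))
    invisible(path)
}

.layout_columns <- c("well_id", "role", "stimulus", "stimulus_conc",
                     "compound_id", "compound_conc", "timepoint_min",
                     "replicate")

#' Construct and validate a plate layout
#'
#' The layout table is the plate's single source of truth for experimental
#' design: per well it records the control role, the NETosis stimulus (PMA in
#' nM or ionomycin in uM), the test compound and its concentration (uM), the
#' endpoint timepoint (min) and the replicate number. Validation is total:
#' every violated constraint is collected and reported in one error.
#'
#' @param df data.frame with columns `well_id`, `role`, `stimulus`,
#'   `stimulus_conc`, `compound_id`, `compound_conc`, `timepoint_min`,
#'   `replicate`. Extra columns are preserved as opaque annotations.
#' @return a `plate_layout` (validated data.frame).
#' @export
plate_layout <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.layout_columns, names(df))
    if (length(missing_cols))
        stop("layout is missing required columns: ",
             paste(missing_cols, collapse = ", "))
    df$well_id <- as.character(df$well_id)
    df$compound_id <- ifelse(is.na(df$compound_id), "",
                             as.character(df$compound_id))
    problems <- character()
    dup <- unique(df$well_id[duplicated(df$well_id)])
    if (length(dup))
        problems <- c(problems, paste0("duplicated well_id: ",
                                       paste(dup, collapse = ", ")))
    bad_id <- df$well_id[!grepl("^[A-P][0-9]{2}$", df$well_id)]
    if (length(bad_id))
        problems <- c(problems, paste0("malformed well_id (expect e.g. 'B03'): ",
                                       paste(unique(bad_id), collapse = ", ")))
    bad_role <- unique(df$role[!df$role %in% .roles])
    if (length(bad_role))
        problems <- c(problems, paste0("unknown role: ",
                                       paste(bad_role, collapse = ", ")))
    bad_stim <- unique(df$stimulus[!df$stimulus %in% .stimuli])
    if (length(bad_stim))
        problems <- c(problems, paste0("unknown stimulus: ",
                                       paste(bad_stim, collapse = ", ")))
    for (col in c("stimulus_conc", "compound_conc", "timepoint_min")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (any(is.na(v)) || any(v < 0))
            problems <- c(problems, paste0(col, " must be numeric and >= 0"))
        df[[col]] <- v
    }
    rep_ok <- suppressWarnings(as.integer(df$replicate))
    if (any(is.na(rep_ok)) || any(rep_ok < 1))
        problems <- c(problems, "replicate must be a positive integer")
    df$replicate <- rep_ok
    neg <- df$role == "negative_control"
    if (any(neg & (df$stimulus != "none" | df$compound_id != ""), na.rm = TRUE))
        problems <- c(problems,
            paste0("negative_control wells must have stimulus 'none' and no compound: ",
                   paste(df$well_id[neg & (df$stimulus != "none" |
                                           df$compound_id != "")],
                         collapse = ", ")))
    pos <- df$role == "positive_control"
    if (any(pos & (df$stimulus == "none" | df$compound_id != ""), na.rm = TRUE))
        problems <- c(problems,
            paste0("positive_control wells must be stimulated and compound-free: ",
                   paste(df$well_id[pos & (df$stimulus == "none" |
                                           df$compound_id != "")],
                         collapse = ", ")))
    if (length(problems))
        stop("invalid plate layout:\n  - ",
             paste(problems, collapse = "\n  - "))
    class(df) <- c("plate_layout", "data.frame")
    df
}

#' Read a plate-layout CSV
#' @param path CSV file with the columns documented in [plate_layout()].
#' @return a validated `plate_layout`.
#' @export
read_layout <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    plate_layout(read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(well_id = "character")))
}

#' Write a plate layout to CSV
#' @param layout a `plate_layout`.
#' @param path output CSV path.
#' @export
write_layout <- function(layout, path) {
    stopifnot(inherits(layout, "plate_layout"))
    write.csv(as.data.frame(layout), path, row.names = FALSE)
    invisible(path)
}

# Shared CSV writer for feature/summary tables: fixed column order, >= 6
# significant digits for floats.
.write_table <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 9,
                                                   format = "g"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a per-cell feature table to CSV
#'
#' One row per cell; identifying columns first (`well_id`, `field_index`,
#' `cell_id`, and `phenotype`/`flag` columns when present), then feature
#' columns in their stored order. All records must share the same feature
#' set. Floats are printed with at least 6 significant digits.
#'
#' @param cells data.frame of per-cell records (e.g. from
#'   [extract_features()]).
#' @param path output CSV path.
#' @export
write_cell_table <- function(cells, path) {
    if (is.null(cells) || (is.data.frame(cells) && nrow(cells) == 0L)) {
        cells <- as.data.frame(cells)
    }
    if (!is.data.frame(cells)) stop("cells must be a data.frame")
    .write_table(cells, path)
}

#' Read a per-cell feature table written by [write_cell_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cell_table <- function(path) {
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(well_id = "character"))
}

#' Write per-well summaries to CSV
#' @param summaries data.frame of well summaries (see [summarize_wells()]).
#' @param path output CSV path.
#' @export
write_well_table <- function(summaries, path) {
    if (!is.data.frame(summaries)) stop("summaries must be a data.frame")
    .write_table(summaries, path)
}

#' Read a per-well summary table written by [write_well_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_well_table <- function(path) {
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(well_id = "character"))
}

#' Bind ragged per-cell record lists into one table
#'
#' Internal convenience used by the pipeline: checks that all records carry
#' the same feature columns and rbinds them.
#' @noRd
.bind_cells <- function(lst) {
    lst <- lst[vapply(lst, function(x) !is.null(x) && nrow(x) > 0, logical(1))]
    if (!length(lst)) return(NULL)
    cols <- lapply(lst, names)
    if (length(unique(vapply(cols, paste, character(1), collapse = "\r"))) != 1L)
        stop("ragged feature sets: records do not share the same columns")
    do.call(rbind, lst)
}
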