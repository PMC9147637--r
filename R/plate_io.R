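# Assay modalities and their fixed read wavelengths. The bubble check is a
# separate 680 nm read taken within the first read window.
MODALITY_DEFS <- list(
  NBT_ABS = list(name = "NBT_ABS", probe = "4-nitrobenzenethiol",
                 measure_nm = 412, signal_kind = "absorbance",
                 dynamic_range_max = 4.0),
  PDA_ABS = list(name = "PDA_ABS", probe = "pyridoxylamine",
                 measure_nm = 324, signal_kind = "absorbance",
                 dynamic_range_max = 4.0),
  PDA_FLUOR = list(name = "PDA_FLUOR", probe = "pyridoxylamine",
                   excitation_nm = 324, emission_nm = 398,
                   signal_kind = "fluorescence",
                   dynamic_range_max = 1e5)
)

TIMEPOINTS_MIN <- c(5, 20, 35, 50)

#' Assay modality descriptor
#'
#' @param name `"NBT_ABS"` (thiol probe, absorbance 412 nm), `"PDA_ABS"`
#'   (amine probe, absorbance 324 nm) or `"PDA_FLUOR"` (amine probe,
#'   fluorescence ex 324 / em 398 nm).
#' @return list with the fixed wavelengths, signal kind and default
#'   instrument dynamic-range ceiling.
#' @export
assay_modality <- function(name) {
  if (!name %in% names(MODALITY_DEFS)) {
    stop("unknown modality '", name, "'; expected one of ",
         paste(names(MODALITY_DEFS), collapse = ", "), call. = FALSE)
  }
  MODALITY_DEFS[[name]]
}

#' Construct a validated plate reading
#'
#' @param values 8 x 12 numeric matrix of instrument values.
#' @param plate_id identifier string.
#' @param modality modality name or `"BUBBLE_680"` for the bubble-test read.
#' @param timepoint_min read time in minutes (5, 20, 35 or 50).
#' @return object of class `easa_plate`.
#' @export
plate_reading <- function(values, plate_id, modality, timepoint_min) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(8, 12))) {
    stop("plate matrix must be 8 x 12, got ", nrow(values), " x ",
         ncol(values), call. = FALSE)
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-finite value at well ", LETTERS[bad[1]], bad[2], call. = FALSE)
  }
  is_bubble <- identical(modality, "BUBBLE_680")
  if (!is_bubble) {
    md <- assay_modality(modality)
    if (md$signal_kind == "absorbance" && any(values < -0.1)) {
      stop("absorbance below the -0.1 baseline tolerance", call. = FALSE)
    }
    if (md$signal_kind == "fluorescence" && any(values < 0)) {
      stop("negative fluorescence value", call. = FALSE)
    }
    if (!timepoint_min %in% TIMEPOINTS_MIN) {
      stop("timepoint_min must be one of ",
           paste(TIMEPOINTS_MIN, collapse = ", "), call. = FALSE)
    }
  }
  dimnames(values) <- list(LETTERS[1:8], as.character(1:12))
  structure(
    list(plate_id = as.character(plate_id), modality = modality,
         timepoint_min = timepoint_min, values = values),
    class = "easa_plate"
  )
}

#' Read one plate-reader matrix from CSV
#'
#' Accepts a plain 8 x 12 numeric grid; an optional header row of column
#' numbers 1..12 and an optional first column of row letters A..H are
#' auto-detected and stripped. The numeric block itself is parsed strictly:
#' any malformed cell is reported with its well coordinate.
#'
#' @param path CSV file path.
#' @inheritParams plate_reading
#' @return `easa_plate`.
#' @export
read_plate_csv <- function(path, plate_id, modality, timepoint_min) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  # drop an optional header row ("", 1..12) and row-label column (A..H)
  first_row_labels <- all(raw[1, ] %in% c("", as.character(1:12), paste0("X", 1:12)))
  if (first_row_labels) raw <- raw[-1, , drop = FALSE]
  first_col_labels <- all(toupper(raw[[1]]) %in% LETTERS[1:8])
  if (first_col_labels) raw <- raw[, -1, drop = FALSE]
  if (nrow(raw) != 8) {
    stop("expected 8 data rows, found ", nrow(raw), " in ", path, call. = FALSE)
  }
  if (ncol(raw) != 12) {
    stop("expected 12 data columns, found ", ncol(raw), " in ", path,
         call. = FALSE)
  }
  vals <- matrix(NA_real_, 8, 12)
  for (i in 1:8) for (j in 1:12) {
    cell <- raw[i, j]
    x <- suppressWarnings(as.numeric(cell))
    if (is.na(x)) {
      stop("cannot parse cell '", cell, "' at well ", LETTERS[i], j,
           call. = FALSE)
    }
    vals[i, j] <- x
  }
  plate_reading(vals, plate_id, modality, timepoint_min)
}

#' Write a plate matrix to CSV (with row/column labels)
#'
#' @param plate an `easa_plate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "easa_plate"))
  df <- cbind(data.frame(row = LETTERS[1:8]), as.data.frame(plate$values))
  names(df) <- c("", as.character(1:12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

CALL_TOKENS <- list(
  dpra_call   = c("binder", "nonbinder", "inconclusive"),
  invivo_call = c("sensitizer", "nonsensitizer"),
  invivo_assay = c("llna", "gpmt"),
  ke2_call    = c("positive", "negative"),
  ke3_call    = c("positive", "negative"),
  easa_call   = c("binder", "nonbinder", "inconclusive")
)

normalize_call <- function(x, field) {
  x <- trimws(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  ok <- CALL_TOKENS[[field]]
  # canonical capitalisation for the assay tokens
  canon <- if (field == "invivo_assay") toupper(x) else x
  bad <- !is.na(x) & !x %in% ok
  if (any(bad)) {
    stop("invalid ", field, " token(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; accepted: ", paste(ok, collapse = ", "), call. = FALSE)
  }
  canon
}

#' Read the chemical reference table
#'
#' Parses a CSV with columns `chemical`, `cas`, `dpra_call`, `invivo_call`,
#' `invivo_assay`, `ec3` and optional `ke2_call`, `ke3_call`, `easa_call`.
#' Call tokens are normalised case-insensitively; blank cells become
#' missing. `inconclusive` is a distinct token, never missing. EC3 is
#' carried as verbatim text metadata (printed values include ranges) and is
#' never used in any computation.
#'
#' @param path CSV file path, or `NULL` for the packaged transcription of
#'   the published 92-chemical reference panel.
#' @return data frame of class `easa_reference`, one row per chemical.
#' @export
read_reference_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_table1.csv", package = "easa96",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  need <- c("chemical", "cas", "dpra_call", "invivo_call", "invivo_assay", "ec3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("reference table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("ke2_call", "ke3_call", "easa_call")) {
    if (!f %in% names(df)) df[[f]] <- NA_character_
  }
  out <- data.frame(
    chemical = trimws(df$chemical),
    cas = trimws(df$cas),
    dpra_call = normalize_call(df$dpra_call, "dpra_call"),
    invivo_call = normalize_call(df$invivo_call, "invivo_call"),
    invivo_assay = normalize_call(df$invivo_assay, "invivo_assay"),
    ec3 = ifelse(trimws(df$ec3) == "", NA_character_, trimws(df$ec3)),
    ke2_call = normalize_call(df$ke2_call, "ke2_call"),
    ke3_call = normalize_call(df$ke3_call, "ke3_call"),
    easa_call = normalize_call(df$easa_call, "easa_call"),
    stringsAsFactors = FALSE
  )
  bad <- xor(is.na(out$invivo_call), is.na(out$invivo_assay))
  if (any(bad)) {
    stop("in vivo call and assay must be present together; offending row(s): ",
         paste(out$chemical[bad], collapse = ", "), call. = FALSE)
  }
  odd_ec3 <- !is.na(out$ec3) & !is.na(out$invivo_call) &
    out$invivo_call != "sensitizer"
  if (any(odd_ec3)) {
    warning("EC3 recorded for non-sensitizer(s): ",
            paste(out$chemical[odd_ec3], collapse = ", "),
            " (kept as metadata)", call. = FALSE)
  }
  class(out) <- c("easa_reference", "data.frame")
  out
}

#' Write a run result set to JSON
#'
#' Results round-trip losslessly through [read_results()]; non-finite
#' numbers (e.g. a depletion that could not be computed for an excluded
#' modality) serialize as `null` and restore as `NA`.
#'
#' @param results a list-like run result set (see [analyze_run()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  payload <- list(schema_version = 1L, results = scrub_nonfinite(results))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null",
                         digits = NA, null = "null", pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}

#' Read a run result set written by [write_results()]
#'
#' @param path JSON file path.
#' @return the restored result list.
#' @export
read_results <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  if (is.null(payload$schema_version)) {
    stop("not an easa96 results file (schema_version missing)", call. = FALSE)
  }
  restore_null(payload$results)
}

# NaN/Inf cannot be represented in JSON; map them to NA (-> null) on write.
# Custom S3 classes are stripped to plain lists (data frames kept).
scrub_nonfinite <- function(x) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) {
      if (is.numeric(col)) col[!is.finite(col)] <- NA_real_
      col
    })
    return(x)
  }
  if (is.list(x)) return(lapply(unclass(x), scrub_nonfinite))
  if (is.numeric(x)) {
    x <- unclass(x)
    x[!is.finite(x)] <- NA_real_
  }
  x
}

restore_null <- function(x) {
  if (is.list(x)) {
    x[vapply(x, is.null, logical(1))] <- NA
    return(lapply(x, restore_null))
  }
  x
}
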