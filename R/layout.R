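# Fixed 96-well design shared by all three assay modalities:
#   column 1            : plate blank (solvent system, no probe)   -> BLANK_SS (8)
#   column 2 + row A 3-9: negative controls (probe in solvent)     -> NEG_CONTROL (15)
#   rows B-H, cols 3-5  : positive-control 1:2 serial dilution,
#                         level 1 (top) in row B ... level 7 in H,
#                         triplicate across columns 3-5            -> PC (21)
#   rows B-H, cols 6-9  : test compound + probe, one TC per row    -> TC_PROBE (28)
#   rows B-H, cols 10-12: test compound without probe              -> TC_BLANK (21)
#   row A, cols 10-12   : solvent system only, unused by analysis  -> AUX_SS (3)

WELL_ROLES <- c("BLANK_SS", "NEG_CONTROL", "PC", "TC_PROBE", "TC_BLANK", "AUX_SS")

#' Build the fixed 96-well plate layout
#'
#' Maps every well of the 8 x 12 plate to its role in the assay design and
#' binds up to seven test-compound identifiers to rows B-H (slot 1 = row B).
#' Unused TC rows keep their `TC_PROBE`/`TC_BLANK` roles but carry an empty
#' slot name and are skipped by the analysis.
#'
#' @param tc_slot_names character vector of at most 7 chemical identifiers.
#' @return An object of class `easa_layout`: a data frame with one row per
#'   well (`well`, `row`, `col`, `kind`, `pc_level`, `pc_rep`, `tc_slot`,
#'   `tc_rep`, `slot_name`) and attribute `tc_slot_names`.
#' @examples
#' lay <- build_layout(c("cinnamal", "glycerol"))
#' well_role(lay, "B6")   # TC_PROBE, slot 1, rep 1
#' @export
build_layout <- function(tc_slot_names = character()) {
  tc_slot_names <- as.character(tc_slot_names)
  if (length(tc_slot_names) > 7) {
    stop("plate capacity is 7 test compounds per run, got ",
         length(tc_slot_names), call. = FALSE)
  }
  if (anyDuplicated(tc_slot_names)) {
    stop("duplicate test-compound identifiers in tc_slot_names", call. = FALSE)
  }
  rows <- LETTERS[1:8]
  grid <- expand.grid(col = 1:12, row = rows, stringsAsFactors = FALSE)
  grid <- grid[order(grid$row, grid$col), c("row", "col")]
  n <- nrow(grid)
  kind <- character(n)
  pc_level <- pc_rep <- tc_slot <- tc_rep <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- grid$row[i]; cl <- grid$col[i]
    ri <- match(r, rows) - 1L  # 0 for A, 1 for B ... 7 for H
    if (cl == 1) {
      kind[i] <- "BLANK_SS"
    } else if (cl == 2 || (r == "A" && cl <= 9)) {
      kind[i] <- "NEG_CONTROL"
    } else if (r == "A") {
      kind[i] <- "AUX_SS"
    } else if (cl <= 5) {
      kind[i] <- "PC"; pc_level[i] <- ri; pc_rep[i] <- cl - 2L
    } else if (cl <= 9) {
      kind[i] <- "TC_PROBE"; tc_slot[i] <- ri; tc_rep[i] <- cl - 5L
    } else {
      kind[i] <- "TC_BLANK"; tc_slot[i] <- ri; tc_rep[i] <- cl - 9L
    }
  }
  slot_name <- rep(NA_character_, n)
  used <- !is.na(tc_slot) & tc_slot <= length(tc_slot_names)
  slot_name[used] <- tc_slot_names[tc_slot[used]]
  out <- data.frame(
    well = paste0(grid$row, grid$col),
    row = grid$row, col = grid$col, kind = kind,
    pc_level = pc_level, pc_rep = pc_rep,
    tc_slot = tc_slot, tc_rep = tc_rep, slot_name = slot_name,
    stringsAsFactors = FALSE
  )
  attr(out, "tc_slot_names") <- tc_slot_names
  class(out) <- c("easa_layout", "data.frame")
  out
}

#' Look up the role of a single well
#'
#' @param layout an `easa_layout`.
#' @param well well name such as `"B6"` (row letter A-H + column 1-12).
#' @return One-row data frame with the well's role fields.
#' @export
well_role <- function(layout, well) {
  stopifnot(inherits(layout, "easa_layout"))
  i <- match(well, layout$well)
  if (is.na(i)) stop("unknown well: ", well, call. = FALSE)
  layout[i, , drop = FALSE]
}

#' Enumerate the wells holding a given role
#'
#' Returns wells in deterministic row-major order (row A first, columns
#' ascending within a row).
#'
#' @param layout an `easa_layout`.
#' @param kind one of `BLANK_SS`, `NEG_CONTROL`, `PC`, `TC_PROBE`,
#'   `TC_BLANK`, `AUX_SS`.
#' @param slot optional TC slot number (1-7), only for the TC kinds.
#' @param pc_level optional dilution level (1-7), only for `PC`.
#' @return character vector of well names.
#' @export
wells_for_role <- function(layout, kind, slot = NULL, pc_level = NULL) {
  stopifnot(inherits(layout, "easa_layout"))
  if (!kind %in% WELL_ROLES) {
    stop("unknown well role '", kind, "'; expected one of ",
         paste(WELL_ROLES, collapse = ", "), call. = FALSE)
  }
  if (!is.null(slot) && !kind %in% c("TC_PROBE", "TC_BLANK")) {
    stop("slot is only meaningful for TC_PROBE/TC_BLANK", call. = FALSE)
  }
  sel <- layout$kind == kind
  if (!is.null(slot)) sel <- sel & !is.na(layout$tc_slot) & layout$tc_slot == slot
  if (!is.null(pc_level)) sel <- sel & !is.na(layout$pc_level) & layout$pc_level == pc_level
  layout$well[sel]
}

#' Serialize a layout to JSON (well -> role audit map)
#'
#' @param layout an `easa_layout`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return path (invisibly) or JSON string.
#' @export
layout_to_json <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "easa_layout"))
  obj <- list(
    tc_slot_names = attr(layout, "tc_slot_names"),
    wells = as.data.frame(layout)
  )
  js <- jsonlite::toJSON(obj, dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore a layout from its JSON serialization
#'
#' @param path_or_json file path or a JSON string produced by
#'   [layout_to_json()].
#' @return an `easa_layout`.
#' @export
layout_from_json <- function(path_or_json) {
  obj <- jsonlite::fromJSON(path_or_json)
  names <- as.character(obj$tc_slot_names)
  lay <- build_layout(names)
  # verify the audit map round-trips onto the canonical design
  w <- obj$wells
  w <- w[match(lay$well, w$well), ]
  if (!identical(w$kind, lay$kind)) {
    stop("layout JSON does not match the canonical 96-well design", call. = FALSE)
  }
  lay
}

# Positive-control concentration series: level k is top * 2^(1 - k),
# from 40 uL of stock in a 200 uL final volume (stock/5 at the top level).
PC_TOP_CONC <- c(NBT_ABS = 0.6, PDA_ABS = 0.2, PDA_FLUOR = 0.02)  # mmol/L

#' Positive-control concentrations for the seven dilution levels
#'
#' Level 1 (row B) holds the top concentration; each level below is a 1:2
#' dilution. Defaults are 0.6 mmol/L benzyl bromide for the thiol-probe
#' absorbance assay and 0.2 / 0.02 mmol/L glutaraldehyde for the amine-probe
#' absorbance / fluorescence assays (stock diluted 1:5 into the well).
#'
#' @param modality modality name (see [assay_modality()]) or `NULL` when
#'   `top` is given directly.
#' @param top optional top concentration in mmol/L, overriding the default.
#' @return numeric vector of 7 concentrations (mmol/L), level 1 first.
#' @export
pc_concentrations <- function(modality = "NBT_ABS", top = NULL) {
  if (is.null(top)) {
    if (!modality %in% names(PC_TOP_CONC)) {
      stop("no default PC top concentration for modality ", modality, call. = FALSE)
    }
    top <- PC_TOP_CONC[[modality]]
  }
  top * 2^(1 - seq_len(7))
}
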