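# Probe-depletion arithmetic. All quantities derive from the 50-minute
# analysis read of one plate:
#
#   window          = mean(NC) - mean(blank)          (assay signal window)
#   depletion (abs) = window - (mean(TC) - mean(TC blank))
#   % depletion     = 100 * depletion / window
#
# Sample SDs use the n-1 denominator; n is the number of wells actually
# included after QC exclusion (nominally 15 NC, 8 blank, 4 TC, 3 TC blank).

group_summary <- function(values) {
  n <- length(values)
  list(mean = if (n) mean(values) else NA_real_,
       sd = if (n >= 2) stats::sd(values) else NA_real_,
       n = n, values = values)
}

#' Summarize a plate reading into per-group means, SDs and counts
#'
#' Computes the plate-wide blank and negative-control summaries, the seven
#' positive-control dilution-level summaries, and per-slot test-compound /
#' test-compound-blank summaries, after dropping QC-excluded wells. Slots
#' with no bound chemical are skipped.
#'
#' @param reading an `easa_plate` (normally the 50-minute analysis read).
#' @param layout an `easa_layout`.
#' @param excluded character vector of QC-excluded well names.
#' @return list of class `easa_groups` with components `blank`, `nc`,
#'   `pc` (list indexed by dilution level), `slots` (list indexed by slot
#'   number, each with `name`, `tc`, `tc_blank`), and `window`.
#' @export
summarize_groups <- function(reading, layout, excluded = character()) {
  stopifnot(inherits(reading, "easa_plate"), inherits(layout, "easa_layout"))
  vals <- reading$values
  value_at <- function(wells) {
    wells <- setdiff(wells, excluded)
    vapply(wells, function(w) {
      vals[match(substr(w, 1, 1), LETTERS), as.integer(substring(w, 2))]
    }, numeric(1))
  }
  take <- function(wells, label) {
    v <- value_at(wells)
    if (length(v) == 0) {
      stop("all wells of group '", label, "' were excluded", call. = FALSE)
    }
    group_summary(v)
  }
  blank <- take(wells_for_role(layout, "BLANK_SS"), "blank")
  nc <- take(wells_for_role(layout, "NEG_CONTROL"), "NC")
  if (!(nc$mean > blank$mean)) {
    stop("no signal window: NC mean (", signif(nc$mean, 4),
         ") does not exceed blank mean (", signif(blank$mean, 4), ")",
         call. = FALSE)
  }
  pc <- lapply(1:7, function(lv) {
    take(wells_for_role(layout, "PC", pc_level = lv), paste0("PC level ", lv))
  })
  slot_names <- attr(layout, "tc_slot_names")
  slots <- list()
  for (s in seq_along(slot_names)) {
    slots[[s]] <- list(
      name = slot_names[s],
      tc = take(wells_for_role(layout, "TC_PROBE", slot = s),
                paste0("TC slot ", s, " (", slot_names[s], ")")),
      tc_blank = take(wells_for_role(layout, "TC_BLANK", slot = s),
                      paste0("TC blank slot ", s, " (", slot_names[s], ")"))
    )
  }
  structure(list(blank = blank, nc = nc, pc = pc, slots = slots,
                 window = nc$mean - blank$mean),
            class = "easa_groups")
}

#' Percentage depletion of a single control well
#'
#' For negative-control or positive-control wells:
#' `(1 - (value - blank_mean) / (nc_mean - blank_mean)) * 100`.
#'
#' @param value single-well signal (or vector of them).
#' @param nc_mean negative-control mean.
#' @param blank_mean solvent-blank mean.
#' @return percentage depletion (vectorised over `value`).
#' @export
control_pct_depletion <- function(value, nc_mean, blank_mean) {
  if (!(nc_mean > blank_mean)) {
    stop("no signal window: NC mean must exceed blank mean", call. = FALSE)
  }
  (1 - (value - blank_mean) / (nc_mean - blank_mean)) * 100
}

#' Test-compound depletion from group summaries
#'
#' Absolute depletion is the signal window minus the interference-corrected
#' test-compound signal, `(NC - blank) - (TC - TC_blank)` on the group
#' means; percentage depletion divides by the window. Negative values
#' (signal gain in the TC wells) are returned as computed; anomaly handling
#' belongs to the classifier.
#'
#' @param groups an `easa_groups` from [summarize_groups()].
#' @param slot TC slot number.
#' @return list with `depletion_abs`, `pct_depletion`, `window`, `slot`,
#'   `chemical`.
#' @export
tc_depletion <- function(groups, slot) {
  stopifnot(inherits(groups, "easa_groups"))
  sl <- groups$slots[[slot]]
  if (is.null(sl)) stop("no chemical bound to slot ", slot, call. = FALSE)
  window <- groups$window
  dep <- window - (sl$tc$mean - sl$tc_blank$mean)
  list(depletion_abs = dep,
       pct_depletion = 100 * dep / window,
       window = window, slot = slot, chemical = sl$name)
}

# Per-well % depletion of the NC wells against their own mean; its SD is
# the basis of the k-times-SD classification rule.
nc_pct_sd <- function(groups) {
  stopifnot(inherits(groups, "easa_groups"))
  stats::sd(control_pct_depletion(groups$nc$values, groups$nc$mean,
                                  groups$blank$mean))
}
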