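# In-process controls: the 680 nm bubble test, TC interference, pipetting
# variability / column trend, and 3-SD control charting of run parameters
# across plates.

#' QC specification
#'
#' @param bubble_abs_threshold 680 nm absorbance above which a well is
#'   excluded on the absorbance assays (default 0.081 AU; the background
#'   mode sits near 0.066 and ~1 % of wells exceed the threshold).
#' @param bubble_fluor_threshold the corresponding instrument-scale
#'   threshold for the fluorescence assay (default 5300), chosen to limit
#'   bubble bias to under 1 %.
#' @param interference_k multiplier on the blank SD beyond which the
#'   TC-blank offset is flagged as interference (default 3; advisory, the
#'   result is reported but "treated with caution").
#' @param trend_alpha significance level for the NC column-trend slope
#'   (default 0.05).
#' @param chart_k control-chart multiplier (fixed at 3 SD).
#' @param chart_min_history accepted runs required before charting
#'   activates (default 5).
#' @param neg_depletion_anomaly carried alongside classification defaults
#'   (default -20 %).
#' @param dynamic_range_max optional named vector overriding the
#'   per-modality instrument ceilings.
#' @return list of class `easa_qc_spec`.
#' @export
qc_spec <- function(bubble_abs_threshold = 0.081,
                    bubble_fluor_threshold = 5300,
                    interference_k = 3,
                    trend_alpha = 0.05,
                    chart_k = 3,
                    chart_min_history = 5,
                    neg_depletion_anomaly = -20,
                    dynamic_range_max = NULL) {
  stopifnot(bubble_abs_threshold > 0, bubble_fluor_threshold > 0,
            interference_k > 0, trend_alpha > 0, trend_alpha < 1,
            chart_min_history >= 1, neg_depletion_anomaly < 0)
  structure(list(bubble_abs_threshold = bubble_abs_threshold,
                 bubble_fluor_threshold = bubble_fluor_threshold,
                 interference_k = interference_k,
                 trend_alpha = trend_alpha,
                 chart_k = chart_k,
                 chart_min_history = chart_min_history,
                 neg_depletion_anomaly = neg_depletion_anomaly,
                 dynamic_range_max = dynamic_range_max),
            class = "easa_qc_spec")
}

dyn_range_max <- function(spec, modality) {
  if (!is.null(spec$dynamic_range_max) &&
      modality %in% names(spec$dynamic_range_max)) {
    return(spec$dynamic_range_max[[modality]])
  }
  assay_modality(modality)$dynamic_range_max
}

#' Bubble test: exclude wells with an elevated 680 nm read
#'
#' @param reading680 the `BUBBLE_680` plate read (taken within the first
#'   read window).
#' @param layout an `easa_layout` (all 96 wells are screened).
#' @param spec an `easa_qc_spec`.
#' @param modality the assay modality the exclusions will apply to; it
#'   selects the absorbance or fluorescence threshold.
#' @return character vector of excluded well names, with a `reason`
#'   attribute (`"bubble"`).
#' @export
bubble_test <- function(reading680, layout, spec = qc_spec(),
                        modality = "NBT_ABS") {
  if (is.null(reading680)) {
    stop("QC incomplete: no 680 nm bubble read; plate cannot be accepted",
         call. = FALSE)
  }
  stopifnot(inherits(reading680, "easa_plate"))
  thr <- if (assay_modality(modality)$signal_kind == "fluorescence") {
    spec$bubble_fluor_threshold
  } else {
    spec$bubble_abs_threshold
  }
  hit <- which(reading680$values > thr, arr.ind = TRUE)
  out <- if (nrow(hit)) paste0(LETTERS[hit[, 1]], hit[, 2]) else character()
  out <- out[order(match(substr(out, 1, 1), LETTERS),
                   as.integer(substring(out, 2)))]
  attr(out, "reason") <- rep("bubble", length(out))
  out
}

#' Test-compound interference check
#'
#' Compares each slot's TC-blank mean with the plate blank mean: an offset
#' beyond `interference_k` blank SDs flags interference (advisory). A
#' TC-blank mean above the instrument's dynamic-range ceiling marks the
#' slot's result as not available for this modality.
#'
#' @param groups an `easa_groups`.
#' @param spec an `easa_qc_spec`.
#' @param modality modality name (for the dynamic-range ceiling).
#' @return data frame with one row per bound slot: `slot`, `chemical`,
#'   `offset`, `flagged`, `assay_na`.
#' @export
interference_check <- function(groups, spec = qc_spec(), modality = "NBT_ABS") {
  stopifnot(inherits(groups, "easa_groups"))
  dmax <- dyn_range_max(spec, modality)
  if (length(groups$slots) == 0) {
    return(data.frame(slot = integer(), chemical = character(),
                      offset = numeric(), flagged = logical(),
                      assay_na = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(groups$slots), function(s) {
    sl <- groups$slots[[s]]
    off <- sl$tc_blank$mean - groups$blank$mean
    data.frame(slot = s, chemical = sl$name, offset = off,
               flagged = abs(off) > spec$interference_k * groups$blank$sd,
               assay_na = sl$tc_blank$mean > dmax,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pipetting variability and column-trend QC
#'
#' Within-stroke CV comes from the column-2 NC wells (one multichannel
#' stroke); between-stroke CV from the row-A NC wells, columns 2-9 (one per
#' stroke). The trend test is an ordinary least-squares regression of the
#' row-A NC value on column index with a two-sided p value for a nonzero
#' slope. A significant trend is a warning, not a plate rejection.
#'
#' @param reading analysis-read `easa_plate`.
#' @param layout an `easa_layout`.
#' @param spec an `easa_qc_spec`.
#' @param excluded QC-excluded wells to drop.
#' @return list with `within_step_cv`, `between_step_cv`, `trend_slope`,
#'   `trend_p`, `trend_warning` (all CVs in %).
#' @export
pipetting_qc <- function(reading, layout, spec = qc_spec(),
                         excluded = character()) {
  vals <- reading$values
  nc_wells <- wells_for_role(layout, "NEG_CONTROL")
  grab <- function(wells) {
    wells <- setdiff(wells, excluded)
    vapply(wells, function(w) vals[match(substr(w, 1, 1), LETTERS),
                                   as.integer(substring(w, 2))], numeric(1))
  }
  col2 <- grab(grep("^[A-H]2$", nc_wells, value = TRUE))
  rowA <- grep("^A[2-9]$", nc_wells, value = TRUE)
  rowA <- setdiff(rowA, excluded)
  ra <- grab(rowA)
  if (length(ra) < 3) {
    stop("QC incomplete: fewer than 3 row-A NC wells for the trend test",
         call. = FALSE)
  }
  cols <- as.integer(substring(rowA, 2))
  if (stats::sd(ra) == 0) {
    slope <- 0; p <- 1  # constant strokes: no trend by construction
  } else {
    fit <- stats::lm(ra ~ cols)
    sm <- summary(fit)$coefficients
    slope <- unname(sm["cols", "Estimate"])
    p <- if (nrow(sm) < 2 || is.nan(sm["cols", "Pr(>|t|)"])) 1 else
      unname(sm["cols", "Pr(>|t|)"])
  }
  list(within_step_cv = 100 * stats::sd(col2) / mean(col2),
       between_step_cv = 100 * stats::sd(ra) / mean(ra),
       trend_slope = slope, trend_p = p,
       trend_warning = p < spec$trend_alpha)
}

#' Initialize an empty control-chart state
#'
#' @return list of class `easa_chart` holding the accepted-run history of
#'   the four charted parameters (blank mean, NC mean, NC CV %, PC IC50).
#' @export
chart_state <- function() {
  structure(list(history = data.frame(ss_mean = numeric(), nc_mean = numeric(),
                                      nc_cv = numeric(), pc_ic50 = numeric())),
            class = "easa_chart")
}

#' Update a control chart with a new run
#'
#' Once at least `chart_min_history` accepted runs exist, a run whose value
#' for any charted parameter lies outside mean +/- 3 SD of the accepted
#' history is declared a plate outlier and its data excluded (the run is
#' not appended). Parameters missing from a run (e.g. an inestimable IC50)
#' are not charted for that run.
#'
#' @param state an `easa_chart`.
#' @param run_params named list or vector with `ss_mean`, `nc_mean`,
#'   `nc_cv`, `pc_ic50`.
#' @param spec an `easa_qc_spec`.
#' @return list with `state` (updated), `accepted`, `outlier_params`
#'   (character), `note`.
#' @export
update_control_chart <- function(state, run_params, spec = qc_spec()) {
  stopifnot(inherits(state, "easa_chart"))
  pars <- c("ss_mean", "nc_mean", "nc_cv", "pc_ic50")
  row <- as.data.frame(lapply(pars, function(p) {
    v <- run_params[[p]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }))
  names(row) <- pars
  h <- state$history
  if (nrow(h) < spec$chart_min_history) {
    state$history <- rbind(h, row)
    return(list(state = state, accepted = TRUE, outlier_params = character(),
                note = "insufficient history; charting inactive"))
  }
  out <- character()
  for (p in pars) {
    x <- row[[p]]
    hist <- h[[p]][!is.na(h[[p]])]
    if (is.na(x) || length(hist) < spec$chart_min_history) next
    ctr <- mean(hist); s <- stats::sd(hist)
    if (abs(x - ctr) > spec$chart_k * s) out <- c(out, p)
  }
  if (length(out)) {
    return(list(state = state, accepted = FALSE, outlier_params = out,
                note = "plate outlier; data excluded"))
  }
  state$history <- rbind(h, row)
  list(state = state, accepted = TRUE, outlier_params = character(), note = "")
}

#' Persist / restore control-chart state as JSON
#'
#' @param state an `easa_chart`.
#' @param path file path.
#' @return `path` invisibly, or the restored state.
#' @export
chart_to_json <- function(state, path) {
  stopifnot(inherits(state, "easa_chart"))
  js <- jsonlite::toJSON(list(history = state$history), dataframe = "columns",
                         na = "null", digits = NA, pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}

#' @rdname chart_to_json
#' @export
chart_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  st <- chart_state()
  if (length(obj$history)) {
    h <- as.data.frame(obj$history)
    for (p in names(st$history)) if (is.null(h[[p]])) h[[p]] <- NA_real_
    st$history <- h[names(st$history)]
  }
  st
}
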