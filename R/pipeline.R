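# End-to-end analysis of one run: bubble test -> group summaries ->
# interference / pipetting QC -> depletion -> classification by the three
# statistical routes -> run-level calls -> quality metrics -> control-chart
# update.

analysis_read <- function(modality_plates, timepoint = 50) {
  rd <- modality_plates$reads[[as.character(timepoint)]]
  if (is.null(rd)) {
    stop("manifest error: no ", timepoint, "-minute read for this modality",
         call. = FALSE)
  }
  rd
}

analyze_modality <- function(modality_plates, modality, layout, cfg, spec,
                             methods, timepoint = 50) {
  if (is.null(modality_plates$bubble)) {
    stop("manifest error: missing 680 nm bubble read", call. = FALSE)
  }
  reading <- analysis_read(modality_plates, timepoint)
  excluded <- bubble_test(modality_plates$bubble, layout, spec, modality)
  groups <- summarize_groups(reading, layout, excluded)
  interference <- interference_check(groups, spec, modality)
  pipetting <- pipetting_qc(reading, layout, spec, excluded)
  ncsd <- nc_pct_sd(groups)

  chems <- list()
  for (s in seq_along(groups$slots)) {
    if (nrow(interference) >= s && interference$assay_na[s]) {
      chems[[groups$slots[[s]]$name]] <- list(
        slot = s, chemical = groups$slots[[s]]$name,
        assay_na = TRUE, calls = list())
      next
    }
    dep <- tc_depletion(groups, s)
    calls <- list()
    if ("frequentist" %in% methods) {
      calls$frequentist <- frequentist_call(groups, s, cfg)
    }
    if ("bayesian" %in% methods) {
      calls$bayesian <- bayesian_call(groups, s, cfg)
    }
    if ("ksd" %in% methods) {
      calls$ksd <- ksd_call(dep$pct_depletion, ncsd, cfg)
    }
    chems[[dep$chemical]] <- list(
      slot = s, chemical = dep$chemical, assay_na = FALSE,
      pct_depletion = dep$pct_depletion,
      depletion_abs = dep$depletion_abs,
      interference_flag = interference$flagged[s],
      calls = calls)
  }

  # quality: per-chemical TC SDs vs the run's maximal-depletion compound
  pct_all <- vapply(chems, function(x)
    if (isTRUE(x$assay_na)) NA_real_ else x$pct_depletion, numeric(1))
  sds <- vapply(seq_along(groups$slots), function(s) groups$slots[[s]]$tc$sd,
                numeric(1))
  names(sds) <- vapply(groups$slots, `[[`, character(1), "name")
  pc_pct <- lapply(groups$pc, function(g)
    control_pct_depletion(g$values, groups$nc$mean, groups$blank$mean))
  pc_fit <- fit_pc_dose_response(pc_concentrations(modality),
                                 vapply(pc_pct, mean, numeric(1)))
  ok <- !is.na(pct_all)
  zres <- tryCatch(
    z_factor(sds[ok], pct_all[ok], pc_sd = groups$pc[[1]]$sd,
             window = groups$window),
    error = function(e) NULL)

  list(modality = modality,
       excluded_wells = as.character(excluded),
       exclusion_reason = attr(excluded, "reason"),
       interference = interference, pipetting = pipetting,
       nc_pct_sd = ncsd,
       groups = list(blank = groups$blank[c("mean", "sd", "n")],
                     nc = groups$nc[c("mean", "sd", "n")],
                     window = groups$window),
       chemicals = chems,
       quality = list(z = if (is.null(zres)) NA_real_ else zres$z,
                      z_detail = zres, pc_ic50 = pc_fit$ic50,
                      pc_fit_method = pc_fit$method))
}

#' Analyze one run end to end
#'
#' Executes, per modality: the 680 nm bubble exclusion, group
#' summarization of the analysis read, interference and pipetting QC,
#' depletion, classification by every requested statistical route, then
#' run-level calls per chemical (driven by the primary route), assay
#' quality metrics, and optionally a control-chart update per modality.
#'
#' @param run an `easa_run` (from [simulate_run()] or [read_run_manifest()]).
#' @param cfg an `easa_config`.
#' @param spec an `easa_qc_spec`.
#' @param methods statistical routes to compute (all three by default).
#' @param primary route that drives the run-level calls (default
#'   `"frequentist"`).
#' @param include_pda_abs if `FALSE`, the amine-probe absorbance modality
#'   is computed but ignored by the run-level call.
#' @param chart_states optional named list of `easa_chart` per modality;
#'   when given, each modality's run parameters are charted and a plate
#'   outlier marks the run excluded.
#' @param timepoint analysis read in minutes (default 50).
#' @return list of class `easa_result`: per-modality analyses,
#'   `run_calls` (per chemical), `excluded` flag + chart verdicts, and
#'   updated `chart_states`.
#' @export
analyze_run <- function(run, cfg = inference_config(), spec = qc_spec(),
                        methods = c("frequentist", "bayesian", "ksd"),
                        primary = "frequentist",
                        include_pda_abs = TRUE,
                        chart_states = NULL, timepoint = 50) {
  stopifnot(inherits(run, "easa_run"), primary %in% methods)
  analyses <- list()
  for (m in names(run$plates)) {
    analyses[[m]] <- analyze_modality(run$plates[[m]], m, run$layout, cfg,
                                      spec, methods, timepoint)
  }

  chart_verdicts <- list()
  excluded_run <- FALSE
  if (!is.null(chart_states)) {
    for (m in names(analyses)) {
      st <- chart_states[[m]]
      if (is.null(st)) st <- chart_state()
      an <- analyses[[m]]
      upd <- update_control_chart(st, list(
        ss_mean = an$groups$blank$mean, nc_mean = an$groups$nc$mean,
        nc_cv = 100 * an$groups$nc$sd / an$groups$nc$mean,
        pc_ic50 = an$quality$pc_ic50), spec)
      chart_states[[m]] <- upd$state
      chart_verdicts[[m]] <- upd[c("accepted", "outlier_params", "note")]
      if (!upd$accepted) excluded_run <- TRUE
    }
  }

  voting <- names(analyses)
  if (!include_pda_abs) voting <- setdiff(voting, "PDA_ABS")
  chem_names <- attr(run$layout, "tc_slot_names")
  run_calls <- list()
  for (ch in chem_names) {
    calls <- lapply(voting, function(m) {
      entry <- analyses[[m]]$chemicals[[ch]]
      if (is.null(entry)) return(NULL)
      if (isTRUE(entry$assay_na)) "not_available" else entry$calls[[primary]]
    })
    calls <- Filter(Negate(is.null), calls)
    run_calls[[ch]] <- tryCatch(run_call(calls),
                                error = function(e) "not_evaluable")
  }

  structure(list(modalities = analyses, run_calls = run_calls,
                 excluded = excluded_run, chart_verdicts = chart_verdicts,
                 chart_states = chart_states,
                 provenance = list(seed = run$seed, primary = primary,
                                   alpha = cfg$alpha, timepoint = timepoint)),
            class = "easa_result")
}

#' Read a run manifest and assemble the plate set
#'
#' The manifest is a JSON object with a `layout` path (JSON layout file)
#' and a `plates` object keyed by modality, each with `reads` (timepoint ->
#' CSV path) and `bubble` (680 nm CSV path). Every modality must provide a
#' 50-minute read and a 680 nm read.
#'
#' @param path manifest JSON path; relative plate paths resolve against the
#'   manifest's directory.
#' @return an `easa_run` (without a truth table).
#' @export
read_run_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  if (is.null(man$layout) || is.null(man$plates)) {
    stop("manifest error: needs 'layout' and 'plates'", call. = FALSE)
  }
  layout <- layout_from_json(resolve(man$layout))
  plates <- list()
  for (m in names(man$plates)) {
    pm <- man$plates[[m]]
    if (is.null(pm$reads[["50"]])) {
      stop("manifest error: modality ", m, " lacks a 50-minute read",
           call. = FALSE)
    }
    if (is.null(pm$bubble)) {
      stop("manifest error: modality ", m, " lacks a 680 nm bubble read",
           call. = FALSE)
    }
    reads <- list()
    for (tp in names(pm$reads)) {
      reads[[tp]] <- read_plate_csv(resolve(pm$reads[[tp]]),
                                    paste0(m, "-t", tp), m, as.numeric(tp))
    }
    plates[[m]] <- list(
      reads = reads,
      bubble = read_plate_csv(resolve(pm$bubble), paste0(m, "-680"),
                              "BUBBLE_680", 5))
  }
  structure(list(layout = layout, plates = plates, truth = NULL, seed = NA),
            class = "easa_run")
}
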