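# Synthetic plate-reader outputs with the statistical structure the
# analysis assumes: Gaussian well groups, a positive-control dose-response,
# test-compound interference offsets, bubble artifacts visible at 680 nm
# with carry-over into the measurement reads, an optional pipetting column
# trend in the negative controls, and a mild probe decay across timepoints.
#
# Default signal scales put the SD of the per-well NC percentage depletion
# near the observed values (~1.3 % thiol-probe absorbance, ~2.3 %
# amine-probe absorbance, ~2.5 % amine-probe fluorescence).

default_modality_params <- function() {
  list(
    NBT_ABS = list(blank_mean = 0.066, nc_mean = 1.00, noise_cv = 1.2,
                   bubble_background = 0.066, bubble_background_sd = 0.003,
                   bubble_spike = c(0.03, 0.30), bubble_carryover = 1.0,
                   pc_curve = list(ic50 = 0.05, hill = 1.3, top = 99, bottom = 0)),
    PDA_ABS = list(blank_mean = 0.060, nc_mean = 0.50, noise_cv = 2.0,
                   bubble_background = 0.066, bubble_background_sd = 0.003,
                   bubble_spike = c(0.03, 0.30), bubble_carryover = 1.0,
                   pc_curve = list(ic50 = 0.017, hill = 1.3, top = 99, bottom = 0)),
    PDA_FLUOR = list(blank_mean = 2000, nc_mean = 50000, noise_cv = 2.4,
                     bubble_background = 4500, bubble_background_sd = 150,
                     bubble_spike = c(1000, 5000), bubble_carryover = 0.2,
                     pc_curve = list(ic50 = 0.0017, hill = 1.3, top = 99, bottom = 0))
  )
}

#' Simulation configuration for synthetic runs
#'
#' The defaults state the simulated world: group-wise multiplicative
#' Gaussian noise at the scale of the published NC variability, a 1 %
#' bubble rate whose 680 nm spikes carry 1:1 into absorbance reads (weakly
#' into fluorescence), no pipetting column trend (set `column_trend_pct`
#' to about 1 for the thiol assay), and a 2 % total probe decay from the
#' 5- to the 50-minute read.
#'
#' @param seed integer RNG seed.
#' @param chemicals data frame with columns `name`, `true_pct_depletion`
#'   and optional `interference_offset` (signal units, per modality scale
#'   factor applied), `viscous_extra_cv` (%).
#' @param modality_params per-modality list overriding entries of the
#'   defaults (see Details in the package vignette).
#' @param bubble_rate per-well probability of a bubble artifact.
#' @param column_trend_pct total NC decline (%) across pipetting columns
#'   2-9.
#' @param time_decay_pct total probe-signal decline (%) from the 5- to the
#'   50-minute read.
#' @param constant_noise_sd optional named vector of per-modality absolute
#'   noise SDs replacing the multiplicative model.
#' @return list of class `easa_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chemicals = data.frame(
                                name = c("strong-binder", "weak-binder",
                                         "nonbinder"),
                                true_pct_depletion = c(50, 10, 0)),
                              modality_params = list(),
                              bubble_rate = 0.01,
                              column_trend_pct = 0,
                              time_decay_pct = 2,
                              constant_noise_sd = NULL) {
  stopifnot(nrow(chemicals) <= 7, bubble_rate >= 0, bubble_rate <= 1)
  if (!"interference_offset" %in% names(chemicals)) {
    chemicals$interference_offset <- 0
  }
  if (!"viscous_extra_cv" %in% names(chemicals)) {
    chemicals$viscous_extra_cv <- 0
  }
  mp <- default_modality_params()
  for (m in names(modality_params)) {
    mp[[m]] <- utils::modifyList(mp[[m]], modality_params[[m]])
  }
  structure(list(seed = as.integer(seed), chemicals = chemicals,
                 modality_params = mp, bubble_rate = bubble_rate,
                 column_trend_pct = column_trend_pct,
                 time_decay_pct = time_decay_pct,
                 constant_noise_sd = constant_noise_sd),
            class = "easa_sim_config")
}

logistic_pct <- function(conc, curve) {
  curve$bottom + (curve$top - curve$bottom) /
    (1 + (curve$ic50 / conc)^curve$hill)
}

# noise on one group of wells: sd = cv% x group mean unless a constant sd
# is configured; viscous chemicals add extra cv in quadrature
sim_noise <- function(n, mean, cv_pct, const_sd = NULL, extra_cv_pct = 0) {
  sd <- if (!is.null(const_sd)) const_sd else {
    abs(mean) * sqrt((cv_pct / 100)^2 + (extra_cv_pct / 100)^2)
  }
  stats::rnorm(n, 0, sd)
}

simulate_modality_plates <- function(cfg, modality, layout, plate_id) {
  p <- cfg$modality_params[[modality]]
  const_sd <- if (!is.null(cfg$constant_noise_sd))
    cfg$constant_noise_sd[[modality]] else NULL
  chems <- cfg$chemicals
  window <- p$nc_mean - p$blank_mean
  pc_conc <- pc_concentrations(modality)

  # bubbles are physical: drawn once per plate, visible at 680 nm and
  # carried into every measurement read of the same well
  bubble <- matrix(stats::runif(96) < cfg$bubble_rate, 8, 12)
  spike <- matrix(0, 8, 12)
  spike[bubble] <- stats::runif(sum(bubble), p$bubble_spike[1], p$bubble_spike[2])

  read680 <- matrix(stats::rnorm(96, p$bubble_background,
                                 p$bubble_background_sd), 8, 12) + spike
  read680 <- pmax(read680, 0)
  bubble_plate <- plate_reading(read680, paste0(plate_id, "-680"),
                                "BUBBLE_680", 5)

  reads <- list()
  for (tp in TIMEPOINTS_MIN) {
    decay <- 1 + (cfg$time_decay_pct / 100) * (50 - tp) / 45
    vals <- matrix(NA_real_, 8, 12)
    for (i in 1:8) for (j in 1:12) {
      r <- LETTERS[i]
      w <- which(layout$row == r & layout$col == j)
      kind <- layout$kind[w]
      trend <- if (j >= 2 && j <= 9 && cfg$column_trend_pct != 0) {
        1 - (cfg$column_trend_pct / 100) * (j - 2) / 7
      } else 1
      probe <- window * decay * trend  # probe-derived signal above blank
      base <- switch(kind,
        BLANK_SS = p$blank_mean,
        AUX_SS = p$blank_mean,
        NEG_CONTROL = p$blank_mean + probe,
        PC = p$blank_mean + probe *
          (1 - logistic_pct(pc_conc[layout$pc_level[w]], p$pc_curve) / 100),
        TC_PROBE = , TC_BLANK = {
          s <- layout$tc_slot[w]
          if (s > nrow(chems)) p$blank_mean else {
            off <- chems$interference_offset[s]
            if (kind == "TC_BLANK") p$blank_mean + off else {
              p$blank_mean + off +
                probe * (1 - chems$true_pct_depletion[s] / 100)
            }
          }
        })
      extra <- if (kind %in% c("TC_PROBE", "TC_BLANK") &&
                   layout$tc_slot[w] <= nrow(chems)) {
        chems$viscous_extra_cv[layout$tc_slot[w]]
      } else 0
      vals[i, j] <- base + sim_noise(1, base, p$noise_cv, const_sd, extra)
    }
    vals <- vals + spike * p$bubble_carryover
    if (assay_modality(modality)$signal_kind == "fluorescence") {
      vals <- pmax(vals, 0)
    } else {
      vals <- pmax(vals, -0.099)
    }
    reads[[as.character(tp)]] <- plate_reading(vals, paste0(plate_id, "-", tp),
                                               modality, tp)
  }
  list(reads = reads, bubble = bubble_plate)
}

#' Simulate one complete run (three modalities, four timepoints + 680 nm)
#'
#' Identical configuration and seed give bit-identical plates. The truth
#' table records the stated depletion of every chemical.
#'
#' @param cfg an `easa_sim_config`.
#' @param modalities modalities to generate (default all three).
#' @return list of class `easa_run`: `layout`, `plates` (per modality:
#'   `reads` by timepoint and the 680 nm `bubble` read), `truth`, `seed`.
#' @export
simulate_run <- function(cfg = simulation_config(),
                         modalities = names(MODALITY_DEFS)) {
  stopifnot(inherits(cfg, "easa_sim_config"))
  layout <- build_layout(cfg$chemicals$name)
  plates <- with_seed(cfg$seed, {
    out <- list()
    for (m in modalities) {
      out[[m]] <- simulate_modality_plates(cfg, m, layout,
                                           paste0("sim", cfg$seed, "-", m))
    }
    out
  })
  structure(list(layout = layout, plates = plates, truth = cfg$chemicals,
                 seed = cfg$seed),
            class = "easa_run")
}

#' Simulate a study of independent runs sharing one truth
#'
#' Each run draws fresh noise from a sub-seed derived from the study seed;
#' feeds control charting and chemical-level majority voting.
#'
#' @param cfg an `easa_sim_config`.
#' @param n_runs number of runs (>= 1).
#' @param modalities modalities to generate.
#' @return list of `easa_run`s.
#' @export
simulate_study <- function(cfg = simulation_config(), n_runs = 3,
                           modalities = names(MODALITY_DEFS)) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(k) {
    ck <- cfg
    ck$seed <- (cfg$seed + 7919L * k) %% .Machine$integer.max
    simulate_run(ck, modalities)
  })
}

#' Write a simulated run to disk (plate CSVs, layout JSON, truth CSV)
#'
#' @param run an `easa_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "easa_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(run$plates)) {
    for (tp in names(run$plates[[m]]$reads)) {
      write_plate_csv(run$plates[[m]]$reads[[tp]],
                      file.path(dir, paste0(m, "_t", tp, ".csv")))
    }
    write_plate_csv(run$plates[[m]]$bubble,
                    file.path(dir, paste0(m, "_680.csv")))
  }
  layout_to_json(run$layout, file.path(dir, "layout.json"))
  utils::write.csv(run$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
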