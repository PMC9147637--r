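# Assay-quality metrics: the Z-factor screening statistic and the
# positive-control dose-response IC50 charted across runs.

#' Fit the positive-control dose-response and extract the IC50
#'
#' Least-squares four-parameter log-logistic fit of the mean percentage
#' depletion per dilution level against concentration,
#' `y = bottom + (top - bottom) / (1 + (ic50/c)^hill)`. The reported IC50
#' is the concentration at which the fitted curve crosses 50 % depletion.
#' When the fit does not converge, a log-linear interpolation between the
#' two levels bracketing 50 % is used instead (`method = "interpolation"`).
#' When the response never brackets 50 %, the IC50 is not estimable: the
#' chart parameter is recorded missing, the run is not rejected.
#'
#' @param concentrations vector of level concentrations (mmol/L), level 1
#'   (top) first, strictly decreasing by factor 2.
#' @param pct_depletions numeric vector of per-level mean % depletions, or
#'   a matrix/list of per-level replicates (averaged per level).
#' @return list of class `easa_pc_fit`: `ic50`, `bottom`, `top`, `hill`,
#'   `residual_rms`, `method` (`"fit"`, `"interpolation"` or
#'   `"not_estimable"`).
#' @export
fit_pc_dose_response <- function(concentrations, pct_depletions) {
  conc <- as.numeric(concentrations)
  if (is.matrix(pct_depletions)) {
    y <- rowMeans(pct_depletions)
  } else if (is.list(pct_depletions)) {
    y <- vapply(pct_depletions, mean, numeric(1))
  } else {
    y <- as.numeric(pct_depletions)
  }
  keep <- is.finite(conc) & is.finite(y)
  conc <- conc[keep]; y <- y[keep]
  if (length(conc) < 5) {
    stop("need at least 5 dilution levels with data", call. = FALSE)
  }
  if (any(diff(conc) >= 0)) {
    stop("concentrations must be strictly decreasing (serial dilution)",
         call. = FALSE)
  }
  fit <- tryCatch({
    df <- data.frame(conc = conc, y = y)
    start <- list(bottom = max(min(y), 0), top = max(y),
                  ic50 = exp(mean(log(range(conc)))), hill = 1)
    stats::nls(y ~ bottom + (top - bottom) / (1 + (ic50 / conc)^hill),
        data = df, start = start, algorithm = "port",
        lower = c(bottom = -50, top = 0, ic50 = min(conc) / 100, hill = 0.1),
        upper = c(bottom = 100, top = 200, ic50 = max(conc) * 100, hill = 10),
        control = stats::nls.control(warnOnly = FALSE, maxiter = 200))
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    rms <- sqrt(mean(stats::residuals(fit)^2))
    # concentration where the fitted curve crosses 50 %
    if (p$bottom < 50 && p$top > 50) {
      u <- (p$top - 50) / (50 - p$bottom)
      ic50 <- p$ic50 / u^(1 / p$hill)
      return(structure(list(ic50 = ic50, bottom = p$bottom, top = p$top,
                            hill = p$hill, residual_rms = rms,
                            method = "fit"),
                       class = "easa_pc_fit"))
    }
    # converged but never crosses 50 % within the fitted asymptotes
    return(structure(list(ic50 = NA_real_, bottom = p$bottom, top = p$top,
                          hill = p$hill, residual_rms = rms,
                          method = "not_estimable"),
                     class = "easa_pc_fit"))
  }
  # fallback: log-linear interpolation between bracketing levels
  for (i in seq_len(length(conc) - 1)) {
    y1 <- y[i]; y2 <- y[i + 1]
    if ((y1 - 50) * (y2 - 50) <= 0 && y1 != y2) {
      f <- (50 - y2) / (y1 - y2)
      lc <- log(conc[i + 1]) + f * (log(conc[i]) - log(conc[i + 1]))
      return(structure(list(ic50 = exp(lc), bottom = NA_real_, top = NA_real_,
                            hill = NA_real_, residual_rms = NA_real_,
                            method = "interpolation"),
                       class = "easa_pc_fit"))
    }
  }
  structure(list(ic50 = NA_real_, bottom = NA_real_, top = NA_real_,
                 hill = NA_real_, residual_rms = NA_real_,
                 method = "not_estimable"),
            class = "easa_pc_fit")
}

#' Z-factor of a run
#'
#' `Z = 1 - 3 (s_sample + s_PC) / (mean NC - mean blank)`. The sample SD is
#' trimmed in two stages: chemicals with less than 5 % depletion are
#' dropped first; then chemicals whose SD exceeds 3 times the mean SD of
#' the remainder are dropped once (no iteration) and the mean SD of the
#' survivors is `s_sample`. `s_PC` is the SD of the maximal-depletion
#' compound of the run (~99 % depletion).
#'
#' @param sample_sds named numeric vector of per-chemical TC-well SDs
#'   (signal units).
#' @param pct_depletions named numeric vector of the matching % depletions.
#' @param pc_sd SD of the maximal-depletion (positive-control) compound.
#' @param window signal window `mean(NC) - mean(blank)`.
#' @return list of class `easa_zfactor`: `z`, `s_sample`, `s_pc`, `window`,
#'   `removed_low_depletion`, `removed_high_sd`.
#' @export
z_factor <- function(sample_sds, pct_depletions, pc_sd, window) {
  stopifnot(length(sample_sds) == length(pct_depletions), window > 0)
  nm <- names(sample_sds)
  if (is.null(nm)) nm <- as.character(seq_along(sample_sds))
  keep1 <- pct_depletions >= 5
  removed_low <- nm[!keep1]
  if (!any(keep1)) stop("no chemicals with >= 5 % depletion; Z not computable",
                        call. = FALSE)
  s1 <- sample_sds[keep1]
  m1 <- mean(s1)
  keep2 <- s1 <= 3 * m1
  removed_high <- names(s1)[!keep2]
  s_sample <- mean(s1[keep2])
  z <- 1 - 3 * (s_sample + pc_sd) / window
  structure(list(z = z, s_sample = s_sample, s_pc = pc_sd, window = window,
                 removed_low_depletion = removed_low,
                 removed_high_sd = removed_high),
            class = "easa_zfactor")
}
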