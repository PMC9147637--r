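# Classification of probe depletion. Three routes are provided:
#   * frequentist: T statistic on the four group means with
#     Welch-Satterthwaite degrees of freedom and a Student-t p value;
#   * Bayesian: Gibbs sampler over four Gaussian groups (diffuse normal
#     priors on means, Gamma priors on precisions), binder when the lower
#     bound of the equal-tailed credible interval on depletion exceeds 0;
#   * k x SD: percentage depletion compared with a multiple of the SD of
#     the per-well NC percentage depletions.

#' Inference configuration
#'
#' @param alpha type I error level; binder when p < alpha (frequentist) or
#'   when the lower bound of the (1 - alpha) credible interval exceeds 0
#'   (Bayesian). Default 0.005, the level carried into the published
#'   chemical determinations; 0.05, 0.01 and 0.001 are the other charted
#'   levels.
#' @param sidedness `"one_sided_greater"` (default; tests depletion > 0,
#'   the direction of the Bayesian lower-bound rule) or `"two_sided"`.
#' @param ksd_factor multiplier for the k x SD rule (default 5).
#' @param mcmc list of Gibbs-sampler settings: `iterations` (post-warm-up
#'   total per chain, default 20000), `burn_in` (default 5000), `chains`
#'   (default 2), `seed`, `prior_mean_sd` (default 1000 x the data scale),
#'   `gamma_shape`/`gamma_rate` on the group precisions (default 0.001 each).
#' @param borderline_type1_pct binder below this % depletion is flagged a
#'   potential false positive (default 10).
#' @param borderline_type2_pct nonbinder above this % depletion is flagged
#'   a potential false negative (default 3).
#' @param neg_depletion_anomaly % depletion below which the result is an
#'   anomalous signal gain and the call inconclusive (default -20).
#' @return list of class `easa_config`.
#' @export
inference_config <- function(alpha = 0.005,
                             sidedness = c("one_sided_greater", "two_sided"),
                             ksd_factor = 5,
                             mcmc = list(),
                             borderline_type1_pct = 10,
                             borderline_type2_pct = 3,
                             neg_depletion_anomaly = -20) {
  stopifnot(alpha > 0, alpha < 0.5, ksd_factor > 0)
  sidedness <- match.arg(sidedness)
  m <- utils::modifyList(
    list(iterations = 20000L, burn_in = 5000L, chains = 2L, seed = NULL,
         prior_mean_sd = NULL, gamma_shape = 0.001, gamma_rate = 0.001),
    mcmc
  )
  stopifnot(m$iterations > m$burn_in)
  structure(list(alpha = alpha, sidedness = sidedness,
                 ksd_factor = ksd_factor, mcmc = m,
                 ci_level = 1 - alpha,
                 borderline_type1_pct = borderline_type1_pct,
                 borderline_type2_pct = borderline_type2_pct,
                 neg_depletion_anomaly = neg_depletion_anomaly),
            class = "easa_config")
}

assay_call <- function(call, method, pct_depletion = NA_real_,
                       depletion_abs = NA_real_, p_value = NA_real_,
                       t_stat = NA_real_, df = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_, ...) {
  structure(list(call = call, method = method,
                 pct_depletion = pct_depletion,
                 depletion_abs = depletion_abs,
                 p_value = p_value, t_stat = t_stat, df = df,
                 ci_low = ci_low, ci_high = ci_high,
                 borderline_type1 = FALSE, borderline_type2 = FALSE,
                 anomalous_negative = FALSE, ...),
            class = "easa_assay_call")
}

check_four_groups <- function(nc, blank, tc, tc_blank) {
  for (g in list(nc = nc, blank = blank, tc = tc, tc_blank = tc_blank)) {
    if (g$n < 2) stop("need at least 2 wells per group for inference",
                      call. = FALSE)
  }
}

#' Welch T statistic and Satterthwaite degrees of freedom
#'
#' `T = [(mean NC - mean blank) - (mean TC - mean TC_blank)] /
#' sqrt(s_NC^2/n_NC + s_blank^2/n_blank + s_TC^2/n_TC + s_TCb^2/n_TCb)`;
#' the degrees of freedom take the usual Satterthwaite form with inner
#' terms `(s^2/n)^2 / (n - 1)`. Counts are the wells actually included
#' after QC (nominally 15, 8, 4 and 3).
#'
#' @param nc,blank,tc,tc_blank group summaries, each a list with `mean`,
#'   `sd`, `n` (as produced by [summarize_groups()]).
#' @return named numeric vector `c(t = , df = )`.
#' @export
welch_t <- function(nc, blank, tc, tc_blank) {
  check_four_groups(nc, blank, tc, tc_blank)
  gs <- list(nc, blank, tc, tc_blank)
  v <- vapply(gs, function(g) g$sd^2 / g$n, numeric(1))
  tot <- sum(v)
  if (tot <= 0) stop("all group variances are zero; T is degenerate",
                     call. = FALSE)
  d <- (nc$mean - blank$mean) - (tc$mean - tc_blank$mean)
  df <- tot^2 / sum(vapply(seq_along(gs),
                           function(i) v[i]^2 / (gs[[i]]$n - 1), numeric(1)))
  c(t = d / sqrt(tot), df = df)
}

#' Frequentist binder/nonbinder call for one chemical and modality
#'
#' @param groups an `easa_groups`.
#' @param slot TC slot number.
#' @param cfg an `easa_config`.
#' @return `easa_assay_call` with p value, T, df and borderline flags.
#' @export
frequentist_call <- function(groups, slot, cfg = inference_config()) {
  sl <- groups$slots[[slot]]
  dep <- tc_depletion(groups, slot)
  td <- welch_t(groups$nc, groups$blank, sl$tc, sl$tc_blank)
  p <- if (cfg$sidedness == "one_sided_greater") {
    stats::pt(td[["t"]], df = td[["df"]], lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(td[["t"]]), df = td[["df"]], lower.tail = FALSE)
  }
  # CI on % depletion from the t quantile on absolute depletion
  se <- sqrt(groups$nc$sd^2 / groups$nc$n + groups$blank$sd^2 / groups$blank$n +
             sl$tc$sd^2 / sl$tc$n + sl$tc_blank$sd^2 / sl$tc_blank$n)
  q <- stats::qt(1 - cfg$alpha / 2, df = td[["df"]])
  ci <- 100 * (dep$depletion_abs + c(-1, 1) * q * se) / dep$window
  call <- if (p < cfg$alpha) "binder" else "nonbinder"
  out <- assay_call(call, "frequentist",
                    pct_depletion = dep$pct_depletion,
                    depletion_abs = dep$depletion_abs,
                    p_value = p, t_stat = td[["t"]], df = td[["df"]],
                    ci_low = ci[1], ci_high = ci[2])
  flag_borderline(out, cfg)
}

# restore the caller's RNG stream after seeded sampling
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gibbs sampler for one Gaussian group: y ~ N(mu, 1/tau),
# mu ~ N(m0, s0^2), tau ~ Gamma(a0, b0). Returns draws of mu.
gibbs_group_mu <- function(y, iters, burn, m0, s0, a0, b0) {
  n <- length(y); ybar <- mean(y)
  ss <- sum((y - ybar)^2)
  mu <- ybar
  tau <- 1 / max(stats::var(y), (1e-6 * max(abs(ybar), 1))^2)
  out <- numeric(iters - burn)
  prec0 <- 1 / s0^2
  for (k in seq_len(iters)) {
    prec <- prec0 + tau * n
    mu <- stats::rnorm(1, (m0 * prec0 + tau * n * ybar) / prec, sqrt(1 / prec))
    tau <- stats::rgamma(1, a0 + n / 2,
                         rate = b0 + (ss + n * (ybar - mu)^2) / 2)
    if (k > burn) out[k - burn] <- mu
  }
  out
}

split_rhat <- function(chains) {
  # chains: list of equal-length numeric vectors; split each in half
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Bayesian binder/nonbinder call via Gibbs sampling
#'
#' Each of the four well groups is modelled as Gaussian with its own mean
#' and variance; means get diffuse Gaussian priors, precisions Gamma
#' priors. Posterior draws of `Depletion = (mu_NC - mu_blank) -
#' (mu_TC - mu_TCblank)` give an equal-tailed `1 - alpha` credible
#' interval; the chemical is a binder when the interval's lower bound is
#' above zero. Percentage depletion uses the same draws divided by the
#' posterior window `mu_NC - mu_blank`. Convergence is checked by split
#' R-hat on the depletion draws; non-convergence attaches a warning flag
#' but the call is still reported.
#'
#' @param groups an `easa_groups` (must retain raw well values).
#' @param slot TC slot number.
#' @param cfg an `easa_config`; see [inference_config()] for the MCMC
#'   settings.
#' @return `easa_assay_call` with credible-interval bounds (on the %
#'   depletion scale), posterior means, and `rhat`/`converged` fields.
#' @export
bayesian_call <- function(groups, slot, cfg = inference_config()) {
  sl <- groups$slots[[slot]]
  m <- cfg$mcmc
  ydata <- list(nc = groups$nc$values, blank = groups$blank$values,
                tc = sl$tc$values, tcb = sl$tc_blank$values)
  # The sampler runs on data standardized by the pooled within-group SD so
  # the vague Gamma prior on precisions stays vague on any instrument
  # scale (raw absorbance variances ~1e-5 would otherwise be swamped by
  # the prior rate); depletion draws are mapped back to signal units.
  unit <- sqrt(mean(vapply(ydata, function(y) stats::var(y), numeric(1))))
  if (!is.finite(unit) || unit <= 0) {
    unit <- 1e-3 * max(vapply(ydata, function(y) max(abs(y)), numeric(1)), 1)
  }
  ysc <- lapply(ydata, function(y) y / unit)
  s0 <- if (is.null(m$prior_mean_sd)) {
    1000 * max(vapply(ysc, function(y) max(abs(y)), numeric(1)), 1)
  } else m$prior_mean_sd / unit
  draws_by_chain <- with_seed(m$seed, {
    lapply(seq_len(m$chains), function(ch) {
      mus <- lapply(ysc, gibbs_group_mu, iters = m$iterations,
                    burn = m$burn_in, m0 = 0, s0 = s0,
                    a0 = m$gamma_shape, b0 = m$gamma_rate)
      win <- (mus$nc - mus$blank) * unit
      dep <- win - (mus$tc - mus$tcb) * unit
      list(dep = dep, pct = 100 * dep / win)
    })
  })
  dep <- unlist(lapply(draws_by_chain, `[[`, "dep"))
  pct <- unlist(lapply(draws_by_chain, `[[`, "pct"))
  rhat <- if (m$chains >= 1) split_rhat(lapply(draws_by_chain, `[[`, "dep")) else NA_real_
  a <- cfg$alpha
  ci_abs <- stats::quantile(dep, c(a / 2, 1 - a / 2), names = FALSE)
  ci_pct <- stats::quantile(pct, c(a / 2, 1 - a / 2), names = FALSE)
  call <- if (ci_abs[1] > 0) "binder" else "nonbinder"
  out <- assay_call(call, "bayesian",
                    pct_depletion = mean(pct),
                    depletion_abs = mean(dep),
                    ci_low = ci_pct[1], ci_high = ci_pct[2],
                    ci_low_abs = ci_abs[1], ci_high_abs = ci_abs[2],
                    rhat = rhat, converged = is.na(rhat) || rhat <= 1.05)
  if (!out$converged) {
    warning("Bayesian depletion chain did not converge (split R-hat = ",
            round(rhat, 3), ")", call. = FALSE)
  }
  flag_borderline(out, cfg)
}

#' k x SD classification rule
#'
#' Binder when the percentage depletion strictly exceeds `factor` times the
#' standard deviation of the per-well NC percentage depletions; ties are
#' nonbinders.
#'
#' @param pct_depletion test-compound % depletion.
#' @param nc_pct_sd SD of the NC per-well % depletion values.
#' @param cfg an `easa_config` (supplies `ksd_factor` and borderline
#'   thresholds).
#' @return `easa_assay_call`.
#' @export
ksd_call <- function(pct_depletion, nc_pct_sd, cfg = inference_config()) {
  call <- if (pct_depletion > cfg$ksd_factor * nc_pct_sd) "binder" else "nonbinder"
  out <- assay_call(call, "ksd", pct_depletion = pct_depletion,
                    threshold = cfg$ksd_factor * nc_pct_sd)
  flag_borderline(out, cfg)
}

#' Borderline and anomaly flags
#'
#' A binder with less than 10 % depletion is a potential Type I error
#' (borderline positive); a nonbinder with more than 3 % depletion is a
#' potential Type II error (borderline negative). A percentage depletion
#' below the negative-anomaly threshold (default -20 %) indicates signal
#' gain in the TC wells (e.g. coloured reaction products) and forces the
#' call to inconclusive.
#'
#' @param call an `easa_assay_call` with a `pct_depletion`.
#' @param cfg an `easa_config`.
#' @return the flagged call.
#' @export
flag_borderline <- function(call, cfg = inference_config()) {
  stopifnot(inherits(call, "easa_assay_call"))
  pct <- call$pct_depletion
  if (is.na(pct)) return(call)
  if (pct < cfg$neg_depletion_anomaly) {
    call$anomalous_negative <- TRUE
    call$call <- "inconclusive"
    call$borderline_type1 <- call$borderline_type2 <- FALSE
    return(call)
  }
  if (call$call == "binder" && pct < cfg$borderline_type1_pct) {
    call$borderline_type1 <- TRUE
  }
  if (call$call == "nonbinder" && pct > cfg$borderline_type2_pct) {
    call$borderline_type2 <- TRUE
  }
  call
}

#' Combine the three modality calls into a run-level call
#'
#' A run indicates binder if any modality shows statistically significant
#' depletion. It is a clean nonbinder only when at least one modality is a
#' conclusive nonbinder and no modality is inconclusive (an anomalous
#' modality blocks a clean negative); otherwise the run is inconclusive.
#'
#' @param calls list of up to three `easa_assay_call`s (or the strings
#'   `"not_available"` for modalities outside the instrument's dynamic
#'   range).
#' @return `"binder"`, `"nonbinder"` or `"inconclusive"`.
#' @export
run_call <- function(calls) {
  lab <- vapply(calls, function(x) {
    if (is.character(x)) x else x$call
  }, character(1))
  if (all(lab == "not_available")) {
    stop("run not evaluable: all modalities unavailable", call. = FALSE)
  }
  if (any(lab == "binder")) return("binder")
  if (any(lab == "nonbinder") && !any(lab == "inconclusive")) return("nonbinder")
  "inconclusive"
}

#' Majority vote across runs for the chemical-level call
#'
#' Run-level inconclusives are dropped from the tally; an exact tie between
#' binder and nonbinder runs is inconclusive.
#'
#' @param run_calls character vector of run-level calls.
#' @return list with `call` and `n_runs`.
#' @export
chemical_call <- function(run_calls) {
  if (length(run_calls) == 0) stop("no runs to evaluate", call. = FALSE)
  nb <- sum(run_calls == "binder")
  nn <- sum(run_calls == "nonbinder")
  if (nb + nn == 0) stop("no evaluable (conclusive) runs", call. = FALSE)
  call <- if (nb > nn) "binder" else if (nn > nb) "nonbinder" else "inconclusive"
  list(call = call, n_runs = length(run_calls))
}
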