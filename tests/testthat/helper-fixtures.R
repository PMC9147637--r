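# Shared fixtures: deterministic plates and group summaries built in code.

# A noiseless plate: blank/AUX wells at `blank`, probe wells at `nc`, PC
# wells following a perfect response, TC wells at a stated depletion.
noiseless_plate <- function(blank = 0.10, nc = 1.10,
                            tc_pct = c(50, 10, 0), interference = 0,
                            modality = "NBT_ABS", timepoint = 50,
                            pc_pct = rep(0, 7)) {
  lay <- build_layout(paste0("chem", seq_along(tc_pct)))
  vals <- matrix(NA_real_, 8, 12)
  window <- nc - blank
  for (i in seq_len(nrow(lay))) {
    k <- lay$kind[i]
    r <- match(lay$row[i], LETTERS)
    v <- switch(k,
      BLANK_SS = blank, AUX_SS = blank, NEG_CONTROL = nc,
      PC = blank + window * (1 - pc_pct[lay$pc_level[i]] / 100),
      TC_PROBE = if (lay$tc_slot[i] <= length(tc_pct)) {
        blank + interference + window * (1 - tc_pct[lay$tc_slot[i]] / 100)
      } else blank,
      TC_BLANK = if (lay$tc_slot[i] <= length(tc_pct)) {
        blank + interference
      } else blank)
    vals[r, lay$col[i]] <- v
  }
  list(plate = plate_reading(vals, "fixture", modality, timepoint),
       layout = lay)
}

# Group summaries straight from moments (for the inference routes that do
# not need raw well values).
gs <- function(mean, sd, n) list(mean = mean, sd = sd, n = n)

# Random group summaries at plausible assay scales, for property tests.
random_groups <- function() {
  blank <- runif(1, 0.05, 0.15)
  ncm <- runif(1, 0.4, 1.5)
  list(nc = gs(ncm, runif(1, 1e-4, 0.05), sample(5:20, 1)),
       blank = gs(blank, runif(1, 1e-4, 0.02), sample(3:10, 1)),
       tc = gs(runif(1, blank, ncm), runif(1, 1e-4, 0.08), sample(2:8, 1)),
       tcb = gs(blank + runif(1, -0.02, 0.05), runif(1, 1e-4, 0.02),
                sample(2:6, 1)))
}

# Independent textbook evaluation of the T statistic and Satterthwaite
# degrees of freedom, written without reference to the package routine.
oracle_welch <- function(nc, blank, tc, tcb) {
  num <- (nc$mean - blank$mean) - (tc$mean - tcb$mean)
  terms <- c(nc$sd^2 / nc$n, blank$sd^2 / blank$n,
             tc$sd^2 / tc$n, tcb$sd^2 / tcb$n)
  ns <- c(nc$n, blank$n, tc$n, tcb$n)
  Tt <- num / sqrt(terms[1] + terms[2] + terms[3] + terms[4])
  df <- (terms[1] + terms[2] + terms[3] + terms[4])^2 /
    (terms[1]^2 / (ns[1] - 1) + terms[2]^2 / (ns[2] - 1) +
     terms[3]^2 / (ns[3] - 1) + terms[4]^2 / (ns[4] - 1))
  c(Tt, df)
}

# `easa_groups`-shaped object carrying raw well values drawn from stated
# group distributions (bypasses plate construction for inference tests).
groups_from_values <- function(blank, nc, tc, tcb, name = "chem1") {
  summ <- function(v) list(mean = mean(v), sd = sd(v), n = length(v),
                           values = v)
  structure(list(blank = summ(blank), nc = summ(nc),
                 pc = NULL,
                 slots = list(list(name = name, tc = summ(tc),
                                   tc_blank = summ(tcb))),
                 window = mean(nc) - mean(blank)),
            class = "easa_groups")
}

fast_mcmc <- function(alpha = 0.005, seed = 99, ...) {
  inference_config(alpha = alpha,
                   mcmc = list(iterations = 2500L, burn_in = 500L,
                               chains = 2L, seed = seed), ...)
}
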