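# Defined approaches for skin-sensitization hazard: combine a protein
# binding call (KE1: this assay or the peptide-reactivity comparator) with
# keratinocyte activation (KE2, KeratinoSens) and dendritic-cell activation
# (KE3, h-CLAT), and score predictions against reference calls with Cooper
# statistics. Binder/nonbinder and sensitizer/nonsensitizer map onto
# positive/negative internally.

POSNEG_MAP <- c(binder = "positive", nonbinder = "negative",
                sensitizer = "positive", nonsensitizer = "negative",
                positive = "positive", negative = "negative",
                inconclusive = "inconclusive")

as_posneg <- function(x) {
  out <- unname(POSNEG_MAP[as.character(x)])
  out[is.na(x)] <- NA_character_
  out
}

#' "2 out of 3" defined approach
#'
#' Positive when two of the non-missing KE calls are concordantly positive;
#' negative when two are concordantly negative; inconclusive when no two
#' concordant calls exist (for instance one positive, one negative and one
#' missing).
#'
#' @param ke1,ke2,ke3 calls for the three key events; accepted tokens are
#'   positive/negative, binder/nonbinder, or `NA` for missing.
#' @return `"positive"`, `"negative"` or `"inconclusive"`.
#' @export
two_of_three <- function(ke1, ke2, ke3) {
  calls <- as_posneg(c(ke1, ke2, ke3))
  calls <- calls[!is.na(calls) & calls != "inconclusive"]
  if (length(calls) == 0) stop("no evaluable key-event calls", call. = FALSE)
  if (sum(calls == "positive") >= 2) return("positive")
  if (sum(calls == "negative") >= 2) return("negative")
  "inconclusive"
}

#' KE 3/1 defined approach
#'
#' Decision tree on dendritic-cell activation (KE3) and protein binding
#' (KE1): a positive KE3 is positive outright; a negative KE3 defers to the
#' KE1 call; a missing KE3, or a negative KE3 with a missing or
#' inconclusive KE1, is inconclusive.
#'
#' @param ke1 protein-binding call (binder/nonbinder or positive/negative).
#' @param ke3 dendritic-cell activation call.
#' @return `"positive"`, `"negative"` or `"inconclusive"`.
#' @export
ke31 <- function(ke1, ke3) {
  k3 <- as_posneg(ke3)
  if (is.na(k3) || k3 == "inconclusive") return("inconclusive")
  if (k3 == "positive") return("positive")
  k1 <- as_posneg(ke1)
  if (is.na(k1) || k1 == "inconclusive") return("inconclusive")
  k1
}

#' Cooper concordance statistics
#'
#' Scores binary hazard predictions against a reference classification.
#' Chemicals with inconclusive or missing predictions, or without a
#' comparator call in the chosen scope, are excluded (and counted).
#' Accuracy = (TP + TN) / n evaluated; the false-positive rate is FP over
#' reference negatives; the false-negative rate FN over reference
#' positives.
#'
#' @param predictions named character vector (chemical -> call); accepted
#'   tokens as in [two_of_three()].
#' @param references an `easa_reference` data frame
#'   (see [read_reference_table()]).
#' @param scope comparator selection: `"LLNA_only"` (in vivo calls from the
#'   murine assay only), `"LLNA_and_GPMT"` (include guinea-pig-test-only
#'   chemicals) or `"vs_DPRA"` (score against the peptide-reactivity
#'   comparator, its inconclusives excluded).
#' @return list of class `easa_cooper`: `accuracy`, `false_positive_rate`,
#'   `false_negative_rate` (each in % with `*_num`/`*_den` fractions),
#'   `tp`, `tn`, `fp`, `fn`, `n_evaluated`, `n_excluded_inconclusive`,
#'   `n_excluded_no_reference`.
#' @export
cooper_stats <- function(predictions,
                         references,
                         scope = c("LLNA_only", "LLNA_and_GPMT", "vs_DPRA")) {
  scope <- match.arg(scope)
  stopifnot(inherits(references, "data.frame"))
  chem <- names(predictions)
  if (is.null(chem)) stop("predictions must be named by chemical", call. = FALSE)
  idx <- match(chem, references$chemical)
  if (anyNA(idx)) {
    stop("prediction(s) for unknown chemical(s): ",
         paste(chem[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ref <- switch(scope,
    LLNA_only = ifelse(!is.na(references$invivo_assay[idx]) &
                         references$invivo_assay[idx] == "LLNA",
                       references$invivo_call[idx], NA_character_),
    LLNA_and_GPMT = references$invivo_call[idx],
    vs_DPRA = references$dpra_call[idx]
  )
  ref <- as_posneg(ref)
  ref[!is.na(ref) & ref == "inconclusive"] <- NA_character_
  pred <- as_posneg(predictions)
  incon <- !is.na(pred) & pred == "inconclusive"
  pred[incon] <- NA_character_
  have_ref <- !is.na(ref)
  eval <- have_ref & !is.na(pred)
  if (!any(eval)) stop("no evaluable chemicals for Cooper statistics",
                       call. = FALSE)
  p <- pred[eval]; r <- ref[eval]
  tp <- sum(p == "positive" & r == "positive")
  tn <- sum(p == "negative" & r == "negative")
  fp <- sum(p == "positive" & r == "negative")
  fn <- sum(p == "negative" & r == "positive")
  n <- sum(eval)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    accuracy = pct(tp + tn, n), accuracy_num = tp + tn, accuracy_den = n,
    false_positive_rate = pct(fp, fp + tn),
    false_positive_num = fp, false_positive_den = fp + tn,
    false_negative_rate = pct(fn, fn + tp),
    false_negative_num = fn, false_negative_den = fn + tp,
    tp = tp, tn = tn, fp = fp, fn = fn,
    n_evaluated = n,
    n_excluded_inconclusive = sum(incon & have_ref),
    n_excluded_no_reference = sum(!have_ref),
    scope = scope
  ), class = "easa_cooper")
}

#' @export
print.easa_cooper <- function(x, ...) {
  cat(sprintf("Cooper statistics (%s, n = %d evaluated)\n", x$scope,
              x$n_evaluated))
  cat(sprintf("  accuracy        %5.1f%%  (%d/%d)\n", x$accuracy,
              x$accuracy_num, x$accuracy_den))
  cat(sprintf("  false positives %5.1f%%  (%d/%d)\n", x$false_positive_rate,
              x$false_positive_num, x$false_positive_den))
  cat(sprintf("  false negatives %5.1f%%  (%d/%d)\n", x$false_negative_rate,
              x$false_negative_num, x$false_negative_den))
  invisible(x)
}
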