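#' Threshold classification of a flow or pressure index
#'
#' Flow indices (MFR, stress MBF) are abnormal when strictly below their
#' cutoff; FFR is abnormal at or below its cutoff. The tie rule matters: an
#' MFR exactly at the cutoff is normal, an FFR exactly at 0.8 is abnormal.
#'
#' @param value numeric, finite; vectorized.
#' @param cutoff scalar cutoff.
#' @param rule `"strictly_below"` (flow indices) or `"at_or_below"` (FFR).
#' @return logical, `TRUE` = abnormal.
#' @examples
#' classifyAbnormal(2.1, 2.1, "strictly_below") # FALSE
#' classifyAbnormal(0.8, 0.8, "at_or_below") # TRUE
#' @export
classifyAbnormal <- function(value, cutoff,
                             rule = c("strictly_below", "at_or_below")) {
  rule <- match.arg(rule)
  if (any(!is.finite(value))) stop("values must be finite")
  if (rule == "strictly_below") value < cutoff else value <= cutoff
}

#' Build a 2x2 contingency table of index test vs. reference
#'
#' @param testAbnormal,refAbnormal logical vectors (index test and reference
#'   standard, `TRUE` = abnormal).
#' @return named list of counts `tp`, `fp`, `fn`, `tn` (tp = abnormal by
#'   both).
#' @export
contingencyTable <- function(testAbnormal, refAbnormal) {
  stopifnot(
    length(testAbnormal) == length(refAbnormal),
    is.logical(testAbnormal), is.logical(refAbnormal)
  )
  list(
    tp = sum(testAbnormal & refAbnormal),
    fp = sum(testAbnormal & !refAbnormal),
    fn = sum(!testAbnormal & refAbnormal),
    tn = sum(!testAbnormal & !refAbnormal)
  )
}

.checkTable <- function(table) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(table)))
  n <- table$tp + table$fp + table$fn + table$tn
  if (any(unlist(table[c("tp", "fp", "fn", "tn")]) < 0) || n <= 0) {
    stop("contingency counts must be >= 0 with a positive total")
  }
  n
}

#' Diagnostic performance of a 2x2 table
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value, each in percent. A rate with a zero denominator is reported as
#' `NA`, never as 0.
#'
#' @param table counts `tp`, `fp`, `fn`, `tn` (see [contingencyTable()]).
#' @return named list of the five rates in percent.
#' @examples
#' diagnosticMetrics(list(tp = 7, fp = 12, fn = 5, tn = 66))
#' @export
diagnosticMetrics <- function(table) {
  n <- .checkTable(table)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(table, list(
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, n),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn)
  ))
}

#' Cohen's kappa of a 2x2 table
#'
#' Unweighted chance-corrected agreement:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement
#' `po = (tp + tn)/n` and chance agreement
#' `pe = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)] / n^2`. Returns `NA` when
#' `pe = 1` (degenerate margins).
#'
#' @inheritParams diagnosticMetrics
#' @return scalar kappa in [-1, 1], or `NA`.
#' @examples
#' cohenKappa(list(tp = 7, fp = 12, fn = 5, tn = 66)) # ~0.344
#' @export
cohenKappa <- function(table) {
  n <- .checkTable(table)
  po <- (table$tp + table$tn) / n
  pe <- ((table$tp + table$fp) * (table$tp + table$fn) +
    (table$fn + table$tn) * (table$fp + table$tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve for a "lower is more abnormal" score
#'
#' Sweeps the abnormality rule `score < threshold` over all unique observed
#' score values plus -Inf/+Inf sentinels, computes (1 - specificity,
#' sensitivity) at each threshold, the area under the curve by the trapezoid
#' rule, and the cutoff maximizing Youden's J = sensitivity + specificity -
#' 1 (ties broken towards the smallest cutoff).
#'
#' @param scores numeric; lower values indicate abnormality.
#' @param truth logical; `TRUE` = abnormal by the reference.
#' @return list: `points` (data.frame `threshold`, `fpr`, `tpr`), `auc`, and
#'   `bestCutoff`.
#' @examples
#' rocCurve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))$auc # 1
#' @export
rocCurve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), is.logical(truth))
  if (any(!is.finite(scores))) stop("scores must be finite")
  nPos <- sum(truth)
  nNeg <- sum(!truth)
  if (nPos == 0 || nNeg == 0) {
    stop("ROC needs both abnormal and normal cases in the truth")
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(c) sum(scores < c & truth) / nPos, numeric(1))
  fpr <- vapply(thr, function(c) sum(scores < c & !truth) / nNeg, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  best <- thr[which(j == max(j))]
  list(
    points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
    auc = auc,
    bestCutoff = min(best)
  )
}

#' Bland-Altman agreement between two measurement methods
#'
#' Bias (mean of `x - y`) and 95% limits of agreement
#' (bias +/- 1.96 * SD of the differences, sample SD with n - 1).
#'
#' @param x,y paired measurements, equal length >= 2.
#' @return list: `bias`, `loaLow`, `loaHigh`, `sd`.
#' @examples
#' blandAltman(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  }
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s, sd = s)
}

#' Pearson product-moment correlation
#'
#' Validated thin wrapper around [stats::cor()]: requires at least 3 pairs
#' and non-degenerate variance in both variables (zero variance yields `NA`
#' rather than an error from downstream arithmetic).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar correlation, or `NA` if either variance is zero.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with at least 3 pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Full diagnostic-concordance report of a dual-modality study
#'
#' The study's statistical layer in one call. Territory-level (LAD, LCX,
#' RCA) MFR from each modality is classified against FFR (CZT-SPECT MFR <
#' `cztMfrCutoff`, PET MFR < `petMfrCutoff`, FFR abnormal <= `ffrCutoff`),
#' yielding a 2x2 table, the five diagnostic rates, Cohen's kappa and the
#' discordant-territory count per modality. Patient-level global MBF
#' (rest and stress pooled) and global MFR are compared across modalities by
#' Bland-Altman and Pearson correlation. ROC analyses evaluate CZT global
#' stress MBF and CZT global MFR against PET-defined abnormality (PET stress
#' MBF < `stressMbfCutoff`, PET MFR < `petMfrCutoff`); an ROC is reported as
#' `NULL` when the PET reference has only one class.
#'
#' @param spectResults,petResults data.frames with columns `patient_id`,
#'   `region`, `rest_mbf`, `stress_mbf`, `mfr` covering regions GLOBAL, LAD,
#'   LCX, RCA for every patient (per-patient outputs of [quantifySpect()] /
#'   [quantifyPet()] with a `patient_id` column added).
#' @param ffrTable data.frame with columns `patient_id`, `territory`, `ffr`.
#' @param thresholds a [FlowThresholds-class].
#' @return nested list: per modality (`czt`, `pet`) the `table`, `metrics`,
#'   `kappa` and `discordant` count; `agreement` with Bland-Altman and
#'   Pearson r for global MBF and MFR; `roc` for CZT stress MBF and MFR;
#'   `nTerritories`.
#' @export
concordanceReport <- function(spectResults, petResults, ffrTable,
                              thresholds = flowThresholds()) {
  stopifnot(is(thresholds, "FlowThresholds"))
  need <- c("patient_id", "region", "rest_mbf", "stress_mbf", "mfr")
  for (nm in c("spectResults", "petResults")) {
    df <- get(nm)
    if (!all(need %in% colnames(df))) {
      stop(nm, " must have columns: ", paste(need, collapse = ", "))
    }
  }
  if (!all(c("patient_id", "territory", "ffr") %in% colnames(ffrTable))) {
    stop("ffrTable must have columns patient_id, territory, ffr")
  }

  key <- function(p, r) paste(p, r, sep = ":")
  terr <- c("LAD", "LCX", "RCA")
  sTerr <- spectResults[spectResults$region %in% terr, ]
  pTerr <- petResults[petResults$region %in% terr, ]
  fKey <- key(ffrTable$patient_id, ffrTable$territory)
  sKey <- key(sTerr$patient_id, sTerr$region)
  pKey <- key(pTerr$patient_id, pTerr$region)
  for (pair in list(
    c("SPECT", paste(setdiff(fKey, sKey), collapse = ", ")),
    c("PET", paste(setdiff(fKey, pKey), collapse = ", "))
  )) {
    if (nzchar(pair[2])) {
      stop(
        "FFR territories missing from ", pair[1], " results: ", pair[2]
      )
    }
  }

  ffrAbn <- classifyAbnormal(ffrTable$ffr, thresholds@ffrCutoff, "at_or_below")
  modality <- function(res, resKey, cutoff) {
    mfr <- res$mfr[match(fKey, resKey)]
    abn <- classifyAbnormal(mfr, cutoff, "strictly_below")
    tab <- contingencyTable(abn, ffrAbn)
    list(
      table = tab,
      metrics = diagnosticMetrics(tab),
      kappa = cohenKappa(tab),
      discordant = tab$fp + tab$fn
    )
  }
  czt <- modality(sTerr, sKey, thresholds@cztMfrCutoff)
  pet <- modality(pTerr, pKey, thresholds@petMfrCutoff)

  # patient-level global agreement between modalities
  sG <- spectResults[spectResults$region == "GLOBAL", ]
  pG <- petResults[petResults$region == "GLOBAL", ]
  m <- match(sG$patient_id, pG$patient_id)
  if (anyNA(m)) {
    stop(
      "patients missing from PET results: ",
      paste(sG$patient_id[is.na(m)], collapse = ", ")
    )
  }
  pG <- pG[m, ]
  mbfS <- c(sG$rest_mbf, sG$stress_mbf)
  mbfP <- c(pG$rest_mbf, pG$stress_mbf)
  agreement <- list(
    mbf = list(
      blandAltman = blandAltman(mbfS, mbfP),
      pearsonR = pearsonR(mbfS, mbfP)
    ),
    mfr = list(
      blandAltman = blandAltman(sG$mfr, pG$mfr),
      pearsonR = pearsonR(sG$mfr, pG$mfr)
    )
  )

  safeRoc <- function(scores, truth) {
    if (all(truth) || !any(truth)) NULL else rocCurve(scores, truth)
  }
  roc <- list(
    stressMbf = safeRoc(
      sG$stress_mbf,
      classifyAbnormal(
        pG$stress_mbf, thresholds@stressMbfCutoff, "strictly_below"
      )
    ),
    mfr = safeRoc(
      sG$mfr,
      classifyAbnormal(pG$mfr, thresholds@petMfrCutoff, "strictly_below")
    )
  )

  list(
    czt = czt, pet = pet, agreement = agreement, roc = roc,
    nTerritories = length(fKey)
  )
}
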