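# Batch screening driver and the regression / classification metrics used
# to benchmark predicted singlet-triplet gaps against reference values.
# The positive class throughout is "inverted" (gap < 0).

#' Screen a manifest of structures
#'
#' Runs the full gap ladder over every row of a manifest and collects one
#' record per row.  Per-molecule failures are captured in the `status`
#' column (`failed:<reason>`) and never abort the batch.
#'
#' @param manifest Data frame or CSV path with columns `id`,
#'   `structure_path`, and optionally `ref_gap_eV`.
#' @param config Configuration list ([pppConfig()]).
#' @param out Optional path; when given, the results are also written as
#'   CSV.
#' @param base_dir Directory against which relative structure paths are
#'   resolved (default: the manifest's directory for path input, `"."`
#'   otherwise).
#' @return Data frame with one row per manifest row: `id`, `E_S1_eV`,
#'   `E_T1_eV`, `f_S1`, `overlap_HL`, `gap_scf`, `dsp_scf`,
#'   `gap_scf_dsp`, `gap_cis`, `dsp_cis`, `gap_cis_dsp`,
#'   `gap_cis_dsp_lc`, `inverted`, `warnings`, `status`, and `ref_gap_eV`
#'   when present in the manifest.  The failure count is attached as
#'   `attr(, "n_failed")`.
#' @export
screen <- function(manifest, config = pppConfig(), out = NULL, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (!all(c("id", "structure_path") %in% names(manifest))) {
    stop("manifest needs columns 'id' and 'structure_path'", call. = FALSE)
  }
  num_cols <- c("E_S1_eV", "E_T1_eV", "f_S1", "overlap_HL", "gap_scf",
                "dsp_scf", "gap_scf_dsp", "gap_cis", "dsp_cis",
                "gap_cis_dsp", "gap_cis_dsp_lc")
  rows <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    rec <- stats::setNames(as.list(rep(NA_real_, length(num_cols))), num_cols)
    rec <- c(list(id = manifest$id[k]), rec,
             list(inverted = NA, warnings = "", status = "ok"))
    res <- tryCatch({
      path <- manifest$structure_path[k]
      if (!file.exists(path)) path <- file.path(base_dir, manifest$structure_path[k])
      gaps <- computeGaps(path, config = config, force = TRUE)
      rec$E_S1_eV <- gaps$E_S1; rec$E_T1_eV <- gaps$E_T1
      rec$f_S1 <- gaps$f_S1; rec$overlap_HL <- gaps$homo_lumo_overlap
      rec$gap_scf <- gaps$gap_scf; rec$dsp_scf <- gaps$dsp_scf
      rec$gap_scf_dsp <- gaps$gap_scf_dsp; rec$gap_cis <- gaps$gap_cis
      rec$dsp_cis <- gaps$dsp_cis; rec$gap_cis_dsp <- gaps$gap_cis_dsp
      rec$gap_cis_dsp_lc <- gaps$gap_cis_dsp_lc
      rec$inverted <- isInverted(gaps, level = config$classify$level,
                                 use_lc = config$classify$use_lc,
                                 threshold = config$classify$threshold)
      rec$warnings <- paste(gaps$warnings, collapse = ";")
      rec
    }, error = function(e) {
      rec$status <- paste0("failed:", conditionMessage(e))
      rec
    })
    rows[[k]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(c(list(id = character(0)),
                    stats::setNames(rep(list(numeric(0)), length(num_cols)),
                                    num_cols),
                    list(inverted = logical(0), warnings = character(0),
                         status = character(0))))
  if ("ref_gap_eV" %in% names(manifest)) res$ref_gap_eV <- manifest$ref_gap_eV
  n_failed <- sum(res$status != "ok")
  attr(res, "n_failed") <- n_failed
  message(sprintf("screened %d molecules, %d failed (success rate %.2f%%)",
                  nrow(res), n_failed,
                  if (nrow(res)) 100 * (1 - n_failed / nrow(res)) else 100))
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Confusion matrix for inverted-gap classification
#'
#' Positive class = inverted (gap below `threshold`).
#'
#' @param pred,ref Numeric gap vectors (eV) of equal length.
#' @param threshold Decision threshold (default 0).
#' @return Object of class `ppp_confusion` with integer fields `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusionMatrix <- function(pred, ref, threshold = 0) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(pred) & !is.na(ref)
  p <- pred[keep] < threshold; r <- ref[keep] < threshold
  structure(list(TP = sum(p & r), TN = sum(!p & !r),
                 FP = sum(p & !r), FN = sum(!p & r)),
            class = "ppp_confusion")
}

#' @export
print.ppp_confusion <- function(x, ...) {
  cat(sprintf("<ppp_confusion> TP %d  TN %d  FP %d  FN %d (total %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' recall = TP/(TP+FN); specificity = TN/(TN+FP); accuracy =
#' (TP+TN)/total; F1 = 2TP/(2TP+FP+FN); for hard binary predictions the
#' ROC-AUC equals the balanced accuracy (recall+specificity)/2.  Ratios
#' with zero denominator are returned as 0 and listed in the `undefined`
#' attribute.
#'
#' @param cm A `ppp_confusion` (or list with TP/TN/FP/FN).
#' @return Named list: `accuracy`, `recall`, `specificity`, `f1`,
#'   `roc_auc`.
#' @export
classificationMetrics <- function(cm) {
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  undef <- character()
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(0) }
    num / den
  }
  recall <- ratio(cm$TP, cm$TP + cm$FN, "recall")
  specificity <- ratio(cm$TN, cm$TN + cm$FP, "specificity")
  out <- list(accuracy = (cm$TP + cm$TN) / tot,
              recall = recall,
              specificity = specificity,
              f1 = ratio(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN, "f1"),
              roc_auc = (recall + specificity) / 2)
  attr(out, "undefined") <- undef
  out
}

#' Regression metrics between predicted and reference gaps
#'
#' Coefficient of determination `R2 = 1 - SS_res/SS_tot`, Spearman rank
#' correlation, and RMSE.  A constant reference makes R2 undefined (NA
#' with a warning).
#'
#' @param pred,ref Numeric vectors, length >= 2.
#' @return Named list `r2`, `spearman`, `rmse`.
#' @export
regressionMetrics <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(pred) & !is.na(ref)
  pred <- pred[keep]; ref <- ref[keep]
  if (length(pred) < 2L) stop("need at least 2 paired values", call. = FALSE)
  ss_tot <- sum((ref - mean(ref))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant reference: R2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum((ref - pred)^2) / ss_tot
  list(r2 = r2,
       spearman = suppressWarnings(stats::cor(pred, ref, method = "spearman")),
       rmse = sqrt(mean((pred - ref)^2)))
}

#' Combined metric report for screening results
#'
#' @param results Data frame from [screen()] (must contain the prediction
#'   column and a reference column).
#' @param ref_col Name of the reference-gap column (default
#'   `"ref_gap_eV"`).
#' @param pred_col Prediction column (default `"gap_cis_dsp"`).
#' @param threshold Classification threshold.
#' @return List with `regression`, `confusion`, `classification`, and
#'   `n` (molecules scored); class `ppp_metrics`.
#' @export
metricsReport <- function(results, ref_col = "ref_gap_eV",
                          pred_col = "gap_cis_dsp", threshold = 0) {
  if (!ref_col %in% names(results)) stop("no column '", ref_col, "'", call. = FALSE)
  ok <- results$status == "ok" & !is.na(results[[ref_col]])
  pred <- results[[pred_col]][ok]; ref <- results[[ref_col]][ok]
  cm <- confusionMatrix(pred, ref, threshold)
  structure(list(regression = regressionMetrics(pred, ref),
                 confusion = cm,
                 classification = classificationMetrics(cm),
                 n = sum(ok), pred_col = pred_col),
            class = "ppp_metrics")
}

#' @export
print.ppp_metrics <- function(x, ...) {
  r <- x$regression; c2 <- x$classification; cm <- x$confusion
  cat(sprintf("<ppp_metrics> %d molecules on %s\n", x$n, x$pred_col))
  # 2-dp display uses round-half-even, matching the conventions of the
  # numeric stack the reference tables were produced with
  cat(sprintf("  R2 %.2f  rho %.2f  RMSE %.2f eV\n", r$r2, r$spearman, r$rmse))
  cat(sprintf("  F1 %.2f  ROC-AUC %.2f  acc %.2f  recall %.2f  spec %.2f\n",
              c2$f1, c2$roc_auc, c2$accuracy, c2$recall, c2$specificity))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", cm$TP, cm$TN, cm$FP, cm$FN))
  invisible(x)
}
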