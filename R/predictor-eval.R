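# Per-residue benchmarking of binary disorder predictors against a
# consensus reference. Positives are consensus-disordered residues,
# negatives consensus-structured; unknown residues are excluded.

.as_predicted_disordered <- function(prediction) {
  if (is.logical(prediction)) return(prediction)
  if (is.numeric(prediction)) return(prediction >= 0.5)
  if (is.character(prediction)) {
    ok <- prediction %in% c("disordered", "ordered", "D", "S", "0", "1")
    if (!all(ok)) {
      stop("unrecognised prediction label: ", prediction[which(!ok)[1L]])
    }
    return(prediction %in% c("disordered", "D", "1"))
  }
  stop("prediction must be logical, numeric scores or character labels")
}

#' Confusion counts of a prediction against a consensus reference
#'
#' Reference \code{"D"} positions are positives, \code{"S"} negatives;
#' \code{"U"} (unknown) positions are skipped entirely. Numeric prediction
#' scores are binarized at 0.5.
#'
#' @param reference A \code{consensus_track} or a character vector over
#'   \code{D}/\code{S}/\code{U}.
#' @param prediction Logical vector (TRUE = predicted disordered), numeric
#'   scores in \code{[0, 1]}, or labels \code{"disordered"}/\code{"ordered"};
#'   same length as the reference.
#' @return List of counts \code{TP}, \code{FP}, \code{TN}, \code{FN} and
#'   \code{n_evaluated}.
#' @export
confusion <- function(reference, prediction) {
  ref <- if (inherits(reference, "consensus_track")) reference$states
         else as.character(reference)
  pred <- .as_predicted_disordered(prediction)
  if (length(ref) != length(pred)) {
    stop("reference and prediction lengths differ (",
         length(ref), " vs ", length(pred), ")")
  }
  keep <- ref != "U"
  ref <- ref[keep]
  pred <- pred[keep]
  list(TP = sum(ref == "D" & pred),
       FP = sum(ref == "S" & pred),
       TN = sum(ref == "S" & !pred),
       FN = sum(ref == "D" & !pred),
       n_evaluated = length(ref))
}

#' Derived classification metrics from confusion counts
#'
#' Computes accuracy, balanced accuracy (BAC), F1, Matthews correlation
#' coefficient (MCC), precision (PPV), specificity (TNR) and recall (TPR).
#' Any metric whose denominator is zero is reported as 0 and named in
#' \code{zero_denominator} so tables stay rectangular.
#'
#' @param counts List with \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @return List with the four counts, the seven derived metrics and a
#'   character vector \code{zero_denominator}.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      0
    } else num / den
  }
  tpr <- safe(tp, tp + fn, "TPR")
  tnr <- safe(tn, tn + fp, "TNR")
  ppv <- safe(tp, tp + fp, "PPV")
  acc <- safe(tp + tn, tp + fp + tn + fn, "accuracy")
  f1 <- safe(2 * ppv * tpr, ppv + tpr, "F1")
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "MCC")
  list(TP = counts$TP, FP = counts$FP, TN = counts$TN, FN = counts$FN,
       accuracy = acc, BAC = (tpr + tnr) / 2, F1 = f1, MCC = mcc,
       PPV = ppv, TNR = tnr, TPR = tpr,
       zero_denominator = flagged)
}

#' Benchmark prediction methods against consensus references
#'
#' Counts are pooled over all proteins per method (micro-averaging, i.e.
#' metrics are computed per residue over the whole dataset) before deriving
#' metrics; methods are ranked by MCC, descending.
#'
#' @param methods Named list; each element is a named list mapping
#'   protein id to a prediction vector (see \code{\link{confusion}}).
#' @param references Named list of \code{consensus_track}s (or state
#'   vectors) keyed by protein id.
#' @return Data.frame, one row per method, with pooled counts and metrics,
#'   sorted by MCC descending.
#' @export
benchmark_predictors <- function(methods, references) {
  rows <- lapply(names(methods), function(method) {
    preds <- methods[[method]]
    ids <- names(preds)
    missing_ref <- setdiff(ids, names(references))
    if (length(missing_ref)) {
      stop("no reference for protein(s): ",
           paste(missing_ref, collapse = ", "))
    }
    pooled <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (id in ids) {
      cc <- confusion(references[[id]], preds[[id]])
      pooled <- Map(`+`, pooled, cc[c("TP", "FP", "TN", "FN")])
    }
    m <- compute_metrics(pooled)
    data.frame(method = method, TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
               MCC = m$MCC, F1 = m$F1, accuracy = m$accuracy, BAC = m$BAC,
               PPV = m$PPV, TNR = m$TNR, TPR = m$TPR,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$MCC), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read per-residue predictions from TSV
#'
#' @param path TSV with columns \code{protein_id}, \code{position},
#'   \code{residue}, \code{score}, \code{state} (\code{disordered} /
#'   \code{ordered}); one method per file.
#' @return Named list mapping protein id to a logical prediction vector
#'   ordered by position, with the scores attached as an attribute.
#' @export
read_predictions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "state")
  if (!all(required %in% names(df))) {
    stop("prediction table must have columns: ",
         paste(required, collapse = ", "))
  }
  out <- lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      stop("prediction positions for ", d$protein_id[1L],
           " are not 1..L without gaps")
    }
    v <- .as_predicted_disordered(d$state)
    if ("score" %in% names(d)) attr(v, "score") <- d$score
    v
  })
  out
}

#' Write a benchmark table as TSV
#'
#' @param benchmark Result of \code{\link{benchmark_predictors}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_benchmark_tsv <- function(benchmark, path) {
  cols <- c("method", "MCC", "F1", "accuracy", "PPV", "TNR", "TPR")
  out <- benchmark[, cols]
  names(out) <- c("method", "MCC", "F1_score", "accuracy", "precision",
                  "specificity", "recall")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
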