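# Multiclass evaluation: confusion matrix, one-vs-rest counts, the five
# metrics (accuracy, precision, recall, specificity, F1) per class and
# macro-averaged, and the 4-class -> 3-class merge used clinically
# (0 and 1+ are negative, 2+ equivocal, 3+ positive).

#' Confusion matrix over a fixed class order
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param classOrder class vocabulary; both label vectors must be drawn
#'   from it. Defaults to the union of observed labels.
#' @return K x K integer matrix; entry (i, j) counts true class i
#'   predicted as class j.
#' @export
#' @examples
#' confusionMatrix(c("0", "1+", "1+"), c("0", "1+", "0"),
#'                 classOrder = c("0", "1+"))
confusionMatrix <- function(yTrue, yPred, classOrder = NULL) {
  if (length(yTrue) != length(yPred)) {
    .data_error("yTrue and yPred must have the same length")
  }
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (is.null(classOrder)) classOrder <- sort(unique(c(yTrue, yPred)))
  if (!all(yTrue %in% classOrder) || !all(yPred %in% classOrder)) {
    .data_error("labels outside the declared class order")
  }
  tab <- table(factor(yTrue, levels = classOrder),
               factor(yPred, levels = classOrder))
  m <- matrix(as.integer(tab), nrow = length(classOrder),
              dimnames = list(true = classOrder, predicted = classOrder))
  m
}

#' One-vs-rest confusion counts per class
#'
#' @param cm a square confusion matrix (true in rows).
#' @return data.frame with columns class, TP, FP, TN, FN.
#' @export
confusionCounts <- function(cm) {
  total <- sum(cm)
  k <- nrow(cm)
  data.frame(
    class = rownames(cm),
    TP = diag(cm),
    FP = colSums(cm) - diag(cm),
    FN = rowSums(cm) - diag(cm),
    TN = total - rowSums(cm) - colSums(cm) + diag(cm),
    row.names = NULL
  )[, c("class", "TP", "FP", "TN", "FN")]
}

.safe_ratio <- function(num, den, what, cls) {
  out <- numeric(length(num))
  zero <- den == 0
  if (any(zero)) {
    warning(sprintf("%s undefined (zero denominator) for class %s; set to 0",
                    what, paste(cls[zero], collapse = ", ")),
            call. = FALSE)
  }
  out[!zero] <- num[!zero] / den[!zero]
  out
}

#' Per-class and macro-averaged classification metrics
#'
#' One-vs-rest metrics per class:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), specificity = TN/(FP+TN),
#' F1 = 2 / (1/precision + 1/recall). Zero-denominator cases yield 0
#' with a warning (never NaN, so repeated-split aggregation stays
#' finite). The macro average is the unweighted mean over classes;
#' overall accuracy (trace over total) is reported alongside.
#'
#' @param x a confusion matrix (square integer matrix, true in rows) or
#'   a data.frame of per-class counts as from [confusionCounts()].
#' @return List with `perClass` (data.frame), `macro` (named numeric of
#'   the five metrics) and `overallAccuracy`.
#' @export
#' @examples
#' cm <- matrix(c(3, 1, 1, 5), 2, byrow = TRUE,
#'              dimnames = list(c("a", "b"), c("a", "b")))
#' computeMetrics(cm)$perClass
computeMetrics <- function(x) {
  if (is.matrix(x)) {
    counts <- confusionCounts(x)
    overall <- sum(diag(x)) / sum(x)
  } else {
    counts <- x
    overall <- NA_real_
  }
  with_cols <- c("TP", "FP", "TN", "FN")
  if (!all(with_cols %in% names(counts))) {
    .data_error("counts must have columns TP, FP, TN, FN")
  }
  if (any(counts[with_cols] < 0)) .data_error("counts must be non-negative")
  cls <- as.character(counts$class)
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  acc  <- .safe_ratio(TP + TN, TP + TN + FP + FN, "accuracy", cls)
  prec <- .safe_ratio(TP, TP + FP, "precision", cls)
  rec  <- .safe_ratio(TP, TP + FN, "recall", cls)
  spec <- .safe_ratio(TN, FP + TN, "specificity", cls)
  f1 <- numeric(length(TP))
  ok <- prec + rec > 0
  f1[ok] <- 2 * prec[ok] * rec[ok] / (prec[ok] + rec[ok])
  if (any(!ok)) {
    warning(sprintf("F1 undefined for class %s; set to 0",
                    paste(cls[!ok], collapse = ", ")), call. = FALSE)
  }
  perClass <- data.frame(class = cls, accuracy = acc, precision = prec,
                         recall = rec, specificity = spec, f1 = f1,
                         row.names = NULL)
  macro <- c(accuracy = mean(acc), precision = mean(prec),
             recall = mean(rec), specificity = mean(spec), f1 = mean(f1))
  list(perClass = perClass, macro = macro, overallAccuracy = overall)
}

#' Merge HER2 scores into the three clinical groups
#'
#' 0 and 1+ map to Negative, 2+ to Equivocal, 3+ to Positive; the tissue
#' classes normal and noise (when present) pass through unchanged.
#'
#' @param y vector of labels.
#' @param mapping named character vector overriding the default map.
#' @return Character vector of merged labels.
#' @export
#' @examples
#' mergeClasses(c("0", "1+", "2+", "3+"))
mergeClasses <- function(y, mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- c("0" = "Negative", "1+" = "Negative",
                 "2+" = "Equivocal", "3+" = "Positive",
                 normal = "normal", noise = "noise")
  }
  y <- as.character(y)
  if (length(y) == 0L) return(character())
  unknown <- setdiff(unique(y), names(mapping))
  if (length(unknown)) {
    .data_error(paste("labels without a merge mapping:",
                      paste(unknown, collapse = ", ")))
  }
  unname(mapping[y])
}
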