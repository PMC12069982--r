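#' One-vs-rest confusion counts
#'
#' @param truth,prediction Vectors (factor or character) of equal length.
#' @param positive The class treated as positive.
#' @return List of class `confusion_counts` with integers `TP`, `FP`,
#'   `TN`, `FN` (summing to `length(truth)`).
#' @export
#' @examples
#' confusion_counts(c("a", "a", "b"), c("a", "b", "b"), positive = "a")
confusion_counts <- function(truth, prediction, positive) {
  if (length(truth) != length(prediction)) {
    abort("truth and prediction lengths differ", class = "nutriclass_shape_error")
  }
  t_pos <- as.character(truth) == positive
  p_pos <- as.character(prediction) == positive
  structure(list(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
                 TN = sum(!t_pos & !p_pos), FN = sum(t_pos & !p_pos)),
            class = "confusion_counts")
}

ratio0 <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s undefined (zero denominator); returning 0", what))
    return(0)
  }
  num / den
}

#' Confusion-matrix metrics
#'
#' Standard one-vs-rest metrics from [confusion_counts()]:
#' sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)`, accuracy `(TP+TN)/n` and
#' `F1 = 2PR/(P+R)`.  Zero-denominator cases return 0 with a warning.
#'
#' @param counts A `confusion_counts` object.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' cc <- structure(list(TP = 9, FP = 0, TN = 0, FN = 1),
#'                 class = "confusion_counts")
#' sensitivity(cc)  # 0.9
sensitivity <- function(counts) ratio0(counts$TP, counts$TP + counts$FN, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(counts) ratio0(counts$TN, counts$TN + counts$FP, "specificity")

#' @rdname sensitivity
#' @export
precision <- function(counts) ratio0(counts$TP, counts$TP + counts$FP, "precision")

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  ratio0(counts$TP + counts$TN, n, "accuracy")
}

#' @rdname sensitivity
#' @export
f1_score <- function(counts) {
  p <- suppressWarnings(precision(counts))
  r <- suppressWarnings(sensitivity(counts))
  if (p + r == 0) {
    warn("F1 undefined (precision + recall = 0); returning 0")
    return(0)
  }
  2 * p * r / (p + r)
}

#' Mean squared error of probability predictions
#'
#' Mean over samples and classes of the squared difference between the
#' one-hot encoded truth and the predicted probability matrix:
#' `(1/(nC)) * sum_j ||Y_j - Yhat_j||^2`.
#'
#' @param truth Vector of true labels; must match the probability
#'   matrix's column names (or levels `1..C` if unnamed).
#' @param prob `n x C` probability matrix with rows summing to 1.
#' @return Scalar MSE.
#' @export
#' @examples
#' mse_prob(c("a", "b"), matrix(c(1, 0, 0, 1), 2, 2,
#'          dimnames = list(NULL, c("a", "b"))))  # 0
mse_prob <- function(truth, prob) {
  prob <- as.matrix(prob)
  if (length(truth) != nrow(prob)) {
    abort("truth length does not match probability rows",
          class = "nutriclass_shape_error")
  }
  lev <- colnames(prob) %||% as.character(seq_len(ncol(prob)))
  ci <- match(as.character(truth), lev)
  if (anyNA(ci)) abort("truth labels not found among probability columns",
                       class = "nutriclass_shape_error")
  onehot <- matrix(0, nrow(prob), ncol(prob))
  onehot[cbind(seq_len(nrow(prob)), ci)] <- 1
  mean((onehot - prob)^2)
}

#' Per-class and macro metrics report
#'
#' One-vs-rest sensitivity, specificity, precision, accuracy and F1 for
#' every class, plus an unweighted macro average row.  When a
#' probability matrix is supplied, a per-class Brier-style MSE (squared
#' error of the class's probability against its one-hot indicator) and
#' its macro mean are included.
#'
#' @param truth,prediction Label vectors of equal length.
#' @param prob Optional `n x C` probability matrix with class column
#'   names.
#' @param levels Label universe; defaults to the union of observed
#'   labels (or `prob` column names).
#' @return Tibble of class `nutri_metrics`: one row per class plus a
#'   `macro` row.
#' @export
metrics_report <- function(truth, prediction, prob = NULL, levels = NULL) {
  levels <- levels %||% colnames(prob) %||%
    sort(union(as.character(truth), as.character(prediction)))
  rows <- map(levels, function(cl) {
    cc <- confusion_counts(truth, prediction, cl)
    tibble(class = cl,
           n = cc$TP + cc$FN,
           sensitivity = suppressWarnings(sensitivity(cc)),
           specificity = suppressWarnings(specificity(cc)),
           precision = suppressWarnings(precision(cc)),
           accuracy = suppressWarnings(accuracy(cc)),
           f1 = suppressWarnings(f1_score(cc)),
           mse = if (is.null(prob)) NA_real_ else {
             pc <- prob[, cl]
             mean(((as.character(truth) == cl) - pc)^2)
           })
  })
  per_class <- list_rbind(rows)
  macro <- per_class |>
    summarise(class = "macro", n = sum(.data$n),
              across(c("sensitivity", "specificity", "precision",
                       "accuracy", "f1", "mse"), mean))
  out <- bind_rows(per_class, macro)
  class(out) <- c("nutri_metrics", class(out))
  out
}

#' Metrics bar plot
#'
#' @param object A `nutri_metrics` report.
#' @param ... Unused.
#' @return A ggplot faceting the per-class metrics.
#' @export
autoplot.nutri_metrics <- function(object, ...) {
  as_tibble(object) |>
    filter(.data$class != "macro") |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "precision",
                          "accuracy", "f1"),
                        names_to = "metric", values_to = "value") |>
    ggplot(aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    labs(x = NULL, y = NULL, title = "Per-class classification metrics")
}
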