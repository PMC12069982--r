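#' Fit min-max normalization parameters
#'
#' Records the exact per-column extrema of the training data.  Together
#' with [apply_minmax()] this implements the rescaling
#' `y' = (y - min) / (max - min)` that maps every feature into `[0, 1]`.
#'
#' @param data Data frame or matrix of numeric features (all finite).
#' @return A tibble of class `minmax_params` with columns `column`,
#'   `min`, `max`.
#' @export
#' @examples
#' fit_minmax(data.frame(a = c(2, 4, 6), b = c(10, 15, 20)))
fit_minmax <- function(data) {
  m <- as_feature_matrix(data)
  out <- tibble(column = colnames(m) %||% paste0("V", seq_len(ncol(m))),
                min = unname(apply(m, 2, min)),
                max = unname(apply(m, 2, max)))
  class(out) <- c("minmax_params", class(out))
  out
}

#' Apply (or invert) min-max normalization
#'
#' `apply_minmax()` rescales each column to `[0, 1]` using the training
#' extrema in `params`; values beyond the training range are clipped so
#' the `[0, 1]` contract holds on new data, and constant columns
#' (`max == min`, where the formula is 0/0) map to 0.  `invert_minmax()`
#' undoes the rescaling for non-constant columns.
#'
#' @param data Data frame or matrix with the same columns as `params`.
#' @param params A `minmax_params` object from [fit_minmax()].
#' @return Tibble of the same shape as `data`.
#' @export
#' @examples
#' p <- fit_minmax(data.frame(a = c(2, 4, 6)))
#' apply_minmax(data.frame(a = c(2, 4, 6, 8)), p)  # 8 clips to 1
apply_minmax <- function(data, params) {
  m <- as_feature_matrix(data)
  if (ncol(m) != nrow(params)) {
    abort("column count does not match normalization parameters",
          class = "nutriclass_shape_error")
  }
  rng <- params$max - params$min
  out <- sweep(m, 2, params$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  colnames(out) <- params$column
  as_tibble(out)
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(data, params) {
  m <- as_feature_matrix(data)
  if (ncol(m) != nrow(params)) {
    abort("column count does not match normalization parameters",
          class = "nutriclass_shape_error")
  }
  out <- sweep(sweep(m, 2, params$max - params$min, "*"), 2, params$min, "+")
  colnames(out) <- params$column
  as_tibble(out)
}

#' Train/test split
#'
#' Seeded, disjoint and exhaustive partition of the rows of `data`.  With
#' `stratify_by` given, sampling is stratified so that each class keeps its
#' proportion in the test set to within one record.  The default
#' `test_fraction` of 0.3 follows the common 70/30 protocol; 0.2 (80/20)
#' is equally supported.
#'
#' @param data Data frame of records.
#' @param test_fraction Fraction of rows assigned to the test set, in (0,1).
#' @param seed Integer seed.
#' @param stratify_by Optional column name (string) with class labels;
#'   every class must have at least 2 members.
#' @return Named list with tibbles `train` and `test`.
#' @export
#' @examples
#' sp <- split_train_test(data.frame(x = 1:10), 0.3, seed = 1)
#' nrow(sp$train); nrow(sp$test)
split_train_test <- function(data, test_fraction = 0.3, seed = 1L,
                             stratify_by = NULL) {
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < 2) abort("need at least 2 rows to split", class = "nutriclass_invalid_input")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)", class = "nutriclass_invalid_input")
  }
  withr::with_seed(as.integer(seed), {
    if (is.null(stratify_by)) {
      n_test <- max(1L, min(n - 1L, round(n * test_fraction)))
      test_idx <- sort(sample.int(n, n_test))
    } else {
      cls <- as.character(data[[stratify_by]])
      tab <- table(cls)
      if (any(tab < 2)) {
        abort("every class must have at least 2 members for stratification",
              class = "nutriclass_invalid_input")
      }
      test_idx <- sort(unlist(lapply(names(tab), function(g) {
        idx <- which(cls == g)
        k <- max(1L, min(length(idx) - 1L, round(length(idx) * test_fraction)))
        sample(idx, k)
      }), use.names = FALSE))
    }
  })
  list(train = data[-test_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE])
}
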