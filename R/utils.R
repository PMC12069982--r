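#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols count pull across left_join
#' @importFrom purrr map map_dbl map_int map2 imap pmap list_rbind
#' @importFrom stats rnorm runif qnorm pnorm median dist setNames predict
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#' @importFrom utils read.csv write.csv
NULL

# Deterministic per-stage seed derived from a global seed: a small polynomial
# hash of the stage name folded into the seed, kept inside the 32-bit integer
# range so set.seed() accepts it on every platform.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(as.numeric(seed)) %% 2147480009 * 7919 + h) %% 2147480009)
}

assert_finite <- function(x, what = "value") {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("non-finite %s supplied", what), class = "nutriclass_invalid_input")
  }
  invisible(x)
}

# Extract the numeric feature matrix from a data frame, erroring on
# non-finite entries; keeps column names.
as_feature_matrix <- function(data, what = "feature data") {
  if (is.matrix(data)) {
    m <- data
  } else {
    data <- as.data.frame(data)
    num <- vapply(data, is.numeric, logical(1))
    if (!all(num)) {
      abort(sprintf("%s contains non-numeric columns: %s", what,
                    paste(names(data)[!num], collapse = ", ")),
            class = "nutriclass_invalid_input")
    }
    m <- as.matrix(data)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    abort(sprintf("%s must have at least one row and one column", what),
          class = "nutriclass_invalid_input")
  }
  assert_finite(m, what)
  m
}
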