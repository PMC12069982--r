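#' EGBF configuration
#'
#' Configuration for the fuzzy-entropy-modulated second-order
#' gradient-boosting classifier.
#'
#' @param rounds Number of boosting rounds `B` (>= 0); each round adds
#'   one tree per class.
#' @param learning_rate Shrinkage applied to every leaf weight, in (0, 1].
#' @param max_depth Maximum number of split levels per tree (a stump is
#'   depth 1).
#' @param alpha Per-leaf complexity penalty (the cost of adding a leaf).
#' @param beta L2 penalty on leaf weights.
#' @param lambda Weight of the fuzzy gain in the combined split score,
#'   in `[0, 1]`; `lambda = 0` reduces the learner to plain second-order
#'   gradient boosting.
#' @param leaf_denominator `"standard"` for the leaf weight `-P/(Q+beta)`
#'   consistent with the structure score, or `"as_printed"` for the
#'   `-P/(2Q+beta)` variant.
#' @param entropy_sign Fuzzy-entropy sign convention, see
#'   [fuzzy_entropy()].
#' @param min_child_hessian Minimum summed hessian required in each
#'   child of an accepted split.
#' @param n_classes Number of classes, or `NULL` to infer from data.
#' @param seed Integer seed.
#' @return List of class `egbf_config`.
#' @export
egbf_config <- function(rounds = 100L, learning_rate = 0.3, max_depth = 3L,
                        alpha = 0, beta = 1, lambda = 0.5,
                        leaf_denominator = c("standard", "as_printed"),
                        entropy_sign = c("conventional", "as_printed"),
                        min_child_hessian = 0, n_classes = NULL, seed = 1L) {
  leaf_denominator <- match.arg(leaf_denominator)
  entropy_sign <- match.arg(entropy_sign)
  if (rounds < 0) abort("rounds must be >= 0", class = "nutriclass_config_error")
  if (learning_rate <= 0 || learning_rate > 1) {
    abort("learning_rate must be in (0, 1]", class = "nutriclass_config_error")
  }
  if (max_depth < 1) abort("max_depth must be >= 1", class = "nutriclass_config_error")
  if (alpha < 0 || beta < 0 || min_child_hessian < 0) {
    abort("alpha, beta, min_child_hessian must be non-negative",
          class = "nutriclass_config_error")
  }
  if (lambda < 0 || lambda > 1) {
    abort("lambda must be in [0, 1]", class = "nutriclass_config_error")
  }
  structure(list(rounds = as.integer(rounds), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth), alpha = alpha,
                 beta = beta, lambda = lambda,
                 leaf_denominator = leaf_denominator,
                 entropy_sign = entropy_sign,
                 min_child_hessian = min_child_hessian,
                 n_classes = n_classes, seed = as.integer(seed)),
            class = "egbf_config")
}

#' Softmax gradients and hessians
#'
#' First and second derivatives of the multiclass cross-entropy loss
#' with softmax link, per sample and class: `p = pi - onehot(label)` and
#' `q = pi * (1 - pi)`, with `q` floored at 1e-16 for numerical safety.
#'
#' @param scores Numeric `n x C` matrix of raw (margin) scores.
#' @param labels Integer vector in `1..C` (or factor).
#' @return List with matrices `p`, `q` and the softmax probabilities `pi`.
#' @export
#' @examples
#' softmax_grad_hess(matrix(0, 1, 2), 1L)
softmax_grad_hess <- function(scores, labels) {
  scores <- as.matrix(scores)
  assert_finite(scores, "scores")
  if (is.factor(labels)) labels <- as.integer(labels)
  C <- ncol(scores)
  if (any(labels < 1 | labels > C)) {
    abort("labels outside 1..n_classes", class = "nutriclass_invalid_input")
  }
  pi <- softmax_rows(scores)
  p <- pi
  p[cbind(seq_len(nrow(scores)), labels)] <-
    p[cbind(seq_len(nrow(scores)), labels)] - 1
  q <- pmax(pi * (1 - pi), 1e-16)
  list(p = p, q = q, pi = pi)
}

softmax_rows <- function(scores) {
  z <- exp(scores - apply(scores, 1, max))
  z / rowSums(z)
}

#' Optimal leaf weight
#'
#' Closed-form minimizer of the regularized second-order objective for a
#' leaf with gradient sum `P` and hessian sum `Q`: `-P/(Q + beta)` (the
#' form consistent with the structure score), or the `-P/(2Q + beta)`
#' variant when `variant = "as_printed"`.
#'
#' @param P,Q Gradient and hessian sums over the leaf.
#' @param beta L2 penalty.
#' @param variant `"standard"` or `"as_printed"`.
#' @return Scalar weight.
#' @export
#' @examples
#' leaf_weight(2, 3, 1)                        # -0.5
#' leaf_weight(2, 3, 1, variant = "as_printed") # -2/7
leaf_weight <- function(P, Q, beta, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  den <- if (variant == "standard") Q + beta else 2 * Q + beta
  if (den <= 0) abort("non-positive leaf denominator",
                      class = "nutriclass_numerical_error")
  -P / den
}

#' Structure score of a tree
#'
#' `-1/2 * sum_k P_k^2 / (Q_k + beta) + alpha * H` over the `H` leaves,
#' with the loss's additive constant dropped.  The structural gain of a
#' split is `score(parent as one leaf) - score(two children)`.
#'
#' @param P,Q Numeric vectors of per-leaf gradient and hessian sums.
#' @param alpha Per-leaf penalty.
#' @param beta L2 penalty.
#' @return Scalar score (lower is better).
#' @export
#' @examples
#' structural_score(2, 3, alpha = 0, beta = 1)  # -0.5
structural_score <- function(P, Q, alpha, beta) {
  if (any(Q + beta <= 0)) abort("non-positive denominator",
                                class = "nutriclass_numerical_error")
  -0.5 * sum(P^2 / (Q + beta)) + alpha * length(P)
}

# Candidate table for a fitted term set: one row per (feature, term)
# with a usable threshold, in feature-column / low-medium-high order.
split_candidates <- function(terms, feature_names) {
  cand <- terms[!is.na(terms$threshold), , drop = FALSE]
  ord <- order(match(cand$feature, feature_names),
               match(cand$term, c("low", "medium", "high")))
  cand[ord, , drop = FALSE]
}

# Score all candidates at one node.  Returns a data frame with the raw
# structural gain, the fuzzy gain, and split admissibility.
score_node_candidates <- function(X, p, q, y, n_classes, idx, cand, mu,
                                  config) {
  PP <- sum(p[idx]); QP <- sum(q[idx])
  parent_leaf <- structural_score(PP, QP, config$alpha, config$beta)
  parent_mass <- vapply(seq_len(n_classes),
                        function(c) sum(y[idx] == c), numeric(1))
  nc <- nrow(cand)
  struct <- fuzz <- numeric(nc); ok <- logical(nc)
  for (i in seq_len(nc)) {
    xf <- X[idx, cand$feature[i]]
    left <- xf <= cand$threshold[i]
    PL <- sum(p[idx][left]); QL <- sum(q[idx][left])
    PR <- PP - PL; QR <- QP - QL
    child <- structural_score(c(PL, PR), c(QL, QR), config$alpha, config$beta)
    struct[i] <- parent_leaf - child
    ok[i] <- any(left) && !all(left) && struct[i] > 0 &&
      QL >= config$min_child_hessian && QR >= config$min_child_hessian
    mu_sub <- mu[[i]][idx]
    mass_t <- vapply(seq_len(n_classes),
                     function(c) sum(mu_sub[y[idx] == c]), numeric(1))
    fuzz[i] <- if (sum(mass_t) <= 0 || sum(parent_mass - mass_t) <= 0) 0 else
      fuzzy_gain(parent_mass, list(mass_t, parent_mass - mass_t),
                 sign = config$entropy_sign)
  }
  data.frame(i = seq_len(nc), struct = struct, fuzz = fuzz, ok = ok)
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Grow one fuzzy-split regression tree
#'
#' Depth-wise greedy growth on second-order statistics: every
#' (feature, fuzzy term) pair is a candidate, routed crisply at the
#' term's 0.5-membership threshold.  Each candidate is scored by the
#' convex combination `(1 - lambda) * g_struct + lambda * g_fuzzy` of
#' its structural and fuzzy gains, each min-max rescaled to `[0, 1]`
#' within the node's candidate set; a split is accepted only if its raw
#' structural gain is positive and both children carry at least
#' `min_child_hessian` summed hessian.  Leaves receive the closed-form
#' weight scaled by the learning rate.
#'
#' @param X Numeric feature matrix (named columns).
#' @param p,q Per-sample gradient and hessian vectors for this tree's
#'   class.
#' @param y Integer class labels in `1..n_classes` (for fuzzy masses).
#' @param n_classes Number of classes.
#' @param terms A `fuzzy_termset` from [fit_fuzzy_terms()].
#' @param config An [egbf_config()].
#' @return Nested list tree: internal nodes have `feature`, `term`,
#'   `threshold`, `left`, `right`; leaves have `weight`.
#' @export
grow_tree <- function(X, p, q, y, n_classes, terms, config = egbf_config()) {
  if (nrow(X) == 0) abort("empty node", class = "nutriclass_invalid_input")
  cand <- split_candidates(terms, colnames(X))
  mu <- map(seq_len(nrow(cand)), function(i) {
    fuzzy_membership(X[, cand$feature[i]], cand$left[i], cand$peak[i],
                     cand$right[i])
  })
  grow_node(X, p, q, y, n_classes, seq_len(nrow(X)), cand, mu, config,
            depth = 1L)
}

grow_node <- function(X, p, q, y, n_classes, idx, cand, mu, config, depth) {
  make_leaf <- function() {
    list(leaf = TRUE,
         weight = config$learning_rate *
           leaf_weight(sum(p[idx]), sum(q[idx]), config$beta,
                       config$leaf_denominator))
  }
  if (depth > config$max_depth || length(idx) < 2L || nrow(cand) == 0L) {
    return(make_leaf())
  }
  sc <- score_node_candidates(X, p, q, y, n_classes, idx, cand, mu, config)
  if (!any(sc$ok)) return(make_leaf())
  combined <- (1 - config$lambda) * rescale01(sc$struct) +
    config$lambda * rescale01(sc$fuzz)
  combined[!sc$ok] <- -Inf
  best <- which.max(combined)  # first maximum: feature then term order
  xf <- X[idx, cand$feature[best]]
  left <- idx[xf <= cand$threshold[best]]
  right <- setdiff(idx, left)
  list(leaf = FALSE,
       feature = cand$feature[best], term = cand$term[best],
       threshold = cand$threshold[best],
       struct_gain = sc$struct[best], fuzzy_gain = sc$fuzz[best],
       left = grow_node(X, p, q, y, n_classes, left, cand, mu, config,
                        depth + 1L),
       right = grow_node(X, p, q, y, n_classes, right, cand, mu, config,
                         depth + 1L))
}

predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (isTRUE(node$leaf)) { out[idx] <<- node$weight; return() }
    left <- idx[X[idx, node$feature] <= node$threshold]
    rec(node$left, left)
    rec(node$right, setdiff(idx, left))
  }
  rec(node, seq_len(nrow(X)))
  out
}

#' Fit the EGBF classifier
#'
#' Second-order additive tree boosting with fuzzy-entropy-modulated
#' splits.  The model keeps one regression tree per class per round;
#' raw margins start at the log class priors and are updated additively,
#' with gradients/hessians of the softmax cross-entropy recomputed every
#' round.  Feature fuzzification (triangular low/medium/high term sets)
#' is fitted once on the training features.
#'
#' @param data Data frame with numeric feature columns and a label
#'   column (factor or character) with at least two classes.
#' @param label_col Name of the label column, default `"label"`.
#' @param config An [egbf_config()].
#' @return Object of class `egbf_model` with elements `trees` (list of
#'   rounds, each a list of per-class trees), `terms`, `class_levels`,
#'   `base_score`, `feature_names`, `config`, `train_logloss` (one value
#'   per round).
#' @export
#' @examples
#' cohort <- generate_child_cohort(cohort_spec(n_records = 200, seed = 1))
#' feats <- encode_cohort(cohort)
#' m <- egbf_fit(feats, config = egbf_config(rounds = 5))
#' head(predict(m, feats))
egbf_fit <- function(data, label_col = "label", config = egbf_config()) {
  data <- as.data.frame(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("label column '%s' not found", label_col),
          class = "nutriclass_invalid_input")
  }
  yf <- data[[label_col]]
  if (!is.factor(yf)) yf <- factor(yf)
  yf <- droplevels(yf)
  class_levels <- levels(yf)
  C <- length(class_levels)
  if (!is.null(config$n_classes) && config$n_classes != C) {
    abort("config$n_classes does not match the number of observed classes",
          class = "nutriclass_invalid_input")
  }
  if (C < 2) abort("training data has a single class",
                   class = "nutriclass_degenerate_input")
  X <- as_feature_matrix(data[setdiff(names(data), label_col)], "features")
  y <- as.integer(yf)
  n <- nrow(X)
  terms <- fit_fuzzy_terms(X)
  priors <- as.numeric(table(yf)) / n
  base_score <- log(pmax(priors, 1e-12))
  margins <- matrix(base_score, n, C, byrow = TRUE)
  trees <- vector("list", config$rounds)
  logloss <- numeric(config$rounds)
  for (b in seq_len(config$rounds)) {
    gh <- softmax_grad_hess(margins, y)
    round_trees <- vector("list", C)
    for (c in seq_len(C)) {
      tr <- grow_tree(X, gh$p[, c], gh$q[, c], y, C, terms, config)
      margins[, c] <- margins[, c] + predict_tree(tr, X)
      round_trees[[c]] <- tr
    }
    trees[[b]] <- round_trees
    pi <- softmax_rows(margins)
    logloss[b] <- -mean(log(pmax(pi[cbind(seq_len(n), y)], 1e-15)))
  }
  structure(list(trees = trees, terms = terms, class_levels = class_levels,
                 base_score = base_score, feature_names = colnames(X),
                 config = config, train_logloss = logloss,
                 n_train = n),
            class = "egbf_model")
}

egbf_margins <- function(model, X) {
  C <- length(model$class_levels)
  margins <- matrix(model$base_score, nrow(X), C, byrow = TRUE)
  for (round_trees in model$trees) {
    for (c in seq_len(C)) {
      margins[, c] <- margins[, c] + predict_tree(round_trees[[c]], X)
    }
  }
  margins
}

check_schema <- function(model, data) {
  data <- as.data.frame(data)
  missing <- setdiff(model$feature_names, names(data))
  if (length(missing)) {
    abort(paste("missing feature columns:", paste(missing, collapse = ", ")),
          class = "nutriclass_shape_error")
  }
  as_feature_matrix(data[model$feature_names], "features")
}

#' Predict class probabilities or labels
#'
#' `predict_proba()` returns the softmax of the summed margins (rows sum
#' to 1); `predict()` returns the argmax label, ties broken by the lowest
#' class index.
#'
#' @param model,object An `egbf_model`.
#' @param data,newdata Data frame with the model's feature columns.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return `predict_proba()`: an `n x C` matrix with class-level column
#'   names; `predict()`: a factor (or the probability matrix for
#'   `type = "prob"`).
#' @export
predict_proba <- function(model, data) {
  X <- check_schema(model, data)
  pr <- softmax_rows(egbf_margins(model, X))
  colnames(pr) <- model$class_levels
  pr
}

#' @rdname predict_proba
#' @export
predict.egbf_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  pr <- predict_proba(object, newdata)
  if (type == "prob") return(pr)
  factor(object$class_levels[max.col(pr, ties.method = "first")],
         levels = object$class_levels)
}

#' @export
print.egbf_model <- function(x, ...) {
  cat("EGBF model:", length(x$trees), "rounds x",
      length(x$class_levels), "classes,",
      length(x$feature_names), "features\n")
  if (length(x$train_logloss)) {
    cat("  final training log-loss:",
        format(x$train_logloss[length(x$train_logloss)], digits = 5), "\n")
  }
  invisible(x)
}

#' @export
tidy.egbf_model <- function(x, ...) {
  tibble(round = seq_along(x$train_logloss), train_logloss = x$train_logloss)
}

#' @export
glance.egbf_model <- function(x, ...) {
  tibble(rounds = length(x$trees), n_classes = length(x$class_levels),
         n_features = length(x$feature_names), n_train = x$n_train,
         final_logloss = if (length(x$train_logloss))
           x$train_logloss[length(x$train_logloss)] else NA_real_)
}

#' Training-loss curve
#'
#' @param object An `egbf_model`.
#' @param ... Unused.
#' @return A ggplot of training log-loss per boosting round.
#' @export
autoplot.egbf_model <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$round, y = .data$train_logloss)) +
    geom_line() +
    labs(x = "Boosting round", y = "Training log-loss",
         title = "EGBF training loss")
}

#' Save / load an EGBF model as JSON
#'
#' The full model (config, term sets, nested trees, class order, base
#' scores) round-trips through a single JSON document at full numeric
#' precision, so reloaded models predict bit-identically.
#'
#' @param model An `egbf_model`.
#' @param path File path.
#' @return `egbf_save()` returns `path` invisibly; `egbf_load()` the
#'   model.
#' @export
egbf_save <- function(model, path) {
  payload <- list(format = "nutriclass/egbf", version = 1L,
                  model = unclass(model))
  payload$model$config <- unclass(payload$model$config)
  payload$model$terms <- as.data.frame(payload$model$terms)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname egbf_save
#' @export
egbf_load <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path),
                                class = "nutriclass_file_error")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "nutriclass/egbf") ||
      !identical(as.integer(payload$version[[1]]), 1L)) {
    abort("unrecognized model format/version", class = "nutriclass_version_error")
  }
  m <- payload$model
  terms <- tibble(
    feature = vapply(m$terms, function(r) r$feature, character(1)),
    term = vapply(m$terms, function(r) r$term, character(1)),
    left = vapply(m$terms, function(r) as.numeric(r$left), numeric(1)),
    peak = vapply(m$terms, function(r) as.numeric(r$peak), numeric(1)),
    right = vapply(m$terms, function(r) as.numeric(r$right), numeric(1)),
    threshold = vapply(m$terms, function(r)
      if (is.null(r$threshold)) NA_real_ else as.numeric(r$threshold),
      numeric(1))
  )
  class(terms) <- c("fuzzy_termset", class(terms))
  cfg <- m$config
  cfg$n_classes <- cfg$n_classes %||% NULL
  m2 <- list(
    trees = map(m$trees, function(rt) map(rt, rebuild_tree)),
    terms = terms,
    class_levels = unlist(m$class_levels),
    base_score = unlist(m$base_score),
    feature_names = unlist(m$feature_names),
    config = structure(cfg, class = "egbf_config"),
    train_logloss = as.numeric(unlist(m$train_logloss)),
    n_train = m$n_train[[1]]
  )
  structure(m2, class = "egbf_model")
}

rebuild_tree <- function(node) {
  if (isTRUE(node$leaf)) {
    return(list(leaf = TRUE, weight = as.numeric(node$weight)))
  }
  list(leaf = FALSE, feature = node$feature, term = node$term,
       threshold = as.numeric(node$threshold),
       struct_gain = as.numeric(node$struct_gain),
       fuzzy_gain = as.numeric(node$fuzzy_gain),
       left = rebuild_tree(node$left), right = rebuild_tree(node$right))
}
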