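test_that("softmax derivatives match closed forms", {
  gh <- softmax_grad_hess(matrix(0, 1, 2), 1L)
  expect_equal(gh$p[1, ], c(-0.5, 0.5))
  expect_equal(gh$q[1, ], c(0.25, 0.25))
  # perfect-fit limit: gradient vanishes as the margin grows
  gh2 <- softmax_grad_hess(matrix(c(50, 0, 0), 1, 3), 1L)
  expect_lt(max(abs(gh2$p)), 1e-15)
  expect_error(softmax_grad_hess(matrix(0, 1, 2), 3L),
               class = "nutriclass_invalid_input")
  expect_error(softmax_grad_hess(matrix(NaN, 1, 2), 1L),
               class = "nutriclass_invalid_input")
})

test_that("softmax derivatives match central finite differences", {
  withr::with_seed(31, {
    for (i in 1:5) {
      scores <- matrix(rnorm(20 * 5), 20, 5)
      labels <- sample(5, 20, replace = TRUE)
      gh <- softmax_grad_hess(scores, labels)
      fd <- oracle_grad_hess_fd(scores, labels)
      expect_lt(max(abs(gh$p - fd$p)), 1e-5)
      expect_lt(max(abs(gh$q - fd$q)), 1e-5)
    }
  })
})

test_that("leaf weights follow both denominator variants", {
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_equal(leaf_weight(2, 3, 1, variant = "as_printed"), -2 / 7)
  expect_equal(leaf_weight(0, 3, 1), 0)
  expect_equal(leaf_weight(0, 3, 1, variant = "as_printed"), 0)
  expect_error(leaf_weight(1, 0, 0), class = "nutriclass_numerical_error")
})

test_that("the structure score matches its formula", {
  expect_equal(structural_score(2, 3, alpha = 0, beta = 1), -0.5)
  # splitting identical-gradient halves is pure penalty (exact at beta = 0,
  # where the leaf values are scale-free)
  parent <- structural_score(4, 6, alpha = 0.3, beta = 0)
  child <- structural_score(c(2, 2), c(3, 3), alpha = 0.3, beta = 0)
  expect_equal(parent - child, -0.3)
  withr::with_seed(14, {
    for (i in 1:10) {
      P <- rnorm(4); Q <- runif(4); a <- runif(1); b <- runif(1)
      expect_lt(abs(structural_score(P, Q, a, b) -
                      (-0.5 * sum(P^2 / (Q + b)) + a * 4)), 1e-12)
    }
  })
})

test_that("with lambda = 0 tree growth equals exhaustive gain maximization", {
  withr::with_seed(41, {
    for (trial in 1:20) {
      n <- sample(10:50, 1)
      X <- cbind(x1 = runif(n), x2 = rnorm(n), x3 = runif(n, -2, 2))
      y <- sample(3, n, replace = TRUE)
      gh <- softmax_grad_hess(matrix(rnorm(n * 3), n, 3), y)
      p <- gh$p[, 1]; q <- gh$q[, 1]
      cfg <- egbf_config(rounds = 1, lambda = 0, max_depth = 1,
                         learning_rate = 1)
      terms <- fit_fuzzy_terms(X)
      tree <- grow_tree(X, p, q, y, 3, terms, cfg)
      cand <- nutriclass:::split_candidates(terms, colnames(X))
      best <- oracle_best_split(X, p, q, cand, cfg$alpha, cfg$beta,
                                cfg$min_child_hessian)
      if (is.null(best$index)) {
        expect_true(isTRUE(tree$leaf))
      } else {
        expect_false(isTRUE(tree$leaf))
        expect_identical(tree$feature, cand$feature[best$index])
        expect_identical(tree$term, cand$term[best$index])
        expect_equal(tree$struct_gain, best$gain, tolerance = 1e-12)
      }
    }
  })
})

test_that("tree growth respects depth limits and degenerate gradients", {
  withr::with_seed(5, {
    X <- cbind(a = runif(40), b = runif(40))
    y <- rep(1:2, 20)
  })
  terms <- fit_fuzzy_terms(X)
  p <- ifelse(y == 1, -0.5, 0.5); q <- rep(0.25, 40)
  stump <- grow_tree(X, p, q, y, 2, terms, egbf_config(max_depth = 1))
  if (!isTRUE(stump$leaf)) {
    expect_true(isTRUE(stump$left$leaf) && isTRUE(stump$right$leaf))
  }
  # all gradients equal: no split has positive gain
  flat <- grow_tree(X, rep(0.2, 40), q, y, 2, terms, egbf_config())
  expect_true(isTRUE(flat$leaf))
})

test_that("zero rounds fall back to the class priors", {
  d <- make_feature_table(200, seed = 51)
  m <- egbf_fit(d, config = egbf_config(rounds = 0))
  pr <- predict_proba(m, d)
  priors <- as.numeric(table(d$label)[m$class_levels]) / nrow(d)
  expect_lt(max(abs(sweep(pr, 2, priors))), 1e-12)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
})

test_that("training log-loss is non-increasing at a small learning rate", {
  d <- make_feature_table(400, seed = 52)
  m <- egbf_fit(d, config = egbf_config(rounds = 25, learning_rate = 0.1))
  expect_true(all(diff(m$train_logloss) <= 1e-10))
})

test_that("a deep overfit model memorizes small separable data", {
  d <- make_feature_table(50, seed = 53, noise_sd = 0.3)
  skip_if(length(unique(d$label)) < 2)
  m <- egbf_fit(d, config = egbf_config(rounds = 60, max_depth = 6,
                                        learning_rate = 0.5))
  expect_equal(mean(predict(m, d) == d$label), 1)
})

test_that("probability predictions are proper and ties break low", {
  d <- make_feature_table(300, seed = 54)
  m <- egbf_fit(d, config = egbf_config(rounds = 8))
  pr <- predict_proba(m, d)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  expect_equal(colnames(pr), m$class_levels)
  pred <- predict(m, d)
  expect_s3_class(pred, "factor")
  expect_identical(as.character(pred),
                   m$class_levels[max.col(pr, ties.method = "first")])
  expect_error(predict_proba(m, d[, 1:3]), class = "nutriclass_shape_error")
})

test_that("the fuzzy-gain weight changes split selection but stays sound", {
  d <- make_feature_table(300, seed = 55)
  m0 <- egbf_fit(d, config = egbf_config(rounds = 5, lambda = 0))
  m1 <- egbf_fit(d, config = egbf_config(rounds = 5, lambda = 1))
  acc0 <- mean(predict(m0, d) == d$label)
  acc1 <- mean(predict(m1, d) == d$label)
  expect_gt(acc0, 0.5); expect_gt(acc1, 0.5)
  # as-printed variants still train
  mv <- egbf_fit(d, config = egbf_config(rounds = 3,
                                         leaf_denominator = "as_printed",
                                         entropy_sign = "as_printed"))
  expect_true(all(is.finite(predict_proba(mv, d))))
})

test_that("models survive a JSON round trip bit-exactly", {
  d <- make_feature_table(150, seed = 56)
  m <- egbf_fit(d, config = egbf_config(rounds = 4))
  path <- withr::local_tempfile(fileext = ".json")
  egbf_save(m, path)
  m2 <- egbf_load(path)
  expect_identical(predict_proba(m, d), predict_proba(m2, d))
  expect_identical(m$trees, m2$trees)
  expect_error(egbf_load(withr::local_tempfile(fileext = ".json")),
               class = "nutriclass_file_error")
})

test_that("degenerate training inputs are rejected", {
  d <- make_feature_table(50, seed = 57)
  d$label <- factor(rep("wasting", 50))
  expect_error(egbf_fit(d), class = "nutriclass_degenerate_input")
  expect_error(egbf_fit(data.frame(x = 1:5)),
               class = "nutriclass_invalid_input")
  expect_error(egbf_config(lambda = 2), class = "nutriclass_config_error")
  expect_error(egbf_config(learning_rate = 0), class = "nutriclass_config_error")
})
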