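# Independent reference implementations used to cross-check the package.
# These deliberately use naive loops / closed forms, never the package's
# own code paths.

# WCSS by explicit double loop over points and centroids.
oracle_wcss <- function(pts, cen) {
  pts <- as.matrix(pts); cen <- as.matrix(cen)
  total <- 0
  for (i in seq_len(nrow(pts))) {
    best <- Inf
    for (k in seq_len(nrow(cen))) {
      d2 <- sum((pts[i, ] - cen[k, ])^2)
      if (d2 < best) best <- d2
    }
    total <- total + best
  }
  total
}

# Shannon entropy (bits) of a mass vector, by direct summation.
oracle_entropy <- function(mass) {
  q <- mass / sum(mass)
  -sum(ifelse(q > 0, q * log2(q), 0))
}

# Fuzzy gain of an arbitrary partition, by direct evaluation.
oracle_fuzzy_gain <- function(parent, branches) {
  tot <- sum(unlist(branches))
  oracle_entropy(parent) -
    sum(vapply(branches, function(b) sum(b) / tot * oracle_entropy(b),
               numeric(1)))
}

# Exhaustive maximum-structural-gain split over a candidate table, with
# the same admissibility rule and the same first-maximum tie-break the
# learner documents (candidates in feature-column then low/medium/high
# order).
oracle_best_split <- function(X, p, q, cand, alpha, beta, min_child_hessian) {
  best <- NULL; best_gain <- 0
  PP <- sum(p); QP <- sum(q)
  parent <- -0.5 * PP^2 / (QP + beta) + alpha
  for (i in seq_len(nrow(cand))) {
    left <- X[, cand$feature[i]] <= cand$threshold[i]
    if (!any(left) || all(left)) next
    PL <- sum(p[left]); QL <- sum(q[left])
    PR <- PP - PL; QR <- QP - QL
    child <- -0.5 * (PL^2 / (QL + beta) + PR^2 / (QR + beta)) + 2 * alpha
    gain <- parent - child
    if (QL < min_child_hessian || QR < min_child_hessian) next
    if (gain > best_gain + 1e-15) { best_gain <- gain; best <- i }
  }
  list(index = best, gain = best_gain)
}

# Numerical gradient/hessian of the multiclass cross-entropy by central
# finite differences on the raw scores.
oracle_grad_hess_fd <- function(scores, labels, h = 1e-4) {
  loss_one <- function(z, lab) {
    z <- z - max(z)
    -(z[lab] - log(sum(exp(z))))
  }
  n <- nrow(scores); C <- ncol(scores)
  g <- matrix(0, n, C); hh <- matrix(0, n, C)
  for (i in seq_len(n)) {
    for (c in seq_len(C)) {
      zp <- scores[i, ]; zm <- scores[i, ]
      zp[c] <- zp[c] + h; zm[c] <- zm[c] - h
      f0 <- loss_one(scores[i, ], labels[i])
      fp <- loss_one(zp, labels[i]); fm <- loss_one(zm, labels[i])
      g[i, c] <- (fp - fm) / (2 * h)
      hh[i, c] <- (fp - 2 * f0 + fm) / h^2
    }
  }
  list(p = g, q = hh)
}

# Element-wise MSE of probabilities against one-hot truth.
oracle_mse <- function(truth, prob) {
  lev <- colnames(prob)
  acc <- 0
  for (i in seq_len(nrow(prob))) {
    for (c in seq_len(ncol(prob))) {
      y <- as.numeric(as.character(truth[i]) == lev[c])
      acc <- acc + (y - prob[i, c])^2
    }
  }
  acc / (nrow(prob) * ncol(prob))
}

# Normalized cohort feature table ready for egbf_fit / clustering.
make_feature_table <- function(n, seed, noise_sd = 0.5) {
  co <- generate_child_cohort(cohort_spec(n_records = n, seed = seed,
                                          noise_sd = noise_sd))
  f <- encode_cohort(co)
  x <- f[setdiff(names(f), "label")]
  xn <- apply_minmax(x, fit_minmax(x))
  xn$label <- f$label
  xn
}
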