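norm_prevalence <- function(n, k, sep, seed) {
  prev <- generate_prevalence_table(n, k, separation = sep, seed = seed)
  x <- prev[c("income_index", "wasting_pct", "severe_wasting_pct",
              "overweight_pct", "stunting_pct", "underweight_pct")]
  list(xn = apply_minmax(x, fit_minmax(x)), truth = prev$.true_cluster)
}

test_that("wcss matches closed forms and the brute-force oracle", {
  pts <- rbind(c(0, 0), c(1, 1))
  expect_equal(wcss(pts, pts), 0)
  expect_equal(wcss(matrix(c(0, 2), 2, 1), matrix(1, 1, 1)), 2)  # 1^2 + 1^2
  withr::with_seed(10, {
    pts <- matrix(runif(150), 50, 3)
    cen <- matrix(runif(12), 4, 3)
  })
  expect_lt(abs(wcss(pts, cen) - oracle_wcss(pts, cen)), 1e-10)
  expect_error(wcss(matrix(numeric(0), 0, 2), cen),
               class = "nutriclass_invalid_input")
})

test_that("nearest-centroid assignment breaks ties by the lowest index", {
  cen <- rbind(c(0, 0), c(2, 0))
  expect_equal(cluster_assign(rbind(c(0, 0), c(2, 0)), cen), c(1L, 2L))
  expect_equal(cluster_assign(rbind(c(1, 0)), cen), 1L)  # equidistant
  # assignment agrees with the one implied by wcss on any input
  withr::with_seed(3, pts <- matrix(runif(60), 20, 3))
  withr::with_seed(4, cen3 <- matrix(runif(9), 3, 3))
  a <- cluster_assign(pts, cen3)
  manual <- sum(vapply(seq_len(20), function(i)
    sum((pts[i, ] - cen3[a[i], ])^2), numeric(1)))
  expect_equal(manual, wcss(pts, cen3))
})

test_that("K = 1 recovers the data mean and the total sum of squares", {
  d <- norm_prevalence(80, 1, 5, seed = 3)
  cl <- fho_cluster(d$xn, 1, fho_config(pop_size = 8, max_iters = 5, seed = 1))
  expect_lt(max(abs(cl$centroids[1, ] - colMeans(as.matrix(d$xn)))), 1e-6)
  tss <- sum(scale(as.matrix(d$xn), scale = FALSE)^2)
  expect_lt(abs(cl$objective - tss), 1e-6)
})

test_that("four separated blobs are recovered and match the Lloyd oracle", {
  d <- norm_prevalence(400, 4, 8, seed = 11)
  cl <- fho_cluster(d$xn, 4, fho_config(pop_size = 20, max_iters = 30, seed = 1))
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(cl$assignments, d$truth), 0.95)
  lloyd <- min(vapply(1:10, function(s) {
    set.seed(s); kmeans(d$xn, 4, nstart = 1)$tot.withinss
  }, numeric(1)))
  expect_lte(cl$objective, 1.02 * lloyd)
  expect_equal(sum(cl$sizes), 400)
  expect_true(all(cl$assignments >= 1 & cl$assignments <= 4))
  expect_equal(cl$objective, wcss(d$xn, cl$centroids))
})

test_that("warm-starting K+1 with the K solution never increases the objective", {
  d <- norm_prevalence(150, 3, 6, seed = 7)
  cfg <- fho_config(pop_size = 10, max_iters = 10, seed = 2)
  e_prev <- NULL
  cl <- fho_cluster(d$xn, 2, cfg)
  for (K in 3:5) {
    warm <- rbind(cl$centroids, as.matrix(d$xn)[K, , drop = FALSE])
    cl <- fho_cluster(d$xn, K, cfg, init = warm)
    if (!is.null(e_prev)) expect_lte(cl$objective, e_prev + 1e-9)
    e_prev <- cl$objective
  }
})

test_that("the optimized objective beats random centroid draws", {
  d <- norm_prevalence(120, 3, 6, seed = 9)
  cl <- fho_cluster(d$xn, 3, fho_config(pop_size = 10, max_iters = 10, seed = 4))
  m <- as.matrix(d$xn)
  withr::with_seed(99, {
    random_e <- vapply(seq_len(1000), function(i) {
      cen <- m[sample(nrow(m), 3), , drop = FALSE]
      wcss(m, cen)
    }, numeric(1))
  })
  expect_true(all(cl$objective <= random_e))
})

test_that("row permutation permutes assignments without changing the solution", {
  d <- norm_prevalence(100, 3, 8, seed = 13)
  cfg <- fho_config(pop_size = 10, max_iters = 15, seed = 6)
  cl1 <- fho_cluster(d$xn, 3, cfg)
  withr::with_seed(1, perm <- sample(100))
  cl2 <- fho_cluster(d$xn[perm, ], 3, cfg)
  # same partition up to the permutation (cluster ids may relabel)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl1$assignments[perm],
                                         cl2$assignments), 1)
})

test_that("silhouette scoring matches an independent implementation", {
  skip_if_not_installed("cluster")
  d <- norm_prevalence(60, 3, 6, seed = 15)
  a <- cluster_assign(d$xn, as.matrix(d$xn)[c(1, 25, 50), ])
  skip_if(length(unique(a)) < 2)
  expect_equal(nutriclass:::mean_silhouette(as.matrix(d$xn), a),
               nutriclass:::silhouette_bruteforce(as.matrix(d$xn), a),
               tolerance = 1e-12)
})

test_that("select_k finds the planted K = 4 and handles flat data", {
  d <- norm_prevalence(300, 4, 8, seed = 17)
  rep <- select_k(d$xn, 2:8, fho_config(pop_size = 15, max_iters = 20, seed = 2))
  expect_equal(attr(rep, "chosen_k"), 4L)
  expect_equal(rep$k, 2:8)
  expect_s3_class(autoplot(rep), "ggplot")
  # single blob: no planted structure, ties resolved to the smallest K
  d1 <- norm_prevalence(60, 1, 5, seed = 19)
  rep1 <- select_k(d1$xn, 2:5, fho_config(pop_size = 8, max_iters = 8, seed = 3))
  expect_true(attr(rep1, "chosen_k") %in% 2:5)
  expect_true(max(rep1$score) < max(rep$score))  # much weaker structure
  expect_error(select_k(d$xn, integer(0)), class = "nutriclass_config_error")
})

test_that("duplicated points collapse to a zero silhouette score", {
  pts <- matrix(0.5, 30, 2)
  a <- rep(1:2, 15)
  expect_equal(nutriclass:::mean_silhouette(pts, a), 0)
})

test_that("clustering model methods are tidy", {
  d <- norm_prevalence(80, 2, 6, seed = 23)
  cl <- fho_cluster(d$xn, 2, fho_config(pop_size = 8, max_iters = 8, seed = 1))
  expect_equal(nrow(tidy(cl)), 2)
  expect_equal(glance(cl)$K, 2L)
  aug <- augment(cl, d$xn)
  expect_equal(levels(aug$.cluster), c("1", "2"))
})
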