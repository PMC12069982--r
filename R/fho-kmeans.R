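#' Within-cluster sum of squares
#'
#' Assigns each point to its nearest centroid (squared Euclidean distance,
#' ties to the lowest centroid index) and returns the total within-cluster
#' sum of squared distances — the k-means objective minimized by
#' [fho_cluster()].
#'
#' @param points Data frame or matrix of numeric points (n x d).
#' @param centroids Numeric matrix (K x d).
#' @return Non-negative scalar.
#' @export
#' @examples
#' wcss(data.frame(x = c(0, 2)), matrix(1, 1, 1))  # 1^2 + 1^2 = 2
wcss <- function(points, centroids) {
  p <- as_feature_matrix(points, "points")
  cmat <- matrix(as.numeric(as.matrix(centroids)), ncol = ncol(p))
  d2 <- sq_dist(p, cmat)
  sum(d2[cbind(seq_len(nrow(p)), max.col(-d2, ties.method = "first"))])
}

# n x K matrix of squared Euclidean distances
sq_dist <- function(p, cmat) {
  d2 <- outer(rowSums(p^2), rep(1, nrow(cmat))) +
    outer(rep(1, nrow(p)), rowSums(cmat^2)) - 2 * p %*% t(cmat)
  pmax(d2, 0)
}

#' Nearest-centroid assignment
#'
#' @param points Data frame or matrix of numeric points.
#' @param centroids Numeric matrix (K x d) or an `fho_kmeans` model.
#' @return Integer vector of cluster ids in `1..K` (ties broken by the
#'   lowest centroid index).
#' @export
cluster_assign <- function(points, centroids) {
  if (inherits(centroids, "fho_kmeans")) centroids <- centroids$centroids
  p <- as_feature_matrix(points, "points")
  cmat <- matrix(as.numeric(as.matrix(centroids)), ncol = ncol(p))
  max.col(-sq_dist(p, cmat), ties.method = "first")
}

# Empty-cluster repair (farthest-point reseeding) + one Lloyd update.
# This is the "k-means move" of the hybrid: every candidate centroid set
# is refined by a single assignment/update step before its objective is
# scored, so the metaheuristic searches over Lloyd-improved solutions.
kmeans_refine <- function(x, pts, K, d) {
  cen <- matrix(x, K, d)
  for (pass in 1:2) {
    a <- max.col(-sq_dist(pts, cen), ties.method = "first")
    empty <- setdiff(seq_len(K), unique(a))
    if (!length(empty)) break
    d2 <- sq_dist(pts, cen)
    nearest <- d2[cbind(seq_len(nrow(pts)), a)]
    for (k in empty) {
      far <- which.max(nearest)
      cen[k, ] <- pts[far, ]
      nearest[far] <- 0
    }
  }
  a <- max.col(-sq_dist(pts, cen), ties.method = "first")
  for (k in seq_len(K)) {
    idx <- which(a == k)
    if (length(idx)) cen[k, ] <- colMeans(pts[idx, , drop = FALSE])
  }
  list(position = as.numeric(cen), fitness = wcss(pts, cen))
}

#' FHO-driven k-means clustering
#'
#' Minimizes the within-cluster sum of squares over centroid positions
#' with the Fire Hawk Optimizer: each candidate is a flattened `K x d`
#' centroid matrix, the search box is the per-coordinate data range, and
#' every candidate is refined by one k-means assignment/update step
#' (with farthest-point reseeding of empty clusters) before its objective
#' is evaluated.
#'
#' @param points Data frame or matrix of numeric points; expected on the
#'   `[0, 1]` normalized scale (a warning is issued otherwise).
#' @param K Number of clusters, `1 <= K <= n`.
#' @param config An [fho_config()].
#' @param init Optional warm-start centroid matrix (`K x d`) injected
#'   into the initial population.
#' @return Object of class `fho_kmeans`: list with `K`, `centroids`,
#'   `assignments` (1-based), `objective` (the WCSS `E`), `sizes`,
#'   `history` and the `fho_fit`.
#' @export
#' @examples
#' pts <- generate_prevalence_table(60, 3, separation = 8, seed = 2) |>
#'   dplyr::select(-country_id, -.true_cluster)
#' pts <- apply_minmax(pts, fit_minmax(pts))
#' fho_cluster(pts, K = 3, fho_config(pop_size = 10, max_iters = 10, seed = 1))
fho_cluster <- function(points, K, config = fho_config(pop_size = 20,
                                                       max_iters = 30),
                        init = NULL) {
  pts <- as_feature_matrix(points, "points")
  n <- nrow(pts); d <- ncol(pts)
  if (K < 1 || K > n) abort("need 1 <= K <= n", class = "nutriclass_invalid_input")
  if (min(pts) < -1e-9 || max(pts) > 1 + 1e-9) {
    warn("points are outside [0, 1]; consider min-max normalization first")
  }
  lo <- rep(apply(pts, 2, min), each = K)
  hi <- rep(apply(pts, 2, max), each = K)
  hi <- ifelse(hi > lo, hi, lo + 1e-9)
  space <- search_space(lo, hi)
  fit <- fho_minimize(objective = function(x) wcss(pts, matrix(x, K, d)),
                      space = space, config = config,
                      init = if (!is.null(init)) as.numeric(as.matrix(init)),
                      refine = function(x) kmeans_refine(x, pts, K, d))
  cen <- matrix(fit$par, K, d, dimnames = list(NULL, colnames(pts)))
  a <- cluster_assign(pts, cen)
  structure(list(K = as.integer(K), centroids = cen, assignments = a,
                 objective = wcss(pts, cen),
                 sizes = tabulate(a, nbins = K),
                 history = fit$history, fho = fit, n = n),
            class = "fho_kmeans")
}

#' @export
print.fho_kmeans <- function(x, ...) {
  cat("FHO-K-Means clustering: K =", x$K, " n =", x$n, "\n")
  cat("  WCSS:", format(x$objective, digits = 6),
      " sizes:", paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' @export
tidy.fho_kmeans <- function(x, ...) {
  as_tibble(x$centroids) |>
    mutate(cluster = seq_len(x$K), size = x$sizes, .before = 1)
}

#' @export
glance.fho_kmeans <- function(x, ...) {
  tibble(K = x$K, wcss = x$objective, n = x$n,
         iterations = length(x$history))
}

#' @export
augment.fho_kmeans <- function(x, data, ...) {
  as_tibble(data) |> mutate(.cluster = factor(x$assignments))
}

# Mean silhouette width of a labelled clustering; 0 when undefined
# (single effective cluster, or n <= K). Uses cluster::silhouette when
# available, else an internal computation.
mean_silhouette <- function(pts, a) {
  if (length(unique(a)) < 2L) return(0)
  val <- if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(a, dist(pts))
    if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
  } else {
    silhouette_bruteforce(pts, a)
  }
  if (!is.finite(val)) 0 else val
}

# Reference silhouette: direct per-point a(i)/b(i) computation.
silhouette_bruteforce <- function(pts, a) {
  n <- nrow(pts)
  dm <- as.matrix(dist(pts))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(a == a[i]); own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    ai <- mean(dm[i, own])
    bi <- min(vapply(setdiff(unique(a), a[i]),
                     function(k) mean(dm[i, a == k]), numeric(1)))
    s[i] <- if (max(ai, bi) > 0) (bi - ai) / max(ai, bi) else 0
  }
  mean(s)
}

#' Select the number of clusters
#'
#' Runs [fho_cluster()] for each candidate `K` and scores the result by
#' the mean silhouette coefficient; the chosen `K` attains the maximum
#' score (ties go to the smallest `K`).  Raw WCSS decreases monotonically
#' in `K` and cannot exhibit an interior optimum, so the silhouette is
#' used as the cluster-quality score.
#'
#' @param points Data frame or matrix of numeric points.
#' @param k_range Integer vector of candidate `K` values, each in
#'   `[2, n - 1]`.
#' @param config An [fho_config()]; a per-`K` seed is derived from
#'   `config$seed` so runs are independent but reproducible.
#' @return Object of class `kselect_report`: tibble with columns `k`,
#'   `score`, `wcss`; attributes `chosen_k` and `models`.
#' @export
select_k <- function(points, k_range = 2:8,
                     config = fho_config(pop_size = 20, max_iters = 30)) {
  if (!length(k_range)) abort("k_range is empty", class = "nutriclass_config_error")
  pts <- as_feature_matrix(points, "points")
  if (any(k_range < 2 | k_range > nrow(pts) - 1)) {
    abort("every K must satisfy 2 <= K <= n - 1", class = "nutriclass_config_error")
  }
  models <- map(k_range, function(K) {
    cfg <- config; cfg$seed <- derive_seed(config$seed, paste0("select_k_", K))
    fho_cluster(pts, K, cfg)
  })
  scores <- map_dbl(models, function(m) mean_silhouette(pts, m$assignments))
  out <- tibble(k = as.integer(k_range), score = scores,
                wcss = map_dbl(models, "objective"))
  chosen <- out$k[which.max(out$score)]  # which.max takes the first maximum
  structure(out, chosen_k = chosen, models = setNames(models, k_range),
            class = c("kselect_report", class(out)))
}

#' @export
print.kselect_report <- function(x, ...) {
  cat("Cluster-number selection (mean silhouette): chosen K =",
      attr(x, "chosen_k"), "\n")
  NextMethod()
}

#' Silhouette-vs-K plot
#'
#' @param object A `kselect_report` from [select_k()].
#' @param ... Unused.
#' @return A ggplot of score against candidate K, with the chosen K marked.
#' @export
autoplot.kselect_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$k, y = .data$score)) +
    geom_line() + geom_point() +
    geom_point(data = df[df$k == attr(object, "chosen_k"), ],
               colour = "red", size = 3) +
    labs(x = "Number of clusters K", y = "Mean silhouette",
         title = "Cluster-number selection")
}
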