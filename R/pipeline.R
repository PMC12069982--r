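#' Encode a child cohort as a numeric feature table
#'
#' Maps the categorical survey fields onto 0/1 indicators
#' (`sex_male`, `residence_urban`) and keeps the numeric anthropometric
#' and socioeconomic columns plus the label, yielding the feature table
#' consumed by the clustering and classification stages.
#'
#' @param cohort Tibble from [generate_child_cohort()] (or any table
#'   with the same columns).
#' @param keep_label Keep the `label` column (default TRUE).
#' @return Tibble of numeric features, label last when kept.
#' @export
encode_cohort <- function(cohort, keep_label = TRUE) {
  out <- tibble(
    age_months = as.numeric(cohort$age_months),
    sex_male = as.numeric(cohort$sex == "male"),
    height_cm = cohort$height_cm,
    weight_kg = cohort$weight_kg,
    muac_cm = cohort$muac_cm,
    residence_urban = as.numeric(cohort$residence == "urban"),
    income_index = cohort$income_index,
    z_wfh = cohort$z_wfh, z_hfa = cohort$z_hfa, z_wfa = cohort$z_wfa
  )
  if (keep_label && "label" %in% names(cohort)) out$label <- cohort$label
  out
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_spec()] describing the synthetic input, or
#'   `NULL` when `input_csv` is given.
#' @param input_csv Optional path to a child-level CSV with the cohort
#'   schema.
#' @param normalize Apply min-max normalization (default TRUE).
#' @param k Fixed number of clusters, or `NULL` to select from
#'   `k_range`.
#' @param k_range Candidate cluster numbers for [select_k()] when `k` is
#'   `NULL`.
#' @param fho An [fho_config()] template for the clustering stage (its
#'   seed is overridden by the derived stage seed).
#' @param test_fraction Test fraction for the stratified split.
#' @param egbf An [egbf_config()] for the classifier (seed overridden).
#' @param out_dir Optional directory for intermediate artifacts.
#' @param seed Global seed; every stage seed is derived from it by
#'   hashing the stage name, so adding a stage never perturbs earlier
#'   stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input_csv = NULL,
                            normalize = TRUE, k = 4L, k_range = 2:8,
                            fho = fho_config(pop_size = 20, max_iters = 30),
                            test_fraction = 0.3,
                            egbf = egbf_config(),
                            out_dir = NULL, seed = 1L) {
  structure(list(cohort = cohort, input_csv = input_csv,
                 normalize = isTRUE(normalize), k = k, k_range = k_range,
                 fho = fho, test_fraction = test_fraction, egbf = egbf,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end nutritional-status pipeline
#'
#' Simulate (or load) a child-level cohort, min-max normalize the
#' features, cluster them with FHO-K-Means (the cluster id is appended
#' as a one-hot feature block, so the clustering provides structured
#' input to the classifier), split stratified by label, fit the EGBF
#' classifier on the training part and evaluate it on the held-out
#' part.  Every stochastic stage consumes a seed derived
#' deterministically from the global seed and the stage name; the seed
#' ledger in the report suffices to replay any stage in isolation.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: list with `metrics`
#'   (a [metrics_report()] tibble), `chosen_k`, `cluster_sizes`,
#'   `timings`, `seed_ledger`, `model` (the fitted `egbf_model`),
#'   `norm_params`, `clustering`, `paths`.
#' @export
#' @examples
#' cfg <- pipeline_config(cohort = cohort_spec(n_records = 300, seed = 5),
#'                        egbf = egbf_config(rounds = 10), seed = 5)
#' rep <- run_pipeline(cfg)
#' rep$metrics
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c(); paths <- list()
  tic <- function() proc.time()[["elapsed"]]
  seed_ledger <- tibble(
    stage = c("simulate", "cluster", "split", "train"),
    seed = vapply(c("simulate", "cluster", "split", "train"),
                  function(s) derive_seed(config$seed, s), numeric(1))
  )
  get_seed <- function(stage) seed_ledger$seed[seed_ledger$stage == stage]

  t0 <- tic()
  if (!is.null(config$input_csv)) {
    if (!file.exists(config$input_csv)) {
      abort(paste("pipeline stage 'load':", config$input_csv, "not found"),
            class = "nutriclass_file_error")
    }
    cohort <- as_tibble(utils::read.csv(config$input_csv))
    cohort$label <- factor(cohort$label,
                           levels = intersect(nutrition_labels(),
                                              unique(cohort$label)))
  } else {
    spec <- config$cohort
    spec$seed <- as.integer(get_seed("simulate"))
    cohort <- generate_child_cohort(spec)
  }
  feats <- encode_cohort(cohort)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  x <- select(feats, -dplyr::any_of("label"))
  norm_params <- fit_minmax(x)
  xn <- if (config$normalize) apply_minmax(x, norm_params) else as_tibble(x)
  timings["normalize"] <- tic() - t0

  t0 <- tic()
  fho_cfg <- config$fho
  fho_cfg$seed <- as.integer(get_seed("cluster"))
  if (is.null(config$k)) {
    ksel <- select_k(xn, config$k_range, fho_cfg)
    chosen_k <- attr(ksel, "chosen_k")
    clustering <- attr(ksel, "models")[[as.character(chosen_k)]]
  } else {
    ksel <- NULL
    chosen_k <- as.integer(config$k)
    clustering <- fho_cluster(xn, chosen_k, fho_cfg)
  }
  onehot <- matrix(0, nrow(xn), chosen_k,
                   dimnames = list(NULL, paste0("cluster_", seq_len(chosen_k))))
  onehot[cbind(seq_len(nrow(xn)), clustering$assignments)] <- 1
  xc <- bind_cols(xn, as_tibble(onehot))
  xc$label <- feats$label
  timings["cluster"] <- tic() - t0

  t0 <- tic()
  sp <- split_train_test(xc, config$test_fraction,
                         seed = get_seed("split"), stratify_by = "label")
  timings["split"] <- tic() - t0

  t0 <- tic()
  egbf_cfg <- config$egbf
  egbf_cfg$seed <- as.integer(get_seed("train"))
  model <- egbf_fit(sp$train, label_col = "label", config = egbf_cfg)
  timings["train"] <- tic() - t0

  t0 <- tic()
  prob <- predict_proba(model, sp$test)
  pred <- predict(model, sp$test)
  metrics <- metrics_report(sp$test$label, pred, prob,
                            levels = model$class_levels)
  timings["evaluate"] <- tic() - t0

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$cohort <- file.path(config$out_dir, "cohort.csv")
    utils::write.csv(cohort, paths$cohort, row.names = FALSE)
    paths$metrics <- file.path(config$out_dir, "metrics.csv")
    utils::write.csv(as.data.frame(metrics), paths$metrics, row.names = FALSE)
    paths$model <- file.path(config$out_dir, "model.json")
    save_model_bundle(list(model = model, norm_params = norm_params,
                           clustering = clustering), paths$model)
    paths$history <- file.path(config$out_dir, "fho_history.csv")
    utils::write.csv(tidy(clustering$fho), paths$history, row.names = FALSE)
  }

  structure(list(metrics = metrics, chosen_k = chosen_k,
                 k_selection = ksel,
                 cluster_sizes = clustering$sizes,
                 timings = timings, seed_ledger = seed_ledger,
                 model = model, norm_params = norm_params,
                 clustering = clustering, paths = paths,
                 n = nrow(feats)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("nutriclass pipeline report (n =", x$n, ")\n")
  cat("  chosen K:", x$chosen_k, " cluster sizes:",
      paste(x$cluster_sizes, collapse = "/"), "\n")
  macro <- x$metrics[x$metrics$class == "macro", ]
  cat(sprintf("  macro accuracy %.4f  sensitivity %.4f  F1 %.4f  MSE %.5f\n",
              macro$accuracy, macro$sensitivity, macro$f1, macro$mse))
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  macro <- x$metrics[x$metrics$class == "macro", ]
  tibble(n = x$n, chosen_k = x$chosen_k,
         macro_accuracy = macro$accuracy, macro_f1 = macro$f1,
         macro_mse = macro$mse)
}

#' Save / load a fitted model bundle
#'
#' Serializes the classifier together with the normalization parameters
#' and the clustering model (everything inference needs) as one JSON
#' document with a version field.
#'
#' @param bundle List with elements `model` (an `egbf_model`),
#'   `norm_params` (a `minmax_params`) and `clustering` (an
#'   `fho_kmeans`, optional).
#' @param path File path.
#' @return `save_model_bundle()` returns `path` invisibly;
#'   `load_model_bundle()` the bundle.
#' @export
save_model_bundle <- function(bundle, path) {
  tmp_model <- tempfile(fileext = ".json")
  on.exit(unlink(tmp_model))
  egbf_save(bundle$model, tmp_model)
  payload <- list(
    format = "nutriclass/bundle", version = 1L,
    model = jsonlite::read_json(tmp_model, simplifyVector = FALSE),
    norm_params = as.data.frame(bundle$norm_params),
    clustering = if (!is.null(bundle$clustering)) {
      list(K = bundle$clustering$K,
           centroids = bundle$clustering$centroids,
           objective = bundle$clustering$objective)
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path),
                                class = "nutriclass_file_error")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "nutriclass/bundle") ||
      !identical(as.integer(payload$version[[1]]), 1L)) {
    abort("unrecognized bundle format/version",
          class = "nutriclass_version_error")
  }
  tmp_model <- tempfile(fileext = ".json")
  on.exit(unlink(tmp_model))
  jsonlite::write_json(payload$model, tmp_model, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  np <- tibble(
    column = vapply(payload$norm_params, function(r) r$column, character(1)),
    min = vapply(payload$norm_params, function(r) as.numeric(r$min), numeric(1)),
    max = vapply(payload$norm_params, function(r) as.numeric(r$max), numeric(1))
  )
  class(np) <- c("minmax_params", class(np))
  clustering <- NULL
  if (!is.null(payload$clustering)) {
    cen <- do.call(rbind, map(payload$clustering$centroids,
                              ~ as.numeric(unlist(.x))))
    clustering <- list(K = as.integer(payload$clustering$K[[1]]),
                       centroids = cen,
                       objective = as.numeric(payload$clustering$objective[[1]]))
  }
  list(model = egbf_load(tmp_model), norm_params = np,
       clustering = clustering)
}
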