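#' Stage-II configuration
#'
#' Defaults are the selected operating point of the prediction engine: MLP
#' with one hidden layer of 100 units, stage-I neighborhood `K = 9`, CRH
#' resolution `c_max = 6` for the completeness model and `c_max = 12` for
#' the contamination model, weight decay `alpha = 1e-4` (completeness) and
#' `1e-7` (contamination). Alternate methods: `knn` (smoothing parameter
#' `knn_k`), `random_forest` (library defaults), `linear_svr`
#' (regularization `svr_C`), `elastic_net` (built-in CV path).
#'
#' @param method one of `"mlp"`, `"knn"`, `"random_forest"`,
#'   `"linear_svr"`, `"elastic_net"`.
#' @param K stage-I neighborhood size.
#' @param c_max_comp,c_max_cont CRH resolution per target.
#' @param hidden_units MLP hidden layer width.
#' @param alpha_comp,alpha_cont MLP weight decay per target.
#' @param svr_C linear SVR regularization parameter.
#' @param knn_k KNN regression neighborhood size.
#' @param maxit MLP iteration cap.
#' @param cont_ceiling reported contamination is clipped to `[0, cont_ceiling]`.
#' @param seed RNG seed used for every stochastic fit.
#' @return A list of class `stage2_config`.
#' @export
stage2_config <- function(method = "mlp", K = 9,
                          c_max_comp = 6, c_max_cont = 12,
                          hidden_units = 100,
                          alpha_comp = 1e-4, alpha_cont = 1e-7,
                          svr_C = 1, knn_k = 5, maxit = 200,
                          cont_ceiling = 1.0, seed = 1) {
  method <- match.arg(method, c("mlp", "knn", "random_forest", "linear_svr",
                                "elastic_net"))
  structure(list(method = method, K = K, c_max_comp = c_max_comp,
                 c_max_cont = c_max_cont, hidden_units = hidden_units,
                 alpha_comp = alpha_comp, alpha_cont = alpha_cont,
                 svr_C = svr_C, knn_k = knn_k, maxit = maxit,
                 cont_ceiling = cont_ceiling, seed = seed),
            class = "stage2_config")
}

#' Train one stage-II regressor
#'
#' Features are used on their natural scale: CRH frequencies and the two
#' stage-I estimates are already commensurate values in `[0, 1]`, and
#' dividing rarely-populated histogram bins by their tiny standard deviation
#' would amplify sampling noise into dominant inputs. All stochastic fits
#' are seeded from `config$seed`, so training is deterministic.
#'
#' @param features numeric matrix (rows = bins, named columns).
#' @param targets numeric vector in `[0, 1]`, one per row.
#' @param config a [stage2_config()].
#' @param target_kind `"completeness"` or `"contamination"` (selects the
#'   per-target MLP weight decay).
#' @return An object of class `quality_regressor`.
#' @export
train_model <- function(features, targets, config,
                        target_kind = c("completeness", "contamination")) {
  target_kind <- match.arg(target_kind)
  features <- as.matrix(features)
  if (nrow(features) != length(targets)) stop("features/targets length mismatch")
  if (nrow(features) < 20) stop("too few training samples (need >= 20)")
  if (anyNA(features) || anyNA(targets)) stop("NA in training data")
  x <- features
  alpha <- if (target_kind == "completeness") config$alpha_comp else config$alpha_cont
  set.seed(config$seed)
  if (stats::sd(targets) == 0) {
    # degenerate training set: every learner reduces to the constant
    return(structure(list(method = "constant",
                          fit = list(value = targets[1]),
                          feature_names = colnames(features),
                          target_kind = target_kind),
                     class = "quality_regressor"))
  }
  fit <- switch(config$method,
    mlp = nnet::nnet(x, targets, size = config$hidden_units, decay = alpha,
                     linout = TRUE, maxit = config$maxit, trace = FALSE,
                     MaxNWts = 100000, abstol = 1e-6, reltol = 1e-8),
    knn = caret::knnreg(x, targets, k = config$knn_k),
    random_forest = randomForest::randomForest(x, targets),
    linear_svr = e1071::svm(x, targets, type = "eps-regression",
                            kernel = "linear", cost = config$svr_C,
                            epsilon = 0, scale = FALSE),
    elastic_net = glmnet::cv.glmnet(x, targets, alpha = 0.5))
  structure(list(method = config$method, fit = fit,
                 feature_names = colnames(features),
                 target_kind = target_kind),
            class = "quality_regressor")
}

#' Predict with a fitted stage-II regressor
#' @param object a `quality_regressor`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return Numeric vector of (unclipped) predictions.
#' @export
predict.quality_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  x <- newdata
  p <- switch(object$method,
    constant = rep(object$fit$value, nrow(x)),
    mlp = as.numeric(stats::predict(object$fit, x)),
    knn = as.numeric(stats::predict(object$fit, as.data.frame(x))),
    random_forest = as.numeric(stats::predict(object$fit, x)),
    linear_svr = as.numeric(stats::predict(object$fit, x)),
    elastic_net = as.numeric(stats::predict(object$fit, newx = x,
                                            s = "lambda.min")))
  p
}

#' Stage-II feature vectors for one query
#'
#' Runs the stage-I analysis once, then assembles the two per-target feature
#' vectors (mean CRH over the K neighbors at the per-target resolution,
#' concatenated with the stage-I estimates).
#'
#' @param q a `domain_profile`.
#' @param db a `reference_db`.
#' @param config a [stage2_config()].
#' @param centers_comp,centers_cont optional prebuilt [bin_centers()].
#' @return List with `stage1` (a `stage1_result`) and, unless the query was
#'   rejected, `features_comp` and `features_cont` (named vectors).
#' @export
stage2_features <- function(q, db, config,
                            centers_comp = NULL, centers_cont = NULL) {
  s1 <- stage1_analyze(q, db, K = config$K)
  if (s1$route == "rejected")
    return(list(stage1 = s1, features_comp = NULL, features_cont = NULL))
  nb_profiles <- lapply(db$entries[s1$neighbors$genome_id], `[[`, "profile")
  if (is.null(centers_comp)) centers_comp <- bin_centers(config$c_max_comp)
  if (is.null(centers_cont)) centers_cont <- bin_centers(config$c_max_cont)
  list(stage1 = s1,
       features_comp = build_features(mean_crh(q, nb_profiles, centers_comp), s1),
       features_cont = build_features(mean_crh(q, nb_profiles, centers_cont), s1))
}

#' Feature matrices for a set of simulated bins
#'
#' @param bins list of bins, each a list with at least `bin_id`, `profile`
#'   (a `domain_profile`), `truth_completeness`, `truth_contamination`,
#'   `source_genome` (see [annotate_bins()]).
#' @param db a `reference_db`.
#' @param config a [stage2_config()].
#' @return List with matrices `features_comp`, `features_cont`, and a
#'   data.frame `info` (bin_id, source_genome, truths, stage-I estimates,
#'   route). Bins rejected at stage I are excluded from the matrices and
#'   flagged in `info`.
#' @export
bin_feature_table <- function(bins, db, config) {
  centers_comp <- bin_centers(config$c_max_comp)
  centers_cont <- bin_centers(config$c_max_cont)
  rows_comp <- list(); rows_cont <- list(); info <- list()
  for (b in bins) {
    fs <- stage2_features(b$profile, db, config, centers_comp, centers_cont)
    s1 <- fs$stage1
    info[[b$bin_id]] <- data.frame(
      bin_id = b$bin_id, source_genome = b$source_genome,
      truth_completeness = b$truth_completeness,
      truth_contamination = b$truth_contamination,
      comp_stage1 = s1$completeness, cont_stage1 = s1$contamination,
      n_markers = s1$n_markers, route = s1$route, stringsAsFactors = FALSE)
    if (s1$route != "rejected") {
      rows_comp[[b$bin_id]] <- fs$features_comp
      rows_cont[[b$bin_id]] <- fs$features_cont
    }
  }
  list(features_comp = do.call(rbind, rows_comp),
       features_cont = do.call(rbind, rows_cont),
       info = do.call(rbind, c(info, list(make.row.names = FALSE))))
}

#' Train the two-regressor quality model
#'
#' Trains one regressor for completeness and one for contamination on the
#' stage-II features of the given bins (all bins that stage I can analyze;
#' simulated training bins lie in the stage-II quality range by
#' construction).
#'
#' @param bins training bins (see [bin_feature_table()]).
#' @param db a `reference_db`.
#' @param config a [stage2_config()].
#' @return An object of class `quality_model`: `comp_model`, `cont_model`,
#'   `config`, `feature_schema`, `training_fingerprint`.
#' @export
train_quality_model <- function(bins, db, config = stage2_config()) {
  ft <- bin_feature_table(bins, db, config)
  usable <- ft$info$route != "rejected"
  if (sum(usable) < 20) stop("too few stage-I-analyzable bins for training")
  truths <- ft$info[usable, ]
  comp_model <- train_model(ft$features_comp, truths$truth_completeness,
                            config, "completeness")
  cont_model <- train_model(ft$features_cont, truths$truth_contamination,
                            config, "contamination")
  fp <- sprintf("seed=%d;n=%d;sum=%.10g", config$seed, sum(usable),
                sum(ft$features_comp) + sum(ft$features_cont))
  structure(list(comp_model = comp_model, cont_model = cont_model,
                 config = config,
                 feature_schema = list(comp = comp_model$feature_names,
                                       cont = cont_model$feature_names),
                 training_fingerprint = fp),
            class = "quality_model")
}

#' @export
#' @method print quality_model
print.quality_model <- function(x, ...) {
  cat(sprintf("<quality_model> method=%s K=%d c_max=%d/%d (%s)\n",
              x$config$method, x$config$K, x$config$c_max_comp,
              x$config$c_max_cont, x$training_fingerprint))
  invisible(x)
}

#' Predict genome quality for a query profile
#'
#' The full two-stage pipeline: prefilter, K-nearest-neighbor search,
#' dynamic marker extraction, marker-based stage-I estimate, routing; when
#' routed to stage II, the two per-target feature vectors are built and the
#' trained regressors produce the final estimates, clipped to completeness
#' in `[0, 1]` and contamination in `[0, cont_ceiling]`. Queries rejected by
#' the prefilter yield an explicit rejected result, not an error.
#'
#' @param q a `domain_profile`.
#' @param db a `reference_db`.
#' @param model a `quality_model` (may be `NULL` for stage-I-only
#'   prediction).
#' @param config defaults to `model$config`.
#' @return A list: `completeness`, `contamination`, `stage` (`"stage1"`,
#'   `"stage2"` or `"rejected"`), `reason` (for rejections), `stage1` (the
#'   full `stage1_result`).
#' @export
predict_quality <- function(q, db, model = NULL,
                            config = if (!is.null(model)) model$config
                                     else stage2_config()) {
  fs <- stage2_features(q, db, config)
  s1 <- fs$stage1
  if (s1$route == "rejected") {
    return(list(completeness = NA_real_, contamination = NA_real_,
                stage = "rejected",
                reason = if (grepl("prefilter", s1$reason))
                  "rejected: completeness below 10%" else s1$reason,
                stage1 = s1))
  }
  if (s1$route == "final" || is.null(model)) {
    return(list(completeness = s1$completeness,
                contamination = s1$contamination,
                stage = "stage1", reason = NA_character_, stage1 = s1))
  }
  comp <- predict(model$comp_model, matrix(fs$features_comp, nrow = 1,
                                           dimnames = list(NULL, names(fs$features_comp))))
  cont <- predict(model$cont_model, matrix(fs$features_cont, nrow = 1,
                                           dimnames = list(NULL, names(fs$features_cont))))
  list(completeness = min(max(comp, 0), 1),
       contamination = min(max(cont, 0), config$cont_ceiling),
       stage = "stage2", reason = NA_character_, stage1 = s1)
}

#' Hyperparameter grid search
#'
#' Exhaustive evaluation over the cartesian product of the supplied value
#' ranges: for each candidate configuration the model is trained on the
#' training bins and scored by validation mean absolute error. Training and
#' validation bins must come from disjoint source genomes (leakage guard).
#'
#' @param train_bins,valid_bins bin lists (see [bin_feature_table()]).
#' @param db a `reference_db`.
#' @param grid named list of value vectors over [stage2_config()] arguments,
#'   e.g. `list(K = c(1, 9), c_max_comp = c(4, 6))`.
#' @param base_config configuration supplying all non-gridded values.
#' @return List with `best_config`, `best_index` and `table` (one row per
#'   grid point with validation MAEs in percentage points).
#' @export
grid_search <- function(train_bins, valid_bins, db, grid,
                        base_config = stage2_config()) {
  tr_src <- unique(vapply(train_bins, `[[`, character(1), "source_genome"))
  va_src <- unique(vapply(valid_bins, `[[`, character(1), "source_genome"))
  if (length(intersect(tr_src, va_src)) > 0)
    stop("leakage: training and validation bins share source genomes")
  if (length(grid) == 0) stop("empty grid")
  if ("method" %in% names(grid)) {
    known <- c("mlp", "knn", "random_forest", "linear_svr", "elastic_net")
    if (!all(grid$method %in% known))
      stop(sprintf("unknown method(s) in grid: %s",
                   paste(setdiff(grid$method, known), collapse = ", ")))
  }
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cfg <- base_config
    for (nm in names(pts)) cfg[[nm]] <- pts[[nm]][i]
    model <- train_quality_model(train_bins, db, cfg)
    ev <- evaluate_bins(valid_bins, db, model, cfg)
    rows[[i]] <- cbind(pts[i, , drop = FALSE],
                       mae_comp = ev$final_mae_comp,
                       mae_cont = ev$final_mae_cont,
                       mae_mean = (ev$final_mae_comp + ev$final_mae_cont) / 2)
  }
  tab <- do.call(rbind, rows)
  best <- which.min(tab$mae_mean)
  best_config <- base_config
  for (nm in names(pts)) best_config[[nm]] <- pts[[nm]][best]
  list(best_config = best_config, best_index = best, table = tab)
}

#' Save a trained quality model to a directory
#'
#' Writes `config.json`, `schema.json` and the serialized fitted regressors.
#' A save/load round trip reproduces predictions exactly.
#'
#' @param model a `quality_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model$feature_schema, file.path(dir, "schema.json"))
  saveRDS(model$comp_model, file.path(dir, "comp_model.rds"))
  saveRDS(model$cont_model, file.path(dir, "cont_model.rds"))
  writeLines(model$training_fingerprint, file.path(dir, "fingerprint.txt"))
  invisible(dir)
}

#' Load a quality model saved by [save_model()]
#' @param dir model directory.
#' @return A `quality_model`.
#' @export
load_model <- function(dir) {
  cfgfile <- file.path(dir, "config.json")
  if (!file.exists(cfgfile)) stop(sprintf("not a model directory: %s", dir))
  cfg <- jsonlite::read_json(cfgfile, simplifyVector = TRUE)
  config <- do.call(stage2_config, cfg[names(cfg) %in% names(formals(stage2_config))])
  schema <- jsonlite::read_json(file.path(dir, "schema.json"),
                                simplifyVector = TRUE)
  comp_model <- tryCatch(readRDS(file.path(dir, "comp_model.rds")),
                         error = function(e) stop("corrupted model file: comp_model.rds"))
  cont_model <- tryCatch(readRDS(file.path(dir, "cont_model.rds")),
                         error = function(e) stop("corrupted model file: cont_model.rds"))
  expected_comp <- c(paste0("crh_", bin_centers(config$c_max_comp)$label),
                     "comp1", "cont1")
  if (!identical(comp_model$feature_names, expected_comp) ||
      !identical(unname(schema$comp), comp_model$feature_names))
    stop("schema mismatch: saved model does not match its configured c_max")
  expected_cont <- c(paste0("crh_", bin_centers(config$c_max_cont)$label),
                     "comp1", "cont1")
  if (!identical(cont_model$feature_names, expected_cont))
    stop("schema mismatch: saved model does not match its configured c_max")
  structure(list(comp_model = comp_model, cont_model = cont_model,
                 config = config,
                 feature_schema = list(comp = comp_model$feature_names,
                                       cont = cont_model$feature_names),
                 training_fingerprint = readLines(file.path(dir, "fingerprint.txt"))),
            class = "quality_model")
}

#' Attach domain profiles to simulated bins
#'
#' Annotates each bin's contigs against the family catalog and returns bins
#' augmented with a `profile` element, ready for [bin_feature_table()].
#'
#' @param bins list of `simulated_bin`.
#' @param catalog family token catalog (see [toy_annotate()]).
#' @return The bins, each with a `profile` added.
#' @export
annotate_bins <- function(bins, catalog) {
  lapply(bins, function(b) {
    b$profile <- toy_annotate(b$contigs, catalog, genome_id = b$bin_id)
    b
  })
}
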