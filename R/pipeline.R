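#' Pipeline configuration
#'
#' Collects everything a full run needs: which reduced alphabet to use,
#' PCA width and scope, model preset, training schedule, fold count, the
#' master seed every source of randomness derives from, and IO paths.
#'
#' @param alphabet Name of a canonical alphabet (see
#'   [canonical_alphabets()]) or an `rtcp_alphabet`.
#' @param d_out PCA output dimension (default 80); `NULL` disables.
#' @param pca_scope `"fold"` or `"global"` (see [cross_validate()]).
#' @param model `"default"` (5-conv, 32-filter network) or `"small"`
#'   (4-conv variant), or any baseline kind.
#' @param epochs,batch_size Training schedule overrides.
#' @param k Cross-validation fold count.
#' @param seed Master seed.
#' @param fasta,pssm_dir,labels,out_dir,checkpoint IO paths as needed by
#'   the command.
#' @param on_missing_pssm `"abort"` or `"skip"`.
#' @return An `rtcp_pipeline_config` list.
#' @export
pipeline_config <- function(alphabet = "ST_SS", d_out = 80L,
                            pca_scope = "fold", model = "default",
                            epochs = 100L, batch_size = 32L, k = 10L,
                            seed = 1L, fasta = NULL, pssm_dir = NULL,
                            labels = NULL, out_dir = ".", checkpoint = NULL,
                            on_missing_pssm = "abort") {
  if (is.character(alphabet)) {
    all_ab <- canonical_alphabets()
    if (!alphabet %in% names(all_ab)) {
      abort(sprintf("unknown alphabet '%s'; canonical ones are %s",
                    alphabet, paste(names(all_ab), collapse = ", ")))
    }
    alphabet <- all_ab[[alphabet]]
  }
  stopifnot(inherits(alphabet, "rtcp_alphabet"))
  if (!is.null(d_out) && d_out < 1L) abort("d_out must be >= 1")
  structure(list(alphabet = alphabet, d_out = d_out, pca_scope = pca_scope,
                 model = model, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), k = as.integer(k),
                 seed = as.integer(seed), fasta = fasta, pssm_dir = pssm_dir,
                 labels = labels, out_dir = out_dir, checkpoint = checkpoint,
                 on_missing_pssm = on_missing_pssm),
            class = "rtcp_pipeline_config")
}

#' Run a pipeline command
#'
#' Ties the modules into the end-to-end workflow. Commands:
#' \describe{
#'   \item{extract-features}{FASTA (+ PSSM dir) in, RTCP feature TSV out.}
#'   \item{train}{Extract features, fit the reducer and classifier on all
#'     labeled data, checkpoint both.}
#'   \item{evaluate}{Stratified k-fold cross-validation; writes a JSON
#'     report and per-fold ROC TSV.}
#'   \item{predict}{Score new FASTA + PSSMs with a saved checkpoint.}
#'   \item{simulate}{Generate synthetic fixtures under `out_dir`.}
#' }
#' Every run logs the seed, alphabet and feature dimensions via
#' [message()].
#'
#' @param cfg An [pipeline_config()].
#' @param command One of `"extract-features"`, `"train"`, `"evaluate"`,
#'   `"predict"`, `"simulate"`.
#' @param n_per_class,signal_strength,pssm_shift Simulation parameters
#'   (command `"simulate"` only).
#' @return The primary artifact of the command, invisibly (a tibble of
#'   features or predictions, an `rtcp_cv`, a checkpoint path, or a file
#'   manifest).
#' @export
run_pipeline <- function(cfg, command = c("extract-features", "train",
                                          "evaluate", "predict", "simulate"),
                         n_per_class = 200L, signal_strength = 0.5,
                         pssm_shift = 1.0) {
  stopifnot(inherits(cfg, "rtcp_pipeline_config"))
  command <- match.arg(command)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  K <- alphabet_size(cfg$alphabet)
  message(sprintf("[rtcp] %s | alphabet %s (K=%d, rtcp dim %d) | seed %d",
                  command, cfg$alphabet$name, K, K^3 + 20L, cfg$seed))

  if (command == "simulate") {
    spec <- synthetic_spec(n_per_class = n_per_class,
                           alphabet = cfg$alphabet,
                           signal_strength = signal_strength,
                           pssm_shift = pssm_shift, seed = cfg$seed)
    return(invisible(write_fixtures(generate_dataset(spec), cfg$out_dir)))
  }

  features <- pipeline_features(cfg)
  if (command == "extract-features") {
    path <- file.path(cfg$out_dir, "features.tsv")
    write_feature_tsv(features, path)
    message(sprintf("[rtcp] wrote %d x %d feature matrix to %s",
                    nrow(features), length(feature_columns(features)), path))
    return(invisible(features))
  }

  if (command == "predict") {
    if (is.null(cfg$checkpoint)) abort("predict needs cfg$checkpoint")
    ck <- load_checkpoint(cfg$checkpoint)
    reduced <- if (is.null(ck$reducer)) features else {
      expected <- length(ck$reducer$mean)
      got <- length(feature_columns(features))
      if (got != expected) {
        abort(sprintf("checkpoint expects %d input features, data has %d",
                      expected, got))
      }
      apply_reducer(ck$reducer, features)
    }
    scores <- predict_proba(ck$model, reduced)
    out <- tibble(id = features$id, score = scores,
                  pred = as.integer(scores >= 0.5))
    write_feature_tsv(out, file.path(cfg$out_dir, "predictions.tsv"))
    return(invisible(out))
  }

  # train / evaluate need labels
  if (!"label" %in% names(features)) {
    if (is.null(cfg$labels)) abort(sprintf("command '%s' needs labels", command))
  }

  if (command == "train") {
    reducer <- NULL
    train_data <- features
    if (!is.null(cfg$d_out)) {
      reducer <- fit_reducer(features, cfg$d_out)
      train_data <- apply_reducer(reducer, features)
    }
    model <- fit_classifier(as_feature_matrix(train_data),
                            as.integer(features$label),
                            classifier = if (cfg$model %in% c("default", "small"))
                              "dcnn" else cfg$model,
                            seed = cfg$seed,
                            model_config = pipeline_model_config(cfg, train_data),
                            train = train_config(epochs = cfg$epochs,
                                                 batch_size = cfg$batch_size,
                                                 seed = cfg$seed))
    path <- file.path(cfg$out_dir, "checkpoint.json")
    save_checkpoint(model, reducer, path)
    if (inherits(model, "rtcp_dcnn")) {
      write_feature_tsv(model$history, file.path(cfg$out_dir, "history.tsv"))
    }
    message(sprintf("[rtcp] checkpoint written to %s", path))
    return(invisible(path))
  }

  # evaluate
  cv <- cross_validate(features,
                       classifier = if (cfg$model %in% c("default", "small"))
                         "dcnn" else cfg$model,
                       k = cfg$k, d_out = cfg$d_out, pca_scope = cfg$pca_scope,
                       seed = cfg$seed,
                       model_config = pipeline_model_config_cv(cfg),
                       train = if (cfg$model %in% c("default", "small"))
                         train_config(epochs = cfg$epochs,
                                      batch_size = cfg$batch_size,
                                      seed = cfg$seed) else NULL)
  report <- list(k = cv$k, classifier = cv$classifier, seed = cv$seed,
                 per_fold = tidy(cv), mean = glance(cv),
                 folds = cv$folds)
  jsonlite::write_json(report, file.path(cfg$out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_feature_tsv(cv$roc, file.path(cfg$out_dir, "roc.tsv"))
  g <- glance(cv)
  message(sprintf("[rtcp] CV mean: acc %.4f spec %.4f sens %.4f F %.4f mcc %.4f auc %.4f",
                  g$acc, g$spec, g$sens, g$f_score, g$mcc, g$auc))
  invisible(cv)
}

pipeline_features <- function(cfg) {
  if (is.null(cfg$fasta)) abort("cfg$fasta is required for this command")
  seqs <- read_fasta(cfg$fasta)
  pssms <- if (!is.null(cfg$pssm_dir)) read_pssm_dir(cfg$pssm_dir) else NULL
  if (!is.null(cfg$labels)) {
    labs <- read_labels(cfg$labels)
    seqs <- dplyr::inner_join(seqs, labs, by = "id")
    if (nrow(seqs) == 0L) abort("no sequence ids matched the label file")
  }
  extract_features(seqs, cfg$alphabet, pssms,
                   on_missing_pssm = cfg$on_missing_pssm)
}

pipeline_model_config <- function(cfg, data) {
  if (!cfg$model %in% c("default", "small")) return(NULL)
  dim_in <- length(feature_columns(data))
  if (cfg$model == "small") small_dcnn(dim_in) else default_dcnn(dim_in)
}

# For CV the input dim depends on d_out; let cross_validate size it unless
# the small preset is requested.
pipeline_model_config_cv <- function(cfg) {
  if (!identical(cfg$model, "small")) return(NULL)
  small_dcnn(if (is.null(cfg$d_out)) alphabet_size(cfg$alphabet)^3 + 20L
             else cfg$d_out)
}

#' Save or load a model checkpoint
#'
#' Serializes the fitted classifier (and reducer, if any) to a single JSON
#' file: configuration plus flattened numeric weights, portable across
#' sessions.
#'
#' @param model An `rtcp_dcnn` or `rtcp_baseline`. Baselines other than
#'   the network are stored via serialized R objects encoded in base64
#'   inside the JSON.
#' @param reducer An `rtcp_reducer` or `NULL`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, reducer, path) {
  enc <- function(obj) jsonlite::base64_enc(serialize(obj, NULL))
  payload <- list(format = "rtcp-checkpoint-1")
  if (inherits(model, "rtcp_dcnn")) {
    payload$type <- "dcnn"
    payload$config <- unclass(model$config)
    payload$params <- lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), values = as.numeric(p))
    })
    payload$bn_state <- model$bn_state
    payload$history <- model$history
  } else {
    payload$type <- "baseline"
    payload$kind <- model$kind
    payload$p <- model$p
    payload$blob <- enc(model)
  }
  if (!is.null(reducer)) {
    payload$reducer <- list(mean = reducer$mean,
                            components = list(dim = dim(reducer$components),
                                              values = as.numeric(reducer$components)),
                            d_out = reducer$d_out, sdev = reducer$sdev,
                            schema = reducer$schema,
                            total_var = reducer$total_var)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "rtcp-checkpoint-1")) {
    abort(sprintf("'%s' is not an rtcp checkpoint", path))
  }
  reducer <- NULL
  if (!is.null(payload$reducer)) {
    r <- payload$reducer
    comp <- matrix(r$components$values, r$components$dim[1], r$components$dim[2])
    mean_v <- r$mean; names(mean_v) <- r$schema
    reducer <- structure(list(mean = mean_v, components = comp,
                              d_out = as.integer(r$d_out), sdev = r$sdev,
                              schema = r$schema, total_var = r$total_var),
                         class = "rtcp_reducer")
  }
  if (identical(payload$type, "dcnn")) {
    cfgl <- payload$config
    config <- model_config(cfgl$input_dim, cfgl$filters, cfgl$kernel_size,
                           cfgl$pool_positions, cfgl$fc_sizes, cfgl$head)
    params <- lapply(payload$params, function(p) {
      if (length(p$dim) == 2L) matrix(p$values, p$dim[1], p$dim[2]) else p$values
    })
    bn_state <- lapply(payload$bn_state, as.numeric)
    model <- structure(list(config = config, train_config = NULL,
                            params = params, bn_state = bn_state,
                            history = as_tibble(payload$history)),
                       class = "rtcp_dcnn")
  } else {
    model <- unserialize(jsonlite::base64_dec(payload$blob))
  }
  list(model = model, reducer = reducer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
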