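#' Default pipeline configuration
#'
#' Nested list of every tunable setting with its documented default.
#' Sections: `profile` (logistic normalisation of log-odds, default off),
#' `condense` (20 x 20 condensation mode), `features` (descriptor kind,
#' energy convention, auto-covariance lag), `svd` (target dimension 300;
#' `paper_mode` fits the projector on all data instead of the training
#' fold only), `pair` (order-symmetrised training augmentation, on by
#' default because interaction is a symmetric relation), `dnn`
#' (architecture, two hidden layers of 48, dropout 0.5, Adam learning
#' rate 0.001, 100 epochs, batch 64), `baseline` (KNN k = 5, RF 500
#' trees), `cv` (5 folds, stratified, seed) and `psiblast` (3 iterations,
#' inclusion E-value 0.001).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    profile = list(normalize = FALSE),
    condense = list(mode = "crossproduct"),
    features = list(kind = "dht", energy = "modulus", ac_lag = 5L),
    svd = list(k = 300L, paper_mode = FALSE),
    pair = list(symmetrize = TRUE),
    classifier = "dnn",
    dnn = list(architecture = "merged", hidden = c(48L, 48L),
               dropout = 0.5, learning_rate = 0.001,
               epochs = 100L, batch_size = 64L),
    baseline = list(knn_k = 5L, rf_trees = 500L),
    cv = list(k = 5L, seed = 1L, stratified = TRUE),
    threshold = 0.5
  )
}

# Fill missing entries of a (possibly partial) config with defaults.
merge_config <- function(config = NULL) {
  def <- default_config()
  if (is.null(config)) return(def)
  for (sec in names(def)) {
    if (is.list(def[[sec]])) {
      for (key in names(def[[sec]]))
        if (!is.null(config[[sec]][[key]]))
          def[[sec]][[key]] <- config[[sec]][[key]]
    } else if (!is.null(config[[sec]])) {
      def[[sec]] <- config[[sec]]
    }
  }
  extra <- setdiff(names(config), names(def))
  if (length(extra)) def[extra] <- config[extra]
  def
}

#' Read a flat `key = value` configuration file
#'
#' The configuration format is plain text, one `section.key = value` per
#' line; `#` starts a comment. Values are parsed as logical
#' (`true`/`false`), numeric, comma-separated numeric vectors, or left as
#' strings. Unset keys keep the [default_config()] values.
#'
#' @param path Path to the configuration file.
#' @return Full nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  config <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config line not of the form key = value: '", ln, "'")
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[[1L]])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parsed <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else if (grepl("^[-0-9.eE,+ ]+$", val) &&
               !is.na(suppressWarnings(as.numeric(
                 strsplit(val, ",")[[1L]][1L])))) {
      as.numeric(strsplit(val, ",")[[1L]])
    } else val
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) config[[parts]] <- parsed
    else config[[parts[1L]]][[parts[2L]]] <- parsed
  }
  merge_config(config)
}

profile_to_descriptor <- function(profile, config) {
  if (isTRUE(config$profile$normalize))
    profile <- normalize_profile(profile)
  kind <- config$features$kind
  if (kind == "ac")
    return(alt_features(profile, kind = "ac",
                        ac_lag = config$features$ac_lag))
  M <- condense(profile, mode = config$condense$mode)
  if (kind == "dht") dht_features(M, energy = config$features$energy)
  else alt_features(M, kind = kind)
}

#' Compute the per-protein descriptor table
#'
#' Applies the configured feature extractor (profile normalisation,
#' 20 x 20 condensation, then DHT local energy or a comparator
#' descriptor) to every protein's profile. With `cache_dir` set, the
#' table is written to disk keyed by the feature settings and reused
#' verbatim by identical re-runs.
#'
#' @param records Named character vector of sequences.
#' @param profiles Named list of `ppi_profile` objects; every record id
#'   must be present.
#' @param config Pipeline configuration (see [default_config()]).
#' @param cache_dir Optional directory for the descriptor cache.
#' @return Numeric matrix, one row per protein (rownames = ids), 400
#'   columns for dht/dct/fft/dwt or `20 * ac_lag` for ac.
#' @export
run_features <- function(records, profiles, config = default_config(),
                         cache_dir = NULL) {
  config <- merge_config(config)
  ids <- names(records)
  missing <- setdiff(ids, names(profiles))
  if (length(missing))
    stop("no profile for protein id(s): ", paste(missing, collapse = ", "))
  cache_key <- paste(config$features$kind, config$features$energy,
                     config$features$ac_lag, config$condense$mode,
                     config$profile$normalize, sep = "_")
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir, paste0("descriptors_", cache_key, ".tsv"))
    if (file.exists(cache_file)) {
      cached <- as.matrix(utils::read.table(cache_file, header = FALSE,
                                            row.names = 1L, sep = "\t"))
      colnames(cached) <- NULL
      if (setequal(rownames(cached), ids))
        return(cached[ids, , drop = FALSE])
    }
  }
  rows <- lapply(ids, function(id)
    as.numeric(profile_to_descriptor(profiles[[id]], config)))
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(format(X, digits = 17), cache_file, sep = "\t",
                       quote = FALSE, col.names = FALSE)
  }
  X
}

#' Run a full cross-validated experiment
#'
#' End-to-end orchestration: load or generate the dataset, extract the
#' configured descriptors, run five-fold cross-validation with the
#' configured classifier ([run_cv()]), and optionally write the report
#' and per-fold ROC tables.
#'
#' @param dataset Either a [gen_dataset()] result or a list with
#'   elements `records`, `profiles`, `pairs`.
#' @param config Pipeline configuration.
#' @param out_dir Optional output directory for `report.txt` and
#'   `roc_fold<k>.csv` files.
#' @return The `cv_report`.
#' @export
run_experiment <- function(dataset, config = default_config(),
                           out_dir = NULL) {
  config <- merge_config(config)
  report <- run_cv(dataset$records, dataset$pairs, dataset$profiles, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.txt"))
    for (f in seq_along(report$roc))
      write_roc(report$roc[[f]],
                file.path(out_dir, sprintf("roc_fold%d.csv", f)))
  }
  report
}

#' Compare descriptors and classifiers on one dataset
#'
#' Runs [run_cv()] for every combination of descriptor kind and
#' classifier requested, reusing the same folds (same `cv$seed`), and
#' returns a table of mean metrics — the benchmarking grid used to set
#' the DHT + DNN combination against DCT/FFT/DWT/AC descriptors and
#' KNN/RF classifiers.
#'
#' @param dataset Dataset list as in [run_experiment()].
#' @param kinds Descriptor kinds to sweep.
#' @param classifiers Classifiers to sweep.
#' @param config Base configuration.
#' @return data.frame with one row per (kind, classifier): mean metrics
#'   and AUC.
#' @export
compare_methods <- function(dataset, kinds = "dht",
                            classifiers = c("dnn", "knn", "rf"),
                            config = default_config()) {
  config <- merge_config(config)
  grid <- expand.grid(kind = kinds, classifier = classifiers,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$features$kind <- grid$kind[i]
    cfg$classifier <- grid$classifier[i]
    rep <- run_cv(dataset$records, dataset$pairs, dataset$profiles, cfg)
    data.frame(kind = grid$kind[i], classifier = grid$classifier[i],
               t(rep$mean))
  })
  do.call(rbind, out)
}
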