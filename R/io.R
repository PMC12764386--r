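# CSV ingestion with declared column roles, results export with a JSON
# sidecar, and YAML configuration.

#' Column roles for a delimited dataset
#'
#' Declares which columns of a CSV hold the two spatial coordinates, the
#' covariates, the response, and (optionally) ground-truth labels. Roles must
#' be disjoint.
#'
#' @param spatial Character vector of exactly two column names.
#' @param covariates Character vector of covariate column names (>= 1).
#' @param response Name of the response column.
#' @param label Optional name of a true-label column.
#' @return An object of class `"column_spec"`.
#' @export
column_spec <- function(spatial, covariates, response, label = NULL) {
  spatial <- as.character(spatial)
  covariates <- as.character(covariates)
  response <- as.character(response)
  if (length(spatial) != 2L) stop("'spatial' must name exactly two columns",
                                  call. = FALSE)
  if (length(covariates) < 1L) stop("'covariates' must name at least one column",
                                    call. = FALSE)
  if (length(response) != 1L) stop("'response' must name one column",
                                   call. = FALSE)
  all_cols <- c(spatial, covariates, response, label)
  if (anyDuplicated(all_cols)) {
    stop("column roles must be disjoint", call. = FALSE)
  }
  structure(list(spatial = spatial, covariates = covariates,
                 response = response, label = label),
            class = "column_spec")
}

as_numeric_col <- function(df, col) {
  v <- df[[col]]
  if (is.numeric(v)) return(as.numeric(v))
  out <- suppressWarnings(as.numeric(as.character(v)))
  bad <- which(is.na(out) & !is.na(v) & trimws(as.character(v)) != "")
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric values in column '%s' (first at row %d)",
                 col, bad[1]), call. = FALSE)
  }
  out
}

#' Read a supervised spatial dataset from a CSV file
#'
#' Reads a comma-delimited file with a header, routes columns per the
#' [column_spec()], and validates the result. Rows with a missing value in
#' any used column are dropped with a message reporting the count; a file
#' with no usable rows is an error.
#'
#' @param path Path to the CSV file.
#' @param spec A [column_spec()].
#' @return A [spatial_dataset()].
#' @export
read_dataset <- function(path, spec) {
  if (!inherits(spec, "column_spec")) stop("'spec' must be a column_spec",
                                           call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  used <- c(spec$spatial, spec$covariates, spec$response, spec$label)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("column(s) missing from '%s': %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  num <- lapply(used, function(col) as_numeric_col(df, col))
  names(num) <- used
  keep <- !Reduce(`|`, lapply(num, is.na))
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("read_dataset: dropped %d row(s) with missing values",
                    dropped))
  }
  if (sum(keep) == 0L) stop("no usable rows after removing missing values",
                            call. = FALSE)
  s <- do.call(cbind, num[spec$spatial])[keep, , drop = FALSE]
  x <- do.call(cbind, num[spec$covariates])[keep, , drop = FALSE]
  y <- num[[spec$response]][keep]
  lab <- if (!is.null(spec$label)) as.integer(num[[spec$label]][keep]) else NULL
  spatial_dataset(s, x, y, true_labels = lab)
}

#' Write a spatial dataset to CSV
#'
#' Columns are `s1, s2, x1..xp, y` and, when present, `true_label`.
#'
#' @param dataset A [spatial_dataset()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Write clustering results with a JSON sidecar
#'
#' Writes a CSV of the input columns plus `predicted_label`, and a JSON
#' sidecar holding the configuration echo, iteration history, per-cluster
#' sizes and kernel parameters, and — when the dataset carries true labels —
#' the ARI and AMI against them.
#'
#' @param state A fitted `"gpsc_state"`.
#' @param dataset The [spatial_dataset()] the state was fitted on.
#' @param path Output CSV path.
#' @param sidecar Output JSON path; defaults to `path` with a `.json`
#'   extension.
#' @return Invisibly, a list with the two paths.
#' @export
write_results <- function(state, dataset, path,
                          sidecar = sub("\\.csv$", ".json", path)) {
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  df <- as.data.frame(dataset)
  df$predicted_label <- state$labels
  utils::write.csv(df, path, row.names = FALSE)

  sizes <- tabulate(state$labels, state$config$L)
  kp <- lapply(state$models, function(m) {
    if (is.null(m)) NULL else unclass(m$params)
  })
  meta <- list(
    config = unclass(state$config)[c("L", "T", "lambda", "feature_mode",
                                     "restarts", "seed", "min_cluster_size",
                                     "init_strategy")],
    iterations = state$iteration,
    converged = state$converged,
    history = state$history,
    cluster_sizes = sizes,
    kernel_params = kp,
    centers = state$centers_raw)
  if (!is.null(dataset$true_labels)) {
    meta$ari <- adjusted_rand_index(state$labels, dataset$true_labels)
    meta$ami <- adjusted_mutual_info(state$labels, dataset$true_labels)
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(csv = path, json = sidecar))
}

#' Read a GPSC configuration from a YAML file
#'
#' Recognized keys: `L`, `T`, `lambda`, `feature_mode`, `restarts`, `seed`,
#' `min_cluster_size`, `init_strategy`, and `bounds` (a mapping of `sigma2`,
#' `b`, `tau2` to (lower, upper) pairs). Unknown keys are an error so typos
#' do not pass silently.
#'
#' @param path YAML file path.
#' @return A [gpsc_config()].
#' @export
read_gpsc_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("L", "T", "lambda", "feature_mode", "bounds", "restarts",
             "seed", "min_cluster_size", "init_strategy")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(cfg$bounds)) cfg$bounds <- lapply(cfg$bounds, as.numeric)
  do.call(gpsc_config, cfg)
}
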