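# Container for supervised spatial data (s, x, y) with optional true labels.

#' Supervised spatial dataset
#'
#' Bundles n observations of a planar location `s`, covariates `x` and a
#' scalar response `y`, with optional integer ground-truth labels. Missing
#' values are rejected at construction rather than imputed.
#'
#' @param s n x 2 numeric matrix of spatial coordinates (e.g.
#'   longitude/latitude or an abstract plane).
#' @param x n x p numeric matrix of covariates.
#' @param y Numeric response vector of length n.
#' @param true_labels Optional integer labels of length n.
#' @return An object of class `"spatial_dataset"`.
#' @export
spatial_dataset <- function(s, x, y, true_labels = NULL) {
  s <- as.matrix(s)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(s)
  if (n < 1L) stop("a dataset needs at least one observation", call. = FALSE)
  if (ncol(s) != 2L) stop("'s' must have exactly two columns", call. = FALSE)
  if (nrow(x) != n || length(y) != n) {
    stop("'s', 'x' and 'y' must have the same number of rows", call. = FALSE)
  }
  if (ncol(x) < 1L) stop("'x' needs at least one covariate column",
                         call. = FALSE)
  if (anyNA(s) || anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed in a spatial_dataset", call. = FALSE)
  }
  if (!is.null(true_labels)) {
    true_labels <- as.integer(true_labels)
    if (length(true_labels) != n || anyNA(true_labels)) {
      stop("'true_labels' must be n complete integers", call. = FALSE)
    }
  }
  if (is.null(colnames(s))) colnames(s) <- c("s1", "s2")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(s = s, x = x, y = y, true_labels = true_labels),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: n = %d, p = %d covariates%s\n",
              nrow(x$s), ncol(x$x),
              if (is.null(x$true_labels)) "" else
                sprintf(", %d true clusters", length(unique(x$true_labels)))))
  invisible(x)
}

#' @export
as.data.frame.spatial_dataset <- function(x, ...) {
  df <- data.frame(x$s, x$x, y = x$y, check.names = FALSE)
  if (!is.null(x$true_labels)) df$true_label <- x$true_labels
  df
}

#' Number of observations in a spatial dataset
#' @param dataset A `"spatial_dataset"`.
#' @return Integer count.
#' @export
n_obs <- function(dataset) nrow(dataset$s)
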