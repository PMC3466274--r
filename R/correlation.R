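#' Construct a validated ROI correlation matrix
#'
#' Wraps a symmetric ROI-by-ROI correlation matrix together with its ROI
#' identifiers and subject metadata.  The matrix must be symmetric (within
#' `tol`), have a unit diagonal and entries in \[-1, 1\].
#'
#' @param values numeric n x n matrix of correlations.
#' @param roi_ids ordered ROI identifiers; defaults to the matrix dimnames or
#'   `1:n`.
#' @param subject_id,group,trial optional labels carried through the pipeline.
#'   `group` is typically `"ASD"` or `"TD"`, `trial` `"green"` or `"red"`.
#' @param tol numeric tolerance for the symmetry and diagonal checks.
#' @return An object of class `dcg_corr`.
#' @export
correlation_matrix <- function(values, roi_ids = NULL, subject_id = NA_character_,
                               group = NA_character_, trial = NA_character_,
                               tol = .dcg_tol) {
  values <- as.matrix(values)
  if (is.null(roi_ids)) {
    roi_ids <- if (!is.null(colnames(values))) colnames(values) else as.character(seq_len(ncol(values)))
  }
  roi_ids <- as.character(roi_ids)
  validate_square_matrix(values, roi_ids, tol = tol, range = c(-1, 1),
                         what = "correlation matrix")
  # enforce exact symmetry / diagonal after validation
  values <- (values + t(values)) / 2
  diag(values) <- 1
  dimnames(values) <- list(roi_ids, roi_ids)
  structure(list(values = values, roi_ids = roi_ids, subject_id = subject_id,
                 group = group, trial = trial),
            class = "dcg_corr")
}

# shared validator: square, numeric, symmetric, unit diagonal, entries in range.
# Errors name the offending cells by ROI id.
validate_square_matrix <- function(values, roi_ids, tol, range, what) {
  if (!is.numeric(values)) stop(what, ": values must be numeric", call. = FALSE)
  n <- nrow(values)
  if (is.null(n) || n != ncol(values)) {
    stop(what, ": matrix must be square, got ", paste(dim(values), collapse = " x "),
         call. = FALSE)
  }
  if (length(roi_ids) != n) {
    stop(what, ": ", length(roi_ids), " ROI ids for ", n, " rows", call. = FALSE)
  }
  if (n < 2) stop(what, ": at least 2 ROIs required", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(what, ": missing value at (", roi_ids[bad[1]], ", ", roi_ids[bad[2]], ")",
         call. = FALSE)
  }
  asym <- abs(values - t(values))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(what, ": asymmetric beyond tolerance at (", roi_ids[bad[1]], ", ",
         roi_ids[bad[2]], "): ", format(values[bad[1], bad[2]]), " vs ",
         format(values[bad[2], bad[1]]), call. = FALSE)
  }
  dd <- abs(diag(values) - 1)
  if (max(dd) > tol) {
    bad <- which.max(dd)
    stop(what, ": diagonal entry for ", roi_ids[bad], " is ",
         format(diag(values)[bad]), ", expected 1", call. = FALSE)
  }
  out <- values < range[1] - tol | values > range[2] + tol
  if (any(out)) {
    bad <- which(out, arr.ind = TRUE)[1, ]
    stop(what, ": entry (", roi_ids[bad[1]], ", ", roi_ids[bad[2]], ") = ",
         format(values[bad[1], bad[2]]), " outside [", range[1], ", ", range[2], "]",
         call. = FALSE)
  }
  invisible(TRUE)
}

as_correlation_matrix <- function(x, ...) {
  if (inherits(x, "dcg_corr")) x else correlation_matrix(x, ...)
}

#' @export
print.dcg_corr <- function(x, ...) {
  cat("ROI correlation matrix:", length(x$roi_ids), "ROIs",
      if (!is.na(x$subject_id)) paste0("(subject ", x$subject_id,
                                       ", ", x$group, ", ", x$trial, " trial)"),
      "\n")
  invisible(x)
}

#' Power transformation of a correlation matrix
#'
#' Maps correlations to similarities at temperature `T` via
#' `s_ij = |r_ij|^(1/T)`.  The temperature acts as a focal scale: for very
#' small `T` the similarity is near 0 unless `|r|` is very close to 1, so only
#' the tightest pairs remain visible; for large `T` all similarities approach
#' 1 and the whole cloud merges.
#'
#' @param corr a [correlation_matrix()] or plain symmetric matrix.
#' @param temperature positive scale parameter `T`.
#' @return An object of class `dcg_sim` with fields `values`, `temperature`,
#'   `roi_ids`.
#' @export
power_transform <- function(corr, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop("temperature must be a single positive number", call. = FALSE)
  }
  corr <- as_correlation_matrix(corr)
  s <- abs(corr$values)^(1 / temperature)
  diag(s) <- 1
  structure(list(values = s, temperature = temperature, roi_ids = corr$roi_ids,
                 subject_id = corr$subject_id, group = corr$group,
                 trial = corr$trial),
            class = "dcg_sim")
}

as_similarity <- function(x, temperature = NA_real_) {
  if (inherits(x, "dcg_sim")) return(x)
  x <- as.matrix(x)
  ids <- if (!is.null(colnames(x))) colnames(x) else as.character(seq_len(ncol(x)))
  validate_square_matrix(x, ids, tol = .dcg_tol, range = c(0, 1),
                         what = "similarity matrix")
  structure(list(values = x, temperature = temperature, roi_ids = ids,
                 subject_id = NA_character_, group = NA_character_,
                 trial = NA_character_),
            class = "dcg_sim")
}
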