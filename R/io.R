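# ---- generic TSV helpers ---------------------------------------------------

# every output file carries its provenance as '# key: value' comment lines
write_dcg_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dcgnet ", as.character(packageVersion("dcgnet"))), con)
  for (k in names(comments)) {
    writeLines(paste0("# ", k, ": ", comments[[k]]), con)
  }
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

read_tsv_comments <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  lines <- lines[grepl(": ", lines, fixed = TRUE)]
  kv <- strsplit(sub("^# ", "", lines), ": ", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}

# square matrix files: first column 'roi_id', then one column per ROI id
write_square_tsv <- function(values, path, comments = character()) {
  df <- data.frame(roi_id = rownames(values), values, check.names = FALSE)
  write_dcg_tsv(df, path, comments)
}

read_square_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] == "roi_id") {
    ids <- as.character(df$roi_id)
    df <- df[, -1, drop = FALSE]
  } else {
    ids <- names(df)
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("matrix file contains non-numeric entries", call. = FALSE)
  dimnames(m) <- list(ids, names(df))
  m
}

# ---- correlation matrices --------------------------------------------------

#' Read and write correlation matrices
#'
#' The on-disk format is a TSV with a `roi_id` column followed by one numeric
#' column per ROI id; `#`-prefixed comment lines record provenance.  The
#' reader validates symmetry, the unit diagonal and the \[-1, 1\] range, and
#' errors name the offending cells.
#'
#' @param path file path.
#' @param subject_id,group,trial metadata attached to the matrix (defaults
#'   are recovered from the file's comment header when present).
#' @return [read_correlation_matrix()] returns a [correlation_matrix()].
#' @export
read_correlation_matrix <- function(path, subject_id = NULL, group = NULL,
                                    trial = NULL) {
  m <- read_square_tsv(path)
  meta <- read_tsv_comments(path)
  pick <- function(x, key) {
    if (!is.null(x)) x else if (key %in% names(meta)) meta[[key]] else NA_character_
  }
  correlation_matrix(m, roi_ids = colnames(m),
                     subject_id = pick(subject_id, "subject_id"),
                     group = pick(group, "group"), trial = pick(trial, "trial"))
}

#' @param corr a [correlation_matrix()].
#' @rdname read_correlation_matrix
#' @export
write_correlation_matrix <- function(corr, path) {
  corr <- as_correlation_matrix(corr)
  write_square_tsv(corr$values, path,
                   comments = c(type = "correlation_matrix",
                                subject_id = corr$subject_id,
                                group = corr$group, trial = corr$trial))
}

#' Read and write cluster-sharing matrices
#'
#' @param path file path.
#' @return [read_sharing_matrix()] returns a `dcg_sharing` object.
#' @export
read_sharing_matrix <- function(path) {
  m <- read_square_tsv(path)
  meta <- read_tsv_comments(path)
  sh <- as_sharing(m)
  if ("temperature" %in% names(meta)) sh$temperature <- as.numeric(meta[["temperature"]])
  if ("n_walks" %in% names(meta)) sh$n_walks <- as.integer(meta[["n_walks"]])
  sh
}

#' @param sharing a `dcg_sharing` object.
#' @rdname read_sharing_matrix
#' @export
write_sharing_matrix <- function(sharing, path) {
  write_square_tsv(sharing$values, path,
                   comments = c(type = "sharing_matrix",
                                temperature = format(sharing$temperature),
                                n_walks = sharing$n_walks,
                                subject_id = sharing$subject_id,
                                trial = sharing$trial))
}

#' Write a clustering-level membership table
#'
#' @param level a `dcg_level`.
#' @param path file path; the TSV has columns `roi_id`, `cluster_label`.
#' @export
write_membership <- function(level, path) {
  df <- data.frame(roi_id = names(level$membership),
                   cluster_label = unname(level$membership))
  write_dcg_tsv(df, path, comments = c(type = "membership",
                                       temperature = format(level$temperature),
                                       k = level$k))
}

#' Write a cluster-count trajectory
#'
#' @param traj a [cluster_trajectory()] result.
#' @param path file path; columns `temperature`, `k`.
#' @export
write_trajectory <- function(traj, path) {
  write_dcg_tsv(as.data.frame(traj), path,
                comments = c(type = "trajectory",
                             subject_id = attr(traj, "subject_id"),
                             trial = attr(traj, "trial")))
}

# ---- edge-list export ------------------------------------------------------

#' Export a connectivity edge list with 3-D coordinates
#'
#' Produces the wiring table behind a 3-D network rendering: one row per ROI
#' pair that shares a cluster (for a clustering level) or whose sharing
#' probability reaches `threshold` (for a sharing matrix), with both ROIs'
#' atlas coordinates attached.
#'
#' @param x a `dcg_level` or `dcg_sharing`.
#' @param atlas a [make_atlas()] table covering all nodes of `x`.
#' @param threshold sharing-probability threshold (required for a sharing
#'   matrix, ignored for a level).
#' @return Data frame with columns `roi_a`, `roi_b`, `weight`, `x_a`, `y_a`,
#'   `z_a`, `x_b`, `y_b`, `z_b`.
#' @export
export_edgelist <- function(x, atlas, threshold = NULL) {
  if (inherits(x, "dcg_level")) {
    ids <- names(x$membership)
    same <- outer(x$membership, x$membership, "==")
    w <- same * 1
  } else {
    sh <- as_sharing(x)
    if (is.null(threshold)) {
      stop("a sharing matrix requires a threshold", call. = FALSE)
    }
    ids <- sh$roi_ids
    w <- sh$values * (sh$values >= threshold)
  }
  missing <- setdiff(ids, as.character(atlas$roi_id))
  if (length(missing)) {
    stop("atlas lacks coordinates for ROI(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  co <- atlas[match(ids, as.character(atlas$roi_id)), c("x", "y", "z")]
  data.frame(roi_a = ids[keep[, 1]], roi_b = ids[keep[, 2]],
             weight = w[keep],
             x_a = co$x[keep[, 1]], y_a = co$y[keep[, 1]], z_a = co$z[keep[, 1]],
             x_b = co$x[keep[, 2]], y_b = co$y[keep[, 2]], z_b = co$z[keep[, 2]])
}

# ---- cohort directories ----------------------------------------------------

#' Write a cohort to a directory of TSV files
#'
#' Writes `atlas.tsv`, `subjects.tsv`, `ground_truth.tsv` and one correlation
#' matrix file `<subject_id>_<trial>.tsv` per subject-trial.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  write_dcg_tsv(cohort$subjects, file.path(dir, "subjects.tsv"),
                comments = c(type = "subjects"))
  if (!is.null(cohort$ground_truth)) {
    write_dcg_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                  comments = c(type = "ground_truth"))
  }
  for (sid in names(cohort$matrices)) {
    for (trl in names(cohort$matrices[[sid]])) {
      write_correlation_matrix(cohort$matrices[[sid]][[trl]],
                               file.path(dir, paste0(sid, "_", trl, ".tsv")))
    }
  }
  invisible(dir)
}

#' @param dir a directory written by [write_cohort()] (or the `simulate` CLI
#'   subcommand).
#' @rdname write_cohort
#' @return [read_cohort()] returns a list with `subjects`, `atlas`,
#'   `matrices` and (when present) `ground_truth`, usable by
#'   [cohort_configurations()] and [cohort_coarse_features()].
#' @export
read_cohort <- function(dir) {
  subjects <- read.delim(file.path(dir, "subjects.tsv"), comment.char = "#",
                         stringsAsFactors = FALSE)
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  files <- list.files(dir, pattern = "_(green|red)\\.tsv$")
  matrices <- list()
  for (f in files) {
    base <- sub("\\.tsv$", "", f)
    trl <- sub("^.*_", "", base)
    sid <- sub("_(green|red)$", "", base)
    matrices[[sid]][[trl]] <- read_correlation_matrix(file.path(dir, f),
                                                      subject_id = sid,
                                                      trial = trl)
  }
  gt_path <- file.path(dir, "ground_truth.tsv")
  gt <- if (file.exists(gt_path)) {
    read.delim(gt_path, comment.char = "#", stringsAsFactors = FALSE)
  }
  list(subjects = subjects, atlas = atlas, matrices = matrices,
       ground_truth = gt)
}
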