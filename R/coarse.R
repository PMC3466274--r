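#' Rand index between two partitions
#'
#' Proportion of unordered element pairs on which two partitions agree: both
#' place the pair in one cluster, or both separate it.
#'
#' @param a,b cluster label vectors over the same element set.  If both are
#'   named, elements are aligned by name.
#' @return The Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions cover different element sets", call. = FALSE)
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions cover different element sets", call. = FALSE)
  }
  n <- length(a)
  if (n < 2) stop("at least 2 elements required", call. = FALSE)
  tab <- table(a, b)
  same_same <- sum(choose(tab, 2))
  same_a <- sum(choose(rowSums(tab), 2))
  same_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # agreements = co-clustered in both + separated in both
  (total + 2 * same_same - same_a - same_b) / total
}

#' Coarse-scale connectivity retention features
#'
#' For a clustering level tuned to the regional scale, computes for each
#' anatomical region the proportion of within-region ROI pairs that share a
#' cluster (intra-regional retention) and, for each unordered region pair,
#' the proportion of cross-region ROI pairs that share a cluster
#' (inter-regional retention).  A shared cluster is read as a retained
#' functional link, so larger values mean more connectivity.
#'
#' @param level a `dcg_level` whose membership covers all atlas ROIs.
#' @param atlas a [make_atlas()] table.
#' @return Named numeric vector of length `n_regions + choose(n_regions, 2)`
#'   (55 for the default 10-region atlas), ordered as all intra features in
#'   region order followed by inter features in lexicographic pair order.
#'   A region with fewer than 2 ROIs yields `NaN` for its intra feature.
#' @export
retention_features <- function(level, atlas) {
  mem <- level$membership
  ids <- as.character(atlas$roi_id)
  if (!all(ids %in% names(mem))) {
    stop("clustering level does not cover all atlas ROIs", call. = FALSE)
  }
  mem <- mem[ids]
  regions <- levels(atlas$region)
  idx <- split(seq_along(ids), atlas$region)
  same <- outer(mem, mem, "==")
  pair_fraction <- function(i, j) {
    if (identical(i, j)) {
      if (length(i) < 2) return(NaN)
      m <- same[i, i]
      mean(m[upper.tri(m)])
    } else {
      mean(same[i, j])
    }
  }
  intra <- vapply(regions, function(r) pair_fraction(idx[[r]], idx[[r]]), numeric(1))
  pairs <- combn(regions, 2)
  inter <- vapply(seq_len(ncol(pairs)), function(p) {
    pair_fraction(idx[[pairs[1, p]]], idx[[pairs[2, p]]])
  }, numeric(1))
  out <- c(intra, inter)
  names(out) <- coarse_feature_names(regions)
  out
}

#' Screen coarse features with two-sample t-tests
#'
#' Runs a Welch two-sample t-test per feature column with sign convention
#' ASD minus TD, so a positive t-statistic means more retained connectivity
#' in the ASD group.  Features with a raw p-value at or below `p_cut` are
#' selected; no multiple-testing correction is applied, as the screen is
#' feature selection rather than confirmatory inference.
#'
#' @param asd,td numeric matrices (subjects x features) with matching
#'   columns.
#' @param p_cut p-value cutoff for selection.
#' @param all if `TRUE`, return every feature with a `selected` flag instead
#'   of only the selected ones.
#' @return Data frame with columns `feature`, `t`, `p`, `direction`
#'   (`"ASD"`/`"TD"`: which group shows more connectivity), sorted by the
#'   input feature order.  Features with zero variance in both groups are
#'   dropped with a warning.
#' @export
screen_features <- function(asd, td, p_cut = 0.105, all = FALSE) {
  asd <- as.matrix(asd); td <- as.matrix(td)
  if (ncol(asd) != ncol(td)) stop("feature counts differ between groups", call. = FALSE)
  if (nrow(asd) < 2 || nrow(td) < 2) {
    stop("at least 2 subjects per group required", call. = FALSE)
  }
  feats <- colnames(asd)
  if (is.null(feats)) feats <- as.character(seq_len(ncol(asd)))
  res <- lapply(seq_len(ncol(asd)), function(j) {
    x <- asd[, j]; y <- td[, j]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      # no within-group variation: the t statistic is undefined when the
      # group means agree, and infinitely significant when they differ
      if (mean(x) == mean(y)) return(NULL)
      return(data.frame(feature = feats[j],
                        t = sign(mean(x) - mean(y)) * Inf, p = 0,
                        direction = if (mean(x) > mean(y)) "ASD" else "TD"))
    }
    # Welch by default; fall back to the direct formula when the spread is
    # so small that t.test refuses ("data are essentially constant")
    tt <- tryCatch(t.test(x, y), error = function(e) NULL)
    if (is.null(tt)) {
      se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
      stat <- (mean(x) - mean(y)) / se
      df <- se^4 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                      (stats::var(y) / length(y))^2 / (length(y) - 1))
      tt <- list(statistic = stat, p.value = 2 * stats::pt(-abs(stat), df))
    }
    data.frame(feature = feats[j], t = unname(tt$statistic),
               p = tt$p.value,
               direction = if (tt$statistic >= 0) "ASD" else "TD")
  })
  dropped <- feats[vapply(res, is.null, logical(1))]
  if (length(dropped)) {
    warning("zero-variance feature(s) excluded from screening: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(feature = character(), t = numeric(), p = numeric(),
                      direction = character())
  }
  if (all) {
    out$selected <- out$p <= p_cut
    out
  } else {
    out[out$p <= p_cut, , drop = FALSE]
  }
}
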