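#' Default temperature grid
#'
#' Logarithmically spaced temperatures covering the finest scale used for
#' motif extraction (`T = 0.001`) up to the all-merged regime.
#'
#' @param n number of grid points.
#' @param t_min,t_max grid end points.
#' @return Increasing numeric vector of temperatures.
#' @export
default_t_grid <- function(n = 40L, t_min = 0.001, t_max = 5) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Cluster-count trajectory over a temperature grid
#'
#' Estimates the cluster count at every grid temperature, tracing the
#' evolution of the clustering geometry from many small core clusters at
#' small `T` to a single cluster at large `T`.  Raw per-temperature estimates
#' are reported without smoothing or monotonicity enforcement.
#'
#' @param corr a [correlation_matrix()].
#' @param t_grid strictly increasing vector of positive temperatures.
#' @param params a [walk_params()] object.
#' @return A data frame of class `dcg_trajectory` with columns `temperature`
#'   and `k`.
#' @export
cluster_trajectory <- function(corr, t_grid = default_t_grid(),
                               params = walk_params()) {
  corr <- as_correlation_matrix(corr)
  check_t_grid(t_grid)
  k <- vapply(t_grid, function(tt) {
    estimate_cluster_count(sharing_matrix(power_transform(corr, tt), params))
  }, integer(1))
  out <- data.frame(temperature = t_grid, k = k)
  attr(out, "subject_id") <- corr$subject_id
  attr(out, "trial") <- corr$trial
  class(out) <- c("dcg_trajectory", "data.frame")
  out
}

check_t_grid <- function(t_grid) {
  if (length(t_grid) < 1) stop("temperature grid must be nonempty", call. = FALSE)
  if (any(t_grid <= 0)) stop("temperatures must be positive", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("temperature grid must be strictly increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Tune a subject's geometry to a target cluster count
#'
#' Sweeps the temperature grid and returns the clustering level whose
#' estimated cluster count is closest to `k_target`.  Because a sensible
#' common scale is one that is robust to small temperature changes, the
#' selection is made on a 3-point running median of the cluster-count
#' trajectory (ignoring isolated spurious counts in the transition zones
#' between scales), and ties are broken toward the highest attaining
#' temperature, i.e. the most consolidated geometry with that count; the
#' returned level carries the raw estimate at the selected temperature.
#' The achieved count may differ from the target; it is reported in the
#' returned level (`$k`) together with the selected temperature.
#'
#' @param corr a [correlation_matrix()].
#' @param k_target desired number of clusters.
#' @param t_grid strictly increasing vector of positive temperatures.
#' @param params a [walk_params()] object.
#' @return A `dcg_level` (see [cluster_level()]) with an extra field
#'   `k_target`.
#' @export
tune_to_count <- function(corr, k_target, t_grid = default_t_grid(),
                          params = walk_params()) {
  corr <- as_correlation_matrix(corr)
  check_t_grid(t_grid)
  k_target <- as.integer(k_target)
  n <- length(corr$roi_ids)
  if (k_target < 1 || k_target > n) {
    stop("k_target must be in [1, ", n, "]", call. = FALSE)
  }
  k <- vapply(t_grid, function(tt) {
    estimate_cluster_count(sharing_matrix(power_transform(corr, tt), params))
  }, integer(1))
  k_smooth <- if (length(k) >= 3) as.integer(stats::runmed(k, 3)) else k
  # among the grid points attaining the best match, take the highest
  # temperature: the coarsest geometry attaining the target count, whose
  # merges are the most consolidated (the low-temperature shoulder of a
  # count plateau can attain the same count with still-fragmented blocks)
  pick <- max(which(abs(k_smooth - k_target) == min(abs(k_smooth - k_target))))
  p <- sharing_matrix(power_transform(corr, t_grid[pick]), params)
  level <- level_from_sharing(p, k = k[pick])
  level$k_target <- k_target
  level
}

#' Critical temperatures of a cluster-count trajectory
#'
#' Phase transitions are temperatures at which the cluster count drops
#' sharply.  All grid intervals whose drop in `k` is at least `frac` times
#' the largest drop are reported, each as the midpoint of its temperature
#' interval.  A trajectory with no decline has no critical temperature.
#'
#' @param traj a [cluster_trajectory()] result (or any data frame with
#'   columns `temperature`, `k`).
#' @param frac fraction of the largest drop required to qualify.
#' @return Numeric vector of critical temperatures (possibly empty).
#' @export
critical_temperatures <- function(traj, frac = 0.5) {
  if (nrow(traj) < 2) stop("at least 2 trajectory points required", call. = FALSE)
  drops <- -diff(traj$k)
  drops[drops < 0] <- 0
  if (max(drops) == 0) return(numeric(0))
  sel <- which(drops >= frac * max(drops) & drops > 0)
  (traj$temperature[sel] + traj$temperature[sel + 1]) / 2
}
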