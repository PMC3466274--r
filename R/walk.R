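#' Parameters of the regulated random walk ensemble
#'
#' @param removal_visits number of visits `m` after which a node is removed
#'   from the walk (the recurrence-time regulation).
#' @param n_walks number of walks aggregated into one cluster-sharing matrix.
#' @param gap_factor factor `c` of the segment-boundary rule: a boundary is
#'   placed between consecutive removals whose step gap exceeds
#'   `mean(gaps) + c * sd(gaps)` within that walk.
#' @param break_frac similarity-break factor: a boundary is also placed
#'   between consecutive removals whose mutual similarity falls below
#'   `break_frac` times the smaller of the two nodes' strongest off-diagonal
#'   similarities (see [segment_removals()]).
#' @param seed integer seed for the walk ensemble.
#' @return A list of class `dcg_walk_params`.
#' @export
walk_params <- function(removal_visits = 3L, n_walks = 100L, gap_factor = 1.0,
                        break_frac = 1e-4, seed = 1L) {
  removal_visits <- as.integer(removal_visits)
  n_walks <- as.integer(n_walks)
  if (removal_visits < 1L) stop("removal_visits must be >= 1", call. = FALSE)
  if (n_walks < 1L) stop("n_walks must be >= 1", call. = FALSE)
  if (gap_factor <= 0) stop("gap_factor must be positive", call. = FALSE)
  if (break_frac < 0 || break_frac >= 1) {
    stop("break_frac must be in [0, 1)", call. = FALSE)
  }
  structure(list(removal_visits = removal_visits, n_walks = n_walks,
                 gap_factor = gap_factor, break_frac = break_frac,
                 seed = as.integer(seed)),
            class = "dcg_walk_params")
}

#' Run one regulated random walk
#'
#' From the current node the walk moves to an active (not yet removed) node
#' with probability proportional to the similarity; a node is removed at its
#' `removal_visits`-th visit.  After a removal the walk continues from the
#' removed node's similarity row, so a tight cluster is exhausted before the
#' walk drifts on; when the current row carries no mass onto active nodes the
#' walk teleports to a uniformly random active node.  Nodes removed in quick
#' succession belong to the same local cluster for this walk: a segment
#' boundary is placed at every teleport and at every unusually large
#' removal-step gap (see [segment_removals()]).
#'
#' @param sim a `dcg_sim` similarity matrix (see [power_transform()]).
#' @param params a [walk_params()] object.
#' @param seed integer seed for this walk.
#' @return A list of class `dcg_walk` with `removal_order` (node indices),
#'   `removal_steps`, `teleported`, and `segments` (a partition of `1:n`
#'   into contiguous removal segments).
#' @export
run_regulated_walk <- function(sim, params = walk_params(), seed = params$seed) {
  sim <- as_similarity(sim)
  n <- nrow(sim$values)
  if (n < 2) stop("at least 2 nodes required", call. = FALSE)
  set.seed(as.integer(seed))
  rec <- regulated_walk_cpp(sim$values, params$removal_visits)
  lb <- link_break_inputs(sim$values, offdiag_rowmax(sim$values), rec,
                          params$break_frac)
  segments <- segment_removals(rec$removal_order, rec$removal_steps,
                               params$gap_factor, rec$teleported,
                               link_sims = lb$sims, link_floors = lb$floors)
  structure(list(removal_order = rec$removal_order,
                 removal_steps = rec$removal_steps,
                 teleported = rec$teleported,
                 segments = segments),
            class = "dcg_walk")
}

#' Split a removal sequence into segments
#'
#' A boundary is placed between consecutive removals when (i) the walk
#' teleported in between, since a teleport means no similarity path led out
#' of the previous cluster; (ii) the step gap exceeds
#' `mean(gaps) + gap_factor * sd(gaps)` over all gaps of the walk (with
#' fewer than two gaps, or zero spread, this criterion is silent); or
#' (iii) the similarity between the two removed nodes is negligible relative
#' to either node's own strongest link (below `break_frac` times the smaller
#' of the two row maxima), which separates nodes that merely happened to
#' saturate back-to-back — late-walk stragglers from different clusters —
#' from genuine cluster mates.  The row-relative form of rule (iii) makes it
#' temperature-invariant: a bond the walk follows with high relative
#' probability is kept no matter how small its absolute similarity.
#'
#' @param removal_order node indices in removal order.
#' @param removal_steps strictly increasing step indices of the removals.
#' @param gap_factor boundary factor `c`.
#' @param teleported optional logical vector flagging removals reached after
#'   a teleport.
#' @param link_sims optional similarities `S(node_i, node_[i+1])` between
#'   consecutive removals, enabling the similarity-break rule.
#' @param link_floors per-link thresholds below which a link is broken
#'   (`break_frac` times the smaller endpoint row maximum).
#' @return A list of integer vectors partitioning `removal_order`.
#' @export
segment_removals <- function(removal_order, removal_steps, gap_factor = 1.0,
                             teleported = NULL,
                             link_sims = NULL, link_floors = NULL) {
  stopifnot(length(removal_order) == length(removal_steps))
  n <- length(removal_order)
  if (n <= 1) return(list(as.integer(removal_order)))
  gaps <- diff(removal_steps)
  s <- if (length(gaps) >= 2) sd(gaps) else 0
  boundary <- gaps > mean(gaps) + gap_factor * s
  if (!is.null(teleported)) boundary <- boundary | teleported[-1]
  if (!is.null(link_sims) && !is.null(link_floors)) {
    boundary <- boundary | link_sims < link_floors
  }
  grp <- cumsum(c(1L, as.integer(boundary)))
  unname(split(as.integer(removal_order), grp))
}

# similarity-break inputs for one walk: the similarity between consecutive
# removals and its row-relative floor
link_break_inputs <- function(values, rowmax, rec, break_frac) {
  ord <- rec$removal_order
  n <- length(ord)
  list(sims = values[cbind(ord[-n], ord[-1])],
       floors = break_frac * pmin(rowmax[ord[-n]], rowmax[ord[-1]]))
}

# strongest off-diagonal similarity per row
offdiag_rowmax <- function(values) {
  v <- values
  diag(v) <- 0
  apply(v, 1, max)
}

#' Cluster-sharing probability matrix from a walk ensemble
#'
#' Runs `params$n_walks` regulated random walks on the similarity matrix and
#' records, for every pair of nodes, the fraction of walks in which the two
#' nodes were removed within the same segment.  High sharing indicates that
#' the pair consistently falls into the same local cluster.
#'
#' @inheritParams run_regulated_walk
#' @return An object of class `dcg_sharing` with fields `values` (n x n, unit
#'   diagonal, entries in \[0, 1\]), `temperature`, `n_walks`.
#' @export
sharing_matrix <- function(sim, params = walk_params()) {
  sim <- as_similarity(sim)
  n <- nrow(sim$values)
  if (n < 2) stop("at least 2 nodes required", call. = FALSE)
  set.seed(params$seed)
  counts <- matrix(0, n, n)
  rowmax <- offdiag_rowmax(sim$values)
  for (w in seq_len(params$n_walks)) {
    rec <- regulated_walk_cpp(sim$values, params$removal_visits)
    lb <- link_break_inputs(sim$values, rowmax, rec, params$break_frac)
    segs <- segment_removals(rec$removal_order, rec$removal_steps,
                             params$gap_factor, rec$teleported,
                             link_sims = lb$sims, link_floors = lb$floors)
    for (idx in segs) counts[idx, idx] <- counts[idx, idx] + 1
  }
  p <- counts / params$n_walks
  diag(p) <- 1
  dimnames(p) <- list(sim$roi_ids, sim$roi_ids)
  structure(list(values = p, temperature = sim$temperature,
                 n_walks = params$n_walks, roi_ids = sim$roi_ids,
                 subject_id = sim$subject_id, group = sim$group,
                 trial = sim$trial),
            class = "dcg_sharing")
}

as_sharing <- function(x) {
  if (inherits(x, "dcg_sharing")) return(x)
  x <- as.matrix(x)
  ids <- if (!is.null(colnames(x))) colnames(x) else as.character(seq_len(ncol(x)))
  validate_square_matrix(x, ids, tol = .dcg_tol, range = c(0, 1),
                         what = "sharing matrix")
  structure(list(values = x, temperature = NA_real_, n_walks = NA_integer_,
                 roi_ids = ids, subject_id = NA_character_,
                 group = NA_character_, trial = NA_character_),
            class = "dcg_sharing")
}
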