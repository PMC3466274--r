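#' Canonical motif identifier
#'
#' A motif is a set of at least two ROI ids; its canonical identifier is the
#' sorted, comma-joined id tuple (e.g. `"87,88"`), making motif identity
#' invariant to input ordering.
#'
#' @param ids ROI ids of one motif.
#' @return Character scalar.
#' @export
motif_id <- function(ids) {
  ids <- suppressWarnings(as.integer(ids))
  if (anyNA(ids)) stop("motif ids must be integer ROI ids", call. = FALSE)
  paste(sort(ids), collapse = ",")
}

#' @param id canonical motif identifier.
#' @rdname motif_id
#' @return [motif_members()] returns the integer ROI ids of a motif.
#' @export
motif_members <- function(id) {
  as.integer(strsplit(id, ",", fixed = TRUE)[[1]])
}

#' Motif configuration of one subject-trial
#'
#' Extracts the fine-scale motif configuration from a cluster-sharing matrix
#' computed at the finest temperature: the complete-linkage hierarchical tree
#' on dissimilarity `1 - P` is pruned at `prune_height`, and every branch
#' with at least two members becomes one motif.  Singletons are excluded.
#'
#' @param sharing a `dcg_sharing` matrix (typically at `T = 0.001`).
#' @param prune_height tree-pruning threshold in (0, 1\].
#' @return An object of class `dcg_config`: a list with `subject_id`,
#'   `group`, `trial` and `motifs`, a character vector of canonical motif
#'   ids.
#' @export
motif_configuration <- function(sharing, prune_height = 0.85) {
  sharing <- as_sharing(sharing)
  if (prune_height <= 0 || prune_height > 1) {
    stop("prune_height must be in (0, 1]", call. = FALSE)
  }
  membership <- cut_sharing_tree(sharing, h = prune_height)
  branches <- split(sharing$roi_ids, membership)
  branches <- branches[lengths(branches) >= 2]
  motifs <- vapply(branches, motif_id, character(1), USE.NAMES = FALSE)
  structure(list(subject_id = sharing$subject_id, group = sharing$group,
                 trial = sharing$trial, motifs = sort(motifs)),
            class = "dcg_config")
}

new_config <- function(motifs, subject_id = NA_character_,
                       group = NA_character_, trial = NA_character_) {
  structure(list(subject_id = subject_id, group = group, trial = trial,
                 motifs = sort(unname(vapply(motifs, motif_id, character(1))))),
            class = "dcg_config")
}

#' Group-trial motif domain with prevalence
#'
#' Pools the motif configurations of one group and trial into a motif domain.
#' The prevalence of a motif is the number of configurations containing it
#' (exact set identity of the ROI members).
#'
#' @param configs list of `dcg_config` objects of a single group and trial.
#' @return An object of class `dcg_domain`: list with `group`, `trial`,
#'   `n_subjects` and `prevalence`, a named integer vector keyed by canonical
#'   motif id.
#' @export
motif_domain <- function(configs) {
  if (!length(configs)) stop("no configurations supplied", call. = FALSE)
  grp <- unique(vapply(configs, `[[`, character(1), "group"))
  trl <- unique(vapply(configs, `[[`, character(1), "trial"))
  if (length(grp[!is.na(grp)]) > 1 || length(trl[!is.na(trl)]) > 1) {
    stop("configurations mix groups or trials", call. = FALSE)
  }
  all_motifs <- unlist(lapply(configs, `[[`, "motifs"), use.names = FALSE)
  prevalence <- if (length(all_motifs)) {
    tab <- table(all_motifs)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(group = grp[1], trial = trl[1], n_subjects = length(configs),
                 prevalence = prevalence),
            class = "dcg_domain")
}

#' Restrict a motif domain by a prevalence threshold
#'
#' @param dom a [motif_domain()].
#' @param tau minimum prevalence; motifs with prevalence `>= tau` are kept.
#' @return The restricted `dcg_domain`.
#' @export
restrict_domain <- function(dom, tau) {
  tau <- as.integer(tau)
  if (tau < 1) stop("tau must be >= 1", call. = FALSE)
  dom$prevalence <- dom$prevalence[dom$prevalence >= tau]
  dom$tau <- tau
  dom
}

#' Fine-scale odds score of a configuration
#'
#' For the motifs of a configuration present in *both* restricted domains,
#' sums the log relative-prevalence ratios
#' `log((prev_ASD(m) / n_ASD) / (prev_TD(m) / n_TD))`, where `n_ASD`, `n_TD`
#' are the numbers of subjects behind each domain.  A positive score favors
#' ASD membership, a negative one TD; motifs absent from either restricted
#' domain contribute nothing (their information is carried by the
#' missing-motif counts instead).  Prevalence is normalized within each
#' domain so that a jackknifed domain (built from one subject fewer) is
#' comparable to a full one; with equally sized domains the score reduces to
#' the plain log prevalence ratio.
#'
#' @param config a `dcg_config`.
#' @param dom_asd,dom_td restricted ASD and TD domains at a common threshold.
#' @return Numeric log-odds score (0 for an empty intersection).
#' @export
odds_score <- function(config, dom_asd, dom_td) {
  m <- intersect(config$motifs,
                 intersect(names(dom_asd$prevalence), names(dom_td$prevalence)))
  if (!length(m)) return(0)
  sum(log((dom_asd$prevalence[m] / dom_asd$n_subjects) /
            (dom_td$prevalence[m] / dom_td$n_subjects)))
}

#' Missing-motif counts of a configuration
#'
#' Counts how many motifs of a configuration are absent from the restricted
#' ASD domain and from the restricted TD domain.
#'
#' @inheritParams odds_score
#' @return Integer vector `c(miss_asd, miss_td)`.
#' @export
missing_counts <- function(config, dom_asd, dom_td) {
  c(miss_asd = sum(!config$motifs %in% names(dom_asd$prevalence)),
    miss_td = sum(!config$motifs %in% names(dom_td$prevalence)))
}

#' Motif prevalence table for two domains
#'
#' Side-by-side prevalence of all motifs seen in either group, with the
#' absolute group difference, sorted by decreasing difference.
#'
#' @param dom_asd,dom_td `dcg_domain` objects for the two groups.
#' @return Data frame with columns `motif`, `prevalence_asd`,
#'   `prevalence_td`, `abs_difference`.
#' @export
motif_table <- function(dom_asd, dom_td) {
  motifs <- union(names(dom_asd$prevalence), names(dom_td$prevalence))
  pa <- ifelse(motifs %in% names(dom_asd$prevalence),
               dom_asd$prevalence[motifs], 0L)
  pt <- ifelse(motifs %in% names(dom_td$prevalence),
               dom_td$prevalence[motifs], 0L)
  out <- data.frame(motif = motifs, prevalence_asd = as.integer(pa),
                    prevalence_td = as.integer(pt),
                    abs_difference = abs(as.integer(pa) - as.integer(pt)))
  out[order(-out$abs_difference, out$motif), , drop = FALSE]
}
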