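#' Extract motif configurations for a whole cohort
#'
#' Runs the fine-scale pipeline (power transform at the finest temperature,
#' walk ensemble, tree pruning) for every subject and trial of a cohort and
#' collects the motif configurations.
#'
#' @param cohort a [simulate_cohort()] result, or any list with `subjects`
#'   (data frame with `subject_id`, `group`) and `matrices`
#'   (`matrices[[subject_id]][[trial]]` correlation matrices).
#' @param temperature finest-scale temperature.
#' @param prune_height tree-pruning threshold.
#' @param params a [walk_params()]; the walk seed of each subject-trial is
#'   derived deterministically from `params$seed`.
#' @param trials trials to process.
#' @return An object of class `dcg_config_set`.
#' @export
cohort_configurations <- function(cohort, temperature = 0.001,
                                  prune_height = 0.85,
                                  params = walk_params(),
                                  trials = NULL) {
  subjects <- cohort$subjects
  if (is.null(trials)) trials <- names(cohort$matrices[[1]])
  configs <- list()
  idx <- 0L
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    for (trl in trials) {
      idx <- idx + 1L
      corr <- cohort$matrices[[sid]][[trl]]
      if (is.null(corr)) stop("missing matrix for ", sid, " / ", trl, call. = FALSE)
      p <- params
      p$seed <- derive_seed(params$seed, idx)
      sharing <- sharing_matrix(power_transform(corr, temperature), p)
      configs[[paste(sid, trl, sep = "|")]] <- motif_configuration(sharing, prune_height)
    }
  }
  config_set(configs, subjects = subjects, trials = trials)
}

# exact (a * b) mod 2^32 without losing precision past 2^53
mul32 <- function(a, b) {
  a <- a %% 4294967296
  lo <- (a %% 65536) * b
  hi <- ((a %/% 65536) * b) %% 65536
  (lo + hi * 65536) %% 4294967296
}

# deterministic seed derivation via a murmur-style integer hash finalizer.
# Linearly related seeds (seed + k * step) must not yield correlated RNG
# streams, so the master seed and index are avalanche-mixed before use.
derive_seed <- function(seed, index) {
  h <- (as.numeric(seed) %% 4294967296 + mul32(as.numeric(index), 2654435761)) %% 4294967296
  h <- bitwXor64(h, h %/% 65536)
  h <- mul32(h, 2246822519)
  h <- bitwXor64(h, h %/% 8192)
  h <- mul32(h, 3266489917)
  h <- bitwXor64(h, h %/% 65536)
  as.integer(h %% 2147483647) + 1L
}

# xor of two nonnegative doubles holding 32-bit values
bitwXor64 <- function(a, b) {
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  as.numeric(hi) * 65536 + as.numeric(lo)
}

#' Assemble a configuration set
#'
#' @param configs named list of `dcg_config` objects keyed
#'   `"subject_id|trial"` (keys are rebuilt from the configurations if
#'   unnamed).
#' @param subjects optional data frame with `subject_id`, `group`; inferred
#'   from the configurations when omitted.
#' @param trials optional trial names; inferred when omitted.
#' @return An object of class `dcg_config_set`.
#' @export
config_set <- function(configs, subjects = NULL, trials = NULL) {
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) {
      paste(cf$subject_id, cf$trial, sep = "|")
    }, character(1))
  }
  if (is.null(subjects)) {
    sid <- vapply(configs, `[[`, character(1), "subject_id")
    grp <- vapply(configs, `[[`, character(1), "group")
    keep <- !duplicated(sid)
    subjects <- data.frame(subject_id = sid[keep], group = grp[keep])
    rownames(subjects) <- NULL
  }
  if (is.null(trials)) {
    trials <- unique(vapply(configs, `[[`, character(1), "trial"))
  }
  structure(list(configs = configs, subjects = subjects, trials = trials),
            class = "dcg_config_set")
}

get_config <- function(cs, subject_id, trial) {
  cf <- cs$configs[[paste(subject_id, trial, sep = "|")]]
  if (is.null(cf)) stop("no configuration for ", subject_id, " / ", trial, call. = FALSE)
  cf
}

# full motif domain of one group-trial, optionally excluding one subject
full_domain <- function(cs, group, trial, exclude = NULL) {
  sids <- cs$subjects$subject_id[cs$subjects$group == group]
  if (!is.null(exclude)) sids <- setdiff(sids, exclude)
  motif_domain(lapply(sids, get_config, cs = cs, trial = trial))
}

# remove one subject's own motifs from a domain (prevalence - 1 each)
jackknife_domain <- function(dom, config) {
  m <- intersect(config$motifs, names(dom$prevalence))
  dom$prevalence[m] <- dom$prevalence[m] - 1L
  dom$prevalence <- dom$prevalence[dom$prevalence > 0L]
  dom$n_subjects <- dom$n_subjects - 1L
  dom
}

#' Fine-scale feature vectors for all subjects
#'
#' For every subject and requested trial, builds the restricted leave-self-out
#' motif domains and computes the three fine-scale components: the log-odds
#' score over motifs present in both restricted domains, and the counts of
#' motifs missing from the restricted ASD and TD domains.  A subject's own
#' group domain always excludes the subject (jackknife); the opposite group's
#' domain uses all of its members.  The per-trial classifier predictors are
#' the odds score and the missing-count difference `miss_td - miss_asd`.
#'
#' @param cs a [cohort_configurations()] result.
#' @param tau prevalence threshold applied to both domains.
#' @param trials trials to use (subset of the set's trials).
#' @param exclude optional subject id excluded from every domain (used for
#'   the held-out subject in per-fold cross-validation).
#' @return Data frame with one row per subject: `subject_id`, `group`, and
#'   per trial `odds_<trial>`, `miss_asd_<trial>`, `miss_td_<trial>`,
#'   `dmiss_<trial>`.
#' @export
fine_features <- function(cs, tau, trials = cs$trials, exclude = NULL) {
  stopifnot(all(trials %in% cs$trials))
  groups <- c("ASD", "TD")
  # restricted full (or held-out-excluded) domains per group-trial
  dom <- lapply(stats::setNames(groups, groups), function(g) {
    lapply(stats::setNames(trials, trials), function(trl) {
      full_domain(cs, g, trl, exclude = exclude)
    })
  })
  subjects <- cs$subjects
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    g <- subjects$group[i]
    other <- setdiff(groups, g)
    out <- list(subject_id = sid, group = g)
    for (trl in trials) {
      cf <- get_config(cs, sid, trl)
      own <- dom[[g]][[trl]]
      if (!identical(sid, exclude)) own <- jackknife_domain(own, cf)
      da <- restrict_domain(if (g == "ASD") own else dom[["ASD"]][[trl]], tau)
      dt <- restrict_domain(if (g == "TD") own else dom[["TD"]][[trl]], tau)
      miss <- missing_counts(cf, da, dt)
      out[[paste0("odds_", trl)]] <- odds_score(cf, da, dt)
      out[[paste0("miss_asd_", trl)]] <- unname(miss["miss_asd"])
      out[[paste0("miss_td_", trl)]] <- unname(miss["miss_td"])
      out[[paste0("dmiss_", trl)]] <- unname(miss["miss_td"] - miss["miss_asd"])
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

# predictor matrix (odds + dmiss per trial) from a fine_features data frame
fine_predictor_matrix <- function(feats, trials) {
  cols <- as.vector(rbind(paste0("odds_", trials), paste0("dmiss_", trials)))
  x <- as.matrix(feats[, cols, drop = FALSE])
  rownames(x) <- feats$subject_id
  x
}
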