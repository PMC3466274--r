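#' Design of a synthetic connectivity cohort
#'
#' Describes a cohort of block-structured ROI correlation matrices with
#' planted multiscale structure: consecutive odd/even ROI pairs form
#' candidate left/right pair motifs, ROIs are grouped into anatomical region
#' blocks, and group-differential motif inclusion probabilities plus regional
#' correlation shifts create the between-group signal.  The three correlation
#' levels must satisfy `within_motif > within_region > baseline` so that the
#' motif, region and global scales are separable by temperature.
#'
#' @param n_per_group subjects per group.
#' @param trials trial labels; each subject gets one matrix per trial, with
#'   motif inclusion drawn independently per trial (trial-specific network
#'   configurations).
#' @param region_counts named ROI counts per region.
#' @param within_motif,within_region,baseline the three correlation levels.
#' @param noise_sd standard deviation of the symmetric Gaussian entry noise.
#' @param red_noise_mult noise multiplier for `"red"` trials, reflecting
#'   their less stable correlation estimates.
#' @param motif_probs optional `n_motifs x 2` matrix (columns `ASD`, `TD`) of
#'   per-group motif inclusion probabilities; defaults to
#'   [default_motif_probs()].
#' @param regional_shifts optional data frame (`region_a`, `region_b`,
#'   `group`, `delta`) of correlation shifts; `region_b = NA` shifts a
#'   within-region block.  Defaults to [default_regional_shifts()].
#' @return A list of class `dcg_design`; `$motifs` holds the canonical motif
#'   ids of the planted pairs.
#' @export
cohort_design <- function(n_per_group = 29L, trials = c("green", "red"),
                          region_counts = default_region_counts(),
                          within_motif = 0.9, within_region = 0.45,
                          baseline = 0.1, noise_sd = 0.05,
                          red_noise_mult = 1.5, motif_probs = NULL,
                          regional_shifts = NULL) {
  if (!(within_motif > within_region && within_region > baseline)) {
    stop("correlation levels must satisfy within_motif > within_region > baseline",
         call. = FALSE)
  }
  n <- sum(region_counts)
  n_motifs <- n %/% 2L
  pairs <- lapply(seq_len(n_motifs), function(k) c(2L * k - 1L, 2L * k))
  motifs <- vapply(pairs, motif_id, character(1))
  if (is.null(motif_probs)) motif_probs <- default_motif_probs(n_motifs)
  motif_probs <- as.matrix(motif_probs)
  if (nrow(motif_probs) != n_motifs || ncol(motif_probs) != 2) {
    stop("motif_probs must be an ", n_motifs, " x 2 matrix", call. = FALSE)
  }
  colnames(motif_probs) <- c("ASD", "TD")
  rownames(motif_probs) <- motifs
  if (any(motif_probs < 0 | motif_probs > 1)) {
    stop("inclusion probabilities must be in [0, 1]", call. = FALSE)
  }
  if (is.null(regional_shifts)) regional_shifts <- default_regional_shifts()
  structure(list(n_per_group = as.integer(n_per_group), trials = trials,
                 region_counts = region_counts, n_roi = n,
                 motif_pairs = pairs, motifs = motifs,
                 motif_probs = motif_probs,
                 within_motif = within_motif, within_region = within_region,
                 baseline = baseline, noise_sd = noise_sd,
                 red_noise_mult = red_noise_mult,
                 regional_shifts = regional_shifts),
            class = "dcg_design")
}

#' Default per-group motif inclusion probabilities
#'
#' Most pair motifs are common to both groups (inclusion 24/29).  Eight
#' motifs are ASD-enriched and eight TD-enriched (24/29 vs 4/29), giving an
#' expected prevalence gap of 20 — a strong, well-separated group signal.
#' The pair (87, 88), when present, gets inclusion 10/29 (ASD) vs 21/29
#' (TD), a moderate TD-leaning motif.
#'
#' @param n_motifs number of pair motifs.
#' @return `n_motifs x 2` probability matrix with columns `ASD`, `TD`.
#' @export
default_motif_probs <- function(n_motifs = 53L) {
  pr <- matrix(24 / 29, n_motifs, 2, dimnames = list(NULL, c("ASD", "TD")))
  asd_enriched <- c(3L, 9L, 12L, 20L, 28L, 35L, 41L, 46L)
  td_enriched <- c(7L, 16L, 18L, 24L, 31L, 40L, 49L, 52L)
  for (k in intersect(asd_enriched, seq_len(n_motifs))) pr[k, ] <- c(24, 4) / 29
  for (k in intersect(td_enriched, seq_len(n_motifs))) pr[k, ] <- c(4, 24) / 29
  if (n_motifs >= 44L) pr[44L, ] <- c(10, 21) / 29   # the (87, 88) pair
  pr
}

#' Default planted regional shifts
#'
#' Mild ASD-specific within-region correlation increases (Parietal and
#' Cingulum).  The default shifts strengthen blocks rather than weaken them
#' so that both groups keep the same recoverable 10-region geometry; a
#' geometry-altering shift (e.g. a strong between-region increase) can be
#' supplied explicitly when regional abnormality detection itself is under
#' study.
#'
#' @return Data frame with columns `region_a`, `region_b`, `group`, `delta`.
#' @export
default_regional_shifts <- function() {
  data.frame(region_a = c("Parietal", "Cingulum"),
             region_b = c(NA, NA),
             group = c("ASD", "ASD"),
             delta = c(0.08, 0.06))
}

#' Null-cohort design with no group differences
#'
#' Same geometry as [cohort_design()] but with identical motif inclusion
#' probabilities in both groups and no regional shifts; downstream
#' classification should be at chance level.
#'
#' @param ... passed to [cohort_design()].
#' @param inclusion common inclusion probability for all motifs.
#' @export
null_cohort_design <- function(..., inclusion = 24 / 29) {
  design <- cohort_design(...)
  design$motif_probs[] <- inclusion
  design$regional_shifts <- design$regional_shifts[0, , drop = FALSE]
  design
}

#' Simulate one subject-trial correlation matrix
#'
#' Builds the three-level block template (baseline, region blocks, included
#' motif blocks), applies the group's regional shifts, adds symmetric
#' Gaussian noise, clips to \[-1, 1\] and repairs the result to the nearest
#' valid correlation matrix by eigenvalue clipping, then returns it together
#' with the planted ground truth.
#'
#' @param design a [cohort_design()].
#' @param group `"ASD"` or `"TD"`.
#' @param trial trial label.
#' @param subject_index integer making each subject's random draw distinct.
#' @param seed master seed; the subject draw is seeded deterministically from
#'   `(seed, subject_index, trial)`.
#' @param included optional logical vector forcing motif inclusion.
#' @return List with `corr` (a [correlation_matrix()]) and `included`
#'   (canonical ids of the planted motifs).
#' @export
simulate_subject <- function(design, group, trial, subject_index, seed = 1L,
                             included = NULL) {
  stopifnot(inherits(design, "dcg_design"))
  group <- match.arg(group, c("ASD", "TD"))
  trial_idx <- match(trial, design$trials)
  if (is.na(trial_idx)) stop("unknown trial: ", trial, call. = FALSE)
  set.seed(derive_seed(seed, subject_index * length(design$trials) + trial_idx))
  n <- design$n_roi
  atlas_region <- rep(names(design$region_counts), design$region_counts)

  m <- matrix(design$baseline, n, n)
  for (r in unique(atlas_region)) {
    i <- which(atlas_region == r)
    m[i, i] <- design$within_region
  }
  if (is.null(included)) {
    included <- runif(length(design$motifs)) < design$motif_probs[, group]
  }
  for (k in which(included)) {
    i <- design$motif_pairs[[k]]
    m[i, i] <- design$within_motif
  }
  shifts <- design$regional_shifts
  if (nrow(shifts)) {
    for (j in seq_len(nrow(shifts))) {
      if (shifts$group[j] != group) next
      ia <- which(atlas_region == shifts$region_a[j])
      if (is.na(shifts$region_b[j])) {
        blk <- m[ia, ia]
        keep <- blk >= design$within_motif   # do not disturb motif blocks
        m[ia, ia] <- ifelse(keep, blk, blk + shifts$delta[j])
      } else {
        ib <- which(atlas_region == shifts$region_b[j])
        m[ia, ib] <- m[ia, ib] + shifts$delta[j]
        m[ib, ia] <- m[ib, ia] + shifts$delta[j]
      }
    }
  }
  sd_eff <- design$noise_sd * if (trial == "red") design$red_noise_mult else 1
  if (sd_eff > 0) {
    noise <- matrix(0, n, n)
    up <- upper.tri(noise)
    noise[up] <- rnorm(sum(up), sd = sd_eff)
    noise <- noise + t(noise)
    m <- m + noise
  }
  diag(m) <- 1
  m[m > 1] <- 1
  m[m < -1] <- -1
  m <- repair_correlation(m)
  dimnames(m) <- list(seq_len(n), seq_len(n))
  corr <- correlation_matrix(m, subject_id = paste0(group, "_", subject_index),
                             group = group, trial = trial)
  list(corr = corr, included = design$motifs[included])
}

# nearest-valid repair: clip negative eigenvalues at zero, renormalize to
# unit diagonal
repair_correlation <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) return((m + t(m)) / 2)
  v <- pmax(e$values, 0)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(m2), .Machine$double.eps))
  m2 <- m2 / tcrossprod(d)
  m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 1
  m2[m2 > 1] <- 1
  m2[m2 < -1] <- -1
  m2
}

#' Simulate a full cohort
#'
#' Generates `2 * n_per_group` subjects with one correlation matrix per trial
#' and records the planted ground truth (included motifs per subject-trial
#' and the region labels).
#'
#' @param design a [cohort_design()].
#' @param seed master seed; every subject-trial draw is derived from it.
#' @return An object of class `dcg_cohort`: list with `design`, `atlas`,
#'   `subjects` (data frame `subject_id`, `group`), `matrices`
#'   (`matrices[[subject_id]][[trial]]`) and `ground_truth` (data frame
#'   `subject_id`, `group`, `trial`, `motif`).
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1L) {
  groups <- c("ASD", "TD")
  subjects <- data.frame(
    subject_id = c(sprintf("ASD_%02d", seq_len(design$n_per_group)),
                   sprintf("TD_%02d", seq_len(design$n_per_group))),
    group = rep(groups, each = design$n_per_group))
  matrices <- list()
  gt <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    matrices[[sid]] <- list()
    for (trl in design$trials) {
      sim <- simulate_subject(design, subjects$group[i], trl,
                              subject_index = i, seed = seed)
      sim$corr$subject_id <- sid
      matrices[[sid]][[trl]] <- sim$corr
      if (length(sim$included)) {
        gt[[length(gt) + 1L]] <- data.frame(
          subject_id = sid, group = subjects$group[i], trial = trl,
          motif = sim$included)
      }
    }
  }
  structure(list(design = design, atlas = make_atlas(design$region_counts),
                 subjects = subjects, matrices = matrices,
                 ground_truth = do.call(rbind, gt), seed = as.integer(seed)),
            class = "dcg_cohort")
}

#' @export
print.dcg_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects x",
      length(x$design$trials), "trials,", x$design$n_roi, "ROIs\n")
  invisible(x)
}
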