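#' Fit a logistic regression with a ridge fallback under separation
#'
#' Maximum-likelihood logistic regression with intercept.  When the fit is
#' perfectly separated (or fails to converge), the model is refit with a
#' small ridge penalty on the standardized predictors, which keeps the
#' coefficients finite while preserving the separating direction.
#'
#' @param x numeric predictor matrix (no intercept column).
#' @param y binary response, 1 = ASD.
#' @param ridge ridge penalty used by the fallback.
#' @return An object of class `dcg_logit` with elements `coef` (intercept
#'   first) and `method` (`"mle"` or `"ridge"`).
#' @export
fit_logistic <- function(x, y, ridge = 1e-4) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  xa <- cbind(`(Intercept)` = 1, x)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(xa, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!isTRUE(fit$converged)) separated <- TRUE
  if (!separated) {
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0            # aliased / constant columns
    return(structure(list(coef = cf, method = "mle"), class = "dcg_logit"))
  }
  structure(list(coef = ridge_logistic(x, y, lambda = ridge), method = "ridge"),
            class = "dcg_logit")
}

# Newton-Raphson ridge logistic regression; penalty applies to standardized
# slopes, never the intercept.  Returns coefficients on the original scale.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 200L, tol = 1e-10) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  xa <- cbind(1, xs)
  p <- ncol(xa)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xa %*% beta)
    prob <- plogis(eta)
    w <- pmax(prob * (1 - prob), 1e-12)
    g <- drop(crossprod(xa, y - prob)) - pen %*% beta
    h <- crossprod(xa * w, xa) + pen
    delta <- solve(h, g)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  slope <- beta[-1] / s
  cf <- c(beta[1] - sum(beta[-1] * mu / s), slope)
  names(cf) <- c("(Intercept)", colnames(x))
  cf
}

#' @param object a `dcg_logit` fit.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @rdname fit_logistic
#' @export
predict.dcg_logit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cf <- object$coef
  plogis(drop(cbind(1, newdata[, names(cf)[-1], drop = FALSE]) %*% cf))
}

#' Leave-one-out cross-validated classification
#'
#' For every held-out subject, fits a logistic regression on the remaining
#' subjects' fine-scale predictors (optionally augmented with coarse
#' predictors) and predicts the held-out subject's probability of ASD
#' membership; subjects with predicted probability above 0.5 are classified
#' ASD.  In `"jackknife"` mode each subject's fine features are computed once
#' with itself excluded from its own group's domain; in `"per_fold"` mode all
#' domains are additionally rebuilt without the held-out subject in every
#' fold.
#'
#' @param cs a [cohort_configurations()] result.
#' @param tau prevalence threshold for the restricted domains.
#' @param trials trials entering the predictors.
#' @param coarse optional numeric matrix of additional predictors with
#'   rownames = subject ids (see [coarse_predictors()]).
#' @param mode feature-construction mode, `"jackknife"` or `"per_fold"`.
#' @param ridge ridge fallback penalty for separated folds.
#' @return An object of class `dcg_loocv`: list with `predictions` (data
#'   frame `subject_id`, `group`, `prob`, `predicted`), `sensitivity`,
#'   `specificity`, the integer numerators `se_correct`/`sp_correct` and
#'   group sizes `n_asd`/`n_td`, plus the settings used.
#' @export
loocv_classify <- function(cs, tau = 14L, trials = cs$trials, coarse = NULL,
                           mode = c("jackknife", "per_fold"), ridge = 1e-4) {
  mode <- match.arg(mode)
  subjects <- cs$subjects
  n <- nrow(subjects)
  if (n < 4 || length(unique(subjects$group)) != 2) {
    stop("two groups with at least 2 subjects each required", call. = FALSE)
  }
  y <- as.numeric(subjects$group == "ASD")
  build_x <- function(exclude = NULL) {
    f <- fine_features(cs, tau = tau, trials = trials, exclude = exclude)
    x <- fine_predictor_matrix(f, trials)
    if (!is.null(coarse)) {
      x <- cbind(x, as.matrix(coarse)[rownames(x), , drop = FALSE])
    }
    x
  }
  if (mode == "jackknife") x_all <- build_x()
  prob <- numeric(n)
  for (i in seq_len(n)) {
    x <- if (mode == "jackknife") x_all else build_x(exclude = subjects$subject_id[i])
    p_i <- tryCatch({
      fit <- fit_logistic(x[-i, , drop = FALSE], y[-i], ridge = ridge)
      predict(fit, x[i, , drop = FALSE])
    }, error = function(e) {
      warning("degenerate fold for ", subjects$subject_id[i], ": ",
              conditionMessage(e), "; recorded as misclassification",
              call. = FALSE)
      NA_real_
    })
    prob[i] <- p_i
  }
  predicted <- ifelse(is.na(prob), ifelse(y == 1, "TD", "ASD"),
                      ifelse(prob > 0.5, "ASD", "TD"))
  correct <- predicted == subjects$group
  n_asd <- sum(y == 1); n_td <- sum(y == 0)
  structure(list(
    predictions = data.frame(subject_id = subjects$subject_id,
                             group = subjects$group, prob = prob,
                             predicted = predicted),
    sensitivity = sum(correct[y == 1]) / n_asd,
    specificity = sum(correct[y == 0]) / n_td,
    se_correct = sum(correct[y == 1]), sp_correct = sum(correct[y == 0]),
    n_asd = n_asd, n_td = n_td,
    tau = tau, trials = trials, mode = mode),
    class = "dcg_loocv")
}

#' @export
print.dcg_loocv <- function(x, ...) {
  cat(sprintf("LOOCV logistic classification (tau = %d, trials: %s)\n",
              x$tau, paste(x$trials, collapse = "+")))
  cat(sprintf("  sensitivity %d/%d = %.3f\n", x$se_correct, x$n_asd, x$sensitivity))
  cat(sprintf("  specificity %d/%d = %.3f\n", x$sp_correct, x$n_td, x$specificity))
  invisible(x)
}

#' Sweep the prevalence threshold and trial modes
#'
#' Repeats [loocv_classify()] for every prevalence threshold and trial mode
#' and tabulates sensitivity and specificity with explicit denominators.
#'
#' @param cs a [cohort_configurations()] result.
#' @param taus integer thresholds to sweep.
#' @param modes trial modes among `"green"`, `"green+red"`, `"red"` (modes
#'   requiring an absent trial are skipped).
#' @param ... passed on to [loocv_classify()].
#' @return Data frame with one row per (tau, mode): `tau`, `mode`,
#'   `sensitivity`, `specificity`, `se_frac`, `sp_frac`.
#' @export
tau_sweep <- function(cs, taus = 2:22, modes = c("green", "green+red", "red"),
                      ...) {
  mode_trials <- list(green = "green", red = "red",
                      `green+red` = c("green", "red"))
  modes <- modes[vapply(modes, function(m) all(mode_trials[[m]] %in% cs$trials),
                        logical(1))]
  rows <- list()
  for (tau in taus) {
    for (m in modes) {
      r <- loocv_classify(cs, tau = tau, trials = mode_trials[[m]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, mode = m,
        sensitivity = r$sensitivity, specificity = r$specificity,
        se_frac = sprintf("%d/%d", r$se_correct, r$n_asd),
        sp_frac = sprintf("%d/%d", r$sp_correct, r$n_td))
    }
  }
  do.call(rbind, rows)
}

#' Coarse variable sets for the classifier
#'
#' Named subsets of the 55 retention features (with the trial each is read
#' from) used as coarse-scale predictor sets alongside or instead of the
#' fine-scale ones.  `coarse1` is the full screened set, `coarse2` and
#' `coarse3` smaller model-selected subsets.
#'
#' @return A named list of data frames with columns `feature`, `trial`.
#' @export
coarse_variable_sets <- function() {
  list(
    coarse1 = data.frame(
      feature = c("intra_Parietal", "inter_Cerebelum_Central",
                  "inter_Temporal_Limbic", "intra_Insular",
                  "inter_Subcortical_Occipital", "inter_Parietal_Limbic",
                  "inter_Occipital_Limbic", "inter_Subcortical_Frontal",
                  "inter_Parietal_Occipital", "intra_Occipital"),
      trial = c(rep("red", 7), rep("green", 3))),
    coarse2 = data.frame(
      feature = c("intra_Insular", "inter_Subcortical_Occipital",
                  "inter_Subcortical_Frontal", "intra_Occipital"),
      trial = c("red", "red", "green", "green")),
    coarse3 = data.frame(
      feature = c("inter_Parietal_Limbic", "inter_Subcortical_Frontal",
                  "inter_Parietal_Occipital", "intra_Occipital"),
      trial = c("red", "green", "green", "green")))
}

#' Build a coarse predictor matrix from per-subject-trial retention features
#'
#' @param features long data frame with columns `subject_id`, `trial` and
#'   retention feature columns (see [cohort_coarse_features()]).
#' @param set a data frame with columns `feature`, `trial` (one of
#'   [coarse_variable_sets()]), or the name of one of those sets.
#' @return Numeric matrix (subjects x selected features) with rownames =
#'   subject ids and columns named `<feature>.<trial>`.
#' @export
coarse_predictors <- function(features, set) {
  if (is.character(set)) set <- coarse_variable_sets()[[set]]
  sids <- unique(features$subject_id)
  x <- sapply(seq_len(nrow(set)), function(j) {
    sub <- features[features$trial == set$trial[j], , drop = FALSE]
    vals <- sub[[set$feature[j]]][match(sids, sub$subject_id)]
    if (anyNA(vals)) stop("missing coarse feature ", set$feature[j], " (",
                          set$trial[j], " trial) for some subjects", call. = FALSE)
    vals
  })
  x <- matrix(x, nrow = length(sids),
              dimnames = list(sids, paste(set$feature, set$trial, sep = ".")))
  x
}

#' Coarse retention features for a whole cohort
#'
#' Tunes every subject-trial geometry to `k_target` clusters and computes the
#' retention features against the cohort atlas.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param k_target target cluster count of the coarse level.
#' @param t_grid temperature grid for tuning.
#' @param params a [walk_params()].
#' @param trials trials to process.
#' @return Long data frame: `subject_id`, `group`, `trial`, `achieved_k`,
#'   then one column per retention feature.
#' @export
cohort_coarse_features <- function(cohort, k_target = 10L,
                                   t_grid = default_t_grid(),
                                   params = walk_params(), trials = NULL) {
  subjects <- cohort$subjects
  if (is.null(trials)) trials <- names(cohort$matrices[[1]])
  idx <- 0L
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    for (trl in trials) {
      idx <- idx + 1L
      p <- params
      p$seed <- derive_seed(params$seed + 7L, idx)
      level <- tune_to_count(cohort$matrices[[sid]][[trl]], k_target,
                             t_grid = t_grid, params = p)
      feats <- retention_features(level, cohort$atlas)
      rows[[idx]] <- cbind(
        data.frame(subject_id = sid, group = subjects$group[i], trial = trl,
                   achieved_k = level$k),
        as.data.frame(as.list(feats), check.names = FALSE))
    }
  }
  do.call(rbind, rows)
}
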