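# builders shared across the test files; all fixtures are generated in code

# block similarity/sharing matrix: `sizes` blocks with `within` inside and
# `cross` elsewhere, unit diagonal
block_matrix <- function(sizes, within = 1, cross = 0) {
  n <- sum(sizes)
  m <- matrix(cross, n, n)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  for (b in seq_along(sizes)) {
    i <- starts[b]:ends[b]
    m[i, i] <- within
  }
  diag(m) <- 1
  dimnames(m) <- list(seq_len(n), seq_len(n))
  m
}

block_labels <- function(sizes) rep(seq_along(sizes), sizes)

# small synthetic design: 3 regions, 7 pair motifs, 14 ROIs
mini_design <- function(n_per_group = 8L, trials = c("green", "red"), ...) {
  cohort_design(n_per_group = n_per_group, trials = trials,
                region_counts = c(A = 6L, B = 6L, C = 2L),
                regional_shifts = data.frame(region_a = character(),
                                             region_b = character(),
                                             group = character(),
                                             delta = numeric()),
                ...)
}

# configuration from explicit motif member lists
make_config <- function(motifs, subject_id = "s1", group = "ASD",
                        trial = "green") {
  dcgnet:::new_config(motifs, subject_id = subject_id, group = group,
                      trial = trial)
}

# domain with given named prevalence counts
make_domain <- function(prevalence, group = "ASD", trial = "green",
                        n_subjects = 29L) {
  structure(list(group = group, trial = trial, n_subjects = n_subjects,
                 prevalence = prevalence),
            class = "dcg_domain")
}

# all set partitions of 1..n as label vectors (for the Rand-index oracle)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (lab in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, lab)
    }
  }
  out
}

# brute-force Rand index over all element pairs
rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1L
      if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1L
    }
  }
  agree / total
}

# a deterministic abstract cohort of configurations for feature tests
abstract_config_set <- function(n_per_group = 6L, n_motifs = 10L,
                                p_asd = rep(0.8, n_motifs),
                                p_td = rep(0.8, n_motifs),
                                trials = c("green", "red"), seed = 1) {
  set.seed(seed)
  configs <- list()
  for (g in c("ASD", "TD")) {
    p <- if (g == "ASD") p_asd else p_td
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      for (trl in trials) {
        carried <- which(runif(n_motifs) < p)
        configs[[paste(sid, trl, sep = "|")]] <-
          make_config(lapply(carried, function(k) c(2 * k - 1, 2 * k)),
                      subject_id = sid, group = g, trial = trl)
      }
    }
  }
  config_set(configs)
}

# adjusted Rand index via the reference implementation
rand_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
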