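#' Default distribution of the 106 ROIs over 10 anatomical regions
#'
#' @return Named integer vector of ROI counts per region, in the canonical
#'   region order used for feature indexing throughout the package.
#' @export
default_region_counts <- function() {
  c(Subcortical = 10L, Parietal = 10L, Occipital = 14L, Cerebelum = 20L,
    Frontal = 22L, Temporal = 8L, Limbic = 8L, Insular = 2L, Central = 6L,
    Cingulum = 6L)
}

#' Build an ROI atlas table
#'
#' Assigns sequential integer ROI ids to regions in the given order and
#' attaches synthetic 3-D coordinates (mm): each region gets a fixed center
#' and its ROIs deterministic offsets, with consecutive odd/even ROI pairs
#' mirrored across the midline to emulate left/right homologues.  The
#' coordinates are artificial and serve only the edge-list export.
#'
#' @param counts named integer vector of ROIs per region.
#' @return A data frame of class `dcg_atlas` with columns `roi_id`,
#'   `roi_name`, `region`, `x`, `y`, `z`.  The region order of `counts` is
#'   preserved as the factor level order.
#' @export
make_atlas <- function(counts = default_region_counts()) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of region sizes", call. = FALSE)
  }
  counts <- as.integer(round(counts)) |> stats::setNames(names(counts))
  if (any(counts < 1)) stop("region counts must be positive", call. = FALSE)
  regions <- names(counts)
  n <- sum(counts)
  region <- factor(rep(regions, counts), levels = regions)
  roi_id <- seq_len(n)
  # fixed region centers on a rough head-sized layout (synthetic)
  k <- length(regions)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cx <- 45 * cos(ang)
  cy <- 55 * sin(ang)
  cz <- 20 * cos(2 * ang)
  within_idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  ri <- as.integer(region)
  # deterministic low-discrepancy offsets; even ids mirrored in x
  off <- cbind(((within_idx * 37L) %% 13L) - 6L,
               ((within_idx * 53L) %% 13L) - 6L,
               ((within_idx * 71L) %% 13L) - 6L) * 1.5
  x <- abs(cx[ri] + off[, 1]) * ifelse(roi_id %% 2 == 1, -1, 1)
  data.frame(roi_id = roi_id,
             roi_name = sprintf("%s_%02d", region, within_idx),
             region = region,
             x = round(x, 1),
             y = round(cy[ri] + off[, 2], 1),
             z = round(cz[ri] + off[, 3], 1)) |>
    structure(class = c("dcg_atlas", "data.frame"))
}

#' Read / write an atlas table
#'
#' The on-disk format is a TSV with columns `roi_id`, `roi_name`, `region`,
#' `x`, `y`, `z`; comment lines starting with `#` are ignored.  Region factor
#' levels follow first appearance.
#'
#' @param path file path.
#' @return [read_atlas()] returns a `dcg_atlas` data frame.
#' @export
read_atlas <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("roi_id", "roi_name", "region", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("atlas file lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df$region <- factor(df$region, levels = unique(df$region))
  structure(df[need], class = c("dcg_atlas", "data.frame"))
}

#' @param atlas a `dcg_atlas` data frame.
#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  write_dcg_tsv(as.data.frame(atlas), path, comments = c(type = "atlas"))
  invisible(path)
}

# canonical labels of the 55 coarse features: 10 intra then 45 inter, in the
# region order of the atlas
coarse_feature_names <- function(regions) {
  regions <- as.character(regions)
  intra <- paste0("intra_", regions)
  pairs <- combn(regions, 2)
  inter <- paste0("inter_", pairs[1, ], "_", pairs[2, ])
  c(intra, inter)
}
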