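# Per-cell measurement: background-subtracted total and per-pixel-mean
# fluorescence for both channels, an opening-spectrum granularity score on
# the transmitted-light channel, and the size-granularity morphology
# diagnostic with a gap-statistic unimodality check.

#' Measure retained cells on one tile
#'
#' For each retained singlet, computes background-subtracted total and
#' average-per-pixel fluorescence in both channels. The per-channel
#' background is the median over non-object pixels of the tile (all labelled
#' objects excluded, not only retained ones); per-pixel signal is
#' `max(raw - background, 0)`; totals are sums over the object's pixel set
#' and means are totals divided by area, so `mean * area == total` exactly.
#'
#' @param tile A `mito_tile`.
#' @param seg Result of [segment_tile()] (needs `retained` and `labels`).
#' @param granularity If `TRUE`, also compute [granularity_score()] per cell
#'   (slower; skippable when only fluorescence is needed).
#' @param granularity_max_radius Largest opening radius (px).
#' @return Data frame of cell records: `patient_id`, `tile_index`,
#'   `object_size_px`, `ppix_total`, `ppix_mean`, `mt_total`, `mt_mean`,
#'   plus `granularity` when requested.
#' @export
measure_cells <- function(tile, seg, granularity = FALSE,
                          granularity_max_radius = 8L) {
  stopifnot(inherits(tile, "mito_tile"))
  ret <- seg$retained
  labels <- seg$labels
  empty <- data.frame(patient_id = character(0), tile_index = integer(0),
                      object_size_px = numeric(0), ppix_total = numeric(0),
                      ppix_mean = numeric(0), mt_total = numeric(0),
                      mt_mean = numeric(0), stringsAsFactors = FALSE)
  if (granularity) empty$granularity <- numeric(0)
  if (is.null(ret) || nrow(ret) == 0L) return(empty)

  nlab <- max(labels)
  st_mt <- .channel_stats_cpp(tile$mt * 1.0, labels, nlab)
  st_ppix <- .channel_stats_cpp(tile$ppix * 1.0, labels, nlab)
  area <- ret$area_px
  if (any(area <= 0)) stop("empty pixel set in retained object")
  mt_total <- st_mt$sums[ret$label]
  ppix_total <- st_ppix$sums[ret$label]
  rec <- data.frame(patient_id = tile$subject_id, tile_index = tile$tile_index,
                    object_size_px = area, ppix_total = ppix_total,
                    ppix_mean = ppix_total / area, mt_total = mt_total,
                    mt_mean = mt_total / area, stringsAsFactors = FALSE)
  if (granularity) {
    bg_trans <- median(tile$trans[labels == 0L])
    rec$granularity <- vapply(ret$label, function(l)
      granularity_score(tile$trans, labels == l, background = bg_trans,
                        max_radius = granularity_max_radius)$score,
      numeric(1))
  }
  rownames(rec) <- NULL
  rec
}

#' Opening-spectrum granularity of one object
#'
#' A texture score in the CellProfiler granularity tradition. The
#' transmitted-light patch is contrast-inverted and background-subtracted
#' (`max(background - raw, 0)`, cells bright), then opened with disks of
#' radius `r = 1..max_radius`. With `I_r` the integrated within-object
#' signal after opening at radius `r` (`I_0` unopened), the spectrum is
#' `g_r = (I_{r-1} - I_r) / I_0` and the score is `sum(r * g_r)` — the mean
#' removal scale in pixels. Fine speckle scores near 1; a uniform convex
#' object of radius R scores near R + 1 (it survives openings up to its own
#' radius).
#'
#' @param trans Transmitted-light channel (matrix).
#' @param obj_mask Logical matrix, `TRUE` on the object's pixel set.
#' @param background Background level; default median of pixels outside
#'   `obj_mask`.
#' @param max_radius Largest opening radius G (px).
#' @return List: `score`, `spectrum` (g_1..g_G), `warn_zero` (TRUE when the
#'   object carried no inverted signal, score forced to 0).
#' @export
granularity_score <- function(trans, obj_mask, background = NULL,
                              max_radius = 8L) {
  stopifnot(is.matrix(trans), identical(dim(trans), dim(obj_mask)))
  if (is.null(background)) background <- median(trans[!obj_mask])
  idx <- which(obj_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty pixel set")
  pad <- max_radius + 1L
  ri <- max(1L, min(idx[, 1]) - pad):min(nrow(trans), max(idx[, 1]) + pad)
  ci <- max(1L, min(idx[, 2]) - pad):min(ncol(trans), max(idx[, 2]) + pad)
  inv <- pmax(background - trans[ri, ci, drop = FALSE], 0)
  sub_mask <- obj_mask[ri, ci, drop = FALSE]
  inv[!sub_mask & inv > 0] <- 0 # restrict signal support to the object
  i0 <- sum(inv[sub_mask])
  if (i0 <= 0)
    return(list(score = 0, spectrum = rep(0, max_radius), warn_zero = TRUE))
  prev <- i0
  g <- numeric(max_radius)
  for (r in seq_len(max_radius)) {
    opened <- .gray_morph_cpp(.gray_morph_cpp(inv, r, FALSE), r, TRUE)
    ir <- sum(opened[sub_mask])
    g[r] <- max(prev - ir, 0) / i0
    prev <- min(ir, prev)
  }
  list(score = sum(seq_len(max_radius) * g), spectrum = g, warn_zero = FALSE)
}

# Tibshirani gap statistic comparing k = 1 vs k = 2 on a 2-D point set,
# with a uniform reference over the bounding box.
gap_k1_vs_k2 <- function(xy, B = 50L, seed = 1L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2L) return(list(k = 1L, gap = c(NA, NA)))
  wk <- function(pts, k) {
    if (k == 1L) sum(scale(pts, scale = FALSE)^2)
    else {
      km <- kmeans(pts, centers = 2L, nstart = 10L)
      km$tot.withinss
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lw <- c(log(wk(xy, 1L) + 1e-12), log(wk(xy, 2L) + 1e-12))
  rng <- apply(xy, 2, range)
  ref <- matrix(0, B, 2)
  for (b in seq_len(B)) {
    sim <- cbind(runif(n, rng[1, 1], rng[2, 1]), runif(n, rng[1, 2], rng[2, 2]))
    ref[b, ] <- c(log(wk(sim, 1L) + 1e-12), log(wk(sim, 2L) + 1e-12))
  }
  gap <- colMeans(ref) - lw
  s <- apply(ref, 2, sd) * sqrt(1 + 1 / B)
  k <- if (gap[1] >= gap[2] - s[2]) 1L else 2L
  list(k = k, gap = gap, s = s)
}

#' Size-granularity morphology summary
#'
#' Returns the per-cell (size, granularity, mt_mean) triples used to assess
#' the morphological homogeneity of the culture, together with a
#' unimodality diagnostic: the gap statistic comparing a 1-cluster vs a
#' 2-cluster partition of the standardized (size, granularity) points. A
#' homogeneous culture prefers k = 1.
#'
#' @param records Cell records containing `object_size_px`, `granularity`
#'   and `mt_mean`.
#' @param B Reference draws for the gap statistic.
#' @return List: `table` (data frame size/granularity/mt_mean), `k_preferred`
#'   (1 or 2), `gap` (gap values for k = 1, 2).
#' @export
morphology_scatter <- function(records, B = 50L) {
  stopifnot(nrow(records) >= 1L)
  tab <- data.frame(size = records$object_size_px,
                    granularity = records$granularity,
                    mt_mean = records$mt_mean)
  if (nrow(tab) < 3L)
    return(list(table = tab, k_preferred = 1L, gap = c(NA, NA)))
  xy <- scale(cbind(tab$size, tab$granularity))
  if (any(!is.finite(xy))) xy[!is.finite(xy)] <- 0
  gp <- gap_k1_vs_k2(xy, B = B)
  list(table = tab, k_preferred = gp$k, gap = gp$gap)
}
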