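# Deterministic single-cell segmentation of the transmitted-light channel:
# edge detection (Gaussian gradient + Otsu) -> morphological cleanup ->
# connected components -> size-based classification into singlet / clump /
# debris with a triangular membership probability, then the retention
# filters (probability > 50%, not on the tile border).

#' Segmentation configuration
#'
#' @param gradient_smooth_sigma Gaussian smoothing sigma (px) applied before
#'   the gradient.
#' @param area_min_singlet,area_max_singlet Singlet area window (px^2):
#'   below = debris, above = clump. Defaults bracket monocyte footprints at
#'   ~0.44 um/px (about 58-580 um^2).
#' @param prob_threshold Strict lower bound on the singlet class probability
#'   for retention (default 0.5, i.e. "over 50%").
#' @param border_margin Pixels from the tile edge within which an object
#'   counts as border-touching (0 = the very edge row/column).
#' @param edge_trim_px Final erosion radius compensating the half-width of
#'   the detected edge band; `NULL` uses `round(1.5 * gradient_smooth_sigma)`.
#' @return A `seg_config` list.
#' @export
seg_config <- function(gradient_smooth_sigma = 1.0, area_min_singlet = 300,
                       area_max_singlet = 3000, prob_threshold = 0.5,
                       border_margin = 0L, edge_trim_px = NULL) {
  if (area_min_singlet <= 0 || area_min_singlet >= area_max_singlet)
    stop("need 0 < area_min_singlet < area_max_singlet")
  if (prob_threshold < 0 || prob_threshold >= 1)
    stop("prob_threshold must lie in [0, 1)")
  if (is.null(edge_trim_px))
    edge_trim_px <- max(0L, as.integer(round(1.5 * gradient_smooth_sigma)))
  structure(list(gradient_smooth_sigma = gradient_smooth_sigma,
                 area_min_singlet = area_min_singlet,
                 area_max_singlet = area_max_singlet,
                 prob_threshold = prob_threshold,
                 border_margin = as.integer(border_margin),
                 edge_trim_px = as.integer(edge_trim_px)),
            class = "seg_config")
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance over a 512-bin histogram of the sample
#' range. Used on gradient-magnitude images to separate edge pixels from
#' background.
#'
#' @param x Numeric vector or matrix.
#' @param n_bins Histogram resolution.
#' @return Threshold value (scalar); `NA` for (near-)constant input.
#' @export
otsu_threshold <- function(x, n_bins = 512L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-12 * max(abs(rng), 1))
    return(NA_real_)
  width <- diff(rng) / n_bins
  h <- tabulate(pmin(floor((v - rng[1]) / width) + 1L, n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Classify pixels into object and background by edge detection
#'
#' The chain is: Gaussian smoothing, discrete gradient magnitude, Otsu
#' threshold on the gradient image, morphological closing (disk radius 2),
#' hole filling, and a final erosion by `edge_trim_px` that shrinks the
#' filled region back from the outer flank of the detected edge band to the
#' true object boundary. A constant image yields an empty mask.
#'
#' @param trans Transmitted-light channel (matrix).
#' @param config A [seg_config()].
#' @return Logical matrix, `TRUE` = object.
#' @export
pixel_classify <- function(trans, config = seg_config()) {
  stopifnot(is.matrix(trans))
  .segment_mask_cpp(trans * 1.0, config$gradient_smooth_sigma, 2L,
                    config$edge_trim_px)
}

# triangular singlet membership: 1 at the window midpoint, 0.5 at the window
# edges, declining linearly outside (floored at 0.01 so probs stay positive)
singlet_membership <- function(area, amin, amax) {
  mid <- (amin + amax) / 2
  half <- (amax - amin) / 2
  pmax(1 - 0.5 * abs(area - mid) / half, 0.01)
}

#' Label and classify segmented objects
#'
#' Labels 8-connected components of the mask and classifies each by area:
#' debris below the singlet window, clump above it, singlet inside
#' (inclusive). Singlets get the triangular membership probability (1 at
#' the window midpoint, 0.5 at the edges); debris and clumps get 1.0.
#' Objects with any pixel within `border_margin` of the tile edge are
#' flagged border-touching.
#'
#' @param mask Logical matrix from [pixel_classify()].
#' @param config A [seg_config()].
#' @return A list with `objects` (data frame: `label`, `area_px`,
#'   `centroid_x`, `centroid_y` [0-based, x = column], `class`, `class_prob`,
#'   `touches_border`) and `labels` (integer label matrix).
#' @export
classify_objects <- function(mask, config = seg_config()) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mm <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  labels <- .label_components_cpp(mm, 8L)
  n <- max(labels)
  h <- nrow(mm); w <- ncol(mm)
  if (n == 0L)
    return(list(objects = data.frame(label = integer(0), area_px = numeric(0),
                                     centroid_x = numeric(0), centroid_y = numeric(0),
                                     class = character(0), class_prob = numeric(0),
                                     touches_border = logical(0),
                                     stringsAsFactors = FALSE),
                labels = labels))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  area <- tabulate(lab, n)
  cy <- rowsum(as.numeric(rows), lab)[, 1] / area - 1
  cx <- rowsum(as.numeric(cols), lab)[, 1] / area - 1
  m <- config$border_margin
  on_border <- rows <= (1L + m) | rows >= (h - m) | cols <= (1L + m) | cols >= (w - m)
  border <- as.logical(rowsum(as.numeric(on_border), lab)[, 1] > 0)
  cls <- ifelse(area < config$area_min_singlet, "debris",
                ifelse(area > config$area_max_singlet, "clump", "singlet"))
  prob <- ifelse(cls == "singlet",
                 singlet_membership(area, config$area_min_singlet,
                                    config$area_max_singlet), 1.0)
  list(objects = data.frame(label = seq_len(n), area_px = as.numeric(area),
                            centroid_x = cx, centroid_y = cy, class = cls,
                            class_prob = prob, touches_border = border,
                            stringsAsFactors = FALSE),
       labels = labels)
}

#' Retain analyzable singlets
#'
#' Keeps objects that are singlets with class probability strictly above
#' `prob_threshold` and that do not touch the tile border. Row order is
#' preserved; the filter is idempotent.
#'
#' @param objects Data frame from [classify_objects()] (the `objects`
#'   element).
#' @param config A [seg_config()].
#' @return The retained subset of `objects`.
#' @export
filter_singlets <- function(objects, config = seg_config()) {
  keep <- objects$class == "singlet" &
    objects$class_prob > config$prob_threshold &
    !objects$touches_border
  objects[keep, , drop = FALSE]
}

#' Segment one tile end to end
#'
#' Convenience wrapper: [pixel_classify()] on the transmitted-light channel,
#' [classify_objects()], and [filter_singlets()].
#'
#' @param tile A `mito_tile`.
#' @param config A [seg_config()].
#' @return List with `objects` (all classified objects), `retained`
#'   (filtered singlets) and `labels` (label matrix).
#' @export
segment_tile <- function(tile, config = seg_config()) {
  stopifnot(inherits(tile, "mito_tile"))
  mask <- pixel_classify(tile$trans, config)
  co <- classify_objects(mask, config)
  list(objects = co$objects, retained = filter_singlets(co$objects, config),
       labels = co$labels)
}
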