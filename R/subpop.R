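# Per-subject bimodal decomposition of per-cell MitoTracker intensity:
# Gaussian KDE on the log10 scale, valley detection between the two
# heaviest modes, and the MitoTracker-low proportion below the valley.

#' Kernel density estimate of per-cell intensities
#'
#' Gaussian-kernel density of `log10(x)` (or of `x` as given when
#' `log10 = FALSE`) on a 512-point grid spanning the data range plus three
#' bandwidths on each side. Bandwidth defaults to Silverman's rule of thumb.
#'
#' @param x Per-cell intensities (positive when `log10 = TRUE`).
#' @param bandwidth `"silverman"` or a positive number (in grid units).
#' @param n_grid Grid resolution.
#' @param log10 Transform to log10 before estimation (default).
#' @param min_cells Minimum cell count; fewer cells returns a flagged
#'   `NULL`-curve (`attr(.,"too_few") = TRUE` on an empty result).
#' @return A `kde_curve`: list with `grid`, `density`, `bandwidth`, `n`;
#'   or `NULL` with a warning when `length(x) < min_cells`.
#' @export
intensity_kde <- function(x, bandwidth = "silverman", n_grid = 512L,
                          log10 = TRUE, min_cells = 50L) {
  x <- x[is.finite(x)]
  if (length(x) < min_cells) {
    warning(sprintf("only %d cells (< %d): no density estimated",
                    length(x), min_cells))
    return(NULL)
  }
  y <- if (log10) {
    if (any(x <= 0)) stop("intensities must be positive for the log scale")
    log10(x)
  } else x
  bw <- if (identical(bandwidth, "silverman")) bw.nrd0(y) else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) bw <- max(diff(range(y)) / 100, 1e-6)
  d <- density(y, bw = bw, kernel = "gaussian", n = n_grid,
               from = min(y) - 3 * bw, to = max(y) + 3 * bw)
  structure(list(grid = d$x, density = d$y, bandwidth = bw, n = length(y)),
            class = "kde_curve")
}

#' Locate the valley between the two major modes of a density curve
#'
#' Modes are interior local maxima whose density exceeds 5% of the global
#' maximum. Each mode's mass is the trapezoidal integral over its basin
#' (bounded by the adjacent local minima). When at least two modes exist,
#' the two with the largest mass are selected and the threshold is the grid
#' point of minimum density strictly between their locations; otherwise the
#' curve is unimodal and no threshold is returned.
#'
#' @param curve A `kde_curve` from [intensity_kde()].
#' @param min_mode_frac Mode prominence floor, as a fraction of the maximum
#'   density.
#' @return List: `threshold` (grid value or `NA`), `modes` (locations of
#'   all qualifying modes), `bimodal` (logical), `mode_mass` (per mode).
#' @export
find_valley <- function(curve, min_mode_frac = 0.05) {
  stopifnot(inherits(curve, "kde_curve"))
  d <- curve$density; g <- curve$grid
  n <- length(d)
  # interior local maxima (strict on the left, non-strict right handles
  # flat-topped numerical plateaus deterministically)
  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n], FALSE)
  peaks <- which(is_max & d >= min_mode_frac * max(d))
  # collapse plateau runs to their first grid point
  if (length(peaks) > 1L) peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  # merge peaks whose separating valley barely dips (numerical tail
  # wiggles of the KDE): the dip must exceed 2% of the global maximum
  while (length(peaks) > 1L) {
    dip <- vapply(seq_len(length(peaks) - 1L), function(i)
      min(d[min(peaks[i], peaks[i + 1L]):max(peaks[i], peaks[i + 1L])]),
      numeric(1))
    shallow <- which(pmin(d[peaks[-length(peaks)]], d[peaks[-1L]]) - dip <
                       0.02 * max(d))
    if (!length(shallow)) break
    i <- shallow[1L]
    drop <- if (d[peaks[i]] < d[peaks[i + 1L]]) i else i + 1L
    peaks <- peaks[-drop]
  }
  if (length(peaks) < 2L)
    return(list(threshold = NA_real_,
                modes = if (length(peaks)) g[peaks] else numeric(0),
                bimodal = FALSE, mode_mass = if (length(peaks)) 1 else numeric(0)))
  # basin boundaries: minimum-density point between consecutive peaks
  cuts <- vapply(seq_len(length(peaks) - 1L), function(i) {
    lo <- peaks[i]; hi <- peaks[i + 1L]
    lo + which.min(d[(lo + 1L):(hi - 1L)])
  }, integer(1))
  bounds <- c(1L, cuts, n)
  trapz <- function(i1, i2)
    sum(diff(g[i1:i2]) * (d[i1:i2][-1] + d[i1:i2][-(i2 - i1 + 1L)]) / 2)
  mass <- vapply(seq_along(peaks), function(i)
    trapz(bounds[i], bounds[i + 1L]), numeric(1))
  top2 <- sort(peaks[order(mass, decreasing = TRUE)[1:2]])
  between <- (top2[1] + 1L):(top2[2] - 1L)
  thr <- g[between[which.min(d[between])]]
  list(threshold = thr, modes = g[peaks], bimodal = TRUE, mode_mass = mass)
}

#' Proportion of MitoTracker-low cells
#'
#' Fraction of cells whose log10 intensity lies strictly below the valley
#' threshold. Cells exactly at the threshold count as high.
#'
#' @param x Per-cell intensities (positive).
#' @param threshold Valley threshold on the log10 scale.
#' @param log10 Interpret `x` on the linear scale and transform (default);
#'   set `FALSE` when `x` is already on the threshold's scale.
#' @return Proportion in `[0, 1]`.
#' @export
proportion_low <- function(x, threshold, log10 = TRUE) {
  if (is.na(threshold)) stop("threshold undefined")
  y <- if (log10) base::log10(x) else x
  mean(y < threshold)
}

#' Per-subject subpopulation decomposition of a cell table
#'
#' Runs [intensity_kde()], [find_valley()] and [proportion_low()] for every
#' subject in a cell table. Subjects whose own curve is unimodal (or that
#' have too few cells for a curve) fall back to the valley of the pooled
#' all-cohort density and are flagged; a subject can never abort the cohort.
#'
#' @param cells Cell records with `patient_id` and the chosen intensity
#'   column.
#' @param intensity `"mean"` (per-pixel average, default — removes the cell
#'   size confound) or `"total"` (integrated).
#' @param bandwidth,min_cells Passed to [intensity_kde()].
#' @return Data frame: `patient_id`, `n_cells`, `threshold_log10`,
#'   `prop_low`, `bimodal`, `fallback`.
#' @export
subpop_pipeline <- function(cells, intensity = c("mean", "total"),
                            bandwidth = "silverman", min_cells = 50L) {
  intensity <- match.arg(intensity)
  col <- if (intensity == "mean") "mt_mean" else "mt_total"
  empty <- data.frame(patient_id = character(0), n_cells = integer(0),
                      threshold_log10 = numeric(0), prop_low = numeric(0),
                      bimodal = logical(0), fallback = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(cells) || nrow(cells) == 0L) return(empty)
  vals <- cells[[col]]
  keep <- is.finite(vals) & vals > 0
  cells <- cells[keep, , drop = FALSE]
  vals <- vals[keep]
  if (!nrow(cells)) return(empty)

  pooled_thr <- NA_real_
  pooled_curve <- suppressWarnings(
    intensity_kde(vals, bandwidth = bandwidth, min_cells = 2L))
  if (!is.null(pooled_curve)) {
    pv <- find_valley(pooled_curve)
    if (pv$bimodal) pooled_thr <- pv$threshold
  }

  ids <- unique(cells$patient_id)
  rows <- lapply(ids, function(id) {
    x <- vals[cells$patient_id == id]
    curve <- suppressWarnings(
      intensity_kde(x, bandwidth = bandwidth, min_cells = min_cells))
    thr <- NA_real_; bimodal <- FALSE; fallback <- FALSE
    if (!is.null(curve)) {
      v <- find_valley(curve)
      bimodal <- v$bimodal
      if (v$bimodal) thr <- v$threshold
    }
    if (is.na(thr) && !is.na(pooled_thr)) { thr <- pooled_thr; fallback <- TRUE }
    data.frame(patient_id = id, n_cells = length(x), threshold_log10 = thr,
               prop_low = if (is.na(thr)) NA_real_ else proportion_low(x, thr),
               bimodal = bimodal, fallback = fallback, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
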