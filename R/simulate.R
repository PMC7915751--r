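# Synthetic tile and cohort generator with ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: fields of view of a primary monocyte culture imaged as
# three-channel 16-bit tiles; a bimodal per-cell MitoTracker intensity
# mixture within each subject; a bimodal across-subject distribution of
# MitoTracker-low proportions; and a negative linear dependence of
# LPS-induced TNF secretion on that proportion.

#' Scene specification for tile rendering
#'
#' Geometry, object mix and noise model of one synthetic field of view.
#' Defaults give a 512 px tile at 0.4395 um/px, i.e. a 225 x 225 um^2 field,
#' populated densely enough that a 27-tile scan yields well over 600
#' retained single cells.
#'
#' @param tile_px Tile edge length in pixels.
#' @param um_per_px Physical scale (um/pixel).
#' @param cells_per_tile_mean Expected object count per tile (Poisson).
#' @param frac_clump,frac_debris Fraction of objects rendered as multi-cell
#'   aggregates / small fragments; the remainder are singlets.
#' @param radius_log_mean,radius_log_sd Natural-log-normal singlet radius
#'   parameters, in micrometres.
#' @param noise_read_sd Gaussian read-noise SD (counts); 0 disables.
#' @param photon_scale Poisson shot-noise scaling: counts are drawn as
#'   `Poisson(photon_scale * signal) / photon_scale`; `Inf` disables shot
#'   noise.
#' @param texture_speckle_sd Within-cell multiplicative speckle SD
#'   (fraction of the per-cell level).
#' @param texture_scale_px Correlation scale of the speckle field
#'   (Gaussian smoothing sigma, px); 0 = independent per pixel.
#' @param trans_background Transmitted-light background level (counts).
#' @param fluor_background Fluorescence-channel background level (counts).
#' @param seed Base RNG seed for the scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(tile_px = 512L, um_per_px = 0.4395,
                       cells_per_tile_mean = 35, frac_clump = 0.08,
                       frac_debris = 0.12, radius_log_mean = log(7),
                       radius_log_sd = 0.18, noise_read_sd = 50,
                       photon_scale = 0.5, texture_speckle_sd = 0.10,
                       texture_scale_px = 1, trans_background = 30000,
                       fluor_background = 50, seed = 1L) {
  s <- list(tile_px = as.integer(tile_px), um_per_px = um_per_px,
            cells_per_tile_mean = cells_per_tile_mean,
            frac_clump = frac_clump, frac_debris = frac_debris,
            radius_log_mean = radius_log_mean, radius_log_sd = radius_log_sd,
            noise_read_sd = noise_read_sd, photon_scale = photon_scale,
            texture_speckle_sd = texture_speckle_sd,
            texture_scale_px = texture_scale_px,
            trans_background = trans_background,
            fluor_background = fluor_background, seed = as.integer(seed))
  if (s$tile_px <= 0 || s$um_per_px <= 0) stop("tile geometry must be positive")
  if (s$frac_clump < 0 || s$frac_debris < 0 || s$frac_clump + s$frac_debris >= 1)
    stop("frac_clump + frac_debris must be < 1 and both nonnegative")
  if (s$radius_log_sd <= 0 || s$noise_read_sd < 0 || s$photon_scale <= 0)
    stop("scale parameters must be positive")
  class(s) <- "scene_spec"
  s
}

#' Subject specification
#'
#' Per-subject truth for tile rendering: the true MitoTracker-low fraction
#' and the log-normal per-cell intensity components. Intensity parameters
#' are log10 of the mean per-pixel fluorescence (counts). Defaults place the
#' low and high components 1.2 log-decades apart, matching a clearly bimodal
#' per-cell distribution.
#'
#' @param subject_id Identifier (character).
#' @param group Study group: 0 young healthy, 1 older healthy, 2
#'   atherosclerosis.
#' @param n_tiles Number of tiles in the subject's scan (protocol floor 27).
#' @param pi_low True MitoTracker-low cell fraction in `[0, 1]`.
#' @param mt_low_log_mean,mt_high_log_mean,mt_log_sd log10 intensity
#'   component parameters; the low mean must be below the high mean.
#' @param ppix_log_mean,ppix_log_sd log10 PpIX intensity parameters (all
#'   intact cells are PpIX positive).
#' @param fccp_mode If `TRUE`, emulates ablated membrane potential: every
#'   cell draws from the low component, attenuated further by `fccp_atten`.
#' @param fccp_atten Multiplicative attenuation applied in `fccp_mode`.
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(subject_id = "S1", group = 2L, n_tiles = 27L,
                         pi_low = 0.3, mt_low_log_mean = 2.0,
                         mt_high_log_mean = 3.2, mt_log_sd = 0.2,
                         ppix_log_mean = 2.7, ppix_log_sd = 0.2,
                         fccp_mode = FALSE, fccp_atten = 0.3) {
  s <- list(subject_id = as.character(subject_id), group = as.integer(group),
            n_tiles = as.integer(n_tiles), pi_low = pi_low,
            mt_low_log_mean = mt_low_log_mean,
            mt_high_log_mean = mt_high_log_mean, mt_log_sd = mt_log_sd,
            ppix_log_mean = ppix_log_mean, ppix_log_sd = ppix_log_sd,
            fccp_mode = isTRUE(fccp_mode), fccp_atten = fccp_atten)
  if (s$pi_low < 0 || s$pi_low > 1) stop("pi_low must lie in [0, 1]")
  if (s$mt_low_log_mean >= s$mt_high_log_mean)
    stop("mt_low_log_mean must be below mt_high_log_mean")
  if (s$n_tiles < 1) stop("n_tiles must be >= 1")
  class(s) <- "subject_spec"
  s
}

#' Cohort specification
#'
#' Across-subject generative model: a two-component Beta mixture for the
#' MitoTracker-low proportion, a linear (negative) effect of that proportion
#' on LPS-induced TNF secretion, basal TNF independent of the proportion,
#' and a plaque-score elevation for subjects drawn from the high-proportion
#' mixture component. Default group sizes are 5 young donors, 7 older
#' healthy donors and 23 atherosclerosis patients (35 subjects).
#'
#' @param n_young,n_old_healthy,n_athero Group sizes (groups 0, 1, 2).
#' @param pi_mix Two-component Beta mixture for `pi_low`: a list with
#'   weights `w` (sums to 1) and shape vectors `shape1`, `shape2`. Component
#'   2 is the high-proportion component.
#' @param beta_tnf Linear effect of `pi_low` on LPS-induced TNF
#'   (pg/mL per unit proportion; negative by default).
#' @param tnf_lps_intercept Expected LPS-induced TNF at `pi_low = 0` (pg/mL).
#' @param tnf_basal_mean,tnf_basal_sd Basal TNF distribution (pg/mL).
#' @param tnf_noise_sd Residual SD of LPS-induced TNF (pg/mL).
#' @param plaque_effect Added expected plaque score for high-component
#'   subjects.
#' @param tnf_floor Lower truncation for generated TNF values (pg/mL).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_young = 5L, n_old_healthy = 7L, n_athero = 23L,
                        pi_mix = list(w = c(0.6, 0.4),
                                      shape1 = c(6, 13.5),
                                      shape2 = c(34, 16.5)),
                        beta_tnf = -3300, tnf_lps_intercept = 3650,
                        tnf_basal_mean = 850, tnf_basal_sd = 500,
                        tnf_noise_sd = 1000, plaque_effect = 0.6,
                        tnf_floor = 50, seed = 1L) {
  s <- list(n_young = as.integer(n_young),
            n_old_healthy = as.integer(n_old_healthy),
            n_athero = as.integer(n_athero), pi_mix = pi_mix,
            beta_tnf = beta_tnf, tnf_lps_intercept = tnf_lps_intercept,
            tnf_basal_mean = tnf_basal_mean, tnf_basal_sd = tnf_basal_sd,
            tnf_noise_sd = tnf_noise_sd, plaque_effect = plaque_effect,
            tnf_floor = tnf_floor, seed = as.integer(seed))
  if (s$n_young < 0 || s$n_old_healthy < 0 || s$n_athero < 0)
    stop("group sizes must be nonnegative")
  if (abs(sum(pi_mix$w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  s$degenerate_mixture <- isTRUE(all.equal(pi_mix$shape1[1], pi_mix$shape1[2])) &&
    isTRUE(all.equal(pi_mix$shape2[1], pi_mix$shape2[2]))
  class(s) <- "cohort_spec"
  s
}

# Deterministic RNG substream key for (seed, subject_id, tile_index); keeps
# tile rendering reproducible independent of generation order.
tile_stream_seed <- function(seed, subject_id, tile_index) {
  sid <- sum(utf8ToInt(as.character(subject_id)) *
               (seq_along(utf8ToInt(as.character(subject_id))) %% 7 + 1))
  ((as.numeric(seed) * 1000003 + sid * 8191 + as.numeric(tile_index) * 127) %%
      2147483629) + 1
}

# Smoothed multiplicative speckle field over a patch, mean ~ 1, clipped > 0.
speckle_field <- function(h, w, sd, scale_px) {
  if (sd <= 0) return(matrix(1, h, w))
  z <- matrix(rnorm(h * w), h, w)
  if (scale_px > 0) {
    z <- .gaussian_blur_cpp(z, scale_px)
    z <- z / sqrt(mean(z^2))  # restore unit variance after smoothing
  }
  pmax(1 + sd * z, 0.05)
}

# Rasterize a disk onto bounding-box indices; returns matrix row/col indices
# within the tile and squared distance from the centre (px^2).
disk_pixels <- function(cx, cy, r, tile_px) {
  # cx = column, cy = row, 1-based centre coordinates
  ci <- as.integer(max(1, floor(cy - r))):as.integer(min(tile_px, ceiling(cy + r)))
  cj <- as.integer(max(1, floor(cx - r))):as.integer(min(tile_px, ceiling(cx + r)))
  if (!length(ci) || !length(cj)) return(NULL)
  d2 <- outer((ci - cy)^2, (cj - cx)^2, "+")
  keep <- d2 <= r^2
  if (!any(keep)) return(NULL)
  list(rows = rep(ci, times = length(cj))[keep],
       cols = rep(cj, each = length(ci))[keep],
       d2 = d2[keep])
}

#' Render one synthetic tile
#'
#' Draws objects (singlets, clumps, debris), places them without
#' singlet-singlet contact, rasterizes the three channels and applies
#' Poisson-Gaussian detector noise. The transmitted-light channel shows each
#' object as a slightly darkened disk with a dark rim on a bright background
#' so that edge detection has contrast to work with; fluorescence channels
#' carry per-cell levels drawn from the subject's low/high MitoTracker
#' mixture and the PpIX component.
#'
#' @param scene A [scene_spec()].
#' @param subject A [subject_spec()].
#' @param tile_index Zero-based tile index (selects the RNG substream).
#' @return A list with elements `tile` (a `mito_tile`) and `truth`
#'   (data frame, one row per rendered object: class, centre, radius,
#'   subpopulation label for singlets, drawn per-pixel levels, noiseless
#'   integrated intensities, rasterized area and border flag).
#' @export
render_tile <- function(scene, subject, tile_index = 0L) {
  stopifnot(inherits(scene, "scene_spec"), inherits(subject, "subject_spec"))
  if (tile_index < 0) stop("tile_index must be >= 0")
  n_px <- as.numeric(scene$tile_px)^2
  mean_r_px <- exp(scene$radius_log_mean + scene$radius_log_sd^2 / 2) /
    scene$um_per_px
  exp_area <- scene$cells_per_tile_mean * pi * mean_r_px^2 * 1.6 # clump margin
  if (exp_area > 0.4 * n_px)
    stop("expected object area exceeds 40% of the tile; placement would fail")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tile_stream_seed(scene$seed, subject$subject_id, tile_index))

  tp <- scene$tile_px
  trans <- matrix(scene$trans_background, tp, tp)
  mt <- matrix(scene$fluor_background, tp, tp)
  ppix <- matrix(scene$fluor_background, tp, tp)
  mt_noiseless <- matrix(0, tp, tp)   # signal only, for conservation checks

  n_obj <- rpois(1L, scene$cells_per_tile_mean)
  tr_cols <- list(class = character(0), cx = numeric(0), cy = numeric(0),
                  radius_px = numeric(0), subpop = character(0),
                  mt_level = numeric(0), ppix_level = numeric(0),
                  mt_integrated = numeric(0), ppix_integrated = numeric(0),
                  area_px = integer(0), touches_border = logical(0))
  add_truth <- function(...) {
    v <- list(...)
    for (nm in names(v)) tr_cols[[nm]][[length(tr_cols[[nm]]) + 1L]] <<- v[[nm]]
  }
  placed <- matrix(numeric(0), ncol = 3) # cx, cy, r (exclusion radius)

  if (n_obj > 0) for (k in seq_len(n_obj)) {
    u <- runif(1L)
    cls <- if (u < scene$frac_clump) "clump"
           else if (u < scene$frac_clump + scene$frac_debris) "debris"
           else "singlet"
    r_um <- exp(rnorm(1L, scene$radius_log_mean, scene$radius_log_sd))
    r_px <- switch(cls,
      singlet = r_um / scene$um_per_px,
      # constituents of aggregates drawn larger and with less spread so the
      # rendered union area reliably exceeds the singlet window
      clump   = 1.6 * exp(rnorm(1L, scene$radius_log_mean,
                                scene$radius_log_sd / 2)) / scene$um_per_px,
      debris  = exp(rnorm(1L, log(2), 0.25)) / scene$um_per_px)
    n_sub <- if (cls == "clump") sample(2:4, 1L) else 1L
    # constituents sit up to 1.6 radii from the clump centre
    excl <- if (cls == "clump") r_px * 2.7 else r_px

    ok <- FALSE
    for (try in 1:40) {
      cx <- runif(1L, 1, tp); cy <- runif(1L, 1, tp)
      if (nrow(placed) == 0L ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + excl + 8)) { ok <- TRUE; break }
    }
    if (!ok) next
    placed <- rbind(placed, c(cx, cy, excl))

    # per-cell fluorescence levels
    low <- if (subject$fccp_mode) TRUE
           else if (cls == "singlet") runif(1L) < subject$pi_low
           else runif(1L) < subject$pi_low
    mt_mu <- if (low) subject$mt_low_log_mean else subject$mt_high_log_mean
    mt_level <- 10^rnorm(1L, mt_mu, subject$mt_log_sd)
    if (subject$fccp_mode) mt_level <- mt_level * subject$fccp_atten
    ppix_level <- if (cls == "debris") 0
                  else 10^rnorm(1L, subject$ppix_log_mean, subject$ppix_log_sd)
    if (cls == "debris") mt_level <- mt_level * 0.2

    # constituent disks
    centres <- cbind(cx, cy)
    if (cls == "clump" && n_sub > 1L) {
      ang <- runif(n_sub - 1L, 0, 2 * pi)
      dd <- runif(n_sub - 1L, 1.2, 1.6) * r_px
      centres <- rbind(centres, cbind(cx + dd * cos(ang), cy + dd * sin(ang)))
    }

    pix_lin <- integer(0)
    rim_lin <- integer(0)
    rim2 <- (max(r_px - 2, 0))^2
    for (s in seq_len(nrow(centres))) {
      dp <- disk_pixels(centres[s, 1], centres[s, 2], r_px, tp)
      if (is.null(dp)) next
      lin <- (dp$cols - 1L) * tp + dp$rows
      if (s == 1L && nrow(centres) == 1L) {
        pix_lin <- lin
        rim_lin <- lin[dp$d2 > rim2]
      } else {
        pix_lin <- union(pix_lin, lin)
        rim_lin <- union(rim_lin, lin[dp$d2 > rim2])
      }
    }
    if (!length(pix_lin)) next
    interior <- setdiff(pix_lin, rim_lin)

    spk <- pmax(1 + scene$texture_speckle_sd * rnorm(length(pix_lin)), 0.05)
    if (scene$texture_scale_px > 1) {
      # correlated speckle: draw on the bounding box and smooth
      rows <- ((pix_lin - 1L) %% tp) + 1L
      cols <- ((pix_lin - 1L) %/% tp) + 1L
      bb_r <- range(rows); bb_c <- range(cols)
      fld <- speckle_field(diff(bb_r) + 1L, diff(bb_c) + 1L,
                           scene$texture_speckle_sd, scene$texture_scale_px)
      spk <- fld[cbind(rows - bb_r[1] + 1L, cols - bb_c[1] + 1L)]
    }

    mt_sig <- mt_level * spk
    ppix_sig <- ppix_level * spk
    mt[pix_lin] <- mt[pix_lin] + mt_sig
    mt_noiseless[pix_lin] <- mt_noiseless[pix_lin] + mt_sig
    ppix[pix_lin] <- ppix[pix_lin] + ppix_sig
    # transmitted light: darken interior mildly, rim strongly (edge contrast)
    tr_spk <- if (cls == "debris") rep(1, length(pix_lin)) else spk
    if (length(interior))
      trans[interior] <- pmin(trans[interior],
                              0.9 * scene$trans_background * tr_spk[match(interior, pix_lin)])
    if (length(rim_lin))
      trans[rim_lin] <- pmin(trans[rim_lin], 0.5 * scene$trans_background)

    r_eff <- if (cls == "clump") excl else r_px
    add_truth(
      class = cls,
      cx = cx - 1, cy = cy - 1,           # 0-based, x = column
      radius_px = r_px,
      subpop = if (cls == "singlet") (if (low) "low" else "high") else NA_character_,
      mt_level = mt_level, ppix_level = ppix_level,
      mt_integrated = sum(mt_sig), ppix_integrated = sum(ppix_sig),
      area_px = length(pix_lin),
      # the edge-detection band extends ~3 px beyond the disk, so objects
      # that close to the tile edge will be border-flagged after masking
      touches_border = (cx - r_eff) <= 5 || (cy - r_eff) <= 5 ||
        (cx + r_eff) >= tp - 4 || (cy + r_eff) >= tp - 4)
  }

  noisify <- function(img)
    .render_noise_cpp(img, scene$photon_scale, scene$noise_read_sd)

  tile <- new_tile(mt = noisify(mt), ppix = noisify(ppix),
                   trans = noisify(trans), subject_id = subject$subject_id,
                   tile_index = tile_index, um_per_px = scene$um_per_px)
  truth_df <- data.frame(obj_id = seq_along(tr_cols$class), tr_cols,
                         stringsAsFactors = FALSE)
  attr(tile, "mt_noiseless") <- mt_noiseless
  list(tile = tile, truth = truth_df)
}

#' Render all tiles for one subject
#'
#' Renders `subject$n_tiles` tiles using disjoint RNG substreams keyed by
#' `(scene$seed, subject_id, tile_index)`, so the output is bit-reproducible
#' and independent of rendering order.
#'
#' @inheritParams render_tile
#' @return List of `render_tile()` results, one per tile.
#' @export
render_subject <- function(scene, subject) {
  stopifnot(inherits(subject, "subject_spec"))
  lapply(seq_len(subject$n_tiles) - 1L,
         function(t) render_tile(scene, subject, t))
}

#' Draw per-cell MitoTracker intensities from a subject's mixture
#'
#' Samples `n` per-cell mean intensities (counts) from the subject's
#' two-component log-normal mixture, bypassing image formation. Used for
#' statistical validation of the thresholding stage at known ground truth.
#'
#' @param subject A [subject_spec()].
#' @param n Number of cells.
#' @return Numeric vector of intensities with attribute `"label"`
#'   (`"low"`/`"high"`).
#' @export
simulate_cell_intensities <- function(subject, n) {
  stopifnot(inherits(subject, "subject_spec"), n >= 1)
  low <- if (subject$fccp_mode) rep(TRUE, n) else runif(n) < subject$pi_low
  mu <- ifelse(low, subject$mt_low_log_mean, subject$mt_high_log_mean)
  x <- 10^rnorm(n, mu, subject$mt_log_sd)
  if (subject$fccp_mode) x <- x * subject$fccp_atten
  attr(x, "label") <- ifelse(low, "low", "high")
  x
}

#' Generate a synthetic cohort
#'
#' Draws per-subject true MitoTracker-low proportions from the two-component
#' Beta mixture and builds the covariate table: group label, IMT, plaque
#' score, basal TNF (independent of the proportion) and LPS-induced TNF with
#' the planted linear dependence on the proportion.
#'
#' @param cohort A [cohort_spec()].
#' @param n_tiles Tiles per subject passed into each [subject_spec()].
#' @return A list with `subjects` (list of `subject_spec`) and `covariates`
#'   (data frame: `subject_id`, `group`, `imt`, `plaque_score`, `tnf_basal`,
#'   `tnf_lps`, `pi_low_true`, `component`).
#' @export
generate_cohort <- function(cohort, n_tiles = 27L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cohort$seed)

  n <- cohort$n_young + cohort$n_old_healthy + cohort$n_athero
  if (n < 1) stop("empty cohort")
  group <- rep(c(0L, 1L, 2L),
               times = c(cohort$n_young, cohort$n_old_healthy, cohort$n_athero))
  ids <- sprintf("%02d", seq_len(n))

  comp <- 1L + rbinom(n, 1L, cohort$pi_mix$w[2])
  pi_low <- rbeta(n, cohort$pi_mix$shape1[comp], cohort$pi_mix$shape2[comp])

  tnf_basal <- pmax(rnorm(n, cohort$tnf_basal_mean, cohort$tnf_basal_sd),
                    cohort$tnf_floor)
  tnf_lps <- pmax(cohort$tnf_lps_intercept + cohort$beta_tnf * pi_low +
                    rnorm(n, 0, cohort$tnf_noise_sd), cohort$tnf_floor)

  imt_mu <- c(`0` = 0.61, `1` = 0.71, `2` = 0.84)[as.character(group)]
  imt <- pmax(rnorm(n, imt_mu, 0.08), 0.4)
  plaque_mu <- c(`0` = 0, `1` = 0.6, `2` = 2.0)[as.character(group)]
  plaque <- pmin(pmax(round(plaque_mu + cohort$plaque_effect * (comp == 2L) +
                              rnorm(n, 0, 0.5)), 0L), 3L)

  subjects <- lapply(seq_len(n), function(i)
    subject_spec(subject_id = ids[i], group = group[i], n_tiles = n_tiles,
                 pi_low = pi_low[i]))
  cov <- data.frame(subject_id = ids, group = group, imt = imt,
                    plaque_score = as.integer(plaque), tnf_basal = tnf_basal,
                    tnf_lps = tnf_lps, pi_low_true = pi_low,
                    component = comp, stringsAsFactors = FALSE)
  if (isTRUE(cohort$degenerate_mixture))
    attr(cov, "degenerate_mixture") <- TRUE
  list(subjects = subjects, covariates = cov)
}
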