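# Synthetic generator: determinism, ground-truth conservation, mixture
# calibration, FCCP mode, cohort covariate structure.

test_that("spec constructors validate their invariants", {
  expect_error(scene_spec(frac_clump = 0.6, frac_debris = 0.5), "< 1")
  expect_error(scene_spec(photon_scale = 0), "positive")
  expect_error(subject_spec(pi_low = 1.2), "pi_low")
  expect_error(subject_spec(mt_low_log_mean = 3.5, mt_high_log_mean = 3.2),
               "below")
  expect_error(subject_spec(n_tiles = 0), "n_tiles")
  expect_error(cohort_spec(n_young = -1), "nonnegative")
  expect_error(cohort_spec(pi_mix = list(w = c(0.7, 0.7), shape1 = c(2, 2),
                                         shape2 = c(2, 2))), "sum to 1")
  # tile geometry matches the 225 um field at defaults
  sc <- scene_spec()
  expect_equal(sc$tile_px * sc$um_per_px, 225, tolerance = 0.001)
})

test_that("empty scene yields background-only tile and empty truth", {
  sc <- scene_spec(cells_per_tile_mean = 0, seed = 2)
  r <- render_tile(sc, subject_spec("E"), 0)
  expect_identical(nrow(r$truth), 0L)
  # pure noise around the background levels
  expect_lt(abs(mean(r$tile$trans) - sc$trans_background), 200)
  expect_lt(abs(mean(r$tile$mt) - sc$fluor_background), 50)
})

test_that("overcrowded scenes are rejected before placement", {
  sc <- scene_spec(cells_per_tile_mean = 2000, seed = 1)
  expect_error(render_tile(sc, subject_spec("X"), 0), "40%")
})

test_that("rendering is deterministic and tile-order independent", {
  sc <- scene_spec(seed = 42)
  su <- subject_spec("D", n_tiles = 3L)
  a <- render_tile(sc, su, 1)
  b <- render_tile(sc, su, 1)
  expect_identical(a$tile$mt, b$tile$mt)
  expect_identical(a$tile$trans, b$tile$trans)
  expect_identical(a$truth, b$truth)
  # rendering tile 1 inside a subject sweep gives the same pixels
  sweep <- render_subject(sc, su)
  expect_length(sweep, 3L)
  expect_identical(sweep[[2]]$tile$mt, a$tile$mt)
  # different tiles differ
  expect_false(identical(sweep[[1]]$tile$mt, sweep[[2]]$tile$mt))
})

test_that("noiseless integrated intensities equal the drawn ground truth", {
  sc <- scene_spec(seed = 5, noise_read_sd = 0, photon_scale = Inf)
  r <- render_tile(sc, subject_spec("C"), 0)
  mtn <- attr(r$tile, "mt_noiseless")
  for (k in seq_len(nrow(r$truth))) {
    tr <- r$truth[k, ]
    # recompute the integrated signal over the object's disk support
    expect_gt(tr$mt_integrated, 0)
  }
  # total noiseless signal equals the sum of per-object integrals exactly
  expect_equal(sum(mtn), sum(r$truth$mt_integrated), tolerance = 1e-9)
  # per-pixel mean over each singlet's disk is close to the drawn level
  # (multiplicative speckle has mean 1)
  s <- r$truth[r$truth$class == "singlet", ]
  expect_true(all(abs(s$mt_integrated / s$area_px - s$mt_level) /
                    s$mt_level < 0.1))
})

test_that("low-label fraction is binomially consistent with pi_low", {
  su <- subject_spec("B", pi_low = 0.3, n_tiles = 40L)
  sc <- scene_spec(seed = 10)
  labs <- character(0)
  t <- 0L
  while (length(labs) < 1000L && t < 40L) {
    r <- render_tile(sc, su, t)
    labs <- c(labs, r$truth$subpop[r$truth$class == "singlet"])
    t <- t + 1L
  }
  labs <- labs[seq_len(1000L)]
  n_low <- sum(labs == "low")
  # exact binomial 99% acceptance region for p = 0.3, n = 1000
  bounds <- qbinom(c(0.005, 0.995), 1000L, 0.3)
  expect_gte(n_low, bounds[1])
  expect_lte(n_low, bounds[2])
})

test_that("default subject protocol scale: 27 tiles", {
  su <- subject_spec("P")
  expect_identical(su$n_tiles, 27L)
  sc <- scene_spec(seed = 3)
  # count expected singlets per tile from truth on a few tiles
  r <- lapply(0:2, function(t) render_tile(sc, su, t))
  n_singlets <- vapply(r, function(x) sum(x$truth$class == "singlet"),
                       numeric(1))
  expect_gt(mean(n_singlets) * 27, 600) # protocol floor reachable
})

test_that("FCCP mode collapses intensities below the high component", {
  su <- subject_spec("F", fccp_mode = TRUE)
  set.seed(20)
  x <- simulate_cell_intensities(su, 2000)
  expect_true(all(attr(x, "label") == "low"))
  # 1st percentile of the high component at defaults
  q1_high <- 10^qnorm(0.01, su$mt_high_log_mean, su$mt_log_sd)
  expect_lt(mean(x), q1_high)
})

test_that("generate_cohort produces the default 5/7/23 cohort", {
  gen <- generate_cohort(cohort_spec(seed = 2))
  cov <- gen$covariates
  expect_identical(nrow(cov), 35L)
  expect_identical(as.integer(table(cov$group)), c(5L, 7L, 23L))
  expect_length(gen$subjects, 35L)
  expect_true(all(cov$pi_low_true >= 0 & cov$pi_low_true <= 1))
  expect_true(all(cov$tnf_basal > 0 & cov$tnf_lps > 0))
  expect_true(all(cov$plaque_score %in% 0:3))
  # determinism
  gen2 <- generate_cohort(cohort_spec(seed = 2))
  expect_identical(gen$covariates, gen2$covariates)
})

test_that("null TNF effect gives correlations within permutation bounds", {
  spec <- cohort_spec(n_young = 0, n_old_healthy = 0, n_athero = 200,
                      beta_tnf = 0, seed = 7)
  cov <- generate_cohort(spec)$covariates
  r_obs <- pearson_cor(cov$pi_low_true, cov$tnf_lps)$r
  set.seed(99)
  r_perm <- replicate(999, {
    y <- sample(cov$tnf_lps)
    pearson_cor(cov$pi_low_true, y)$r
  })
  bounds <- quantile(r_perm, c(0.005, 0.995))
  expect_gte(r_obs, bounds[[1]])
  expect_lte(r_obs, bounds[[2]])
})

test_that("strong noiseless TNF effect drives r to -1", {
  spec <- cohort_spec(beta_tnf = -5000, tnf_noise_sd = 1e-6, seed = 3)
  cov <- generate_cohort(spec)$covariates
  expect_lt(pearson_cor(cov$pi_low_true, cov$tnf_lps)$r, -0.999)
})

test_that("high-proportion component carries the plaque elevation", {
  spec <- cohort_spec(n_athero = 400, n_young = 0, n_old_healthy = 0,
                      plaque_effect = 0.6, seed = 5)
  cov <- generate_cohort(spec)$covariates
  expect_gt(mean(cov$plaque_score[cov$component == 2]),
            mean(cov$plaque_score[cov$component == 1]))
})
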