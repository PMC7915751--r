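# Per-cell measurement: background subtraction, exact mean*area identity,
# granularity spectrum, morphology unimodality diagnostic.

make_seg <- function(labels, areas_from = NULL) {
  n <- max(labels)
  idx <- which(labels > 0)
  area <- tabulate(labels[idx], n)
  h <- nrow(labels)
  rows <- ((idx - 1) %% h) + 1
  cols <- ((idx - 1) %/% h) + 1
  objects <- data.frame(
    label = seq_len(n), area_px = as.numeric(area),
    centroid_x = rowsum(cols, labels[idx])[, 1] / area - 1,
    centroid_y = rowsum(rows, labels[idx])[, 1] / area - 1,
    class = "singlet", class_prob = 0.9, touches_border = FALSE,
    stringsAsFactors = FALSE)
  list(objects = objects, retained = objects, labels = labels)
}

test_that("uniform cell measures by arithmetic; identity mean*area = total", {
  n <- 64
  labels <- matrix(0L, n, n)
  labels[11:20, 11:20] <- 1L # 100 px
  mt <- matrix(0, n, n); mt[labels == 1L] <- 500
  ppix <- matrix(0, n, n)
  ti <- new_tile(mt, ppix, matrix(1000, n, n), "7", 0)
  rec <- measure_cells(ti, make_seg(labels))
  expect_equal(rec$object_size_px, 100)
  expect_equal(rec$mt_total, 50000)
  expect_equal(rec$mt_mean, 500)
  expect_equal(rec$ppix_total, 0)

  # raw equal to background everywhere -> totals 0
  ti2 <- new_tile(matrix(7, n, n), matrix(9, n, n), matrix(1000, n, n), "7", 0)
  rec2 <- measure_cells(ti2, make_seg(labels))
  expect_equal(rec2$mt_total, 0)
  expect_equal(rec2$ppix_total, 0)
})

test_that("measurements are invariant to tile-wide additive offsets", {
  set.seed(12)
  n <- 64
  labels <- matrix(0L, n, n)
  labels[5:24, 5:24] <- 1L
  labels[40:55, 30:50] <- 2L
  base <- matrix(runif(n * n, 100, 200), n, n)
  base[labels > 0] <- base[labels > 0] + 800
  t1 <- new_tile(base, base, matrix(1000, n, n), "s", 0)
  t2 <- new_tile(base + 500, base + 500, matrix(1000, n, n), "s", 0)
  r1 <- measure_cells(t1, make_seg(labels))
  r2 <- measure_cells(t2, make_seg(labels))
  expect_equal(r1$mt_total, r2$mt_total, tolerance = 1e-8)
  expect_equal(r1$ppix_mean, r2$ppix_mean, tolerance = 1e-8)
})

test_that("identity holds on random records from rendered tiles", {
  r <- render_tile(scene_spec(seed = 21), subject_spec("ID"), 0)
  rec <- measure_cells(r$tile, segment_tile(r$tile))
  expect_gt(nrow(rec), 5)
  expect_equal(rec$mt_mean * rec$object_size_px, rec$mt_total, tolerance = 1e-12)
  expect_equal(rec$ppix_mean * rec$object_size_px, rec$ppix_total,
               tolerance = 1e-12)
  expect_true(all(rec$object_size_px > 0))
  expect_true(all(rec$mt_total >= 0 & rec$ppix_total >= 0))
})

test_that("noiseless synthetic singlet totals match drawn intensities", {
  sc <- scene_spec(seed = 33, noise_read_sd = 0, photon_scale = Inf,
                   texture_speckle_sd = 0)
  r <- render_tile(sc, subject_spec("CN"), 0)
  seg <- segment_tile(r$tile)
  rec <- measure_cells(r$tile, seg)
  gt <- r$truth[r$truth$class == "singlet" & !r$truth$touches_border, ]
  for (k in seq_len(nrow(gt))) {
    d <- sqrt((seg$retained$centroid_x - gt$cx[k])^2 +
                (seg$retained$centroid_y - gt$cy[k])^2)
    j <- which.min(d)
    if (d[j] > gt$radius_px[k]) next
    # integrated intensity within a few percent (mask/disk rasterization)
    expect_lt(abs(rec$mt_total[j] - gt$mt_integrated[k]) / gt$mt_integrated[k],
              0.08)
  }
})

test_that("granularity spectrum behaves on analytic textures", {
  # uniform disk of radius 5: survives openings up to its radius
  img <- matrix(1000, 64, 64)
  mk <- disk_mask(64, 32, 32, 5)
  img[mk] <- 200
  g <- granularity_score(img, mk, background = 1000)
  expect_false(g$warn_zero)
  expect_gt(g$score, 5)
  expect_lte(g$score, 7)
  expect_true(all(g$spectrum >= 0))
  expect_lte(sum(g$spectrum), 1 + 1e-12)

  # radius-1 speckle: mass removed at the first opening
  set.seed(2)
  mk2 <- disk_mask(64, 32, 32, 15)
  img2 <- matrix(1000, 64, 64)
  hit <- mk2 & matrix(runif(64 * 64) < 0.25, 64, 64)
  img2[hit] <- 200
  g2 <- granularity_score(img2, mk2, background = 1000)
  expect_lt(g2$score, 2)

  # zero signal -> flagged zero score
  g0 <- granularity_score(matrix(1000, 32, 32), disk_mask(32, 16, 16, 5),
                          background = 1000)
  expect_true(g0$warn_zero)
  expect_identical(g0$score, 0)
})

test_that("planted coarse texture scores above planted fine texture", {
  score_at_scale <- function(scale_px, seed) {
    sc <- scene_spec(seed = seed, texture_scale_px = scale_px,
                     texture_speckle_sd = 0.35, noise_read_sd = 0,
                     photon_scale = Inf)
    r <- render_tile(sc, subject_spec("TX"), 0)
    seg <- segment_tile(r$tile)
    rec <- measure_cells(r$tile, seg, granularity = TRUE)
    mean(rec$granularity)
  }
  fine <- mean(vapply(1:2, function(s) score_at_scale(1, s), numeric(1)))
  coarse <- mean(vapply(1:2, function(s) score_at_scale(4, s), numeric(1)))
  expect_gt(coarse, fine)
})

test_that("morphology gap diagnostic prefers k=1 for one class, k=2 for two", {
  set.seed(41)
  one <- data.frame(object_size_px = rnorm(150, 800, 60),
                    granularity = rnorm(150, 3, 0.3),
                    mt_mean = runif(150, 10, 100))
  ms1 <- morphology_scatter(one)
  expect_identical(ms1$k_preferred, 1L)

  two <- data.frame(object_size_px = c(rnorm(80, 400, 25), rnorm(80, 2400, 60)),
                    granularity = c(rnorm(80, 1, 0.1), rnorm(80, 6, 0.2)),
                    mt_mean = runif(160, 10, 100))
  ms2 <- morphology_scatter(two)
  expect_identical(ms2$k_preferred, 2L)

  # single record -> k = 1 by definition
  expect_identical(morphology_scatter(one[1, ])$k_preferred, 1L)
})
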