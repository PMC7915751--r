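# Segmentation: edge-detection mask, size classification, retention filters,
# and recovery against generator ground truth.

test_that("pixel_classify handles constant and single-disk images", {
  expect_identical(sum(pixel_classify(matrix(500, 64, 64))), 0L)

  img <- disk_image(128, centers = cbind(64, 64), radii = 12)
  mask <- pixel_classify(img)
  labs <- classify_objects(mask, seg_config(area_min_singlet = 100))
  expect_identical(nrow(labs$objects), 1L)
  # area within 15% of pi * 12^2
  expect_lt(abs(labs$objects$area_px - pi * 144), 0.15 * pi * 144)
  expect_equal(labs$objects$centroid_x, 63, tolerance = 1)
  expect_equal(labs$objects$centroid_y, 63, tolerance = 1)
})

test_that("two disjoint disks give exactly two components", {
  img <- disk_image(128, centers = rbind(c(34, 34), c(94, 94)),
                    radii = c(10, 10))
  mask <- pixel_classify(img)
  co <- classify_objects(mask, seg_config(area_min_singlet = 100))
  expect_identical(nrow(co$objects), 2L)
})

test_that("size classes and the triangular membership follow the rules", {
  cfg <- seg_config(area_min_singlet = 300, area_max_singlet = 3000)
  # build masks with known pixel counts: rectangles
  mk <- function(area) {
    m <- matrix(FALSE, 330, 40)
    m[10 + seq_len(area %/% 10), 11:20] <- TRUE
    if (area %% 10) m[10 + area %/% 10 + 1, 11:(10 + area %% 10)] <- TRUE
    m
  }
  deb <- classify_objects(mk(290), cfg)$objects
  expect_identical(deb$class, "debris")
  expect_identical(deb$class_prob, 1.0)

  s_mid <- classify_objects(mk(1650), cfg)$objects
  expect_identical(s_mid$class, "singlet")
  expect_identical(s_mid$class_prob, 1.0)

  s_edge <- classify_objects(mk(300), cfg)$objects
  expect_identical(s_edge$class, "singlet")
  expect_equal(s_edge$class_prob, 0.5)
  # boundary object is excluded by the strict > 50% filter
  expect_identical(nrow(filter_singlets(s_edge, cfg)), 0L)

  cl <- classify_objects(mk(3010), cfg)$objects
  expect_identical(cl$class, "clump")
})

test_that("filter_singlets applies all three rules and is idempotent", {
  cfg <- seg_config()
  obj <- data.frame(label = 1:4,
                    area_px = c(500, 500, 500, 5000),
                    centroid_x = 1:4, centroid_y = 1:4,
                    class = c("singlet", "singlet", "singlet", "clump"),
                    class_prob = c(0.9, 0.4, 0.9, 1.0),
                    touches_border = c(FALSE, FALSE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  kept <- filter_singlets(obj, cfg)
  expect_identical(kept$label, 1L)
  expect_identical(filter_singlets(kept, cfg), kept)
  # all clumps -> empty
  expect_identical(nrow(filter_singlets(obj[obj$class == "clump", ], cfg)), 0L)
})

test_that("border-touching ground-truth singlets are excluded", {
  su <- subject_spec("BR")
  found_border <- FALSE
  for (s in 1:6) {
    r <- render_tile(scene_spec(seed = s), su, 0)
    tp <- nrow(r$tile$trans)
    tr <- r$truth
    # unambiguous cases: the disk protrudes >= 2 px beyond the tile edge
    prot <- pmax(1 - (tr$cx - tr$radius_px), 1 - (tr$cy - tr$radius_px),
                 tr$cx + tr$radius_px - tp, tr$cy + tr$radius_px - tp)
    gt_border <- tr[tr$class == "singlet" & prot >= 2, ]
    if (nrow(gt_border) == 0) next
    found_border <- TRUE
    ret <- segment_tile(r$tile)$retained
    if (nrow(ret) == 0) next
    for (k in seq_len(nrow(gt_border))) {
      d <- sqrt((ret$centroid_x - gt_border$cx[k])^2 +
                  (ret$centroid_y - gt_border$cy[k])^2)
      expect_gt(min(d), 3) # no retained object sits on the border cell
    }
  }
  expect_true(found_border)
})

test_that("ground-truth singlets are recovered one-to-one on default tiles", {
  su <- subject_spec("RC", pi_low = 0.3)
  tot <- c(gt = 0, rec = 0, ret = 0, fp = 0)
  for (s in 1:3) {
    r <- render_tile(scene_spec(seed = 100 + s), su, 0)
    seg <- segment_tile(r$tile)
    m <- match_recovery(r$truth, seg$retained)
    tot["gt"] <- tot["gt"] + m$n_gt
    tot["rec"] <- tot["rec"] + m$n_matched
    tot["ret"] <- tot["ret"] + nrow(seg$retained)
    tot["fp"] <- tot["fp"] + count_unmatched_retained(r$truth, seg$retained)
  }
  expect_gte(tot["rec"] / tot["gt"], 0.95)
  expect_lte(tot["fp"] / tot["ret"], 0.05)
})

test_that("classification output is invariant to mask relabelling", {
  # reversing the image flips component discovery order; the set of
  # (area, class, rounded centroid) pairs must be unchanged
  img <- disk_image(128, centers = rbind(c(30, 40), c(90, 80)),
                    radii = c(9, 13))
  cfg <- seg_config(area_min_singlet = 100)
  a <- classify_objects(pixel_classify(img), cfg)$objects
  b <- classify_objects(pixel_classify(img[rev(seq_len(128)),
                                           rev(seq_len(128))]), cfg)$objects
  key <- function(o) {
    k <- o[order(o$area_px), c("area_px", "class", "class_prob")]
    rownames(k) <- NULL
    k
  }
  expect_equal(key(a), key(b), tolerance = 1e-12)
})

test_that("otsu_threshold separates a clear bimodal sample", {
  set.seed(31)
  x <- c(rnorm(3000, 10, 1), rnorm(1000, 40, 2))
  thr <- otsu_threshold(x)
  expect_gt(thr, 12)   # above ~all of the low component
  expect_lt(thr, 35)   # below ~all of the high component
  expect_lt(mean(x[x > thr] < 20), 0.01)
  expect_true(is.na(otsu_threshold(rep(3, 100))))
})
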