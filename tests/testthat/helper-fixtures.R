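# Shared fixtures: analytic images built in code and ground-truth matching.

# flat image with one or more uniform disks (bright background, dark disks)
disk_image <- function(size = 128, centers, radii, bg = 30000, fg = 10000) {
  img <- matrix(bg, size, size)
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(size)) {
      dj <- which((i - centers[k, 2])^2 + (seq_len(size) - centers[k, 1])^2 <=
                    radii[k]^2)
      if (length(dj)) img[i, dj] <- fg
    }
  }
  img
}

# binary disk mask
disk_mask <- function(size, cx, cy, r) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) {
    dj <- which((i - cy)^2 + (seq_len(size) - cx)^2 <= r^2)
    if (length(dj)) m[i, dj] <- TRUE
  }
  m
}

# one-to-one matching of ground-truth singlets to retained objects:
# nearest retained centroid within one cell radius, used at most once
match_recovery <- function(truth, retained) {
  gt <- truth[truth$class == "singlet" & !truth$touches_border, , drop = FALSE]
  if (nrow(gt) == 0L || nrow(retained) == 0L)
    return(list(n_gt = nrow(gt), n_matched = 0L))
  d <- sqrt(outer(gt$cx, retained$centroid_x, "-")^2 +
              outer(gt$cy, retained$centroid_y, "-")^2)
  nn <- apply(d, 1, which.min)
  within <- d[cbind(seq_len(nrow(gt)), nn)] < gt$radius_px
  # one-to-one: a retained object may absorb only one in-radius match
  nn[!within] <- NA_integer_
  ok <- within & !duplicated(nn, incomparables = NA)
  list(n_gt = nrow(gt), n_matched = sum(ok))
}

# retained objects with no ground-truth singlet within one cell radius
count_unmatched_retained <- function(truth, retained) {
  gts <- truth[truth$class == "singlet", , drop = FALSE]
  if (nrow(retained) == 0L) return(0L)
  if (nrow(gts) == 0L) return(nrow(retained))
  d <- sqrt(outer(retained$centroid_x, gts$cx, "-")^2 +
              outer(retained$centroid_y, gts$cy, "-")^2)
  nn <- apply(d, 1, which.min)
  sum(d[cbind(seq_len(nrow(retained)), nn)] > gts$radius_px[nn])
}

random_tile <- function(seed = 1, n = 32) {
  set.seed(seed)
  new_tile(matrix(sample(0:65535, n * n, TRUE), n, n),
           matrix(sample(0:65535, n * n, TRUE), n, n),
           matrix(sample(0:65535, n * n, TRUE), n, n),
           subject_id = "9", tile_index = 2L)
}
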