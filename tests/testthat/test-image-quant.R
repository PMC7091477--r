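# Wavelet segmentation on constructed spots, metric arithmetic,
# colocalization and the surface/internalized classification.

gaussian_spot_image <- function(shape, centers, amplitude, background, sigma = 1.5,
                                seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(background, shape[1], shape[2])
    for (i in seq_len(nrow(centers))) {
      g <- outer(exp(-(seq_len(shape[1]) - centers[i, 1])^2 / (2 * sigma^2)),
                 exp(-(seq_len(shape[2]) - centers[i, 2])^2 / (2 * sigma^2)))
      img <- img + amplitude * g
    }
    matrix(rpois(length(img), img), shape[1], shape[2])
  })
}

test_that("wavelet segmentation finds constructed spots and nothing in flat fields", {
  # constant image: no structures
  m <- wavelet_segment(matrix(7, 64, 64))
  expect_equal(nrow(m$structures), 0)
  expect_true(all(m$labels == 0L))

  # one spot at peak SNR 10 on Poisson background: exactly one structure
  # containing the true peak pixel
  img <- gaussian_spot_image(c(64, 64), matrix(c(32, 32), 1), 10 * sqrt(10), 10,
                             seed = 2)
  m <- wavelet_segment(img)
  expect_equal(nrow(m$structures), 1)
  expect_true(m$labels[32, 32] == 1L)

  # two spots 10 sigma apart: two structures, centroids within 1 px of truth
  ctr <- matrix(c(25, 25, 25, 40), 2, byrow = TRUE)
  img <- gaussian_spot_image(c(64, 64), ctr, 40, 10, sigma = 1.5, seed = 3)
  m <- wavelet_segment(img)
  expect_equal(nrow(m$structures), 2)
  d <- centroid_match_dist(m, tibble::tibble(row = ctr[, 1], col = ctr[, 2]))
  expect_true(all(d <= 1))
})

test_that("raising the detection threshold never increases the structure count", {
  sim <- simulate_two_channel_image(c(128, 128), 100, 25, 25, 0.5,
                                    amplitude = 30, seed = 4)
  counts <- vapply(c(1.5, 2, 3, 4, 6), function(k) {
    nrow(wavelet_segment(sim$channel_a, threshold_k = k)$structures)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("structure metrics do the arithmetic stated on constructed masks", {
  # two structures of total intensity 100 and 300 on a known grid
  img <- matrix(0, 100, 100)
  img[10:11, 10:11] <- 25    # 4 px x 25 = 100
  img[60:62, 60:63] <- 25    # 12 px x 25 = 300
  mask <- mask_from_logical(img > 0, img, pixel_size_nm = 1000)
  sm <- structure_metrics(mask)
  expect_equal(sm$n_structures, 2)
  expect_equal(sm$mean_intensity_per_cluster, 200)
  expect_equal(sm$summed_intensity, 400)
  # 2 structures in a (100 px * 1 um/px)^2 = 10,000 um^2 field
  expect_equal(sm$clusters_per_um2, 2 / 1e4)
  # mask covering 16 of 10,000 pixels
  expect_equal(sm$percent_area, 100 * 16 / 1e4)

  # summed intensity equals the original image restricted to the mask, exactly
  sim <- simulate_two_channel_image(c(64, 64), 100, 8, 8, 0.5,
                                    amplitude = 40, seed = 5)
  m <- wavelet_segment(sim$channel_a)
  expect_equal(sum(m$structures$total_intensity),
               sum(sim$channel_a[m$labels > 0L]))
})

test_that("colocalization counts pixel-overlapping structure pairs", {
  a <- matrix(FALSE, 50, 50); b <- matrix(FALSE, 50, 50)
  # 10 A structures in rows, 3 of them overlapped by B
  for (i in 1:10) a[5 * i - (1:0), 10:12] <- TRUE
  for (i in 1:3) b[5 * i - (1:0), 12:14] <- TRUE
  ma <- mask_from_logical(a); mb <- mask_from_logical(b)
  cl <- colocalize(ma, mb)
  expect_equal(cl$n_a, 10)
  expect_equal(cl$fraction_a_coloc, 0.30)
  expect_equal(nrow(cl$pairing), 3)

  # identical masks: full colocalization; disjoint: none
  expect_equal(colocalize(ma, ma)$fraction_a_coloc, 1.0)
  empty <- mask_from_logical(matrix(FALSE, 50, 50))
  expect_equal(colocalize(ma, empty)$fraction_a_coloc, 0.0)

  # shape mismatch rejected
  expect_error(colocalize(ma, mask_from_logical(matrix(FALSE, 10, 10))),
               "identical dimensions")
})

test_that("endocytosis classification = green structures without red overlap", {
  g <- matrix(FALSE, 60, 60); r <- matrix(FALSE, 60, 60)
  for (i in 1:20) g[3 * i - 2, seq(3, 9)] <- TRUE
  # red covers all but structures 7 and 13
  for (i in setdiff(1:20, c(7, 13))) r[3 * i - 2, seq(3, 9)] <- TRUE
  res <- classify_endocytosed(mask_from_logical(g), mask_from_logical(r))
  expect_equal(res$n_total_green, 20)
  expect_equal(res$n_internal, 2)
  expect_equal(res$n_surface + res$n_internal, res$n_total_green)
  expect_equal(res$fraction_internal, 0.10)

  # every green overlapping red: nothing internalized
  res <- classify_endocytosed(mask_from_logical(g), mask_from_logical(g))
  expect_equal(res$fraction_internal, 0.0)

  # empty red mask: everything internalized
  res <- classify_endocytosed(mask_from_logical(g),
                              mask_from_logical(matrix(FALSE, 60, 60)))
  expect_equal(res$fraction_internal, 1.0)

  # no green structures: undefined fraction
  res <- classify_endocytosed(mask_from_logical(matrix(FALSE, 60, 60)),
                              mask_from_logical(r))
  expect_true(is.na(res$fraction_internal))
})

test_that("apposition mode also pairs near-but-disjoint structures", {
  a <- matrix(FALSE, 40, 40); b <- matrix(FALSE, 40, 40)
  a[10:11, 10:11] <- TRUE
  b[10:11, 13:14] <- TRUE   # 2.5 px centroid gap, no shared pixel
  ma <- mask_from_logical(a); mb <- mask_from_logical(b)
  expect_equal(colocalize(ma, mb, mode = "overlap")$fraction_a_coloc, 0)
  expect_equal(colocalize(ma, mb, mode = "apposition",
                          apposition_dist_px = 3)$fraction_a_coloc, 1)
})
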