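# Blink correction, DBSCAN semantics against a brute-force oracle,
# cluster metrics, and rendering mass conservation.

make_locs <- function(frame, x, y) tibble::tibble(frame = frame, x = x, y = y)

test_that("blink correction merges consecutive-frame chains at the centroid", {
  # single detection unchanged
  one <- make_locs(0L, 5, 5)
  expect_equal(nrow(merge_consecutive_detections(one)), 1)

  # 5 detections at one position over frames 0-4 collapse to frame 0
  chain <- make_locs(0:4, rep(100, 5), rep(200, 5))
  m <- merge_consecutive_detections(chain)
  expect_equal(nrow(m), 1)
  expect_equal(m$frame, 0L)
  expect_equal(c(m$x, m$y), c(100, 200))

  # frame gap beyond max_frame_gap is not merged
  gap <- make_locs(c(0L, 2L), c(100, 100), c(200, 200))
  expect_equal(nrow(merge_consecutive_detections(gap, max_frame_gap = 1)), 2)
  expect_equal(nrow(merge_consecutive_detections(gap, max_frame_gap = 2)), 1)

  # centroid of a drifting chain within the merge radius
  drift <- make_locs(0:2, c(0, 6, 12), c(0, 0, 0))
  m <- merge_consecutive_detections(drift, merge_radius_nm = 20)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 6)

  # same-frame detections are never merged
  simfr <- make_locs(c(0L, 0L), c(0, 1), c(0, 0))
  expect_equal(nrow(merge_consecutive_detections(simfr)), 2)
})

test_that("blink correction is idempotent", {
  sim <- simulate_smlm_field(5, 80, 40, 2, 10, 500, 3, seed = 7)
  once <- merge_consecutive_detections(sim$localizations)
  twice <- merge_consecutive_detections(once)
  expect_equal(twice, once)
})

test_that("dbscan matches the textbook definition on constructed inputs", {
  # empty input
  cs <- dbscan_cluster(make_locs(integer(0), numeric(0), numeric(0)))
  expect_equal(nrow(cs$clusters), 0)
  expect_length(cs$labels, 0)

  # 25 points in a 10 nm disc plus 5 isolated points >= 1 um away
  set.seed(11)
  th <- runif(25, 0, 2 * pi); rr <- 10 * sqrt(runif(25))
  x <- c(500 + rr * cos(th), 2000, 3000, 4000, 5000, 6000)
  y <- c(500 + rr * sin(th), 2000, 3000, 4000, 5000, 6000)
  cs <- dbscan_cluster(make_locs(seq_along(x), x, y), eps_nm = 20, min_pts = 20)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$n_detections, 25)
  expect_equal(sum(cs$labels == -1L), 5)

  # 19 coincident points stay noise at min_pts = 20
  cs <- dbscan_cluster(make_locs(1:19, rep(1, 19), rep(1, 19)),
                       eps_nm = 20, min_pts = 20)
  expect_equal(nrow(cs$clusters), 0)
  expect_equal(sum(cs$labels == -1L), 19)
})

test_that("dbscan equals the brute-force O(n^2) oracle on random fields", {
  for (s in 1:12) {
    set.seed(s)
    n_bg <- sample(30:120, 1)
    x <- runif(n_bg, 0, 400); y <- runif(n_bg, 0, 400)
    # add 1-3 dense blobs so clusters actually form
    for (b in seq_len(sample(1:3, 1))) {
      cxy <- runif(2, 50, 350)
      m <- sample(15:40, 1)
      x <- c(x, cxy[1] + rnorm(m, 0, 8))
      y <- c(y, cxy[2] + rnorm(m, 0, 8))
    }
    locs <- make_locs(seq_along(x), x, y)
    cs <- dbscan_cluster(locs, eps_nm = 20, min_pts = 20)
    oracle <- dbscan_brute(cs$localizations$x, cs$localizations$y, 20, 20)
    expect_true(same_partition(cs$labels, oracle),
                label = sprintf("partition match, seed %d", s))
  }
})

test_that("cluster partition is invariant to input row order", {
  sim <- simulate_smlm_field(4, 80, 20, 1, 10, 1000, 2, seed = 5)
  locs <- sim$localizations
  cs1 <- dbscan_cluster(locs)
  set.seed(1)
  cs2 <- dbscan_cluster(locs[sample(nrow(locs)), ])
  expect_true(same_partition(cs1$labels, cs2$labels))
})

test_that("cluster metrics: fractions, densities and hull areas", {
  # all points in one cluster
  set.seed(2)
  locs <- make_locs(1:30, rnorm(30, 100, 5), rnorm(30, 100, 5))
  cs <- dbscan_cluster(locs, eps_nm = 20, min_pts = 20,
                       field_width_nm = 1000, field_height_nm = 1000)
  expect_equal(cluster_metrics(cs)$fraction_in_clusters, 1.0)

  # square-corner cluster: shoelace hull area 10,000 nm^2
  sq <- make_locs(1:4, c(0, 0, 100, 100), c(0, 100, 0, 100))
  cs <- dbscan_cluster(sq, eps_nm = 150, min_pts = 4,
                       field_width_nm = 1000, field_height_nm = 1000)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$area_nm2, 10000)
  expect_false(cs$clusters$degenerate)

  # collinear cluster flagged degenerate with area 0
  lin <- make_locs(1:5, seq(0, 40, 10), rep(0, 5))
  cs <- dbscan_cluster(lin, eps_nm = 15, min_pts = 3,
                       field_width_nm = 1000, field_height_nm = 1000)
  expect_equal(cs$clusters$area_nm2, 0)
  expect_true(cs$clusters$degenerate)

  # no clusters -> fraction 0; density = n / field area
  iso <- make_locs(1:5, seq(0, 4000, 1000), seq(0, 4000, 1000))
  cs <- dbscan_cluster(iso, field_width_nm = 10000, field_height_nm = 10000)
  gm <- cluster_metrics(cs)
  expect_equal(gm$fraction_in_clusters, 0)
  expect_equal(gm$detections_per_um2, 5 / 100)

  # detections conservation: clustered + noise = total
  sim <- simulate_smlm_field(6, 80, 30, 2, 10, 1000, 2, seed = 9)
  cs <- dbscan_cluster(sim$localizations)
  expect_equal(sum(cs$clusters$n_detections) + sum(cs$labels == -1L),
               length(cs$labels))
})

test_that("rendering conserves unit kernel mass and separates distant emitters", {
  # single localization: total mass 1
  one <- make_locs(0L, 500, 500)
  img <- render_storm(one, field_width_nm = 1000, field_height_nm = 1000)
  expect_equal(sum(img), 1, tolerance = 1e-6)

  # two localizations 1 um apart: two local maxima at their pixels
  two <- make_locs(c(0L, 1L), c(500, 1500), c(500, 500))
  img <- render_storm(two, field_width_nm = 2000, field_height_nm = 1000)
  expect_equal(sum(img), 2, tolerance = 1e-6)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(sort(unique(round(peak[, 2] / 10) * 10)), c(50, 150), tolerance = 0.2)

  # zero localizations: all-zero image
  img <- render_storm(make_locs(integer(0), numeric(0), numeric(0)),
                      field_width_nm = 500, field_height_nm = 500)
  expect_true(all(img == 0))
})
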