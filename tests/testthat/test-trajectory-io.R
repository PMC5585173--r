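test_that("valid rows are read sorted, untracked rows dropped and counted", {
  tf <- write_track_file(c("frame,x,y,z",
                           "2,0.1,0.0,0.0",
                           "1,0.0,0.0,0.0",
                           "3,0.2,0.1,0.0",
                           "4,0.3,0.1,0.0",
                           "5,0.4,0.2,0.1"))
  tr <- read_tracked_points(tf, frame_rate = 30, species = "demo")
  expect_equal(nrow(tr), 5L)
  expect_equal(tr$frame, 1:5)
  expect_equal(attr(tr, "frame_rate"), 30)
  expect_equal(attr(tr, "n_dropped"), 0L)

  tf2 <- write_track_file(c("frame,x,y,z",
                            "1,0,0,0", "2,0.1,0,0", "3,,,",
                            "4,NA,0,0", "5,0.2,0,0", "6,0.3,0,0",
                            "7,0.4,0,0"))
  tr2 <- read_tracked_points(tf2, frame_rate = 30, species = "demo")
  expect_equal(nrow(tr2), 5L)
  expect_equal(attr(tr2, "n_dropped"), 2L)
})

test_that("degenerate and malformed files raise informative errors", {
  expect_error(read_tracked_points(write_track_file(character()), 30, "s"),
               "no data")
  expect_error(read_tracked_points(write_track_file("frame,x,y,z"), 30, "s"),
               "no data")
  dup <- write_track_file(c("1,0,0,0", "1,1,0,0", "2,2,0,0"))
  expect_error(read_tracked_points(dup, 30, "s"), "duplicate frame")
  good <- write_track_file(c("1,0,0,0", "2,1,0,0"))
  expect_error(read_tracked_points(good, frame_rate = 0, species = "s"),
               "frame_rate")
})

test_that("tab-delimited and xyzpts layouts are accepted", {
  tf <- write_track_file(c("frame\tx\ty\tz", "1\t0\t0\t0", "2\t0.5\t0\t0"),
                         ext = ".tsv")
  tr <- read_tracked_points(tf, 30, "s")
  expect_equal(tr$x, c(0, 0.5))

  xyz <- write_track_file(c("0,0,0", "0.1,0,0", "0.2,0.1,0"))
  tr2 <- read_tracked_points(xyz, 30, "s", format = "xyzpts")
  expect_equal(tr2$frame, 1:3)
  expect_equal(tr2$x, c(0, 0.1, 0.2))
})

test_that("segmentation keeps maximal runs of at least min_len frames", {
  # runs of 19 and 25 frames separated by a gap: only the 25 survives
  frames <- c(1:19, 30:54)
  tr <- trajectory(frames, rnorm(44), rnorm(44), rnorm(44), frame_rate = 30)
  seg <- segment_tracks(tr, min_len = 20)
  expect_equal(length(unique(seg$segment)), 1L)
  expect_equal(nrow(seg), 25L)
  expect_equal(seg$frame, 30:54)

  # fully continuous track: one segment, everything kept
  tr2 <- trajectory(1:100, rnorm(100), rnorm(100), rnorm(100), frame_rate = 30)
  seg2 <- segment_tracks(tr2)
  expect_equal(unique(seg2$segment), 1L)
  expect_equal(nrow(seg2), 100L)

  # all runs too short: empty result
  frames3 <- c(1:5, 10:14, 20:24)
  tr3 <- trajectory(frames3, rnorm(15), rnorm(15), rnorm(15), frame_rate = 30)
  expect_equal(nrow(segment_tracks(tr3)), 0L)

  # total segmented frames never exceed tracked frames
  expect_lte(nrow(segment_tracks(tr, min_len = 2)), nrow(tr))
})

test_that("displacements difference positions within segments only", {
  tr <- trajectory(1:3, c(0, 1, 1), c(0, 0, 1), c(0, 0, 0), frame_rate = 30)
  d <- displacements(segment_tracks(tr, min_len = 2))
  expect_equal(as.matrix(d[, c("dx", "dy", "dz")]),
               rbind(c(1, 0, 0), c(0, 1, 0)), ignore_attr = TRUE)

  # two segments of 20 and 30 frames: N = 19 + 29 = 48
  frames <- c(1:20, 100:129)
  tr2 <- trajectory(frames, rnorm(50), rnorm(50), rnorm(50), frame_rate = 30)
  d2 <- displacements(segment_tracks(tr2, min_len = 20))
  expect_equal(nrow(d2), 48L)
  expect_equal(unname(attr(d2, "source_counts")), c(19L, 29L))

  # stationary animal: all-zero vectors
  tr3 <- trajectory(1:25, rep(1, 25), rep(2, 25), rep(3, 25), frame_rate = 30)
  d3 <- displacements(segment_tracks(tr3))
  expect_true(all(as.matrix(d3[, c("dx", "dy", "dz")]) == 0))
})

test_that("the pipeline is invariant to translating all positions", {
  set.seed(4)
  x <- cumsum(rnorm(60)); y <- cumsum(rnorm(60)); z <- cumsum(rnorm(60))
  tr <- trajectory(1:60, x, y, z, frame_rate = 30)
  tr_shift <- trajectory(1:60, x + 5, y - 3, z + 0.7, frame_rate = 30)
  d <- displacements(segment_tracks(tr))
  d_shift <- displacements(segment_tracks(tr_shift))
  expect_equal(as.matrix(d[, 2:4]), as.matrix(d_shift[, 2:4]),
               tolerance = 1e-12)
})

test_that("outlier trimming keeps the ceiling(retain * N) most central rows", {
  set.seed(11)
  d <- tibble::tibble(segment = 1L, dx = rnorm(1000), dy = rnorm(1000),
                      dz = rnorm(1000))
  kept <- trim_outliers(d, retain = 0.97)
  expect_equal(nrow(kept), 970L)
  expect_equal(attr(kept, "n_removed"), 30L)

  expect_identical(nrow(trim_outliers(d, retain = 1.0)), 1000L)

  # planted far outliers are exactly the rows removed (brute-force oracle)
  core <- matrix(rnorm(97 * 3, sd = 0.1), ncol = 3)
  out <- matrix(c(10, 0, 0, 0, -12, 0, 0, 0, 15), ncol = 3, byrow = TRUE)
  dd <- tibble::tibble(segment = 1L,
                       dx = c(core[, 1], out[, 1]),
                       dy = c(core[, 2], out[, 2]),
                       dz = c(core[, 3], out[, 3]))
  kept2 <- trim_outliers(dd, retain = 0.97)
  expect_equal(nrow(kept2), 97L)
  expect_true(all(abs(kept2$dx) < 5))

  # nested kept-sets: a larger retain keeps a superset
  k90 <- trim_outliers(d, retain = 0.90)
  k95 <- trim_outliers(d, retain = 0.95)
  key <- function(t) paste(t$dx, t$dy, t$dz)
  expect_true(all(key(k90) %in% key(k95)))
})

test_that("trimming falls back to standardized distance on singular covariance", {
  d <- tibble::tibble(segment = 1L, dx = rnorm(50), dy = rnorm(50),
                      dz = rep(0, 50))
  expect_warning(kept <- trim_outliers(d, retain = 0.9), "singular|Euclidean")
  expect_equal(nrow(kept), 45L)
})

test_that("cube normalization scales correctly and round-trips", {
  set.seed(2)
  d <- tibble::tibble(segment = 1L, dx = runif(100, -0.08, 0.08),
                      dy = runif(100, -0.05, 0.05),
                      dz = runif(100, -0.02, 0.02))
  d$dx[1] <- 0.08  # pin the max
  ds <- normalize_to_cube(d, scale = "auto")
  expect_equal(attr(ds, "scale"), 0.08)
  expect_equal(max(abs(as.matrix(ds[, 1:3]))), 1, tolerance = 1e-12)
  back <- as.matrix(ds[, 1:3]) * attr(ds, "scale")
  expect_equal(back, as.matrix(d[, 2:4]), ignore_attr = TRUE,
               tolerance = 1e-12)

  # already-normalized data with explicit scale 1 is unchanged
  ds2 <- normalize_to_cube(tibble::tibble(dx = c(0.5, -1), dy = c(0, 0),
                                          dz = c(0.2, 0.3)), scale = 1)
  expect_equal(ds2$dx, c(0.5, -1))

  # degenerate all-zero input
  zz <- tibble::tibble(dx = 0, dy = 0, dz = 0)
  expect_error(normalize_to_cube(zz, scale = "auto"), "degenerate")

  # explicit scale must cover the data
  expect_error(normalize_to_cube(d, scale = 0.01), "scale smaller")

  # per-axis normalization maxes out each axis at 1
  dpa <- normalize_to_cube(d, scale = "auto", per_axis = TRUE)
  expect_equal(unname(apply(abs(as.matrix(dpa[, 1:3])), 2, max)),
               c(1, 1, 1), tolerance = 1e-12)
})

test_that("shared_scale pools the maximum over all datasets", {
  a <- tibble::tibble(dx = c(0.02, -0.01), dy = c(0, 0), dz = c(0, 0))
  b <- tibble::tibble(dx = c(0.01, 0), dy = c(-0.07, 0), dz = c(0, 0))
  expect_equal(shared_scale(a, b), 0.07)
})
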