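# Blob detection on synthetic slices and the axial-oversampling correction.

test_that("detect_blobs recovers planted blob centres", {
  # constant sub-threshold image: nothing detected
  flat <- matrix(5, 32, 32)
  expect_equal(nrow(detect_blobs(flat, threshold = 10)), 0L)

  # three well-separated blobs with Poisson noise, amplitude >> background:
  # three centroids within 1 px of the planted positions
  planted <- rbind(c(50, 80), c(150, 200), c(200, 60))
  img <- render_synthetic_slice(planted, amplitudes = 200, size_px = 128,
                                pixel_um = 2, psf_sd_px = 2, background = 10,
                                poisson_noise = TRUE, seed = 4)
  got <- detect_blobs(img, threshold = 40, min_area_px = 3, pixel_um = 2)
  expect_equal(nrow(got), 3L)
  for (i in seq_len(3)) {
    d <- sqrt((got$x_um - planted[i, 1])^2 + (got$y_um - planted[i, 2])^2)
    expect_lt(min(d), 2)  # 1 px = 2 um
  }
})

test_that("touching blobs merge into a single component at low threshold", {
  planted <- rbind(c(60, 64), c(76, 64))  # 16 um apart, psf 4 um
  img <- render_synthetic_slice(planted, amplitudes = 100, size_px = 64,
                                pixel_um = 2, psf_sd_px = 2, background = 0,
                                poisson_noise = FALSE)
  merged <- detect_blobs(img, threshold = 1, min_area_px = 1, pixel_um = 2)
  expect_equal(nrow(merged), 1L)   # documented behaviour, not an error
  # centroid of the merged pair sits between the two planted centres
  expect_gt(merged$x_um, 60); expect_lt(merged$x_um, 76)
  # a higher threshold separates them again (inter-blob valley ~ 27)
  split <- detect_blobs(img, threshold = 60, min_area_px = 1, pixel_um = 2)
  expect_equal(nrow(split), 2L)
})

test_that("8-connectivity joins diagonal pixels", {
  img <- matrix(0, 8, 8)
  img[2, 2] <- 10; img[3, 3] <- 10  # touching only diagonally
  expect_equal(nrow(detect_blobs(img, threshold = 5)), 1L)
  img[6, 6] <- 10                   # far away: its own component
  expect_equal(nrow(detect_blobs(img, threshold = 5)), 2L)
})

test_that("oversampling correction collapses axial chains", {
  # single event: identity
  one <- data.frame(x_um = 1, y_um = 2, z_um = 30)
  got <- correct_axial_oversampling(one, radius = 10)
  expect_equal(got[, c("x_um", "y_um", "z_um")], one)

  # chain 0/10/20 um with radius 10: transitive closure links all three,
  # the median plane 10 is kept
  chain <- data.frame(x_um = 0, y_um = 0, z_um = c(0, 10, 20))
  got <- correct_axial_oversampling(chain, radius = 10)
  expect_equal(nrow(got), 1L)
  expect_equal(got$z_um, 10)
  expect_equal(got$n_events, 3L)

  # two events 30 um apart stay separate
  two <- data.frame(x_um = 0, y_um = 0, z_um = c(0, 30))
  expect_equal(nrow(correct_axial_oversampling(two, radius = 10)), 2L)

  # empty input: empty output, not an error
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0))
  expect_equal(nrow(correct_axial_oversampling(empty)), 0L)

  # averaging variant returns the chain centroid
  got <- correct_axial_oversampling(chain, radius = 10, mode = "mean")
  expect_equal(got$z_um, 10)
  uneven <- data.frame(x_um = 0, y_um = 0, z_um = c(10, 20))
  expect_equal(correct_axial_oversampling(uneven, mode = "mean")$z_um, 15)
  # median mode on an even group: tie towards lower z
  expect_equal(correct_axial_oversampling(uneven, mode = "median")$z_um, 10)
})

test_that("dedup output is invariant to event order", {
  for (s in 1:5) {
    cells <- make_separated_cells(40, seed = s)
    ev <- simulate_serial_detections(cells, serial_imaging_config(),
                                     seed = s)
    base <- correct_axial_oversampling(ev, radius = 10)
    set.seed(s + 100)
    perm <- ev[sample.int(nrow(ev)), ]
    for (mode in c("median", "mean")) {
      expect_equal(correct_axial_oversampling(perm, radius = 10, mode = mode),
                   correct_axial_oversampling(ev, radius = 10, mode = mode))
    }
    expect_equal(nrow(base), nrow(cells))
  }
})

test_that("increasing the radius never increases the output count", {
  set.seed(21)
  ev <- data.frame(x_um = runif(120, 0, 100), y_um = runif(120, 0, 100),
                   z_um = 10 * sample(0:10, 120, replace = TRUE))
  radii <- c(2, 5, 10, 20, 40, 80)
  counts <- vapply(radii, function(r) {
    nrow(correct_axial_oversampling(ev, radius = r))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("correction exactly inverts the forward model for separated cells", {
  # min pairwise distance > 2 * radius, detection_prob 1, jitter 0
  for (s in 1:10) {
    cells <- make_separated_cells(sample(20:60, 1), seed = s)
    ev <- simulate_serial_detections(cells, serial_imaging_config(),
                                     seed = s)
    rec <- correct_axial_oversampling(ev, radius = 10, mode = "mean")
    expect_equal(nrow(rec), nrow(cells))
    # match by xy (jitter 0 keeps xy exact and unique)
    m <- match(paste(rec$x_um, rec$y_um), paste(cells$x_um, cells$y_um))
    expect_false(anyNA(m))
    expect_true(all(abs(rec$z_um - cells$z_um[m]) <= 5 + 1e-9))
  }
})

test_that("count_region matches a brute-force containment tally", {
  atlas <- demo_atlas()
  expect_error(count_region(data.frame(), atlas, "nope"), "unknown region_id")
  none <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0))
  expect_equal(count_region(none, atlas, "LGd"), 0L)

  inside <- data.frame(x_um = runif(20, 1100, 1900),
                       y_um = runif(20, 800, 1400),
                       z_um = runif(20, 100, 1100))
  expect_equal(count_region(inside, atlas, "LGd"), 20L)

  set.seed(33)
  mixed <- as.data.frame(random_points(400, 2600))
  for (rid in c("LGd", "MD", "other_TC")) {
    expect_equal(count_region(mixed, atlas, rid),
                 sum(bf_locate(as.matrix(mixed), atlas) == rid))
  }
})

test_that("event tables round-trip through CSV", {
  ev <- data.frame(brain_id = "b1", slice_index = 1:3,
                   x_um = c(1, 2, 3), y_um = c(4, 5, 6),
                   z_um = c(10, 10, 20))
  path <- tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- load_events(path)
  expect_equal(back$z_um, ev$z_um)
  bad <- write_tmp_csv(c("x_um,y_um", "1,2"))
  expect_error(load_events(bad), "z_um")
})
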