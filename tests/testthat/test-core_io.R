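# Atlas handling, region assignment, cell CSV I/O, per-nucleus counting,
# across-brain proportion summaries.

test_that("load_cells handles valid, empty and malformed files", {
  header <- "brain_id,genotype,x_um,y_um,z_um,class_label"
  path <- write_tmp_csv(c(header,
                          "b1,het,10,20,30,classA",
                          "b1,het,11,21,31,classA",
                          "b1,het,12,22,32,classB"))
  ds <- load_cells(path)
  expect_s3_class(ds, "brain_dataset")
  expect_equal(nrow(ds$cells), 3L)
  expect_equal(ds$brain_id, "b1")

  empty <- load_cells(write_tmp_csv(header))
  expect_equal(nrow(empty$cells), 0L)

  # missing required column, named in the error
  bad <- write_tmp_csv(c("brain_id,genotype,x_um,y_um,class_label",
                         "b1,het,1,2,classA"))
  expect_error(load_cells(bad), "z_um")

  # non-numeric coordinate, row number named
  nn <- write_tmp_csv(c(header, "b1,het,1,2,3,classA",
                        "b1,het,1,oops,3,classA"))
  expect_error(load_cells(nn), "row 2")

  # multi-brain file needs explicit selection
  mb <- write_tmp_csv(c(header, "b1,het,1,2,3,classA",
                        "b2,het,1,2,3,classA"))
  expect_error(load_cells(mb), "several brains")
  expect_equal(load_cells(mb, brain_id = "b2")$brain_id, "b2")
})

test_that("region assignment follows half-open first-match-wins semantics", {
  atlas <- demo_atlas()
  # strictly inside the LGd box
  inside <- data.frame(x_um = 1500, y_um = 1000, z_um = 600)
  expect_equal(assign_regions(inside, atlas)$region_id, "LGd")
  # exactly on the max-x face of LGd: not in any box (x = 2000 excluded
  # everywhere)
  face <- data.frame(x_um = 2000, y_um = 1000, z_um = 600)
  expect_equal(assign_regions(face, atlas)$region_id, "unassigned")
  # min faces are included
  minface <- data.frame(x_um = 1000, y_um = 750, z_um = 0)
  expect_equal(assign_regions(minface, atlas)$region_id, "LGd")
})

test_that("overlapping boxes resolve by list order, matching brute force", {
  overlap <- region_atlas(list(
    region_box("LP", min = c(0, 0, 0), max = c(100, 100, 100)),
    region_box("PO", min = c(50, 0, 0), max = c(150, 100, 100))
  ))
  p <- data.frame(x_um = 75, y_um = 50, z_um = 50)  # inside both
  expect_equal(assign_regions(p, overlap)$region_id, "LP")

  set.seed(42)
  pts <- random_points(300, scale = 160)
  got <- assign_regions(as.data.frame(pts), overlap)$region_id
  expect_equal(got, unname(bf_locate(pts, overlap)))
})

test_that("assign_regions is idempotent and order-independent", {
  atlas <- demo_atlas()
  set.seed(7)
  cells <- as.data.frame(random_points(200, scale = 2600))
  once <- assign_regions(cells, atlas)
  expect_identical(assign_regions(once, atlas), once)
  perm <- sample.int(nrow(cells))
  shuffled <- assign_regions(cells[perm, ], atlas)
  expect_equal(shuffled$region_id, once$region_id[perm])
})

test_that("counts_by_region conserves the total cell count", {
  atlas <- demo_atlas()
  # hand-built case
  cells <- data.frame(
    x_um = c(rep(1500, 5), rep(500, 2)),
    y_um = c(rep(1000, 5), rep(700, 2)),
    z_um = c(rep(600, 5), rep(1500, 2)),
    class_label = c(rep("classA", 5), rep("classB", 2)))
  tab <- counts_by_region(assign_regions(cells, atlas), atlas)
  expect_equal(unname(tab["LGd", "classA"]), 5L)
  expect_equal(unname(tab["MD", "classB"]), 2L)
  expect_equal(sum(tab), 7L)

  # empty dataset
  empty <- counts_by_region(
    data.frame(region_id = character(0), class_label = character(0)))
  expect_equal(sum(empty), 0L)

  # property: conservation over random datasets (some outside the atlas)
  for (s in 1:10) {
    set.seed(s)
    n <- sample(50:150, 1)
    cells <- data.frame(random_points(n, scale = 3000))
    cells$class_label <- sample(c("classA", "classB"), n, replace = TRUE)
    tab <- counts_by_region(assign_regions(cells, atlas), atlas)
    expect_equal(sum(tab), n)
  }
})

test_that("distribution_proportions normalises per brain and summarises", {
  # single brain: proportions only, SEM 0, flagged n = 1
  one <- data.frame(brain_id = "b1", region_id = c("LGd", "MD"),
                    count = c(2, 2))
  res <- distribution_proportions(one)
  expect_equal(res$mean_prop, c(0.5, 0.5))
  expect_equal(res$sem_prop, c(0, 0))
  expect_equal(attr(res, "n_brains"), 1L)

  # two brains, hand SEM = SD / sqrt(2)
  two <- data.frame(brain_id = rep(c("b1", "b2"), each = 2),
                    region_id = rep(c("LGd", "MD"), 2),
                    count = c(6, 4, 8, 2))
  res <- distribution_proportions(two)
  expect_equal(res$mean_prop, c(0.7, 0.3))
  expect_equal(res$sem_prop, c(0.1, 0.1))

  # proportions sum to 1 per brain for arbitrary inputs
  set.seed(11)
  rand <- data.frame(brain_id = rep(c("b1", "b2", "b3"), each = 4),
                     region_id = rep(c("LGd", "LP", "MD", "VP"), 3),
                     count = sample(1:50, 12, replace = TRUE))
  res <- distribution_proportions(rand)
  expect_equal(sum(res$mean_prop), 1, tolerance = 1e-12)

  # zero class total names the brain
  zero <- data.frame(brain_id = c("b1", "b2"), region_id = "LGd",
                     count = c(5, 0))
  expect_error(distribution_proportions(zero), "b2")
})

test_that("atlas JSON round-trips with priority order preserved", {
  atlas <- demo_atlas()
  path <- tempfile(fileext = ".json")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_equal(back$ids, atlas$ids)
  expect_equal(back$boxes[[1]]$min, atlas$boxes[[1]]$min)

  set.seed(3)
  pts <- as.data.frame(random_points(100, 2600))
  expect_equal(assign_regions(pts, back)$region_id,
               assign_regions(pts, atlas)$region_id)
})

test_that("invalid atlas definitions are rejected", {
  expect_error(region_box("bad", min = c(0, 0, 0), max = c(1, 0, 1)),
               "min must be < max")
  expect_error(region_atlas(list(
    region_box("a", c(0, 0, 0), c(1, 1, 1)),
    region_box("a", c(0, 0, 0), c(2, 2, 2)))), "duplicate")
  expect_error(region_atlas(list()), "at least one box")
})
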