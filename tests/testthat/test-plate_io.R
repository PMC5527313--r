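test_that("plate tables round-trip through disk, preserving flags and missing cells", {
  area <- matrix(rlnorm(32 * 48, log(500), 0.3), 32, 48)
  area[sample(length(area), 25)] <- NA
  flag <- matrix("", 32, 48)
  flag[1, 1] <- "S"; flag[5, 7] <- "C"
  g <- plate_grid(area, "P1", "Q01", "induced", medium = "YNB", flag = flag)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_table(g, path)
  g2 <- read_plate_table(path)
  expect_equal(g2$area, g$area)
  expect_identical(g2$flag, g$flag)
  expect_identical(g2[c("plate_id", "query_id", "condition", "medium")],
                   g[c("plate_id", "query_id", "condition", "medium")])
})

test_that("plate reader reports malformed files with their location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("row\tcol\tsize\tflag",
               "1\t1\t100\t", "1\t1\t200\t"), path)
  expect_error(read_plate_table(path, condition = "induced"),
               "duplicate position")
  writeLines(c("row\tcol\tsize\tflag", "40\t1\t100\t"), path)
  expect_error(read_plate_table(path, condition = "induced"),
               "outside the declared")
  writeLines(c("row\tcol\tsize\tflag", "1\t1\t-5\t"), path)
  expect_error(read_plate_table(path, condition = "induced"), "negative")
})

test_that("positions omitted from the file become missing cells, not zeros", {
  g <- uniform_plate(500, condition = "induced")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_table(g, path)
  lines <- readLines(path)
  # drop 10 data lines (first 5 lines are 4 comments + header)
  keep <- setdiff(seq_along(lines), 6:15)
  writeLines(lines[keep], path)
  g2 <- read_plate_table(path)
  expect_equal(sum(is.na(g2$area)), 10)
  expect_equal(sum(g2$area == 0, na.rm = TRUE), 0)
})

test_that("an empty grid writes a header-only table", {
  g <- plate_grid(matrix(NA_real_, 16, 24), "E", "Q", "uninduced")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_table(g, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_equal(body, "row\tcol\tsize\tflag")
})

test_that("layouts round-trip and reject a group spanning two strains", {
  sim <- tiny_sim(60, seed = 4)
  lay <- sim$layouts$T1
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layout(lay, path)
  lay2 <- read_layout(path)
  expect_equal(as.data.frame(lay2), as.data.frame(lay))
  expect_error(
    array_layout(row = c(0, 0), col = c(0, 1),
                 strain_id = c("A", "B"), replicate_group = c("g", "g")),
    "more than one strain")
  expect_error(
    array_layout(row = c(0, 0), col = c(0, 0),
                 strain_id = c("A", "A"), replicate_group = c("g", "g")),
    "duplicate grid position")
})

test_that("manifests round-trip and enforce paired conditions", {
  sim <- tiny_sim(40, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(sim$manifest, path)
  m2 <- read_manifest(path)
  expect_equal(m2$records[names(sim$manifest$records)],
               sim$manifest$records)
  expect_identical(m2$control_query_id, sim$manifest$control_query_id)
  recs <- sim$manifest$records
  expect_error(screen_manifest(recs[recs$condition == "induced", ], "Q01"),
               "lacks an uninduced")
  expect_error(screen_manifest(recs, "nope"), "control query")
})

test_that("FD matrices round-trip with signatures and missing cells", {
  set.seed(1)
  fd <- matrix(rnorm(50 * 6), 50, 6,
               dimnames = list(sprintf("S%03d", 1:50),
                               sprintf("exp%02d", 1:6)))
  fd[sample(length(fd), 30)] <- NA
  ref <- structure(list(fd = fd,
                        signature = setNames(rep(c("sigA", "sigB"), 3),
                                             colnames(fd))),
                   class = "fd_matrix")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fd_matrix(ref, path)
  ref2 <- read_fd_matrix(path)
  expect_equal(ref2$fd, ref$fd, tolerance = 1e-12)
  expect_identical(ref2$signature, ref$signature)
})

test_that("a full simulated screen survives the disk round trip unchanged", {
  sim <- tiny_sim(50, seed = 12, missing_prob = 0.02)
  dir <- withr::local_tempdir()
  path <- write_screen(sim, dir)
  back <- read_screen(path)
  for (pid in names(sim$plates))
    expect_equal(back$plates[[pid]]$area, sim$plates[[pid]]$area,
                 tolerance = 1e-12)
  expect_equal(back$truth$true_S, sim$truth$true_S, tolerance = 1e-12)
  fit_a <- suppressMessages(score_screen(sim))
  fit_b <- suppressMessages(score_screen(back))
  expect_equal(fit_b$records$s, fit_a$records$s, tolerance = 1e-9)
  expect_identical(fit_b$records$class, fit_a$records$class)
})
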