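test_that("point_pattern validates lattice side and coordinates", {
  p <- point_pattern(c(1, 50), c(1, 50), X = 100)
  expect_s3_class(p, "point_pattern")
  expect_equal(npoints(p), 2L)
  expect_error(point_pattern(1, 1, X = 99), "even")
  expect_error(point_pattern(0, 5, X = 100), "out of range")
  expect_error(point_pattern(5, 101, X = 100), "out of range")
  expect_equal(npoints(point_pattern(integer(0), integer(0), X = 10)), 0L)
})

test_that("pattern CSV round-trips exactly and flags bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  p <- point_pattern(c(1, 50, 7), c(1, 50, 93), X = 100, pixel_size = 0.44)
  write_pattern_csv(p, path)
  q <- read_pattern_csv(path, X = 100, pixel_size = 0.44)
  expect_identical(q$x, p$x)
  expect_identical(q$y, p$y)

  writeLines(c("x,y", "1,1", "50,50"), path)
  expect_equal(npoints(read_pattern_csv(path, X = 100)), 2L)

  writeLines("x,y", path)
  expect_equal(npoints(read_pattern_csv(path, X = 100)), 0L)

  writeLines(c("x,y", "0,5"), path)
  expect_error(read_pattern_csv(path, X = 100), "out of range")

  writeLines(c("x,y", "3,3", "3,3"), path)
  expect_warning(read_pattern_csv(path, X = 100), "duplicate")

  writeLines(c("x,y", "1,1"), path)
  expect_error(read_pattern_csv(path, X = 99), "even")
})

test_that("sample sets enforce a shared lattice side", {
  a <- point_pattern(1:3, 1:3, X = 10)
  b <- point_pattern(2:4, 2:4, X = 10)
  ss <- sample_set(list(a, b))
  expect_equal(ss$N, 2L)
  expect_equal(ss$X, 10L)
  wrong <- point_pattern(1:3, 1:3, X = 20)
  expect_error(sample_set(list(a, wrong)), "same lattice side")
  expect_error(sample_set(list()), "non-empty")
})

test_that("sample-set directories round-trip with manifest and ordering", {
  dir <- withr::local_tempdir()
  pats <- lapply(1:4, function(i) {
    point_pattern(sample.int(60, 10), sample.int(60, 10), X = 60,
                  label = paste0("s", i))
  })
  ss <- sample_set(pats, label = "demo")
  write_sampleset_dir(ss, dir)
  back <- read_sampleset_dir(dir)
  expect_equal(back$N, 4L)
  expect_equal(back$X, 60L)
  for (i in 1:4) {
    expect_identical(back$samples[[i]]$x, pats[[i]]$x)
    expect_identical(back$samples[[i]]$y, pats[[i]]$y)
  }
  expect_error(read_sampleset_dir(file.path(dir, "nope")), "directory")
  empty <- withr::local_tempdir()
  jsonlite::write_json(list(X = 10), file.path(empty, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(read_sampleset_dir(empty), "no pattern CSV")
})

test_that("MAT v5 coordinate reader maps scipy-written arrays", {
  matfile <- file.path(withr::local_tempdir(), "coords.mat")
  script <- sprintf(paste(
    "import numpy as np, scipy.io as sio",
    "rng = np.random.default_rng(3)",
    "c = np.empty((4, 1), dtype=object)",
    "for i in range(4):",
    "    c[i, 0] = rng.integers(1, 41, (5 + i, 2)).astype(float)",
    "sio.savemat(%s, {'coords': c}, do_compression=True)",
    sep = "\n"), deparse(matfile))
  status <- system2("python", "-", input = script,
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  ss <- read_mat_coordinates(matfile, X = 40)
  expect_equal(ss$N, 4L)
  expect_equal(ss$X, 40L)
  expect_equal(vapply(ss$samples, npoints, integer(1)), 5:8)

  # separate two-column variables, one per image
  mat2 <- file.path(withr::local_tempdir(), "flat.mat")
  script2 <- sprintf(paste(
    "import numpy as np, scipy.io as sio",
    "rng = np.random.default_rng(4)",
    "d = {'imB': rng.integers(1, 21, (6, 2)).astype(float),",
    "     'imA': rng.integers(1, 21, (3, 2)).astype(float)}",
    "sio.savemat(%s, d, do_compression=False)",
    sep = "\n"), deparse(mat2))
  status2 <- system2("python", "-", input = script2,
                     stdout = FALSE, stderr = FALSE)
  expect_identical(status2, 0L)
  ss2 <- read_mat_coordinates(mat2, X = 20)
  expect_equal(ss2$N, 2L)
  # lexicographic by variable name: imA first
  expect_equal(npoints(ss2$samples[[1]]), 3L)

  expect_error(read_mat_coordinates("/nonexistent/file.mat"), "no such file")
})
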