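# stackio: ImageStack container, TIFF round trips, axis normalization,
# CSV tables.

test_that("image_stack validates calibration, channels and intensities", {
  arr <- array(runif(8 * 8 * 2), dim = c(8, 8, 1, 2, 1))
  st <- image_stack(arr, voxel_size = c(dx = 0.5, dy = 0.5, dz = 1),
                    channels = c("EGFP", "SHG"))
  expect_identical(unname(stack_dim(st)), c(1L, 1L, 2L, 8L, 8L))
  expect_equal(channel_index(st, "SHG"), 2L)
  expect_error(channel_index(st, "DAPI"), "not found")
  expect_error(image_stack(arr, voxel_size = c(0, 1, 1)), "positive")
  expect_error(image_stack(arr, channels = c("a", "a")), "unique")
  expect_error(image_stack(-arr), "nonnegative")
  # trailing axes of length one are re-inserted
  st3 <- image_stack(array(0, dim = c(4, 5, 3)))
  expect_identical(unname(stack_dim(st3)), c(1L, 3L, 1L, 4L, 5L))
})

test_that("stack save/load round-trips voxels and calibration", {
  arr <- array(runif(6 * 7 * 3 * 2 * 2), dim = c(6, 7, 3, 2, 2))
  st <- image_stack(arr, voxel_size = c(dx = 0.4, dy = 0.3, dz = 1.2),
                    frame_interval = 15, time_unit = "s",
                    channels = c("EGFP", "SHG"))
  path <- tempfile(fileext = ".tif")
  save_stack(st, path)
  st2 <- load_stack(path)
  expect_equal(st2$data, st$data, tolerance = 1e-7)  # float32 storage
  expect_equal(st2$voxel_size, st$voxel_size)
  expect_equal(st2$frame_interval, 15)
  expect_identical(st2$time_unit, "s")
  expect_identical(st2$channels, c("EGFP", "SHG"))
  # channel lookup by label on the loaded stack
  expect_equal(get_frame(st2, 1, "SHG"), get_frame(st, 1, 2),
               tolerance = 1e-7)
})

test_that("16-bit stacks are preserved bit-exactly and empty stacks refused", {
  arr <- array(sample(0:65535, 5 * 5 * 2, replace = TRUE), dim = c(5, 5, 2))
  st <- image_stack(arr, dtype = "uint16")
  path <- tempfile(fileext = ".tif")
  save_stack(st, path)
  st2 <- load_stack(path)
  expect_identical(st2$dtype, "uint16")
  expect_equal(st2$data, st$data)                   # exact for integers
  expect_error(save_stack(st, file.path(tempdir(), "no/such/dir/x.tif")),
               "directory")
})

test_that("foreign multi-page TIFFs load with calibration axes (tifffile oracle)", {
  # tifffile (Python) writes a ZCYX stack; our reader must normalize to
  # TZCYX with a length-1 T axis, and our writer's pages must be readable
  # by tifffile byte-for-byte.
  py <- Sys.which("python")
  expect_true(nzchar(py))
  tmp <- tempfile(fileext = ".tif")
  script <- sprintf(paste0(
    "import numpy, tifffile\n",
    "a = numpy.arange(3*2*8*9, dtype=numpy.uint16).reshape(3,2,8,9)\n",
    "tifffile.imwrite(%s, a)\n"), shQuote(tmp))
  writeLines(script, f <- tempfile(fileext = ".py"))
  expect_equal(system2(py, f), 0L)
  st <- load_stack(tmp, calibration = list(axes = "ZCYX",
                                           shape = c(Z = 3, C = 2),
                                           channels = c("EGFP", "SHG")))
  expect_identical(unname(stack_dim(st)), c(1L, 3L, 2L, 8L, 9L))
  a_r <- get_frame(st, 1, "EGFP")                   # channel 0 in python
  expect_equal(a_r[3, 5, 2],                        # z=2 (1-based), y=3, x=5
               (1 - 1) * 0 + ((2 - 1) * 2 * 8 * 9 + 0 * 8 * 9 + 2 * 9 + 4))
  # reverse direction: python reads our pages
  arr <- array(sample(0:60000, 4 * 6 * 2, replace = TRUE), dim = c(4, 6, 2))
  st2 <- image_stack(arr, dtype = "uint16")
  ours <- tempfile(fileext = ".tif")
  save_stack(st2, ours)
  chk <- sprintf(paste0(
    "import numpy, tifffile, sys\n",
    "a = tifffile.imread(%s)\n",
    "print(int(a.size), int(a.sum()))\n"), shQuote(ours))
  writeLines(chk, f2 <- tempfile(fileext = ".py"))
  out <- system2(py, f2, stdout = TRUE)
  got <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  expect_equal(got[1], length(arr))   # tifffile honours our shape metadata
  expect_equal(got[2], sum(arr))
})

test_that("write_table enforces one schema and round-trips with units", {
  recs <- list(list(id = 1L, v = 2.5, label = "a"),
               list(id = 2L, v = 3.5, label = "b"))
  path <- tempfile(fileext = ".csv")
  write_table(recs, path, units = c(v = "um^3"))
  txt <- readLines(path)
  expect_true(any(grepl("# column v: um\\^3", txt)))
  back <- read_table_csv(path)
  expect_equal(back$v, c(2.5, 3.5))
  expect_identical(back$label, c("a", "b"))
  bad <- list(list(id = 1L, v = 2), list(id = 2L, w = 3))
  expect_error(write_table(bad, path), "field 'v'|field 'w'")
  # empty record list -> header-only file
  write_table(list(), path)
  expect_true(file.exists(path))
  expect_equal(nrow(read_table_csv(path)), 0L)
  # CellRecord schema echo
  rec <- nodule4d:::empty_cell_records()
  write_table(rec, path)
  hdr <- names(read_table_csv(path))
  expect_true(all(c("volume_um3", "area_um2", "sphericity", "oblateness",
                    "prolateness", "compartment") %in% hdr))
})
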