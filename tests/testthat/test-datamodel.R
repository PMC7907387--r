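test_that("dataset constructor enforces the grid and axis invariants", {
  expect_error(msi_dataset(2, 2, c(100, 200), cbind(3, 1),
                           matrix(0, 1, 2)), "outside")
  expect_error(msi_dataset(2, 2, c(200, 100), cbind(1, 1),
                           matrix(0, 1, 2)), "increasing")
  expect_error(msi_dataset(2, 2, c(100, 200),
                           rbind(c(1, 1), c(1, 1)), matrix(0, 2, 2)),
               "duplicate")
  expect_error(msi_dataset(2, 2, c(100, 200), cbind(1, 1),
                           matrix(-1, 1, 2)), "negative")
  expect_error(msi_dataset(2, 2, c(100, 200), cbind(1, 1),
                           matrix(0, 1, 3)), "x d")
})

test_that("mean spectrum is the column mean over spectral pixels only", {
  ds <- msi_dataset(2, 1, c(100, 200), cbind(i = 1:2, j = c(1, 1)),
                    rbind(c(0, 2), c(2, 0)))
  expect_equal(mean_spectrum(ds)$mu, c(1, 1))

  one <- msi_dataset(3, 3, c(100, 200), cbind(2, 2),
                     matrix(c(5, 7), 1, 2))
  expect_equal(mean_spectrum(one)$mu, c(5, 7))

  # brute-force summation oracle on a larger random dataset
  ds2 <- tiny_dataset()
  expected <- numeric(length(ds2$mz))
  for (s in seq_len(nrow(ds2$intensities)))
    expected <- expected + ds2$intensities[s, ]
  expect_equal(mean_spectrum(ds2)$mu, expected / nrow(ds2$intensities))
})

test_that("mean spectrum is linear in the intensities", {
  ds <- tiny_dataset()
  for (a in c(0, 0.5, 3)) {
    scaled <- ds
    scaled$intensities <- a * ds$intensities
    expect_equal(mean_spectrum(scaled)$mu, a * mean_spectrum(ds)$mu)
  }
})

test_that("channel images index the grid correctly", {
  ds <- msi_dataset(2, 2, c(100, 200), cbind(2, 1),
                    matrix(c(0, 9), 1, 2))
  img <- channel_image(ds, 2)
  expect_equal(dim(img$values), c(2, 2))
  expect_equal(img$values[1, 2], 9)
  expect_equal(sum(img$values != 0), 1)
  expect_equal(channel_image(ds, 1)$values, matrix(0, 2, 2))
  expect_error(channel_image(ds, 3), "out of range")

  ds2 <- tiny_dataset()
  k <- 4
  img2 <- channel_image(ds2, k)
  for (s in seq_len(nrow(ds2$coords)))
    expect_equal(img2$values[ds2$coords[s, 2], ds2$coords[s, 1]],
                 ds2$intensities[s, k])
})

test_that("m/z cropping keeps the closed interval", {
  ds <- msi_dataset(1, 1, c(100, 500, 1150), cbind(1, 1),
                    matrix(1:3, 1))
  expect_equal(crop_mz(ds, 100, 1150)$mz, c(100, 500, 1150))

  ds2 <- msi_dataset(1, 1, c(99.9, 100.0, 100.1), cbind(1, 1),
                     matrix(1:3, 1))
  cropped <- crop_mz(ds2, 100, 100.05)
  expect_equal(length(cropped$mz), 1)
  expect_equal(cropped$mz, 100.0)
  expect_error(crop_mz(ds2, 2000, 3000), "no m/z channels")
  expect_error(crop_mz(ds2, 100, 100), "lo < hi")
})

test_that("cropping commutes with the mean spectrum", {
  ds <- tiny_dataset()
  lo <- ds$mz[3]; hi <- ds$mz[8]
  keep <- ds$mz >= lo & ds$mz <= hi
  expect_equal(mean_spectrum(crop_mz(ds, lo, hi))$mu,
               mean_spectrum(ds)$mu[keep])
})

test_that("imzML continuous round trip preserves the dataset to float32", {
  ds <- tiny_dataset()
  path <- file.path(withr::local_tempdir(), "t.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_equal(back$mz, ds$mz)
  expect_identical(back$coords, ds$coords)
  expect_equal(back$intensities, ds$intensities,
               tolerance = 1e-6)
  expect_equal(length(back$mz), 10)
  expect_equal(nrow(back$coords), 5)
})

test_that("single-channel datasets survive the imzML round trip", {
  ds <- msi_dataset(2, 1, 150.5, cbind(i = 1:2, j = c(1, 1)),
                    matrix(c(3, 4), 2, 1))
  path <- file.path(withr::local_tempdir(), "one.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_equal(back$mz, 150.5)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-6)
})

test_that("processed-mode imzML is unified onto the union axis", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "proc.imzML")
  msimaps:::write_imzml_processed(
    path, cbind(c(1, 2), c(1, 1)),
    mz_list = list(c(100.0, 200.0), c(100.0, 300.0)),
    int_list = list(c(1, 2), c(3, 4)))
  ds <- read_imzml(path)
  expect_equal(ds$mz, c(100, 200, 300))
  expect_equal(ds$intensities,
               rbind(c(1, 2, 0), c(3, 0, 4)), tolerance = 1e-6)
})

test_that("imzML reader fails clearly on missing or malformed companions", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  path <- file.path(dir, "x.imzML")
  write_imzml(ds, path)
  file.remove(msimaps:::ibd_path_for(path))
  expect_error(read_imzml(path), "\\.ibd")

  bad <- file.path(dir, "bad.imzML")
  writeLines("<mzML><unclosed>", bad)
  writeLines("", msimaps:::ibd_path_for(bad))
  expect_error(read_imzml(bad), "parse")
})

test_that("HDF5 store round trips losslessly and enumerates datasets", {
  dir <- withr::local_tempdir()
  store <- file.path(dir, "s.h5")
  ds <- tiny_dataset("a")
  save_store(ds, store)
  back <- load_store(store)
  expect_equal(back$mz, ds$mz)
  expect_identical(back$coords, ds$coords)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-6)
  expect_identical(back$dataset_id, "a")

  ds2 <- tiny_dataset("b")
  ds2$intensities <- ds2$intensities * 2
  save_store(ds2, store)
  expect_setequal(list_store(store), c("a", "b"))
  expect_error(load_store(store), "dataset_id")
  expect_equal(load_store(store, "b")$intensities, ds2$intensities,
               tolerance = 1e-6)
})

test_that("the store rejects files without a valid schema tag", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.h5")
  writeLines("not an hdf5 file", bad)
  expect_error(load_store(bad), "store")
})
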