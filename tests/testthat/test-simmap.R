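test_that("the byte transform scales each spectrum to 0..255", {
  ds <- msi_dataset(3, 1, c(1, 2, 3), cbind(i = 1:3, j = c(1, 1, 1)),
                    rbind(c(0, 1, 2), c(0, 0, 0), c(4, 4, 4)))
  b <- to_bytes(ds)
  expect_equal(b$bytes[1, ], c(0L, 128L, 255L))   # round half away
  expect_equal(b$bytes[2, ], c(0L, 0L, 0L))       # all-zero stays zero
  expect_equal(b$bytes[3, ], c(255L, 255L, 255L))
  expect_true(all(b$bytes >= 0 & b$bytes <= 255))
})

test_that("a 512-step ramp spectrum carries exactly 256 byte values", {
  ds <- msi_dataset(1, 1, seq(100, 611.1, length.out = 512), cbind(1, 1),
                    matrix(0:511, nrow = 1))
  b <- to_bytes(ds)
  expect_equal(length(unique(as.vector(b$bytes))), 256)
})

test_that("similarity follows the inverse angular distance", {
  ds <- msi_dataset(3, 1, c(1, 2), cbind(i = 1:3, j = c(1, 1, 1)),
                    rbind(c(200, 200), c(200, 0), c(0, 200)))
  b <- to_bytes(ds)
  f <- similarity_field(b, 2, 1)
  expect_equal(f$values[1, 2], 255)   # self
  expect_equal(f$values[1, 3], 0)     # orthogonal
  expect_equal(f$values[1, 1], 128)   # 45 degrees -> round(127.5)
})

test_that("similarity errors on non-spectral or zero references", {
  ds <- msi_dataset(2, 2, c(1, 2), cbind(i = 1:2, j = c(1, 1)),
                    rbind(c(1, 0), c(0, 0)))
  b <- to_bytes(ds)
  expect_error(similarity_field(b, 1, 2), "not a spectral")
  expect_error(similarity_field(b, 2, 1), "all-zero")
})

test_that("similarity is invariant to rescaling one original spectrum", {
  ds <- tiny_dataset()
  base <- similarity_field(to_bytes(ds), ds$coords[1, 1], ds$coords[1, 2])
  for (lambda in c(0.1, 7)) {
    scaled <- ds
    scaled$intensities[3, ] <- lambda * scaled$intensities[3, ]
    f <- similarity_field(to_bytes(scaled),
                          ds$coords[1, 1], ds$coords[1, 2])
    expect_equal(f$values, base$values)
  }
})

test_that("similarity is symmetric in pixel and reference", {
  ds <- tiny_dataset()
  b <- to_bytes(ds)
  for (a in 1:2) for (z in 3:5) {
    ca <- ds$coords[a, ]; cz <- ds$coords[z, ]
    fa <- similarity_field(b, ca[1], ca[2])
    fz <- similarity_field(b, cz[1], cz[2])
    expect_equal(fa$values[cz[2], cz[1]], fz$values[ca[2], ca[1]])
  }
})

test_that("browsing equals the byte channel image", {
  ds <- tiny_dataset()
  b <- to_bytes(ds)
  for (k in c(1, 5, 10)) {
    f <- browsing_field(b, k)
    for (s in seq_len(n_pixels(ds)))
      expect_equal(f$values[ds$coords[s, 2], ds$coords[s, 1]],
                   b$bytes[s, k])
  }
  zero <- msi_dataset(1, 1, c(1, 2), cbind(1, 1), matrix(c(1, 0), 1))
  expect_equal(browsing_field(to_bytes(zero), 2)$values,
               matrix(0, 1, 1))
  expect_error(browsing_field(b, 99), "out of range")
})

test_that("grouping reduces to browsing for a single channel", {
  ds <- tiny_dataset()
  b <- to_bytes(ds)
  for (k in c(2, 7))
    expect_equal(grouping_field(b, k)$values, browsing_field(b, k)$values)
  # duplicated channel in the set equals either alone
  expect_equal(grouping_field(b, c(3, 3))$values,
               browsing_field(b, 3)$values)
  # brute-force mean oracle
  M <- c(1, 4, 9)
  g <- grouping_field(b, M)
  for (s in seq_len(n_pixels(ds)))
    expect_equal(g$values[ds$coords[s, 2], ds$coords[s, 1]],
                 floor(mean(b$bytes[s, M]) + 0.5))
  expect_error(grouping_field(b, integer(0)), "empty")
})

test_that("field normalization stretches to the full byte range", {
  ds <- msi_dataset(3, 1, 1, cbind(i = 1:3, j = c(1, 1, 1)),
                    matrix(c(10, 20, 30), 3, 1))
  f <- msimaps:::new_field(3, 1, ds$coords, c(10, 20, 30))
  nf <- normalize_field(f)
  expect_equal(sort(msimaps:::field_values(nf)), c(0, 127.5, 255))

  const <- msimaps:::new_field(3, 1, ds$coords, c(7, 7, 7))
  expect_equal(msimaps:::field_values(normalize_field(const)), c(0, 0, 0))

  full <- msimaps:::new_field(3, 1, ds$coords, c(0, 100, 255))
  expect_equal(msimaps:::field_values(normalize_field(full)),
               c(0, 100, 255))
})

test_that("color scales map endpoints faithfully", {
  ds <- msi_dataset(2, 1, 1, cbind(i = 1:2, j = c(1, 1)),
                    matrix(c(1, 2), 2, 1))
  f <- msimaps:::new_field(2, 1, ds$coords, c(0, 255))
  gray <- apply_colormap(f, "gray")
  expect_equal(gray[1, 1, ], c(0, 0, 0))
  expect_equal(gray[1, 2, ], c(255, 255, 255))
  # gray is bit-exact identity on the value channel
  f2 <- msimaps:::new_field(2, 1, ds$coords, c(37, 201))
  expect_equal(apply_colormap(f2, "gray")[1, , 1], c(37, 201))

  fire <- apply_colormap(f, "fire")
  expect_equal(fire[1, 1, ], c(0, 0, 0))
  expect_equal(fire[1, 2, ], c(255, 255, 255))
  expect_error(apply_colormap(f, "viridis"), "unknown")
})

test_that("rendering is deterministic and conserves the histogram", {
  ph <- make_phantom(small_phantom_spec(seed = 5))
  b <- to_bytes(ph$dataset)
  ref <- c(10, 10)
  dir <- withr::local_tempdir()
  m1 <- render_map(b, "similarity", ref = ref,
                   out_prefix = file.path(dir, "a"))
  m2 <- render_map(b, "similarity", ref = ref,
                   out_prefix = file.path(dir, "b"))
  expect_identical(readBin(file.path(dir, "a.png"), "raw", 1e6),
                   readBin(file.path(dir, "b.png"), "raw", 1e6))
  expect_equal(sum(m1$histogram), n_pixels(ph$dataset))
  expect_true(all(m1$raw$values >= 0 & m1$raw$values <= 255))
  expect_true(all(m1$normalized$values >= 0 &
                    m1$normalized$values <= 255))
})

test_that("non-spectral pixels render as the background color", {
  ds <- msi_dataset(2, 2, c(1, 2), cbind(i = 1:2, j = c(1, 1)),
                    rbind(c(5, 1), c(1, 5)))
  b <- to_bytes(ds)
  m <- render_map(b, "similarity", ref = c(1, 1), scale = "fire")
  expect_equal(m$image[2, 1, ], c(0, 0, 0))
  expect_equal(m$image[2, 2, ], c(0, 0, 0))
})

test_that("the reference spectrum falls back to the byte mean", {
  ds <- msi_dataset(2, 2, c(1, 2), cbind(i = 1:2, j = c(1, 1)),
                    rbind(c(4, 2), c(2, 4)))
  b <- to_bytes(ds)
  expect_equal(reference_spectrum(b, 2, 1), as.numeric(b$bytes[2, ]))
  expect_equal(reference_spectrum(b, 1, 2), colMeans(b$bytes))
})
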