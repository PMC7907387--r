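# The slower UMAP-based checks run on reduced phantoms; the full-size
# recovery experiment lives in the acceptance suite.

test_that("the embedding chain depends on the channel count", {
  ph <- make_phantom(small_phantom_spec(seed = 1))   # d = 120
  emb <- embed_pixels(ph$dataset, seed = 1)
  expect_equal(emb$method_chain, "umap")
  expect_equal(nrow(emb$coords2d), n_pixels(ph$dataset))
  expect_true(all(is.finite(emb$coords2d)))

  # above 1000 channels a tSVD pre-step is inserted
  set.seed(9)
  wide <- msi_dataset(6, 5, seq(100, 2000, length.out = 1500),
                      as.matrix(expand.grid(i = 1:6, j = 1:5)),
                      matrix(runif(30 * 1500), 30, 1500))
  emb2 <- embed_pixels(wide, seed = 1, tsvd_components = 10)
  expect_equal(emb2$method_chain, c("tsvd", "umap"))

  expect_error(embed_pixels(msi_dataset(2, 1, 1, cbind(i = 1:2,
                                                       j = c(1, 1)),
                                        matrix(1, 2, 1)), seed = 1),
               "at least 10")
})

test_that("identical spectra share one embedding point and seeds fix it", {
  ph <- make_phantom(small_phantom_spec(seed = 2, sigma_noise = 0,
                                        sigma_scale = 0))
  ds <- ph$dataset
  emb <- embed_pixels(ds, seed = 3)
  # zero-noise matrix pixels are identical spectra
  m <- which(ph$truth$labels == "matrix")
  expect_equal(max(dist(emb$coords2d[m[1:5], ])), 0)

  emb2 <- embed_pixels(ds, seed = 3)
  expect_identical(emb$coords2d, emb2$coords2d)
})

test_that("selection-based classification labels exactly the selection", {
  ds <- tiny_dataset()
  emb <- structure(list(coords2d = cbind(c(0, 1, 2, 3, 4),
                                         c(0, 0, 0, 0, 0)),
                        method_chain = "umap", seed = 1L),
                   class = "embedding2d")
  # polygon covering the whole embedding
  all_m <- classify_by_selection(ds, emb,
                                 list(polygon = rbind(c(-1, -1), c(5, -1),
                                                      c(5, 1), c(-1, 1))),
                                 "matrix")
  expect_true(all(all_m$labels == "matrix"))

  # polygon covering points 2..3 only
  part <- classify_by_selection(ds, emb,
                                list(polygon = rbind(c(0.5, -1), c(2.5, -1),
                                                     c(2.5, 1), c(0.5, 1))),
                                "artifact")
  expect_equal(as.character(part$labels),
               c("sample", "artifact", "artifact", "sample", "sample"))

  # explicit coordinate list of 3 pixels
  three <- classify_by_selection(ds, NULL,
                                 list(coords = ds$coords[c(1, 3, 5), ]),
                                 "matrix")
  expect_equal(sum(three$labels == "matrix"), 3)

  expect_error(classify_by_selection(ds, emb,
                                     list(polygon = rbind(c(0, 0),
                                                          c(1, 1))),
                                     "matrix"), "3 vertices")
  expect_error(classify_by_selection(ds, NULL,
                                     list(coords = ds$coords[1, ,
                                                             drop = FALSE]),
                                     "tissue"), "label")
})

test_that("class-mean subtraction clamps at zero and never increases", {
  ds <- msi_dataset(2, 1, c(1, 2), cbind(i = 1:2, j = c(1, 1)),
                    rbind(c(5, 2), c(3, 4)))
  cls <- msimaps:::new_classification(c("sample", "matrix"), "manual")
  out <- subtract_class_mean(ds, cls, "matrix")
  expect_equal(out$intensities[1, ], c(2, 0))   # 5-3, 2-4 clamped
  expect_equal(out$intensities[2, ], c(0, 0))
  expect_true(all(out$intensities >= 0))
  expect_true(all(out$intensities <= ds$intensities))
  expect_error(subtract_class_mean(ds, cls, "artifact"), "no pixels")
})

test_that("zero-noise matrix pixels are zeroed exactly by subtraction", {
  ph <- make_phantom(small_phantom_spec(seed = 4, sigma_noise = 0,
                                        sigma_scale = 0))
  cls <- msimaps:::new_classification(as.character(ph$truth$labels),
                                      "manual")
  out <- subtract_class_mean(ph$dataset, cls, "matrix")
  m <- ph$truth$labels == "matrix"
  expect_equal(max(out$intensities[m, ]), 0)
})

test_that("pixel removal drops rows but keeps the grid", {
  ds <- tiny_dataset()
  cls0 <- msimaps:::new_classification(rep("sample", 5), "manual")
  expect_error(remove_pixels(ds, cls0, "matrix"), NA)
  expect_equal(n_pixels(remove_pixels(ds, cls0, "matrix")), 5)

  cls1 <- msimaps:::new_classification(
    c("matrix", "matrix", "matrix", "matrix", "sample"), "manual")
  out <- remove_pixels(ds, cls1, "matrix")
  expect_equal(n_pixels(out), 1)
  expect_equal(out$width, ds$width)
  expect_equal(out$height, ds$height)

  cls2 <- msimaps:::new_classification(rep("artifact", 5), "manual")
  expect_error(remove_pixels(ds, cls2, "artifact"), "empty")
})

test_that("uniform datasets classify as all sample with a warning", {
  base <- rep(c(1, 0), length.out = 20)
  ds <- msi_dataset(4, 3, seq_len(20),
                    cbind(i = c(1:4, 1:4, 1:4), j = rep(1:3, each = 4)),
                    matrix(rep(base, 12), 12, byrow = TRUE))
  emb <- embed_pixels(ds, seed = 1)
  expect_warning(cls <- auto_classify(ds, emb), "sample")
  expect_true(all(cls$labels == "sample"))
})

test_that("automatic classification recovers small-phantom structure", {
  ph <- make_phantom(small_phantom_spec(seed = 0))
  emb <- embed_pixels(ph$dataset, seed = 0)
  cls <- auto_classify(ph$dataset, emb)
  truth <- ph$truth$labels
  expect_gte(f1_score(cls$labels, truth, "matrix"), 0.9)
  expect_gte(sum(cls$labels == "artifact" & truth == "artifact") /
               sum(truth == "artifact"), 0.8)

  # phantom without artifacts: none may be invented by the cluster rules
  ph0 <- make_phantom(small_phantom_spec(seed = 0, artifact_count = 0L))
  emb0 <- embed_pixels(ph0$dataset, seed = 0)
  cls0 <- auto_classify(ph0$dataset, emb0)
  expect_equal(sum(cls0$labels == "artifact"), 0)
})

test_that("iterative cleaning equals single-pass when artifact-free", {
  ph <- make_phantom(small_phantom_spec(seed = 6, artifact_count = 0L))
  ds <- ph$dataset
  res <- iterative_clean(ds, seed = 2)
  emb <- embed_pixels(ds, seed = 2)
  cls <- auto_classify(ds, emb)
  single <- if (any(cls$labels == "matrix"))
    subtract_class_mean(ds, cls, "matrix") else ds
  expect_equal(res$dataset$intensities, single$intensities)
  expect_identical(res$classification$labels, cls$labels)
})
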