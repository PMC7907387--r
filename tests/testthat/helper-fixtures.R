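# Small in-code fixtures shared across test files.

# a deterministic 4 x 3 grid dataset with 5 spectral pixels, 10 channels
tiny_dataset <- function(dataset_id = "tiny") {
  set.seed(42)
  mz <- sort(runif(10, 100, 500))
  coords <- cbind(i = c(1L, 2L, 3L, 4L, 2L), j = c(1L, 1L, 2L, 3L, 3L))
  intens <- matrix(round(runif(50, 0, 100), 3), nrow = 5, ncol = 10)
  msi_dataset(4, 3, mz, coords, intens, dataset_id = dataset_id)
}

# small phantom used where the full 64 x 64 x 500 default would be slow;
# overrides passed through ... win over the helper's defaults
small_phantom_spec <- function(seed, ...) {
  base <- list(width = 28L, height = 28L, d = 120L, mz_lo = 100,
               mz_hi = 220, matrix_border = 4L,
               regions = list(
                 list(cx = 10, cy = 10, radius = 4,
                      channels = c(20L, 40L, 60L), height = 1),
                 list(cx = 20, cy = 19, radius = 4,
                      channels = c(30L, 50L, 70L), height = 1)),
               background_channels = c(90L, 100L),
               matrix_channels = c(10L, 14L, 80L),
               artifact_count = 8L, artifact_types = 2L,
               seed = seed)
  do.call(phantom_spec, utils::modifyList(base, list(...)))
}

f1_score <- function(pred, truth, label) {
  tp <- sum(pred == label & truth == label)
  fp <- sum(pred == label & truth != label)
  fn <- sum(pred != label & truth == label)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}
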