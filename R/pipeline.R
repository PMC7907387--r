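# Pipeline driver: chains the processing stages with a serializable
# configuration and writes a run manifest next to the outputs.

PIPELINE_SCHEMA_VERSION <- "1"

pipeline_defaults <- function() list(
  input = NULL,            # path to .imzML or .h5, or "phantom"
  dataset_id = NULL,
  out_dir = ".",
  seed = 1L,
  phantom = list(),        # overrides passed to phantom_spec()
  stages = list(convert = TRUE, normalize = TRUE, clean = TRUE,
                pick = TRUE, render = TRUE),
  normalize = list(method = "mfc"),
  clean = list(iterative = TRUE),
  pick = list(z_t = 0.019, z_w = NA, relative = TRUE,
              deisotope = FALSE, tol = 0.01),
  render = list(mode = "similarity", ref = NULL, channel = 1L,
                channels = 1L, scale = "fire"))

#' Build a pipeline configuration
#'
#' Merges user settings into the defaults; unknown keys (at top level or
#' inside a stage block) raise a validation error naming the key. The
#' resolved configuration is serializable to JSON and is written beside
#' the outputs of every run.
#'
#' @param ... named settings, e.g. `input = "x.imzML"`,
#'   `pick = list(z_t = 0.019)`, `seed = 7`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- pipeline_defaults()
  for (key in names(user)) {
    if (!key %in% names(cfg))
      stop("unknown configuration key '", key, "'")
    if (is.list(cfg[[key]]) && !is.null(names(cfg[[key]])) &&
        key != "phantom" && key != "regions") {
      sub <- user[[key]]
      for (k2 in names(sub)) {
        if (!k2 %in% names(cfg[[key]]))
          stop("unknown configuration key '", key, ".", k2, "'")
        cfg[[key]][[k2]] <- sub[[k2]]
      }
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the processing pipeline
#'
#' Executes convert, normalize, clean, pick and render in order, skipping
#' disabled stages, and writes every intermediate product plus a manifest
#' (`manifest.json`: configuration, seed, stage list, output file MD5
#' hashes) into `config$out_dir`. A stage failure aborts with an error
#' naming the stage. With the pick stage disabled, rendering uses all
#' channels.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the final `dataset`, the `manifest` and
#'   the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  outputs <- character(0)
  stages_run <- character(0)
  truth <- NULL

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # convert: bring the input into the HDF5 store
  ds <- run_stage("convert", function() {
    if (identical(config$input, "phantom") || is.null(config$input)) {
      spec <- do.call(phantom_spec,
                      c(config$phantom,
                        if (is.null(config$phantom$seed))
                          list(seed = config$seed)))
      ph <- make_phantom(spec)
      truth <<- ph$truth
      ph$dataset
    } else if (grepl("\\.imzml$", config$input, ignore.case = TRUE)) {
      read_imzml(config$input, dataset_id = config$dataset_id)
    } else {
      load_store(config$input, config$dataset_id)
    }
  })
  if (isTRUE(config$stages$convert)) {
    store <- file.path(config$out_dir, "dataset.h5")
    if (file.exists(store)) unlink(store)
    save_store(ds, store)
    outputs <- c(outputs, store)
    stages_run <- c(stages_run, "convert")
  }

  if (isTRUE(config$stages$normalize)) {
    res <- run_stage("normalize", function()
      intra_normalize(ds, config$normalize$method))
    ds <- res$dataset
    p <- file.path(config$out_dir, "normalization.csv")
    write_normalization_csv(res$report, p)
    outputs <- c(outputs, p)
    stages_run <- c(stages_run, "normalize")
  }

  if (isTRUE(config$stages$clean)) {
    res <- run_stage("clean", function() {
      if (isTRUE(config$clean$iterative))
        iterative_clean(ds, config$seed)
      else {
        emb <- embed_pixels(ds, config$seed)
        cls <- auto_classify(ds, emb)
        out <- if (any(cls$labels == "matrix"))
          subtract_class_mean(ds, cls, "matrix") else ds
        list(dataset = out, classification = cls, embedding = emb)
      }
    })
    ds <- res$dataset
    prefix <- file.path(config$out_dir, "labels")
    write_classification(ds, res$classification, prefix)
    embp <- file.path(config$out_dir, "embedding.csv")
    utils::write.csv(data.frame(x = res$embedding$coords2d[, 1],
                                y = res$embedding$coords2d[, 2]),
                     embp, row.names = FALSE)
    outputs <- c(outputs, paste0(prefix, ".csv"), paste0(prefix, ".png"),
                 embp)
    stages_run <- c(stages_run, "clean")
  }

  if (isTRUE(config$stages$pick)) {
    ds <- run_stage("pick", function() {
      mu <- mean_spectrum(ds)
      z_w <- config$pick$z_w
      if (!is.null(z_w) && !is.na(z_w)) mu <- winsorize_mean(mu, z_w)
      ps <- detect_peaks(mu, config$pick$z_t,
                         if (is.null(z_w)) NA_integer_ else z_w,
                         relative = isTRUE(config$pick$relative))
      if (isTRUE(config$pick$deisotope))
        ps <- deisotope(ps, config$pick$tol)
      p <- file.path(config$out_dir, "peaks.csv")
      write_peaks_csv(ps, p)
      outputs <<- c(outputs, p)
      reduce_to_peaks(ds, ps)
    })
    stages_run <- c(stages_run, "pick")
  }

  if (isTRUE(config$stages$render)) {
    run_stage("render", function() {
      bds <- to_bytes(ds)
      ref <- config$render$ref
      if (config$render$mode == "similarity" && is.null(ref)) {
        # default reference: the spectral pixel nearest the grid center
        ctr <- c(round(ds$width / 2), round(ds$height / 2))
        d2 <- (ds$coords[, 1] - ctr[1])^2 + (ds$coords[, 2] - ctr[2])^2
        ref <- ds$coords[which.min(d2), ]
      }
      prefix <- file.path(config$out_dir, "map")
      render_map(bds, mode = config$render$mode, ref = ref,
                 channel = config$render$channel,
                 channels = config$render$channels,
                 scale = config$render$scale, out_prefix = prefix)
      outputs <<- c(outputs, paste0(prefix, ".png"),
                    paste0(prefix, "_field.csv"),
                    paste0(prefix, "_histogram.csv"))
    })
    stages_run <- c(stages_run, "render")
  }

  manifest <- list(
    schema = PIPELINE_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("msimaps")),
    seed = config$seed,
    stages = stages_run,
    config = unclass(config),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(dataset = ds, truth = truth, manifest = manifest,
                 manifest_path = mp))
}
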