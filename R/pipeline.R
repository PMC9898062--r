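#' @title Pipeline orchestration, configuration and overlays
#' @description Runs the full stage sequence — downsample, shading
#'   correction, tissue mask, boundary classification, segmentation,
#'   measurement, filtering, typing — on one or more section images,
#'   writing each stage's suffix-named artifact (`_Mask`, `_Lamin_Masked`,
#'   `Masked_Probabilities`, `_Segmentation`, `_MFI`, `_Filt`, `_check[X]`)
#'   plus a run log, and returning the per-sample composition.
#' @name cli_app
NULL

#' Pipeline configuration
#'
#' Defaults follow the published protocol: 4x downsampling to ~2.6 um/px,
#' mask feather sigma 4 px, 3-px boundary strip, certainty percentiles
#' 5/95, CSA percentiles 10/99, circularity 1st percentile, at least 100
#' fibers per sample, 2% cluster pruning.
#'
#' @param input_paths character vector of multichannel TIFF paths (each
#'   with a JSON sidecar); alternatively a list of in-memory phantoms (as
#'   returned by [generate_phantom()]) via `phantoms`.
#' @param phantoms optional list of phantom bundles to run instead of
#'   files.
#' @param out_dir output directory; created if missing.
#' @param downsample_factor block-averaging factor applied first (1 = skip).
#' @param shading_correct estimate and divide out a median shading profile.
#' @param mask_sigma_px,mask_min_area_px automatic tissue-mask parameters.
#' @param mask_edits optional per-image list of [polygon_edit()] lists.
#' @param lamin_sigma_px feather sigma for the masked laminin image.
#' @param classifier optional pre-trained [train_classifier()] model; when
#'   `NULL` and phantoms are supplied, a classifier is trained on their
#'   truth annotations.
#' @param annotations_per_class truth annotations sampled per class when
#'   training on phantoms.
#' @param seg segmentation parameters, see [segmentation_params()].
#' @param strip_width_px boundary strip width for measurement.
#' @param filter_cfg a [filter_config()].
#' @param typing_cfg a [typing_config()].
#' @param seed master seed for classifier training and annotation sampling.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_paths = NULL, phantoms = NULL,
                            out_dir = tempfile("myotyper_run_"),
                            downsample_factor = 1,
                            shading_correct = FALSE,
                            mask_sigma_px = 10, mask_min_area_px = 2000,
                            mask_edits = NULL,
                            lamin_sigma_px = 4,
                            classifier = NULL,
                            annotations_per_class = 300,
                            seg = segmentation_params(),
                            strip_width_px = 3,
                            filter_cfg = filter_config(),
                            typing_cfg = typing_config(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_label_tiff <- function(labels, path) {
  write_float_tiff(as_plain_matrix(labels) * 1.0, path)
}

stage_fail <- function(stage, e) {
  stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the full pipeline
#'
#' Executes every stage per image, pools the measurement tables, filters,
#' types, and writes the composition table. All artifacts land in
#' `config$out_dir`; partial outputs are retained when a stage aborts (the
#' error names the stage).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `out_dir`, per-image `tables`, pooled
#'   `flags`, `model` (a `cluster_model`) and `composition`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  images <- list(); truths <- list()
  if (!is.null(config$phantoms)) {
    for (ph in config$phantoms) {
      images[[ph$image$sample_id]] <- ph$image
      truths[[ph$image$sample_id]] <- ph
    }
  } else if (!is.null(config$input_paths)) {
    for (p in config$input_paths) {
      img <- tryCatch(read_multichannel_tiff(p), error = function(e) stage_fail("read", e))
      images[[img$sample_id]] <- img
    }
  } else stop("pipeline failed at stage 'read': no inputs configured")

  log <- list(package_version = as.character(utils::packageVersion("myotyper")),
              r_version = R.version.string,
              seed = config$seed,
              n_images = length(images),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  # preprocess
  for (id in names(images)) {
    if (config$downsample_factor > 1) {
      images[[id]] <- tryCatch(
        downsample_by_averaging(images[[id]], config$downsample_factor),
        error = function(e) stage_fail("downsample", e))
    }
  }
  if (isTRUE(config$shading_correct)) {
    tryCatch({
      nch <- n_channels(images[[1]])
      for (ch in seq_len(nch)) {
        profs <- lapply(images, estimate_shading_profile, channel = ch)
        med <- median_shading_profile(profs)
        write_float_tiff(as_plain_matrix(med),
                         file.path(config$out_dir, sprintf("shading_ch%d.tif", ch)))
        for (id in names(images)) {
          pix <- images[[id]]$pixels
          pix[, , ch] <- round(pmin(pmax(pix[, , ch] / as_plain_matrix(med), 0), MAX_16BIT))
          images[[id]]$pixels <- pix
        }
      }
    }, error = function(e) stage_fail("shade", e))
  }

  # mask + masked laminin
  masks <- list(); lamins <- list()
  for (id in names(images)) {
    masks[[id]] <- tryCatch(
      auto_tissue_mask(images[[id]], sigma_px = config$mask_sigma_px,
                       min_area_px = config$mask_min_area_px),
      error = function(e) stage_fail("mask", e))
    if (!is.null(config$mask_edits[[id]])) {
      masks[[id]] <- apply_mask_edits(masks[[id]], config$mask_edits[[id]])
    }
    tiff::writeTIFF((as_plain_matrix(masks[[id]]) > 0) * 1,
                    file.path(config$out_dir, paste0(id, "_Mask.tif")),
                    bits.per.sample = 8L)
    lamins[[id]] <- tryCatch(
      masked_laminin(images[[id]], masks[[id]], config$lamin_sigma_px),
      error = function(e) stage_fail("masked_laminin", e))
    write_float_tiff(lamins[[id]],
                     file.path(config$out_dir, paste0(id, "_Lamin_Masked.tif")))
  }

  # classifier
  clf <- config$classifier
  if (is.null(clf)) {
    if (length(truths) == 0) {
      stop("pipeline failed at stage 'classify': no classifier and no phantom truth to train on")
    }
    clf <- tryCatch({
      id <- names(truths)[1]
      ann <- sample_annotations(truths[[id]]$labels, config$annotations_per_class,
                                seed = config$seed)
      train_classifier(lamins[[id]], ann, seed = config$seed)
    }, error = function(e) stage_fail("classify-train", e))
  }

  tables <- list(); labmaps <- list(); flags_by_image <- list()
  for (id in names(images)) {
    prob <- tryCatch(predict_probability(clf, lamins[[id]]),
                     error = function(e) stage_fail("classify-predict", e))
    write_float_tiff(as_plain_matrix(prob),
                     file.path(config$out_dir, paste0(id, "_Masked_Probabilities.tif")))
    lab <- tryCatch({
      l <- segment_fibers(prob, masks[[id]], config$seg)
      filter_labels(l, min_area_px = config$seg$min_seed_area_px,
                    border_policy = config$seg$border_policy)
    }, error = function(e) stage_fail("segment", e))
    labmaps[[id]] <- lab
    write_label_tiff(lab, file.path(config$out_dir, paste0(id, "_Segmentation.tif")))

    tab <- tryCatch({
      img5 <- append_classification_channel(images[[id]], prob)
      dm <- edge_distance_map(masks[[id]], images[[id]]$pixel_size_um)
      measure_section(img5, lab, dm, strip_width_px = config$strip_width_px)
    }, error = function(e) stage_fail("measure", e))
    tables[[id]] <- tab
    write_mfi_table(tab, file.path(config$out_dir, paste0(id, "_MFI.txt")))
  }

  # pooled filtering
  pooled <- do.call(rbind, lapply(names(tables), function(id) {
    df <- as.data.frame(tables[[id]])
    df$sample_id <- id
    df$roi_id <- paste0(id, ":", df$roi_id)
    df
  }))
  pooled <- mfi_table(pooled, attr(tables[[1]], "n_channels"), provenance = "pooled")
  flags <- tryCatch(qc_filter(pooled, config$filter_cfg),
                    error = function(e) stage_fail("filter", e))
  for (id in names(tables)) {
    sel <- startsWith(flags$roi_id, paste0(id, ":"))
    fl <- flags[sel, , drop = FALSE]
    fl$roi_id <- sub(paste0("^", id, ":"), "", fl$roi_id)
    write_filt_table(tables[[id]], fl,
                     file.path(config$out_dir, paste0(id, "_Filt.txt")))
    # overlay of aggregate codes
    vals <- stats::setNames(fl$aggregate_code, fl$roi_id)
    ov <- render_overlay(labmaps[[id]], vals)
    png::writePNG(ov, file.path(config$out_dir, paste0(id, "_check4.png")))
    flags_by_image[[id]] <- fl
  }

  # typing on surviving fibers, pooled across images
  model <- tryCatch({
    keep <- flags$roi_id[flags$aggregate_code == 1]
    r <- as.data.frame(pooled)
    iso <- r[r$channel == 1 & r$roi_id %in% keep, c("roi_id", "sample_id")]
    m <- sapply(1:3, function(ch) {
      rr <- r[r$channel == ch, c("roi_id", "Mean")]
      rr$Mean[match(iso$roi_id, rr$roi_id)]
    })
    colnames(m) <- c("MYHC1", "MYHC2A", "MYHC2X_OR_2B")
    fiber_typing(m, iso$sample_id, config$typing_cfg)
  }, error = function(e) stage_fail("type", e))

  comp_path <- file.path(config$out_dir, "composition.txt")
  utils::write.table(data.frame(sample = rownames(model$composition),
                                model$composition, check.names = FALSE),
                     comp_path, sep = "\t", quote = FALSE, row.names = FALSE)

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  log$config_md5 <- unname(tools::md5sum(cfg_path))
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))

  invisible(list(out_dir = config$out_dir, tables = tables, flags = flags,
                 model = model, composition = model$composition))
}

#' Render a per-ROI value overlay
#'
#' Paints every ROI with `palette(value)`; background is black. Used for
#' the aggregate-code check image (4 grey levels) and for cluster-colour
#' overlays.
#'
#' @param labels a [label_map()].
#' @param value_of named numeric vector in `[0, 1]`: label id (as written
#'   in the measurement table, zero-padded or not) -> value. A label
#'   missing from `value_of` is painted black; an unknown id in `value_of`
#'   is an error.
#' @param palette function value -> colour (anything [grDevices::col2rgb()]
#'   accepts); defaults to grey levels.
#' @return H x W x 3 numeric array in `[0, 1]` (writable with
#'   [png::writePNG()]).
#' @export
render_overlay <- function(labels, value_of, palette = grDevices::gray) {
  lab <- as_plain_matrix(labels)
  if (length(value_of)) {
    if (is.null(names(value_of))) stop("value_of must be named by label id")
    if (any(value_of < 0 | value_of > 1)) stop("values must lie in [0, 1]")
    ids <- suppressWarnings(as.integer(names(value_of)))
    if (anyNA(ids)) stop("value_of names must be label ids")
    present <- unique(lab[lab > 0])
    unknown <- setdiff(ids, present)
    if (length(unknown)) stop("unknown label id(s) in value map: ",
                              paste(unknown, collapse = ", "))
  } else ids <- integer(0)
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (k in seq_along(ids)) {
    col <- grDevices::col2rgb(palette(value_of[k]))[, 1] / 255
    sel <- lab == ids[k]
    for (ch in 1:3) {
      plane <- out[, , ch]; plane[sel] <- col[ch]; out[, , ch] <- plane
    }
  }
  out
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips the scalar configuration fields losslessly so a run is
#' reproducible from its logged config plus seed. In-memory fields
#' (phantoms, classifier) are recorded by fingerprint only.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$phantoms <- if (is.null(x$phantoms)) NULL else
    sprintf("<%d in-memory phantom(s)>", length(x$phantoms))
  x$classifier <- if (is.null(x$classifier)) NULL else "<pre-trained classifier>"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$phantoms <- NULL
  if (is.character(x$classifier)) x$classifier <- NULL
  cfg <- do.call(pipeline_config, x[intersect(names(x), names(formals(pipeline_config)))])
  cfg
}
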