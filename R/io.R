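# Dataset readers/writers, configuration files, checkpoints and provenance.
#
# Conventions: arrays are channel-first with origin at the top-left; masks
# are 0/1 integers everywhere inside the package and 0/255 8-bit PNGs on
# disk, binarised at >= 128 on read (so external dermoscopy datasets with
# the usual mask encoding can be dropped in unchanged). Arbitrary input
# sizes are bilinearly resized (not cropped) to the working resolution.

read_image_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package; convert to PNG",
           call. = FALSE)
    }
    img <- EBImage::imageData(EBImage::readImage(path))
    img <- aperm(img, if (length(dim(img)) == 3L) c(2, 1, 3) else c(2, 1))
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim2(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (any(dim(img)[1:2] == 0L)) stop("size-zero image: ", path, call. = FALSE)
  img                                        # (H, W, C) in [0, 1]
}

# separable bilinear resize of a (H, W) matrix stack
resize_weights <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  lo <- floor(pos); hi <- pmin(lo + 1, n_in)
  f <- pos - lo
  w <- matrix(0, n_out, n_in)
  w[cbind(seq_len(n_out), lo)] <- w[cbind(seq_len(n_out), lo)] + (1 - f)
  w[cbind(seq_len(n_out), hi)] <- w[cbind(seq_len(n_out), hi)] + f
  w
}

resize_bilinear <- function(img, target) {
  # img (C, H, W) -> (C, target[1], target[2])
  d <- dim(img)
  if (identical(d[2:3], as.integer(target))) return(img)
  wr <- resize_weights(d[2], target[1])
  wc <- resize_weights(d[3], target[2])
  out <- array(0, c(d[1], target[1], target[2]))
  for (c in seq_len(d[1])) out[c, , ] <- wr %*% img[c, , ] %*% t(wc)
  out
}

resize_nearest <- function(m, target) {
  if (identical(dim(m), as.integer(target))) return(m)
  ri <- pmin(pmax(round((seq_len(target[1]) - 0.5) * nrow(m) / target[1] + 0.5), 1), nrow(m))
  ci <- pmin(pmax(round((seq_len(target[2]) - 0.5) * ncol(m) / target[2] + 0.5), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Load an image/mask pair at the working resolution
#'
#' The image is bilinearly resized to `target_size`, scaled to `[0, 1]` and
#' returned channel-first; the mask is nearest-neighbour resized and
#' binarised at >= 128 (of 255).
#'
#' @param image_path,mask_path file paths (PNG; JPEG images via EBImage).
#' @param target_size integer pair, default `c(256, 256)`.
#' @return `list(image = (3, H, W) array, mask = (H, W) 0/1 matrix)`.
#' @export
load_pair <- function(image_path, mask_path, target_size = c(256L, 256L)) {
  img <- read_image_file(image_path)
  if (dim(img)[3] == 1L) img <- img[, , c(1, 1, 1), drop = FALSE]
  img <- aperm(img[, , 1:3, drop = FALSE], c(3, 1, 2))
  img <- resize_bilinear(img, target_size)
  msk <- read_image_file(mask_path)[, , 1]
  msk <- resize_nearest(msk, target_size)
  msk <- matrix(as.integer(msk >= 128 / 255), nrow(msk), ncol(msk))
  list(image = img, mask = msk)
}

#' Load a directory dataset of paired images and masks
#'
#' Expects `root/images/` and `root/masks/` with files paired by shared stem.
#'
#' @param root dataset directory.
#' @param target_size working resolution.
#' @param stems optionally restrict to these stems (e.g. a split manifest).
#' @return list of `load_pair()` results, named by stem.
#' @export
load_dataset <- function(root, target_size = c(256L, 256L), stems = NULL) {
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir)) {
    stop("dataset root must contain images/ and masks/: ", root, call. = FALSE)
  }
  imgs <- list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  st <- sort(tools::file_path_sans_ext(imgs))
  if (!is.null(stems)) st <- intersect(st, stems)
  out <- lapply(st, function(s) {
    ip <- list.files(img_dir, pattern = paste0("^", s, "\\."), full.names = TRUE)[1]
    mp <- list.files(msk_dir, pattern = paste0("^", s, "\\."), full.names = TRUE)[1]
    if (is.na(mp)) stop("no mask for image stem: ", s, call. = FALSE)
    load_pair(ip, mp, target_size)
  })
  names(out) <- st
  out
}

#' Seeded 70/30 train/test split of dataset stems
#'
#' @param stems character vector of example stems.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed shuffle seed.
#' @return `list(train, test)` of stem vectors.
#' @export
split_dataset <- function(stems, train_fraction = 0.7, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  sh <- sample(stems)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ntr <- max(1L, round(train_fraction * length(stems)))
  list(train = sort(sh[seq_len(ntr)]),
       test = sort(sh[setdiff(seq_along(sh), seq_len(ntr))]))
}

#' Export a probability map as a binary (and optionally probability) PNG
#'
#' @param prob_map numeric matrix in `[0, 1]`.
#' @param out_path output PNG path (values 0/255).
#' @param threshold binarisation threshold (strictly greater-or-equal).
#' @param prob_path optional path for the 8-bit probability map.
#' @return invisibly, `out_path`.
#' @export
export_prediction <- function(prob_map, out_path, threshold = 0.5,
                              prob_path = NULL) {
  stopifnot(all(prob_map >= 0 & prob_map <= 1))
  png::writePNG(matrix(as.numeric(prob_map >= threshold),
                       nrow(prob_map), ncol(prob_map)), out_path)
  if (!is.null(prob_path)) png::writePNG(prob_map, prob_path)
  invisible(out_path)
}

#' Read a model/training configuration file (YAML or JSON)
#'
#' Recognised top-level keys: `model` (fields of [model_config()]) and
#' `train` (fields of [train_config()]).
#'
#' @param path file path.
#' @return `list(model = dermseg_config, train = dermseg_train_config)`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  mm <- raw$model %||% list()
  mm$num_stages <- NULL                      # derived from stage_channels
  mc <- do.call(model_config, mm)
  tc <- do.call(train_config, raw$train %||% list())
  list(model = mc, train = tc)
}

#' Write a configuration file
#' @param cfg list with elements `model` and/or `train`.
#' @param path output path (`.yaml` or `.json`).
#' @return invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  plain <- lapply(cfg, unclass)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Save model weights and configuration to a single checkpoint file
#'
#' @param model a `seg_network`.
#' @param path output `.rds` path.
#' @param history optional training history to store alongside.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  cfg <- model$meta$cfg
  saveRDS(list(config = unclass(cfg), config_hash = config_hash(cfg),
               state = param_state(model), history = history,
               package_version = as.character(utils::packageVersion("dermseg"))),
          path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' Rebuilds the model from the stored configuration (validating its hash) and
#' restores the weights.
#'
#' @param path checkpoint path.
#' @return `list(model, config, history)`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), "num_stages")])
  if (!identical(config_hash(cfg), ck$config_hash)) {
    stop("checkpoint config hash mismatch: file corrupted or incompatible",
         call. = FALSE)
  }
  model <- build_model(cfg)
  load_param_state(model, ck$state)
  list(model = model, config = cfg, history = ck$history)
}

write_provenance <- function(out_dir, command, seed, extra = list()) {
  prov <- c(list(command = command,
                 seed = seed,
                 package = "dermseg",
                 version = as.character(utils::packageVersion("dermseg")),
                 r_version = R.version.string,
                 timestamp = format(Sys.time(), tz = "UTC")),
            extra)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prov)
}
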