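#' Write spine tracks to CSV
#'
#' Writes a cohort (or list of tracks) in the spine-tracking CSV dialect:
#' one row per (larva_id, frame) with columns `larva_id, frame, time_s,
#' x1..x5, y1..y5` in mm, frames 0-based, point 3 the centroid. Gap frames
#' are written with empty coordinate fields. An optional cohort metadata
#' CSV (`larva_id, genotype, seed`) is written alongside.
#'
#' @param cohort a `track_cohort`, or list of `spine_track`.
#' @param path output CSV path.
#' @param metadata_path optional path for the cohort metadata CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(cohort, path, metadata_path = NULL) {
  tracks <- if (inherits(cohort, "track_cohort")) cohort$tracks else cohort
  rows <- lapply(tracks, function(tr) {
    n <- length(tr$time)
    df <- data.frame(larva_id = tr$larva_id, frame = seq_len(n) - 1L,
                     time_s = tr$time)
    for (i in 1:5) df[[paste0("x", i)]] <- tr$x[, i]
    for (i in 1:5) df[[paste0("y", i)]] <- tr$y[, i]
    coords <- c(paste0("x", 1:5), paste0("y", 1:5))
    df[tr$gap, coords] <- NA_real_
    df
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(metadata_path)) {
    md <- if (inherits(cohort, "track_cohort")) cohort$metadata else
      data.frame(larva_id = vapply(tracks, `[[`, "", "larva_id"),
                 genotype = NA_character_, seed = NA_integer_)
    md$schema_version <- track_schema_version()
    utils::write.csv(md, metadata_path, row.names = FALSE)
  }
  invisible(path)
}

track_schema_version <- function() "larvaquant-tracks-1"

#' Read spine tracks from CSV
#'
#' Reads the spine-tracking CSV dialect written by [write_tracks()] (or a
#' compatible export remapped via `col_map`). Frames are sorted per larva;
#' missing frame indices become explicit gap frames with `NA` coordinates;
#' duplicate (larva, frame) pairs are an error.
#'
#' @param path CSV file path.
#' @param fps frames per second; when `NULL`, inferred from the median
#'   `time_s` spacing.
#' @param col_map optional named character vector remapping this dialect's
#'   column names to the file's (e.g. `c(larva_id = "id")`).
#' @param metadata optional metadata CSV path (larva_id, genotype, seed).
#' @return a `track_cohort`.
#' @export
read_tracks <- function(path, fps = NULL, col_map = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("larva_id", "frame", "time_s",
                paste0("x", 1:5), paste0("y", 1:5))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df))
        stop(sprintf("col_map: column '%s' not in file", col_map[[std]]))
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("track CSV schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$frame) || anyNA(df$frame))
    stop("track CSV schema violation: non-numeric 'frame'")

  dup <- duplicated(df[, c("larva_id", "frame")])
  if (any(dup)) {
    r <- which(dup)[1]
    stop(sprintf("duplicate (larva_id, frame) at row %d: (%s, %d)",
                 r, df$larva_id[r], df$frame[r]))
  }

  tracks <- lapply(split(df, df$larva_id), function(d) {
    d <- d[order(d$frame), ]
    f <- if (is.null(fps)) {
      dt <- stats::median(diff(d$time_s) / diff(d$frame))
      1 / dt
    } else fps
    frames <- d$frame[1]:d$frame[nrow(d)]
    full <- data.frame(frame = frames)
    full <- merge(full, d, by = "frame", all.x = TRUE, sort = TRUE)
    gap <- is.na(full$x3) | is.na(full$y3)
    x <- as.matrix(full[, paste0("x", 1:5)])
    y <- as.matrix(full[, paste0("y", 1:5)])
    dimnames(x) <- dimnames(y) <- NULL
    structure(list(
      larva_id = d$larva_id[1], fps = f,
      time = frames / f,
      x = x, y = y, gap = gap
    ), class = "spine_track")
  })
  md <- if (!is.null(metadata) && file.exists(metadata)) {
    utils::read.csv(metadata, stringsAsFactors = FALSE)
  } else {
    data.frame(larva_id = names(tracks),
               genotype = NA_character_, seed = NA_integer_,
               stringsAsFactors = FALSE)
  }
  structure(list(tracks = tracks, metadata = md), class = "track_cohort")
}

#' Write a two-channel stack and nuclear masks as TIFF
#'
#' The stack is written as a multi-directory 16-bit TIFF, slices ordered
#' channel-major (all z of channel 1 = col, then channel 2 = nau); the mask
#' as a single 16-bit image of integer labels. Intensities must lie in
#' `[0, 65535]`; integer-valued data round-trip losslessly.
#'
#' @param stack an `image_stack` (array `c(2, z, y, x)`).
#' @param masks integer label matrix `(y, x)`.
#' @param path_tiff,path_mask output file paths.
#' @return `path_tiff`, invisibly.
#' @export
write_stack <- function(stack, masks, path_tiff, path_mask) {
  d <- dim(stack)
  if (length(d) != 4 || d[1] != 2) stop("stack must be (2, z, y, x)")
  if (max(stack) > 65535 || min(stack) < 0)
    stop("stack intensities must be within [0, 65535] for 16-bit TIFF")
  slices <- list()
  for (c in 1:2) for (z in seq_len(d[2])) {
    m <- stack[c, z, , ]
    dim(m) <- d[3:4]
    slices[[length(slices) + 1]] <- m / 65535
  }
  tiff::writeTIFF(slices, path_tiff, bits.per.sample = 16L)
  if (max(masks) > 65535) stop("mask labels exceed 16-bit range")
  tiff::writeTIFF(masks / 65535, path_mask, bits.per.sample = 16L)
  invisible(path_tiff)
}

#' Read a two-channel stack and nuclear masks from TIFF
#'
#' Inverse of [write_stack()]: expects an even number of directories
#' (channel-major slice order) and a single-image label mask whose `(y, x)`
#' shape matches the stack.
#'
#' @param path_tiff,path_mask file paths.
#' @param channels channel names, first = numerator of the ratio.
#' @return list with `stack` (an `image_stack`) and `masks` (integer
#'   matrix); a mask without labels yields an empty mask with a warning.
#' @export
read_stack <- function(path_tiff, path_mask, channels = c("col", "nau")) {
  if (length(channels) != 2) stop("exactly 2 channels are supported")
  slices <- tiff::readTIFF(path_tiff, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  n <- length(slices)
  if (n %% 2 != 0)
    stop(sprintf("stack TIFF has %d directories; need 2 channels x z", n))
  nz <- n / 2
  dyx <- dim(slices[[1]])
  img <- array(0, dim = c(2L, nz, dyx[1], dyx[2]))
  k <- 1
  for (c in 1:2) for (z in seq_len(nz)) {
    img[c, z, , ] <- slices[[k]] * 65535
    k <- k + 1
  }
  img <- round(img, 6)
  masks_raw <- tiff::readTIFF(path_mask)
  if (length(dim(masks_raw)) > 2) masks_raw <- masks_raw[, , 1]
  masks <- matrix(as.integer(round(masks_raw * 65535)),
                  nrow = nrow(masks_raw), ncol = ncol(masks_raw))
  if (!all(dim(masks) == dyx))
    stop("stack and mask (y, x) shapes disagree")
  if (all(masks == 0))
    warning("mask contains no labels")
  stack <- structure(img, channels = channels, pixel_size = NA_real_,
                     class = "image_stack")
  list(stack = stack, masks = masks)
}

#' Read / write generator configs (YAML)
#'
#' Configuration files hold generator or analysis parameters as flat YAML
#' maps with a `type` field (`kinematics`, `fish`, `phenotype`). The
#' packaged per-genotype configs shipped under
#' `inst/extdata/config/` transcribe the published group values.
#'
#' @param path YAML file path.
#' @return for `read_config`: a parameter object of the class matching the
#'   config `type` (plus a `genotype` attribute); `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  y <- yaml::read_yaml(path)
  type <- y$type %||% stop("config missing 'type' field")
  genotype <- y$genotype %||% NA_character_
  group_n <- y$group_n
  y$type <- NULL; y$genotype <- NULL; y$group_n <- NULL
  obj <- switch(type,
    kinematics = do.call(kinematic_params, y),
    fish = do.call(fish_gen_params, y),
    phenotype = do.call(phenotype_proportions,
                        y[intersect(names(y), phenotype_levels())]),
    stop("unknown config type: ", type))
  attr(obj, "genotype") <- genotype
  attr(obj, "group_n") <- group_n
  obj
}

#' @param obj a `kinematic_params`, `fish_gen_params` or
#'   `phenotype_proportions` object.
#' @param genotype genotype label stored in the file.
#' @param n optional group size stored in the file.
#' @rdname read_config
#' @export
write_config <- function(obj, path, genotype = NA_character_, n = NULL) {
  type <- if (inherits(obj, "kinematic_params")) "kinematics"
    else if (inherits(obj, "fish_gen_params")) "fish"
    else if (inherits(obj, "phenotype_proportions")) "phenotype"
    else stop("unsupported config object")
  y <- c(list(type = type, genotype = genotype),
         if (!is.null(n)) list(group_n = n),
         as.list(unclass(obj)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Packaged per-genotype configuration
#'
#' Returns one of the configuration files shipped with the package, which
#' transcribe the published group parameters: kinematics for `control`,
#' `colDL0.5`, `colDL1.3`; FISH for `wt-fc`, `control-pc`, `colDL1.3-fc`,
#' `colDL0.5-fc`; phenotypes for `wt`, `colDL1.3`, `colDL0.5`.
#'
#' @param type one of `"kinematics"`, `"fish"`, `"phenotype"`.
#' @param name config name (see above).
#' @param as_path return the file path instead of the parsed object.
#' @return parameter object (see [read_config()]) or a path.
#' @export
packaged_config <- function(type = c("kinematics", "fish", "phenotype"),
                            name, as_path = FALSE) {
  type <- match.arg(type)
  p <- system.file("extdata", "config", type, paste0(name, ".yaml"),
                   package = "larvaquant")
  if (p == "")
    stop(sprintf("no packaged %s config named '%s'", type, name))
  if (as_path) p else read_config(p)
}
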