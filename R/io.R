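# Movie readers, trajectory writers and run configuration.  Frames are
# grayscale matrices in [0, 1] with rows = y and columns = x; pixel (x, y)
# is 0-based and centered on the integer grid.

#' Read a movie from a multi-page TIFF or a directory of frames
#'
#' Directories are read in lexicographic filename order (`.png`, `.tif`,
#' `.tiff`).  8- and 16-bit grayscale frames are normalized to `[0, 1]`;
#' multi-channel frames are averaged to grayscale.
#'
#' @param path Multi-page TIFF file or a directory of single-frame images.
#' @return A list of frame matrices with attribute `source`.
#' @export
read_movie <- function(path) {
  to_gray <- function(a, file) {
    if (is.matrix(a)) return(a)
    if (length(dim(a)) == 3) return(apply(a, c(1, 2), mean))
    stop(sprintf("unsupported image layout in '%s'", file), call. = FALSE)
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0)
      stop(sprintf("no frames found in '%s'", path), call. = FALSE)
    frames <- lapply(files, function(f) {
      img <- tryCatch({
        if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
        else tiff::readTIFF(f)
      }, error = function(e)
        stop(sprintf("unreadable frame '%s': %s", f, conditionMessage(e)),
             call. = FALSE))
      to_gray(img, f)
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray, file = path)
  } else {
    stop(sprintf("'%s' does not exist", path), call. = FALSE)
  }
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                 character(1))
  if (length(unique(dims)) > 1) {
    bad <- which(dims != dims[1])[1]
    stop(sprintf("frame %d has shape %s, expected %s", bad, dims[bad],
                 dims[1]), call. = FALSE)
  }
  attr(frames, "source") <- path
  frames
}

# accept a list of matrices, a synthetic_movie, or a path
as_frame_list <- function(movie) {
  if (inherits(movie, "synthetic_movie")) return(movie$frames)
  if (is.character(movie)) return(read_movie(movie))
  if (is.list(movie)) return(movie)
  stop("`movie` must be a list of frames, a synthetic_movie, or a path",
       call. = FALSE)
}

#' Write a movie as numbered 8-bit TIFF frames
#'
#' @param frames List of matrices in `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return The directory path, invisibly.
#' @export
write_movie <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames)) {
    tiff::writeTIFF(pmin(pmax(frames[[i]], 0), 1),
                    file.path(dir, sprintf("%s_%05d.tif", prefix, i)),
                    bits.per.sample = 8L)
  }
  invisible(dir)
}

#' Write trajectories to CSV
#'
#' One row per (object, frame, control point):
#' `object_id, frame, point_index, x, y` plus flag columns, floats with six
#' decimals.  Reading the file back reproduces the coordinates within 1e-6.
#'
#' @param tracks A `ram_tracks` object (or any tibble from [tidy()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tracks, path) {
  df <- if (inherits(tracks, "ram_tracks")) tidy(tracks) else tracks
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  invisible(path)
}

#' Read trajectories written by [write_trajectories()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_trajectories <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

run_config_keys <- c(
  "schema_version", "kind", "movie", "out_csv", "n_objects",
  "object_length_px", "object_width_px", "fps", "frame_interval",
  "mm_per_px", "um_per_px", "gamma", "max_iters", "tol", "block_size",
  "block_overlap", "redistribute_every", "temporal_alpha", "temporal_beta",
  "alpha", "beta", "k_str", "kappa", "shrink_fraction", "blur_sigma",
  "hessian_scale", "align_window", "r0", "epsilon", "weights",
  "valley_shrink", "jump_energy_threshold", "hmm_flip_prob",
  "hmm_velocity_scale", "speed_smooth_sigma", "seed")

#' Read a run configuration YAML
#'
#' A single YAML document with a `schema_version` field; unknown keys are
#' rejected so typos fail loudly rather than silently using defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version))
    stop("config must declare `schema_version`", call. = FALSE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Write a run configuration YAML
#'
#' @param cfg Named list (validated against the known keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg$schema_version <- cfg$schema_version %||% 1L
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
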