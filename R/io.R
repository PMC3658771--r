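# Image readers/writers, run configuration and result serialization.
# PNG/PGM/TIFF in; PNG, CSV polylines and JSON trees/manifests out.
# All exported coordinates are 0-based (row, col) with pixel centers at
# integer positions.

#' Read a single-channel image
#'
#' Reads PNG, PGM (P2/P5) or TIFF and returns intensities on the 0-255 real
#' scale. Multi-channel (e.g. RGB) inputs are rejected, not silently
#' converted; 16-bit inputs are rescaled to 0-255 with a warning.
#'
#' @param path path to a `.png`, `.pgm`, `.tif`/`.tiff` file.
#' @return numeric matrix, values in `[0, 255]`.
#' @export
read_grayscale <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io(sprintf("cannot read image: no such file '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      reject_multichannel(x, path)
      x * 255
    },
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE)
      reject_multichannel(x, path)
      bits <- attr(x, "bits.per.sample") %||% if (max(x) > 255) 16L else 8L
      if (bits > 8 || max(x) > 255) {
        warning(sprintf("'%s': %d-bit input rescaled to the 0-255 scale", path, bits))
        x <- x / (2^bits - 1) * 255
      }
      x + 0  # drop attributes
    },
    pgm = read_pgm(path),
    stop_io(sprintf("unsupported image format '.%s' (PNG/PGM/TIFF only): %s",
                    ext, path))
  )
  if (!all(is.finite(img))) stop_io(sprintf("non-finite pixel values in '%s'", path))
  img
}

reject_multichannel <- function(x, path) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] > 1L) {
      stop_io(sprintf("'%s' has %d channels; a single-channel image is required",
                      path, dim(x)[3L]))
    }
  }
  invisible(x)
}

# Minimal PGM reader (plain P2 and binary P5); no installed package reads
# PGM, and the format is two lines of header plus raster data.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop_io(sprintf("truncated PGM header in '%s'", path))
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- token()
  if (!magic %in% c("P2", "P5")) {
    stop_io(sprintf("'%s' is not a PGM file (magic '%s')", path, magic))
  }
  w <- as.integer(token())
  h <- as.integer(token())
  maxval <- as.integer(token())
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1 || maxval < 1) {
    stop_io(sprintf("malformed PGM header in '%s'", path))
  }
  n <- w * h
  vals <- if (magic == "P2") {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
    if (length(v) < n) stop_io(sprintf("truncated PGM raster in '%s'", path))
    v
  } else {
    if (maxval > 255) {
      v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
    } else {
      v <- as.integer(readBin(con, "raw", n = n))
    }
    if (length(v) < n) stop_io(sprintf("truncated PGM raster in '%s'", path))
    v
  }
  img <- matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
  if (maxval > 255) {
    warning(sprintf("'%s': 16-bit input rescaled to the 0-255 scale", path))
    img <- img / maxval * 255
  }
  img
}

#' Write a matrix as plain-text PGM (P2)
#'
#' @param image numeric matrix; values are clamped to `[0, maxval]` and
#'   rounded.
#' @param path output path.
#' @param maxval maximum gray value of the file.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  check_field(image, "image")
  vals <- round(pmin(pmax(image, 0), maxval))
  lines <- c("P2",
             sprintf("%d %d", ncol(image), nrow(image)),
             as.character(maxval),
             apply(vals, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write an image or label matrix as 8-bit grayscale PNG
#'
#' Label maps are spread over the full gray range so each depth gets a
#' distinct gray value.
#'
#' @param image numeric matrix (intensities 0-255, masks 0/1, or integer
#'   labels if `labels = TRUE`).
#' @param path output path.
#' @param labels if TRUE, map label values `0..max` evenly onto `0..255`.
#' @export
write_grayscale_png <- function(image, path, labels = FALSE) {
  check_field(image, "image")
  if (labels) {
    mx <- max(image)
    norm <- if (mx > 0) image / mx else image
  } else {
    mx <- max(image)
    norm <- if (mx > 1) image / 255 else image
  }
  png::writePNG(pmin(pmax(norm, 0), 1), path)
  invisible(path)
}

#' Read a run configuration
#'
#' Loads a flat YAML config with optional blocks `params` (fields of
#' [algo_params()]), `rof` ([rof_config()]), `phantom` ([phantom_spec()])
#' and scalar `max_passes`. Validation happens at load time: in particular
#' a config violating the stability condition `tau * alpha < 1/4` is
#' rejected before any computation.
#'
#' @param path YAML file path.
#' @return list with `params`, `rof`, `max_passes` and (if present)
#'   `phantom`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such config file: '%s'", path))
  raw <- yaml::read_yaml(path)
  cfg_from_list(raw)
}

cfg_from_list <- function(raw) {
  params <- do.call(algo_params, raw$params %||% list())
  rof <- do.call(rof_config, raw$rof %||% list())
  phantom <- NULL
  if (!is.null(raw$phantom)) {
    ph <- raw$phantom
    if (!is.null(ph$shape)) ph$shape <- as.integer(ph$shape)
    phantom <- do.call(phantom_spec, ph)
  }
  list(params = params, rof = rof,
       max_passes = as.integer(raw$max_passes %||% 20L),
       phantom = phantom)
}

#' Write a run configuration
#'
#' Inverse of [read_run_config()]; the round trip is lossless.
#'
#' @param cfg list as returned by [read_run_config()].
#' @param path output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  out <- list(params = unclass(cfg$params), rof = unclass(cfg$rof),
              max_passes = cfg$max_passes)
  if (!is.null(cfg$phantom)) out$phantom <- unclass(cfg$phantom)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Save a multipass result to a directory
#'
#' Writes everything needed to inspect and reproduce a run: per-pass inner
#' masks and the label map as PNG, all contour polylines as one CSV
#' (`contour_id, vertex_index, row, col`; 0-based, pixel centers at
#' integers), the inclusion tree as JSON, and a manifest JSON holding the
#' full configuration, per-pass summaries (iterations, c1, c2, areas,
#' termination, final energy) and the package version.
#'
#' @param result an `mpac_result`.
#' @param dir output directory (created if missing).
#' @param image_id identifier recorded in the manifest.
#' @return the directory path, invisibly.
#' @export
save_multipass_result <- function(result, dir, image_id = "image") {
  if (!inherits(result, "mpac_result")) stop_param("`result` must be an mpac_result")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cmap <- build_contour_map(result)
  tree <- build_inclusion_tree(cmap, result$image)

  write_grayscale_png(cmap$labels, file.path(dir, "labels.png"), labels = TRUE)
  for (k in seq_along(result$passes)) {
    write_grayscale_png(result$passes[[k]]$inner_mask,
                        file.path(dir, sprintf("mask_pass%02d.png", k)),
                        labels = TRUE)
  }

  rows <- list()
  cid <- 0L
  for (k in seq_along(cmap$contours)) {
    for (poly in cmap$contours[[k]]) {
      cid <- cid + 1L
      rows[[cid]] <- data.frame(contour_id = cid, pass = k,
                                vertex_index = seq_len(nrow(poly)) - 1L,
                                row = poly$row, col = poly$col)
    }
  }
  csv_path <- file.path(dir, "contours.csv")
  header <- "# contour polylines; coordinates are 0-based (row, col), pixel centers at integers"
  writeLines(header, csv_path)
  if (length(rows)) {
    suppressWarnings(utils::write.table(do.call(rbind, rows), csv_path,
                                        sep = ",", row.names = FALSE,
                                        col.names = TRUE, append = TRUE))
  } else {
    cat("contour_id,pass,vertex_index,row,col\n", file = csv_path, append = TRUE)
  }

  jsonlite::write_json(as.data.frame(unclass(tree)),
                       file.path(dir, "tree.json"), digits = NA)

  manifest <- list(
    image_id = image_id,
    package_version = as.character(utils::packageVersion("mpac")),
    termination = result$termination,
    n_passes = length(result$passes),
    params = unclass(result$params),
    rof = unclass(result$rof),
    passes = if (length(result$passes)) summarize_passes(result) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
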