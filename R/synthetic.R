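# Synthetic phantoms: nested sharp-edged intensity plateaus plus uniform
# noise, with ground-truth region masks. These emulate the structure the
# segmentation assumes -- piecewise-constant regions ordered from a dark
# surround to a bright core -- and give known answers for testing.

#' Phantom specification
#'
#' @param shape integer vector `c(height, width)`, each at least 16.
#' @param levels strictly increasing plateau intensities (0-255 scale,
#'   darkest first), between 2 and 8 of them.
#' @param geometry `"nested_squares"` (default), `"nested_disks"` or
#'   `"offset_blobs"` (nested disks whose centers drift, so the nesting is
#'   not concentric).
#' @param noise_frac additive uniform noise amplitude as a fraction of the
#'   full 0-255 range, in `[0, 0.5)`; 0.05 means noise drawn from
#'   `[-12.75, +12.75]`.
#' @param seed integer seed making the phantom reproducible.
#' @return an object of class `mpac_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         levels = c(40, 100, 160, 220),
                         geometry = c("nested_squares", "nested_disks",
                                      "offset_blobs"),
                         noise_frac = 0.05, seed = 1L) {
  geometry <- match.arg(geometry)
  if (length(shape) != 2L || any(shape < 16)) {
    stop_param("`shape` must be two integers, each at least 16")
  }
  n <- length(levels)
  if (n < 2L || n > 8L) stop_param("between 2 and 8 intensity levels required")
  if (any(diff(levels) <= 0)) stop_param("`levels` must be strictly increasing")
  if (any(levels < 0 | levels > 255)) stop_param("`levels` must lie in [0, 255]")
  if (!is.numeric(noise_frac) || noise_frac < 0 || noise_frac >= 0.5) {
    stop_param("`noise_frac` must lie in [0, 0.5)")
  }
  structure(list(shape = as.integer(shape), levels = as.numeric(levels),
                 geometry = geometry, noise_frac = noise_frac,
                 seed = as.integer(seed)),
            class = "mpac_phantom_spec")
}

#' Generate a nested-plateau phantom with ground truth
#'
#' Builds a piecewise-constant image whose plateaus nest strictly: level 1
#' (darkest) covers the whole domain, each brighter level occupies a
#' smaller centered (or drifting, for `"offset_blobs"`) region inside the
#' previous one. Uniform noise is then added per
#' [add_uniform_noise()]. Mask `i` of the returned ground truth marks the
#' region at intensity level `i` *and brighter*, so the masks form the same
#' strictly nested chain the multipass segmentation should recover.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (noisy), `clean` (noise-free), `masks` (list
#'   of integer 0/1 matrices, `masks[[1]]` all ones) and the `spec`.
#' @export
make_nested_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "mpac_phantom_spec")) {
    stop_param("`spec` must come from phantom_spec()")
  }
  h <- spec$shape[1L]
  w <- spec$shape[2L]
  n <- length(spec$levels)
  ri <- matrix(seq_len(h), h, w)
  ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  cr <- (h + 1) / 2
  cc <- (w + 1) / 2
  half <- min(h, w) / 2

  masks <- vector("list", n)
  masks[[1L]] <- matrix(1L, h, w)
  for (i in seq_len(n)[-1L]) {
    frac <- (n - i + 1) / n
    m <- matrix(0L, h, w)
    if (spec$geometry == "nested_squares") {
      hs <- floor(half * frac)
      if (hs < 2) stop_param("geometry too small for the number of levels")
      m[abs(ri - cr) <= hs & abs(ci - cc) <= hs] <- 1L
    } else {
      r <- half * frac - 1
      if (r < 2) stop_param("geometry too small for the number of levels")
      if (spec$geometry == "nested_disks") {
        ctr <- c(cr, cc)
      } else {
        # drift each deeper disk along the diagonal by half the radius gap,
        # which keeps it strictly inside its parent
        gap <- half / n
        ctr <- c(cr, cc) + (i - 2) * gap / 2
      }
      m[(ri - ctr[1L])^2 + (ci - ctr[2L])^2 <= r^2] <- 1L
    }
    masks[[i]] <- m
  }

  clean <- matrix(spec$levels[1L], h, w)
  for (i in seq_len(n)[-1L]) clean[masks[[i]] == 1L] <- spec$levels[i]
  image <- add_uniform_noise(clean, spec$noise_frac, spec$seed)
  list(image = image, clean = clean, masks = masks, spec = spec)
}

#' Add clamped uniform noise
#'
#' Adds i.i.d. noise drawn uniformly from `[-frac * 255, +frac * 255]` and
#' clamps the result to `[0, 255]`. Deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param image numeric matrix, 0-255 scale.
#' @param frac nonnegative noise amplitude as a fraction of the 0-255 range.
#' @param seed integer seed.
#' @return matrix of the same shape.
#' @export
add_uniform_noise <- function(image, frac, seed = 1L) {
  check_field(image, "image")
  if (!is.numeric(frac) || length(frac) != 1L || frac < 0) {
    stop_param("`frac` must be a nonnegative scalar")
  }
  if (frac == 0) return(image)
  amp <- frac * 255
  noise <- with_local_seed(seed, stats::runif(length(image), -amp, amp))
  out <- image + matrix(noise, nrow(image), ncol(image))
  pmin(pmax(out, 0), 255)
}

#' Pixel agreement between two binary masks
#'
#' Jaccard index `|A & B| / |A | B|` used to score recovered regions
#' against ground truth. Returns 1 when both masks are empty.
#'
#' @param a,b binary masks of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
region_agreement <- function(a, b) {
  check_mask(a, "a")
  check_mask(b, "b")
  same_shape(a, b, "a", "b")
  un <- sum(a == 1 | b == 1)
  if (un == 0) return(1)
  sum(a == 1 & b == 1) / un
}
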