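# Recursive driver: repeatedly bisect the current inside region, update the
# restriction mask, and terminate when the recursion degenerates or goes
# stationary.

#' Restriction mask from a converged level set
#'
#' Binary mask of the retained (inner) region: 1 exactly where `phi < 0`.
#' The regions are defined by the sign of the level set, so the mask is a
#' sharp threshold, not a smoothed characteristic function.
#'
#' @param phi_prev converged level set of the previous pass.
#' @return integer 0/1 matrix.
#' @export
restrict_mask <- function(phi_prev) {
  check_field(phi_prev, "phi_prev")
  m <- matrix(0L, nrow(phi_prev), ncol(phi_prev))
  m[phi_prev < 0] <- 1L
  m
}

#' Outer sub-region by set difference
#'
#' \eqn{\bar w_{k+1} = w_k - w_{k+1}}: pixels of the parent region not in
#' the inner region. Errors if `inner` is not a subset of `parent`.
#'
#' @param parent,inner binary masks.
#' @return integer 0/1 matrix; `outer + inner == parent` pixelwise.
#' @export
outer_region <- function(parent, inner) {
  check_mask(parent, "parent")
  check_mask(inner, "inner")
  same_shape(parent, inner, "parent", "inner")
  if (any(inner == 1 & parent == 0)) {
    stop_consistency("`inner` is not a subset of `parent`")
  }
  out <- parent - inner
  storage.mode(out) <- "integer"
  out
}

#' Run the full multipass segmentation
#'
#' Denoises the raw image once ([rof_denoise()]), computes the edge
#' indicator once ([edge_indicator()]), then iterates two-phase passes:
#' the base region starts as the whole domain and after each productive
#' pass shrinks to that pass's inner region. The recursion stops when a
#' pass degenerates (one sub-region empties -- in particular when the
#' current region is homogeneous to within `kappa`, so every pixel joins
#' the dark seed), when a pass is a stationary fixed point -- it peels off
#' nothing, or its two sides differ by less than `min_split_contrast` gray
#' levels, meaning the region is homogeneous at the map's intensity
#' resolution -- or after `max_passes` passes.
#'
#' Because every pass keeps the brighter sub-region, the mean intensity of
#' the retained region increases strictly from pass to pass: the image is
#' decomposed from its darkest shell inward to its brightest core.
#'
#' @param image_raw raw single-channel image, 0-255 scale.
#' @param params an [algo_params()] object.
#' @param rof an [rof_config()] object.
#' @param max_passes safety cap on the number of passes.
#' @return an object of class `mpac_result`: list with `passes` (the
#'   productive `mpac_pass` objects, in order), `termination` (one of
#'   `"degenerate"`, `"stationary"`, `"max_passes"`), the denoised `image`,
#'   `image_raw`, edge indicator `g`, and the `params`/`rof` used.
#' @export
#' @examples
#' ph <- make_nested_phantom(phantom_spec(shape = c(48, 48),
#'                                        levels = c(50, 200),
#'                                        noise_frac = 0))
#' res <- run_multipass(ph$image)
#' length(res$passes)  # one productive bisection
run_multipass <- function(image_raw, params = algo_params(),
                          rof = rof_config(), max_passes = 20L) {
  check_image(image_raw)
  if (!inherits(params, "mpac_params")) stop_param("`params` must come from algo_params()")
  if (!inherits(rof, "mpac_rof_config")) stop_param("`rof` must come from rof_config()")
  check_positive_scalar(max_passes, "max_passes")

  image <- rof_denoise(image_raw, rof$lam, rof$n_iters, rof$dt, params$eps_d)
  g <- edge_indicator(image)

  mask <- matrix(1L, nrow(image), ncol(image))
  passes <- list()
  termination <- "max_passes"
  for (k in seq_len(max_passes)) {
    pass <- tryCatch(
      evolve_pass(image, g, mask, params),
      mpac_error = function(e) {
        if (inherits(e, "mpac_degenerate_error")) return(e)
        stop_numeric(sprintf("pass %d failed: %s", k, conditionMessage(e)))
      })
    if (inherits(pass, "mpac_degenerate_error") ||
        startsWith(pass$terminated_by, "degenerate")) {
      termination <- "degenerate"
      break
    }
    if (identical(pass$inner_mask, mask) ||
        abs(pass$c1 - pass$c2) < params$min_split_contrast) {
      termination <- "stationary"
      break
    }
    passes[[k]] <- pass
    mask <- pass$inner_mask
  }
  structure(list(passes = passes, termination = termination,
                 image = image, image_raw = image_raw, g = g,
                 params = params, rof = rof),
            class = "mpac_result")
}

#' @export
print.mpac_result <- function(x, ...) {
  k <- length(x$passes)
  cat(sprintf("Multipass segmentation: %d productive pass%s, terminated by %s\n",
              k, if (k == 1) "" else "es", x$termination))
  if (k > 0) {
    df <- summarize_passes(x)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Per-pass summary table
#'
#' @param result an `mpac_result`.
#' @return data.frame with one row per productive pass: iterations,
#'   termination reason, region means and areas, final energy.
#' @export
summarize_passes <- function(result) {
  if (!inherits(result, "mpac_result")) stop_param("`result` must be an mpac_result")
  do.call(rbind, lapply(seq_along(result$passes), function(k) {
    p <- result$passes[[k]]
    data.frame(pass = k, iters = p$n_iters, terminated = p$terminated_by,
               c1 = p$c1, c2 = p$c2,
               inner_area = sum(p$inner_mask), outer_area = sum(p$outer_mask),
               energy = if (length(p$energy_trace)) p$energy_trace[length(p$energy_trace)] else NA_real_)
  }))
}
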