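# Adaptive contour map and inclusion tree: per-pixel region labels from all
# passes, sub-pixel zero-level polylines and the nesting tree over regions.
#
# Coordinate convention for polylines: 0-based (row, col), pixel centers at
# integer coordinates, linear interpolation along pixel edges.

#' Extract sub-pixel zero-level contours
#'
#' Polylines of the \eqn{\phi = 0} level set via linear interpolation on
#' pixel edges (marching-squares style, through [grDevices::contourLines()]).
#' When `parent_mask` is given, `phi` is forced positive outside it first,
#' clipping the contours to the base region. Contours not touching the
#' domain boundary come back closed (first vertex repeated as last).
#'
#' @param phi level set field.
#' @param parent_mask optional binary mask to clip against.
#' @return list of data.frames with columns `row`, `col` (0-based, pixel
#'   centers at integers); may be empty.
#' @export
extract_zero_contours <- function(phi, parent_mask = NULL) {
  check_field(phi, "phi")
  z <- phi
  if (!is.null(parent_mask)) {
    check_mask(parent_mask, "parent_mask")
    same_shape(phi, parent_mask, "phi", "parent_mask")
    z[parent_mask == 0] <- max(abs(z)) + 1
  }
  if (all(z >= 0) || all(z <= 0)) return(list())
  cl <- grDevices::contourLines(x = seq_len(nrow(z)) - 1,
                                y = seq_len(ncol(z)) - 1,
                                z = z, levels = 0)
  lapply(cl, function(cc) {
    poly <- data.frame(row = cc$x, col = cc$y)
    n <- nrow(poly)
    closed <- n > 2 &&
      abs(poly$row[1] - poly$row[n]) < 1e-9 &&
      abs(poly$col[1] - poly$col[n]) < 1e-9
    if (!closed && n > 2) {
      # close loops that contourLines leaves open but whose endpoints meet
      if (sqrt((poly$row[1] - poly$row[n])^2 +
                 (poly$col[1] - poly$col[n])^2) < 1e-6) {
        poly <- rbind(poly, poly[1, ])
        closed <- TRUE
      }
    }
    attr(poly, "closed") <- closed
    poly
  })
}

#' Build the adaptive contour map
#'
#' Collapses a multipass result into a per-pixel label grid -- pixel `p`
#' gets the index of the deepest pass whose inner region contains it, 0
#' meaning outside all contours -- plus the sub-pixel zero-level polylines
#' of every pass, clipped to that pass's base region.
#'
#' The labels lose no information: `labels >= k` reproduces pass `k`'s
#' inner mask exactly.
#'
#' @param result an `mpac_result` from [run_multipass()].
#' @return object of class `mpac_contour_map`: list with integer matrix
#'   `labels`, `contours` (list, one entry per pass, each a list of
#'   polylines) and `n_passes`.
#' @export
build_contour_map <- function(result) {
  if (!inherits(result, "mpac_result")) stop_param("`result` must be an mpac_result")
  dims <- dim(result$image)
  labels <- matrix(0L, dims[1L], dims[2L])
  parent <- matrix(1L, dims[1L], dims[2L])
  contours <- vector("list", length(result$passes))
  for (k in seq_along(result$passes)) {
    p <- result$passes[[k]]
    labels <- labels + p$inner_mask
    contours[[k]] <- extract_zero_contours(p$phi_final, parent)
    parent <- p$inner_mask
  }
  structure(list(labels = labels, contours = contours,
                 n_passes = length(result$passes)),
            class = "mpac_contour_map")
}

#' Inner mask of a given depth, reconstructed from labels
#'
#' @param cmap an `mpac_contour_map`.
#' @param k pass index (1-based).
#' @return integer 0/1 matrix equal to pass `k`'s inner mask.
#' @export
labels_to_mask <- function(cmap, k) {
  if (!inherits(cmap, "mpac_contour_map")) stop_param("`cmap` must be an mpac_contour_map")
  if (k < 1 || k > cmap$n_passes) stop_param("`k` out of range")
  m <- matrix(0L, nrow(cmap$labels), ncol(cmap$labels))
  m[cmap$labels >= k] <- 1L
  m
}

#' Build the region-inclusion tree
#'
#' The nesting tree over the map's regions: the root is the whole domain
#' `w0`; each pass `k` hangs its outer shell `w̄k` and its inner core `wk`
#' off `w(k-1)`, and only the inner core is split further, so the inner
#' chain `w0 -> w1 -> ... -> wK` is a path. Outer shells are annotated leaf
#' siblings. Every node carries its pixel area and mean (denoised)
#' intensity; the outer shells plus the terminal core partition the domain.
#'
#' @param cmap an `mpac_contour_map`.
#' @param image image supplying the node intensity annotations (typically
#'   the denoised image of the run).
#' @return object of class `mpac_inclusion_tree`: a data.frame of nodes
#'   with columns `id`, `name`, `parent` (id, NA for root), `depth`,
#'   `kind` (`"root"`, `"inner"`, `"outer"`), `area`, `mean_intensity`.
#' @export
build_inclusion_tree <- function(cmap, image) {
  if (!inherits(cmap, "mpac_contour_map")) stop_param("`cmap` must be an mpac_contour_map")
  check_image(image)
  same_shape(cmap$labels, image, "labels", "image")
  k_max <- cmap$n_passes
  nodes <- data.frame(id = 1L, name = "w0", parent = NA_integer_,
                      depth = 0L, kind = "root",
                      area = length(image),
                      mean_intensity = mean(image))
  inner_id <- 1L
  for (k in seq_len(k_max)) {
    inner <- cmap$labels >= k
    outer <- cmap$labels == (k - 1L)
    out_node <- data.frame(id = nrow(nodes) + 1L,
                           name = sprintf("w%d_bar", k),
                           parent = inner_id, depth = k, kind = "outer",
                           area = sum(outer),
                           mean_intensity = if (any(outer)) mean(image[outer]) else NA_real_)
    nodes <- rbind(nodes, out_node)
    in_node <- data.frame(id = nrow(nodes) + 1L,
                          name = sprintf("w%d", k),
                          parent = inner_id, depth = k, kind = "inner",
                          area = sum(inner),
                          mean_intensity = if (any(inner)) mean(image[inner]) else NA_real_)
    nodes <- rbind(nodes, in_node)
    inner_id <- in_node$id
  }
  structure(nodes, class = c("mpac_inclusion_tree", "data.frame"))
}

#' Total polyline length of one pass's contours
#'
#' Sum of segment lengths over all polylines of pass `k`; on smooth
#' phantoms this is close to the discrete weighted length energy with
#' `g = 1`.
#'
#' @param cmap an `mpac_contour_map`.
#' @param k pass index.
#' @return nonnegative scalar (pixel units).
#' @export
contour_length <- function(cmap, k) {
  if (!inherits(cmap, "mpac_contour_map")) stop_param("`cmap` must be an mpac_contour_map")
  if (k < 1 || k > cmap$n_passes) stop_param("`k` out of range")
  sum(vapply(cmap$contours[[k]], function(poly) {
    if (nrow(poly) < 2) return(0)
    sum(sqrt(diff(poly$row)^2 + diff(poly$col)^2))
  }, numeric(1)))
}

#' @export
print.mpac_contour_map <- function(x, ...) {
  areas <- vapply(seq_len(x$n_passes), function(k) sum(x$labels >= k), integer(1))
  cat(sprintf("Adaptive contour map: %d nested contour%s over a %dx%d grid\n",
              x$n_passes, if (x$n_passes == 1) "" else "s",
              nrow(x$labels), ncol(x$labels)))
  if (x$n_passes > 0) {
    cat("  inner areas by depth:", paste(areas, collapse = " > "), "\n")
  }
  invisible(x)
}
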