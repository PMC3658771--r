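# Internal helpers: classed conditions, shifted-matrix access, validation.

mpac_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mpac_error", "error")))
}

stop_param <- function(msg) mpac_stop(msg, "mpac_param_error")
stop_numeric <- function(msg) mpac_stop(msg, "mpac_numeric_error")
stop_io <- function(msg) mpac_stop(msg, "mpac_io_error")
stop_consistency <- function(msg) mpac_stop(msg, "mpac_consistency_error")

# Degenerate-region signal; `side` records which sub-region emptied.
stop_degenerate <- function(msg, side = c("inner", "outer")) {
  side <- match.arg(side)
  cond <- errorCondition(msg, side = side,
                         class = c("mpac_degenerate_error", "mpac_error", "error"))
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# m[i + dr, j + dc] with replicate-edge (zero normal derivative) boundaries.
shift_mat <- function(m, dr = 0L, dc = 0L) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

check_field <- function(m, name = "field", min_dim = 2L) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_param(sprintf("`%s` must be a numeric matrix", name))
  }
  if (nrow(m) < min_dim || ncol(m) < min_dim) {
    stop_param(sprintf("`%s` must be at least %dx%d", name, min_dim, min_dim))
  }
  if (!all(is.finite(m))) {
    stop_param(sprintf("`%s` contains non-finite values", name))
  }
  invisible(m)
}

check_image <- function(img, name = "image") {
  check_field(img, name, min_dim = 3L)
}

check_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask)) stop_param(sprintf("`%s` must be a matrix", name))
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1))) {
    stop_param(sprintf("`%s` must be binary (0/1)", name))
  }
  invisible(mask)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_param(sprintf("`%s` must be a positive finite scalar", name))
  }
  invisible(x)
}

same_shape <- function(a, b, na, nb) {
  if (!identical(dim(a), dim(b))) {
    stop_param(sprintf("`%s` and `%s` must have identical dimensions", na, nb))
  }
  invisible(TRUE)
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
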