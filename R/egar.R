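# Extended grey absolute relational (EGAR) surface model.
#
# Each zero-point image is rendered as a piecewise-linear surface over the
# (sample, time) grid: every unit cell is split into two triangles by a
# diagonal, and the signed volume under the surface is a weighted sum of
# the four cell corners
#
#   A1 = x0(s, t),  A2 = x0(s+1, t),  A3 = x0(s, t+1),  A4 = x0(s+1, t+1).
#
# The two possible diagonals give two weightings:
#   style 1:  (1/3)(A2 + A3) + (1/6)(A1 + A4)   per cell
#   style 2:  (1/6)(A2 + A3) + (1/3)(A1 + A4)   per cell
#
# and the relational degree
#
#   eps = (1 + |s_i| + |s_j|) / (1 + |s_i| + |s_j| + |s_i - s_j|)
#
# generally differs between the two styles -- the non-uniqueness that the
# dispersion model removes.  Absolute values are taken of the whole-panel
# signed sums; the difference volume subtracts corner-wise inside the sum
# before the absolute value.

# Internal: corner sub-matrices of an (N x n) value grid, one entry per
# unit cell.
cell_corners <- function(v) {
  N <- nrow(v); n <- ncol(v)
  if (N < 2L || n < 2L)
    stop("surface volumes need at least 2 samples and 2 time points",
         call. = FALSE)
  list(A1 = v[seq_len(N - 1L), seq_len(n - 1L), drop = FALSE],
       A2 = v[2L:N, seq_len(n - 1L), drop = FALSE],
       A3 = v[seq_len(N - 1L), 2L:n, drop = FALSE],
       A4 = v[2L:N, 2L:n, drop = FALSE])
}

#' Signed volume under a triangulated zero-image surface
#'
#' Sums the per-cell triangulated volume weights over all `(N-1)(n-1)`
#' unit cells, before any absolute value is taken.  `style` selects the
#' cell diagonal: style 1 weights the anti-diagonal corners (A2, A3) by
#' 1/3 and the main-diagonal corners (A1, A4) by 1/6; style 2 swaps the
#' weights.
#'
#' @param image a [zero_point_image()] result, a [panel_matrix()], or a
#'   plain numeric matrix of zero-image values, at least 2 x 2.
#' @param style `1` or `2`, the surface connection style.
#' @return single signed real.
#' @examples
#' signed_volume(matrix(c(0, 1, 0, 0), 2), style = 1)  # 1/3
#' @export
signed_volume <- function(image, style = 1) {
  v <- if (inherits(image, "panel_matrix")) image$values else as.matrix(image)
  style <- check_style(style)
  cc <- cell_corners(v)
  if (style == 1L)
    sum((cc$A2 + cc$A3) / 3 + (cc$A1 + cc$A4) / 6)
  else
    sum((cc$A2 + cc$A3) / 6 + (cc$A1 + cc$A4) / 3)
}

check_style <- function(style) {
  if (length(style) != 1L || !style %in% c(1, 2))
    stop("`style` must be 1 or 2", call. = FALSE)
  as.integer(style)
}

#' EGAR degree from two zero-point images
#'
#' Computes the surface volumes `|s_i|`, `|s_j|` and the difference volume
#' `|s_i - s_j|` (difference taken corner-wise inside the cell sums) for
#' the given connection style, then
#' `eps = (1 + |s_i| + |s_j|) / (1 + |s_i| + |s_j| + |s_i - s_j|)`.
#'
#' @param image_a,image_b zero-image matrices (or `panel_matrix` objects)
#'   of identical shape, at least 2 x 2.
#' @inheritParams signed_volume
#' @return an object of class `egar_result`: `style`, `vol_i`, `vol_j`,
#'   `vol_diff`, `degree`.
#' @export
egar_from_images <- function(image_a, image_b, style = 1) {
  va <- if (inherits(image_a, "panel_matrix")) image_a$values else as.matrix(image_a)
  vb <- if (inherits(image_b, "panel_matrix")) image_b$values else as.matrix(image_b)
  if (!identical(dim(va), dim(vb)))
    stop("zero images have different shapes", call. = FALSE)
  style <- check_style(style)
  si <- signed_volume(va, style)
  sj <- signed_volume(vb, style)
  sdiff <- signed_volume(va - vb, style)
  vol_i <- abs(si); vol_j <- abs(sj); vol_diff <- abs(sdiff)
  structure(
    list(style = style, vol_i = vol_i, vol_j = vol_j, vol_diff = vol_diff,
         degree = (1 + vol_i + vol_j) / (1 + vol_i + vol_j + vol_diff)),
    class = "egar_result"
  )
}

#' @export
print.egar_result <- function(x, ...) {
  cat("<egar_result> style ", x$style,
      ": |s_i| = ", format(round(x$vol_i, 4), nsmall = 4),
      ", |s_j| = ", format(round(x$vol_j, 4), nsmall = 4),
      ", |s_i - s_j| = ", format(round(x$vol_diff, 4), nsmall = 4),
      ", degree = ", format(round(x$degree, 4), nsmall = 4), "\n", sep = "")
  invisible(x)
}

#' EGAR degree between two raw panels
#'
#' Takes the zero-point image of both panels, then applies
#' [egar_from_images()] under the chosen connection style.
#'
#' @param a,b aligned [panel_matrix()] objects, at least 2 samples and
#'   2 time points.
#' @inheritParams signed_volume
#' @return an `egar_result`.
#' @export
egar_degree <- function(a, b, style = 1) {
  stopifnot(inherits(a, "panel_matrix"), inherits(b, "panel_matrix"))
  check_aligned(a, b)
  egar_from_images(zero_point_image(a), zero_point_image(b), style)
}

#' Connection-style uniqueness gap
#'
#' Absolute difference between the EGAR degrees under the two surface
#' connection styles.  Zero whenever both zero images vanish identically
#' (every row of both raw panels constant over time); on generic panels
#' the two styles disagree, which is the defect that motivates the
#' dispersion-based model.
#'
#' @inheritParams egar_degree
#' @return single nonnegative real.
#' @export
uniqueness_gap <- function(a, b) {
  abs(egar_degree(a, b, 1)$degree - egar_degree(a, b, 2)$degree)
}
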