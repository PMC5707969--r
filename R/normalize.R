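# Dimensionless normalization (the "average operator" Z) and zero-point
# imaging shared by the dispersion and surface relational models.

#' Mean-normalize a panel matrix
#'
#' Applies the average operator: each entry is divided by the mean of its
#' scope, making heterogeneous units (yuan, persons, event counts)
#' dimensionless.  Under the default `"row-mean"` scope each sample's time
#' series is divided by its own mean, so every row with nonzero mean has
#' mean exactly 1 afterwards; `"matrix-mean"` divides all entries by the
#' grand mean.
#'
#' Scopes with zero mean (e.g. an all-zero death-toll series) are handled
#' by `zero_row_policy`: `"zeros"` leaves them as all-zero rows (the
#' default, so pipelines run on data containing an identically-zero
#' series), `"error"` aborts naming the offending row.
#'
#' @param panel a [panel_matrix()].
#' @param scope `"row-mean"` (each row by its own mean) or `"matrix-mean"`
#'   (all entries by the grand mean).
#' @param zero_row_policy `"zeros"` or `"error"`.
#' @return a `panel_matrix` additionally of class `normalized_panel`, with
#'   attributes `normalization_scope` and `zero_row_policy`.
#' @examples
#' mean_normalize(panel_matrix(matrix(c(1, 2, 3, 10, 20, 30), 2,
#'                                    byrow = TRUE), "x"))
#' @export
mean_normalize <- function(panel,
                           scope = c("row-mean", "matrix-mean"),
                           zero_row_policy = c("zeros", "error")) {
  stopifnot(inherits(panel, "panel_matrix"))
  scope <- match.arg(scope)
  zero_row_policy <- match.arg(zero_row_policy)
  v <- panel$values
  if (scope == "row-mean") {
    mu <- rowMeans(v)
    zero <- mu == 0
    if (any(zero) && zero_row_policy == "error")
      stop("series '", panel$series_id, "': row(s) ",
           paste(panel$sample_labels[zero], collapse = ", "),
           " have zero mean and cannot be normalized", call. = FALSE)
    mu[zero] <- 1  # 0/1 = 0: all-zero rows stay all-zero
    out <- v / mu
  } else {
    mu <- mean(v)
    if (mu == 0) {
      if (zero_row_policy == "error")
        stop("series '", panel$series_id,
             "': matrix mean is zero and cannot be normalized",
             call. = FALSE)
      out <- v * 0
    } else {
      out <- v / mu
    }
  }
  res <- panel_matrix(out, panel$series_id,
                      panel$sample_labels, panel$time_labels,
                      units = "dimensionless")
  class(res) <- c("normalized_panel", class(res))
  attr(res, "normalization_scope") <- scope
  attr(res, "zero_row_policy") <- zero_row_policy
  res
}

#' Zero-point image of a panel matrix
#'
#' Shifts each sample's time series so its first value is zero:
#' \eqn{x^0(s,t) = x(s,t) - x(s,1)}.  This is the standard starting point
#' for absolute (area/volume based) grey relational degrees; the first
#' time column of the result is identically zero.
#'
#' @param panel a [panel_matrix()].
#' @return a `panel_matrix` additionally of class `zero_image_panel`.
#' @examples
#' zero_point_image(panel_matrix(matrix(c(5, 7, 6), 1), "x"))$values
#' @export
zero_point_image <- function(panel) {
  stopifnot(inherits(panel, "panel_matrix"))
  v <- panel$values - panel$values[, 1L]
  res <- panel_matrix(v, panel$series_id,
                      panel$sample_labels, panel$time_labels,
                      units = panel$units)
  class(res) <- c("zero_image_panel", class(res))
  res
}

#' Mean-normalize every member of a panel set
#'
#' @inheritParams mean_normalize
#' @param panels a [panel_set()].
#' @return a `panel_set` of normalized members.
#' @export
normalize_panel_set <- function(panels,
                                scope = c("row-mean", "matrix-mean"),
                                zero_row_policy = c("zeros", "error")) {
  stopifnot(inherits(panels, "panel_set"))
  scope <- match.arg(scope)
  zero_row_policy <- match.arg(zero_row_policy)
  panel_set(lapply(panels$members, mean_normalize,
                   scope = scope, zero_row_policy = zero_row_policy))
}
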