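# Domain containers: a single behaviour matrix and an aligned set of them.
#
# A behaviour matrix X_i(s, t) holds the values of one indicator (or one
# investigation object) over N samples (rows, e.g. provinces) and n time
# points (columns, e.g. years).  A panel set is an ordered collection of m
# such matrices sharing sample and time labels -- the three-dimensional
# panel the relational models operate on.

#' Construct a panel behaviour matrix
#'
#' A `panel_matrix` is one indicator's behaviour matrix \eqn{X_i(s,t)}:
#' `N` samples (rows) observed at `n` time points (columns).  All entries
#' must be finite.  Sample and time labels default to the matrix dimnames
#' or to `"s1"..."sN"` / `"t1"..."tn"`.
#'
#' @param values numeric matrix (or object coercible to one), N x n,
#'   all entries finite.
#' @param series_id single character label identifying the series.
#' @param sample_labels character vector of length N.
#' @param time_labels character vector of length n.
#' @param units optional free-text annotation (e.g. "10^4 yuan").
#' @return an object of class `panel_matrix`.
#' @examples
#' pm <- panel_matrix(matrix(1:6, 2, 3), "losses")
#' dim(pm$values)
#' @export
panel_matrix <- function(values, series_id,
                         sample_labels = NULL, time_labels = NULL,
                         units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(series_id) != 1L || !nzchar(as.character(series_id)))
    stop("`series_id` must be a single non-empty label", call. = FALSE)
  if (!all(is.finite(values)))
    stop("panel matrix '", series_id, "' contains non-finite entries",
         call. = FALSE)
  N <- nrow(values); n <- ncol(values)
  if (N < 1L || n < 1L)
    stop("panel matrix '", series_id, "' must have at least 1 row and 1 column",
         call. = FALSE)
  if (is.null(sample_labels))
    sample_labels <- rownames(values) %||% paste0("s", seq_len(N))
  if (is.null(time_labels))
    time_labels <- colnames(values) %||% paste0("t", seq_len(n))
  sample_labels <- as.character(sample_labels)
  time_labels <- as.character(time_labels)
  if (length(sample_labels) != N)
    stop("sample_labels length (", length(sample_labels),
         ") does not match row count (", N, ")", call. = FALSE)
  if (length(time_labels) != n)
    stop("time_labels length (", length(time_labels),
         ") does not match column count (", n, ")", call. = FALSE)
  dimnames(values) <- list(sample_labels, time_labels)
  structure(
    list(series_id = as.character(series_id), values = values,
         sample_labels = sample_labels, time_labels = time_labels,
         units = as.character(units)),
    class = "panel_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.panel_matrix <- function(x, ...) {
  cat("<panel_matrix> series '", x$series_id, "': ",
      nrow(x$values), " samples x ", ncol(x$values), " times",
      if (nzchar(x$units)) paste0(" [", x$units, "]"), "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
dim.panel_matrix <- function(x) dim(x$values)

#' Construct a panel set
#'
#' An ordered collection of `m >= 2` aligned behaviour matrices sharing
#' sample and time labels -- the full panel
#' \eqn{X = \{X_1(s,t), \ldots, X_m(s,t)\}}.
#'
#' @param members list of [panel_matrix()] objects with identical shapes
#'   and identical sample/time labels, and distinct `series_id`s.
#' @return an object of class `panel_set`.
#' @examples
#' ps <- panel_set(list(
#'   panel_matrix(matrix(1:4, 2), "a"),
#'   panel_matrix(matrix(4:1, 2), "b")
#' ))
#' series_ids(ps)
#' @export
panel_set <- function(members) {
  if (!is.list(members) || length(members) < 2L)
    stop("a panel set needs at least 2 member matrices", call. = FALSE)
  ok <- vapply(members, inherits, logical(1), "panel_matrix")
  if (!all(ok))
    stop("all members must be panel_matrix objects", call. = FALSE)
  ids <- vapply(members, function(p) p$series_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate series_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ref <- members[[1L]]
  for (p in members[-1L]) {
    if (!identical(dim(p$values), dim(ref$values)))
      stop("series '", p$series_id, "' shape ",
           paste(dim(p$values), collapse = "x"),
           " differs from '", ref$series_id, "' shape ",
           paste(dim(ref$values), collapse = "x"), call. = FALSE)
    if (!identical(p$sample_labels, ref$sample_labels) ||
        !identical(p$time_labels, ref$time_labels))
      stop("series '", p$series_id,
           "' sample/time labels differ from '", ref$series_id, "'",
           call. = FALSE)
  }
  names(members) <- ids
  structure(
    list(members = members,
         sample_labels = ref$sample_labels,
         time_labels = ref$time_labels),
    class = "panel_set"
  )
}

#' @export
print.panel_set <- function(x, ...) {
  cat("<panel_set> ", length(x$members), " series, ",
      length(x$sample_labels), " samples x ",
      length(x$time_labels), " times\n", sep = "")
  cat("  series:", paste(series_ids(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.panel_set <- function(x) length(x$members)

#' Series identifiers of a panel set
#' @param panels a [panel_set()].
#' @return character vector of member `series_id`s, in order.
#' @export
series_ids <- function(panels) {
  stopifnot(inherits(panels, "panel_set"))
  unname(vapply(panels$members, function(p) p$series_id, character(1)))
}

# Internal: fetch a member by id with a helpful error.
panel_member <- function(panels, id) {
  ids <- series_ids(panels)
  k <- match(id, ids)
  if (is.na(k))
    stop("series '", id, "' not found; available: ",
         paste(ids, collapse = ", "), call. = FALSE)
  panels$members[[k]]
}

# Internal: check two panel matrices are mutually aligned.
check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("panels '", a$series_id, "' and '", b$series_id,
         "' have different shapes", call. = FALSE)
  if (!identical(a$sample_labels, b$sample_labels) ||
      !identical(a$time_labels, b$time_labels))
    stop("panels '", a$series_id, "' and '", b$series_id,
         "' have different sample/time labels", call. = FALSE)
  invisible(TRUE)
}
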