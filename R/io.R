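# Tabular readers and writers.
#
# Long layout (canonical): one CSV with columns series, sample, time,
# value; one row per cell; (series, sample, time) triples unique; every
# series must cover the full sample x time grid.  Wide layout: one CSV
# per series, first column the sample labels, remaining columns the time
# points; the series id is taken from the file name.  Labels are opaque
# strings; sample/time order is taken from first appearance in the file.

#' Read a panel set from tabular text
#'
#' @param path for `layout = "long"`, a single CSV path; for
#'   `layout = "wide"`, a character vector of CSV paths, one per series
#'   (series ids from the file base names).
#' @param layout `"long"` or `"wide"`.
#' @param sep field delimiter (default comma).
#' @return a [panel_set()].
#' @export
read_panel_table <- function(path, layout = c("long", "wide"), sep = ",") {
  layout <- match.arg(layout)
  if (layout == "long") read_panel_long(path, sep) else read_panel_wide(path, sep)
}

read_panel_long <- function(path, sep) {
  if (length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("series", "sample", "time", "value")
  if (!all(need %in% names(df)))
    stop("long layout needs columns ", paste(need, collapse = ", "),
         "; found ", paste(names(df), collapse = ", "), call. = FALSE)
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val))
    stop("non-numeric value at row(s) ",
         paste(utils::head(which(is.na(val)), 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  key <- paste(df$series, df$sample, df$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (series, sample, time) triple at row ",
         which(duplicated(key))[1L], " of ", path, call. = FALSE)
  sids <- unique(df$series)
  samples <- unique(df$sample)
  times <- unique(df$time)
  members <- lapply(sids, function(id) {
    sub <- df[df$series == id, ]
    v <- matrix(NA_real_, length(samples), length(times),
                dimnames = list(samples, times))
    si <- match(sub$sample, samples)
    ti <- match(sub$time, times)
    if (anyNA(si) || anyNA(ti))
      stop("series '", id, "' uses unknown sample/time labels", call. = FALSE)
    v[cbind(si, ti)] <- val[df$series == id]
    if (anyNA(v)) {
      miss <- which(is.na(v), arr.ind = TRUE)[1L, ]
      stop("series '", id, "' is missing cell (sample '",
           samples[miss[1L]], "', time '", times[miss[2L]], "')",
           call. = FALSE)
    }
    panel_matrix(v, id, samples, times)
  })
  panel_set(members)
}

read_panel_wide <- function(paths, sep) {
  if (length(paths) < 2L)
    stop("wide layout needs one file per series (at least 2)", call. = FALSE)
  members <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    df <- utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE,
                            colClasses = "character", strip.white = TRUE)
    if (ncol(df) < 2L)
      stop("wide file ", p, " needs a sample column plus time columns",
           call. = FALSE)
    samples <- df[[1L]]
    v <- vapply(df[-1L],
                function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(df)))
    v <- matrix(v, nrow = nrow(df),
                dimnames = list(samples, names(df)[-1L]))
    if (anyNA(v))
      stop("non-numeric or missing value in ", p, call. = FALSE)
    id <- sub("\\.[^.]*$", "", basename(p))
    panel_matrix(v, id, samples, colnames(v))
  })
  panel_set(members)
}

#' Write a panel set as tabular text
#'
#' @param panels a [panel_set()].
#' @param path long layout: the output CSV path.  Wide layout: a
#'   directory; one `<series_id>.csv` file is written per member.
#' @param layout `"long"` or `"wide"`.
#' @return the path(s) written, invisibly.
#' @export
write_panel_table <- function(panels, path, layout = c("long", "wide")) {
  stopifnot(inherits(panels, "panel_set"))
  layout <- match.arg(layout)
  if (layout == "long") {
    rows <- do.call(rbind, lapply(panels$members, function(p) {
      data.frame(series = p$series_id,
                 sample = rep(p$sample_labels, times = ncol(p$values)),
                 time = rep(p$time_labels, each = nrow(p$values)),
                 value = as.vector(p$values),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  out <- vapply(panels$members, function(p) {
    f <- file.path(path, paste0(p$series_id, ".csv"))
    df <- data.frame(sample = p$sample_labels, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df[p$time_labels] <- as.data.frame(p$values, optional = TRUE)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    f
  }, character(1))
  invisible(out)
}

#' Read a dispersion table
#'
#' Direct ingestion of precomputed dispersions, ready for
#' [epsilon_from_dispersions()].  Reference mode expects two columns
#' (comparison label, dispersion).  Pairwise mode expects a square
#' labelled matrix (first column = row labels) with zero diagonal; an
#' upper triangle left empty is completed by symmetry, and a filled
#' matrix must be symmetric within `1e-9`.
#'
#' @param path CSV path.
#' @param mode `"reference"` or `"pairwise"`.
#' @param sep field delimiter.
#' @return reference mode: named numeric vector.  Pairwise mode:
#'   symmetric numeric matrix with zero diagonal.
#' @export
read_dispersion_table <- function(path, mode = c("reference", "pairwise"),
                                  sep = ",") {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (mode == "reference") {
    if (ncol(df) < 2L)
      stop("reference dispersion table needs (label, dispersion) columns",
           call. = FALSE)
    d <- suppressWarnings(as.numeric(df[[2L]]))
    if (anyNA(d)) stop("non-numeric dispersion in ", path, call. = FALSE)
    if (any(d < 0)) stop("negative dispersion in ", path, call. = FALSE)
    names(d) <- df[[1L]]
    return(d)
  }
  labels <- df[[1L]]
  m <- nrow(df)
  if (ncol(df) != m + 1L)
    stop("pairwise dispersion table must be square: ", m, " rows but ",
         ncol(df) - 1L, " value columns", call. = FALSE)
  v <- sapply(df[-1L], function(col) suppressWarnings(as.numeric(col)))
  v <- matrix(v, m, m, dimnames = list(labels, names(df)[-1L]))
  # empty upper triangle => mirror the lower
  if (all(is.na(v[upper.tri(v)])) && !anyNA(v[lower.tri(v, diag = TRUE)])) {
    v[upper.tri(v)] <- t(v)[upper.tri(v)]
  }
  if (anyNA(v))
    stop("missing or non-numeric dispersion entries in ", path, call. = FALSE)
  if (any(v < 0)) stop("negative dispersion in ", path, call. = FALSE)
  if (any(abs(diag(v)) > 1e-9))
    stop("pairwise dispersion diagonal must be zero", call. = FALSE)
  if (any(abs(v - t(v)) > 1e-9))
    stop("pairwise dispersion matrix is asymmetric beyond tolerance",
         call. = FALSE)
  dimnames(v) <- list(labels, labels)
  v
}

#' Write a relational result as CSV
#'
#' Full-precision values plus a 4-decimal display column (reference mode)
#' or a full-precision matrix (pairwise mode).
#'
#' @param result a `relational_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_relational_result <- function(result, path) {
  stopifnot(inherits(result, "relational_result"))
  if (result$mode == "reference") {
    df <- data.frame(series = names(result$degrees),
                     dispersion = result$dispersions,
                     degree = result$degrees,
                     degree_4dp = sprintf("%.4f", result$degrees),
                     rank = result$ranking,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(as.data.frame(result$degrees), path, quote = FALSE)
  }
  invisible(path)
}
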