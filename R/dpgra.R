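# Dispersion-based panel grey relational analysis (DPGRA).
#
# The association between two aligned panels is scored through the
# entrywise absolute-distance field l_ij(s,t) = |x_i(s,t) - x_j(s,t)| of
# their mean-normalized matrices.  The dispersion
#
#   D_ij = (1 / (N*n)) * sum_{s,t} (l_ij(s,t) - lbar_ij)^2
#
# is the population variance of that field: D_ij = 0 means the two
# surfaces differ by a constant gap everywhere (maximal relation), large
# D_ij means volatile, unstable differences.  The relational degree is
#
#   eps_ij = Dbar / (Dbar + D_ij),
#
# with Dbar a cohort mean of dispersions, so eps lies in (0, 1] and
# decreases in D_ij.  Rankings depend only on the D_ij ordering, not on
# the Dbar convention.

#' Entrywise absolute-distance field between two panels
#'
#' @param a,b aligned [panel_matrix()] objects (typically
#'   [mean_normalize()]d), identical shapes and labels.
#' @return numeric N x n matrix `|a - b|`; symmetric in its arguments.
#' @export
distance_field <- function(a, b) {
  stopifnot(inherits(a, "panel_matrix"), inherits(b, "panel_matrix"))
  check_aligned(a, b)
  abs(a$values - b$values)
}

#' Dispersion of panel data between two panels
#'
#' The population variance (divide by `N * n`, not `N * n - 1`) of the
#' absolute-distance field between the two panels.  Zero iff the field is
#' constant, i.e. the panels differ by the same amount everywhere.
#'
#' @inheritParams distance_field
#' @return an object of class `dispersion_record`: list with `pair`
#'   (the two series ids), `distance_field` (N x n matrix),
#'   `mean_distance` and `dispersion`.
#' @examples
#' a <- panel_matrix(matrix(1, 2, 2), "a")
#' b <- panel_matrix(matrix(c(0, 1, 1, 1), 2), "b")
#' dispersion(a, b)$dispersion  # 0.1875
#' @export
dispersion <- function(a, b) {
  l <- distance_field(a, b)
  lbar <- mean(l)
  D <- mean((l - lbar)^2)
  structure(
    list(pair = c(a$series_id, b$series_id),
         distance_field = l, mean_distance = lbar, dispersion = D),
    class = "dispersion_record"
  )
}

#' @export
print.dispersion_record <- function(x, ...) {
  cat("<dispersion_record> ", x$pair[1], " vs ", x$pair[2],
      ": l-bar = ", format(round(x$mean_distance, 4), nsmall = 4),
      ", D = ", format(round(x$dispersion, 4), nsmall = 4), "\n", sep = "")
  invisible(x)
}

#' Cohort mean dispersion
#'
#' The normalizing constant Dbar used in the relational degree.  Its
#' convention is mode dependent:
#' \describe{
#'   \item{reference}{`dispersions` holds the comparison-vs-reference
#'     values (self-pair excluded); Dbar is their arithmetic mean.}
#'   \item{pairwise}{`dispersions` holds the `m(m-1)/2` distinct
#'     unordered-pair values (strict lower triangle); Dbar is their sum
#'     divided by `m(m+1)/2`, i.e. the mean over all unordered pairs
#'     including the zero-valued self-pairs.}
#' }
#'
#' @param dispersions numeric vector of nonnegative dispersion values.
#' @param mode `"reference"` or `"pairwise"`.
#' @param m number of series in the cohort; required for pairwise mode,
#'   where `length(dispersions)` must equal `m(m-1)/2`.
#' @return the cohort mean Dbar (single nonnegative number).
#' @export
cohort_mean_dispersion <- function(dispersions,
                                   mode = c("reference", "pairwise"),
                                   m = NULL) {
  mode <- match.arg(mode)
  dispersions <- as.numeric(dispersions)
  if (length(dispersions) == 0L)
    stop("no dispersion values supplied", call. = FALSE)
  if (any(!is.finite(dispersions)) || any(dispersions < 0))
    stop("dispersions must be finite and nonnegative", call. = FALSE)
  if (mode == "reference") return(mean(dispersions))
  if (is.null(m))
    stop("pairwise mode needs `m`, the number of series", call. = FALSE)
  m <- as.integer(m)
  if (length(dispersions) != m * (m - 1L) / 2L)
    stop("pairwise mode expects m(m-1)/2 = ", m * (m - 1L) / 2L,
         " values, got ", length(dispersions), call. = FALSE)
  sum(dispersions) / (m * (m + 1L) / 2L)
}

#' Dispersion-based relational degree
#'
#' `eps = Dbar / (Dbar + D)`: 1 when `D = 0`, strictly decreasing in `D`.
#' When the whole cohort is perfectly related (`Dbar = 0`, so every `D`
#' is 0) the degree is defined as 1 by convention, avoiding 0/0.
#'
#' @param D nonnegative dispersion value(s); vectorized.
#' @param D_bar nonnegative cohort mean dispersion.
#' @return relational degree(s) in (0, 1].
#' @export
dpgra_degree <- function(D, D_bar) {
  if (any(!is.finite(D)) || any(D < 0))
    stop("`D` must be finite and nonnegative", call. = FALSE)
  if (length(D_bar) != 1L || !is.finite(D_bar) || D_bar < 0)
    stop("`D_bar` must be a single finite nonnegative value", call. = FALSE)
  if (D_bar == 0) return(rep(1, length(D)))
  D_bar / (D_bar + D)
}

#' Rank relational degrees
#'
#' Rank 1 is the largest degree.  `"competition"` ranking (ties share the
#' smallest rank, next rank skipped) is the default; `"average"` assigns
#' tied entries their average rank.
#'
#' @param degrees numeric vector of relational degrees; names preserved.
#' @param tie_policy `"competition"` or `"average"`.
#' @return integer (competition) or numeric (average) vector of ranks.
#' @export
rank_series <- function(degrees, tie_policy = c("competition", "average")) {
  tie_policy <- match.arg(tie_policy)
  if (length(degrees) == 0L)
    stop("no degrees to rank", call. = FALSE)
  r <- rank(-as.numeric(degrees),
            ties.method = if (tie_policy == "competition") "min" else "average")
  if (tie_policy == "competition") r <- as.integer(r)
  names(r) <- names(degrees)
  r
}

# Internal: assemble a relational_result.
new_relational_result <- function(mode, cohort_mean, degrees, ranking,
                                  dispersions, reference_id = NULL,
                                  tie_policy = "competition") {
  structure(
    list(mode = mode, reference_id = reference_id,
         cohort_mean = cohort_mean, dispersions = dispersions,
         degrees = degrees, ranking = ranking, tie_policy = tie_policy),
    class = "relational_result"
  )
}

#' @export
print.relational_result <- function(x, ...) {
  cat("<relational_result> mode = ", x$mode,
      if (!is.null(x$reference_id)) paste0(", reference = '",
                                           x$reference_id, "'"),
      "\n  cohort mean dispersion D-bar = ",
      format(round(x$cohort_mean, 4), nsmall = 4), "\n", sep = "")
  if (x$mode == "reference") {
    df <- data.frame(series = names(x$degrees),
                     dispersion = round(x$dispersions, 4),
                     degree = round(x$degrees, 4),
                     rank = x$ranking, row.names = NULL)
    print(df[order(df$rank), ], row.names = FALSE)
  } else {
    cat("  relational degree matrix:\n")
    print(round(x$degrees, 4))
  }
  invisible(x)
}

#' Reference-mode DPGRA analysis of a panel set
#'
#' Normalizes every member, computes the dispersion of each comparison
#' series against the reference, the reference-mode cohort mean, the
#' relational degree per comparison, and the ranking (rank 1 = most
#' related).
#'
#' @param panels a [panel_set()].
#' @param reference_id `series_id` of the reference member.
#' @param scope,zero_row_policy passed to [mean_normalize()].
#' @param tie_policy passed to [rank_series()].
#' @return a `relational_result` with one degree per comparison series.
#' @export
dpgra_reference <- function(panels, reference_id,
                            scope = c("row-mean", "matrix-mean"),
                            zero_row_policy = c("zeros", "error"),
                            tie_policy = c("competition", "average")) {
  stopifnot(inherits(panels, "panel_set"))
  tie_policy <- match.arg(tie_policy)
  norm <- normalize_panel_set(panels, scope = scope,
                              zero_row_policy = zero_row_policy)
  ref <- panel_member(norm, reference_id)
  comp_ids <- setdiff(series_ids(norm), reference_id)
  if (length(comp_ids) < 1L)
    stop("need at least one comparison series besides the reference",
         call. = FALSE)
  Ds <- vapply(comp_ids,
               function(id) dispersion(ref, norm$members[[id]])$dispersion,
               numeric(1))
  D_bar <- cohort_mean_dispersion(Ds, "reference")
  eps <- dpgra_degree(Ds, D_bar)
  names(eps) <- comp_ids
  new_relational_result("reference", D_bar, eps,
                        rank_series(eps, tie_policy), Ds,
                        reference_id = reference_id,
                        tie_policy = tie_policy)
}

#' Pairwise-mode DPGRA analysis of a panel set
#'
#' Computes the dispersion for every unordered pair of members, the
#' pairwise-mode cohort mean (lower-triangle sum over `m(m+1)/2`), and the
#' symmetric relational-degree matrix with unit diagonal.
#'
#' @inheritParams dpgra_reference
#' @return a `relational_result` whose `degrees` and `dispersions` are
#'   symmetric m x m matrices; `ranking` ranks each series by its mean
#'   off-diagonal degree.
#' @export
dpgra_pairwise <- function(panels,
                           scope = c("row-mean", "matrix-mean"),
                           zero_row_policy = c("zeros", "error"),
                           tie_policy = c("competition", "average")) {
  stopifnot(inherits(panels, "panel_set"))
  tie_policy <- match.arg(tie_policy)
  norm <- normalize_panel_set(panels, scope = scope,
                              zero_row_policy = zero_row_policy)
  ids <- series_ids(norm)
  m <- length(ids)
  Dm <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      Dm[i, j] <- Dm[j, i] <-
        dispersion(norm$members[[i]], norm$members[[j]])$dispersion
    }
  }
  epsilon_from_dispersions(Dm, mode = "pairwise", tie_policy = tie_policy)
}

#' Relational degrees from precomputed dispersions
#'
#' Entry point for analyses whose dispersions are already known (e.g.
#' transcribed from a published table): applies the cohort-mean convention
#' and the degree formula without touching raw panels.
#'
#' @param dispersions reference mode: nonnegative vector of
#'   comparison-vs-reference dispersions (names become series labels).
#'   Pairwise mode: symmetric nonnegative square matrix with zero
#'   diagonal.
#' @param mode `"reference"` or `"pairwise"`.
#' @param tie_policy passed to [rank_series()].
#' @return a `relational_result`; pairwise mode carries matrix `degrees`
#'   with unit diagonal.
#' @examples
#' # six indicator dispersions vs direct economic losses:
#' d <- c(mariculture = 1.4547, coastal_engineering = 1.4778,
#'        death_toll = 13.3995, ship = 1.1552,
#'        collapsed_home = 3.4671, storm_surge_frequency = 1.0942)
#' round(epsilon_from_dispersions(d, "reference")$degrees, 4)
#' @export
epsilon_from_dispersions <- function(dispersions,
                                     mode = c("reference", "pairwise"),
                                     tie_policy = c("competition",
                                                    "average")) {
  mode <- match.arg(mode)
  tie_policy <- match.arg(tie_policy)
  if (mode == "reference") {
    d <- as.numeric(dispersions)
    names(d) <- names(dispersions) %||% paste0("series", seq_along(d))
    if (any(!is.finite(d)) || any(d < 0))
      stop("dispersions must be finite and nonnegative", call. = FALSE)
    D_bar <- cohort_mean_dispersion(d, "reference")
    eps <- dpgra_degree(d, D_bar)
    names(eps) <- names(d)
    return(new_relational_result("reference", D_bar, eps,
                                 rank_series(eps, tie_policy), d,
                                 tie_policy = tie_policy))
  }
  Dm <- as.matrix(dispersions)
  m <- nrow(Dm)
  if (m < 2L || ncol(Dm) != m)
    stop("pairwise mode needs a square matrix with m >= 2", call. = FALSE)
  if (any(!is.finite(Dm)) || any(Dm < 0))
    stop("dispersion matrix must be finite and nonnegative", call. = FALSE)
  if (any(abs(diag(Dm)) > 1e-9))
    stop("dispersion matrix must have a zero diagonal", call. = FALSE)
  if (any(abs(Dm - t(Dm)) > 1e-9))
    stop("dispersion matrix must be symmetric", call. = FALSE)
  ids <- rownames(Dm) %||% paste0("series", seq_len(m))
  dimnames(Dm) <- list(ids, ids)
  lower <- Dm[lower.tri(Dm)]
  D_bar <- cohort_mean_dispersion(lower, "pairwise", m = m)
  eps <- dpgra_degree(as.numeric(Dm), D_bar)
  eps <- matrix(eps, m, m, dimnames = dimnames(Dm))
  diag(eps) <- 1
  mean_off <- (rowSums(eps) - 1) / (m - 1L)
  new_relational_result("pairwise", D_bar, eps,
                        rank_series(mean_off, tie_policy), Dm,
                        tie_policy = tie_policy)
}
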