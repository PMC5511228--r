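#' NODF nestedness of a binary matrix
#'
#' Nestedness metric based on Overlap and Decreasing Fill. Rows and columns
#' are first sorted by their marginal totals in decreasing order (stable
#' tie-break on the original order, which cannot affect the result because
#' pairs with equal totals contribute zero). For an ordered column pair
#' (`u` before `v`) the paired contribution is 0 when
#' `total(u) <= total(v)` or `total(v) = 0` (the decreasing-fill condition,
#' strict), and otherwise `100 * overlap(u, v) / total(v)`; row pairs are
#' scored the same way. `nodf_cols` and `nodf_rows` average the column- and
#' row-pair contributions, and `nodf_matrix` divides the grand sum of
#' contributions by the total number of pairs.
#'
#' @param m binary matrix (species rows, island columns). Row/column order
#'   is irrelevant.
#' @return named numeric vector `c(matrix, rows, cols)`, each in \[0, 100\]
#'   (`NA` for a dimension with fewer than two elements).
#' @examples
#' stair <- outer(1:4, 1:4, ">=") * 1L   # perfectly nested staircase
#' nodf(stair)["matrix"]                 # 100
#' @export
nodf <- function(m) {
  m <- unclass(m)
  if (length(m) == 0) stop("empty matrix")
  if (!all(m %in% c(0, 1))) stop("matrix must be binary")
  if (nrow(m) == 1 && ncol(m) == 1) {
    stop("NODF undefined for a single-row, single-column matrix")
  }
  storage.mode(m) <- "double"
  rows <- nodf_axis_sum(m)          # row pairs
  cols <- nodf_axis_sum(t(m))       # column pairs
  np_r <- nrow(m) * (nrow(m) - 1) / 2
  np_c <- ncol(m) * (ncol(m) - 1) / 2
  c(matrix = (rows + cols) / (np_r + np_c),
    rows = if (np_r > 0) rows / np_r else NA_real_,
    cols = if (np_c > 0) cols / np_c else NA_real_)
}

# Sum of paired NODF contributions over the row pairs of m. For the pair
# (u, v) with u ranked before v, decreasing fill requires tot[u] > tot[v];
# after the descending sort the qualifying u for a given v are exactly the
# first k[v] rows (k[v] = number of totals strictly greater than tot[v]),
# so the per-v contribution is a prefix sum of the overlap column.
nodf_axis_sum <- function(m) {
  n <- nrow(m)
  if (n < 2) return(0)
  tot <- rowSums(m)
  ord <- order(tot, decreasing = TRUE)
  m <- m[ord, , drop = FALSE]
  tot <- tot[ord]
  k <- match(tot, tot) - 1L                # ties are contiguous when sorted
  keep <- which(tot > 0 & k > 0L)
  if (!length(keep)) return(0)
  ov <- tcrossprod(m, m[keep, , drop = FALSE])   # overlaps with qualifying v
  cs <- apply(ov, 2, cumsum)
  sum(100 * cs[cbind(k[keep], seq_along(keep))] / tot[keep])
}

#' CE (proportional-proportional) null matrices
#'
#' Cell-probabilistic randomization: each null cell `(i, j)` is an
#' independent Bernoulli draw with probability
#' `p_ij = (row_total_i / n_cols + col_total_j / n_rows) / 2`, clipped to
#' \[0, 1\] — i.e. the mean of the focal species' incidence proportion and
#' the focal island's fill. The expected fill of a null equals the observed
#' fill. Nulls may contain empty rows or columns; they are kept as drawn.
#'
#' @param m binary matrix.
#' @param n_null number of null matrices.
#' @param seed optional integer seed.
#' @return list of `n_null` binary matrices with the dimensions of `m`.
#' @export
ce_null <- function(m, n_null, seed = NULL) {
  if (n_null < 1) stop("n_null must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- ce_probabilities(m)
  lapply(seq_len(n_null), function(i) {
    matrix(stats::rbinom(length(p), 1L, p), nrow(m), ncol(m),
           dimnames = dimnames(m))
  })
}

ce_probabilities <- function(m) {
  m <- unclass(m)
  p <- (outer(rowSums(m) / ncol(m), rep(1, ncol(m))) +
          outer(rep(1, nrow(m)), colSums(m) / nrow(m))) / 2
  pmin(pmax(p, 0), 1)
}

#' Nestedness significance test against CE nulls
#'
#' Computes observed NODF (`Nr`), the NODF distribution over `n_null` CE
#' null matrices (`Ns`), the standardized effect size
#' `Z = (Nr - mean(Ns)) / sd(Ns)` (sample standard deviation), the relative
#' nestedness `RN = (Nr - mean(Ns)) / mean(Ns)`, and a one-tailed p-value
#' `(#\{Ns >= Nr\} + 1) / (n_null + 1)`. Nulls on which NODF is undefined
#' are redrawn (and counted in `n_redrawn`). When the null distribution has
#' zero variance `Z` is reported as `NA`; `RN` is still computed.
#'
#' @param m binary incidence matrix.
#' @param n_null number of null matrices (default 100).
#' @param seed optional integer seed for the null draws.
#' @return object of class `nestedness_test`: list with `nodf` (the
#'   observed `c(matrix, rows, cols)` vector), `Nr`, `Ns`, `Z`, `RN`, `p`,
#'   `n_null`, `n_redrawn`, `seed`.
#' @export
nestedness_test <- function(m, n_null = 100, seed = NULL) {
  obs <- nodf(m)
  if (!is.null(seed)) set.seed(seed)
  p <- ce_probabilities(m)
  Ns <- numeric(n_null)
  n_redrawn <- 0L
  for (i in seq_len(n_null)) {
    repeat {
      nm <- matrix(stats::rbinom(length(p), 1L, p), nrow(m), ncol(m))
      v <- tryCatch(nodf(nm)[["matrix"]], error = function(e) NA_real_)
      if (is.finite(v)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 1000L) stop("could not draw a null with defined NODF")
    }
    Ns[i] <- v
  }
  mu <- mean(Ns)
  sdev <- stats::sd(Ns)
  structure(list(
    nodf = obs, Nr = obs[["matrix"]], Ns = Ns,
    Z = if (sdev > 0) (obs[["matrix"]] - mu) / sdev else NA_real_,
    RN = if (mu > 0) (obs[["matrix"]] - mu) / mu
         else if (obs[["matrix"]] == mu) 0 else NA_real_,
    p = (sum(Ns >= obs[["matrix"]]) + 1) / (n_null + 1),
    n_null = n_null, n_redrawn = n_redrawn, seed = seed
  ), class = "nestedness_test")
}

#' @export
print.nestedness_test <- function(x, ...) {
  cat(sprintf("NODF = %.3f (rows %.3f, cols %.3f)\n",
              x$nodf[["matrix"]], x$nodf[["rows"]], x$nodf[["cols"]]))
  cat(sprintf("CE null (n = %d): mean %.3f, Z = %.3f, RN = %.3f, p = %.4g\n",
              x$n_null, mean(x$Ns), x$Z, x$RN, x$p))
  invisible(x)
}
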