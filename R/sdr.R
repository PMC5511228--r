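#' Partition pairwise beta diversity into similarity, richness difference
#' and replacement
#'
#' For two islands with richness `S_i`, `S_j` and `S_ij` shared species,
#' with pooled richness `S_t = S_i + S_j - S_ij`:
#' Jaccard similarity `S = S_ij / S_t`, relative richness difference
#' `D = |S_i - S_j| / S_t`, and relative species replacement
#' `R = 2 * min(S_i - S_ij, S_j - S_ij) / S_t`. The three components always
#' sum to 1, so a set of pairs lives on a ternary simplex.
#'
#' @param m incidence matrix ([build_incidence()]).
#' @param island_a,island_b island (column) names.
#' @return named numeric vector `c(S, D, R)` with attribute `pair`.
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 1, 0, 0, 1), 4, 2,
#'             dimnames = list(letters[1:4], c("i1", "i2")))
#' sdr_pair(m, "i1", "i2")
#' @export
sdr_pair <- function(m, island_a, island_b) {
  if (!all(c(island_a, island_b) %in% colnames(m))) {
    stop("both islands must be columns of the incidence matrix")
  }
  a <- m[, island_a] > 0
  b <- m[, island_b] > 0
  sdr_from_counts(sum(a), sum(b), sum(a & b),
                  pair = c(island_a, island_b))
}

sdr_from_counts <- function(s_i, s_j, s_ij, pair = NULL) {
  s_i <- unname(s_i); s_j <- unname(s_j); s_ij <- unname(s_ij)
  s_t <- s_i + s_j - s_ij
  if (s_t == 0) {
    stop("SDR undefined: pooled richness is zero for pair ",
         paste(pair, collapse = " / "))
  }
  out <- c(S = s_ij / s_t,
           D = abs(s_i - s_j) / s_t,
           R = 2 * min(s_i - s_ij, s_j - s_ij) / s_t)
  attr(out, "pair") <- pair
  attr(out, "counts") <- c(S_i = s_i, S_j = s_j, S_ij = s_ij, S_t = s_t)
  out
}

#' All-pairs SDR table and simplex summary
#'
#' Computes the (S, D, R) triple for every unordered island pair of an
#' incidence matrix. Pairs whose pooled richness is zero are excluded from
#' the table and the summary means, with a warning (the indices are
#' undefined there). Summary means are arithmetic means of per-pair
#' components, expressed as percentages; because each triple sums to 1 the
#' three means sum to 100%.
#'
#' @param m incidence matrix.
#' @return list with `pairs` (data.frame `island_a`, `island_b`, `S`, `D`,
#'   `R`) and `summary` (list `n_pairs`, `mean_S`, `mean_D`, `mean_R` in
#'   percent, and `matrix_fill` in percent).
#' @export
sdr_simplex <- function(m) {
  isl <- colnames(m)
  if (length(isl) < 2) stop("need at least 2 islands")
  cross <- crossprod(m > 0)           # shared-species counts, diag = richness
  rich <- diag(cross)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(length(isl) - 1)) {
    for (j in seq(i + 1, length(isl))) {
      if (rich[i] + rich[j] - cross[i, j] == 0) {
        dropped <- dropped + 1L
        next
      }
      tri <- sdr_from_counts(rich[i], rich[j], cross[i, j])
      rows[[length(rows) + 1L]] <- data.frame(
        island_a = isl[i], island_b = isl[j],
        S = tri[["S"]], D = tri[["D"]], R = tri[["R"]])
    }
  }
  if (dropped > 0) {
    warning(dropped, " island pair(s) with zero pooled richness excluded")
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       summary = list(n_pairs = nrow(pairs),
                      mean_S = 100 * mean(pairs$S),
                      mean_D = 100 * mean(pairs$D),
                      mean_R = 100 * mean(pairs$R),
                      matrix_fill = 100 * matrix_fill(m)))
}

#' Cross-temporal SDR decomposition for one island
#'
#' Applies the same partition to the two period floras of a single island:
#' `S_t` is the island's cumulative richness over both periods and `S_ij`
#' the number of species present in both. High `S` means a stable flora;
#' `D` captures net richness change and `R` species-for-species
#' replacement.
#'
#' @param m1,m2 incidence matrices of the two periods (same island columns).
#' @param island island name present in both matrices.
#' @return named numeric vector `c(S, D, R)`.
#' @export
sdr_cross_temporal <- function(m1, m2, island) {
  set1 <- island_species(m1, island)
  set2 <- island_species(m2, island)
  sdr_from_counts(length(set1), length(set2), length(intersect(set1, set2)),
                  pair = c(island, "periods"))
}

#' Stable / gained / lost species counts for one island (or the archipelago)
#'
#' @param m1,m2 incidence matrices of the two periods.
#' @param island island name, or `NULL` for the archipelago-level union over
#'   all islands.
#' @return named integer vector `c(stable, gained, lost)`: species present
#'   in both periods, only in the second, and only in the first.
#' @export
turnover_counts <- function(m1, m2, island = NULL) {
  if (is.null(island)) {
    set1 <- rownames(m1)[rowSums(m1) > 0]
    set2 <- rownames(m2)[rowSums(m2) > 0]
  } else {
    set1 <- island_species(m1, island)
    set2 <- island_species(m2, island)
  }
  c(stable = length(intersect(set1, set2)),
    gained = length(setdiff(set2, set1)),
    lost = length(setdiff(set1, set2)))
}

island_species <- function(m, island) {
  if (!island %in% colnames(m)) stop("island not in incidence matrix: ", island)
  rownames(m)[m[, island] > 0]
}

#' Ternary plot of SDR triples
#'
#' Draws the simplex with Similarity at the top vertex, richness Difference
#' at the lower left and Replacement at the lower right (fixed orientation
#' for comparability across periods).
#'
#' @param pairs data.frame with columns `S`, `D`, `R` (e.g.
#'   `sdr_simplex(m)$pairs`).
#' @param main plot title.
#' @param ... further arguments passed to [graphics::points()].
#' @return invisibly, the plotted (x, y) coordinates.
#' @export
plot_sdr_simplex <- function(pairs, main = "SDR simplex", ...) {
  # vertices: D = (0,0), R = (1,0), S = (0.5, sqrt(3)/2)
  h <- sqrt(3) / 2
  x <- pairs$R + pairs$S / 2
  y <- pairs$S * h
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, h), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, h))
  graphics::text(c(0, 1, 0.5), c(0, 0, h), labels = c("D", "R", "S"),
                 pos = c(1, 1, 3), xpd = NA)
  graphics::points(x, y, ...)
  invisible(cbind(x = x, y = y))
}
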