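#' Build a binary species-by-island incidence matrix
#'
#' Constructs the presence/absence matrix for one census period, optionally
#' restricted to a species group (by origin and/or functional type). Rows are
#' the species with at least one record in the selected period and group;
#' species unrecorded in the period are excluded, so matrix fill always
#' refers to the recorded flora of that period. Columns follow the island
#' order of the island table and include islands with no records (all-zero
#' columns).
#'
#' @param occ occurrence table ([read_occurrences()]).
#' @param islands island table ([read_islands()]); fixes column order.
#' @param period period label to select.
#' @param traits trait table; required when `origin` or `functional_type`
#'   filters are used.
#' @param origin optional filter, `"native"` or `"alien"`.
#' @param functional_type optional filter, one of `"AH"`, `"PH"`, `"W"`.
#' @return a binary integer matrix with species rownames and island colnames,
#'   of class `incidence`, carrying attributes `period` and `group`.
#' @examples
#' occ <- data.frame(species = c("a", "a", "b"),
#'                   island = c("i1", "i2", "i1"),
#'                   period = "P1")
#' isl <- data.frame(island = c("i1", "i2"), area_km2 = c(1, 10))
#' m <- build_incidence(occ, isl, period = "P1")
#' matrix_fill(m) # 3/4
#' @export
build_incidence <- function(occ, islands, period, traits = NULL,
                            origin = NULL, functional_type = NULL) {
  stopifnot(is.data.frame(occ), is.data.frame(islands))
  if (!period %in% occ$period) {
    stop("period not present in occurrence table: ", period)
  }
  sub <- occ[occ$period == period, , drop = FALSE]
  group <- "total"
  if (!is.null(origin) || !is.null(functional_type)) {
    if (is.null(traits)) stop("trait table required to filter by group")
    keep <- traits$species
    if (!is.null(origin)) {
      origin <- match.arg(origin, c("native", "alien"))
      keep <- intersect(keep, traits$species[traits$origin == origin])
    }
    if (!is.null(functional_type)) {
      functional_type <- match.arg(functional_type, c("AH", "PH", "W"))
      keep <- intersect(keep, traits$species[traits$functional_type == functional_type])
    }
    sub <- sub[sub$species %in% keep, , drop = FALSE]
    group <- paste(c(origin, functional_type), collapse = "+")
  }
  if (nrow(sub) == 0) {
    stop("selected group has no occurrence records in period ", period)
  }
  species <- sort(unique(sub$species))
  m <- matrix(0L, nrow = length(species), ncol = nrow(islands),
              dimnames = list(species, islands$island))
  idx <- cbind(match(sub$species, species), match(sub$island, islands$island))
  if (anyNA(idx[, 2])) {
    stop("occurrence records refer to islands absent from the island table")
  }
  m[idx] <- 1L
  structure(m, class = c("incidence", "matrix"), period = period, group = group)
}

#' @export
print.incidence <- function(x, ...) {
  cat(sprintf("incidence matrix: %d species x %d islands (period %s, group %s)\n",
              nrow(x), ncol(x), attr(x, "period") %||% "?", attr(x, "group") %||% "?"))
  cat(sprintf("fill: %.2f%%\n", 100 * matrix_fill(x)))
  invisible(x)
}

#' Per-island species richness
#'
#' Column sums of an incidence matrix.
#'
#' @param m incidence matrix ([build_incidence()]) or any binary matrix with
#'   island columns.
#' @return data.frame with columns `island` and `richness`.
#' @export
richness_by_island <- function(m) {
  if (length(m) == 0) stop("empty incidence matrix")
  data.frame(island = colnames(m), richness = as.integer(colSums(m)),
             row.names = NULL)
}

#' Matrix fill
#'
#' Proportion of 1s in a presence/absence matrix.
#'
#' @param m binary matrix.
#' @return fill as a proportion in (0, 1].
#' @export
matrix_fill <- function(m) {
  if (length(m) == 0) stop("empty incidence matrix")
  sum(m) / length(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
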