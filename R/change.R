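#' Jaccard similarity from richness counts
#'
#' `shared / (s1 + s2 - shared)`: the similarity of two species sets given
#' only their sizes and overlap. Vectorized.
#'
#' @param s1,s2 set sizes (species richness of the two periods or islands).
#' @param shared size of the intersection.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_index <- function(s1, s2, shared) {
  denom <- s1 + s2 - shared
  ifelse(denom > 0, shared / denom, NA_real_)
}

#' Relative change in percent
#'
#' `100 * (after - before) / before`. Vectorized; `NA` where `before` is 0.
#'
#' @param before,after counts in the first and second period.
#' @return percent change.
#' @export
pct_change <- function(before, after) {
  ifelse(before > 0, 100 * (after - before) / before, NA_real_)
}

#' Archipelago-level comparison of two census periods
#'
#' Pools species over all islands within each period (optionally for one
#' species group) and reports richness in each period, the shared count,
#' Jaccard similarity, percent richness change, and the numbers of gained
#' and lost species.
#'
#' @param occ occurrence table.
#' @param traits trait table (needed for group filters).
#' @param origin,functional_type optional group filter, as in
#'   [build_incidence()].
#' @param periods the two period labels in temporal order; defaults to the
#'   sorted unique periods of `occ`.
#' @return list of class `period_comparison`: `richness_p1`, `richness_p2`,
#'   `shared`, `jaccard`, `pct_change`, `gained`, `lost`, `periods`,
#'   `group`.
#' @export
compare_periods <- function(occ, traits = NULL, origin = NULL,
                            functional_type = NULL, periods = NULL) {
  if (is.null(periods)) periods <- sort(unique(occ$period))
  if (length(periods) != 2) stop("exactly two periods required")
  sub <- occ
  group <- "total"
  if (!is.null(origin) || !is.null(functional_type)) {
    if (is.null(traits)) stop("trait table required to filter by group")
    keep <- traits$species
    if (!is.null(origin)) keep <- intersect(keep, traits$species[traits$origin == origin])
    if (!is.null(functional_type)) {
      keep <- intersect(keep, traits$species[traits$functional_type == functional_type])
    }
    sub <- sub[sub$species %in% keep, , drop = FALSE]
    group <- paste(c(origin, functional_type), collapse = "+")
  }
  if (nrow(sub) == 0) stop("selected group has no occurrence records")
  set1 <- unique(sub$species[sub$period == periods[1]])
  set2 <- unique(sub$species[sub$period == periods[2]])
  shared <- length(intersect(set1, set2))
  structure(list(
    richness_p1 = length(set1), richness_p2 = length(set2), shared = shared,
    jaccard = jaccard_index(length(set1), length(set2), shared),
    pct_change = pct_change(length(set1), length(set2)),
    gained = length(setdiff(set2, set1)), lost = length(setdiff(set1, set2)),
    periods = periods, group = group
  ), class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("%s: %d -> %d species (%+.1f%%), %d shared, Jaccard %.2f, +%d / -%d\n",
              x$group, x$richness_p1, x$richness_p2, x$pct_change, x$shared,
              x$jaccard, x$gained, x$lost))
  invisible(x)
}

#' G-test of independence (log-likelihood ratio test)
#'
#' `G = 2 * sum(O * ln(O / E))` over the cells of an r x c count table,
#' with expected counts from the independence model; cells with a zero
#' observed count contribute 0 (their limit value). The p-value uses the
#' chi-square approximation with `(r - 1) * (c - 1)` degrees of freedom
#' and no continuity or Williams correction.
#'
#' @param observed matrix of non-negative counts with positive row and
#'   column sums.
#' @return list of class `g_test`: `G`, `df`, `p`, `observed`, `expected`.
#' @examples
#' g_test(matrix(c(1523, 78, 1360, 181), 2, 2, byrow = TRUE))$G # 50.19
#' @export
g_test <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("counts must be non-negative")
  rs <- rowSums(observed)
  cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column marginal")
  expected <- outer(rs, cs) / sum(observed)
  terms <- ifelse(observed > 0, observed * log(observed / expected), 0)
  G <- 2 * sum(terms)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  structure(list(G = G, df = df,
                 p = stats::pchisq(G, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test: G = %.3f, df = %d, p = %.4g\n", x$G, x$df, x$p))
  invisible(x)
}

#' Regression of second-period on first-period island richness
#'
#' Ordinary least squares of per-island richness in the later period on
#' richness in the earlier period. Under a no-change null the intercept is
#' 0 and the slope 1; a slope below 1 indicates a proportional per-island
#' loss. Relative residuals `(observed - predicted) / predicted` are
#' reported per island.
#'
#' @param richness_p1,richness_p2 per-island richness vectors (same island
#'   order), length >= 3.
#' @return list of class `interperiod_ols`: `intercept`, `slope`, `r2`,
#'   `adj_r2`, `p`, `residuals`, `relative_residuals`, `fitted`, `n`.
#' @export
interperiod_regression <- function(richness_p1, richness_p2) {
  x <- as.numeric(richness_p1)
  y <- as.numeric(richness_p2)
  if (length(x) != length(y)) stop("richness vectors differ in length")
  if (length(x) < 3) stop("need at least 3 islands")
  if (stats::sd(x) == 0) stop("zero variance in first-period richness")
  fit <- stats::lm(y ~ x)
  smry <- summary(fit)
  pred <- stats::fitted(fit)
  structure(list(
    intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]),
    r2 = smry$r.squared, adj_r2 = smry$adj.r.squared,
    p = stats::pf(smry$fstatistic[1], smry$fstatistic[2], smry$fstatistic[3],
                  lower.tail = FALSE),
    residuals = unname(stats::resid(fit)),
    relative_residuals = unname(ifelse(pred != 0, stats::resid(fit) / pred, NA_real_)),
    fitted = unname(pred), n = length(x)
  ), class = "interperiod_ols")
}

#' @export
print.interperiod_ols <- function(x, ...) {
  cat(sprintf("OLS (n = %d): S2 = %.2f + %.3f * S1, R2 = %.3f (adj %.3f), p = %.4g\n",
              x$n, x$intercept, x$slope, x$r2, x$adj_r2, x$p))
  invisible(x)
}

#' Per-island relative richness change versus area
#'
#' `100 * (S_p2 - S_p1) / S_p1` for each island, joined with island area.
#' Islands with zero first-period richness get `NA` and are flagged in the
#' `undefined` column. On small islands this quantity is expected to be far
#' more variable than on large ones (the funnel pattern associated with the
#' Small Island Effect).
#'
#' @param occ occurrence table.
#' @param islands island table.
#' @param traits trait table (for group filters).
#' @param origin,functional_type optional group filter.
#' @param periods the two period labels in temporal order.
#' @return data.frame: `island`, `area_km2`, `richness_p1`, `richness_p2`,
#'   `rel_change_pct`, `undefined`.
#' @export
relative_change_by_area <- function(occ, islands, traits = NULL, origin = NULL,
                                    functional_type = NULL, periods = NULL) {
  if (is.null(periods)) periods <- sort(unique(occ$period))
  if (length(periods) != 2) stop("exactly two periods required")
  m1 <- build_incidence(occ, islands, periods[1], traits, origin, functional_type)
  m2 <- build_incidence(occ, islands, periods[2], traits, origin, functional_type)
  s1 <- colSums(m1)
  s2 <- colSums(m2)
  data.frame(island = islands$island, area_km2 = islands$area_km2,
             richness_p1 = as.integer(s1), richness_p2 = as.integer(s2),
             rel_change_pct = pct_change(s1, s2),
             undefined = s1 == 0, row.names = NULL)
}

#' Composition shares by origin or functional type
#'
#' Proportional composition of one period's flora: archipelago-level shares
#' (based on the pooled species set) and per-island shares with their mean.
#'
#' @param occ occurrence table.
#' @param traits trait table.
#' @param period period label.
#' @param by classifier: `"origin"` or `"functional_type"`.
#' @return list with `archipelago` (data.frame `class`, `n_species`,
#'   `share_pct`) and `by_island` (data.frame of per-island share
#'   percentages per class, plus a `mean` row attribute `mean_share_pct`).
#' @export
composition_shares <- function(occ, traits, period, by = c("origin", "functional_type")) {
  by <- match.arg(by)
  if (!period %in% occ$period) stop("period not present: ", period)
  sub <- occ[occ$period == period, , drop = FALSE]
  cls <- traits[[by]][match(sub$species, traits$species)]
  if (anyNA(cls)) stop("species missing from trait table")
  sp_class <- tapply(cls, sub$species, `[`, 1)          # one class per species
  counts <- table(factor(sp_class, levels = sort(unique(traits[[by]]))))
  arch <- data.frame(class = names(counts), n_species = as.integer(counts),
                     share_pct = 100 * as.integer(counts) / sum(counts),
                     row.names = NULL)
  isl_tab <- table(sub$island, cls)
  isl_share <- 100 * isl_tab / rowSums(isl_tab)
  by_island <- as.data.frame.matrix(isl_share)
  attr(by_island, "mean_share_pct") <- colMeans(isl_share)
  list(archipelago = arch, by_island = by_island)
}
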