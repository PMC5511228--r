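# Independent brute-force oracles used to validate the package's
# implementations. Deliberately naive: explicit loops, no shared code with
# the functions under test.

# NODF by direct pair enumeration over the sorted matrix.
nodf_oracle <- function(m) {
  rt <- rowSums(m)
  ct <- colSums(m)
  m <- m[order(rt, decreasing = TRUE), order(ct, decreasing = TRUE), drop = FALSE]
  rt <- rowSums(m)
  ct <- colSums(m)
  row_contrib <- c()
  if (nrow(m) >= 2) {
    for (u in 1:(nrow(m) - 1)) for (v in (u + 1):nrow(m)) {
      row_contrib <- c(row_contrib,
                       if (rt[u] <= rt[v] || rt[v] == 0) 0
                       else 100 * sum(m[u, ] == 1 & m[v, ] == 1) / rt[v])
    }
  }
  col_contrib <- c()
  if (ncol(m) >= 2) {
    for (u in 1:(ncol(m) - 1)) for (v in (u + 1):ncol(m)) {
      col_contrib <- c(col_contrib,
                       if (ct[u] <= ct[v] || ct[v] == 0) 0
                       else 100 * sum(m[, u] == 1 & m[, v] == 1) / ct[v])
    }
  }
  c(matrix = sum(row_contrib, col_contrib) /
      (length(row_contrib) + length(col_contrib)),
    rows = if (length(row_contrib)) mean(row_contrib) else NA_real_,
    cols = if (length(col_contrib)) mean(col_contrib) else NA_real_)
}

# Brute-force SSE grid search for the power SAR.
grid_fit_oracle <- function(area, richness, c_range, z_range,
                            c_step = 0.1, z_step = 0.001) {
  cs <- seq(c_range[1], c_range[2], by = c_step)
  zs <- seq(z_range[1], z_range[2], by = z_step)
  best <- c(c = NA, z = NA, sse = Inf)
  for (cc in cs) {
    for (zz in zs) {
      sse <- sum((richness - cc * area^zz)^2)
      if (sse < best[["sse"]]) best <- c(c = cc, z = zz, sse = sse)
    }
  }
  best
}

# Random binary matrix with no all-zero guarantee (tests handle degenerate
# shapes explicitly where needed).
random_incidence <- function(nr, nc, fill = 0.5) {
  matrix(rbinom(nr * nc, 1L, fill), nr, nc,
         dimnames = list(sprintf("sp%02d", seq_len(nr)),
                         sprintf("is%02d", seq_len(nc))))
}

# Small in-memory occurrence dataset builder.
make_occ <- function(...) {
  recs <- list(...)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(species = r[[1]], island = r[[2]], period = r[[3]])
  }))
  class(df) <- c("occurrence_table", "data.frame")
  df
}

# Fast small synthetic config for tests that only need structure, not the
# full-size archipelago.
small_config <- function(seed, ...) {
  args <- list(
    n_islands = 12, area_range = c(0.01, 150),
    sar = list(native = list(p1 = c(c = 40, z = 0.30), p2 = c(c = 35, z = 0.27)),
               alien = list(p1 = c(c = 4, z = 0.30), p2 = c(c = 8, z = 0.28))),
    pool_sizes = c(native = 400, alien = 80),
    seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(archipelago_config, args)
}
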