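#' Read a run configuration file
#'
#' YAML configuration for [run_all()]. Either an `input` block with paths
#' `occurrences`, `islands`, `traits`, or a `simulate` block with arguments
#' for [archipelago_config()]. Optional top-level fields: `periods` (two
#' labels in temporal order; never inferred from label text), `n_null`
#' (CE nulls for the nestedness test, default 100), `seed`, `outdir`.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    stop("config needs an 'input' block (occurrences, islands, traits) or a 'simulate' block")
  }
  if (!is.null(cfg$input)) {
    for (f in c("occurrences", "islands", "traits")) {
      if (is.null(cfg$input[[f]])) stop("config input block is missing the '", f, "' path")
    }
  }
  if (!is.null(cfg$periods) && length(cfg$periods) != 2) {
    stop("config must declare exactly two periods, in temporal order")
  }
  cfg$n_null <- cfg$n_null %||% 100L
  cfg$seed <- cfg$seed %||% 1L
  class(cfg) <- "run_config"
  cfg
}

#' Run the complete archipelago change analysis
#'
#' Orchestrates every stage on one dataset (loaded from files or freshly
#' simulated): per-period richness tables, the SAR table over all species
#' groups, period comparisons and G-tests of composition, inter-period OLS,
#' per-island relative change, SDR simplex tables per period, the
#' cross-temporal SDR decomposition versus area, and the nestedness tests.
#' All outputs are plain tab-delimited text under `outdir`, plus a
#' `run_summary.txt` of `key<TAB>value` pairs; every summary number is
#' recomputable from the per-stage tables. All stochastic steps derive from
#' the single configured seed, so a fixed config reproduces byte-identical
#' outputs. A failure in any stage aborts with a stage-labelled error;
#' outputs of completed stages are retained.
#'
#' @param config a `run_config` ([read_run_config()]) or a plain list with
#'   the same fields.
#' @param outdir output directory; overrides `config$outdir`.
#' @return invisibly, the run summary as a named list.
#' @export
run_all <- function(config, outdir = NULL) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  acc <- new.env(parent = emptyenv())
  acc$summary <- list(
    package_version = as.character(utils::packageVersion("islandflora")),
    seed = config$seed,
    config_hash = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else "none")
  put <- function(key, value) acc$summary[[key]] <- value
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- data -------------------------------------------------------------------
  dat <- stage("load", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      arch <- generate_archipelago(do.call(archipelago_config, sim_args))
      truth_report(arch$truth, file.path(outdir, "truth.tsv"))
      arch
    } else {
      occ <- read_occurrences(config$input$occurrences, quiet = TRUE)
      isl <- read_islands(config$input$islands)
      tra <- read_traits(config$input$traits)
      validate_dataset(occ, isl, tra, strict = config$strict %||% TRUE)
      list(occurrences = occ, islands = isl, traits = tra)
    }
  })
  occ <- dat$occurrences; islands <- dat$islands; traits <- dat$traits
  periods <- config$periods %||% sort(unique(occ$period))
  if (length(periods) != 2) stop("dataset must contain exactly two periods")
  put("n_islands", nrow(islands))
  put("n_species", length(unique(occ$species)))
  put("n_records", nrow(occ))
  put("period_1", periods[1])
  put("period_2", periods[2])

  # -- incidence and richness -------------------------------------------------
  mats <- stage("incidence", {
    lapply(stats::setNames(periods, c("p1", "p2")), function(p) {
      build_incidence(occ, islands, p)
    })
  })
  stage("richness", {
    for (i in 1:2) {
      r <- richness_by_island(mats[[i]])
      r$area_km2 <- islands$area_km2
      tsv(r, sprintf("richness_period%d.tsv", i))
      put(sprintf("occurrences_p%d", i), sum(mats[[i]]))
      put(sprintf("matrix_fill_p%d_pct", i), 100 * matrix_fill(mats[[i]]))
    }
  })

  # -- ISAR -------------------------------------------------------------------
  sar <- stage("isar", fit_all_groups(occ, islands, traits, periods))
  tsv(sar, "isar_table.tsv")
  put("c_native_p1", sar$c[sar$group == "native" & sar$period == periods[1]])
  put("z_native_p1", sar$z[sar$group == "native" & sar$period == periods[1]])

  # -- period comparison and G-tests ------------------------------------------
  stage("change", {
    cmp_rows <- lapply(c("total", "native", "alien"), function(g) {
      cmp <- if (g == "total") compare_periods(occ, periods = periods)
      else compare_periods(occ, traits, origin = g, periods = periods)
      data.frame(group = g, richness_p1 = cmp$richness_p1,
                 richness_p2 = cmp$richness_p2, shared = cmp$shared,
                 jaccard = cmp$jaccard, pct_change = cmp$pct_change,
                 gained = cmp$gained, lost = cmp$lost)
    })
    cmp <- do.call(rbind, cmp_rows)
    tsv(cmp, "period_comparison.tsv")
    put("jaccard_total", cmp$jaccard[cmp$group == "total"])
    put("pct_change_native", cmp$pct_change[cmp$group == "native"])
    put("pct_change_alien", cmp$pct_change[cmp$group == "alien"])

    origin_counts <- t(vapply(periods, function(p) {
      sh <- composition_shares(occ, traits, p, "origin")$archipelago
      stats::setNames(sh$n_species, sh$class)
    }, numeric(2)))
    gt_origin <- g_test(origin_counts)
    ft_counts <- t(vapply(periods, function(p) {
      sh <- composition_shares(occ, traits, p, "functional_type")$archipelago
      stats::setNames(sh$n_species, sh$class)
    }, numeric(3)))
    gt_ft <- g_test(ft_counts)
    tsv(data.frame(classifier = c("origin", "functional_type"),
                   G = c(gt_origin$G, gt_ft$G), df = c(gt_origin$df, gt_ft$df),
                   p = c(gt_origin$p, gt_ft$p)), "g_tests.tsv")
    put("g_origin", gt_origin$G)
  })

  # -- inter-period OLS and relative change ------------------------------------
  stage("ols", {
    ols_rows <- lapply(c("native", "alien"), function(g) {
      rc <- relative_change_by_area(occ, islands, traits, origin = g, periods = periods)
      tsv(rc, sprintf("relative_change_%s.tsv", g))
      fit <- interperiod_regression(rc$richness_p1, rc$richness_p2)
      resid_tab <- data.frame(island = rc$island, area_km2 = rc$area_km2,
                              relative_residual = fit$relative_residuals)
      tsv(resid_tab, sprintf("ols_relative_residuals_%s.tsv", g))
      data.frame(group = g, r2 = fit$r2, adj_r2 = fit$adj_r2, p = fit$p,
                 intercept = fit$intercept, slope = fit$slope)
    })
    ols <- do.call(rbind, ols_rows)
    tsv(ols, "ols_table.tsv")
    put("slope_native", ols$slope[ols$group == "native"])
  })

  # -- SDR simplex -------------------------------------------------------------
  stage("sdr", {
    for (i in 1:2) {
      sx <- sdr_simplex(mats[[i]])
      tsv(sx$pairs, sprintf("sdr_pairs_period%d.tsv", i))
      tsv(data.frame(sx$summary), sprintf("sdr_summary_period%d.tsv", i))
      put(sprintf("sdr_mean_S_p%d", i), sx$summary$mean_S)
      put(sprintf("sdr_mean_D_p%d", i), sx$summary$mean_D)
      put(sprintf("sdr_mean_R_p%d", i), sx$summary$mean_R)
    }
    ct <- lapply(islands$island, function(isl) {
      tri <- tryCatch(sdr_cross_temporal(mats$p1, mats$p2, isl),
                      error = function(e) c(S = NA_real_, D = NA_real_, R = NA_real_))
      tc <- turnover_counts(mats$p1, mats$p2, isl)
      data.frame(island = isl, S = tri[["S"]], D = tri[["D"]], R = tri[["R"]],
                 stable = tc[["stable"]], gained = tc[["gained"]],
                 lost = tc[["lost"]])
    })
    ct <- do.call(rbind, ct)
    ct$area_km2 <- islands$area_km2
    tsv(ct, "cross_temporal_sdr.tsv")
  })

  # -- nestedness --------------------------------------------------------------
  stage("nestedness", {
    rows <- lapply(1:2, function(i) {
      nt <- nestedness_test(mats[[i]], n_null = config$n_null,
                            seed = config$seed + i)
      data.frame(period = periods[i], nodf_matrix = nt$nodf[["matrix"]],
                 nodf_rows = nt$nodf[["rows"]], nodf_cols = nt$nodf[["cols"]],
                 null_mean = mean(nt$Ns), Z = nt$Z, RN = nt$RN, p = nt$p,
                 n_null = nt$n_null)
    })
    nst <- do.call(rbind, rows)
    tsv(nst, "nestedness.tsv")
    put("nodf_p1", nst$nodf_matrix[1])
    put("nodf_p2", nst$nodf_matrix[2])
    put("nestedness_Z_p1", nst$Z[1])
    put("nestedness_RN_p1", nst$RN[1])
  })

  # -- summary -----------------------------------------------------------------
  fmt <- vapply(acc$summary, function(v) {
    if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
  }, character(1))
  writeLines(paste(names(acc$summary), fmt, sep = "\t"),
             file.path(outdir, "run_summary.txt"))
  invisible(acc$summary)
}
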