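## Readers/writers and the end-to-end pipeline.

strategies_all <- c("S-P-LME", "S-P-LQMM", "S-P-SFMM", "S-T-LME",
                    "D-P-LME", "D-P-NBME", "D-P-NLME")

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  issues <- character(0)
  for (v in intersect(numeric_cols, names(df))) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    bad <- is.na(x) & !is.na(df[[v]])
    if (any(bad))
      issues <- c(issues, sprintf("row %d: non-numeric %s", which(bad), v))
    df[[v]] <- x
  }
  list(df = df, issues = issues)
}

#' Read a plot-measurement table
#'
#' CSV with header `plot_id, occasion, area_m2, n_ha, dg_cm[, g_m2ha,
#' pba_pct]`. Rows with non-numeric cells or non-positive N/dg are rejected
#' and reported via the `"issues"` attribute; the surviving rows are
#' validated with [validate_plot_table()].
#'
#' @param path CSV file path.
#' @return validated plot data.frame with attribute `"issues"`.
#' @export
read_plot_table <- function(path) {
  r <- read_checked_csv(path, c("plot_id", "occasion", "n_ha", "dg_cm"),
                        c("occasion", "area_m2", "n_ha", "dg_cm", "g_m2ha",
                          "pba_pct"))
  df <- r$df; issues <- r$issues
  bad <- !is.finite(df$n_ha) | df$n_ha <= 0 | !is.finite(df$dg_cm) | df$dg_cm <= 0
  if (any(bad)) {
    issues <- c(issues, sprintf("row %d: rejected (non-positive N or dg)",
                                which(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  df <- validate_plot_table(df)
  attr(df, "issues") <- c(issues, attr(df, "issues"))
  df
}

#' Read a tree-list table
#'
#' CSV with header `plot_id, occasion, tree_id, d_cm, species, sg, ef`.
#'
#' @param path CSV file path.
#' @return tree data.frame with attribute `"issues"`.
#' @export
read_tree_table <- function(path) {
  r <- read_checked_csv(path, c("plot_id", "occasion", "d_cm", "species", "ef"),
                        c("occasion", "tree_id", "d_cm", "sg", "ef"))
  df <- r$df; issues <- r$issues
  bad <- !is.finite(df$d_cm) | df$d_cm <= 0 | !is.finite(df$ef) | df$ef <= 0
  if (any(bad)) {
    issues <- c(issues, sprintf("row %d: rejected (non-positive d or ef)",
                                which(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "issues") <- issues
  df
}

#' Write a synthetic dataset as CSV tables
#'
#' Writes `plots.csv`, `trees.csv` and `covariates.csv` (floats at 17
#' significant digits so a write-read round trip is lossless).
#'
#' @param sim a `selfthin_sim` from [simulate_network()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(sim$plots, file.path(dir, "plots.csv"))
  write_table_csv(sim$trees, file.path(dir, "trees.csv"))
  write_table_csv(sim$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' @param simulate a [simulation_config()] (or NULL when reading inputs).
#' @param plot_table,tree_table,covariate_table input CSV paths (used when
#'   `simulate` is NULL).
#' @param strategies subset of the seven strategy labels.
#' @param tau frontier quantile for the quantile strategies.
#' @param dbase reference diameter (cm).
#' @param alpha level for CI shifts and the Scheffe test.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = simulation_config(),
                       plot_table = NULL, tree_table = NULL,
                       covariate_table = NULL,
                       strategies = strategies_all,
                       tau = 0.95, dbase = 25.4, alpha = 0.05, seed = 1L) {
  bad <- setdiff(strategies, strategies_all)
  if (length(bad)) stop("unknown strategies: ", paste(bad, collapse = ", "))
  if (dbase <= 0) stop("dbase must be positive")
  structure(list(simulate = simulate, plot_table = plot_table,
                 tree_table = tree_table, covariate_table = covariate_table,
                 strategies = strategies, tau = tau, dbase = dbase,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate`
#' block holds [simulation_config()] fields.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    for (nm in c("frontier", "ode_params", "dg_range", "dg0_range_dynamic",
                 "n_range_static", "n_range_dynamic", "area_range"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    sim <- do.call(simulation_config, sim_args)
  }
  args <- y[setdiff(names(y), "simulate")]
  args$simulate <- sim
  do.call(run_config, args)
}

#' Run the full estimation pipeline
#'
#' Simulates (or reads) the plot network, fits the requested strategies,
#' derives the self-thinning lines, predicts plot-level SDI_max, compares
#' strategies with Scheffe's test, fits the carrying-capacity model for the
#' quantile strategy, and writes the report bundle: `fits.json`,
#' `lines.csv`, `capacity.csv`, `capacity_groups.csv`,
#' `capacity_model.json` and `manifest.json`. Stage failures are recorded
#' in the manifest and leave earlier outputs intact. With a fixed seed the
#' bundle is byte-identical across runs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return list with the fitted objects, tables and the manifest, invisibly.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("selfthin_run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = serialize_config(config),
                   package_version = as.character(utils::packageVersion("selfthin")),
                   failures = list(), skipped = list(),
                   counts = list())

  ## -- data ----------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    sim <- simulate_network(sim_cfg)
    plots <- sim$plots; trees <- sim$trees; covs <- sim$covariates
  } else {
    plots <- read_plot_table(config$plot_table)
    trees <- if (!is.null(config$tree_table)) read_tree_table(config$tree_table)
    covs <- if (!is.null(config$covariate_table))
      utils::read.csv(config$covariate_table, stringsAsFactors = FALSE)
    occ_n <- table(plots$plot_id)
    plots$is_dynamic <- plots$plot_id %in% names(occ_n)[occ_n > 1L]
  }
  manifest$counts$plot_occasions <- nrow(plots)
  manifest$counts$plots <- length(unique(plots$plot_id))
  manifest$counts$trees <- if (!is.null(trees)) nrow(trees) else 0L

  static <- plots[!plots$is_dynamic, , drop = FALSE]
  dynamic <- plots[plots$is_dynamic, , drop = FALSE]
  want <- config$strategies
  fits <- list()
  try_fit <- function(name, expr) {
    f <- tryCatch(expr, error = function(e) e)
    if (inherits(f, "error")) {
      manifest$failures[[name]] <<- conditionMessage(f)
      NULL
    } else fits[[name]] <<- f
  }

  ## -- static strategies ----------------------------------------------------
  if (nrow(static) >= 10L) {
    if ("S-P-LME" %in% want) try_fit("S-P-LME", fit_lme_reineke(static))
    if ("S-P-LQMM" %in% want) try_fit("S-P-LQMM", fit_lqmm(static, tau = config$tau))
    if ("S-P-SFMM" %in% want) try_fit("S-P-SFMM", fit_sfmm(static))
  } else if (any(c("S-P-LME", "S-P-LQMM", "S-P-SFMM") %in% want)) {
    manifest$skipped$static <- "fewer than 10 static plot-occasions"
  }
  ducey <- NULL
  if ("S-T-LME" %in% want) {
    if (!is.null(trees) && nrow(trees)) {
      ducey <- compute_ducey_covariates(trees)
      try_fit("S-T-LME", fit_tree_level_frontier(ducey, tau = config$tau))
    } else manifest$skipped$`S-T-LME` <- "no tree lists"
  }

  ## -- dynamic strategies ---------------------------------------------------
  trans <- NULL
  if (any(c("D-P-LME", "D-P-NBME", "D-P-NLME") %in% want)) {
    if (nrow(dynamic)) {
      trans <- build_transitions(dynamic)
      manifest$counts$transitions <- nrow(trans)
      manifest$counts$transitions_excluded <- as.list(attr(trans, "excluded"))
      if ("D-P-LME" %in% want && nrow(trans) >= 10L)
        try_fit("D-P-LME", fit_density_model(trans, random_specs = "b0"))
      if ("D-P-NBME" %in% want && nrow(trans) >= 10L)
        try_fit("D-P-NBME", fit_mortality_nbme(trans))
      if ("D-P-NLME" %in% want)
        try_fit("D-P-NLME", fit_trajectory_nlme(dynamic))
    } else {
      manifest$skipped$dynamic <- "no dynamic plots"
    }
  }

  ## -- lines ----------------------------------------------------------------
  lines <- list()
  for (nm in names(fits)) {
    l <- tryCatch(switch(nm,
                         "S-P-LME" = line_from_upper_ci(fits[[nm]], config$alpha),
                         "S-P-LQMM" = line_from_upper_ci(fits[[nm]], config$alpha),
                         "S-P-SFMM" = line_from_frontier(fits[[nm]]),
                         "D-P-LME" = line_from_ode_params(fits[[nm]]),
                         "D-P-NBME" = line_from_ode_params(fits[[nm]]),
                         "D-P-NLME" = line_from_trajectory(fits[[nm]]),
                         "S-T-LME" = NULL),
                  error = function(e) {
                    manifest$failures[[paste0("line:", nm)]] <<- conditionMessage(e)
                    NULL
                  })
    if (!is.null(l))
      lines[[nm]] <- data.frame(strategy = l$strategy,
                                intercept = l$intercept, slope = l$slope,
                                intercept_unshifted = l$intercept_unshifted,
                                provenance = l$provenance,
                                stringsAsFactors = FALSE)
  }
  lines_tab <- if (length(lines)) do.call(rbind, lines) else NULL
  if (!is.null(lines_tab)) {
    rownames(lines_tab) <- NULL
    write_table_csv(lines_tab, file.path(out_dir, "lines.csv"))
  }

  ## -- capacities and comparison (per strategy, so one inadmissible fit
  ## does not lose the others) ----------------------------------------------
  cap_parts <- lapply(names(fits), function(nm) {
    tryCatch(capacity_estimates(fits[nm], dbase = config$dbase,
                                ducey_covariates = ducey),
             error = function(e) {
               manifest$failures[[paste0("capacity:", nm)]] <<-
                 conditionMessage(e)
               NULL
             })
  })
  cap_parts <- cap_parts[!vapply(cap_parts, is.null, logical(1))]
  cap <- if (length(cap_parts)) do.call(rbind, cap_parts) else NULL
  cmp <- NULL
  if (!is.null(cap) && nrow(cap)) {
    write_table_csv(cap, file.path(out_dir, "capacity.csv"))
    per <- table(cap$strategy)
    usable <- names(per)[per >= 2L]
    if (length(usable) >= 2L) {
      cmp <- tryCatch(scheffe_compare(cap[cap$strategy %in% usable, ],
                                      alpha = config$alpha),
                      error = function(e) {
                        manifest$failures$scheffe <<- conditionMessage(e)
                        NULL
                      })
      if (!is.null(cmp))
        write_table_csv(cmp$groups, file.path(out_dir, "capacity_groups.csv"))
    }
  }

  ## -- capacity model --------------------------------------------------------
  cap_model <- NULL
  model_strategy <- intersect(c("S-P-LQMM", "S-P-LME", "S-P-SFMM"), names(fits))[1]
  if (!is.null(cap) && !is.na(model_strategy) && !is.null(covs) &&
      !is.null(trees)) {
    cap_model <- tryCatch({
      cs <- cap[cap$strategy == model_strategy, c("plot_id", "sdi_max")]
      struct <- do.call(rbind, lapply(split(trees, trees$plot_id), function(tl) {
        tl <- tl[tl$occasion == min(tl$occasion), , drop = FALSE]
        site_covariates(tl)
      }))
      covtab <- merge(struct, covs, by = "plot_id")
      pba <- plots[!duplicated(plots$plot_id), c("plot_id", "pba_pct")]
      covtab <- merge(covtab, pba, by = "plot_id")
      fit_capacity_model(cs, covtab)
    }, error = function(e) {
      manifest$failures$capacity_model <<- conditionMessage(e)
      NULL
    })
    if (!is.null(cap_model))
      jsonlite::write_json(
        list(strategy = model_strategy,
             coefficients = as.list(cap_model$coefficients),
             se = as.list(cap_model$se), rmse = cap_model$rmse,
             rel_rmse = cap_model$rel_rmse, r2 = cap_model$r2,
             bic = cap_model$bic, pba_optimum = cap_model$pba_optimum),
        file.path(out_dir, "capacity_model.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## -- fit summaries and manifest -------------------------------------------
  jsonlite::write_json(lapply(fits, fit_summary_list),
                       file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$fitted <- names(fits)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, lines = lines_tab, capacity = cap,
                 comparison = cmp, capacity_model = cap_model,
                 manifest = manifest, out_dir = out_dir))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  cfg
}

fit_summary_list <- function(f) {
  keep <- setdiff(names(f), c("model", "plot_effects", "comparison"))
  out <- lapply(f[keep], function(x) if (is.numeric(x)) as.list(x) else x)
  if (!is.null(f$comparison)) out$comparison <- f$comparison
  out$class <- class(f)[1]
  out
}
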