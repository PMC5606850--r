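#' Run the full tail-core interaction pipeline
#'
#' Ties the stages together: read (or accept) an ensemble, score it with
#' the surrogate potential (or load an external pair-energy table), keep
#' the lowest-energy fraction of models, summarise per-residue counts and
#' energies with bootstrap errors, and compute EEC and delta-EEC. Every
#' stage logs its counts; the returned report embeds the exact settings
#' and seed so a rerun with the same config and inputs is byte-identical
#' in payload.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   * `ensemble` — a [model_ensemble], or `ensemble_path` (+
#'     `energy_source`, `energy_path`) for [read_ensemble()];
#'   * `energy_table_path` — alternative to scoring: a CSV for
#'     [load_energy_table()];
#'   * `species` (default `"E. coli"`) or `selections` (a
#'     [selection_sets]);
#'   * `threshold` (default -1), `low_energy_fraction` (default 0.01),
#'     `bootstrap_B` (default 1000), `count_mode` (default
#'     `"as-printed"`), `exclude_buried` (default FALSE), `sasa_cutoff`
#'     (default 2), `seed` (default 1);
#'   * `out_dir` — optional directory for the JSON report and its CSV
#'     twin.
#' @return A report list (settings, stage counts, per-residue table, EEC
#'   and delta-EEC blocks), invisibly written to `out_dir` when given.
#' @export
run_eec_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(threshold = -1.0, low_energy_fraction = 0.01,
         bootstrap_B = 1000L, count_mode = "as-printed",
         exclude_buried = FALSE, sasa_cutoff = 2.0, seed = 1L,
         species = "E. coli"),
    config
  )
  selections <- cfg[["selections"]] %||% load_selections(cfg[["species"]])

  if (!is.null(cfg[["energy_table_path"]])) {
    inform(paste0("stage load_energy_table: ", cfg[["energy_table_path"]]))
    table <- load_energy_table(cfg[["energy_table_path"]],
                               model_ids = cfg[["model_ids"]])
    ensemble <- NULL
    models_read <- length(attr(table, "model_ids"))
    models_kept <- models_read
  } else {
    ensemble <- cfg[["ensemble"]]
    if (is.null(ensemble)) {
      if (is.null(cfg[["ensemble_path"]])) {
        abort("config needs one of: ensemble, ensemble_path, energy_table_path")
      }
      inform(paste0("stage read_ensemble: ", cfg[["ensemble_path"]]))
      ensemble <- read_ensemble(cfg[["ensemble_path"]],
                                energy_source = cfg[["energy_source"]] %||%
                                  "remark-field",
                                energy_path = cfg[["energy_path"]])
    }
    models_read <- n_models(ensemble)
    inform(paste0("stage select_low_energy: fraction ",
                  cfg$low_energy_fraction))
    subset <- select_low_energy(ensemble, cfg$low_energy_fraction)
    models_kept <- n_models(subset)
    inform(paste0("stage score_ensemble: ", models_kept, " of ",
                  models_read, " models retained"))
    table <- score_ensemble(subset, selections,
                            params = cfg[["params"]] %||% surrogate_params())
  }
  inform(paste0("stage interaction_summary: ", nrow(table),
                " favorable records (", attr(table, "n_dropped"),
                " dropped at construction)"))

  buried <- integer(0)
  if (isTRUE(cfg$exclude_buried)) {
    if (is.null(ensemble)) {
      abort("exclude_buried requires an ensemble (surface areas of a model)")
    }
    rep_model <- select_low_energy(ensemble, 1 / n_models(ensemble))
    sasa <- residue_sasa(rep_model,
                         exclude_residues = selections$tail)
    buried <- flag_buried(sasa, cfg$sasa_cutoff, selections$core[
      selections$core %in% sasa$resno])
    inform(paste0("stage flag_buried: ", length(buried),
                  " residue(s) below ", cfg$sasa_cutoff, " A^2"))
  }

  summ <- interaction_summary(table, selections,
                              threshold = cfg$threshold,
                              B = cfg$bootstrap_B, seed = cfg$seed,
                              count_mode = cfg$count_mode)
  eec_basic <- eec(summ, selections$basic_core)
  deec <- delta_eec(summ, selections, buried = buried,
                    exclude_buried = isTRUE(cfg$exclude_buried))

  report <- list(
    settings = list(species = selections$species,
                    threshold = cfg$threshold,
                    low_energy_fraction = cfg$low_energy_fraction,
                    bootstrap_B = as.integer(cfg$bootstrap_B),
                    count_mode = cfg$count_mode,
                    exclude_buried = isTRUE(cfg$exclude_buried),
                    sasa_cutoff = cfg$sasa_cutoff,
                    seed = as.integer(cfg$seed)),
    counts = list(models_read = models_read,
                  models_retained = models_kept,
                  favorable_records = nrow(table),
                  records_dropped = attr(table, "n_dropped"),
                  buried_excluded = length(buried)),
    per_residue = as.data.frame(summ),
    eec = as.list(eec_basic),
    delta_eec = as.list(deec),
    buried = buried
  )
  if (!is.null(cfg[["out_dir"]])) write_eec_report(report, cfg[["out_dir"]])
  report
}

#' Write an EEC report bundle
#'
#' JSON report plus a CSV twin of the per-residue table (the machine twin
#' of the per-residue interaction bar data). No timestamps: payloads of
#' identical runs are byte-identical.
#'
#' @param report A report list from [run_eec_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_eec_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "eec_report.json")
  csv_path <- file.path(dir, "per_residue.csv")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  readr::write_csv(tibble::as_tibble(report$per_residue), csv_path)
  invisible(c(json = json_path, csv = csv_path))
}

#' Fit a binding-style dataset and report a verifiable table
#'
#' Dispatches to the matching fitter and returns the parameter table with
#' confidence intervals together with the fitted curve sampled on a grid,
#' so results are verifiable without figures.
#'
#' @param data Data frame: columns `x`, `y` for titrations, `t`, `y` for
#'   progress curves; or a path to a CSV with those columns.
#' @param method One of `"isotherm"`, `"hill"`, `"ic50"`, `"expo"`.
#' @param ... Passed to the underlying fitter (e.g. `fix_n`, `order`).
#' @param grid_n Points in the fitted-curve grid (default 50).
#' @return List with `method`, `parameters` (tidy coefficient tibble),
#'   `glance` row, and `curve` (grid of fitted values).
#' @export
run_bindfit <- function(data, method = c("isotherm", "hill", "ic50", "expo"),
                        ..., grid_n = 50L) {
  method <- match.arg(method)
  if (is.character(data)) {
    data <- readr::read_csv(data, show_col_types = FALSE, progress = FALSE)
    xcol <- intersect(c("x", "t", "time"), names(data))
    if (length(xcol) == 0 || !"y" %in% names(data)) {
      abort("input table needs columns (x or t) and y")
    }
  }
  fit <- switch(method,
    isotherm = fit_single_site(data, ...),
    hill = fit_hill(data, ...),
    ic50 = fit_ic50(data, ...),
    expo = fit_exponential(data, ...)
  )
  xvar <- if (method == "expo") "t" else "x"
  xs <- fit$data[[xvar]]
  pos <- xs[xs > 0]
  grid <- if (method == "expo" || length(pos) < 2) {
    seq(min(xs), max(xs), length.out = grid_n)
  } else {
    10^seq(log10(min(pos)), log10(max(pos)), length.out = grid_n)
  }
  nd <- tibble::tibble(!!xvar := grid)
  curve <- dplyr::mutate(nd, y_fit = as.numeric(predict(fit, newdata = nd)))
  list(method = method, parameters = tidy(fit), glance = glance(fit),
       k_obs = fit$extra$k_obs, curve = curve)
}

#' Relative-affinity table from product/substrate dissociation constants
#'
#' Convenience wrapper applying [compute_krel()] across variants and
#' adding the conventional one-decimal display rounding.
#'
#' @param kd_table Data frame with columns `variant`, `kd_product`,
#'   `kd_substrate` (same units).
#' @return The table with `k_rel` (full precision) and `k_rel_display`
#'   (1 decimal) appended.
#' @export
krel_table <- function(kd_table) {
  d <- tibble::as_tibble(kd_table)
  need <- c("variant", "kd_product", "kd_substrate")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(paste0("kd_table missing column(s): ", paste(miss, collapse = ", ")))
  }
  d |>
    dplyr::mutate(k_rel = compute_krel(.data$kd_product, .data$kd_substrate),
                  k_rel_display = round(.data$k_rel, 1))
}
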