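#' Select the lowest-energy subset of an ensemble
#'
#' Keeps the `max(1, floor(fraction * M))` models with the smallest total
#' energy, ties broken by ascending model id; deterministic.
#'
#' @param ensemble A [model_ensemble].
#' @param fraction Fraction of models to keep, in (0, 1] (default 0.01,
#'   the "lowest-energy 1%" convention).
#' @return A [model_ensemble] restricted to the selected models.
#' @export
select_low_energy <- function(ensemble, fraction = 0.01) {
  if (!inherits(ensemble, "model_ensemble")) abort("expected a model_ensemble")
  m <- n_models(ensemble)
  if (m == 0) abort("ensemble is empty")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  k <- max(1L, floor(fraction * m))
  en <- ensemble$energies
  keep <- en$model_id[order(en$total_energy, en$model_id)][seq_len(k)]
  model_ensemble(
    ensemble$atoms[ensemble$atoms$model_id %in% keep, ],
    en[en$model_id %in% keep, ],
    n_subunits = ensemble$n_subunits,
    species_label = ensemble$species_label
  )
}

#' Restrict a pair-energy table to a model subset
#'
#' @param table A [pair_energy_table()].
#' @param model_ids Model ids to retain (e.g. those of a low-energy subset).
#' @return A [pair_energy_table()] over the given models.
#' @export
restrict_models <- function(table, model_ids) {
  keep <- intersect(attr(table, "model_ids"), model_ids)
  if (length(keep) == 0) abort("no requested model ids present in the table")
  suppressMessages(pair_energy_table(
    table[table$model_id %in% keep, ],
    model_ids = keep, n_subunits = attr(table, "n_subunits")
  ))
}

# Per-model interaction count for one core residue, already divided by
# N_subunits; the basis of both the mean and the bootstrap.
per_model_counts <- function(table, x, threshold = -1.0,
                             count_mode = c("as-printed", "binary")) {
  count_mode <- match.arg(count_mode)
  mids <- attr(table, "model_ids")
  ns <- attr(table, "n_subunits")
  rec <- table[table$core_residue == x &
                 is_favorable(table$energy, threshold) == 1L, ]
  counts <- setNames(numeric(length(mids)), mids)
  if (nrow(rec) > 0) {
    per <- if (count_mode == "as-printed") {
      dplyr::count(rec, .data$model_id, name = "n")
    } else {
      rec |>
        dplyr::distinct(.data$model_id, .data$subunit) |>
        dplyr::count(.data$model_id, name = "n")
    }
    counts[as.character(per$model_id)] <- per$n
  }
  counts / ns
}

#' Mean tail-interaction counts per core residue
#'
#' The average number of favorable tail contacts for each core residue,
#' i.e. the number of (model, subunit, tail-residue) pairings with energy
#' strictly below the threshold, divided by `N_subunits * N_models`.
#' `count_mode = "as-printed"` counts every qualifying tail residue (a core
#' residue touching two tail residues in one subunit counts twice);
#' `"binary"` counts at most one interaction per (model, subunit).
#'
#' @param table A [pair_energy_table()] (already restricted to the model
#'   subset of interest).
#' @param selections A [selection_sets]; counts are reported for every core
#'   residue, zero where no record qualifies.
#' @param threshold Favorability threshold in REU (default -1.0).
#' @param count_mode `"as-printed"` (default) or `"binary"`.
#' @return Tibble with columns `core_residue`, `mean_count`.
#' @export
mean_counts <- function(table, selections, threshold = -1.0,
                        count_mode = c("as-printed", "binary")) {
  count_mode <- match.arg(count_mode)
  tibble::tibble(
    core_residue = selections$core,
    mean_count = vapply(selections$core, function(x) {
      mean(per_model_counts(table, x, threshold, count_mode))
    }, numeric(1))
  )
}

#' Mean interaction energy of a core residue with the tail set
#'
#' The qualifying pair energies of residue `x` are summed within each
#' (model, subunit) cell and averaged over all `N_subunits * N_models`
#' cells (cells without a qualifying pair contribute zero). The returned
#' spread is the population standard deviation of the per-cell sums around
#' that mean, computed without bootstrap resampling.
#'
#' @inheritParams mean_counts
#' @param x Core residue number.
#' @return Named list with `mean_energy` (REU) and `sd_energy`.
#' @export
mean_energy <- function(table, x, threshold = -1.0) {
  mids <- attr(table, "model_ids")
  ns <- attr(table, "n_subunits")
  ncells <- ns * length(mids)
  rec <- table[table$core_residue == x &
                 is_favorable(table$energy, threshold) == 1L, ]
  if (nrow(rec) == 0) return(list(mean_energy = 0, sd_energy = 0))
  cells <- rec |>
    dplyr::group_by(.data$model_id, .data$subunit) |>
    dplyr::summarise(s = sum(.data$energy), .groups = "drop")
  mean_e <- sum(cells$s) / ncells
  var_e <- (sum((cells$s - mean_e)^2) +
              (ncells - nrow(cells)) * mean_e^2) / ncells
  list(mean_energy = mean_e, sd_energy = sqrt(var_e))
}

#' Bootstrap standard deviation of the mean interaction count
#'
#' Resamples the model set with replacement `B` times, recomputes the mean
#' count of residue `x` on each replicate, and returns the population
#' standard deviation of the `B` replicate values. The replicate stream is
#' derived deterministically from `seed` and the residue number, so per-
#' residue results are independent of evaluation order.
#'
#' @inheritParams mean_counts
#' @param x Core residue number.
#' @param B Number of bootstrap replicates (default 1000; must be >= 2).
#' @param seed Integer seed.
#' @return Bootstrap standard deviation (single number).
#' @export
bootstrap_sd_counts <- function(table, x, B = 1000L, seed = 1L,
                                threshold = -1.0,
                                count_mode = c("as-printed", "binary")) {
  count_mode <- match.arg(count_mode)
  if (B < 2) abort("B must be >= 2")
  counts <- per_model_counts(table, x, threshold, count_mode)
  m <- length(counts)
  if (m == 1) {
    warn("single-model table: bootstrap standard deviation is 0")
    return(0)
  }
  withr::with_seed(derive_seed(seed, x), {
    idx <- matrix(sample.int(m, m * B, replace = TRUE), nrow = m)
    reps <- colMeans(matrix(counts[idx], nrow = m))
    sqrt(mean((reps - mean(reps))^2))
  })
}

derive_seed <- function(seed, x) {
  as.integer((as.numeric(seed) * 1000 + as.numeric(x)) %% 2147483647)
}

#' Per-residue interaction summary
#'
#' The machine-readable twin of the per-residue interaction bar data:
#' mean count, bootstrap count SD, mean energy, and energy SD for every
#' core residue, with the analysis settings attached as attributes.
#'
#' @inheritParams bootstrap_sd_counts
#' @param selections A [selection_sets].
#' @return Tibble of class `interaction_summary` with columns
#'   `core_residue`, `mean_count`, `sd_count`, `mean_energy`, `sd_energy`
#'   and a logical `basic` marking membership in the basic patch.
#' @export
interaction_summary <- function(table, selections, threshold = -1.0,
                                B = 1000L, seed = 1L,
                                count_mode = c("as-printed", "binary")) {
  count_mode <- match.arg(count_mode)
  cnt <- mean_counts(table, selections, threshold, count_mode)
  en <- purrr::map(selections$core, ~ mean_energy(table, .x, threshold))
  out <- cnt |>
    dplyr::mutate(
      sd_count = vapply(selections$core, function(x) {
        suppressWarnings(
          bootstrap_sd_counts(table, x, B = B, seed = seed,
                              threshold = threshold, count_mode = count_mode)
        )
      }, numeric(1)),
      mean_energy = vapply(en, `[[`, numeric(1), "mean_energy"),
      sd_energy = vapply(en, `[[`, numeric(1), "sd_energy"),
      basic = .data$core_residue %in% selections$basic_core
    )
  structure(out,
            class = c("interaction_summary", class(out)),
            selections = selections,
            settings = list(threshold = threshold, B = as.integer(B),
                            seed = as.integer(seed), count_mode = count_mode,
                            n_models = length(attr(table, "model_ids")),
                            n_subunits = attr(table, "n_subunits")))
}

#' @method glance interaction_summary
#' @export
glance.interaction_summary <- function(x, ...) {
  s <- attr(x, "settings")
  ee <- eec(x, attr(x, "selections")$basic_core)
  tibble::tibble(eec_basic = ee$eec, sd_eec_basic = ee$sd_eec,
                 n_models = s$n_models, n_subunits = s$n_subunits,
                 threshold = s$threshold, B = s$B, seed = s$seed,
                 count_mode = s$count_mode)
}

#' Expected energetic contribution (EEC) over a residue set
#'
#' EEC = sum over the residue set of mean_count * mean_energy, with the
#' per-residue variance propagated as
#' `sd_energy^2 sd_count^2 + sd_energy^2 mean_count^2 + sd_count^2 mean_energy^2`
#' under independence, summed across residues.
#'
#' @param summary An [interaction_summary()] tibble (or any tibble with
#'   columns `core_residue`, `mean_count`, `sd_count`, `mean_energy`,
#'   `sd_energy`).
#' @param residues Residue set to sum over (must be contained in the
#'   summary's core residues).
#' @return One-row tibble with `eec`, `sd_eec`, `n_residues`.
#' @export
eec <- function(summary, residues) {
  residues <- unique(as.integer(residues))
  outside <- setdiff(residues, summary$core_residue)
  if (length(outside) > 0) {
    abort(paste0("residue(s) outside the summarised core set: ",
                 paste(outside, collapse = ", ")))
  }
  s <- summary[summary$core_residue %in% residues, ]
  v <- s$sd_energy^2 * s$sd_count^2 +
    s$sd_energy^2 * s$mean_count^2 +
    s$sd_count^2 * s$mean_energy^2
  tibble::tibble(eec = sum(s$mean_count * s$mean_energy),
                 sd_eec = sqrt(sum(v)),
                 n_residues = length(residues))
}

#' On-target minus off-target EEC (delta-EEC)
#'
#' Difference between the EEC of the basic patch ("on-target") and the EEC
#' of the remaining core residues ("off-target"), with independent-error
#' propagation. A negative value means tail-core contacts concentrate on
#' the basic patch. Buried residues (surface area below the cutoff) may be
#' excluded from the off-target set.
#'
#' @param summary An [interaction_summary()]; its attached selections
#'   define the on/off split unless `selections` is supplied.
#' @param selections Optional [selection_sets] overriding the attached one.
#' @param buried Integer vector of buried core residues (from
#'   [flag_buried()]); only used when `exclude_buried = TRUE`.
#' @param exclude_buried Drop `buried` from the off-target set?
#' @return One-row tibble with `delta_eec`, `sd_delta_eec`, `eec_on`,
#'   `sd_on`, `eec_off`, `sd_off`.
#' @export
delta_eec <- function(summary, selections = NULL, buried = NULL,
                      exclude_buried = FALSE) {
  selections <- selections %||% attr(summary, "selections")
  if (is.null(selections)) abort("no selections available for delta_eec")
  on <- selections$basic_core
  off <- setdiff(selections$core, on)
  if (exclude_buried && length(buried) > 0) off <- setdiff(off, buried)
  if (length(off) == 0) {
    abort("off-target set is empty (basic_core covers the whole core)")
  }
  e_on <- eec(summary, on)
  e_off <- eec(summary, off)
  tibble::tibble(
    delta_eec = e_on$eec - e_off$eec,
    sd_delta_eec = sqrt(e_on$sd_eec^2 + e_off$sd_eec^2),
    eec_on = e_on$eec, sd_on = e_on$sd_eec,
    eec_off = e_off$eec, sd_off = e_off$sd_eec
  )
}
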