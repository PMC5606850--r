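#' Surrogate pair-potential parameters
#'
#' Declares the two-term surrogate used to score tail-residue/core-residue
#' contacts in REU-like units: a distance-dependent-dielectric Coulomb term
#' plus a soft-sphere repulsion,
#'
#' \deqn{E(r) = k q_1 q_2 / (s r^2) + \max(0, c (r_{rep} - r))^2,}
#'
#' evaluated between side-chain charge centers. With the defaults
#' (k = 332, s = 4, r_rep = 4 A, c = 2) an oppositely charged pair scores
#' about -2 to -6 REU at salt-bridge separations (3-6 A) and crosses the
#' -1.0 REU favorability threshold near 9 A. The Coulomb distance is
#' clamped below `min_distance` so the potential stays bounded.
#'
#' @param charge_map Named numeric vector mapping residue names to formal
#'   side-chain charges; residues absent from the map are neutral.
#' @param dielectric_slope Slope s of the distance-dependent dielectric
#'   eps(r) = s r (must be > 0; default 4).
#' @param repulsion_radius Onset r_rep of the soft repulsion in Angstrom
#'   (must be > 0; default 4).
#' @param coulomb_k Coulomb constant k (default 332, kcal A / (mol e^2)).
#' @param repulsion_scale Repulsion steepness c (default 2).
#' @param min_distance Coulomb clamp distance in Angstrom (default 2).
#' @param energy_unit_scale Multiplier mapping the kcal/mol-like scale onto
#'   REU (default 1).
#' @return An object of class `surrogate_params`.
#' @export
surrogate_params <- function(charge_map = c(ASP = -1, GLU = -1,
                                            ARG = 1, LYS = 1),
                             dielectric_slope = 4,
                             repulsion_radius = 4,
                             coulomb_k = 332,
                             repulsion_scale = 2,
                             min_distance = 2,
                             energy_unit_scale = 1) {
  if (dielectric_slope <= 0) abort("dielectric_slope must be > 0")
  if (repulsion_radius <= 0) abort("repulsion_radius must be > 0")
  if (min_distance <= 0) abort("min_distance must be > 0")
  structure(list(charge_map = charge_map,
                 dielectric_slope = dielectric_slope,
                 repulsion_radius = repulsion_radius,
                 coulomb_k = coulomb_k,
                 repulsion_scale = repulsion_scale,
                 min_distance = min_distance,
                 energy_unit_scale = energy_unit_scale),
            class = "surrogate_params")
}

residue_charge <- function(resname, params) {
  q <- params$charge_map[resname]
  q[is.na(q)] <- 0
  unname(q)
}

# Vectorized pair energy as a function of separation and charges.
pair_energy_fn <- function(r, q1, q2, params) {
  rc <- pmax(r, params$min_distance)
  coul <- params$coulomb_k * q1 * q2 / (params$dielectric_slope * rc^2)
  rep <- pmax(0, params$repulsion_scale * (params$repulsion_radius - r))^2
  (coul + rep) * params$energy_unit_scale
}

# Side-chain charge-center per (chain, resno): mean of side-chain heavy
# atoms, falling back to the alpha carbon (glycine, or bead models carrying
# only CA atoms).
interaction_sites <- function(atoms) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$resname) |>
    dplyr::summarise(
      x = site_coord(.data$atom, .data$element, .data$x),
      y = site_coord(.data$atom, .data$element, .data$y),
      z = site_coord(.data$atom, .data$element, .data$z),
      .groups = "drop"
    )
}

site_coord <- function(atom, element, v) {
  side <- !(atom %in% c("N", "CA", "C", "O", "OXT")) & element != "H"
  if (any(side)) mean(v[side]) else v[match("CA", atom)]
}

#' Surrogate pairwise interaction energy
#'
#' Evaluates the declared surrogate potential between one core residue and
#' one tail residue of a conformation. The interaction site of each residue
#' is the mean position of its side-chain heavy atoms (alpha carbon for
#' glycine and for bead models). When a residue number occurs on several
#' chains, pass `chain_x`/`chain_y` to disambiguate, or leave `NULL` to sum
#' the energy over all chain instances of `x` against the given `y` site
#' (the convention used by [score_ensemble()]).
#'
#' @param conformation Atom tibble (one model).
#' @param x Core residue number.
#' @param y Tail residue number.
#' @param params A [surrogate_params] object.
#' @param chain_x,chain_y Optional chain ids pinning the residue instances.
#' @return Energy in REU (symmetric in the two residues).
#' @export
pair_energy_surrogate <- function(conformation, x, y,
                                  params = surrogate_params(),
                                  chain_x = NULL, chain_y = NULL) {
  sites <- interaction_sites(tibble::as_tibble(conformation))
  sx <- sites[sites$resno == x, ]
  if (!is.null(chain_x)) sx <- sx[sx$chain == chain_x, ]
  sy <- sites[sites$resno == y, ]
  if (!is.null(chain_y)) sy <- sy[sy$chain == chain_y, ]
  if (nrow(sx) == 0) abort(paste0("residue ", x, " not found in conformation"))
  if (nrow(sy) == 0) abort(paste0("residue ", y, " not found in conformation"))
  if (nrow(sy) > 1) {
    abort(paste0("residue ", y, " occurs on several chains; give chain_y"))
  }
  qx <- residue_charge(sx$resname, params)
  qy <- residue_charge(sy$resname, params)
  r <- sqrt((sx$x - sy$x)^2 + (sx$y - sy$y)^2 + (sx$z - sy$z)^2)
  sum(pair_energy_fn(r, qx, qy, params))
}

#' Pair-energy tables
#'
#' Sparse records of favorable (E < 0) tail-core residue-pair energies:
#' one row per `(model_id, subunit, core_residue, tail_residue)` key.
#' Rows with non-negative energy are excluded at construction, mirroring
#' the rule that unfavorable pairwise energies (0 or greater) are not
#' considered further.
#'
#' @param records Data frame with columns `model_id`, `subunit`,
#'   `core_residue`, `tail_residue`, `energy`.
#' @param model_ids All model ids of the underlying ensemble (models
#'   contributing no favorable pair must still enter the normalization and
#'   the bootstrap); defaults to the ids present in `records`.
#' @param n_subunits Number of subunits (default 6).
#' @return A tibble of class `pair_energy_tbl` with attributes
#'   `model_ids`, `n_subunits` and `n_dropped`.
#' @export
pair_energy_table <- function(records, model_ids = NULL, n_subunits = 6L) {
  rec <- tibble::as_tibble(records)
  need <- c("model_id", "subunit", "core_residue", "tail_residue", "energy")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0) {
    abort(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  }
  rec <- rec[, need]
  if (nrow(rec) > 0 && !all(is.finite(rec$energy))) {
    abort("energies must be finite")
  }
  key <- paste(rec$model_id, rec$subunit, rec$core_residue, rec$tail_residue)
  if (anyDuplicated(key) > 0) {
    abort(paste0("duplicate (model, subunit, core, tail) key: ",
                 key[duplicated(key)][1]))
  }
  n_dropped <- sum(rec$energy >= 0)
  if (n_dropped > 0) {
    inform(paste0("dropped ", n_dropped,
                  " record(s) with unfavorable energy (0 or greater)"))
    rec <- rec[rec$energy < 0, ]
  }
  model_ids <- sort(unique(as.integer(model_ids %||% rec$model_id)))
  if (nrow(rec) > 0) {
    stray <- setdiff(rec$model_id, model_ids)
    if (length(stray) > 0) {
      abort(paste0("records reference model id(s) outside model_ids: ",
                   paste(stray, collapse = ", ")))
    }
  }
  structure(rec,
            class = c("pair_energy_tbl", class(tibble::tibble())),
            model_ids = model_ids,
            n_subunits = as.integer(n_subunits),
            n_dropped = n_dropped)
}

#' Score an ensemble with the surrogate potential
#'
#' One pass over all (model, subunit, core residue, tail residue) pairs.
#' A tail residue belongs to the subunit whose chain carries it; the core
#' residue is recorded by residue identity, with its energy summed over all
#' chain instances (tails are long enough to reach neighboring subunits,
#' and the 1/r^2 decay makes distant instances negligible). Only favorable
#' records (E < 0) are kept.
#'
#' @param ensemble A [model_ensemble].
#' @param selections A [selection_sets] object.
#' @param params A [surrogate_params] object.
#' @return A [pair_energy_table()] tibble.
#' @export
score_ensemble <- function(ensemble, selections, params = surrogate_params()) {
  stopifnot(inherits(ensemble, "model_ensemble"),
            inherits(selections, "selection_sets"))
  if (length(selections$core) == 0 || length(selections$tail) == 0) {
    abort("core and tail selections must be non-empty")
  }
  mids <- ensemble$energies$model_id
  chains <- sort(unique(ensemble$atoms$chain[ensemble$atoms$model_id == mids[1]]))
  recs <- purrr::map_dfr(mids, function(m) {
    sites <- interaction_sites(get_conformation(ensemble, m))
    core_s <- sites[sites$resno %in% selections$core, ]
    tail_s <- sites[sites$resno %in% selections$tail, ]
    if (nrow(core_s) == 0 || nrow(tail_s) == 0) return(NULL)
    qc <- residue_charge(core_s$resname, params)
    qt <- residue_charge(tail_s$resname, params)
    cm <- as.matrix(core_s[, c("x", "y", "z")])
    tm <- as.matrix(tail_s[, c("x", "y", "z")])
    # distance matrix tail-sites x core-sites
    d <- sqrt(pmax(outer(rowSums(tm^2), rowSums(cm^2), "+") -
                     2 * tcrossprod(tm, cm), 0))
    e <- pair_energy_fn(d, outer(qt, qc, function(a, b) a), # q1 per tail row
                        outer(qt, qc, function(a, b) b), params)
    tibble::tibble(
      model_id = m,
      subunit = rep(match(tail_s$chain, chains), times = nrow(core_s)),
      core_residue = rep(core_s$resno, each = nrow(tail_s)),
      tail_residue = rep(tail_s$resno, times = nrow(core_s)),
      energy = as.vector(e)
    ) |>
      dplyr::group_by(.data$model_id, .data$subunit,
                      .data$core_residue, .data$tail_residue) |>
      dplyr::summarise(energy = sum(.data$energy), .groups = "drop") |>
      dplyr::filter(.data$energy < 0)
  })
  suppressMessages(
    pair_energy_table(recs, model_ids = mids,
                      n_subunits = ensemble$n_subunits)
  )
}

#' Load a pair-energy table from CSV
#'
#' Ingests externally computed pairwise energies (columns `model_id`,
#' `subunit`, `core_residue`, `tail_residue`, `energy`). Rows with energy
#' >= 0 are dropped with a message reporting the count; duplicate keys are
#' a hard error.
#'
#' @param path CSV file path.
#' @param model_ids Optional full model-id set of the source ensemble.
#' @param n_subunits Number of subunits (default 6).
#' @return A [pair_energy_table()] tibble.
#' @export
load_energy_table <- function(path, model_ids = NULL, n_subunits = 6L) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols())
  if (nrow(tab) == 0) {
    tab <- tibble::tibble(model_id = integer(), subunit = integer(),
                          core_residue = integer(), tail_residue = integer(),
                          energy = numeric())
  }
  pair_energy_table(tab, model_ids = model_ids, n_subunits = n_subunits)
}

#' Favorability indicator
#'
#' Returns 1 when the pairwise energy lies strictly below the threshold
#' (default -1.0 REU), 0 otherwise: an energy equal to the threshold is not
#' favorable.
#'
#' @param energy Numeric vector of pair energies (REU).
#' @param threshold Favorability threshold (default -1.0 REU).
#' @return Integer vector of 0/1.
#' @export
is_favorable <- function(energy, threshold = -1.0) {
  as.integer(energy < threshold)
}
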