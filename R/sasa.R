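#' Van der Waals radii used for accessible-surface-area calculation
#'
#' Element radii (Angstrom) for the Shrake-Rupley calculation. Unknown
#' elements raise an error naming the offending atom.
#' @keywords internal
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# Deterministic, near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Per-atom accessible surface area, Shrake-Rupley test-point method.
# coords: n x 3 matrix; radii: per-atom vdW radii.
atom_sasa <- function(coords, radii, probe_radius = 1.4, n_points = 960L) {
  n <- nrow(coords)
  rad <- radii + probe_radius
  pts <- sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    test <- pts * rad[i] +
      matrix(coords[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (test[, 1] - coords[j, 1])^2 + (test[, 2] - coords[j, 2])^2 +
        (test[, 3] - coords[j, 3])^2
      exposed <- exposed & dj > rad[j]^2
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * mean(exposed)
  }
  area
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley accessible surface with a probe sphere and a fixed,
#' deterministic test-point count. Residues appearing on several chains
#' (one per subunit of the ring) are aggregated by the mean across chains,
#' matching the per-residue-identity reporting used throughout the
#' interaction statistics.
#'
#' @param conformation A tibble of atom records (as returned by
#'   [get_conformation()]) or a [model_ensemble] (the model selected by
#'   `model` is used).
#' @param model Model id when `conformation` is an ensemble (default: first).
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @param n_points Sphere test points per atom (default 960).
#' @param exclude_residues Residue numbers to drop before the calculation
#'   (e.g. tail residues, so that core burial is assessed on the core alone).
#' @return Tibble with columns `resno`, `area` (Angstrom^2).
#' @export
residue_sasa <- function(conformation, model = NULL, probe_radius = 1.4,
                         n_points = 960L, exclude_residues = NULL) {
  if (inherits(conformation, "model_ensemble")) {
    model <- model %||% conformation$energies$model_id[1]
    conformation <- get_conformation(conformation, model)
  }
  at <- tibble::as_tibble(conformation)
  if (!is.null(exclude_residues)) {
    at <- at[!at$resno %in% exclude_residues, ]
  }
  if (nrow(at) == 0) abort("no atoms left to compute surface area for")
  elem <- if ("element" %in% names(at)) at$element else guess_element(at$atom)
  unknown <- !(elem %in% names(.vdw_radii))
  if (any(unknown)) {
    k <- which(unknown)[1]
    abort(paste0("no van der Waals radius for element '", elem[k],
                 "' (atom ", at$atom[k], ", residue ", at$resno[k], ")"))
  }
  area <- atom_sasa(as.matrix(at[, c("x", "y", "z")]),
                    .vdw_radii[elem], probe_radius, n_points)
  tibble::tibble(resno = at$resno, chain = at$chain, area = area) |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop") |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(area = mean(.data$area), .groups = "drop") |>
    dplyr::arrange(.data$resno)
}

#' Flag buried core residues
#'
#' Returns the core residues whose accessible surface area falls below the
#' cutoff (strict `<`); these cannot make tail contacts and may be excluded
#' from the off-target set of [delta_eec()].
#'
#' @param sasa A tibble as returned by [residue_sasa()] (columns `resno`,
#'   `area`) or a named numeric vector of areas keyed by residue number.
#' @param cutoff Area cutoff in Angstrom^2 (default 2.0; must be > 0).
#' @param core Integer vector of core residue numbers to assess.
#' @return Sorted integer vector of buried core residues.
#' @export
flag_buried <- function(sasa, cutoff = 2.0, core) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  if (is.data.frame(sasa)) {
    areas <- setNames(sasa$area, sasa$resno)
  } else {
    areas <- sasa
  }
  core <- as.integer(core)
  missing <- core[!as.character(core) %in% names(areas)]
  if (length(missing) > 0) {
    abort(paste0("core residue(s) absent from the surface-area map: ",
                 paste(missing, collapse = ", ")))
  }
  sort(core[areas[as.character(core)] < cutoff])
}
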