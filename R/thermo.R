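#' Relative product/substrate affinity
#'
#' K_rel = Kd(product) / Kd(substrate): the ratio of dissociation constants
#' for the annealed duplex product versus the single-stranded substrate. A
#' large K_rel means the chaperone releases its product efficiently.
#' Reported values are conventionally rounded to one decimal for display;
#' the full-precision ratio is returned.
#'
#' @param kd_product,kd_substrate Dissociation constants (> 0, same units).
#' @param unit_product,unit_substrate Optional unit labels; a mismatch is
#'   an error rather than a silent conversion.
#' @return Numeric ratio (dimensionless), vectorized.
#' @export
#' @examples
#' round(compute_krel(117, 15.5), 1) # 7.5
compute_krel <- function(kd_product, kd_substrate,
                         unit_product = NULL, unit_substrate = NULL) {
  if (!is.null(unit_product) && !is.null(unit_substrate) &&
      any(unit_product != unit_substrate)) {
    abort(paste0("unit mismatch: ", unit_product, " vs ", unit_substrate))
  }
  if (any(kd_product <= 0) || any(kd_substrate <= 0)) {
    abort("dissociation constants must be > 0")
  }
  kd_product / kd_substrate
}

#' Binding free-energy perturbation
#'
#' DeltaDeltaG = -R T ln(Kd_mut / Kd_wt) in kcal/mol, with
#' R = 1.987e-3 kcal/(mol K) and T defaulting to 303.15 K (30 C, the assay
#' temperature). Negative values mean the mutation weakened binding.
#'
#' @param kd_mut,kd_wt Dissociation constants (> 0, same units).
#' @param temperature Temperature in kelvin (default 303.15).
#' @return DeltaDeltaG in kcal/mol, vectorized.
#' @export
compute_ddg <- function(kd_mut, kd_wt, temperature = 303.15) {
  if (any(kd_mut <= 0) || any(kd_wt <= 0)) abort("Kd values must be > 0")
  r_gas <- 1.987e-3
  -r_gas * temperature * log(kd_mut / kd_wt)
}

#' Relative observed rate
#'
#' k_rel = k_obs(variant) / k_obs(reference); below 1 when the variant is
#' slower (i.e. the mutated residue matters for annealing).
#'
#' @param k_obs_variant,k_obs_reference Observed rates (> 0).
#' @return Numeric ratio, vectorized.
#' @export
relative_rate <- function(k_obs_variant, k_obs_reference) {
  if (any(k_obs_variant <= 0) || any(k_obs_reference <= 0)) {
    abort("rates must be > 0")
  }
  k_obs_variant / k_obs_reference
}

#' Anisotropy phase parameters
#'
#' Endpoint anisotropies of the three-state release experiment: `r_AP` at
#' the end of the annealing-and-release phase, `r_Mdr` for free duplex,
#' `r_Mhdr` for the ternary chaperone-duplex complex, `r_hd` for the
#' binary chaperone-probe complex at the annealing-phase endpoint (the
#' equilibrium maximum `r_Mhd` is carried for reporting only), plus the
#' relative affinity `K_rel` linking the binary and ternary fractions.
#'
#' @param r_AP,r_Mdr,r_Mhdr,r_hd Anisotropies, each in (0, 0.4).
#' @param r_Mhd Optional equilibrium binary-complex anisotropy (reporting
#'   only).
#' @param K_rel Relative affinity (>= 0).
#' @return An object of class `anisotropy_phases`.
#' @export
anisotropy_phases <- function(r_AP, r_Mdr, r_Mhdr, r_hd, r_Mhd = NULL,
                              K_rel) {
  vals <- c(r_AP = r_AP, r_Mdr = r_Mdr, r_Mhdr = r_Mhdr, r_hd = r_hd,
            r_Mhd = r_Mhd %||% NA_real_)
  chk <- vals[!is.na(vals)]
  if (any(chk <= 0 | chk >= 0.4)) {
    abort(paste0("anisotropies must lie in (0, 0.4); offending: ",
                 paste(names(chk)[chk <= 0 | chk >= 0.4], collapse = ", ")))
  }
  if (K_rel < 0) abort("K_rel must be >= 0")
  structure(list(r_AP = r_AP, r_Mdr = r_Mdr, r_Mhdr = r_Mhdr,
                 r_hd = r_hd, r_Mhd = r_Mhd, K_rel = K_rel),
            class = "anisotropy_phases")
}

#' Three-state molar fractions from endpoint anisotropy
#'
#' Deconvolves the endpoint anisotropy into molar fractions of released
#' duplex (`chi_dr`), ternary complex (`chi_hdr`) and binary complex
#' (`chi_hd`) by solving the mixture equation
#' `r_AP = chi_dr r_Mdr + chi_hdr r_Mhdr + chi_hd r_hd`
#' under conservation (`chi_dr + chi_hdr + chi_hd = 1`) and the affinity
#' link (`chi_hd = K_rel chi_hdr`):
#'
#' `chi_hdr = (r_AP - r_Mdr) / (r_Mhdr + K_rel r_hd - (1 + K_rel) r_Mdr)`.
#'
#' Fractions outside `[0, 1]` trigger a warning (the inputs are then
#' mutually inconsistent), not an error; a near-zero denominator is an
#' error.
#'
#' @param phases An [anisotropy_phases()] object, or a data frame with
#'   columns `r_AP`, `r_Mdr`, `r_Mhdr`, `r_hd`, `K_rel` (one row per
#'   condition).
#' @return Tibble with columns `chi_dr`, `chi_hdr`, `chi_hd` (rows sum to
#'   1 exactly).
#' @export
molar_fractions <- function(phases) {
  if (inherits(phases, "anisotropy_phases")) {
    df <- tibble::tibble(r_AP = phases$r_AP, r_Mdr = phases$r_Mdr,
                         r_Mhdr = phases$r_Mhdr, r_hd = phases$r_hd,
                         K_rel = phases$K_rel)
  } else {
    df <- tibble::as_tibble(phases)
    need <- c("r_AP", "r_Mdr", "r_Mhdr", "r_hd", "K_rel")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      abort(paste0("phases missing column(s): ", paste(miss, collapse = ", ")))
    }
  }
  denom <- df$r_Mhdr + df$K_rel * df$r_hd - (1 + df$K_rel) * df$r_Mdr
  scale <- pmax(abs(df$r_Mhdr), abs(df$r_Mdr), .Machine$double.eps)
  if (any(abs(denom) < 1e-10 * scale)) {
    abort("anisotropy denominator is (near) zero; fractions are undefined")
  }
  chi_hdr <- (df$r_AP - df$r_Mdr) / denom
  chi_hd <- df$K_rel * chi_hdr
  chi_dr <- 1 - chi_hdr - chi_hd
  out <- tibble::tibble(chi_dr = chi_dr, chi_hdr = chi_hdr, chi_hd = chi_hd)
  bad <- chi_dr < 0 | chi_dr > 1 | chi_hdr < 0 | chi_hdr > 1 |
    chi_hd < 0 | chi_hd > 1
  if (any(bad)) {
    warn(paste0("molar fraction(s) outside [0, 1] in row(s) ",
                paste(which(bad), collapse = ", "),
                "; inputs may be inconsistent"))
  }
  out
}
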