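#' Toy hexamer specification
#'
#' Declares the coarse-grained bead hexamer used by [sample_tail_ensemble()]:
#' a six-fold symmetric ring of core beads (a basic rim patch mapped to the
#' E. coli basic-core numbering 3/16/17/19/47, plus neutral core beads) with
#' one disordered tail grafted per subunit. The last residues of each tail
#' carry `tip_charges` (default: -1 at positions 97, 99, 100 and 102,
#' matching an acidic D/E/E/E tip; set all zero for a neutralized tip).
#' Every bead is written as an alpha-carbon-like atom so ensembles
#' round-trip through the PDB reader with residue numbers matching the
#' shipped selections.
#'
#' @param ring_radius Rim radius in Angstrom (default 30).
#' @param tail_length Number of tail residues (>= 5; default 13, residues
#'   90-102).
#' @param tip_charges Charges of the last `length(tip_charges)` tail
#'   residues (default `c(-1, 0, -1, -1, 0, -1)` for residues 97-102).
#' @param bond_length Bead-bead bond length in Angstrom (default 3.8).
#' @param kT Temperature-like Metropolis parameter in REU (default 1).
#' @param seed Integer seed recorded in the spec.
#' @return An object of class `toy_hexamer_spec`.
#' @export
toy_hexamer_spec <- function(ring_radius = 30, tail_length = 13L,
                             tip_charges = c(-1, 0, -1, -1, 0, -1),
                             bond_length = 3.8, kT = 1, seed = 1L) {
  if (tail_length < 5) abort("tail_length must be >= 5")
  if (length(tip_charges) > tail_length) {
    abort("tip_charges cannot be longer than the tail")
  }
  if (ring_radius <= 0 || bond_length <= 0 || kT <= 0) {
    abort("ring_radius, bond_length and kT must be > 0")
  }
  structure(list(ring_radius = ring_radius,
                 tail_length = as.integer(tail_length),
                 tip_charges = tip_charges,
                 bond_length = bond_length, kT = kT,
                 seed = as.integer(seed), n_subunits = 6L,
                 basic_resno = c(3L, 16L, 17L, 19L, 47L),
                 neutral_resno = c(25L, 30L, 35L, 40L, 55L, 60L),
                 tail_last = 102L),
            class = "toy_hexamer_spec")
}

#' Selections matching the toy hexamer
#'
#' @param spec A [toy_hexamer_spec()].
#' @return A [selection_sets] whose core covers the toy core beads, whose
#'   basic patch is the charged rim set, and whose tail set is the acidic
#'   tip numbering 97/99/100/102.
#' @export
toy_selections <- function(spec = toy_hexamer_spec()) {
  selection_sets(core = sort(c(spec$basic_resno, spec$neutral_resno)),
                 basic_core = spec$basic_resno,
                 tail = c(97L, 99L, 100L, 102L),
                 species = "toy hexamer")
}

charge_to_resname <- function(q) {
  ifelse(q < 0, "GLU", ifelse(q > 0, "ARG", "ALA"))
}

# Core bead template for one toy hexamer: tibble(chain, resno, resname,
# charge, x, y, z). Rim basic beads sit at the ring radius; neutral beads
# sit deeper in the ring.
toy_core_beads <- function(spec) {
  deg <- pi / 180
  purrr::map_dfr(0:(spec$n_subunits - 1), function(s) {
    th0 <- 60 * s * deg
    basic <- tibble::tibble(
      resno = spec$basic_resno, charge = 1,
      ang = th0 + c(-12, -6, 0, 6, 12) * deg,
      rad = spec$ring_radius, z = 2
    )
    neutral <- tibble::tibble(
      resno = spec$neutral_resno, charge = 0,
      ang = th0 + c(-15, -9, -3, 3, 9, 15) * deg,
      rad = 0.55 * spec$ring_radius,
      z = rep(c(-3, 3), length.out = length(spec$neutral_resno))
    )
    dplyr::bind_rows(basic, neutral) |>
      dplyr::mutate(chain = LETTERS[s + 1],
                    resname = charge_to_resname(.data$charge),
                    x = .data$rad * cos(.data$ang),
                    y = .data$rad * sin(.data$ang)) |>
      dplyr::select("chain", "resno", "resname", "charge", "x", "y", "z")
  })
}

toy_anchor <- function(spec, s) {
  deg <- pi / 180
  th <- (60 * s + 20) * deg
  c(spec$ring_radius * cos(th), spec$ring_radius * sin(th), 6)
}

# Rodrigues rotation of points about an axis through `origin`.
rotate_about <- function(pts, origin, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  p <- sweep(pts, 2, origin)
  ca <- cos(angle)
  sa <- sin(angle)
  cross <- cbind(axis[2] * p[, 3] - axis[3] * p[, 2],
                 axis[3] * p[, 1] - axis[1] * p[, 3],
                 axis[1] * p[, 2] - axis[2] * p[, 1])
  dot <- as.vector(p %*% axis)
  rot <- p * ca + cross * sa + outer(dot, axis) * (1 - ca)
  sweep(rot, 2, origin, "+")
}

# Per-bead surrogate energy against all core beads (matrix form of
# pair_energy_fn); `qq` is the precomputed bead x core charge product.
beads_core_energy <- function(bead_xyz, qq, core_xyz, core_ss, params) {
  d2 <- outer(rowSums(bead_xyz^2), core_ss, "+") -
    2 * tcrossprod(bead_xyz, core_xyz)
  d <- sqrt(pmax(d2, 0))
  rc2 <- pmax(d, params$min_distance)^2
  coul <- params$coulomb_k * qq / (params$dielectric_slope * rc2)
  rep <- pmax(0, params$repulsion_scale * (params$repulsion_radius - d))^2
  rowSums(coul + rep) * params$energy_unit_scale
}

#' Sample a coarse-grained tail-on-hexamer ensemble
#'
#' Generates `n_models` conformations of the toy hexamer: each of the six
#' tails is a freely jointed bead chain grafted at its subunit's rim
#' anchor, equilibrated by Metropolis pivot moves against the fixed core
#' beads under the surrogate potential. The per-model total energy (sum of
#' all tail-core pair energies) is recorded, so low-energy subsets can be
#' selected exactly as for externally modeled ensembles. The sampler is a
#' pure function of the spec, seed and move budget.
#'
#' @param spec A [toy_hexamer_spec()].
#' @param n_models Number of models to generate.
#' @param moves_per_residue Attempted pivot moves per disordered residue
#'   (default 50).
#' @param params A [surrogate_params()] (the same potential later used for
#'   scoring).
#' @param seed Integer seed; defaults to the spec's seed.
#' @return A [model_ensemble] with a `ground_truth` attribute recording
#'   the spec, tip charges and seed.
#' @export
sample_tail_ensemble <- function(spec, n_models, moves_per_residue = 50L,
                                 params = surrogate_params(),
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "toy_hexamer_spec"))
  if (n_models < 1) abort("n_models must be >= 1")
  core <- toy_core_beads(spec)
  core_xyz <- as.matrix(core[, c("x", "y", "z")])
  core_q <- core$charge
  L <- spec$tail_length
  tail_resno <- seq(spec$tail_last - L + 1L, spec$tail_last)
  tail_q <- numeric(L)
  ntip <- length(spec$tip_charges)
  if (ntip > 0) tail_q[(L - ntip + 1):L] <- spec$tip_charges
  n_moves <- moves_per_residue * L
  core_ss <- rowSums(core_xyz^2)
  qq <- outer(tail_q, core_q)

  sample_one_tail <- function(anchor) {
    u <- c(anchor[1], anchor[2], 0)
    u <- u / sqrt(sum(u^2))
    u <- (u + c(0, 0, 0.3)) / sqrt(1 + 0.09)
    beads <- matrix(anchor, L, 3, byrow = TRUE) +
      outer(seq_len(L) * spec$bond_length, u)
    d2 <- outer(rowSums(beads^2), core_ss, "+") -
      2 * tcrossprod(beads, core_xyz)
    dmin <- sqrt(max(min(d2), 0))
    if (!is.finite(dmin) || dmin < 0.6 * spec$bond_length) {
      abort("chain cannot avoid core overlap at the given bond_length")
    }
    # cache the per-bead energies; a pivot move only touches beads j..L
    ebead <- beads_core_energy(beads, qq, core_xyz, core_ss, params)
    for (mv in seq_len(n_moves)) {
      j <- sample.int(L, 1)
      origin <- if (j == 1) anchor else beads[j - 1, ]
      axis <- rnorm(3)
      angle <- rnorm(1, 0, 0.7)
      seg <- j:L
      new_seg <- rotate_about(beads[seg, , drop = FALSE], origin, axis, angle)
      e_new <- beads_core_energy(new_seg, qq[seg, , drop = FALSE],
                                 core_xyz, core_ss, params)
      de <- sum(e_new) - sum(ebead[seg])
      if (de <= 0 || runif(1) < exp(-de / spec$kT)) {
        beads[seg, ] <- new_seg
        ebead[seg] <- e_new
      }
    }
    list(beads = beads, energy = sum(ebead))
  }

  withr::with_seed(seed, {
    models <- purrr::map(seq_len(n_models), function(m) {
      tails <- purrr::map(0:(spec$n_subunits - 1), function(s) {
        sample_one_tail(toy_anchor(spec, s))
      })
      atoms <- dplyr::bind_rows(
        core |>
          dplyr::mutate(model_id = m, atom = "CA", element = "C") |>
          dplyr::select("model_id", "chain", "resno", "resname",
                        "atom", "element", "x", "y", "z"),
        purrr::map_dfr(seq_along(tails), function(i) {
          b <- tails[[i]]$beads
          tibble::tibble(model_id = m, chain = LETTERS[i],
                         resno = tail_resno,
                         resname = charge_to_resname(tail_q),
                         atom = "CA", element = "C",
                         x = b[, 1], y = b[, 2], z = b[, 3])
        })
      ) |>
        dplyr::arrange(.data$chain, .data$resno)
      list(atoms = atoms,
           energy = sum(vapply(tails, `[[`, numeric(1), "energy")))
    })
    ens <- model_ensemble(
      purrr::map_dfr(models, "atoms"),
      tibble::tibble(model_id = seq_len(n_models),
                     total_energy = vapply(models, `[[`, numeric(1), "energy")),
      n_subunits = spec$n_subunits,
      species_label = "toy hexamer"
    )
    attr(ens, "ground_truth") <- list(spec = spec, tip_charges = spec$tip_charges,
                                      seed = seed,
                                      moves_per_residue = moves_per_residue)
    ens
  })
}

#' Generate a noisy titration dataset with known ground truth
#'
#' Log-spaced concentrations spanning `x_span`, signal from the Hill model
#' `y = x^n / (Kd^n + x^n)` (n = 1 gives the single-site isotherm) plus
#' i.i.d. Gaussian noise. Bit-reproducible for a fixed seed.
#'
#' @param true_kd True dissociation constant.
#' @param hill_n True Hill coefficient (default 1).
#' @param n_points Points per replicate (default 12).
#' @param x_span Concentration range (default `true_kd * c(1/50, 50)`;
#'   must bracket `true_kd`).
#' @param noise_sd Gaussian noise SD on the signal (default 0).
#' @param seed Integer seed.
#' @param replicates Number of replicates (default 1).
#' @param unit,basis Recorded concentration unit and basis.
#' @return A [titration_data()] tibble with a `ground_truth` attribute.
#' @export
generate_titration <- function(true_kd, hill_n = 1, n_points = 12L,
                               x_span = true_kd * c(1 / 50, 50),
                               noise_sd = 0, seed = 1L, replicates = 1L,
                               unit = "uM", basis = "monomer") {
  if (x_span[1] >= true_kd || x_span[2] <= true_kd) {
    abort("x_span must bracket true_kd")
  }
  x <- 10^seq(log10(x_span[1]), log10(x_span[2]), length.out = n_points)
  withr::with_seed(seed, {
    df <- purrr::map_dfr(seq_len(replicates), function(r) {
      tibble::tibble(x = x,
                     y = x^hill_n / (true_kd^hill_n + x^hill_n) +
                       rnorm(n_points, 0, noise_sd),
                     replicate = r)
    })
    out <- titration_data(df$x, df$y, replicate = df$replicate,
                          unit = unit, basis = basis)
    attr(out, "ground_truth") <- list(true_kd = true_kd, hill_n = hill_n,
                                      noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Generate a noisy competition dataset with known ground truth
#'
#' Signal from `y = minY + (maxY - minY)/(1 + (x/IC50)^n)` plus Gaussian
#' noise, on log-spaced competitor concentrations spanning `x_span`.
#'
#' @param true_ic50 True half-displacement concentration.
#' @param n True steepness (default 1).
#' @param minY,maxY Lower and upper signal plateaus (defaults 0 and 1).
#' @inheritParams generate_titration
#' @return A [titration_data()] tibble with a `ground_truth` attribute.
#' @export
generate_competition <- function(true_ic50, n = 1, minY = 0, maxY = 1,
                                 n_points = 12L,
                                 x_span = true_ic50 * c(1 / 50, 50),
                                 noise_sd = 0, seed = 1L,
                                 unit = "uM", basis = "monomer") {
  if (x_span[1] >= true_ic50 || x_span[2] <= true_ic50) {
    abort("x_span must bracket true_ic50")
  }
  x <- 10^seq(log10(x_span[1]), log10(x_span[2]), length.out = n_points)
  withr::with_seed(seed, {
    y <- minY + (maxY - minY) / (1 + (x / true_ic50)^n) +
      rnorm(n_points, 0, noise_sd)
    out <- titration_data(x, y, unit = unit, basis = basis)
    attr(out, "ground_truth") <- list(true_ic50 = true_ic50, n = n,
                                      minY = minY, maxY = maxY,
                                      noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Generate an anisotropy release endpoint with known fractions
#'
#' Builds the endpoint anisotropy implied by known molar fractions of
#' released duplex, ternary and binary complex,
#' `r_AP = chi_dr r_Mdr + chi_hdr r_Mhdr + chi_hd r_hd`, emits a
#' 20-second-interval anisotropy series around it, and returns phase
#' parameters whose `K_rel` is consistent with the fractions — so
#' [molar_fractions()] applied to the noiseless output recovers the truth
#' exactly.
#'
#' @param phases An [anisotropy_phases()] supplying `r_Mdr`, `r_Mhdr`,
#'   `r_hd` (its `r_AP`/`K_rel` are ignored and recomputed).
#' @param true_fractions Numeric length-3 `c(chi_dr, chi_hdr, chi_hd)`
#'   summing to 1, all >= 0, `chi_hdr > 0`.
#' @param noise_sd Gaussian noise SD on the series (default 0).
#' @param seed Integer seed.
#' @param n_points Series length (default 10, i.e. 3 min at 20 s).
#' @return List with `series` (tibble `time`, `anisotropy`), `phases`
#'   (an [anisotropy_phases()] carrying the implied `r_AP` and `K_rel`)
#'   and `ground_truth`.
#' @export
generate_release_timecourse <- function(phases, true_fractions,
                                        noise_sd = 0, seed = 1L,
                                        n_points = 10L) {
  if (length(true_fractions) != 3 || any(true_fractions < 0) ||
      abs(sum(true_fractions) - 1) > 1e-8) {
    abort("true_fractions must be length 3, non-negative, summing to 1")
  }
  chi <- setNames(true_fractions, c("chi_dr", "chi_hdr", "chi_hd"))
  if (chi[["chi_hdr"]] <= 0) {
    abort("chi_hdr must be > 0 (K_rel = chi_hd / chi_hdr is undefined)")
  }
  k_rel <- chi[["chi_hd"]] / chi[["chi_hdr"]]
  r_ap <- chi[["chi_dr"]] * phases$r_Mdr + chi[["chi_hdr"]] * phases$r_Mhdr +
    chi[["chi_hd"]] * phases$r_hd
  out_phases <- anisotropy_phases(r_AP = r_ap, r_Mdr = phases$r_Mdr,
                                  r_Mhdr = phases$r_Mhdr, r_hd = phases$r_hd,
                                  r_Mhd = phases$r_Mhd, K_rel = k_rel)
  withr::with_seed(seed, {
    series <- tibble::tibble(
      time = seq(0, by = 20, length.out = n_points),
      anisotropy = r_ap + rnorm(n_points, 0, noise_sd)
    )
    list(series = series, phases = out_phases,
         ground_truth = list(fractions = chi, K_rel = k_rel,
                             noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a noisy single-exponential progress curve
#'
#' `y = A (1 - exp(-k t)) + c` plus Gaussian noise on an even time grid.
#'
#' @param k True rate (per second, > 0).
#' @param A Amplitude (default 1).
#' @param c Offset (default 0).
#' @param n_points Time points (default 100).
#' @param t_max End time (default `5 / k`, five lifetimes).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed Integer seed.
#' @return Tibble with columns `t`, `y` and a `ground_truth` attribute.
#' @export
generate_progress_curve <- function(k, A = 1, c = 0, n_points = 100L,
                                    t_max = 5 / k, noise_sd = 0, seed = 1L) {
  if (k <= 0) abort("rate k must be > 0")
  t <- seq(0, t_max, length.out = n_points)
  withr::with_seed(seed, {
    out <- tibble::tibble(t = t,
                          y = A * (1 - exp(-k * t)) + c +
                            rnorm(n_points, 0, noise_sd))
    attr(out, "ground_truth") <- list(k = k, A = A, c = c,
                                      noise_sd = noise_sd, seed = seed)
    out
  })
}
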