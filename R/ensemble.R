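#' Multi-model structural ensembles
#'
#' A `model_ensemble` holds an ordered set of conformations of one hexamer
#' (or any oligomer) sharing a single chain/residue topology, together with
#' one total energy per model. Atom records live in a tibble with columns
#' `model_id`, `chain`, `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`;
#' energies in a tibble with columns `model_id`, `total_energy` (REU).
#'
#' @param atoms Tibble of atom records (see Details).
#' @param energies Tibble with columns `model_id`, `total_energy`.
#' @param n_subunits Number of subunits in the ring (default 6).
#' @param species_label Free-text label carried through reports.
#'
#' @return An object of class `model_ensemble`.
#' @export
model_ensemble <- function(atoms, energies, n_subunits = 6L, species_label = "") {
  atoms <- tibble::as_tibble(atoms)
  energies <- tibble::as_tibble(energies)
  need <- c("model_id", "chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$atom)
  }
  if (n_subunits < 1) abort("n_subunits must be >= 1")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must all be finite")
  }
  mids <- unique(atoms$model_id)
  if (anyDuplicated(energies$model_id) > 0) abort("duplicate model_id in energies")
  if (!setequal(mids, energies$model_id)) {
    abort("energies must cover exactly the model_ids present in atoms")
  }
  if (!all(is.finite(energies$total_energy))) abort("total energies must be finite")
  # identical topology across models, checked against the first model
  ref <- atoms[atoms$model_id == mids[1], c("chain", "resno", "resname", "atom")]
  for (m in mids[-1]) {
    cur <- atoms[atoms$model_id == m, c("chain", "resno", "resname", "atom")]
    if (!identical(as.data.frame(ref), as.data.frame(cur))) {
      abort(paste0("topology mismatch: model ", m,
                   " differs from model ", mids[1]))
    }
  }
  # residue numbers strictly ordered within a chain (first model suffices)
  first <- atoms[atoms$model_id == mids[1], ]
  bad <- first |>
    dplyr::distinct(.data$chain, .data$resno) |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(ok = !is.unsorted(.data$resno, strictly = TRUE),
                     .groups = "drop")
  if (!all(bad$ok)) {
    abort(paste0("residue numbers not strictly increasing in chain(s): ",
                 paste(bad$chain[!bad$ok], collapse = ", ")))
  }
  structure(
    list(atoms = atoms,
         energies = dplyr::arrange(energies, match(.data$model_id, mids)),
         n_subunits = as.integer(n_subunits),
         species_label = species_label),
    class = "model_ensemble"
  )
}

#' @export
print.model_ensemble <- function(x, ...) {
  m1 <- x$atoms[x$atoms$model_id == x$energies$model_id[1], ]
  cat("<model_ensemble> ", n_models(x), " model(s), ",
      length(unique(m1$chain)), " chain(s), ",
      nrow(m1), " atoms/model, n_subunits = ", x$n_subunits,
      if (nzchar(x$species_label)) paste0(" [", x$species_label, "]") else "",
      "\n", sep = "")
  cat("  total_energy range: [",
      sprintf("%.3f", min(x$energies$total_energy)), ", ",
      sprintf("%.3f", max(x$energies$total_energy)), "] REU\n", sep = "")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble A `model_ensemble`.
#' @return Integer count of models.
#' @export
n_models <- function(ensemble) nrow(ensemble$energies)

#' Extract one conformation
#'
#' @param ensemble A `model_ensemble`.
#' @param model A model id present in the ensemble.
#' @return Tibble of atom records for that model, with the per-model
#'   `total_energy` attached as an attribute.
#' @export
get_conformation <- function(ensemble, model) {
  if (!model %in% ensemble$energies$model_id) {
    abort(paste0("model ", model, " not present in ensemble"))
  }
  out <- ensemble$atoms[ensemble$atoms$model_id == model, ]
  attr(out, "total_energy") <-
    ensemble$energies$total_energy[ensemble$energies$model_id == model]
  out
}

guess_element <- function(atom_name) {
  core <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", atom_name)))
  ifelse(substr(core, 1, 1) %in% c("C", "N", "O", "S", "P", "H"),
         substr(core, 1, 1), core)
}

#' Read a multi-model PDB ensemble
#'
#' Reads a standard MODEL/ENDMDL-delimited PDB file into a [model_ensemble],
#' verifying that every model shares the topology of the first (same chains,
#' residue identities, numbering and atom names). Per-model total energies
#' are taken either from `REMARK ENERGY <model_id> <value>` header lines or
#' from a two-column sidecar table (`model_id, energy`).
#'
#' @param path Path to a PDB file.
#' @param format Only `"pdb-multimodel"` is supported.
#' @param energy_source `"remark-field"` or `"sidecar-table"`.
#' @param energy_path Path to the sidecar CSV when
#'   `energy_source = "sidecar-table"`.
#' @param n_subunits,species_label Passed to [model_ensemble()].
#' @return A [model_ensemble].
#' @export
read_ensemble <- function(path,
                          format = "pdb-multimodel",
                          energy_source = c("remark-field", "sidecar-table"),
                          energy_path = NULL,
                          n_subunits = 6L,
                          species_label = "") {
  format <- match.arg(format)
  energy_source <- match.arg(energy_source)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE)

  model_ids <- check_pdb_topology(raw)
  multi <- length(model_ids) > 1
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) != length(model_ids)) {
    abort("model count from MODEL records disagrees with coordinate sets read")
  }

  at <- pdb$atom
  natom <- nrow(at)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- guess_element(at$elety)
  } else {
    elem <- toupper(trimws(elem))
    elem[!nzchar(elem)] <- guess_element(at$elety[!nzchar(elem)])
  }

  atoms <- purrr::map_dfr(seq_along(model_ids), function(i) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    tibble::tibble(
      model_id = model_ids[i],
      chain = at$chain, resno = as.integer(at$resno),
      resname = at$resid, atom = at$elety, element = elem,
      x = co[, 1], y = co[, 2], z = co[, 3]
    )
  })

  energies <- switch(energy_source,
    "remark-field" = read_remark_energies(raw),
    "sidecar-table" = {
      if (is.null(energy_path)) abort("energy_path is required for sidecar-table")
      read_energy_sidecar(energy_path)
    }
  )
  missing_e <- setdiff(model_ids, energies$model_id)
  if (length(missing_e) > 0) {
    abort(paste0("missing per-model energies for model(s): ",
                 paste(missing_e, collapse = ", ")))
  }
  energies <- energies[energies$model_id %in% model_ids, ]

  model_ensemble(atoms, energies, n_subunits = n_subunits,
                 species_label = species_label)
}

# Verify each MODEL block carries the same atom identity records; returns
# the model ids in file order. Identity = PDB columns 13-27
# (atom name, altLoc, resname, chain, resno, iCode).
check_pdb_topology <- function(raw) {
  is_model <- startsWith(raw, "MODEL")
  is_atom <- startsWith(raw, "ATOM") | startsWith(raw, "HETATM")
  if (!any(is_model)) {
    if (!any(is_atom)) abort("no ATOM records found")
    return(1L)
  }
  starts <- which(is_model)
  ends <- which(startsWith(raw, "ENDMDL"))
  if (length(ends) != length(starts)) abort("unbalanced MODEL/ENDMDL records")
  model_ids <- vapply(raw[starts], function(l) {
    id <- suppressWarnings(as.integer(trimws(substr(l, 6, 80))))
    if (is.na(id)) NA_integer_ else id
  }, integer(1), USE.NAMES = FALSE)
  if (anyNA(model_ids)) model_ids <- seq_along(starts)
  if (anyDuplicated(model_ids) > 0) abort("duplicate MODEL ids in file")
  ident <- lapply(seq_along(starts), function(i) {
    blk <- raw[starts[i]:ends[i]]
    substr(blk[startsWith(blk, "ATOM") | startsWith(blk, "HETATM")], 13, 27)
  })
  for (i in seq_along(ident)[-1]) {
    if (!identical(ident[[i]], ident[[1]])) {
      abort(paste0("topology mismatch: model ", model_ids[i],
                   " differs from model ", model_ids[1]))
    }
  }
  model_ids
}

read_remark_energies <- function(raw) {
  rem <- raw[grepl("^REMARK\\s+ENERGY\\b", raw)]
  if (length(rem) == 0) {
    abort("no 'REMARK ENERGY <model_id> <energy>' lines found")
  }
  parts <- strsplit(trimws(rem), "\\s+")
  tibble::tibble(
    model_id = vapply(parts, function(p) as.integer(p[3]), integer(1)),
    total_energy = vapply(parts, function(p) as.numeric(p[4]), numeric(1))
  )
}

read_energy_sidecar <- function(path) {
  if (!file.exists(path)) abort(paste0("energy sidecar not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ecol <- intersect(c("energy", "total_energy"), names(tab))
  if (!"model_id" %in% names(tab) || length(ecol) == 0) {
    abort("energy sidecar needs columns model_id and energy (or total_energy)")
  }
  tibble::tibble(model_id = as.integer(tab$model_id),
                 total_energy = as.numeric(tab[[ecol[1]]]))
}

#' Write a multi-model PDB ensemble
#'
#' Writes MODEL/ENDMDL-delimited coordinates via bio3d, with per-model
#' energies as `REMARK ENERGY <model_id> <energy>` header lines so that
#' [read_ensemble()] round-trips the ensemble.
#'
#' @param ensemble A [model_ensemble].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  mids <- ensemble$energies$model_id
  first <- ensemble$atoms[ensemble$atoms$model_id == mids[1], ]
  xyz <- t(vapply(mids, function(m) {
    a <- ensemble$atoms[ensemble$atoms$model_id == m, ]
    as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  }, numeric(3 * nrow(first))))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp, xyz = xyz,
                   resno = first$resno, chain = first$chain,
                   resid = first$resname, elety = first$atom,
                   elesy = first$element)
  body <- readLines(tmp, warn = FALSE)
  # bio3d numbers MODEL blocks 1..M; relabel with the ensemble's model ids
  midx <- 0L
  for (i in seq_along(body)) {
    if (startsWith(body[i], "MODEL")) {
      midx <- midx + 1L
      body[i] <- sprintf("MODEL     %4d", mids[midx])
    }
  }
  remarks <- sprintf("REMARK ENERGY %d %.6f", mids,
                     ensemble$energies$total_energy)
  writeLines(c(remarks, body), path)
  invisible(path)
}
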