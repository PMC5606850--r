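# Programmatic fixtures; nothing is stored on disk.

# A hand-built bead ensemble: `layout` is a data frame with columns
# chain, resno, resname, atom, element and per-model coordinate columns
# are supplied via the `coords` list (one n_atoms x 3 matrix per model).
make_bead_ensemble <- function(layout, coords, energies = NULL,
                               n_subunits = 6) {
  atoms <- do.call(rbind, lapply(seq_along(coords), function(m) {
    cbind(data.frame(model_id = m), layout,
          data.frame(x = coords[[m]][, 1], y = coords[[m]][, 2],
                     z = coords[[m]][, 3]))
  }))
  en <- data.frame(model_id = seq_along(coords),
                   total_energy = energies %||% seq_along(coords))
  model_ensemble(atoms, en, n_subunits = n_subunits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random sparse pair-energy table with all energies < threshold, plus the
# raw record data frame for oracle consumption.
make_pair_table <- function(n_models = 3, n_subunits = 6,
                            core = c(3, 16, 17, 19, 47, 25, 30),
                            tail = c(97, 99, 100, 102),
                            density = 0.15, seed = 1,
                            energy_range = c(-6, -1.01)) {
  withr::with_seed(seed, {
    grid <- expand.grid(model_id = seq_len(n_models),
                        subunit = seq_len(n_subunits),
                        core_residue = core, tail_residue = tail)
    keep <- runif(nrow(grid)) < density
    rec <- grid[keep, ]
    rec$energy <- runif(nrow(rec), energy_range[1], energy_range[2])
    tab <- pair_energy_table(rec, model_ids = seq_len(n_models),
                             n_subunits = n_subunits)
    list(table = tab, records = rec)
  })
}

# Minimal multi-model PDB text for reader edge-case tests.
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          elem = "C") {
  sprintf("ATOM  %5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, paste0(" ", name), resn, chain, resno, x, y, z, elem)
}

write_toy_pdb <- function(path, n_models = 2, drop_chain_in_model = NULL,
                          remark_energies = TRUE) {
  lines <- character(0)
  if (remark_energies) {
    lines <- c(lines, sprintf("REMARK ENERGY %d %.3f", seq_len(n_models),
                              -10 - seq_len(n_models)))
  }
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (ch in c("A", "B")) {
      if (!is.null(drop_chain_in_model) && m == drop_chain_in_model &&
          ch == "B") next
      lines <- c(lines,
                 pdb_atom_line(1, "CA", "ALA", ch, 1, 1 + m, 2, 3),
                 pdb_atom_line(2, "CA", "GLY", ch, 2, 5 + m, 2, 3))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Cached paired acidic/neutral simulation shared by the property and
# acceptance tests (simulation conditions fixed; run once per session).
.sim_cache <- new.env(parent = emptyenv())

paired_tip_runs <- function(n_seeds = 20, n_models = 3,
                            moves_per_residue = 30) {
  key <- paste("paired", n_seeds, n_models, moves_per_residue, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  spec_acidic <- toy_hexamer_spec()
  spec_neutral <- toy_hexamer_spec(tip_charges = rep(0, 6))
  sel <- toy_selections(spec_acidic)
  run_one <- function(spec, seed) {
    ens <- sample_tail_ensemble(spec, n_models = n_models,
                                moves_per_residue = moves_per_residue,
                                seed = seed)
    tab <- score_ensemble(ens, sel)
    summ <- interaction_summary(tab, sel, B = 100, seed = seed)
    list(summary = summ, delta = delta_eec(summ)$delta_eec)
  }
  out <- lapply(seq_len(n_seeds), function(s) {
    list(acidic = run_one(spec_acidic, seed = 100 + s),
         neutral = run_one(spec_neutral, seed = 100 + s))
  })
  .sim_cache[[key]] <- out
  out
}
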