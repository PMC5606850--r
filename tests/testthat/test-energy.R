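two_residue_conf <- function(r, res_x = "LYS", res_y = "GLU") {
  data.frame(model_id = 1, chain = c("A", "B"), resno = c(10, 90),
             resname = c(res_x, res_y), atom = "CA", element = "C",
             x = c(0, r), y = 0, z = 0)
}

test_that("surrogate energy matches the declared formula", {
  p <- surrogate_params(dielectric_slope = 4, coulomb_k = 332,
                        repulsion_radius = 4)
  # opposite unit charges at 5 A, no overlap: 332 * (-1) / (4 * 25)
  e <- pair_energy_surrogate(two_residue_conf(5), x = 10, y = 90, params = p)
  expect_equal(e, -3.32, tolerance = 1e-12)

  # neutral partner beyond the repulsion radius: exactly zero
  e0 <- pair_energy_surrogate(two_residue_conf(6, res_x = "ALA"),
                              x = 10, y = 90, params = p)
  expect_equal(e0, 0)

  # 1/r^2: doubling the separation quarters the magnitude
  e1 <- pair_energy_surrogate(two_residue_conf(6), 10, 90, params = p)
  e2 <- pair_energy_surrogate(two_residue_conf(12), 10, 90, params = p)
  expect_equal(e2, e1 / 4, tolerance = 1e-12)

  # symmetric in the two residues
  esym <- pair_energy_surrogate(two_residue_conf(5, res_x = "GLU",
                                                 res_y = "LYS"), 10, 90,
                                params = p)
  expect_equal(esym, e)

  expect_error(pair_energy_surrogate(two_residue_conf(5), 10, 91), "91")
})

test_that("like-charged acidic pairs are never favorable", {
  p <- surrogate_params()
  for (r in seq(2, 30, by = 0.5)) {
    e <- pair_energy_surrogate(two_residue_conf(r, res_x = "ASP"),
                               10, 90, params = p)
    if (r >= p$repulsion_radius) expect_gte(e, 0)
    expect_equal(is_favorable(e), 0L)
  }
})

test_that("score_ensemble equals the exhaustive all-pairs oracle", {
  spec <- toy_hexamer_spec()
  sel <- toy_selections(spec)
  p <- surrogate_params()
  ens <- sample_tail_ensemble(spec, n_models = 2, moves_per_residue = 15,
                              seed = 21)
  tab <- score_ensemble(ens, sel, params = p)
  expect_gt(nrow(tab), 0)
  for (m in 1:2) {
    want <- oracle_score_model(as.data.frame(get_conformation(ens, m)),
                               sel, p)
    sub <- tab[tab$model_id == m, ]
    got <- data.frame(subunit = sub$subunit, core_residue = sub$core_residue,
                      tail_residue = sub$tail_residue, energy = sub$energy)
    want <- want[order(want$subunit, want$core_residue, want$tail_residue), ]
    got <- got[order(got$subunit, got$core_residue, got$tail_residue), ]
    rownames(want) <- rownames(got) <- NULL
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("tails pointing away from the core yield an empty table", {
  spec <- toy_hexamer_spec(tip_charges = rep(0, 6))
  sel <- toy_selections(spec)
  ens <- sample_tail_ensemble(spec, n_models = 1, moves_per_residue = 1,
                              seed = 2)
  tab <- score_ensemble(ens, sel)
  expect_equal(nrow(tab), 0)
})

test_that("stretching tails away from the core weakens the interactions", {
  spec <- toy_hexamer_spec()
  sel <- toy_selections(spec)
  ens <- sample_tail_ensemble(spec, n_models = 1, moves_per_residue = 30,
                              seed = 4)
  before <- score_ensemble(ens, sel)
  stretched <- ens
  tail_rows <- stretched$atoms$resno >= 90
  for (col in c("x", "y", "z")) {
    stretched$atoms[[col]][tail_rows] <- stretched$atoms[[col]][tail_rows] * 3
  }
  after <- score_ensemble(stretched, sel)
  # fewer contacts pass the favorability threshold, and the total
  # favorable energy is weaker
  expect_lt(sum(is_favorable(after$energy)), sum(is_favorable(before$energy)))
  expect_gt(sum(after$energy), sum(before$energy))
})

test_that("load_energy_table drops unfavorable rows and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model_id,subunit,core_residue,tail_residue,energy",
               "1,1,16,97,-2.0", "1,1,16,99,-1.5", "1,2,16,97,-3.0",
               "1,3,17,97,0.3", "2,1,16,97,0.0"), f)
  expect_message(tab <- load_energy_table(f), "2 record")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$energy < 0))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model_id,subunit,core_residue,tail_residue,energy",
               "1,1,16,97,-2.0", "1,1,16,97,-2.5"), dup)
  expect_error(load_energy_table(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("model_id,subunit,core_residue,tail_residue,energy", empty)
  expect_equal(nrow(load_energy_table(empty)), 0)
})

test_that("favorability threshold is strict", {
  expect_equal(is_favorable(-2.0), 1L)
  expect_equal(is_favorable(-1.0), 0L)
  expect_equal(is_favorable(-0.5), 0L)
  expect_equal(is_favorable(c(-1.0000001, -0.9999999)), c(1L, 0L))
  expect_equal(is_favorable(-2.5, threshold = -3), 0L)
})
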