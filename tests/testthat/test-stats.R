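tbl_from <- function(rows, model_ids, n_subunits = 6) {
  pair_energy_table(rows, model_ids = model_ids, n_subunits = n_subunits)
}

sel_small <- selection_sets(core = c(16, 17, 25), basic_core = 16,
                            tail = c(97, 99))

test_that("select_low_energy keeps floor(f*M) models, at least one", {
  layout <- data.frame(chain = "A", resno = 1:2, resname = "ALA",
                       atom = "CA", element = "C")
  mk <- function(m, energies) {
    make_bead_ensemble(layout,
                       replicate(m, matrix(seq_len(6), 2), simplify = FALSE),
                       energies = energies)
  }
  withr::with_seed(1, {
    e300 <- mk(300, rnorm(300))
    sub <- select_low_energy(e300, 0.01)
    expect_equal(n_models(sub), 3)
    expect_equal(sort(sub$energies$total_energy),
                 sort(e300$energies$total_energy)[1:3])
  })
  e50 <- mk(50, rnorm(50))
  expect_equal(n_models(select_low_energy(e50, 0.01)), 1)
  # ties broken by ascending model id
  etie <- mk(10, rep(5, 10))
  expect_equal(select_low_energy(etie, 0.25)$energies$model_id, 1:2)
  expect_error(select_low_energy(e50, 0), "fraction")
  expect_error(select_low_energy(e50, 1.5), "fraction")
})

test_that("mean_counts matches the printed-equation normalization", {
  # one model, 6 subunits, residue 16 contacts tail 97 in every subunit
  rows <- data.frame(model_id = 1, subunit = 1:6, core_residue = 16,
                     tail_residue = 97, energy = -2)
  tab <- tbl_from(rows, model_ids = 1)
  mc <- mean_counts(tab, sel_small)
  expect_equal(mc$mean_count[mc$core_residue == 16], 1.0)
  expect_equal(mc$mean_count[mc$core_residue == 17], 0.0)

  # 2 models; qualifies in 2 subunits of model 1 only -> 2/12
  rows2 <- data.frame(model_id = 1, subunit = 1:2, core_residue = 16,
                      tail_residue = 97, energy = -2)
  tab2 <- tbl_from(rows2, model_ids = 1:2)
  expect_equal(mean_counts(tab2, sel_small)$mean_count[1], 2 / 12)

  # two tail partners in one subunit: 2/6 as printed, 1/6 binary
  rows3 <- data.frame(model_id = 1, subunit = 1, core_residue = 16,
                      tail_residue = c(97, 99), energy = -2)
  tab3 <- tbl_from(rows3, model_ids = 1)
  expect_equal(mean_counts(tab3, sel_small)$mean_count[1], 2 / 6)
  expect_equal(mean_counts(tab3, sel_small,
                           count_mode = "binary")$mean_count[1], 1 / 6)
})

test_that("mean_energy averages per-cell sums including zero cells", {
  rows <- data.frame(model_id = 1, subunit = 1:6, core_residue = 16,
                     tail_residue = 97, energy = -2)
  me <- mean_energy(tbl_from(rows, 1), 16)
  expect_equal(me$mean_energy, -2.0)
  expect_equal(me$sd_energy, 0)

  one <- data.frame(model_id = 1, subunit = 1, core_residue = 16,
                    tail_residue = 97, energy = -2)
  me1 <- mean_energy(tbl_from(one, 1), 16)
  expect_equal(me1$mean_energy, -2 / 6)
  # population SD over cells (-2, 0, 0, 0, 0, 0)
  expect_equal(me1$sd_energy, sqrt(mean((c(-2, rep(0, 5)) + 2 / 6)^2)))

  none <- mean_energy(tbl_from(one, 1), 25)
  expect_equal(none$mean_energy, 0)
  expect_equal(none$sd_energy, 0)
})

test_that("statistics equal the enumeration oracle on random tables", {
  for (seed in 1:4) {
    fx <- make_pair_table(n_models = 4, seed = seed)
    sel <- selection_sets(core = c(3, 16, 17, 19, 47, 25, 30),
                          basic_core = c(3, 16, 17, 19, 47),
                          tail = c(97, 99, 100, 102))
    for (x in c(16, 25, 47)) {
      expect_equal(
        mean_counts(fx$table, sel)$mean_count[
          mean_counts(fx$table, sel)$core_residue == x],
        oracle_mean_count(fx$records, x, 1:4, 6),
        info = paste("seed", seed, "residue", x)
      )
      om <- oracle_mean_energy(fx$records, x, 1:4, 6)
      me <- mean_energy(fx$table, x)
      expect_equal(me$mean_energy, om$mean, tolerance = 1e-12)
      expect_equal(me$sd_energy, om$sd, tolerance = 1e-12)
    }
  }
})

test_that("bootstrap SD is deterministic, zero for identical models, and
           close to the analytic standard error", {
  # identical per-model counts -> zero spread
  rows <- data.frame(model_id = rep(1:3, each = 6),
                     subunit = rep(1:6, 3), core_residue = 16,
                     tail_residue = 97, energy = -2)
  tab <- tbl_from(rows, 1:3)
  expect_equal(bootstrap_sd_counts(tab, 16, B = 200, seed = 9), 0)

  # same seed -> identical result
  fx <- make_pair_table(n_models = 10, seed = 3)
  s1 <- bootstrap_sd_counts(fx$table, 16, B = 300, seed = 42)
  s2 <- bootstrap_sd_counts(fx$table, 16, B = 300, seed = 42)
  expect_identical(s1, s2)

  # i.i.d. per-model counts: bootstrap SE ~ sd/sqrt(M) within 15%
  withr::with_seed(7, {
    m <- 50
    per_model <- rpois(m, 4)
    rows <- do.call(rbind, lapply(seq_len(m), function(i) {
      if (per_model[i] == 0) return(NULL)
      data.frame(model_id = i, subunit = 1,
                 core_residue = 16,
                 tail_residue = seq_len(per_model[i]) + 96,
                 energy = -2)
    }))
    tabm <- pair_energy_table(rows, model_ids = seq_len(m), n_subunits = 1)
    sig <- bootstrap_sd_counts(tabm, 16, B = 1000, seed = 5)
    analytic <- sd(per_model) / sqrt(m)
    expect_lt(abs(sig - analytic) / analytic, 0.15)
  })

  # single model: warning and zero
  one <- tbl_from(data.frame(model_id = 1, subunit = 1, core_residue = 16,
                             tail_residue = 97, energy = -2), 1)
  expect_warning(s <- bootstrap_sd_counts(one, 16, B = 100, seed = 1),
                 "single-model")
  expect_equal(s, 0)
})

test_that("eec sums count*energy with independent-error propagation", {
  summ <- data.frame(core_residue = c(1, 2),
                     mean_count = c(0.5, 0.25),
                     sd_count = 0, mean_energy = c(-1, -2), sd_energy = 0)
  out <- eec(summ, c(1, 2))
  expect_equal(out$eec, -1.0)
  expect_equal(out$sd_eec, 0)

  one <- data.frame(core_residue = 1, mean_count = 1, sd_count = 0,
                    mean_energy = -2, sd_energy = 0)
  expect_equal(eec(one, 1)$eec, -2.0)
  expect_equal(eec(one, integer(0))$eec, 0)

  # propagation formula
  s <- data.frame(core_residue = 1, mean_count = 0.4, sd_count = 0.1,
                  mean_energy = -3, sd_energy = 0.5)
  expect_equal(eec(s, 1)$sd_eec,
               sqrt(0.5^2 * 0.1^2 + 0.5^2 * 0.4^2 + 0.1^2 * 3^2))
  expect_error(eec(s, 99), "99")
})

test_that("delta_eec splits on/off target and propagates errors", {
  sel <- selection_sets(core = c(16, 25), basic_core = 16, tail = 97)
  # symmetric contacts on one basic and one non-basic residue
  rows <- data.frame(model_id = 1, subunit = c(1, 1),
                     core_residue = c(16, 25), tail_residue = 97,
                     energy = -2)
  tab <- tbl_from(rows, 1)
  summ <- interaction_summary(tab, sel, B = 50, seed = 1)
  d <- delta_eec(summ)
  expect_equal(d$delta_eec, 0)
  expect_equal(d$eec_on, d$eec_off)
  expect_equal(d$sd_delta_eec, sqrt(d$sd_on^2 + d$sd_off^2))

  # all records on the basic patch: delta = EEC(basic) < 0
  rows_on <- data.frame(model_id = 1, subunit = 1, core_residue = 16,
                        tail_residue = 97, energy = -2)
  summ_on <- interaction_summary(tbl_from(rows_on, 1), sel, B = 50, seed = 1)
  d_on <- delta_eec(summ_on)
  expect_lt(d_on$delta_eec, 0)
  expect_equal(d_on$delta_eec, d_on$eec_on)

  # basic == core -> empty off-target set
  sel_all <- selection_sets(core = 16, basic_core = 16, tail = 97)
  summ_all <- interaction_summary(tbl_from(rows_on, 1), sel_all,
                                  B = 50, seed = 1)
  expect_error(delta_eec(summ_all), "off-target")

  # buried residues can be dropped from the off-target set
  sel3 <- selection_sets(core = c(16, 25, 30), basic_core = 16, tail = 97)
  summ3 <- interaction_summary(tab, sel3, B = 50, seed = 1)
  d3 <- delta_eec(summ3, buried = 25, exclude_buried = TRUE)
  # with residue 25 excluded the off-target EEC vanishes
  expect_equal(d3$eec_off, 0)
  expect_lt(d3$delta_eec, 0)
  # excluding the whole off-target set is an error
  expect_error(delta_eec(summ3, buried = c(25, 30), exclude_buried = TRUE),
               "off-target")
})

test_that("statistics are invariant to model order and subunit labels", {
  fx <- make_pair_table(n_models = 4, seed = 8)
  sel <- selection_sets(core = c(3, 16, 17, 19, 47, 25, 30),
                        basic_core = c(3, 16), tail = c(97, 99, 100, 102))
  base <- interaction_summary(fx$table, sel, B = 100, seed = 2)

  perm <- fx$records
  perm$model_id <- c(4, 3, 2, 1)[perm$model_id]
  perm$subunit <- c(3, 1, 2, 6, 5, 4)[perm$subunit]
  tab_p <- pair_energy_table(perm, model_ids = 1:4, n_subunits = 6)
  perm_summ <- interaction_summary(tab_p, sel, B = 100, seed = 2)
  expect_equal(perm_summ$mean_count, base$mean_count)
  expect_equal(perm_summ$mean_energy, base$mean_energy)
  expect_equal(perm_summ$sd_energy, base$sd_energy)
})

test_that("a more stringent threshold never increases mean counts", {
  fx <- make_pair_table(n_models = 5, seed = 12, energy_range = c(-6, -0.5))
  sel <- selection_sets(core = c(3, 16, 17, 19, 47, 25, 30),
                        basic_core = 3, tail = c(97, 99, 100, 102))
  thresholds <- c(-0.5, -1, -2, -4)
  prev <- NULL
  for (th in thresholds) {
    cur <- mean_counts(fx$table, sel, threshold = th)$mean_count
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("EEC is never positive when all retained energies are favorable", {
  for (seed in 1:5) {
    fx <- make_pair_table(n_models = 3, seed = seed)
    sel <- selection_sets(core = c(3, 16, 17, 19, 47, 25, 30),
                          basic_core = c(3, 16, 17, 19, 47),
                          tail = c(97, 99, 100, 102))
    summ <- interaction_summary(fx$table, sel, B = 50, seed = seed)
    expect_lte(eec(summ, sel$basic_core)$eec, 0)
    expect_lte(eec(summ, sel$core)$eec, 0)
  }
})
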