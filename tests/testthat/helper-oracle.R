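# Independent oracles, written as plain loops so they share no code path
# with the package internals they check.

# Exhaustive enumeration of Eq.-style ensemble statistics from a record
# data frame (columns model_id, subunit, core_residue, tail_residue,
# energy), the full model id set and the subunit count.
oracle_mean_count <- function(records, x, model_ids, n_subunits,
                              threshold = -1, binary = FALSE) {
  mid <- records$model_id
  sub <- records$subunit
  cres <- records$core_residue
  en <- records$energy
  total <- 0
  for (m in model_ids) {
    for (s in seq_len(n_subunits)) {
      hit <- sum(mid == m & sub == s & cres == x & en < threshold)
      total <- total + if (binary) as.integer(hit > 0) else hit
    }
  }
  total / (n_subunits * length(model_ids))
}

oracle_mean_energy <- function(records, x, model_ids, n_subunits,
                               threshold = -1) {
  mid <- records$model_id
  sub <- records$subunit
  cres <- records$core_residue
  en <- records$energy
  cells <- c()
  for (m in model_ids) {
    for (s in seq_len(n_subunits)) {
      pick <- mid == m & sub == s & cres == x & en < threshold
      cells <- c(cells, sum(en[pick]))
    }
  }
  mean_e <- sum(cells) / (n_subunits * length(model_ids))
  list(mean = mean_e,
       sd = sqrt(mean((cells - mean_e)^2)))
}

oracle_eec <- function(records, residues, model_ids, n_subunits,
                       threshold = -1) {
  total <- 0
  for (x in residues) {
    n_x <- oracle_mean_count(records, x, model_ids, n_subunits, threshold)
    e_x <- oracle_mean_energy(records, x, model_ids, n_subunits, threshold)$mean
    total <- total + n_x * e_x
  }
  total
}

# Brute-force accessible surface by sphere-grid integration at high point
# density: latitude/longitude grid (different point construction from the
# package's golden-spiral points).
oracle_sasa <- function(coords, radii, probe = 1.4, n_lat = 100) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    acc <- 0
    wsum <- 0
    for (k in seq_len(n_lat)) {
      th <- pi * (k - 0.5) / n_lat
      n_lon <- max(1, round(2 * n_lat * sin(th)))
      w <- sin(th)
      for (l in seq_len(n_lon)) {
        ph <- 2 * pi * (l - 0.5) / n_lon
        p <- coords[i, ] + R * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
        exposed <- TRUE
        for (j in seq_len(n)) {
          if (j == i) next
          if (sum((p - coords[j, ])^2) < (radii[j] + probe)^2) {
            exposed <- FALSE
            break
          }
        }
        acc <- acc + w * exposed / n_lon
        wsum <- wsum + w / n_lon
      }
    }
    out[i] <- 4 * pi * R^2 * acc / wsum
  }
  out
}

# Brute-force all-pairs surrogate scoring of a conformation: every tail
# site against every chain instance of every core residue number, energies
# summed per (tail-subunit, core-number, tail-number) key.
oracle_score_model <- function(atoms, selections, params) {
  chains <- sort(unique(atoms$chain))
  site_of <- function(ch, rn) {
    a <- atoms[atoms$chain == ch & atoms$resno == rn, ]
    side <- !(a$atom %in% c("N", "CA", "C", "O", "OXT")) & a$element != "H"
    if (any(side)) {
      c(mean(a$x[side]), mean(a$y[side]), mean(a$z[side]))
    } else {
      ca <- a[a$atom == "CA", ]
      c(ca$x, ca$y, ca$z)
    }
  }
  charge_of <- function(ch, rn) {
    rname <- atoms$resname[atoms$chain == ch & atoms$resno == rn][1]
    q <- params$charge_map[rname]
    if (is.na(q)) 0 else unname(q)
  }
  recs <- NULL
  for (s in seq_along(chains)) {
    ch <- chains[s]
    for (yres in selections$tail) {
      if (!any(atoms$chain == ch & atoms$resno == yres)) next
      ysite <- site_of(ch, yres)
      qy <- charge_of(ch, yres)
      for (xres in selections$core) {
        e <- 0
        found <- FALSE
        for (chx in chains) {
          if (!any(atoms$chain == chx & atoms$resno == xres)) next
          found <- TRUE
          xsite <- site_of(chx, xres)
          qx <- charge_of(chx, xres)
          r <- sqrt(sum((xsite - ysite)^2))
          rc <- max(r, params$min_distance)
          coul <- params$coulomb_k * qx * qy / (params$dielectric_slope * rc^2)
          rep <- max(0, params$repulsion_scale *
                       (params$repulsion_radius - r))^2
          e <- e + (coul + rep) * params$energy_unit_scale
        }
        if (found && e < 0) {
          recs <- rbind(recs, data.frame(subunit = s, core_residue = xres,
                                         tail_residue = yres, energy = e))
        }
      }
    }
  }
  recs
}

# Closed-form OLS (textbook formulas) for the linear-fit check.
oracle_ols <- function(x, y) {
  n <- length(x)
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  res <- y - (ic + sl * x)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se_sl <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  tval <- sl / se_sl
  list(slope = sl, intercept = ic, r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
       p_value = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE))
}
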