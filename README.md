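# hfqtail

Quantitative analysis of autoinhibitory disordered tails on the bacterial
RNA chaperone Hfq — for structural bioinformaticians and biochemists
studying how an acidic C-terminal tail (CTD) competes with RNA for the
basic rim of the Sm-core hexamer.

Hfq's rim carries a basic patch (ℬ, e.g. K3/R16/R17/R19/K47 in *E. coli*)
that anneals sRNA·mRNA pairs; each subunit's disordered CTD ends in an
acidic tip (𝒯, D97/E99/E100/E102) tethered right next to it. The package
measures that tug-of-war from three directions:

**Ensemble statistics.** Over a multi-model conformational ensemble, for
each core residue *x*, with δ(x,y) = 1 when the pair energy E(x,y) is
strictly below −1 REU:

- mean contact count ⟨N_x⟩ = Σ_models Σ_subunits Σ_{y∈𝒯} δ(x,y) /
  (N_subunits·N_models), with a bootstrap SD over B = 1000 model resamples;
- mean interaction energy ⟨E_x:𝒯⟩ (same normalization), with a closed-form
  population SD;
- EEC = Σ_{x∈ℬ} ⟨N_x⟩⟨E_x:𝒯⟩, the expected energetic contribution of the
  basic patch, and ΔEEC = EEC(ℬ) − EEC(𝒞∖ℬ), the on-target vs off-target
  specificity (more negative ⇒ the tail targets the basic patch).

**Tether geometry.** The worm-like-chain effective concentration of the
tethered tip, C = 1/((V_tail − V_core)·N_A), with V_tail a sphere set by
the linker reach and V_core the core cylinder (31.5 Å × 25 Å).

**Solution experiments.** Single-site (y = K_a·x/(1+K_a·x)), Hill and
IC50 fits, single/double-exponential annealing kinetics,
ΔΔG° = −RT·ln(K_d^MUT/K_d), K_rel = K_d(P)/K_d(S), and the three-state
deconvolution of endpoint anisotropy into released-duplex / ternary /
binary molar fractions.

A seeded synthetic-data module generates every input with known ground
truth: coarse-grained Monte-Carlo tail-on-hexamer ensembles (with tunable
tip charges) and noisy titration / competition / release / kinetics
datasets.

## Worked example

Sample a toy ensemble with acidic tips, keep the low-energy half, score
tail–core pairs with the documented surrogate potential, and summarise:

```r
library(hfqtail)

spec <- toy_hexamer_spec()                      # acidic tip: -1 at 97/99/100/102
ens  <- sample_tail_ensemble(spec, n_models = 6, moves_per_residue = 30,
                             seed = 42)
sel  <- toy_selections(spec)
tab  <- score_ensemble(select_low_energy(ens, fraction = 0.5), sel)
summ <- interaction_summary(tab, sel, B = 500, seed = 42)
summ
#>    core_residue mean_count sd_count mean_energy sd_energy basic
#> 1             3       3.67   0.0000       -9.42      3.11  TRUE
#> 2            16       3.94   0.0452      -15.12      3.20  TRUE
#> 3            17       3.94   0.0443      -16.36      2.76  TRUE
#> 4            19       3.78   0.0458      -14.74      3.01  TRUE
#> 5            25       0.00   0.0000        0.00      0.00 FALSE
#> ...
delta_eec(summ)
#>   delta_eec sd_delta_eec eec_on sd_on eec_off sd_off
#> 1      -247         26.2   -247  26.2       0      0
```

Every favorable contact lands on the basic patch (residues 3–47 marked
`basic`), so the off-target EEC is zero and ΔEEC is strongly negative —
the acidic tip specifically targets the basic rim. Rerun with
`toy_hexamer_spec(tip_charges = rep(0, 6))` (a neutralized tip) and the
favorable-contact table is empty, ΔEEC = 0.

The tether arithmetic and the experiment-side helpers:

```r
local_concentration(chain_geometry(r_tail = 105))   # full-length tail
#>   r_tail core_radius core_height conc_uM conc_uM_2sig
#> 1    105        31.5          25     348          350

fit_single_site(generate_titration(true_kd = 2.9, noise_sd = 0.03, seed = 42))
#> <binding_fit: single_site>
#>  term estimate std_error conf_low conf_high
#>    Ka   0.3833   0.02606   0.3322    0.4344
#>    Kd   2.6087   0.17735   2.2611    2.9563

krel_table(data.frame(variant = c("Hfq102", "Hfq65", "Hfq-sCTD"),
                      kd_product = c(117, 45.5, 181),
                      kd_substrate = c(15.5, 20.0, 12.9)))$k_rel_display
#> [1]  7.5  2.3 14.0

molar_fractions(anisotropy_phases(r_AP = 0.0732, r_Mdr = 0.0400,
                                  r_Mhdr = 0.2227, r_hd = 0.1332,
                                  K_rel = 7.5))
#>   chi_dr chi_hdr chi_hd
#> 1   0.68  0.0377  0.282
```

The 350 µM effective tip concentration (105 Å reach) rises to ~1220 µM
when the reach drops to 70 Å — shortening the leash triples the local
concentration of the autoinhibitory tip. The last call shows that with a
high K_rel, two-thirds of the duplex product ends up released (χ_dr ≈
0.68) rather than chaperone-bound.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(per-residue bar charts, fit curves); `run_eec_pipeline()` chains the
ensemble stages into a seeded, logged run whose JSON/CSV report is
byte-reproducible.

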