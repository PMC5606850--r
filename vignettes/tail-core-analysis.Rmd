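---
title: "Quantifying autoinhibitory tail–core interactions in Hfq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying autoinhibitory tail–core interactions in Hfq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(hfqtail)
```

## The biological question

Hfq is a bacterial Sm-family RNA chaperone: a homohexameric ring whose
proximal face, distal face and outer rim each bind RNA. An
arginine/lysine-rich *basic patch* on the rim and N-terminal domain (in
*E. coli*: K3, R16, R17, R19, K47) grips RNA backbones and is essential for
annealing sRNAs to their mRNA targets. Each subunit also carries an
intrinsically disordered C-terminal domain (CTD) ending in an acidic tip
(D97, E99, E100, E102 in *E. coli*). Because the tip is tethered next to the
rim, it can fold back and occupy the basic patch, competing with RNA —
an autoinhibitory circuit that helps the chaperone release annealed duplex
product and discriminate against non-specific RNA.

hfqtail provides the quantitative machinery for studying this circuit:

1. ensemble statistics that measure how often and how strongly tail
   residues contact each core residue across a conformational ensemble;
2. a worm-like-chain estimate of the effective concentration of the
   tethered tip;
3. the binding/competition/kinetics formulas used to analyse the
   corresponding solution experiments; and
4. seeded synthetic-data generators so every estimator can be exercised
   against known ground truth.

## Ensemble interaction statistics

The input is a multi-model ensemble of hexamer conformations (standard
MODEL/ENDMDL PDB, read with `read_ensemble()`), each with a total energy in
Rosetta-energy-like units (REU), supplied as `REMARK ENERGY` lines or a
sidecar table. Analysis restricts to the lowest-energy fraction of models
(`select_low_energy()`, default 1%, ties broken by model id).

For a core residue $x \in \mathcal{C}$ and tail residues
$y \in \mathcal{T}$, a pairwise energy $E(x,y)$ is *favorable* when it is
strictly below a threshold (default $-1$ REU; `is_favorable()`), giving the
indicator $\delta(x,y)$. Three statistics follow:

* **Mean contact count** $\langle N_x \rangle$: the number of favorable
  $(\text{model}, \text{subunit}, y)$ pairings divided by
  $N_{\rm subunits} N_{\rm models}$ (`mean_counts()`).
* **Mean interaction energy** $\langle E_{x:\mathcal{T}} \rangle$: the sum
  of favorable energies divided by the same normalization; its spread
  $\sigma_E$ is the population standard deviation of the per-(model,
  subunit) summed energies, cells without contacts included as zeros
  (`mean_energy()`). No resampling is involved: the energy varies within
  a fixed model set, whereas the presence of a contact only varies when
  models are resampled.
* **Count uncertainty** $\sigma_N$: the standard deviation of
  $\langle N_x \rangle$ recomputed over $B = 1000$ bootstrap resamples of
  the model set (`bootstrap_sd_counts()`). The replicate stream for each
  residue is derived deterministically from the seed and the residue
  number, so results do not depend on evaluation order.

The **expected energetic contribution** over a residue set, typically the
basic patch $\mathcal{B}$, is

$$\mathrm{EEC} = \sum_{x \in \mathcal{B}} \langle N_x \rangle
  \langle E_{x:\mathcal{T}} \rangle,$$

with per-residue variance
$\sigma_E^2\sigma_N^2 + \sigma_E^2\langle N\rangle^2 +
 \sigma_N^2\langle E\rangle^2$ under independence, summed across residues
(also treated as independent — a consistent extension of the same
assumption). The specificity of tail docking is the difference
$\Delta\mathrm{EEC} = \mathrm{EEC}(\mathcal{B}) -
\mathrm{EEC}(\mathcal{C}\setminus\mathcal{B})$ between on-target and
off-target contacts; more negative means the tail prefers the basic patch.

Two deliberate design choices here were genuinely open:

* **Count mode.** The count definition above sums over tail residues, so a
  core residue touching two tail residues in one subunit counts twice. An
  alternative reading — "interacts with at least one tail residue" — is
  binary per (model, subunit). Both are implemented
  (`count_mode = "as-printed"` vs `"binary"`); the summed form is the
  default because the equation-level definition outranks a caption-level
  paraphrase. Both are verified against exhaustive enumeration.
* **Off-target normalization.** $\mathcal{C}\setminus\mathcal{B}$ has many
  more residues than $\mathcal{B}$. The off-target EEC is a plain sum, not
  rescaled by set size; reports carry both set sizes so users can
  normalize downstream if they prefer. Buried core residues
  (`flag_buried()`, see below) can optionally be excluded from the
  off-target set (`exclude_buried`), since a residue with no exposed
  surface cannot make tail contacts; both modes are available because the
  choice is not forced by anything in the statistics.

Residue selections for five species (in *E. coli* numbering) ship in a
config read by `load_selections()`. In the *S. aureus* row, residue 65
belongs to the acidic tail, so its core role is truncated at residue 64 —
the core and tail sets must be disjoint for the on/off-target split to be
well defined.

## The surrogate pair potential

Full-atom forcefield scoring of residue pairs is outside this package's
scope. What the analysis actually needs is a documented potential that
preserves the electrostatic logic under test: an acidic tip attracted to a
basic patch, indifferent to neutral surfaces, repelled by like charges.
`surrogate_params()` declares a two-term potential between side-chain
charge centers (mean of side-chain heavy atoms; the alpha carbon for
glycine and for bead models):

$$E(r) = \frac{k\, q_1 q_2}{s\, r^2} + \max\!\big(0,\ c\,(r_{\rm rep} - r)\big)^2$$

with $k = 332$ kcal·Å/mol (the Coulomb constant in these units), a
distance-dependent dielectric of slope $s = 4$, soft-sphere repulsion
starting at $r_{\rm rep} = 4$ Å with steepness $c = 2$, and formal charges
$-1$ for Asp/Glu and $+1$ for Arg/Lys. The Coulomb distance is clamped
below 2 Å so the potential is bounded (the bare $1/r^2$ form diverges at
contact, which would break Metropolis sampling); above 2 Å the formula is
exact as written. An opposite-charge pair then has its minimum of about
$-5.8$ REU near 3.5 Å, scores $-5$ to $-2$ REU across salt-bridge
separations, and crosses the $-1$ REU favorability threshold near 9 Å.
Like-charge pairs are never favorable at any separation beyond the
repulsion radius.

When scoring an ensemble (`score_ensemble()`), a tail residue is attributed
to the subunit whose chain carries it — tails are long enough to reach
neighboring subunits — while the core residue is recorded by residue
identity, its energy summed over the six chain instances. The $1/r^2$
decay makes all but the nearest instance negligible, and the identity-level
bookkeeping is what the per-residue statistics aggregate anyway. Records
with $E \ge 0$ are excluded at construction, and externally computed pair
tables (e.g. from a full-atom scorer) enter through `load_energy_table()`
under the same rule.

## Solvent accessibility

Buried-residue flagging uses a Shrake–Rupley accessible surface
(`residue_sasa()`): each atom's sphere of radius $r_{\rm vdW} + 1.4$ Å is
sampled at 960 deterministic test points (golden-spiral construction), a
point counting as exposed when outside every neighbor's expanded sphere.
The calculation is run on one representative low-energy model with tail
residues removed, because the flag concerns *core* exposure — whether the
disordered tails happen to cover a residue in one snapshot is irrelevant
to whether it could ever be a tail target. Residues appearing on all six
chains are averaged per residue number. Areas are deterministic for a
fixed point count, rotation-invariant to within the point discretization
(~1%), and checked in the tests against an independent dense latitude–
longitude integration at 10× density. The default burial cutoff is
2.0 Å², applied strictly.

## Effective concentration of the tethered tip

The disordered linker is modeled as a worm-like chain with a statistical
segment of 35 Å per 10 residues (twice the 15–20 Å persistence length of a
random-coil polypeptide). The linker is taken to start at residue 71 —
the first CTD residues pack along the core as part of the Sm fold — and
the last five residues form the acidic tip. The tip then explores a
sphere of radius $r_{\rm tail}$ around the hexamer center, minus the core
cylinder (radius 31.5 Å, height 25 Å), giving an effective concentration

$$C = \frac{1}{(V_{\rm tail} - V_{\rm core})\, N_A}.$$

`local_concentration(chain_geometry(105))` gives 348 µM per tail
(displayed as 350 µM at two significant figures) for the full-length
protein; shortening the linker to a 70 Å reach gives 1222 µM — a
roughly 3.5-fold increase from deleting eleven linker residues, which is
the quantitative heart of the "shorter leash, stronger autoinhibition"
prediction. The radii are inputs, not outputs: `chain_reach()` shows the
segment arithmetic that makes 105 Å (three segments) and 70 Å (two)
plausible for the two constructs, but does not derive them.

## Binding, competition and kinetics

The solution-side mathematics lives in plain fitters, all
trust-region nonlinear least squares (via minpack.lm) with a coarse
multi-start grid fallback, Jacobian-based confidence intervals and
relative parameter tolerances near machine precision. Each returns a
`binding_fit` with `tidy()`/`glance()`/`predict()`/`autoplot()` methods:

* `fit_single_site()`: $y = K_a x / (1 + K_a x)$, reporting both $K_a$ and
  $K_d = 1/K_a$ (delta-method error) in the dataset's recorded
  concentration unit *and basis* — published constants mix "per monomer"
  and "per hexamer" conventions, so `titration_data()` refuses to let the
  basis stay implicit.
* `fit_hill()`: $y = x^n/(K_d^n + x^n)$; reduces exactly to the
  single-site form at $n = 1$ (`fix_n = 1`). The half-maximal point is
  $x = K_d$ for any $n$.
* `fit_ic50()`: $y = \min Y + (\max Y - \min Y)/(1 + (x/\mathrm{IC}_{50})^n)$
  for probe-displacement curves; monotonically rising data are rejected
  rather than fit.
* `fit_exponential()`: single or double exponential progress curves; for
  double fits the larger-amplitude rate is reported as $k_{\rm obs}$.
* `linear_fit()`: OLS with adjusted $R^2 = 1-(1-R^2)(n-1)/(n-2)$ and the
  two-sided slope t-test, for relating in-silico per-residue energetics to
  measured binding perturbations.

Derived quantities: $\Delta\Delta G^\circ = -RT\ln(K_d^{\rm MUT}/K_d)$
with $R = 1.987\times10^{-3}$ kcal/(mol·K) and $T = 303.15$ K by default
(30 °C assays); relative affinity $K_{\rm rel} = K_d(P)/K_d(S)$
(`compute_krel()`, conventionally displayed at one decimal); relative rate
$k_{\rm rel} = k_{\rm obs}^{\rm MUT}/k_{\rm obs}^{\rm WT}$.

### Three-state anisotropy deconvolution

At the end of an annealing-and-release experiment the probe's anisotropy
$r_{AP}$ is a mixture over released duplex, ternary complex and binary
complex:

$$r_{AP} = \chi_{dr} r_{Mdr} + \chi_{hdr} r_{Mhdr} + \chi_{hd} r_{hd},$$

with $\chi_{dr} + \chi_{hdr} + \chi_{hd} = 1$ and
$\chi_{hd} = K_{\rm rel}\,\chi_{hdr}$. Solving the linear system gives

$$\chi_{hdr} = \frac{r_{AP} - r_{Mdr}}
  {r_{Mhdr} + K_{\rm rel}\, r_{hd} - (1 + K_{\rm rel})\, r_{Mdr}}.$$

Two notes on this implementation. First, the denominator is the algebraic
consequence of the mixture equation plus the two constraints; printed
variants of this expression circulate with ambiguous grouping, and the
derived form is the one that conserves mass exactly and reproduces the
expected release ordering on published endpoint parameters. Second, the
binary-complex anisotropy entering the mixture is the phase-specific
$r_{hd}$ (the binary complex as it exists at the annealing-phase
endpoint), not the equilibrium maximum $r_{Mhd}$, which is carried in
`anisotropy_phases()` for reporting only. Fractions outside $[0,1]$ warn
rather than error — they indicate mutually inconsistent inputs, which the
user should see, not a numerical failure. A near-zero denominator
(parameters that cannot distinguish the states) is an error.

## The synthetic-data generators

Every estimator is exercised against data with known ground truth:

* `sample_tail_ensemble()` builds a coarse-grained stand-in for a
  disordered-tail modeling run: a six-fold symmetric ring of beads with a
  +1 basic patch at the rim (numbered 3/16/17/19/47 to match the shipped
  selections) and neutral core beads deeper in the ring, plus one
  freely-jointed bead tail per subunit (default 13 residues, 90–102, with
  charges $-1$ at 97/99/100/102), equilibrated by Metropolis pivot moves
  under the same surrogate potential used for scoring, at $k_BT = 1$ REU
  with 50 attempted moves per disordered residue by default. Per-model
  total energies are recorded, and ensembles serialize to multi-model PDB
  with matching residue numbering, so the full read → score → summarise
  path is exercised end to end. Setting the tip charges to zero produces
  the matched "neutralized tip" control: under the surrogate potential a
  neutral tip can never form a favorable contact, so its
  $\Delta\mathrm{EEC}$ is exactly zero, and the acidic/neutral contrast
  is a pure function of the tip charges — the property the ensemble
  statistics are supposed to detect.
* `generate_titration()`, `generate_competition()` and
  `generate_progress_curve()` draw from the exact model curves plus
  homoscedastic Gaussian noise (matching the duplicate-SD style of real
  error bars without overclaiming a noise model).
* `generate_release_timecourse()` builds the endpoint anisotropy implied
  by chosen molar fractions, with $K_{\rm rel}$ set consistently, so the
  deconvolution recovers the fractions to machine precision at zero
  noise.

All generators are pure functions of their parameters and seed.

What the toy sampler deliberately does *not* model: excluded volume
between tail beads, tail–tail interactions, backbone geometry beyond a
fixed bond length, solvation, or any sequence specificity beyond formal
charge. Passing tests on synthetic ensembles therefore demonstrate that
the *statistics* are computed correctly and respond to a known contact
bias — not that the toy ensembles resemble real Hfq conformational
distributions, which require full-atom modeling at far larger scale.

## Numerical choices and problem sizes

* Low-energy selection keeps $\max(1, \lfloor f M \rfloor)$ models, ties
  by ascending model id.
* Bootstrap uses $B = 1000$ by default; tests use $B$ of 50–1000 as
  appropriate to the check.
* The test suite validates the ensemble statistics by exhaustive
  enumeration on tables of up to 5 models × 6 subunits; parameter-recovery
  studies use 100–200 seeded noisy replicates per fitter; the
  acidic-versus-neutral contrast uses 20 paired seeds of 3-model
  ensembles at 30 moves per residue. These sizes were chosen so the whole
  suite exercises every claim at desk scale; the statistics themselves
  are independent of ensemble size beyond the usual $1/\sqrt{M}$
  uncertainty scaling.
* Nonlinear fits start from data-derived heuristics (half-maximal point,
  63% rise time) and fall back to a log-spaced multi-start grid; a fit
  that still fails raises an error with the optimizer's diagnostics
  rather than returning a silent estimate. Constant-signal inputs are
  rejected before fitting.
* All reports embed their settings and seed; JSON payloads of identical
  runs are byte-identical.

## Known limitations

* The surrogate potential is electrostatics-plus-repulsion only; its REU
  scale is calibrated by construction, not fitted to a forcefield, so
  absolute EEC values from surrogate-scored ensembles are comparable
  within this package but not to full-atom pipelines. Externally scored
  pair tables bypass this limitation via `load_energy_table()`.
* Published ensemble-scale results in this problem domain rest on tens of
  thousands of full-atom models; desk-scale toy ensembles reproduce the
  qualitative contrasts (sign and ordering), not those printed values.
* The worm-like-chain concentration treats the accessible region as a
  clean sphere minus a cylinder; real excluded volume is rougher, so the
  µM values are order-of-magnitude estimates — which is how they should
  be used.
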