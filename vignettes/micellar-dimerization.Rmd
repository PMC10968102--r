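---
title: "Methods: peptide dimerization thermodynamics in detergent micelles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide dimerization thermodynamics in detergent micelles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptidimer)
```

# The problem

Cationic β-hairpin antimicrobial peptides bound to detergent micelles often
exist as a mixture of monomer and non-covalent dimer. When the two species
exchange slowly on the NMR timescale, an isolated reporter resonance — here
the Trp indole Hε1 proton, which sits in an otherwise empty region of the 1D
¹H spectrum and is insensitive to the *cis/trans* isomerization of an
N-terminal Xaa–Pro bond — shows separate lines for monomer and dimer. Their
integrals are proportional to the number of peptide *chains* in each state
(one reporter proton per chain), so a titration with detergent, or a
temperature series, maps out the dimerization equilibrium. `peptidimer` turns
such series into standard-state free energies, enthalpies and entropies.

# The micellar-solvent model

Dimerization in micelles is not a simple two-state reaction in water: the
monomer- and dimer-bearing micelles carry different numbers of detergent
molecules, so detergent participates in the reaction stoichiometry. With
aggregation numbers $N_m$ (micelle with a monomer), $N_d$ (with a dimer) and
$N_e$ (empty), the dissociation of one dimer into two monomers consumes
$2N_m - N_d$ detergent molecules, i.e. $\gamma = (2N_m - N_d)/N_e$ empty
micelles. The equilibrium dissociation constant is written

$$K_d = \frac{[M]^2}{[D]\,[Det_E]^{\gamma}}, \qquad
[Det_E] = [Det_0] - N_m [M] - N_d [D] - CMC,$$

where $[Det_E]$ is the detergent in empty micelles: the total pool minus what
the peptide-bearing micelles hold and minus the free (pre-micellar) detergent
at the critical micelle concentration. At the conventional standard state
$[Det_0] = 1\,\mathrm{M}$ this reduces to $K_d^{std} = [M]^2/[D]$, which makes
free energies $\Delta G = RT\ln K_d$ comparable across detergent
concentrations and across systems. We use
$R = 1.98720\times10^{-3}$ kcal/(mol K) and report all energies in kcal/mol.

Two readings of the typeset equilibrium expression are possible
($[Det_E]^\gamma$ multiplying $[M]^2/[D]$ or dividing it). Only the dividing
form makes the dimer *dissociate* as detergent is added — each added empty
micelle offers the monomers somewhere else to live — which is the observed
behaviour; the package implements that form throughout.

## Forward solver

`solve_equilibrium()` finds the chain dimer fraction
$f = 2[D]/P_0 \in (0,1)$ satisfying the model at given $(K_d^{std}, P_0,
Det_0)$. The log-residual

$$g(f) = 2\ln[(1-f)P_0] - \ln(fP_0/2) - \gamma\ln[Det_E(f)] - \ln K_d$$

is strictly decreasing on the feasible interval (for $\gamma > 0$), running
from $+\infty$ to $-\infty$, so the root is unique. $Det_E(f)$ is linear in
$f$ and may be negative at small $f$ (all-monomer states can demand more
detergent than the pool holds); the solver restricts the bracket to the
sub-interval where $Det_E > 0$ and then applies a bisection-safeguarded
Newton iteration, vectorised over conditions, converging to
$|g| < 10^{-12}$. An independent dense-grid-scan oracle in the test suite
confirms $|\Delta f| < 10^{-5}$ over random parameter draws, and every
returned state satisfies the peptide and detergent mass balances exactly.

## Inverse problem (titration fit)

`fit_titration()` performs weighted nonlinear least squares of observed
dimer fractions over $(\log K_d^{std}, N_m, N_d)$ with $N_e$ and the CMC
fixed (defaults 55 and 1.5 mM, appropriate for DPC). Bounds are
$K_d^{std} \in [10^{-8}, 10^2]$, $N_m, N_d \in [10, 200]$; optimization is
L-BFGS-B from five fixed Latin-hypercube starts plus a heuristic start
(micelles assumed barely perturbed, $N_m \approx N_e$), with a final polish
at tight tolerance. $\gamma$ is always derived, never fit. Standard errors
come from the numerical Jacobian at the optimum,
$\mathrm{cov} = s^2 (J^TWJ)^{-1}$. Weights are $1/\sigma_f^2$ when
per-point uncertainties are supplied, otherwise the fit is unweighted; both
modes are available because published analyses rarely state which was used.
A titration should span at least a 4-fold detergent range (warned
otherwise) and must be at a single temperature.

With only ~8 points, $(K_d, N_m, N_d)$ are correlated; recovered $N_m, N_d$
individually scatter by a few units at $\sigma_f = 0.02$, while the derived
$\Delta G$ is robust (recovered to better than 0.2 kcal/mol in the mean over
100 replicates — the quantity the acceptance suite checks).

# van't Hoff decomposition

With no measurable heat-capacity change, $\Delta G(T) = \Delta H - T\Delta S$
is linear. `vant_hoff_fit()` is a weighted linear regression of $\Delta G$
on $T$ (intercept $\Delta H$, slope $-\Delta S$); regressing $\ln K$ on
$1/T$ would be the classical alternative, but the direct linear form is the
analysis path here and is exact under the same assumption. Entropies are
kept in kcal/(mol K) internally and also reported in cal/(mol K), the
conventional printing unit. `curvature_check()` refits with a quadratic term
in centred temperature and reports its t-test p-value: p > 0.05 is taken as
"linear", i.e. $\Delta C_p \approx 0$. For converting a temperature series
of populations into $\Delta G(T)$, the aggregation numbers are *frozen*
(typically at the titration-fit values) rather than refit per temperature —
with one observation per temperature a per-point refit would be
underdetermined; `cmd_thermo()` exposes the frozen values as arguments.

`hbond_estimate()` divides $|\Delta G|$ by 0.5 kcal/mol — the canonical
per-residue (per hydrogen bond) free-energy gain for β-sheet formation in a
membrane environment — and rounds to the nearest integer (round-half-even,
the R default; the estimate is approximate by construction, e.g.
$\Delta G = -3.0$ kcal/mol gives six intermonomer hydrogen bonds).

# Line-shape analysis

`fit_components()` models a spectral region as a sum of Lorentzians
$L(\nu) = (A/\pi)\,h/[(\nu-\nu_0)^2 + h^2]$, $h = \mathrm{FWHM}/2$, plus a
linear baseline. Centres and log-widths are the nonlinear parameters
(L-BFGS-B under bounds: centres inside the region, widths in 0.5–100 Hz,
followed by a Nelder–Mead polish); areas and baseline coefficients are
profiled out by linear least squares at every step (variable projection).
This makes the fit exact on noiseless model data and fast. Because areas are
physical, candidate solutions whose components cancel (large negative and
positive areas) are penalised in proportion to their negative-area fraction.
Initialization is by local-maxima picking with a 0.025 ppm merge radius, so
noise riding on a line's flanks is not mistaken for a component.

The assumptions: the reporter region is free of overlapping signals, the
baseline is at most linear, and lines are purely Lorentzian. Under the last
assumption $T_2 = 1/(\pi\,\mathrm{FWHM})$, and `relaxation_correct()`
multiplies each area by $\exp(t_{ws}/T_2)$ to undo the differential decay
accrued during a water-suppression element of duration $t_{ws}$ — broader
(dimer) lines decay faster and are scaled up more. The delay is not usually
published; it is a required parameter defaulting to 0 (correction off), and
the synthetic generator records the value it used.

`assign_peaks()` labels peaks by proximity (±0.03 ppm) to user-supplied
reference shifts; where several peaks fall in one window the largest area is
taken as the principal (*trans*) form and the rest as *cis* satellites,
matching the ~10 % minor population from Xaa–Pro isomerization.
`populations()` excludes *cis* satellites from the monomer/dimer balance by
default (they are reported separately as `f_minor`); an `include_cis`
switch adds them to their parent species, since published analyses do not
always state the convention.

`exchange_regime()` is a deliberately simple heuristic for excluding
pre-micellar points: a single resonance between the aqueous and bound
reference shifts means fast exchange, resolved peaks at the bound shifts
mean slow exchange. Near-complete binding (bound fraction ≳ 0.95) pushes the
averaged fast-exchange peak to within the assignment window of the bound
shift, where the classifier can no longer distinguish the regimes; such
points also carry no usable population information, so this limitation is
immaterial to the fits.

# Synthetic data: what it emulates, what it does not

The generators state one world and keep it fixed: a 0.14 mM peptide sample,
DPC-like micelles ($N_e = 55$, CMC = 1.5 mM), fitted aggregation numbers
$N_m = 56$, $N_d = 59$, and generating thermodynamics
$\Delta H = -8.88$ kcal/mol, $\Delta S = -19.0$ cal/(mol K) (hence
$\Delta G(30\,°C) \approx -3.1$ kcal/mol). Titrations default to eight D:P
ratios from 50:1 to 400:1 at 30 °C; temperature series to ten points over
5–50 °C at D:P 400:1. Spectra carry monomer/dimer lines (10 and 18 Hz wide
at 600 MHz — plausible placeholders, recorded in the config), 10 % *cis*
satellites offset by −0.08 ppm, optional water-suppression decay, and
additive i.i.d. Gaussian noise. Population-level simulators
(`simulate_titration_points()`, `simulate_temperature_points()`) apply
Gaussian noise $\sigma_f = 0.02$ directly to dimer fractions, which is the
input contract of the fitting stage and the basis of the stochastic
acceptance checks.

The low-detergent fast-exchange regime is modelled with a simple
water/micelle partition constant (3500 M⁻¹ of micellar detergent) chosen so
binding completes near D:P 50:1; this is generator plumbing, not a claim
about any real binding curve. Not emulated: time-domain effects
(apodization, phase), t₁ noise, baseline roll, solvent artifacts,
field-dependent exchange broadening, higher-order oligomers, and anionic
detergent electrostatics. A green end-to-end test therefore establishes that
the pipeline inverts its own stated model at realistic noise levels — not
that the model is correct for any particular experimental system.

# Descriptors and composite correlations

Sequence descriptors are composition-based: GRAVY (mean Kyte–Doolittle
hydropathy), AROM (fraction of F/W/Y, His excluded, the ProtParam
convention), formal charge at neutral pH (Arg/Lys +1, His 0, Asp/Glu −1,
+1 free N-terminal amine, −1 free C-terminal carboxyl — a convention that
reproduces the known +5 of capitellacin and is overridable via the termini
annotations), nitrogen counts, and mono/average masses (disulfides −2H
each; uniform ¹⁵N labelling adds the isotope shift per nitrogen). Literature
"theoretical" masses often leave the mono/average convention unstated, so
the package computes both and the tests assert agreement only to 1 Da.
Surface descriptors (S_lip, S_tot, MHP) are never computed here — they come
from external structure-based tools and enter only as table columns.

Minimal hemolytic concentrations reported as bounds (">128 µM") are replaced
by a fixed surrogate (150 µM) before log-transformation, mirroring the
simple censoring convention of comparative AMP studies; no survival-style
censoring model is attempted.

`optimize_composite()` maximizes the squared Pearson correlation of a linear
descriptor combination with a target. Since $R^2$ is scale- and
shift-invariant, one coefficient is anchored to remove the degeneracy, and
the rest are searched by Nelder–Mead (Brent in 1-D) from multiple starts.
One start comes from the ordinary-least-squares regression of the target on
all descriptor columns — the closed-form maximizer of $R^2$ over
unconstrained linear combinations — which guarantees the search never
returns less than the best single-descriptor correlation. p-values use the
exact t-distribution of the Pearson r under normality; the test suite
cross-checks them against a permutation null.

# Numerical choices and degenerate inputs

* Equilibrium solver: tolerance $10^{-12}$ on the log-residual; brackets
  clipped to $[10^{-12}, 1-10^{-12}]$; explicit errors for "no micelles"
  (det0 ≤ CMC) and "insufficient micellar detergent" (empty-micelle pool
  exhausted over the whole feasible branch).
* $\gamma \le 0$ (i.e. $N_d \ge 2N_m$): the system constructor warns — the
  detergent-release picture is then meaningless, though the algebra still
  evaluates.
* Titration fit: parameters pinned at bounds produce a warning;
  non-convergence from all starts is an error carrying the residual value.
* Line-shape fit: needs ≥ 10 samples per component; more requested
  components than resolvable maxima triggers a warning and the extra
  components are seeded across the region.
* Curvature check on an exact line: the quadratic coefficient is ~0 and its
  p-value is reported as 1 when the residual variance collapses.
* Temperatures are converted as K = °C + 273.15 everywhere; tables use
  mM / °C, internals use M / K.

# Known limitations

* The standard errors of the titration fit are asymptotic (Jacobian-based);
  bootstrap errors can be obtained by refitting resampled points but are not
  built in.
* The exchange-regime classifier is heuristic and intended only to exclude
  pre-micellar points, not to analyse intermediate exchange.
* Composite-descriptor optimization with an anchored coefficient cannot
  reach combinations in which the anchor descriptor has a true coefficient
  of the opposite sign to its anchor value; re-anchor on a different term in
  that case.
* The packaged non-capitellacin sequences are convenience fixtures from the
  external literature (marked as such in the FASTA headers) and should not
  be treated as curated reference data.
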