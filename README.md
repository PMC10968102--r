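# peptidimer

Quantitative analysis of β-hairpin antimicrobial-peptide (AMP) dimerization in
detergent micelles, as monitored by 1D ¹H NMR.

Many β-hairpin AMPs (protegrins, arenicins, capitellacin, …) form non-covalent
dimers in membrane-mimicking micelles. When a single isolated reporter
resonance is available — typically the Trp indole Hε1 proton — the
monomer/dimer balance can be read directly from the spectrum: in slow exchange
the two species give separate Lorentzian lines whose integrals are
proportional to the number of peptide chains in each state. `peptidimer`
implements the full pipeline from spectral traces to thermodynamic parameters:

1. **Line-shape decomposition** — fit a spectral region as a sum of
   Lorentzians plus a linear baseline (`fit_components()`), correct integrals
   for transverse relaxation during water suppression
   (`relaxation_correct()`, T₂ = 1/(π·FWHM)), and convert assigned areas into
   chain populations (`populations()`), with minor *cis*-proline satellite
   signals (~10 %) handled separately.
2. **Micellar-solvent equilibrium model** — the dimer dissociation constant

       Kd = [M]² / ([D] · [DetE]^γ),   [DetE] = [Det0] − Nm·[M] − Nd·[D] − CMC,
       γ  = (2·Nm − Nd) / Ne

   where Nm, Nd, Ne are detergent aggregation numbers of monomer-bearing,
   dimer-bearing and empty micelles and γ is the apparent reaction order with
   respect to detergent. At the standard state [Det0] = 1 M, Kd_std = [M]²/[D].
   `solve_equilibrium()` computes species concentrations; `fit_titration()`
   inverts a detergent titration for (Kd_std, Nm, Nd); `delta_g()` gives
   ΔG = R·T·ln Kd.
3. **van't Hoff decomposition** — `vant_hoff_fit()` fits ΔG(T) = ΔH − T·ΔS
   (valid when ΔCp ≈ 0, which `curvature_check()` verifies), and
   `hbond_estimate()` converts ΔG into an approximate number of intermonomer
   hydrogen bonds at ~0.5 kcal/mol per bond.
4. **Sequence descriptors** — Kyte–Doolittle GRAVY, aromatic content,
   formal charge, nitrogen counts, mono/average masses from annotated FASTA
   (`read_fasta()`, `peptide_descriptors()`), censored minimal-hemolytic-
   concentration handling (`censor_mhc()`), and composite descriptor–activity
   correlation (`pearson_fit()`, `optimize_composite()`).
5. **Synthetic data** — seeded generators for titration/temperature spectral
   series and descriptor datasets with recorded ground truth
   (`generate_titration_series()`, `simulate_temperature_points()`, …), so the
   whole pipeline is testable offline.

## Worked example

```r
library(peptidimer)

## the 20-residue, doubly disulfide-bonded hairpin capitellacin
cap <- peptide_sequence("SPRVCIRVCRNGVCYRRCWG", id = "capitellacin",
                        disulfide_pairs = list(c(5, 18), c(9, 14)))
peptide_descriptors(cap)
#>     peptide_id length  gravy arom charge n_nitrogen mass_mono mass_avg
#> 1 capitellacin     20 -0.215  0.1      5         37  2378.124 2379.826

## micellar-solvent model with the fitted DPC aggregation numbers
sys <- micelle_system(Nm = 56, Nd = 59, Ne = 55, CMC = 1.5e-3)
gamma_order(sys)                    # 0.9636364  (apparent reaction order)

kd <- kd_from_delta_g(-3.0, 303.15) # Kd_std for dG = -3.0 kcal/mol at 30 C
st <- solve_equilibrium(equilibrium_params(kd, sys), p0 = 1.4e-4, det0 = 9.8e-3)
st$f_dimer                          # 0.734: ~73% dimer at D:P = 70:1

## invert a noisy synthetic titration (8 points, D:P 50-400, 30 C)
cfg <- generator_config(sigma_f = 0.01)
fit <- fit_titration(simulate_titration_points(cfg, seed = 1))
fit
#> <titration_fit>
#>   n = 8 points, RSS = 4.38
#>   kd_std  = 0.00553815 +/- 0.000914
#>   Nm      = 55.087 +/- 1.3
#>   Nd      = 57.045 +/- 4.17
#>   gamma  = 0.9660 (derived)
#>   dG(303.15 K) = -3.130 kcal/mol

## van't Hoff decomposition of a temperature series (D:P 400:1, 5-50 C)
vh <- vant_hoff_fit(points_to_delta_g(simulate_temperature_points(cfg, seed = 1), sys))
vh
#> <thermo_params>
#>   dH = -8.761 +/- 0.193 kcal/mol
#>   dS = -0.0186 +/- 0.0006 kcal/(mol K)  [-18.6 cal/(mol K)]
#>   valid T range: 278.15 - 323.15 K (n = 10)
hbond_estimate(predict_delta_g(vh, 303.15))   # 6 intermonomer H-bonds
```

The recovered values match the generating truth (ΔH = −8.88 kcal/mol,
ΔS = −19.0 cal/(mol K), Nm = 56, Nd = 59) within the noise: a favourable,
enthalpy-driven dimerization whose ΔG(30 °C) ≈ −3 kcal/mol corresponds to
about six intermonomer hydrogen bonds.

## Command line

```sh
Rscript inst/cli/peptidimer-cli.R simulate --out runs/sim --mode titration --seed 1
Rscript inst/cli/peptidimer-cli.R fit-lineshape --spectra runs/sim --out runs/populations.csv
Rscript inst/cli/peptidimer-cli.R thermo --populations runs/populations.csv --mode titration
Rscript inst/cli/peptidimer-cli.R descriptors --fasta inst/extdata/amp_peptides.fasta \
    --table inst/extdata/amp_activity.csv
```

## Vignette

See `vignettes/micellar-dimerization.Rmd` for the model, its assumptions, the
synthetic-data design and the numerical choices.
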