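# glymadc

Region-wise apparent diffusion coefficient (ADC) estimation for a
cerebrospinal-fluid (CSF) tracer from sparse concentration snapshots, by
PDE-constrained optimization.

## The problem

After intrathecal injection of a gadolinium tracer (gadobutrol, 604 Da),
contrast-enhanced MRI shows the tracer spreading from the subarachnoid space
(SAS) and ventricles into grey and white matter over 24–48 hours. Whether
that spread is explained by extracellular diffusion alone, or is accelerated
by glymphatic bulk flow, can be probed by fitting a pure-diffusion model to
the observed concentration fields: if the fitted *apparent* diffusion
coefficient exceeds the diffusion-only value predicted from DTI water maps,
transport beyond diffusion is implied.

The fit is a PDE-constrained least-squares problem over the region-wise
diffusivities `D = (D_CSF, D_GM, D_WM)` and the unknown time-varying boundary
concentration `g` on the Dirichlet surfaces:

```
min_{D,g}  sum_i  ∫_Ω |u(t_i) − u_obs(t_i)|² dΩ
         + ∫_0^T ∫_{∂Ω_D} ( α/2 |g|² + β/2 |∂g/∂t|² + γ/2 |∇g|² ) ds dt

s.t.  ∂u/∂t = D ∇²u  in Ω,    u = g on ∂Ω_D,    ∂u/∂n = 0 on ∂Ω_N,
```

with `γ` facet-wise: the reference weight `γ̃` on the SAS-facing ("red")
boundary and `0.01 γ̃` on the ventricular ("blue") boundary. The package
provides:

* **geometry** — synthetic concentric brain-like labeled meshes
  (CSF/GM/WM subdomains, tagged SAS/ventricular boundaries), MSH I/O;
* **forward model** — P1 finite elements, theta-scheme time stepping
  (implicit Euler default, Crank–Nicolson optional), strong Dirichlet data;
* **inverse problem** — discrete-adjoint gradients (verified by Taylor and
  finite-difference tests) and box-constrained L-BFGS over `(log D, g)`;
* **synthetic data** — ground-truth generation on a finer time grid, uniform
  vertex noise, the histogram-based SNR statistic;
* **image preprocessing** — spoiled-gradient-echo signal → concentration,
  CSF-value projection (CP, 7×7×7 labeled-voxel averaging), Gaussian
  smoothing (GS, σ = 1.5 mm), trilinear/nearest image-to-mesh sampling (RAW);
* **comparison** — tortuosity `λ = sqrt(D_free/D_ADC)`, DTI-to-tracer ADC
  prediction, percent differences, unit conversion, the relative-l2 misfit.

Units are mm, hours, mM throughout (`convert_adc_units()` maps mm²/h to
mm²/s).

## Worked example

Recover grey/white ADCs from noisy synthetic observations on an annular
two-domain proxy (true values: GM 0.468, WM 0.396 mm²/h, i.e. the
DTI-predicted gadobutrol ADCs 1.3 and 1.1 ×10⁻⁴ mm²/s):

```r
library(glymadc)

mesh  <- build_synthetic_geometry(2, c(45, 35, 10), resolution = 3,
                                  mode = "two_domain")
grid  <- time_grid(2.4, 24)                       # 10 steps over 24 h
truth <- generate_ground_truth(mesh, region_adc(GM = 0.468, WM = 0.396),
                               boundary_profile_spec(), seq(0, 24, 2.4), grid)
obs   <- add_noise(truth$obs, noise_spec(0.3, seed = 1))
fit   <- estimate_adc(obs, mesh, regularization_params(1e-6, 1e-2, 0.01),
                      grid, u0 = numeric(nrow(mesh$vertices)))
fit
#> inverse_result
#>   ADC [mm^2/h]: GM = 0.4535, WM = 0.3785
#>   ADC [mm^2/s]: GM = 0.000126, WM = 0.0001052
#>   objective = 932.004 (misfit 930.9, alpha 0.003771, beta 0.8368, gamma 0.2568)
#>   55 fn evals, convergence code 0 (converged)
```

Despite ±0.3 mM uniform noise on every vertex of every observation (the
noise floor dominates the residual misfit), both ADCs are recovered within
a few percent: GM −3.1 %, WM −4.4 %. The DTI comparison arithmetic:

```r
adc_from_tortuosity(D_FREE_GADOBUTROL, 1.72) # 1.28e-04 mm^2/s (grey)
percent_difference(1.6e-4, 1.3e-4)           # 23.1 %
convert_adc_units(0.57, "mm2_h", "mm2_s")    # 1.58e-04
```

Higher-level drivers `run_simulate()`, `run_estimate()` and `run_compare()`
(also exposed by the thin CLI in `inst/cli/glymadc.R`) generate dataset
directories, sweep the regularization grid, and emit comparison tables.

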