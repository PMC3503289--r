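# immobead

Reaction–diffusion modelling of enzymes immobilized in spherical gel
beads, built around a bench-scale system: starch hydrolysis by
alpha-amylase entrapped in calcium-alginate beads packed in a fixed-bed
column.

## The problem

When an enzyme is entrapped in a hydrogel bead, the observed conversion
in a reactor reflects two coupled processes: the intrinsic
Michaelis–Menten kinetics of the enzyme and the diffusion of substrate
and product through the gel. `immobead` covers the full analysis chain:

* **Kinetics** — the integrated Michaelis–Menten law
  `Km·ln(S0/St) + (S0 − St) = Vmax·t` and its inverse
  (`integrated_time()`, `predict_outlet()`), where `S0` and `St` are the
  inlet and outlet substrate concentrations and `t` is the residence
  time in the bed.
* **Estimation** — the linearization `ln(1−X)/t = (S0/Km)·(X/t) −
  Vmax/Km` of the integrated law, fitted by ordinary least squares to
  conversion data (`estimate_km_vmax()`), plus fixed-bed helpers for
  residence time, bed voidage and entrapment efficiency.
* **Scaling** — the dimensionless groups that govern intraparticle
  transport: Thiele modulus `phi = (R/3)·sqrt(Vmax/(Km·Ds))`, saturation
  parameter `beta = S0/Km`, and diffusivity ratio `lambda = Dp/Ds`.
* **Bead simulation** — the nonlinear reaction–diffusion equations for
  substrate and product inside a spherical bead, solved in 1-D radial
  and 2-D axisymmetric form, steady and transient, with effectiveness
  factors and concentration profiles (`steady_sphere_1d()`,
  `steady_axisymmetric()`, `transient_solve()`,
  `effectiveness_factor()`).
* **Synthetic data** — a generator for conversion experiments with
  mean-one lognormal measurement noise (`scenario_spec()`,
  `generate_series()`), so estimators can be validated against known
  truths.
* **Pipeline** — `run_pipeline()` chains data → fit → scale → simulate
  from a YAML/list configuration and writes CSV tables, field files and
  a JSON manifest.

The methods vignette (`vignettes/bead-reaction-diffusion.Rmd`) documents
the model, the numerical schemes and their limitations.

## Worked example

Generate a noiseless conversion dataset from the default scenario
(inlet grid 1–100 g/L, residence times 5–120 min, truth Km = 3.38 g/L,
Vmax = 0.134 g/(L·s)), then fit the 10 g/L series back:

```r
library(immobead)

sp  <- scenario_starch_default()          # noiseless, seed 20121031
ser <- generate_series(sp)
s10 <- Filter(function(s) s$S0 == 10, ser)[[1]]
fit <- estimate_km_vmax(s10, drop_complete = TRUE)
fit
#> Integrated-rate linearized fit
#>   S0       = 10 g/L (2 points)
#>   Km_hat   = 3.38 g/L
#>   Vmax_hat = 8.04 g/(L.min)
#>   R^2      = 1.000000
```

(With this fast enzyme, five of the seven residence times reach
numerically complete conversion and are dropped — with a warning — from
the fit; `8.04 g/(L·min)` is `0.134 g/(L·s)`.) The recovered parameters
and the default bead transport properties (R = 0.1 cm, Ds = 7.8e-8
cm²/min) give the dimensionless groups:

```r
g <- scale_parameters(bead_transport(),
                      mm_kinetics(Km = fit$Km_hat, Vmax = fit$Vmax_hat),
                      S0 = 10)
g
#> Dimensionless groups: phi = 184.078, beta = 2.95858, lambda = 1, R^2/Ds = 128205 min
```

A Thiele modulus of ~184 means the bench system is strongly
diffusion-limited. At a moderate Thiele modulus the bead solver
quantifies the limitation directly:

```r
effectiveness_factor(steady_sphere_1d(phi = 1, beta = 0.5, n_radial = 64))
#> Effectiveness factor: eta = 0.7870 (phi = 1, beta = 0.5, centre Cs = 0.3727)
```

Residence times of the two bench operating points (60 cm³ bed, voidage
0.42):

```r
residence_time(reactor_spec(VR = 60, epsilon = 0.42, Q = 5.04))  # 5 min
residence_time(reactor_spec(VR = 60, epsilon = 0.42, Q = 0.21))  # 120 min
```

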