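# heelstrike

Estimation of the mechanical energy absorbed by the foot–ankle system
during the heel-strike phase of barefoot walking, from synchronized
force-plate and optical-marker recordings.

When the heel hits the ground, the heel pad, foot and ankle compress
over the first ~10–50 ms of stance and absorb energy.  `heelstrike`
implements two estimators of that energy for a single recorded step
and the machinery to compare them across a study:

* **Force-integral method** — the work done by the ground reaction
  force **F** over the foot–ankle deformation
  **S**(t) = **R**_H(t) − **R**_H(t₀) of a bone-fixed heel point:

      W = ∫ F · dS = W_X + W_Y + W_Z,

  integrated by the trapezoidal rule from contact (t₀) to the instant
  of zero vertical heel velocity (t_e, maximal compression).

* **Effective-mass model** — a point mass M decelerated by the
  vertical GRF and gravity, from the impulse–momentum balance
  M = ∫F_Z dt / (Ż_H(t) − Ż_H(t₀) + g·(t − t₀)), with the energy
  change ΔE = ½M(Ż_end² − Ż₀²) + Mg·ΔZ.  Three variants: the improved
  application evaluated to t_e (M_e, ΔE_e), the same evaluated to the
  impact-force peak t_p with measured velocity (M_p, ΔE_p), and the
  original assumption that the heel is stationary at t_p
  (M_p_CS, ΔE_p_CS) — an assumption that fails whenever the contact
  is substantially damped, because peak force then precedes peak
  deformation.

The package covers the full chain: reduction of the raw 8-channel
Kistler-style plate record to net GRF + centre of pressure, gait-event
detection, zero-phase marker filtering, local lower-leg frames from a
two-LED cluster, heel-point estimation (median of the local COP cloud
around the impact peak), per-trial energetics, three-level study
aggregation (subject means / intra- / inter-subject variability),
exact small-sample method-comparison statistics (Friedman, exact
Wilcoxon signed rank), heel-point sensitivity analysis, and a
viscoelastic heel-impact simulator with a full energy audit that makes
every stage testable against known ground truth.

## A worked example

Simulate one synthetic trial (effective mass 8.5 kg, Kelvin–Voigt
contact, touchdown at −0.57 m/s, realistic marker noise and
synchronization jitter) and run the full pipeline on its rendered raw
channels and markers:

```r
library(heelstrike)
cfg   <- sim_config(seed = 42)
trial <- simulate_trial(cfg)
fit   <- heel_strike(trial$channels, trial$markers, body_mass = 76.7)
summary(fit)
```

```
Heel-strike energy absorption (one trial)
  heel strike: t0 = 0.1000 s, t_p = t0 + 18.3 ms, t_e = t0 + 31.3 ms (t_e/t_p = 1.71)
  deformation at t_e: S = (0.1, -0.0, -9.4) mm, |S| = 9.4 mm
  force-integral work:  W = -2.10 J  (X 0.00, Y 0.00, Z -2.10)
  effective-mass model: dE_e = -2.14 J, dE_p = -1.76 J, dE_p_CS = -1.33 J
  heel point r_H (local, m): (0.0100, -0.0401, -0.1122)
  heel velocity: Zdot(t0) = -0.582 m/s, Zdot(t_p) = -0.269 m/s
  effective masses: M_e = 8.18 kg, M_p = 8.39 kg, M_p_CS = 5.42 kg
    as % body mass (76.7 kg): 10.7%, 10.9%, 7.1%
```

Reading the output: the impact-force peak arrives 18.3 ms after
contact but the heel keeps compressing until 31.3 ms (ratio 1.71) —
the damped-contact signature.  The force-integral work (−2.10 J)
agrees with the improved effective-mass energy ΔE_e (−2.14 J, the
work–energy theorem for a point mass), while the original model's
assumption of zero heel velocity at the force peak underestimates the
absorbed energy (ΔE_p_CS = −1.33 J) and the effective mass
(7.1% vs 10.7% of body mass).  The true simulated mass here is 8.5 kg;
M_e recovers it within a few percent despite 0.1 mm marker noise and
sub-millisecond synchronization error.

`plot(fit)` draws the GRF and deformation with the three event times
marked; `plot(fit, "cop")` shows the local COP cloud with the
estimated heel point; `heel_point_sensitivity()` quantifies how little
the energetics depend on that point; `make_fixture_study()` +
`aggregate_trials()` run whole synthetic cohorts; `write_trial_json()`
/ `trial_table()` persist and collect per-trial results.  A thin CLI
(`exec/heelstrike`) exposes `process-trial`, `simulate`, `aggregate`
and `sensitivity` over CSV/JSON/YAML files.

See `vignettes/heelstrike-methods.Rmd` for the models, the parameter
defaults and their rationale, numerical choices, and known
limitations.

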