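# piuptake

Spatiotemporal analysis of propidium iodide (PI) uptake by surface-attached
bacteria after a **single microbubble cavitation event**.

A collapsing microbubble porates nearby cell membranes; PI in the medium
enters damaged cells and stains their DNA. A time-lapse fluorescence stack
then carries, for every cell, the extent of damage (the fluorescence
plateau) and the transport kinetics through the transient pores (the rise
time). `piuptake` turns such stacks — or synthetic equivalents — into
per-cell kinetic parameters, a radial damage law, and model-derived
permeability and membrane-damage fields. It is aimed at researchers
quantifying sonoporation, cavitation-based delivery, or membrane-poration
assays at single-cell resolution.

## The model

For each cell at normalized distance γ = l_cell / R_max from the cavitation
center:

- First-order uptake: `I(t) = I_final (1 − e^{−kt})`, fitted per cell by
  Levenberg–Marquardt least squares; identity `dI/dt|₀ = k·I_final`.
- Radial law: `I_final(γ) = a + b/γ` (2D spreading of the collapse energy).
- Modified Goldman transport: permeability `P(γ,t) = k k₁ I_final(γ) e^{−kt}`
  decays as pores reseal; the two-compartment dye balance
  `∂c₁/∂t = αP (c₂α_m − c₁)/(1 − α_m)`, `c₂ = 1 − c₁`, solves in closed form
  and linearizes to the measured fluorescence time course. Relative
  permeability doubles as the membrane damage fraction `S_p = P/p₀`.

Because no raw stack is distributed, a first-class synthetic generator
reproduces the statistical structure of the experiment (Poisson cell field
at 0.28 cells/µm², radial plateau law, truncated-normal rate constants,
frame noise, rendered 16-bit stacks with autofluorescent beads), so every
stage is testable end to end.

## Worked example

```r
library(piuptake)

cfg <- load_config(overrides = list(seed = 42L,
                                    synthetic = list(n_cells = 5000L)))
res <- run_pipeline(cfg, out_dir = "run42")
```

The run log prints (seed 42):

```
fits: 4998/5000 converged; mean k = 0.004598 1/s (sd 0.001725), tau = 217.5 s
radial law: a = 321 AU, b = 227.4 AU (R^2 = 0.916)
```

Meaning: the per-cell rate constants average k ≈ 0.0046 s⁻¹ — a
characteristic saturation time τ = 1/k ≈ 217 s, i.e. uptake plateaus over
minutes although the mechanical insult lasted microseconds — and the
plateau intensity falls off with distance as ≈ 321 + 228/γ AU, so cells
within one bubble radius (γ ≤ 1) take up roughly twice the dye of distant
ones. `run42/` contains the traces, fits, population summary, spatiotemporal
field maps (`fields.csv`: I, P/p₀, S_p, c₁, c₂ over a γ × t grid) and
figures. A thin CLI wrapper with `simulate/extract/fit/model/run`
subcommands is installed at `inst/cli/piuptake`.

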