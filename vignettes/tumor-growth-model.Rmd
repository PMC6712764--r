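---
title: "A voxel-lattice stochastic model of 3-D tumor growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A voxel-lattice stochastic model of 3-D tumor growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorvox)
```

## The model

`tumorvox` simulates the growth of a solid tumor inside a cube of tissue
discretized into an $N \times N \times N$ lattice of voxels of edge
$\Delta s$ (default 2 mm — the resolution of clinical imaging), advanced in
discrete steps of $\Delta \tau$ (default 10 s — the time scale of chemical
diffusion). Each voxel $A$ carries aggregate, continuous quantities rather
than individual cells: live tumor cells $l(A)$, necrotic tumor cells
$nc(A)$, necrotic host cells $nn(A)$, oxygen and glucose stocks $o(A)$,
$gl(A)$ (pmol), vascular supply rates $o_b(A)$, $gl_b(A)$ (pmol/s, possibly
negative — vessels can absorb as well as provide) and supply-capacity caps
$o_{b,\max}(A)$, $gl_{b,\max}(A)$. Live *normal* cells are never stored:
their count is always the derived quantity
$s(M - l - nc - nn)$ with $s(x) = \max(x, 0)$, which encodes the assumption
that invading tumor cells dislocate normal cells. The full state is nine
vectors of length $N^3$ plus a per-voxel angiogenesis switch $sw$.

One step applies four operators in sequence:

1. **Vascular remodeling** $F_{vr}$ — supply rates relax stochastically
   toward blood/tissue concentration balance,
   $o_b \leftarrow o_b + r_1(\bar o_0 - o)/\Delta\tau$ with
   $r_1 \sim U(0,1)$, and are clipped to $[-o_{b,\max}, o_{b,\max}]$. In
   voxels the tumor has reached, the caps evolve multiplicatively by
   $1 - f_r r_3 v_r + sw\, f_e r_4 v_e$, with linear occupancy fractions
   $f_r = (l + nc)/M$ (regression grows with tumor burden) and
   $f_e = (M - l - nc - nn)/M$ (angiogenesis needs room and viable
   signaling tissue), both clamped to $[0, 1]$.
2. **Metabolism** $F_{pn}$ — normal cells consume first at fixed rates
   $K_o$, $K_{gl}$; cells that cannot be fed necrose. Tumor cells then meet
   their ATP demand $\lambda_{\text{eff}} K_{ATP}$ by a mix of glycolysis
   (fraction $\beta$) and clean combustion, needing
   $\frac{17\beta + 1}{36}\lambda_{\text{eff}}K_{ATP}$ pmol glucose/s and
   $\frac{1-\beta}{6}\lambda_{\text{eff}}K_{ATP}$ pmol oxygen/s. The
   available oxygen imposes a lower bound $\underline\beta$ and the
   available glucose an upper bound $\bar\beta$ on $\beta$; if the window
   $[\max(\underline\beta, \beta_1), \min(\bar\beta, \beta_2)]$ is
   nonempty, a fraction is drawn uniformly from it and the cohort divides
   at the resource-limited mitosis rate
   $\tilde a = \min(a_o(\tilde\beta), a_{gl}(\tilde\beta), a_{max})$;
   otherwise a fraction is drawn from $[\beta_1, \beta_2]$ and the
   unsupported cells necrose.
3. **Chemical diffusion** $F_o$, $F_{gl}$ — one sparse multiply per
   species, $q \leftarrow T q$, under fixed Dirichlet boundaries (the
   lattice boundary stays at normal-tissue levels, modeling healthy
   surrounding tissue).
4. **Cell invasion** $F_c$ — applied every $\kappa$ steps (default 30,
   i.e. 5 min), because cells diffuse about three orders of magnitude more
   slowly than molecules. Only live tumor cells in excess of
   $s_1 = s(M_{max} - nc - nn)$ move; they scatter along the
   column-stochastic, zero-diagonal operator $T_c$ built from an
   anisotropic diffusion tensor under a reflecting boundary, so total live
   tumor mass is conserved exactly.

The angiogenesis switch is recomputed at the end of each step, on the
post-diffusion fields: $sw(A) = 1$ iff the voxel holds live tumor cells and
is hypoxic ($o < h_o \bar o_0$) or hypoglycemic ($gl < h_{gl}\,
\overline{gl}_0$).

## Diffusion kernels

Transition probabilities are estimated by Monte Carlo from the underlying
stochastic differential equations: a particle starts uniformly distributed
in a voxel, is displaced by a Gaussian with per-axis variance
$2D\Delta\tau$ (isotropic, chemicals) or by
$U\,\mathrm{diag}(\sqrt{\alpha\lambda_i})\,b$, $b \sim N(0,
\Delta\tau I)$ (anisotropic, cells), and its endpoint is binned into
self/face/edge/vertex neighbor classes. The discretization contract is that
essentially no mass escapes beyond the 26-neighborhood in one step; the
residual escape is reported by `check_containment()` and, once it passes
(default tolerance $10^{-4}$; it is $\sim 10^{-26}$ for oxygen at the
default $\Delta s, \Delta\tau$), the four class probabilities are
renormalized so that $p_{self} + 6p_{face} + 12p_{edge} + 8p_{vertex} = 1$
exactly. This makes spatially uniform fields exact fixed points of the
interior diffusion operator — without it, escape mass of any size drains
the lattice over hundreds of thousands of steps.

`analytic_isotropic_kernel()` computes the same quantities by 1-D
quadrature (the three axes factorize) and serves as the independent oracle
for the sampler in the test suite. The default sample count is $10^6$ with
a fixed seed on a private RNG stream, so kernel estimation never disturbs
run-level reproducibility; kernels can be cached as JSON with
`write_kernel()`.

The default cell tensor (`synthetic_tensor()`) is spatially constant with
orthonormal frame $u_1 = (1/2, 1/2, \sqrt2/2)$,
$u_2 = (-1/2, -1/2, \sqrt2/2)$, $u_3 = (\sqrt2/2, -\sqrt2/2, 0)$ and
$\alpha\lambda_i = 2D_i$. The principal coefficient is taken from the top
of the motility range ($1.5\times10^{-6}$ cm²/s) and the transverse ones
from the bottom ($1.5\times10^{-8}$ cm²/s), so invasion runs predominantly
along $u_1$ and simulated tumors elongate along that axis.

## Stochasticity

Three noise sources, all drawn from one seeded stream in a fixed order
(perturbation draws, then $r_1..r_4$, then the per-voxel glycolysis
uniforms), make runs bit-reproducible from their seed:

- the per-voxel uniform draws $r_1..r_4$ in $F_{vr}$;
- the per-voxel glycolysis fraction $\tilde\beta$, uniform on its feasible
  window (the natural choice given only the window is specified; it also
  yields the intended "decreased probability of attaining high mitosis
  rates" as the window narrows);
- a periodic random perturbation of the chemical matrices: every 6 steps,
  each column belonging to a voxel in or adjacent to the tumor is rebuilt
  from the *nominal* matrix with each nonzero multiplied by
  $e^{\varepsilon u}$, $u \sim U(-1,1)$, $\varepsilon = 0.1$, then rescaled
  to its original column sum. Re-deriving from the nominal matrix (rather
  than compounding perturbations) keeps every entry within a factor
  $e^{\varepsilon}$ of its kernel value at all times, which is what
  "entries retain their relative orders of magnitude" must mean over long
  horizons; a compounding variant lets entries random-walk arbitrarily far
  and destroys the diffusion structure within days of simulated time.
  Under the defaults the induced local oxygen variation near the tumor is
  roughly 4–10% per hour, comfortably inside the ≤50%/hour variability
  reported for real tumor tissue. Columns whose entry ranking would change
  are redrawn (with order-of-magnitude-separated entries and
  $\varepsilon \le 0.5$ this essentially never triggers).

## Parameters

Defaults are the reference parameterization: $N = 21$, $\Delta s = 2$ mm,
$\Delta\tau = 10$ s, $M = 8\times10^6$ cells, $M_{max} = 1.02M$,
$K_o = 2.5\times10^{-4}$ and $K_{gl} = 5\times10^{-5}$ pmol/s (whence
$K_{ATP} = \frac{17}{3}K_o + 2K_{gl}$), $\lambda = 10$, 24 h cell cycle,
$a_{max} = 1.6\times10^{-5}$ mitoses/cell/step (5-day minimum doubling
time), $D_o = 1.8\times10^{-5}$ and $D_{gl} = 1.05\times10^{-5}$ cm²/s,
hypoxia/hypoglycemia thresholds at 30%/50% of $\bar o_0 = 1.2\times10^3$ /
$\overline{gl}_0 = 4\times10^4$ pmol, caps $2.8\times10^3$ and $560$
pmol/s, $\kappa = 30$. Supply rates initialize at exact balance,
$o_b = MK_o$, $gl_b = MK_{gl}$, which together with the renormalized
kernels makes a tumor-free lattice a fixed point of the full step.

Two defaults are this package's own choices where the reference study
varies them per experiment: the glycolysis window is
$[\beta_1, \beta_2] = [0.1, 0.2]$ (the regime in which simulated tumors
most robustly survive and grow — a natural default for a malignant
phenotype that still respects the observed 1:1-at-most glucose:oxygen
uptake ratios), and the vasculature rates default to a 5-day minimum
regression halftime with a 1-day minimum expansion doubling time
(`rate_from_halftime()`, `rate_from_doubling()`), the configuration used
for the reference visualizations. "Minimum" is literal: the nominal rates
apply at full occupancy and maximal random draw, so effective half/doubling
times are substantially longer — see *Limitations*.

## Numerical choices

- Cell counts are continuous nonnegative reals; no rounding anywhere.
- Case conditions use the printed inclusive inequalities exactly (no
  epsilons); a feasibility window that collapses to one point is feasible.
- Clamps: occupancy fractions to $[0,1]$; stocks, populations and caps
  floored at 0 (consumption formulas can undershoot by float rounding, and
  a voxel whose vasculature would absorb more than its stock holds is
  truncated at an empty stock).
- The number of actively proliferating cells uses the deterministic
  estimate $a\,l\,(cc/\Delta\tau)$; normal cells consume before tumor
  cells (the printed ordering — a `resource_split` refinement is left as
  future work, and `apply_cell_diffusion()` exposes a chemotaxis-style
  reweighting hook that is disabled by default).
- The inner loop is compiled (Rcpp, hand-rolled CSC multiplies); the
  exported R operators are the reference implementation, consume the RNG
  stream in the identical order, and the two are asserted equal in the
  tests. A 10-day, $N = 11$ replicate takes ~20 s on one core; a 90-day,
  $N = 21$ run (777,600 steps) takes on the order of an hour.

## What the tests do and do not show

The test suite verifies the machinery (kernel estimates against a
quadrature oracle; matrix structure; exact conservation and fixed-point
properties; vectorized operators against independent scalar
re-implementations; bit-reproducibility) and scaled-down behavioral
patterns at $N = 11$ over 10 simulated days. Those short-horizon ensembles
exercise the full operator stack but cannot show the late-stage phenomena —
multi-voxel invasion begins only once the seed voxel overflows
$M_{max}$ (around day 18–20 under defaults), after which a necrotic core
forms (by day 30, the central voxel's necrotic fraction exceeds the tumor
surface average, ≈0.58 vs ≈0.48 in a seeded reference run) and
regression/angiogenesis rates begin to differentiate survival. Nothing in
the suite validates the model against biological measurements; like the
modeling framework it implements, it is a hypothesis-exploration tool.

## Known limitations

- Survival-probability contrasts need long horizons: vessel regression is
  weighted by tumor occupancy, so early-phase tumors are insensitive to
  $v_r$; at short horizons the regression rate shows up in final
  population sizes, not extinction rates.
- No lactate/acidity, cell-cycle phases, necrotic-debris clearance,
  therapy, or multiple tumor clones; the operator architecture is designed
  so these enter as additional operators or $F_{pn}$ extensions.
- Spatially varying diffusion tensors are not supported (the constant
  synthetic tensor covers the reference experiments); neither are
  non-cubic domains.
- Single-threaded; the operators are embarrassingly parallel over voxels
  but no parallel backend is wired.

## A small worked example

```{r example, eval = FALSE}
p <- model_params(n = 11)
ops <- build_operators(p)
res <- run(p, n_steps = 30 * 8640, seed = 1, ops = ops,
           record_every = 5 * 8640)
tidy(res)
cls <- with(res$final_state, classify_occupancy(l, nc, nn, p$M))
plot_section(extract_section(cls, p$spec))
```
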