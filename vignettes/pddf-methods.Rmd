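---
title: "Coordinate-based PDDF and scattering simulation: models, numerics and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based PDDF and scattering simulation: models, numerics and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddfsim)
```

## The physical model

Solution X-ray scattering measures the orientationally averaged intensity
$I(q)$ of a particle ensemble; its real-space mate is the pair distance
distribution function (PDDF) $P(r)$, the histogram of all intra-particle
pair distances weighted by scattering contrast. The two are linked by

$$I(q) = \int_0^\infty P(r)\,\frac{\sin qr}{qr}\,dr, \qquad
  P(r) = \frac{2r}{\pi}\int_0^\infty q\,I(q)\sin(qr)\,dq,$$

with $q = 4\pi\sin\theta/\lambda$ in Å$^{-1}$ and $r$ in Å. Experimental
PDDFs are usually obtained by regularized indirect Fourier transforms,
which can introduce artefacts (ripples, oversmoothing, ambiguous long
tails). This package goes the other way: it computes *theoretical* PDDFs
and intensity profiles directly from an atomic model, so simulated and
measured data can be compared in both spaces.

Solvent is implicit. Each non-hydrogen atom (with its bonded hydrogens
merged into an atom group: C, CH, CH$_2$, CH$_3$, N, NH, ..., listed by
`atom_group_table()`) scatters with a combined factor

$$A_j(q) = f_j(q) - g_j(q), \qquad
  g_j(q) = \rho_s V_j \exp\!\left(-\frac{q^2 V_j^{2/3}}{4\pi}\right),$$

where $f_j$ is the group's atomic form factor, $g_j$ the Gaussian
dummy-atom factor of the solvent it displaces ($V_j$: displaced volume,
$\rho_s$: solvent electron density, default 0.334 e/Å$^3$ for water,
user-overridable). At zero angle $A_j(0) = Z_j - \rho_s V_j = \Delta Z_j$,
the *effective electron number* — possibly negative (a CH$_2$ group in
water displaces more solvent electrons than it carries).

## Three engines

**Point charge (PC).** All $\Delta Z_j$ electrons sit at the atom centre;
$P(r)$ is the pair histogram weighted by $\Delta Z_j \Delta Z_k$
(`pc_pddf()`), and `pddf_to_xs()` transforms it numerically, converging
for grid steps of about 0.1 Å or finer. Fastest, exact at $q = 0$,
increasingly approximate at wide angle where the $q$ dependence of the
form factors matters.

**Direct Debye (DD).** The reference: $I(q) = \sum_{jk} A_j A_k
\,\mathrm{sinc}(q r_{jk})$ over all atom pairs (`dd_xs()`). Because each
product $A_jA_k$ is a Gaussian sum $\sum_l c_l e^{-d_l q^2}$, the inverse
transform of every pair term has the closed form

$$K(r; a, d) = \frac{r}{2a\sqrt{\pi d}}
  \left[e^{-(r-a)^2/4d} - e^{-(r+a)^2/4d}\right], \quad a = r_{jk},$$

so the Debye PDDF is *analytic* — a sum of distance-weighted Gaussians —
with the $a \to 0$ self-pair limit $r^2 e^{-r^2/4d}/(2d\sqrt{\pi d})$
(`dd_pddf()`). Cost scales as $O(N_A^2)$, impractical beyond ~$10^4$
atoms.

**Distance histogram (DH).** Atoms are grouped into the 10–15 types that
occur in biomolecules; pair distances are binned once into typed
histograms $H_{jk}(r_m)$ (`build_histograms()`), after which
`dh_xs()`/`dh_pddf()` evaluate the same sums per (type pair, bin) at
$O(N_T^2 N_R)$ — the production path for large assemblies, with the
$O(N_A^2)$ histogram build as the only expensive step. In the fine-bin
limit DH reproduces DD identically.

## Numerical choices

* **Bin convention.** Everywhere, a distance $r$ belongs to bin
  $\mathrm{round}(r/\Delta r)$: bins are centred on $m\,\Delta r$, and the
  bin centre is the abscissa used inside every sinc and kernel. The
  $r = 0$ bin spans only $[0, \Delta r/2]$, so its density divides by the
  half width — with that convention the trapezoidal area of every curve
  reproduces $(\sum_j \Delta Z_j)^2 = I(0)$ to machine precision, which
  the test suite asserts for all engines.
* **Exact kernel masses.** Analytic PDDFs deposit each Gaussian term into
  bins via the closed-form cumulative integral (an erf expression), not
  point sampling; mass is conserved for arbitrarily narrow kernels, and a
  $d = 0$ (point-charge) term degenerates to plain binning. Kernels are
  truncated at 14 Gaussian widths (relative error $< 10^{-21}$).
* **Self pairs.** PC and DH keep the $j = k$ mass separate from the bins
  (a point mass at $r = 0$), so the forward-scattering identity is exact
  at any bin width; in analytic curves the self term appears as the
  broadened peak near $r = 0$.
* **Form-factor table.** Published element factors (4 Gaussians plus a
  constant) are refit to *pure* five-Gaussian form over $q \in [0, 25]$
  Å$^{-1}$ so that products stay within the Gaussian algebra with no
  delta-function bookkeeping; amplitudes are rescaled so $f(0) = Z$
  exactly. Exponents are constrained $\ge 1.5\times10^{-3}$ Å$^2$: an
  effectively constant term would make $I(q)$ non-decaying far beyond the
  fitted range and put near-delta spikes into $r$-space. The cost is a
  small (up to ~2%) deviation from the published curves at
  $q \gtrsim 15$ Å$^{-1}$ for elements with a large constant (P, S, K);
  within the SAXS/WAXS output range ($q \le 3$) agreement is within 1%.
  Group factors add the hydrogen factor $n_H$ times before refitting.
  Displaced volumes are the standard per-group excluded-solvent values;
  elements without a literature value fall back to the van der Waals
  sphere and are flagged in the shipped JSON table, which users can
  extend (`fit_five_gaussians()`, `atom_group_table(path)`).
* **Inverse-transform oracle.** `xs_to_pddf_numeric()` exists to validate
  the analytic PDDF, not as a production path: it integrates
  $r\sin(qr)$ in closed form over each bin and apodizes the last 10% of
  the $q$ range with a raised cosine, because a sharp cutoff at $q_{max}$
  leaves ringing of amplitude $\sim (2/\pi)\,q_{max} I(q_{max})$ across
  all $r$. Truncating at SAXS range ($q_{max} = 3$) demonstrates the
  classic indirect-transform ripple artefact.

## Defaults and tunables

| parameter | default | meaning |
|---|---|---|
| `solvent_ed` | 0.334 e/Å$^3$ | bulk water electron density; 0 = vacuum |
| PDDF `dr` | 0.5 Å | output grid step (curve resolution) |
| histogram `dr` | 0.2 Å | DH binning; binning error in $I(q)$ is $O(dr^2)$ at fixed $q$ |
| $q$ grid | 300 points on [0, 3] Å$^{-1}$ | SAXS/WAXS output range |
| Dmax threshold | 0.001 | apparent-Dmax fraction of peak maximum |

The apparent-Dmax diagnostic (`apparent_dmax()`) reads the largest $r$
where $P(r)$ still reaches a fraction (default 0.1%) of the main peak,
located on the stored grid without interpolation — the same precision the
0.5 Å curve carries. The self peak region ($r <$ 1 Å by default) is
excluded from the peak maximum. Because theoretical PDDFs of folded
particles end in a long shallow tail carried by very few pairs, the
apparent value underestimates the true maximum pair distance by several
Å; `normalize_pddf()` demonstrates the companion normalization pitfall —
per-mass instead of per-particle scaling — that distorts comparisons
between related assemblies.

## What the synthetic generator emulates — and what it does not

`make_fixture()` builds point sets with known distance structure: a
two-site dimer (closed-form Debye), a linear or two-rail ladder (the
layered repeat of duplex DNA and its oscillatory PDDF), a helix, a
uniform ball (compact globule; optional ellipsoid axes), a hollow shell
(capsid-like), and a ring of spherical clusters (cyclic oligomer, one
chain per subunit, for decomposition tests). Random kinds enforce a
1.5 Å minimum site separation — atoms are never closer than a bond
length, and uncontrolled overlaps would pile unphysical weight into the
first bin. Coordinates are quantized to 0.001 Å so PDB round trips are
exact, and all randomness derives from the `seed` argument through R's
default generator.

Two deliberate idealizations matter for interpreting test results.
First, a mathematically exact sphere has deep orientation-averaged
intensity minima that no real protein shows; pointwise *relative* method
comparisons are therefore run on a slightly ellipsoidal globule.
Second, a globule whose sites are all the same group in water rings
coherently at short $r$ (every pair shares the identical
spike-plus-negative-lobe contrast kernel); `protein_composition()`
provides a protein-like group mixture that restores the short-range
diversity of real heteroatomic structures. Passing tests on these
fixtures validate the machinery — conservation, oracle equivalence,
limit equivalence, additivity — not the chemistry of any particular
molecule; the published per-structure constants (atom counts, Dmax
values, protein accuracy bands) are checked by separate tests that
require the deposited PDB entries to be fetched first (see the README).

The fixtures also have sharp surfaces, unlike the fuzzy surface of a
real protein, so their apparent-Dmax gap is at the low end of what
folded proteins show.

## Subunit decomposition

For a system of $N$ subunits the PDDF splits exactly into per-subunit
terms plus inter-subunit correlation terms,

$$P(r) = \sum_j P_j(r) + \sum_{j<k} P^{corr}_{jk}(r),$$

where $P^{corr}_{jk}$ counts only cross pairs, both ordered directions —
each correlation curve carries the factor 2 of the dimer expansion, so
summing the returned curves reproduces the total bin-exactly
(`decompose_pddf()`, all three engines). This is the tool for asking
*which* structural unit or unit-pair correlation produces a PDDF
feature: short-distance peaks come from subunit internals, intermediate
peaks from specific neighbour correlations.

## Problem sizes and performance

The direct Debye pair (`dd_xs()` + `dd_pddf()`) is the accuracy
reference and scales quadratically; the suite verifies the quadratic
growth empirically. The package's validation battery uses 10–1500-site
fixtures: naive-oracle equivalence at 50 (Debye), 10 (inverse-FT,
$q_{max} = 50$ Å$^{-1}$), 1000 (histograms) and 20 sites (fine-bin
limit), and the method-agreement bands on a 1500-site protein-like
ellipsoidal globule, where the distance-histogram engine at 0.2 Å
binning stays within a fraction of a percent of the direct Debye
profiles below $q = 0.2$ Å$^{-1}$ and within ~1% elsewhere while being
roughly two orders of magnitude faster. On the same globule the
point-charge PDDF deviates from the analytic Debye PDDF by a few percent
in the central distance range — larger than for real compact proteins,
whose heavier, more diverse atoms broaden less coherently. The expected
cost ordering PC $\le$ DH $\ll$ DD holds throughout.

## Known limitations

* No hydration-layer construction: a water shell is supported only as
  explicit user-supplied water coordinates (typed OH$_2$).
* No empirical wide-angle intensity correction for the PC profile; PC-XS
  intensities deviate beyond $q \approx 0.2$ Å$^{-1}$ by design.
* No fitting of experimental data, smearing, or indirect-transform
  estimation — the package audits those workflows from the model side.
* Form factors are spherical and neutral-atom; no anomalous dispersion
  or ion-specific corrections.
* mmCIF assembly operators are not expanded (PDB REMARK 350 BIOMT only);
  high-$q$ fidelity of the refit element factors degrades above
  $q \approx 15$ Å$^{-1}$ as described above.
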