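# pddfsim

Coordinate-based simulation of pair distance distribution functions
(PDDFs) and solution X-ray scattering (SAXS/WAXS) profiles from atomic
models, for structural biologists and scattering scientists who want to
compare models with experiment in *both* reciprocal and real space.

Experimental PDDFs come from regularized indirect Fourier transforms of
measured intensities and can carry artefacts — false ripples,
oversmoothed features, ambiguous maximum dimensions. A PDDF computed
directly from coordinates is artefact-free and makes a reliable
reference. `pddfsim` implements three engines over one implicit-solvent
contrast model, in which each atom group scatters with
`A(q) = f(q) − g(q)` (atomic form factor minus the Gaussian dummy-atom
factor of the displaced solvent), so that `A(0) = ΔZ = Z − ρ_s·V`, the
effective electron number:

* **PC** — point-charge distance histogram weighted by `ΔZ_j ΔZ_k`, with
  the scattering profile from a numerical Fourier transform
  (`pc_pddf()`, `pddf_to_xs()`): the quick estimate.
* **DD** — the direct Debye double sum
  `I(q) = Σ_jk A_j(q) A_k(q) sinc(q r_jk)` and its fully *analytical*
  PDDF: every form-factor product is a Gaussian sum, and each Gaussian
  term has a closed-form inverse transform
  `K(r; a, d) = r/(2a√(πd)) [e^{−(r−a)²/4d} − e^{−(r+a)²/4d}]`
  (`dd_xs()`, `dd_pddf()`): the accuracy reference, O(N²).
* **DH** — typed pair-distance histograms (10–15 atom-group types in
  biomolecules) that accelerate both calculations by orders of magnitude
  for large assemblies (`build_histograms()`, `dh_xs()`, `dh_pddf()`):
  the production path.

Around the engines: PDB/mmCIF reading with implicit-hydrogen atom-group
typing, NMR model selection and biological-assembly expansion
(`read_structure()`); exact subunit decomposition of a PDDF into
per-subunit and inter-subunit correlation curves (`decompose_pddf()`);
true-versus-apparent Dmax diagnostics and normalization utilities
(`apparent_dmax()`, `normalize_pddf()`); synthetic geometry generators
(`make_fixture()`); and a CLI (`inst/cli/pddfsim.R`) with `compute`,
`decompose`, `dmax`, `fixture` and `histogram` verbs.

## Worked example

An eight-subunit ring (a cyclic-oligomer stand-in, 12 carbon-like sites
per subunit) in water:

```r
library(pddfsim)
fx <- make_fixture("ring", seed = 1, solvent_ed = 0.334)
m  <- fx$model
m
#> <structure_model: 96 sites, 1 type(s), solvent_ed = 0.334 e/A^3>
#>   types: C

h <- build_histograms(m, dr = 0.2)
h
#> <typed_pair_histogram: 1 types, dr = 0.2 A, 88 bins, 96 atoms, total pairs = 9216>

dh_xs(h)                       # scattering profile, 300 q points on [0, 3]
#> <xs_curve [DH]: 300 points, q in [0, 3] 1/A, I(0) = 2388.07>

p <- dh_pddf(h, dr = 0.25)     # analytical distance-histogram PDDF
p
#> <pddf_curve [DH]: 151 points, dr = 0.25 A, r max = 37.5 A, area = 2388.07>

sum(effective_electrons(m))^2
#> [1] 2388.066
```

The total pair count is `96² = 9216` (ordered pairs, self pairs
included), and the forward scattering `I(0)`, the PDDF area and the
squared total effective electron number `(Σ ΔZ)²` all agree — the
conservation identity every engine maintains exactly. Which distances
come from where:

```r
decompose_pddf(m, method = "DH", dr = 0.25, dr_hist = 0.05)
#> <pddf_decomposition [DH]: 8 subunit(s), 28 correlation curve(s), additivity residual = 2.52e-11>

apparent_dmax(p, max_pair_distance(m))
#> <dmax_report [DH]: true 17.48 A, apparent 17.48 A at 0.1% threshold, gap 0.00 A>
```

The 28 correlation curves plus 8 subunit curves sum back to the total
PDDF bin-exactly. The apparent Dmax (largest r where P(r) still reaches
0.1% of the peak) coincides with the true maximum pair distance here
because this small dense ring has no shallow tail; folded proteins
typically show a 3–7 Å shortfall.

The same workflow from a shell:

```sh
Rscript inst/cli/pddfsim.R fixture --kind shell --n 800 --radius 30 --out shell.pdb
Rscript inst/cli/pddfsim.R compute --input shell.pdb --method dh --solvent-ed 0 --out shell
# -> shell_pddf.dat, shell_xs.dat, shell_manifest.json
```

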