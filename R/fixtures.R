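#' Synthetic geometry fixtures
#'
#' Generates point sets with known pair-distance structure so every engine
#' can be validated without external files:
#'
#' * `two_atom`: two sites `d` apart -- the closed-form Debye case.
#' * `ladder`: `n_rungs` rungs stacked along z with spacing `rise`
#'   (default 3.4 \eqn{\mathrm{\AA}}, the base rise of duplex DNA whose
#'   layered ladder structure produces the characteristic PDDF
#'   oscillations); `width > 0` puts two rails `width` apart,
#'   `width = 0` degenerates to a linear stack whose pair distances are
#'   exact multiples of `rise`.
#' * `helix`: `n` sites on a helix (`radius`, `rise`, `twist` per site).
#' * `sphere`: `n` sites uniform in a ball of radius `radius` -- a compact
#'   globule; optional `axes` scale factors deform it into an ellipsoid
#'   (protein-like globules are rarely perfect spheres, whose sharp
#'   orientation-averaged minima are atypical).
#' * `shell`: `n` sites uniform in a spherical shell (`radius` =
#'   mid-surface, `thickness`) -- a capsid-like hollow particle.
#' * `ring`: `n_subunits` spherical clusters of `subunit_n` sites each,
#'   centres on a ring of radius `ring_radius` -- a cyclic oligomer
#'   (chains A, B, ... per subunit) for decomposition tests.
#'
#' Sites are carbon atoms by default (`label = "C"`); coordinates are
#' quantized to 0.001 \eqn{\mathrm{\AA}} so writing to PDB and re-reading
#' reproduces the model exactly.  All randomness comes from `seed` via
#' R's default generator, so fixtures are bit-reproducible from
#' `(kind, params, seed)`.
#'
#' @param kind one of `"two_atom"`, `"ladder"`, `"helix"`, `"sphere"`,
#'   `"shell"`, `"ring"`.
#' @param ... kind-specific parameters, see Details above.
#' @param label atom-group label for the sites (default `"C"`); a vector
#'   is recycled over sites.
#' @param composition optional named probability vector of group labels
#'   (e.g. `c(C = 0.2, CH2 = 0.2, N = 0.1, O = 0.2, ...)`); sites are then
#'   assigned labels by seeded sampling, emulating a heteroatomic
#'   composition.
#' @param solvent_ed solvent electron density; default 0 (vacuum), so
#'   \eqn{\Delta Z = Z}.
#' @param seed integer seed for the random kinds.
#' @param path optional: also write the fixture as a PDB file.
#' @return A list: `model` (typed [structure_model()]), `info` (exact
#'   ground truths: `dmax`, generation parameters), and `path` if written.
#' @export
make_fixture <- function(kind = c("two_atom", "ladder", "helix", "sphere",
                                  "shell", "ring"),
                         ..., label = "C", composition = NULL,
                         solvent_ed = 0, seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  prm <- list(...)
  gen <- switch(kind,
    two_atom = fixture_two_atom,
    ladder = fixture_ladder,
    helix = fixture_helix,
    sphere = fixture_sphere,
    shell = fixture_shell,
    ring = fixture_ring)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  g <- do.call(gen, prm)
  xyz <- round(g$xyz, 3)
  if (!is.null(composition)) {
    stopifnot(!is.null(names(composition)), all(composition >= 0))
    label <- sample(names(composition), nrow(xyz), replace = TRUE,
                    prob = composition)
  }
  atoms <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      label = rep_len(label, nrow(xyz)),
                      chain = if (is.null(g$chain)) "A" else g$chain,
                      resname = "FIX",
                      elety = label,
                      resno = seq_len(nrow(xyz)),
                      stringsAsFactors = FALSE)
  m <- structure_model(atoms, solvent_ed = solvent_ed,
                       source = list(fixture = kind, seed = seed, params = prm))
  m <- assign_atom_types(m)
  m$atoms$elety <- m$atoms$label
  info <- c(g$info, list(kind = kind, seed = seed,
                         dmax = if (nrow(xyz) > 1)
                           cpp_max_pair_dist(m$atoms$x, m$atoms$y, m$atoms$z)
                         else 0))
  out <- list(model = m, info = info)
  if (!is.null(path)) {
    write_pdb(m, path)
    out$path <- path
  }
  out
}

fixture_two_atom <- function(d = 5) {
  stopifnot(d > 0)
  list(xyz = rbind(c(0, 0, 0), c(0, 0, d)), info = list(d = d))
}

fixture_ladder <- function(n_rungs = 10, rise = 3.4, width = 0) {
  stopifnot(n_rungs >= 2, rise > 0, width >= 0)
  z <- (seq_len(n_rungs) - 1) * rise
  xyz <- if (width > 0) {
    rbind(cbind(-width / 2, 0, z), cbind(width / 2, 0, z))
  } else cbind(0, 0, z)
  list(xyz = xyz, info = list(n_rungs = n_rungs, rise = rise, width = width))
}

fixture_helix <- function(n = 20, radius = 9, rise = 2.8, twist = 36) {
  stopifnot(n >= 2, radius > 0)
  th <- (seq_len(n) - 1) * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
  list(xyz = xyz, info = list(n = n, radius = radius, rise = rise,
                              twist = twist))
}

fixture_sphere <- function(n = 500, radius = 20, min_sep = 1.5,
                           axes = c(1, 1, 1)) {
  stopifnot(n >= 2, radius > 0, length(axes) == 3, all(axes > 0))
  xyz <- sample_min_sep(n, min_sep, function(k) {
    u <- stats::runif(k)
    pts <- unit_directions(k) * (radius * u^(1 / 3))
    pts %*% diag(axes)
  })
  list(xyz = xyz, info = list(n = n, radius = radius, min_sep = min_sep,
                              axes = axes))
}

fixture_shell <- function(n = 2000, radius = 80, thickness = 15,
                          min_sep = 1.5) {
  stopifnot(n >= 2, radius > 0, thickness > 0, thickness < 2 * radius)
  r1 <- radius - thickness / 2
  r2 <- radius + thickness / 2
  xyz <- sample_min_sep(n, min_sep, function(k) {
    u <- stats::runif(k)
    unit_directions(k) * (r1^3 + u * (r2^3 - r1^3))^(1 / 3)
  })
  list(xyz = xyz, info = list(n = n, radius = radius,
                              thickness = thickness, min_sep = min_sep))
}

fixture_ring <- function(n_subunits = 8, subunit_n = 12, ring_radius = 7,
                         subunit_radius = 2.2, min_sep = 1) {
  stopifnot(n_subunits >= 2, subunit_n >= 1, ring_radius > 0)
  th <- (seq_len(n_subunits) - 1) * 2 * pi / n_subunits
  centres <- cbind(ring_radius * cos(th), ring_radius * sin(th), 0)
  pieces <- lapply(seq_len(n_subunits), function(i) {
    blob <- sample_min_sep(subunit_n, min_sep, function(k) {
      u <- stats::runif(k)
      unit_directions(k) * (subunit_radius * u^(1 / 3))
    })
    sweep(blob, 2, centres[i, ], `+`)
  })
  xyz <- do.call(rbind, pieces)
  list(xyz = xyz,
       chain = rep(LETTERS[seq_len(n_subunits)], each = subunit_n),
       info = list(n_subunits = n_subunits, subunit_n = subunit_n,
                   ring_radius = ring_radius,
                   subunit_radius = subunit_radius,
                   chord = 2 * ring_radius * sin(pi / n_subunits)))
}

# dart-throwing sampler: draw candidates from `draw` until n points at
# least min_sep apart are accepted (atoms are never closer than a bond
# length in real structures; random overlaps would also dominate the
# short-r PDDF bins unphysically)
sample_min_sep <- function(n, min_sep, draw, max_tries = 200L) {
  if (min_sep <= 0) return(draw(n))
  acc <- matrix(numeric(0), 0, 3)
  for (it in seq_len(max_tries)) {
    cand <- draw(max(n, 64L))
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (nrow(acc) == 0 ||
          min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2 +
                (acc[, 3] - p[3])^2) >= min_sep^2) {
        acc <- rbind(acc, p)
        if (nrow(acc) == n) return(unname(acc))
      }
    }
  }
  stop(sprintf("could not place %d points with min_sep = %g", n, min_sep))
}

unit_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Canonical protein-like group composition
#'
#' Sampling frequencies approximating the atom-group makeup of a folded
#' protein (carbon backbone/side-chain groups, amide and amine nitrogens,
#' carbonyl and hydroxyl oxygens, some sulfur), for
#' [make_fixture()]'s `composition` argument.
#' @return Named numeric probability vector.
#' @export
protein_composition <- function() {
  c(C = 0.20, CH = 0.12, CH2 = 0.14, CH3 = 0.05, N = 0.05, NH = 0.12,
    O = 0.20, OH = 0.08, S = 0.04)
}

#' Write a model as a PDB file
#'
#' Minimal ATOM-record writer for fixtures and derived site lists;
#' coordinates are written with three decimals, the group label goes in
#' the atom-name field and the bare element in the element column.
#'
#' @param model a typed [structure_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  check_typed(model)
  at <- model$atoms
  tab <- load_ff_table()
  elem <- tab$element[match(at$label, tab$label)]
  elem[is.na(elem)] <- "C"
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)) %% 100000,
    substr(at$label, 1, 4),
    substr(at$resname, 1, 3),
    substr(ifelse(at$chain == "", "A", at$chain), 1, 1),
    at$resno %% 10000, at$x, at$y, at$z, 1, 0, toupper(elem))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
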