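#' Read an atomic structure into a scattering-site model
#'
#' Parses a PDB or mmCIF file (via bio3d), applies the stated filters and
#' returns a [structure_model] of non-hydrogen scattering sites with
#' atom-group types assigned.  Explicit hydrogens are merged into their
#' parent heavy atom's group: for residues covered by the standard
#' dictionaries the implicit-hydrogen counts come from the dictionary (file
#' hydrogens are dropped); for other residues each file hydrogen is
#' attached to the nearest heavy atom of the same residue.  Alternate
#' locations are resolved to the highest occupancy (ties: first in file).
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param model model number for multi-model (NMR ensemble) files; default 1.
#' @param assembly if `TRUE`, expand the biological assembly using the
#'   file's BIOMT transforms (PDB only); default `FALSE` (asymmetric unit).
#' @param include_het keep non-water HETATM heterocompounds; default `FALSE`.
#' @param include_waters keep waters; default `FALSE`.
#' @param selection optional selection (see [parse_selection()]) applied
#'   after the filters.
#' @param solvent_ed solvent electron density (e/\eqn{\mathrm{\AA}^3}).
#' @return A [structure_model].
#' @export
read_structure <- function(path, model = 1L, assembly = FALSE,
                           include_het = FALSE, include_waters = FALSE,
                           selection = NULL, solvent_ed = 0.334) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  multi <- model > 1L
  pdb <- if (ext == "cif") {
    suppressWarnings(bio3d::read.cif(path, multi = multi, rm.alt = FALSE,
                                     verbose = FALSE))
  } else {
    bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  # requested model
  nmodel <- max(1L, nrow(pdb$xyz))
  if (model > nmodel)
    stop(sprintf("model %d requested but file has %d model(s)", model, nmodel))
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  # altloc: keep highest occupancy per (chain, resno, insert, atom name)
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      i <- which(key == k)
      keep[i] <- FALSE
      keep[i[which.max(occ[i])]] <- TRUE
    }
    at <- at[keep, , drop = FALSE]
  }
  if (!include_waters)
    at <- at[!toupper(at$resid) %in% water_resnames, , drop = FALSE]
  if (!include_het) {
    drop_het <- at$type == "HETATM" &
      !toupper(at$resid) %in% water_resnames
    at <- at[!drop_het, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no atoms left after filters in ", path)
  model_df <- data.frame(
    elety = at$elety, resname = toupper(at$resid), chain = at$chain,
    resno = at$resno, element = guess_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  # assembly expansion (PDB BIOMT transforms)
  if (isTRUE(assembly)) {
    mats <- biomt_matrices(pdb)
    if (length(mats) > 1) {
      pieces <- lapply(seq_along(mats), function(i) {
        m <- mats[[i]]
        out <- model_df
        xyz <- cbind(model_df$x, model_df$y, model_df$z) %*% t(m[, 1:3])
        out$x <- xyz[, 1] + m[1, 4]
        out$y <- xyz[, 2] + m[2, 4]
        out$z <- xyz[, 3] + m[3, 4]
        out$chain <- paste0(out$chain, ".", i)
        out
      })
      model_df <- do.call(rbind, pieces)
    }
  }
  sm <- structure_model(model_df, solvent_ed = solvent_ed,
                        source = list(file = path, model = model,
                                      assembly = assembly))
  sm <- merge_hydrogens(sm)
  sm <- assign_atom_types(sm)
  if (!is.null(selection)) {
    idx <- select_atoms(sm, selection)
    if (length(idx) == 0) stop("selection matches no atoms")
    sm <- subset_model(sm, idx)
  }
  sm
}

biomt_matrices <- function(pdb) {
  bm <- pdb$remark$biomat
  if (is.null(bm) || is.null(bm$mat)) return(list(diag(4)[1:3, ]))
  lapply(bm$mat[[1]], function(m) m)
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # derive from the atom name: first alphabetic character(s)
    nm <- toupper(gsub("[^A-Z].*", "", gsub("^[0-9']+", "", elety[miss])))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    el[miss] <- ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL",
                                  "CA", "SE", "BR"), two, one)
  }
  substr(el, 1, 1) <- toupper(substr(el, 1, 1))
  if (any(nchar(el) == 2))
    el[nchar(el) == 2] <- paste0(substr(el[nchar(el) == 2], 1, 1),
                                 tolower(substr(el[nchar(el) == 2], 2, 2)))
  el
}

#' Construct a structure model from raw sites
#'
#' The flat scattering-site container consumed by all engines.  `atoms`
#' needs at least `x`, `y`, `z`; optional columns `elety`, `resname`,
#' `chain`, `resno`, `element`, `label`.  Call [assign_atom_types()] to
#' derive group labels and the type registry, or supply `z_el`/`volume`
#' columns directly for synthetic point models (see [point_model()]).
#'
#' @param atoms data.frame of atom records.
#' @param solvent_ed solvent electron density (e/\eqn{\mathrm{\AA}^3}).
#' @param source free-form provenance list.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, solvent_ed = 0.334, source = list()) {
  stopifnot(all(c("x", "y", "z") %in% names(atoms)), nrow(atoms) >= 1)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  for (col in c("elety", "resname", "chain"))
    if (is.null(atoms[[col]])) atoms[[col]] <- ""
  if (is.null(atoms$resno)) atoms$resno <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, solvent_ed = solvent_ed, source = source,
                 types = NULL),
            class = "structure_model")
}

#' Synthetic point-charge model
#'
#' Builds a model whose sites scatter as fixed point charges: the form
#' factor of site j is the constant \eqn{\Delta Z_j} (no q dependence, no
#' displaced volume).  Useful for closed-form oracle tests.
#'
#' @param coords matrix or data.frame with columns x, y, z.
#' @param dz effective electron number per site (recycled).
#' @return A [structure_model()] with types assigned.
#' @export
point_model <- function(coords, dz = 1) {
  coords <- as.data.frame(coords)
  names(coords)[1:3] <- c("x", "y", "z")
  dz <- rep_len(dz, nrow(coords))
  atoms <- data.frame(coords[, c("x", "y", "z")],
                      label = sprintf("PT%g", dz),
                      z_el = dz, volume = 0, stringsAsFactors = FALSE)
  m <- structure_model(atoms, solvent_ed = 0)
  labs <- unique(atoms$label)
  m$types <- data.frame(label = labs,
                        z = dz[match(labs, atoms$label)],
                        volume = 0, mass = NA_real_, point = TRUE,
                        stringsAsFactors = FALSE)
  m$atoms$type_index <- match(atoms$label, labs)
  m
}

#' Assign atom-group types
#'
#' Gives every atom a group label from [atom_group_table()] (using the
#' standard residue dictionaries for implicit hydrogens) and builds the
#' model's compact type registry.  Atoms of residues not covered by the
#' dictionaries fall back to their bare element with zero implicit
#' hydrogens (a warning lists them), unless hydrogens were merged
#' geometrically beforehand.  Errors if an element is absent from the
#' table.
#'
#' @param model a [structure_model()].
#' @return The model with `label`, `z_el`, `volume`, `mass` and
#'   `type_index` columns filled and a `types` registry attached; the
#'   number of distinct labels is reported as `n_types`.
#' @export
assign_atom_types <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  tab <- load_ff_table()
  if (is.null(at$label) || any(is.na(at$label)) || any(at$label == "")) {
    lab <- mapply(lookup_group_label, at$resname, at$elety, USE.NAMES = FALSE)
    miss <- is.na(lab)
    # atom names that are themselves table labels (fixture/site files)
    direct <- miss & toupper(trimws(at$elety)) %in% tab$label
    lab[direct] <- toupper(trimws(at$elety[direct]))
    miss <- is.na(lab)
    if (any(miss)) {
      nh <- if (!is.null(at$n_h_merged)) at$n_h_merged else rep(0, nrow(at))
      lab[miss] <- element_fallback_label(at$element[miss], nh[miss], tab)
      bad_res <- unique(at$resname[miss])
      warning(sprintf(
        "element-only typing (no implicit-H dictionary) for %d atom(s) in residue(s): %s",
        sum(miss), paste(bad_res, collapse = ", ")), call. = FALSE)
    }
    unknown <- !lab %in% tab$label
    if (any(unknown))
      stop("element(s) unknown to the form-factor table: ",
           paste(unique(at$element[unknown]), collapse = ", "),
           " (atoms ", paste(utils::head(which(unknown), 10), collapse = ","),
           ")")
    at$label <- lab
  }
  i <- match(at$label, tab$label)
  if (anyNA(i)) {
    # custom labels must already carry z_el/volume (synthetic models)
    if (is.null(at$z_el))
      stop("unknown label(s): ", paste(unique(at$label[is.na(i)]), collapse = ", "))
  } else {
    at$z_el <- tab$z[i]
    at$volume <- tab$volume[i]
    at$mass <- tab$mass[i]
  }
  labs <- unique(at$label)
  at$type_index <- match(at$label, labs)
  model$atoms <- at
  ti <- match(labs, tab$label)
  model$types <- data.frame(
    label = labs,
    z = ifelse(is.na(ti), at$z_el[match(labs, at$label)], tab$z[ti]),
    volume = ifelse(is.na(ti), 0, tab$volume[ti]),
    mass = ifelse(is.na(ti), NA_real_, tab$mass[ti]),
    point = is.na(ti), stringsAsFactors = FALSE)
  model
}

element_fallback_label <- function(element, n_h, tab) {
  lab <- element
  has_h <- n_h > 0
  cand <- paste0(element, ifelse(n_h == 1, "H", paste0("H", n_h)))
  use <- has_h & cand %in% tab$label
  lab[use] <- cand[use]
  lab
}

# merge explicit hydrogens: drop them, counting those in non-dictionary
# residues toward the nearest heavy atom of the same residue
merge_hydrogens <- function(model) {
  at <- model$atoms
  is_h <- at$element %in% c("H", "D")
  if (!any(is_h)) return(model)
  heavy <- at[!is_h, , drop = FALSE]
  hyd <- at[is_h, , drop = FALSE]
  heavy$n_h_merged <- 0
  indict <- toupper(hyd$resname) %in%
    c(names(aa_sidechains), names(nt_resnames), water_resnames)
  hyd <- hyd[!indict, , drop = FALSE]
  if (nrow(hyd) > 0) {
    key_h <- paste(hyd$chain, hyd$resno, hyd$resname)
    key_a <- paste(heavy$chain, heavy$resno, heavy$resname)
    for (i in seq_len(nrow(hyd))) {
      j <- which(key_a == key_h[i])
      if (length(j) == 0) next
      d2 <- (heavy$x[j] - hyd$x[i])^2 + (heavy$y[j] - hyd$y[i])^2 +
        (heavy$z[j] - hyd$z[i])^2
      heavy$n_h_merged[j[which.min(d2)]] <-
        heavy$n_h_merged[j[which.min(d2)]] + 1
    }
  }
  model$atoms <- heavy
  model
}

#' Effective (contrast) electron numbers
#'
#' \eqn{\Delta Z_j = Z_j - \rho_s V_j} per atom: the net electrons of the
#' group over the displaced solvent.  May be negative (e.g. a CH2 group in
#' water).
#'
#' @param model a typed [structure_model()].
#' @param solvent_ed override the model's solvent electron density.
#' @return numeric vector, one \eqn{\Delta Z} per atom.
#' @export
effective_electrons <- function(model, solvent_ed = NULL) {
  check_typed(model)
  rho <- if (is.null(solvent_ed)) model$solvent_ed else solvent_ed
  model$atoms$z_el - rho * model$atoms$volume
}

#' Largest intra-particle pair distance (true Dmax)
#'
#' Exact maximum over all pairs of site-centre distances.
#'
#' @param model a [structure_model()] with at least two atoms.
#' @return Dmax in \eqn{\mathrm{\AA}}.
#' @export
max_pair_distance <- function(model) {
  at <- model$atoms
  if (nrow(at) < 2) stop("need at least 2 atoms for a pair distance")
  cpp_max_pair_dist(at$x, at$y, at$z)
}

check_typed <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$types) || is.null(model$atoms$type_index))
    stop("model has no atom types; call assign_atom_types() first")
  invisible(model)
}

#' Subset a structure model
#'
#' @param model a [structure_model()].
#' @param idx integer atom indices to keep.
#' @return A [structure_model()] with the same type registry.
#' @export
subset_model <- function(model, idx) {
  stopifnot(inherits(model, "structure_model"))
  m <- model
  m$atoms <- model$atoms[idx, , drop = FALSE]
  rownames(m$atoms) <- NULL
  m
}

#' Concatenate structure models
#'
#' Atom records are stacked and the type registries merged; both models
#' must share the same solvent electron density.
#'
#' @param a,b typed [structure_model()] objects.
#' @return A [structure_model()].
#' @export
combine_models <- function(a, b) {
  check_typed(a); check_typed(b)
  if (!isTRUE(all.equal(a$solvent_ed, b$solvent_ed)))
    stop("models have different solvent_ed")
  labs <- union(a$types$label, b$types$label)
  types <- rbind(a$types, b$types[!b$types$label %in% a$types$label, ,
                                  drop = FALSE])
  types <- types[match(labs, types$label), , drop = FALSE]
  rownames(types) <- NULL
  cols <- intersect(names(a$atoms), names(b$atoms))
  atoms <- rbind(a$atoms[, cols, drop = FALSE], b$atoms[, cols, drop = FALSE])
  atoms$type_index <- match(atoms$label, labs)
  m <- structure_model(atoms, solvent_ed = a$solvent_ed,
                       source = list(combined = TRUE))
  m$types <- types
  m
}

#' @export
print.structure_model <- function(x, ...) {
  nt <- if (is.null(x$types)) NA_integer_ else nrow(x$types)
  cat(sprintf("<structure_model: %d sites, %s type(s), solvent_ed = %.3f e/A^3>\n",
              nrow(x$atoms), nt, x$solvent_ed))
  if (!is.null(x$types))
    cat("  types:", paste(x$types$label, collapse = " "), "\n")
  invisible(x)
}

#' Number of distinct atom-group types in a model
#' @param model a typed [structure_model()].
#' @return integer N_T.
#' @export
n_types <- function(model) {
  check_typed(model)
  nrow(model$types)
}

# ---- selections -------------------------------------------------------------

#' Parse an atom selection
#'
#' Mini-language with clauses joined by `and`:
#' `"chain A"`, `"chains A,B"`, `"resname BCD"`, `"resi 1-12,30"`,
#' `"index 5-20"`.  A numeric vector is taken as explicit atom indices; a
#' list with fields `chain`, `resname`, `resno`, `index` is used directly.
#'
#' @param sel selection string, numeric index vector, or list.
#' @return A predicate specification consumed by [select_atoms()].
#' @export
parse_selection <- function(sel) {
  if (is.numeric(sel)) return(list(index = as.integer(sel)))
  if (is.list(sel)) return(sel)
  stopifnot(is.character(sel), length(sel) == 1)
  out <- list()
  for (clause in strsplit(sel, "\\s+and\\s+")[[1]]) {
    parts <- strsplit(trimws(clause), "\\s+")[[1]]
    if (length(parts) < 2) stop("cannot parse selection clause: ", clause)
    key <- tolower(parts[1])
    val <- paste(parts[-1], collapse = "")
    if (key %in% c("chain", "chains")) {
      out$chain <- strsplit(val, ",")[[1]]
    } else if (key == "resname") {
      out$resname <- toupper(strsplit(val, ",")[[1]])
    } else if (key %in% c("resi", "resno")) {
      out$resno <- parse_ranges(val)
    } else if (key == "index") {
      out$index <- parse_ranges(val)
    } else stop("unknown selection keyword: ", key)
  }
  out
}

parse_ranges <- function(s) {
  unlist(lapply(strsplit(s, ",")[[1]], function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq(ab[1], ab[2])
    } else as.integer(p)
  }))
}

#' Atom indices matching a selection
#'
#' @param model a [structure_model()].
#' @param sel anything [parse_selection()] accepts.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(model, sel) {
  sel <- parse_selection(sel)
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chain)) keep <- keep & at$chain %in% sel$chain
  if (!is.null(sel$resname)) keep <- keep & toupper(at$resname) %in% sel$resname
  if (!is.null(sel$resno)) keep <- keep & at$resno %in% sel$resno
  if (!is.null(sel$index)) keep <- keep & seq_len(nrow(at)) %in% sel$index
  which(keep)
}

# ---- internal site-list TSV (debugging / fixtures) --------------------------

#' Write and read the internal scattering-site list
#'
#' Plain TSV with columns label, x, y, z, z_el, volume, dz (and chain,
#' resno for selections); [read_sites_tsv()] reproduces the model exactly.
#'
#' @param model a typed [structure_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(model, path) {
  check_typed(model)
  at <- model$atoms
  df <- data.frame(label = at$label, x = at$x, y = at$y, z = at$z,
                   z_el = at$z_el, volume = at$volume,
                   dz = effective_electrons(model),
                   chain = at$chain, resno = at$resno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pddfsim sites v1 solvent_ed=%.17g", model$solvent_ed),
             con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  rho <- as.numeric(sub(".*solvent_ed=", "", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE,
                          colClasses = c(label = "character",
                                         chain = "character"))
  m <- structure_model(df[, c("x", "y", "z")], solvent_ed = rho,
                       source = list(file = path))
  m$atoms$label <- df$label
  m$atoms$chain <- df$chain
  m$atoms$resno <- df$resno
  m$atoms$z_el <- df$z_el
  m$atoms$volume <- df$volume
  labs <- unique(df$label)
  tab <- load_ff_table()
  ti <- match(labs, tab$label)
  m$types <- data.frame(
    label = labs,
    z = ifelse(is.na(ti), df$z_el[match(labs, df$label)], tab$z[ti]),
    volume = ifelse(is.na(ti), df$volume[match(labs, df$label)],
                    tab$volume[ti]),
    mass = ifelse(is.na(ti), NA_real_, tab$mass[ti]),
    point = is.na(ti), stringsAsFactors = FALSE)
  m$atoms$type_index <- match(df$label, labs)
  m
}
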