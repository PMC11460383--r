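#' Apparent versus true Dmax
#'
#' Theoretical PDDFs typically approach zero through a long shallow tail,
#' so the largest dimension read off a curve at any practical threshold
#' underestimates the true maximum pair distance.  This diagnostic reports
#' the apparent Dmax -- the largest grid point where P(r) still reaches a
#' stated fraction of the main-peak maximum (default 0.1%) -- next to the
#' exact Dmax of the coordinates.
#'
#' The threshold crossing is located on the stored grid without
#' interpolation and reported at the bin centre; the self-pair
#' contribution is excluded from the peak maximum (the separate self mass
#' always, and for analytic curves also the broadened self peak below
#' `r_min`).
#'
#' @param p a [pddf_curve()].
#' @param true_dmax exact largest pair distance of the structure
#'   (\eqn{\mathrm{\AA}}), from [max_pair_distance()].
#' @param threshold fraction of the peak maximum, in (0, 1); default 0.001.
#' @param r_min grid points below this are excluded from the peak search
#'   (analytic self peak); default 1.
#' @return A list of class `dmax_report`: `true_dmax`, `apparent_dmax`,
#'   `threshold`, `gap`, `method`, `dr`.
#' @export
apparent_dmax <- function(p, true_dmax, threshold = 0.001, r_min = 1) {
  stopifnot(inherits(p, "pddf_curve"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  main <- p$p[p$r >= r_min]
  if (all(p$p == 0)) stop("all-zero PDDF curve")
  pmax_ <- max(main)
  above <- which(p$p >= threshold * pmax_)
  apparent <- p$r[max(above)]
  apparent <- min(apparent, true_dmax)
  structure(list(true_dmax = true_dmax, apparent_dmax = apparent,
                 threshold = threshold, gap = true_dmax - apparent,
                 method = p$method, dr = p$dr),
            class = "dmax_report")
}

#' @export
print.dmax_report <- function(x, ...) {
  cat(sprintf(
    "<dmax_report [%s]: true %.2f A, apparent %.2f A at %.3g%% threshold, gap %.2f A>\n",
    x$method, x$true_dmax, x$apparent_dmax, 100 * x$threshold, x$gap))
  invisible(x)
}

#' Serialize a Dmax report to JSON
#' @param x a `dmax_report`.
#' @param path optional output file.
#' @return JSON string, invisibly if written to a file.
#' @export
dmax_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "dmax_report"))
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}

#' Normalize a PDDF for cross-assembly comparison
#'
#' Coordinate-based PDDFs are computed on the single-particle level
#' (`per_particle`, the identity), which is the correct footing for
#' comparing assemblies: curves then differ exactly by the added
#' component's self and cross terms.  `per_mass` divides by the molecular
#' weight (in kDa), mimicking PDDFs from scattering data normalized by
#' mass concentration instead of molar concentration -- provided to
#' demonstrate how that common practice distorts comparisons between
#' assemblies of different mass.
#'
#' @param p a [pddf_curve()].
#' @param mode `"per_particle"` or `"per_mass"`.
#' @param mw molecular weight in kDa (required for `per_mass`).
#' @return A [pddf_curve()].
#' @export
normalize_pddf <- function(p, mode = c("per_particle", "per_mass"), mw = NULL) {
  stopifnot(inherits(p, "pddf_curve"))
  mode <- match.arg(mode)
  if (mode == "per_particle") return(p)
  if (is.null(mw) || !is.numeric(mw) || mw <= 0)
    stop("per_mass normalization needs mw > 0 (kDa)")
  pddf_curve(p$r, p$p / mw, self_mass = p$self_mass / mw,
             method = p$method, meta = c(p$meta, list(normalized_by_mw = mw)))
}

#' Molecular weight of a model
#'
#' Sum of group masses (heavy atoms plus implicit hydrogens).
#'
#' @param model a typed [structure_model()].
#' @return Molecular weight in kDa.
#' @export
molecular_weight <- function(model) {
  check_typed(model)
  m <- model$atoms$mass
  if (is.null(m) || anyNA(m)) {
    tab <- load_ff_table()
    m <- tab$mass[match(model$atoms$label, tab$label)]
    if (anyNA(m))
      stop("mass unknown for label(s): ",
           paste(unique(model$atoms$label[is.na(m)]), collapse = ", "))
  }
  sum(m) / 1000
}
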