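#' Subunit decomposition of a PDDF
#'
#' Dissects the PDDF of a multi-subunit assembly into the PDDFs of the
#' individual subunits plus one inter-subunit distance-correlation curve
#' per subunit pair:
#' \deqn{P(r) = \sum_j P_j(r) + \sum_{j<k} P^{corr}_{jk}(r),}
#' where \eqn{P_j} is computed on subunit j alone and
#' \eqn{P^{corr}_{jk}} accumulates only cross pairs (one atom in j, one in
#' k), counting both ordered directions -- hence each correlation curve
#' carries the factor 2 of the dimer expansion and the identity above
#' holds bin-exactly.  Useful for identifying which structural unit or
#' unit-pair correlation a PDDF feature comes from.
#'
#' @param model a typed [structure_model()].
#' @param subunits named list of selections (anything [parse_selection()]
#'   accepts); must be disjoint and cover every atom.  Default: one
#'   subunit per chain.
#' @param method `"PC"`, `"DD"` or `"DH"`.
#' @param dr output grid step (\eqn{\mathrm{\AA}}).
#' @param dr_hist histogram bin width for `method = "DH"`.
#' @param r_max common grid maximum; defaults to the whole-model reach.
#' @return An object of class `pddf_decomposition`: `subunit` (named list
#'   of [pddf_curve()]), `correlation` (named list, names `"A|B"`),
#'   `total` ([pddf_curve()] of the whole model), `residual` (max absolute
#'   difference between the total and the summed parts).
#' @export
decompose_pddf <- function(model, subunits = NULL, method = c("PC", "DD", "DH"),
                           dr = 0.5, dr_hist = 0.2, r_max = NULL) {
  check_typed(model)
  method <- match.arg(method)
  at <- model$atoms
  n <- nrow(at)
  if (is.null(subunits)) {
    ch <- unique(at$chain)
    subunits <- lapply(ch, function(x) list(chain = x))
    names(subunits) <- ch
  }
  if (is.null(names(subunits)) || any(names(subunits) == ""))
    names(subunits) <- paste0("S", seq_along(subunits))
  idx <- lapply(subunits, function(s) select_atoms(model, s))
  cover <- unlist(idx)
  if (anyDuplicated(cover))
    stop("subunit selections overlap (atoms ",
         paste(utils::head(unique(cover[duplicated(cover)]), 10),
               collapse = ","), ")")
  uncovered <- setdiff(seq_len(n), cover)
  if (length(uncovered))
    stop("subunit selections do not cover atoms ",
         paste(utils::head(uncovered, 10), collapse = ","),
         if (length(uncovered) > 10) " ..." else "")

  # common r grid from the whole model
  dmax <- max_pair_distance(model)
  prods <- if (method == "PC") NULL else
    type_pair_products(model$types, model$solvent_ed)
  if (is.null(r_max))
    r_max <- dmax + if (method == "PC") 2 * dr else
      kernel_pad(prods$max_d, dr)
  nr <- as.integer(floor(r_max / dr + 0.5)) + 1L
  rmx <- (nr - 1) * dr

  sub_curve <- function(i) {
    m <- subset_model(model, i)
    switch(method,
      PC = pc_pddf(m, dr = dr, r_max = rmx),
      DD = dd_pddf(m, dr = dr, r_max = rmx),
      DH = dh_pddf(build_histograms(m, dr = dr_hist), dr = dr, r_max = rmx))
  }
  corr_curve <- function(i, j) {
    a <- model$atoms[i, ]; b <- model$atoms[j, ]
    ta <- as.integer(a$type_index) - 1L
    tb <- as.integer(b$type_index) - 1L
    if (method == "PC") {
      dza <- a$z_el - model$solvent_ed * a$volume
      dzb <- b$z_el - model$solvent_ed * b$volume
      bins <- cpp_cross_weighted_hist(a$x, a$y, a$z, dza,
                                      b$x, b$y, b$z, dzb, dr, nr)
      pddf_curve((seq_len(nr) - 1) * dr, bins / bin_widths(nr, dr), 0,
                 "partial")
    } else if (method == "DD") {
      acc <- cpp_cross_dd_pddf(a$x, a$y, a$z, ta, b$x, b$y, b$z, tb,
                               nrow(model$types), prods$c, prods$d,
                               prods$nterms, dr, nr)
      pddf_curve((seq_len(nr) - 1) * dr, acc / bin_widths(nr, dr), 0,
                 "partial")
    } else {
      nbins <- as.integer(floor(dmax / dr_hist + 0.5)) + 1L
      cube <- cpp_cross_typed_hist(a$x, a$y, a$z, ta, b$x, b$y, b$z, tb,
                                   nrow(model$types), dr_hist, nbins)
      acc <- cpp_dh_pddf(cube, numeric(nrow(model$types)),
                         nrow(model$types), nbins, dr_hist,
                         prods$c, prods$d, prods$nterms, dr, nr)
      pddf_curve((seq_len(nr) - 1) * dr, acc / bin_widths(nr, dr), 0,
                 "partial")
    }
  }

  parts <- lapply(idx, sub_curve)
  nms <- names(subunits)
  corr <- list()
  if (length(idx) > 1)
    for (a in seq_len(length(idx) - 1))
      for (b in seq((a + 1), length(idx)))
        corr[[paste(nms[a], nms[b], sep = "|")]] <- corr_curve(idx[[a]], idx[[b]])

  total <- switch(method,
    PC = pc_pddf(model, dr = dr, r_max = rmx),
    DD = dd_pddf(model, dr = dr, r_max = rmx),
    DH = dh_pddf(build_histograms(model, dr = dr_hist), dr = dr, r_max = rmx))

  psum <- Reduce(`+`, lapply(c(parts, corr), `[[`, "p"))
  ssum <- sum(vapply(parts, `[[`, 0, "self_mass"))
  resid <- max(abs(psum - total$p)) * dr + abs(ssum - total$self_mass)

  structure(list(subunit = parts, correlation = corr, total = total,
                 residual = resid, method = method, names = nms),
            class = "pddf_decomposition")
}

#' @export
print.pddf_decomposition <- function(x, ...) {
  cat(sprintf(
    "<pddf_decomposition [%s]: %d subunit(s), %d correlation curve(s), additivity residual = %.3g>\n",
    x$method, length(x$subunit), length(x$correlation), x$residual))
  invisible(x)
}

#' @export
plot.pddf_decomposition <- function(x, ...) {
  ymax <- max(x$total$p)
  ymin <- min(0, min(x$total$p),
              min(vapply(c(x$subunit, x$correlation),
                         function(cv) min(cv$p), 0)))
  plot(x$total$r, x$total$p, type = "l", lwd = 2, xlab = "r (A)",
       ylab = "P(r)", ylim = c(ymin, ymax), ...)
  cols <- seq_along(x$subunit) + 1
  for (i in seq_along(x$subunit))
    lines(x$subunit[[i]]$r, x$subunit[[i]]$p, col = cols[i])
  for (cv in x$correlation)
    lines(cv$r, cv$p, lty = 2, col = "grey40")
  legend("topright", bty = "n", lwd = c(2, rep(1, length(x$subunit))),
         col = c(1, cols), legend = c("total", x$names))
  invisible(x)
}
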