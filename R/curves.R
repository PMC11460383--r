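#' PDDF and scattering-curve containers
#'
#' `pddf_curve` holds a pair distance distribution function P(r) sampled on
#' a uniform r grid starting at 0 (bin centres `m * dr`), as a density in
#' effective-electrons squared per \eqn{\mathrm{\AA}}, plus a separate
#' `self_mass`: the weight of the self (j = k) pairs kept as a point mass
#' at r = 0 so the area identity and the Fourier transform's constant
#' offset stay exact.  `xs_curve` holds an intensity profile I(q) on a q
#' grid in \eqn{\mathrm{\AA}^{-1}}.
#'
#' @param r,p uniform r grid and density values.
#' @param self_mass total self-pair weight at r = 0 (not divided by the bin
#'   width).
#' @param method engine tag: `"PC"`, `"DD"`, `"DH"` or `"partial"`.
#' @param meta free-form provenance list.
#' @return An object of class `pddf_curve`.
#' @export
pddf_curve <- function(r, p, self_mass = 0, method = "PC", meta = list()) {
  stopifnot(length(r) == length(p), length(r) >= 2)
  dr <- r[2] - r[1]
  if (r[1] != 0) stop("r grid must start at 0")
  if (max(abs(diff(r) - dr)) > 1e-9 * dr) stop("r grid must be uniform")
  structure(list(r = r, p = p, dr = dr, self_mass = self_mass,
                 method = method, meta = meta),
            class = "pddf_curve")
}

#' @rdname pddf_curve
#' @param q,i q grid and intensities.
#' @export
xs_curve <- function(q, i, method = "PC", meta = list()) {
  stopifnot(length(q) == length(i))
  if (any(q < 0)) stop("negative q")
  structure(list(q = q, i = i, method = method, meta = meta),
            class = "xs_curve")
}

#' Area of a PDDF
#'
#' Trapezoidal integral of the density plus the self-pair mass; because
#' the r = 0 bin is half-width (its density divides by dr/2), the
#' trapezoid recovers every bin's mass and for every engine this
#' reproduces the square of the total effective electron number, which is
#' also the forward scattering I(0).
#'
#' @param p a [pddf_curve()].
#' @return numeric scalar.
#' @export
pddf_area <- function(p) {
  stopifnot(inherits(p, "pddf_curve"))
  n <- length(p$p)
  p$dr * (sum(p$p) - 0.5 * (p$p[1] + p$p[n])) + p$self_mass
}

#' @export
print.pddf_curve <- function(x, ...) {
  cat(sprintf("<pddf_curve [%s]: %d points, dr = %g A, r max = %g A, area = %.6g>\n",
              x$method, length(x$r), x$dr, max(x$r), pddf_area(x)))
  invisible(x)
}

#' @export
print.xs_curve <- function(x, ...) {
  cat(sprintf("<xs_curve [%s]: %d points, q in [%g, %g] 1/A, I(0) = %.6g>\n",
              x$method, length(x$q), min(x$q), max(x$q), x$i[which.min(x$q)]))
  invisible(x)
}

#' @export
plot.pddf_curve <- function(x, ..., xlab = "r (A)", ylab = "P(r)",
                            type = "l") {
  plot(x$r, x$p, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
plot.xs_curve <- function(x, ..., xlab = "q (1/A)", ylab = "I(q)",
                          log = "y", type = "l") {
  i <- x$i
  if (grepl("y", log) && any(i <= 0)) log <- sub("y", "", log)
  plot(x$q, i, type = type, xlab = xlab, ylab = ylab, log = log, ...)
  invisible(x)
}

#' Write curves as two-column ASCII
#'
#' Formats: `"# q(1/A) I(q)"` or `"# r(A) P(r)"` header, then
#' `"%.6e %.6e"` pairs, one per line.  For PDDFs the self mass is recorded
#' in a second header line; `include_self = FALSE` omits it.
#'
#' @param x a [pddf_curve()] or [xs_curve()].
#' @param path output file.
#' @param include_self record the r = 0 self mass header (PDDF only).
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path, include_self = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "xs_curve")) {
    writeLines("# q(1/A) I(q)", con)
    writeLines(sprintf("%.6e %.6e", x$q, x$i), con)
  } else if (inherits(x, "pddf_curve")) {
    writeLines("# r(A) P(r)", con)
    if (include_self && x$self_mass != 0)
      writeLines(sprintf("# self_mass %.17e", x$self_mass), con)
    writeLines(sprintf("%.6e %.6e", x$r, x$p), con)
  } else stop("not a curve object")
  invisible(path)
}

#' Read a two-column ASCII curve
#'
#' @param path file written by [write_curve()].
#' @param what `"auto"`, `"pddf"` or `"xs"`.
#' @return A [pddf_curve()] or [xs_curve()].
#' @export
read_curve <- function(path, what = "auto") {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  vals <- utils::read.table(text = lines[!startsWith(lines, "#")])
  if (what == "auto")
    what <- if (any(grepl("q\\(1/A\\)", hdr))) "xs" else "pddf"
  if (what == "xs") return(xs_curve(vals[[1]], vals[[2]]))
  self <- 0
  sm <- grep("# self_mass", hdr, value = TRUE)
  if (length(sm)) self <- as.numeric(sub("# self_mass ", "", sm[1]))
  pddf_curve(vals[[1]], vals[[2]], self_mass = self)
}

# bin m of a curve with step dr covers [max(0, (m - 1/2) dr), (m + 1/2) dr]:
# the r = 0 bin is half-width, so densities there divide by dr/2
bin_widths <- function(nr, dr) c(dr / 2, rep(dr, nr - 1L))

# mass-conserving split of a binned PDDF onto a finer quadrature set:
# returns list(r, mass) point masses (used by the Fourier transform when
# the input grid is coarser than target_dr)
pddf_quadrature_points <- function(p, target_dr = 0.1) {
  dr <- p$dr
  if (dr <= target_dr + 1e-12)
    return(list(r = p$r, mass = p$p * bin_widths(length(p$r), dr)))
  k <- as.integer(ceiling(dr / target_dr))
  m <- seq_along(p$r) - 1L
  e1 <- pmax(0, (m - 0.5) * dr)
  e2 <- (m + 0.5) * dr
  r <- unlist(lapply(seq_along(m), function(i) {
    e1[i] + (seq_len(k) - 0.5) * (e2[i] - e1[i]) / k
  }))
  mass <- rep(p$p * bin_widths(length(p$r), dr) / k, each = k)
  list(r = r, mass = mass)
}
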