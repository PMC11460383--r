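#' Gaussian sums
#'
#' A Gaussian sum represents a function of momentum transfer
#' \eqn{S(q) = \sum_l c_l \exp(-d_l q^2)} as a list of `(c, d)` term pairs.
#' Atomic form factors, excluded-solvent dummy-atom factors and their
#' differences and products are all closed under this algebra, which is what
#' makes the analytical Debye PDDF possible: the product of two atomic
#' factors is again a Gaussian sum, and each product term has an exact
#' closed-form inverse Fourier transform in r-space.
#'
#' A term with `d = 0` is a constant (a point charge); products involving it
#' remain valid.
#'
#' @param c numeric vector of amplitudes (electrons).
#' @param d numeric vector of exponents in \eqn{\mathrm{\AA}^2}; must be
#'   `>= 0` and the same length as `c`.
#' @return An object of class `gaussian_sum`.
#' @examples
#' g <- gaussian_sum(c = c(2, 1), d = c(0.1, 0.5))
#' evaluate_gaussian_sum(g, q = c(0, 1, 2))
#' @export
gaussian_sum <- function(c, d) {
  stopifnot(length(c) == length(d), length(c) >= 1L)
  if (any(!is.finite(c)) || any(!is.finite(d)) || any(d < 0))
    stop("gaussian_sum: exponents must be finite and >= 0")
  structure(list(c = as.numeric(c), d = as.numeric(d)),
            class = "gaussian_sum")
}

#' Evaluate a Gaussian sum on a q grid
#'
#' @param gs a [gaussian_sum()].
#' @param q numeric vector of momentum-transfer values (\eqn{\mathrm{\AA}^{-1}}).
#' @return numeric vector, \eqn{\sum_l c_l \exp(-d_l q^2)}.
#' @export
evaluate_gaussian_sum <- function(gs, q) {
  stopifnot(inherits(gs, "gaussian_sum"))
  drop(crossprod(gs$c, exp(-outer(gs$d, q^2))))
}

#' Product of two Gaussian sums
#'
#' Every cross pair of terms multiplies by the Gaussian product rule
#' \eqn{(c_a e^{-d_a q^2})(c_b e^{-d_b q^2}) = c_a c_b e^{-(d_a+d_b) q^2}},
#' so a product of sums with m and n terms has exactly m*n terms and its
#' evaluation equals the pointwise product of the factors.
#'
#' @param a,b [gaussian_sum()] objects.
#' @return A [gaussian_sum()] with `length(a$c) * length(b$c)` terms.
#' @export
gaussian_sum_product <- function(a, b) {
  stopifnot(inherits(a, "gaussian_sum"), inherits(b, "gaussian_sum"))
  gaussian_sum(c = as.vector(outer(a$c, b$c)),
               d = as.vector(outer(a$d, b$d, `+`)))
}

#' @export
print.gaussian_sum <- function(x, ...) {
  cat(sprintf("<gaussian_sum: %d terms, S(0) = %.6g>\n",
              length(x$c), sum(x$c)))
  invisible(x)
}
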