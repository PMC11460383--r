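#' Typed pair-distance histograms
#'
#' Builds the N_T x N_T family of pair-distance histograms
#' \eqn{H_{jk}(r_m)}: exact ordered-pair counts between atom types j and k
#' per distance bin (bin rule `round(r / dr)`, centres `m * dr`), with the
#' diagonal self pairs (one count per atom) stored separately per type so
#' the Debye diagonal stays exact.  This is the precomputation that makes
#' the DH engines O(N_T^2 N_R) instead of O(N_A^2) per curve; building the
#' histogram itself is the O(N_A^2) step.
#'
#' @param model a typed [structure_model()].
#' @param dr histogram bin width (\eqn{\mathrm{\AA}}); default 0.2.
#' @return An object of class `typed_pair_histogram`: fields `labels`,
#'   `dr`, `counts` (nbins x N_T x N_T array), `self_counts`, `types`,
#'   `solvent_ed`, `n_atoms`.
#' @export
build_histograms <- function(model, dr = 0.2) {
  check_typed(model)
  if (!is.numeric(dr) || dr <= 0) stop("dr must be > 0")
  at <- model$atoms
  nt <- nrow(model$types)
  dmax <- if (nrow(at) > 1) cpp_max_pair_dist(at$x, at$y, at$z) else 0
  nbins <- as.integer(floor(dmax / dr + 0.5)) + 1L
  est_bytes <- 8 * as.numeric(nbins) * nt * nt
  if (est_bytes > 4e9)
    stop(sprintf("histogram would need %.1f GB; increase dr", est_bytes / 1e9))
  h <- cpp_typed_hist(at$x, at$y, at$z, as.integer(at$type_index) - 1L,
                      nt, dr, nbins)
  structure(list(labels = model$types$label, dr = dr,
                 counts = array(h$cube, dim = c(nbins, nt, nt)),
                 self_counts = h$self_counts,
                 types = model$types, solvent_ed = model$solvent_ed,
                 n_atoms = nrow(at), dmax = dmax),
            class = "typed_pair_histogram")
}

#' @export
print.typed_pair_histogram <- function(x, ...) {
  cat(sprintf(
    "<typed_pair_histogram: %d types, dr = %g A, %d bins, %d atoms, total pairs = %g>\n",
    length(x$labels), x$dr, dim(x$counts)[1], x$n_atoms,
    sum(x$counts) + sum(x$self_counts)))
  invisible(x)
}

#' Distance-histogram scattering profile
#'
#' The Debye sum evaluated over typed histogram bins instead of atom
#' pairs:
#' \deqn{I(q) = \sum_{jk} \sum_m H_{jk}(r_m) A_j(q) A_k(q)
#'       \mathrm{sinc}(q r_m) + \sum_t n_t A_t(q)^2,}
#' which reproduces [dd_xs()] in the fine-bin limit and satisfies
#' \eqn{I(0) = (\sum \Delta Z)^2} exactly for any bin width.
#'
#' @param h a [build_histograms()] result.
#' @param q momentum-transfer grid.
#' @param solvent_ed override the stored solvent electron density.
#' @return An [xs_curve()] with method `"DH"`.
#' @export
dh_xs <- function(h, q = default_q_grid(), solvent_ed = NULL) {
  stopifnot(inherits(h, "typed_pair_histogram"))
  if (any(q < 0)) stop("negative q")
  rho <- if (is.null(solvent_ed)) h$solvent_ed else solvent_ed
  Amat <- type_ff_matrix(h$types, rho, q)
  nt <- length(h$labels)
  nbins <- dim(h$counts)[1]
  i <- cpp_dh_xs(as.numeric(h$counts), h$self_counts, nt, nbins, h$dr,
                 Amat, q)
  xs_curve(q, i, method = "DH",
           meta = list(n_atoms = h$n_atoms, n_types = nt, dr_hist = h$dr))
}

#' Distance-histogram analytical PDDF
#'
#' [dd_pddf()]'s analytic Gaussian kernel applied per (type pair, bin)
#' with weight \eqn{H_{jk}(r_m)} instead of per atom pair; self counts use
#' the self-pair kernel.  Same conservation contract as the direct
#' engine.
#'
#' @param h a [build_histograms()] result.
#' @param dr output grid step (\eqn{\mathrm{\AA}}); default 0.5.
#' @param r_max largest grid point; defaults to the histogram reach plus
#'   kernel padding.
#' @param solvent_ed override the stored solvent electron density.
#' @return A [pddf_curve()] with method `"DH"`.
#' @export
dh_pddf <- function(h, dr = 0.5, r_max = NULL, solvent_ed = NULL) {
  stopifnot(inherits(h, "typed_pair_histogram"))
  if (!is.numeric(dr) || dr <= 0) stop("dr must be > 0")
  rho <- if (is.null(solvent_ed)) h$solvent_ed else solvent_ed
  prods <- type_pair_products(h$types, rho)
  nt <- length(h$labels)
  nbins <- dim(h$counts)[1]
  if (is.null(r_max))
    r_max <- (nbins - 1) * h$dr + kernel_pad(prods$max_d, dr)
  nr <- as.integer(floor(r_max / dr + 0.5)) + 1L
  acc <- cpp_dh_pddf(as.numeric(h$counts), h$self_counts, nt, nbins, h$dr,
                     prods$c, prods$d, prods$nterms, dr, nr)
  pddf_curve(r = (seq_len(nr) - 1) * dr, p = acc / bin_widths(nr, dr),
             self_mass = 0, method = "DH",
             meta = list(n_atoms = h$n_atoms, dr = dr, dr_hist = h$dr))
}

#' Save / load a typed histogram as TSV
#'
#' Versioned plain-text cache so expensive histogram builds are reusable:
#' a header with labels, bin width, self counts and atom count, then one
#' row per non-empty (type pair, bin) cell.
#'
#' @param h a [build_histograms()] result.
#' @param path output file.
#' @return `path` (write) or the histogram (read).
#' @export
write_histograms <- function(h, path) {
  stopifnot(inherits(h, "typed_pair_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pddfsim typed_pair_histogram v1",
               paste0("# labels\t", paste(h$labels, collapse = "\t")),
               sprintf("# dr\t%.17g", h$dr),
               sprintf("# n_atoms\t%d", h$n_atoms),
               sprintf("# dmax\t%.17g", h$dmax),
               sprintf("# solvent_ed\t%.17g", h$solvent_ed),
               paste0("# self_counts\t",
                      paste(sprintf("%.17g", h$self_counts), collapse = "\t")),
               sprintf("# nbins\t%d", dim(h$counts)[1]),
               "type_j\ttype_k\tbin\tcount"), con)
  idx <- which(h$counts != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    keep <- idx[, 2] <= idx[, 3]  # store upper triangle, symmetric
    idx <- idx[keep, , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%d\t%.17g", idx[, 2], idx[, 3], idx[, 1] - 1L,
                       h$counts[idx]), con)
  }
  invisible(path)
}

#' @rdname write_histograms
#' @export
read_histograms <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  gethdr <- function(key) {
    l <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)[1]
    strsplit(sub(paste0("^# ", key, "\t"), "", l), "\t")[[1]]
  }
  labels <- gethdr("labels")
  dr <- as.numeric(gethdr("dr"))
  n_atoms <- as.integer(gethdr("n_atoms"))
  dmax <- as.numeric(gethdr("dmax"))
  rho <- as.numeric(gethdr("solvent_ed"))
  selfc <- as.numeric(gethdr("self_counts"))
  nbins <- as.integer(gethdr("nbins"))
  nt <- length(labels)
  counts <- array(0, dim = c(nbins, nt, nt))
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # column header
  if (length(body)) {
    df <- utils::read.table(text = body, sep = "\t",
                            col.names = c("j", "k", "bin", "count"))
    counts[cbind(df$bin + 1L, df$j, df$k)] <- df$count
    counts[cbind(df$bin + 1L, df$k, df$j)] <- df$count
  }
  tab <- load_ff_table()
  ti <- match(labels, tab$label)
  types <- data.frame(label = labels,
                      z = tab$z[ti], volume = tab$volume[ti],
                      mass = tab$mass[ti], point = is.na(ti),
                      stringsAsFactors = FALSE)
  structure(list(labels = labels, dr = dr, counts = counts,
                 self_counts = selfc, types = types, solvent_ed = rho,
                 n_atoms = n_atoms, dmax = dmax),
            class = "typed_pair_histogram")
}
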