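#' Atomic scattering factors and direct structure-factor summation
#'
#' X-ray form factors use the standard four-Gaussian-plus-constant
#' parameterization (five terms) from the International Tables:
#' f(s) = sum_i a_i exp(-b_i s^2) + c with s = sin(theta)/lambda = 1/(2d).
#' The table covers the elements that occur in the package's models; f(0)
#' equals the electron count of the neutral atom.
#'
#' @name scattering
#' @keywords internal
NULL

.CROMER_MANN <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  Se = list(a = c(17.0006, 5.81960, 3.97310, 4.35430),
            b = c(2.40980, 0.272600, 15.2372, 43.8163), c = 2.84090)
)

#' Form factor f(s^2) for one element at squared scattering vector s2 = 1/(2d)^2
#' @noRd
form_factor <- function(element, s2) {
  el <- normalize_element(element)
  cm <- .CROMER_MANN[[el]]
  if (is.null(cm)) {
    stop("no scattering factors tabulated for element '", el, "'",
         call. = FALSE)
  }
  f <- rep(cm$c, length(s2))
  for (i in seq_along(cm$a)) f <- f + cm$a[i] * exp(-cm$b[i] * s2)
  f
}

#' Structure factors by direct summation over atoms
#'
#' F(h) = sum_j occ_j f_j(s) exp(-B s^2) exp(2 pi i h . x_j) with fractional
#' coordinates x_j and a single isotropic B factor applied to every atom.
#' Hydrogens contribute their (small) tabulated form factor; waters
#' contribute as oxygen. No bulk-solvent term is modeled: difference maps
#' are dominated by local features, and the same convention is used by both
#' the synthetic generator and the phase calculation so the two stay
#' consistent.
#'
#' @param model an [atomic_model] with a unit cell.
#' @param hkl integer n x 3 matrix of Miller indices.
#' @param b_factor isotropic Debye-Waller B (Angstrom^2) applied uniformly.
#' @return complex vector of length `nrow(hkl)`.
#' @export
calc_structure_factors <- function(model, hkl, b_factor = 20) {
  if (is.null(model$cell)) stop("model has no unit cell", call. = FALSE)
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  at <- model$atoms
  keep <- toupper(at$element) %in% toupper(names(.CROMER_MANN))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("model has no atoms with tabulated form factors",
                      call. = FALSE)
  frac <- t(frac_matrix(model$cell) %*% t(as.matrix(at[, c("x", "y", "z")])))
  d <- d_spacing(hkl, model$cell)
  s2 <- ifelse(is.finite(d), 1 / (4 * d^2), 0)
  dw <- exp(-b_factor * s2)
  Fout <- complex(real = numeric(nrow(hkl)), imaginary = numeric(nrow(hkl)))
  el <- normalize_element(at$element)
  chunk <- 4000L
  starts <- seq(1L, nrow(hkl), by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, nrow(hkl))
    ph <- 2 * pi * (hkl[idx, , drop = FALSE] %*% t(frac))  # n_chunk x n_atom
    E <- exp(1i * ph)
    acc <- complex(real = numeric(length(idx)), imaginary = numeric(length(idx)))
    for (e in unique(el)) {
      j <- el == e
      v <- E[, j, drop = FALSE] %*% at$occupancy[j]
      acc <- acc + form_factor(e, s2[idx]) * as.vector(v)
    }
    Fout[idx] <- acc * dw[idx]
  }
  Fout
}
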