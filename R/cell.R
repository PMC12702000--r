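#' Unit-cell geometry helpers
#'
#' A unit cell is stored as a named numeric vector
#' `c(a, b, c, alpha, beta, gamma)` with lengths in Angstrom and angles in
#' degrees. These helpers provide the orthogonalization matrix (fractional ->
#' Cartesian), cell volume, resolution of Miller indices, and the canonical
#' (Friedel-reduced) hemisphere used to join reflection sets.
#'
#' @name cell-helpers
#' @keywords internal
NULL

new_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  validate_cell(cell)
  cell
}

validate_cell <- function(cell) {
  if (length(cell) != 6 || any(!is.finite(cell))) {
    stop("unit cell must be six finite numbers (a, b, c, alpha, beta, gamma)",
         call. = FALSE)
  }
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive", call. = FALSE)
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  invisible(cell)
}

#' Orthogonalization matrix (fractional -> Cartesian, PDB convention)
#' @noRd
orth_matrix <- function(cell) {
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  al <- cell[[4]] * pi / 180; be <- cell[[5]] * pi / 180; ga <- cell[[6]] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), cc * cos(be),
    0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0,           cc * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

frac_matrix <- function(cell) solve(orth_matrix(cell))

cell_volume <- function(cell) {
  det(orth_matrix(cell))
}

cells_compatible <- function(cell1, cell2, tol = 0.01) {
  all(abs(cell1 - cell2) <= tol * pmax(abs(cell1), abs(cell2)))
}

#' Resolution (d-spacing, Angstrom) of Miller indices
#'
#' Uses the reciprocal metric tensor, so any cell geometry is supported.
#' `hkl` is an n x 3 matrix; (0,0,0) maps to `Inf`.
#' @noRd
d_spacing <- function(hkl, cell) {
  A <- orth_matrix(cell)
  Gstar <- solve(t(A) %*% A)
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  inv_d2 <- rowSums((hkl %*% Gstar) * hkl)
  d <- rep(Inf, nrow(hkl))
  pos <- inv_d2 > 0
  d[pos] <- 1 / sqrt(inv_d2[pos])
  d
}

#' Canonical Friedel hemisphere representative of (h,k,l)
#'
#' Amplitudes are Friedel-invariant, so each reflection is keyed by the
#' representative with h > 0, or h = 0 & k > 0, or h = k = 0 & l >= 0.
#' @noRd
canonical_hkl <- function(hkl) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  flip <- hkl[, 1] < 0 |
    (hkl[, 1] == 0 & hkl[, 2] < 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] < 0)
  hkl[flip, ] <- -hkl[flip, , drop = FALSE]
  hkl
}

hkl_key <- function(hkl) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  paste(hkl[, 1], hkl[, 2], hkl[, 3], sep = ",")
}

#' All unique Miller indices (canonical Friedel hemisphere) to a resolution
#'
#' @param cell unit cell (a, b, c, alpha, beta, gamma).
#' @param d_min high-resolution limit in Angstrom.
#' @param include_f000 include the (0,0,0) term.
#' @return Integer n x 3 matrix with columns `h`, `k`, `l`.
#' @export
generate_hkl <- function(cell, d_min, include_f000 = TRUE) {
  A <- orth_matrix(cell)
  astar <- sqrt(diag(solve(t(A) %*% A)))
  hmax <- ceiling(1 / (d_min * astar))
  grid <- expand.grid(h = 0:hmax[1], k = -hmax[2]:hmax[2], l = -hmax[3]:hmax[3])
  grid <- as.matrix(grid)
  keep <- grid[, 1] > 0 |
    (grid[, 1] == 0 & grid[, 2] > 0) |
    (grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] >= 0)
  grid <- grid[keep, , drop = FALSE]
  d <- d_spacing(grid, cell)
  grid <- grid[d >= d_min, , drop = FALSE]
  if (!include_f000) {
    grid <- grid[!(grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] == 0), ,
                 drop = FALSE]
  }
  storage.mode(grid) <- "integer"
  dimnames(grid) <- list(NULL, c("h", "k", "l"))
  grid
}

#' Next 5-smooth integer >= n (efficient FFT length)
#' @noRd
good_fft_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Deterministic sub-seed for a named random substream
#'
#' All generator randomness flows from one top-level seed through named
#' substreams so each stage is independently reproducible.
#' @noRd
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

res_key <- function(chain, resnum) paste0(chain, ":", resnum)

parse_res_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resnum = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}
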