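#' Density grids and per-residue difference-density scoring
#'
#' A `density_grid` is a real 3-D array sampling the unit cell, with grid
#' point (1,1,1) at fractional (0,0,0) and axis i sampled at fractional
#' (j-1)/dim_i. Values are on the absolute electron-density scale
#' (e-/Angstrom^3) when the input amplitudes are in electrons.
#'
#' @param data numeric 3-D array.
#' @param cell unit cell.
#' @param units value-unit label.
#' @export
density_grid <- function(data, cell, units = "e/A^3") {
  if (length(dim(data)) != 3 || any(dim(data) < 2)) {
    stop("density grid must be a 3-D array with >= 2 points per axis",
         call. = FALSE)
  }
  if (!all(is.finite(data))) stop("density grid contains non-finite values",
                                  call. = FALSE)
  validate_cell(cell)
  structure(list(data = data, cell = cell, units = units),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid> ", paste(dim(x$data), collapse = " x "),
      " (", x$units, "), rms ", signif(stats::sd(as.vector(x$data)), 4),
      "\n", sep = "")
  invisible(x)
}

#' Synthesize a difference density map by inverse Fourier transform
#'
#' Places the coefficients {w dF, phi} on a reciprocal grid, applies Friedel
#' completion (F(-h) = conj(F(h))), and inverse-transforms:
#' rho(x) = (1/V) sum_h F_h exp(i phi_h) exp(-2 pi i h.x).
#' The grid spacing is at most d_min / `grid_spacing_factor` per axis
#' (factor 3 by default), which also keeps every index inside Nyquist so
#' the synthesis is alias-free.
#'
#' @param diffs a [weighted_differences] object (phases present).
#' @param grid_spacing_factor oversampling factor relative to d_min.
#' @return A [density_grid] in e-/Angstrom^3 (for amplitudes in electrons).
#' @export
synthesize_map <- function(diffs, grid_spacing_factor = 3) {
  if (is.null(diffs$phi) || any(!is.finite(diffs$phi))) {
    stop("phases missing: run weighted_differences() with a phase source",
         call. = FALSE)
  }
  cell <- attr(diffs, "cell")
  d_min <- attr(diffs, "d_min")
  if (is.null(d_min) || !is.finite(d_min)) {
    stop("resolution limit d_min unknown", call. = FALSE)
  }
  dims <- vapply(cell[1:3], function(len) {
    good_fft_size(max(4, ceiling(len * grid_spacing_factor / d_min)))
  }, 0L)
  hmax_allowed <- (dims - 1) %/% 2
  hkl <- as.matrix(diffs[, c("h", "k", "l")])
  if (any(abs(hkl) > matrix(hmax_allowed, nrow(hkl), 3, byrow = TRUE))) {
    stop("grid too coarse for the data; increase grid_spacing_factor",
         call. = FALSE)
  }
  coef <- complex(modulus = diffs$wdF, argument = diffs$phi * pi / 180)
  arr <- array(complex(real = 0, imaginary = 0), dim = dims)
  put <- function(h, val) {
    # coefficient F_h goes to index (-h mod N): fft(..., inverse = TRUE)
    # applies exp(+2 pi i m.n/N) and rho uses exp(-2 pi i h.x)
    i <- (-h[, 1]) %% dims[1] + 1L
    j <- (-h[, 2]) %% dims[2] + 1L
    k <- (-h[, 3]) %% dims[3] + 1L
    arr[cbind(i, j, k)] <<- arr[cbind(i, j, k)] + val
  }
  centro <- hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0
  put(hkl[!centro, , drop = FALSE], coef[!centro])
  put(-hkl[!centro, , drop = FALSE], Conj(coef[!centro]))
  if (any(centro)) put(hkl[centro, , drop = FALSE], Re(coef[centro]))
  V <- cell_volume(cell)
  rho <- Re(stats::fft(arr, inverse = TRUE)) / V
  density_grid(rho, cell)
}

#' Per-residue score tracks
#'
#' A `residue_track` is a per-residue scalar track: a data.frame with
#' columns `chain`, `resnum`, `resname`, `score` (plus optional `display`
#' and `neutral` columns added by downstream steps), with metadata recording
#' the modality and the thresholds that produced it. IADDAT tracks are
#' non-negative; HDX difference tracks are signed and may contain `NA` for
#' residues covered by no peptide.
#'
#' @param df data.frame with columns `chain`, `resnum`, `score` (and
#'   optionally `resname`).
#' @param modality label, e.g. `"iaddat"` or `"delta_hdx"`.
#' @param ... further metadata stored as attributes.
#' @export
residue_track <- function(df, modality = "score", ...) {
  if (is.null(df$resname)) df$resname <- NA_character_
  df <- df[order(df$chain, df$resnum),
           c("chain", "resnum", "resname", "score",
             intersect(c("display", "neutral"), names(df)))]
  rownames(df) <- NULL
  structure(df, modality = modality, ...,
            class = c("residue_track", "data.frame"))
}

#' @export
print.residue_track <- function(x, ...) {
  cat("<residue_track> ", attr(x, "modality"), ", ", nrow(x), " residues (",
      sum(is.na(x$score)), " missing)\n", sep = "")
  invisible(x)
}

#' Integrate absolute difference density above threshold (IADDAT)
#'
#' Every voxel whose |density| exceeds `threshold` and which lies within
#' `radius` of at least one protein heavy atom (waters and hydrogens
#' excluded; periodic minimum-image distances) is assigned to the residue of
#' the nearest such atom; ties go to the lower (chain, residue number). A
#' residue's score is the sum of |density| over its assigned voxels divided
#' by its number of heavy atoms (`denominator = "atoms"`, the default;
#' `"voxels"` divides by the number of assigned voxels, `"none"` leaves the
#' plain sum). Residues with no qualifying voxel score 0. Defaults:
#' threshold 0.04 e-/Angstrom^3, radius 1.5 Angstrom.
#'
#' @param grid a [density_grid].
#' @param model an [atomic_model] sharing the grid's unit cell.
#' @param threshold absolute density threshold, `>= 0` (in the map's units).
#' @param radius atom search radius in Angstrom, `> 0`.
#' @param denominator per-residue averaging convention.
#' @return A non-negative [residue_track] over all non-water residues of
#'   `model`.
#' @export
iaddat <- function(grid, model, threshold = 0.04, radius = 1.5,
                   denominator = c("atoms", "voxels", "none")) {
  denominator <- match.arg(denominator)
  stopifnot(threshold >= 0, radius > 0)
  if (is.null(model$cell) || !cells_compatible(grid$cell, model$cell)) {
    stop("grid and model do not share a unit cell", call. = FALSE)
  }
  ha <- heavy_atoms(model)
  res <- unique(ha[, c("chain", "resnum", "resname")])
  res <- res[order(res$chain, res$resnum), , drop = FALSE]
  keys <- res_key(res$chain, res$resnum)
  scores <- stats::setNames(numeric(length(keys)), keys)
  nvox <- stats::setNames(numeric(length(keys)), keys)
  natoms <- table(factor(res_key(ha$chain, ha$resnum), levels = keys))

  dims <- dim(grid$data)
  above <- which(abs(grid$data) > threshold)
  if (length(above) && nrow(ha)) {
    A <- orth_matrix(grid$cell)
    fa <- t(frac_matrix(grid$cell) %*% t(as.matrix(ha[, c("x", "y", "z")])))
    # atom residue index ordered so that ties at equal distance resolve to
    # the lower (chain, resnum): order atoms by residue rank, keep first min
    atom_res <- match(res_key(ha$chain, ha$resnum), keys)
    ord <- order(atom_res)
    fa <- fa[ord, , drop = FALSE]
    atom_res <- atom_res[ord]

    idx0 <- above - 1L
    i <- idx0 %% dims[1]
    j <- (idx0 %/% dims[1]) %% dims[2]
    k <- idx0 %/% (dims[1] * dims[2])
    fv <- cbind(i / dims[1], j / dims[2], k / dims[3])
    vals <- abs(grid$data[above])
    r2max <- radius^2
    chunk <- 2048L
    for (s0 in seq(1L, length(above), by = chunk)) {
      sel <- s0:min(s0 + chunk - 1L, length(above))
      best_d2 <- rep(Inf, length(sel))
      best_res <- rep(NA_integer_, length(sel))
      for (a in seq_len(nrow(fa))) {
        df <- fv[sel, , drop = FALSE] -
          matrix(fa[a, ], length(sel), 3, byrow = TRUE)
        df <- df - round(df)          # minimum image in fractional space
        dx <- df %*% t(A)
        d2 <- rowSums(dx * dx)
        better <- d2 < best_d2 - 1e-12
        best_d2[better] <- d2[better]
        best_res[better] <- atom_res[a]
      }
      ok <- best_d2 <= r2max
      if (any(ok)) {
        add <- tapply(vals[sel][ok], best_res[ok], sum)
        cnt <- tapply(rep(1, sum(ok)), best_res[ok], sum)
        ridx <- as.integer(names(add))
        scores[ridx] <- scores[ridx] + as.numeric(add)
        nvox[ridx] <- nvox[ridx] + as.numeric(cnt)
      }
    }
  }
  denom <- switch(denominator,
                  atoms = as.numeric(natoms),
                  voxels = ifelse(nvox > 0, nvox, 1),
                  none = rep(1, length(scores)))
  out <- data.frame(chain = res$chain, resnum = res$resnum,
                    resname = res$resname, score = scores / denom,
                    stringsAsFactors = FALSE)
  residue_track(out, modality = "iaddat", threshold = threshold,
                radius = radius, denominator = denominator,
                normalized = FALSE)
}

#' Normalize a residue track to [0, 1] with an optional display cap
#'
#' Divides every score by the maximum (a no-op on an all-zero track). With
#' `cap` given, a `display` column is added in which normalized values above
#' the cap are set to the cap; raw normalized scores are preserved in
#' `score`.
#'
#' @param track a non-negative [residue_track].
#' @param cap display cap on the normalized scale (e.g. 0.3), or `NULL`.
#' @export
normalize_track <- function(track, cap = NULL) {
  sc <- track$score
  if (any(sc < 0, na.rm = TRUE)) {
    stop("normalize_track requires non-negative scores", call. = FALSE)
  }
  m <- max(sc, na.rm = TRUE)
  if (is.finite(m) && m > 0) sc <- sc / m
  track$score <- sc
  if (!is.null(cap)) track$display <- pmin(sc, cap)
  attr(track, "normalized") <- TRUE
  attr(track, "cap") <- cap
  track
}

#' Write a residue track as CSV
#'
#' Columns: chain, resnum, resname, score, plus display/neutral when
#' present. Byte-deterministic for identical inputs.
#' @param track a [residue_track].
#' @param path output path.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a density grid as plain text (index + value per line)
#' @param grid a [density_grid].
#' @param path output path.
#' @export
write_grid_txt <- function(grid, path) {
  d <- dim(grid$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims %d %d %d cell %s", d[1], d[2], d[3],
                     paste(signif(grid$cell, 8), collapse = " ")), con)
  utils::write.table(
    data.frame(value = as.vector(grid$data)), con,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}
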