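#' Reflection sets
#'
#' A `reflection_set` holds merged structure-factor amplitudes: one row per
#' unique reflection with Miller indices, amplitude `F` (electrons for
#' synthetic data, arbitrary units otherwise) and its uncertainty `sigF`,
#' plus the unit cell, space group and resolution limits. Indices are stored
#' on the canonical Friedel hemisphere so that joins between datasets are by
#' exact (h,k,l) in a common asymmetric unit. Only space group P 1 is
#' handled; expand other symmetries to P 1 before import.
#'
#' @param hkl integer n x 3 matrix of Miller indices.
#' @param f amplitudes, `>= 0`.
#' @param sigf amplitude uncertainties, `>= 0`.
#' @param cell unit cell (see [atomic_model]).
#' @param spacegroup space-group symbol; must be P 1.
#' @param d_min high-resolution limit; computed from the data if `NULL`.
#' @return An object of class `reflection_set` (a data.frame with columns
#'   `h`, `k`, `l`, `F`, `sigF` and attributes `cell`, `spacegroup`,
#'   `d_min`, `d_max`).
#' @export
reflection_set <- function(hkl, f, sigf, cell, spacegroup = "P 1",
                           d_min = NULL) {
  validate_cell(cell)
  if (!identical(toupper(gsub(" ", "", spacegroup)), "P1")) {
    stop("only space group P 1 is supported; expand symmetry to P 1 first",
         call. = FALSE)
  }
  hkl <- canonical_hkl(hkl)
  if (anyDuplicated(hkl_key(hkl))) {
    stop("duplicate Miller indices after Friedel reduction", call. = FALSE)
  }
  if (any(f < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(sigf < 0)) stop("sigma(F) must be >= 0", call. = FALSE)
  d <- d_spacing(hkl, cell)
  df <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   F = as.numeric(f), sigF = as.numeric(sigf))
  structure(df,
            cell = cell, spacegroup = "P 1",
            d_min = if (is.null(d_min)) min(d) else d_min,
            d_max = max(d[is.finite(d)]),
            class = c("reflection_set", "data.frame"))
}

#' @export
print.reflection_set <- function(x, ...) {
  cat("<reflection_set> ", nrow(x), " unique reflections, d_min ",
      signif(attr(x, "d_min"), 4), " A\n", sep = "")
  invisible(x)
}

#' Read reflections from CSV (columns h,k,l,F,SIGF)
#'
#' @param path CSV file with a header naming columns `h`, `k`, `l`, `F`,
#'   `SIGF` (case-insensitive; `sigF` accepted).
#' @inheritParams reflection_set
#' @export
read_reflections_csv <- function(path, cell, spacegroup = "P 1") {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("h", "k", "l", "f", "sigf")
  if (!all(need %in% names(df))) {
    stop("reflection CSV must have columns h,k,l,F,SIGF", call. = FALSE)
  }
  reflection_set(as.matrix(df[, c("h", "k", "l")]), df$f, df$sigf,
                 cell = cell, spacegroup = spacegroup)
}

#' Write reflections to CSV
#' @param refl a [reflection_set].
#' @param path output path.
#' @export
write_reflections_csv <- function(refl, path) {
  out <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                    F = refl$F, SIGF = refl$sigF)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

join_reflections <- function(mut, wt) {
  km <- hkl_key(as.matrix(mut[, c("h", "k", "l")]))
  kw <- hkl_key(as.matrix(wt[, c("h", "k", "l")]))
  common <- intersect(km, kw)
  list(mut = match(common, km), wt = match(common, kw), n = length(common),
       only_mut = sum(!(km %in% kw)), only_wt = sum(!(kw %in% km)))
}

#' Scale a mutant dataset onto a reference (WT) dataset
#'
#' Least-squares isotropic scaling: the returned dataset is `mut` with
#' amplitudes multiplied by the scalar k minimizing
#' sum over common reflections of (k F_mut - F_WT)^2; sigmas scale by the
#' same k. Optionally the scale is determined per resolution bin.
#'
#' @param mut,wt [reflection_set]s on matching unit cells (within 1%).
#' @param bins number of equal-count resolution bins (1 = single scalar).
#' @return `mut`, rescaled; the scale(s) are attached as attribute `scale`.
#' @export
scale_to_reference <- function(mut, wt, bins = 1L) {
  if (!cells_compatible(attr(mut, "cell"), attr(wt, "cell"))) {
    stop("incompatible datasets: unit cells differ by more than 1%",
         call. = FALSE)
  }
  j <- join_reflections(mut, wt)
  if (j$n < 10) {
    stop("insufficient overlap: fewer than 10 common reflections",
         call. = FALSE)
  }
  fm <- mut$F[j$mut]; fw <- wt$F[j$wt]
  out <- mut
  if (bins <= 1L) {
    k <- sum(fm * fw) / sum(fm * fm)
    out$F <- mut$F * k
    out$sigF <- mut$sigF * k
    attr(out, "scale") <- k
  } else {
    d <- d_spacing(as.matrix(mut[j$mut, c("h", "k", "l")]), attr(mut, "cell"))
    brk <- stats::quantile(d, probs = seq(0, 1, length.out = bins + 1))
    brk[1] <- -Inf; brk[length(brk)] <- Inf
    bin_common <- cut(d, brk, labels = FALSE)
    ks <- vapply(seq_len(bins), function(b) {
      i <- bin_common == b
      sum(fm[i] * fw[i]) / sum(fm[i]^2)
    }, 0)
    d_all <- d_spacing(as.matrix(mut[, c("h", "k", "l")]), attr(mut, "cell"))
    bin_all <- cut(pmin(pmax(d_all, min(d)), max(d)), brk, labels = FALSE)
    out$F <- mut$F * ks[bin_all]
    out$sigF <- mut$sigF * ks[bin_all]
    attr(out, "scale") <- ks
  }
  out
}

#' Weighted isomorphous difference structure factors
#'
#' For each reflection common to the two (already scaled) datasets:
#' dF = F_mut - F_WT, sigma(dF)^2 = sigma_mut^2 + sigma_WT^2, and the
#' error-model weight
#' w = 1 / (1 + sigma(dF)^2/<sigma(dF)^2> + alpha dF^2/<dF^2>)
#' with <.> the mean over all common reflections. The alpha term (default
#' 0.05) down-weights outlier difference amplitudes. Phases are taken from
#' a reference model by direct structure-factor summation, so the map
#' coefficients are {w dF, phi_calc}. Reflections present in only one set
#' are dropped and counted in the attached report.
#'
#' @param mut,wt [reflection_set]s, already on a common scale.
#' @param alpha weight sharpness parameter, `>= 0`; default 0.05.
#' @param phase_source an [atomic_model] (typically the refined WT model).
#' @param b_factor isotropic B used in the phase calculation.
#' @return A `weighted_differences` object: data.frame with columns `h, k,
#'   l, dF, sigdF, w, wdF, phi` (phi in degrees), attributes `cell`,
#'   `d_min`, `alpha`, `report`.
#' @export
weighted_differences <- function(mut, wt, alpha = 0.05, phase_source,
                                 b_factor = 20) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  j <- join_reflections(mut, wt)
  if (j$n == 0) stop("no common reflections between datasets", call. = FALSE)
  dF <- mut$F[j$mut] - wt$F[j$wt]
  sig2 <- mut$sigF[j$mut]^2 + wt$sigF[j$wt]^2
  mean_sig2 <- mean(sig2)
  mean_dF2 <- mean(dF^2)
  sig_term <- if (mean_sig2 > 0) sig2 / mean_sig2 else 0
  dF_term <- if (mean_dF2 > 0) alpha * dF^2 / mean_dF2 else 0
  w <- 1 / (1 + sig_term + dF_term)
  hkl <- as.matrix(mut[j$mut, c("h", "k", "l")])
  Fc <- calc_structure_factors(phase_source, hkl, b_factor = b_factor)
  phi <- Arg(Fc) * 180 / pi
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    dF = dF, sigdF = sqrt(sig2), w = w, wdF = w * dF,
                    phi = phi)
  structure(out,
            cell = attr(wt, "cell"),
            d_min = max(attr(mut, "d_min"), attr(wt, "d_min")),
            alpha = alpha,
            report = list(n_common = j$n, dropped_mut_only = j$only_mut,
                          dropped_wt_only = j$only_wt),
            class = c("weighted_differences", "data.frame"))
}

#' @export
print.weighted_differences <- function(x, ...) {
  rep <- attr(x, "report")
  cat("<weighted_differences> ", nrow(x), " reflections (alpha = ",
      attr(x, "alpha"), "); dropped ", rep$dropped_mut_only, " mut-only, ",
      rep$dropped_wt_only, " wt-only\n", sep = "")
  invisible(x)
}
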