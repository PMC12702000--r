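#' Synthetic paired crystallography + HDX-MS data with known ground truth
#'
#' The generator emulates, at desk scale, the data a dual-modality allosteric
#' mapping study consumes: a small single-chain crystal in P1, a
#' mutation-like structural edit (side-chain deletion at the mutated site, a
#' new ordered water in its place, sub-Angstrom displacements of "tendril"
#' residue side chains), simulated merged reflection amplitudes with
#' Gaussian measurement noise, and pepsin-like HDX peptide tables with a
#' planted residue-level exchange difference. All randomness flows from one
#' top-level seed through named substreams so every stage is independently
#' reproducible.
#'
#' @name synthetic
NULL

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Build a toy single-chain crystal
#'
#' A poly-alanine-like alpha helix (2.3 Angstrom radius, 1.5 Angstrom rise,
#' 100 degrees per residue) with backbone atoms N, CA, C, O and three
#' side-chain pseudo-atoms CB, CG, OD1 pointing radially outward (7 heavy
#' atoms per residue), packed in an orthorhombic P1 cell with at least 4
#' Angstrom of padding around the molecule. Residue names follow a randomly
#' drawn 20-letter sequence (stored as attribute `sequence`) so the same
#' chain can drive the HDX generator.
#'
#' @param n_residues number of residues, 10..100.
#' @param seed integer seed (deterministic output per seed).
#' @return An [atomic_model] with attribute `sequence`.
#' @export
make_toy_crystal <- function(n_residues, seed = 1) {
  if (n_residues < 10 || n_residues > 100) {
    stop("n_residues must be in [10, 100]", call. = FALSE)
  }
  aa1 <- names(.RESIDUE_MASS)
  aa3 <- c(G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL", T = "THR",
           C = "CYS", L = "LEU", I = "ILE", N = "ASN", D = "ASP", Q = "GLN",
           K = "LYS", E = "GLU", M = "MET", H = "HIS", F = "PHE", R = "ARG",
           Y = "TYR", W = "TRP")
  set.seed(substream_seed(seed, "structure"))
  wts <- rep(1, 20); names(wts) <- aa1
  wts["P"] <- 0.4; wts["W"] <- 0.4   # scarce Pro/Trp, as in natural sequences
  sequence <- paste(sample(aa1, n_residues, replace = TRUE,
                           prob = wts / sum(wts)), collapse = "")
  i <- seq_len(n_residues)
  theta <- i * 100 * pi / 180
  ca <- cbind(1.5 * i, 2.3 * cos(theta), 2.3 * sin(theta))
  t_hat <- cbind(rep(1, n_residues), 0, 0)        # helix axis along x
  r_hat <- cbind(0, cos(theta), sin(theta))        # radial outward
  s_hat <- cbind(0, -sin(theta), cos(theta))       # tangential
  jit <- function(n) matrix(stats::rnorm(3 * n, sd = 0.05), ncol = 3)
  atoms <- list()
  for (r in i) {
    base <- ca[r, ]
    pos <- rbind(
      N   = base - 1.20 * t_hat[r, ] + 0.60 * s_hat[r, ],
      CA  = base,
      C   = base + 1.20 * t_hat[r, ] + 0.60 * s_hat[r, ],
      O   = base + 1.20 * t_hat[r, ] + 1.80 * s_hat[r, ],
      CB  = base + 1.53 * r_hat[r, ],
      CG  = base + 2.86 * r_hat[r, ] + 0.70 * t_hat[r, ],
      OD1 = base + 3.96 * r_hat[r, ] + 0.70 * t_hat[r, ] + 0.80 * s_hat[r, ])
    pos[5:7, ] <- pos[5:7, ] + jit(3)
    atoms[[r]] <- data.frame(
      chain = "A", resnum = r,
      resname = unname(aa3[substr(sequence, r, r)]),
      atom = rownames(pos),
      element = substr(rownames(pos), 1, 1),
      x = unname(pos[, 1]), y = unname(pos[, 2]), z = unname(pos[, 3]),
      occupancy = 1, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, atoms)
  rownames(at) <- NULL
  pad <- 4
  for (ax in c("x", "y", "z")) at[[ax]] <- at[[ax]] - min(at[[ax]]) + pad
  cell <- new_cell(max(at$x) + pad, max(at$y) + pad, max(at$z) + pad)
  model <- atomic_model(at, cell = cell, spacegroup = "P 1")
  attr(model, "sequence") <- sequence
  model
}

is_sidechain <- function(atom_names) !(atom_names %in% .BACKBONE_ATOMS)

#' Apply a mutation-like structural edit
#'
#' Emulates the structural signature of a destabilizing point mutation:
#' deletes the side-chain atoms at `site`, adds one ordered water at the
#' centroid of the deleted atoms, and displaces the side-chain atoms of each
#' tendril residue by exactly `shift_A` Angstrom in independent seeded
#' random directions (so the RMSD over displaced atoms equals `shift_A`).
#'
#' @param model an [atomic_model] from [make_toy_crystal].
#' @param site residue number of the mutated site.
#' @param tendril integer residue numbers of the allosteric tendril.
#' @param shift_A displacement magnitude, Angstrom (default 0.5).
#' @param seed integer seed.
#' @param chain chain id.
#' @return `list(model = edited atomic_model, truth = ground-truth list)`.
#'   The truth records the site, tendril, deleted/shifted atoms, added
#'   water, and seed.
#' @export
apply_mutation_like_edit <- function(model, site, tendril = integer(0),
                                     shift_A = 0.5, seed = 1, chain = "A") {
  at <- model$atoms
  have <- unique(at$resnum[at$chain == chain & !at$water])
  missing <- setdiff(c(site, tendril), have)
  if (length(missing)) {
    stop("residue(s) not in model: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "mutation"))
  del <- at$chain == chain & at$resnum == site & is_sidechain(at$atom) &
    !at$water
  deleted <- at[del, , drop = FALSE]
  centroid <- colMeans(deleted[, c("x", "y", "z"), drop = FALSE])
  at <- at[!del, , drop = FALSE]
  shifted <- data.frame()
  if (length(tendril) && shift_A != 0) {
    mv <- at$chain == chain & at$resnum %in% tendril &
      is_sidechain(at$atom) & !at$water
    n <- sum(mv)
    dir <- matrix(stats::rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    shifted <- at[mv, , drop = FALSE]
    at[mv, c("x", "y", "z")] <- at[mv, c("x", "y", "z")] + shift_A * dir
  } else if (length(tendril)) {
    shifted <- at[at$chain == chain & at$resnum %in% tendril &
                    is_sidechain(at$atom) & !at$water, , drop = FALSE]
  }
  water <- data.frame(chain = chain, resnum = max(have) + 500L,
                      resname = "HOH", atom = "O", element = "O",
                      x = centroid[1], y = centroid[2], z = centroid[3],
                      occupancy = 1, altloc = "",
                      stringsAsFactors = FALSE)
  at$altloc <- at$altloc %||% ""
  at <- rbind(at[, names(water)], water)
  edited <- atomic_model(at, cell = model$cell, spacegroup = model$spacegroup)
  attr(edited, "sequence") <- attr(model, "sequence")
  truth <- list(site = site, tendril = tendril,
                perturbed_residues = sort(unique(c(site, tendril))),
                deleted_atoms = deleted, shifted_atoms = shifted,
                water = water, shift_A = shift_A, seed = seed)
  list(model = edited, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate merged reflection amplitudes from a model
#'
#' F = |direct structure-factor sum| for every unique reflection to `d_min`
#' (canonical Friedel hemisphere, F(0,0,0) included), with seeded Gaussian
#' noise of standard deviation `noise_frac * F` added and
#' sigma(F) = noise_frac * F reported.
#'
#' @param model an [atomic_model] with a cell.
#' @param d_min high-resolution limit, `>= 1.0` Angstrom.
#' @param noise_frac relative amplitude noise (e.g. 0.05).
#' @param seed integer seed.
#' @param b_factor uniform isotropic B (Angstrom^2).
#' @return A [reflection_set] with amplitudes in electrons.
#' @export
simulate_reflections <- function(model, d_min = 2.0, noise_frac = 0,
                                 seed = 1, b_factor = 20) {
  stopifnot(d_min >= 1.0, noise_frac >= 0)
  hkl <- generate_hkl(model$cell, d_min)
  f <- Mod(calc_structure_factors(model, hkl, b_factor = b_factor))
  sig <- noise_frac * f
  if (noise_frac > 0) {
    set.seed(substream_seed(seed, "reflections"))
    f <- pmax(f + stats::rnorm(length(f), sd = sig), 0)
  }
  reflection_set(hkl, f, sig, cell = model$cell, d_min = d_min)
}

#' Planted residue-level exchange-difference track
#'
#' Segmental perturbation model: each center (the mutated site and each
#' tendril residue) causes local unfolding of the contiguous segment of
#' residues within `halfwidth` of it, raising their exchange by a uniform
#' `amplitude` percentage points; all other residues are unperturbed. The
#' planted set is exactly the union of the perturbed segments, so the
#' ground truth is defined by the perturbation itself, not by any
#' detection threshold.
#'
#' @param n_residues sequence length.
#' @param centers residue numbers of perturbed centers.
#' @param amplitude exchange increase on perturbed residues, percentage
#'   points (default 15, the scale of strong variant-induced differences).
#' @param halfwidth segment half-width in residues (default 1: a local
#'   unfolding event spans a few consecutive amides).
#' @return Numeric vector of length `n_residues` (delta %D per residue),
#'   with attribute `planted_set` (the perturbed residue numbers).
#' @export
planted_delta_track <- function(n_residues, centers, amplitude = 15,
                                halfwidth = 1) {
  r <- seq_len(n_residues)
  hit <- vapply(r, function(x) any(abs(x - centers) <= halfwidth), TRUE)
  delta <- ifelse(hit, amplitude, 0)
  structure(delta, planted_set = r[hit])
}

#' Simulate HDX-MS peptide tables with a planted difference
#'
#' Generates a pepsin-like peptide map (random cut sites, peptide lengths
#' 5-15, roughly 4x average redundancy from three independent tiling passes
#' plus extra short peptides, the redundancy of typical pepsin digests), then per-residue WT uptake curves (two
#' -parameter logistic in log time) and mutant uptake = WT + planted delta
#' scaled smoothly across timepoints so the planted difference is attained
#' exactly at 300 s. Peptide %D is the mean over the peptide's exchangeable
#' amide positions plus Gaussian noise; masses are emitted through the exact
#' inverse of [percent_deuteration]'s FD-corrected form, together with
#' undeuterated (timepoint 0) and FD rows per state.
#'
#' @param sequence one-letter protein sequence (length >= 20).
#' @param planted_track numeric per-residue delta %D (mutant - WT).
#' @param timepoints labeling times in seconds (default 30, 100, 300, 1000,
#'   3000, 10000).
#' @param replicates named or unnamed vector of replicate counts per
#'   timepoint; default duplicates at 30 s and 300 s, single otherwise.
#' @param noise_sd peptide-level %D noise, percentage points.
#' @param seed integer seed.
#' @param d2o_fraction labeling D2O fraction (default 0.90).
#' @param states state labels, `c(WT, mutant)`.
#' @return Peptide measurement table (see [read_peptide_table]) with
#'   attribute `peptide_truth` (the noiseless per-peptide %D per state and
#'   timepoint) and `tiling` (the generated spans).
#' @export
simulate_hdx_tables <- function(sequence, planted_track,
                                timepoints = c(30, 100, 300, 1000, 3000, 10000),
                                replicates = NULL,
                                noise_sd = 1.5, seed = 1,
                                d2o_fraction = 0.90,
                                states = c("WT", "MUT")) {
  L <- nchar(sequence)
  stopifnot(L >= 20, noise_sd >= 0, length(planted_track) == L)
  if (is.null(replicates)) {
    replicates <- ifelse(timepoints %in% c(30, 300), 2L, 1L)
  }
  set.seed(substream_seed(seed, "peptides"))
  tile_once <- function() {
    spans <- list()
    start <- sample(1:3, 1)
    while (start <= L - 4) {
      len <- sample(5:15, 1)
      end <- min(start + len - 1L, L)
      if (end - start + 1L >= 5L) spans[[length(spans) + 1L]] <- c(start, end)
      start <- end - sample(1:4, 1) + 1L   # overlap of 1-4 residues
      start <- max(start, spans[[length(spans)]][1] + 1L)
    }
    do.call(rbind, spans)
  }
  spans <- rbind(tile_once(), tile_once(), tile_once())
  extra <- max(6L, L %/% 4L)
  for (e in seq_len(extra)) {
    s <- sample(1:(L - 5L), 1)
    spans <- rbind(spans, c(s, min(s + sample(5:8, 1) - 1L, L)))
  }
  spans <- unique(spans)
  spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]

  # per-residue WT uptake kinetics: logistic in log time
  set.seed(substream_seed(seed, "kinetics"))
  plateau <- stats::runif(L, 40, 75)
  log_tau <- stats::runif(L, log(30), log(3000))
  shape <- 1.2
  uptake_wt <- function(t) plateau * stats::plogis((log(t) - log_tau) / shape)
  # smooth timepoint scaling of the planted difference, = 1 at 300 s,
  # bounded so mutant %D stays below 100
  gscale <- function(t) stats::plogis(log(t / 100)) / stats::plogis(log(3))

  rows <- list()
  truth <- list()
  set.seed(substream_seed(seed, "noise"))
  for (si in seq_along(states)) {
    state <- states[si]
    for (p in seq_len(nrow(spans))) {
      s <- spans[p, 1]; e <- spans[p, 2]
      pep_seq <- substr(sequence, s, e)
      n_ex <- tryCatch(exchangeable_amides(pep_seq), error = function(err) 0L)
      if (n_ex < 1) next
      pos <- exchangeable_positions(pep_seq, s)
      m0 <- peptide_mass(pep_seq)
      mFD <- m0 + n_ex * .D_MINUS_H * d2o_fraction
      rows[[length(rows) + 1L]] <- data.frame(
        state = state, sequence = pep_seq, start = s, end = e,
        timepoint_s = 0, replicate = 1L, centroid_mass_da = m0,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        state = state, sequence = pep_seq, start = s, end = e,
        timepoint_s = Inf, replicate = 1L, centroid_mass_da = mFD,
        stringsAsFactors = FALSE)
      for (ti in seq_along(timepoints)) {
        t <- timepoints[ti]
        u <- uptake_wt(t)[pos]
        if (si > 1) u <- u + planted_track[pos] * gscale(t)
        pd_true <- mean(u)
        truth[[length(truth) + 1L]] <- data.frame(
          state = state, start = s, end = e, timepoint_s = t,
          pct_d = pd_true, stringsAsFactors = FALSE)
        for (rep in seq_len(replicates[ti])) {
          pd <- pd_true + if (noise_sd > 0) stats::rnorm(1, sd = noise_sd) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            state = state, sequence = pep_seq, start = s, end = e,
            timepoint_s = t, replicate = rep,
            centroid_mass_da = m0 + (pd / 100) * (mFD - m0),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            peptide_truth = do.call(rbind, truth),
            tiling = spans,
            d2o_fraction = d2o_fraction,
            class = c("data.frame"))
}

#' Generate a complete paired synthetic study
#'
#' One call produces everything a toy-study dual-modality run consumes: WT
#' and mutant toy crystals, noisy reflection sets for both, an HDX peptide
#' table for both states, and the ground truth (planted structural edit,
#' planted exchange track, and the planted network set = edited residues
#' plus residues inside the planted exchange bumps at half maximum).
#'
#' @param n_residues chain length (default 40).
#' @param site mutated residue (default 25).
#' @param tendril allosteric tendril residues (default 10, 12, 30).
#' @param seed top-level seed.
#' @param d_min resolution limit for simulated reflections (default 2.0).
#' @param noise_frac relative amplitude noise (default 0.05).
#' @param hdx_noise_sd peptide %D noise, points (default 1.5).
#' @param shift_A tendril side-chain displacement (default 0.5).
#' @param amplitude planted exchange-bump amplitude, points (default 15).
#' @return list with `wt_model`, `mut_model`, `wt_refl`, `mut_refl`,
#'   `hdx_table`, `sequence`, `truth`.
#' @export
simulate_study <- function(n_residues = 40, site = 25,
                           tendril = c(10, 12, 30), seed = 1,
                           d_min = 2.0, noise_frac = 0.05,
                           hdx_noise_sd = 1.5, shift_A = 0.5,
                           amplitude = 15) {
  wt <- make_toy_crystal(n_residues, seed = seed)
  ed <- apply_mutation_like_edit(wt, site = site, tendril = tendril,
                                 shift_A = shift_A, seed = seed)
  wt_refl <- simulate_reflections(wt, d_min = d_min, noise_frac = noise_frac,
                                  seed = substream_seed(seed, "wt"))
  mut_refl <- simulate_reflections(ed$model, d_min = d_min,
                                   noise_frac = noise_frac,
                                   seed = substream_seed(seed, "mut"))
  track <- planted_delta_track(n_residues, centers = c(site, tendril),
                               amplitude = amplitude)
  hdx <- simulate_hdx_tables(attr(wt, "sequence"), track,
                             noise_sd = hdx_noise_sd, seed = seed)
  planted_network <- sort(unique(c(site, tendril, attr(track, "planted_set"))))
  list(wt_model = wt, mut_model = ed$model, wt_refl = wt_refl,
       mut_refl = mut_refl, hdx_table = hdx,
       sequence = attr(wt, "sequence"),
       truth = c(ed$truth,
                 list(planted_track = as.numeric(track),
                      planted_network = planted_network,
                      seed = seed)))
}

#' Planted coevolving-sector stand-in
#'
#' Builds the synthetic analogue of an externally supplied coevolving
#' sector: the planted network residues plus `extras` seeded random
#' unperturbed residues (a sector that contains the perturbed tendril), as
#' a [residue_set] on the model's residues.
#'
#' @param sim a [simulate_study] result.
#' @param extras number of random unperturbed residues to add (default 4).
#' @param seed integer seed.
#' @param chain chain id.
#' @export
planted_sector <- function(sim, extras = 4, seed = 1, chain = "A") {
  n <- nchar(sim$sequence)
  planted <- sim$truth$planted_network
  set.seed(substream_seed(seed, "sector"))
  pad <- sample(setdiff(seq_len(n), planted), extras)
  residue_set(res_key(chain, sort(c(planted, pad))),
              label = "planted_sector",
              population = res_key(chain, seq_len(n)),
              provenance = "synthetic sector containing the planted network")
}
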