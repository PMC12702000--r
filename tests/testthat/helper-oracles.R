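# Independent oracles and small programmatic fixtures shared by the tests.
# Every oracle is written as plain, direct code (full distance matrices,
# exhaustive enumeration) so it shares no path with the implementation.

# -- tiny atomic models -------------------------------------------------

make_atoms <- function(chain, resnum, resname, atom, element, xyz,
                       occupancy = 1) {
  data.frame(chain = chain, resnum = resnum, resname = resname, atom = atom,
             element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = occupancy, stringsAsFactors = FALSE)
}

# a random toy model of n_atoms heavy atoms spread over n_res residues,
# inside a given orthorhombic cell
random_toy_model <- function(n_res, cell, seed) {
  set.seed(seed)
  n_atoms <- n_res * sample(1:3, 1)
  resnum <- sort(sample(seq_len(n_res), n_atoms, replace = TRUE))
  xyz <- cbind(runif(n_atoms, 0, cell[1]), runif(n_atoms, 0, cell[2]),
               runif(n_atoms, 0, cell[3]))
  atomic_model(
    make_atoms("A", resnum, "ALA", "CA", sample(c("C", "N", "O"), n_atoms,
                                                replace = TRUE), xyz),
    cell = cell)
}

# -- brute-force IADDAT oracle ------------------------------------------
# Scans EVERY voxel against EVERY heavy atom with a full minimum-image
# distance matrix; no threshold shortcuts, no chunking, no shared helpers
# beyond basic cell algebra.
iaddat_oracle <- function(grid, model, threshold, radius,
                          denominator = "atoms") {
  at <- model$atoms
  at <- at[!(toupper(at$element) %in% c("H", "D")) &
             !(toupper(at$resname) %in% c("HOH", "WAT")), , drop = FALSE]
  cell <- grid$cell
  ortho <- diag(cell[1:3])  # oracle fixtures are orthorhombic
  dims <- dim(grid$data)
  res_ids <- unique(at[, c("chain", "resnum")])
  res_ids <- res_ids[order(res_ids$chain, res_ids$resnum), , drop = FALSE]
  rkey <- paste(res_ids$chain, res_ids$resnum)
  akey <- paste(at$chain, at$resnum)
  sums <- setNames(numeric(length(rkey)), rkey)
  fa <- cbind(at$x / cell[1], at$y / cell[2], at$z / cell[3])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      v <- grid$data[i, j, k]
      if (abs(v) <= threshold) next
      fv <- c((i - 1) / dims[1], (j - 1) / dims[2], (k - 1) / dims[3])
      df <- sweep(fa, 2, fv)
      df <- df - round(df)
      d <- sqrt(rowSums((df %*% ortho)^2))
      if (min(d) > radius) next
      # nearest atom; ties -> lower (chain, resnum)
      cand <- which(abs(d - min(d)) < 1e-12)
      winner <- cand[order(match(akey[cand], rkey))][1]
      sums[akey[winner]] <- sums[akey[winner]] + abs(v)
    }
  denom <- switch(denominator,
                  atoms = as.numeric(table(factor(akey, levels = rkey))),
                  none = 1)
  data.frame(chain = res_ids$chain, resnum = res_ids$resnum,
             score = unname(sums) / denom, stringsAsFactors = FALSE)
}

# -- exhaustive hypergeometric oracle -----------------------------------
# Enumerates every size-nx subset of 1..N and counts overlaps with a fixed
# size-ny set; returns P(K >= k) by direct counting.
enum_hyper_tail <- function(k, nx, ny, N) {
  draws <- utils::combn(N, nx)
  y <- seq_len(ny)
  hits <- apply(draws, 2, function(d) sum(d %in% y))
  mean(hits >= k)
}

# sample standard deviation by definition, for worked HDX examples
expect_track_scores <- function(track, expected, tol = 1e-10) {
  got <- setNames(track$score, paste0(track$chain, ":", track$resnum))
  for (nm in names(expected)) {
    expect_equal(unname(got[nm]), expected[[nm]], tolerance = tol)
  }
}

# vectorized brute force: one full voxel x atom minimum-image distance
# matrix, no above-threshold shortcut (distinct path from the package's
# chunked nearest-first scan)
iaddat_oracle_vec <- function(grid, model, threshold, radius) {
  at <- model$atoms
  at <- at[!(toupper(at$element) %in% c("H", "D")) &
             !(toupper(at$resname) %in% c("HOH", "WAT")), , drop = FALSE]
  at <- at[order(at$chain, at$resnum), , drop = FALSE]
  cell <- grid$cell
  dims <- dim(grid$data)
  res_ids <- unique(at[, c("chain", "resnum")])
  res_ids <- res_ids[order(res_ids$chain, res_ids$resnum), , drop = FALSE]
  rkey <- paste(res_ids$chain, res_ids$resnum)
  akey <- paste(at$chain, at$resnum)
  idx <- expand.grid(i = seq_len(dims[1]) - 1L, j = seq_len(dims[2]) - 1L,
                     k = seq_len(dims[3]) - 1L)
  fv <- cbind(idx$i / dims[1], idx$j / dims[2], idx$k / dims[3])
  fa <- cbind(at$x / cell[1], at$y / cell[2], at$z / cell[3])
  nv <- nrow(fv)
  best_d <- rep(Inf, nv)
  best_atom <- rep(NA_integer_, nv)
  for (a in seq_len(nrow(fa))) {
    df <- fv - matrix(fa[a, ], nv, 3, byrow = TRUE)
    df <- df - round(df)
    d <- sqrt(rowSums((df %*% diag(cell[1:3]))^2))
    # strictly-better keeps the first (lowest-residue) atom on exact ties,
    # because atoms arrive ordered by residue
    upd <- d < best_d - 1e-12
    best_d[upd] <- d[upd]
    best_atom[upd] <- a
  }
  vals <- abs(as.vector(grid$data))
  take <- vals > threshold & best_d <= radius
  sums <- setNames(numeric(length(rkey)), rkey)
  if (any(take)) {
    agg <- tapply(vals[take], akey[best_atom[take]], sum)
    sums[names(agg)] <- agg
  }
  denom <- as.numeric(table(factor(akey, levels = rkey)))
  data.frame(chain = res_ids$chain, resnum = res_ids$resnum,
             score = unname(sums) / denom, stringsAsFactors = FALSE)
}
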