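#' HDX-MS peptide-level analysis
#'
#' The HDX primitives are centroid-mass records: one row per state x peptide
#' x timepoint x replicate. The module converts them to back-exchange
#' -corrected percent deuteration, mutant-minus-WT differences, and signed
#' residue-level tracks, mirroring standard local HDX-MS practice: uptake is
#' the centroid-mass increase over the undeuterated control, normalized
#' either to a fully-deuterated (FD) control of the same peptide or to the
#' theoretical maximum for the labeling D2O fraction.
#'
#' @name hdx
NULL

.D_MINUS_H <- 1.006277  # mass shift per deuterium-for-hydrogen substitution

# monoisotopic residue masses (Da)
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

peptide_mass <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  if (any(!aa %in% names(.RESIDUE_MASS))) {
    stop("non-standard amino acid in '", sequence, "'", call. = FALSE)
  }
  sum(.RESIDUE_MASS[aa]) + 18.010565  # + water
}

#' Number of exchangeable backbone amides of a peptide
#'
#' Backbone amides excluding the N-terminal residue and all prolines (no
#' amide NH), minus one more for the fast-back-exchanging amide adjacent to
#' the N-terminus when the second residue is not proline. Closed form:
#' (L - 1) - #Pro(positions 2..L) - [residue 2 != Pro], which equals the
#' count of non-proline positions 3..L.
#'
#' @param sequence one-letter amino-acid string, length >= 2.
#' @return Integer count, `>= 1`.
#' @export
exchangeable_amides <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 2 || any(!aa %in% names(.RESIDUE_MASS))) {
    stop("degenerate peptide: need >= 2 standard residues, got '",
         sequence, "'", call. = FALSE)
  }
  n <- sum(aa[-(1:2)] != "P")
  if (n < 1) {
    stop("degenerate peptide '", sequence, "': no exchangeable amides",
         call. = FALSE)
  }
  n
}

#' Exchangeable residue positions of a peptide (absolute numbering)
#' @param sequence peptide sequence.
#' @param start 1-based residue number of the first peptide residue.
#' @return Integer vector of residue numbers carrying measurable amides.
#' @export
exchangeable_positions <- function(sequence, start) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  rel <- which(aa != "P")
  rel <- rel[rel >= 3]
  start + rel - 1L
}

#' Read an HDX peptide table
#'
#' CSV with one row per state x peptide x timepoint x replicate and columns
#' `state, sequence, start, end, timepoint_s, replicate, centroid_mass_da`.
#' `timepoint_s` is seconds, with `0` marking undeuterated controls and the
#' token `"FD"` marking fully-deuterated controls (stored as `Inf`).
#'
#' @param path CSV path.
#' @return data.frame of peptide measurements.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("state", "sequence", "start", "end", "timepoint_s",
            "replicate", "centroid_mass_da")
  if (!all(need %in% names(df))) {
    stop("peptide CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tp <- as.character(df$timepoint_s)
  df$timepoint_s <- ifelse(toupper(tp) == "FD", Inf,
                           suppressWarnings(as.numeric(tp)))
  if (any(is.na(df$timepoint_s))) {
    stop("unparseable timepoint_s values", call. = FALSE)
  }
  validate_peptide_table(df)
  df
}

validate_peptide_table <- function(df) {
  bad <- df$end - df$start + 1L != nchar(df$sequence)
  if (any(bad)) {
    stop("peptide span does not match sequence length in ",
         sum(bad), " row(s)", call. = FALSE)
  }
  if (any(df$centroid_mass_da <= 0)) {
    stop("centroid masses must be positive", call. = FALSE)
  }
  invisible(df)
}

#' Write an HDX peptide table (FD timepoints rendered as "FD")
#' @param df peptide table.
#' @param path output path.
#' @export
write_peptide_table <- function(df, path) {
  out <- df
  out$timepoint_s <- ifelse(is.infinite(out$timepoint_s), "FD",
                            format(out$timepoint_s, trim = TRUE,
                                   scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Percent deuteration per peptide, back-exchange corrected
#'
#' For each (state, peptide, labeled timepoint): uptake = m_t - m_0 against
#' the state's undeuterated control. With an FD control present (default),
#' %D = 100 (m_t - m_0) / (m_FD - m_0); otherwise %D = 100 uptake /
#' (n_exchangeable x 1.006277 x d2o_fraction). Replicates are averaged and
#' their sample standard deviation reported. Quality control: peptides with
#' %D outside [0, 100] by at most `qc_slack` points are kept with a warning
#' (measurement noise); larger excursions are dropped, with the drops
#' recorded in the `qc_dropped` attribute.
#'
#' @param table peptide measurement table (see [read_peptide_table]).
#' @param d2o_fraction labeling D2O fraction; default 0.90.
#' @param use_fd use FD controls when present.
#' @param qc_slack tolerated excursion outside [0, 100], percentage points.
#' @return data.frame of class `peptide_exchange`: one row per state x
#'   peptide x timepoint with `pct_d`, `uptake_da`, `n_exchangeable`,
#'   `n_replicates`, `sd_pct_d`.
#' @export
percent_deuteration <- function(table, d2o_fraction = 0.90, use_fd = TRUE,
                                qc_slack = 5) {
  validate_peptide_table(table)
  pep_id <- paste(table$state, table$start, table$end, table$sequence,
                  sep = "|")
  out <- list()
  for (id in unique(pep_id)) {
    rows <- table[pep_id == id, , drop = FALSE]
    m0_rows <- rows$timepoint_s == 0
    fd_rows <- is.infinite(rows$timepoint_s)
    if (!any(m0_rows)) {
      stop("no undeuterated (timepoint 0) control for peptide ",
           rows$sequence[1], " in state ", rows$state[1], call. = FALSE)
    }
    m0 <- mean(rows$centroid_mass_da[m0_rows])
    n_ex <- exchangeable_amides(rows$sequence[1])
    fd <- NA_real_
    if (use_fd && any(fd_rows)) {
      fd <- mean(rows$centroid_mass_da[fd_rows])
      if (fd <= m0) {
        stop("invalid FD control (m_FD <= m_0) for peptide ",
             rows$sequence[1], call. = FALSE)
      }
    }
    lab <- rows[!m0_rows & !fd_rows, , drop = FALSE]
    for (tp in unique(lab$timepoint_s)) {
      reps <- lab[lab$timepoint_s == tp, , drop = FALSE]
      uptake <- reps$centroid_mass_da - m0
      pd <- if (!is.na(fd)) {
        100 * uptake / (fd - m0)
      } else {
        100 * uptake / (n_ex * .D_MINUS_H * d2o_fraction)
      }
      out[[length(out) + 1L]] <- data.frame(
        state = reps$state[1], sequence = reps$sequence[1],
        start = reps$start[1], end = reps$end[1], timepoint_s = tp,
        pct_d = mean(pd), uptake_da = mean(uptake), n_exchangeable = n_ex,
        n_replicates = nrow(reps),
        sd_pct_d = if (nrow(reps) > 1) stats::sd(pd) else NA_real_,
        fd_corrected = !is.na(fd), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  excur <- pmax(res$pct_d - 100, -res$pct_d, 0)
  drop <- excur > qc_slack
  if (any(excur > 0 & !drop)) {
    warning(sum(excur > 0 & !drop),
            " peptide value(s) slightly outside [0, 100] retained",
            call. = FALSE)
  }
  dropped <- res[drop, , drop = FALSE]
  if (nrow(dropped)) {
    warning("dropped ", nrow(dropped),
            " peptide value(s) failing the [0, 100] QC window",
            call. = FALSE)
  }
  res <- res[!drop, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, qc_dropped = dropped,
            class = c("peptide_exchange", "data.frame"))
}

#' Mutant-minus-WT peptide difference records
#'
#' Inner join of two [percent_deuteration] outputs on (span, timepoint);
#' delta %D = %D_mut - %D_WT (positive = faster exchange in the mutant).
#' Unmatched peptides are listed in the `coverage_report` attribute, and a
#' Woods-plot table (span midpoint vs difference) is attached as attribute
#' `woods`.
#'
#' @param mutant,wt `peptide_exchange` tables for one mutant state and WT.
#' @return data.frame of class `hdx_differences` with columns `state,
#'   sequence, start, end, timepoint_s, d_pct_d, n_exchangeable`.
#' @export
difference_records <- function(mutant, wt) {
  if (!identical(unique(mutant$fd_corrected), unique(wt$fd_corrected))) {
    stop("mutant and WT records mix FD-correction modes", call. = FALSE)
  }
  key <- function(d) paste(d$start, d$end, d$sequence, d$timepoint_s, sep = "|")
  km <- key(mutant); kw <- key(wt)
  common <- intersect(km, kw)
  if (!length(common)) stop("no common peptides between states", call. = FALSE)
  im <- match(common, km); iw <- match(common, kw)
  out <- data.frame(
    state = mutant$state[im], sequence = mutant$sequence[im],
    start = mutant$start[im], end = mutant$end[im],
    timepoint_s = mutant$timepoint_s[im],
    d_pct_d = mutant$pct_d[im] - wt$pct_d[iw],
    n_exchangeable = mutant$n_exchangeable[im],
    stringsAsFactors = FALSE)
  out <- out[order(out$timepoint_s, out$start, out$end), ]
  rownames(out) <- NULL
  woods <- data.frame(midpoint = (out$start + out$end) / 2,
                      start = out$start, end = out$end,
                      d_pct_d = out$d_pct_d, timepoint_s = out$timepoint_s)
  structure(out,
            coverage_report = list(
              mut_only = mutant[!(km %in% kw), c("sequence", "start", "end",
                                                 "timepoint_s")],
              wt_only = wt[!(kw %in% km), c("sequence", "start", "end",
                                            "timepoint_s")]),
            woods = woods,
            class = c("hdx_differences", "data.frame"))
}

#' Project peptide-level differences to a signed residue track
#'
#' Each residue receives the weighted mean of delta %D over the peptides
#' whose exchangeable amide positions include it, with weight
#' 1 / n_exchangeable so that short peptides dominate (they localize the
#' signal best). Residues measured by no peptide are marked missing (`NA`),
#' not zero. An optional centered moving average smooths over `window`
#' residues (default 1 = none). Residues with |value| <= `neutral_band` are
#' tagged neutral in the `neutral` column, mirroring the +/- 5 point gray
#' band used when such tracks are displayed.
#'
#' @param diffs an [difference_records] table (one mutant vs WT).
#' @param timepoint labeling time in seconds to project (default 300).
#' @param window centered moving-average window (odd integer, 1 = none).
#' @param chain chain id to stamp on the track (single-chain data).
#' @param length_out sequence length; defaults to the maximal peptide end.
#' @param neutral_band half-width of the neutral display band (points).
#' @return A signed [residue_track] with `modality = "delta_hdx"`.
#' @export
residue_projection <- function(diffs, timepoint = 300, window = 1L,
                               chain = "A", length_out = NULL,
                               neutral_band = 5) {
  sel <- diffs[diffs$timepoint_s == timepoint, , drop = FALSE]
  if (!nrow(sel)) {
    stop("no difference records at timepoint ", timepoint, " s",
         call. = FALSE)
  }
  L <- if (is.null(length_out)) max(sel$end) else length_out
  num <- numeric(L); den <- numeric(L)
  for (i in seq_len(nrow(sel))) {
    pos <- exchangeable_positions(sel$sequence[i], sel$start[i])
    pos <- pos[pos <= L]
    w <- 1 / sel$n_exchangeable[i]
    num[pos] <- num[pos] + w * sel$d_pct_d[i]
    den[pos] <- den[pos] + w
  }
  val <- ifelse(den > 0, num / den, NA_real_)
  if (window > 1L) {
    half <- (as.integer(window) - 1L) %/% 2L
    sm <- val
    for (r in seq_len(L)) {
      win <- max(1L, r - half):min(L, r + half)
      v <- val[win]
      sm[r] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    sm[is.na(val)] <- NA_real_   # smoothing never invents coverage
    val <- sm
  }
  df <- data.frame(chain = chain, resnum = seq_len(L),
                   resname = NA_character_, score = val,
                   neutral = !is.na(val) & abs(val) <= neutral_band,
                   stringsAsFactors = FALSE)
  residue_track(df, modality = "delta_hdx", timepoint = timepoint,
                window = as.integer(window), neutral_band = neutral_band,
                projection = "inverse-amide-count weighted mean")
}

#' Greedy minimal spanning-peptide selection
#'
#' Weighted set cover over residues 1..L: repeatedly pick the peptide
#' maximizing (newly covered residues) / (peptide length); ties prefer the
#' shorter peptide, then the smaller start. Stops when no peptide adds
#' coverage. This prioritizes short peptides while still spanning the
#' sequence, for the closest comparison with single-residue tracks.
#'
#' @param records a table with `start`, `end` (and optionally `sequence`)
#'   columns; duplicate spans are collapsed.
#' @param length_out sequence length; defaults to the maximal end.
#' @return The unique (start, end) spans selected, as a data.frame.
#' @export
select_spanning_peptides <- function(records, length_out = NULL) {
  spans <- unique(data.frame(start = records$start, end = records$end))
  if (!nrow(spans)) stop("no peptides supplied", call. = FALSE)
  L <- if (is.null(length_out)) max(spans$end) else length_out
  covered <- rep(FALSE, L)
  spans$len <- spans$end - spans$start + 1L
  chosen <- integer(0)
  repeat {
    gain <- vapply(seq_len(nrow(spans)), function(i) {
      rng <- spans$start[i]:min(spans$end[i], L)
      sum(!covered[rng])
    }, 0)
    ratio <- gain / spans$len
    if (max(gain) == 0) break
    best <- which(ratio == max(ratio))
    best <- best[order(spans$len[best], spans$start[best])][1]
    chosen <- c(chosen, best)
    rng <- spans$start[best]:min(spans$end[best], L)
    covered[rng] <- TRUE
  }
  # prune: drop any peptide made redundant by later picks (longest first)
  repeat {
    removable <- vapply(seq_along(chosen), function(i) {
      cov <- rep(FALSE, L)
      for (j in chosen[-i]) cov[spans$start[j]:min(spans$end[j], L)] <- TRUE
      identical(cov, covered)
    }, TRUE)
    if (!any(removable)) break
    cand <- chosen[removable]
    drop <- cand[order(-spans$len[cand], spans$start[cand])][1]
    chosen <- setdiff(chosen, drop)
  }
  out <- spans[sort(chosen), c("start", "end"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared sequence coverage across states
#'
#' Percentage of residues 1..`length_out` covered by the union of spans of
#' peptides observed in every state of the table (the shared peptide set).
#'
#' @param table peptide measurement table with `state`, `start`, `end`,
#'   `sequence` columns.
#' @param length_out protein sequence length.
#' @return Percent coverage in [0, 100].
#' @export
coverage_fraction <- function(table, length_out) {
  stopifnot(length_out >= 1)
  states <- unique(table$state)
  pep <- unique(data.frame(state = table$state, start = table$start,
                           end = table$end, sequence = table$sequence))
  key <- paste(pep$start, pep$end, pep$sequence, sep = "|")
  shared <- names(which(table(unique(data.frame(key, pep$state))$key) ==
                          length(states)))
  covered <- rep(FALSE, length_out)
  for (k in shared) {
    i <- match(k, key)
    rng <- pep$start[i]:min(pep$end[i], length_out)
    covered[rng] <- TRUE
  }
  100 * sum(covered) / length_out
}
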