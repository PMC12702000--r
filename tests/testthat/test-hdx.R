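test_that("exchangeable amide counts match the worked rules", {
  expect_equal(exchangeable_amides("GSAMPE"), 3)
  expect_equal(exchangeable_amides("APKLM"), 3)
  expect_equal(exchangeable_amides("AAAA"), 2)
  expect_error(exchangeable_amides("A"), "degenerate")
  expect_error(exchangeable_amides("APP"), "degenerate")
})

test_that("amide counting equals the closed form over dipeptide prefixes", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(5)
  for (a1 in aa) for (a2 in aa) {
    suffix <- paste(sample(aa, 6, replace = TRUE), collapse = "")
    pep <- paste0(a1, a2, suffix)
    chars <- strsplit(pep, "")[[1]]
    L <- length(chars)
    closed <- (L - 1) - sum(chars[2:L] == "P") - (chars[2] != "P")
    if (closed < 1) {
      expect_error(exchangeable_amides(pep), "degenerate")
    } else {
      expect_equal(exchangeable_amides(pep), closed)
      # the positions helper must agree with the count
      expect_length(exchangeable_positions(pep, 1), closed)
    }
  }
})

make_pep_rows <- function(state, seq, start, tp, rep, mass) {
  data.frame(state = state, sequence = seq, start = start,
             end = start + nchar(seq) - 1L, timepoint_s = tp,
             replicate = rep, centroid_mass_da = mass,
             stringsAsFactors = FALSE)
}

test_that("percent deuteration with FD correction matches hand values", {
  tab <- rbind(
    make_pep_rows("WT", "AAAAA", 1, 0, 1, 1000.0),
    make_pep_rows("WT", "AAAAA", 1, Inf, 1, 1003.0),
    make_pep_rows("WT", "AAAAA", 1, 300, 1, 1001.5))
  rec <- percent_deuteration(tab)
  expect_equal(rec$pct_d, 50.0)
  expect_equal(rec$uptake_da, 1.5)
  expect_true(rec$fd_corrected)

  # no exchange: m_t = m_0
  tab2 <- tab; tab2$centroid_mass_da[3] <- 1000.0
  rec2 <- percent_deuteration(tab2)
  expect_equal(rec2$pct_d, 0)
  expect_equal(rec2$uptake_da, 0)

  # replicate aggregation: 40% and 44% -> mean 42, sd 2.828 (n-1 form)
  tab3 <- rbind(
    make_pep_rows("WT", "AAAAA", 1, 0, 1, 1000.0),
    make_pep_rows("WT", "AAAAA", 1, Inf, 1, 1010.0),
    make_pep_rows("WT", "AAAAA", 1, 30, 1, 1004.0),
    make_pep_rows("WT", "AAAAA", 1, 30, 2, 1004.4))
  rec3 <- percent_deuteration(tab3)
  expect_equal(rec3$pct_d, 42)
  expect_equal(rec3$sd_pct_d, sqrt(((40 - 42)^2 + (44 - 42)^2) / 1),
               tolerance = 1e-12)
  expect_equal(rec3$n_replicates, 2L)

  # invalid FD control
  bad <- tab; bad$centroid_mass_da[2] <- 999
  expect_error(percent_deuteration(bad), "FD")
})

test_that("FD-corrected %D is invariant under affine mass recalibration", {
  for (seed in 1:5) {
    set.seed(seed)
    m0 <- runif(1, 800, 2000); up <- runif(1, 0.5, 3); fd <- m0 + runif(1, 4, 8)
    tab <- rbind(
      make_pep_rows("WT", "GAMKLV", 10, 0, 1, m0),
      make_pep_rows("WT", "GAMKLV", 10, Inf, 1, fd),
      make_pep_rows("WT", "GAMKLV", 10, 300, 1, m0 + up))
    a <- runif(1, 0.9, 1.1); b <- runif(1, -5, 5)
    tab2 <- tab; tab2$centroid_mass_da <- a * tab$centroid_mass_da + b
    expect_equal(percent_deuteration(tab2)$pct_d,
                 percent_deuteration(tab)$pct_d, tolerance = 1e-9)
  }
})

test_that("theoretical-maximum normalization is used without FD controls", {
  n_ex <- exchangeable_amides("GAMKLV")
  up <- 1.2
  tab <- rbind(
    make_pep_rows("WT", "GAMKLV", 10, 0, 1, 900),
    make_pep_rows("WT", "GAMKLV", 10, 300, 1, 900 + up))
  rec <- percent_deuteration(tab, d2o_fraction = 0.90)
  expect_false(rec$fd_corrected)
  expect_equal(rec$pct_d, 100 * up / (n_ex * 1.006277 * 0.90),
               tolerance = 1e-9)
})

test_that("QC drops gross excursions and keeps small ones with a warning", {
  tab <- rbind(
    make_pep_rows("WT", "AAAAA", 1, 0, 1, 1000.0),
    make_pep_rows("WT", "AAAAA", 1, Inf, 1, 1002.0),
    make_pep_rows("WT", "AAAAA", 1, 30, 1, 1002.08),   # 104% -> kept
    make_pep_rows("WT", "AAAAA", 1, 300, 1, 1002.4))   # 120% -> dropped
  expect_warning(expect_warning(rec <- percent_deuteration(tab), "retained"),
                 "QC")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$timepoint_s, 30)
  expect_equal(nrow(attr(rec, "qc_dropped")), 1)
})

test_that("difference records inner-join states and report the unmatched", {
  wt <- rbind(
    make_pep_rows("WT", "AAAAA", 1, 0, 1, 500), make_pep_rows("WT", "AAAAA", 1, Inf, 1, 503),
    make_pep_rows("WT", "AAAAA", 1, 300, 1, 501.5),
    make_pep_rows("WT", "MKLVA", 10, 0, 1, 600), make_pep_rows("WT", "MKLVA", 10, Inf, 1, 603),
    make_pep_rows("WT", "MKLVA", 10, 300, 1, 601.2))
  mut <- rbind(
    make_pep_rows("M1", "AAAAA", 1, 0, 1, 500), make_pep_rows("M1", "AAAAA", 1, Inf, 1, 503),
    make_pep_rows("M1", "AAAAA", 1, 300, 1, 501.71),
    make_pep_rows("M1", "QWERT", 20, 0, 1, 700), make_pep_rows("M1", "QWERT", 20, Inf, 1, 703),
    make_pep_rows("M1", "QWERT", 20, 300, 1, 701))
  dr <- difference_records(percent_deuteration(mut), percent_deuteration(wt))
  expect_equal(nrow(dr), 1)                      # only the shared peptide
  expect_equal(dr$d_pct_d, 7, tolerance = 1e-9)  # 57% - 50%
  rep <- attr(dr, "coverage_report")
  expect_equal(rep$mut_only$start, 20)
  expect_equal(rep$wt_only$start, 10)
  expect_true(!is.null(attr(dr, "woods")))
  # identical inputs -> all-zero differences
  dr0 <- difference_records(percent_deuteration(wt), percent_deuteration(wt))
  expect_true(all(dr0$d_pct_d == 0))
})

fake_diffs <- function(df) {
  df$n_exchangeable <- vapply(df$sequence, exchangeable_amides, 0L)
  df$state <- "M1"
  df$end <- df$start + nchar(df$sequence) - 1L
  structure(df, class = c("hdx_differences", "data.frame"))
}

test_that("residue projection averages peptides and flags the neutral band", {
  # two equal-length peptides covering residue 14 with +10 and +20 -> +15
  d <- fake_diffs(data.frame(
    sequence = c("AAAAAA", "AAAAAA"), start = c(9, 12),
    timepoint_s = 300, d_pct_d = c(10, 20), stringsAsFactors = FALSE))
  tr <- residue_projection(d, timepoint = 300)
  expect_equal(tr$score[tr$resnum == 14], 15)
  # single-cover passthrough with a negative value, outside the +/-5 band
  d2 <- fake_diffs(data.frame(sequence = "AAAAAA", start = 1,
                              timepoint_s = 300, d_pct_d = -12,
                              stringsAsFactors = FALSE))
  tr2 <- residue_projection(d2, timepoint = 300)
  expect_equal(tr2$score[tr2$resnum == 4], -12)
  expect_false(tr2$neutral[tr2$resnum == 4])
  # residues with no measuring peptide stay missing, not zero
  expect_true(is.na(tr2$score[tr2$resnum == 1]))
  expect_error(residue_projection(d2, timepoint = 1000), "timepoint")
})

test_that("projection of a constant field returns that constant", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 12
    starts <- sample(1:24, n, replace = TRUE)
    lens <- sample(5:12, n, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste(sample(c("A", "G", "K", "L", "V"), l, replace = TRUE),
            collapse = ""), "")
    d <- fake_diffs(data.frame(sequence = seqs, start = starts,
                               timepoint_s = 300, d_pct_d = 6.5,
                               stringsAsFactors = FALSE))
    tr <- residue_projection(d, timepoint = 300)
    covered <- !is.na(tr$score)
    expect_true(any(covered))
    expect_equal(tr$score[covered], rep(6.5, sum(covered)), tolerance = 1e-12)
    expect_true(all(tr$neutral[covered] == FALSE))
  }
})

test_that("greedy spanning selection prefers short peptides and stays minimal", {
  d <- data.frame(start = c(1, 1, 6), end = c(10, 5, 10))
  sel <- select_spanning_peptides(d, length_out = 10)
  expect_equal(sel, data.frame(start = c(1, 6), end = c(5, 10)))
  # a single peptide is selected as-is
  one <- select_spanning_peptides(data.frame(start = 3, end = 9))
  expect_equal(nrow(one), 1)
  # random tilings: cover complete where coverable, and no selected peptide
  # removable without losing coverage
  for (seed in 1:20) {
    set.seed(seed)
    n <- 15
    starts <- sample(1:30, n, replace = TRUE)
    ends <- pmin(starts + sample(4:11, n, replace = TRUE), 36)
    tl <- data.frame(start = starts, end = ends)
    sel <- select_spanning_peptides(tl, length_out = 36)
    coverable <- rep(FALSE, 36)
    for (i in seq_len(n)) coverable[starts[i]:ends[i]] <- TRUE
    covered <- rep(FALSE, 36)
    for (i in seq_len(nrow(sel))) covered[sel$start[i]:sel$end[i]] <- TRUE
    expect_identical(covered, coverable)
    for (drop in seq_len(nrow(sel))) {
      part <- rep(FALSE, 36)
      for (i in setdiff(seq_len(nrow(sel)), drop))
        part[sel$start[i]:sel$end[i]] <- TRUE
      expect_false(identical(part, coverable))
    }
  }
})

test_that("shared coverage counts only peptides observed in every state", {
  tab <- rbind(
    make_pep_rows("WT", "AAAA", 1, 30, 1, 400),
    make_pep_rows("M1", "AAAA", 1, 30, 1, 400),
    make_pep_rows("WT", "GGGGG", 6, 30, 1, 300),
    make_pep_rows("M1", "GGGGG", 6, 30, 1, 300),
    make_pep_rows("WT", "KKKK", 20, 30, 1, 500))   # WT-only: not shared
  expect_equal(coverage_fraction(tab, 10), 90)
  # no shared peptides -> zero
  tab2 <- rbind(make_pep_rows("WT", "AAAA", 1, 30, 1, 400),
                make_pep_rows("M1", "GGGG", 6, 30, 1, 300))
  expect_equal(coverage_fraction(tab2, 10), 0)
  # random fixtures vs boolean-union oracle
  for (seed in 1:10) {
    set.seed(seed)
    states <- c("WT", "A", "B")
    rows <- list()
    pool <- data.frame(start = sample(1:40, 12, replace = TRUE))
    pool$len <- sample(4:9, 12, replace = TRUE)
    for (st in states) {
      pick <- sample(12, sample(6:12, 1))
      for (i in pick) {
        rows[[length(rows) + 1L]] <- make_pep_rows(
          st, strrep("A", pool$len[i]), pool$start[i], 30, 1, 500)
      }
    }
    tab3 <- do.call(rbind, rows)
    got <- coverage_fraction(tab3, 50)
    # oracle: mark residues of spans present in all three states
    key <- paste(tab3$start, tab3$end)
    shared <- Reduce(intersect, lapply(states,
                                       function(s) key[tab3$state == s]))
    mark <- rep(FALSE, 50)
    for (k in unique(shared)) {
      se <- as.integer(strsplit(k, " ")[[1]])
      mark[se[1]:min(se[2], 50)] <- TRUE
    }
    expect_equal(got, 100 * mean(mark))
  }
})

test_that("peptide tables round-trip through CSV including FD sentinels", {
  m <- make_toy_crystal(25, seed = 2)
  track <- planted_delta_track(25, centers = 12)
  tab <- simulate_hdx_tables(attr(m, "sequence"), track, noise_sd = 0.5,
                             seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_peptide_table(tab, f)
  back <- read_peptide_table(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$centroid_mass_da, tab$centroid_mass_da, tolerance = 1e-9)
  expect_identical(is.infinite(back$timepoint_s), is.infinite(tab$timepoint_s))
})
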