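#' Residue sets and overlap statistics
#'
#' The combined allosteric network is built by thresholding per-residue
#' tracks into residue sets, pooling them across variants and modalities,
#' and quantifying overlap with externally supplied residue sectors
#' (e.g. coevolving sectors) by the Jaccard ratio and a one-sided
#' hypergeometric enrichment test.
#'
#' @name network
NULL

#' Construct a residue set
#'
#' @param members character keys `"chain:resnum"` (see [res_key]).
#' @param label set label.
#' @param population the declared population (universe) of residue keys;
#'   members must be contained in it.
#' @param provenance free-text provenance (modality + thresholds).
#' @export
residue_set <- function(members, label = "set", population = NULL,
                        provenance = "") {
  members <- unique(as.character(members))
  if (!is.null(population)) {
    population <- unique(as.character(population))
    if (!all(members %in% population)) {
      stop("residue set '", label, "' is not contained in its population",
           call. = FALSE)
    }
  }
  structure(list(label = label, members = members, population = population,
                 provenance = provenance),
            class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat("<residue_set> '", x$label, "': ", length(x$members), " residues",
      if (!is.null(x$population)) paste0(" (population ",
                                         length(x$population), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Threshold a residue track into a residue set
#'
#' `mode = "greater"` keeps residues with score > cutoff (IADDAT tracks;
#' default cutoff 0.13 on the normalized 0-1 scale); `mode = "abs_greater"`
#' keeps |score| > cutoff (signed delta-HDX tracks; default cutoff 7
#' percentage points at 300 s). Missing residues are never included.
#'
#' @param track a [residue_track].
#' @param cutoff non-negative cutoff.
#' @param mode comparison mode.
#' @param label set label; defaults to the track modality.
#' @param population population keys; defaults to the track's non-missing
#'   residues.
#' @export
threshold_track <- function(track, cutoff, mode = c("greater", "abs_greater"),
                            label = NULL, population = NULL) {
  mode <- match.arg(mode)
  stopifnot(cutoff >= 0)
  ok <- !is.na(track$score)
  keys <- res_key(track$chain, track$resnum)
  hit <- if (mode == "greater") ok & track$score > cutoff
         else ok & abs(track$score) > cutoff
  if (is.null(population)) population <- keys[ok]
  residue_set(keys[hit],
              label = if (is.null(label)) attr(track, "modality") else label,
              population = population,
              provenance = paste0(attr(track, "modality"), " ", mode, " ",
                                  cutoff))
}

#' Pool residue sets (union)
#'
#' @param sets list of [residue_set]s sharing one population.
#' @param label label for the pooled set.
#' @export
pool_sets <- function(sets, label = "pooled") {
  stopifnot(length(sets) >= 1)
  pop <- sets[[1]]$population
  for (s in sets[-1]) {
    if (!setequal(s$population, pop)) {
      stop("cannot pool residue sets with different populations",
           call. = FALSE)
    }
  }
  residue_set(unique(unlist(lapply(sets, `[[`, "members"))),
              label = label, population = pop,
              provenance = paste(vapply(sets, `[[`, "", "provenance"),
                                 collapse = " | "))
}

#' Jaccard ratio of two residue sets
#'
#' J(X, Y) = |X intersect Y| / |X union Y|.
#' @param x,y [residue_set]s (or character vectors of keys).
#' @export
jaccard <- function(x, y) {
  mx <- if (inherits(x, "residue_set")) x$members else unique(x)
  my <- if (inherits(y, "residue_set")) y$members else unique(y)
  u <- union(mx, my)
  if (!length(u)) stop("Jaccard undefined: both sets empty", call. = FALSE)
  length(intersect(mx, my)) / length(u)
}

#' Upper-tail hypergeometric probability P(K >= k)
#'
#' K ~ Hypergeometric(population N, successes K_y, draws n_x), evaluated by
#' a log-factorial (lchoose) tail sum for numerical stability.
#' @noRd
hyper_upper_tail <- function(k, n_x, k_y, N) {
  if (k <= 0) return(1)
  i <- k:min(n_x, k_y)
  if (!length(i) || k > min(n_x, k_y)) return(0)
  sum(exp(lchoose(k_y, i) + lchoose(N - k_y, n_x - i) - lchoose(N, n_x)))
}

#' Hypergeometric overlap test between two residue sets
#'
#' Tests enrichment of the observed overlap k = |X intersect Y| against
#' drawing |X| residues without replacement from the population: one-sided
#' upper tail p = P(K >= k). Both sets must be contained in the population.
#'
#' @param x,y [residue_set]s.
#' @param population a [residue_set] (or character vector) defining the
#'   universe.
#' @return An `overlap_result`: list with set sizes, intersection, union,
#'   Jaccard, and p-value.
#' @export
hypergeometric_overlap <- function(x, y, population) {
  pop <- if (inherits(population, "residue_set")) population$members
         else unique(as.character(population))
  if (!all(x$members %in% pop) || !all(y$members %in% pop)) {
    stop("sets are not contained in the stated population", call. = FALSE)
  }
  k <- length(intersect(x$members, y$members))
  u <- length(union(x$members, y$members))
  p <- hyper_upper_tail(k, length(x$members), length(y$members), length(pop))
  structure(list(x_label = x$label, y_label = y$label,
                 n_x = length(x$members), n_y = length(y$members),
                 intersection = k, union = u,
                 jaccard = if (u > 0) k / u else NA_real_,
                 p_value = p, population_size = length(pop)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", x$x_label, " vs ", x$y_label, ": |X|=", x$n_x,
      " |Y|=", x$n_y, " k=", x$intersection,
      " J=", signif(x$jaccard, 4), " p=", signif(x$p_value, 4),
      " (N=", x$population_size, ")\n", sep = "")
  invisible(x)
}

#' Load a residue sector from a plain-text file
#'
#' One residue per line, either `chain:resnum` tokens or bare residue
#' numbers (single-chain shortcut; `chain` supplies the chain id).
#' Duplicates are collapsed with a warning. Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path file path.
#' @param label set label; defaults to the file name.
#' @param chain chain id for bare-number lines.
#' @param population optional population keys.
#' @export
load_sector <- function(path, label = NULL, chain = "A", population = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  toks <- lines[keep]
  lineno <- which(keep)
  keys <- character(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (grepl("^[A-Za-z0-9]+:[0-9]+$", t)) {
      keys[i] <- t
    } else if (grepl("^[0-9]+$", t)) {
      keys[i] <- res_key(chain, as.integer(t))
    } else {
      stop("unparseable sector token '", t, "' at line ", lineno[i],
           " of ", path, call. = FALSE)
    }
  }
  if (anyDuplicated(keys)) {
    warning("duplicate residues in sector file ", basename(path),
            " collapsed", call. = FALSE)
  }
  residue_set(keys, label = if (is.null(label))
                tools::file_path_sans_ext(basename(path)) else label,
              population = population,
              provenance = paste0("file:", basename(path)))
}

#' Write a residue set to a plain-text sector file
#' @param set a [residue_set].
#' @param path output path.
#' @export
write_sector <- function(set, path) {
  df <- parse_res_key(set$members)
  writeLines(set$members[order(df$chain, df$resnum)], path)
  invisible(path)
}

#' Restrict a residue set to a population
#'
#' Intersects the members with the population and re-declares the
#' population; used when an externally supplied sector extends beyond the
#' measurable universe.
#' @param set a [residue_set].
#' @param population character keys or a [residue_set].
#' @export
restrict_to_population <- function(set, population) {
  pop <- if (inherits(population, "residue_set")) population$members
         else unique(as.character(population))
  residue_set(intersect(set$members, pop), label = set$label,
              population = pop,
              provenance = paste0(set$provenance, " | restricted"))
}
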