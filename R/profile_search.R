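#' Build a position-specific scoring profile from a seed alignment
#'
#' Constructs a per-column residue emission model from a gapped seed
#' alignment. Alignment columns whose gap fraction reaches `max_gap_frac`
#' are dropped. Emissions are smoothed with background pseudocounts:
#' `emission[a] = (count_a + w * background_a) / (n_column + w)`, where
#' `n_column` is the number of non-gap residues in the column.
#'
#' @param seed_alignment Character vector of equal-length aligned sequences
#'   (gaps as `-`).
#' @param pseudocount_weight Nonnegative pseudocount weight `w` (default 1).
#' @param background Length-20 named probability vector over the standard
#'   residues; defaults to uniform 1/20.
#' @param max_gap_frac Columns with a gap fraction `>= max_gap_frac` are
#'   dropped (default 0.5).
#' @return An object of class `hsf_profile`: list with `length`, `emissions`
#'   (20 x length matrix), `log_odds`, `background`, `pseudocount_weight`,
#'   `kept_columns` (indices into the original alignment) and optional
#'   per-column `elements` labels.
#' @export
build_profile <- function(seed_alignment, pseudocount_weight = 1,
                          background = NULL, max_gap_frac = 0.5) {
  if (length(seed_alignment) < 1) stop("empty seed alignment")
  L0 <- unique(nchar(seed_alignment))
  if (length(L0) != 1) stop("aligned sequences must have equal length")
  if (pseudocount_weight < 0) stop("pseudocount_weight must be nonnegative")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  } else {
    stopifnot(setequal(names(background), AA_STANDARD),
              abs(sum(background) - 1) < 1e-9, all(background > 0))
    background <- background[AA_STANDARD]
  }
  mat <- do.call(rbind, strsplit(toupper(seed_alignment), ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac < max_gap_frac - 1e-12)
  if (length(keep) == 0) stop("no columns left after gap-column removal")
  mat <- mat[, keep, drop = FALSE]
  w <- pseudocount_weight
  em <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA_STANDARD]
    counts <- table(factor(col, levels = AA_STANDARD))
    (as.numeric(counts) + w * background) / (length(col) + w)
  }, numeric(20))
  rownames(em) <- AA_STANDARD
  if (w == 0) em[em == 0] <- 0  # columns then emit observed residues only
  structure(list(length = ncol(em), emissions = em,
                 log_odds = log2(em / background), background = background,
                 pseudocount_weight = w, kept_columns = keep,
                 elements = NULL),
            class = "hsf_profile")
}

#' Attach secondary-structure element labels to a profile
#'
#' Labels each retained profile column with a DBD secondary-structure element
#' (`a1`, `b1`, `b2`, `a2`, `a3`, `b3`, `b4`) or `"-"` for loop/linker
#' columns, enabling element-presence calls in [detect_dbd()].
#'
#' @param model An `hsf_profile`.
#' @param elements Character vector of per-column labels for the *original*
#'   alignment columns.
#' @return The profile with an `elements` field for its retained columns.
#' @export
set_profile_elements <- function(model, elements) {
  stopifnot(inherits(model, "hsf_profile"))
  if (length(elements) < max(model$kept_columns))
    stop("element vector shorter than the seed alignment")
  model$elements <- elements[model$kept_columns]
  model
}

#' @export
print.hsf_profile <- function(x, ...) {
  cat("hsf_profile:", x$length, "columns, pseudocount weight",
      x$pseudocount_weight, "\n")
  invisible(x)
}

# per-window log-odds scores for one sequence; X scores 0 at every column
window_scores <- function(model, sequence) {
  n <- nchar(sequence)
  L <- model$length
  if (n < L) return(numeric(0))
  idx <- match(strsplit(sequence, "")[[1]], AA_STANDARD)
  lo <- model$log_odds
  nw <- n - L + 1
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    col <- lo[, j]
    v <- unname(col[idx[j:(j + nw - 1)]])
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

#' Scan a protein with a profile
#'
#' Scores every ungapped window of the target against the profile as the sum
#' of per-column log2 odds (emission over background).
#'
#' @param model An `hsf_profile`.
#' @param target Either a single sequence string or a one-row data frame with
#'   `id` and `sequence`.
#' @return Data frame of hits (`seq_id`, `start`, `end` 1-based inclusive,
#'   `bitscore`) sorted by descending bitscore; zero rows if the target is
#'   shorter than the profile.
#' @export
scan_profile <- function(model, target) {
  stopifnot(inherits(model, "hsf_profile"))
  if (is.data.frame(target)) {
    id <- target$id[1]; seq <- target$sequence[1]
  } else {
    id <- NA_character_; seq <- target
  }
  sc <- window_scores(model, seq)
  if (length(sc) == 0) {
    message("target shorter than profile; no windows scanned")
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), bitscore = numeric()))
  }
  out <- data.frame(seq_id = id, start = seq_along(sc),
                    end = seq_along(sc) + model$length - 1L, bitscore = sc,
                    stringsAsFactors = FALSE)
  out[order(-out$bitscore, out$start), , drop = FALSE]
}

#' Empirical E-value for a window score
#'
#' Converts a window bitscore into an expected number of equal-or-better hits
#' using an empirical null score sample: the per-window tail probability is
#' `P = (1 + #\{null >= score\}) / (n_null + 1)` and `E = P * n_windows`.
#'
#' @param hit_score Observed window bitscore.
#' @param null_scores Numeric vector of window scores from shuffled decoys.
#' @param n_windows Total number of windows scanned in the search.
#' @return The E-value (nonnegative real).
#' @export
estimate_evalue <- function(hit_score, null_scores, n_windows) {
  if (length(null_scores) == 0)
    stop("empty null score set: calibrate with shuffled decoys first")
  p <- (1 + sum(null_scores >= hit_score)) / (length(null_scores) + 1)
  p * n_windows
}

# Gumbel (EVD) right-tail probability fitted to null window scores by the
# method of moments; used for far-tail extrapolation where the empirical
# tail saturates at 1 / (n_null + 1).
gumbel_tail <- function(score, null_scores) {
  beta <- stats::sd(null_scores) * sqrt(6) / pi
  mu <- mean(null_scores) - 0.5772156649 * beta
  z <- (score - mu) / beta
  # P(S >= s) = 1 - exp(-exp(-z)); use the stable log1p form for large z
  -expm1(-exp(-z))
}

#' Screen a proteome for profile matches
#'
#' Scans every target with the profile, calibrates a null window-score
#' distribution from residue-shuffled decoys drawn from the same length
#' distribution, and returns the targets with at least one window below the
#' E-value threshold.
#'
#' The per-window tail probability is estimated from a Gumbel fit to the null
#' scores by default (`tail = "gumbel"`), which extrapolates beyond the
#' resolution limit of the empirical tail; `tail = "empirical"` uses
#' [estimate_evalue()] directly.
#'
#' @param model An `hsf_profile`.
#' @param proteome Data frame with `id` and `sequence` columns.
#' @param e_threshold E-value threshold (default 0.001).
#' @param n_shuffles Number of shuffled decoy sequences for the null
#'   (default 200).
#' @param tail `"gumbel"` (default) or `"empirical"`.
#' @param seed Integer seed controlling the decoy shuffles.
#' @return List with `candidates` (rows of `proteome` with a hit at
#'   `E < e_threshold`), `hits` (per-target best window with `bitscore` and
#'   `evalue`) and `n_windows` (total windows scanned).
#' @export
screen_proteome <- function(model, proteome, e_threshold = 0.001,
                            n_shuffles = 200, tail = c("gumbel", "empirical"),
                            seed = 1) {
  stopifnot(inherits(model, "hsf_profile"), is.data.frame(proteome))
  tail <- match.arg(tail)
  set.seed(seed)
  lens <- nchar(proteome$sequence)
  best <- vapply(proteome$sequence, function(s) {
    sc <- window_scores(model, s)
    if (length(sc) == 0) NA_real_ else max(sc)
  }, numeric(1), USE.NAMES = FALSE)
  n_windows <- sum(pmax(0L, lens - model$length + 1L))
  src <- sample(which(lens >= model$length), n_shuffles, replace = TRUE)
  null_scores <- unlist(lapply(src, function(i) {
    shuf <- paste(sample(strsplit(proteome$sequence[i], "")[[1]]),
                  collapse = "")
    window_scores(model, shuf)
  }))
  if (length(null_scores) == 0) stop("null calibration produced no windows")
  ev <- vapply(best, function(s) {
    if (is.na(s)) return(Inf)
    p <- if (tail == "gumbel") gumbel_tail(s, null_scores) else
      (1 + sum(null_scores >= s)) / (length(null_scores) + 1)
    p * n_windows
  }, numeric(1))
  hits <- data.frame(id = proteome$id, bitscore = best, evalue = ev,
                     stringsAsFactors = FALSE)
  list(candidates = proteome[!is.na(best) & ev < e_threshold, , drop = FALSE],
       hits = hits, n_windows = n_windows)
}
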