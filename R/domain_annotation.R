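DBD_ELEMENTS <- c("a1", "b1", "b2", "a2", "a3", "b3", "b4")

#' Load the shipped DBD seed alignment
#'
#' Returns the synthetic plant-Hsf DNA-binding-domain seed alignment shipped
#' with the package, together with per-column secondary-structure element
#' labels following the canonical alpha1-beta1-beta2-alpha2-alpha3-beta3-beta4
#' DBD layout. The seed is a synthetic consensus construct, not an export from
#' any external database.
#'
#' @return List with `alignment` (named character vector of aligned rows),
#'   `elements` (per-column labels, `"-"` for loops) and `consensus` (the
#'   first seed row).
#' @export
hsf_dbd_seed <- function() {
  afa <- read_fasta(system.file("extdata", "dbd_seed_synthetic.afa",
                                package = "hsfkit"))
  elements <- strsplit(readLines(system.file("extdata", "dbd_elements.txt",
                                             package = "hsfkit")), " ")[[1]]
  list(alignment = stats::setNames(afa$sequence, afa$id),
       elements = elements, consensus = afa$sequence[1])
}

#' Build the default DBD search profile
#'
#' Convenience wrapper: [build_profile()] on the shipped DBD seed with element
#' labels attached.
#'
#' @param pseudocount_weight Passed to [build_profile()].
#' @return An `hsf_profile` with element labels.
#' @export
hsf_dbd_profile <- function(pseudocount_weight = 1) {
  seed <- hsf_dbd_seed()
  set_profile_elements(build_profile(seed$alignment, pseudocount_weight),
                       seed$elements)
}

#' Locate the DNA-binding domain in a protein
#'
#' Scans the protein with an element-labelled DBD profile and returns the
#' best-scoring window if it clears the score floor. Each secondary-structure
#' element is called `full` when at least `full_frac` of its columns score
#' positively (log-odds of the aligned residue > 0), `partial` when some but
#' fewer do, and `absent` when none do.
#'
#' @param model An `hsf_profile` with element labels
#'   (see [set_profile_elements()]).
#' @param protein Sequence string or one-row data frame with `id`,`sequence`.
#' @param score_floor Minimum bitscore for a reported hit, as a fraction of
#'   the profile's maximum attainable bitscore (default 0.3).
#' @param full_frac Column fraction required for a `full` element call
#'   (default 0.8).
#' @return `NULL` if no window clears the floor; otherwise a list with
#'   `kind = "DBD"`, `start`, `end` (1-based inclusive), `score` and
#'   `element_presence` (named character over the seven elements).
#' @export
detect_dbd <- function(model, protein, score_floor = 0.3, full_frac = 0.8) {
  stopifnot(inherits(model, "hsf_profile"))
  if (is.null(model$elements)) stop("profile carries no element labels")
  seq <- if (is.data.frame(protein)) protein$sequence[1] else protein
  sc <- window_scores(model, seq)
  if (length(sc) == 0) return(NULL)
  max_attainable <- sum(apply(model$log_odds, 2, max))
  best <- which.max(sc)
  if (sc[best] < score_floor * max_attainable) return(NULL)
  res <- strsplit(substr(seq, best, best + model$length - 1), "")[[1]]
  colpos <- vapply(seq_len(model$length), function(j) {
    i <- match(res[j], AA_STANDARD)
    !is.na(i) && model$log_odds[i, j] > 0
  }, logical(1))
  presence <- vapply(DBD_ELEMENTS, function(el) {
    cols <- model$elements == el
    if (!any(cols)) return(NA_character_)
    f <- mean(colpos[cols])
    if (f >= full_frac) "full" else if (f > 0) "partial" else "absent"
  }, character(1))
  list(kind = "DBD", start = best, end = best + model$length - 1L,
       score = sc[best], element_presence = presence)
}

HYDROPHOBIC_AD <- c("L", "I", "V", "F", "M", "A")

# is seq[p..p+6] a heptad with hydrophobic a/d positions (fraction >= min_frac)
heptad_good <- function(residues, p, hydrophobic, min_frac) {
  ad <- residues[c(p, p + 3)]
  mean(ad %in% hydrophobic) >= min_frac
}

# maximal chain of good heptads stepping by 7, starting at the smallest
# admissible position >= from; returns c(start, end, n) or NULL
find_heptad_chain <- function(good, from, min_heptads = 2) {
  n <- length(good)
  p <- unname(from)
  while (p + 7 <= n) {
    if (good[p] && good[p + 7]) {
      k <- 2
      while (p + 7 * k <= n && good[p + 7 * k]) k <- k + 1
      return(c(start = p, end = p + 7 * k - 1, n = k))
    }
    p <- p + 1
  }
  NULL
}

#' Detect the HR-A/B oligomerization region
#'
#' Searches C-terminal of the DBD for two arrays of coiled-coil heptad
#' repeats. A heptad is accepted when its `a`/`d` positions are hydrophobic
#' (set `LIVFMA` by default, fraction `>= min_frac` per heptad); an array is a
#' maximal run of at least two frame-aligned heptads. HR-A is the first array
#' after `search_start`, HR-B the next one, and the insert is the residue
#' count strictly between them. A single contiguous array of four or more
#' heptads is interpreted as a fused HR-A/HR-B with insert 0 (its last two
#' heptads are reported as HR-B).
#'
#' @param protein Sequence string or one-row data frame.
#' @param search_start 1-based position at which the search begins (typically
#'   one past the DBD end).
#' @param hydrophobic Residues accepted at heptad `a`/`d` positions.
#' @param min_frac Minimum hydrophobic fraction over the `a`/`d` positions of
#'   a heptad (default 0.75, i.e. both positions with the default set).
#' @return `NULL` if fewer than two heptad arrays are found; otherwise a list
#'   with `hr_a`, `hr_b` (each `c(start, end)`, 1-based inclusive) and
#'   `insert_length`.
#' @export
detect_hrab <- function(protein, search_start = 1,
                        hydrophobic = HYDROPHOBIC_AD, min_frac = 0.75) {
  seq <- if (is.data.frame(protein)) protein$sequence[1] else protein
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  if (search_start < 1 || search_start > n - 13) return(NULL)
  good <- rep(FALSE, n)
  for (p in search_start:(n - 6))
    good[p] <- heptad_good(res, p, hydrophobic, min_frac)
  hra <- find_heptad_chain(good, search_start)
  if (is.null(hra)) return(NULL)
  hrb <- find_heptad_chain(good, hra["end"] + 1)
  if (is.null(hrb)) {
    if (hra["n"] >= 4) {
      split_at <- hra["start"] + 7 * (hra["n"] - 2)
      hrb <- c(start = unname(split_at), end = unname(hra["end"]), n = 2)
      hra <- c(start = unname(hra["start"]), end = unname(split_at - 1),
               n = unname(hra["n"]) - 2)
    } else return(NULL)
  }
  insert <- unname(hrb["start"] - hra["end"] - 1)
  list(hr_a = unname(c(hra["start"], hra["end"])),
       hr_b = unname(c(hrb["start"], hrb["end"])),
       insert_length = as.integer(insert))
}

#' Classify an Hsf by its HR-A/B insert length
#'
#' Plant Hsfs fall into three classes by the number of residues inserted
#' between HR-A and HR-B: class A carries a 21-residue insert, class C a
#' 7-residue insert, and class B none. The classifier bands interpolate these
#' canonical values (B: 0-2, C: 3-13, A: >= 14); inserts outside the canonical
#' values +/- 2 are assigned by band but flagged as out-of-band.
#'
#' @param insert_length Nonnegative integer.
#' @return List with `hsf_class`, `insert_length`, `in_band` (TRUE iff the
#'   insert is within 2 of a canonical 0/7/21) and a `note`.
#' @export
classify_by_insert <- function(insert_length) {
  if (is.na(insert_length) || insert_length < 0)
    stop("insert_length must be a nonnegative integer")
  k <- as.integer(insert_length)
  cls <- if (k <= 2) "B" else if (k <= 13) "C" else "A"
  canon <- c(A = 21L, B = 0L, C = 7L)[cls]
  in_band <- abs(k - canon) <= 2
  list(hsf_class = unname(cls), insert_length = k, in_band = unname(in_band),
       note = if (in_band) "" else
         sprintf("insert %d outside canonical %d +/- 2 for class %s",
                 k, canon, cls))
}

#' Apply the family retention filter
#'
#' Drops candidates lacking a DBD or an HR-A/B annotation, then resolves
#' overlapping gene models (same chromosome and strand) by keeping the longest
#' protein, ties broken lexicographically by ID. Every exclusion is reported
#' with its reason.
#'
#' @param candidates Data frame with columns `id`, `aa` (protein length),
#'   `has_dbd`, `has_hrab` (logicals).
#' @param gene_models Optional data frame with columns `id`, `chromosome`,
#'   `strand`, `start`, `end` giving the genomic span of each candidate.
#' @return List with `retained` (subset of `candidates`) and `exclusions`
#'   (data frame `id`, `reason`).
#' @export
apply_family_filter <- function(candidates, gene_models = NULL) {
  stopifnot(is.data.frame(candidates),
            all(c("id", "aa", "has_dbd", "has_hrab") %in% names(candidates)))
  excl <- data.frame(id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  drop <- !candidates$has_dbd | !candidates$has_hrab
  if (any(drop)) {
    reason <- ifelse(!candidates$has_dbd[drop] & !candidates$has_hrab[drop],
                     "no DBD and no HR-A/B",
                     ifelse(!candidates$has_dbd[drop], "no DBD", "no HR-A/B"))
    excl <- rbind(excl, data.frame(id = candidates$id[drop], reason = reason,
                                   stringsAsFactors = FALSE))
  }
  kept <- candidates[!drop, , drop = FALSE]
  if (!is.null(gene_models) && nrow(kept) > 1) {
    gm <- gene_models[gene_models$id %in% kept$id, , drop = FALSE]
    gm <- merge(gm, kept[, c("id", "aa")], by = "id")
    for (key in unique(paste(gm$chromosome, gm$strand))) {
      g <- gm[paste(gm$chromosome, gm$strand) == key, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) < 2) next
      # connected components of interval overlap
      comp <- cumsum(c(1, g$start[-1] > cummax(g$end[-nrow(g)])))
      for (cc in unique(comp)) {
        members <- g[comp == cc, , drop = FALSE]
        if (nrow(members) < 2) next
        members <- members[order(-members$aa, members$id), , drop = FALSE]
        losers <- members$id[-1]
        excl <- rbind(excl, data.frame(
          id = losers,
          reason = sprintf("overlaps %s; shorter protein", members$id[1]),
          stringsAsFactors = FALSE))
        kept <- kept[!kept$id %in% losers, , drop = FALSE]
      }
    }
  }
  list(retained = kept, exclusions = excl)
}
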