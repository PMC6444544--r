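# ExPASy-standard average residue masses (Da) and the mass of water
AA_AVG_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# side-chain and terminal pKa values (Lehninger table)
PKA <- list(pos = c(Nterm = 9.69, K = 10.53, R = 12.48, H = 6.00),
            neg = c(Cterm = 2.34, D = 3.65, E = 4.25, C = 8.18, Y = 10.07))

motif_hit_frame <- function(kind = character(), position = integer(),
                            matched = character()) {
  data.frame(kind = kind, position = as.integer(position), matched = matched,
              stringsAsFactors = FALSE)
}

#' Scan for AHA activator motifs
#'
#' The aromatic-hydrophobic-acidic (AHA) activator element of class-A Hsf
#' C-terminal activation domains is matched with the core consensus
#' `F W x x [FL]`; whether the core is followed within three residues by an
#' additional `[FIL]` is reported but not required, since published class-A
#' activator peptides do not always carry it.
#'
#' @param seq Protein sequence string.
#' @param pattern Core regular expression (default `"FW..[FL]"`).
#' @return Data frame of non-overlapping hits: `kind`, `position` (1-based),
#'   `matched` (the core match) and `extended` (trailing `[FIL]` present).
#' @export
scan_aha <- function(seq, pattern = "FW..[FL]") {
  m <- gregexpr(pattern, seq)[[1]]
  if (m[1] == -1) return(cbind(motif_hit_frame(), extended = logical()))
  len <- attr(m, "match.length")
  hits <- motif_hit_frame("AHA", as.integer(m),
                          substring(seq, m, m + len - 1))
  hits$extended <- vapply(seq_along(m), function(i) {
    tail_start <- m[i] + len[i]
    grepl("[FIL]", substr(seq, tail_start, tail_start + 2))
  }, logical(1))
  hits
}

# count of K/R in every window of width w (zero-length result if seq shorter)
kr_window_counts <- function(residues, w) {
  kr <- as.integer(residues %in% c("K", "R"))
  n <- length(kr)
  if (n < w) return(integer(0))
  cs <- cumsum(c(0L, kr))
  cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
}

#' Scan for nuclear localization signals
#'
#' Consensus-based NLS caller. Monopartite signals are basic clusters: any
#' 4-residue window containing at least 3 K/R; overlapping windows are merged
#' into maximal runs. Bipartite signals are two basic clusters (a 3-window
#' with >= 2 K/R, then a 5-window with >= 3 K/R) separated by a 6-14 residue
#' spacer.
#'
#' @param seq Protein sequence string.
#' @return Data frame of hits with `kind` (`NLS_mono`/`NLS_bipartite`),
#'   `position` and `matched`.
#' @export
scan_nls <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  out <- motif_hit_frame()
  c4 <- kr_window_counts(res, 4)
  qual <- which(c4 >= 3)
  if (length(qual) > 0) {
    runs <- split(qual, cumsum(c(1, diff(qual) > 1)))
    for (r in runs) {
      s <- min(r); e <- max(r) + 3
      # trim the merged run to its basic core
      while (s < e && !res[s] %in% c("K", "R")) s <- s + 1
      while (e > s && !res[e] %in% c("K", "R")) e <- e - 1
      out <- rbind(out, motif_hit_frame("NLS_mono", s,
                                        paste(res[s:e], collapse = "")))
    }
  }
  c3 <- kr_window_counts(res, 3)
  c5 <- kr_window_counts(res, 5)
  last_end <- 0
  for (s1 in which(c3 >= 2)) {
    if (s1 <= last_end) next  # overlapping bipartite variants collapse
    for (spacer in 6:14) {
      s2 <- s1 + 3 + spacer
      if (s2 <= length(c5) && c5[s2] >= 3) {
        out <- rbind(out, motif_hit_frame(
          "NLS_bipartite", s1, paste(res[s1:(s2 + 4)], collapse = "")))
        last_end <- s2 + 4
        break
      }
    }
  }
  out
}

NES_PHI <- c("L", "I", "V", "F", "M")

#' Scan for leucine-rich nuclear export signals
#'
#' Matches the classic leucine-rich NES consensus
#' `Phi-x(1,4)-Phi-x(1,4)-Phi-x(0,2)-Phi` with `Phi` in `{L,I,V,F,M}`.
#' At each start position the longest match is taken; matches are then
#' reported greedily left to right without overlap (maximal matches).
#'
#' @param seq Protein sequence string.
#' @return Data frame of hits (`kind = "NES"`, `position`, `matched`).
#' @export
scan_nes <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  phi <- which(res %in% NES_PHI)
  out <- motif_hit_frame()
  if (length(phi) < 4) return(out)
  is_phi <- res %in% NES_PHI
  # longest match length starting at each phi position, 0 if none
  longest_at <- function(p1) {
    best <- 0L
    for (g1 in 4:1) {
      p2 <- p1 + 1 + g1
      if (p2 > n || !is_phi[p2]) next
      for (g2 in 4:1) {
        p3 <- p2 + 1 + g2
        if (p3 > n || !is_phi[p3]) next
        for (g3 in 2:0) {
          p4 <- p3 + 1 + g3
          if (p4 > n || !is_phi[p4]) next
          best <- max(best, p4 - p1 + 1L)
        }
      }
    }
    best
  }
  p <- 1L
  while (p <= n - 5) {  # shortest admissible match spans 6 residues
    if (is_phi[p]) {
      len <- longest_at(p)
      if (len > 0) {
        out <- rbind(out, motif_hit_frame(
          "NES", p, paste(res[p:(p + len - 1)], collapse = "")))
        p <- p + len
        next
      }
    }
    p <- p + 1L
  }
  out
}

#' Default ER membrane retention signal lexicon
#'
#' C-terminal tetrapeptides treated as endoplasmic-reticulum membrane
#' retention signals. The lexicon is data, not code: it is shipped as an
#' editable plain-text file and can be replaced per call.
#'
#' @return Character vector of tetrapeptides.
#' @export
er_retention_lexicon <- function() {
  readLines(system.file("extdata", "er_retention_lexicon.txt",
                        package = "hsfkit"))
}

#' Scan C-terminal signals: ER retention and the LFGV repressor tetrapeptide
#'
#' The ER retention call matches the protein's C-terminal tetrapeptide
#' against a lexicon. The LFGV call is an exact tetrapeptide search
#' restricted to the C-terminal half of the protein, where the class-B
#' repressor element resides.
#'
#' @param seq Protein sequence (length >= 4).
#' @param er_lexicon Tetrapeptide lexicon (default
#'   [er_retention_lexicon()]).
#' @param lfgv Repressor tetrapeptide (default `"LFGV"`).
#' @return Data frame of hits with `kind` (`ER`/`LFGV`), `position`,
#'   `matched`.
#' @export
scan_c_terminal_signals <- function(seq, er_lexicon = er_retention_lexicon(),
                                    lfgv = "LFGV") {
  n <- nchar(seq)
  if (n < 4) stop("sequence shorter than 4 residues")
  out <- motif_hit_frame()
  tail4 <- substr(seq, n - 3, n)
  if (tail4 %in% er_lexicon)
    out <- rbind(out, motif_hit_frame("ER", n - 3L, tail4))
  m <- gregexpr(lfgv, seq, fixed = TRUE)[[1]]
  if (m[1] != -1) {
    keep <- m > n / 2
    if (any(keep))
      out <- rbind(out, motif_hit_frame("LFGV", as.integer(m[keep]),
                                        rep(lfgv, sum(keep))))
  }
  out
}

#' Protein molecular weight (average isotopic)
#'
#' Sum of ExPASy-standard average residue masses plus one water. Unknown
#' residues (`X`) are excluded with a warning.
#'
#' @param seq Protein sequence string.
#' @return Molecular weight in Daltons.
#' @export
compute_mw <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  res <- strsplit(toupper(seq), "")[[1]]
  nx <- sum(res == "X")
  if (nx > 0) {
    warning(nx, " unknown residue(s) 'X' excluded from molecular weight")
    res <- res[res != "X"]
  }
  m <- AA_AVG_MASS[res]
  if (anyNA(m)) stop("illegal residue: ", res[which(is.na(m))[1]])
  sum(m) + WATER_MASS
}

# signed net charge at a given pH (Henderson-Hasselbalch over termini and
# the ionisable side chains D, E, C, Y, K, R, H); strictly decreasing in pH
protein_net_charge <- function(counts, pH) {
  pos_n <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
             H = unname(counts["H"]))
  neg_n <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
             C = unname(counts["C"]), Y = unname(counts["Y"]))
  sum(pos_n / (1 + 10^(pH - PKA$pos))) - sum(neg_n / (1 + 10^(PKA$neg - pH)))
}

#' Protein isoelectric point
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge of the protein
#' is zero, by bisection to `|charge| < tol`. The pKa table (Lehninger
#' values for D, E, C, Y, K, R, H and the termini) is documented in
#' `hsfkit:::PKA`. Unknown residues are excluded.
#'
#' @param seq Protein sequence string.
#' @param tol Charge tolerance for convergence (default 1e-4).
#' @return The isoelectric point (pH units, in (0, 14)).
#' @export
compute_pi <- function(seq, tol = 1e-4) {
  if (!nzchar(seq)) stop("empty sequence")
  res <- strsplit(toupper(seq), "")[[1]]
  res <- res[res != "X"]
  counts <- table(factor(res, levels = AA_STANDARD))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- protein_net_charge(counts, mid)
    if (abs(q) < tol || hi - lo < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Annotate the Table-style motif columns for one protein
#'
#' Runs all C-terminal motif scanners plus the physico-chemical calculators
#' and returns the per-gene annotation bundle.
#'
#' @param seq Protein sequence string.
#' @param er_lexicon Passed to [scan_c_terminal_signals()].
#' @return List with `aa`, `mw_da`, `pi`, and data frames `nes`, `nls`,
#'   `aha`, `cterm`.
#' @export
annotate_motifs <- function(seq, er_lexicon = er_retention_lexicon()) {
  list(aa = nchar(seq), mw_da = compute_mw(seq), pi = compute_pi(seq),
       nes = scan_nes(seq), nls = scan_nls(seq), aha = scan_aha(seq),
       cterm = scan_c_terminal_signals(seq, er_lexicon))
}
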