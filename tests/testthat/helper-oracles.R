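# shared fixtures and independent brute-force oracles used across tests

random_protein <- function(n, alphabet = c("A","R","N","D","C","E","Q","G",
                                           "H","I","L","K","M","F","P","S",
                                           "T","W","Y","V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# alphabet enriched for basic and hydrophobic residues so NLS/NES hits occur
motif_rich_alphabet <- c("K","K","R","R","L","L","I","V","F","M","G","S","T",
                         "E","D","A","P","Q","N","W")

# ideal heptad construct: 3 HR-A heptads + k polar insert + 2 HR-B heptads
heptad_construct <- function(k, lead = 0) {
  polar <- c("D","E","G","H","K","N","P","Q","R","S","T")
  paste0(paste(sample(polar, lead, replace = TRUE), collapse = ""),
         "LEQLKSDLRELESDLKQLEND",
         paste(sample(polar, k, replace = TRUE), collapse = ""),
         "LEDLKTRLSELRND")
}

# greedy leftmost non-overlap reduction of (start, length) matches
greedy_nonoverlap <- function(starts, lens) {
  keep_s <- integer(0); keep_l <- integer(0)
  last_end <- 0
  for (i in order(starts)) {
    if (starts[i] > last_end) {
      keep_s <- c(keep_s, starts[i]); keep_l <- c(keep_l, lens[i])
      last_end <- starts[i] + lens[i] - 1
    }
  }
  list(start = keep_s, len = keep_l)
}

# NES oracle: anchored full-match regex over all substrings, longest per
# start, then the same greedy reduction the scanner defines
oracle_nes <- function(seq) {
  n <- nchar(seq)
  pat <- "^[LIVFM].{1,4}[LIVFM].{1,4}[LIVFM].{0,2}[LIVFM]$"
  best_len <- rep(0L, n)
  for (len in 6:14) {
    if (len > n) break
    starts <- 1:(n - len + 1)
    hit <- grepl(pat, substring(seq, starts, starts + len - 1))
    best_len[starts[hit]] <- len  # increasing len loop keeps the longest
  }
  ok <- which(best_len > 0)
  red <- greedy_nonoverlap(ok, best_len[ok])
  if (!length(red$start))
    return(data.frame(position = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  data.frame(position = red$start,
             matched = substring(seq, red$start, red$start + red$len - 1),
             stringsAsFactors = FALSE)
}

# monopartite NLS oracle: K/R counts per 4-window via gsub, merged + trimmed
oracle_nls_mono <- function(seq) {
  n <- nchar(seq)
  if (n < 4) return(data.frame(position = integer(), matched = character()))
  starts <- 1:(n - 3)
  wins <- substring(seq, starts, starts + 3)
  qual <- starts[nchar(gsub("[^KR]", "", wins)) >= 3]
  if (!length(qual)) return(data.frame(position = integer(),
                                       matched = character()))
  runs <- split(qual, cumsum(c(1, diff(qual) > 1)))
  res <- strsplit(seq, "")[[1]]
  out <- lapply(runs, function(r) {
    s <- min(r); e <- max(r) + 3
    while (s < e && !res[s] %in% c("K", "R")) s <- s + 1
    while (e > s && !res[e] %in% c("K", "R")) e <- e - 1
    data.frame(position = s, matched = paste(res[s:e], collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

# AHA oracle: anchored full-match over all 5-mers, greedy non-overlap
oracle_aha <- function(seq) {
  n <- nchar(seq)
  if (n < 5) return(data.frame(position = integer(), matched = character()))
  starts <- 1:(n - 4)
  five <- substring(seq, starts, starts + 4)
  ok <- starts[grepl("^FW..[FL]$", five)]
  red <- greedy_nonoverlap(ok, rep(5L, length(ok)))
  if (!length(red$start))
    return(data.frame(position = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  data.frame(position = red$start,
             matched = substring(seq, red$start, red$start + 4),
             stringsAsFactors = FALSE)
}

# brute-force window bitscore via substr, independent of window_scores
oracle_window_score <- function(model, seq, start) {
  win <- strsplit(substr(seq, start, start + model$length - 1), "")[[1]]
  sum(vapply(seq_len(model$length), function(j) {
    i <- match(win[j], rownames(model$log_odds))
    if (is.na(i)) 0 else model$log_odds[i, j]
  }, numeric(1)))
}
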