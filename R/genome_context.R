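#' Per-chromosome and per-homeologous-group gene counts
#'
#' Counts genes on each of the 21 bread-wheat chromosomes (1A..7D). Genes on
#' unanchored scaffolds (`"U"`) are excluded from the chromosome totals and
#' reported separately. Group totals sum the A, B and D chromosomes of each
#' homeologous group 1-7.
#'
#' @param chromosomes Character vector of chromosome labels (`"1A"`..`"7D"`,
#'   `"U"`), or a list of gene models with a `chromosome` field.
#' @return List with `per_chromosome` (named integer, 21 entries),
#'   `per_group` (named integer, groups 1-7) and `unanchored` (count on `U`).
#' @export
chromosome_counts <- function(chromosomes) {
  if (is.list(chromosomes) && !is.data.frame(chromosomes))
    chromosomes <- vapply(chromosomes, `[[`, character(1), "chromosome")
  bad <- setdiff(unique(chromosomes), VALID_CHROMOSOMES)
  if (length(bad) > 0) stop("invalid chromosome label: ", bad[1])
  chrom_levels <- setdiff(VALID_CHROMOSOMES, "U")
  per_chrom <- table(factor(chromosomes[chromosomes != "U"],
                            levels = chrom_levels))
  groups <- substr(names(per_chrom), 1, 1)
  per_group <- tapply(as.integer(per_chrom), groups, sum)
  list(per_chromosome = stats::setNames(as.integer(per_chrom),
                                        names(per_chrom)),
       per_group = stats::setNames(as.integer(per_group), names(per_group)),
       unanchored = sum(chromosomes == "U"))
}

#' Tally complete homeolog triads from an annotation table
#'
#' Counts A/B/D homeolog triads using the family naming convention in which
#' homeologous copies receive consecutive indices within a subclass: a triad
#' is a window of three consecutive-index genes covering the A, B and D
#' subgenomes (group numbers are deliberately ignored because chromosome
#' translocations, e.g. wheat 4A/5A, place genuine homeologs on different
#' group numbers). Genes on unanchored scaffolds never join a triad.
#'
#' @param ann Data frame with columns `gene`, `chromosome`, `subclass`,
#'   `index` (as from [wheat_hsf_annotation()]).
#' @return List with `n_triads`, `triad_members` (character vector of gene
#'   names in complete triads) and `ungrouped` (genes not in any triad).
#' @export
triad_tally <- function(ann) {
  stopifnot(all(c("gene", "chromosome", "subclass", "index") %in% names(ann)))
  members <- character(0)
  n <- 0L
  for (s in unique(ann$subclass)) {
    g <- ann[ann$subclass == s, , drop = FALSE]
    g <- g[order(g$index), , drop = FALSE]
    i <- 1
    while (i + 2 <= nrow(g)) {
      ch <- g$chromosome[i:(i + 2)]
      if (!any(ch == "U") && setequal(substr(ch, 2, 2), c("A", "B", "D"))) {
        n <- n + 1L
        members <- c(members, g$gene[i:(i + 2)])
        i <- i + 3
      } else i <- i + 1
    }
  }
  list(n_triads = n, triad_members = members,
       ungrouped = setdiff(ann$gene, members))
}

# percent identity of a global (Needleman-Wunsch) alignment of two sequences
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln, type = "PID1")
}

#' Identify homeolog A/B/D gene groups by sequence identity
#'
#' Candidate triples are one gene on each of the nA, nB and nD chromosomes of
#' the same homeologous group number and the same subclass. A triple is
#' accepted when all three pairwise global identities reach the threshold.
#' Each gene joins at most one group; conflicts are resolved greedily by
#' descending mean identity (ties by gene ID). Genes on `U` never group.
#'
#' @param genes Data frame with columns `id`, `chromosome`, `subclass`,
#'   `sequence` (protein by default; use CDS consistently if preferred).
#' @param identity_threshold Minimum pairwise identity, fraction (default
#'   0.90).
#' @return List with `groups` (data frame `group`, `A`, `B`, `D`,
#'   `min_identity`, `mean_identity`, `homeologous_group`) and
#'   `incomplete` (data frame of best same-subclass cross-subgenome pairs
#'   reaching the threshold for ungrouped genes).
#' @export
find_homeolog_groups <- function(genes, identity_threshold = 0.90) {
  stopifnot(all(c("id", "chromosome", "subclass", "sequence") %in% names(genes)))
  genes <- genes[genes$chromosome != "U", , drop = FALSE]
  genes$grp_no <- substr(genes$chromosome, 1, 1)
  genes$subgenome <- substr(genes$chromosome, 2, 2)
  cand <- list()
  for (key in unique(paste(genes$subclass, genes$grp_no))) {
    g <- genes[paste(genes$subclass, genes$grp_no) == key, , drop = FALSE]
    ga <- g$id[g$subgenome == "A"]; gb <- g$id[g$subgenome == "B"]
    gd <- g$id[g$subgenome == "D"]
    if (!length(ga) || !length(gb) || !length(gd)) next
    for (a in ga) for (b in gb) for (dd in gd)
      cand[[length(cand) + 1]] <- c(a, b, dd)
  }
  seqs <- stats::setNames(genes$sequence, genes$id)
  grp_no <- stats::setNames(genes$grp_no, genes$id)
  pid_cache <- new.env()
  pid2 <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = "~")
    if (is.null(pid_cache[[key]]))
      pid_cache[[key]] <- global_identity(seqs[[x]], seqs[[y]]) / 100
    pid_cache[[key]]
  }
  scored <- lapply(cand, function(tr) {
    ids <- c(pid2(tr[1], tr[2]), pid2(tr[1], tr[3]), pid2(tr[2], tr[3]))
    list(triple = tr, min_id = min(ids), mean_id = mean(ids))
  })
  scored <- Filter(function(s) s$min_id >= identity_threshold, scored)
  ord <- order(-vapply(scored, `[[`, numeric(1), "mean_id"),
               vapply(scored, function(s) paste(s$triple, collapse = ","),
                      character(1)))
  used <- character(0)
  groups <- list()
  for (s in scored[ord]) {
    if (any(s$triple %in% used)) next
    used <- c(used, s$triple)
    groups[[length(groups) + 1]] <- data.frame(
      group = length(groups) + 1L, A = s$triple[1], B = s$triple[2],
      D = s$triple[3], min_identity = s$min_id, mean_identity = s$mean_id,
      homeologous_group = unname(grp_no[s$triple[1]]),
      stringsAsFactors = FALSE)
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(group = integer(), A = character(), B = character(),
               D = character(), min_identity = numeric(),
               mean_identity = numeric(), homeologous_group = character(),
               stringsAsFactors = FALSE)
  leftovers <- setdiff(genes$id, used)
  pairs <- list()
  for (x in leftovers) {
    mates <- genes$id[genes$subclass == genes$subclass[genes$id == x] &
                      genes$id != x &
                      genes$subgenome != genes$subgenome[genes$id == x]]
    mates <- setdiff(mates, used)
    if (!length(mates)) next
    ids <- vapply(mates, function(y) pid2(x, y), numeric(1))
    if (max(ids) >= identity_threshold) {
      best <- mates[which.max(ids)]
      key <- paste(sort(c(x, best)), collapse = "~")
      pairs[[key]] <- data.frame(gene1 = sort(c(x, best))[1],
                                 gene2 = sort(c(x, best))[2],
                                 identity = max(ids), stringsAsFactors = FALSE)
    }
  }
  incomplete <- if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE)) else
    data.frame(gene1 = character(), gene2 = character(), identity = numeric(),
               stringsAsFactors = FALSE)
  list(groups = groups, incomplete = incomplete)
}

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- utf8ToInt(substr(a, 1, n)); bv <- utf8ToInt(substr(b, 1, n))
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

# recursive exact-anchoring spliced placement; returns exon matrix or NULL
anchor_exons <- function(cdna, genomic, c0, g0, probe_len = 12L) {
  nc <- nchar(cdna); ng <- nchar(genomic)
  L <- lcp_len(substr(cdna, c0, nc), substr(genomic, g0, ng))
  if (c0 + L - 1 == nc)  # final exon
    return(matrix(c(g0, g0 + L - 1), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  if (L < 1) return(NULL)
  for (k in L:1) {  # exon boundary at c0+k-1; intron must start GT
    ist <- g0 + k
    if (substr(genomic, ist, ist + 1) != "GT") next
    probe <- substr(cdna, c0 + k, min(nc, c0 + k + probe_len - 1))
    from <- ist + 4  # minimal intron GT..AG
    repeat {
      hit <- regexpr(probe, substr(genomic, from, ng), fixed = TRUE)
      if (hit == -1) break
      nxt <- from + as.integer(hit) - 1L
      if (nxt - 2 >= ist + 2 && substr(genomic, nxt - 2, nxt - 1) == "AG") {
        rest <- anchor_exons(cdna, genomic, c0 + k, nxt, probe_len)
        if (!is.null(rest))
          return(rbind(c(g0, g0 + k - 1), rest))
      }
      from <- nxt + 1
    }
  }
  NULL
}

#' Derive intron-exon structure from a cDNA/genomic pair
#'
#' Reconstructs exons by ordered exact anchoring of cDNA blocks in the
#' genomic sequence, accepting only splice junctions bounded by the canonical
#' GT..AG dinucleotides. This is an exact-match spliced placement for
#' sequences where the cDNA is the concatenation of genomic exon blocks (as
#' produced by the synthetic generator); mismatched inputs raise an error
#' rather than guessing an alignment.
#'
#' @param cdna cDNA sequence string.
#' @param genomic Genomic sequence string containing the gene.
#' @return List of class `gene_structure`: `exons` (matrix of genomic
#'   start/end, 1-based inclusive), `introns` (matrix, zero rows if none),
#'   `intron_lengths`, `n_introns`.
#' @export
derive_gene_structure <- function(cdna, genomic) {
  cdna <- toupper(cdna); genomic <- toupper(genomic)
  start <- as.integer(regexpr(substr(cdna, 1, min(nchar(cdna), 12L)),
                              genomic, fixed = TRUE))
  if (start == -1) stop("cDNA not reconstructable from genomic sequence")
  exons <- anchor_exons(cdna, genomic, 1L, start)
  if (is.null(exons)) stop("cDNA not reconstructable from genomic sequence")
  storage.mode(exons) <- "integer"
  ne <- nrow(exons)
  introns <- if (ne > 1)
    cbind(start = exons[-ne, 2] + 1L, end = exons[-1, 1] - 1L) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  structure(list(exons = exons, introns = introns,
                 intron_lengths = if (ne > 1)
                   as.integer(introns[, 2] - introns[, 1] + 1) else integer(0),
                 n_introns = ne - 1L),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat("gene structure:", nrow(x$exons), "exon(s),", x$n_introns,
      "intron(s)", if (x$n_introns > 0)
        paste0("(lengths ", paste(x$intron_lengths, collapse = ", "), " bp)"),
      "\n")
  invisible(x)
}

#' Does an intron interrupt the DNA-binding domain?
#'
#' Projects a protein-coordinate DBD span onto the cDNA (via the coding
#' offset) and reports whether any intron boundary falls strictly within it.
#'
#' @param structure A `gene_structure` from [derive_gene_structure()].
#' @param dbd_protein_span `c(start, end)` of the DBD on the protein,
#'   1-based inclusive.
#' @param cds_offset 0-based offset of the first coding base on the cDNA
#'   (0 when the cDNA starts at the start codon).
#' @return List with `in_dbd` (logical) and `intron_index` (first qualifying
#'   intron, or `NA`).
#' @export
intron_in_dbd <- function(structure, dbd_protein_span, cds_offset = 0L) {
  stopifnot(inherits(structure, "gene_structure"))
  if (structure$n_introns == 0)
    return(list(in_dbd = FALSE, intron_index = NA_integer_))
  cdna_start <- cds_offset + (dbd_protein_span[1] - 1) * 3 + 1
  cdna_end <- cds_offset + dbd_protein_span[2] * 3
  exon_len <- structure$exons[, 2] - structure$exons[, 1] + 1
  boundaries <- cumsum(exon_len)[-nrow(structure$exons)]  # cDNA pos before each intron
  inside <- which(boundaries >= cdna_start & boundaries < cdna_end)
  list(in_dbd = length(inside) > 0,
       intron_index = if (length(inside)) inside[1] else NA_integer_)
}
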