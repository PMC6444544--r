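#' hsfkit: plant heat shock transcription factor family analysis
#'
#' Discovery, domain annotation, class/subclass assignment, homeolog-triad
#' detection, gene-structure and treatment-response analysis for plant Hsf
#' gene families, plus a seedable synthetic-data generator for end-to-end
#' validation.
#'
#' @keywords internal
"_PACKAGE"

AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a data frame of protein records. Sequences are
#' uppercased and validated against the 20 standard one-letter residue codes
#' plus `X` (unknown residue).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first token of the header),
#'   `description` (remainder of the header) and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  ids <- unname(sub("\\s.*$", "", headers))
  desc <- unname(ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), ""))
  seqs <- unname(toupper(as.character(set)))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0)
    stop("FASTA format error: record ", empty[1], " ('", ids[empty[1]],
         "') has an empty sequence")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate sequence ID: ", dup[1])
  bad <- regexpr(sprintf("[^%sX]", paste(AA_STANDARD, collapse = "")), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal residue character '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i])
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse an Hsf gene name
#'
#' Gene names follow the `<family>Hsf<class><subclass digits>-<index>`
#' convention, e.g. `"TaHsfA2-10"`. Both the plain hyphen and the en-dash
#' separator are accepted.
#'
#' @param name Gene name string.
#' @return An object of class `hsf_gene_name`: a list with fields `family`
#'   (e.g. `"Ta"`), `hsf_class` (`"A"`, `"B"` or `"C"`), `subclass`
#'   (e.g. `"A2"`) and `index` (positive integer).
#' @export
parse_gene_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  m <- regexec("^([A-Za-z]+)Hsf([ABC])([0-9]+)[-–]([0-9]+)$", name)
  g <- regmatches(name, m)[[1]]
  if (length(g) == 0)
    stop("not a valid Hsf gene name: '", name, "'")
  idx <- as.integer(g[5])
  if (idx < 1) stop("gene index must be positive in '", name, "'")
  structure(list(family = g[2], hsf_class = g[3],
                 subclass = paste0(g[3], g[4]), index = idx),
            class = "hsf_gene_name")
}

#' Format an Hsf gene name
#'
#' Inverse of [parse_gene_name()]. The en-dash separator is emitted, matching
#' the convention used in published wheat Hsf gene tables.
#'
#' @param g An `hsf_gene_name` object.
#' @param dash Separator between subclass and index; defaults to en-dash.
#' @return The formatted gene name string.
#' @export
format_gene_name <- function(g, dash = "–") {
  stopifnot(inherits(g, "hsf_gene_name"))
  paste0(g$family, "Hsf", g$subclass, dash, g$index)
}

#' @export
print.hsf_gene_name <- function(x, ...) {
  cat(format_gene_name(x), "\n")
  invisible(x)
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' All user-facing positions in hsfkit are 1-based inclusive; these helpers
#' convert losslessly to and from the 0-based half-open form used internally
#' for span arithmetic.
#'
#' @param start,end 1-based inclusive coordinates (`to_half_open`) or 0-based
#'   half-open coordinates (`to_one_based`).
#' @return A list with fields `start` and `end` in the other convention.
#' @export
to_half_open <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = start - 1L, end = end)
}

#' @rdname to_half_open
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = start + 1L, end = end)
}

VALID_CHROMOSOMES <- c(paste0(rep(1:7, each = 3), c("A", "B", "D")), "U")

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon features and groups exons per transcript. GFF3
#' coordinates are kept 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return A list of gene models; each is a list with fields `id` (transcript
#'   ID), `gene` (parent gene ID or `NA`), `chromosome`, `strand` and `exons`
#'   (two-column matrix of start/end, sorted, non-overlapping).
#' @export
read_gff3 <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr$Parent1 <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  mrna <- gr[gr$type %in% c("mRNA", "transcript"), ]
  exons <- gr[gr$type == "exon", ]
  if (nrow(mrna) == 0) stop("no mRNA/transcript features in ", path)
  lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    ex <- exons[!is.na(exons$Parent1) & exons$Parent1 == tid, ]
    if (nrow(ex) == 0) stop("transcript '", tid, "' has no exons")
    strand <- as.character(ex$strand)
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand for exons of transcript '", tid, "'")
    sp <- cbind(start = ex$start, end = ex$end)
    sp <- sp[order(sp[, 1]), , drop = FALSE]
    if (nrow(sp) > 1 && any(sp[-1, 1] <= sp[-nrow(sp), 2]))
      stop("overlapping exons in transcript '", tid, "'")
    if (min(sp[, 1]) < mrna$start[i] || max(sp[, 2]) > mrna$end[i])
      stop("exon outside parent span in transcript '", tid, "'")
    list(id = tid, gene = mrna$Parent1[i],
         chromosome = as.character(mrna$seqnames[i]),
         strand = strand[1], exons = sp)
  })
}

#' Write gene models to a GFF3 file
#'
#' Companion writer for [read_gff3()], used mainly to emit synthetic gene
#' models.
#'
#' @param models List of gene models as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    gid <- if (is.na(m$gene)) paste0(m$id, ".gene") else m$gene
    writeLines(c(
      paste(m$chromosome, "hsfkit", "gene", span[1], span[2], ".", m$strand,
            ".", paste0("ID=", gid), sep = "\t"),
      paste(m$chromosome, "hsfkit", "mRNA", span[1], span[2], ".", m$strand,
            ".", paste0("ID=", m$id, ";Parent=", gid), sep = "\t"),
      vapply(seq_len(nrow(m$exons)), function(i)
        paste(m$chromosome, "hsfkit", "exon", m$exons[i, 1], m$exons[i, 2],
              ".", m$strand, ".",
              paste0("ID=", m$id, ".exon", i, ";Parent=", m$id), sep = "\t"),
        character(1))), con)
  }
  invisible(path)
}

#' Write the per-gene annotation table
#'
#' Emits a TSV with the fixed column order gene, chromosome, transcript,
#' AA, MW (kDa, two decimals), NES, NLS, AHA, ER. Motif cells are formatted
#' `"(pos)SEQ"`, multiple hits separated by `";"`; genes without a motif get
#' an empty cell.
#'
#' @param rows Data frame with columns `gene`, `chromosome`, `transcript`,
#'   `aa`, `mw_kda`, and optionally `nes`, `nls`, `aha`, `er` (each either a
#'   preformatted string or a list column of data frames with `position` and
#'   `matched`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(rows, path) {
  stopifnot(is.data.frame(rows),
            all(c("gene", "chromosome", "transcript", "aa", "mw_kda")
                %in% names(rows)))
  if (any(rows$mw_kda <= 0)) stop("mw_kda must be positive")
  fmt_cell <- function(x, aa_len) {
    if (is.null(x) || (is.atomic(x) && length(x) == 1 && is.na(x))) return("")
    if (is.character(x)) return(x)
    if (is.data.frame(x)) {
      if (nrow(x) == 0) return("")
      if (any(x$position < 1 | x$position > aa_len))
        stop("motif position outside [1, ", aa_len, "]")
      return(paste0("(", x$position, ")", x$matched, collapse = ";"))
    }
    stop("unsupported motif cell type")
  }
  cols <- c("nes", "nls", "aha", "er")
  out <- data.frame(gene = rows$gene, chromosome = rows$chromosome,
                    transcript = rows$transcript, aa = rows$aa,
                    mw_kda = sprintf("%.2f", rows$mw_kda),
                    stringsAsFactors = FALSE)
  for (cc in cols) {
    vals <- if (cc %in% names(rows)) {
      vapply(seq_len(nrow(rows)), function(i)
        fmt_cell(rows[[cc]][[i]], rows$aa[i]), character(1))
    } else rep("", nrow(rows))
    out[[toupper(cc)]] <- vals
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the published wheat Hsf family annotation
#'
#' Returns the curated annotation of the 82 bread-wheat Hsf genes (gene name,
#' chromosome, transcript ID, protein length in amino acids, molecular weight
#' in kDa, and the reported C-terminal signal strings), shipped with the
#' package as a plain-text table.
#'
#' @return A data frame with columns `gene`, `chromosome`, `transcript`, `aa`,
#'   `mw_kda`, `signals`, plus derived columns `hsf_class`, `subclass` and
#'   `index` parsed from the gene names.
#' @export
wheat_hsf_annotation <- function() {
  path <- system.file("extdata", "wheat_hsf_annotation.tsv", package = "hsfkit")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parsed <- lapply(tab$gene, parse_gene_name)
  tab$hsf_class <- vapply(parsed, `[[`, character(1), "hsf_class")
  tab$subclass <- vapply(parsed, `[[`, character(1), "subclass")
  tab$index <- vapply(parsed, `[[`, integer(1), "index")
  tab
}
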