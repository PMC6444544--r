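#' Extract the N-terminal classification region
#'
#' Returns the region used for family phylogeny: from the DBD start through
#' the HR-B end (DBD + linker + HR-A/B).
#'
#' @param protein Sequence string or one-row data frame.
#' @param dbd_span,hrab_span Domain annotations: `dbd_span = c(start, end)`;
#'   `hrab_span` either `c(start, end)` of HR-B or the list returned by
#'   [detect_hrab()].
#' @return The subsequence (string).
#' @export
extract_n_terminal_region <- function(protein, dbd_span, hrab_span) {
  seq <- if (is.data.frame(protein)) protein$sequence[1] else protein
  if (is.null(dbd_span) || is.null(hrab_span)) stop("missing domain annotation")
  hrb_end <- if (is.list(hrab_span)) hrab_span$hr_b[2] else hrab_span[2]
  if (hrb_end > nchar(seq)) stop("HR-B end beyond protein length")
  if (dbd_span[1] < 1 || dbd_span[1] > hrb_end) stop("invalid DBD span")
  substr(seq, dbd_span[1], hrb_end)
}

#' Align sequences onto the profile coordinate system
#'
#' Places each sequence's best-scoring ungapped window onto the profile
#' columns, yielding an equal-length pseudo-alignment usable for distance
#' computation. This keeps the stage deterministic for strongly conserved
#' regions; it is not a substitute for multiple alignment of divergent
#' sequences.
#'
#' @param model An `hsf_profile`.
#' @param sequences Named character vector of protein sequences.
#' @return Named character vector of aligned rows (all of profile length).
#' @export
profile_align <- function(model, sequences) {
  stopifnot(inherits(model, "hsf_profile"))
  vapply(sequences, function(s) {
    sc <- window_scores(model, s)
    if (length(sc) == 0) stop("sequence shorter than profile")
    b <- which.max(sc)
    substr(s, b, b + model$length - 1)
  }, character(1))
}

#' Proportion of differing sites under pairwise deletion
#'
#' Sites with a gap (`-`) in either aligned row are excluded; `p` is the
#' mismatch fraction over the remaining sites.
#'
#' @param seq_a,seq_b Equal-length aligned sequence strings.
#' @return p-distance in `[0, 1]`.
#' @export
pdistance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned rows must have equal length")
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("zero comparable sites under pairwise deletion")
  mean(a[ok] != b[ok])
}

#' Percent identity under pairwise deletion
#'
#' @inheritParams pdistance
#' @return Identity percentage in `[0, 100]`.
#' @export
percent_identity <- function(seq_a, seq_b) 100 * (1 - pdistance(seq_a, seq_b))

#' Poisson-corrected distance
#'
#' Corrects an observed proportion of differing sites for multiple
#' substitutions: `d = -ln(1 - p)`.
#'
#' @param p p-distance(s) in `[0, 1)`.
#' @return Corrected distance(s).
#' @export
poisson_correct <- function(p) {
  if (any(p < 0)) stop("p must be nonnegative")
  if (any(p >= 1)) stop("p >= 1: distance saturated, Poisson correction undefined")
  -log(1 - p)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
poisson_dist_matrix <- function(alignment) {
  n <- length(alignment)
  labs <- names(alignment)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  mat <- do.call(rbind, strsplit(alignment, ""))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) stop("zero comparable sites between ", labs[i], " and ", labs[j])
    d[i, j] <- d[j, i] <- poisson_correct(mean(mat[i, ok] != mat[j, ok]))
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Saitou-Nei Q-criterion, iterative agglomeration)
#' on a symmetric distance matrix. Ties in the Q-criterion are broken by the
#' lowest-index pair, making the result deterministic. Negative branch-length
#' estimates are clamped to zero and counted in the `negative_branches`
#' attribute. On additive matrices the generating tree is recovered exactly.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and dimnames
#'   (at least 3 taxa).
#' @return An unrooted `phylo` object (ape).
#' @export
build_nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3) stop("at least 3 taxa required")
  if (any(!is.finite(dm))) stop("non-finite distances")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(dm)))
  nwk <- labs
  d <- dm
  n_neg <- 0L
  clamp <- function(x) {
    if (x < 0) { n_neg <<- n_neg + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.17g", x)
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index pair among Q minima (row-major, i < j)
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_lab <- paste0("(", nwk[i], ":", fmt(bi), ",", nwk[j], ":", fmt(bj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], new_lab)
    rownames(d2) <- colnames(d2) <- seq_len(nrow(d2))
    d <- d2
  }
  b1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  b2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  b3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- paste0("(", nwk[1], ":", fmt(b1), ",", nwk[2], ":", fmt(b2), ",",
                nwk[3], ":", fmt(b3), ");")
  phy <- ape::read.tree(text = txt)
  attr(phy, "negative_branches") <- n_neg
  phy
}

# splits (bipartitions) of an unrooted tree: for each internal edge, the tip
# set on the child side plus a canonical key (the side not containing the
# first taxon, sorted)
tree_splits <- function(phy) {
  nt <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  desc <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ref <- sort(phy$tip.label)[1]
  out <- list()
  for (k in seq_len(nrow(po$edge))) {
    ch <- po$edge[k, 2]
    if (ch <= nt) next
    side <- desc[[ch]]
    if (length(side) < 2 || length(side) > nt - 2) next
    canon <- if (ref %in% side) setdiff(phy$tip.label, side) else side
    key <- paste(sort(canon), collapse = "|")
    out[[key]] <- list(key = key, side = side)
  }
  out
}

#' Bootstrap support for NJ bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-corrected NJ tree for each replicate, and reports for every
#' internal edge of the original tree the percentage of replicate trees
#' containing the same bipartition.
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (resampling is reproducible).
#' @return An object of class `hsf_boot`: list with `tree` (the original NJ
#'   `phylo`), `splits` (data frame `key`, `support` in `[0, 100]`) and
#'   `n_replicates`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  alignment <- alignment[order(names(alignment))]  # input-order invariance
  set.seed(seed)
  L <- unique(nchar(alignment))
  stopifnot(length(L) == 1)
  tree <- build_nj_tree(poisson_dist_matrix(alignment))
  sp0 <- tree_splits(tree)
  keys <- names(sp0)
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- stats::setNames(apply(mat[, cols, drop = FALSE], 1, paste,
                                     collapse = ""), names(alignment))
    tb <- build_nj_tree(poisson_dist_matrix(rep_aln))
    kb <- names(tree_splits(tb))
    hit <- keys %in% kb
    counts[hit] <- counts[hit] + 1L
  }
  structure(list(tree = tree,
                 splits = data.frame(key = keys,
                                     support = 100 * counts / n_replicates,
                                     stringsAsFactors = FALSE),
                 n_replicates = n_replicates),
            class = "hsf_boot")
}

#' @export
print.hsf_boot <- function(x, ...) {
  cat("NJ tree with", length(x$tree$tip.label), "tips;",
      nrow(x$splits), "internal splits;", x$n_replicates,
      "bootstrap replicates\n")
  invisible(x)
}

#' Reference-anchored subclass assignment
#'
#' Each query takes the subclass of the reference sharing its smallest
#' well-supported enclosing clade (bootstrap above `boot_threshold`),
#' provided the best-hit identity between query and that clade's references
#' exceeds `identity_threshold`. Queries whose smallest well-supported clade
#' contains no reference are assigned a novel subclass label: the query's
#' insert-based class letter plus the next unused integer for that letter.
#' Queries with no well-supported enclosing clade are flagged `unresolved`.
#'
#' @param boot An `hsf_boot` from [bootstrap_support()] whose tree contains
#'   both query and reference leaves.
#' @param query_ids Character vector of query leaf labels.
#' @param ref_subclass Named character vector: reference leaf label ->
#'   subclass (e.g. `"A2"`).
#' @param identity Numeric matrix of percent identities, rows = queries,
#'   columns = references.
#' @param query_class Named character vector: query -> insert-based class
#'   letter; used for novel labels and conflict flagging.
#' @param boot_threshold Bootstrap percentage a clade must exceed
#'   (default 50).
#' @param identity_threshold Best-hit identity percentage required to adopt a
#'   reference label (default 90).
#' @return Data frame with `gene`, `subclass`, `supporting_ref` (reference ID
#'   or `"novel"`), `identity`, `bootstrap` and `flag` (`""`, `"unresolved"`,
#'   `"low_identity"` or `"class_conflict"`).
#' @export
assign_subclasses <- function(boot, query_ids, ref_subclass, identity,
                              query_class, boot_threshold = 50,
                              identity_threshold = 90) {
  stopifnot(inherits(boot, "hsf_boot"))
  tips <- boot$tree$tip.label
  missing <- setdiff(query_ids, tips)
  if (length(missing) > 0) stop("query absent from tree: ", missing[1])
  sp <- tree_splits(boot$tree)
  supp <- stats::setNames(boot$splits$support, boot$splits$key)
  nt <- length(tips)
  # both orientations of every well-supported split are candidate clades
  clades <- list()
  for (s in sp) {
    if (is.na(supp[s$key]) || supp[s$key] <= boot_threshold) next
    for (side in list(s$side, setdiff(tips, s$side))) {
      if (length(side) < 2 || length(side) > nt - 2) next
      clades[[length(clades) + 1]] <- list(tips = side, support = supp[s$key])
    }
  }
  next_index <- function(letter) {
    idx <- as.integer(sub("^[ABC]", "", c(ref_subclass, novel_labels)))
    letters_of <- substr(c(ref_subclass, novel_labels), 1, 1)
    known <- idx[letters_of == letter]
    if (length(known) == 0) 1L else max(known) + 1L
  }
  novel_labels <- character(0)
  novel_by_clade <- list()
  rows <- lapply(query_ids, function(q) {
    enclosing <- Filter(function(cl) q %in% cl$tips, clades)
    if (length(enclosing) == 0)
      return(data.frame(gene = q, subclass = NA_character_,
                        supporting_ref = NA_character_, identity = NA_real_,
                        bootstrap = NA_real_, flag = "unresolved",
                        stringsAsFactors = FALSE))
    sizes <- vapply(enclosing, function(cl) length(cl$tips), integer(1))
    cl <- enclosing[[order(sizes)[1]]]
    refs_in <- intersect(cl$tips, names(ref_subclass))
    if (length(refs_in) == 0) {
      ckey <- paste(sort(cl$tips), collapse = "|")
      if (is.null(novel_by_clade[[ckey]])) {
        lab <- paste0(query_class[[q]], next_index(query_class[[q]]))
        novel_by_clade[[ckey]] <<- lab
        novel_labels <<- c(novel_labels, lab)
      }
      lab <- novel_by_clade[[ckey]]
      flag <- if (substr(lab, 1, 1) != query_class[[q]]) "class_conflict" else ""
      return(data.frame(gene = q, subclass = lab, supporting_ref = "novel",
                        identity = NA_real_, bootstrap = unname(cl$support),
                        flag = flag, stringsAsFactors = FALSE))
    }
    ids <- identity[q, refs_in]
    best <- refs_in[which.max(ids)]
    if (max(ids) <= identity_threshold)
      return(data.frame(gene = q, subclass = NA_character_,
                        supporting_ref = best, identity = max(ids),
                        bootstrap = unname(cl$support), flag = "low_identity",
                        stringsAsFactors = FALSE))
    lab <- unname(ref_subclass[best])
    flag <- if (substr(lab, 1, 1) != query_class[[q]]) "class_conflict" else ""
    data.frame(gene = q, subclass = lab, supporting_ref = best,
               identity = max(ids), bootstrap = unname(cl$support),
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
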