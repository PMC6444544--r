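# residues considered "polar" by the generator: kept out of heptad a/d
# positions, inserts and linkers so planted coiled-coil boundaries stay sharp
POLAR_AA <- c("D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T")

# ideal heptads (a/d hydrophobic, b/c/e/f/g polar)
HRA_TEMPLATE <- c("LEQLKSD", "LRELESD", "LKQLEND")
HRB_TEMPLATE <- c("LEDLKTR", "LSELRND")

# canonical wheat-like subclass composition (class A 40, B 16, C 26)
WHEAT_SUBCLASS_COUNTS <- c(A1 = 3L, A2 = 18L, A3 = 4L, A4 = 6L, A5 = 3L,
                           A6 = 3L, A9 = 3L, B1 = 3L, B2 = 8L, B4 = 5L,
                           C1 = 9L, C2 = 4L, C3 = 13L)

#' Specification for a synthetic Hsf family
#'
#' Bundles and validates the parameters of the synthetic-family generator.
#' Defaults emulate the bread-wheat family composition: 13 subclasses with
#' the published member counts (class A 40, B 16, C 26), canonical HR-A/B
#' insert lengths 21/0/7, homeolog-triad identity 0.97, and the class-specific
#' motif plan (AHA in class A only, LFGV in class B only).
#'
#' @param counts Named integer vector of members per subclass (names like
#'   `"A2"`, `"C3"`).
#' @param insert_lengths Named integers, insert residues per class.
#' @param triad_identity Target pairwise identity of homeolog copies.
#' @param substitution_rate Per-residue substitution rate applied outside
#'   protected motif/anchor positions.
#' @param n_decoys Number of shuffled-composition decoy proteins.
#' @param er_fraction Fraction of genes given a C-terminal ER retention
#'   tetrapeptide.
#' @param motif_plan Named character vector mapping motif kinds to the class
#'   letters that may carry them.
#' @param family Gene-name prefix (default `"Sy"`, giving e.g. `"SyHsfA2-1"`).
#' @param hard_mode If `TRUE`, substitutions may also hit motif/anchor
#'   positions (robustness testing).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @return Validated list of class `hsf_family_spec`.
#' @export
family_spec <- function(counts = WHEAT_SUBCLASS_COUNTS,
                        insert_lengths = c(A = 21L, B = 0L, C = 7L),
                        triad_identity = 0.97, substitution_rate = 0.02,
                        n_decoys = 100L, er_fraction = 0.25,
                        motif_plan = c(AHA = "A", LFGV = "B", NLS = "ABC",
                                       NES = "ABC"),
                        family = "Sy", hard_mode = FALSE, seed = 1L) {
  stopifnot(all(counts >= 0), substitution_rate >= 0, substitution_rate <= 1,
            triad_identity > 0, triad_identity <= 1, n_decoys >= 0,
            er_fraction >= 0, er_fraction <= 1)
  if (length(counts) > 0 &&
      !all(substr(names(counts), 1, 1) %in% c("A", "B", "C")))
    stop("subclass names must begin with A, B or C")
  if (!is.na(motif_plan["AHA"]) && grepl("[BC]", motif_plan["AHA"]))
    stop("contradictory spec: AHA is a class-A activator motif")
  if (!is.na(motif_plan["LFGV"]) && grepl("[AC]", motif_plan["LFGV"]))
    stop("contradictory spec: LFGV is the class-B repressor tetrapeptide")
  structure(list(counts = counts, insert_lengths = insert_lengths,
                 triad_identity = triad_identity,
                 substitution_rate = substitution_rate,
                 n_decoys = as.integer(n_decoys), er_fraction = er_fraction,
                 motif_plan = motif_plan, family = family,
                 hard_mode = hard_mode, seed = as.integer(seed)),
            class = "hsf_family_spec")
}

rand_seq <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE),
                                        collapse = "")

# subclass-specific DBD: substitute 6 loop columns deterministically so
# subclasses separate in the phylogeny without touching element columns
subclass_dbd <- function(subclass, seed_data) {
  cons <- strsplit(seed_data$consensus, "")[[1]]
  loops <- which(seed_data$elements == "-")
  h <- utf8ToInt(subclass)
  key <- sum(h * 31^(seq_along(h) - 1)) %% 100000L
  # subclass-keyed draw, isolated from the caller's RNG stream
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(key)
  pick <- sample(loops, 6)
  for (p in pick) cons[p] <- sample(setdiff(POLAR_AA, cons[p]), 1)
  paste(cons, collapse = "")
}

# assemble one synthetic Hsf; returns sequence, span/motif truth and
# per-position category ("free", "polar", "anchor", "motif")
build_hsf_gene <- function(hsf_class, subclass, spec, seed_data,
                           plant_er = FALSE) {
  piece <- function(s, cat) list(seq = s, cat = rep(cat, nchar(s)))
  pieces <- list()
  add <- function(p, name = NULL) {
    pieces[[length(pieces) + 1]] <<- c(p, list(name = name))
  }
  heptad_piece <- function(templates) {
    cat <- rep(rep(c("anchor", "polar", "polar", "anchor", rep("polar", 3)),
                   length(templates)), 1)
    list(seq = paste(templates, collapse = ""), cat = cat)
  }
  plan_has <- function(kind)
    !is.na(spec$motif_plan[kind]) && grepl(hsf_class, spec$motif_plan[kind])

  add(piece(rand_seq(sample(20:40, 1), AA_STANDARD), "free"), "ntail")
  add(piece(subclass_dbd(subclass, seed_data), "free"), "dbd")
  add(piece(rand_seq(sample(15:30, 1), POLAR_AA), "polar"), "linker")
  add(heptad_piece(HRA_TEMPLATE), "hra")
  k <- spec$insert_lengths[[hsf_class]]
  if (k > 0) add(piece(rand_seq(k, POLAR_AA), "polar"), "insert")
  add(heptad_piece(HRB_TEMPLATE), "hrb")
  add(piece(rand_seq(sample(5:10, 1), POLAR_AA), "polar"), "ct1")
  if (plan_has("NLS")) add(piece("KKRR", "motif"), "NLS")
  add(piece(rand_seq(sample(10:15, 1), POLAR_AA), "polar"), "ct2")
  if (plan_has("NES")) add(piece("LDVRQLDLRLL", "motif"), "NES")
  add(piece(rand_seq(sample(8:12, 1), POLAR_AA), "polar"), "ct3")
  if (plan_has("AHA")) add(piece("DSFWEQFL", "motif"), "AHA")
  if (plan_has("LFGV")) add(piece("LFGV", "motif"), "LFGV")
  add(piece(rand_seq(sample(8:12, 1), POLAR_AA), "polar"), "ct4")
  if (plant_er) add(piece("AEKL", "motif"), "ER")

  seqs <- vapply(pieces, `[[`, character(1), "seq")
  lens <- nchar(seqs)
  starts <- cumsum(c(1, lens[-length(lens)]))
  names(starts) <- vapply(pieces, function(p)
    if (is.null(p$name)) "" else p$name, character(1))
  span <- function(nm) {
    i <- which(names(starts) == nm)
    if (length(i) == 0) return(NULL)
    c(starts[i], starts[i] + lens[i] - 1L)
  }
  motifs <- list()
  for (nm in c("NLS", "NES", "AHA", "LFGV", "ER")) {
    sp <- span(nm)
    if (!is.null(sp))
      motifs[[nm]] <- data.frame(kind = nm, position = unname(sp[1]),
                                 matched = seqs[which(names(starts) == nm)],
                                 stringsAsFactors = FALSE)
  }
  list(sequence = paste(seqs, collapse = ""),
       category = unlist(lapply(pieces, `[[`, "cat"), use.names = FALSE),
       dbd = unname(span("dbd")), hra = unname(span("hra")),
       hrb = unname(span("hrb")), insert_length = as.integer(k),
       motifs = if (length(motifs)) do.call(rbind, motifs) else NULL)
}

# substitute residues at `rate` outside protected positions; polar-category
# positions stay within the polar alphabet
mutate_sequence <- function(sequence, category, rate, hard_mode = FALSE) {
  if (rate == 0) return(sequence)
  res <- strsplit(sequence, "")[[1]]
  eligible <- if (hard_mode) rep(TRUE, length(res)) else
    category %in% c("free", "polar")
  hit <- which(eligible & stats::runif(length(res)) < rate)
  for (i in hit) {
    pool <- if (!hard_mode && category[i] == "polar") POLAR_AA else AA_STANDARD
    pool <- setdiff(pool, res[i])
    res[i] <- sample(pool, 1)
  }
  paste(res, collapse = "")
}

#' Generate a synthetic Hsf family with truth table
#'
#' Builds one protein per requested subclass member (random N-tail +
#' subclass-flavoured DBD consensus + polar linker + HR-A heptads +
#' class-specific insert + HR-B heptads + C-terminal region carrying the
#' planted motifs), applies background substitutions at the spec rate outside
#' motif and heptad-anchor positions, appends shuffled-composition decoys,
#' and records everything in a truth table. Deterministic for a fixed seed.
#'
#' @param spec An `hsf_family_spec`.
#' @return List with `proteins` (data frame `id`, `description`, `sequence`,
#'   Hsf genes then decoys), `truth` (per-gene spans, class, subclass,
#'   chromosome, insert length), `motifs` (planted motif truth) and `spec`.
#' @export
generate_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "hsf_family_spec"))
  set.seed(spec$seed)
  seed_data <- hsf_dbd_seed()
  genes <- list(); truth <- list(); motifs <- list()
  chrom_cycle <- setdiff(VALID_CHROMOSOMES, "U")
  ci <- 0L
  for (s in names(spec$counts)) {
    n <- spec$counts[[s]]
    if (n == 0) next
    cls <- substr(s, 1, 1)
    er_on <- stats::runif(n) < spec$er_fraction
    for (i in seq_len(n)) {
      g <- build_hsf_gene(cls, s, spec, seed_data, plant_er = er_on[i])
      id <- paste0(spec$family, "Hsf", s, "-", i)
      seq_mut <- mutate_sequence(g$sequence, g$category,
                                 spec$substitution_rate, spec$hard_mode)
      ci <- ci + 1L
      genes[[id]] <- seq_mut
      truth[[id]] <- data.frame(
        id = id, hsf_class = cls, subclass = s, index = i,
        chromosome = chrom_cycle[(ci - 1L) %% 21L + 1L],
        aa = nchar(seq_mut), dbd_start = g$dbd[1], dbd_end = g$dbd[2],
        hra_start = g$hra[1], hra_end = g$hra[2],
        hrb_start = g$hrb[1], hrb_end = g$hrb[2],
        insert_length = g$insert_length, has_er = er_on[i],
        stringsAsFactors = FALSE)
      if (!is.null(g$motifs))
        motifs[[id]] <- cbind(gene = id, g$motifs)
    }
  }
  truth <- if (length(truth))
    do.call(rbind, c(truth, make.row.names = FALSE)) else NULL
  if (is.null(truth))
    truth <- data.frame(id = character(), hsf_class = character(),
                        subclass = character(), index = integer(),
                        chromosome = character(), aa = integer(),
                        dbd_start = integer(), dbd_end = integer(),
                        hra_start = integer(), hra_end = integer(),
                        hrb_start = integer(), hrb_end = integer(),
                        insert_length = integer(), has_er = logical(),
                        stringsAsFactors = FALSE)
  pool <- if (length(genes)) unlist(strsplit(unlist(genes), "")) else
    AA_STANDARD
  lens <- if (length(genes)) nchar(unlist(genes)) else c(250L, 300L, 350L)
  decoys <- stats::setNames(lapply(seq_len(spec$n_decoys), function(i)
    rand_seq(sample(lens, 1), pool)),
    sprintf("decoy_%03d", seq_len(spec$n_decoys)))
  proteins <- data.frame(
    id = c(names(genes), names(decoys)),
    description = c(rep("synthetic Hsf", length(genes)),
                    rep("shuffled-composition decoy", length(decoys))),
    sequence = c(unlist(genes, use.names = FALSE),
                 unlist(decoys, use.names = FALSE)),
    stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth,
       motifs = if (length(motifs))
         do.call(rbind, c(motifs, make.row.names = FALSE)) else NULL,
       spec = spec)
}

#' Generate a synthetic allohexaploid Hsf family (homeolog triads)
#'
#' Emulates the tripling of a gene family by allopolyploidy: each ancestral
#' gene is copied onto the A, B and D subgenome chromosomes of one
#' homeologous group and the copies are diverged independently to the spec's
#' triad identity. A chosen number of genes are deliberately left as
#' singletons to exercise incomplete-group reporting. Homeolog copies receive
#' consecutive indices within their subclass, following the family naming
#' convention.
#'
#' @param spec An `hsf_family_spec`; `spec$counts` is ignored in favour of
#'   `n_triads`/`n_singletons`.
#' @param n_triads Number of complete A/B/D triads to plant.
#' @param n_singletons Number of single-copy genes.
#' @param subclasses Subclass labels cycled over the planted genes.
#' @return List with `proteins`, `truth` (adds `triad` id, `NA` for
#'   singletons) and `spec`.
#' @export
generate_allohexaploid <- function(spec = family_spec(), n_triads = 7,
                                   n_singletons = 3,
                                   subclasses = c("A2", "B1", "C1")) {
  stopifnot(inherits(spec, "hsf_family_spec"))
  set.seed(spec$seed)
  seed_data <- hsf_dbd_seed()
  r <- (1 - spec$triad_identity) / 2  # per-copy divergence from the ancestor
  genes <- list(); truth <- list()
  sub_counter <- stats::setNames(rep(0L, length(subclasses)), subclasses)
  for (t in seq_len(n_triads + n_singletons)) {
    s <- subclasses[(t - 1) %% length(subclasses) + 1]
    cls <- substr(s, 1, 1)
    anc <- build_hsf_gene(cls, s, spec, seed_data)
    grp <- (t - 1) %% 7 + 1
    is_triad <- t <= n_triads
    subg <- if (is_triad) c("A", "B", "D") else
      c("A", "B", "D")[(t %% 3) + 1]
    for (sg in subg) {
      sub_counter[s] <- sub_counter[s] + 1L
      id <- paste0(spec$family, "Hsf", s, "-", sub_counter[s])
      seq_mut <- mutate_sequence(anc$sequence, anc$category, r)
      genes[[id]] <- seq_mut
      truth[[id]] <- data.frame(
        id = id, hsf_class = cls, subclass = s, index = sub_counter[[s]],
        chromosome = paste0(grp, sg), aa = nchar(seq_mut),
        dbd_start = anc$dbd[1], dbd_end = anc$dbd[2],
        hra_start = anc$hra[1], hra_end = anc$hra[2],
        hrb_start = anc$hrb[1], hrb_end = anc$hrb[2],
        insert_length = anc$insert_length,
        triad = if (is_triad) t else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  proteins <- data.frame(id = names(genes),
                         description = "synthetic allohexaploid Hsf",
                         sequence = unlist(genes, use.names = FALSE),
                         stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth, spec = spec)
}

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  E = c("GAA", "GAG"), Q = c("CAA", "CAG"), G = c("GGT", "GGC", "GGA"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"), M = "ATG",
  F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA"),
  S = c("TCT", "TCC", "AGT", "AGC"), T = c("ACT", "ACC", "ACA"),
  W = "TGG", Y = c("TAT", "TAC"), V = c("GTT", "GTC", "GTA", "GTG"))

back_translate <- function(protein) {
  res <- strsplit(protein, "")[[1]]
  paste(vapply(res, function(a) {
    cods <- CODON_TABLE[[a]]
    if (is.null(cods)) "NNN" else sample(cods, 1)
  }, character(1)), collapse = "")
}

#' Generate gene models (cDNA + genomic + GFF) for a synthetic family
#'
#' Back-translates each protein to a CDS, then plants one canonical GT..AG
#' intron inside the DBD codons for class A and B genes, leaves
#' C3-designated genes intronless, and samples intron lengths uniformly from
#' `intron_range` (default 80-5836 bp, the observed extremes of the wheat
#' family).
#'
#' @param fam Output of [generate_family()] or [generate_allohexaploid()].
#' @param intron_range Length-2 integer vector of intron length bounds.
#' @param flank Flanking genomic sequence added on each side (bp).
#' @param seed Integer seed.
#' @return List with `cdna`, `genomic` (named character vectors), `models`
#'   (gene-model lists as from [read_gff3()]) and `structure_truth` (per-gene
#'   exon matrices in genomic coordinates plus planted intron length).
#' @export
generate_gene_models <- function(fam, intron_range = c(80L, 5836L),
                                 flank = 50L, seed = 1L) {
  set.seed(seed)
  truth <- fam$truth
  cdna <- character(0); genomic <- character(0)
  models <- list(); structure_truth <- list()
  for (i in seq_len(nrow(truth))) {
    g <- truth[i, ]
    cds <- back_translate(fam$proteins$sequence[fam$proteins$id == g$id])
    intronless <- startsWith(g$subclass, "C3")
    f5 <- rand_seq(flank, c("A", "C", "G", "T"))
    f3 <- rand_seq(flank, c("A", "C", "G", "T"))
    if (intronless) {
      gen <- paste0(f5, cds, f3)
      exons <- matrix(c(flank + 1L, flank + nchar(cds)), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
      ilen <- integer(0)
    } else {
      mid_codon <- g$dbd_start + 43L        # inside the DBD projection
      cut <- mid_codon * 3L                  # cDNA position of exon-1 end
      ilen <- sample(intron_range[1]:intron_range[2], 1)
      intron <- paste0("GT", rand_seq(ilen - 4L, c("A", "C", "G", "T")), "AG")
      gen <- paste0(f5, substr(cds, 1, cut), intron,
                    substr(cds, cut + 1, nchar(cds)), f3)
      exons <- matrix(c(flank + 1L, flank + cut,
                        flank + cut + ilen + 1L,
                        flank + ilen + nchar(cds)),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("start", "end")))
    }
    storage.mode(exons) <- "integer"
    cdna[g$id] <- cds
    genomic[g$id] <- gen
    models[[g$id]] <- list(id = g$id, gene = paste0(g$id, ".gene"),
                           chromosome = g$chromosome, strand = "+",
                           exons = exons)
    structure_truth[[g$id]] <- list(exons = exons, intron_length = ilen)
  }
  list(cdna = cdna, genomic = genomic, models = models,
       structure_truth = structure_truth)
}

#' Default class x organ x treatment expression design
#'
#' Mean TPM values emulating the published family-level response pattern:
#' class A strongly induced by H2O2 and heat in leaf (and by H2O2 in root),
#' class B induced by H2O2, heat and ABA, class C mainly ABA-responsive, on
#' a low constitutive baseline.
#'
#' @param baseline Constitutive mean TPM (default 5).
#' @return Data frame with `hsf_class`, `organ`, `treatment`, `mean_tpm`.
#' @export
hsf_expression_design <- function(baseline = 5) {
  grid <- expand.grid(hsf_class = c("A", "B", "C"), organ = HSF_ORGANS,
                      treatment = HSF_TREATMENTS, stringsAsFactors = FALSE)
  grid$mean_tpm <- baseline
  bump <- function(g, cls, org, tr, val) {
    sel <- g$hsf_class == cls & g$organ == org & g$treatment %in% tr
    g$mean_tpm[sel] <- val
    g
  }
  grid <- bump(grid, "A", "leaf", c("H2O2", "HS"), 60)
  grid <- bump(grid, "A", "root", "H2O2", 30)
  grid <- bump(grid, "B", "leaf", c("H2O2", "HS"), 40)
  grid <- bump(grid, "B", "leaf", "ABA", 25)
  grid <- bump(grid, "B", "root", "ABA", 20)
  grid <- bump(grid, "C", "leaf", "ABA", 40)
  grid <- bump(grid, "C", "root", "ABA", 40)
  grid <- bump(grid, "C", "root", "PEG", 20)
  grid
}

#' Generate a synthetic treatment x organ TPM matrix
#'
#' Draws TPM values around the design cell means with multiplicative
#' log-normal noise (`TPM = mean * exp(N(0, sigma))`). Designated
#' root-specific genes get a leaf mean below the expression floor. With
#' `sigma = 0` the design is reproduced exactly.
#'
#' @param truth Truth table from [generate_family()] (`id`, `hsf_class`).
#' @param sigma Log-scale noise standard deviation (default 0.2).
#' @param n_reps Replicate samples per condition (default 1).
#' @param design Design table from [hsf_expression_design()].
#' @param root_specific Character vector of gene IDs expressed in root only.
#' @param seed Integer seed.
#' @return List with `expr` (an `hsf_expr`) and `design`.
#' @export
generate_expression <- function(truth, sigma = 0.2, n_reps = 1,
                                design = hsf_expression_design(),
                                root_specific = character(0), seed = 1L) {
  set.seed(seed)
  conditions <- expand.grid(organ = HSF_ORGANS, treatment = HSF_TREATMENTS,
                            rep = seq_len(n_reps), stringsAsFactors = FALSE)
  tpm <- matrix(0, nrow(truth), nrow(conditions),
                dimnames = list(truth$id, NULL))
  for (j in seq_len(nrow(conditions))) {
    cond <- conditions[j, ]
    mu <- vapply(seq_len(nrow(truth)), function(i) {
      if (truth$id[i] %in% root_specific && cond$organ == "leaf") return(0.2)
      design$mean_tpm[design$hsf_class == truth$hsf_class[i] &
                      design$organ == cond$organ &
                      design$treatment == cond$treatment]
    }, numeric(1))
    noise <- if (sigma > 0) exp(stats::rnorm(nrow(truth), 0, sigma)) else 1
    tpm[, j] <- mu * noise
  }
  colnames(tpm) <- paste(conditions$organ, conditions$treatment,
                         conditions$rep, sep = "_")
  list(expr = expression_set(tpm, conditions$organ, conditions$treatment),
       design = design)
}

#' Expected response calls implied by a design table
#'
#' Applies the [call_responses()] decision rule to the design cell means,
#' giving the noiseless ground truth per class x organ x treatment.
#'
#' @param design Design table from [hsf_expression_design()].
#' @inheritParams call_responses
#' @return Data frame `hsf_class`, `organ`, `treatment`, `call`.
#' @export
expected_calls_from_design <- function(design, fc_threshold = 2,
                                       expression_floor = 1, eps = 0.01) {
  out <- list()
  for (cls in unique(design$hsf_class)) for (org in HSF_ORGANS) {
    ctrl <- design$mean_tpm[design$hsf_class == cls & design$organ == org &
                            design$treatment == "control"]
    for (tr in setdiff(HSF_TREATMENTS, "control")) {
      treat <- design$mean_tpm[design$hsf_class == cls &
                               design$organ == org & design$treatment == tr]
      fc <- (treat + eps) / (ctrl + eps)
      call <- if (treat < expression_floor && ctrl < expression_floor)
        "not_expressed" else if (fc >= fc_threshold &&
                                 treat >= expression_floor) "up" else
        if (fc <= 1 / fc_threshold && ctrl >= expression_floor) "down" else
        "insensitive"
      out[[length(out) + 1]] <- data.frame(
        hsf_class = cls, organ = org, treatment = tr, call = call,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
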