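test_that("chromosome counts cover the 21 chromosomes and report U separately", {
  ann <- wheat_hsf_annotation()
  cc <- chromosome_counts(ann$chromosome)
  expect_equal(unname(cc$per_chromosome["3B"]), 8)
  expect_equal(unname(cc$per_chromosome["5A"]), 8)
  expect_equal(unname(cc$per_chromosome[c("6A", "6B", "6D")]), c(1, 1, 1))
  expect_equal(unname(cc$per_group["5"]), 19)
  expect_equal(unname(cc$per_group["3"]), 18)
  expect_equal(cc$unanchored, 3)
  # conservation: per-chromosome counts plus U equals the input size
  expect_equal(sum(cc$per_chromosome) + cc$unanchored, nrow(ann))

  empty <- chromosome_counts(character(0))
  expect_true(all(empty$per_chromosome == 0))
  expect_equal(empty$unanchored, 0)
  expect_error(chromosome_counts("8Z"), "invalid chromosome")
})

test_that("naming-convention triads: consecutive indices covering A, B and D", {
  ann <- wheat_hsf_annotation()
  tt <- triad_tally(ann)
  expect_equal(tt$n_triads, 21)
  expect_equal(length(tt$triad_members), 63)
  expect_equal(length(tt$ungrouped), 19)
})

test_that("sequence-based homeolog grouping obeys the identity threshold", {
  hex <- generate_allohexaploid(family_spec(triad_identity = 0.97,
                                            substitution_rate = 0, seed = 9),
                                n_triads = 4, n_singletons = 2)
  genes <- data.frame(
    id = hex$truth$id, chromosome = hex$truth$chromosome,
    subclass = hex$truth$subclass,
    sequence = hex$proteins$sequence[match(hex$truth$id, hex$proteins$id)],
    stringsAsFactors = FALSE)
  hg <- find_homeolog_groups(genes, 0.90)
  expect_equal(nrow(hg$groups), 4)
  # recovered triples match the planted triad partition
  planted <- split(hex$truth$id, hex$truth$triad)
  for (i in seq_len(nrow(hg$groups)))
    expect_true(any(vapply(planted, setequal,
                           y = unlist(hg$groups[i, c("A", "B", "D")]),
                           logical(1))))
  # above the planted identity no group survives
  expect_equal(nrow(find_homeolog_groups(genes, 0.999)$groups), 0)

  # a diverged D copy breaks the triad; the remaining pair is reported
  g3 <- genes[genes$subclass == genes$subclass[1], ][1:3, ]
  g3$sequence[3] <- paste(rev(strsplit(g3$sequence[3], "")[[1]]),
                          collapse = "")
  res <- find_homeolog_groups(g3, 0.90)
  expect_equal(nrow(res$groups), 0)
  expect_equal(nrow(res$incomplete), 1)

  # unanchored genes never group
  g3u <- g3
  g3u$chromosome <- "U"
  expect_equal(nrow(find_homeolog_groups(g3u, 0)$groups), 0)
})

test_that("spliced anchoring recovers exons and demands GT..AG junctions", {
  set.seed(61)
  exon1 <- random_protein(60, c("A", "C", "G", "T"))
  exon2 <- random_protein(45, c("A", "C", "G", "T"))
  cdna <- paste0(exon1, exon2)

  st0 <- derive_gene_structure(cdna, cdna)   # identical: single exon
  expect_equal(st0$n_introns, 0)
  expect_equal(unname(st0$exons), matrix(c(1L, 105L), 1))

  intron <- paste0("GT", random_protein(96, c("A", "C", "G", "T")), "AG")
  st <- derive_gene_structure(cdna, paste0(exon1, intron, exon2))
  expect_equal(st$n_introns, 1)
  expect_equal(st$intron_lengths, 100L)
  expect_equal(unname(st$exons),
               matrix(c(1L, 161L, 60L, 205L), 2))

  # a non-canonical junction is not an acceptable anchoring
  badintron <- paste0("CT", random_protein(96, c("A", "C", "G", "T")), "AC")
  expect_error(derive_gene_structure(cdna, paste0(exon1, badintron, exon2)),
               "not reconstructable")
  expect_error(derive_gene_structure("AAAACCCC", "GGGGTTTT"),
               "not reconstructable")
})

test_that("generated gene models round-trip through structure derivation", {
  fam <- generate_family(family_spec(counts = c(A1 = 2, B1 = 2, C3 = 2),
                                     substitution_rate = 0, n_decoys = 0,
                                     seed = 67))
  gm <- generate_gene_models(fam, intron_range = c(80, 400), seed = 68)
  for (id in names(gm$cdna)) {
    st <- derive_gene_structure(gm$cdna[[id]], gm$genomic[[id]])
    expect_identical(unname(st$exons),
                     unname(gm$structure_truth[[id]]$exons))
    tr <- fam$truth[fam$truth$id == id, ]
    ind <- intron_in_dbd(st, c(tr$dbd_start, tr$dbd_end))
    if (startsWith(tr$subclass, "C3")) {
      expect_equal(st$n_introns, 0)
      expect_false(ind$in_dbd)
    } else {
      expect_equal(st$n_introns, 1)
      expect_true(ind$in_dbd)
      expect_equal(ind$intron_index, 1L)
      expect_gte(st$intron_lengths, 80)
      expect_lte(st$intron_lengths, 400)
    }
  }
})

test_that("introns outside the DBD projection do not count", {
  # two exons with the junction after the DBD codons
  st <- structure(list(
    exons = matrix(c(1L, 400L, 501L, 700L), 2, byrow = TRUE),
    introns = matrix(c(401L, 500L), 1),
    intron_lengths = 100L, n_introns = 1L), class = "gene_structure")
  expect_false(intron_in_dbd(st, c(10, 100))$in_dbd)   # DBD ends at cDNA 300
  expect_true(intron_in_dbd(st, c(100, 150))$in_dbd)   # junction inside
  # with a 5' UTR offset the same junction can fall outside the projection
  expect_false(intron_in_dbd(st, c(10, 80), cds_offset = 150L)$in_dbd)
})
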