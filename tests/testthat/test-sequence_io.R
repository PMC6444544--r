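test_that("FASTA reading preserves order and validates records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 first gene", "MKTAYIAK", ">g2", "acdef"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("g1", "g2"))
  expect_equal(recs$description, c("first gene", ""))
  expect_equal(recs$sequence, c("MKTAYIAK", "ACDEF"))  # uppercased

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no records|FASTA")

  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "MKT", ">g2", "", ">g3", "MAA"), f2)
  expect_error(read_fasta(f2), "record 2")

  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "MKT", ">g1", "MAA"), f3)
  expect_error(read_fasta(f3), "duplicate.*g1")

  f4 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "MKT1AA"), f4)
  expect_error(read_fasta(f4), "position 4")
})

test_that("FASTA write/read round-trips record sets", {
  set.seed(1)
  recs <- data.frame(id = paste0("p", 1:5),
                     description = c("alpha", "", "c", "", "e"),
                     sequence = vapply(5:9 * 10, random_protein, ""),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  expect_equal(read_fasta(f), recs)
})

test_that("gene names parse, format and round-trip", {
  g <- parse_gene_name("TaHsfA2-10")
  expect_equal(g$hsf_class, "A")
  expect_equal(g$subclass, "A2")
  expect_equal(g$index, 10L)
  g2 <- parse_gene_name("TaHsfC3–13")  # en-dash form
  expect_equal(g2$subclass, "C3")
  expect_equal(g2$index, 13L)
  expect_error(parse_gene_name("TaWRKY1"), "not a valid Hsf gene name")

  # round-trip property over generated names
  set.seed(7)
  for (i in 1:50) {
    g <- list(family = sample(c("Ta", "Os", "At", "Sy"), 1),
              hsf_class = sample(c("A", "B", "C"), 1), index = sample(30, 1))
    g$subclass <- paste0(g$hsf_class, sample(9, 1))
    g <- structure(g[c("family", "hsf_class", "subclass", "index")],
                   class = "hsf_gene_name")
    expect_equal(parse_gene_name(format_gene_name(g)), g)
    expect_equal(parse_gene_name(format_gene_name(g, dash = "-")), g)
  }
})

test_that("coordinate conventions convert losslessly both ways", {
  set.seed(2)
  for (i in 1:100) {
    s <- sample(1000, 1); e <- s + sample(0:500, 1)
    ho <- to_half_open(s, e)
    expect_equal(ho$end - ho$start, e - s + 1)  # width preserved
    ob <- to_one_based(ho$start, ho$end)
    expect_identical(c(ob$start, ob$end), c(as.integer(s), as.integer(e)))
  }
})

test_that("GFF3 gene models are grouped, sorted and validated", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tsrc\texon\t500\t900\t.\t+\t.\tID=e2;Parent=t1",
           "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=t1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  models <- read_gff3(f)
  expect_length(models, 1)
  expect_equal(models[[1]]$id, "t1")
  expect_equal(unname(models[[1]]$exons[, 1]), c(100, 500))  # sorted

  bad <- sub("500\t900", "150\t900", gff)  # overlaps exon 100-200
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(bad, f2)
  expect_error(read_gff3(f2), "overlapping exons")
})

test_that("GFF3 writer round-trips synthetic gene models", {
  fam <- generate_family(family_spec(counts = c(A1 = 1, C3 = 1),
                                     substitution_rate = 0, n_decoys = 0,
                                     seed = 3))
  gm <- generate_gene_models(fam, intron_range = c(80, 200), seed = 4)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gm$models, f)
  back <- read_gff3(f)
  ids <- vapply(back, `[[`, character(1), "id")
  for (m in gm$models) {
    b <- back[[match(m$id, ids)]]
    expect_equal(unname(b$exons), unname(m$exons))
    expect_equal(b$chromosome, m$chromosome)
  }
})

test_that("annotation table cells follow the (pos)SEQ and rounding rules", {
  rows <- data.frame(gene = c("TaHsfA1-1", "TaHsfB9-1"),
                     chromosome = c("4A", "1A"), transcript = c("t1", "t2"),
                     aa = c(521L, 100L), mw_kda = c(57.3649, 10.5),
                     stringsAsFactors = FALSE)
  rows$aha <- list(data.frame(position = 464L, matched = "DSFWEQFLCA"),
                   data.frame(position = integer(), matched = character()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(rows, f)
  lines <- readLines(f)
  expect_match(lines[2], "\t57\\.36\t")          # 2-decimal kDa
  expect_match(lines[2], "\\(464\\)DSFWEQFLCA")  # (pos)SEQ cell
  cells <- strsplit(lines[3], "\t")[[1]]
  expect_equal(cells[8], "")                     # no placeholder text
  bad <- rows
  bad$aha <- list(data.frame(position = 600L, matched = "X"),
                  data.frame(position = integer(), matched = character()))
  expect_error(write_annotation_table(bad, f), "position outside")
})

test_that("the shipped wheat family annotation loads and parses", {
  ann <- wheat_hsf_annotation()
  expect_equal(nrow(ann), 82)
  expect_true(all(ann$hsf_class %in% c("A", "B", "C")))
  expect_true(all(ann$chromosome %in%
                    c(paste0(rep(1:7, each = 3), c("A", "B", "D")), "U")))
})
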