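test_that("DBD detection locates the consensus and calls all elements full", {
  seed <- hsf_dbd_seed()
  model <- hsf_dbd_profile()
  set.seed(13)
  prot <- paste0(random_protein(35), seed$consensus, random_protein(60))
  hit <- detect_dbd(model, prot)
  expect_equal(hit$start, 36)
  expect_equal(hit$end, 35 + nchar(seed$consensus))
  expect_equal(unname(hit$element_presence),
               rep("full", 7))

  # replacing the beta4 columns with poly-G ablates only beta4
  b4 <- range(which(seed$elements == "b4"))
  broken <- seed$consensus
  substr(broken, b4[1], b4[2]) <- strrep("G", b4[2] - b4[1] + 1)
  hit2 <- detect_dbd(model, paste0(random_protein(35), broken,
                                   random_protein(60)))
  expect_equal(unname(hit2$element_presence["b4"]), "absent")
  expect_true(all(hit2$element_presence[setdiff(names(hit2$element_presence),
                                                "b4")] == "full"))

  # random decoys stay below the score floor
  set.seed(14)
  for (i in 1:5) expect_null(detect_dbd(model, random_protein(300)))
})

test_that("heptad-array detection recovers the planted insert for k = 0..40", {
  set.seed(17)
  for (k in 0:40) {
    prot <- heptad_construct(k, lead = 10)
    ann <- detect_hrab(prot, search_start = 1)
    expect_false(is.null(ann))
    expect_equal(ann$insert_length, k)
    # insert is the residues strictly between HR-A end and HR-B start
    expect_equal(ann$hr_b[1] - ann$hr_a[2] - 1, k)
  }
})

test_that("fewer than two heptad arrays yields no HR-A/B call", {
  polar <- strrep("SEQTN", 40)
  expect_null(detect_hrab(polar, 1))
  one_array <- paste0("LEQLKSDLRELESD", strrep("SEQTN", 10))  # 2 heptads only
  expect_null(detect_hrab(one_array, 1))
})

test_that("insert-length bands assign classes with no gaps or overlaps", {
  expect_equal(classify_by_insert(21)$hsf_class, "A")
  expect_true(classify_by_insert(21)$in_band)
  expect_equal(classify_by_insert(7)$hsf_class, "C")
  expect_true(classify_by_insert(7)$in_band)
  expect_equal(classify_by_insert(0)$hsf_class, "B")
  expect_true(classify_by_insert(0)$in_band)
  expect_error(classify_by_insert(-1), "nonnegative")

  # total on 0..100: every insert gets exactly one class; band edges exact
  cls <- vapply(0:100, function(k) classify_by_insert(k)$hsf_class, "")
  expect_true(all(cls %in% c("A", "B", "C")))
  expect_equal(cls[1:3], rep("B", 3))       # 0..2
  expect_equal(cls[4:14], rep("C", 11))     # 3..13
  expect_equal(cls[15:101], rep("A", 87))   # >= 14
  in_band <- vapply(0:100, function(k) classify_by_insert(k)$in_band, NA)
  expect_equal(which(in_band) - 1, c(0:2, 5:9, 19:23))
})

test_that("family filter drops domain-less candidates and resolves overlaps", {
  cand <- data.frame(id = paste0("g", 1:5), aa = c(300, 250, 400, 350, 200),
                     has_dbd = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                     has_hrab = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  res <- apply_family_filter(cand)
  expect_equal(res$retained$id, c("g1", "g3", "g4"))
  expect_equal(sort(res$exclusions$id), c("g2", "g5"))
  expect_true(all(res$exclusions$reason == "no HR-A/B"))

  # identical coordinates: the longer protein wins
  cand2 <- data.frame(id = c("long", "short"), aa = c(300, 200),
                      has_dbd = TRUE, has_hrab = TRUE,
                      stringsAsFactors = FALSE)
  gm <- data.frame(id = c("long", "short"), chromosome = "1A", strand = "+",
                   start = c(1000, 1000), end = c(3000, 3000),
                   stringsAsFactors = FALSE)
  res2 <- apply_family_filter(cand2, gm)
  expect_equal(res2$retained$id, "long")
  expect_match(res2$exclusions$reason, "overlaps long")

  # non-overlapping models on the same chromosome are both kept
  gm$start <- c(1000, 5000); gm$end <- c(3000, 8000)
  expect_equal(nrow(apply_family_filter(cand2, gm)$retained), 2)
})

test_that("class recovery is perfect on noise-free families and >= 95% at 5% substitution", {
  model <- hsf_dbd_profile()
  recover <- function(rate, seed) {
    fam <- generate_family(family_spec(substitution_rate = rate,
                                       n_decoys = 0, seed = seed))
    got <- vapply(fam$proteins$sequence, function(s) {
      dbd <- detect_dbd(model, s)
      if (is.null(dbd)) return(NA_character_)
      hrab <- detect_hrab(s, dbd$end + 1)
      if (is.null(hrab)) return(NA_character_)
      classify_by_insert(hrab$insert_length)$hsf_class
    }, character(1), USE.NAMES = FALSE)
    mean(!is.na(got) & got == fam$truth$hsf_class)
  }
  expect_equal(recover(0, seed = 23), 1)
  expect_gte(recover(0.05, seed = 24), 0.95)
})
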