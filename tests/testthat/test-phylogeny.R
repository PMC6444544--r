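test_that("the N-terminal region runs from DBD start through HR-B end", {
  prot <- paste0(strrep("S", 9), strrep("D", 96), strrep("L", 75),
                 strrep("T", 40))
  expect_equal(extract_n_terminal_region(prot, c(10, 105), c(106, 180)),
               paste0(strrep("D", 96), strrep("L", 75)))
  expect_error(extract_n_terminal_region(prot, c(10, 105), c(150, 900)),
               "beyond protein length")
  expect_error(extract_n_terminal_region(prot, NULL, c(1, 2)), "missing domain")

  fam <- generate_family(family_spec(counts = c(A1 = 2), substitution_rate = 0,
                                     n_decoys = 0, seed = 31))
  tr <- fam$truth[1, ]
  seq <- fam$proteins$sequence[1]
  reg <- extract_n_terminal_region(seq, c(tr$dbd_start, tr$dbd_end),
                                   c(tr$hrb_start, tr$hrb_end))
  expect_equal(reg, substr(seq, tr$dbd_start, tr$hrb_end))
  expect_equal(nchar(reg), tr$hrb_end - tr$dbd_start + 1)
})

test_that("p-distance uses pairwise deletion", {
  expect_equal(pdistance("AAAA", "AAAA"), 0)
  expect_equal(pdistance("AAAA", "AAAT"), 0.25)
  expect_equal(pdistance("A-AA", "AAAA"), 0)      # 3 comparable sites
  expect_equal(pdistance("A-TA", "AATA"), 0)
  expect_error(pdistance("--", "AA"), "zero comparable")
  expect_error(pdistance("AA", "AAA"), "equal length")
  expect_equal(percent_identity("AAAA", "AAAT"), 75)
})

test_that("Poisson correction matches the closed form and dominates p", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.1), 0.105361, tolerance = 1e-5)
  expect_equal(poisson_correct(0.5), 0.693147, tolerance = 1e-5)
  expect_error(poisson_correct(1), "saturated")
  p <- seq(0, 0.99, by = 0.01)
  d <- poisson_correct(p)
  expect_true(all(diff(d) > 0))   # strictly increasing
  expect_true(all(d >= p))        # correction never shrinks a distance
})

test_that("NJ reproduces the 3-taxon closed form and breaks ties deterministically", {
  dm <- matrix(c(0, .4, .6, .4, 0, .8, .6, .8, 0), 3, 3,
               dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  phy <- build_nj_tree(dm)
  pend <- phy$edge.length[match(1:3, phy$edge[, 2])]
  expect_equal(pend[match(c("t1", "t2", "t3"), phy$tip.label)],
               c(0.1, 0.3, 0.5))

  eq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  t1 <- build_nj_tree(eq)
  t2 <- build_nj_tree(eq)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))  # deterministic

  expect_error(build_nj_tree(eq[1:2, 1:2]), "at least 3")
  bad <- eq; bad[1, 2] <- bad[2, 1] <- Inf
  expect_error(build_nj_tree(bad), "non-finite")
})

test_that("NJ recovers topology and branch lengths of random additive matrices", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  for (i in 1:100) {
    nt <- sample(4:10, 1)
    ref <- ape::rtree(nt)
    ref$edge.length <- stats::runif(nrow(ref$edge), 0.05, 0.6)
    dm <- stats::cophenetic(ref)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    mine <- build_nj_tree(dm)
    expect_equal(phangorn::RF.dist(mine, ape::unroot(ref)), 0)
    # additivity: path lengths of the reconstruction equal the input matrix
    expect_equal(stats::cophenetic(mine)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on generic matrices", {
  set.seed(47)
  for (i in 1:20) {
    nt <- sample(5:12, 1)
    m <- matrix(stats::runif(nt * nt, 0.1, 1), nt)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("x", 1:nt), paste0("x", 1:nt))
    expect_equal(phangorn::RF.dist(build_nj_tree(m), ape::nj(m)), 0)
  }
})

test_that("bootstrap supports are reproducible and certain for identical cherries", {
  # two identical rows, maximally distant from two other identical rows:
  # every resample preserves the cherry
  aln <- c(a1 = strrep("AG", 20), a2 = strrep("AG", 20),
           b1 = strrep("WG", 20), b2 = strrep("WG", 20))
  boot <- bootstrap_support(aln, n_replicates = 50, seed = 3)
  expect_equal(nrow(boot$splits), 1)
  expect_equal(boot$splits$support, 100)

  one <- bootstrap_support(aln, n_replicates = 1, seed = 5)
  expect_true(all(one$splits$support %in% c(0, 100)))

  set.seed(53)
  # six related rows (20% divergence from a common base) so no replicate
  # saturates the Poisson correction
  base <- strsplit(random_protein(60), "")[[1]]
  aln2 <- stats::setNames(vapply(1:6, function(i) {
    v <- base
    hit <- sample(60, 12)
    v[hit] <- sample(c("A", "C", "D", "E", "F"), 12, replace = TRUE)
    paste(v, collapse = "")
  }, ""), paste0("s", 1:6))
  b1 <- bootstrap_support(aln2, n_replicates = 30, seed = 7)
  b2 <- bootstrap_support(aln2, n_replicates = 30, seed = 7)
  expect_equal(b1$splits, b2$splits)   # same seed, same supports
  perm <- bootstrap_support(aln2[sample(6)], n_replicates = 30, seed = 7)
  expect_equal(perm$splits[order(perm$splits$key), ],
               b1$splits[order(b1$splits$key), ],
               ignore_attr = TRUE)     # taxon input order does not matter
})

test_that("subclass assignment follows clade references, novel clades and flags", {
  spec <- family_spec(counts = c(A1 = 2, A2 = 2, B1 = 2, C1 = 2, C2 = 2),
                      substitution_rate = 0, n_decoys = 0, seed = 11)
  fam <- generate_family(spec)
  model <- hsf_dbd_profile()
  aln <- profile_align(model, stats::setNames(fam$proteins$sequence,
                                              fam$proteins$id))
  boot <- bootstrap_support(aln, n_replicates = 50, seed = 2)
  refs <- fam$truth$id[fam$truth$index == 1]
  ref_sub <- stats::setNames(fam$truth$subclass[fam$truth$index == 1], refs)
  qs <- setdiff(fam$truth$id, refs)
  idm <- outer(qs, refs, Vectorize(function(q, r)
    percent_identity(aln[[q]], aln[[r]])))
  dimnames(idm) <- list(qs, refs)
  qcls <- stats::setNames(fam$truth$hsf_class, fam$truth$id)[qs]
  asg <- assign_subclasses(boot, qs, ref_sub, idm, qcls)
  truth_sub <- stats::setNames(fam$truth$subclass, fam$truth$id)
  expect_equal(asg$subclass, unname(truth_sub[asg$gene]))
  expect_true(all(asg$flag == ""))
  expect_error(assign_subclasses(boot, "nonexistent", ref_sub, idm, qcls),
               "absent from tree")
})

test_that("a reference-free well-supported class-C clade is labelled C3", {
  # hand-built bootstrap object: ((q1,q2),ref_C1,ref_C2) with a certain clade
  tree <- ape::read.tree(text = "((q1:1,q2:1):1,refC1:1,refC2:1);")
  # canonical split key: the side not containing the first taxon
  key <- paste(sort(c("refC1", "refC2")), collapse = "|")
  boot <- structure(list(tree = tree,
                         splits = data.frame(key = key, support = 95,
                                             stringsAsFactors = FALSE),
                         n_replicates = 100), class = "hsf_boot")
  idm <- matrix(50, 2, 2, dimnames = list(c("q1", "q2"),
                                          c("refC1", "refC2")))
  asg <- assign_subclasses(boot, c("q1", "q2"),
                           c(refC1 = "C1", refC2 = "C2"), idm,
                           c(q1 = "C", q2 = "C"))
  expect_equal(asg$subclass, c("C3", "C3"))  # next unused class-C integer
  expect_equal(asg$supporting_ref, c("novel", "novel"))

  # with no well-supported enclosing clade the query is unresolved
  boot$splits$support <- 40
  asg2 <- assign_subclasses(boot, "q1", c(refC1 = "C1", refC2 = "C2"),
                            idm, c(q1 = "C"))
  expect_equal(asg2$flag, "unresolved")
})
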