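test_that("sliding windows follow the count formula and start positions", {
  ws <- makeWindows(paste(rep("A", 10), collapse = ""), Lw = 4, Sw = 2)
  expect_equal(nrow(ws$windows), 4)
  expect_equal(ws$windows$start, c(1, 3, 5, 7))
  # degenerate: L == Lw gives exactly one window
  ws1 <- makeWindows("ACGT", 4, 3)
  expect_equal(nrow(ws1$windows), 1)
  # L=7, Lw=4, Sw=1 enumerates all 4 substrings of length 4
  s <- "ACGTACG"
  ws2 <- makeWindows(s, 4, 1)
  expect_equal(ws2$windows$subsequence,
               substring(s, 1:4, 4:7))
  # randomized sweep of the count formula
  set.seed(1)
  for (i in 1:50) {
    L <- sample(5:60, 1); Lw <- sample(2:min(L, 20), 1)
    Sw <- sample(1:10, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    ws <- makeWindows(seq, Lw, Sw)
    expect_equal(nrow(ws$windows), floor((L - Lw) / Sw) + 1)
    expect_true(all(nchar(ws$windows$subsequence) == Lw))
  }
  # shorter than the window length: empty set with warning
  expect_warning(wse <- makeWindows("ACG", 5, 1), "shorter")
  expect_equal(nrow(wse$windows), 0)
})

test_that("event detectors find duplications, mirrors, inversions and indels", {
  # duplication found by the repeat scan
  ev <- detectEvents("ACGTACGT", "ACGTACGT", kMin = 4)
  dup <- ev[ev$event == "duplication", ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$segment, "ACGT")
  # whole-window palindrome is a mirror at kMin = 8
  ev2 <- detectEvents("ACGTTGCA", "ACGTTGCA", kMin = 8)
  expect_true("mirror" %in% ev2$event)
  # identical windows produce no indel events
  ev3 <- detectEvents("ACGGTCAG", "ACGGTCAG", kMin = 4)
  expect_false(any(ev3$event %in% c("insertion", "deletion")))
  # a reversed reference block is an inversion
  ref <- "AATTCCGGCAGT"
  win <- "AATTGGCCCAGT"  # CCGG -> GGCC reversed
  ev4 <- detectEvents(win, ref, kMin = 4)
  expect_true("inversion" %in% ev4$event)
  # an inserted block is an insertion
  ev5 <- detectEvents("AACCGGTTAACCTTGG", "AACCGGAACCTTGG", kMin = 2)
  expect_true("insertion" %in% ev5$event)
})

test_that("segment descriptors are 12-dimensional and deterministic", {
  d <- segmentDescriptor("ACGT", "duplication")
  expect_length(d, 12)
  expect_equal(unname(d["length"]), 4)
  expect_equal(unname(d["gc"]), 0.5)
  expect_equal(unname(d[c("A", "C", "G", "T")]), rep(0.25, 4))
  expect_equal(unname(d["duplication"]), 1)
  expect_equal(sum(d[c("insertion", "deletion", "inversion", "mirror",
                       "duplication")]), 1)
  # homopolymer has zero 2-mer entropy
  expect_equal(unname(segmentDescriptor("AAAA", "insertion")["entropy2"]), 0)
  expect_identical(segmentDescriptor("ACGGT", "mirror"),
                   segmentDescriptor("ACGGT", "mirror"))
})

test_that("neighbor joining matches the classical oracle on additive matrices", {
  # 2 leaves: total path length equals the input distance
  t2 <- mnjaBuildTree(matrix(c(0, 3, 3, 0), 2), labels = c("a", "b"))
  expect_equal(sum(t2$edge.length), 3)
  # 3 leaves: three-point formula
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- mnjaBuildTree(D3)
  len <- t3$edge.length[order(t3$edge[, 2])]
  expect_equal(len, c((2 + 3 - 4) / 2, (2 + 4 - 3) / 2, (3 + 4 - 2) / 2))
  # additive matrices up to 6 leaves: exact topology + branch lengths
  set.seed(42)
  for (i in 1:12) {
    nt <- sample(4:6, 1)
    tr0 <- ape::rtree(nt)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.2, 2)
    tr0 <- ape::unroot(tr0)
    D <- ape::cophenetic.phylo(tr0)
    mine <- mnjaBuildTree(D[tr0$tip.label, tr0$tip.label],
                          labels = tr0$tip.label)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    pm <- ape::cophenetic.phylo(mine)[tr0$tip.label, tr0$tip.label]
    expect_lt(max(abs(pm - D[tr0$tip.label, tr0$tip.label])), 1e-9)
  }
  expect_error(mnjaBuildTree(matrix(0, 1, 1)), "at least 2")
})

test_that("descriptor input to the tree builder uses Euclidean dissimilarity", {
  set.seed(3)
  desc <- matrix(rnorm(5 * 12), 5, 12)
  tr <- mnjaBuildTree(desc)
  trD <- mnjaBuildTree(as.matrix(dist(desc)))
  expect_equal(sort(tr$edge.length), sort(trD$edge.length))
})

test_that("tree maps are symmetric patristic distances normalized to [0,1]", {
  t2 <- mnjaBuildTree(matrix(c(0, 3, 3, 0), 2), labels = c("a", "b"))
  m <- treeToMap(t2, size = 4)
  expect_equal(m[1:2, 1:2], matrix(c(0, 1, 1, 0), 2))
  expect_equal(m[3:4, ], matrix(0, 2, 4))
  set.seed(8)
  tr <- mnjaBuildTree(matrix(rnorm(6 * 12), 6, 12))
  mp <- treeToMap(tr, size = 8)
  expect_equal(mp, t(mp), ignore_attr = TRUE)
  expect_equal(diag(mp), rep(0, 8))
  expect_true(all(mp >= 0 & mp <= 1))
  # patristic distances match an independent all-pairs shortest-path oracle
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tr$edge.length
  oracle <- igraph::distances(g, v = tr$tip.label, to = tr$tip.label)
  mine <- ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label]
  expect_equal(unname(oracle), unname(mine), tolerance = 1e-12)
  # too many leaves for the requested size
  expect_error(treeToMap(tr, size = 4), "raise size")
})

test_that("detectors recover planted events at high rate and stay quiet on nulls", {
  set.seed(19)
  events <- c("insertion", "deletion", "inversion", "mirror", "duplication")
  planted <- 0; recovered <- 0
  for (i in 1:12) {
    ref <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    refs <- Biostrings::DNAStringSet(c(g = ref))
    plan <- data.frame(gene = "g",
                       event = sample(events, 2),
                       pos = c(60, 200), len = c(10, 10),
                       stringsAsFactors = FALSE)
    var <- mutateSequences(refs, plan)
    det <- detectGeneEvents(as.character(var[["g"]]), ref,
                            Lw = 40, Sw = 20, kMin = 4)
    for (r in seq_len(nrow(plan))) {
      planted <- planted + 1
      hit <- det$event == plan$event[r] &
        abs(det$start - plan$pos[r]) <= 45
      if (any(hit)) recovered <- recovered + 1
    }
  }
  expect_gte(recovered / planted, 0.95)
  # reference-identical repeat- and palindrome-free window yields no events
  quiet <- detectEvents("ACCGGTAA", "ACCGGTAA", kMin = 5)
  expect_equal(nrow(quiet), 0)
})
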