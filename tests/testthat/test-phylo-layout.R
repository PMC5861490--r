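# K2P distances, NJ recovery, tree-topology scan, circular positions

test_that("K2P distance matches the closed form and an independent oracle", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)

  # 100 columns, 10 transitions, 0 transversions: -1/2 log(0.8)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)

  # columns with gaps or N are excluded
  expect_equal(k2p_distance("ACG-A", "ACGTA"), 0)
  expect_equal(k2p_distance("ACGNA", "ACGTA"), 0)

  # random pairs against ape's K80 implementation (pairwise deletion)
  set.seed(10)
  for (i in 1:10) {
    x <- random_dna(500)
    y <- mutate_seq(x, sample(10:60, 1))
    m <- rbind(strsplit(tolower(x), "")[[1]], strsplit(tolower(y), "")[[1]])
    oracle <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                       pairwise.deletion = TRUE))
    expect_equal(k2p_distance(x, y), oracle, tolerance = 1e-9)
  }

  # saturation returns NA rather than a bogus number
  expect_true(is.na(k2p_distance(strrep("A", 100), strrep("G", 100))))
})

test_that("distance matrix is symmetric, relabels with input order, flags saturation", {
  set.seed(11)
  x <- random_dna(300)
  aln <- c(a = x, b = mutate_seq(x, 15), c = mutate_seq(x, 30))
  d <- build_distance_matrix(aln)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  # permuting input permutes rows/columns identically
  d2 <- build_distance_matrix(aln[c(3, 1, 2)])
  expect_equal(d2[names(aln), names(aln)], d[names(aln), names(aln)],
               ignore_attr = TRUE)

  # saturated pair replaced by 1.5x the max finite distance and recorded
  sat <- c(p = strrep("A", 200), q = strrep("G", 200),
           r = paste0(strrep("A", 190), strrep("C", 10)))
  ds <- build_distance_matrix(sat)
  expect_equal(nrow(attr(ds, "saturated")), 2)  # p-q and q-r saturate
  expect_equal(ds["p", "q"], 1.5 * max(ds["p", "r"]))
})

test_that("NJ recovers additive matrices exactly", {
  # hand-built additive matrix from tree ((A:1,B:2):1,(C:3,D:1))
  dm <- matrix(c(0, 3, 5, 3,
                 3, 0, 6, 4,
                 5, 6, 0, 4,
                 3, 4, 4, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  pat <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(pat, dm, tolerance = 1e-9)
  # internal edge of length 1 present, terminal branches as constructed
  expect_equal(round(sort(tr$edge.length), 9), c(1, 1, 1, 2, 3))

  # three taxa: unique star with solvable branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)], d3,
               tolerance = 1e-9)

  # random additive matrices (n <= 8) round-trip to 1e-9
  set.seed(12)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n)
    dm0 <- ape::cophenetic.phylo(tr0)
    tr1 <- nj_tree(dm0)
    expect_equal(ape::cophenetic.phylo(tr1)[rownames(dm0), colnames(dm0)],
                 dm0, tolerance = 1e-9)
  }

  # two leaves: trivial cherry splitting the distance
  t2 <- nj_tree(matrix(c(0, 4, 4, 0), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(sum(t2$edge.length), 4)
})

test_that("tree topology scan emits the worked six-leaf ordering", {
  tr <- fig_tree()
  dm <- ape::cophenetic.phylo(tr)
  # distances from A order the leaves C > B > F > E > D
  expect_identical(names(sort(dm["A", -1], decreasing = TRUE)),
                   c("C", "B", "F", "E", "D"))
  co <- tree_topology_scan(tr, dm, "A")
  expect_identical(co$ordered_ids, c("A", "D", "E", "F", "B", "C"))
  expect_length(co$gaps, 5)
  expect_equal(co$closing_gap, dm["C", "A"])
})

test_that("scan covers every leaf once and matches a recursive oracle", {
  # independent formulation: depth-first emission, visiting subtrees by
  # decreasing maximum distance to the initial leaf
  scan_oracle <- function(tr, initial) {
    rt <- ape::root(tr, outgroup = initial, resolve.root = TRUE)
    D <- ape::cophenetic.phylo(tr)[initial, ]
    ntip <- length(rt$tip.label)
    kids <- split(rt$edge[, 2], rt$edge[, 1])
    tips_under <- function(node) {
      if (node <= ntip) return(rt$tip.label[node])
      unlist(lapply(kids[[as.character(node)]], tips_under))
    }
    emit <- function(node) {
      if (node <= ntip) return(rt$tip.label[node])
      subs <- kids[[as.character(node)]]
      maxd <- vapply(subs, function(s) max(D[tips_under(s)]), numeric(1))
      unlist(lapply(subs[order(-maxd)], emit))
    }
    c(initial, rev(setdiff(emit(ntip + 1L), initial)))
  }
  for (s in 1:8) {
    set.seed(s)
    tr <- ape::rtree(8)
    init <- sample(tr$tip.label, 1)
    got <- tree_topology_scan(tr, initial_id = init, use_tree_dist = TRUE)
    expect_setequal(got$ordered_ids, tr$tip.label)
    expect_identical(got$ordered_ids, scan_oracle(tr, init))
  }

  # two leaves: (initial, other)
  t2 <- nj_tree(matrix(c(0, 1, 1, 0), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  expect_identical(tree_topology_scan(t2, initial_id = "b")$ordered_ids,
                   c("b", "a"))

  # unknown initial leaf errors
  expect_error(tree_topology_scan(fig_tree(), initial_id = "Z"), "leaf")
})

test_that("circular positions spread leaves by cumulative gap fractions", {
  mk <- function(ids, gaps, closing) {
    structure(list(ordered_ids = ids, gaps = gaps, closing_gap = closing),
              class = "circular_order")
  }
  # equal gaps over 4 leaves: quarter turns
  p <- circular_positions(mk(letters[1:4], c(1, 1, 1), 1))
  expect_equal(p$angle, c(0, pi / 2, pi, 3 * pi / 2))

  # gaps 1,1,2 with closing gap 4: cumulative fractions 0, 1/8, 1/4, 1/2
  p2 <- circular_positions(mk(letters[1:4], c(1, 1, 2), 4))
  expect_equal(p2$angle, c(0, pi / 4, pi / 2, pi))

  # strictly increasing for positive gaps; arc fractions sum to 1
  set.seed(13)
  g <- runif(9, 0.1, 2); cg <- runif(1, 0.1, 2)
  p3 <- circular_positions(mk(paste0("l", 1:10), g, cg))
  expect_true(all(diff(p3$angle) > 0))
  expect_equal((2 * pi - p3$angle[10]) / (2 * pi), cg / (sum(g) + cg))

  # degenerate all-zero gaps: uniform spacing fallback
  p4 <- circular_positions(mk(letters[1:4], c(0, 0, 0), 0))
  expect_equal(p4$angle, 2 * pi * (0:3) / 4)
})

test_that("taxon positions are wraparound-correct circular means", {
  deg <- function(x) x * pi / 180
  pos <- data.frame(id = c("a", "b", "c", "d", "e"),
                    angle = deg(c(10, 20, 350, 10, 123)))
  tp <- taxon_positions(pos, c(a = "X", b = "X", c = "Y", d = "Y", e = "Z"))
  expect_equal(tp$angle[tp$taxon == "X"], deg(15), tolerance = 1e-9)
  expect_equal(tp$angle[tp$taxon == "Y"], 0, tolerance = 1e-9)   # 350 and 10
  expect_equal(tp$angle[tp$taxon == "Z"], deg(123), tolerance = 1e-9)
  expect_error(taxon_positions(pos, c(a = "X")), "taxon")
})

test_that("layout JSON round-trips ids, angles and taxa", {
  pos <- data.frame(id = c("a", "b"), angle = c(0, pi))
  f <- tempfile(fileext = ".json")
  write_layout_json(pos, c(a = "PhylumA", b = "PhylumB"), f)
  back <- read_layout_json(f)
  expect_equal(back$id, pos$id)
  expect_equal(back$angle, pos$angle)
  expect_equal(back$taxon, c("PhylumA", "PhylumB"))
})
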