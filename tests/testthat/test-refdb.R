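# reference-database curation: trimming, filters, ordering, clustering

test_that("trimming anchors to the 8F and anti-SD motifs", {
  set.seed(1)
  core <- random_dna(1400)

  # motif at position 10: trimmed sequence starts at original position 4
  s <- paste0(strrep("G", 9), "TTGATCCT", core, "CACCTCCTTA")
  rec <- trim_to_anchors(seq_records("a", s))
  expect_true(rec$trimmed)
  expect_identical(rec$seq, substring(s, 4, nchar(s)))

  # only 2 upstream bases available: margin clamps to the sequence start
  s2 <- paste0("GG", "TTGATCCT", core, "CACCTCCTTA", "AAA")
  rec2 <- trim_to_anchors(seq_records("b", s2))
  expect_identical(rec2$seq, substring(s2, 1, nchar(s2) - 3))

  # derived: trimmed length equals 3'-motif end minus (5'-start - margin) + 1
  for (i in 1:5) {
    up <- random_dna(sample(7:30, 1))
    down <- random_dna(sample(1:20, 1))
    s3 <- paste0(up, "TTGATCCT", random_dna(500), "CACCTCCTTG", down)
    m5 <- regexpr("TTGATCCT", s3, fixed = TRUE)
    m3 <- regexpr("CACCTCCTT.", s3)
    expected_len <- (as.integer(m3) + 9) - (as.integer(m5) - 6) + 1
    got <- trim_to_anchors(seq_records("c", s3))
    expect_equal(got$length, expected_len)
  }

  # N in the 3' motif matches any base
  s4 <- paste0(random_dna(10), "TTGATCCT", random_dna(100), "CACCTCCTTT")
  expect_true(endsWith(trim_to_anchors(seq_records("d", s4))$seq, "CACCTCCTTT"))

  # neither motif, no guide: flagged untrimmable, sequence untouched
  s5 <- strrep("AC", 100)            # contains neither anchor motif
  rec5 <- trim_to_anchors(seq_records("e", s5))
  expect_false(rec5$trimmed)
  expect_identical(rec5$seq, s5)
})

test_that("guide alignment transfers trim coordinates when motifs are absent", {
  set.seed(2)
  guide <- random_dna(800)
  # record = junk + (guide with a few substitutions) + junk, no anchor motifs
  body <- mutate_seq(guide, 8)
  s <- paste0(random_dna(60), body, random_dna(40))
  rec <- trim_to_anchors(seq_records("g1", s), guide = guide)
  expect_true(rec$trimmed)
  expect_identical(rec$seq, body)
})

test_that("length filter keeps the inclusive 1120-1660 window", {
  recs <- seq_records(paste0("s", 1:4), lengths = c(1119, 1120, 1660, 1661))
  f <- filter_by_length(recs)
  expect_setequal(f$kept$length, c(1120, 1660))
  expect_setequal(f$removed$length, c(1119, 1661))

  # empty input
  empty <- filter_by_length(seq_records(character(0), lengths = integer(0)))
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$removed), 0)

  # derived: random lengths against a direct count, and partition invariant
  set.seed(3)
  lens <- sample(1000:1800, 100, replace = TRUE)
  recs <- seq_records(paste0("r", 1:100), lengths = lens)
  f <- filter_by_length(recs)
  expect_equal(nrow(f$kept), sum(lens >= 1120 & lens <= 1660))
  expect_setequal(c(f$kept$id, f$removed$id), recs$id)
})

test_that("homopolymer filter removes runs of 10+, keeps runs of 9", {
  base <- strrep("ACGT", 300)
  recs <- seq_records(c("ten", "nine"),
                      c(paste0(base, "AAAAAAAAAA"), paste0(base, "AAAAAAAAA")))
  f <- filter_homopolymer(recs)
  expect_identical(f$removed$id, "ten")
  expect_identical(f$kept$id, "nine")

  # derived: injected runs of known lengths vs an rle-based oracle
  set.seed(4)
  for (i in 1:20) {
    run_len <- sample(5:14, 1)
    b <- sample(c("A", "C", "G", "T"), 1)
    s <- paste0(random_dna(50), strrep(b, run_len), random_dna(50))
    max_run <- max(rle(strsplit(s, "")[[1]])$lengths)
    f <- filter_homopolymer(seq_records("x", s))
    expect_equal(nrow(f$removed) == 1, max_run >= 10)
  }
})

test_that("clustering order puts classified first, longest first", {
  recs <- seq_records(c("u1", "c1", "c2"), lengths = c(1600, 1300, 1500),
                      lineage = data.frame(id = c("u1", "c1", "c2"),
                                           genus = c("unclassified", "X", "Y")))
  recs$seq <- NA_character_
  expect_identical(sort_for_clustering(recs)$length, c(1500L, 1300L, 1600L))

  # all classified: plain descending length
  recs2 <- seq_records(paste0("c", 1:4), lengths = c(120, 150, 90, 150),
                       lineage = data.frame(id = paste0("c", 1:4),
                                            genus = rep("G", 4)))
  expect_identical(sort_for_clustering(recs2)$length, c(150L, 150L, 120L, 90L))

  # derived: random mix vs the two-key comparison oracle
  set.seed(5)
  n <- 40
  recs3 <- seq_records(paste0("m", 1:n), lengths = sample(1000:1100, n, TRUE),
                       lineage = data.frame(
                         id = paste0("m", 1:n),
                         genus = sample(c("A", "B", "unclassified"), n, TRUE)))
  got <- sort_for_clustering(recs3)
  oracle <- recs3[order(recs3$genus == "unclassified", -recs3$length,
                        recs3$id), ]
  expect_identical(got$id, oracle$id)
})

test_that("greedy clustering joins the first admissible representative", {
  set.seed(6)
  s <- random_dna(1000)
  # identical pair: one cluster of two
  recs <- seq_records(c("a", "b"), c(s, s),
                      lineage = data.frame(id = c("a", "b"), genus = "G"))
  cl <- greedy_cluster(recs)
  expect_equal(length(unique(cl$representative_id)), 1)

  # ~90% identity (below the 94% threshold): two singletons
  recs2 <- seq_records(c("a", "b"), c(s, mutate_seq(s, 100)),
                       lineage = data.frame(id = c("a", "b"), genus = "G"))
  cl2 <- greedy_cluster(recs2)
  expect_equal(length(unique(cl2$representative_id)), 2)

  # every input id appears exactly once
  expect_setequal(cl2$member_id, c("a", "b"))
})

test_that("finalize removes both-flagged chimeras and unclassified reps only", {
  reps <- data.frame(id = paste0("r", 1:6),
                     genus = c("A", "B", "unclassified", "C", "D", "E"),
                     stringsAsFactors = FALSE)
  flags <- data.frame(id = c("r1", "r2", "r4"),
                      denovo = c(TRUE, TRUE, FALSE),
                      reference = c(TRUE, FALSE, TRUE))
  fin <- finalize_representatives(reps, flags)
  # r1 both-flagged, r3 unclassified; r2/r4 single-flagged survive
  expect_setequal(fin$kept$id, c("r2", "r4", "r5", "r6"))
  expect_equal(unname(fin$counts["chimera"]), 1)
  expect_equal(unname(fin$counts["unclassified"]), 1)

  # unknown flag ids warn and are ignored
  expect_warning(finalize_representatives(reps,
    data.frame(id = "zz", denovo = TRUE, reference = TRUE)), "unknown")

  # derived: random flags on 100 reps vs a set-difference oracle
  set.seed(7)
  reps2 <- data.frame(id = sprintf("q%03d", 1:100),
                      genus = sample(c("A", "B", "unclassified"), 100, TRUE),
                      stringsAsFactors = FALSE)
  fl <- data.frame(id = reps2$id, denovo = sample(c(TRUE, FALSE), 100, TRUE),
                   reference = sample(c(TRUE, FALSE), 100, TRUE))
  fin2 <- finalize_representatives(reps2, fl)
  bad <- union(fl$id[fl$denovo & fl$reference],
               reps2$id[reps2$genus == "unclassified"])
  expect_setequal(fin2$kept$id, setdiff(reps2$id, bad))
})

test_that("phylum subsampling takes min(30, available), per class for Proteobacteria", {
  set.seed(8)
  recs <- seq_records(
    sprintf("s%03d", 1:102), lengths = rep(1400L, 102),
    lineage = data.frame(
      id = sprintf("s%03d", 1:102),
      phylum = c(rep("Firmicutes", 40), rep("Tinyphylum", 12),
                 rep("Proteobacteria", 50)),
      class = c(rep("Bacilli", 40), rep("Tinyclass", 12),
                rep(c("Alpha", "Gamma"), each = 25))))
  out <- subsample_for_phylum_layout(recs, n_per_taxon = 30, seed = 42)
  tab <- table(out$layout_group)
  expect_equal(unname(tab["Firmicutes"]), 30L)
  expect_equal(unname(tab["Tinyphylum"]), 12L)        # fewer than 30: all
  expect_equal(unname(tab["Proteobacteria/Alpha"]), 25L)
  expect_equal(unname(tab["Proteobacteria/Gamma"]), 25L)

  # same seed is byte-identical, different seed generally is not
  again <- subsample_for_phylum_layout(recs, n_per_taxon = 30, seed = 42)
  expect_identical(out$id, again$id)
})
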