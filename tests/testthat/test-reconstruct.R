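# read binning, overlap-consensus assembly, contig filtering, species calls

test_that("binning groups reads by reference and orients minus-strand reads", {
  set.seed(40)
  reads <- setNames(vapply(1:30, function(i) random_dna(150), ""),
                    sprintf("q%02d", 1:30))
  hits <- data.frame(query_id = names(reads),
                     ref_id = rep(c("refA", "refB"), each = 15),
                     strand = rep("+", 30), stringsAsFactors = FALSE)
  hits$strand[7] <- "-"
  bins <- bin_reads_by_reference(hits, reads)
  expect_setequal(names(bins), c("refA", "refB"))
  expect_equal(lengths(bins), c(refA = 15L, refB = 15L))
  expect_identical(bins$refA[["q07"]], revcomp(reads[["q07"]]))
  expect_identical(bins$refA[["q01"]], reads[["q01"]])

  # random assignment table vs a split() oracle
  hits2 <- data.frame(query_id = names(reads),
                      ref_id = sample(c("x", "y", "z"), 30, TRUE),
                      strand = "+", stringsAsFactors = FALSE)
  bins2 <- bin_reads_by_reference(hits2, reads)
  oracle <- split(names(reads), hits2$ref_id)
  for (r in names(oracle)) expect_setequal(names(bins2[[r]]), oracle[[r]])
})

test_that("tiled error-free reads assemble into the exact template", {
  set.seed(41)
  tpl <- random_dna(1500)
  reads <- tiling_reads(tpl, 150, 75)
  ctg <- assemble_bin(reads, min_overlap = 40, max_mismatch_rate = 0.02)
  expect_equal(nrow(ctg), 1)
  expect_identical(ctg$seq, tpl)
  expect_equal(ctg$mean_coverage, sum(nchar(reads)) / 1500)

  # single read: one contig equal to the read
  one <- assemble_bin(reads[1])
  expect_equal(nrow(one), 1)
  expect_identical(one$seq, unname(reads[1]))

  # two non-overlapping reads stay separate
  two <- assemble_bin(c(a = substring(tpl, 1, 150),
                        b = substring(tpl, 500, 649)))
  expect_equal(nrow(two), 2)
})

test_that("consensus takes the per-column majority over the read layout", {
  set.seed(42)
  tpl <- random_dna(400)
  reads <- tiling_reads(tpl, 150, 30)    # 5x coverage over most columns
  # corrupt one read with a single error; majority vote restores the template
  reads[3] <- mutate_seq(reads[3], 1)
  ctg <- assemble_bin(reads, min_overlap = 40, max_mismatch_rate = 0.05)
  expect_equal(nrow(ctg), 1)
  expect_identical(ctg$seq, tpl)
})

test_that("contig filter enforces length >= 800 and coverage >= 10", {
  ctgs <- data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                     seq = "N", length = c(1500L, 790L, 800L, 1200L),
                     mean_coverage = c(12, 50, 10, 9.9),
                     n_reads = 1L, source_ref_id = "r",
                     stringsAsFactors = FALSE)
  kept <- filter_contigs(ctgs)
  expect_setequal(kept$contig_id, c("c1", "c3"))

  # predicate oracle on random contig sets
  set.seed(43)
  rnd <- data.frame(contig_id = sprintf("k%02d", 1:40), seq = "N",
                    length = sample(600:1700, 40, TRUE),
                    mean_coverage = runif(40, 1, 20), n_reads = 1L,
                    source_ref_id = "r", stringsAsFactors = FALSE)
  expect_setequal(filter_contigs(rnd)$contig_id,
                  rnd$contig_id[rnd$length >= 800 & rnd$mean_coverage >= 10])
})

test_that("species names require >= 97% identity to a type strain", {
  set.seed(44)
  ts <- c("Escherichia coli" = random_dna(1500),
          "Bacillus subtilis" = random_dna(1500))
  ctg <- data.frame(contig_id = "c1", seq = ts[[1]], length = 1500L,
                    mean_coverage = 20, n_reads = 10L, source_ref_id = "r",
                    stringsAsFactors = FALSE)
  out <- assign_species(ctg, ts)
  expect_identical(out$species, "Escherichia coli")
  expect_equal(out$species_identity, 100)

  # just below threshold: 47/1500 substitutions ~ 96.87% -> no call
  ctg2 <- ctg; ctg2$seq <- mutate_seq(ts[[1]], 47)
  expect_true(is.na(assign_species(ctg2, ts)$species))

  # 1% mutations (~99%) keeps the right species
  ctg3 <- ctg; ctg3$seq <- mutate_seq(ts[[1]], 15)
  expect_identical(assign_species(ctg3, ts)$species, "Escherichia coli")

  expect_error(assign_species(ctg, character(0)), "empty")
})

test_that("the reconstruction workflow rebuilds a 16S gene at 100% identity", {
  set.seed(45)
  cm <- small_community(n = 2, seed = 45, error_rate = 0)
  tpl <- cm$refs[[1]]
  reads <- tiling_reads(tpl, 150, 12)   # >= 10x everywhere
  idx <- build_kmer_index(cm$refs, k = 16)
  hits <- classify_reads(reads, idx)
  contigs <- reconstruct_16s(hits, reads,
                             type_strains = setNames(cm$refs, cm$species))
  expect_equal(nrow(contigs), 1)
  expect_gte(contigs$length, 800)
  expect_gte(contigs$mean_coverage, 10)
  expect_equal(align_pair(contigs$seq, tpl)$identity, 100)
  expect_identical(contigs$species, cm$species[1])
})

test_that("binned assembly never fuses reads from two references", {
  set.seed(46)
  cm <- small_community(n = 2, seed = 46, error_rate = 0, mean_branch = 0.1)
  second <- tiling_reads(cm$refs[[2]], 150, 12)
  reads <- c(tiling_reads(cm$refs[[1]], 150, 12),
             setNames(second, sprintf("two%04d", seq_along(second))))
  idx <- build_kmer_index(cm$refs, k = 16)
  hits <- classify_reads(reads, idx)
  contigs <- reconstruct_16s(hits, reads)
  expect_gte(nrow(contigs), 2)
  for (i in seq_len(nrow(contigs))) {
    # near-full-span identity to each candidate source (short spurious
    # local matches to conserved motifs do not count as a source)
    ids <- vapply(cm$refs, function(r) {
      al <- align_pair(contigs$seq[i], r, mode = "local")
      if ((al$q_end - al$q_start + 1) / contigs$length[i] >= 0.5)
        al$identity else 0
    }, 0)
    expect_equal(sum(ids >= 97), 1)   # each contig matches exactly one source
  }
})
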