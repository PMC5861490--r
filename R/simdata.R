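#' Random DNA string
#'
#' @param n length in bp.
#' @param seed optional integer seed.
#' @return a single DNA string over `A,C,G,T`.
#' @export
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a random phylogenetic tree
#'
#' Random topology (via [ape::rtree()]) with independent exponential
#' branch lengths; reproducible under `seed`.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed.
#' @param mean_branch mean branch length (substitutions per site).
#' @return an [ape::phylo] tree with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_leaves, seed = NULL, mean_branch = 0.05) {
  stopifnot(n_leaves >= 2)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_leaves)
  tr$edge.length <- rexp(length(tr$edge.length), rate = 1 / mean_branch)
  tr
}

# K2P per-site substitution probabilities for branch length t with
# transition rate alpha and per-transversion rate beta
k2p_probs <- function(t, alpha, beta) {
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)          # each of the two transversions
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

mutate_k2p <- function(seq_chars, t, alpha, beta, invariant = integer(0)) {
  p <- k2p_probs(t, alpha, beta)
  n <- length(seq_chars)
  u <- runif(n)
  ts <- u < p["ts"]
  tv1 <- !ts & u < p["ts"] + p["tv"]
  tv2 <- !ts & !tv1 & u < p["ts"] + 2 * p["tv"]
  out <- seq_chars
  out[ts] <- TS_PARTNER[seq_chars[ts]]
  out[tv1] <- vapply(seq_chars[tv1], function(b) TV_PARTNERS[[b]][1], "")
  out[tv2] <- vapply(seq_chars[tv2], function(b) TV_PARTNERS[[b]][2], "")
  out[invariant] <- seq_chars[invariant]
  out
}

#' Evolve sequences along a tree under the Kimura model
#'
#' Forward simulation of the two-parameter substitution model: per
#' branch, each site changes according to the K2P transition
#' probabilities for that branch length (substitutions only, so the
#' leaves form a gap-free alignment).  Unless a root sequence is given,
#' a 16S-like root is generated with the 8F primer motif near the 5'
#' end and the anti-Shine-Dalgarno motif at the 3' end; the anchor
#' motifs (and their margins) are held invariant so trimming can be
#' exercised on the descendants.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param root_seq optional root DNA string.
#' @param core_length length of the variable core when generating the
#'   root (total root length = core + 24 anchor/flank bases).
#' @param alpha transition rate; `beta` rate of each of the two
#'   transversions.  The defaults satisfy `alpha + 2 * beta = 1`, so
#'   branch lengths are expected substitutions per site and K2P
#'   distance estimates are directly comparable to patristic distances.
#' @param beta see `alpha`.
#' @param seed integer seed.
#' @return named character vector of equal-length leaf sequences.
#' @export
evolve_sequences <- function(tree, root_seq = NULL, core_length = 1400L,
                             alpha = 0.5, beta = 0.25, seed = NULL) {
  stopifnot(alpha >= 0, beta >= 0)
  if (!is.null(seed)) set.seed(seed)
  anchors <- trim_anchors()
  if (is.null(root_seq)) {
    root_seq <- paste0("GCTCAG", anchors$five_prime_motif,
                       random_dna(core_length), "CACCTCCTTA")
  }
  chars <- strsplit(toupper(root_seq), "", fixed = TRUE)[[1]]
  m5 <- regexpr(motif_regex(anchors$five_prime_motif), root_seq)
  m3 <- regexpr(motif_regex(anchors$three_prime_motif), root_seq)
  invariant <- integer(0)
  if (m5 > 0) {
    invariant <- c(invariant, max(1, m5 - anchors$five_prime_margin):
                     (m5 + attr(m5, "match.length") - 1))
  }
  if (m3 > 0) invariant <- c(invariant, m3:(m3 + attr(m3, "match.length") - 1))

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  ord <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  root_node <- ord$edge[1, 1]
  seqs[[root_node]] <- chars
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    seqs[[child]] <- mutate_k2p(seqs[[par]], ord$edge.length[e],
                                alpha, beta, invariant)
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}

#' Define a mock community
#'
#' A set of species with reference 16S sequences, lineage labels, DNA
#' molarity weights and genomic 16S copy numbers.  The expected read
#' share of a species is proportional to molarity times copy number
#' (shotgun reads sample gene copies, not genomes).
#'
#' @param refs named character vector of reference 16S sequences (names
#'   are sequence ids).
#' @param genus,species character vectors parallel to `refs`.
#' @param molarity positive DNA molarity weights.
#' @param copy_number integer 16S copy counts (>= 1).
#' @param read_length read length for simulation (default 150 bp).
#' @param error_rate per-base substitution error rate.
#' @return object of class `mock_community`.
#' @export
mock_community <- function(refs, genus, species = names(refs),
                           molarity = rep(1, length(refs)),
                           copy_number = rep(1L, length(refs)),
                           read_length = 150L, error_rate = 0) {
  stopifnot(!is.null(names(refs)), length(genus) == length(refs),
            all(molarity > 0), all(copy_number >= 1),
            all(nchar(refs) >= read_length))
  structure(list(refs = refs, genus = genus, species = species,
                 molarity = molarity, copy_number = as.integer(copy_number),
                 read_length = as.integer(read_length),
                 error_rate = error_rate),
            class = "mock_community")
}

#' Simulate shotgun reads from a mock community
#'
#' Species are drawn with probability proportional to molarity times
#' 16S copy number; read start positions are uniform, strands are
#' random, and substitution errors are applied at the community's
#' error rate.  A truth table records the origin of every read.
#'
#' @param community a [mock_community()].
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `ref_id`, `genus`, `species`, `start`,
#'   `strand`).
#' @export
simulate_reads <- function(community, n_reads, seed = NULL) {
  stopifnot(inherits(community, "mock_community"), n_reads >= 1)
  if (!is.null(seed)) set.seed(seed)
  prob <- community$molarity * community$copy_number
  src <- sample(seq_along(community$refs), n_reads, replace = TRUE,
                prob = prob / sum(prob))
  rl <- community$read_length
  reads <- character(n_reads)
  starts <- integer(n_reads)
  strands <- character(n_reads)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_reads)) {
    ref <- community$refs[[src[i]]]
    start <- sample.int(nchar(ref) - rl + 1L, 1L)
    r <- substring(ref, start, start + rl - 1L)
    if (community$error_rate > 0) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      err <- which(runif(rl) < community$error_rate)
      for (e in err) ch[e] <- sample(setdiff(bases, ch[e]), 1L)
      r <- paste(ch, collapse = "")
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") r <- revcomp(r)
    reads[i] <- r; starts[i] <- start; strands[i] <- strand
  }
  ids <- sprintf("read%05d", seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids,
                          ref_id = names(community$refs)[src],
                          genus = community$genus[src],
                          species = community$species[src],
                          start = starts, strand = strands,
                          stringsAsFactors = FALSE))
}

#' Generate non-16S contaminant sequences
#'
#' Decoy sequences unrelated to any 16S reference: random DNA for the
#' `random` kind, short tRNA-like (~76 bp repeated motif structure) and
#' longer 23S-like random sequences.  Unrelatedness (< 80% identity to
#' the references) should be verified with the search itself where it
#' matters.
#'
#' @param n number of sequences.
#' @param kinds subset of `c("random", "tRNA", "23S")` cycled over the
#'   output.
#' @param length length of `random` kind sequences.
#' @param seed integer seed.
#' @return named character vector.
#' @export
make_contaminants <- function(n, kinds = c("random", "tRNA", "23S"),
                              length = 150L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kinds <- match.arg(kinds, several.ok = TRUE)
  kind <- rep_len(kinds, n)
  out <- vapply(kind, function(k) {
    switch(k,
           random = random_dna(length),
           tRNA = random_dna(76L),
           "23S" = random_dna(600L))
  }, "")
  names(out) <- sprintf("contam%03d_%s", seq_len(n), kind)
  out
}

#' Simulate an annotated reference set for layout tests
#'
#' A convenience generator: simulates one tree per phylum-analog,
#' evolves 16S-like sequences on it, and assembles the lineage table
#' (each phylum gets `genera_per_phylum` genera assigned cyclically to
#' its leaves).
#'
#' @param n_phyla number of phylum-analog clades.
#' @param leaves_per_phylum leaves in each clade.
#' @param genera_per_phylum genera per clade.
#' @param seed integer seed.
#' @param core_length root core length passed to [evolve_sequences()].
#' @return list with `seqs` (named character vector), `lineage`
#'   (data.frame `id`, `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`) and `records` (a [seq_records()] table).
#' @export
simulate_reference_set <- function(n_phyla = 3, leaves_per_phylum = 8,
                                   genera_per_phylum = 3, seed = 1,
                                   core_length = 600L) {
  set.seed(seed)
  seqs <- character(0)
  lin <- list()
  for (p in seq_len(n_phyla)) {
    tr <- simulate_tree(leaves_per_phylum, mean_branch = 0.03)
    leaves <- evolve_sequences(tr, core_length = core_length)
    # divergent phylum-level roots: evolve each phylum from its own root
    ids <- sprintf("P%02dL%02d", p, seq_along(leaves))
    names(leaves) <- ids
    seqs <- c(seqs, leaves)
    lin[[p]] <- data.frame(
      id = ids, domain = "Bacteria", phylum = sprintf("Phylum%02d", p),
      class = sprintf("Class%02d", p), order = sprintf("Order%02d", p),
      family = sprintf("Family%02d", p),
      genus = sprintf("Genus%02d_%d", p,
                      rep_len(seq_len(genera_per_phylum), length(ids))),
      stringsAsFactors = FALSE)
  }
  lineage <- do.call(rbind, lin)
  list(seqs = seqs, lineage = lineage,
       records = seq_records(names(seqs), seqs, lineage = lineage))
}
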