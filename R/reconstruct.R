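#' Bin reads by their top-hit reference
#'
#' Groups reads assigned to the same reference sequence; minus-strand
#' reads are stored reverse-complemented so every bin is oriented to
#' the reference strand.
#'
#' @param hits top-hit data.frame with `query_id`, `ref_id`, `strand`.
#' @param reads named character vector of the read sequences.
#' @return named list of bins; each bin is a named character vector of
#'   oriented reads, the list names being the reference ids.
#' @export
bin_reads_by_reference <- function(hits, reads) {
  stopifnot(all(c("query_id", "ref_id", "strand") %in% names(hits)))
  oriented <- reads[hits$query_id]
  minus <- hits$strand == "-"
  if (any(minus)) oriented[minus] <- revcomp(oriented[minus])
  split(oriented, hits$ref_id)
}

consensus_from_layout <- function(offsets, seqs) {
  len <- max(offsets + nchar(seqs))
  counts <- matrix(0L, nrow = 4, ncol = len,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    b <- match(ch, c("A", "C", "G", "T"))
    pos <- offsets[i] + seq_along(ch)
    ok <- !is.na(b)
    counts[cbind(b[ok], pos[ok])] <- counts[cbind(b[ok], pos[ok])] + 1L
  }
  cons <- rownames(counts)[apply(counts, 2, which.max)]
  paste(cons, collapse = "")
}

#' Greedy overlap-consensus assembly of one read bin
#'
#' Repeatedly merges the pair of contigs with the longest suffix-prefix
#' overlap of at least `min_overlap` bases and mismatch rate at most
#' `max_mismatch_rate`, until no admissible overlap remains.  The final
#' sequence of every contig is the per-column majority vote over its
#' read layout; mean coverage is total read bases over contig length.
#' Reads without any admissible overlap become single-read contigs
#' (removed later by the length filter).
#'
#' @param bin named character vector of oriented reads (one bin from
#'   [bin_reads_by_reference()]).
#' @param min_overlap minimum overlap length in bp (default 40).
#' @param max_mismatch_rate maximum mismatch fraction within the
#'   overlap (default 0.02).
#' @param source_ref_id optional reference id recorded on the contigs.
#' @return data.frame with `contig_id`, `seq`, `length`,
#'   `mean_coverage`, `n_reads`, `source_ref_id`.
#' @export
assemble_bin <- function(bin, min_overlap = 40L, max_mismatch_rate = 0.02,
                         source_ref_id = NA_character_) {
  stopifnot(length(bin) >= 1)
  # each contig: sequence + layout of (read offset, read seq)
  contigs <- lapply(seq_along(bin), function(i) {
    list(seq = bin[[i]], offsets = 0L, reads = bin[i])
  })
  n <- length(contigs)
  ov <- function(i, j) {
    best_overlap_cpp(contigs[[i]]$seq, contigs[[j]]$seq,
                     as.integer(min_overlap), max_mismatch_rate)$length
  }
  # pairwise suffix-prefix overlap matrix, rows/cols refreshed on merge
  M <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) M[i, j] <- ov(i, j)
  alive <- rep(TRUE, n)
  while (sum(alive) >= 2 && max(M) > 0) {
    k <- arrayInd(which.max(M), dim(M))
    i <- k[1]; j <- k[2]; L <- M[i, j]
    ci <- contigs[[i]]; cj <- contigs[[j]]
    shift <- nchar(ci$seq) - L
    contigs[[i]] <- list(seq = paste0(ci$seq, substring(cj$seq, L + 1)),
                         offsets = c(ci$offsets, cj$offsets + shift),
                         reads = c(ci$reads, cj$reads))
    alive[j] <- FALSE
    M[j, ] <- 0L; M[, j] <- 0L
    for (o in which(alive)) {
      if (o != i) { M[i, o] <- ov(i, o); M[o, i] <- ov(o, i) }
    }
  }
  alive <- which(alive)
  out <- lapply(seq_along(alive), function(n) {
    cg <- contigs[[alive[n]]]
    seq <- if (length(cg$reads) > 1) {
      consensus_from_layout(cg$offsets, cg$reads)
    } else cg$seq
    data.frame(contig_id = sprintf("%s_contig%d",
                                   ifelse(is.na(source_ref_id), "bin",
                                          source_ref_id), n),
               seq = seq, length = nchar(seq),
               mean_coverage = sum(nchar(cg$reads)) / nchar(seq),
               n_reads = length(cg$reads),
               source_ref_id = source_ref_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Contig length and coverage filter
#'
#' Keeps contigs that are nearly full length (>= `min_len` bp) and
#' well supported (mean coverage >= `min_cov`).
#'
#' @param contigs contig data.frame from [assemble_bin()].
#' @param min_len minimum contig length (default 800 bp).
#' @param min_cov minimum mean read coverage (default 10).
#' @return the kept contigs.
#' @export
filter_contigs <- function(contigs, min_len = 800L, min_cov = 10) {
  keep <- contigs$length >= min_len & contigs$mean_coverage >= min_cov
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species assignment of reconstructed 16S contigs
#'
#' Aligns each contig against the type-strain sequences and assigns
#' the species name of the best alignment when its identity reaches
#' `min_identity` (default 97).  To keep a short spurious perfect
#' segment (e.g. a conserved motif) from producing a species call, the
#' alignment must also span at least `min_span` of the contig.  Ties at
#' equal identity report all tied names joined with `;` in
#' lexicographic order.
#'
#' @param contigs contig data.frame.
#' @param type_strains named character vector of type-strain 16S
#'   sequences; names are the species names.
#' @param min_identity species-call identity threshold (percent).
#' @param min_span minimum aligned fraction of the contig.
#' @return the contigs with `species` and `species_identity` columns
#'   (`NA` when below threshold).
#' @export
assign_species <- function(contigs, type_strains, min_identity = 97,
                           min_span = 0.5) {
  if (!length(type_strains)) stop("type-strain database is empty")
  contigs$species <- NA_character_
  contigs$species_identity <- NA_real_
  for (i in seq_len(nrow(contigs))) {
    ids <- numeric(length(type_strains))
    for (j in seq_along(type_strains)) {
      al <- align_pair(contigs$seq[i], type_strains[[j]], mode = "local")
      span <- (al$q_end - al$q_start + 1) / contigs$length[i]
      ids[j] <- if (span >= min_span) al$identity else 0
    }
    top <- max(ids)
    if (top >= min_identity) {
      tied <- sort(names(type_strains)[ids == top])
      contigs$species[i] <- paste(tied, collapse = ";")
      contigs$species_identity[i] <- top
    }
  }
  contigs
}

#' Reconstruct nearly full-length 16S genes from classified reads
#'
#' Bins reads by top-hit reference, assembles each bin greedily,
#' applies the length / coverage filters and (optionally) assigns
#' species names against a type-strain set.
#'
#' @param hits top-hit data.frame.
#' @param reads named character vector of reads.
#' @param type_strains optional named character vector of type-strain
#'   sequences (names = species).
#' @param min_overlap,max_mismatch_rate assembly parameters.
#' @param min_len,min_cov contig filters.
#' @param species_identity species-call threshold.
#' @return data.frame of kept contigs (possibly with species columns).
#' @export
reconstruct_16s <- function(hits, reads, type_strains = NULL,
                            min_overlap = 40L, max_mismatch_rate = 0.02,
                            min_len = 800L, min_cov = 10,
                            species_identity = 97) {
  bins <- bin_reads_by_reference(hits, reads)
  contigs <- do.call(rbind, lapply(names(bins), function(rid) {
    assemble_bin(bins[[rid]], min_overlap, max_mismatch_rate,
                 source_ref_id = rid)
  }))
  kept <- filter_contigs(contigs, min_len, min_cov)
  if (!is.null(type_strains) && nrow(kept)) {
    kept <- assign_species(kept, type_strains, species_identity)
  }
  kept
}
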