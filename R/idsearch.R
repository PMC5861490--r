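#' Build a k-mer index over reference sequences
#'
#' Indexing is separated from searching: the index of a reference set
#' is built once, can be serialized to disk, and is reused for every
#' sample.  Postings record, for every non-ambiguous k-mer of every
#' reference, the reference and 1-based offset where it occurs.
#'
#' @param refs named character vector of reference sequences.
#' @param k word size (default 16).
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(refs, k = 16L) {
  stopifnot(length(refs) > 0, !is.null(names(refs)))
  k <- as.integer(k)
  lens <- nchar(refs)
  if (k > min(lens)) stop("k exceeds the shortest reference length")
  all_km <- character(0); all_ref <- integer(0); all_pos <- integer(0)
  for (i in seq_along(refs)) {
    L <- lens[i]
    km <- substring(refs[[i]], 1:(L - k + 1), k:L)
    ok <- !grepl("[^ACGT]", km)
    all_km <- c(all_km, km[ok])
    all_ref <- c(all_ref, rep.int(i, sum(ok)))
    all_pos <- c(all_pos, which(ok))
  }
  sp <- split(seq_along(all_km), all_km)
  postings <- lapply(sp, function(ii) list(ref = all_ref[ii], pos = all_pos[ii]))
  idx <- list(k = k, ref_ids = names(refs), ref_lengths = unname(lens),
              refs = unname(refs), postings = postings)
  idx$post_env <- list2env(postings, hash = TRUE)
  class(idx) <- "kmer_index"
  idx
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d references, %d distinct k-mers\n",
              x$k, length(x$ref_ids), length(x$postings)))
  invisible(x)
}

#' Serialize / load a k-mer index
#'
#' The index is written as versioned JSON so saved and freshly built
#' indexes give identical search results.
#'
#' @param index a `kmer_index`.
#' @param path file path.
#' @export
save_kmer_index <- function(index, path) {
  obj <- list(format = "vitring-kmer-index", version = 1L, k = index$k,
              ref_ids = index$ref_ids, ref_lengths = index$ref_lengths,
              refs = index$refs, postings = index$postings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_kmer_index
#' @export
load_kmer_index <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(obj$format, "vitring-kmer-index")) {
    stop("not a vitring k-mer index file")
  }
  postings <- lapply(obj$postings, function(p) {
    list(ref = as.integer(p$ref), pos = as.integer(p$pos))
  })
  idx <- list(k = as.integer(obj$k), ref_ids = obj$ref_ids,
              ref_lengths = as.integer(obj$ref_lengths), refs = obj$refs,
              postings = postings)
  idx$post_env <- list2env(postings, hash = TRUE)
  class(idx) <- "kmer_index"
  idx
}

# seed counting on one strand: returns per-candidate ref the seed count
# and the most seed-supported diagonal (ref_pos - query_pos)
seed_candidates <- function(seq, index) {
  k <- index$k
  L <- nchar(seq)
  if (L < k) return(NULL)
  km <- substring(seq, 1:(L - k + 1), k:L)
  qpos <- seq_along(km)
  ok <- !grepl("[^ACGT]", km)
  refs <- integer(0); diags <- integer(0)
  env <- index$post_env
  for (i in which(ok)) {
    p <- env[[km[i]]]
    if (!is.null(p)) {
      refs <- c(refs, p$ref)
      diags <- c(diags, p$pos - qpos[i])
    }
  }
  if (!length(refs)) return(NULL)
  bydiag <- split(diags, refs)
  data.frame(ref = as.integer(names(bydiag)),
             count = lengths(bydiag),
             diag = vapply(bydiag, function(d) {
               tb <- table(d)
               as.integer(names(tb)[which.max(tb)])
             }, integer(1)),
             row.names = NULL)
}

#' Seed-and-extend identity search for one query
#'
#' Candidate references are ranked by shared k-mer seeds on both
#' strands (the reverse complement of the query is searched too); the
#' best-supported candidates are then aligned with a banded affine-gap
#' local alignment around the most seed-supported diagonal.  The single
#' top hit passing both thresholds is returned, ranked by identity,
#' then alignment length, then reference id.
#'
#' @param query a single DNA string (optionally named).
#' @param index a [build_kmer_index()] index.
#' @param min_identity minimum percent identity (default 80).
#' @param min_aln_len minimum aligned columns (default 100).
#' @param max_candidates candidate references aligned per strand.
#' @param band_pad half-width of the alignment band around the seed
#'   diagonal (absorbs indels up to this size).
#' @return one-row data.frame (`query_id`, `ref_id`, `identity`,
#'   `aln_len`, `score`, `strand`) or `NULL` when nothing passes.
#' @export
identity_search <- function(query, index, min_identity = 80,
                            min_aln_len = 100, max_candidates = 8L,
                            band_pad = 16L) {
  qid <- if (!is.null(names(query))) names(query)[1] else NA_character_
  q <- unname(query[1])
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") q else revcomp(q)
    cand <- seed_candidates(s, index)
    if (is.null(cand)) next
    cand <- cand[order(-cand$count), , drop = FALSE]
    cand <- head(cand, max_candidates)
    for (r in seq_len(nrow(cand))) {
      ri <- cand$ref[r]
      al <- banded_local_align_cpp(s, index$refs[[ri]],
                                   cand$diag[r] - band_pad,
                                   cand$diag[r] + band_pad,
                                   1, -1, 2, 1)
      if (al$identity >= min_identity && al$columns >= min_aln_len) {
        h <- list(ref_id = index$ref_ids[ri], identity = al$identity,
                  aln_len = al$columns, score = al$score, strand = strand)
        if (is.null(best) ||
            h$identity > best$identity ||
            (h$identity == best$identity && h$aln_len > best$aln_len) ||
            (h$identity == best$identity && h$aln_len == best$aln_len &&
             h$ref_id < best$ref_id)) {
          best <- h
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(query_id = qid, ref_id = best$ref_id,
             identity = best$identity, aln_len = best$aln_len,
             score = best$score, strand = best$strand,
             stringsAsFactors = FALSE)
}

#' Classify a read set against an index
#'
#' Runs [identity_search()] for every read and binds the top hits.
#' Reads without a passing hit are absent from the result.
#'
#' @param reads named character vector of reads.
#' @inheritParams identity_search
#' @return data.frame of top hits (possibly zero rows).
#' @export
classify_reads <- function(reads, index, min_identity = 80,
                           min_aln_len = 100, max_candidates = 8L,
                           band_pad = 16L) {
  stopifnot(!is.null(names(reads)))
  hits <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    hits[[i]] <- identity_search(reads[i], index, min_identity, min_aln_len,
                                 max_candidates, band_pad)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(query_id = character(0), ref_id = character(0),
                      identity = numeric(0), aln_len = integer(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Screen reads against a negative reference set
#'
#' Reads hitting the negative index (eukaryote 18S / mitochondrial
#' rRNA) at the same thresholds as the positive search are excluded
#' from profiling; the rest are retained.
#'
#' @param reads named character vector.
#' @param negative_index `kmer_index` over the negative set.
#' @inheritParams identity_search
#' @return list with `excluded_ids` and `retained_ids`.
#' @export
negative_screen <- function(reads, negative_index, min_identity = 80,
                            min_aln_len = 100) {
  neg <- classify_reads(reads, negative_index, min_identity, min_aln_len)
  excluded <- unique(neg$query_id)
  list(excluded_ids = excluded,
       retained_ids = setdiff(names(reads), excluded))
}
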