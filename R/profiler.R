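#' Genus profile from top hits
#'
#' Reads whose top-hit identity reaches `min_identity` (default 94)
#' contribute one count to the genus of their reference; the rest are
#' reported as unassigned and excluded from relative abundances.
#' References without a lineage entry count as unassigned with a
#' warning.
#'
#' @param hits top-hit data.frame from [classify_reads()] (already
#'   thresholded at the search level).
#' @param lineage_map data.frame with columns `id` and `genus` (one row
#'   per reference).
#' @param min_identity genus-assignment identity threshold (percent).
#' @param sample_id label stored in the profile.
#' @return object of class `genus_profile`: list with `sample_id`,
#'   `genera` (data.frame `genus`, `raw_count`, `weight`,
#'   `rel_abundance`), `assigned` (per-read data.frame `read_id`,
#'   `ref_id`, `genus`, `identity`), `unassigned_ids` and `normalized`
#'   flag.  Relative abundances sum to 1 whenever any read is assigned.
#' @export
assign_genus <- function(hits, lineage_map, min_identity = 94,
                         sample_id = "sample") {
  genus <- lineage_map$genus[match(hits$ref_id, lineage_map$id)]
  nolin <- !is.na(hits$ref_id) & is.na(genus)
  if (any(nolin)) {
    warning(sprintf("%d hits to references without lineage counted unassigned",
                    sum(nolin)))
  }
  ok <- hits$identity >= min_identity & !is.na(genus)
  assigned <- data.frame(read_id = hits$query_id[ok],
                         ref_id = hits$ref_id[ok],
                         genus = genus[ok],
                         identity = hits$identity[ok],
                         stringsAsFactors = FALSE)
  profile_from_assigned(assigned, unassigned_ids = hits$query_id[!ok],
                        sample_id = sample_id)
}

profile_from_assigned <- function(assigned, unassigned_ids = character(0),
                                  sample_id = "sample", weights = NULL,
                                  normalized = FALSE) {
  if (nrow(assigned)) {
    raw <- table(assigned$genus)
    genera <- data.frame(genus = names(raw),
                         raw_count = as.integer(raw),
                         stringsAsFactors = FALSE)
    genera$weight <- if (is.null(weights)) as.numeric(genera$raw_count) else
      unname(weights[genera$genus])
    genera$rel_abundance <- genera$weight / sum(genera$weight)
    genera <- genera[order(-genera$rel_abundance, genera$genus), ]
    rownames(genera) <- NULL
  } else {
    genera <- data.frame(genus = character(0), raw_count = integer(0),
                         weight = numeric(0), rel_abundance = numeric(0),
                         stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, genera = genera, assigned = assigned,
                 unassigned_ids = unassigned_ids, normalized = normalized),
            class = "genus_profile")
}

#' @export
print.genus_profile <- function(x, ...) {
  cat(sprintf("<genus_profile> sample '%s': %d reads over %d genera (%d unassigned)%s\n",
              x$sample_id, nrow(x$assigned), nrow(x$genera),
              length(x$unassigned_ids),
              if (x$normalized) ", copy-number normalized" else ""))
  if (nrow(x$genera)) print.data.frame(head(x$genera, 10), digits = 4)
  invisible(x)
}

#' Build a 16S copy-number reference database
#'
#' One reference sequence per species together with its genomic 16S
#' copy count and a k-mer index for nearest-neighbor lookups.
#'
#' @param seqs named character vector (one record per species).
#' @param copies named integer vector of 16S copy counts (>= 1), names
#'   matching `seqs`.
#' @param k index word size.
#' @return object of class `copy_number_db`.
#' @export
copy_number_db <- function(seqs, copies, k = 16L) {
  stopifnot(!is.null(names(seqs)), all(names(seqs) %in% names(copies)))
  copies <- copies[names(seqs)]
  if (any(copies < 1)) stop("copy counts must be >= 1")
  structure(list(seqs = seqs,
                 copies = setNames(as.integer(copies), names(seqs)),
                 index = build_kmer_index(seqs, k)),
            class = "copy_number_db")
}

#' Infer 16S copy number by nearest neighbor
#'
#' Each query inherits the copy count of its top hit in the
#' copy-number database (the copy number of a genome and of its nearest
#' 16S relative are assumed equal).  Queries without a passing hit fall
#' back to copy number 1 (no down-weighting) and are flagged.
#'
#' @param queries named character vector of reads or references.
#' @param cndb a [copy_number_db()].
#' @param min_identity,min_aln_len search thresholds (defaults 80 / 100,
#'   as in the primary search).
#' @return data.frame with `id`, `copies`, `cn_ref` (matched record or
#'   `NA`) and `fallback` (logical).
#' @export
infer_copy_number <- function(queries, cndb, min_identity = 80,
                              min_aln_len = 100) {
  stopifnot(inherits(cndb, "copy_number_db"))
  res <- data.frame(id = names(queries), copies = 1L,
                    cn_ref = NA_character_, fallback = TRUE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(queries)) {
    h <- identity_search(queries[i], cndb$index, min_identity, min_aln_len)
    if (!is.null(h)) {
      res$copies[i] <- cndb$copies[[h$ref_id]]
      res$cn_ref[i] <- h$ref_id
      res$fallback[i] <- FALSE
    }
  }
  res
}

#' Copy-number normalization of a genus profile
#'
#' Each assigned read contributes `1 / c` to its genus, where `c` is
#' the read's inferred 16S copy number; relative abundances are
#' recomputed from the normalized weights.  The set of detected genera
#' is unchanged.
#'
#' @param profile a `genus_profile` from [assign_genus()].
#' @param per_read_copies named integer vector (read id -> copy number
#'   `>= 1`), e.g. from [infer_copy_number()] on the reads.
#' @return a normalized `genus_profile`.
#' @export
normalize_profile <- function(profile, per_read_copies) {
  stopifnot(inherits(profile, "genus_profile"))
  a <- profile$assigned
  cc <- per_read_copies[a$read_id]
  if (anyNA(cc)) stop("every assigned read needs an inferred copy number")
  if (any(cc < 1)) stop("copy numbers must be >= 1")
  w <- vapply(split(1 / as.numeric(cc), a$genus), sum, numeric(1))
  profile_from_assigned(a, profile$unassigned_ids, profile$sample_id,
                        weights = w, normalized = TRUE)
}

#' Leave-one-out validation of copy-number inference
#'
#' Each record of the copy-number database is searched against the
#' database with itself removed; the inferred copy number is compared
#' with the record's true count as a fold error
#' `max(true, inferred) / min(true, inferred)`.
#'
#' @param cndb a [copy_number_db()].
#' @param min_identity,min_aln_len search thresholds.
#' @return data.frame `id`, `true_copies`, `inferred_copies`,
#'   `fold_error`; attribute `frac_within_twofold` summarizes the
#'   fraction of records with fold error <= 2.
#' @export
leave_one_out_cn <- function(cndb, min_identity = 80, min_aln_len = 100) {
  stopifnot(inherits(cndb, "copy_number_db"), length(cndb$seqs) >= 2)
  ids <- names(cndb$seqs)
  out <- data.frame(id = ids, true_copies = unname(cndb$copies[ids]),
                    inferred_copies = NA_integer_, fold_error = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rest <- copy_number_db(cndb$seqs[-i], cndb$copies[-i], k = cndb$index$k)
    inf <- infer_copy_number(cndb$seqs[i], rest, min_identity, min_aln_len)
    out$inferred_copies[i] <- inf$copies
    t <- out$true_copies[i]; v <- inf$copies
    out$fold_error[i] <- max(t, v) / min(t, v)
  }
  attr(out, "frac_within_twofold") <- mean(out$fold_error <= 2)
  out
}

#' Write / read a genus composition TSV
#'
#' Columns: `genus`, `raw_count`, `normalized_weight`,
#' `relative_abundance`.
#'
#' @param profile a `genus_profile`.
#' @param path file path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- profile$genera
  names(df) <- c("genus", "raw_count", "normalized_weight",
                 "relative_abundance")
  write_tsv(df, path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  read_tsv(path)
}
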