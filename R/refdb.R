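#' Trimming anchors for 16S reference curation
#'
#' The 5' end of a curated reference is anchored six bases upstream of
#' the 8F primer motif (`TTGATCCT`); the 3' end at the end of the
#' anti-Shine-Dalgarno motif (`CACCTCCTTN`, `N` matching any base).
#'
#' @param five_prime_motif 5' anchor motif.
#' @param five_prime_margin bases kept upstream of the 5' motif.
#' @param three_prime_motif 3' anchor motif; `N` matches any base.
#' @return list of class `trim_anchors`.
#' @export
trim_anchors <- function(five_prime_motif = "TTGATCCT",
                         five_prime_margin = 6L,
                         three_prime_motif = "CACCTCCTTN") {
  stopifnot(nzchar(five_prime_motif), nzchar(three_prime_motif),
            five_prime_margin >= 0)
  structure(list(five_prime_motif = five_prime_motif,
                 five_prime_margin = as.integer(five_prime_margin),
                 three_prime_motif = three_prime_motif),
            class = "trim_anchors")
}

motif_regex <- function(motif) gsub("N", ".", motif, fixed = TRUE)

#' Trim sequences to the 16S anchor motifs
#'
#' Each record is cut to start `five_prime_margin` bases before the
#' first occurrence of the 5' motif (clamped to the sequence start when
#' fewer bases are available) and to end at the end of the first 3'
#' motif downstream of the 5' anchor.  When a motif is absent and a
#' trimmed guide reference is supplied, the cut points are transferred
#' from the best local alignment to the guide (coordinates extended to
#' the guide ends, clamped).  Records with neither motifs nor a guide
#' hit are flagged untrimmable and kept unmodified.
#'
#' @param records a [seq_records()] table with sequences present.
#' @param anchors a [trim_anchors()] object.
#' @param guide optional single trimmed reference sequence (character).
#' @param guide_min_identity minimum percent identity for a guide
#'   alignment to be trusted.
#' @return the records with `seq`/`length` replaced by the trimmed
#'   values and a logical `trimmed` column (`FALSE` = untrimmable,
#'   original sequence retained).
#' @export
trim_to_anchors <- function(records, anchors = trim_anchors(), guide = NULL,
                            guide_min_identity = 80) {
  stopifnot(all(nchar(records$seq) > 0))
  re5 <- motif_regex(anchors$five_prime_motif)
  re3 <- motif_regex(anchors$three_prime_motif)
  out <- records
  out$trimmed <- FALSE
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]
    m5 <- regexpr(re5, s)
    if (m5 > 0) {
      from <- max(1L, m5 - anchors$five_prime_margin)
      tail_s <- substring(s, m5 + attr(m5, "match.length"))
      m3 <- regexpr(re3, tail_s)
      to <- if (m3 > 0) {
        m5 + attr(m5, "match.length") - 1L + m3 + attr(m3, "match.length") - 1L
      } else nchar(s)
      if (m3 > 0 || is.null(guide)) {
        out$seq[i] <- substring(s, from, to)
        out$trimmed[i] <- m3 > 0 || is.null(guide)
        if (m3 > 0) next
      }
    }
    if (!out$trimmed[i] && !is.null(guide)) {
      al <- align_pair(s, guide, mode = "local")
      if (al$identity >= guide_min_identity) {
        from <- max(1L, al$q_start - (al$t_start - 1L))
        to <- min(nchar(s), al$q_end + (nchar(guide) - al$t_end))
        out$seq[i] <- substring(s, from, to)
        out$trimmed[i] <- TRUE
      }
    }
  }
  out$length <- nchar(out$seq)
  as_seq_records(out)
}

#' Length filter for trimmed references
#'
#' Splits records into those within the accepted length window and the
#' abnormally short or long remainder.
#'
#' @param records a [seq_records()] table (sequences may be absent as
#'   long as `length` is filled).
#' @param min_bp,max_bp inclusive length bounds (defaults 1120/1660 bp).
#' @return list with `kept` and `removed` record tables partitioning the
#'   input.
#' @export
filter_by_length <- function(records, min_bp = 1120L, max_bp = 1660L) {
  ok <- records$length >= min_bp & records$length <= max_bp
  list(kept = as_seq_records(records[ok, , drop = FALSE]),
       removed = as_seq_records(records[!ok, , drop = FALSE]))
}

#' Homopolymer filter
#'
#' Removes records containing a single-base run longer than `max_run`
#' (default: runs of 10 or more are removed).
#'
#' @param records a [seq_records()] table with sequences.
#' @param max_run longest tolerated homopolymer run.
#' @return list with `kept` and `removed` partitioning the input.
#' @export
filter_homopolymer <- function(records, max_run = 9L) {
  n <- max_run + 1L
  re <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}|N{%d}", n, n, n, n, n)
  bad <- grepl(re, records$seq)
  list(kept = as_seq_records(records[!bad, , drop = FALSE]),
       removed = as_seq_records(records[bad, , drop = FALSE]))
}

#' Order records for greedy clustering
#'
#' Greedy centroid clustering is order dependent, so genus-classified
#' records are placed first (longest first), followed by records whose
#' genus is `"unclassified"` (again longest first); this keeps
#' unclassified sequences from founding clusters whenever a classified
#' sequence could.  Length ties are broken by id for determinism.
#'
#' @param records a [seq_records()] table with a `genus` column.
#' @return the reordered records.
#' @export
sort_for_clustering <- function(records) {
  stopifnot("genus" %in% names(records))
  unclass_flag <- is.na(records$genus) | records$genus == "unclassified"
  ord <- order(unclass_flag, -records$length, records$id)
  as_seq_records(records[ord, , drop = FALSE])
}

cluster_match <- function(query, rep_seq, id_threshold, query_cov, target_cov) {
  al <- align_pair(query, rep_seq, mode = "local")
  cov_q <- (al$q_end - al$q_start + 1) / nchar(query)
  cov_t <- (al$t_end - al$t_start + 1) / nchar(rep_seq)
  al$identity / 100 >= id_threshold && cov_q >= query_cov && cov_t >= target_cov
}

#' Greedy centroid clustering
#'
#' Scans records in their given order; each record joins the first
#' existing cluster whose representative aligns at `id_threshold`
#' identity with aligned coverage of at least `query_cov` of the record
#' and `target_cov` of the representative, otherwise it founds a new
#' cluster with itself as representative.  With input ordered by
#' [sort_for_clustering()], representatives are the longest classified
#' members.
#'
#' @param records ordered [seq_records()] table with sequences.
#' @param id_threshold identity fraction (default 0.94).
#' @param query_cov,target_cov aligned-coverage fractions (default 0.9).
#' @return data.frame with columns `member_id` and `representative_id`
#'   (every input id appears exactly once).
#' @export
greedy_cluster <- function(records, id_threshold = 0.94,
                           query_cov = 0.9, target_cov = 0.9) {
  reps <- character(0)
  rep_seqs <- character(0)
  assign <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    q <- records$seq[i]
    hit <- NA_character_
    for (j in seq_along(reps)) {
      if (cluster_match(q, rep_seqs[j], id_threshold, query_cov, target_cov)) {
        hit <- reps[j]
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, records$id[i])
      rep_seqs <- c(rep_seqs, q)
      hit <- records$id[i]
    }
    assign[i] <- hit
  }
  data.frame(member_id = records$id, representative_id = assign,
             stringsAsFactors = FALSE)
}

#' Final representative filtering
#'
#' Drops cluster representatives flagged as chimeric by *both* the de
#' novo and reference chimera screens (flags are caller-supplied
#' annotations) and representatives whose genus is `"unclassified"`.
#' Classified, unflagged representatives are never removed.
#'
#' @param representatives data.frame with columns `id` and `genus`.
#' @param chimera_flags data.frame with columns `id`, `denovo`,
#'   `reference` (logical); flags for unknown ids raise a warning and
#'   are ignored.
#' @return list with `kept` (data.frame of surviving representatives),
#'   `removed` (data.frame `id`, `reason`), and `counts` (named vector:
#'   `chimera`, `unclassified`, `kept`).
#' @export
finalize_representatives <- function(representatives, chimera_flags = NULL) {
  stopifnot(all(c("id", "genus") %in% names(representatives)))
  chim <- rep(FALSE, nrow(representatives))
  if (!is.null(chimera_flags) && nrow(chimera_flags)) {
    unknown <- setdiff(chimera_flags$id, representatives$id)
    if (length(unknown)) {
      warning(sprintf("%d chimera flags for unknown ids ignored",
                      length(unknown)))
    }
    both <- chimera_flags$id[chimera_flags$denovo & chimera_flags$reference]
    chim <- representatives$id %in% both
  }
  unclass_flag <- is.na(representatives$genus) |
    representatives$genus == "unclassified"
  reason <- ifelse(chim, "chimera",
                   ifelse(unclass_flag, "unclassified", NA_character_))
  removed <- data.frame(id = representatives$id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  kept <- representatives[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed,
       counts = c(chimera = sum(reason == "chimera", na.rm = TRUE),
                  unclassified = sum(reason == "unclassified", na.rm = TRUE),
                  kept = nrow(kept)))
}

#' Subsample references for the phylum-level layout
#'
#' Draws up to `n_per_taxon` records uniformly without replacement from
#' every phylum; the (extraordinarily diverse) phylum Proteobacteria is
#' sampled per class instead.  Phyla with fewer records contribute all
#' of them.  Reproducible under `seed`.
#'
#' @param records a [seq_records()] table with `phylum` (and `class` for
#'   Proteobacteria) columns.
#' @param n_per_taxon sample size per phylum / Proteobacteria class.
#' @param seed integer seed.
#' @return the sampled records, with a `layout_group` column naming the
#'   phylum or Proteobacteria class each record was drawn for.
#' @export
subsample_for_phylum_layout <- function(records, n_per_taxon = 30L,
                                        seed = NULL) {
  stopifnot("phylum" %in% names(records))
  if (!is.null(seed)) set.seed(seed)
  grp <- ifelse(records$phylum == "Proteobacteria" & "class" %in% names(records),
                paste0("Proteobacteria/", records$class), records$phylum)
  idx <- unlist(lapply(split(seq_len(nrow(records)), grp), function(ii) {
    if (length(ii) <= n_per_taxon) ii else sort(sample(ii, n_per_taxon))
  }), use.names = FALSE)
  out <- records[sort(idx), , drop = FALSE]
  out$layout_group <- grp[sort(idx)]
  as_seq_records(out)
}

#' Run the full reference-curation pipeline
#'
#' Trim to anchors, filter by length and homopolymers, sort, cluster
#' greedily and finalize representatives, keeping an audit trail of
#' every removal.
#'
#' @param records raw annotated [seq_records()].
#' @param anchors [trim_anchors()].
#' @param chimera_flags see [finalize_representatives()].
#' @param min_bp,max_bp,max_run,id_threshold,query_cov,target_cov filter
#'   and clustering parameters.
#' @param guide optional trim guide sequence.
#' @return list with `db` (kept representative records), `clusters`
#'   (membership data.frame), `audit` (data.frame `id`, `stage`,
#'   `reason`) and `counts`.
#' @export
build_refdb <- function(records, anchors = trim_anchors(),
                        chimera_flags = NULL, guide = NULL,
                        min_bp = 1120L, max_bp = 1660L, max_run = 9L,
                        id_threshold = 0.94, query_cov = 0.9,
                        target_cov = 0.9) {
  audit <- data.frame(id = character(0), stage = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  trimmed <- trim_to_anchors(records, anchors, guide = guide)
  if (any(!trimmed$trimmed)) {
    audit <- rbind(audit, data.frame(id = trimmed$id[!trimmed$trimmed],
                                     stage = "trim", reason = "untrimmable"))
  }
  lf <- filter_by_length(trimmed, min_bp, max_bp)
  if (nrow(lf$removed)) {
    audit <- rbind(audit, data.frame(id = lf$removed$id, stage = "length",
                                     reason = "out_of_range"))
  }
  hf <- filter_homopolymer(lf$kept, max_run)
  if (nrow(hf$removed)) {
    audit <- rbind(audit, data.frame(id = hf$removed$id, stage = "homopolymer",
                                     reason = "long_run"))
  }
  ordered <- sort_for_clustering(hf$kept)
  clusters <- greedy_cluster(ordered, id_threshold, query_cov, target_cov)
  reps <- ordered[match(unique(clusters$representative_id), ordered$id), ,
                  drop = FALSE]
  fin <- finalize_representatives(reps[, c("id", "genus")], chimera_flags)
  if (nrow(fin$removed)) {
    audit <- rbind(audit, data.frame(id = fin$removed$id, stage = "finalize",
                                     reason = fin$removed$reason))
  }
  db <- ordered[match(fin$kept$id, ordered$id), , drop = FALSE]
  rownames(db) <- NULL
  list(db = as_seq_records(db), clusters = clusters, audit = audit,
       counts = fin$counts)
}
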