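#' Restrict a profile to confident assignments
#'
#' Drops assigned reads below the identity threshold (default 94) and
#' recomputes counts and relative abundances, so that sample
#' comparisons only use confident matches.
#'
#' @param profile a `genus_profile`.
#' @param min_identity identity threshold (percent).
#' @return a `genus_profile` (empty profiles are valid; comparisons on
#'   them are flagged `NA`).
#' @export
restrict_to_confident <- function(profile, min_identity = 94) {
  stopifnot(inherits(profile, "genus_profile"))
  a <- profile$assigned
  keep <- a$identity >= min_identity
  profile_from_assigned(a[keep, , drop = FALSE],
                        c(profile$unassigned_ids, a$read_id[!keep]),
                        profile$sample_id)
}

#' Jaccard similarity of two composition vectors
#'
#' Presence/absence overlap: shared labels with positive abundance over
#' labels present in either profile.  `NA` when both supports are
#' empty.
#'
#' @param a,b named numeric abundance vectors (any shared label
#'   universe; absent labels count as zero).
#' @return similarity in `[0, 1]`, or `NA`.
#' @export
jaccard_similarity <- function(a, b) {
  sa <- names(a)[a > 0]; sb <- names(b)[b > 0]
  u <- union(sa, sb)
  if (!length(u)) return(NA_real_)
  length(intersect(sa, sb)) / length(u)
}

#' Pearson correlation of two composition vectors
#'
#' Product-moment correlation on the union of labels (absent = 0).
#' `NA` when either vector has zero variance.
#'
#' @inheritParams jaccard_similarity
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_similarity <- function(a, b) {
  u <- union(names(a), names(b))
  if (length(u) < 2) return(NA_real_)   # correlation needs >= 2 labels
  va <- setNames(rep(0, length(u)), u); va[names(a)] <- a
  vb <- setNames(rep(0, length(u)), u); vb[names(b)] <- b
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Yue-Clayton theta similarity
#'
#' Abundance-weighted community overlap,
#' `theta = sum(p*q) / (sum(p^2) + sum(q^2) - sum(p*q))`, computed on
#' the union of labels.  Equals 1 iff the two (normalized) profiles are
#' identical and 0 for disjoint supports; `NA` when both profiles are
#' empty.
#'
#' @inheritParams jaccard_similarity
#' @return similarity in `[0, 1]`, or `NA`.
#' @export
yue_clayton_theta <- function(a, b) {
  u <- union(names(a), names(b))
  if (!length(u)) return(NA_real_)
  p <- setNames(rep(0, length(u)), u); p[names(a)] <- a
  q <- setNames(rep(0, length(u)), u); q[names(b)] <- b
  if (sum(p) <= 0 && sum(q) <= 0) return(NA_real_)
  if (sum(p) > 0) p <- p / sum(p)
  if (sum(q) > 0) q <- q / sum(q)
  pq <- sum(p * q)
  pq / (sum(p^2) + sum(q^2) - pq)
}

profile_abundances <- function(profile, level = c("cluster", "genus")) {
  level <- match.arg(level)
  a <- profile$assigned
  if (!nrow(a)) return(setNames(numeric(0), character(0)))
  if (level == "genus") {
    setNames(profile$genera$rel_abundance, profile$genera$genus)
  } else {
    tb <- table(a$ref_id)
    setNames(as.numeric(tb) / sum(tb), names(tb))
  }
}

#' Pairwise comparison of sample profiles
#'
#' Computes Jaccard, Pearson and Yue-Clayton theta matrices over all
#' sample pairs, at the reference-cluster level (default) or the genus
#' level.  Undefined pairs (empty profiles, zero variance) are `NA`,
#' never coerced to 0; diagonals are 1.
#'
#' @param profiles named list of `genus_profile` objects (>= 2).
#' @param level `"cluster"` (per-reference composition) or `"genus"`.
#' @param min_identity confidence threshold applied via
#'   [restrict_to_confident()] before comparing.
#' @return object of class `comparison_result`: list of three symmetric
#'   matrices `jaccard`, `pearson`, `theta`.
#' @export
compare_samples <- function(profiles, level = c("cluster", "genus"),
                            min_identity = 94) {
  level <- match.arg(level)
  stopifnot(length(profiles) >= 2)
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) p$sample_id, character(1))
  }
  vecs <- lapply(profiles, function(p) {
    profile_abundances(restrict_to_confident(p, min_identity), level)
  })
  n <- length(vecs)
  mk <- function() matrix(1, n, n, dimnames = list(ids, ids))
  J <- mk(); P <- mk(); Th <- mk()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      J[i, j] <- J[j, i] <- jaccard_similarity(vecs[[i]], vecs[[j]])
      P[i, j] <- P[j, i] <- pearson_similarity(vecs[[i]], vecs[[j]])
      Th[i, j] <- Th[j, i] <- yue_clayton_theta(vecs[[i]], vecs[[j]])
    }
  }
  structure(list(jaccard = J, pearson = P, theta = Th, level = level),
            class = "comparison_result")
}

#' Write a comparison result as long-format TSV
#'
#' Columns: `sample_a`, `sample_b`, `metric`, `value` (one row per
#' unordered pair and metric).
#'
#' @param cmp a `comparison_result`.
#' @param path file path.
#' @export
write_comparison_tsv <- function(cmp, path) {
  ids <- rownames(cmp$jaccard)
  rows <- list()
  for (metric in c("jaccard", "pearson", "theta")) {
    m <- cmp[[metric]]
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i < j) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_a = ids[i], sample_b = ids[j], metric = metric,
            value = m[i, j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  write_tsv(do.call(rbind, rows), path)
}
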