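#' Build a sequence record table
#'
#' The working unit of the reference-curation pipeline: a data.frame with
#' one row per sequence and columns `id`, `seq`, `length`, plus any
#' lineage ranks supplied.  `seq` may be `NA` when only lengths matter
#' (e.g. when auditing filter arithmetic on large id lists); `length`
#' then has to be given explicitly.
#'
#' @param ids character vector of unique ids.
#' @param seqs character vector of DNA strings, or `NULL`/`NA` when only
#'   lengths are tracked.
#' @param lengths integer lengths; derived from `seqs` when absent.
#' @param lineage optional data.frame keyed by `id` with rank columns
#'   (`domain` ... `genus`); merged onto the records.
#' @return data.frame of class `seq_records`.
#' @export
seq_records <- function(ids, seqs = NULL, lengths = NULL, lineage = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("record ids must be unique")
  if (is.null(seqs)) seqs <- rep(NA_character_, length(ids))
  seqs <- toupper(as.character(seqs))
  if (is.null(lengths)) {
    if (all(is.na(seqs))) stop("either seqs or lengths must be supplied")
    lengths <- nchar(seqs)
  }
  df <- data.frame(id = ids, seq = seqs, length = as.integer(lengths),
                   stringsAsFactors = FALSE)
  if (!is.null(lineage)) {
    keep <- setdiff(names(lineage), "id")
    df <- cbind(df, lineage[match(df$id, lineage$id), keep, drop = FALSE])
    rownames(df) <- NULL
  }
  class(df) <- c("seq_records", "data.frame")
  df
}

as_seq_records <- function(df) {
  stopifnot(all(c("id", "seq", "length") %in% names(df)))
  class(df) <- unique(c("seq_records", class(df)))
  rownames(df) <- NULL
  df
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d records, lengths %s-%s bp\n", nrow(x),
              if (nrow(x)) min(x$length) else "-",
              if (nrow(x)) max(x$length) else "-"))
  if (nrow(x)) print.data.frame(head(as.data.frame(x)[c("id", "length")], 5))
  invisible(x)
}
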