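#' Pairwise alignment with identity and coverage summaries
#'
#' Oracle-grade affine-gap dynamic-programming alignment (via
#' [Biostrings::pairwiseAlignment()]) shared by reference clustering,
#' species assignment and the verification of the seed-and-extend
#' search.  Identity is defined as matched columns over all aligned
#' columns (gap columns included); alignment length is that column
#' count.
#'
#' @param a,b DNA strings (a is the query/pattern, b the subject).
#' @param mode `"global"` (Needleman-Wunsch) or `"local"`
#'   (Smith-Waterman).
#' @param match,mismatch,gap_open,gap_ext scoring scheme; a gap of
#'   length L costs `gap_open + L * gap_ext`.
#' @return list with `identity` (percent), `aln_len` (aligned columns),
#'   `score`, and the 1-based aligned ranges `q_start`, `q_end`,
#'   `t_start`, `t_end` on the original sequences.
#' @export
align_pair <- function(a, b, mode = c("global", "local"),
                       match = 1, mismatch = -1, gap_open = 2, gap_ext = 1) {
  mode <- match.arg(mode)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = mode,
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_ext)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  matches <- Biostrings::nmatch(aln)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  list(identity = if (cols > 0) 100 * matches / cols else 0,
       aln_len = cols,
       score = Biostrings::score(aln),
       q_start = Biostrings::start(pat),
       q_end = Biostrings::end(pat),
       t_start = Biostrings::start(sub),
       t_end = Biostrings::end(sub))
}
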