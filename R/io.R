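#' Read sequences from FASTA or FASTQ
#'
#' Reads a FASTA or FASTQ file (format detected from the first character
#' unless given) into a named character vector of uppercase DNA strings.
#' FASTQ base qualities are ignored: every downstream step works on the
#' called bases only.
#'
#' @param path file path.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return named character vector of sequences; names are the full header
#'   lines (id plus any description).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readChar(path, 1L)
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Parse RDP-style lineage headers
#'
#' Splits FASTA headers of the form
#' `"id domain;phylum;class;order;family;genus"` into an id vector and a
#' lineage table.  Missing ranks are filled with `"unclassified"`.
#'
#' @param headers character vector of FASTA header lines (no `>`).
#' @return list with `ids` and `lineage` (data.frame with columns `id`,
#'   `domain`, `phylum`, `class`, `order`, `family`, `genus`).
#' @export
parse_lineage_headers <- function(headers) {
  ids <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(rest, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    length(p) <- 6L
    p[is.na(p)] <- "unclassified"
    p
  }, character(6)))
  lineage <- data.frame(id = ids, mat, stringsAsFactors = FALSE)
  names(lineage) <- c("id", ranks)
  list(ids = ids, lineage = lineage)
}

#' Read a reference FASTA with lineage annotations
#'
#' @param path FASTA path whose headers carry semicolon-delimited lineages
#'   after the first whitespace.
#' @return list with `seqs` (named character vector, names are bare ids)
#'   and `lineage` (data.frame, see [parse_lineage_headers()]).
#' @export
read_ref_fasta <- function(path) {
  raw <- read_sequences(path, format = "fasta")
  p <- parse_lineage_headers(names(raw))
  names(raw) <- p$ids
  list(seqs = raw, lineage = p$lineage)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write sequences to FASTQ with constant qualities
#'
#' Qualities carry no information in this toolkit; a constant high
#' quality (`I`) is emitted so the files stay valid FASTQ.
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep("I", nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# plain TSV helpers used by every module's file interface
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
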