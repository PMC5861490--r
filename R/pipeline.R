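#' Pipeline run configuration
#'
#' Thresholds and toggles for [run_pipeline()], validated and recorded
#' in every run manifest.
#'
#' @param min_identity search identity threshold (percent, default 80).
#' @param genus_identity genus-assignment threshold (default 94).
#' @param species_identity species-call threshold (default 97).
#' @param min_aln_len minimum alignment length (bp, default 100).
#' @param contig_min_len,contig_min_cov contig filters (800 bp / 10x).
#' @param k index word size.
#' @param seed integer seed recorded with the run.
#' @param normalize_cn toggle copy-number normalization.
#' @param reconstruct toggle 16S reconstruction.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_identity = 80, genus_identity = 94,
                       species_identity = 97, min_aln_len = 100,
                       contig_min_len = 800, contig_min_cov = 10,
                       k = 16L, seed = 1L, normalize_cn = FALSE,
                       reconstruct = FALSE) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            genus_identity >= min_identity, genus_identity <= 100,
            species_identity >= 0, species_identity <= 100,
            min_aln_len >= 1, contig_min_len >= 1, contig_min_cov >= 0,
            k >= 4)
  structure(list(min_identity = min_identity,
                 genus_identity = genus_identity,
                 species_identity = species_identity,
                 min_aln_len = min_aln_len,
                 contig_min_len = contig_min_len,
                 contig_min_cov = contig_min_cov,
                 k = as.integer(k), seed = as.integer(seed),
                 normalize_cn = isTRUE(normalize_cn),
                 reconstruct = isTRUE(reconstruct)),
            class = "run_config")
}

#' Run the classification workflow end to end
#'
#' Classify reads against the reference index, screen against the
#' negative (18S / mitochondrial) set, build the genus profile,
#' optionally normalize by inferred 16S copy number, optionally
#' reconstruct nearly full-length 16S contigs, and render the circular
#' diagram when a layout is supplied.  Outputs (hits TSV, profile
#' TSV(s), contig FASTA + species TSV, diagram SVG/JSON, JSON manifest)
#' are written under `out_dir` when given.  The run is a pure function
#' of its inputs and configuration: rerunning writes identical files.
#'
#' @param reads named character vector of reads (or a FASTA/FASTQ path).
#' @param index `kmer_index` of the curated reference database.
#' @param lineage_map reference lineage data.frame (`id`, ..., `genus`).
#' @param config a [run_config()].
#' @param negative_index optional `kmer_index` of the negative screen set.
#' @param cndb optional [copy_number_db()] (used when
#'   `config$normalize_cn`).
#' @param type_strains optional named vector of type-strain sequences
#'   (species calls during reconstruction).
#' @param layout optional layout data.frame (`id`, `angle`, `taxon`).
#' @param taxa optional taxon ring positions for the diagram.
#' @param sample_id sample label.
#' @param out_dir optional output directory.
#' @return list with `hits`, `screen`, `profile`, `profile_raw`,
#'   `contigs`, `diagram`, `manifest`.
#' @export
run_pipeline <- function(reads, index, lineage_map, config = run_config(),
                         negative_index = NULL, cndb = NULL,
                         type_strains = NULL, layout = NULL, taxa = NULL,
                         sample_id = "sample", out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_sequences(reads)
  }
  if (!length(reads)) warning("empty read set; outputs will be empty")

  hits <- classify_reads(reads, index, config$min_identity,
                         config$min_aln_len)
  screen <- if (!is.null(negative_index) && nrow(hits)) {
    negative_screen(reads[hits$query_id], negative_index,
                    config$min_identity, config$min_aln_len)
  } else list(excluded_ids = character(0),
              retained_ids = hits$query_id)
  kept_hits <- hits[hits$query_id %in% screen$retained_ids, , drop = FALSE]

  profile_raw <- assign_genus(kept_hits, lineage_map,
                              config$genus_identity, sample_id)
  profile <- profile_raw
  if (config$normalize_cn) {
    if (is.null(cndb)) stop("normalize_cn requires a copy-number database")
    cn <- infer_copy_number(reads[profile_raw$assigned$read_id], cndb,
                            config$min_identity, config$min_aln_len)
    profile <- normalize_profile(profile_raw,
                                 setNames(cn$copies, cn$id))
  }

  contigs <- NULL
  if (config$reconstruct && nrow(kept_hits)) {
    contigs <- reconstruct_16s(kept_hits, reads, type_strains,
                               min_len = config$contig_min_len,
                               min_cov = config$contig_min_cov,
                               species_identity = config$species_identity)
  }

  diagram <- if (!is.null(layout)) {
    build_diagram(profile, layout, taxa = taxa, level = "phylum")
  }

  manifest <- list(tool = "vitring",
                   version = as.character(utils::packageVersion("vitring")),
                   sample_id = sample_id, n_reads = length(reads),
                   n_hits = nrow(hits),
                   n_excluded = length(screen$excluded_ids),
                   config = unclass(config))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(hits, file.path(out_dir, "hits.tsv"))
    write_profile_tsv(profile, file.path(out_dir, "profile.tsv"))
    if (config$normalize_cn) {
      write_profile_tsv(profile_raw, file.path(out_dir, "profile_raw.tsv"))
    }
    if (!is.null(contigs) && nrow(contigs)) {
      cs <- setNames(contigs$seq,
                     sprintf("%s source_ref=%s length=%d coverage=%.1f",
                             contigs$contig_id, contigs$source_ref_id,
                             contigs$length, contigs$mean_coverage))
      write_fasta(cs, file.path(out_dir, "contigs.fasta"))
      if ("species" %in% names(contigs)) {
        write_tsv(contigs[, c("contig_id", "species", "species_identity")],
                  file.path(out_dir, "species.tsv"))
      }
    }
    if (!is.null(diagram)) {
      render_svg(diagram, file.path(out_dir, "diagram.svg"))
      render_json(diagram, file.path(out_dir, "diagram.json"))
    }
    manifest$input_md5 <- NULL
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  list(hits = hits, screen = screen, profile = profile,
       profile_raw = profile_raw, contigs = contigs, diagram = diagram,
       manifest = manifest)
}
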