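# shared fixture builders; everything is generated in code, no files

# six-leaf tree whose patristic distances from A order the other leaves
# C > B > F > E > D, i.e. the canonical worked example for the scan
fig_tree <- function() {
  ape::read.tree(text = "((A:1,D:1):1,(E:3,(F:3.5,(B:4,C:6):1):1):1);")
}

# n dissimilar random references of the given length
make_refs <- function(n, len = 1500, seed = 1, prefix = "ref") {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i) random_dna(len), ""),
           sprintf("%s%02d", prefix, seq_len(n)))
}

# substitute exactly n_mut positions of a DNA string
mutate_seq <- function(seq, n_mut) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# small mock community: n species on one simulated tree, distinct genera
small_community <- function(n = 10, copies = NULL, seed = 11,
                            error_rate = 0, mean_branch = 0.04) {
  set.seed(seed)
  tr <- simulate_tree(n, mean_branch = mean_branch)
  refs <- evolve_sequences(tr, core_length = 1400L)
  names(refs) <- sprintf("sp%02d", seq_len(n))
  if (is.null(copies)) copies <- rep(1L, n)
  mock_community(refs,
                 genus = sprintf("Genus%02d", seq_len(n)),
                 species = sprintf("Species%02d", seq_len(n)),
                 molarity = runif(n, 0.5, 2),
                 copy_number = copies,
                 error_rate = error_rate)
}

# lineage table for a community (one genus per reference)
community_lineage <- function(cm) {
  data.frame(id = names(cm$refs), genus = cm$genus,
             stringsAsFactors = FALSE)
}

# reads tiling a template end to end at roughly len/step-fold coverage
tiling_reads <- function(template, read_len = 150L, step = 12L) {
  L <- nchar(template)
  starts <- unique(c(seq(1L, L - read_len + 1L, by = step), L - read_len + 1L))
  setNames(substring(template, starts, starts + read_len - 1L),
           sprintf("tile%04d", seq_along(starts)))
}
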