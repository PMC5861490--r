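#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration via [ape::nj()]; negative
#' branch-length estimates are clamped to zero.  Additive matrices are
#' recovered exactly (patristic distances reproduce the input).
#'
#' @param dm symmetric distance matrix with dimnames.
#' @return an [ape::phylo] tree (unrooted for n >= 3; a two-leaf cherry
#'   for n == 2).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 labels")
  if (n == 2) {
    h <- dm[1, 2] / 2
    txt <- sprintf("(%s:%g,%s:%g);", rownames(dm)[1], h, rownames(dm)[2], h)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# tip index sets for every node of a phylo tree (1..Ntip are the tips)
node_tip_sets <- function(tr) {
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  # edges in postorder so children are resolved before parents
  eo <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    par <- eo[k, 1]; child <- eo[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

#' Linearize a tree by topology scanning
#'
#' Orders the leaves of a phylogenetic tree into the one-dimensional
#' sequence used for the circular diagram.  Starting from
#' `initial_id`, the most distant leaf is found; the next leaf is the
#' most distant one within the smallest ancestral clade of the
#' last-chosen leaf that still contains unordered leaves, and so on.
#' The resulting far-to-near list is reversed and prefixed with the
#' initial leaf, so the order runs from the initial sequence outward to
#' its most distant relative.
#'
#' @param tree an [ape::phylo] tree whose tips include `initial_id`.
#' @param dist distance matrix over the tip labels used for the
#'   "most distant" comparisons (typically the K2P matrix the tree was
#'   built from).  Set `use_tree_dist = TRUE` to use patristic distances
#'   from the tree instead.
#' @param initial_id the starting leaf.
#' @param use_tree_dist use cophenetic tree distances instead of `dist`.
#' @return object of class `circular_order`: list with `ordered_ids`,
#'   `gaps` (distance between consecutive leaves, length n-1) and
#'   `closing_gap` (distance from the last leaf back to the first).
#' @export
tree_topology_scan <- function(tree, dist = NULL, initial_id,
                               use_tree_dist = FALSE) {
  tips <- tree$tip.label
  if (!initial_id %in% tips) stop("initial_id is not a leaf of the tree")
  if (use_tree_dist || is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  dist <- as.matrix(dist)
  stopifnot(all(tips %in% rownames(dist)))
  if (length(tips) == 1) stop("tree has a single leaf")

  rooted <- ape::root(tree, outgroup = initial_id, resolve.root = TRUE)
  tips <- rooted$tip.label
  ntip <- length(tips)
  sets <- node_tip_sets(rooted)
  parent <- integer(ntip + rooted$Nnode)
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  root_node <- ntip + 1L

  d0 <- dist[initial_id, tips]
  pick_far <- function(cand) {       # farthest from initial, ties by id
    dd <- d0[cand]
    cand[order(-dd, cand)][1]
  }

  remaining <- setdiff(tips, initial_id)
  emitted <- character(0)
  last <- pick_far(remaining)
  emitted <- last
  remaining <- setdiff(remaining, last)
  while (length(remaining)) {
    node <- parent[match(last, tips)]
    repeat {
      cand <- intersect(tips[sets[[node]]], remaining)
      if (length(cand)) break
      if (node == root_node) break
      node <- parent[node]
    }
    if (!length(cand)) cand <- remaining   # defensive; root covers all
    last <- pick_far(cand)
    emitted <- c(emitted, last)
    remaining <- setdiff(remaining, last)
  }

  ordered <- c(initial_id, rev(emitted))
  gaps <- if (length(ordered) > 1) {
    vapply(seq_len(length(ordered) - 1),
           function(i) dist[ordered[i], ordered[i + 1]], numeric(1))
  } else numeric(0)
  structure(list(ordered_ids = ordered, gaps = gaps,
                 closing_gap = dist[ordered[length(ordered)], ordered[1]]),
            class = "circular_order")
}

#' Angles on the circle from a leaf ordering
#'
#' The first leaf sits at angle 0; each subsequent leaf advances by its
#' gap to the previous leaf as a fraction of the total circumference
#' (sum of all gaps plus the closing last-to-first gap, so the ring
#' closes).  When every gap is zero the leaves are spaced uniformly.
#'
#' @param order a `circular_order` from [tree_topology_scan()].
#' @return data.frame with columns `id` and `angle` (radians in
#'   `[0, 2*pi)`, strictly increasing for positive gaps).
#' @export
circular_positions <- function(order) {
  stopifnot(inherits(order, "circular_order"))
  n <- length(order$ordered_ids)
  total <- sum(order$gaps) + order$closing_gap
  if (total <= 0) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
  } else {
    ang <- 2 * pi * cumsum(c(0, order$gaps)) / total
  }
  data.frame(id = order$ordered_ids, angle = ang, stringsAsFactors = FALSE)
}

circular_mean <- function(angles) {
  s <- sum(sin(angles)); c <- sum(cos(angles))
  if (sqrt(s^2 + c^2) < 1e-12) return(min(angles))  # degenerate: antipodal
  a <- (atan2(s, c) + 2 * pi) %% (2 * pi)
  if (2 * pi - a < 1e-9) a <- 0                     # snap 2*pi - eps to 0
  a
}

#' Average circular position per taxon
#'
#' Places each taxon at the circular mean (direction of the summed unit
#' vectors) of its members' angles; wraparound across 0 is handled
#' correctly and single-member taxa get their member's angle.
#'
#' @param positions data.frame `id`, `angle` from
#'   [circular_positions()].
#' @param taxon_map named character vector mapping leaf id to taxon
#'   label (e.g. phylum/class or genus).
#' @return data.frame with columns `taxon` and `angle`.
#' @export
taxon_positions <- function(positions, taxon_map) {
  tax <- taxon_map[positions$id]
  if (anyNA(tax)) stop("every leaf needs a taxon label")
  sp <- split(positions$angle, tax)
  data.frame(taxon = names(sp),
             angle = vapply(sp, circular_mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a circular layout as JSON
#'
#' @param positions data.frame `id`, `angle`.
#' @param taxon_map optional named vector mapping id to taxon.
#' @param path output file.
#' @export
write_layout_json <- function(positions, taxon_map = NULL, path) {
  df <- positions
  df$taxon <- if (is.null(taxon_map)) NA_character_ else
    unname(taxon_map[df$id])
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a circular layout from JSON
#'
#' @param path JSON file written by [write_layout_json()].
#' @return data.frame with `id`, `angle` and `taxon` columns.
#' @export
read_layout_json <- function(path) {
  jsonlite::fromJSON(path)
}
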