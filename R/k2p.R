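#' Kimura two-parameter distance between aligned sequences
#'
#' Columns where either sequence carries a gap (`-`, `.`) or an
#' ambiguous base are excluded.  With P the transition and Q the
#' transversion fraction over the included columns, the distance is
#' `-1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.  Saturated pairs (log
#' argument not positive) return `NA`; [build_distance_matrix()]
#' replaces them with a finite sentinel.
#'
#' @param a,b equal-length aligned DNA strings.
#' @return numeric distance (substitutions per site), or `NA` when
#'   saturated.
#' @export
k2p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("sequences must be aligned (equal length)")
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  if (n == 0) return(NA_real_)
  diff <- ca != cb
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- diff & (purine[ca] == purine[cb])
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' All-pairs K2P distance matrix from a multiple alignment
#'
#' Pairwise-deletion K2P distances for every pair of aligned sequences.
#' Saturated pairs are replaced by 1.5 times the largest finite distance
#' in the matrix and recorded in the `saturated` attribute.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences.
#' @return symmetric numeric matrix with zero diagonal and the input
#'   names as dimnames; attribute `saturated` lists replaced pairs
#'   (two-column character matrix, possibly empty).
#' @export
build_distance_matrix <- function(alignment) {
  n <- length(alignment)
  ids <- names(alignment)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(character(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- k2p_distance(alignment[[i]], alignment[[j]])
      if (is.na(dij)) {
        sat <- rbind(sat, c(ids[i], ids[j]))
        dij <- NA_real_
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- 1.5 * mx
    diag(d) <- 0
  }
  attr(d, "saturated") <- sat
  d
}
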