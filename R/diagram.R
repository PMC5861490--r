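#' Build a circular diagram specification
#'
#' Turns a profile and a circular layout into a renderable diagram:
#' each reference cluster with at least one assigned read becomes a dot
#' at its layout angle, with dot *area* proportional to the cluster's
#' share of assigned reads (clamped to a visible range) and radial
#' position encoding the best top-hit identity of the cluster in
#' discrete bands (100, >= 97, >= 94, >= 90, >= 80 percent).  Taxon
#' ring labels are drawn at the average circular positions.  Clusters
#' missing from the layout are collected into an "unplaced" sector and
#' reported with a warning.
#'
#' @param profile a `genus_profile`.
#' @param layout data.frame with `id`, `angle` (and optionally `taxon`)
#'   from [circular_positions()] / [read_layout_json()].
#' @param taxa optional data.frame `taxon`, `angle` from
#'   [taxon_positions()] for the ring annotations.
#' @param level `"phylum"` or `"genus"`, recorded on the spec.
#' @param min_area,max_area dot area clamp (square pixels).
#' @return object of class `diagram_spec`: list with `level`, `points`
#'   (data.frame `label`, `angle`, `band`, `area`, `read_count`,
#'   `unplaced`), `taxa`, `total_reads`.
#' @export
build_diagram <- function(profile, layout, taxa = NULL,
                          level = c("phylum", "genus"),
                          min_area = 4, max_area = 400) {
  level <- match.arg(level)
  a <- profile$assigned
  if (nrow(a)) {
    counts <- table(a$ref_id)
    topid <- vapply(split(a$identity, a$ref_id), max, numeric(1))
    ids <- names(counts)
    band <- cut(topid[ids], breaks = c(80, 90, 94, 97, 100 - 1e-9, Inf),
                labels = c(">=80", ">=90", ">=94", ">=97", "100"),
                right = FALSE, include.lowest = TRUE)
    angle <- layout$angle[match(ids, layout$id)]
    unplaced <- is.na(angle)
    if (any(unplaced)) {
      warning(sprintf("%d clusters missing from the layout placed in the unplaced sector",
                      sum(unplaced)))
      # park unplaced dots on a small dedicated arc just before angle 0
      angle[unplaced] <- 2 * pi - 0.2 +
        0.2 * (seq_len(sum(unplaced)) - 1) / max(1, sum(unplaced))
    }
    share <- as.numeric(counts) / sum(counts)
    area <- pmin(max_area, pmax(min_area, max_area * share))
    points <- data.frame(label = ids, angle = angle,
                         band = as.character(band), area = area,
                         read_count = as.integer(counts),
                         unplaced = unplaced, stringsAsFactors = FALSE)
    points <- points[order(points$label), ]
    rownames(points) <- NULL
  } else {
    points <- data.frame(label = character(0), angle = numeric(0),
                         band = character(0), area = numeric(0),
                         read_count = integer(0), unplaced = logical(0),
                         stringsAsFactors = FALSE)
  }
  structure(list(level = level, points = points, taxa = taxa,
                 total_reads = nrow(a)), class = "diagram_spec")
}

band_radius <- function(band, r_outer) {
  # discrete radial bands, best identity outermost
  fr <- c("100" = 1.00, ">=97" = 0.92, ">=94" = 0.84, ">=90" = 0.76,
          ">=80" = 0.68)
  r_outer * unname(fr[band])
}

fmt <- function(x) formatC(x, format = "f", digits = 3)

#' Render a diagram specification to SVG
#'
#' Deterministic, byte-stable SVG 1.1 output: the same spec always
#' renders to identical bytes.
#'
#' @param spec a `diagram_spec`.
#' @param path output file.
#' @param size canvas edge in pixels.
#' @export
render_svg <- function(spec, path, size = 600) {
  cx <- size / 2; cy <- size / 2; r_outer <- size * 0.42
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
            as.integer(size), as.integer(size)),
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#888" stroke-width="1"/>',
            fmt(cx), fmt(cy), fmt(r_outer))
  )
  pts <- spec$points
  if (nrow(pts)) {
    r <- band_radius(pts$band, r_outer)
    x <- cx + r * sin(pts$angle)
    y <- cy - r * cos(pts$angle)
    dot_r <- sqrt(pts$area / pi)
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="#3366cc" fill-opacity="0.6"><title>%s (%d reads)</title></circle>',
      fmt(x), fmt(y), fmt(dot_r), pts$label, pts$read_count))
  }
  if (!is.null(spec$taxa) && nrow(spec$taxa)) {
    tx <- cx + (r_outer + 16) * sin(spec$taxa$angle)
    ty <- cy - (r_outer + 16) * cos(spec$taxa$angle)
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
      fmt(tx), fmt(ty), spec$taxa$taxon))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Render a diagram specification to JSON
#'
#' @param spec a `diagram_spec`.
#' @param path output file.
#' @export
render_json <- function(spec, path) {
  obj <- list(format = "vitring-diagram", version = 1L, level = spec$level,
              total_reads = spec$total_reads, points = spec$points,
              taxa = spec$taxa)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a diagram specification back from JSON
#'
#' @param path JSON file written by [render_json()].
#' @return a `diagram_spec`.
#' @export
read_diagram_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "vitring-diagram")) {
    stop("not a vitring diagram file")
  }
  pts <- obj$points
  if (is.null(pts) || !length(pts)) {
    pts <- data.frame(label = character(0), angle = numeric(0),
                      band = character(0), area = numeric(0),
                      read_count = integer(0), unplaced = logical(0),
                      stringsAsFactors = FALSE)
  }
  structure(list(level = obj$level, points = pts, taxa = obj$taxa,
                 total_reads = obj$total_reads), class = "diagram_spec")
}
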