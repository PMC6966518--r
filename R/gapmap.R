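#' Build a gap-map for one aligned sequence
#'
#' A gap-map is a bidirectional index between a sequence's own residue
#' numbering (1-based, gaps skipped) and alignment columns. It is the
#' coordinate-liftover core: positions predicted on one orthologue are
#' translated residue -> column -> reference residue, so homologous sites can
#' be compared across species in the reference's coordinates.
#'
#' Gap characters are \code{"-"} and \code{"."}; any other non-letter
#' character is rejected. An all-gap row is legal and yields a map with zero
#' mapped residues.
#'
#' @param row Aligned sequence: a single string possibly containing gaps.
#' @param id Sequence identifier carried along in the map (optional).
#' @return An object of class \code{gapmap}: list with \code{id},
#'   \code{res2col} (strictly increasing integer vector, residue index ->
#'   alignment column), \code{col2res} (integer vector over columns,
#'   \code{NA} at gap columns), \code{residues} (ungapped residue characters)
#'   and \code{aln_length}.
#' @examples
#' m <- build_gapmap("AC-GT")
#' seq_to_aln(m, 3)   # residue 3 (G) sits in column 4
#' aln_to_seq(m, 3)   # column 3 is a gap: NA
#' @export
build_gapmap <- function(row, id = NULL) {
  if (!is.character(row) || length(row) != 1L || is.na(row) || !nzchar(row)) {
    gm_stop("aligned row must be a non-empty string", "validation")
  }
  row <- toupper(chartr(".", "-", row))
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(LETTERS, "-"))
  if (any(bad)) {
    gm_stop(sprintf("invalid character '%s' at column %d",
                    chars[which(bad)[1L]], which(bad)[1L]), "validation")
  }
  nongap <- which(chars != "-")
  col2res <- rep(NA_integer_, length(chars))
  col2res[nongap] <- seq_along(nongap)
  structure(list(id = id, res2col = nongap, col2res = col2res,
                 residues = chars[nongap], aln_length = length(chars)),
            class = "gapmap")
}

#' @export
print.gapmap <- function(x, ...) {
  cat(sprintf("gapmap%s: %d residues over %d alignment columns\n",
              if (!is.null(x$id)) paste0(" [", x$id, "]") else "",
              length(x$res2col), x$aln_length))
  invisible(x)
}

#' Translate residue positions to alignment columns
#'
#' @param map A \code{gapmap}.
#' @param pos Residue positions (1-based); every position must lie within
#'   the sequence's ungapped length.
#' @return Integer alignment columns, same length as \code{pos}.
#' @export
seq_to_aln <- function(map, pos) {
  stopifnot(inherits(map, "gapmap"))
  if (length(pos) == 0L) return(integer(0))
  if (!is.numeric(pos) || anyNA(pos) || any(pos != trunc(pos)) ||
      any(pos < 1L) || any(pos > length(map$res2col))) {
    gm_stop(sprintf("residue position out of range 1..%d",
                    length(map$res2col)), "coordinate")
  }
  map$res2col[as.integer(pos)]
}

#' Translate alignment columns to residue positions
#'
#' Returns \code{NA} for a column at which this sequence is gapped — a
#' deliberate, explicit "undefined" rather than the nearest residue, since
#' nearest-neighbour mapping would fabricate homology.
#'
#' @param map A \code{gapmap}.
#' @param column Alignment columns (1-based, within the alignment length).
#' @return Integer residue positions, \code{NA} at gap columns.
#' @export
aln_to_seq <- function(map, column) {
  stopifnot(inherits(map, "gapmap"))
  if (length(column) == 0L) return(integer(0))
  if (!is.numeric(column) || anyNA(column) || any(column != trunc(column)) ||
      any(column < 1L) || any(column > map$aln_length)) {
    gm_stop(sprintf("alignment column out of range 1..%d", map$aln_length),
            "coordinate")
  }
  map$col2res[as.integer(column)]
}

#' Lift a residue position from one orthologue onto a reference
#'
#' Composes \code{\link{seq_to_aln}} on the orthologue with
#' \code{\link{aln_to_seq}} on the reference. \code{NA} is returned where the
#' reference is gapped at the homologous column (the site is unmappable).
#'
#' @param pos Residue positions in the orthologue.
#' @param map Gap-map of the orthologue carrying the site.
#' @param ref_map Gap-map of the reference sequence (same alignment).
#' @return Integer reference residue positions (\code{NA} when unmappable).
#' @export
liftover_site <- function(pos, map, ref_map) {
  stopifnot(inherits(map, "gapmap"), inherits(ref_map, "gapmap"))
  if (map$aln_length != ref_map$aln_length) {
    gm_stop("gap-maps come from alignments of different lengths", "config")
  }
  cols <- seq_to_aln(map, pos)
  ref_map$col2res[cols]
}

#' Tabulate liftovers of many site positions onto a reference
#'
#' @param sites Data frame with columns \code{id} and \code{position}
#'   (residue coordinates in each orthologue), e.g. site predictions from
#'   \code{\link{load_site_predictions}}.
#' @param gapmaps Named list of \code{gapmap}s covering every id.
#' @param reference_id Name of the reference sequence within \code{gapmaps}.
#' @param path Optional TSV output path.
#' @return Data frame (id, position, column, ref_pos); \code{ref_pos} is
#'   \code{NA} where the reference is gapped. Written as TSV if \code{path}
#'   is given.
#' @export
liftover_table <- function(sites, gapmaps, reference_id, path = NULL) {
  stopifnot(is.data.frame(sites), all(c("id", "position") %in% names(sites)))
  if (!reference_id %in% names(gapmaps)) {
    gm_stop(sprintf("reference '%s' has no gap-map", reference_id), "config")
  }
  missing <- setdiff(unique(sites$id), names(gapmaps))
  if (length(missing)) {
    gm_stop(paste("no gap-map for sequence(s):",
                  paste(missing, collapse = ", ")), "config")
  }
  refmap <- gapmaps[[reference_id]]
  column <- vapply(seq_len(nrow(sites)), function(i) {
    seq_to_aln(gapmaps[[sites$id[i]]], sites$position[i])
  }, integer(1))
  out <- data.frame(id = sites$id, position = sites$position,
                    column = column, ref_pos = refmap$col2res[column],
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    lines <- c("id\tposition\tcolumn\tref_pos",
               sprintf("%s\t%d\t%d\t%s", out$id, out$position, out$column,
                       ifelse(is.na(out$ref_pos), "NA", out$ref_pos)))
    gm_write_lines(lines, path)
  }
  out
}
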