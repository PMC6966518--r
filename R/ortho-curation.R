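#' Keep the longest isoform per gene
#'
#' Orthologue sets retrieved from sequence databases usually carry several
#' isoforms per gene record; downstream scoring wants exactly one protein per
#' gene. This keeps, for each gene, the record with the greatest ungapped
#' length. Length ties are broken deterministically towards the
#' lexicographically smallest accession.
#'
#' @param records Data frame of protein records (see \code{\link{read_fasta}}).
#' @param gene_id Either the name of a column in \code{records} holding gene
#'   identifiers, or a character vector of gene ids parallel to the records.
#'   Defaults to a \code{gene_id} column if present.
#' @return The subset of \code{records} with one row per gene, ordered by
#'   gene id.
#' @export
select_longest_per_gene <- function(records, gene_id = NULL) {
  stopifnot(is.data.frame(records))
  gid <- if (is.null(gene_id)) {
    records[["gene_id"]]
  } else if (length(gene_id) == 1L && gene_id %in% names(records)) {
    records[[gene_id]]
  } else {
    gene_id
  }
  if (is.null(gid) || length(gid) != nrow(records) || anyNA(gid) ||
      any(!nzchar(gid))) {
    gm_stop("every record needs a non-missing gene_id", "validation")
  }
  len <- nchar(gsub("-", "", records$sequence, fixed = TRUE))
  keep <- vapply(split(seq_len(nrow(records)), gid), function(ix) {
    best <- ix[len[ix] == max(len[ix])]
    best[order(records$id[best])][1L]
  }, integer(1))
  out <- records[keep[order(names(keep))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter aligned orthologues by N-terminal alignment quality
#'
#' Applies the two membership rules used before scoring secretion signals
#' over a trimmed alignment block: a row is removed if (a) it has a gap
#' within the first \code{window} alignment columns after its own first
#' residue (an internal N-terminal gap), or (b) its first non-gap column
#' diverges from the modal (consensus) first non-gap column by more than
#' \code{start_tol} columns (leading gaps are judged by this start rule,
#' not the gap rule). Rows whose ungapped length is
#' shorter than the window are removed as \code{short-sequence}, since the
#' gap rule is undefined for them. The input is taken as an already trimmed
#' alignment; the window is counted in alignment columns.
#'
#' @param records Data frame of aligned records; all sequences must have the
#'   same alignment length.
#' @param window Number of leading alignment columns inspected for gaps
#'   (default 15).
#' @param start_tol Allowed deviation, in columns, of a row's first non-gap
#'   column from the modal start (default 0: strict agreement).
#' @return An object of class \code{curation_report}: a list with
#'   \code{retained} (ids), \code{removed} (data frame of id and reason,
#'   one of \code{gap-in-window}, \code{divergent-start},
#'   \code{short-sequence}), \code{records} (the retained rows),
#'   \code{modal_start}, \code{window} and \code{start_tol}. Retained and
#'   removed ids always partition the input.
#' @examples
#' aln <- data.frame(id = c("a", "b", "c"),
#'                   sequence = c("MKLVILSECK", "MK-VILSECK", "MKLVILSECK"))
#' filter_alignment_members(aln, window = 5)
#' @export
filter_alignment_members <- function(records, window = 15L, start_tol = 0L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (!gm_is_count(window)) gm_stop("window must be a positive integer", "parameter")
  n <- nrow(records)
  alen <- unique(nchar(records$sequence))
  if (length(alen) > 1L) {
    gm_stop("ragged alignment: sequences have differing lengths", "format")
  }
  seqs <- chartr(".", "-", toupper(records$sequence))
  ungapped <- nchar(gsub("-", "", seqs, fixed = TRUE))
  weff <- min(window, if (length(alen)) alen else window)
  first_col <- regexpr("[^-]", seqs)
  first_col[first_col < 0L] <- NA_integer_
  # gap rule looks at gaps after the row's own start: leading gaps are the
  # divergent-start rule's concern, internal gaps in the window are this one's
  has_gap <- !is.na(first_col) & first_col <= weff &
    grepl("-", substr(seqs, first_col, weff), fixed = TRUE)

  # modal first non-gap column over all rows with a defined start;
  # ties broken towards the smallest column index
  fc <- first_col[!is.na(first_col)]
  modal <- if (length(fc)) {
    tab <- table(fc)
    as.integer(names(tab)[which.max(tab)])  # which.max takes first = smallest
  } else {
    NA_integer_
  }

  reason <- rep(NA_character_, n)
  reason[is.na(first_col) | ungapped < window] <- "short-sequence"
  reason[is.na(reason) & has_gap] <- "gap-in-window"
  divergent <- !is.na(first_col) & abs(first_col - modal) > start_tol
  reason[is.na(reason) & divergent] <- "divergent-start"

  removed <- data.frame(id = records$id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(retained = kept$id, removed = removed, records = kept,
                 modal_start = modal, window = as.integer(window),
                 start_tol = as.integer(start_tol)),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Alignment curation report\n")
  cat(sprintf("  retained: %d   removed: %d   (window = %d, modal start = column %s)\n",
              length(x$retained), nrow(x$removed), x$window, x$modal_start))
  if (nrow(x$removed)) {
    tab <- table(x$removed$reason)
    for (r in names(tab)) cat(sprintf("    %-16s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Export a curation report as TSV
#'
#' One row per input sequence with columns \code{id}, \code{status}
#' (\code{retained}/\code{removed}) and \code{reason}.
#'
#' @param report A \code{curation_report}.
#' @param path Output file, or \code{NULL} to return the TSV text.
#' @export
write_curation_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "curation_report"))
  df <- rbind(
    data.frame(id = report$retained, status = "retained", reason = "",
               stringsAsFactors = FALSE),
    data.frame(id = report$removed$id, status = "removed",
               reason = report$removed$reason, stringsAsFactors = FALSE)
  )
  lines <- c("id\tstatus\treason",
             sprintf("%s\t%s\t%s", df$id, df$status, df$reason))
  gm_write_lines(lines, path)
}
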