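#' Read a (possibly aligned) protein FASTA file
#'
#' Parses plain or gapped FASTA into a data frame of protein records.
#' Sequences are upper-cased; the alternative gap character \code{"."} is
#' normalised to \code{"-"} so aligned FASTA from different aligners can be
#' mixed. Gap columns are preserved verbatim, which is what the gap-map
#' machinery (\code{\link{build_gapmap}}) relies on.
#'
#' @param x A file path, or FASTA text (a single string with newlines or a
#'   character vector of lines).
#' @return A data frame with columns \code{id} (first header token),
#'   \code{description} (remainder of the header, possibly \code{""}) and
#'   \code{sequence}.
#' @seealso \code{\link{write_fasta}} for the inverse; the pair round-trips
#'   id, description and sequence losslessly.
#' @examples
#' recs <- read_fasta(">a ref\nPKSPV-Y\n>b\nPKS-VQY\n")
#' recs$sequence
#' @export
read_fasta <- function(x) {
  lines <- gm_read_lines(x)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) gm_stop("empty FASTA input", "format")
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    gm_stop(sprintf("line %d: expected FASTA header starting with '>'",
                    nonblank[1L]), "format")
  }
  is_hdr <- startsWith(lines, ">")
  hdr <- which(is_hdr)
  for (h in hdr) {
    if (trimws(lines[h]) == ">") {
      gm_stop(sprintf("line %d: malformed FASTA header (no identifier)", h),
              "format")
    }
    upto <- c(hdr, length(lines) + 1L)
    nxt <- min(upto[upto > h])
    body <- lines[seq.int(h + 1L, length.out = nxt - h - 1L)]
    if (!any(nzchar(trimws(body)))) {
      gm_stop(sprintf("line %d: record '%s' has an empty sequence",
                      h, sub("^>\\s*", "", lines[h])), "format")
    }
  }
  # normalise before parsing so '.' gaps and lower case survive validation
  lines[!is_hdr] <- toupper(chartr(".", "-", lines[!is_hdr]))
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  aas <- Biostrings::readAAStringSet(tf)
  nm <- names(aas)
  id <- sub("\\s.*$", "", nm)
  description <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  data.frame(id = id, description = description,
             sequence = as.character(aas),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write protein records as FASTA
#'
#' @param records Data frame with columns \code{id}, \code{sequence} and
#'   optionally \code{description}.
#' @param path Output file; if \code{NULL} the FASTA text is returned as a
#'   single string.
#' @param width Sequence line width (default 60).
#' @return Invisibly the path, or the FASTA text when \code{path = NULL}.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  desc <- ifelse(is.na(desc), "", desc)
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$id[i],
                  if (nzchar(desc[i])) paste0(" ", desc[i]) else "")
    s <- records$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    out <- c(out, hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  gm_write_lines(out, path)
}
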