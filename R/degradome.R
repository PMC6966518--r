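#' Parameters for TAILS degradome filtering
#'
#' @param ratio_threshold Heavy:light enrichment cut-off; peptides must
#'   exceed it strictly (default 3).
#' @param gelA_residues P1' residues characteristic of gelatinase A
#'   cleavage, one-letter (default Ile, Leu, Val).
#' @param category_rules Named character vector of case-insensitive keywords
#'   matched against the protein description; the first matching rule names
#'   the category (default: \code{myosin} for descriptions containing
#'   "myosin"). Non-matching records fall into \code{"other"}.
#' @param normalization \code{"none"} (ratios taken as already normalized)
#'   or \code{"median-center"} (log2 ratios median-centred before
#'   filtering, for raw tables).
#' @return A list of class \code{degradome_params}.
#' @export
degradome_params <- function(ratio_threshold = 3,
                             gelA_residues = c("I", "L", "V"),
                             category_rules = c(myosin = "myosin"),
                             normalization = c("none", "median-center")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(ratio_threshold) || length(ratio_threshold) != 1L ||
      ratio_threshold <= 0) {
    gm_stop("ratio_threshold must be a positive number", "parameter")
  }
  if (!all(gelA_residues %in% AA20)) {
    gm_stop("gelA_residues must be one-letter codes of the 20 standard residues",
            "parameter")
  }
  if (length(category_rules) && is.null(names(category_rules))) {
    gm_stop("category_rules must be a named vector (category = keyword)",
            "parameter")
  }
  structure(list(ratio_threshold = ratio_threshold,
                 gelA_residues = gelA_residues,
                 category_rules = category_rules,
                 normalization = normalization),
            class = "degradome_params")
}

#' Parse a TAILS peptide quantification table
#'
#' Tab-separated with a header naming at least \code{peptide},
#' \code{protein_description} and \code{hl_ratio} (\code{#} comment lines
#' ignored). Rows with an empty peptide, a non-amino-acid character, or a
#' non-numeric or non-positive ratio are skipped with a warning and listed
#' in the \code{"rejected"} attribute.
#'
#' @param x File path, TSV text, or a data frame with the columns above.
#' @return Validated data frame of peptide records.
#' @export
parse_peptide_table <- function(x) {
  if (is.data.frame(x)) {
    need <- c("peptide", "protein_description", "hl_ratio")
    if (!all(need %in% names(x))) {
      gm_stop(paste("peptide table must have columns:",
                    paste(need, collapse = ", ")), "format")
    }
    df <- x[, need]
    df$hl_ratio <- suppressWarnings(as.numeric(df$hl_ratio))
    lineno <- seq_len(nrow(df))
  } else {
    dl <- gm_data_lines(gm_read_lines(x))
    if (length(dl$lines) == 0L) gm_stop("empty peptide table", "format")
    fields <- strsplit(dl$lines, "\t", fixed = TRUE)
    hdr <- trimws(fields[[1L]])
    need <- c("peptide", "protein_description", "hl_ratio")
    if (!all(need %in% hdr)) {
      gm_stop(paste("peptide table must have columns:",
                    paste(need, collapse = ", ")), "format")
    }
    rows <- fields[-1L]
    get <- function(r, col) {
      i <- match(col, hdr)
      if (i > length(r)) NA_character_ else trimws(r[[i]])
    }
    df <- data.frame(
      peptide = vapply(rows, get, "", col = "peptide"),
      protein_description = vapply(rows, get, "", col = "protein_description"),
      hl_ratio = suppressWarnings(as.numeric(vapply(rows, get, "", col = "hl_ratio"))),
      stringsAsFactors = FALSE)
    lineno <- if (length(rows)) dl$lineno[-1L] else integer(0)
  }
  reason <- rep(NA_character_, nrow(df))
  pep <- toupper(df$peptide)
  bad_pep <- is.na(pep) | !nzchar(pep) |
    !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), pep)
  reason[bad_pep] <- "invalid-peptide"
  bad_ratio <- is.na(df$hl_ratio) | df$hl_ratio <= 0
  reason[is.na(reason) & bad_ratio] <- "invalid-ratio"
  ok <- is.na(reason)
  rejected <- data.frame(row = lineno[!ok], reason = reason[!ok],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("skipped %d invalid peptide row(s): %s", nrow(rejected),
                    paste(unique(rejected$reason), collapse = ", ")),
            call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  out$peptide <- toupper(out$peptide)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write peptide records in the degradome TSV dialect
#'
#' @param records Data frame with columns peptide, protein_description,
#'   hl_ratio.
#' @param path Output file, or \code{NULL} to return the text.
#' @export
write_peptide_table <- function(records, path = NULL) {
  lines <- c("peptide\tprotein_description\thl_ratio",
             sprintf("%s\t%s\t%s", records$peptide,
                     records$protein_description,
                     format(records$hl_ratio, digits = 8, trim = TRUE,
                            scientific = FALSE)))
  gm_write_lines(lines, path)
}

#' Keep peptides strictly above the enrichment threshold
#'
#' @param records Peptide records.
#' @param params \code{\link{degradome_params}}.
#' @return The records with \code{hl_ratio} strictly greater than the
#'   threshold, input order preserved. A ratio exactly at the threshold is
#'   dropped.
#' @export
filter_enriched <- function(records, params = degradome_params()) {
  stopifnot(is.data.frame(records), inherits(params, "degradome_params"))
  out <- records[records$hl_ratio > params$ratio_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' P1' residue of a neo-N-terminal peptide
#'
#' In a labelled neo-N-terminus the first residue of the peptide is the
#' residue immediately C-terminal to the cleaved bond, i.e. the protease's
#' P1' position.
#'
#' @param peptide Character vector of peptide sequences (or a peptide
#'   record data frame).
#' @return One-letter P1' residues.
#' @examples
#' p1_prime("IEELEEELEAER")  # "I"
#' @export
p1_prime <- function(peptide) {
  if (is.data.frame(peptide)) peptide <- peptide$peptide
  if (!is.character(peptide) || any(is.na(peptide)) || any(!nzchar(peptide))) {
    gm_stop("peptides must be non-empty sequences", "validation")
  }
  toupper(substr(peptide, 1L, 1L))
}

#' Is a P1' residue characteristic of gelatinase A cleavage?
#'
#' @param residue One-letter residues.
#' @param params \code{\link{degradome_params}} (defines the residue set,
#'   by default Ile/Leu/Val).
#' @return Logical vector.
#' @export
classify_gelA_like <- function(residue, params = degradome_params()) {
  residue <- toupper(residue)
  if (!all(residue %in% AA20)) {
    gm_stop("residues must be one-letter codes of the 20 standard residues",
            "validation")
  }
  residue %in% params$gelA_residues
}

# first matching category rule, else "other"
categorize_description <- function(description, rules) {
  out <- rep("other", length(description))
  if (length(rules) == 0L) return(out)
  lower <- tolower(description)
  for (cat in rev(names(rules))) {  # first rule wins on overlap
    out[grepl(tolower(rules[[cat]]), lower, fixed = TRUE)] <- cat
  }
  out
}

#' Summarize a TAILS degradome table
#'
#' Applies (optional) normalization and the strict enrichment filter, then
#' annotates passing peptides with their P1' residue, gelatinase A-likeness
#' and protein category, and tallies the results. Percentages are rounded
#' half-to-even to integer percent (so 12/49 = 24.49\% reports as 24\%).
#' When no peptide passes the filter, fractions are reported as \code{NA}
#' ("undefined"), never as zero.
#'
#' @param records Peptide records (see \code{\link{parse_peptide_table}}).
#' @param params \code{\link{degradome_params}}.
#' @return An object of class \code{degradome_summary}: list with
#'   \code{total}, \code{n_passing}, \code{categories} (category, count,
#'   fraction, percent among passing), \code{p1_counts} (named counts over
#'   P1' residues of passing peptides), \code{n_gelA_like},
#'   \code{gelA_by_category}, \code{passing} (annotated table with columns
#'   \code{p1_prime}, \code{gelA_like}, \code{category}) and \code{params}.
#' @export
summarize_degradome <- function(records, params = degradome_params()) {
  stopifnot(is.data.frame(records), inherits(params, "degradome_params"))
  ratio <- records$hl_ratio
  if (params$normalization == "median-center" && nrow(records)) {
    ratio <- 2^(log2(ratio) - median(log2(ratio)))
  }
  adj <- records
  adj$hl_ratio <- ratio
  passing <- filter_enriched(adj, params)
  if (nrow(passing)) {
    passing$p1_prime <- p1_prime(passing$peptide)
    passing$gelA_like <- classify_gelA_like(passing$p1_prime, params)
    passing$category <- categorize_description(passing$protein_description,
                                               params$category_rules)
  } else {
    passing$p1_prime <- character(0)
    passing$gelA_like <- logical(0)
    passing$category <- character(0)
  }
  n_pass <- nrow(passing)
  cats <- c(names(params$category_rules), "other")
  cat_count <- vapply(cats, function(ct) sum(passing$category == ct), integer(1))
  frac <- if (n_pass > 0) cat_count / n_pass else rep(NA_real_, length(cats))
  categories <- data.frame(category = cats, count = cat_count,
                           fraction = frac,
                           percent = ifelse(is.na(frac), NA_real_,
                                            round(100 * frac)),
                           row.names = NULL, stringsAsFactors = FALSE)
  p1_counts <- if (n_pass > 0) {
    tab <- table(factor(passing$p1_prime, levels = AA20))
    setNames(as.integer(tab), AA20)
  } else {
    setNames(integer(length(AA20)), AA20)
  }
  gelA_by_category <- vapply(cats, function(ct) {
    sum(passing$gelA_like & passing$category == ct)
  }, integer(1))
  structure(list(total = nrow(records), n_passing = n_pass,
                 categories = categories, p1_counts = p1_counts,
                 n_gelA_like = sum(passing$gelA_like),
                 gelA_by_category = gelA_by_category,
                 passing = passing, params = params),
            class = "degradome_summary")
}

#' @export
print.degradome_summary <- function(x, ...) {
  cat(sprintf("TAILS degradome summary: %d peptides, %d with H/L ratio > %g\n",
              x$total, x$n_passing, x$params$ratio_threshold))
  if (x$n_passing == 0L) {
    cat("  no peptides pass the enrichment filter; fractions undefined\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$categories))) {
    with(x$categories[i, ], cat(sprintf(
      "  %-10s %3d / %d passing (%s%%)\n", category, count, x$n_passing,
      ifelse(is.na(percent), "NA", percent))))
  }
  cat(sprintf("  gelatinase A-like P1' (%s): %d of %d passing\n",
              paste(x$params$gelA_residues, collapse = "/"),
              x$n_gelA_like, x$n_passing))
  invisible(x)
}

#' Export a degradome summary as JSON and the passing table as TSV
#'
#' With normalization \code{"none"} the JSON is a pure, byte-stable function
#' of the input table.
#'
#' @param x A \code{degradome_summary}.
#' @param json,tsv Optional output paths.
#' @return Invisibly a list with the JSON text and TSV text.
#' @export
write_degradome_summary <- function(x, json = NULL, tsv = NULL) {
  stopifnot(inherits(x, "degradome_summary"))
  obj <- list(total = x$total, n_passing = x$n_passing,
              categories = x$categories,
              p1_counts = as.list(x$p1_counts[x$p1_counts > 0]),
              n_gelA_like = x$n_gelA_like,
              gelA_by_category = as.list(x$gelA_by_category),
              ratio_threshold = x$params$ratio_threshold,
              normalization = x$params$normalization)
  json_txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                            digits = NA, na = "null"))
  if (!is.null(json)) writeLines(json_txt, json)
  p <- x$passing
  lines <- c("peptide\tprotein_description\thl_ratio\tp1_prime\tgelA_like\tcategory",
             if (nrow(p)) sprintf("%s\t%s\t%s\t%s\t%s\t%s", p$peptide,
                                  p$protein_description,
                                  format(p$hl_ratio, digits = 8, trim = TRUE,
                                         scientific = FALSE),
                                  p$p1_prime, p$gelA_like, p$category))
  tsv_txt <- gm_write_lines(lines, tsv)
  invisible(list(json = json_txt, tsv = tsv_txt))
}
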