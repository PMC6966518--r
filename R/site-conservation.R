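#' Parameters for conservation tiering of predicted phosphosites
#'
#' @param score_threshold Minimum predictor score; the comparison is strict
#'   (a site must score \emph{higher than} the threshold). Default 0.65.
#' @param tier_fractions Named, strictly decreasing conservation fractions in
#'   (0, 1]; the comparison is inclusive (\emph{at least} that fraction of
#'   orthologues). Defaults to the 100\%/99\%/97\% bands.
#' @param residue_match \code{"exact"}: a call supports a reference position
#'   only when its residue equals the reference residue there (a serine call
#'   supports only a serine site). \code{"acceptor-class"}: any
#'   phospho-acceptor (S/T/Y) call at the homologous column counts.
#' @return A list of class \code{conservation_params}.
#' @export
conservation_params <- function(score_threshold = 0.65,
                                tier_fractions = c("100%" = 1.00,
                                                   "99%" = 0.99,
                                                   "97%" = 0.97),
                                residue_match = c("exact", "acceptor-class")) {
  residue_match <- match.arg(residue_match)
  if (!is.numeric(score_threshold) || length(score_threshold) != 1L ||
      score_threshold <= 0 || score_threshold >= 1) {
    gm_stop("score_threshold must lie in (0, 1)", "parameter")
  }
  if (!is.numeric(tier_fractions) || any(tier_fractions <= 0) ||
      any(tier_fractions > 1) || is.unsorted(rev(tier_fractions), strictly = TRUE)) {
    gm_stop("tier_fractions must be strictly decreasing values in (0, 1]",
            "parameter")
  }
  if (is.null(names(tier_fractions))) {
    names(tier_fractions) <- paste0(format(100 * tier_fractions), "%")
  }
  structure(list(score_threshold = score_threshold,
                 tier_fractions = tier_fractions,
                 residue_match = residue_match),
            class = "conservation_params")
}

#' Load per-orthologue phosphosite predictions
#'
#' Reads a NetPhos-style tab-separated table (columns \code{id},
#' \code{position}, \code{residue}, \code{score}, optional \code{kinase};
#' \code{#} comment lines ignored) and validates every row against the
#' sequences: the residue claimed at a position must actually be there, the
#' residue must be a phospho-acceptor (S/T/Y) and the score must lie in
#' [0, 1]. Invalid rows are skipped with a warning, not fatal — predictor
#' exports routinely contain a few stale coordinates.
#'
#' @param x File path, TSV text, or a data frame with the columns above.
#' @param sequences Named character vector of sequences the ids resolve to;
#'   aligned sequences are accepted (gaps are ignored for validation).
#' @return Data frame of validated site calls with an attribute
#'   \code{"rejected"} (data frame of row, id, reason) listing skipped rows.
#' @export
load_site_predictions <- function(x, sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  degapped <- gsub("[-.]", "", toupper(sequences))
  if (is.data.frame(x)) {
    df <- x
    lineno <- seq_len(nrow(df))
  } else {
    dl <- gm_data_lines(gm_read_lines(x))
    if (length(dl$lines) == 0L) {
      return(empty_site_calls())
    }
    fields <- strsplit(dl$lines, "\t", fixed = TRUE)
    hdr <- trimws(fields[[1L]])
    need <- c("id", "position", "residue", "score")
    if (!all(need %in% hdr)) {
      gm_stop(paste("site table must have columns:", paste(need, collapse = ", ")),
              "format")
    }
    rows <- fields[-1L]
    if (length(rows) == 0L) return(empty_site_calls())
    get <- function(r, col) {
      i <- match(col, hdr)
      if (is.na(i) || i > length(r)) NA_character_ else trimws(r[[i]])
    }
    df <- data.frame(
      id = vapply(rows, get, "", col = "id"),
      position = suppressWarnings(as.numeric(vapply(rows, get, "", col = "position"))),
      residue = vapply(rows, get, "", col = "residue"),
      score = suppressWarnings(as.numeric(vapply(rows, get, "", col = "score"))),
      kinase = if ("kinase" %in% hdr) vapply(rows, get, "", col = "kinase") else NA_character_,
      stringsAsFactors = FALSE)
    lineno <- dl$lineno[-1L]
  }
  if (!"kinase" %in% names(df)) df$kinase <- NA_character_

  reason <- rep(NA_character_, nrow(df))
  known <- df$id %in% names(degapped)
  reason[!known] <- "unknown-sequence"
  bad_pos <- is.na(df$position) | df$position != trunc(df$position) |
    df$position < 1
  reason[is.na(reason) & bad_pos] <- "bad-position"
  bad_res <- !(df$residue %in% c("S", "T", "Y"))
  reason[is.na(reason) & bad_res] <- "not-an-acceptor"
  bad_score <- is.na(df$score) | df$score < 0 | df$score > 1
  reason[is.na(reason) & bad_score] <- "score-out-of-range"
  ok <- is.na(reason)
  # residue consistency against the actual sequence
  if (any(ok)) {
    ix <- which(ok)
    inlen <- df$position[ix] <= nchar(degapped[df$id[ix]])
    reason[ix[!inlen]] <- "position-beyond-sequence"
    ix <- ix[inlen]
    at <- substr(degapped[df$id[ix]], df$position[ix], df$position[ix])
    mism <- at != df$residue[ix]
    reason[ix[mism]] <- "residue-mismatch"
  }
  ok <- is.na(reason)
  rejected <- data.frame(row = lineno[!ok], id = df$id[!ok],
                         reason = reason[!ok], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("skipped %d invalid site prediction row(s): %s",
                    nrow(rejected),
                    paste(unique(rejected$reason), collapse = ", ")),
            call. = FALSE)
  }
  out <- df[ok, c("id", "position", "residue", "score", "kinase"), drop = FALSE]
  out$position <- as.integer(out$position)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

empty_site_calls <- function() {
  out <- data.frame(id = character(0), position = integer(0),
                    residue = character(0), score = numeric(0),
                    kinase = character(0), stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(row = integer(0), id = character(0),
                                      reason = character(0))
  out
}

#' Write site predictions in the NetPhos-like TSV dialect
#'
#' @param calls Data frame with columns id, position, residue, score and
#'   optionally kinase.
#' @param path Output file, or \code{NULL} to return the text.
#' @export
write_site_predictions <- function(calls, path = NULL) {
  kin <- if ("kinase" %in% names(calls)) calls$kinase else NA_character_
  kin <- ifelse(is.na(kin), "unsp", kin)
  lines <- c("id\tposition\tresidue\tscore\tkinase",
             sprintf("%s\t%d\t%s\t%s\t%s", calls$id,
                     as.integer(calls$position), calls$residue,
                     format(calls$score, digits = 6, trim = TRUE,
                            scientific = FALSE), kin))
  gm_write_lines(lines, path)
}

#' Smallest count meeting a conservation fraction
#'
#' The smallest integer \code{c} with \code{c / n >= fraction}; e.g. "at
#' least 97\% of 208 sequences" means 202 of them.
#'
#' @param n Number of sequences (>= 1).
#' @param fraction Required fraction in (0, 1].
#' @return Integer count.
#' @examples
#' min_count_for_fraction(208, 0.97)  # 202
#' @export
min_count_for_fraction <- function(n, fraction) {
  if (!gm_is_count(n)) gm_stop("n must be a positive integer", "parameter")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    gm_stop("fraction must lie in (0, 1]", "parameter")
  }
  cnt <- as.integer(ceiling(n * fraction))
  # guard the exact-boundary cases against floating-point round-off
  while (cnt > 1L && (cnt - 1L) / n >= fraction) cnt <- cnt - 1L
  while (cnt / n < fraction) cnt <- cnt + 1L
  cnt
}

#' Reference domain architecture of gelatinase A
#'
#' The canonical domain intervals used to annotate conserved sites, in
#' 1-based closed reference coordinates: signal peptide 1-29, propeptide
#' 30-107, catalytic domain 118-446, hemopexin-like domain 463-657. The
#' stretches 108-117 and 447-462 (and anything beyond) are inter-domain.
#'
#' @return Data frame with columns \code{domain}, \code{start}, \code{end}.
#' @export
gelA_domains <- function() {
  data.frame(domain = c("signal", "propeptide", "catalytic", "hemopexin"),
             start = c(1L, 30L, 118L, 463L),
             end = c(29L, 107L, 446L, 657L),
             stringsAsFactors = FALSE)
}

#' Annotate reference positions with their protein domain
#'
#' @param pos Reference residue positions (1-based).
#' @param domains Domain table as returned by \code{\link{gelA_domains}}.
#' @return Character vector of domain labels; \code{"inter-domain"} for
#'   positions outside every interval.
#' @export
annotate_domains <- function(pos, domains = gelA_domains()) {
  if (!is.numeric(pos) || any(pos < 1)) {
    gm_stop("positions must be >= 1", "validation")
  }
  out <- rep("inter-domain", length(pos))
  for (i in seq_len(nrow(domains))) {
    hit <- pos >= domains$start[i] & pos <= domains$end[i]
    out[hit] <- domains$domain[i]
  }
  out
}

# assign each count its highest tier (first tier whose minimum count is met)
assign_tiers <- function(counts, n, tier_fractions) {
  mins <- vapply(tier_fractions, min_count_for_fraction, integer(1), n = n)
  labels <- names(tier_fractions)
  vapply(counts, function(cnt) {
    hit <- which(cnt >= mins)
    if (length(hit)) labels[hit[1L]] else "below"
  }, character(1))
}

#' Tier conserved sites by the fraction of supporting orthologues
#'
#' Reports both cumulative counts per threshold (how many sites are
#' conserved in at least 100\%, at least 99\%, ...) and disjoint bands (how
#' many sites fall in each tier and no higher one).
#'
#' @param x A \code{conserved_sites} data frame (from
#'   \code{\link{conservation_tally}}) or a numeric vector of supporting
#'   counts.
#' @param n Number of orthologues in the family.
#' @param params \code{\link{conservation_params}}.
#' @return List with \code{tier} (label per site), \code{min_counts},
#'   \code{cumulative} and \code{bands} (named integer vectors).
#' @export
tier_sites <- function(x, n, params = conservation_params()) {
  counts <- if (is.data.frame(x)) x$count else x
  if (any(counts > n)) gm_stop("site counts exceed family size", "validation")
  tf <- params$tier_fractions
  mins <- vapply(tf, min_count_for_fraction, integer(1), n = n)
  tier <- assign_tiers(counts, n, tf)
  cumulative <- vapply(mins, function(m) sum(counts >= m), integer(1))
  bands <- vapply(c(names(tf), "below"), function(lb) sum(tier == lb), integer(1))
  list(tier = tier, min_counts = mins, cumulative = cumulative, bands = bands)
}

#' Tally cross-species conservation of predicted sites on a reference
#'
#' The central computation: every site call scoring strictly above the
#' threshold is lifted through its orthologue's gap-map into alignment
#' columns and back into reference coordinates; a reference position is
#' supported by an orthologue if at least one of its calls lands there with
#' a residue satisfying the residue-match mode. Orthologues are counted
#' once per position regardless of how many calls they contribute; the
#' reference's own calls count like any other orthologue's. Calls that land
#' on a gap in the reference are unmappable and are excluded (recorded in
#' the \code{"unmappable"} attribute).
#'
#' @param calls Validated site calls (see \code{\link{load_site_predictions}}).
#' @param gapmaps Named list of \code{gapmap}s, one per orthologue in the
#'   family (the family size is \code{length(gapmaps)}).
#' @param reference_id Name of the reference sequence in \code{gapmaps}.
#' @param params \code{\link{conservation_params}}.
#' @param domains Domain annotation table (see \code{\link{gelA_domains}}).
#' @return A data frame of class \code{conserved_sites} with columns
#'   \code{ref_pos}, \code{residue} (reference residue), \code{count},
#'   \code{fraction}, \code{tier}, \code{domain} and \code{supporting}
#'   (comma-separated orthologue ids), sorted by reference position.
#'   Attributes: \code{n_orthologues}, \code{params}, \code{tiers} (the
#'   \code{\link{tier_sites}} report) and \code{unmappable}.
#' @export
conservation_tally <- function(calls, gapmaps, reference_id,
                               params = conservation_params(),
                               domains = gelA_domains()) {
  stopifnot(is.data.frame(calls), inherits(params, "conservation_params"))
  if (is.null(names(gapmaps)) ||
      !all(vapply(gapmaps, inherits, logical(1), what = "gapmap"))) {
    gm_stop("gapmaps must be a named list of gapmap objects", "config")
  }
  if (!reference_id %in% names(gapmaps)) {
    gm_stop(sprintf("reference '%s' has no gap-map", reference_id), "config")
  }
  missing <- setdiff(unique(calls$id), names(gapmaps))
  if (length(missing)) {
    gm_stop(paste("no gap-map for sequence(s):",
                  paste(missing, collapse = ", ")), "config")
  }
  refmap <- gapmaps[[reference_id]]
  n_orth <- length(gapmaps)

  kc <- calls[calls$score > params$score_threshold, , drop = FALSE]
  if (nrow(kc)) {
    column <- vapply(seq_len(nrow(kc)), function(i) {
      seq_to_aln(gapmaps[[kc$id[i]]], kc$position[i])
    }, integer(1))
    ref_pos <- refmap$col2res[column]
  } else {
    column <- integer(0)
    ref_pos <- integer(0)
  }
  unmappable <- kc[is.na(ref_pos), , drop = FALSE]
  mapped <- kc[!is.na(ref_pos), , drop = FALSE]
  mapped$ref_pos <- ref_pos[!is.na(ref_pos)]

  if (nrow(mapped) && params$residue_match == "exact") {
    refres <- refmap$residues[mapped$ref_pos]
    mapped <- mapped[mapped$residue == refres, , drop = FALSE]
  }

  if (nrow(mapped)) {
    by_pos <- split(mapped$id, mapped$ref_pos)
    supp <- lapply(by_pos, function(ids) sort(unique(ids)))
    pos <- as.integer(names(by_pos))
    ord <- order(pos)
    pos <- pos[ord]
    supp <- supp[ord]
    count <- lengths(supp)
  } else {
    pos <- integer(0)
    supp <- list()
    count <- integer(0)
  }
  tiers <- tier_sites(count, n_orth, params)
  out <- data.frame(
    ref_pos = pos,
    residue = if (length(pos)) refmap$residues[pos] else character(0),
    count = as.integer(count),
    fraction = if (length(pos)) count / n_orth else numeric(0),
    tier = tiers$tier,
    domain = annotate_domains(if (length(pos)) pos else numeric(0), domains),
    supporting = vapply(supp, paste, "", collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out,
            class = c("conserved_sites", "data.frame"),
            n_orthologues = n_orth, params = params, tiers = tiers,
            unmappable = unmappable)
}

#' Export conserved sites as TSV
#'
#' @param sites A \code{conserved_sites} data frame.
#' @param path Output file, or \code{NULL} to return the text.
#' @export
write_conserved_sites <- function(sites, path = NULL) {
  lines <- c("ref_pos\tresidue\tcount\tfraction\ttier\tdomain\tsupporting",
             sprintf("%d\t%s\t%d\t%s\t%s\t%s\t%s",
                     sites$ref_pos, sites$residue, sites$count,
                     format(sites$fraction, digits = 6, trim = TRUE),
                     sites$tier, sites$domain, sites$supporting))
  gm_write_lines(lines, path)
}
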