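#' Parse a SignalP-4.1-style summary table
#'
#' Reads the whitespace-delimited per-protein summary dialect (one line per
#' protein: \code{name Cmax pos Ymax pos Smean D}; \code{#} comment lines
#' ignored). Scores are validated to [0, 1]. The protein family label used
#' for the cross-family comparison is taken from the name by stripping a
#' trailing \code{_<number>} suffix (the convention the synthetic generator
#' emits, e.g. \code{MMP2_017} -> \code{MMP2}), unless supplied explicitly.
#'
#' @param x File path or summary text.
#' @param family Optional family label(s), recycled across records; if
#'   \code{NULL} the label is derived from the protein name.
#' @return Data frame with columns \code{name}, \code{family}, \code{cmax},
#'   \code{cpos}, \code{ymax}, \code{ypos}, \code{smean}, \code{d}.
#' @export
parse_signalp_summary <- function(x, family = NULL) {
  dl <- gm_data_lines(gm_read_lines(x))
  if (length(dl$lines) == 0L) {
    return(data.frame(name = character(0), family = character(0),
                      cmax = numeric(0), cpos = integer(0),
                      ymax = numeric(0), ypos = integer(0),
                      smean = numeric(0), d = numeric(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(dl$lines), "\\s+")
  parse_row <- function(i) {
    f <- fields[[i]]
    if (length(f) != 7L) {
      gm_stop(sprintf("line %d: expected 7 whitespace-delimited fields, got %d",
                      dl$lineno[i], length(f)), "format")
    }
    num <- suppressWarnings(as.numeric(f[2:7]))
    if (anyNA(num)) {
      gm_stop(sprintf("line %d: non-numeric score field", dl$lineno[i]),
              "format")
    }
    scores <- num[c(1L, 3L, 5L, 6L)]  # Cmax, Ymax, Smean, D
    if (any(scores < 0 | scores > 1)) {
      gm_stop(sprintf("line %d: score outside [0, 1]", dl$lineno[i]), "format")
    }
    if (any(num[c(2L, 4L)] < 1 | num[c(2L, 4L)] != trunc(num[c(2L, 4L)]))) {
      gm_stop(sprintf("line %d: cleavage position must be a positive integer",
                      dl$lineno[i]), "format")
    }
    list(name = f[1L], cmax = num[1L], cpos = as.integer(num[2L]),
         ymax = num[3L], ypos = as.integer(num[4L]),
         smean = num[5L], d = num[6L])
  }
  rows <- lapply(seq_along(fields), parse_row)
  name <- vapply(rows, `[[`, "", "name")
  fam <- if (is.null(family)) sub("_[0-9]+$", "", name) else
    rep_len(as.character(family), length(name))
  data.frame(name = name, family = fam,
             cmax = vapply(rows, `[[`, 0, "cmax"),
             cpos = vapply(rows, `[[`, 0L, "cpos"),
             ymax = vapply(rows, `[[`, 0, "ymax"),
             ypos = vapply(rows, `[[`, 0L, "ypos"),
             smean = vapply(rows, `[[`, 0, "smean"),
             d = vapply(rows, `[[`, 0, "d"),
             stringsAsFactors = FALSE)
}

#' Write records in the SignalP-4.1-style summary dialect
#'
#' @param records Data frame as returned by \code{\link{parse_signalp_summary}}
#'   or \code{\link{simulate_signal_scores}}.
#' @param path Output file, or \code{NULL} to return the text.
#' @export
write_signalp_summary <- function(records, path = NULL) {
  fmt <- function(v) format(round(v, 3), nsmall = 3, trim = TRUE)
  lines <- c("# SignalP-4.1-like summary (gelmap dialect)",
             "# name Cmax pos Ymax pos Smean D",
             sprintf("%s  %s %2d  %s %2d  %s  %s",
                     records$name, fmt(records$cmax), records$cpos,
                     fmt(records$ymax), records$ypos,
                     fmt(records$smean), fmt(records$d)))
  gm_write_lines(lines, path)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Computes the U statistic from its definition (number of pairs where an
#' observation of \code{a} exceeds one of \code{b}, ties counting one half).
#' When both samples have at most eight observations (or the pooled sample
#' at most ten) the two-sided p-value is obtained by exhaustive enumeration
#' of all assignments of the pooled values (exact even under ties);
#' otherwise the normal approximation with continuity correction and the
#' tie-corrected variance is used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest per-sample size for which the exact enumeration
#'   is used (default 8).
#' @return An object of class \code{htest} with \code{statistic} (U for
#'   \code{a}) and \code{p.value}.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p.value  # exact 0.1
#' @export
rank_sum_test <- function(a, b, exact_max = 8L) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) == 0L || length(b) == 0L ||
      anyNA(a) || anyNA(b)) {
    gm_stop("both samples must be non-empty numeric vectors without NA",
            "validation")
  }
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))  # midranks under ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if ((na <= exact_max && nb <= exact_max) || N <= 10L) {
    idx <- combn(N, na)
    rsums <- colSums(matrix(r[idx], nrow = na))
    Uperm <- rsums - na * (na + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    method <- "Mann-Whitney rank-sum test (exact enumeration)"
  } else {
    tie <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "Mann-Whitney rank-sum test (normal approximation, tie- and continuity-corrected)"
  }
  structure(list(statistic = c(U = U), p.value = p, method = method,
                 alternative = "two.sided",
                 data.name = sprintf("a (n = %d) vs b (n = %d)", na, nb)),
            class = "htest")
}

#' Holm step-down adjustment of p-values
#'
#' Thin wrapper over \code{stats::p.adjust(method = "holm")} with input
#' validation; kept as a named operation so the multiplicity control used by
#' \code{\link{family_comparison}} is explicit and swappable.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    gm_stop("p-values must be numeric in [0, 1]", "validation")
  }
  p.adjust(p, method = "holm")
}

#' Compact letter display from a significance matrix
#'
#' Implements the insert-and-absorb algorithm: starting from one group
#' containing every family, each significantly different pair splits any
#' group containing both, and groups contained in another are absorbed.
#' The result satisfies the two display axioms — families \emph{not}
#' significantly different share at least one letter, and significantly
#' different families share none. Letters are assigned in first-use order
#' over the input family order.
#'
#' @param signif Symmetric logical matrix (\code{TRUE} = significantly
#'   different) with \code{FALSE} diagonal; dimnames label the families.
#' @return Named character vector of letter strings, one per family.
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' m[1, 3] <- m[3, 1] <- TRUE
#' compact_letter_display(m)  # "a", "ab", "b"
#' @export
compact_letter_display <- function(signif) {
  if (!is.matrix(signif) || !is.logical(signif) ||
      nrow(signif) != ncol(signif)) {
    gm_stop("significance matrix must be a square logical matrix", "validation")
  }
  if (!identical(signif, t(signif))) {
    gm_stop("significance matrix must be symmetric", "validation")
  }
  if (any(diag(signif))) {
    gm_stop("diagonal must be FALSE (a family is not different from itself)",
            "validation")
  }
  k <- nrow(signif)
  fams <- rownames(signif)
  if (is.null(fams)) fams <- as.character(seq_len(k))

  groups <- list(seq_len(k))
  absorb <- function(gs) {
    gs <- unique(lapply(gs, sort))
    keep <- rep(TRUE, length(gs))
    for (i in seq_along(gs)) {
      for (j in seq_along(gs)) {
        if (i != j && keep[j] && all(gs[[i]] %in% gs[[j]])) keep[i] <- FALSE
      }
    }
    gs[keep]
  }
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (!signif[i, j]) next
      hit <- vapply(groups, function(g) i %in% g && j %in% g, logical(1))
      if (!any(hit)) next
      split_off <- unlist(lapply(groups[hit], function(g) {
        list(setdiff(g, i), setdiff(g, j))
      }), recursive = FALSE)
      groups <- absorb(c(groups[!hit], split_off))
    }
  }
  # letters in first-use order over the family order
  lettered <- character(0)
  order_of <- integer(0)
  for (f in seq_len(k)) {
    for (g in seq_along(groups)) {
      if (f %in% groups[[g]] && !(g %in% order_of)) {
        order_of <- c(order_of, g)
      }
    }
  }
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lab <- setNames(letter_pool[seq_along(order_of)], order_of)
  out <- vapply(seq_len(k), function(f) {
    gs <- which(vapply(groups, function(g) f %in% g, logical(1)))
    paste(sort(lab[as.character(gs)]), collapse = "")
  }, character(1))
  setNames(out, fams)
}

#' Compare secretion-signal score distributions across protein families
#'
#' Per-family summary statistics plus all pairwise two-sided rank-sum tests
#' on a score column (S-mean by default), Holm-adjusted, with letter groups
#' from \code{\link{compact_letter_display}}. Families sharing a letter are
#' statistically indistinguishable at level \code{alpha}. If a reference
#' family is named (e.g. an efficiently secreted control such as
#' vitronectin), each family is additionally flagged as indistinguishable
#' from it (shares a letter with it) or not.
#'
#' @param records Data frame with columns \code{family} and the score column.
#' @param alpha Significance level for the adjusted pairwise tests
#'   (default 0.05).
#' @param reference_family Optional family name used for the
#'   indistinguishable-from-reference flag.
#' @param value Name of the score column (default \code{"smean"}).
#' @return An object of class \code{family_comparison}: list with
#'   \code{summary} (family, n, mean, median, q1, q3, letters, and
#'   \code{like_reference} if requested), \code{p_raw} and \code{p_adj}
#'   (symmetric matrices with unit diagonal), \code{signif}, \code{alpha}.
#'   Families with fewer than two observations are excluded with a warning.
#' @export
family_comparison <- function(records, alpha = 0.05, reference_family = NULL,
                              value = "smean") {
  stopifnot(is.data.frame(records), "family" %in% names(records),
            value %in% names(records))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    gm_stop("alpha must lie in (0, 1)", "parameter")
  }
  scores <- split(records[[value]], records$family)
  small <- names(scores)[lengths(scores) < 2L]
  if (length(small)) {
    warning(sprintf("excluding family(ies) with n < 2: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    scores <- scores[!(names(scores) %in% small)]
  }
  if (length(scores) < 2L) {
    gm_stop("need at least two families with n >= 2 to compare", "validation")
  }
  fams <- sort(names(scores))
  scores <- scores[fams]
  k <- length(fams)

  p_raw <- matrix(1, k, k, dimnames = list(fams, fams))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      p <- rank_sum_test(scores[[i]], scores[[j]])$p.value
      p_raw[i, j] <- p_raw[j, i] <- p
    }
  }
  ut <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[ut] <- holm_adjust(p_raw[ut])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  signif <- p_adj < alpha
  diag(signif) <- FALSE
  letters <- compact_letter_display(signif)

  qs <- vapply(scores, quantile, numeric(3), probs = c(0.25, 0.5, 0.75),
               names = FALSE)
  summary <- data.frame(family = fams, n = lengths(scores),
                        mean = vapply(scores, mean, 0),
                        median = qs[2L, ], q1 = qs[1L, ], q3 = qs[3L, ],
                        letters = letters[fams],
                        row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(reference_family)) {
    if (!reference_family %in% fams) {
      gm_stop(sprintf("reference family '%s' not among compared families",
                      reference_family), "config")
    }
    ref_letters <- strsplit(letters[[reference_family]], "")[[1L]]
    summary$like_reference <- vapply(summary$letters, function(l) {
      any(strsplit(l, "")[[1L]] %in% ref_letters)
    }, logical(1))
  }
  structure(list(summary = summary, p_raw = p_raw, p_adj = p_adj,
                 signif = signif, alpha = alpha,
                 reference_family = reference_family, value = value),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Family comparison of '%s' (%d families, pairwise rank-sum + Holm, alpha = %g)\n",
              x$value, nrow(x$summary), x$alpha))
  df <- x$summary
  df$mean <- round(df$mean, digits)
  df$median <- round(df$median, digits)
  df$q1 <- round(df$q1, digits)
  df$q3 <- round(df$q3, digits)
  print(df, row.names = FALSE)
  cat("Families sharing a letter are statistically indistinguishable.\n")
  invisible(x)
}

#' Export a family comparison as TSV and JSON
#'
#' @param x A \code{family_comparison}.
#' @param tsv,json Optional output paths; omitted outputs are skipped.
#' @return Invisibly a list of the texts written.
#' @export
write_family_comparison <- function(x, tsv = NULL, json = NULL) {
  stopifnot(inherits(x, "family_comparison"))
  s <- x$summary
  lines <- c(paste(names(s), collapse = "\t"),
             do.call(sprintf, c(list(fmt = paste(rep("%s", ncol(s)),
                                                 collapse = "\t")),
                                lapply(s, function(col) {
                                  if (is.numeric(col)) format(col, digits = 6, trim = TRUE)
                                  else as.character(col)
                                }))))
  tsv_txt <- gm_write_lines(lines, tsv)
  obj <- list(alpha = x$alpha, value = x$value,
              reference_family = x$reference_family, summary = s,
              p_adj = x$p_adj)
  json_txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                               matrix = "rowmajor")
  if (!is.null(json)) writeLines(as.character(json_txt), json)
  invisible(list(tsv = tsv_txt, json = as.character(json_txt)))
}
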