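#' Correlation between two 1-D intensity profiles
#'
#' Sample correlation between paired fluorescence intensity line profiles
#' (e.g. two channels sampled along a line drawn perpendicular to
#' sarcomeres). Anti-phased periodic signals — one protein banded between
#' the bands of another — give negative coefficients. Pearson is the
#' default; Spearman is available for monotone association.
#'
#' @param a,b Numeric intensity profiles of equal length (>= 3), each with
#'   nonzero variance.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Correlation coefficient in [-1, 1].
#' @examples
#' x <- seq(0, 4 * pi, length.out = 100)
#' pearson_r(1 + sin(x), 1 - sin(x))  # exactly anti-phased: -1
#' @export
pearson_r <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b) ||
      any(!is.finite(a)) || any(!is.finite(b))) {
    gm_stop("profiles must be finite numeric vectors", "validation")
  }
  if (length(a) != length(b)) {
    gm_stop("profiles must have equal length", "validation")
  }
  if (length(a) < 3L) gm_stop("profiles must have length >= 3", "validation")
  if (var(a) == 0 || var(b) == 0) {
    gm_stop("profiles must have nonzero variance", "validation")
  }
  cor(a, b, method = method)
}

#' Read a two-channel intensity profile table
#'
#' Tab-separated with header columns \code{channel_a} and \code{channel_b};
#' values must be finite and nonnegative.
#'
#' @param x File path or TSV text.
#' @return Data frame with columns \code{channel_a}, \code{channel_b}.
#' @export
read_profiles <- function(x) {
  dl <- gm_data_lines(gm_read_lines(x))
  if (length(dl$lines) < 2L) gm_stop("empty profile table", "format")
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  hdr <- trimws(fields[[1L]])
  if (!all(c("channel_a", "channel_b") %in% hdr)) {
    gm_stop("profile table must have columns channel_a, channel_b", "format")
  }
  ia <- match("channel_a", hdr)
  ib <- match("channel_b", hdr)
  rows <- fields[-1L]
  a <- suppressWarnings(as.numeric(vapply(rows, `[`, "", ia)))
  b <- suppressWarnings(as.numeric(vapply(rows, `[`, "", ib)))
  if (anyNA(a) || anyNA(b)) gm_stop("non-numeric intensity value", "format")
  if (any(a < 0) || any(b < 0)) {
    gm_stop("intensities must be nonnegative", "validation")
  }
  if (length(a) < 3L) gm_stop("profiles must have length >= 3", "validation")
  data.frame(channel_a = a, channel_b = b)
}

#' @importFrom stats var
NULL
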