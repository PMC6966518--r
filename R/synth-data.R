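#' Parameters for simulating an orthologue family alignment
#'
#' The generator emulates the inputs of the phosphosite-conservation
#' analysis: an aligned family of orthologues of a reference protein with
#' per-sequence indels and substitutions, and planted phospho-acceptor
#' sites whose cross-species presence is controlled exactly. Defaults match
#' the study conditions of the conservation analysis: a family of 208
#' orthologues with planted sites at the 100\%, 99\% and 97\% conservation
#' tiers plus a 50\%-presence decoy.
#'
#' Site presence is planted by quota: exactly \code{round(presence * n)}
#' orthologues (chosen at random) carry a high-scoring site, so the
#' realised conservation fraction equals the requested one by construction
#' and tier recovery is deterministic given the parameters.
#'
#' @param n_orthologues Family size (>= 2). Default 208.
#' @param ref_length Reference sequence length in residues. Default 120.
#' @param indel_rate Per-column probability that a non-reference orthologue
#'   is gapped at that column (reference row never gapped; planted columns
#'   never gapped). Default 0.03.
#' @param substitution_rate Per-residue substitution probability away from
#'   the reference (planted columns exempt). Default 0.05.
#' @param planted_sites Data frame with columns \code{pos} (reference
#'   position), \code{residue} (one of S/T/Y) and \code{presence} (fraction
#'   in [0, 1]). If \code{NULL}, four sites are planted at fixed fractions
#'   of the reference length with presences 1.00, 0.99, 0.97 and 0.50.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class \code{family_sim_params}.
#' @export
family_sim_params <- function(n_orthologues = 208L, ref_length = 120L,
                              indel_rate = 0.03, substitution_rate = 0.05,
                              planted_sites = NULL, seed = 1L) {
  if (!gm_is_count(n_orthologues) || n_orthologues < 2) {
    gm_stop("n_orthologues must be an integer >= 2", "parameter")
  }
  if (!gm_is_count(ref_length)) {
    gm_stop("ref_length must be a positive integer", "parameter")
  }
  if (is.null(planted_sites)) {
    pos <- pmax(1L, as.integer(round(ref_length * c(0.25, 0.46, 0.67, 0.875))))
    keep <- !duplicated(pos)  # collapses only for very short references
    planted_sites <- data.frame(pos = pos,
                                residue = c("S", "T", "Y", "S"),
                                presence = c(1.00, 0.99, 0.97, 0.50))[keep, ]
  }
  for (r in c(indel_rate, substitution_rate)) {
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= 1) {
      gm_stop("rates must lie in [0, 1)", "parameter")
    }
  }
  ps <- planted_sites
  if (!is.data.frame(ps) || !all(c("pos", "residue", "presence") %in% names(ps))) {
    gm_stop("planted_sites needs columns pos, residue, presence", "parameter")
  }
  if (any(ps$pos < 1 | ps$pos > ref_length) || anyDuplicated(ps$pos)) {
    gm_stop("planted positions must be distinct and within ref_length",
            "parameter")
  }
  if (!all(ps$residue %in% c("S", "T", "Y"))) {
    gm_stop("planted residues must be phospho-acceptors (S, T or Y)",
            "parameter")
  }
  if (any(ps$presence < 0 | ps$presence > 1)) {
    gm_stop("presence fractions must lie in [0, 1]", "parameter")
  }
  if (!gm_is_count(seed + 1)) gm_stop("seed must be an integer", "parameter")
  structure(list(n_orthologues = as.integer(n_orthologues),
                 ref_length = as.integer(ref_length),
                 indel_rate = indel_rate,
                 substitution_rate = substitution_rate,
                 planted_sites = ps, seed = as.integer(seed)),
            class = "family_sim_params")
}

#' Simulate an aligned orthologue family with planted phosphosites
#'
#' Builds an alignment whose columns coincide with the reference residue
#' coordinates (the reference row carries no gap, so every planted site has
#' a defined reference position). Non-reference rows receive independent
#' per-column gaps and per-residue substitutions, never touching planted
#' columns, so the planted residue is present and mappable in every
#' orthologue. Per-orthologue site predictions are emitted for every
#' planted site: orthologues planted as "present" score uniformly on
#' (0.65, 1], the rest uniformly on [0, 0.65), making the strict 0.65
#' filter a perfect separator.
#'
#' @param params A \code{\link{family_sim_params}}.
#' @return A list of class \code{ortho_family_sim} with \code{alignment}
#'   (named character vector of aligned rows; the first sequence is the
#'   reference), \code{fasta} (aligned FASTA text), \code{calls} (site
#'   prediction table: id, position in the orthologue's own residue
#'   coordinates, residue, score, kinase), \code{truth} (planted ground
#'   truth: logical presence matrix orthologue x site, realised presence
#'   fractions, reference id) and \code{reference_id}.
#' @export
simulate_orthologue_family <- function(params = family_sim_params()) {
  stopifnot(inherits(params, "family_sim_params"))
  set.seed(params$seed)
  n <- params$n_orthologues
  L <- params$ref_length
  ps <- params$planted_sites
  ids <- sprintf("seq%03d", seq_len(n))
  reference_id <- ids[1L]

  refseq <- sample(AA20, L, replace = TRUE)
  refseq[ps$pos] <- ps$residue
  planted_cols <- ps$pos

  mat <- matrix("", nrow = n, ncol = L)
  mat[1L, ] <- refseq
  open_cols <- setdiff(seq_len(L), planted_cols)
  for (i in seq.int(2L, n)) {
    s <- refseq
    sub_at <- open_cols[runif(length(open_cols)) < params$substitution_rate]
    for (j in sub_at) s[j] <- sample(AA20[AA20 != s[j]], 1L)
    gap_at <- open_cols[runif(length(open_cols)) < params$indel_rate]
    s[gap_at] <- "-"
    mat[i, ] <- s
  }
  alignment <- setNames(apply(mat, 1L, paste, collapse = ""), ids)

  k <- nrow(ps)
  site_labels <- sprintf("%s%d", ps$residue, ps$pos)
  presence <- matrix(FALSE, nrow = n, ncol = k,
                     dimnames = list(ids, site_labels))
  for (s in seq_len(k)) {
    n_present <- round(ps$presence[s] * n)
    if (n_present > 0) presence[sample(ids, n_present), s] <- TRUE
  }

  # residue coordinate of each planted column within each (gapped) row
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    nongap <- mat[i, ] != "-"
    respos <- cumsum(nongap)
    data.frame(id = ids[i],
               position = as.integer(respos[planted_cols]),
               residue = ps$residue,
               score = ifelse(presence[i, ],
                              runif(k, 0.65, 1.0),
                              runif(k, 0.0, 0.65)),
               kinase = "unsp",
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL

  fasta <- write_fasta(data.frame(
    id = ids,
    description = c("reference", rep("", n - 1L)),
    sequence = unname(alignment), stringsAsFactors = FALSE))

  truth <- list(site_presence = presence,
                presence_fraction = colMeans(presence),
                planted_sites = ps,
                reference_id = reference_id)
  structure(list(alignment = alignment, fasta = fasta, calls = calls,
                 truth = truth, reference_id = reference_id, params = params),
            class = "ortho_family_sim")
}

#' Simulate per-family secretion-signal score tables
#'
#' Draws bounded S-mean scores per protein family from a Beta distribution
#' parameterised by mean and spread (standard deviation), so samples live
#' strictly in (0, 1) with expectation equal to the stated mean. A spread
#' of zero degenerates to all samples equal to the mean. Companion C/Y/D
#' scores are generated as bounded jitter below the S-mean purely to fill
#' the summary dialect.
#'
#' @param families Data frame with columns \code{family}, \code{n},
#'   \code{mean} (in (0, 1)) and \code{spread} (sd, with
#'   \code{spread^2 < mean * (1 - mean)}).
#' @param seed Integer seed.
#' @return Data frame in the layout of \code{\link{parse_signalp_summary}}
#'   (name, family, cmax, cpos, ymax, ypos, smean, d).
#' @examples
#' fams <- data.frame(family = c("MMP2", "Vtn"), n = c(5, 5),
#'                    mean = c(0.795, 0.95), spread = c(0.05, 0.02))
#' simulate_signal_scores(fams, seed = 1)
#' @export
simulate_signal_scores <- function(families, seed = 1L) {
  stopifnot(is.data.frame(families),
            all(c("family", "n", "mean", "spread") %in% names(families)))
  if (any(families$mean <= 0 | families$mean >= 1)) {
    gm_stop("family means must lie strictly in (0, 1)", "parameter")
  }
  if (any(families$spread < 0) ||
      any(families$spread > 0 &
          families$spread^2 >= families$mean * (1 - families$mean))) {
    gm_stop("spread must satisfy 0 <= spread^2 < mean * (1 - mean)",
            "parameter")
  }
  if (any(families$n < 1)) gm_stop("family n must be >= 1", "parameter")
  set.seed(as.integer(seed))
  clamp <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)
  out <- lapply(seq_len(nrow(families)), function(i) {
    fam <- families$family[i]
    n <- families$n[i]
    m <- families$mean[i]
    sp <- families$spread[i]
    s <- if (sp == 0) rep(m, n) else {
      conc <- m * (1 - m) / sp^2 - 1
      clamp(rbeta(n, m * conc, (1 - m) * conc))
    }
    data.frame(name = sprintf("%s_%03d", fam, seq_len(n)),
               family = fam,
               cmax = clamp(s - runif(n, 0, 0.2)),
               cpos = sample(20:35, n, replace = TRUE),
               ymax = clamp(s - runif(n, 0, 0.1)),
               ypos = sample(20:35, n, replace = TRUE),
               smean = s,
               d = clamp(s - runif(n, 0, 0.15)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parameters for simulating a TAILS degradome table
#'
#' Defaults emulate the scale of the embryo degradome experiment: 321
#' identified neo-N-terminal peptides with log-normal heavy:light ratios
#' calibrated so roughly 15\% exceed the enrichment cut-off of 3.
#'
#' @param n_peptides Number of peptides (> 0). Default 321.
#' @param myosin_fraction Probability that a peptide derives from a myosin
#'   heavy chain (description labelled accordingly). Default 0.1.
#' @param log_ratio_mean,log_ratio_sd Parameters (meanlog, sdlog) of the
#'   log-normal H/L ratio distribution. Defaults 0.28 and 0.8.
#' @param p1prime_bias Optional named weight vector over residues biasing
#'   the first (P1') residue of each peptide; uniform if \code{NULL}.
#' @param seed Integer seed.
#' @return A list of class \code{degradome_sim_params}.
#' @export
degradome_sim_params <- function(n_peptides = 321L, myosin_fraction = 0.1,
                                 log_ratio_mean = 0.28, log_ratio_sd = 0.8,
                                 p1prime_bias = NULL, seed = 1L) {
  if (!gm_is_count(n_peptides)) {
    gm_stop("n_peptides must be a positive integer", "parameter")
  }
  if (!is.numeric(myosin_fraction) || myosin_fraction < 0 ||
      myosin_fraction > 1) {
    gm_stop("myosin_fraction must lie in [0, 1]", "parameter")
  }
  if (!is.numeric(log_ratio_sd) || log_ratio_sd <= 0) {
    gm_stop("log_ratio_sd must be positive", "parameter")
  }
  if (!is.null(p1prime_bias)) {
    if (is.null(names(p1prime_bias)) || !all(names(p1prime_bias) %in% AA20) ||
        any(p1prime_bias < 0) || sum(p1prime_bias) <= 0) {
      gm_stop("p1prime_bias must be nonnegative weights named by residues",
              "parameter")
    }
  }
  structure(list(n_peptides = as.integer(n_peptides),
                 myosin_fraction = myosin_fraction,
                 log_ratio_mean = log_ratio_mean,
                 log_ratio_sd = log_ratio_sd,
                 p1prime_bias = p1prime_bias, seed = as.integer(seed)),
            class = "degradome_sim_params")
}

#' Simulate a TAILS peptide quantification table with ground truth
#'
#' @param params A \code{\link{degradome_sim_params}}.
#' @return A list of class \code{degradome_sim} with \code{records}
#'   (peptide, protein_description, hl_ratio) and \code{truth}
#'   (\code{is_myosin} logical per record and the parameters).
#' @export
simulate_degradome <- function(params = degradome_sim_params()) {
  stopifnot(inherits(params, "degradome_sim_params"))
  set.seed(params$seed)
  n <- params$n_peptides
  bias <- params$p1prime_bias
  w <- rep(1, length(AA20))
  if (!is.null(bias)) {
    w <- rep(0, length(AA20))
    w[match(names(bias), AA20)] <- bias
  }
  first <- sample(AA20, n, replace = TRUE, prob = w)
  len <- sample(7:20, n, replace = TRUE)
  rest <- vapply(len, function(l) {
    paste(sample(AA20, l - 1L, replace = TRUE), collapse = "")
  }, character(1))
  peptide <- paste0(first, rest)

  is_myosin <- runif(n) < params$myosin_fraction
  myosin_pool <- c("myosin heavy chain, fast skeletal muscle",
                   "myosin heavy chain 4",
                   "myosin heavy polypeptide 2, fast muscle specific")
  other_pool <- c("alpha-actinin-3", "troponin T, fast skeletal muscle",
                  "creatine kinase M-type", "parvalbumin beta",
                  "beta-enolase", "vitronectin b precursor",
                  "collagen alpha-1(I) chain",
                  "heat shock cognate 71 kDa protein")
  description <- character(n)
  description[is_myosin] <- sample(myosin_pool, sum(is_myosin), replace = TRUE)
  description[!is_myosin] <- sample(other_pool, sum(!is_myosin), replace = TRUE)

  hl <- rlnorm(n, meanlog = params$log_ratio_mean, sdlog = params$log_ratio_sd)
  records <- data.frame(peptide = peptide, protein_description = description,
                        hl_ratio = hl, stringsAsFactors = FALSE)
  structure(list(records = records,
                 truth = list(is_myosin = is_myosin, params = params)),
            class = "degradome_sim")
}

#' Simulate a pair of periodic, phase-shifted intensity profiles
#'
#' Emulates two-channel line profiles across a striated structure: both
#' channels are sinusoidal with the given period; the second is shifted by
#' a fraction of the period. With zero noise, phase 0 gives identical
#' profiles and phase 0.5 an exactly anti-phased pair (Pearson r of -1).
#' Gaussian noise is added and intensities clipped at zero to keep them
#' nonnegative.
#'
#' @param period Period in pixels (>= 4).
#' @param phase Phase shift as a fraction of the period in [0, 1).
#' @param length Profile length in pixels (default 200).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0).
#' @param seed Integer seed.
#' @return Data frame with columns \code{channel_a}, \code{channel_b}.
#' @export
simulate_profiles <- function(period, phase = 0.5, length = 200L,
                              noise_sd = 0, seed = 1L) {
  if (!is.numeric(period) || length(period) != 1L || period < 4) {
    gm_stop("period must be at least 4 pixels", "parameter")
  }
  if (!is.numeric(phase) || phase < 0 || phase >= 1) {
    gm_stop("phase must lie in [0, 1)", "parameter")
  }
  if (!gm_is_count(length) || length < 3) {
    gm_stop("length must be an integer >= 3", "parameter")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    gm_stop("noise_sd must be nonnegative", "parameter")
  }
  set.seed(as.integer(seed))
  theta <- 2 * pi * (seq_len(length) - 1L) / period
  a <- 1 + sin(theta)
  b <- 1 + sin(theta - 2 * pi * phase)
  if (noise_sd > 0) {
    a <- a + rnorm(length, sd = noise_sd)
    b <- b + rnorm(length, sd = noise_sd)
  }
  data.frame(channel_a = pmax(a, 0), channel_b = pmax(b, 0))
}
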