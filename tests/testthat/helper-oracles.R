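# Independent oracles kept deliberately naive: brute-force scans and
# exhaustive enumerations that never share code with the implementation.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random aligned row with gaps
random_gapped_row <- function(max_len = 60, gap_p = 0.3) {
  n <- sample(1:max_len, 1)
  paste(ifelse(runif(n) < gap_p, "-", sample(AA, n, replace = TRUE)),
        collapse = "")
}

# residue index -> column by scanning and counting non-gap characters
brute_res_to_col <- function(row, pos) {
  chars <- strsplit(row, "")[[1]]
  seen <- 0
  for (col in seq_along(chars)) {
    if (chars[col] != "-") {
      seen <- seen + 1
      if (seen == pos) return(col)
    }
  }
  NA_integer_
}

# column -> residue index (NA at gaps) by the same scan
brute_col_to_res <- function(row, col) {
  chars <- strsplit(row, "")[[1]]
  if (chars[col] == "-") return(NA_integer_)
  sum(chars[seq_len(col)] != "-")
}

# exhaustive two-sided Mann-Whitney p-value: every assignment of the pooled
# values to group a, U computed by a literal pair count
perm_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  N <- length(pooled)
  count_U <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  U_obs <- count_U(a, b)
  mu <- na * (N - na) / 2
  sets <- utils::combn(N, na)
  Us <- apply(sets, 2, function(ix) count_U(pooled[ix], pooled[-ix]))
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# check the two compact-letter-display axioms against a significance matrix
cld_axioms_hold <- function(letters, signif) {
  k <- length(letters)
  sets <- lapply(letters, function(l) strsplit(l, "")[[1]])
  for (i in seq_len(k)) {
    if (length(sets[[i]]) == 0) return(FALSE)  # every family needs a letter
    for (j in seq_len(k)) {
      if (i == j) next
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      if (signif[i, j] && share) return(FALSE)
      if (!signif[i, j] && !share) return(FALSE)
    }
  }
  TRUE
}

random_signif_matrix <- function(k, p = 0.3) {
  m <- matrix(FALSE, k, k, dimnames = list(paste0("g", 1:k), paste0("g", 1:k)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- runif(1) < p
  }
  m
}

# brute-force conservation tally: for every planted alignment column, loop
# over orthologues and their calls, counting orthologues that contribute a
# strictly-above-threshold call whose residue matches the reference residue
brute_conservation_counts <- function(calls, alignment, reference_id,
                                      threshold = 0.65) {
  ref_chars <- strsplit(alignment[[reference_id]], "")[[1]]
  counts <- list()
  for (o in names(alignment)) {
    chars <- strsplit(alignment[[o]], "")[[1]]
    oc <- calls[calls$id == o & calls$score > threshold, , drop = FALSE]
    seen_ref_pos <- integer(0)
    for (r in seq_len(nrow(oc))) {
      col <- brute_res_to_col(alignment[[o]], oc$position[r])
      if (is.na(col) || ref_chars[col] == "-") next
      ref_pos <- sum(ref_chars[seq_len(col)] != "-")
      if (ref_chars[col] != oc$residue[r]) next    # exact residue match
      if (ref_pos %in% seen_ref_pos) next          # orthologue counts once
      seen_ref_pos <- c(seen_ref_pos, ref_pos)
      key <- as.character(ref_pos)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  unlist(counts)[order(as.integer(names(unlist(counts))))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build gapmaps for a whole named alignment
gapmaps_of <- function(alignment) {
  maps <- lapply(names(alignment), function(id) {
    build_gapmap(alignment[[id]], id = id)
  })
  names(maps) <- names(alignment)
  maps
}

table1_path <- function() {
  system.file("extdata", "tails_myosin_peptides.tsv", package = "gelmap")
}
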