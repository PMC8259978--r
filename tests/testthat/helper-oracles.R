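# Independent brute-force oracles, deliberately implemented without reusing
# package internals.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", V = "B", D = "H", H = "D")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

oracle_word_matches <- function(word, consensus) {
  w <- strsplit(word, "")[[1]]
  p <- strsplit(consensus, "")[[1]]
  if (length(w) != length(p)) return(FALSE)
  all(mapply(function(a, b) a %in% ORACLE_IUPAC[[b]], w, p))
}

# per-window sliding check over both strands; returns data.frame(start,
# strand) with 0-based starts, sorted like the scanner output
oracle_scan <- function(sequence, consensus, strands = "both") {
  L <- nchar(consensus)
  n <- nchar(sequence)
  out <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      w <- substr(sequence, s + 1, s + L)
      if (strands %in% c("both", "+") && oracle_word_matches(w, consensus))
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "+")
      if (strands %in% c("both", "-") &&
          oracle_word_matches(oracle_revcomp(w), consensus))
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "-")
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), strand = character()))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# score every one of the 4^L words of a matrix by direct summation
oracle_all_pwm_scores <- function(weights) {
  scores <- 0
  for (j in seq_len(ncol(weights)))
    scores <- as.vector(outer(scores, weights[, j], `+`))
  scores
}

# exact two-sided Mann-Whitney p by full enumeration of the C(n1+n2, n1)
# group assignments of the pooled ranks
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_consensus <- function(L) {
  codes <- names(ORACLE_IUPAC)
  # bias toward concrete bases so matches are informative but not absent
  paste(sample(c(rep(c("A", "C", "G", "T"), 4), codes), L, replace = TRUE),
        collapse = "")
}
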