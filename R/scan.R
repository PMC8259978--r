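# Motif scanning. All coordinates are 0-based, half-open, on the forward
# strand; minus-strand hits report the forward-strand interval they cover.

empty_hits <- function() {
  structure(data.frame(motif = character(), start = integer(), end = integer(),
                       strand = character(), word = character(),
                       raw_score = numeric(), norm_score = numeric(),
                       stringsAsFactors = FALSE),
            class = c("motif_hits", "data.frame"))
}

as_motif_hits <- function(df) {
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("motif_hits", "data.frame")
  df
}

check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) > 0) {
    bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T", "N"))
    if (length(bad) > 0)
      stop("sequence contains characters outside {A,C,G,T,N}: ",
           paste(bad, collapse = ", "))
  }
  sequence
}

consensus_regex <- function(consensus) {
  sets <- iupac_sets(consensus)
  paste(vapply(sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

match_starts <- function(sequence, regex) {
  # overlapping matches via zero-width lookahead; returns 0-based starts
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Every (possibly overlapping) window matching the consensus is reported.
#' Minus-strand matches are found by scanning for the reverse complement of
#' the consensus and are reported at forward-strand coordinates with
#' `strand = "-"`; the `word` column always holds the forward-strand slice.
#' An N in the sequence matches nothing.
#'
#' @param sequence A/C/G/T/N string (case-insensitive).
#' @param motif a [motif_def()] with `kind = "consensus"`.
#' @param strands "both", "+" or "-".
#' @return a `motif_hits` data frame sorted by (start, strand) with 0-based
#'   half-open coordinates.
#' @examples
#' q50 <- motif_def("Q50", "consensus", consensus = "TAATTR")
#' scan_consensus("TAATTGAATTT", q50)
#' @export
scan_consensus <- function(sequence, motif, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (!inherits(motif, "motif_def") || motif$kind != "consensus")
    stop("scan_consensus requires a consensus motif_def")
  sequence <- check_sequence(sequence)
  L <- nchar(motif$consensus)
  if (nchar(sequence) < L) return(empty_hits())
  out <- list()
  if (strands %in% c("both", "+")) {
    st <- match_starts(sequence, consensus_regex(motif$consensus))
    if (length(st) > 0)
      out[[length(out) + 1L]] <- data.frame(
        motif = motif$name, start = st, end = st + L, strand = "+",
        word = substring(sequence, st + 1L, st + L),
        raw_score = NA_real_, norm_score = NA_real_,
        stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "-")) {
    st <- match_starts(sequence, consensus_regex(revcomp(motif$consensus)))
    if (length(st) > 0)
      out[[length(out) + 1L]] <- data.frame(
        motif = motif$name, start = st, end = st + L, strand = "-",
        word = substring(sequence, st + 1L, st + L),
        raw_score = NA_real_, norm_score = NA_real_,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_hits())
  as_motif_hits(do.call(rbind, out))
}

#' Scan a sequence with a position weight matrix
#'
#' Every window whose normalized similarity score reaches `min_norm` is
#' reported with raw and normalized scores. Minus-strand windows are scored
#' on their reverse complement; windows containing N are skipped.
#'
#' @param sequence A/C/G/T/N string.
#' @param pwm a [pwm()] object.
#' @param min_norm percent-of-maximum threshold (may be negative).
#' @param strands "both", "+" or "-".
#' @param motif_name name recorded in the hit table (default the pwm id).
#' @return a `motif_hits` data frame (0-based half-open coordinates).
#' @export
scan_pwm <- function(sequence, pwm, min_norm = 80,
                     strands = c("both", "+", "-"), motif_name = pwm$id) {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "pwm"))
  sequence <- check_sequence(sequence)
  L <- pwm$length
  n <- nchar(sequence)
  if (n < L) return(empty_hits())
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))  # N -> NA, poisons its windows
  starts0 <- 0:(n - L)
  score_with <- function(w) {
    vapply(starts0, function(s) {
      i <- idx[(s + 1L):(s + L)]
      if (anyNA(i)) return(NA_real_)
      sum(w[cbind(i, seq_len(L))])
    }, numeric(1))
  }
  out <- list()
  add <- function(raw, strand) {
    norm <- pwm_norm_score(raw, pwm)
    keep <- !is.na(norm) & norm >= min_norm
    if (!any(keep)) return()
    st <- starts0[keep]
    out[[length(out) + 1L]] <<- data.frame(
      motif = motif_name, start = st, end = st + L, strand = strand,
      word = substring(sequence, st + 1L, st + L),
      raw_score = raw[keep], norm_score = norm[keep],
      stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "+")) add(score_with(pwm$weights), "+")
  if (strands %in% c("both", "-")) {
    # scoring the reverse complement of each window == scoring the window
    # with the reverse-complemented matrix
    w_rc <- pwm$weights[c("T", "G", "C", "A"), rev(seq_len(L)), drop = FALSE]
    rownames(w_rc) <- c("A", "C", "G", "T")
    add(score_with(w_rc), "-")
  }
  if (length(out) == 0) return(empty_hits())
  as_motif_hits(do.call(rbind, out))
}

#' Create a promoter record
#'
#' @param id promoter name.
#' @param sequence A/C/G/T/N string (normalized to uppercase).
#' @param hits optional `motif_hits` data frame.
#' @param rcsi,rcsii,tata optional 0-based half-open `c(start, end)` anchors.
#' @return object of class `promoter_record`.
#' @export
promoter_record <- function(id, sequence, hits = NULL, rcsi = NULL,
                            rcsii = NULL, tata = NULL) {
  sequence <- check_sequence(sequence)
  n <- nchar(sequence)
  chk <- function(a, what) {
    if (is.null(a)) return(NULL)
    a <- as.integer(a)
    if (length(a) != 2 || a[1] < 0 || a[2] > n || a[1] >= a[2])
      stop(what, " anchor must be a valid 0-based half-open interval within the sequence")
    a
  }
  structure(list(id = id, sequence = sequence,
                 hits = if (is.null(hits)) empty_hits() else hits,
                 rcsi = chk(rcsi, "rcsi"), rcsii = chk(rcsii, "rcsii"),
                 tata = chk(tata, "tata")),
            class = "promoter_record")
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter %s: %d bp, %d motif hits%s>\n", x$id,
              nchar(x$sequence), nrow(x$hits),
              if (!is.null(x[["rcsi"]]))
                sprintf(", RCSI [%d,%d)", x[["rcsi"]][1], x[["rcsi"]][2]) else ""))
  invisible(x)
}

#' Annotate a promoter against a motif catalog
#'
#' Scans the promoter with every catalog motif (consensus motifs by pattern
#' match, pwm motifs through the PWM store) and populates the hit table.
#' If no explicit RCSI anchor was given, the anchor is set to the unique
#' interval hit by an RCSI-class motif (catalog entries with
#' `element == "RCSI"`); zero or several distinct candidate intervals raise
#' an ambiguity error because downstream construct building requires the
#' anchor.
#'
#' @param record a [promoter_record()].
#' @param catalog a `motif_catalog` (see [read_motif_catalog()]) or list of
#'   [motif_def()] objects.
#' @param pwms named list of [pwm()] objects (required for pwm motifs).
#' @param min_norm normalized-score threshold for pwm motifs.
#' @param strands strand selection passed to the scanners.
#' @return the record with `hits` populated and `rcsi` set.
#' @export
annotate_promoter <- function(record, catalog, pwms = list(), min_norm = 80,
                              strands = "both") {
  stopifnot(inherits(record, "promoter_record"))
  hits <- lapply(catalog, function(m) {
    if (m$kind == "consensus") {
      scan_consensus(record$sequence, m, strands = strands)
    } else {
      if (is.null(pwms[[m$pwm_id]]))
        stop("pwm '", m$pwm_id, "' for motif '", m$name, "' not in store")
      scan_pwm(record$sequence, pwms[[m$pwm_id]], min_norm = min_norm,
               strands = strands, motif_name = m$name)
    }
  })
  hits <- do.call(rbind, c(list(empty_hits()), hits))
  record$hits <- as_motif_hits(hits)
  if (is.null(record[["rcsi"]])) {
    rcsi_motifs <- vapply(catalog, function(m) identical(m$element, "RCSI"),
                          logical(1))
    cand <- record$hits[record$hits$motif %in%
                          names(catalog)[rcsi_motifs], , drop = FALSE]
    ivals <- unique(cand[, c("start", "end")])
    if (nrow(ivals) != 1)
      stop(sprintf(
        "RCSI anchor ambiguous for '%s': %d candidate interval(s); supply an explicit anchor",
        record$id, nrow(ivals)))
    record[["rcsi"]] <- c(ivals$start[1], ivals$end[1])
  }
  record
}

#' Write motif hits as BED-like TSV
#'
#' Six columns: seq_id, start, end, motif, norm_score (or "." for consensus
#' hits), strand; 0-based half-open coordinates.
#'
#' @param hits a `motif_hits` data frame.
#' @param seq_id sequence identifier for column 1.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(hits, seq_id, path) {
  bed <- data.frame(seq_id = seq_id, start = hits$start, end = hits$end,
                    motif = hits$motif,
                    score = ifelse(is.na(hits$norm_score), ".",
                                   format(hits$norm_score, trim = TRUE)),
                    strand = hits$strand, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read promoter sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named list of [promoter_record()] objects (no hits, no anchors).
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  recs <- lapply(seq_along(ss), function(i) {
    promoter_record(id = strsplit(names(ss)[i], "\\s+")[[1]][1],
                    sequence = as.character(ss[[i]]))
  })
  names(recs) <- vapply(recs, `[[`, character(1), "id")
  recs
}

#' Write promoter records to a FASTA file
#'
#' @param records list of [promoter_record()] objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_promoters_fasta <- function(records, path) {
  if (inherits(records, "promoter_record")) records <- list(records)
  ss <- Biostrings::DNAStringSet(
    vapply(records, `[[`, character(1), "sequence"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
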