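# Cross-species motif conservation calling on multi-species promoter
# alignments. Gaps are '-'; a distinct configurable marker (default '=')
# encodes stretches with no alignable orthologous sequence, which keeps
# "deleted" and "unalignable" unambiguous.

#' Create a multi-species alignment set
#'
#' @param rows named character vector (species -> aligned row); all rows the
#'   same length, over A/C/G/T/N, '-' (gap) and the unalignable marker.
#' @param reference name of the reference species (must be a row).
#' @param unalignable_marker single character marking unalignable stretches.
#' @return object of class `alignment_set`.
#' @export
alignment_set <- function(rows, reference, unalignable_marker = "=") {
  rows <- toupper(unlist(rows))
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("rows must be named by species")
  if (length(unique(nchar(rows))) != 1)
    stop("all alignment rows must have equal length")
  if (!reference %in% names(rows))
    stop("reference species '", reference, "' not among rows")
  if (nchar(unalignable_marker) != 1)
    stop("unalignable_marker must be a single character")
  legal <- c("A", "C", "G", "T", "N", "-", unalignable_marker)
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]), legal)
  if (length(bad) > 0)
    stop("illegal alignment characters: ", paste(bad, collapse = ", "))
  structure(list(rows = rows, reference = reference,
                 unalignable_marker = unalignable_marker),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment: %d species x %d columns, reference %s>\n",
              length(x$rows), nchar(x$rows[1]), x$reference))
  invisible(x)
}

#' Read an aligned FASTA file into an alignment set
#'
#' Rows may contain the unalignable marker, so the file is read as plain
#' text sequences rather than strict DNA.
#'
#' @param path aligned FASTA (all records equal length).
#' @param reference reference species name (default: first record).
#' @param unalignable_marker see [alignment_set()].
#' @param collapse_gap_runs if TRUE, a run of '-' spanning at least
#'   `min_run` columns in a row is reinterpreted as unalignable sequence
#'   (for inputs that encode unalignable stretches as long dashes).
#' @param min_run minimum run length for `collapse_gap_runs`.
#' @return an `alignment_set`.
#' @export
read_alignment_fasta <- function(path, reference = NULL,
                                 unalignable_marker = "=",
                                 collapse_gap_runs = FALSE, min_run = 20) {
  ss <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(ss))
  names(rows) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  if (isTRUE(collapse_gap_runs)) {
    rows <- vapply(rows, function(r) {
      m <- gregexpr(sprintf("-{%d,}", min_run), r, perl = TRUE)[[1]]
      if (m[1] != -1) {
        chars <- strsplit(r, "")[[1]]
        for (k in seq_along(m)) {
          i <- as.integer(m[k])
          len <- attr(m, "match.length")[k]
          chars[i:(i + len - 1L)] <- unalignable_marker
        }
        r <- paste(chars, collapse = "")
      }
      r
    }, character(1), USE.NAMES = TRUE)
  }
  if (is.null(reference)) reference <- names(rows)[1]
  alignment_set(rows, reference, unalignable_marker)
}

ungap <- function(row) gsub("[^ACGTN]", "", row)

#' Ungapped reference sequence of an alignment
#'
#' @param align an [alignment_set()].
#' @return the reference row with gaps/markers removed.
#' @export
reference_sequence <- function(align) {
  stopifnot(inherits(align, "alignment_set"))
  ungap(align$rows[[align$reference]])
}

#' Lift an ungapped reference interval to alignment columns
#'
#' Returns the minimal 0-based half-open column interval whose reference
#' non-gap characters are exactly the requested reference positions.
#'
#' @param align an [alignment_set()].
#' @param ref_start,ref_end 0-based half-open interval on the ungapped
#'   reference sequence.
#' @return integer `c(start, end)` column interval (0-based half-open).
#' @export
map_ref_interval <- function(align, ref_start, ref_end) {
  stopifnot(inherits(align, "alignment_set"))
  chars <- strsplit(align$rows[[align$reference]], "")[[1]]
  is_base <- chars %in% c("A", "C", "G", "T", "N")
  n_ref <- sum(is_base)
  if (ref_start < 0 || ref_end > n_ref || ref_start >= ref_end)
    stop("reference interval out of range")
  base_cols <- which(is_base)  # 1-based columns of reference bases
  c(base_cols[ref_start + 1L] - 1L, base_cols[ref_end])
}

# number of species bases strictly before column `col0` (0-based)
bases_before <- function(row_chars, col0) {
  if (col0 == 0) return(0L)
  sum(row_chars[seq_len(col0)] %in% c("A", "C", "G", "T", "N"))
}

matches_consensus <- function(word, consensus) {
  nchar(word) == nchar(consensus) &&
    grepl(paste0("^", consensus_regex(consensus), "$"), word)
}

#' Call the evolutionary fate of a reference motif across species
#'
#' For each non-reference species the motif's alignment columns are
#' inspected and the first matching rule in fixed order decides the call:
#' (1) the unalignable marker covers the core columns -> "unalignable";
#' (2) the word at offset 0 equals the reference word -> "identical";
#' (3) it matches the motif consensus on the forward strand -> "variant";
#' (4) its reverse complement matches the consensus -> "inverted";
#' (5) a forward or reverse-complement consensus match exists within
#' `window` bp of the aligned position -> "shifted" (offset and strand
#' recorded; smaller |offset| wins, upstream before downstream on ties);
#' (6) otherwise "absent".
#'
#' @param align an [alignment_set()].
#' @param ref_hit one-row `motif_hits` data frame (or list with start/end/
#'   word) giving the motif occurrence on the ungapped reference.
#' @param motif a consensus [motif_def()]; pwm-only motifs are rejected
#'   because fate calling is consensus-based.
#' @param window shifted-match search radius in bp (>= 0). This automates
#'   the manual re-adjustment of local misalignments around conserved
#'   motifs; windows running past the species sequence are clipped.
#' @return data frame of class `conservation_calls` with one row per
#'   non-reference species: species, status, word, strand, offset.
#' @export
call_conservation <- function(align, ref_hit, motif, window = 10) {
  stopifnot(inherits(align, "alignment_set"))
  if (!inherits(motif, "motif_def") || motif$kind != "consensus")
    stop("conservation calling is consensus-based; motif must have a consensus")
  if (window < 0) stop("window must be >= 0")
  start <- as.integer(ref_hit$start[1]); end <- as.integer(ref_hit$end[1])
  L <- end - start
  refseq <- reference_sequence(align)
  if (start < 0 || end > nchar(refseq))
    stop("ref_hit lies outside the reference sequence")
  ref_word <- substr(refseq, start + 1L, end)
  cols <- map_ref_interval(align, start, end)
  species <- setdiff(names(align$rows), align$reference)
  calls <- lapply(species, function(sp) {
    row <- align$rows[[sp]]
    chars <- strsplit(row, "")[[1]]
    core <- chars[(cols[1] + 1L):cols[2]]
    if (all(core %in% c(align$unalignable_marker, "-")) &&
        any(core == align$unalignable_marker))
      return(data.frame(species = sp, status = "unalignable", word = "",
                        strand = "none", offset = 0L, stringsAsFactors = FALSE))
    word0 <- paste(core[core %in% c("A", "C", "G", "T", "N")], collapse = "")
    if (nchar(word0) == L) {
      if (word0 == ref_word)
        return(data.frame(species = sp, status = "identical", word = word0,
                          strand = "+", offset = 0L, stringsAsFactors = FALSE))
      if (matches_consensus(word0, motif$consensus))
        return(data.frame(species = sp, status = "variant", word = word0,
                          strand = "+", offset = 0L, stringsAsFactors = FALSE))
      if (matches_consensus(revcomp(word0), motif$consensus))
        return(data.frame(species = sp, status = "inverted", word = word0,
                          strand = "-", offset = 0L, stringsAsFactors = FALSE))
    }
    # shifted search on the ungapped species sequence around the aligned pos
    spseq <- ungap(row)
    pos <- bases_before(chars, cols[1])  # 0-based expected start in species
    offsets <- setdiff(as.vector(rbind(-(1:window), 1:window)), 0)
    if (window == 0) offsets <- integer(0)
    for (d in offsets) {
      s <- pos + d
      if (s < 0 || s + L > nchar(spseq)) next  # clipped, not an error
      w <- substr(spseq, s + 1L, s + L)
      if (matches_consensus(w, motif$consensus))
        return(data.frame(species = sp, status = "shifted", word = w,
                          strand = "+", offset = d, stringsAsFactors = FALSE))
      if (matches_consensus(revcomp(w), motif$consensus))
        return(data.frame(species = sp, status = "shifted", word = w,
                          strand = "-", offset = d, stringsAsFactors = FALSE))
    }
    data.frame(species = sp, status = "absent", word = "", strand = "none",
               offset = 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("conservation_calls", "data.frame")
  out
}

#' Tally motif variant words across species
#'
#' Counts each distinct matched word across species, including the
#' reference word for the reference species itself; "absent" and
#' "unalignable" calls contribute nothing. "shifted" and "inverted" calls
#' contribute their observed word (an inverted word is counted as its
#' consensus-matching reverse complement).
#'
#' @param calls a `conservation_calls` data frame (possibly pooled over
#'   several occurrences).
#' @param ref_word the reference species' motif word (counted once per
#'   occurrence pooled into `calls`; set `include_reference = FALSE` to
#'   tally the non-reference species only).
#' @param include_reference logical.
#' @return object of class `variant_tally`: list with `counts` (named
#'   integer vector) and `scores` (NULL until [score_variants()] is run).
#' @export
tally_variants <- function(calls, ref_word, include_reference = TRUE) {
  words <- character(0)
  if (isTRUE(include_reference)) words <- toupper(ref_word)
  keep <- calls$status %in% c("identical", "variant", "shifted", "inverted")
  w <- calls$word[keep]
  inv <- calls$status[keep] == "inverted"
  if (any(inv)) w[inv] <- revcomp(w[inv])
  words <- c(words, w)
  counts <- if (length(words) == 0) {
    integer(0)
  } else {
    tab <- table(words)
    stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(counts = counts, scores = NULL), class = "variant_tally")
}

#' Attach normalized PWM scores to a variant tally
#'
#' @param tally a [tally_variants()] result.
#' @param pwm a [pwm()] whose length equals the variant word length.
#' @return the tally with `scores` filled (percent of matrix maximum).
#' @export
score_variants <- function(tally, pwm) {
  stopifnot(inherits(tally, "variant_tally"), inherits(pwm, "pwm"))
  words <- names(tally$counts)
  if (length(words) == 0) {
    tally$scores <- stats::setNames(numeric(0), character(0))
    return(tally)
  }
  if (any(nchar(words) != pwm$length))
    stop("variant word length does not match pwm length")
  tally$scores <- stats::setNames(
    vapply(words, function(w) pwm_norm_score(pwm_raw_score(w, pwm), pwm),
           numeric(1)), words)
  tally
}

#' @export
print.variant_tally <- function(x, ...) {
  cat("<variant tally>\n")
  for (w in names(x$counts)) {
    cat(sprintf("  %s  n=%d%s\n", w, x$counts[[w]],
                if (!is.null(x$scores))
                  sprintf("  score=%.1f", x$scores[[w]]) else ""))
  }
  invisible(x)
}

#' Write a conservation report as TSV
#'
#' @param calls a `conservation_calls` data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_conservation_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
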