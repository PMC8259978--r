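# In-silico construction of hybrid promoters and RCSI/RCSII swap
# constructs. The break/fusion point of a hybrid is strictly the first base
# upstream of the RCSI motif: the distal part excludes the RCSI, the
# proximal part includes it. The promoter that provided the distal region
# is always named first.

shift_hits <- function(hits, from, by) {
  if (nrow(hits) == 0 || by == 0) return(hits)
  sel <- hits$start >= from
  hits$start[sel] <- hits$start[sel] + by
  hits$end[sel] <- hits$end[sel] + by
  hits
}

shift_anchor <- function(a, from, by) {
  if (is.null(a)) return(NULL)
  if (a[1] >= from) a + as.integer(by) else a
}

#' Build a hybrid promoter from a distal and a proximal donor
#'
#' The hybrid sequence is the distal donor's sequence up to (excluding) its
#' RCSI, fused to the proximal donor's sequence from (including) its RCSI.
#' The hybrid id follows the distal-donor-first convention
#' (`"{distal$id}-{proximal$id}"`). Distal-donor hits upstream of its RCSI
#' are carried over unchanged; proximal-donor hits at or downstream of its
#' RCSI are carried over with re-offset coordinates, as are the proximal
#' donor's RCSI/RCSII/TATA anchors.
#'
#' @param distal,proximal [promoter_record()] objects with `rcsi` anchors.
#' @return a new `promoter_record` for the hybrid.
#' @export
build_hybrid <- function(distal, proximal) {
  stopifnot(inherits(distal, "promoter_record"),
            inherits(proximal, "promoter_record"))
  if (is.null(distal[["rcsi"]]) || is.null(proximal[["rcsi"]]))
    stop("both donors need an RCSI anchor to define the break/fusion point")
  bp_d <- distal[["rcsi"]][1]     # breakpoint: first base of the distal RCSI
  bp_p <- proximal[["rcsi"]][1]
  seq_d <- substr(distal$sequence, 1, bp_d)
  seq_p <- substr(proximal$sequence, bp_p + 1L, nchar(proximal$sequence))
  offset <- bp_d - bp_p
  hits_d <- distal$hits[distal$hits$end <= bp_d, , drop = FALSE]
  hits_p <- proximal$hits[proximal$hits$start >= bp_p, , drop = FALSE]
  if (nrow(hits_p) > 0) {
    hits_p$start <- hits_p$start + offset
    hits_p$end <- hits_p$end + offset
  }
  promoter_record(
    id = paste0(distal$id, "-", proximal$id),
    sequence = paste0(seq_d, seq_p),
    hits = as_motif_hits(rbind(hits_d, hits_p)),
    rcsi = proximal[["rcsi"]] + offset,
    rcsii = shift_anchor(proximal[["rcsii"]], bp_p, offset),
    tata = shift_anchor(proximal[["tata"]], bp_p, offset))
}

#' Replace (or insert at) an interval of a promoter sequence
#'
#' Implements RCSI/RCSII swaps and insertions: the 0-based half-open
#' `interval` is replaced by `donor_word`. A zero-width interval inserts.
#' Anchors and hits at or beyond the interval end are shifted by the length
#' difference; hits overlapping the replaced interval are dropped (rescan
#' with [annotate_promoter()] if needed). The RCSI anchor is updated to the
#' donor word when the replaced interval is exactly the current RCSI.
#'
#' @param context a [promoter_record()].
#' @param interval integer `c(start, end)`, 0-based half-open,
#'   `start == end` for an insertion.
#' @param donor_word replacement A/C/G/T string (non-empty for a swap).
#' @return modified `promoter_record` (id gets a "*" suffix unless renamed).
#' @param id optional id for the construct; default `paste0(context$id, "*")`.
#' @export
swap_element <- function(context, interval, donor_word, id = NULL) {
  stopifnot(inherits(context, "promoter_record"))
  n <- nchar(context$sequence)
  interval <- as.integer(interval)
  if (length(interval) != 2 || interval[1] < 0 || interval[2] > n ||
      interval[1] > interval[2])
    stop("interval out of bounds")
  donor_word <- check_sequence(donor_word)
  if (interval[1] == interval[2] && nchar(donor_word) == 0)
    stop("insertion requires a non-empty donor_word")
  delta <- nchar(donor_word) - (interval[2] - interval[1])
  sequence <- paste0(substr(context$sequence, 1, interval[1]), donor_word,
                     substr(context$sequence, interval[2] + 1L, n))
  hits <- context$hits
  if (nrow(hits) > 0) {
    keep <- hits$end <= interval[1] | hits$start >= interval[2]
    hits <- hits[keep, , drop = FALSE]
    hits <- shift_hits(hits, interval[2], delta)
  }
  adj <- function(a) {
    if (is.null(a)) return(NULL)
    if (identical(as.integer(a), interval))
      return(c(interval[1], interval[1] + nchar(donor_word)))
    if (a[1] >= interval[2]) return(a + delta)
    if (a[2] <= interval[1]) return(a)
    NULL  # anchor overlaps the replaced interval and is no longer valid
  }
  promoter_record(id = if (is.null(id)) paste0(context$id, "*") else id,
                  sequence = sequence, hits = as_motif_hits(hits),
                  rcsi = adj(context[["rcsi"]]), rcsii = adj(context[["rcsii"]]),
                  tata = adj(context[["tata"]]))
}

strip_restriction_sites <- function(primer) {
  # BglII (agatct) / NotI (gcggccgc) cloning adapters at primer termini
  primer <- toupper(primer)
  for (site in c("AGATCT", "GCGGCCGC")) {
    if (startsWith(primer, site)) primer <- substring(primer, nchar(site) + 1L)
    if (endsWith(primer, site))
      primer <- substring(primer, 1L, nchar(primer) - nchar(site))
  }
  primer
}

#' Check a construct sequence against a printed primer
#'
#' Reports whether the primer, or its reverse complement, occurs as a
#' substring of the record's sequence. Restriction-site adapters (BglII
#' "agatct", NotI "gcggccgc") at the primer termini are ignored. A
#' non-match is a report, not an error.
#'
#' @param record a [promoter_record()].
#' @param primer A/C/G/T string, case-insensitive.
#' @return list with `match` (logical), `orientation` ("forward",
#'   "revcomp" or NA), `start`, `end` (0-based half-open match coordinates
#'   or NA) and `searched` (the adapter-stripped primer).
#' @export
validate_against_primer <- function(record, primer) {
  stopifnot(inherits(record, "promoter_record"))
  core <- strip_restriction_sites(primer)
  find <- function(p) {
    i <- regexpr(p, record$sequence, fixed = TRUE)
    if (i[1] == -1) NULL else c(as.integer(i) - 1L, as.integer(i) - 1L + nchar(p))
  }
  hit <- find(core)
  if (!is.null(hit))
    return(list(match = TRUE, orientation = "forward",
                start = hit[1], end = hit[2], searched = core))
  hit <- find(revcomp(core))
  if (!is.null(hit))
    return(list(match = TRUE, orientation = "revcomp",
                start = hit[1], end = hit[2], searched = core))
  list(match = FALSE, orientation = NA_character_,
       start = NA_integer_, end = NA_integer_, searched = core)
}
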