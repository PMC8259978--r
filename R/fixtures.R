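# Bundled fixtures: the printed primer tables, the observed construct
# outcome table, the motif catalog / TF model, and synthetic stand-in
# promoters assembled from printed sequence fragments.

extdata <- function(...) {
  path <- system.file("extdata", ..., package = "rhocis")
  if (!nzchar(path)) stop("bundled file not found: ", paste(..., sep = "/"))
  path
}

#' Bundled motif catalog
#'
#' The core motif catalog: K50 (TAATCC), Q50 (TAATTR), the five per-Rh RCSI
#' variants, the RCSI consensus relatives (P3), the Rh4 RCSII, ATTC, and
#' placeholder consensus entries for XRE, S-box and Seq56 (their exact
#' sequences are not established; replace for real scans).
#'
#' @param include_rcsi_consensus if TRUE, add a generic "RCSI_consensus"
#'   (TAATYNRATTN) entry tagged as an RCSI-class motif. Off by default so
#'   that promoters carrying one named RCSI variant anchor unambiguously.
#' @return a `motif_catalog`.
#' @export
rh_motif_catalog <- function(include_rcsi_consensus = FALSE) {
  cat_ <- read_motif_catalog(extdata("motif_catalog.json"))
  if (isTRUE(include_rcsi_consensus)) {
    m <- motif_def("RCSI_consensus", "consensus", consensus = "TAATYNRATTN",
                   role = "activator", bound_factors = c("Otd", "Pph13"),
                   region_class = "proximal", element = "RCSI")
    cat_[[m$name]] <- m
  }
  cat_
}

#' Bundled synthetic PWM store
#'
#' Synthetic stand-in matrices for the Otd-like (K50) and Pph13-like (Q50)
#' homeodomain binding preferences, in JASPAR-style text under
#' `inst/extdata/pwm/`. They are labelled synthetic: real matrices (e.g.
#' from FlyFactorSurvey) can be dropped into any directory and loaded with
#' [read_pwm_store()].
#'
#' @return named list of [pwm()] objects (OTD_SYN, PPH13_SYN).
#' @export
rh_pwm_store <- function() {
  read_pwm_store(extdata("pwm"))
}

#' Printed primer tables
#'
#' @param which "minimal" for the minimal-promoter amplification primers
#'   (one forward/reverse pair flanking each promoter) or "swap" for the
#'   site-directed mutagenesis primer pairs of the RCSI/RCSII swap
#'   constructs (each pair mutually reverse-complementary).
#' @return data.frame.
#' @export
rh_primer_table <- function(which = c("minimal", "swap")) {
  which <- match.arg(which)
  utils::read.delim(extdata(if (which == "minimal") "primers_minimal.tsv"
                            else "primers_swap.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' RCSI variant words and the Rh4 RCSII
#'
#' The per-rhodopsin RCSI variants (each matching the RCSI consensus
#' TAATYNRATTN) and the Rh4 RCSII word, as recovered from the printed
#' construct sequences. Rh1 and Rh4 share an identical RCSI.
#'
#' @return named character vector.
#' @export
rh_rcsi_words <- function() {
  c(Rh1 = "TAATTGAATTT", Rh3 = "TAATCCAATTC", Rh4 = "TAATTGAATTT",
    Rh5 = "TAATTAGATTC", Rh6 = "TAATTGGATTA", RCSII_Rh4 = "GGTTG")
}

# neutral spacer: A/C/G only (no T), no AA run, so it can create no motif
# match on either strand at any junction
spacer <- function(n) substr(strrep("CAGCGG", ceiling(n / 6)), 1, n)

#' Synthetic stand-in minimal promoters
#'
#' The real minimal promoter sequences are not published; these stand-ins
#' are assembled purely from printed fragments — the amplification primer
#' cores as termini, the mutagenesis-primer flanks as the RCSI
#' neighbourhood (including the TATA box where covered), the RCSI variant
#' words — joined by a neutral C/G/A spacer. They reproduce every printed
#' primer match and carry each promoter's RCSI (plus the Rh4 RCSII) at
#' known coordinates, but they are synthetic: do not mistake them for the
#' genomic promoters. Real sequences can be supplied via
#' [read_promoters_fasta()] instead.
#'
#' @return named list of [promoter_record()] objects (Rh1, Rh3, Rh4, Rh5,
#'   Rh6) with explicit `rcsi` anchors (and `rcsii`/`tata` where known).
#' @export
rh_synthetic_promoters <- function() {
  rcsi <- rh_rcsi_words()
  tab1 <- rh_primer_table("minimal")
  head_of <- function(rh) {
    toupper(sub("^agatct", "", tab1$forward[tab1$rh == rh]))
  }
  tail_of <- function(rh) {
    revcomp(sub("^gcggccgc", "", tab1$reverse[tab1$rh == rh]))
  }
  # RCSI neighbourhoods from the mutagenesis primer flanks
  flanks <- list(
    Rh3 = c("TAATCCCGCTGCGACAATGC", "CGATGGGCCGTATAAAAGC"),
    Rh4 = c("AACCACAAAGTC",         "GGTTGGCAGCACAAAATGCGAT"),
    Rh5 = c("GGTCACCACTTAATCCGTCT", "TTTGGCGGGCTATAAAAGCA"),
    Rh6 = c("GGCCAAGTGCCGGC",       "GGGCAATTAGTCTA"))
  flanks$Rh1 <- c(spacer(12), spacer(14))  # no mutagenesis row for Rh1
  build <- function(rh, distal_words = character()) {
    parts <- c(head_of(rh), spacer(10))
    for (w in distal_words) parts <- c(parts, w, spacer(8))
    pre_len <- sum(nchar(parts)) + nchar(flanks[[rh]][1])
    parts <- c(parts, flanks[[rh]][1], rcsi[[rh]], flanks[[rh]][2],
               spacer(10), tail_of(rh))
    sequence <- paste(parts, collapse = "")
    anchor <- c(pre_len, pre_len + nchar(rcsi[[rh]]))
    rcsii <- NULL
    tata <- NULL
    if (rh == "Rh4")  # RCSII (GGTTG) opens the downstream flank
      rcsii <- c(anchor[2], anchor[2] + 5L)
    tpos <- regexpr("TATAAAA", flanks[[rh]][2], fixed = TRUE)
    if (tpos[1] != -1) {
      t0 <- anchor[2] + as.integer(tpos) - 1L
      tata <- c(t0, t0 + 7L)
    }
    promoter_record(rh, sequence, rcsi = anchor, rcsii = rcsii, tata = tata)
  }
  list(
    Rh1 = build("Rh1"),
    Rh3 = build("Rh3", c("TAATCC", "ATTC")),
    Rh4 = build("Rh4", c("TTGCGTG", "AATCAA")),
    Rh5 = build("Rh5", c("TAATCC", "TAAGACG", "ATTC")),
    Rh6 = build("Rh6", c("TAATCC", "TAAGACG")))
}

json_pattern <- function(obj) {
  if (length(obj) == 0) return(expression_pattern())
  expression_pattern(stats::setNames(unlist(obj), names(obj)))
}

#' Bundled construct outcome table
#'
#' The observed reporter expression patterns: five wild-type minimal
#' promoters, the fourteen hybrid promoters, and the eight RCSI/RCSII swap
#' or addition constructs, with per-subtype levels.
#'
#' @param path JSON file; default the bundled table.
#' @return list with `wildtype` (named list of [expression_pattern()]s),
#'   `hybrids` and `swaps` (lists of records with `construct`, `observed`
#'   pattern, `note`, and for swaps `context`/`element`/`donor`/`mode`).
#' @export
rh_outcome_table <- function(path = extdata("outcomes.json")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  wt <- lapply(raw$wildtype, json_pattern)
  hybrids <- lapply(raw$hybrids, function(h) {
    list(construct = h$construct, observed = json_pattern(h$observed),
         kind = "hybrid", note = h$note)
  })
  swaps <- lapply(raw$swaps, function(s) {
    list(construct = s$construct, observed = json_pattern(s$observed),
         kind = if (identical(s$mode, "insert")) "rcsii_add" else "rcsi_swap",
         context = s$context, element = s$element, donor = s$donor,
         mode = s$mode, note = s$note)
  })
  list(wildtype = wt, hybrids = hybrids, swaps = swaps)
}
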