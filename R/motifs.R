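# IUPAC nucleotide codes -> base sets (N deliberately matches only A/C/G/T
# in the subject, never a literal N)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse complement of a nucleotide or IUPAC consensus string
#'
#' Plain A/C/G/T strings and IUPAC ambiguity codes are both supported
#' (R<->Y, K<->M, B<->V, D<->H swap; S, W, N are self-complementary).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements, uppercase.
#' @examples
#' revcomp("TAATCC")      # "GGATTA"
#' revcomp("TAATYNRATTN") # "NAATYNRATTA"
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]),
                 names(IUPAC_COMPLEMENT))
  if (length(bad) > 0)
    stop("illegal nucleotide code(s): ", paste(bad, collapse = ", "))
  vapply(x, function(s) {
    paste(rev(IUPAC_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Hamming distance between equal-length strings
#'
#' @param a,b strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("hamming() requires equal-length strings")
  sum(a != b)
}

#' Enumerate the concrete words matched by an IUPAC consensus
#'
#' @param consensus IUPAC string.
#' @return character vector of all A/C/G/T words matching the consensus.
#' @examples
#' consensus_words("TAATTR") # TAATTA, TAATTG
#' @export
consensus_words <- function(consensus) {
  sets <- iupac_sets(consensus)
  words <- ""
  for (s in sets) words <- as.vector(outer(words, s, paste0))
  sort(words)
}

iupac_sets <- function(consensus) {
  consensus <- toupper(consensus)
  if (nchar(consensus) == 0) stop("empty consensus")
  chars <- strsplit(consensus, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop("illegal IUPAC code(s) in consensus: ", paste(bad, collapse = ", "))
  lapply(chars, function(ch) IUPAC_SETS[[ch]])
}

#' Define a binding motif
#'
#' A motif is either an IUPAC consensus (e.g. the K50 homeodomain motif
#' TAATCC) or a reference to a position weight matrix in a PWM store.
#'
#' @param name short unique identifier (e.g. "K50", "Q50", "RCSI_Rh4").
#' @param kind "consensus" or "pwm".
#' @param consensus IUPAC string (required iff `kind = "consensus"`).
#' @param pwm_id id of a matrix in the PWM store (required iff `kind = "pwm"`).
#' @param role "activator", "repressor" or "dual".
#' @param bound_factors character vector of transcription factor names.
#' @param region_class "distal", "proximal" or "either".
#' @param element optional promoter element tag ("RCSI" or "RCSII"); motifs
#'   tagged "RCSI" are the candidates for the RCSI anchor during annotation.
#' @param placeholder logical; TRUE marks a user-supplied stand-in consensus
#'   for a motif whose exact sequence is not established.
#' @return an object of class `motif_def`.
#' @export
motif_def <- function(name, kind = c("consensus", "pwm"), consensus = NULL,
                      pwm_id = NULL, role = c("activator", "repressor", "dual"),
                      bound_factors = character(), region_class = "either",
                      element = NULL, placeholder = FALSE) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (!region_class %in% c("distal", "proximal", "either"))
    stop("region_class must be distal, proximal or either")
  if (kind == "consensus") {
    if (is.null(consensus) || !is.null(pwm_id))
      stop("consensus motifs set 'consensus' and not 'pwm_id'")
    iupac_sets(consensus)  # validates codes, rejects empty
    consensus <- toupper(consensus)
  } else {
    if (is.null(pwm_id) || !is.null(consensus))
      stop("pwm motifs set 'pwm_id' and not 'consensus'")
  }
  structure(list(name = name, kind = kind, consensus = consensus,
                 pwm_id = pwm_id, role = role,
                 bound_factors = as.character(bound_factors),
                 region_class = region_class, element = element,
                 placeholder = isTRUE(placeholder)),
            class = "motif_def")
}

#' @export
print.motif_def <- function(x, ...) {
  cat(sprintf("<motif %s: %s %s, %s, binds %s>\n", x$name, x$kind,
              if (x$kind == "consensus") x$consensus else x$pwm_id,
              x$role, paste(x$bound_factors, collapse = "/")))
  invisible(x)
}

#' Read a motif catalog from JSON
#'
#' The catalog file is a JSON object with a "motifs" array; each entry has
#' the fields of [motif_def()]. Motif names must be unique.
#'
#' @param path path to the catalog JSON.
#' @return named list of `motif_def` objects (class `motif_catalog`).
#' @export
read_motif_catalog <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$motifs)) stop("catalog JSON must contain a 'motifs' array")
  motifs <- lapply(raw$motifs, function(m) {
    motif_def(name = m$name, kind = m$kind,
              consensus = m$consensus, pwm_id = m$pwm_id,
              role = if (is.null(m$role)) "activator" else m$role,
              bound_factors = unlist(m$bound_factors),
              region_class = if (is.null(m$region_class)) "either" else m$region_class,
              element = m$element,
              placeholder = isTRUE(m$placeholder))
  })
  nm <- vapply(motifs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate motif names in catalog")
  names(motifs) <- nm
  structure(motifs, class = "motif_catalog")
}

#' Construct a position weight matrix object
#'
#' Weights are real-valued (log-odds-like) per position and base; the score
#' of a word is the sum of its per-position weights, and `max_score` is the
#' score of the per-column argmax word.
#'
#' @param id identifier.
#' @param weights 4 x L numeric matrix with rownames A, C, G, T.
#' @return object of class `pwm` with fields id, length, weights, max_score.
#' @export
pwm <- function(id, weights) {
  weights <- as.matrix(weights)
  if (!all(c("A", "C", "G", "T") %in% rownames(weights)))
    stop("weights must have rownames A, C, G, T")
  weights <- weights[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(weights) < 1) stop("pwm must have length >= 1")
  if (any(!is.finite(weights))) stop("weights must be finite for every (position, base)")
  structure(list(id = id, length = ncol(weights), weights = weights,
                 max_score = sum(apply(weights, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s: %d columns, max score %.4g, argmax %s>\n",
              x$id, x$length, x$max_score, pwm_argmax_word(x)))
  invisible(x)
}

#' Per-column argmax word of a PWM
#'
#' @param x a [pwm()] object.
#' @return the highest-scoring word (ties broken toward A < C < G < T).
#' @export
pwm_argmax_word <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(rownames(x$weights)[apply(x$weights, 2, which.max)], collapse = "")
}

#' Raw PWM score of a window
#'
#' Sum of the per-position weights for each mononucleotide of `window`.
#'
#' @param window A/C/G/T string with `nchar(window) == pwm$length`.
#' @param pwm a [pwm()] object.
#' @return numeric raw score.
#' @export
pwm_raw_score <- function(window, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  window <- toupper(window)
  chars <- strsplit(window, "")[[1]]
  if (length(chars) != pwm$length)
    stop(sprintf("window length %d does not match pwm length %d",
                 length(chars), pwm$length))
  idx <- match(chars, rownames(pwm$weights))
  if (anyNA(idx))
    stop("window must contain only A, C, G, T (no ambiguity codes)")
  sum(pwm$weights[cbind(idx, seq_along(idx))])
}

#' Normalized PWM similarity score (percent of maximum)
#'
#' Scores are expressed relative to the highest-scoring base-pair
#' configuration of the matrix, with the strongest motif represented as 100.
#' Negative percentages are possible and indicate a non-functional or
#' random site.
#'
#' @param raw raw score (sum of weights), e.g. from [pwm_raw_score()].
#' @param pwm a [pwm()] object with `max_score > 0`.
#' @return numeric percent: `100 * raw / pwm$max_score`.
#' @export
pwm_norm_score <- function(raw, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  if (pwm$max_score <= 0)
    stop("degenerate matrix: max_score must be > 0 for normalization")
  100 * raw / pwm$max_score
}

#' Read a JASPAR-style plain-text matrix
#'
#' Accepts the common 4-row format: an optional `>` header line with the
#' matrix id, then four rows labelled A, C, G, T with whitespace-separated
#' numbers, with or without surrounding square brackets.
#'
#' @param path path to the matrix file.
#' @param id optional id override; defaults to the header word or file name.
#' @return a [pwm()] object.
#' @export
read_jaspar_pwm <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- grepl("^>", lines)
  if (is.null(id)) {
    id <- if (any(header)) {
      strsplit(sub("^>\\s*", "", lines[which(header)[1]]), "\\s+")[[1]][1]
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  rows <- lines[!header]
  parse_row <- function(base) {
    ln <- rows[grepl(paste0("^\\s*", base, "\\b"), rows, ignore.case = FALSE)]
    if (length(ln) != 1) stop("expected exactly one row for base ", base)
    ln <- gsub("[][]", " ", sub(paste0("^\\s*", base), "", ln))
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }
  w <- t(vapply(c("A", "C", "G", "T"), parse_row,
                numeric(length(parse_row("A")))))
  pwm(id, w)
}

#' Load every JASPAR-style matrix in a directory
#'
#' @param dir directory containing `.jaspar` / `.pfm` / `.txt` matrix files.
#' @return named list of [pwm()] objects keyed by matrix id.
#' @export
read_pwm_store <- function(dir) {
  files <- list.files(dir, pattern = "\\.(jaspar|pfm|txt)$", full.names = TRUE)
  store <- lapply(files, read_jaspar_pwm)
  names(store) <- vapply(store, `[[`, character(1), "id")
  store
}
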