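# Seeded generators for promoters with planted motif architectures,
# multi-species alignments with controlled motif fates, and per-retina
# rhabdomere count tables. Everything is bit-reproducible given
# (recipe, seed), and the generators leave the caller's RNG state alone.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Background element of a promoter architecture
#' @param length background length in bp.
#' @return element for [promoter_architecture()].
#' @export
bg <- function(length) list(background = as.integer(length))

#' Planted-motif element of a promoter architecture
#' @param motif motif name recorded in the truth hits.
#' @param word explicit A/C/G/T word (for `strand = "-"` the word is the
#'   motif as read on the minus strand; its reverse complement is written
#'   into the forward sequence).
#' @param strand "+" or "-".
#' @return element for [promoter_architecture()].
#' @export
planted <- function(motif, word, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  list(motif = motif, word = check_sequence(word), strand = strand)
}

#' Define a promoter architecture
#'
#' An ordered list of [bg()] and [planted()] elements, emulating promoter
#' schematics where named motifs sit at defined positions in neutral
#' background.
#'
#' @param elements list of [bg()] / [planted()] elements.
#' @param gc background GC fraction in `[0, 1]`.
#' @param forbid_spurious if TRUE, [gen_promoter()] rejection-samples the
#'   background until scanning with the supplied catalog finds no motif
#'   match outside the planted intervals.
#' @return object of class `promoter_architecture`.
#' @export
promoter_architecture <- function(elements, gc = 0.4, forbid_spurious = FALSE) {
  if (length(elements) == 0) stop("architecture must have elements")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  total <- sum(vapply(elements, function(e) {
    if (!is.null(e$background)) e$background else nchar(e$word)
  }, numeric(1)))
  if (total <= 0) stop("total architecture length must be > 0")
  structure(list(elements = elements, gc = gc,
                 forbid_spurious = isTRUE(forbid_spurious)),
            class = "promoter_architecture")
}

sample_background <- function(n, gc) {
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a promoter with planted motifs
#'
#' Background is sampled i.i.d. per base at the stated GC fraction; planted
#' words are written in order. With `forbid_spurious`, the background is
#' resampled until the catalog scan finds no hit outside the planted
#' intervals (a hit nested inside a planted interval, e.g. a Q50 core
#' inside a planted RCSI, does not count as spurious).
#'
#' @param arch a [promoter_architecture()].
#' @param seed integer seed (deterministic output).
#' @param id promoter id.
#' @param catalog motif catalog used for the spurious-hit check (required
#'   when `arch$forbid_spurious`).
#' @param pwms PWM store for pwm catalog motifs.
#' @param min_norm threshold for pwm motifs in the spurious check.
#' @param max_attempts rejection-sampling bound.
#' @return list with `record` (a [promoter_record()]) and `truth`
#'   (`motif_hits` of the planted motifs with exact coordinates).
#' @export
gen_promoter <- function(arch, seed, id = "synthetic", catalog = NULL,
                         pwms = list(), min_norm = 80, max_attempts = 100) {
  stopifnot(inherits(arch, "promoter_architecture"))
  if (arch$forbid_spurious && is.null(catalog))
    stop("forbid_spurious requires a catalog to scan against")
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      pos <- 0L
      seqs <- character(0)
      truth <- list()
      for (e in arch$elements) {
        if (!is.null(e$background)) {
          seqs <- c(seqs, sample_background(e$background, arch$gc))
          pos <- pos + e$background
        } else {
          fwd <- if (e$strand == "+") e$word else revcomp(e$word)
          seqs <- c(seqs, fwd)
          truth[[length(truth) + 1L]] <- data.frame(
            motif = e$motif, start = pos, end = pos + nchar(fwd),
            strand = e$strand, word = fwd, raw_score = NA_real_,
            norm_score = NA_real_, stringsAsFactors = FALSE)
          pos <- pos + nchar(fwd)
        }
      }
      truth <- as_motif_hits(do.call(rbind, c(list(empty_hits()), truth)))
      record <- promoter_record(id, paste(seqs, collapse = ""))
      if (!arch$forbid_spurious) return(list(record = record, truth = truth))
      hits <- do.call(rbind, c(list(empty_hits()), lapply(catalog, function(m) {
        if (m$kind == "consensus") scan_consensus(record$sequence, m)
        else scan_pwm(record$sequence, pwms[[m$pwm_id]], min_norm = min_norm,
                      motif_name = m$name)
      })))
      contained <- vapply(seq_len(nrow(hits)), function(i) {
        any(truth$start <= hits$start[i] & hits$end[i] <= truth$end)
      }, logical(1))
      if (all(contained)) return(list(record = record, truth = truth))
    }
    stop("forbid_spurious: no clean background after ", max_attempts,
         " attempts; use longer background or fewer constraints")
  })
}

#' Define an alignment recipe with per-species motif fates
#'
#' @param species character vector of non-reference species names.
#' @param fates named list: `fates[[species]][[motif_name]]` is one of
#'   "identical", "inverted", "deleted", "unalignable" or "variant:WORD"
#'   (WORD an A/C/G/T string of the motif's length).
#' @param substitution_prob per-site background substitution probability.
#' @param indel_prob per-site background single-base deletion probability
#'   (deletions become gaps in that species; insertion columns are not
#'   generated).
#' @return object of class `alignment_recipe`.
#' @export
alignment_recipe <- function(species, fates, substitution_prob = 0,
                             indel_prob = 0) {
  if (length(species) < 1) stop("need at least one non-reference species")
  if (!setequal(names(fates), species))
    stop("fates must be specified for every non-reference species")
  if (substitution_prob < 0 || substitution_prob > 1 ||
      indel_prob < 0 || indel_prob > 1)
    stop("probabilities must be in [0, 1]")
  structure(list(species = species, fates = fates,
                 substitution_prob = substitution_prob,
                 indel_prob = indel_prob),
            class = "alignment_recipe")
}

fate_status <- c(identical = "identical", variant = "variant",
                 inverted = "inverted", deleted = "absent",
                 unalignable = "unalignable")

#' Generate a multi-species alignment with known motif fates
#'
#' Each species row is derived from the reference promoter by applying its
#' per-motif fate (keeping, substituting a variant word of equal length,
#' reverse-complementing in place, deleting to gaps, or writing the
#' unalignable marker) and i.i.d. background substitutions/deletions
#' outside the motif intervals. No insertion columns are generated, so the
#' reference row is the ungapped reference sequence.
#'
#' @param ref a [promoter_record()] whose `hits` hold the planted motif
#'   intervals (e.g. the truth hits from [gen_promoter()]).
#' @param recipe an [alignment_recipe()].
#' @param seed integer seed.
#' @param unalignable_marker see [alignment_set()].
#' @return list with `align` (an [alignment_set()], reference row named by
#'   `ref$id`) and `truth` (data.frame: species, motif, status — the
#'   conservation call implied by each fate).
#' @export
gen_alignment <- function(ref, recipe, seed, unalignable_marker = "=") {
  stopifnot(inherits(ref, "promoter_record"),
            inherits(recipe, "alignment_recipe"))
  hits <- ref$hits
  if (nrow(hits) == 0) stop("ref must carry truth hits for planted motifs")
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  n <- length(ref_chars)
  in_motif <- rep(FALSE, n)
  for (i in seq_len(nrow(hits)))
    in_motif[(hits$start[i] + 1L):hits$end[i]] <- TRUE
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (sp in recipe$species) {
      chars <- ref_chars
      for (i in seq_len(nrow(hits))) {
        motif <- hits$motif[i]
        fate <- recipe$fates[[sp]][[motif]]
        if (is.null(fate))
          stop("no fate for motif '", motif, "' in species '", sp, "'")
        span <- (hits$start[i] + 1L):hits$end[i]
        L <- length(span)
        if (startsWith(fate, "variant:")) {
          word <- check_sequence(sub("^variant:", "", fate))
          if (nchar(word) != L)
            stop("variant word length != motif length for ", motif)
          chars[span] <- strsplit(word, "")[[1]]
          kind <- "variant"
        } else {
          kind <- match.arg(fate, names(fate_status))
          if (kind == "inverted") {
            chars[span] <- strsplit(revcomp(paste(chars[span], collapse = "")),
                                    "")[[1]]
          } else if (kind == "deleted") {
            chars[span] <- "-"
          } else if (kind == "unalignable") {
            chars[span] <- unalignable_marker
          }
        }
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, motif = motif, status = fate_status[[kind]],
          stringsAsFactors = FALSE)
      }
      bgp <- which(!in_motif)
      if (recipe$substitution_prob > 0 && length(bgp) > 0) {
        sub_at <- bgp[stats::runif(length(bgp)) < recipe$substitution_prob]
        for (j in sub_at)
          chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
      }
      if (recipe$indel_prob > 0 && length(bgp) > 0) {
        del_at <- bgp[stats::runif(length(bgp)) < recipe$indel_prob]
        chars[del_at] <- "-"
      }
      rows[[sp]] <- paste(chars, collapse = "")
    }
    rows[[ref$id]] <- ref$sequence
    align <- alignment_set(unlist(rows), reference = ref$id,
                           unalignable_marker = unalignable_marker)
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(align = align, truth = truth)
  })
}

#' Define a count-table recipe
#'
#' @param construct construct name.
#' @param p named vector of per-marker co-expression probabilities in
#'   `[0, 1]` (names from Rh3/Rh4/Rh5/Rh6/R1_6).
#' @param n_retinas number of retinas N (>= 1).
#' @param rhabdomeres per-retina marker rhabdomere count: a fixed integer,
#'   or `list(poisson = mean)` for Poisson-distributed counts.
#' @param region_mix named probabilities over dorsal_third/central/ventral
#'   used to split each retina's rhabdomeres into scoring regions.
#' @return object of class `count_recipe`.
#' @export
count_recipe <- function(construct, p, n_retinas = 10, rhabdomeres = 80,
                         region_mix = c(dorsal_third = 1/3, central = 1/3,
                                        ventral = 1/3)) {
  if (is.null(names(p)) || !all(names(p) %in% MARKERS))
    stop("p must be named by markers: ", paste(MARKERS, collapse = ", "))
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  if (n_retinas < 1) stop("n_retinas must be >= 1")
  if (!setequal(names(region_mix), REGIONS))
    stop("region_mix must cover ", paste(REGIONS, collapse = ", "))
  structure(list(construct = construct, p = p, n_retinas = n_retinas,
                 rhabdomeres = rhabdomeres,
                 region_mix = region_mix[REGIONS] / sum(region_mix)),
            class = "count_recipe")
}

marker_layer <- c(Rh3 = "R7", Rh4 = "R7", Rh5 = "R8", Rh6 = "R8",
                  R1_6 = "R8")

#' Generate a rhabdomere count table with known co-expression probabilities
#'
#' For each retina and marker, the marker rhabdomere count is drawn from
#' the stated distribution, split into retinal regions by the region mix,
#' and the GFP-positive count per region is Binomial(n_marker, p(marker)).
#'
#' @param recipe a [count_recipe()].
#' @param seed integer seed.
#' @return a [count_records()] data frame.
#' @export
gen_counts <- function(recipe, seed) {
  stopifnot(inherits(recipe, "count_recipe"))
  with_seed(seed, {
    out <- list()
    for (r in seq_len(recipe$n_retinas)) {
      rid <- sprintf("%s_retina%02d", recipe$construct, r)
      for (m in names(recipe$p)) {
        total <- if (is.list(recipe$rhabdomeres)) {
          stats::rpois(1, recipe$rhabdomeres$poisson)
        } else {
          as.integer(recipe$rhabdomeres)
        }
        by_region <- as.integer(stats::rmultinom(1, total, recipe$region_mix))
        for (k in seq_along(REGIONS)) {
          nm <- by_region[k]
          out[[length(out) + 1L]] <- data.frame(
            retina_id = rid, construct = recipe$construct,
            layer = marker_layer[[m]], marker = m, region = REGIONS[k],
            n_marker = nm,
            n_gfp = if (nm > 0) stats::rbinom(1, nm, recipe$p[[m]]) else 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, out)
    count_records(df$retina_id, df$construct, df$layer, df$marker, df$region,
                  df$n_marker, df$n_gfp)
  })
}
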