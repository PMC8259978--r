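# Combinatorial motif -> photoreceptor-subtype expression logic.
#
# Five photoreceptor subtypes carry one rhodopsin each: R1-R6 (Rh1),
# pale R7 (Rh3), yellow R7 (Rh4), pale R8 (Rh5), yellow R8 (Rh6).

#' The five photoreceptor subtypes
#' @export
SUBTYPES <- c("R1_6", "pR7", "yR7", "pR8", "yR8")

#' Expression levels a subtype can show
#' @export
EXPRESSION_LEVELS <- c("none", "weak", "strong", "partial", "variable")

#' The five hybrid outcome categories
#' @export
OUTCOME_CATEGORIES <- c("interchangeable_consistent", "partial", "silent",
                        "additive", "broadened_novel")

#' Create a per-subtype expression pattern
#'
#' @param ... named levels (subtype = level); unnamed subtypes default to
#'   "none". Alternatively pass a single named character vector.
#' @return named character vector over the five subtypes, class
#'   `expression_pattern`.
#' @examples
#' expression_pattern(pR7 = "strong")
#' @export
expression_pattern <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && !is.null(names(args[[1]])))
    args <- as.list(args[[1]])
  pat <- stats::setNames(rep("none", length(SUBTYPES)), SUBTYPES)
  if (length(args) > 0) {
    bad <- setdiff(names(args), SUBTYPES)
    if (length(bad) > 0) stop("unknown subtype(s): ", paste(bad, collapse = ", "))
    lv <- unlist(args)
    if (!all(lv %in% EXPRESSION_LEVELS))
      stop("levels must be one of ", paste(EXPRESSION_LEVELS, collapse = ", "))
    pat[names(args)] <- lv
  }
  structure(pat, class = "expression_pattern")
}

#' Subtypes with any expression (level != "none")
#'
#' Variable and weak expression count as presence.
#'
#' @param pattern an [expression_pattern()].
#' @return character vector of present subtypes.
#' @export
presence_set <- function(pattern) {
  names(pattern)[pattern != "none"]
}

#' @export
print.expression_pattern <- function(x, ...) {
  glyph <- c(none = ".", weak = "+", strong = "++", partial = "+/..",
             variable = "+/-")
  cat(paste(sprintf("%s:%s", names(x), glyph[unclass(x)]), collapse = "  "),
      "\n")
  invisible(x)
}

#' Read the transcription-factor expression model from JSON
#'
#' The model lists, per factor, its activity (activator/repressor), its
#' expression level (off/low/high) in each of the five subtypes, and the
#' motif classes it binds. The default model bundles the known regulators:
#' broad activators Otd (K50) and Pph13 (Q50), the yR7 activator Ss (XRE),
#' and the repressors Dve (K50; high in R1-R6, low in yR7), Pros (Seq56,
#' R7s), Sens (S-box, R8s) and the unidentified "y" repressor (ATTC).
#'
#' @param path JSON file; default the bundled model.
#' @return list of class `tf_model`: per-factor list(activity, expression,
#'   motifs).
#' @export
read_tf_model <- function(path = system.file("extdata", "tf_model.json",
                                             package = "rhocis")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  model <- lapply(raw$factors, function(f) {
    expr <- stats::setNames(rep("off", length(SUBTYPES)), SUBTYPES)
    got <- unlist(f$expression)
    bad <- setdiff(names(got), SUBTYPES)
    if (length(bad) > 0) stop("unknown subtype in tf model: ", bad[1])
    expr[names(got)] <- got
    list(activity = match.arg(f$activity, c("activator", "repressor")),
         expression = expr, motifs = unlist(f$motifs))
  })
  names(model) <- vapply(raw$factors, `[[`, character(1), "name")
  structure(model, class = "tf_model")
}

# map a hit's motif name to the motif classes a TF model knows about.
# RCSI variants contain sub-motifs; annotation-based prediction works off
# the individual sub-motif hits (K50, Q50, ...), so the mapping here is by
# motif name with RCSI_*/RCSII_* entries carrying no class of their own.
motif_class_of <- function(motif_names) {
  cls <- sub("_.*$", "", motif_names)
  cls[cls %in% c("RCSI", "RCSII", "P3")] <- NA_character_
  cls
}

#' Baseline motif-presence expression predictor
#'
#' Predicts "strong" in a subtype iff at least one hit binds an activator
#' expressed there and no hit binds a repressor expressed there ("expressed"
#' means level != off, so Dve counts in both its high (R1-R6) and low (yR7)
#' subtypes). This predictor is deliberately a baseline: motif presence
#' alone under-determines the real patterns, and its disagreements with
#' observed patterns are the point, not a defect to patch.
#'
#' @param promoter an annotated [promoter_record()] (hits populated), or a
#'   character vector of motif class names (e.g. `c("K50","K50","ATTC")`).
#' @param model a [read_tf_model()] result.
#' @param attc_scope scope of the unidentified "y" repressor bound by ATTC
#'   motifs: "yR7" (R7-context promoters), "yR8" (R8-context), or "both".
#'   Both behaviours occur in vivo, depending on the promoter context.
#' @return an [expression_pattern()] ("strong"/"none" per subtype).
#' @export
predict_motif_logic <- function(promoter, model,
                                attc_scope = c("both", "yR7", "yR8")) {
  attc_scope <- match.arg(attc_scope)
  stopifnot(inherits(model, "tf_model"))
  classes <- if (inherits(promoter, "promoter_record")) {
    motif_class_of(promoter$hits$motif)
  } else {
    motif_class_of(as.character(promoter))
  }
  classes <- classes[!is.na(classes)]
  known <- unique(unlist(lapply(model, `[[`, "motifs")))
  unmapped <- setdiff(unique(classes), known)
  if (length(unmapped) > 0)
    warning("motif class(es) unmapped in TF model, ignored: ",
            paste(unmapped, collapse = ", "))
  activated <- repressed <- stats::setNames(rep(FALSE, length(SUBTYPES)),
                                            SUBTYPES)
  for (tf in names(model)) {
    f <- model[[tf]]
    if (!any(classes %in% f$motifs)) next
    expressed_in <- names(f$expression)[f$expression != "off"]
    if (all(f$motifs == "ATTC") && attc_scope != "both")
      expressed_in <- intersect(expressed_in, attc_scope)
    if (f$activity == "activator") {
      activated[expressed_in] <- TRUE
    } else {
      repressed[expressed_in] <- TRUE
    }
  }
  lv <- ifelse(activated & !repressed, "strong", "none")
  expression_pattern(stats::setNames(lv, SUBTYPES))
}

parse_hybrid_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("hybrid name must be '<distal>-<proximal>': ", name)
  stats::setNames(parts, c("distal", "proximal"))
}

#' Interchangeable-core model prediction for a hybrid
#'
#' Under the interchangeable-core (bipartite promoter) model the proximal
#' core only provides general activation, so a hybrid is predicted to
#' reproduce the wild-type pattern of the rhodopsin that contributed its
#' distal region.
#'
#' @param hybrid_name "<distal>-<proximal>" construct name.
#' @param wt_patterns named list of wild-type [expression_pattern()]s.
#' @return the distal donor's wild-type pattern.
#' @export
predict_interchangeable <- function(hybrid_name, wt_patterns) {
  donors <- parse_hybrid_name(hybrid_name)
  if (!donors[["distal"]] %in% names(wt_patterns))
    stop("unknown distal donor: ", donors[["distal"]])
  wt_patterns[[donors[["distal"]]]]
}

#' Classify an observed hybrid outcome
#'
#' Fixed rule order (first match wins):
#' 1. no presence anywhere -> "silent";
#' 2. presence set equals the distal donor's presence set and every present
#'    level is "strong" -> "interchangeable_consistent";
#' 3. presence set is a subset of the distal donor's and some present level
#'    is "partial" or "weak" -> "partial";
#' 4. presence set equals the union of the two donors' presence sets and
#'    differs from the distal donor's -> "additive";
#' 5. otherwise -> "broadened_novel".
#'
#' @param observed observed [expression_pattern()].
#' @param distal_wt,proximal_wt wild-type patterns of the two donors.
#' @return one of [OUTCOME_CATEGORIES].
#' @export
classify_outcome <- function(observed, distal_wt, proximal_wt) {
  obs <- presence_set(observed)
  dis <- presence_set(distal_wt)
  pro <- presence_set(proximal_wt)
  if (length(obs) == 0) return("silent")
  if (setequal(obs, dis) && all(observed[obs] == "strong"))
    return("interchangeable_consistent")
  if (all(obs %in% dis) && any(observed[obs] %in% c("partial", "weak")))
    return("partial")
  if (setequal(obs, union(dis, pro)) && !setequal(obs, dis))
    return("additive")
  "broadened_novel"
}

#' Evaluate the interchangeable-core model against observed outcomes
#'
#' Classifies each hybrid outcome, tabulates category counts, and reports
#' how many hybrids deviate from the interchangeable-core prediction (all
#' categories except "interchangeable_consistent" deviate).
#'
#' @param hybrid_outcomes list of outcome records: each a list with
#'   `construct` ("<distal>-<proximal>") and `observed`
#'   ([expression_pattern()]); see [rh_outcome_table()].
#' @param wt_patterns named list of wild-type patterns.
#' @return list of class `model_evaluation`: `counts` (named integer vector
#'   over [OUTCOME_CATEGORIES]), `n_total`, `n_deviating`, and `table`
#'   (data.frame: construct, category, interchangeable_correct).
#' @export
evaluate_models <- function(hybrid_outcomes, wt_patterns) {
  counts <- stats::setNames(integer(length(OUTCOME_CATEGORIES)),
                            OUTCOME_CATEGORIES)
  rows <- lapply(hybrid_outcomes, function(rec) {
    donors <- parse_hybrid_name(rec$construct)
    cat_ <- classify_outcome(rec$observed,
                             wt_patterns[[donors[["distal"]]]],
                             wt_patterns[[donors[["proximal"]]]])
    data.frame(construct = rec$construct, category = cat_,
               interchangeable_correct = cat_ == "interchangeable_consistent",
               stringsAsFactors = FALSE)
  })
  table <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(construct = character(), category = character(),
               interchangeable_correct = logical())
  tab <- table(factor(table$category, levels = OUTCOME_CATEGORIES))
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, n_total = nrow(table),
                 n_deviating = nrow(table) - counts[["interchangeable_consistent"]],
                 table = table),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("Hybrid outcome classification (%d constructs):\n", x$n_total))
  for (k in names(x$counts))
    cat(sprintf("  %-27s %d\n", k, x$counts[[k]]))
  cat(sprintf("  deviating from interchangeable-core model: %d/%d\n",
              x$n_deviating, x$n_total))
  invisible(x)
}

#' Per-subtype agreement between a predicted and an observed pattern
#'
#' @param predicted,observed [expression_pattern()]s.
#' @return list with `per_subtype` (named vector over subtypes with values
#'   "match", "false_positive" or "false_negative") and `exact` (logical:
#'   all five match in presence).
#' @export
compare_prediction <- function(predicted, observed) {
  p <- SUBTYPES %in% presence_set(predicted)
  o <- SUBTYPES %in% presence_set(observed)
  per <- ifelse(p == o, "match", ifelse(p & !o, "false_positive",
                                        "false_negative"))
  list(per_subtype = stats::setNames(per, SUBTYPES), exact = all(p == o))
}
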