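# Per-retina reporter co-expression quantification and Mann-Whitney
# comparisons. The unit of analysis is the per-retina percentage of
# marker-positive rhabdomeres that co-express the reporter.

REGIONS <- c("dorsal_third", "central", "ventral")
LAYERS <- c("R7", "R8")
MARKERS <- c("Rh3", "Rh4", "Rh5", "Rh6", "R1_6")

#' Create a rhabdomere count table
#'
#' @param retina_id,construct,layer,marker,region,n_marker,n_gfp vectors
#'   (recycled to equal length). `layer` in R7/R8, `region` in
#'   dorsal_third/central/ventral, `0 <= n_gfp <= n_marker`.
#' @return data.frame of class `count_records`.
#' @export
count_records <- function(retina_id, construct, layer, marker, region,
                          n_marker, n_gfp) {
  df <- data.frame(retina_id = as.character(retina_id),
                   construct = as.character(construct),
                   layer = as.character(layer), marker = as.character(marker),
                   region = as.character(region),
                   n_marker = as.integer(n_marker),
                   n_gfp = as.integer(n_gfp), stringsAsFactors = FALSE)
  if (!all(df$layer %in% LAYERS)) stop("layer must be R7 or R8")
  if (!all(df$region %in% REGIONS))
    stop("region must be one of ", paste(REGIONS, collapse = ", "))
  if (any(df$n_marker < 0)) stop("n_marker must be >= 0")
  if (any(df$n_gfp < 0 | df$n_gfp > df$n_marker))
    stop("n_gfp must satisfy 0 <= n_gfp <= n_marker")
  class(df) <- c("count_records", "data.frame")
  df
}

#' Read a rhabdomere count table from CSV
#'
#' Expected columns: retina_id, construct, layer, marker, region,
#' n_marker, n_gfp.
#'
#' @param path CSV file.
#' @return a [count_records()] data frame.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  count_records(df$retina_id, df$construct, df$layer, df$marker, df$region,
                df$n_marker, df$n_gfp)
}

#' Apply the scoring-region filter
#'
#' R7-layer records from the dorsal third are excluded: dorsal-third yR7
#' ommatidia co-express Rh3 and Rh4, which would be confounded with
#' reporter derepression. R8-layer records are kept in all regions.
#'
#' @param records a [count_records()] data frame.
#' @return the filtered records.
#' @export
filter_region <- function(records) {
  keep <- !(records$layer == "R7" & records$region == "dorsal_third")
  records[keep, , drop = FALSE]
}

#' Summarize per-retina reporter co-expression for one construct and marker
#'
#' Per retina, the percentage is `100 * n_gfp / n_marker` pooled over that
#' retina's records; the summary reports the mean over retinas and the
#' standard error of the mean (sample sd, denominator N-1, divided by
#' sqrt(N)). Retinas with zero marker rhabdomeres are dropped with a
#' warning; a single qualifying retina reports `sem_pct = 0` with a
#' degenerate-N warning.
#'
#' @param records [count_records()], already region-filtered as desired
#'   (see [filter_region()]).
#' @param construct,marker selection.
#' @return object of class `coexpression_summary`: construct, marker, N
#'   (retinas), n (total marker rhabdomeres), per_retina_pct, mean_pct,
#'   sem_pct.
#' @export
summarize_coexpression <- function(records, construct, marker) {
  sel <- records[records$construct == construct & records$marker == marker, ,
                 drop = FALSE]
  if (nrow(sel) == 0)
    stop("no records for construct '", construct, "', marker '", marker, "'")
  n_marker <- tapply(sel$n_marker, sel$retina_id, sum)
  n_gfp <- tapply(sel$n_gfp, sel$retina_id, sum)
  if (any(n_marker == 0)) {
    warning(sum(n_marker == 0),
            " retina(s) with zero marker rhabdomeres dropped")
    keep <- n_marker > 0
    n_marker <- n_marker[keep]; n_gfp <- n_gfp[keep]
  }
  if (length(n_marker) == 0) stop("no qualifying retinas")
  pct <- 100 * n_gfp / n_marker
  N <- length(pct)
  sem <- if (N == 1) {
    warning("single retina: sem reported as 0 (degenerate N)")
    0
  } else {
    stats::sd(pct) / sqrt(N)
  }
  structure(list(construct = construct, marker = marker, N = N,
                 n = sum(n_marker), per_retina_pct = as.numeric(pct),
                 mean_pct = mean(pct), sem_pct = sem),
            class = "coexpression_summary")
}

#' @export
print.coexpression_summary <- function(x, ...) {
  cat(sprintf("%s / %s: mean %.1f%% GFP co-expression (s.e.m. %.2f), N = %d retinas, n = %d rhabdomeres\n",
              x$construct, x$marker, x$mean_pct, x$sem_pct, x$N, x$n))
  invisible(x)
}

#' @export
plot.coexpression_summary <- function(x, ..., col = "darkgreen") {
  bp <- graphics::barplot(x$mean_pct, ylim = c(0, 110), col = col,
                          names.arg = paste(x$construct, x$marker, sep = " / "),
                          ylab = "GFP co-expression (%)", ...)
  graphics::arrows(bp, x$mean_pct - x$sem_pct, bp, x$mean_pct + x$sem_pct,
                   angle = 90, code = 3, length = 0.08)
  graphics::text(bp, min(x$mean_pct + x$sem_pct + 6, 108),
                 sprintf("%.1f", x$mean_pct), col = col)
  invisible(bp)
}

#' Mann-Whitney U test between two groups
#'
#' U is computed from rank sums with ties sharing mid-ranks. When the data
#' contain no ties and `max(n1, n2) <= 12` the two-sided p-value is exact
#' (the full permutation distribution over C(n1+n2, n1) arrangements);
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. Computation is delegated to
#' [stats::wilcox.test()], whose exact and corrected-normal paths implement
#' exactly these two methods.
#'
#' @param a,b numeric vectors (non-empty), e.g. per-retina percentages of
#'   two reporter constructs.
#' @return object of class `mw_result`: U (for group `a`), n1, n2, method
#'   ("exact" or "normal_tie_corrected"), p_two_sided.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && max(n1, n2) <= 12
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  structure(list(U = unname(wt$statistic), n1 = n1, n2 = n2,
                 method = if (use_exact) "exact" else "normal_tie_corrected",
                 p_two_sided = min(wt$p.value, 1)),
            class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}
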