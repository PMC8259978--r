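catalog <- rh_motif_catalog()

test_that("promoter generation plants motifs at exact coordinates, reproducibly", {
  arch <- promoter_architecture(
    list(bg(4), planted("RCSI_Rh4", "TAATTGAATTT"), bg(3)), gc = 0.5)
  gp <- gen_promoter(arch, seed = 1)
  expect_equal(nchar(gp$record$sequence), 18)
  expect_equal(gp$truth$start, 4)
  expect_equal(gp$truth$end, 15)
  expect_equal(substr(gp$record$sequence, 5, 15), "TAATTGAATTT")
  expect_identical(gen_promoter(arch, seed = 1)$record$sequence,
                   gp$record$sequence)
  expect_false(identical(gen_promoter(arch, seed = 2)$record$sequence,
                         gp$record$sequence))
})

test_that("minus-strand plants write the reverse complement forward", {
  arch <- promoter_architecture(
    list(bg(6), planted("K50", "TAATCC", strand = "-"), bg(6)), gc = 1)
  gp <- gen_promoter(arch, seed = 4)
  expect_equal(substr(gp$record$sequence, 7, 12), "GGATTA")
  h <- scan_consensus(gp$record$sequence, catalog$K50)
  expect_equal(h$strand, "-")
  expect_equal(h$start, gp$truth$start)
})

test_that("forbid_spurious yields promoters whose scan equals the truth set", {
  arch <- promoter_architecture(
    list(bg(25), planted("K50", "TAATCC"), bg(20), planted("Q50", "TAATTG"),
         bg(25)), gc = 0.45, forbid_spurious = TRUE)
  sub_catalog <- catalog[c("K50", "Q50")]
  for (seed in 1:10) {
    gp <- gen_promoter(arch, seed = seed, catalog = sub_catalog)
    hits <- do.call(rbind, lapply(sub_catalog, function(m)
      scan_consensus(gp$record$sequence, m)))
    expect_equal(sort(hits$start), sort(gp$truth$start))
    expect_setequal(hits$word, gp$truth$word)
  }
  expect_error(gen_promoter(arch, seed = 1), "catalog")
  # an impossible constraint fails with advice rather than looping forever:
  # at gc = 0 every background base is A or T and so matches the W motif
  tight <- promoter_architecture(list(planted("W1", "A"), bg(2)),
                                 gc = 0, forbid_spurious = TRUE)
  w1 <- list(W1 = motif_def("W1", "consensus", consensus = "W"))
  expect_error(gen_promoter(tight, seed = 1, catalog = w1, max_attempts = 5),
               "attempts")
})

test_that("alignment generation realizes every requested fate", {
  arch <- promoter_architecture(list(bg(20), planted("Q50", "TAATTG"), bg(20)),
                                gc = 1)
  gp <- gen_promoter(arch, seed = 6)
  ref <- gp$record; ref$hits <- gp$truth; ref$id <- "Dmel"
  recipe <- alignment_recipe(
    paste0("sp", 1:5),
    fates = list(sp1 = list(Q50 = "identical"),
                 sp2 = list(Q50 = "variant:TAATTA"),
                 sp3 = list(Q50 = "inverted"),
                 sp4 = list(Q50 = "deleted"),
                 sp5 = list(Q50 = "unalignable")))
  ga <- gen_alignment(ref, recipe, seed = 8)
  # zero noise: the identical species equals the reference row
  expect_equal(ga$align$rows[["sp1"]], ref$sequence)
  calls <- call_conservation(ga$align, gp$truth[1, ], catalog$Q50, window = 10)
  merged <- merge(calls, ga$truth, by = "species")
  expect_equal(merged$status.x, merged$status.y)
  # determinism
  expect_identical(gen_alignment(ref, recipe, seed = 8)$align$rows,
                   ga$align$rows)
  expect_error(
    gen_alignment(ref, alignment_recipe("sp1",
                                        list(sp1 = list(Q50 = "variant:TA"))),
                  seed = 1),
    "length")
})

test_that("count generation respects degenerate probabilities and the seed", {
  all_on <- gen_counts(count_recipe("c", c(Rh4 = 1), n_retinas = 5), seed = 2)
  expect_true(all(all_on$n_gfp == all_on$n_marker))
  all_off <- gen_counts(count_recipe("c", c(Rh4 = 0), n_retinas = 5), seed = 2)
  expect_true(all(all_off$n_gfp == 0))
  expect_identical(gen_counts(count_recipe("c", c(Rh6 = 0.4)), seed = 3),
                   gen_counts(count_recipe("c", c(Rh6 = 0.4)), seed = 3))
  pois <- gen_counts(count_recipe("c", c(Rh6 = 0.5),
                                  rhabdomeres = list(poisson = 60)), seed = 4)
  expect_gt(stats::var(tapply(pois$n_marker, pois$retina_id, sum)), 0)
})

test_that("generated counts concentrate around the recipe probability", {
  rec <- gen_counts(count_recipe("c", c(Rh6 = 0.5), n_retinas = 200,
                                 rhabdomeres = 100), seed = 5)
  s <- summarize_coexpression(rec, "c", "Rh6")
  expect_gt(s$mean_pct, 48)
  expect_lt(s$mean_pct, 52)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_counts(count_recipe("c", c(Rh4 = 0.5)), seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("the full in-silico pipeline runs from generator to classification", {
  arch_for <- function(rh) promoter_architecture(
    list(bg(20), planted("K50", "TAATCC"), bg(15),
         planted(paste0("RCSI_", rh), rh_rcsi_words()[[rh]]), bg(12)),
    gc = 0.4)
  g3 <- gen_promoter(arch_for("Rh3"), seed = 31, id = "Rh3")
  g6 <- gen_promoter(arch_for("Rh6"), seed = 32, id = "Rh6")
  ann <- function(g) promoter_record(g$record$id, g$record$sequence,
                                     hits = g$truth,
                                     rcsi = unlist(g$truth[2, c("start", "end")]))
  hyb <- build_hybrid(ann(g3), ann(g6))
  expect_equal(hyb$id, "Rh3-Rh6")
  tab <- rh_outcome_table()
  pred <- predict_interchangeable(hyb$id, tab$wildtype)
  obs <- tab$hybrids[[which(vapply(tab$hybrids, `[[`, character(1),
                                   "construct") == "Rh3-Rh6")]]$observed
  expect_equal(classify_outcome(obs, tab$wildtype$Rh3, tab$wildtype$Rh6),
               "broadened_novel")
  expect_false(compare_prediction(pred, obs)$exact)
})

test_that("power to detect a 0.5 vs 0.9 co-expression difference is high at N = 10", {
  n_sim <- 200
  rejections <- 0
  for (i in seq_len(n_sim)) {
    a <- gen_counts(count_recipe("a", c(Rh6 = 0.5)), seed = 1000 + i)
    b <- gen_counts(count_recipe("b", c(Rh6 = 0.9)), seed = 5000 + i)
    pa <- summarize_coexpression(a, "a", "Rh6")$per_retina_pct
    pb <- summarize_coexpression(b, "b", "Rh6")$per_retina_pct
    if (mann_whitney(pa, pb)$p_two_sided < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_sim, 0.8)
})
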