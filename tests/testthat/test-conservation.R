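q50 <- motif_def("Q50", "consensus", consensus = "TAATTR")

toy_alignment <- function(rows, ref = names(rows)[1]) {
  alignment_set(unlist(rows), reference = ref)
}

test_that("reference intervals lift through gaps to minimal column spans", {
  al <- toy_alignment(c(ref = "TA-AT", sp = "TACAT"))
  expect_equal(map_ref_interval(al, 0, 4), c(0L, 5L))
  al2 <- toy_alignment(c(ref = "TAAT", sp = "TAAT"))
  expect_equal(map_ref_interval(al2, 1, 3), c(1L, 3L))  # gap-free: identity
  al3 <- toy_alignment(c(ref = "--TAAT", sp = "GGTAAT"))
  expect_equal(map_ref_interval(al3, 0, 2), c(2L, 4L))
  expect_error(map_ref_interval(al3, 0, 9), "out of range")
  # round trip: ungapped slice of the returned columns is the ref substring
  al4 <- toy_alignment(c(ref = "A-CG--TA", sp = "AACGGGTA"))
  for (st in 0:4) for (en in (st + 1):5) {
    cols <- map_ref_interval(al4, st, en)
    slice <- substr(al4$rows[["ref"]], cols[1] + 1, cols[2])
    expect_equal(gsub("-", "", slice),
                 substr(reference_sequence(al4), st + 1, en))
  }
})

test_that("fate calling follows the fixed rule order", {
  ref_hit <- data.frame(start = 4, end = 10)
  mk <- function(word) paste0("GGGC", word, "CCGGA")
  al <- toy_alignment(c(
    Dmel = mk("TAATTG"),
    same = mk("TAATTG"),          # identical
    vari = mk("TAATTA"),          # consensus variant
    invr = mk(revcomp("TAATTG")), # inverted in place
    lost = mk("GGGGGG"),          # no match anywhere
    unal = paste0("GGGC", "======", "CCGGA")))
  calls <- call_conservation(al, ref_hit, q50, window = 3)
  expect_equal(calls$status[match(c("same", "vari", "invr", "lost", "unal"),
                                  calls$species)],
               c("identical", "variant", "inverted", "absent", "unalignable"))
  expect_equal(calls$word[calls$species == "vari"], "TAATTA")
  expect_equal(calls$strand[calls$species == "invr"], "-")
  # pwm-only motifs cannot drive consensus-based fate calling
  pm <- motif_def("m", "pwm", pwm_id = "X")
  expect_error(call_conservation(al, ref_hit, pm), "consensus")
})

test_that("position shifts within the window are recognized with offset", {
  #            0123456789
  ref <- "GGGCTAATTGCCGGACGG"
  shifted2 <- "GGTAATTGCCCCGGACGG"  # motif two bp upstream in this species
  al <- toy_alignment(c(Dmel = ref, sp = shifted2))
  calls <- call_conservation(al, data.frame(start = 4, end = 10), q50,
                             window = 5)
  expect_equal(calls$status, "shifted")
  expect_equal(calls$offset, -2L)
  # window 0 disables the shifted search
  calls0 <- call_conservation(al, data.frame(start = 4, end = 10), q50,
                              window = 0)
  expect_equal(calls0$status, "absent")
})

test_that("calls are stable under species reordering", {
  mk <- function(word) paste0("GGGC", word, "CCGGA")
  rows <- c(Dmel = mk("TAATTG"), a = mk("TAATTA"), b = mk("GGGGGG"),
            c = mk("TAATTG"))
  al1 <- toy_alignment(rows)
  al2 <- toy_alignment(rows[c("Dmel", "c", "b", "a")])
  ref_hit <- data.frame(start = 4, end = 10)
  c1 <- call_conservation(al1, ref_hit, q50)
  c2 <- call_conservation(al2, ref_hit, q50)
  expect_equal(c1[order(c1$species), ], c2[order(c2$species), ],
               ignore_attr = TRUE)
})

test_that("variant tallies count words across species and score them", {
  mk <- function(word) paste0("GGGC", word, "CCGGA")
  rows <- c(Dmel = mk("TAATTG"),
            stats::setNames(rep(mk("TAATTG"), 8), paste0("s", 1:8)),
            stats::setNames(rep(mk("TAATTA"), 3), paste0("v", 1:3)))
  al <- toy_alignment(rows)
  calls <- call_conservation(al, data.frame(start = 4, end = 10), q50)
  tal <- tally_variants(calls, "TAATTG")
  expect_equal(tal$counts, c(TAATTA = 3L, TAATTG = 9L))  # ref counted once

  pph13 <- rh_pwm_store()$PPH13_SYN
  tal <- score_variants(tal, pph13)
  expect_equal(unname(tal$scores["TAATTG"]), 100)
  expect_lt(tal$scores[["TAATTA"]], 100)

  # all-absent calls tally to nothing
  none <- calls; none$status <- "absent"; none$word <- ""
  t0 <- tally_variants(none, "TAATTG", include_reference = FALSE)
  expect_length(t0$counts, 0)
  expect_length(score_variants(t0, pph13)$scores, 0)

  # toy matrix scoring by hand: "AT" is the argmax (100), "CA" scores 0
  toy <- pwm("toy", matrix(c(2, -1, 0, 1,   1, 0, -2, 3), nrow = 4,
                           dimnames = list(c("A", "C", "G", "T"), NULL)))
  t2 <- structure(list(counts = c(AT = 2L, CA = 1L), scores = NULL),
                  class = "variant_tally")
  t2 <- score_variants(t2, toy)
  expect_equal(unname(t2$scores), c(100, 0))
  expect_error(score_variants(structure(list(counts = c(AAA = 1L)),
                                        class = "variant_tally"), toy),
               "length")
})

test_that("aligned FASTA reader enforces equal lengths and handles markers", {
  f <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">Dmel", "TAAT-TGCC", ">sp1", "TAATCTG==",
               ">sp2", "TAAT-TGGG"), f)
  al <- read_alignment_fasta(f)
  expect_equal(al$reference, "Dmel")
  expect_equal(reference_sequence(al), "TAATTGCC")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment_fasta(f), "equal length")
})

test_that("long gap runs can be reinterpreted as unalignable stretches", {
  f <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">Dmel", "GGGCTAATTGCCGGA", ">far", "GG------------A"), f)
  al <- read_alignment_fasta(f, collapse_gap_runs = TRUE, min_run = 5)
  calls <- call_conservation(al, data.frame(start = 4, end = 10),
                             motif_def("Q50", "consensus", consensus = "TAATTR"))
  expect_equal(calls$status, "unalignable")
})
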