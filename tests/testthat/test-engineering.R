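test_that("hybrids splice at the base immediately 5' of the RCSI", {
  X <- promoter_record("X", paste0("GGGG", "TAATTGAATTT", "CCC"),
                       rcsi = c(4, 15))
  Y <- promoter_record("Y", paste0("AAAA", "TAATCCAATTCG", "TTT"),
                       rcsi = c(4, 16))
  h <- build_hybrid(X, Y)
  expect_equal(h$id, "X-Y")
  expect_equal(h$sequence, paste0("GGGG", "TAATCCAATTCG", "TTT"))
  expect_equal(h[["rcsi"]], c(4L, 16L))
  # hybrid length identity
  expect_equal(nchar(h$sequence),
               X[["rcsi"]][1] + nchar(Y$sequence) - Y[["rcsi"]][1])
  # self-hybrid is the identity on the sequence
  expect_equal(build_hybrid(X, X)$sequence, X$sequence)
  # distal-donor-first naming on the bundled promoters
  proms <- rh_synthetic_promoters()
  expect_equal(build_hybrid(proms$Rh3, proms$Rh4)$id, "Rh3-Rh4")
  noanchor <- promoter_record("Z", "ACGTACGT")
  expect_error(build_hybrid(X, noanchor), "RCSI anchor")
})

test_that("hybrids carry donor hits over with re-offset coordinates", {
  catalog <- rh_motif_catalog()
  proms <- rh_synthetic_promoters()
  d <- annotate_promoter(proms$Rh3, catalog)
  p <- annotate_promoter(proms$Rh4, catalog)
  h <- build_hybrid(d, p)
  off <- d[["rcsi"]][1] - p[["rcsi"]][1]
  # every carried proximal hit sits on the same word as in the donor
  prox <- h$hits[h$hits$start >= h[["rcsi"]][1], , drop = FALSE]
  expect_gt(nrow(prox), 0)
  for (i in seq_len(nrow(prox)))
    expect_equal(substr(h$sequence, prox$start[i] + 1, prox$end[i]),
                 prox$word[i])
  # re-annotating the hybrid reproduces the carried hit intervals
  h2 <- annotate_promoter(promoter_record(h$id, h$sequence,
                                          rcsi = h[["rcsi"]]), catalog)
  expect_true(all(paste(prox$motif, prox$start, prox$strand) %in%
                  paste(h2$hits$motif, h2$hits$start, h2$hits$strand)))
})

test_that("swap_element replaces, inserts, shifts anchors and round-trips", {
  rec <- promoter_record("ctx", paste0("GTC", "TAATTGAATTT", "GGTACG"),
                         rcsi = c(3, 14), tata = c(16, 20))
  sw <- swap_element(rec, c(3, 14), "TAATCCAATTCG")
  expect_equal(sw$sequence, paste0("GTC", "TAATCCAATTCG", "GGTACG"))
  expect_equal(sw[["rcsi"]], c(3L, 15L))
  expect_equal(sw[["tata"]], c(17L, 21L))          # shifted by +1
  # identity swap changes nothing
  expect_equal(swap_element(rec, c(3, 14), "TAATTGAATTT")$sequence,
               rec$sequence)
  # insertion at a zero-width interval lengthens and shifts downstream
  ins <- swap_element(rec, c(14, 14), "GGTTG")
  expect_equal(nchar(ins$sequence), nchar(rec$sequence) + 5)
  expect_equal(ins[["tata"]], c(21L, 25L))
  expect_equal(ins[["rcsi"]], rec[["rcsi"]])       # upstream anchor untouched
  # swap back restores the original sequence exactly
  back <- swap_element(sw, sw[["rcsi"]], "TAATTGAATTT")
  expect_equal(back$sequence, rec$sequence)
  expect_error(swap_element(rec, c(-1, 5), "AA"), "out of bounds")
  expect_error(swap_element(rec, c(5, 99), "AA"), "out of bounds")
})

test_that("mutagenesis primer pairs are mutual reverse complements", {
  swaps <- rh_primer_table("swap")
  expect_equal(nrow(swaps), 10)
  for (i in seq_len(nrow(swaps)))
    expect_equal(revcomp(swaps$reverse[i]), toupper(swaps$forward[i]),
                 label = swaps$construct[i])
})

test_that("in-silico swap constructs reproduce every printed mutagenesis primer", {
  proms <- rh_synthetic_promoters()
  words <- rh_rcsi_words()
  swaps <- rh_primer_table("swap")
  for (i in seq_len(nrow(swaps))) {
    row <- swaps[i, ]
    ctx <- proms[[row$context]]
    built <- if (row$mode == "insert") {
      swap_element(ctx, c(ctx[["rcsi"]][2], ctx[["rcsi"]][2]),
                   words[["RCSII_Rh4"]], id = row$construct)
    } else if (row$element == "RCSI+II") {
      swap_element(ctx, ctx[["rcsi"]],
                   paste0(words[[row$donor]], words[["RCSII_Rh4"]]),
                   id = row$construct)
    } else {
      swap_element(ctx, ctx[["rcsi"]], words[[row$donor]], id = row$construct)
    }
    fwd <- validate_against_primer(built, row$forward)
    rev <- validate_against_primer(built, row$reverse)
    expect_true(fwd$match, label = paste(row$construct, "forward"))
    expect_equal(fwd$orientation, "forward")
    expect_equal(rev$orientation, "revcomp")
    # the donor word sits inside the matched primer interval
    if (row$mode != "insert")
      expect_true(grepl(words[[row$donor]],
                        substr(built$sequence, fwd$start + 1, fwd$end),
                        fixed = TRUE))
  }
})

test_that("amplification primers match construct termini, adapters ignored", {
  proms <- rh_synthetic_promoters()
  tab <- rh_primer_table("minimal")
  for (i in seq_len(nrow(tab))) {
    p <- proms[[tab$rh[i]]]
    f <- validate_against_primer(p, tab$forward[i])
    r <- validate_against_primer(p, tab$reverse[i])
    expect_true(f$match && f$start == 0, label = paste(tab$rh[i], "fwd"))
    expect_true(r$match && r$orientation == "revcomp" &&
                  r$end == nchar(p$sequence), label = paste(tab$rh[i], "rev"))
  }
  # a record always matches its own prefix
  own <- validate_against_primer(proms$Rh1,
                                 substr(proms$Rh1$sequence, 1, 20))
  expect_equal(c(own$start, own$end), c(0L, 20L))
  # and a non-match is a report, not an error
  expect_false(validate_against_primer(proms$Rh1,
                                       strrep("ACGT", 10))$match)
})
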