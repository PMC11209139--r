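test_that("the three motif classes are recognised with correct priority", {
  # glutamate within three residues of the arginine: quadruplet motif
  s1 <- scan_cleavage_sites("EPVVERANC")
  expect_equal(s1$motif_kind[s1$position == 6], "quadruplet")
  expect_equal(s1$motif_seq[s1$position == 6], "VVER")

  # lone arginine with no E upstream and no basic neighbour: monobasic
  s2 <- scan_cleavage_sites("AQVVVRANC")
  expect_equal(s2$motif_kind[s2$position == 6], "monobasic")

  # adjacent basic pairs: dibasic, reported at the second residue
  for (pair in c("KR", "RR", "KK", "RK")) {
    s <- scan_cleavage_sites(paste0("AAVA", pair, "GANC"))
    hit <- s[s$position == 6, ]
    expect_equal(hit$motif_kind, "dibasic")
    expect_equal(hit$motif_seq, pair)
  }

  # quadruplet outranks dibasic when both apply at a position
  s4 <- scan_cleavage_sites("AAEKRGA")
  expect_equal(s4$motif_kind[s4$position == 5], "quadruplet")

  expect_equal(nrow(scan_cleavage_sites("AAAAAA")), 0L)
})

test_that("scanning is deterministic and complete on planted motifs", {
  set.seed(33)
  kinds <- c("quadruplet", "monobasic", "dibasic")
  alphabet <- c("A", "S", "T", "V", "L", "G", "N", "Q", "F")
  for (i in 1:30) {
    kind <- sample(kinds, 1L)
    body <- paste(sample(alphabet, 5, replace = TRUE), collapse = "")
    motif <- switch(kind,
                    quadruplet = "VVER",
                    monobasic = "R",
                    dibasic = sample(c("KR", "RR", "KK", "RK"), 1L))
    mature <- paste(sample(alphabet, 8, replace = TRUE), collapse = "")
    seqs <- paste0(body, motif, mature)
    pos <- nchar(body) + nchar(motif)
    res <- scan_cleavage_sites(seqs)
    hit <- res[res$position == pos, ]
    expect_equal(hit$motif_kind, kind)
    expect_identical(res, scan_cleavage_sites(seqs))  # rescan identical
  }
})

test_that("products are suffixes of the post-signal region with correct PTM counts", {
  tab <- toxin_precursor_table()
  r <- tab[tab$name == "U-Lampyristoxin-Ln1a", ]
  rec <- segment_precursor(r$protein, r$name, r$signal_end)
  prods <- enumerate_products(rec)
  mats <- prods[prods$label == "mature", ]
  expect_true("ANCGLCPVFCKLGFHCTANGQRCC" %in% mats$sequence)
  interm <- prods[prods$label == "propeptide_mature_intermediate", ]
  expect_equal(interm$sequence, "EPVVERANCGLCPVFCKLGFHCTANGQRCC")
  expect_equal(unique(prods$n_disulfides[
    prods$sequence %in% c(interm$sequence, "ANCGLCPVFCKLGFHCTANGQRCC")]), 3L)

  # Ln2: the mature peptide follows the monobasic arginine
  r2 <- tab[tab$name == "U-Lampyristoxin-Ln2", ]
  rec2 <- segment_precursor(r2$protein, r2$name, r2$signal_end)
  prods2 <- enumerate_products(rec2)
  expect_true(any(startsWith(
    prods2$sequence[prods2$label == "mature"], "AVSCK")))

  ps <- post_signal(rec)
  for (s in prods$sequence) expect_true(endsWith(ps, s))
  # the intermediate strictly contains every mature product
  expect_true(all(nchar(interm$sequence) > nchar(mats$sequence)))
})

test_that("cysteine-free products carry zero disulfides and no-site precursors pass through", {
  rec <- segment_precursor("MAAAGGGSSSTTTVVV", "p", 4L)
  prods <- enumerate_products(rec)
  expect_equal(prods$label, "mature")
  expect_equal(prods$sequence, post_signal(rec))
  expect_equal(prods$n_disulfides, 0L)
})

test_that("cleavage annotations round-trip through TSV", {
  ann <- scan_cleavage_sites("EPVVERANCGLCAAR")
  ann$precursor_id <- "p1"
  path <- tempfile(fileext = ".tsv")
  write_cleavage_annotations(ann, path)
  back <- read_cleavage_annotations(path)
  expect_equal(back$position, ann$position)
  expect_equal(back$motif_kind, ann$motif_kind)
  expect_equal(back$motif_seq, ann$motif_seq)
})
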