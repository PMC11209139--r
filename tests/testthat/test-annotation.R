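write_blast_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(rows, path)
  path
}

test_that("tabular BLAST parsing validates rows and flags sub-threshold hits", {
  rows <- c(
    "q1\ts1\t45.0\t80\t40\t2\t1\t80\t1\t80\t1e-20\t150\t100\t90\tsome toxin",
    "q1\ts2\t30.0\t50\t30\t1\t1\t50\t1\t50\t1e-3\t90\t100\t120\tother protein",
    "q1\tbroken\trow",
    "q2\ts3\t99.0\t100\t1\t0\t1\t100\t1\t100\t0.5\t60\t100\t100\thypothetical")
  path <- write_blast_fixture(rows)
  expect_warning(hits <- parse_blast_tab(path, "metazoa"), "malformed")
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$sub_threshold, c(FALSE, TRUE, TRUE))
  # toxprot threshold is laxer (1e-2)
  expect_warning(hits2 <- parse_blast_tab(path, "toxprot"))
  expect_equal(hits2$sub_threshold, c(FALSE, FALSE, TRUE))
  # round trip: re-serialising parsed fields reproduces the table
  expect_equal(hits$evalue, c(1e-20, 1e-3, 0.5))
  expect_equal(hits$subject_description,
               c("some toxin", "other protein", "hypothetical"))
})

test_that("accordance follows the bidirectional length-fraction formula", {
  expect_equal(accordance(100, 100, 100), 1.0)
  expect_equal(accordance(50, 100, 100), 0.25)
  expect_equal(accordance(100, 100, 200), 0.5)
  expect_error(accordance(0, 100, 100), "positive")
})

test_that("best-hit selection equals brute force over the ten-lowest-E subset", {
  one <- random_hit_list(1)
  expect_equal(select_best_hit(one)$subject_id, one$subject_id)
  expect_null(select_best_hit(one[0, ]))

  # explicit tie on accordance: the lower E-value wins
  ties <- data.frame(query_id = "q", subject_id = c("sA", "sB"),
                     alignment_length = c(50, 50),
                     query_length = c(100, 100),
                     subject_length = c(100, 100),
                     evalue = c(1e-8, 1e-6), stringsAsFactors = FALSE)
  expect_equal(select_best_hit(ties)$subject_id, "sA")

  set.seed(41)
  for (i in 1:500) {
    hits <- random_hit_list(sample(1:15, 1L))
    got <- select_best_hit(hits)
    want <- oracle_best_hit(hits)
    expect_equal(got$subject_id, want$subject_id)
    expect_equal(got$evalue, want$evalue)
  }
})

test_that("coverage is the union of PSM spans", {
  psm <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(span_start = m[, 1], span_end = m[, 2])
  }
  expect_equal(compute_coverage(100, psm(1, 7)), 7.0)
  expect_equal(compute_coverage(100, psm(1, 10, 5, 14)), 14.0)
  expect_equal(compute_coverage(100, NULL), 0)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(50:200, 1L)
    k <- sample(1:6, 1L)
    st <- sample(n, k, replace = TRUE)
    sp <- data.frame(span_start = st,
                     span_end = pmin(n, st + sample(5:30, k, replace = TRUE)))
    mask <- rep(FALSE, n)
    for (j in seq_len(k)) mask[sp$span_start[j]:sp$span_end[j]] <- TRUE
    expect_equal(compute_coverage(n, sp), 100 * mean(mask))
  }
})

test_that("quality gates are inclusive and monotone in their thresholds", {
  mk <- function(id, cov_end, score, stop = TRUE) {
    rec <- segment_precursor(paste0("M", strrep("A", 99)), id, 20L,
                             has_stop = stop)
    psm <- data.frame(precursor_id = id, span_start = 1L,
                      span_end = cov_end, score = score)
    list(rec = rec, psm = psm)
  }
  a <- mk("a", 7L, 30)    # exactly at both thresholds: kept
  b <- mk("b", 6L, 80)    # coverage 6% < 7%: rejected
  c_ <- mk("c", 50L, 29.9)
  d <- mk("d", 50L, 80, stop = FALSE)
  recs <- list(a$rec, b$rec, c_$rec, d$rec)
  psms <- rbind(a$psm, b$psm, c_$psm, d$psm)
  res <- apply_filters(recs, psms, filter_config())
  rep <- res$report
  expect_equal(rep$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(rep$reasons[2], "coverage")
  expect_match(rep$reasons[3], "score")
  expect_match(rep$reasons[4], "complete")

  # tightening thresholds never grows the kept set
  base_kept <- sum(res$report$kept)
  for (cfg in list(filter_config(min_coverage = 20),
                   filter_config(min_score = 60))) {
    expect_lte(sum(apply_filters(recs, psms, cfg)$report$kept), base_kept)
  }
})

test_that("classification follows toxin evidence plus the cysteine floor", {
  cysrich <- paste0("M", strrep("L", 19), "ANCGLCPVFCKLGFHCTANGQRCC")
  rec <- segment_precursor(cysrich, "tox1", 20L)
  toxhit <- data.frame(subject_id = "P1", subject_description = "K channel blocker",
                       evalue = 1e-4, percent_identity = 38,
                       stringsAsFactors = FALSE)
  a1 <- classify(rec, toxprot_best = toxhit)
  expect_equal(a1$functional_class, "putative_neurotoxin")

  # InterPro toxin-domain evidence alone suffices
  a2 <- classify(rec, interpro_terms = "Scorpion toxin-like domain")
  expect_equal(a2$functional_class, "putative_neurotoxin")

  # no evidence at all: novel, and cysteine-rich flagged as candidate
  a3 <- classify(rec)
  expect_equal(a3$functional_class, "novel")
  expect_true(a3$cysteine_rich_candidate)

  # toxin hit but too few cysteines: not a neurotoxin
  poor <- segment_precursor(paste0("M", strrep("L", 19), "AACAGSTV"),
                            "low", 20L)
  expect_false(classify(poor, toxprot_best = toxhit)$functional_class ==
                 "putative_neurotoxin")

  # keyword classes from metazoa descriptions
  methit <- data.frame(subject_id = "M1",
                       subject_description = "Serine peptidase S1",
                       evalue = 1e-30, percent_identity = 80,
                       stringsAsFactors = FALSE)
  a4 <- classify(poor, metazoa_best = methit)
  expect_equal(a4$functional_class, "peptidase")
})

test_that("family clustering and rational names reproduce the printed scheme", {
  tab <- toxin_precursor_table()
  ln1 <- tab[grepl("Ln1", tab$name), ]
  matures <- vapply(seq_len(nrow(ln1)), function(i) {
    mature_peptide(segment_precursor(ln1$protein[i], ln1$name[i],
                                     ln1$signal_end[i],
                                     ln1$cleavage_pos[i]))
  }, character(1L))
  ln5 <- tab[grepl("Ln5", tab$name), ]
  m5 <- vapply(seq_len(nrow(ln5)), function(i) {
    mature_peptide(segment_precursor(ln5$protein[i], ln5$name[i],
                                     ln5$signal_end[i]))
  }, character(1L))
  fam <- cluster_families(c(ln1$name, ln5$name), c(matures, m5))
  expect_equal(length(unique(fam[1:3])), 1L)   # Ln1a-c one family
  expect_equal(length(unique(fam[4:5])), 1L)   # Ln5a-b one family
  expect_false(fam[1] == fam[4])

  expect_equal(assign_toxin_name(1, isoform_rank = 1), "U-Lampyristoxin-Ln1a")
  expect_equal(assign_toxin_name(1, isoform_rank = 2), "U-Lampyristoxin-Ln1b")
  expect_equal(assign_toxin_name(2, multi_isoform = FALSE),
               "U-Lampyristoxin-Ln2")
  expect_equal(assign_toxin_name(1, novel = TRUE), "NLVC 1")
})

test_that("per-class expression aggregation matches a group-by oracle", {
  results <- data.frame(
    precursor_id = c("a", "b", "c", "d"),
    functional_class = c("putative_neurotoxin", "putative_neurotoxin",
                         "putative_neurotoxin", "peptidase"),
    stringsAsFactors = FALSE)
  tpm <- c(a = 18044, b = 13146, c = 8310, d = 50)
  agg <- aggregate_expression(results, tpm)
  expect_equal(agg$sum_tpm[agg$functional_class == "putative_neurotoxin"],
               39500)
  expect_equal(agg$functional_class[1], "putative_neurotoxin")  # sorted desc
  oracle <- tapply(tpm[results$precursor_id], results$functional_class, sum)
  expect_equal(sort(stats::setNames(agg$sum_tpm, agg$functional_class)),
               sort(c(oracle)))

  expect_equal(nrow(aggregate_expression(results[0, ], tpm)), 0L)
  expect_warning(aggregate_expression(
    data.frame(precursor_id = "zz", functional_class = "other"), tpm),
    "without tpm")
})
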