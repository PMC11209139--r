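make_peaklist <- function(mz, intensity = NULL, id = "s1", specimen = "l1") {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(mz = mz, intensity = intensity), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  load_peaklist(path, id, specimen)
}

test_that("peak lists load sorted and validated", {
  pl <- make_peaklist(c(1200.5, 900.1, 2500.0))
  expect_equal(pl$peaks$mz, c(900.1, 1200.5, 2500.0))

  empty <- tempfile(fileext = ".tsv")
  writeLines("mz\tintensity", empty)
  pl0 <- load_peaklist(empty, "s0", "l0")
  expect_equal(nrow(pl0$peaks), 0L)

  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(mz = c(1000, 1001), intensity = c(5, -1)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(pl2 <- load_peaklist(path, "s2", "l2"), "negative")
  expect_equal(nrow(pl2$peaks), 1L)

  # write-then-read round trip
  out <- tempfile(fileext = ".tsv")
  write_peaklist(pl, out)
  expect_equal(load_peaklist(out, "s1", "l1")$peaks, pl$peaks)
})

test_that("cross-spectrum clustering counts distinct spectra", {
  set.seed(5)
  # a planted signal at 2539.04 in 7 of 13 spectra, jitter within tolerance
  lists <- lapply(1:13, function(i) {
    mz <- if (i <= 7) 2539.04 + rnorm(1, 0, 0.05) else numeric()
    make_peaklist(c(mz, 3100 + i * 10), id = sprintf("s%02d", i),
                  specimen = "l1")
  })
  cl <- cluster_peaks(lists, tol_da = 0.3)
  planted <- cl[abs(cl$consensus_mz - 2539.04) < 0.3, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$occurrence, 7L)
  # the 13 well-separated singleton peaks stay singletons
  expect_equal(sum(cl$occurrence == 1L), 13L)

  # peaks further apart than the tolerance never merge
  two <- cluster_peaks(list(make_peaklist(c(2000, 2005))), tol_da = 0.5)
  expect_equal(nrow(two), 2L)
  expect_equal(two$occurrence, c(1L, 1L))

  # no peak is assigned twice
  expect_lte(sum(vapply(cl$members, nrow, integer(1L))),
             sum(vapply(lists, function(l) nrow(l$peaks), integer(1L))))
})

test_that("clustering is invariant under spectrum order", {
  set.seed(6)
  lists <- lapply(1:8, function(i) {
    make_peaklist(sort(runif(20, 800, 4500)), id = sprintf("s%02d", i),
                  specimen = "l1")
  })
  a <- cluster_peaks(lists, 0.3)
  b <- cluster_peaks(rev(lists), 0.3)
  expect_equal(a$consensus_mz, b$consensus_mz)
  expect_equal(a$occurrence, b$occurrence)
})

test_that("the ceiling-of-half reproducibility rule is exact", {
  peaks <- data.frame(consensus_mz = c(2000, 3000, 4000),
                      occurrence = c(7L, 6L, 13L), n_spectra = 13L)
  flagged <- flag_reproducible(peaks, 0.5)
  expect_equal(flagged$reproducible, c(TRUE, FALSE, TRUE))
  # full-presence requirement
  expect_equal(flag_reproducible(peaks, 1.0)$reproducible,
               c(FALSE, FALSE, TRUE))
})

test_that("mass matching respects tolerance and the acquisition window", {
  prods <- data.frame(
    precursor_id = c("ln1a", "ln3"), label = "mature",
    sequence = c("A", "B"),
    theoretical_mh = c(2539.04, 10661.77), stringsAsFactors = FALSE)
  peaks <- data.frame(consensus_mz = c(2539.0, 10661.8),
                      occurrence = c(7L, 7L), n_spectra = 13L,
                      reproducible = TRUE)
  m <- match_masses(prods, peaks, tol = 0.5, mz_window = c(800, 4500))
  expect_equal(m$precursor_id, "ln1a")
  expect_equal(m$peak_mz, 2539.0)
  # a large product outside the window is never searched
  expect_false("ln3" %in% m$precursor_id)
  # empty peak set gives empty matches
  m0 <- match_masses(prods, peaks[0, , drop = FALSE], tol = 0.5)
  expect_equal(nrow(m0), 0L)
  # ppm tolerance mode
  mp <- match_masses(prods, peaks, tol = 20, tol_unit = "ppm")
  expect_equal(nrow(mp), 1L)
})
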