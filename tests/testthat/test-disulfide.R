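test_that("PDB round trip preserves SG coordinates to 3 decimals", {
  sg <- data.frame(resno = c(2, 7), x = c(1.234, 3.284), y = c(0.5, -2.125),
                   z = c(10.001, 9.999))
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb("ACAAAACAA", sg, path, bfactor = 73.02)
  model <- parse_structure(path)
  expect_equal(nrow(model$sg), 2L)
  expect_equal(model$sg$x, sg$x, tolerance = 1e-3)
  expect_equal(model$sg$y, sg$y, tolerance = 1e-3)
  expect_equal(model$sg$z, sg$z, tolerance = 1e-3)
  expect_equal(nrow(model$residues), 9L)
  expect_equal(unname(model$confidence[1]), 73.02, tolerance = 1e-2)
})

test_that("a cysteine without an SG atom is reported unassignable", {
  sg <- data.frame(resno = 2, x = 0, y = 0, z = 0)
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb("ACAACAA", sg, path)  # CYS at 5 has no SG
  expect_warning(model <- parse_structure(path), "unassignable")
  expect_equal(model$unassignable_cys, 5)
  expect_equal(sg_distance_matrix(model), matrix(numeric(), 0, 0))
})

test_that("SG distance matrices are Euclidean and symmetric", {
  sg <- data.frame(resno = c(1, 5), x = c(0, 2.05), y = 0, z = 0)
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb("CAAACA", sg, path)
  d <- sg_distance_matrix(parse_structure(path))
  expect_equal(d["1", "5"], 2.05, tolerance = 1e-9)
  expect_equal(d, t(d), tolerance = 1e-9)

  set.seed(3)
  coords <- data.frame(resno = c(1, 3, 5, 7),
                       x = runif(4, -20, 20), y = runif(4, -20, 20),
                       z = runif(4, -20, 20))
  path2 <- tempfile(fileext = ".pdb")
  write_toy_pdb("CACACAC", coords, path2)
  d2 <- sg_distance_matrix(parse_structure(path2))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d2[i, j],
                 sqrt(sum((coords[i, c("x", "y", "z")] -
                             coords[j, c("x", "y", "z")])^2)),
                 tolerance = 2e-3)  # PDB stores 3 decimals
  }
})

test_that("bridge assignment picks the single close pair and leaves others free", {
  # four cysteines, only the 2nd and 4th within bonding distance
  d <- matrix(20, 4, 4, dimnames = list(1:4, 1:4))
  diag(d) <- 0
  d["2", "4"] <- d["4", "2"] <- 2.05
  asg <- assign_bridges(d, threshold = 2.5)
  expect_equal(asg$n_bridges, 1L)
  expect_setequal(c(asg$pairs$cys_i, asg$pairs$cys_j), c("2", "4"))
  expect_setequal(asg$free_cysteines, c("1", "3"))

  expect_equal(assign_bridges(matrix(numeric(), 0, 0))$n_bridges, 0L)
})

test_that("planted bridges are recovered exactly and matching is optimal", {
  set.seed(19)
  # planted: three bridges at 2.05 A, pairs far apart
  centers <- c(0, 100, 200)
  sg <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(resno = c(2 * k - 1, 2 * k),
               x = c(centers[k], centers[k] + 2.05), y = 0, z = 0)
  }))
  d <- as.matrix(stats::dist(sg[, c("x", "y", "z")]))
  dimnames(d) <- list(sg$resno, sg$resno)
  asg <- assign_bridges(d, 2.5)
  expect_equal(asg$n_bridges, 3L)
  expect_setequal(paste(asg$pairs$cys_i, asg$pairs$cys_j),
                  c("1 2", "3 4", "5 6"))

  # optimality vs exhaustive enumeration on random configurations
  for (rep in 1:25) {
    n <- sample(2:8, 1L)
    pts <- matrix(runif(3 * n, 0, 8), ncol = 3)
    dm <- as.matrix(stats::dist(pts))
    dimnames(dm) <- list(seq_len(n), seq_len(n))
    thr <- runif(1, 2, 6)
    got <- assign_bridges(dm, thr)
    want <- oracle_pairing(dm, thr)
    expect_equal(got$n_bridges, want$count)
    expect_equal(sum(got$pairs$sg_distance), want$total, tolerance = 1e-9)
  }
})

test_that("raising the threshold never loses bridges; rigid motions do not matter", {
  set.seed(29)
  pts <- matrix(runif(18, 0, 6), ncol = 3)
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(1:6, 1:6)
  thresholds <- c(1, 2, 3, 4, 6, 10)
  counts <- vapply(thresholds,
                   function(t) assign_bridges(dm, t)$n_bridges, integer(1L))
  expect_true(all(diff(counts) >= 0))

  # rotation + translation leaves SG distances, hence assignment, unchanged
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  pts2 <- sweep(pts %*% rot, 2, c(5, -3, 12), `+`)
  dm2 <- as.matrix(stats::dist(pts2))
  dimnames(dm2) <- list(1:6, 1:6)
  a1 <- assign_bridges(dm, 3)
  a2 <- assign_bridges(dm2, 3)
  expect_equal(a1$n_bridges, a2$n_bridges)
  expect_equal(a1$pairs[, c("cys_i", "cys_j")],
               a2$pairs[, c("cys_i", "cys_j")])
})

test_that("structural and proteomic bridge counts are reconciled honestly", {
  d <- matrix(20, 4, 4, dimnames = list(1:4, 1:4)); diag(d) <- 0
  d["2", "4"] <- d["4", "2"] <- 2.05
  asg <- assign_bridges(d, 2.5)
  # a predictor finding one bridge where the mass data show three
  r <- reconcile(asg, 3L)
  expect_false(r$concordant)
  expect_equal(r$structural_n, 1L)
  expect_true(reconcile(asg, 1L)$concordant)
  expect_true(reconcile(assign_bridges(matrix(numeric(), 0, 0)), 0L)$concordant)
})
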