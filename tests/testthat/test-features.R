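test_that("distance_matrix is a Euclidean metric on Calpha coordinates", {
  ch <- protein_chain(rbind(c(0, 0, 0), c(3, 4, 0)))
  d <- distance_matrix(ch)
  expect_equal(d[1, 2], 5)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(0, 0))
})

test_that("distance_matrix is invariant under rigid transformation", {
  set.seed(3)
  ch <- make_helix_chain(20)
  d0 <- distance_matrix(ch)
  for (rep in 1:5) {
    moved <- protein_chain(random_rigid_transform(ch$ca_coords))
    expect_equal(distance_matrix(moved), d0, tolerance = 1e-9)
  }
})

test_that("an ideal alpha-helix is assigned one long H segment", {
  ss <- assign_secondary_structure(make_helix_chain(12))
  segs <- ss$segments
  h <- segs[segs$type == "H", ]
  expect_equal(nrow(h), 1)
  expect_gte(h$end - h$start + 1, 8)
})

test_that("collinear Calpha traces are never called helix", {
  ss <- assign_secondary_structure(make_line_chain(10))
  expect_false(any(ss$labels == "H"))
  expect_true(all(ss$labels %in% c("E", "C")))
})

test_that("chains below the minimum window are all coil", {
  ss <- assign_secondary_structure(make_line_chain(4))
  expect_equal(ss$labels, rep("C", 4))
  # degenerate geometry (all atoms coincident) also yields coil
  ss2 <- assign_secondary_structure(protein_chain(matrix(0, 8, 3)))
  expect_equal(ss2$labels, rep("C", 8))
})

test_that("ss_channels encodes co-membership and +1/-1 boundaries", {
  # helix covering residues 3..6 (1-based) in a chain of 8
  ss <- secondary_structure(c("C", "C", "H", "H", "H", "H", "C", "C"))
  ch <- ss_channels(ss, 8)
  co <- ch[, , 1]
  expect_equal(co[3:6, 3:6], matrix(1, 4, 4))
  co[3:6, 3:6] <- 0
  expect_true(all(co == 0))
  b <- c(0, 0, 1, 0, 0, -1, 0, 0)
  expect_equal(ch[, , 3], matrix(b, 8, 8))
  # no strand: channels 2 and 4 are zero
  expect_true(all(ch[, , c(2, 4)] == 0))
})

test_that("residues of different segments are not co-members", {
  ss <- secondary_structure(c("H", "H", "H", "H", "C", "H", "H", "H", "H"))
  ch <- ss_channels(ss, 9)
  expect_equal(ch[1, 6, 1], 0)
  expect_equal(ch[1, 2, 1], 1)
  expect_equal(ch[6, 9, 1], 1)
})

test_that("no segments gives all-zero secondary-structure channels", {
  ch <- ss_channels(secondary_structure(rep("C", 5)), 5)
  expect_true(all(ch == 0))
})

test_that("featurize stacks distance and SS channels with scaling", {
  ch <- make_line_chain(3)
  f <- featurize(ch)
  expect_equal(dim(f), c(3, 3, 5))
  expect_equal(f[, , 1], distance_matrix(ch) / 10)
  expect_true(all(f[, , 2:5] == 0))
  raw <- featurize(ch, config = feature_config(dist_scale = 1))
  expect_equal(raw[, , 1], distance_matrix(ch))
})

test_that("featurize is invariant under rigid motion and reflection", {
  set.seed(9)
  g <- generate_chain(synthetic_spec(n_domains = 2,
                                     domain_sizes = c(20, 20)), seed = 2)
  f0 <- featurize(g$chain, g$ss)
  for (reflect in c(FALSE, TRUE)) {
    moved <- protein_chain(random_rigid_transform(g$chain$ca_coords,
                                                  reflect = reflect))
    f1 <- featurize(moved, g$ss)
    expect_lt(max(abs(f0 - f1)), 1e-9)
  }
})

test_that("STRIDE and DSSP files map onto the three-state alphabet", {
  stride <- c(
    "REM  --------------- stride output ----------------",
    "ASG  ALA A    1    1    H    AlphaHelix   -60.00    -40.00     100.0",
    "ASG  GLY A    2    2    G    310Helix     -60.00    -40.00     100.0",
    "ASG  VAL A    3    3    E    Strand      -120.00    130.00     100.0",
    "ASG  SER A    4    4    T    Turn         -70.00    -20.00     100.0")
  path <- withr::local_tempfile(fileext = ".stride")
  writeLines(stride, path)
  ss <- read_ss_file(path, "stride")
  expect_equal(ss$labels, c("H", "H", "E", "C"))

  dssp <- c(
    "==== Secondary Structure Definition ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >  S+",
    "    2    2 A G  B     -",
    "    3    3 A V  T     -")
  path2 <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp, path2)
  ss2 <- read_ss_file(path2, "dssp")
  expect_equal(ss2$labels, c("H", "E", "C"))
})
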