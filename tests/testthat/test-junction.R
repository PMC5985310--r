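# V-J junction decomposition and diversity summaries.

test_that("untrimmed joins decompose with no inserts", {
  d <- decomposeJunction("ACGTCA", "GTTTGG", "ACGTCAGTTTGG")
  expect_equal(d$v_trim, 0L)
  expect_equal(d$j_trim, 0L)
  expect_equal(d$p_v, "")
  expect_equal(d$n_region, "")
  expect_equal(d$j_retained, "GTTTGG")
})

test_that("P-nucleotides are recognized as palindromic extensions", {
  # V ends ...TCA untrimmed; TGA = revcomp(TCA) inserted before J
  d <- decomposeJunction("AAGTCA", "GTTTGG", "AAGTCATGAGTTTGG")
  expect_equal(d$p_v, "TGA")
  expect_equal(d$n_region, "")
  expect_equal(d$v_trim, 0L)
  # J-side P: revcomp(GT) = AC before an untrimmed J start
  d2 <- decomposeJunction("AAGTCC", "GTTTGG", "AAGTCCACGTTTGG")
  expect_equal(d2$p_j, "AC")
  expect_equal(d2$n_region, "")
})

test_that("decomposition equals the exhaustive-partition oracle", {
  set.seed(17)
  for (i in 1:200) {
    v3 <- random_dna(10)
    j5 <- random_dna(10)
    vt <- sample(0:5, 1); jt <- sample(0:5, 1)
    mid <- if (runif(1) < 0.5) random_dna(sample(0:4, 1)) else ""
    obs <- paste0(substr(v3, 1, 10 - vt), mid,
                  substr(j5, jt + 1, 10))
    got <- decomposeJunction(v3, j5, obs)
    want <- oracle_decompose(v3, j5, obs)
    expect_equal(got[names(want)], want, label = paste("case", i))
    # concatenation invariant
    expect_equal(paste0(got$v_retained, got$p_v, got$n_region, got$p_j,
                        got$j_retained), obs)
  }
})

test_that("ambiguous overlap nucleotides go to V and are counted", {
  # observed shorter than the two full flanks: overlap region
  d <- decomposeJunction("AAACCC", "CCCGGG", "AAACCCGGG")
  expect_equal(d$ambiguous_overlap, 3L)
  expect_equal(d$v_retained, "AAACCC")
  expect_equal(d$j_retained, "GGG")
  expect_equal(paste0(d$v_retained, d$p_v, d$n_region, d$p_j, d$j_retained),
               "AAACCCGGG")
})

test_that("simulated junctions satisfy the concatenation invariant and the no-TdT signature", {
  cfg <- simConfig(seed = 5, nVFamilies = 2L, familySize = 2L, nJ = 2L,
                   pProb = 0.2, nAdditionProb = 0)
  g <- genGermline(cfg)
  sim <- simulateRearrangements(g, 400L, seed = 6)
  win <- 12L
  tr <- sim$truth
  obs <- vapply(seq_len(nrow(tr)), function(i) {
    v <- g$v_seqs[[tr$v_id[i]]]; j <- g$j_seqs[[tr$j_id[i]]]
    lead <- nchar(g$leader[tr$v_id[i]])
    s <- lead + nchar(v) - win + 1L
    e <- lead + (nchar(v) - tr$v_trim[i]) + nchar(tr$p_v[i]) +
      nchar(tr$n_region[i]) + nchar(tr$p_j[i]) + (win - tr$j_trim[i])
    substr(sim$cdna[[tr$sequence_id[i]]], s, e)
  }, character(1))
  v3 <- vapply(tr$v_id, function(v) {
    s <- g$v_seqs[[v]]; substr(s, nchar(s) - win + 1L, nchar(s))
  }, character(1))
  j5 <- vapply(tr$j_id, function(j) substr(g$j_seqs[[j]], 1L, win),
               character(1))
  dec <- decomposeJunctions(v3, j5, obs)
  expect_equal(paste0(dec$v_retained, dec$p_v, dec$n_region, dec$p_j,
                      dec$j_retained), unname(obs))
  s <- summarizeJunctions(dec)
  expect_equal(s$frac_with_N, 0)          # no-TdT model: no N additions

  # determinism and order invariance
  perm <- sample(length(obs))
  dec2 <- decomposeJunctions(v3[perm], j5[perm], obs[perm])
  expect_equal(dec2[order(perm), ], dec[order(seq_along(obs)), ],
               ignore_attr = TRUE)
})

test_that("P fraction matches the generation probability when trims are off", {
  cfg <- simConfig(seed = 8, nVFamilies = 2L, familySize = 1L, nJ = 2L,
                   vTrimP = 1, jTrimP = 1, pProb = 0.3, nAdditionProb = 0)
  g <- genGermline(cfg)
  n <- 1500L
  sim <- simulateRearrangements(g, n, seed = 9)
  truth_p <- mean(nchar(sim$truth$p_v) > 0 | nchar(sim$truth$p_j) > 0)
  win <- 12L
  tr <- sim$truth
  obs <- vapply(seq_len(nrow(tr)), function(i) {
    v <- g$v_seqs[[tr$v_id[i]]]
    lead <- nchar(g$leader[tr$v_id[i]])
    s <- lead + nchar(v) - win + 1L
    e <- lead + nchar(v) + nchar(tr$p_v[i]) + nchar(tr$p_j[i]) + win
    substr(sim$cdna[[tr$sequence_id[i]]], s, e)
  }, character(1))
  v3 <- vapply(tr$v_id, function(v) {
    s <- g$v_seqs[[v]]; substr(s, nchar(s) - win + 1L, nchar(s))
  }, character(1))
  j5 <- vapply(tr$j_id, function(j) substr(g$j_seqs[[j]], 1L, win),
               character(1))
  dec <- decomposeJunctions(v3, j5, obs)
  s <- summarizeJunctions(dec)
  expect_equal(s$frac_with_N, 0)
  expect_equal(s$frac_with_P, truth_p)    # trims off: measurement is exact
  p_junction <- 1 - (1 - 0.3)^2
  sd3 <- 3 * sqrt(p_junction * (1 - p_junction) / n)
  expect_lt(abs(s$frac_with_P - p_junction), sd3)
})

test_that("N fraction recovers the configured addition probability", {
  cfg <- simConfig(seed = 12, nVFamilies = 1L, familySize = 1L, nJ = 1L,
                   pProb = 0, nAdditionProb = 0.5)
  g <- genGermline(cfg)
  n <- 2000L
  sim <- simulateRearrangements(g, n, seed = 13)
  frac_truth <- mean(nchar(sim$truth$n_region) > 0)
  expect_lt(abs(frac_truth - 0.5), 3 * sqrt(0.25 / n))

  d1 <- decomposeJunctions("ACGTAC", "GGATCC", "ACGTACGGATCC")
  s1 <- summarizeJunctions(d1)
  expect_true(all(unlist(s1[c("frac_with_N", "frac_with_P")]) %in% c(0, 1)))
  expect_error(summarizeJunctions(d1[0, ]), "empty")
})

test_that("junction residues and deletion classes tabulate to 1", {
  cfg <- simConfig(seed = 14, nVFamilies = 2L, familySize = 1L, nJ = 2L)
  g <- genGermline(cfg)
  sim <- simulateRearrangements(g, 100L, seed = 15)
  win <- 12L
  tr <- sim$truth
  v3 <- vapply(tr$v_id, function(v) {
    s <- g$v_seqs[[v]]; substr(s, nchar(s) - win + 1L, nchar(s))
  }, character(1))
  j5 <- vapply(tr$j_id, function(j) substr(g$j_seqs[[j]], 1L, win),
               character(1))
  obs <- vapply(seq_len(nrow(tr)), function(i) {
    v <- g$v_seqs[[tr$v_id[i]]]
    lead <- nchar(g$leader[tr$v_id[i]])
    s <- lead + nchar(v) - win + 1L
    e <- lead + (nchar(v) - tr$v_trim[i]) + nchar(tr$p_v[i]) +
      nchar(tr$n_region[i]) + nchar(tr$p_j[i]) + (win - tr$j_trim[i])
    substr(sim$cdna[[tr$sequence_id[i]]], s, e)
  }, character(1))
  dec <- decomposeJunctions(v3, j5, obs)
  res <- sample(c("V", "P", "F"), nrow(dec), replace = TRUE)
  s <- summarizeJunctions(dec, junctionResidues = res)
  expect_equal(sum(s$junction_residue_table), 1)
  expect_equal(sum(s$deletion_class_table), 1)
})
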