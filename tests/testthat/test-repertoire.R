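# Pool assignment, QC, unique collapsing, subfamily clustering, alleles.

make_two_locus_world <- function(seed = 3) {
  g1 <- genGermline(simConfig(seed = seed, nVFamilies = 2L, familySize = 2L,
                              nJ = 2L, rssType = "kappa"))
  g2 <- genGermline(simConfig(seed = seed + 100L, nVFamilies = 1L,
                              familySize = 1L, nJ = 1L, rssType = "lambda"))
  list(g1 = g1, g2 = g2,
       cl = Biostrings::DNAStringSet(c(IgL1 = unname(g1$c_seqs["C1"]),
                                       IgL2 = unname(g2$c_seqs["C1"]))))
}

test_that("amplicons sort into their CL pool; junk stays unassigned", {
  w <- make_two_locus_world()
  s1 <- simulateRearrangements(w$g1, 30L, seed = 4)
  s2 <- simulateRearrangements(w$g2, 20L, seed = 5)
  set.seed(6)
  junk <- setNames(vapply(1:5, function(i) random_dna(500), character(1)),
                   paste0("junk", 1:5))
  seqs <- Biostrings::DNAStringSet(c(s1$cdna, s2$cdna, junk))
  a <- assignPool(seqs, w$cl)
  expect_equal(a$c_call[1:30], rep("IgL1", 30))
  expect_equal(a$c_call[31:50], rep("IgL2", 20))
  expect_equal(a$c_call[51:55], rep("unassigned", 5))
  # count conservation: input = assigned + unassigned
  pools <- splitPools(a)
  expect_equal(sum(vapply(pools, length, integer(1))) +
                 sum(a$c_call == "unassigned"), length(seqs))
})

test_that("equal-scoring CL hits break ties lexicographically and flag ambiguity", {
  set.seed(7)
  cl_seq <- random_dna(300)
  cl <- Biostrings::DNAStringSet(c(B_ref = cl_seq, A_ref = cl_seq))
  read <- Biostrings::DNAStringSet(c(r1 = paste0(random_dna(60), cl_seq)))
  a <- assignPool(read, cl)
  expect_equal(a$c_call, "A_ref")
  expect_true(a$ambiguous)
})

test_that("QC discards frameshifts, stops, truncations and conserves counts", {
  w <- make_two_locus_world(seed = 11)
  sim <- simulateRearrangements(w$g1, 60L, seed = 12)
  keep <- sim$truth$productive
  cd <- sim$cdna[keep]
  # corrupt three productive cDNAs in the pre-CL (V) region
  fs <- cd[[1]]
  cd[[1]] <- paste0(substr(fs, 1, 99), substr(fs, 101, nchar(fs)))  # 1-nt del
  st <- cd[[2]]
  substr(st, 70, 72) <- "TAG"                       # in-frame stop in V
  cd[[2]] <- st
  cstart <- regexpr(substr(w$g1$c_seqs[["C1"]], 1, 30), cd[[3]], fixed = TRUE)
  cd[[3]] <- substr(cd[[3]], cstart - 40L, nchar(cd[[3]]))  # truncated
  a <- assignPool(Biostrings::DNAStringSet(cd),
                  Biostrings::DNAStringSet(c(IgL1 = unname(w$g1$c_seqs["C1"]))))
  pool <- splitPools(a)[[1]]
  q <- qcFilter(pool)
  st_ <- poolStats(q)
  expect_equal(st_$n_discarded_frameshift, 1L)
  expect_equal(st_$n_discarded_stop, 1L)
  expect_equal(st_$n_discarded_truncated, 1L)
  expect_equal(length(q) + st_$n_discarded_frameshift +
                 st_$n_discarded_stop + st_$n_discarded_truncated,
               st_$n_input)
  expect_true(all(!grepl("\\*", members(q)$aa)))
})

test_that("unique collapsing preserves counts and J usage matches truth", {
  w <- make_two_locus_world(seed = 21)
  sim <- simulateRearrangements(w$g1, 600L, seed = 22, jWeights = c(9, 1))
  truth_j2 <- mean(sim$truth$j_id == "J2")
  expect_lt(abs(truth_j2 - 0.1), 3 * sqrt(0.1 * 0.9 / 600))
  a <- assignPool(Biostrings::DNAStringSet(sim$cdna),
                  Biostrings::DNAStringSet(c(IgL1 = unname(w$g1$c_seqs["C1"]))))
  pool <- qcFilter(splitPools(a)[[1]])
  pool <- assignJCall(pool, Biostrings::DNAStringSet(w$g1$j_seqs))
  uniq <- collapseUnique(pool)
  expect_equal(sum(uniq$unique$duplicate_count), uniq$n_total)
  expect_lte(uniq$n_unique, uniq$n_total)
  # J calls agree with simulation truth for the kept sequences
  m <- members(pool)
  truth <- setNames(sim$truth$j_id, sim$truth$sequence_id)
  expect_equal(mean(m$j_call == truth[m$sequence_id]), 1)
})

test_that("a pool of n identical sequences collapses to one unique", {
  seqs <- rep("ACGTACGTACGT", 7)
  m <- S4Vectors::DataFrame(sequence_id = paste0("s", 1:7), sequence = seqs,
                            c_call = "X", c_start = 13L)
  pool <- AmpliconPool("X", m)
  u <- collapseUnique(pool)
  expect_equal(u$n_unique, 1L)
  expect_equal(u$unique$duplicate_count, 7L)
})

test_that("28 sequences with 13 distinct variants collapse to 13 uniques", {
  set.seed(23)
  variants <- vapply(1:13, function(i) random_dna(200), character(1))
  counts <- c(10, 4, 3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1)  # sums to 28
  seqs <- rep(variants, counts)
  m <- S4Vectors::DataFrame(sequence_id = sprintf("c%02d", seq_along(seqs)),
                            sequence = seqs, c_call = "IgL2",
                            c_start = nchar(seqs[1]) + 1L)
  u <- collapseUnique(AmpliconPool("IgL2", m))
  expect_equal(u$n_unique, 13L)
  expect_equal(u$n_total, 28L)
  expect_equal(sum(u$unique$duplicate_count), 28L)
})

test_that("subfamily clustering recovers planted families and is monotone", {
  set.seed(31)
  sizes <- c(6, 4, 3)
  founders <- lapply(1:3, function(i) random_dna(288))
  seqs <- unlist(lapply(1:3, function(f)
    vapply(seq_len(sizes[f]), function(m)
      mutate_string(founders[[f]], 0.06, c("A", "C", "G", "T")),
      character(1))))
  truth <- rep(1:3, sizes)
  cl <- clusterSubfamilies(seqs, 0.75)
  expect_equal(cl$n_families, 3L)
  expect_equal(as.integer(sort(cl$family_sizes, decreasing = TRUE)),
               sort(sizes, decreasing = TRUE))
  # same-truth pairs cluster together
  expect_true(all(tapply(cl$families, truth,
                         function(x) length(unique(x)) == 1)))

  # monotone: families at a higher threshold refine those at a lower one
  cl2 <- clusterSubfamilies(seqs, 0.9)
  for (f in unique(cl2$families)) {
    parent <- cl$families[cl2$families == f]
    expect_equal(length(unique(parent)), 1L)
  }

  # distinct sequences at threshold 1 are singletons
  set.seed(32)
  distinct <- vapply(1:5, function(i) random_dna(100), character(1))
  cl3 <- clusterSubfamilies(distinct, 1.0)
  expect_equal(cl3$n_families, 5L)
  expect_error(clusterSubfamilies(character(0)), "at least one")
})

test_that("allele inference matches the diploid presence model", {
  # two genes (C1, C2), four allelic variants each, <=2 per specimen
  vars <- c(paste0("C1", letters[1:4]), paste0("C2", letters[1:4]))
  pres <- matrix(FALSE, 8, 4, dimnames = list(vars, LETTERS[1:4]))
  pres["C1a", ] <- c(TRUE, TRUE, FALSE, FALSE)
  pres["C1b", ] <- c(FALSE, TRUE, TRUE, FALSE)
  pres["C1c", ] <- c(FALSE, FALSE, TRUE, TRUE)
  pres["C1d", ] <- c(TRUE, FALSE, FALSE, TRUE)
  pres["C2a", ] <- c(TRUE, FALSE, TRUE, FALSE)
  pres["C2b", ] <- c(FALSE, TRUE, FALSE, TRUE)
  pres["C2c", ] <- c(TRUE, FALSE, FALSE, TRUE)
  pres["C2d", ] <- c(FALSE, TRUE, TRUE, FALSE)
  set.seed(41)
  base1 <- random_dna(315); base2 <- mutate_string(base1, 0.10,
                                                   c("A", "C", "G", "T"))
  seqs <- c(vapply(1:4, function(i)
    mutate_string(base1, 0.01, c("A", "C", "G", "T")), character(1)),
    vapply(1:4, function(i)
      mutate_string(base2, 0.01, c("A", "C", "G", "T")), character(1)))
  names(seqs) <- vars
  res <- inferAlleles(pres, seqs)
  expect_equal(res$n_genes, 2L)
  expect_equal(sort(vapply(res$genes, length, integer(1))), c(4L, 4L))
  expect_equal(res$forced_splits, 0L)

  # single variant everywhere: one gene, one allele
  p1 <- matrix(TRUE, 1, 3, dimnames = list("v1", NULL))
  r1 <- inferAlleles(p1)
  expect_equal(r1$n_genes, 1L)

  # three co-occurring close variants force a second gene
  p3 <- matrix(TRUE, 3, 1, dimnames = list(c("x", "y", "z"), NULL))
  expect_warning(r3 <- inferAlleles(p3), "split")
  expect_equal(r3$n_genes, 2L)
  expect_equal(r3$n_genes, oracle_min_genes(p3))
})

test_that("greedy gene grouping matches the exhaustive minimum on small tables", {
  set.seed(51)
  for (rep in 1:10) {
    nv <- sample(3:6, 1); ns <- sample(2:4, 1)
    pres <- matrix(runif(nv * ns) < 0.5, nv, ns,
                   dimnames = list(paste0("v", 1:nv), NULL))
    got <- suppressWarnings(inferAlleles(pres))$n_genes
    want <- oracle_min_genes(pres)
    expect_equal(got, want, label = paste("table", rep))
  }
})

test_that("V family assignment matches simulation truth without errors", {
  w <- make_two_locus_world(seed = 61)
  sim <- simulateRearrangements(w$g1, 120L, seed = 62)
  a <- assignPool(Biostrings::DNAStringSet(sim$cdna),
                  Biostrings::DNAStringSet(c(IgL1 = unname(w$g1$c_seqs["C1"]))))
  pool <- qcFilter(splitPools(a)[[1]])
  fams <- setNames(w$g1$founders, paste0("fam", seq_along(w$g1$founders)))
  pool <- assignVFamily(pool, Biostrings::DNAStringSet(fams))
  m <- members(pool)
  truth_fam <- paste0("fam", w$g1$family_of[
    sim$truth$v_id[match(m$sequence_id, sim$truth$sequence_id)]])
  expect_equal(mean(m$v_family == truth_fam), 1)
})
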