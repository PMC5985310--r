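# Column filtering, p-distance, neighbor joining, bootstrap, isotype calls.

test_that("column filtering matches per-column coverage counting", {
  # gap-free alignment passes through unchanged
  set.seed(3)
  aln <- setNames(vapply(1:5, function(i) random_dna(40), character(1)),
                  paste0("t", 1:5))
  f <- filterColumns(aln)
  expect_equal(ncol(f), 40L)

  # a column with 2 gaps out of 20 rows (coverage 0.90) is removed
  m <- do.call(rbind, strsplit(vapply(1:20, function(i) random_dna(30),
                                      character(1)), ""))
  rownames(m) <- paste0("t", 1:20)
  m[1:2, 7] <- "-"
  f2 <- filterColumns(m, 0.95)
  expect_equal(ncol(f2), 29L)
  expect_false(7L %in% attr(f2, "kept"))

  # randomized gap pattern against a brute-force counting oracle
  set.seed(4)
  m3 <- m
  m3[cbind(sample(1:20, 40, TRUE), sample(1:30, 40, TRUE))] <- "-"
  f3 <- filterColumns(m3, 0.95)
  want <- which(vapply(1:30, function(j) mean(m3[, j] != "-") >= 0.95,
                       logical(1)))
  expect_equal(attr(f3, "kept"), want)
  all_gap <- matrix("-", 4, 5, dimnames = list(paste0("t", 1:4), NULL))
  expect_error(filterColumns(all_gap), "all columns")
})

test_that("p-distance equals site-by-site counting with pairwise deletion", {
  a <- c(x = "ACGTACGTAC", y = "ACGTACGTAC")
  expect_equal(max(pDistance(a)), 0)
  b <- c(x = "AAAAAAAAAA", y = "AAATTTAAAA")   # 3 differences over 10
  expect_equal(pDistance(b)["x", "y"], 0.3)

  set.seed(5)
  m <- do.call(rbind, strsplit(vapply(1:5, function(i) random_dna(60),
                                      character(1)), ""))
  rownames(m) <- paste0("t", 1:5)
  m[cbind(sample(1:5, 20, TRUE), sample(1:60, 20, TRUE))] <- "-"
  d <- pDistance(m)
  for (i in 1:4) for (j in (i + 1):5) {
    comp <- m[i, ] != "-" & m[j, ] != "-"
    expect_equal(d[i, j], sum(m[i, comp] != m[j, comp]) / sum(comp))
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("NJ reconstructs additive matrices exactly", {
  # the classic 4-taxon case, built from known branch lengths
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(tr)
  got <- njTree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), got), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)], D)

  # random additive matrices for 5..8 taxa: topology and path lengths
  set.seed(7)
  for (n in 5:8) {
    rt <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    D2 <- ape::cophenetic.phylo(rt)
    t2 <- njTree(D2)
    expect_equal(ape::dist.topo(ape::unroot(rt), t2), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(t2)[rownames(D2), colnames(D2)], D2,
                 tolerance = 1e-8)
  }
})

test_that("NJ handles 3 taxa, ties and degenerate input deterministically", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- njTree(D)
  expect_equal(sort(t3$tip.label), c("a", "b", "c"))
  # closed-form branch lengths: va = (2+3-4)/2 etc.
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.5, 1.5, 2.5))
  expect_error(njTree(D[1:2, 1:2]), "at least 3")

  # equidistant taxa: repeated runs join the same (smallest-index) pair
  E <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(E) <- 0
  expect_equal(ape::write.tree(njTree(E)), ape::write.tree(njTree(E)))

  # negative pendant lengths are clamped, none below zero
  N <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  N["A", "B"] <- N["B", "A"] <- 0.01
  tn <- njTree(N)
  expect_true(all(tn$edge.length >= 0))
})

test_that("NJ agrees with the reference implementation on random distances", {
  set.seed(9)
  for (rep in 1:3) {
    m <- do.call(rbind, strsplit(vapply(1:12, function(i) random_dna(80),
                                        character(1)), ""))
    rownames(m) <- paste0("t", 1:12)
    d <- pDistance(m)
    expect_equal(ape::dist.topo(njTree(d), ape::nj(as.dist(d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are seed-deterministic and rank clade strength", {
  set.seed(11)
  # two well-separated clades
  rootA <- random_dna(240); rootB <- mutate_string(rootA, 0.4,
                                                   c("A", "C", "G", "T"))
  aln <- c(
    setNames(vapply(1:4, function(i)
      mutate_string(rootA, 0.02, c("A", "C", "G", "T")), character(1)),
      paste0("a", 1:4)),
    setNames(vapply(1:4, function(i)
      mutate_string(rootB, 0.02, c("A", "C", "G", "T")), character(1)),
      paste0("b", 1:4)))
  t1 <- bootstrapSupport(aln, bootstrapReps = 100, seed = 5)
  t2 <- bootstrapSupport(aln, bootstrapReps = 100, seed = 5)
  expect_equal(t1$node.label, t2$node.label)
  # the a|b split is maximally supported
  seps <- vapply((length(aln) + 2):(length(aln) + t1$Nnode), function(nd) {
    tips <- t1$tip.label[iglkit:::.tip_descendants(t1, nd)]
    setequal(tips, paste0("a", 1:4)) || setequal(tips, paste0("b", 1:4))
  }, logical(1))
  sup <- suppressWarnings(as.numeric(t1$node.label[-1]))
  expect_true(any(sup[seps] >= 95, na.rm = TRUE))

  # identical sequences resolve nothing
  same <- setNames(rep(paste(rep("ACGT", 30), collapse = ""), 5),
                   paste0("s", 1:5))
  ts <- bootstrapSupport(same, bootstrapReps = 20, seed = 2)
  expect_true(all(ts$edge.length == 0))
})

test_that("queries are assigned to the smallest supported homogeneous clade", {
  nwk <- paste0("((k1:0.02,k2:0.02,kq:0.02):0.3,",
                "(l1:0.02,l2:0.02,lq:0.02):0.3,",
                "(s1:0.02,s2:0.02,sq:0.02):0.3,",
                "(t1:0.02,t2:0.02,tq:0.02):0.3,",
                "(u1:0.02,u2:0.02,uq:0.02):0.3);")
  set.seed(13)
  root <- random_dna(300)
  seqs <- evolvePanel(nwk, root, seed = 14)
  bt <- bootstrapSupport(seqs, bootstrapReps = 100, seed = 15)
  panel <- setNames(rep(c("kappa", "lambda", "sigma", "sigma-2", "lambda-2"),
                        each = 2),
                    c("k1", "k2", "l1", "l2", "s1", "s2", "t1", "t2",
                      "u1", "u2"))
  calls <- assignIsotype(bt, panel, c("kq", "lq", "sq", "tq", "uq"))
  expect_equal(unname(calls),
               c("kappa", "lambda", "sigma", "sigma-2", "lambda-2"))

  # an unreachable support threshold leaves queries unresolved
  calls2 <- assignIsotype(bt, panel, "kq", supportThreshold = 101)
  expect_equal(unname(calls2), "unresolved")
  expect_error(assignIsotype(bt, panel, "absent_leaf"))
})

test_that("codon back-threading reproduces the protein alignment gaps", {
  cds <- c(a = "ATGGCTTGTGAT", b = "ATGTGTGAT")
  paln <- c(a = "MACD", b = "M-CD")
  nt <- backThreadCodons(paln, cds)
  expect_equal(nt[["a"]], "ATGGCTTGTGAT")
  expect_equal(nt[["b"]], "ATG---TGTGAT")
  expect_equal(unique(nchar(nt)), 12L)
  expect_error(backThreadCodons(c(a = "MKKKKK"), c(a = "ATG")), "shorter")
})
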