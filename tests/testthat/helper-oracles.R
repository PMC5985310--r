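# Independent brute-force oracles used to validate the implementations.

# standard genetic code, written out independently of any library
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(nt, frame = 0) {
  nt <- toupper(nt)
  out <- character()
  i <- frame + 1
  while (i + 2 <= nchar(nt)) {
    out <- c(out, ORACLE_CODON_TABLE[[substr(nt, i, i + 2)]])
    i <- i + 3
  }
  paste(out, collapse = "")
}

# exhaustive window-enumeration RSS scan
oracle_scan_rss <- function(seq, heptamer = "CACAGTG",
                            nonamer = "ACAAAAACC", tol = 1, minScore = 10,
                            requireCAC = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  matches <- function(a, b)
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  rows <- list()
  spacers <- sort(unique(c((12 - tol):(12 + tol), (23 - tol):(23 + tol))))
  for (pos in 0:(n - 1)) {
    if (pos + 7 > n) break
    h <- substr(seq, pos + 1, pos + 7)
    if (requireCAC && substr(h, 1, 3) != "CAC") next
    for (sp in spacers) {
      ns <- pos + 7 + sp
      if (ns + 9 > n) next
      no <- substr(seq, ns + 1, ns + 9)
      sc <- matches(h, heptamer) + matches(no, nonamer)
      if (sc < minScore) next
      rows[[length(rows) + 1]] <- data.frame(
        position = pos, heptamer = h, spacer_len = sp,
        spacer_class = if (abs(sp - 12) <= tol) 12L else 23L,
        nonamer = no, score = sc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$position, out$spacer_len), , drop = FALSE]
}

# exhaustive-partition junction decomposition: maximal total germline
# assignment, ties resolved in favor of a longer V
oracle_decompose <- function(v3, j5, obs, maxP = 4) {
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  n <- nchar(obs)
  v_opts <- 0
  for (k in 1:min(n, nchar(v3)))
    if (substr(obs, 1, k) == substr(v3, 1, k)) v_opts <- c(v_opts, k) else break
  j_opts <- 0
  ro <- paste(rev(strsplit(obs, "")[[1]]), collapse = "")
  rj <- paste(rev(strsplit(j5, "")[[1]]), collapse = "")
  for (k in 1:min(n, nchar(j5)))
    if (substr(ro, 1, k) == substr(rj, 1, k)) j_opts <- c(j_opts, k) else break
  best <- NULL
  for (v_len in v_opts) for (j_len in j_opts) {
    if (v_len + j_len > n) next
    tot <- v_len + j_len
    if (is.null(best) || tot > best$tot ||
        (tot == best$tot && v_len > best$v_len))
      best <- list(v_len = v_len, j_len = j_len, tot = tot)
  }
  v_len <- best$v_len; j_len <- best$j_len
  middle <- substr(obs, v_len + 1, n - j_len)
  v_trim <- nchar(v3) - v_len
  j_trim <- nchar(j5) - j_len
  p_v <- ""
  if (v_trim == 0 && nchar(middle) > 0) {
    for (k in min(maxP, nchar(middle)):1) {
      cand <- revcomp(substr(v3, nchar(v3) - k + 1, nchar(v3)))
      if (substr(middle, 1, k) == cand) { p_v <- cand; break }
    }
  }
  rest <- substr(middle, nchar(p_v) + 1, nchar(middle))
  p_j <- ""
  if (j_trim == 0 && nchar(rest) > 0) {
    for (k in min(maxP, nchar(rest)):1) {
      cand <- revcomp(substr(j5, 1, k))
      if (substr(rest, nchar(rest) - k + 1, nchar(rest)) == cand) {
        p_j <- cand; break
      }
    }
  }
  list(v_retained = substr(obs, 1, v_len), v_trim = v_trim, p_v = p_v,
       n_region = substr(rest, 1, nchar(rest) - nchar(p_j)), p_j = p_j,
       j_trim = j_trim,
       j_retained = if (j_len) substr(obs, n - j_len + 1, n) else "")
}

# exhaustive minimum-gene grouping for allele inference (<= 8 variants)
oracle_min_genes <- function(presence, maxAlleles = 2) {
  vars <- rownames(presence)
  n <- length(vars)
  # enumerate set partitions via restricted growth strings
  best <- n
  rgs <- function(i, groups) {
    if (i > n) {
      ok <- all(vapply(groups, function(g)
        all(colSums(presence[g, , drop = FALSE]) <= maxAlleles), logical(1)))
      if (ok) best <<- min(best, length(groups))
      return(invisible())
    }
    for (g in seq_along(groups)) {
      groups[[g]] <- c(groups[[g]], vars[i])
      rgs(i + 1, groups)
      groups[[g]] <- setdiff(groups[[g]], vars[i])
    }
    rgs(i + 1, c(groups, list(vars[i])))
  }
  rgs(2, list(vars[1]))
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# substitution mutator for synthetic stand-in panels (protein or dna)
mutate_string <- function(x, rate, alphabet) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  paste(ch, collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
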