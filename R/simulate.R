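# Synthetic-data generator with full ground truth.
#
# Emulates the germline anatomy and recombination statistics the analysis
# assumes: translocon or single-VJC loci with leader exons, AG/GT splice
# sites and kappa- or lambda-type RSS; V-J recombination with exonucleolytic
# trimming, optional P-nucleotides and configurable (default zero)
# N-additions, matching the no-TdT junction model; family-structured V
# repertoires separable at the 75% identity criterion; amplicon reads with
# iid substitution errors; and CL-proportioned transcriptome read mixtures.
# All outputs are byte-reproducible under a fixed seed.

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

.rand_cds <- function(nCodons, startATG = FALSE) {
  cods <- sample(.SENSE_CODONS, nCodons, replace = TRUE)
  if (startATG) cods[1L] <- "ATG"
  paste(cods, collapse = "")
}

# substitute bases at `rate` without creating in-frame stops (frame 0)
.mutate_coding <- function(nt, rate) {
  ch <- strsplit(nt, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) {
    old <- ch[p]
    for (try in 1:10) {
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      ch[p] <- new
      cod_i <- (p - 1L) %/% 3L
      cod <- paste(ch[(cod_i * 3L + 1L):(cod_i * 3L + 3L)], collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA")) break
      ch[p] <- old
    }
  }
  paste(ch, collapse = "")
}

.mutate_free <- function(nt, rate) {
  ch <- strsplit(nt, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: geometric
#' exonucleolytic trimming (p = 0.25, max 6 nt), P-nucleotides on 20% of
#' untrimmed ends, and no N-additions (the no-TdT junction model); V families
#' at ~92% within-family and well below 65% between-family nucleotide
#' identity.
#'
#' @param seed integer seed.
#' @param nVFamilies,familySize V families and members per family.
#' @param withinFamilyIdentity target within-family nt identity (>= 0.85).
#' @param nJ,nC numbers of J and C segments.
#' @param rssType `"kappa"` (V-12/J-23), `"lambda"` (V-23/J-12) or `"none"`
#'   (non-rearranging locus, no V).
#' @param organization `"translocon"`, `"vjc_cluster"` or
#'   `"non_rearranging"` (annotation ground truth).
#' @param vTrimP,jTrimP,maxTrim geometric trimming parameters.
#' @param pProb P-nucleotide probability per untrimmed end.
#' @param nAdditionProb probability of an N-insertion per junction
#'   (default 0).
#' @param nLenRange N length range (uniform; default 1..6).
#' @param jWeights J usage weights (recycled/normalized; default uniform).
#' @param vExonCodons,leaderCodons,cExonCodons,intronLen segment geometry.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, nVFamilies = 3L, familySize = 3L,
                      withinFamilyIdentity = 0.92, nJ = 2L, nC = 1L,
                      rssType = c("kappa", "lambda", "none"),
                      organization = NULL,
                      vTrimP = 0.25, jTrimP = 0.25, maxTrim = 6L,
                      pProb = 0.2, nAdditionProb = 0,
                      nLenRange = c(1L, 6L), jWeights = NULL,
                      vExonCodons = 96L, leaderCodons = 19L,
                      cExonCodons = 105L, intronLen = 80L) {
  rssType <- match.arg(rssType)
  stopifnot(withinFamilyIdentity >= 0.85, pProb >= 0, pProb <= 1,
            nAdditionProb >= 0, nAdditionProb <= 1)
  if (is.null(organization)) {
    nv <- if (rssType == "none") 0L else nVFamilies * familySize
    organization <- if (nv == 0L) "non_rearranging"
                    else if (nv == 1L) "vjc_cluster" else "translocon"
  }
  structure(list(seed = as.integer(seed), nVFamilies = as.integer(nVFamilies),
                 familySize = as.integer(familySize),
                 withinFamilyIdentity = withinFamilyIdentity,
                 nJ = as.integer(nJ), nC = as.integer(nC), rssType = rssType,
                 organization = organization, vTrimP = vTrimP,
                 jTrimP = jTrimP, maxTrim = as.integer(maxTrim),
                 pProb = pProb, nAdditionProb = nAdditionProb,
                 nLenRange = as.integer(nLenRange), jWeights = jWeights,
                 vExonCodons = as.integer(vExonCodons),
                 leaderCodons = as.integer(leaderCodons),
                 cExonCodons = as.integer(cExonCodons),
                 intronLen = as.integer(intronLen)),
            class = "SimConfig")
}

.rss_fwd <- function(spacerLen) {
  paste0(RSS_HEPTAMER, .rand_nt(spacerLen), RSS_NONAMER)
}

.rss_rev <- function(spacerLen) {
  # J-RSS on the forward strand: revcomp(nonamer) spacer revcomp(heptamer)
  paste0(revComp(RSS_NONAMER), .rand_nt(spacerLen), revComp(RSS_HEPTAMER))
}

# J coding: starts with the GT dinucleotide typical of RSS-proximal J ends;
# the first in-window GT after the coding start is the splice donor, so the
# body is rejection-sampled to keep the donor unambiguous
.make_j <- function(nCodons = 12L) {
  for (try in 1:200) {
    body <- .rand_cds(nCodons)
    body <- paste0("GT", substr(body, 3L, nchar(body)))
    cod1 <- substr(body, 1L, 3L)
    if (cod1 %in% c("TAA", "TAG", "TGA")) next
    interior <- substr(body, 30L, nchar(body))
    if (grepl("GT", interior, fixed = TRUE)) next
    return(body)
  }
  stop("failed to sample a J segment with an unambiguous donor")
}

#' Generate a germline IgL locus with ground truth
#'
#' Builds a scaffold carrying leader exons (AG/GT intron splice sites), V
#' exons with downstream RSS, J segments with upstream RSS and a 3' splice
#' donor, and C exons, according to the configured organization and RSS
#' type. Optional defects turn individual V segments into pseudogenes.
#'
#' @param cfg a [simConfig()].
#' @param defects optional list with integer vectors `v_stop`,
#'   `v_frameshift`, `v_no_leader`, `v_bad_rss` (1-based V indices).
#' @return List with `scaffold` (character), `truth` (`GRanges` of planted
#'   V/J/C features with `kind`, `segment_id`, `family`, `functional`),
#'   `leader` (named leader sequences), `v_seqs`, `j_seqs`, `c_seqs` (named
#'   germline coding sequences), `founders` (family founder V sequences),
#'   `family_of` (named family index per V), `cfg`.
#' @export
genGermline <- function(cfg = simConfig(), defects = list()) {
  set.seed(cfg$seed)
  v_spacer <- switch(cfg$rssType, kappa = 12L, lambda = 23L, none = NA)
  j_spacer <- switch(cfg$rssType, kappa = 23L, lambda = 12L, none = NA)

  n_v <- if (cfg$rssType == "none") 0L else cfg$nVFamilies * cfg$familySize
  founders <- character(cfg$nVFamilies)
  if (n_v > 0L)
    founders <- vapply(seq_len(cfg$nVFamilies),
                       function(i) .rand_cds(cfg$vExonCodons), character(1))
  mut_rate <- 1 - cfg$withinFamilyIdentity

  pieces <- character(); pos <- 0L
  rows <- list(); r <- 1L
  leader_seqs <- v_seqs <- j_seqs <- c_seqs <- character()
  family_of <- integer()
  emit <- function(x) { pieces[[length(pieces) + 1L]] <<- x; pos <<- pos + nchar(x) }
  feat <- function(kind, id, family, functional, start, end) {
    rows[[r]] <<- data.frame(kind = kind, segment_id = id, family = family,
                             functional = functional, start = start,
                             end = end, stringsAsFactors = FALSE)
    r <<- r + 1L
  }

  emit(.rand_nt(60L))
  vi <- 0L
  for (fam in seq_len(cfg$nVFamilies)) {
    if (cfg$rssType == "none") break
    for (mem in seq_len(cfg$familySize)) {
      vi <- vi + 1L
      vid <- sprintf("V%d.%d", fam, mem)
      v_nt <- if (mem == 1L) founders[fam] else
        .mutate_coding(founders[fam], mut_rate)
      has_stop <- vi %in% (defects$v_stop %||% integer())
      has_fs <- vi %in% (defects$v_frameshift %||% integer())
      no_leader <- vi %in% (defects$v_no_leader %||% integer())
      bad_rss <- vi %in% (defects$v_bad_rss %||% integer())
      if (has_stop) {
        cod <- sample(10:(cfg$vExonCodons - 10L), 1L)
        substr(v_nt, cod * 3L + 1L, cod * 3L + 3L) <- "TAA"
      }
      if (has_fs) {
        p <- sample(30:(nchar(v_nt) - 30L), 1L)
        v_nt <- paste0(substr(v_nt, 1L, p - 1L),
                       substr(v_nt, p + 1L, nchar(v_nt)))
      }
      leader <- .rand_cds(cfg$leaderCodons, startATG = TRUE)
      if (no_leader) {
        # no leader exon/intron; scrub the would-be AG acceptor so absence
        # is a sequence property
        pad <- .rand_nt(40L)
        substr(pad, nchar(pad) - 1L, nchar(pad)) <- "CC"
        emit(pad)
      } else {
        emit(leader)
        leader_seqs[vid] <- leader
        emit(paste0("GT", .rand_nt(cfg$intronLen - 4L), "AG"))
      }
      v_start <- pos + 1L
      emit(v_nt)
      feat("V", vid, fam, !(has_stop || has_fs || no_leader || bad_rss),
           v_start, pos)
      v_seqs[vid] <- v_nt
      family_of[vid] <- fam
      rss <- .rss_fwd(v_spacer)
      if (bad_rss) substr(rss, 1L, 3L) <- "TAC"
      emit(rss)
      emit(.rand_nt(50L))
    }
  }

  for (j in seq_len(cfg$nJ)) {
    jid <- sprintf("J%d", j)
    emit(.rand_nt(30L))
    if (cfg$rssType != "none") emit(.rss_rev(j_spacer))
    j_nt <- .make_j()
    j_start <- pos + 1L
    emit(j_nt)
    feat("J", jid, NA_integer_, cfg$rssType != "none", j_start, pos)
    j_seqs[jid] <- j_nt
    emit("GT")   # splice donor
    emit(.rand_nt(40L))
  }

  for (ci in seq_len(cfg$nC)) {
    cid <- sprintf("C%d", ci)
    emit(.rand_nt(60L))
    emit("AG")   # splice acceptor
    c_nt <- .rand_cds(cfg$cExonCodons)
    c_start <- pos + 1L
    emit(c_nt)
    feat("C", cid, NA_integer_, TRUE, c_start, pos)
    c_seqs[cid] <- c_nt
  }
  emit(.rand_nt(60L))

  df <- do.call(rbind, rows)
  truth <- GRanges("scaffold", IRanges(df$start, df$end), strand = "+")
  mcols(truth) <- DataFrame(kind = df$kind, segment_id = df$segment_id,
                            family = df$family, functional = df$functional)
  list(scaffold = paste(pieces, collapse = ""), truth = truth,
       leader = leader_seqs, v_seqs = v_seqs, j_seqs = j_seqs,
       c_seqs = c_seqs, founders = setNames(founders,
                                            paste0("F", seq_along(founders))),
       family_of = family_of, cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rgeom_capped <- function(n, p, cap) pmin(rgeom(n, p), cap)

#' Simulate V-J rearranged cDNAs from a germline locus
#'
#' Each cDNA is leader + trimmed V + \[P\]\[N\]\[P\] + trimmed J + C. Trimming is
#' geometric (capped); P-nucleotides (palindromic, 1-2 nt) occur with
#' `pProb` per untrimmed end; N-additions with `nAdditionProb`.
#'
#' @param germ result of [genGermline()].
#' @param n number of cDNAs.
#' @param seed integer seed.
#' @param jWeights optional J usage weights (e.g. `c(9, 1)`).
#' @param vWeights optional V usage weights.
#' @return List with `cdna` (named character), `truth` (`data.frame` with
#'   `v_id`, `j_id`, `c_id`, `v_trim`, `p_v`, `n_region`, `p_j`, `j_trim`,
#'   `productive`).
#' @export
simulateRearrangements <- function(germ, n, seed = 1L, jWeights = NULL,
                                   vWeights = NULL) {
  cfg <- germ$cfg
  if (!length(germ$v_seqs)) stop("locus is non-rearranging")
  set.seed(seed)
  v_ids <- names(germ$v_seqs); j_ids <- names(germ$j_seqs)
  c_ids <- names(germ$c_seqs)
  jW <- jWeights %||% cfg$jWeights %||% rep(1, length(j_ids))
  vW <- vWeights %||% rep(1, length(v_ids))
  pick_v <- sample(v_ids, n, replace = TRUE, prob = vW)
  pick_j <- sample(j_ids, n, replace = TRUE, prob = jW)
  pick_c <- sample(c_ids, n, replace = TRUE)
  v_trim <- .rgeom_capped(n, cfg$vTrimP, cfg$maxTrim)
  j_trim <- .rgeom_capped(n, cfg$jTrimP, cfg$maxTrim)

  cdna <- character(n)
  tr <- vector("list", n)
  for (i in seq_len(n)) {
    v <- germ$v_seqs[[pick_v[i]]]
    j <- germ$j_seqs[[pick_j[i]]]
    cc <- germ$c_seqs[[pick_c[i]]]
    vt <- v_trim[i]; jt <- j_trim[i]
    v_kept <- substr(v, 1L, nchar(v) - vt)
    j_kept <- substr(j, jt + 1L, nchar(j))
    p_v <- p_j <- n_reg <- ""
    if (vt == 0L && runif(1) < cfg$pProb) {
      k <- sample(1:2, 1L)
      p_v <- revComp(substr(v, nchar(v) - k + 1L, nchar(v)))
    }
    if (jt == 0L && runif(1) < cfg$pProb) {
      k <- sample(1:2, 1L)
      p_j <- revComp(substr(j, 1L, k))
    }
    if (runif(1) < cfg$nAdditionProb) {
      len <- sample(cfg$nLenRange[1]:cfg$nLenRange[2], 1L)
      n_reg <- .rand_nt(len)
    }
    leader <- germ$leader[pick_v[i]]
    if (is.na(leader)) leader <- ""
    body <- paste0(leader, v_kept, p_v, n_reg, p_j, j_kept, cc)
    cdna[i] <- body
    tr[[i]] <- data.frame(v_id = pick_v[i], j_id = pick_j[i],
                          c_id = pick_c[i], v_trim = vt, p_v = p_v,
                          n_region = n_reg, p_j = p_j, j_trim = jt,
                          stringsAsFactors = FALSE)
  }
  names(cdna) <- sprintf("cdna%05d", seq_len(n))
  truth <- do.call(rbind, tr)
  aa <- .translate_many(unname(cdna))
  truth$productive <- nchar(cdna) %% 3L == 0L &
    !grepl("*", sub("\\*+$", "", aa), fixed = TRUE)
  truth$sequence_id <- names(cdna)
  list(cdna = cdna, truth = truth)
}

#' Simulate amplicon reads from cDNA templates
#'
#' Full-length amplicon reads (`depth` copies per template) with iid
#' substitution errors.
#'
#' @param cdnas named character vector of templates.
#' @param depth copies per template.
#' @param err per-base substitution error rate (0..0.05).
#' @param seed integer seed.
#' @return List with `reads` (named character) and `origin` (template name
#'   per read).
#' @export
simulateReads <- function(cdnas, depth = 1L, err = 0, seed = 1L) {
  stopifnot(err >= 0, err <= 0.05)
  set.seed(seed)
  if (depth < 1L || !length(cdnas))
    return(list(reads = character(0), origin = character(0)))
  origin <- rep(names(cdnas), each = depth)
  reads <- vapply(origin, function(nm)
    if (err > 0) .mutate_free(cdnas[[nm]], err) else cdnas[[nm]],
    character(1))
  names(reads) <- sprintf("%s_r%d", origin,
                          sequence(rep(depth, length(cdnas))))
  list(reads = reads, origin = origin)
}

#' Simulate a CL-proportioned transcriptome read mixture
#'
#' Reads are sampled from the CL references at the given proportions with
#' uniform start positions and iid substitution errors.
#'
#' @param clRefs named character vector (or `DNAStringSet`) of references.
#' @param proportions numeric vector summing to 1, parallel to `clRefs`.
#' @param nReads total reads.
#' @param readLen read length (capped at reference length).
#' @param err substitution error rate.
#' @param seed integer seed.
#' @return List with `reads` (named character) and `truth_counts` (reads per
#'   reference).
#' @export
simulateTranscriptome <- function(clRefs, proportions, nReads,
                                  readLen = 100L, err = 0, seed = 1L) {
  if (is(clRefs, "DNAStringSet")) clRefs <- as.character(clRefs)
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            length(proportions) == length(clRefs))
  set.seed(seed)
  if (nReads < 1L)
    return(list(reads = character(0),
                truth_counts = setNames(rep(0L, length(clRefs)),
                                        names(clRefs))))
  src <- sample(names(clRefs), nReads, replace = TRUE, prob = proportions)
  reads <- vapply(seq_len(nReads), function(i) {
    ref <- clRefs[[src[i]]]
    L <- min(readLen, nchar(ref))
    s <- sample.int(nchar(ref) - L + 1L, 1L)
    rd <- substr(ref, s, s + L - 1L)
    if (err > 0) rd <- .mutate_free(rd, err)
    rd
  }, character(1))
  names(reads) <- sprintf("tr%06d_%s", seq_len(nReads), src)
  list(reads = reads,
       truth_counts = table(factor(src, levels = names(clRefs))))
}

#' Evolve a sequence panel along a tree
#'
#' Substitution-only evolution: along each branch the number of
#' substitutions is Poisson with mean branch-length x sequence-length
#' (branch lengths in expected substitutions per site); mutated coding
#' positions avoid creating in-frame stops.
#'
#' @param tree `phylo` or newick string; tip labels name the leaves.
#' @param rootSeq nucleotide root sequence (in-frame coding).
#' @param seed integer seed.
#' @return Named character vector of leaf sequences.
#' @export
evolvePanel <- function(tree, rootSeq, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("character", n_tip + tree$Nnode)
  seqs[root] <- rootSeq
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  L <- nchar(rootSeq)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    bl <- if (is.null(tree$edge.length)) 0 else tree$edge.length[e]
    nsub <- rpois(1L, bl * L)
    s <- seqs[par]
    if (nsub > 0L) {
      sites <- sample.int(L, min(nsub, L))
      ch <- strsplit(s, "")[[1L]]
      for (p in sites) {
        old <- ch[p]
        for (try in 1:10) {
          new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          ch[p] <- new
          cod_i <- (p - 1L) %/% 3L
          cod <- paste(ch[(cod_i * 3L + 1L):min(cod_i * 3L + 3L, L)],
                       collapse = "")
          if (nchar(cod) < 3L || !cod %in% c("TAA", "TAG", "TGA")) break
          ch[p] <- old
        }
      }
      s <- paste(ch, collapse = "")
    }
    seqs[chd] <- s
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

#' Simulate a protein V-domain panel with planted CDR lengths
#'
#' Profile-derived amino-acid V domains built on the IMGT-style reference of
#' an isotype, with chosen CDR lengths and randomized CDR residue content;
#' used to validate CDR delineation (lengths are recovered exactly because
#' evolution here is substitution-free in the frameworks).
#'
#' @param isotype isotype name (see [imgtReference()]).
#' @param cdr1Lens,cdr2Lens,cdr3Lens integer vectors of planted lengths
#'   (recycled to the longest).
#' @param seed integer seed.
#' @return List with `aa` (named character), `truth` (`data.frame` of planted
#'   lengths).
#' @export
simulateVPanel <- function(isotype = "kappa", cdr1Lens = 6:12,
                           cdr2Lens = 3L, cdr3Lens = 9L, seed = 1L) {
  set.seed(seed)
  n <- max(length(cdr1Lens), length(cdr2Lens), length(cdr3Lens))
  c1 <- rep_len(cdr1Lens, n); c2 <- rep_len(cdr2Lens, n)
  c3 <- rep_len(cdr3Lens, n)
  pool <- setdiff(strsplit("ARNDQEGHILKMPSTVY", "")[[1L]], c("C", "W"))
  aa <- character(n)
  truth <- data.frame(cdr1 = c1, cdr2 = c2, cdr3 = c3)
  for (i in seq_len(n)) {
    ref <- imgtReference(isotype, c(cdr1 = c1[i], cdr2 = c2[i],
                                    cdr3 = c3[i]))
    s <- strsplit(ref$sequence, "")[[1L]]
    # randomize CDR residue content, keep frameworks and anchors intact
    cdr_cols <- which((ref$imgt_pos >= 27 & ref$imgt_pos <= 38) |
                        (ref$imgt_pos >= 56 & ref$imgt_pos <= 65) |
                        (ref$imgt_pos >= 105 & ref$imgt_pos <= 117))
    s[cdr_cols] <- sample(pool, length(cdr_cols), replace = TRUE)
    aa[i] <- paste(s, collapse = "")
  }
  names(aa) <- sprintf("%s_v%02d", isotype, seq_len(n))
  list(aa = aa, truth = truth)
}
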