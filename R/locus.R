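# Germline segment annotation on genomic scaffolds.
#
# C exons are located by local alignment to constant-region references, V
# exons by cross-subfamily similarity plus a downstream RSS and an upstream
# leader exon across an AG/GT intron, and J segments de novo by an adjacent
# RSS plus the splice donor GT at their 3' end. Defect flagging (in-frame
# stops, frameshifts, missing leader, disrupted RSS) demotes segments to
# pseudogenes, and segment counts classify the locus organization.
#
# Coordinates follow the Bioconductor convention (1-based, closed, GRanges).

#' Annotation configuration
#'
#' @param cIdentity,cCoverage minimum percent identity / reference-length
#'   coverage for a C exon hit (defaults 70, 0.80).
#' @param vIdentity,vCoverage thresholds for V exon hits (defaults 60, 0.80;
#'   lower identity permits cross-subfamily detection).
#' @param leaderWindow nt searched upstream of a V exon for the leader exon
#'   and intron donor (default 500).
#' @param flankWindow nt of flank scanned for segment RSS (default 45, one
#'   heptamer + 23 spacer + nonamer + slack).
#' @param jLengthRange allowed J coding length (default 30..60 nt).
#' @param jMinScore RSS score threshold for de novo J discovery (default 13;
#'   stricter than flank classification because J segments are found genome
#'   wide from the RSS alone, without sequence-similarity support).
#' @param rss an [rssConfig()].
#' @return list of class `LocusConfig`.
#' @export
locusConfig <- function(cIdentity = 70, cCoverage = 0.80,
                        vIdentity = 60, vCoverage = 0.80,
                        leaderWindow = 500L, flankWindow = 45L,
                        jLengthRange = c(30L, 60L), jMinScore = 13L,
                        rss = rssConfig()) {
  structure(list(cIdentity = cIdentity, cCoverage = cCoverage,
                 vIdentity = vIdentity, vCoverage = vCoverage,
                 leaderWindow = as.integer(leaderWindow),
                 flankWindow = as.integer(flankWindow),
                 jLengthRange = as.integer(jLengthRange),
                 jMinScore = as.integer(jMinScore), rss = rss),
            class = "LocusConfig")
}

# all sufficiently good local hits of `ref` in `scaffold` by iterative masking
.locate_hits <- function(ref, scaffold, minIdentity, minCoverage,
                         maxHits = 50L) {
  subj <- as.character(scaffold)
  hits <- list()
  for (k in seq_len(maxHits)) {
    al <- localAlign(ref, subj)
    cov <- (al$query_end - al$query_start + 1L) / nchar(as.character(ref))
    if (is.na(al$identity_pct) || al$identity_pct < minIdentity ||
        cov < minCoverage) break
    hits[[k]] <- data.frame(start = al$target_start, end = al$target_end,
                            score = al$score, identity = al$identity_pct,
                            q_start = al$query_start, q_end = al$query_end)
    # mask the hit so the next-best occurrence surfaces
    substr(subj, al$target_start, al$target_end) <-
      strrep("N", al$target_end - al$target_start + 1L)
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

.has_gap <- function(scaffold, start, end) {
  grepl("NNN", substr(as.character(scaffold), start, end), fixed = TRUE)
}

# snap a V-candidate 3' end to the heptamer of its RSS (coding end abuts the
# heptamer); returns NULL if no RSS in the window around the aligned end
.v_rss_near <- function(scaffold, approxEnd, cfg, slack = 10L) {
  s <- as.character(scaffold)
  lo <- max(1L, approxEnd - slack)
  window <- substr(s, lo, min(nchar(s), approxEnd + slack + cfg$flankWindow))
  hits <- scanRSS(window, cfg$rss)
  if (!nrow(hits)) return(NULL)
  hits$abs_hept <- lo + hits$position          # 1-based heptamer start
  hits <- hits[abs(hits$abs_hept - (approxEnd + 1L)) <= slack, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  hits[order(-hits$score, abs(hits$abs_hept - (approxEnd + 1L))), ][1L, ]
}

.leader_upstream <- function(scaffold, vStart, window) {
  s <- as.character(scaffold)
  if (vStart < 10L) return(FALSE)
  # acceptor AG immediately 5' of the V exon
  if (substr(s, vStart - 2L, vStart - 1L) != "AG") return(FALSE)
  lo <- max(1L, vStart - window)
  up <- substr(s, lo, vStart - 3L)
  # a donor GT with a leader-sized ORF start (ATG) upstream of it
  donors <- gregexpr("GT", up, fixed = TRUE)[[1L]]
  if (donors[1L] == -1L) return(FALSE)
  for (d in donors) {
    before <- substr(up, 1L, d - 1L)
    if (nchar(before) >= 24L && grepl("ATG", before, fixed = TRUE))
      return(TRUE)
  }
  FALSE
}

#' Locate V, J and C gene segments on a scaffold
#'
#' @param scaffold nucleotide sequence (character or `DNAString`).
#' @param refs named `DNAStringSet` (or named character vector) of reference
#'   exemplars; names are `"C:<label>"` for constant regions and
#'   `"V:<label>"` for V family exemplars.
#' @param cfg a [locusConfig()].
#' @return `GRanges` on seqname `"scaffold"` with metadata columns `kind`,
#'   `segment_id`, `ref_label`, `identity`, `rss_spacer` (NA when absent),
#'   `has_leader` (V only), `frame`. An empty `GRanges` (with a warning) when
#'   no C reference hits the scaffold.
#' @export
findSegments <- function(scaffold, refs, cfg = locusConfig()) {
  scaffold <- .as_dna(scaffold, "scaffold")
  if (is.character(refs)) refs <- DNAStringSet(refs)
  labs <- names(refs)
  stopifnot(!is.null(labs), all(grepl("^[VC]:", labs)))
  s <- as.character(scaffold)

  rows <- list(); k <- 1L
  add <- function(kind, start, end, id, ref_label, identity, rss_spacer,
                  has_leader, frame) {
    rows[[k]] <<- data.frame(kind = kind, start = start, end = end,
                             segment_id = id, ref_label = ref_label,
                             identity = identity, rss_spacer = rss_spacer,
                             has_leader = has_leader, frame = frame,
                             stringsAsFactors = FALSE)
    k <<- k + 1L
  }

  ## --- C exons ---
  c_refs <- refs[grepl("^C:", labs)]
  c_found <- FALSE
  for (i in seq_along(c_refs)) {
    h <- .locate_hits(c_refs[[i]], scaffold, cfg$cIdentity, cfg$cCoverage)
    if (is.null(h)) next
    for (r in seq_len(nrow(h))) {
      if (.has_gap(scaffold, h$start[r], h$end[r])) {
        warning("C candidate spans an assembly gap; dropped")
        next
      }
      st <- h$start[r]
      # translation offset restoring the reference frame at the hit start
      frame <- (3L - (h$q_start[r] - 1L) %% 3L) %% 3L
      add("C", st, h$end[r], sprintf("C_%d", st),
          sub("^C:", "", names(c_refs)[i]), h$identity[r], NA_integer_,
          NA, frame)
      c_found <- TRUE
    }
  }
  if (!c_found) {
    warning("no constant-region hit: scaffold unclassifiable")
    return(.segments_granges(NULL))
  }

  ## --- V exons ---
  v_refs <- refs[grepl("^V:", labs)]
  for (i in seq_along(v_refs)) {
    h <- .locate_hits(v_refs[[i]], scaffold, cfg$vIdentity, cfg$vCoverage)
    if (is.null(h)) next
    for (r in seq_len(nrow(h))) {
      if (.has_gap(scaffold, h$start[r], h$end[r])) {
        warning("V candidate spans an assembly gap; dropped")
        next
      }
      vstart <- h$start[r] - (h$q_start[r] - 1L)   # extend to full ref start
      vstart <- max(1L, vstart)
      rss <- .v_rss_near(scaffold, h$end[r] + (nchar(as.character(v_refs[[i]])) - h$q_end[r]), cfg)
      vend <- if (!is.null(rss)) rss$abs_hept - 1L else
        h$end[r] + (nchar(as.character(v_refs[[i]])) - h$q_end[r])
      vend <- min(nchar(s), vend)
      if (vend <= vstart) next
      leader <- .leader_upstream(scaffold, vstart, cfg$leaderWindow)
      add("V", vstart, vend, sprintf("V_%d", vstart),
          sub("^V:", "", names(v_refs)[i]), h$identity[r],
          if (!is.null(rss)) rss$spacer_class else NA_integer_,
          leader, 0L)
    }
  }

  ## --- J segments: RSS-adjacent coding with a 3' splice donor GT ---
  # scan reverse complement so J-RSS (heptamer adjacent to coding start on the
  # forward strand) appears in consensus orientation
  rc <- revComp(s)
  j_cfg <- cfg$rss
  j_cfg$minScore <- max(j_cfg$minScore, cfg$jMinScore)
  jh <- scanRSS(rc, j_cfg)
  if (nrow(jh)) {
    # one motif per heptamer position: keep the best-scoring spacer window
    jh <- jh[order(jh$position, -jh$score), , drop = FALSE]
    jh <- jh[!duplicated(jh$position), , drop = FALSE]
  }
  if (nrow(jh)) {
    for (r in seq_len(nrow(jh))) {
      # heptamer start at rc offset p (0-based) corresponds to forward
      # position n - p: the J coding starts immediately after it
      j_start <- nchar(s) - jh$position[r] + 1L
      if (j_start > nchar(s)) next
      jlen <- NA_integer_
      for (L in cfg$jLengthRange[1]:cfg$jLengthRange[2]) {
        if (j_start + L + 1L > nchar(s)) break
        if (substr(s, j_start + L, j_start + L + 1L) == "GT") {
          jlen <- L; break
        }
      }
      if (is.na(jlen)) next
      if (.has_gap(scaffold, j_start, j_start + jlen - 1L)) next
      # identity column carries the RSS match score for J candidates so that
      # overlap resolution keeps the best-supported motif (a 12-spacer window
      # nested inside a true 23-spacer RSS can otherwise shadow the real J)
      add("J", j_start, j_start + jlen - 1L, sprintf("J_%d", j_start),
          NA_character_, jh$score[r], jh$spacer_class[r], NA, 0L)
    }
  }

  df <- do.call(rbind, rows)
  ## overlap resolution per kind: keep highest identity (V/C), leftmost ties
  df <- df[order(df$kind, -ifelse(is.na(df$identity), 0, df$identity),
                 df$start), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[j]) next
      if (df$kind[i] == df$kind[j] &&
          df$start[j] <= df$end[i] && df$end[j] >= df$start[i]) {
        keep[j] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  .segments_granges(df)
}

.segments_granges <- function(df) {
  if (is.null(df) || !nrow(df)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(kind = character(), segment_id = character(),
                           ref_label = character(), identity = numeric(),
                           rss_spacer = integer(), has_leader = logical(),
                           frame = integer(), functionality = character(),
                           defects = character())
    return(gr)
  }
  gr <- GRanges("scaffold", IRanges(df$start, df$end), strand = "+")
  mcols(gr) <- DataFrame(kind = df$kind, segment_id = df$segment_id,
                         ref_label = df$ref_label, identity = df$identity,
                         rss_spacer = as.integer(df$rss_spacer),
                         has_leader = as.logical(df$has_leader),
                         frame = as.integer(df$frame),
                         functionality = rep("functional", nrow(df)),
                         defects = rep("", nrow(df)))
  gr
}

#' Flag pseudogene defects on annotated segments
#'
#' Adds `in_frame_stop` when the translated coding sequence contains a stop,
#' `frameshift` when the coding length differs from the matched reference by a
#' non-multiple of 3, `disrupted_rss` when a V or J segment lacks an RSS, and
#' `missing_leader_exon` when a V has no upstream leader. Any defect sets
#' `functionality` to `"pseudogene"`.
#'
#' @param segs `GRanges` from [findSegments()].
#' @param scaffold the scaffold sequence.
#' @param refs the reference panel used for annotation (for length
#'   comparison).
#' @return The `GRanges` with updated `defects` and `functionality`.
#' @export
flagDefects <- function(segs, scaffold, refs = NULL) {
  if (!length(segs)) return(segs)
  s <- as.character(.as_dna(scaffold, "scaffold"))
  if (!is.null(refs) && is.character(refs)) refs <- DNAStringSet(refs)
  md <- mcols(segs)
  defects <- character(length(segs))
  for (i in seq_along(segs)) {
    d <- character()
    kind <- md$kind[i]
    seq_i <- substr(s, start(segs)[i], end(segs)[i])
    if (kind %in% c("V", "C")) {
      aa <- translateNT(seq_i, md$frame[i])
      # trailing stop after the domain is fine; internal stops are defects
      if (grepl("\\*", sub("\\*+$", "", aa))) d <- c(d, "in_frame_stop")
      lab <- md$ref_label[i]
      if (!is.null(refs) && !is.na(lab)) {
        rn <- paste0(kind, ":", lab)
        if (rn %in% names(refs)) {
          if ((nchar(seq_i) - nchar(as.character(refs[[rn]]))) %% 3L != 0L)
            d <- c(d, "frameshift")
        }
      }
    }
    if (kind %in% c("V", "J") && is.na(md$rss_spacer[i]))
      d <- c(d, "disrupted_rss")
    if (kind == "V" && isFALSE(md$has_leader[i]))
      d <- c(d, "missing_leader_exon")
    defects[i] <- paste(d, collapse = ",")
  }
  md$defects <- defects
  md$functionality <- ifelse(defects == "", "functional", "pseudogene")
  mcols(segs) <- md
  segs
}

#' Classify the organization of a locus from its segments
#'
#' Functional-segment counts decide: no functional V (with RSS) is
#' non-rearranging; exactly one functional V is a V-J-C cluster; two or more
#' functional V with at least one J and one C is a translocon. The locus RSS
#' type is taken from [classifyLocusRSS()] over the functional segments.
#'
#' @param segs `GRanges` of flagged segments (see [flagDefects()]).
#' @param locusId label for the resulting model.
#' @return A [LocusModel-class] object.
#' @export
classifyOrganization <- function(segs, locusId = "locus") {
  if (!length(segs)) stop("no segments to classify")
  md <- mcols(segs)
  fun <- md$functionality == "functional"
  nv <- sum(fun & md$kind == "V")
  nj <- sum(fun & md$kind == "J")
  nc <- sum(fun & md$kind == "C")
  v_sp <- md$rss_spacer[fun & md$kind == "V"]
  j_sp <- md$rss_spacer[fun & md$kind == "J"]
  rss <- classifyLocusRSS(v_sp[!is.na(v_sp)], j_sp[!is.na(j_sp)])
  org <- if (nv == 0L) "non_rearranging"
         else if (nv == 1L && nj >= 1L && nc >= 1L) "vjc_cluster"
         else if (nv >= 2L && nj >= 1L && nc >= 1L) "translocon"
         else "non_rearranging"
  LocusModel(locusId, segs, org, rss)
}

#' Write annotated segments as GFF3
#'
#' @param segs `GRanges` of flagged segments.
#' @param path output path.
#' @param source feature source string.
#' @export
writeSegmentsGFF <- function(segs, path, source = "iglkit") {
  md <- mcols(segs)
  lines <- c("##gff-version 3")
  type_of <- c(L = "exon", V = "V_gene_segment", J = "J_gene_segment",
               C = "C_gene_segment")
  for (i in seq_along(segs)) {
    attrs <- sprintf("ID=%s;kind=%s;functionality=%s;defects=%s;rss_spacer=%s",
                     md$segment_id[i], md$kind[i], md$functionality[i],
                     md$defects[i],
                     ifelse(is.na(md$rss_spacer[i]), ".", md$rss_spacer[i]))
    lines <- c(lines, paste(as.character(seqnames(segs))[i], source,
                            type_of[[md$kind[i]]], start(segs)[i],
                            end(segs)[i], ".",
                            as.character(strand(segs))[i], ".", attrs,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract annotated segment sequences as FASTA
#'
#' @param segs `GRanges` of segments.
#' @param scaffold scaffold sequence.
#' @param path output FASTA path.
#' @export
writeSegmentsFasta <- function(segs, scaffold, path) {
  s <- as.character(.as_dna(scaffold, "scaffold"))
  seqs <- vapply(seq_along(segs), function(i)
    substr(s, start(segs)[i], end(segs)[i]), character(1))
  names(seqs) <- mcols(segs)$segment_id
  writeFasta(seqs, path)
}
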