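.nuc_matrix <- function(match, mismatch) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = TRUE)
}

#' Align one read against a set of candidate gene segments
#'
#' Affine-gap local (Smith--Waterman) alignment of a read against every
#' candidate segment; the highest score wins, ties broken by the
#' lexicographically smallest segment name. Intervals are returned 0-based
#' half-open on both the read and the segment.
#'
#' @param read a nucleotide string (length >= 20).
#' @param segments a subset of `germline_set$segments` (tibble with `name`
#'   and `sequence`), or a named character vector of sequences.
#' @param scoring numeric vector `c(match, mismatch, gap_open, gap_extend)`;
#'   penalties are magnitudes.
#' @return A list: `name`, `score`, `read_interval` (c(start, end)),
#'   `segment_interval`.
#' @export
align_to_segments <- function(read, segments, scoring = c(2, -1, -3, -1)) {
  if (is.character(segments)) {
    segments <- tibble(name = names(segments), sequence = unname(segments))
  }
  if (nrow(segments) == 0) stop("empty candidate segment set")
  if (nchar(read) < 20) stop("read shorter than 20 nt")
  segments <- arrange(segments, .data$name)
  mat <- .nuc_matrix(scoring[1], scoring[2])
  best <- NULL
  for (i in seq_len(nrow(segments))) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(segments$sequence[i]),
      type = "local", substitutionMatrix = mat,
      gapOpening = abs(scoring[3]), gapExtension = abs(scoring[4]))
    sc <- Biostrings::score(pa)
    if (is.null(best) || sc > best$score) {
      pat <- Biostrings::pattern(pa); subj <- Biostrings::subject(pa)
      best <- list(name = segments$name[i], score = sc,
                   read_interval = c(Biostrings::start(pat) - 1L,
                                     Biostrings::end(pat)),
                   segment_interval = c(Biostrings::start(subj) - 1L,
                                        Biostrings::end(subj)))
    }
  }
  best
}

#' Extract the IMGT-style junction from an annotated read
#'
#' The junction spans from the start of the V anchor cysteine codon through
#' the end of the J anchor codon (inclusive). The amino-acid junction is
#' the translation in the V reading frame and is only defined when the
#' junction length is a multiple of 3.
#'
#' @param read nucleotide string.
#' @param v_hit,j_hit alignment hits as returned by [align_to_segments()]
#'   (V before J on the read).
#' @param gl the `germline_set` the hits refer to.
#' @return A list `junction_nt`, `junction_aa` (NA when out of frame), or
#'   `NULL` when an anchor is not locatable within the aligned intervals.
#' @export
extract_junction <- function(read, v_hit, j_hit, gl) {
  s <- gl$segments
  va <- s$anchor_offset[s$name == v_hit$name]
  ja <- s$anchor_offset[s$name == j_hit$name]
  # 1-based read position of the V anchor codon start / J anchor codon end.
  # The V anchor is mapped from the alignment's left end and the J anchor
  # from its right end: indels picked up by the local aligner sit in the
  # junction-facing extension, never between a segment terminus and its
  # anchor, so these linear mappings stay exact.
  v_pos <- v_hit$read_interval[1] + 1L + (va - v_hit$segment_interval[1])
  j_pos <- j_hit$read_interval[2] - (j_hit$segment_interval[2] - (ja + 3L))
  anchors_inside <- va >= v_hit$segment_interval[1] &&
    va + 3L <= v_hit$segment_interval[2] &&
    ja >= j_hit$segment_interval[1] && ja + 3L <= j_hit$segment_interval[2]
  if (!anchors_inside || v_pos < 1L || j_pos > nchar(read) || j_pos <= v_pos)
    return(NULL)
  jx <- substr(read, v_pos, j_pos)
  aa <- if (nchar(jx) %% 3L == 0L) .translate_nt(jx) else NA_character_
  list(junction_nt = jx, junction_aa = aa, v_anchor_read = v_pos,
       j_anchor_end_read = j_pos)
}

#' Four-way productivity classification of a rearrangement
#'
#' Applies the classification used for repertoire preprocessing:
#' a read is `non_ig` when its best V or J alignment is missing or scores
#' below the identity threshold (decoys and orphon-like sequences),
#' `out_of_frame` when the junction length is not a multiple of 3,
#' `stop_codon` when the translation from the V start through the J anchor
#' contains a stop, and productive otherwise. The decision order is fixed,
#' so every read receives exactly one failure mode.
#'
#' @param v_ok,j_ok logical: V / J hit present and above the score threshold.
#' @param junction_nt junction string (NA if not found).
#' @param aa_through_j translation from the V coding start through the J
#'   anchor (NA when unavailable).
#' @return list(productive = flag, failure_mode = one of "none",
#'   "out_of_frame", "stop_codon", "non_ig").
#' @export
classify_productivity <- function(v_ok, j_ok, junction_nt, aa_through_j) {
  if (!isTRUE(v_ok) || !isTRUE(j_ok) || is.na(junction_nt))
    return(list(productive = FALSE, failure_mode = "non_ig"))
  if (nchar(junction_nt) %% 3L != 0L)
    return(list(productive = FALSE, failure_mode = "out_of_frame"))
  if (!is.na(aa_through_j) && grepl("*", aa_through_j, fixed = TRUE))
    return(list(productive = FALSE, failure_mode = "stop_codon"))
  list(productive = TRUE, failure_mode = "none")
}

# vectorised seeded alignment of many reads against one segment class.
# Returns per-read: segment index (NA if none), score, intervals (1-based).
.align_class <- function(rd_chr, seg_tbl, side = c("prefix", "suffix"),
                         scoring, seed_len, full_scan) {
  side <- match.arg(side)
  n <- length(rd_chr)
  out <- list(idx = rep(NA_integer_, n), score = numeric(n),
              p1 = integer(n), p2 = integer(n), s1 = integer(n), s2 = integer(n))
  if (n == 0) return(out)
  keys <- if (side == "prefix") substr(seg_tbl$sequence, 1L, seed_len)
  else substr(seg_tbl$sequence, nchar(seg_tbl$sequence) - seed_len + 1L,
              nchar(seg_tbl$sequence))
  lookup <- setNames(seq_len(nrow(seg_tbl)), keys)
  rkeys <- if (side == "prefix") substr(rd_chr, 1L, seed_len)
  else substr(rd_chr, nchar(rd_chr) - seed_len + 1L, nchar(rd_chr))
  cand <- unname(lookup[rkeys])
  mat <- .nuc_matrix(scoring[1], scoring[2])
  run_aln <- function(ridx, seg_i) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(rd_chr[ridx]),
      Biostrings::DNAString(seg_tbl$sequence[seg_i]),
      type = "local", substitutionMatrix = mat,
      gapOpening = abs(scoring[3]), gapExtension = abs(scoring[4]))
    pat <- Biostrings::pattern(pa); subj <- Biostrings::subject(pa)
    list(score = Biostrings::score(pa),
         p1 = Biostrings::start(pat), p2 = Biostrings::end(pat),
         s1 = Biostrings::start(subj), s2 = Biostrings::end(subj))
  }
  for (seg_i in unique(cand[!is.na(cand)])) {
    ridx <- which(!is.na(cand) & cand == seg_i)
    r <- run_aln(ridx, seg_i)
    out$idx[ridx] <- seg_i; out$score[ridx] <- r$score
    out$p1[ridx] <- r$p1; out$p2[ridx] <- r$p2
    out$s1[ridx] <- r$s1; out$s2[ridx] <- r$s2
  }
  if (full_scan) {
    miss <- which(is.na(cand))
    if (length(miss)) {
      ord <- order(seg_tbl$name)           # lexicographic tie-break
      for (seg_i in ord) {
        r <- run_aln(miss, seg_i)
        better <- r$score > out$score[miss]
        upd <- miss[better]
        out$idx[upd] <- seg_i; out$score[upd] <- r$score[better]
        out$p1[upd] <- r$p1[better]; out$p2[upd] <- r$p2[better]
        out$s1[upd] <- r$s1[better]; out$s2[upd] <- r$s2[better]
      }
    }
  }
  out
}

#' Annotate a repertoire of raw reads against a germline set
#'
#' Produces one AIRR-style rearrangement record per read: V/J gene calls
#' with local-alignment scores, IMGT-style junction and CDR3, the four-way
#' productivity classification, and duplicate collapsing of identical
#' (V, J, junction) reads within a cell.
#'
#' Candidate segments are found by exact terminal seed lookup (the read's
#' 5' prefix against V starts, 3' suffix against J ends) and verified by
#' affine-gap local alignment; with `full_scan = TRUE` reads without a seed
#' hit are additionally scanned against every segment, which is what
#' external (non-simulated) reads need. A hit counts as Ig only when its
#' score reaches `min_ig_frac` of the maximum attainable local score
#' `2 * min(read length, segment length)`; everything below is classified
#' `non_ig` (decoys, orphon-like sequences).
#'
#' @param reads a FASTA path or a named [Biostrings::DNAStringSet]; read
#'   names `cellID|chain` keep cell pairing.
#' @param gl a `germline_set`.
#' @param scoring `c(match, mismatch, gap_open, gap_extend)`.
#' @param min_ig_frac identity fraction below which a hit is discarded.
#' @param seed_len terminal seed length for candidate lookup.
#' @param full_scan also align seed-less reads against all segments.
#' @param collapse collapse duplicate (cell, V, J, junction) reads into one
#'   record with a `duplicate_count`.
#' @return A tibble with AIRR-style columns: `sequence_id`, `cell_id`,
#'   `chain`, `locus`, `v_call`, `d_call`, `j_call`, `junction`,
#'   `junction_aa`, `cdr3_aa`, `productive`, `failure_mode`, `v_score`,
#'   `j_score`, `duplicate_count`, sorted by `sequence_id`.
#' @export
annotate_repertoire <- function(reads, gl, scoring = c(2, -1, -3, -1),
                                min_ig_frac = 0.6, seed_len = 24L,
                                full_scan = FALSE, collapse = TRUE) {
  if (is.character(reads)) {
    reads <- tryCatch(Biostrings::readDNAStringSet(reads),
                      error = function(e) stop("unparseable FASTA: ",
                                               conditionMessage(e)))
  }
  n <- length(reads)
  ids <- names(reads)
  if (n == 0) {
    return(tibble(sequence_id = character(), cell_id = character(),
                  chain = character(), locus = character(),
                  v_call = character(), d_call = character(),
                  j_call = character(), junction = character(),
                  junction_aa = character(), cdr3_aa = character(),
                  productive = logical(), failure_mode = character(),
                  v_score = numeric(), j_score = numeric(),
                  duplicate_count = integer()))
  }
  rd_chr <- as.character(reads)
  s <- gl$segments
  vseg <- s[s$segment_class == "V", ]
  jseg <- s[s$segment_class == "J", ]
  v <- .align_class(rd_chr, vseg, "prefix", scoring, seed_len, full_scan)
  j <- .align_class(rd_chr, jseg, "suffix", scoring, seed_len, full_scan)

  thr <- function(hit, seg_tbl) {
    ok <- !is.na(hit$idx)
    lim <- numeric(length(rd_chr))
    lim[ok] <- min_ig_frac * 2 *
      pmin(nchar(rd_chr[ok]), nchar(seg_tbl$sequence[hit$idx[ok]]))
    ok & hit$score >= lim
  }
  v_ok <- thr(v, vseg)
  j_ok <- thr(j, jseg)
  v_call <- ifelse(v_ok, vseg$name[v$idx], NA_character_)
  j_call <- ifelse(j_ok, jseg$name[j$idx], NA_character_)
  v_locus <- ifelse(v_ok, vseg$locus[v$idx], NA_character_)
  j_locus <- ifelse(j_ok, jseg$locus[j$idx], NA_character_)
  ig <- v_ok & j_ok & v_locus == j_locus
  ig[is.na(ig)] <- FALSE

  junction <- junction_aa <- cdr3_aa <- rep(NA_character_, n)
  aa_through_j <- rep(NA_character_, n)
  v_anchor_read <- rep(NA_integer_, n)
  for (i in which(ig)) {
    hit_v <- list(name = v_call[i], score = v$score[i],
                  read_interval = c(v$p1[i] - 1L, v$p2[i]),
                  segment_interval = c(v$s1[i] - 1L, v$s2[i]))
    hit_j <- list(name = j_call[i], score = j$score[i],
                  read_interval = c(j$p1[i] - 1L, j$p2[i]),
                  segment_interval = c(j$s1[i] - 1L, j$s2[i]))
    jx <- extract_junction(rd_chr[i], hit_v, hit_j, gl)
    if (is.null(jx)) { ig[i] <- FALSE; next }
    junction[i] <- jx$junction_nt
    junction_aa[i] <- jx$junction_aa
    v_anchor_read[i] <- jx$v_anchor_read
    if (!is.na(jx$junction_aa) && nchar(jx$junction_aa) >= 2)
      cdr3_aa[i] <- substr(jx$junction_aa, 2L, nchar(jx$junction_aa) - 1L)
    if (nchar(jx$junction_nt) %% 3L == 0L) {
      # translation from the V coding start through the J anchor end
      t0 <- (v$p1[i]) - (v$s1[i] - 1L) + vseg$reading_frame[v$idx[i]]
      while (t0 < 1L) t0 <- t0 + 3L
      span <- jx$j_anchor_end_read - t0 + 1L
      span <- span - span %% 3L
      if (span >= 3L)
        aa_through_j[i] <- .translate_nt(substr(rd_chr[i], t0, t0 + span - 1L))
    }
  }
  cls <- lapply(seq_len(n), function(i)
    classify_productivity(ig[i], ig[i], junction[i], aa_through_j[i]))
  productive <- vapply(cls, `[[`, logical(1), "productive")
  failure_mode <- vapply(cls, `[[`, character(1), "failure_mode")
  locus <- ifelse(ig, v_locus, NA_character_)
  # reads whose V passed but that are non-Ig overall keep no calls
  v_call[failure_mode == "non_ig"] <- NA_character_
  j_call[failure_mode == "non_ig"] <- NA_character_

  # D-gene call: exact >= 5 nt match of a D core inside the V..J gap
  d_call <- rep(NA_character_, n)
  dseg <- s[s$segment_class == "D", ]
  dseg <- dseg[order(dseg$name), ]
  if (nrow(dseg) > 0) {
    for (i in which(ig & locus == "IGH")) {
      gap <- substr(rd_chr[i], v$p2[i] + 1L, j$p1[i] - 1L)
      if (nchar(gap) < 5L) next
      found <- NA_character_
      for (k in seq_len(nrow(dseg))) {
        dsq <- dseg$sequence[k]
        wmax <- min(nchar(dsq), nchar(gap))
        if (wmax < 5L) next
        for (w in seq(wmax, 5L, by = -1L)) {
          hit <- FALSE
          for (st in seq_len(nchar(dsq) - w + 1L)) {
            if (grepl(substr(dsq, st, st + w - 1L), gap, fixed = TRUE)) {
              hit <- TRUE; break
            }
          }
          if (hit) { found <- dseg$name[k]; break }
        }
        if (!is.na(found)) break
      }
      d_call[i] <- found
    }
  }

  chain <- ifelse(grepl("|", ids, fixed = TRUE), sub("^.*\\|", "", ids),
                  NA_character_)
  out <- tibble(
    sequence_id = ids,
    cell_id = sub("\\|.*$", "", ids),
    chain = chain, locus = locus,
    v_call = v_call, d_call = d_call, j_call = j_call,
    junction = junction, junction_aa = junction_aa, cdr3_aa = cdr3_aa,
    productive = productive, failure_mode = failure_mode,
    v_score = ifelse(v_ok, v$score, 0), j_score = ifelse(j_ok, j$score, 0),
    duplicate_count = 1L)
  if (collapse) {
    out <- out |>
      arrange(.data$sequence_id) |>
      group_by(.data$cell_id, .data$locus, .data$v_call, .data$j_call,
               .data$junction) |>
      mutate(duplicate_count = n()) |>
      slice(1L) |>
      ungroup()
  }
  arrange(out, .data$sequence_id)
}
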