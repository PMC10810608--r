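#' Toy murine immunoglobulin germline model
#'
#' A `germline_set` holds the gene segments of the three murine immunoglobulin
#' loci (Igh, Igk, Igl) as a tibble plus the structural maps the analysis
#' relies on: the Igl cassette topology and the J--C to lambda-family map.
#'
#' The murine Igl locus is modelled with its two-cassette architecture: one
#' cassette holds Iglv2 and Iglv3 upstream of the Iglj2--Iglc2 unit (family
#' lambda2); the second holds Iglv1 upstream of Iglj3--Iglc3 (lambda3) and
#' Iglj1--Iglc1 (lambda1). V--J recombination happens within a cassette.
#' The Igk locus carries five named J segments of which Igkj3 is a pseudogene,
#' leaving four functional Igk-J genes.
#'
#' Segment sequences are random coding-like DNA with implanted junction
#' anchors (the conserved V-region cysteine codon and the J-region
#' \[FW\]G.G motif); gene identity, not sequence content, carries the
#' repertoire statistics. Every V segment is stop-free in its reading frame
#' through the anchor codon. All offsets are 0-based; intervals half-open.
#'
#' @param n_ighv,n_igkv number of heavy-chain and kappa V segments (>= 2).
#' @param n_ighd number of heavy-chain D segments.
#' @param seed integer seed; the build is deterministic for a fixed seed.
#' @return An object of class `germline_set`: a list with elements
#'   `segments` (tibble: name, locus, segment_class, sequence, cassette,
#'   anchor_offset, reading_frame, functional), `igl_cassettes` (cassette id
#'   to V names and J--C pairs), and `lambda_family_of` (named character,
#'   J name to family label).
#' @examples
#' gl <- build_germline(seed = 1)
#' subset(gl$segments, locus == "IGL" & segment_class == "V")$name
#' @export
build_germline <- function(n_ighv = 20, n_igkv = 15, n_ighd = 10, seed = 1) {
  if (!is.numeric(n_ighv) || n_ighv < 2 || !is.numeric(n_igkv) || n_igkv < 2 ||
      !is.numeric(n_ighd) || n_ighd < 1) {
    stop("invalid segment counts: need n_ighv >= 2, n_igkv >= 2, n_ighd >= 1")
  }
  set.seed(as.integer(seed))

  v_len <- 120L; v_anchor <- 111L   # Cys codon at 111..113, 6-nt trimmable tail
  j_len <- 39L;  j_anchor <- 6L     # [FW] codon at 6..8, then G-x-G codons

  make_v <- function(name, locus) {
    body <- .rcodons_nostop(v_anchor / 3L)           # stop-free through anchor
    cys <- sample(c("TGT", "TGC"), 1L)
    tail <- .rcodons_nostop((v_len - v_anchor - 3L) / 3L)
    tibble(name = name, locus = locus, segment_class = "V",
           sequence = paste0(body, cys, tail), cassette = NA_character_,
           anchor_offset = v_anchor, reading_frame = 0L, functional = TRUE)
  }
  make_j <- function(name, locus) {
    head_nt <- .rdna(j_anchor)
    fw <- sample(c("TTT", "TTC", "TGG"), 1L)         # Phe or Trp anchor
    gly1 <- paste0("GG", sample(DNA_BASES, 1L))
    mid <- .rcodons_nostop(1L)
    gly2 <- paste0("GG", sample(DNA_BASES, 1L))
    rest <- .rdna(j_len - j_anchor - 12L)
    tibble(name = name, locus = locus, segment_class = "J",
           sequence = paste0(head_nt, fw, gly1, mid, gly2, rest),
           cassette = NA_character_, anchor_offset = j_anchor,
           reading_frame = 0L, functional = TRUE)
  }
  make_plain <- function(name, locus, cls, len) {
    tibble(name = name, locus = locus, segment_class = cls,
           sequence = .rdna(len), cassette = NA_character_,
           anchor_offset = NA_integer_, reading_frame = 0L, functional = TRUE)
  }

  segs <- bind_rows(
    bind_rows(lapply(sprintf("Ighv%d-1", seq_len(n_ighv)), make_v, locus = "IGH")),
    bind_rows(lapply(sprintf("Ighd%d", seq_len(n_ighd)), make_plain,
                     locus = "IGH", cls = "D", len = 12L)),
    bind_rows(lapply(sprintf("Ighj%d", 1:4), make_j, locus = "IGH")),
    bind_rows(lapply(sprintf("Igkv%d", seq_len(n_igkv)), make_v, locus = "IGK")),
    bind_rows(lapply(sprintf("Igkj%d", 1:5), make_j, locus = "IGK")),
    bind_rows(lapply(sprintf("Iglv%d", 1:3), make_v, locus = "IGL")),
    bind_rows(lapply(sprintf("Iglj%d", 1:3), make_j, locus = "IGL")),
    bind_rows(lapply(sprintf("Iglc%d", 1:3), make_plain,
                     locus = "IGL", cls = "C", len = 30L))
  )
  segs$functional[segs$name == "Igkj3"] <- FALSE      # pseudogene
  segs$cassette[segs$name %in% c("Iglv2", "Iglv3", "Iglj2", "Iglc2")] <- "1"
  segs$cassette[segs$name %in% c("Iglv1", "Iglj1", "Iglj3",
                                 "Iglc1", "Iglc3")] <- "2"

  # the alignment seeds (terminal 24-mers) must be unique across segments;
  # regenerate deterministically on the vanishingly rare collision
  for (pass in 1:100) {
    pre <- substr(segs$sequence, 1L, 24L)
    suf <- substr(segs$sequence, nchar(segs$sequence) - 23L, nchar(segs$sequence))
    dup <- duplicated(pre) | duplicated(pre, fromLast = TRUE) |
      duplicated(suf) | duplicated(suf, fromLast = TRUE)
    if (!any(dup)) break
    for (i in which(dup)) {
      row <- segs[i, ]
      segs[i, ] <- switch(row$segment_class,
        V = mutate(make_v(row$name, row$locus),
                   cassette = row$cassette, functional = row$functional),
        J = mutate(make_j(row$name, row$locus),
                   cassette = row$cassette, functional = row$functional),
        mutate(make_plain(row$name, row$locus, row$segment_class,
                          nchar(row$sequence)),
               cassette = row$cassette, functional = row$functional))
    }
  }

  gl <- structure(
    list(
      segments = segs,
      igl_cassettes = list(
        "1" = list(v = c("Iglv2", "Iglv3"),
                   jc = list(c(j = "Iglj2", c = "Iglc2"))),
        "2" = list(v = "Iglv1",
                   jc = list(c(j = "Iglj3", c = "Iglc3"),
                             c(j = "Iglj1", c = "Iglc1")))
      ),
      lambda_family_of = c(Iglj1 = "lambda1", Iglj2 = "lambda2",
                           Iglj3 = "lambda3")
    ),
    class = "germline_set"
  )
  validate_germline(gl)
  gl
}

#' Validate a germline set against its structural invariants
#'
#' Checks the nucleotide alphabet, anchor placement (codon boundary, inside
#' the segment), the V-region cysteine and J-region \[FW\]G.G anchors, name
#' uniqueness, the stop-free V reading frame, and that the Igl cassette map
#' partitions the Igl V and J segments.
#'
#' @param gl a `germline_set`.
#' @return `gl`, invisibly; errors describe the first violated invariant.
#' @export
validate_germline <- function(gl) {
  stopifnot(inherits(gl, "germline_set"))
  s <- gl$segments
  if (nrow(s) == 0) stop("empty germline set")
  if (anyDuplicated(s$name)) stop("duplicate segment names")
  if (!all(grepl("^[ACGT]+$", s$sequence))) stop("non-ACGT characters in sequences")
  has_anchor <- !is.na(s$anchor_offset)
  if (!all(s$segment_class[has_anchor] %in% c("V", "J")))
    stop("anchor on a non-V/J segment")
  if (any(!has_anchor & s$segment_class %in% c("V", "J")))
    stop(sprintf("V/J segment without anchor: %s",
                 paste(s$name[!has_anchor & s$segment_class %in% c("V", "J")],
                       collapse = ", ")))
  a <- s[has_anchor, ]
  if (!all(a$anchor_offset < nchar(a$sequence) - 2))
    stop("anchor_offset beyond sequence end")
  if (!all((a$anchor_offset - a$reading_frame) %% 3 == 0))
    stop("anchor_offset off the codon grid")
  for (i in seq_len(nrow(a))) {
    seq_i <- a$sequence[i]; off <- a$anchor_offset[i]
    if (a$segment_class[i] == "V") {
      aa <- .translate_nt(substr(seq_i, a$reading_frame[i] + 1L, off + 3L))
      if (substr(aa, nchar(aa), nchar(aa)) != "C")
        stop(sprintf("V segment %s lacks anchor Cys", a$name[i]))
      if (grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
        stop(sprintf("V segment %s has a stop before the anchor", a$name[i]))
    } else {
      aa <- .translate_nt(substr(seq_i, off + 1L, off + 12L))
      if (!grepl("^[FW]G.G$", aa))
        stop(sprintf("J segment %s lacks the [FW]G.G motif", a$name[i]))
    }
  }
  igl_v <- s$name[s$locus == "IGL" & s$segment_class == "V"]
  igl_j <- s$name[s$locus == "IGL" & s$segment_class == "J"]
  cass_v <- unlist(lapply(gl$igl_cassettes, `[[`, "v"))
  cass_j <- unlist(lapply(gl$igl_cassettes,
                          function(cc) vapply(cc$jc, `[[`, "", "j")))
  if (anyDuplicated(cass_v) || anyDuplicated(cass_j) ||
      !setequal(cass_v, igl_v) || !setequal(cass_j, igl_j))
    stop("igl_cassettes does not partition the Igl V/J segments")
  invisible(gl)
}

#' @export
print.germline_set <- function(x, ...) {
  tab <- table(x$segments$locus, x$segments$segment_class)
  cat("<germline_set>", nrow(x$segments), "segments\n")
  print(tab)
  invisible(x)
}

#' Cassette relationship of a V--J pair
#'
#' Classifies a V--J gene pair relative to the Igl cassette topology:
#' `same_cassette` when both belong to one cassette (the biologically
#' preferred configuration), `cross_cassette` when they span cassettes,
#' and `not_igl` for any non-Igl pair.
#'
#' @param gl a `germline_set`.
#' @param v_name,j_name segment names present in `gl`.
#' @return One of `"same_cassette"`, `"cross_cassette"`, `"not_igl"`.
#' @examples
#' gl <- build_germline(seed = 1)
#' cassette_of(gl, "Iglv1", "Iglj1")  # same_cassette
#' cassette_of(gl, "Iglv2", "Iglj1")  # cross_cassette
#' @export
cassette_of <- function(gl, v_name, j_name) {
  s <- gl$segments
  for (nm in c(v_name, j_name)) {
    if (!nm %in% s$name) stop(sprintf("unknown segment name: %s", nm))
  }
  loc_v <- s$locus[s$name == v_name]
  loc_j <- s$locus[s$name == j_name]
  if (loc_v != "IGL" || loc_j != "IGL") return("not_igl")
  for (cass in gl$igl_cassettes) {
    js <- vapply(cass$jc, `[[`, "", "j")
    if (v_name %in% cass$v && j_name %in% js) return("same_cassette")
  }
  "cross_cassette"
}

#' Lambda family of an Igl J gene
#'
#' @param gl a `germline_set`.
#' @param j_name character vector of Igl J segment names.
#' @return Character vector of family labels (`"lambda1"`, `"lambda2"`,
#'   `"lambda3"`); `NA` for non-Igl-J names.
#' @export
lambda_family <- function(gl, j_name) {
  unname(gl$lambda_family_of[j_name])
}

#' Write / read a germline set as annotated FASTA
#'
#' The description line carries the structured fields in a pipe-delimited
#' grammar: `name|locus|class|cassette=<id or .>|anchor=<offset or .>|`
#' `frame=<0-2>|func=<0/1>`, e.g. `>Iglv1|IGL|V|cassette=2|anchor=111|frame=0|func=1`.
#' `write_germline_fasta` followed by `read_germline_fasta` is the identity
#' on the germline set, field for field.
#'
#' @param gl a `germline_set`.
#' @param path file path.
#' @return `write_germline_fasta`: `path` invisibly. `read_germline_fasta`:
#'   a `germline_set`.
#' @export
write_germline_fasta <- function(gl, path) {
  validate_germline(gl)
  s <- gl$segments
  hdr <- sprintf("%s|%s|%s|cassette=%s|anchor=%s|frame=%d|func=%d",
                 s$name, s$locus, s$segment_class,
                 ifelse(is.na(s$cassette), ".", s$cassette),
                 ifelse(is.na(s$anchor_offset), ".", s$anchor_offset),
                 s$reading_frame, as.integer(s$functional))
  x <- Biostrings::DNAStringSet(setNames(s$sequence, hdr))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_germline_fasta
#' @export
read_germline_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty germline FASTA: no records")
  parse_one <- function(hdr) {
    f <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    if (length(f) != 7)
      stop(sprintf("malformed germline header (expected 7 fields): '%s'", hdr))
    kv <- function(field, key) {
      if (!startsWith(field, paste0(key, "=")))
        stop(sprintf("malformed germline header (missing %s=): '%s'", key, hdr))
      sub(paste0("^", key, "="), "", field)
    }
    cass <- kv(f[4], "cassette"); anch <- kv(f[5], "anchor")
    if (f[3] %in% c("V", "J") && anch == ".")
      stop(sprintf("germline record '%s': %s segment without anchor", f[1], f[3]))
    tibble(name = f[1], locus = f[2], segment_class = f[3],
           cassette = if (cass == ".") NA_character_ else cass,
           anchor_offset = if (anch == ".") NA_integer_ else as.integer(anch),
           reading_frame = as.integer(kv(f[6], "frame")),
           functional = kv(f[7], "func") == "1")
  }
  meta <- bind_rows(lapply(names(x), parse_one))
  meta$sequence <- unname(as.character(x))
  segs <- meta[, c("name", "locus", "segment_class", "sequence", "cassette",
                   "anchor_offset", "reading_frame", "functional")]
  # rebuild the structural maps from the cassette annotations + J index
  jc_pair <- function(j) c(j = j, c = sub("j", "c", j))
  cass_ids <- sort(unique(segs$cassette[!is.na(segs$cassette)]))
  igl_cassettes <- lapply(setNames(cass_ids, cass_ids), function(id) {
    inside <- segs[!is.na(segs$cassette) & segs$cassette == id, ]
    list(v = inside$name[inside$segment_class == "V"],
         jc = lapply(sort(inside$name[inside$segment_class == "J"]), jc_pair))
  })
  igl_j <- sort(segs$name[segs$locus == "IGL" & segs$segment_class == "J"])
  fam <- setNames(sprintf("lambda%s", sub("^Iglj", "", igl_j)), igl_j)
  gl <- structure(list(segments = segs, igl_cassettes = igl_cassettes,
                       lambda_family_of = fam),
                  class = "germline_set")
  validate_germline(gl)
  gl
}
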