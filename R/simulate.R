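#' @importFrom utils modifyList
NULL

# geometric trim length, capped; p = 0 disables trimming entirely
.trim_len <- function(p, cap) if (p <= 0) 0L else min(rgeom(1L, p), cap)

# draw a failure mode for one read given the preset's unproductive fraction
.draw_failure_mode <- function(preset, locus) {
  u <- preset$unproductive_fraction_per_locus[[locus]]
  if (runif(1L) >= u) return("none")
  if (runif(1L) < preset$stop_codon_share_of_unproductive) "stop_codon"
  else "out_of_frame"
}

# Build one rearranged read and its junction from drawn segments.
# The junction spans the V anchor-Cys codon through the J anchor codon
# (IMGT-style). Productivity is forced to the requested failure mode by
# adjusting the N-addition length (frame) and rewriting stop codons.
.build_read <- function(vrow, jrow, drow = NULL, preset, failure_mode) {
  vseq <- vrow$sequence; va <- vrow$anchor_offset
  jseq <- jrow$sequence; ja <- jrow$anchor_offset
  cap <- preset$trim_cap
  v_tail_max <- nchar(vseq) - va - 3L            # nt after the anchor codon
  trim_v <- min(.trim_len(preset$trim_p, cap), v_tail_max)
  trim_j <- min(.trim_len(preset$trim_p, cap), ja)
  v_part <- substr(vseq, va + 1L, nchar(vseq) - trim_v)   # anchor..trimmed end
  j_part <- substr(jseq, trim_j + 1L, ja + 3L)            # trimmed head..anchor
  heavy <- !is.null(drow)
  if (heavy) {
    d <- drow$sequence
    dt1 <- min(.trim_len(preset$trim_p, 3L), 3L)
    dt2 <- min(.trim_len(preset$trim_p, 3L), 3L)
    d_part <- substr(d, dt1 + 1L, nchar(d) - dt2)
    n1 <- rpois(1L, preset$n_add_heavy / 2)
    n2 <- rpois(1L, preset$n_add_heavy / 2)
  } else {
    d_part <- ""
    n1 <- rpois(1L, preset$n_add_light)
    n2 <- 0L
  }
  # force the junction frame: multiple of 3 for none/stop_codon, off-grid
  # for out_of_frame
  len0 <- nchar(v_part) + n1 + nchar(d_part) + n2 + nchar(j_part)
  rem <- len0 %% 3L
  delta <- if (failure_mode == "out_of_frame") {
    target <- sample(1:2, 1L)
    (target - rem) %% 3L
  } else {
    (3L - rem) %% 3L
  }
  n1 <- n1 + delta
  if (failure_mode == "stop_codon" &&
      nchar(v_part) + n1 + nchar(d_part) + n2 + nchar(j_part) < 9L) {
    n1 <- n1 + 3L                                # room for an injected stop
  }
  mid <- paste0(.rdna(n1), d_part, .rdna(n2))
  junction <- paste0(v_part, mid, j_part)

  if (failure_mode %in% c("none", "stop_codon")) {
    L <- nchar(junction)
    codon_starts <- if (L >= 9L) seq(4L, L - 5L, by = 3L) else integer(0)
    stops <- if (length(codon_starts)) {
      codons <- substring(junction, codon_starts, codon_starts + 2L)
      codon_starts[codons %in% STOP_CODONS]
    } else integer(0)
    if (failure_mode == "none") {
      for (ps in stops) substr(junction, ps, ps) <- "C"   # TAA->CAA etc.
    } else if (length(stops) == 0L) {
      ps <- codon_starts[sample.int(length(codon_starts), 1L)]
      substr(junction, ps, ps + 2L) <- "TAA"
    }
  }
  read <- paste0(substr(vseq, 1L, va), junction,
                 substr(jseq, ja + 4L, nchar(jseq)))
  list(read = read, junction = junction)
}

.truth_row <- function(locus, v, d, j, built, failure_mode, n_edit_rounds = NA_integer_) {
  list(locus = locus, v_call_truth = v, d_call_truth = d, j_call_truth = j,
       junction_truth = built$junction, sequence_nt = built$read,
       productive_truth = failure_mode == "none",
       failure_mode_truth = failure_mode,
       n_edit_rounds = n_edit_rounds)
}

#' Simulate one heavy-chain rearrangement
#'
#' Draws V, D and J segments (uniformly over functional segments unless a
#' clonal expansion forces the V gene), builds the junction as V-tail +
#' N1 + D-core + N2 + J-head with geometric exonuclease trimming and
#' Poisson N-additions, and forces the read's productivity to a Bernoulli
#' draw of the preset's IGH unproductive fraction.
#'
#' @param gl a `germline_set`.
#' @param preset a `genotype_preset`.
#' @param forced_v optional V gene name (clonal expansion).
#' @param forced_productive force a productive read (used for clone seeds).
#' @return One-row tibble with the ground-truth fields (`locus`,
#'   `v_call_truth`, `d_call_truth`, `j_call_truth`, `junction_truth`,
#'   `sequence_nt`, `productive_truth`, `failure_mode_truth`).
#' @export
recombine_heavy <- function(gl, preset, forced_v = NULL,
                            forced_productive = FALSE) {
  as_tibble(.recombine_heavy_core(gl, preset, forced_v, forced_productive))
}

.recombine_heavy_core <- function(gl, preset, forced_v = NULL,
                                  forced_productive = FALSE) {
  s <- gl$segments
  vs <- s[s$locus == "IGH" & s$segment_class == "V" & s$functional, ]
  ds <- s[s$locus == "IGH" & s$segment_class == "D" & s$functional, ]
  js <- s[s$locus == "IGH" & s$segment_class == "J" & s$functional, ]
  vrow <- if (!is.null(forced_v)) s[s$name == forced_v, ] else
    vs[sample.int(nrow(vs), 1L), ]
  drow <- ds[sample.int(nrow(ds), 1L), ]
  jrow <- js[sample.int(nrow(js), 1L), ]
  fm <- if (forced_productive) "none" else .draw_failure_mode(preset, "IGH")
  built <- .build_read(vrow, jrow, drow, preset, fm)
  .truth_row("IGH", vrow$name, drow$name, jrow$name, built, fm)
}

#' Simulate one light-chain rearrangement (empirical mode)
#'
#' Chooses the locus so that the kappa share *among productive light
#' chains* equals the preset's `kappa_fraction` (the raw locus probability
#' is back-solved from the per-locus unproductive fractions). Igk V genes
#' are uniform and J genes follow `igk_j_weights`; Igl V--J pairs are drawn
#' jointly via the lambda-family weights and the cassette map, so
#' cross-cassette pairs never arise.
#'
#' @inheritParams recombine_heavy
#' @return One-row truth tibble as in [recombine_heavy()].
#' @export
rearrange_light_empirical <- function(gl, preset) {
  as_tibble(.rearrange_light_empirical_core(gl, preset))
}

.rearrange_light_empirical_core <- function(gl, preset) {
  stopifnot(preset$mode == "empirical")
  if (isTRUE(preset$kappa_silenced) && preset$kappa_fraction > 0)
    stop("preset contradiction: kappa_fraction > 0 with kappa_silenced = TRUE")
  f <- preset$kappa_fraction
  uk <- preset$unproductive_fraction_per_locus[["IGK"]]
  ul <- preset$unproductive_fraction_per_locus[["IGL"]]
  q <- if (f >= 1) 1 else if (f <= 0) 0 else
    f * (1 - ul) / (f * (1 - ul) + (1 - f) * (1 - uk))
  s <- gl$segments
  if (runif(1L) < q) {
    locus <- "IGK"
    vs <- s[s$locus == "IGK" & s$segment_class == "V" & s$functional, ]
    vrow <- vs[sample.int(nrow(vs), 1L), ]
    jname <- .draw1(preset$igk_j_weights)
  } else {
    locus <- "IGL"
    fam <- .draw1(preset$lambda_family_weights)
    if (fam == "lambda2") {
      vname <- if (runif(1L) < preset$igl_v2_share_within_lambda2)
        "Iglv2" else "Iglv3"
      jname <- "Iglj2"
    } else {
      vname <- "Iglv1"
      jname <- if (fam == "lambda1") "Iglj1" else "Iglj3"
    }
    vrow <- s[s$name == vname, ]
  }
  jrow <- s[s$name == jname, ]
  fm <- .draw_failure_mode(preset, locus)
  built <- .build_read(vrow, jrow, NULL, preset, fm)
  .truth_row(locus, vrow$name, NA_character_, jname, built, fm)
}

#' Simulate one light-chain rearrangement (mechanistic mode)
#'
#' Sequential kappa-then-lambda rearrangement with receptor editing. The
#' cell attempts Igk rearrangements (two alleles, J segments tried in
#' ascending functional order so that secondary rearrangements move to
#' higher-numbered J genes, skipping the Igkj3 pseudogene) unless the locus
#' is silenced. Each attempt succeeds with `p_igk_productive`; a successful
#' but autoreactive kappa chain (`p_autoreactive_kappa`, or always under
#' `kappa_forced_autoreactive`) sends the cell back into editing. When both
#' kappa alleles are exhausted (RS deletion after at most
#' `max_edit_attempts` J steps per allele), the cell attempts Igl -- but
#' only if the locus opened (`p_igl_open`, drawn once per cell), choosing a
#' lambda family (uniform over cassette-consistent units) and succeeding
#' with `p_igl_productive` per attempt. Every attempt carries a death
#' hazard derived from `survival_halflife` (attempts at which survival is
#' 50%). `n_edit_rounds` counts rearrangement attempts after the first.
#'
#' @inheritParams recombine_heavy
#' @return One-row truth tibble, or `NULL` when the cell dies before a
#'   usable light chain is produced (cell death).
#' @export
rearrange_light_mechanistic <- function(gl, preset) {
  res <- .rearrange_light_mechanistic_core(gl, preset)
  if (is.null(res)) NULL else as_tibble(res)
}

.rearrange_light_mechanistic_core <- function(gl, preset) {
  stopifnot(preset$mode == "mechanistic")
  s <- gl$segments
  p_live <- 2 ^ (-1 / preset$survival_halflife)   # per-attempt survival
  igl_open <- runif(1L) < preset$p_igl_open
  attempts <- 0L

  kappa_js <- s$name[s$locus == "IGK" & s$segment_class == "J" & s$functional]
  kappa_js <- kappa_js[order(as.integer(sub("^Igkj", "", kappa_js)))]
  n_steps <- min(preset$max_edit_attempts, length(kappa_js))

  emit <- function(locus, vname, jname) {
    vrow <- s[s$name == vname, ]; jrow <- s[s$name == jname, ]
    built <- .build_read(vrow, jrow, NULL, preset, "none")
    .truth_row(locus, vname, NA_character_, jname, built, "none",
               n_edit_rounds = attempts - 1L)
  }

  if (!isTRUE(preset$kappa_silenced)) {
    kvs <- s$name[s$locus == "IGK" & s$segment_class == "V" & s$functional]
    for (allele in 1:2) {
      for (step in seq_len(n_steps)) {
        attempts <- attempts + 1L
        if (runif(1L) >= p_live) return(NULL)          # death on this attempt
        if (runif(1L) < preset$p_igk_productive) {
          autoreactive <- isTRUE(preset$kappa_forced_autoreactive) ||
            runif(1L) < preset$p_autoreactive_kappa
          if (!autoreactive)
            return(emit("IGK", sample(kvs, 1L), kappa_js[step]))
          # autoreactive: keep editing (next J / allele)
        }
      }
    }
  }
  if (!igl_open) return(NULL)                          # RS deletion, Igl shut
  units <- list(c("Iglv1", "Iglj1"), c("Iglv2", "Iglj2"),
                c("Iglv3", "Iglj2"), c("Iglv1", "Iglj3"))
  repeat {
    attempts <- attempts + 1L
    if (runif(1L) >= p_live) return(NULL)
    if (runif(1L) < preset$p_igl_productive) {
      u <- units[[sample.int(length(units), 1L)]]
      return(emit("IGL", u[1], u[2]))
    }
  }
}

#' Simulate a paired single-cell repertoire
#'
#' Emits one heavy and one light read per surviving cell, plus decoy non-Ig
#' reads (random DNA) at `decoy_rate`, together with a full ground-truth
#' manifest. Per-cell RNG sub-streams are derived from the master seed and
#' the cell index, so increasing `n_cells` leaves earlier cells unchanged.
#' Cells assigned to an injected clonal expansion copy a clone-specific
#' productive heavy rearrangement (identical junction), mirroring a
#' clonally expanded B-cell population.
#'
#' @param gl a `germline_set`.
#' @param preset a `genotype_preset`.
#' @param n_cells number of cells to simulate (>= 1).
#' @param seed master integer seed; the output is byte-deterministic.
#' @param decoy_rate expected decoy reads per Ig read.
#' @return A list with `reads` (named [Biostrings::DNAStringSet], headers
#'   `cellID|heavy`, `cellID|light`, `decoyID|decoy`) and `truth` (tibble:
#'   one row per read with `sequence_id`, `cell_id`, `chain`, truth fields,
#'   `clone_id`, `died`).
#' @seealso [write_repertoire()] to serialise reads and manifest.
#' @export
simulate_repertoire <- function(gl, preset, n_cells, seed, decoy_rate = 0.05) {
  stopifnot(n_cells >= 1)
  preset <- validate_preset(preset)
  ce <- preset$clonal_expansion
  clone_heavy <- list()
  if (!is.null(ce)) {
    for (cl in seq_len(ce$n_clones)) {
      set.seed(.sub_seed(seed, 0L, salt = cl))
      clone_heavy[[cl]] <- .recombine_heavy_core(gl, preset,
                                                 forced_v = ce$forced_v_gene,
                                                 forced_productive = TRUE)
    }
  }
  blank <- list(locus = NA_character_, v_call_truth = NA_character_,
                d_call_truth = NA_character_, j_call_truth = NA_character_,
                junction_truth = NA_character_, sequence_nt = NA_character_,
                productive_truth = NA, failure_mode_truth = NA_character_,
                n_edit_rounds = NA_integer_)
  rows <- vector("list", 2L * n_cells)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  clone_ids <- rep(NA_character_, n_cells)
  died <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(.sub_seed(seed, i))
    if (!is.null(ce)) {
      u <- runif(1L)
      if (u < ce$n_clones * ce$clone_mass)
        clone_ids[i] <- sprintf("clone%02d", floor(u / ce$clone_mass) + 1L)
    }
    heavy <- if (!is.na(clone_ids[i]))
      clone_heavy[[as.integer(sub("clone", "", clone_ids[i]))]]
    else .recombine_heavy_core(gl, preset)
    light <- if (preset$mode == "empirical")
      .rearrange_light_empirical_core(gl, preset)
    else .rearrange_light_mechanistic_core(gl, preset)
    if (is.null(light)) {                       # mechanistic cell death
      died[i] <- TRUE
      rows[[2L * i - 1L]] <- blank
      rows[[2L * i]] <- blank
      next
    }
    rows[[2L * i - 1L]] <- heavy
    rows[[2L * i]] <- light
  }
  col <- function(nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  truth <- tibble(
    sequence_id = paste0(rep(cell_ids, each = 2L), "|",
                         rep(c("heavy", "light"), n_cells)),
    cell_id = rep(cell_ids, each = 2L),
    chain = rep(c("heavy", "light"), n_cells),
    locus = col("locus"),
    v_call_truth = col("v_call_truth"), d_call_truth = col("d_call_truth"),
    j_call_truth = col("j_call_truth"),
    junction_truth = col("junction_truth"),
    sequence_nt = col("sequence_nt"),
    productive_truth = col("productive_truth"),
    failure_mode_truth = col("failure_mode_truth"),
    n_edit_rounds = col("n_edit_rounds"),
    clone_id = rep(clone_ids, each = 2L),
    died = rep(died, each = 2L))
  truth$sequence_id[truth$died] <- NA_character_
  truth$chain[truth$died] <- NA_character_
  # dead cells keep a single manifest row
  truth <- truth[!(truth$died & duplicated(paste(truth$cell_id))), ]
  # decoy non-Ig reads
  set.seed(.sub_seed(seed, n_cells + 1L, salt = 99L))
  n_ig_reads <- sum(!truth$died)
  n_decoys <- rbinom(1L, n_ig_reads, decoy_rate)
  if (n_decoys > 0) {
    decoys <- tibble(
      sequence_id = sprintf("decoy%05d|decoy", seq_len(n_decoys)),
      cell_id = sprintf("decoy%05d", seq_len(n_decoys)),
      chain = "decoy", locus = NA_character_,
      v_call_truth = NA_character_, d_call_truth = NA_character_,
      j_call_truth = NA_character_, junction_truth = NA_character_,
      sequence_nt = vapply(seq_len(n_decoys), function(k) .rdna(150L), ""),
      productive_truth = FALSE, failure_mode_truth = "non_ig",
      n_edit_rounds = NA_integer_, clone_id = NA_character_, died = FALSE)
    truth <- bind_rows(truth, decoys)
  }
  live <- truth[!truth$died, ]
  reads <- Biostrings::DNAStringSet(setNames(live$sequence_nt,
                                             live$sequence_id))
  list(reads = reads, truth = truth)
}

#' Write simulated reads and truth manifest to disk
#'
#' @param sim result of [simulate_repertoire()].
#' @param fasta_path output FASTA path for the reads.
#' @param manifest_path output TSV path for the ground-truth manifest.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_repertoire <- function(sim, fasta_path, manifest_path) {
  Biostrings::writeXStringSet(sim$reads, fasta_path, width = 80L)
  readr::write_tsv(sim$truth, manifest_path, progress = FALSE)
  invisible(c(fasta = fasta_path, manifest = manifest_path))
}
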