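.usage_table <- function(labels, counts, axis, locus = NA_character_) {
  counts <- as.integer(counts)
  total <- sum(counts)
  tbl <- tibble(label = labels, count = counts,
                frequency = if (total > 0) counts / total else rep(0, length(counts)))
  structure(tbl, axis = axis, locus = locus, empty = total == 0,
            class = c("usage_table", class(tbl)))
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("<usage_table> axis=%s locus=%s\n",
              attr(x, "axis"), attr(x, "locus")))
  NextMethod()
}

#' Preprocess annotated rearrangements for repertoire statistics
#'
#' Standard repertoire preprocessing: keep productive records whose CDR3 is
#' at least `min_cdr3_aa_len` amino acids long and whose CDR3 occurs at
#' least `min_occurrence` times within its chain (locus), counting
#' duplicate-collapsed reads via `duplicate_count`. The default
#' `min_occurrence = 2` keeps CDR3s occurring more than once. The filter is
#' idempotent.
#'
#' @param records annotation tibble from [annotate_repertoire()].
#' @param min_cdr3_aa_len minimum CDR3 length in amino acids.
#' @param min_occurrence minimum per-locus CDR3 occurrence count.
#' @return The filtered tibble.
#' @export
preprocess_repertoire <- function(records, min_cdr3_aa_len = 4,
                                  min_occurrence = 2) {
  kept <- records |>
    filter(.data$productive, !is.na(.data$cdr3_aa),
           nchar(.data$cdr3_aa) >= min_cdr3_aa_len)
  kept |>
    group_by(.data$locus, .data$cdr3_aa) |>
    mutate(.occ = sum(.data$duplicate_count)) |>
    ungroup() |>
    filter(.data$.occ >= min_occurrence) |>
    select(-".occ")
}

#' Isotype and lambda-family frequencies over cells
#'
#' Computes the kappa/lambda split over cells that carry a productive light
#' chain, and the lambda1/lambda2/lambda3 family distribution (assigned
#' from the `j_call` through the J--C linkage) over the lambda cells.
#' Cells without a productive light chain are excluded (the BCR-negative
#' pool) and reported as `n_bcr_negative`.
#'
#' @param records annotation tibble (unfiltered or preprocessed).
#' @param gl the `germline_set` (provides the J-to-family map).
#' @return list(isotype = usage_table over c("IGK","IGL"), lambda_family =
#'   usage_table over families, n_bcr_negative = count of cells with reads
#'   but no productive light chain).
#' @export
isotype_family_frequencies <- function(records, gl) {
  lights <- records |>
    filter(.data$locus %in% c("IGK", "IGL"), .data$productive) |>
    group_by(.data$cell_id) |>
    arrange(desc(.data$v_score), .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  n_cells_total <- length(unique(records$cell_id[!is.na(records$chain) &
                                                   records$chain != "decoy"]))
  iso <- .usage_table(c("IGK", "IGL"),
                      c(sum(lights$locus == "IGK"), sum(lights$locus == "IGL")),
                      axis = "isotype")
  lam <- lights |> filter(.data$locus == "IGL")
  fams <- c("lambda1", "lambda2", "lambda3")
  fam_of <- lambda_family(gl, lam$j_call)
  fam_tab <- .usage_table(fams, vapply(fams, function(f)
    sum(fam_of == f, na.rm = TRUE), 0), axis = "lambda_family", locus = "IGL")
  list(isotype = iso, lambda_family = fam_tab,
       n_bcr_negative = n_cells_total - nrow(lights))
}

#' Germline gene usage frequencies
#'
#' Relative frequency of each germline V or J gene among the productive
#' records of one locus. Labels cover every functional germline gene of
#' that locus and class, so unused genes appear with zero counts.
#'
#' @param records annotation tibble (preprocessed for figure-style usage).
#' @param gl the `germline_set`.
#' @param axis `"v_gene"` or `"j_gene"`.
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @return A `usage_table`; its `empty` attribute is TRUE when no records
#'   matched.
#' @export
gene_usage <- function(records, gl, axis = c("v_gene", "j_gene"),
                       locus = c("IGH", "IGK", "IGL")) {
  axis <- match.arg(axis); locus <- match.arg(locus)
  cls <- if (axis == "v_gene") "V" else "J"
  col <- if (axis == "v_gene") "v_call" else "j_call"
  s <- gl$segments
  labels <- sort(s$name[s$locus == locus & s$segment_class == cls & s$functional])
  rec <- records |> filter(.data$locus == !!locus, .data$productive)
  counts <- vapply(labels, function(g) sum(rec[[col]] == g, na.rm = TRUE), 0)
  .usage_table(labels, counts, axis = axis, locus = locus)
}

#' Pearson correlation between two usage tables
#'
#' Standard two-tailed Pearson correlation of the frequency vectors of two
#' usage tables, the statistic used to compare germline gene usage between
#' genotypes. Tables are aligned on the union of their labels, with absent
#' labels entering as zero frequency.
#'
#' @param a,b `usage_table`s (or tibbles with `label` and `frequency`).
#' @return list(r = correlation coefficient, p = two-tailed p-value from
#'   the t distribution with n - 2 degrees of freedom, n = labels used).
#' @export
pearson_usage <- function(a, b) {
  labels <- union(a$label, b$label)
  if (length(labels) < 3) stop("pearson_usage needs at least 3 labels")
  fa <- setNames(rep(0, length(labels)), labels)
  fb <- fa
  fa[a$label] <- a$frequency
  fb[b$label] <- b$frequency
  ct <- cor.test(fa, fb, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(labels))
}

#' V--J pairing matrix for one light-chain locus
#'
#' Counts of every germline V--J gene combination among productive records
#' of the locus, with row-normalised frequencies, plus the cross-cassette
#' mass: the fraction of Igl records whose V and J belong to different
#' cassettes (biologically near-zero, since recombination stays within a
#' cassette).
#'
#' @param records preprocessed annotation tibble.
#' @param gl the `germline_set`.
#' @param locus `"IGL"` (default) or `"IGK"`.
#' @return list(counts = V x J integer matrix, frequencies = row-normalised
#'   matrix, cross_cassette_mass = fraction, n = records used).
#' @export
vj_pairing_matrix <- function(records, gl, locus = c("IGL", "IGK")) {
  locus <- match.arg(locus)
  s <- gl$segments
  vs <- sort(s$name[s$locus == locus & s$segment_class == "V" & s$functional])
  js <- sort(s$name[s$locus == locus & s$segment_class == "J" & s$functional])
  rec <- records |>
    filter(.data$locus == !!locus, .data$productive,
           !is.na(.data$v_call), !is.na(.data$j_call))
  m <- matrix(0L, nrow = length(vs), ncol = length(js),
              dimnames = list(vs, js))
  if (nrow(rec) > 0) {
    tab <- table(factor(rec$v_call, levels = vs),
                 factor(rec$j_call, levels = js))
    m[] <- as.integer(tab)
  }
  freq <- m / pmax(rowSums(m), 1L)
  cross <- 0
  if (locus == "IGL" && sum(m) > 0) {
    cross_mask <- outer(vs, js, Vectorize(function(v, j)
      cassette_of(gl, v, j) == "cross_cassette"))
    cross <- sum(m[cross_mask]) / sum(m)
  }
  list(counts = m, frequencies = freq, cross_cassette_mass = cross,
       n = sum(m))
}

#' Receptor-editing signature from Igk J usage
#'
#' Usage of the downstream-most functional Igk J gene (Igkj5) marks
#' secondary Igk V-to-J rearrangements (receptor editing). Returns the
#' per-J usage table over productive Igk records and the Igkj5 share.
#'
#' @param records annotation tibble.
#' @param gl the `germline_set`.
#' @return list(igkj_usage = usage_table, jk5_fraction = Igkj5 share,
#'   empty = flag when no Igk records are present).
#' @export
editing_signature <- function(records, gl) {
  u <- gene_usage(records, gl, axis = "j_gene", locus = "IGK")
  jk5 <- if (attr(u, "empty")) NA_real_ else
    u$frequency[u$label == "Igkj5"]
  list(igkj_usage = u, jk5_fraction = jk5, empty = attr(u, "empty"))
}

#' CDR3 length and net-charge distributions
#'
#' Per-locus distributions of CDR3 amino-acid length and net charge, the
#' usual proxies for autoreactivity-prone receptors (longer or more
#' positively charged CDR3s). Net charge counts R and K as +1 and D and E
#' as -1; histidine is neutral by default (pH 7 approximation) and can be
#' counted as +1 with `include_his`.
#'
#' @param records preprocessed annotation tibble.
#' @param include_his count histidine as +1.
#' @return list(per_record = tibble(locus, cdr3_aa, length, charge),
#'   summary = tibble of per-locus mean/median length and charge).
#' @export
cdr3_properties <- function(records, include_his = FALSE) {
  rec <- records |> filter(!is.na(.data$cdr3_aa))
  count_aa <- function(x, set) {
    vapply(strsplit(x, ""), function(ch) sum(ch %in% set), 0)
  }
  pos <- c("R", "K", if (include_his) "H")
  per <- tibble(locus = rec$locus, cdr3_aa = rec$cdr3_aa,
                length = nchar(rec$cdr3_aa),
                charge = count_aa(rec$cdr3_aa, pos) -
                  count_aa(rec$cdr3_aa, c("D", "E")))
  summary <- per |>
    group_by(.data$locus) |>
    summarise(n = n(), mean_length = mean(.data$length),
              median_length = stats::median(.data$length),
              mean_charge = mean(.data$charge),
              median_charge = stats::median(.data$charge), .groups = "drop")
  list(per_record = per, summary = summary)
}

#' Clonotype frequency table
#'
#' Unique-clonotype frequency table (treemap-ready), sorted by descending
#' frequency. Clonotypes are defined per chain by the CDR3 amino-acid
#' string, or for `"paired_hl"` by the (heavy CDR3, light CDR3) pair of a
#' cell; each cell contributes one count per definition.
#'
#' @param records preprocessed annotation tibble.
#' @param definition one of `"heavy_cdr3"`, `"kappa_cdr3"`, `"lambda_cdr3"`,
#'   `"paired_hl"`.
#' @return A tibble (key, count, frequency) of class `clonotype_table`.
#' @export
clonotype_table <- function(records, definition = c("heavy_cdr3", "kappa_cdr3",
                                                    "lambda_cdr3", "paired_hl")) {
  definition <- match.arg(definition)
  keys <- switch(definition,
    heavy_cdr3 = records |> filter(.data$locus == "IGH", .data$productive,
                                   !is.na(.data$cdr3_aa)) |> pull("cdr3_aa"),
    kappa_cdr3 = records |> filter(.data$locus == "IGK", .data$productive,
                                   !is.na(.data$cdr3_aa)) |> pull("cdr3_aa"),
    lambda_cdr3 = records |> filter(.data$locus == "IGL", .data$productive,
                                    !is.na(.data$cdr3_aa)) |> pull("cdr3_aa"),
    paired_hl = {
      h <- records |> filter(.data$locus == "IGH", .data$productive,
                             !is.na(.data$cdr3_aa)) |>
        select("cell_id", heavy = "cdr3_aa")
      l <- records |> filter(.data$locus %in% c("IGK", "IGL"),
                             .data$productive, !is.na(.data$cdr3_aa)) |>
        select("cell_id", light = "cdr3_aa")
      inner_join(h, l, by = "cell_id") |>
        mutate(key = paste(.data$heavy, .data$light, sep = "+")) |>
        pull("key")
    })
  if (length(keys) == 0) {
    out <- tibble(key = character(), count = integer(), frequency = numeric())
  } else {
    cnt <- sort(table(keys), decreasing = TRUE)
    out <- tibble(key = names(cnt), count = as.integer(cnt),
                  frequency = as.integer(cnt) / sum(cnt))
  }
  structure(out, definition = definition,
            class = c("clonotype_table", class(out)))
}

#' Productivity fractions per locus
#'
#' Shares of each failure mode over all raw (uncollapsed, unfiltered)
#' reads, bucketed by locus; reads without a confident Ig assignment form
#' the `non_ig` bucket. Every read falls into exactly one bucket, and
#' within a bucket the failure-mode shares sum to 1.
#'
#' @param records annotation tibble from [annotate_repertoire()] (run
#'   before [preprocess_repertoire()]; pass `collapse = FALSE` reads for
#'   strict read-level fractions).
#' @return list(by_mode = tibble(bucket, failure_mode, count, share),
#'   unproductive_share = named vector of per-bucket unproductive shares).
#' @export
productivity_fractions <- function(records) {
  rec <- records |>
    mutate(bucket = ifelse(is.na(.data$locus), "non_ig", .data$locus),
           weight = .data$duplicate_count)
  by_mode <- rec |>
    group_by(.data$bucket, .data$failure_mode) |>
    summarise(count = sum(.data$weight), .groups = "drop_last") |>
    mutate(share = .data$count / sum(.data$count)) |>
    ungroup()
  unprod <- rec |>
    group_by(.data$bucket) |>
    summarise(unproductive_share =
                sum(.data$weight[!.data$productive]) / sum(.data$weight),
              .groups = "drop")
  list(by_mode = by_mode,
       unproductive_share = setNames(unprod$unproductive_share, unprod$bucket))
}
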