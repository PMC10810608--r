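#' Build a resolved pipeline run configuration
#'
#' Collects every knob of the simulate-annotate-stats-network pipeline into
#' one list with defaults filled in, so a run can be reproduced from its
#' emitted manifest alone. The seed is mandatory.
#'
#' @param preset a preset name (see [genotype_preset()]) or a
#'   `genotype_preset` object.
#' @param n_cells number of cells to simulate.
#' @param seed master seed (mandatory).
#' @param out_dir output directory (created if missing).
#' @param n_ighv,n_igkv,n_ighd,germline_seed germline build parameters.
#' @param decoy_rate decoy read rate.
#' @param scoring,min_ig_frac,full_scan annotation parameters.
#' @param min_cdr3_aa_len,min_occurrence preprocessing filters.
#' @param min_cluster_size,metric network parameters.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = "ctrl", n_cells = 1000, seed,
                       out_dir = tempfile("bcrsim_run_"),
                       n_ighv = 20, n_igkv = 15, n_ighd = 10,
                       germline_seed = 20260101, decoy_rate = 0.05,
                       scoring = c(2, -1, -3, -1), min_ig_frac = 0.6,
                       full_scan = FALSE, min_cdr3_aa_len = 4,
                       min_occurrence = 2, min_cluster_size = 3,
                       metric = "levenshtein") {
  if (missing(seed)) stop("run_config: seed is mandatory")
  preset_obj <- if (is.character(preset)) genotype_preset(preset) else
    validate_preset(preset)
  structure(list(preset = preset_obj, n_cells = n_cells, seed = seed,
                 out_dir = out_dir, n_ighv = n_ighv, n_igkv = n_igkv,
                 n_ighd = n_ighd, germline_seed = germline_seed,
                 decoy_rate = decoy_rate, scoring = scoring,
                 min_ig_frac = min_ig_frac, full_scan = full_scan,
                 min_cdr3_aa_len = min_cdr3_aa_len,
                 min_occurrence = min_occurrence,
                 min_cluster_size = min_cluster_size, metric = metric),
            class = "run_config")
}

.write_manifest <- function(config, path) {
  cfg <- unclass(config)
  cfg$preset <- unclass(cfg$preset)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.log_count <- function(stage, n, what = "records") {
  message(sprintf("[bcrsim] %s: %d %s", stage, n, what))
}

#' Run pipeline stages
#'
#' `run_simulate` builds the germline, simulates the repertoire and writes
#' reads FASTA + truth manifest. `run_annotate` annotates the reads.
#' `run_stats` computes the repertoire statistics and writes the JSON
#' report and TSV tables. `run_network` builds and exports the per-chain
#' CDR3 similarity networks. `run_pipeline` chains all four. Every stage
#' logs its input/output record counts; identical configurations and seeds
#' give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return `run_simulate`: list(gl, sim, paths). `run_annotate`: the
#'   annotation tibble. `run_stats`: the stats report list.
#'   `run_network`: named list of `cdr3_network`s. `run_pipeline`: all of
#'   the above.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gl <- build_germline(n_ighv = config$n_ighv, n_igkv = config$n_igkv,
                       n_ighd = config$n_ighd, seed = config$germline_seed)
  sim <- simulate_repertoire(gl, config$preset, n_cells = config$n_cells,
                             seed = config$seed,
                             decoy_rate = config$decoy_rate)
  fasta <- file.path(config$out_dir, "reads.fasta")
  manifest <- file.path(config$out_dir, "truth.tsv")
  write_repertoire(sim, fasta, manifest)
  write_germline_fasta(gl, file.path(config$out_dir, "germline.fasta"))
  .write_manifest(config, file.path(config$out_dir, "run_manifest.json"))
  .log_count("simulate", length(sim$reads), "reads")
  list(gl = gl, sim = sim,
       paths = c(fasta = fasta, manifest = manifest))
}

#' @rdname run_simulate
#' @param reads FASTA path or `DNAStringSet`.
#' @param gl a `germline_set`.
#' @export
run_annotate <- function(reads, gl, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- annotate_repertoire(reads, gl, scoring = config$scoring,
                             min_ig_frac = config$min_ig_frac,
                             full_scan = config$full_scan)
  .log_count("annotate", nrow(ann))
  readr::write_tsv(ann, file.path(config$out_dir, "rearrangements.tsv"),
                   progress = FALSE)
  ann
}

#' @rdname run_simulate
#' @param ann annotation tibble.
#' @export
run_stats <- function(ann, gl, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- preprocess_repertoire(ann, min_cdr3_aa_len = config$min_cdr3_aa_len,
                               min_occurrence = config$min_occurrence)
  .log_count("preprocess", nrow(pre), sprintf("of %d records kept", nrow(ann)))
  iso <- isotype_family_frequencies(ann, gl)
  report <- list(
    preset = config$preset$name,
    n_records = nrow(ann), n_preprocessed = nrow(pre),
    isotype = as.data.frame(iso$isotype),
    lambda_family = as.data.frame(iso$lambda_family),
    n_bcr_negative = iso$n_bcr_negative,
    gene_usage = lapply(
      setNames(nm = c("IGH", "IGK", "IGL")), function(loc) list(
        v = as.data.frame(gene_usage(pre, gl, "v_gene", loc)),
        j = as.data.frame(gene_usage(pre, gl, "j_gene", loc)))),
    igl_pairing = {
      pm <- vj_pairing_matrix(pre, gl, "IGL")
      list(counts = as.data.frame(as.table(pm$counts)),
           cross_cassette_mass = pm$cross_cassette_mass)
    },
    editing = {
      ed <- editing_signature(pre, gl)
      list(igkj_usage = as.data.frame(ed$igkj_usage),
           jk5_fraction = ed$jk5_fraction)
    },
    cdr3 = as.data.frame(cdr3_properties(pre)$summary),
    productivity = {
      pf <- productivity_fractions(ann)
      list(by_mode = as.data.frame(pf$by_mode),
           unproductive_share = as.list(pf$unproductive_share))
    })
  jsonlite::write_json(report, file.path(config$out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (def in c("heavy_cdr3", "kappa_cdr3", "lambda_cdr3", "paired_hl")) {
    readr::write_tsv(clonotype_table(pre, def),
                     file.path(config$out_dir, paste0("clonotypes_", def, ".tsv")),
                     progress = FALSE)
  }
  report
}

#' @rdname run_simulate
#' @export
run_network <- function(ann, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- preprocess_repertoire(ann, min_cdr3_aa_len = config$min_cdr3_aa_len,
                               min_occurrence = config$min_occurrence)
  chains <- list(heavy = "IGH", kappa = "IGK", lambda = "IGL")
  nets <- list()
  for (nm in names(chains)) {
    sub <- pre |> filter(.data$locus == chains[[nm]], !is.na(.data$cdr3_aa))
    uc <- sub |> count(.data$cdr3_aa, wt = .data$duplicate_count, name = "n")
    if (nrow(uc) == 0) next
    net <- build_cdr3_network(uc$cdr3_aa, uc$n,
                              min_cluster_size = config$min_cluster_size,
                              metric = config$metric)
    export_network(net,
                   file.path(config$out_dir, paste0("network_", nm, "_edges.tsv")),
                   file.path(config$out_dir, paste0("network_", nm, "_nodes.tsv")))
    .log_count(paste0("network/", nm), nrow(net$nodes), "nodes")
    nets[[nm]] <- net
  }
  nets
}

#' @rdname run_simulate
#' @export
run_pipeline <- function(config) {
  simres <- run_simulate(config)
  ann <- run_annotate(simres$sim$reads, simres$gl, config)
  stats <- run_stats(ann, simres$gl, config)
  nets <- run_network(ann, config)
  list(gl = simres$gl, sim = simres$sim, annotations = ann,
       stats = stats, networks = nets)
}

.network_summary <- function(net) {
  if (is.null(net)) return(list(nodes = 0, edges = 0, max_component_mass = 0))
  mass <- tapply(net$nodes$count, net$nodes$component, sum)
  list(nodes = nrow(net$nodes), edges = nrow(net$edges),
       n_expanded_components =
         length(unique(net$nodes$component[net$nodes$expanded])),
       max_component_mass = max(mass) / sum(net$nodes$count))
}

#' Two-genotype comparison report
#'
#' Runs the full pipeline for two configurations (typically two genotype
#' presets sharing one germline) and assembles the joint comparison:
#' per-genotype usage tables, Pearson correlations per gene class between
#' the genotypes, Igl pairing matrices, editing signatures, productivity
#' fractions and similarity-network summaries. The report is written as
#' versioned JSON into `configA$out_dir`.
#'
#' @param configA,configB two [run_config()]s.
#' @return The comparison report list (also written to
#'   `comparison_report.json`).
#' @export
run_compare <- function(configA, configB) {
  resA <- run_pipeline(configA)
  resB <- run_pipeline(configB)
  preA <- preprocess_repertoire(resA$annotations,
                                configA$min_cdr3_aa_len, configA$min_occurrence)
  preB <- preprocess_repertoire(resB$annotations,
                                configB$min_cdr3_aa_len, configB$min_occurrence)
  gl <- resA$gl
  pearson <- list()
  for (loc in c("IGH", "IGK", "IGL")) {
    for (ax in c("v_gene", "j_gene")) {
      ua <- gene_usage(preA, gl, ax, loc)
      ub <- gene_usage(preB, gl, ax, loc)
      pearson[[paste(loc, ax, sep = "_")]] <-
        if (attr(ua, "empty") || attr(ub, "empty")) NULL else
          pearson_usage(ua, ub)
    }
  }
  report <- list(
    schema_version = "1.0",
    genotypes = c(configA$preset$name, configB$preset$name),
    seeds = c(configA$seed, configB$seed),
    pearson = pearson,
    isotype = list(A = resA$stats$isotype, B = resB$stats$isotype),
    lambda_family = list(A = resA$stats$lambda_family,
                         B = resB$stats$lambda_family),
    editing = list(A = resA$stats$editing, B = resB$stats$editing),
    productivity = list(A = resA$stats$productivity,
                        B = resB$stats$productivity),
    cross_cassette_mass = list(A = resA$stats$igl_pairing$cross_cassette_mass,
                               B = resB$stats$igl_pairing$cross_cassette_mass),
    networks = list(A = lapply(resA$networks, .network_summary),
                    B = lapply(resB$networks, .network_summary)))
  jsonlite::write_json(report,
                       file.path(configA$out_dir, "comparison_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  report
}
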