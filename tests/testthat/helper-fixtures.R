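# Shared fixtures: one small germline (fewer V genes than the default, for
# speed) built once per test run, plus builders for hand-made annotation
# records.

test_germline <- function() {
  if (is.null(.fixture_env$gl)) .fixture_env$gl <- build_germline(
    n_ighv = 6, n_igkv = 8, n_ighd = 5, seed = 42)
  .fixture_env$gl
}
.fixture_env <- new.env(parent = emptyenv())

# a minimal annotation record row for stats-level tests
make_record <- function(cell_id, locus, v_call, j_call, cdr3_aa,
                        productive = TRUE,
                        failure_mode = if (productive) "none" else "stop_codon",
                        duplicate_count = 1L, chain = "light") {
  tibble::tibble(
    sequence_id = paste0(cell_id, "|", chain), cell_id = cell_id,
    chain = chain, locus = locus, v_call = v_call, d_call = NA_character_,
    j_call = j_call,
    junction = NA_character_,
    junction_aa = if (is.na(cdr3_aa)) NA_character_ else paste0("C", cdr3_aa, "W"),
    cdr3_aa = cdr3_aa, productive = productive, failure_mode = failure_mode,
    v_score = 200, j_score = 60, duplicate_count = duplicate_count)
}

# simulate + annotate in one go (small n), returning both tables
sim_annotated <- function(preset, n_cells, seed, gl = test_germline(),
                          decoy_rate = 0) {
  sim <- simulate_repertoire(gl, preset, n_cells = n_cells, seed = seed,
                             decoy_rate = decoy_rate)
  list(sim = sim, ann = annotate_repertoire(sim$reads, gl))
}
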