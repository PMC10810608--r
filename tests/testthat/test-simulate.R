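test_that("preset weight tables are validated", {
  expect_error(genotype_preset("custom", kappa_fraction = 1.2), "\\[0, 1\\]")
  expect_error(genotype_preset("custom",
    lambda_family_weights = c(lambda1 = 0.5, lambda2 = 0.4, lambda3 = 0.2)),
    "sum to 1")
  expect_error(genotype_preset("custom",
    igk_j_weights = c(Igkj1 = 0.5, Igkj3 = 0.5)), "pseudogene")
  expect_error(genotype_preset("nonsense"), "arg")
  p_bad <- genotype_preset("ctrl")
  p_bad$kappa_silenced <- TRUE
  expect_error(rearrange_light_empirical(test_germline(), p_bad),
               "contradiction")
})

test_that("the no-diversity limit reproduces the germline junction exactly", {
  gl <- test_germline()
  p <- genotype_preset("custom", trim_p = 0, n_add_heavy = 0,
    unproductive_fraction_per_locus = c(IGH = 0, IGK = 0, IGL = 0))
  set.seed(1)
  h <- recombine_heavy(gl, p)
  s <- gl$segments
  v <- s[s$name == h$v_call_truth, ]
  j <- s[s$name == h$j_call_truth, ]
  d <- s[s$name == h$d_call_truth, ]
  expected <- paste0(substr(v$sequence, v$anchor_offset + 1, nchar(v$sequence)),
                     d$sequence,
                     substr(j$sequence, 1, j$anchor_offset + 3))
  expect_equal(h$junction_truth, expected)
  expect_true(h$productive_truth)
  expect_equal(nchar(h$junction_truth) %% 3, 0)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(h$junction_truth)))
  expect_match(aa, "^C.*[FW]$")
})

test_that("heavy-chain unproductive fraction matches its Bernoulli target", {
  gl <- test_germline()
  p <- genotype_preset("custom",
    unproductive_fraction_per_locus = c(IGH = 0.3, IGK = 0.1, IGL = 0.1))
  set.seed(101)
  n <- 5000
  unprod <- vapply(seq_len(n), function(i)
    !bcrsim:::.recombine_heavy_core(gl, p)$productive_truth, logical(1))
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(unprod) - 0.3), 3 * se)
})

test_that("clonal expansion injects a clone carrying the forced V gene", {
  gl <- test_germline()
  p <- genotype_preset("custom",
    clonal_expansion = list(n_clones = 1, clone_mass = 0.1,
                            forced_v_gene = "Ighv5-1"))
  sim <- simulate_repertoire(gl, p, n_cells = 500, seed = 9, decoy_rate = 0)
  clones <- sim$truth[!is.na(sim$truth$clone_id) & sim$truth$chain == "heavy", ]
  expect_gt(nrow(clones), 0)
  expect_true(all(clones$v_call_truth == "Ighv5-1"))
  expect_equal(length(unique(clones$junction_truth)), 1)  # identical clone CDR3
  se <- sqrt(0.1 * 0.9 / 500)
  expect_lt(abs(nrow(clones) / 500 - 0.1), 3 * se)
})

test_that("degenerate empirical presets collapse to the expected genes", {
  gl <- test_germline()
  set.seed(2)
  all_kappa <- genotype_preset("custom", kappa_fraction = 1)
  for (i in 1:50)
    expect_equal(rearrange_light_empirical(gl, all_kappa)$locus, "IGK")
  all_l1 <- genotype_preset("custom", kappa_fraction = 0,
    lambda_family_weights = c(lambda1 = 1, lambda2 = 0, lambda3 = 0))
  for (i in 1:50) {
    r <- rearrange_light_empirical(gl, all_l1)
    expect_equal(unname(c(r$v_call_truth, r$j_call_truth)),
                 c("Iglv1", "Iglj1"))
  }
})

test_that("empirical lambda V-J draws never cross cassettes", {
  gl <- test_germline()
  p <- genotype_preset("ctrl")
  set.seed(31)
  n_igl <- 0
  for (i in 1:3000) {
    r <- bcrsim:::.rearrange_light_empirical_core(gl, p)
    if (r$locus == "IGL") {
      n_igl <- n_igl + 1
      expect_equal(cassette_of(gl, r$v_call_truth, r$j_call_truth),
                   "same_cassette")
    }
  }
  expect_gt(n_igl, 50)
})

test_that("empirical gene frequencies converge to the preset weights", {
  gl <- test_germline()
  p <- genotype_preset("ctrl")
  set.seed(77)
  n <- 10000
  draws <- vector("list", n)
  for (i in seq_len(n)) draws[[i]] <- bcrsim:::.rearrange_light_empirical_core(gl, p)
  locus <- vapply(draws, `[[`, "", "locus")
  jgene <- vapply(draws, `[[`, "", "j_call_truth")
  prod <- vapply(draws, `[[`, logical(1), "productive_truth")
  # kappa share among productive light chains recovers kappa_fraction
  k_share <- mean(locus[prod] == "IGK")
  expect_lt(abs(k_share - 0.83), 3 * sqrt(0.83 * 0.17 / sum(prod)))
  # chi-squared sanity on Igk J usage against preset weights
  jk <- jgene[locus == "IGK"]
  obs <- table(factor(jk, levels = names(p$igk_j_weights)))
  expect_gt(stats::chisq.test(obs, p = p$igk_j_weights)$p.value, 1e-4)
})

test_that("mechanistic limits: silenced kappa, macroself, closed Igl", {
  gl <- test_germline()
  set.seed(5)
  ko <- genotype_preset("kappa_ko")
  survivors <- list()
  for (i in 1:300) {
    r <- bcrsim:::.rearrange_light_mechanistic_core(gl, ko)
    if (!is.null(r)) survivors <- c(survivors, list(r))
  }
  expect_gt(length(survivors), 0)
  expect_true(all(vapply(survivors, `[[`, "", "locus") == "IGL"))

  ms <- genotype_preset("macroself")
  for (i in 1:300) {
    r <- bcrsim:::.rearrange_light_mechanistic_core(gl, ms)
    if (!is.null(r)) expect_equal(r$locus, "IGL")
  }

  dead <- genotype_preset("custom", mode = "mechanistic",
                          kappa_silenced = TRUE, p_igl_open = 0)
  for (i in 1:100)
    expect_null(bcrsim:::.rearrange_light_mechanistic_core(gl, dead))
})

test_that("surviving-cell lambda fraction is monotone in the mechanism knobs", {
  gl <- test_germline()
  lam_frac <- function(preset, n = 5000, seed = 11) {
    set.seed(seed)
    n_igl <- 0; n_live <- 0
    for (i in seq_len(n)) {
      r <- bcrsim:::.rearrange_light_mechanistic_core(gl, preset)
      if (!is.null(r)) {
        n_live <- n_live + 1
        if (r$locus == "IGL") n_igl <- n_igl + 1
      }
    }
    n_igl / n_live
  }
  # mid-range editing parameters so the lambda share is measurable
  base <- list(mode = "mechanistic", p_igk_productive = 0.3,
               p_autoreactive_kappa = 0.5, max_edit_attempts = 2L)
  mk <- function(...) do.call(genotype_preset,
                              c(list(name = "custom"), base, list(...)))
  open_grid <- vapply(c(0.2, 0.5, 0.9),
                      function(x) lam_frac(mk(p_igl_open = x)), 0)
  expect_true(all(diff(open_grid) >= 0))
  hl_grid <- vapply(c(2, 4, 8),
                    function(x) lam_frac(mk(survival_halflife = x)), 0)
  expect_true(all(diff(hl_grid) >= 0))
  pk_grid <- vapply(c(0.2, 0.5, 0.9),
                    function(x) lam_frac(mk(p_igk_productive = x)), 0)
  expect_true(all(diff(pk_grid) <= 0))
  # extending precursor life-span never lowers the lambda share
  expect_gte(lam_frac(mk(survival_halflife = 6)),
             lam_frac(mk(survival_halflife = 3)))
})

test_that("Igkj5 use marks more editing rounds than Igkj1 use", {
  gl <- test_germline()
  p <- genotype_preset("custom", mode = "mechanistic")
  set.seed(3)
  rounds <- list(Igkj1 = numeric(0), Igkj5 = numeric(0))
  for (i in 1:4000) {
    r <- bcrsim:::.rearrange_light_mechanistic_core(gl, p)
    if (!is.null(r) && r$locus == "IGK" &&
        r$j_call_truth %in% names(rounds))
      rounds[[r$j_call_truth]] <- c(rounds[[r$j_call_truth]], r$n_edit_rounds)
  }
  expect_gt(mean(rounds$Igkj5), mean(rounds$Igkj1))
})

test_that("simulated repertoires are deterministic and cell-stable", {
  gl <- test_germline()
  p <- genotype_preset("ctrl")
  a <- simulate_repertoire(gl, p, n_cells = 50, seed = 13)
  b <- simulate_repertoire(gl, p, n_cells = 50, seed = 13)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$reads), as.character(b$reads))
  # growing n_cells leaves earlier cells untouched (per-cell sub-streams)
  big <- simulate_repertoire(gl, p, n_cells = 80, seed = 13)
  first <- function(x) x$truth[x$truth$cell_id %in% sprintf("cell%05d", 1:50), ]
  expect_identical(first(a), first(big))
  # FASTA bytes identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_repertoire(a, f1, tempfile()); write_repertoire(b, f2, tempfile())
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("manifest structure and decoy rate match the design", {
  gl <- test_germline()
  p <- genotype_preset("ctrl")
  sim <- simulate_repertoire(gl, p, n_cells = 2000, seed = 21,
                             decoy_rate = 0.05)
  cells <- sim$truth[sim$truth$chain %in% c("heavy", "light"), ]
  expect_equal(length(unique(cells$cell_id)), 2000)
  expect_true(all(table(cells$cell_id) == 2))
  decoys <- sim$truth[!is.na(sim$truth$failure_mode_truth) &
                        sim$truth$failure_mode_truth == "non_ig", ]
  n_reads <- 4000
  se <- sqrt(0.05 * 0.95 / n_reads)
  expect_lt(abs(nrow(decoys) / n_reads - 0.05), 3 * se)
  # junction is always a substring of the read
  live <- cells[!cells$died, ]
  expect_true(all(mapply(grepl, live$junction_truth, live$sequence_nt,
                         MoreArgs = list(fixed = TRUE))))
})
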