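test_that("preprocessing keeps productive, long-enough, recurrent CDR3s", {
  rec <- dplyr::bind_rows(
    make_record("c1", "IGK", "Igkv1", "Igkj1", "ARDYW"),
    make_record("c2", "IGK", "Igkv1", "Igkj1", "ARDYW"),
    make_record("c3", "IGK", "Igkv2", "Igkj1", "ARQQW"),      # occurs once
    make_record("c4", "IGK", "Igkv2", "Igkj2", "AR"),          # too short
    make_record("c5", "IGK", "Igkv3", "Igkj1", "ARDYF", productive = FALSE))
  kept <- preprocess_repertoire(rec)
  expect_setequal(kept$cell_id, c("c1", "c2"))
  # idempotence
  expect_equal(preprocess_repertoire(kept), kept)
  # identity on the productive subset when filters are off
  loose <- preprocess_repertoire(rec, min_cdr3_aa_len = 0, min_occurrence = 1)
  expect_setequal(loose$cell_id, c("c1", "c2", "c3", "c4"))
})

test_that("isotype and lambda-family frequencies count cells correctly", {
  gl <- test_germline()
  rec <- dplyr::bind_rows(
    make_record("c1", "IGK", "Igkv1", "Igkj1", "ARDYW"),
    make_record("c2", "IGK", "Igkv2", "Igkj2", "ARQQW"),
    make_record("c3", "IGL", "Iglv1", "Iglj1", "ARLLW"),
    make_record("c4", "IGL", "Iglv1", "Iglj3", "ARMMW"),
    make_record("c5", "IGL", "Iglv2", "Iglj2", "ARNNW"),
    make_record("c6", "IGL", "Iglv1", "Iglj1", "ARPPW", productive = FALSE))
  out <- isotype_family_frequencies(rec, gl)
  expect_equal(out$isotype$count, c(2L, 3L))
  expect_equal(out$isotype$frequency, c(0.4, 0.6))
  expect_equal(out$lambda_family$frequency, c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(out$n_bcr_negative, 1)
  # degenerate all-lambda1 repertoire
  only1 <- isotype_family_frequencies(
    make_record("z", "IGL", "Iglv1", "Iglj1", "AAAAW"), gl)
  expect_equal(only1$lambda_family$frequency, c(1, 0, 0))
})

test_that("gene usage recovers uniform draws within multinomial error", {
  gl <- test_germline()
  res <- sim_annotated(genotype_preset("custom", kappa_fraction = 1),
                       n_cells = 2500, seed = 19)
  kap <- res$ann[res$ann$locus %in% "IGK" & res$ann$productive, ]
  u <- gene_usage(kap, gl, "v_gene", "IGK")
  n_v <- length(u$label)
  se <- sqrt((1 / n_v) * (1 - 1 / n_v) / nrow(kap))
  expect_true(all(abs(u$frequency - 1 / n_v) < 3.5 * se))
  expect_equal(sum(u$frequency), 1)
  # single record
  u1 <- gene_usage(make_record("c", "IGK", "Igkv1", "Igkj1", "ADDDW"),
                   gl, "v_gene", "IGK")
  expect_equal(u1$frequency[u1$label == "Igkv1"], 1)
  # empty input flagged
  u0 <- gene_usage(make_record("c", "IGK", "Igkv1", "Igkj1", "ADDDW")[0, ],
                   gl, "v_gene", "IGK")
  expect_true(attr(u0, "empty"))
})

test_that("pearson_usage matches closed-form expectations", {
  mk <- function(f) tibble::tibble(label = c("g1", "g2", "g3"), frequency = f)
  self <- pearson_usage(mk(c(0.5, 0.3, 0.2)), mk(c(0.5, 0.3, 0.2)))
  expect_equal(self$r, 1.0)
  # hand-derived closed form for the reversed triple:
  # r = sum(dx*dy) / sqrt(sum(dx^2) sum(dy^2)) with dy = rev(dx) = -13/14
  rev3 <- pearson_usage(mk(c(0.5, 0.3, 0.2)), mk(c(0.2, 0.3, 0.5)))
  expect_equal(rev3$r, -13 / 14, tolerance = 1e-12)
  # an arithmetic triple reversed is exactly anticorrelated
  anti <- pearson_usage(mk(c(0.5, 0.3, 0.1)), mk(c(0.1, 0.3, 0.5)))
  expect_equal(anti$r, -1.0)
  # symmetry and joint relabeling invariance
  a <- mk(c(0.6, 0.3, 0.1)); b <- mk(c(0.2, 0.5, 0.3))
  expect_equal(pearson_usage(a, b)$r, pearson_usage(b, a)$r)
  perm <- c(3, 1, 2)
  expect_equal(pearson_usage(a[perm, ], b[perm, ])$r, pearson_usage(a, b)$r)
  expect_error(pearson_usage(a[1:2, ], b[1:2, ]), "3 labels")
})

test_that("independent samples of one preset correlate above 0.95", {
  gl <- test_germline()
  p <- genotype_preset("ctrl")
  a <- sim_annotated(p, n_cells = 1500, seed = 101)$ann
  b <- sim_annotated(p, n_cells = 1500, seed = 202)$ann
  # J usage carries real structure (the V draw is uniform, so its usage
  # vector is flat and correlation between noise replicates is undefined)
  ua <- gene_usage(a[a$productive & a$locus %in% "IGK", ], gl, "j_gene", "IGK")
  ub <- gene_usage(b[b$productive & b$locus %in% "IGK", ], gl, "j_gene", "IGK")
  expect_gt(pearson_usage(ua, ub)$r, 0.95)
})

test_that("V-J pairing matrix matches hand counts and cassette structure", {
  gl <- test_germline()
  rec <- dplyr::bind_rows(
    make_record("c1", "IGL", "Iglv1", "Iglj1", "AAAAW"),
    make_record("c2", "IGL", "Iglv1", "Iglj1", "CCCCW"),
    make_record("c3", "IGL", "Iglv1", "Iglj3", "DDDDW"),
    make_record("c4", "IGL", "Iglv2", "Iglj2", "EEEEW"),
    make_record("c5", "IGL", "Iglv3", "Iglj2", "FFFFW"),
    make_record("c6", "IGL", "Iglv3", "Iglj2", "GGGGW"))
  pm <- vj_pairing_matrix(rec, gl, "IGL")
  expect_equal(pm$counts["Iglv1", "Iglj1"], 2L)
  expect_equal(pm$counts["Iglv1", "Iglj3"], 1L)
  expect_equal(pm$counts["Iglv3", "Iglj2"], 2L)
  expect_equal(sum(pm$counts), 6)
  expect_equal(pm$cross_cassette_mass, 0)
  # a cross-cassette record contributes mass
  pm2 <- vj_pairing_matrix(dplyr::bind_rows(rec,
    make_record("c7", "IGL", "Iglv2", "Iglj1", "HHHHW")), gl, "IGL")
  expect_equal(pm2$cross_cassette_mass, 1 / 7)
  # simulated control repertoire never crosses cassettes
  res <- sim_annotated(genotype_preset("ctrl"), n_cells = 1500, seed = 55)
  pre <- preprocess_repertoire(res$ann, min_occurrence = 1)
  expect_equal(vj_pairing_matrix(pre, gl, "IGL")$cross_cassette_mass, 0)
})

test_that("editing signature reports the Igkj5 share", {
  gl <- test_germline()
  rec <- dplyr::bind_rows(
    make_record("c1", "IGK", "Igkv1", "Igkj1", "AAAAW"),
    make_record("c2", "IGK", "Igkv1", "Igkj2", "CCCCW"),
    make_record("c3", "IGK", "Igkv2", "Igkj4", "DDDDW"),
    make_record("c4", "IGK", "Igkv2", "Igkj5", "EEEEW"))
  ed <- editing_signature(rec, gl)
  expect_equal(ed$jk5_fraction, 0.25)
  expect_false(ed$empty)
  ed0 <- editing_signature(rec[0, ], gl)
  expect_true(ed0$empty)
})

test_that("CDR3 length and net charge follow the residue-count rules", {
  props <- cdr3_properties(dplyr::bind_rows(
    make_record("c1", "IGH", "Ighv1-1", "Ighj1", "ARDY"),   # R+1, D-1 -> 0
    make_record("c2", "IGH", "Ighv1-1", "Ighj1", "GGGGG"),  # neutral
    make_record("c3", "IGH", "Ighv1-1", "Ighj1", "KRKDH")))  # +3 -1 = 2
  per <- props$per_record
  expect_equal(per$charge[per$cdr3_aa == "ARDY"], 0)
  expect_equal(per$length[per$cdr3_aa == "ARDY"], 4)
  expect_equal(per$charge[per$cdr3_aa == "GGGGG"], 0)
  expect_equal(per$charge[per$cdr3_aa == "KRKDH"], 2)
  with_h <- cdr3_properties(
    make_record("c", "IGH", "Ighv1-1", "Ighj1", "KRKDH"), include_his = TRUE)
  expect_equal(with_h$per_record$charge, 3)
  # histogram of a printed fixture equals the hand tally:
  # CARW -> +1 (x2), CDEW -> -2 (x1), CKKW -> +2 (x3)
  fix <- c("CARW", "CARW", "CDEW", "CKKW", "CKKW", "CKKW")
  tall <- cdr3_properties(dplyr::bind_rows(lapply(seq_along(fix), function(i)
    make_record(paste0("x", i), "IGH", "Ighv1-1", "Ighj1", fix[i]))))
  hist <- table(tall$per_record$charge)
  expect_equal(names(hist), c("-2", "1", "2"))
  expect_equal(as.vector(hist), c(1, 2, 3))
})

test_that("clonotype tables are proper frequency distributions", {
  rec <- dplyr::bind_rows(lapply(1:5, function(i)
    make_record(paste0("c", i), "IGK", "Igkv1", "Igkj1",
                paste0("AR", LETTERS[i], "W"))))
  ct <- clonotype_table(rec, "kappa_cdr3")
  expect_equal(nrow(ct), 5)
  expect_true(all(ct$frequency == 0.2))
  expect_equal(sum(ct$frequency), 1)
  expect_equal(nrow(clonotype_table(rec[0, ], "kappa_cdr3")), 0)
  # paired definition keys on (heavy, light) CDR3s per cell
  paired <- dplyr::bind_rows(
    make_record("p1", "IGH", "Ighv1-1", "Ighj1", "HHHH", chain = "heavy"),
    make_record("p1", "IGK", "Igkv1", "Igkj1", "LLLL"),
    make_record("p2", "IGH", "Ighv1-1", "Ighj1", "HHHH", chain = "heavy"),
    make_record("p2", "IGK", "Igkv1", "Igkj1", "LLLL"))
  pt <- clonotype_table(paired, "paired_hl")
  expect_equal(pt$key, "HHHH+LLLL")
  expect_equal(pt$frequency, 1)
})

test_that("an injected clone dominates the heavy clonotype table", {
  gl <- test_germline()
  p <- genotype_preset("custom",
    unproductive_fraction_per_locus = c(IGH = 0.1, IGK = 0.1, IGL = 0.1),
    clonal_expansion = list(n_clones = 1, clone_mass = 0.1,
                            forced_v_gene = "Ighv2-1"))
  res <- sim_annotated(p, n_cells = 3000, seed = 67)
  heavy <- res$ann[res$ann$locus %in% "IGH" & res$ann$productive, ]
  ct <- clonotype_table(heavy, "heavy_cdr3")
  top_members <- heavy[heavy$cdr3_aa == ct$key[1], ]
  expect_true(all(top_members$v_call == "Ighv2-1"))
  # clone mass recovered among cells (clone reads are always productive,
  # so compare against all simulated cells)
  se <- sqrt(0.1 * 0.9 / 3000)
  expect_lt(abs(ct$count[1] / 3000 - 0.1), 3 * se)
})

test_that("productivity fractions bucket every read exactly once", {
  res <- sim_annotated(genotype_preset("ctrl"), n_cells = 400, seed = 71,
                       decoy_rate = 0.1)
  pf <- productivity_fractions(res$ann)
  shares <- pf$by_mode |> dplyr::group_by(bucket) |>
    dplyr::summarise(s = sum(share))
  expect_true(all(abs(shares$s - 1) < 1e-12))
  expect_equal(sum(pf$by_mode$count), length(res$sim$reads))
  expect_equal(unname(pf$unproductive_share["non_ig"]), 1)
  # all-productive fixture
  pf2 <- productivity_fractions(make_record("c", "IGK", "Igkv1", "Igkj1", "AW"))
  expect_equal(unname(pf2$unproductive_share["IGK"]), 0)
})
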