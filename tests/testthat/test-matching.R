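toy_refs <- function(mz = 400, rt = 100, n = 1, polarity = "positive") {
  data.frame(ref_id = sprintf("REF%04d", seq_len(n)),
             name = sprintf("M%d", seq_len(n)), accession = NA_character_,
             mode = "metabolite", mz = mz, rt = rt, polarity = polarity,
             adduct = if (polarity == "positive") "+H" else "-H", z = 1L,
             formula = NA_character_, lipid_class = NA_character_,
             fatty_acids = NA_character_, stringsAsFactors = FALSE)
}

toy_features <- function(mz, rt, intensity = 1e5, polarity = "positive") {
  data.frame(sample_id = "S1", polarity = polarity, mz = mz, rt = rt,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("the joint m/z-RT score evaluates as a weighted Euclidean distance", {
  expect_identical(iso_score(0, 0, 0.1), 1)
  expect_equal(iso_score(0.0007, 0.14, 0.1), 0.86000, tolerance = 1e-4)
  expect_equal(iso_score(0, 0.39, 0.1), 0.61)
  expect_equal(iso_score(0, -0.39, 0.1), 0.61)            # signs ignored
  expect_lt(iso_score(0, 2, 0.1), 0)                      # can go negative
  # strictly decreasing in either deviation
  expect_true(all(diff(iso_score(seq(0, 1, 0.1), 0.1, 0.1)) < 0))
  expect_true(all(diff(iso_score(0.01, seq(0, 1, 0.1), 0.1)) < 0))
  # the unrooted variant is preserved as an option
  expect_equal(iso_score(0, 0.5, 0.1, score_form = "sum_of_squares"), 0.75)
})

test_that("grades bin the accepted score range with A best", {
  expect_identical(assign_grade(1.0), "A")
  expect_identical(assign_grade(0.86), "B")
  expect_identical(assign_grade(0.61), "D")
  expect_identical(assign_grade(c(0.95, 0.85, 0.70, 0.69)),
                   c("A", "B", "C", "D"))
  expect_error(assign_grade(0.5), "cutoff")
})

test_that("matching takes the best gated feature and applies tie rules", {
  refs <- toy_refs()
  cands <- build_candidates(refs, cap_by_formula = FALSE)
  # score tie by construction: symmetric m/z offsets, equal RT
  feats <- toy_features(mz = c(400 - 0.002, 400 + 0.002), rt = c(100, 100),
                        intensity = c(1e5, 1e6))
  h <- match_candidates(cands[cands$n == 0, ], feats, refs, match_params())
  expect_equal(nrow(h), 1L)
  expect_equal(h$intensity, 1e6)                 # higher intensity wins the tie
  # no feature inside both gates -> no hit
  far <- toy_features(mz = 400.5, rt = 100)
  expect_equal(nrow(match_candidates(cands, far, refs, match_params())), 0L)
  # mixed polarity input is rejected
  mixed <- rbind(feats, toy_features(400, 100, polarity = "negative"))
  expect_error(match_candidates(cands, mixed, refs, match_params()), "polarit")
})

test_that("hits satisfy the gates and their stored score is reproducible", {
  set.seed(21)
  inst <- random_match_instance(n_refs = 10, n_features = 400)
  p <- match_params()
  h <- match_candidates(inst$candidates, inst$features, inst$refs, p)
  expect_gt(nrow(h), 0L)
  expect_true(all(h$score >= p$score_min & h$score <= 1))
  expect_true(all(abs(h$mz2 - h$theoretical_mz) <=
                    h$theoretical_mz * p$mz_window_ppm * 1e-6))
  expect_true(all(abs(h$rt2 - h$rt1) <= p$rt_window))
  recomputed <- iso_score(h$mz2 - h$theoretical_mz, h$rt2 - h$rt1, p$beta)
  expect_true(all(abs(recomputed - h$score) < 1e-9))
  expect_true(all(abs((h$mz2 - h$theoretical_mz) / h$theoretical_mz * 1e6 -
                        h$dmz_ppm) < 1e-9))
  expect_identical(h$grade, assign_grade(h$score, p$score_min))
})

test_that("matching equals the exhaustive brute-force search", {
  set.seed(31)
  for (k in 1:10) {
    inst <- random_match_instance(n_refs = 10, cap = 9, n_features = 400)
    p <- match_params()
    h <- match_candidates(inst$candidates, inst$features, inst$refs, p)
    o <- brute_force_match(inst$candidates, inst$features, inst$refs, p)
    expect_identical(paste(h$ref_id, h$n, h$feature_id),
                     paste(o$ref_id, o$n, o$feature_id))
    expect_equal(h$score, o$score, tolerance = 1e-12)
  }
})

test_that("raising the score cutoff only removes hits", {
  set.seed(41)
  inst <- random_match_instance(n_refs = 12, n_features = 600)
  cuts <- c(0.61, 0.75, 0.9, 0.99)
  sets <- lapply(cuts, function(s) {
    h <- match_candidates(inst$candidates, inst$features, inst$refs,
                          match_params(score_min = s))
    paste(h$ref_id, h$n, h$feature_id)
  })
  for (i in seq_along(cuts)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("matching is invariant to a common RT shift of features and references", {
  set.seed(51)
  inst <- random_match_instance(n_refs = 8, n_features = 300)
  p <- match_params()
  h1 <- match_candidates(inst$candidates, inst$features, inst$refs, p)
  refs2 <- inst$refs; refs2$rt <- refs2$rt + 500
  feats2 <- inst$features; feats2$rt <- feats2$rt + 500
  cands2 <- build_candidates(refs2, n_max_metabolite = 9, cap_by_formula = FALSE)
  h2 <- match_candidates(cands2, feats2, refs2, p)
  expect_identical(paste(h1$ref_id, h1$n, h1$feature_id),
                   paste(h2$ref_id, h2$n, h2$feature_id))
  expect_equal(h1$score, h2$score, tolerance = 1e-9)
})

test_that("a co-eluting heavier lipid cannot claim the M+26 slot", {
  # host M+26 candidate sits at 804.6470; the interfering M+0 of the heavier
  # lipid lies at 804.5755, i.e. 0.0715 Th away (~89 ppm), outside the gate
  refs <- toy_refs(mz = 778.5598, rt = 1200, polarity = "negative")
  refs$mode <- "lipid"; refs$adduct <- "+HCOO"
  cands <- build_candidates(refs, cap_by_formula = FALSE)
  m26 <- cands[cands$n == 26, ]
  feats <- toy_features(mz = c(804.6470, 804.5755), rt = c(1200, 1200),
                        intensity = c(1e5, 5e6), polarity = "negative")
  h <- match_candidates(m26, feats, refs, match_params())
  expect_equal(nrow(h), 1L)
  expect_equal(h$mz2, 804.6470)       # the planted isotopomer, not the interferer
  expect_equal(h$grade, "A")
  # with the planted peak absent the interferer still cannot pass the gate
  h2 <- match_candidates(m26, feats[2, ], refs, match_params())
  expect_equal(nrow(h2), 0L)
})

test_that("features may serve several candidates and are flagged as shared", {
  refs <- rbind(toy_refs(mz = 400, rt = 100),
                toy_refs(mz = 400 + DELTA_13C, rt = 100))
  refs$ref_id <- c("REF0001", "REF0002"); refs$name <- c("A", "B")
  cands <- build_candidates(refs, n_max_metabolite = 1, cap_by_formula = FALSE)
  # one feature at A's M+1 == B's M+0
  feats <- toy_features(mz = 400 + DELTA_13C, rt = 100)
  h <- match_candidates(cands, feats, refs, match_params())
  expect_equal(nrow(h), 2L)
  expect_true(all(h$feature_shared))
})

test_that("the driver concatenates samples and writes the result sheet", {
  refs <- pool_references(list(load_metabolite_export(
    write_toy_metabolite_export(tempfile(fileext = ".csv")))))
  cands <- build_candidates(refs)
  pos_mz <- refs$mz[refs$polarity == "positive"]
  neg_mz <- refs$mz[refs$polarity == "negative"]
  s1 <- rbind(
    toy_features(pos_mz, refs$rt[refs$polarity == "positive"]),
    toy_features(neg_mz + DELTA_13C, refs$rt[refs$polarity == "negative"],
                 polarity = "negative"))
  s2 <- s1; s2$sample_id <- "S2"
  out <- tempfile(fileext = ".csv")
  expect_warning(
    hits <- flux_result(refs, list(S1 = s1, S2 = s2, S3 = s1[0, ]),
                        output_csv = out),
    "zero features")
  expect_setequal(unique(hits$sample_id), c("S1", "S2"))
  expect_equal(sum(hits$sample_id == "S1"), sum(hits$sample_id == "S2"))
  sheet <- read.csv(out, check.names = FALSE)
  expect_identical(
    names(sheet)[1:17],
    c("mz1", "rt1", "Intensity", "mz2", "rt2", "Metabolite/Lipid",
      "fattyAcid", "lipidClass", "lipidForm", "Accession", "Theoretical_mz",
      "Adduct", "Charge", "Annotation", "Score", "dmz_ppm", "Grades"))
  expect_true(all(sheet$Grades %in% c("A", "B", "C", "D")))
  # empty feature input yields a header-only sheet
  out2 <- tempfile(fileext = ".csv")
  suppressWarnings(flux_result(refs, list(S1 = s1[0, ]), output_csv = out2))
  expect_equal(nrow(read.csv(out2, check.names = FALSE)), 0L)
})
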