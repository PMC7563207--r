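hits_of <- function(n, intensity, ref_id = "REF0001", sample_id = "S1") {
  data.frame(ref_id = rep_len(ref_id, length(n)),
             sample_id = rep_len(sample_id, length(n)), n = n,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("labeling ratio is heavy over heavy-plus-M0", {
  expect_equal(as.numeric(labeling_ratio(hits_of(c(0, 3, 5), c(100, 50, 50)))),
               0.5)
  r0 <- labeling_ratio(hits_of(0, 100))
  expect_equal(as.numeric(r0), 0)
  expect_false(attr(r0, "m0_missing"))
  r1 <- labeling_ratio(hits_of(c(3, 5), c(50, 50)))
  expect_equal(as.numeric(r1), 1)
  expect_true(attr(r1, "m0_missing"))
  expect_error(labeling_ratio(hits_of(integer(0), numeric(0))), "undefined")
  expect_error(labeling_ratio(rbind(hits_of(0, 1), hits_of(1, 1, "REF0002"))),
               "one molecule")
})

test_that("labeling ratio is invariant to uniform intensity scaling", {
  set.seed(61)
  for (i in 1:10) {
    ns <- sort(sample(0:10, sample(2:6, 1)))
    int <- runif(length(ns), 1e4, 1e6)
    r <- as.numeric(labeling_ratio(hits_of(ns, int)))
    expect_equal(as.numeric(labeling_ratio(hits_of(ns, int * 37.5))), r,
                 tolerance = 1e-12)
    expect_true(r >= 0 && r <= 1)
  }
})

test_that("isotopomer distributions normalize to one and agree with the ratio", {
  d <- isotopomer_distribution(hits_of(c(0, 5, 6), c(0, 900, 100)))
  expect_equal(unname(d), c(0, 0.9, 0.1))
  expect_equal(names(d), c("0", "5", "6"))
  expect_equal(sum(d), 1)
  expect_equal(unname(isotopomer_distribution(hits_of(4, 123))), 1)
  expect_error(isotopomer_distribution(hits_of(c(0, 1), c(0, 0))), "zero")
  # ratio from the distribution equals ratio from raw intensities
  h <- hits_of(c(0, 2, 3), c(300, 500, 200))
  d2 <- isotopomer_distribution(h)
  expect_equal(sum(d2[names(d2) != "0"]), as.numeric(labeling_ratio(h)))
})

test_that("per-molecule summaries split by molecule and sample", {
  h <- rbind(hits_of(c(0, 3), c(100, 100)),
             hits_of(c(0, 2), c(100, 300), sample_id = "S2"),
             hits_of(c(1, 4), c(10, 30), ref_id = "REF0002"))
  s <- labeling_summaries(h)
  expect_equal(nrow(s), 3L)
  expect_equal(s$labeling_ratio[s$ref_id == "REF0001" & s$sample_id == "S1"], 0.5)
  expect_equal(s$labeling_ratio[s$ref_id == "REF0001" & s$sample_id == "S2"], 0.75)
  expect_true(s$m0_missing[s$ref_id == "REF0002"])
  expect_equal(s$labeling_ratio[s$ref_id == "REF0002"], 1)
})

ref_row <- function(ref_id, name, class = NA, fa = NA) {
  data.frame(ref_id = ref_id, name = name, accession = NA, mode = "lipid",
             mz = 700, rt = 1000, polarity = "negative", adduct = "+HCOO",
             z = 1L, formula = NA, lipid_class = class, fatty_acids = fa,
             stringsAsFactors = FALSE)
}

test_that("class aggregation averages member ratios within bounds", {
  refs <- rbind(ref_row("REF0001", "PC(16:0/16:0)", "PC", "16:0/16:0"),
                ref_row("REF0002", "PC(16:0/18:1)", "PC", "16:0/18:1"),
                ref_row("REF0003", "TG(16:0/18:1/18:1)", "TG", "16:0/18:1/18:1"))
  s <- data.frame(ref_id = c("REF0001", "REF0002", "REF0003"),
                  sample_id = "S1", labeling_ratio = c(0.4, 0.6, 0.2))
  agg <- aggregate_lipid_class(s, refs)
  expect_equal(agg$mean_ratio[agg$lipid_class == "PC"], 0.5)
  expect_equal(agg$mean_ratio[agg$lipid_class == "TG"], 0.2)
  expect_equal(agg$n_lipids[agg$lipid_class == "PC"], 2L)
  # single-member class equals its only member; means stay inside [min, max]
  expect_true(all(agg$mean_ratio >= 0.2 & agg$mean_ratio <= 0.6))
  expect_equal(nrow(aggregate_lipid_class(s[0, ], refs)), 0L)
})

test_that("fatty-acid aggregation counts each distinct chain token once per lipid", {
  refs <- rbind(ref_row("REF0001", "PC(16:0/16:0)", "PC", "16:0/16:0"),
                ref_row("REF0002", "PC(16:0/18:1)", "PC", "16:0/18:1"),
                ref_row("REF0003", "unchained", "PC", NA))
  s <- data.frame(ref_id = c("REF0001", "REF0002", "REF0003"),
                  sample_id = "S1", labeling_ratio = c(0.4, 0.6, 0.9))
  agg <- aggregate_fatty_acid(s, refs)
  expect_equal(agg$mean_ratio[agg$fatty_acid == "16:0"], 0.5)
  expect_equal(agg$n_lipids[agg$fatty_acid == "16:0"], 2L)  # not 3: 16:0/16:0 counts once
  expect_equal(agg$mean_ratio[agg$fatty_acid == "18:1"], 0.6)
  expect_equal(attr(agg, "n_skipped"), 1L)
  empty <- aggregate_fatty_acid(s[0, ], refs)
  expect_equal(nrow(empty), 0L)
})

test_that("the time-course table maps samples and rejects bad designs", {
  s <- expand.grid(ref_id = c("REF0001", "REF0002"),
                   sample_id = paste0("S", 1:6), stringsAsFactors = FALSE)
  s$labeling_ratio <- runif(nrow(s))
  map <- data.frame(sample_id = paste0("S", 1:6),
                    condition = rep(c("vehicle", "drug"), each = 3),
                    timepoint = rep(c(2, 16, 24), 2))
  tc <- timecourse_table(s, map)
  expect_equal(nrow(tc), 12L)   # 2 refs x 3 timepoints x 2 conditions
  expect_error(timecourse_table(s, map[1:3, ]), "unmapped")
  expect_error(timecourse_table(s, rbind(map, map[1, ])), "duplicate")
  # missing summaries stay absent
  tc2 <- timecourse_table(s[-1, ], map)
  expect_equal(nrow(tc2), 11L)
})

test_that("condition comparison reports log2 fold change against vehicle", {
  tc <- data.frame(ref_id = rep("REF0001", 2), sample_id = c("S1", "S2"),
                   condition = c("vehicle", "drug"), timepoint = 24,
                   labeling_ratio = c(0.25, 0.5))
  cmp <- compare_conditions(tc, "drug")
  expect_equal(cmp$log2_fc, log2(0.5001 / 0.2501), tolerance = 1e-9)
  expect_equal(cmp$difference, 0.25)
})
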