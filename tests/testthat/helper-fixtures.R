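# Shared fixtures: toy export writers, synthetic spectra, and the exhaustive
# brute-force matcher used as the independent oracle for the search.

write_toy_metabolite_export <- function(path, df = NULL) {
  if (is.null(df))
    df <- data.frame(
      name = c("glycine", "lactate", "UTP"),
      accession = c("HMDB0000123", "HMDB0000190", "HMDB0000285"),
      formula = c("C2H5NO2", "C3H6O3", "C9H15N2O15P3"),
      mz = c(76.0393, 89.0244, 482.9611),
      rt = c(300, 320, 410),
      polarity = c("positive", "negative", "negative"),
      stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  path
}

# the five-row grade/m-score fixture: grades A,B,C,D,A with m-scores 9,6,5,9,3
write_toy_lipid_export <- function(path) {
  df <- data.frame(
    LipidID = c("PC(16:0/16:0)", "PC(16:0/18:1)", "LPC(16:0)",
                "TG(16:0/18:1/18:1)", "PE(18:0/18:1)"),
    Class = c("PC", "PC", "LPC", "TG", "PE"),
    FA = c("16:0/16:0", "16:0/18:1", "16:0", "16:0/18:1/18:1", "18:0/18:1"),
    Formula = c("C40H80NO8P", "C42H82NO8P", "C24H50NO7P", "C55H102O6",
                "C41H80NO8P"),
    Grade = c("A", "B", "C", "D", "A"),
    `m-score` = c(9, 6, 5, 9, 3),
    CalcMz = c(778.5598, 804.5755, 540.3307, 876.8015, 790.5598),
    Rt = c(1200, 1260, 700, 1500, 1300),
    Ion = c("+HCOO", "+HCOO", "+HCOO", "+NH4", "+HCOO"),
    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  path
}

# a Gaussian extracted-ion chromatogram as a list of single-peak spectra
gaussian_eic_spectra <- function(mz = 300, apex = 1e6, n_scans = 11,
                                 rt0 = 100, dt = 2, sigma = 4,
                                 polarity = "positive", noise = 0,
                                 extra = NULL) {
  rts <- rt0 + dt * (seq_len(n_scans) - 1)
  apex_rt <- rts[(n_scans + 1) %/% 2]
  lapply(seq_along(rts), function(i) {
    int <- apex * exp(-(rts[i] - apex_rt)^2 / (2 * sigma^2)) + noise
    pk <- cbind(mz, int)
    if (!is.null(extra)) {
      e_int <- extra$apex * exp(-(rts[i] - apex_rt)^2 / (2 * sigma^2)) + noise
      pk <- rbind(pk, cbind(extra$mz, e_int))
    }
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    colnames(pk) <- c("mz", "intensity")
    list(rt = rts[i], polarity = polarity, ms_level = 1L, peaks = pk)
  })
}

# Exhaustive O(C x F) reference matcher: dense score matrix over every
# candidate-feature pair, same gates / score / tie rules, no windowing or
# sorting tricks. Returns (ref_id, n, feature_id, score) rows.
brute_force_match <- function(candidates, features, refs, params) {
  rt_scale <- if (params$rt_unit == "minutes") 1 / 60 else 1
  th <- candidates$theoretical_mz
  rt0 <- refs$rt[match(candidates$ref_id, refs$ref_id)]
  dmz <- outer(th, features$mz, function(a, b) b - a)
  drt <- outer(rt0, features$rt, function(a, b) (b - a) * rt_scale)
  ok <- abs(dmz) <= (th %o% rep(1, nrow(features))) * params$mz_window_ppm * 1e-6 &
    abs(drt) <= params$rt_window
  sc <- 1 - sqrt((dmz * params$beta)^2 + drt^2)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    j <- which(ok[i, ])
    if (!length(j)) next
    o <- j[order(-sc[i, j], -features$intensity[j], abs(dmz[i, j]))][1]
    if (sc[i, o] >= params$score_min)
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = candidates$ref_id[i], n = candidates$n[i],
        feature_id = o, score = sc[i, o], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(ref_id = character(0), n = integer(0),
                      feature_id = integer(0), score = numeric(0)))
  do.call(rbind, rows)
}

# a random matching instance: refs with isotopomer ladders plus a feature
# cloud of uniform decoys and features planted near random candidates
random_match_instance <- function(n_refs = 20, cap = 9, n_features = 2000,
                                  planted_frac = 0.5) {
  refs <- data.frame(
    ref_id = sprintf("REF%04d", seq_len(n_refs)),
    name = sprintf("M%03d", seq_len(n_refs)),
    accession = NA_character_, mode = "metabolite",
    mz = runif(n_refs, 100, 800), rt = runif(n_refs, 60, 900),
    polarity = "positive", adduct = "+H", z = 1L,
    formula = NA_character_, lipid_class = NA_character_,
    fatty_acids = NA_character_, stringsAsFactors = FALSE)
  cands <- build_candidates(refs, n_max_metabolite = cap, cap_by_formula = FALSE)
  n_planted <- round(n_features * planted_frac)
  pick <- sample.int(nrow(cands), n_planted, replace = TRUE)
  rt0 <- refs$rt[match(cands$ref_id[pick], refs$ref_id)]
  # RT offsets straddle every regime: scoreable (< 0.39 s), gated-but-low,
  # and outside the 30 s gate; m/z offsets straddle the 10 ppm gate
  rt_off <- runif(n_planted, -45, 45) *
    sample(c(0.005, 1), n_planted, replace = TRUE)
  planted <- data.frame(
    sample_id = "S1", polarity = "positive",
    mz = cands$theoretical_mz[pick] *
      (1 + runif(n_planted, -15e-6, 15e-6)),
    rt = rt0 + rt_off,
    intensity = 10^runif(n_planted, 4, 7), stringsAsFactors = FALSE)
  n_decoy <- n_features - n_planted
  decoys <- data.frame(
    sample_id = "S1", polarity = "positive",
    mz = runif(n_decoy, 100, 820), rt = runif(n_decoy, 0, 1000),
    intensity = 10^runif(n_decoy, 4, 7), stringsAsFactors = FALSE)
  features <- rbind(planted, decoys)
  list(refs = refs, candidates = cands, features = features)
}

# the co-eluting heavier-lipid scenario: dipalmitoyl PC traced to M+26 with
# the M+0 formate ion of PC(16:0/18:1) planted 26.01565 Th (= +C2H2) above
# the host M+0, i.e. 0.0715 Th from the M+26 candidate
overlap_scenario_config <- function(seed, envelope = c("0" = 0.2, "3" = 0.3,
                                                       "26" = 0.5)) {
  molecules <- data.frame(
    name = "PC(16:0/16:0)", formula = "C40H80NO8P", rt = 1200,
    adduct = "+HCOO", base_intensity = 1e6, mode = "lipid",
    lipid_class = "PC", stringsAsFactors = FALSE)
  interferers <- data.frame(
    molecule = "PC(16:0/16:0)", offset_th = 26.0156501, rt_offset_s = 0,
    intensity = 5e6, stringsAsFactors = FALSE)
  sim_config(molecules, list("PC(16:0/16:0)" = envelope),
             interferers = interferers, seed = seed)
}

# matching configuration used for simulation studies: chromatography with
# seconds-scale RT scatter, so RT enters the score in minutes
sim_match_params <- function() match_params(rt_unit = "minutes", rt_window = 0.5)

refs_from_sim <- function(res) {
  lists <- list()
  if (!is.null(res$metabolite_export)) {
    f <- tempfile(fileext = ".csv")
    write.csv(res$metabolite_export, f, row.names = FALSE)
    lists <- c(lists, list(load_metabolite_export(f)))
    unlink(f)
  }
  if (!is.null(res$lipid_export)) {
    f <- tempfile(fileext = ".csv")
    write.csv(res$lipid_export, f, row.names = FALSE)
    lists <- c(lists, list(load_lipid_export(f)))
    unlink(f)
  }
  pool_references(lists)
}
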