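# Ground-truth simulator: generates unlabeled identification exports and
# labeled MS1 feature lists with planted isotopologue envelopes, uniform
# decoys, and co-eluting interferers, plus evaluation of search output
# against the planted truth.

#' Simulation configuration
#'
#' `molecules` describes the planted species: name, neutral formula, nominal
#' RT (seconds), adduct, base intensity and a labeling envelope (named
#' fractions over label counts, summing to 1). Default noise scales emulate
#' high-resolution Orbitrap acquisition: ~1.5 ppm m/z jitter and ~2 s RT
#' jitter around the planted values, with 10% lognormal intensity scatter.
#' Decoy features are uniform in (m/z, RT); interferer features are placed at
#' fixed m/z / RT offsets from their host molecule's M+0 ion, reproducing the
#' co-eluting heavier-lipid scenario in which another molecule's envelope
#' invades an isotopomer ladder ~0.07 Th away.
#'
#' @param molecules data.frame with columns `name`, `formula`, `rt`,
#'   `adduct`, `base_intensity`, optionally `mode` ("metabolite"/"lipid"),
#'   `lipid_class`.
#' @param envelopes Named list (by molecule name) of named numeric vectors:
#'   names are label counts n, values are fractions summing to 1.
#' @param mz_jitter_ppm_sd Gaussian m/z jitter, ppm (default 1.5).
#' @param rt_jitter_sd_s Gaussian RT jitter, seconds (default 2).
#' @param intensity_cv Lognormal intensity coefficient of variation
#'   (default 0.1).
#' @param n_decoys Uniform decoy features per sample (default 0).
#' @param decoy_mz_range,decoy_rt_range Ranges the decoys are drawn from.
#' @param interferers Optional data.frame: `molecule`, `offset_th`,
#'   `rt_offset_s`, `intensity` — one interferer feature per row per sample.
#' @param hard_decoys If TRUE, decoys are instead placed one isotope spacing
#'   (± a small uniform offset) above randomly chosen planted features, to
#'   stress tie-breaking (default FALSE).
#' @param samples Character vector of sample ids (default "S1").
#' @param seed Integer master seed; per-sample substreams are derived by
#'   hashing the sample id, so adding a sample never perturbs existing ones.
#' @param adducts Adduct table.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(molecules, envelopes,
                       mz_jitter_ppm_sd = 1.5, rt_jitter_sd_s = 2,
                       intensity_cv = 0.1, n_decoys = 0L,
                       decoy_mz_range = c(150, 900),
                       decoy_rt_range = NULL,
                       interferers = NULL, hard_decoys = FALSE,
                       samples = "S1", seed = 1L,
                       adducts = default_adducts()) {
  stopifnot(is.data.frame(molecules),
            all(c("name", "formula", "rt", "adduct", "base_intensity") %in%
                  names(molecules)),
            mz_jitter_ppm_sd >= 0, rt_jitter_sd_s >= 0, intensity_cv >= 0,
            n_decoys >= 0)
  if (anyDuplicated(molecules$name)) stop("duplicate molecule names")
  if (!"mode" %in% names(molecules)) molecules$mode <- "metabolite"
  for (nm in molecules$name) {
    e <- envelopes[[nm]]
    if (is.null(e)) stop("no envelope for molecule ", sQuote(nm))
    if (any(e < 0) || abs(sum(e) - 1) > 1e-9)
      stop("envelope of ", sQuote(nm),
           " must have non-negative fractions summing to 1")
    nmax <- carbon_count(molecules$formula[match(nm, molecules$name)])
    if (any(as.integer(names(e)) > nmax))
      stop("envelope of ", sQuote(nm), " labels more carbons than formula has")
  }
  if (is.null(decoy_rt_range))
    decoy_rt_range <- range(molecules$rt) + c(-60, 60)
  structure(list(molecules = molecules, envelopes = envelopes,
                 mz_jitter_ppm_sd = mz_jitter_ppm_sd,
                 rt_jitter_sd_s = rt_jitter_sd_s,
                 intensity_cv = intensity_cv, n_decoys = as.integer(n_decoys),
                 decoy_mz_range = decoy_mz_range,
                 decoy_rt_range = decoy_rt_range,
                 interferers = interferers, hard_decoys = hard_decoys,
                 samples = samples, seed = as.integer(seed),
                 adducts = adducts),
            class = "sim_config")
}

# stable 31-bit string hash for per-sample RNG substreams
.string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Simulate unlabeled identification exports and labeled feature lists
#'
#' Produces (1) identification exports for the unlabeled sample — each
#' molecule's M+0 ion m/z (from its formula and adduct) at its nominal RT, in
#' the metabolite and/or lipid export dialect the loaders read; (2) per
#' labeled sample, a feature list containing one feature per envelope
#' component with fraction > 0, at the theoretical isotopomer m/z perturbed
#' by the configured jitters, plus decoys and interferers; and (3) the
#' ground-truth table of all planted features. Fully reproducible from the
#' master seed.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `metabolite_export` and `lipid_export`
#'   (data.frames in the loader dialects, possibly empty), `features`
#'   (named list per sample), `truth` (data.frame: sample_id, name, n,
#'   true_mz, true_rt, true_intensity, kind), and `base_ions`
#'   (per molecule: M+0 ion m/z and charge).
#' @export
simulate_tracing <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mol <- config$molecules
  base <- do.call(rbind, lapply(seq_len(nrow(mol)), function(i) {
    a <- get_adduct(mol$adduct[i], config$adducts)
    data.frame(name = mol$name[i],
               mz0 = ion_mz(monoisotopic_mass(mol$formula[i]), a),
               z = abs(a$z), polarity = a$polarity,
               stringsAsFactors = FALSE)
  }))

  lognorm <- function(rng_n) {
    if (config$intensity_cv <= 0) return(rep(1, rng_n))
    sdl <- sqrt(log(1 + config$intensity_cv^2))
    stats::rlnorm(rng_n, meanlog = -sdl^2 / 2, sdlog = sdl)
  }

  features <- list(); truth_rows <- list()
  for (sid in config$samples) {
    set.seed((config$seed + .string_hash(sid)) %% 2147483647L)
    rows <- list()
    for (i in seq_len(nrow(mol))) {
      e <- config$envelopes[[mol$name[i]]]
      e <- e[e > 0]
      ns <- as.integer(names(e))
      th <- isotopomer_mz(base$mz0[i], ns, base$z[i])
      mz <- th * (1 + stats::rnorm(length(ns), 0, config$mz_jitter_ppm_sd) * 1e-6)
      rt <- mol$rt[i] + stats::rnorm(length(ns), 0, config$rt_jitter_sd_s)
      int <- mol$base_intensity[i] * as.numeric(e) * lognorm(length(ns))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, polarity = base$polarity[i], mz = mz, rt = rt,
        intensity = int, name = mol$name[i], n = ns, kind = "planted",
        stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, rows)
    extra <- NULL
    if (config$n_decoys > 0L) {
      if (config$hard_decoys) {
        pick <- sample.int(nrow(planted), config$n_decoys, replace = TRUE)
        dmz <- planted$mz[pick] + DELTA_13C +
          stats::runif(config$n_decoys, -0.01, 0.01)
        drt <- planted$rt[pick] + stats::rnorm(config$n_decoys, 0, 1)
        dpol <- planted$polarity[pick]
      } else {
        dmz <- stats::runif(config$n_decoys, config$decoy_mz_range[1],
                            config$decoy_mz_range[2])
        drt <- stats::runif(config$n_decoys, config$decoy_rt_range[1],
                            config$decoy_rt_range[2])
        dpol <- sample(unique(base$polarity), config$n_decoys, replace = TRUE)
      }
      extra <- data.frame(
        sample_id = sid, polarity = dpol, mz = dmz, rt = drt,
        intensity = stats::runif(config$n_decoys, 1e4, 1e6),
        name = NA_character_, n = NA_integer_, kind = "decoy",
        stringsAsFactors = FALSE)
    }
    interf <- NULL
    if (!is.null(config$interferers) && nrow(config$interferers) > 0L) {
      ii <- match(config$interferers$molecule, base$name)
      if (anyNA(ii)) stop("interferer references unknown molecule")
      interf <- data.frame(
        sample_id = sid, polarity = base$polarity[ii],
        mz = base$mz0[ii] + config$interferers$offset_th,
        rt = mol$rt[ii] + config$interferers$rt_offset_s,
        intensity = config$interferers$intensity,
        name = NA_character_, n = NA_integer_, kind = "interferer",
        stringsAsFactors = FALSE)
    }
    all <- rbind(planted, extra, interf)
    all <- all[order(all$mz), , drop = FALSE]
    rownames(all) <- NULL
    features[[sid]] <- all[, c("sample_id", "polarity", "mz", "rt", "intensity")]
    truth_rows[[sid]] <- data.frame(
      sample_id = all$sample_id, name = all$name, n = all$n,
      true_mz = all$mz, true_rt = all$rt, true_intensity = all$intensity,
      kind = all$kind, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  is_lipid <- mol$mode == "lipid"
  met_export <- if (any(!is_lipid)) data.frame(
    name = mol$name[!is_lipid], accession = paste0("SYN", which(!is_lipid)),
    formula = mol$formula[!is_lipid], mz = base$mz0[!is_lipid],
    rt = mol$rt[!is_lipid], polarity = base$polarity[!is_lipid],
    adduct = mol$adduct[!is_lipid],
    z = base$z[!is_lipid], stringsAsFactors = FALSE) else NULL
  lip_export <- if (any(is_lipid)) data.frame(
    LipidID = mol$name[is_lipid],
    Class = if ("lipid_class" %in% names(mol))
      mol$lipid_class[is_lipid] else sub("\\(.*$", "", mol$name[is_lipid]),
    Formula = mol$formula[is_lipid], Grade = "A", `m-score` = 10,
    CalcMz = base$mz0[is_lipid], Rt = mol$rt[is_lipid],
    Ion = mol$adduct[is_lipid], check.names = FALSE,
    stringsAsFactors = FALSE) else NULL

  list(metabolite_export = met_export, lipid_export = lip_export,
       features = features, truth = truth, base_ions = base)
}

#' Evaluate search hits against the simulated ground truth
#'
#' A hit is a true positive iff its (molecule, n) was planted in that sample
#' and the matched feature is the planted feature itself (m/z and RT agree
#' within tight tolerances), not a decoy or interferer. Precision is
#' TP / (TP + FP); with zero hits precision is reported as 1.0 with a
#' `zero_hits` flag. Recall is TP / number of planted components.
#'
#' @param hits Hits data.frame from [flux_result()] (needs `name`,
#'   `sample_id`, `n`, `mz2`, `rt2`).
#' @param truth Truth table from [simulate_tracing()].
#' @param mz_tol_ppm m/z identity tolerance for "same feature" (default 0.5).
#' @param rt_tol_s RT identity tolerance (default 0.01).
#' @return List: precision, recall, tp, fp, fn, n_planted, zero_hits,
#'   and `per_n` — a data.frame of TP/FN counts per label count.
#' @export
evaluate_hits <- function(hits, truth, mz_tol_ppm = 0.5, rt_tol_s = 0.01) {
  planted <- truth[truth$kind == "planted", , drop = FALSE]
  key <- function(s, nm, n) paste(s, nm, n, sep = "\r")
  pk <- key(planted$sample_id, planted$name, planted$n)
  if (nrow(hits) == 0L) {
    per_n <- stats::aggregate(list(tp = rep(0L, nrow(planted))),
                              by = list(n = planted$n), FUN = sum)
    per_n$fn <- as.integer(table(planted$n)[as.character(per_n$n)])
    return(list(precision = 1.0, recall = 0, tp = 0L, fp = 0L,
                fn = nrow(planted), n_planted = nrow(planted),
                zero_hits = TRUE, per_n = per_n))
  }
  hk <- key(hits$sample_id, hits$name, hits$n)
  i <- match(hk, pk)
  same_feature <- !is.na(i) &
    abs(hits$mz2 - planted$true_mz[i]) <=
      planted$true_mz[i] * mz_tol_ppm * 1e-6 &
    abs(hits$rt2 - planted$true_rt[i]) <= rt_tol_s
  tp <- sum(same_feature)
  fp <- nrow(hits) - tp
  matched_planted <- unique(i[same_feature])
  fn <- nrow(planted) - length(matched_planted)
  tp_by_n <- table(planted$n[matched_planted])
  all_n <- sort(unique(planted$n))
  per_n <- data.frame(
    n = all_n,
    tp = as.integer(ifelse(is.na(tp_by_n[as.character(all_n)]), 0,
                           tp_by_n[as.character(all_n)])),
    planted = as.integer(table(planted$n)[as.character(all_n)]))
  per_n$fn <- per_n$planted - per_n$tp
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 1.0,
       recall = tp / nrow(planted), tp = tp, fp = fp, fn = fn,
       n_planted = nrow(planted), zero_hits = FALSE, per_n = per_n)
}

#' A default panel of simulated metabolite-like molecules
#'
#' A panel generator used by tests and the evaluation command: `n` distinct
#' molecules with small CHNO formulas (3-10 carbons, so every envelope
#' component lies within the metabolite isotopomer cap), RTs spread over the
#' run, and randomly drawn labeling envelopes. The panel emulates a
#' deduplicated identification list: formulas are unique, and molecules
#' whose M+0 ions fall within 20 ppm of each other are forced at least
#' 120 s apart in RT — two species indistinguishable in both m/z and RT
#' would not appear as separate entries in an upstream identification
#' export. Drawn from the currently set RNG stream.
#'
#' @param n Number of molecules.
#' @param polarity Adducts assigned (`"+H"` for positive, `"-H"` negative,
#'   alternating when `"both"`).
#' @return List with `molecules` and `envelopes` ready for [sim_config()].
#' @export
random_panel <- function(n = 50L, polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  grid <- expand.grid(nc = 3:10, dh = -1:8, no = 1:8, nn = 0:3)
  pick <- grid[sample.int(nrow(grid), n), ]
  nc <- pick$nc
  nh <- pmax(2L, nc + pick$dh)
  formula <- paste0("C", nc, "H", nh,
                    ifelse(pick$nn > 0, paste0("N", pick$nn), ""),
                    "O", pick$no)
  adduct <- switch(polarity,
                   positive = rep("+H", n),
                   negative = rep("-H", n),
                   both = rep(c("+H", "-H"), length.out = n))
  rt <- stats::runif(n, 60, 900)
  # resolve near-isobaric co-elution: same-polarity ions within 20 ppm get
  # pushed apart in RT until separated by at least 120 s
  mz0 <- vapply(seq_len(n), function(i)
    ion_mz(monoisotopic_mass(formula[i]), adduct[i]), numeric(1))
  repeat {
    clash <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (adduct[i] == adduct[j] &&
          abs(mz0[i] - mz0[j]) <= mz0[i] * 20e-6 &&
          abs(rt[i] - rt[j]) < 120) {
        rt[j] <- stats::runif(1, 60, 900)
        clash <- TRUE
      }
    }
    if (!clash) break
  }
  molecules <- data.frame(
    name = sprintf("MOL%03d", seq_len(n)), formula = formula,
    rt = rt, adduct = adduct,
    base_intensity = 10^stats::runif(n, 5, 7),
    mode = "metabolite", stringsAsFactors = FALSE)
  envelopes <- lapply(seq_len(n), function(i) {
    ks <- sort(sample(0:nc[i], min(nc[i] + 1L, sample(2:5, 1))))
    w <- stats::runif(length(ks), 0.2, 1)
    stats::setNames(w / sum(w), ks)
  })
  names(envelopes) <- molecules$name
  list(molecules = molecules, envelopes = envelopes)
}
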