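# The search core: labeled-sample MS1 features are matched against the
# theoretical isotopomer ladder of each reference with hard m/z (ppm) and RT
# gates, then ranked by a joint m/z-RT score that screens false positives.
# RT is carried in seconds throughout the package; when rt_unit = "minutes"
# the deviations (and the rt_window gate) are converted at this boundary.

#' Matching parameters
#'
#' `beta` is the unit-fixing weight that puts the m/z deviation (Th) on the
#' retention-time scale inside the score; 0.1 is the default used for both
#' metabolite and lipid searches. `score_min` is the acceptance cutoff
#' (default 0.61 — with `beta = 0.1` this corresponds to an RT deviation of
#' 0.39 at zero mass error). The hard pre-gates reject features before
#' scoring: with `beta = 0.1` the m/z term is numerically tiny, so a ppm
#' window is what actually discriminates co-eluting envelopes of heavier
#' molecules (e.g. the M+0 of a lipid 0.07 Th above another lipid's M+26).
#'
#' @param beta Weight coefficient for the m/z term (default 0.1).
#' @param score_min Score cutoff in (0, 1] (default 0.61).
#' @param mz_window_ppm Hard m/z gate in ppm (default 10).
#' @param rt_window Hard RT gate in `rt_unit` (default 30).
#' @param rt_unit `"seconds"` (default) or `"minutes"`; the unit both RT
#'   values and `rt_window` are expressed in. The score uses RT deviations in
#'   this unit directly, so the effective RT tolerance implied by `score_min`
#'   scales with it.
#' @param score_form `"euclidean"` (default): `1 - sqrt((dmz*beta)^2 + drt^2)`;
#'   `"sum_of_squares"` keeps the unrooted reading `1 - ((dmz*beta)^2 + drt^2)`.
#' @return A list of class `match_params`.
#' @export
match_params <- function(beta = 0.1, score_min = 0.61, mz_window_ppm = 10,
                         rt_window = 30, rt_unit = c("seconds", "minutes"),
                         score_form = c("euclidean", "sum_of_squares")) {
  rt_unit <- match.arg(rt_unit)
  score_form <- match.arg(score_form)
  stopifnot(beta > 0, score_min > 0, score_min <= 1,
            mz_window_ppm > 0, rt_window > 0)
  structure(list(beta = beta, score_min = score_min,
                 mz_window_ppm = mz_window_ppm, rt_window = rt_window,
                 rt_unit = rt_unit, score_form = score_form),
            class = "match_params")
}

#' Joint m/z-RT match score
#'
#' `1 - sqrt((dmz * beta)^2 + drt^2)`: a weighted Euclidean distance from a
#' perfect match, subtracted from 1. A perfect match scores 1; the score
#' decreases strictly with either deviation and can go negative (such
#' assignments are always rejected by the cutoff). Signs of the deviations
#' are ignored.
#'
#' @param dmz m/z deviation (feature minus theoretical), Th.
#' @param drt RT deviation (feature minus reference), in the run's RT unit.
#' @param beta Weight coefficient (default 0.1).
#' @param score_form See [match_params()].
#' @return Numeric score <= 1 (vectorised).
#' @examples
#' iso_score(0, 0, 0.1)        # 1
#' iso_score(0, 0.39, 0.1)     # 0.61, the default cutoff
#' @export
iso_score <- function(dmz, drt, beta = 0.1, score_form = "euclidean") {
  d2 <- (dmz * beta)^2 + drt^2
  if (identical(score_form, "sum_of_squares")) 1 - d2 else 1 - sqrt(d2)
}

#' Letter grade for an accepted match score
#'
#' Declared quality bins over the accepted score range: A >= 0.95,
#' B >= 0.85, C >= 0.70, D otherwise (still at or above the cutoff).
#'
#' @param score Score(s) at or above `score_min`.
#' @param score_min Acceptance cutoff the scores were filtered at.
#' @return Character vector of grades `"A"`-`"D"`.
#' @export
assign_grade <- function(score, score_min = 0.61) {
  if (any(score < score_min))
    stop("assign_grade() called on score(s) below the cutoff; ",
         "sub-threshold hits are rejected before grading")
  cut_pts <- c(-Inf, 0.70, 0.85, 0.95, Inf)
  c("D", "C", "B", "A")[findInterval(score, cut_pts)]
}

.HIT_COLUMNS <- c("ref_id", "n", "annotation", "mz1", "rt1", "intensity",
                  "mz2", "rt2", "theoretical_mz", "adduct", "z",
                  "score", "dmz_ppm", "grade", "feature_id")

.empty_hits <- function() {
  data.frame(ref_id = character(0), n = integer(0), annotation = character(0),
             mz1 = numeric(0), rt1 = numeric(0), intensity = numeric(0),
             mz2 = numeric(0), rt2 = numeric(0), theoretical_mz = numeric(0),
             adduct = character(0), z = integer(0), score = numeric(0),
             dmz_ppm = numeric(0), grade = character(0),
             feature_id = integer(0), stringsAsFactors = FALSE)
}

#' Match isotopomer candidates against a labeled-sample feature list
#'
#' For each candidate, features within the hard gates
#' (|m/z - theoretical| <= `mz_window_ppm` ppm AND |RT - reference RT| <=
#' `rt_window`) are scored with [iso_score()]; the RT deviation is taken
#' against the reference entry's RT, since isotopomers co-elute with their
#' unlabeled molecule. The best-scoring feature is emitted as a hit iff its
#' score reaches `score_min`. Score ties are broken by higher intensity, then
#' by smaller |m/z deviation|. At most one hit per candidate; a feature may
#' serve several candidates (overlapping envelopes of different molecules are
#' physically real), and such shared features are flagged.
#'
#' @param candidates Candidate data.frame from [build_candidates()].
#' @param features Feature data.frame (`mz`, `rt`, `intensity`, `polarity`)
#'   of a single sample and polarity.
#' @param refs Reference pool the candidates were built from.
#' @param params A [match_params()] object.
#' @return Hits data.frame: ref_id, n, annotation, mz1/rt1 (reference),
#'   intensity, mz2/rt2 (matched feature), theoretical_mz, adduct, z, score,
#'   dmz_ppm, grade, feature_id, feature_shared.
#' @export
match_candidates <- function(candidates, features, refs,
                             params = match_params()) {
  stopifnot(inherits(params, "match_params"))
  if (nrow(features) > 0 && length(unique(features$polarity)) > 1L)
    stop("feature list mixes polarities; match one polarity at a time")
  ri <- match(candidates$ref_id, refs$ref_id)
  if (anyNA(ri)) stop("candidates reference unknown ref_id(s)")
  if (nrow(features) > 0 && nrow(refs) > 0) {
    fpol <- unique(features$polarity)
    if (length(unique(refs$polarity[ri])) > 1L ||
        unique(refs$polarity[ri])[1] != fpol)
      stop("candidate and feature polarities differ")
  }
  if (nrow(features) == 0L || nrow(candidates) == 0L) {
    out <- .empty_hits(); out$feature_shared <- logical(0); return(out)
  }

  ord <- order(features$mz)
  fmz <- features$mz[ord]
  frt <- features$rt[ord]
  fint <- features$intensity[ord]
  fid <- ord  # row index in the caller's feature table

  rt_scale <- if (params$rt_unit == "minutes") 1 / 60 else 1

  n_c <- nrow(candidates)
  sel_fid <- integer(n_c); sel_score <- numeric(n_c)
  hit <- logical(n_c)
  for (i in seq_len(n_c)) {
    th <- candidates$theoretical_mz[i]
    rt0 <- refs$rt[ri[i]]
    tol <- th * params$mz_window_ppm * 1e-6
    lo <- findInterval(th - tol, fmz) + 1L
    hi <- findInterval(th + tol, fmz)
    if (hi < lo) next
    j <- lo:hi
    keep <- abs(frt[j] - rt0) * rt_scale <= params$rt_window
    j <- j[keep]
    if (!length(j)) next
    sc <- iso_score(fmz[j] - th, (frt[j] - rt0) * rt_scale,
                    params$beta, params$score_form)
    best <- j[order(-sc, -fint[j], abs(fmz[j] - th))[1]]
    s <- iso_score(fmz[best] - th, (frt[best] - rt0) * rt_scale,
                   params$beta, params$score_form)
    if (s >= params$score_min) {
      hit[i] <- TRUE
      sel_fid[i] <- fid[best]
      sel_score[i] <- s
    }
  }
  if (!any(hit)) { out <- .empty_hits(); out$feature_shared <- logical(0); return(out) }

  ci <- which(hit)
  k <- ri[ci]
  f <- sel_fid[ci]
  out <- data.frame(
    ref_id = candidates$ref_id[ci],
    n = candidates$n[ci],
    annotation = candidates$annotation[ci],
    mz1 = refs$mz[k],
    rt1 = refs$rt[k],
    intensity = features$intensity[f],
    mz2 = features$mz[f],
    rt2 = features$rt[f],
    theoretical_mz = candidates$theoretical_mz[ci],
    adduct = refs$adduct[k],
    z = refs$z[k],
    score = sel_score[ci],
    dmz_ppm = (features$mz[f] - candidates$theoretical_mz[ci]) /
      candidates$theoretical_mz[ci] * 1e6,
    grade = assign_grade(sel_score[ci], params$score_min),
    feature_id = f,
    stringsAsFactors = FALSE)
  out$feature_shared <- duplicated(out$feature_id) |
    duplicated(out$feature_id, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

#' Run the full isotopomer search over all labeled samples
#'
#' The main driver: expands the reference pool to isotopomer candidates,
#' matches each labeled sample's feature list polarity by polarity, and
#' concatenates the hits into the final result table. Deterministic for
#' identical inputs and parameters.
#'
#' @param refs Pooled reference data.frame.
#' @param samples Named list of feature data.frames, one per labeled sample
#'   (names are sample ids); each may contain both polarities and is split
#'   internally. Alternatively a single data.frame with a `sample_id` column.
#' @param params A [match_params()] object.
#' @param n_max_metabolite,n_max_lipid,cap_by_formula Candidate expansion
#'   settings, see [build_candidates()].
#' @param output_csv Optional path; when given the result table is written
#'   with [write_result_csv()].
#' @return Hits data.frame over all samples with a `sample_id` column and the
#'   reference annotation columns (name, accession, lipid fields) merged in.
#'   A sample with zero features contributes no rows and raises a warning.
#' @export
flux_result <- function(refs, samples, params = match_params(),
                        n_max_metabolite = 10L, n_max_lipid = 40L,
                        cap_by_formula = TRUE, output_csv = NULL) {
  if (nrow(refs) == 0L) stop("empty reference pool")
  if (is.data.frame(samples)) {
    if (!"sample_id" %in% names(samples))
      stop("feature table needs a sample_id column")
    samples <- split(samples, samples$sample_id)
  }
  if (length(samples) == 0L) stop("at least one labeled sample required")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("'samples' must be a named list of feature tables")

  cands <- build_candidates(refs, n_max_metabolite, n_max_lipid, cap_by_formula)
  cand_pol <- refs$polarity[match(cands$ref_id, refs$ref_id)]

  pieces <- list()
  for (sid in names(samples)) {
    feats <- samples[[sid]]
    if (is.null(feats) || nrow(feats) == 0L) {
      warning("sample ", sQuote(sid), " has zero features; no hits reported")
      next
    }
    for (pol in unique(feats$polarity)) {
      fsub <- feats[feats$polarity == pol, , drop = FALSE]
      csub <- cands[cand_pol == pol, , drop = FALSE]
      if (nrow(csub) == 0L) next
      h <- match_candidates(csub, fsub, refs, params)
      if (nrow(h) > 0L) {
        h$sample_id <- sid
        pieces[[length(pieces) + 1L]] <- h
      }
    }
  }
  hits <- if (length(pieces)) do.call(rbind, pieces) else {
    h <- .empty_hits(); h$feature_shared <- logical(0)
    h$sample_id <- character(0); h
  }
  # merge reference annotations for the result sheet
  k <- match(hits$ref_id, refs$ref_id)
  hits$name <- refs$name[k]
  hits$accession <- refs$accession[k]
  hits$fatty_acids <- refs$fatty_acids[k]
  hits$lipid_class <- refs$lipid_class[k]
  hits$formula <- refs$formula[k]
  rownames(hits) <- NULL
  if (!is.null(output_csv)) write_result_csv(hits, output_csv)
  hits
}

.RESULT_HEADERS <- c("mz1", "rt1", "Intensity", "mz2", "rt2",
                     "Metabolite/Lipid", "fattyAcid", "lipidClass",
                     "lipidForm", "Accession", "Theoretical_mz", "Adduct",
                     "Charge", "Annotation", "Score", "dmz_ppm", "Grades")

#' Write the search result as the standard CSV sheet
#'
#' Columns, in order: mz1, rt1, Intensity, mz2, rt2, Metabolite/Lipid,
#' fattyAcid, lipidClass, lipidForm, Accession, Theoretical_mz, Adduct,
#' Charge, Annotation, Score, dmz_ppm, Grades — mz1/rt1 are the reference
#' (unlabeled) values and mz2/rt2 the matched labeled feature. The lipid-only
#' columns are empty for metabolite entries. An 18th column `sample_id` is
#' appended because the driver concatenates all labeled samples into one
#' sheet.
#'
#' @param hits Hits data.frame from [flux_result()].
#' @param path Output CSV path.
#' @export
write_result_csv <- function(hits, path) {
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- data.frame(
    mz1 = hits$mz1, rt1 = hits$rt1, Intensity = hits$intensity,
    mz2 = hits$mz2, rt2 = hits$rt2,
    `Metabolite/Lipid` = blank(hits$name),
    fattyAcid = blank(hits$fatty_acids),
    lipidClass = blank(hits$lipid_class),
    lipidForm = blank(hits$formula),
    Accession = blank(hits$accession),
    Theoretical_mz = hits$theoretical_mz,
    Adduct = hits$adduct, Charge = hits$z, Annotation = hits$annotation,
    Score = hits$score, dmz_ppm = hits$dmz_ppm, Grades = hits$grade,
    sample_id = if (nrow(hits)) blank(hits$sample_id) else character(0),
    check.names = FALSE, stringsAsFactors = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
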