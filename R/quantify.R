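# Labeling quantification: per-molecule labeling ratios, normalized
# isotopomer distributions, and the lipid class / fatty-acid-chain /
# time-course aggregations.

#' Labeling ratio of one molecule in one labeled sample
#'
#' The fraction of the molecule's summed isotopomer intensity carried by
#' heavy isotopomers: sum of 13C isotopomer intensities divided by the sum of
#' 13C isotopomer intensities plus the 12C (M+0) intensity. When heavy
#' isotopomers are present but no M+0 was matched (a fully labeled pool can
#' extinguish M+0), the ratio is 1.0 and the result carries the attribute
#' `m0_missing = TRUE` rather than dropping the molecule.
#'
#' No natural-abundance correction is applied anywhere in this package: raw
#' M+1/M+2 intensities include the ~1.1% per carbon of naturally occurring
#' 13C.
#'
#' @param hits Hits data.frame rows of a single ref_id in a single sample
#'   (columns `n`, `intensity`).
#' @return A single fraction in \[0, 1\], with attribute `m0_missing`.
#' @export
labeling_ratio <- function(hits) {
  if (nrow(hits) == 0L) stop("no hits: labeling ratio is undefined, not 0")
  if (length(unique(hits$ref_id)) > 1L ||
      ("sample_id" %in% names(hits) && length(unique(hits$sample_id)) > 1L))
    stop("labeling_ratio() expects hits of one molecule in one sample")
  m0 <- sum(hits$intensity[hits$n == 0])
  heavy <- sum(hits$intensity[hits$n >= 1])
  m0_missing <- !any(hits$n == 0)
  r <- if (heavy + m0 > 0) heavy / (heavy + m0) else 0
  structure(r, m0_missing = m0_missing)
}

#' Normalized isotopomer distribution of one molecule in one sample
#'
#' Intensities of the matched isotopomers (including M+0) normalized to sum
#' to 1 — the mass isotopomer distribution restricted to matched components.
#'
#' @param hits Hits data.frame rows of a single ref_id in a single sample.
#' @return Named numeric vector, names are label counts `n`, values sum to 1.
#' @export
isotopomer_distribution <- function(hits) {
  if (nrow(hits) == 0L) stop("no hits: distribution is undefined")
  tot <- sum(hits$intensity)
  if (tot <= 0) stop("all matched intensities are zero")
  ord <- order(hits$n)
  stats::setNames(hits$intensity[ord] / tot, hits$n[ord])
}

#' Per-molecule labeling summaries over a result table
#'
#' Splits a multi-sample hits table by (ref_id, sample_id) and computes the
#' M+0 intensity, total heavy intensity, labeling ratio and number of matched
#' isotopomers for each group. Molecules with no hits in a sample are absent
#' (undefined), not zero-filled.
#'
#' @param hits Hits data.frame from [flux_result()] (needs `sample_id`).
#' @return data.frame: ref_id, sample_id, m0_intensity, heavy_intensity,
#'   labeling_ratio, n_isotopomers, m0_missing.
#' @export
labeling_summaries <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(ref_id = character(0), sample_id = character(0),
                      m0_intensity = numeric(0), heavy_intensity = numeric(0),
                      labeling_ratio = numeric(0), n_isotopomers = integer(0),
                      m0_missing = logical(0), stringsAsFactors = FALSE))
  groups <- split(hits, list(hits$ref_id, hits$sample_id), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- labeling_ratio(g)
    data.frame(ref_id = g$ref_id[1], sample_id = g$sample_id[1],
               m0_intensity = sum(g$intensity[g$n == 0]),
               heavy_intensity = sum(g$intensity[g$n >= 1]),
               labeling_ratio = as.numeric(r),
               n_isotopomers = nrow(g),
               m0_missing = attr(r, "m0_missing"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean labeling ratio per lipid class and sample
#'
#' Groups the per-molecule summaries of lipid references by their lipid class
#' and reports the unweighted mean labeling ratio and member count per
#' (class, sample). Classes with no summarized member are omitted.
#'
#' @param summaries Output of [labeling_summaries()].
#' @param refs Reference pool (provides `lipid_class`).
#' @return data.frame: lipid_class, sample_id, mean_ratio, n_lipids.
#' @export
aggregate_lipid_class <- function(summaries, refs) {
  cls <- refs$lipid_class[match(summaries$ref_id, refs$ref_id)]
  keep <- !is.na(cls) & nzchar(cls)
  s <- summaries[keep, , drop = FALSE]
  if (nrow(s) == 0L)
    return(data.frame(lipid_class = character(0), sample_id = character(0),
                      mean_ratio = numeric(0), n_lipids = integer(0)))
  cls <- cls[keep]
  agg <- stats::aggregate(s$labeling_ratio,
                          by = list(lipid_class = cls, sample_id = s$sample_id),
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(lipid_class = agg$lipid_class, sample_id = agg$sample_id,
                    mean_ratio = agg$x[, 1], n_lipids = as.integer(agg$x[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$lipid_class), , drop = FALSE]
}

#' Mean labeling ratio per fatty-acid chain and sample
#'
#' Lipids carrying the same fatty-acid chain length are summarized together:
#' each lipid contributes its labeling ratio once to every *distinct* chain
#' token it carries (PC(16:0/16:1) contributes to the 16:0 and the 16:1
#' groups; PC(16:0/16:0) contributes once to 16:0). References without
#' parsed chains are skipped; their count is reported in the attribute
#' `n_skipped`.
#'
#' @param summaries Output of [labeling_summaries()].
#' @param refs Reference pool (provides `fatty_acids`).
#' @return data.frame: fatty_acid, sample_id, mean_ratio, n_lipids; attribute
#'   `n_skipped`.
#' @export
aggregate_fatty_acid <- function(summaries, refs) {
  fa <- refs$fatty_acids[match(summaries$ref_id, refs$ref_id)]
  skipped <- sum(is.na(fa) | !nzchar(fa))
  keep <- !is.na(fa) & nzchar(fa)
  s <- summaries[keep, , drop = FALSE]
  empty <- data.frame(fatty_acid = character(0), sample_id = character(0),
                      mean_ratio = numeric(0), n_lipids = integer(0))
  if (nrow(s) == 0L) return(structure(empty, n_skipped = skipped))
  chains <- lapply(strsplit(fa[keep], "/", fixed = TRUE), unique)
  idx <- rep(seq_len(nrow(s)), lengths(chains))
  chain <- unlist(chains)
  agg <- stats::aggregate(s$labeling_ratio[idx],
                          by = list(fatty_acid = chain,
                                    sample_id = s$sample_id[idx]),
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(fatty_acid = agg$fatty_acid, sample_id = agg$sample_id,
                    mean_ratio = agg$x[, 1], n_lipids = as.integer(agg$x[, 2]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$fatty_acid), , drop = FALSE]
  structure(out, n_skipped = skipped)
}

#' Long-format time-course table of labeling ratios
#'
#' Joins per-molecule summaries with a sample design (condition, timepoint)
#' into the long layout used for time-course analysis. Missing (molecule,
#' sample) summaries stay absent; every sample present in the summaries must
#' be mapped, and a sample mapped twice is an error.
#'
#' @param summaries Output of [labeling_summaries()].
#' @param sample_map data.frame with columns `sample_id`, `condition`,
#'   `timepoint` (numeric, e.g. hours).
#' @return data.frame: ref_id, sample_id, condition, timepoint,
#'   labeling_ratio — ordered by molecule, condition, numeric timepoint.
#' @export
timecourse_table <- function(summaries, sample_map) {
  need <- c("sample_id", "condition", "timepoint")
  if (!all(need %in% names(sample_map)))
    stop("sample_map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sample_map$sample_id))
    stop("duplicate sample mapping for: ",
         paste(unique(sample_map$sample_id[duplicated(sample_map$sample_id)]),
               collapse = ", "))
  unmapped <- setdiff(unique(summaries$sample_id), sample_map$sample_id)
  if (length(unmapped))
    stop("unmapped sample(s): ", paste(unmapped, collapse = ", "))
  i <- match(summaries$sample_id, sample_map$sample_id)
  out <- data.frame(ref_id = summaries$ref_id,
                    sample_id = summaries$sample_id,
                    condition = sample_map$condition[i],
                    timepoint = sample_map$timepoint[i],
                    labeling_ratio = summaries$labeling_ratio,
                    stringsAsFactors = FALSE)
  out <- out[order(out$ref_id, out$condition, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare labeling ratios between a condition and a vehicle control
#'
#' Per molecule and timepoint, the log2 ratio and plain difference of the
#' labeling ratio under `condition` versus `reference_condition`. A small
#' pseudo-ratio guards the log against zero ratios. No statistical test is
#' attached; this is the effect-size layer for ranking and display.
#'
#' @param timecourse Output of [timecourse_table()].
#' @param condition Treatment condition label.
#' @param reference_condition Control condition label (default "vehicle").
#' @param pseudo Additive guard for the log ratio (default 1e-4).
#' @return data.frame: ref_id, timepoint, ratio_condition, ratio_reference,
#'   log2_fc, difference.
#' @export
compare_conditions <- function(timecourse, condition,
                               reference_condition = "vehicle",
                               pseudo = 1e-4) {
  a <- timecourse[timecourse$condition == condition, , drop = FALSE]
  b <- timecourse[timecourse$condition == reference_condition, , drop = FALSE]
  key <- function(d) paste(d$ref_id, d$timepoint, sep = "\r")
  i <- match(key(a), key(b))
  ok <- !is.na(i)
  a <- a[ok, , drop = FALSE]; i <- i[ok]
  data.frame(ref_id = a$ref_id, timepoint = a$timepoint,
             ratio_condition = a$labeling_ratio,
             ratio_reference = b$labeling_ratio[i],
             log2_fc = log2((a$labeling_ratio + pseudo) /
                              (b$labeling_ratio[i] + pseudo)),
             difference = a$labeling_ratio - b$labeling_ratio[i],
             stringsAsFactors = FALSE)
}

#' Write the per-molecule, per-class, per-chain and time-course summaries
#'
#' @param summaries Output of [labeling_summaries()].
#' @param refs Reference pool.
#' @param dir Output directory (created if missing).
#' @param sample_map Optional sample design for the time-course table.
#' @return Invisibly, the paths written.
#' @export
write_summary_csvs <- function(summaries, refs, dir, sample_map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "labeling_summary.csv")
  utils::write.csv(summaries, p, row.names = FALSE); paths <- c(paths, p)
  cls <- aggregate_lipid_class(summaries, refs)
  if (nrow(cls)) {
    p <- file.path(dir, "lipid_class_summary.csv")
    utils::write.csv(cls, p, row.names = FALSE); paths <- c(paths, p)
  }
  fa <- aggregate_fatty_acid(summaries, refs)
  if (nrow(fa)) {
    p <- file.path(dir, "fatty_acid_summary.csv")
    utils::write.csv(fa, p, row.names = FALSE); paths <- c(paths, p)
  }
  if (!is.null(sample_map)) {
    tc <- timecourse_table(summaries, sample_map)
    p <- file.path(dir, "timecourse.csv")
    utils::write.csv(tc, p, row.names = FALSE); paths <- c(paths, p)
  }
  invisible(paths)
}
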