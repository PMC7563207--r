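# MS1 spectra input and feature (chromatographic peak) detection: the
# replaceable upstream stage that turns centroided full-scan data into the
# per-sample peak lists the isotopomer search consumes.

#' Peak-picking parameters
#'
#' Defaults follow common high-resolution Orbitrap settings: centroids within
#' 4 ppm cluster into one m/z trace, a peak needs at least 3 scans, a
#' signal-to-noise of 3 and signal-to-baseline of 2, and apex intensities
#' between 1e4 and 1e7 counts are kept.
#'
#' Legacy parameters of EIC-density peak pickers (`dmzgap`, `drtdens`,
#' `recurs`, `weight`, `drtfill`, `drttotal`, `ended`) are accepted through
#' `...` for configuration provenance but have no analogue in this trace
#' builder; they are ignored with a notice.
#'
#' @param mz_cluster_ppm m/z clustering tolerance for trace building, ppm
#'   (default 4).
#' @param min_scans Minimum scans in a peak run (default 3).
#' @param sn_min Minimum apex / trace-noise ratio (default 3).
#' @param sb_min Minimum apex / local-baseline ratio (default 2).
#' @param min_intensity,max_intensity Apex intensity window kept
#'   (defaults 1e4 and 1e7).
#' @param rt_gap_s Trace broken at RT gaps larger than this, seconds
#'   (default 300).
#' @param rt_peak_window_s Half-window around the apex used for the local
#'   baseline, seconds (default 20).
#' @param intensity_type Report the apex intensity (default) or the summed
#'   area of the peak run.
#' @param ... Ignored legacy parameters (noticed by name).
#' @return A list of class `peak_picking_params`.
#' @export
peak_picking_params <- function(mz_cluster_ppm = 4, min_scans = 3L,
                                sn_min = 3, sb_min = 2,
                                min_intensity = 1e4, max_intensity = 1e7,
                                rt_gap_s = 300, rt_peak_window_s = 20,
                                intensity_type = c("apex", "area"), ...) {
  intensity_type <- match.arg(intensity_type)
  extra <- list(...)
  if (length(extra))
    message("ignoring peak-picking parameter(s) with no analogue here: ",
            paste(names(extra), collapse = ", "))
  stopifnot(mz_cluster_ppm > 0, min_scans >= 1, sn_min > 0, sb_min > 0,
            min_intensity > 0, max_intensity > min_intensity,
            rt_gap_s > 0, rt_peak_window_s > 0)
  structure(list(mz_cluster_ppm = mz_cluster_ppm,
                 min_scans = as.integer(min_scans), sn_min = sn_min,
                 sb_min = sb_min, min_intensity = min_intensity,
                 max_intensity = max_intensity, rt_gap_s = rt_gap_s,
                 rt_peak_window_s = rt_peak_window_s,
                 intensity_type = intensity_type),
            class = "peak_picking_params")
}

#' Read MS1 spectra of one polarity from an mzML/mzXML file
#'
#' Returns only MS1 scans of the requested polarity, in ascending retention
#' time. Requires the Bioconductor package mzR. Profile-mode spectra trigger
#' a warning and are reduced to local intensity maxima (naive centroiding).
#'
#' @param path Path to an mzML or mzXML file (centroided MS1 expected).
#' @param polarity `"positive"` or `"negative"`.
#' @return List of spectra; each is a list with `rt` (seconds), `polarity`,
#'   `ms_level`, and `peaks` — a 2-column matrix (mz, intensity) sorted by
#'   m/z.
#' @export
read_ms1 <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML/mzXML requires the 'mzR' package; ",
         "alternatively supply a pre-picked feature CSV")
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  if (is.null(hdr) || nrow(hdr) == 0L) stop("no spectra in ", sQuote(path))
  if (all(hdr$polarity < 0))
    stop("file carries no polarity metadata; split the file by polarity ",
         "upstream or supply feature CSVs with an explicit polarity column")
  want_pol <- if (polarity == "positive") 1L else 0L
  idx <- which(hdr$msLevel == 1L & hdr$polarity == want_pol)
  if (!length(idx)) return(list())
  idx <- idx[order(hdr$retentionTime[idx])]
  if (!is.null(hdr$centroided) && any(!hdr$centroided[idx], na.rm = TRUE))
    warning("profile-mode spectra detected; applying naive local-maxima centroiding")
  lapply(idx, function(i) {
    pk <- mzR::peaks(ms, i)
    if (!is.null(hdr$centroided) && isFALSE(hdr$centroided[i]))
      pk <- .naive_centroid(pk)
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    list(rt = hdr$retentionTime[i], polarity = polarity,
         ms_level = 1L, peaks = pk)
  })
}

# keep local maxima of a profile trace
.naive_centroid <- function(pk) {
  if (nrow(pk) < 3L) return(pk)
  y <- pk[, 2]
  keep <- c(FALSE, y[2:(length(y) - 1)] >= y[1:(length(y) - 2)] &
              y[2:(length(y) - 1)] > y[3:length(y)], FALSE) & y > 0
  pk[keep, , drop = FALSE]
}

#' Detect MS1 features from centroided spectra
#'
#' Two stages. (1) Trace building: all centroids are pooled and single-linkage
#' clustered along m/z — a gap between m/z-adjacent centroids larger than
#' `mz_cluster_ppm` starts a new cluster — then each cluster is split at RT
#' gaps larger than `rt_gap_s`. (2) Peak detection within each trace: local
#' maxima are expanded to monotone runs; a run qualifies as a peak if it
#' spans at least `min_scans` points and its apex is at least `sn_min` times
#' the trace noise (median of the trace's non-peak points, floored at 1) and
#' `sb_min` times the local baseline (median of non-peak points within
#' `rt_peak_window_s` of the apex). Apex intensities outside
#' `[min_intensity, max_intensity]` are dropped. One feature per peak, with
#' the intensity-weighted mean m/z and the apex RT.
#'
#' Isotopomer envelopes are deliberately not de-isotoped: every isotopologue
#' must survive as its own feature for the downstream search.
#'
#' @param spectra List of spectra from [read_ms1()] (one polarity).
#' @param params A [peak_picking_params()] object.
#' @param sample_id Sample label stamped on the features.
#' @return Feature data.frame: `sample_id`, `polarity`, `mz`, `rt` (seconds),
#'   `intensity`.
#' @export
pick_features <- function(spectra, params = peak_picking_params(),
                          sample_id = "sample") {
  stopifnot(inherits(params, "peak_picking_params"))
  if (length(spectra) == 0L) return(.empty_features())
  polarity <- spectra[[1]]$polarity
  cent <- do.call(rbind, lapply(spectra, function(s) {
    if (is.null(s$peaks) || nrow(s$peaks) == 0L) return(NULL)
    cbind(mz = s$peaks[, 1], rt = s$rt, int = s$peaks[, 2])
  }))
  if (is.null(cent) || nrow(cent) == 0L) return(.empty_features())

  ord <- order(cent[, "mz"])
  cent <- cent[ord, , drop = FALSE]
  mz <- cent[, "mz"]
  # single-linkage along m/z: break where the relative gap exceeds the tol
  gap <- diff(mz) / mz[-length(mz)] * 1e6
  cluster <- cumsum(c(1L, as.integer(gap > params$mz_cluster_ppm)))

  feats <- list()
  for (cl in split(seq_along(cluster), cluster)) {
    tr <- cent[cl, , drop = FALSE]
    tr <- tr[order(tr[, "rt"]), , drop = FALSE]
    # split at RT gaps
    rtgap <- diff(tr[, "rt"])
    seg <- cumsum(c(1L, as.integer(rtgap > params$rt_gap_s)))
    for (sg in split(seq_len(nrow(tr)), seg)) {
      f <- .trace_peaks(tr[sg, , drop = FALSE], params)
      if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    }
  }
  if (!length(feats)) return(.empty_features())
  out <- do.call(rbind, feats)
  out <- data.frame(sample_id = sample_id, polarity = polarity,
                    mz = out[, "mz"], rt = out[, "rt"],
                    intensity = out[, "intensity"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mz, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_features <- function() {
  data.frame(sample_id = character(0), polarity = character(0),
             mz = numeric(0), rt = numeric(0), intensity = numeric(0),
             stringsAsFactors = FALSE)
}

# peak detection within a single (rt-sorted) trace; returns a matrix of
# (mz, rt, intensity) rows or NULL
.trace_peaks <- function(tr, params) {
  npt <- nrow(tr)
  int <- tr[, "int"]
  assigned <- logical(npt)
  runs <- list()
  repeat {
    cand <- which(!assigned)
    if (!length(cand)) break
    apex <- cand[which.max(int[cand])]
    if (int[apex] < params$min_intensity) break  # remainder is sub-floor noise
    lo <- apex
    while (lo > 1L && !assigned[lo - 1L] && int[lo - 1L] <= int[lo]) lo <- lo - 1L
    hi <- apex
    while (hi < npt && !assigned[hi + 1L] && int[hi + 1L] <= int[hi]) hi <- hi + 1L
    assigned[lo:hi] <- TRUE
    runs[[length(runs) + 1L]] <- list(lo = lo, hi = hi, apex = apex)
  }
  if (!length(runs)) return(NULL)
  noise <- stats::median(int[!assigned])
  noise <- max(noise, 1, na.rm = TRUE)
  out <- NULL
  for (r in runs) {
    len <- r$hi - r$lo + 1L
    if (len < params$min_scans) next
    a <- int[r$apex]
    if (a < params$min_intensity || a > params$max_intensity) next
    if (a < params$sn_min * noise) next
    near <- which(!assigned &
                    abs(tr[, "rt"] - tr[r$apex, "rt"]) <= params$rt_peak_window_s)
    baseline <- if (length(near)) max(stats::median(int[near]), 1) else noise
    if (a < params$sb_min * baseline) next
    idx <- r$lo:r$hi
    out <- rbind(out, c(
      mz = unname(stats::weighted.mean(tr[idx, "mz"], int[idx])),
      rt = unname(tr[r$apex, "rt"]),
      intensity = unname(if (params$intensity_type == "area")
        sum(int[idx]) else a)))
  }
  out
}

#' Read / write a pre-picked feature list CSV
#'
#' The first-class bypass of peak picking: a delimited table with the header
#' `sample_id, polarity, mz, rt_s, intensity`. RT is in seconds.
#'
#' @param path CSV path.
#' @return Feature data.frame (`rt` column in seconds).
#' @export
read_feature_csv <- function(path) {
  df <- .read_delim(path)
  need <- c("sample_id", "polarity", "mz", "rt_s", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("feature CSV ", sQuote(path), " missing column(s): ",
         paste(missing, collapse = ", "))
  data.frame(sample_id = as.character(df$sample_id),
             polarity = .check_polarity(df$polarity),
             mz = as.numeric(df$mz), rt = as.numeric(df$rt_s),
             intensity = as.numeric(df$intensity),
             stringsAsFactors = FALSE)
}

#' @rdname read_feature_csv
#' @param features Feature data.frame with columns `sample_id`, `polarity`,
#'   `mz`, `rt`, `intensity`.
#' @export
write_feature_csv <- function(features, path) {
  out <- data.frame(sample_id = features$sample_id,
                    polarity = features$polarity, mz = features$mz,
                    rt_s = features$rt, intensity = features$intensity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write spectra to a minimal mzML file
#'
#' A small writer covering what [read_ms1()] needs back: centroided spectra
#' with MS level, scan polarity and retention time, peaks as uncompressed
#' 64-bit little-endian base64 arrays. Intended for fixtures and end-to-end
#' tests, not as a general-purpose exporter.
#'
#' @param spectra List of spectra (`rt`, `polarity`, `ms_level`, `peaks`).
#' @param path Output path.
#' @export
write_mzml <- function(spectra, path) {
  enc64 <- function(x) {
    jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                  endian = "little"))
  }
  n <- length(spectra)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <cvList count="1">')
  w('    <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>')
  w('  </cvList>')
  w('  <fileDescription><fileContent>')
  w('    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>')
  w('    <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
  w('  </fileContent></fileDescription>')
  w('  <softwareList count="1"><software id="sw" version="0"/></softwareList>')
  w('  <instrumentConfigurationList count="1"><instrumentConfiguration id="ic"/></instrumentConfigurationList>')
  w('  <dataProcessingList count="1"><dataProcessing id="dp">')
  w('    <processingMethod order="1" softwareRef="sw">')
  w('      <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>')
  w('    </processingMethod></dataProcessing></dataProcessingList>')
  w('  <run id="run" defaultInstrumentConfigurationRef="ic">')
  w('    <spectrumList count="', n, '" defaultDataProcessingRef="dp">')
  for (i in seq_len(n)) {
    s <- spectra[[i]]
    pk <- s$peaks
    npk <- if (is.null(pk)) 0L else nrow(pk)
    pol_acc <- if (s$polarity == "positive") "MS:1000130" else "MS:1000129"
    pol_name <- if (s$polarity == "positive") "positive scan" else "negative scan"
    b_mz <- if (npk) enc64(pk[, 1]) else ""
    b_int <- if (npk) enc64(pk[, 2]) else ""
    w('      <spectrum index="', i - 1L, '" id="scan=', i,
      '" defaultArrayLength="', npk, '">')
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="',
      s$ms_level, '"/>')
    w('        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>')
    w('        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
    w('        <cvParam cvRef="MS" accession="', pol_acc, '" name="', pol_name, '" value=""/>')
    w('        <scanList count="1">')
    w('          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>')
    w('          <scan>')
    w('            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      format(s$rt, digits = 12), '" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>')
    w('          </scan>')
    w('        </scanList>')
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="', nchar(b_mz), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
    w('            <binary>', b_mz, '</binary>')
    w('          </binaryDataArray>')
    w('          <binaryDataArray encodedLength="', nchar(b_int), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
    w('            <binary>', b_int, '</binary>')
    w('          </binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}
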