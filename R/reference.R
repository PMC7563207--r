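# Import of unlabeled-sample identification exports, pooling into the
# reference list, and expansion to theoretical isotopomer candidates.

.REF_COLUMNS <- c("ref_id", "name", "accession", "mode", "mz", "rt",
                  "polarity", "adduct", "z", "formula", "lipid_class",
                  "fatty_acids")

.empty_refs <- function() {
  df <- data.frame(
    ref_id = character(0), name = character(0), accession = character(0),
    mode = character(0), mz = numeric(0), rt = numeric(0),
    polarity = character(0), adduct = character(0), z = integer(0),
    formula = character(0), lipid_class = character(0),
    fatty_acids = character(0), stringsAsFactors = FALSE)
  df
}

.check_polarity <- function(polarity) {
  p <- tolower(trimws(polarity))
  p[p %in% c("pos", "+", "p")] <- "positive"
  p[p %in% c("neg", "-", "n")] <- "negative"
  bad <- !p %in% c("positive", "negative")
  if (any(bad))
    stop("invalid polarity value(s): ", paste(unique(polarity[bad]), collapse = ", "))
  p
}

# Case-insensitive column lookup with aliases; returns values or NULL.
.col <- function(df, aliases) {
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(df))))
  for (a in aliases) {
    i <- match(gsub("[^a-z0-9]", "", tolower(a)), nm)
    if (!is.na(i)) return(df[[i]])
  }
  NULL
}

#' Load a metabolite identification export from unlabeled samples
#'
#' Reads a delimited identification table (the dialect written by MS1/MS2
#' identification software for polar metabolites) into reference entries.
#' Required columns (case-insensitive): `name`, `mz`, `rt`, `polarity`.
#' Optional: `accession`, `formula`, `adduct`, `z`, `intensity`. When no
#' adduct column is present the default protonation adducts are assumed:
#' `+H` in positive mode, `-H` in negative mode, z = 1.
#'
#' Duplicate rows on (name, adduct, polarity) are collapsed to the
#' highest-intensity row (first row when no intensity column), with a message.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @param adducts Adduct table, see [default_adducts()].
#' @return A reference data.frame (one row per entry, `mode = "metabolite"`).
#' @export
load_metabolite_export <- function(path, adducts = default_adducts()) {
  df <- .read_delim(path)
  if (nrow(df) == 0L) return(.empty_refs())
  need <- c("name", "mz", "rt", "polarity")
  got <- vapply(need, function(a) !is.null(.col(df, a)), logical(1))
  if (!all(got))
    stop("metabolite export ", sQuote(path), " missing required column(s): ",
         paste(need[!got], collapse = ", "))
  polarity <- .check_polarity(.col(df, "polarity"))
  adduct <- .col(df, "adduct")
  if (is.null(adduct)) adduct <- ifelse(polarity == "positive", "+H", "-H")
  adduct <- .normalize_adduct_name(adduct)
  z <- .col(df, list("z", "charge"))
  z <- if (is.null(z)) rep(1L, nrow(df)) else abs(as.integer(z))
  formula <- .col(df, "formula")
  if (is.null(formula)) formula <- rep(NA_character_, nrow(df))
  accession <- .col(df, "accession")
  if (is.null(accession)) accession <- rep(NA_character_, nrow(df))
  intensity <- .col(df, "intensity")

  out <- data.frame(
    ref_id = NA_character_,
    name = as.character(.col(df, "name")),
    accession = as.character(accession),
    mode = "metabolite",
    mz = as.numeric(.col(df, "mz")),
    rt = as.numeric(.col(df, list("rt", "rt_s"))),
    polarity = polarity,
    adduct = adduct,
    z = z,
    formula = as.character(formula),
    lipid_class = NA_character_,
    fatty_acids = NA_character_,
    stringsAsFactors = FALSE)
  if (anyNA(out$mz) || anyNA(out$rt))
    stop("metabolite export ", sQuote(path), " has non-numeric mz/rt values")

  key <- paste(out$name, out$adduct, out$polarity, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- if (!is.null(intensity))
      order(key, -as.numeric(intensity)) else order(seq_len(nrow(out)))
    out <- out[ord, , drop = FALSE]
    dup <- duplicated(paste(out$name, out$adduct, out$polarity, sep = "\r"))
    message(sum(dup), " duplicate metabolite row(s) collapsed on (name, adduct, polarity)")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Load a lipid identification export, applying grade and m-score filters
#'
#' Reads a LipidSearch-style delimited table. Expected columns
#' (case-insensitive, aliases accepted): `LipidID`, `Class`, `Formula`,
#' `Grade`, `m-score`, `CalcMz` or `ObsMz`, `Rt`, `Ion` (adduct). Rows are
#' kept iff the identification grade is A up to `grade_max` and the m-score
#' is at least `mscore_min` — the defaults (grade A-C, m-score >= 5)
#' mirror common acceptance thresholds for lipid identifications. Fatty-acid
#' chain tokens are parsed from the LipidID, e.g. `PC(16:0/18:1)` carries
#' chains `16:0` and `18:1`.
#'
#' @param path Path to the export file.
#' @param grade_max Worst accepted grade letter (default `"C"`).
#' @param mscore_min Minimum accepted m-score (default `5.0`).
#' @param adducts Adduct table for polarity lookup of the `Ion` column.
#' @return A reference data.frame (`mode = "lipid"`). Rows with an
#'   unparseable grade are dropped with a warning.
#' @export
load_lipid_export <- function(path, grade_max = "C", mscore_min = 5.0,
                              adducts = default_adducts()) {
  df <- .read_delim(path)
  if (nrow(df) == 0L) return(.empty_refs())
  lipid_id <- .col(df, list("LipidID", "LipidIon", "name"))
  if (is.null(lipid_id)) stop("lipid export ", sQuote(path), " missing LipidID column")
  grade <- .col(df, "Grade")
  mscore <- .col(df, list("m-score", "mscore", "m.score"))
  mz <- .col(df, list("CalcMz", "ObsMz", "mz"))
  rt <- .col(df, list("Rt", "rt"))
  ion <- .col(df, list("Ion", "adduct"))
  for (nm in c("grade", "mscore", "mz", "rt", "ion"))
    if (is.null(get(nm)))
      stop("lipid export ", sQuote(path), " missing required column: ", nm)

  grade <- toupper(trimws(as.character(grade)))
  ok_grade <- grepl("^[A-Z]$", grade)
  if (any(!ok_grade)) {
    warning(sum(!ok_grade), " lipid row(s) dropped: unparseable grade")
  }
  accepted <- LETTERS[seq_len(match(toupper(grade_max), LETTERS))]
  keep <- ok_grade & grade %in% accepted & as.numeric(mscore) >= mscore_min
  keep[is.na(keep)] <- FALSE
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(.empty_refs())
  lipid_id <- lipid_id[keep]; mz <- mz[keep]; rt <- rt[keep]; ion <- ion[keep]

  adduct <- .normalize_adduct_name(as.character(ion))
  pol <- vapply(adduct, function(a) get_adduct(a, adducts)$polarity, character(1))
  zz <- vapply(adduct, function(a) abs(get_adduct(a, adducts)$z), integer(1))
  klass <- .col(df, "Class")
  if (is.null(klass)) klass <- sub("\\(.*$", "", lipid_id)
  fa <- vapply(as.character(lipid_id), .parse_chain_tokens, character(1))
  formula <- .col(df, "Formula")
  if (is.null(formula)) formula <- rep(NA_character_, nrow(df))

  out <- data.frame(
    ref_id = NA_character_,
    name = as.character(lipid_id),
    accession = NA_character_,
    mode = "lipid",
    mz = as.numeric(mz),
    rt = as.numeric(rt),
    polarity = pol,
    adduct = adduct,
    z = zz,
    formula = gsub("[[:space:]]+", "", as.character(formula)),
    lipid_class = as.character(klass),
    fatty_acids = fa,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# "PC(16:0/18:1)" -> "16:0/18:1" (distinct tokens preserved in order)
.parse_chain_tokens <- function(lipid_id) {
  m <- gregexpr("[0-9]+:[0-9]+", lipid_id)[[1]]
  if (m[1] == -1L) return(NA_character_)
  paste(regmatches(lipid_id, list(m))[[1]], collapse = "/")
}

#' Pool identification lists into one reference
#'
#' Takes the union of one or more reference lists, deduplicating on
#' (name, adduct, polarity). A molecule seen in several lists (typical when
#' multiple unlabeled runs are pooled to widen coverage) keeps the median m/z
#' and median retention time over its occurrences. Reference ids are then
#' assigned stably, sorted by polarity and m/z.
#'
#' @param ... Reference data.frames as returned by the loaders.
#' @return A pooled reference data.frame with `ref_id` filled in.
#' @export
pool_references <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) && !is.data.frame(lists[[1]]))
    lists <- lists[[1]]
  if (length(lists) == 0L) stop("at least one reference list required")
  all <- do.call(rbind, lists)
  if (nrow(all) == 0L) return(.empty_refs())
  key <- paste(all$name, all$adduct, all$polarity, sep = "\r")
  groups <- split(seq_len(nrow(all)), key)
  pooled <- do.call(rbind, lapply(groups, function(idx) {
    r <- all[idx[1], , drop = FALSE]
    r$mz <- stats::median(all$mz[idx])
    r$rt <- stats::median(all$rt[idx])
    # fill optional fields from any occurrence that has them
    for (f in c("accession", "formula", "lipid_class", "fatty_acids")) {
      v <- all[[f]][idx]
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v)) r[[f]] <- v[1]
    }
    r
  }))
  ord <- order(pooled$polarity, pooled$mz, pooled$name)
  pooled <- pooled[ord, , drop = FALSE]
  pooled$ref_id <- sprintf("REF%04d", seq_len(nrow(pooled)))
  rownames(pooled) <- NULL
  pooled
}

#' Expand references to theoretical isotopomer candidates
#'
#' For every reference entry, generates candidates M+0 ... M+N where N is the
#' per-mode isotopomer cap: 10 for polar metabolites and 40 for lipids,
#' reflecting the relative carbon counts of the two molecule types. With
#' `cap_by_formula = TRUE` (the default) the cap is further reduced to the
#' formula's carbon count when a formula is known — a molecule cannot carry
#' more 13C labels than it has carbons. M+0 is generated as a candidate so
#' that the unlabeled isotopomer is located in the labeled run, which the
#' labeling-ratio denominator requires.
#'
#' @param refs Pooled reference data.frame.
#' @param n_max_metabolite Isotopomer cap for metabolite entries (default 10).
#' @param n_max_lipid Isotopomer cap for lipid entries (default 40).
#' @param cap_by_formula Reduce the cap to the carbon count when a formula is
#'   present (default TRUE).
#' @return data.frame with columns `ref_id`, `n`, `theoretical_mz`,
#'   `annotation` (`"M+0"`, `"M+1"`, ...).
#' @export
build_candidates <- function(refs, n_max_metabolite = 10L, n_max_lipid = 40L,
                             cap_by_formula = TRUE) {
  if (nrow(refs) == 0L) stop("empty reference list")
  caps <- ifelse(refs$mode == "lipid", n_max_lipid, n_max_metabolite)
  if (cap_by_formula) {
    nc <- vapply(refs$formula, function(f)
      if (is.na(f) || !nzchar(f)) NA_integer_ else carbon_count(f), integer(1))
    caps <- ifelse(!is.na(nc), pmin(caps, nc), caps)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(refs)), function(i) {
    n <- 0:caps[i]
    data.frame(
      ref_id = refs$ref_id[i],
      n = n,
      theoretical_mz = isotopomer_mz(refs$mz[i], n, refs$z[i]),
      annotation = paste0("M+", n),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read the pooled reference as CSV
#'
#' Round-trips the reference pool through a documented flat CSV (one row per
#' entry, columns as in the pooled data.frame).
#'
#' @param refs Reference data.frame.
#' @param path Output path.
#' @export
write_reference_csv <- function(refs, path) {
  utils::write.csv(refs[, .REF_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(.REF_COLUMNS, names(df))
  if (length(missing))
    stop("reference CSV missing column(s): ", paste(missing, collapse = ", "))
  df$z <- as.integer(df$z)
  df
}

# Delimiter-sniffing reader for vendor-style exports (comma or tab).
.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty file: ", sQuote(path))
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}
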