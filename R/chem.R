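# Chemical-formula arithmetic underpinning the isotopomer search: monoisotopic
# masses, adduct ion m/z, and the 13C isotopomer spacing.

#' Mass difference added per incorporated 13C label, in Da
#'
#' The monoisotopic mass difference between 13C and 12C. Each heavy isotopomer
#' M+n of a singly charged ion sits `n * DELTA_13C` above the M+0 ion; for
#' charge magnitude z the spacing shrinks to `DELTA_13C / z`.
#'
#' @export
DELTA_13C <- 1.0033548378

# Monoisotopic (most-abundant isotope) atomic masses, IUPAC values, Da.
# 12C is exactly 12 by definition.
.ATOMIC_MASSES <- c(
  C  = 12,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  S  = 31.9720707,
  Na = 22.9897693,
  K  = 38.9637065,
  Cl = 34.9688527,
  F  = 18.9984032,
  Br = 78.9183376,
  I  = 126.9044719,
  Si = 27.9769265,
  Se = 79.9165218,
  B  = 11.0093054,
  Fe = 55.9349375,
  Mg = 23.9850417,
  Ca = 39.9625909,
  Zn = 63.9291422,
  Li = 7.0160034,
  D  = 2.0141018
)

#' Parse a Hill-notation chemical formula
#'
#' Reads an element-count string such as `"C40H80NO8P"` into a named integer
#' vector of element counts. Parsing is case-sensitive on element symbols
#' (`Co` is cobalt-like two-letter token, `CO` is carbon + oxygen); an implicit
#' count of 1 is allowed. Whitespace is stripped, so LipidSearch-style
#' formulas like `"C40 H80 N O8 P"` are accepted. Parentheses and isotope
#' prefixes are not supported.
#'
#' @param text A single formula string.
#' @return A named integer vector of class `chem_formula`; names are element
#'   symbols, values are counts (all >= 1).
#' @examples
#' parse_formula("C40H80NO8P")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single formula string")
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) stop("empty formula string")
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s))
    stop("malformed formula: ", sQuote(text))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  counts <- integer(0)
  for (tok in tokens) {
    elem <- sub("[0-9]*$", "", tok)
    ndig <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(ndig)) as.integer(ndig) else 1L
    if (!elem %in% names(.ATOMIC_MASSES))
      stop("unknown element ", sQuote(elem), " in formula ", sQuote(text))
    if (n < 1L)
      stop("zero count for element ", sQuote(elem), " in formula ", sQuote(text))
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
  }
  structure(counts, class = "chem_formula")
}

#' Number of carbon atoms in a formula
#'
#' @param formula A `chem_formula` or formula string. `NA` or empty input
#'   returns `NA_integer_`.
#' @return Integer carbon count (0 if the formula has no carbon).
#' @export
carbon_count <- function(formula) {
  if (length(formula) == 1L && (is.na(formula) || identical(formula, "")))
    return(NA_integer_)
  f <- if (inherits(formula, "chem_formula")) formula else parse_formula(formula)
  if ("C" %in% names(f)) as.integer(f[["C"]]) else 0L
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of count x monoisotopic atomic mass over all elements, using the
#' most-abundant-isotope masses tabulated in the package.
#'
#' @param formula A `chem_formula` or formula string.
#' @return Neutral mass in Da.
#' @examples
#' monoisotopic_mass("H2O")          # 18.010565
#' monoisotopic_mass("C40H80NO8P")   # 733.5622, dipalmitoyl PC
#' @export
monoisotopic_mass <- function(formula) {
  f <- if (inherits(formula, "chem_formula")) formula else parse_formula(formula)
  if (length(f) == 0L) stop("empty formula")
  sum(unclass(f) * .ATOMIC_MASSES[names(f)])
}

#' Built-in electrospray adduct table
#'
#' Mass deltas are atom-level sums ignoring the electron mass (error below
#' 0.001 Th at z = 1, negligible at the 2-decimal precision the search
#' operates at). The sign of `z` is consistent with `polarity`. Additional
#' adducts can be appended through the run configuration.
#'
#' @return A data.frame with columns `name`, `mass_delta` (Da), `z`
#'   (signed charge), `polarity`.
#' @export
default_adducts <- function() {
  data.frame(
    name = c("+H", "-H", "+Na", "+NH4", "+HCOO", "-H2O-H"),
    mass_delta = c(
      1.0078250,    # +H
      -1.0078250,   # -H
      22.9897693,   # +Na
      18.0343740,   # +NH4 = N + 4H
      44.9976542,   # +HCOO formate = C + H + 2O
      -19.0183896   # -H2O-H = -(H2O + H)
    ),
    z = c(1L, -1L, 1L, 1L, -1L, -1L),
    polarity = c("positive", "negative", "positive", "positive",
                 "negative", "negative"),
    stringsAsFactors = FALSE
  )
}

# Unicode minus signs from vendor exports normalised to ASCII hyphen.
.normalize_adduct_name <- function(name) {
  gsub("[−‐–]", "-", trimws(name))
}

#' Look up an adduct by name
#'
#' @param name Adduct token, e.g. `"+H"`, `"-H"`, `"+HCOO"`. Unicode minus
#'   signs are normalised.
#' @param adducts Adduct table, defaults to [default_adducts()].
#' @return A one-row data.frame (name, mass_delta, z, polarity).
#' @export
get_adduct <- function(name, adducts = default_adducts()) {
  nm <- .normalize_adduct_name(name)
  i <- match(nm, adducts$name)
  if (is.na(i))
    stop("unknown adduct ", sQuote(name), "; known: ",
         paste(adducts$name, collapse = ", "))
  adducts[i, , drop = FALSE]
}

#' Ion m/z of a neutral molecule under an adduct
#'
#' `(neutral_mass + mass_delta) / |z|`. With the formate adduct (z = -1) the
#' dipalmitoyl-phosphatidylcholine neutral C40H80NO8P gives m/z 778.56 and
#' PC(16:0/18:1) C42H82NO8P gives 804.58 at 2-decimal rounding.
#'
#' @param neutral_mass Neutral monoisotopic mass, Da (> 0).
#' @param adduct Adduct name or a row from the adduct table.
#' @param adducts Adduct table used when `adduct` is a name.
#' @return m/z in Th.
#' @export
ion_mz <- function(neutral_mass, adduct, adducts = default_adducts()) {
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0))
    stop("'neutral_mass' must be positive")
  a <- if (is.character(adduct)) get_adduct(adduct, adducts) else as.list(adduct)
  if (a$z == 0L) stop("adduct charge z must be nonzero")
  (neutral_mass + a$mass_delta) / abs(a$z)
}

#' Theoretical m/z of the M+n 13C isotopomer
#'
#' Adds `n` times the 13C-12C mass difference, divided by the charge
#' magnitude, to the M+0 ion m/z: `base_mz + n * 1.0033548378 / z`.
#' Vectorised over `n`.
#'
#' @param base_mz M+0 ion m/z, Th.
#' @param n Number of 13C labels (>= 0).
#' @param z Charge magnitude (>= 1).
#' @return m/z in Th, strictly increasing in `n`.
#' @examples
#' isotopomer_mz(778.5598, 0:3)
#' @export
isotopomer_mz <- function(base_mz, n, z = 1L) {
  if (any(n < 0)) stop("label count 'n' must be non-negative")
  if (any(z < 1)) stop("charge magnitude 'z' must be >= 1")
  base_mz + n * DELTA_13C / z
}
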