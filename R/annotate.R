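# Lipid annotation: molecular formulas, monoisotopic masses, adduct m/z and
# matching of detected peaks against a candidate table.

# Most-abundant-isotope masses (Da), CODATA/AME2020 values.
.isotope_mass <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  Mg = 23.9850417,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.9637064864,
  Ca = 39.96259098,
  Fe = 55.9349375,
  Li = 7.01600455,
  F  = 18.99840322,
  Si = 27.9769265325,
  Zn = 63.9291422,
  Cu = 62.9295975,
  Se = 79.9165213,
  Br = 78.9183371,
  I  = 126.904473,
  B  = 11.0093054
)

.electron_mass <- 0.000548579909

#' Parse a molecular formula in Hill-like notation
#'
#' Accepts formulas such as `"C23H45NO4"` or `"C34H32FeN4O4"`: element symbols
#' (one capital letter optionally followed by one lowercase letter) each
#' followed by an optional count. Repeated symbols accumulate.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C23H45NO4")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    msi_stop("cannot parse formula: '", text, "'", class = "msi3d_parse_error")
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, names(.isotope_mass))
  if (length(unknown)) {
    msi_stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
             class = "msi3d_parse_error")
  }
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of an element-count vector
#'
#' Sums most-abundant-isotope masses; the empty composition has mass 0.
#'
#' @param counts Named vector of element counts (as from [parse_formula()]),
#'   or a formula string.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) {
    if (length(counts) == 0L) return(0)
    counts <- parse_formula(counts)
  }
  if (length(counts) == 0L) return(0)
  if (any(counts < 0)) msi_stop("element counts must be non-negative")
  unknown <- setdiff(names(counts), names(.isotope_mass))
  if (length(unknown)) {
    msi_stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.isotope_mass[names(counts)] * as.numeric(counts))
}

.supported_adducts <- function() c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+Li]+", "[M]+.")

#' Theoretical m/z of a singly charged positive adduct
#'
#' For `[M+X]+` the cation mass X is added and one electron mass subtracted;
#' the radical cation `[M]+.` (also written `[M]+•`) only loses an electron.
#'
#' @param formula Formula string or element-count vector of the neutral
#'   molecule M.
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"`, `"[M+Li]+"`,
#'   `"[M]+."`.
#' @return Theoretical m/z in Da.
#' @examples
#' adduct_mz("C23H45NO4", "[M+H]+")   # palmitoylcarnitine, 400.3
#' adduct_mz("C34H32FeN4O4", "[M]+.") # heme b, 616.2
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  adduct <- gsub("•", ".", adduct)
  m <- monoisotopic_mass(formula)
  add <- switch(adduct,
    "[M+H]+"  = .isotope_mass[["H"]],
    "[M+Na]+" = .isotope_mass[["Na"]],
    "[M+K]+"  = .isotope_mass[["K"]],
    "[M+Li]+" = .isotope_mass[["Li"]],
    "[M]+."   = 0,
    msi_stop("unsupported adduct: '", adduct, "' (supported: ",
             paste(.supported_adducts(), collapse = ", "), ")")
  )
  m + add - .electron_mass
}

#' Bundled lipid candidate table
#'
#' The acylcarnitine, lysoPC, PC and heme species relevant to spinal-cord
#' lesion imaging, with the adduct under which each is observed in positive
#' mode and the theoretical m/z computed by [adduct_mz()]. The entry at
#' nominal m/z 372.3 is tetradecanoylcarnitine (C21H41NO4, the saturated
#' 14:0 species, whose mass matches the printed value; see the package
#' vignette for the naming caveat).
#'
#' @return A data.frame with columns `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `class`.
#' @export
lipid_candidates <- function() {
  path <- system.file("extdata", "lipid_candidates.csv", package = "msi3d",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$theoretical_mz <- vapply(
    seq_len(nrow(tab)),
    function(i) adduct_mz(tab$formula[i], tab$adduct[i]),
    numeric(1)
  )
  tab
}

#' Match detected peaks to lipid candidates
#'
#' Nearest-candidate matching within a mass tolerance. When several
#' candidates fall within the tolerance of one peak, all are reported and
#' flagged ambiguous.
#'
#' @param peaklist A [peaklist] (or data.frame with a `center` column, or a
#'   numeric vector of peak centers).
#' @param candidates Candidate table as from [lipid_candidates()].
#' @param tolerance_da Match tolerance in Da (default 0.3, TOF-appropriate).
#' @return data.frame of assignments with columns `peak_mz`, `name`,
#'   `formula`, `adduct`, `theoretical_mz`, `error_da`, `error_ppm`,
#'   `ambiguous`. Unmatched peaks are omitted.
#' @export
match_peaks <- function(peaklist, candidates = lipid_candidates(),
                        tolerance_da = 0.3) {
  centers <- if (is.numeric(peaklist)) peaklist else peaklist$center
  stopifnot(tolerance_da > 0, nrow(candidates) >= 1L)
  rows <- lapply(centers, function(mz) {
    err <- mz - candidates$theoretical_mz
    hit <- which(abs(err) <= tolerance_da)
    if (!length(hit)) return(NULL)
    data.frame(
      peak_mz = mz,
      name = candidates$name[hit],
      formula = candidates$formula[hit],
      adduct = candidates$adduct[hit],
      theoretical_mz = candidates$theoretical_mz[hit],
      error_da = err[hit],
      error_ppm = 1e6 * err[hit] / candidates$theoretical_mz[hit],
      ambiguous = length(hit) > 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      peak_mz = numeric(0), name = character(0), formula = character(0),
      adduct = character(0), theoretical_mz = numeric(0),
      error_da = numeric(0), error_ppm = numeric(0), ambiguous = logical(0)
    )
  }
  rownames(out) <- NULL
  out
}
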