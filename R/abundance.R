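# Natural isotopic abundances and abundance-ratio arithmetic.
#
# Every spillover estimate and transmission-bias calculation in the package is
# driven by ratios of natural isotopic abundances, so the table lives here and
# is exposed read-only.  Values are bundled from a standard isotopic-composition
# reference (CIAAW/NIST representative composition; see
# inst/extdata/isotope_abundances.csv for source and retrieval date).

.tecyto_env <- new.env(parent = emptyenv())

#' Bundled natural isotopic-abundance table
#'
#' Fractional natural abundances for all stable isotopes of tellurium
#' (120, 122, 123, 124, 125, 126, 128, 130) and xenon
#' (124, 126, 128, 129, 130, 131, 132, 134, 136), taken from a standard
#' isotopic-composition reference (CIAAW/NIST representative composition).
#' Per element the fractions sum to 1 within table-source rounding (1e-3).
#'
#' @return A data.frame with columns `element` (character), `mass` (integer)
#'   and `abundance` (double, in `[0, 1]`).
#' @seealso [abundance()], [theoretical_ratio()], [read_abundance_table()]
#' @export
#' @examples
#' head(isotope_abundances())
isotope_abundances <- function() {
  if (is.null(.tecyto_env$abundance_table)) {
    path <- system.file("extdata", "isotope_abundances.csv", package = "tecyto",
                        mustWork = TRUE)
    .tecyto_env$abundance_table <- read_abundance_table(path)
  }
  .tecyto_env$abundance_table
}

#' Read an isotopic-abundance table from file
#'
#' Reads a CSV with columns `element,mass,abundance` (lines starting with `#`
#' are comments).  The result can be passed as the `table` argument of
#' [abundance()] and [theoretical_ratio()] to override the bundled values,
#' e.g. for sensitivity analysis with a different abundance compilation.
#'
#' @param path Path to a CSV file in the same layout as the bundled table.
#' @return A validated abundance data.frame (see [isotope_abundances()]).
#' @export
read_abundance_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("element", "mass", "abundance")
  if (!all(required %in% names(tab))) {
    stop("abundance table must have columns: ", paste(required, collapse = ", "))
  }
  tab$element <- as.character(tab$element)
  tab$mass <- as.integer(tab$mass)
  tab$abundance <- as.numeric(tab$abundance)
  if (anyNA(tab$mass) || any(tab$mass <= 0)) {
    stop("abundance table mass numbers must be positive integers")
  }
  if (any(tab$abundance < 0 | tab$abundance > 1)) {
    stop("abundances must lie in [0, 1]")
  }
  if (anyDuplicated(tab[c("element", "mass")])) {
    stop("duplicate (element, mass) entries in abundance table")
  }
  sums <- tapply(tab$abundance, tab$element, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-3]
  if (length(bad)) {
    stop("abundances do not sum to 1 (within 1e-3) for element(s): ",
         paste(bad, collapse = ", "))
  }
  tab
}

#' Natural abundance of one isotope
#'
#' @param element Element symbol, case-sensitive (e.g. `"Te"`, `"Xe"`).
#' @param mass Mass number of the isotope.
#' @param table Abundance table; defaults to the bundled one.
#' @return Fractional abundance in `[0, 1]`.
#' @export
#' @examples
#' abundance("Xe", 134)
abundance <- function(element, mass, table = isotope_abundances()) {
  i <- which(table$element == element & table$mass == as.integer(mass))
  if (length(i) != 1L) {
    stop(sprintf("unknown isotope: %s-%d is not in the abundance table",
                 element, as.integer(mass)))
  }
  table$abundance[i]
}

#' Theoretical abundance ratio of two isotopes of one element
#'
#' The ratio `abundance(element, mass_a) / abundance(element, mass_b)`.  This
#' is the expected channel-intensity ratio of two isotopes of an element whose
#' isotopic composition is natural, and the multiplier used to project the
#' xenon 134 channel onto a xenon isobar of tellurium.
#'
#' @inheritParams abundance
#' @param mass_a,mass_b Mass numbers of the numerator and denominator isotopes.
#' @return A positive ratio.
#' @export
#' @examples
#' theoretical_ratio("Xe", 128, 134)  # xenon spillover factor for mass 128
theoretical_ratio <- function(element, mass_a, mass_b,
                              table = isotope_abundances()) {
  a <- abundance(element, mass_a, table)
  b <- abundance(element, mass_b, table)
  if (b == 0) {
    stop(sprintf("abundance of %s-%d is zero; ratio undefined",
                 element, as.integer(mass_b)))
  }
  a / b
}

# Te mass numbers that have a stable Xe isobar (unit-mass overlap).
te_xenon_isobars <- function() c(124L, 126L, 128L, 130L)
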