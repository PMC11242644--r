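## average residue masses (Da) and the ionizable-group pKa set used for
## protein statistics.  The pKa values are the EMBOSS defaults; pI is
## table-dependent, so the table can be overridden per call.

AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

PKA_DEFAULT <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                 H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Molecular mass and isoelectric point of a protein
#'
#' Mass is the sum of average residue masses plus one water; the
#' isoelectric point solves net charge = 0 with Henderson-Hasselbalch
#' terms for the two termini and the ionizable side chains (D, E, C, Y
#' negative; H, K, R positive), by bisection on pH.
#'
#' @param protein amino-acid string over the 20 standard residues
#'   (a trailing \code{*} translation stop is tolerated and dropped).
#' @param pka named pKa vector (\code{Nterm, Cterm, C, D, E, H, K, R, Y}).
#' @return object of class \code{protein_properties}: list with
#'   \code{mw_kda} (kilodaltons) and \code{pi} (pH units, resolved to
#'   0.01).
#' @export
protein_properties <- function(protein, pka = PKA_DEFAULT) {
  protein <- sub("\\*$", "", toupper(protein))
  if (nchar(protein) == 0L) stop("empty protein sequence")
  aa <- strsplit(protein, "")[[1L]]
  bad <- setdiff(unique(aa), names(AA_MASS))
  if (length(bad) > 0L)
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  mw <- (sum(AA_MASS[aa]) + WATER_MASS) / 1000
  cnt <- table(factor(aa, levels = names(AA_MASS)))
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pka["Nterm"])) +
      cnt[["H"]] / (1 + 10^(ph - pka["H"])) +
      cnt[["K"]] / (1 + 10^(ph - pka["K"])) +
      cnt[["R"]] / (1 + 10^(ph - pka["R"]))
    neg <- 1 / (1 + 10^(pka["Cterm"] - ph)) +
      cnt[["D"]] / (1 + 10^(pka["D"] - ph)) +
      cnt[["E"]] / (1 + 10^(pka["E"] - ph)) +
      cnt[["C"]] / (1 + 10^(pka["C"] - ph)) +
      cnt[["Y"]] / (1 + 10^(pka["Y"] - ph))
    unname(pos - neg)
  }
  pi <- stats::uniroot(charge, c(0.001, 13.999), tol = 1e-4)$root
  structure(list(mw_kda = mw, pi = pi), class = "protein_properties")
}

#' @export
print.protein_properties <- function(x, ...) {
  cat(sprintf("<protein_properties> MW %.2f kDa, pI %.2f\n",
              x$mw_kda, x$pi))
  invisible(x)
}

#' Translate an in-frame coding sequence to protein
#' @param cds nucleotide string, length divisible by 3.
#' @param trim_stop drop the trailing stop, if present.
#' @return amino-acid string (stops as \code{*}).
#' @export
translate_cds <- function(cds, trim_stop = TRUE) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  if (trim_stop) aa <- sub("\\*$", "", aa)
  aa
}
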