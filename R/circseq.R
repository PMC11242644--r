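#' Circular (or linear) nucleotide sequence
#'
#' The coordinate substrate used throughout the package: a named uppercase
#' nucleotide string over \code{A,C,G,T,N} together with its topology.
#' Plant mitochondrial molecules assemble as circles, so all downstream
#' coordinate arithmetic (repeat detection, junction extraction, read
#' simulation) must respect wrap-around; reads and proteins are linear.
#'
#' @param id character scalar, the molecule label.
#' @param residues nucleotide string; lowercase is normalized to uppercase
#'   and IUPAC ambiguity codes other than N are normalized to N with a
#'   warning (exact-repeat logic requires a fixed alphabet).
#' @param topology one of \code{"circular"} or \code{"linear"}.
#' @return An object of class \code{circseq} with fields \code{id},
#'   \code{residues}, \code{topology} and \code{length}.
#' @examples
#' m <- circseq("toy", "ACGTACGTAC")
#' seq_length(m)
#' gc_content(m)
#' @export
circseq <- function(id, residues, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop("sequence '", id, "' is empty")
  bad <- gsub("[ACGTN]", "", residues)
  if (nzchar(bad)) {
    amb <- gsub("[^RYSWKMBDHV]", "", bad)
    if (nchar(amb) == nchar(bad)) {
      warning("sequence '", id, "': ", nchar(bad),
              " IUPAC ambiguity base(s) normalized to N")
      residues <- gsub("[RYSWKMBDHV]", "N", residues)
    } else {
      off <- regexpr("[^ACGTN]", gsub("[RYSWKMBDHV]", "N", residues))
      stop("sequence '", id, "': illegal character at offset ", off - 1L)
    }
  }
  structure(
    list(id = id, residues = residues, topology = topology,
         length = nchar(residues)),
    class = "circseq")
}

#' @export
print.circseq <- function(x, ...) {
  cat(sprintf("<circseq> %s  %s, %s bp\n", x$id, x$topology,
              format(x$length, big.mark = ",")))
  head <- substr(x$residues, 1L, 60L)
  cat(" ", head, if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Length of a sequence object
#' @param x a \code{circseq}.
#' @return integer length in bases.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "circseq"))
  x$length
}

#' Genomic interval (0-based, half-open, strand-explicit)
#'
#' Internal coordinate convention for every stage: \code{start} is 0-based
#' inclusive, \code{end} exclusive, strand \code{"+"} or \code{"-"}.  On a
#' circular molecule an interval may cross the origin; this is flagged with
#' \code{wraps = TRUE} and encoded as \code{end <= start}.  An \code{end}
#' beyond the molecule length is accepted at construction and normalized.
#'
#' @param start 0-based inclusive start.
#' @param end exclusive end; may exceed \code{L} (wrap) when \code{L} given.
#' @param strand \code{"+"} or \code{"-"}; minus denotes the reverse
#'   complement of the extracted span.
#' @param L optional molecule length used to normalize a wrapping end.
#' @return a list of class \code{interval}.
#' @export
interval <- function(start, end, strand = "+", L = NULL) {
  stopifnot(strand %in% c("+", "-"), start >= 0, end >= 0)
  wraps <- FALSE
  if (!is.null(L)) {
    stopifnot(start < L)
    if (end > L) {
      end <- end - L
      wraps <- TRUE
    } else if (end <= start) {
      wraps <- TRUE
    }
  } else if (end <= start) {
    wraps <- TRUE
  }
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand, wraps = wraps),
            class = "interval")
}

#' Span length of an interval on a molecule
#' @param iv an \code{interval}.
#' @param L molecule length.
#' @return integer number of bases covered.
#' @export
interval_width <- function(iv, L) {
  if (iv$wraps) (iv$end - iv$start) %% L else iv$end - iv$start
}

#' Extract the nucleotide span of an interval
#'
#' Wrap-aware substring extraction: for an origin-crossing interval on a
#' circular molecule the suffix and prefix are concatenated; strand
#' \code{"-"} returns the reverse complement.
#'
#' @param seq a \code{circseq}.
#' @param iv an \code{interval} valid for the topology of \code{seq}.
#' @return a nucleotide string.
#' @examples
#' m <- circseq("toy", "ACGTACGTAC")
#' extract_seq(m, interval(8, 12, L = seq_length(m)))  # "ACAC"
#' @export
extract_seq <- function(seq, iv) {
  stopifnot(inherits(seq, "circseq"), inherits(iv, "interval"))
  L <- seq$length
  if (iv$start >= L || iv$end > L)
    iv <- interval(iv$start %% L, iv$end, strand = iv$strand, L = L)
  if (iv$wraps) {
    if (seq$topology != "circular")
      stop("origin-crossing interval requested on linear molecule '",
           seq$id, "'")
    s <- paste0(substr(seq$residues, iv$start + 1L, L),
                substr(seq$residues, 1L, iv$end))
  } else {
    s <- substr(seq$residues, iv$start + 1L, iv$end)
  }
  if (iv$strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a nucleotide string
#' @param s nucleotide string over A,C,G,T,N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' GC content of a molecule
#'
#' Fraction of G+C among non-N bases; N bases are excluded from the
#' denominator so that masked regions do not dilute the estimate.
#'
#' @param seq a \code{circseq}.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  stopifnot(inherits(seq, "circseq"))
  cnt <- base_counts(seq$residues)
  denom <- sum(cnt[c("A", "C", "G", "T")])
  if (denom == 0L) stop("GC content undefined: sequence '", seq$id,
                        "' is all N")
  unname((cnt[["G"]] + cnt[["C"]]) / denom)
}

## per-base counts without constructing an XString
base_counts <- function(s) {
  r <- charToRaw(s)
  c(A = sum(r == charToRaw("A")), C = sum(r == charToRaw("C")),
    G = sum(r == charToRaw("G")), T = sum(r == charToRaw("T")),
    N = sum(r == charToRaw("N")))
}

#' Rotate a circular molecule
#'
#' Moves the origin so that reference position \code{k} becomes position 0.
#' Rotation is a no-op biologically (same circle) and is used by the
#' rotation-invariance checks.
#'
#' @param seq a circular \code{circseq}.
#' @param k rotation offset in bases.
#' @return a \code{circseq} with rotated residues.
#' @export
seq_rotate <- function(seq, k) {
  stopifnot(inherits(seq, "circseq"), seq$topology == "circular")
  L <- seq$length
  k <- ((as.integer(k)) %% L)
  if (k == 0L) return(seq)
  circseq(seq$id,
          paste0(substr(seq$residues, k + 1L, L),
                 substr(seq$residues, 1L, k)),
          "circular")
}

#' Reverse-complement a molecule object
#' @param seq a \code{circseq}.
#' @return a \code{circseq} on the opposite strand.
#' @export
seq_revcomp <- function(seq) {
  stopifnot(inherits(seq, "circseq"))
  circseq(seq$id, revcomp(seq$residues), seq$topology)
}
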