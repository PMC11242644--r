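#' Scan a molecule for microsatellites (SSRs)
#'
#' Finds maximal perfect tandem runs of 1-6 bp motifs whose full-copy
#' number meets the MISA-style per-unit thresholds (defaults 10, 5, 4, 3,
#' 3, 3 for mono- through hexanucleotides).  A run whose motif is itself a
#' repetition of a shorter motif (e.g. \code{ACAC} of \code{AC}) is
#' reported only at the shortest unit length.  The reported motif is the
#' lexicographically smallest rotation of the repeated unit, while the
#' interval keeps the genomic phase of the run; the interval covers full
#' copies only.  Motifs containing N are never reported.
#'
#' @param seq a \code{circseq}.
#' @param thresholds integer vector of length 6: minimum copy number for
#'   unit lengths 1-6.
#' @return data.frame of class \code{ssr_records} with columns
#'   \code{molecule,motif,unit,copies,start,end} (0-based half-open;
#'   \code{end <= start} marks an origin-crossing run).
#' @export
find_ssrs <- function(seq, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  stopifnot(inherits(seq, "circseq"), length(thresholds) == 6L)
  L <- seq$length
  r <- charToRaw(seq$residues)
  isn <- r == charToRaw("N")
  circular <- seq$topology == "circular"
  out <- list()
  for (u in 1:6) {
    thr <- as.integer(thresholds[u])
    if (L < u * thr) next
    if (circular) {
      idx2 <- ((0:(L - 1L) + u) %% L) + 1L
      m <- r[1:L] == r[idx2] & !isn[1:L] & !isn[idx2]
      runs <- circ_runs(m)
      if (identical(runs, "degenerate"))
        runs <- data.frame(t0 = 0L, len = L)
    } else {
      if (L <= u) next
      m <- r[1:(L - u)] == r[(u + 1L):L] & !isn[1:(L - u)] & !isn[(u + 1L):L]
      runs <- lin_runs(m)
    }
    if (is.null(runs) || nrow(runs) == 0L) next
    copies <- pmin((runs$len + u) %/% u, L %/% u)
    keep <- copies >= thr
    if (!any(keep)) next
    runs <- runs[keep, , drop = FALSE]
    copies <- copies[keep]
    dbl <- paste0(seq$residues, substr(seq$residues, 1L, 2L * u))
    motifs <- substring(dbl, runs$t0 + 1L, runs$t0 + u)
    prim <- !vapply(motifs, motif_is_periodic, TRUE)
    if (!any(prim)) next
    out[[length(out) + 1L]] <- data.frame(
      molecule = seq$id,
      motif = vapply(motifs[prim], canonical_rotation_motif, ""),
      unit = u,
      copies = copies[prim],
      start = runs$t0[prim],
      end = if (circular) (runs$t0[prim] + copies[prim] * u) %% L
            else runs$t0[prim] + copies[prim] * u,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    res <- data.frame(molecule = character(), motif = character(),
                      unit = integer(), copies = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$start, res$unit), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("ssr_records", "data.frame")
  res
}

## TRUE when the motif is a whole-number repetition of a shorter motif
motif_is_periodic <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(FALSE)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L &&
        strrep(substr(motif, 1L, p), u %/% p) == motif) return(TRUE)
  }
  FALSE
}

## lexicographically smallest rotation of a short motif
canonical_rotation_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(motif)
  dbl <- paste0(motif, motif)
  min(substring(dbl, 1:u, 1:u + u - 1L))
}
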