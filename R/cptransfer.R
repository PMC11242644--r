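#' Detect plastid-derived insertions (MTPTs) in mitochondrial molecules
#'
#' Seed-and-chain homology scan: exact k-mer seeds between each
#' mitochondrial molecule and the plastome (both strands) are grouped by
#' alignment diagonal, chained along the diagonal with a bounded gap, and
#' greedily extended at both ends while bases match.  Per-segment identity
#' is the fraction of matching columns over the chained span.  Segments
#' whose mitochondrial intervals overlap by at least half are merged.
#' The scanner targets the substitution-divergence regime typical of
#' recent organelle transfers; large indels inside a transferred fragment
#' split it into separate reported segments.
#'
#' @param mito list of \code{circseq} (or a single one).
#' @param plastome donor \code{circseq}.
#' @param min_len minimum reported segment length (bases).
#' @param min_identity minimum percent identity.
#' @param k seed k-mer length.
#' @param max_gap maximum distance between chained seeds on a diagonal.
#' @return data.frame of class \code{cp_insertions} with columns
#'   \code{molecule,start,end,cp_start,cp_end,strand,length,identity}
#'   (identity in percent, one decimal), sorted by mito coordinate.
#' @export
find_insertions <- function(mito, plastome, min_len = 80L,
                            min_identity = 85, k = 15L, max_gap = 200L) {
  if (inherits(mito, "circseq")) mito <- list(mito)
  stopifnot(inherits(plastome, "circseq"), min_len >= 20L)
  if (plastome$length < k) stop("plastome shorter than seed length k")
  P <- plastome$length
  prc <- revcomp(plastome$residues)

  pk <- linear_kmers(plastome$residues, P, k)
  pkr <- linear_kmers(prc, P, k)
  PD <- data.table::rbindlist(list(
    data.table::data.table(kmer = pk$kmer, ppos = pk$pos, strand = "+"),
    data.table::data.table(kmer = pkr$kmer, ppos = pkr$pos, strand = "-")))

  out <- list()
  for (mol in mito) {
    mk <- linear_kmers(mol$residues, mol$length, k)
    if (length(mk$pos) == 0L) next
    MD <- data.table::data.table(kmer = mk$kmer, mpos = mk$pos)
    H <- merge(MD, PD, by = "kmer", allow.cartesian = TRUE)
    if (nrow(H) == 0L) next
    H$diag <- H$mpos - H$ppos
    data.table::setorderv(H, c("strand", "diag", "mpos"))
    ## split diagonal runs at gaps larger than max_gap
    brk <- c(TRUE, diff(H$mpos) > max_gap |
                   diff(H$diag) != 0L |
                   H$strand[-1L] != H$strand[-nrow(H)])
    H$chain <- cumsum(brk)
    ch <- H[, list(m1 = min(mpos), m2 = max(mpos) + k,
                   strand = strand[1L], diag = diag[1L],
                   nseed = .N),
            by = "chain"]
    rm <- charToRaw(mol$residues)
    rp <- charToRaw(plastome$residues)
    rpr <- charToRaw(prc)
    for (i in seq_len(nrow(ch))) {
      st <- ch$strand[i]; dg <- ch$diag[i]
      m1 <- ch$m1[i]; m2 <- ch$m2[i]
      tgt <- if (st == "+") rp else rpr
      ## X-drop extension at both ends along the diagonal: tolerate the
      ## isolated mismatches of a diverged transfer, stop in random flank
      m1 <- m1 - xdrop_extend(rm, tgt, m1 - 1L, m1 - dg - 1L, -1L,
                              mol$length, P)
      m2 <- m2 + xdrop_extend(rm, tgt, m2, m2 - dg, +1L,
                              mol$length, P)
      len <- m2 - m1
      if (len < min_len) next
      ident <- 100 * mean(rm[(m1 + 1L):m2] == tgt[(m1 - dg + 1L):(m2 - dg)])
      if (ident < min_identity) next
      p1 <- m1 - dg; p2 <- m2 - dg
      if (st == "-") { tmp <- p1; p1 <- P - p2; p2 <- P - tmp }
      out[[length(out) + 1L]] <- data.frame(
        molecule = mol$id, start = m1, end = m2,
        cp_start = p1, cp_end = p2, strand = st,
        length = len, identity = round(ident, 1L))
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(molecule = character(), start = integer(),
                         end = integer(), cp_start = integer(),
                         cp_end = integer(), strand = character(),
                         length = integer(), identity = numeric())
  res <- merge_insertions(res)
  res <- res[order(res$molecule, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cp_insertions", "data.frame")
  res
}

## X-drop diagonal extension: walk outward from 0-based positions pm/pt
## (the first candidate bases) scoring +1/match, -2/mismatch, stop when
## the score falls `xdrop` below its maximum; returns bases gained up to
## the best-scoring point
xdrop_extend <- function(rm, rt, pm, pt, dirn, len_m, len_t,
                         xdrop = 10L) {
  best <- 0L; cur <- 0L; best_off <- 0L; off <- 0L
  while (TRUE) {
    qm <- pm + dirn * off
    qt <- pt + dirn * off
    if (qm < 0L || qm >= len_m || qt < 0L || qt >= len_t) break
    cur <- cur + if (rm[qm + 1L] == rt[qt + 1L]) 1L else -2L
    off <- off + 1L
    if (cur > best) { best <- cur; best_off <- off }
    if (best - cur > xdrop) break
  }
  best_off
}

## merge records whose mito intervals overlap >= 50% of the shorter one;
## the longest member supplies the plastome interval and identity
merge_insertions <- function(res) {
  if (nrow(res) < 2L) return(res)
  keep <- list()
  for (mol in unique(res$molecule)) {
    sub <- res[res$molecule == mol, , drop = FALSE]
    sub <- sub[order(sub$start, -sub$length), , drop = FALSE]
    grp <- integer(nrow(sub)); grp[1L] <- 1L
    for (i in seq_len(nrow(sub))[-1L]) {
      prev <- which(grp == grp[i - 1L])
      g_end <- max(sub$end[prev])
      ov <- min(g_end, sub$end[i]) - max(sub$start[prev][1L], sub$start[i])
      shorter <- min(sub$end[i] - sub$start[i],
                     g_end - min(sub$start[prev]))
      grp[i] <- if (ov >= 0.5 * shorter) grp[i - 1L] else grp[i - 1L] + 1L
    }
    for (g in unique(grp)) {
      rows <- sub[grp == g, , drop = FALSE]
      lead <- rows[which.max(rows$length), , drop = FALSE]
      lead$start <- min(rows$start); lead$end <- max(rows$end)
      lead$length <- lead$end - lead$start
      keep[[length(keep) + 1L]] <- lead
    }
  }
  out <- do.call(rbind, keep)
  class(out) <- class(res)
  out
}

#' Plastid-derived fraction of the mitogenome
#'
#' @param insertions a \code{cp_insertions} table (non-overlapping after
#'   merging; overlapping intervals here are an error).
#' @param total_length total mitogenome length (bases).
#' @return percent of the genome covered, to one decimal.
#' @export
summarize_fraction <- function(insertions, total_length) {
  stopifnot(total_length >= 1)
  if (nrow(insertions) == 0L) return(0.0)
  for (mol in unique(insertions$molecule)) {
    sub <- insertions[insertions$molecule == mol, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping insertion intervals; merge contract violated")
  }
  round(100 * sum(insertions$end - insertions$start) / total_length, 1L)
}
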