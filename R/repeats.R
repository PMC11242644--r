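#' Find maximal exact repeat pairs on a molecule
#'
#' Detects all maximal exact repeated pairs (direct, and optionally
#' inverted) of length at least \code{min_len}, respecting circular
#' topology (copies may cross the origin).  The algorithm seeds candidate
#' diagonals with shared k-mers and then scans each candidate diagonal of
#' the (doubled, for circular molecules) sequence for maximal match runs;
#' a run flanked by mismatches on its diagonal is exactly a maximal pair.
#' Only exact repeats are reported (identity 1): mismatch-tolerant repeat
#' detection is out of scope.  N bases never match anything, including
#' other Ns, so masked regions cannot seed spurious repeats.
#'
#' Tandem-like pairs are excluded: copies must be disjoint on the circle,
#' and direct copies must not abut exactly (an abutting direct pair is a
#' tandem duplication, a different feature class).
#'
#' @param seq a \code{circseq}.
#' @param min_len minimum repeat length in bases (>= 2).
#' @param include_inverted also report inverted (reverse-complement) pairs.
#' @return data.frame of class \code{repeat_pairs} with columns
#'   \code{molecule,start1,end1,start2,end2,length,orientation,identity}.
#'   Coordinates are 0-based half-open; an \code{end} not larger than its
#'   \code{start} denotes an origin-crossing copy on a circular molecule.
#'   Sorted by (\code{start1}, decreasing \code{length}); \code{start1 <=
#'   start2} canonically.
#' @export
find_maximal_repeats <- function(seq, min_len = 30L, include_inverted = TRUE) {
  stopifnot(inherits(seq, "circseq"))
  min_len <- as.integer(min_len)
  if (min_len < 2L) stop("min_len must be >= 2")
  L <- seq$length
  empty <- repeat_pairs_df()
  if (L < 2L * min_len && seq$topology == "linear") return(empty)
  if (L < min_len) return(empty)

  circular <- seq$topology == "circular"
  res <- find_direct_pairs(seq$residues, L, min_len, circular)
  if (include_inverted) {
    res <- rbind(res, find_inverted_pairs(seq$residues, L, min_len, circular))
  }
  if (nrow(res) == 0L) return(empty)

  res$molecule <- seq$id
  res$identity <- 1.0
  ## canonical copy order, dedup, sort
  swap <- res$start1 > res$start2
  if (any(swap)) {
    tmp <- res[swap, c("start1", "end1")]
    res[swap, c("start1", "end1")] <- res[swap, c("start2", "end2")]
    res[swap, c("start2", "end2")] <- tmp
  }
  key <- paste(res$start1, res$start2, res$length, res$orientation)
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$start1, -res$length, res$start2), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("molecule", "start1", "end1", "start2", "end2",
                 "length", "orientation", "identity")]
  class(res) <- c("repeat_pairs", "data.frame")
  res
}

repeat_pairs_df <- function() {
  out <- data.frame(molecule = character(), start1 = integer(),
                    end1 = integer(), start2 = integer(), end2 = integer(),
                    length = integer(), orientation = character(),
                    identity = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("repeat_pairs", "data.frame")
  out
}

## seed k-mer length: long enough that random collisions are rare on
## genome-scale input, never longer than the repeat sought
seed_k <- function(min_len) min(min_len, 31L)

## positions (0-based) of every circular k-mer, N-free only
circular_kmers <- function(s, L, k) {
  T2 <- paste0(s, substr(s, 1L, k - 1L))
  km <- substring(T2, 1:L, 1:L + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  list(kmer = km[keep], pos = (0:(L - 1L))[keep])
}

linear_kmers <- function(s, L, k) {
  n <- L - k + 1L
  if (n < 1L) return(list(kmer = character(), pos = integer()))
  km <- substring(s, 1:n, 1:n + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  list(kmer = km[keep], pos = (0:(n - 1L))[keep])
}

## match-run extraction over one circular diagonal; returns 0-based start
## positions and lengths of maximal TRUE runs
circ_runs <- function(m) {
  Lm <- length(m)
  if (!any(m)) return(NULL)
  if (all(m)) return("degenerate")
  mc2 <- c(m, m)
  r <- rle(mc2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts >= 2L & starts <= Lm + 1L
  if (!any(keep)) return(NULL)
  data.frame(t0 = (starts[keep] - 1L) %% Lm, len = r$lengths[keep])
}

lin_runs <- function(m) {
  if (!any(m)) return(NULL)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(t0 = starts[keep] - 1L, len = r$lengths[keep])
}

## circular interval overlap in bases between [a,a+la) and [b,b+lb) mod L
circ_overlap <- function(a, la, b, lb, L) {
  ## compare on the doubled line, taking the best of the two relative shifts
  ov <- function(x1, x2, y1, y2) max(0L, min(x2, y2) - max(x1, y1))
  max(ov(a, a + la, b, b + lb),
      ov(a, a + la, b + L, b + L + lb),
      ov(a + L, a + la + L, b, b + lb))
}

find_direct_pairs <- function(s, L, min_len, circular) {
  k <- seed_k(min_len)
  kl <- if (circular) circular_kmers(s, L, k) else linear_kmers(s, L, k)
  if (length(kl$pos) == 0L) return(repeat_pairs_df())
  DT <- data.table::data.table(kmer = kl$kmer, pos = kl$pos)
  cnt <- DT[, .N, by = "kmer"]
  dup <- cnt[cnt$N > 1L, ]
  if (nrow(dup) == 0L) return(repeat_pairs_df())
  if (sum(as.numeric(dup$N)^2) > 5e7)
    stop("seed collision explosion; raise min_len for this input")
  DT <- DT[DT$kmer %in% dup$kmer, ]
  pr <- merge(DT, DT, by = "kmer", allow.cartesian = TRUE,
              suffixes = c("", ".b"))
  pr <- pr[pr$pos < pr$pos.b, ]
  if (nrow(pr) == 0L) return(repeat_pairs_df())
  d <- pr$pos.b - pr$pos
  diags <- if (circular) unique(pmin(d %% L, (L - d) %% L)) else unique(d)
  diags <- diags[diags > 0L]

  r <- charToRaw(s)
  rn <- r == charToRaw("N")
  out <- list()
  if (circular) {
    r2 <- c(r, r)
    rn2 <- c(rn, rn)
    for (dd in diags) {
      i1 <- 1:L
      i2 <- ((0:(L - 1L) + dd) %% (2L * L)) + 1L
      m <- r2[i1] == r2[i2] & !rn2[i1] & !rn2[i2]
      runs <- circ_runs(m)
      if (is.null(runs)) next
      if (identical(runs, "degenerate")) next  # x equals its own rotation
      runs <- runs[runs$len >= min_len & runs$len < pmin(dd, L - dd), ,
                   drop = FALSE]
      if (nrow(runs) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = runs$t0, end1 = (runs$t0 + runs$len) %% L,
        start2 = (runs$t0 + dd) %% L,
        end2 = (runs$t0 + dd + runs$len) %% L,
        length = runs$len, orientation = "direct")
    }
  } else {
    for (dd in diags) {
      n <- L - dd
      i1 <- 1:n
      i2 <- (dd + 1L):L
      m <- r[i1] == r[i2] & !rn[i1] & !rn[i2]
      runs <- lin_runs(m)
      if (is.null(runs)) next
      runs <- runs[runs$len >= min_len & runs$len < dd, , drop = FALSE]
      if (nrow(runs) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = runs$t0, end1 = runs$t0 + runs$len,
        start2 = runs$t0 + dd, end2 = runs$t0 + dd + runs$len,
        length = runs$len, orientation = "direct")
    }
  }
  if (length(out) == 0L) return(repeat_pairs_df())
  do.call(rbind, out)
}

find_inverted_pairs <- function(s, L, min_len, circular) {
  y <- revcomp(s)
  k <- seed_k(min_len)
  klx <- if (circular) circular_kmers(s, L, k) else linear_kmers(s, L, k)
  kly <- if (circular) circular_kmers(y, L, k) else linear_kmers(y, L, k)
  if (length(klx$pos) == 0L || length(kly$pos) == 0L)
    return(repeat_pairs_df())
  DX <- data.table::data.table(kmer = klx$kmer, pos = klx$pos)
  DY <- data.table::data.table(kmer = kly$kmer, qos = kly$pos)
  cx <- DX[, .N, by = "kmer"]; cy <- DY[, .N, by = "kmer"]
  shared <- merge(cx, cy, by = "kmer")
  if (nrow(shared) == 0L) return(repeat_pairs_df())
  if (sum(as.numeric(shared$N.x) * shared$N.y) > 5e7)
    stop("seed collision explosion; raise min_len for this input")
  pr <- merge(DX[DX$kmer %in% shared$kmer, ],
              DY[DY$kmer %in% shared$kmer, ],
              by = "kmer", allow.cartesian = TRUE)
  if (nrow(pr) == 0L) return(repeat_pairs_df())
  rx <- charToRaw(s); ry <- charToRaw(y)
  nx <- rx == charToRaw("N"); ny <- ry == charToRaw("N")
  out <- list()
  if (circular) {
    diags <- unique((pr$qos - pr$pos) %% L)
    rx2 <- c(rx, rx); ry2 <- c(ry, ry)
    nx2 <- c(nx, nx); ny2 <- c(ny, ny)
    for (cc in diags) {
      i1 <- 1:L
      i2 <- ((0:(L - 1L) + cc) %% (2L * L)) + 1L
      m <- rx2[i1] == ry2[i2] & !nx2[i1] & !ny2[i2]
      runs <- circ_runs(m)
      if (is.null(runs)) next
      if (identical(runs, "degenerate")) next
      runs <- runs[runs$len >= min_len, , drop = FALSE]
      if (nrow(runs) == 0L) next
      a <- runs$t0
      j <- (L - ((runs$t0 + cc) %% L) - runs$len) %% L
      keep <- mapply(function(ai, ji, li)
        circ_overlap(ai, li, ji, li, L) == 0L && ai != ji,
        a, j, runs$len)
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = a[keep], end1 = (a[keep] + runs$len[keep]) %% L,
        start2 = j[keep], end2 = (j[keep] + runs$len[keep]) %% L,
        length = runs$len[keep], orientation = "inverted")
    }
  } else {
    diags <- unique(pr$qos - pr$pos)
    for (cc in diags) {
      t_lo <- max(0L, -cc)
      t_hi <- min(L - 1L, L - 1L - cc)
      if (t_hi - t_lo + 1L < min_len) next
      i1 <- (t_lo:t_hi) + 1L
      i2 <- (t_lo:t_hi) + cc + 1L
      m <- rx[i1] == ry[i2] & !nx[i1] & !ny[i2]
      runs <- lin_runs(m)
      if (is.null(runs)) next
      runs$t0 <- runs$t0 + t_lo
      runs <- runs[runs$len >= min_len, , drop = FALSE]
      if (nrow(runs) == 0L) next
      a <- runs$t0
      j <- L - (runs$t0 + cc) - runs$len
      keep <- (a + runs$len <= j) | (j + runs$len <= a)
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = a[keep], end1 = a[keep] + runs$len[keep],
        start2 = j[keep], end2 = j[keep] + runs$len[keep],
        length = runs$len[keep], orientation = "inverted")
    }
  }
  if (length(out) == 0L) return(repeat_pairs_df())
  do.call(rbind, out)
}

#' Extract the two copy intervals of one repeat pair
#' @param pairs a \code{repeat_pairs} data.frame.
#' @param i row index.
#' @param L molecule length.
#' @return list with \code{copy1} and \code{copy2} \code{interval}s.
#' @export
repeat_intervals <- function(pairs, i, L) {
  row <- pairs[i, ]
  list(copy1 = interval(row$start1, row$start1 + row$length, L = L),
       copy2 = interval(row$start2, row$start2 + row$length, L = L))
}

#' Summarize repeats by the conventional size classes
#' @param pairs a \code{repeat_pairs} data.frame.
#' @return data.frame of counts in the 30-59, 60-99 and >=100 bp classes,
#'   split by orientation.
#' @export
repeat_size_classes <- function(pairs) {
  cls <- cut(pairs$length, breaks = c(30, 60, 100, Inf), right = FALSE,
             labels = c("30-59", "60-99", ">=100"))
  as.data.frame(table(size_class = cls, orientation = pairs$orientation))
}
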