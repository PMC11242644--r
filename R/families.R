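#' Decompose overlapping repeat pairs into core/extension families
#'
#' Large plant-mitogenome repeats often come as a family: several copies
#' sharing a conserved core block, with copy-specific flanking blocks
#' ("extensions") on the left and/or right.  This operation groups the
#' copies of maximal repeat pairs whose genomic intervals overlap into
#' loci, links loci that are paired with each other into families, and
#' computes for each family the core (the block contained in every copy)
#' and the per-copy left/right extension lengths.
#'
#' The core is computed by projecting every locus onto a reference locus
#' (the one with the widest extent) through the exact pair alignments:
#' because the repeat finder reports all maximal pairs, any two copies
#' sharing the core are directly paired, and the core on the reference is
#' the intersection of the reference-side intervals of its pairs.
#'
#' Copies crossing the circular origin are not supported here; rotate the
#' molecule first ([seq_rotate()]) if a family straddles the origin.
#'
#' @param pairs a \code{repeat_pairs} data.frame for one molecule.
#' @param min_core minimum core length for a family to be reported.
#' @return list of \code{repeat_family} objects, ordered by decreasing
#'   core length and named R1, R2, ...  Each has fields \code{id},
#'   \code{molecule}, \code{core_length}, \code{core} (interval on the
#'   reference copy) and \code{copies} (data.frame with locus extents and
#'   left/right extension lengths).
#' @export
decompose_families <- function(pairs, min_core = 1000L) {
  if (nrow(pairs) == 0L) return(list())
  if (length(unique(pairs$molecule)) > 1L)
    stop("pairs from multiple molecules; decompose one molecule at a time")
  wraps <- pairs$end1 <= pairs$start1 | pairs$end2 <= pairs$start2
  if (any(wraps))
    stop("origin-crossing repeat copies: rotate the molecule first")

  np <- nrow(pairs)
  copies <- data.frame(
    pair = rep(seq_len(np), 2L),
    side = rep(1:2, each = np),
    start = c(pairs$start1, pairs$start2),
    end = c(pairs$end1, pairs$end2))

  ## cluster copies into loci by interval overlap
  o <- order(copies$start, copies$end)
  locus <- integer(nrow(copies))
  cur <- 0L; cur_end <- -1L
  for (i in o) {
    if (copies$start[i] >= cur_end) cur <- cur + 1L
    locus[i] <- cur
    cur_end <- max(cur_end, copies$end[i])
  }
  copies$locus <- locus

  ## union-find over loci, linked by pairs
  nl <- max(locus)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in seq_len(np)) {
    a <- find(copies$locus[copies$pair == p & copies$side == 1L])
    b <- find(copies$locus[copies$pair == p & copies$side == 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(nl), find, 1L)

  locus_extent <- do.call(rbind, lapply(seq_len(nl), function(l) {
    sub <- copies[copies$locus == l, ]
    data.frame(locus = l, start = min(sub$start), end = max(sub$end),
               comp = comp[l])
  }))

  fams <- list()
  for (cp in unique(locus_extent$comp)) {
    loci <- locus_extent[locus_extent$comp == cp, ]
    if (nrow(loci) < 2L) next
    fam <- family_core(loci, copies, pairs)
    if (is.null(fam) || fam$core_length < min_core) next
    fam$molecule <- pairs$molecule[1L]
    fams[[length(fams) + 1L]] <- fam
  }
  if (length(fams) == 0L) return(list())
  ord <- order(-vapply(fams, `[[`, 0L, "core_length"))
  fams <- fams[ord]
  for (i in seq_along(fams)) {
    fams[[i]]$id <- paste0("R", i)
    class(fams[[i]]) <- "repeat_family"
  }
  names(fams) <- vapply(fams, `[[`, "", "id")
  fams
}

## core/extension geometry for one family (one connected locus set)
family_core <- function(loci, copies, pairs) {
  ref <- loci$locus[which.max(loci$end - loci$start)]
  ref_ext <- loci[loci$locus == ref, ]
  others <- setdiff(loci$locus, ref)

  ## for each non-reference locus pick its longest direct pair with ref
  links <- list()
  for (b in others) {
    cand <- NULL
    for (p in unique(copies$pair)) {
      lc <- copies[copies$pair == p, ]
      l1 <- lc$locus[lc$side == 1L]; l2 <- lc$locus[lc$side == 2L]
      if ((l1 == ref && l2 == b) || (l1 == b && l2 == ref)) {
        ref_side <- if (l1 == ref) 1L else 2L
        len <- pairs$length[p]
        if (is.null(cand) || len > cand$len)
          cand <- list(pair = p, ref_side = ref_side, len = len)
      }
    }
    if (is.null(cand)) return(NULL)  # no direct link; unsupported topology
    links[[as.character(b)]] <- cand
  }

  ## core on the reference = intersection of ref-side pair intervals
  ca <- ref_ext$start; cb <- ref_ext$end
  for (lk in links) {
    p <- pairs[lk$pair, ]
    rs <- if (lk$ref_side == 1L) p$start1 else p$start2
    re <- rs + p$length
    ca <- max(ca, rs); cb <- min(cb, re)
  }
  if (cb <= ca) return(NULL)

  rows <- list(data.frame(locus = ref, start = ref_ext$start,
                          end = ref_ext$end, left_ext = ca - ref_ext$start,
                          right_ext = ref_ext$end - cb, reference = TRUE))
  for (b in others) {
    lk <- links[[as.character(b)]]
    p <- pairs[lk$pair, ]
    if (lk$ref_side == 1L) {
      rs <- p$start1; bs <- p$start2
    } else {
      rs <- p$start2; bs <- p$start1
    }
    re <- rs + p$length
    ext <- loci[loci$locus == b, ]
    if (p$orientation == "direct") {
      core_b <- c(ca + (bs - rs), cb + (bs - rs))
    } else {
      core_b <- c(bs + (re - cb), bs + (re - ca))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus = b, start = ext$start, end = ext$end,
      left_ext = max(0L, core_b[1L] - ext$start),
      right_ext = max(0L, ext$end - core_b[2L]), reference = FALSE)
  }
  cdf <- do.call(rbind, rows)
  rownames(cdf) <- NULL
  list(id = NA_character_, core_length = cb - ca,
       core = c(start = ca, end = cb), copies = cdf)
}

#' @export
print.repeat_family <- function(x, ...) {
  cat(sprintf("<repeat_family> %s on %s: %d copies, core %s bp\n",
              x$id, x$molecule, nrow(x$copies),
              format(x$core_length, big.mark = ",")))
  print(x$copies, row.names = FALSE)
  invisible(x)
}
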