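#' Build reference and recombinant junction sequences for one repeat
#'
#' For every conformation, every occurrence of the repeat is extracted
#' together with \code{flank} bases on each side (wrap-aware).  Junctions
#' from the reference conformation are labeled \code{ref}, all others
#' \code{alt}.  Junction strings identical (up to reverse complement)
#' across labels cannot discriminate conformations and are dropped as
#' uninformative; the assay is flagged uninformative when nothing
#' discriminating remains.
#'
#' @param cset a \code{conformation_set} from [enumerate_conformations()].
#' @param event_id id of the event (repeat) whose junctions to build, as
#'   in the events table used for enumeration.
#' @param flank flank length on each side (bases).
#' @param min_flank_cov minimum flank coverage a spanning read must reach
#'   on both sides to be counted (bases).
#' @return object of class \code{junction_assay}.
#' @export
build_junctions <- function(cset, event_id, flank = 1000L,
                            min_flank_cov = 100L) {
  stopifnot(inherits(cset, "conformation_set"))
  run <- cset$segments$runs[[event_id]]
  if (is.null(run)) stop("unknown event id: ", event_id)
  segs <- cset$segments$segs
  rep_len <- sum(segs$end[run$copy1] - segs$start[run$copy1])
  L <- cset$segments$L
  ## flanks must not reach into the other copy on the reference circle
  s1 <- segs$start[run$copy1[1L]]; s2 <- segs$start[run$copy2[1L]]
  gap1 <- (s2 - (s1 + rep_len)) %% L
  gap2 <- (s1 - (s2 + rep_len)) %% L
  if (flank > min(gap1, gap2))
    stop("flank (", flank, ") exceeds the smallest arc between copies (",
         min(gap1, gap2), "); junctions would overlap the other copy")

  rows <- list()
  for (conf in cset$conformations) {
    is_ref <- conf$id == cset$reference_id
    mols <- realize_conformation(cset, conf$id)
    for (cp in c("copy1", "copy2")) {
      occ <- locate_run(conf$molecules, run[[cp]])
      if (is.null(occ)) next
      v <- conf$molecules[[occ$mol]]
      lens <- segs$end[abs(v)] - segs$start[abs(v)]
      base_at <- if (occ$at == 1L) 0L else sum(lens[seq_len(occ$at - 1L)])
      mol <- mols[[occ$mol]]
      if (mol$length < rep_len + 2L * flank) next
      jseq <- extract_seq(mol, interval(
        (base_at - flank) %% mol$length,
        base_at + rep_len + flank, L = mol$length))
      rows[[length(rows) + 1L]] <- data.frame(
        seq = jseq, label = if (is_ref) "ref" else "alt",
        conformation = conf$id, copy = cp, stringsAsFactors = FALSE)
    }
  }
  jdf <- do.call(rbind, rows)
  ## dedup under reverse complement; cross-label strings are uninformative
  key <- vapply(jdf$seq, function(s) min(s, revcomp(s)), "")
  agg <- split(seq_len(nrow(jdf)), key)
  keep <- lapply(agg, function(ix) {
    labs <- unique(jdf$label[ix])
    data.frame(seq = jdf$seq[ix[1L]],
               label = if (length(labs) == 1L) labs else "uninformative",
               conformations = paste(unique(substr(
                 jdf$conformation[ix], 1L, 8L)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  jd <- do.call(rbind, keep)
  jd <- jd[jd$label != "uninformative", , drop = FALSE]
  informative <- nrow(jd) > 0L && all(c("ref", "alt") %in% jd$label)
  if (nrow(jd) > 0L)
    jd$name <- sprintf("%s.j%02d", event_id, seq_len(nrow(jd)))
  structure(list(event = event_id, repeat_length = rep_len, flank = flank,
                 min_flank_cov = min_flank_cov, junctions = jd,
                 informative = informative,
                 ref_count = NA_integer_, alt_count = NA_integer_),
            class = "junction_assay")
}

#' @export
print.junction_assay <- function(x, ...) {
  cat(sprintf("<junction_assay> %s: repeat %d bp, flank %d bp, %d junction(s)%s\n",
              x$event, x$repeat_length, x$flank, nrow(x$junctions),
              if (!x$informative) " [uninformative]" else ""))
  if (!is.na(x$ref_count)) {
    f <- estimate_frequency(x)
    if (isTRUE(f$undefined)) {
      cat("  counts: ref", x$ref_count, "alt", x$alt_count,
          "(frequency undefined)\n")
    } else {
      cat(sprintf("  counts: ref %d alt %d  frequency %.3f [%.3f, %.3f]\n",
                  x$ref_count, x$alt_count, f$frequency, f$ci[1L], f$ci[2L]))
    }
  }
  invisible(x)
}

#' Tally long reads spanning junctions
#'
#' A read supports a junction if and only if its alignment covers the
#' entire repeat copy and at least \code{min_flank_cov} bases of BOTH
#' flanks.  Two ingestion paths are provided: the internal matcher (raw
#' reads; exact k-mer anchoring on both strands followed by projection of
#' the read extent along the modal anchor diagonal) and external PAF
#' alignments against the junction references.  A read matching several
#' junctions is assigned to its best-scoring one; ties are discarded.
#'
#' @param reads named character vector of read sequences (ignored when
#'   \code{paf} is given).
#' @param assay a \code{junction_assay} from [build_junctions()].
#' @param paf optional PAF alignment table (path or data.frame from
#'   [read_paf()]) targeting the junction names.
#' @param k anchor k-mer length for the internal matcher.
#' @param stride distance between successive anchors along a read.
#' @param min_anchors minimum anchors on the modal diagonal.
#' @return the assay with per-junction and pooled ref/alt counts filled.
#' @export
tally_support <- function(reads = NULL, assay, paf = NULL, k = 15L,
                          stride = 25L, min_anchors = 3L) {
  stopifnot(inherits(assay, "junction_assay"))
  jd <- assay$junctions
  if (nrow(jd) == 0L) {
    assay$ref_count <- assay$alt_count <- 0L
    return(assay)
  }
  hits <- if (!is.null(paf)) paf_hits(paf, assay)
          else matcher_hits(reads, assay, k, stride, min_anchors)
  assay$junctions$count <- 0L
  if (!is.null(hits) && nrow(hits) > 0L) {
    ## best-scoring junction per read; ties discarded
    hits <- hits[order(hits$read, -hits$score), , drop = FALSE]
    best <- hits[!duplicated(hits$read), , drop = FALSE]
    tie <- tapply(hits$score, hits$read, function(s)
      sum(s == max(s)) > 1L)
    best <- best[!tie[best$read], , drop = FALSE]
    cnt <- table(best$junction)
    m <- match(assay$junctions$name, names(cnt))
    assay$junctions$count <- ifelse(is.na(m), 0L, as.integer(cnt[m]))
  }
  assay$ref_count <- sum(assay$junctions$count[assay$junctions$label == "ref"])
  assay$alt_count <- sum(assay$junctions$count[assay$junctions$label == "alt"])
  assay
}

## internal matcher: anchor k-mers at a stride, take the modal diagonal per
## (read, strand, junction), project the read extent along it
matcher_hits <- function(reads, assay, k, stride, min_anchors) {
  stopifnot(!is.null(reads), length(reads) > 0L)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  jd <- assay$junctions
  jidx <- do.call(rbind, lapply(seq_len(nrow(jd)), function(i) {
    s <- jd$seq[i]
    n <- nchar(s) - k + 1L
    data.table::data.table(kmer = substring(s, 1:n, 1:n + k - 1L),
                           jpos = 0:(n - 1L), junction = jd$name[i])
  }))
  rl <- nchar(reads)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(reads))))
  anchors <- lapply(seq_along(reads), function(i) {
    if (rl[i] < k) return(NULL)
    pos <- seq(0L, rl[i] - k, by = stride)
    data.table::data.table(
      read = names(reads)[i], rlen = rl[i],
      strand = rep(c("+", "-"), each = length(pos)),
      rpos = c(pos, pos),
      kmer = c(substring(reads[i], pos + 1L, pos + k),
               substring(rcs[i], pos + 1L, pos + k)))
  })
  A <- data.table::rbindlist(anchors)
  if (nrow(A) == 0L) return(NULL)
  H <- merge(A, jidx, by = "kmer", allow.cartesian = TRUE)
  if (nrow(H) == 0L) return(NULL)
  H$diag <- H$jpos - H$rpos
  ## cluster anchors into diagonal bands (tolerating indel drift) and
  ## score each read/strand/junction by its best band
  band <- 100L
  data.table::setorderv(H, c("read", "strand", "junction", "diag"))
  H[, cl := cumsum(c(1L, diff(diag) > band)),
    by = c("read", "strand", "junction")]
  grp <- H[, list(score = .N,
                  diag = as.integer(stats::median(diag)),
                  rlen = rlen[1L]),
           by = c("read", "strand", "junction", "cl")]
  data.table::setorderv(grp, c("read", "strand", "junction", "score"),
                        order = c(1L, 1L, 1L, -1L))
  grp <- grp[!duplicated(grp[, c("read", "strand", "junction")]), ]
  ## projected alignment span on the junction
  jlen <- stats::setNames(nchar(jd$seq), jd$name)
  span_lo <- pmax(0L, grp$diag)
  span_hi <- pmin(jlen[grp$junction], grp$diag + grp$rlen)
  lo_need <- assay$flank - assay$min_flank_cov
  hi_need <- assay$flank + assay$repeat_length + assay$min_flank_cov
  ok <- grp$score >= min_anchors & span_lo <= lo_need & span_hi >= hi_need
  grp <- grp[ok, ]
  if (nrow(grp) == 0L) return(NULL)
  ## strands pooled: keep the better strand per read/junction
  grp <- grp[order(grp$read, grp$junction, -grp$score), ]
  grp <- grp[!duplicated(grp[, c("read", "junction")]), ]
  as.data.frame(grp[, c("read", "junction", "score")])
}

paf_hits <- function(paf, assay) {
  if (is.character(paf)) paf <- read_paf(paf)
  jd <- assay$junctions
  unknown <- setdiff(unique(paf$tname), jd$name)
  if (length(unknown) > 0L)
    stop("alignment references unknown junction name(s): ",
         paste(unknown, collapse = ", "))
  lo_need <- assay$flank - assay$min_flank_cov
  hi_need <- assay$flank + assay$repeat_length + assay$min_flank_cov
  ok <- paf$tstart <= lo_need & paf$tend >= hi_need
  paf <- paf[ok, , drop = FALSE]
  if (nrow(paf) == 0L) return(NULL)
  data.frame(read = paf$qname, junction = paf$tname, score = paf$nmatch,
             stringsAsFactors = FALSE)
}

#' Read a PAF alignment table
#' @param path PAF file (tab-separated, first 12 standard columns used).
#' @return data.frame with the 12 standard PAF columns.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("qname", "qlen", "qstart", "qend", "strand",
            "tname", "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          fill = TRUE, comment.char = "",
                          col.names = paste0("V", 1:18))[, 1:12]
  names(df) <- cols
  df
}

#' Recombination frequency with Wilson 95 percent interval
#'
#' Frequency is the fraction of informative spanning reads supporting the
#' recombinant adjacency, \code{alt / (alt + ref)}.  The Wilson score
#' interval is used rather than the Wald interval for its sane behavior
#' at frequencies near 0 and 1 with small counts.
#'
#' @param assay a tallied \code{junction_assay}, or \code{NULL} when
#'   \code{ref} and \code{alt} are given directly.
#' @param ref,alt optional direct counts.
#' @param conf confidence level.
#' @return list with \code{frequency}, \code{ci} (length 2), \code{ref},
#'   \code{alt}; or \code{undefined = TRUE} when no reads were counted.
#' @export
estimate_frequency <- function(assay = NULL, ref = NULL, alt = NULL,
                               conf = 0.95) {
  if (!is.null(assay)) {
    stopifnot(inherits(assay, "junction_assay"))
    ref <- assay$ref_count; alt <- assay$alt_count
  }
  if (is.na(ref) || is.na(alt)) stop("counts not tallied yet")
  n <- ref + alt
  if (n == 0L) return(list(undefined = TRUE, ref = ref, alt = alt))
  list(undefined = FALSE, frequency = alt / n,
       ci = wilson_interval(alt, n, conf), ref = ref, alt = alt)
}

#' Wilson score interval for a binomial proportion
#' @param x successes.
#' @param n trials.
#' @param conf confidence level.
#' @return numeric vector \code{c(low, high)}.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Majority-rule consensus of per-gene multiple alignments
#'
#' Per-column majority base; columns whose majority character is a gap are
#' dropped; ties are broken to the alphabetically first base with a
#' warning reporting the number of tied columns.
#'
#' @param alignments list of character vectors, each an alignment of >= 2
#'   equal-length rows (gaps as \code{-}).
#' @return character vector of consensus sequences, one per alignment.
#' @export
build_cds_consensus <- function(alignments) {
  if (is.character(alignments)) alignments <- list(alignments)
  vapply(alignments, function(rows) {
    if (length(rows) < 2L) stop("alignment needs >= 2 rows")
    if (length(unique(nchar(rows))) != 1L) stop("ragged alignment")
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(rows))
    keep_rows <- intersect(c("A", "C", "G", "T", "-"), rownames(cm))
    cm <- cm[keep_rows, , drop = FALSE]
    top <- apply(cm, 2L, function(col) {
      mx <- max(col)
      winners <- rownames(cm)[col == mx]
      base_winners <- setdiff(winners, "-")
      if ("-" %in% winners && col["-"] == mx &&
          (length(base_winners) == 0L || col["-"] > max(col[base_winners])))
        return(NA_character_)
      c(sort(base_winners)[1L], length(base_winners) > 1L)[1L]
    })
    ties <- apply(cm, 2L, function(col) {
      base <- col[setdiff(rownames(cm), "-")]
      sum(base == max(base)) > 1L && max(base) >= max(col)
    })
    if (any(ties & !is.na(top)))
      warning(sum(ties & !is.na(top)), " tied column(s) broken to the ",
              "alphabetically first base")
    paste(top[!is.na(top)], collapse = "")
  }, "")
}

#' Recruit reads sharing k-mers with a reference set
#'
#' A read is recruited when at least \code{min_shared} of its canonical
#' (strand-insensitive) k-mers occur in the reference k-mer set.  Used to
#' pull organelle reads out of a whole-cell long-read pool using conserved
#' coding sequences as bait.
#'
#' @param reads named character vector of reads.
#' @param references character vector of reference (consensus) sequences.
#' @param k k-mer length.
#' @param min_shared minimum shared fraction of read k-mers.
#' @return the recruited subset of \code{reads}.
#' @export
recruit_reads <- function(reads, references, k = 15L, min_shared = 0.1) {
  if (length(references) == 0L || all(!nzchar(references)))
    stop("empty reference set")
  if (any(nchar(reads) < k))
    stop("k (", k, ") larger than the shortest read")
  ref_set <- unique(unlist(lapply(references, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    canonical_kmers(substring(s, 1:n, 1:n + k - 1L))
  })))
  shared <- vapply(reads, function(s) {
    n <- nchar(s) - k + 1L
    km <- canonical_kmers(substring(s, 1:n, 1:n + k - 1L))
    mean(km %in% ref_set)
  }, 0)
  reads[shared >= min_shared]
}

canonical_kmers <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}
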