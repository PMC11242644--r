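#' Classify recombination events mediated by large repeats
#'
#' On a circular molecule, homologous recombination between the two copies
#' of a repeat has a topological outcome fixed by the copy orientation:
#' same-direction (direct) copies split the circle into two smaller
#' circles (fission), opposite-direction (inverted) copies reverse the
#' intervening segment (inversion).  Repeats above ~1 kb are the ones that
#' recombine at appreciable frequency, hence the default threshold.
#'
#' @param molecule a \code{circseq}.
#' @param repeats a \code{repeat_pairs} data.frame located on
#'   \code{molecule}.
#' @param min_len minimum repeat length mediating an event (bases).
#' @return data.frame with one row per qualifying pair: \code{event},
#'   \code{type} (\code{fission}/\code{inversion}) and the copy
#'   coordinates.
#' @export
classify_events <- function(molecule, repeats, min_len = 1000L) {
  stopifnot(inherits(molecule, "circseq"))
  if (nrow(repeats) > 0L && any(repeats$molecule != molecule$id))
    stop("repeat pair references a different molecule than '",
         molecule$id, "'")
  sel <- repeats[repeats$length >= min_len, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(event = character(), type = character(),
                      start1 = integer(), start2 = integer(),
                      length = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  data.frame(event = paste0("E", seq_len(nrow(sel))),
             type = ifelse(sel$orientation == "direct",
                           "fission", "inversion"),
             start1 = sel$start1, start2 = sel$start2,
             length = sel$length, orientation = sel$orientation,
             stringsAsFactors = FALSE)
}

#' Fission of a circle at a direct repeat pair
#'
#' Recombination between direct copies at \code{[a,b)} and \code{[c,d)}
#' divides the molecule into two circles, cut at the two copy starts:
#' child 1 spans \code{[a,c)} and child 2 spans \code{[c,a)}, so each
#' child retains exactly one full repeat copy and the child lengths sum
#' to the parent length.
#'
#' @param circle a circular \code{circseq}.
#' @param copy1,copy2 \code{interval}s of the two (disjoint) direct copies.
#' @return list of two \code{circseq} children.
#' @export
apply_fission <- function(circle, copy1, copy2) {
  stopifnot(inherits(circle, "circseq"), circle$topology == "circular")
  L <- circle$length
  l1 <- interval_width(copy1, L); l2 <- interval_width(copy2, L)
  if (circ_overlap(copy1$start, l1, copy2$start, l2, L) > 0L)
    stop("repeat copies overlap; tandem-like pairs cannot mediate fission")
  a <- copy1$start; c0 <- copy2$start
  child1 <- circseq(paste0(circle$id, ".f1"),
                    extract_seq(circle, interval(a, c0, L = L)), "circular")
  child2 <- circseq(paste0(circle$id, ".f2"),
                    extract_seq(circle, interval(c0, a, L = L)), "circular")
  list(child1, child2)
}

#' Fuse two circles at a shared repeat copy (inverse of fission)
#'
#' @param child1,child2 circular \code{circseq} children.
#' @param start1,start2 0-based start of the shared repeat copy on each
#'   child.
#' @return one circular \code{circseq}; a rotation of the original parent
#'   when the children came from [apply_fission()].
#' @export
apply_fusion <- function(child1, child2, start1 = 0L, start2 = 0L) {
  s1 <- seq_rotate(child1, start1)
  s2 <- seq_rotate(child2, start2)
  circseq(paste0(child1$id, "+", child2$id),
          paste0(s1$residues, s2$residues), "circular")
}

#' Inversion of the segment between an inverted repeat pair
#'
#' Recombination between inverted copies reverse-complements the arc
#' strictly between them: with copies at \code{[a,b)} and \code{[c,d)}
#' (copy1 the lower-coordinate copy), the arc \code{[b,c)} is inverted in
#' place and both repeat copies are left untouched.  Inverting the
#' complementary arc instead yields the same molecule up to
#' rotation/reflection.  Length and base composition are conserved and
#' the operation is an involution.
#'
#' @param circle a circular \code{circseq}.
#' @param copy1,copy2 \code{interval}s of the two (disjoint) inverted
#'   copies; \code{copy1} is the lower-coordinate copy.
#' @return a circular \code{circseq} of the same length.
#' @export
apply_inversion <- function(circle, copy1, copy2) {
  stopifnot(inherits(circle, "circseq"), circle$topology == "circular")
  L <- circle$length
  l1 <- interval_width(copy1, L); l2 <- interval_width(copy2, L)
  if (circ_overlap(copy1$start, l1, copy2$start, l2, L) > 0L)
    stop("repeat copies overlap; cannot invert between them")
  ## rotate so copy1 starts at 0; invert [l1, c0); rotate back
  shift <- copy1$start
  rot <- seq_rotate(circle, shift)
  c0 <- (copy2$start - shift) %% L
  mid <- extract_seq(rot, interval(l1, c0, L = L))
  res <- paste0(substr(rot$residues, 1L, l1),
                revcomp(mid),
                substr(rot$residues, c0 + 1L, L))
  out <- circseq(circle$id, res, "circular")
  seq_rotate(out, (L - shift) %% L)
}

## ---- segment-level conformation machinery --------------------------------
## A conformation is a set of circular molecules, each an ordered vector of
## signed elementary-segment ids over the reference.  Events never split a
## repeat copy, so every copy stays a contiguous signed run and every
## segment id occurs exactly once across the whole conformation (segment
## partition invariant).

## cut the reference circle at every event copy boundary
build_segments <- function(molecule, events) {
  L <- molecule$length
  bps <- sort(unique(c(0L, events$start1, events$start1 + events$length,
                       events$start2, events$start2 + events$length) %% L))
  if (any(events$start1 + events$length > L |
          events$start2 + events$length > L))
    stop("origin-crossing repeat copies: rotate the molecule first")
  segs <- data.frame(id = seq_along(bps), start = bps,
                     end = c(bps[-1L], L + bps[1L]))
  segs$seq <- vapply(seq_len(nrow(segs)), function(i)
    extract_seq(molecule, interval(segs$start[i], segs$end[i], L = L)), "")
  ## content token: orientation-insensitive identity of the segment sequence
  canon <- vapply(segs$seq, function(s) {
    rc <- revcomp(s)
    if (s <= rc) s else rc
  }, "")
  segs$token <- match(canon, unique(canon))
  segs$canon_fwd <- segs$seq == canon
  ## run of segment ids composing each event copy
  runs <- lapply(seq_len(nrow(events)), function(e) {
    r1 <- which(segs$start >= events$start1[e] &
                segs$end <= events$start1[e] + events$length[e])
    r2 <- which(segs$start >= events$start2[e] &
                segs$end <= events$start2[e] + events$length[e])
    list(copy1 = segs$id[r1], copy2 = segs$id[r2])
  })
  names(runs) <- events$event
  list(segs = segs, runs = runs, L = L)
}

new_conformation <- function(molecules, events_applied, parent, segctx) {
  id <- conformation_signature(molecules, segctx)
  structure(list(id = id, molecules = molecules,
                 events_applied = events_applied, parent = parent),
            class = "conformation")
}

## canonical rotation/reflection-invariant signature of a molecule set
conformation_signature <- function(molecules, segctx) {
  segs <- segctx$segs
  mol_sig <- vapply(molecules, function(v) {
    tok <- segs$token[abs(v)]
    eff <- sign(v) * ifelse(segs$canon_fwd[abs(v)], 1L, -1L)
    lab <- paste0(tok, ifelse(eff > 0L, "+", "-"))
    rlab <- paste0(tok[rev(seq_along(v))],
                   ifelse(eff[rev(seq_along(v))] > 0L, "-", "+"))
    n <- length(v)
    cands <- character(2L * n)
    for (r in seq_len(n)) {
      idx <- c(r:n, seq_len(r - 1L))
      cands[r] <- paste(lab[idx], collapse = ",")
      cands[n + r] <- paste(rlab[idx], collapse = ",")
    }
    min(cands)
  }, "")
  paste(sort(mol_sig), collapse = " | ")
}

## position and orientation of a copy's segment run inside a conformation;
## NULL when the run is no longer contiguous (event inapplicable)
locate_run <- function(molecules, run) {
  first <- run[1L]
  for (m in seq_along(molecules)) {
    v <- molecules[[m]]
    n <- length(v)
    pf <- which(v == first)
    pr <- which(v == -run[length(run)])
    if (length(pf) == 1L) {
      idx <- ((pf - 1L + seq_along(run) - 1L) %% n) + 1L
      if (all(v[idx] == run))
        return(list(mol = m, at = pf, len = length(run), sign = 1L))
    }
    if (length(pr) == 1L) {
      idx <- ((pr - 1L + seq_along(run) - 1L) %% n) + 1L
      if (all(v[idx] == -rev(run)))
        return(list(mol = m, at = pr, len = length(run), sign = -1L))
    }
  }
  NULL
}

## apply one recombination event to a conformation's molecule set;
## returns the new molecule list or NULL when inapplicable
apply_event_segments <- function(molecules, event_run, orientation) {
  o1 <- locate_run(molecules, event_run$copy1)
  o2 <- locate_run(molecules, event_run$copy2)
  if (is.null(o1) || is.null(o2)) return(NULL)
  if (o1$mol != o2$mol) return(NULL)  # intermolecular: out of scope
  v <- molecules[[o1$mol]]
  n <- length(v)
  ## effective relative direction of the two repeat-sequence occurrences
  same_dir <- if (orientation == "direct") o1$sign == o2$sign
              else o1$sign != o2$sign
  ## rotate so occurrence 1 starts at index 1
  rot <- c(o1$at:n, seq_len(o1$at - 1L))[seq_len(n)]
  w <- v[rot]
  at2 <- ((o2$at - o1$at) %% n) + 1L
  if (at2 <= o1$len) return(NULL)  # interleaved occurrences; degenerate
  if (same_dir) {
    child1 <- w[seq_len(at2 - 1L)]
    child2 <- w[at2:n]
    out <- molecules[-o1$mol]
    out[[length(out) + 1L]] <- child1
    out[[length(out) + 1L]] <- child2
  } else {
    lo <- o1$len + 1L
    hi <- at2 - 1L
    if (hi >= lo) w[lo:hi] <- -rev(w[lo:hi])
    out <- molecules
    out[[o1$mol]] <- w
  }
  out
}

#' Enumerate alternative conformations reachable by repeat-mediated events
#'
#' Breadth-first application of recombination events (from
#' [classify_events()]) up to \code{max_depth} successive events.  The
#' molecule content is tracked as oriented reference segments, so every
#' conformation's bases are exactly the reference bases (partition
#' invariant) and event outcomes (fission vs inversion) are decided by the
#' orientation the two copies actually have in the current molecule.
#' Conformations are deduplicated by a rotation- and strand-invariant
#' signature of the molecule set; ids are content-derived, so enumeration
#' order never changes them.
#'
#' @param molecule the reference circular \code{circseq}.
#' @param events data.frame from [classify_events()].
#' @param max_depth maximum number of successive events.
#' @param max_states combinatorial budget; exceeding it is an error
#'   advising a lower depth.
#' @return object of class \code{conformation_set}: list with
#'   \code{reference}, \code{segments}, and \code{conformations} (each
#'   with \code{id}, \code{molecules} as signed segment-id vectors,
#'   \code{events_applied}, \code{parent}).
#' @export
enumerate_conformations <- function(molecule, events, max_depth = 1L,
                                    max_states = 1000L) {
  stopifnot(inherits(molecule, "circseq"), max_depth >= 1L)
  if (nrow(events) == 0L) {
    segctx <- build_segments(molecule, events)
    ref <- new_conformation(list(segctx$segs$id), character(), NA, segctx)
    return(structure(list(reference = molecule, segments = segctx,
                          conformations = stats::setNames(list(ref), ref$id),
                          reference_id = ref$id),
                     class = "conformation_set"))
  }
  segctx <- build_segments(molecule, events)
  ref <- new_conformation(list(segctx$segs$id), character(), NA, segctx)
  seen <- stats::setNames(list(ref), ref$id)
  frontier <- list(ref)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (conf in frontier) {
      for (e in seq_len(nrow(events))) {
        run <- segctx$runs[[events$event[e]]]
        mols <- apply_event_segments(conf$molecules, run,
                                     events$orientation[e])
        if (is.null(mols)) next
        cand <- new_conformation(mols,
                                 c(conf$events_applied, events$event[e]),
                                 conf$id, segctx)
        if (!cand$id %in% names(seen)) {
          seen[[cand$id]] <- cand
          nxt[[length(nxt) + 1L]] <- cand
          if (length(seen) > max_states)
            stop("conformation budget exceeded (", max_states,
                 "); lower max_depth")
        }
      }
    }
    if (length(nxt) == 0L) break
    frontier <- nxt
  }
  structure(list(reference = molecule, segments = segctx,
                 conformations = seen, reference_id = ref$id),
            class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat(sprintf("<conformation_set> %d conformation(s) of %s\n",
              length(x$conformations), x$reference$id))
  for (conf in x$conformations) {
    lens <- vapply(conf$molecules, function(v)
      sum(x$segments$segs$end[abs(v)] - x$segments$segs$start[abs(v)]), 0)
    cat(sprintf("  %s: %d molecule(s) [%s bp]  events: %s\n",
                substr(conf$id_label %||% conf$id, 1L, 24L),
                length(conf$molecules),
                paste(format(lens, big.mark = ",", scientific = FALSE,
                             trim = TRUE), collapse = ", "),
                if (length(conf$events_applied))
                  paste(conf$events_applied, collapse = "+") else "none"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realize the molecules of one conformation as sequences
#'
#' @param cset a \code{conformation_set}.
#' @param id conformation id (default: the reference conformation).
#' @return list of circular \code{circseq}, one per molecule.
#' @export
realize_conformation <- function(cset, id = cset$reference_id) {
  stopifnot(inherits(cset, "conformation_set"))
  conf <- cset$conformations[[id]]
  if (is.null(conf)) stop("unknown conformation id")
  segs <- cset$segments$segs
  lapply(seq_along(conf$molecules), function(m) {
    v <- conf$molecules[[m]]
    parts <- vapply(v, function(sid) {
      s <- segs$seq[abs(sid)]
      if (sid < 0L) revcomp(s) else s
    }, "")
    circseq(paste0(cset$reference$id, ".c", substr(conf$id, 1L, 8L),
                   ".m", m),
            paste(parts, collapse = ""), "circular")
  })
}

#' Molecule lengths of every conformation
#' @param cset a \code{conformation_set}.
#' @return named list of integer vectors of molecule lengths (bases).
#' @export
conformation_lengths <- function(cset) {
  segs <- cset$segments$segs
  lapply(cset$conformations, function(conf)
    vapply(conf$molecules, function(v)
      sum(segs$end[abs(v)] - segs$start[abs(v)]), 0))
}
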