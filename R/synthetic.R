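#' Configuration for the synthetic mitogenome simulator
#'
#' Defaults emulate a two-chromosome plant mitogenome of the size and
#' composition reported for water-primrose species: two circular
#' molecules of ~545 kb and ~167 kb at 45.2% GC, long reads of mean
#' length ~4.9 kb, and plastid-derived insertions approaching 8% of the
#' genome.  Every stochastic quantity is drawn under \code{seed}, so a
#' fixed seed fixes every emitted byte.
#'
#' @param molecule_lengths background lengths (bases) of the circular
#'   molecules before any insertion.
#' @param gc target GC fraction of the i.i.d. background.
#' @param repeats list of planted repeat specs.  A plain spec is
#'   \code{list(length=, orientation="direct"|"inverted", copies=2,
#'   molecule=1, positions=NULL)}; a family spec is \code{list(family=TRUE,
#'   core=, left=, right=, extension=0, molecule=1, positions=NULL)} and
#'   plants three copies (core+extension+right, left+core,
#'   left+core+extension+right).
#' @param mtpt plastid-insertion spec: \code{list(count=, length_range=,
#'   divergence=, lengths=NULL)}; explicit \code{lengths} override
#'   \code{count}/\code{length_range}.
#' @param read_model \code{list(n=, mean=, sd=, min=, sub_rate=,
#'   indel_rate=)}.
#' @param weights probability vector over conformations (must sum to 1).
#' @param min_gap minimum distance kept between planted features (bases).
#' @param seed integer seed driving all randomness.
#' @return list of class \code{sim_config}.
#' @export
simulation_config <- function(molecule_lengths = c(545000L, 167000L),
                              gc = 0.452,
                              repeats = list(),
                              mtpt = list(count = 24L,
                                          length_range = c(147L, 8051L),
                                          divergence = 0.02),
                              read_model = list(n = 1000L, mean = 4944,
                                                sd = 2500, min = 300L,
                                                sub_rate = 0.01,
                                                indel_rate = 0.002),
                              weights = 1,
                              min_gap = 2500L,
                              seed = 1L) {
  stopifnot(all(molecule_lengths >= 1L), gc >= 0, gc <= 1)
  if (abs(sum(weights) - 1) > 1e-9) stop("conformation weights must sum to 1")
  rates <- c(read_model$sub_rate, read_model$indel_rate,
             mtpt$divergence %||% 0)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(molecule_lengths = as.integer(molecule_lengths), gc = gc,
                 repeats = repeats, mtpt = mtpt, read_model = read_model,
                 weights = weights, min_gap = as.integer(min_gap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_residues <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## sample a non-overlapping placement start, away from existing features
place_feature <- function(len, L, occupied, min_gap, retries = 200L) {
  for (i in seq_len(retries)) {
    s <- sample.int(L - len, 1L) - 1L
    lo <- s - min_gap; hi <- s + len + min_gap
    if (!any(occupied$start < hi & occupied$end > lo)) return(s)
  }
  stop("could not place a ", len, " bp feature without overlap after ",
       retries, " retries")
}

#' Generate a ground-truthed synthetic mitogenome
#'
#' Draws i.i.d. background residues at the configured GC and plants the
#' configured repeats as exact copies (direct) or reverse-complement
#' copies (inverted) at non-overlapping, non-origin-crossing loci by
#' overwriting background.  Every planted feature is recorded in the
#' ground truth.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{molecules} (list of \code{circseq}) and
#'   \code{truth} (list with \code{repeats} pair table and
#'   \code{families} descriptors).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    mols <- lapply(seq_along(config$molecule_lengths), function(i)
      random_residues(config$molecule_lengths[i], config$gc))
    occupied <- lapply(mols, function(x)
      data.frame(start = integer(), end = integer()))
    pair_rows <- list()
    fams <- list()
    for (spec in config$repeats) {
      mi <- spec$molecule %||% 1L
      L <- nchar(mols[[mi]])
      if (isTRUE(spec$family)) {
        core <- random_residues(spec$core, config$gc)
        left <- random_residues(spec$left %||% 0L, config$gc)
        right <- random_residues(spec$right %||% 0L, config$gc)
        ext <- random_residues(spec$extension %||% 0L, config$gc)
        copies <- c(paste0(core, ext, right),       # core + right arm
                    paste0(left, core),             # left arm + core
                    paste0(left, core, ext, right)) # both arms
        starts <- integer(3L)
        for (ci in 1:3) {
          len <- nchar(copies[ci])
          s <- spec$positions[ci] %||%
            place_feature(len, L, occupied[[mi]], config$min_gap)
          starts[ci] <- s
          substr(mols[[mi]], s + 1L, s + len) <- copies[ci]
          occupied[[mi]] <- rbind(occupied[[mi]],
                                  data.frame(start = s, end = s + len))
        }
        lens <- nchar(copies)
        nl <- nchar(left); nc <- nchar(core); ne <- nchar(ext)
        ## expected maximal pairwise matches implied by the arm structure
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          molecule = mi,
          start1 = c(starts[1L], starts[1L], starts[2L]),
          start2 = c(starts[2L] + nl, starts[3L] + nl, starts[3L]),
          length = c(nc, nc + ne + nchar(right), nl + nc),
          orientation = "direct")
        fams[[length(fams) + 1L]] <- list(
          molecule = mi, core_length = nc,
          copies = data.frame(start = starts, end = starts + lens,
                              left_ext = c(0L, nl, nl),
                              right_ext = c(ne + nchar(right), 0L,
                                            ne + nchar(right))))
      } else {
        ncop <- spec$copies %||% 2L
        unit <- random_residues(spec$length, config$gc)
        starts <- integer(ncop)
        for (ci in seq_len(ncop)) {
          s <- spec$positions[ci] %||%
            place_feature(spec$length, L, occupied[[mi]], config$min_gap)
          starts[ci] <- s
          put <- if (spec$orientation == "inverted" && ci > 1L)
            revcomp(unit) else unit
          substr(mols[[mi]], s + 1L, s + spec$length) <- put
          occupied[[mi]] <- rbind(occupied[[mi]],
                                  data.frame(start = s,
                                             end = s + spec$length))
        }
        cmb <- utils::combn(ncop, 2L)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          molecule = mi, start1 = starts[cmb[1L, ]],
          start2 = starts[cmb[2L, ]], length = spec$length,
          orientation = if (spec$orientation == "inverted" &&
                            any(cmb > 1L)) {
            ifelse(cmb[1L, ] == 1L | cmb[2L, ] == 1L,
                   spec$orientation, "direct")
          } else spec$orientation)
      }
    }
    molecules <- lapply(seq_along(mols), function(i)
      circseq(paste0("M", i), mols[[i]], "circular"))
    truth <- list(
      repeats = if (length(pair_rows)) do.call(rbind, pair_rows)
                else data.frame(molecule = integer(), start1 = integer(),
                                start2 = integer(), length = integer(),
                                orientation = character()),
      families = fams)
    list(molecules = molecules, truth = truth)
  })
}

## substitute bases at a fixed per-base rate; returns the mutated string
mutate_substitutions <- function(s, rate) {
  if (rate <= 0) return(s)
  r <- charToRaw(s)
  n <- length(r)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(s)
  bases <- charToRaw("ACGT")
  cur <- match(r[hit], bases)           # NA for N: left untouched
  ok <- !is.na(cur)
  hit <- hit[ok]; cur <- cur[ok]
  if (length(hit) == 0L) return(s)
  off <- sample.int(3L, length(hit), replace = TRUE)
  r[hit] <- bases[((cur - 1L + off) %% 4L) + 1L]
  rawToChar(r)
}

#' Insert plastid-derived fragments into mitochondrial molecules
#'
#' Each fragment is copied from a random plastome interval (random
#' strand), mutated at the configured per-base divergence, and inserted
#' at a random position outside previously planted features.  Ground
#' truth records source and destination intervals and the realized
#' identity; previously recorded truth coordinates are shifted past the
#' insertions.  Total molecule length grows by exactly the summed
#' fragment lengths.
#'
#' @param molecules list of \code{circseq}.
#' @param plastome a \code{circseq} donor.
#' @param spec list with \code{lengths} (explicit fragment lengths) or
#'   \code{count} + \code{length_range}, plus \code{divergence}.
#' @param truth optional truth list from [generate_genome()]; its
#'   coordinates are shifted and the \code{mtpt} table added.
#' @param seed integer seed.
#' @param min_gap minimum distance from existing features.
#' @return list with updated \code{molecules} and \code{truth}.
#' @export
insert_plastid_fragments <- function(molecules, plastome, spec,
                                     truth = NULL, seed = 1L,
                                     min_gap = 200L) {
  stopifnot(inherits(plastome, "circseq"))
  withr::with_seed(seed, {
    lens <- spec$lengths %||%
      sample(spec$length_range[1L]:spec$length_range[2L], spec$count,
             replace = TRUE)
    lens <- as.integer(lens)
    tot_len <- sum(vapply(molecules, seq_length, 0L))
    if (sum(lens) > 0.5 * tot_len)
      stop("requested insertion fraction exceeds 50% of the genome; ",
           "implausible configuration")
    if (max(lens) > plastome$length)
      stop("plastome shorter than the longest requested fragment")
    div <- spec$divergence %||% 0
    mol_lens <- vapply(molecules, seq_length, 0L)
    target <- sample(seq_along(molecules), length(lens), replace = TRUE,
                     prob = mol_lens / sum(mol_lens))

    ## forbidden intervals per molecule: planted repeat copies
    forbid <- lapply(seq_along(molecules), function(i) {
      out <- data.frame(start = integer(), end = integer())
      if (!is.null(truth) && nrow(truth$repeats) > 0L) {
        tr <- truth$repeats[truth$repeats$molecule == i, , drop = FALSE]
        if (nrow(tr) > 0L)
          out <- data.frame(start = c(tr$start1, tr$start2),
                            end = c(tr$start1, tr$start2) + tr$length)
      }
      for (f in (truth$families %||% list()))
        if (f$molecule == i)
          out <- rbind(out, f$copies[, c("start", "end")])
      out
    })

    plan <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      mi <- target[i]
      L <- molecules[[mi]]$length
      src <- sample.int(plastome$length, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      frag0 <- extract_seq(plastome,
                           interval(src, src + lens[i],
                                    strand = strand, L = plastome$length))
      frag <- mutate_substitutions(frag0, div)
      ident <- mean(strsplit(frag, "")[[1L]] == strsplit(frag0, "")[[1L]])
      at <- place_feature(1L, L, forbid[[mi]], min_gap)
      plan[[i]] <- list(mol = mi, at = at, frag = frag, len = lens[i],
                        src = src, strand = strand, identity = ident)
    }

    ## apply insertions per molecule in descending position order
    mtpt_rows <- list()
    for (mi in seq_along(molecules)) {
      items <- Filter(function(p) p$mol == mi, plan)
      if (length(items) == 0L) next
      ord <- order(-vapply(items, `[[`, 0L, "at"))
      s <- molecules[[mi]]$residues
      for (p in items[ord]) {
        s <- paste0(substr(s, 1L, p$at),
                    p$frag,
                    substr(s, p$at + 1L, nchar(s)))
      }
      molecules[[mi]] <- circseq(molecules[[mi]]$id, s, "circular")
      ## final coordinates: shift each insertion by earlier insertions
      ats <- vapply(items, `[[`, 0L, "at")
      for (j in seq_along(items)) {
        p <- items[[j]]
        shift <- sum(vapply(items, function(q)
          if (q$at < p$at) q$len else 0L, 0L))
        mtpt_rows[[length(mtpt_rows) + 1L]] <- data.frame(
          molecule = mi, start = p$at + shift, end = p$at + shift + p$len,
          src_start = p$src, src_end = p$src + p$len, strand = p$strand,
          length = p$len, identity = 100 * p$identity)
      }
      ## shift previously recorded truth features on this molecule
      if (!is.null(truth)) {
        shift_of <- function(pos) vapply(pos, function(x)
          x + sum(vapply(items, function(q)
            if (q$at <= x) q$len else 0L, 0L)), 0L)
        if (nrow(truth$repeats) > 0L) {
          on <- truth$repeats$molecule == mi
          truth$repeats$start1[on] <- shift_of(truth$repeats$start1[on])
          truth$repeats$start2[on] <- shift_of(truth$repeats$start2[on])
        }
        for (fi in seq_along(truth$families %||% list())) {
          if (truth$families[[fi]]$molecule != mi) next
          cp <- truth$families[[fi]]$copies
          w <- cp$end - cp$start
          cp$start <- shift_of(cp$start)
          cp$end <- cp$start + w
          truth$families[[fi]]$copies <- cp
        }
      }
    }
    if (is.null(truth)) truth <- list()
    truth$mtpt <- if (length(mtpt_rows)) do.call(rbind, mtpt_rows)
                  else data.frame()
    list(molecules = molecules, truth = truth)
  })
}

#' Simulate long reads from a mixture of conformations
#'
#' Each read picks a conformation by weight, a molecule proportional to
#' its length, a uniform start on the circle and a length from the
#' (truncated normal) model; substitutions are applied first, then
#' indels.  Ground-truth origin labels are returned alongside.
#'
#' @param conformation_molecules list over conformations; each element a
#'   list of circular \code{circseq} molecules.
#' @param weights probability vector over conformations.
#' @param read_model list with \code{n, mean, sd, min, sub_rate,
#'   indel_rate}.
#' @param seed integer seed.
#' @return list with \code{reads} (named character vector) and
#'   \code{truth} (data.frame of origin labels).
#' @export
simulate_reads <- function(conformation_molecules, weights, read_model,
                           seed = 1L) {
  stopifnot(length(conformation_molecules) >= 1L,
            length(weights) == length(conformation_molecules))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  n <- read_model$n
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    reads <- character(n)
    tr <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- sample.int(length(weights), 1L, prob = weights)
      mols <- conformation_molecules[[ci]]
      ml <- vapply(mols, seq_length, 0L)
      mi <- if (length(mols) == 1L) 1L
            else sample.int(length(mols), 1L, prob = ml / sum(ml))
      L <- ml[mi]
      len <- round(stats::rnorm(1L, read_model$mean, read_model$sd))
      len <- min(max(len, read_model$min), L)
      if (len < 1L) stop("read length model produced a length < 1")
      start <- sample.int(L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      raw <- extract_seq(mols[[mi]],
                         interval(start, start + len, strand = strand,
                                  L = L))
      mut <- mutate_substitutions(raw, read_model$sub_rate)
      mut <- mutate_indels(mut, read_model$indel_rate)
      reads[i] <- mut
      tr[[i]] <- data.frame(read = sprintf("sim%06d", i),
                            conformation = ci, molecule = mols[[mi]]$id,
                            start = start, strand = strand, length = len)
    }
    names(reads) <- sprintf("sim%06d", seq_len(n))
    list(reads = reads, truth = do.call(rbind, tr))
  })
}

mutate_indels <- function(s, rate) {
  if (rate <= 0) return(s)
  r <- charToRaw(s)
  n <- length(r)
  u <- stats::runif(n)
  del <- u < rate / 2
  ins <- u >= rate / 2 & u < rate
  ni <- sum(ins)
  if (ni == 0L && !any(del)) return(s)
  ins_bases <- charToRaw("ACGT")[sample.int(4L, ni, replace = TRUE)]
  ## interleave inserted bases just after their host positions
  ord <- order(c(seq_len(n), which(ins) + 0.5))
  vals <- c(r, ins_bases)[ord]
  keep <- c(!del, rep(TRUE, ni))[ord]
  rawToChar(vals[keep])
}

#' Simulate junction-spanning reads for a frequency study
#'
#' Targeted variant of [simulate_reads()] that only emits informative
#' reads: each read picks a conformation by weight, then one of that
#' conformation's repeat-copy loci uniformly, and a start position such
#' that the read covers the full repeat copy plus at least
#' \code{min_flank_cov} bases of both flanks.  Used to study how the
#' spanning-read frequency estimator recovers a planted conformation
#' mixture without paying for the ~99% of whole-genome reads that never
#' touch a junction.
#'
#' @param cset a \code{conformation_set}.
#' @param event_id the repeat event whose junctions are assayed.
#' @param weights probability vector over \code{cset$conformations}
#'   (reference first, then the others in storage order).
#' @param n number of reads.
#' @param read_model list with \code{mean, sd, min, sub_rate, indel_rate};
#'   lengths shorter than repeat + 2*min_flank_cov are resampled up.
#' @param min_flank_cov flank coverage the tally rule will require.
#' @param margin extra flank coverage guaranteed beyond
#'   \code{min_flank_cov}, so that alignment-boundary jitter from indels
#'   cannot push a simulated informative read below the rule.
#' @param seed integer seed.
#' @return list with \code{reads} and \code{truth} (conformation index
#'   per read).
#' @export
simulate_spanning_reads <- function(cset, event_id, weights, n,
                                    read_model, min_flank_cov = 100L,
                                    margin = 50L, seed = 1L) {
  stopifnot(inherits(cset, "conformation_set"))
  run <- cset$segments$runs[[event_id]]
  if (is.null(run)) stop("unknown event id: ", event_id)
  segs <- cset$segments$segs
  rep_len <- sum(segs$end[run$copy1] - segs$start[run$copy1])
  confs <- cset$conformations
  ord <- c(cset$reference_id, setdiff(names(confs), cset$reference_id))
  stopifnot(length(weights) == length(ord))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")

  ## repeat-copy loci (molecule realization + base interval) per conformation
  loci <- lapply(ord, function(id) {
    conf <- confs[[id]]
    mols <- realize_conformation(cset, id)
    out <- list()
    for (cp in c("copy1", "copy2")) {
      occ <- locate_run(conf$molecules, run[[cp]])
      if (is.null(occ)) next
      v <- conf$molecules[[occ$mol]]
      lens <- segs$end[abs(v)] - segs$start[abs(v)]
      base_at <- if (occ$at == 1L) 0L else sum(lens[seq_len(occ$at - 1L)])
      out[[length(out) + 1L]] <- list(mol = mols[[occ$mol]],
                                      start = base_at)
    }
    out
  })

  withr::with_seed(seed, {
    reads <- character(n)
    conf_of <- integer(n)
    cov <- min_flank_cov + margin   # guarantee coverage beyond the rule,
                                    # so indel drift cannot cross the edge
    min_len <- rep_len + 2L * cov
    for (i in seq_len(n)) {
      ci <- sample.int(length(weights), 1L, prob = weights)
      lc <- loci[[ci]][[sample.int(length(loci[[ci]]), 1L)]]
      L <- lc$mol$length
      len <- round(stats::rnorm(1L, read_model$mean, read_model$sd))
      len <- min(max(len, read_model$min, min_len + 10L), L)
      lo <- lc$start + rep_len + cov - len
      hi <- lc$start - cov
      start <- (lo + sample.int(hi - lo + 1L, 1L) - 1L) %% L
      strand <- sample(c("+", "-"), 1L)
      raw <- extract_seq(lc$mol, interval(start, (start + len) %% L,
                                          strand = strand, L = L))
      mut <- mutate_indels(mutate_substitutions(raw, read_model$sub_rate),
                           read_model$indel_rate)
      reads[i] <- mut
      conf_of[i] <- ci
    }
    names(reads) <- sprintf("jr%06d", seq_len(n))
    list(reads = reads,
         truth = data.frame(read = names(reads), conformation = conf_of))
  })
}
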