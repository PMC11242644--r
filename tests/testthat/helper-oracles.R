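# Independent brute-force oracles used to validate the package's
# algorithmic operations.  These deliberately share no code with the
# implementation: the repeat oracle scans every diagonal exhaustively
# with character vectors and which()-based run detection, the SSR oracle
# is a backreference regex, and the Ka/Ks oracle enumerates mutational
# pathways recursively.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
}

## maximal run length starting at each 0-based position of a circular
## logical vector (requires at least one FALSE)
.circ_run_len <- function(m, starts0) {
  L <- length(m)
  f <- which(!m) - 1L               # 0-based FALSE positions, sorted
  f2 <- c(f, f + L)
  ## first FALSE strictly after each start (starts are TRUE positions)
  f2[findInterval(starts0, f2) + 1L] - starts0
}

## exhaustive maximal exact pair enumeration on a circular sequence
oracle_repeats <- function(s, min_len, include_inverted = TRUE) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1L]]
  chd <- c(ch, ch)
  keys <- character()
  add <- function(a, b, len, orient) {
    lo <- min(a, b); hi <- max(a, b)
    keys <<- c(keys, paste(lo, hi, len, orient))
  }
  okch <- ch != "N"
  okd <- c(okch, okch)
  for (d in seq_len(L - 1L)) {
    other <- chd[(1L + d):(L + d)]
    m <- ch == other & okch & okd[(1L + d):(L + d)]
    if (!any(!m)) next                      # periodic circle; skip
    prev <- c(m[L], m[-L])
    starts <- which(m & !prev) - 1L
    if (length(starts) == 0L) next
    lens <- .circ_run_len(m, starts)
    keep <- lens >= min_len & lens < pmin(d, L - d)
    for (i in which(keep))
      add(starts[i], (starts[i] + d) %% L, lens[i], "direct")
  }
  if (include_inverted) {
    y <- rc_chr(s)
    yc <- strsplit(y, "")[[1L]]
    ycd <- c(yc, yc)
    oky <- yc != "N"
    okyd <- c(oky, oky)
    for (cc in 0:(L - 1L)) {
      m <- ch == ycd[(1L + cc):(L + cc)] & okch & okyd[(1L + cc):(L + cc)]
      if (!any(m) || !any(!m)) next
      prev <- c(m[L], m[-L])
      starts <- which(m & !prev) - 1L
      if (length(starts) == 0L) next
      lens <- .circ_run_len(m, starts)
      for (i in seq_along(starts)) {
        len <- lens[i]
        if (len < min_len) next
        a <- starts[i]
        j <- (L - ((a + cc) %% L) - len) %% L
        if (a == j) next
        ## circular overlap of [a,a+len) and [j,j+len)
        sep <- min((j - a) %% L, (a - j) %% L)
        if (sep < len) next
        add(a, j, len, "inverted")
      }
    }
  }
  sort(unique(keys))
}

repeat_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character())
  sort(paste(pairs$start1, pairs$start2, pairs$length, pairs$orientation))
}

## regex-backreference SSR oracle (linear strings)
oracle_ssrs <- function(s, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  is_periodic <- function(motif) {
    u <- nchar(motif)
    any(vapply(seq_len(u - 1L), function(p)
      u %% p == 0L && strrep(substr(motif, 1L, p), u %/% p) == motif,
      TRUE))
  }
  canon <- function(motif) {
    u <- nchar(motif)
    if (u == 1L) return(motif)
    min(substring(strrep(motif, 2L), 1:u, 1:u + u - 1L))
  }
  out <- character()
  n <- nchar(s)
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1+", u)
    off <- 0L                     # 0-based scan offset
    repeat {
      if (off >= n) break
      m <- regexpr(pat, substr(s, off + 1L, n), perl = TRUE)
      if (m < 0L) break
      st <- off + m               # 1-based match start in s
      len <- attr(m, "match.length")
      motif <- substr(s, st, st + u - 1L)
      if (u > 1L && is_periodic(motif)) {
        ## a periodic-motif match may hide an overlapping primitive-motif
        ## run in another phase: rescan from the next base
        off <- st
        next
      }
      copies <- len %/% u
      if (copies >= thresholds[u]) {
        out <- c(out, paste(st - 1L, u, copies, canon(motif)))
        ## adjacent maximal regions of the same unit can share up to
        ## u-1 bases; resume exactly where the next one may begin
        off <- st + len - u
      } else {
        ## a sub-threshold match may overlap a qualifying run in a
        ## different phase: rescan from the next base
        off <- st
      }
    }
  }
  sort(out)
}

ssr_keys <- function(rec) {
  if (nrow(rec) == 0L) return(character())
  sort(paste(rec$start, rec$unit, rec$copies, rec$motif))
}

## recursive pathway-enumeration oracle for Nei-Gojobori counts
GEN_CODE <- Biostrings::GENETIC_CODE

oracle_ng_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  syn <- 0
  for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- b
    if (GEN_CODE[[mut]] == GEN_CODE[[codon]]) syn <- syn + 1 / 3
  }
  syn
}

oracle_ng_pair <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0, blocked = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GEN_CODE[[nxt]] == "*" && nxt != c2) next
      step_syn <- GEN_CODE[[nxt]] == GEN_CODE[[cur]]
      walk(nxt, setdiff(remaining, p), sd + step_syn, nd + !step_syn)
    }
  }
  walk(c1, pos, 0, 0)
  if (length(paths) == 0L) {
    sd <- 0; nd <- 0
    for (p in pos) {
      x <- c1
      substr(x, p, p) <- substr(c2, p, p)
      if (GEN_CODE[[x]] != "*" && GEN_CODE[[x]] == GEN_CODE[[c1]])
        sd <- sd + 1 else nd <- nd + 1
    }
    return(c(sd = sd, nd = nd, blocked = 1))
  }
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1L]), nd = mean(m[, 2L]), blocked = 0)
}

oracle_ng <- function(s1, s2) {
  co1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  co2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  ok <- !grepl("[^ACGT]", co1) & !grepl("[^ACGT]", co2)
  ok <- ok & GEN_CODE[ifelse(ok, co1, "TTT")] != "*" &
             GEN_CODE[ifelse(ok, co2, "TTT")] != "*"
  co1 <- co1[ok]; co2 <- co2[ok]
  S <- mean(c(sum(vapply(co1, oracle_ng_sites, 0)),
              sum(vapply(co2, oracle_ng_sites, 0))))
  d <- vapply(seq_along(co1), function(i)
    oracle_ng_pair(co1[i], co2[i]), numeric(3L))
  list(S = S, N = 3 * length(co1) - S,
       Sd = sum(d["sd", ]), Nd = sum(d["nd", ]))
}

## random in-frame coding sequence without stop codons
rand_cds <- function(ncodons) {
  sense <- names(GEN_CODE)[GEN_CODE != "*"]
  paste(sample(sense, ncodons, replace = TRUE), collapse = "")
}

## strand-insensitive (double-stranded) base content
base_pair_counts <- function(s) {
  ct <- table(factor(strsplit(s, "")[[1L]],
                     levels = c("A", "C", "G", "T", "N")))
  c(AT = ct[["A"]] + ct[["T"]], GC = ct[["C"]] + ct[["G"]])
}
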