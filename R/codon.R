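#' Extract coding sequences from annotated molecules
#'
#' Splices exons in annotation order with strand applied per exon.
#' Trans-spliced genes (in plant mitochondria, typically nad1/nad2/nad5)
#' are assembled across molecules by grouping features on the gene name
#' and ordering by the exon-number qualifier.  Pseudogenes are excluded
#' unless asked for; a CDS whose spliced length is not divisible by 3 and
#' is not marked pseudo is excluded with a warning.
#'
#' @param molecules list of \code{circseq} (ids must match feature seqids).
#' @param features data.frame of CDS features as returned by [read_gff3()]
#'   or attached by the GenBank reader (columns
#'   \code{molecule|seqid,type,start,end,strand,gene,exon,pseudo}).  When
#'   \code{NULL}, features attached to the molecules are pooled.
#' @param include_pseudo keep pseudogenes.
#' @return list of coding sequences: each a list with \code{gene},
#'   \code{molecules}, \code{seq}, \code{pseudo}.
#' @export
extract_cds <- function(molecules, features = NULL, include_pseudo = FALSE) {
  if (inherits(molecules, "circseq")) molecules <- list(molecules)
  if (is.null(features)) {
    features <- do.call(rbind, lapply(molecules, function(m) {
      f <- attr(m, "features")
      if (is.null(f)) NULL else f
    }))
    if (is.null(features)) stop("no feature annotations found")
  }
  if ("seqid" %in% names(features) && !"molecule" %in% names(features))
    features$molecule <- features$seqid
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features")
  if (!"exon" %in% names(cds) || all(is.na(cds$exon)))
    cds$exon <- stats::ave(seq_len(nrow(cds)), cds$gene, FUN = seq_along)
  if (!"pseudo" %in% names(cds)) cds$pseudo <- FALSE
  mol_ids <- vapply(molecules, `[[`, "", "id")

  out <- list()
  for (g in unique(cds$gene)) {
    sub <- cds[cds$gene == g, , drop = FALSE]
    sub <- sub[order(sub$exon), , drop = FALSE]
    pseudo <- any(sub$pseudo)
    if (pseudo && !include_pseudo) next
    parts <- vapply(seq_len(nrow(sub)), function(i) {
      mi <- match(sub$molecule[i], mol_ids)
      if (is.na(mi)) stop("CDS of '", g, "' references unknown molecule '",
                          sub$molecule[i], "'")
      mol <- molecules[[mi]]
      extract_seq(mol, interval(sub$start[i], sub$end[i],
                                strand = sub$strand[i], L = mol$length))
    }, "")
    seq <- paste(parts, collapse = "")
    if (nchar(seq) %% 3L != 0L && !pseudo) {
      warning("CDS '", g, "' length ", nchar(seq),
              " not divisible by 3; excluded")
      next
    }
    out[[g]] <- list(gene = g, molecules = unique(sub$molecule),
                     seq = seq, pseudo = pseudo)
  }
  out
}

## the 64 codons in a fixed order, with their standard-code amino acids
CODONS <- names(Biostrings::GENETIC_CODE)
AA_OF <- Biostrings::GENETIC_CODE

split_codons <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3L == 0L)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Codon counts and relative synonymous codon usage (RSCU)
#'
#' Counts codons over the concatenation of the supplied coding sequences
#' and computes RSCU: the observed count of a codon divided by the mean
#' count of its synonymous family, i.e. \code{count * |F| / sum(F)}.
#' Families follow the standard genetic code (plant mitochondria use the
#' universal code); the three stop codons form one family, fed by the
#' terminal codon of each CDS.  Codons of an entirely unused family get
#' RSCU 0.
#'
#' @param cds list from [extract_cds()] (or character vector of in-frame
#'   sequences).
#' @param include_stops count terminal stop codons (and any other stop
#'   codons present in frame).
#' @return object of class \code{codon_usage_table}: list with
#'   \code{counts} (named 64-vector), \code{total}, \code{rscu}.
#' @export
codon_usage <- function(cds, include_stops = TRUE) {
  seqs <- if (is.character(cds)) cds else vapply(cds, `[[`, "", "seq")
  cod <- unlist(lapply(seqs, split_codons))
  cod <- cod[!grepl("[^ACGT]", cod)]
  if (!include_stops) cod <- cod[AA_OF[cod] != "*"]
  counts <- table(factor(cod, levels = CODONS))
  counts <- stats::setNames(as.integer(counts), CODONS)
  fam <- split(CODONS, AA_OF[CODONS])
  rscu <- stats::setNames(numeric(64L), CODONS)
  for (f in fam) {
    tot <- sum(counts[f])
    rscu[f] <- if (tot == 0L) 0 else counts[f] * length(f) / tot
  }
  structure(list(counts = counts, total = sum(counts), rscu = rscu),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table>", x$total, "codons\n")
  top <- sort(x$rscu[x$counts > 0L], decreasing = TRUE)
  cat("  highest RSCU:",
      paste(sprintf("%s=%.2f", names(top)[1:min(5, length(top))],
                    top[1:min(5, length(top))]), collapse = " "), "\n")
  invisible(x)
}

## ---- Nei-Gojobori (1986) with Jukes-Cantor correction --------------------

## per-position synonymous-site fraction of one codon: among the three
## possible substitutions at each position, the fraction preserving the
## amino acid; substitutions creating a stop count as nonsynonymous
syn_site_fractions <- function(codon) {
  aa <- AA_OF[[codon]]
  vapply(1:3, function(p) {
    alts <- setdiff(c("T", "C", "A", "G"), substr(codon, p, p))
    muts <- vapply(alts, function(b) {
      x <- codon
      substr(x, p, p) <- b
      AA_OF[[x]]
    }, "")
    sum(muts == aa) / 3
  }, 0)
}

## averaged Sd/Nd contribution of one codon pair over all minimal
## mutational pathways; pathways through stop codons are excluded, and
## when every pathway is blocked the differing positions are classified
## independently by single-site swaps (flagged)
pair_differences <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0, blocked = 0))
  perms <- list(list(1L), list(c(1L, 2L), c(2L, 1L)),
                list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))[[nd]]
  sds <- numeric(0); nds <- numeric(0)
  for (ord in perms) {
    cur <- c1
    sd <- 0; ndf <- 0; ok <- TRUE
    for (step in ord) {
      p <- pos[step]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (AA_OF[[nxt]] == "*" && nxt != c2) { ok <- FALSE; break }
      if (AA_OF[[nxt]] == AA_OF[[cur]]) sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, ndf) }
  }
  if (length(sds) > 0L)
    return(c(sd = mean(sds), nd = mean(nds), blocked = 0))
  ## all pathways blocked by stop intermediates
  sd <- 0; ndf <- 0
  for (p in pos) {
    x <- c1
    substr(x, p, p) <- substr(c2, p, p)
    if (AA_OF[[x]] != "*" && AA_OF[[x]] == AA_OF[[c1]]) sd <- sd + 1
    else ndf <- ndf + 1
  }
  c(sd = sd, nd = ndf, blocked = 1)
}

.pair_cache <- new.env(parent = emptyenv())

pair_differences_cached <- function(c1, c2) {
  key <- if (c1 <= c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- pair_differences(c1, c2)
  assign(key, val, envir = .pair_cache)
  val
}

#' Pairwise Ka/Ks by the Nei-Gojobori method with Jukes-Cantor correction
#'
#' Synonymous (S) and nonsynonymous (N) site counts are per-codon
#' synonymous-substitution fractions averaged over the two sequences;
#' synonymous/nonsynonymous differences (Sd, Nd) are averaged over all
#' minimal mutational pathways between each codon pair, excluding
#' pathways through stop codons.  Proportions pS = Sd/S and pN = Nd/N are
#' distance-corrected with Jukes-Cantor, d = -(3/4) ln(1 - (4/3) p).
#' Codon pairs containing gaps, N, or a stop codon are skipped and
#' tallied.  The statistic is symmetric in its arguments.
#'
#' @param cds1,cds2 aligned in-frame nucleotide strings of equal length
#'   (alignment is the caller's job; codon-aware alignment is out of
#'   scope).
#' @return object of class \code{kaks_result}: list with \code{S, N, Sd,
#'   Nd, pS, pN, Ks, Ka, ratio, codons_compared, codons_skipped,
#'   blocked_pairs} and \code{undefined} flags.
#' @export
nei_gojobori <- function(cds1, cds2) {
  s1 <- toupper(cds1); s2 <- toupper(cds2)
  if (nchar(s1) != nchar(s2)) stop("sequences must be aligned (equal length)")
  if (nchar(s1) %% 3L != 0L) stop("aligned length not divisible by 3")
  co1 <- split_codons(s1); co2 <- split_codons(s2)
  ok <- !grepl("[^ACGT]", co1) & !grepl("[^ACGT]", co2)
  ok <- ok & AA_OF[ifelse(ok, co1, "TTT")] != "*" &
             AA_OF[ifelse(ok, co2, "TTT")] != "*"
  skipped <- sum(!ok)
  co1 <- co1[ok]; co2 <- co2[ok]
  ncod <- length(co1)
  if (ncod == 0L) stop("no comparable codons")
  syn1 <- vapply(co1, function(c) sum(syn_site_fractions(c)), 0)
  syn2 <- vapply(co2, function(c) sum(syn_site_fractions(c)), 0)
  S <- (sum(syn1) + sum(syn2)) / 2
  N <- 3 * ncod - S
  dif <- vapply(seq_len(ncod), function(i)
    pair_differences_cached(co1[i], co2[i]), numeric(3L))
  Sd <- sum(dif["sd", ]); Nd <- sum(dif["nd", ])
  blocked <- sum(dif["blocked", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    if (p == 0) return(0)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio,
                 codons_compared = ncod, codons_skipped = skipped,
                 blocked_pairs = blocked,
                 undefined = list(Ks = is.na(Ks), Ka = is.na(Ka),
                                  ratio = is.na(ratio))),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %d codons (S=%.1f, N=%.1f)\n",
              x$codons_compared, x$S, x$N))
  cat(sprintf("  Sd=%.2f Nd=%.2f  pS=%.4f pN=%.4f\n",
              x$Sd, x$Nd, x$pS, x$pN))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("  Ks=%s Ka=%s Ka/Ks=%s\n", fmt(x$Ks), fmt(x$Ka),
              fmt(x$ratio)))
  invisible(x)
}
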