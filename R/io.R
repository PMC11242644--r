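#' Read sequences from FASTA or GenBank flat files
#'
#' Records are returned in file order as \code{circseq} objects.  For
#' GenBank input, CDS/gene feature annotations are parsed as well and
#' attached as the \code{"features"} attribute of each record (a
#' data.frame, one row per exon, 0-based half-open coordinates), for use
#' by [extract_cds()].  The GenBank topology flag is deliberately ignored:
#' deposited organelle records do not mark circularity reliably, so
#' topology is always taken from the \code{topology} argument.
#'
#' @param path input file.
#' @param format \code{"auto"} (sniff first character), \code{"fasta"} or
#'   \code{"genbank"}.
#' @param topology topology assigned to every record.
#' @return list of \code{circseq}.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "genbank"),
                           topology = c("circular", "linear")) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("no records in ", path)
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no records in ", path)
    ids <- sub("\\s.*$", "", names(set))
    out <- lapply(seq_along(set), function(i)
      circseq(ids[i], as.character(set[[i]]), topology))
  } else {
    out <- read_genbank(path, topology)
  }
  out
}

#' Write sequences to FASTA
#' @param seqs list of \code{circseq} (or a single one).
#' @param path output file.
#' @param width line width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "circseq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read long reads from FASTQ
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(set) == 0L) stop("no records in ", path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write reads to FASTQ with constant placeholder qualities
#'
#' No stage of the pipeline consumes base qualities, so simulated reads
#' carry a constant placeholder quality.
#'
#' @param reads named character vector.
#' @param path output file.
#' @param qual single quality character applied to every base.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  set <- Biostrings::DNAStringSet(unname(reads))
  names(set) <- names(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(qual, n), ""))
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

## ---- GenBank flat-file parsing -------------------------------------------
## Minimal parser: LOCUS id, ORIGIN sequence, and gene/CDS features with
## join()/complement() locations plus /gene, /pseudo, /exon qualifiers.

read_genbank <- function(path, topology) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("no records in ", path)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no records in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i)
    parse_genbank_record(lines[starts[i]:ends[i]], topology))
}

parse_genbank_record <- function(rec, topology) {
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", rec[1L])), "\\s+")[[1L]][1L]
  oi <- grep("^ORIGIN", rec)
  if (length(oi) != 1L) stop("GenBank record '", id, "': no ORIGIN block")
  seq_lines <- rec[(oi + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  obj <- circseq(id, residues, topology)

  fi <- grep("^FEATURES", rec)
  feats <- NULL
  if (length(fi) == 1L) {
    body <- rec[(fi + 1L):(oi - 1L)]
    feats <- parse_genbank_features(body, id)
  }
  attr(obj, "features") <- feats
  obj
}

parse_genbank_features <- function(body, molecule) {
  key_lines <- grep("^ {5}\\S", body)
  if (length(key_lines) == 0L) return(NULL)
  bounds <- c(key_lines, length(body) + 1L)
  rows <- list()
  for (i in seq_along(key_lines)) {
    blk <- body[key_lines[i]:(bounds[i + 1L] - 1L)]
    key <- sub("^\\s*(\\S+).*$", "\\1", blk[1L])
    if (!key %in% c("CDS", "gene")) next
    txt <- paste(trimws(blk), collapse = " ")
    loc <- sub(paste0("^", key, "\\s+"), "", txt)
    loc <- sub("\\s*/.*$", "", loc)
    quals <- regmatches(txt, gregexpr("/[A-Za-z_]+(=(\"[^\"]*\"|\\S+))?",
                                      txt))[[1L]]
    getq <- function(name) {
      hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1L]))
    }
    pseudo <- any(grepl("^/pseudo\\b", quals))
    exons <- parse_genbank_location(loc)
    exons$molecule <- molecule
    exons$type <- key
    exons$gene <- getq("gene")
    exons$pseudo <- pseudo
    en <- getq("exon")
    exons$exon <- if (!is.na(en)) as.integer(en) else seq_len(nrow(exons))
    rows[[length(rows) + 1L]] <- exons
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

## GenBank locations are 1-based inclusive; converted to 0-based half-open
## here, at the I/O boundary only.
parse_genbank_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1L]]
  out <- lapply(parts, function(p) {
    p <- trimws(p)
    st <- "+"
    if (grepl("^complement\\(", p)) {
      st <- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    } else if (strand == "-") st <- "-"
    m <- regmatches(p, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", p))[[1L]]
    if (length(m) == 0L) {
      m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1L]]
      if (length(m1) == 0L) stop("unparsable GenBank location: ", p)
      a <- as.integer(m1[2L]); b <- a
    } else {
      a <- as.integer(m[2L]); b <- as.integer(m[3L])
    }
    data.frame(start = a - 1L, end = b, strand = st)
  })
  out <- do.call(rbind, out)
  ## a fully complemented join lists exons in genome order; translation
  ## order for minus-strand genes is last exon first
  if (strand == "-") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- GFF3 ----------------------------------------------------------------

#' Write a feature table as GFF3
#'
#' @param df data.frame with columns \code{seqid,type,start,end,strand} and
#'   optionally \code{score} and \code{attributes}; \code{start,end} are the
#'   package's 0-based half-open coordinates, converted to GFF3 1-based
#'   inclusive on output.
#' @param path output file.
#' @param source value of the GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(df, path, source = "mitorec") {
  stopifnot(all(c("seqid", "type", "start", "end", "strand") %in% names(df)))
  score <- if ("score" %in% names(df)) df$score else rep(".", nrow(df))
  att <- if ("attributes" %in% names(df)) df$attributes else rep(".", nrow(df))
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                     df$seqid, source, df$type, df$start + 1L, df$end,
                     as.character(score), df$strand, att))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 annotation table
#'
#' Thin wrapper over \code{rtracklayer::import} returning a plain
#' data.frame with the package's 0-based half-open coordinates and
#' convenience columns for the qualifiers used by [extract_cds()]
#' (\code{gene}, \code{exon}, \code{pseudo}).
#'
#' @param path GFF3 file.
#' @return data.frame, one row per feature line.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(gr)
  getcol <- function(name, default) {
    if (name %in% names(mc)) mc[[name]] else rep(default, nrow(mc))
  }
  data.frame(
    seqid = as.character(mc$seqnames),
    type = as.character(getcol("type", NA_character_)),
    start = mc$start - 1L,
    end = mc$end,
    strand = ifelse(as.character(mc$strand) == "-", "-", "+"),
    gene = as.character(getcol("gene", NA_character_)),
    exon = suppressWarnings(as.integer(getcol("exon", NA))),
    pseudo = !is.na(getcol("pseudo", NA)),
    stringsAsFactors = FALSE)
}
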