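# Reading and writing the standard formats the pipeline touches:
# FASTA references, SAM/BAM alignments, samtools-style pileup text,
# tabular variant output, and the simulator truth table.
#
# Coordinates are 1-based and intervals fully closed throughout the
# user-visible API (SAM/pileup convention).

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; IUPAC ambiguity codes other than N are
#' normalized to N. Positions whose reference base is N are never
#' compared against reads and never called.
#'
#' @param path Path to a FASTA file.
#' @return An object of class \code{ref_genome}: a named character vector
#'   of chromosome sequences with a \code{lengths()} accessor.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !startsWith(first, ">")) {
    stop("malformed FASTA (missing '>' header): ", path)
  }
  ss <- Biostrings::readDNAStringSet(path)
  ref_genome(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' Construct a reference genome from named sequences
#'
#' @param sequences Named character vector, one element per chromosome.
#' @return A \code{ref_genome} object.
#' @export
ref_genome <- function(sequences) {
  if (length(sequences) == 0 || is.null(names(sequences))) {
    stop("sequences must be a non-empty named character vector")
  }
  up <- toupper(sequences)
  # IUPAC ambiguity codes other than N -> N
  up <- vapply(up, function(s) gsub("[^ACGTN]", "N", s), character(1))
  names(up) <- names(sequences)
  structure(up, class = "ref_genome")
}

#' Chromosome lengths of a reference genome
#' @param ref A \code{ref_genome}.
#' @return Named integer vector of sequence lengths in bp.
#' @export
ref_lengths <- function(ref) {
  stopifnot(inherits(ref, "ref_genome"))
  setNames(nchar(unclass(ref)), names(ref))
}

#' @export
print.ref_genome <- function(x, ...) {
  l <- ref_lengths(x)
  cat("ref_genome with", length(l), "sequence(s),", sum(l), "bp total\n")
  for (n in utils::head(names(l), 10)) cat("  ", n, ": ", l[[n]], " bp\n", sep = "")
  if (length(l) > 10) cat("  ...\n")
  invisible(x)
}

ref_seq <- function(ref, chrom) {
  s <- unclass(ref)[[chrom]]
  if (is.null(s) || is.na(s)) stop("chromosome not in reference: ", chrom)
  s
}

#' Write a reference genome to FASTA
#' @param ref A \code{ref_genome}.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SAM/BAM alignments

#' Construct an alignment set
#'
#' An \code{aln_reads} object is a data.frame with one row per SAM record
#' and columns \code{qname, flag, chrom, pos, mapq, cigar, mchrom, mpos,
#' isize, seq, qual, rg}, carrying the reference chromosome lengths needed
#' to emit a valid header.
#'
#' @param df Data frame of SAM fields.
#' @param ref_lengths Named integer vector of chromosome lengths.
#' @param n_unmapped Count of unmapped records skipped on input.
#' @return An \code{aln_reads} object.
#' @export
aln_reads <- function(df, ref_lengths, n_unmapped = 0L) {
  need <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
            "mchrom", "mpos", "isize", "seq", "qual", "rg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing alignment columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df[, need], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  bad <- setdiff(unique(df$chrom), names(ref_lengths))
  if (length(bad)) stop("alignment references unknown chromosome: ", bad[1])
  # CIGAR read-length consistency (vectorized: called on every construction)
  if (nrow(df)) {
    bad_c <- cigar_read_lens(df$cigar) != nchar(df$seq)
    if (any(bad_c)) {
      stop("CIGAR/sequence length mismatch for read ", df$qname[which(bad_c)[1]])
    }
    bad_q <- df$qual != "*" & nchar(df$qual) != nchar(df$seq)
    if (any(bad_q)) {
      stop("quality/sequence length mismatch for read ", df$qname[which(bad_q)[1]])
    }
  }
  structure(df,
            ref_lengths = ref_lengths,
            n_unmapped = as.integer(n_unmapped),
            class = c("aln_reads", "data.frame"))
}

#' @export
print.aln_reads <- function(x, ...) {
  cat("aln_reads:", nrow(x), "mapped read(s) on",
      length(unique(x$chrom)), "chromosome(s);",
      attr(x, "n_unmapped") %||% 0L, "unmapped skipped on input\n")
  if (nrow(x)) print(utils::head(as.data.frame(x)[, c("qname", "flag", "chrom",
                                                      "pos", "cigar")], 6))
  invisible(x)
}

#' Read alignments from SAM or BAM
#'
#' Mapped reads are returned coordinate-sorted; unmapped records are
#' skipped and counted (see \code{attr(x, "n_unmapped")}).
#'
#' @param path SAM (.sam) or BAM file.
#' @param region Optional region string \code{"chrom:start-end"}
#'   (1-based, closed); only reads overlapping it are returned.
#' @param ref Optional \code{ref_genome}; when given, an alignment naming a
#'   chromosome absent from it is an error.
#' @return An \code{aln_reads} object.
#' @export
read_alignments <- function(path, region = NULL, ref = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  lens <- setNames(as.integer(hdr$targets), names(hdr$targets))
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq", "qual")
  p <- Rsamtools::ScanBamParam(what = what, tag = "RG")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- as.integer(res$flag)
  mapped <- !is_unmapped(flag) & !is.na(res$pos)
  n_unmapped <- sum(!mapped)
  rg <- res$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, length(flag))
  df <- data.frame(
    qname = res$qname, flag = flag,
    chrom = as.character(res$rname), pos = as.integer(res$pos),
    mapq = as.integer(res$mapq), cigar = as.character(res$cigar),
    mchrom = as.character(res$mrnm), mpos = as.integer(res$mpos),
    isize = as.integer(res$isize),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    rg = as.character(rg),
    stringsAsFactors = FALSE
  )[mapped, , drop = FALSE]
  if (!is.null(ref)) {
    bad <- setdiff(unique(df$chrom), names(ref_lengths(ref)))
    if (length(bad)) stop("alignment references chromosome absent from reference: ", bad[1])
  }
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("bad region (expected chrom:start-end): ", region)
    rchrom <- m[2]; rstart <- as.integer(m[3]); rend <- as.integer(m[4])
    span <- vapply(df$cigar, function(cg) cigar_ref_span(parse_cigar(cg)), integer(1))
    keep <- df$chrom == rchrom & df$pos <= rend & (df$pos + span - 1L) >= rstart
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(match(df$chrom, names(lens)), df$pos), , drop = FALSE]
  aln_reads(df, lens, n_unmapped)
}

#' Write alignments as SAM
#'
#' Emits a valid SAM file (header from the object's chromosome lengths,
#' \code{@RG} records for every read group present) that round-trips
#' through \code{\link{read_alignments}}.
#'
#' @param reads An \code{aln_reads} object.
#' @param path Output path (.sam).
#' @param sort_output Coordinate-sort records before writing.
#' @export
write_sam <- function(reads, path, sort_output = TRUE) {
  stopifnot(inherits(reads, "aln_reads"))
  lens <- attr(reads, "ref_lengths")
  bad <- setdiff(unique(reads$chrom), names(lens))
  if (length(bad)) stop("read references chromosome absent from header: ", bad[1])
  hd <- c(sprintf("@HD\tVN:1.6\tSO:%s", if (sort_output) "coordinate" else "unknown"),
          sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  rgs <- unique(reads$rg[!is.na(reads$rg)])
  if (length(rgs)) hd <- c(hd, sprintf("@RG\tID:%s\tSM:%s", rgs, rgs))
  df <- as.data.frame(reads)
  if (sort_output && nrow(df)) {
    df <- df[order(match(df$chrom, names(lens)), df$pos), , drop = FALSE]
  }
  rec <- character(0)
  if (nrow(df)) {
    mchrom <- ifelse(is.na(df$mchrom) | df$mchrom == "", "*",
                     ifelse(df$mchrom == df$chrom, "=", df$mchrom))
    rec <- paste(df$qname, df$flag, df$chrom, df$pos, df$mapq, df$cigar,
                 mchrom,
                 ifelse(is.na(df$mpos), 0L, df$mpos),
                 ifelse(is.na(df$isize), 0L, df$isize),
                 df$seq, df$qual, sep = "\t")
    hasrg <- !is.na(df$rg)
    rec[hasrg] <- paste0(rec[hasrg], "\tRG:Z:", df$rg[hasrg])
  }
  writeLines(c(hd, rec), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pileup text

#' A pileup column
#'
#' Per-position stack of read bases, qualities and indel observations.
#' \code{depth} is the read depth the producer stated for the column;
#' \code{length(bases)} is the recounted observation depth (the two are
#' exposed separately because historical pileup emitters could disagree).
#'
#' @param chrom,pos,ref_base Position and reference base.
#' @param depth Stated read depth.
#' @param bases Character vector of decoded base observations
#'   (\code{A/C/G/T/N}, or \code{"*"} for a deletion placeholder).
#' @param quals Integer Phred qualities parallel to \code{bases}.
#' @param rg Optional read-group per observation.
#' @param read_id,read_off Optional backlinks to the generating reads.
#' @param indels Optional data.frame of indel observations with columns
#'   \code{type} (\code{"INS"}/\code{"DEL"}), \code{len}, \code{seq},
#'   \code{rg}, \code{read_id}.
#' @param end3_count Number of reads whose 3' terminus (including
#'   soft-clipped ends) is located at the site.
#' @return A \code{pileup_column} object.
#' @export
pileup_column <- function(chrom, pos, ref_base, depth, bases, quals,
                          rg = NULL, read_id = NULL, read_off = NULL,
                          indels = NULL, end3_count = 0L) {
  stopifnot(pos >= 1, length(bases) == length(quals))
  if (depth < sum(bases != "")) depth <- max(depth, length(bases))
  structure(list(
    chrom = chrom, pos = as.integer(pos), ref_base = ref_base,
    depth = as.integer(depth), bases = bases, quals = as.integer(quals),
    rg = rg %||% rep(NA_character_, length(bases)),
    read_id = read_id, read_off = read_off,
    indels = indels %||% data.frame(type = character(0), len = integer(0),
                                    seq = character(0), rg = character(0),
                                    read_id = integer(0),
                                    stringsAsFactors = FALSE),
    end3_count = as.integer(end3_count)
  ), class = "pileup_column")
}

# Decode one samtools pileup base string together with its quality string.
decode_pileup_bases <- function(bases, quals, ref_base, qual_offset = 33L) {
  qv <- qual_to_int(quals, qual_offset)
  out_b <- character(0); out_q <- integer(0)
  indels <- list()
  i <- 1L; qi <- 1L; n <- nchar(bases)
  while (i <= n) {
    ch <- substr(bases, i, i)
    if (ch == "^") {            # read start marker + mapq char
      i <- i + 2L
    } else if (ch == "$") {     # read end marker
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      m <- regmatches(substr(bases, i, n),
                      regexec("^[+-]([0-9]+)", substr(bases, i, n)))[[1]]
      ilen <- as.integer(m[2])
      seq_start <- i + 1L + nchar(m[2])
      iseq <- toupper(substr(bases, seq_start, seq_start + ilen - 1L))
      indels[[length(indels) + 1L]] <- data.frame(
        type = if (ch == "+") "INS" else "DEL",
        len = ilen, seq = iseq, rg = NA_character_, read_id = NA_integer_,
        stringsAsFactors = FALSE)
      i <- seq_start + ilen
    } else {
      b <- if (ch %in% c(".", ",")) ref_base else toupper(ch)
      if (!(b %in% c("A", "C", "G", "T", "N", "*"))) {
        stop("unexpected pileup base character: ", ch)
      }
      out_b <- c(out_b, b)
      out_q <- c(out_q, if (qi <= length(qv)) qv[qi] else NA_integer_)
      qi <- qi + 1L
      i <- i + 1L
    }
  }
  list(bases = out_b, quals = out_q,
       indels = if (length(indels)) do.call(rbind, indels) else NULL)
}

#' Read a samtools-style text pileup
#'
#' Supports the classic 10-column consensus pileup (depth in column 8)
#' and the 6-column mpileup (depth in column 4). The dialect must be
#' stated explicitly: the two are column-ambiguous on short lines.
#'
#' @param path Pileup text file.
#' @param dialect \code{"consensus10"} or \code{"mpileup6"}.
#' @param qual_offset Phred encoding offset (33 by default; 64 supported).
#' @return List of \code{\link{pileup_column}} objects.
#' @export
read_pileup <- function(path, dialect = c("consensus10", "mpileup6"),
                        qual_offset = 33L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- lapply(seq_along(lines), function(li) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (dialect == "mpileup6") {
      if (length(f) < 6) stop("pileup line ", li, ": expected >=6 columns, got ",
                              length(f))
      depth <- as.integer(f[4]); bases <- f[5]; quals <- f[6]
    } else {
      if (length(f) < 10) stop("pileup line ", li, ": expected >=10 columns, got ",
                               length(f))
      depth <- as.integer(f[8]); bases <- f[9]; quals <- f[10]
    }
    if (is.na(depth)) stop("pileup line ", li, ": non-numeric depth column")
    dec <- decode_pileup_bases(bases, quals, toupper(f[3]), qual_offset)
    pileup_column(chrom = f[1], pos = as.integer(f[2]), ref_base = toupper(f[3]),
                  depth = depth, bases = dec$bases, quals = dec$quals,
                  indels = dec$indels)
  })
  cols
}

# ---------------------------------------------------------------------------
# Variant tables and truth tables

VARIANT_COLS <- c("chrom", "pos", "type", "ref", "alt", "depth",
                  "alt_count", "freq", "mean_qual", "zygosity")

empty_variants <- function() {
  structure(data.frame(chrom = character(0), pos = integer(0),
                       type = character(0), ref = character(0),
                       alt = character(0), depth = integer(0),
                       alt_count = integer(0), freq = numeric(0),
                       mean_qual = numeric(0), zygosity = character(0),
                       stringsAsFactors = FALSE),
            class = c("variant_calls", "data.frame"))
}

as_variants <- function(df) {
  if (nrow(df) == 0) return(empty_variants())
  df <- df[order(df$chrom, df$pos, df$type), VARIANT_COLS, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("variant_calls", "data.frame"))
}

#' @export
print.variant_calls <- function(x, ...) {
  cat("variant_calls:", nrow(x), "call(s) (",
      sum(x$type == "SNP"), "SNP,", sum(x$type != "SNP"), "indel )\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write called variants as TSV
#' @param calls A \code{variant_calls} data.frame.
#' @param path Output path.
#' @export
write_variants <- function(calls, path) {
  write.table(as.data.frame(calls)[, VARIANT_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant TSV written by \code{\link{write_variants}}
#' @param path Input path.
#' @return A \code{variant_calls} data.frame.
#' @export
read_variants <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character"))
  as_variants(df)
}

#' Write a simulator truth table as TSV
#' @param truth A truth-table data.frame from \code{\link{mutate_genome}}.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table TSV
#' @param path Input path.
#' @return Truth-table data.frame sorted by (chrom, pos).
#' @export
read_truth <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character"))
  df[order(df$chrom, df$pos), , drop = FALSE]
}
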