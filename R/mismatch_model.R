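# Differences of an aligned read against the reference, computed by direct
# sequence comparison (deliberately not via the MD tag, so any aligner's
# output can be processed), and the mismatch-counting rule used by the
# refinement filters: every substituted base is one mismatch, and each
# indel or soft-clipped end also counts as ONE mismatch regardless of its
# length.

#' Compare one aligned read with the reference
#'
#' Walks the CIGAR, comparing every aligned (M/=/X) base with the
#' reference. Positions where the reference base is N are neither matches
#' nor substitutions; a read N over a differing reference base counts as a
#' substitution. Each I/D CIGAR run yields one INS/DEL event, each S run
#' one SOFTCLIP event; H consumes nothing and N (skip) advances the
#' reference only.
#'
#' @param read One-row slice of an \code{aln_reads} object (or an
#'   equivalent list with \code{chrom,pos,cigar,seq,qual} fields).
#' @param ref A \code{ref_genome}.
#' @return An \code{aln_diff} object: list with \code{events} (data.frame
#'   of kind/ref_pos/read_offset/length/read_bases/ref_bases/qual),
#'   counts \code{n_sub}, \code{n_indel}, \code{n_clip}, and the read's
#'   span on the reference.
#' @export
diff_read <- function(read, ref) {
  read <- as.list(read)
  chrom <- read$chrom
  rseq <- toupper(read$seq)
  quals <- qual_to_int(read$qual)
  if (length(quals) == 0) quals <- rep(NA_integer_, nchar(rseq))
  ops <- parse_cigar(read$cigar)
  refstr <- ref_seq(ref, chrom)
  reflen <- nchar(refstr)
  span <- cigar_ref_span(ops)
  if (read$pos < 1 || read$pos + span - 1L > reflen) {
    stop("read ", read$qname %||% "?", " extends past end of chromosome ", chrom)
  }
  ev <- list()
  rp <- as.integer(read$pos)   # next reference position
  ro <- 0L                     # 0-based read offset
  for (k in seq_len(nrow(ops))) {
    len <- ops$len[k]; op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      rb <- substr(rseq, ro + 1L, ro + len)
      fb <- substr(refstr, rp, rp + len - 1L)
      rbv <- strsplit(rb, "", fixed = TRUE)[[1]]
      fbv <- strsplit(fb, "", fixed = TRUE)[[1]]
      mis <- which(rbv != fbv & fbv != "N")
      for (j in mis) {
        ev[[length(ev) + 1L]] <- data.frame(
          kind = "SUB", ref_pos = rp + j - 1L, read_offset = ro + j - 1L,
          length = 1L, read_bases = rbv[j], ref_bases = fbv[j],
          qual = as.numeric(quals[ro + j]), stringsAsFactors = FALSE)
      }
      rp <- rp + len; ro <- ro + len
    } else if (op == "I") {
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "INS", ref_pos = rp - 1L, read_offset = ro, length = len,
        read_bases = substr(rseq, ro + 1L, ro + len), ref_bases = "",
        qual = mean(quals[(ro + 1L):(ro + len)]), stringsAsFactors = FALSE)
      ro <- ro + len
    } else if (op == "D") {
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "DEL", ref_pos = rp, read_offset = ro, length = len,
        read_bases = "", ref_bases = substr(refstr, rp, rp + len - 1L),
        qual = NA_real_, stringsAsFactors = FALSE)
      rp <- rp + len
    } else if (op == "S") {
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "SOFTCLIP", ref_pos = rp - (k > 1L), read_offset = ro,
        length = len, read_bases = substr(rseq, ro + 1L, ro + len),
        ref_bases = "", qual = mean(quals[(ro + 1L):(ro + len)]),
        stringsAsFactors = FALSE)
      ro <- ro + len
    } else if (op == "N") {
      rp <- rp + len
    }
    # H and P consume nothing we track
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(0), ref_pos = integer(0),
               read_offset = integer(0), length = integer(0),
               read_bases = character(0), ref_bases = character(0),
               qual = numeric(0), stringsAsFactors = FALSE)
  events <- events[order(events$read_offset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(
    events = events,
    n_sub = sum(events$kind == "SUB"),
    n_indel = sum(events$kind %in% c("INS", "DEL")),
    n_clip = sum(events$kind == "SOFTCLIP"),
    read_len = nchar(rseq),
    chrom = chrom, pos = as.integer(read$pos), ref_span = span
  ), class = "aln_diff")
}

#' Diffs for every read of an alignment set
#' @param reads An \code{aln_reads} object.
#' @param ref A \code{ref_genome}.
#' @return List of \code{aln_diff}, one per row of \code{reads}.
#' @export
read_diffs <- function(reads, ref) {
  cols <- list(qname = reads$qname, chrom = reads$chrom, pos = reads$pos,
               cigar = reads$cigar, seq = reads$seq, qual = reads$qual)
  lapply(seq_len(nrow(reads)), function(i) diff_read(lapply(cols, `[`, i), ref))
}

#' Count mismatches of a read under the filtering rule
#'
#' Substituted bases count one each (restricted to bases with Phred
#' quality below \code{minq} when \code{minq} is set); each indel and
#' each soft-clipped end counts as one mismatch. A specified
#' two-mismatch threshold therefore effectively becomes a one-mismatch
#' threshold for a read containing a single indel.
#'
#' @param diff An \code{aln_diff}.
#' @param minq Optional Phred threshold: only substitutions with quality
#'   below it are counted. \code{NULL} counts all substitutions.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(diff, minq = NULL) {
  ev <- diff$events
  subs <- ev[ev$kind == "SUB", , drop = FALSE]
  nsub <- if (is.null(minq)) nrow(subs) else
    sum(is.na(subs$qual) | subs$qual < minq)
  as.integer(nsub + diff$n_indel + diff$n_clip)
}

#' Does a read carry a substitution within its terminal regions?
#'
#' @param diff An \code{aln_diff}.
#' @param k Size of each terminal window in bp (default 2).
#' @return \code{TRUE} iff any substitution's read offset lies within the
#'   first or last \code{k} positions of the read.
#' @export
terminal_mismatch <- function(diff, k = 2L) {
  stopifnot(k >= 1)
  subs <- diff$events[diff$events$kind == "SUB", , drop = FALSE]
  if (nrow(subs) == 0) return(FALSE)
  off <- subs$read_offset
  any(off < k | off >= diff$read_len - k)
}
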