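# In-memory pileup built directly from parsed alignments. Unlike a counts
# pileup, every base observation keeps a backlink (read row index + read
# offset) so that the error corrector can rewrite individual read bases,
# and a per-observation read group so pooled samples can be treated
# separately.

# Returns a list of three data.tables:
#   $bases:  chrom, pos, base, qual, read_id, read_off, rg
#            (deletion placeholders have base "*" and qual NA)
#   $indels: chrom, pos (preceding base for INS, first deleted base for DEL),
#            type, len, seq, read_id, rg
#   $end3:   chrom, pos, n  -- counts of read 3' termini (incl. soft clips)
pileup_tables <- function(reads, ref) {
  stopifnot(inherits(reads, "aln_reads"))
  n <- nrow(reads)
  base_l <- vector("list", n)
  ind_l <- vector("list", n)
  end3_chrom <- reads$chrom; end3_pos <- integer(n)
  cols <- list(qname = reads$qname, flag = reads$flag, chrom = reads$chrom,
               pos = reads$pos, cigar = reads$cigar, seq = reads$seq,
               qual = reads$qual, rg = reads$rg)
  # fast path: gapless all-M reads expand without a CIGAR walk
  simple <- grepl("^[0-9]+M$", reads$cigar) & !is.na(reads$qual) &
    reads$qual != "*"
  if (any(simple)) {
    si <- which(simple)
    rl <- nchar(reads$seq[si])
    bt <- data.table::data.table(
      pos = unlist(lapply(si, function(i) {
        reads$pos[i] + 0:(nchar(reads$seq[i]) - 1L)
      })),
      base = unlist(strsplit(toupper(reads$seq[si]), "", fixed = TRUE)),
      qual = unlist(lapply(reads$qual[si], qual_to_int)),
      read_off = unlist(lapply(rl, function(l) 0:(l - 1L))),
      chrom = rep(reads$chrom[si], rl),
      read_id = rep(si, rl),
      rg = rep(reads$rg[si], rl))
    base_l[[si[1]]] <- bt
    end3_pos[si] <- ifelse(is_reverse(reads$flag[si]), reads$pos[si],
                           reads$pos[si] + rl - 1L)
  }
  for (i in which(!simple)) {
    r <- lapply(cols, `[`, i)
    ops <- parse_cigar(r$cigar)
    quals <- qual_to_int(r$qual)
    if (length(quals) == 0) quals <- rep(NA_integer_, nchar(r$seq))
    rp <- as.integer(r$pos); ro <- 0L
    lead_clip <- if (nrow(ops) && ops$op[1] == "S") ops$len[1] else 0L
    bb <- list(); ii <- list()
    for (k in seq_len(nrow(ops))) {
      len <- ops$len[k]; op <- ops$op[k]
      if (op %in% c("M", "=", "X")) {
        idx <- seq_len(len)
        bb[[length(bb) + 1L]] <- data.table::data.table(
          pos = rp + idx - 1L,
          base = strsplit(toupper(substr(r$seq, ro + 1L, ro + len)), "",
                          fixed = TRUE)[[1]],
          qual = quals[ro + idx],
          read_off = ro + idx - 1L)
        rp <- rp + len; ro <- ro + len
      } else if (op == "I") {
        ii[[length(ii) + 1L]] <- data.table::data.table(
          pos = rp - 1L, type = "INS", len = len,
          seq = toupper(substr(r$seq, ro + 1L, ro + len)))
        ro <- ro + len
      } else if (op == "D") {
        # samtools convention: deletion observation anchored at the base
        # preceding the deleted run
        refstr <- ref_seq(ref, r$chrom)
        ii[[length(ii) + 1L]] <- data.table::data.table(
          pos = rp - 1L, type = "DEL", len = len,
          seq = substr(refstr, rp, rp + len - 1L))
        bb[[length(bb) + 1L]] <- data.table::data.table(
          pos = rp + seq_len(len) - 1L, base = "*", qual = NA_integer_,
          read_off = NA_integer_)
        rp <- rp + len
      } else if (op == "S") {
        ro <- ro + len
      } else if (op == "N") {
        rp <- rp + len
      }
    }
    trail_clip <- if (nrow(ops) && ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
    # 3' terminus in reference coordinates, including soft-clipped ends
    end3_chrom[i] <- r$chrom
    end3_pos[i] <- if (is_reverse(r$flag)) r$pos - lead_clip else rp - 1L + trail_clip
    if (length(bb)) {
      b <- data.table::rbindlist(bb)
      b[, `:=`(chrom = r$chrom, read_id = i, rg = r$rg)]
      base_l[[i]] <- b
    }
    if (length(ii)) {
      d <- data.table::rbindlist(ii)
      d[, `:=`(chrom = r$chrom, read_id = i, rg = r$rg)]
      ind_l[[i]] <- d
    }
  }
  bases <- data.table::rbindlist(base_l)
  indels <- data.table::rbindlist(ind_l)
  if (nrow(bases) == 0) {
    bases <- data.table::data.table(pos = integer(0), base = character(0),
                                    qual = integer(0), read_off = integer(0),
                                    chrom = character(0), read_id = integer(0),
                                    rg = character(0))
  }
  if (nrow(indels) == 0) {
    indels <- data.table::data.table(pos = integer(0), type = character(0),
                                     len = integer(0), seq = character(0),
                                     chrom = character(0), read_id = integer(0),
                                     rg = character(0))
  }
  end3 <- data.table::data.table(chrom = end3_chrom, pos = end3_pos)
  end3 <- end3[, .(n = .N), by = .(chrom, pos)]
  list(bases = bases, indels = indels, end3 = end3)
}

# Reference base per observation, vectorized per chromosome.
ref_base_at <- function(ref, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(ref_seq(ref, ch), pos[i], pos[i])
  }
  out
}

# Positions worth materializing: any non-reference base observation or
# any indel observation. Everything the caller and corrector do is a
# no-op elsewhere.
candidate_keys <- function(tb, ref) {
  pos <- NULL
  b <- tb$bases
  cand_b <- if (nrow(b)) {
    refb <- ref_base_at(ref, b$chrom, b$pos)
    unique(b[b$base != refb & b$base != "*", .(chrom, pos)])
  } else b[, .(chrom, pos)]
  unique(data.table::rbindlist(list(cand_b, tb$indels[, .(chrom, pos)])))
}

#' Build pileup columns from an alignment set
#'
#' Produces the same per-position stacks that decoding a samtools text
#' pileup of the same reads would give: decoded base observations with
#' qualities and deletion placeholders, indel observations attached to
#' their anchor position, and the count of read 3' termini at each site.
#'
#' @param reads An \code{aln_reads} object.
#' @param ref A \code{ref_genome}.
#' @param positions \code{"covered"} materializes every covered position;
#'   \code{"variant"} only positions with at least one non-reference base
#'   or indel observation (sufficient for calling and correction, and far
#'   cheaper on large inputs).
#' @return List of \code{\link{pileup_column}} objects, sorted by
#'   (chrom, pos).
#' @export
pileup_from_reads <- function(reads, ref, positions = c("covered", "variant")) {
  positions <- match.arg(positions)
  tb <- pileup_tables(reads, ref)
  pos <- NULL # R CMD check appeasement for data.table NSE
  keys <- if (positions == "covered") {
    unique(data.table::rbindlist(list(
      tb$bases[, .(chrom, pos)], tb$indels[, .(chrom, pos)])))
  } else {
    candidate_keys(tb, ref)
  }
  data.table::setkey(keys, chrom, pos)
  data.table::setkey(tb$bases, chrom, pos)
  data.table::setkey(tb$indels, chrom, pos)
  data.table::setkey(tb$end3, chrom, pos)
  lapply(seq_len(nrow(keys)), function(j) {
    ch <- keys$chrom[j]; p <- keys$pos[j]
    b <- tb$bases[.(ch, p)]
    b <- b[!is.na(base)]
    d <- tb$indels[.(ch, p), nomatch = 0L]
    e3 <- tb$end3[.(ch, p), nomatch = 0L]
    refb <- substr(ref_seq(ref, ch), p, p)
    pileup_column(
      chrom = ch, pos = p, ref_base = refb,
      depth = nrow(b), bases = b$base, quals = b$qual,
      rg = b$rg, read_id = b$read_id, read_off = b$read_off,
      indels = if (nrow(d)) as.data.frame(d[, .(type, len, seq, rg, read_id)])
               else NULL,
      end3_count = if (nrow(e3)) e3$n[1] else 0L)
  })
}
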