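# Shared fixture builders and independent oracles. Everything is built
# in code at test time; no stored data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_genome <- function(len, seed, name = "c1") {
  set.seed(seed)
  s <- setNames(
    vapply(len, function(l) paste(sample(c("A", "C", "G", "T"), l,
                                         replace = TRUE), collapse = ""),
           character(1)),
    if (length(len) == 1) name else paste0(name, seq_along(len)))
  ref_genome(s)
}

# Minimal aln_reads constructor for hand-built records.
mk_reads <- function(..., lens) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    defaults <- list(qname = "r", flag = 0L, chrom = names(lens)[1],
                     pos = 1L, mapq = 60L, cigar = NA_character_,
                     mchrom = NA_character_, mpos = NA_integer_,
                     isize = NA_integer_, seq = NA_character_,
                     qual = NA_character_, rg = NA_character_)
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
  aln_reads(df, lens)
}

q35 <- function(n) paste(rep("D", n), collapse = "")   # Phred 35
qv <- function(q) {
  stopifnot(all(q >= 0))
  intToUtf8(q + 33L)
}

# ---------------------------------------------------------------------------
# Independent oracle: event extraction by explicit alignment expansion.
# Builds the aligned read/reference strings column by column (a textbook
# alignment matrix walk), then reads events off the expanded columns --
# deliberately a different algorithm from diff_read's substring logic.
oracle_diff <- function(read, ref) {
  s <- unclass(ref)[[read$chrom]]
  toks <- regmatches(read$cigar,
                     gregexpr("[0-9]+[MIDNSHP=X]", read$cigar))[[1]]
  lens <- as.integer(sub(".$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  rp <- read$pos; ro <- 1L
  rseq <- strsplit(toupper(read$seq), "")[[1]]
  quals <- utf8ToInt(read$qual) - 33L
  events <- list()
  for (k in seq_along(ops)) {
    op <- ops[k]; L <- lens[k]
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(L)) {
        rb <- rseq[ro]; fb <- substr(s, rp, rp)
        if (rb != fb && fb != "N") {
          events[[length(events) + 1L]] <-
            list(kind = "SUB", ref_pos = rp, read_offset = ro - 1L,
                 qual = quals[ro])
        }
        rp <- rp + 1L; ro <- ro + 1L
      }
    } else if (op == "I") {
      events[[length(events) + 1L]] <- list(kind = "INS", ref_pos = rp - 1L,
                                            read_offset = ro - 1L)
      ro <- ro + L
    } else if (op == "D") {
      events[[length(events) + 1L]] <- list(kind = "DEL", ref_pos = rp,
                                            read_offset = ro - 1L)
      rp <- rp + L
    } else if (op == "S") {
      events[[length(events) + 1L]] <- list(kind = "SOFTCLIP",
                                            read_offset = ro - 1L)
      ro <- ro + L
    } else if (op == "N") {
      rp <- rp + L
    }
  }
  events
}

oracle_count <- function(read, ref, minq = NULL) {
  ev <- oracle_diff(read, ref)
  kinds <- vapply(ev, `[[`, character(1), "kind")
  nsub <- if (is.null(minq)) sum(kinds == "SUB") else
    sum(vapply(ev[kinds == "SUB"], function(e) e$qual < minq, logical(1)))
  nsub + sum(kinds != "SUB")
}

# Brute-force enumeration of every single-gap placement of a read
# (used as the oracle for the realignment minimum).
oracle_best_gap <- function(seq, chrom, ref, gap_type, gap_len,
                            pos_range) {
  s <- unclass(ref)[[chrom]]
  L <- nchar(seq)
  best <- Inf
  for (start in pos_range) {
    for (k in 1:(L - 1)) {
      if (gap_type == "DEL") {
        ref_aln <- paste0(substr(s, start, start + k - 1L),
                          substr(s, start + k + gap_len,
                                 start + k + gap_len + (L - k) - 1L))
      } else {
        if (L - k - gap_len < 1) next
        ref_aln <- paste0(substr(s, start, start + k - 1L),
                          strrep("?", gap_len),
                          substr(s, start + k, start + k + (L - k - gap_len) - 1L))
      }
      if (nchar(ref_aln) != L) next
      mism <- sum(strsplit(seq, "")[[1]] != strsplit(ref_aln, "")[[1]] &
                    strsplit(ref_aln, "")[[1]] != "?" &
                    strsplit(ref_aln, "")[[1]] != "N")
      best <- min(best, mism + 1L)  # the gap itself counts one mismatch
    }
  }
  best
}

tmp_path <- function(ext) tempfile(fileext = ext)

# A small literal variant table for IO tests.
as_calls_fixture <- function() {
  suppress_near_indel(structure(data.frame(
    chrom = c("c1", "c1"), pos = c(10L, 40L), type = c("SNP", "DEL"),
    ref = c("A", "TT"), alt = c("G", "-"), depth = c(12L, 9L),
    alt_count = c(11L, 8L), freq = c(11 / 12, 1), mean_qual = c(36, NA),
    zygosity = c("hom", "hom"), stringsAsFactors = FALSE),
    class = c("variant_calls", "data.frame")))
}
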