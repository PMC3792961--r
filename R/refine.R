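# Alignment refinement: local realignment of mismatched reads around
# catalogued indels, base-quality / allele-frequency error correction of
# aligned reads (optionally per sample for pooled data), and removal of
# mismatch-heavy, discordant and degenerate reads.
#
# Two modes:
#   basic            -- realign, then filter
#   error_correction -- 10%-of-read-length prefilter, realign, correct
#                       sequencing errors, then filter

#' Refinement parameters
#'
#' @param num Maximum mismatches tolerated per read (default 2). An indel
#'   or a soft-clipped end counts as one mismatch.
#' @param fnum Maximum total mismatches in a read pair; default
#'   \code{floor(1.7 * num)} (so 3 for the default \code{num} of 2).
#' @param mrate Maximum mismatch fraction of read length; \code{NULL}
#'   disables the rate filter.
#' @param minq_count Optional Phred threshold for quality-aware mismatch
#'   counting: only substitutions with quality below it count.
#' @param minq_correct Quality threshold of the error corrector: a
#'   non-reference allele whose mean base quality is below it is rewritten
#'   to the reference (default 10).
#' @param mfreq Minimum non-reference allele frequency below which bases
#'   are corrected (default 0, i.e. disabled).
#' @param msamp Optional named character vector mapping read-group to
#'   \code{"hom"} or \code{"het"}; enables pooled-sample correction with
#'   per-sample frequency thresholds 0.8 (hom) and 0.3 (het).
#' @param fpair Remove the mate of every filtered paired read. Default:
#'   on in error-correction mode, off in basic mode.
#' @param mode \code{"basic"} or \code{"error_correction"}.
#' @param realign Run local realignment (default \code{TRUE}).
#' @param discordant_filter Remove pairs with unmapped mates or inserts
#'   beyond mean + \code{insert_sd_mult} SD (default \code{TRUE}).
#' @param insert_sd_mult SD multiplier of the insert-size filter (5).
#' @param precorrection_rate Error-correction mode removes reads whose
#'   mismatch count exceeds this fraction of read length before
#'   realignment (0.10).
#' @param terminal_k Width of the terminal windows checked when
#'   realignment is disabled (2 bp).
#' @param msamp_hom,msamp_het Pooled-mode frequency thresholds.
#' @return A \code{refine_params} list.
#' @export
refine_params <- function(num = 2L, fnum = NULL, mrate = NULL,
                          minq_count = NULL, minq_correct = 10,
                          mfreq = 0, msamp = NULL, fpair = NULL,
                          mode = c("basic", "error_correction"),
                          realign = TRUE, discordant_filter = TRUE,
                          insert_sd_mult = 5, precorrection_rate = 0.10,
                          terminal_k = 2L,
                          msamp_hom = 0.8, msamp_het = 0.3) {
  mode <- match.arg(mode)
  if (is.null(fnum)) fnum <- as.integer(floor(1.7 * num))
  if (is.null(fpair)) fpair <- (mode == "error_correction")
  stopifnot(num >= 0, fnum >= num, mfreq >= 0, mfreq <= 1,
            msamp_hom > 0, msamp_hom < 1, msamp_het > 0, msamp_het < 1)
  if (!is.null(msamp)) {
    if (is.null(names(msamp)) || !all(msamp %in% c("hom", "het"))) {
      stop("msamp must be a named vector with values 'hom' or 'het'")
    }
  }
  structure(list(num = as.integer(num), fnum = as.integer(fnum),
                 mrate = mrate, minq_count = minq_count,
                 minq_correct = minq_correct, mfreq = mfreq, msamp = msamp,
                 fpair = fpair, mode = mode, realign = realign,
                 discordant_filter = discordant_filter,
                 insert_sd_mult = insert_sd_mult,
                 precorrection_rate = precorrection_rate,
                 terminal_k = as.integer(terminal_k),
                 msamp_hom = msamp_hom, msamp_het = msamp_het),
            class = "refine_params")
}

#' Catalogue the indels observed in an alignment set
#'
#' One entry per distinct (chromosome, position, type, length, sequence)
#' indel seen in any read's CIGAR, with its supporting-read count.
#'
#' @param reads An \code{aln_reads} object.
#' @param ref A \code{ref_genome}.
#' @param diffs Optional pre-computed list of diffs for \code{reads}.
#' @return Data frame with columns \code{chrom, ref_pos, type, length,
#'   seq, support}. For DEL entries \code{ref_pos} is the first deleted
#'   reference base; for INS the base preceding the insertion.
#' @export
build_indel_catalog <- function(reads, ref, diffs = NULL) {
  if (is.null(diffs)) diffs <- read_diffs(reads, ref)
  rows <- list()
  for (d in diffs) {
    ev <- d$events
    ev <- ev[ev$kind %in% c("INS", "DEL"), , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = d$chrom, ref_pos = ev$ref_pos[j], type = ev$kind[j],
        length = ev$length[j],
        seq = if (ev$kind[j] == "INS") ev$read_bases[j] else ev$ref_bases[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), ref_pos = integer(0),
                      type = character(0), length = integer(0),
                      seq = character(0), support = integer(0),
                      stringsAsFactors = FALSE))
  }
  d <- data.table::rbindlist(rows)
  agg <- d[, .(support = .N), by = .(chrom, ref_pos, type, length, seq)]
  out <- as.data.frame(agg)
  out[order(out$chrom, out$ref_pos), , drop = FALSE]
}

# Candidate single-gap re-alignments of a read at one catalogued indel.
# Anchoring either the 5' start or the 3' end of the (unclipped) read,
# the opposite portion is shifted by the indel length.
realign_candidates <- function(read, indel, ref) {
  L <- nchar(read$seq)
  ops <- parse_cigar(read$cigar)
  lead_clip <- if (nrow(ops) && ops$op[1] == "S") ops$len[1] else 0L
  trail_clip <- if (nrow(ops) && ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
  s0 <- read$pos - lead_clip                       # ref pos of read base 1 if gapless
  e0 <- read$pos + cigar_ref_span(ops) - 1L + trail_clip  # ref pos of last base
  p <- indel$ref_pos; ilen <- indel$length
  reflen <- nchar(ref_seq(ref, read$chrom))
  out <- list()
  add <- function(s, k) {
    # k = read bases aligned before the gap
    if (indel$type == "DEL") {
      rest <- L - k
      if (k < 1 || rest < 1) return()
      if (s < 1 || p + ilen + rest - 1L > reflen) return()
      cig <- sprintf("%dM%dD%dM", k, ilen, rest)
    } else {
      rest <- L - k - ilen
      if (k < 1 || rest < 1) return()
      if (s < 1 || p + rest > reflen) return()
      cig <- sprintf("%dM%dI%dM", k, ilen, rest)
    }
    out[[length(out) + 1L]] <<- list(pos = as.integer(s), cigar = cig,
                                     gap_pos = p)
  }
  if (indel$type == "DEL") {
    # bases 1..k cover s..p-1, gap deletes p..p+ilen-1
    add(p - (p - s0), p - s0)                       # 5'-anchored: s = s0
    k3 <- L - (e0 - p - ilen + 1L)                  # 3'-anchored
    add(p - k3, k3)
  } else {
    # bases 1..k cover s..p (insertion after p)
    add(s0, p - s0 + 1L)                            # 5'-anchored
    k3 <- L - ilen - (e0 - p)                       # 3'-anchored
    add(p - k3 + 1L, k3)
  }
  unique(out)
}

#' Locally realign one read around catalogued indels
#'
#' Only reads with at most one indel or one soft-clipped end are
#' candidates; gapless, unclipped reads must carry at least one
#' substitution. For every catalogued indel overlapping the read's span
#' (extended by the indel length), the 5' or the 3' portion of the read is
#' shifted by the indel length; the candidate with the fewest mismatches
#' is accepted only if its mismatch count is lower than or equal to the
#' original's. Ties are broken by fewest substitutions, then leftmost gap.
#'
#' @param read One-row slice of an \code{aln_reads} object.
#' @param diff Its \code{aln_diff} against \code{ref}.
#' @param catalog Output of \code{\link{build_indel_catalog}}.
#' @param ref A \code{ref_genome}.
#' @return List with the (possibly re-gapped) \code{read} (pos/cigar
#'   updated, sequence and qualities untouched), its new \code{diff}, and
#'   \code{changed} flag.
#' @export
local_realign <- function(read, diff, catalog, ref) {
  unchanged <- list(read = read, diff = diff, changed = FALSE)
  if (diff$n_indel + diff$n_clip > 1) return(unchanged)
  if (diff$n_indel == 0 && diff$n_clip == 0 && diff$n_sub == 0) return(unchanged)
  if (nrow(catalog) == 0) return(unchanged)
  c0 <- count_mismatches(diff)
  span_lo <- read$pos; span_hi <- read$pos + diff$ref_span - 1L
  cand_idx <- which(catalog$chrom == diff$chrom &
                    catalog$ref_pos >= span_lo - catalog$length &
                    catalog$ref_pos <= span_hi + catalog$length)
  if (length(cand_idx) == 0) return(unchanged)
  best <- NULL
  for (ci in cand_idx) {
    indel <- catalog[ci, ]
    for (cand in realign_candidates(read, indel, ref)) {
      rr <- read
      rr$pos <- cand$pos
      rr$cigar <- cand$cigar
      dd <- tryCatch(diff_read(rr, ref), error = function(e) NULL)
      if (is.null(dd)) next
      score <- c(count_mismatches(dd), dd$n_sub, cand$gap_pos)
      if (is.null(best) ||
          score[1] < best$score[1] ||
          (score[1] == best$score[1] && score[2] < best$score[2]) ||
          (score[1] == best$score[1] && score[2] == best$score[2] &&
           score[3] < best$score[3])) {
        best <- list(read = rr, diff = dd, score = score)
      }
    }
  }
  if (is.null(best) || best$score[1] > c0) return(unchanged)
  # identical placement: report unchanged
  if (best$read$pos == read$pos && best$read$cigar == read$cigar) return(unchanged)
  list(read = best$read, diff = best$diff, changed = TRUE)
}

#' Realign every eligible read of an alignment set
#'
#' @param reads An \code{aln_reads} object.
#' @param ref A \code{ref_genome}.
#' @param catalog Optional pre-built indel catalogue (built from
#'   \code{reads} when omitted).
#' @param diffs Optional pre-computed list of diffs.
#' @return List with updated \code{reads}, \code{diffs}, and the number of
#'   reads whose placement changed (\code{n_realigned}).
#' @export
realign_reads <- function(reads, ref, catalog = NULL, diffs = NULL) {
  if (is.null(catalog)) catalog <- build_indel_catalog(reads, ref)
  if (is.null(diffs)) diffs <- read_diffs(reads, ref)
  n_re <- 0L
  for (i in seq_len(nrow(reads))) {
    if (nrow(diffs[[i]]$events) == 0) next  # nothing to improve
    res <- local_realign(reads[i, ], diffs[[i]], catalog, ref)
    if (res$changed) {
      reads$pos[i] <- res$read$pos
      reads$cigar[i] <- res$read$cigar
      diffs[[i]] <- res$diff
      n_re <- n_re + 1L
    }
  }
  list(reads = reads, diffs = diffs, n_realigned = n_re)
}

#' Correct likely sequencing errors in aligned reads
#'
#' Column by column over the pileup of the (realigned) reads, each
#' non-reference allele is rewritten to the reference base in every read
#' carrying it when (a) the mean Phred quality of its bases is below
#' \code{minq_correct}, (b) its allele frequency is below \code{mfreq},
#' or (c) a higher-frequency non-reference allele co-occurs at the site
#' (only the most frequent non-reference allele is retained). In pooled
#' mode (\code{msamp}) frequencies are computed per read group and a
#' sample's non-reference bases are corrected when the per-sample
#' frequency falls below 0.8 (homozygous sample) or 0.3 (heterozygous
#' sample). Corrected bases keep their original quality scores;
#' reference-matching bases are never altered.
#'
#' @param reads An \code{aln_reads} object (typically realigned).
#' @param ref A \code{ref_genome}.
#' @param params A \code{\link{refine_params}}.
#' @return List with edited \code{reads}, total \code{n_corrected} bases,
#'   and \code{n_columns} touched.
#' @export
error_correct <- function(reads, ref, params = refine_params(mode = "error_correction")) {
  cols <- pileup_from_reads(reads, ref, positions = "variant")
  correct_read <- integer(0); correct_off <- integer(0); correct_to <- character(0)
  n_cols <- 0L
  for (col in cols) {
    if (!(col$ref_base %in% c("A", "C", "G", "T"))) next
    isbase <- col$bases %in% c("A", "C", "G", "T", "N")
    nonref <- isbase & col$bases != col$ref_base
    if (!any(nonref)) next
    fix <- rep(FALSE, length(col$bases))
    n_obs <- sum(isbase)
    if (is.null(params$msamp)) {
      alleles <- unique(col$bases[nonref])
      afreq <- vapply(alleles, function(a) sum(col$bases == a) / n_obs, numeric(1))
      amq <- vapply(alleles, function(a) mean(col$quals[col$bases == a],
                                              na.rm = TRUE), numeric(1))
      top <- max(afreq)
      for (j in seq_along(alleles)) {
        hit <- (amq[j] < params$minq_correct) ||      # quality rule
               (afreq[j] < params$mfreq) ||           # frequency rule
               (length(alleles) > 1 && afreq[j] < top) # multi-allele rule
        if (hit) fix <- fix | (col$bases == alleles[j] & isbase)
      }
    } else {
      if (anyNA(col$rg[isbase])) {
        bad <- unique(col$read_id[isbase & is.na(col$rg)])
        stop("pooled (msamp) correction requires a read group on every read; ",
             "missing for read row(s): ", paste(bad, collapse = ", "))
      }
      for (s in unique(col$rg[isbase])) {
        zyg <- params$msamp[[s]]
        if (is.null(zyg) || is.na(zyg)) {
          stop("read group not listed in msamp: ", s)
        }
        thr <- if (zyg == "hom") params$msamp_hom else params$msamp_het
        insamp <- isbase & col$rg == s
        ns <- sum(insamp)
        alleles <- unique(col$bases[insamp & nonref])
        for (a in alleles) {
          f <- sum(col$bases == a & insamp) / ns
          if (f < thr) fix <- fix | (col$bases == a & insamp)
        }
      }
    }
    if (any(fix)) {
      n_cols <- n_cols + 1L
      keep <- fix & !is.na(col$read_off)
      correct_read <- c(correct_read, col$read_id[keep])
      correct_off <- c(correct_off, col$read_off[keep])
      correct_to <- c(correct_to, rep(col$ref_base, sum(keep)))
    }
  }
  for (j in seq_along(correct_read)) {
    i <- correct_read[j]; o <- correct_off[j]
    substr(reads$seq[i], o + 1L, o + 1L) <- correct_to[j]
  }
  list(reads = reads, n_corrected = length(correct_read), n_columns = n_cols)
}

# Insert-size statistics from pairs with both mates mapped, counted once
# per pair (positive template length).
insert_stats <- function(reads) {
  ok <- is_paired(reads$flag) & !mate_unmapped(reads$flag) &
    !is.na(reads$isize) & reads$isize > 0
  x <- reads$isize[ok]
  if (length(x) < 2) return(list(mean = NA_real_, sd = NA_real_, n = length(x)))
  list(mean = mean(x), sd = sd(x), n = length(x))
}

#' Filter mismatch-heavy, discordant and degenerate reads
#'
#' A read is removed when any of the following holds: its mismatch count
#' (indels and soft clips counting one each) exceeds \code{num}; the total
#' mismatches of its pair exceed \code{fnum}; its mismatch fraction of
#' read length exceeds \code{mrate}; it contains more than two indels; it
#' is soft-clipped at both termini; its mate is unmapped or the insert
#' size exceeds mean + 5 SD of the library (estimated from the input);
#' or, only when realignment is disabled, it carries a substitution in a
#' terminal 2 bp window. With \code{fpair} on (default in
#' error-correction mode) the mate of every removed read is removed too.
#'
#' @param reads An \code{aln_reads} object.
#' @param ref A \code{ref_genome}.
#' @param params A \code{\link{refine_params}}.
#' @param diffs Optional pre-computed diffs.
#' @return List with retained \code{reads} and a \code{removed} data.frame
#'   (\code{qname, flag, reason}) logging one reason per removed read.
#' @export
filter_reads <- function(reads, ref, params = refine_params(), diffs = NULL) {
  if (is.null(diffs)) diffs <- read_diffs(reads, ref)
  n <- nrow(reads)
  counts <- vapply(diffs, count_mismatches, integer(1), minq = params$minq_count)
  reason <- rep(NA_character_, n)
  mark <- function(idx, why) {
    new <- idx[is.na(reason[idx])]
    reason[new] <<- why
    invisible(NULL)
  }
  mark(which(counts > params$num), "num")
  # pair totals (mates identified by qname)
  if (params$fnum < Inf) {
    tot <- tapply(counts, reads$qname, sum)
    both <- tapply(rep(1L, n), reads$qname, sum)
    over <- names(tot)[tot > params$fnum & both >= 2]
    mark(which(reads$qname %in% over), "fnum")
  }
  if (!is.null(params$mrate)) {
    rl <- vapply(diffs, function(d) d$read_len, integer(1))
    mark(which(counts / rl > params$mrate), "mrate")
  }
  n_ind <- vapply(diffs, function(d) d$n_indel, integer(1))
  mark(which(n_ind > 2L), "multi_indel")
  dclip <- vapply(seq_len(n), function(i) {
    ops <- parse_cigar(reads$cigar[i])
    nrow(ops) >= 2 && ops$op[1] == "S" && ops$op[nrow(ops)] == "S"
  }, logical(1))
  mark(which(dclip), "double_clip")
  if (params$discordant_filter) {
    st <- insert_stats(reads)
    paired <- is_paired(reads$flag)
    disc <- paired & mate_unmapped(reads$flag)
    if (!is.na(st$mean) && !is.na(st$sd)) {
      lim <- st$mean + params$insert_sd_mult * st$sd
      disc <- disc | (paired & !is.na(reads$isize) & abs(reads$isize) > lim)
    }
    mark(which(disc), "discordant")
  }
  if (!params$realign) {
    term <- vapply(diffs, terminal_mismatch, logical(1), k = params$terminal_k)
    mark(which(term), "terminal")
  }
  if (params$fpair) {
    gone <- unique(reads$qname[!is.na(reason)])
    mates <- which(is.na(reason) & reads$qname %in% gone & is_paired(reads$flag))
    mark(mates, "mate")
  }
  keep <- is.na(reason)
  removed <- data.frame(qname = reads$qname[!keep], flag = reads$flag[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- reads[keep, , drop = FALSE]
  attr(out, "ref_lengths") <- attr(reads, "ref_lengths")
  attr(out, "n_unmapped") <- attr(reads, "n_unmapped")
  class(out) <- class(reads)
  list(reads = out, removed = removed)
}

#' Run the full alignment-refinement pipeline
#'
#' Basic mode: local realignment, then filtering. Error-correction mode:
#' reads with more mismatches than \code{precorrection_rate} of their
#' length are removed first, the rest are realigned, sequencing errors
#' are corrected from the pileup, then the filters run.
#'
#' @param reads An \code{aln_reads} object, or a path to a SAM/BAM file.
#' @param ref A \code{ref_genome}.
#' @param params A \code{\link{refine_params}}.
#' @param out Optional path: refined alignment written as SAM.
#' @return A \code{refine_result}: list with refined \code{reads},
#'   \code{removed} log, and a \code{summary} (reads in/out, removals by
#'   reason, realigned reads, corrected bases).
#' @export
refine_pipeline <- function(reads, ref, params = refine_params(), out = NULL) {
  if (is.character(reads)) reads <- read_alignments(reads, ref = ref)
  stopifnot(inherits(reads, "aln_reads"))
  n_in <- nrow(reads)
  pre_removed <- data.frame(qname = character(0), flag = integer(0),
                            reason = character(0), stringsAsFactors = FALSE)
  diffs <- read_diffs(reads, ref)
  if (params$mode == "error_correction") {
    counts <- vapply(diffs, count_mismatches, integer(1))
    rl <- vapply(diffs, function(d) d$read_len, integer(1))
    drop <- counts > params$precorrection_rate * rl
    if (any(drop)) {
      pre_removed <- data.frame(qname = reads$qname[drop],
                                flag = reads$flag[drop],
                                reason = "precorrection",
                                stringsAsFactors = FALSE)
      keep <- !drop
      attrs <- attributes(reads)
      reads <- reads[keep, , drop = FALSE]
      attr(reads, "ref_lengths") <- attrs$ref_lengths
      attr(reads, "n_unmapped") <- attrs$n_unmapped
      class(reads) <- c("aln_reads", "data.frame")
      diffs <- diffs[keep]
    }
  }
  re <- if (params$realign) realign_reads(reads, ref, diffs = diffs)
        else list(reads = reads, diffs = diffs, n_realigned = 0L)
  n_corrected <- 0L
  if (params$mode == "error_correction") {
    ec <- error_correct(re$reads, ref, params)
    re$reads <- ec$reads
    re$diffs <- read_diffs(re$reads, ref)  # seq edits change the diffs
    n_corrected <- ec$n_corrected
  }
  fl <- filter_reads(re$reads, ref, params, diffs = re$diffs)
  removed <- rbind(pre_removed, fl$removed)
  if (!is.null(out)) write_sam(fl$reads, out)
  by_reason <- if (nrow(removed)) table(removed$reason) else table(character(0))
  structure(list(
    reads = fl$reads, removed = removed,
    summary = list(n_in = n_in, n_out = nrow(fl$reads),
                   n_removed = nrow(removed),
                   removed_by_reason = by_reason,
                   n_realigned = re$n_realigned,
                   n_corrected_bases = n_corrected,
                   mode = params$mode)
  ), class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  s <- x$summary
  cat("refine_result (", s$mode, " mode)\n", sep = "")
  cat("  reads in:        ", s$n_in, "\n")
  cat("  reads out:       ", s$n_out, "\n")
  cat("  realigned:       ", s$n_realigned, "\n")
  cat("  corrected bases: ", s$n_corrected_bases, "\n")
  if (length(s$removed_by_reason)) {
    cat("  removals by reason:\n")
    for (r in names(s$removed_by_reason)) {
      cat("    ", r, ": ", s$removed_by_reason[[r]], "\n", sep = "")
    }
  }
  invisible(x)
}
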