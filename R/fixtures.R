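# Synthetic pre-aligned reads with controlled error content. Reads are
# emitted at their true positions of origin (no aligner involved), so
# pileups over them are exact and every downstream stage can be tested
# hermetically. Misalignment is modelled separately, by injecting reads
# drawn from foreign sequence with forged coordinates.

#' Read error profile
#'
#' Describes where sequencing errors are placed in generated reads:
#' a per-base error rate rising toward the 3' end (the dominant pattern
#' in Illumina-type data), an optional region in which reads carry a
#' fixed number of clustered low-quality errors, and the Phred values
#' assigned to correct and erroneous bases.
#'
#' @param base_error_rate Per-base substitution error probability at the
#'   5' end (default 0.0012).
#' @param three_prime_ramp Non-decreasing multiplier applied across the
#'   read, recycled/interpolated to read length; the default ramps
#'   linearly from 1 to ~6.7 so the 3'-end error rate reaches ~0.8%.
#' @param cluster_spec Optional list \code{(chrom, start, end, errors)}:
#'   every read overlapping the region receives exactly \code{errors}
#'   extra low-quality errors at random offsets.
#' @param qual_correct Phred score of correct bases (default 35).
#' @param qual_error Phred score of erroneous bases (default 5).
#' @return A \code{read_error_profile} list.
#' @export
read_error_profile <- function(base_error_rate = 0.0012,
                               three_prime_ramp = c(1, 6.7),
                               cluster_spec = NULL,
                               qual_correct = 35L, qual_error = 5L) {
  stopifnot(base_error_rate >= 0, base_error_rate <= 1,
            all(diff(three_prime_ramp) >= 0))
  structure(list(base_error_rate = base_error_rate,
                 three_prime_ramp = three_prime_ramp,
                 cluster_spec = cluster_spec,
                 qual_correct = as.integer(qual_correct),
                 qual_error = as.integer(qual_error)),
            class = "read_error_profile")
}

substitute_base <- function(b) {
  vapply(b, function(x) safe_sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Generate paired-end reads pre-aligned at their true positions
#'
#' Fragments are placed uniformly to reach the target mean depth; insert
#' sizes are drawn from a normal distribution; both mates are emitted as
#' proper-pair SAM records whose coordinates are the fragments' true
#' origins. Substitution errors are injected per the profile, with
#' matching low quality scores, and logged base-by-base in a sidecar
#' table.
#'
#' @param genome A \code{ref_genome} to draw reads from.
#' @param depth Target mean coverage (default 20).
#' @param read_len Read length in bp (default 75).
#' @param insert_mean,insert_sd Insert size distribution (defaults 270
#'   and 20, typical paired-end library values).
#' @param profile A \code{\link{read_error_profile}}.
#' @param seed Optional integer seed.
#' @param rg Optional read-group identifier stamped on every read.
#' @param qname_prefix Prefix of generated read names.
#' @return List with \code{reads} (an \code{aln_reads}) and \code{errors}
#'   (sidecar data.frame \code{qname, flag, chrom, read_off, ref_pos,
#'   orig_base, new_base}; \code{read_off} is the 0-based offset in the
#'   stored, reference-oriented sequence).
#' @export
generate_reads <- function(genome, depth = 20, read_len = 75L,
                           insert_mean = 270, insert_sd = 20,
                           profile = read_error_profile(), seed = NULL,
                           rg = NULL, qname_prefix = "sim") {
  if (!is.null(seed)) set.seed(seed)
  lens <- ref_lengths(genome)
  if (read_len > min(lens)) stop("read_len exceeds shortest chromosome")
  ramp <- approx(seq_along(profile$three_prime_ramp),
                 profile$three_prime_ramp, n = read_len)$y
  err_p <- pmin(1, profile$base_error_rate * ramp)
  qual_clean <- int_to_qual(rep(profile$qual_correct, read_len))
  chunks <- list(); errs <- list()
  pair_id0 <- 0L
  for (chrom in names(lens)) {
    clen <- lens[[chrom]]
    n_pairs <- max(0L, round(depth * clen / (2 * read_len)))
    if (n_pairs == 0) next
    ins <- pmax(2L * read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
    ins <- as.integer(pmin(ins, clen))
    start1 <- as.integer(floor(runif(n_pairs, 1, clen - ins + 1 + 1)))
    start2 <- start1 + ins - as.integer(read_len)
    cseq <- ref_seq(genome, chrom)
    qn <- sprintf("%s_%06d", qname_prefix, pair_id0 + seq_len(n_pairs))
    pair_id0 <- pair_id0 + n_pairs
    pos <- c(start1, start2)           # mate 1 then mate 2, ref orientation
    flag <- rep(c(99L, 147L), each = n_pairs)
    sq <- substring(cseq, pos, pos + read_len - 1L)
    qual <- rep(qual_clean, 2L * n_pairs)
    # per-base error probability indexed from the read 5' end; stored
    # orientation is reference-forward, so the ramp reverses for mate 2
    n_reads <- 2L * n_pairs
    u <- runif(n_reads * read_len)
    pvec <- c(rep(err_p, n_pairs), rep(rev(err_p), n_pairs))
    dim(u) <- c(read_len, n_reads)
    hit_idx <- which(u < matrix(pvec, nrow = read_len), arr.ind = TRUE)
    hits <- split(hit_idx[, 1], hit_idx[, 2])
    cs <- profile$cluster_spec
    if (!is.null(cs) && chrom == cs$chrom) {
      in_cl <- which(pos <= cs$end & pos + read_len - 1L >= cs$start)
      for (i in in_cl) {
        extra <- safe_sample(seq_len(read_len), min(cs$errors, read_len))
        hits[[as.character(i)]] <- union(hits[[as.character(i)]], extra)
      }
    }
    for (nm in names(hits)) {
      i <- as.integer(nm)
      hit <- sort(hits[[nm]])
      old <- substring(sq[i], hit, hit)
      keep <- old %in% c("A", "C", "G", "T")
      if (!any(keep)) next
      hit <- hit[keep]; old <- old[keep]
      new <- substitute_base(old)
      sv <- strsplit(sq[i], "", fixed = TRUE)[[1]]
      sv[hit] <- new
      sq[i] <- paste(sv, collapse = "")
      qv <- rep(profile$qual_correct, read_len)
      qv[hit] <- profile$qual_error
      qual[i] <- int_to_qual(qv)
      errs[[length(errs) + 1L]] <- data.frame(
        qname = qn[(i - 1L) %% n_pairs + 1L],
        flag = flag[i], chrom = chrom, read_off = hit - 1L,
        ref_pos = pos[i] + hit - 1L,
        orig_base = old, new_base = new, stringsAsFactors = FALSE)
    }
    chunks[[length(chunks) + 1L]] <- data.frame(
      qname = rep(qn, 2L), flag = flag, chrom = chrom, pos = pos,
      mapq = 60L, cigar = sprintf("%dM", read_len), mchrom = chrom,
      mpos = c(start2, start1), isize = c(ins, -ins),
      seq = sq, qual = qual, rg = rg %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, chunks)
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(qname = character(0), flag = integer(0), chrom = character(0),
               read_off = integer(0), ref_pos = integer(0),
               orig_base = character(0), new_base = character(0),
               stringsAsFactors = FALSE)
  list(reads = aln_reads(df, lens), errors = errors)
}

#' Re-express reads from an unmutated genome as alignments on the
#' mutated genome
#'
#' A simulated study aligns reads of the original sample against a
#' reference carrying introduced mutations. This function performs that
#' alignment exactly (it plays the role of a perfect aligner): each
#' gapless read generated from the original genome is lifted through the
#' simulator truth table into mutated-reference coordinates, with
#' introduced SNPs left as substitutions, sample-frame insertions emitted
#' as I CIGAR ops, deletions as D ops, and read ends falling inside
#' deleted reference sequence soft-clipped. Reads lying entirely within
#' removed sequence are dropped.
#'
#' @param reads An \code{aln_reads} generated from the ORIGINAL genome
#'   (gapless, all-M CIGARs).
#' @param truth Truth table from \code{\link{mutate_genome}} (must carry
#'   the \code{orig_pos} and \code{ref_edit} provenance columns).
#' @param target_ref The mutated \code{ref_genome}.
#' @return An \code{aln_reads} in mutated-reference coordinates.
#' @export
lift_reads <- function(reads, truth, target_ref) {
  tlens <- ref_lengths(target_ref)
  by_chrom <- split(truth, truth$chrom)
  # per-chromosome edit tables with cumulative offsets
  ed <- lapply(by_chrom, function(tt) {
    tt <- tt[order(tt$orig_pos), , drop = FALSE]
    elen <- ifelse(tt$ref_edit == "ins", nchar(tt$ref),
                   ifelse(tt$ref_edit == "del", nchar(tt$alt), 0L))
    delta <- ifelse(tt$ref_edit == "ins", elen,
                    ifelse(tt$ref_edit == "del", -elen, 0L))
    list(p = tt$orig_pos, kind = tt$ref_edit, elen = elen,
         end = tt$orig_pos + ifelse(tt$ref_edit == "del", elen, 0L),
         offafter = cumsum(delta))
  })
  mut_pos <- function(e, x) {
    if (is.null(e)) return(x)
    i <- findInterval(x - 1L, e$end)  # last edit fully left of x
    x + if (i > 0) e$offafter[i] else 0L
  }
  rdf <- as.data.frame(reads)
  keep_row <- rep(FALSE, nrow(rdf))
  new_pos <- rdf$pos; new_cigar <- rdf$cigar
  for (ri in seq_len(nrow(reads))) {
    r <- lapply(rdf, `[`, ri)
    e <- ed[[r$chrom]]
    L <- nchar(r$seq)
    s <- r$pos; en <- s + L - 1L
    ops_len <- integer(0); ops_op <- character(0)
    push <- function(len, op) {
      if (len <= 0) return(invisible(NULL))
      n <- length(ops_len)
      if (n > 0 && ops_op[n] == op) {
        ops_len[n] <<- ops_len[n] + len
      } else {
        ops_len <<- c(ops_len, len); ops_op <<- c(ops_op, op)
      }
      invisible(NULL)
    }
    cur <- s; dropped <- FALSE
    if (!is.null(e)) {
      rel <- which(e$p <= en & e$end >= s - 1L & e$kind != "sub")
      for (j in rel) {
        if (cur > en) break
        if (e$kind[j] == "ins") {
          # junction between orig p and p+1 gains e$elen reference bases
          if (e$p[j] >= cur && e$p[j] < en) {
            push(e$p[j] - cur + 1L, "M")
            push(e$elen[j], "D")
            cur <- e$p[j] + 1L
          }
        } else {  # "del": orig bases p+1 .. p+elen absent from target
          lo <- e$p[j] + 1L; hi <- e$p[j] + e$elen[j]
          if (hi < cur || lo > en) next
          if (cur >= lo) {           # read starts inside removed sequence
            if (en <= hi) { dropped <- TRUE; break }
            push(min(hi, en) - cur + 1L, "S")
            cur <- hi + 1L
          } else if (hi <= en) {
            push(e$p[j] - cur + 1L, "M")
            push(e$elen[j], "I")
            cur <- hi + 1L
          } else {                   # read ends inside removed sequence
            push(e$p[j] - cur + 1L, "M")
            push(en - e$p[j], "S")
            cur <- en + 1L
          }
        }
      }
    }
    if (!dropped && cur <= en) push(en - cur + 1L, "M")
    if (dropped || !any(ops_op == "M")) next
    # SAM pos = mutated coordinate of the first aligned original base;
    # any ops before the first M consume read bases only (leading S)
    mi <- which(ops_op == "M")[1]
    lead <- if (mi > 1) sum(ops_len[seq_len(mi - 1L)]) else 0L
    first_aligned_orig <- s + lead
    pos_mut <- mut_pos(e, first_aligned_orig)
    cigar <- paste0(ops_len, ops_op, collapse = "")
    span <- sum(ops_len[ops_op %in% c("M", "D")])
    if (pos_mut < 1 || pos_mut + span - 1L > tlens[[r$chrom]]) next
    keep_row[ri] <- TRUE
    new_pos[ri] <- pos_mut
    new_cigar[ri] <- cigar
  }
  if (!any(keep_row)) stop("no reads survived the lift")
  rdf$pos <- new_pos
  rdf$cigar <- new_cigar
  aln_reads(rdf[keep_row, , drop = FALSE], tlens,
            attr(reads, "n_unmapped") %||% 0L)
}

#' Inject misaligned foreign reads into an alignment
#'
#' Emulates a "targeted" alignment, where reads belonging elsewhere are
#' attracted into a locally aligned region: reads are drawn from donor
#' sequence, their coordinates forged uniformly into the span covered by
#' the native reads, and extra substitutions are planted until each
#' carries at least \code{mismatch_floor} mismatches against the target
#' reference. A sidecar truth table flags which reads are foreign.
#'
#' @param native An \code{aln_reads} of genuine reads on the target.
#' @param target_ref The target \code{ref_genome}.
#' @param donor_ref A \code{ref_genome} to draw foreign sequence from.
#' @param fraction Foreign reads added as a fraction of native count
#'   (0 <= fraction < 1 of the combined set; interpreted as
#'   n_foreign = round(fraction * n_native)).
#' @param mismatch_floor Minimum substitution count of each injected read
#'   against the target reference (default 4).
#' @param seed Optional integer seed.
#' @return List with \code{reads} (native + foreign combined) and
#'   \code{truth} (data.frame \code{qname, foreign}).
#' @export
inject_foreign_reads <- function(native, target_ref, donor_ref,
                                 fraction = 0.5, mismatch_floor = 4L,
                                 seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n_f <- round(fraction * nrow(native))
  lens <- attr(native, "ref_lengths")
  rows <- list()
  if (n_f > 0) {
    dl <- ref_lengths(donor_ref)
    read_len <- nchar(native$seq[1])
    for (k in seq_len(n_f)) {
      dchrom <- safe_sample(names(dl), 1L)
      dpos <- floor(runif(1, 1, dl[[dchrom]] - read_len + 1 + 1))
      sq <- substr(ref_seq(donor_ref, dchrom), dpos, dpos + read_len - 1L)
      tchrom <- safe_sample(unique(native$chrom), 1L)
      span <- range(native$pos[native$chrom == tchrom])
      tpos <- floor(runif(1, span[1], max(span[1], span[2] - read_len) + 1))
      tref <- substr(ref_seq(target_ref, tchrom), tpos, tpos + read_len - 1L)
      # plant extra substitutions until the mismatch floor is guaranteed
      sqv <- strsplit(sq, "", fixed = TRUE)[[1]]
      trv <- strsplit(tref, "", fixed = TRUE)[[1]]
      mism <- sum(sqv != trv & trv != "N")
      while (mism < mismatch_floor) {
        j <- safe_sample(which(sqv == trv & trv != "N"), 1L)
        sqv[j] <- substitute_base(trv[j])
        mism <- mism + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        qname = sprintf("foreign_%06d", k), flag = 0L,
        chrom = tchrom, pos = as.integer(tpos), mapq = 37L,
        cigar = sprintf("%dM", read_len), mchrom = NA_character_,
        mpos = NA_integer_, isize = NA_integer_,
        seq = paste(sqv, collapse = ""),
        qual = int_to_qual(rep(35L, read_len)),
        rg = NA_character_, stringsAsFactors = FALSE)
    }
  }
  foreign <- if (length(rows)) do.call(rbind, rows) else NULL
  combined <- rbind(as.data.frame(native), foreign)
  truth <- data.frame(qname = combined$qname,
                      foreign = grepl("^foreign_", combined$qname),
                      stringsAsFactors = FALSE)
  list(reads = aln_reads(combined, lens, attr(native, "n_unmapped") %||% 0L),
       truth = truth)
}

#' Generate a pooled-sample alignment from two haplotypes
#'
#' Two read populations, one per haplotype genome, are generated with
#' distinct read groups and merged -- the fixture for pooled-sample
#' (read-group aware) error correction.
#'
#' @param hap1,hap2 \code{ref_genome} haplotypes (same chromosome names).
#' @param depth Combined target depth, split equally.
#' @param rg1,rg2 Read-group identifiers.
#' @param ... Passed to \code{\link{generate_reads}}.
#' @param seed Optional integer seed.
#' @return List with \code{reads} (merged \code{aln_reads}) and
#'   \code{errors} (combined sidecar).
#' @export
generate_pooled_reads <- function(hap1, hap2, depth = 20, rg1 = "s1",
                                  rg2 = "s2", seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  a <- generate_reads(hap1, depth = depth / 2, rg = rg1,
                      qname_prefix = paste0(rg1, "r"), ...)
  b <- generate_reads(hap2, depth = depth / 2, rg = rg2,
                      qname_prefix = paste0(rg2, "r"), ...)
  lens <- ref_lengths(hap1)
  df <- rbind(as.data.frame(a$reads), as.data.frame(b$reads))
  list(reads = aln_reads(df, lens),
       errors = rbind(a$errors, b$errors))
}
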