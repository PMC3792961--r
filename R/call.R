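# Threshold-based SNP and small-indel calling from pileup columns (parsed
# text pileup or pileup built internally from alignments). Calls are
# gated on supporting-read counts, allele frequency and base quality;
# SNPs adjacent to homozygous indels are suppressed.

#' Variant-calling parameters
#'
#' @param num Minimum reads with the non-reference base at a called site
#'   (default 2); gates alleles with frequency at or above
#'   \code{het_boundary}.
#' @param freq Minimum frequency of the called allele among reads covering
#'   the site (default 0.8).
#' @param qual_ave Minimum mean base quality of the non-reference bases;
#'   applies to SNPs only (default 20).
#' @param qual_base Minimum base quality for an individual non-reference
#'   base to support a call (default 3).
#' @param maxr Maximum number of reads covering non-reference alleles;
#'   \code{NULL} disables the cap. A common setting is 3x the average
#'   read depth.
#' @param maxr_mode \code{"alt"} caps the non-reference supporting-read
#'   count (the default reading); \code{"depth"} caps total column depth.
#' @param tnum Minimum reads supporting a heterozygous non-reference
#'   allele, i.e. one with frequency below \code{het_boundary}
#'   (default 3).
#' @param het_boundary Frequency at or above which an allele is treated as
#'   homozygous and gated by \code{num} instead of \code{tnum} (0.9).
#' @return A \code{call_params} list.
#' @export
call_params <- function(num = 2L, freq = 0.8, qual_ave = 20, qual_base = 3,
                        maxr = NULL, maxr_mode = c("alt", "depth"),
                        tnum = 3L, het_boundary = 0.9) {
  maxr_mode <- match.arg(maxr_mode)
  stopifnot(num >= 1, tnum >= 1, freq > 0, freq <= 1,
            het_boundary > 0, het_boundary <= 1)
  structure(list(num = as.integer(num), freq = freq, qual_ave = qual_ave,
                 qual_base = qual_base, maxr = maxr, maxr_mode = maxr_mode,
                 tnum = as.integer(tnum), het_boundary = het_boundary),
            class = "call_params")
}

variant_row <- function(chrom, pos, type, ref, alt, depth, alt_count,
                        freq, mean_qual, zygosity) {
  data.frame(chrom = chrom, pos = as.integer(pos), type = type, ref = ref,
             alt = alt, depth = as.integer(depth),
             alt_count = as.integer(alt_count), freq = freq,
             mean_qual = mean_qual, zygosity = zygosity,
             stringsAsFactors = FALSE)
}

#' Call a SNP from one pileup column
#'
#' Non-reference bases below \code{qual_base} are excluded from allele
#' support. The majority non-reference allele (ties yield no call) is
#' called when its frequency over the column depth reaches \code{freq},
#' its mean base quality reaches \code{qual_ave}, the \code{maxr} cap (if
#' set) is not exceeded, and its supporting-read count reaches \code{num}
#' (frequency >= \code{het_boundary}: homozygous) or \code{tnum}
#' (below it: heterozygous). No call is made at ambiguous (non-ACGT)
#' reference bases.
#'
#' @param col A \code{\link{pileup_column}}.
#' @param params A \code{\link{call_params}}.
#' @return One-row variant data.frame, or \code{NULL}.
#' @export
call_snp <- function(col, params = call_params()) {
  if (!(col$ref_base %in% c("A", "C", "G", "T"))) return(NULL)
  depth <- col$depth
  if (depth < 1) return(NULL)
  ok <- col$bases %in% c("A", "C", "G", "T") & col$bases != col$ref_base &
    !is.na(col$quals) & col$quals >= params$qual_base
  if (!any(ok)) return(NULL)
  tab <- sort(table(col$bases[ok]), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NULL)  # ambiguous majority
  alt <- names(tab)[1]
  alt_count <- as.integer(tab[1])
  alt_freq <- alt_count / depth
  mean_q <- mean(col$quals[ok & col$bases == alt])
  if (alt_freq < params$freq) return(NULL)
  if (mean_q < params$qual_ave) return(NULL)
  if (!is.null(params$maxr)) {
    covered <- if (params$maxr_mode == "alt") sum(ok) else depth
    if (covered > params$maxr) return(NULL)
  }
  if (alt_freq >= params$het_boundary) {
    if (alt_count < params$num) return(NULL)
    zyg <- "hom"
  } else {
    if (alt_count < params$tnum) return(NULL)
    zyg <- "het"
  }
  variant_row(col$chrom, col$pos, "SNP", col$ref_base, alt, depth,
              alt_count, alt_freq, mean_q, zyg)
}

#' Call an indel from one pileup column
#'
#' Support is the number of reads carrying the identical indel allele
#' (type, length and sequence). The frequency denominator is the column
#' depth minus the number of reads whose 3' termini (including
#' soft-clipped ends) are located at the site -- reads ending at the site
#' cannot attest an indel that starts past their end, so excluding them
#' lets indels be recovered from low-coverage regions. \code{qual_ave}
#' is not applied to indels.
#'
#' @param col A \code{\link{pileup_column}} with indel observations.
#' @param params A \code{\link{call_params}}.
#' @return One-row variant data.frame, or \code{NULL}.
#' @export
call_indel <- function(col, params = call_params()) {
  d <- col$indels
  if (is.null(d) || nrow(d) == 0) return(NULL)
  if (!(col$ref_base %in% c("A", "C", "G", "T"))) return(NULL)
  key <- paste(d$type, d$len, d$seq, sep = "|")
  tab <- sort(table(key), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NULL)
  parts <- strsplit(names(tab)[1], "|", fixed = TRUE)[[1]]
  type <- parts[1]; len <- as.integer(parts[2]); seqa <- parts[3]
  support <- as.integer(tab[1])
  denom <- col$depth - col$end3_count
  if (denom < 1) return(NULL)
  f <- support / denom
  if (support < params$num) return(NULL)
  if (f < params$freq) return(NULL)
  if (!is.null(params$maxr)) {
    covered <- if (params$maxr_mode == "alt") support else col$depth
    if (covered > params$maxr) return(NULL)
  }
  zyg <- if (f >= params$het_boundary) "hom" else "het"
  # both INS and DEL observations are anchored at the base preceding the
  # event (samtools convention), so the call position is the column's
  if (type == "INS") {
    variant_row(col$chrom, col$pos, "INS", "-", seqa, col$depth, support,
                min(f, 1), NA_real_, zyg)
  } else {
    variant_row(col$chrom, col$pos, "DEL", seqa, "-", col$depth,
                support, min(f, 1), NA_real_, zyg)
  }
}

#' Suppress SNP calls adjacent to homozygous indels
#'
#' SNPs within 3 bp upstream or downstream of a homozygous indel call on
#' the same chromosome are dropped; indel calls are unaffected and
#' heterozygous indels do not suppress.
#'
#' @param calls A \code{variant_calls} data.frame.
#' @param window Suppression distance in bp (default 3).
#' @return Filtered \code{variant_calls}.
#' @export
suppress_near_indel <- function(calls, window = 3L) {
  if (nrow(calls) == 0) return(as_variants(calls))
  hom_ind <- calls[calls$type %in% c("INS", "DEL") & calls$zygosity == "hom", ]
  if (nrow(hom_ind) == 0) return(as_variants(calls))
  drop <- rep(FALSE, nrow(calls))
  for (i in which(calls$type == "SNP")) {
    near <- hom_ind$chrom == calls$chrom[i] &
      abs(hom_ind$pos - calls$pos[i]) <= window
    if (any(near)) drop[i] <- TRUE
  }
  as_variants(calls[!drop, , drop = FALSE])
}

#' Call SNPs and indels
#'
#' Applies \code{\link{call_snp}} and \code{\link{call_indel}} to every
#' column, then \code{\link{suppress_near_indel}}. Input may be a list of
#' pileup columns (from \code{\link{read_pileup}} or
#' \code{\link{pileup_from_reads}}), an \code{aln_reads} object (columns
#' are generated internally; requires \code{ref}), or a path to a
#' SAM/BAM or pileup file.
#'
#' @param x Pileup columns, alignments, or a file path.
#' @param params A \code{\link{call_params}}.
#' @param ref A \code{ref_genome}; required for alignment input.
#' @param dialect Pileup text dialect, for pileup file paths.
#' @return A \code{variant_calls} data.frame.
#' @export
call_variants <- function(x, params = call_params(), ref = NULL,
                          dialect = c("consensus10", "mpileup6")) {
  if (is.character(x)) {
    if (grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
      x <- read_alignments(x, ref = ref)
    } else {
      x <- read_pileup(x, match.arg(dialect))
    }
  }
  if (inherits(x, "aln_reads")) {
    if (is.null(ref)) stop("calling from alignments requires ref")
    x <- pileup_from_reads(x, ref, positions = "variant")
  }
  rows <- list()
  for (col in x) {
    s <- call_snp(col, params)
    if (!is.null(s)) rows[[length(rows) + 1L]] <- s
    d <- call_indel(col, params)
    if (!is.null(d)) rows[[length(rows) + 1L]] <- d
  }
  calls <- if (length(rows)) do.call(rbind, rows) else empty_variants()
  suppress_near_indel(as_variants(calls))
}
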