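# Reference-genome mutation simulator and truth-set evaluator. SNPs and
# 1-6 bp indels are introduced into a reference at user-set rates (default
# 0.2% and 0.02% of positions), with transitions drawn 4-fold more often
# than transversions and indel lengths following an empirical table
# (66/17/7/7/2/1% for 1..6 bp). Because the unmutated sample's reads are
# aligned TO the mutated reference, the truth table records the variant a
# caller should observe (an insertion written into the reference appears
# to the caller as a deletion, and vice versa), in mutated-reference
# coordinates; original coordinates and the applied reference edit are
# kept as provenance columns.

#' Simulation parameters
#'
#' @param snp_rate SNPs per reference position (default 0.002, i.e. 0.2%).
#' @param indel_rate Indels per reference position (default 0.0002).
#' @param snp_count,indel_count Absolute counts; override the rates.
#' @param titv_ratio Desired transition:transversion count ratio among
#'   simulated SNPs (default 4): per site the transition partner is drawn
#'   with probability \code{titv_ratio/(titv_ratio+1)} and each
#'   transversion partner with half the remainder.
#' @param indel_length_weights Proportions of indel lengths 1..6 bp;
#'   must sum to 1.
#' @param length_sampling \code{"apportion"} (default) fixes the length
#'   histogram deterministically by largest remainder; \code{"sample"}
#'   draws lengths from the weights.
#' @param clustered Optional stress mode: proportion of variants placed in
#'   clusters of >= 3 within \code{cluster_span} bp (default 0 = off).
#' @param cluster_span Span of a cluster in bp (default 75, a read length).
#' @return A \code{sim_params} list.
#' @export
sim_params <- function(snp_rate = 0.002, indel_rate = 0.0002,
                       snp_count = NULL, indel_count = NULL,
                       titv_ratio = 4,
                       indel_length_weights = c(`1` = 0.66, `2` = 0.17,
                                                `3` = 0.07, `4` = 0.07,
                                                `5` = 0.02, `6` = 0.01),
                       length_sampling = c("apportion", "sample"),
                       clustered = 0, cluster_span = 75L) {
  stopifnot(titv_ratio > 0,
            abs(sum(indel_length_weights) - 1) < 1e-8,
            clustered >= 0, clustered <= 1)
  structure(list(snp_rate = snp_rate, indel_rate = indel_rate,
                 snp_count = snp_count, indel_count = indel_count,
                 titv_ratio = titv_ratio,
                 indel_length_weights = indel_length_weights,
                 length_sampling = match.arg(length_sampling),
                 clustered = clustered,
                 cluster_span = as.integer(cluster_span)),
            class = "sim_params")
}

#' Apportion a total count across chromosomes by length
#'
#' Counts proportional to chromosome lengths, integerized by the largest
#' remainder method (ties broken by input order), summing exactly to the
#' total. Used both for spreading mutations over chromosomes and for
#' fixing the indel-length histogram.
#'
#' @param total Non-negative integer total.
#' @param lengths Named numeric vector of weights (e.g. chromosome bp).
#' @return Named integer vector summing to \code{total}.
#' @export
apportion <- function(total, lengths) {
  stopifnot(total >= 0, length(lengths) > 0, all(lengths >= 0),
            sum(lengths) > 0)
  q <- as.numeric(total) * as.numeric(lengths) / sum(as.numeric(lengths))
  names(q) <- names(lengths)
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    extra <- order(-(q - base), seq_along(q))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(lengths))
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Draw substituted bases under the transition/transversion model
#'
#' For each reference base the transition partner is chosen with
#' probability \code{r/(r+1)} where \code{r} is the configured
#' transition:transversion count ratio; the two transversion partners
#' split the remainder equally. The drawn base never equals the
#' reference.
#'
#' @param ref_base Character vector of reference bases (A/C/G/T).
#' @param titv_ratio Transition:transversion count ratio (default 4).
#' @return Character vector of alternate bases.
#' @export
draw_snp <- function(ref_base, titv_ratio = 4) {
  if (any(!ref_base %in% c("A", "C", "G", "T"))) {
    stop("draw_snp requires unambiguous reference bases (A/C/G/T)")
  }
  p_ti <- titv_ratio / (titv_ratio + 1)
  u <- runif(length(ref_base))
  pick <- ifelse(u < p_ti, 1L, ifelse(u < p_ti + (1 - p_ti) / 2, 2L, 3L))
  vapply(seq_along(ref_base), function(i) {
    b <- ref_base[i]
    if (pick[i] == 1L) TRANSITION[[b]] else TRANSVERSIONS[[b]][pick[i] - 1L]
  }, character(1))
}

#' Is a substitution a transition?
#' @param ref,alt Single-base character vectors.
#' @return Logical vector: \code{TRUE} for A<->G and C<->T changes.
#' @export
is_transition <- function(ref, alt) {
  unname(TRANSITION[ref] == alt)
}

# Eligible positions on one chromosome: non-N with a non-N neighbourhood
# wide enough for the largest footprint, spaced so no two mutation
# footprints overlap or abut.
place_positions <- function(seqstr, n_needed, max_len, cluster_n = 0L,
                            cluster_span = 75L) {
  len <- nchar(seqstr)
  if (n_needed == 0) return(integer(0))
  pad <- max_len + 1L
  bases <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  okN <- bases != "N"
  # positions where [p - 1, p + pad] is N-free and inside the chromosome
  run <- cumsum(!okN)
  good <- function(p) {
    # vectorized over candidate positions (p > 1, p + pad <= len holds)
    (run[p + pad] - run[p - 1L]) == 0L & okN[p - 1L]
  }
  elig <- which(okN)
  elig <- elig[elig > 1L & elig + pad <= len]
  if (length(elig) < n_needed * 2) {
    stop("chromosome too small (or too N-rich) for requested mutation count")
  }
  accepted <- integer(0)
  tries <- 0L
  remaining <- elig
  spacing <- pad + 1L
  while (length(accepted) < n_needed && tries < 50L) {
    tries <- tries + 1L
    want <- n_needed - length(accepted)
    cand <- sort(safe_sample(remaining, min(length(remaining), want * 2L + 10L)))
    if (length(cand)) cand <- cand[good(cand)]
    all_p <- sort(c(accepted, cand))
    keep <- rep(TRUE, length(all_p))
    last <- -spacing
    for (j in seq_along(all_p)) {
      if (all_p[j] - last >= spacing) last <- all_p[j] else keep[j] <- FALSE
    }
    accepted <- sort(unique(all_p[keep]))
    if (length(accepted) > n_needed) {
      accepted <- sort(safe_sample(accepted, n_needed))
    }
    remaining <- setdiff(remaining, cand)
    if (length(remaining) == 0) break
  }
  if (length(accepted) < n_needed) {
    stop("could not place ", n_needed, " mutations with required spacing")
  }
  sort(accepted)
}

# Stress mode: move a fraction of placed positions next to randomly
# chosen anchors so that >= 3 variants fall within one read length,
# keeping the minimum footprint spacing. Relocations that would collide
# with neighbours or N bases are skipped, so the achieved clustering is
# approximate.
form_clusters <- function(pos, seqstr, frac, span, spacing = 8L) {
  n_cl <- floor(frac * length(pos) / 3)
  if (n_cl < 1) return(pos)
  len <- nchar(seqstr)
  anchors <- safe_sample(seq_along(pos), n_cl)
  movable <- setdiff(seq_along(pos), anchors)
  for (a in anchors) {
    if (length(movable) < 2) break
    mv <- safe_sample(movable, 2)
    slots <- pos[a] + spacing * c(1L, 2L)
    ok <- all(slots + spacing <= len) &&
      !grepl("N", substr(seqstr, pos[a], max(slots) + spacing)) &&
      !any(abs(outer(slots, pos[-c(a, mv)], "-")) < spacing)
    if (ok) {
      pos[mv] <- slots
      movable <- setdiff(movable, mv)
    }
  }
  sort(pos)
}

#' Introduce SNPs and short indels into a reference genome
#'
#' Mutation counts are apportioned over chromosomes by length (largest
#' remainder); indel lengths follow the configured table, apportioned
#' deterministically by default. Mutations avoid N bases and never
#' overlap or abut one another. Reference edits are split 50/50 between
#' insertions and deletions; the truth table records each variant as a
#' caller aligned against the mutated genome observes it (reference
#' insertions appear as sample deletions and vice versa), positioned in
#' mutated-reference coordinates with the original coordinate kept in
#' \code{orig_pos}.
#'
#' @param ref A \code{ref_genome}.
#' @param params A \code{\link{sim_params}}.
#' @param seed Optional integer seed (deterministic output under a fixed
#'   seed).
#' @return List with \code{genome} (mutated \code{ref_genome}) and
#'   \code{truth} (data.frame \code{chrom, pos, type, ref, alt, orig_pos,
#'   ref_edit}, sorted by chrom then pos).
#' @export
mutate_genome <- function(ref, params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- ref_lengths(ref)
  genome_len <- sum(lens)
  n_snp <- params$snp_count %||% round(params$snp_rate * genome_len)
  n_indel <- params$indel_count %||% round(params$indel_rate * genome_len)
  snp_per_chr <- apportion(n_snp, lens)
  ind_per_chr <- apportion(n_indel, lens)
  # global indel length multiset
  w <- params$indel_length_weights
  lens_ind <- if (params$length_sampling == "apportion") {
    counts <- apportion(n_indel, w)
    rep(as.integer(names(w)), counts)
  } else {
    sample(as.integer(names(w)), n_indel, replace = TRUE, prob = w)
  }
  if (length(lens_ind)) lens_ind <- safe_sample(lens_ind)  # deal into chromosomes
  ind_off <- 0L
  out_seqs <- character(length(lens))
  names(out_seqs) <- names(lens)
  truth_l <- list()
  for (ci in seq_along(lens)) {
    chrom <- names(lens)[ci]
    s <- ref_seq(ref, chrom)
    ns <- snp_per_chr[[chrom]]; ni <- ind_per_chr[[chrom]]
    ntot <- ns + ni
    if (ntot == 0) { out_seqs[ci] <- s; next }
    pos <- place_positions(s, ntot, max_len = 6L)
    if (params$clustered > 0 && ntot >= 3) {
      pos <- form_clusters(pos, s, params$clustered, params$cluster_span)
    }
    is_snp <- rep(FALSE, ntot)
    if (ns > 0) is_snp[sample.int(ntot, ns)] <- TRUE
    my_lens <- if (ni > 0) lens_ind[ind_off + seq_len(ni)] else integer(0)
    ind_off <- ind_off + ni
    # reference edit direction: insertion into ref (caller sees DEL) or
    # deletion from ref (caller sees INS)
    edit_ins <- if (ni > 0) runif(ni) < 0.5 else logical(0)
    # assemble edits sorted by position
    edits <- data.frame(pos = pos, is_snp = is_snp)
    li <- 1L
    edits$len <- 0L; edits$edit <- "SNP"; edits$seq <- ""
    bases <- substring(s, pos, pos)
    snp_alt <- character(ntot)
    if (ns > 0) snp_alt[is_snp] <- draw_snp(bases[is_snp], params$titv_ratio)
    for (j in seq_len(ntot)) {
      if (!edits$is_snp[j]) {
        L <- my_lens[li]
        if (edit_ins[li]) {
          edits$edit[j] <- "ref_ins"
          edits$seq[j] <- paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")
        } else {
          edits$edit[j] <- "ref_del"
          edits$seq[j] <- substr(s, pos[j] + 1L, pos[j] + L)
        }
        edits$len[j] <- L
        li <- li + 1L
      }
    }
    # build mutated sequence and truth records in one left-to-right pass
    # (pieces preallocated: appending with c() is quadratic at this scale)
    pieces <- character(2L * ntot + 1L)
    np <- 0L
    push_piece <- function(x) {
      np <<- np + 1L
      pieces[np] <<- x
    }
    cur <- 1L; off <- 0L
    t_pos <- integer(ntot); t_type <- character(ntot)
    t_ref <- character(ntot); t_alt <- character(ntot)
    t_edit <- character(ntot)
    for (j in seq_len(ntot)) {
      p <- edits$pos[j]
      if (edits$edit[j] == "SNP") {
        push_piece(substr(s, cur, p - 1L)); push_piece(snp_alt[j])
        cur <- p + 1L
        t_pos[j] <- p + off; t_type[j] <- "SNP"
        t_ref[j] <- snp_alt[j]; t_alt[j] <- bases[j]; t_edit[j] <- "sub"
      } else if (edits$edit[j] == "ref_ins") {
        push_piece(substr(s, cur, p)); push_piece(edits$seq[j])
        cur <- p + 1L
        t_pos[j] <- p + off; t_type[j] <- "DEL"
        t_ref[j] <- edits$seq[j]; t_alt[j] <- "-"; t_edit[j] <- "ins"
        off <- off + edits$len[j]
      } else {  # ref_del
        push_piece(substr(s, cur, p))
        cur <- p + edits$len[j] + 1L
        t_pos[j] <- p + off; t_type[j] <- "INS"
        t_ref[j] <- "-"; t_alt[j] <- edits$seq[j]; t_edit[j] <- "del"
        off <- off - edits$len[j]
      }
    }
    push_piece(substr(s, cur, nchar(s)))
    out_seqs[ci] <- paste(pieces[seq_len(np)], collapse = "")
    truth_l[[ci]] <- data.frame(chrom = chrom, pos = t_pos, type = t_type,
                                ref = t_ref, alt = t_alt, orig_pos = edits$pos,
                                ref_edit = t_edit, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_l[!vapply(truth_l, is.null, logical(1))])
  if (is.null(truth)) {
    truth <- data.frame(chrom = character(0), pos = integer(0),
                        type = character(0), ref = character(0),
                        alt = character(0), orig_pos = integer(0),
                        ref_edit = character(0), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = ref_genome(out_seqs), truth = truth)
}

#' Apply variants to a genome
#'
#' Applies SNP/INS/DEL records (variant frame: the carrier's sequence
#' relative to the given reference) to reconstruct the carrier sequence.
#' Applying a simulator truth table to the mutated genome reproduces the
#' original genome exactly.
#'
#' @param ref A \code{ref_genome} (the frame of \code{variants}).
#' @param variants Data frame with \code{chrom, pos, type, ref, alt}
#'   (truth table or \code{variant_calls}).
#' @return A \code{ref_genome} with the variants applied.
#' @export
apply_variants <- function(ref, variants) {
  lens <- ref_lengths(ref)
  out <- character(length(lens)); names(out) <- names(lens)
  for (ci in seq_along(lens)) {
    chrom <- names(lens)[ci]
    s <- ref_seq(ref, chrom)
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    pieces <- character(0); cur <- 1L
    for (j in seq_len(nrow(v))) {
      p <- v$pos[j]
      if (v$type[j] == "SNP") {
        pieces <- c(pieces, substr(s, cur, p - 1L), v$alt[j])
        cur <- p + 1L
      } else if (v$type[j] == "INS") {
        pieces <- c(pieces, substr(s, cur, p), v$alt[j])
        cur <- p + 1L
      } else {  # DEL: reference bases p+1 .. p+nchar(ref) removed
        pieces <- c(pieces, substr(s, cur, p))
        cur <- p + nchar(v$ref[j]) + 1L
      }
    }
    out[ci] <- paste(c(pieces, substr(s, cur, nchar(s))), collapse = "")
  }
  ref_genome(out)
}

#' Score calls against a simulator truth table
#'
#' A call matches a truth record iff chromosome, position, type and
#' alleles agree exactly (for indels: type, length and sequence). The
#' true positive rate is 100 x matched truth records / truth records; the
#' false positive rate is 100 x unmatched calls / total calls. SNPs and
#' indels are scored separately.
#'
#' @param calls A \code{variant_calls} data.frame.
#' @param truth Truth table from \code{\link{mutate_genome}}.
#' @param type Classes to score: \code{"snp"}, \code{"indel"} or both.
#' @return Data frame with one row per class: \code{type, n_truth,
#'   n_called, n_matched, tpr, fpr} (percentages).
#' @export
evaluate_calls <- function(calls, truth, type = c("snp", "indel")) {
  type <- match.arg(type, several.ok = TRUE)
  keyify <- function(df) paste(df$chrom, df$pos, df$type, df$ref, df$alt)
  rows <- lapply(type, function(tp) {
    want <- if (tp == "snp") "SNP" else c("INS", "DEL")
    tt <- truth[truth$type %in% want, , drop = FALSE]
    cc <- calls[calls$type %in% want, , drop = FALSE]
    if (nrow(tt) == 0) {
      stop("truth table contains no ", tp, " records; TPR undefined")
    }
    matched <- sum(keyify(tt) %in% keyify(cc))
    n_called <- nrow(cc)
    fp <- sum(!(keyify(cc) %in% keyify(tt)))
    fpr <- if (n_called == 0) {
      warning("no ", tp, " calls; FPR reported as 0")
      0
    } else 100 * fp / n_called
    data.frame(type = tp, n_truth = nrow(tt), n_called = n_called,
               n_matched = matched, tpr = 100 * matched / nrow(tt),
               fpr = fpr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
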