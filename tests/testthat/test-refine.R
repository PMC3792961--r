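# Local realignment, error correction and read filtering.

test_that("indel catalogue aggregates distinct indel observations", {
  g <- random_genome(100, seed = 21)
  s <- unclass(g)[["c1"]]
  # two reads sharing a 1 bp deletion at position 31 (10M1D10M from pos 21)
  del_seq <- paste0(substr(s, 21, 30), substr(s, 32, 41))
  reads <- mk_reads(
    list(qname = "a", pos = 21L, cigar = "10M1D10M", seq = del_seq,
         qual = q35(20)),
    list(qname = "b", pos = 21L, cigar = "10M1D10M", seq = del_seq,
         qual = q35(20)),
    lens = ref_lengths(g))
  cat1 <- build_indel_catalog(reads, g)
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$support, 2L)
  expect_equal(cat1$type, "DEL")
  expect_equal(cat1$ref_pos, 31L)

  # same-position insertions with different sequences are distinct entries
  ins <- function(q, iseq) {
    list(qname = q, pos = 21L, cigar = "10M2I8M",
         seq = paste0(substr(s, 21, 30), iseq, substr(s, 31, 38)),
         qual = q35(20))
  }
  reads2 <- mk_reads(ins("a", "AG"), ins("b", "AC"), lens = ref_lengths(g))
  cat2 <- build_indel_catalog(reads2, g)
  expect_equal(nrow(cat2), 2L)
  expect_setequal(cat2$seq, c("AG", "AC"))

  # no indels -> empty catalogue
  reads3 <- mk_reads(list(qname = "a", pos = 1L, cigar = "10M",
                          seq = substr(s, 1, 10), qual = q35(10)),
                     lens = ref_lengths(g))
  expect_equal(nrow(build_indel_catalog(reads3, g)), 0L)
})

test_that("realignment recovers a gapless read spanning a deletion", {
  g <- random_genome(200, seed = 22)
  s <- unclass(g)[["c1"]]
  # true event: 2 bp deletion of ref 101-102
  # a supporting read that carries the deletion in its CIGAR:
  sup_seq <- paste0(substr(s, 81, 100), substr(s, 103, 122))
  # a misaligned gapless read: sample sequence skips 101-102, aligned 40M
  mis_seq <- paste0(substr(s, 91, 100), substr(s, 103, 132))
  reads <- mk_reads(
    list(qname = "sup", pos = 81L, cigar = "20M2D20M", seq = sup_seq,
         qual = q35(40)),
    list(qname = "mis", pos = 91L, cigar = "40M", seq = mis_seq,
         qual = q35(40)),
    lens = ref_lengths(g))
  diffs <- read_diffs(reads, g)
  c0 <- count_mismatches(diffs[[2]])
  expect_gt(c0, 1L)  # the gapless placement shows spurious substitutions
  catalog <- build_indel_catalog(reads, g)
  res <- local_realign(reads[2, ], diffs[[2]], catalog, g)
  expect_true(res$changed)
  expect_equal(count_mismatches(res$diff), 1L)  # only the deletion remains
  expect_equal(res$read$cigar, "10M2D30M")
  expect_equal(res$read$pos, 91L)
  # oracle: brute-force enumeration over all single-gap placements finds
  # no better alignment than the accepted one
  best <- oracle_best_gap(mis_seq, "c1", g, "DEL", 2L, pos_range = 85:95)
  expect_equal(count_mismatches(res$diff), best)
})

test_that("realignment never accepts a worse placement and skips clean reads", {
  g <- random_genome(200, seed = 23)
  s <- unclass(g)[["c1"]]
  reads <- mk_reads(
    list(qname = "clean", pos = 51L, cigar = "30M", seq = substr(s, 51, 80),
         qual = q35(30)),
    list(qname = "del", pos = 101L, cigar = "10M1D20M",
         seq = paste0(substr(s, 101, 110), substr(s, 112, 131)),
         qual = q35(30)),
    lens = ref_lengths(g))
  diffs <- read_diffs(reads, g)
  catalog <- build_indel_catalog(reads, g)
  # a clean read (0 events) passes through untouched
  res <- local_realign(reads[1, ], diffs[[1]], catalog, g)
  expect_false(res$changed)
  # realign_reads leaves total mismatch mass no worse anywhere
  re <- realign_reads(reads, g)
  for (i in seq_len(nrow(reads))) {
    expect_lte(count_mismatches(re$diffs[[i]]),
               count_mismatches(diffs[[i]]))
  }
})

test_that("quality-rule correction rewrites only low-quality alleles to the reference", {
  g <- ref_genome(c(c1 = strrep("A", 40)))
  reads <- mk_reads(
    list(qname = "r1", pos = 1L, cigar = "10M", seq = strrep("A", 10),
         qual = q35(10)),
    list(qname = "r2", pos = 1L, cigar = "10M", seq = strrep("A", 10),
         qual = q35(10)),
    list(qname = "r3", pos = 1L, cigar = "10M", seq = strrep("A", 10),
         qual = q35(10)),
    list(qname = "r4", pos = 1L, cigar = "10M", seq = strrep("A", 10),
         qual = q35(10)),
    list(qname = "r5", pos = 1L, cigar = "10M",
         seq = paste0("AAAA", "C", "AAAAA"), qual = qv(c(rep(35, 4), 5, rep(35, 5)))),
    lens = c(c1 = 40L))
  res <- error_correct(reads, g, refine_params(mode = "error_correction"))
  expect_equal(res$n_corrected, 1L)
  expect_equal(res$reads$seq[res$reads$qname == "r5"], strrep("A", 10))
  # quality preserved on the corrected base
  expect_equal(res$reads$qual[res$reads$qname == "r5"],
               qv(c(rep(35, 4), 5, rep(35, 5))))

  # high-quality balanced site is untouched (mean qual 30 >= 10, freq >= 0)
  reads2 <- mk_reads(
    list(qname = "r1", pos = 1L, cigar = "4M", seq = "AAAA", qual = q35(4)),
    list(qname = "r2", pos = 1L, cigar = "4M", seq = "AAAA", qual = q35(4)),
    list(qname = "r3", pos = 1L, cigar = "4M", seq = "CAAA", qual = qv(rep(30, 4))),
    list(qname = "r4", pos = 1L, cigar = "4M", seq = "CAAA", qual = qv(rep(30, 4))),
    lens = c(c1 = 40L))
  res2 <- error_correct(reads2, g, refine_params(mode = "error_correction"))
  expect_equal(res2$n_corrected, 0L)
  expect_equal(sort(res2$reads$seq), sort(reads2$seq))
})

test_that("multi-allele rule corrects the minority non-reference allele", {
  g <- ref_genome(c(c1 = strrep("A", 40)))
  reads <- mk_reads(
    list(qname = "r1", pos = 1L, cigar = "4M", seq = "CAAA", qual = qv(rep(30, 4))),
    list(qname = "r2", pos = 1L, cigar = "4M", seq = "CAAA", qual = qv(rep(30, 4))),
    list(qname = "r3", pos = 1L, cigar = "4M", seq = "CAAA", qual = qv(rep(30, 4))),
    list(qname = "r4", pos = 1L, cigar = "4M", seq = "GAAA", qual = qv(rep(30, 4))),
    lens = c(c1 = 40L))
  res <- error_correct(reads, g, refine_params(mode = "error_correction"))
  # G (frequency 1/4) is corrected; C (3/4) is retained
  expect_equal(res$reads$seq[res$reads$qname == "r4"], "AAAA")
  expect_equal(res$reads$seq[res$reads$qname == "r1"], "CAAA")
})

test_that("frequency-rule correction fires below mfreq", {
  g <- ref_genome(c(c1 = strrep("A", 40)))
  reads <- mk_reads(
    list(qname = "r1", pos = 1L, cigar = "4M", seq = "CAAA", qual = qv(rep(30, 4))),
    list(qname = "r2", pos = 1L, cigar = "4M", seq = "AAAA", qual = q35(4)),
    list(qname = "r3", pos = 1L, cigar = "4M", seq = "AAAA", qual = q35(4)),
    list(qname = "r4", pos = 1L, cigar = "4M", seq = "AAAA", qual = q35(4)),
    list(qname = "r5", pos = 1L, cigar = "4M", seq = "AAAA", qual = q35(4)),
    lens = c(c1 = 40L))
  # freq 0.2 >= default mfreq 0 and qual 30 >= 10: untouched
  res0 <- error_correct(reads, g, refine_params(mode = "error_correction"))
  expect_equal(res0$n_corrected, 0L)
  # with mfreq 0.3 the 0.2-frequency allele is corrected
  res1 <- error_correct(reads, g, refine_params(mode = "error_correction",
                                                mfreq = 0.3))
  expect_equal(res1$n_corrected, 1L)
  expect_equal(res1$reads$seq[1], "AAAA")
})

test_that("pooled-sample correction applies per-read-group thresholds", {
  g <- ref_genome(c(c1 = strrep("A", 40)))
  mk <- function(q, seq, rg, qual = q35(4)) {
    list(qname = q, pos = 1L, cigar = "4M", seq = seq, qual = qual, rg = rg)
  }
  reads <- mk_reads(
    # sample s1 (hom): 3/4 reads carry C -> freq 0.75 < 0.8 -> corrected
    mk("a1", "CAAA", "s1", qv(rep(30, 4))), mk("a2", "CAAA", "s1", qv(rep(30, 4))),
    mk("a3", "CAAA", "s1", qv(rep(30, 4))), mk("a4", "AAAA", "s1"),
    # sample s2 (het): 2/4 reads carry C -> freq 0.5 >= 0.3 -> retained
    mk("b1", "CAAA", "s2", qv(rep(30, 4))), mk("b2", "CAAA", "s2", qv(rep(30, 4))),
    mk("b3", "AAAA", "s2"), mk("b4", "AAAA", "s2"),
    lens = c(c1 = 40L))
  params <- refine_params(mode = "error_correction",
                          msamp = c(s1 = "hom", s2 = "het"))
  res <- error_correct(reads, g, params)
  expect_equal(res$n_corrected, 3L)
  expect_true(all(res$reads$seq[res$reads$rg == "s1"] == "AAAA"))
  expect_equal(sum(res$reads$seq[res$reads$rg == "s2"] == "CAAA"), 2L)

  # a read without a read group is an error in pooled mode
  reads_bad <- mk_reads(mk("a1", "CAAA", "s1"),
                        list(qname = "x", pos = 1L, cigar = "4M",
                             seq = "CAAA", qual = q35(4)),
                        lens = c(c1 = 40L))
  expect_error(error_correct(reads_bad, g, params), "read group")
})

test_that("correction only ever rewrites bases to the reference", {
  g <- random_genome(400, seed = 31)
  fx <- generate_reads(g, depth = 12, read_len = 40, insert_mean = 100,
                       insert_sd = 8, seed = 32,
                       profile = read_error_profile(base_error_rate = 0.02))
  res <- error_correct(fx$reads, g, refine_params(mode = "error_correction"))
  s <- unclass(g)[["c1"]]
  changed <- 0L
  for (i in seq_len(nrow(fx$reads))) {
    before <- strsplit(fx$reads$seq[i], "")[[1]]
    after <- strsplit(res$reads$seq[i], "")[[1]]
    diffpos <- which(before != after)
    changed <- changed + length(diffpos)
    if (length(diffpos)) {
      refbases <- strsplit(substr(s, fx$reads$pos[i],
                                  fx$reads$pos[i] + 39L), "")[[1]]
      # every edit rewrites to the reference base
      expect_equal(after[diffpos], refbases[diffpos])
      # and never touches a base that already matched the reference
      expect_false(any(before[diffpos] == refbases[diffpos]))
    }
  }
  expect_equal(changed, res$n_corrected)
  expect_gt(res$n_corrected, 0L)
})

test_that("filter_reads removes reads by each rule with a logged reason", {
  g <- random_genome(300, seed = 24)
  s <- unclass(g)[["c1"]]
  seg <- function(a, b) substr(s, a, b)
  mut <- function(seq, n) {
    v <- strsplit(seq, "")[[1]]
    at <- seq(3, length.out = n, by = 7)
    v[at] <- vapply(v[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
    paste(v, collapse = "")
  }
  reads <- mk_reads(
    list(qname = "many", pos = 11L, cigar = "30M", seq = mut(seg(11, 40), 3),
         qual = q35(30)),
    list(qname = "dclip", pos = 61L, cigar = "2S26M2S",
         seq = paste0("TT", seg(61, 86), "TT"), qual = q35(30)),
    list(qname = "ok", pos = 101L, cigar = "30M", seq = seg(101, 130),
         qual = q35(30)),
    list(qname = "mateless", flag = 9L, pos = 141L, cigar = "30M",
         seq = seg(141, 170), qual = q35(30)),
    lens = ref_lengths(g))
  res <- filter_reads(reads, g, refine_params(num = 2))
  expect_setequal(res$reads$qname, "ok")
  rl <- setNames(res$removed$reason, res$removed$qname)
  expect_equal(unname(rl["many"]), "num")
  expect_equal(unname(rl["dclip"]), "double_clip")
  expect_equal(unname(rl["mateless"]), "discordant")
})

test_that("pair-level fnum removes both mates", {
  g <- random_genome(300, seed = 25)
  s <- unclass(g)[["c1"]]
  mut <- function(seq, n) {
    v <- strsplit(seq, "")[[1]]
    at <- seq(5, length.out = n, by = 9)
    v[at] <- vapply(v[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
    paste(v, collapse = "")
  }
  pair <- function(qn, p1, p2, n1, n2) {
    list(
      list(qname = qn, flag = 99L, pos = p1, cigar = "30M",
           seq = mut(substr(s, p1, p1 + 29), n1), qual = q35(30),
           mchrom = "c1", mpos = p2, isize = p2 + 30L - p1),
      list(qname = qn, flag = 147L, pos = p2, cigar = "30M",
           seq = mut(substr(s, p2, p2 + 29), n2), qual = q35(30),
           mchrom = "c1", mpos = p1, isize = -(p2 + 30L - p1)))
  }
  args <- c(pair("p1", 11L, 111L, 2L, 2L),   # 2+2 = 4 > fnum 3
            pair("p2", 41L, 141L, 1L, 2L),   # 3 <= 3 kept
            list(lens = ref_lengths(g)))
  reads <- do.call(mk_reads, args)
  res <- filter_reads(reads, g, refine_params(num = 2, discordant_filter = FALSE))
  expect_setequal(res$reads$qname, "p2")
  expect_true(all(res$removed$reason == "fnum"))
  expect_equal(nrow(res$removed), 2L)
})

test_that("insert-size outliers are discordant beyond mean + 5 SD", {
  g <- random_genome(3000, seed = 26)
  s <- unclass(g)[["c1"]]
  mkpair <- function(qn, p1, isz) {
    p2 <- p1 + isz - 30L
    list(
      list(qname = qn, flag = 99L, pos = p1, cigar = "30M",
           seq = substr(s, p1, p1 + 29), qual = q35(30), mchrom = "c1",
           mpos = p2, isize = isz),
      list(qname = qn, flag = 147L, pos = p2, cigar = "30M",
           seq = substr(s, p2, p2 + 29), qual = q35(30), mchrom = "c1",
           mpos = p1, isize = -isz))
  }
  set.seed(27)
  args <- list()
  for (i in 1:30) {
    args <- c(args, mkpair(paste0("n", i), 10L + 40L * i,
                           100L + sample(-5:5, 1)))
  }
  args <- c(args, mkpair("wild", 1500L, 1200L))
  args$lens <- ref_lengths(g)
  reads <- do.call(mk_reads, args)
  res <- filter_reads(reads, g, refine_params())
  expect_false("wild" %in% res$reads$qname)
  expect_true(all(res$removed$qname == "wild"))
  expect_equal(sort(unique(res$removed$reason)), "discordant")
})

test_that("terminal-mismatch removal applies only with realignment disabled", {
  g <- random_genome(200, seed = 28)
  s <- unclass(g)[["c1"]]
  v <- strsplit(substr(s, 11, 40), "")[[1]]
  v[2] <- setdiff(c("A", "C", "G", "T"), v[2])[1]
  reads <- mk_reads(
    list(qname = "t", pos = 11L, cigar = "30M", seq = paste(v, collapse = ""),
         qual = q35(30)),
    lens = ref_lengths(g))
  on_ <- filter_reads(reads, g, refine_params(realign = TRUE))
  expect_equal(nrow(on_$removed), 0L)
  off_ <- filter_reads(reads, g, refine_params(realign = FALSE))
  expect_equal(off_$removed$reason, "terminal")
})

test_that("filtering is anti-monotone in num", {
  g <- random_genome(600, seed = 29)
  fx <- generate_reads(g, depth = 10, read_len = 40, insert_mean = 100,
                       insert_sd = 8, seed = 30,
                       profile = read_error_profile(base_error_rate = 0.03))
  kept <- lapply(0:3, function(k) {
    res <- filter_reads(fx$reads, g, refine_params(num = k,
                                                   discordant_filter = FALSE))
    paste(res$reads$qname, res$reads$flag)
  })
  for (k in 1:3) {
    expect_true(all(kept[[k]] %in% kept[[k + 1]]))
  }
})

test_that("default fnum follows the 1.7-fold rule", {
  expect_equal(refine_params(num = 2)$fnum, 3L)
  expect_equal(refine_params(num = 4)$fnum, 6L)
  expect_equal(refine_params(num = 6)$fnum, 10L)
})

test_that("pipeline leaves an already-clean alignment untouched", {
  g <- random_genome(500, seed = 33)
  fx <- generate_reads(g, depth = 8, read_len = 40, insert_mean = 100,
                       insert_sd = 8, seed = 34,
                       profile = read_error_profile(base_error_rate = 0))
  res <- refine_pipeline(fx$reads, g, refine_params())
  expect_equal(res$summary$n_out, res$summary$n_in)
  expect_equal(res$summary$n_removed, 0L)
  expect_equal(res$summary$n_corrected_bases, 0L)
})

test_that("error-correction mode heals singleton errors and keeps the true variant", {
  g <- random_genome(800, seed = 35)
  s <- unclass(g)[["c1"]]
  # plant one true SNP at position 400 carried by ALL reads (high quality),
  # plus scattered singleton q5 errors
  sample_genome <- g
  v <- strsplit(s, "")[[1]]
  true_alt <- setdiff(c("A", "C", "G", "T"), v[400])[1]
  v[400] <- true_alt
  sample_genome <- ref_genome(c(c1 = paste(v, collapse = "")))
  fx <- generate_reads(sample_genome, depth = 14, read_len = 50,
                       insert_mean = 120, insert_sd = 8, seed = 36,
                       profile = read_error_profile(base_error_rate = 0.004,
                                                    qual_error = 5))
  spurious_cols <- function(reads) {
    cols <- pileup_from_reads(reads, g, positions = "variant")
    ps <- vapply(cols, function(cc) cc$pos, integer(1))
    setdiff(ps, 400L)
  }
  before <- spurious_cols(fx$reads)
  expect_gt(length(before), 0)
  res <- refine_pipeline(fx$reads, g,
                         refine_params(mode = "error_correction"))
  after <- spurious_cols(res$reads)
  # spurious mismatch columns strictly decrease; the true variant survives
  expect_lt(length(after), length(before))
  calls <- call_variants(res$reads, call_params(), ref = g)
  expect_true(any(calls$type == "SNP" & calls$pos == 400 &
                    calls$alt == true_alt))
  # no reads were removed on account of the corrected singleton errors:
  # corrected bases outnumber removed reads in this regime
  expect_gt(res$summary$n_corrected_bases, 0L)

  # basic mode on the same fixture removes instead of correcting: every
  # read over the mismatch cap is gone (plus possibly mates via fnum)
  res_basic <- refine_pipeline(fx$reads, g, refine_params(mode = "basic"))
  expect_equal(res_basic$summary$n_corrected_bases, 0L)
  counts <- vapply(read_diffs(fx$reads, g), count_mismatches, integer(1))
  over <- paste(fx$reads$qname, fx$reads$flag)[counts > 2]
  kept_basic <- paste(res_basic$reads$qname, res_basic$reads$flag)
  expect_gt(length(over), 0)
  expect_false(any(over %in% kept_basic))
  expect_gte(res_basic$summary$n_removed, length(over))
})

test_that("pipeline output reads are a subset of input reads", {
  g <- random_genome(500, seed = 37)
  fx <- generate_reads(g, depth = 10, read_len = 40, insert_mean = 100,
                       insert_sd = 8, seed = 38,
                       profile = read_error_profile(base_error_rate = 0.02))
  res <- refine_pipeline(fx$reads, g, refine_params(mode = "error_correction"))
  key <- function(r) paste(r$qname, r$flag)
  expect_true(all(key(res$reads) %in% key(fx$reads)))
  expect_false(any(duplicated(key(res$reads))))
  expect_equal(res$summary$n_in - res$summary$n_removed, res$summary$n_out)
})

test_that("refinement preferentially removes injected foreign reads", {
  target <- random_genome(2000, seed = 39)
  donor <- random_genome(2000, seed = 40, name = "d1")
  fx <- generate_reads(target, depth = 10, read_len = 50, insert_mean = 120,
                       insert_sd = 8, seed = 41,
                       profile = read_error_profile(base_error_rate = 0.002))
  inj <- inject_foreign_reads(fx$reads, target, donor, fraction = 0.4,
                              mismatch_floor = 5L, seed = 42)
  res <- refine_pipeline(inj$reads, target,
                         refine_params(discordant_filter = FALSE))
  kept <- paste(res$reads$qname, res$reads$flag)
  all_keys <- paste(inj$reads$qname, inj$reads$flag)
  foreign <- inj$truth$foreign[match(all_keys, paste(inj$truth$qname,
                                                     inj$reads$flag))]
  removed <- !(all_keys %in% kept)
  frac_foreign_removed <- mean(removed[foreign])
  frac_native_removed <- mean(removed[!foreign])
  expect_gt(frac_foreign_removed, frac_native_removed)
  expect_gt(frac_foreign_removed, 0.9)  # floor of 5 mismatches >> num 2
})
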