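test_that("pair merging reconstructs the template and applies quality rules", {
  set.seed(51)
  template <- rand_seq(80)
  r1 <- substr(template, 1, 60)
  r2 <- revcomp(substr(template, 21, 80))
  pr <- read_pairs("p1", r1, strrep("I", 60), r2, strrep("I", 60))
  m <- merge_pairs(pr, min_overlap = 16)
  expect_equal(nrow(m), 1)
  expect_equal(m$seq, template)
  expect_equal(attr(m, "n_dropped"), 0)
  # conflicting base: Q40 ("I") on r1 beats Q10 ("+") on r2
  r2c <- strsplit(r2, "")[[1]]
  pos_in_r2 <- 60 - (30 - 21)      # template position 30 within revcomp'd r2
  r2c[pos_in_r2] <- setdiff(BASES, r2c[pos_in_r2])[1]
  pr2 <- read_pairs("p2", r1, strrep("I", 60),
                    paste(r2c, collapse = ""), strrep("+", 60))
  m2 <- merge_pairs(pr2, min_overlap = 16)
  expect_equal(m2$seq, template)   # r1's high-quality base retained
  # agreement keeps the max quality
  prq <- read_pairs("p3", r1, strrep("5", 60), r2, strrep("I", 60))
  m3 <- merge_pairs(prq, min_overlap = 16)
  expect_equal(phred_scores(m3$qual)[30], 40)
  # no admissible overlap -> dropped and tallied
  pr4 <- read_pairs("p4", rand_seq(60), strrep("I", 60),
                    rand_seq(60), strrep("I", 60))
  m4 <- merge_pairs(pr4, min_overlap = 30)
  expect_equal(nrow(m4), 0)
  expect_equal(attr(m4, "n_dropped"), 1)
})

test_that("demultiplexing is exact on the index and tolerant on the primer", {
  set.seed(52)
  primer <- degenerate_primer("f", "GCAGATGGTCCAATGCCWCAAAC")
  idx <- c(S1 = "ACGTACGT", S2 = "TTGGCCAA")
  insert <- rand_seq(100)
  site <- sub("W", "A", primer$bases)
  good <- paste0(idx[["S1"]], site, insert)
  reads <- data.frame(
    id = c("ok", "idx_err", "prim2"),
    seq = c(good,
            paste0("CCGTACGT", site, insert),                  # 1 index mm
            paste0(idx[["S2"]], mutate_seq(site, 2, c(3, 9)), insert)),
    qual = strrep("I", 8 + nchar(site) + 100),
    stringsAsFactors = FALSE)
  out <- demultiplex(reads, idx, primer, primer_mismatch = 1)
  expect_equal(out$id, "ok")
  expect_equal(out$sample, "S1")
  expect_equal(out$seq, insert)
  expect_equal(nchar(out$qual), 100)
  expect_equal(attr(out, "n_dropped"), 2)
  expect_error(demultiplex(reads, c(S1 = "AAAA", S2 = "AAAA"), primer),
               "duplicate")
})

test_that("expected-error filter keeps E <= cutoff (boundary inclusive)", {
  reads <- data.frame(
    id = c("q20x10", "q2x1", "q20x50"),
    seq = c(strrep("A", 10), "A", strrep("A", 50)),
    qual = c(strrep("5", 10), "#", strrep("5", 50)),  # "5"=Q20, "#"=Q2
    sample = NA, stringsAsFactors = FALSE)
  expect_equal(expected_errors(reads$qual[1]), 0.1)
  expect_equal(round(expected_errors(reads$qual[2]), 4), 0.631)
  expect_equal(expected_errors(reads$qual[3]), 0.5)
  out <- quality_filter(reads, 0.5)
  expect_setequal(out$id, c("q20x10", "q20x50"))   # E = 0.5 kept, 0.631 out
})

test_that("size filter bounds are inclusive and trimming crops 5'/3'", {
  mk <- function(n) data.frame(id = paste0("L", n), seq = rand_seq(n),
                               qual = strrep("I", n), sample = "S1",
                               stringsAsFactors = FALSE)
  set.seed(53)
  reads <- rbind(mk(445), mk(400), mk(399), mk(440), mk(441))
  out <- size_filter_and_trim(reads)   # defaults 400-440, crops 20/50
  expect_setequal(out$id, c("L400", "L440"))
  expect_equal(nchar(out$seq[out$id == "L400"]), 330)
  expect_equal(nchar(out$seq[out$id == "L440"]), 370)
  out450 <- size_filter_and_trim(reads, max_len = 450)
  expect_equal(nchar(out450$seq[out450$id == "L445"]), 375)
  expect_equal(nchar(out450$qual[out450$id == "L445"]), 375)
  expect_error(size_filter_and_trim(reads, min_len = 60, crop5 = 20,
                                    crop3 = 50), "crop")
})

test_that("dereplication preserves per-sample counts with deterministic order", {
  set.seed(54)
  x <- rand_seq(30)
  y <- sort(c(x, rand_seq(30)))  # y[1] lexicographically first
  reads <- data.frame(
    id = paste0("r", 1:10),
    seq = c(rep(x, 5), rep(x, 2), rep(y[y != x], 3)),
    qual = strrep("I", 30),
    sample = c(rep("A", 5), rep("B", 2), rep("A", 3)),
    stringsAsFactors = FALSE)
  amps <- dereplicate(reads)
  expect_equal(amps$seq[1], x)
  expect_equal(amps$total, c(7L, 3L))
  expect_equal(amps$counts[1, ], c(A = 5L, B = 2L))
  expect_equal(sum(amps$total), nrow(reads))
  # ties broken lexicographically
  tied <- data.frame(id = paste0("t", 1:6), seq = rep(y, each = 3),
                     qual = strrep("I", 30), sample = "A",
                     stringsAsFactors = FALSE)
  expect_equal(dereplicate(tied)$seq, y)
})

test_that("abundance denoising removes counts 1-3 at the default floor", {
  set.seed(55)
  amps <- make_amps(vapply(1:4, function(i) rand_seq(40), character(1)),
                    counts = c(10, 4, 3, 1))
  out <- denoise_by_abundance(amps)
  expect_equal(out$total, c(10L, 4L))
  expect_equal(attr(out, "n_dropped_reads"), 4)
  empty <- denoise_by_abundance(make_amps(rand_seq(40), 1))
  expect_equal(length(empty$seq), 0)
})

test_that("chimera screen flags constructed bimeras and matches brute force", {
  set.seed(56)
  ref1 <- rand_seq(375)
  ref2 <- mutate_seq(ref1, 75)     # 80 % identical parents
  chim <- paste0(substr(ref1, 1, 200), substr(ref2, 201, 375))
  amps <- make_amps(c(ref1, chim), c(50, 5))
  res <- chimera_screen(amps, c(ref1, ref2))
  expect_equal(res$flagged$seq, chim)
  expect_equal(res$clean$seq, ref1)
  # brute-force oracle over all parent pairs and crossovers on a ladder
  refs <- c(ref1, ref2, mutate_seq(ref1, 30), mutate_seq(ref2, 15))
  queries <- c(ref1,
               paste0(substr(refs[3], 1, 150), substr(refs[4], 151, 375)),
               mutate_seq(ref1, 3))
  amps2 <- make_amps(queries, c(9, 8, 7))
  res2 <- chimera_screen(amps2, refs)
  cmatch <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    ca == cb
  }
  for (q in amps2$seq) {
    mv <- lapply(refs, cmatch, a = q)
    single <- 100 * max(vapply(mv, mean, numeric(1)))
    best2 <- 0
    L <- nchar(q)
    for (a in 1:4) for (b in 1:4) {
      if (a == b) next
      pa <- cumsum(mv[[a]]); pb <- cumsum(mv[[b]])
      best2 <- max(best2,
                   100 * max(pa[1:(L - 1)] + pb[L] - pb[1:(L - 1)]) / L)
    }
    expected <- (best2 - single >= 3) && (best2 >= 99)
    expect_equal(res2$detail$flagged[res2$detail$seq == q], expected)
  }
})

test_that("decontamination keeps marker-like amplicons, drops random ones", {
  set.seed(57)
  ref <- rand_seq(375)
  diverged <- mutate_seq(ref, 131)     # ~35 % divergence, still on-target
  amps <- make_amps(c(ref, diverged, rand_seq(375)), c(5, 5, 5))
  out <- decontaminate(amps, ref)
  expect_true(ref %in% out$on_target$seq)
  expect_true(diverged %in% out$on_target$seq)
  expect_equal(length(out$off_target$seq), 1)
})

test_that("ledger percentages and monotonicity follow the accounting rules", {
  led <- pipeline_ledger(c("raw", "merged", "demultiplexed"),
                         c(4917888L, 4720138L, 1928898L))
  expect_equal(led$percent_of_raw, c(100L, 96L, 39L))
  expect_error(pipeline_ledger(c("a", "b"), c(10L, 11L)), "non-increasing")
})
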