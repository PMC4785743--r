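test_that("global clustering resolves planted clusters and audits members", {
  set.seed(61)
  anchors <- c(rand_seq(375), NA, NA)
  anchors[2] <- mutate_seq(anchors[1], 60)
  anchors[3] <- mutate_seq(anchors[2], 60)
  seqs <- unlist(lapply(anchors, function(a)
    c(a, vapply(1:9, function(i) mutate_seq(a, sample(1:3, 1)),
                character(1)))))
  # brute-force audit: planted partition is threshold-consistent
  planted <- rep(1:3, each = 10)
  for (i in 1:29) for (j in (i + 1):30) {
    idy <- 100 * (375 - hamming(seqs[i], seqs[j])) / 375
    if (planted[i] == planted[j]) expect_gte(idy, 98)
    else expect_lte(idy, 90)
  }
  amps <- make_amps(seqs, counts = rep(c(20, rep(2, 9)), 3))
  otus <- cluster_global(amps, 97)
  expect_equal(length(otus$centroid), 3)
  expect_setequal(otus$centroid, anchors)
  # partition property + member-to-centroid identity audit
  expect_setequal(unlist(otus$members), seq_along(amps$seq))
  for (k in 1:3) for (m in otus$members[[k]])
    expect_gte(percent_identity(amps$seq[m], otus$centroid[k],
                                mode = "global"), 97)
  expect_equal(sum(otus$total), sum(amps$total))
  # simple cases
  two <- make_amps(c(anchors[1], mutate_seq(anchors[1], 4)), c(5, 3))
  expect_equal(length(cluster_global(two, 97)$centroid), 1)
  expect_equal(cluster_global(two, 97)$centroid, two$seq[which.max(two$total)])
  far <- make_amps(c(anchors[1], mutate_seq(anchors[1], 38)), c(5, 3))
  expect_equal(length(cluster_global(far, 97)$centroid), 2)
  expect_error(cluster_global(two, 45), "threshold")
})

test_that("local clustering is the transitive closure of the d-graph", {
  set.seed(62)
  a <- rand_seq(100)
  b <- mutate_seq(a, 1, positions = 10)
  c_ <- mutate_seq(b, 1, positions = 50)
  chain <- make_amps(c(a, b, c_), c(5, 3, 2))
  one <- cluster_local(chain, d = 1)
  expect_equal(length(one$centroid), 1)
  expect_equal(one$centroid, a)            # seed = most abundant
  pair <- make_amps(c(a, mutate_seq(a, 11)), c(5, 3))
  expect_equal(length(cluster_local(pair, d = 10)$centroid), 2)
  # random fixture vs connected-components oracle
  for (trial in 1:5) {
    seqs <- unique(vapply(1:20, function(i)
      mutate_seq(a, sample(0:15, 1)), character(1)))
    amps <- make_amps(seqs, sample(1:30, length(seqs), replace = TRUE))
    for (d in c(2, 5, 10)) {
      otus <- cluster_local(amps, d)
      oracle <- lev_components(amps$seq, d)
      got <- integer(length(amps$seq))
      for (k in seq_along(otus$members)) got[otus$members[[k]]] <- k
      # same partition (component labels may differ)
      expect_equal(length(otus$centroid), max(oracle))
      expect_true(all(tapply(got, oracle, function(x)
        length(unique(x))) == 1))
      # each seed is its component's most abundant member (ties lexicographic)
      for (k in seq_along(otus$members)) {
        mem <- otus$members[[k]]
        best <- mem[order(-amps$total[mem], amps$seq[mem])][1]
        expect_equal(otus$centroid[k], amps$seq[best])
      }
    }
  }
})

test_that("core consensus intersects the two partitions by centroid/seed", {
  set.seed(63)
  a <- rand_seq(200)
  b <- mutate_seq(a, 40)
  amps <- make_amps(c(a, mutate_seq(a, 2), b, mutate_seq(b, 2)),
                    c(10, 5, 8, 4))
  glob <- cluster_global(amps, 97)
  loc <- cluster_local(amps, 10)
  core <- core_consensus(glob, loc)
  expect_equal(length(core$centroid), 2)      # identical partitions
  expect_setequal(core$centroid, c(a, b))
  expect_lte(length(core$centroid),
             min(length(glob$centroid), length(loc$centroid)))
  # a global centroid absorbed as non-seed member of a local swarm is not core
  bridge <- make_amps(c(a, mutate_seq(a, 8)), c(10, 6))
  g2 <- cluster_global(bridge, 99)   # split at 99 (8 subs ~ 96 %)
  l2 <- cluster_local(bridge, 10)    # merged at d = 10
  expect_equal(length(g2$centroid), 2)
  expect_equal(length(l2$centroid), 1)
  core2 <- core_consensus(g2, l2)
  expect_equal(core2$centroid, a)    # only the shared seed survives
  # jaccard alternative accepts both split halves (each overlaps at 0.5)
  expect_equal(length(core_consensus(g2, l2, method = "jaccard")$centroid), 2)
})

test_that("d-scan finds the stable core plateau and is monotone", {
  set.seed(64)
  a <- rand_seq(150)
  anchors <- c(a, mutate_seq(a, 50), mutate_seq(a, 100))
  seqs <- unlist(lapply(anchors, function(x)
    c(x, mutate_seq(x, 2), mutate_seq(x, 3))))
  amps <- make_amps(seqs, rep(c(9, 3, 2), 3))
  scan <- d_scan(amps, d_values = 1:16)
  expect_true(all(diff(scan$n_local) <= 0))
  expect_true(all(scan$n_core[scan$d >= 3 & scan$d <= 16] == 3))
  expect_equal(attr(scan, "optimum")[2], 16)
  # ladder: clusters 5 and 12 apart; core count drops when d bridges them
  x <- rand_seq(80)
  ladder <- make_amps(c(x, mutate_seq(x, 5, positions = 1:5),
                        mutate_seq(x, 12, positions = 21:32)),
                      c(9, 5, 3))
  sc <- d_scan(ladder, d_values = 1:16,
               global_otus = cluster_global(ladder, 97))
  n_comp <- vapply(1:16, function(d) max(lev_components(ladder$seq, d)),
                   integer(1))
  expect_equal(sc$n_local, n_comp)
  expect_true(all(sc$n_local[sc$d < 5] == 3))
  expect_true(all(sc$n_local[sc$d >= 5 & sc$d < 7] == 2))
  expect_true(all(sc$n_local[sc$d >= 12] == 1))
})
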