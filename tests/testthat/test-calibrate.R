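test_that("rank divergence classifies intra vs inter pairs (all-pairs oracle)", {
  set.seed(81)
  tc <- two_clade_seqs(L = 375, n_per = 3, intra_subs = 2, inter_subs = 40)
  lin1 <- lineage("Eukaryota", "Chlorophyta", "Ulvophyceae", "Bryopsidales",
                  "Ostreobidineae", "FamA", "x")
  lin2 <- lineage("Eukaryota", "Chlorophyta", "Ulvophyceae", "Bryopsidales",
                  "Ostreobidineae", "FamB", "y")
  db <- make_db(c(tc$clade1, tc$clade2),
                c(rep(list(lin1), 3), rep(list(lin2), 3)))
  div <- rank_divergence(db, "family")
  expect_equal(length(div$intra), 6)      # 2 x choose(3, 2)
  expect_equal(length(div$inter), 9)      # 3 x 3 cross pairs
  # oracle: direct pair enumeration
  idm <- identity_matrix(db)$identity
  lab <- db$family
  oi <- oo <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    if (lab[i] == lab[j]) oi <- c(oi, idm[i, j]) else oo <- c(oo, idm[i, j])
  }
  expect_setequal(round(div$intra, 6), round(oi, 6))
  expect_setequal(round(div$inter, 6), round(oo, 6))
  expect_true(max(div$inter) < min(div$intra))
  # single record per clade: intra empty, inter populated
  db1 <- make_db(c(tc$clade1[1], tc$clade2[1]), list(lin1, lin2))
  div1 <- rank_divergence(db1, "family")
  expect_equal(length(div1$intra), 0)
  expect_equal(length(div1$inter), 1)
  # UNRESOLVED records excluded from the rank computation
  lin3 <- lineage("Eukaryota", "Chlorophyta", "Ulvophyceae", "Bryopsidales",
                  "Ostreobidineae")
  db3 <- make_db(c(tc$clade1, tc$clade2[1]),
                 c(rep(list(lin1), 3), list(lin3)))
  expect_equal(length(rank_divergence(db3, "family")$inter), 0)
})

test_that("conservative threshold is the ceiling of the max inter identity", {
  set.seed(82)
  # plant max inter-family identity exactly 88.0 % = 330/375
  tc <- two_clade_seqs(L = 375, n_per = 2, intra_subs = 2, inter_subs = 45)
  lin <- function(f, s) lineage("Eukaryota", "Chlorophyta", "Ulvophyceae",
                                "Bryopsidales", "Ostreobidineae", f, s)
  db <- make_db(c(tc$clade1, tc$clade2),
                list(lin("FamA", "a1"), lin("FamA", "a2"),
                     lin("FamB", "b1"), lin("FamB", "b2")))
  div <- rank_divergence(db, "family")
  cons <- conservative_threshold(div)
  expect_equal(cons$raw, max(div$inter))
  expect_equal(cons$raw, 100 * (375 - 45) / 375)    # anchors 45 subs apart
  expect_equal(cons$rounded, 88)
  expect_setequal(cons$provenance, c(db$id[1], db$id[3]))
  # every inter-pair identity <= the raw threshold (defining guarantee)
  expect_true(all(div$inter <= cons$raw))
  expect_error(conservative_threshold(
    rank_divergence(db[1:2, ], "family")), "empty")
})

test_that("conservative thresholds recover realized oracles across seeds", {
  for (seed in 1:20) {
    set.seed(100 + seed)
    sim <- simulate_reference_db(sim_config(
      seed = 100 + seed, n_domains = 1, phyla_per_domain = 1,
      classes_per_phylum = 1, orders_per_class = 1, suborders_per_order = 2,
      families_per_suborder = 2, species_per_family = 2))
    db <- sim$records
    idm <- identity_matrix(db)$identity
    for (rank in c("suborder", "family")) {
      div <- rank_divergence(db, rank, idmat = list(identity = idm,
                                                    kept = db$id,
                                                    excluded = character(0)))
      # oracle: max over brute-force enumerated cross-clade pairs
      lab <- db[[rank]]
      inter_max <- max(idm[outer(lab, lab, "!=")])
      expect_equal(conservative_threshold(div)$raw, inter_max)
      expect_equal(conservative_threshold(div)$rounded,
                   threshold_round_up(inter_max))
    }
  }
})

test_that("relaxed threshold scores leave-one-out best-hit discrepancies", {
  set.seed(83)
  # all best hits correct (each record has a within-family sibling)
  tc <- two_clade_seqs(L = 375, n_per = 3, intra_subs = 2, inter_subs = 40)
  linA <- lineage("Eukaryota", "Chlorophyta", "Ulvophyceae", "Bryopsidales",
                  "Ostreobidineae", "FamA", "a")
  linB <- lineage("Eukaryota", "Chlorophyta", "Ulvophyceae", "Bryopsidales",
                  "Ostreobidineae", "FamB", "b")
  db <- make_db(c(tc$clade1, tc$clade2),
                c(rep(list(linA), 3), rep(list(linB), 3)))
  rel <- relaxed_threshold(db, "family")
  expect_true(rel$unbounded)
  expect_true(all(rel$scores$correct))
  # oracle: minimum over queries of their best-hit identity
  idm0 <- identity_matrix(db)$identity
  diag(idm0) <- -1
  expect_equal(rel$min_correct, min(apply(idm0, 1, max)))
  # singleton families force incorrect best hits; raw = max wrong identity
  linC <- lineage("Eukaryota", "Chlorophyta", "Ulvophyceae", "Bryopsidales",
                  "Ostreobidineae", "FamC", "c")
  dbs <- make_db(c(tc$clade1[1], tc$clade2[1],
                   mutate_seq(tc$clade2[1], 20)),
                 list(linA, linB, linC))
  rel2 <- relaxed_threshold(dbs, "family")
  expect_false(rel2$unbounded)
  idm <- identity_matrix(dbs)$identity
  # oracle: every query's best hit is in another family -> all wrong
  diag(idm) <- -1
  expect_equal(rel2$raw, max(apply(idm, 1, max)))
  expect_equal(rel2$rounded, threshold_round_up(rel2$raw))
  expect_true(all(!rel2$scores$correct))
})

test_that("relaxed threshold equals the misassigned-neighbor oracle on sims", {
  for (seed in 1:8) {
    cfg <- sim_config(seed = 200 + seed, n_domains = 1, phyla_per_domain = 1,
                      classes_per_phylum = 1, orders_per_class = 1,
                      suborders_per_order = 2, families_per_suborder = 3,
                      species_per_family = 1)   # singletons: hits cross family
    db <- simulate_reference_db(cfg)$records
    rel <- relaxed_threshold(db, "family")
    idm <- identity_matrix(db)$identity
    diag(idm) <- -1
    wrong_max <- -1
    for (i in seq_len(nrow(db))) {
      j <- which.max(idm[i, ])
      if (db$family[j] != db$family[i]) wrong_max <- max(wrong_max, idm[i, j])
    }
    if (wrong_max < 0) {
      expect_true(rel$unbounded)
    } else {
      expect_equal(rel$raw, wrong_max)
    }
  }
})

test_that("multi-rank annotation applies thresholds deepest-first", {
  th <- structure(data.frame(
    rank = c("domain", "phylum", "class", "order", "suborder", "family"),
    conservative_raw = c(81.9, 82.2, 85.1, 78.9, 83.2, 91.2),
    conservative = c(82L, 83L, 86L, 79L, 84L, 92L),
    relaxed_raw = c(76.3, 82.7, 84.0, 76.3, 78.4, 84.5),
    relaxed = c(77L, 83L, 84L, 77L, 79L, 85L),
    relaxed_unbounded = FALSE, min_intra = NA_real_,
    stringsAsFactors = FALSE), class = c("threshold_set", "data.frame"))
  set.seed(84)
  ref_seq <- rand_seq(375)
  refs <- make_db(ref_seq,
                  list(lineage("Eukaryota", "Chlorophyta", "Ulvophyceae",
                               "Bryopsidales", "Ostreobidineae", "Odoaceae",
                               "sp23")))
  # 93 % identity with conservative set {family 92, suborder 84, order 79}:
  # family level annotation, species unresolved
  q93 <- mutate_seq(ref_seq, 26)       # 349/375 = 93.07 %
  a <- annotate_otu(q93, refs, th, mode = "conservative")
  expect_equal(a$deepest_rank, "family")
  expect_equal(unname(a$lineage["family"]), "Odoaceae")
  expect_equal(unname(a$lineage["species"]), UNRESOLVED)
  # 80 %: order only (79 <= 80 < 84)
  q80 <- mutate_seq(ref_seq, 75)
  a80 <- annotate_otu(q80, refs, th, mode = "conservative")
  expect_equal(a80$deepest_rank, "order")
  expect_equal(unname(a80$lineage["order"]), "Bryopsidales")
  expect_equal(unname(a80$lineage["suborder"]), UNRESOLVED)
  # 100 %: full lineage including species
  a100 <- annotate_otu(ref_seq, refs, th, mode = "conservative")
  expect_equal(unname(a100$lineage["species"]), "sp23")
  expect_equal(a100$identity, 100)
  # below every threshold: fully unresolved, identity recorded
  aU <- annotate_otu(mutate_seq(ref_seq, 150), refs, th, "conservative")
  expect_true(all(aU$lineage == UNRESOLVED))
  expect_lt(aU$identity, 77)
  # relaxed mode anotates deeper at the same identity
  a85 <- annotate_otu(mutate_seq(ref_seq, 56), refs, th, "relaxed")
  expect_equal(a85$deepest_rank, "family")    # 85.07 >= 85
})

test_that("conservative annotation never misassigns when margins hold", {
  for (seed in 1:6) {
    cfg <- sim_config(seed = 300 + seed, n_domains = 1, phyla_per_domain = 1,
                      classes_per_phylum = 1, orders_per_class = 1,
                      suborders_per_order = 2, families_per_suborder = 2,
                      species_per_family = 3)
    db <- simulate_reference_db(cfg)$records
    th <- calibrate_thresholds(db, high_ranks = character(0),
                               low_ranks = c("suborder", "family"))
    for (i in seq_len(nrow(db))) {
      a <- annotate_otu(db$seq[i], db[-i, ], th, mode = "conservative",
                        species_min = NA)
      for (r in c("suborder", "family")) {
        if (a$lineage[[r]] != UNRESOLVED)
          expect_equal(a$lineage[[r]], db[[r]][i])
      }
    }
  }
})

test_that("full calibration reports both threshold families per rank", {
  cfg <- sim_config(seed = 91)
  db <- simulate_reference_db(cfg)$records
  run <- run_calibration(db, subset_rank = "class",
                         subset_label = db$class[1])
  th <- run$thresholds
  expect_equal(th$rank, c("domain", "phylum", "class", "order", "suborder",
                          "family"))
  multi <- !vapply(run$divergences[th$rank], `[[`, logical(1),
                   "single_clade")
  expect_true(all(!is.na(th$conservative[multi])))
  expect_true(all(th$conservative[multi] ==
                    ceiling(th$conservative_raw[multi])))
  # internal consistency: every inter-pair identity <= its rank's raw value
  for (r in th$rank) {
    div <- run$divergences[[r]]
    if (!div$single_clade)
      expect_true(all(div$inter <= th$conservative_raw[th$rank == r]))
  }
  # low ranks calibrated on the clade subset only
  sub <- db[db$class == db$class[1], ]
  div_fam <- rank_divergence(sub, "family")
  expect_equal(th$conservative_raw[th$rank == "family"], max(div_fam$inter))
  # order rank inside one class has a single clade here: flagged, NA
  expect_true(run$divergences[["order"]]$single_clade)
  expect_true(is.na(th$conservative[th$rank == "order"]))
})

test_that("db_performance summarizes best-hit identities and abundant subset", {
  set.seed(85)
  refs_seq <- vapply(1:3, function(i) rand_seq(375), character(1))
  lin <- lineage("Eukaryota", "Chlorophyta", "Ulvophyceae")
  refs <- make_db(refs_seq, rep(list(lin), 3))
  amps <- make_amps(c(refs_seq[1], mutate_seq(refs_seq[2], 38)), c(60, 4))
  otus <- cluster_global(amps, 97)
  reads <- data.frame(id = paste0("r", 1:64),
                      seq = rep(otus$centroid, otus$total),
                      qual = strrep("I", 375), sample = "A",
                      stringsAsFactors = FALSE)
  tab <- map_reads(reads, otus, cell_floor = 1)
  perf <- db_performance(otus, refs, tab, min_share = 1)
  expect_equal(perf$identities[1], 100)
  expect_equal(round(perf$identities[2], 2), round(100 * 337 / 375, 2))
  expect_equal(perf$summary_overall[c(1, 5)],
               range(perf$identities))
  expect_true(all(perf$identities[perf$abundant] %in% perf$identities))
})
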