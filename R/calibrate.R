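## Calibration of per-rank identity thresholds from a taxonomy-annotated
## reference alignment: clade-based (conservative) thresholds from the
## intra/inter-clade identity distributions, and relaxed thresholds from
## leave-one-out best-hit misclassification, plus multi-rank OTU
## annotation and database-performance summaries.

#' Round a raw threshold up to its working integer value
#'
#' Calibration thresholds are reported as the smallest integer percent at
#' or above the raw value (so a best hit at the rounded threshold is
#' strictly above every identity that motivated it).
#'
#' @param raw Raw threshold(s) in percent.
#' @return Integer threshold(s).
#' @examples
#' threshold_round_up(91.2)  # 92
#' threshold_round_up(84.0)  # 84
#' @export
threshold_round_up <- function(raw) {
  as.integer(ceiling(raw))
}

#' Intra- vs inter-clade identity distributions at one rank
#'
#' Classifies every comparable record pair (both resolved at \code{rank})
#' as intra-clade (same label) or inter-clade (different labels), using
#' the all-pairs identity matrix over the metabarcode alignment.
#'
#' @param records Reference database data frame (aligned \code{seq}
#'   column).
#' @param rank Rank name.
#' @param max_end_missing Passed to [identity_matrix()].
#' @param idmat Optional precomputed [identity_matrix()] result (reused
#'   across ranks).
#' @return List of class \code{rank_divergence}: \code{rank},
#'   \code{intra}, \code{inter} (numeric identity vectors), \code{summary}
#'   (min/quartiles/max per class), \code{n_clades},
#'   \code{single_clade} flag, and \code{provenance} (the record pair
#'   attaining the inter-clade maximum).
#' @export
rank_divergence <- function(records, rank, max_end_missing = 20,
                            idmat = NULL) {
  if (!rank %in% TAXONOMIC_RANKS) stop("unknown rank: ", rank)
  if (is.null(idmat))
    idmat <- identity_matrix(records, max_end_missing = max_end_missing)
  keep <- records$id %in% idmat$kept & records[[rank]] != UNRESOLVED
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 2) stop("fewer than 2 records resolved at rank ", rank)
  m <- idmat$identity[rec$id, rec$id]
  lab <- rec[[rank]]
  same <- outer(lab, lab, "==")
  ut <- upper.tri(m)
  intra <- m[ut & same]
  inter <- m[ut & !same]
  prov <- NULL
  if (length(inter) > 0) {
    w <- which(ut & !same & m == max(inter), arr.ind = TRUE)[1, ]
    prov <- c(rec$id[w[1]], rec$id[w[2]])
  }
  summ <- function(x) if (length(x) == 0) rep(NA_real_, 5) else
    unname(stats::quantile(x, c(0, .25, .5, .75, 1)))
  structure(list(rank = rank, intra = intra, inter = inter,
                 summary = rbind(intra = summ(intra), inter = summ(inter)),
                 n_clades = length(unique(lab)),
                 single_clade = length(unique(lab)) < 2,
                 provenance = prov),
            class = "rank_divergence")
}

#' @export
print.rank_divergence <- function(x, ...) {
  cat(sprintf("<rank_divergence %s: %d clades, %d intra / %d inter pairs>\n",
              x$rank, x$n_clades, length(x$intra), length(x$inter)))
  invisible(x)
}

#' Conservative (clade-based) annotation threshold
#'
#' The raw conservative threshold at a rank is the maximum inter-clade
#' identity — the worst-case similarity between records of different
#' clades — so any best hit at or above the rounded-up value is guaranteed
#' to share the hit's clade. The minimum intra-clade identity is reported
#' alongside as the alternative clade-cohesion statistic.
#'
#' @param div A \code{rank_divergence}.
#' @return List: \code{rank}, \code{raw}, \code{rounded},
#'   \code{min_intra}, \code{provenance} (the inter-clade pair that set
#'   the raw value).
#' @export
conservative_threshold <- function(div) {
  if (length(div$inter) == 0)
    stop("inter-clade distribution empty at rank ", div$rank,
         " (single clade?)")
  raw <- max(div$inter)
  list(rank = div$rank, raw = raw, rounded = threshold_round_up(raw),
       min_intra = if (length(div$intra) > 0) min(div$intra) else NA_real_,
       provenance = div$provenance)
}

# best hits of query rows against reference rows of an identity matrix;
# ties at equal identity resolved toward the majority lineage of the tied
# hits, UNRESOLVED where the tied hits conflict and no majority exists
.best_hits <- function(m, qids, rids, records) {
  rec <- records[match(rids, records$id), , drop = FALSE]
  lapply(qids, function(q) {
    v <- m[q, setdiff(rids, q)]
    top <- names(v)[v == max(v)]
    lin <- rec[match(top, rec$id), TAXONOMIC_RANKS, drop = FALSE]
    cons <- vapply(TAXONOMIC_RANKS, function(r) {
      tt <- table(lin[[r]])
      if (max(tt) > length(top) / 2) names(tt)[which.max(tt)] else UNRESOLVED
    }, character(1))
    list(id = q, identity = unname(max(v)), hits = top, lineage = cons)
  })
}

#' Relaxed (best-hit) annotation threshold by leave-one-out
#'
#' Every record is queried against the remaining references; its best hit
#' is scored correct when the hit's label at \code{rank} equals the
#' query's. The raw relaxed threshold is the maximum identity among
#' incorrect best hits — above it, no best hit was misclassified. When no
#' best hit is incorrect the threshold is unbounded below and the minimum
#' correct-hit identity is reported instead.
#'
#' @param records Reference database data frame (aligned).
#' @param rank Rank name.
#' @param max_end_missing Passed to [identity_matrix()].
#' @param idmat Optional precomputed [identity_matrix()] result.
#' @return List of class \code{relaxed_threshold}: \code{rank},
#'   \code{raw}, \code{rounded} (both \code{NA} when unbounded),
#'   \code{unbounded}, \code{min_correct}, and \code{scores} — the full
#'   per-query best-hit table (id, identity, correct).
#' @export
relaxed_threshold <- function(records, rank, max_end_missing = 20,
                              idmat = NULL) {
  if (!rank %in% TAXONOMIC_RANKS) stop("unknown rank: ", rank)
  if (is.null(idmat))
    idmat <- identity_matrix(records, max_end_missing = max_end_missing)
  keep <- records$id %in% idmat$kept & records[[rank]] != UNRESOLVED
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 2) stop("fewer than 2 records resolved at rank ", rank)
  hits <- .best_hits(idmat$identity[rec$id, rec$id], rec$id, rec$id, rec)
  scores <- do.call(rbind, lapply(hits, function(h) {
    truth <- rec[[rank]][rec$id == h$id]
    hit_lab <- h$lineage[[rank]]
    data.frame(id = h$id, identity = h$identity,
               correct = !identical(hit_lab, UNRESOLVED) && hit_lab == truth,
               stringsAsFactors = FALSE)
  }))
  wrong <- scores$identity[!scores$correct]
  if (length(wrong) == 0) {
    out <- list(rank = rank, raw = NA_real_, rounded = NA_integer_,
                unbounded = TRUE, min_correct = min(scores$identity),
                scores = scores)
  } else {
    out <- list(rank = rank, raw = max(wrong),
                rounded = threshold_round_up(max(wrong)),
                unbounded = FALSE,
                min_correct = if (any(scores$correct))
                  min(scores$identity[scores$correct]) else NA_real_,
                scores = scores)
  }
  structure(out, class = "relaxed_threshold")
}

#' @export
print.relaxed_threshold <- function(x, ...) {
  if (x$unbounded)
    cat(sprintf("<relaxed_threshold %s: unbounded below (min correct %.2f)>\n",
                x$rank, x$min_correct))
  else
    cat(sprintf("<relaxed_threshold %s: raw %.2f -> %d>\n",
                x$rank, x$raw, x$rounded))
  invisible(x)
}

#' Calibrate the full per-rank threshold set
#'
#' Computes conservative and relaxed thresholds for each requested rank.
#' High ranks are conventionally calibrated on the full phototroph set and
#' low ranks on a clade subset (e.g. one class); pass \code{subset_rank} /
#' \code{subset_label} to restrict the low-rank calibration.
#'
#' @param records Reference database data frame (aligned).
#' @param high_ranks Ranks calibrated on all records (default domain,
#'   phylum, class).
#' @param low_ranks Ranks calibrated on the subset (default order,
#'   suborder, family).
#' @param subset_rank,subset_label Restriction for the low ranks (e.g.
#'   \code{subset_rank = "class", subset_label = "Ulvophyceae"}); both
#'   \code{NULL} to calibrate every rank on all records.
#' @param max_end_missing Passed to [identity_matrix()].
#' @return A \code{threshold_set}: data frame with one row per rank and
#'   columns rank, conservative_raw, conservative, relaxed_raw, relaxed,
#'   relaxed_unbounded, min_intra; attribute \code{divergences} holds the
#'   per-rank \code{rank_divergence} objects.
#' @export
calibrate_thresholds <- function(records,
                                 high_ranks = c("domain", "phylum", "class"),
                                 low_ranks = c("order", "suborder", "family"),
                                 subset_rank = NULL, subset_label = NULL,
                                 max_end_missing = 20) {
  idmat_all <- identity_matrix(records, max_end_missing = max_end_missing)
  low_records <- records
  idmat_low <- idmat_all
  if (!is.null(subset_rank)) {
    low_records <- records[records[[subset_rank]] == subset_label, ,
                           drop = FALSE]
    idmat_low <- identity_matrix(low_records,
                                 max_end_missing = max_end_missing)
  }
  one <- function(rec, rank, idm) {
    div <- rank_divergence(rec, rank, idmat = idm)
    cons <- if (div$single_clade) NULL else conservative_threshold(div)
    rel <- relaxed_threshold(rec, rank, idmat = idm)
    list(div = div,
         row = data.frame(
           rank = rank,
           conservative_raw = if (is.null(cons)) NA_real_ else cons$raw,
           conservative = if (is.null(cons)) NA_integer_ else cons$rounded,
           relaxed_raw = rel$raw, relaxed = rel$rounded,
           relaxed_unbounded = rel$unbounded,
           min_intra = if (is.null(cons)) NA_real_ else cons$min_intra,
           stringsAsFactors = FALSE))
  }
  res <- c(lapply(high_ranks, function(r) one(records, r, idmat_all)),
           lapply(low_ranks, function(r) one(low_records, r, idmat_low)))
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "divergences") <- setNames(lapply(res, `[[`, "div"), out$rank)
  class(out) <- c("threshold_set", "data.frame")
  out
}

#' Annotate an OTU against the reference database
#'
#' Finds the OTU's best-identity reference (global alignment, exhaustive;
#' identity ties resolved toward the majority lineage of the tied hits)
#' and copies the hit's taxonomy down to the deepest rank whose threshold
#' — conservative or relaxed, per \code{mode} — is at or below the
#' best-hit identity. Ranks below that are left [UNRESOLVED]. The species
#' rank is only assigned within the species identity band
#' (\code{species_min}, default 97.87).
#'
#' @param otu_seq OTU centroid sequence (gap-free).
#' @param references Reference database data frame (sequences may be
#'   aligned; gaps are removed for the search).
#' @param thresholds A \code{threshold_set} from [calibrate_thresholds()].
#' @param mode \code{"conservative"} or \code{"relaxed"}.
#' @param species_min Species-band identity floor in percent.
#' @return List: \code{lineage} (named over [TAXONOMIC_RANKS]),
#'   \code{identity}, \code{best_hit} (reference id(s)),
#'   \code{deepest_rank} (or \code{NA} when below every threshold).
#' @export
annotate_otu <- function(otu_seq, references, thresholds,
                         mode = c("conservative", "relaxed"),
                         species_min = 97.87) {
  mode <- match.arg(mode)
  refs <- degap(references$seq)
  idy <- .identities_vs(degap(otu_seq), refs)
  best <- max(idy)
  top <- which(idy == best)
  lin <- references[top, TAXONOMIC_RANKS, drop = FALSE]
  hit_lineage <- vapply(TAXONOMIC_RANKS, function(r) {
    tt <- table(lin[[r]])
    if (max(tt) > length(top) / 2) names(tt)[which.max(tt)] else UNRESOLVED
  }, character(1))
  col <- if (mode == "conservative") "conservative" else "relaxed"
  th <- setNames(thresholds[[col]], thresholds$rank)
  # deepest rank (species excluded: it has its own band) passing at `best`
  ranked <- intersect(TAXONOMIC_RANKS, thresholds$rank)
  passing <- ranked[!is.na(th[ranked]) & th[ranked] <= best]
  out <- setNames(rep(UNRESOLVED, length(TAXONOMIC_RANKS)), TAXONOMIC_RANKS)
  deepest <- NA_character_
  if (length(passing) > 0) {
    deepest <- passing[length(passing)]
    upto <- seq_len(match(deepest, TAXONOMIC_RANKS))
    out[upto] <- hit_lineage[upto]
  }
  if (!is.na(species_min) && best >= species_min) {
    out["species"] <- hit_lineage[["species"]]
    if (is.na(deepest)) deepest <- "species"
  }
  list(lineage = out, identity = best,
       best_hit = references$id[top], deepest_rank = deepest)
}

#' Annotate a whole OTU set
#'
#' @param otus An \code{otu_set}.
#' @param references,thresholds,mode,species_min See [annotate_otu()].
#' @return Data frame: otu, one column per rank, best_hit, identity,
#'   deepest_rank.
#' @export
annotate_otus <- function(otus, references, thresholds,
                          mode = c("conservative", "relaxed"),
                          species_min = 97.87) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(otus$centroid), function(i) {
    a <- annotate_otu(otus$centroid[i], references, thresholds,
                      mode = mode, species_min = species_min)
    cbind(data.frame(otu = sprintf("OTU%03d", i), stringsAsFactors = FALSE),
          as.data.frame(as.list(a$lineage), stringsAsFactors = FALSE),
          data.frame(best_hit = paste(a$best_hit, collapse = ","),
                     identity = a$identity,
                     deepest_rank = a$deepest_rank,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Database-performance distribution of OTU best hits
#'
#' Best-hit identity of every OTU against the reference database, with
#' quartile summaries overall and restricted to the high-abundance subset
#' (OTUs holding at least \code{min_share} percent of mapped reads in any
#' sample) — the OTUs that drive abundance profiles.
#'
#' @param otus An \code{otu_set}.
#' @param references Reference database data frame.
#' @param tab Optional \code{abundance_table} defining the high-abundance
#'   subset; without it only the overall distribution is returned.
#' @param min_share Percent-of-mapped-reads floor, default 1.
#' @return List: \code{identities} (per-OTU best-hit identity),
#'   \code{summary_overall}, \code{abundant} (logical), and
#'   \code{summary_abundant} when \code{tab} is given.
#' @export
db_performance <- function(otus, references, tab = NULL, min_share = 1) {
  refs <- degap(references$seq)
  idy <- vapply(otus$centroid,
                function(q) max(.identities_vs(degap(q), refs)),
                numeric(1), USE.NAMES = FALSE)
  qs <- function(x) if (length(x) == 0) rep(NA_real_, 5) else
    unname(stats::quantile(x, c(0, .25, .5, .75, 1)))
  out <- list(identities = idy, summary_overall = qs(idy))
  if (!is.null(tab)) {
    share <- sweep(tab$counts, 2, pmax(colSums(tab$counts), 1), "/") * 100
    abundant <- apply(share >= min_share, 1, any)
    out$abundant <- abundant
    out$summary_abundant <- qs(idy[abundant])
  }
  out
}

#' Write a threshold report as TSV
#'
#' @param thresholds A \code{threshold_set}.
#' @param path Output path.
#' @export
write_threshold_tsv <- function(thresholds, path) {
  utils::write.table(as.data.frame(thresholds), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
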