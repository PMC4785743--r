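## Reference-database curation: identity dereplication that respects
## taxonomy, maximally-distant representative selection ("framing" of
## large heterotroph clades), and composition summaries.

# no resolved rank disagrees between the two lineages
.lineage_compatible <- function(a, b) {
  for (r in TAXONOMIC_RANKS) {
    ag <- lineage_agree(a, b, r)
    if (isFALSE(ag)) return(FALSE)
  }
  TRUE
}

#' Dereplicate a reference database at an identity level
#'
#' Greedy longest-first (ties lexicographic) dereplication: a record joins
#' the first representative reaching the identity threshold whose lineage
#' does not conflict at any resolved rank (taxonomy-curated databases must
#' never merge across taxa), otherwise it becomes a representative. At
#' 100 percent, exact duplicates and exact substrings collapse.
#'
#' @param records Reference database data frame.
#' @param identity Threshold in percent, in (50, 100\]; default 100.
#' @return List: \code{representatives} (data frame subset) and
#'   \code{members} (named list representative id -> member ids).
#' @export
dereplicate_db <- function(records, identity = 100) {
  if (identity <= 50 || identity > 100) stop("identity must lie in (50, 100]")
  seqs <- degap(records$seq)
  ord <- order(-nchar(seqs), seqs)
  reps <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[k]
      ok <-
        if (identity == 100) {
          grepl(seqs[i], seqs[r], fixed = TRUE)   # equal or substring
        } else {
          percent_identity(seqs[i], seqs[r], mode = "global") >= identity
        }
      if (ok && .lineage_compatible(
            unlist(records[i, TAXONOMIC_RANKS]),
            unlist(records[r, TAXONOMIC_RANKS]))) {
        members[[k]] <- c(members[[k]], records$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- records$id[i]
    }
  }
  names(members) <- records$id[reps]
  list(representatives = records[reps, , drop = FALSE], members = members)
}

#' Select maximally distant representatives
#'
#' Greedy farthest-point selection used to "frame" large clades with few
#' sequences: start from the globally most divergent pair, then
#' iteratively add the record with the largest minimum identity-distance
#' to the chosen set. Ties break lexicographically by id, so selection is
#' deterministic.
#'
#' @param records Reference database data frame (aligned or gap-free
#'   sequences).
#' @param k Number of representatives, 2 <= k <= nrow(records).
#' @param max_end_missing Passed to [identity_matrix()] when sequences are
#'   aligned.
#' @return Data frame of the k selected records (original row order).
#' @export
select_distant_representatives <- function(records, k,
                                           max_end_missing = 20) {
  n <- nrow(records)
  if (k < 2 || k > n) stop("k must lie in [2, nrow(records)]")
  if (length(unique(nchar(records$seq))) == 1) {
    m <- identity_matrix(records, max_end_missing = max_end_missing)$identity
  } else {
    seqs <- degap(records$seq)
    m <- matrix(100, n, n, dimnames = list(records$id, records$id))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      m[i, j] <- m[j, i] <- percent_identity(seqs[i], seqs[j],
                                             mode = "global")
  }
  dm <- 100 - m[records$id, records$id]
  ids <- records$id
  # seed: the most divergent pair, ties lexicographic
  w <- which(dm == max(dm), arr.ind = TRUE)
  pair <- t(apply(w, 1, function(x) sort(ids[x])))
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  chosen <- pair
  while (length(chosen) < k) {
    rest <- setdiff(ids, chosen)
    mind <- vapply(rest, function(r) min(dm[r, chosen]), numeric(1))
    best <- rest[mind == max(mind)]
    chosen <- c(chosen, sort(best)[1])
  }
  records[records$id %in% chosen, , drop = FALSE]
}

#' Reference-database composition summary
#'
#' @param records Reference database data frame.
#' @return List: \code{total}, \code{phototrophs}, \code{heterotrophs},
#'   and count tables \code{by_domain}, \code{by_phylum}, \code{by_class}
#'   (phototroph records only for the latter two).
#' @export
db_summary <- function(records) {
  ph <- records[records$phototroph, , drop = FALSE]
  tab <- function(x) {
    x <- x[x != UNRESOLVED]
    if (length(x) == 0) return(table(character(0)))
    table(x)
  }
  list(total = nrow(records),
       phototrophs = sum(records$phototroph),
       heterotrophs = sum(!records$phototroph),
       by_domain = tab(records$domain),
       by_phylum = tab(ph$phylum),
       by_class = tab(ph$class))
}

#' Lineage-based exclusion filter
#'
#' Removes records matching any configured (rank, label) exclusion rule —
#' e.g. off-target organellar or nuclear-encoded homolog groups that must
#' not enter calibration.
#'
#' @param records Reference database data frame.
#' @param rules Data frame with columns \code{rank} and \code{label}.
#' @return Filtered records; attribute \code{n_excluded}.
#' @export
exclude_lineages <- function(records, rules) {
  drop <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(rules)))
    drop <- drop | records[[rules$rank[i]]] == rules$label[i]
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}
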