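## Read-to-OTU mapping, the abundance table with its low-count cell filter,
## rank-abundance curves, and community richness/abundance profiles.

#' Map reads onto OTU centroids
#'
#' Every quality-filtered read (including the low-abundance ones removed
#' before clustering) is assigned to the best-identity centroid at or above
#' \code{threshold} (global alignment; identity ties resolved toward the
#' more abundant OTU). Unmatched reads are tallied as unmapped. Cells of
#' the resulting OTU x sample table with fewer than \code{cell_floor}
#' reads are then zeroed — isolated 1-2 read cells are indistinguishable
#' from index hopping — and the zeroed reads are reported as the
#' "corrected" delta.
#'
#' @param reads Reads with sample labels (post-trim, pre-denoise).
#' @param otus An \code{otu_set}.
#' @param threshold Mapping identity threshold, default 97.
#' @param cell_floor Minimum per-cell count retained, default 3.
#' @return An \code{abundance_table}: list with \code{counts} (OTU x
#'   sample matrix, OTU ids as rownames), \code{mapped}, \code{unmapped},
#'   \code{corrected} (reads zeroed by the cell filter), \code{otus}.
#' @export
map_reads <- function(reads, otus, threshold = 97, cell_floor = 3) {
  if (length(otus$centroid) == 0) stop("no OTUs to map against")
  if (any(is.na(reads$sample))) stop("reads must carry sample labels")
  samples <- sort(unique(reads$sample))
  otu_ids <- sprintf("OTU%03d", seq_along(otus$centroid))
  # map unique sequences once, then expand per-sample counts
  uniq <- unique(reads$seq)
  assign <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    idy <- .identities_vs(uniq[i], otus$centroid)
    hit <- which(idy >= threshold)
    assign[i] <- if (length(hit) == 0) NA_integer_ else {
      best <- idy[hit] == max(idy[hit])
      # identity ties toward the more abundant OTU
      hit[best][which.max(otus$total[hit[best]])]
    }
  }
  ridx <- assign[match(reads$seq, uniq)]
  mapped <- !is.na(ridx)
  tab <- table(factor(ridx[mapped], levels = seq_along(otus$centroid)),
               factor(reads$sample[mapped], levels = samples))
  counts <- matrix(as.integer(tab), nrow = length(otus$centroid),
                   dimnames = list(otu_ids, samples))
  pre_total <- sum(counts)
  low <- counts > 0 & counts < cell_floor
  corrected <- sum(counts[low])
  counts[low] <- 0L
  structure(list(counts = counts, mapped = pre_total,
                 unmapped = sum(!mapped), corrected = corrected,
                 otus = otus),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "<abundance_table: %d OTUs x %d samples; mapped %d, unmapped %d, corrected %d>\n",
    nrow(x$counts), ncol(x$counts), x$mapped, x$unmapped, x$corrected))
  invisible(x)
}

#' Rank-abundance curve for one sample
#'
#' OTUs sorted by descending count in the sample (count ties broken by OTU
#' id, so curves are deterministic). Non-cumulative curves report counts
#' and per-OTU shares; cumulative curves report the running share of the
#' sample's mapped reads.
#'
#' @param tab An \code{abundance_table}.
#' @param sample Sample name.
#' @param cumulative Return the running share (default \code{FALSE}).
#' @param top_n Optional truncation to the first \code{top_n} ranks.
#' @return Data frame (rank, otu, count, share or cumulative_share;
#'   shares in percent).
#' @export
rank_abundance <- function(tab, sample, cumulative = FALSE, top_n = NULL) {
  if (!sample %in% colnames(tab$counts)) stop("unknown sample: ", sample)
  v <- setNames(tab$counts[, sample], rownames(tab$counts))
  ord <- order(-v, names(v))
  v <- v[ord]
  v <- v[v > 0]
  total <- sum(v)
  out <- data.frame(rank = seq_along(v), otu = names(v), count = as.integer(v),
                    stringsAsFactors = FALSE)
  if (cumulative) {
    out$cumulative_share <- 100 * cumsum(v) / total
  } else {
    out$share <- 100 * v / total
  }
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Community richness and abundance profile
#'
#' Aggregates the abundance table at one taxonomic rank: richness share =
#' percent of OTUs per taxon label, abundance share = percent of mapped
#' reads, per sample and overall, plus the phototroph/heterotroph split
#' when the annotation carries the flag. OTUs lacking an annotation are
#' reported under [UNRESOLVED], never dropped. Taxa whose overall
#' abundance share falls below \code{others_floor} percent can be pooled
#' into \code{"Others"}.
#'
#' @param tab An \code{abundance_table}.
#' @param annotations Data frame with rownames (or column \code{otu})
#'   matching the table's OTU ids, rank columns as in [TAXONOMIC_RANKS],
#'   optionally a logical \code{phototroph} column.
#' @param rank Rank to profile at.
#' @param others_floor Pool taxa below this mean abundance share (percent);
#'   0 (default) disables pooling.
#' @return List with \code{by_sample} and \code{overall} data frames
#'   (taxon, n_otus, richness_share, reads, abundance_share) and, when
#'   available, \code{trophic} (phototroph vs heterotroph split).
#' @export
community_profile <- function(tab, annotations, rank = "class",
                              others_floor = 0) {
  if (!rank %in% TAXONOMIC_RANKS) stop("unknown rank: ", rank)
  ids <- rownames(tab$counts)
  if ("otu" %in% names(annotations)) rownames(annotations) <- annotations$otu
  lab <- rep(UNRESOLVED, length(ids))
  hit <- ids %in% rownames(annotations)
  lab[hit] <- annotations[ids[hit], rank]
  lab[is.na(lab)] <- UNRESOLVED
  keep <- rowSums(tab$counts) > 0    # OTUs emptied by the cell filter drop out
  counts <- tab$counts[keep, , drop = FALSE]
  lab <- lab[keep]
  overall_reads <- tapply(rowSums(counts), lab, sum)
  if (others_floor > 0) {
    share <- 100 * overall_reads / sum(overall_reads)
    pool <- names(share)[share < others_floor & names(share) != UNRESOLVED]
    if (length(pool) > 0) lab[lab %in% pool] <- "Others"
  }
  agg <- function(cnt) {
    reads <- tapply(cnt, lab, sum)
    notus <- tapply(cnt > 0, lab, sum)
    data.frame(taxon = names(reads), n_otus = as.integer(notus),
               richness_share = 100 * as.integer(notus) / sum(notus),
               reads = as.integer(reads),
               abundance_share = if (sum(reads) > 0)
                 100 * as.integer(reads) / sum(reads) else 0,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  overall <- agg(rowSums(counts))
  by_sample <- lapply(colnames(counts), function(s) agg(counts[, s]))
  names(by_sample) <- colnames(counts)
  out <- list(overall = overall, by_sample = by_sample, rank = rank)
  if ("phototroph" %in% names(annotations)) {
    ph <- annotations[ids[keep], "phototroph"]
    ph <- ifelse(is.na(ph), NA, ifelse(ph, "Phototrophs", "Heterotrophs"))
    reads <- tapply(rowSums(counts), ph, sum)
    notus <- tapply(rep(1, length(ph)), ph, sum)
    out$trophic <- data.frame(
      group = names(reads), n_otus = as.integer(notus),
      richness_share = 100 * as.integer(notus) / sum(notus),
      reads = as.integer(reads),
      abundance_share = 100 * as.integer(reads) / sum(reads),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Write an abundance table as TSV
#'
#' @param tab An \code{abundance_table}.
#' @param path Output path (OTUs x samples, header row = samples).
#' @export
write_abundance_tsv <- function(tab, path) {
  utils::write.table(tab$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
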