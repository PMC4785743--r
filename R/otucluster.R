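## Dual OTU clustering: greedy global-threshold centroid clustering and
## local d-step (Levenshtein) agglomeration, plus the core-OTU consensus of
## the two partitions and a d-scan for the local threshold optimum.

# identity of one query against many gap-free centroids (global alignment)
.identities_vs <- function(query, targets, gap_opening = 5, gap_extension = 2) {
  if (length(targets) == 0) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    rep(Biostrings::DNAStringSet(query), length(targets)),
    Biostrings::DNAStringSet(targets),
    type = "global", substitutionMatrix = .nuc_submat(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(pa), function(j) {
    cnt <- .aligned_counts(pa[j], sa[j])
    if (cnt[["comparable"]] == 0) return(0)
    100 * cnt[["matches"]] / cnt[["comparable"]]
  }, numeric(1))
}

.new_otu_set <- function(centroids, members, amps, source) {
  counts <- do.call(rbind, lapply(members, function(m)
    colSums(amps$counts[m, , drop = FALSE])))
  if (is.null(counts)) counts <- matrix(0L, 0, length(amps$samples))
  structure(list(centroid = centroids, members = members,
                 total = as.integer(rowSums(counts)),
                 counts = counts, samples = amps$samples, source = source),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("<otu_set (%s): %d OTUs, %d reads>\n",
              x$source, length(x$centroid), sum(x$total)))
  invisible(x)
}

# enforce the deterministic processing order: abundance desc, lexicographic
.abundance_order <- function(amps) order(-amps$total, amps$seq)

#' Greedy global-threshold centroid clustering
#'
#' Amplicons are processed in decreasing abundance (ties lexicographic);
#' each joins the existing centroid of best global-alignment identity among
#' those at or above \code{threshold} (identity ties resolved toward the
#' more abundant centroid), otherwise it founds a new OTU. Fully
#' deterministic for a given input.
#'
#' @param amps An \code{amplicon_tab}.
#' @param threshold Global identity threshold in percent, default 97.
#' @return An \code{otu_set} with \code{source = "global"}; OTU counts are
#'   sums over member amplicons.
#' @export
cluster_global <- function(amps, threshold = 97) {
  if (threshold <= 50 || threshold > 100)
    stop("threshold must lie in (50, 100]")
  ord <- .abundance_order(amps)
  centroids <- character(0)
  members <- list()
  for (i in ord) {
    idy <- .identities_vs(amps$seq[i], centroids)
    hit <- which(idy >= threshold)
    if (length(hit) > 0) {
      # best identity; ties toward the more abundant (earlier) centroid
      best <- hit[which.max(idy[hit])]
      members[[best]] <- c(members[[best]], i)
    } else {
      centroids <- c(centroids, amps$seq[i])
      members[[length(centroids)]] <- i
    }
  }
  .new_otu_set(centroids, members, amps, "global")
}

#' Local d-step (swarm-style) agglomerative clustering
#'
#' The most abundant unassigned amplicon seeds an OTU; any unassigned
#' amplicon within at most \code{d} differences (Levenshtein distance —
#' amplicons may differ in length) of any current member joins, generation
#' by generation, until closure; then the next seed is taken. The resulting
#' partition equals the connected components of the \eqn{\le d}-difference
#' graph, seeded in abundance order.
#'
#' @param amps An \code{amplicon_tab}.
#' @param d Maximum per-link difference count, >= 1.
#' @return An \code{otu_set} with \code{source = "local"}; each OTU's
#'   centroid is its seed.
#' @export
cluster_local <- function(amps, d = 10) {
  if (d < 1) stop("d must be >= 1")
  n <- length(amps$seq)
  dist <- utils::adist(amps$seq)
  ord <- .abundance_order(amps)
  assigned <- rep(FALSE, n)
  centroids <- character(0)
  members <- list()
  for (s in ord) {
    if (assigned[s]) next
    swarm <- s
    assigned[s] <- TRUE
    frontier <- s
    while (length(frontier) > 0) {
      reach <- which(!assigned &
                     apply(dist[frontier, , drop = FALSE], 2, min) <= d)
      assigned[reach] <- TRUE
      swarm <- c(swarm, reach)
      frontier <- reach
    }
    centroids <- c(centroids, amps$seq[s])
    members[[length(centroids)]] <- swarm
  }
  .new_otu_set(centroids, members, amps, "local")
}

#' Core-OTU consensus of the two clusterings
#'
#' An OTU is "core" when it is produced concordantly by both algorithms. By
#' default a global OTU qualifies when its centroid sequence is also the
#' seed sequence of some local OTU (exact string match); the alternative
#' criterion requires member-set Jaccard overlap >= 0.5 with some local
#' OTU.
#'
#' @param global_otus,local_otus \code{otu_set}s from [cluster_global()]
#'   and [cluster_local()] on the same amplicons.
#' @param method \code{"centroid"} (default) or \code{"jaccard"}.
#' @return An \code{otu_set} with \code{source = "core"}, inheriting the
#'   global OTUs' membership.
#' @export
core_consensus <- function(global_otus, local_otus,
                           method = c("centroid", "jaccard")) {
  method <- match.arg(method)
  if (method == "centroid") {
    core <- global_otus$centroid %in% local_otus$centroid
  } else {
    core <- vapply(global_otus$members, function(g) {
      any(vapply(local_otus$members, function(l) {
        length(intersect(g, l)) / length(union(g, l)) >= 0.5
      }, logical(1)))
    }, logical(1))
  }
  structure(list(centroid = global_otus$centroid[core],
                 members = global_otus$members[core],
                 total = global_otus$total[core],
                 counts = global_otus$counts[core, , drop = FALSE],
                 samples = global_otus$samples, source = "core"),
            class = "otu_set")
}

#' Scan the local clustering threshold d
#'
#' Clusters at every \code{d} in \code{d_values}, reports the local OTU
#' count and the core count against a fixed global clustering, and flags
#' the widest plateau of constant core count as the local-threshold
#' optimum (the d range where the two algorithms agree stably).
#'
#' @param amps An \code{amplicon_tab}.
#' @param d_values Integer vector, default 1:16.
#' @param global_otus Fixed global clustering (default: [cluster_global()]
#'   at 97).
#' @return Data frame (d, n_local, n_core, in_optimum) with attribute
#'   \code{optimum} = the d range of the widest constant-core plateau.
#' @export
d_scan <- function(amps, d_values = 1:16, global_otus = NULL) {
  if (is.null(global_otus)) global_otus <- cluster_global(amps, 97)
  rows <- lapply(d_values, function(d) {
    loc <- cluster_local(amps, d)
    data.frame(d = d, n_local = length(loc$centroid),
               n_core = length(core_consensus(global_otus, loc)$centroid))
  })
  out <- do.call(rbind, rows)
  # widest run of constant core count; ties -> first (smallest d)
  r <- rle(out$n_core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  w <- which.max(r$lengths)
  opt <- c(out$d[starts[w]], out$d[ends[w]])
  out$in_optimum <- out$d >= opt[1] & out$d <= opt[2]
  attr(out, "optimum") <- opt
  out
}

#' Write OTU centroids as FASTA
#'
#' Headers carry \code{;size=} annotations in the usual amplicon dialect.
#'
#' @param otus An \code{otu_set}.
#' @param path Output path.
#' @export
write_otu_fasta <- function(otus, path) {
  ids <- sprintf("OTU%03d;size=%d", seq_along(otus$centroid), otus$total)
  write_fasta(setNames(otus$centroid, ids), path)
}
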