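## Read-processing chain: merge -> demultiplex -> expected-error filter ->
## size filter/trim -> dereplicate -> abundance denoise -> chimera and
## contaminant screens. Every stage returns its survivors and reports its
## discards, so a pipeline ledger can be assembled stage by stage.

#' Phred quality helpers
#'
#' Convert a Phred+33 quality string to integer scores, and compute the
#' expected number of errors E = sum(10^(-Q/10)).
#'
#' @param qual Quality string(s), Phred offset 33.
#' @return \code{phred_scores}: integer vector (single string) ;
#'   \code{expected_errors}: numeric vector, one per string.
#' @export
phred_scores <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' @rdname phred_scores
#' @export
expected_errors <- function(qual) {
  vapply(qual, function(q) sum(10^(-phred_scores(q) / 10)), numeric(1),
         USE.NAMES = FALSE)
}

#' Construct a read-pair table
#'
#' @param id Read ids.
#' @param seq1,qual1 Forward read bases and Phred+33 qualities.
#' @param seq2,qual2 Reverse read bases and qualities (as sequenced, i.e.
#'   reverse-complement orientation relative to the template).
#' @return Data frame of class \code{read_pairs}.
#' @export
read_pairs <- function(id, seq1, qual1, seq2, qual2) {
  stopifnot(nchar(seq1) == nchar(qual1), nchar(seq2) == nchar(qual2))
  structure(data.frame(id = id, seq1 = seq1, qual1 = qual1,
                       seq2 = seq2, qual2 = qual2,
                       stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path File path (uncompressed FASTQ).
#' @return \code{read_fastq}: data frame with id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads Data frame with id, seq, qual.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

# best ungapped overlap merge of one pair; r2 already reverse-complemented
# with reversed qualities. Returns NULL when no admissible overlap exists.
.merge_one <- function(s1, q1, s2, q2, min_overlap, max_mismatch_frac) {
  c1 <- strsplit(s1, "")[[1]]; p1 <- phred_scores(q1)
  c2 <- strsplit(s2, "")[[1]]; p2 <- phred_scores(q2)
  n1 <- length(c1); n2 <- length(c2)
  best <- NULL; best_matches <- -1L
  # offset o: r2 starts at position o of r1 (1-based)
  for (o in seq_len(n1)) {
    ov <- min(n1 - o + 1L, n2)
    if (ov < min_overlap) next
    i1 <- o:(o + ov - 1L)
    i2 <- seq_len(ov)
    matches <- sum(c1[i1] == c2[i2])
    if ((ov - matches) / ov > max_mismatch_frac) next
    if (matches > best_matches) {
      best_matches <- matches
      best <- list(o = o, ov = ov)
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o; ov <- best$ov
  i1 <- o:(o + ov - 1L); i2 <- seq_len(ov)
  cons <- c1[i1]; consq <- p1[i1]
  agree <- c1[i1] == c2[i2]
  # agreement keeps the max quality; conflict: higher-quality base wins
  consq[agree] <- pmax(p1[i1][agree], p2[i2][agree])
  take2 <- !agree & p2[i2] > p1[i1]
  cons[take2] <- c2[i2][take2]
  consq[take2] <- p2[i2][take2]
  seq <- paste(c(c1[seq_len(o - 1L)], cons,
                 if (ov < n2) c2[(ov + 1L):n2]), collapse = "")
  qual <- intToUtf8(c(p1[seq_len(o - 1L)], consq,
                      if (ov < n2) p2[(ov + 1L):n2]) + 33L)
  list(seq = seq, qual = qual)
}

#' Merge overlapping paired-end reads
#'
#' The reverse read is reverse-complemented, the best ungapped overlap of at
#' least \code{min_overlap} bases is chosen by maximum matches, and in the
#' overlap the higher-quality base wins (agreement keeps the maximum
#' quality). Pairs with no admissible overlap are dropped and tallied.
#'
#' @param pairs A [read_pairs()] data frame.
#' @param min_overlap Minimum overlap length (default 16).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap
#'   (default 0.25).
#' @return Data frame of merged reads (id, seq, qual, sample = NA) with
#'   attribute \code{n_dropped}.
#' @export
merge_pairs <- function(pairs, min_overlap = 16, max_mismatch_frac = 0.25) {
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    m <- .merge_one(pairs$seq1[i], pairs$qual1[i],
                    revcomp(pairs$seq2[i]),
                    paste(rev(strsplit(pairs$qual2[i], "")[[1]]),
                          collapse = ""),
                    min_overlap, max_mismatch_frac)
    if (!is.null(m)) out[[i]] <- data.frame(id = pairs$id[i], seq = m$seq,
                                            qual = m$qual,
                                            stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, out)
  if (is.null(kept))
    kept <- data.frame(id = character(0), seq = character(0),
                       qual = character(0), stringsAsFactors = FALSE)
  kept$sample <- rep(NA_character_, nrow(kept))
  rownames(kept) <- NULL
  attr(kept, "n_dropped") <- nrow(pairs) - nrow(kept)
  kept
}

#' Demultiplex merged reads by index prefix
#'
#' A read is assigned to a sample when its 5' prefix equals that sample's
#' index exactly (zero mismatches — index errors cannot be distinguished
#' from index hopping, so none are tolerated) and the window following the
#' index matches the forward primer within \code{primer_mismatch}. Index and
#' primer are stripped from assigned reads; everything else is discarded.
#'
#' @param reads Merged reads (id, seq, qual).
#' @param index_table Named character vector sample -> index; indexes must
#'   be equal-length and mutually distinct.
#' @param fwd_primer A \code{degenerate_primer}.
#' @param primer_mismatch Mismatches tolerated in the primer window
#'   (default 1).
#' @return Assigned reads with \code{sample} set and prefixes stripped;
#'   attribute \code{n_dropped}.
#' @export
demultiplex <- function(reads, index_table, fwd_primer, primer_mismatch = 1) {
  if (anyDuplicated(index_table)) stop("duplicate index in table")
  if (length(unique(nchar(index_table))) != 1)
    stop("indexes must be equal length")
  ilen <- nchar(index_table[1])
  plen <- nchar(fwd_primer$bases)
  prefix <- substr(reads$seq, 1, ilen)
  sample <- names(index_table)[match(prefix, index_table)]
  keep <- !is.na(sample) & nchar(reads$seq) >= ilen + plen
  pwin <- substr(reads$seq, ilen + 1, ilen + plen)
  pok <- logical(nrow(reads))
  for (i in which(keep))
    pok[i] <- primer_match(fwd_primer, pwin[i], primer_mismatch)$match
  keep <- keep & pok
  out <- reads[keep, , drop = FALSE]
  out$sample <- sample[keep]
  out$seq <- substr(out$seq, ilen + plen + 1, nchar(out$seq))
  out$qual <- substr(out$qual, ilen + plen + 1, nchar(out$qual))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(reads) - nrow(out)
  out
}

#' Expected-error quality filter
#'
#' Keeps reads whose expected error count E = sum(10^(-Q/10)) does not
#' exceed \code{max_expected_error}; the discard rule is E > cutoff, so a
#' read exactly at the cutoff is kept.
#'
#' @param reads Reads with qualities.
#' @param max_expected_error Default 0.5.
#' @return Surviving reads; attribute \code{n_dropped}.
#' @export
quality_filter <- function(reads, max_expected_error = 0.5) {
  ee <- expected_errors(reads$qual)
  out <- reads[ee <= max_expected_error, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(reads) - nrow(out)
  out
}

#' Size filter and global trim
#'
#' Drops reads outside \[min_len, max_len\] (both bounds inclusive), then
#' crops \code{crop5} leading and \code{crop3} trailing bases from the
#' survivors — removing primer-proximal and low-quality tail regions.
#'
#' @param reads Reads (qualities trimmed alongside when present).
#' @param min_len,max_len Inclusive length bounds (defaults 400 / 440).
#' @param crop5,crop3 Bases cropped from the 5' / 3' ends (defaults 20 /
#'   50).
#' @return Trimmed survivors; attribute \code{n_dropped}.
#' @export
size_filter_and_trim <- function(reads, min_len = 400, max_len = 440,
                                 crop5 = 20, crop3 = 50) {
  if (crop5 + crop3 >= min_len)
    stop("crop5 + crop3 must be smaller than min_len")
  len <- nchar(reads$seq)
  out <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  n <- nchar(out$seq)
  out$seq <- substr(out$seq, crop5 + 1, n - crop3)
  if (!is.null(out$qual)) out$qual <- substr(out$qual, crop5 + 1, n - crop3)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(reads) - nrow(out)
  out
}

#' Dereplicate reads into unique amplicons
#'
#' Exact-string grouping with per-sample counts. Output order is
#' deterministic: decreasing total count, ties broken lexicographically by
#' sequence.
#'
#' @param reads Reads carrying sample labels.
#' @return An \code{amplicon_tab}: list with \code{seq} (character),
#'   \code{total} (integer), and \code{counts} (amplicon x sample integer
#'   matrix).
#' @export
dereplicate <- function(reads) {
  if (any(is.na(reads$sample))) stop("reads must carry sample labels")
  samples <- sort(unique(reads$sample))
  tab <- table(factor(reads$seq), factor(reads$sample, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), samples))
  total <- rowSums(counts)
  ord <- order(-total, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  seqs <- rownames(counts)
  dimnames(counts) <- list(NULL, samples)
  structure(list(seq = seqs, total = unname(total[ord]),
                 counts = counts, samples = samples),
            class = "amplicon_tab")
}

#' @export
print.amplicon_tab <- function(x, ...) {
  cat(sprintf("<amplicon_tab: %d unique amplicons, %d reads, %d samples>\n",
              length(x$seq), sum(x$total), length(x$samples)))
  invisible(x)
}

# subset helper preserving the class
.amp_subset <- function(amps, keep) {
  structure(list(seq = amps$seq[keep], total = amps$total[keep],
                 counts = amps$counts[keep, , drop = FALSE],
                 samples = amps$samples),
            class = "amplicon_tab")
}

#' Abundance-based denoising
#'
#' Removes unique amplicons whose dataset-wide abundance is below
#' \code{min_total} — at the default 4, singletons, doubletons and
#' tripletons, which are dominated by sequencing error.
#'
#' @param amps An \code{amplicon_tab}.
#' @param min_total Minimum total count to keep (default 4).
#' @return Filtered \code{amplicon_tab}; attribute \code{n_dropped_reads}.
#' @export
denoise_by_abundance <- function(amps, min_total = 4) {
  keep <- amps$total >= min_total
  out <- .amp_subset(amps, keep)
  attr(out, "n_dropped_reads") <- sum(amps$total[!keep])
  out
}

# per-amplicon-position match vector against one reference (global align)
.match_vector <- function(query, ref) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = .nuc_submat(),
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- pa != "-"
  hit <- pa[qpos] == sa[qpos] & sa[qpos] != "-"
  hit
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Reference-based chimera (bimera) screen
#'
#' For each amplicon, candidate parents are pre-screened by shared k-mers;
#' the best single-parent global identity is compared with the best
#' two-parent model (left prefix from parent A, right suffix from parent B,
#' over all crossover points). An amplicon is flagged as chimeric when the
#' two-parent model both gains at least \code{min_parent_gain} percentage
#' points over any single parent and itself reaches
#' \code{min_two_parent_identity}.
#'
#' @param amps An \code{amplicon_tab}.
#' @param references Reference database data frame (or character vector of
#'   gap-free sequences).
#' @param min_parent_gain Identity gain (percentage points) required to
#'   flag, default 3.
#' @param min_two_parent_identity Floor on the two-parent model identity,
#'   default 99.
#' @param k k-mer size of the parent pre-screen, default 8.
#' @param max_parents Candidate parents retained per amplicon, default 20.
#' @return List with \code{clean} and \code{flagged} \code{amplicon_tab}s
#'   and a \code{detail} data frame (single/two-parent identities).
#' @export
chimera_screen <- function(amps, references, min_parent_gain = 3,
                           min_two_parent_identity = 99, k = 8,
                           max_parents = 20) {
  refs <- if (is.data.frame(references)) degap(references$seq)
          else degap(references)
  if (length(refs) == 0) stop("references must be non-empty")
  ref_kmers <- lapply(refs, .kmer_set, k = k)
  n <- length(amps$seq)
  single <- two <- numeric(n)
  for (i in seq_len(n)) {
    q <- amps$seq[i]
    qk <- .kmer_set(q, k)
    shared <- vapply(ref_kmers, function(s) sum(qk %in% s), numeric(1))
    cand <- order(-shared)[seq_len(min(max_parents, length(refs)))]
    cand <- cand[shared[cand] > 0]
    if (length(cand) == 0) { single[i] <- 0; two[i] <- 0; next }
    L <- nchar(q)
    mv <- lapply(refs[cand], .match_vector, query = q)
    pref <- lapply(mv, cumsum)            # prefix match counts along amplicon
    tot <- vapply(pref, function(p) p[L], numeric(1))
    single[i] <- 100 * max(tot) / L
    best2 <- 0
    for (a in seq_along(cand)) {
      for (b in seq_along(cand)) {
        if (a == b) next
        # crossover after position c: left from a, right from b
        sc <- max(pref[[a]][1:(L - 1)] + (tot[b] - pref[[b]][1:(L - 1)]))
        if (sc > best2) best2 <- sc
      }
    }
    two[i] <- 100 * best2 / L
  }
  flagged <- (two - single >= min_parent_gain) &
             (two >= min_two_parent_identity)
  list(clean = .amp_subset(amps, !flagged),
       flagged = .amp_subset(amps, flagged),
       detail = data.frame(seq = amps$seq, single_parent = single,
                           two_parent = two, flagged = flagged,
                           stringsAsFactors = FALSE))
}

#' Contaminant (off-target) screen
#'
#' Keeps an amplicon when its best local alignment against any reference
#' reaches \code{min_identity} percent over at least \code{min_coverage} of
#' the amplicon length; everything else is tallied as non-marker
#' contamination.
#'
#' @param amps An \code{amplicon_tab}.
#' @param references Reference database data frame or character vector.
#' @param min_identity Percent identity floor, default 60.
#' @param min_coverage Fraction of the amplicon that must align, default
#'   0.5.
#' @return List with \code{on_target} and \code{off_target}
#'   \code{amplicon_tab}s.
#' @export
decontaminate <- function(amps, references, min_identity = 60,
                          min_coverage = 0.5) {
  refs <- if (is.data.frame(references)) degap(references$seq)
          else degap(references)
  refset <- Biostrings::DNAStringSet(refs)
  keep <- logical(length(amps$seq))
  for (i in seq_along(amps$seq)) {
    q <- Biostrings::DNAString(amps$seq[i])
    aln <- Biostrings::pairwiseAlignment(
      rep(Biostrings::DNAStringSet(as.character(q)), length(refs)), refset,
      type = "local", substitutionMatrix = .nuc_submat(),
      gapOpening = 5, gapExtension = 2)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    for (j in seq_along(pa)) {
      cnt <- .aligned_counts(pa[j], sa[j])
      if (cnt[["comparable"]] == 0) next
      idy <- 100 * cnt[["matches"]] / cnt[["comparable"]]
      cov <- seq_length(pa[j]) / nchar(amps$seq[i])
      if (idy >= min_identity && cov >= min_coverage) { keep[i] <- TRUE; break }
    }
  }
  list(on_target = .amp_subset(amps, keep),
       off_target = .amp_subset(amps, !keep))
}

#' Pipeline ledger
#'
#' Stage-by-stage read accounting: remaining reads and integer percent of
#' raw input.
#'
#' @param stages Character vector of stage names.
#' @param remaining Integer vector of reads remaining after each stage; the
#'   first entry is the raw count.
#' @return Data frame with stage, reads, percent_of_raw.
#' @export
pipeline_ledger <- function(stages, remaining) {
  stopifnot(length(stages) == length(remaining))
  if (any(diff(remaining) > 0)) stop("ledger counts must be non-increasing")
  raw <- remaining[1]
  pct <- if (raw > 0) round(100 * remaining / raw) else rep(0L, length(remaining))
  data.frame(stage = stages, reads = remaining, percent_of_raw = as.integer(pct),
             stringsAsFactors = FALSE)
}
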