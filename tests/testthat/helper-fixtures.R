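# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (direct enumeration / brute force) and never call the code paths
# they check.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# mutate k distinct positions of a plain ACGT string (oracle-side twin of
# the generator's operation, implemented independently)
mutate_seq <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(ch), k)
  for (p in positions) ch[p] <- setdiff(BASES, ch[p])[sample.int(3, 1)]
  paste(ch, collapse = "")
}

# plain Hamming count on equal-length gap-free strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# connected components of the <= d Levenshtein graph (igraph-free BFS)
lev_components <- function(seqs, d) {
  dm <- utils::adist(seqs)
  n <- length(seqs)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(is.na(comp) & dm[v, ] <= d)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# connected components of the <= h graph on a distance matrix
mat_components <- function(dm, h) {
  n <- nrow(dm)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(is.na(comp) & dm[v, ] <= h)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# amplicon_tab built directly from sequences and per-sample counts
make_amps <- function(seqs, counts) {
  reads <- data.frame(
    id = paste0("r", seq_len(sum(counts))),
    seq = rep(seqs, counts),
    qual = strrep("I", nchar(rep(seqs, counts))),
    sample = "S1", stringsAsFactors = FALSE)
  dereplicate(reads)
}

# small aligned reference database with explicit lineages; seqs must share
# one length
make_db <- function(seqs, lineages, phototroph = TRUE) {
  make_ref_db(sprintf("r%02d", seq_along(seqs)), seqs, lineages, phototroph)
}

# two-clade aligned fixture: `n_per` sequences per clade, intra pairs differ
# by `intra_subs`, clades differ by `inter_subs` (all over length L)
two_clade_seqs <- function(L = 375, n_per = 3, intra_subs = 2,
                           inter_subs = 40) {
  root <- rand_seq(L)
  clade2 <- mutate_seq(root, inter_subs, positions = seq_len(inter_subs))
  grow <- function(anchor, offset) {
    vapply(seq_len(n_per), function(i) {
      if (i == 1) anchor
      else mutate_seq(anchor, intra_subs,
                      positions = offset + (i - 1) * intra_subs +
                        seq_len(intra_subs))
    }, character(1))
  }
  list(clade1 = grow(root, L - 60), clade2 = grow(clade2, L - 30))
}
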