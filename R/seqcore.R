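#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement pairwiseAlignment alignedPattern
#'   alignedSubject nucleotideSubstitutionMatrix quality
#' @importFrom stats quantile rbinom runif setNames
#' @importFrom utils adist head read.delim write.table
NULL

## Fixed rank system used throughout: high ranks (domain..class) apply to all
## phototrophs, low ranks (order..family) to a clade subset, species last.
#' Taxonomic rank order
#'
#' The fixed, ordered rank system used by all taxonomy-aware operations:
#' domain, phylum, class, order, suborder, family, species.
#'
#' @format Character vector of length 7.
#' @export
TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order",
                     "suborder", "family", "species")

#' Reserved label for an unresolved rank
#'
#' Lineage labels equal to this token mark ranks with no assignment.
#' Comparisons at an unresolved rank are undefined (neither match nor
#' mismatch), never counted as disagreement.
#'
#' @format Character scalar.
#' @export
UNRESOLVED <- "UNRESOLVED"

# IUPAC base sets, gap "-" and missing "." excluded (non-comparable marks)
.iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.valid_chars <- c(names(.iupac), "-", ".")

# 17x17 lookup: do the base sets of two IUPAC codes intersect?
.iupac_compat <- local({
  n <- names(.iupac)
  m <- matrix(FALSE, length(n), length(n), dimnames = list(n, n))
  for (a in n) for (b in n)
    m[a, b] <- length(intersect(.iupac[[a]], .iupac[[b]])) > 0
  m
})

#' Normalize a nucleotide string
#'
#' Upper-cases, maps U to T, and validates the alphabet (IUPAC codes plus
#' the gap mark \code{-} and the missing-data mark \code{.}).
#'
#' @param x Character vector of sequences.
#' @return Normalized character vector.
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- setdiff(unique(unlist(strsplit(x, ""))), .valid_chars)
  if (length(bad) > 0)
    stop("invalid sequence characters: ", paste(bad, collapse = ", "))
  if (any(!nzchar(x))) stop("empty sequence")
  x
}

#' Sequence length excluding gap and missing marks
#'
#' @param x Character vector of (possibly aligned) sequences.
#' @return Integer vector of ungapped lengths.
#' @export
seq_length <- function(x) {
  nchar(gsub("[-.]", "", x))
}

#' Remove gap and missing marks from aligned sequences
#'
#' @param x Character vector.
#' @return Character vector without \code{-} or \code{.}.
#' @export
degap <- function(x) gsub("[-.]", "", x)

#' Reverse complement
#'
#' IUPAC-aware reverse complement of plain character sequences.
#'
#' @param x Character vector of gap-free sequences.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# column-wise identity on two equal-length aligned character strings.
# Returns c(matches, comparable). Pairwise deletion: columns where either
# side carries "-" or "." are dropped from the denominator.
.aligned_counts <- function(a, b, strict = FALSE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  comp <- !(ca %in% c("-", ".")) & !(cb %in% c("-", "."))
  ca <- ca[comp]
  cb <- cb[comp]
  if (strict) {
    plain <- c("A", "C", "G", "T")
    match <- ca == cb & ca %in% plain
  } else {
    match <- .iupac_compat[cbind(ca, cb)]
  }
  c(matches = sum(match), comparable = sum(comp))
}

# shared scoring for global alignments; amb codes scored leniently so they
# align through degenerate primer remnants
.nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Pairwise percent identity
#'
#' Identity between two nucleotide sequences, either over the columns of an
#' existing alignment (\code{mode = "aligned"}; both sequences must have the
#' same raw length) or after computing an end-to-end global alignment
#' (\code{mode = "global"}). The denominator counts only columns where both
#' sequences carry a non-gap, non-missing character (pairwise deletion); by
#' default ambiguity codes match whenever their base sets intersect
#' (\code{W} matches \code{A}), while \code{strict = TRUE} restricts matches
#' to identical unambiguous bases.
#'
#' @param a,b Character sequences (IUPAC alphabet; \code{-} gap, \code{.}
#'   missing).
#' @param mode \code{"aligned"} or \code{"global"}.
#' @param strict Count ambiguity codes as mismatches (default \code{FALSE}).
#' @param gap_opening,gap_extension Global-alignment gap penalties.
#' @return Percent identity in \[0, 100\] (unrounded; print at 2 dp).
#' @examples
#' percent_identity(strrep("A", 10), strrep("A", 10))          # 100
#' round(percent_identity("ACGTACGT", "ACGTACGA"), 2)          # 87.5
#' @export
percent_identity <- function(a, b, mode = c("aligned", "global"),
                             strict = FALSE,
                             gap_opening = 5, gap_extension = 2) {
  mode <- match.arg(mode)
  a <- normalize_seq(a)
  b <- normalize_seq(b)
  if (mode == "aligned") {
    if (nchar(a) != nchar(b))
      stop("aligned mode requires equal raw lengths")
  } else {
    da <- degap(a)
    db <- degap(b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(da), Biostrings::DNAString(db),
      type = "global", substitutionMatrix = .nuc_submat(),
      gapOpening = gap_opening, gapExtension = gap_extension)
    a <- as.character(Biostrings::alignedPattern(aln))
    b <- as.character(Biostrings::alignedSubject(aln))
  }
  cnt <- .aligned_counts(a, b, strict = strict)
  if (cnt[["comparable"]] == 0) stop("no overlap")
  100 * cnt[["matches"]] / cnt[["comparable"]]
}

# leading/trailing run of gap or missing marks
.end_missing <- function(x) {
  lead <- attr(regexpr("^[-.]*", x), "match.length")
  trail <- attr(regexpr("[-.]*$", x), "match.length")
  c(lead = lead, trail = trail)
}

#' All-pairs identity matrix over a metabarcode alignment
#'
#' Computes the symmetric percent-identity matrix over records sharing one
#' alignment coordinate system, after excluding records with more than
#' \code{max_end_missing} gap/missing characters at either end (such
#' truncated sequences inflate pairwise-deletion identities).
#'
#' @param records Reference set: a data frame with columns \code{id} and
#'   \code{seq} (aligned), e.g. from [make_ref_db()], or a named character
#'   vector of aligned sequences.
#' @param max_end_missing Exclusion bound in bp; a record is dropped when a
#'   leading or trailing gap/missing run is strictly longer than this
#'   (default 20).
#' @param strict Passed to [percent_identity()].
#' @return List with \code{identity} (matrix, diagonal 100, ids as
#'   dimnames), \code{kept} and \code{excluded} (character id vectors).
#' @export
identity_matrix <- function(records, max_end_missing = 20, strict = FALSE) {
  if (is.data.frame(records)) {
    seqs <- setNames(records$seq, records$id)
  } else {
    seqs <- records
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  seqs <- normalize_seq(seqs)
  if (length(unique(nchar(seqs))) != 1)
    stop("records must share one alignment coordinate system")
  ends <- vapply(seqs, .end_missing, numeric(2))
  drop <- ends["lead", ] > max_end_missing | ends["trail", ] > max_end_missing
  excluded <- names(seqs)[drop]
  seqs <- seqs[!drop]
  n <- length(seqs)
  if (n < 2) stop("fewer than 2 records survive the end-missing exclusion")
  chars <- do.call(rbind, strsplit(seqs, ""))
  comp <- !(chars == "-" | chars == ".")
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both <- comp[i, ] & comp[j, ]
      if (!any(both)) stop("no overlap between ", names(seqs)[i], " and ",
                           names(seqs)[j])
      if (strict) {
        plain <- chars[i, both] %in% c("A", "C", "G", "T")
        hit <- (chars[i, both] == chars[j, both]) & plain
      } else {
        hit <- .iupac_compat[cbind(chars[i, both], chars[j, both])]
      }
      m[i, j] <- m[j, i] <- 100 * sum(hit) / sum(both)
    }
  }
  list(identity = m, kept = names(seqs), excluded = excluded)
}

#' Build a taxonomy lineage
#'
#' @param ... Labels in rank order (domain, phylum, class, order, suborder,
#'   family, species); missing trailing ranks filled with [UNRESOLVED].
#' @return Named character vector over [TAXONOMIC_RANKS].
#' @export
lineage <- function(...) {
  lbl <- c(...)
  if (length(lbl) > length(TAXONOMIC_RANKS)) stop("too many rank labels")
  out <- rep(UNRESOLVED, length(TAXONOMIC_RANKS))
  out[seq_along(lbl)] <- lbl
  names(out) <- TAXONOMIC_RANKS
  out
}

#' Do two lineages agree at a rank?
#'
#' @param a,b Lineages (named character vectors over [TAXONOMIC_RANKS]).
#' @param rank Rank name.
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when either label is
#'   [UNRESOLVED] (comparison undefined, not a mismatch).
#' @export
lineage_agree <- function(a, b, rank) {
  la <- a[[rank]]
  lb <- b[[rank]]
  if (identical(la, UNRESOLVED) || identical(lb, UNRESOLVED)) return(NA)
  la == lb
}

#' Assemble a reference database
#'
#' One row per reference record: a marker sequence plus its ranked lineage
#' and a phototroph flag. This data frame is the unit consumed by the
#' calibration, clustering, and curation functions.
#'
#' @param id Character ids (unique).
#' @param seq Character sequences (aligned or not, IUPAC alphabet).
#' @param lineages A data frame / matrix with columns [TAXONOMIC_RANKS], or
#'   a list of [lineage()] vectors.
#' @param phototroph Logical vector.
#' @return A data frame with columns id, seq, the seven ranks, phototroph.
#' @export
make_ref_db <- function(id, seq, lineages, phototroph = TRUE) {
  if (anyDuplicated(id)) stop("duplicate record ids")
  seq <- normalize_seq(seq)
  if (is.list(lineages) && !is.data.frame(lineages))
    lineages <- do.call(rbind, lineages)
  lineages <- as.data.frame(lineages, stringsAsFactors = FALSE)
  if (!all(TAXONOMIC_RANKS %in% names(lineages)))
    stop("lineages must provide all ranks: ",
         paste(TAXONOMIC_RANKS, collapse = ", "))
  db <- data.frame(id = id, seq = seq, lineages[TAXONOMIC_RANKS],
                   phototroph = phototroph, stringsAsFactors = FALSE)
  # heterotroph records must not claim a phototroph lineage
  bad <- !db$phototroph & db$phylum != UNRESOLVED & db$domain == "Eukaryota"
  if (any(bad))
    stop("heterotroph records with eukaryote phototroph lineage: ",
         paste(db$id[bad], collapse = ", "))
  rownames(db) <- NULL
  db
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings that keep sequences as plain character
#' vectors (wrapped and single-line dialects both read; alignment FASTA with
#' \code{-} gaps and \code{.} missing-ends supported).
#'
#' @param path File path.
#' @return \code{read_fasta}: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read / write the taxonomy sidecar TSV
#'
#' Format: one row per record with columns \code{id}, semicolon-joined
#' lineage (domain;phylum;class;order;suborder;family;species), and a
#' phototroph flag in \{0, 1\}.
#'
#' @param path File path.
#' @param seqs Named character vector of the matching sequences (ids must
#'   agree with the TSV).
#' @return \code{read_taxonomy_tsv} combined with \code{seqs}: a reference
#'   database data frame (see [make_ref_db()]).
#' @export
read_taxonomy_tsv <- function(path, seqs) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "lineage", "phototroph"))
  missing <- setdiff(tab$id, names(seqs))
  if (length(missing) > 0)
    stop("taxonomy/sequence id mismatch: ", paste(missing, collapse = ", "))
  parts <- strsplit(tab$lineage, ";", fixed = TRUE)
  lin <- do.call(rbind, lapply(parts, function(p) lineage(p)))
  make_ref_db(tab$id, unname(seqs[tab$id]), lin,
              phototroph = tab$phototroph == 1)
}

#' @rdname read_taxonomy_tsv
#' @param db Reference database data frame.
#' @export
write_taxonomy_tsv <- function(db, path) {
  lin <- apply(db[TAXONOMIC_RANKS], 1, paste, collapse = ";")
  out <- data.frame(db$id, lin, as.integer(db$phototroph))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
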