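#' Define a degenerate primer
#'
#' Primers are stored as written 5'->3'; reverse primers are
#' reverse-complemented internally wherever they are matched against the
#' forward strand of a template.
#'
#' @param name Primer name.
#' @param bases IUPAC sequence (no gaps).
#' @param orientation \code{"forward"} or \code{"reverse"}.
#' @return An object of class \code{degenerate_primer}.
#' @export
degenerate_primer <- function(name, bases, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  bases <- normalize_seq(bases)
  if (grepl("[-.]", bases)) stop("primer must be gap-free")
  structure(list(name = name, bases = bases, orientation = orientation),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<primer %s (%s) %s  length %d  degeneracy %d  GC %.1f%%>\n",
              x$name, x$orientation, x$bases, nchar(x$bases),
              primer_degeneracy(x), primer_gc_percent(x)))
  invisible(x)
}

.primer_chars <- function(p) {
  strsplit(if (inherits(p, "degenerate_primer")) p$bases else
           normalize_seq(p), "")[[1]]
}

#' Primer degeneracy
#'
#' Product over positions of the IUPAC ambiguity-set sizes.
#'
#' @param p A \code{degenerate_primer} or IUPAC string.
#' @return Integer >= 1.
#' @export
primer_degeneracy <- function(p) {
  prod(vapply(.iupac[.primer_chars(p)], length, integer(1)))
}

#' Fractional GC content of a degenerate primer
#'
#' Each position contributes the fraction of its ambiguity set that is G or
#' C (G, C, S -> 1; W, A, T -> 0; N and two-fold mixed codes -> 0.5; B, V ->
#' 2/3; D, H -> 1/3), averaged over the primer length. Equivalent to the
#' mean GC over all expanded non-degenerate primer variants.
#'
#' @param p A \code{degenerate_primer} or IUPAC string.
#' @param digits Rounding (default 1 dp, the conventional reporting
#'   precision).
#' @return GC percentage.
#' @examples
#' primer_gc_percent("TTTTAATGGCTGTCGAAAATGTTG")  # 33.3
#' @export
primer_gc_percent <- function(p, digits = 1) {
  ch <- .primer_chars(p)
  if (length(ch) == 0) stop("empty primer")
  frac <- vapply(.iupac[ch], function(s) mean(s %in% c("G", "C")), numeric(1))
  round(100 * mean(frac), digits)
}

#' Expand a degenerate primer into all concrete variants
#'
#' @param p A \code{degenerate_primer} or IUPAC string.
#' @param max_variants Guard against combinatorial blow-up.
#' @return Character vector of unambiguous sequences.
#' @export
expand_primer <- function(p, max_variants = 4096) {
  ch <- .primer_chars(p)
  deg <- prod(vapply(.iupac[ch], length, integer(1)))
  if (deg > max_variants) stop("degeneracy ", deg, " exceeds max_variants")
  do.call(paste0, expand.grid(.iupac[ch], stringsAsFactors = FALSE))
}

#' Match a primer against a same-length template window
#'
#' A position mismatches when the window base is not contained in the
#' primer's ambiguity set at that position (an all-N primer matches
#' anything; W covers A and T).
#'
#' @param p A \code{degenerate_primer} or IUPAC string (as written; not
#'   reverse-complemented here).
#' @param window Template window, same length as the primer.
#' @param max_mismatch Allowed mismatches.
#' @return List with \code{match} (logical) and \code{mismatches} (count).
#' @export
primer_match <- function(p, window, max_mismatch = 0) {
  pc <- .primer_chars(p)
  wc <- strsplit(normalize_seq(window), "")[[1]]
  if (length(pc) != length(wc))
    stop("window length (", length(wc), ") != primer length (", length(pc), ")")
  mm <- sum(!mapply(function(pb, wb) wb %in% .iupac[[pb]], pc, wc))
  list(match = mm <= max_mismatch, mismatches = mm)
}

# positions (0-based starts) where primer matches template within max_mismatch
.scan_sites <- function(primer_bases, template, max_mismatch) {
  pc <- strsplit(primer_bases, "")[[1]]
  tc <- strsplit(template, "")[[1]]
  L <- length(pc)
  n <- length(tc)
  if (n < L) return(integer(0))
  # logical compatibility per template position and primer position
  ok <- matrix(FALSE, L, n)
  for (i in seq_len(L)) ok[i, ] <- tc %in% .iupac[[pc[i]]]
  starts <- integer(0)
  for (s in 0:(n - L)) {
    mm <- L - sum(ok[cbind(seq_len(L), s + seq_len(L))])
    if (mm <= max_mismatch) starts <- c(starts, s)
  }
  starts
}

#' In-silico PCR
#'
#' Scans a gap-free template (forward strand) for the forward primer site
#' and, downstream of it, the reverse complement of the reverse primer;
#' reports every site pair as one amplicon.
#'
#' @param template Gap-free template sequence.
#' @param fwd,rev \code{degenerate_primer}s.
#' @param max_mismatch Allowed mismatches per primer site.
#' @param both_strands Also scan the reverse-complemented template.
#' @return Data frame with 0-based half-open coordinates \code{start},
#'   \code{end} (amplicon including primers), \code{full_length},
#'   \code{insert_length} (\code{full - len(fwd) - len(rev)}),
#'   \code{strand}, and sequences \code{amplicon} / \code{insert}. Empty
#'   when no site pair is found.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatch = 0,
                          both_strands = FALSE) {
  template <- normalize_seq(template)
  if (grepl("[-.]", template)) stop("template must be gap-free")
  scan_one <- function(tmpl, strand) {
    fl <- nchar(fwd$bases)
    rl <- nchar(rev$bases)
    f_sites <- .scan_sites(fwd$bases, tmpl, max_mismatch)
    r_sites <- .scan_sites(revcomp(rev$bases), tmpl, max_mismatch)
    hits <- list()
    for (fs in f_sites) {
      for (rs in r_sites) {
        if (rs >= fs + fl) {   # reverse site strictly downstream of forward
          start <- fs
          end <- rs + rl
          hits[[length(hits) + 1L]] <- data.frame(
            start = start, end = end,
            full_length = end - start,
            insert_length = end - start - fl - rl,
            strand = strand,
            amplicon = substr(tmpl, start + 1, end),
            insert = substr(tmpl, start + fl + 1, end - rl),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits) == 0) return(NULL)
    do.call(rbind, hits)
  }
  out <- scan_one(template, "+")
  if (both_strands) out <- rbind(out, scan_one(revcomp(template), "-"))
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      full_length = integer(0), insert_length = integer(0),
                      strand = character(0), amplicon = character(0),
                      insert = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Alignment conservation profile
#'
#' Per-column Shannon entropy over \{A, C, G, T\} frequencies (gap, missing,
#' and ambiguity characters are excluded from the column count), expressed
#' as percent of the 2-bit maximum, with a centered moving average. Fully
#' conserved columns are classed A/T vs G/C — the signal used to position
#' degenerate primers on conserved blocks.
#'
#' @param alignment Character vector of equal-length aligned sequences.
#' @param window Odd moving-average window (columns), default 11.
#' @return Data frame with columns \code{column}, \code{entropy} (bits),
#'   \code{percent_max}, \code{moving_avg}, \code{conserved}
#'   (\code{"AT"}, \code{"GC"} or \code{NA}).
#' @export
conservation_profile <- function(alignment, window = 11) {
  if (length(alignment) == 0) stop("empty alignment")
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  alignment <- normalize_seq(alignment)
  if (length(unique(nchar(alignment))) != 1)
    stop("sequences must have equal raw lengths")
  chars <- do.call(rbind, strsplit(alignment, ""))
  ncol_aln <- ncol(chars)
  ent <- numeric(ncol_aln)
  conserved <- rep(NA_character_, ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- chars[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0) { ent[j] <- NA; next }
    p <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    p <- p[p > 0]
    ent[j] <- -sum(p * log2(p))
    if (length(p) == 1)
      conserved[j] <- if (names(p) %in% c("A", "T")) "AT" else "GC"
  }
  pct <- 100 * ent / 2
  half <- (window - 1) / 2
  mov <- vapply(seq_len(ncol_aln), function(j) {
    lo <- max(1, j - half)
    hi <- min(ncol_aln, j + half)
    mean(pct[lo:hi], na.rm = TRUE)
  }, numeric(1))
  data.frame(column = seq_len(ncol_aln), entropy = ent, percent_max = pct,
             moving_avg = mov, conserved = conserved,
             stringsAsFactors = FALSE)
}

#' Informational melting temperature
#'
#' Wallace-rule estimate (2 degrees per A/T, 4 per G/C, fractional over
#' ambiguity sets). Provided for orientation only; not a validated
#' thermodynamic model.
#'
#' @param p A \code{degenerate_primer} or IUPAC string.
#' @return Temperature in degrees Celsius.
#' @export
primer_tm_wallace <- function(p) {
  ch <- .primer_chars(p)
  gc <- vapply(.iupac[ch], function(s) mean(s %in% c("G", "C")), numeric(1))
  sum(4 * gc + 2 * (1 - gc))
}
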