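## Synthetic-fixture generator: taxonomy-structured reference databases
## built by copy-with-substitution down the rank hierarchy, and amplicon
## read sets with sample indexes, substitution errors, chimeras and
## off-target contaminants. Every draw is seeded, and the manifest records
## what was planted so downstream stages can be checked against ground
## truth (realized divergences, not nominal ones - substitutions can
## collide).

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

# k substitutions at distinct positions within [from, to]; each new base
# differs from the current one
.mutate <- function(seq, k, from = 1, to = nchar(seq)) {
  if (k == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(from:to, min(k, to - from + 1))
  for (p in pos) ch[p] <- sample(setdiff(.BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: the clade hierarchy and the
#' per-rank divergence plan of the reference database, the amplicon
#' geometry, and the read-generation parameters.
#'
#' The divergence plan gives, per rank, the substitution count applied to
#' the 375-bp metabarcode window when a new clade of that rank is born
#' from its parent sequence (flanks receive a proportional share).
#' Divergences must strictly increase with rank height so identity bands
#' stay separable.
#'
#' @param seed RNG seed; every downstream draw derives from it.
#' @param n_domains,phyla_per_domain,classes_per_phylum,orders_per_class,suborders_per_order,families_per_suborder,species_per_family
#'   Clade hierarchy shape (defaults 2, 2, 2, 1, 2, 2, 3).
#' @param divergence_plan Named numeric vector of per-rank substitution
#'   counts over the metabarcode (domain through species).
#' @param metabarcode_len Metabarcode window length (default 375 bp).
#' @param pad5,pad3 Flanking template lengths outside the window (defaults
#'   20 and 50, so the post-demultiplex read spans 445 bp and global
#'   trimming recovers exactly the metabarcode).
#' @param n_heterotrophs Prokaryote heterotroph records added from an
#'   independent random root (domain \code{"Bacteria"}, no phototroph
#'   phylum).
#' @param heterotroph_subs Substitutions between heterotroph haplotypes.
#' @param samples Sample names (default four, as in a small multi-site
#'   metabarcoding run).
#' @param reads_per_sample Reads drawn per sample (default 200).
#' @param community Optional samples x species proportion matrix; by
#'   default each sample gets 1/rank weights over its own seeded species
#'   permutation (few dominant species, long tail).
#' @param error_rate Per-base substitution error probability on the
#'   sequenced fragment (default 0.001, a polished-Illumina-like rate).
#' @param base_quality Constant Phred score assigned to simulated bases
#'   (default 35).
#' @param chimera_rate,contaminant_rate Fractions of reads replaced by
#'   two-parent chimeras / random off-target fragments (defaults 0).
#' @param index_len Sample-index length (default 8).
#' @param fwd_primer Forward primer sequence attached after the index.
#' @param read_len Length of each paired-end read (default 250).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_domains = 2, phyla_per_domain = 2,
                       classes_per_phylum = 2, orders_per_class = 1,
                       suborders_per_order = 2, families_per_suborder = 2,
                       species_per_family = 3,
                       divergence_plan = c(domain = 110, phylum = 80,
                                           class = 50, order = 35,
                                           suborder = 24, family = 14,
                                           species = 2),
                       metabarcode_len = 375, pad5 = 20, pad3 = 50,
                       n_heterotrophs = 0, heterotroph_subs = 30,
                       samples = c("FLA", "FLB", "JPA", "GMA"),
                       reads_per_sample = 200,
                       community = NULL,
                       error_rate = 0.001, base_quality = 35,
                       chimera_rate = 0, contaminant_rate = 0,
                       index_len = 8,
                       fwd_primer = "GCAGATGGTCCAATGCCWCAAAC",
                       read_len = 250) {
  plan <- divergence_plan[TAXONOMIC_RANKS]
  names(plan) <- TAXONOMIC_RANKS
  if (any(is.na(plan))) stop("divergence_plan must cover all ranks")
  if (any(diff(plan) >= 0))
    stop("divergence plan must strictly decrease from domain to species")
  structure(list(
    seed = seed, n_domains = n_domains, phyla_per_domain = phyla_per_domain,
    classes_per_phylum = classes_per_phylum,
    orders_per_class = orders_per_class,
    suborders_per_order = suborders_per_order,
    families_per_suborder = families_per_suborder,
    species_per_family = species_per_family,
    divergence_plan = plan,
    metabarcode_len = metabarcode_len, pad5 = pad5, pad3 = pad3,
    n_heterotrophs = n_heterotrophs, heterotroph_subs = heterotroph_subs,
    samples = samples, reads_per_sample = reads_per_sample,
    community = community,
    error_rate = error_rate, base_quality = base_quality,
    chimera_rate = chimera_rate, contaminant_rate = contaminant_rate,
    index_len = index_len, fwd_primer = fwd_primer, read_len = read_len),
    class = "sim_config")
}

#' Simulate a taxonomy-structured reference database
#'
#' Draws a random root template, then recursively copies it with the
#' planned per-rank substitution counts down the clade hierarchy. The
#' returned records hold the metabarcode window (shared coordinates, no
#' indels by default so Hamming equals Levenshtein on fixtures); the
#' manifest keeps the full-region sequences used for read simulation,
#' every record's true lineage, and a band-separation warning flag when
#' accumulated within-clade divergence could overlap the next rank's
#' band.
#'
#' @param cfg A [sim_config()].
#' @return List: \code{records} (reference database data frame),
#'   \code{manifest} (record table with full-region sequences + flags),
#'   \code{config}.
#' @export
simulate_reference_db <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  region_len <- cfg$pad5 + cfg$metabarcode_len + cfg$pad3
  win <- c(cfg$pad5 + 1, cfg$pad5 + cfg$metabarcode_len)
  flank_scale <- (region_len - cfg$metabarcode_len) / cfg$metabarcode_len
  mutate_rank <- function(seq, rank) {
    k_meta <- cfg$divergence_plan[[rank]]
    k_flank <- round(k_meta * flank_scale)
    seq <- .mutate(seq, k_meta, win[1], win[2])
    if (k_flank > 0 && cfg$pad5 > 0)
      seq <- .mutate(seq, round(k_flank * cfg$pad5 /
                                  (region_len - cfg$metabarcode_len)),
                     1, cfg$pad5)
    if (k_flank > 0 && cfg$pad3 > 0)
      seq <- .mutate(seq, k_flank - round(k_flank * cfg$pad5 /
                                            (region_len - cfg$metabarcode_len)),
                     win[2] + 1, region_len)
    seq
  }
  root <- .random_seq(region_len)
  rows <- list()
  clade_counter <- setNames(integer(length(TAXONOMIC_RANKS)),
                            TAXONOMIC_RANKS)
  recurse <- function(seq, lin, level) {
    rank <- TAXONOMIC_RANKS[level]
    n_children <- switch(rank,
      domain = cfg$n_domains, phylum = cfg$phyla_per_domain,
      class = cfg$classes_per_phylum, order = cfg$orders_per_class,
      suborder = cfg$suborders_per_order,
      family = cfg$families_per_suborder, species = cfg$species_per_family)
    for (i in seq_len(n_children)) {
      child_seq <- mutate_rank(seq, rank)
      clade_counter[rank] <<- clade_counter[rank] + 1L
      label <- if (rank == "species") {
        sprintf("sp%03d", clade_counter[rank])
      } else if (rank == "domain") {
        c("Eukaryota", "Cyanobacteria", paste0("Dom", 3:10))[i]
      } else {
        # globally unique per clade: e.g. phy1, cla3, fam12
        sprintf("%s%d", substr(rank, 1, 3), clade_counter[rank])
      }
      child_lin <- c(lin, label)
      if (rank == "species") {
        rows[[length(rows) + 1L]] <<- data.frame(
          id = sprintf("ref%03d", length(rows) + 1L),
          full_seq = child_seq,
          t(setNames(child_lin, TAXONOMIC_RANKS)),
          stringsAsFactors = FALSE)
      } else {
        recurse(child_seq, child_lin, level + 1)
      }
    }
  }
  recurse(root, character(0), 1)
  man <- do.call(rbind, rows)
  # heterotrophs: independent root, prokaryote domain, no phototroph phylum
  if (cfg$n_heterotrophs > 0) {
    hroot <- .random_seq(region_len)
    het <- do.call(rbind, lapply(seq_len(cfg$n_heterotrophs), function(i) {
      data.frame(id = sprintf("het%03d", i),
                 full_seq = .mutate(hroot, cfg$heterotroph_subs,
                                    win[1], win[2]),
                 t(setNames(lineage("Bacteria"), TAXONOMIC_RANKS)),
                 stringsAsFactors = FALSE)
    }))
    man <- rbind(man, het)
  }
  man$phototroph <- !startsWith(man$id, "het")
  man$metabarcode <- substr(man$full_seq, win[1], win[2])
  # species/family band separation: conspecific leaves spread by up to
  # 2*species subs, sibling families sit >= 2*family - 2*species subs
  # apart, so the bands collide when 2*species >= family. Higher-rank
  # bands are allowed to overlap - real rank divergences do.
  plan <- cfg$divergence_plan
  band_warning <- 2 * plan[["species"]] >= plan[["family"]]
  records <- make_ref_db(man$id, man$metabarcode,
                         man[TAXONOMIC_RANKS], man$phototroph)
  list(records = records,
       manifest = list(records = man, plan = plan,
                       band_warning = band_warning,
                       metabarcode_window = win, region_len = region_len),
       config = cfg)
}

# default community: per-sample 1/rank weights over a seeded permutation
.default_community <- function(n_species, samples) {
  t(vapply(samples, function(s) {
    w <- 1 / seq_len(n_species)
    w[sample.int(n_species)] / sum(w)
  }, numeric(n_species)))
}

#' Simulate paired-end amplicon reads
#'
#' Draws species per sample from the community multinomial, builds each
#' fragment as index + forward primer (degenerate positions realized at
#' random) + full template region, applies per-base substitution errors,
#' and splits the fragment into overlapping paired reads with constant
#' qualities. Chimeric reads splice two parent templates at a random
#' crossover; contaminant reads are uniform-random off-target fragments.
#' Every event is logged in the truth table.
#'
#' @param sim Output of [simulate_reference_db()].
#' @param cfg Configuration; defaults to the one inside \code{sim}.
#' @return List: \code{pairs} ([read_pairs()] data frame),
#'   \code{index_table} (named sample -> index), \code{truth} (data frame
#'   id, sample, species, type, n_errors), \code{community} (the
#'   proportion matrix actually used).
#' @export
simulate_reads <- function(sim, cfg = sim$config) {
  set.seed(cfg$seed + 1L)
  man <- sim$manifest$records
  photo <- man[man$phototroph, , drop = FALSE]
  n_sp <- nrow(photo)
  comm <- cfg$community
  if (is.null(comm)) comm <- .default_community(n_sp, cfg$samples)
  if (is.null(rownames(comm))) rownames(comm) <- cfg$samples
  # distinct sample indexes
  repeat {
    idx <- vapply(seq_along(cfg$samples), function(i)
      .random_seq(cfg$index_len), character(1))
    if (!anyDuplicated(idx)) break
  }
  index_table <- setNames(idx, cfg$samples)
  primer_concrete <- function() {
    paste(vapply(strsplit(cfg$fwd_primer, "")[[1]],
                 function(b) sample(.iupac[[b]], 1), character(1)),
          collapse = "")
  }
  region_len <- sim$manifest$region_len
  rows <- truth <- list()
  rid <- 0L
  for (s in cfg$samples) {
    for (r in seq_len(cfg$reads_per_sample)) {
      rid <- rid + 1L
      u <- stats::runif(1)
      if (u < cfg$contaminant_rate) {
        type <- "contaminant"; species <- NA_character_
        region <- .random_seq(region_len)
      } else if (u < cfg$contaminant_rate + cfg$chimera_rate && n_sp >= 2) {
        type <- "chimera"
        par <- sample.int(n_sp, 2)
        cross <- sample(50:(region_len - 50), 1)
        region <- paste0(substr(photo$full_seq[par[1]], 1, cross),
                         substr(photo$full_seq[par[2]], cross + 1,
                                region_len))
        species <- paste(photo$species[par], collapse = "+")
      } else {
        type <- "normal"
        sp <- sample.int(n_sp, 1, prob = comm[s, ])
        region <- photo$full_seq[sp]
        species <- photo$species[sp]
      }
      frag <- paste0(index_table[[s]], primer_concrete(), region)
      n_err <- stats::rbinom(1, nchar(frag), cfg$error_rate)
      if (n_err > 0) frag <- .mutate(frag, n_err)
      L <- nchar(frag)
      q <- strrep(intToUtf8(cfg$base_quality + 33L), cfg$read_len)
      rows[[rid]] <- data.frame(
        id = sprintf("read%05d", rid),
        seq1 = substr(frag, 1, cfg$read_len), qual1 = q,
        seq2 = revcomp(substr(frag, L - cfg$read_len + 1, L)), qual2 = q,
        stringsAsFactors = FALSE)
      truth[[rid]] <- data.frame(id = sprintf("read%05d", rid), sample = s,
                                 species = species, type = type,
                                 n_errors = n_err, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  class(pairs) <- c("read_pairs", "data.frame")
  list(pairs = pairs, index_table = index_table,
       truth = do.call(rbind, truth), community = comm)
}
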