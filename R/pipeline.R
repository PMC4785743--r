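## Orchestration of the two workflows: the metabarcoding run
## (merge -> demultiplex -> filter -> trim -> dereplicate -> denoise ->
## chimera/contaminant screens -> dual clustering -> core consensus ->
## mapping) and the threshold calibration run.

#' Default metabarcoding stage parameters
#'
#' The stage defaults of the standard run: 97 percent global clustering,
#' local clustering at d = 10, expected-error cutoff 0.5, size window
#' 400-440 bp, 20/50 bp global crops, minimum amplicon abundance 4, and
#' abundance-cell floor 3.
#'
#' @return Named list of parameters accepted by [run_metabarcoding()].
#' @export
metabarcoding_params <- function() {
  list(min_overlap = 16, max_mismatch_frac = 0.25,
       primer_mismatch = 1, max_expected_error = 0.5,
       min_len = 400, max_len = 440, crop5 = 20, crop3 = 50,
       min_total = 4, chimera_min_parent_gain = 3,
       chimera_min_identity = 99, decontam_min_identity = 60,
       decontam_min_coverage = 0.5, global_threshold = 97, d = 10,
       map_threshold = 97, cell_floor = 3)
}

#' Run the full metabarcoding workflow
#'
#' Executes the read-processing chain, the dual clustering with its
#' core-OTU consensus, and read mapping, assembling a stage-by-stage
#' ledger of remaining reads. Chimera and contaminant screens run only
#' when \code{references} are supplied.
#'
#' @param pairs A [read_pairs()] data frame.
#' @param index_table Named character vector sample -> index.
#' @param fwd_primer A [degenerate_primer()] (or IUPAC string, taken as
#'   forward).
#' @param references Optional reference database data frame for the
#'   chimera/contaminant screens.
#' @param params Stage parameters; see [metabarcoding_params()].
#' @return List of class \code{metabarcoding_run}: \code{otus} (core),
#'   \code{global_otus}, \code{local_otus}, \code{table}
#'   (\code{abundance_table}), \code{ledger}, \code{amplicons} (the
#'   clustered set), \code{reads} (mapped read set).
#' @export
run_metabarcoding <- function(pairs, index_table, fwd_primer,
                              references = NULL,
                              params = metabarcoding_params()) {
  p <- utils::modifyList(metabarcoding_params(), params)
  if (p$crop5 + p$crop3 >= p$min_len)
    stop("config validation: crop5 + crop3 must be smaller than min_len")
  if (is.character(fwd_primer))
    fwd_primer <- degenerate_primer("fwd", fwd_primer, "forward")
  stages <- "raw"
  remaining <- nrow(pairs)
  note <- function(stage, n) {
    stages <<- c(stages, stage)
    remaining <<- c(remaining, n)
  }
  if (nrow(pairs) == 0) {
    ledger <- pipeline_ledger("raw", 0L)
    return(structure(list(otus = NULL, table = NULL, ledger = ledger),
                     class = "metabarcoding_run"))
  }
  merged <- merge_pairs(pairs, p$min_overlap, p$max_mismatch_frac)
  note("merged", nrow(merged))
  demux <- demultiplex(merged, index_table, fwd_primer, p$primer_mismatch)
  note("demultiplexed", nrow(demux))
  filt <- quality_filter(demux, p$max_expected_error)
  note("quality_filtered", nrow(filt))
  trimmed <- size_filter_and_trim(filt, p$min_len, p$max_len,
                                  p$crop5, p$crop3)
  note("size_filtered_trimmed", nrow(trimmed))
  amps <- dereplicate(trimmed)
  den <- denoise_by_abundance(amps, p$min_total)
  note("denoised", sum(den$total))
  if (!is.null(references)) {
    chi <- chimera_screen(den, references, p$chimera_min_parent_gain,
                          p$chimera_min_identity)
    den <- chi$clean
    note("chimera_screened", sum(den$total))
    dec <- decontaminate(den, references, p$decontam_min_identity,
                         p$decontam_min_coverage)
    den <- dec$on_target
    note("decontaminated", sum(den$total))
  }
  glob <- cluster_global(den, p$global_threshold)
  loc <- cluster_local(den, p$d)
  core <- core_consensus(glob, loc)
  tab <- map_reads(trimmed, core, p$map_threshold, p$cell_floor)
  structure(list(otus = core, global_otus = glob, local_otus = loc,
                 table = tab,
                 ledger = pipeline_ledger(stages, as.integer(remaining)),
                 amplicons = den, reads = trimmed, params = p),
            class = "metabarcoding_run")
}

#' @export
print.metabarcoding_run <- function(x, ...) {
  cat("<metabarcoding_run>\n")
  if (!is.null(x$ledger)) print(x$ledger)
  if (!is.null(x$otus))
    cat(sprintf("core OTUs: %d (global %d, local %d)\n",
                length(x$otus$centroid), length(x$global_otus$centroid),
                length(x$local_otus$centroid)))
  invisible(x)
}

#' Run the threshold-calibration workflow
#'
#' Applies the end-missing exclusion to an annotated reference alignment,
#' computes intra/inter-clade divergences and both threshold families per
#' rank, and summarizes leave-one-out best-hit performance.
#'
#' @param records Reference database data frame (aligned sequences).
#' @param high_ranks,low_ranks,subset_rank,subset_label,max_end_missing
#'   See [calibrate_thresholds()].
#' @return List of class \code{calibration_run}: \code{thresholds} (a
#'   \code{threshold_set}), \code{divergences}, \code{loo} (per-rank
#'   \code{relaxed_threshold} score tables), \code{excluded} (ids dropped
#'   by the end-missing rule).
#' @export
run_calibration <- function(records,
                            high_ranks = c("domain", "phylum", "class"),
                            low_ranks = c("order", "suborder", "family"),
                            subset_rank = NULL, subset_label = NULL,
                            max_end_missing = 20) {
  idmat <- identity_matrix(records, max_end_missing = max_end_missing)
  th <- calibrate_thresholds(records, high_ranks, low_ranks,
                             subset_rank, subset_label, max_end_missing)
  structure(list(thresholds = th,
                 divergences = attr(th, "divergences"),
                 excluded = idmat$excluded),
            class = "calibration_run")
}

#' @export
print.calibration_run <- function(x, ...) {
  cat("<calibration_run>\n")
  print(as.data.frame(x$thresholds))
  if (length(x$excluded) > 0)
    cat("excluded (end-missing):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
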