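#' Quality-control policy for AS-qPCR result classification
#'
#' Bundles the thresholds that turn a raw Cq quartet into a reportable call.
#' The defaults are the validated operating point of the JAK2 V617F assay:
#' mutant-reaction signals at or beyond 42 cycles are treated as unspecific
#' amplification, the limit of detection is 0.15% mutant allele and the limit
#' of quantification 1.16%, and RNase P is expected below Cq 30 with the two
#' reactions of a pair within 1 cycle of each other.
#'
#' @param cq_cutoff Cq at or above which a mutant-reaction signal is treated
#'   as unspecific amplification (cycles; default 42).
#' @param total_cycles Number of cycles in the run; a reaction with no signal
#'   by this cycle is `undetermined` (default 45).
#' @param lod_percent Limit of detection, percent mutant allele (default 0.15).
#' @param loq_percent Limit of quantification, percent mutant allele
#'   (default 1.16). Results between `lod_percent` and `loq_percent` are
#'   reported as detected but not quantifiable.
#' @param rp_delta_warn Warn when the two RNase P Cqs of a pair differ by more
#'   than this many cycles (default 1), indicating a pipetting imbalance.
#' @param rp_max_cq Warn when either RNase P Cq exceeds this value
#'   (default 30), indicating low or poor-quality template.
#'
#' @return An object of class `qc_policy` (a named list).
#' @examples
#' qc_policy()
#' qc_policy(cq_cutoff = 40)
#' @export
qc_policy <- function(cq_cutoff = 42, total_cycles = 45,
                      lod_percent = 0.15, loq_percent = 1.16,
                      rp_delta_warn = 1, rp_max_cq = 30) {
  stopifnot(
    is.numeric(cq_cutoff), cq_cutoff > 0,
    is.numeric(total_cycles), cq_cutoff <= total_cycles,
    is.numeric(lod_percent), lod_percent > 0,
    is.numeric(loq_percent), lod_percent <= loq_percent, loq_percent < 100,
    rp_delta_warn > 0, rp_max_cq > 0
  )
  structure(
    list(
      cq_cutoff = cq_cutoff, total_cycles = total_cycles,
      lod_percent = lod_percent, loq_percent = loq_percent,
      rp_delta_warn = rp_delta_warn, rp_max_cq = rp_max_cq
    ),
    class = "qc_policy"
  )
}

#' @export
print.qc_policy <- function(x, ...) {
  cat("<qc_policy>\n")
  cat(sprintf("  Cq cutoff: %g (run length %g cycles)\n", x$cq_cutoff, x$total_cycles))
  cat(sprintf("  LOD: %g%%  LOQ: %g%% mutant allele\n", x$lod_percent, x$loq_percent))
  cat(sprintf("  RNase P QC: |delta Cq| <= %g, Cq <= %g\n", x$rp_delta_warn, x$rp_max_cq))
  invisible(x)
}

#' Constants for converting template copies to DNA concentration
#'
#' A single-copy reference target (RNase P) counts haploid genome equivalents,
#' so copies convert to mass via the haploid genome weight, halved because the
#' quantified standard is single-stranded while genomic DNA is double-stranded,
#' and to concentration via the reaction input volume.
#'
#' @param haploid_genome_ng Mass of one human haploid genome in ng
#'   (default 0.0033).
#' @param ds_correction Divisor correcting an ssDNA-calibrated copy count to
#'   dsDNA genomes (default 2).
#' @param reaction_input_volume DNA volume added per reaction in microlitres
#'   (default 5).
#' @return An object of class `genome_constants` (a named list).
#' @examples
#' dna_concentration_from_copies(1000, genome_constants())
#' @export
genome_constants <- function(haploid_genome_ng = 0.0033, ds_correction = 2,
                             reaction_input_volume = 5) {
  stopifnot(haploid_genome_ng > 0, ds_correction > 0, reaction_input_volume > 0)
  structure(
    list(
      haploid_genome_ng = haploid_genome_ng,
      ds_correction = ds_correction,
      reaction_input_volume = reaction_input_volume
    ),
    class = "genome_constants"
  )
}

# Internal: TRUE where a Cq is the `undetermined` sentinel (Inf). NA stays NA.
is_undetermined <- function(cq) is.infinite(cq) & cq > 0
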