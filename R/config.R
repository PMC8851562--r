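#' Analysis configuration
#'
#' Bundles every tunable threshold of the analysis layers with its default.
#' All window sizes are in base pairs.
#'
#' @slot min_total_count peaks with fewer raw counts summed over all samples
#'   are removed before ranking (default 10).
#' @slot bin_size target number of peaks per rank bin (default 1000).
#' @slot top_n size of the top loss / gain peak selections (default 1000).
#' @slot promoter_upstream,promoter_downstream promoter window around the TSS
#'   on the gene strand (defaults 1000 / 100).
#' @slot tts_window half-width of the transcription-termination-site window
#'   (default 100).
#' @slot de_alpha adjusted-p cutoff for calling a gene differentially
#'   expressed (default 0.05).
#' @slot lfc_threshold absolute log2-fold-change gate on top of `de_alpha`
#'   (default 0: significance alone decides).
#' @slot motif_similarity_threshold PWM similarity above which same-family
#'   motifs are merged (default 0.90).
#' @slot pwm_score_fraction fraction of a PWM's maximum log-odds score
#'   required to call a hit (default 0.80).
#' @slot enrich_min,change_min motif-landscape filters: minimum -log10 p
#'   reached in at least one bin (default 3) and minimum -log10 p range
#'   across bins (default 1).
#' @slot footprint_window half-width of the footprint window (default 100).
#' @slot footprint_flank flank width per side used for the protection
#'   baseline; the outer 25% of the window (default 25).
#' @slot rpkm_loss_flag mean RPKM loss at which a binding-site peak is
#'   flagged as a large loss (default 10).
#' @slot rng_seed seed for any randomized step (bootstraps).
#' @export
setClass("AnalysisConfig", representation(
  min_total_count = "numeric", bin_size = "numeric", top_n = "numeric",
  promoter_upstream = "numeric", promoter_downstream = "numeric",
  tts_window = "numeric", de_alpha = "numeric", lfc_threshold = "numeric",
  motif_similarity_threshold = "numeric", pwm_score_fraction = "numeric",
  enrich_min = "numeric", change_min = "numeric",
  footprint_window = "numeric", footprint_flank = "numeric",
  rpkm_loss_flag = "numeric", rng_seed = "numeric"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  pos <- c("min_total_count", "bin_size", "top_n", "promoter_upstream",
           "promoter_downstream", "tts_window", "footprint_window",
           "footprint_flank", "rpkm_loss_flag")
  for (s in pos)
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  if (object@bin_size < 1) msg <- c(msg, "bin_size must be >= 1")
  if (object@de_alpha <= 0 || object@de_alpha >= 1)
    msg <- c(msg, "de_alpha must lie in (0, 1)")
  if (object@motif_similarity_threshold <= 0 ||
      object@motif_similarity_threshold > 1)
    msg <- c(msg, "motif_similarity_threshold must lie in (0, 1]")
  if (object@pwm_score_fraction <= 0 || object@pwm_score_fraction > 1)
    msg <- c(msg, "pwm_score_fraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn AnalysisConfig Constructor with package defaults; any slot can
#'   be overridden by name.
#' @param ... named overrides for the slots documented above.
#' @return A validated `AnalysisConfig`.
#' @examples
#' cfg <- analysisConfig(bin_size = 500)
#' @export
analysisConfig <- function(...) {
  defaults <- list(
    min_total_count = 10, bin_size = 1000, top_n = 1000,
    promoter_upstream = 1000, promoter_downstream = 100, tts_window = 100,
    de_alpha = 0.05, lfc_threshold = 0,
    motif_similarity_threshold = 0.90, pwm_score_fraction = 0.80,
    enrich_min = 3, change_min = 1,
    footprint_window = 100, footprint_flank = 25,
    rpkm_loss_flag = 10, rng_seed = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) .stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  do.call(new, c(list("AnalysisConfig"), defaults))
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-27s %g\n", s, slot(object, s)))
})
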