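#' Population CNVR detection from normalized profiles
#'
#' Convenience wrapper chaining matrix assembly, individual candidate
#' flagging, population window selection, the adjacent-window correlation
#' criterion, initial region definition and correlated-region merging.
#'
#' @param profiles List of normalized `sample_profile`s.
#' @param grid The shared `window_grid`.
#' @param mode `"outbred"` or `"selfbred"` candidate thresholds.
#' @param min_af,min_hom,keep_all_het Passed to
#'   [select_population_windows()].
#' @param correlation Apply the adjacent-window correlation criterion
#'   (default TRUE; needs >= 4 samples).
#' @param min_run Minimum region span in windows (default 5).
#' @param max_gap_frac,p_threshold Passed to [merge_adjacent_cnvrs()].
#' @return List with the `population_matrix` (`pm`) and the merged
#'   `cnvr_set` (`cnvrs`).
#' @export
detect_cnvrs <- function(profiles, grid, mode = "outbred", min_af = 0.05,
                         min_hom = 2L, keep_all_het = FALSE,
                         correlation = TRUE, min_run = 5L,
                         max_gap_frac = 0.2, p_threshold = 0.01) {
  pm <- assemble_matrix(profiles, grid)
  pm <- flag_individual_candidates(pm, mode)
  pm <- select_population_windows(pm, min_af = min_af, min_hom = min_hom,
                                  keep_all_het = keep_all_het)
  if (correlation) pm <- apply_correlation_criterion(pm, p_threshold)
  cnvrs <- define_cnvrs(pm, min_run = min_run)
  cnvrs <- merge_adjacent_cnvrs(cnvrs, pm, max_gap_frac, p_threshold)
  list(pm = pm, cnvrs = cnvrs)
}
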