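#' Run the band-resolved network pipeline on a cohort
#'
#' Convenience driver covering the full individual-to-group chain for a set
#' of frequency bands: per subject, Welch coherence spectra are band-averaged
#' and thresholded at sparsity S; per band, individual networks are averaged
#' into the consistent edge matrix Ce, the group network A^g is thresholded
#' from Ce, subject-level Louvain partitions are combined into the consistent
#' assignment matrix Ca, and the group partition is detected on Ca.
#'
#' @param panels list of [ts_panel()] objects.
#' @param bands named list of [band()] objects.
#' @param S sparsity for individual and group thresholding.
#' @param settings [spectral_settings()].
#' @param n_restarts Louvain restarts.
#' @param seed RNG seed (community detection).
#' @return list of class `band_pipeline`, one element per band, each with
#'   `band`, `adjacencies` (per subject), `subject_partitions`, `ce`, `ag`
#'   (with `connected` flag), `ca`, `group_partition`.
#' @export
run_band_pipeline <- function(panels, bands, S = 0.25,
                              settings = spectral_settings(),
                              n_restarts = 100L, seed = 1L) {
  spectra <- lapply(panels, coherence_spectrum, settings = settings)
  out <- lapply(seq_along(bands), function(bi) {
    bd <- bands[[bi]]
    adjs <- lapply(spectra, function(sp) sparsity_threshold(band_average(sp, bd), S))
    parts <- lapply(seq_along(adjs), function(i) {
      louvain_partition(adjs[[i]], n_restarts = n_restarts,
                        seed = seed + 97L * i)
    })
    ce <- consistency_matrix(adjs)
    ag <- group_network(ce, S)
    cons <- consensus_assignment(parts, n_restarts = n_restarts,
                                 seed = seed + 13L * bi)
    list(band = bd, adjacencies = adjs, subject_partitions = parts,
         ce = ce, ag = ag, ca = cons$ca, group_partition = cons$partition)
  })
  names(out) <- names(bands)
  structure(out, class = "band_pipeline")
}

#' Subject-level modularity and efficiency over a sparsity grid
#'
#' Computes, for every subject, band and sparsity threshold, the modularity
#' of the subject's Louvain partition and the global efficiency of the
#' thresholded network — the inputs of [compare_bands()].
#'
#' @param panels list of [ts_panel()] objects.
#' @param bands named list of [band()] objects.
#' @param s_grid sparsity thresholds (default 0.05 to 0.25 in 0.05 steps).
#' @param settings [spectral_settings()].
#' @param n_restarts Louvain restarts per cell.
#' @param seed RNG seed.
#' @return long data.frame with columns `subject`, `band`, `sparsity`,
#'   `metric` (`"modularity"` or `"efficiency"`), `value`.
#' @export
subject_metrics <- function(panels, bands, s_grid = seq(0.05, 0.25, by = 0.05),
                            settings = spectral_settings(),
                            n_restarts = 20L, seed = 1L) {
  rows <- list()
  for (si in seq_along(panels)) {
    sp <- coherence_spectrum(panels[[si]], settings = settings)
    sid <- panels[[si]]$subject_id
    for (bi in seq_along(bands)) {
      cm <- band_average(sp, bands[[bi]])
      for (S in s_grid) {
        adj <- sparsity_threshold(cm, S)
        part <- louvain_partition(adj, n_restarts = n_restarts,
                                  seed = seed + 1000L * si + bi)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sid, band = names(bands)[[bi]], sparsity = S,
          metric = c("modularity", "efficiency"),
          value = c(modularity_q(adj, part), global_efficiency(adj)$value))
      }
    }
  }
  do.call(rbind, rows)
}
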