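#' Reconstruct a volume end to end
#'
#' Convenience pipeline: [trace_neuron()] from the given seeds, then
#' [merge_redundant_paths()] and [prune_short_branches()].
#'
#' @inheritParams trace_neuron
#' @param merge apply redundant-path merging (default TRUE).
#' @param prune_abs,prune_rel short-branch pruning thresholds (voxels /
#'   multiples of the bifurcation radius); set both to 0 to disable.
#' @return A [neuron_tree()].
#' @export
reconstruct <- function(vol, seeds, cfg = tracer_config(),
                        detector = boundary_detector(), merge = TRUE,
                        prune_abs = 5, prune_rel = 2) {
  tree <- trace_neuron(vol, seeds, cfg, detector)
  if (merge) tree <- merge_redundant_paths(tree)
  if (prune_abs > 0 || prune_rel > 0)
    tree <- prune_short_branches(tree, prune_abs, prune_rel)
  tree
}

#' Trace a phantom from its root and score against ground truth
#'
#' Seeds the tracer at the phantom's true root, reconstructs, and runs
#' [compare_to_reference()] against the ground-truth SWC.
#'
#' @param ph a [phantom_tree()] / [phantom_tube()] result.
#' @inheritParams reconstruct
#' @return One-row tibble: the comparison report plus `n_nodes` and
#'   `elapsed` (seconds).
#' @export
trace_phantom <- function(ph, cfg = tracer_config(),
                          detector = boundary_detector(), merge = TRUE,
                          prune_abs = 5, prune_rel = 2) {
  t0 <- proc.time()[["elapsed"]]
  tree <- reconstruct(ph$volume, ph$truth$root, cfg, detector, merge,
                      prune_abs, prune_rel)
  rep <- compare_to_reference(tree, ph$truth$swc)
  rep$n_nodes <- nrow(tree)
  rep$elapsed <- proc.time()[["elapsed"]] - t0
  rep
}

#' Sampling-distance sweep on a phantom
#'
#' Traces the same phantom with a range of 3D sampling distances and
#' reports the length and bifurcation proportions for each, mirroring the
#' parameter-selection experiment: too small a sampling distance loses
#' branches, too large creates redundancy, and both proportions peak at an
#' intermediate value.
#'
#' @param ph a phantom.
#' @param distances sampling distances, in multiples of the local radius
#'   (default `seq(1.5, 4.5, 0.5)`).
#' @inheritParams reconstruct
#' @return tibble with one row per sampling distance, of class
#'   `rayburst_sweep`.
#' @export
sweep_sampling_distance <- function(ph, distances = seq(1.5, 4.5, by = 0.5),
                                    cfg = tracer_config(),
                                    detector = boundary_detector()) {
  rows <- lapply(distances, function(sd_i) {
    cfg_i <- cfg
    cfg_i$sampling_distance <- sd_i
    cfg_i$location_distance <- min(cfg$location_distance, sd_i)
    rep <- trace_phantom(ph, cfg_i, detector)
    dplyr::mutate(rep, sampling_distance = sd_i, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rayburst_sweep", class(out))
  out
}

#' Noise-robustness series on a phantom
#'
#' Adds Gaussian noise of increasing standard deviation (8-bit scale) to a
#' fixed phantom, traces each noisy volume with the same configuration,
#' and reports the score series. The correct-bifurcation count is expected
#' to degrade (never improve beyond jitter) as noise grows.
#'
#' @param ph a phantom.
#' @param sds noise standard deviations (default `seq(5, 30, 5)`).
#' @param noise_seed RNG seed for the noise fields.
#' @inheritParams reconstruct
#' @return tibble with one row per noise level, of class `rayburst_sweep`.
#' @export
noise_robustness <- function(ph, sds = seq(5, 30, by = 5), noise_seed = 1,
                             cfg = tracer_config(),
                             detector = boundary_detector()) {
  rows <- lapply(sds, function(s) {
    noisy <- list(volume = add_noise(ph$volume, s, seed = noise_seed),
                  truth = ph$truth)
    rep <- trace_phantom(noisy, cfg, detector)
    dplyr::mutate(rep, noise_sd = s, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rayburst_sweep", class(out))
  out
}
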