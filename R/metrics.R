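#' Compare a reconstruction to a reference tree
#'
#' Simplified node-matching evaluation of a test reconstruction against a
#' reference (gold-standard) tree. Nodes are matched greedily by mutual
#' proximity: candidate pairs within the match distance are taken in order
#' of increasing distance, each node matching at most once. With `G`
#' reference nodes, `T` test nodes, `M` unmatched reference nodes (misses)
#' and `E` unmatched test nodes (extras), the report gives
#' `recall = (G - M) / G` and `precision = (T - E) / T`, the
#' length proportion (path length of the test tree restricted to segments
#' whose endpoints both matched, divided by the total reference path
#' length), and the bifurcation proportion (reference bifurcations with a
#' matched test bifurcation within the match distance, divided by the
#' reference bifurcation count; 1 when the reference has none).
#'
#' This matcher is a simplified stand-in for the full topology-aware
#' DIADEM metric program; scores are comparable in spirit, not in value.
#'
#' @param test,ref non-empty [neuron_tree()] objects.
#' @param match_distance matching radius in voxels; the default is twice
#'   the local reference radius with a floor of 2 voxels.
#' @return One-row tibble with columns `G`, `T`, `M`, `E`, `recall`,
#'   `precision`, `length_proportion`, `bifurcation_proportion`,
#'   `ref_bifurcations`, `matched_bifurcations`.
#' @export
compare_to_reference <- function(test, ref, match_distance = NULL) {
  stopifnot(inherits(test, "neuron_tree"), inherits(ref, "neuron_tree"))
  if (nrow(test) == 0L || nrow(ref) == 0L)
    stop("both trees must be non-empty", call. = FALSE)
  Pt <- cbind(test$x, test$y, test$z)
  Pr <- cbind(ref$x, ref$y, ref$z)
  thr <- if (is.null(match_distance)) pmax(2 * ref$radius, 2)
         else rep(match_distance, nrow(ref))
  match_t <- greedy_match(Pt, Pr, thr)
  G <- nrow(ref); Tn <- nrow(test)
  M <- sum(!(seq_len(G) %in% match_t))
  E <- sum(is.na(match_t))
  # test path length restricted to segments with both endpoints matched
  pos <- match(test$parent, test$id)
  has_par <- which(!is.na(pos))
  both <- has_par[!is.na(match_t[has_par]) & !is.na(match_t[pos[has_par]])]
  matched_len <- sum(sqrt(rowSums(
    (Pt[both, , drop = FALSE] - Pt[pos[both], , drop = FALSE])^2)))
  ref_len <- total_path_length(ref)
  # bifurcation matching
  bt <- which(child_counts(test) >= 2L)
  br <- which(child_counts(ref) >= 2L)
  if (length(br) == 0L) {
    matched_bif <- 0L
    bif_prop <- 1
  } else if (length(bt) == 0L) {
    matched_bif <- 0L
    bif_prop <- 0
  } else {
    mb <- greedy_match(Pt[bt, , drop = FALSE], Pr[br, , drop = FALSE],
                       thr[br])
    matched_bif <- sum(!is.na(mb))
    bif_prop <- matched_bif / length(br)
  }
  tibble::tibble(
    G = G, T = Tn, M = M, E = E,
    recall = (G - M) / G,
    precision = (Tn - E) / Tn,
    length_proportion = if (ref_len > 0) matched_len / ref_len else NA_real_,
    bifurcation_proportion = bif_prop,
    ref_bifurcations = length(br),
    matched_bifurcations = as.integer(matched_bif))
}

# Greedy minimum-distance matching of test points to reference points.
# thr is per-reference-point acceptance distance. Returns, for each test
# point, the index of its matched reference point or NA.
greedy_match <- function(Pt, Pr, thr) {
  nt <- nrow(Pt); nr <- nrow(Pr)
  D <- outer(rowSums(Pt^2), rep(1, nr)) +
       outer(rep(1, nt), rowSums(Pr^2)) - 2 * Pt %*% t(Pr)
  D[D < 0] <- 0
  D <- sqrt(D)
  ok <- D <= matrix(thr, nt, nr, byrow = TRUE)
  cand <- which(ok, arr.ind = TRUE)
  match_t <- rep(NA_integer_, nt)
  if (nrow(cand) == 0L) return(match_t)
  cand <- cand[order(D[cand]), , drop = FALSE]
  used_r <- logical(nr)
  used_t <- logical(nt)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_t[i] || used_r[j]) next
    used_t[i] <- TRUE; used_r[j] <- TRUE
    match_t[i] <- j
  }
  match_t
}
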