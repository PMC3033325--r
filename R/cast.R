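#' Binarize a mutual-information matrix
#'
#' Dependences at or above the threshold `t_mi` become similarity 1, the rest
#' 0; the diagonal is 1 by convention. This binary similarity is the input
#' expected by the CAST clique-partitioning heuristic.
#'
#' @param mi symmetric MI matrix (bits), as from [pairwise_mi_matrix()].
#' @param t_mi non-negative threshold, typically a quantile of `mi` from
#'   [mi_quantile_threshold()].
#' @return A symmetric 0/1 integer matrix with unit diagonal.
#' @export
binarize_similarity <- function(mi, t_mi) {
  if (!is.numeric(t_mi) || length(t_mi) != 1L || is.na(t_mi) || t_mi < 0) {
    abort("t_mi must be a single non-negative number")
  }
  sim <- (mi >= t_mi) * 1L
  diag(sim) <- 1L
  storage.mode(sim) <- "integer"
  sim
}

#' Partition variables with the CAST heuristic
#'
#' Clusters are grown one at a time from a binary similarity graph. The
#' affinity `a(x)` of a variable is its number of similarity-1 links to the
#' members of the currently open cluster (self-links never count). The open
#' cluster alternates between adding the highest-affinity outside variable
#' with `a(x) >= t_cast * |C|` and removing the lowest-affinity member with
#' `a(x) < t_cast * (|C| - 1)`; when neither move applies the cluster is
#' closed and a new one is seeded from the unassigned variable of highest
#' remaining degree. All tie-breaks are by variable index, so the procedure
#' is deterministic. A variable with no similarity-1 neighbour among the
#' unassigned set is emitted directly as a singleton.
#'
#' @param sim symmetric 0/1 similarity matrix, e.g. from
#'   [binarize_similarity()].
#' @param t_cast affinity threshold in (0, 1\].
#' @return A list of character vectors (or integer vectors when `sim` has no
#'   dimnames): disjoint clusters covering every variable, in creation order.
#' @export
cast_partition <- function(sim, t_cast) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim) || nrow(sim) == 0L) {
    abort("sim must be a non-empty square matrix")
  }
  if (!is.numeric(t_cast) || length(t_cast) != 1L || is.na(t_cast) ||
      t_cast <= 0 || t_cast > 1) {
    abort("t_cast must lie in (0, 1]")
  }
  ids <- colnames(sim)
  if (is.null(ids)) ids <- seq_len(ncol(sim))
  m <- nrow(sim)
  unassigned <- rep(TRUE, m)
  clusters <- list()

  while (any(unassigned)) {
    u_idx <- which(unassigned)
    deg <- colSums(sim[u_idx, u_idx, drop = FALSE]) - 1L
    seed <- u_idx[which.max(deg)] # ties -> lowest index (which.max rule)
    if (max(deg) == 0L) {
      # no neighbour left: this and all remaining isolated nodes close alone
      clusters[[length(clusters) + 1L]] <- ids[seed]
      unassigned[seed] <- FALSE
      next
    }
    open <- seed
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 4L * m * m + 16L) break # pathological oscillation cutoff
      moved <- FALSE
      # add step: single highest-affinity eligible outsider, ties lowest index
      outside <- setdiff(which(unassigned), open)
      if (length(outside)) {
        aff <- colSums(sim[open, outside, drop = FALSE])
        eligible <- aff >= t_cast * length(open)
        if (any(eligible)) {
          cand <- outside[eligible]
          open <- c(open, cand[which.max(aff[eligible])])
          moved <- TRUE
        }
      }
      # remove step: drop lowest-affinity ineligible members one at a time,
      # ties -> highest index
      repeat {
        if (length(open) <= 1L) break
        aff_in <- colSums(sim[open, open, drop = FALSE]) - 1L
        bad <- aff_in < t_cast * (length(open) - 1L)
        if (!any(bad)) break
        worst <- min(aff_in[bad])
        drop_pos <- max(which(bad & aff_in == worst))
        open <- open[-drop_pos]
        moved <- TRUE
      }
      if (!moved) break
    }
    clusters[[length(clusters) + 1L]] <- ids[sort(open)]
    unassigned[open] <- FALSE
  }
  clusters
}
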