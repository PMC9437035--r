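# Minimum pairwise 3D distance (um) between two voxel index sets; 0 on overlap.
min_voxel_distance <- function(a, b, voxel_size) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  am <- as.matrix(a[, c("i_ap", "i_dv", "i_ml")])
  bm <- as.matrix(b[, c("i_ap", "i_dv", "i_ml")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
  sqrt(max(min(d2), 0)) * voxel_size
}

# Voxel sets of a receptor's assigned clusters, optionally one side only.
assigned_voxels <- function(pairs, receptor_id, side = NULL) {
  a <- pairs$assignments[[receptor_id]]
  if (is.null(a)) return(pairs$voxels[0, ])
  take <- if (is.null(side)) c("lateral", "medial") else side
  idx <- unlist(lapply(take, function(s) if (!is.null(a[[s]])) a[[s]]$voxels))
  pairs$voxels[idx, , drop = FALSE]
}

#' Evaluate glomerulus assignments against reference positions
#'
#' For each reference receptor, the assignment error is the minimum pairwise
#' 3D Euclidean distance (um) between the voxels of its assigned cluster(s)
#' and the reference voxel region, 0 when they overlap. A random baseline
#' repeats the measurement for `n_random` receptors drawn without
#' replacement from assigned receptors of the same DV zone (and side, when
#' the reference specifies one); a two-tailed Mann-Whitney U test compares
#' observed against baseline distances.
#'
#' @param pairs a `glom_pairs` object.
#' @param references data frame of reference voxel regions: columns
#'   `receptor_id`, `i_ap`, `i_dv`, `i_ml` and optionally `side` (one row
#'   per region voxel).
#' @param receptors receptor metadata with `id` and `oe_zone_index`
#'   (`dv_zone` is derived as dorsal when `oe_zone_index <= dorsal_cutoff`).
#' @param n_random baseline receptors per reference (default 50); when fewer
#'   are eligible, all are used with a warning.
#' @param dorsal_cutoff OE-zone threshold separating dorsal from ventral
#'   receptors (default 0.3).
#' @param seed RNG seed for the baseline draw.
#' @return Object of class `glom_eval`: list with `per_reference` (data
#'   frame: receptor_id, distance_um, n_baseline, baseline_median_um),
#'   `observed`, `baseline` distance vectors, `median_error_um`, and `mwu`
#'   (U, p).
#' @export
evaluate_assignments <- function(pairs, references, receptors, n_random = 50,
                                 dorsal_cutoff = 0.3, seed = 1) {
  stopifnot(inherits(pairs, "glom_pairs"))
  if (!all(c("receptor_id", "i_ap", "i_dv", "i_ml") %in% names(references))) {
    stopf("`references` needs receptor_id, i_ap, i_dv, i_ml columns")
  }
  zone <- ifelse(receptors$oe_zone_index <= dorsal_cutoff, "dorsal", "ventral")
  names(zone) <- receptors$id
  passed <- names(Filter(function(a) isTRUE(a$passed_filter), pairs$assignments))

  ref_ids <- unique(references$receptor_id)
  obs <- numeric(0); base <- numeric(0); rows <- list()
  with_seed(derive_seed(seed, "evaluation"), {
    for (id in ref_ids) {
      region <- references[references$receptor_id == id, , drop = FALSE]
      side <- if ("side" %in% names(region)) region$side[1] else NULL
      av <- assigned_voxels(pairs, id, side)
      if (nrow(av) == 0) next
      d <- min_voxel_distance(av, region, pairs$voxel_size)

      eligible <- setdiff(passed[zone[passed] == zone[id]], id)
      eligible <- eligible[!is.na(eligible)]
      if (length(eligible) < n_random) {
        warning(sprintf("reference %s: only %d eligible baseline receptors (requested %d)",
                        id, length(eligible), n_random))
        draw <- eligible
      } else {
        draw <- sample(eligible, n_random)
      }
      bd <- vapply(draw, function(rid) {
        bv <- assigned_voxels(pairs, rid, side)
        if (nrow(bv) == 0) return(NA_real_)
        min_voxel_distance(bv, region, pairs$voxel_size)
      }, numeric(1))
      bd <- bd[!is.na(bd)]
      obs <- c(obs, d); base <- c(base, bd)
      rows[[length(rows) + 1L]] <- data.frame(
        receptor_id = id, distance_um = d, n_baseline = length(bd),
        baseline_median_um = stats::median(bd), stringsAsFactors = FALSE)
    }
  })
  mwu <- if (length(obs) && length(base)) mwu_test(obs, base) else NULL
  structure(list(per_reference = if (length(rows)) do.call(rbind, rows) else NULL,
                 observed = obs, baseline = base,
                 median_error_um = if (length(obs)) stats::median(obs) else NA_real_,
                 mwu = mwu),
            class = "glom_eval")
}

#' @export
print.glom_eval <- function(x, ...) {
  cat(sprintf("Assignment evaluation: %d references, median error %.0f um\n",
              length(x$observed), x$median_error_um))
  if (!is.null(x$mwu)) {
    cat(sprintf("  observed vs baseline (median %.0f um): Mann-Whitney p = %.3g\n",
                stats::median(x$baseline), x$mwu$p))
  }
  invisible(x)
}

#' Between-model positional variance from replicate reconstructions
#'
#' Compares the best-probability voxel per assigned glomerulus between
#' models built from disjoint replicate subsets: for every receptor/side
#' assigned in both models, the 3D and per-axis distances between best
#' voxels, with medians across receptors.
#'
#' @param pairs_a,pairs_b `glom_pairs` objects from independently fitted
#'   models.
#' @return list with `per_receptor` (data frame of distances in um) and
#'   `median_um` (named: d3d, ap, dv, ml).
#' @export
replicate_variance <- function(pairs_a, pairs_b) {
  vs <- pairs_a$voxel_size
  rows <- list()
  for (id in intersect(names(pairs_a$assignments), names(pairs_b$assignments))) {
    for (side in c("lateral", "medial")) {
      ca <- pairs_a$assignments[[id]][[side]]
      cb <- pairs_b$assignments[[id]][[side]]
      if (is.null(ca) || is.null(cb)) next
      va <- pairs_a$voxels[ca$best_voxel, ]
      vb <- pairs_b$voxels[cb$best_voxel, ]
      dap <- abs(va$i_ap - vb$i_ap) * vs
      ddv <- abs(va$i_dv - vb$i_dv) * vs
      dml <- abs(va$i_ml - vb$i_ml) * vs
      rows[[length(rows) + 1L]] <- data.frame(
        receptor_id = id, side = side, ap = dap, dv = ddv, ml = dml,
        d3d = sqrt(dap^2 + ddv^2 + dml^2), stringsAsFactors = FALSE)
    }
  }
  per <- if (length(rows)) do.call(rbind, rows) else NULL
  med <- if (is.null(per)) c(d3d = NA_real_, ap = NA_real_, dv = NA_real_,
                             ml = NA_real_) else
    c(d3d = stats::median(per$d3d), ap = stats::median(per$ap),
      dv = stats::median(per$dv), ml = stats::median(per$ml))
  list(per_receptor = per, median_um = med)
}
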