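# Triangular (1,2,1)/4 smoothing with edge renormalization: replicate
# positional jitter splits a mode's mass across neighboring sections, and
# smoothing reassembles it so mode heights reflect integrals, not the
# accident of slab boundaries.
smooth_profile <- function(p) {
  n <- length(p)
  if (n < 3) return(p)
  num <- 2 * p + c(0, p[-n]) + c(p[-1], 0)
  den <- c(3, rep(4, n - 2), 3)
  num / den
}

# Anterior/posterior mode pair of a (possibly bimodal) 1D composition
# profile. The dominant mode is the profile argmax; a secondary mode on the
# other flank counts when, at least two sections away, the profile reaches
# `ratio` of the main peak (a genuine second component sits well above the
# within-animal smear tail at that distance).
profile_mode_pair <- function(p, ratio) {
  main <- which.max(p)
  ant <- main
  idx <- seq_len(max(main - 2L, 0L))
  if (length(idx) && max(p[idx]) >= ratio * p[main]) ant <- idx[which.max(p[idx])]
  post <- main
  idx <- if (main + 2L <= length(p)) (main + 2L):length(p) else integer(0)
  if (length(idx) && max(p[idx]) >= ratio * p[main]) post <- idx[which.max(p[idx])]
  c(anterior = ant, posterior = post)
}

# Sub-section position estimate: expression-weighted mean of the profile in
# a window around a mode, clipped to [lo, hi] (so the two modes of a
# bimodal profile each average only their own flank).
refine_mode <- function(p, mode, w = 2L, lo = 1L, hi = length(p)) {
  if (is.na(mode)) return(NA_real_)
  win <- max(lo, mode - w):min(hi, mode + w)
  sum(p[win] * win) / sum(p[win])
}

# Connected components (26-connectivity) among a set of shell voxels.
# `vox` is a data.frame with i_ap, i_dv, i_ml; returns an integer component
# label per row.
connected_components <- function(vox) {
  n <- nrow(vox)
  if (n == 0) return(integer(0))
  key <- paste(vox$i_ap, vox$i_dv, vox$i_ml)
  lookup <- stats::setNames(seq_len(n), key)
  comp <- integer(n)
  cur <- 0L
  off <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  off <- off[!(off$a == 0 & off$b == 0 & off$c == 0), ]
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb_keys <- paste(vox$i_ap[v] + off$a, vox$i_dv[v] + off$b,
                       vox$i_ml[v] + off$c)
      nb <- lookup[nb_keys]
      nb <- nb[!is.na(nb)]
      nb <- nb[comp[nb] == 0L]
      if (length(nb)) {
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Assign mirror-symmetric glomerulus pairs from the posterior field
#'
#' Scans, per receptor, for an anterolateral and a posteromedial glomerulus.
#' Voxels are scored by the corner statistic: the minimum across the three
#' axes of the receptor's per-section posterior median composition at the
#' voxel's slabs (a true glomerulus position is bright along all three
#' sectioning axes, whereas a voxel sharing only two true slab coordinates
#' is not). The receptor's anteroposterior composition profile is typically
#' bimodal - an anterior mode from the lateral glomerulus and a posterior
#' mode from its medial mirror partner - and its mediolateral profile has
#' one mode per hemisphere. The scan locates these axis modes (a secondary
#' AP mode counts when the profile reaches `peak_ratio` of the main peak at
#' least two sections away, above any within-animal smear tail), refines
#' each coordinate to sub-section precision by the expression-weighted mean
#' position in a one-section window around the mode, and assigns each
#' glomerulus to the shell voxel of its hemisphere nearest the target
#' coordinates: the lateral target pairs the anterior AP mode with the
#' lateral ML mode, the medial target the posterior AP mode with the medial
#' ML mode, constrained not to lie anterior to the lateral pick (a pair's
#' tomographic ghost shares the lateral AP slab, so anchoring each side to
#' its own AP mode resolves it). The dorsoventral coordinate is the refined
#' DV mode nearest `dv_mean`, searched within `dv_mean +/- dv_tolerance`.
#' A medial pick additionally requires a corner score of at least
#' `side_gate` of the lateral one, so receptors forming a single glomerulus
#' are not forced into a pair.
#'
#' Each pick is reported with its cluster: the 26-connected component of
#' high-median voxels (median field thresholded at the `quantile_threshold`
#' quantile of its nonzero values, within the DV band and hemisphere)
#' containing the pick. A receptor passes the expression filter when the
#' best cluster peak median reaches `tau`. All ties break deterministically
#' toward smaller AP, then DV, then ML index.
#'
#' When the field carries no per-axis compositions (e.g. hand-built median
#' fields), the median field itself is used as the score.
#'
#' @param field a `glom_field` from [project_to_voxels()].
#' @param scaffold the matching `glom_scaffold`.
#' @param dv_mean named per-receptor DV mean position in section units
#'   (typically from the merged DV axis matrix); `NA` disables the band for
#'   that receptor.
#' @param dv_tolerance half-width of the DV band in sections (default 3).
#' @param tau posterior-median expression filter (default 0.0005).
#' @param quantile_threshold upper quantile of a receptor's nonzero medians
#'   defining high-probability cluster voxels (default 0.99).
#' @param peak_ratio fraction of the profile maximum a secondary or
#'   hemisphere mode must reach to enter the scan (default 0.3).
#' @param side_gate minimum medial-to-lateral corner score ratio for
#'   assigning a medial partner (default 0.2).
#' @param axis_profiles optional named list (`AP`, `DV`, `ML`) of receptor x
#'   section matrices used as the scan profiles, typically the
#'   replicate-median merged normalized matrices (robust to a single
#'   replicate's positional jitter); the field's posterior axis medians are
#'   used for receptors or axes not covered.
#' @return Object of class `glom_pairs`: list with `assignments` (per
#'   receptor: lateral/medial cluster voxel indices, best voxel, peak
#'   median, `passed_filter`) and the configuration used.
#' @export
assign_glomeruli <- function(field, scaffold, dv_mean = NULL, dv_tolerance = 3,
                             tau = 5e-4, quantile_threshold = 0.99,
                             peak_ratio = 0.3, side_gate = 0.2,
                             axis_profiles = NULL) {
  vox <- field$voxels
  ids <- rownames(field$medians)
  res <- vector("list", length(ids))
  names(res) <- ids
  n_vox <- nrow(vox)
  lat_all <- which(vox$side == "lateral")
  med_all <- which(vox$side == "medial")

  for (r in seq_along(ids)) {
    med <- field$medians[r, ]
    nz <- med > 0
    entry <- list(lateral = NULL, medial = NULL, passed_filter = FALSE,
                  peak_median = if (any(nz)) max(med) else 0)
    if (!any(nz)) { res[[r]] <- entry; next }

    score <- if (!is.null(field$axis_medians)) {
      pmin(field$axis_medians$AP[r, vox$i_ap],
           field$axis_medians$DV[r, vox$i_dv],
           field$axis_medians$ML[r, vox$i_ml])
    } else med

    in_band <- rep(TRUE, n_vox)
    dv0 <- if (!is.null(dv_mean)) unname(dv_mean[ids[r]]) else NA_real_
    if (!is.na(dv0)) in_band <- abs(vox$i_dv - dv0) <= dv_tolerance

    thr <- stats::quantile(med[nz], quantile_threshold, names = FALSE)
    cand <- which(med >= thr & nz & in_band)

    cluster_of <- function(pick, side) {
      members <- cand[vox$side[cand] == side]
      members <- union(members, pick)
      sub <- vox[members, , drop = FALSE]
      comp <- connected_components(sub)
      keep <- members[comp == comp[match(pick, members)]]
      peaks <- med[keep]
      ord <- order(-peaks, vox$i_ap[keep], vox$i_dv[keep], vox$i_ml[keep])
      list(voxels = keep, best_voxel = keep[ord[1]], peak = peaks[ord[1]],
           pick_voxel = pick, score = score[pick])
    }

    if (!is.null(field$axis_medians)) {
      prof <- function(ax) {
        p <- axis_profiles[[ax]]
        raw <- if (!is.null(p) && ids[r] %in% rownames(p) &&
                   sum(p[ids[r], ]) > 0) p[ids[r], ] else
                     field$axis_medians[[ax]][r, ]
        smooth_profile(raw)
      }
      pa <- prof("AP")
      pd <- prof("DV")
      pm <- prof("ML")
      ap_pair <- profile_mode_pair(pa, peak_ratio)
      ml_mid <- max(vox$i_ml) / 2
      ml_lat_idx <- which(seq_along(pm) > ml_mid)
      ml_med_idx <- which(seq_along(pm) <= ml_mid)
      ml_lat <- if (length(ml_lat_idx) && max(pm[ml_lat_idx]) > 0) {
        ml_lat_idx[which.max(pm[ml_lat_idx])]
      } else NA_integer_
      ml_med <- if (length(ml_med_idx) && max(pm[ml_med_idx]) > 0) {
        ml_med_idx[which.max(pm[ml_med_idx])]
      } else NA_integer_
      dv_idx <- if (!is.na(dv0)) {
        which(abs(seq_along(pd) - dv0) <= dv_tolerance)
      } else seq_along(pd)
      dv_anchor <- if (length(dv_idx)) dv_idx[which.max(pd[dv_idx])] else which.max(pd)

      bimodal <- ap_pair[["anterior"]] != ap_pair[["posterior"]]
      ap_mid <- (ap_pair[["anterior"]] + ap_pair[["posterior"]]) / 2
      ml_cut <- ceiling(ml_mid)
      # DV target: the merged expression-weighted DV mean when available
      # (sub-section accurate), otherwise the refined DV profile mode
      dv_target <- if (!is.na(dv0)) dv0 else refine_mode(pd, dv_anchor)
      target_um <- function(ap_mode, ap_lo, ap_hi, ml_mode, ml_lo, ml_hi) {
        tgt <- c(refine_mode(pa, ap_mode, lo = ap_lo, hi = ap_hi),
                 dv_target,
                 refine_mode(pm, ml_mode, lo = ml_lo, hi = ml_hi))
        (tgt - 0.5) * scaffold$voxel_size
      }
      nearest_on <- function(side_idx, target, min_ap = -Inf) {
        if (anyNA(target)) return(NULL)
        sel <- side_idx[in_band[side_idx] & vox$i_ap[side_idx] >= min_ap]
        if (!length(sel)) return(NULL)
        d2 <- (vox$x_um[sel] - target[1])^2 + (vox$y_um[sel] - target[2])^2 +
          (vox$z_um[sel] - target[3])^2
        sel[order(d2, vox$i_ap[sel], vox$i_dv[sel], vox$i_ml[sel])][1]
      }
      lat_pick <- nearest_on(lat_all, target_um(
        ap_pair[["anterior"]], 1L,
        if (bimodal) floor(ap_mid) else length(pa), ml_lat, ml_cut,
        length(pm)))
      med_pick <- nearest_on(med_all, target_um(
        ap_pair[["posterior"]], if (bimodal) ceiling(ap_mid) else 1L,
        length(pa), ml_med, 1L, ml_cut - 1L),
        min_ap = if (!is.null(lat_pick)) vox$i_ap[lat_pick] else -Inf)
      if (!is.null(med_pick) && !is.null(lat_pick) &&
          score[med_pick] < side_gate * score[lat_pick]) {
        med_pick <- NULL
      }
    } else {
      # bare median field: argmax per hemisphere, medial not anterior to
      # lateral and gated against the lateral score
      pick_max <- function(side_idx, min_ap = -Inf, floor_score = 0) {
        sel <- side_idx[in_band[side_idx] & vox$i_ap[side_idx] >= min_ap]
        sel <- sel[med[sel] > 0]
        if (!length(sel)) return(NULL)
        mx <- max(score[sel])
        if (mx <= 0 || mx < floor_score) return(NULL)
        best <- sel[score[sel] == mx]
        best[order(vox$i_ap[best], vox$i_dv[best], vox$i_ml[best])][1]
      }
      lat_pick <- pick_max(lat_all)
      med_pick <- pick_max(med_all,
                           min_ap = if (!is.null(lat_pick))
                             vox$i_ap[lat_pick] else -Inf,
                           floor_score = if (!is.null(lat_pick))
                             side_gate * score[lat_pick] else 0)
    }
    lateral <- if (!is.null(lat_pick)) cluster_of(lat_pick, "lateral") else NULL
    medial <- if (!is.null(med_pick)) cluster_of(med_pick, "medial") else NULL

    peaks <- c(if (!is.null(lateral)) lateral$peak,
               if (!is.null(medial)) medial$peak)
    entry$lateral <- lateral
    entry$medial <- medial
    entry$peak_median <- if (length(peaks)) max(peaks) else 0
    entry$passed_filter <- length(peaks) > 0 && max(peaks) >= tau
    res[[r]] <- entry
  }
  structure(list(assignments = res, tau = tau, dv_tolerance = dv_tolerance,
                 quantile_threshold = quantile_threshold,
                 peak_ratio = peak_ratio, side_gate = side_gate, voxels = vox,
                 voxel_size = scaffold$voxel_size),
            class = "glom_pairs")
}

#' @export
print.glom_pairs <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Glomerulus assignments: %d receptors, %d passed the tau = %g filter\n",
              length(x$assignments),
              sum(vapply(x$assignments, `[[`, logical(1), "passed_filter")),
              x$tau))
  cat(sprintf("  %d lateral and %d medial clusters assigned\n",
              sum(df$side == "lateral"), sum(df$side == "medial")))
  invisible(x)
}

#' Flatten glomerulus assignments into a table
#'
#' @param x a `glom_pairs` object.
#' @param ... unused.
#' @return data frame with one row per assigned cluster: `receptor_id`,
#'   `side`, best voxel indices and center coordinates (um), `peak_median`,
#'   `n_voxels`, `passed_filter`. The best voxel is the scan pick (the
#'   corner-score optimum); `peak_median` is the cluster's maximum field
#'   median.
#' @method as.data.frame glom_pairs
#' @export
as.data.frame.glom_pairs <- function(x, ...) {
  vox <- x$voxels
  rows <- list()
  for (id in names(x$assignments)) {
    a <- x$assignments[[id]]
    for (side in c("lateral", "medial")) {
      cl <- a[[side]]
      if (is.null(cl)) next
      b <- cl$pick_voxel %||% cl$best_voxel
      rows[[length(rows) + 1L]] <- data.frame(
        receptor_id = id, side = side,
        i_ap = vox$i_ap[b], i_dv = vox$i_dv[b], i_ml = vox$i_ml[b],
        x_um = vox$x_um[b], y_um = vox$y_um[b], z_um = vox$z_um[b],
        peak_median = cl$peak, n_voxels = length(cl$voxels),
        passed_filter = a$passed_filter, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(receptor_id = character(), side = character(),
                      i_ap = integer(), i_dv = integer(), i_ml = integer(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      peak_median = numeric(), n_voxels = integer(),
                      passed_filter = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
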