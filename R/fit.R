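#' Reconstruct the 3D glomerular map from three axis section series
#'
#' The central estimator of the package. Per axis: OMP/layer section weights
#' are computed for every replicate, weighted values are min-max normalized
#' and merged across replicates by the cellwise median, and the
#' expression-weighted mean positions are extracted. Weighted counts summed
#' across replicates feed the Bayesian multinomial-Dirichlet composition
#' model; per-section posterior draws are projected onto the voxel scaffold
#' and summarized by per-voxel medians, from which mirror-symmetric
#' glomerulus pairs are assigned within the dorsoventral band implied by the
#' merged DV positions.
#'
#' @param ap,dv,ml a `glom_sections` table or a list of replicate tables for
#'   the respective axis.
#' @param scaffold a `glom_scaffold`; slab counts must match the section
#'   counts of every axis.
#' @param excluded receptor ids dropped before analysis.
#' @param alpha Dirichlet prior concentration (default 0.65).
#' @param n_samples posterior draws per section (default 1000).
#' @param tau posterior-median expression filter (default 0.0005).
#' @param dv_tolerance DV band half-width in sections (default 3).
#' @param quantile_threshold per-receptor high-probability quantile
#'   (default 0.99).
#' @param peak_ratio near-tie tolerance of the anterolateral/posteromedial
#'   scan (see [assign_glomeruli()]).
#' @param side_gate minimum medial-to-lateral corner score ratio for pairing
#'   (see [assign_glomeruli()]).
#' @param seed RNG seed for the posterior draws.
#' @return An object of class `glom_map`; see [summary.glom_map()],
#'   [fitted.glom_map()], [plot.glom_map()].
#' @seealso [simulate_experiment()] for generating synthetic inputs.
#' @export
glom_reconstruct <- function(ap, dv, ml, scaffold,
                             excluded = default_excluded_receptors(),
                             alpha = 0.65, n_samples = 1000, tau = 5e-4,
                             dv_tolerance = 3, quantile_threshold = 0.99,
                             peak_ratio = 0.3, side_gate = 0.2, seed = 1) {
  tables <- list(AP = ap, DV = dv, ML = ml)
  tables <- lapply(tables, function(t) if (inherits(t, "glom_sections")) list(t) else t)

  axes <- list()
  counts <- list()
  for (ax in AXES) {
    reps <- tables[[ax]]
    mats <- vector("list", length(reps))
    wsum <- NULL
    for (i in seq_along(reps)) {
      w <- compute_section_weights(reps[[i]], scaffold)
      mats[[i]] <- normalize_and_mean_position(reps[[i]], w, excluded)
      wsum <- if (is.null(wsum)) mats[[i]]$weighted else wsum + mats[[i]]$weighted
    }
    merged <- if (length(mats) >= 2) merge_replicates(mats) else mats[[1]]
    axes[[ax]] <- merged
    counts[[ax]] <- round(wsum)
  }

  posteriors <- lapply(AXES, function(ax) {
    sample_posterior_compositions(counts[[ax]], alpha = alpha,
                                  n_samples = n_samples,
                                  seed = derive_seed(seed, "posterior",
                                                     match(ax, AXES)))
  })
  names(posteriors) <- AXES
  field <- project_to_voxels(posteriors, scaffold)
  # absolute-mass scan profiles: per-section composition medians scaled by
  # the section's OMP share (the amount of glomerular material it sampled)
  omp_share <- lapply(AXES, function(ax) {
    o <- Reduce(`+`, lapply(tables[[ax]], `[[`, "omp"))
    o / sum(o)
  })
  names(omp_share) <- AXES
  profiles <- lapply(AXES, function(ax) {
    sweep(field$axis_medians[[ax]], 2, omp_share[[ax]], "*")
  })
  names(profiles) <- AXES
  pairs <- assign_glomeruli(field, scaffold,
                            dv_mean = axes$DV$mean_position,
                            dv_tolerance = dv_tolerance, tau = tau,
                            quantile_threshold = quantile_threshold,
                            peak_ratio = peak_ratio, side_gate = side_gate,
                            axis_profiles = profiles)

  structure(list(call = match.call(), scaffold = scaffold, axes = axes,
                 field = field, pairs = pairs,
                 config = list(alpha = alpha, n_samples = n_samples,
                               tau = tau, dv_tolerance = dv_tolerance,
                               quantile_threshold = quantile_threshold,
                               peak_ratio = peak_ratio,
                               side_gate = side_gate,
                               seed = seed, excluded = excluded)),
            class = "glom_map")
}

#' @export
print.glom_map <- function(x, ...) {
  cat("3D glomerular map reconstruction\n")
  cat("Call: "); print(x$call)
  n <- length(x$pairs$assignments)
  passed <- sum(vapply(x$pairs$assignments, `[[`, logical(1), "passed_filter"))
  cat(sprintf("%d receptors; %d passed the tau = %g posterior-median filter\n",
              n, passed, x$config$tau))
  invisible(x)
}

#' Summarize a reconstructed glomerular map
#'
#' @param object a `glom_map`.
#' @param ... unused.
#' @return list of class `summary.glom_map` with assignment counts, pairing
#'   statistics and the AP offset of medial relative to lateral glomeruli.
#' @method summary glom_map
#' @export
summary.glom_map <- function(object, ...) {
  df <- as.data.frame(object$pairs)
  n <- length(object$pairs$assignments)
  passed <- sum(vapply(object$pairs$assignments, `[[`, logical(1),
                       "passed_filter"))
  lat <- df[df$side == "lateral", ]
  med <- df[df$side == "medial", ]
  both <- intersect(lat$receptor_id, med$receptor_id)
  offset <- if (length(both)) {
    (med$i_ap[match(both, med$receptor_id)] -
       lat$i_ap[match(both, lat$receptor_id)]) * object$scaffold$voxel_size
  } else numeric(0)
  structure(list(n_receptors = n, n_passed = passed,
                 n_lateral = nrow(lat), n_medial = nrow(med),
                 n_pairs = length(both),
                 median_ap_offset_um = if (length(offset)) stats::median(offset) else NA,
                 frac_medial_posterior = if (length(offset)) mean(offset > 0) else NA,
                 config = object$config),
            class = "summary.glom_map")
}

#' @export
print.summary.glom_map <- function(x, ...) {
  cat("Glomerular map summary\n")
  cat(sprintf("  receptors: %d, passed filter: %d\n", x$n_receptors, x$n_passed))
  cat(sprintf("  clusters: %d lateral, %d medial (%d mirror pairs)\n",
              x$n_lateral, x$n_medial, x$n_pairs))
  if (!is.na(x$median_ap_offset_um)) {
    cat(sprintf("  median medial-lateral AP offset: %.0f um (%.0f%% of pairs posterior)\n",
                x$median_ap_offset_um, 100 * x$frac_medial_posterior))
  }
  invisible(x)
}

#' Assigned glomerulus positions of a fitted map
#'
#' @param object a `glom_map`.
#' @param ... unused.
#' @return data frame with one row per assigned cluster (see
#'   [as.data.frame.glom_pairs()]).
#' @method fitted glom_map
#' @export
fitted.glom_map <- function(object, ...) as.data.frame(object$pairs)

#' @method as.data.frame glom_map
#' @export
as.data.frame.glom_map <- function(x, ...) as.data.frame(x$pairs)

#' Expression-weighted mean positions of a fitted map
#'
#' @param object a `glom_map`.
#' @param ... unused.
#' @return receptor x axis matrix of merged mean positions (section units).
#' @method coef glom_map
#' @export
coef.glom_map <- function(object, ...) {
  ids <- rownames(object$field$medians)
  out <- sapply(AXES, function(ax) object$axes[[ax]]$mean_position[ids])
  rownames(out) <- ids
  out
}

#' Plot assigned glomerulus positions
#'
#' Anteroposterior versus mediolateral best-voxel positions, lateral and
#' medial clusters distinguished, point shade tracking the dorsoventral
#' position.
#'
#' @param x a `glom_map`.
#' @param ... passed to [graphics::plot()].
#' @method plot glom_map
#' @export
plot.glom_map <- function(x, ...) {
  df <- as.data.frame(x$pairs)
  df <- df[df$passed_filter, ]
  if (!nrow(df)) {
    warning("no assignments passed the filter; nothing to plot")
    return(invisible(x))
  }
  shade <- grDevices::gray(0.8 * (df$i_dv - min(df$i_dv)) /
                             max(1, diff(range(df$i_dv))))
  graphics::plot(df$x_um, df$z_um, pch = ifelse(df$side == "lateral", 16, 17),
                 col = shade, xlab = "AP position (um)",
                 ylab = "ML position (um)",
                 main = "Assigned glomerulus positions", ...)
  graphics::legend("topright", pch = c(16, 17), legend = c("lateral", "medial"),
                   bty = "n")
  invisible(x)
}
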