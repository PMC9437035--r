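#' Sample posterior receptor compositions for each section
#'
#' Models the reads of one section as a multinomial draw over receptors with
#' a symmetric Dirichlet prior: with counts `n` over `K` receptors, the
#' posterior composition is `Dirichlet(n + alpha)`. The default
#' concentration `alpha = 0.65` encodes the weak prior knowledge that each
#' section contains only a subset of all glomeruli. Sampling uses the
#' standard gamma normalization.
#'
#' @param table a `glom_sections` table, or a non-negative receptor x section
#'   matrix (values are rounded to integers, the count scale the model
#'   expects).
#' @param alpha Dirichlet prior concentration (> 0), default 0.65.
#' @param n_samples posterior draws per section, default 1000.
#' @param seed RNG seed.
#' @return Object of class `glom_posterior`: list with `axis`, `samples`
#'   (K x S x n_samples array; each column composition sums to 1), `alpha`,
#'   `n_samples`, `counts`.
#' @examples
#' m <- matrix(c(10, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
#' ps <- sample_posterior_compositions(m, alpha = 0.65, n_samples = 200, seed = 1)
#' rowMeans(ps$samples[, 1, ])  # ~ (10.65, 0.65, 0.65)/11.95
#' @export
sample_posterior_compositions <- function(table, alpha = 0.65,
                                          n_samples = 1000, seed = 1) {
  if (alpha <= 0) stopf("`alpha` must be positive")
  if (n_samples < 1) stopf("`n_samples` must be >= 1")
  if (inherits(table, "glom_sections")) {
    counts <- round(table$values)
    axis <- table$axis
  } else {
    counts <- round(as.matrix(table))
    axis <- NA_character_
  }
  K <- nrow(counts); S <- ncol(counts)
  if (K < 2) stopf("need at least 2 receptors to model compositions")

  samples <- array(NA_real_, dim = c(K, S, n_samples),
                   dimnames = list(rownames(counts), NULL, NULL))
  with_seed(derive_seed(seed, "posterior"), {
    for (s in seq_len(S)) {
      shape <- counts[, s] + alpha
      g <- matrix(stats::rgamma(K * n_samples, shape = rep(shape, n_samples)),
                  nrow = K)
      samples[, s, ] <- sweep(g, 2, colSums(g), "/")
    }
  })
  structure(list(axis = axis, samples = samples, alpha = alpha,
                 n_samples = n_samples, counts = counts),
            class = "glom_posterior")
}

#' Project per-section posterior compositions onto the voxel scaffold
#'
#' For each posterior draw, a voxel's receptor composition is the weighted
#' average of the compositions of the three sections (one per axis) that
#' intersect it, each section weighted by the inverse of its shell voxel
#' count so that a section's signal is conserved when spread over its
#' voxels; the average is renormalized to sum to 1. The per-voxel,
#' per-receptor posterior median across draws summarizes the field.
#'
#' @param posteriors named list (`AP`, `DV`, `ML`) of `glom_posterior`
#'   objects with matching receptor sets and draw counts.
#' @param scaffold a `glom_scaffold`; each slab must have a matching section.
#' @return Object of class `glom_field`: list with `medians` (receptor x
#'   voxel matrix), `voxels` (the scaffold's shell voxel table),
#'   `axis_medians` (per-axis receptor x section median compositions, used
#'   by the assignment scan), `n_samples`.
#' @export
project_to_voxels <- function(posteriors, scaffold) {
  if (!all(AXES %in% names(posteriors))) {
    stopf("`posteriors` must be a named list with elements AP, DV, ML")
  }
  K <- dim(posteriors$AP$samples)[1]
  Tn <- dim(posteriors$AP$samples)[3]
  ids <- rownames(posteriors$AP$samples)
  for (ax in AXES) {
    d <- dim(posteriors[[ax]]$samples)
    if (d[1] != K || d[3] != Tn) stopf("posterior dimensions differ across axes")
    n_slab <- scaffold$dims[match(ax, AXES)]
    if (d[2] != n_slab) {
      stopf("axis %s has %d sections but the scaffold has %d slabs",
            ax, d[2], n_slab)
    }
  }

  vox <- scaffold$voxels
  V <- lapply(AXES, function(ax) shell_counts(scaffold, ax))
  names(V) <- AXES
  for (ax in AXES) {
    empty <- which(V[[ax]] == 0)
    if (length(empty)) {
      warning(sprintf("axis %s: slab(s) %s contain no shell voxels; their sections are unused",
                      ax, paste(empty, collapse = ",")))
    }
  }

  # pre-scale each section's draws by 1/V once
  slices <- lapply(AXES, function(ax) {
    lapply(seq_along(V[[ax]]), function(s) {
      if (V[[ax]][s] == 0) return(NULL)
      posteriors[[ax]]$samples[, s, ] / V[[ax]][s]
    })
  })
  names(slices) <- AXES

  # per-axis per-section median compositions (the corner statistic inputs)
  axis_medians <- lapply(posteriors, function(p) apply(p$samples, c(1, 2),
                                                       stats::median))
  n_vox <- nrow(vox)
  med <- matrix(NA_real_, nrow = K, ncol = n_vox, dimnames = list(ids, NULL))
  half <- floor(Tn / 2)
  for (v in seq_len(n_vox)) {
    m <- slices$AP[[vox$i_ap[v]]] + slices$DV[[vox$i_dv[v]]] +
      slices$ML[[vox$i_ml[v]]]
    m <- sweep(m, 2, colSums(m), "/")
    # row medians across draws (sort-based; T is fixed across voxels)
    ms <- apply(m, 1, sort.int, method = "quick")
    med[, v] <- if (Tn %% 2 == 1) ms[half + 1, ] else
      (ms[half, ] + ms[half + 1, ]) / 2
  }
  structure(list(medians = med, voxels = vox, axis_medians = axis_medians,
                 n_samples = Tn),
            class = "glom_field")
}

#' @export
print.glom_field <- function(x, ...) {
  cat(sprintf("Posterior voxel field: %d receptors x %d voxels (median of %d draws)\n",
              nrow(x$medians), ncol(x$medians), x$n_samples))
  invisible(x)
}

#' Export posterior medians as a long-format table
#'
#' @param field a `glom_field`.
#' @param path TSV path.
#' @export
write_field <- function(field, path) {
  vox <- field$voxels
  long <- data.frame(
    receptor_id = rep(rownames(field$medians), times = ncol(field$medians)),
    i_ap = rep(vox$i_ap, each = nrow(field$medians)),
    i_dv = rep(vox$i_dv, each = nrow(field$medians)),
    i_ml = rep(vox$i_ml, each = nrow(field$medians)),
    median_prob = as.vector(field$medians))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
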