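#' Receptors excluded from all positional analyses
#'
#' Four receptors whose abnormally high abundances are consistent with
#' ectopic expression in non-sensory bulb cell types rather than axonal
#' transcripts; they are dropped by default before normalization.
#'
#' @return character vector of receptor ids.
#' @export
default_excluded_receptors <- function() {
  c("Olfr287", "Olfr32", "Olfr361", "Olfr1033")
}

#' Compute OMP/layer section weights
#'
#' Each section's abundances are weighted by a factor that accounts for the
#' proportion of total OMP signal found in that section (`omp_share`, a proxy
#' for the amount of mature-OSN axonal material collected) and the proportion
#' of the glomerular layer the section geometrically contains (`layer_share`,
#' from the scaffold's shell voxel counts). The weight is
#' `w_s = layer_share_s / omp_share_s`, rescaled to mean 1 over sections with
#' nonzero OMP; sections with zero OMP get weight 0 and are flagged.
#'
#' @param table a `glom_sections` table.
#' @param scaffold a `glom_scaffold` with slab counts for the table's axis.
#' @return An object of class `glom_weights`: list with `axis`, `weights`,
#'   `omp_share`, `layer_share`, `flagged` (indices of zero-OMP sections).
#' @examples
#' sc <- build_scaffold(c(6, 6, 6))
#' tab <- section_table(matrix(1, 2, 6, dimnames = list(c("a", "b"), NULL)),
#'                      omp = rep(10, 6), axis = "AP")
#' compute_section_weights(tab, sc)$weights
#' @export
compute_section_weights <- function(table, scaffold) {
  stopifnot(inherits(table, "glom_sections"))
  omp <- table$omp
  if (sum(omp) == 0) stopf("all-zero OMP vector: cannot compute section weights")
  counts <- shell_counts(scaffold, table$axis)
  if (length(counts) != length(omp)) {
    stopf("scaffold has %d slabs along %s but the table has %d sections",
          length(counts), table$axis, length(omp))
  }
  p <- omp / sum(omp)
  l <- counts / sum(counts)
  w <- ifelse(p > 0, l / p, 0)
  pos <- p > 0
  if (any(pos)) w[pos] <- w[pos] / mean(w[pos])
  structure(list(axis = table$axis, weights = w, omp_share = p,
                 layer_share = l, flagged = which(!pos)),
            class = "glom_weights")
}

#' Weight, min-max normalize and locate each receptor along one axis
#'
#' Applies the section weights, min-max normalizes each receptor's weighted
#' profile to \[0, 1\], and computes the expression-weighted mean position
#' `sum(pos_s * v_rs) / sum(v_rs)` on the weighted (pre-normalization)
#' values. Rows with no dynamic range are zeroed and recorded in
#' `flat_rows`; receptors in `excluded` are dropped.
#'
#' @param table a `glom_sections` table.
#' @param weights matching `glom_weights`.
#' @param excluded receptor ids to drop (default: the four receptors with
#'   suspected ectopic expression).
#' @return Object of class `glom_axis_matrix`: list with `axis`,
#'   `replicate_id`, `normalized` (rows in \[0,1\]), `weighted` (weighted
#'   pre-normalization values), `mean_position` (section-index units),
#'   `mean_position_um`, `flat_rows`, `section_positions`,
#'   `section_thickness`.
#' @export
normalize_and_mean_position <- function(table, weights,
                                        excluded = default_excluded_receptors()) {
  stopifnot(inherits(table, "glom_sections"), inherits(weights, "glom_weights"))
  if (weights$axis != table$axis) stopf("weights were computed for axis %s", weights$axis)
  v <- table$values[!(rownames(table$values) %in% excluded), , drop = FALSE]
  v <- sweep(v, 2, weights$weights, "*")
  pos <- table$section_positions

  tot <- rowSums(v)
  mean_pos <- ifelse(tot > 0, as.numeric(v %*% pos) / tot, NA_real_)
  names(mean_pos) <- rownames(v)

  rng_min <- apply(v, 1, min)
  rng_max <- apply(v, 1, max)
  flat <- rng_max == rng_min
  norm <- (v - rng_min) / ifelse(flat, 1, rng_max - rng_min)
  norm[flat, ] <- 0
  mean_pos[flat] <- NA_real_

  structure(list(axis = table$axis, replicate_id = table$replicate_id,
                 normalized = norm, weighted = v, mean_position = mean_pos,
                 mean_position_um = (mean_pos - 0.5) * table$section_thickness,
                 flat_rows = rownames(v)[flat],
                 section_positions = pos,
                 section_thickness = table$section_thickness),
            class = "glom_axis_matrix")
}

#' @export
print.glom_axis_matrix <- function(x, ...) {
  cat(sprintf("Normalized axis matrix (%s, %s): %d receptors x %d sections, %d flat\n",
              x$axis, x$replicate_id, nrow(x$normalized), ncol(x$normalized),
              length(x$flat_rows)))
  invisible(x)
}

#' Merge replicate axis matrices by the cellwise median
#'
#' Takes the median normalized value at each (receptor, section) cell across
#' replicates, re-min-max-normalizes each receptor row, and recomputes the
#' expression-weighted mean position on the merged matrix.
#'
#' @param matrices list of >= 2 `glom_axis_matrix` objects with identical
#'   receptor and section sets.
#' @return A merged `glom_axis_matrix` with `replicate_id = "merged"`.
#' @export
merge_replicates <- function(matrices) {
  if (length(matrices) < 2L) stopf("need at least two replicates to merge")
  ref <- matrices[[1]]
  for (i in seq_along(matrices)[-1]) {
    m <- matrices[[i]]
    if (!identical(dim(m$normalized), dim(ref$normalized)) ||
        !identical(rownames(m$normalized), rownames(ref$normalized))) {
      stopf("replicate '%s' does not match the receptor/section set of '%s'",
            m$replicate_id, ref$replicate_id)
    }
  }
  arr <- simplify2array(lapply(matrices, function(m) m$normalized))
  med <- apply(arr, c(1, 2), stats::median)
  dimnames(med) <- dimnames(ref$normalized)

  rng_min <- apply(med, 1, min)
  rng_max <- apply(med, 1, max)
  flat <- rng_max == rng_min
  norm <- (med - rng_min) / ifelse(flat, 1, rng_max - rng_min)
  norm[flat, ] <- 0

  pos <- ref$section_positions
  tot <- rowSums(norm)
  mean_pos <- ifelse(tot > 0, as.numeric(norm %*% pos) / tot, NA_real_)
  names(mean_pos) <- rownames(norm)

  structure(list(axis = ref$axis, replicate_id = "merged",
                 normalized = norm, weighted = med, mean_position = mean_pos,
                 mean_position_um = (mean_pos - 0.5) * ref$section_thickness,
                 flat_rows = rownames(norm)[flat],
                 section_positions = pos,
                 section_thickness = ref$section_thickness),
            class = "glom_axis_matrix")
}

#' Compare mean positions between receptor groups
#'
#' Runs a two-tailed Mann-Whitney U test (exact enumeration when both groups
#' have at most 8 members, continuity-corrected normal approximation
#' otherwise) on the ranked mean positions for each requested two-group
#' contrast, and optionally a Spearman correlation of mean position against
#' an external reference index (e.g. the OE dorsoventral zone index).
#'
#' @param mean_positions named numeric vector of per-receptor mean positions.
#' @param groups factor or character vector of group labels, named by (or
#'   aligned with) receptor id.
#' @param contrasts list of length-2 character vectors of group labels to
#'   compare; default: all pairs of observed labels.
#' @param reference_index optional named numeric vector; Spearman correlation
#'   is computed over the receptors present in both vectors.
#' @return Object of class `glom_comparison`: list with `tests` (data frame:
#'   contrast, n1, n2, U, p, method) and `spearman` (rho, p) or `NULL`.
#' @export
group_position_comparison <- function(mean_positions, groups, contrasts = NULL,
                                      reference_index = NULL) {
  if (is.null(names(groups)) && length(groups) == length(mean_positions)) {
    names(groups) <- names(mean_positions)
  }
  groups <- groups[names(mean_positions)]
  lev <- unique(stats::na.omit(as.character(groups)))
  if (is.null(contrasts)) {
    contrasts <- if (length(lev) >= 2) {
      apply(utils::combn(lev, 2), 2, identity, simplify = FALSE)
    } else list()
  }
  rows <- lapply(contrasts, function(ct) {
    x <- mean_positions[which(groups == ct[1])]
    y <- mean_positions[which(groups == ct[2])]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      stopf("contrast %s vs %s has an empty group", ct[1], ct[2])
    }
    res <- mwu_test(x, y)
    data.frame(contrast = paste(ct, collapse = " vs "),
               n1 = length(x), n2 = length(y), U = res$U, p = res$p,
               method = res$method, stringsAsFactors = FALSE)
  })
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contrast = character(), n1 = integer(), n2 = integer(),
               U = numeric(), p = numeric(), method = character())

  spearman <- NULL
  if (!is.null(reference_index)) {
    common <- intersect(names(mean_positions)[!is.na(mean_positions)],
                        names(reference_index))
    ct <- suppressWarnings(stats::cor.test(mean_positions[common],
                                           reference_index[common],
                                           method = "spearman"))
    spearman <- list(rho = unname(ct$estimate), p = ct$p.value,
                     n = length(common))
  }
  structure(list(tests = tests, spearman = spearman),
            class = "glom_comparison")
}

#' @export
print.glom_comparison <- function(x, ...) {
  cat("Group position comparison\n")
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  if (!is.null(x$spearman)) {
    cat(sprintf("Spearman vs reference index: rho = %.3f, p = %.3g (n = %d)\n",
                x$spearman$rho, x$spearman$p, x$spearman$n))
  }
  invisible(x)
}
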