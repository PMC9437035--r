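#' Percent identity of two protein sequences under global alignment
#'
#' Aligns two ungapped amino-acid sequences globally (Needleman-Wunsch with
#' affine gaps via [Biostrings::pairwiseAlignment()]) and reports percent
#' identity. Defaults follow the scheme used for OR repertoire comparisons:
#' BLOSUM62, gap opening 11, gap extension 1. Identity is pinned to
#' matches / alignment length (gap columns included); alternative flavors
#' are selectable.
#'
#' @param seq_a,seq_b amino-acid sequence strings (no gaps).
#' @param substitution substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1).
#' @param flavor identity denominator: `"alignment"` (full alignment length,
#'   default), `"aligned"` (non-gap columns), or `"shorter"` (length of the
#'   shorter input).
#' @return percent identity in \[0, 100\].
#' @examples
#' pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV")  # 90
#' @export
pairwise_identity <- function(seq_a, seq_b, substitution = "BLOSUM62",
                              gap_open = 11, gap_extend = 1,
                              flavor = c("alignment", "aligned", "shorter")) {
  flavor <- match.arg(flavor)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stopf("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = substitution,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-")
  denom <- switch(flavor,
                  alignment = length(p),
                  aligned = sum(p != "-" & s != "-"),
                  shorter = min(nchar(seq_a), nchar(seq_b)))
  100 * matches / denom
}

#' All-pairs identity and position-distance records
#'
#' Computes percent identity and the absolute difference of per-axis mean
#' positions for every unordered pair of receptors.
#'
#' @param seqs named character vector of ungapped protein sequences.
#' @param positions data frame or matrix of mean positions with receptors as
#'   row names and axes (`AP`, `DV`, `ML`) as columns; missing axes yield
#'   `NA` distances.
#' @param ... passed to [pairwise_identity()].
#' @return data frame: `id_a`, `id_b`, `pct_identity`, `d_ap`, `d_dv`,
#'   `d_ml`.
#' @export
pairwise_records <- function(seqs, positions, ...) {
  ids <- names(seqs)
  if (is.null(ids)) stopf("`seqs` must be named by receptor id")
  pairs <- utils::combn(ids, 2)
  pos <- as.matrix(positions)
  get_d <- function(ax, a, b) {
    if (!ax %in% colnames(pos)) return(NA_real_)
    abs(pos[a, ax] - pos[b, ax])
  }
  out <- data.frame(id_a = pairs[1, ], id_b = pairs[2, ],
                    pct_identity = NA_real_, d_ap = NA_real_,
                    d_dv = NA_real_, d_ml = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    out$pct_identity[k] <- pairwise_identity(seqs[[a]], seqs[[b]], ...)
    out$d_ap[k] <- get_d("AP", a, b)
    out$d_dv[k] <- get_d("DV", a, b)
    out$d_ml[k] <- get_d("ML", a, b)
  }
  out
}

#' Sequence-similarity versus position-distance analysis
#'
#' Within each stratum (e.g. Class I, Class II dorsal, Class II ventral) and
#' axis, compares mean position distances between receptor pairs above and
#' below the family-level identity cutoff, and between the family
#' (40-60\%), subfamily (60-80\%) and highly-similar (>= 80\%) identity
#' bins, using two-tailed Mann-Whitney U tests.
#'
#' @param records data frame from [pairwise_records()].
#' @param strata named character vector mapping receptor id to stratum; a
#'   pair contributes only when both members share a stratum.
#' @param cutoffs identity cutoffs, default `c(40, 60, 80)`.
#' @return data frame: stratum, axis, comparison, n1, n2, U, p (NA rows for
#'   empty bins).
#' @export
identity_vs_distance_analysis <- function(records, strata,
                                          cutoffs = c(40, 60, 80)) {
  stopifnot(length(cutoffs) == 3)
  same <- strata[records$id_a] == strata[records$id_b]
  same[is.na(same)] <- FALSE
  records <- records[same, , drop = FALSE]
  records$stratum <- strata[records$id_a]

  bins <- function(idy) {
    cut(idy, breaks = c(-Inf, cutoffs, Inf),
        labels = c(paste0("<", cutoffs[1]),
                   paste0(cutoffs[1], "-", cutoffs[2]),
                   paste0(cutoffs[2], "-", cutoffs[3]),
                   paste0(">=", cutoffs[3])), right = FALSE)
  }
  records$bin <- bins(records$pct_identity)

  rows <- list()
  add <- function(stratum, axis, label, x, y) {
    if (length(x) == 0 || length(y) == 0) {
      rows[[length(rows) + 1L]] <<- data.frame(
        stratum = stratum, axis = axis, comparison = label,
        n1 = length(x), n2 = length(y), U = NA_real_, p = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      res <- mwu_test(x, y)
      rows[[length(rows) + 1L]] <<- data.frame(
        stratum = stratum, axis = axis, comparison = label,
        n1 = length(x), n2 = length(y), U = res$U, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  bin_levels <- levels(records$bin)[-1]
  for (st in unique(records$stratum)) {
    sub <- records[records$stratum == st, ]
    for (axis in c("AP", "DV", "ML")) {
      d <- sub[[paste0("d_", tolower(axis))]]
      ok <- !is.na(d)
      hi <- d[ok & sub$pct_identity >= cutoffs[1]]
      lo <- d[ok & sub$pct_identity < cutoffs[1]]
      add(st, axis, sprintf(">=%g vs <%g", cutoffs[1], cutoffs[1]), hi, lo)
      for (i in 1:2) for (j in (i + 1):3) {
        x <- d[ok & sub$bin == bin_levels[i]]
        y <- d[ok & sub$bin == bin_levels[j]]
        add(st, axis, sprintf("%s vs %s", bin_levels[i], bin_levels[j]), x, y)
      }
    }
  }
  do.call(rbind, rows)
}

# Residue codes (1..20 in Grantham row order; NA for gaps/unknowns) for a
# gapped alignment given as a named character vector.
alignment_matrix <- function(alignment) {
  if (is.list(alignment) && !is.null(alignment$alignment)) {
    alignment <- alignment$alignment
  }
  nm <- names(alignment)
  alignment <- as.character(alignment)
  names(alignment) <- nm
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stopf("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  mat
}

#' Grantham-conservation permutation test per alignment column
#'
#' Tests, column by column, whether a query set of receptors (e.g. the most
#' anterior ventral Class II ORs) is more physicochemically conserved than
#' expected by chance. The statistic is the mean pairwise Grantham distance
#' among the query residues in the column; the null distribution is the
#' same statistic over `n_perm` random subsets of `subset_size` receptors
#' drawn from the background set (the same subsets are reused across
#' columns). The p-value is lower-tailed,
#' `(1 + #\{null <= observed\}) / (1 + n_perm)` (conservation = smaller
#' distances), with Benjamini-Hochberg correction across retained columns.
#' Columns with a gap fraction above `max_gap_fraction` are excluded.
#'
#' @param alignment gapped alignment: named character vector of equal-length
#'   sequences (or the list returned by [generate_aligned_sequences()]).
#' @param query_set,background_set receptor ids; the query must have >= 2
#'   members and the null subsets are drawn from the background (which may
#'   include the query members).
#' @param subset_size null subset size; default half the query size,
#'   rounded up.
#' @param n_perm number of random subsets (default 1000).
#' @param max_gap_fraction per-column gap tolerance (default 0.10).
#' @param seed RNG seed.
#' @return data frame: `column`, `statistic`, `p`, `q`, `excluded`,
#'   `gap_fraction`.
#' @export
residue_association_test <- function(alignment, query_set, background_set,
                                     subset_size = NULL, n_perm = 1000,
                                     max_gap_fraction = 0.10, seed = 1) {
  mat <- alignment_matrix(alignment)
  if (length(query_set) < 2) stopf("`query_set` must have at least 2 members")
  missing_ids <- setdiff(c(query_set, background_set), rownames(mat))
  if (length(missing_ids)) {
    stopf("ids absent from the alignment: %s",
          paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  if (is.null(subset_size)) subset_size <- ceiling(length(query_set) / 2)
  if (subset_size > length(background_set)) {
    stopf("`subset_size` exceeds the background set size")
  }

  codes <- matrix(match(mat, .grantham_aa), nrow = nrow(mat),
                  dimnames = dimnames(mat))
  gap_frac <- colMeans(mat == "-")
  retained <- which(gap_frac <= max_gap_fraction)
  D <- .grantham_matrix

  pair_stat_counts <- function(N) {
    # N: draws x 20 residue counts; mean pairwise distance per draw
    m_eff <- rowSums(N)
    pairsum <- rowSums((N %*% D) * N) / 2
    denom <- m_eff * (m_eff - 1) / 2
    ifelse(denom > 0, pairsum / denom, NA_real_)
  }
  counts_of <- function(code_mat) {
    N <- vapply(seq_len(20), function(k) rowSums(code_mat == k, na.rm = TRUE),
                numeric(nrow(code_mat)))
    if (is.null(dim(N))) N <- matrix(N, nrow = 1)
    N
  }

  q_codes <- codes[query_set, , drop = FALSE]
  perm <- with_seed(derive_seed(seed, "sequences", 1L), {
    t(replicate(n_perm, sample(background_set, subset_size)))
  })

  statistic <- rep(NA_real_, ncol(mat))
  pvals <- rep(NA_real_, ncol(mat))
  for (j in retained) {
    qc <- matrix(q_codes[, j], nrow = 1)
    obs <- pair_stat_counts(counts_of(qc))
    statistic[j] <- obs
    if (is.na(obs)) next
    pc <- matrix(codes[perm, j], nrow = n_perm)
    null_stats <- pair_stat_counts(counts_of(pc))
    valid <- !is.na(null_stats)
    pvals[j] <- (1 + sum(null_stats[valid] <= obs)) / (1 + sum(valid))
  }
  q <- rep(NA_real_, ncol(mat))
  q[retained] <- stats::p.adjust(pvals[retained], method = "BH")
  data.frame(column = seq_len(ncol(mat)), statistic = statistic,
             p = pvals, q = q,
             excluded = seq_len(ncol(mat)) %in% setdiff(seq_len(ncol(mat)), retained),
             gap_fraction = gap_frac)
}

#' Select receptors from one end of an axis
#'
#' The anterior/posterior query sets of the residue association analysis are
#' the stated quantile cuts of the ranked axis positions.
#'
#' @param positions named numeric vector of mean positions.
#' @param fraction quantile fraction (e.g. 0.20, 0.275, 0.35).
#' @param end `"anterior"` (smallest positions) or `"posterior"`.
#' @return character vector of receptor ids.
#' @export
select_extreme_receptors <- function(positions, fraction = 0.30,
                                     end = c("anterior", "posterior")) {
  end <- match.arg(end)
  positions <- positions[!is.na(positions)]
  k <- max(2L, round(fraction * length(positions)))
  ord <- order(positions, decreasing = (end == "posterior"))
  names(positions)[ord[seq_len(k)]]
}

#' Configuration for the sequence-to-position regressor
#'
#' @param n_trees boosting rounds (default 1000).
#' @param cv_folds cross-validation folds for tuning (default 10).
#' @param holdout_fraction stratified holdout fraction (default 0.10).
#' @param eta,max_depth,min_child_weight,gamma base hyperparameters.
#' @param tune_grid optional data frame of candidate hyperparameter rows
#'   (columns among eta, max_depth, min_child_weight, gamma) evaluated by
#'   cross-validated RMSE on the training split.
#' @param seed RNG seed (split, folds and fitting).
#' @return list of class `glom_regressor_config`.
#' @export
regressor_config <- function(n_trees = 1000, cv_folds = 10,
                             holdout_fraction = 0.10, eta = 0.05,
                             max_depth = 6, min_child_weight = 1, gamma = 0,
                             tune_grid = NULL, seed = 1) {
  structure(list(n_trees = n_trees, cv_folds = cv_folds,
                 holdout_fraction = holdout_fraction, eta = eta,
                 max_depth = max_depth, min_child_weight = min_child_weight,
                 gamma = gamma, tune_grid = tune_grid, seed = seed),
            class = "glom_regressor_config")
}

#' Predict axis position from sequence physicochemistry with boosted trees
#'
#' Builds a feature matrix of Grantham composition, polarity and volume for
#' every gapless alignment column, holds out a position-stratified fraction
#' of receptors, optionally tunes hyperparameters by k-fold cross-validation
#' on the training split, fits a gradient-boosted tree ensemble, and
#' reports holdout R-squared, RMSE and feature importances.
#'
#' @param alignment gapped alignment (named character vector or the list
#'   from [generate_aligned_sequences()]).
#' @param positions named numeric vector: axis mean position per receptor.
#' @param cfg a [regressor_config()].
#' @return list of class `glom_seqfit`: `r_squared`, `rmse`, `importance`,
#'   `model`, `holdout_ids`, `predicted`, `observed`, `tuned_params`.
#' @export
fit_position_regressor <- function(alignment, positions,
                                   cfg = regressor_config()) {
  mat <- alignment_matrix(alignment)
  ids <- intersect(rownames(mat), names(positions)[!is.na(positions)])
  if (length(ids) < 20) stopf("need >= 20 receptors with positions to fit")
  mat <- mat[ids, , drop = FALSE]
  y <- positions[ids]

  gapless <- which(colSums(mat == "-") == 0)
  if (!length(gapless)) stopf("no gapless alignment columns")
  tab <- grantham_table()$properties
  feats <- lapply(gapless, function(j) {
    cbind(tab$composition[mat[, j]], tab$polarity[mat[, j]],
          tab$volume[mat[, j]])
  })
  X <- do.call(cbind, feats)
  colnames(X) <- as.vector(t(outer(gapless, c("comp", "pol", "vol"),
                                   function(j, p) sprintf("col%03d_%s", j, p))))
  rownames(X) <- ids

  with_seed(derive_seed(cfg$seed, "sequences", 2L), {
    strata <- cut(rank(y, ties.method = "first"), breaks = 5, labels = FALSE)
    hold <- unlist(lapply(split(seq_along(y), strata), function(ix) {
      k <- max(1L, round(cfg$holdout_fraction * length(ix)))
      sample(ix, k)
    }))
    train <- setdiff(seq_along(y), hold)

    base_params <- list(objective = "reg:squarederror", eta = cfg$eta,
                        max_depth = cfg$max_depth,
                        min_child_weight = cfg$min_child_weight,
                        gamma = cfg$gamma, nthread = 1)
    tuned <- base_params
    if (!is.null(cfg$tune_grid) && nrow(cfg$tune_grid) > 1) {
      dtrain <- xgboost::xgb.DMatrix(X[train, , drop = FALSE], label = y[train])
      cv_rmse <- vapply(seq_len(nrow(cfg$tune_grid)), function(i) {
        p <- base_params
        p[names(cfg$tune_grid)] <- as.list(cfg$tune_grid[i, ])
        cv <- xgboost::xgb.cv(params = p, data = dtrain,
                              nrounds = cfg$n_trees, nfold = cfg$cv_folds,
                              verbose = 0, early_stopping_rounds = 25)
        min(cv$evaluation_log$test_rmse_mean)
      }, numeric(1))
      best <- which.min(cv_rmse)
      tuned[names(cfg$tune_grid)] <- as.list(cfg$tune_grid[best, ])
    }

    dtrain <- xgboost::xgb.DMatrix(X[train, , drop = FALSE], label = y[train])
    model <- xgboost::xgb.train(params = tuned, data = dtrain,
                                nrounds = cfg$n_trees, verbose = 0)
    pred <- stats::predict(model, xgboost::xgb.DMatrix(X[hold, , drop = FALSE]))
    obs <- y[hold]
    ss_res <- sum((obs - pred)^2)
    ss_tot <- sum((obs - mean(obs))^2)
    imp <- tryCatch(as.data.frame(xgboost::xgb.importance(model = model)),
                    error = function(e) NULL)
    structure(list(r_squared = 1 - ss_res / ss_tot,
                   rmse = sqrt(mean((obs - pred)^2)),
                   importance = imp, model = model,
                   holdout_ids = ids[hold], predicted = pred, observed = obs,
                   tuned_params = tuned),
              class = "glom_seqfit")
  })
}

#' @export
print.glom_seqfit <- function(x, ...) {
  cat(sprintf("Sequence-to-position regression: holdout R^2 = %.3f, RMSE = %.3f (n = %d)\n",
              x$r_squared, x$rmse, length(x$observed)))
  if (!is.null(x$importance) && nrow(x$importance)) {
    cat("Top features:\n")
    print(utils::head(x$importance[, c("Feature", "Gain")], 5), row.names = FALSE)
  }
  invisible(x)
}
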