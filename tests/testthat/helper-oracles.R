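# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Global affine-gap aligner (Gotoh) under the same scoring convention as
# Biostrings::pairwiseAlignment: a gap of length L costs open + L * extend.
# Returns the optimal score and the set of percent identities (gap-inclusive
# denominator) achievable by optimal alignments, found by exhaustive
# backtracking. Intended for short sequences only.
oracle_global_align <- function(a, b, open = 11, extend = 1,
                                submat = NULL) {
  if (is.null(submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # align av[i] with bv[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consume av[i])
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consume bv[j])
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  # exhaustive enumeration over optimal alignment paths (fine for short
  # sequences): recurse from the end over the three states
  res <- character(0)
  rec <- function(i, j, state, score_needed, matches, len) {
    if (i == 0 && j == 0) {
      if (abs(score_needed) < 1e-9) {
        res[[length(res) + 1]] <<- sprintf("%.6f", 100 * matches / len)
      }
      return(invisible())
    }
    eps <- 1e-9
    if (state == "M") {
      if (i > 0 && j > 0) {
        s <- submat[av[i], bv[j]]
        for (prev in c("M", "X", "Y")) {
          pv <- switch(prev, M = M[i, j], X = X[i, j], Y = Y[i, j])
          if (abs(pv + s - score_needed) < eps) {
            rec(i - 1, j - 1, prev, pv,
                matches + (av[i] == bv[j]), len + 1)
          }
        }
      }
    } else if (state == "X") {
      if (i > 0) {
        if (abs(M[i, j + 1] - open - extend - score_needed) < eps) {
          rec(i - 1, j, "M", M[i, j + 1], matches, len + 1)
        }
        if (abs(X[i, j + 1] - extend - score_needed) < eps) {
          rec(i - 1, j, "X", X[i, j + 1], matches, len + 1)
        }
      }
    } else {
      if (j > 0) {
        if (abs(M[i + 1, j] - open - extend - score_needed) < eps) {
          rec(i, j - 1, "M", M[i + 1, j], matches, len + 1)
        }
        if (abs(Y[i + 1, j] - extend - score_needed) < eps) {
          rec(i, j - 1, "Y", Y[i + 1, j], matches, len + 1)
        }
      }
    }
    invisible()
  }
  for (state in c("M", "X", "Y")) {
    v <- switch(state, M = M[n + 1, m + 1], X = X[n + 1, m + 1],
                Y = Y[n + 1, m + 1])
    if (abs(v - best) < 1e-9) rec(n, m, state, v, 0, 0)
  }
  list(score = best, identities = as.numeric(unique(res)))
}

# Brute-force Benjamini-Hochberg adjusted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Random amino-acid sequence (20-letter alphabet, no gaps).
random_protein <- function(len) {
  paste(sample(rownames(glomap::grantham_table()$matrix), len,
               replace = TRUE), collapse = "")
}

# Minimal hand-built scaffold: a bare voxel list with the class attached,
# for tests that need exact slab geometry rather than an ellipsoid.
stub_scaffold <- function(i_ap, i_dv, i_ml, voxel_size = 100,
                          dims = c(max(i_ap), max(i_dv), max(i_ml)),
                          side = NULL) {
  vox <- data.frame(i_ap = i_ap, i_dv = i_dv, i_ml = i_ml)
  vox$x_um <- (vox$i_ap - 0.5) * voxel_size
  vox$y_um <- (vox$i_dv - 0.5) * voxel_size
  vox$z_um <- (vox$i_ml - 0.5) * voxel_size
  vox$side <- side %||% ifelse(vox$i_ml <= dims[3] / 2, "medial", "lateral")
  structure(list(voxels = vox, dims = as.integer(dims),
                 voxel_size = voxel_size, center = dims * voxel_size / 2,
                 semiaxes = dims * voxel_size / 2, layer_thickness = 1,
                 symmetry_tilt_deg = 0),
            class = "glom_scaffold")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Constant-composition posterior stub: every draw equals `comp` (receptor x
# section matrix of compositions).
stub_posterior <- function(comp, n_samples = 5) {
  samples <- array(rep(comp, n_samples),
                   dim = c(nrow(comp), ncol(comp), n_samples),
                   dimnames = list(rownames(comp), NULL, NULL))
  structure(list(axis = NA_character_, samples = samples, alpha = 0.65,
                 n_samples = n_samples, counts = comp),
            class = "glom_posterior")
}
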