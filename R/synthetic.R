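#' Simulation settings for the synthetic sectioning experiment
#'
#' Bundles and validates the parameters of the synthetic ground-truth map and
#' the simulated serial-sectioning sequencing experiment. Defaults encode the
#' study conditions: 100-um sections, 23/22/22 sections along AP/DV/ML,
#' between-animal positional jitter of 100 um (inside the 75-270 um range
#' reported for glomerular positional variability), 5e4 reads per section,
#' spherical glomeruli of 60 um radius, and a 300 um posterior offset of the
#' medial glomerulus relative to its mirror-symmetric lateral partner.
#'
#' @param n_receptors number of receptors to simulate.
#' @param sections_per_axis integer triple: sections along AP, DV, ML.
#' @param section_thickness section (and voxel) thickness in micrometers.
#' @param jitter_sd per-animal positional jitter SD in micrometers.
#' @param reads_per_section multinomial read total per section.
#' @param singleton_fraction fraction of receptors forming a single (lateral
#'   only) glomerulus instead of a mirror pair.
#' @param posterior_offset AP offset (um) of the medial glomerulus, posterior
#'   to its lateral partner.
#' @param radius glomerulus radius in micrometers.
#' @param abundance_gsd geometric SD of the log-normal receptor abundances.
#' @param noise_floor relative ambient intensity added to every receptor in
#'   every section (free background mRNA); keeps per-section multinomial
#'   totals defined even in slabs without glomerular mass. 0 disables it.
#' @param spread_sd within-animal spread of one receptor's signal across
#'   neighboring sections, SD in micrometers (default 60, matching the
#'   default glomerular radius: the glomerular neuropil plus the axon
#'   fibers approaching it deposit receptor mRNA in adjacent sections; 0
#'   confines signal to the sections the glomerulus occupies).
#' @param seed master seed; replicate- and stage-specific streams are derived
#'   from it by fixed increments.
#' @return A validated list of class `glom_sim_config`.
#' @export
simulation_config <- function(n_receptors = 100,
                              sections_per_axis = c(AP = 23, DV = 22, ML = 22),
                              section_thickness = 100,
                              jitter_sd = 100,
                              reads_per_section = 5e4,
                              singleton_fraction = 0.1,
                              posterior_offset = 300,
                              radius = 60,
                              abundance_gsd = 2,
                              noise_floor = 1e-4,
                              spread_sd = 60,
                              seed = 1) {
  if (section_thickness <= 0) stopf("`section_thickness` must be positive")
  if (length(sections_per_axis) != 3L || any(sections_per_axis < 2)) {
    stopf("`sections_per_axis` must give >= 2 sections per axis")
  }
  if (singleton_fraction < 0 || singleton_fraction > 1) {
    stopf("`singleton_fraction` must lie in [0, 1]")
  }
  if (jitter_sd < 0 || reads_per_section < 1 || radius <= 0) {
    stopf("invalid simulation parameters")
  }
  structure(list(n_receptors = as.integer(n_receptors),
                 sections_per_axis = stats::setNames(as.integer(sections_per_axis), AXES),
                 section_thickness = section_thickness,
                 jitter_sd = jitter_sd,
                 reads_per_section = as.integer(reads_per_section),
                 singleton_fraction = singleton_fraction,
                 posterior_offset = posterior_offset,
                 radius = radius,
                 abundance_gsd = abundance_gsd,
                 noise_floor = noise_floor,
                 spread_sd = spread_sd,
                 seed = as.integer(seed)),
            class = "glom_sim_config")
}

#' Generate a synthetic receptor repertoire
#'
#' Receptors carry a class label (Class I, Class II, or TAAR) and a
#' continuous olfactory-epithelium dorsoventral zone index in \[0, 1\]
#' (0 = most dorsal). Class I receptors and TAARs are confined to dorsal
#' zones, as in the mouse repertoire.
#'
#' @param n number of receptors.
#' @param class_probs sampling probabilities for ClassII, ClassI, TAAR.
#' @param seed RNG seed.
#' @return data frame with columns `id`, `class_label`, `oe_zone_index`,
#'   `excluded`.
#' @export
make_receptors <- function(n, class_probs = c(ClassII = 0.80, ClassI = 0.15,
                                              TAAR = 0.05), seed = 1) {
  if (n < 1) stopf("`n` must be >= 1")
  with_seed(seed, {
    cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
    zone <- ifelse(cls == "ClassII", stats::runif(n), stats::runif(n, 0, 0.3))
    data.frame(id = sprintf("synOlfr%04d", seq_len(n)),
               class_label = cls,
               oe_zone_index = round(zone, 6),
               excluded = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Generate a ground-truth glomerular map
#'
#' Places, for every receptor, a lateral glomerulus on the scaffold surface
#' and (unless the receptor is a singleton) a medial partner mirrored across
#' the mediolateral midplane and shifted posteriorly by
#' `cfg$posterior_offset`. Dorsoventral placement is monotone in the
#' receptor's OE zone index, mirroring the epithelium-to-bulb zonal map. The
#' medial mirror keeps the AP offset exact by re-solving the ML coordinate on
#' the ellipsoid surface at the shifted AP position.
#'
#' @param receptors data frame from [make_receptors()] (or with the same
#'   columns).
#' @param scaffold a `glom_scaffold` built with ellipsoid geometry.
#' @param cfg a `glom_sim_config`.
#' @return data frame of class `glom_truth`: `receptor_id`, `side`, `ap_um`,
#'   `dv_um`, `ml_um`, `radius_um`, `abundance`.
#' @export
generate_ground_truth <- function(receptors, scaffold, cfg) {
  if (is.null(receptors) || nrow(receptors) == 0L) {
    stopf("`receptors` must contain at least one receptor")
  }
  n <- nrow(receptors)
  a <- scaffold$semiaxes; ctr <- scaffold$center
  margin <- 0.95
  off_rel <- cfg$posterior_offset / a[1]

  with_seed(derive_seed(cfg$seed, "truth"), {
    abundance <- stats::rlnorm(n, meanlog = 0, sdlog = log(cfg$abundance_gsd))
    n_single <- round(cfg$singleton_fraction * n)
    singleton <- rep(FALSE, n)
    if (n_single > 0) singleton[sample.int(n, n_single)] <- TRUE

    dv_rel <- (receptors$oe_zone_index - 0.5) * 2 * 0.9
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      s <- sqrt(pmax(margin^2 - dv_rel[i]^2, 0))
      lo <- -s
      hi <- s - (if (singleton[i]) 0 else off_rel)
      if (hi <= lo) { lo <- -s / 2; hi <- lo + 1e-6 }  # offset infeasible: pin near center
      ap_rel <- stats::runif(1, lo, hi)
      ml_rel <- sqrt(pmax(1 - ap_rel^2 - dv_rel[i]^2, 0))
      lat <- data.frame(receptor_id = receptors$id[i], side = "lateral",
                        ap_um = ctr[1] + ap_rel * a[1],
                        dv_um = ctr[2] + dv_rel[i] * a[2],
                        ml_um = ctr[3] + ml_rel * a[3],
                        radius_um = cfg$radius, abundance = abundance[i],
                        stringsAsFactors = FALSE)
      if (singleton[i]) {
        rows[[i]] <- lat
      } else {
        ap2 <- ap_rel + off_rel
        ml2 <- -sqrt(pmax(1 - ap2^2 - dv_rel[i]^2, 0))
        med <- lat
        med$side <- "medial"
        med$ap_um <- ctr[1] + ap2 * a[1]
        med$ml_um <- ctr[3] + ml2 * a[3]
        rows[[i]] <- rbind(lat, med)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("glom_truth", "data.frame")
    out
  })
}

# Distribute one glomerulus over grid voxels by membership: voxels whose
# center lies within the glomerular radius share its mass equally; if the
# sphere covers no voxel center, the nearest voxel carries all of it.
glomerulus_slab_overlap <- function(center, radius, axis_index, dims, thickness) {
  lo <- pmax(1L, floor((center - radius) / thickness) + 1L)
  hi <- pmin(dims, ceiling((center + radius) / thickness))
  if (any(lo > hi)) {  # center off-grid; clamp to nearest voxel
    idx <- pmin(pmax(ceiling(center / thickness), 1L), dims)
    ov <- numeric(dims[axis_index]); ov[idx[axis_index]] <- 1
    return(ov)
  }
  cand <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  cc <- cbind((cand$i - 0.5) * thickness, (cand$j - 0.5) * thickness,
              (cand$k - 0.5) * thickness)
  d2 <- rowSums(sweep(cc, 2, center)^2)
  inside <- d2 <= radius^2
  if (!any(inside)) inside <- d2 == min(d2)
  member_idx <- cand[inside, axis_index]
  ov <- tabulate(member_idx, nbins = dims[axis_index]) / sum(inside)
  ov
}

#' Simulate one replicate of the serial-section sequencing experiment
#'
#' Slices the ground-truth map into axis-aligned slabs of one section
#' thickness. A receptor's expected share in a section is the overlap of its
#' glomerular volume with the slab (computed by voxel membership) times its
#' abundance; reads are then drawn multinomially with `cfg$reads_per_section`
#' per section. An OMP row proportional to the total glomerular volume in
#' each slab proxies the amount of OMP-positive axonal material collected,
#' so that the downstream section weights can convert per-section shares to
#' per-unit-glomerular-material abundances. Replicate
#' jitter redraws glomerulus centers with SD `cfg$jitter_sd`; jittered
#' centers landing off the surface shell are re-projected to the nearest
#' shell voxel.
#'
#' @param truth a `glom_truth` map.
#' @param axis `"AP"`, `"DV"` or `"ML"`.
#' @param cfg a `glom_sim_config`.
#' @param scaffold scaffold used for off-shell re-projection; rebuilt from
#'   `cfg` when `NULL`.
#' @param replicate replicate number (determines the jitter stream).
#' @param quiet suppress the re-projection message.
#' @return A `glom_sections` table (see [section_table()]).
#' @export
simulate_section_counts <- function(truth, axis, cfg, scaffold = NULL,
                                    replicate = 1, quiet = FALSE) {
  check_axis(axis)
  if (is.null(truth) || nrow(truth) == 0L) stopf("`truth` map is empty")
  if (is.null(scaffold)) {
    scaffold <- build_scaffold(cfg$sections_per_axis, cfg$section_thickness)
  }
  ax <- match(axis, AXES)
  dims <- scaffold$dims
  thick <- cfg$section_thickness
  n_sec <- dims[ax]
  ids <- unique(truth$receptor_id)
  K <- length(ids)

  centers <- as.matrix(truth[, c("ap_um", "dv_um", "ml_um")])
  if (cfg$jitter_sd > 0) {
    centers <- with_seed(derive_seed(cfg$seed, "jitter", (replicate - 1L) * 3L + ax), {
      centers + matrix(stats::rnorm(length(centers), 0, cfg$jitter_sd),
                       ncol = 3)
    })
    # re-project off-shell centers to the nearest shell voxel center
    shell_xyz <- as.matrix(scaffold$voxels[, c("x_um", "y_um", "z_um")])
    half <- scaffold$layer_thickness * scaffold$voxel_size / 2
    rel <- sweep(sweep(centers, 2, scaffold$center), 2, scaffold$semiaxes, "/")
    f <- sqrt(rowSums(rel^2))
    rho <- sqrt(rowSums(sweep(centers, 2, scaffold$center)^2))
    d <- ifelse(f > 0, rho * (f - 1) / f, -min(scaffold$semiaxes))
    off <- abs(d) > half
    if (any(off)) {
      for (g in which(off)) {
        j <- which.min(colSums((t(shell_xyz) - centers[g, ])^2))
        centers[g, ] <- shell_xyz[j, ]
      }
      if (!quiet) {
        message(sprintf("%d jittered glomerulus center(s) re-projected to the shell",
                        sum(off)))
      }
    }
  }

  lambda <- matrix(0, nrow = K, ncol = n_sec, dimnames = list(ids, NULL))
  vol <- numeric(n_sec)
  for (g in seq_len(nrow(truth))) {
    ov <- glomerulus_slab_overlap(centers[g, ], truth$radius_um[g], ax, dims, thick)
    r <- match(truth$receptor_id[g], ids)
    lambda[r, ] <- lambda[r, ] + truth$abundance[g] * ov
    vol <- vol + ov
  }
  if (cfg$spread_sd > 0) {
    sd_sec <- cfg$spread_sd / thick
    w <- stats::dnorm(seq(-n_sec, n_sec), 0, sd_sec)
    lambda <- t(apply(lambda, 1, function(row) {
      sm <- stats::filter(c(rep(0, n_sec), row, rep(0, n_sec)), w, sides = 2)
      as.numeric(sm)[(n_sec + 1):(2 * n_sec)]
    }))
    dimnames(lambda) <- list(ids, NULL)
  }

  floor_val <- cfg$noise_floor * mean(truth$abundance)
  probs <- lambda + floor_val
  counts <- matrix(0L, nrow = K, ncol = n_sec, dimnames = list(ids, NULL))
  with_seed(derive_seed(cfg$seed, "counts", (replicate - 1L) * 3L + ax), {
    for (s in seq_len(n_sec)) {
      if (sum(probs[, s]) > 0) {
        counts[, s] <- stats::rmultinom(1, cfg$reads_per_section, probs[, s])
      }
    }
  })
  omp <- if (max(vol) > 0) round(cfg$reads_per_section * vol / max(vol)) else vol

  section_table(counts, omp, axis = axis,
                replicate_id = sprintf("rep%d", replicate),
                section_thickness = thick)
}

#' Construct a receptor-by-section abundance table
#'
#' @param values non-negative receptor x section matrix (counts or TPM) with
#'   receptor ids as row names.
#' @param omp per-section OMP abundance vector.
#' @param axis sectioning axis.
#' @param replicate_id replicate label.
#' @param section_positions per-section center coordinate (defaults to the
#'   1-based section index; section 1 is anterior/dorsal/medial).
#' @param section_thickness section thickness in micrometers.
#' @return An object of class `glom_sections`.
#' @export
section_table <- function(values, omp, axis, replicate_id = "rep1",
                          section_positions = NULL, section_thickness = 100) {
  check_axis(axis)
  values <- as.matrix(values)
  if (any(values < 0)) stopf("section table contains negative entries")
  if (length(omp) != ncol(values)) {
    stopf("`omp` length (%d) must equal the section count (%d)",
          length(omp), ncol(values))
  }
  if (any(omp < 0)) stopf("OMP vector contains negative entries")
  if (is.null(rownames(values))) stopf("`values` must carry receptor ids as row names")
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  structure(list(axis = axis, replicate_id = replicate_id, values = values,
                 omp = as.numeric(omp),
                 section_positions = section_positions %||% seq_len(ncol(values)),
                 section_thickness = section_thickness),
            class = "glom_sections")
}

#' @export
print.glom_sections <- function(x, ...) {
  cat(sprintf("Section table (%s, %s): %d receptors x %d sections, %.3g reads\n",
              x$axis, x$replicate_id, nrow(x$values), ncol(x$values),
              sum(x$values)))
  invisible(x)
}

#' Simulate a complete sectioning experiment
#'
#' Convenience wrapper generating the ground truth once and one section
#' table per axis and replicate.
#'
#' @param receptors data frame from [make_receptors()].
#' @param cfg a `glom_sim_config`.
#' @param scaffold optional pre-built scaffold.
#' @param n_replicates named integer vector: replicate animals per axis.
#'   The default mirrors the study design: six animals sectioned along AP,
#'   three each along DV and ML.
#' @return list with `truth`, `scaffold`, and `tables` (a list `AP`/`DV`/`ML`
#'   of per-replicate `glom_sections`).
#' @export
simulate_experiment <- function(receptors, cfg, scaffold = NULL,
                                n_replicates = c(AP = 6, DV = 3, ML = 3)) {
  if (is.null(scaffold)) {
    scaffold <- build_scaffold(cfg$sections_per_axis, cfg$section_thickness)
  }
  truth <- generate_ground_truth(receptors, scaffold, cfg)
  tables <- lapply(AXES, function(ax) {
    lapply(seq_len(n_replicates[[ax]]), function(r) {
      simulate_section_counts(truth, ax, cfg, scaffold, replicate = r,
                              quiet = TRUE)
    })
  })
  names(tables) <- AXES
  list(truth = truth, scaffold = scaffold, tables = tables)
}

# Amino-acid background frequencies (approximate vertebrate proteome usage).
aa_background_freq <- function() {
  c(A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, Q = 0.037,
    E = 0.058, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
    M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
    Y = 0.033, V = 0.068)
}

#' Generate a gapped protein alignment with planted position-linked residues
#'
#' Background columns draw residues i.i.d. from a fixed amino-acid frequency.
#' In signal columns the residue distribution is tilted toward a target
#' residue that walks along a physicochemical scale (the first principal
#' coordinate of the Grantham distance matrix, along which neighboring
#' residues are similar) with the receptor's AP rank `z` in \[0, 1\]:
#' sampling weights are proportional to
#' `background * exp(-effect * (D(residue, target(z))/100)^2)` with `D` the
#' Grantham distance, so the drawn residues' composition, polarity and
#' volume all shift monotonically with AP position and receptors of similar
#' position carry physicochemically similar residues. `effect = 0` recovers
#' the exchangeable null exactly. Optional gap injection never exceeds
#' `max_gap_fraction` per column.
#'
#' @param receptors data frame with receptor `id`s.
#' @param positions numeric AP mean position per receptor (same order).
#' @param n_columns alignment length.
#' @param signal_columns indices of position-linked columns; default: four
#'   consecutive columns in the middle of the alignment.
#' @param effect non-negative tilt strength; 0 = null.
#' @param max_gap_fraction per-column cap on the injected gap fraction.
#' @param inject_gaps logical; draw a per-column gap count up to the cap.
#' @param seed RNG seed.
#' @return list with `alignment` (named character vector of equal-length
#'   gapped sequences), `signal_columns`, and `positions`.
#' @export
generate_aligned_sequences <- function(receptors, positions, n_columns = 60,
                                       signal_columns = NULL, effect = 0,
                                       max_gap_fraction = 0.10,
                                       inject_gaps = FALSE, seed = 1) {
  if (effect < 0) stopf("`effect` must be non-negative")
  n <- nrow(receptors)
  if (length(positions) != n) stopf("`positions` must match `receptors`")
  if (is.null(signal_columns)) {
    start <- max(1L, floor(n_columns / 2) - 1L)
    signal_columns <- start:(start + 3L)
  }
  if (any(signal_columns < 1 | signal_columns > n_columns)) {
    stopf("`signal_columns` must lie within 1..n_columns")
  }
  bg <- aa_background_freq()
  gt <- grantham_table()
  D <- gt$matrix[names(bg), names(bg)]
  # 1D physicochemical path: first principal coordinate of the Grantham
  # matrix, oriented so tryptophan precedes cysteine (orientation of
  # cmdscale axes is arbitrary)
  pc1 <- stats::cmdscale(stats::as.dist(D), k = 1)[, 1]
  if (pc1["W"] > pc1["C"]) pc1 <- -pc1
  path_order <- names(sort(pc1))
  z <- (rank(positions, ties.method = "average") - 1) / max(n - 1, 1)
  target_res <- path_order[pmin(20L, pmax(1L, round(1 + z * 19)))]

  with_seed(derive_seed(seed, "sequences"), {
    mat <- matrix("", nrow = n, ncol = n_columns)
    for (j in seq_len(n_columns)) {
      if (effect > 0 && j %in% signal_columns) {
        for (i in seq_len(n)) {
          w <- bg * exp(-effect * (D[, target_res[i]] / 100)^2)
          mat[i, j] <- sample(names(bg), 1, prob = w)
        }
      } else {
        mat[, j] <- sample(names(bg), n, replace = TRUE, prob = bg)
      }
      if (inject_gaps && max_gap_fraction > 0) {
        n_gap <- sample.int(floor(max_gap_fraction * n) + 1L, 1L) - 1L
        if (n_gap > 0) mat[sample.int(n, n_gap), j] <- "-"
      }
    }
    aln <- apply(mat, 1, paste, collapse = "")
    names(aln) <- receptors$id
    list(alignment = aln, signal_columns = signal_columns,
         positions = positions)
  })
}
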