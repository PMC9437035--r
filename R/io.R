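# Readers and writers for the pipeline's plain-text interchange formats.

#' Write / read a receptor-by-section table as TSV
#'
#' Rows are receptors plus a reserved `OMP` row; columns are `s01..sNN`.
#'
#' @param table a `glom_sections` object.
#' @param path TSV path.
#' @param axis,replicate_id,section_thickness metadata to attach on read
#'   (the TSV itself stores only the matrix).
#' @return `read_section_table()` returns a `glom_sections`.
#' @export
write_section_table <- function(table, path) {
  m <- rbind(table$values, OMP = table$omp)
  df <- data.frame(receptor_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_section_table
#' @export
read_section_table <- function(path, axis, replicate_id = "rep1",
                               section_thickness = 100) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!"OMP" %in% rownames(m)) stopf("section table %s lacks the OMP row", path)
  omp <- m["OMP", ]
  values <- m[setdiff(rownames(m), "OMP"), , drop = FALSE]
  section_table(values, omp, axis = axis, replicate_id = replicate_id,
                section_thickness = section_thickness)
}

#' Write / read a ground-truth glomerular map as TSV
#'
#' @param truth a `glom_truth` data frame.
#' @param path TSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("glom_truth", "data.frame")
  out
}

#' Write / read a gapped protein alignment as FASTA
#'
#' @param alignment named character vector of gapped sequences (or the list
#'   from [generate_aligned_sequences()]).
#' @param path FASTA path.
#' @export
write_alignment <- function(alignment, path) {
  if (is.list(alignment) && !is.null(alignment$alignment)) {
    alignment <- alignment$alignment
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment), path)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write per-receptor mean positions as TSV
#'
#' @param matrices list of `glom_axis_matrix` objects (any mix of axes and
#'   replicates).
#' @param path TSV path.
#' @return invisibly, the written data frame (`receptor_id`, `axis`,
#'   `replicate`, `mean_position_sections`, `mean_position_um`).
#' @export
write_mean_positions <- function(matrices, path) {
  if (inherits(matrices, "glom_axis_matrix")) matrices <- list(matrices)
  df <- do.call(rbind, lapply(matrices, function(m) {
    data.frame(receptor_id = names(m$mean_position), axis = m$axis,
               replicate = m$replicate_id,
               mean_position_sections = unname(m$mean_position),
               mean_position_um = unname(m$mean_position_um),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write glomerulus assignments as TSV
#'
#' @param pairs a `glom_pairs` object (or a fitted `glom_map`).
#' @param path TSV path.
#' @export
write_assignments <- function(pairs, path) {
  if (inherits(pairs, "glom_map")) pairs <- pairs$pairs
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
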