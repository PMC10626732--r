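# Readers/writers for the delimited formats the pipeline exchanges.

#' Read/write a probes-by-samples matrix as tab-delimited text
#'
#' Probes are rows; the header carries sample ids; the first column,
#' `probe_id`, carries probe ids.
#'
#' @param path file path.
#' @param x numeric matrix with dimnames.
#' @return `read_beta_matrix()` returns a numeric matrix.
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(x, path) {
  df <- tibble::as_tibble(x, rownames = "probe_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read/write a sample sheet as CSV
#' @param path file path.
#' @param sheet sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Read/write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, s) paste(c(nm, d, s), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write probe annotation as a BED-like table
#'
#' 0-based half-open single-base intervals with columns chrom, start, end,
#' probe_id, design_class, context, promoter_id, gene_id.
#'
#' @param annotation probe annotation tibble.
#' @param path file path.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- annotation |>
    dplyr::transmute(chrom = .data$chrom, start = .data$position,
                     end = .data$position + 1L, probe_id = .data$probe_id,
                     design_class = .data$design_class,
                     context = .data$context,
                     snp_overlap = .data$snp_overlap,
                     cross_reactive = .data$cross_reactive,
                     promoter_id = .data$promoter_id,
                     gene_id = .data$gene_id)
  readr::write_tsv(bed, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  bed |>
    dplyr::transmute(probe_id = .data$probe_id, chrom = as.character(.data$chrom),
                     position = .data$start,
                     design_class = .data$design_class, context = .data$context,
                     snp_overlap = .data$snp_overlap,
                     cross_reactive = .data$cross_reactive,
                     promoter_id = .data$promoter_id, gene_id = .data$gene_id)
}

#' Write a truth record as JSON
#' @param truth truth record list from [simulate_cohort()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  truth$true_fractions <- as.data.frame(truth$true_fractions)
  truth$latent_causal <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
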