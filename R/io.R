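#' @name olfstate-io
#' @title Readers and writers for pipeline fixtures
#'
#' @description Plain-text interchange formats used throughout the pipeline:
#' long-format TSV for expression tables and atlases, CSV for recordings and
#' assay counts, multi-page TIFF for image stacks, and JSON sidecars for
#' ground truth and results. Every reader returns the in-memory
#' representation the analysis functions consume.
NULL

#' @describeIn olfstate-io Write an expression table (columns `gene_id`,
#'   `family`, `condition`, `replicate`, `abundance`) as TSV.
#' @param table,path,atlas,rec,counts,x Object to write / file path.
#' @export
write_expression_tsv <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @describeIn olfstate-io Read an expression table from TSV.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    family = readr::col_character(),
                    condition = readr::col_character(),
                    replicate = readr::col_integer(),
                    abundance = readr::col_double()
                  ))
}

#' @describeIn olfstate-io Write a binary atlas matrix as long TSV
#'   (`neuron`, `gene_id`, `expressed`).
#' @export
write_atlas_tsv <- function(atlas, path) {
  long <- tibble::tibble(
    neuron = rep(rownames(atlas), times = ncol(atlas)),
    gene_id = rep(colnames(atlas), each = nrow(atlas)),
    expressed = as.integer(atlas)
  )
  readr::write_tsv(long, path)
  invisible(path)
}

#' @describeIn olfstate-io Read a long-format atlas TSV back into a binary
#'   neuron x gene matrix.
#' @export
read_atlas_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  neurons <- unique(long$neuron)
  genes <- unique(long$gene_id)
  atlas <- matrix(0L, length(neurons), length(genes),
                  dimnames = list(neurons, genes))
  atlas[cbind(match(long$neuron, neurons), match(long$gene_id, genes))] <-
    as.integer(long$expressed)
  atlas
}

#' @describeIn olfstate-io Write a recording as CSV (`time_s`, `x_mm`,
#'   `y_mm`, `f_neuron`, `f_background`); lawn geometry, if present, goes to
#'   a JSON sidecar at `<path>.lawn.json`.
#' @export
write_recording_csv <- function(rec, path) {
  df <- tibble::tibble(
    time_s = rec$time,
    x_mm = if (is.null(rec$x)) NA_real_ else rec$x,
    y_mm = if (is.null(rec$y)) NA_real_ else rec$y,
    f_neuron = rec$f_neuron,
    f_background = rec$f_background
  )
  readr::write_csv(df, path)
  if (!is.null(rec$lawn)) {
    jsonlite::write_json(
      list(center = rec$lawn$center, radius = rec$lawn$radius,
           encounter_frame = rec$encounter_frame),
      paste0(path, ".lawn.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @describeIn olfstate-io Read a recording CSV (plus lawn sidecar when
#'   present) back into a [recording()].
#' @export
read_recording_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  lawn <- NULL
  encounter_frame <- NULL
  sidecar <- paste0(path, ".lawn.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    lawn <- list(center = as.numeric(meta$center), radius = meta$radius)
    if (!is.null(meta$encounter_frame) && !is.na(meta$encounter_frame)) {
      encounter_frame <- as.integer(meta$encounter_frame)
    }
  }
  has_xy <- !all(is.na(df$x_mm))
  recording(df$time_s, df$f_neuron, df$f_background,
            x = if (has_xy) df$x_mm else NULL,
            y = if (has_xy) df$y_mm else NULL,
            lawn = lawn, encounter_frame = encounter_frame)
}

#' @describeIn olfstate-io Write an image stack as a 16-bit multi-page TIFF.
#'   Intensities are stored on a 0-65535 count scale; values are rounded to
#'   the nearest count on write.
#' @export
write_stack_tiff <- function(x, path) {
  if (max(x) > 65535 || min(x) < 0) {
    stop("stack intensities must lie in [0, 65535] for 16-bit TIFF",
         call. = FALSE)
  }
  pages <- lapply(seq_len(dim(x)[1]), function(z) round(x[z, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @describeIn olfstate-io Read a multi-page TIFF back into a `(z, y, x)`
#'   array on the 0-65535 count scale.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) stack[z, , ] <- pages[[z]] * 65535
  stack
}

#' @describeIn olfstate-io Write assay counts as CSV.
#' @export
write_counts_csv <- function(counts, path) {
  readr::write_csv(tibble::as_tibble(counts), path)
  invisible(path)
}

#' @describeIn olfstate-io Read assay counts from CSV.
#' @export
read_counts_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @describeIn olfstate-io Write a ground-truth (or results) list as a JSON
#'   sidecar.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
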