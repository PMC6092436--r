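#' OTU count matrices
#'
#' The package's universal currency is an integer matrix of sequence counts
#' with OTUs as rows and samples as columns, carrying unique row and column
#' names. `as_count_matrix()` coerces and validates; `validate_count_matrix()`
#' checks the invariants (non-negative integer counts, unique ids) and errors
#' with the offending position otherwise.
#'
#' @param x a numeric matrix with OTU row names and sample column names, or a
#'   data frame whose first column holds OTU ids.
#' @return an integer matrix with `dimnames = list(otu_ids, sample_ids)`.
#' @export
as_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x)) abort("count matrix must be a matrix or data frame")
  storage.mode(x) <- "double"
  validate_count_matrix(x)
  storage.mode(x) <- "integer"
  x
}

#' @rdname as_count_matrix
#' @export
validate_count_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("count matrix must have OTU row names and sample column names")
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) abort(paste0("duplicate OTU id: ", dup[1]))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) abort(paste0("duplicate sample id: ", dup[1]))
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "counts must be non-negative integers; offending cell at OTU '%s', sample '%s'",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]
    ))
  }
  invisible(x)
}

#' Read an OTU count table
#'
#' Reads a wide tab-separated OTU table (first column `#OTU ID` or any id
#' column, remaining columns one per sample) or a BIOM file, into a validated
#' count matrix.
#'
#' @param path file path.
#' @param dialect `"tsv"` (wide tab-separated, the canonical dialect) or
#'   `"biom"` (read-only, requires the biomformat package).
#' @return an integer OTU x sample count matrix.
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(as_count_matrix(m))
  }
  df <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                        progress = FALSE, name_repair = "minimal")
  if (nrow(df) == 0L) abort("no data rows")
  cm <- as_count_matrix(as.data.frame(df, check.names = FALSE))
  message(sprintf("read %d OTUs x %d samples, %.0f total reads",
                  nrow(cm), ncol(cm), sum(cm)))
  cm
}

#' Write an OTU count table in the canonical tsv-wide dialect
#'
#' @param cm count matrix.
#' @param path output path; UTF-8, Unix newlines, first column `#OTU ID`.
#' @export
write_count_table <- function(cm, path) {
  validate_count_matrix(cm)
  df <- tibble(`#OTU ID` = rownames(cm))
  df <- dplyr::bind_cols(df, as_tibble(cm))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects columns `sample_id`, optionally `station`, `bay`, `layer`,
#' `latitude`, `longitude`, and any physico-chemical variables after them.
#' The delimiter (tab or comma) is sniffed from the header line.
#'
#' @param path file path.
#' @return a tibble, one row per sample; missing env values stay `NA`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  meta <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta a sample-metadata data frame to validate.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- as_tibble(meta)
  if (!"sample_id" %in% names(meta)) abort("metadata must have a sample_id column")
  meta$sample_id <- as.character(meta$sample_id)
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) abort(paste0("duplicate sample_id: ", dup[1]))
  for (cc in c("latitude", "longitude")) {
    if (cc %in% names(meta)) {
      v <- meta[[cc]]
      if (!is.numeric(v)) abort(sprintf("column %s must be numeric", cc))
      lim <- if (cc == "latitude") 90 else 180
      bad <- which(!is.na(v) & abs(v) > lim)
      if (length(bad)) {
        abort(sprintf("unparseable %s for sample %s", cc, meta$sample_id[bad[1]]))
      }
    }
  }
  meta
}

#' Names of the environmental variables in a metadata table
#'
#' Everything that is not an identifier, group, or coordinate column.
#' @param meta metadata tibble.
#' @export
env_vars <- function(meta) {
  setdiff(names(meta), c("sample_id", "station", "bay", "layer",
                         "latitude", "longitude"))
}

#' Drop singleton OTUs
#'
#' Removes OTUs whose total count across all samples equals exactly 1,
#' preserving the order of survivors.
#'
#' @param cm count matrix.
#' @export
drop_singletons <- function(cm) {
  validate_count_matrix(cm)
  keep <- rowSums(cm) != 1L
  out <- cm[keep, , drop = FALSE]
  if (nrow(out) == 0L) warn("all OTUs were singletons; returning a 0-row matrix")
  out
}

#' Rarefy all samples to an even sequencing depth
#'
#' Subsamples every sample (column) without replacement to exactly `depth`
#' reads — a multivariate hypergeometric draw per sample, the semantics of
#' MOTHUR's sub.sample and vegan's `rrarefy()` (which performs the draw).
#' Samples with fewer than `depth` reads are rejected, never padded.
#'
#' @param cm count matrix.
#' @param depth target reads per sample.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param prune_empty drop OTUs whose counts are all zero after subsampling?
#' @export
rarefy_even_depth <- function(cm, depth, seed = 1L, prune_empty = FALSE) {
  validate_count_matrix(cm)
  cs <- colSums(cm)
  low <- names(cs)[cs < depth]
  if (length(low)) {
    abort(sprintf("depth %d exceeds the reads of sample(s): %s",
                  as.integer(depth), paste(low, collapse = ", ")))
  }
  out <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(cm), sample = depth))))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(cm)
  if (prune_empty) out <- out[rowSums(out) > 0L, , drop = FALSE]
  out
}

#' Per-sample relative abundance
#'
#' @param cm count matrix with strictly positive column sums.
#' @return a numeric matrix whose columns each sum to 1.
#' @export
relative_abundance <- function(cm) {
  validate_count_matrix(cm)
  cs <- colSums(cm)
  zero <- names(cs)[cs == 0]
  if (length(zero)) {
    abort(sprintf("sample(s) with zero total reads: %s", paste(zero, collapse = ", ")))
  }
  sweep(cm, 2L, cs, "/")
}
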