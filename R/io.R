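## Plain-text readers and writers for the pipeline's tables and
## spectra: counts/expression TSV (first column gene_id), catalog and
## sample TSV, Compound Discoverer-style feature CSV, and MGF spectra.

#' Read / write a gene-by-sample matrix as TSV
#'
#' First column `gene_id`, remaining columns samples.
#'
#' @param path File path.
#' @param x Matrix to write.
#' @return `read_matrix_tsv`: numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write plain data-frame TSV (catalog, samples, truth tables)
#'
#' @param path File path.
#' @param x Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an LC-MS feature table CSV
#'
#' Compound Discoverer-style export: feature_id, formula, rt, mz, and
#' one column of raw areas per sample.
#'
#' @param path File path.
#' @param features Feature table.
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_feature_csv
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS2 spectra from an MGF file
#'
#' Minimal Mascot Generic Format support: `BEGIN IONS` / `END IONS`
#' blocks with `TITLE` (used as the precursor feature id), `PEPMASS`,
#' optional `RTINSECONDS`, and peak lines `mz intensity`.
#'
#' @param path MGF file.
#' @return Named list of peak matrices (`mz`, `intensity`) keyed by
#'   TITLE.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE; title <- NULL; peaks <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "BEGIN IONS") {
      in_block <- TRUE; title <- NULL; peaks <- list()
    } else if (ln == "END IONS") {
      if (is.null(title)) stop("MGF block without TITLE")
      m <- if (length(peaks)) do.call(rbind, peaks) else
        matrix(numeric(0), 0, 2)
      colnames(m) <- c("mz", "intensity")
      spectra[[title]] <- m
      in_block <- FALSE
    } else if (in_block && nzchar(ln)) {
      if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^[A-Z]+=", ln)) {
        ## other headers (PEPMASS, RTINSECONDS, CHARGE) ignored
      } else {
        parts <- as.numeric(strsplit(ln, "[[:space:]]+")[[1]])
        peaks[[length(peaks) + 1]] <- parts[1:2]
      }
    }
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra Named list of peak matrices.
#' @param path Output path.
#' @param precursors Optional data frame (feature_id, mz, rt) for
#'   PEPMASS / RTINSECONDS headers.
#' @export
write_mgf <- function(spectra, path, precursors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(spectra)) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", id), con)
    if (!is.null(precursors)) {
      row <- precursors[precursors$feature_id == id, , drop = FALSE]
      if (nrow(row) == 1) {
        writeLines(sprintf("PEPMASS=%.6f", row$mz), con)
        writeLines(sprintf("RTINSECONDS=%.4f", row$rt), con)
      }
    }
    m <- spectra[[id]]
    if (nrow(m) > 0)
      writeLines(sprintf("%.6f %.2f", m[, "mz"], m[, "intensity"]), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a simulated expression dataset to a directory
#'
#' Writes the outputs of [gen_expression_dataset()] in the same
#' formats the pipeline reads: counts.tsv, catalog.tsv, samples.tsv,
#' truth.tsv.
#'
#' @param dataset Output of [gen_expression_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(dataset$counts, file.path(dir, "counts.tsv"))
  write_table_tsv(dataset$catalog, file.path(dir, "catalog.tsv"))
  write_table_tsv(dataset$samples, file.path(dir, "samples.tsv"))
  write_table_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
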