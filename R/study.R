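#' Build a two-cohort abundance study
#'
#' Constructs the central `sna_study` object from a taxa-by-samples abundance
#' table and a sample metadata table assigning each sample to one of two
#' cohorts (reference, e.g. healthy controls, versus condition). Input
#' abundances may be counts or proportions; every sample column is
#' renormalised to proportions, since all downstream network and stiffness
#' computations operate on relative abundances.
#'
#' @param abundance Data frame whose first column holds taxon identifiers and
#'   whose remaining columns are numeric per-sample abundances, or the
#'   transposed layout (samples in the first column); the orientation is
#'   auto-detected by matching sample identifiers against `metadata`.
#'   A numeric matrix with taxa rownames and sample colnames is also accepted.
#' @param metadata Data frame whose first column holds sample identifiers and
#'   which contains `cohort_column`.
#' @param cohort_column Name of the metadata column with cohort labels.
#' @param ref_label Label in `cohort_column` to treat as the reference cohort
#'   (cohort A); the single other label becomes cohort B.
#'
#' @return An `sna_study`: a list with `taxa`, `samples`, `abundance`
#'   (taxa-by-samples matrix of proportions; columns sum to 1), `cohort`
#'   (named vector of `"A"`/`"B"`), and `cohort_labels` (original labels).
#' @export
#' @examples
#' ab <- data.frame(taxon = c("t1", "t2", "t3"),
#'                  s1 = c(5, 3, 2), s2 = c(1, 1, 2),
#'                  s3 = c(4, 4, 2), s4 = c(0, 6, 4))
#' md <- data.frame(sample = paste0("s", 1:4),
#'                  group = c("HC", "HC", "ASD", "ASD"))
#' sna_study(ab, md, cohort_column = "group", ref_label = "HC")
sna_study <- function(abundance, metadata, cohort_column = "cohort",
                      ref_label = NULL) {
  md <- as.data.frame(metadata)
  if (!cohort_column %in% names(md)) {
    abort(paste0("metadata has no column '", cohort_column, "'"))
  }
  md_samples <- as.character(md[[1]])
  labels <- as.character(md[[cohort_column]])
  if (anyDuplicated(md_samples)) {
    abort("duplicated sample identifiers in metadata")
  }

  mat <- orient_abundance(abundance, md_samples)

  missing <- setdiff(md_samples, colnames(mat))
  if (length(missing)) {
    abort(paste0("metadata samples absent from abundance table: ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(colnames(mat), md_samples)
  if (length(extra)) {
    warn(paste0("dropping ", length(extra),
                " table sample(s) absent from metadata: ",
                paste(head(extra, 5L), collapse = ", ")))
    mat <- mat[, md_samples, drop = FALSE]
  }
  mat <- mat[, md_samples, drop = FALSE]

  ulab <- unique(labels)
  if (length(ulab) != 2L) {
    abort(paste0("expected exactly 2 cohort labels, found: ",
                 paste(ulab, collapse = ", ")))
  }
  ref_label <- ref_label %||% ulab[1L]
  if (!ref_label %in% ulab) {
    abort(paste0("ref_label '", ref_label, "' not among cohort labels"))
  }
  other <- setdiff(ulab, ref_label)
  cohort <- setNames(ifelse(labels == ref_label, "A", "B"), md_samples)
  for (cc in c("A", "B")) {
    if (sum(cohort == cc) < 2L) {
      abort(paste0("cohort '", c(A = ref_label, B = other)[[cc]],
                   "' has fewer than 2 samples"))
    }
  }

  if (any(mat < 0)) abort("negative abundance values")
  zero_taxa <- rowSums(mat) == 0
  if (any(zero_taxa)) {
    warn(paste0("dropping ", sum(zero_taxa), " all-zero taxon/taxa: ",
                paste(head(rownames(mat)[zero_taxa], 5L), collapse = ", ")))
    mat <- mat[!zero_taxa, , drop = FALSE]
  }
  if (nrow(mat) == 0L) abort("no taxa with nonzero abundance")
  csum <- colSums(mat)
  if (any(csum == 0)) {
    abort(paste0("sample(s) with zero total abundance: ",
                 paste(colnames(mat)[csum == 0], collapse = ", ")))
  }
  mat <- sweep(mat, 2L, csum, "/")

  structure(
    list(taxa = rownames(mat), samples = colnames(mat), abundance = mat,
         cohort = cohort,
         cohort_labels = c(A = ref_label, B = other)),
    class = "sna_study"
  )
}

# Coerce a data frame / matrix to a taxa x samples numeric matrix, detecting
# whether samples are in columns or rows by matching metadata sample IDs.
orient_abundance <- function(abundance, md_samples) {
  if (is.matrix(abundance)) {
    if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
      abort("abundance matrix needs taxa rownames and sample colnames")
    }
    mat <- abundance
    storage.mode(mat) <- "double"
  } else {
    df <- as.data.frame(abundance)
    ids <- as.character(df[[1L]])
    body <- df[, -1L, drop = FALSE]
    bad <- !vapply(body, is.numeric, logical(1))
    if (any(bad)) {
      # tolerate character numerics, but report the first offending cell
      for (j in which(bad)) {
        conv <- suppressWarnings(as.numeric(as.character(body[[j]])))
        if (anyNA(conv)) {
          i <- which(is.na(conv))[1L]
          abort(paste0("non-numeric abundance value '", body[[j]][i],
                       "' at row ", i, ", column '", names(body)[j], "'"))
        }
        body[[j]] <- conv
      }
    }
    mat <- as.matrix(body)
    rownames(mat) <- ids
  }
  overlap_cols <- length(intersect(colnames(mat), md_samples))
  overlap_rows <- length(intersect(rownames(mat), md_samples))
  if (overlap_cols == 0L && overlap_rows == 0L) {
    abort("no metadata sample identifiers found in abundance table rows or columns")
  }
  if (overlap_rows > overlap_cols) mat <- t(mat)
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    abort(paste0("non-numeric or missing abundance value at taxon '",
                 rownames(mat)[idx[1L]], "', sample '",
                 colnames(mat)[idx[2L]], "'"))
  }
  mat
}

#' Read a two-cohort abundance study from files
#'
#' Reads a taxa-by-samples abundance table (TSV or CSV, orientation
#' auto-detected; a JSON BIOM file is accepted when the \pkg{biomformat}
#' package is installed) together with a sample metadata table, and builds an
#' [sna_study()].
#'
#' @param table_path Path to the abundance table (`.tsv`/`.txt`/`.csv`, or
#'   `.biom`).
#' @param metadata_path Path to the metadata table (TSV/CSV with header;
#'   first column = sample identifiers).
#' @param cohort_column,ref_label Passed to [sna_study()].
#' @return An `sna_study`.
#' @export
read_abundance <- function(table_path, metadata_path,
                           cohort_column = "cohort", ref_label = NULL) {
  if (!file.exists(table_path)) abort(paste0("no such file: ", table_path))
  if (!file.exists(metadata_path)) abort(paste0("no such file: ", metadata_path))
  md <- read_delim_auto(metadata_path)
  if (grepl("\\.biom$", table_path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading .biom files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(table_path)
    mat <- as.matrix(biomformat::biom_data(b))
    ab <- data.frame(taxon = rownames(mat), mat, check.names = FALSE)
  } else {
    ab <- read_delim_auto(table_path)
  }
  sna_study(ab, md, cohort_column = cohort_column, ref_label = ref_label)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"")
}

#' Write an abundance study back to plain-text files
#'
#' Inverse of [read_abundance()]: writes the (renormalised) abundance matrix
#' as a taxa-by-samples TSV and the cohort assignment as a metadata TSV, so
#' that reading the pair back reproduces the study.
#'
#' @param study An `sna_study`.
#' @param table_path,metadata_path Output paths (TSV).
#' @param cohort_column Metadata column name to write cohort labels under.
#' @return Invisibly, `study`.
#' @export
write_abundance <- function(study, table_path, metadata_path,
                            cohort_column = "cohort") {
  stopifnot(inherits(study, "sna_study"))
  df <- data.frame(taxon = study$taxa, study$abundance, check.names = FALSE)
  utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- data.frame(sample = study$samples,
                   stats::setNames(
                     list(unname(study$cohort_labels[study$cohort])),
                     cohort_column),
                   check.names = FALSE)
  utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' Restrict a study to one cohort
#'
#' @param study An `sna_study`.
#' @param cohort `"A"` (reference) or `"B"`.
#' @return An `sna_study`-like object containing only that cohort's samples
#'   (columns renormalised are untouched: they already sum to 1).
#' @export
cohort_subset <- function(study, cohort = c("A", "B")) {
  cohort <- match.arg(cohort)
  keep <- names(study$cohort)[study$cohort == cohort]
  out <- study
  out$samples <- keep
  out$abundance <- study$abundance[, keep, drop = FALSE]
  out$cohort <- study$cohort[keep]
  out
}

#' Per-taxon mean relative abundance of each cohort
#'
#' The node attribute used by the stiffness computations: for each taxon its
#' mean relative abundance within cohort A (`x_a`) and cohort B (`x_b`).
#'
#' @param study An `sna_study`.
#' @return A tibble with columns `taxon`, `x_a`, `x_b`.
#' @export
cohort_means <- function(study) {
  a <- study$abundance[, study$cohort == "A", drop = FALSE]
  b <- study$abundance[, study$cohort == "B", drop = FALSE]
  tibble(taxon = study$taxa,
         x_a = rowMeans(a),
         x_b = rowMeans(b))
}

#' @export
print.sna_study <- function(x, ...) {
  cat("<sna_study> ", length(x$taxa), " taxa x ", length(x$samples),
      " samples\n", sep = "")
  cat("  cohort A (", x$cohort_labels[["A"]], "): ",
      sum(x$cohort == "A"), " samples\n", sep = "")
  cat("  cohort B (", x$cohort_labels[["B"]], "): ",
      sum(x$cohort == "B"), " samples\n", sep = "")
  invisible(x)
}

#' Tidy an abundance study into long form
#'
#' @param x An `sna_study`.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `sample`, `cohort`, `abundance`.
#' @method tidy sna_study
#' @export
tidy.sna_study <- function(x, ...) {
  tibble(taxon = rep(x$taxa, times = length(x$samples)),
         sample = rep(x$samples, each = length(x$taxa)),
         cohort = rep(unname(x$cohort[x$samples]), each = length(x$taxa)),
         abundance = as.vector(x$abundance))
}

#' @method glance sna_study
#' @export
glance.sna_study <- function(x, ...) {
  tibble(n_taxa = length(x$taxa),
         n_samples = length(x$samples),
         n_a = sum(x$cohort == "A"),
         n_b = sum(x$cohort == "B"),
         sparsity = mean(x$abundance == 0))
}
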