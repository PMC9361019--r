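#' Read a gene expression matrix
#'
#' Reads a tab-separated log2 expression table (header row of sample ids,
#' first column gene ids) into a genes x samples numeric matrix. Duplicate
#' gene ids are collapsed by keeping the row with the highest mean
#' expression, the usual microarray convention; the number of dropped rows
#' is reported via `message()`.
#'
#' @param path path to a tab-separated expression file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("parse error: empty or malformed expression file: ", path)
  ids <- as.character(df[[1L]])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("format error: duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop("parse error: non-numeric cell at row ", bad,
           ", column '", samples[j], "'")
    }
  }
  X <- as.matrix(vals)
  if (anyNA(X)) stop("parse error: missing values in expression file")
  if (anyDuplicated(ids)) {
    means <- rowMeans(X)
    keep <- !logical(length(ids))
    for (id in unique(ids[duplicated(ids)])) {
      rows <- which(ids == id)
      keep[rows[-which.max(means[rows])]] <- FALSE
    }
    message("collapsed ", sum(!keep), " duplicate gene-id row(s) by max mean")
    X <- X[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  rownames(X) <- ids
  X
}

#' Write a gene expression matrix
#'
#' @param X genes x samples matrix (or SummarizedExperiment).
#' @param path output path; tab-separated with a `gene_id` first column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(X, path) {
  X <- .asExprMatrix(X, "X")
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line holds a set name, a description, and one or more member genes,
#' tab-separated. Duplicate members within a line are removed.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors, with a `"descriptions"`
#'   attribute (named character).
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("parse error: GMT line ", i, " has fewer than 3 fields")
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
    descs[parts[1L]] <- parts[2L]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a GMT gene-set file
#'
#' @param db named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character of per-set descriptions;
#'   defaults to the db's `"descriptions"` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(db, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(db, "descriptions")
  lines <- vapply(names(db), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm]))
      descriptions[[nm]] else "na"
    paste(c(nm, d, db[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with columns `sample_id`, `time_months`, `event` and
#' optionally `response` plus further covariates.
#'
#' @param path path to the table.
#' @return Validated data.frame.
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("format error: clinical table missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("format error: duplicate sample ids in clinical table")
  if (any(df$time_months < 0)) stop("format error: negative survival time")
  if (!all(df$event %in% c(0L, 1L)))
    stop("format error: event must be 0/1")
  df
}

#' Write a clinical table
#'
#' @param clinical data.frame as returned by [readClinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Mutation Annotation Format (MAF) table
#'
#' Requires the `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns; lines starting with `#` are skipped.
#'
#' @param path path to a tab-separated MAF file.
#' @return data.frame of the three required columns (plus any others).
#' @export
readMaf <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("format error: MAF missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

# MAF variant classes not counted as functional mutations.
.silentClasses <- c("Silent", "Intron", "IGR", "3'UTR", "5'UTR",
                    "3'Flank", "5'Flank", "RNA")

#' Per-gene mutation frequency from a MAF
#'
#' For each gene, the fraction of distinct samples carrying at least one
#' non-silent record. Returns the top genes by frequency plus all panel
#' genes (even when unmutated), ranked by frequency.
#'
#' @param maf data.frame from [readMaf()].
#' @param nSamples total number of samples in the cohort (denominator).
#' @param panel character vector of genes always reported.
#' @param topN number of top mutated genes reported (default 10).
#' @param excludeSilent drop silent/intronic/UTR/flank/RNA records first
#'   (default TRUE).
#' @return data.frame with columns `gene`, `n_mutated_samples`, `frequency`,
#'   sorted by decreasing frequency.
#' @export
mutationFrequency <- function(maf, nSamples, panel = character(),
                              topN = 10L, excludeSilent = TRUE) {
  if (nSamples < 1L) stop("domain error: nSamples must be >= 1")
  keep <- maf
  if (excludeSilent && nrow(maf)) {
    dropped <- maf$Variant_Classification %in% .silentClasses
    if (any(dropped))
      message("excluded ", sum(dropped), " silent-class record(s)")
    keep <- maf[!dropped, , drop = FALSE]
  }
  counts <- if (nrow(keep)) {
    tab <- tapply(keep$Tumor_Sample_Barcode, keep$Hugo_Symbol,
                  function(s) length(unique(s)))
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  top <- names(sort(counts, decreasing = TRUE))
  top <- utils::head(top, topN)
  genes <- union(top, panel)
  n <- vapply(genes, function(g) {
    if (g %in% names(counts)) counts[[g]] else 0L
  }, integer(1))
  out <- data.frame(gene = genes, n_mutated_samples = n,
                    frequency = n / nSamples, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene), , drop = FALSE]
}
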