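#' Binary alteration matrices
#'
#' An `alteration_matrix` holds the binary status (0/1, `NA` allowed) of a set
#' of cancer functional events (CFEs) across a cohort of samples, together
#' with per-sample annotations (cohort, cancer type, microsatellite
#' instability status). It is the universal feature object of the pipeline:
#' tumors and cell lines use the same representation.
#'
#' @param values integer or numeric matrix, samples in rows (rownames are
#'   sample ids), CFEs in columns (colnames are CFE ids); entries must be
#'   0, 1 or `NA`.
#' @param annotations data frame with columns `sample_id`, `cohort`
#'   (`"tumor"` or `"cell_line"`), `cancer_type` (non-empty label) and `msi`
#'   (`"MSI"`, `"MSS"` or `"unknown"`). Every matrix sample must be annotated;
#'   extra annotation rows are dropped.
#' @return an object of class `alteration_matrix`: a list with elements
#'   `values` (the validated integer matrix) and `annotations` (data frame
#'   aligned to the matrix rows).
#' @examples
#' v <- matrix(c(0, 1, 1, 0, 1, 0), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("TP53_mut", "EGFR_amp")))
#' ann <- data.frame(sample_id = paste0("s", 1:3), cohort = "cell_line",
#'                   cancer_type = "LUAD", msi = "MSS")
#' am <- alteration_matrix(v, ann)
#' dim(am$values)
#' @export
alteration_matrix <- function(values, annotations) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and CFE ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicated CFE ids in `values`")
  bad <- which(!(is.na(values) | values == 0 | values == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid entry '%s' at sample '%s', CFE '%s' (must be 0, 1 or NA)",
      format(values[bad[1, 1], bad[1, 2]]),
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  annotations <- validate_annotations(annotations)
  missing_ann <- setdiff(rownames(values), annotations$sample_id)
  if (length(missing_ann) > 0)
    stop("samples without annotation: ", paste(head(missing_ann, 5), collapse = ", "))
  annotations <- annotations[match(rownames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  storage.mode(values) <- "integer"
  structure(list(values = values, annotations = annotations),
            class = "alteration_matrix")
}

validate_annotations <- function(annotations) {
  req <- c("sample_id", "cohort", "cancer_type", "msi")
  if (!is.data.frame(annotations) || !all(req %in% names(annotations)))
    stop("annotations must contain columns: ", paste(req, collapse = ", "))
  annotations <- as.data.frame(annotations)[req]
  for (col in req) annotations[[col]] <- as.character(annotations[[col]])
  if (anyDuplicated(annotations$sample_id))
    stop("duplicated sample ids in annotations")
  if (!all(annotations$cohort %in% c("tumor", "cell_line")))
    stop("annotation `cohort` must be 'tumor' or 'cell_line'")
  if (any(is.na(annotations$cancer_type) | annotations$cancer_type == ""))
    stop("annotation `cancer_type` must be non-empty")
  if (!all(annotations$msi %in% c("MSI", "MSS", "unknown")))
    stop("annotation `msi` must be 'MSI', 'MSS' or 'unknown'")
  annotations
}

#' @export
print.alteration_matrix <- function(x, ...) {
  tab <- table(x$annotations$cohort)
  cat(sprintf("alteration_matrix: %d samples x %d CFEs (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  cancer types: %s\n",
              paste(sort(unique(x$annotations$cancer_type)), collapse = ", ")))
  invisible(x)
}

#' Read and write alteration matrices as TSV
#'
#' The on-disk format is a UTF-8 tab-delimited table: header row of CFE ids,
#' first column of sample ids, entries `0`, `1` or `NA`. Annotations travel in
#' a companion TSV with columns `sample_id`, `cohort`, `cancer_type`, `msi`.
#'
#' @param path path of the matrix TSV.
#' @param annotation_path path of the annotation TSV.
#' @return `read_alteration_matrix()` returns a validated
#'   [alteration_matrix()]; a malformed entry raises an error naming the
#'   offending sample and CFE, and matrix samples absent from the annotation
#'   table are rejected.
#' @export
read_alteration_matrix <- function(path, annotation_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "NA")
  sample_ids <- as.character(raw[[1]])
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- sample_ids
  suppressWarnings(storage.mode(values) <- "numeric")
  # re-check original text entries so a non-numeric token is reported by cell
  txt <- as.matrix(raw[, -1, drop = FALSE])
  ok <- matrix(txt %in% c("0", "1") | is.na(txt), nrow = nrow(txt))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid entry '%s' at sample '%s', CFE '%s' in %s",
                 txt[bad[1, 1], bad[1, 2]], sample_ids[bad[1, 1]],
                 colnames(values)[bad[1, 2]], path))
  }
  ann <- read_sample_annotations(annotation_path)
  alteration_matrix(values, ann)
}

#' @rdname read_alteration_matrix
#' @param x an [alteration_matrix()].
#' @export
write_alteration_matrix <- function(x, path, annotation_path = NULL) {
  stopifnot(inherits(x, "alteration_matrix"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(annotation_path))
    write.table(x$annotations, annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_alteration_matrix
#' @export
read_sample_annotations <- function(path) {
  validate_annotations(read.delim(path, stringsAsFactors = FALSE))
}

# internal: subset an alteration_matrix by sample ids, keeping annotations
subset_samples <- function(x, sample_ids) {
  alteration_matrix(x$values[sample_ids, , drop = FALSE],
                    x$annotations[x$annotations$sample_id %in% sample_ids, ,
                                  drop = FALSE])
}
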