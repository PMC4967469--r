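#' Catalogs of cancer functional events
#'
#' A `cfe_catalog` is the tumor-derived list of cancer functional events
#' (CFEs) with their per-cancer-type frequencies. It is the filter applied to
#' cell line alterations before any pharmacogenomic modeling: only events seen
#' recurrently in patient tumors are carried into the analysis.
#'
#' @param cfes data frame with columns `cfe_id` (unique), `cfe_class` (one of
#'   `"CG"`, `"RACS_amp"`, `"RACS_del"`, `"iCpG"`, `"fusion"`,
#'   `"pathway_activity"`) and optionally `locus_label`.
#' @param frequency data frame with columns `cfe_id`, `cancer_type`,
#'   `frequency` (tumor frequency in `[0, 1]`); every `cfe_id` must appear in
#'   `cfes`.
#' @param mode `"cancer_specific"` or `"pan_cancer"`.
#' @return an object of class `cfe_catalog`.
#' @export
cfe_catalog <- function(cfes, frequency, mode = c("cancer_specific", "pan_cancer")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cfes), all(c("cfe_id", "cfe_class") %in% names(cfes)))
  cfes <- as.data.frame(cfes)
  cfes$cfe_id <- as.character(cfes$cfe_id)
  cfes$cfe_class <- as.character(cfes$cfe_class)
  if (is.null(cfes$locus_label)) cfes$locus_label <- NA_character_
  if (anyDuplicated(cfes$cfe_id)) stop("duplicated CFE ids in catalog")
  if (!all(cfes$cfe_class %in% cfe_classes()))
    stop("cfe_class must be one of: ", paste(cfe_classes(), collapse = ", "))
  stopifnot(is.data.frame(frequency),
            all(c("cfe_id", "cancer_type", "frequency") %in% names(frequency)))
  frequency <- as.data.frame(frequency)[c("cfe_id", "cancer_type", "frequency")]
  frequency$cfe_id <- as.character(frequency$cfe_id)
  frequency$cancer_type <- as.character(frequency$cancer_type)
  frequency$frequency <- as.numeric(frequency$frequency)
  if (!all(frequency$cfe_id %in% cfes$cfe_id))
    stop("frequency table references CFE ids absent from the catalog")
  if (any(is.na(frequency$frequency) | frequency$frequency < 0 |
            frequency$frequency > 1))
    stop("frequencies must lie in [0, 1]")
  if (anyDuplicated(frequency[c("cfe_id", "cancer_type")]))
    stop("duplicated (cfe_id, cancer_type) frequency entries")
  rownames(cfes) <- rownames(frequency) <- NULL
  structure(list(cfes = cfes, frequency = frequency, mode = mode),
            class = "cfe_catalog")
}

cfe_classes <- function() {
  c("CG", "RACS_amp", "RACS_del", "iCpG", "fusion", "pathway_activity")
}

#' @export
print.cfe_catalog <- function(x, ...) {
  cat(sprintf("cfe_catalog (%s): %d CFEs, %d cancer types\n", x$mode,
              nrow(x$cfes), length(unique(x$frequency$cancer_type))))
  print(table(x$cfes$cfe_class))
  invisible(x)
}

#' Cancer types covered by each catalog entry
#'
#' @param catalog a [cfe_catalog()].
#' @return named list mapping each CFE id to the cancer types in which it is
#'   defined (i.e. has a tumor frequency entry).
#' @export
catalog_cancer_types <- function(catalog) {
  stopifnot(inherits(catalog, "cfe_catalog"))
  split(catalog$frequency$cancer_type, catalog$frequency$cfe_id)[catalog$cfes$cfe_id]
}

#' Merge cancer-specific catalogs into one pan-cancer catalog
#'
#' CFE ids are deduplicated, their cancer types unioned, and the per
#' (id, cancer type) tumor frequencies retained. The merge mirrors how
#' per-cancer-type event lists are pooled into a single pan-cancer event set.
#'
#' @param catalogs list of [cfe_catalog()] objects with mode
#'   `"cancer_specific"`.
#' @return a [cfe_catalog()] with mode `"pan_cancer"`. A CFE id appearing with
#'   two different classes raises a consistency error.
#' @export
merge_catalogs <- function(catalogs) {
  if (inherits(catalogs, "cfe_catalog")) catalogs <- list(catalogs)
  stopifnot(length(catalogs) >= 1,
            all(vapply(catalogs, inherits, logical(1), "cfe_catalog")))
  cfes <- do.call(rbind, lapply(catalogs, `[[`, "cfes"))
  cls <- tapply(cfes$cfe_class, cfes$cfe_id, unique)
  conflicts <- names(cls)[lengths(cls) > 1]
  if (length(conflicts) > 0)
    stop("conflicting cfe_class for: ", paste(head(conflicts, 5), collapse = ", "))
  cfes <- cfes[!duplicated(cfes$cfe_id), , drop = FALSE]
  cfes <- cfes[order(cfes$cfe_id), , drop = FALSE]
  freq <- do.call(rbind, lapply(catalogs, `[[`, "frequency"))
  freq <- freq[!duplicated(freq[c("cfe_id", "cancer_type")]), , drop = FALSE]
  freq <- freq[order(freq$cfe_id, freq$cancer_type), , drop = FALSE]
  cfe_catalog(cfes, freq, mode = "pan_cancer")
}

#' Filter cell line alterations by a tumor-derived catalog
#'
#' Restricts the columns of a cell line alteration matrix to the events in a
#' tumor-derived catalog, in catalog order. Catalog CFEs never observed in the
#' cell line panel become all-zero columns and are listed in the attached
#' coverage report, so downstream scans see a consistent feature universe.
#'
#' @param cell_line_alterations an [alteration_matrix()].
#' @param catalog a [cfe_catalog()].
#' @return the filtered [alteration_matrix()] with attribute `coverage`, a
#'   list with `n_catalog`, `n_present`, `fraction`
#'   (`n_present / n_catalog`) and `absent_cfes`. An empty intersection emits
#'   a warning and returns a matrix of all-zero columns with zero coverage.
#' @export
filter_by_catalog <- function(cell_line_alterations, catalog) {
  stopifnot(inherits(cell_line_alterations, "alteration_matrix"),
            inherits(catalog, "cfe_catalog"))
  ids <- catalog$cfes$cfe_id
  present <- intersect(ids, colnames(cell_line_alterations$values))
  if (length(present) == 0)
    warning("no catalog CFEs present in the cell line alteration matrix")
  out <- matrix(0L, nrow = nrow(cell_line_alterations$values),
                ncol = length(ids),
                dimnames = list(rownames(cell_line_alterations$values), ids))
  out[, present] <- cell_line_alterations$values[, present, drop = FALSE]
  res <- alteration_matrix(out, cell_line_alterations$annotations)
  attr(res, "coverage") <- list(
    n_catalog = length(ids),
    n_present = length(present),
    fraction = length(present) / length(ids),
    absent_cfes = setdiff(ids, present))
  res
}

#' Read and write CFE catalogs as TSV
#'
#' Columns: `cfe_id`, `cfe_class`, `cancer_types` (comma-joined), then one
#' `freq_<cancer type>` column per cancer type (empty when the CFE is not
#' defined in that type).
#'
#' @param catalog a [cfe_catalog()].
#' @param path file path.
#' @return `read_cfe_catalog()` returns a [cfe_catalog()].
#' @export
write_cfe_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "cfe_catalog"))
  types <- sort(unique(catalog$frequency$cancer_type))
  wide <- matrix(NA_real_, nrow = nrow(catalog$cfes), ncol = length(types),
                 dimnames = list(catalog$cfes$cfe_id, types))
  wide[cbind(match(catalog$frequency$cfe_id, catalog$cfes$cfe_id),
             match(catalog$frequency$cancer_type, types))] <-
    catalog$frequency$frequency
  ct <- vapply(catalog_cancer_types(catalog),
               function(x) paste(sort(x), collapse = ","), "")
  df <- data.frame(cfe_id = catalog$cfes$cfe_id,
                   cfe_class = catalog$cfes$cfe_class,
                   cancer_types = ct[catalog$cfes$cfe_id],
                   wide, check.names = FALSE)
  names(df)[-(1:3)] <- paste0("freq_", types)
  attr(df, "mode") <- catalog$mode
  write.table(cbind(mode = catalog$mode, df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cfe_catalog
#' @export
read_cfe_catalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  freq_cols <- grep("^freq_", names(df), value = TRUE)
  types <- sub("^freq_", "", freq_cols)
  long <- do.call(rbind, lapply(seq_along(freq_cols), function(i) {
    f <- df[[freq_cols[i]]]
    keep <- !is.na(f)
    data.frame(cfe_id = df$cfe_id[keep], cancer_type = types[i],
               frequency = f[keep])
  }))
  cfe_catalog(df[c("cfe_id", "cfe_class")], long, mode = unique(df$mode))
}
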