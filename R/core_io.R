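#' Construct an omics matrix
#'
#' A features-by-samples numeric matrix carrying its measurement kind.
#' Counts must be non-negative integers; intensities non-negative reals
#' (non-detects are zero-filled, matching common LC-MS table practice).
#'
#' @param values Numeric matrix with feature ids as rownames and sample ids
#'   as colnames.
#' @param kind Either `"counts"` or `"intensities"`.
#' @return The validated matrix with class `omics_matrix` and a `kind`
#'   attribute.
#' @export
omics_matrix <- function(values, kind = c("counts", "intensities")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("matrix must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate feature id: %s",
          rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicate sample id: %s",
          colnames(values)[duplicated(colnames(values))][1])
  }
  bad <- which(values < 0 | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("negative or non-finite value at feature '%s', sample '%s'",
          rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  }
  if (kind == "counts") {
    off <- which(values != round(values), arr.ind = TRUE)
    if (nrow(off)) {
      stopf("non-integer count at feature '%s', sample '%s'",
            rownames(values)[off[1, 1]], colnames(values)[off[1, 2]])
    }
  }
  structure(values, kind = kind, class = c("omics_matrix", class(values)))
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "kind") <- attr(x, "kind")
    class(out) <- class(x)
  }
  out
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

matrix_kind <- function(x) attr(x, "kind") %||% "intensities"

#' Read a features-by-samples TSV matrix
#'
#' Expects a header row of sample ids; the first column holds feature ids.
#' Tables must be rectangular; every data cell must parse as a non-negative
#' number (integer for counts).
#'
#' @param path Path to a tab-separated file.
#' @param kind `"counts"` or `"intensities"`.
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, kind = c("counts", "intensities")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          fill = FALSE, comment.char = "")
  if (ncol(df) < 2) stopf("matrix file '%s' has no sample columns", path)
  feats <- df[[1]]
  if (anyDuplicated(feats)) {
    stopf("duplicate feature id '%s' in %s", feats[duplicated(feats)][1], path)
  }
  samples <- colnames(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(feats, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stopf("non-numeric value '%s' at feature '%s', sample '%s'",
            col[bad[1]], feats[bad[1]], samples[j])
    }
    vals[, j] <- num
  }
  omics_matrix(vals, kind)
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(x, p))` returns `x`.
#'
#' @param matrix An [omics_matrix()] (or plain named numeric matrix).
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(feature_id = rownames(matrix),
                   as.data.frame(unclass(matrix), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (term id -> member gene ids).
#' @param descriptions Optional named character vector of term descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stopf("every gene set needs a term id")
  }
  if (anyDuplicated(names(sets))) {
    stopf("duplicate term id: %s", names(sets)[duplicated(names(sets))][1])
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) {
    stopf("empty gene set: %s", names(sets)[lengths(sets) == 0][1])
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, member counts %s\n",
              length(x$sets),
              if (length(x$sets)) paste0(min(lengths(x$sets)), "-",
                                         max(lengths(x$sets))) else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are collapsed with a warning; an empty file yields an empty
#' collection.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(list(sets = stats::setNames(list(), character()),
                          descriptions = stats::setNames(character(),
                                                         character())),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stopf("GMT line %d has fewer than 3 fields", short[1])
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(sets, function(g) sum(duplicated(g)), integer(1))
  if (any(ndup > 0)) {
    warnf("collapsed duplicated members in %d gene set(s) (e.g. '%s')",
          sum(ndup > 0), ids[ndup > 0][1])
  }
  gene_set_collection(stats::setNames(sets, ids),
                      stats::setNames(desc, ids))
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

METADATA_COLS <- c("sample_id", "dam_id", "group", "sex", "tissue", "assay")

#' Validate a sample-metadata table
#'
#' Required columns (exactly): sample_id, dam_id, group (GF/SPF),
#' sex (M/F), tissue, assay (transcriptome/metabolome). Sample ids must be
#' unique and a dam's group must be constant.
#'
#' @param metadata A data.frame.
#' @return The validated data.frame (character columns).
#' @export
validate_metadata <- function(metadata) {
  missing <- setdiff(METADATA_COLS, colnames(metadata))
  if (length(missing)) {
    stopf("metadata missing column(s): %s", paste(missing, collapse = ", "))
  }
  metadata <- metadata[, METADATA_COLS]
  for (cc in METADATA_COLS) metadata[[cc]] <- as.character(metadata[[cc]])
  if (anyDuplicated(metadata$sample_id)) {
    stopf("duplicate sample_id: %s",
          metadata$sample_id[duplicated(metadata$sample_id)][1])
  }
  if (!all(metadata$group %in% c("GF", "SPF"))) {
    stopf("group must be GF or SPF")
  }
  if (!all(metadata$sex %in% c("M", "F"))) stopf("sex must be M or F")
  if (!all(metadata$assay %in% c("transcriptome", "metabolome"))) {
    stopf("assay must be transcriptome or metabolome")
  }
  grp_per_dam <- tapply(metadata$group, metadata$dam_id,
                        function(g) length(unique(g)))
  if (any(grp_per_dam > 1)) {
    stopf("dam '%s' appears in more than one group",
          names(grp_per_dam)[grp_per_dam > 1][1])
  }
  metadata
}

#' Read sample metadata TSV
#' @param path Path to tab-separated metadata with the required columns.
#' @return Validated data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          fill = FALSE)
  validate_metadata(df)
}

#' Write sample metadata TSV
#' @param metadata Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(validate_metadata(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
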