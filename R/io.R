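#' Read a genes-by-samples expression matrix from TSV/CSV
#'
#' Expression values are expected on the log scale, genes in rows. The first
#' column holds gene identifiers, the header row holds sample identifiers
#' (a header cell for the gene-id column is accepted but not required).
#' Cells matching one of `na_tokens` (case-insensitive) are parsed as
#' "not detected" and stored as `NA`.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param na_tokens Character vector of tokens marking undetected values,
#'   matched case-insensitively after trimming whitespace.
#' @param transpose If `TRUE` the file is samples-by-genes and is transposed
#'   on read.
#' @return A numeric matrix, genes in rows, with `rownames` = gene ids and
#'   `colnames` = sample ids.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv"),
                                   na_tokens = c("", "na", "nan", "null"),
                                   transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  dat <- utils::read.table(path, sep = sep, skip = 1L, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(dat) == length(header)) {
    sample_ids <- header[-1L]
  } else if (ncol(dat) == length(header) + 1L) {
    # header row without a cell for the gene-id column
    sample_ids <- header
  } else {
    stop("header/data field counts disagree in ", path)
  }
  gene_ids <- dat[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample id(s) in header")
  vals <- as.matrix(dat[, -1L, drop = FALSE])
  tok <- tolower(trimws(vals))
  is_nd <- tok %in% tolower(na_tokens)
  num <- suppressWarnings(as.numeric(vals))
  bad <- !is_nd & is.na(num) & !is.na(vals)
  if (any(bad)) {
    stop("non-numeric cell(s) not in na_tokens, e.g. \"",
         vals[which(bad)[1L]], "\"")
  }
  num[is_nd] <- NA_real_
  m <- matrix(num, nrow = length(gene_ids),
              dimnames = list(gene_ids, sample_ids))
  if (transpose) m <- t(m)
  m
}

#' Write an expression matrix in the format [read_expression_matrix()] reads
#'
#' @param m Numeric matrix, genes in rows.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_expression_matrix <- function(m, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate genes within a line are counted once.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `display_name` attribute (named character vector of descriptions).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", lineno[which(nf < 3L)[1L]],
         " has fewer than 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  gene_set_collection(members,
                      display_name = stats::setNames(vapply(fields, `[[`, "", 2L), ids))
}

#' Construct a gene-set collection
#'
#' @param members Named list of character vectors (pathway id -> member genes).
#' @param display_name Optional named character vector of display names.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(members, display_name = NULL) {
  stopifnot(is.list(members))
  if (length(members) > 0L && is.null(names(members)))
    stop("members must be a named list")
  if (anyDuplicated(names(members))) stop("pathway ids must be unique")
  members <- lapply(members, function(g) unique(as.character(g)))
  if (is.null(display_name))
    display_name <- stats::setNames(names(members), names(members))
  structure(members, display_name = display_name[names(members)],
            class = c("gene_set_collection", "list"))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "pathways\n")
  if (length(x) > 0L) {
    sz <- lengths(x)
    cat("  member genes per pathway: min", min(sz), "median",
        stats::median(sz), "max", max(sz), "\n")
  }
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param gs A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(gs, path) {
  dn <- attr(gs, "display_name")
  if (is.null(dn)) dn <- stats::setNames(names(gs), names(gs))
  lines <- vapply(names(gs), function(id) {
    paste(c(id, dn[[id]], gs[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Remove genes undetected in a large fraction of samples
#'
#' A gene is dropped when the fraction of its samples flagged as not detected
#' (`NA`) reaches `frac`. The boundary is inclusive: a gene undetected in
#' exactly `frac` of the samples is removed. Sample set and the order of the
#' surviving genes are unchanged.
#'
#' @param m Expression matrix, genes in rows.
#' @param frac Removal threshold in (0, 1]; default 0.75.
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_undetected_genes <- function(m, frac = 0.75) {
  stopifnot(is.matrix(m))
  if (!(frac > 0 && frac <= 1)) stop("frac must be in (0, 1]")
  nd <- rowMeans(is.na(m))
  m[nd < frac, , drop = FALSE]
}

#' Restrict gene sets to measured genes
#'
#' Intersects every pathway's member set with the genes of an expression
#' matrix and drops pathways left with no measured member.
#'
#' @param gs A `gene_set_collection`.
#' @param m Expression matrix (its `rownames` define the measured genes), or a
#'   character vector of gene ids.
#' @return A restricted `gene_set_collection`.
#' @export
restrict_gene_sets <- function(gs, m) {
  genes <- if (is.matrix(m)) rownames(m) else as.character(m)
  members <- lapply(gs, function(g) g[g %in% genes])
  members <- members[lengths(members) > 0L]
  gene_set_collection(members, display_name = attr(gs, "display_name"))
}

#' Classify radiation doses into zero / low / high
#'
#' Doses of exactly 0 Gy are `ZERO`; doses in `(0, threshold]` are `LOW`;
#' doses above the threshold are `HIGH`. The default threshold of 0.1 Gy is
#' inclusive on the low side.
#'
#' @param dose_gy Numeric vector of non-negative doses in Gy, or a data frame
#'   with a `dose_gy` column (in which case a `dose_class` column is
#'   added/replaced).
#' @param threshold Low/high boundary in Gy; default 0.1.
#' @return A factor with levels `ZERO`, `LOW`, `HIGH` (or the annotated data
#'   frame).
#' @export
assign_dose_class <- function(dose_gy, threshold = 0.1) {
  if (is.data.frame(dose_gy)) {
    ann <- dose_gy
    stopifnot("dose_gy" %in% names(ann))
    ann$dose_class <- assign_dose_class(ann$dose_gy, threshold)
    return(ann)
  }
  if (any(is.na(dose_gy)) || any(dose_gy < 0)) stop("doses must be >= 0 Gy")
  if (threshold <= 0) stop("threshold must be positive")
  cls <- ifelse(dose_gy == 0, "ZERO", ifelse(dose_gy <= threshold, "LOW", "HIGH"))
  factor(cls, levels = c("ZERO", "LOW", "HIGH"))
}

#' Read per-sample annotations
#'
#' Expects a TSV with columns `sample_id`, `donor_id`, `dose_gy`; a
#' `dose_class` column is derived from the dose.
#'
#' @param path Path to the annotation TSV.
#' @param threshold Low/high dose boundary in Gy.
#' @return Data frame with columns `sample_id`, `donor_id`, `dose_gy`,
#'   `dose_class`.
#' @export
read_sample_annotation <- function(path, threshold = 0.1) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("sample_id", "donor_id", "dose_gy")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotations")
  assign_dose_class(ann, threshold)
}

#' Write per-sample annotations
#' @param ann Annotation data frame.
#' @param path Output path.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample z-scoring (optional)
#'
#' Centers and scales each sample (column) to mean 0, sd 1, ignoring `NA`s.
#' Off by default everywhere in the workflow: inputs are assumed to be
#' already normalized, log-scale expression.
#'
#' @param m Expression matrix, genes in rows.
#' @return The column-standardized matrix.
#' @export
zscore_samples <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  sd <- apply(m, 2L, stats::sd, na.rm = TRUE)
  sd[sd == 0 | is.na(sd)] <- 1
  sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
}
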