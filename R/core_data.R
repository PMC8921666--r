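#' Expression matrix container
#'
#' A light container for gene-level log2 expression: a numeric matrix with
#' genes in rows and cell lines (samples) in columns, plus an optional
#' per-sample tissue annotation. Gene and sample identifiers must be unique
#' and the matrix must be complete (no missing values) — radiosensitivity
#' models downstream assume a dense, gene-collapsed matrix.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene symbols)
#'   and colnames (sample identifiers).
#' @param tissue optional character vector of tissue labels, named by sample
#'   identifier; samples without a label may be omitted or NA.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, tissue = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "),
         " (collapse probes to genes first)")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  tis <- rep(NA_character_, ncol(values))
  names(tis) <- colnames(values)
  if (!is.null(tissue)) {
    if (is.null(names(tissue))) stop("`tissue` must be named by sample id")
    keep <- intersect(names(tissue), colnames(values))
    tis[keep] <- as.character(tissue[keep])
  }
  structure(list(values = values, tissue = tis), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d tissue-labelled)\n",
              nrow(x$values), ncol(x$values), sum(!is.na(x$tissue))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

n_genes <- function(em) nrow(em$values)
n_samples <- function(em) ncol(em$values)

#' Radiosensitivity table
#'
#' One radiosensitivity endpoint value per cell line, with tissue labels.
#' Two endpoints are supported: SF2, the surviving fraction after a 2 Gy
#' dose (a fraction in (0, 1]) and MID, the mean inactivation dose in Gy
#' (positive). A table is homogeneous in endpoint kind.
#'
#' @param sample_id character cell-line identifiers (unique).
#' @param value numeric endpoint values.
#' @param tissue character tissue labels (NA allowed).
#' @param endpoint "SF2" or "MID".
#' @return a data.frame of class `rs_table` with attribute `endpoint`.
#' @export
rs_table <- function(sample_id, value, tissue = NA_character_,
                     endpoint = c("SF2", "MID")) {
  endpoint <- match.arg(endpoint)
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in RS table")
  if (anyNA(value)) stop("missing endpoint values")
  if (endpoint == "SF2" && any(value <= 0 | value > 1))
    stop("SF2 values must lie in (0, 1]")
  if (endpoint == "MID" && any(value <= 0))
    stop("MID values must be positive")
  out <- data.frame(sample_id = sample_id, value = as.numeric(value),
                    tissue = rep_len(as.character(tissue), length(sample_id)),
                    stringsAsFactors = FALSE)
  attr(out, "endpoint") <- endpoint
  class(out) <- c("rs_table", "data.frame")
  out
}

#' @export
print.rs_table <- function(x, ...) {
  cat(sprintf("rs_table: %d cell lines, endpoint %s\n",
              nrow(x), attr(x, "endpoint")))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

endpoint_kind <- function(rs) attr(rs, "endpoint")

#' Gene signature
#'
#' A named gene multiset used as a joint predictor of radiosensitivity.
#' Duplicate gene symbols are allowed and counted by `size` — resampled
#' control signatures are drawn with replacement, so duplicates are a real
#' feature of the null model, not an error.
#'
#' @param name signature name.
#' @param genes character vector of gene symbols (duplicates allowed).
#' @param source provenance: "published", "process", "proliferation" or
#'   "resampled".
#' @return an object of class `rs_signature`.
#' @export
rs_signature <- function(name, genes,
                         source = c("published", "process", "proliferation",
                                    "resampled")) {
  source <- match.arg(source)
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) < 1L) stop("signature '", name, "' has no genes")
  structure(list(name = as.character(name), genes = genes, source = source,
                 size = length(genes)),
            class = "rs_signature")
}

#' @export
print.rs_signature <- function(x, ...) {
  cat(sprintf("rs_signature '%s' (%s): %d genes (%d distinct)\n",
              x$name, x$source, x$size, length(unique(x$genes))))
  invisible(x)
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene-expression matrix from delimited text
#'
#' Expects one header row of identifiers and one leading identifier column;
#' all remaining cells must be numeric (log2-scale intensities). The file may
#' be laid out either genes x samples (default) or transposed.
#'
#' @param path TSV (default) or CSV file; delimiter chosen by extension.
#' @param layout "genes_by_samples" or "samples_by_genes".
#' @param tissue optional named character vector of tissue labels.
#' @return an [expr_matrix].
#' @export
read_expression <- function(path,
                            layout = c("genes_by_samples", "samples_by_genes"),
                            tissue = NULL) {
  layout <- match.arg(layout)
  raw <- utils::read.table(path, sep = .delim_for(path), header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("expected an id column plus at least one data column")
  ids <- trimws(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 m[idx[1L], idx[2L]], ids[idx[1L]], colnames(m)[idx[2L]],
                 path))
  }
  dimnames(num) <- list(ids, colnames(m))
  if (layout == "samples_by_genes") num <- t(num)
  expr_matrix(num, tissue = tissue)
}

#' Write an expression matrix to delimited text
#'
#' Values are serialised with 9 significant digits so a write/read round trip
#' reproduces them exactly at the printed precision and output files are
#' byte-stable across runs.
#'
#' @param em an [expr_matrix].
#' @param path output TSV/CSV path (delimiter chosen by extension).
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene_id = rownames(em$values),
                   apply(em$values, 2L, function(col)
                     formatC(col, digits = 9, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(em$values))
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' Probe sets mapping to the same gene symbol are averaged (unweighted
#' arithmetic mean of probe rows); probes with no gene mapping are dropped.
#' Symbols are matched case-sensitively after whitespace trimming.
#'
#' @param values numeric matrix, probes x samples, with unique probe rownames.
#' @param probe_to_gene character vector of gene symbols named by probe id;
#'   NA or empty entries mark unmapped probes.
#' @param tissue optional tissue labels passed through.
#' @return an [expr_matrix]; the number of excluded probes is attached as
#'   attribute `n_excluded_probes`.
#' @export
collapse_probes <- function(values, probe_to_gene, tissue = NULL) {
  if (!is.matrix(values) || is.null(rownames(values)))
    stop("`values` must be a matrix with probe rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate probe identifiers")
  map <- trimws(as.character(probe_to_gene[rownames(values)]))
  mapped <- !is.na(map) & nzchar(map) & map != "NA"
  if (!any(mapped)) stop("no probes could be mapped to gene symbols")
  n_excluded <- sum(!mapped)
  sub <- values[mapped, , drop = FALSE]
  gene <- map[mapped]
  # group-by mean via an indicator matrix: rows in file order of first occurrence
  ugenes <- unique(gene)
  g <- match(gene, ugenes)
  counts <- tabulate(g, nbins = length(ugenes))
  sums <- rowsum(sub, group = g, reorder = FALSE)
  out <- sums / counts
  rownames(out) <- ugenes
  em <- expr_matrix(out, tissue = tissue)
  attr(em, "n_excluded_probes") <- n_excluded
  em
}

#' Read gene signatures from GMT or one-gene-per-line text
#'
#' GMT records are tab-separated: name, description, then member genes.
#' Duplicate genes within a record are kept (the signature size counts them).
#' For "lines" format the whole file is one signature named after the file
#' stem.
#'
#' @param path input file.
#' @param format "gmt" or "lines".
#' @param source provenance label applied to every signature read.
#' @return a list of [rs_signature] objects.
#' @export
read_signatures <- function(path, format = c("gmt", "lines"),
                            source = "published") {
  format <- match.arg(format)
  if (format == "lines") {
    genes <- trimws(readLines(path))
    genes <- genes[nzchar(genes)]
    nm <- sub("\\.[^.]*$", "", basename(path))
    return(list(rs_signature(nm, genes, source = source)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT record '", f[1L], "' has no genes")
    genes <- trimws(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) < 1L) stop("GMT record '", f[1L], "' has no genes")
    rs_signature(f[1L], genes, source = source)
  })
}

#' Write signatures to a GMT file
#' @param sigs list of [rs_signature] objects.
#' @param path output path.
#' @param descriptions optional character vector of record descriptions.
#' @export
write_gmt <- function(sigs, path, descriptions = NULL) {
  if (inherits(sigs, "rs_signature")) sigs <- list(sigs)
  desc <- if (is.null(descriptions)) vapply(sigs, `[[`, "", "source")
          else rep_len(descriptions, length(sigs))
  lines <- vapply(seq_along(sigs), function(i)
    paste(c(sigs[[i]]$name, desc[i], sigs[[i]]$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Align an expression matrix and a radiosensitivity table
#'
#' Restricts both to their shared cell lines, in a common order. Whole-panel
#' modelling needs a minimum overlap (default 10; 3-fold cross-validation is
#' meaningless below that), configurable for small examples.
#'
#' @param em an [expr_matrix].
#' @param rs an [rs_table].
#' @param min_shared minimum number of shared sample ids (default 10).
#' @return list with elements `em`, `rs` (restricted, same sample order) and
#'   `dropped` (counts dropped from each input).
#' @export
align_samples <- function(em, rs, min_shared = 10L) {
  stopifnot(inherits(em, "expr_matrix"), inherits(rs, "rs_table"))
  shared <- intersect(colnames(em$values), rs$sample_id)
  if (length(shared) < min_shared)
    stop(sprintf("only %d shared samples (minimum %d)",
                 length(shared), min_shared))
  em2 <- expr_matrix(em$values[, shared, drop = FALSE],
                     tissue = em$tissue[shared])
  rs2 <- rs[match(shared, rs$sample_id), , drop = FALSE]
  rownames(rs2) <- NULL
  attr(rs2, "endpoint") <- attr(rs, "endpoint")
  class(rs2) <- class(rs)
  list(em = em2, rs = rs2,
       dropped = c(em = ncol(em$values) - length(shared),
                   rs = nrow(rs) - length(shared)))
}

#' Read a radiosensitivity table from CSV
#'
#' Expects columns `sample_id`, `value` and optionally `tissue`.
#'
#' @param path CSV file.
#' @param endpoint "SF2" or "MID" (the file does not declare it).
#' @return an [rs_table].
#' @export
read_rs_table <- function(path, endpoint = c("SF2", "MID")) {
  endpoint <- match.arg(endpoint)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "value")
  if (!all(need %in% names(df)))
    stop("RS table must have columns sample_id and value")
  rs_table(df$sample_id, df$value,
           tissue = if ("tissue" %in% names(df)) df$tissue else NA_character_,
           endpoint = endpoint)
}

#' Write a radiosensitivity table to CSV
#' @param rs an [rs_table].
#' @param path output CSV path.
#' @export
write_rs_table <- function(rs, path) {
  df <- as.data.frame(rs)
  df$value <- formatC(df$value, digits = 9, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
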