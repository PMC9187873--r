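#' Single-cell count matrix with per-cell metadata
#'
#' Container for a genes x cells matrix of non-negative expression values
#' together with aligned gene and cell identifiers and per-cell metadata
#' (batch label, optional clone, cycle phase, and -- for synthetic fixtures --
#' the true subpopulation).  All downstream stages consume this type; joins
#' with bulk or signature matrices are always by gene id, never by position.
#'
#' @param counts genes x cells matrix (base or \pkg{Matrix} sparse),
#'   non-negative.  Raw counts unless `normalized = TRUE`.
#' @param gene_ids unique gene identifiers, one per row.  Defaults to
#'   `rownames(counts)`.
#' @param cell_ids unique cell identifiers, one per column.  Defaults to
#'   `colnames(counts)`.
#' @param cell_meta optional data.frame of per-cell metadata; matched to
#'   `cell_ids` by its `cell_id` column (or row names).  Cells without a
#'   metadata row get `NA` fields.
#' @param normalized logical flag; `TRUE` once values are CPM-normalised.
#' @return an object of class `cell_matrix` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`, `normalized`.
#' @export
cell_matrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts), cell_meta = NULL,
                        normalized = FALSE) {
  .assert(!is.null(gene_ids) && !is.null(cell_ids),
          "cell_matrix: gene and cell identifiers are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  .assert(length(gene_ids) == nrow(counts) && length(cell_ids) == ncol(counts),
          "cell_matrix: identifier lengths (%d genes, %d cells) do not match matrix [%d x %d]",
          length(gene_ids), length(cell_ids), nrow(counts), ncol(counts))
  .assert(!anyDuplicated(gene_ids), "cell_matrix: duplicated gene ids")
  .assert(!anyDuplicated(cell_ids), "cell_matrix: duplicated cell ids")
  .assert(min(counts) >= 0, "cell_matrix: negative entries are not allowed")
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  if (!is.null(cell_meta)) {
    cm <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
    if (is.null(cm$cell_id)) cm$cell_id <- rownames(cm)
    .assert(!anyDuplicated(cm$cell_id), "cell_matrix: duplicated cell ids in metadata")
    meta <- merge(meta, cm, by = "cell_id", all.x = TRUE, sort = FALSE)
    meta <- meta[match(cell_ids, meta$cell_id), , drop = FALSE]
  }
  rownames(meta) <- NULL
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = meta, normalized = isTRUE(normalized)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (x$normalized) "normalised" else "raw counts"))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Bulk expression matrix
#'
#' Genes x samples matrix of bulk expression values with an explicit scale
#' flag.  Deconvolution refuses matrices still flagged `log2`; use
#' [delog()] first.
#'
#' @param values genes x samples numeric matrix.
#' @param gene_ids,sample_ids identifiers; default to dimnames.
#' @param scale `"linear"` or `"log2"`.
#' @param normalized logical; `TRUE` once columns are CPM-normalised.
#' @return object of class `bulk_matrix`.
#' @export
bulk_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values),
                        scale = c("linear", "log2"), normalized = FALSE) {
  scale <- match.arg(scale)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  .assert(length(gene_ids) == nrow(values) && length(sample_ids) == ncol(values),
          "bulk_matrix: identifier lengths do not match matrix dimensions")
  .assert(!anyDuplicated(gene_ids), "bulk_matrix: duplicated gene ids")
  .assert(!anyDuplicated(sample_ids), "bulk_matrix: duplicated sample ids")
  values <- .as_dense(values)
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 scale = scale, normalized = isTRUE(normalized)),
            class = "bulk_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat(sprintf("<bulk_matrix> %d genes x %d samples, scale=%s%s\n",
              length(x$gene_ids), length(x$sample_ids), x$scale,
              if (x$normalized) " (CPM)" else ""))
  invisible(x)
}

#' Per-sample screen metadata
#'
#' One row per bulk sample: perturbagen id, concentration (micromolar),
#' time (hours), plate id, control flag and replicate group.  The replicate
#' group collects the treated samples whose compositions are averaged in the
#' susceptibility formula; plate-matched controls define the control mean.
#'
#' @param df data.frame with columns `sample_id`, `pert_id`, `dose_um`,
#'   `time_h`, `plate`, `is_control`, `replicate_group` (missing ones are
#'   created where derivable; controls may carry NA pert fields).
#' @return validated data.frame of class `sample_meta`.
#' @export
sample_meta <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  .assert(!is.null(df$sample_id), "sample_meta: sample_id column required")
  .assert(!anyDuplicated(df$sample_id), "sample_meta: duplicated sample ids")
  if (is.null(df$is_control)) df$is_control <- FALSE
  for (col in c("pert_id", "plate")) if (is.null(df[[col]])) df[[col]] <- NA_character_
  for (col in c("dose_um", "time_h")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  df$is_control <- as.logical(df$is_control)
  treated <- df[!df$is_control, , drop = FALSE]
  if (nrow(treated)) {
    ok <- !is.na(treated$pert_id) & !is.na(treated$dose_um) &
      !is.na(treated$time_h) & !is.na(treated$plate)
    .assert(all(ok), "sample_meta: treated samples missing perturbagen/dose/time/plate: %s",
            paste(treated$sample_id[!ok], collapse = ", "))
  }
  if (is.null(df$replicate_group)) {
    df$replicate_group <- ifelse(df$is_control,
                                 paste0("control@", df$plate),
                                 paste(df$pert_id, df$dose_um, df$time_h, sep = "@"))
  }
  grp <- df[!df$is_control, c("replicate_group", "pert_id", "dose_um", "time_h")]
  if (nrow(grp)) {
    n_distinct <- tapply(paste(grp$pert_id, grp$dose_um, grp$time_h),
                         grp$replicate_group, function(z) length(unique(z)))
    .assert(all(n_distinct == 1L),
            "sample_meta: replicate groups mixing different conditions: %s",
            paste(names(n_distinct)[n_distinct != 1L], collapse = ", "))
  }
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read a 10x-style sparse count triplet
#'
#' Reads a MatrixMarket coordinate file plus one-id-per-line feature and
#' barcode files (the layout CellRanger emits) into a [cell_matrix()].
#'
#' @param matrix_path MatrixMarket `.mtx` file (genes x cells).
#' @param features_path,barcodes_path text files, one identifier per line
#'   (a features file may be multi-column TSV; the first column is used).
#' @param meta_path optional TSV of per-cell metadata keyed by barcode
#'   (column `cell_id` or first column).
#' @return a [cell_matrix()] with ids in file order.
#' @export
read_sparse_counts <- function(matrix_path, features_path, barcodes_path,
                               meta_path = NULL) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  bcs <- readLines(barcodes_path)
  bcs <- bcs[nzchar(bcs)]
  .assert(length(feats) == nrow(m),
          "read_sparse_counts: %d features but matrix header declares %d rows",
          length(feats), nrow(m))
  .assert(length(bcs) == ncol(m),
          "read_sparse_counts: %d barcodes but matrix header declares %d columns",
          length(bcs), ncol(m))
  .assert(!anyDuplicated(bcs), "read_sparse_counts: duplicate barcodes")
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (is.null(meta$cell_id)) names(meta)[1L] <- "cell_id"
  }
  cell_matrix(methods::as(m, "CsparseMatrix"), gene_ids = feats, cell_ids = bcs,
              cell_meta = meta)
}

#' Read a GCT 1.3 text file
#'
#' Parses the `#1.3` text dialect (header sentinel, dimensions line, row and
#' column annotation blocks).  Recognised column annotations (`pert_id` /
#' `pert_iname`, `pert_dose`, `pert_time`, `det_plate` / `plate`,
#' `is_control`) are mapped onto a [sample_meta()] table.
#'
#' @param path GCT file.
#' @param scale scale flag to stamp on the result; L1000-style level-3 input
#'   is log2 by default and must be passed through [delog()] before
#'   deconvolution.
#' @return list with elements `bulk` ([bulk_matrix()]) and `meta`
#'   ([sample_meta()] or `NULL` when no annotations are recognised).
#' @export
read_gct <- function(path, scale = "log2") {
  lines <- readLines(path)
  .assert(length(lines) >= 3L && grepl("^#1\\.3", lines[1L]),
          "read_gct: missing '#1.3' sentinel in %s", path)
  dims <- as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]])
  .assert(length(dims) >= 2L && !anyNA(dims[1:2]), "read_gct: malformed dimensions line")
  nr <- dims[1L]; nc <- dims[2L]
  nrmeta <- if (length(dims) >= 3L) dims[3L] else 0L
  ncmeta <- if (length(dims) >= 4L) dims[4L] else 0L
  header <- strsplit(lines[3L], "\t")[[1L]]
  sample_ids <- header[(2L + nrmeta):(1L + nrmeta + nc)]
  col_ann <- list()
  if (ncmeta > 0L) {
    for (i in seq_len(ncmeta)) {
      fields <- strsplit(lines[3L + i], "\t")[[1L]]
      col_ann[[fields[1L]]] <- fields[(2L + nrmeta):(1L + nrmeta + nc)]
    }
  }
  body <- lines[(4L + ncmeta):length(lines)]
  body <- body[nzchar(body)]
  .assert(length(body) == nr,
          "read_gct: dimensions line declares %d data rows but body has %d",
          nr, length(body))
  parts <- strsplit(body, "\t")
  gene_ids <- vapply(parts, `[[`, character(1), 1L)
  vals <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[(2L + nrmeta):(1L + nrmeta + nc)]))
    v
  }, numeric(nc)))
  if (nc == 1L) vals <- matrix(vals, ncol = 1L)
  .assert(!anyNA(vals), "read_gct: non-numeric value in data block")
  bulk <- bulk_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids,
                      scale = scale)
  meta <- NULL
  if (length(col_ann)) {
    pick <- function(...) {
      for (nm in c(...)) if (!is.null(col_ann[[nm]])) return(col_ann[[nm]])
      NULL
    }
    md <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
    md$pert_id <- pick("pert_id", "pert_iname") %||% NA_character_
    md$dose_um <- suppressWarnings(as.numeric(pick("pert_dose", "dose_um") %||% NA))
    md$time_h <- suppressWarnings(as.numeric(pick("pert_time", "time_h") %||% NA))
    md$plate <- pick("det_plate", "plate") %||% NA_character_
    ic <- pick("is_control")
    md$is_control <- if (is.null(ic)) {
      !is.na(md$pert_id) & md$pert_id %in% c("DMSO", "ctl_vehicle", "control")
    } else ic %in% c("1", "TRUE", "true", "yes")
    rg <- pick("replicate_group")
    if (!is.null(rg)) md$replicate_group <- rg
    meta <- tryCatch(sample_meta(md), error = function(e) NULL)
  }
  list(bulk = bulk, meta = meta)
}

#' Write a bulk matrix (plus optional metadata) as GCT 1.3
#'
#' @param bulk a [bulk_matrix()].
#' @param path output file.
#' @param meta optional [sample_meta()]; written as column annotations.
#' @return `path`, invisibly.
#' @export
write_gct <- function(bulk, path, meta = NULL) {
  nc <- length(bulk$sample_ids)
  ann <- list()
  if (!is.null(meta)) {
    m <- meta[match(bulk$sample_ids, meta$sample_id), , drop = FALSE]
    ann <- list(pert_id = as.character(m$pert_id),
                pert_dose = as.character(m$dose_um),
                pert_time = as.character(m$time_h),
                det_plate = as.character(m$plate),
                is_control = as.character(as.integer(m$is_control)),
                replicate_group = as.character(m$replicate_group))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(length(bulk$gene_ids), nc, 0L, length(ann), sep = "\t"), con)
  writeLines(paste(c("id", bulk$sample_ids), collapse = "\t"), con)
  for (nm in names(ann)) {
    writeLines(paste(c(nm, ann[[nm]]), collapse = "\t"), con)
  }
  body <- cbind(bulk$gene_ids,
                format(bulk$values, trim = TRUE, digits = 15, scientific = FALSE))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense expression table
#'
#' TSV/CSV with one identifier column and a numeric body; the result is
#' always genes x columns regardless of the input orientation.
#'
#' @param path table file; `.csv` is comma-separated, anything else tab.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @param as one of `"bulk"` (default) or `"cells"`.
#' @param scale scale flag for bulk output.
#' @return [bulk_matrix()] or [cell_matrix()].
#' @export
read_dense_table <- function(path,
                             orientation = c("genes_in_rows", "genes_in_columns"),
                             as = c("bulk", "cells"), scale = "linear") {
  orientation <- match.arg(orientation)
  as <- match.arg(as)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "genes_in_columns") m <- t(m)
  .assert(!anyDuplicated(rownames(m)), "read_dense_table: duplicated gene ids")
  if (as == "bulk") {
    bulk_matrix(m, scale = scale)
  } else {
    cell_matrix(m)
  }
}

#' Write a pipeline result object as annotated TSV
#'
#' Writes a [composition_table()], [susceptibility_table()] result,
#' [greedy_cocktail()] result or signature matrix as a TSV whose leading
#' `#` comment lines record the package version, result kind and parameter
#' fingerprint.  [read_results()] reconstructs the object.
#'
#' @param object the result object.
#' @param path output file.
#' @param params optional named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, params = NULL) {
  UseMethod("write_results")
}

#' @export
write_results.composition_table <- function(object, path, params = NULL) {
  df <- data.frame(sample_id = rownames(object$fractions),
                   object$fractions, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(object$diagnostics)) {
    df <- cbind(df, object$diagnostics[match(df$sample_id,
                                             object$diagnostics$sample_id),
                                       setdiff(names(object$diagnostics), "sample_id"),
                                       drop = FALSE])
  }
  .write_tsv_with_header(df, path, "composition_table", params)
}

#' @export
write_results.susceptibility_table <- function(object, path, params = NULL) {
  df <- object$pct
  add <- function(mat, prefix) {
    colnames(mat) <- paste0(prefix, ".", colnames(mat))
    mat
  }
  df <- cbind(df,
              add(object$susceptibility, "susceptibility"),
              add(object$consistency, "consistency"),
              add(object$killed * 1L, "killed"))
  .write_tsv_with_header(df, path, "susceptibility_table", params)
}

#' @export
write_results.cocktail <- function(object, path, params = NULL) {
  df <- object$selections
  if (nrow(df) == 0L) {
    df <- data.frame(step = integer(), pert_id = character(),
                     dose_um = numeric(), time_h = numeric(),
                     kills = character(), stringsAsFactors = FALSE)
  }
  attr(df, "residual") <- NULL
  p <- c(params, list(residual = paste(object$residual, collapse = ";")))
  .write_tsv_with_header(df, path, "cocktail", p)
}

#' @export
write_results.signature_matrix <- function(object, path, params = NULL) {
  df <- data.frame(gene_id = object$gene_ids, object$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv_with_header(df, path, "signature_matrix",
                         c(params, object$provenance))
}

#' Read back a TSV written by [write_results()]
#'
#' @param path TSV file with `# kind:` header.
#' @return the reconstructed object (class depends on the recorded kind).
#' @export
read_results <- function(path) {
  parsed <- .read_tsv_with_header(path)
  kind_line <- grep("^# kind:", parsed$header, value = TRUE)
  .assert(length(kind_line) == 1L, "read_results: no kind header in %s", path)
  kind <- trimws(sub("^# kind:", "", kind_line))
  tab <- parsed$table
  switch(kind,
    composition_table = {
      diag_cols <- intersect(c("rmse", "r", "p_value", "nu"), names(tab))
      frac_cols <- setdiff(names(tab), c("sample_id", diag_cols))
      fr <- as.matrix(tab[, frac_cols, drop = FALSE])
      rownames(fr) <- tab$sample_id
      diagnostics <- if (length(diag_cols)) {
        cbind(data.frame(sample_id = tab$sample_id, stringsAsFactors = FALSE),
              tab[, diag_cols, drop = FALSE])
      } else NULL
      composition_table(fr, diagnostics)
    },
    susceptibility_table = {
      take <- function(prefix) {
        cols <- grep(paste0("^", prefix, "\\."), names(tab), value = TRUE)
        m <- as.matrix(tab[, cols, drop = FALSE])
        colnames(m) <- sub(paste0("^", prefix, "\\."), "", cols)
        m
      }
      pct_cols <- setdiff(names(tab),
                          grep("^(susceptibility|consistency|killed)\\.",
                               names(tab), value = TRUE))
      structure(list(pct = tab[, pct_cols, drop = FALSE],
                     susceptibility = take("susceptibility"),
                     consistency = take("consistency"),
                     killed = take("killed") > 0),
                class = "susceptibility_table")
    },
    cocktail = {
      params_line <- grep("^# params:", parsed$header, value = TRUE)
      residual <- character()
      if (length(params_line)) {
        p <- jsonlite::fromJSON(sub("^# params:", "", params_line))
        if (!is.null(p$residual) && nzchar(p$residual))
          residual <- strsplit(p$residual, ";")[[1L]]
      }
      structure(list(selections = tab, residual = residual), class = "cocktail")
    },
    signature_matrix = {
      vals <- as.matrix(tab[, -1L, drop = FALSE])
      rownames(vals) <- tab$gene_id
      signature_matrix(vals)
    },
    .stopf("read_results: unknown kind '%s'", kind))
}
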