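# TSV readers/writers for the handful of bespoke table layouts the tool
# exchanges: multi-block time-series tables, steady-state matrices, edge
# lists, decay-rate tables, regulator lists and knockout matrices.
# Dialect: tab-delimited, "." decimal, "#"-prefixed comment lines
# skipped, no quoting, no missing values. The multi-block layout (one
# block per experiment, separated by a blank line or a time reset) has
# no standard reader, so parsing is done line-by-line with row-numbered
# errors.

read_tsv_rows <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#")
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  list(rows = rows, line_no = which(keep))
}

is_blank_row <- function(rows) {
  vapply(rows, function(r) {
    length(r) == 0L || (length(r) == 1L && !nzchar(r[1]))
  }, logical(1))
}

check_ragged <- function(rows, line_no, width, path) {
  widths <- lengths(rows)
  blank <- is_blank_row(rows)
  bad <- which(widths != width & !blank)
  if (length(bad) > 0L) {
    stop("ragged row in ", path, ": line ", line_no[bad[1]], " has ",
         widths[bad[1]], " fields, expected ", width)
  }
  blank
}

parse_numeric_cell <- function(txt, line, col, path) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- is.na(v) & !is.na(txt)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-numeric value \"", txt[i], "\" in ", path, " at line ",
         line[i], ", column ", col[i])
  }
  v
}

#' Read one or more expression time series from a TSV file
#'
#' The file holds a header row (`Time` followed by gene names, matched
#' case-insensitively and canonicalized to `Time` on write) and one row
#' per sampled time point. Several experiments may share one file: a new
#' block starts at a blank line, or wherever the time value drops below
#' its predecessor (the usual layout for benchmark perturbation files,
#' where each experiment restarts at t = 0).
#'
#' @param path Path to the TSV file.
#' @return A list of [expression_series()], one per block, sharing the
#'   header's gene order.
#' @export
read_time_series <- function(path) {
  parsed <- read_tsv_rows(path)
  rows <- parsed$rows; line_no <- parsed$line_no
  if (length(rows) == 0L) stop("empty time-series file: ", path)
  header <- rows[[1]]
  if (length(header) < 2L || tolower(trimws(header[1])) != "time") {
    stop("time-series header must be \"Time\" followed by gene names: ", path)
  }
  genes <- trimws(header[-1])
  if (any(!nzchar(genes))) stop("empty gene name in header of ", path)
  if (anyDuplicated(genes)) {
    stop("duplicate gene name in header of ", path, ": ",
         genes[duplicated(genes)][1])
  }
  body <- rows[-1]; body_lines <- line_no[-1]
  blank <- check_ragged(body, body_lines, length(header), path)

  series <- list(); cur_t <- numeric(0); cur_x <- list()
  flush <- function() {
    if (length(cur_t) == 0L) return()
    if (length(cur_t) < 2L) {
      stop("time-series block with fewer than 2 time points in ", path,
           " (no regression sample derivable)")
    }
    vals <- do.call(rbind, cur_x)
    colnames(vals) <- genes
    series[[length(series) + 1L]] <<- expression_series(
      cur_t, vals, label = paste0("series_", length(series) + 1L))
    cur_t <<- numeric(0); cur_x <<- list()
  }
  for (i in seq_along(body)) {
    if (blank[i]) { flush(); next }
    v <- parse_numeric_cell(body[[i]], rep(body_lines[i], length(header)),
                            seq_along(header), path)
    if (length(cur_t) > 0L && v[1] <= cur_t[length(cur_t)]) flush()
    cur_t <- c(cur_t, v[1])
    cur_x[[length(cur_x) + 1L]] <- v[-1]
  }
  flush()
  if (length(series) == 0L) stop("no data rows in ", path)
  series
}

align_genes <- function(mat, genes, path) {
  have <- colnames(mat)
  if (setequal(have, genes)) return(mat[, genes, drop = FALSE])
  miss <- setdiff(genes, have); extra <- setdiff(have, genes)
  stop("gene set in ", path, " does not match the run's genes",
       if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
       if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
}

read_matrix_tsv <- function(path, what) {
  parsed <- read_tsv_rows(path)
  rows <- parsed$rows; line_no <- parsed$line_no
  if (length(rows) < 2L) stop("empty ", what, " file: ", path)
  header <- trimws(rows[[1]])
  body <- rows[-1]; body_lines <- line_no[-1]
  blank <- is_blank_row(body)
  body <- body[!blank]; body_lines <- body_lines[!blank]
  if (length(body) == 0L) stop("empty ", what, " file: ", path)
  # a label column may be declared in the header, or present only in the
  # body (non-numeric first field, one extra field per row)
  first_field <- body[[1]][1]
  labelled <- !nzchar(header[1]) ||
    tolower(header[1]) %in% c("condition", "label", "name", "gene") ||
    is.na(suppressWarnings(as.numeric(first_field)))
  header_has_label <- labelled && length(body[[1]]) == length(header)
  genes <- if (header_has_label) header[-1] else header
  if (any(!nzchar(genes))) stop("empty gene name in header of ", path)
  if (anyDuplicated(genes)) stop("duplicate gene name in header of ", path)
  width <- length(genes) + labelled
  bad <- which(lengths(body) != width)
  if (length(bad) > 0L) {
    stop("ragged row in ", path, ": line ", body_lines[bad[1]], " has ",
         length(body[[bad[1]]]), " fields, expected ", width)
  }
  labels <- character(0)
  vals <- matrix(0, nrow = length(body), ncol = length(genes),
                 dimnames = list(NULL, genes))
  for (i in seq_along(body)) {
    r <- body[[i]]
    if (labelled) { labels <- c(labels, r[1]); r <- r[-1] }
    vals[i, ] <- parse_numeric_cell(r, rep(body_lines[i], length(r)),
                                    seq_along(r) + labelled, path)
  }
  rownames(vals) <- if (labelled) labels else paste0(what, "_", seq_len(nrow(vals)))
  vals
}

#' Read a steady-state expression matrix
#'
#' TSV with gene names as header (an optional leading label column is
#' detected from the header) and one row per experimental condition.
#' When `genes` is given, columns are realigned to that canonical order
#' and any mismatch in the gene set is an error.
#'
#' @param path Path to the TSV file.
#' @param genes Optional canonical gene order to align to.
#' @return Numeric matrix, conditions x genes.
#' @export
read_steady_state <- function(path, genes = NULL) {
  vals <- read_matrix_tsv(path, "condition")
  if (!is.null(genes)) vals <- align_genes(vals, genes, path)
  vals
}

#' Read a gold-standard edge list
#'
#' Two- or three-column TSV `regulator TAB target [TAB indicator]`. With
#' an indicator column only rows flagged `1` are kept; without one every
#' row is an edge. Duplicates are collapsed and self-edges dropped with
#' a warning.
#'
#' @param path Path to the TSV file.
#' @param genes Optional gene universe; unknown names are an error.
#' @return Tibble with columns `regulator`, `target`.
#' @export
read_edge_list <- function(path, genes = NULL) {
  parsed <- read_tsv_rows(path)
  rows <- parsed$rows; line_no <- parsed$line_no
  blank <- is_blank_row(rows)
  rows <- rows[!blank]; line_no <- line_no[!blank]
  if (length(rows) == 0L) stop("empty edge list: ", path)
  if (!all(lengths(rows) %in% 2:3)) {
    bad <- which(!lengths(rows) %in% 2:3)[1]
    stop("edge list rows must have 2 or 3 fields; line ", line_no[bad],
         " of ", path, " has ", lengths(rows)[bad])
  }
  reg <- vapply(rows, `[`, character(1), 1L)
  tgt <- vapply(rows, `[`, character(1), 2L)
  ind <- vapply(rows, function(r) if (length(r) >= 3L) r[3] else "1", character(1))
  ind <- parse_numeric_cell(ind, line_no, rep(3L, length(ind)), path)
  if (!is.null(genes)) {
    unknown <- setdiff(union(reg, tgt), genes)
    if (length(unknown) > 0L) {
      stop("unknown gene name(s) in ", path, ": ", paste(unknown, collapse = ", "))
    }
  }
  keep <- ind == 1
  reg <- reg[keep]; tgt <- tgt[keep]
  self <- reg == tgt
  if (any(self)) {
    warning("dropping ", sum(self), " self-edge(s) from ", path)
    reg <- reg[!self]; tgt <- tgt[!self]
  }
  dplyr::distinct(tibble::tibble(regulator = reg, target = tgt))
}

#' Write a link ranking to TSV
#'
#' Emits `regulator TAB target TAB weight`, sorted by decreasing weight
#' with ties broken lexicographically by (regulator, target), weights
#' printed with 10 significant digits. Deterministic: rewriting the same
#' ranking gives a byte-identical file.
#'
#' @param ranking A `link_ranking` or the tibble from [rank_edges()].
#' @param path Output path.
#' @param top_n Optional cap on the number of rows written.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, top_n = NULL) {
  edges <- if (inherits(ranking, "link_ranking")) rank_edges(ranking) else ranking
  stopifnot(all(c("regulator", "target", "weight") %in% names(edges)))
  if (!is.null(top_n)) edges <- utils::head(edges, top_n)
  lines <- sprintf("%s\t%s\t%.10g", edges$regulator, edges$target, edges$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Read per-gene decay rates
#'
#' Two-column TSV `gene TAB rate` (a header row is detected and
#' skipped). Genes absent from the file receive the median of the
#' provided rates, the usual fallback when a measured mRNA decay rate
#' could not be retrieved for a gene.
#'
#' @param path Path to the TSV file.
#' @param genes Canonical gene vector to fill.
#' @return A tibble with columns `gene`, `alpha`, `source` (`"user"` or
#'   `"median_fill"`).
#' @export
read_decay_rates <- function(path, genes) {
  parsed <- read_tsv_rows(path)
  rows <- parsed$rows; line_no <- parsed$line_no
  blank <- is_blank_row(rows)
  rows <- rows[!blank]; line_no <- line_no[!blank]
  if (length(rows) == 0L) stop("empty decay-rate file: ", path)
  if (any(lengths(rows) != 2L)) {
    bad <- which(lengths(rows) != 2L)[1]
    stop("decay-rate rows must have 2 fields; line ", line_no[bad], " of ", path)
  }
  g <- vapply(rows, `[`, character(1), 1L)
  v_txt <- vapply(rows, `[`, character(1), 2L)
  if (is.na(suppressWarnings(as.numeric(v_txt[1])))) { # header row
    rows <- rows[-1]; g <- g[-1]; v_txt <- v_txt[-1]; line_no <- line_no[-1]
  }
  v <- parse_numeric_cell(v_txt, line_no, rep(2L, length(v_txt)), path)
  if (any(v <= 0)) {
    stop("non-positive decay rate for gene ", g[which(v <= 0)[1]], " in ", path)
  }
  unknown <- setdiff(g, genes)
  if (length(unknown) > 0L) {
    stop("unknown gene name(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  alpha <- stats::setNames(rep(NA_real_, length(genes)), genes)
  alpha[g] <- v
  filled <- unname(is.na(alpha))
  alpha[filled] <- stats::median(v)
  tibble::tibble(gene = genes, alpha = unname(alpha),
                 source = ifelse(filled, "median_fill", "user"))
}

#' Read a candidate-regulator list
#'
#' One regulator name per line.
#'
#' @param path Path to the file.
#' @param genes Optional gene universe; unknown names are an error.
#' @return Character vector of regulator names.
#' @export
read_regulators <- function(path, genes = NULL) {
  parsed <- read_tsv_rows(path)
  rows <- parsed$rows[!is_blank_row(parsed$rows)]
  regs <- trimws(vapply(rows, `[`, character(1), 1L))
  regs <- regs[nzchar(regs)]
  if (length(regs) == 0L) stop("empty regulator list: ", path)
  if (!is.null(genes)) {
    unknown <- setdiff(regs, genes)
    if (length(unknown) > 0L) {
      stop("unknown regulator name(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  unique(regs)
}

#' Read a systematic single-knockout matrix
#'
#' TSV with gene names as header and one labelled row per experiment:
#' a row labelled with gene name `g` holds the steady-state expression
#' after deleting `g`, and a row labelled `wild_type` (or `wt`) holds
#' the unperturbed steady state. Every gene must be knocked out exactly
#' once.
#'
#' @param path Path to the TSV file.
#' @param genes Optional canonical gene order to align to.
#' @return List with `ko_values` (p x p matrix, row i = knockout of gene
#'   i) and `wild_type` (named vector).
#' @export
read_knockout_matrix <- function(path, genes = NULL) {
  vals <- read_matrix_tsv(path, "knockout")
  if (!is.null(genes)) vals <- align_genes(vals, genes, path)
  g <- colnames(vals)
  lab <- rownames(vals)
  wt_row <- which(tolower(lab) %in% c("wild_type", "wildtype", "wt"))
  if (length(wt_row) != 1L) stop("knockout file must contain exactly one wild_type row: ", path)
  ko <- vals[-wt_row, , drop = FALSE]
  missing <- setdiff(g, rownames(ko))
  if (length(missing) > 0L) {
    stop("knockout matrix is incomplete; no knockout row for gene(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(rownames(ko), g)
  if (length(extra) > 0L) {
    stop("knockout rows for unknown gene(s): ", paste(extra, collapse = ", "))
  }
  list(ko_values = ko[g, , drop = FALSE], wild_type = vals[wt_row, ])
}

#' Write a list of expression series to a multi-block TSV
#'
#' Inverse of [read_time_series()]: one block per series, blank-line
#' separated, header `Time` + gene names, values with 10 significant
#' digits.
#'
#' @param series An `expression_series` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(series, path) {
  series <- as_series_list(series)
  genes <- series_genes(series)
  out <- paste(c("Time", genes), collapse = "\t")
  for (s in series) {
    rows <- vapply(seq_along(s$times), function(k) {
      paste(sprintf("%.10g", c(s$times[k], s$values[k, ])), collapse = "\t")
    }, character(1))
    out <- c(out, rows, "")
  }
  writeLines(out[-length(out)], path)
  invisible(path)
}

#' Write a gene-by-column numeric matrix to TSV
#'
#' Header = optional label column + gene names; one row per condition.
#'
#' @param mat Numeric matrix with gene column names.
#' @param path Output path.
#' @param label_col Name for the leading row-label column, or `NULL` to
#'   omit labels.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, label_col = "condition") {
  stopifnot(!is.null(colnames(mat)))
  header <- paste(c(if (!is.null(label_col)) label_col, colnames(mat)),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    vals <- sprintf("%.10g", mat[i, ])
    paste(c(if (!is.null(label_col)) rownames(mat)[i], vals), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
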