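#' Construct a validated expression matrix
#'
#' An `expr_matrix` is a numeric genes x conditions matrix carrying the
#' molecular level it was measured at and whether its condition axis is
#' ordered (a time course / life-cycle series) or an unordered sample
#' panel.  Ordered data are a prerequisite for any nonzero delay in the
#' downstream scan.
#'
#' Validation enforces: unique non-empty gene identifiers as rownames, at
#' least 3 conditions, and at least one finite value per row.  Rows with
#' no finite value are rejected: they are dropped with a warning and
#' listed in the `"rejected"` attribute rather than silently discarded.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   conditions in columns (colnames = condition labels).
#' @param level `"mRNA"` or `"protein"`.
#' @param ordered logical; `TRUE` for ordered conditions.
#' @return an object of class `expr_matrix`.
#' @seealso [read_expression()], [write_expression()], [align_levels()]
#' @export
expression_matrix <- function(values, level = c("mRNA", "protein"),
                              ordered = TRUE) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (ncol(values) < 3L)
    stop("an expression matrix needs at least 3 conditions, got ",
         ncol(values), call. = FALSE)
  ids <- rownames(values)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("rownames must hold non-empty gene identifiers", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cond", seq_len(ncol(values)))
  bad <- rowSums(is.finite(values)) == 0L
  rejected <- character(0)
  if (any(bad)) {
    rejected <- ids[bad]
    warning(sum(bad), " row(s) with no finite value rejected: ",
            paste(rejected, collapse = ", "), call. = FALSE)
    values <- values[!bad, , drop = FALSE]
    if (nrow(values) == 0L)
      stop("no valid rows remain", call. = FALSE)
  }
  structure(values, level = level, ordered = isTRUE(ordered),
            rejected = rejected, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix (%s level): %d genes x %d %s conditions\n",
              attr(x, "level"), nrow(x), ncol(x),
              if (attr(x, "ordered")) "ordered" else "unordered"))
  n <- min(nrow(x), 6L)
  print(unclass(x)[seq_len(n), , drop = FALSE], ...)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more rows)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of condition labels and gene identifiers in the
#' first column.  Cells holding the token `NA` (or empty cells) are
#' treated as missing; any other non-numeric cell is a structured error
#' naming the offending gene and condition.
#'
#' @param path path to the file.
#' @param level,ordered passed to [expression_matrix()].
#' @param sep field delimiter; tab by default, use `","` for CSV.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, level = c("mRNA", "protein"),
                            ordered = TRUE, sep = "\t") {
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L)
    stop("malformed header in ", path,
         ": need a gene-id column plus >= 3 condition columns", call. = FALSE)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells == "" | cells == "NA"] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                 dimnames = dimnames(cells)))
  broken <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(broken)) {
    k <- broken[1L, ]
    stop(sprintf("non-numeric cell '%s' at gene '%s', condition '%s' in %s",
                 cells[k[1L], k[2L]], ids[k[1L]],
                 colnames(cells)[k[2L]], path), call. = FALSE)
  }
  rownames(vals) <- ids
  expression_matrix(vals, level = level, ordered = ordered)
}

#' Write an expression matrix as delimited text
#'
#' Values are written with 17 significant digits so that a
#' [read_expression()] round-trip reproduces them exactly.
#'
#' @param x an `expr_matrix` (or plain numeric matrix with dimnames).
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = "\t") {
  chr <- vapply(as.vector(x), function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out <- matrix(chr, nrow = nrow(x),
                dimnames = list(rownames(x), colnames(x)))
  df <- data.frame(gene_id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene identity map
#'
#' Maps mRNA row identifiers to protein row identifiers for same-gene
#' analysis.  The file is two-column delimited text with a header.
#'
#' @param path path to the file.
#' @param sep field delimiter.
#' @return data.frame with columns `mRNA_id`, `protein_id`.
#' @export
read_id_map <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("identity map needs two columns", call. = FALSE)
  out <- data.frame(mRNA_id = m[[1L]], protein_id = m[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$mRNA_id) || anyDuplicated(out$protein_id))
    stop("identity map must be one-to-one", call. = FALSE)
  out
}

#' Align mRNA and protein matrices on shared genes
#'
#' Returns the genes present at both molecular levels under the identity
#' map (by default, identical identifiers) together with the per-level
#' exclusive sets, so that every input gene is accounted for.  Presence
#' filtering (e.g. detection calls) is assumed done upstream; only joint
#' presence of the gene row is enforced here.
#'
#' @param m mRNA `expr_matrix`.
#' @param p protein `expr_matrix`.
#' @param id_map optional data.frame as from [read_id_map()]; identity
#'   map on shared rownames when `NULL`.
#' @return a `level_alignment` list: `pairs` (data.frame `mRNA_gene`,
#'   `protein_gene`), `mRNA_only`, `protein_only`, and counts
#'   `n_shared`, `n_discarded`.
#' @export
align_levels <- function(m, p, id_map = NULL) {
  mid <- rownames(m); pid <- rownames(p)
  if (is.null(id_map)) {
    shared <- intersect(mid, pid)
    pairs <- data.frame(mRNA_gene = shared, protein_gene = shared,
                        stringsAsFactors = FALSE)
  } else {
    keep <- id_map$mRNA_id %in% mid & id_map$protein_id %in% pid
    pairs <- data.frame(mRNA_gene = id_map$mRNA_id[keep],
                        protein_gene = id_map$protein_id[keep],
                        stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L)
    stop("no genes shared between the two levels", call. = FALSE)
  out <- list(pairs = pairs,
              mRNA_only = setdiff(mid, pairs$mRNA_gene),
              protein_only = setdiff(pid, pairs$protein_gene),
              n_shared = nrow(pairs))
  out$n_discarded <- length(out$mRNA_only) + length(out$protein_only)
  class(out) <- "level_alignment"
  out
}

#' @export
print.level_alignment <- function(x, ...) {
  cat(sprintf(
    "Level alignment: %d shared genes (%d mRNA-only, %d protein-only discarded)\n",
    x$n_shared, length(x$mRNA_only), length(x$protein_only)))
  invisible(x)
}
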