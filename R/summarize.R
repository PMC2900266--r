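#' Sample gene pairs for a comparison group
#'
#' Draws a uniform sample of distinct gene pairs without replacement.
#' Within-level sampling (`cross_level = FALSE`) draws unordered pairs
#' from one identifier set, excluding self-pairs.  Cross-level sampling
#' draws (x, y) pairs from two identifier sets, excluding same-gene
#' pairs (those form their own comparison group; see
#' [same_gene_pairs()]).
#'
#' @param ids_x gene identifiers for the first member.
#' @param ids_y gene identifiers for the second member; defaults to
#'   `ids_x` (within-level).
#' @param n number of pairs to draw.
#' @param cross_level logical; `TRUE` for mRNA-protein pairs.
#' @param seed integer seed; the same seed reproduces the sample.
#' @param same_gene optional data.frame (`mRNA_gene`, `protein_gene`)
#'   defining which cross-level pairs count as same-gene; identical
#'   identifiers by default.
#' @return data.frame `id_x`, `id_y` with attributes `group_sampled`
#'   and `cross_level`.
#' @export
sample_pairs <- function(ids_x, ids_y = ids_x, n, cross_level = FALSE,
                         seed = 1L, same_gene = NULL) {
  n <- as.integer(n)
  mx <- length(ids_x); my <- length(ids_y)
  if (cross_level) {
    if (is.null(same_gene)) {
      shared <- intersect(ids_x, ids_y)
      same_gene <- data.frame(mRNA_gene = shared, protein_gene = shared,
                              stringsAsFactors = FALSE)
    }
    excl <- sum(same_gene$mRNA_gene %in% ids_x &
                same_gene$protein_gene %in% ids_y)
    n_avail <- as.double(mx) * my - excl
  } else {
    n_avail <- choose(as.double(mx), 2)
  }
  if (n > n_avail)
    stop("requested ", n, " pairs but only ", format(n_avail, digits = 15),
         " are available", call. = FALSE)
  empty <- data.frame(id_x = character(0), id_y = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L)
    return(structure(empty, group_sampled = TRUE, cross_level = cross_level))
  set.seed(seed)
  if (cross_level) {
    forbid <- paste(same_gene$mRNA_gene, same_gene$protein_gene, sep = "\r")
    keys <- character(0)
    while (length(keys) < n) {
      k <- n - length(keys)
      i <- sample.int(mx, 2L * k + 8L, replace = TRUE)
      j <- sample.int(my, 2L * k + 8L, replace = TRUE)
      cand <- paste(ids_x[i], ids_y[j], sep = "\r")
      cand <- cand[!(cand %in% forbid)]
      keys <- unique(c(keys, cand))
    }
    keys <- keys[seq_len(n)]
    parts <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(id_x = vapply(parts, `[[`, character(1), 1L),
                      id_y = vapply(parts, `[[`, character(1), 2L),
                      stringsAsFactors = FALSE)
  } else {
    keys <- integer(0)
    while (length(keys) < n) {
      k <- n - length(keys)
      i <- sample.int(mx, 2L * k + 8L, replace = TRUE)
      j <- sample.int(mx, 2L * k + 8L, replace = TRUE)
      keep <- i != j
      lo <- pmin(i, j)[keep]; hi <- pmax(i, j)[keep]
      keys <- unique(c(keys, (lo - 1) * mx + hi))
    }
    keys <- keys[seq_len(n)]
    lo <- (keys - 1) %/% mx + 1
    hi <- keys - (lo - 1) * mx
    out <- data.frame(id_x = ids_x[lo], id_y = ids_x[hi],
                      stringsAsFactors = FALSE)
  }
  structure(out, group_sampled = TRUE, cross_level = cross_level)
}

#' Same-gene mRNA-protein pairs from a level alignment
#'
#' @param alignment a `level_alignment` from [align_levels()].
#' @return data.frame `id_x` (mRNA id), `id_y` (protein id), one row per
#'   shared gene.
#' @export
same_gene_pairs <- function(alignment) {
  stopifnot(inherits(alignment, "level_alignment"))
  data.frame(id_x = alignment$pairs$mRNA_gene,
             id_y = alignment$pairs$protein_gene,
             stringsAsFactors = FALSE)
}

.delayed_classes <- function(classes) grep("^delayed_", classes, value = TRUE)

#' Tabulate co-expression classes for one pair group
#'
#' Counts and percentages over the classes simultaneous,
#' delayed_1..delayed_k, none (or the pooled three-class scheme).  The
#' denominator is the number of testable pairs; untestable pairs are
#' excluded and reported separately.  Percentages are rounded half-up
#' to two decimals, and the composite time-delayed percentage is the
#' sum of the rounded per-delay cells, matching how such tables are
#' conventionally read.
#'
#' @param results a results data.frame from [test_pairs()], or a named
#'   count vector (names = classes) to tabulate counts directly.
#' @param pooled logical; pool delayed_1..k into one `time_delayed`
#'   class.
#' @param max_delay number of delay classes when `results` is a
#'   data.frame (default 3).
#' @return a `class_table` list: `counts`, `percentages`, `n` (testable
#'   pairs), `n_untestable`, `pooled`, `time_delayed_pct` (NA when
#'   pooled or when there are no delay classes).
#' @export
tabulate_classes <- function(results, pooled = FALSE, max_delay = 3L) {
  if (is.numeric(results) && !is.null(names(results))) {
    counts <- results
    n_untestable <- 0L
  } else {
    stopifnot(is.data.frame(results), "class" %in% names(results))
    if (nrow(results) == 0L) stop("empty results", call. = FALSE)
    cls <- coexpr_classes(max_delay, pooled = FALSE)
    n_untestable <- sum(results$class == "untestable")
    keep <- results$class[results$class != "untestable"]
    counts <- vapply(cls, function(k) sum(keep == k), numeric(1))
  }
  if (sum(counts) == 0) stop("no testable pairs to tabulate", call. = FALSE)
  if (pooled) {
    dly <- .delayed_classes(names(counts))
    if (length(dly)) {
      pooled_counts <- c(simultaneous = unname(counts["simultaneous"]),
                         time_delayed = sum(counts[dly]),
                         none = unname(counts["none"]))
      counts <- pooled_counts[!is.na(pooled_counts)]
    }
  }
  n <- sum(counts)
  pct <- round_half_up(100 * counts / n, 2)
  dly <- .delayed_classes(names(counts))
  structure(list(counts = counts, percentages = pct, n = n,
                 n_untestable = n_untestable, pooled = pooled,
                 time_delayed_pct = if (length(dly)) sum(pct[dly])
                                    else NA_real_),
            class = "class_table")
}

#' @export
print.class_table <- function(x, ...) {
  cat("Co-expression class counts (", x$n, " testable pairs",
      if (x$n_untestable) paste0(", ", x$n_untestable, " untestable"),
      ")\n", sep = "")
  cells <- sprintf("%d (%.2f%%)", x$counts, x$percentages)
  names(cells) <- names(x$counts)
  print(cells, quote = FALSE)
  if (!is.na(x$time_delayed_pct))
    cat(sprintf("time-delayed composite: %.2f%%\n", x$time_delayed_pct))
  invisible(x)
}

## shared stats for a square class x class cross-tabulation
.transfer_stats <- function(counts) {
  total <- sum(counts)
  none <- which(rownames(counts) == "none")
  co <- if (length(none)) counts[-none, -none, drop = FALSE] else counts
  list(total = total,
       conserved_fraction = round_half_up(100 * sum(diag(counts)) / total, 2),
       coexpressed_both = round_half_up(100 * sum(co) / total, 2),
       origin_pct = round_half_up(100 * counts / rowSums(counts), 2))
}

#' Build a transfer matrix from a ready cross-tabulation
#'
#' @param counts square numeric matrix, origin classes (transcript
#'   level) in rows, destination classes (protein level) in columns,
#'   with matching dimnames.
#' @return a `transfer_matrix`: the counts plus `total`,
#'   `conserved_fraction` (diagonal percentage), `coexpressed_both`
#'   (percentage co-expressed at both levels, i.e. excluding `none` at
#'   either level) and `origin_pct` (per-origin transition percentages,
#'   rows summing to ~100).
#' @export
transfer_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || is.null(rownames(counts)) ||
      !identical(rownames(counts), colnames(counts)))
    stop("'counts' must be square with matching class dimnames",
         call. = FALSE)
  structure(c(list(counts = counts), .transfer_stats(counts)),
            class = "transfer_matrix")
}

#' Track co-expression classes from transcript to protein level
#'
#' Cross-tabulates each gene pair's class at the transcript level
#' against its class at the protein level.  With `pooled = TRUE`
#' (default) the delayed classes are merged into one `time_delayed`
#' group, the granularity at which cross-level conservation is usually
#' reported; `pooled = FALSE` keeps all delay classes.  For unordered
#' data the table is simultaneous/none only.  Pairs untestable at
#' either level are excluded.
#'
#' @param transcript_results,protein_results results data.frames from
#'   [test_pairs()] for the same pair set (matched by `id_x`, `id_y`
#'   order).
#' @param pooled logical, see above.
#' @param max_delay number of delay classes in the results.
#' @return a `transfer_matrix`, see [transfer_matrix()].
#' @export
transfer_analysis <- function(transcript_results, protein_results,
                              pooled = TRUE, max_delay = 3L) {
  tx <- transcript_results; px <- protein_results
  if (nrow(tx) != nrow(px) ||
      !identical(paste(tx$id_x, tx$id_y), paste(px$id_x, px$id_y)))
    stop("transcript and protein results must cover the same pairs",
         call. = FALSE)
  keep <- tx$class != "untestable" & px$class != "untestable"
  pool <- function(cl) {
    if (pooled) ifelse(grepl("^delayed_", cl), "time_delayed", cl) else cl
  }
  lev <- coexpr_classes(max_delay, pooled)
  counts <- table(factor(pool(tx$class[keep]), levels = lev),
                  factor(pool(px$class[keep]), levels = lev))
  counts <- matrix(as.numeric(counts), nrow = length(lev),
                   dimnames = list(lev, lev))
  transfer_matrix(counts)
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("Co-expression transfer, transcript (rows) to protein (columns)\n")
  print(x$counts)
  cat(sprintf("conserved: %.2f%%; co-expressed at both levels: %.2f%%\n",
              x$conserved_fraction, x$coexpressed_both))
  invisible(x)
}

#' Pearson chi-square contrast of two class-count rows
#'
#' Compares two groups' class counts (a 2 x k contingency table) with
#' the Pearson chi-square test without continuity correction,
#' `df = k - 1`.
#'
#' @param table 2 x k matrix of counts; all row and column margins must
#'   be positive.
#' @return a `chisq_2xk` list: `statistic`, `df`, `p`, `expected`,
#'   `table`.
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("'table' must be 2 x k with k >= 2", call. = FALSE)
  if (any(!is.finite(table)) || any(table < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin", call. = FALSE)
  ht <- stats::chisq.test(table, correct = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value, expected = ht$expected, table = table),
            class = "chisq_2xk")
}

#' @export
print.chisq_2xk <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.2f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Histogram of co-expression scores
#'
#' Bins the best-shift gamma values of pairs classified simultaneous or
#' time-delayed over \[-1, 1\].
#'
#' @param results results data.frame from [test_pairs()].
#' @param which `"simultaneous"` (pairs significant at shift 0) or
#'   `"time_delayed"` (pairs significant at a nonzero shift, using
#'   their best-shift gamma).
#' @param bins number of equal-width bins over \[-1, 1\].
#' @return a `gamma_hist` data.frame: `bin_left`, `bin_right`, `count`;
#'   counts sum to the number of selected pairs.
#' @export
gamma_distribution <- function(results,
                               which = c("simultaneous", "time_delayed"),
                               bins = 40L) {
  which <- match.arg(which)
  sel <- if (which == "simultaneous") results$class == "simultaneous"
         else grepl("^delayed_", results$class)
  g <- results$gamma[sel]
  if (length(g) == 0L) stop("no pairs in class '", which, "'", call. = FALSE)
  breaks <- seq(-1, 1, length.out = bins + 1L)
  h <- graphics::hist(g, breaks = breaks, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  structure(data.frame(bin_left = breaks[-length(breaks)],
                       bin_right = breaks[-1L], count = h$counts),
            which = which, class = c("gamma_hist", "data.frame"))
}

#' @export
plot.gamma_hist <- function(x, ...) {
  graphics::barplot(x$count, width = diff(c(x$bin_left[1], x$bin_right)),
                    space = 0, xlab = "Spearman correlation",
                    ylab = "number of gene pairs",
                    main = paste("Score distribution,", attr(x, "which")),
                    ...)
  graphics::axis(1, at = seq(0, 2, 0.5), labels = seq(-1, 1, 0.5))
  invisible(x)
}
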