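log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Configure an end-to-end co-expression run
#'
#' A run either simulates its inputs (`sim` is a [sim_config()]) or
#' reads them from files (`mrna_path` / `protein_path`, optionally
#' `id_map_path`) — exactly one of the two.  The single `seed` expands
#' deterministically into per-stage and per-pair sub-seeds, so repeated
#' runs with the same configuration are byte-identical.
#'
#' @param out_dir output directory for all artifacts.
#' @param sim a [sim_config()] for simulate mode, or `NULL`.
#' @param mrna_path,protein_path,id_map_path input files for analyze
#'   mode (the [read_expression()] / [read_id_map()] dialect).
#' @param ordered logical; whether the condition axis is ordered (file
#'   mode; simulate mode takes it from `sim`).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutation replicates per pair (default 500).
#' @param max_delay largest shift scanned (default 3; ignored with a
#'   warning for unordered data).
#' @param n_within within-level pairs to sample; default
#'   `min(10 * n_genes, choose(n_genes, 2))`, mirroring a 25020-pair
#'   sample from 2502 genes.
#' @param n_cross cross-level different-gene pairs; default
#'   `min(20 * n_genes, n_genes^2 - n_genes)`.
#' @param seed master seed.
#' @return a validated `run_config` list.
#' @export
pipeline_config <- function(out_dir, sim = NULL, mrna_path = NULL,
                            protein_path = NULL, id_map_path = NULL,
                            ordered = TRUE, alpha = 0.05, n_perm = 500L,
                            max_delay = 3L, n_within = NULL, n_cross = NULL,
                            seed = 1L) {
  file_mode <- !is.null(mrna_path) || !is.null(protein_path)
  if (is.null(sim) == !file_mode)
    stop("provide exactly one of 'sim' or input paths", call. = FALSE)
  if (file_mode && (is.null(mrna_path) || is.null(protein_path)))
    stop("file mode needs both 'mrna_path' and 'protein_path'",
         call. = FALSE)
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    ordered <- sim$ordered
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)",
                                     call. = FALSE)
  if (n_perm < 1L) stop("'n_perm' must be >= 1", call. = FALSE)
  if (max_delay < 0L) stop("'max_delay' must be >= 0", call. = FALSE)
  structure(list(out_dir = out_dir, sim = sim, mrna_path = mrna_path,
                 protein_path = protein_path, id_map_path = id_map_path,
                 ordered = isTRUE(ordered), alpha = alpha,
                 n_perm = as.integer(n_perm), max_delay = as.integer(max_delay),
                 n_within = n_within, n_cross = n_cross,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' mapping holds [sim_config()] arguments.
#'
#' @param path config file ending in `.yaml`/`.yml` or `.json`.
#' @param out_dir optional override of the file's `out_dir`.
#' @return a `run_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}

## group labels used in file names and summaries
.group_names <- c("mRNA_mRNA", "protein_protein",
                  "mRNA_protein_diff", "mRNA_protein_same")

#' Simulate stage: generate and write the input matrices
#'
#' @param cfg a `run_config` in simulate mode.
#' @return named vector of files written (`mrna`, `protein`, `truth`),
#'   invisibly.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$sim)) stop("config is not in simulate mode", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- cfg$sim
  sim_cfg$seed <- derive_seed(cfg$seed, 1L)
  sim <- simulate_coexpression(sim_cfg)
  log_msg("INFO", "simulated ", sim_cfg$n_genes, " gene pairs x ",
          sim_cfg$n_conditions, " conditions")
  write_simulation(sim, cfg$out_dir)
}

.load_inputs <- function(cfg) {
  if (is.null(cfg$sim)) {
    mrna_path <- cfg$mrna_path; protein_path <- cfg$protein_path
  } else {
    mrna_path <- file.path(cfg$out_dir, "mrna.tsv")
    protein_path <- file.path(cfg$out_dir, "protein.tsv")
  }
  mrna <- read_expression(mrna_path, "mRNA", ordered = cfg$ordered)
  protein <- read_expression(protein_path, "protein", ordered = cfg$ordered)
  id_map <- if (!is.null(cfg$id_map_path)) read_id_map(cfg$id_map_path)
  list(mrna = mrna, protein = protein, id_map = id_map)
}

#' Analyze stage: sample the four pair groups and test every pair
#'
#' Groups: (i) within-level mRNA-mRNA pairs, (ii) the same gene pairs
#' evaluated on the protein matrix (so cross-level transfer tracks one
#' pair set at both levels), (iii) cross-level different-gene pairs,
#' (iv) same-gene mRNA-protein pairs.  Writes one results TSV per
#' group.
#'
#' @param cfg a `run_config`; in file mode the matrices are read from
#'   the configured paths, in simulate mode from `out_dir` (run
#'   [run_simulate()] first).
#' @return named vector of result files, invisibly.
#' @export
run_analyze <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- .load_inputs(cfg)
  max_delay <- cfg$max_delay
  if (!cfg$ordered && max_delay > 0L) {
    warning("unordered conditions: ignoring max_delay = ", max_delay,
            call. = FALSE)
    max_delay <- 0L
  }
  aln <- align_levels(inp$mrna, inp$protein, inp$id_map)
  log_msg("INFO", "aligned levels: ", aln$n_shared, " shared genes, ",
          aln$n_discarded, " discarded")
  n <- aln$n_shared
  n_within <- if (is.null(cfg$n_within)) min(10 * n, choose(n, 2))
              else cfg$n_within
  n_cross <- if (is.null(cfg$n_cross)) min(20 * n, as.double(n)^2 - n)
             else cfg$n_cross
  m_ids <- aln$pairs$mRNA_gene
  p_of <- stats::setNames(aln$pairs$protein_gene, m_ids)
  pairs_w <- sample_pairs(m_ids, n = n_within,
                          seed = derive_seed(cfg$seed, 11L))
  pairs_c <- sample_pairs(m_ids, aln$pairs$protein_gene, n = n_cross,
                          cross_level = TRUE,
                          seed = derive_seed(cfg$seed, 12L),
                          same_gene = aln$pairs)
  pairs_s <- same_gene_pairs(aln)
  groups <- list(
    mRNA_mRNA = list(pairs = pairs_w, x = inp$mrna, y = inp$mrna),
    protein_protein = list(
      pairs = data.frame(id_x = unname(p_of[pairs_w$id_x]),
                         id_y = unname(p_of[pairs_w$id_y]),
                         stringsAsFactors = FALSE),
      x = inp$protein, y = inp$protein),
    mRNA_protein_diff = list(pairs = pairs_c, x = inp$mrna, y = inp$protein),
    mRNA_protein_same = list(pairs = pairs_s, x = inp$mrna, y = inp$protein))
  files <- character(0)
  for (k in seq_along(groups)) {
    g <- names(groups)[k]
    res <- test_pairs(groups[[g]]$pairs, groups[[g]]$x, groups[[g]]$y,
                      ordered = cfg$ordered, max_delay = max_delay,
                      alpha = cfg$alpha, n_perm = cfg$n_perm,
                      seed = derive_seed(cfg$seed, 20L + k))
    log_msg("INFO", g, ": ", nrow(res), " pairs tested, ",
            sum(res$class == "untestable"), " untestable, ",
            sum(res$significant, na.rm = TRUE), " significant")
    f <- file.path(cfg$out_dir, paste0("results_", g, ".tsv"))
    write_tsv(res, f)
    files[[g]] <- f
  }
  invisible(files)
}

.read_results <- function(cfg, group) {
  f <- file.path(cfg$out_dir, paste0("results_", group, ".tsv"))
  if (!file.exists(f)) stop("missing results file: ", f, call. = FALSE)
  r <- utils::read.table(f, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(id_x = "character",
                                        id_y = "character"))
  if (nrow(r) == 0L) stop("empty results in ", f, call. = FALSE)
  r
}

#' Summarize stage: class tables, transfer matrix, histograms, JSON
#'
#' Reads the per-group results TSVs from `out_dir` and writes
#' class-count tables (full and pooled), the transcript-to-protein
#' transfer matrix over the within-level pair set, per-group score
#' histograms, and a JSON master summary.
#'
#' @param cfg a `run_config` whose `out_dir` holds the analyze-stage
#'   results.
#' @return named vector of files written, invisibly.
#' @export
run_summarize <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  max_delay <- if (cfg$ordered) cfg$max_delay else 0L
  res <- lapply(stats::setNames(.group_names, .group_names),
                function(g) .read_results(cfg, g))
  files <- character(0)
  summary <- list(alpha = cfg$alpha, n_perm = cfg$n_perm,
                  max_delay = max_delay, seed = cfg$seed, groups = list())
  ct_rows <- list()
  for (g in .group_names) {
    ct <- tabulate_classes(res[[g]], pooled = FALSE, max_delay = max_delay)
    ct_rows[[g]] <- data.frame(group = g, class = names(ct$counts),
                               count = as.integer(ct$counts),
                               percent = as.numeric(ct$percentages),
                               stringsAsFactors = FALSE)
    summary$groups[[g]] <- list(
      n_testable = ct$n, n_untestable = ct$n_untestable,
      counts = as.list(ct$counts),
      percentages = as.list(ct$percentages),
      time_delayed_pct = ct$time_delayed_pct)
  }
  files[["class_tables"]] <- write_tsv(do.call(rbind, ct_rows),
                                       file.path(cfg$out_dir,
                                                 "class_tables.tsv"))
  tm <- transfer_analysis(res$mRNA_mRNA, res$protein_protein,
                          pooled = TRUE, max_delay = max_delay)
  tm_df <- data.frame(origin = rownames(tm$counts), tm$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
  files[["transfer"]] <- write_tsv(tm_df,
                                   file.path(cfg$out_dir,
                                             "transfer_matrix.tsv"))
  summary$transfer <- list(conserved_fraction = tm$conserved_fraction,
                           coexpressed_both = tm$coexpressed_both,
                           total = tm$total)
  if (max_delay > 0L) {
    full <- transfer_analysis(res$mRNA_mRNA, res$protein_protein,
                              pooled = FALSE, max_delay = max_delay)
    full_df <- data.frame(origin = rownames(full$counts), full$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
    files[["transfer_full"]] <- write_tsv(
      full_df, file.path(cfg$out_dir, "transfer_matrix_full.tsv"))
  }
  hists <- list()
  for (g in .group_names) {
    for (w in c("simultaneous", if (max_delay > 0L) "time_delayed")) {
      h <- tryCatch(gamma_distribution(res[[g]], w), error = function(e) NULL)
      if (!is.null(h))
        hists[[paste(g, w)]] <- data.frame(group = g, which = w,
                                           as.data.frame(h),
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(hists))
    files[["histograms"]] <- write_tsv(do.call(rbind, hists),
                                       file.path(cfg$out_dir,
                                                 "histograms.tsv"))
  files[["summary"]] <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  log_msg("INFO", "summaries written to ", cfg$out_dir)
  invisible(files)
}

#' Run the full pipeline: simulate (or load), analyze, summarize
#'
#' Composes [run_simulate()] (simulate mode only), [run_analyze()] and
#' [run_summarize()], then writes `manifest.json` recording the
#' configuration, seed, and an MD5 checksum of every artifact.  Two
#' runs with identical configuration and seed produce byte-identical
#' artifacts and hence identical manifests.
#'
#' @param cfg a `run_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return a `coexpr_run` list (`config`, `files`, `checksums`,
#'   `summary`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$sim)) run_simulate(cfg)
  run_analyze(cfg)
  run_summarize(cfg)
  arts <- sort(setdiff(list.files(cfg$out_dir, full.names = FALSE),
                       "manifest.json"))
  sums <- tools::md5sum(file.path(cfg$out_dir, arts))
  names(sums) <- arts
  cfg_rec <- unclass(cfg)
  cfg_rec$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim)
  manifest <- list(config = cfg_rec, seed = cfg$seed,
                   checksums = as.list(sums))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  out <- structure(list(config = cfg,
                        files = c(file.path(cfg$out_dir, arts),
                                  manifest_path),
                        checksums = sums,
                        summary = jsonlite::read_json(
                          file.path(cfg$out_dir, "summary.json"),
                          simplifyVector = TRUE)),
                   class = "coexpr_run")
  invisible(out)
}

#' @export
print.coexpr_run <- function(x, ...) {
  cat("Co-expression pipeline run\n")
  cat("  output:", x$config$out_dir, "\n")
  cat("  seed:", x$config$seed, "| alpha:", x$config$alpha,
      "| n_perm:", x$config$n_perm, "\n")
  for (g in names(x$summary$groups)) {
    gg <- x$summary$groups[[g]]
    cat(sprintf("  %-18s %d testable, time-delayed %s%%\n", g,
                gg$n_testable,
                if (is.null(gg$time_delayed_pct) ||
                    is.na(gg$time_delayed_pct)) "-"
                else format(gg$time_delayed_pct)))
  }
  cat(sprintf("  transfer: conserved %.2f%%, co-expressed at both %.2f%%\n",
              x$summary$transfer$conserved_fraction,
              x$summary$transfer$coexpressed_both))
  invisible(x)
}
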