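#' Run the full codon usage bias pipeline
#'
#' Orchestrates, per species: CDS screening, per-gene metrics, pooled RSCU,
#' ENC-ratio histogram, ENC-plot / PR2 / neutrality / correspondence
#' analysis plot data, and the delta-RSCU optimal-codon screen; then across
#' species: shared high-frequency and optimal codon sets and pairwise codon
#' usage ratio comparisons (including any external Kazusa-format tables).
#' All intermediates are plain TSV so every stage is diffable; a
#' machine-readable `summary.json` collects counts, slopes, axis inertias
#' and verdicts. Rerunning with the same config and seed reproduces the
#' summary byte for byte.
#'
#' @param config A named list, or path to a YAML/JSON file, with fields:
#'   `species` (named list of CDS FASTA paths; required), `outdir`
#'   (required), and optional `scheme` ("split"/"standard"), `fraction`
#'   (expression-group fraction, 0.10), `delta` (delta-RSCU threshold,
#'   0.08), `min_len` (300), `comparisons` (named list of Kazusa-format
#'   table paths), `seed` (1). Unknown fields are an error.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run.log")
  log_lines <- c(
    paste0("cubkit ", as.character(utils::packageVersion("cubkit"))),
    paste0("R ", R.version.string),
    paste0("scheme=", cfg$scheme, " fraction=", cfg$fraction,
           " delta=", cfg$delta, " min_len=", cfg$min_len, " seed=", cfg$seed),
    paste0("started ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  )
  set.seed(cfg$seed)

  stage <- function(name, sp, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed for species '", sp, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  out_path <- function(...) file.path(cfg$outdir, paste0(...))

  summary <- list(parameters = cfg[c("scheme", "fraction", "delta",
                                     "min_len", "seed")],
                  species = list())
  pooled_list <- list()
  hf_sets <- list()
  opt_sets <- list()

  for (sp in names(cfg$species)) {
    genes <- stage("parse_fasta", sp, parse_fasta(cfg$species[[sp]]))
    rep <- stage("filter_cds", sp, filter_cds(genes, min_len = cfg$min_len))
    write_filter_report(rep, out_path(sp, "_filter_report.tsv"))
    write_fasta(rep$kept, out_path(sp, "_filtered.fasta"))
    log_lines <- c(log_lines, sprintf("%s: %d parsed, %d kept, %d rejected",
                                      sp, nrow(genes), nrow(rep$kept),
                                      nrow(rep$rejected)))
    counts <- stage("count_codons", sp, codon_count_matrix(rep$kept))
    met <- stage("metrics", sp, metrics_from_counts(
      counts, scheme = cfg$scheme, delta = cfg$delta))
    readr::write_tsv(met, out_path(sp, "_metrics.tsv"))

    pooled <- pool_counts(counts)
    pooled_list[[sp]] <- pooled
    rs <- rscu(pooled, scheme = cfg$scheme)
    readr::write_tsv(rs, out_path(sp, "_rscu.tsv"))
    hf_sets[[sp]] <- high_frequency_codons(rs)

    hist <- stage("enc_ratio", sp, enc_ratio_histogram(met$enc, met$gc3s))
    readr::write_tsv(hist, out_path(sp, "_enc_ratio.tsv"))

    readr::write_tsv(dplyr::select(met, "id", "gc3s", "enc"),
                     out_path(sp, "_enc_plot.tsv"))
    pr2 <- stage("pr2", sp, dplyr::bind_cols(met["id"], pr2_point(counts)))
    readr::write_tsv(pr2, out_path(sp, "_pr2.tsv"))

    fit <- stage("neutrality", sp, neutrality_fit(met$gc12, met$gc3))
    readr::write_tsv(dplyr::select(met, "id", "gc3", "gc12"),
                     out_path(sp, "_neutrality.tsv"))

    coa <- stage("coa", sp, correspondence_analysis(
      rscu_matrix(counts, scheme = cfg$scheme)))
    n_ax <- min(4L, ncol(coa$row_coords))
    coa_genes <- dplyr::bind_cols(
      tibble::tibble(id = rownames(coa$row_coords)),
      tibble::as_tibble(coa$row_coords[, seq_len(n_ax), drop = FALSE]))
    coa_genes$gc_class <- as.character(
      gc_class_labels(met$gc_all[match(coa_genes$id, met$id)]))
    readr::write_tsv(coa_genes, out_path(sp, "_coa_genes.tsv"))
    readr::write_tsv(dplyr::bind_cols(
      tibble::tibble(codon = rownames(coa$col_coords)),
      tibble::as_tibble(coa$col_coords[, seq_len(n_ax), drop = FALSE])),
      out_path(sp, "_coa_codons.tsv"))

    opt <- stage("optimal_codons", sp, {
      grp <- expression_groups(met, fraction = cfg$fraction)
      optimal_codons(
        pool_counts(counts[rownames(counts) %in% grp$high, , drop = FALSE]),
        pool_counts(counts[rownames(counts) %in% grp$low, , drop = FALSE]),
        rs, threshold = cfg$delta, scheme = cfg$scheme)
    })
    readr::write_tsv(opt, out_path(sp, "_optimal.tsv"))
    opt_sets[[sp]] <- opt$codon[opt$optimal]
    write_kazusa(frequency_table(pooled, species = sp),
                 out_path(sp, "_kazusa.txt"))

    summary$species[[sp]] <- list(
      n_input = nrow(genes), n_kept = nrow(rep$kept),
      rejected = as.list(rep$counts),
      mean_enc = round(mean(met$enc, na.rm = TRUE), 6),
      mean_gc = round(mean(met$gc_all, na.rm = TRUE), 6),
      n_high_frequency = length(hf_sets[[sp]]),
      n_optimal = length(opt_sets[[sp]]),
      neutrality = list(slope = round(fit$slope, 6),
                        pearson_r = round(fit$pearson_r, 6),
                        mutation_share = round(fit$mutation_share, 4)),
      coa_axis_percent = round(coa$percent_inertia[seq_len(n_ax)], 4)
    )
  }

  if (length(hf_sets) >= 2) {
    sh <- shared_codons(hf_sets)
    readr::write_tsv(sh$endings, out_path("high_frequency_endings.tsv"))
    writeLines(sh$shared, out_path("shared_high_frequency_codons.txt"))
    summary$shared_high_frequency <- sh$shared
    summary$shared_optimal <- shared_codons(opt_sets)$shared
  }

  freq_tables <- lapply(names(pooled_list), function(sp)
    frequency_table(pooled_list[[sp]], species = sp))
  names(freq_tables) <- names(pooled_list)
  for (nm in names(cfg$comparisons)) {
    freq_tables[[nm]] <- stage("parse_kazusa", nm,
                               parse_kazusa(cfg$comparisons[[nm]], species = nm))
  }
  if (length(freq_tables) >= 2) {
    pairs <- utils::combn(names(freq_tables), 2, simplify = FALSE)
    summary$comparisons <- list()
    for (pr in pairs) {
      rr <- usage_ratio(freq_tables[[pr[1]]], freq_tables[[pr[2]]])
      readr::write_tsv(rr$table, out_path("ratio_", pr[1], "_vs_", pr[2], ".tsv"))
      summary$comparisons[[paste(pr, collapse = "_vs_")]] <-
        list(n_flagged = rr$n_flagged, verdict = rr$verdict)
    }
  }

  jsonlite::write_json(summary, out_path("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, paste0("finished ",
                                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             log_path)
  invisible(summary)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    stopifnot(file.exists(config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  allowed <- c("species", "outdir", "scheme", "fraction", "delta",
               "min_len", "comparisons", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$species) || is.null(names(config$species))) {
    stop("config needs a named 'species' list of FASTA paths")
  }
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  for (p in c(unlist(config$species), unlist(config$comparisons))) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  list(
    species = config$species,
    outdir = config$outdir,
    scheme = match.arg(config$scheme %||% "split", c("split", "standard")),
    fraction = config$fraction %||% 0.10,
    delta = config$delta %||% 0.08,
    min_len = config$min_len %||% 300,
    comparisons = config$comparisons %||% list(),
    seed = as.integer(config$seed %||% 1L)
  )
}
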