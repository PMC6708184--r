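#' Run the full simulate-detect-deconvolve screen
#'
#' Executes the stages in fixed order — population simulation, pooled
#' count simulation, optional library-failure injection, pooled detection,
#' EMS filtering, row/column deconvolution, duplicate collapse, optional
#' effect annotation, and population statistics — under a single
#' configuration and master seed, and returns a screen report. The same
#' configuration and seed reproduce the report bit-identically.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{layout}{list(n_blocks, n_rows, n_cols).}
#'     \item{targets}{named character vector of sequences, a FASTA path,
#'       or a named vector of lengths under `target_lengths` to generate
#'       random targets.}
#'     \item{sim}{arguments for [sim_config()] (seed is taken from the
#'       top-level `seed`).}
#'     \item{detect}{arguments for [detection_params()].}
#'     \item{fail_pools}{optional pool ids to degrade, with
#'       `fail_residual_depth` (default 0).}
#'     \item{gene_models}{optional list of [gene_model()] objects or a
#'       GFF3 path.}
#'     \item{seed}{master seed.}
#'   }
#' @return object of class `screen_report`.
#' @export
run_pipeline <- function(config) {
  stage <- "config"
  res <- tryCatch({
    ly_args <- config$layout
    stage <- "layout"
    layout <- build_layout(ly_args$n_blocks, ly_args$n_rows, ly_args$n_cols)

    stage <- "targets"
    targets <- if (!is.null(config$targets)) {
      if (is.character(config$targets) && length(config$targets) == 1L &&
          file.exists(config$targets)) {
        read_fasta(config$targets)
      } else reference_targets(config$targets)
    } else if (!is.null(config$target_lengths)) {
      if (!is.null(config$seed)) set.seed(config$seed + 500L)
      random_targets(config$target_lengths)
    } else .stopf("config must name targets or target_lengths")

    stage <- "simulate"
    sc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    pop <- simulate_population(sc, targets, layout)
    counts <- simulate_pool_counts(pop, layout, targets, sc)
    if (!is.null(config$fail_pools)) {
      counts <- inject_pool_failure(counts, config$fail_pools,
                                    config$fail_residual_depth %||% 0)
    }

    stage <- "detect"
    dp <- do.call(detection_params, config$detect %||% list())
    failed <- flag_failed_pools(counts, dp$min_pool_depth)
    hits <- detect_pool_variants(counts, dp)
    hits <- apply_ems_filter(hits)

    stage <- "deconvolve"
    zp <- zygosity_params(layout$n_cols)
    calls <- deconvolve_calls(hits, layout, failed, zp)
    confirmed <- calls[calls$status == "confirmed", , drop = FALSE]
    collapsed <- collapse_duplicates(confirmed)

    stage <- "annotate"
    ann <- NULL
    if (!is.null(config$gene_models)) {
      models <- if (is.character(config$gene_models)) {
        read_gene_models(config$gene_models)
      } else config$gene_models
      if (nrow(collapsed)) {
        ann <- annotate_variants(collapsed, models, targets)
      }
    }

    stage <- "stats"
    spectrum <- spectrum_table(confirmed)
    evaluation <- evaluate_against_truth(calls, pop)
    density <- mutation_density(nrow(pop$mutations),
                                sum(nchar(targets)), length(pop$plants))

    rows <- calls
    rows$carrier_count <- rep(NA_integer_, nrow(rows))
    if (nrow(rows)) {
      ck <- paste(rows$target, rows$position, rows$ref, rows$alt)
      colk <- paste(collapsed$target, collapsed$position, collapsed$ref,
                    collapsed$alt)
      rows$carrier_count <- collapsed$n_carriers[match(ck, colk)]
    }
    if (!is.null(ann)) {
      ck <- paste(rows$target, rows$position, rows$ref, rows$alt)
      ak <- paste(ann$target, ann$position, ann$ref, ann$alt)
      rows$effect <- ann$category[match(ck, ak)]
    } else {
      rows$effect <- rep(NA_character_, nrow(rows))
    }

    structure(list(
      rows = rows, collapsed = collapsed, annotations = ann,
      hits = hits, failed_pools = failed, spectrum = spectrum,
      density = density, evaluation = evaluation, truth = pop,
      layout = layout,
      metadata = list(seed = config$seed,
                      config_digest = .config_digest(config),
                      package_version =
                        as.character(utils::packageVersion("gridtill")))),
      class = "screen_report")
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  res
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.config_digest <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Pooled TILLING screen report\n")
  print(x$layout)
  st <- table(factor(x$rows$status,
                     c("confirmed", "row_only", "column_only", "ambiguous",
                       "undetermined")))
  cat(sprintf("  pool hits: %d   calls: %s\n", nrow(x$hits),
              paste(sprintf("%s %d", names(st), st), collapse = ", ")))
  cat(sprintf("  independent variants after duplicate collapse: %d\n",
              nrow(x$collapsed)))
  if (length(x$failed_pools)) {
    cat(sprintf("  failed libraries: %s\n",
                paste(x$failed_pools, collapse = ", ")))
  }
  ev <- x$evaluation
  cat(sprintf("  vs truth: sensitivity %.3f, FDR %.3f, zygosity accuracy %.3f\n",
              ev$sensitivity, ev$fdr, ev$zygosity_accuracy))
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  list(n_hits = nrow(object$hits),
       status = table(object$rows$status),
       n_independent = nrow(object$collapsed),
       spectrum = object$spectrum,
       evaluation = object$evaluation)
}

#' Write a screen report to disk
#'
#' Emits the per-variant table as TSV, confirmed calls as a VCF with
#' STATUS/PLANT/ZYG/MEANAF INFO keys, and a JSON metadata sidecar (seed,
#' config digest, package version) sufficient to re-run the screen
#' bit-identically.
#'
#' @param report a [screen_report][run_pipeline].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$rows, file.path(dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$collapsed, file.path(dir, "independent_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  conf <- report$rows[report$rows$status == "confirmed", , drop = FALSE]
  .write_calls_vcf(conf, file.path(dir, "confirmed.vcf"))
  jsonlite::write_json(report$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @noRd
.write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gridtill",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Deconvolution status\">",
    "##INFO=<ID=PLANT,Number=1,Type=String,Description=\"Carrier plant\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Inferred zygosity\">",
    "##INFO=<ID=MEANAF,Number=1,Type=Float,Description=\"Depth-weighted mean pooled alternate fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  ), con)
  if (nrow(calls)) {
    o <- order(calls$target, calls$position, calls$alt)
    calls <- calls[o, , drop = FALSE]
    info <- sprintf("STATUS=%s;PLANT=%s;ZYG=%s;MEANAF=%.6g",
                    calls$status, calls$plant_id, calls$zygosity,
                    calls$mean_alt_fraction)
    writeLines(paste(calls$target, calls$position, ".", calls$ref,
                     calls$alt, ".", ".", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Write pooled counts as TSV
#'
#' @param counts a [pool_counts][simulate_pool_counts] object.
#' @param path output TSV (pool_id, target, position, ref, A, C, G, T,
#'   depth).
#' @return `path`, invisibly.
#' @export
write_pool_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read pooled counts from TSV
#'
#' @param path TSV written by [write_pool_counts()].
#' @return a `pool_counts` data frame.
#' @export
read_pool_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pool_id", "target", "position", "ref", "A", "C", "G", "T",
            "depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("%s: missing column(s) %s", path,
                           paste(miss, collapse = ", "))
  structure(df[need], class = c("pool_counts", "data.frame"),
            pools = unique(df$pool_id))
}
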