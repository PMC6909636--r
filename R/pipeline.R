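# Pipeline orchestration: a run configuration (YAML or list), the two
# analysis stages composed from the lower-level modules, and a run report.

.default_run_config <- function() {
  list(
    cytobands = NULL,
    genesets = NULL,
    datasets = list(),
    outdir = NULL,
    resolution = "subband",
    cutoff = 0.15,
    gain_threshold = 0.2,
    loss_threshold = -0.2,
    min_genes = 10,
    alpha = 0.05,
    centering = "mean",
    log_transform = FALSE,
    span_fraction = 0.9,
    seed = 1L)
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults, and validates:
#' unknown keys are errors, thresholds must lie in their documented
#' domains, and referenced input files must exist. Per-dataset inputs live
#' under `datasets`, a named map of lists with optional `seg`,
#' `expression`, `clinical` paths.
#'
#' @param config Path to a YAML file, or a list of settings.
#' @param ... Individual settings overriding the file/list values.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  overrides <- list(...)
  defaults <- .default_run_config()
  unknown <- setdiff(names(c(config, overrides)), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, overrides)
  stopifnot(cfg$cutoff >= 0, cfg$cutoff < 1,
            cfg$gain_threshold > 0, cfg$loss_threshold < 0,
            cfg$min_genes >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$span_fraction > 0, cfg$span_fraction <= 1,
            cfg$centering %in% c("mean", "median"),
            cfg$resolution %in% c("subband", "fine"))
  for (p in c(cfg$cytobands, cfg$genesets,
              unlist(cfg$datasets, use.names = FALSE))) {
    if (is.character(p) && !file.exists(p)) {
      stop("configured input file does not exist: ", p, call. = FALSE)
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

.stage_write <- function(df, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outdir, name)
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

.band_set_table <- function(sets) {
  data.frame(
    band = c(sets$amplified, sets$deleted),
    direction = rep(c("amplified", "deleted"),
                    c(length(sets$amplified), length(sets$deleted))),
    frequency = c(sets$gain_freq[sets$amplified],
                  sets$loss_freq[sets$deleted]),
    stringsAsFactors = FALSE)
}

#' Run the gain/loss frequency stage
#'
#' For every dataset with a `seg` input: maps segments to bands, calls
#' gains/losses, and selects frequent bands at the configured cutoff; then
#' takes the union across datasets and collapses adjacent bands to
#' nonredundant representatives. Band copy-number, call, frequency and
#' band-set tables are written under `outdir` when set (atomically, via a
#' temporary file).
#'
#' @param config A `run_config` (see [load_run_config()]).
#' @return A `frequency_stage` list: `catalog`, per-dataset results,
#'   `union`, `nonredundant`, and per-stage counts.
#' @export
run_frequency_stage <- function(config) {
  config <- load_run_config(unclass(config))
  if (is.null(config$cytobands)) stop("config needs 'cytobands'", call. = FALSE)
  catalog <- load_cytobands(config$cytobands, config$resolution)
  ds_names <- names(config$datasets)
  per_dataset <- list()
  for (nm in ds_names) {
    ds <- config$datasets[[nm]]
    if (is.null(ds$seg)) next
    segs <- read_seg(ds$seg)
    if (nrow(segs) == 0L) {
      warning("dataset '", nm, "': segment file is empty; ",
              "emitting an empty frequency table", call. = FALSE)
      per_dataset[[nm]] <- list(band_cnv = NULL, calls = NULL, frequent = NULL,
                                n_samples = 0L)
      .stage_write(data.frame(band = character(0), gain_freq = numeric(0),
                              loss_freq = numeric(0)),
                   config$outdir, paste0("frequencies_", nm, ".tsv"))
      next
    }
    cnv <- map_segments_to_bands(segs, catalog)
    calls <- call_gain_loss(cnv, config$gain_threshold, config$loss_threshold)
    frequent <- select_frequent_bands(calls, config$cutoff)
    per_dataset[[nm]] <- list(band_cnv = cnv, calls = calls,
                              frequent = frequent, n_samples = ncol(cnv))
    .stage_write(data.frame(band = rownames(cnv), cnv, check.names = FALSE),
                 config$outdir, paste0("band_cnv_", nm, ".tsv"))
    .stage_write(data.frame(band = rownames(calls$calls), calls$calls,
                            check.names = FALSE),
                 config$outdir, paste0("calls_", nm, ".tsv"))
    .stage_write(data.frame(band = names(calls$gain_freq),
                            gain_freq = calls$gain_freq,
                            loss_freq = calls$loss_freq),
                 config$outdir, paste0("frequencies_", nm, ".tsv"))
  }
  freq_sets <- Filter(Negate(is.null),
                      lapply(per_dataset, function(d) d$frequent))
  band_union <- if (length(freq_sets)) Reduce(union_band_sets, freq_sets)
                else NULL
  nonredundant <- if (!is.null(band_union)) {
    collapse_redundant_bands(band_union, catalog)
  } else NULL
  if (!is.null(band_union)) {
    .stage_write(.band_set_table(band_union), config$outdir,
                 "frequent_union.tsv")
    .stage_write(.band_set_table(nonredundant), config$outdir,
                 "nonredundant.tsv")
  }
  structure(
    list(catalog = catalog, per_dataset = per_dataset, union = band_union,
         nonredundant = nonredundant, config = config),
    class = "frequency_stage")
}

#' Run the iCNV + survival stage
#'
#' For every dataset with `expression` and `clinical` inputs: normalizes
#' expression, computes iCNVs, runs the univariate Cox screen with BH
#' adjustment, then the covariate-adjusted screen on the bands passing
#' adjusted p < alpha. With two or more datasets the univariate-significant
#' bands are intersected, and for the most significant shared band a
#' median-split Kaplan-Meier comparison and a MYCN-stratified analysis are
#' computed per dataset. Result tables and KM curve data are written under
#' `outdir` when set.
#'
#' @param config A `run_config` (see [load_run_config()]).
#' @param bands Optional band subset to screen (e.g. the frequency stage's
#'   union set).
#' @return A `survival_stage` list with per-dataset `icnv`, `univariate`,
#'   `multivariate`, `km`, `stratified`, plus `intersection`.
#' @export
run_survival_stage <- function(config, bands = NULL) {
  config <- load_run_config(unclass(config))
  if (is.null(config$cytobands) || is.null(config$genesets)) {
    stop("config needs 'cytobands' and 'genesets'", call. = FALSE)
  }
  catalog <- load_cytobands(config$cytobands, config$resolution)
  gene_sets <- load_positional_gene_sets(config$genesets, catalog,
                                         config$min_genes)
  per_dataset <- list()
  for (nm in names(config$datasets)) {
    ds <- config$datasets[[nm]]
    if (is.null(ds$expression) || is.null(ds$clinical)) next
    expr <- read_expression(ds$expression)
    clin <- read_clinical(ds$clinical)
    rel <- normalize_expression(expr, log_transform = config$log_transform,
                                center = config$centering)
    icnv <- compute_icnv(rel, gene_sets)
    m <- icnv$icnv
    if (!is.null(bands)) {
      keep <- intersect(bands, rownames(m))
      if (!length(keep)) stop("no requested band has an iCNV in dataset '",
                              nm, "'", call. = FALSE)
      m <- m[keep, , drop = FALSE]
    }
    uni <- univariate_screen(m, clin)
    sig <- uni$band[uni$status == "ok" & !is.na(uni$p_adj) &
                      uni$p_adj < config$alpha]
    multi <- if (length(sig)) multivariate_screen(m, clin, bands = sig)
             else NULL
    per_dataset[[nm]] <- list(icnv = icnv, clinical = clin, matrix = m,
                              univariate = uni, multivariate = multi,
                              significant = sig)
    .stage_write(as.data.frame(uni), config$outdir,
                 paste0("univariate_", nm, ".tsv"))
    if (!is.null(multi)) {
      .stage_write(as.data.frame(multi), config$outdir,
                   paste0("multivariate_", nm, ".tsv"))
    }
  }
  if (!length(per_dataset)) {
    stop("no dataset provides both expression and clinical inputs",
         call. = FALSE)
  }
  intersection <- if (length(per_dataset) >= 2L) {
    intersect_significant(lapply(per_dataset, `[[`, "univariate"),
                          alpha = config$alpha)
  } else NULL
  focus <- .pick_focus_band(per_dataset, intersection)
  for (nm in names(per_dataset)) {
    d <- per_dataset[[nm]]
    if (is.null(focus) || !(focus %in% rownames(d$matrix))) next
    x <- d$matrix[focus, ]
    km <- tryCatch(km_median_split(x, d$clinical), error = function(e) NULL)
    strat <- tryCatch(suppressWarnings(mycn_stratified_analysis(x, d$clinical)),
                      error = function(e) NULL)
    per_dataset[[nm]]$km <- km
    per_dataset[[nm]]$stratified <- strat
    if (!is.null(km)) {
      .stage_write(km$curves, config$outdir,
                   paste0("km_", focus, "_", nm, ".tsv"))
    }
    if (!is.null(strat)) {
      .stage_write(strat$strata, config$outdir,
                   paste0("mycn_strata_", focus, "_", nm, ".tsv"))
    }
  }
  if (!is.null(intersection)) {
    .stage_write(intersection, config$outdir, "intersection.tsv")
  }
  structure(
    list(per_dataset = per_dataset, intersection = intersection,
         focus_band = focus, config = config),
    class = "survival_stage")
}

# band to illustrate with KM/stratified plots: smallest combined univariate
# p among bands significant everywhere, falling back to the overall top band
.pick_focus_band <- function(per_dataset, intersection) {
  cand <- if (!is.null(intersection) && nrow(intersection)) {
    intersection$band
  } else {
    u <- per_dataset[[1L]]$univariate
    u <- u[u$status == "ok", ]
    if (!nrow(u)) return(NULL)
    u$band
  }
  score <- vapply(cand, function(b) {
    sum(vapply(per_dataset, function(d) {
      p <- d$univariate$p[match(b, d$univariate$band)]
      if (is.na(p)) 0 else -log10(p)
    }, numeric(1)))
  }, numeric(1))
  cand[which.max(score)]
}

#' Summarize a pipeline run
#'
#' Prints per-stage counts (samples, frequent bands, amplified/deleted
#' overlap, excluded bands, failed fits, significant bands) and echoes the
#' resolved thresholds; the same lines are returned invisibly.
#'
#' @param frequency A `frequency_stage` result, or `NULL`.
#' @param survival A `survival_stage` result, or `NULL`.
#' @return Invisibly, the report as a character vector.
#' @export
run_report <- function(frequency = NULL, survival = NULL) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  if (!is.null(frequency)) {
    cfg <- frequency$config
    add("frequency stage (cutoff > ", cfg$cutoff, ", call thresholds +",
        cfg$gain_threshold, "/", cfg$loss_threshold, ")")
    add("  catalog: ", nrow(frequency$catalog), " bands")
    for (nm in names(frequency$per_dataset)) {
      d <- frequency$per_dataset[[nm]]
      if (is.null(d$frequent)) {
        add("  dataset ", nm, ": no segments")
      } else {
        add("  dataset ", nm, ": ", d$n_samples, " samples, ",
            length(d$frequent$amplified), " amplified / ",
            length(d$frequent$deleted), " deleted frequent bands")
      }
    }
    if (!is.null(frequency$union)) {
      add("  union: ", length(frequency$union$amplified), " amplified / ",
          length(frequency$union$deleted), " deleted; ",
          length(frequency$union$overlap), " band(s) in both sets",
          if (length(frequency$union$overlap))
            paste0(" (", paste(frequency$union$overlap, collapse = ", "), ")"))
      add("  nonredundant: ", length(frequency$nonredundant$amplified),
          " amplified / ", length(frequency$nonredundant$deleted), " deleted")
    }
  }
  if (!is.null(survival)) {
    cfg <- survival$config
    add("survival stage (alpha ", cfg$alpha, ", centering ", cfg$centering, ")")
    for (nm in names(survival$per_dataset)) {
      d <- survival$per_dataset[[nm]]
      add("  dataset ", nm, ": ", ncol(d$matrix), " samples, ",
          nrow(d$matrix), " bands screened, ",
          nrow(d$icnv$excluded), " excluded (<",
          d$icnv$min_genes, " genes), ",
          sum(d$univariate$status == "failed"), " failed fits, ",
          length(d$significant), " significant (adjusted p < ", cfg$alpha, ")")
      if (!is.null(d$multivariate)) {
        add("    multivariate: ",
            sum(d$multivariate$status == "ok" &
                  d$multivariate$p < cfg$alpha, na.rm = TRUE),
            " of ", nrow(d$multivariate), " bands at raw p < ", cfg$alpha)
      }
    }
    if (!is.null(survival$intersection)) {
      add("  intersection: ", nrow(survival$intersection),
          " band(s) significant in all datasets, ",
          sum(survival$intersection$discordant), " discordant")
    }
    if (!is.null(survival$focus_band)) {
      add("  focus band: ", survival$focus_band)
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Reproduce the published full-data analysis
#'
#' Drives the complete pipeline over the study's real accessions (Kocak
#' GSE45478 and Pugh NBL-US segment data; Su GSE62564 and Oberthuer
#' E-MTAB-179 expression + clinical data), which must already have been
#' downloaded and converted to the package's input formats under `dir`:
#' `cytoBand.txt`, `c1_positional.gmt`, `kocak.seg`, `pugh.seg`,
#' `su_expression.tsv`, `su_clinical.tsv`, `oberthuer_expression.tsv`,
#' `oberthuer_clinical.tsv`. Returns the headline counts (frequent bands
#' per dataset, union sizes, intersected prognostic bands, multivariate-
#' robust bands). No downloading is performed.
#'
#' @param dir Directory holding the converted accession files.
#' @param outdir Optional output directory for stage tables.
#' @return A list of counts and the two stage results.
#' @export
reproduce_full_study <- function(dir, outdir = NULL) {
  need <- c(cytobands = "cytoBand.txt", genesets = "c1_positional.gmt",
            kocak_seg = "kocak.seg", pugh_seg = "pugh.seg",
            su_expr = "su_expression.tsv", su_clin = "su_clinical.tsv",
            ob_expr = "oberthuer_expression.tsv",
            ob_clin = "oberthuer_clinical.tsv")
  paths <- file.path(dir, need)
  names(paths) <- names(need)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("full-data reproduction needs accession-derived files; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  cfg <- load_run_config(list(
    cytobands = paths[["cytobands"]], genesets = paths[["genesets"]],
    outdir = outdir,
    datasets = list(
      kocak = list(seg = paths[["kocak_seg"]]),
      pugh = list(seg = paths[["pugh_seg"]]),
      su = list(expression = paths[["su_expr"]],
                clinical = paths[["su_clin"]]),
      oberthuer = list(expression = paths[["ob_expr"]],
                       clinical = paths[["ob_clin"]]))))
  freq <- run_frequency_stage(cfg)
  surv <- run_survival_stage(
    cfg, bands = union(freq$union$amplified, freq$union$deleted))
  multi_robust <- Reduce(intersect, lapply(surv$per_dataset, function(d) {
    if (is.null(d$multivariate)) character(0)
    else d$multivariate$band[d$multivariate$status == "ok" &
                               d$multivariate$p < cfg$alpha]
  }))
  list(
    counts = list(
      catalog_bands = nrow(freq$catalog),
      per_dataset = lapply(freq$per_dataset, function(d)
        c(amplified = length(d$frequent$amplified),
          deleted = length(d$frequent$deleted))),
      union_amplified = length(freq$union$amplified),
      union_deleted = length(freq$union$deleted),
      union_total = length(union(freq$union$amplified, freq$union$deleted)),
      overlap_bands = freq$union$overlap,
      intersect_significant = nrow(surv$intersection),
      multivariate_robust = length(multi_robust)),
    frequency = freq, survival = surv,
    multivariate_robust_bands = multi_robust)
}
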