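# Synthetic cohort generator: band-structured copy-number events,
# expression coupled additively to band copy number, and survival drawn
# from a proportional-hazards model, with full ground truth retained so
# every pipeline stage can be checked for recovery.

#' Build a simulation configuration
#'
#' Defaults describe the reference cohort used throughout the test suite:
#' 500 samples, 4 chromosomes x 2 arms x 5 bands, 30 genes per band, one
#' band-level gain (chr1p3) firing in 30% of samples at log2-ratio 0.585
#' (a single-copy gain), expression coupling delta = 0.3 per unit log2
#' copy state with gene noise sd 0.5, exponential survival with a log 2
#' per-unit hazard coefficient on the event band, MYCN amplification in
#' 25% of samples at hazard ratio 3, and 30% independent uniform
#' censoring.
#'
#' @param seed Integer RNG seed.
#' @param n_samples,n_chromosomes,bands_per_arm,genes_per_band Cohort
#'   dimensions.
#' @param band_length Band length in bp.
#' @param events List of events, each `list(target=, direction=, frequency=,
#'   magnitude=)`; `target` is a band ("chr1p3"), an arm ("chr1p") or a
#'   chromosome ("chr1"); `magnitude` is an absolute log2-ratio.
#' @param delta Expression shift per unit of true log2 copy state.
#' @param sigma Gene-level noise standard deviation.
#' @param baseline_hazard Exponential baseline hazard rate.
#' @param beta Named vector of per-band log-hazard coefficients on the true
#'   copy state.
#' @param mycn_prevalence,mycn_loghr MYCN amplification frequency and its
#'   log hazard.
#' @param mycn_cnv_correlation Logit shift of MYCN probability for carriers
#'   of the first event (0 = independent; positive builds confounding).
#' @param censoring_rate Target fraction of censored samples.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 500L,
                              n_chromosomes = 4L,
                              bands_per_arm = 5L,
                              genes_per_band = 30L,
                              band_length = 2e6,
                              events = list(list(target = "chr1p3",
                                                 direction = "gain",
                                                 frequency = 0.3,
                                                 magnitude = 0.585)),
                              delta = 0.3,
                              sigma = 0.5,
                              baseline_hazard = 0.1,
                              beta = c(chr1p3 = log(2)),
                              mycn_prevalence = 0.25,
                              mycn_loghr = log(3),
                              mycn_cnv_correlation = 0,
                              censoring_rate = 0.3) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              bands_per_arm = as.integer(bands_per_arm),
              genes_per_band = as.integer(genes_per_band),
              band_length = band_length, events = events, delta = delta,
              sigma = sigma, baseline_hazard = baseline_hazard, beta = beta,
              mycn_prevalence = mycn_prevalence, mycn_loghr = mycn_loghr,
              mycn_cnv_correlation = mycn_cnv_correlation,
              censoring_rate = censoring_rate)
  stopifnot(cfg$n_samples >= 1L, cfg$n_chromosomes >= 1L,
            cfg$bands_per_arm >= 1L, cfg$genes_per_band >= 1L,
            cfg$band_length > 0, cfg$sigma > 0, cfg$baseline_hazard > 0,
            cfg$mycn_prevalence >= 0, cfg$mycn_prevalence <= 1,
            cfg$censoring_rate >= 0, cfg$censoring_rate < 1)
  for (ev in cfg$events) {
    stopifnot(is.character(ev$target),
              ev$direction %in% c("gain", "loss"),
              ev$frequency >= 0, ev$frequency <= 1,
              is.numeric(ev$magnitude))
  }
  class(cfg) <- "simulation_config"
  cfg
}

.sim_catalog <- function(cfg) {
  rows <- list()
  L <- cfg$band_length
  B <- cfg$bands_per_arm
  for (c in seq_len(cfg$n_chromosomes)) {
    ch <- paste0("chr", c)
    for (arm_i in 1:2) {
      arm <- c("p", "q")[arm_i]
      off <- (arm_i - 1L) * B * L
      rows[[length(rows) + 1L]] <- data.frame(
        band = paste0(ch, arm, seq_len(B)),
        chrom = ch, arm = arm,
        start = off + (seq_len(B) - 1L) * L,
        end = off + seq_len(B) * L,
        stringsAsFactors = FALSE)
    }
  }
  .new_cytoband_catalog(do.call(rbind, rows))
}

.resolve_target <- function(target, catalog) {
  if (target %in% catalog$band) return(which(catalog$band == target))
  if (grepl("^chr[0-9]+[pq]$", target)) {
    ch <- sub("[pq]$", "", target)
    arm <- substr(target, nchar(target), nchar(target))
    rows <- which(catalog$chrom == ch & catalog$arm == arm)
  } else if (grepl("^chr[0-9]+$", target)) {
    rows <- which(catalog$chrom == target)
  } else {
    rows <- integer(0)
  }
  if (!length(rows)) stop("event target '", target,
                          "' matches no band, arm or chromosome", call. = FALSE)
  rows
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Builds a contiguous equal-length band catalog, positional gene sets,
#' per-sample segmental CNV profiles, an expression matrix and a clinical
#' table, all consistent with one underlying truth:
#' * each event fires independently per sample at its frequency; fired
#'   events add their signed log2 magnitude to the target bands
#'   (overlapping opposite-sign events sum);
#' * segments are emitted exactly covering maximal runs of equal non-zero
#'   band value, so mapping them back reproduces the truth;
#' * expression of gene g on band i in sample s is
#'   baseline_g + delta * trueCNV(i, s) + N(0, sigma^2), baselines drawn
#'   once per gene from N(0, 1);
#' * survival is exponential with hazard
#'   lambda0 * exp(sum_k beta_k trueCNV(k, s) + beta_mycn * mycn_s), with
#'   independent uniform censoring calibrated to the configured rate.
#'
#' @param config A `simulation_config`.
#' @return A `synthetic_cohort` list: `catalog`, `gene_sets`, `segments`,
#'   `expression`, `clinical`, `truth` (band_cnv matrix, carriers, beta,
#'   mycn, event/censoring times, config).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  catalog <- .sim_catalog(config)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  nb <- nrow(catalog)

  sets <- lapply(catalog$band, function(b) {
    sprintf("%s_g%03d", b, seq_len(config$genes_per_band))
  })
  names(sets) <- catalog$band
  gene_sets <- .new_positional_gene_sets(sets, catalog, min_genes = 10)

  truth <- matrix(0, nb, n, dimnames = list(catalog$band, samples))
  carriers <- list()
  for (i in seq_along(config$events)) {
    ev <- config$events[[i]]
    rows <- .resolve_target(ev$target, catalog)
    fired <- stats::rbinom(n, 1L, ev$frequency)
    sign <- if (ev$direction == "gain") 1 else -1
    truth[rows, fired == 1L] <- truth[rows, fired == 1L] +
      sign * abs(ev$magnitude)
    carriers[[i]] <- fired
  }
  names(carriers) <- vapply(config$events, function(e)
    paste(e$target, e$direction, sep = ":"), character(1))

  seg_list <- vector("list", n)
  for (s in seq_len(n)) {
    per_chrom <- lapply(unique(catalog$chrom), function(ch) {
      rows <- which(catalog$chrom == ch)
      r <- rle(truth[rows, s])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0
      if (!any(keep)) return(NULL)
      data.frame(sample = samples[s], chrom = ch,
                 start = catalog$start[rows[starts[keep]]],
                 end = catalog$end[rows[ends[keep]]],
                 value = r$values[keep], stringsAsFactors = FALSE)
    })
    seg_list[[s]] <- do.call(rbind, per_chrom)
  }
  segments <- do.call(rbind, seg_list)
  if (is.null(segments)) {
    segments <- data.frame(sample = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           value = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(segments) <- NULL

  genes <- unlist(sets, use.names = FALSE)
  band_of_gene <- rep(seq_len(nb), each = config$genes_per_band)
  baseline <- stats::rnorm(length(genes))
  expr <- baseline + config$delta * truth[band_of_gene, , drop = FALSE] +
    matrix(stats::rnorm(length(genes) * n, 0, config$sigma), length(genes), n)
  dimnames(expr) <- list(genes, samples)

  if (length(config$beta)) {
    missb <- setdiff(names(config$beta), catalog$band)
    if (length(missb)) stop("beta names not in catalog: ",
                            paste(missb, collapse = ", "), call. = FALSE)
  }
  linpred <- rep(0, n)
  if (length(config$beta)) {
    linpred <- linpred +
      colSums(config$beta * truth[names(config$beta), , drop = FALSE])
  }
  mycn_p <- stats::plogis(stats::qlogis(config$mycn_prevalence) +
                            config$mycn_cnv_correlation *
                            (if (length(carriers)) carriers[[1L]] else 0))
  mycn <- stats::rbinom(n, 1L, mycn_p)
  linpred <- linpred + config$mycn_loghr * mycn
  event_time <- stats::rexp(n, rate = config$baseline_hazard * exp(linpred))

  if (config$censoring_rate > 0) {
    f <- function(th) mean(pmin(event_time / th, 1)) - config$censoring_rate
    theta <- stats::uniroot(f, c(1e-12, max(event_time) * 1e6))$root
    censor_time <- stats::runif(n, 0, theta)
  } else {
    censor_time <- rep(Inf, n)
  }
  os_time <- pmin(event_time, censor_time)
  os_event <- as.integer(event_time <= censor_time)

  clinical <- data.frame(
    sample = samples,
    os_time = os_time,
    os_event = os_event,
    age = round(stats::runif(n, 0, 10), 2),
    gender = sample(c("male", "female"), n, replace = TRUE),
    stage = sample(c("1", "2", "2B", "3", "4", "4S"), n, replace = TRUE,
                   prob = c(0.15, 0.10, 0.10, 0.15, 0.40, 0.10)),
    mycn = ifelse(mycn == 1L, "amplified", "nonamplified"),
    stringsAsFactors = FALSE)

  structure(
    list(catalog = catalog, gene_sets = gene_sets, segments = segments,
         expression = expr, clinical = clinical,
         truth = list(band_cnv = truth, carriers = carriers,
                      beta = config$beta, mycn = mycn,
                      mycn_loghr = config$mycn_loghr,
                      event_time = event_time, censor_time = censor_time,
                      config = config)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort: ", ncol(x$truth$band_cnv), " samples, ",
      nrow(x$catalog), " bands, ", nrow(x$expression), " genes, ",
      length(x$truth$carriers), " event(s), ",
      sum(x$clinical$os_event == 0), " censored\n", sep = "")
  invisible(x)
}

#' Check that mapped band values reproduce the simulated truth
#'
#' Compares a [map_segments_to_bands()] result against the generator's true
#' band copy matrix; by construction emitted segments exactly tile the
#' event bands, so the two must agree to numerical tolerance everywhere.
#'
#' @param truth A `synthetic_cohort`, its `truth` element, or the true
#'   bands x samples matrix.
#' @param mapped A bands x samples matrix from [map_segments_to_bands()].
#' @param tol Tolerance (default 1e-9).
#' @return A list: `ok`, `max_abs_diff`, and `offending` (data frame of
#'   band/sample/diff rows exceeding `tol`, empty when `ok`).
#' @export
roundtrip_check <- function(truth, mapped, tol = 1e-9) {
  tm <- if (inherits(truth, "synthetic_cohort")) truth$truth$band_cnv
        else if (is.list(truth) && !is.null(truth$band_cnv)) truth$band_cnv
        else as.matrix(truth)
  mm <- as.matrix(mapped)
  bands <- intersect(rownames(tm), rownames(mm))
  samples <- intersect(colnames(tm), colnames(mm))
  d <- abs(tm[bands, samples, drop = FALSE] - mm[bands, samples, drop = FALSE])
  bad <- which(d > tol, arr.ind = TRUE)
  list(ok = nrow(bad) == 0L,
       max_abs_diff = if (length(d)) max(d) else 0,
       offending = data.frame(band = bands[bad[, 1L]],
                              sample = samples[bad[, 2L]],
                              diff = d[bad], stringsAsFactors = FALSE))
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits cytobands.tsv (UCSC cytoBand dialect), gene_sets.gmt, segments.seg
#' (SEG TSV with header), expression.tsv, clinical.tsv and truth.json under
#' `dir`, all readable by the package's loaders.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cytobands = file.path(dir, "cytobands.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             segments = file.path(dir, "segments.seg"),
             expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  cb <- cohort$catalog
  utils::write.table(
    data.frame(cb$chrom, cb$start, cb$end,
               substring(cb$band, nchar(cb$chrom) + 1L), "gneg"),
    paths["cytobands"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  utils::write.table(cohort$segments, paths["segments"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression(cohort$expression, paths["expression"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(bands = rownames(tr$band_cnv), samples = colnames(tr$band_cnv),
         band_cnv = tr$band_cnv, carriers = tr$carriers,
         beta = as.list(tr$beta), mycn = tr$mycn,
         mycn_loghr = tr$mycn_loghr, event_time = tr$event_time),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read a gene expression matrix
#'
#' Tab-separated, first column gene ids, header of sample ids.
#'
#' @param path Path to the expression TSV.
#' @return A genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write a gene expression matrix
#'
#' Inverse of [read_expression()].
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
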