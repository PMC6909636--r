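# Band-level survival screening: univariate and covariate-adjusted Cox
# proportional-hazards models, cross-dataset intersection, median-split
# Kaplan-Meier comparisons, and MYCN-stratified analyses. All model fits go
# through the survival package (coxph/survfit/survdiff) with Efron tie
# handling.

#' Default ordinal coding of INSS tumor stage
#'
#' Stage 1 -> 1, 2/2A -> 2, 2B and 4S -> 2.5, 3 -> 3, 4 -> 4. The map is an
#' argument of [multivariate_screen()] so other codings can be supplied.
#'
#' @return A named numeric vector.
#' @export
default_stage_map <- function() {
  c("1" = 1, "2" = 2, "2A" = 2, "2B" = 2.5, "3" = 3, "4" = 4, "4S" = 2.5)
}

#' Read a clinical table
#'
#' Tab-separated with header; required columns: sample, os_time (days,
#' non-negative), os_event (0/1), age (years), gender (male/female), stage,
#' mycn (amplified/nonamplified/unknown). A missing column is a hard error
#' naming it.
#'
#' @param path Path to the clinical TSV.
#' @return A validated data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table
#'
#' @param clin Data frame with the columns documented in [read_clinical()].
#' @return The validated data frame (invisibly the same object).
#' @export
validate_clinical <- function(clin) {
  need <- c("sample", "os_time", "os_event", "age", "gender", "stage", "mycn")
  miss <- setdiff(need, names(clin))
  if (length(miss)) {
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  clin$sample <- as.character(clin$sample)
  if (anyDuplicated(clin$sample)) {
    stop("duplicate sample id '", clin$sample[duplicated(clin$sample)][1L],
         "' in clinical table", call. = FALSE)
  }
  if (any(clin$os_time < 0, na.rm = TRUE)) stop("negative os_time", call. = FALSE)
  if (!all(clin$os_event %in% c(0, 1))) {
    stop("os_event must be 0/1", call. = FALSE)
  }
  clin$stage <- as.character(clin$stage)
  clin
}

.align_survival <- function(x, clin) {
  clin <- validate_clinical(clin)
  common <- intersect(colnames(x), clin$sample)
  if (length(common) < 3L) {
    stop("fewer than 3 samples shared between iCNV matrix and clinical table",
         call. = FALSE)
  }
  list(m = x[, common, drop = FALSE],
       clin = clin[match(common, clin$sample), , drop = FALSE])
}

.cox_row <- function(fit, term, conf_level) {
  s <- summary(fit, conf.int = conf_level)
  co <- s$coefficients
  if (!(term %in% rownames(co))) return(NULL)
  beta <- co[term, "coef"]
  se <- co[term, "se(coef)"]
  if (!is.finite(beta) || !is.finite(se)) return(NULL)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p = co[term, "Pr(>|z|)"])
}

.failed_row <- function(band, model, n, n_events, reason) {
  data.frame(band = band, model = model, hr = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, p = NA_real_, p_adj = NA_real_,
             n = n, n_events = n_events, status = "failed", reason = reason,
             stringsAsFactors = FALSE)
}

#' Univariate Cox screen of band iCNVs against overall survival
#'
#' Fits, for every band, a proportional-hazards model with the band's iCNV
#' as the sole continuous covariate, then applies Benjamini-Hochberg
#' adjustment across the successfully fitted bands. Bands whose fit fails
#' (constant covariate, non-convergence) are recorded with
#' `status = "failed"` and excluded from the adjustment denominator, with a
#' warning.
#'
#' @param icnv An `icnv_matrix` (or bands x samples matrix).
#' @param clin Clinical table (see [read_clinical()]); samples are aligned
#'   by id, and at least 2 events are required.
#' @param conf_level Confidence level for the hazard-ratio interval
#'   (default 0.95).
#' @return A `band_survival_result` data frame: band, model, hr, ci_low,
#'   ci_high, p, p_adj, n, n_events, status, reason.
#' @export
univariate_screen <- function(icnv, clin, conf_level = 0.95) {
  al <- .align_survival(.band_matrix(icnv), clin)
  m <- al$m; cl <- al$clin
  if (sum(cl$os_event) < 2L) stop("need at least 2 events", call. = FALSE)
  rows <- lapply(rownames(m), function(b) {
    x <- m[b, ]
    n <- length(x); ne <- sum(cl$os_event)
    if (!all(is.finite(x))) {
      return(.failed_row(b, "univariate", n, ne, "non-finite iCNV"))
    }
    if (stats::sd(x) == 0) {
      return(.failed_row(b, "univariate", n, ne, "constant iCNV"))
    }
    d <- data.frame(time = cl$os_time, event = cl$os_event, x = x)
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ x, data = d, ties = "efron"),
      error = function(e) NULL)
    r <- if (is.null(fit)) NULL else .cox_row(fit, "x", conf_level)
    if (is.null(r)) {
      return(.failed_row(b, "univariate", n, ne, "fit did not converge"))
    }
    data.frame(band = b, model = "univariate", hr = r$hr, ci_low = r$ci_low,
               ci_high = r$ci_high, p = r$p, p_adj = NA_real_, n = n,
               n_events = ne, status = "ok", reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  if (any(!ok)) {
    warning(sum(!ok), " band fit(s) failed and were excluded from the ",
            "multiple-testing adjustment", call. = FALSE)
  }
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  class(out) <- c("band_survival_result", "data.frame")
  out
}

#' Covariate-adjusted Cox models per band
#'
#' Fits, for each requested band, a proportional-hazards model with the
#' band's iCNV plus MYCN status (amplified = 1), age (continuous years),
#' gender (male = 1) and ordinally coded stage as covariates, and returns
#' the iCNV term. Samples with unknown MYCN or any missing covariate are
#' dropped listwise (count in attribute `n_dropped`). Covariates that are
#' constant in the analysis cohort are dropped from the formula, so with
#' all covariates constant the model reduces to the univariate fit.
#'
#' @param icnv An `icnv_matrix` (or bands x samples matrix).
#' @param clin Clinical table (see [read_clinical()]).
#' @param bands Bands to model (default: all rows of `icnv`).
#' @param stage_map Named numeric vector coding stage labels ordinally
#'   (default [default_stage_map()]).
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return A `band_survival_result` data frame (`p_adj` is `NA`: selection
#'   for this model uses raw p-values).
#' @export
multivariate_screen <- function(icnv, clin, bands = NULL,
                                stage_map = default_stage_map(),
                                conf_level = 0.95) {
  al <- .align_survival(.band_matrix(icnv), clin)
  m <- al$m; cl <- al$clin
  if (is.null(bands)) bands <- rownames(m)
  miss <- setdiff(bands, rownames(m))
  if (length(miss)) stop("band(s) not in iCNV matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  unknown_stage <- setdiff(unique(cl$stage), names(stage_map))
  if (length(unknown_stage)) {
    stop("stage label(s) not in stage_map: ",
         paste(unknown_stage, collapse = ", "), call. = FALSE)
  }
  d0 <- data.frame(
    time = cl$os_time, event = cl$os_event,
    mycn = ifelse(cl$mycn == "amplified", 1,
                  ifelse(cl$mycn == "nonamplified", 0, NA)),
    age = cl$age,
    male = as.numeric(cl$gender == "male"),
    stage = unname(stage_map[cl$stage]))
  keep <- stats::complete.cases(d0)
  n_dropped <- sum(!keep)
  d0 <- d0[keep, , drop = FALSE]
  m <- m[, keep, drop = FALSE]
  if (sum(d0$event) < 2L) stop("fewer than 2 events after listwise deletion",
                               call. = FALSE)
  covars <- c("mycn", "age", "male", "stage")
  covars <- covars[vapply(covars, function(v) stats::sd(d0[[v]]) > 0, logical(1))]
  rows <- lapply(bands, function(b) {
    x <- m[b, ]
    n <- nrow(d0); ne <- sum(d0$event)
    if (!all(is.finite(x)) || stats::sd(x) == 0) {
      return(.failed_row(b, "multivariate", n, ne, "constant or non-finite iCNV"))
    }
    d <- cbind(d0, x = x)
    fml <- stats::reformulate(c("x", covars),
                              response = quote(survival::Surv(time, event)))
    fit <- tryCatch(
      survival::coxph(fml, data = d, ties = "efron"),
      error = function(e) NULL)
    r <- if (is.null(fit)) NULL else .cox_row(fit, "x", conf_level)
    if (is.null(r)) {
      return(.failed_row(b, "multivariate", n, ne,
                         "fit did not converge (separation/collinearity)"))
    }
    data.frame(band = b, model = "multivariate", hr = r$hr, ci_low = r$ci_low,
               ci_high = r$ci_high, p = r$p, p_adj = NA_real_, n = n,
               n_events = ne, status = "ok", reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "covariates") <- covars
  class(out) <- c("band_survival_result", "data.frame")
  out
}

#' @export
print.band_survival_result <- function(x, digits = 3, ...) {
  ok <- x$status == "ok"
  cat(x$model[1L], " Cox screen: ", nrow(x), " bands (", sum(!ok),
      " failed), ", x$n_events[1L], " events / ", x$n[1L], " samples\n",
      sep = "")
  d <- as.data.frame(x)[, c("band", "hr", "ci_low", "ci_high", "p", "p_adj")]
  d <- d[order(d$p), ]
  print.data.frame(utils::head(d, 10L), digits = digits, row.names = FALSE)
  if (nrow(d) > 10L) cat("... and", nrow(d) - 10L, "more bands\n")
  invisible(x)
}

#' Intersect significant bands across datasets
#'
#' Keeps the bands significant in every supplied screen (by adjusted
#' p-value where available, raw p otherwise, at `alpha`), annotates the
#' hazard-ratio direction per dataset (HR > 1 poor outcome, HR < 1 good
#' outcome), and flags bands whose direction is discordant between
#' datasets rather than excluding them.
#'
#' @param results Named list of two or more `band_survival_result` objects.
#' @param alpha Significance level (default 0.05).
#' @return A data frame: band, per-dataset `hr_*` and `direction_*`
#'   columns, and `discordant`.
#' @export
intersect_significant <- function(results, alpha = 0.05) {
  stopifnot(is.list(results), length(results) >= 2L)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("dataset", seq_along(results))
  }
  sig_bands <- lapply(results, function(r) {
    p <- ifelse(is.na(r$p_adj), r$p, r$p_adj)
    r$band[r$status == "ok" & p < alpha]
  })
  bands <- Reduce(intersect, sig_bands)
  out <- data.frame(band = bands, stringsAsFactors = FALSE)
  dirs <- matrix(NA_character_, length(bands), length(results))
  for (i in seq_along(results)) {
    r <- results[[i]]
    hr <- r$hr[match(bands, r$band)]
    out[[paste0("hr_", names(results)[i])]] <- hr
    dirs[, i] <- ifelse(hr > 1, "poor", "good")
    out[[paste0("direction_", names(results)[i])]] <- dirs[, i]
  }
  out$discordant <- apply(dirs, 1L, function(d) length(unique(d)) > 1L)
  out
}

.km_curves <- function(fit, labels) {
  s <- summary(fit)
  strata <- if (is.null(s$strata)) factor(rep(labels[1L], length(s$time))) else s$strata
  grp <- sub("^.*=", "", as.character(strata))
  steps <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                      surv = s$surv, stringsAsFactors = FALSE)
  t0 <- data.frame(group = labels, time = 0,
                   n_risk = as.vector(table(factor(grp, levels = labels))),
                   surv = 1, stringsAsFactors = FALSE)
  n0 <- fit$n
  if (length(n0) == length(labels)) t0$n_risk <- n0
  out <- rbind(t0, steps)
  out[order(match(out$group, labels), out$time), , drop = FALSE]
}

#' Median-split Kaplan-Meier comparison for one band
#'
#' Dichotomizes the per-sample iCNV at its median (values at or below the
#' median form the "low" group — documented convention), estimates
#' product-limit curves per group and compares them with the log-rank test.
#'
#' @param x Named numeric vector of per-sample iCNVs (names = sample ids).
#' @param clin Clinical table (see [read_clinical()]).
#' @return A `km_comparison` object: `groups`, `median`, `fit` (survfit),
#'   `curves` (group/time/n_risk/surv step data starting at survival 1),
#'   `p_logrank`, `n`.
#' @export
km_median_split <- function(x, clin) {
  clin <- validate_clinical(clin)
  common <- intersect(names(x), clin$sample)
  if (length(common) < 4L) stop("need at least 4 shared samples", call. = FALSE)
  x <- x[common]
  cl <- clin[match(common, clin$sample), ]
  if (length(unique(x)) == 1L) {
    stop("all iCNV values identical: no median split possible", call. = FALSE)
  }
  med <- stats::median(x)
  grp <- factor(ifelse(x <= med, "low", "high"), levels = c("low", "high"))
  if (min(table(grp)) < 2L) {
    stop("median split leaves a group with fewer than 2 samples", call. = FALSE)
  }
  d <- data.frame(time = cl$os_time, event = cl$os_event, group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  structure(
    list(groups = stats::setNames(grp, common), median = med, fit = fit,
         curves = .km_curves(fit, levels(grp)), p_logrank = p,
         n = table(grp)),
    class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat("Kaplan-Meier comparison (median split at ", signif(x$median, 4), "): ",
      paste(names(x$n), x$n, sep = " = ", collapse = ", "),
      "; log-rank p = ", signif(x$p_logrank, 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.km_comparison <- function(x, col = NULL, xlab = "Time",
                               ylab = "Survival probability", ...) {
  ngrp <- length(x$n)
  if (is.null(col)) col <- seq_len(ngrp)
  graphics::plot(x$fit, col = col, xlab = xlab, ylab = ylab, ...)
  graphics::legend("bottomleft", legend = names(x$n), col = col, lty = 1,
                   bty = "n")
  invisible(x)
}

#' MYCN-stratified analysis of one band's iCNV
#'
#' Splits samples into four groups (iCNV high/low at the overall median x
#' MYCN amplified/nonamplified), compares the four survival curves, and
#' fits, within each MYCN stratum, a univariate Cox model of the high-iCNV
#' indicator. Samples with unknown MYCN are dropped; a stratum with fewer
#' than 2 samples per split group or no events is skipped with a warning.
#'
#' @param x Named numeric vector of per-sample iCNVs.
#' @param clin Clinical table (see [read_clinical()]).
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @return A list: `km` (four-group `km_comparison`-like list with curves
#'   and log-rank p) and `strata` (data frame with per-stratum hr, ci, p,
#'   n, n_events, status).
#' @export
mycn_stratified_analysis <- function(x, clin, conf_level = 0.95) {
  clin <- validate_clinical(clin)
  clin <- clin[clin$mycn %in% c("amplified", "nonamplified"), , drop = FALSE]
  common <- intersect(names(x), clin$sample)
  if (length(common) < 4L) stop("need at least 4 samples with known MYCN",
                                call. = FALSE)
  x <- x[common]
  cl <- clin[match(common, clin$sample), ]
  if (!all(c("amplified", "nonamplified") %in% cl$mycn)) {
    stop("both MYCN strata must be non-empty", call. = FALSE)
  }
  med <- stats::median(x)
  level <- ifelse(x <= med, "low", "high")
  grp <- factor(paste(cl$mycn, level, sep = "/"),
                levels = c("nonamplified/low", "nonamplified/high",
                           "amplified/low", "amplified/high"))
  grp <- droplevels(grp)
  d <- data.frame(time = cl$os_time, event = cl$os_event, group = grp,
                  mycn = cl$mycn, high = as.numeric(level == "high"))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  p4 <- if (nlevels(grp) > 1L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  } else NA_real_
  strata <- lapply(c("nonamplified", "amplified"), function(st) {
    ds <- d[d$mycn == st, , drop = FALSE]
    n <- nrow(ds); ne <- sum(ds$event)
    fail <- function(reason) {
      warning("MYCN ", st, " stratum skipped: ", reason, call. = FALSE)
      data.frame(stratum = st, hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, n = n, n_events = ne,
                 status = "skipped", stringsAsFactors = FALSE)
    }
    if (n < 4L || min(table(factor(ds$high, levels = 0:1))) < 2L) {
      return(fail("fewer than 2 samples per iCNV group"))
    }
    if (ne == 0L) return(fail("no events"))
    fitc <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ high, data = ds,
                      ties = "efron"),
      error = function(e) NULL)
    r <- if (is.null(fitc)) NULL else .cox_row(fitc, "high", conf_level)
    if (is.null(r)) return(fail("fit did not converge"))
    data.frame(stratum = st, hr = r$hr, ci_low = r$ci_low, ci_high = r$ci_high,
               p = r$p, n = n, n_events = ne, status = "ok",
               stringsAsFactors = FALSE)
  })
  list(
    km = structure(
      list(groups = stats::setNames(grp, common), median = med, fit = fit,
           curves = .km_curves(fit, levels(grp)), p_logrank = p4,
           n = table(grp)),
      class = "km_comparison"),
    strata = do.call(rbind, strata))
}
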