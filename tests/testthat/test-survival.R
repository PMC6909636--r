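# Cox screening, intersection, Kaplan-Meier median splits and MYCN strata.

# cohort with realistic dosage coupling so the iCNV is a faithful proxy;
# the default hazard doubles on the gained band (log 2 per carrier, i.e.
# log(2)/0.585 per unit log2-ratio copy state)
strong_cohort <- function(seed, n = 400, beta = log(2) / 0.585, freq = 0.3,
                          corr = 0, mycn_loghr = log(3)) {
  generate_cohort(simulation_config(
    seed = seed, n_samples = n, delta = 1,
    events = list(list(target = "chr1p3", direction = "gain",
                       frequency = freq, magnitude = 0.585)),
    beta = c(chr1p3 = beta), mycn_loghr = mycn_loghr,
    mycn_cnv_correlation = corr))
}

test_that("a true hazard on a band is recovered by the univariate screen", {
  # isolated band effect: hazard doubles on the gain, no MYCN hazard
  co <- strong_cohort(seed = 101, n = 500, mycn_loghr = 0)
  ic <- compute_icnv(normalize_expression(co$expression), co$gene_sets)
  uni <- univariate_screen(ic, co$clinical)
  row <- uni[uni$band == "chr1p3", ]
  expect_equal(row$status, "ok")
  expect_gt(row$hr, 1)
  expect_lt(row$p_adj, 0.05)
  expect_true(all(uni$ci_low <= uni$hr & uni$hr <= uni$ci_high, na.rm = TRUE))
  expect_true(all(uni$p_adj >= uni$p, na.rm = TRUE))
})

test_that("adjusted p-values are BH: monotone in p and p*m/rank pre-step-up", {
  co <- strong_cohort(seed = 102, n = 150)
  ic <- compute_icnv(normalize_expression(co$expression), co$gene_sets)
  uni <- univariate_screen(ic, co$clinical)
  ok <- uni[uni$status == "ok", ]
  ord <- order(ok$p)
  expect_true(all(diff(ok$p_adj[ord]) >= -1e-12))
  m <- nrow(ok)
  raw_bh <- ok$p[ord] * m / seq_len(m)
  stepped <- rev(cummin(rev(raw_bh)))
  expect_equal(ok$p_adj[ord], pmin(stepped, 1))
})

test_that("a constant-iCNV band is recorded as a failed, non-informative fit", {
  co <- strong_cohort(seed = 103, n = 80)
  m <- compute_icnv(normalize_expression(co$expression), co$gene_sets)$icnv
  m["chr4q5", ] <- 1.3
  expect_warning(uni <- univariate_screen(m, co$clinical), "failed")
  row <- uni[uni$band == "chr4q5", ]
  expect_equal(row$status, "failed")
  expect_true(is.na(row$p) && is.na(row$p_adj))
  # failed fits do not enter the adjustment denominator
  ok <- uni[uni$status == "ok", ]
  expect_equal(ok$p_adj, stats::p.adjust(ok$p, "BH"))
})

test_that("with all covariates constant the multivariate fit reduces to univariate", {
  co <- strong_cohort(seed = 104, n = 200)
  ic <- compute_icnv(normalize_expression(co$expression), co$gene_sets)
  clin <- co$clinical
  clin$age <- 3; clin$gender <- "female"; clin$stage <- "4"
  clin$mycn <- "nonamplified"
  uni <- univariate_screen(ic, clin)
  multi <- multivariate_screen(ic, clin, bands = "chr1p3")
  expect_equal(multi$hr[1], uni$hr[uni$band == "chr1p3"], tolerance = 1e-6)
  expect_length(attr(multi, "covariates"), 0)
})

test_that("independent band and MYCN effects are both recovered on true copy state", {
  co <- generate_cohort(simulation_config(
    seed = 105, n_samples = 500, genes_per_band = 1,
    events = list(list(target = "chr1p3", direction = "gain",
                       frequency = 0.4, magnitude = 1)),
    beta = c(chr1p3 = log(1.5)), mycn_loghr = log(3)))
  multi <- multivariate_screen(co$truth$band_cnv, co$clinical,
                               bands = "chr1p3")
  expect_equal(multi$status[1], "ok")
  expect_true(multi$ci_low[1] <= 1.5 && 1.5 <= multi$ci_high[1])
  expect_true("mycn" %in% attr(multi, "covariates"))
})

test_that("an effect acting only through MYCN is explained away by adjustment", {
  co <- generate_cohort(simulation_config(
    seed = 106, n_samples = 600, genes_per_band = 1,
    events = list(list(target = "chr1p3", direction = "gain",
                       frequency = 0.4, magnitude = 1)),
    beta = c(chr1p3 = 0), mycn_loghr = log(4),
    mycn_cnv_correlation = 2.5))
  x <- co$truth$band_cnv
  uni <- univariate_screen(x["chr1p3", , drop = FALSE], co$clinical)
  multi <- multivariate_screen(x, co$clinical, bands = "chr1p3")
  # confounding inflates the crude fit; adjustment removes the association
  expect_gt(uni$hr[1], multi$hr[1])
  expect_gt(multi$p[1], 0.05)
})

test_that("unknown-MYCN samples are dropped only from the adjusted model", {
  co <- strong_cohort(seed = 107, n = 200)
  clin <- co$clinical
  clin$mycn[1:40] <- "unknown"
  ic <- compute_icnv(normalize_expression(co$expression), co$gene_sets)
  uni <- univariate_screen(ic, clin)
  multi <- multivariate_screen(ic, clin, bands = "chr1p3")
  expect_equal(uni$n[1], 200L)
  expect_equal(multi$n[1], 160L)
  expect_equal(attr(multi, "n_dropped"), 40L)
})

test_that("intersection keeps bands significant everywhere and flags discordance", {
  mk <- function(bands, p_adj, hr) {
    structure(data.frame(band = bands, model = "univariate", hr = hr,
                         ci_low = hr / 2, ci_high = hr * 2, p = p_adj / 2,
                         p_adj = p_adj, n = 100L, n_events = 60L,
                         status = "ok", reason = "",
                         stringsAsFactors = FALSE),
              class = c("band_survival_result", "data.frame"))
  }
  a <- mk(c("b1", "b2", "b3"), c(0.01, 0.04, 0.20), c(2.0, 0.5, 1.5))
  b <- mk(c("b1", "b2", "b3"), c(0.03, 0.01, 0.01), c(1.8, 1.6, 1.2))
  out <- intersect_significant(list(ds1 = a, ds2 = b))
  expect_setequal(out$band, c("b1", "b2"))
  expect_false(out$discordant[out$band == "b1"])
  expect_true(out$discordant[out$band == "b2"])
})

test_that("identical survival in both median-split groups gives log-rank p = 1", {
  times <- rep(c(2, 4, 6, 8, 10), 2)
  events <- rep(c(1, 0, 1, 1, 0), 2)
  clin <- make_clinical(10, times, events)
  x <- stats::setNames(rep(c(-1, 1), each = 5), clin$sample)
  km <- km_median_split(x, clin)
  expect_equal(km$p_logrank, 1)
  expect_equal(unname(as.vector(km$n)), c(5L, 5L))
  # curves start at probability 1 and never increase
  for (g in unique(km$curves$group)) {
    s <- km$curves$surv[km$curves$group == g]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
  }
})

test_that("extreme group separation drives the log-rank p toward zero", {
  n <- 400
  clin <- make_clinical(n, time = c(rep(1, n / 2), rep(10, n / 2)),
                        event = c(rep(1, n / 2), rep(0, n / 2)))
  x <- stats::setNames(c(rep(-1, n / 2), rep(1, n / 2)), clin$sample)
  km <- km_median_split(x, clin)
  expect_lt(km$p_logrank, 1e-10)
})

test_that("a hazardous band separates median-split survival curves", {
  co <- strong_cohort(seed = 108, n = 400, beta = log(3) / 0.585, freq = 0.5,
                      mycn_loghr = 0)
  ic <- compute_icnv(normalize_expression(co$expression), co$gene_sets)
  km <- km_median_split(ic$icnv["chr1p3", ], co$clinical)
  expect_lt(km$p_logrank, 0.001)
  # the high-iCNV arm fares worse: lower final survival estimate
  last <- vapply(c("low", "high"), function(g) {
    s <- km$curves$surv[km$curves$group == g]
    s[length(s)]
  }, numeric(1))
  expect_lt(last[["high"]], last[["low"]])
})

test_that("ties at the median land in the low group; no-split is an error", {
  clin <- make_clinical(6, time = 1:6, event = rep(1, 6))
  x <- stats::setNames(c(1, 1, 1, 1, 5, 6), clin$sample)  # median = 1
  km <- km_median_split(x, clin)
  expect_equal(unname(km$groups[1:4]), factor(rep("low", 4),
                                              levels = c("low", "high")))
  expect_error(km_median_split(stats::setNames(rep(2, 6), clin$sample), clin),
               "identical")
})

test_that("the log-rank test agrees with the score test of the binary Cox fit", {
  set.seed(77)
  for (i in 1:5) {
    n <- 150
    grp <- rbinom(n, 1, 0.5)
    time <- rexp(n, rate = 0.1 * exp(0.5 * grp))
    cens <- runif(n, 0, 25)
    clin <- make_clinical(n, pmin(time, cens), as.integer(time <= cens))
    x <- stats::setNames(grp + rnorm(n, 0, 1e-8), clin$sample)
    km <- km_median_split(x, clin)
    fit <- survival::coxph(
      survival::Surv(clin$os_time, clin$os_event) ~ I(x > median(x)))
    p_score <- summary(fit)$sctest["pvalue"]
    expect_lt(abs(km$p_logrank - p_score) / p_score, 0.1)
  }
})

test_that("MYCN-stratified analysis localizes a stratum-specific effect", {
  set.seed(55)
  n <- 500
  mycn <- rbinom(n, 1, 0.3)
  x <- rnorm(n)
  high <- x > median(x)
  # hazard doubled by high iCNV in nonamplified samples only
  rate <- 0.1 * exp(log(2) * high * (mycn == 0) + log(2) * mycn)
  time <- rexp(n, rate)
  cens <- runif(n, 0, 30)
  clin <- make_clinical(n, pmin(time, cens), as.integer(time <= cens),
                        mycn = ifelse(mycn == 1, "amplified", "nonamplified"))
  names(x) <- clin$sample
  out <- mycn_stratified_analysis(x, clin)
  st <- out$strata
  non <- st[st$stratum == "nonamplified", ]
  amp <- st[st$stratum == "amplified", ]
  expect_gt(non$hr, 1.4)
  expect_lt(non$p, 0.01)
  expect_true(amp$ci_low <= 1 && 1 <= amp$ci_high)
  expect_equal(nrow(out$km$curves[out$km$curves$time == 0, ]), 4L)
})

test_that("a global band effect appears in both MYCN strata", {
  set.seed(56)
  n <- 600
  mycn <- rbinom(n, 1, 0.4)
  x <- rnorm(n)
  rate <- 0.1 * exp(log(2.5) * (x > median(x)))
  time <- rexp(n, rate)
  clin <- make_clinical(n, time, rep(1L, n),
                        mycn = ifelse(mycn == 1, "amplified", "nonamplified"))
  names(x) <- clin$sample
  st <- mycn_stratified_analysis(x, clin)$strata
  expect_true(all(st$status == "ok"))
  expect_true(all(st$hr > 1.5))
})

test_that("a degenerate MYCN stratum is skipped with a warning", {
  clin <- make_clinical(9, time = 1:9, event = rep(1, 9),
                        mycn = c(rep("nonamplified", 8), "amplified"))
  x <- stats::setNames(c(1:8, 2), clin$sample)
  w <- capture_warnings(out <- mycn_stratified_analysis(x, clin))
  expect_true(any(grepl("amplified stratum skipped", w)))
  expect_equal(out$strata$status[out$strata$stratum == "amplified"], "skipped")
})

test_that("clinical validation names missing columns and bad values", {
  clin <- make_clinical(4, 1:4, rep(1, 4))
  expect_error(validate_clinical(clin[, -7]), "mycn")
  bad <- clin; bad$os_event[1] <- 2
  expect_error(validate_clinical(bad), "os_event")
  bad2 <- clin; bad2$sample[2] <- bad2$sample[1]
  expect_error(validate_clinical(bad2), "duplicate sample")
})
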