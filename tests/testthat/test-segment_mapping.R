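# Length-weighted segment-to-band mapping, gain/loss calling, frequency
# selection, union, redundancy collapse and arm-level classification.

test_that("a segment exactly covering a band transfers its value", {
  cat <- toy_catalog()
  segs <- data.frame(sample = "S1", chrom = "chr1", start = 0, end = 100,
                     value = 0.8)
  m <- map_segments_to_bands(segs, cat)
  expect_equal(m["chr1p2", "S1"], 0.8)
  expect_equal(m["chr1p1", "S1"], 0)
  expect_equal(attr(m, "provenance"), "mapped")
})

test_that("partial overlaps combine as the length-weighted sum", {
  # band [0,100); 40 bp at +1.0 and 60 bp at -1.0 -> 0.4 - 0.6 = -0.2
  cat <- load_cytobands(write_ucsc_cytobands(data.frame(
    chrom = "chr1", start = 0, end = 100, name = "p1")), "fine")
  segs <- data.frame(sample = "S1", chrom = "chr1",
                     start = c(0, 40), end = c(40, 100), value = c(1, -1))
  m <- map_segments_to_bands(segs, cat)
  expect_equal(m["chr1p1", "S1"], -0.2)
})

test_that("samples with zero segments get all-zero columns", {
  cat <- toy_catalog()
  segs <- data.frame(sample = "S1", chrom = "chr1", start = 0, end = 100,
                     value = 1)
  m <- map_segments_to_bands(segs, cat, samples = c("S1", "S2"))
  expect_equal(unname(m[, "S2"]), rep(0, nrow(cat)))
})

test_that("segments on unknown chromosomes are skipped with a warning", {
  cat <- toy_catalog()
  segs <- data.frame(sample = "S1", chrom = c("chr1", "chr7"),
                     start = c(0, 0), end = c(100, 50), value = c(1, 2))
  expect_warning(m <- map_segments_to_bands(segs, cat), "chr7")
  expect_equal(m["chr1p2", "S1"], 1)
})

test_that("overlapping segments within a sample are rejected", {
  cat <- toy_catalog()
  segs <- data.frame(sample = "S1", chrom = "chr1",
                     start = c(0, 50), end = c(80, 120), value = c(1, 1))
  expect_error(map_segments_to_bands(segs, cat), "overlapping segments")
})

test_that("mapping matches the per-basepair oracle on random cases", {
  set.seed(42)
  for (i in 1:20) {
    case <- random_mapping_case()
    got <- map_segments_to_bands(case$segments, case$catalog)
    want <- brute_force_band_cnv(case$segments, case$catalog)
    expect_lt(max(abs(got[rownames(want), colnames(want)] - want)), 1e-9)
  }
})

test_that("mapping is linear in the segment values", {
  set.seed(7)
  case <- random_mapping_case()
  m1 <- map_segments_to_bands(case$segments, case$catalog)
  scaled <- case$segments
  scaled$value <- scaled$value * -2.5
  m2 <- map_segments_to_bands(scaled, case$catalog)
  expect_equal(m2, -2.5 * m1)
})

test_that("gain/loss calls use strict thresholds", {
  m <- matrix(c(0.5, -0.5, 0.1, 0, 0.2, -0.2), nrow = 2, byrow = TRUE,
              dimnames = list(c("b1", "b2"), c("S1", "S2", "S3")))
  calls <- call_gain_loss(m, 0.2, -0.2)
  expect_equal(unname(calls$calls["b1", ]), c(1L, -1L, 0L))
  # values exactly at the threshold are neutral
  expect_equal(unname(calls$calls["b2", ]), c(0L, 0L, 0L))
  expect_equal(unname(calls$gain_freq["b1"]), 1 / 3)
  expect_equal(unname(calls$loss_freq["b1"]), 1 / 3)
  expect_error(call_gain_loss(m, -0.1, 0.1), "exceed")
  expect_error(call_gain_loss(m, 0.2, 0.1), "gain_threshold > 0 > loss_threshold")
})

test_that("frequency selection is strict and allows a band in both sets", {
  calls <- structure(list(
    calls = matrix(0L, 3, 1, dimnames = list(c("b1", "b2", "b3"), "S1")),
    gain_freq = c(b1 = 0.16, b2 = 0.18, b3 = 0.15),
    loss_freq = c(b1 = 0.02, b2 = 0.26, b3 = 0.15),
    gain_threshold = 0.2, loss_threshold = -0.2),
    class = "gain_loss_calls")
  sets <- select_frequent_bands(calls, 0.15)
  expect_equal(sets$amplified, c("b1", "b2"))
  expect_equal(sets$deleted, "b2")
  expect_equal(sets$overlap, "b2")
  # exactly at the cutoff is not frequent
  expect_false("b3" %in% c(sets$amplified, sets$deleted))
})

test_that("union of band sets is componentwise with max frequencies", {
  mk <- function(amp, del, gf, lf) {
    structure(list(amplified = amp, deleted = del,
                   overlap = intersect(amp, del), cutoff = 0.15,
                   gain_freq = gf, loss_freq = lf),
              class = "frequent_band_sets")
  }
  a <- mk("chr17q21", character(0), c(chr17q21 = 0.95), c(chr17q21 = 0))
  b <- mk("chr2p24", character(0), c(chr2p24 = 0.3), c(chr2p24 = 0))
  u <- union_band_sets(a, b)
  expect_setequal(u$amplified, c("chr17q21", "chr2p24"))
  expect_equal(union_band_sets(a, a)$amplified, a$amplified)
  expect_equal(unname(union_band_sets(a, a)$gain_freq["chr17q21"]), 0.95)
})

test_that("adjacent same-direction frequent bands collapse to the max-frequency representative", {
  cat <- load_cytobands(write_ucsc_cytobands(data.frame(
    chrom = "chr1", start = c(0, 100, 200, 300, 400),
    end = c(100, 200, 300, 400, 500),
    name = c("p36", "p35", "p34", "p33", "p32"))), "fine")
  sets <- structure(list(
    amplified = character(0),
    deleted = c("chr1p36", "chr1p35", "chr1p34", "chr1p33"),
    overlap = character(0), cutoff = 0.15,
    gain_freq = numeric(0),
    loss_freq = c(chr1p36 = 0.36, chr1p35 = 0.30, chr1p34 = 0.22,
                  chr1p33 = 0.18)),
    class = "frequent_band_sets")
  out <- collapse_redundant_bands(sets, cat)
  expect_equal(out$deleted, "chr1p36")
})

test_that("collapse keeps singletons, breaks ties proximally, respects arms", {
  cat <- load_cytobands(write_ucsc_cytobands(data.frame(
    chrom = "chr2", start = c(0, 100, 200, 300),
    end = c(100, 200, 300, 400),
    name = c("p2", "p1", "q1", "q2"))), "fine")
  sets <- structure(list(
    amplified = c("chr2p2", "chr2p1", "chr2q1", "chr2q2"),
    deleted = character(0), overlap = character(0), cutoff = 0.15,
    gain_freq = c(chr2p2 = 0.4, chr2p1 = 0.4, chr2q1 = 0.2, chr2q2 = 0.5),
    loss_freq = numeric(0)),
    class = "frequent_band_sets")
  out <- collapse_redundant_bands(sets, cat)
  # p cluster ties at 0.4 -> smaller start wins; q cluster separate despite
  # genomic adjacency across the centromere
  expect_setequal(out$amplified, c("chr2p2", "chr2q2"))
  # a frequent band with no frequent neighbour is its own cluster
  solo <- structure(list(amplified = "chr2q2", deleted = character(0),
                         overlap = character(0), cutoff = 0.15,
                         gain_freq = c(chr2q2 = 0.2), loss_freq = numeric(0)),
                    class = "frequent_band_sets")
  expect_equal(collapse_redundant_bands(solo, cat)$amplified, "chr2q2")
})

test_that("arm- and chromosome-level events are classified by length coverage", {
  cat <- load_cytobands(write_ucsc_cytobands(data.frame(
    chrom = "chr11", start = c(0, 85, 100, 150),
    end = c(85, 100, 150, 200),
    name = c("p2", "p1", "q2", "q1"))), "fine")
  # S1: whole-chromosome loss; S2: whole-arm gain of 11p only;
  # S3: 85% of 11p length lost -> below the 0.9 span -> no event
  cnv <- matrix(c(-1, -1, -1, -1,
                  1,  1,  0,  0,
                  -1, 0,  0,  0), nrow = 4,
                dimnames = list(c("chr11p2", "chr11p1", "chr11q2", "chr11q1"),
                                c("S1", "S2", "S3")))
  ev <- classify_arm_level_events(call_gain_loss(cnv), cat, span_fraction = 0.9)
  get <- function(s, col) ev[[col]][ev$sample == s & ev$chrom == "chr11"]
  expect_equal(get("S1", "p_event"), "loss")
  expect_equal(get("S1", "q_event"), "loss")
  expect_equal(get("S1", "chrom_event"), "loss")
  expect_equal(get("S2", "p_event"), "gain")
  expect_equal(get("S2", "q_event"), "none")
  expect_equal(get("S2", "chrom_event"), "none")
  expect_equal(get("S3", "p_event"), "none")
})

test_that("SEG reading validates structure and accepts seg.value headers", {
  f <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tseg.value",
               "S1\t1\t0\t100\t0.5",
               "S1\tchr2\t0\t50\t-0.3"), f)
  segs <- read_seg(f)
  expect_equal(segs$chrom, c("chr1", "chr2"))
  expect_equal(segs$value, c(0.5, -0.3))
  f2 <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tvalue", "S1\tchr1\t100\t100\t0.5"), f2)
  expect_error(read_seg(f2), "end <= start")
})
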