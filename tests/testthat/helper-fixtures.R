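# Fixtures are built in code: writers for the standard text formats and a
# brute-force per-basepair oracle for the segment-to-band mapping.

# write UCSC cytoBand.txt-style lines; rows = data.frame(chrom, start, end, name)
write_ucsc_cytobands <- function(rows, path = tempfile(fileext = ".txt")) {
  writeLines(sprintf("%s\t%d\t%d\t%s\tgneg",
                     rows$chrom, as.integer(rows$start), as.integer(rows$end),
                     rows$name), path)
  path
}

# a small two-chromosome sub-band catalog used across tests
toy_catalog <- function() {
  load_cytobands(write_ucsc_cytobands(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(0, 100, 250, 0, 500),
    end   = c(100, 250, 400, 500, 800),
    name  = c("p2", "p1", "q1", "p1", "q1"))), resolution = "fine")
}

write_gmt_lines <- function(sets, path = tempfile(fileext = ".gmt")) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  path
}

# independent oracle: per-basepair average of segment values over each band,
# uncovered basepairs contributing 0
brute_force_band_cnv <- function(segments, catalog,
                                 samples = unique(segments$sample)) {
  M <- matrix(0, nrow(catalog), length(samples),
              dimnames = list(catalog$band, samples))
  for (s in samples) {
    for (bi in seq_len(nrow(catalog))) {
      len <- catalog$end[bi] - catalog$start[bi]
      bp <- numeric(len)
      segs <- segments[segments$sample == s &
                         segments$chrom == catalog$chrom[bi], , drop = FALSE]
      for (j in seq_len(nrow(segs))) {
        lo <- max(segs$start[j], catalog$start[bi])
        hi <- min(segs$end[j], catalog$end[bi])
        if (hi > lo) {
          bp[(lo - catalog$start[bi] + 1):(hi - catalog$start[bi])] <- segs$value[j]
        }
      }
      M[bi, s] <- mean(bp)
    }
  }
  M
}

# random small catalog + non-overlapping segments for oracle comparisons;
# all coordinates below 2000
random_mapping_case <- function(n_samples = 3) {
  chroms <- c("chr1", "chr2")
  rows <- do.call(rbind, lapply(chroms, function(ch) {
    cuts <- sort(sample(1:1999, sample(2:5, 1)))
    bounds <- unique(c(0, cuts, 2000))
    nb <- length(bounds) - 1L
    arm <- c(rep("p", ceiling(nb / 2)), rep("q", floor(nb / 2)))
    idx <- stats::ave(seq_len(nb), arm, FUN = seq_along)
    data.frame(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1L],
               name = paste0(arm, idx))
  }))
  catalog <- load_cytobands(write_ucsc_cytobands(rows), resolution = "fine")
  segs <- do.call(rbind, lapply(seq_len(n_samples), function(s) {
    do.call(rbind, lapply(chroms, function(ch) {
      cuts <- sort(sample(1:1999, sample(2:6, 1)))
      bounds <- unique(c(0, cuts, 2000))
      n_iv <- length(bounds) - 1L
      keep <- which(stats::runif(n_iv) < 0.6)
      if (!length(keep)) return(NULL)
      data.frame(sample = paste0("S", s), chrom = ch,
                 start = bounds[keep], end = bounds[keep + 1L],
                 value = round(stats::rnorm(length(keep)), 3))
    }))
  }))
  list(catalog = catalog, segments = segs)
}

# minimal clinical table builder
make_clinical <- function(n, time, event, mycn = rep("nonamplified", n),
                          stage = rep("4", n)) {
  data.frame(sample = sprintf("S%03d", seq_len(n)), os_time = time,
             os_event = event, age = rep(2, n),
             gender = rep(c("male", "female"), length.out = n),
             stage = stage, mycn = mycn, stringsAsFactors = FALSE)
}
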