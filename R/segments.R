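# Segment-to-band mapping and recurrent gain/loss selection.
#
# The band-level copy number of band i in one sample is the length-weighted
# sum over that sample's segments,
#
#   CNV(i) = sum_j (l_ij / l_i) * SCNV(j),
#
# where l_i is the band length, l_ij the band/segment overlap, and SCNV(j)
# the segment's log-ratio value. Basepairs not covered by any segment
# contribute 0 (neutral), so a band untouched by segments scores exactly 0.

.validate_segments <- function(segments) {
  need <- c("sample", "chrom", "start", "end", "value")
  miss <- setdiff(need, names(segments))
  if (length(miss)) {
    stop("segment table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(segments) == 0L) return(segments)
  if (any(segments$end <= segments$start)) {
    i <- which(segments$end <= segments$start)[1L]
    stop("segment with end <= start (sample ", segments$sample[i],
         ", ", segments$chrom[i], ":", segments$start[i], "-",
         segments$end[i], ")", call. = FALSE)
  }
  key <- paste(segments$sample, segments$chrom)
  for (k in unique(key)) {
    d <- segments[key == k, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop("overlapping segments within sample ", d$sample[1L],
           " on ", d$chrom[1L], call. = FALSE)
    }
  }
  segments
}

#' Read a SEG-like table of segmental copy-number calls
#'
#' Expects a tab-separated file with a header naming the columns sample,
#' chrom, start, end and a value column (`value`, `seg.value` or
#' `seg.mean`), coordinates 0-based half-open, values on a log-ratio scale.
#' Segments within a sample and chromosome must not overlap.
#'
#' @param path Path to the SEG TSV.
#' @return A data frame with columns sample, chrom, start, end, value.
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  vcol <- intersect(c("value", "seg.value", "seg.mean"), names(df))
  if (!length(vcol)) stop("no value column (value/seg.value/seg.mean) in '",
                          path, "'", call. = FALSE)
  names(df)[names(df) == vcol[1L]] <- "value"
  df <- df[, c("sample", "chrom", "start", "end", "value")]
  df$sample <- as.character(df$sample)
  df$chrom <- .normalize_chrom(df$chrom)
  .validate_segments(df)
}

#' Map segmental copy-number calls to chromosome bands
#'
#' Computes, for every band and sample, the length-weighted sum of the
#' sample's segment values over the band: overlap-length / band-length times
#' the segment value, summed over segments. Bands untouched by any segment
#' score 0. Segments on chromosomes absent from the catalog are skipped with
#' one warning.
#'
#' @param segments Segment data frame (see [read_seg()]): sample, chrom,
#'   start, end, value; 0-based half-open; non-overlapping within a sample
#'   and chromosome.
#' @param catalog A `cytoband_catalog`.
#' @param samples Optional character vector of sample ids for the matrix
#'   columns; defaults to the samples present in `segments`. Samples with no
#'   segments get all-zero columns.
#' @return A bands x samples numeric matrix with attribute
#'   `provenance = "mapped"`.
#' @export
map_segments_to_bands <- function(segments, catalog, samples = NULL) {
  stopifnot(inherits(catalog, "cytoband_catalog"))
  segments <- .validate_segments(as.data.frame(segments))
  if (is.null(samples)) samples <- unique(segments$sample)
  samples <- as.character(samples)
  nb <- nrow(catalog)
  M <- matrix(0, nrow = nb, ncol = length(samples),
              dimnames = list(catalog$band, samples))
  unknown <- !(segments$chrom %in% catalog$chrom)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " segment(s) on chromosome(s) ",
            paste(unique(segments$chrom[unknown]), collapse = ", "),
            " absent from the catalog", call. = FALSE)
    segments <- segments[!unknown, , drop = FALSE]
  }
  stray <- setdiff(unique(segments$sample), samples)
  if (length(stray)) {
    stop("segments present for sample(s) not in `samples`: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  for (ch in unique(segments$chrom)) {
    b <- which(catalog$chrom == ch)
    s <- which(segments$chrom == ch)
    ir_b <- IRanges::IRanges(start = catalog$start[b] + 1, end = catalog$end[b])
    ir_s <- IRanges::IRanges(start = segments$start[s] + 1, end = segments$end[s])
    h <- IRanges::findOverlaps(ir_b, ir_s)
    if (!length(h)) next
    q <- S4Vectors::queryHits(h)
    j <- S4Vectors::subjectHits(h)
    ov <- IRanges::width(IRanges::pintersect(ir_b[q], ir_s[j]))
    contrib <- ov / catalog$length[b][q] * segments$value[s][j]
    col <- match(segments$sample[s][j], samples)
    key <- (col - 1) * nb + b[q]
    agg <- rowsum(contrib, group = key)
    k <- as.numeric(rownames(agg))
    M[cbind(((k - 1) %% nb) + 1, ((k - 1) %/% nb) + 1)] <- agg[, 1L]
  }
  attr(M, "provenance") <- "mapped"
  M
}

#' Call per-band gains and losses and their population frequencies
#'
#' Thresholds the band x sample copy-number matrix into ternary calls
#' (+1 gain where value > `gain_threshold`, -1 loss where value <
#' `loss_threshold`, else 0; strict inequalities) and computes per-band
#' gain/loss frequencies as the fraction of all samples called.
#'
#' @param cnv Bands x samples numeric matrix on a log-ratio scale.
#' @param gain_threshold Positive log-ratio above which a band is called
#'   gained (default 0.2, common aCGH practice).
#' @param loss_threshold Negative log-ratio below which a band is called
#'   lost (default -0.2).
#' @return A `gain_loss_calls` object: integer `calls` matrix in
#'   \{-1, 0, +1\}, named `gain_freq` and `loss_freq` vectors, and the
#'   thresholds used.
#' @export
call_gain_loss <- function(cnv, gain_threshold = 0.2, loss_threshold = -0.2) {
  if (gain_threshold <= loss_threshold) {
    stop("gain_threshold must exceed loss_threshold", call. = FALSE)
  }
  if (gain_threshold <= 0 || loss_threshold >= 0) {
    stop("need gain_threshold > 0 > loss_threshold", call. = FALSE)
  }
  cnv <- as.matrix(cnv)
  calls <- matrix(0L, nrow(cnv), ncol(cnv), dimnames = dimnames(cnv))
  calls[cnv > gain_threshold] <- 1L
  calls[cnv < loss_threshold] <- -1L
  structure(
    list(calls = calls,
         gain_freq = rowMeans(calls == 1L),
         loss_freq = rowMeans(calls == -1L),
         gain_threshold = gain_threshold,
         loss_threshold = loss_threshold),
    class = "gain_loss_calls")
}

#' @export
print.gain_loss_calls <- function(x, ...) {
  cat("gain/loss calls: ", nrow(x$calls), " bands x ", ncol(x$calls),
      " samples (thresholds +", x$gain_threshold, " / ",
      x$loss_threshold, ")\n", sep = "")
  invisible(x)
}

#' Select frequently gained/lost chromosome bands
#'
#' A band is frequently amplified when its gain frequency strictly exceeds
#' the cutoff, frequently deleted when its loss frequency does; a band can
#' be both (reported in `overlap`).
#'
#' @param calls A `gain_loss_calls` object.
#' @param cutoff Frequency cutoff (default 0.15).
#' @return A `frequent_band_sets` object with `amplified`, `deleted`,
#'   `overlap` band vectors, the cutoff, and the per-band frequencies.
#' @export
select_frequent_bands <- function(calls, cutoff = 0.15) {
  stopifnot(inherits(calls, "gain_loss_calls"), cutoff >= 0, cutoff < 1)
  amp <- names(calls$gain_freq)[calls$gain_freq > cutoff]
  del <- names(calls$loss_freq)[calls$loss_freq > cutoff]
  structure(
    list(amplified = amp, deleted = del, overlap = intersect(amp, del),
         cutoff = cutoff, gain_freq = calls$gain_freq,
         loss_freq = calls$loss_freq),
    class = "frequent_band_sets")
}

#' Union of frequent-band sets across datasets
#'
#' Componentwise set union of the amplified and deleted sets; per-band
#' frequencies are carried forward as the maximum across the inputs (used
#' downstream to pick cluster representatives), and the amplified/deleted
#' overlap is recomputed on the union.
#'
#' @param a,b `frequent_band_sets` objects computed at the same cutoff.
#' @return A `frequent_band_sets` object.
#' @export
union_band_sets <- function(a, b) {
  stopifnot(inherits(a, "frequent_band_sets"), inherits(b, "frequent_band_sets"))
  if (!isTRUE(all.equal(a$cutoff, b$cutoff))) {
    stop("cannot union band sets computed at different cutoffs", call. = FALSE)
  }
  merge_freq <- function(fa, fb) {
    bands <- union(names(fa), names(fb))
    va <- fa[match(bands, names(fa))]; va[is.na(va)] <- 0
    vb <- fb[match(bands, names(fb))]; vb[is.na(vb)] <- 0
    stats::setNames(pmax(va, vb), bands)
  }
  amp <- union(a$amplified, b$amplified)
  del <- union(a$deleted, b$deleted)
  structure(
    list(amplified = amp, deleted = del, overlap = intersect(amp, del),
         cutoff = a$cutoff,
         gain_freq = merge_freq(a$gain_freq, b$gain_freq),
         loss_freq = merge_freq(a$loss_freq, b$loss_freq)),
    class = "frequent_band_sets")
}

#' @export
print.frequent_band_sets <- function(x, ...) {
  cat("frequent bands (freq > ", x$cutoff, "): ",
      length(x$amplified), " amplified, ", length(x$deleted), " deleted",
      if (length(x$overlap)) paste0(", ", length(x$overlap), " in both"),
      "\n", sep = "")
  invisible(x)
}

#' Collapse genomically adjacent frequent bands to nonredundant representatives
#'
#' Consecutive frequent bands of the same direction within one chromosome
#' arm form a cluster (adjacent rows of the catalog; clusters never cross
#' the centromere); each cluster is replaced by its band of maximal
#' frequency in that direction, ties broken by smallest start coordinate.
#'
#' @param sets A `frequent_band_sets` object (frequencies carried inside).
#' @param catalog The `cytoband_catalog` the sets were computed against.
#' @return A `frequent_band_sets` object holding only the representatives.
#' @export
collapse_redundant_bands <- function(sets, catalog) {
  stopifnot(inherits(sets, "frequent_band_sets"),
            inherits(catalog, "cytoband_catalog"))
  pick <- function(members, freq) {
    if (!length(members)) return(character(0))
    idx <- match(members, catalog$band)
    if (anyNA(idx)) {
      stop("band '", members[is.na(idx)][1L], "' not in catalog", call. = FALSE)
    }
    idx <- sort(idx)
    armkey <- paste(catalog$chrom[idx], catalog$arm[idx])
    newrun <- c(TRUE, diff(idx) != 1L | armkey[-1L] != armkey[-length(armkey)])
    cluster <- cumsum(newrun)
    vapply(split(idx, cluster), function(rows) {
      f <- freq[catalog$band[rows]]
      best <- rows[f == max(f)]
      catalog$band[best[which.min(catalog$start[best])]]
    }, character(1), USE.NAMES = FALSE)
  }
  amp <- pick(sets$amplified, sets$gain_freq)
  del <- pick(sets$deleted, sets$loss_freq)
  structure(
    list(amplified = amp, deleted = del, overlap = intersect(amp, del),
         cutoff = sets$cutoff, gain_freq = sets$gain_freq,
         loss_freq = sets$loss_freq),
    class = "frequent_band_sets")
}

#' Classify whole-arm and whole-chromosome events per sample
#'
#' An arm-level event is declared for a sample when the bands sharing one
#' non-zero call cover at least `span_fraction` of the arm's total band
#' length; a whole-chromosome event when both arms qualify with the same
#' sign.
#'
#' @param calls A `gain_loss_calls` object.
#' @param catalog The `cytoband_catalog` behind the calls.
#' @param span_fraction Minimum fraction of arm length sharing the call
#'   (default 0.9); must be in (0, 1].
#' @return A data frame with one row per sample x chromosome: columns
#'   `sample`, `chrom`, `p_event`, `q_event`, `chrom_event`, each in
#'   \{"gain", "loss", "none"\} (arm columns are "none" for absent arms).
#' @export
classify_arm_level_events <- function(calls, catalog, span_fraction = 0.9) {
  stopifnot(inherits(calls, "gain_loss_calls"),
            inherits(catalog, "cytoband_catalog"),
            span_fraction > 0, span_fraction <= 1)
  cm <- calls$calls[catalog$band, , drop = FALSE]
  samples <- colnames(cm)
  chroms <- unique(catalog$chrom)
  arm_call <- function(rows, s) {
    if (!length(rows)) return("none")
    len <- catalog$length[rows]
    v <- cm[rows, s]
    gain <- sum(len[v == 1L]) / sum(len)
    loss <- sum(len[v == -1L]) / sum(len)
    if (gain >= span_fraction && gain >= loss) "gain"
    else if (loss >= span_fraction) "loss"
    else "none"
  }
  out <- expand.grid(sample = samples, chrom = chroms,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  p_rows <- lapply(chroms, function(ch) which(catalog$chrom == ch & catalog$arm == "p"))
  q_rows <- lapply(chroms, function(ch) which(catalog$chrom == ch & catalog$arm == "q"))
  names(p_rows) <- names(q_rows) <- chroms
  out$p_event <- mapply(function(ch, s) arm_call(p_rows[[ch]], s),
                        out$chrom, out$sample, USE.NAMES = FALSE)
  out$q_event <- mapply(function(ch, s) arm_call(q_rows[[ch]], s),
                        out$chrom, out$sample, USE.NAMES = FALSE)
  out$chrom_event <- ifelse(
    out$p_event != "none" & out$p_event == out$q_event, out$p_event, "none")
  out
}
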