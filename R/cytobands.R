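# Cytoband catalog: the band coordinate universe every other stage consumes.
# All coordinates are 0-based half-open (UCSC convention).

.normalize_chrom <- function(x) {
  x <- as.character(x)
  if (!length(x)) return(character(0))
  paste0("chr", sub("^chr", "", x, ignore.case = TRUE))
}

.chrom_num <- function(chrom) {
  suppressWarnings(as.integer(sub("^chr", "", chrom)))
}

.new_cytoband_catalog <- function(df) {
  df <- df[order(.chrom_num(df$chrom), df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end <= df$start)) {
    bad <- df$band[df$end <= df$start][1L]
    stop("band '", bad, "' has end <= start", call. = FALSE)
  }
  if (anyDuplicated(df$band)) {
    stop("duplicate band name '", df$band[duplicated(df$band)][1L], "'", call. = FALSE)
  }
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) > 1L) {
      ov <- which(d$start[-1L] < d$end[-nrow(d)])
      if (length(ov)) {
        stop("overlapping bands '", d$band[ov[1L]], "' and '", d$band[ov[1L] + 1L],
             "' on ", ch, call. = FALSE)
      }
    }
  }
  df$length <- df$end - df$start
  class(df) <- c("cytoband_catalog", "data.frame")
  df
}

#' Load a cytoband catalog from a UCSC cytoBand.txt file
#'
#' Reads the tab-separated UCSC dialect (chrom, start, end, band name, stain;
#' no header; 0-based half-open coordinates), drops every band on the X and Y
#' chromosomes, and optionally merges fine bands (e.g. 1p36.33, 1p36.32) into
#' sub-band resolution (chr1p36) via [aggregate_to_subband()]. The "chr"
#' prefix is accepted and normalized in either form.
#'
#' @param path Path to a cytoBand.txt-style TSV.
#' @param resolution `"subband"` (default) merges fine bands sharing a
#'   `<chrom><arm><major>` prefix; `"fine"` keeps the file's bands as is.
#' @return A `cytoband_catalog`: a data frame with columns `band` (e.g.
#'   "chr1p36"), `chrom`, `arm`, `start`, `end`, `length`, sorted by genomic
#'   position, autosomes only.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t0\t100\tp36.33\tgneg",
#'              "chr1\t100\t250\tp36.32\tgpos25",
#'              "chr1\t250\t400\tp36.31\tgneg"), f)
#' load_cytobands(f)
#' @export
load_cytobands <- function(path, resolution = c("subband", "fine")) {
  resolution <- match.arg(resolution)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse cytoband file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(raw) == 0L) stop("cytoband file '", path, "' is empty", call. = FALSE)
  if (ncol(raw) < 4L) {
    stop("expected UCSC cytoBand columns chrom, start, end, name[, stain]",
         call. = FALSE)
  }
  chrom <- .normalize_chrom(raw[[1L]])
  keep <- !is.na(.chrom_num(chrom))
  if (!any(keep)) {
    stop("no autosomal bands in '", path,
         "' after excluding X/Y chromosomes", call. = FALSE)
  }
  name <- as.character(raw[[4L]])[keep]
  if (!all(grepl("^[pq][0-9]+(\\.[0-9]+)?$", name))) {
    stop("malformed band name '", name[!grepl("^[pq][0-9]+(\\.[0-9]+)?$", name)][1L],
         "': expected <arm><major>[.<minor>]", call. = FALSE)
  }
  chrom <- chrom[keep]
  df <- data.frame(
    band  = paste0(chrom, name),
    chrom = chrom,
    arm   = substr(name, 1L, 1L),
    start = as.numeric(raw[[2L]])[keep],
    end   = as.numeric(raw[[3L]])[keep],
    stringsAsFactors = FALSE
  )
  cat <- .new_cytoband_catalog(df)
  if (resolution == "subband") cat <- aggregate_to_subband(cat) # nolint
  cat
}

#' Merge fine cytobands into sub-band resolution
#'
#' Bands sharing a `<chrom><arm><major>` prefix (e.g. chr1p36.1-chr1p36.3)
#' are replaced by a single band (chr1p36) spanning the union of their
#' intervals. Constituents of a prefix must tile the union contiguously;
#' bands without a minor suffix pass through unchanged.
#'
#' @param fine A `cytoband_catalog` at fine resolution.
#' @return A `cytoband_catalog` with one band per distinct prefix.
#' @export
aggregate_to_subband <- function(fine) {
  stopifnot(inherits(fine, "cytoband_catalog"))
  prefix <- sub("^((chr[0-9]+)([pq])([0-9]+))(\\.[0-9]+)?$", "\\1", fine$band)
  bad <- prefix == fine$band & grepl("\\.", fine$band)
  if (any(bad)) {
    stop("band name '", fine$band[bad][1L],
         "' does not follow <chrom><arm><major>.<minor>", call. = FALSE)
  }
  pieces <- split(seq_len(nrow(fine)), factor(prefix, levels = unique(prefix)))
  rows <- lapply(names(pieces), function(p) {
    d <- fine[pieces[[p]], , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] != d$end[-nrow(d)])) {
      stop("constituent bands of '", p, "' are not contiguous", call. = FALSE)
    }
    data.frame(band = p, chrom = d$chrom[1L], arm = d$arm[1L],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  })
  .new_cytoband_catalog(do.call(rbind, rows))
}

#' Serialize a cytoband catalog as BED4
#'
#' Writes chrom, start, end, band-name (0-based half-open), one band per
#' line, tab-separated, no header.
#'
#' @param catalog A `cytoband_catalog`.
#' @param path Output path.
#' @export
write_cytobands_bed <- function(catalog, path) {
  stopifnot(inherits(catalog, "cytoband_catalog"))
  utils::write.table(
    catalog[, c("chrom", "start", "end", "band")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4-serialized cytoband catalog
#'
#' Inverse of [write_cytobands_bed()].
#'
#' @param path Path to a BED4 file (chrom, start, end, band-name).
#' @return A `cytoband_catalog`.
#' @export
read_cytobands_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("expected BED4: chrom, start, end, band", call. = FALSE)
  band <- as.character(raw[[4L]])
  arm <- sub("^chr[0-9]+([pq]).*$", "\\1", band)
  .new_cytoband_catalog(data.frame(
    band = band, chrom = .normalize_chrom(raw[[1L]]), arm = arm,
    start = as.numeric(raw[[2L]]), end = as.numeric(raw[[3L]]),
    stringsAsFactors = FALSE))
}

#' @export
print.cytoband_catalog <- function(x, ...) {
  cat("cytoband catalog: ", nrow(x), " bands on ",
      length(unique(x$chrom)), " chromosomes\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more bands\n")
  invisible(x)
}
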