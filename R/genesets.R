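# Positional gene sets: band -> genes, the MSigDB C1-style assignment that
# the expression-based copy-number inference is computed against.

.new_positional_gene_sets <- function(sets, catalog, min_genes) {
  full <- stats::setNames(vector("list", nrow(catalog)), catalog$band)
  for (b in catalog$band) full[[b]] <- character(0)
  for (b in names(sets)) full[[b]] <- sets[[b]]
  n_genes <- vapply(full, length, integer(1))
  structure(
    list(sets = full,
         n_genes = n_genes,
         unreliable = names(n_genes)[n_genes < min_genes],
         min_genes = min_genes),
    class = "positional_gene_sets")
}

#' Load positional gene sets from a GMT file
#'
#' Parses the GMT dialect (one set per line: name, description, then gene
#' symbols, tab-separated) and restricts the sets to bands present in the
#' catalog. Set names without a "chr" prefix are normalized. A gene claimed
#' by more than one band set is assigned to the band whose set lists it
#' first in file order (one warning reports how many were reassigned), so
#' each gene belongs to at most one band. Bands with fewer than `min_genes`
#' genes — including catalog bands absent from the file — are flagged
#' unreliable and excluded from downstream t-statistic inference.
#'
#' @param path Path to a GMT file.
#' @param catalog A `cytoband_catalog` defining the band universe.
#' @param min_genes Minimum genes for a band's t-statistic to be considered
#'   reliable (default 10).
#' @return A `positional_gene_sets` object: `sets` (band -> character vector
#'   over all catalog bands), `n_genes`, `unreliable`, `min_genes`.
#' @export
load_positional_gene_sets <- function(path, catalog, min_genes = 10) {
  stopifnot(inherits(catalog, "cytoband_catalog"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("malformed GMT line ", which(short)[1L],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  nm <- ifelse(grepl("^[0-9]+[pq]", nm), paste0("chr", nm), nm)
  keep <- nm %in% catalog$band
  if (!any(keep)) {
    stop("no GMT set name matches a catalog band (naming-convention ",
         "mismatch); first set was '", nm[1L], "'", call. = FALSE)
  }
  fields <- fields[keep]
  nm <- nm[keep]
  if (anyDuplicated(nm)) {
    stop("GMT file lists band '", nm[duplicated(nm)][1L], "' twice", call. = FALSE)
  }
  sets <- vector("list", length(nm))
  names(sets) <- nm
  seen <- character(0)
  n_dup <- 0L
  for (i in seq_along(nm)) {
    g <- unique(fields[[i]][-c(1L, 2L)])
    g <- g[nzchar(g)]
    dup <- g %in% seen
    n_dup <- n_dup + sum(dup)
    sets[[i]] <- g[!dup]
    seen <- c(seen, g[!dup])
  }
  if (n_dup > 0L) {
    warning(n_dup, " gene(s) appeared in more than one band set; ",
            "kept the first occurrence in file order", call. = FALSE)
  }
  .new_positional_gene_sets(sets, catalog, min_genes)
}

#' Write positional gene sets as GMT
#'
#' Bands with at least one gene are written one per line (name, "na"
#' description, genes), in catalog order. Re-loading the output with
#' [load_positional_gene_sets()] against the same catalog reproduces the
#' object exactly.
#'
#' @param sets A `positional_gene_sets` object.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "positional_gene_sets"))
  nonempty <- names(sets$sets)[sets$n_genes > 0L]
  lines <- vapply(nonempty, function(b) {
    paste(c(b, "na", sets$sets[[b]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# gene -> band lookup (first-wins already enforced at load)
.gene_band_map <- function(sets) {
  n <- sets$n_genes
  stats::setNames(rep(names(sets$sets), n), unlist(sets$sets, use.names = FALSE))
}

#' @export
print.positional_gene_sets <- function(x, ...) {
  cat("positional gene sets: ", sum(x$n_genes), " genes on ",
      sum(x$n_genes > 0), " bands (", length(x$unreliable),
      " bands unreliable: < ", x$min_genes, " genes)\n", sep = "")
  invisible(x)
}
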