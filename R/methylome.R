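#' Read per-cytosine methylation calls
#'
#' Parses a Bismark-style coverage file: tab-separated
#' `chrom, start, end, percent_methylated, count_methylated,
#' count_unmethylated` in bedGraph coordinates (0-based half-open, one
#' cytosine per row). The percentage field is ignored in favour of the
#' counts. An optional 7th column carries the cytosine context (`CG` or
#' `CH`); without it all sites get the `context` argument.
#'
#' @param path Coverage file path.
#' @param context Context assigned when the file has no context column.
#' @return data.frame sorted by (chrom, pos): `chrom`, `pos` (0-based
#'   position of the cytosine, as in the bedGraph dialect), `context`,
#'   `n_meth`, `n_unmeth`.
#' @export
read_methylation_calls <- function(path, context = "CG") {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      context = character(), n_meth = integer(),
                      n_unmeth = integer(), stringsAsFactors = FALSE))
  ncol_file <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (!ncol_file %in% c(6L, 7L))
    stop("expected 6 or 7 tab-separated columns, found ", ncol_file)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    pos = as.integer(df[[2]]),
                    context = if (ncol_file == 7L) as.character(df[[7]])
                              else rep(context, nrow(df)),
                    n_meth = as.integer(df[[5]]),
                    n_unmeth = as.integer(df[[6]]),
                    stringsAsFactors = FALSE)
  if (any(out$n_meth < 0 | out$n_unmeth < 0))
    stop("negative methylation counts in ", path)
  if (!all(out$context %in% c("CG", "CH")))
    stop("context column must be CG or CH")
  unsorted <- stats::ave(out$pos, out$chrom,
                         FUN = function(p) c(0L, diff(p))) < 0
  if (any(unsorted))
    stop("input not sorted by position within chromosome; sort the file first")
  out
}

#' Mean mCpG/CpG ratio over regions
#'
#' For each region, computes the mean of per-site methylation ratios
#' `n_meth / (n_meth + n_unmeth)` over CpG sites falling inside the region
#' with coverage at least `min_coverage` (default 3x). Regions with no
#' qualifying site get `mean_ratio = NA` and are flagged undefined.
#'
#' @param calls data.frame from [read_methylation_calls()].
#' @param regions `GRanges` of regions (a metadata column `element_id` or
#'   the names are used as region ids when present).
#' @param min_coverage Minimum per-site read coverage (default 3).
#' @param context Context of sites to use (default `"CG"`).
#' @return data.frame: `region_id`, `mean_ratio`, `n_sites_used`.
#' @export
region_methylation <- function(calls, regions, min_coverage = 3L,
                               context = "CG") {
  stopifnot(inherits(regions, "GRanges"))
  ids <- if (!is.null(regions$element_id)) regions$element_id
         else if (!is.null(names(regions))) names(regions)
         else as.character(seq_along(regions))
  use <- calls$context == context &
    (calls$n_meth + calls$n_unmeth) >= min_coverage
  sites <- calls[use, , drop = FALSE]
  out <- data.frame(region_id = ids, mean_ratio = NA_real_,
                    n_sites_used = 0L, stringsAsFactors = FALSE)
  if (nrow(sites) > 0 && length(regions) > 0) {
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(site_gr, regions, ignore.strand = TRUE)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ratio <- sites$n_meth[q] / (sites$n_meth[q] + sites$n_unmeth[q])
      agg <- data.table::data.table(region = s, ratio = ratio)[
        , list(mean_ratio = mean(ratio), n = .N), by = "region"]
      out$mean_ratio[agg$region] <- agg$mean_ratio
      out$n_sites_used[agg$region] <- agg$n
    }
  }
  out
}

#' Mean mCpG/CpG ratio in fixed genomic tiles
#'
#' Partitions each chromosome into non-overlapping tiles of `tile_bp`
#' bases and summarises methylation per tile with the same site rules as
#' [region_methylation()]. Useful for genome-wide distributions (e.g.
#' violin plots of 1-kb tile means).
#'
#' @param calls data.frame from [read_methylation_calls()].
#' @param genome_sizes Named integer vector of chromosome lengths (bp).
#' @param tile_bp Tile width in bp (default 1000).
#' @inheritParams region_methylation
#' @return data.frame: `chrom`, `tile_start` (0-based), `tile_end`,
#'   `mean_ratio`, `n_sites_used`, plus attribute `mean_of_tile_means`
#'   over defined tiles.
#' @export
tile_methylation <- function(calls, genome_sizes, tile_bp = 1000L,
                             min_coverage = 3L, context = "CG") {
  stopifnot(!is.null(names(genome_sizes)), all(genome_sizes > 0), tile_bp > 0)
  tiles <- do.call(rbind, lapply(names(genome_sizes), function(chr) {
    starts <- seq.int(0L, genome_sizes[[chr]] - 1L, by = tile_bp)
    data.frame(chrom = chr, tile_start = starts,
               tile_end = pmin(starts + tile_bp, genome_sizes[[chr]]),
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(tiles$chrom,
                               IRanges::IRanges(tiles$tile_start + 1L,
                                                tiles$tile_end))
  summ <- region_methylation(calls, gr, min_coverage = min_coverage,
                             context = context)
  out <- cbind(tiles, summ[, c("mean_ratio", "n_sites_used")])
  attr(out, "mean_of_tile_means") <- mean(out$mean_ratio, na.rm = TRUE)
  out
}

#' Global methylation level
#'
#' Computes the genome-wide methylation level for a cytosine context,
#' both as the read-weighted fraction `sum(n_meth) / sum(coverage)` (the
#' default estimator) and as the unweighted mean of per-site ratios.
#'
#' @param calls data.frame from [read_methylation_calls()].
#' @param context `"CG"` or `"CH"`.
#' @param min_coverage Minimum per-site coverage (default 3).
#' @param estimator `"read-weighted"` (default) or `"site-mean"`; selects
#'   which variant is returned in `$fraction`.
#' @return list: `fraction` (selected estimator, NA when no qualifying
#'   sites), `fraction_weighted`, `fraction_site_mean`, `n_sites`.
#' @export
global_methylation <- function(calls, context = c("CG", "CH"),
                               min_coverage = 3L,
                               estimator = c("read-weighted", "site-mean")) {
  context <- match.arg(context)
  estimator <- match.arg(estimator)
  use <- calls$context == context &
    (calls$n_meth + calls$n_unmeth) >= min_coverage
  s <- calls[use, , drop = FALSE]
  if (nrow(s) == 0)
    return(list(fraction = NA_real_, fraction_weighted = NA_real_,
                fraction_site_mean = NA_real_, n_sites = 0L))
  cov <- s$n_meth + s$n_unmeth
  fw <- sum(s$n_meth) / sum(cov)
  fs <- mean(s$n_meth / cov)
  list(fraction = if (estimator == "read-weighted") fw else fs,
       fraction_weighted = fw, fraction_site_mean = fs, n_sites = nrow(s))
}
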