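#' Count unique fragments per TE locus
#'
#' Assigns each uniquely mapping fragment to the TE element with the
#' largest base overlap to the union of its aligned blocks; ties go to
#' the lower-coordinate element, each fragment is counted at most once,
#' and multi-mapping fragments contribute to no TE. Assignment is
#' strand-blind (strand is handled separately by [strand_counts()]).
#'
#' @param fragments A `read_fragments` object from [load_fragments()].
#' @param te_set `GRanges` of exon-filtered TE fragments (see
#'   [filter_nonexonic()]).
#' @param mode `"largest-overlap"` (default) or `"discard-ambiguous"`
#'   (drop fragments touching more than one element, featureCounts-like).
#' @return Named integer vector of counts, one entry per `element_id` of
#'   `te_set`.
#' @export
count_te_fragments <- function(fragments, te_set,
                               mode = c("largest-overlap",
                                        "discard-ambiguous")) {
  mode <- match.arg(mode)
  feats <- te_set
  feats$feature_id <- te_set$element_id
  uniq <- which(fragments$meta$unique)
  asn <- assign_fragments(fragments$blocks[uniq], feats, mode = mode)
  counts <- integer(length(te_set))
  names(counts) <- te_set$element_id
  if (nrow(asn) > 0) {
    tab <- table(asn$feature_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Count unique fragments per gene (exon overlap)
#'
#' Like [count_te_fragments()] but features are gene exon sets: a
#' fragment is assigned to the gene whose exons it overlaps most.
#'
#' @param fragments `read_fragments` object.
#' @param genes Output of [parse_gene_annotation()] or an exon `GRanges`
#'   with a `gene_id` metadata column.
#' @inheritParams count_te_fragments
#' @return Named integer vector of counts per gene.
#' @export
count_gene_fragments <- function(fragments, genes,
                                 mode = c("largest-overlap",
                                          "discard-ambiguous")) {
  mode <- match.arg(mode)
  exons <- if (inherits(genes, "GRanges")) genes else genes$exons
  feats <- exons
  feats$feature_id <- exons$gene_id
  uniq <- which(fragments$meta$unique)
  asn <- assign_fragments(fragments$blocks[uniq], feats, mode = mode)
  gene_ids <- unique(exons$gene_id)
  counts <- integer(length(gene_ids))
  names(counts) <- gene_ids
  if (nrow(asn) > 0) {
    tab <- table(asn$feature_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Build a count matrix over samples
#'
#' Applies a per-sample counter over a list of `read_fragments` and
#' collects a features x samples integer matrix plus per-sample library
#' sizes (total uniquely mapped fragments).
#'
#' @param fragments_list Named list of `read_fragments` (one per sample).
#' @param features `GRanges` TE set, or gene annotation, depending on `type`.
#' @param type `"te"` or `"gene"`.
#' @param mode Assignment mode, see [count_te_fragments()].
#' @return list with `counts` (matrix) and `library_size` (named vector).
#' @export
build_count_matrix <- function(fragments_list, features,
                               type = c("te", "gene"),
                               mode = "largest-overlap") {
  type <- match.arg(type)
  counter <- if (type == "te") count_te_fragments else count_gene_fragments
  cols <- lapply(fragments_list, counter, features, mode = mode)
  counts <- do.call(cbind, cols)
  colnames(counts) <- names(fragments_list)
  lib <- vapply(fragments_list, function(f) sum(f$meta$unique), integer(1))
  list(counts = counts, library_size = lib)
}

#' Drop features with fewer than `min_total` fragments across all samples
#'
#' @param counts features x samples count matrix.
#' @param min_total Minimum row total required to keep a feature
#'   (default 5).
#' @return The surviving submatrix.
#' @export
filter_min_total <- function(counts, min_total = 5L) {
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Sample normalization of a count matrix
#'
#' `median-ratio`: the median-of-ratios size factor — per sample, the
#' median over features (with nonzero counts in every sample) of the
#' ratio between the count and the feature's geometric mean.
#' `library-scaling`: size factor proportional to the number of reads
#' mapping to the genome (library size), scaled to mean 1.
#'
#' @param counts features x samples count matrix.
#' @param mode `"median-ratio"` or `"library-scaling"`.
#' @param library_size Named vector of genome-mapped fragment totals,
#'   required for `library-scaling`.
#' @return list with `size_factors` and `normalized` (counts swept by the
#'   size factors).
#' @export
normalize_counts <- function(counts, mode = c("median-ratio",
                                              "library-scaling"),
                             library_size = NULL) {
  mode <- match.arg(mode)
  if (mode == "median-ratio") {
    log_geo <- rowMeans(log(counts))
    ok <- is.finite(log_geo)
    if (!any(ok))
      stop("no feature has nonzero counts in every sample; ",
           "use mode = \"library-scaling\"")
    sf <- apply(counts, 2, function(k) {
      exp(stats::median((log(k) - log_geo)[ok & k > 0]))
    })
  } else {
    stopifnot(!is.null(library_size), length(library_size) == ncol(counts))
    sf <- library_size / mean(library_size)
  }
  names(sf) <- colnames(counts)
  list(size_factors = sf, normalized = sweep(counts, 2, sf, "/"))
}

#' Negative-binomial Wald differential expression test
#'
#' Two-group differential test for count data: per-feature dispersion by
#' method of moments, shrunk in log space toward a fitted mean-dispersion
#' trend, followed by maximum-likelihood group means (with size-factor
#' offsets) and a Wald test on the log2 fold change. P values are
#' Benjamini-Hochberg adjusted; features with no counts anywhere are
#' excluded from the BH denominator.
#'
#' This is a calibrated re-implementation of the standard NB
#' shrinkage-Wald approach (as popularised by DESeq2), not a bit-exact
#' clone; simulation-based calibration is part of the test suite.
#'
#' @param counts features x samples integer matrix.
#' @param groups Factor or vector of length `ncol(counts)` with exactly
#'   two levels; the first level is the reference (control).
#' @param mode Normalization mode passed to [normalize_counts()].
#' @param library_size Library sizes when `mode = "library-scaling"`.
#' @param alpha_sig Significance threshold on adjusted p (default 0.05).
#' @return data.frame: `feature_id`, `base_mean`, `log2_fold_change`,
#'   `p_value`, `p_adj`, `significant`, `direction` (`"up"`/`"down"`/
#'   `"ns"`).
#' @export
differential_test <- function(counts, groups,
                              mode = c("library-scaling", "median-ratio"),
                              library_size = NULL, alpha_sig = 0.05) {
  mode <- match.arg(mode)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == ncol(counts),
            all(table(groups) >= 2))
  if (mode == "library-scaling" && is.null(library_size))
    library_size <- colSums(counts)
  nrm <- normalize_counts(counts, mode = mode, library_size = library_size)
  sf <- nrm$size_factors
  q <- nrm$normalized
  g1 <- groups == levels(groups)[1]
  g2 <- !g1

  base_mean <- rowMeans(q)
  defined <- rowSums(counts) > 0

  ## --- dispersion: method of moments, then log-space shrinkage to trend
  mu_bar <- base_mean
  var_w <- (rowSums((q[, g1, drop = FALSE] - rowMeans(q[, g1, drop = FALSE]))^2) +
            rowSums((q[, g2, drop = FALSE] - rowMeans(q[, g2, drop = FALSE]))^2)) /
           (ncol(counts) - 2)
  xi <- mean(1 / sf)
  alpha_mom <- (var_w - mu_bar * xi) / mu_bar^2
  alpha_mom[!is.finite(alpha_mom)] <- NA
  min_disp <- 1e-8
  est <- which(defined & !is.na(alpha_mom) & mu_bar > 0)
  pos <- which(defined & !is.na(alpha_mom) & alpha_mom > min_disp &
               mu_bar > 0)
  trend <- fit_dispersion_trend(mu_bar[est], alpha_mom[est])
  alpha_tr <- pmax(trend$a0 + trend$a1 / pmax(mu_bar, 1e-8), min_disp)
  m <- ncol(counts)
  s2_samp <- trigamma((m - 2) / 2)           # sampling var of log dispersion
  log_res <- log(alpha_mom[pos]) - log(alpha_tr[pos])
  s2_prior <- if (length(log_res) >= 2)
    max(stats::var(log_res) - s2_samp, 0.25) else 0.25
  log_mom <- log(pmax(alpha_mom, min_disp))
  log_post <- (log_mom / s2_samp + log(alpha_tr) / s2_prior) /
              (1 / s2_samp + 1 / s2_prior)
  alpha_use <- exp(log_post)
  # a non-positive moment estimate carries no usable dispersion signal
  # (censored below); fall back to the prior mean rather than shrink
  # toward the numerical floor
  censored <- is.na(alpha_mom) | alpha_mom <= min_disp
  alpha_use[censored] <- alpha_tr[censored]
  alpha_use[is.na(alpha_use)] <- alpha_tr[is.na(alpha_use)]
  alpha_use <- pmax(alpha_use, min_disp)

  ## --- group-mean MLE with offsets, Newton on log scale
  mu_min <- 0.5 * xi / max(table(groups))    # half-a-read equivalent floor
  fit_group <- function(gsel) {
    k <- counts[, gsel, drop = FALSE]
    s <- sf[gsel]
    b <- log(pmax(rowSums(k) / sum(s), mu_min))
    for (it in 1:25) {
      mu <- exp(b) %o% s
      w <- 1 + sweep(mu, 1, alpha_use, "*")
      U <- rowSums((k - mu) / w)
      I <- rowSums(mu / w)
      step <- U / pmax(I, 1e-12)
      step <- pmin(pmax(step, -3), 3)
      b <- pmax(b + step, log(mu_min))
      if (max(abs(step), na.rm = TRUE) < 1e-10) break
    }
    mu <- exp(b) %o% s
    w <- 1 + sweep(mu, 1, alpha_use, "*")
    list(b = b, info = rowSums(mu / w))
  }
  f1 <- fit_group(g1)
  f2 <- fit_group(g2)
  beta <- f2$b - f1$b
  se <- sqrt(1 / pmax(f1$info, 1e-12) + 1 / pmax(f2$info, 1e-12))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!defined] <- NA

  p_adj <- rep(NA_real_, length(p))
  p_adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  lfc <- beta / log(2)
  sig <- !is.na(p_adj) & p_adj < alpha_sig
  data.frame(
    feature_id = if (!is.null(rownames(counts))) rownames(counts)
                 else as.character(seq_len(nrow(counts))),
    base_mean = base_mean,
    log2_fold_change = lfc,
    p_value = p,
    p_adj = p_adj,
    significant = sig,
    direction = ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Trend fit of dispersion ~ a0 + a1/mu by trimmed least squares over the
# raw moment estimates. Negative estimates are kept: excluding them would
# bias the trend upward (only the upper tail of the sampling distribution
# would enter the fit).
fit_dispersion_trend <- function(mu, alpha) {
  fallback <- list(a0 = max(mean(alpha, na.rm = TRUE), 1e-6, na.rm = TRUE),
                   a1 = 0)
  if (length(mu) < 10) return(fallback)
  fit <- tryCatch({
    x <- 1 / mu
    f0 <- stats::lm(alpha ~ x)
    res <- stats::residuals(f0)
    keep <- abs(res) <= 4 * stats::mad(res) + 1e-12
    co <- stats::coef(stats::lm(alpha ~ x, subset = keep))
    if (any(!is.finite(co))) stop("bad fit")
    list(a0 = max(co[1], 1e-6), a1 = max(co[2], 0))
  }, error = function(e) fallback)
  fit
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] exposed for symmetry with the
#' differential test; `NA` p values are excluded from the denominator.
#'
#' @param p Numeric vector of p values (may contain `NA`).
#' @return Adjusted p values, `NA` preserved.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Sense/antisense fragment counts per element
#'
#' Assigns unique fragments to elements by largest overlap and splits
#' counts by orientation: sense when the fragment strand equals the
#' element strand, antisense otherwise. Requires a stranded protocol.
#'
#' @param fragments `read_fragments` object (stranded protocol).
#' @param elements `GRanges` of elements (e.g. FLI-L1s) with `element_id`.
#' @return data.frame: `element_id`, `sense_count`, `antisense_count`.
#' @export
strand_counts <- function(fragments, elements) {
  if (fragments$protocol == "unstranded")
    stop("strand_counts requires a stranded protocol")
  feats <- elements
  feats$feature_id <- elements$element_id
  uniq <- which(fragments$meta$unique)
  asn <- assign_fragments(fragments$blocks[uniq], feats,
                          mode = "largest-overlap")
  out <- data.frame(element_id = elements$element_id,
                    sense_count = 0L, antisense_count = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(asn) > 0) {
    el_strand <- as.character(GenomicRanges::strand(elements))
    names(el_strand) <- elements$element_id
    frag_strand <- fragments$meta$fragment_strand[uniq][asn$frag]
    sense <- frag_strand == el_strand[asn$feature_id]
    ts <- table(factor(asn$feature_id[sense], levels = out$element_id))
    ta <- table(factor(asn$feature_id[!sense], levels = out$element_id))
    out$sense_count <- as.integer(ts)
    out$antisense_count <- as.integer(ta)
  }
  out
}

#' Two-sided Wilcoxon rank-sum test, exact for small samples
#'
#' Compares two groups of per-element normalized expression values with
#' the two-sided Wilcoxon rank-sum test: exact enumeration when the
#' combined sample size is at most 20 and there are no ties, otherwise
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Numeric vectors.
#' @return list: `p_value`, `statistic` (W), `method`.
#' @export
rank_sum_test <- function(x, y) {
  n <- length(x) + length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= 20 && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       method = if (exact) "exact" else "normal approximation")
}

#' Per-subfamily summary of upregulated elements
#'
#' Joins differential results onto element annotation and reports, per
#' subfamily, the number of significantly upregulated elements and the
#' total number of annotated elements, ordered by evolutionary age
#' (youngest first; age-unknown subfamilies last).
#'
#' @param de_results data.frame from [differential_test()] with
#'   `feature_id` matching `element_id`.
#' @param fragments `GRanges` from [assign_subfamily_ages()] (needs
#'   `subfamily`, `age_my`).
#' @return data.frame: `subfamily`, `n_upregulated`, `n_total_elements`,
#'   `age_my`.
#' @export
subfamily_summary <- function(de_results, fragments) {
  up_ids <- de_results$feature_id[de_results$direction == "up"]
  dt <- data.table::data.table(
    subfamily = fragments$subfamily,
    age_my = fragments$age_my,
    up = fragments$element_id %in% up_ids)
  summ <- dt[, list(n_upregulated = sum(up), n_total_elements = .N,
                    age_my = age_my[1]), by = "subfamily"]
  data.table::setorderv(summ, "age_my", na.last = TRUE)
  as.data.frame(summ)
}
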