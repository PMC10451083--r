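## Interval algebra connecting ICRs, sweep regions, QTLs and genes.
## Intervals are data.tables (chrom, start, end), 0-based half-open; set
## operations are backed by IRanges behind this module's own API.

iv_to_gr <- function(dt) {
  dt <- as.data.table(dt)
  if (any(dt$start >= dt$end))
    ps_stop("interval with start >= end rejected (half-open coordinates)")
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
}

gr_to_iv <- function(gr) {
  if (!length(gr))
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = as.numeric(GenomicRanges::end(gr)))
  dt[order(chrom, start)]
}

#' Interval-set operations
#'
#' `iv_normalize` sorts and merges overlapping or abutting intervals;
#' `iv_union` and `iv_intersect` are the usual set operations on normalized
#' sets; `iv_total_length` is the summed bp length.
#'
#' @param ... interval tables (`chrom`, `start`, `end`; 0-based half-open).
#' @param x,y interval tables.
#' @return normalized interval `data.table`, or a bp total.
#' @export
iv_normalize <- function(x) gr_to_iv(GenomicRanges::reduce(iv_to_gr(x)))

#' @rdname iv_normalize
#' @export
iv_union <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(as.data.table(d)),
                  list(...))
  if (!length(parts))
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  iv_normalize(rbindlist(lapply(parts, function(d)
    as.data.table(d)[, .(chrom, start, end)])))
}

#' @rdname iv_normalize
#' @export
iv_intersect <- function(x, y) {
  gx <- GenomicRanges::reduce(iv_to_gr(x))
  gy <- GenomicRanges::reduce(iv_to_gr(y))
  lv <- union(GenomeInfoDb::seqlevels(gx), GenomeInfoDb::seqlevels(gy))
  GenomeInfoDb::seqlevels(gx) <- lv
  GenomeInfoDb::seqlevels(gy) <- lv
  gr_to_iv(GenomicRanges::intersect(gx, gy))
}

#' @rdname iv_normalize
#' @export
iv_total_length <- function(x) {
  x <- as.data.table(x)
  if (!nrow(x)) return(0)
  x <- iv_normalize(x)
  sum(x$end - x$start)
}

#' ICR / sweep-region co-localization report
#'
#' Against the union of the per-statistic sweep-region sets, reports both
#' the percentage of ICRs (by count) with at least 1 bp of overlap and the
#' percentage of total ICR length overlapped, overall and split by parent;
#' per-statistic splits are included.
#'
#' @param icrs ICR table from [call_icrs()] (`chrom`, `start`, `end`,
#'   `parent`).
#' @param ssw_sets named list of sweep-region tables (one per statistic).
#' @return list `overall`, `by_parent`, `by_statistic`; percentages on the
#'   0-100 scale. Zero denominators are reported as `NA` with a flag.
#' @export
icr_ssw_coloc <- function(icrs, ssw_sets) {
  icrs <- as.data.table(icrs)
  ssw_union <- do.call(iv_union, unname(lapply(ssw_sets, as.data.table)))
  report_against <- function(ic, regions) {
    if (!nrow(ic))
      return(list(n_icr = 0L, pct_count = NA_real_, pct_length = NA_real_,
                  total_bp = 0, overlapped_bp = 0, empty = TRUE))
    ov_bp <- vapply(seq_len(nrow(ic)), function(i)
      iv_total_length(iv_intersect(ic[i], regions)), 0)
    list(n_icr = nrow(ic),
         pct_count = 100 * mean(ov_bp > 0),
         pct_length = 100 * sum(ov_bp) / sum(ic$end - ic$start),
         total_bp = sum(ic$end - ic$start),
         overlapped_bp = sum(ov_bp), empty = FALSE)
  }
  list(overall = report_against(icrs, ssw_union),
       by_parent = lapply(c(P1 = 1L, P2 = 2L), function(p)
         report_against(icrs[parent == p], ssw_union)),
       by_statistic = lapply(ssw_sets, function(s)
         report_against(icrs, as.data.table(s))))
}

#' Flag QTLs in or near a region set
#'
#' A QTL is flagged if its physical interval overlaps the region set or
#' lies within `near_dist` bp of it; the flagged fraction over all QTLs is
#' reported, plus a sensitivity sweep over several distances.
#'
#' @param qtls_bp QTL table with `chrom`, `start`, `end` (bp).
#' @param regions interval table.
#' @param near_dist flag distance in bp (default 1e6).
#' @param sensitivity distances for the sensitivity output
#'   (default `c(0, 5e5, 1e6, 2e6)`).
#' @return list `flags` (per-QTL logical + distance), `fraction` (0-100 %),
#'   `sensitivity` (named fractions).
#' @export
qtl_near <- function(qtls_bp, regions, near_dist = 1e6,
                     sensitivity = c(0, 5e5, 1e6, 2e6)) {
  q <- as.data.table(qtls_bp)
  regions <- iv_normalize(as.data.table(regions))
  if (!nrow(q))
    return(list(flags = data.table(), fraction = NA_real_,
                sensitivity = setNames(rep(NA_real_, length(sensitivity)),
                                       sensitivity)))
  dist <- vapply(seq_len(nrow(q)), function(i) {
    r <- regions[chrom == q$chrom[i]]
    if (!nrow(r)) return(Inf)
    gap <- pmax(r$start - q$end[i], q$start[i] - r$end, 0)
    min(gap)
  }, 0)
  frac <- function(d) 100 * mean(dist <= d)
  list(flags = cbind(q, data.table(dist_bp = dist, near = dist <= near_dist)),
       fraction = frac(near_dist),
       sensitivity = setNames(vapply(sensitivity, frac, 0),
                              format(sensitivity, scientific = FALSE)))
}

#' Interpolate between genetic (cM) and physical (bp) coordinates
#'
#' Piecewise-linear interpolation between flanking map entries; positions
#' outside the map span are clamped to the ends and flagged.
#'
#' @param map map table (`chrom`, `pos_bp`, `pos_cM`).
#' @param chrom chromosome id(s).
#' @param pos_cM,pos_bp positions to convert.
#' @return numeric vector of converted positions, with attribute `clamped`
#'   (logical vector).
#' @export
cm_to_bp <- function(map, chrom, pos_cM) {
  interp_map(map, chrom, pos_cM, from = "pos_cM", to = "pos_bp")
}

#' @rdname cm_to_bp
#' @export
bp_to_cm <- function(map, chrom, pos_bp) {
  interp_map(map, chrom, pos_bp, from = "pos_bp", to = "pos_cM")
}

interp_map <- function(map, chrom, pos, from, to) {
  map <- as.data.table(map)
  if (!nrow(map)) ps_stop("empty genetic map")
  chrom <- as.character(chrom)
  out <- numeric(length(pos)); clamped <- logical(length(pos))
  for (ch in unique(chrom)) {
    sub <- map[map$chrom == ch]
    if (nrow(sub) < 2L) ps_stop("need >= 2 map entries on chromosome %s", ch)
    sel <- chrom == ch
    x <- sub[[from]]; yv <- sub[[to]]
    clamped[sel] <- pos[sel] < min(x) | pos[sel] > max(x)
    ## ties = mean handles flat cM stretches deterministically
    out[sel] <- approx(x, yv, xout = pmin(pmax(pos[sel], min(x)), max(x)),
                       ties = mean, rule = 2)$y
  }
  structure(out, clamped = clamped)
}

#' Convert QTL support intervals to physical intervals
#'
#' @param qtls QTL table with `chrom`, `ci_lo_cM`, `ci_hi_cM` (and
#'   `peak_cM`).
#' @param map map table.
#' @return the QTL table with added `start`, `end`, `peak_bp` (bp) columns.
#' @export
qtls_to_bp <- function(qtls, map) {
  q <- copy(as.data.table(qtls))
  if (!nrow(q)) return(q)
  q[, start := floor(as.numeric(cm_to_bp(map, chrom, ci_lo_cM)))]
  q[, end := ceiling(as.numeric(cm_to_bp(map, chrom, ci_hi_cM)))]
  q[end <= start, end := start + 1]
  if ("peak_cM" %in% names(q))
    q[, peak_bp := as.numeric(cm_to_bp(map, chrom, peak_cM))]
  q[]
}

#' Genes overlapping a region set
#'
#' Genes with at least 1 bp of overlap (half-open coordinates: a gene
#' abutting a region boundary is excluded).
#'
#' @param genes gene table (`chrom`, `start`, `end`, `gene_id`), 0-based
#'   half-open, e.g. from [read_genes()].
#' @param regions interval table.
#' @return the subset of `genes` overlapping `regions`.
#' @export
genes_in_regions <- function(genes, regions) {
  genes <- as.data.table(genes)
  regions <- as.data.table(regions)
  if (!nrow(genes) || !nrow(regions)) return(genes[0])
  hit <- GenomicRanges::findOverlaps(iv_to_gr(genes),
                                     GenomicRanges::reduce(iv_to_gr(regions)))
  genes[sort(unique(S4Vectors::queryHits(hit)))]
}
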