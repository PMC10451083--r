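## Parent-of-origin IBD tracing for descendant inbred lines of a known
## biparental cross. Because both parents are known inbred lines, origin is
## assigned by allele match at informative markers, scored with a segment
## LOD against the panel allele-frequency background, gaps are attributed by
## minimum recombination, and IBD-conserved regions (ICRs) are called where
## nearly all lines retain the same parent.
## All coordinates are 0-based half-open internally; 1-based closed in
## written reports.

#' Parameters for IBD segment and ICR calling
#'
#' @param min_lod minimum segment LOD for a reported IBD segment (default 3).
#' @param trim_lod end-trimming threshold (default 2.5): a segment end is
#'   trimmed through the last minimum of its inward cumulative marker LOD
#'   when that minimum dips below `-(min_lod - trim_lod)`.
#' @param error_rate assumed allele error rate epsilon (default 1e-4).
#' @param min_markers minimum run length; shorter interior discordant runs
#'   are smoothed to the flanking parent (default 5).
#' @param tau ICR retention threshold: minimum fraction of assigned lines
#'   sharing the parent (default 0.9, "almost all").
#' @param icr_window_bp bin width for ICR retention profiles (default 1e5).
#' @return object of class `ibd_params`.
#' @export
ibd_params <- function(min_lod = 3, trim_lod = 2.5, error_rate = 1e-4,
                       min_markers = 5L, tau = 0.9, icr_window_bp = 1e5) {
  if (!(min_lod >= trim_lod && trim_lod >= 0))
    ps_stop("need min_lod >= trim_lod >= 0")
  if (!(tau > 0 && tau <= 1)) ps_stop("tau must be in (0, 1]")
  if (!(error_rate > 0 && error_rate < 0.5)) ps_stop("error_rate in (0, 0.5)")
  structure(list(min_lod = min_lod, trim_lod = trim_lod,
                 error_rate = error_rate, min_markers = as.integer(min_markers),
                 tau = tau, icr_window_bp = icr_window_bp),
            class = "ibd_params")
}

#' Informative markers between the two parents
#'
#' Markers where the parental alleles differ and neither is missing.
#' @param p1,p2 parental allele vectors (0/1/NA).
#' @return integer vector of marker indices (possibly empty).
#' @export
informative_markers <- function(p1, p2) {
  which(!is.na(p1) & !is.na(p2) & p1 != p2)
}

#' Trace a line's parent of origin at informative markers
#'
#' Each informative, non-missing marker is labelled by allele match (1 =
#' parent 1, 2 = parent 2); a marker matching neither parent is a conflict
#' (`NA`, excluded from segments). Interior discordant runs shorter than
#' `min_markers` flanked on both sides by the same label are flipped to that
#' label (error smoothing); the raw label is kept alongside.
#'
#' @param line allele vector of the line (0/1/NA).
#' @param p1,p2 parental allele vectors.
#' @param map marker map (`chrom`, `pos_bp`).
#' @param params an [ibd_params()].
#' @return `data.table(marker, chrom, pos_bp, allele, raw, parent)` over the
#'   informative markers; `parent` is the smoothed label.
#' @export
trace_origin <- function(line, p1, p2, map, params = ibd_params()) {
  inf <- informative_markers(p1, p2)
  map <- as.data.table(map)
  dt <- data.table(marker = inf, chrom = map$chrom[inf],
                   pos_bp = map$pos_bp[inf], allele = line[inf])
  dt[, raw := fifelse(is.na(allele), NA_integer_,
               fifelse(allele == p1[marker], 1L,
               fifelse(allele == p2[marker], 2L, NA_integer_)))]
  dt[, parent := smooth_labels(raw, params$min_markers), by = chrom]
  dt[]
}

## flip interior runs shorter than min_markers whose flanking (non-NA) labels
## agree; iterate to a fixed point. NA entries are carried through untouched.
smooth_labels <- function(x, min_markers) {
  ok <- !is.na(x)
  y <- x[ok]
  if (length(y) < 3L) return(x)
  repeat {
    r <- rle(y)
    k <- length(r$lengths)
    if (k < 3L) break
    idx <- which(r$lengths[-c(1L, k)] < min_markers) + 1L
    idx <- idx[r$values[idx - 1L] == r$values[idx + 1L] &
                 r$values[idx] != r$values[idx - 1L]]
    if (!length(idx)) break
    r$values[idx] <- r$values[idx - 1L]
    y <- inverse.rle(r)
  }
  x[ok] <- y
  x
}

#' Score maximal same-parent runs and call IBD segments
#'
#' Each maximal run of one parent label is scored
#' `lod = sum_markers log10( P(allele | IBD with parent, eps) /
#' P(allele | panel frequency) )`; the IBD likelihood is `1 - eps` when the
#' observed allele matches the parent and `eps` otherwise, the background is
#' the panel frequency of the observed allele. Markers with panel frequency
#' 0 or 1 contribute 0 (never +/-Inf). Ends are trimmed at deep negative
#' dips of the cumulative LOD (see [ibd_params()]); runs with fewer than
#' `min_markers` markers or trimmed LOD `< min_lod` are dropped.
#'
#' @param trace output of [trace_origin()] for one line.
#' @param panel_freq numeric vector, per-marker frequency of allele 1 among
#'   the descendant panel (length = total markers).
#' @param params an [ibd_params()].
#' @param line_id optional line id stored in the result.
#' @param all if `TRUE`, return every maximal run with at least
#'   `min_markers` markers together with a `pass` flag instead of only the
#'   runs passing the LOD threshold. Sub-threshold runs carry no
#'   frequency-based evidence (typically because the panel is fixed there)
#'   but their allele-match assignment against the known inbred parents is
#'   still the most parsimonious origin, which gap attribution relies on.
#' @return `data.table(line, chrom, start_bp, end_bp, parent,
#'   n_informative_markers, lod)`, 0-based half-open (plus `pass` when
#'   `all = TRUE`).
#' @export
score_and_call_segments <- function(trace, panel_freq, params = ibd_params(),
                                    line_id = NA_character_, all = FALSE) {
  eps <- params$error_rate
  dt <- trace[!is.na(parent) & !is.na(allele)]
  if (!nrow(dt)) {
    empty <- data.table(line = character(), chrom = character(),
                        start_bp = numeric(), end_bp = numeric(),
                        parent = integer(), n_informative_markers = integer(),
                        lod = numeric())
    if (all) empty[, pass := logical()]
    return(empty)
  }
  ## per-marker lod against the panel background
  f1 <- panel_freq[dt$marker]
  f_obs <- fifelse(dt$allele == 1L, f1, 1 - f1)
  ## the parent allele the *label* claims: matches observed allele unless the
  ## label was smoothed over an error
  match_par <- dt$raw == dt$parent & !is.na(dt$raw)
  p_ibd <- fifelse(match_par, 1 - eps, eps)
  lod_m <- log10(p_ibd / f_obs)
  lod_m[f_obs <= 0 | f_obs >= 1] <- 0
  dt[, lod_m := lod_m]
  segs <- dt[, call_runs_chrom(.SD, params), by = chrom]
  if (!all) segs <- segs[pass == TRUE][, pass := NULL]
  segs[, line := if (nrow(segs)) line_id else character()]
  setcolorder(segs, c("line", "chrom", "start_bp", "end_bp", "parent",
                      "n_informative_markers", "lod"))
  segs[]
}

call_runs_chrom <- function(sd, params) {
  r <- rle(sd$parent)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- vector("list", length(r$values))
  for (i in seq_along(r$values)) {
    span <- starts[i]:ends[i]
    lods <- sd$lod_m[span]
    tr <- trim_run(lods, params)
    if (is.null(tr)) next
    span <- span[tr$keep]
    tot <- tr$lod
    if (length(span) < params$min_markers) next
    out[[i]] <- data.table(start_bp = sd$pos_bp[span[1L]] - 1,
                           end_bp = as.numeric(sd$pos_bp[span[length(span)]]),
                           parent = r$values[i],
                           n_informative_markers = length(span),
                           lod = tot, pass = tot >= params$min_lod)
  }
  res <- rbindlist(out)
  if (!nrow(res))
    res <- data.table(start_bp = numeric(), end_bp = numeric(),
                      parent = integer(), n_informative_markers = integer(),
                      lod = numeric(), pass = logical())
  res
}

## End trimming: from each end walk inward; if the cumulative lod dips below
## -(min_lod - trim_lod), trim through the last index attaining its minimum.
## Error-free ends (all contributions positive) are never trimmed.
trim_run <- function(lods, params) {
  dip <- -(params$min_lod - params$trim_lod)
  keep <- seq_along(lods)
  for (pass in 1:2) {
    if (!length(keep)) return(NULL)
    cs <- cumsum(lods[keep])
    m <- min(cs)
    if (m < dip) {
      cut <- max(which(cs == m))
      if (cut >= length(keep)) return(NULL)
      keep <- keep[(cut + 1L):length(keep)]
    }
    keep <- rev(keep)          # second pass trims the other end
  }
  keep <- sort(keep)
  list(keep = keep, lod = sum(lods[keep]))
}

#' Attribute uninformative gaps by minimum recombination
#'
#' Extends IBD segments into the gaps between them so that the implied
#' recombination count is minimal: a gap flanked by the same parent joins
#' that parent (0 recombinations); a gap flanked by different parents gets a
#' single breakpoint at its midpoint; terminal gaps take the nearest
#' segment's parent.
#'
#' @param segments segment table for one line (as from
#'   [score_and_call_segments()]), possibly several chromosomes.
#' @param bounds `data.table(chrom, len_bp)`.
#' @return `data.table(chrom, start, end, parent)` tiling each chromosome
#'   that has at least one segment; chromosomes with none are returned with
#'   `parent = NA` (flagged unassigned).
#' @export
attribute_gaps <- function(segments, bounds) {
  segments <- as.data.table(segments)
  bounds <- as.data.table(bounds)
  out <- lapply(seq_len(nrow(bounds)), function(i) {
    ch <- bounds$chrom[i]; len <- bounds$len_bp[i]
    s <- segments[chrom == ch][order(start_bp)]
    if (!nrow(s))
      return(data.table(chrom = ch, start = 0, end = len, parent = NA_integer_))
    brk <- 0
    res <- list()
    for (k in seq_len(nrow(s))) {
      if (k < nrow(s) && s$parent[k + 1L] == s$parent[k]) next
      end_k <- if (k == nrow(s)) len
               else floor((s$end_bp[k] + s$start_bp[k + 1L]) / 2)
      res[[length(res) + 1L]] <-
        data.table(chrom = ch, start = brk, end = end_k, parent = s$parent[k])
      brk <- end_k
    }
    rbindlist(res)
  })
  rbindlist(out)
}

#' Trace, score and tile every descendant line of a panel
#'
#' @param panel a [geno_matrix()] containing the two parents and the
#'   descendant lines.
#' @param parents character vector of length 2: parent line ids (P1, P2).
#' @param params an [ibd_params()].
#' @return list `segments` (one table, all lines), `tilings` (named list of
#'   per-line tilings), `informative`, `panel_freq`.
#' @export
ibd_trace_panel <- function(panel, parents = c("P1", "P2"),
                            params = ibd_params()) {
  if (!all(parents %in% panel$lines))
    ps_stop("parent ids %s not in panel", paste(parents, collapse = ", "))
  kids <- setdiff(panel$lines, parents)
  p1 <- panel$geno[parents[1], ]; p2 <- panel$geno[parents[2], ]
  freq <- colMeans(panel$geno[kids, , drop = FALSE] == 1L, na.rm = TRUE)
  freq[is.nan(freq)] <- NA_real_
  bounds <- panel$map[, .(len_bp = max(pos_bp)), by = chrom]
  segs <- list(); tilings <- list()
  for (id in kids) {
    tr <- trace_origin(panel$geno[id, ], p1, p2, panel$map, params)
    sg <- score_and_call_segments(tr, freq, params, line_id = id, all = TRUE)
    segs[[id]] <- sg[pass == TRUE][, pass := NULL]
    ## tiling anchors on every maximal run: sub-threshold runs occur where
    ## the panel is fixed (no frequency evidence) yet the allele match to a
    ## known inbred parent still determines origin
    tilings[[id]] <- attribute_gaps(sg, bounds)
  }
  list(segments = rbindlist(segs), tilings = tilings,
       informative = informative_markers(p1, p2), panel_freq = freq,
       bounds = bounds)
}

#' Call IBD-conserved regions (ICRs)
#'
#' The genome is divided into `icr_window_bp` bins; in each bin a line's
#' parent is the one covering the majority of the bin in its tiling
#' (unassigned lines are excluded from the denominator). Maximal runs of
#' bins with retention `>= tau` for one parent are merged into ICRs.
#'
#' @param tilings named list of per-line tilings from [attribute_gaps()].
#' @param bounds `data.table(chrom, len_bp)`.
#' @param params an [ibd_params()].
#' @return `data.table(chrom, start, end, parent, retention, n_bins)` plus
#'   attribute `genome_fraction` (named per-parent fraction of the genome in
#'   ICRs).
#' @export
call_icrs <- function(tilings, bounds, params = ibd_params()) {
  if (length(tilings) < 2L) ps_stop("need >= 2 lines to call ICRs")
  bounds <- as.data.table(bounds)
  w <- params$icr_window_bp
  bins <- bounds[, .(start = seq(0, len_bp - 1, by = w)), by = chrom]
  bins[, end := pmin(start + w, bounds$len_bp[match(chrom, bounds$chrom)])]
  ## majority parent per line per bin
  lab <- sapply(tilings, function(tl) bin_majority_parent(tl, bins))
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = length(tilings))
  n_assigned <- rowSums(!is.na(lab))
  icrs <- list()
  for (p in 1:2) {
    ret <- rowSums(lab == p, na.rm = TRUE) / pmax(n_assigned, 1L)
    ret[n_assigned == 0L] <- 0
    hit <- ret >= params$tau
    bb <- copy(bins)[, `:=`(hit = hit, ret = ret)]
    runs <- bb[, merge_bin_runs(.SD), by = chrom]
    if (nrow(runs)) icrs[[p]] <- runs[, parent := p]
  }
  out <- rbindlist(icrs)
  if (!nrow(out)) {
    ps_warn("no ICRs at tau = %g", params$tau)
    out <- data.table(chrom = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), retention = numeric(),
                      parent = integer())
  }
  setcolorder(out, c("chrom", "start", "end", "parent", "retention", "n_bins"))
  gl <- sum(bounds$len_bp)
  gf <- vapply(1:2, function(p) out[parent == p, sum(end - start)] / gl, 0)
  setattr(out, "genome_fraction", setNames(gf, c("P1", "P2")))
  out[order(chrom, start)]
}

bin_majority_parent <- function(tiling, bins) {
  tl <- as.data.table(tiling)[!is.na(parent)]
  vapply(seq_len(nrow(bins)), function(i) {
    seg <- tl[chrom == bins$chrom[i] & start < bins$end[i] & end > bins$start[i]]
    if (!nrow(seg)) return(NA_integer_)
    ov <- pmin(seg$end, bins$end[i]) - pmax(seg$start, bins$start[i])
    cov <- tapply(ov, seg$parent, sum)
    as.integer(names(cov)[which.max(cov)])
  }, 1L)
}

merge_bin_runs <- function(sd) {
  r <- rle(sd$hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(data.table(start = numeric(), end = numeric(),
                                       n_bins = integer(),
                                       retention = numeric()))
  data.table(start = sd$start[starts[keep]], end = sd$end[ends[keep]],
             n_bins = ends[keep] - starts[keep] + 1L,
             retention = vapply(keep, function(k)
               mean(sd$ret[starts[k]:ends[k]]), 0))
}

#' Per-line parental retention ratio
#'
#' Ratio of bp assigned to parent 1 within P1-ICRs over bp assigned to
#' parent 2 within P2-ICRs; a variant over all assigned IBD (ignoring ICRs)
#' is also returned. A zero denominator yields `NA` with `undefined = TRUE`
#' rather than an error.
#'
#' @param tiling a per-line tiling from [attribute_gaps()].
#' @param icrs ICR table from [call_icrs()] (only needed for the ICR-based
#'   ratio).
#' @return one-row `data.table(p1_icr_bp, p2_icr_bp, ratio_icr, p1_bp,
#'   p2_bp, ratio_all, undefined)`.
#' @export
retention_ratio <- function(tiling, icrs = NULL) {
  tl <- as.data.table(tiling)[!is.na(parent)]
  tot <- function(x) if (nrow(x)) sum(x$end - x$start) else 0
  p1_all <- tot(tl[parent == 1L]); p2_all <- tot(tl[parent == 2L])
  if (!is.null(icrs) && nrow(icrs)) {
    ov <- function(p) {
      a <- tl[parent == p]; b <- as.data.table(icrs)[parent == p]
      if (!nrow(a) || !nrow(b)) return(0)
      iv_total_length(iv_intersect(a, b))
    }
    p1_icr <- ov(1L); p2_icr <- ov(2L)
  } else {
    p1_icr <- NA_real_; p2_icr <- NA_real_
  }
  data.table(p1_icr_bp = p1_icr, p2_icr_bp = p2_icr,
             ratio_icr = ifelse(!is.na(p2_icr) & p2_icr > 0,
                                p1_icr / p2_icr, NA_real_),
             p1_bp = p1_all, p2_bp = p2_all,
             ratio_all = ifelse(p2_all > 0, p1_all / p2_all, NA_real_),
             undefined = p2_all == 0 |
               (!is.na(p2_icr) & p2_icr == 0))
}
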