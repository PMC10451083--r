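## Site-frequency-spectrum window statistics and sweep-region calling:
## nucleotide diversity (pi), Watterson's theta, Tajima's D in 10-kb tiles,
## aggregation to 100-kb means, top-10%-of-genome selection in the sweep
## direction, and adjacent-window merging into selective-sweep regions.
## Inbred lines contribute one haplotype each; the derived (non-reference)
## allele is the VCF ALT allele, i.e. the parent-2 allele in simulations.

#' Per-site derived-allele counts of a panel
#'
#' @param gm a [geno_matrix()].
#' @return `data.table(marker, chrom, pos_bp, j, n)` with `j` the derived
#'   count among the `n` non-missing lines at the site; all markers kept
#'   (monomorphic sites have `j = 0` or `j = n`).
#' @export
site_counts <- function(gm) {
  j <- colSums(gm$geno == 1L, na.rm = TRUE)
  n <- colSums(!is.na(gm$geno))
  data.table(marker = seq_len(ncol(gm$geno)), chrom = gm$map$chrom,
             pos_bp = gm$map$pos_bp, j = as.integer(j), n = as.integer(n))
}

#' Per-window site frequency spectrum
#'
#' Tiles each chromosome into `win`-bp windows and collects the derived
#' counts of segregating sites per window (`0 < j < n`, per-site `n`).
#'
#' @param gm a [geno_matrix()].
#' @param win window width in bp (default 1e4).
#' @param bounds optional `data.table(chrom, len_bp)`; defaults to the last
#'   marker per chromosome.
#' @return `data.table(chrom, start, end, sites)` where `sites` is a list
#'   column of `data.table(j, n)` (empty for windows with no segregating
#'   site).
#' @export
window_sfs <- function(gm, win = 1e4, bounds = NULL) {
  sc <- site_counts(gm)
  if (is.null(bounds))
    bounds <- gm$map[, .(len_bp = max(pos_bp)), by = chrom]
  bounds <- as.data.table(bounds)
  wins <- bounds[, .(start = seq(0, len_bp - 1, by = win)), by = chrom]
  wins[, end := pmin(start + win, bounds$len_bp[match(chrom, bounds$chrom)])]
  seg <- sc[j > 0L & j < n]
  seg[, start := (pos_bp - 1) %/% win * win]
  agg <- seg[, .(sites = list(data.table(j = j, n = n))), by = .(chrom, start)]
  out <- agg[wins, on = c("chrom", "start")]
  out[, sites := lapply(sites, function(s)
    if (is.null(s)) data.table(j = integer(), n = integer()) else s)]
  setcolorder(out, c("chrom", "start", "end", "sites"))
  out[order(chrom, start)]
}

#' Nucleotide diversity and Watterson's theta of one window
#'
#' `pi = sum_sites 2 j (n - j) / (n (n - 1))` (per-window total, not
#' per-bp); `theta_w = sum_sites 1 / a1(n_site)`, which equals `S / a1(n)`
#' when all sites share the same `n`.
#'
#' @param sfs `data.table(j, n)` of one window's segregating sites.
#' @return `list(pi, theta_w, S)`.
#' @export
pi_theta <- function(sfs) {
  sfs <- as.data.table(sfs)[n >= 2L]
  if (!nrow(sfs)) return(list(pi = 0, theta_w = 0, S = 0L))
  a1 <- vapply(sfs$n, function(n) sum(1 / seq_len(n - 1L)), 0)
  list(pi = sum(2 * sfs$j * (sfs$n - sfs$j) / (sfs$n * (sfs$n - 1))),
       theta_w = sum(1 / a1), S = nrow(sfs))
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D of one window
#'
#' `D = (pi - theta_w) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants as functions of `n`. Undefined (`NA`) when `S = 0` or the
#' variance term is non-positive. With missing data the constants use the
#' maximum per-site `n` of the window.
#'
#' @param sfs `data.table(j, n)` of one window's segregating sites.
#' @return scalar D (or `NA`).
#' @export
tajimas_d <- function(sfs) {
  sfs <- as.data.table(sfs)[n >= 2L]
  S <- nrow(sfs)
  if (S == 0L) return(NA_real_)
  n <- max(sfs$n)
  if (n < 3L) return(NA_real_)
  pt <- pi_theta(sfs)
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pt$pi - pt$theta_w) / sqrt(v)
}

#' Per-window diversity statistics
#'
#' @param gm a [geno_matrix()].
#' @param win window width in bp (default 1e4).
#' @param bounds optional chromosome bounds (`chrom`, `len_bp`).
#' @return `data.table(chrom, start, end, n, S, pi, theta_w, tajima_d)`.
#' @export
window_stats <- function(gm, win = 1e4, bounds = NULL) {
  ws <- window_sfs(gm, win = win, bounds = bounds)
  ws[, c("n", "S", "pi", "theta_w", "tajima_d") := {
    res <- lapply(sites, function(s) {
      pt <- pi_theta(s)
      list(n = if (nrow(s)) max(s$n) else NA_integer_,
           S = pt$S, pi = pt$pi, theta_w = pt$theta_w,
           tajima_d = tajimas_d(s))
    })
    list(vapply(res, function(r) as.integer(r$n %||% NA), 1L),
         vapply(res, `[[`, 1L, "S"),
         vapply(res, `[[`, 0, "pi"),
         vapply(res, `[[`, 0, "theta_w"),
         vapply(res, `[[`, 0, "tajima_d"))
  }]
  ws[, sites := NULL]
  ws[]
}

#' Genome-wide background site frequency spectrum
#'
#' Normalized distribution of derived counts `1..n-1` over all segregating
#' sites with complete data (`n` = panel size).
#'
#' @param gm a [geno_matrix()].
#' @return numeric vector `phi` of length `n - 1`, summing to 1, with
#'   attribute `n`.
#' @export
background_sfs <- function(gm) {
  n <- nrow(gm$geno)
  sc <- site_counts(gm)[n == nrow(gm$geno)]
  sc <- sc[j > 0L & j < n]
  if (!nrow(sc)) ps_stop("no polymorphic complete-data site; cannot form background SFS")
  phi <- tabulate(sc$j, nbins = n - 1L)
  phi <- phi / sum(phi)
  structure(phi, n = n)
}

#' Aggregate per-window or per-grid values into coarse window means
#'
#' Mean of the defined values whose interval centre (or grid position)
#' falls in each `agg`-bp tile; tiles with no defined contributor are `NA`.
#'
#' @param dt `data.table` with `chrom`, a position (`start`/`end` interval
#'   centres, or a `pos` column), and the value column.
#' @param value name of the value column.
#' @param agg tile width in bp (default 1e5).
#' @param bounds optional chromosome bounds.
#' @return `data.table(chrom, start, end, value, n_contrib)`.
#' @export
aggregate_windows <- function(dt, value, agg = 1e5, bounds = NULL) {
  dt <- as.data.table(dt)
  pos <- if ("pos" %in% names(dt)) dt$pos else (dt$start + dt$end) / 2
  x <- dt[[value]]
  tmp <- data.table(chrom = dt$chrom, tile = floor(pos / agg) * agg, x = x)
  res <- tmp[!is.na(x), .(value = mean(x), n_contrib = .N), by = .(chrom, tile)]
  if (is.null(bounds))
    bounds <- data.table(chrom = dt$chrom, p = pos)[, .(len_bp = max(p)),
                                                    by = chrom]
  bounds <- as.data.table(bounds)
  tiles <- bounds[, .(tile = seq(0, len_bp - 1, by = agg)), by = chrom]
  out <- res[tiles, on = c("chrom", "tile")]
  out[is.na(n_contrib), n_contrib := 0L]
  out[, `:=`(start = tile, end = tile + agg, tile = NULL)]
  setcolorder(out, c("chrom", "start", "end", "value", "n_contrib"))
  out[order(chrom, start)]
}

#' Select the extreme top fraction of the genome and merge into regions
#'
#' Windows are ranked in the sweep-evidence direction (`"low"` for pi and
#' Tajima's D, `"high"` for CLR); the smallest top-ranked set whose summed
#' length reaches `fraction` of the total defined length is selected (ties
#' at the cutoff value all included), and coordinate-adjacent selected
#' windows are merged into maximal regions.
#'
#' @param dt `data.table(chrom, start, end, value)` (NA values excluded).
#' @param fraction genome fraction to select (default 0.10).
#' @param direction `"low"` or `"high"`: which tail is sweep evidence.
#' @param statistic label stored in the output.
#' @return `data.table(chrom, start, end, statistic, peak_value, n_windows)`
#'   with attribute `selected` (the selected windows).
#' @export
select_top_and_merge <- function(dt, fraction = 0.10,
                                 direction = c("high", "low"),
                                 statistic = "stat") {
  direction <- match.arg(direction)
  dt <- as.data.table(dt)[!is.na(value)]
  if (nrow(dt) < 10L) ps_stop("need >= 10 defined windows")
  ord <- order(if (direction == "high") -dt$value else dt$value)
  dt <- dt[ord]
  len <- dt$end - dt$start
  need <- fraction * sum(len)
  k <- which(cumsum(len) >= need)[1L]
  cut_val <- dt$value[k]
  sel <- if (direction == "high") dt[value >= cut_val] else dt[value <= cut_val]
  sel <- sel[order(chrom, start)]
  ## cumsum over logical "new region" flags
  sel[, grp := cumsum(c(TRUE, start[-1L] != head(end, -1L) |
                          chrom[-1L] != head(chrom, -1L)))]
  out <- sel[, .(chrom = chrom[1L], start = min(start), end = max(end),
                 statistic = statistic,
                 peak_value = if (direction == "high") max(value) else min(value),
                 n_windows = .N), by = grp][, grp := NULL]
  setattr(out, "selected", sel[, .(chrom, start, end, value)])
  out[]
}

#' Panel marker diagnostics: MAF and PIC
#'
#' Minor-allele frequency `min(p, 1 - p)` and polymorphism information
#' content `1 - p^2 - q^2 - 2 p^2 q^2` per marker, plus the proportions of
#' markers with MAF below 0.01 and 0.02. All-missing markers are excluded.
#'
#' @param gm a [geno_matrix()].
#' @return list `per_marker` (`data.table(marker_id, chrom, pos_bp, p, maf,
#'   pic)`), `prop_maf_lt_01`, `prop_maf_lt_02`, `mean_pic`.
#' @export
popstats <- function(gm) {
  sc <- site_counts(gm)
  sc <- sc[n > 0L]
  p <- sc$j / sc$n
  q <- 1 - p
  dt <- data.table(marker_id = gm$map$marker_id[sc$marker],
                   chrom = sc$chrom, pos_bp = sc$pos_bp, p = p,
                   maf = pmin(p, q),
                   pic = 1 - p^2 - q^2 - 2 * p^2 * q^2)
  list(per_marker = dt,
       prop_maf_lt_01 = mean(dt$maf < 0.01),
       prop_maf_lt_02 = mean(dt$maf < 0.02),
       mean_pic = mean(dt$pic))
}
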