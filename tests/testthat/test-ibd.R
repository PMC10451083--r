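test_that("informative_markers handles the degenerate cases", {
  p <- c(0L, 1L, 0L, NA, 1L)
  expect_length(informative_markers(p, p), 0)
  expect_identical(informative_markers(c(0L, 0L, 0L), c(1L, 1L, 1L)), 1:3)
  expect_identical(informative_markers(c(0L, 0L, NA), c(1L, 0L, 1L)), 1L)
})

test_that("trace_origin recovers the true path and smooths isolated errors", {
  cfg <- tiny_cfg(seed = 31, divergence = 1)
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  d <- simulate_descendants(cfg, f)
  for (i in 1:5) {
    ## noiseless: no smoothing needed; raw labels equal the true path
    tr <- trace_origin(d$truth$geno_clean[i, ], f$p1, f$p2, f$map,
                       ibd_params(min_markers = 1))
    expect_identical(tr$parent, d$truth$origin[i, tr$marker])
  }

  ## one flipped allele inside a long parent-1 block stays one block
  line <- f$p1
  line[100] <- f$p2[100]
  tr <- trace_origin(line, f$p1, f$p2, f$map, ibd_params(min_markers = 3))
  expect_true(all(tr$parent == 1L))
  expect_identical(tr$raw[tr$marker == 100], 2L)

  ## per-marker accuracy >= 99% under eps = 0.001
  cfg2 <- tiny_cfg(seed = 32, divergence = 1, genotype_error = 0.001,
                   n_descendants = 10)
  set.seed(cfg2$seed)
  f2 <- make_founders(cfg2)
  d2 <- simulate_descendants(cfg2, f2)
  acc <- vapply(1:10, function(i) {
    g <- d2$panel$geno[paste0("X", sprintf("%02d", i)), ]
    tr <- trace_origin(g, f2$p1, f2$p2, f2$map)
    mean(tr$parent == d2$truth$origin[i, tr$marker], na.rm = TRUE)
  }, 0)
  expect_gte(min(acc), 0.99)
})

test_that("segment LOD matches the hand formula and drives calling", {
  ## single-marker run at panel frequency 0.5: lod = log10((1-eps)/0.5)
  map <- data.table(chrom = "1", pos_bp = c(1000, 2000), pos_cM = c(0, 1))
  trace <- data.table(marker = 1:2, chrom = "1", pos_bp = c(1000, 2000),
                      allele = c(0L, 1L), raw = c(1L, 2L), parent = c(1L, 2L))
  freq <- c(0.5, 0.5)
  eps <- 1e-4
  lone <- score_and_call_segments(trace, freq,
                                  ibd_params(min_markers = 1, min_lod = 3),
                                  "L1")
  expect_equal(nrow(lone), 0)     # lod ~ 0.301 < 3 -> dropped
  kept <- score_and_call_segments(trace, freq,
                                  ibd_params(min_markers = 1, min_lod = 0.2,
                                             trim_lod = 0.2), "L1")
  expect_equal(kept$lod, rep(log10((1 - eps) / 0.5), 2), tolerance = 1e-12)

  ## long error-free run: lod grows linearly in marker count
  M <- 100
  trace2 <- data.table(marker = 1:M, chrom = "1", pos_bp = (1:M) * 1000,
                       allele = 0L, raw = 1L, parent = 1L)
  seg <- score_and_call_segments(trace2, rep(0.5, M), ibd_params(), "L1")
  expect_equal(seg$lod, M * log10((1 - eps) / 0.5), tolerance = 1e-9)
  expect_equal(seg$n_informative_markers, M)

  ## panel frequency 0 or 1 contributes 0, never +/- Inf
  seg2 <- score_and_call_segments(trace2, rep(1, M),
                                  ibd_params(min_lod = 0, trim_lod = 0,
                                             min_markers = 1), "L1")
  expect_equal(seg2$lod, 0)

  ## all-missing line -> no segments
  trace3 <- copy(trace2)[, `:=`(allele = NA_integer_, raw = NA_integer_,
                                parent = NA_integer_)]
  expect_equal(nrow(score_and_call_segments(trace3, rep(0.5, M),
                                            ibd_params(), "L1")), 0)
})

test_that("attribute_gaps implements minimum recombination", {
  bounds <- data.table(chrom = "1", len_bp = 20000)

  same <- data.table(line = "L", chrom = "1",
                     start_bp = c(0, 12000), end_bp = c(10000, 20000),
                     parent = c(1L, 1L), n_informative_markers = 5L, lod = 9)
  tl <- attribute_gaps(same, bounds)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$start, 0); expect_equal(tl$end, 20000)
  expect_equal(tl$parent, 1L)

  diffp <- data.table(line = "L", chrom = "1",
                      start_bp = c(0, 14000), end_bp = c(10000, 20000),
                      parent = c(1L, 2L), n_informative_markers = 5L, lod = 9)
  tl2 <- attribute_gaps(diffp, bounds)
  expect_equal(tl2$end[1], 12000)   # midpoint of the 10-14 kb gap
  expect_equal(tl2$parent, c(1L, 2L))

  ## no segments -> flagged unassigned
  tl3 <- attribute_gaps(same[0], bounds)
  expect_true(is.na(tl3$parent))

  ## optimality against enumeration on random <= 10-segment chromosomes
  set.seed(33)
  for (rep in 1:25) {
    k <- sample(1:10, 1)
    cuts <- sort(sample(1000:19000, 2 * k))
    segs <- data.table(line = "L", chrom = "1",
                       start_bp = cuts[seq(1, 2 * k, 2)],
                       end_bp = cuts[seq(2, 2 * k, 2)],
                       parent = sample(1:2, k, replace = TRUE),
                       n_informative_markers = 5L, lod = 9)
    tl <- attribute_gaps(segs, bounds)
    got <- sum(tl$parent[-1] != tl$parent[-nrow(tl)])
    expect_equal(got, oracle_min_recomb(segs$parent))
    ## tiling conservation
    expect_equal(sum(tl$end - tl$start), 20000)
    expect_equal(tl$start[-1], tl$end[-nrow(tl)])
  }
})

test_that("ICR calling respects the retention threshold", {
  bounds <- data.table(chrom = "1", len_bp = 1e6)
  mk <- function(parent) data.table(chrom = "1", start = 0, end = 1e6,
                                    parent = parent)
  all_p1 <- replicate(15, mk(1L), simplify = FALSE)
  icr <- call_icrs(all_p1, bounds, ibd_params())
  expect_equal(nrow(icr), 1)
  expect_equal(icr$retention, 1)
  expect_equal(icr$parent, 1L)
  expect_equal(unname(attr(icr, "genome_fraction")["P1"]), 1)

  ## 13 of 15 = 0.867 < tau = 0.9 -> nothing
  mixed <- c(replicate(13, mk(1L), simplify = FALSE),
             replicate(2, mk(2L), simplify = FALSE))
  expect_warning(icr2 <- call_icrs(mixed, bounds, ibd_params()), "no ICR")
  expect_equal(nrow(icr2), 0)

  ## reported retention always >= tau, recomputed from the raw tilings
  cfg <- tiny_cfg(seed = 34, n_descendants = 12, n_candidates = 40,
                  n_cycles = 4)
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  d <- simulate_descendants(cfg, f)
  tr <- ibd_trace_panel(d$panel)
  bounds2 <- data.table(chrom = c("1", "2"), len_bp = 2e6)
  icr3 <- call_icrs(tr$tilings, bounds2, ibd_params())
  ## independent recomputation of bin-majority retention over each ICR
  bin_ret <- function(chrom_id, lo, hi, par) {
    bins <- seq(lo, hi - 1, by = 1e5)
    rets <- vapply(bins, function(b0) {
      b1 <- min(b0 + 1e5, hi)
      lab <- vapply(tr$tilings, function(tl) {
        tl <- tl[tl$chrom == chrom_id & !is.na(tl$parent), ]
        ov <- pmax(pmin(tl$end, b1) - pmax(tl$start, b0), 0)
        if (!sum(ov)) return(NA_integer_)
        cov <- tapply(ov, tl$parent, sum)
        as.integer(names(cov)[which.max(cov)])
      }, 1L)
      sum(lab == par, na.rm = TRUE) / max(sum(!is.na(lab)), 1L)
    }, 0)
    rets
  }
  expect_gt(nrow(icr3), 0)
  for (r in seq_len(nrow(icr3))) {
    rets <- bin_ret(icr3$chrom[r], icr3$start[r], icr3$end[r], icr3$parent[r])
    expect_true(all(rets >= 0.9))
    expect_equal(icr3$retention[r], mean(rets), tolerance = 1e-9)
  }
})

test_that("retention_ratio matches an independent interval-sum oracle", {
  tiling <- data.table(chrom = "1",
                       start = c(0, 4e5, 7e5), end = c(4e5, 7e5, 1e6),
                       parent = c(1L, 2L, 1L))
  icrs <- data.table(chrom = "1", start = c(0, 45e4), end = c(2e5, 65e4),
                     parent = c(1L, 2L), retention = 1, n_bins = 2L)
  rr <- retention_ratio(tiling, icrs)
  expect_equal(rr$p1_icr_bp, 2e5)
  expect_equal(rr$p2_icr_bp, 2e5)
  expect_equal(rr$ratio_icr, 1)
  expect_equal(rr$ratio_all, (4e5 + 3e5) / 3e5)
  expect_false(rr$undefined)

  ## line entirely parent 1 -> undefined, not an error
  solo <- data.table(chrom = "1", start = 0, end = 1e6, parent = 1L)
  rr2 <- retention_ratio(solo, icrs)
  expect_true(rr2$undefined)
  expect_true(is.na(rr2$ratio_all))
})

test_that("noiseless breakpoints sit within one inter-marker gap of truth", {
  cfg <- tiny_cfg(seed = 35, n_descendants = 8)
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  d <- simulate_descendants(cfg, f)
  tr <- ibd_trace_panel(d$panel)
  ids <- setdiff(d$panel$lines, c("P1", "P2"))
  inf_pos <- split(f$map$pos_bp[f$informative], f$map$chrom[f$informative])
  for (i in seq_along(ids)) {
    tl <- tr$tilings[[ids[i]]]
    truth_bp <- d$truth$breakpoints[[i]]
    for (ch in c("1", "2")) {
      got <- tl[chrom == ch]
      brks <- head(got$end, -1)
      tb <- if (!is.null(truth_bp) && nrow(truth_bp)) truth_bp[chrom == ch]
            else data.table(bp = numeric())
      pos <- inf_pos[[ch]]
      for (b in brks) {
        expect_gt(nrow(tb), 0)
        k <- which.min(abs(tb$bp - b))
        ## the true crossover, localized to its flanking *informative*
        ## markers, must contain the inferred breakpoint
        lo <- max(pos[pos <= tb$bp[k]], 0)
        hi <- min(pos[pos >= tb$bp[k]], 2e6)
        expect_true(b >= lo - 1 && b <= hi + 1,
                    label = sprintf("line %s chr%s breakpoint %g in [%g, %g]",
                                    ids[i], ch, b, lo, hi))
      }
    }
  }
})
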