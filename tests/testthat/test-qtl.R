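test_that("moisture adjustment: closed form and domain", {
  expect_equal(adjust_moisture(100, 0.13), 100, tolerance = 1e-12)
  expect_equal(adjust_moisture(100, 0.20), 100 * 0.80 / 0.87,
               tolerance = 1e-9)                 # 91.954...
  expect_equal(adjust_moisture(50, 0), 50 / 0.87, tolerance = 1e-12)
  expect_error(adjust_moisture(10, 1), "water content")
})

test_that("Kosambi map function: closed form, inverses, domain", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi_inv(0), 0)
  expect_equal(kosambi_inv(10), 0.5 * tanh(0.2), tolerance = 1e-12)
  d <- seq(0, 200, by = 0.5)
  expect_equal(kosambi(kosambi_inv(d)), d, tolerance = 1e-12)
  expect_error(kosambi(0.5), "r must")
  expect_error(kosambi_inv(-1), "d_cM")
})

test_that("stepwise selection: null, single signal, degenerate bound", {
  ## pure noise: empty set in >= 95% of 100 seeded runs at p_in = 0.001
  set.seed(61)
  empty <- vapply(1:100, function(i) {
    X <- matrix(sample(c(-1, 1), 100 * 50, replace = TRUE), 100)
    y <- rnorm(100)
    length(stepwise_select(X, y)) == 0L
  }, TRUE)
  expect_gte(mean(empty), 0.95)

  ## clear single signal is found
  set.seed(62)
  hits <- vapply(1:20, function(i) {
    X <- matrix(sample(c(-1, 1), 100 * 50, replace = TRUE), 100)
    y <- 2 * X[, 17] + rnorm(100, 0, 0.5)
    identical(stepwise_select(X, y), 17L)
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  ## p_in = 1: everything non-collinear enters up to the cap
  set.seed(63)
  X <- matrix(sample(c(-1, 1), 60 * 8, replace = TRUE), 60)
  sel <- stepwise_select(X, rnorm(60), p_in = 1, p_out = 1)
  expect_equal(sel, 1:8)

  ## collinear duplicate is skipped
  X2 <- cbind(X, X[, 1])
  y2 <- X[, 1] + rnorm(60, 0, 0.1)
  sel2 <- stepwise_select(X2, y2, p_in = 1e-6, p_out = 1e-6)
  expect_true(1L %in% sel2 && !(9L %in% sel2))
})

test_that("ICIM scan: marker positions, noiseless recovery, affine invariance", {
  cfg <- tiny_cfg(seed = 64, dh_n = 200, divergence = 1)
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  dh <- simulate_dh_population(cfg, f)
  gm <- geno_matrix(dh$truth$geno_clean, f$map)

  ## noiseless single QTL: effect recovered to 1e-6, peak at the QTL marker
  qt <- data.frame(trait = "t", chrom = "1", pos_cM = 50, add = 0.8)
  ph <- simulate_phenotypes(dh$truth$geno_clean, f$map, qt, h2 = 1,
                            n_env = 1, n_rep = 1, env_sd_frac = 0)
  y <- setNames(ph$t, ph$line)
  prof <- icim_scan(gm, y, integer(), scan_params())
  qtls <- call_qtls(prof, scan_params(), trait = "t", env = "E1")
  ## without noise every marker correlated with the QTL clears LOD 2.5, so
  ## several peaks are legitimate; the max-LOD one is the QTL itself
  top <- qtls[which.max(lod)]
  expect_equal(top$a, 0.8, tolerance = 1e-6)
  idx <- which.min(abs(f$map$pos_cM - 50) + (f$map$chrom != "1") * 1e9)
  expect_lt(abs(top$peak_cM - f$map$pos_cM[idx]), 1)
  expect_gte(top$pve, 99)

  ## at a marker position the expected code equals the observed code: on a
  ## grid-aligned integer-cM map the profile value at the marker equals the
  ## plain single-marker regression LOD
  set.seed(640)
  gsync <- matrix(sample(0:1, 100 * 30, replace = TRUE), 100)
  gma <- make_gm(gsync, spacing_bp = 1e4, cm_per_marker = 1)
  ya <- (1 - 2 * gsync[, 10]) * 0.8 + rnorm(100)
  names(ya) <- gma$lines
  pa <- icim_scan(gma, ya, integer(), scan_params())
  ysc <- ya - mean(ya)
  xm <- 1 - 2 * gsync[, 10]
  rss0 <- sum(ysc^2)
  rss1 <- sum(lm(ysc ~ xm)$residuals^2)
  lod_marker <- (100 / 2) * log10(rss0 / rss1)
  expect_equal(pa[pa$pos_cM == 9, ]$lod, lod_marker, tolerance = 1e-8)

  ## LOD profile is invariant to affine transformation of y
  prof2 <- icim_scan(gm, 3 * y + 11, integer(), scan_params())
  expect_equal(prof2$lod, prof$lod, tolerance = 1e-8)

  ## flat profile -> no calls
  expect_equal(nrow(call_qtls(copy(prof)[, lod := 0], scan_params())), 0)
})

test_that("stable QTL grouping follows support-interval overlap", {
  q <- data.table(trait = "t", env = c("E1", "E2", "E3"), chrom = "1",
                  peak_cM = c(50, 51, 49), lod = c(5, 6, 7), a = 1, pve = 10,
                  ci_lo_cM = c(45, 46, 44), ci_hi_cM = c(55, 56, 54))
  st <- stable_qtls(q)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_env, 3L)

  ## disjoint intervals 50 cM apart on one chromosome: not stable
  q2 <- copy(q)[, `:=`(ci_lo_cM = c(10, 70, 130), ci_hi_cM = c(20, 80, 140),
                       peak_cM = c(15, 75, 135))]
  expect_equal(nrow(stable_qtls(q2)), 0)

  ## same interval but a single environment: not stable
  q3 <- copy(q)[, env := "E1"]
  expect_equal(nrow(stable_qtls(q3)), 0)
})

test_that("QTL clusters match brute-force chaining", {
  mk <- function(n, chrom = "1", start0 = 0, gap = 1e5, w = 3e5)
    data.table(trait = paste0("t", seq_len(n)), chrom = chrom,
               start = start0 + (seq_len(n) - 1) * gap,
               end = start0 + (seq_len(n) - 1) * gap + w)
  ## 13 overlapping QTLs -> one cluster of 13
  cl <- qtl_clusters(mk(13), cluster_gap = 2e6, min_size = 4)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_qtls, 13L)

  ## 3 overlapping QTLs below min_size -> nothing
  expect_equal(nrow(qtl_clusters(mk(3), min_size = 4)), 0)

  ## random layouts vs oracle
  set.seed(65)
  for (r in 1:15) {
    n <- sample(5:25, 1)
    q <- data.table(trait = "t", chrom = sample(c("1", "2"), n, TRUE),
                    start = sample(1e7, n))
    q[, end := start + sample(1e5:2e6, n, replace = TRUE)]
    gap <- 5e5
    cl <- qtl_clusters(q, cluster_gap = gap, min_size = 1)
    grp <- oracle_chain(q, gap)
    expect_equal(nrow(cl), length(unique(grp)))
    expect_equal(sort(cl$n_qtls), sort(unname(as.vector(table(grp)))))
  }
})

test_that("cumulative additive effects: maximum, antisymmetry, missing", {
  cfg <- tiny_cfg(seed = 66, divergence = 1, markers_per_chrom = 50)
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  qtls <- data.table(trait = "t", chrom = c("1", "2"), peak_cM = c(30, 60),
                     a = c(1.2, -0.7))
  g <- rbind(P1like = f$p1, P2like = f$p2)
  gm <- geno_matrix(g, f$map)
  res <- cae(gm, qtls)
  ## P1-like line carries +1 everywhere: CAE = sum(a); antisymmetry holds
  expect_equal(res$cae[1], sum(qtls$a))
  expect_equal(res$cae[1] + res$cae[2], 0)
  ## favourable alleles at every QTL -> sum |a|
  best <- ifelse(rep(qtls$a, each = 1) > 0, 0L, 1L)
  gbest <- f$p1
  idx <- sapply(seq_len(nrow(qtls)), function(i) {
    w <- which(f$map$chrom == qtls$chrom[i])
    w[which.min(abs(f$map$pos_cM[w] - qtls$peak_cM[i]))]
  })
  gbest[idx] <- best
  res2 <- cae(geno_matrix(rbind(best = gbest), f$map), qtls)
  expect_equal(res2$cae, sum(abs(qtls$a)))
  ## missing genotype at a QTL skips the term and reports it
  gmiss <- f$p1; gmiss[idx[1]] <- NA
  res3 <- cae(geno_matrix(rbind(m = gmiss), f$map), qtls)
  expect_equal(res3$n_missing, 1L)
  expect_equal(res3$cae, qtls$a[2] * 1)
})
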