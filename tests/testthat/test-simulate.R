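test_that("make_founders places the stated number of informative markers", {
  set.seed(1)
  f <- make_founders(tiny_cfg(markers_per_chrom = 50, divergence = 1))
  expect_length(f$informative, 100)            # all markers differ
  expect_true(all(f$p1 == 0L) && all(f$p2[f$informative] == 1L))

  cfg <- tiny_cfg(markers_per_chrom = 500, divergence = 0.5)
  set.seed(42); a <- make_founders(cfg)
  set.seed(42); b <- make_founders(cfg)
  expect_length(a$informative, 500)            # round(0.5 * 1000)
  expect_identical(a, b)                       # seed reproducibility

  set.seed(43); c3 <- make_founders(cfg)
  expect_length(c3$informative, 500)           # same count, different set
  expect_false(identical(a$informative, c3$informative))

  expect_error(make_founders(tiny_cfg(markers_per_chrom = 50,
                                      divergence = 0.01)),
               "informative")
})

test_that("map is monotone and positions within bounds", {
  set.seed(5)
  f <- make_founders(tiny_cfg())
  m <- f$map
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch]
    expect_true(all(diff(sub$pos_bp) > 0))
    expect_true(all(diff(sub$pos_cM) >= 0))
    expect_true(all(sub$pos_bp >= 1 & sub$pos_bp <= 2e6))
  }
})

test_that("simulate_gamete: crossover process and block structure", {
  set.seed(2)
  f <- make_founders(tiny_cfg(n_chrom = 1, markers_per_chrom = 50))
  o1 <- rep(1L, 50); o2 <- rep(2L, 50)

  ## zero map length -> never a crossover
  g0 <- simulate_gamete(f$p1, f$p2, o1, o2, f$map, c("1" = 0))
  expect_length(g0$crossovers[["1"]], 0)

  ## Poisson mean: 100 cM -> 1 crossover per meiosis on average
  ns <- replicate(4000, length(
    simulate_gamete(f$p1, f$p2, o1, o2, f$map, c("1" = 100))$crossovers[["1"]]))
  se <- sqrt(1 / 4000)        # Poisson(1) variance = 1
  expect_lt(abs(mean(ns) - 1), 3 * se)

  ## origin path switches only at crossovers: between adjacent markers the
  ## origin changes iff an odd number of crossovers falls between them
  for (i in 1:20) {
    g <- simulate_gamete(f$p1, f$p2, o1, o2, f$map, c("1" = 150))
    xo <- g$crossovers[["1"]]
    cm <- f$map$pos_cM
    n_between <- vapply(seq_len(49), function(k)
      sum(xo > cm[k] & xo <= cm[k + 1]), 0L)
    switched <- g$origin[-1] != g$origin[-50]
    expect_identical(switched, n_between %% 2L == 1L)
  }
})

test_that("descendants under selection carry the favoured allele", {
  cfg <- tiny_cfg(seed = 3, n_cycles = 3,
                  selected_loci = data.frame(chrom = "1", pos_bp = 6e5,
                                             weight = 1, favored = 1L))
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  d <- simulate_descendants(cfg, f)
  idx <- which.min(abs(f$map$pos_bp - 6e5) + (f$map$chrom != "1") * 1e9)
  expect_gte(mean(d$truth$origin[, idx] == 1L), 0.9)
})

test_that("neutral breeding gives ~50% parent-1 genome and a warning", {
  cfg <- tiny_cfg(seed = 4, n_descendants = 30, n_candidates = 30,
                  n_cycles = 1,
                  selected_loci = data.frame(chrom = "1", pos_bp = 5e5,
                                             weight = 0, favored = 1L))
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  expect_warning(d <- simulate_descendants(cfg, f), "neutral")
  p1 <- mean(d$truth$origin == 1L)
  ## 30 lines x 2 chromosomes: line-level origin fractions are highly
  ## correlated within a chromosome; SE on the mean is ~ sd/sqrt(60 blocks)
  expect_lt(abs(p1 - 0.5), 0.2)
})

test_that("n_cycles = 0 yields plain F1 DH lines", {
  cfg <- tiny_cfg(seed = 5, n_cycles = 0, n_descendants = 8)
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  d <- simulate_descendants(cfg, f)
  expect_equal(nrow(d$truth$origin), 8)
  ## Mendelian origin: every clean allele matches the origin parent's allele
  for (i in 1:8) {
    o <- d$truth$origin[i, ]
    expect_identical(d$truth$geno_clean[i, ],
                     ifelse(o == 1L, f$p1, f$p2))
  }
})

test_that("DH population segregates 1:1 and respects the genetic map", {
  ## chi-square 1:1 not rejected at alpha = 0.001 for >= 99% of markers;
  ## markers in LD fail in clumps, so the marginal rate is assessed pooled
  ## over several independent populations
  pass <- unlist(lapply(1:5, function(s) {
    cfg <- tiny_cfg(seed = s, dh_n = 240, divergence = 1)
    set.seed(cfg$seed)
    f <- make_founders(cfg)
    dh <- simulate_dh_population(cfg, f)
    g <- dh$truth$geno_clean
    expect_true(all(g %in% c(0L, 1L)))
    cnt <- colSums(g == 1L)
    (cnt - 120)^2 / 60 < qchisq(0.999, 1)   # (O-E)^2/E over both classes
  }))
  expect_gte(mean(pass), 0.99)

  ## recombinant fraction between adjacent markers ~ kosambi_inv(d)
  set.seed(7)
  f1 <- make_founders(tiny_cfg(n_chrom = 1, markers_per_chrom = 2,
                               chrom_len_cM = 1, divergence = 1))
  o1 <- rep(1L, 2); o2 <- rep(2L, 2)
  gam <- replicate(10000, simulate_gamete(f1$p1, f1$p2, o1, o2, f1$map,
                                          c("1" = 1))$alleles)
  d_cm <- diff(f1$map$pos_cM)
  r_hat <- mean(gam[1, ] != gam[2, ])
  r_exp <- kosambi_inv(d_cm)
  se <- sqrt(r_exp * (1 - r_exp) / 10000)
  expect_lt(abs(r_hat - r_exp), 3 * se + 1e-4)   # Haldane vs Kosambi ~ equal here

  ## unlinked markers (different chromosomes) -> r ~ 0.5
  set.seed(8)
  f2 <- make_founders(tiny_cfg(n_chrom = 2, markers_per_chrom = 2,
                               divergence = 1))
  o1 <- rep(1L, 4); o2 <- rep(2L, 4)
  gam2 <- replicate(4000, simulate_gamete(f2$p1, f2$p2, o1, o2, f2$map,
                                          c("1" = 100, "2" = 100))$alleles)
  r2 <- mean(gam2[1, ] != gam2[3, ])   # first marker of each chromosome
  expect_lt(abs(r2 - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("phenotype model: noiseless limit, effect size, heritability", {
  cfg <- tiny_cfg(seed = 9, dh_n = 240, divergence = 1)
  set.seed(cfg$seed)
  f <- make_founders(cfg)
  dh <- simulate_dh_population(cfg, f)
  qt <- data.frame(trait = "t", chrom = "1", pos_cM = 50, add = 1)

  ## h2 = 1, no environment effect -> replicates identical per line
  ph <- simulate_phenotypes(dh$truth$geno_clean, f$map, qt, h2 = 1,
                            n_env = 2, n_rep = 2, env_sd_frac = 0)
  spread <- ph[, diff(range(t)), by = line]$V1
  expect_true(all(spread < 1e-12))

  ## class means differ by ~ 2a
  idx <- which.min(abs(f$map$pos_cM - 50) + (f$map$chrom != "1") * 1e9)
  x <- 1 - 2 * dh$truth$geno_clean[, idx]
  g <- attr(ph, "genetic_values")[, 1]
  expect_equal(mean(g[x == 1]) - mean(g[x == -1]), 2, tolerance = 1e-9)

  ## realized line-mean heritability ~ h2 (mean over replicate draws)
  r2s <- replicate(30, {
    p2 <- simulate_phenotypes(dh$truth$geno_clean, f$map, qt, h2 = 0.6,
                              n_env = 3, n_rep = 2)
    lm_means <- p2[, .(y = mean(t)), by = line]
    gv <- attr(p2, "genetic_values")[lm_means$line, 1]
    summary(lm(lm_means$y ~ gv))$r.squared
  })
  expect_lt(abs(mean(r2s) - 0.6), 0.05)

  expect_error(simulate_phenotypes(dh$truth$geno_clean, f$map, qt, h2 = 1.2),
               "h2")
})

test_that("fixed seed makes the full study bit-reproducible", {
  a <- simulate_study(tiny_cfg(seed = 10))
  b <- simulate_study(tiny_cfg(seed = 10))
  expect_identical(a$panel$geno, b$panel$geno)
  expect_identical(a$dh$geno, b$dh$geno)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("genotype noise: homozygous coding, Mendelian origin at eps = 0", {
  sim <- simulate_study(tiny_cfg(seed = 11, missing_rate = 0.1))
  g <- sim$panel$geno
  expect_true(all(g %in% c(0L, 1L, NA_integer_)))
  expect_lt(abs(mean(is.na(g[-(1:2), ])) - 0.1), 0.01)
  ## eps = 0: every non-missing allele matches a parent
  p1 <- g["P1", ]; p2 <- g["P2", ]
  kid <- g[-(1:2), , drop = FALSE]
  ok <- sweep(kid, 2, p1, "==") | sweep(kid, 2, p2, "==")
  expect_true(all(ok, na.rm = TRUE))
})
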