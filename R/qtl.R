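## Inclusive composite interval mapping (ICIM) for DH populations, in its
## regression form: stepwise cofactor selection on marker codes, cofactor
## pre-adjustment of the phenotype, then a 0.5-cM interval scan regressing
## on the Kosambi-derived conditional expectation of the QTL genotype.
## Marker/QTL codes are +1 (parent-1 allele) / -1 (parent-2 allele).

#' Moisture correction of a trait value
#'
#' Rescales a measurement taken at water content `wc` to the standard water
#' content (default 13%): `value * (1 - wc) / (1 - target)`.
#'
#' @param value measured value(s).
#' @param wc water content fraction(s) in `[0, 1)`.
#' @param target standard water content (default 0.13).
#' @return adjusted value(s).
#' @export
adjust_moisture <- function(value, wc, target = 0.13) {
  if (any(wc < 0 | wc >= 1)) ps_stop("water content must be in [0, 1)")
  value * (1 - wc) / (1 - target)
}

#' Kosambi map function and its inverse
#'
#' `kosambi(r)` maps a recombination fraction `r` in `[0, 0.5)` to genetic
#' distance in cM, `d = 25 ln((1 + 2r) / (1 - 2r))`; `kosambi_inv(d)` maps
#' cM back, `r = 0.5 tanh(2 d / 100)`. Mutual inverses.
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`.
#' @param d_cM genetic distance(s) in cM, `>= 0`.
#' @return distance in cM / recombination fraction.
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) ps_stop("r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d_cM) {
  if (any(d_cM < 0)) ps_stop("d_cM must be >= 0")
  0.5 * tanh(2 * d_cM / 100)
}

#' Stepwise marker selection (forward inclusion, backward elimination)
#'
#' Forward step: the candidate with the smallest partial-F p-value enters if
#' `p < p_in`. Backward step: any included marker whose p-value exceeds
#' `p_out` leaves (worst first). Iterated to a fixed point; ties are broken
#' by marker (map) order, collinear candidates are skipped.
#'
#' @param X numeric matrix, lines x markers, codes +1/-1 (`NA` imputed to
#'   the column mean).
#' @param y phenotype vector (finite).
#' @param p_in,p_out entry/stay probability thresholds (default 0.001).
#' @param max_terms cap on the number of selected markers (default
#'   `min(ncol(X), floor(nrow(X)/5))`).
#' @return integer vector of selected marker column indices (map order).
#' @export
stepwise_select <- function(X, y, p_in = 0.001, p_out = p_in,
                            max_terms = NULL) {
  stopifnot(nrow(X) == length(y), all(is.finite(y)))
  if (!(p_in > 0 && p_in <= 1)) ps_stop("p_in must be in (0, 1]")
  n <- nrow(X); m <- ncol(X)
  max_terms <- max_terms %||% min(m, floor(n / 5))
  X <- apply(X, 2L, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  sel <- integer()
  repeat {
    changed <- FALSE
    ## forward
    if (length(sel) < max_terms) {
      Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
      r <- y - Q %*% crossprod(Q, y)
      Xp <- X - Q %*% crossprod(Q, X)
      ss <- colSums(Xp^2)
      ok <- ss > 1e-8 * n & !(seq_len(m) %in% sel)
      if (any(ok)) {
        num <- as.vector(crossprod(Xp, r))^2 / pmax(ss, 1e-300)
        rss <- sum(r^2)
        df2 <- n - length(sel) - 2L
        Fst <- num / pmax((rss - num) / df2, 1e-300)
        pv <- pf(Fst, 1, df2, lower.tail = FALSE)
        pv[!ok] <- Inf
        best <- which.min(pv)       # which.min takes first = map order on ties
        if (pv[best] < p_in) {
          sel <- c(sel, best)
          changed <- TRUE
        }
      }
    }
    ## backward
    while (length(sel) > 1L) {
      fit <- lm(y ~ X[, sel, drop = FALSE])
      pv <- summary(fit)$coefficients[-1L, 4L]
      if (length(pv) < length(sel)) break   # aliased column; keep as is
      worst <- which.max(pv)
      if (pv[worst] > p_out) {
        sel <- sel[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sort(sel)
}

## DH conditional expectation of the QTL code at distances dl, dr (cM) from
## flanking markers with codes xl, xr in {+1,-1} (NA = missing flank).
dh_expected_code <- function(xl, xr, dl, dr) {
  r1 <- kosambi_inv(dl); r2 <- kosambi_inv(dr)
  t1 <- function(same) ifelse(same, 1 - r1, r1)
  t2 <- function(same) ifelse(same, 1 - r2, r2)
  both <- !is.na(xl) & !is.na(xr)
  out <- numeric(length(xl))
  ## both flanks: P(+1|xl,xr) ~ t1(xl==+1) t2(xr==+1)
  pp <- t1(xl == 1) * t2(xr == 1)
  pm <- t1(xl == -1) * t2(xr == -1)
  out[both] <- ((pp - pm) / (pp + pm))[both]
  only_l <- !is.na(xl) & is.na(xr)
  out[only_l] <- ((1 - 2 * r1) * xl)[only_l]
  only_r <- is.na(xl) & !is.na(xr)
  out[only_r] <- ((1 - 2 * r2) * xr)[only_r]
  out     # neither flank -> 0 (population mean)
}

#' ICIM interval scan
#'
#' Scans each chromosome on a `step_cM` grid. At each position the
#' phenotype is adjusted by the fitted contributions of all cofactors
#' except those within `win_cM` of the position (so the tested interval's
#' own signal is not absorbed), and regressed on the expected QTL code
#' computed from the flanking markers via Kosambi recombination fractions
#' under DH class probabilities. `LOD = (n/2) log10(RSS0 / RSS1)`.
#'
#' @param gm a [geno_matrix()] of the DH lines (map must carry `pos_cM`).
#' @param y named phenotype vector (line means), names matching line ids.
#' @param cofactors marker column indices from [stepwise_select()].
#' @param params a [scan_params()].
#' @return `data.table(chrom, pos_cM, lod, a, pve, n)`; `a` is half the
#'   difference between expected-code genotype class means, `pve` the
#'   percent variance of the adjusted phenotype explained at the position.
#' @export
icim_scan <- function(gm, y, cofactors = integer(), params = scan_params()) {
  if (!"pos_cM" %in% names(gm$map)) ps_stop("map must carry pos_cM")
  ids <- intersect(names(y) %||% gm$lines, gm$lines)
  if (!length(ids)) ps_stop("no phenotyped line found in genotypes")
  y <- if (is.null(names(y))) setNames(y, gm$lines) else y
  y <- y[ids]
  keep <- is.finite(y)
  y <- y[keep]; ids <- ids[keep]
  G <- gm$geno[ids, , drop = FALSE]
  Xc <- 1 - 2 * G                      # +1 parent-1 allele, -1 parent-2
  n <- length(y)
  ## only properly segregating markers carry linkage information:
  ## monomorphic columns collapse the expected code to a constant, and
  ## low-MAF columns are error artifacts in a 1:1-segregating DH population
  maf <- apply(Xc, 2L, function(x) {
    p <- mean(x == 1, na.rm = TRUE); min(p, 1 - p) })
  seg <- which(!is.na(maf) & maf >= params$maf_min)
  if (!length(seg)) ps_stop("no segregating marker in the population")
  ## cofactor fit (joint), missing codes imputed to column means
  b <- NULL
  if (length(cofactors)) {
    Xco <- apply(Xc[, cofactors, drop = FALSE], 2L, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE); x })
    fit <- lm(y ~ Xco)
    b <- coef(fit)[-1L]
    b[is.na(b)] <- 0
    contrib <- sweep(Xco, 2L, b, `*`)   # n x n_cof
  }
  map <- gm$map
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- seg[map$chrom[seg] == ch]
    if (length(idx) < 2L) return(NULL)
    cm <- map$pos_cM[idx]
    grid <- seq(cm[1L], cm[length(idx)], by = params$step_cM)
    res <- data.table(chrom = ch, pos_cM = grid, lod = NA_real_,
                      a = NA_real_, pve = NA_real_, n = n)
    li <- pmax(findInterval(grid, cm), 1L)
    ri <- pmin(li + 1L, length(idx))
    at_marker <- grid >= cm[length(idx)] | li == ri
    ri[at_marker] <- li[at_marker]
    for (g in seq_along(grid)) {
      l <- idx[li[g]]; r <- idx[ri[g]]
      dl <- grid[g] - cm[li[g]]; dr <- cm[ri[g]] - grid[g]
      xs <- if (l == r) {
        xx <- Xc[, l]; xx[is.na(xx)] <- 0; xx
      } else dh_expected_code(Xc[, l], Xc[, r], dl, dr)
      ## adjust y by cofactors outside the scan window
      ys <- y
      if (length(cofactors)) {
        far <- map$chrom[cofactors] != ch |
          abs(map$pos_cM[cofactors] - grid[g]) > params$win_cM
        if (any(far))
          ys <- y - rowSums(contrib[, far, drop = FALSE])
      }
      ys <- ys - mean(ys)
      rss0 <- sum(ys^2)
      vx <- sum((xs - mean(xs))^2)
      if (vx < 1e-12 || rss0 < 1e-300) next
      bhat <- sum((xs - mean(xs)) * ys) / vx
      rss1 <- rss0 - bhat^2 * vx
      lod_val <- (n / 2) * log10(rss0 / max(rss1, 1e-300))
      pos_cls <- xs > 0; neg_cls <- xs < 0
      a_hat <- if (any(pos_cls) && any(neg_cls))
        (mean(ys[pos_cls]) - mean(ys[neg_cls])) / 2 else bhat
      set(res, g, c("lod", "a", "pve"),
          list(lod_val, a_hat, 100 * (1 - rss1 / rss0)))
    }
    res
  })
  rbindlist(out)
}

#' Scan parameters for QTL mapping
#'
#' @param step_cM scan step (default 0.5).
#' @param p_in,p_out stepwise entry/stay thresholds (default 0.001).
#' @param lod_threshold QTL calling threshold (default 2.5).
#' @param win_cM cofactor exclusion window around the scan position
#'   (default 20; calibrated so that the cofactor for a QTL under test does
#'   not re-enter the adjustment inside its own support region, see the
#'   methods vignette).
#' @param min_peak_sep_cM minimum separation between called peaks unless a
#'   1-LOD valley lies between them (default 20).
#' @param maf_min markers with minor-allele frequency below this are
#'   excluded from the scan map (default 0.05); in a DH population true
#'   markers segregate ~1:1, so low-MAF columns are genotyping-error
#'   artifacts that would corrupt flanking-marker expectations.
#' @return object of class `scan_params`.
#' @export
scan_params <- function(step_cM = 0.5, p_in = 0.001, p_out = p_in,
                        lod_threshold = 2.5, win_cM = 20,
                        min_peak_sep_cM = 20, maf_min = 0.05) {
  if (step_cM <= 0) ps_stop("step_cM must be > 0")
  if (!(p_in > 0 && p_in <= 1)) ps_stop("p_in must be in (0, 1]")
  structure(list(step_cM = step_cM, p_in = p_in, p_out = p_out,
                 lod_threshold = lod_threshold, win_cM = win_cM,
                 min_peak_sep_cM = min_peak_sep_cM, maf_min = maf_min),
            class = "scan_params")
}

#' Call QTLs from a LOD profile
#'
#' Local maxima at or above the threshold become QTLs; two peaks on one
#' chromosome are kept separate only if they are `>= min_peak_sep_cM` apart
#' or the profile drops at least 1 LOD below the smaller peak between them.
#' Each QTL carries its additive effect, PVE and 1-LOD support interval.
#'
#' @param profile output of [icim_scan()].
#' @param params a [scan_params()].
#' @param trait,env labels stored on the QTLs.
#' @return `data.table(trait, env, chrom, peak_cM, lod, a, pve, ci_lo_cM,
#'   ci_hi_cM)`.
#' @export
call_qtls <- function(profile, params = scan_params(),
                      trait = NA_character_, env = NA_character_) {
  thr <- params$lod_threshold
  out <- lapply(unique(profile$chrom), function(ch) {
    pr <- profile[chrom == ch][!is.na(lod)]
    if (!nrow(pr)) return(NULL)
    lod_v <- pr$lod; cm <- pr$pos_cM
    cand <- order(lod_v, decreasing = TRUE)
    cand <- cand[lod_v[cand] >= thr]
    peaks <- integer()
    for (i in cand) {
      ok <- TRUE
      for (p in peaks) {
        if (abs(cm[i] - cm[p]) >= params$min_peak_sep_cM) next
        rng <- sort(c(i, p))
        valley <- min(lod_v[rng[1]:rng[2]])
        if (valley > min(lod_v[i], lod_v[p]) - 1) { ok <- FALSE; break }
      }
      if (ok) peaks <- c(peaks, i)
    }
    if (!length(peaks)) return(NULL)
    rbindlist(lapply(peaks, function(p) {
      lo <- p; while (lo > 1L && lod_v[lo - 1L] > lod_v[p] - 1) lo <- lo - 1L
      hi <- p; while (hi < length(lod_v) && lod_v[hi + 1L] > lod_v[p] - 1)
        hi <- hi + 1L
      data.table(trait = trait, env = env, chrom = ch, peak_cM = cm[p],
                 lod = lod_v[p], a = pr$a[p], pve = pr$pve[p],
                 ci_lo_cM = cm[lo], ci_hi_cM = cm[hi])
    }))
  })
  res <- rbindlist(out)
  if (!nrow(res))
    res <- data.table(trait = character(), env = character(),
                      chrom = character(), peak_cM = numeric(),
                      lod = numeric(), a = numeric(), pve = numeric(),
                      ci_lo_cM = numeric(), ci_hi_cM = numeric())
  res[order(chrom, peak_cM)]
}

#' Full ICIM QTL scan for one trait in one environment
#'
#' Replicates are averaged to line means, cofactors selected by
#' [stepwise_select()], the genome scanned by [icim_scan()] and QTLs called
#' by [call_qtls()].
#'
#' @param gm DH [geno_matrix()].
#' @param pheno phenotype table (`line`, `env`, `rep`, trait columns).
#' @param trait trait column name.
#' @param env environment id (`NULL` = pool all environments).
#' @param params a [scan_params()].
#' @return list `qtls`, `profile`, `cofactors`, `line_means`.
#' @export
qtl_scan <- function(gm, pheno, trait, env = NULL, params = scan_params()) {
  ph <- as.data.table(pheno)
  if (!trait %in% names(ph)) ps_stop("trait %s not in phenotype table", trait)
  if (!is.null(env)) {
    env_id <- env
    ph <- ph[ph[["env"]] == env_id]
    if (!nrow(ph)) ps_stop("no phenotype rows for environment %s", env_id)
  }
  lm_dt <- ph[, .(y = mean(.SD[[1]], na.rm = TRUE)), by = line,
              .SDcols = trait]
  y <- setNames(lm_dt$y, lm_dt$line)
  y <- y[names(y) %in% gm$lines]
  Xc <- 1 - 2 * gm$geno[names(y), , drop = FALSE]
  maf <- apply(Xc, 2L, function(x) {
    p <- mean(x == 1, na.rm = TRUE); min(p, 1 - p) })
  keep <- which(!is.na(maf) & maf >= params$maf_min)
  cof <- keep[stepwise_select(Xc[, keep, drop = FALSE], as.vector(y),
                              p_in = params$p_in, p_out = params$p_out)]
  prof <- icim_scan(gm, y, cofactors = cof, params = params)
  qtls <- call_qtls(prof, params, trait = trait,
                    env = env %||% "pooled")
  list(qtls = qtls, profile = prof, cofactors = cof, line_means = y)
}

#' Group QTLs stable across environments
#'
#' QTLs of the same trait on the same chromosome whose 1-LOD support
#' intervals overlap in at least two distinct environments form a stable
#' group.
#'
#' @param qtls combined QTL table across environments.
#' @return `data.table` of stable groups: trait, chrom, cM span, member
#'   environments and per-env LODs, `n_env`.
#' @export
stable_qtls <- function(qtls) {
  qtls <- as.data.table(qtls)
  if (!nrow(qtls)) return(data.table())
  out <- list()
  for (key in unique(paste(qtls$trait, qtls$chrom))) {
    q <- qtls[paste(trait, chrom) == key][order(ci_lo_cM)]
    if (nrow(q) < 2L) next
    ## chain QTLs whose support intervals overlap (single linkage)
    grp <- cumsum(c(TRUE, q$ci_lo_cM[-1L] > cummax(head(q$ci_hi_cM, -1L))))
    for (g in unique(grp)) {
      qq <- q[grp == g]
      if (length(unique(qq$env)) < 2L) next
      out[[length(out) + 1L]] <- data.table(
        trait = qq$trait[1L], chrom = qq$chrom[1L],
        lo_cM = min(qq$ci_lo_cM), hi_cM = max(qq$ci_hi_cM),
        peak_cM = qq$peak_cM[which.max(qq$lod)],
        n_env = length(unique(qq$env)),
        envs = paste(qq$env, collapse = ","),
        lods = paste(sprintf("%.2f", qq$lod), collapse = ","))
    }
  }
  if (!length(out)) return(data.table())
  rbindlist(out)
}

#' Chain physically close QTLs into clusters
#'
#' Single-linkage chaining of QTL physical (bp) intervals with
#' inter-interval gap at most `cluster_gap`; chains with at least
#' `min_size` members are reported.
#'
#' @param qtls_bp QTL table with `chrom`, `start`, `end` (bp) columns (see
#'   [cm_to_bp()] for converting support intervals).
#' @param cluster_gap maximum gap between chained intervals (default 2e6).
#' @param min_size minimum chain size (default 4).
#' @return `data.table(cluster, chrom, start, end, n_qtls, traits)`.
#' @export
qtl_clusters <- function(qtls_bp, cluster_gap = 2e6, min_size = 4L) {
  q <- as.data.table(qtls_bp)
  if (!nrow(q)) return(data.table())
  q <- q[order(chrom, start)]
  q[, grp := cumsum(c(TRUE, start[-1L] > cummax(head(end, -1L)) + cluster_gap)),
    by = chrom]
  cl <- q[, .(start = min(start), end = max(end), n_qtls = .N,
              traits = paste(sort(unique(trait)), collapse = ",")),
          by = .(chrom, grp)]
  cl <- cl[n_qtls >= min_size][, grp := NULL]
  if (!nrow(cl)) return(cl)
  cl[, cluster := sprintf("QTL-Cluster %d", .I)]
  setcolorder(cl, c("cluster", "chrom", "start", "end", "n_qtls", "traits"))
  cl[]
}

#' Per-line cumulative additive effect (CAE)
#'
#' `CAE_i = sum_q a_q x_q(i)` with `x = +1/-1` the parental code of the
#' line's allele at the marker nearest each QTL peak; missing genotypes
#' skip the term (skipped count reported).
#'
#' @param gm DH or panel [geno_matrix()].
#' @param qtls QTL table with `chrom`, `peak_cM`, `a`.
#' @return `data.table(line, cae, n_qtls_used, n_missing)`.
#' @export
cae <- function(gm, qtls) {
  qtls <- as.data.table(qtls)
  if (!nrow(qtls))
    return(data.table(line = gm$lines, cae = 0, n_qtls_used = 0L,
                      n_missing = 0L))
  idx <- nearest_marker(gm$map, qtls$chrom, qtls$peak_cM, unit = "cM")
  X <- 1 - 2 * gm$geno[, idx, drop = FALSE]
  eff <- sweep(X, 2L, qtls$a, `*`)
  data.table(line = gm$lines,
             cae = rowSums(eff, na.rm = TRUE),
             n_qtls_used = rowSums(!is.na(eff)),
             n_missing = rowSums(is.na(eff)))
}
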