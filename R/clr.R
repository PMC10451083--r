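## Composite likelihood ratio sweep scan (SweepFinder/SweeD style, unfolded
## SFS). A hard sweep at x0 lets each of the n sampled lineages escape via
## recombination with probability p_e(d) = 1 - exp(-alpha d); the non-escaped
## lineages coalesce into the swept haplotype, which together with the k
## escapees amounts to k+1 draws *without replacement* from the background
## sample configuration (i derived among n). Mixing over the genome-wide
## background SFS phi and conditioning on polymorphism gives the post-sweep
## site distribution; the CLR compares its maximum composite likelihood over
## an alpha grid with the background likelihood. The hypergeometric draw
## (rather than a binomial approximation) makes the background model exactly
## nested: as alpha -> large, p_e -> 1, all lineages escape and the
## distribution reduces to phi, so CLR -> 0.

#' Parameters for the CLR sweep scan
#'
#' @param alpha_grid sweep-intensity grid (per-bp escape rate scale),
#'   default 20 log-spaced points in `[1e-8, 1e-2]`.
#' @param radius_bp only sites within this distance of a proposed sweep
#'   position contribute to its composite likelihood; default `Inf` (all
#'   sites of the chromosome, as in SweepFinder/SweeD), which lets flanking
#'   sites localize a sweep whose core is monomorphic.
#' @param grid_bp spacing of proposed sweep positions x0 (default 1e4, one
#'   per 10-kb window centre).
#' @param d_bins number of log-spaced distance bins used to cache the
#'   post-sweep site distributions (default 64).
#' @return object of class `clr_params`.
#' @export
clr_params <- function(alpha_grid = 10^seq(-8, -2, length.out = 20),
                       radius_bp = Inf, grid_bp = 1e4, d_bins = 64L) {
  if (any(alpha_grid <= 0)) ps_stop("alpha_grid must be positive")
  structure(list(alpha_grid = alpha_grid, radius_bp = radius_bp,
                 grid_bp = grid_bp, d_bins = as.integer(d_bins)),
            class = "clr_params")
}

#' Post-sweep site distribution
#'
#' Probability of observing derived count `j` in `1..n-1` at a site a
#' distance `d` from a sweep of intensity `alpha`, given background SFS
#' `phi`. With `k ~ Bin(n, p_e)` escaped lineages, the swept haplotype and
#' the `k` escapees are `k + 1` exchangeable draws without replacement from
#' the background configuration (`i` derived among `n`); the swept draw is
#' copied to all `n - k` non-escaped lineages:
#' `P(j | alpha, d) = sum_i phi(i) [ Bin(n; n, p_e) 1{j = i} + sum_{k<n}
#' Bin(k; n, p_e) ( (i/n) Hyp(j - (n-k); i-1, n-i, k) +
#' ((n-i)/n) Hyp(j; i, n-i-1, k) ) ]`,
#' renormalized over `j = 1..n-1` (conditioning on polymorphism).
#' `p_e` is floored at 1e-8 and renormalized classes at 1e-12 to keep logs
#' finite in the fully swept limit.
#'
#' @param phi background SFS from [background_sfs()] (attribute `n`).
#' @param alpha sweep intensity (per bp).
#' @param d distance from the sweep site (bp).
#' @return numeric vector over `j = 1..n-1`, summing to 1.
#' @export
sweep_site_dist <- function(phi, alpha, d) {
  n <- attr(phi, "n")
  G <- sweep_mix_tensor(phi)
  site_dist_from_tensor(G, n, alpha, d)
}

## (n+1) x (n-1) matrix M with M[k+1, j] = sum_i phi(i) g(j | i, k): the
## alpha/d-independent part of the model (k = number of escaped lineages)
sweep_mix_tensor <- function(phi) {
  n <- attr(phi, "n")
  k <- 0:(n - 1L)
  jj <- seq_len(n - 1L)
  M <- matrix(0, n + 1L, n - 1L)
  for (i in seq_len(n - 1L)) {
    if (phi[i] == 0) next
    A <- outer(k, jj, function(kk, j) dhyper(j - (n - kk), i - 1L, n - i, kk))
    B <- outer(k, jj, function(kk, j) dhyper(j, i, n - i - 1L, kk))
    M[1:n, ] <- M[1:n, ] + phi[i] * ((i / n) * A + ((n - i) / n) * B)
    M[n + 1L, i] <- M[n + 1L, i] + phi[i]   # all escaped: j = i exactly
  }
  M
}

site_dist_from_tensor <- function(G, n, alpha, d) {
  pe <- max(1 - exp(-alpha * d), 1e-8)
  wk <- dbinom(0:n, n, pe)
  P <- as.vector(wk %*% G)
  s <- sum(P)
  if (s <= 0) P <- rep(1 / (n - 1L), n - 1L) else P <- P / s
  P <- pmax(P, 1e-12)
  P / sum(P)
}

## cache of log P(j | alpha, d-bin) : list over alpha of matrices d_bin x j
clr_cache <- function(phi, params, max_d) {
  edges <- c(0, 10^seq(log10(50), log10(max_d),
                       length.out = params$d_bins - 1L))
  mids <- c(edges[2] / 2, (head(edges[-1], -1) + edges[-(1:2)]) / 2, max_d)
  n <- attr(phi, "n")
  G <- sweep_mix_tensor(phi)
  tabs <- lapply(params$alpha_grid, function(a) {
    t(vapply(mids, function(d) log(site_dist_from_tensor(G, n, a, d)),
             numeric(length(phi))))
  })
  list(edges = edges, tabs = tabs)
}

#' Composite likelihood ratio scan for selective sweeps
#'
#' Evaluates `CLR(x0) = 2 [ max_alpha sum_s log P(j_s | alpha, d_s) -
#' sum_s log phi(j_s) ]`, floored at 0, on a grid of proposed sweep
#' positions; only complete-data segregating sites within `radius_bp` of x0
#' contribute. Grid points with no nearby site score 0.
#'
#' @param gm a [geno_matrix()].
#' @param phi background SFS from [background_sfs()]; computed if `NULL`.
#' @param params a [clr_params()].
#' @param bounds optional chromosome bounds (`chrom`, `len_bp`).
#' @return `data.table(chrom, pos, clr, alpha_hat, n_sites)`.
#' @export
clr_scan <- function(gm, phi = NULL, params = clr_params(), bounds = NULL) {
  if (is.null(phi)) phi <- background_sfs(gm)
  n <- attr(phi, "n")
  sc <- site_counts(gm)[n == nrow(gm$geno)][j > 0L & j < n]
  if (is.null(bounds))
    bounds <- gm$map[, .(len_bp = max(pos_bp)), by = chrom]
  bounds <- as.data.table(bounds)
  max_d <- min(params$radius_bp, max(bounds$len_bp))
  cache <- clr_cache(phi, params, max_d)
  lphi <- log(pmax(phi, 1e-12))
  out <- lapply(seq_len(nrow(bounds)), function(ci) {
    ch <- bounds$chrom[ci]
    x0 <- seq(params$grid_bp / 2, bounds$len_bp[ci], by = params$grid_bp)
    s <- sc[chrom == ch]
    res <- data.table(chrom = ch, pos = x0, clr = 0, alpha_hat = NA_real_,
                      n_sites = 0L)
    if (!nrow(s)) return(res)
    finite_r <- is.finite(params$radius_bp)
    pos_s <- s$pos_bp; j_s <- s$j
    for (gi in seq_along(x0)) {
      if (finite_r) {
        inwin <- abs(pos_s - x0[gi]) <= params$radius_bp
        if (!any(inwin)) next
        d <- abs(pos_s[inwin] - x0[gi]); jj <- j_s[inwin]
      } else {
        d <- abs(pos_s - x0[gi]); jj <- j_s
      }
      db <- pmin(findInterval(d, cache$edges), length(cache$edges))
      l0 <- sum(lphi[jj])
      la <- vapply(cache$tabs, function(tab)
        sum(tab[cbind(db, jj)]), 0)
      best <- which.max(la)
      set(res, gi, c("clr", "alpha_hat", "n_sites"),
          list(max(0, 2 * (la[best] - l0)), params$alpha_grid[best],
               length(jj)))
    }
    res
  })
  rbindlist(out)
}
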