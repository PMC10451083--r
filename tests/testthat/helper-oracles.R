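## Independent brute-force oracles and fixture builders used across tests.
## These deliberately avoid the package's own code paths.

suppressPackageStartupMessages(library(data.table))

## build a geno_matrix from a lines x markers matrix with an evenly spaced map
make_gm <- function(m, chrom = "1", spacing_bp = 1000, cm_per_marker = 1) {
  M <- ncol(m)
  map <- data.table(chrom = chrom,
                    pos_bp = seq_len(M) * spacing_bp,
                    pos_cM = (seq_len(M) - 1) * cm_per_marker)
  geno_matrix(m, map)
}

## pi by explicit enumeration of all haplotype pairs, reconstructing the
## site columns from (j, n) counts
oracle_pi <- function(sfs) {
  tot <- 0
  for (r in seq_len(nrow(sfs))) {
    n <- sfs$n[r]; j <- sfs$j[r]
    col <- c(rep(1L, j), rep(0L, n - j))
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      diffs <- diffs + (col[a] != col[b]); pairs <- pairs + 1
    }
    tot <- tot + diffs / pairs * 1   # mean pairwise difference at this site
  }
  tot
}

oracle_theta_w <- function(S, n) S / sum(1 / seq_len(n - 1))

## independently coded Tajima's D (different algebraic arrangement)
oracle_tajima <- function(sfs) {
  S <- nrow(sfs)
  if (S == 0) return(NA_real_)
  n <- max(sfs$n)
  pi <- oracle_pi(sfs)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  th <- S / a1
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  varD <- (c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1)
  if (varD <= 0) return(NA_real_)
  (pi - th) / sqrt(varD)
}

## total overlap length of two interval sets by per-bp boolean masks
oracle_overlap_len <- function(a, b, len) {
  ma <- logical(len); mb <- logical(len)
  for (r in seq_len(nrow(a))) ma[(a$start[r] + 1):a$end[r]] <- TRUE
  for (r in seq_len(nrow(b))) mb[(b$start[r] + 1):b$end[r]] <- TRUE
  sum(ma & mb)
}

oracle_union_len <- function(a, len) {
  ma <- logical(len)
  for (r in seq_len(nrow(a))) ma[(a$start[r] + 1):a$end[r]] <- TRUE
  sum(ma)
}

## minimum number of parent switches achievable by assigning each gap fully
## to one flanking parent (exhaustive over gap assignments)
oracle_min_recomb <- function(parents) {
  ## parents: vector of segment parents in order; gaps between them can at
  ## best merge equal neighbours; count switches in the sequence
  if (length(parents) <= 1) return(0L)
  sum(parents[-1] != parents[-length(parents)])
}

## brute-force single-linkage chaining of intervals with a gap threshold
oracle_chain <- function(dt, gap) {
  dt <- dt[order(chrom, start)]
  out <- integer(nrow(dt)); out[1] <- 1L
  for (i in seq_len(nrow(dt))[-1]) {
    prev <- dt[seq_len(i - 1)]
    same <- prev$chrom == dt$chrom[i] &
      dt$start[i] <= max(prev$end[prev$chrom == dt$chrom[i]], -Inf) + gap
    out[i] <- if (isTRUE(any(same))) out[max(which(same))] else max(out) + 1L
  }
  out
}

## deterministic small panel simulation used by several tests
tiny_cfg <- function(seed = 1, ...) {
  args <- list(n_chrom = 2, markers_per_chrom = 200, chrom_len_bp = 2e6,
               chrom_len_cM = 100, n_descendants = 10, n_candidates = 30,
               n_cycles = 2, dh_n = 60, genotype_error = 0,
               missing_rate = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
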