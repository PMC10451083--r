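## Forward simulator: two inbred founders, recombinant descendants bred under
## truncation selection, a DH mapping population and its phenotypes.
## Crossovers follow a Poisson (no-interference) process on the cM scale;
## genetic mapping downstream deliberately uses Kosambi instead -- map
## functions are analysis conventions, not generative truth.

#' Create the two founder haplotypes and the marker map
#'
#' Parent 1 carries the reference allele (0) everywhere; parent 2 carries the
#' alternate allele (1) at exactly `round(divergence * M)` markers drawn
#' uniformly (the informative markers). Marker bp positions are uniform per
#' chromosome; cM positions are proportional to bp.
#'
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param config a [sim_config()].
#' @return list with `p1`, `p2` (integer allele vectors), `map`
#'   (`data.table`: chrom, pos_bp, pos_cM, marker_id, ref, alt) and
#'   `informative` (marker indices where the parents differ).
#' @export
make_founders <- function(config) {
  cfg <- validate_sim_config(config)
  if (cfg$divergence * cfg$markers_per_chrom < 1)
    ps_stop("divergence x markers_per_chrom < 1: no informative markers per chromosome")
  maps <- lapply(seq_len(cfg$n_chrom), function(ch) {
    pos <- sort(sample.int(cfg$chrom_len_bp, cfg$markers_per_chrom))
    data.table(chrom = as.character(ch), pos_bp = pos,
               pos_cM = pos / cfg$chrom_len_bp * cfg$chrom_len_cM)
  })
  map <- rbindlist(maps)
  M <- nrow(map)
  map[, marker_id := sprintf("m%s_%07d", chrom, pos_bp)]
  nucs <- c("A", "C", "G", "T")
  map[, ref := sample(nucs, M, replace = TRUE)]
  map[, alt := vapply(ref, function(r) sample(setdiff(nucs, r), 1L), "")]
  n_inf <- round(cfg$divergence * M)
  informative <- sort(sample.int(M, n_inf))
  p2 <- integer(M)
  p2[informative] <- 1L
  list(p1 = integer(M), p2 = p2, map = map, informative = informative)
}

#' Simulate one gamete of an F1 between two inbred genomes
#'
#' Crossover counts per chromosome are Poisson(length_cM / 100) with uniform
#' cM positions and no interference; the transmitted haplotype switches
#' source at every crossover, starting from a random phase.
#'
#' @param h1,h2 allele vectors of the two transmitting genomes.
#' @param o1,o2 parent-of-origin vectors of the two genomes (founder F1:
#'   all 1 and all 2).
#' @param map marker map (`chrom`, `pos_cM`, `pos_bp`).
#' @param len_cM named vector of chromosome genetic lengths.
#' @return list `alleles`, `origin`, `crossovers` (per-chromosome cM
#'   positions of the crossovers of this meiosis).
#' @export
simulate_gamete <- function(h1, h2, o1, o2, map, len_cM) {
  M <- nrow(map)
  stopifnot(length(h1) == M, length(h2) == M)
  alleles <- integer(M); origin <- integer(M)
  xo_out <- list()
  for (ch in names(len_cM)) {
    idx <- which(map$chrom == ch)
    L <- len_cM[[ch]]
    nxo <- if (L > 0) rpois(1L, L / 100) else 0L
    xo <- sort(runif(nxo, 0, L))
    phase <- sample.int(2L, 1L)
    src <- 1L + (phase - 1L + findInterval(map$pos_cM[idx], xo)) %% 2L
    one <- src == 1L
    alleles[idx] <- ifelse(one, h1[idx], h2[idx])
    origin[idx]  <- ifelse(one, o1[idx], o2[idx])
    xo_out[[ch]] <- xo
  }
  list(alleles = alleles, origin = origin, crossovers = xo_out)
}

## nearest marker index (global) to each locus, matching on chromosome
nearest_marker <- function(map, chrom, pos, unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  col <- if (unit == "bp") "pos_bp" else "pos_cM"
  vapply(seq_along(chrom), function(i) {
    idx <- which(map$chrom == as.character(chrom[i]))
    if (!length(idx)) ps_stop("no markers on chromosome %s", chrom[i])
    idx[which.min(abs(map[[col]][idx] - pos[i]))]
  }, 1L)
}

## per-column variance ignoring NA (no matrixStats dependency)
matrixStats_colVar <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  colMeans(sweep(m, 2L, mu)^2, na.rm = TRUE)
}

## symmetric allele flip with prob error, then missingness
apply_genotype_noise <- function(geno, error, missing_rate) {
  if (error > 0) {
    flip <- matrix(runif(length(geno)) < error, nrow(geno))
    geno[flip] <- 1L - geno[flip]
  }
  if (missing_rate > 0)
    geno[matrix(runif(length(geno)) < missing_rate, nrow(geno))] <- NA_integer_
  geno
}

#' Simulate the descendant inbred-line panel under truncation selection
#'
#' Each cycle produces `n_candidates` doubled-gamete (DH-style) lines and
#' keeps the `n_descendants` with the highest weighted score at the selected
#' loci (score = sum of weights of loci where the line's parent of origin is
#' the favoured parent). Cycle 1 draws gametes from the founder F1; later
#' cycles draw from crosses between two selected lines of the previous
#' cycle. With `n_cycles = 0` the lines are plain DH lines of the F1.
#'
#' @param config a [sim_config()].
#' @param founders output of [make_founders()]; created if `NULL`.
#' @return list with `panel` (a [geno_matrix()] of parents P1, P2 and the
#'   descendant lines X01..; genotype error/missingness applied to
#'   descendants only) and `truth` (clean origin matrix, per-line final
#'   meiosis crossovers, origin-path breakpoints, selected loci, informative
#'   markers).
#' @export
simulate_descendants <- function(config, founders = NULL) {
  cfg <- validate_sim_config(config)
  if (is.null(founders)) founders <- make_founders(cfg)
  map <- founders$map
  len_cM <- setNames(rep(cfg$chrom_len_cM, cfg$n_chrom),
                     as.character(seq_len(cfg$n_chrom)))
  loci <- cfg$selected_loci
  if (cfg$n_cycles > 0L && nrow(loci) == 0L)
    ps_stop("selected_loci must be non-empty when n_cycles > 0")
  if (cfg$n_cycles > 0L && nrow(loci) && all(loci$weight == 0))
    ps_warn("all selection weights are zero; selection is neutral")
  loci_idx <- if (nrow(loci)) nearest_marker(map, loci$chrom, loci$pos_bp) else integer()

  new_line <- function(hA, hB, oA, oB) {
    g <- simulate_gamete(hA, hB, oA, oB, map, len_cM)
    g$score <- if (length(loci_idx))
      sum(loci$weight * (g$origin[loci_idx] == loci$favored)) else 0
    g
  }
  f1 <- list(h = list(founders$p1, founders$p2),
             o = list(rep(1L, nrow(map)), rep(2L, nrow(map))))
  pool <- NULL
  n_cyc <- max(cfg$n_cycles, 1L)
  for (cyc in seq_len(n_cyc)) {
    n_cand <- if (cfg$n_cycles == 0L) cfg$n_descendants else cfg$n_candidates
    cand <- vector("list", n_cand)
    for (i in seq_len(n_cand)) {
      if (is.null(pool)) {
        cand[[i]] <- new_line(f1$h[[1]], f1$h[[2]], f1$o[[1]], f1$o[[2]])
      } else {
        pr <- sample.int(length(pool), 2L, replace = length(pool) == 1L)
        a <- pool[[pr[1]]]; b <- pool[[pr[2]]]
        cand[[i]] <- new_line(a$alleles, b$alleles, a$origin, b$origin)
      }
    }
    if (cfg$n_cycles == 0L) { pool <- cand; break }
    keep <- head(order(vapply(cand, `[[`, 0, "score"), decreasing = TRUE),
                 cfg$n_descendants)
    pool <- cand[sort(keep)]
  }
  n <- length(pool)
  geno <- do.call(rbind, lapply(pool, `[[`, "alleles"))
  origin <- do.call(rbind, lapply(pool, `[[`, "origin"))
  ids <- sprintf("X%02d", seq_len(n))
  rownames(geno) <- ids; rownames(origin) <- ids
  noisy <- apply_genotype_noise(geno, cfg$genotype_error, cfg$missing_rate)
  panel_geno <- rbind(P1 = founders$p1, P2 = founders$p2, noisy)
  truth <- list(
    origin = origin,
    crossovers = setNames(lapply(pool, `[[`, "crossovers"), ids),
    breakpoints = origin_breakpoints(origin, map),
    selected_loci = loci,
    informative = founders$informative,
    geno_clean = geno
  )
  list(panel = geno_matrix(panel_geno, map), truth = truth)
}

## bp breakpoints of each line's parent-of-origin path (midpoint between the
## flanking informative-for-origin markers where the path switches)
origin_breakpoints <- function(origin, map) {
  lapply(seq_len(nrow(origin)), function(i) {
    out <- lapply(unique(map$chrom), function(ch) {
      idx <- which(map$chrom == ch)
      o <- origin[i, idx]
      sw <- which(diff(o) != 0)
      if (!length(sw)) return(NULL)
      data.table(chrom = ch,
                 left_bp = map$pos_bp[idx][sw],
                 right_bp = map$pos_bp[idx][sw + 1L],
                 bp = (map$pos_bp[idx][sw] + map$pos_bp[idx][sw + 1L]) / 2)
    })
    rbindlist(out)
  })
}

#' Simulate a DH mapping population from the founder F1
#'
#' Each line is a single gamete of the founder F1, doubled; at every
#' informative marker the two genotype classes therefore segregate ~1:1.
#'
#' @inheritParams simulate_descendants
#' @return list `dh` (a [geno_matrix()] of `dh_n` lines, noise applied) and
#'   `truth` (clean genotypes and origins, crossovers per line).
#' @export
simulate_dh_population <- function(config, founders = NULL) {
  cfg <- validate_sim_config(config)
  if (cfg$dh_n < 2L) ps_stop("dh_n must be >= 2")
  if (is.null(founders)) founders <- make_founders(cfg)
  map <- founders$map
  len_cM <- setNames(rep(cfg$chrom_len_cM, cfg$n_chrom),
                     as.character(seq_len(cfg$n_chrom)))
  o1 <- rep(1L, nrow(map)); o2 <- rep(2L, nrow(map))
  lines <- lapply(seq_len(cfg$dh_n), function(i)
    simulate_gamete(founders$p1, founders$p2, o1, o2, map, len_cM))
  geno <- do.call(rbind, lapply(lines, `[[`, "alleles"))
  ids <- sprintf("DH%03d", seq_len(cfg$dh_n))
  rownames(geno) <- ids
  noisy <- apply_genotype_noise(geno, cfg$genotype_error, cfg$missing_rate)
  truth <- list(geno_clean = geno,
                origin = do.call(rbind, lapply(lines, `[[`, "origin")),
                crossovers = setNames(lapply(lines, `[[`, "crossovers"), ids))
  rownames(truth$origin) <- ids
  list(dh = geno_matrix(noisy, map), truth = truth)
}

#' Simulate multi-environment phenotypes for a DH population
#'
#' Line genetic value is the sum of signed additive QTL effects,
#' `g_i = sum_q a_q x_q(i)` with `x = +1` for the parent-1 allele and `-1`
#' for the parent-2 allele at the marker nearest each QTL. Observations are
#' `y_ijk = g_i + E_j + e_ijk` with a common environment shift `E_j` and
#' residual `e` whose variance is set so the realized line-mean heritability
#' (over `n_env * n_rep` observations) is approximately `h2`.
#'
#' @param geno clean genotype matrix (lines x markers, 0/1), e.g.
#'   `truth$geno_clean` from [simulate_dh_population()].
#' @param map marker map with `pos_cM`.
#' @param qtls `data.frame(trait, chrom, pos_cM, add)`.
#' @param h2 line-mean heritability, scalar or named per trait.
#' @param n_env,n_rep environments / replicates.
#' @param env_sd_frac sd of the environment shift as a fraction of the
#'   genetic sd (default 0.5).
#' @return `data.table(line, env, rep, <one column per trait>)`, with the
#'   matrix of true genetic values attached as attribute `genetic_values`.
#' @export
simulate_phenotypes <- function(geno, map, qtls, h2 = 0.7, n_env = 3L,
                                n_rep = 2L, env_sd_frac = 0.5) {
  if (any(h2 <= 0 | h2 > 1)) ps_stop("h2 must be in (0, 1]")
  qtls <- as.data.table(qtls)
  map <- as.data.table(map)
  traits <- unique(qtls$trait)
  n <- nrow(geno)
  lines <- rownames(geno) %||% sprintf("L%03d", seq_len(n))
  out <- CJ(line = lines, env = sprintf("E%d", seq_len(n_env)),
            rep = seq_len(n_rep), sorted = FALSE)
  setkey(out, NULL)
  gmat <- matrix(0, n, length(traits), dimnames = list(lines, traits))
  ## QTL effects attach to the nearest *segregating* marker: a marker fixed
  ## in the population (parents identical there) carries no signal
  seg <- which(matrixStats_colVar(geno) > 0)
  if (!length(seg)) ps_stop("no segregating marker to place QTLs on")
  seg_map <- map[seg]
  for (tr in traits) {
    qt <- qtls[trait == tr]
    idx <- seg[nearest_marker(seg_map, qt$chrom, qt$pos_cM, unit = "cM")]
    x <- 1 - 2 * geno[, idx, drop = FALSE]          # allele 0 -> +1
    g <- as.vector(x %*% qt$add)
    gmat[, tr] <- g
    h2t <- if (length(h2) > 1L) h2[[tr]] else h2
    vg <- var(g)
    if (vg == 0) {
      sde <- 1; sdE <- 0
      ps_warn("trait %s has zero genetic variance; unit residual sd used", tr)
    } else {
      sde <- sqrt(vg * (1 / h2t - 1) * n_env * n_rep)
      sdE <- env_sd_frac * sqrt(vg)
    }
    E <- rnorm(n_env, 0, sdE)
    names(E) <- sprintf("E%d", seq_len(n_env))
    y <- g[match(out$line, lines)] + E[out$env] +
      if (sde > 0) rnorm(nrow(out), 0, sde) else 0
    out[, (tr) := y]
  }
  setattr(out, "genetic_values", gmat)
  out[]
}

#' Simulate a complete breeding study
#'
#' One call generating everything the downstream pipeline consumes: founder
#' haplotypes and map, the descendant panel bred under selection, the DH
#' mapping population with phenotypes, and a small synthetic gene
#' annotation. Seeded by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list `config`, `founders`, `panel`, `panel_truth`, `dh`,
#'   `dh_truth`, `phenotypes`, `genes`.
#' @export
simulate_study <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  founders <- make_founders(cfg)
  desc <- simulate_descendants(cfg, founders)
  dh <- simulate_dh_population(cfg, founders)
  pheno <- simulate_phenotypes(dh$truth$geno_clean, founders$map, cfg$qtls,
                               h2 = cfg$h2, n_env = cfg$n_env,
                               n_rep = cfg$n_rep)
  genes <- make_gene_annotation(chrom_bounds(cfg))
  list(config = cfg, founders = founders,
       panel = desc$panel, panel_truth = desc$truth,
       dh = dh$dh, dh_truth = dh$truth,
       phenotypes = pheno, genes = genes)
}

#' Generate a synthetic gene annotation
#'
#' Random non-overlapping gene intervals, for exercising gene-by-region
#' intersection; purely synthetic, carries no biological content.
#'
#' @param bounds `data.table(chrom, len_bp)` as from [chrom_bounds()].
#' @param genes_per_mb mean gene density (default 4).
#' @param mean_len_bp mean gene length (default 4000).
#' @return `data.table(chrom, start, end, gene_id)`, 0-based half-open.
#' @export
make_gene_annotation <- function(bounds, genes_per_mb = 4, mean_len_bp = 4000) {
  bounds <- as.data.table(bounds)
  out <- lapply(seq_len(nrow(bounds)), function(i) {
    len <- bounds$len_bp[i]
    ng <- max(1L, rpois(1L, genes_per_mb * len / 1e6))
    start <- sort(sample.int(len - 2L * mean_len_bp, ng))
    glen <- pmax(200L, rpois(ng, mean_len_bp))
    end <- pmin(start + glen, len)
    dt <- data.table(chrom = bounds$chrom[i], start = start, end = end)
    dt <- dt[c(TRUE, start[-1] >= head(end, -1))]   # drop overlaps
    dt
  })
  out <- rbindlist(out)
  out[, gene_id := sprintf("gene_%s_%05d", chrom, seq_len(.N)), by = chrom]
  out[]
}
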