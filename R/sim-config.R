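#' Simulation configuration for a two-parent breeding study
#'
#' Describes the synthetic world the simulator generates: a pair of fully
#' inbred parents, a panel of descendant inbred lines bred from their cross
#' under truncation selection, and a doubled-haploid (DH) mapping population
#' phenotyped for additive traits in several environments.
#'
#' Defaults emulate the structure of an elite biparental maize breeding
#' program at desk scale: 15 descendant lines, a 240-line DH population
#' measured in 3 environments with 2 replicates, parents polymorphic at 60%
#' of markers, and line-mean trait heritability 0.7.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers simulated per chromosome.
#' @param chrom_len_bp physical chromosome length (bp).
#' @param chrom_len_cM genetic chromosome length (centimorgans).
#' @param divergence fraction of markers at which the two parents carry
#'   different alleles (informative markers); in (0, 1].
#' @param n_descendants descendant inbred lines kept per breeding cycle.
#' @param n_candidates candidate lines generated per cycle before selection.
#' @param n_cycles breeding cycles of DH-generation + truncation selection.
#' @param selected_loci `data.frame(chrom, pos_bp, weight, favored)` of loci
#'   under selection; `favored` is 1 or 2 for the parent whose allele is
#'   selected. `NULL` gives one locus favouring parent 1 on chromosome 1
#'   and (if present) one favouring parent 2 on chromosome 2.
#' @param dh_n size of the DH mapping population.
#' @param qtls `data.frame(trait, chrom, pos_cM, add)` of additive QTLs;
#'   `add` is the additive effect a (half the difference between genotype
#'   class means, positive when the parent-1 allele increases the trait).
#'   `NULL` gives three QTLs for one trait `"yield"`.
#' @param h2 line-mean heritability per trait, scalar or named vector; (0, 1].
#' @param n_env,n_rep environments and replicates per environment.
#' @param genotype_error probability of a symmetric allele flip applied to
#'   descendant/DH genotypes after line construction.
#' @param missing_rate probability a genotype call is set missing.
#' @param seed integer seed used by the top-level simulators.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chrom = 2L, markers_per_chrom = 500L,
                       chrom_len_bp = 1e7, chrom_len_cM = 150,
                       divergence = 0.6,
                       n_descendants = 15L, n_candidates = 60L, n_cycles = 3L,
                       selected_loci = NULL,
                       dh_n = 240L, qtls = NULL, h2 = 0.7,
                       n_env = 3L, n_rep = 2L,
                       genotype_error = 0.001, missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_chrom = as.integer(n_chrom),
    markers_per_chrom = as.integer(markers_per_chrom),
    chrom_len_bp = as.numeric(chrom_len_bp),
    chrom_len_cM = as.numeric(chrom_len_cM),
    divergence = divergence,
    n_descendants = as.integer(n_descendants),
    n_candidates = as.integer(n_candidates),
    n_cycles = as.integer(n_cycles),
    selected_loci = selected_loci,
    dh_n = as.integer(dh_n),
    qtls = qtls,
    h2 = h2, n_env = as.integer(n_env), n_rep = as.integer(n_rep),
    genotype_error = genotype_error, missing_rate = missing_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  if (is.null(cfg$selected_loci)) {
    loci <- data.table(chrom = "1", pos_bp = round(0.3 * cfg$chrom_len_bp),
                       weight = 1, favored = 1L)
    if (cfg$n_chrom >= 2L)
      loci <- rbind(loci, data.table(chrom = "2",
                                     pos_bp = round(0.7 * cfg$chrom_len_bp),
                                     weight = 1, favored = 2L))
    cfg$selected_loci <- loci
  } else {
    cfg$selected_loci <- as.data.table(selected_loci)
    cfg$selected_loci[, chrom := as.character(chrom)]
  }
  if (is.null(cfg$qtls)) {
    q <- data.table(trait = "yield", chrom = c("1", "1"),
                    pos_cM = c(0.27, 0.73) * cfg$chrom_len_cM,
                    add = c(1, 0.6))
    if (cfg$n_chrom >= 2L)
      q <- rbind(q, data.table(trait = "yield", chrom = "2",
                               pos_cM = 0.5 * cfg$chrom_len_cM, add = 0.8))
    cfg$qtls <- q
  } else {
    cfg$qtls <- as.data.table(qtls)
    cfg$qtls[, chrom := as.character(chrom)]
  }
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(cfg$divergence > 0 && cfg$divergence <= 1))
    ps_stop("divergence must be in (0, 1], got %g", cfg$divergence)
  if (any(cfg$h2 <= 0 | cfg$h2 > 1))
    ps_stop("h2 must be in (0, 1]")
  if (cfg$dh_n <= 0L) ps_stop("dh_n must be positive")
  if (cfg$n_chrom < 1L || cfg$markers_per_chrom < 2L)
    ps_stop("need >= 1 chromosome and >= 2 markers per chromosome")
  if (cfg$genotype_error < 0 || cfg$genotype_error >= 0.5 ||
      cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    ps_stop("genotype_error must be in [0, 0.5), missing_rate in [0, 1)")
  chroms <- as.character(seq_len(cfg$n_chrom))
  if (nrow(cfg$selected_loci)) {
    with(cfg$selected_loci, {
      if (!all(chrom %in% chroms)) ps_stop("selected locus on unknown chromosome")
      if (any(pos_bp < 1 | pos_bp > cfg$chrom_len_bp))
        ps_stop("selected locus outside chromosome bounds")
      if (!all(favored %in% c(1L, 2L))) ps_stop("favored must be 1 or 2")
    })
  }
  if (nrow(cfg$qtls)) {
    with(cfg$qtls, {
      if (!all(chrom %in% chroms)) ps_stop("QTL on unknown chromosome")
      if (any(pos_cM < 0 | pos_cM > cfg$chrom_len_cM))
        ps_stop("QTL outside chromosome genetic span")
    })
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d chrom x %d markers (%g Mb / %g cM each), divergence %.2f\n",
    x$n_chrom, x$markers_per_chrom, x$chrom_len_bp / 1e6, x$chrom_len_cM,
    x$divergence))
  cat(sprintf("  panel: %d lines kept of %d candidates x %d cycles; %d selected loci\n",
              x$n_descendants, x$n_candidates, x$n_cycles,
              nrow(x$selected_loci)))
  cat(sprintf("  DH: %d lines, %d QTLs, %d env x %d rep, h2 = %s\n",
              x$dh_n, nrow(x$qtls), x$n_env, x$n_rep,
              paste(format(x$h2), collapse = ", ")))
  invisible(x)
}

#' Chromosome bounds of a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @return `data.table(chrom, len_bp, len_cM)`.
#' @export
chrom_bounds <- function(cfg) {
  data.table(chrom = as.character(seq_len(cfg$n_chrom)),
             len_bp = cfg$chrom_len_bp, len_cM = cfg$chrom_len_cM)
}
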