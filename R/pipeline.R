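## End-to-end orchestration: simulate -> ibd -> sweep -> qtl -> coloc with a
## single config, deterministic seeding and a machine-readable summary.

#' Build a run configuration
#'
#' One declarative object holding every stage's parameters. Per-module
#' blocks accept the same arguments as [sim_config()], [ibd_params()],
#' [clr_params()] and [scan_params()]; flat keys control the sweep and
#' co-localization settings.
#'
#' @param sim list of [sim_config()] arguments.
#' @param ibd list of [ibd_params()] arguments.
#' @param clr list of [clr_params()] arguments.
#' @param scan list of [scan_params()] arguments.
#' @param sweep_win,sweep_agg fine and aggregation window widths (bp).
#' @param top_fraction genome fraction selected per statistic (default 0.10).
#' @param near_dist QTL in-or-near distance (bp, default 1e6).
#' @param cluster_gap,cluster_min_size QTL cluster chaining parameters.
#' @param seed global seed; propagates to the simulator.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = list(), ibd = list(), clr = list(),
                       scan = list(), sweep_win = 1e4, sweep_agg = 1e5,
                       top_fraction = 0.10, near_dist = 1e6,
                       cluster_gap = 2e6, cluster_min_size = 4L,
                       seed = 1L) {
  sim$seed <- seed
  structure(list(sim = do.call(sim_config, sim),
                 ibd = do.call(ibd_params, ibd),
                 clr = do.call(clr_params, clr),
                 scan = do.call(scan_params, scan),
                 sweep_win = sweep_win, sweep_agg = sweep_agg,
                 top_fraction = top_fraction, near_dist = near_dist,
                 cluster_gap = cluster_gap,
                 cluster_min_size = as.integer(cluster_min_size),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of [run_config()]'s arguments
#'   (per-module blocks as objects).
#' @param seed optional seed overriding the file's.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!file.exists(path)) ps_stop("config not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) ps_warn("ignoring unknown config keys: %s",
                           paste(bad, collapse = ", "))
  cfg <- cfg[intersect(names(cfg), known)]
  for (blk in c("sim", "ibd", "clr", "scan"))
    if (!is.null(cfg[[blk]])) cfg[[blk]] <- as.list(cfg[[blk]])
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  do.call(run_config, cfg)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[pedsweep:%s] %s", stage, sprintf(fmt, ...)))
}

#' Validate pipeline input files
#'
#' Checks VCF / map / phenotype / parents concordance: parents present in
#' the VCF (fatal if absent), phenotyped lines present in the DH VCF
#' (warning), map monotone (fatal), map markers matching VCF positions
#' (warning).
#'
#' @param panel_vcf,dh_vcf,map_tsv,pheno_tsv,parents_txt file paths; any
#'   may be `NULL` to skip its checks.
#' @return list `fatal`, `warnings` (character vectors); zero fatal entries
#'   means the inputs are usable.
#' @export
validate_inputs <- function(panel_vcf = NULL, dh_vcf = NULL, map_tsv = NULL,
                            pheno_tsv = NULL, parents_txt = NULL) {
  fatal <- character(); warn <- character()
  map <- NULL
  if (!is.null(map_tsv)) {
    map <- tryCatch(read_map(map_tsv), error = function(e) {
      fatal <<- c(fatal, conditionMessage(e)); NULL })
  }
  if (!is.null(panel_vcf)) {
    panel <- tryCatch(read_vcf_genotypes(panel_vcf),
                      error = function(e) {
                        fatal <<- c(fatal, conditionMessage(e)); NULL })
    if (!is.null(panel) && !is.null(parents_txt)) {
      pr <- read_parents(parents_txt)
      miss <- setdiff(pr, panel$lines)
      if (length(miss))
        fatal <- c(fatal, sprintf("parent id(s) missing from VCF: %s",
                                  paste(miss, collapse = ", ")))
    }
    if (!is.null(panel) && !is.null(map)) {
      nm <- nrow(fintersect(panel$map[, .(chrom, pos_bp)],
                            map[, .(chrom = as.character(chrom), pos_bp)]))
      if (nm < nrow(panel$map))
        warn <- c(warn, sprintf("%d VCF marker(s) absent from map",
                                nrow(panel$map) - nm))
    }
  }
  if (!is.null(dh_vcf) && !is.null(pheno_tsv)) {
    dh <- tryCatch(read_vcf_genotypes(dh_vcf), error = function(e) {
      fatal <<- c(fatal, conditionMessage(e)); NULL })
    ph <- tryCatch(read_pheno(pheno_tsv), error = function(e) {
      fatal <<- c(fatal, conditionMessage(e)); NULL })
    if (!is.null(dh) && !is.null(ph)) {
      miss <- setdiff(unique(ph$line), dh$lines)
      if (length(miss))
        warn <- c(warn, sprintf("phenotyped line(s) absent from VCF: %s",
                                paste(head(miss, 10L), collapse = ", ")))
    }
  }
  list(fatal = fatal, warnings = warn)
}

read_parents <- function(path) {
  if (!file.exists(path)) ps_stop("parents file not found: %s", path)
  pr <- fread(path, header = FALSE)
  as.character(pr[[ncol(pr)]])[1:2]
}

#' Run the full pipeline
#'
#' Executes simulate -> ibd -> sweep -> qtl -> coloc in dependency order.
#' The simulator's files are written to `out_dir` and read back by each
#' consuming stage (exercising the round-trip contracts); per-stage tables
#' are written as TSV/BED and a collated summary as `summary.json`.
#' Identical seeds give byte-identical summaries. A stage failure aborts
#' with the stage name; earlier outputs are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the summary list, invisibly; files under `out_dir`.
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  run_stage <- function(stage, expr) {
    stage_log(stage, "start")
    tryCatch(expr, error = function(e)
      ps_stop("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  ## -- simulate ------------------------------------------------------------
  files <- run_stage("simulate", {
    sim <- simulate_study(config$sim)
    f <- write_sim_outputs(sim, out_dir)
    stage_log("simulate", "%d panel lines, %d DH lines, %d markers",
              nrow(sim$panel$geno), nrow(sim$dh$geno), ncol(sim$panel$geno))
    f
  })

  ## -- validate ------------------------------------------------------------
  diag <- run_stage("validate", {
    d <- validate_inputs(files["panel_vcf"], files["dh_vcf"], files["map"],
                         files["pheno"], files["parents"])
    if (length(d$fatal))
      ps_stop("fatal input diagnostics: %s", paste(d$fatal, collapse = "; "))
    for (w in d$warnings) stage_log("validate", "warning: %s", w)
    d
  })

  map <- read_map(files["map"])
  bounds <- map[, .(len_bp = max(pos_bp)), by = chrom]

  ## -- ibd -----------------------------------------------------------------
  ibd <- run_stage("ibd", {
    panel <- read_vcf_genotypes(files["panel_vcf"], map)
    tr <- ibd_trace_panel(panel, read_parents(files["parents"]), config$ibd)
    icrs <- call_icrs(tr$tilings, bounds, config$ibd)
    ratios <- rbindlist(lapply(names(tr$tilings), function(id)
      cbind(line = id, retention_ratio(tr$tilings[[id]], icrs))))
    write_bed(tr$segments[, .(chrom, start = start_bp, end = end_bp,
                              name = paste0("P", parent),
                              score = round(lod * 100))], p("ibd_segments.bed"))
    write_bed(icrs[, .(chrom, start, end, name = paste0("P", parent),
                       score = round(retention * 1000))], p("icr.bed"))
    fwrite(ratios, p("retention_ratios.tsv"), sep = "\t")
    stage_log("ibd", "%d segments, %d ICRs", nrow(tr$segments), nrow(icrs))
    list(trace = tr, icrs = icrs, ratios = ratios, panel = panel)
  })

  ## -- sweep ---------------------------------------------------------------
  sweep <- run_stage("sweep", {
    panel <- ibd$panel
    kids <- gm_lines(panel, setdiff(panel$lines,
                                    read_parents(files["parents"])))
    ws <- window_stats(kids, win = config$sweep_win, bounds = bounds)
    phi <- background_sfs(kids)
    clr <- clr_scan(kids, phi, config$clr, bounds = bounds)
    agg <- list(
      pi = aggregate_windows(ws[, .(chrom, start, end, value = pi)],
                             "value", config$sweep_agg, bounds),
      tajima_d = aggregate_windows(ws[, .(chrom, start, end,
                                          value = tajima_d)],
                                   "value", config$sweep_agg, bounds),
      clr = aggregate_windows(clr[, .(chrom, pos, value = clr)],
                              "value", config$sweep_agg, bounds))
    dirs <- c(pi = "low", tajima_d = "low", clr = "high")
    ssw <- lapply(names(agg), function(s)
      select_top_and_merge(agg[[s]], fraction = config$top_fraction,
                           direction = dirs[[s]], statistic = s))
    names(ssw) <- names(agg)
    fwrite(ws, p("window_stats.tsv"), sep = "\t")
    fwrite(clr, p("clr_scan.tsv"), sep = "\t")
    for (s in names(ssw))
      write_bed(ssw[[s]][, .(chrom, start, end, name = statistic)],
                p(sprintf("ssw_%s.bed", s)))
    ps <- popstats(kids)
    fwrite(ps$per_marker, p("popstats.tsv"), sep = "\t")
    stage_log("sweep", "SSWs: pi %d, tajima_d %d, clr %d",
              nrow(ssw$pi), nrow(ssw$tajima_d), nrow(ssw$clr))
    list(window_stats = ws, clr = clr, ssw = ssw, popstats = ps)
  })

  ## -- qtl -----------------------------------------------------------------
  qtl <- run_stage("qtl", {
    if (!file.exists(files["pheno"]))
      ps_stop("phenotype file missing: %s", files["pheno"])
    dh <- read_vcf_genotypes(files["dh_vcf"], map)
    pheno <- read_pheno(files["pheno"])
    traits <- setdiff(names(pheno), c("line", "env", "rep"))
    envs <- unique(pheno$env)
    scans <- list(); qtab <- list()
    for (tr in traits) for (e in envs) {
      sc <- qtl_scan(dh, pheno, tr, env = e, params = config$scan)
      scans[[paste(tr, e, sep = ".")]] <- sc
      qtab[[paste(tr, e, sep = ".")]] <- sc$qtls
      fwrite(sc$profile, p(sprintf("lod_profile_%s_%s.tsv", tr, e)),
             sep = "\t")
    }
    qtls <- rbindlist(qtab)
    stable <- stable_qtls(qtls)
    qtls_bp <- qtls_to_bp(qtls, map)
    clusters <- qtl_clusters(qtls_bp, config$cluster_gap,
                             config$cluster_min_size)
    caes <- cae(dh, qtls)
    fwrite(qtls_bp, p("qtls.tsv"), sep = "\t")
    if (nrow(stable)) fwrite(stable, p("stable_qtls.tsv"), sep = "\t")
    if (nrow(clusters)) fwrite(clusters, p("qtl_clusters.tsv"), sep = "\t")
    fwrite(caes, p("cae.tsv"), sep = "\t")
    stage_log("qtl", "%d QTLs (%d stable groups, %d clusters)",
              nrow(qtls), nrow(stable), nrow(clusters))
    list(qtls = qtls_bp, stable = stable, clusters = clusters, cae = caes)
  })

  ## -- coloc ---------------------------------------------------------------
  coloc <- run_stage("coloc", {
    ssw_sets <- lapply(sweep$ssw, function(s) s[, .(chrom, start, end)])
    rep_icr <- icr_ssw_coloc(ibd$icrs, ssw_sets)
    ssw_union <- do.call(iv_union, unname(ssw_sets))
    icr_iv <- ibd$icrs[, .(chrom, start, end)]
    qn_ssw <- qtl_near(qtl$qtls, ssw_union, config$near_dist)
    qn_icr <- if (nrow(icr_iv)) qtl_near(qtl$qtls, icr_iv, config$near_dist)
              else list(fraction = NA_real_)
    genes <- read_genes(files["genes"])
    overlap_iv <- if (nrow(icr_iv)) iv_intersect(icr_iv, ssw_union)
                  else icr_iv
    gl <- genes_in_regions(genes, overlap_iv)
    by_parent_genes <- lapply(c(P1 = 1L, P2 = 2L), function(pp) {
      iv <- ibd$icrs[parent == pp, .(chrom, start, end)]
      if (!nrow(iv)) return(0L)
      nrow(genes_in_regions(genes, iv_intersect(iv, ssw_union)))
    })
    fwrite(gl, p("genes_in_icr_ssw.tsv"), sep = "\t")
    if (nrow(qn_ssw$flags)) fwrite(qn_ssw$flags, p("qtl_near_ssw.tsv"),
                                   sep = "\t")
    stage_log("coloc", "ICR length overlapped by SSW: %.2f%%",
              rep_icr$overall$pct_length %||% NA)
    list(icr_ssw = rep_icr, qtl_near_ssw = qn_ssw, qtl_near_icr = qn_icr,
         genes = gl, genes_by_parent = by_parent_genes)
  })

  ## -- summary -------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    n_icr = nrow(ibd$icrs),
    n_icr_by_parent = list(P1 = nrow(ibd$icrs[parent == 1L]),
                           P2 = nrow(ibd$icrs[parent == 2L])),
    genome_fraction = as.list(attr(ibd$icrs, "genome_fraction")),
    n_ssw = lapply(sweep$ssw, nrow),
    n_qtls = nrow(qtl$qtls),
    pve_range = if (nrow(qtl$qtls)) range(qtl$qtls$pve) else NULL,
    n_stable_qtl_groups = nrow(qtl$stable),
    n_qtl_clusters = nrow(qtl$clusters),
    icr_ssw_pct_length = coloc$icr_ssw$overall$pct_length,
    icr_ssw_pct_count = coloc$icr_ssw$overall$pct_count,
    qtl_near_ssw_pct = coloc$qtl_near_ssw$fraction,
    qtl_near_icr_pct = coloc$qtl_near_icr$fraction,
    n_genes_in_icr_ssw = nrow(coloc$genes),
    prop_maf_lt_02 = sweep$popstats$prop_maf_lt_02,
    mean_pic = sweep$popstats$mean_pic
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  stage_log("summary", "written to %s", p("summary.json"))
  invisible(list(summary = summary, ibd = ibd[c("icrs", "ratios")],
                 sweep = sweep["ssw"], qtl = qtl, coloc = coloc,
                 files = files))
}
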