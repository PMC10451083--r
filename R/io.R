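## File formats: VCF v4.2 (GT-only) for genotypes, TSV for map/phenotypes,
## JSON for simulator ground truth, BED/GFF3 for regions and genes.
## Writing VCF is done here (deterministic, so write -> read -> write is
## byte-identical); reading delegates to VariantAnnotation.

#' Write inbred-line genotypes as VCF v4.2
#'
#' GT-only FORMAT; homozygous calls `0/0` / `1/1`, missing `./.`; contigs
#' declared in the header. The reference allele is parent 1's allele in
#' simulated data.
#'
#' @param gm a [geno_matrix()]; its map must carry `ref` and `alt` columns
#'   (defaults A/T are used otherwise).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  map <- copy(gm$map)
  if (!"ref" %in% names(map)) map[, ref := "A"]
  if (!"alt" %in% names(map)) map[, alt := "T"]
  bounds <- map[, .(len = max(pos_bp)), by = chrom]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pedsweep",
    sprintf("##contig=<ID=%s,length=%d>", bounds$chrom, bounds$len),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$lines), collapse = "\t"))
  gt <- matrix("./.", ncol(gm$geno), nrow(gm$geno))
  tg <- t(gm$geno)
  gt[!is.na(tg) & tg == 0L] <- "0/0"
  gt[!is.na(tg) & tg == 1L] <- "1/1"
  body <- paste(map$chrom, map$pos_bp, map$marker_id, map$ref, map$alt,
                ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "wb")   # "wb": fixed \n line endings for byte-identity
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read inbred-line genotypes from a VCF
#'
#' Parses with `VariantAnnotation::readVcf`. Calls are collapsed to one
#' allele per line: `0/0 -> 0`, `1/1 -> 1`, missing `-> NA`; heterozygous
#' calls (unexpected for inbred lines) are set missing with a warning.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param map optional map `data.table` (e.g. from [read_map()]) supplying
#'   `pos_cM`; joined on `chrom` + `pos_bp`.
#' @return a [geno_matrix()].
#' @export
read_vcf_genotypes <- function(path, map = NULL) {
  if (!file.exists(path)) ps_stop("VCF not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  vmap <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos_bp = GenomicRanges::start(rr),
    marker_id = names(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""))
  gt <- VariantAnnotation::geno(vcf)$GT         # markers x samples
  g <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g[gt %in% c("0/0", "0|0", "0")] <- 0L
  g[gt %in% c("1/1", "1|1", "1")] <- 1L
  n_het <- sum(gt %in% c("0/1", "1/0", "0|1", "1|0"))
  if (n_het > 0)
    ps_warn("%d heterozygous calls set to missing (inbred lines expected)", n_het)
  if (!is.null(map)) {
    map <- as.data.table(map)
    m <- map[vmap, on = c("chrom", "pos_bp")]
    vmap[, pos_cM := m$pos_cM]
  }
  geno_matrix(t(g), vmap)
}

#' Write / read the genetic map TSV
#'
#' Columns `chrom`, `pos_bp`, `pos_cM`, `marker_id`.
#' @param map map `data.table`.
#' @param path TSV file.
#' @return `path` / the map `data.table`.
#' @export
write_map <- function(map, path) {
  fwrite(as.data.table(map)[, .(chrom, pos_bp, pos_cM, marker_id)],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) ps_stop("map file not found: %s", path)
  map <- fread(path, colClasses = list(character = "chrom"))
  need <- c("chrom", "pos_bp", "pos_cM")
  if (!all(need %in% names(map)))
    ps_stop("map %s must have columns %s", path, paste(need, collapse = ", "))
  bad <- map[, any(diff(pos_cM) < 0), by = chrom][V1 == TRUE]
  if (nrow(bad))
    ps_stop("map %s not monotone on chromosome(s) %s", path,
            paste(bad$chrom, collapse = ", "))
  map[]
}

#' Write / read the phenotype TSV
#'
#' Long-by-observation table: `line`, `env`, `rep`, then one column per trait.
#' @param pheno phenotype `data.table`.
#' @param path TSV file.
#' @return `path` / the phenotype `data.table`.
#' @export
write_pheno <- function(pheno, path) {
  fwrite(as.data.table(pheno), path, sep = "\t")
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  if (!file.exists(path)) ps_stop("phenotype file not found: %s", path)
  ph <- fread(path, colClasses = list(character = c("line", "env")))
  if (!all(c("line", "env", "rep") %in% names(ph)))
    ps_stop("phenotype file %s must have columns line, env, rep", path)
  ph[]
}

#' Write / read the simulator ground-truth JSON
#'
#' Stores per-line parent-of-origin paths (run-length encoded), crossovers,
#' origin-path breakpoints, selected loci and informative-marker indices.
#'
#' @param truth `truth` list from [simulate_descendants()].
#' @param path JSON file.
#' @return `path` / the truth list (origin re-expanded to a matrix).
#' @export
write_truth <- function(truth, path) {
  enc <- list(
    lines = rownames(truth$origin),
    origin_rle = apply(truth$origin, 1L, function(o) {
      r <- rle(o); list(lengths = r$lengths, values = r$values)
    }, simplify = FALSE),
    crossovers = truth$crossovers,
    breakpoints = truth$breakpoints,
    selected_loci = truth$selected_loci,
    informative = truth$informative
  )
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) ps_stop("truth file not found: %s", path)
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  origin <- do.call(rbind, lapply(enc$origin_rle, function(r)
    inverse.rle(structure(list(lengths = r$lengths, values = r$values),
                          class = "rle"))))
  rownames(origin) <- enc$lines
  bps <- enc$breakpoints
  if (is.data.frame(bps)) bps <- list(as.data.table(bps))
  else bps <- lapply(bps, as.data.table)
  list(origin = origin, crossovers = enc$crossovers,
       breakpoints = bps,
       selected_loci = as.data.table(enc$selected_loci),
       informative = enc$informative)
}

#' Write an interval table as BED
#'
#' Intervals are 0-based half-open internally, matching BED directly.
#' @param dt `data.table` with `chrom`, `start`, `end` and optional `name`
#'   and `score` columns.
#' @param path BED file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  out <- dt[, .(chrom, start = as.integer(start), end = as.integer(end))]
  out[, name := if ("name" %in% names(dt)) dt$name else "."]
  out[, score := if ("score" %in% names(dt))
    pmin(pmax(as.integer(dt$score), 0L), 1000L) else 0L]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene/region intervals from BED or GFF3
#'
#' Delegates to `rtracklayer::import`; GFF records are filtered to
#' `type == "gene"` when that column is present. Malformed records that
#' rtracklayer rejects abort; use well-formed annotations.
#'
#' @param path BED or GFF3 file (format chosen by extension).
#' @return `data.table(chrom, start, end, gene_id)`, 0-based half-open.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) ps_stop("annotation not found: %s", path)
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID)
        else if ("name" %in% names(mc)) as.character(mc$name)
        else sprintf("gene_%05d", seq_along(gr))
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
             end = GenomicRanges::end(gr),
             gene_id = id)
}

#' Write a gene annotation table as GFF3
#' @param genes `data.table(chrom, start, end, gene_id)` (0-based half-open).
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  genes <- as.data.table(genes)
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    type = "gene", ID = genes$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write all simulator outputs to a directory
#'
#' Emits `panel.vcf` (parents + descendant lines), `dh.vcf` (mapping
#' population), `map.tsv`, `phenotypes.tsv`, `truth.json`,
#' `genes.synthetic.gff3` and `parents.txt`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_vcf(sim$panel, p("panel.vcf"))
  write_vcf(sim$dh, p("dh.vcf"))
  write_map(sim$founders$map, p("map.tsv"))
  write_pheno(sim$phenotypes, p("phenotypes.tsv"))
  write_truth(sim$panel_truth, p("truth.json"))
  write_genes_gff3(sim$genes, p("genes.synthetic.gff3"))
  writeLines(c("P1\tP1", "P2\tP2"), p("parents.txt"))
  invisible(c(panel_vcf = p("panel.vcf"), dh_vcf = p("dh.vcf"),
              map = p("map.tsv"), pheno = p("phenotypes.tsv"),
              truth = p("truth.json"), genes = p("genes.synthetic.gff3"),
              parents = p("parents.txt")))
}
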