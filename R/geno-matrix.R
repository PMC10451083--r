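#' Genotype matrix for inbred lines
#'
#' Container for biallelic calls on fully inbred (homozygous) lines: one
#' allele per line per marker, coded 0 (reference = parent-1 allele in
#' simulations), 1 (alternate) or `NA` (missing), plus the marker map.
#'
#' @param geno integer matrix, lines x markers, values in `{0, 1, NA}`.
#' @param map `data.frame` with columns `chrom`, `pos_bp`, `pos_cM`
#'   (optional), `marker_id`, and optionally `ref`/`alt` alleles.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, map) {
  map <- as.data.table(map)
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno))
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("L%03d", seq_len(nrow(geno)))
  if (!"marker_id" %in% names(map))
    map[, marker_id := sprintf("m%05d", .I)]
  map[, chrom := as.character(chrom)]
  bad <- map[, any(diff(pos_bp) <= 0), by = chrom][V1 == TRUE]
  if (nrow(bad))
    ps_stop("map positions must be strictly increasing within a chromosome")
  if ("pos_cM" %in% names(map)) {
    bad <- map[, any(diff(pos_cM) < 0), by = chrom][V1 == TRUE]
    if (nrow(bad)) ps_stop("pos_cM must be non-decreasing within a chromosome")
  }
  colnames(geno) <- map$marker_id
  structure(list(geno = geno, map = map, lines = rownames(geno)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers on %d chromosome(s); %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(i)) i <- match(i, x$lines)
  geno_matrix(x$geno[i, j, drop = FALSE], x$map[j])
}

#' Subset a genotype matrix to a set of lines
#' @param x a [geno_matrix()].
#' @param lines character vector of line ids.
#' @return a `geno_matrix` with those lines, in the given order.
#' @export
gm_lines <- function(x, lines) {
  miss <- setdiff(lines, x$lines)
  if (length(miss)) ps_stop("lines absent from genotypes: %s",
                            paste(miss, collapse = ", "))
  x[lines, ]
}
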