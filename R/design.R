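#' Column index for an (SNP, origin class) pair
#'
#' The origin design matrix lays SNP j out as three adjacent columns in fixed
#' order Bi, Bt, Bx: columns 3(j-1)+1 .. 3(j-1)+3 (1-based).
#'
#' @param j 1-based SNP index (vectorised).
#' @param cls origin class, "Bi", "Bt" or "Bx".
#' @return 1-based column index into the origin design matrix.
#' @export
column_key <- function(j, cls) {
  k <- match(cls, ORIGIN_LEVELS)
  if (anyNA(k)) abort("class must be one of Bi, Bt, Bx")
  as.integer(3L * (j - 1L) + k)
}

#' Inverse of [column_key()]
#'
#' @param col 1-based column index (vectorised).
#' @return tibble with `snp` (1-based SNP index) and `class`.
#' @export
column_key_inverse <- function(col) {
  col <- as.integer(col)
  if (any(col < 1)) abort("column index must be >= 1")
  tibble(snp = (col - 1L) %/% 3L + 1L,
         class = ORIGIN_LEVELS[(col - 1L) %% 3L + 1L])
}

#' Build the origin-partitioned design matrix
#'
#' Expands the animals x SNP dosage matrix into animals x 3*nsnp: each SNP
#' contributes three columns (Bi, Bt, Bx) and an animal's dosage at that SNP
#' is written, whole, into the single column matching the diplotype origin
#' class of the SNP's haplotype window. The other two columns stay zero, so
#' collapsing the three columns of every SNP recovers the plain dosage
#' matrix exactly. At least two thirds of entries are structural zeros, so
#' the matrix is returned sparse.
#'
#' @param g `phased_genotypes` for the target population.
#' @param calls `origin_calls` covering every window and every animal of `g`.
#' @param ws the `window_set` the calls were made on (same map as `g`).
#' @return a `Matrix::dgCMatrix` (animals x 3*nsnp) with rownames the animal
#'   ids and colnames "snp_id|class".
#' @export
build_origin_xmatrix <- function(g, calls, ws) {
  stopifnot(inherits(g, "phased_genotypes"), inherits(calls, "origin_calls"),
            inherits(ws, "window_set"))
  wmap <- attr(ws, "map")
  if (!identical(g$map$snp_id, wmap$snp_id)) {
    abort("genotype map does not match the window set")
  }
  n <- n_animals(g); p <- n_snps(g)
  # diplotype class per animal x window
  aid <- match(calls$animal_id, g$animal_ids)
  wid <- match(calls$window, ws$window)
  if (anyNA(aid)) abort("origin calls contain animals absent from the genotypes")
  cls <- matrix(NA_integer_, n, nrow(ws))
  cls[cbind(aid, wid)] <- match(calls$diplotype, ORIGIN_LEVELS)
  if (anyNA(cls)) {
    bad <- which(is.na(cls), arr.ind = TRUE)[1, ]
    abort(paste0("no origin call for animal ", g$animal_ids[bad[1]],
                 " in window ", ws$window[bad[2]]))
  }
  D <- dosage(g)
  win_of_snp <- rep(seq_len(nrow(ws)), times = ws$m)
  nz <- which(D != 0, arr.ind = TRUE)
  i <- nz[, 1]
  j <- nz[, 2]
  k <- cls[cbind(i, win_of_snp[j])]
  X <- Matrix::sparseMatrix(i = i, j = 3L * (j - 1L) + k, x = as.numeric(D[nz]),
                            dims = c(n, 3L * p))
  rownames(X) <- g$animal_ids
  colnames(X) <- paste(rep(g$map$snp_id, each = 3), rep(ORIGIN_LEVELS, p), sep = "|")
  X
}

#' Build the control (plain dosage) design matrix
#'
#' The animals x nsnp alternative-allele dosage matrix with no subspecies
#' adjustment, used by the multi-breed control analysis.
#'
#' @param g `phased_genotypes`.
#' @return integer matrix, animals x SNP, entries 0/1/2.
#' @export
build_control_xmatrix <- function(g) {
  stopifnot(inherits(g, "phased_genotypes"))
  dosage(g)
}

#' Column annotation for a design matrix
#'
#' Maps design columns back to SNP id, origin class and genomic position,
#' for effect labelling and Manhattan-style reports.
#'
#' @param map a SNP map.
#' @param kind "origin" (three columns per SNP, classes Bi/Bt/Bx) or
#'   "control" (one column per SNP, class "control").
#' @return tibble: `col`, `snp_id`, `snp_index`, `class`, `chrom`, `pos_bp`.
#' @export
design_column_info <- function(map, kind = c("origin", "control")) {
  kind <- match.arg(kind)
  map <- validate_snp_map(map)
  p <- nrow(map)
  if (kind == "control") {
    tibble(col = seq_len(p), snp_id = map$snp_id, snp_index = seq_len(p),
           class = "control", chrom = map$chrom, pos_bp = map$pos_bp)
  } else {
    tibble(col = seq_len(3L * p),
           snp_id = rep(map$snp_id, each = 3),
           snp_index = rep(seq_len(p), each = 3),
           class = rep(ORIGIN_LEVELS, p),
           chrom = rep(map$chrom, each = 3),
           pos_bp = rep(map$pos_bp, each = 3))
  }
}

#' Collapse an origin design matrix back to plain dosages
#'
#' Sums the Bi, Bt, Bx column triple of each SNP; the result must equal the
#' control matrix (the row-block sum identity).
#'
#' @param X an origin design matrix (animals x 3*nsnp).
#' @return dense matrix, animals x nsnp.
#' @export
collapse_origin_xmatrix <- function(X) {
  p3 <- ncol(X)
  if (p3 %% 3 != 0) abort("origin matrix must have 3 columns per SNP")
  p <- p3 %/% 3
  agg <- Matrix::sparseMatrix(i = seq_len(p3), j = rep(seq_len(p), each = 3),
                              x = 1, dims = c(p3, p))
  out <- as.matrix(X %*% agg)
  colnames(out) <- sub("\\|Bi$", "", colnames(X)[seq(1, p3, by = 3)])
  rownames(out) <- rownames(X)
  out
}

#' Write a sparse design matrix as MatrixMarket triplets with a label sidecar
#'
#' @param X design matrix (sparse or dense).
#' @param path output path for the MatrixMarket file; the column-label TSV is
#'   written beside it as `<path>.cols.tsv`.
#' @param col_info optional tibble from [design_column_info()].
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(X, path, col_info = NULL) {
  Xs <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               paste(nrow(Xs), ncol(Xs), length(Xs@x))), con)
  writeLines(paste(Xs@i + 1L, Xs@j + 1L, Xs@x), con)
  close(con)
  if (!is.null(col_info)) {
    write_output_tsv(col_info, paste0(path, ".cols.tsv"))
  }
  invisible(path)
}
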