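#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom rlang abort warn inform `%||%`
NULL

ORIGIN_LEVELS <- c("Bi", "Bt", "Bx")

#' Validate a SNP map
#'
#' A SNP map is a tibble with one row per bi-allelic SNP: `snp_id`, `chrom`,
#' `pos_bp` (1-based physical position), `ref`, `alt` (single characters).
#' SNP ids must be unique, positions strictly increasing within a chromosome,
#' and each chromosome's rows must form one contiguous block so that window
#' SNP ranges are contiguous in map order.
#'
#' @param map a data frame with columns snp_id, chrom, pos_bp, ref, alt.
#' @return the map as a tibble, invisibly validated.
#' @export
validate_snp_map <- function(map) {
  map <- as_tibble(map)
  need <- c("snp_id", "chrom", "pos_bp", "ref", "alt")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols) > 0) {
    abort(paste0("SNP map is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(map) == 0) abort("SNP map is empty")
  if (anyNA(map$pos_bp) || any(map$pos_bp < 1)) {
    abort("SNP map positions must be present and >= 1 (1-based)")
  }
  if (anyDuplicated(map$snp_id)) abort("SNP ids must be unique")
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  # chromosome blocks must be contiguous
  r <- rle(map$chrom)
  if (anyDuplicated(r$values)) {
    abort("SNP map chromosomes must form contiguous blocks")
  }
  ok <- unlist(lapply(split(map$pos_bp, factor(map$chrom, levels = r$values)),
                      function(p) all(diff(p) > 0)), use.names = FALSE)
  if (!all(ok)) abort("Positions must be strictly increasing within each chromosome")
  map
}

#' Construct a phased genotype set
#'
#' Holds phased bi-allelic genotypes: two haplotype allele matrices
#' (animals x SNP, entries 0 = reference allele, 1 = alternative allele),
#' slot 0 being the first (paternal) and slot 1 the second (maternal)
#' chromosome copy, plus the SNP map.
#'
#' @param animal_ids character vector of unique animal ids.
#' @param map SNP map (see [validate_snp_map()]).
#' @param hap0,hap1 integer matrices, animals x SNP, entries in \{0, 1\}.
#' @return an object of class `phased_genotypes`.
#' @export
phased_genotypes <- function(animal_ids, map, hap0, hap1) {
  map <- validate_snp_map(map)
  animal_ids <- as.character(animal_ids)
  if (anyDuplicated(animal_ids)) abort("animal ids must be unique")
  hap0 <- as.matrix(hap0); hap1 <- as.matrix(hap1)
  storage.mode(hap0) <- "integer"; storage.mode(hap1) <- "integer"
  n <- length(animal_ids); m <- nrow(map)
  if (!all(dim(hap0) == c(n, m)) || !all(dim(hap1) == c(n, m))) {
    abort("haplotype matrices must be n_animals x n_snp")
  }
  if (anyNA(hap0) || anyNA(hap1)) abort("missing genotypes are not allowed")
  if (!all(hap0 %in% 0:1) || !all(hap1 %in% 0:1)) {
    abort("haplotype alleles must be 0 or 1")
  }
  dimnames(hap0) <- dimnames(hap1) <- list(animal_ids, map$snp_id)
  structure(list(animal_ids = animal_ids, map = map, hap0 = hap0, hap1 = hap1),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("<phased_genotypes> ", length(x$animal_ids), " animals x ",
      nrow(x$map), " SNP on ", length(unique(x$map$chrom)),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Allele dosage matrix
#'
#' Count of the alternative allele per animal and SNP (0, 1 or 2), the sum
#' of the two phased haplotype allele matrices.
#'
#' @param g a `phased_genotypes` object.
#' @return integer matrix, animals x SNP.
#' @export
dosage <- function(g) {
  stopifnot(inherits(g, "phased_genotypes"))
  d <- g$hap0 + g$hap1
  storage.mode(d) <- "integer"
  d
}

n_animals <- function(g) length(g$animal_ids)
n_snps <- function(g) nrow(g$map)

#' Check that two genotype sets share marker identity
#'
#' The reference and target populations must be typed on the same panel with
#' the same reference-allele orientation: identical snp ids, chromosomes,
#' positions and REF/ALT alleles, in the same order.
#'
#' @param a,b `phased_genotypes` objects.
#' @return TRUE invisibly, or an error describing the first mismatch.
#' @export
check_same_markers <- function(a, b) {
  stopifnot(inherits(a, "phased_genotypes"), inherits(b, "phased_genotypes"))
  if (nrow(a$map) != nrow(b$map)) {
    abort("marker mismatch between genotype sets: different SNP counts")
  }
  for (col in c("snp_id", "chrom", "pos_bp", "ref", "alt")) {
    if (!identical(a$map[[col]], b$map[[col]])) {
      i <- which(a$map[[col]] != b$map[[col]])[1]
      abort(paste0("marker mismatch between genotype sets in column '", col,
                   "' (first at row ", i, ")"))
    }
  }
  invisible(TRUE)
}
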