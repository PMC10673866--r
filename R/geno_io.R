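#' Read phased genotypes from a VCF file
#'
#' Reads a VCF of bi-allelic SNP records with phased GT fields ("0|1" style)
#' into a [phased_genotypes()] object. Parsing is delegated to
#' \pkg{vcfR}; this wrapper enforces the contracts the downstream haplotype
#' machinery needs: bi-allelic sites only, no missing genotypes, and (by
#' default) fully phased calls.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param require_phased error on any "/"-separated genotype. Set FALSE only
#'   when dosages, not haplotypes, are needed.
#' @return a `phased_genotypes` object; animal order follows the VCF header,
#'   SNP order the records.
#' @export
read_phased_vcf <- function(path, require_phased = TRUE) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  alt <- fix[, "ALT"]
  bad <- which(grepl(",", alt) | nchar(fix[, "REF"]) != 1 | nchar(alt) != 1 | is.na(alt))
  if (length(bad) > 0) {
    abort(paste0("multi-allelic or non-SNP record at ", fix[bad[1], "CHROM"],
                 ":", fix[bad[1], "POS"], "; only bi-allelic SNP are supported"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (ncol(gt) == 0) abort("VCF has no sample columns")
  miss <- which(is.na(gt) | gt %in% c(".", "./.", ".|."), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    i <- miss[1, 1]
    abort(paste0("missing genotype at ", fix[i, "CHROM"], ":", fix[i, "POS"],
                 " (imputation is out of scope; genotypes must be complete)"))
  }
  unphased <- which(matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt)),
                    arr.ind = TRUE)
  if (require_phased && nrow(unphased) > 0) {
    i <- unphased[1, 1]
    abort(paste0("unphased genotype at record ", fix[i, "CHROM"], ":",
                 fix[i, "POS"], " sample ", colnames(gt)[unphased[1, 2]]))
  }
  a0 <- substr(gt, 1, 1)
  a1 <- substr(gt, 3, 3)
  if (!all(a0 %in% c("0", "1")) || !all(a1 %in% c("0", "1"))) {
    abort("GT alleles must be 0 or 1 for bi-allelic SNP")
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- tibble(snp_id = unname(ids), chrom = unname(fix[, "CHROM"]),
                pos_bp = as.integer(fix[, "POS"]),
                ref = unname(fix[, "REF"]), alt = unname(alt))
  # gt is SNP x sample; internal layout is animal x SNP
  hap0 <- t(matrix(as.integer(a0), nrow = nrow(gt)))
  hap1 <- t(matrix(as.integer(a1), nrow = nrow(gt)))
  phased_genotypes(colnames(gt), map, hap0, hap1)
}

#' Write phased genotypes to a VCF file
#'
#' Minimal VCFv4.2 writer with phased GT fields, the inverse of
#' [read_phased_vcf()].
#'
#' @param g a `phased_genotypes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(g, path) {
  stopifnot(inherits(g, "phased_genotypes"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=boaqtl",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$animal_ids), collapse = "\t"))
  gts <- matrix(paste0(t(g$hap0), "|", t(g$hap1)), nrow = n_snps(g))
  body <- paste(g$map$chrom, g$map$pos_bp, g$map$snp_id, g$map$ref, g$map$alt,
                ".", "PASS", ".", "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# TSV haplotype dialect:
#   '##boaqtl-haplotypes' magic line
#   '#map<TAB>snp_id<TAB>chrom<TAB>pos_bp<TAB>ref<TAB>alt' per SNP
#   header row: animal_id<TAB>hap<TAB><snp ids...>
#   one row per haplotype copy (hap in {0,1}), alleles in {0,1}

#' Write phased haplotypes as TSV
#'
#' Lossless plain-text serialisation: map rows as '#map' comment lines, then
#' one row per haplotype copy with one column per SNP.
#'
#' @param g a `phased_genotypes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "phased_genotypes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##boaqtl-haplotypes", con)
  writeLines(paste("#map", g$map$snp_id, g$map$chrom, g$map$pos_bp,
                   g$map$ref, g$map$alt, sep = "\t"), con)
  writeLines(paste(c("animal_id", "hap", g$map$snp_id), collapse = "\t"), con)
  n <- n_animals(g)
  rows <- character(2L * n)
  for (i in seq_len(n)) {
    rows[2L * i - 1L] <- paste(c(g$animal_ids[i], "0", g$hap0[i, ]), collapse = "\t")
    rows[2L * i] <- paste(c(g$animal_ids[i], "1", g$hap1[i, ]), collapse = "\t")
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read phased haplotypes from TSV
#'
#' Inverse of [write_haplotype_tsv()]. Errors on ragged rows, alleles outside
#' \{0, 1\}, or a file with no haplotype rows.
#'
#' @param path path to a haplotype TSV.
#' @return a `phased_genotypes` object.
#' @export
read_haplotype_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("haplotype TSV not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  map_lines <- lines[startsWith(lines, "#map")]
  body <- lines[!startsWith(lines, "#")]
  if (length(map_lines) == 0) abort("no #map lines in haplotype TSV")
  mp <- do.call(rbind, strsplit(map_lines, "\t", fixed = TRUE))
  if (ncol(mp) != 6) abort("malformed #map line in haplotype TSV")
  map <- tibble(snp_id = mp[, 2], chrom = mp[, 3], pos_bp = as.integer(mp[, 4]),
                ref = mp[, 5], alt = mp[, 6])
  if (length(body) < 2) abort("no haplotypes in file")
  fields <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    abort(paste0("ragged row in haplotype TSV (line with ", widths[which(widths != widths[1])[1]],
                 " fields, expected ", widths[1], ")"))
  }
  header <- fields[[1]]
  if (!identical(header[1:2], c("animal_id", "hap")) ||
      !identical(header[-(1:2)], map$snp_id)) {
    abort("haplotype TSV header does not match its #map lines")
  }
  rows <- fields[-1]
  if (length(rows) == 0 || length(rows) %% 2 != 0) abort("no haplotypes: need two rows per animal")
  rmat <- do.call(rbind, rows)
  ids <- rmat[, 1]; hap <- rmat[, 2]
  allele_chr <- rmat[, -(1:2), drop = FALSE]
  if (!all(allele_chr %in% c("0", "1"))) {
    bad <- allele_chr[!(allele_chr %in% c("0", "1"))][1]
    abort(paste0("allele '", bad, "' outside {0,1} in haplotype TSV"))
  }
  alleles <- matrix(as.integer(allele_chr), nrow = nrow(rmat))
  i0 <- which(hap == "0"); i1 <- which(hap == "1")
  if (length(i0) != length(i1) || !identical(ids[i0], ids[i1])) {
    abort("haplotype rows must come in (hap 0, hap 1) pairs per animal")
  }
  phased_genotypes(ids[i0], map, alleles[i0, , drop = FALSE], alleles[i1, , drop = FALSE])
}

#' Read a phenotype table
#'
#' Tab-delimited file with header columns `animal_id`, `trait`, `cg`
#' (contemporary group: year-herd-season class), `age` (days) and `breed`.
#' Animals with a missing trait are retained as prediction-only candidates.
#'
#' @param path path to the phenotype TSV.
#' @param rms_range_check warn when trait values fall outside the 0-5
#'   reproductive maturity score scale.
#' @return a tibble with typed columns.
#' @export
read_phenotypes <- function(path, rms_range_check = TRUE) {
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("animal_id", "trait", "cg", "age", "breed")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("phenotype file missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tab$animal_id)) {
    abort(paste0("duplicate animal_id in phenotype file: ",
                 tab$animal_id[duplicated(tab$animal_id)][1]))
  }
  num_or_die <- function(x, what) {
    blank <- is.na(x) | x == "" | x == "NA"
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!blank & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("non-numeric ", what, " '", x[bad[1]], "' at row ", bad[1]))
    }
    out
  }
  trait <- num_or_die(tab$trait, "trait")
  age <- num_or_die(tab$age, "age")
  if (any(is.na(age))) abort("age must be non-missing for all animals")
  if (any(is.na(tab$cg) | tab$cg == "")) abort("cg must be non-missing for all animals")
  if (rms_range_check && any(!is.na(trait) & (trait < 0 | trait > 5))) {
    warn("trait values outside the 0-5 RMS scale found")
  }
  tibble(animal_id = tab$animal_id, trait = trait,
         cg = factor(tab$cg), age = age, breed = factor(tab$breed))
}

#' Read reference-panel subspecies labels
#'
#' TSV with columns `animal_id`, `subspecies` (one of "indicus", "taurus")
#' and `breed`.
#'
#' @param path path to the labels TSV.
#' @return a tibble.
#' @export
read_reference_labels <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("animal_id", "subspecies", "breed")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("labels file missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(tab$subspecies %in% c("indicus", "taurus"))) {
    abort("subspecies must be 'indicus' or 'taurus'")
  }
  tibble(animal_id = tab$animal_id,
         subspecies = factor(tab$subspecies, levels = c("indicus", "taurus")),
         breed = factor(tab$breed))
}

#' Write a tibble as a commented-header TSV
#'
#' All tabular outputs use plain TSV with leading '#' comment lines.
#'
#' @param x a data frame.
#' @param path output path.
#' @param comment optional character vector of comment lines (without '#').
#' @return `path`, invisibly.
#' @export
write_output_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
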