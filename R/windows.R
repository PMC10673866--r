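#' Partition a SNP map into fixed non-overlapping windows
#'
#' SNP are allocated to windows by physical position: a SNP at 1-based
#' position p on a chromosome falls in within-chromosome window index
#' floor((p - 1) / (window_kb * 1000)). The grid is anchored at bp 1 on every
#' chromosome and window bounds are reported 0-based half-open,
#' \[k*W, (k+1)*W). Windows containing no SNP are dropped; trailing partial
#' windows are kept.
#'
#' @param map a SNP map (see [validate_snp_map()]).
#' @param window_kb window length in kilobases (50, 100 and 250 are the usual
#'   choices; any positive integer is allowed).
#' @return a `window_set`: a tibble with columns `window` (1-based index over
#'   retained windows), `chrom`, `win_index` (within-chromosome grid index),
#'   `start_bp`, `end_bp`, `snp_start`, `snp_end` (contiguous range into map
#'   order) and `m` (SNP count), with the map and window_kb as attributes.
#' @export
build_windows <- function(map, window_kb) {
  map <- validate_snp_map(map)
  if (length(window_kb) != 1 || !is.finite(window_kb) || window_kb <= 0) {
    abort("window_kb must be a single positive number")
  }
  w_bp <- window_kb * 1000
  idx <- floor((map$pos_bp - 1) / w_bp)
  key <- paste(map$chrom, idx, sep = "\r")
  r <- rle(key)
  snp_end <- cumsum(r$lengths)
  snp_start <- snp_end - r$lengths + 1L
  chrom <- map$chrom[snp_start]
  win_index <- idx[snp_start]
  ws <- tibble(window = seq_along(snp_start),
               chrom = chrom,
               win_index = as.integer(win_index),
               start_bp = as.numeric(win_index) * w_bp,
               end_bp = (as.numeric(win_index) + 1) * w_bp,
               snp_start = as.integer(snp_start),
               snp_end = as.integer(snp_end),
               m = as.integer(r$lengths))
  attr(ws, "window_kb") <- window_kb
  attr(ws, "map") <- map
  class(ws) <- c("window_set", class(ws))
  ws
}

#' Within-chromosome window index of a position
#'
#' @param pos_bp 1-based physical position(s).
#' @param window_kb window length in kilobases.
#' @return integer window index (0-based within chromosome).
#' @export
window_index <- function(pos_bp, window_kb) {
  as.integer(floor((pos_bp - 1) / (window_kb * 1000)))
}

#' Mean SNP count per retained window
#'
#' @param ws a `window_set`.
#' @return arithmetic mean of the per-window SNP counts.
#' @export
mean_snps_per_window <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  mean(ws$m)
}

#' Encode per-animal haplotype variants per window
#'
#' Each haplotype copy's alleles over a window's SNP, in map order, form the
#' window's haplotype variant. Variants are coded as 0/1 character strings
#' (first SNP of the window leftmost), so a window of m SNP can carry up to
#' 2^m distinct codes at any m.
#'
#' @param g a `phased_genotypes` object.
#' @param ws a `window_set` built from the same map.
#' @return a `haplotype_codes` object: list with `animal_ids`, `windows`
#'   (the window set) and two character matrices `hap0`, `hap1`
#'   (animals x windows).
#' @export
encode_haplotypes <- function(g, ws) {
  stopifnot(inherits(g, "phased_genotypes"), inherits(ws, "window_set"))
  wmap <- attr(ws, "map")
  if (!identical(g$map$snp_id, wmap$snp_id) ||
      !identical(g$map$pos_bp, wmap$pos_bp) ||
      !identical(g$map$chrom, wmap$chrom)) {
    abort("genotype map does not match the map the window set was built from")
  }
  nw <- nrow(ws)
  n <- n_animals(g)
  code_block <- function(hap, a, b) {
    if (a == b) return(as.character(hap[, a]))
    do.call(paste0, as.data.frame(hap[, a:b, drop = FALSE]))
  }
  hap0 <- matrix("", n, nw)
  hap1 <- matrix("", n, nw)
  for (w in seq_len(nw)) {
    hap0[, w] <- code_block(g$hap0, ws$snp_start[w], ws$snp_end[w])
    hap1[, w] <- code_block(g$hap1, ws$snp_start[w], ws$snp_end[w])
  }
  dimnames(hap0) <- dimnames(hap1) <- list(g$animal_ids, NULL)
  structure(list(animal_ids = g$animal_ids, windows = ws, hap0 = hap0, hap1 = hap1),
            class = "haplotype_codes")
}

#' Decode a haplotype variant code back to alleles
#'
#' @param code a 0/1 character string code.
#' @return integer vector of alleles.
#' @export
decode_haplotype <- function(code) {
  as.integer(strsplit(code, "", fixed = TRUE)[[1]])
}

#' Tabulate reference-panel haplotype variant frequencies per subspecies
#'
#' Counts each distinct haplotype variant over haplotype copies (two per
#' animal) separately for the Bos indicus and Bos taurus reference animals,
#' and converts counts to within-subspecies frequencies. These frequencies
#' (pBi, pBt) drive the b-value origin assignment of target haplotypes.
#'
#' @param codes a `haplotype_codes` object for the reference panel.
#' @param labels reference labels tibble (`animal_id`, `subspecies`, `breed`);
#'   every coded animal must be labelled and both subspecies represented.
#' @return a `haplotype_freqs` tibble: `window`, `chrom`, `start_bp`,
#'   `end_bp`, `code`, `count_bi`, `count_bt`, `freq_bi`, `freq_bt`, with
#'   attributes `n_hap_bi`, `n_hap_bt` and the window set.
#' @export
reference_frequencies <- function(codes, labels) {
  stopifnot(inherits(codes, "haplotype_codes"))
  pos <- match(codes$animal_ids, labels$animal_id)
  if (anyNA(pos)) {
    abort(paste0("no subspecies label for animal ", codes$animal_ids[which(is.na(pos))[1]]))
  }
  sub <- as.character(labels$subspecies[pos])
  is_bi <- sub == "indicus"
  if (!any(is_bi) || all(is_bi)) {
    abort("reference panel must contain animals of both subspecies")
  }
  n_hap_bi <- 2L * sum(is_bi)
  n_hap_bt <- 2L * sum(!is_bi)
  ws <- codes$windows
  per_window <- lapply(seq_len(nrow(ws)), function(w) {
    bi_codes <- c(codes$hap0[is_bi, w], codes$hap1[is_bi, w])
    bt_codes <- c(codes$hap0[!is_bi, w], codes$hap1[!is_bi, w])
    all_codes <- sort(unique(c(bi_codes, bt_codes)))
    cb <- tabulate(match(bi_codes, all_codes), nbins = length(all_codes))
    ct <- tabulate(match(bt_codes, all_codes), nbins = length(all_codes))
    tibble(window = ws$window[w], chrom = ws$chrom[w],
           start_bp = ws$start_bp[w], end_bp = ws$end_bp[w],
           code = all_codes, count_bi = cb, count_bt = ct,
           freq_bi = cb / n_hap_bi, freq_bt = ct / n_hap_bt)
  })
  out <- dplyr::bind_rows(per_window)
  attr(out, "n_hap_bi") <- n_hap_bi
  attr(out, "n_hap_bt") <- n_hap_bt
  attr(out, "windows") <- ws
  class(out) <- c("haplotype_freqs", class(out))
  out
}

#' Export a haplotype frequency table as TSV
#'
#' Columns: chrom, window_start, window_end, code_hex (hexadecimal packing of
#' the 0/1 variant code, left-padded to full SNP length), code, counts and
#' frequencies per subspecies.
#'
#' @param freqs a `haplotype_freqs` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(freqs, path) {
  stopifnot(inherits(freqs, "haplotype_freqs"))
  out <- tibble(chrom = freqs$chrom, window_start = freqs$start_bp,
                window_end = freqs$end_bp,
                code_hex = vapply(freqs$code, code_to_hex, character(1)),
                code = freqs$code,
                count_bi = freqs$count_bi, count_bt = freqs$count_bt,
                freq_bi = freqs$freq_bi, freq_bt = freqs$freq_bt)
  write_output_tsv(out, path,
                   comment = c("haplotype variant frequencies per window and subspecies",
                               paste0("n_hap_bi=", attr(freqs, "n_hap_bi"),
                                      " n_hap_bt=", attr(freqs, "n_hap_bt"))))
}

code_to_hex <- function(code) {
  bits <- decode_haplotype(code)
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(rep(0L, pad), bits)
  nib <- matrix(bits, nrow = 4)
  vals <- as.integer(8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ])
  paste(format.hexmode(vals), collapse = "")
}
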