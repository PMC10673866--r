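# shared in-code fixtures and independent oracles

# a tiny deterministic genotype set: 3 animals x 6 SNP on two chromosomes
toy_genotypes <- function() {
  map <- tibble::tibble(
    snp_id = paste0("s", 1:6),
    chrom = c("1", "1", "1", "1", "2", "2"),
    pos_bp = c(5L, 60000L, 100000L, 100001L, 10L, 150000L),
    ref = "A", alt = "B")
  hap0 <- rbind(c(0L, 1L, 1L, 0L, 1L, 0L),
                c(1L, 1L, 0L, 0L, 0L, 0L),
                c(0L, 0L, 0L, 1L, 1L, 1L))
  hap1 <- rbind(c(0L, 1L, 0L, 1L, 1L, 1L),
                c(1L, 0L, 0L, 0L, 0L, 0L),
                c(0L, 0L, 0L, 1L, 1L, 1L))
  phased_genotypes(c("A1", "A2", "A3"), map, hap0, hap1)
}

# write a small VCF by hand (independent of write_phased_vcf)
write_toy_vcf <- function(path, gts, chrom = NULL, pos = NULL, ids = NULL,
                          samples = c("S1", "S2")) {
  nrec <- nrow(gts)
  chrom <- chrom %||% rep("1", nrec)
  pos <- pos %||% seq(100, by = 100, length.out = nrec)
  ids <- ids %||% paste0("v", seq_len(nrec))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrec), function(i) {
    paste(c(chrom[i], pos[i], ids[i], "A", "G", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Hamming distance between two 0/1 code strings
hd_brute <- function(a, b) {
  av <- as.integer(strsplit(a, "")[[1]])
  bv <- as.integer(strsplit(b, "")[[1]])
  sum(av != bv)
}

# Hudson-style Fst estimator on two haplotype allele matrices
# (rows = haplotypes, cols = SNP): ratio of averages, with the standard
# finite-sample correction in the numerator
fst_hudson <- function(h1, h2) {
  p1 <- colMeans(h1); p2 <- colMeans(h2)
  n1 <- nrow(h1); n2 <- nrow(h2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# deterministic small study used by several tests (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_snp = 600, n_chrom = 3, n_ref_bi = 50, n_ref_bt = 50,
                        n_target_per_breed = 30, n_qtl = 4, h2 = 0.5, seed = 42)
      cache <<- simulate_hybrid_study(cfg)
    }
    cache
  }
})

# null windows for false-positive accounting: not a QTL window and not an
# immediate same-chromosome neighbour of one (adjacent windows share the
# QTL's ancestry-class pattern and genuinely absorb signal)
null_windows <- function(ws, truewins) {
  truewins <- as.integer(truewins)
  nb <- unlist(lapply(truewins, function(w) {
    cand <- c(w - 1L, w, w + 1L)
    cand[cand >= 1 & cand <= nrow(ws) & ws$chrom[pmax(pmin(cand, nrow(ws)), 1)] == ws$chrom[w]]
  }))
  setdiff(ws$window, unique(nb))
}
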