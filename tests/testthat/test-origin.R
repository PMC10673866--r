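test_that("b-values follow pBi / (pBi + pBt)", {
  expect_equal(b_value(0.5, 0.5), 0.5)
  expect_equal(b_value(0.09, 0), 1.0)
  expect_equal(b_value(0.02, 0.08), 0.2)
  expect_error(b_value(0, 0), class = "boaqtl_unseen_haplotype")
  expect_error(b_value(-0.1, 0.5), "non-negative")
  # invariant to common positive scaling (counts vs frequencies)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(2); s <- runif(1, 0.1, 10)
    expect_equal(classify_haplotype(b_value(p[1], p[2])),
                 classify_haplotype(b_value(s * p[1], s * p[2])))
  }
})

test_that("the 0.5 threshold assigns the boundary to Bos indicus", {
  expect_equal(classify_haplotype(0.5), "Bi")
  expect_equal(classify_haplotype(0.4999), "Bt")
  expect_equal(classify_haplotype(1.0), "Bi")
  expect_equal(classify_haplotype(0), "Bt")
  expect_error(classify_haplotype(1.2), "\\[0, 1\\]")
})

test_that("diplotype classes combine the two haplotype origins", {
  expect_equal(classify_diplotype("Bi", "Bi"), "Bi")
  expect_equal(classify_diplotype("Bi", "Bt"), "Bx")
  expect_equal(classify_diplotype("Bt", "Bi"), "Bx")
  expect_equal(classify_diplotype("Bt", "Bt"), "Bt")
  expect_error(classify_diplotype("Bx", "Bi"), "'Bi' or 'Bt'")
})

test_that("Hamming fallback matches hand-evaluated sums in both modes", {
  # query 00; Bi refs {00, 00}; Bt refs {11}: sum(Bi)=0, sum(Bt)=2
  r <- hamming_fallback("00", "00", "11", counts_bi = 2L, counts_bt = 1L)
  expect_equal(r$sum_bi, 0); expect_equal(r$sum_bt, 2)
  expect_equal(r$prob_bi, 0)          # as printed: 0 / (0 + 2)
  expect_equal(r$assigned, "Bt")      # larger probability wins
  # same input in similarity mode: mean dist Bi = 0 < mean dist Bt = 2
  r2 <- hamming_fallback("00", "00", "11", counts_bi = 2L, counts_bt = 1L,
                         mode = "similarity")
  expect_equal(r2$assigned, "Bi")
  expect_equal(r2$prob_bi, 1)         # meanDist(Bt) / (0 + 2)
  # tie: equal sums give 0.5/0.5 and the documented Bi tie-break
  r3 <- hamming_fallback("01", "00", "11")
  expect_equal(r3$sum_bi, r3$sum_bt)
  expect_equal(r3$prob_bi, 0.5)
  expect_equal(r3$assigned, "Bi")
  # panel-size normalisation divides by copy totals before Eq-style ratio
  r4 <- hamming_fallback("00", c("01", "11"), "11",
                         counts_bi = c(4L, 4L), counts_bt = 2L, normalise = TRUE)
  expect_equal(r4$prob_bi, (12 / 8) / (12 / 8 + 4 / 2))
  # contract errors
  expect_error(hamming_fallback("00", character(0), "11"), "non-empty")
  expect_error(hamming_fallback("00", "0", "11"), "same length")
})

test_that("fallback sums agree with a brute-force distance count", {
  set.seed(9)
  for (i in 1:10) {
    m <- sample(3:8, 1)
    mk <- function(k) apply(matrix(sample(0:1, k * m, TRUE), k), 1, paste, collapse = "")
    q <- mk(1); rb <- mk(3); rt <- mk(2)
    cb <- sample(1:4, 3, TRUE); ct <- sample(1:4, 2, TRUE)
    r <- hamming_fallback(q, rb, rt, counts_bi = cb, counts_bt = ct)
    expect_equal(r$sum_bi, sum(vapply(rb, hd_brute, numeric(1), a = q) * cb))
    expect_equal(r$sum_bt, sum(vapply(rt, hd_brute, numeric(1), a = q) * ct))
  }
})

test_that("similarity-mode fallback is nearest-centroid when one panel is unanimous", {
  set.seed(21)
  m <- 6
  centre <- paste(sample(0:1, m, TRUE), collapse = "")
  flip <- function(code, k) {
    v <- as.integer(strsplit(code, "")[[1]])
    i <- sample(m, k); v[i] <- 1L - v[i]
    paste(v, collapse = "")
  }
  refs_bt <- vapply(1:5, function(i) flip(centre, sample(2:4, 1)), character(1))
  for (k in 0:2) {
    q <- flip(centre, k)  # close to the unanimous Bi panel
    r <- hamming_fallback(q, rep(centre, 3), refs_bt, mode = "similarity")
    d_bi <- hd_brute(q, centre)
    d_bt <- mean(vapply(refs_bt, hd_brute, numeric(1), a = q))
    expect_equal(r$assigned, if (d_bi <= d_bt) "Bi" else "Bt")
  }
})

test_that("assign_origins reproduces an exhaustive hand computation on a toy set", {
  map <- tibble::tibble(snp_id = paste0("s", 1:6), chrom = "1",
                        pos_bp = c(1L, 2L, 100001L, 100002L, 200001L, 200002L),
                        ref = "A", alt = "B")
  ws <- build_windows(map, 100)
  # reference: 2 indicus animals all-1 haplotypes, 2 taurus all-0
  ref <- phased_genotypes(paste0("r", 1:4), map,
                          rbind(rep(1L, 6), rep(1L, 6), rep(0L, 6), rep(0L, 6)),
                          rbind(rep(1L, 6), rep(1L, 6), rep(0L, 6), rep(0L, 6)))
  labels <- tibble::tibble(animal_id = paste0("r", 1:4),
                           subspecies = factor(c("indicus", "indicus", "taurus", "taurus"),
                                               levels = c("indicus", "taurus")),
                           breed = "x")
  freqs <- reference_frequencies(encode_haplotypes(ref, ws), labels)
  # four target animals x three windows, mixing seen and unseen variants
  tgt <- phased_genotypes(paste0("t", 1:4), map,
    rbind(c(1L, 1L, 0L, 0L, 1L, 1L),    # t1: Bi, Bt, Bi on hap0
          c(0L, 0L, 0L, 0L, 0L, 0L),    # t2: all Bt
          c(1L, 1L, 1L, 1L, 1L, 1L),    # t3: all Bi
          c(1L, 0L, 1L, 1L, 0L, 0L)),   # t4 hap0 w1: "10" unseen -> fallback
    rbind(c(1L, 1L, 1L, 1L, 1L, 1L),
          c(0L, 0L, 1L, 1L, 0L, 0L),
          c(1L, 1L, 1L, 1L, 1L, 1L),
          c(0L, 0L, 1L, 1L, 1L, 1L)))
  suppressMessages(calls <- assign_origins(encode_haplotypes(tgt, ws), freqs))
  expect_s3_class(calls, "origin_calls")
  got <- function(a, w) calls[calls$animal_id == a & calls$window == w, ]
  # t1: hap0 = Bi("11"), Bt("00"), Bi("11"); hap1 all Bi
  expect_equal(got("t1", 1)$diplotype, "Bi")
  expect_equal(got("t1", 2)$diplotype, "Bx")
  expect_equal(got("t1", 3)$diplotype, "Bi")
  expect_equal(got("t2", 1)$diplotype, "Bt")
  expect_equal(got("t2", 2)$diplotype, "Bx")
  expect_equal(got("t3", 1)$diplotype, "Bi")
  # t4 hap0 window 1 is "10": unseen in both panels, equidistant (1 vs 1)
  # from the all-1 and all-0 references -> tie -> Bi via the fallback
  t4 <- got("t4", 1)
  expect_equal(t4$source0, "hamming")
  expect_equal(t4$b0, 0.5)
  expect_equal(t4$hap0, "Bi")
  expect_equal(t4$source1, "frequency")
  expect_equal(t4$hap1, "Bt")
  expect_equal(t4$diplotype, "Bx")
  # diplotype is always consistent with the two haplotype calls
  expect_identical(calls$diplotype, classify_diplotype(calls$hap0, calls$hap1))
  # fallback fraction: exactly one of 24 haplotype assignments
  expect_equal(attr(calls, "fallback_fraction"), 1 / 24)
  # a window missing from the frequency table is an error
  expect_error(suppressMessages(assign_origins(encode_haplotypes(tgt, ws),
                                               freqs[freqs$window != 2, ])),
               "absent from frequency table")
})

test_that("indicus percentage summarises haplotype origin calls", {
  study <- small_study()
  ws <- study$windows
  freqs <- reference_frequencies(encode_haplotypes(study$ref, ws), study$labels)
  calls <- assign_origins(encode_haplotypes(study$target, ws), freqs,
                          mode = "similarity", quiet = TRUE)
  pct <- indicus_percentage(calls, breeds = study$breeds)
  expect_true(all(pct$pct_indicus >= 0 & pct$pct_indicus <= 100))
  # hand-built extremes: all copies Bi -> 100%, half the copies Bi -> 50%
  fake <- calls[calls$animal_id == calls$animal_id[1], ]
  fake$hap0 <- "Bi"; fake$hap1 <- "Bi"
  class(fake) <- class(calls)
  expect_equal(indicus_percentage(fake)$pct_indicus, 100)
  fake$hap1 <- "Bt"
  expect_equal(indicus_percentage(fake)$pct_indicus, 50)
  # per-SNP weighting reweights windows by marker count
  fake2 <- fake[1:2, ]
  fake2$m <- c(1L, 3L)
  fake2$hap0 <- c("Bi", "Bt"); fake2$hap1 <- c("Bi", "Bt")
  class(fake2) <- class(calls)
  expect_equal(indicus_percentage(fake2)$pct_indicus, 50)
  expect_equal(indicus_percentage(fake2, weighting = "per_snp")$pct_indicus, 25)
  # breed summary carries mean/sd/min/max
  bs <- breed_content_summary(pct)
  expect_setequal(as.character(bs$breed), as.character(unique(study$breeds$breed)))
  expect_true(all(bs$min <= bs$mean & bs$mean <= bs$max))
})
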