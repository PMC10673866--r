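#' Simulation configuration for a synthetic two-subspecies hybrid study
#'
#' Emulates the study design the package targets: two ancestral cattle
#' subspecies diverged to a given Fst, purebred reference panels from each,
#' and hybrid target breeds ranging from a graded-up (~90% indicus)
#' population to stabilised composites (~50% and ~37% indicus), with
#' origin-specific QTL effects and a lowly heritable trait.
#'
#' @param n_snp total SNP count across chromosomes.
#' @param n_chrom number of chromosomes (SNP split evenly).
#' @param snp_spacing_bp uniform marker spacing in bp.
#' @param window_kb haplotype window length the founder pools are organised
#'   by (the analysis should use the same window length).
#' @param n_ref_bi,n_ref_bt reference animals per subspecies.
#' @param breed_profiles tibble with `name`, `indicus_fraction`,
#'   `generations` (admixture age: higher = shorter ancestry tracts);
#'   defaults emulate the three study breeds at 0.90 / 0.50 / 0.37.
#' @param n_target_per_breed target animals per breed profile.
#' @param divergence_fst Balding-Nichols divergence between the subspecies'
#'   allele frequencies, default 0.3.
#' @param founder_pool_size distinct founder haplotypes per window per
#'   subspecies; panel and target haplotypes are copies of founders, which
#'   is what creates the within-subspecies haplotype sharing the frequency
#'   method relies on.
#' @param recomb_rate_per_bp Morgans per bp. The default 1e-7 is ten times
#'   the genomic 1 cM/Mb: the simulated genome is a few megabases rather
#'   than a few gigabases, and compressing the map keeps the number of
#'   independent ancestry blocks per animal (hence the between-animal
#'   spread of indicus fraction) at a realistic level for a multi-
#'   chromosome genome.
#' @param n_qtl number of QTL (each placed in a distinct window).
#' @param qtl_min_maf QTL are drawn among SNP with at least this minor
#'   allele frequency in both ancestral pools, so each origin-specific
#'   effect can actually segregate.
#' @param qtl_variance_fraction per-QTL share of the genetic variance:
#'   NULL (default) gives every QTL an equal 1/n_qtl share (effect triples
#'   are rescaled against the realised population so each locus contributes
#'   the same genetic variance); a numeric vector of length n_qtl gives
#'   custom shares (normalised to sum to 1); NA disables rescaling and
#'   leaves the raw standard-normal draws (variance shares then vary
#'   chi-square-like across QTL).
#' @param effect_correlation correlation of QTL effects across the three
#'   origin classes (0 = independent, the default assumption for long-
#'   diverged subspecies; 1 = identical effects).
#' @param h2 narrow-sense heritability of the simulated trait, default 0.20.
#' @param n_cg contemporary-group levels.
#' @param cg_sd contemporary-group effect standard deviation, in phenotypic
#'   standard deviations.
#' @param age_range age-at-measurement range in days.
#' @param age_slope_sd age covariate slope, in phenotypic standard
#'   deviations per 100 days.
#' @param seed master seed; every stage derives its own sub-stream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_snp = 2000, n_chrom = 5, snp_spacing_bp = 5000,
                       window_kb = 100,
                       n_ref_bi = 60, n_ref_bt = 60,
                       breed_profiles = tibble(
                         name = c("graded_indicus", "composite_50", "composite_37"),
                         indicus_fraction = c(0.90, 0.50, 0.37),
                         generations = c(10, 8, 8)),
                       n_target_per_breed = 100,
                       divergence_fst = 0.3,
                       founder_pool_size = 12,
                       recomb_rate_per_bp = 1e-7,
                       n_qtl = 10, qtl_min_maf = 0.1,
                       qtl_variance_fraction = NULL,
                       effect_correlation = 0,
                       h2 = 0.20, n_cg = 5, cg_sd = 0.5,
                       age_range = c(550, 650), age_slope_sd = 0.3,
                       seed = 1) {
  stopifnot(all(breed_profiles$indicus_fraction > 0 & breed_profiles$indicus_fraction < 1),
            h2 > 0, h2 <= 1, divergence_fst > 0, divergence_fst < 1,
            effect_correlation >= 0, effect_correlation <= 1)
  structure(list(n_snp = as.integer(n_snp), n_chrom = as.integer(n_chrom),
                 snp_spacing_bp = as.integer(snp_spacing_bp),
                 window_kb = window_kb,
                 n_ref_bi = as.integer(n_ref_bi), n_ref_bt = as.integer(n_ref_bt),
                 breed_profiles = as_tibble(breed_profiles),
                 n_target_per_breed = as.integer(n_target_per_breed),
                 divergence_fst = divergence_fst,
                 founder_pool_size = as.integer(founder_pool_size),
                 recomb_rate_per_bp = recomb_rate_per_bp,
                 n_qtl = as.integer(n_qtl), qtl_min_maf = qtl_min_maf,
                 qtl_variance_fraction = qtl_variance_fraction,
                 effect_correlation = effect_correlation,
                 h2 = h2, n_cg = as.integer(n_cg), cg_sd = cg_sd,
                 age_range = age_range, age_slope_sd = age_slope_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# named sub-streams off the master seed so each stage is independently
# reproducible; kept well below 2^31
derive_seed <- function(seed, stream) {
  offsets <- c(pools = 1L, panel = 2L, hybrids = 3L, effects = 4L, phenotypes = 5L)
  (abs(as.integer(seed)) %% 100000000L) * 10L + offsets[[stream]]
}

#' Simulate diverged ancestral allele-frequency pools and founder haplotypes
#'
#' Per-SNP subspecies allele frequencies are drawn from a Balding-Nichols
#' divergence model: a common ancestral frequency p ~ U(0.1, 0.9), then each
#' subspecies' frequency ~ Beta(p (1-F)/F, (1-p)(1-F)/F) at the configured
#' Fst. Per haplotype window, each subspecies gets a pool of
#' `founder_pool_size` founder haplotypes drawn SNP-wise from its
#' frequencies, with Dirichlet(1) pool weights; all simulated haplotypes are
#' copies (or recombination splices) of founders.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_pools` list: SNP `map`, per-subspecies frequency vectors
#'   `freq_bi` / `freq_bt`, the `window_set`, and per-window founder pools.
#' @export
simulate_ancestral_pools <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "pools"))
  per_chrom <- rep(cfg$n_snp %/% cfg$n_chrom, cfg$n_chrom)
  per_chrom[seq_len(cfg$n_snp %% cfg$n_chrom)] <- per_chrom[1] + 1L
  map <- dplyr::bind_rows(lapply(seq_len(cfg$n_chrom), function(cc) {
    m <- per_chrom[cc]
    tibble(snp_id = sprintf("snp_%d_%d", cc, seq_len(m)),
           chrom = as.character(cc),
           pos_bp = as.integer(cfg$snp_spacing_bp * seq_len(m)),
           ref = "A", alt = "B")
  }))
  F <- cfg$divergence_fst
  p_anc <- stats::runif(cfg$n_snp, 0.1, 0.9)
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  freq_bi <- stats::rbeta(cfg$n_snp, a, b)
  freq_bt <- stats::rbeta(cfg$n_snp, a, b)
  ws <- build_windows(map, cfg$window_kb)
  K <- cfg$founder_pool_size
  draw_pool <- function(freq_slice) {
    m <- length(freq_slice)
    matrix(stats::rbinom(K * m, 1, rep(freq_slice, each = K)), nrow = K)
  }
  founders <- lapply(seq_len(nrow(ws)), function(w) {
    idx <- ws$snp_start[w]:ws$snp_end[w]
    wt_bi <- as.numeric(stats::rgamma(K, 1)); wt_bi <- wt_bi / sum(wt_bi)
    wt_bt <- as.numeric(stats::rgamma(K, 1)); wt_bt <- wt_bt / sum(wt_bt)
    list(bi = draw_pool(freq_bi[idx]), bt = draw_pool(freq_bt[idx]),
         wt_bi = wt_bi, wt_bt = wt_bt)
  })
  structure(list(map = map, freq_bi = freq_bi, freq_bt = freq_bt,
                 windows = ws, founders = founders, cfg = cfg),
            class = "sim_pools")
}

# draw one haplotype for window w of subspecies sub ("bi"/"bt"); returns the
# founder row index
sample_founder <- function(pool, sub) {
  wt <- if (sub == "bi") pool$wt_bi else pool$wt_bt
  sample.int(length(wt), 1, prob = wt)
}

#' Simulate the purebred reference panel
#'
#' Each reference animal's two haplotype copies are, window by window,
#' founder haplotypes sampled from its subspecies' pool weights.
#'
#' @param cfg a [sim_config()].
#' @param pools output of [simulate_ancestral_pools()].
#' @return list with `genotypes` (`phased_genotypes`) and `labels`
#'   (reference label tibble).
#' @export
simulate_reference_panel <- function(cfg, pools) {
  stopifnot(inherits(pools, "sim_pools"))
  set.seed(derive_seed(cfg$seed, "panel"))
  ws <- pools$windows
  n_bi <- cfg$n_ref_bi; n_bt <- cfg$n_ref_bt
  n <- n_bi + n_bt
  subspecies <- c(rep("indicus", n_bi), rep("taurus", n_bt))
  ids <- c(sprintf("BI_REF_%03d", seq_len(n_bi)), sprintf("BT_REF_%03d", seq_len(n_bt)))
  hap0 <- matrix(0L, n, cfg$n_snp)
  hap1 <- matrix(0L, n, cfg$n_snp)
  for (w in seq_len(nrow(ws))) {
    idx <- ws$snp_start[w]:ws$snp_end[w]
    pool <- pools$founders[[w]]
    for (i in seq_len(n)) {
      sub <- if (subspecies[i] == "indicus") "bi" else "bt"
      fmat <- if (sub == "bi") pool$bi else pool$bt
      hap0[i, idx] <- fmat[sample_founder(pool, sub), ]
      hap1[i, idx] <- fmat[sample_founder(pool, sub), ]
    }
  }
  g <- phased_genotypes(ids, pools$map, hap0, hap1)
  labels <- tibble(animal_id = ids,
                   subspecies = factor(subspecies, levels = c("indicus", "taurus")),
                   breed = factor(ifelse(subspecies == "indicus", "ref_indicus", "ref_taurus")))
  list(genotypes = g, labels = labels)
}

# ancestry tract structure for one haplotype copy of one chromosome:
# a two-state continuous Markov switch process along bp. pi_bi is the
# stationary indicus fraction; switch intensity g * c per bp splits into
# Bi->Bt rate g*c*(1-pi) and Bt->Bi rate g*c*pi, so tract lengths shorten
# with admixture age while the stationary mix stays pi.
sim_tracts <- function(chrom_len_bp, pi_bi, generations, recomb_rate_per_bp) {
  rate_out_bi <- generations * recomb_rate_per_bp * (1 - pi_bi)
  rate_out_bt <- generations * recomb_rate_per_bp * pi_bi
  state <- if (stats::runif(1) < pi_bi) "Bi" else "Bt"
  pos <- 0
  starts <- numeric(0); states <- character(0)
  while (pos < chrom_len_bp) {
    starts <- c(starts, pos); states <- c(states, state)
    rate <- if (state == "Bi") rate_out_bi else rate_out_bt
    pos <- pos + stats::rexp(1, rate)
    state <- if (state == "Bi") "Bt" else "Bi"
  }
  list(start = starts, end = c(starts[-1], chrom_len_bp), state = states)
}

# majority-bp ancestry of [w0, w1) windows (vectorised over windows) under a
# tract list: F(x) = Bi bp accumulated in [0, x), evaluated at both bounds
window_majority_vec <- function(tracts, w0, w1) {
  is_bi <- tracts$state == "Bi"
  len <- tracts$end - tracts$start
  cum_bi <- c(0, cumsum(ifelse(is_bi, len, 0)))
  F_bi <- function(x) {
    x <- pmin(x, tracts$end[length(tracts$end)])  # cap at chromosome end
    i <- findInterval(x, tracts$start)
    cum_bi[i] + ifelse(is_bi[i], x - tracts$start[i], 0)
  }
  bi_bp <- F_bi(w1) - F_bi(w0)
  ifelse(bi_bp >= (w1 - w0) / 2, "Bi", "Bt")
}

#' Simulate the hybrid target population with tracked ancestry
#'
#' Each target haplotype is a mosaic of Bos indicus / Bos taurus ancestry
#' tracts from a two-state Markov switch process along the genome, calibrated
#' so the expected indicus fraction matches the breed profile and tract
#' lengths shorten with the profile's admixture age. Within a window, each
#' maximal same-ancestry run of SNP is copied from a founder haplotype of
#' that ancestry, so un-recombined windows carry exact founder variants and
#' windows straddling a switch carry novel spliced variants. Truth is
#' recorded per window and haplotype copy as the majority-bp tract ancestry.
#'
#' @param cfg a [sim_config()].
#' @param pools output of [simulate_ancestral_pools()].
#' @return list with `genotypes` (`phased_genotypes`), `breeds` (tibble
#'   animal_id, breed) and `truth` (tibble animal_id, window, chrom,
#'   start_bp, end_bp, ancestry0, ancestry1, diplotype).
#' @export
simulate_hybrids <- function(cfg, pools) {
  stopifnot(inherits(pools, "sim_pools"))
  set.seed(derive_seed(cfg$seed, "hybrids"))
  ws <- pools$windows
  map <- pools$map
  chroms <- unique(map$chrom)
  chrom_len <- vapply(chroms, function(cc) max(map$pos_bp[map$chrom == cc]) + cfg$snp_spacing_bp,
                      numeric(1))
  names(chrom_len) <- chroms
  win_by_chrom <- split(seq_len(nrow(ws)), ws$chrom)

  profiles <- cfg$breed_profiles
  n_per <- cfg$n_target_per_breed
  n_total <- nrow(profiles) * n_per
  hap0 <- matrix(0L, n_total, cfg$n_snp)
  hap1 <- matrix(0L, n_total, cfg$n_snp)
  anc0 <- matrix("", n_total, nrow(ws))
  anc1 <- matrix("", n_total, nrow(ws))
  ids <- character(n_total)
  breed <- character(n_total)

  pos_by_chrom <- split(map$pos_bp, factor(map$chrom, levels = chroms))
  fill_copy <- function(hap_row, anc_row, pi_bi, generations) {
    for (cc in chroms) {
      tr <- sim_tracts(chrom_len[[cc]], pi_bi, generations, cfg$recomb_rate_per_bp)
      # tract state at each SNP position (tracts are half-open [start, end))
      state_chrom <- tr$state[findInterval(pos_by_chrom[[cc]] - 0.5, tr$start)]
      wins <- win_by_chrom[[cc]]
      off <- ws$snp_start[wins[1]] - 1L
      anc_row[wins] <- window_majority_vec(tr, ws$start_bp[wins], ws$end_bp[wins])
      for (w in wins) {
        idx <- ws$snp_start[w]:ws$snp_end[w]
        snp_state <- state_chrom[idx - off]
        pool <- pools$founders[[w]]
        if (all(snp_state == snp_state[1])) {
          # common case: the whole window sits inside one ancestry tract
          sub <- if (snp_state[1] == "Bi") "bi" else "bt"
          fmat <- if (sub == "bi") pool$bi else pool$bt
          hap_row[idx] <- fmat[sample_founder(pool, sub), ]
        } else {
          runs <- rle(snp_state)
          at <- 1L
          for (r in seq_along(runs$lengths)) {
            len <- runs$lengths[r]
            sub <- if (runs$values[r] == "Bi") "bi" else "bt"
            fmat <- if (sub == "bi") pool$bi else pool$bt
            f <- sample_founder(pool, sub)
            hap_row[idx[at:(at + len - 1L)]] <- fmat[f, at:(at + len - 1L)]
            at <- at + len
          }
        }
      }
    }
    list(hap = hap_row, anc = anc_row)
  }

  row <- 0L
  for (b in seq_len(nrow(profiles))) {
    for (i in seq_len(n_per)) {
      row <- row + 1L
      ids[row] <- sprintf("%s_%03d", toupper(profiles$name[b]), i)
      breed[row] <- profiles$name[b]
      r0 <- fill_copy(hap0[row, ], anc0[row, ], profiles$indicus_fraction[b],
                      profiles$generations[b])
      hap0[row, ] <- r0$hap; anc0[row, ] <- r0$anc
      r1 <- fill_copy(hap1[row, ], anc1[row, ], profiles$indicus_fraction[b],
                      profiles$generations[b])
      hap1[row, ] <- r1$hap; anc1[row, ] <- r1$anc
    }
  }
  g <- phased_genotypes(ids, map, hap0, hap1)
  truth <- dplyr::bind_rows(lapply(seq_len(nrow(ws)), function(w) {
    tibble(animal_id = ids, window = ws$window[w], chrom = ws$chrom[w],
           start_bp = ws$start_bp[w], end_bp = ws$end_bp[w],
           ancestry0 = anc0[, w], ancestry1 = anc1[, w],
           diplotype = classify_diplotype(anc0[, w], anc1[, w]))
  }))
  list(genotypes = g,
       breeds = tibble(animal_id = ids, breed = factor(breed)),
       truth = truth)
}

#' Draw origin-specific QTL effects
#'
#' Picks `n_qtl` SNP in distinct windows (restricted to SNP with minor
#' allele frequency >= `qtl_min_maf` in both ancestral pools) and draws a
#' (Bi, Bt, Bx) effect triple per QTL from an exchangeable trivariate normal
#' with pairwise correlation `effect_correlation`: 0 gives independent
#' subspecies effects, 1 identical effects across origins.
#'
#' @param cfg a [sim_config()].
#' @param pools output of [simulate_ancestral_pools()].
#' @return tibble: `snp_index`, `snp_id`, `window`, `beta_bi`, `beta_bt`,
#'   `beta_bx`.
#' @export
assign_qtl_effects <- function(cfg, pools) {
  stopifnot(inherits(pools, "sim_pools"))
  set.seed(derive_seed(cfg$seed, "effects"))
  if (cfg$n_qtl == 0) {
    return(tibble(snp_index = integer(), snp_id = character(), window = integer(),
                  beta_bi = numeric(), beta_bt = numeric(), beta_bx = numeric()))
  }
  maf <- function(f) pmin(f, 1 - f)
  eligible <- which(maf(pools$freq_bi) >= cfg$qtl_min_maf &
                    maf(pools$freq_bt) >= cfg$qtl_min_maf)
  ws <- pools$windows
  win_of_snp <- rep(ws$window, times = ws$m)
  elig_win <- win_of_snp[eligible]
  wins <- unique(elig_win)
  if (length(wins) < cfg$n_qtl) abort("not enough eligible windows for the requested QTL count")
  chosen_wins <- sample(wins, cfg$n_qtl)
  snp_index <- vapply(chosen_wins, function(w) {
    cand <- eligible[elig_win == w]
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  rho <- cfg$effect_correlation
  z0 <- stats::rnorm(cfg$n_qtl)
  zz <- matrix(stats::rnorm(3 * cfg$n_qtl), ncol = 3)
  eff <- sqrt(rho) * z0 + sqrt(1 - rho) * zz
  tibble(snp_index = snp_index, snp_id = pools$map$snp_id[snp_index],
         window = as.integer(chosen_wins),
         beta_bi = eff[, 1], beta_bt = eff[, 2], beta_bx = eff[, 3])
}

#' Simulate phenotypes from true origin-specific breeding values
#'
#' The true breeding value routes each QTL's dosage through the effect of the
#' animal's TRUE window diplotype class (Bi, Bt or Bx), i.e. through the true
#' origin design matrix. Contemporary-group effects and an age covariate are
#' added, and the residual variance is set so the realised narrow-sense
#' heritability matches the configuration. With h2 = 1 the phenotype equals
#' the breeding value plus fixed effects exactly.
#'
#' @param g target `phased_genotypes`.
#' @param truth truth tibble from [simulate_hybrids()].
#' @param qtl effect tibble from [assign_qtl_effects()].
#' @param cfg a [sim_config()].
#' @param breeds tibble animal_id, breed.
#' @return list with `phenotypes` (tibble animal_id, trait, cg, age, breed),
#'   `tbv` (named true breeding values), `sigma_e2`, `fixed` (cg effects and
#'   age slope actually used).
#' @export
simulate_phenotypes <- function(g, truth, qtl, cfg, breeds) {
  stopifnot(inherits(g, "phased_genotypes"))
  set.seed(derive_seed(cfg$seed, "phenotypes"))
  n <- n_animals(g)
  tbv <- stats::setNames(numeric(n), g$animal_ids)
  if (nrow(qtl) > 0) {
    D <- dosage(g)
    contrib <- matrix(0, n, nrow(qtl))
    for (qi in seq_len(nrow(qtl))) {
      w <- qtl$window[qi]
      tw <- truth[truth$window == w, , drop = FALSE]
      cls <- tw$diplotype[match(g$animal_ids, tw$animal_id)]
      beta <- c(Bi = qtl$beta_bi[qi], Bt = qtl$beta_bt[qi], Bx = qtl$beta_bx[qi])[cls]
      contrib[, qi] <- D[, qtl$snp_index[qi]] * beta
    }
    vf <- cfg$qtl_variance_fraction
    if (is.null(vf) || !anyNA(vf)) {
      # rescale each QTL's effect triple so its realised contribution
      # carries the requested share of the genetic variance
      share <- if (is.null(vf)) rep(1 / nrow(qtl), nrow(qtl)) else vf / sum(vf)
      v_q <- apply(contrib, 2, stats::var)
      scale_q <- ifelse(v_q > 0, sqrt(share / pmax(v_q, 1e-300)), 0)
      # overall level is arbitrary before the h2-based residual scaling;
      # normalise so var(tbv) is O(1)
      contrib <- sweep(contrib, 2, scale_q, `*`)
      qtl$beta_bi <- qtl$beta_bi * scale_q
      qtl$beta_bt <- qtl$beta_bt * scale_q
      qtl$beta_bx <- qtl$beta_bx * scale_q
    }
    tbv <- tbv + rowSums(contrib)
  }
  var_tbv <- stats::var(tbv)
  sigma_e2 <- if (var_tbv > 0) var_tbv * (1 - cfg$h2) / cfg$h2 else 1
  sd_p <- sqrt(if (var_tbv > 0) var_tbv / cfg$h2 else 1)
  cg <- factor(sample(sprintf("cg%02d", seq_len(cfg$n_cg)), n, replace = TRUE))
  cg_eff <- stats::setNames(stats::rnorm(cfg$n_cg, 0, cfg$cg_sd * sd_p),
                            sprintf("cg%02d", seq_len(cfg$n_cg)))
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  age_slope <- cfg$age_slope_sd * sd_p / 100
  e <- if (cfg$h2 < 1) stats::rnorm(n, 0, sqrt(sigma_e2)) else numeric(n)
  trait <- 2.5 + cg_eff[as.character(cg)] + age_slope * (age - mean(cfg$age_range)) + tbv + e
  list(phenotypes = tibble(animal_id = g$animal_ids, trait = unname(trait),
                           cg = cg, age = age,
                           breed = breeds$breed[match(g$animal_ids, breeds$animal_id)]),
       tbv = tbv, qtl = qtl, sigma_e2 = if (cfg$h2 < 1) sigma_e2 else 0,
       fixed = list(cg_eff = cg_eff, age_slope = age_slope))
}

#' One-shot synthetic hybrid study
#'
#' Runs the full generator: ancestral pools, reference panel, hybrid targets
#' with tracked ancestry, QTL effects and phenotypes.
#'
#' @param cfg a [sim_config()].
#' @return list: `pools`, `ref` (genotypes), `labels`, `target` (genotypes),
#'   `breeds`, `truth`, `qtl`, `phenotypes`, `tbv`, `windows`, `map`, `cfg`.
#' @export
simulate_hybrid_study <- function(cfg = sim_config()) {
  pools <- simulate_ancestral_pools(cfg)
  ref <- simulate_reference_panel(cfg, pools)
  hyb <- simulate_hybrids(cfg, pools)
  qtl <- assign_qtl_effects(cfg, pools)
  phe <- simulate_phenotypes(hyb$genotypes, hyb$truth, qtl, cfg, hyb$breeds)
  list(pools = pools, ref = ref$genotypes, labels = ref$labels,
       target = hyb$genotypes, breeds = hyb$breeds, truth = hyb$truth,
       qtl = phe$qtl, phenotypes = phe$phenotypes, tbv = phe$tbv,
       sigma_e2 = phe$sigma_e2,
       windows = pools$windows, map = pools$map, cfg = cfg)
}
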