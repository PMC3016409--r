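test_that("configuration prior follows HWE founder terms and Mendelian transmissions", {
  freq <- c("3" = 0.3, "5" = 0.2, "0" = 0.5)
  # unequal founder pair: 2 * 0.3 * 0.2
  expect_equal(config_prior(cbind(3L, 5L), 0, freq), 0.12)
  # equal founder pair: 0.3^2
  expect_equal(config_prior(cbind(3L, 3L), 0, freq), 0.09)
  # trio: two heterozygous parents each transmit one haplotype (1/2 each)
  expect_equal(config_prior(rbind(c(3L, 5L), c(0L, 3L)), 2, freq),
               0.12 * (2 * 0.5 * 0.3) * 0.25)
  # absent haplotype has frequency zero
  expect_equal(config_prior(cbind(9L, 9L), 0, freq), 0)
})

test_that("double heterozygote alone is a stationary point with symmetric posteriors", {
  ind <- data.frame(fid = "S1", iid = "1", pat = "0", mat = "0",
                    sex = 0L, aff = 1L)
  res <- hap_resource(ind, matrix(1L, 1, 2), matrix(2L, 1, 2))
  ph <- phase_resource(res)
  expect_equal(sort(names(ph$freq)), c("0", "1", "2", "3"))
  expect_equal(unname(ph$freq), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(ph$mle$posterior, 0.5, tolerance = 1e-9)
})

test_that("fully phased individuals give counting proportions in one EM pass", {
  set.seed(3)
  n <- 40
  rp <- random_cc_resource(n, n_loci = 2, missing_rate = 0,
                           freq = c(0.4, 0.3, 0.2, 0.1))
  # make everyone unambiguous: homozygous or single-het individuals only
  keep <- (rp$h1 == rp$h2) | (bitwXor(rp$h1, rp$h2) %in% c(1L, 2L))
  res <- rp$resource
  res <- hap_resource(res$ind[keep, ], res$g1[keep, , drop = FALSE],
                      res$g2[keep, , drop = FALSE])
  ph <- phase_resource(res)
  hcount <- table(c(rp$h1[keep], rp$h2[keep]))
  want <- as.numeric(hcount) / sum(hcount)
  expect_equal(unname(ph$freq[names(hcount)]), want, tolerance = 1e-9)
})

test_that("pedigree EM on unrelated individuals matches an independent genotype-EM", {
  set.seed(5)
  for (rep in 1:5) {
    rp <- random_cc_resource(30, n_loci = 3, missing_rate = 0.1)
    res <- rp$resource
    ph <- phase_resource(res, min_genotyped_fraction = 0, tol = 1e-10,
                         max_iter = 5000)
    want <- oracle_em_unrelated(res$g1, res$g2)
    got <- ph$freq[names(want)]
    got[is.na(got)] <- 0
    expect_equal(unname(got), unname(want), tolerance = 1e-6)
  }
})

test_that("EM log-likelihood is monotone and frequencies stay a distribution", {
  set.seed(9)
  for (rep in 1:60) {
    kind <- sample(c("trio", "nuclear", "threegen", "mixed"), 1)
    rp <- random_ped_resource(kind, n_loci = sample(2:4, 1),
                              missing_rate = 0.2)
    ph <- phase_resource(rp$resource, min_genotyped_fraction = 0)
    expect_true(all(diff(ph$loglik) >= -1e-9),
                info = sprintf("rep %d: loglik not monotone", rep))
    expect_true(all(ph$freq >= 0))
    expect_equal(sum(ph$freq), 1, tolerance = 1e-9)
  }
})

test_that("likelihood and posteriors are invariant to allele relabelling", {
  set.seed(21)
  for (rep in 1:10) {
    rp <- random_ped_resource("nuclear", n_loci = 3, missing_rate = 0.15)
    res <- rp$resource
    ph <- phase_resource(res, min_genotyped_fraction = 0)
    # flip allele labels at one marker
    j <- sample(1:3, 1)
    flip <- function(a) ifelse(a == 0L, 0L, 3L - a)
    g1 <- res$g1; g2 <- res$g2
    g1[, j] <- flip(g1[, j]); g2[, j] <- flip(g2[, j])
    res2 <- hap_resource(res$ind, pmin(g1, g2), pmax(g1, g2))
    ph2 <- phase_resource(res2, min_genotyped_fraction = 0)
    expect_equal(ph$loglik[length(ph$loglik)],
                 ph2$loglik[length(ph2$loglik)], tolerance = 1e-6)
    # frequency spectrum is permuted, not changed
    expect_equal(sort(unname(ph$freq)), sort(unname(ph2$freq)),
                 tolerance = 1e-6)
  }
})

test_that("partition-ligation with zero cutoff reproduces the full EM", {
  set.seed(33)
  for (rep in 1:6) {
    rp <- random_cc_resource(25, n_loci = 7, missing_rate = 0.05)
    res <- rp$resource
    full <- phase_resource(res, partition_len = 10, tol = 1e-9,
                           max_iter = 5000)
    pl <- phase_resource(res, partition_len = 4, overlap = 1, cutoff = 0,
                         buffer = .Machine$integer.max, tol = 1e-9,
                         max_iter = 5000)
    common <- union(names(full$freq), names(pl$freq))
    f1 <- full$freq[common]; f1[is.na(f1)] <- 0
    f2 <- pl$freq[common]; f2[is.na(f2)] <- 0
    expect_equal(unname(f1), unname(f2), tolerance = 1e-6)
  }
})

test_that("pedigree-informed MLE pairs beat the pedigree-naive EM on family data", {
  set.seed(77)
  pool <- default_hap_pool(0.10, 5)
  model <- disease_model(pool$risk_hap, 0.10, grr = 1)
  spec <- design_spec("ASP", scale = 0.12, missing_rate = 0.10)
  wins <- 0; ties <- 0
  for (rep in 1:8) {
    sim <- simulate_design(spec, model, pool)
    informed <- phase_resource(sim$resource, method = "pedigree")
    naive <- phase_resource(sim$resource, method = "naive")
    tr <- sim$truth
    acc_i <- phasing_accuracy(informed, tr)
    acc_n <- phasing_accuracy(naive, tr)
    if (acc_i > acc_n) wins <- wins + 1
    if (acc_i == acc_n) ties <- ties + 1
  }
  # directional property: informed phasing should never lose, and should
  # win most replicates at 10% missingness
  expect_gte(wins + ties, 7)
  expect_gte(wins, 4)
})

test_that("default partition-ligation settings phase a 15-locus family resource", {
  set.seed(55)
  pool <- default_hap_pool(0.10, 15)
  model <- disease_model(pool$risk_hap, 0.10, grr = 1)
  sim <- simulate_design(design_spec("ASP", scale = 0.1,
                                     missing_rate = 0.05), model, pool)
  ph <- phase_resource(sim$resource)  # defaults: 5 / 1 / 1e-6 / 25
  expect_equal(ph$settings$partition_len, 5L)
  expect_equal(ph$settings$buffer, 25L)
  expect_equal(sum(ph$freq), 1, tolerance = 1e-9)
  expect_true(all(nchar(ph$freq_table$haplotype) == 15))
  acc_i <- phasing_accuracy(ph, sim$truth)
  acc_n <- phasing_accuracy(phase_resource(sim$resource, method = "naive"),
                            sim$truth)
  expect_gte(acc_i, acc_n)
  expect_gt(acc_i, 0.9)
})

test_that("MLE tie-breaking is deterministic across runs", {
  ind <- data.frame(fid = "S1", iid = "1", pat = "0", mat = "0",
                    sex = 0L, aff = 1L)
  res <- hap_resource(ind, matrix(1L, 1, 2), matrix(2L, 1, 2))
  p1 <- mle_pairs(phase_resource(res))
  p2 <- mle_pairs(phase_resource(res))
  expect_identical(p1, p2)
  # the lexicographically smallest of the two tied configurations: (12,21)
  # sorts before (11,22)? encoded pairs are {0,3} and {1,2}; (0,3) first
  expect_equal(c(p1$hap1, p1$hap2), c("11", "22"))
})
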