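test_that("trend statistic matches the closed form and stats::prop.trend.test", {
  # identical case/control distributions: statistic 0
  expect_equal(trend_test(rbind(c(10, 20, 5), c(10, 20, 5))), 0)
  # 2x2 reduction: cases (5,15,0), controls (15,5,0) -> 10.0
  expect_equal(trend_test(rbind(c(5, 15, 0), c(15, 5, 0))), 10.0)
  # random tables match the standard implementation
  set.seed(2)
  for (rep in 1:30) {
    tab <- matrix(rpois(6, 12) + 1, 2, 3)
    want <- unname(stats::prop.trend.test(tab[1, ], colSums(tab),
                                          score = 0:2)$statistic)
    expect_equal(trend_test(tab), want, tolerance = 1e-10)
  }
  expect_warning(trend_test(rbind(c(10, 0, 0), c(20, 0, 0))),
                 "monomorphic")
})

test_that("chi-square and odds ratio match textbook formulas", {
  tab <- matrix(c(20, 10, 10, 20), 2, 2, byrow = TRUE)
  expect_equal(as.numeric(odds_ratio(tab)), 4.0)
  want <- unname(stats::chisq.test(tab, correct = FALSE)$statistic)
  expect_equal(chi_square(tab), want, tolerance = 1e-12)
  # symmetric table
  sym <- matrix(c(15, 15, 15, 15), 2, 2)
  expect_equal(as.numeric(odds_ratio(sym)), 1.0)
  expect_equal(chi_square(sym), 0)
  # zero cell: Haldane correction, flagged
  z <- matrix(c(10, 0, 5, 5), 2, 2, byrow = TRUE)
  or <- odds_ratio(z)
  expect_true(attr(or, "corrected"))
  expect_equal(as.numeric(or), (10.5 * 5.5) / (0.5 * 5.5))
  set.seed(4)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 15) + 1, 2, 2)
    expect_equal(chi_square(tab),
                 unname(stats::chisq.test(tab, correct = FALSE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("pseudocontrols are the untransmitted parental haplotypes", {
  # father (A,B), mother (C,D), case (C, A) -> pseudocontrol (D, B)
  expect_equal(generate_pseudocontrol(c(1L, 2L), c(5L, 6L), 5L, 1L),
               c(6L, 2L))
  # homozygous father (A,A)
  expect_equal(generate_pseudocontrol(c(1L, 1L), c(5L, 6L), 6L, 1L),
               c(5L, 1L))
  expect_error(generate_pseudocontrol(c(1L, 2L), c(5L, 6L), 7L, 1L),
               "do not match")
  # conservation on simulated trios: case + pseudocontrol = all four
  # parental haplotypes, as a multiset
  set.seed(6)
  ok <- vapply(1:10000, function(rep) {
    fa <- sample(0:7, 2, replace = TRUE)
    mo <- sample(0:7, 2, replace = TRUE)
    cm <- sample(mo, 1); cp <- sample(fa, 1)
    pc <- generate_pseudocontrol(fa, mo, cm, cp)
    identical(sort(c(cm, cp, pc)), sort(c(fa, mo)))
  }, logical(1))
  expect_true(all(ok))
})

trio_resource_known <- function() {
  # father 22/22, mother 11/11, child het at both loci -> fully phased
  ind <- data.frame(fid = "T1", iid = c("F", "M", "C"),
                    pat = c("0", "0", "F"), mat = c("0", "0", "M"),
                    sex = c(1L, 2L, 0L), aff = c(1L, 1L, 2L))
  g1 <- rbind(c(2, 2), c(1, 1), c(1, 1))
  g2 <- rbind(c(2, 2), c(1, 1), c(2, 2))
  hap_resource(ind, g1, g2)
}

test_that("control selection implements the EC and PC rules", {
  res <- trio_resource_known()
  ph <- phase_resource(res)
  ec <- select_controls(res, ph, "EC")
  expect_equal(sum(ec$role == "case"), 1)
  expect_equal(sum(ec$role == "control"), 2)  # both parents explicit
  pc <- select_controls(res, ph, "PC")
  expect_equal(sum(pc$role == "case"), 1)
  expect_equal(sum(pc$role == "control"), 0)  # parents consumed
  expect_equal(sum(pc$role == "pseudocontrol"), 1)
  # pseudocontrol = untransmitted pair = (11, 22) again (parents hom)
  pcr <- pc[pc$role == "pseudocontrol", ]
  expect_setequal(c(pcr$h1, pcr$h2), c(0L, 3L))
  # case counts are identical in both modes
  expect_equal(sum(ec$role == "case"), sum(pc$role == "case"))
})

test_that("PC mode equals EC mode when there are no parents", {
  set.seed(8)
  rp <- random_cc_resource(20, n_loci = 2)
  ph <- phase_resource(rp$resource)
  ec <- select_controls(rp$resource, ph, "EC")
  pc <- select_controls(rp$resource, ph, "PC")
  expect_identical(ec, pc)
})

test_that("PC mode on trios replaces two parental controls by one pseudocontrol", {
  set.seed(10)
  pool <- default_hap_pool(0.10, 5)
  model <- disease_model(pool$risk_hap, 0.10, grr = 1.5)
  sim <- simulate_design(design_spec("TRIO", scale = 0.06), model, pool)
  ph <- phase_resource(sim$resource)
  ec <- select_controls(sim$resource, ph, "EC")
  pc <- select_controls(sim$resource, ph, "PC")
  n_pc <- sum(pc$role == "pseudocontrol")
  expect_gt(n_pc, 0)
  expect_equal(sum(pc$role == "case"), sum(ec$role == "case"))
  expect_equal(sum(pc$role != "case"),
               sum(ec$role != "case") - 2 * n_pc + n_pc)
  # exposure-table margins: total copies across exhaustive targets equals
  # twice the subject count
  loci <- 1:5
  total <- 0
  for (t in unique(c(pc$h1, pc$h2))) {
    d <- hapmc:::exposure_diploid(pc, t, loci)
    total <- total + sum(d * matrix(rep(0:2, each = 2), 2))
  }
  expect_equal(total, 2 * nrow(pc))
})

test_that("TDT counts informative transmissions from the MLE configuration", {
  # father het (12, 11 at locus 1): informative for target "2x"
  ind <- data.frame(fid = "T1", iid = c("F", "M", "C"),
                    pat = c("0", "0", "F"), mat = c("0", "0", "M"),
                    sex = c(1L, 2L, 0L), aff = c(1L, 1L, 2L))
  # father 12/11 -> haplotypes {11,21}; mother 11/11; child 12/11
  g1 <- rbind(c(1, 1), c(1, 1), c(1, 1))
  g2 <- rbind(c(2, 1), c(1, 1), c(2, 1))
  res <- hap_resource(ind, g1, g2)
  ph <- phase_resource(res)
  # target = "21" (allele 2 at locus 1): father transmitted it
  stat <- tdt(res, ph, str_to_hap("21"), 1:2)
  expect_equal(attr(stat, "b"), 1L)
  expect_equal(attr(stat, "c"), 0L)
  expect_equal(as.numeric(stat), 1)
  # closed form: b=10, c=5 -> 25/15
  expect_equal((10 - 5)^2 / (10 + 5), 5 / 3)
  # ASP family: each affected sib counts once per informative parent
  ind2 <- data.frame(fid = "A1", iid = c("F", "M", "C1", "C2"),
                     pat = c("0", "0", "F", "F"),
                     mat = c("0", "0", "M", "M"),
                     sex = c(1L, 2L, 0L, 0L), aff = c(1L, 1L, 2L, 2L))
  g1 <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  g2 <- rbind(c(2, 1), c(1, 1), c(2, 1), c(1, 1))
  res2 <- hap_resource(ind2, g1, g2)
  ph2 <- phase_resource(res2)
  stat2 <- tdt(res2, ph2, str_to_hap("21"), 1:2)
  # father transmitted 21 to C1 (b) and 11 to C2 (c): (1-1)^2/2 = 0
  expect_equal(attr(stat2, "b"), 1L)
  expect_equal(attr(stat2, "c"), 1L)
  expect_equal(as.numeric(stat2), 0)
})

test_that("statistics are invariant to subject order", {
  set.seed(12)
  rp <- random_cc_resource(30, n_loci = 3)
  res <- rp$resource
  perm <- sample(nrow(res$ind))
  res2 <- hap_resource(res$ind[perm, ], res$g1[perm, , drop = FALSE],
                       res$g2[perm, , drop = FALSE])
  ph <- phase_resource(res)
  ph2 <- phase_resource(res2)
  target <- names(sort(ph$freq, decreasing = TRUE))[1]
  tstr <- hap_to_str(as.integer(target), 3)
  sp <- analysis_spec("trend", "EC", target = tstr, n_null = 5)
  s1 <- hapmc:::compute_statistic(res, ph, sp)
  s2 <- hapmc:::compute_statistic(res2, ph2, sp)
  expect_equal(s1, s2, tolerance = 1e-9)
})
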