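test_that("dSNP conditionals preserve the marginal frequency and target r2", {
  m <- disease_model("21111", q = 0.1, r2 = 0.8, grr = 1.5)
  cond <- dsnp_conditionals(m)
  expect_equal(unname(cond["p_risk"]), 0.1 + sqrt(0.8) * 0.9,
               tolerance = 1e-12)
  expect_equal(unname(cond["p_other"]), 0.1 * (1 - sqrt(0.8)),
               tolerance = 1e-12)
  # marginal allele frequency equals q
  expect_equal(unname(0.1 * cond["p_risk"] + 0.9 * cond["p_other"]), 0.1,
               tolerance = 1e-12)
  # perfect LD collapses to the haplotype indicator
  m1 <- disease_model("21111", q = 0.1, r2 = 1, grr = 1.5)
  expect_equal(unname(dsnp_conditionals(m1)), c(1, 0), tolerance = 1e-12)
  # empirical r2 over simulated founder chromosomes
  set.seed(30)
  n <- 1e5
  risk <- runif(n) < 0.1
  d <- ifelse(risk, runif(n) < cond["p_risk"], runif(n) < cond["p_other"])
  r2_hat <- cor(risk, d)^2
  expect_lt(abs(r2_hat - 0.8), 3 * 2 * 0.8 * sqrt(2 / n) + 0.02)
  expect_equal(r2_hat, 0.8, tolerance = 0.05)
})

test_that("the packaged pool is a valid frequency table at any truncation", {
  for (nl in c(4, 5, 10, 15)) {
    pool <- default_hap_pool(0.07, nl)
    expect_length(pool$freq, 15)
    expect_equal(sum(pool$freq), 1, tolerance = 1e-12)
    expect_equal(unname(pool$freq[pool$risk_hap]), 0.07)
    expect_false(anyDuplicated(names(pool$freq)) > 0)
    expect_true(all(nchar(names(pool$freq)) == nl))
  }
})

test_that("penetrance is multiplicative in dSNP allele count", {
  m <- disease_model("21111", q = 0.1, grr = 2.0, sporadic = 0.05)
  expect_equal(hapmc:::penetrance(0:2, m), c(0.05, 0.10, 0.20))
  expect_error(disease_model("21111", q = 0.1, grr = 5, sporadic = 0.05),
               "infeasible")
})

test_that("TRIO design produces ascertained case-parent trios with hidden truth", {
  set.seed(31)
  pool <- default_hap_pool(0.10, 5)
  model <- disease_model(pool$risk_hap, 0.10, grr = 2.0)
  sim <- simulate_design(design_spec("TRIO", scale = 0.04), model, pool)
  res <- sim$resource
  expect_equal(length(unique(res$ind$fid)), 20)
  expect_equal(nrow(res$ind), 60)
  kids <- res$ind$pat != "0"
  expect_true(all(res$ind$aff[kids] == 2L))
  # hidden truth is Mendelian-consistent: each child haplotype is parental
  for (i in which(kids)) {
    fa <- which(res$ind$fid == res$ind$fid[i] & res$ind$iid == res$ind$pat[i])
    mo <- which(res$ind$fid == res$ind$fid[i] & res$ind$iid == res$ind$mat[i])
    expect_true(sim$truth$h1[i] %in% c(sim$truth$h1[mo], sim$truth$h2[mo]))
    expect_true(sim$truth$h2[i] %in% c(sim$truth$h1[fa], sim$truth$h2[fa]))
  }
  # genotypes equal the truth haplotypes
  expect_equal(res$g1[1, ] + res$g2[1, ],
               hapmc:::pair_genotype(sim$truth$h1[1], sim$truth$h2[1], 5) + 2L)
})

test_that("ASP and CC designs hit their subject targets", {
  set.seed(32)
  pool <- default_hap_pool(0.10, 5)
  model <- disease_model(pool$risk_hap, 0.10, grr = 1.5)
  asp <- simulate_design(design_spec("ASP", scale = 0.04), model, pool)
  expect_equal(length(unique(asp$resource$ind$fid)), 10)
  expect_equal(nrow(asp$resource$ind), 40)  # 2 parents + 2 affected sibs
  sibs <- asp$resource$ind$pat != "0"
  expect_true(all(asp$resource$ind$aff[sibs] == 2L))
  cc <- simulate_design(design_spec("CC", scale = 0.1), model, pool)
  expect_equal(sum(cc$resource$ind$aff == 2L), 50)
  expect_equal(sum(cc$resource$ind$aff == 1L), 50)
})

test_that("cases are enriched for the risk haplotype monotonically in GRR", {
  set.seed(33)
  pool <- default_hap_pool(0.10, 5)
  risk <- hapmc::str_to_hap(pool$risk_hap)
  ors <- vapply(c(1.2, 1.5, 2.0), function(grr) {
    model <- disease_model(pool$risk_hap, 0.10, grr = grr)
    mean(vapply(1:6, function(r) {
      sim <- simulate_design(design_spec("CC", scale = 1), model, pool)
      aff <- sim$resource$ind$aff
      carrier <- sim$truth$h1 == risk | sim$truth$h2 == risk
      t <- table(factor(aff == 2L, c(TRUE, FALSE)),
                 factor(carrier, c(TRUE, FALSE)))
      (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
  expect_gt(ors[3], 1.3)
})

test_that("null generator keeps risk-haplotype frequency equal in cases and controls", {
  set.seed(34)
  pool <- default_hap_pool(0.10, 5)
  null_model <- disease_model(pool$risk_hap, 0.10, grr = 1)
  risk <- hapmc::str_to_hap(pool$risk_hap)
  pvals <- vapply(1:15, function(i) {
    sim <- simulate_design(design_spec("CC", scale = 0.5), null_model, pool)
    aff <- sim$resource$ind$aff
    copies <- (sim$truth$h1 == risk) + (sim$truth$h2 == risk)
    suppressWarnings(stats::chisq.test(
      table(aff, copies > 0))$p.value)
  }, numeric(1))
  expect_gt(min(p.adjust(pvals, "bonferroni")), 0.01)
})

test_that("missing-data injection hits the target rate and spares untyped rows", {
  set.seed(35)
  pool <- default_hap_pool(0.10, 5)
  model <- disease_model(pool$risk_hap, 0.10, grr = 1)
  sim <- simulate_design(design_spec("CC", scale = 1), model, pool)
  res0 <- sim$resource
  expect_identical(inject_missing(res0, 0)$g1, res0$g1)
  res <- inject_missing(res0, 0.15)
  frac <- mean(res$g1 == 0L)
  n <- length(res$g1)
  expect_lt(abs(frac - 0.15), 3 * sqrt(0.15 * 0.85 / n))
})

test_that("large pedigrees are five-generation, ascertained, with missing top generations", {
  set.seed(36)
  pool <- default_hap_pool(0.10, 5)
  model <- disease_model(pool$risk_hap, 0.10, grr = 2.0)
  spec <- design_spec("LP2", scale = 0.05, min_cases = 8)
  sim <- simulate_design(spec, model, pool)
  res <- sim$resource
  tpl <- hapmc:::lp_template()
  expect_equal(max(tpl$gen), 5L)
  fids <- unique(res$ind$fid)
  for (f in fids) {
    rows <- which(res$ind$fid == f)
    expect_gte(sum(res$ind$aff[rows] == 2L), 8)
    # top two generations untyped and phenotype-unknown
    top <- rows[match(tpl$iid[tpl$gen <= 2L], res$ind$iid[rows])]
    expect_true(all(res$g1[top, ] == 0L))
    expect_true(all(res$ind$aff[top] == 0L))
  }
  # control composition: parents and siblings of cases dominate controls
  ctrl <- res$ind$aff == 1L
  expect_gt(sum(ctrl), 0)
  # gene-dropped truth is Mendelian-consistent wherever typed
  kids <- which(res$ind$pat != "0" & !is.na(sim$truth$h1))
  for (i in kids) {
    mo <- which(res$ind$fid == res$ind$fid[i] &
                  res$ind$iid == res$ind$mat[i])
    if (!is.na(sim$truth$h1[mo])) {
      expect_true(sim$truth$h1[i] %in% c(sim$truth$h1[mo],
                                         sim$truth$h2[mo]))
    }
  }
})
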