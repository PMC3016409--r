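test_that("genotype loading fills the six bit-variables as in the worked example", {
  # genotypes 12 00 11 12 22 over 5 loci
  s <- load_phase_state(c(1L, 0L, 1L, 1L, 2L), c(2L, 0L, 1L, 2L, 2L))
  bits <- function(x) paste(as.integer(x), collapse = "")
  expect_equal(bits(s$hom), "00101")
  expect_equal(bits(s$het), "10010")
  expect_equal(bits(s$unph), "10010")
  for (k in 1:2) {
    expect_equal(bits(s$set[k, ]), "00101")
    expect_equal(bits(s$mis[k, ]), "01000")
    expect_equal(bits(s$val[k, ]), "00001")
  }
  # all-missing individual
  s0 <- load_phase_state(c(0L, 0L), c(0L, 0L))
  expect_false(any(s0$hom) || any(s0$het) || any(s0$unph) || any(s0$set))
  expect_true(all(s0$mis))
  # fully homozygous individual: phased at load
  s1 <- load_phase_state(c(1L, 1L), c(1L, 1L))
  expect_false(any(s1$unph))
  expect_true(all(s1$set))
  expect_false(any(s1$val))
})

make_trio_res <- function(g1, g2) {
  ind <- data.frame(fid = "F1", iid = c("F", "M", "C"),
                    pat = c("0", "0", "F"), mat = c("0", "0", "M"),
                    sex = c(1L, 2L, 0L), aff = 1L)
  hap_resource(ind, g1, g2)
}

test_that("parental homozygosity resolves offspring phase and vice versa", {
  # mother hom 11/11, father het 12/12, child het 12/12:
  # child maternal haplotype forced to 11, paternal to 22; father phased
  res <- make_trio_res(rbind(c(1, 1), c(1, 1), c(1, 1)),
                       rbind(c(2, 2), c(1, 1), c(2, 2)))
  sp <- split_pedigree(res, "F1", 0.5)
  ctx <- run_preprocessing(res, "F1", sp$fragments[[1]])
  for (id in c("F", "M", "C")) {
    expect_false(any(ctx$states[[id]]$unph), info = id)
    expect_true(all(ctx$states[[id]]$set), info = id)
  }
  subs <- hapmc:::build_substructures(res, 0.5)
  expect_length(subs$classes, 1)
  expect_equal(nrow(subs$classes[[1]]$tab$mat), 1)  # fully determined
  # child hom 22 at a locus resolves the transmitted parental haplotype
  res2 <- make_trio_res(rbind(c(1, 1), c(1, 2), c(2, 2)),
                        rbind(c(2, 2), c(2, 2), c(2, 2)))
  sp2 <- split_pedigree(res2, "F1", 0.5)
  ctx2 <- run_preprocessing(res2, "F1", sp2$fragments[[1]])
  # mother het at locus 1 must now be phased: transmitted hap carries 2
  expect_false(any(ctx2$states[["M"]]$unph))
})

test_that("preprocessing flags Mendelian inconsistencies with a diagnostic", {
  # parent hom 11, child hom 22 at the same locus
  res <- make_trio_res(rbind(c(1, 1), c(1, 1), c(2, 1)),
                       rbind(c(1, 1), c(1, 1), c(2, 1)))
  sp <- split_pedigree(res, "F1", 0.5)
  expect_error(run_preprocessing(res, "F1", sp$fragments[[1]]),
               class = "hapmc_mendel_error")
})

test_that("preprocessing is idempotent and leaves only truly ambiguous loci", {
  set.seed(41)
  for (rep in 1:40) {
    kind <- sample(c("trio", "nuclear", "threegen"), 1)
    rp <- random_ped_resource(kind, n_loci = sample(2:4, 1),
                              missing_rate = 0.15)
    res <- rp$resource
    sp <- split_pedigree(res, "F1", 0)
    if (length(sp$fragments) == 0) next
    ctx1 <- run_preprocessing(res, "F1", sp$fragments[[1]])
    ctx2 <- run_preprocessing(res, "F1", sp$fragments[[1]])
    # a second full run changes nothing beyond what the first reached
    for (id in names(ctx1$states)) {
      expect_equal(ctx1$states[[id]][c("set", "mis", "val", "unph")],
                   ctx2$states[[id]][c("set", "mis", "val", "unph")])
    }
    # deductions are consistent with the raw genotypes: reconstructed
    # genotype at set loci equals the input
    rows <- which(res$ind$fid == "F1")
    for (id in names(ctx1$states)) {
      r <- rows[match(id, res$ind$iid[rows])]
      s <- ctx1$states[[id]]
      both <- s$set[1, ] & s$set[2, ]
      g_in <- res$g1[r, ] + res$g2[r, ]  # 2,3,4 or 0 for missing
      g_st <- as.integer(s$val[1, ]) + as.integer(s$val[2, ]) + 2L
      known <- both & res$g1[r, ] != 0L
      expect_true(all(g_st[known] == g_in[known]))
    }
  }
})

test_that("pedigree splitting retains, detaches, and excludes per the genotyping threshold", {
  # fully typed trio is one retained substructure
  res <- make_trio_res(rbind(c(1, 1), c(1, 1), c(1, 1)),
                       rbind(c(2, 2), c(1, 1), c(1, 2)))
  sp <- split_pedigree(res, "F1", 0.5)
  expect_length(sp$fragments, 1)
  expect_setequal(sp$fragments[[1]]$members, c("F", "M", "C"))
  # both parents untyped: child detached, parents excluded
  res2 <- make_trio_res(rbind(c(0, 0), c(0, 0), c(1, 1)),
                        rbind(c(0, 0), c(0, 0), c(1, 2)))
  sp2 <- split_pedigree(res2, "F1", 0.5)
  expect_length(sp2$fragments, 0)
  expect_equal(sp2$detached, "C")
  expect_setequal(sp2$excluded, c("F", "M"))
  # three-generation pedigree with untyped grandparents: typed nuclear
  # family retained, grandparents excluded
  ind <- data.frame(fid = "F1",
                    iid = c("GF", "GM", "F", "M", "C1"),
                    pat = c("0", "0", "GF", "0", "F"),
                    mat = c("0", "0", "GM", "0", "M"),
                    sex = 0L, aff = 1L)
  g1 <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 2), c(1, 1))
  g2 <- rbind(c(0, 0), c(0, 0), c(1, 2), c(2, 2), c(1, 2))
  res3 <- hap_resource(ind, g1, g2)
  sp3 <- split_pedigree(res3, "F1", 0.5)
  expect_length(sp3$fragments, 1)
  expect_setequal(sp3$fragments[[1]]$members, c("F", "M", "C1"))
  expect_setequal(sp3$excluded, c("GF", "GM"))
})
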