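#' @title Synthetic study resources
#' @description
#' Generates case-control, case-parent trio, affected-sib-pair, and large
#' five-generation pedigree resources for power and validity studies.
#' Founder chromosomes are drawn from a population haplotype frequency
#' table; a hidden disease SNP (dSNP) allele is assigned to each founder
#' chromosome conditional on whether it carries the designated risk
#' haplotype, calibrated so the squared correlation between the
#' risk-haplotype indicator and the dSNP risk allele equals a target r^2.
#' Descendant chromosomes are gene-dropped (zero recombination, dSNP
#' linked).  Disease status follows a multiplicative penetrance model,
#' P(affected | g copies of the dSNP risk allele) = sporadic * GRR^g.
#' The dSNP is stripped from the returned resource; the hidden truth
#' (true phases and dSNP genotypes) is kept separately for accuracy
#' scoring.
#' @name simgen
NULL

# Packaged haplotype pool: 15 haplotypes over 15 biallelic markers with
# distinct 4-locus prefixes (so truncation to >= 4 loci preserves all 15
# haplotypes and the risk-haplotype frequency).  Pairwise marker r^2 in
# the pool is low, mimicking a regional tagging-SNP panel.
POOL_HAPS <- c(
  "111112122121211",
  "211121211212112",
  "121122112122121",
  "112212221211212",
  "111221212212221",
  "221111122221122",
  "212122221112211",
  "211212112121221",
  "122121221212112",
  "121211212221211",
  "112122121122122",
  "222121211211121",
  "221212122112212",
  "212211211221121",
  "122212212112221")
POOL_BASE_FREQ <- c(0.13, 0.12, 0.11, 0.10, 0.09, 0.08, 0.07, 0.06, 0.05,
                    0.05, 0.04, 0.04, 0.03, 0.02, 0.01)
POOL_RISK_INDEX <- 2L

#' Packaged haplotype frequency pool
#'
#' @param q frequency assigned to the designated risk haplotype; the other
#'   14 haplotypes are rescaled to sum to 1 - q.
#' @param n_loci number of leading loci to keep (4..15).
#' @return list with `freq` (named numeric, names are haplotype strings),
#'   `risk_hap` (string), and `n_loci`.
#' @export
default_hap_pool <- function(q = 0.10, n_loci = 15L) {
  stopifnot(q > 0, q < 1, n_loci >= 4, n_loci <= 15)
  haps <- substr(POOL_HAPS, 1L, n_loci)
  if (anyDuplicated(haps)) stop("internal: pool prefixes collide")
  f <- POOL_BASE_FREQ
  f[POOL_RISK_INDEX] <- 0
  f <- f / sum(f) * (1 - q)
  f[POOL_RISK_INDEX] <- q
  names(f) <- haps
  list(freq = f, risk_hap = haps[POOL_RISK_INDEX], n_loci = n_loci)
}

#' Disease model
#'
#' @param risk_hap risk haplotype allele string.
#' @param q risk-haplotype population frequency.
#' @param r2 squared correlation between the risk-haplotype indicator and
#'   the dSNP risk allele across chromosomes (default 0.8).
#' @param grr multiplicative genotypic relative risk per dSNP risk allele.
#' @param sporadic baseline penetrance for zero risk alleles (default
#'   0.05).
#' @return a `disease_model` object.
#' @export
disease_model <- function(risk_hap, q, r2 = 0.8, grr = 1.5,
                          sporadic = 0.05) {
  stopifnot(q > 0, q < 1, r2 > 0, r2 <= 1, grr >= 1, sporadic > 0)
  if (grr^2 * sporadic > 1) {
    stop("infeasible model: GRR^2 * sporadic exceeds 1")
  }
  structure(list(risk_hap = risk_hap, q = q, r2 = r2, grr = grr,
                 sporadic = sporadic), class = "disease_model")
}

#' dSNP conditional allele probabilities
#'
#' The dSNP marginal risk-allele frequency is set equal to the
#' risk-haplotype frequency q, which makes r = sqrt(r2) the sole LD
#' parameter: D = r * q * (1 - q), so P(A | risk) = q + r (1 - q) and
#' P(A | other) = q (1 - r).
#'
#' @param model a [disease_model].
#' @return named numeric: `p_risk`, `p_other`.
#' @export
dsnp_conditionals <- function(model) {
  r <- sqrt(model$r2)
  p_risk <- model$q + r * (1 - model$q)
  p_other <- model$q * (1 - r)
  if (p_risk > 1 + 1e-12 || p_other < -1e-12) {
    stop("infeasible dSNP conditional probabilities")
  }
  c(p_risk = min(p_risk, 1), p_other = max(p_other, 0))
}

#' Design specification for simulated resources
#'
#' @param design `"CC"`, `"TRIO"`, `"ASP"`, `"LP1"`, or `"LP2"`.
#' @param scale multiplies the default subject targets (500 cases / 500
#'   controls for CC; 500 trios; 250 sib-pair families; ~500 cases with
#'   ~1000 (LP1) or ~500 (LP2) controls).
#' @param missing_rate per-genotype missing probability applied to typed
#'   individuals.
#' @param min_cases large-pedigree ascertainment: minimum affected count
#'   (default 14).
#' @param max_attempts bound on rejection-sampling attempts.
#' @return a `design_spec` object.
#' @export
design_spec <- function(design = c("CC", "TRIO", "ASP", "LP1", "LP2"),
                        scale = 1, missing_rate = 0, min_cases = 14L,
                        max_attempts = 1e6) {
  design <- match.arg(design)
  stopifnot(scale > 0, missing_rate >= 0, missing_rate < 1)
  structure(list(design = design, scale = scale,
                 missing_rate = missing_rate,
                 min_cases = as.integer(min_cases),
                 max_attempts = max_attempts),
            class = "design_spec")
}

# draw k founder chromosomes: haplotype index + dSNP allele (0/1)
draw_chromosomes <- function(k, pool_haps, pool_freq, risk_int, cond) {
  h <- sample(pool_haps, k, replace = TRUE, prob = pool_freq)
  p <- ifelse(h == risk_int, cond["p_risk"], cond["p_other"])
  d <- as.integer(stats::runif(k) < p)
  list(h = h, d = d)
}

penetrance <- function(g, model) {
  pmin(1, model$sporadic * model$grr^g)
}

#' Simulate a study resource
#'
#' Draws founder chromosomes from the pool, gene-drops descendants,
#' assigns affection by the multiplicative penetrance model, applies the
#' design's ascertainment, strips the dSNP, and injects missing data.
#' Setting `grr = 1` in the model gives the null (genotypes independent
#' of phenotype).  For null large-pedigree simulations, supply
#' `lp_cluster_model`: phenotypes then cluster according to that
#' alternative model while the returned genotypes are re-dropped
#' independently of phenotype.
#'
#' @param spec a [design_spec].
#' @param model a [disease_model]; its `risk_hap` must be in the pool at
#'   frequency `q`.
#' @param pool a haplotype pool from [default_hap_pool()] (or of the same
#'   shape).
#' @param lp_cluster_model optional [disease_model] used only to generate
#'   phenotype clustering in null LP simulations.
#' @return list with `resource` (a [hap_resource]) and `truth`
#'   (data.frame of true haplotypes `h1`/`h2` and dSNP allele counts,
#'   aligned with the resource rows).
#' @export
simulate_design <- function(spec, model, pool = default_hap_pool(model$q),
                            lp_cluster_model = NULL) {
  stopifnot(inherits(spec, "design_spec"), inherits(model, "disease_model"))
  if (!model$risk_hap %in% names(pool$freq)) {
    stop("risk haplotype absent from the pool")
  }
  if (abs(pool$freq[[model$risk_hap]] - model$q) > 1e-9) {
    stop("pool frequency of the risk haplotype does not match q")
  }
  nl <- pool$n_loci
  pool_haps <- str_to_hap(names(pool$freq))
  risk_int <- str_to_hap(model$risk_hap)
  cond <- dsnp_conditionals(model)
  out <- switch(spec$design,
    CC = sim_cc(spec, model, pool_haps, pool$freq, risk_int, cond),
    TRIO = sim_nuclear(spec, model, pool_haps, pool$freq, risk_int, cond,
                       n_kids = 1L,
                       n_fam = round(500 * spec$scale)),
    ASP = sim_nuclear(spec, model, pool_haps, pool$freq, risk_int, cond,
                      n_kids = 2L,
                      n_fam = round(250 * spec$scale)),
    LP1 = sim_lp(spec, model, pool_haps, pool$freq, risk_int, cond,
                 control_ratio = 2, lp_cluster_model),
    LP2 = sim_lp(spec, model, pool_haps, pool$freq, risk_int, cond,
                 control_ratio = 1, lp_cluster_model))
  res <- build_resource(out$ind, out$h1, out$h2, nl)
  if (spec$missing_rate > 0) {
    res <- inject_missing(res, spec$missing_rate)
  }
  truth <- data.frame(fid = out$ind$fid, iid = out$ind$iid,
                      h1 = out$h1, h2 = out$h2,
                      dsnp = out$d1 + out$d2, stringsAsFactors = FALSE)
  list(resource = res, truth = truth)
}

# assemble a hap_resource from true haplotypes; untyped individuals
# (h1 = NA) get fully missing genotypes
build_resource <- function(ind, h1, h2, nl) {
  n <- length(h1)
  g1 <- matrix(0L, n, nl)
  g2 <- matrix(0L, n, nl)
  ok <- !is.na(h1)
  for (j in seq_len(nl)) {
    a <- hap_bit(h1[ok], j) + 1L
    b <- hap_bit(h2[ok], j) + 1L
    g1[ok, j] <- pmin(a, b)
    g2[ok, j] <- pmax(a, b)
  }
  hap_resource(ind, g1, g2)
}

sim_cc <- function(spec, model, pool_haps, pool_freq, risk_int, cond) {
  n_cases <- round(500 * spec$scale)
  n_controls <- round(500 * spec$scale)
  h1 <- integer(0); h2 <- integer(0); d1 <- integer(0); d2 <- integer(0)
  aff <- integer(0)
  got_case <- 0L; got_ctrl <- 0L
  attempts <- 0
  while (got_case < n_cases || got_ctrl < n_controls) {
    attempts <- attempts + 1
    if (attempts > spec$max_attempts) {
      stop("case-control ascertainment failed after ", spec$max_attempts,
           " attempts")
    }
    ch <- draw_chromosomes(2L, pool_haps, pool_freq, risk_int, cond)
    g <- sum(ch$d)
    affected <- stats::runif(1) < penetrance(g, model)
    if (affected && got_case < n_cases) {
      got_case <- got_case + 1L
    } else if (!affected && got_ctrl < n_controls) {
      got_ctrl <- got_ctrl + 1L
    } else next
    h1 <- c(h1, ch$h[1]); h2 <- c(h2, ch$h[2])
    d1 <- c(d1, ch$d[1]); d2 <- c(d2, ch$d[2])
    aff <- c(aff, if (affected) 2L else 1L)
  }
  n <- length(h1)
  ind <- data.frame(fid = paste0("CC", seq_len(n)), iid = "1",
                    pat = "0", mat = "0", sex = 0L, aff = aff,
                    stringsAsFactors = FALSE)
  list(ind = ind, h1 = h1, h2 = h2, d1 = d1, d2 = d2)
}

# TRIO (1 affected child) and ASP (2 affected children) nuclear families;
# parental phenotypes are drawn from the penetrance model unconditionally
sim_nuclear <- function(spec, model, pool_haps, pool_freq, risk_int, cond,
                        n_kids, n_fam) {
  ind <- NULL
  h1 <- integer(0); h2 <- integer(0); d1 <- integer(0); d2 <- integer(0)
  fam <- 0L
  attempts <- 0
  while (fam < n_fam) {
    attempts <- attempts + 1
    if (attempts > spec$max_attempts) {
      stop("family ascertainment failed after ", spec$max_attempts,
           " attempts")
    }
    fa <- draw_chromosomes(2L, pool_haps, pool_freq, risk_int, cond)
    mo <- draw_chromosomes(2L, pool_haps, pool_freq, risk_int, cond)
    ki <- lapply(seq_len(n_kids), function(k) {
      i <- sample.int(2L, 1L)
      j <- sample.int(2L, 1L)
      list(h = c(mo$h[i], fa$h[j]), d = c(mo$d[i], fa$d[j]))
    })
    kid_aff <- vapply(ki, function(k)
      stats::runif(1) < penetrance(sum(k$d), model), logical(1))
    if (!all(kid_aff)) next
    fam <- fam + 1L
    fid <- sprintf("%s%d", if (n_kids == 1) "TR" else "ASP", fam)
    pa_aff <- vapply(list(fa, mo), function(p)
      if (stats::runif(1) < penetrance(sum(p$d), model)) 2L else 1L,
      integer(1))
    rows <- data.frame(
      fid = fid,
      iid = c("F", "M", paste0("C", seq_len(n_kids))),
      pat = c("0", "0", rep("F", n_kids)),
      mat = c("0", "0", rep("M", n_kids)),
      sex = c(1L, 2L, rep(0L, n_kids)),
      aff = c(pa_aff, rep(2L, n_kids)),
      stringsAsFactors = FALSE)
    ind <- rbind(ind, rows)
    h1 <- c(h1, fa$h[1], mo$h[1], vapply(ki, function(k) k$h[1], integer(1)))
    h2 <- c(h2, fa$h[2], mo$h[2], vapply(ki, function(k) k$h[2], integer(1)))
    d1 <- c(d1, fa$d[1], mo$d[1], vapply(ki, function(k) k$d[1], integer(1)))
    d2 <- c(d2, fa$d[2], mo$d[2], vapply(ki, function(k) k$d[2], integer(1)))
  }
  list(ind = ind, h1 = h1, h2 = h2, d1 = d1, d2 = d2)
}

# ---- large pedigrees --------------------------------------------------

# Five-generation template: one G1 couple; 4 G2 children with spouses;
# 3 children per G3 couple; 2 per G4 couple; 2 per G5 sibship (leaves).
lp_template <- function() {
  ind <- data.frame(iid = c("g1f", "g1m"), pat = "0", mat = "0",
                    sex = c(1L, 2L), gen = 1L, married_in = TRUE,
                    stringsAsFactors = FALSE)
  add <- function(ind, iid, pat, mat, sex, gen, married_in = FALSE) {
    rbind(ind, data.frame(iid = iid, pat = pat, mat = mat, sex = sex,
                          gen = gen, married_in = married_in,
                          stringsAsFactors = FALSE))
  }
  couples <- list(c("g1f", "g1m"))
  nid <- 0L
  for (gen in 2:5) {
    per <- c(NA, 4L, 3L, 2L, 2L)[gen]
    new_couples <- list()
    for (cp in couples) {
      for (k in seq_len(per)) {
        nid <- nid + 1L
        kid <- paste0("i", nid)
        sex <- if (k %% 2 == 0) 2L else 1L
        ind <- add(ind, kid, cp[1], cp[2], sex, gen)
        if (gen < 5) {
          nid <- nid + 1L
          sp <- paste0("s", nid)
          ind <- add(ind, sp, "0", "0", if (sex == 1L) 2L else 1L, gen,
                     married_in = TRUE)
          new_couples[[length(new_couples) + 1]] <-
            if (sex == 1L) c(kid, sp) else c(sp, kid)
        }
      }
    }
    couples <- new_couples
  }
  ind
}

# Gene-drop chromosomes over the template; returns h1/h2 (maternal,
# paternal for non-founders), dSNP alleles.
lp_drop <- function(tpl, pool_haps, pool_freq, risk_int, cond) {
  n <- nrow(tpl)
  h1 <- integer(n); h2 <- integer(n); d1 <- integer(n); d2 <- integer(n)
  done <- rep(FALSE, n)
  idx <- function(iid) match(iid, tpl$iid)
  repeat {
    todo <- which(!done)
    if (length(todo) == 0) break
    for (i in todo) {
      if (tpl$pat[i] == "0") {
        ch <- draw_chromosomes(2L, pool_haps, pool_freq, risk_int, cond)
        h1[i] <- ch$h[1]; h2[i] <- ch$h[2]
        d1[i] <- ch$d[1]; d2[i] <- ch$d[2]
        done[i] <- TRUE
      } else {
        fa <- idx(tpl$pat[i]); mo <- idx(tpl$mat[i])
        if (done[fa] && done[mo]) {
          mi <- sample.int(2L, 1L); pi <- sample.int(2L, 1L)
          h1[i] <- c(h1[mo], h2[mo])[mi]; d1[i] <- c(d1[mo], d2[mo])[mi]
          h2[i] <- c(h1[fa], h2[fa])[pi]; d2[i] <- c(d1[fa], d2[fa])[pi]
          done[i] <- TRUE
        }
      }
    }
  }
  list(h1 = h1, h2 = h2, d1 = d1, d2 = d2)
}

sim_lp <- function(spec, model, pool_haps, pool_freq, risk_int, cond,
                   control_ratio, lp_cluster_model = NULL) {
  tpl <- lp_template()
  target_cases <- round(500 * spec$scale)
  target_controls <- round(500 * control_ratio * spec$scale)
  pheno_model <- if (!is.null(lp_cluster_model)) lp_cluster_model else model
  pheno_cond <- dsnp_conditionals(pheno_model)
  ind <- NULL
  h1 <- integer(0); h2 <- integer(0); d1 <- integer(0); d2 <- integer(0)
  tot_cases <- 0L; tot_controls <- 0L
  fam <- 0L
  attempts <- 0
  while (tot_cases < target_cases || tot_controls < target_controls) {
    attempts <- attempts + 1
    if (attempts > spec$max_attempts) {
      stop("large-pedigree ascertainment failed after ", spec$max_attempts,
           " attempts (min_cases = ", spec$min_cases, ")")
    }
    dr <- lp_drop(tpl, pool_haps, pool_freq, risk_int, pheno_cond)
    aff <- ifelse(stats::runif(nrow(tpl)) <
                    penetrance(dr$d1 + dr$d2, pheno_model), 2L, 1L)
    if (sum(aff == 2L) < spec$min_cases) next
    if (!is.null(lp_cluster_model)) {
      # null LP: phenotypes cluster per the alternative model above, but
      # the analysed genotypes are dropped independently of phenotype
      dr <- lp_drop(tpl, pool_haps, pool_freq, risk_int, cond)
    }
    fam <- fam + 1L
    picked <- sample_lp_controls(tpl, aff, target_controls - tot_controls,
                                 control_ratio)
    top2 <- tpl$gen <= 2L
    typed <- !top2 & (aff == 2L | picked)
    status <- ifelse(aff == 2L, 2L, ifelse(picked, 1L, 0L))
    status[top2] <- 0L
    rows <- data.frame(fid = paste0("LP", fam), iid = tpl$iid,
                       pat = tpl$pat, mat = tpl$mat, sex = tpl$sex,
                       aff = status, stringsAsFactors = FALSE)
    ind <- rbind(ind, rows)
    h1 <- c(h1, ifelse(typed, dr$h1, NA_integer_))
    h2 <- c(h2, ifelse(typed, dr$h2, NA_integer_))
    d1 <- c(d1, dr$d1); d2 <- c(d2, dr$d2)
    tot_cases <- tot_cases + sum(status == 2L & !top2)
    tot_controls <- tot_controls + sum(picked & !top2)
  }
  list(ind = ind, h1 = h1, h2 = h2, d1 = d1, d2 = d2)
}

# Sample family controls: ~80% close relatives of an affected individual
# (50% parents, 30% siblings) and ~20% beyond first degree.
sample_lp_controls <- function(tpl, aff, still_needed, control_ratio) {
  n <- nrow(tpl)
  unaff <- aff == 1L & tpl$gen > 2L
  cases <- which(aff == 2L)
  case_ids <- tpl$iid[cases]
  is_parent <- tpl$iid %in% c(tpl$pat[cases], tpl$mat[cases])
  sibkey <- paste(tpl$pat, tpl$mat)
  case_sibkeys <- sibkey[cases][tpl$pat[cases] != "0"]
  is_sib <- tpl$pat != "0" & sibkey %in% case_sibkeys & aff != 2L
  want <- min(still_needed, round(control_ratio * sum(aff == 2L)))
  quota <- c(parent = 0.5, sib = 0.3, distant = 0.2) * want
  pools <- list(parent = which(unaff & is_parent),
                sib = which(unaff & is_sib & !is_parent),
                distant = which(unaff & !is_parent & !is_sib))
  picked <- logical(n)
  taken <- 0L
  for (cls in c("parent", "sib", "distant")) {
    k <- min(round(quota[[cls]]), length(pools[[cls]]))
    if (k > 0) {
      picked[sample(pools[[cls]], k)] <- TRUE
      taken <- taken + k
    }
  }
  # fill any shortfall from remaining unaffected
  if (taken < want) {
    rest <- which(unaff & !picked)
    k <- min(want - taken, length(rest))
    if (k > 0) picked[sample(rest, k)] <- TRUE
  }
  picked
}

#' Inject missing genotypes
#'
#' Sets each (typed individual, marker) genotype missing independently
#' with the given probability; already-missing genotypes are unchanged.
#'
#' @param res a [hap_resource].
#' @param rate missing probability in \[0, 1).
#' @return the modified resource.
#' @export
inject_missing <- function(res, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(res)
  drop <- matrix(stats::runif(length(res$g1)) < rate, nrow(res$g1))
  res$g1[drop] <- 0L
  res$g2[drop] <- 0L
  res
}
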