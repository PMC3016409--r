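#' @title Association statistics on MLE-phased data
#' @description
#' Haplotype, sub-haplotype, and single-SNP association statistics
#' computed from MLE haplotype pairs: Cochran-Armitage trend (diploid
#' copy-count coding with scores 0/1/2), Pearson chi-square and odds ratio
#' (haploid chromosome-based or diploid carrier-collapsed coding), and the
#' transmission/disequilibrium test.  Controls are either explicit (EC:
#' every genotyped unaffected individual) or pseudocontrols (PC: for each
#' affected case whose parents are both genotyped and unaffected, the two
#' untransmitted parental haplotypes replace the parents' explicit-control
#' roles).  These statistics are pure test statistics: significance always
#' comes from the gene-dropping Monte Carlo null, never from asymptotic
#' distributions.
#' @name assoc_stats
NULL

#' Analysis specification
#'
#' @param statistic one of `"trend"`, `"chisq"`, `"odds_ratio"`, `"tdt"`.
#' @param controls `"EC"` (explicit) or `"PC"` (pseudocontrols where
#'   available); ignored by the TDT.
#' @param coding `"haploid"` (chromosome-based) or `"diploid"`
#'   (individual-based); the trend test is always diploid, the TDT is
#'   transmission-based.
#' @param loci 1-based marker indices defining the locus subset (`NULL` =
#'   all markers).
#' @param target target haplotype as an allele string over `loci`.
#' @param n_null number of Monte Carlo null configurations.
#' @param seed RNG seed for the Monte Carlo run.
#' @param min_genotyped_fraction per-individual genotyping threshold.
#' @return an `analysis_spec` object.
#' @export
analysis_spec <- function(statistic = c("trend", "chisq", "odds_ratio",
                                        "tdt"),
                          controls = c("EC", "PC"),
                          coding = c("haploid", "diploid"),
                          loci = NULL, target, n_null = 1000L, seed = 1L,
                          min_genotyped_fraction = 0.5) {
  statistic <- match.arg(statistic)
  controls <- match.arg(controls)
  coding <- match.arg(coding)
  if (n_null < 1) stop("n_null must be at least 1")
  stopifnot(is.character(target), length(target) == 1)
  structure(list(statistic = statistic, controls = controls,
                 coding = coding, loci = loci, target = target,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 min_genotyped_fraction = min_genotyped_fraction),
            class = "analysis_spec")
}

#' Project a haplotype pair onto a locus subset
#'
#' @param hap1,hap2 haplotype allele strings (full length).
#' @param loci 1-based locus indices.
#' @return character vector of the two projected haplotypes.
#' @export
extract_subhaplotype <- function(hap1, hap2, loci) {
  h <- str_to_hap(c(hap1, hap2))
  hap_to_str(hap_project(h, loci), length(loci))
}

#' Pseudocontrol haplotype pair
#'
#' The pseudocontrol for a case consists of the two parental haplotypes
#' not transmitted to the case: the case pair and the pseudocontrol pair
#' together equal the multiset of the four parental haplotypes.
#'
#' @param father_pair,mother_pair integer vectors of length 2 (encoded
#'   haplotypes).
#' @param case_mat,case_pat the case's maternal and paternal haplotypes as
#'   assigned by the MLE configuration.
#' @return integer vector: (untransmitted maternal, untransmitted
#'   paternal).
#' @export
generate_pseudocontrol <- function(father_pair, mother_pair, case_mat,
                                   case_pat) {
  if (!case_mat %in% mother_pair || !case_pat %in% father_pair) {
    stop("case haplotypes do not match the parental pairs")
  }
  um <- if (mother_pair[1] == case_mat) mother_pair[2] else mother_pair[1]
  up <- if (father_pair[1] == case_pat) father_pair[2] else father_pair[1]
  c(um, up)
}

# ---- subject roles ----------------------------------------------------

#' Select cases and controls from a phased resource
#'
#' Cases are all affected genotyped individuals.  In EC mode every
#' genotyped unaffected individual is an explicit control.  In PC mode,
#' each affected case whose parents are both genotyped and unaffected and
#' whose transmissions are resolved by the MLE configuration contributes
#' one pseudocontrol that replaces those two parents' explicit-control
#' roles; all other unaffected individuals remain explicit controls.
#'
#' @param res a [hap_resource].
#' @param phasing a `hap_phasing` of `res`.
#' @param mode `"EC"` or `"PC"`.
#' @return data.frame with columns `fid`, `iid`, `role`
#'   ("case"/"control"/"pseudocontrol"), and encoded haplotypes `h1`,
#'   `h2`.
#' @export
select_controls <- function(res, phasing, mode = c("EC", "PC")) {
  mode <- match.arg(mode)
  m <- phasing$mle
  ind <- res$ind
  genotyped <- !is.na(m$h1)
  keys <- ind_key(ind$fid, ind$iid)
  fid_v <- character(0); iid_v <- character(0); role_v <- character(0)
  h1_v <- integer(0); h2_v <- integer(0)
  consumed <- character(0)  # parents replaced by pseudocontrols
  if (mode == "PC") {
    fa_row <- match(ind_key(ind$fid, ind$pat), keys)
    mo_row <- match(ind_key(ind$fid, ind$mat), keys)
    for (i in which(genotyped & ind$aff == 2L & ind$pat != "0")) {
      fa <- fa_row[i]
      mo <- mo_row[i]
      if (!genotyped[fa] || !genotyped[mo]) next
      if (ind$aff[fa] != 1L || ind$aff[mo] != 1L) next
      # transmission must be resolved by the MLE configuration: the case
      # was phased as a child in the same substructure as both parents
      if (!m$ordered[i] || is.na(m$sub_id[i]) ||
          m$sub_id[i] != m$sub_id[fa] || m$sub_id[i] != m$sub_id[mo]) next
      pc <- generate_pseudocontrol(c(m$h1[fa], m$h2[fa]),
                                   c(m$h1[mo], m$h2[mo]),
                                   m$h1[i], m$h2[i])
      fid_v <- c(fid_v, ind$fid[i])
      iid_v <- c(iid_v, paste0(ind$iid[i], ":pc"))
      role_v <- c(role_v, "pseudocontrol")
      h1_v <- c(h1_v, pc[1]); h2_v <- c(h2_v, pc[2])
      consumed <- union(consumed, keys[c(fa, mo)])
    }
  }
  is_case <- genotyped & ind$aff == 2L
  is_ctrl <- genotyped & ind$aff == 1L & !(keys %in% consumed)
  sel <- c(which(is_case), which(is_ctrl))
  data.frame(fid = c(fid_v, ind$fid[sel]),
             iid = c(iid_v, ind$iid[sel]),
             role = c(role_v, rep(c("case", "control"),
                                  c(sum(is_case), sum(is_ctrl)))),
             h1 = c(h1_v, m$h1[sel]), h2 = c(h2_v, m$h2[sel]),
             stringsAsFactors = FALSE)
}

# ---- exposure tables --------------------------------------------------

# Diploid 2x3 (case/control x copies of target) and haploid 2x2
# (case/control chromosomes x target/other) count tables.
exposure_diploid <- function(subjects, target_proj, loci) {
  cp1 <- hap_project(subjects$h1, loci)
  cp2 <- hap_project(subjects$h2, loci)
  copies <- (cp1 == target_proj) + (cp2 == target_proj)
  is_case <- subjects$role == "case"
  t(vapply(c(TRUE, FALSE), function(cs)
    vapply(0:2, function(k) sum(copies == k & is_case == cs), numeric(1)),
    numeric(3)))
}

exposure_haploid <- function(subjects, target_proj, loci) {
  cp <- c(hap_project(subjects$h1, loci), hap_project(subjects$h2, loci))
  is_case <- rep(subjects$role == "case", 2)
  hit <- cp == target_proj
  matrix(c(sum(hit & is_case), sum(!hit & is_case),
           sum(hit & !is_case), sum(!hit & !is_case)),
         2, 2, byrow = TRUE)
}

# carrier-collapsed diploid 2x2: carriers (>= 1 copy) vs non-carriers
exposure_carrier <- function(subjects, target_proj, loci) {
  d <- exposure_diploid(subjects, target_proj, loci)
  cbind(d[, 2] + d[, 3], d[, 1])
}

# ---- statistics -------------------------------------------------------

#' Cochran-Armitage trend statistic
#'
#' One-degree-of-freedom chi-square for linear trend in proportions with
#' scores (0, 1, 2) over copies of the target haplotype.
#'
#' @param tab 2 x 3 matrix of counts: rows case/control, columns 0/1/2
#'   copies.
#' @return the trend chi-square (0, with a warning, for degenerate
#'   tables).
#' @export
trend_test <- function(tab) {
  stopifnot(nrow(tab) == 2, ncol(tab) == 3)
  x <- 0:2
  N <- sum(tab)
  R <- sum(tab[1, ])
  n_j <- colSums(tab)
  if (N == 0 || R == 0 || R == N) {
    warning("degenerate trend table; statistic set to 0")
    return(0)
  }
  T_ <- sum(x * tab[1, ]) - R / N * sum(x * n_j)
  V <- R / N * (1 - R / N) * (sum(n_j * x^2) - sum(n_j * x)^2 / N)
  if (V <= 0) {
    warning("zero trend variance (monomorphic); statistic set to 0")
    return(0)
  }
  T_^2 / V
}

#' Pearson chi-square on a 2 x 2 table
#'
#' @param tab 2 x 2 count matrix.
#' @return the 1-df chi-square statistic (0 for degenerate margins).
#' @export
chi_square <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  N <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(0)
  N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(c(rs, cs))
}

#' Odds ratio on a 2 x 2 table
#'
#' Computed as ad/bc; when any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe correction) and the result is flagged with the
#' attribute `corrected = TRUE`.
#'
#' @param tab 2 x 2 count matrix (rows case/control, columns
#'   exposed/unexposed).
#' @return the odds ratio.
#' @export
odds_ratio <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  structure(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]),
            corrected = corrected)
}

#' TDT statistic for a target haplotype
#'
#' Counts transmissions (b) and non-transmissions (c) of the target from
#' informative parents (exactly one of the parent's two haplotypes is the
#' target on the analysis loci) to affected offspring, one count per
#' parent-offspring pair, transmission read from the MLE configuration;
#' the statistic is (b - c)^2 / (b + c).
#'
#' @param res a [hap_resource].
#' @param phasing a `hap_phasing` of `res`.
#' @param target_proj encoded target haplotype on `loci`.
#' @param loci 1-based locus indices.
#' @return the TDT statistic, with attributes `b` and `c`.
#' @export
tdt <- function(res, phasing, target_proj, loci) {
  m <- phasing$mle
  ind <- res$ind
  b <- 0L
  cc <- 0L
  for (i in which(ind$aff == 2L & ind$pat != "0" & !is.na(m$h1) &
                    m$ordered)) {
    fa <- which(ind$fid == ind$fid[i] & ind$iid == ind$pat[i])
    mo <- which(ind$fid == ind$fid[i] & ind$iid == ind$mat[i])
    if (is.na(m$sub_id[fa]) || is.na(m$sub_id[mo]) ||
        m$sub_id[i] != m$sub_id[fa] || m$sub_id[i] != m$sub_id[mo]) next
    for (side in 1:2) {
      p <- if (side == 1) mo else fa   # h1 = maternal, h2 = paternal
      pp <- hap_project(c(m$h1[p], m$h2[p]), loci)
      if (sum(pp == target_proj) != 1) next  # uninformative parent
      transmitted <- hap_project(if (side == 1) m$h1[i] else m$h2[i], loci)
      if (transmitted == target_proj) b <- b + 1L else cc <- cc + 1L
    }
  }
  if (b + cc == 0) {
    warning("no informative transmissions; TDT statistic set to 0")
    return(structure(0, b = b, c = cc))
  }
  structure((b - cc)^2 / (b + cc), b = b, c = cc)
}

# ---- dispatch ---------------------------------------------------------

# Compute the observed (or null) statistic for an analysis spec on a
# phased resource.
compute_statistic <- function(res, phasing, spec) {
  loci <- if (is.null(spec$loci)) seq_len(n_loci(res)) else spec$loci
  target_proj <- str_to_hap(spec$target)
  if (nchar(spec$target) != length(loci)) {
    stop("target length does not match the locus subset")
  }
  if (spec$statistic == "tdt") {
    return(as.numeric(tdt(res, phasing, target_proj, loci)))
  }
  subjects <- select_controls(res, phasing, spec$controls)
  if (spec$statistic == "trend") {
    suppressWarnings(trend_test(exposure_diploid(subjects, target_proj,
                                                 loci)))
  } else {
    tab <- if (spec$coding == "haploid") {
      exposure_haploid(subjects, target_proj, loci)
    } else {
      exposure_carrier(subjects, target_proj, loci)
    }
    if (spec$statistic == "chisq") chi_square(tab)
    else as.numeric(odds_ratio(tab))
  }
}
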