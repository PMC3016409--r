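#' @title Gene-dropping Monte Carlo significance
#' @description
#' Significance is assessed empirically against a null built by
#' gene-dropping: founders and independents draw haplotype pairs i.i.d.
#' from the frequencies estimated on the observed data, descendants
#' receive one haplotype from each parent chosen uniformly (zero
#' recombination), the observed missing-data mask is imposed, phase is
#' discarded, and the whole phasing pipeline is re-run on each null data
#' set with the same settings as the observed data.  Matching the full
#' phasing process between observed and null data is what makes tests on
#' MLE haplotypes valid despite phase uncertainty.  The full pedigree
#' structure is always used for gene-dropping, even when phasing split a
#' pedigree into substructures.
#' @name mc_engine
NULL

#' Gene-drop a null genotype configuration
#'
#' @param res a [hap_resource] (the observed data, already masked to the
#'   genotyping threshold); its pedigree structures and missingness define
#'   the null template.
#' @param freq named numeric vector of haplotype frequencies (names are
#'   encoded haplotype integers) estimated from the observed data.
#' @return a new [hap_resource] with simulated genotypes: same
#'   individuals, phenotypes, and missing-data mask; phase-unknown.
#' @export
gene_drop <- function(res, freq) {
  if (length(freq) == 0 || sum(freq) <= 0) {
    stop("empty haplotype frequency table")
  }
  haps <- as.integer(names(freq))
  nl <- n_loci(res)
  n <- nrow(res$ind)
  ind <- res$ind
  key <- ind_key(ind$fid, ind$iid)
  fa_row <- match(ind_key(ind$fid, ind$pat), key)  # NA for founders
  mo_row <- match(ind_key(ind$fid, ind$mat), key)
  founders <- which(ind$pat == "0")
  h1 <- integer(n)
  h2 <- integer(n)
  h1[founders] <- sample(haps, length(founders), replace = TRUE, prob = freq)
  h2[founders] <- sample(haps, length(founders), replace = TRUE, prob = freq)
  assigned <- logical(n)
  assigned[founders] <- TRUE
  while (!all(assigned)) {
    ready <- which(!assigned & assigned[ifelse(is.na(fa_row), 1L, fa_row)] &
                     assigned[ifelse(is.na(mo_row), 1L, mo_row)] &
                     !is.na(fa_row))
    if (length(ready) == 0) stop("internal: pedigree not gene-droppable")
    mo <- mo_row[ready]
    fa <- fa_row[ready]
    pick_m <- stats::runif(length(ready)) < 0.5
    pick_p <- stats::runif(length(ready)) < 0.5
    h1[ready] <- ifelse(pick_m, h1[mo], h2[mo])  # maternal
    h2[ready] <- ifelse(pick_p, h1[fa], h2[fa])  # paternal
    assigned[ready] <- TRUE
  }
  g1 <- matrix(0L, n, nl)
  g2 <- matrix(0L, n, nl)
  for (j in seq_len(nl)) {
    a <- hap_bit(h1, j) + 1L
    b <- hap_bit(h2, j) + 1L
    # discard phase: store alleles in canonical order
    g1[, j] <- pmin(a, b)
    g2[, j] <- pmax(a, b)
  }
  miss <- res$g1 == 0L
  g1[miss] <- 0L
  g2[miss] <- 0L
  out <- res
  out$g1 <- g1
  out$g2 <- g2
  out
}

#' Monte Carlo empirical p-value
#'
#' Add-one convention: p = (1 + #\{null >= observed\}) / (1 + n_null).
#' Ties count toward the null tail.  Odds ratios are compared on the
#' |log OR| scale; chi-square-type statistics are already non-negative.
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of null statistics.
#' @param statistic statistic name (only `"odds_ratio"` changes the
#'   comparison scale).
#' @return empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, nulls, statistic = "chisq") {
  stopifnot(length(nulls) >= 1)
  if (statistic == "odds_ratio") {
    observed <- abs(log(observed))
    nulls <- abs(log(nulls))
  }
  (1 + sum(nulls >= observed)) / (1 + length(nulls))
}

#' Run a full Monte Carlo association analysis
#'
#' Phases the observed resource, computes the observed statistic, then
#' repeatedly gene-drops null configurations, re-phases each with the same
#' pipeline and settings, and computes the null statistics.  Individuals
#' below the genotyping threshold are coded completely missing before
#' anything else runs, so the null missing-data mask matches the data the
#' phaser saw.
#'
#' @param res a [hap_resource].
#' @param spec an [analysis_spec].
#' @param phasing_args list of extra arguments passed to
#'   [phase_resource()] (e.g. `method`, `partition_len`).
#' @param max_redraw_rate a null whose phasing fails is redrawn; a redraw
#'   rate above this fraction aborts.
#' @return object of class `hapmc_result`: observed statistic, null
#'   statistics, empirical p-value, redraw count.
#' @export
run_analysis <- function(res, spec, phasing_args = list(),
                         max_redraw_rate = 0.01) {
  stopifnot(inherits(spec, "analysis_spec"))
  set.seed(spec$seed)
  res <- mask_below_threshold(res, spec$min_genotyped_fraction)
  # configuration enumeration is deterministic given a substructure's
  # genotypes, so the per-signature tables are shared across null
  # replicates; the EM itself is re-run for every null
  enum_cache <- new.env(parent = emptyenv())
  phase_call <- function(r) {
    do.call(phase_resource,
            c(list(res = r,
                   min_genotyped_fraction = spec$min_genotyped_fraction,
                   cache = enum_cache),
              phasing_args))
  }
  obs_phasing <- phase_call(res)
  observed <- compute_statistic(res, obs_phasing, spec)
  nulls <- numeric(spec$n_null)
  redraws <- 0L
  max_redraws <- max(1, ceiling(max_redraw_rate * spec$n_null))
  for (i in seq_len(spec$n_null)) {
    repeat {
      nd <- gene_drop(res, obs_phasing$freq)
      val <- tryCatch(
        compute_statistic(nd, phase_call(nd), spec),
        hapmc_mendel_error = function(e) NULL,
        error = function(e) {
          if (grepl("degenerac", conditionMessage(e))) NULL else stop(e)
        })
      if (!is.null(val)) {
        nulls[i] <- val
        break
      }
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("null phasing failure rate exceeds ", max_redraw_rate)
      }
    }
  }
  structure(list(observed = observed,
                 nulls = nulls,
                 p = empirical_p(observed, nulls, spec$statistic),
                 n_null = spec$n_null, seed = spec$seed,
                 redraws = redraws, spec = spec,
                 phasing = obs_phasing),
            class = "hapmc_result")
}

#' @export
print.hapmc_result <- function(x, ...) {
  cat(sprintf("%s statistic (%s controls): observed %.4f, empirical p = %.4g (%d nulls, %d redraws)\n",
              x$spec$statistic, x$spec$controls, x$observed, x$p,
              x$n_null, x$redraws))
  invisible(x)
}

# Code individuals below the genotyping threshold as completely missing.
mask_below_threshold <- function(res, min_genotyped_fraction) {
  low <- genotyped_fraction(res) < min_genotyped_fraction
  if (any(low)) {
    res$g1[low, ] <- 0L
    res$g2[low, ] <- 0L
  }
  res
}

#' Write an association result table
#'
#' @param result a `hapmc_result`.
#' @param path output path; tab-delimited.
#' @return `result`, invisibly.
#' @export
write_result <- function(result, path) {
  spec <- result$spec
  loci <- if (is.null(spec$loci)) "all" else paste(spec$loci, collapse = ",")
  tab <- data.frame(loci = loci, target = spec$target,
                    statistic = spec$statistic, controls = spec$controls,
                    observed = result$observed, p = result$p,
                    n_null = result$n_null)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(result)
}
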