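#' @title Power and type-I-error experiments
#' @description
#' Replicate loops around [simulate_design()] and [run_analysis()]:
#' generate a resource, test the risk haplotype, and estimate the
#' rejection rate at a chosen alpha level over replicates.  With a null
#' model (GRR = 1, or an LP clustering model with independent genotypes)
#' the rejection rate estimates the type-I error; under an alternative
#' model it estimates power.
#' @name experiments
NULL

#' Estimate a rejection rate by simulation
#'
#' @param spec a [design_spec].
#' @param model a [disease_model] (use `grr = 1` for the null).
#' @param pool haplotype pool (default [default_hap_pool()] at `model$q`).
#' @param statistic,controls statistic and control mode for
#'   [analysis_spec()].
#' @param n_replicates number of simulated resources.
#' @param n_null Monte Carlo null configurations per replicate.
#' @param alpha rejection level (default 0.05).
#' @param seed master seed; every replicate's generator and Monte Carlo
#'   seeds descend from it.
#' @param lp_cluster_model see [simulate_design()].
#' @param phasing_args extra arguments to [phase_resource()].
#' @param min_genotyped_fraction genotyping threshold.
#' @return list with `rate`, the per-replicate `p_values`, and the
#'   binomial standard error of the rate.
#' @export
estimate_rejection_rate <- function(spec, model,
                                    pool = default_hap_pool(model$q),
                                    statistic = "trend", controls = "EC",
                                    n_replicates = 100L, n_null = 200L,
                                    alpha = 0.05, seed = 1L,
                                    lp_cluster_model = NULL,
                                    phasing_args = list(),
                                    min_genotyped_fraction = 0.5) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  p_values <- vapply(seq_len(n_replicates), function(i) {
    set.seed(rep_seeds[2L * i - 1L])
    sim <- simulate_design(spec, model, pool,
                           lp_cluster_model = lp_cluster_model)
    aspec <- analysis_spec(statistic = statistic, controls = controls,
                           target = model$risk_hap, n_null = n_null,
                           seed = rep_seeds[2L * i],
                           min_genotyped_fraction = min_genotyped_fraction)
    run_analysis(sim$resource, aspec, phasing_args = phasing_args)$p
  }, numeric(1))
  rate <- mean(p_values <= alpha)
  list(rate = rate, p_values = p_values,
       se = sqrt(alpha * (1 - alpha) / n_replicates))
}

#' Phasing accuracy of MLE haplotype pairs
#'
#' Fraction of phased individuals whose MLE pair matches the true pair
#' (compared unordered).
#'
#' @param phasing a `hap_phasing`.
#' @param truth truth data.frame from [simulate_design()].
#' @return accuracy in \[0, 1\].
#' @export
phasing_accuracy <- function(phasing, truth) {
  m <- phasing$mle
  stopifnot(nrow(m) == nrow(truth))
  ok <- !is.na(m$h1) & !is.na(truth$h1)
  est <- cbind(pmin(m$h1[ok], m$h2[ok]), pmax(m$h1[ok], m$h2[ok]))
  tru <- cbind(pmin(truth$h1[ok], truth$h2[ok]),
               pmax(truth$h1[ok], truth$h2[ok]))
  mean(est[, 1] == tru[, 1] & est[, 2] == tru[, 2])
}
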