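#' @title EM haplotype frequency estimation over pedigree configurations
#' @description
#' Population haplotype frequencies are estimated by maximum likelihood
#' under the Elston-Stewart factorisation of the pedigree likelihood:
#' founders contribute Hardy-Weinberg pair probabilities (the squared
#' frequency for a homozygous pair, twice the product for a heterozygous
#' pair) and descendants contribute Mendelian transmission probabilities
#' (1/2 per heterozygous parent).  The E-step computes the posterior of
#' every enumerated configuration within its substructure; the M-step sets
#' each haplotype frequency to its expected founder-chromosome count over
#' twice the number of founders and independents.  A partition-ligation
#' mode splits longer marker sets into overlapping windows, phases each,
#' prunes rare haplotypes, and ligates progressively.
#' @name em_phaser
NULL

# ---- substructure construction ---------------------------------------

# Build phasing substructure "classes": identical (structure, genotype)
# substructures are collapsed and carry a weight, so that resources with
# many repeated units (case-control singletons, trios) are phased once per
# distinct unit.  `allowed` optionally restricts haplotypes (PL-EM).
build_substructures <- function(res, min_genotyped_fraction = 0.5,
                                allowed = NULL,
                                method = c("pedigree", "naive"),
                                cap = CONFIG_CAP, cache = NULL) {
  method <- match.arg(method)
  cache_suffix <- if (is.null(allowed)) "" else
    paste0("|A", paste(allowed, collapse = ","))
  classes <- new.env(parent = emptyenv())
  excluded <- character(0)
  fallback_n <- 0L
  add_instance <- function(sig, rows, build) {
    cl <- classes[[sig]]
    if (is.null(cl)) {
      tab <- NULL
      ckey <- paste0(sig, cache_suffix)
      if (!is.null(cache)) tab <- cache[[ckey]]
      if (is.null(tab)) {
        tab <- build()
        if (is.null(tab)) return(invisible(NULL))
        if (!is.null(cache)) cache[[ckey]] <- tab
      }
      cl <- list(tab = tab, instances = list())
    }
    cl$instances[[length(cl$instances) + 1]] <- rows
    classes[[sig]] <- cl
    invisible(NULL)
  }
  gm <- cbind(pmin(res$g1, res$g2), pmax(res$g1, res$g2))
  row_sigs <- do.call(paste, c(lapply(seq_len(ncol(gm)),
                                      function(j) gm[, j]), sep = ","))
  geno_sig <- function(rows) paste(row_sigs[rows], collapse = ";")
  frac <- genotyped_fraction(res)
  singleton_state <- function(row) {
    load_phase_state(res$g1[row, ], res$g2[row, ])
  }
  add_detached <- function(row) {
    sig <- paste0("S|", geno_sig(row))
    add_instance(sig, row, function() {
      s <- singleton_state(row)
      p <- individual_pairs(s, allowed = allowed)
      if (nrow(p) == 0 && !is.null(allowed)) {
        fallback_n <<- fallback_n + 1L
        p <- individual_pairs(s)
      }
      if (nrow(p) == 0) {
        stop("no haplotype pair consistent with individual ",
             res$ind$iid[row])
      }
      list(members = "1", role = "F", mat = p,
           child_rel = matrix(integer(0), 0, 3,
                              dimnames = list(NULL, c("c", "f", "m"))))
    })
  }
  if (method == "naive") {
    for (row in seq_len(nrow(res$ind))) {
      if (frac[row] >= min_genotyped_fraction) add_detached(row) else {
        excluded <- c(excluded, ind_key(res$ind$fid[row], res$ind$iid[row]))
      }
    }
  } else {
    fam_rows_all <- split(seq_len(nrow(res$ind)), res$ind$fid)
    for (fid in names(fam_rows_all)) {
      fam_rows <- fam_rows_all[[fid]]
      if (all(res$ind$pat[fam_rows] == "0")) {
        # no parent-child links: every member is independent
        for (row in fam_rows) {
          if (frac[row] >= min_genotyped_fraction) add_detached(row) else {
            excluded <- c(excluded, ind_key(res$ind$fid[row],
                                            res$ind$iid[row]))
          }
        }
        next
      }
      sp <- split_pedigree(res, fid, min_genotyped_fraction,
                           all_fractions = frac)
      row_of <- function(iid) fam_rows[match(iid, res$ind$iid[fam_rows])]
      for (frag in sp$fragments) {
        rows <- vapply(frag$members, row_of, integer(1))
        # canonical structural signature: member order, trio indices,
        # normalised genotypes, restriction marker
        trio_sig <- paste(vapply(frag$trios, function(tr)
          paste(match(c(tr$father, tr$mother, tr$child), frag$members),
                collapse = "-"), character(1)), collapse = "+")
        sig <- paste0("P|", trio_sig, "|", geno_sig(rows),
                      if (is.null(allowed)) "" else "|R")
        one_family <- length(unique(vapply(frag$trios, function(tr)
          paste(tr$father, tr$mother), character(1)))) == 1L
        add_instance(sig, rows, function() {
          if (one_family) {
            fast_nuclear_table(res, frag, rows, allowed, cap,
                               on_fallback = function()
                                 fallback_n <<- fallback_n + 1L)
          } else {
            build_fragment_table(res, fid, frag, allowed, cap,
                                 on_fallback = function()
                                   fallback_n <<- fallback_n + 1L)
          }
        })
      }
      for (iid in sp$detached) add_detached(row_of(iid))
      excluded <- c(excluded, ind_key(fid, sp$excluded))
    }
  }
  out <- as.list(classes)
  structure(list(classes = unname(out), excluded = excluded,
                 fallbacks = fallback_n),
            class = "hapmc_substructures")
}

# Fast path for fragments that are a single nuclear family: enumerate in
# compiled code directly from the genotypes (identical result to the
# preprocessing + enumeration path, which the test suite asserts).
fast_nuclear_table <- function(res, frag, rows, allowed, cap, on_fallback) {
  father <- frag$trios[[1]]$father
  mother <- frag$trios[[1]]$mother
  kids <- vapply(frag$trios, function(tr) tr$child, character(1))
  members <- c(father, mother, kids)
  r <- rows[match(members, frag$members)]
  run <- function(restrict) {
    .enum_nuclear_cpp(res$g1[r[1], ], res$g2[r[1], ],
                      res$g1[r[2], ], res$g2[r[2], ],
                      res$g1[r[-(1:2)], , drop = FALSE],
                      res$g2[r[-(1:2)], , drop = FALSE],
                      restrict, cap)
  }
  mat <- run(allowed)
  if (nrow(mat) == 0 && !is.null(allowed)) {
    on_fallback()
    mat <- run(NULL)
  }
  if (nrow(mat) == 0) {
    mendel_error(sprintf(
      "no Mendelian-consistent haplotype configuration for family %s",
      res$ind$fid[r[1]]))
  }
  nk <- length(kids)
  list(members = members, role = c("F", "M", rep("C", nk)), mat = mat,
       child_rel = cbind(c = 2L + seq_len(nk), f = 1L, m = 2L),
       member_order = match(members, frag$members))
}

# Enumerate one fragment's configuration table (members, role, mat,
# child_rel) with the PL restriction fallback.
build_fragment_table <- function(res, fid, frag, allowed, cap, on_fallback) {
  enumerate <- function(restrict) {
    ctx <- run_preprocessing(res, fid, frag)
    pairs <- lapply(frag$members, function(id) {
      p <- individual_pairs(ctx$states[[id]], allowed = restrict)
      if (nrow(p) == 0 && !is.null(restrict)) {
        on_fallback()
        p <- individual_pairs(ctx$states[[id]])
      }
      p
    })
    names(pairs) <- frag$members
    # group trios back into nuclear families
    famkey <- vapply(frag$trios, function(tr)
      paste(tr$father, tr$mother, sep = "|"), character(1))
    tabs <- list()
    for (k in unique(famkey)) {
      trs <- frag$trios[famkey == k]
      father <- trs[[1]]$father
      mother <- trs[[1]]$mother
      kids <- vapply(trs, function(tr) tr$child, character(1))
      t <- family_configurations(pairs[[father]], pairs[[mother]],
                                 pairs[kids], cap = cap)
      t$members <- c(father, mother, kids)
      if (nrow(t$mat) == 0) return(NULL)
      tabs[[length(tabs) + 1]] <- t
    }
    tab <- assemble_substructure(tabs, cap = cap)
    if (nrow(tab$mat) == 0) return(NULL)
    tab
  }
  tab <- enumerate(allowed)
  if (is.null(tab) && !is.null(allowed)) {
    on_fallback()
    tab <- enumerate(NULL)
  }
  if (is.null(tab)) {
    mendel_error(sprintf(
      "no Mendelian-consistent haplotype configuration for family %s", fid))
  }
  # child transmission relations as member indices
  crel <- do.call(rbind, lapply(frag$trios, function(tr)
    cbind(c = match(tr$child, tab$members),
          f = match(tr$father, tab$members),
          m = match(tr$mother, tab$members))))
  tab$child_rel <- crel
  # reorder instance mapping: members of tab may be permuted relative to
  # frag$members; store the permutation so instances can be aligned
  tab$member_order <- match(tab$members, frag$members)
  tab
}

# ---- configuration prior ---------------------------------------------

#' Prior probability of a pedigree configuration
#'
#' Product over founders of the Hardy-Weinberg pair probability and over
#' descendants of the Mendelian transmission probability.
#'
#' @param founder_pairs two-column integer matrix of founder pairs.
#' @param n_het_parent_transmissions number of transmissions from
#'   heterozygous parents in the configuration.
#' @param freq named numeric vector of haplotype frequencies (names are
#'   encoded haplotype integers); absent haplotypes have frequency 0.
#' @return the prior probability.
#' @export
config_prior <- function(founder_pairs, n_het_parent_transmissions, freq) {
  look <- function(h) {
    v <- freq[as.character(h)]
    v[is.na(v)] <- 0
    unname(v)
  }
  pr <- 1
  for (i in seq_len(nrow(founder_pairs))) {
    h1 <- founder_pairs[i, 1]
    h2 <- founder_pairs[i, 2]
    pr <- pr * if (h1 == h2) look(h1)^2 else 2 * look(h1) * look(h2)
  }
  pr * 0.5^n_het_parent_transmissions
}

# ---- EM core ----------------------------------------------------------

# Prepare per-class cached quantities for fast EM iterations.
prep_class_em <- function(tab, universe) {
  fcols <- which(tab$role != "C")
  fidx <- c(2L * fcols - 1L, 2L * fcols)
  fmat <- tab$mat[, sort(fidx), drop = FALSE]
  uidx <- matrix(match(fmat, universe), nrow(fmat))
  if (anyNA(uidx)) stop("internal: founder haplotype missing from universe")
  # doubling for heterozygous founder pairs
  nhet <- integer(nrow(tab$mat))
  for (f in fcols) {
    nhet <- nhet + (tab$mat[, 2L * f - 1L] != tab$mat[, 2L * f])
  }
  # transmission constant: 1/2 per heterozygous transmitting parent
  ntrans <- integer(nrow(tab$mat))
  if (nrow(tab$child_rel) > 0) {
    for (r in seq_len(nrow(tab$child_rel))) {
      for (p in c(tab$child_rel[r, "f"], tab$child_rel[r, "m"])) {
        ntrans <- ntrans + (tab$mat[, 2L * p - 1L] != tab$mat[, 2L * p])
      }
    }
  }
  list(uidx = uidx, mult = 2^nhet, trans_const = 0.5^ntrans,
       n_founders = length(fcols))
}

# EM over prepared classes.  Returns frequencies over `universe`, the
# log-likelihood trace, and final per-class posteriors.  Classes with the
# same number of founder columns are stacked into one matrix so each EM
# iteration is a handful of vectorised operations.
em_core <- function(prepped, weights, universe, tol = 1e-6,
                    max_iter = 1000L) {
  nu <- length(universe)
  freq <- rep(1 / nu, nu)
  denom <- 2 * sum(weights * vapply(prepped, `[[`, numeric(1), "n_founders"))
  ncls <- length(prepped)
  width <- vapply(prepped, function(p) ncol(p$uidx), integer(1))
  groups <- lapply(unique(width), function(w) {
    ci <- which(width == w)
    U <- do.call(rbind, lapply(prepped[ci], `[[`, "uidx"))
    nrows <- vapply(prepped[ci], function(p) nrow(p$uidx), integer(1))
    cid <- rep(seq_along(ci), nrows)
    list(ci = ci, U = U, Uvec = as.vector(U), w = w, cid = cid,
         base = unlist(lapply(prepped[ci], function(p)
           p$mult * p$trans_const)),
         wt = weights[ci], nrows = nrows)
  })
  loglik <- numeric(0)
  posts <- vector("list", ncls)
  for (it in seq_len(max_iter)) {
    counts <- numeric(nu)
    ll <- 0
    for (g in groups) {
      fm <- matrix(freq[g$U], nrow(g$U))
      pr <- g$base
      for (j in seq_len(g$w)) pr <- pr * fm[, j]
      s <- rowsum(pr, g$cid, reorder = FALSE)[, 1]
      if (any(!is.finite(s) | s <= 0)) {
        stop("numerical degeneracy: all configuration priors are zero")
      }
      post <- pr / s[g$cid]
      wpost <- post * g$wt[g$cid]
      tabk <- rowsum(rep.int(wpost, g$w), g$Uvec)
      ki <- as.integer(rownames(tabk))
      counts[ki] <- counts[ki] + tabk[, 1]
      ll <- ll + sum(g$wt * log(s))
    }
    newf <- counts / denom
    loglik <- c(loglik, ll)
    delta <- max(abs(newf - freq))
    freq <- newf
    if (delta < tol) break
  }
  # posteriors at the converged frequencies, for MLE extraction
  for (g in groups) {
    fm <- matrix(freq[g$U], nrow(g$U))
    pr <- g$base
    for (j in seq_len(g$w)) pr <- pr * fm[, j]
    s <- rowsum(pr, g$cid, reorder = FALSE)[, 1]
    post <- pr / s[g$cid]
    sp <- split(post, g$cid)
    for (k in seq_along(g$ci)) posts[[g$ci[k]]] <- sp[[k]]
  }
  names(freq) <- as.character(universe)
  list(freq = freq, loglik = loglik, posts = posts, n_iter = length(loglik))
}

# ---- full-region phasing ---------------------------------------------

# Phase a resource over all its loci with a single EM (no partitioning).
phase_full <- function(res, min_genotyped_fraction = 0.5, allowed = NULL,
                       method = c("pedigree", "naive"), tol = 1e-6,
                       max_iter = 1000L, cap = CONFIG_CAP, cache = NULL) {
  method <- match.arg(method)
  subs <- build_substructures(res, min_genotyped_fraction, allowed, method,
                              cap, cache)
  classes <- subs$classes
  if (length(classes) == 0) {
    stop("no individual meets the genotyping threshold")
  }
  weights <- vapply(classes, function(cl) length(cl$instances), numeric(1))
  universe <- sort(unique(unlist(lapply(classes, function(cl) {
    fcols <- which(cl$tab$role != "C")
    as.vector(cl$tab$mat[, c(2L * fcols - 1L, 2L * fcols), drop = FALSE])
  }))))
  prepped <- lapply(classes, function(cl) prep_class_em(cl$tab, universe))
  em <- em_core(prepped, weights, universe, tol, max_iter)
  mle <- extract_mle(res, classes, em$posts)
  structure(list(freq = em$freq, loglik = em$loglik, n_iter = em$n_iter,
                 mle = mle, excluded = subs$excluded,
                 fallbacks = subs$fallbacks, n_loci = n_loci(res),
                 method = method,
                 settings = list(threshold = min_genotyped_fraction,
                                 tol = tol, max_iter = max_iter)),
            class = "hap_phasing")
}

# Per-individual MLE haplotype pairs from maximum-posterior configurations.
# Ties are broken by the lexicographically smallest configuration row.
extract_mle <- function(res, classes, posts) {
  key_all <- ind_key(res$ind$fid, res$ind$iid)
  n <- nrow(res$ind)
  h1 <- rep(NA_integer_, n)
  h2 <- rep(NA_integer_, n)
  ordered <- rep(FALSE, n)
  posterior <- rep(NA_real_, n)
  sub_id <- rep(NA_integer_, n)
  sid <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    post <- posts[[ci]]
    best <- which(post >= max(post) - 1e-12)
    if (length(best) > 1) {
      o <- do.call(order, as.data.frame(cl$tab$mat[best, , drop = FALSE]))
      best <- best[o[1]]
    }
    row_cfg <- cl$tab$mat[best, ]
    for (inst in cl$instances) {
      sid <- sid + 1L
      rows <- inst
      if (!is.null(cl$tab$member_order)) {
        rows <- inst[cl$tab$member_order]
      }
      for (m in seq_along(rows)) {
        r <- rows[m]
        h1[r] <- row_cfg[2L * m - 1L]
        h2[r] <- row_cfg[2L * m]
        ordered[r] <- cl$tab$role[m] == "C"
        posterior[r] <- post[best]
        sub_id[r] <- sid
      }
    }
  }
  data.frame(fid = res$ind$fid, iid = res$ind$iid, h1 = h1, h2 = h2,
             ordered = ordered, posterior = posterior, sub_id = sub_id,
             stringsAsFactors = FALSE)
}

# ---- pruning and ligation --------------------------------------------

# Haplotypes surviving a partition: frequency >= cutoff plus up to `buffer`
# of the highest-frequency haplotypes below the cutoff.
prune_haplotypes <- function(freq, cutoff, buffer) {
  keep <- names(freq)[freq >= cutoff]
  below <- sort(freq[freq < cutoff], decreasing = TRUE)
  if (buffer > 0 && length(below) > 0) {
    keep <- c(keep, names(below)[seq_len(min(buffer, length(below)))])
  }
  as.integer(keep)
}

# Consistent concatenations of two adjacent regions sharing `ov` loci:
# region A spans p loci; region B starts at locus p - ov + 1.
ligate_haplotypes <- function(ha, hb, p, ov) {
  ka <- hap_project(ha, (p - ov + 1):p)
  kb <- hb %% 2^ov
  out <- integer(0)
  bmap <- split(hb, kb)
  for (u in unique(ka)) {
    bs <- bmap[[as.character(u)]]
    if (is.null(bs)) next
    as_ <- ha[ka == u]
    grid <- expand.grid(a = as_, b = bs)
    out <- c(out, grid$a + bitwShiftL(grid$b %/% 2^ov, p))
  }
  sort(unique(out))
}

#' Phase a resource
#'
#' Estimates population haplotype frequencies and per-individual MLE
#' haplotype pairs.  For marker sets longer than `partition_len` a
#' partition-ligation EM is used: overlapping windows are phased
#' separately, rare haplotypes are pruned (keeping `buffer` extra
#' haplotypes beyond the `cutoff`), and windows are ligated progressively
#' with a final EM over the full region.
#'
#' @param res a [hap_resource].
#' @param min_genotyped_fraction per-individual genotyping threshold;
#'   individuals below it are treated as completely missing.
#' @param method `"pedigree"` (default) uses pedigree structure;
#'   `"naive"` phases everyone as unrelated individuals.
#' @param partition_len,overlap,cutoff,buffer partition-ligation settings
#'   (defaults 5, 1, 1e-6, 25).
#' @param tol,max_iter EM convergence settings.
#' @return object of class `hap_phasing`: `freq` (named by encoded
#'   haplotype), `freq_table` (haplotype string + frequency), `mle`
#'   (per-individual pair, `ordered` TRUE when (maternal, paternal)),
#'   `loglik`, `excluded`.
#' @export
phase_resource <- function(res, min_genotyped_fraction = 0.5,
                           method = c("pedigree", "naive"),
                           partition_len = 5L, overlap = 1L,
                           cutoff = 1e-6, buffer = 25L,
                           tol = 1e-6, max_iter = 1000L, cache = NULL) {
  method <- match.arg(method)
  n <- n_loci(res)
  if (n <= partition_len) {
    out <- phase_full(res, min_genotyped_fraction, NULL, method, tol,
                      max_iter, cache = cache)
  } else {
    stopifnot(partition_len >= 2, overlap >= 1, overlap < partition_len)
    starts <- integer(0)
    s <- 1L
    repeat {
      starts <- c(starts, s)
      if (s + partition_len - 1L >= n) break
      s <- s + partition_len - overlap
    }
    w1 <- starts[1]:min(starts[1] + partition_len - 1L, n)
    ph <- phase_full(subset_loci(res, w1), min_genotyped_fraction, NULL,
                     method, tol, max_iter)
    surv <- prune_haplotypes(ph$freq, cutoff, buffer)
    a_len <- length(w1)
    for (wi in seq_along(starts)[-1]) {
      w <- starts[wi]:min(starts[wi] + partition_len - 1L, n)
      phw <- phase_full(subset_loci(res, w), min_genotyped_fraction, NULL,
                        method, tol, max_iter)
      sw <- prune_haplotypes(phw$freq, cutoff, buffer)
      ov <- a_len - (w[1] - 1L)
      allowed <- ligate_haplotypes(surv, sw, a_len, ov)
      comb <- 1:max(w)
      ph <- phase_full(subset_loci(res, comb), min_genotyped_fraction,
                       allowed, method, tol, max_iter)
      surv <- prune_haplotypes(ph$freq, cutoff, buffer)
      a_len <- length(comb)
    }
    out <- ph
  }
  out$settings <- c(out$settings,
                    list(partition_len = partition_len, overlap = overlap,
                         cutoff = cutoff, buffer = buffer, method = method))
  out$freq_table <- data.frame(
    haplotype = hap_to_str(as.integer(names(out$freq)), n),
    frequency = unname(out$freq), stringsAsFactors = FALSE)
  out
}

#' @export
print.hap_phasing <- function(x, ...) {
  cat(sprintf("hap_phasing (%s): %d haplotypes, loglik %.4f after %d EM iterations\n",
              x$method, length(x$freq), x$loglik[length(x$loglik)], x$n_iter))
  tab <- x$freq_table
  if (!is.null(tab)) {
    tab <- tab[order(-tab$frequency), ]
    print(utils::head(tab, 10), row.names = FALSE)
  }
  invisible(x)
}

#' MLE haplotype pairs
#'
#' @param phasing a `hap_phasing` object.
#' @return data.frame with one row per individual: `fid`, `iid`, phased
#'   haplotype strings `hap1`/`hap2` (maternal/paternal order when
#'   `ordered` is TRUE), and the posterior probability of the
#'   configuration they were taken from.  Individuals excluded from
#'   phasing have NA haplotypes.
#' @export
mle_pairs <- function(phasing) {
  m <- phasing$mle
  out <- data.frame(fid = m$fid, iid = m$iid,
                    hap1 = NA_character_, hap2 = NA_character_,
                    ordered = m$ordered, posterior = m$posterior,
                    stringsAsFactors = FALSE)
  ok <- !is.na(m$h1)
  out$hap1[ok] <- hap_to_str(m$h1[ok], phasing$n_loci)
  out$hap2[ok] <- hap_to_str(m$h2[ok], phasing$n_loci)
  out
}

#' Write phasing outputs as tab-delimited text
#'
#' @param phasing a `hap_phasing` object.
#' @param freq_path,pairs_path output paths (either may be `NULL`).
#' @return `phasing`, invisibly.
#' @export
write_phasing <- function(phasing, freq_path = NULL, pairs_path = NULL) {
  if (!is.null(freq_path)) {
    tab <- phasing$freq_table[order(-phasing$freq_table$frequency), ]
    utils::write.table(tab, freq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(pairs_path)) {
    utils::write.table(mle_pairs(phasing), pairs_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(phasing)
}
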