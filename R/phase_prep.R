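#' @title Phase preprocessing
#' @description
#' Before any haplotype configurations are enumerated, each individual's
#' genotypes are loaded into six locus-length bit vectors (homozygous,
#' heterozygous, unphased for the haplotype pair; set, missing, value for
#' each of the two haplotypes), and parent-offspring trios inside retained
#' nuclear families are swept with deterministic Mendelian rules that
#' resolve phase and missing data wherever the pedigree forces a unique
#' answer.  Transmission bits (which parental haplotype was passed to a
#' child) and inheritance bits (which parent a child haplotype came from)
#' are maintained alongside and drive which haplotype each update targets.
#' All rules are implemented as whole-vector logical operations and are
#' conservative: a rule fires only when the deduction is forced, so the set
#' of haplotype configurations consistent with the processed state equals
#' the set consistent with the raw genotypes.
#' @name phase_prep
NULL

mendel_error <- function(msg) {
  stop(structure(class = c("hapmc_mendel_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Load an individual's genotypes into the six phase bit-vectors
#'
#' @param a1,a2 integer vectors of allele codes (1/2, 0 = missing) at each
#'   locus; a half-missing genotype must already have been coerced.
#' @return a `phase_state`: logical vectors `hom`, `het`, `unph` (length n)
#'   and 2 x n logical matrices `set`, `mis`, `val` (row = haplotype;
#'   `val` TRUE means the minor allele "2").
#' @export
load_phase_state <- function(a1, a2) {
  n <- length(a1)
  miss <- a1 == 0L
  hom <- !miss & a1 == a2
  het <- !miss & a1 != a2
  set <- matrix(rep(hom, each = 2L), 2L, n)
  mis <- matrix(rep(miss, each = 2L), 2L, n)
  val <- matrix(rep(hom & a1 == 2L, each = 2L), 2L, n)
  structure(list(hom = hom, het = het, unph = het, set = set, mis = mis,
                 val = val), class = "phase_state")
}

#' @export
print.phase_state <- function(x, ...) {
  b <- function(v) paste(as.integer(v), collapse = "")
  cat("Haplotype pair\n")
  cat("  homozygous   ", b(x$hom), "\n")
  cat("  heterozygous ", b(x$het), "\n")
  cat("  unphased     ", b(x$unph), "\n")
  for (k in 1:2) {
    cat(sprintf("Haplotype %d\n", k))
    cat("  set          ", b(x$set[k, ]), "\n")
    cat("  missing      ", b(x$mis[k, ]), "\n")
    cat("  value        ", b(x$val[k, ]), "\n")
  }
  invisible(x)
}

# Re-establish internal consistency after an update: at heterozygous loci
# with one haplotype set, force the other to the complementary allele; clear
# 'unphased'/'missing' where both haplotypes are set; detect contradictions.
normalize_state <- function(s, who = "individual") {
  n <- length(s$hom)
  for (k in 1:2) {
    o <- 3L - k
    force_other <- s$het & s$set[k, ] & !s$set[o, ]
    if (any(force_other)) {
      s$val[o, force_other] <- !s$val[k, force_other]
      s$set[o, force_other] <- TRUE
      s$mis[o, force_other] <- FALSE
    }
  }
  both <- s$set[1, ] & s$set[2, ]
  bad <- s$het & both & (s$val[1, ] == s$val[2, ])
  if (any(bad)) {
    mendel_error(sprintf("phase contradiction for %s at locus %d",
                         who, which(bad)[1]))
  }
  s$unph[both] <- FALSE
  s$mis[1, ] <- s$mis[1, ] & !s$set[1, ]
  s$mis[2, ] <- s$mis[2, ] & !s$set[2, ]
  s
}

# TRUE when nothing distinguishes the two haplotype labels of a state.
state_symmetric <- function(s) {
  identical(s$set[1, ], s$set[2, ]) &&
    identical(s$mis[1, ], s$mis[2, ]) &&
    identical(s$val[1, ] & s$set[1, ], s$val[2, ] & s$set[2, ])
}

# Can haplotype j of parent state `ps` have been transmitted as (one of)
# the child's haplotypes?  `k` restricts to a specific child haplotype.
parent_hap_fits_child <- function(ps, j, cs, k = NULL) {
  ks <- if (is.null(k)) 1:2 else k
  for (kk in ks) {
    both <- ps$set[j, ] & cs$set[kk, ]
    conflict <- any(both & (ps$val[j, ] != cs$val[kk, ]))
    if (!conflict) return(TRUE)
  }
  FALSE
}

# Can haplotype k of child state `cs` have come from parent `ps`?
child_hap_fits_parent <- function(cs, k, ps) {
  # against the parent's genotype: a set child allele absent from a known
  # parent genotype excludes the parent
  g_conf <- cs$set[k, ] & ps$hom & (cs$val[k, ] != ps$val[1, ])
  if (any(g_conf)) return(FALSE)
  # against the parent's set haplotypes: child hap must match at least one
  # parental haplotype wherever both parental haplotypes are set
  for (j in 1:2) {
    both <- cs$set[k, ] & ps$set[j, ]
    if (!any(both & (cs$val[k, ] != ps$val[j, ]))) return(TRUE)
  }
  FALSE
}

# -- trio working context -----------------------------------------------

# A `prep_ctx` environment holds, for one substructure:
#   states: named list iid -> phase_state
#   inh:    named list iid -> integer(2), parent side of each child
#           haplotype (1 = father, 2 = mother, NA = unassigned)
#   trans:  named list "parent|child" -> transmitted parental haplotype
#           index (1/2, NA = unassigned)
new_prep_ctx <- function(states) {
  ctx <- new.env(parent = emptyenv())
  ctx$states <- states
  ctx$inh <- list()
  ctx$trans <- list()
  ctx
}

tkey <- function(parent, child) paste(parent, child, sep = "|")

get_inh <- function(ctx, child) {
  v <- ctx$inh[[child]]
  if (is.null(v)) c(NA_integer_, NA_integer_) else v
}

set_inh <- function(ctx, child, k, side) {
  v <- get_inh(ctx, child)
  v[k] <- side
  v[3L - k] <- 3L - side
  ctx$inh[[child]] <- v
}

get_trans <- function(ctx, parent, child) {
  v <- ctx$trans[[tkey(parent, child)]]
  if (is.null(v)) NA_integer_ else v
}

# TRUE if any transmission bit from `id` (as a parent) is assigned.
has_trans_as_parent <- function(ctx, id) {
  keys <- names(ctx$trans)
  if (length(keys) == 0) return(FALSE)
  any(startsWith(keys, paste0(id, "|")) & !is.na(unlist(ctx$trans)))
}

individual_untouched <- function(ctx, id) {
  all(is.na(get_inh(ctx, id))) && !has_trans_as_parent(ctx, id) &&
    state_symmetric(ctx$states[[id]])
}

# Which child haplotype receives from this parent?  `side` is 1 for father,
# 2 for mother.  Returns the haplotype index, or NA when inconclusive.
choose_child_hap <- function(ctx, child, side, parent) {
  inh <- get_inh(ctx, child)
  if (!all(is.na(inh))) {
    k <- which(inh == side)
    return(if (length(k) == 1) k else NA_integer_)
  }
  cs <- ctx$states[[child]]
  ps <- ctx$states[[parent]]
  if (individual_untouched(ctx, child)) {
    set_inh(ctx, child, 1L, side)
    return(1L)
  }
  # inheritance rule (exclusion): a child haplotype that cannot have come
  # from this parent must be from the other one
  fits <- c(child_hap_fits_parent(cs, 1L, ps),
            child_hap_fits_parent(cs, 2L, ps))
  if (!any(fits)) {
    mendel_error(sprintf(
      "neither haplotype of %s is compatible with parent %s", child, parent))
  }
  if (sum(fits) == 1) {
    k <- which(fits)
    set_inh(ctx, child, k, side)
    return(k)
  }
  NA_integer_
}

# Which parental haplotype was transmitted to this child?
choose_parent_hap <- function(ctx, parent, child) {
  tr <- get_trans(ctx, parent, child)
  if (!is.na(tr)) return(tr)
  ps <- ctx$states[[parent]]
  cs <- ctx$states[[child]]
  if (individual_untouched(ctx, parent)) {
    ctx$trans[[tkey(parent, child)]] <- 1L
    return(1L)
  }
  # transmission rule (exclusion): a parental haplotype excluded as being
  # either child haplotype cannot be the transmitted one
  fits <- c(parent_hap_fits_child(ps, 1L, cs),
            parent_hap_fits_child(ps, 2L, cs))
  if (!any(fits)) {
    mendel_error(sprintf(
      "neither haplotype of %s can have been transmitted to %s",
      parent, child))
  }
  if (sum(fits) == 1) {
    j <- which(fits)
    ctx$trans[[tkey(parent, child)]] <- j
    return(j)
  }
  NA_integer_
}

#' Parent-to-offspring homozygous update
#'
#' Uses the parent's homozygous loci to fill unphased or missing positions
#' of the child haplotype inherited from that parent (chosen through the
#' inheritance bits, or by exclusion; haplotype 1 for a still-symmetric
#' child).  Performed with whole-vector logical operations.
#'
#' @param ctx preprocessing context (internal).
#' @param parent,child individual ids; `side` 1 = father, 2 = mother.
#' @return TRUE if any bit changed.
#' @keywords internal
parent_to_offspring_update <- function(ctx, parent, child, side) {
  ps <- ctx$states[[parent]]
  cs <- ctx$states[[child]]
  if (!any(ps$hom)) return(FALSE)
  k <- choose_child_hap(ctx, child, side, parent)
  if (is.na(k)) return(FALSE)
  # Mendelian genotype check: parent hom a, child hom b, a != b
  conflict <- ps$hom & cs$hom & (ps$val[1, ] != cs$val[1, ])
  if (any(conflict)) {
    mendel_error(sprintf("Mendelian inconsistency between %s and %s at locus %d",
                         parent, child, which(conflict)[1]))
  }
  upd <- ps$hom & (cs$unph | cs$mis[k, ]) & !cs$set[k, ]
  # a previously set child allele conflicting with a forced parental allele
  hard <- ps$hom & cs$set[k, ] & (cs$val[k, ] != ps$val[1, ])
  if (any(hard)) {
    mendel_error(sprintf("Mendelian inconsistency between %s and %s at locus %d",
                         parent, child, which(hard)[1]))
  }
  if (!any(upd)) return(FALSE)
  cs$val[k, ] <- (cs$val[k, ] & !upd) | (ps$val[1, ] & upd)
  cs$set[k, ] <- cs$set[k, ] | upd
  cs$mis[k, ] <- cs$mis[k, ] & !upd
  cs$unph <- cs$unph & !(upd & cs$het)
  ctx$states[[child]] <- normalize_state(cs, child)
  TRUE
}

#' Offspring-to-parent homozygous update
#'
#' Mirror of the parent-to-offspring rule: the child's homozygous loci fill
#' unphased or missing positions of the transmitted parental haplotype
#' (chosen through the transmission bits, or by exclusion).
#'
#' @inheritParams parent_to_offspring_update
#' @return TRUE if any bit changed.
#' @keywords internal
offspring_to_parent_update <- function(ctx, parent, child) {
  ps <- ctx$states[[parent]]
  cs <- ctx$states[[child]]
  if (!any(cs$hom)) return(FALSE)
  j <- choose_parent_hap(ctx, parent, child)
  if (is.na(j)) return(FALSE)
  conflict <- ps$hom & cs$hom & (ps$val[1, ] != cs$val[1, ])
  if (any(conflict)) {
    mendel_error(sprintf("Mendelian inconsistency between %s and %s at locus %d",
                         parent, child, which(conflict)[1]))
  }
  upd <- cs$hom & (ps$unph | ps$mis[j, ]) & !ps$set[j, ]
  hard <- cs$hom & ps$set[j, ] & (ps$val[j, ] != cs$val[1, ])
  if (any(hard)) {
    mendel_error(sprintf("Mendelian inconsistency between %s and %s at locus %d",
                         parent, child, which(hard)[1]))
  }
  if (!any(upd)) return(FALSE)
  ps$val[j, ] <- (ps$val[j, ] & !upd) | (cs$val[1, ] & upd)
  ps$set[j, ] <- ps$set[j, ] | upd
  ps$mis[j, ] <- ps$mis[j, ] & !upd
  ps$unph <- ps$unph & !(upd & ps$het)
  ctx$states[[parent]] <- normalize_state(ps, parent)
  TRUE
}

# Copy set alleles between a parent's transmitted haplotype and the child
# haplotype inherited from that parent (they are the same chromosome under
# zero recombination).
copy_shared_haplotype <- function(ctx, parent, child, side) {
  inh <- get_inh(ctx, child)
  tr <- get_trans(ctx, parent, child)
  k <- which(inh == side)
  if (length(k) != 1 || is.na(tr)) return(FALSE)
  ps <- ctx$states[[parent]]
  cs <- ctx$states[[child]]
  both <- ps$set[tr, ] & cs$set[k, ]
  if (any(both & (ps$val[tr, ] != cs$val[k, ]))) {
    mendel_error(sprintf(
      "shared haplotype of %s and %s disagrees at locus %d",
      parent, child, which(both & (ps$val[tr, ] != cs$val[k, ]))[1]))
  }
  changed <- FALSE
  p2c <- ps$set[tr, ] & !cs$set[k, ]
  if (any(p2c)) {
    cs$val[k, p2c] <- ps$val[tr, p2c]
    cs$set[k, p2c] <- TRUE
    cs$mis[k, p2c] <- FALSE
    cs$unph <- cs$unph & !(p2c & cs$het)
    ctx$states[[child]] <- normalize_state(cs, child)
    cs <- ctx$states[[child]]
    changed <- TRUE
  }
  c2p <- cs$set[k, ] & !ps$set[tr, ]
  if (any(c2p)) {
    ps$val[tr, c2p] <- cs$val[k, c2p]
    ps$set[tr, c2p] <- TRUE
    ps$mis[tr, c2p] <- FALSE
    ps$unph <- ps$unph & !(c2p & ps$het)
    ctx$states[[parent]] <- normalize_state(ps, parent)
    changed <- TRUE
  }
  changed
}

#' Trio ambiguity-reduction sweep
#'
#' One pass of the inheritance/transmission deduction rules over a
#' father-mother-child trio: resolve unknown transmissions and inheritances
#' by exclusion (a haplotype excluded from one parent must come from the
#' other); propagate set alleles along established shared haplotypes; and
#' phase the last heterozygous locus of a still-symmetric individual.
#'
#' @param ctx preprocessing context (internal).
#' @param father,mother,child individual ids.
#' @return TRUE if any bit changed.
#' @keywords internal
reduce_ambiguities <- function(ctx, father, mother, child) {
  changed <- FALSE
  # transmission resolution for both parents, then inheritance resolution
  for (p in c(father, mother)) {
    if (is.na(get_trans(ctx, p, child)) && !individual_untouched(ctx, p)) {
      j <- tryCatch(choose_parent_hap(ctx, p, child), error = function(e) stop(e))
      if (!is.na(j)) changed <- TRUE
    }
  }
  if (all(is.na(get_inh(ctx, child)))) {
    for (side in 1:2) {
      p <- if (side == 1) father else mother
      if (!individual_untouched(ctx, child)) {
        k <- choose_child_hap(ctx, child, side, p)
        if (!is.na(k)) {
          changed <- TRUE
          break
        }
      }
    }
  }
  # known-transmission vs known-inheritance cross rule: if a parent's
  # transmitted haplotype is known and one child haplotype cannot equal it,
  # the other child haplotype is the one inherited from that parent
  if (all(is.na(get_inh(ctx, child)))) {
    for (side in 1:2) {
      p <- if (side == 1) father else mother
      tr <- get_trans(ctx, p, child)
      if (is.na(tr)) next
      ps <- ctx$states[[p]]
      cs <- ctx$states[[child]]
      can <- vapply(1:2, function(k) {
        both <- ps$set[tr, ] & cs$set[k, ]
        !any(both & (ps$val[tr, ] != cs$val[k, ]))
      }, logical(1))
      if (!any(can)) {
        mendel_error(sprintf(
          "transmitted haplotype of %s fits neither haplotype of %s", p, child))
      }
      if (sum(can) == 1 && !state_symmetric(cs)) {
        set_inh(ctx, child, which(can), side)
        changed <- TRUE
        break
      }
    }
  }
  # one-of-(inheritance, transmission)-known: the unknown bit can be fixed
  # freely when the other individual's haplotype labels are still
  # symmetric (relabelling is a bijection on configurations)
  for (side in 1:2) {
    p <- if (side == 1) father else mother
    inh <- get_inh(ctx, child)
    k <- which(inh == side)
    if (length(k) == 1 && is.na(get_trans(ctx, p, child)) &&
        individual_untouched(ctx, p)) {
      ctx$trans[[tkey(p, child)]] <- 1L
      changed <- TRUE
    }
    if (all(is.na(inh)) && !is.na(get_trans(ctx, p, child)) &&
        individual_untouched(ctx, child)) {
      set_inh(ctx, child, 1L, side)
      changed <- TRUE
    }
  }
  # propagate along established parent-child shared haplotypes
  for (side in 1:2) {
    p <- if (side == 1) father else mother
    if (copy_shared_haplotype(ctx, p, child, side)) changed <- TRUE
  }
  # last-heterozygous-locus phasing for label-symmetric members
  for (id in c(father, mother, child)) {
    s <- ctx$states[[id]]
    if (sum(s$unph) == 1 && !any(s$mis) && individual_untouched(ctx, id)) {
      i <- which(s$unph)
      s$val[1, i] <- FALSE
      s$val[2, i] <- TRUE
      s$set[, i] <- TRUE
      s$unph[i] <- FALSE
      ctx$states[[id]] <- normalize_state(s, id)
      changed <- TRUE
    }
  }
  changed
}

#' Split a pedigree into phasing substructures
#'
#' A nuclear family is retained for phasing when both parents and at least
#' one offspring meet the per-individual genotyping threshold (fraction of
#' non-missing markers).  Retained families sharing individuals are joined
#' into connected fragments.  Individuals in no retained family become
#' detached singletons if they meet the threshold and are otherwise
#' excluded from phasing (they always remain part of the full structure
#' used by the Monte Carlo engine).
#'
#' @param res a [hap_resource].
#' @param fid family id within `res`.
#' @param min_genotyped_fraction threshold in \[0, 1\] (default 0.5).
#' @param all_fractions optional precomputed [genotyped_fraction] vector.
#' @return list with elements `fragments` (each a list of `members` and
#'   `trios`), `detached` (character ids), `excluded` (character ids).
#' @export
split_pedigree <- function(res, fid, min_genotyped_fraction = 0.5,
                           all_fractions = NULL) {
  sel <- which(res$ind$fid == fid)
  ids <- res$ind$iid[sel]
  pats <- res$ind$pat[sel]
  mats <- res$ind$mat[sel]
  if (is.null(all_fractions)) all_fractions <- genotyped_fraction(res)
  frac <- all_fractions[sel]
  names(frac) <- ids
  ok <- frac >= min_genotyped_fraction
  kid_i <- which(pats != "0")
  pairkey <- paste(pats[kid_i], mats[kid_i])
  retained <- list()
  for (k in unique(pairkey)) {
    kk <- kid_i[pairkey == k]
    father <- pats[kk[1]]
    mother <- mats[kk[1]]
    kids_ok <- ids[kk][ok[ids[kk]]]
    if (ok[father] && ok[mother] && length(kids_ok) > 0) {
      retained[[length(retained) + 1]] <-
        list(father = father, mother = mother, offspring = kids_ok)
    }
  }
  # connect retained families via shared members (union-find)
  comp <- integer(0)
  if (length(retained) > 0) {
    parent <- seq_along(retained)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    members_of <- lapply(retained, function(f)
      c(f$father, f$mother, f$offspring))
    for (i in seq_along(retained)) {
      for (j in seq_len(i - 1)) {
        if (length(intersect(members_of[[i]], members_of[[j]])) > 0) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    comp <- vapply(seq_along(retained), find, integer(1))
  }
  fragments <- lapply(unique(comp), function(cc) {
    fs <- retained[comp == cc]
    members <- unique(unlist(lapply(fs, function(f)
      c(f$father, f$mother, f$offspring))))
    trios <- list()
    for (f in fs) {
      for (kid in f$offspring) {
        trios[[length(trios) + 1]] <-
          list(father = f$father, mother = f$mother, child = kid)
      }
    }
    list(members = members, trios = trios)
  })
  in_frag <- unique(unlist(lapply(fragments, `[[`, "members")))
  rest <- setdiff(ids, in_frag)
  list(fragments = fragments,
       detached = rest[ok[rest]],
       excluded = rest[!ok[rest]])
}

#' Run preprocessing to a fixed point over a substructure
#'
#' Loads phase states for every member and sweeps the homozygous-update and
#' ambiguity-reduction rules over all retained parent-offspring trios until
#' no bit changes.
#'
#' @param res a [hap_resource].
#' @param fid family id.
#' @param fragment one `fragments` element from [split_pedigree()].
#' @return a preprocessing context: `states` (named list of phase states),
#'   `inh`, `trans` (deduction bits).
#' @export
run_preprocessing <- function(res, fid, fragment) {
  sel <- which(res$ind$fid == fid)
  idx <- sel[match(fragment$members, res$ind$iid[sel])]
  states <- lapply(idx, function(i) load_phase_state(res$g1[i, ], res$g2[i, ]))
  names(states) <- fragment$members
  ctx <- new_prep_ctx(states)
  n <- n_loci(res)
  max_sweeps <- 2L * n * length(fragment$members) + 2L
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (tr in fragment$trios) {
      if (parent_to_offspring_update(ctx, tr$father, tr$child, 1L)) changed <- TRUE
      if (parent_to_offspring_update(ctx, tr$mother, tr$child, 2L)) changed <- TRUE
      if (offspring_to_parent_update(ctx, tr$father, tr$child)) changed <- TRUE
      if (offspring_to_parent_update(ctx, tr$mother, tr$child)) changed <- TRUE
      if (reduce_ambiguities(ctx, tr$father, tr$mother, tr$child)) changed <- TRUE
    }
    if (!changed) break
  }
  ctx
}

#' Dump a phase state in tabular text form
#'
#' One row per bit-variable, one column per locus; used for debugging and
#' fixture tests.
#'
#' @param s a `phase_state`.
#' @return character vector of lines.
#' @export
format_phase_state <- function(s) {
  b <- function(v) paste(as.integer(v), collapse = "")
  c(paste0("homozygous\t", b(s$hom)),
    paste0("heterozygous\t", b(s$het)),
    paste0("unphased\t", b(s$unph)),
    paste0("set1\t", b(s$set[1, ])),
    paste0("missing1\t", b(s$mis[1, ])),
    paste0("value1\t", b(s$val[1, ])),
    paste0("set2\t", b(s$set[2, ])),
    paste0("missing2\t", b(s$mis[2, ])),
    paste0("value2\t", b(s$val[2, ])))
}
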