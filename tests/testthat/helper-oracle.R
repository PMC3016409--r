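# Independent oracles used to verify the main implementation.  These are
# deliberately simple and share no code with the package internals beyond
# the public haplotype string/integer converters.

# All unordered haplotype pairs consistent with one individual's genotypes
# (vectors of allele codes 1/2 with 0 = missing).
oracle_individual_pairs <- function(a1, a2) {
  n <- length(a1)
  opts <- vector("list", n)
  for (i in seq_len(n)) {
    if (a1[i] == 0) {
      opts[[i]] <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    } else if (a1[i] == a2[i]) {
      b <- as.integer(a1[i] == 2)
      opts[[i]] <- list(c(b, b))
    } else {
      opts[[i]] <- list(c(0, 1), c(1, 0))
    }
  }
  pairs <- matrix(0L, 1, 2)
  for (i in seq_len(n)) {
    new <- list()
    for (r in seq_len(nrow(pairs))) {
      for (o in opts[[i]]) {
        new[[length(new) + 1]] <- c(pairs[r, 1] + o[1] * 2^(i - 1),
                                    pairs[r, 2] + o[2] * 2^(i - 1))
      }
    }
    pairs <- do.call(rbind, new)
  }
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  unique(cbind(lo, hi))
}

# Brute-force enumeration of all Mendelian-consistent configurations of
# one family: founders carry canonical unordered pairs, non-founders
# ordered (maternal, paternal) pairs.  Returns a sorted character vector
# of configuration keys "id=h1/h2;..." with member ids sorted.
oracle_configurations <- function(res, fid) {
  # enumerate per connected component of the parent-child graph, mirroring
  # the package's independent substructures for unrelated members
  all_sub <- res$ind[res$ind$fid == fid, , drop = FALSE]
  comp <- seq_len(nrow(all_sub))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(all_sub))) {
      if (all_sub$pat[i] != "0") {
        grp <- range(comp[c(i, match(all_sub$pat[i], all_sub$iid),
                            match(all_sub$mat[i], all_sub$iid))])
        if (grp[1] != grp[2]) {
          comp[comp == grp[2]] <- grp[1]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keys <- character(0)
  for (cc in unique(comp)) {
    keys <- c(keys,
              oracle_component(res, fid, all_sub$iid[comp == cc]))
  }
  sort(keys)
}

oracle_component <- function(res, fid, iids) {
  sel <- res$ind$fid == fid & res$ind$iid %in% iids
  sub <- res$ind[sel, , drop = FALSE]
  rows <- which(sel)
  n <- nrow(sub)
  # topological order: founders first
  depth <- integer(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (sub$pat[i] != "0") {
        d <- 1L + max(depth[match(sub$pat[i], sub$iid)],
                      depth[match(sub$mat[i], sub$iid)])
        if (d != depth[i]) { depth[i] <- d; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  ord <- order(depth)
  cand <- lapply(seq_len(n), function(i) {
    p <- oracle_individual_pairs(res$g1[rows[i], ], res$g2[rows[i], ])
    if (sub$pat[i] == "0") {
      p
    } else {
      sw <- p[p[, 1] != p[, 2], , drop = FALSE]
      rbind(p, cbind(sw[, 2], sw[, 1]))  # ordered (maternal, paternal)
    }
  })
  configs <- list()
  assign_next <- function(k, acc) {
    if (k > n) {
      ids <- sub$iid
      o <- order(ids)
      key <- paste(sprintf("%s=%d/%d", ids[o],
                           vapply(acc[o], `[`, numeric(1), 1),
                           vapply(acc[o], `[`, numeric(1), 2)),
                   collapse = ";")
      configs[[length(configs) + 1]] <<- key
      return(invisible(NULL))
    }
    i <- ord[k]
    for (r in seq_len(nrow(cand[[i]]))) {
      pair <- cand[[i]][r, ]
      ok <- TRUE
      if (sub$pat[i] != "0") {
        mo <- acc[[match(sub$mat[i], sub$iid)]]
        fa <- acc[[match(sub$pat[i], sub$iid)]]
        ok <- pair[1] %in% mo && pair[2] %in% fa
      }
      if (ok) {
        acc[[i]] <- pair
        assign_next(k + 1, acc)
      }
    }
  }
  assign_next(1, vector("list", n))
  sort(unlist(configs))
}

# Package-path configurations of a (single-family) resource, in the same
# canonical key form, using threshold 0 so every nuclear family is
# retained.
package_configurations <- function(res, fid) {
  subs <- hapmc:::build_substructures(res, min_genotyped_fraction = 0)
  keys <- character(0)
  for (cl in subs$classes) {
    for (inst in cl$instances) {
      rows <- inst
      if (!is.null(cl$tab$member_order)) rows <- inst[cl$tab$member_order]
      if (!all(res$ind$fid[rows] == fid)) next
      ids <- res$ind$iid[rows]
      for (r in seq_len(nrow(cl$tab$mat))) {
        pr <- lapply(seq_along(ids), function(m)
          c(cl$tab$mat[r, 2 * m - 1], cl$tab$mat[r, 2 * m]))
        o <- order(ids)
        keys <- c(keys, paste(sprintf("%s=%d/%d", ids[o],
                                      vapply(pr[o], `[`, numeric(1), 1),
                                      vapply(pr[o], `[`, numeric(1), 2)),
                              collapse = ";"))
      }
    }
  }
  sort(keys)
}

# Textbook genotype-EM for unrelated individuals (haplotype frequencies),
# independent of the package EM.
oracle_em_unrelated <- function(g1, g2, tol = 1e-10, max_iter = 5000) {
  n <- nrow(g1)
  pairs <- lapply(seq_len(n), function(i) oracle_individual_pairs(g1[i, ],
                                                                  g2[i, ]))
  universe <- sort(unique(unlist(pairs)))
  f <- stats::setNames(rep(1 / length(universe), length(universe)),
                       universe)
  for (it in seq_len(max_iter)) {
    cnt <- stats::setNames(numeric(length(universe)), universe)
    for (i in seq_len(n)) {
      p <- pairs[[i]]
      w <- ifelse(p[, 1] == p[, 2],
                  f[as.character(p[, 1])]^2,
                  2 * f[as.character(p[, 1])] * f[as.character(p[, 2])])
      w <- w / sum(w)
      for (r in seq_len(nrow(p))) {
        cnt[as.character(p[r, 1])] <- cnt[as.character(p[r, 1])] + w[r]
        cnt[as.character(p[r, 2])] <- cnt[as.character(p[r, 2])] + w[r]
      }
    }
    newf <- cnt / (2 * n)
    if (max(abs(newf - f)) < tol) { f <- newf; break }
    f <- newf
  }
  f
}
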