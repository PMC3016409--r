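#' @title Haplotype configuration enumeration
#' @description
#' After preprocessing, remaining unphased or missing positions are
#' expanded to every haplotype pair consistent with an individual's phase
#' state.  Nuclear-family configurations are then constructed with
#' genotype elimination integrated into the construction: building starts
#' from the offspring with the fewest haplotype possibilities and partial
#' configurations incompatible with Mendelian inheritance are discarded as
#' they arise.  Connected nuclear families are finally joined through
#' their linking individuals into whole-substructure configurations.
#'
#' Within a configuration, a child's pair is ordered (maternal, paternal);
#' a founder's pair is unordered and stored in canonical (sorted) form.
#' @name config_enum
NULL

# default cap on stored (partial) configurations
CONFIG_CAP <- 5e6

#' Enumerate haplotype pairs consistent with a phase state
#'
#' @param s a `phase_state`.
#' @param allowed optional integer vector restricting both haplotypes to a
#'   set of encoded haplotypes (used by partition-ligation).
#' @param max_pairs expansion cap; exceeding it is an error.
#' @return two-column integer matrix of canonical (sorted) haplotype pairs.
#' @export
individual_pairs <- function(s, allowed = NULL, max_pairs = 2^21) {
  n <- length(s$hom)
  h1 <- 0L
  h2 <- 0L
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    if (s$set[1, i] && s$set[2, i]) {
      h1 <- h1 + if (s$val[1, i]) bit else 0L
      h2 <- h2 + if (s$val[2, i]) bit else 0L
    } else if (s$het[i]) {
      # both unset, unphased heterozygote: allele 2 on either haplotype
      h1 <- c(h1, h1 + bit)
      h2 <- c(h2 + bit, h2)
    } else {
      # missing genotype: each unset haplotype free
      o1 <- if (s$set[1, i]) as.integer(s$val[1, i]) else 0:1
      o2 <- if (s$set[2, i]) as.integer(s$val[2, i]) else 0:1
      g <- expand.grid(a = o1, b = o2)
      h1 <- rep(h1, each = nrow(g)) + rep(g$a * bit, length(h1))
      h2 <- rep(h2, each = nrow(g)) + rep(g$b * bit, length(h2))
    }
    if (length(h1) > max_pairs) {
      stop("haplotype pair expansion exceeds cap (", max_pairs,
           "); raise the genotyping threshold")
    }
  }
  lo <- pmin(h1, h2)
  hi <- pmax(h1, h2)
  if (!is.null(allowed)) {
    keep <- (lo %in% allowed) & (hi %in% allowed)
    lo <- lo[keep]
    hi <- hi[keep]
  }
  key <- lo * 2^26 + hi
  dup <- duplicated(key)
  cbind(h1 = lo[!dup], h2 = hi[!dup], deparse.level = 0)
}

# All haplotypes consistent with an individual's own genotypes (used by the
# partition-ligation fallback).
genotype_consistent_haps <- function(s) {
  p <- individual_pairs(s)
  unique(as.vector(p))
}

#' Enumerate Mendelian-consistent nuclear-family configurations
#'
#' @param father_pairs,mother_pairs two-column matrices of canonical pairs.
#' @param child_pairs list of two-column matrices, one per offspring.
#' @param cap abort threshold on stored partial configurations.
#' @return list with `role` = c("F","M","C",...) and `mat`, an integer
#'   matrix with two columns per member: father and mother pairs sorted,
#'   child pairs ordered (maternal, paternal).  Zero rows signal Mendelian
#'   inconsistency (the caller decides whether that is an error).
#' @export
family_configurations <- function(father_pairs, mother_pairs, child_pairs,
                                  cap = CONFIG_CAP) {
  nk <- length(child_pairs)
  stopifnot(nk >= 1)
  ord <- order(vapply(child_pairs, nrow, integer(1)))
  # ordered (maternal, paternal) candidate assignments per child
  orient <- lapply(child_pairs, function(p) {
    sw <- p[p[, 1] != p[, 2], , drop = FALSE]
    rbind(cbind(p[, 1], p[, 2]), cbind(sw[, 2], sw[, 1]))
  })
  # seed from the child with the fewest possibilities
  first <- ord[1]
  o <- orient[[first]]
  im <- list(); ifa <- list(); kid <- list()
  for (r in seq_len(nrow(o))) {
    ms <- which(mother_pairs[, 1] == o[r, 1] | mother_pairs[, 2] == o[r, 1])
    fs <- which(father_pairs[, 1] == o[r, 2] | father_pairs[, 2] == o[r, 2])
    if (length(ms) == 0 || length(fs) == 0) next
    g <- expand.grid(m = ms, f = fs)
    im[[length(im) + 1]] <- g$m
    ifa[[length(ifa) + 1]] <- g$f
    kid[[length(kid) + 1]] <- matrix(rep(o[r, ], each = nrow(g)), ncol = 2)
  }
  if (length(im) == 0) {
    return(empty_family_config(nk))
  }
  im <- unlist(im)
  ifa <- unlist(ifa)
  kids <- vector("list", nk)
  kids[[first]] <- do.call(rbind, kid)
  # extend child by child, discarding incompatible partial configurations
  for (ci in ord[-1]) {
    o <- orient[[ci]]
    new_im <- integer(0); new_if <- integer(0)
    new_kids <- lapply(kids, function(x) NULL)
    add_rows <- vector("list", 0)
    sel_rows <- vector("list", 0)
    for (r in seq_len(nrow(o))) {
      okm <- mother_pairs[im, 1] == o[r, 1] | mother_pairs[im, 2] == o[r, 1]
      okf <- father_pairs[ifa, 1] == o[r, 2] | father_pairs[ifa, 2] == o[r, 2]
      sel <- which(okm & okf)
      if (length(sel) == 0) next
      sel_rows[[length(sel_rows) + 1]] <- sel
      add_rows[[length(add_rows) + 1]] <-
        matrix(rep(o[r, ], each = length(sel)), ncol = 2)
    }
    if (length(sel_rows) == 0) {
      return(empty_family_config(nk))
    }
    sel <- unlist(sel_rows)
    if (length(sel) > cap) {
      stop("configuration count exceeds cap (", cap,
           "); raise the genotyping threshold")
    }
    im <- im[sel]
    ifa <- ifa[sel]
    for (cj in seq_len(nk)) {
      if (!is.null(kids[[cj]])) kids[[cj]] <- kids[[cj]][sel, , drop = FALSE]
    }
    kids[[ci]] <- do.call(rbind, add_rows)
  }
  mat <- cbind(father_pairs[ifa, , drop = FALSE],
               mother_pairs[im, , drop = FALSE])
  for (cj in seq_len(nk)) mat <- cbind(mat, kids[[cj]])
  storage.mode(mat) <- "integer"
  list(role = c("F", "M", rep("C", nk)), mat = mat)
}

empty_family_config <- function(nk) {
  list(role = c("F", "M", rep("C", nk)),
       mat = matrix(integer(0), 0, 2 * (2 + nk)))
}

# key for joining on a member's pair: order-free (sorted)
pair_key <- function(mat, col) {
  a <- mat[, col, drop = TRUE]
  b <- mat[, col + 1L, drop = TRUE]
  pmin(a, b) * 2^26 + pmax(a, b)
}

#' Assemble whole-substructure configurations
#'
#' Joins the configuration tables of connected nuclear families on the
#' equality of each linking individual's haplotype pair (compared
#' unordered; the ordered maternal/paternal form is kept from the family
#' in which the individual is an offspring).
#'
#' @param tables list of per-family tables: each `list(members, role, mat)`
#'   as produced by [family_configurations()] plus a `members` id vector.
#' @param cap abort threshold on stored configurations.
#' @return one joined table `list(members, role, mat)`; roles are "C" for
#'   members that are offspring in some family, else "F" (founder of the
#'   substructure).
#' @export
assemble_substructure <- function(tables, cap = CONFIG_CAP) {
  stopifnot(length(tables) >= 1)
  acc <- tables[[1]]
  todo <- tables[-1]
  while (length(todo) > 0) {
    linked <- which(vapply(todo, function(t)
      length(intersect(t$members, acc$members)) > 0, logical(1)))
    if (length(linked) == 0) {
      stop("substructure families are not connected")
    }
    t2 <- todo[[linked[1]]]
    todo <- todo[-linked[1]]
    acc <- join_config_tables(acc, t2, cap)
    if (nrow(acc$mat) == 0) return(acc)
  }
  acc
}

join_config_tables <- function(a, b, cap = CONFIG_CAP) {
  shared <- intersect(a$members, b$members)
  key_of <- function(t) {
    cols <- 2L * match(shared, t$members) - 1L
    k <- rep("", nrow(t$mat))
    for (cc in cols) k <- paste(k, pair_key(t$mat, cc))
    k
  }
  ka <- key_of(a)
  kb <- key_of(b)
  bmap <- split(seq_along(kb), kb)
  hits <- bmap[ka]
  na <- vapply(hits, length, integer(1))
  na[is.na(names(hits)) | !(ka %in% names(bmap))] <- 0L
  ia <- rep(seq_along(ka), na)
  ib <- unlist(hits[na > 0], use.names = FALSE)
  if (length(ia) > cap) {
    stop("configuration count exceeds cap (", cap,
         "); raise the genotyping threshold")
  }
  new_members <- c(a$members, setdiff(b$members, shared))
  role <- c(a$role, b$role[match(setdiff(b$members, shared), b$members)])
  # a shared member that is a child in b upgrades role and takes b's ordered
  # columns
  mat <- matrix(0L, length(ia), 2L * length(new_members))
  for (m in seq_along(new_members)) {
    id <- new_members[m]
    src <- NULL
    if (id %in% shared) {
      ra <- a$role[match(id, a$members)]
      rb <- b$role[match(id, b$members)]
      if (rb == "C" && ra != "C") {
        src <- list(t = b, idx = ib)
        role[m] <- "C"
      } else {
        src <- list(t = a, idx = ia)
      }
    } else if (id %in% a$members) {
      src <- list(t = a, idx = ia)
    } else {
      src <- list(t = b, idx = ib)
    }
    cc <- 2L * match(id, src$t$members) - 1L
    mat[, 2L * m - 1L] <- src$t$mat[src$idx, cc]
    mat[, 2L * m] <- src$t$mat[src$idx, cc + 1L]
  }
  list(members = new_members, role = role, mat = mat)
}
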