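#' @title Pedigreed genotype resources
#' @description
#' A *resource* is a mixed collection of pedigrees and independent
#' singletons typed at a common set of tightly linked biallelic SNP
#' markers.  It is represented as an S3 object of class `hap_resource`
#' holding an individual table (family id, individual id, parent ids, sex,
#' affection status) and two allele matrices (one row per individual, one
#' column per marker, codes 1/2 with 0 for missing).  Alleles within a
#' genotype are unordered; phase is never part of the input.
#' @name hap_resource
NULL

SEX_CODES <- c(unknown = 0L, male = 1L, female = 2L)
AFF_CODES <- c(unknown = 0L, unaffected = 1L, affected = 2L)

ind_key <- function(fid, iid) paste(fid, iid, sep = "\r")

#' Construct a genotype resource
#'
#' @param ind data.frame with character columns `fid`, `iid`, `pat`, `mat`
#'   (`"0"` for no parent), and integer columns `sex` (0 unknown, 1 male,
#'   2 female) and `aff` (0 unknown, 1 unaffected, 2 affected).
#' @param g1,g2 integer matrices (individuals x markers) of allele codes in
#'   \{0, 1, 2\}, 0 meaning missing.  A genotype with exactly one missing
#'   allele is coerced to fully missing.
#' @param markers optional data.frame with columns `index` (0-based) and
#'   `id`; defaults to `M1..Mn`.
#' @return object of class `hap_resource`.
#' @export
hap_resource <- function(ind, g1, g2, markers = NULL) {
  stopifnot(is.data.frame(ind), is.matrix(g1), is.matrix(g2))
  n_loci <- ncol(g1)
  if (is.null(markers)) {
    markers <- data.frame(index = seq_len(n_loci) - 1L,
                          id = paste0("M", seq_len(n_loci)),
                          stringsAsFactors = FALSE)
  }
  ind$fid <- as.character(ind$fid)
  ind$iid <- as.character(ind$iid)
  ind$pat <- as.character(ind$pat)
  ind$mat <- as.character(ind$mat)
  ind$sex <- as.integer(ind$sex)
  ind$aff <- as.integer(ind$aff)
  rownames(ind) <- NULL
  storage.mode(g1) <- "integer"
  storage.mode(g2) <- "integer"
  res <- structure(list(ind = ind, g1 = g1, g2 = g2, markers = markers),
                   class = "hap_resource")
  validate_resource(res)
}

# Coerce half-missing genotypes to fully missing and check all invariants.
validate_resource <- function(res) {
  ind <- res$ind
  n <- nrow(ind)
  if (nrow(res$g1) != n || nrow(res$g2) != n) {
    stop("genotype matrices must have one row per individual")
  }
  if (ncol(res$g1) != ncol(res$g2)) stop("allele matrices differ in width")
  if (ncol(res$g1) != nrow(res$markers)) {
    stop("marker table does not match genotype width")
  }
  if (!all(res$markers$index == seq_len(nrow(res$markers)) - 1L)) {
    stop("marker indices must be consecutive 0-based")
  }
  bad <- !(res$g1 %in% 0:2) | !(res$g2 %in% 0:2)
  if (any(bad)) stop("allele code outside {0,1,2}")
  half <- xor(res$g1 == 0L, res$g2 == 0L)
  if (any(half)) {
    message(sum(half), " half-missing genotype(s) coerced to fully missing")
    res$g1[half] <- 0L
    res$g2[half] <- 0L
  }
  key <- ind_key(ind$fid, ind$iid)
  if (anyDuplicated(key)) stop("duplicated individual id within family")
  # parents: both-or-neither, and must exist within the family
  has_p <- ind$pat != "0"
  has_m <- ind$mat != "0"
  if (any(has_p != has_m)) {
    i <- which(has_p != has_m)[1]
    stop(sprintf("individual %s/%s names only one parent (both-or-neither)",
                 ind$fid[i], ind$iid[i]))
  }
  for (i in which(has_p)) {
    for (p in c(ind$pat[i], ind$mat[i])) {
      if (!ind_key(ind$fid[i], p) %in% key) {
        stop(sprintf("individual %s/%s references nonexistent parent %s",
                     ind$fid[i], ind$iid[i], p))
      }
    }
  }
  # parent-child graph must be acyclic within each family
  for (f in unique(ind$fid)) {
    sub <- ind[ind$fid == f, , drop = FALSE]
    depth <- rep(NA_integer_, nrow(sub))
    names(depth) <- sub$iid
    resolve <- function(id, seen) {
      if (id %in% seen) stop("pedigree cycle in family ", f)
      if (!is.na(depth[id])) return(depth[id])
      row <- which(sub$iid == id)
      d <- if (sub$pat[row] == "0") 0L else {
        max(resolve(sub$pat[row], c(seen, id)),
            resolve(sub$mat[row], c(seen, id))) + 1L
      }
      depth[id] <<- d
      d
    }
    for (id in sub$iid) resolve(id, character(0))
  }
  res
}

#' @export
print.hap_resource <- function(x, ...) {
  nf <- sum(x$ind$pat == "0")
  cat(sprintf("hap_resource: %d individuals (%d founders/independents), %d families, %d markers\n",
              nrow(x$ind), nf, length(unique(x$ind$fid)), nrow(x$markers)))
  invisible(x)
}

n_loci <- function(res) nrow(res$markers)

#' Read a LINKAGE-style pedigree file
#'
#' Reads a whitespace-delimited pre-makeped ped file with six fixed columns
#' (family id, individual id, father id, mother id, sex, affection) followed
#' by two allele columns per marker (codes 1/2, 0 = missing), plus a marker
#' info file (one marker id per line, optionally preceded by an index
#' column).
#'
#' @param ped_path path to the ped file.
#' @param marker_path optional path to the marker info file; if `NULL`,
#'   markers are named `M1..Mn`.
#' @return a [hap_resource].
#' @examples
#' ped <- system.file("extdata", "trios_synthetic.ped", package = "hapmc")
#' map <- system.file("extdata", "trios_synthetic.map", package = "hapmc")
#' res <- read_ped(ped, map)
#' nuclear_families(res, res$ind$fid[1])
#' @export
read_ped <- function(ped_path, marker_path = NULL) {
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  if (length(unique(len)) != 1) {
    stop("ragged ped file: differing column counts at line ",
         which(len != len[1])[1])
  }
  if (len[1] < 8 || (len[1] - 6) %% 2 != 0) {
    stop("ped file must have 6 fixed columns plus 2 allele columns per marker")
  }
  nl <- (len[1] - 6L) %/% 2L
  m <- do.call(rbind, fields)
  ind <- data.frame(fid = m[, 1], iid = m[, 2], pat = m[, 3], mat = m[, 4],
                    sex = suppressWarnings(as.integer(m[, 5])),
                    aff = suppressWarnings(as.integer(m[, 6])),
                    stringsAsFactors = FALSE)
  if (any(is.na(ind$sex)) || any(is.na(ind$aff))) {
    stop("non-integer sex/affection column in ped file")
  }
  al <- suppressWarnings(matrix(as.integer(m[, -(1:6), drop = FALSE]),
                                nrow = nrow(m)))
  if (any(is.na(al)) || !all(al %in% 0:2)) {
    bad <- which(is.na(al) | !(al %in% 0:2), arr.ind = TRUE)[1, 1]
    stop("allele code outside {0,1,2} at ped line ", bad)
  }
  g1 <- al[, 2 * seq_len(nl) - 1L, drop = FALSE]
  g2 <- al[, 2 * seq_len(nl), drop = FALSE]
  markers <- NULL
  if (!is.null(marker_path)) {
    mk <- utils::read.table(marker_path, header = FALSE,
                            stringsAsFactors = FALSE)
    ids <- if (ncol(mk) >= 2) as.character(mk[[2]]) else as.character(mk[[1]])
    if (length(ids) != nl) {
      stop(sprintf("marker file lists %d markers but ped file has %d",
                   length(ids), nl))
    }
    markers <- data.frame(index = seq_len(nl) - 1L, id = ids,
                          stringsAsFactors = FALSE)
  }
  hap_resource(ind, g1, g2, markers)
}

#' Write a resource as LINKAGE-style ped and marker files
#'
#' @param res a [hap_resource].
#' @param ped_path,marker_path output paths (`marker_path` may be `NULL`).
#' @return `res`, invisibly.
#' @export
write_ped <- function(res, ped_path, marker_path = NULL) {
  nl <- n_loci(res)
  al <- matrix(0L, nrow(res$ind), 2L * nl)
  al[, 2 * seq_len(nl) - 1L] <- res$g1
  al[, 2 * seq_len(nl)] <- res$g2
  out <- cbind(res$ind$fid, res$ind$iid, res$ind$pat, res$ind$mat,
               res$ind$sex, res$ind$aff, al)
  writeLines(apply(out, 1, paste, collapse = "\t"), ped_path)
  if (!is.null(marker_path)) {
    writeLines(sprintf("%d\t%s", res$markers$index, res$markers$id),
               marker_path)
  }
  invisible(res)
}

#' Nuclear families of a pedigree
#'
#' Lists every mated parent pair with their common offspring, for one family
#' of a resource.  Overlapping families share linking individuals.
#'
#' @param res a [hap_resource].
#' @param fid family id.
#' @return list of `list(father, mother, offspring)` (individual ids).
#' @export
nuclear_families <- function(res, fid) {
  sub <- res$ind[res$ind$fid == fid, , drop = FALSE]
  kids <- sub[sub$pat != "0", , drop = FALSE]
  if (nrow(kids) == 0) return(list())
  pairs <- unique(kids[, c("pat", "mat")])
  lapply(seq_len(nrow(pairs)), function(i) {
    sel <- kids$pat == pairs$pat[i] & kids$mat == pairs$mat[i]
    list(father = pairs$pat[i], mother = pairs$mat[i],
         offspring = kids$iid[sel])
  })
}

# Fraction of non-missing markers per individual.
genotyped_fraction <- function(res) {
  rowMeans(res$g1 != 0L)
}

# Subset a resource to a set of loci (1-based), keeping all individuals.
subset_loci <- function(res, loci) {
  hap_resource(res$ind,
               res$g1[, loci, drop = FALSE],
               res$g2[, loci, drop = FALSE],
               data.frame(index = seq_along(loci) - 1L,
                          id = res$markers$id[loci],
                          stringsAsFactors = FALSE))
}
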