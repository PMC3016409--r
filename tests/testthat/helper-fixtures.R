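# Programmatic fixtures: random Mendelian-consistent pedigree resources
# built by assigning founder haplotypes and gene-dropping, then masking
# genotypes at random.

# Random pedigree structure table.  `kind` picks a template:
# "trio", "nuclear" (2-4 kids), "threegen" (grandparents, parents, kids),
# "mixed" (one nuclear family plus singletons).
random_structure <- function(kind = c("trio", "nuclear", "threegen",
                                      "mixed")) {
  kind <- match.arg(kind)
  trio <- data.frame(iid = c("F", "M", "C1"), pat = c("0", "0", "F"),
                     mat = c("0", "0", "M"), stringsAsFactors = FALSE)
  if (kind == "trio") return(trio)
  if (kind == "nuclear") {
    k <- sample(2:4, 1)
    return(data.frame(iid = c("F", "M", paste0("C", 1:k)),
                      pat = c("0", "0", rep("F", k)),
                      mat = c("0", "0", rep("M", k)),
                      stringsAsFactors = FALSE))
  }
  if (kind == "threegen") {
    k <- sample(1:2, 1)
    return(data.frame(
      iid = c("GF", "GM", "F", "M", paste0("C", 1:k), "U"),
      pat = c("0", "0", "GF", "0", rep("F", k), "GF"),
      mat = c("0", "0", "GM", "0", rep("M", k), "GM"),
      stringsAsFactors = FALSE))
  }
  data.frame(iid = c("F", "M", "C1", "C2", "X"),
             pat = c("0", "0", "F", "F", "0"),
             mat = c("0", "0", "M", "M", "0"),
             stringsAsFactors = FALSE)
}

# Gene-drop over a structure from a random frequency table; returns a
# hap_resource plus the hidden true haplotypes.
random_ped_resource <- function(kind = "trio", n_loci = 3,
                                missing_rate = 0.1, fid = "F1") {
  st <- random_structure(kind)
  n <- nrow(st)
  nh <- 2^n_loci
  freq <- stats::rgamma(nh, 1) ; freq <- freq / sum(freq)
  haps <- 0:(nh - 1)
  h1 <- integer(n); h2 <- integer(n)
  done <- rep(FALSE, n)
  repeat {
    todo <- which(!done)
    if (!length(todo)) break
    for (i in todo) {
      if (st$pat[i] == "0") {
        h1[i] <- sample(haps, 1, prob = freq)
        h2[i] <- sample(haps, 1, prob = freq)
        done[i] <- TRUE
      } else {
        fa <- match(st$pat[i], st$iid); mo <- match(st$mat[i], st$iid)
        if (done[fa] && done[mo]) {
          h1[i] <- sample(c(h1[mo], h2[mo]), 1)
          h2[i] <- sample(c(h1[fa], h2[fa]), 1)
          done[i] <- TRUE
        }
      }
    }
  }
  g1 <- matrix(0L, n, n_loci); g2 <- matrix(0L, n, n_loci)
  for (j in seq_len(n_loci)) {
    a <- bitwAnd(bitwShiftR(h1, j - 1L), 1L) + 1L
    b <- bitwAnd(bitwShiftR(h2, j - 1L), 1L) + 1L
    g1[, j] <- pmin(a, b); g2[, j] <- pmax(a, b)
  }
  drop <- matrix(stats::runif(n * n_loci) < missing_rate, n)
  g1[drop] <- 0L; g2[drop] <- 0L
  ind <- data.frame(fid = fid, iid = st$iid, pat = st$pat, mat = st$mat,
                    sex = 0L, aff = sample(1:2, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  list(resource = hap_resource(ind, g1, g2), h1 = h1, h2 = h2)
}

# A small unrelated case-control resource from a fixed frequency table.
random_cc_resource <- function(n_ind, n_loci = 3, missing_rate = 0,
                               freq = NULL) {
  nh <- 2^n_loci
  if (is.null(freq)) { freq <- stats::rgamma(nh, 1); freq <- freq / sum(freq) }
  h1 <- sample(0:(nh - 1), n_ind, replace = TRUE, prob = freq)
  h2 <- sample(0:(nh - 1), n_ind, replace = TRUE, prob = freq)
  g1 <- matrix(0L, n_ind, n_loci); g2 <- matrix(0L, n_ind, n_loci)
  for (j in seq_len(n_loci)) {
    a <- bitwAnd(bitwShiftR(h1, j - 1L), 1L) + 1L
    b <- bitwAnd(bitwShiftR(h2, j - 1L), 1L) + 1L
    g1[, j] <- pmin(a, b); g2[, j] <- pmax(a, b)
  }
  drop <- matrix(stats::runif(n_ind * n_loci) < missing_rate, n_ind)
  g1[drop] <- 0L; g2[drop] <- 0L
  ind <- data.frame(fid = paste0("S", seq_len(n_ind)), iid = "1",
                    pat = "0", mat = "0", sex = 0L,
                    aff = rep(1:2, length.out = n_ind),
                    stringsAsFactors = FALSE)
  list(resource = hap_resource(ind, g1, g2), h1 = h1, h2 = h2)
}
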