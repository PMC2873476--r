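# Independent oracles used across the test files. Each one recomputes a
# quantity by brute force or via a different library than the implementation
# under test.

# --- fitting (semi-global) alignment oracle ---------------------------------
# Affine-gap dynamic program: pattern aligned end-to-end, subject local
# (leading/trailing subject skips free). Match +1, mismatch -1, a gap of
# length L costs 1 + L (open -2 counting the first base, extend -1).
oracle_fit_score <- function(pattern, subject) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  open <- 2; ext <- 1
  M <- matrix(NEG, m + 1, n + 1)  # ends in aligned pair
  X <- matrix(NEG, m + 1, n + 1)  # ends in gap consuming subject
  Y <- matrix(NEG, m + 1, n + 1)  # ends in gap consuming pattern
  M[1, ] <- 0                     # free start anywhere in subject
  for (i in 1:m) Y[i + 1, 1] <- -(open + (i - 1) * ext)
  for (i in 1:m) {
    for (j in 1:n) {
      sub <- if (p[i] == s[j]) 1 else -1
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i + 1, j] - open, X[i + 1, j] - ext,
                             Y[i + 1, j] - open)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - open, Y[i, j + 1] - ext,
                             X[i, j + 1] - open)
    }
  }
  max(M[m + 1, ], Y[m + 1, ], X[m + 1, ])  # free end anywhere in subject
}

# Best score of a read over every amplicon and both strands.
oracle_best_score <- function(read, panel) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  max(vapply(panel$amplicons, function(a) {
    max(oracle_fit_score(read, a$reference_seq),
        oracle_fit_score(rc, a$reference_seq))
  }, numeric(1)))
}

# --- minimal-CN composition oracle ------------------------------------------
# Enumerates every composition of every n <= max_cn into parts >= 1 and
# returns the smallest n whose best (minimum max-deviation) composition
# meets tol.
oracle_minimal_cn <- function(counts, tol = 0.05, max_cn = 12) {
  f <- counts / sum(counts)
  k <- length(f)
  compositions <- function(n, parts) {
    if (parts == 1) return(list(n))
    out <- list()
    for (first in 1:(n - parts + 1)) {
      for (rest in compositions(n - first, parts - 1)) {
        out[[length(out) + 1]] <- c(first, rest)
      }
    }
    out
  }
  for (n in k:max_cn) {
    devs <- vapply(compositions(n, k),
                   function(a) max(abs(f - a / n)), numeric(1))
    if (min(devs) <= tol + 1e-9) {
      comps <- compositions(n, k)
      return(list(n = n, composition = comps[[which.min(devs)]],
                  deviation = min(devs)))
    }
  }
  NULL
}

# --- minimum-support transportation oracle ----------------------------------
# Exhaustive search over ALL arc subsets (not size-ordered): minimum number
# of arcs covering every node, maximizing transported mass at that size.
# Max flow per subset is delegated to igraph, independently of the
# augmenting-path code in the package.
oracle_min_support <- function(supply, demand, arcs) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  nf <- length(supply); nr <- length(demand)
  m <- nrow(arcs)
  flow_of <- function(sub) {
    edges <- rbind(
      cbind(1, 1 + seq_len(nf)),
      cbind(1 + arcs$i[sub], 1 + nf + arcs$j[sub]),
      cbind(1 + nf + seq_len(nr), 2 + nf + nr))
    caps <- c(supply, rep(sum(supply) + 1, length(sub)), demand)
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    igraph::max_flow(g, source = 1, target = 2 + nf + nr,
                     capacity = caps)$value
  }
  best_size <- Inf; best_flow <- -Inf
  for (mask in 1:(2^m - 1)) {
    sub <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (!all(seq_len(nf) %in% arcs$i[sub])) next
    if (!all(seq_len(nr) %in% arcs$j[sub])) next
    size <- length(sub)
    if (size > best_size) next
    fl <- flow_of(sub)
    if (size < best_size || fl > best_flow + 1e-12) {
      best_size <- size; best_flow <- fl
    }
  }
  list(support_size = best_size, flow = best_flow)
}

# --- misc -------------------------------------------------------------------
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
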