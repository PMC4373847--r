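# Shared builders and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# quick structural-only matrix from a 0/1/? state grid (taxa x chars)
toy_matrix <- function(states, taxa = rownames(states)) {
  states <- as.matrix(states)
  if (is.null(colnames(states))) {
    colnames(states) <- sprintf("S.c%02d", seq_len(ncol(states)))
  }
  defs <- lapply(colnames(states), function(id)
    character_def(id, "structural", id))
  character_matrix(taxa, defs, states)
}

random_binary_matrix <- function(taxa, n_char, p_missing = 0.1) {
  st <- matrix(sample(c("0", "1"), length(taxa) * n_char, replace = TRUE),
               length(taxa), n_char, dimnames = list(taxa, NULL))
  miss <- matrix(stats::runif(length(st)) < p_missing, nrow(st))
  st[miss] <- "?"
  # keep every character scored in at least one taxon
  for (j in seq_len(ncol(st))) {
    if (all(st[, j] == "?")) st[1L, j] <- sample(c("0", "1"), 1L)
  }
  toy_matrix(st, taxa)
}

# Brute-force Fitch oracle: minimise the number of state-change edges over
# every assignment of {0,1} to internal nodes and to '?' tips. Independent of
# the production bitmask pass.
oracle_fitch <- function(tree, matrix) {
  st <- matrix$states[match(tree$tip.label, matrix$taxa), , drop = FALSE]
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  total <- 0L
  for (ci in seq_len(ncol(st))) {
    fixed <- rep(NA_integer_, M)
    fixed[seq_len(n)] <- c("0" = 0L, "1" = 1L)[st[, ci]]
    free <- which(is.na(fixed))
    best <- Inf
    for (code in seq_len(2L^length(free)) - 1L) {
      assign <- fixed
      assign[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L)
      chg <- sum(assign[tree$edge[, 1L]] != assign[tree$edge[, 2L]])
      if (chg < best) best <- chg
    }
    total <- total + best
  }
  as.integer(total)
}

# the published rooted topology shape used across simulation tests:
# outgroup (DEC,(DRO,DYO)) against the ingroup (TSA,(LSI,(PHA,PDI)))
fig_tree <- function() {
  ape::read.tree(
    text = "((DEC:1,(DRO:1,DYO:1):1):1,(TSA:1,(LSI:1,(PHA:1,PDI:1):1):1):1);")
}

# 5-taxon matrix in which clade {A,B} is supported by k clean, uncontradicted
# characters plus optional uninformative filler autapomorphies
clean_clade_matrix <- function(k, filler = 0L) {
  taxa <- c("A", "B", "C", "D", "E")
  st <- matrix("0", 5L, k + filler, dimnames = list(taxa, NULL))
  st[c("A", "B"), seq_len(k)] <- "1"
  if (filler > 0L) {
    for (j in seq_len(filler)) st[1L + (j %% 5L), k + j] <- "1"
  }
  toy_matrix(st)
}

# identity self-map of the reference species (every probe paints itself)
identity_map <- function(k) {
  labels <- c(k$autosome_pairs$label, k$sex_system$label[1L])
  homology_map(k$species_code, k$species_code,
               data.frame(probe = labels, target = labels,
                          n_blocks = 1L, region = NA_character_,
                          stringsAsFactors = FALSE))
}

expect_empty_report <- function(report) {
  expect_s3_class(report, "data.frame")
  expect_identical(nrow(report), 0L)
}
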