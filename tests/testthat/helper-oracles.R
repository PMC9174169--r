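# Independent oracles used across test files. These deliberately avoid the
# package's code paths: plain dynamic programming, brute-force column
# counting, exhaustive enumeration.

rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random coding string: ATG + sense codons, no stops
rand_coding <- function(ncodons) {
  nt <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nt, nt, nt), 1, paste0, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0(c("ATG", sample(sense, ncodons - 1, replace = TRUE)),
         collapse = "")
}

# Smith-Waterman score by straightforward DP (linear gap penalty).
sw_score_oracle <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (x[i] == y[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                           H[i + 1, j] + gap)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# percent identity / distance by brute-force column counting
pid_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  ok <- x != "-" & y != "-"
  100 * sum(x[ok] == y[ok]) / sum(ok)
}

# per-codon synonymous site fraction by exhaustive enumeration
syn_sites_oracle <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  nt <- c("A", "C", "G", "T")
  cs <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(nt, cs[pos])) {
    alt <- cs; alt[pos] <- b
    a2 <- code[[paste0(alt, collapse = "")]]
    if (identical(a2, aa) && a2 != "*") s <- s + 1
  }
  s / 3
}

# losses of an LCA reconciliation by explicit embedding walk: every gene
# edge is traced through the species tree; at every species node it passes
# through, the sibling branch not containing the next step loses a copy;
# a duplication edge additionally fails to reach the sibling of its own
# mapped node.
loss_oracle <- function(gene_tree, species_tree) {
  gt <- gene_tree; st <- species_tree
  ntg <- ape::Ntip(gt); nts <- ape::Ntip(st)
  sp <- sub("_.*$", "", gt$tip.label)
  smap <- integer(ntg + gt$Nnode)
  smap[seq_len(ntg)] <- match(sp, st$tip.label)
  below <- function(v) if (v <= nts) v else
    c(v, unlist(lapply(st$edge[st$edge[, 1] == v, 2], below)))
  desc <- lapply(seq_len(nts + st$Nnode), below)
  # LCA: the common ancestor with the fewest descendants
  lca2 <- function(a, b) {
    cands <- which(vapply(desc, function(dd) a %in% dd && b %in% dd,
                          logical(1)))
    cands[which.min(lengths(desc)[cands])]
  }
  post <- rev(ape::reorder.phylo(gt, "cladewise")$edge[, 2])
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  for (v in c(post, ntg + 1L)) {
    if (v <= ntg) next
    ks <- kids[[as.character(v)]]
    smap[v] <- Reduce(lca2, smap[ks])
  }
  sparent <- rep(NA_integer_, nts + st$Nnode)
  sparent[st$edge[, 2]] <- st$edge[, 1]
  losses <- 0L
  for (e in seq_len(nrow(gt$edge))) {
    u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
    dup <- any(smap[kids[[as.character(u)]]] == smap[u])
    x <- smap[v]
    steps <- integer(0)
    while (x != smap[u]) { x <- sparent[x]; steps <- c(steps, x) }
    d <- length(steps)
    losses <- losses + max(0L, d - 1L) + if (dup && d >= 1) 1L else 0L
  }
  losses
}
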