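#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (deterministic for a given matrix), or its
#' variance-weighted variant BIONJ, which is preferable when the matrix
#' mixes shallow and deep (high-variance, near-saturated) distances.
#' Negative branch lengths are clamped to zero; when this happens the
#' returned tree carries attribute `clamped` listing the affected edges
#' and a warning is raised.
#'
#' @param d symmetric distance matrix (>= 3 taxa) with finite entries.
#' @param method `"nj"` (default) or `"bionj"`.
#' @return an unrooted `phylo` tree with branch lengths in subs/site.
#' @export
nj_tree <- function(d, method = c("nj", "bionj")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("non-finite distance entries")
  tr <- if (method == "bionj") ape::bionj(stats::as.dist(d))
        else ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    warning(length(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- neg
  }
  tr
}

#' Bootstrap support for NJ trees
#'
#' Resamples alignment columns with replacement, rebuilds the JC69/NJ tree
#' per replicate, and scores each internal edge of the full-data tree by
#' the fraction of replicate trees containing the same split. Supports are
#' stored as node labels in `[0, 1]`.
#'
#' @param aln named character vector of aligned nt sequences.
#' @param n number of replicates (>= 1).
#' @param seed RNG seed.
#' @param outgroup optional tip set; when given, the full-data tree is
#'   rooted on it before supports are assigned (splits are still compared
#'   unrooted).
#' @param keep_trees also return the replicate trees.
#' @return the NJ tree of the full alignment with `node.label` supports;
#'   with `keep_trees = TRUE`, attribute `replicates` (a `multiPhylo`).
#' @export
bootstrap_support <- function(aln, n = 100L, seed = NULL, outgroup = NULL,
                              keep_trees = FALSE) {
  stopifnot(n >= 1)
  m <- aln_matrix(aln)
  if (ncol(m) < 2) stop("alignment has fewer than 2 columns")
  if (!is.null(seed)) set.seed(seed)
  base <- nj_tree(jc69_distance_matrix(aln))
  if (!is.null(outgroup)) base <- root_tree(base, outgroup)
  reps <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    ab <- apply(mb, 1, paste0, collapse = "")
    names(ab) <- names(aln)
    reps[[b]] <- suppressWarnings(nj_tree(jc69_distance_matrix(ab)))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base$node.label <- counts / n
  if (keep_trees) attr(base, "replicates") <- reps
  base
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup leaves from the
#' rest. Fails, listing the conflicting leaves, when the outgroup is not
#' separable by a single edge.
#'
#' @param tree a `phylo` (typically unrooted NJ output).
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup) {
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss)) stop("outgroup leaves not in tree: ",
                         paste(miss, collapse = ", "))
  sep <- if (length(outgroup) == 1L ||
             length(outgroup) == length(tree$tip.label) - 1L) TRUE
         else ape::is.monophyletic(tree, outgroup)
  if (!sep)
    stop("outgroup is not separable by one edge; conflicting leaves: ",
         paste(outgroup, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  rooted
}

#' Test monophyly of a leaf set with a support threshold
#'
#' TRUE when the clade descending from the set's MRCA equals the set and
#' the support recorded at the MRCA (if any) is at least `min_support`.
#' Singleton sets and the full leaf set are monophyletic by convention.
#'
#' @param tree rooted `phylo`, optionally with numeric `node.label`
#'   supports in `[0, 1]`.
#' @param leaves character vector of tip labels.
#' @param min_support required support (default 0.7); ignored when the
#'   tree carries no support values.
#' @return list: `monophyletic`, `mrca` (node id), `support` (NA if none).
#' @export
is_monophyletic <- function(tree, leaves, min_support = 0.7) {
  if (!length(leaves)) stop("empty leaf set")
  miss <- setdiff(leaves, tree$tip.label)
  if (length(miss)) stop("unknown leaves: ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  if (length(leaves) == 1L)
    return(list(monophyletic = TRUE, mrca = match(leaves, tree$tip.label),
                support = NA_real_))
  node <- ape::getMRCA(tree, leaves)
  clade <- ape::extract.clade(tree, node)$tip.label
  mono <- setequal(clade, leaves)
  supp <- NA_real_
  if (!is.null(tree$node.label)) {
    s <- suppressWarnings(as.numeric(tree$node.label[node - ntip]))
    if (!is.na(s)) supp <- s
  }
  if (mono && !is.na(supp) && node != ntip + 1L && supp < min_support)
    mono <- FALSE
  list(monophyletic = mono, mrca = node, support = supp)
}
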