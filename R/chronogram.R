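#' Chronograms: dated species trees
#'
#' A chronogram is a rooted, binary, ultrametric [ape::phylo] tree whose
#' branch lengths are absolute times in million years (MY). Leaves sit at
#' age 0 and every internal node is strictly older than each of its
#' children. `as_chronogram()` validates a phylo object and stamps the
#' class; `node_ages()` returns the age of every node.
#'
#' @param phy a rooted `phylo` with branch lengths in MY.
#' @param tol numeric tolerance for the ultrametricity check (MY).
#' @return `as_chronogram()`: the tree with class `c("chronogram","phylo")`.
#' @export
as_chronogram <- function(phy, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("chronogram must be rooted")
  if (is.null(phy$edge.length)) stop("chronogram needs branch lengths (MY)")
  ages <- node_ages(phy)
  tip_ages <- ages[seq_len(ape::Ntip(phy))]
  if (any(abs(tip_ages) > tol)) {
    bad <- phy$tip.label[which.max(abs(tip_ages))]
    stop("tree is not ultrametric: leaf '", bad, "' has age ",
         format(tip_ages[which.max(abs(tip_ages))]))
  }
  parent_age <- ages[phy$edge[, 1]]
  child_age <- ages[phy$edge[, 2]]
  if (any(parent_age <= child_age - tol)) {
    i <- which(parent_age <= child_age - tol)[1]
    stop("node ", phy$edge[i, 1], " is not older than its child ",
         phy$edge[i, 2])
  }
  class(phy) <- unique(c("chronogram", class(phy)))
  phy
}

#' @rdname as_chronogram
#' @return `node_ages()`: numeric vector of ages (MY) indexed by node number
#'   (tips `1..Ntip`, internals `Ntip+1..`), tips at (numerically) 0.
#' @export
node_ages <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)   # distance from root
  ages <- max(depths) - depths
  # snap tiny numerical negatives
  ages[abs(ages) < 1e-9] <- 0
  ages
}

#' @rdname as_chronogram
#' @export
root_age <- function(phy) {
  node_ages(phy)[ape::Ntip(phy) + 1L]
}

#' Age of the most recent common ancestor of a set of leaves
#'
#' @param phy a chronogram.
#' @param leaves character vector of tip labels (length >= 1). For a single
#'   leaf the age is 0.
#' @return age in MY.
#' @export
mrca_age <- function(phy, leaves) {
  miss <- setdiff(leaves, phy$tip.label)
  if (length(miss)) stop("leaves not in tree: ", paste(miss, collapse = ", "))
  if (length(leaves) == 1L) return(0)
  node <- ape::getMRCA(phy, leaves)
  node_ages(phy)[node]
}

#' The default study chronogram
#'
#' Eight poppy (Papaver) species with sequenced genomes plus two outgroups,
#' with node ages in MY: Ranunculales crown 110, Papaveraceae crown 77,
#' Papaver crown (P. nudicaule vs Clade 2) 24.1, Clade 2 crown
#' (P. californicum split) 16.8, and the P. bracteatum / P. somniferum split
#' 9.7. The remaining internal ages (14, 12, 10.5 and 3 MY) are plausible
#' fill-ins consistent with those brackets.
#'
#' Species codes: Pnu P. nudicaule, Pca P. californicum, Prh P. rhoeas,
#' Pat P. atlanticum, Par P. armeniacum, Pbr P. bracteatum,
#' Pso P. somniferum, Pse P. setigerum; outgroups Aquilegia (Ranunculaceae)
#' and Eschscholzia (Papaveraceae).
#'
#' @param outgroups include the two non-Papaver outgroups (default TRUE).
#' @return a chronogram.
#' @export
papaver_chronogram <- function(outgroups = TRUE) {
  nwk <- paste0(
    "(Aquilegia:110,(Eschscholzia:77,(Pnu:24.1,(Pca:16.8,(Prh:14,",
    "(Pat:12,(Par:10.5,(Pbr:9.7,(Pso:3,Pse:3):6.7):0.8):1.5):2):2.8)",
    ":7.3):52.9):33);")
  phy <- ape::read.tree(text = nwk)
  if (!outgroups) {
    phy <- ape::drop.tip(phy, c("Aquilegia", "Eschscholzia"))
  }
  as_chronogram(phy)
}

#' Write / read a chronogram as Newick plus a node-age table
#'
#' The Newick carries branch lengths in MY; the sidecar TSV lists one row
#' per node (node id, a leaf-set fingerprint, age in MY).
#'
#' @param phy chronogram.
#' @param newick_path,ages_path output paths.
#' @return invisibly, the paths.
#' @export
write_chronogram <- function(phy, newick_path, ages_path) {
  ape::write.tree(phy, file = newick_path)
  ages <- node_ages(phy)
  ntip <- ape::Ntip(phy)
  labs <- vapply(seq_along(ages), function(i) {
    if (i <= ntip) phy$tip.label[i]
    else paste(sort(ape::extract.clade(phy, i)$tip.label), collapse = ",")
  }, character(1))
  df <- data.frame(node = seq_along(ages), leaves = labs, age_my = ages)
  utils::write.table(df, ages_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(newick_path, ages_path))
}
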