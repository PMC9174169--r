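## Gene-tree / species-tree reconciliation, Dollo losses, fusion bracketing.

# default mapping: species id = leaf-label prefix before the first "_"
species_prefix <- function(x) sub("_.*$", "", x)

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the species-tree node that is the LCA of
#' the species of its descendant genes, labels a gene node a duplication
#' exactly when it maps to the same species node as one of its children,
#' and counts losses with the standard path-difference rule (for a gene
#' edge whose endpoints map d species edges apart: d - 1 losses below a
#' speciation, d below a duplication).
#'
#' @param gene_tree rooted `phylo` over genes.
#' @param species_tree rooted `phylo` over species.
#' @param species_map function mapping gene tip labels to species ids
#'   (default: prefix before the first underscore).
#' @return list: `mapping` (gene node -> species node), `events`
#'   (`"speciation"`/`"duplication"`/`"leaf"` per gene node), `n_dup`,
#'   `n_loss`, `loss_branches` (species nodes whose stem carries a loss).
#' @export
lca_reconcile <- function(gene_tree, species_tree,
                          species_map = species_prefix) {
  gt <- gene_tree; st <- species_tree
  if (!ape::is.rooted(gt) || !ape::is.rooted(st))
    stop("both trees must be rooted")
  ntg <- ape::Ntip(gt); nts <- ape::Ntip(st)
  sp_of_tip <- species_map(gt$tip.label)
  bad <- setdiff(sp_of_tip, st$tip.label)
  if (length(bad)) stop("gene leaves map to unknown species: ",
                        paste(unique(bad), collapse = ", "))

  # species-tree helpers: parent and depth per node
  sparent <- rep(NA_integer_, nts + st$Nnode)
  sparent[st$edge[, 2]] <- st$edge[, 1]
  sroot <- nts + 1L
  sdepth <- integer(nts + st$Nnode)
  ord <- ape::reorder.phylo(st, "cladewise")$edge
  for (i in seq_len(nrow(ord))) sdepth[ord[i, 2]] <- sdepth[ord[i, 1]] + 1L
  s_lca <- function(a, b) {
    while (a != b) {
      if (sdepth[a] < sdepth[b]) b <- sparent[b] else a <- sparent[a]
    }
    a
  }

  gparent <- rep(NA_integer_, ntg + gt$Nnode)
  gparent[gt$edge[, 2]] <- gt$edge[, 1]
  kids <- split(gt$edge[, 2], gt$edge[, 1])

  mapping <- integer(ntg + gt$Nnode)
  mapping[seq_len(ntg)] <- match(sp_of_tip, st$tip.label)
  post <- rev(ape::reorder.phylo(gt, "cladewise")$edge[, 2])
  groot <- ntg + 1L
  for (v in c(post, groot)) {
    if (v <= ntg || mapping[v] != 0L) next
    ks <- kids[[as.character(v)]]
    mapping[v] <- Reduce(s_lca, mapping[ks])
  }
  # ensure every internal node mapped (root included)
  for (v in (ntg + 1L):(ntg + gt$Nnode)) if (mapping[v] == 0L) {
    ks <- kids[[as.character(v)]]
    mapping[v] <- Reduce(s_lca, mapping[ks])
  }

  events <- character(ntg + gt$Nnode)
  events[seq_len(ntg)] <- "leaf"
  for (v in (ntg + 1L):(ntg + gt$Nnode)) {
    ks <- kids[[as.character(v)]]
    events[v] <- if (any(mapping[ks] == mapping[v])) "duplication"
                 else "speciation"
  }

  n_loss <- 0L
  loss_branches <- integer(0)
  for (i in seq_len(nrow(gt$edge))) {
    u <- gt$edge[i, 1]; v <- gt$edge[i, 2]
    mu <- mapping[u]; mv <- mapping[v]
    # species nodes strictly between mv and mu, child-to-parent
    path <- integer(0)
    x <- mv
    while (x != mu) {
      x <- sparent[x]
      path <- c(path, x)
    }
    d <- length(path)                      # edges between mappings
    below <- mv
    intermediates <- if (d >= 1) head(path, -1) else integer(0)
    # losses on the sibling branch at each intermediate node, plus one at
    # mu itself when u is a duplication (the lineage fails to reach the
    # other child of mu)
    for (x in intermediates) {
      sib <- setdiff(st$edge[st$edge[, 1] == x, 2], below)
      loss_branches <- c(loss_branches, sib)
      below <- x
    }
    n_here <- length(intermediates)
    if (events[u] == "duplication" && d >= 1) {
      sib <- setdiff(st$edge[st$edge[, 1] == mu, 2], below)
      loss_branches <- c(loss_branches, sib)
      n_here <- n_here + 1L
    }
    n_loss <- n_loss + n_here
  }

  list(mapping = mapping, events = events,
       n_dup = sum(events == "duplication"), n_loss = n_loss,
       loss_branches = loss_branches)
}

#' Extract orthologous subgroups from a reconciled gene tree
#'
#' Subgroups are the maximal duplication-free clades of the gene tree
#' under the LCA reconciliation: starting from the root, any clade whose
#' subtree contains no duplication node (and whose subtending support, if
#' recorded, is at least `min_support`) becomes one subgroup; otherwise its
#' children are visited. Every gene ends up in exactly one subgroup.
#'
#' @param gene_tree rooted `phylo`, optionally with numeric `node.label`
#'   supports.
#' @param reconciliation output of [lca_reconcile()] for this tree.
#' @param min_support support needed to accept a multi-gene clade
#'   (default 0; ignored when no supports are present).
#' @return list of subgroups: `members` (gene ids), `node` (defining clade
#'   root).
#' @export
extract_subgroups <- function(gene_tree, reconciliation, min_support = 0) {
  gt <- gene_tree
  ntg <- ape::Ntip(gt)
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  has_dup <- logical(ntg + gt$Nnode)
  post <- rev(ape::reorder.phylo(gt, "cladewise")$edge[, 2])
  for (v in c(post, ntg + 1L)) {
    if (v <= ntg) next
    ks <- kids[[as.character(v)]]
    has_dup[v] <- reconciliation$events[v] == "duplication" ||
      any(has_dup[ks])
  }
  supp_ok <- function(v) {
    if (v <= ntg || is.null(gt$node.label)) return(TRUE)
    s <- suppressWarnings(as.numeric(gt$node.label[v - ntg]))
    is.na(s) || s >= min_support
  }
  out <- list()
  visit <- function(v) {
    if (!has_dup[v] && supp_ok(v)) {
      tips <- if (v <= ntg) gt$tip.label[v]
              else ape::extract.clade(gt, v)$tip.label
      out[[length(out) + 1L]] <<- list(members = tips, node = v)
      return(invisible(NULL))
    }
    if (v <= ntg) {
      out[[length(out) + 1L]] <<- list(members = gt$tip.label[v], node = v)
      return(invisible(NULL))
    }
    for (k in kids[[as.character(v)]]) visit(k)
    invisible(NULL)
  }
  visit(ntg + 1L)
  out
}

#' Dollo parsimony: single origin, minimal losses
#'
#' Under Dollo parsimony a character (here: carrying the gene) is gained
#' once, on the stem of the MRCA of the carrier species, and lost on the
#' minimal set of branches: the stems of the maximal carrier-free subtrees
#' inside the carrier clade.
#'
#' @param species_tree rooted `phylo`.
#' @param carriers character vector of carrier species (non-empty).
#' @return list: `origin` (node whose stem carries the gain),
#'   `loss_branches` (nodes whose stems carry losses), `loss_species`
#'   (tip labels under each lost branch).
#' @export
dollo_losses <- function(species_tree, carriers) {
  st <- species_tree
  if (!length(carriers)) stop("empty carrier set")
  miss <- setdiff(carriers, st$tip.label)
  if (length(miss)) stop("carriers not in tree: ",
                         paste(miss, collapse = ", "))
  nts <- ape::Ntip(st)
  origin <- if (length(carriers) == 1L) match(carriers, st$tip.label)
            else ape::getMRCA(st, carriers)
  kids <- split(st$edge[, 2], st$edge[, 1])
  tips_below <- function(v) {
    if (v <= nts) st$tip.label[v]
    else ape::extract.clade(st, v)$tip.label
  }
  losses <- integer(0)
  visit <- function(v) {
    tb <- tips_below(v)
    if (!any(tb %in% carriers)) {
      losses <<- c(losses, v)
      return(invisible(NULL))
    }
    if (v > nts) for (k in kids[[as.character(v)]]) visit(k)
    invisible(NULL)
  }
  if (origin > nts) for (k in kids[[as.character(origin)]]) visit(k)
  list(origin = origin, loss_branches = losses,
       loss_species = lapply(losses, tips_below))
}

#' Bracket the fusion origin in absolute time
#'
#' Given the dated species tree and the set of species carrying the fusion
#' gene, the origin is bracketed between the crown age of the carriers'
#' MRCA (lower bound: the fusion must predate their radiation) and the age
#' at which the nearest sampled non-carrier lineage diverged from the
#' carrier stem (upper bound: the parent node of the MRCA). The bracket is
#' refused when the carrier-derived gene subgroup is not monophyletic,
#' since multiple origins could then not be excluded.
#'
#' @param chron a chronogram containing all carriers.
#' @param carriers character vector of carrier species.
#' @param monophyly result of [is_monophyletic()] on the carrier-derived
#'   gene subgroup (or NULL to skip the gate).
#' @return list: `lower_my`, `upper_my`, `carriers`, `support`, or (when
#'   refused) `refused = TRUE` with `reason`.
#' @export
bracket_fusion <- function(chron, carriers, monophyly = NULL) {
  miss <- setdiff(carriers, chron$tip.label)
  if (length(miss)) stop("carriers not in chronogram: ",
                         paste(miss, collapse = ", "))
  if (!is.null(monophyly) && !isTRUE(monophyly$monophyletic))
    return(list(refused = TRUE, reason = "possible multiple origins"))
  ages <- node_ages(chron)
  nts <- ape::Ntip(chron)
  node <- if (length(carriers) == 1L) match(carriers, chron$tip.label)
          else ape::getMRCA(chron, carriers)
  lower <- if (node <= nts) 0 else ages[node]
  parent <- if (node == nts + 1L) NA_integer_
            else chron$edge[match(node, chron$edge[, 2]), 1]
  upper <- if (is.na(parent)) ages[node] else ages[parent]
  list(lower_my = lower, upper_my = upper, carriers = sort(carriers),
       support = if (!is.null(monophyly)) monophyly$support else NA_real_)
}

#' Assemble a chronologically ordered event history
#'
#' Merges the inference products (Dollo origin and losses, fusion bracket,
#' duplication evidence from the reconciliations, layout/synteny evidence)
#' into one ordered table with one row per inferred event and a
#' machine-readable evidence column. Contradictions (e.g. a Dollo origin
#' strictly above the gene-subgroup MRCA bracket) are recorded as
#' `conflict` rows, never silently resolved.
#'
#' @param events list of event records, each a list with `kind`, `branch`
#'   (species node id or label), `age_my` (number) or `bracket_my`
#'   (length-2 numeric c(lower, upper)), and `evidence` (character).
#' @return data.frame ordered from oldest to youngest (by upper age).
#' @export
assemble_event_history <- function(events) {
  if (!length(events))
    return(data.frame(kind = character(), branch = character(),
                      lower_my = numeric(), upper_my = numeric(),
                      evidence = character()))
  rows <- lapply(events, function(e) {
    br <- if (!is.null(e$bracket_my)) e$bracket_my
          else c(e$age_my, e$age_my)
    data.frame(kind = e$kind, branch = as.character(e$branch),
               lower_my = br[1], upper_my = br[2],
               evidence = e$evidence %||% "", stringsAsFactors = FALSE)
  })
  hist <- do.call(rbind, rows)
  hist <- hist[order(-hist$upper_my, -hist$lower_my), ]
  rownames(hist) <- NULL
  # flag impossible orderings among dependent kinds
  conflicts <- character(0)
  fus <- hist[hist$kind == "fusion", ]
  pai <- hist[hist$kind == "pairing", ]
  if (nrow(fus) && nrow(pai) &&
      isTRUE(pai$upper_my[1] < fus$lower_my[1]))
    conflicts <- c(conflicts,
                   "pairing bracket lies entirely below the fusion bracket")
  attr(hist, "conflicts") <- conflicts
  hist
}
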