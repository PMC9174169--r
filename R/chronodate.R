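#' Calibration point for divergence dating
#'
#' A node (the MRCA of `leaves`) with a prior mean age and standard
#' deviation in MY. In [ls_date()] the calibration enters the objective as
#' the quadratic penalty `((age - mean)/sd)^2`; `sd = 0` is treated as a
#' hard equality constraint.
#'
#' @param leaves character vector of tip labels (>= 2) whose MRCA is
#'   calibrated.
#' @param age mean age, MY.
#' @param sd standard deviation, MY (>= 0).
#' @return a `calibration` list.
#' @export
calibration <- function(leaves, age, sd = 0) {
  stopifnot(length(leaves) >= 2, age > 0, sd >= 0)
  structure(list(leaves = leaves, age = age, sd = sd), class = "calibration")
}

#' Strict-clock least-squares divergence dating
#'
#' Converts a rooted tree with substitution branch lengths into a
#' chronogram by minimizing
#' `sum_branches (length - rate * (t_parent - t_child))^2 +
#'  sum_calibrations ((t_node - mean)/sd)^2`
#' over node ages `t` (leaves fixed at 0) and a single rate, subject to
#' parent age > child age >= 0. Calibrations with `sd = 0` fix their node's
#' age exactly. Because the position of the root along the (arbitrarily
#' split) outgroup edge is not identifiable, the two root-child branches
#' contribute one pooled residual.
#'
#' The problem is biconvex and is solved by alternating closed-form
#' updates: linear least squares for the ages given the rate, then the
#' closed-form rate given the ages, initialized deterministically from
#' mean-path-length ages scaled to the calibrations. Ordering violations
#' (possible with very noisy input) are repaired to an epsilon separation
#' of 1e-6 MY and reported.
#'
#' @param tree rooted binary `phylo` with nonnegative branch lengths
#'   (subs/site).
#' @param calibrations list of [calibration()] objects (>= 1).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list: `chronogram`, `rate` (subs/site/MY), `ages` (per node),
#'   `objective`, `iterations`.
#' @export
ls_date <- function(tree, calibrations, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(tree, "phylo"), length(calibrations) >= 1)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  nodes <- seq_len(ntip + nnode)

  cal_node <- vapply(calibrations, function(cl) {
    miss <- setdiff(cl$leaves, tree$tip.label)
    if (length(miss)) stop("calibration leaves not in tree: ",
                           paste(miss, collapse = ", "))
    ape::getMRCA(tree, cl$leaves)
  }, integer(1))
  cal_age <- vapply(calibrations, `[[`, numeric(1), "age")
  cal_sd <- vapply(calibrations, `[[`, numeric(1), "sd")

  # hard calibrations fix the age; check feasibility among them
  hard <- cal_sd == 0
  fixed_age <- rep(NA_real_, length(nodes))
  fixed_age[seq_len(ntip)] <- 0
  fixed_age[cal_node[hard]] <- cal_age[hard]
  anc_list <- lapply(nodes, function(v) {
    out <- integer(0)
    while (v != root) {
      v <- tree$edge[match(v, tree$edge[, 2]), 1]
      out <- c(out, v)
    }
    out
  })
  for (i in which(hard)) for (j in which(hard)) {
    if (cal_node[j] %in% anc_list[[cal_node[i]]] &&
        cal_age[j] <= cal_age[i])
      stop("infeasible calibrations: ancestor node ", cal_node[j],
           " (", cal_age[j], " MY) not older than descendant node ",
           cal_node[i], " (", cal_age[i], " MY)")
  }

  free <- which(is.na(fixed_age))            # internal, non-hard nodes
  idx <- match(nodes, free)                  # node -> column

  # mean path length init
  mpl <- numeric(length(nodes))
  po <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  elen_of <- split(tree$edge.length, tree$edge[, 1])
  for (v in c(po, root)) {
    if (v <= ntip) next
    ks <- kids_of[[as.character(v)]]
    ls <- elen_of[[as.character(v)]]
    mpl[v] <- mean(mpl[ks] + ls)
  }
  w <- ifelse(cal_sd > 0, 1 / cal_sd^2, 1e6)
  a <- mpl[cal_node]
  scale <- if (sum(w * a^2) > 0) sum(w * cal_age * a) / sum(w * a^2) else 1
  if (!is.finite(scale) || scale <= 0) scale <- 1
  ages <- mpl * scale
  ages[!is.na(fixed_age)] <- fixed_age[!is.na(fixed_age)]
  rate <- 1 / scale

  # residual builders -------------------------------------------------
  edges <- tree$edge
  elen <- tree$edge.length
  root_rows <- which(edges[, 1] == root)
  nonroot <- setdiff(seq_len(nrow(edges)), root_rows)
  soft <- which(!hard)

  objective <- function(ages, rate) {
    r1 <- elen[nonroot] -
      rate * (ages[edges[nonroot, 1]] - ages[edges[nonroot, 2]])
    rc <- edges[root_rows, 2]
    r2 <- sum(elen[root_rows]) -
      rate * (2 * ages[root] - sum(ages[rc]))
    r3 <- if (length(soft))
      (ages[cal_node[soft]] - cal_age[soft]) / cal_sd[soft] else numeric(0)
    sum(r1^2) + r2^2 + sum(r3^2)
  }

  solve_ages <- function(rate) {
    nfree <- length(free)
    rows <- length(nonroot) + 1L + length(soft)
    A <- matrix(0, rows, nfree)
    y <- numeric(rows)
    ri <- 0L
    add <- function(coef_nodes, coefs, const) {
      ri <<- ri + 1L
      rhs <- const
      for (k in seq_along(coef_nodes)) {
        v <- coef_nodes[k]
        if (is.na(idx[v])) rhs <- rhs - coefs[k] * fixed_age[v]
        else A[ri, idx[v]] <<- A[ri, idx[v]] + coefs[k]
      }
      y[ri] <<- rhs
    }
    for (e in nonroot)
      add(c(edges[e, 1], edges[e, 2]), c(rate, -rate), elen[e])
    rc <- edges[root_rows, 2]
    add(c(root, rc[1], rc[2]), c(2 * rate, -rate, -rate),
        sum(elen[root_rows]))
    for (ci in soft)
      add(cal_node[ci], 1 / cal_sd[ci], cal_age[ci] / cal_sd[ci])
    sol <- qr.solve(A, y)
    out <- ages
    out[free] <- sol
    out
  }

  solve_rate <- function(ages) {
    d1 <- ages[edges[nonroot, 1]] - ages[edges[nonroot, 2]]
    rc <- edges[root_rows, 2]
    d2 <- 2 * ages[root] - sum(ages[rc])
    num <- sum(elen[nonroot] * d1) + sum(elen[root_rows]) * d2
    den <- sum(d1^2) + d2^2
    if (den <= 0) stop("degenerate tree: zero total age span")
    num / den
  }

  obj <- objective(ages, rate)
  it <- 0L
  repeat {
    it <- it + 1L
    ages <- solve_ages(rate)
    rate <- solve_rate(ages)
    new_obj <- objective(ages, rate)
    if (abs(obj - new_obj) <= tol * max(1, obj) || it >= max_iter) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }

  # enforce parent strictly older than child (>= 0), eps separation
  eps <- 1e-6
  ages <- pmax(ages, 0)
  ages[seq_len(ntip)] <- 0
  repaired <- 0L
  for (v in c(po, root)) {           # children before parents
    if (v <= ntip) next
    ks <- kids_of[[as.character(v)]]
    lo <- max(ages[ks]) + eps
    if (ages[v] < lo) {
      ages[v] <- lo
      repaired <- repaired + 1L
    }
  }
  if (repaired > 0)
    message("ls_date: repaired ", repaired,
            " parent/child age ordering violation(s) with eps separation")

  chron <- tree
  chron$edge.length <- ages[edges[, 1]] - ages[edges[, 2]]
  chron$node.label <- NULL
  chron <- as_chronogram(chron, tol = 1e-3)
  list(chronogram = chron, rate = rate, ages = ages, objective = obj,
       iterations = it)
}

#' Strict-clock least-squares dating from a distance matrix
#'
#' Fits node ages and a single clock rate directly to the pairwise
#' distances: every tip pair (i, j) contributes the residual
#' `d_ij - 2 * rate * t_lca(i,j)`, weighted by the inverse of the
#' (delta-method) variance of its Jukes-Cantor distance estimate, plus the
#' same quadratic calibration penalties as [ls_date()]. Compared to dating
#' a tree's estimated branch lengths this uses the full matrix and
#' naturally down-weights long, near-saturated distances, which makes the
#' shallow node ages considerably less noisy; see the methods vignette.
#'
#' The fit alternates closed-form updates (each node age appears in an
#' independent set of residuals given the rate) and is deterministic.
#'
#' @param tree rooted binary `phylo` giving the topology (branch lengths
#'   ignored).
#' @param d distance matrix over the tips (subs/site, e.g. from
#'   [jc69_distance_matrix()]).
#' @param n_sites alignment length behind `d`, used for the variance
#'   weights.
#' @param calibrations list of [calibration()] objects (>= 1).
#' @param tol,max_iter convergence controls.
#' @return list: `chronogram`, `rate` (subs/site/MY), `ages`, `objective`,
#'   `iterations`.
#' @export
ls_date_distances <- function(tree, d, n_sites, calibrations, tol = 1e-10,
                              max_iter = 500L) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree), n_sites > 0,
            length(calibrations) >= 1)
  ntip <- ape::Ntip(tree)
  tips <- tree$tip.label
  d <- as.matrix(d)[tips, tips]
  prs <- t(combn(ntip, 2))
  mrca_all <- ape::mrca(tree)
  lca <- mrca_all[prs]
  dv <- d[prs]
  p <- 0.75 * (1 - exp(-4 * dv / 3))
  w <- (1 - 4 * p / 3)^2 * n_sites / pmax(p * (1 - p), 1e-12)

  cal_node <- vapply(calibrations, function(cl) {
    miss <- setdiff(cl$leaves, tips)
    if (length(miss)) stop("calibration leaves not in tree: ",
                           paste(miss, collapse = ", "))
    ape::getMRCA(tree, cl$leaves)
  }, integer(1))
  cal_age <- vapply(calibrations, `[[`, numeric(1), "age")
  cal_sd <- vapply(calibrations, `[[`, numeric(1), "sd")

  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  ages <- numeric(ntip + tree$Nnode)
  for (v in nodes) ages[v] <- mean(dv[lca == v]) / 2   # subs/site heights
  rate <- sum(ages[cal_node] * cal_age / pmax(cal_sd, 1)^2) /
    sum(cal_age^2 / pmax(cal_sd, 1)^2)
  if (!is.finite(rate) || rate <= 0) rate <- max(ages) / max(cal_age)
  ages <- ages / rate

  objective <- function(ages, rate) {
    o <- sum(w * (dv - 2 * rate * ages[lca])^2)
    s <- cal_sd > 0
    o + sum(((ages[cal_node[s]] - cal_age[s]) / cal_sd[s])^2)
  }
  obj <- objective(ages, rate)
  it <- 0L
  repeat {
    it <- it + 1L
    for (v in nodes) {
      sel <- lca == v
      num <- sum(w[sel] * 2 * rate * dv[sel])
      den <- sum(w[sel] * 4 * rate^2)
      k <- match(v, cal_node)
      if (!is.na(k)) {
        if (cal_sd[k] == 0) { ages[v] <- cal_age[k]; next }
        num <- num + 2 * cal_age[k] / cal_sd[k]^2
        den <- den + 2 / cal_sd[k]^2
      }
      ages[v] <- num / den
    }
    rate <- sum(w * 2 * ages[lca] * dv) / sum(w * 4 * ages[lca]^2)
    new_obj <- objective(ages, rate)
    if (abs(obj - new_obj) <= tol * max(1, obj) || it >= max_iter) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }

  # enforce parent strictly older than child
  eps <- 1e-6
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  po <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  repaired <- 0L
  for (v in c(po, ntip + 1L)) {
    if (v <= ntip) next
    lo <- max(ages[kids_of[[as.character(v)]]]) + eps
    if (ages[v] < lo) { ages[v] <- lo; repaired <- repaired + 1L }
  }
  if (repaired > 0)
    message("ls_date_distances: repaired ", repaired,
            " ordering violation(s) with eps separation")
  chron <- tree
  chron$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  chron$node.label <- NULL
  chron <- as_chronogram(chron, tol = 1e-3)
  list(chronogram = chron, rate = rate, ages = ages, objective = obj,
       iterations = it)
}

## ---- Ks (Nei-Gojobori) ---------------------------------------------------

ng_codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  list(code = code, stops = stops)
}

# fraction of synonymous sites in a codon (changes to stop codons are
# non-synonymous; denominator 3 per position)
ng_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  s <- 0
  cs <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), cs[pos])) {
    alt <- cs
    alt[pos] <- nt
    aa2 <- code[[paste0(alt, collapse = "")]]
    if (identical(aa2, aa) && aa2 != "*") s <- s + 1
  }
  s / 3
}

# pathway-averaged synonymous difference count between two codons
ng_syn_diffs <- function(c1, c2, code) {
  x <- strsplit(c1, "")[[1]]
  y <- strsplit(c2, "")[[1]]
  pos <- which(x != y)
  k <- length(pos)
  if (k == 0) return(0)
  perms <- if (k == 1) list(pos) else {
    pp <- list()
    for (ord in asplit(permutations_k(k), 1)) pp <- c(pp, list(pos[ord]))
    pp
  }
  step_syn <- function(path) {
    cur <- x
    syn <- 0
    for (p in path) {
      nxt <- cur
      nxt[p] <- y[p]
      aa1 <- code[[paste0(cur, collapse = "")]]
      aa2 <- code[[paste0(nxt, collapse = "")]]
      if (aa2 == "*") return(NULL)          # pathway through a stop codon
      if (identical(aa1, aa2)) syn <- syn + 1
      cur <- nxt
    }
    syn
  }
  vals <- lapply(perms, step_syn)
  ok <- !vapply(vals, is.null, logical(1))
  if (!any(ok)) {                           # all pathways blocked: use all
    vals <- lapply(perms, function(path) {
      cur <- x; syn <- 0
      for (p in path) {
        nxt <- cur; nxt[p] <- y[p]
        if (identical(code[[paste0(cur, collapse = "")]],
                      code[[paste0(nxt, collapse = "")]])) syn <- syn + 1
        cur <- nxt
      }
      syn
    })
    ok <- rep(TRUE, length(vals))
  }
  mean(unlist(vals[ok]))
}

permutations_k <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations_k(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Synonymous divergence (Ks) by Nei-Gojobori counting
#'
#' Counts synonymous sites per codon (fraction of the 3 possible changes
#' per position that preserve the amino acid without creating a stop),
#' averages them over both sequences, counts pathway-averaged synonymous
#' differences per codon pair, and applies the Jukes-Cantor multiple-hit
#' correction `Ks = -(3/4) log(1 - (4/3) Sd/S)`.
#'
#' @param a,b coding nucleotide strings, equal length divisible by 3, no
#'   internal stop codons.
#' @param on_saturation `"error"` (default) stops when `Sd/S >= 0.75`;
#'   `"na"` returns a saturated estimate with `ks = NA`.
#' @return a `ks_estimate` list: `ks`, `S` (synonymous sites), `Sd`
#'   (synonymous differences), `ps` (= Sd/S), `saturated`.
#' @export
ks_nei_gojobori <- function(a, b, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  if (nchar(a) %% 3 != 0) stop("length not divisible by 3")
  tb <- ng_codon_table()
  code <- tb$code
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  ncod <- length(ca)
  for (i in seq_len(ncod)) {
    if (i < ncod && ca[i] %in% tb$stops)
      stop("internal stop codon in first sequence at codon ", i)
    if (i < ncod && cb[i] %in% tb$stops)
      stop("internal stop codon in second sequence at codon ", i)
  }
  use <- !(ca %in% tb$stops) & !(cb %in% tb$stops)  # drop terminal stops
  ca <- ca[use]; cb <- cb[use]
  Sa <- sum(vapply(ca, ng_syn_sites, numeric(1), code = code))
  Sb <- sum(vapply(cb, ng_syn_sites, numeric(1), code = code))
  S <- (Sa + Sb) / 2
  Sd <- sum(mapply(ng_syn_diffs, ca, cb, MoreArgs = list(code = code)))
  ps <- Sd / S
  saturated <- ps >= 0.75
  ks <- if (saturated) NA_real_ else -0.75 * log(1 - 4 * ps / 3)
  if (saturated && on_saturation == "error")
    stop("saturated synonymous divergence: Sd/S = ", format(ps), " >= 0.75")
  structure(list(ks = ks, S = S, Sd = Sd, ps = ps, saturated = saturated),
            class = "ks_estimate")
}

#' Date a duplication from a Ks estimate
#'
#' `T = Ks / (2 r)`, reported in MY. A saturated (undated) Ks propagates as
#' `NA` with the reason attached.
#'
#' @param ks a `ks_estimate` (or a bare Ks value).
#' @param rate substitutions/site/year (> 0).
#' @return age in MY, or NA with attribute `reason` when undated.
#' @export
date_duplication <- function(ks, rate) {
  stopifnot(rate > 0)
  k <- if (inherits(ks, "ks_estimate")) ks$ks else as.numeric(ks)
  if (is.na(k)) {
    out <- NA_real_
    attr(out, "reason") <- "saturated Ks estimate"
    return(out)
  }
  k / (2 * rate) / 1e6
}
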