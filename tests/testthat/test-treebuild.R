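test_that("nj_tree solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # pendant lengths: a = (dAB + dAC - dBC)/2, etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens["A"]), (3 + 5 - 6) / 2)
  expect_equal(unname(lens["B"]), (3 + 6 - 5) / 2)
  expect_equal(unname(lens["C"]), (5 + 6 - 3) / 2)
})

test_that("nj reproduces an additive 4-taxon tree exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) => AB=3 AC=5 AD=6 BC=6 BD=7 CD=7
  taxa <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(truth))), 0)
  # all pairwise path lengths reproduced
  dd <- ape::cophenetic.phylo(tr)[taxa, taxa]
  expect_equal(dd, d, tolerance = 1e-12)
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), "3 taxa|non-finite")
})

test_that("nj recovers the generating topology from simulated sequences", {
  # fixed 8-tip chronogram, depth 20 MY, internal branches >= 2.5 MY
  truth <- simulate_chronogram(topology = paste0(
    "(((A:5,B:5):5,(C:5,D:5):5):10,((E:7.5,F:7.5):7.5,",
    "(G:10,H:10):5):5);"))
  set.seed(100)
  ok <- 0L
  n_rep <- 20L
  for (k in seq_len(n_rep)) {
    aln <- simulate_alignment(truth, clock_model(rate = 1.396e-8,
                                                 length = 2000))
    tr <- nj_tree(jc69_distance_matrix(aln))
    if (as.numeric(ape::dist.topo(ape::unroot(tr),
                                  ape::unroot(truth))) == 0)
      ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("bootstrap supports behave at the edges and match a recount", {
  set.seed(8)
  base <- simulate_chronogram(tips = 6, birth = 0.5, seed = 12)
  base$edge.length <- base$edge.length / root_age(base) * 15
  aln <- simulate_alignment(base, clock_model(length = 400))
  one <- bootstrap_support(aln, n = 1, seed = 1)
  expect_true(all(one$node.label %in% c(0, 1)))
  # a repeated identical column set gives full support everywhere
  pat <- c(a = "AAAAT", b = "AAAAT", c = "AAATA", d = "AAATA")
  rep_aln <- vapply(pat, function(s) paste(rep(s, 50), collapse = ""),
                    character(1))
  allsup <- bootstrap_support(rep_aln, n = 20, seed = 2)
  internal <- allsup$node.label[-1]   # root split is trivial
  expect_true(all(internal == 1))
  # supports equal a split recount over the stored replicate trees
  bs <- bootstrap_support(aln, n = 30, seed = 3, keep_trees = TRUE)
  reps <- attr(bs, "replicates")
  counts <- ape::prop.clades(bs, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  expect_equal(unname(bs$node.label), unname(counts / 30))
})

test_that("bootstrap supports are invariant to record order", {
  set.seed(9)
  base <- simulate_chronogram(tips = 5, birth = 0.5, seed = 5)
  base$edge.length <- base$edge.length / root_age(base) * 10
  aln <- simulate_alignment(base, clock_model(length = 600))
  b1 <- bootstrap_support(aln, n = 25, seed = 4)
  b2 <- bootstrap_support(rev(aln), n = 25, seed = 4)
  sup <- function(b) {
    s <- setNames(b$node.label,
                  vapply((ape::Ntip(b) + 1):(ape::Ntip(b) + b$Nnode),
                         function(v) paste(sort(
                           ape::extract.clade(b, v)$tip.label),
                           collapse = ","), character(1)))
    s[order(names(s))]
  }
  # same splits receive the same support regardless of input order
  common <- intersect(names(sup(b1)), names(sup(b2)))
  expect_gt(length(common), 0)
  expect_equal(sup(b1)[common], sup(b2)[common])
})

test_that("root_tree places and validates the outgroup", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:2);")
  r <- root_tree(tr, "C")
  expect_true(ape::is.rooted(r))
  expect_true(ape::is.monophyletic(r, c("A", "B")))
  # rooting then unrooting preserves the splits
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(as.numeric(ape::dist.topo(
    ape::unroot(root_tree(ape::unroot(tr2), "D")), ape::unroot(tr2))), 0)
  expect_error(root_tree(ape::unroot(tr2), c("A", "C")), "not separable")
  expect_error(root_tree(tr2, "Z"), "not in tree")
})

test_that("monophyly testing honours clades and supports", {
  tr <- ape::read.tree(text = "((A:1,B:1)0.95:1,(C:1,D:1)0.4:1);")
  tr$node.label <- c("", "0.95", "0.4")
  expect_true(is_monophyletic(tr, "A")$monophyletic)
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D"))$monophyletic)
  expect_true(is_monophyletic(tr, c("A", "B"), min_support = 0.7)
              $monophyletic)
  expect_false(is_monophyletic(tr, c("C", "D"), min_support = 0.7)
               $monophyletic)
  expect_false(is_monophyletic(tr, c("A", "C"))$monophyletic)
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
})

test_that("fused-gene leaves are monophyletic on simulated histories", {
  ch <- papaver_chronogram()
  b <- simulate_gene_family(ch, seed = 6,
                            clock = clock_model(rate = 3.4e-9))
  aln <- module_alignment(b, "P450")
  ln <- intersect(b$genes$gene_id[b$genes$subgroup == "Ln"], names(aln))
  gt <- bootstrap_support(aln, n = 50, seed = 1, outgroup = ln)
  storr <- b$genes$gene_id[b$genes$subgroup == "STORR"]
  expect_true(is_monophyletic(gt, intersect(storr, gt$tip.label),
                              min_support = 0.5)$monophyletic)
  mixed <- c(storr[1], setdiff(gt$tip.label, storr)[1])
  expect_false(is_monophyletic(gt, mixed)$monophyletic)
})
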