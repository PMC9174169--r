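sp_tree4 <- ape::read.tree(text = "(((Pso:1,Pbr:1):1,Pat:2):1,Pca:3);")

test_that("congruent gene trees reconcile with no events", {
  gt <- ape::read.tree(text = "(((Pso_g:1,Pbr_g:1):1,Pat_g:2):1,Pca_g:3);")
  rec <- lca_reconcile(gt, sp_tree4)
  expect_equal(rec$n_dup, 0)
  expect_equal(rec$n_loss, 0)
  expect_true(all(rec$events[rec$events != "leaf"] == "speciation"))
})

test_that("hand-enumerated duplication cases give the known counts", {
  st <- ape::read.tree(text = "(A:1,B:1);")
  g1 <- ape::read.tree(text = "((A_1:1,A_2:1):1,B_1:2);")
  r1 <- lca_reconcile(g1, st)
  expect_equal(r1$n_dup, 1)
  expect_equal(r1$n_loss, 0)
  # the duplication maps to the A leaf node
  expect_equal(r1$mapping[ape::getMRCA(g1, c("A_1", "A_2"))],
               match("A", st$tip.label))
  g2 <- ape::read.tree(text = "((A_1:1,B_1:1):1,(A_2:1,B_2:1):1);")
  r2 <- lca_reconcile(g2, st)
  expect_equal(r2$n_dup, 1)
  expect_equal(r2$n_loss, 0)
  expect_equal(r2$events[ape::Ntip(g2) + 1L], "duplication")
  # one lost copy: ((A_1,A_2),B_1) with a missing B copy costs a loss
  g3 <- ape::read.tree(text = "((A_1:1,B_1:1):1,A_2:2);")
  r3 <- lca_reconcile(g3, st)
  expect_equal(r3$n_dup, 1)
  expect_equal(r3$n_loss, 1)
  expect_error(lca_reconcile(
    ape::read.tree(text = "(A_1:1,Z_1:1);"), st), "unknown species")
})

test_that("loss counts match the independent embedding oracle", {
  set.seed(21)
  st <- ape::read.tree(text = "((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  for (k in 1:15) {
    sp <- sample(c("A", "B", "C", "D", "E"), 6, replace = TRUE)
    labs <- paste0(sp, "_", seq_along(sp))
    gt <- ape::rtree(6, tip.label = labs)
    rec <- lca_reconcile(gt, st)
    expect_equal(rec$n_loss, loss_oracle(gt, st), info = paste("case", k))
  }
})

test_that("LCA mapping minimizes duplications over all valid mappings", {
  # exhaustive check on a small instance: every internal gene node may map
  # to any ancestor of its LCA; no alternative yields fewer duplications
  st <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  gt <- ape::read.tree(text = "((A_1:1,B_1:1):1,(A_2:1,C_1:1):1);")
  rec <- lca_reconcile(gt, st)
  anc_sets <- list("4" = c(4), "5" = c(5, 4))  # species node ancestors
  ntg <- ape::Ntip(gt)
  lca_map <- rec$mapping
  combos <- expand.grid(lapply((ntg + 1):(ntg + gt$Nnode), function(v) {
    m <- lca_map[v]
    if (m <= ape::Ntip(st)) m else as.numeric(anc_sets[[as.character(m)]])
  }))
  dups <- apply(combos, 1, function(mm) {
    map <- lca_map
    map[(ntg + 1):(ntg + gt$Nnode)] <- mm
    ok <- all(vapply(seq_len(nrow(gt$edge)), function(e) {
      u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
      # parent must map at or above child
      mv <- map[v]
      repeat {
        if (mv == map[u]) return(TRUE)
        ee <- match(mv, st$edge[, 2])
        if (is.na(ee)) return(FALSE)
        mv <- st$edge[ee, 1]
      }
    }, logical(1)))
    if (!ok) return(NA_integer_)
    sum(vapply((ntg + 1):(ntg + gt$Nnode), function(v) {
      ks <- gt$edge[gt$edge[, 1] == v, 2]
      any(map[ks] == map[v])
    }, logical(1)))
  })
  expect_equal(rec$n_dup, min(dups, na.rm = TRUE))
})

test_that("orthologous subgroups are the maximal duplication-free clades", {
  st <- ape::read.tree(text = "(A:1,B:1);")
  flat <- ape::read.tree(text = "(A_1:1,B_1:1);")
  rec <- lca_reconcile(flat, st)
  sub <- extract_subgroups(flat, rec)
  expect_equal(length(sub), 1)
  expect_setequal(sub[[1]]$members, c("A_1", "B_1"))
  g2 <- ape::read.tree(text = "((A_1:1,B_1:1):1,(A_2:1,B_2:1):1);")
  sub2 <- extract_subgroups(g2, lca_reconcile(g2, st))
  expect_equal(length(sub2), 2)
  members <- lapply(sub2, `[[`, "members")
  expect_true(any(vapply(members, setequal, logical(1),
                         c("A_1", "B_1"))))
  # every gene in exactly one subgroup
  expect_setequal(unlist(members), g2$tip.label)
})

test_that("simulated subgroup labels are recovered from the gene tree", {
  ch <- papaver_chronogram()
  b <- simulate_gene_family(ch, seed = 8,
                            clock = clock_model(rate = 3.4e-9))
  aln <- module_alignment(b, "P450")
  ln <- intersect(b$genes$gene_id[b$genes$subgroup == "Ln"], names(aln))
  gt <- bootstrap_support(aln, n = 30, seed = 2, outgroup = ln)
  rec <- lca_reconcile(gt, ch)
  subs <- extract_subgroups(gt, rec, min_support = 0.5)
  got <- lapply(subs, `[[`, "members")
  truth <- split(b$genes$gene_id[b$genes$gene_id %in% gt$tip.label],
                 b$genes$subgroup[b$genes$gene_id %in% gt$tip.label])
  for (lab in names(truth))
    expect_true(any(vapply(got, setequal, logical(1), truth[[lab]])),
                info = lab)
})

test_that("Dollo reconstruction finds origins and minimal losses", {
  st <- ape::read.tree(text = "(((Pso:1,Pbr:1):1,Pat:2):1,Pca:3);")
  all_sp <- dollo_losses(st, st$tip.label)
  expect_equal(all_sp$origin, ape::Ntip(st) + 1L)
  expect_equal(length(all_sp$loss_branches), 0)
  one <- dollo_losses(st, c("Pso", "Pbr", "Pca"))
  expect_equal(unlist(one$loss_species), "Pat")
  pap <- papaver_chronogram(outgroups = FALSE)
  carriers <- c("Pca", "Par", "Pbr", "Pso", "Pse")
  res <- dollo_losses(pap, carriers)
  expect_setequal(unlist(res$loss_species), c("Pat", "Prh"))
})

test_that("the Dollo loss set is minimal by exhaustive enumeration", {
  pap <- papaver_chronogram(outgroups = FALSE)
  carriers <- c("Pca", "Par", "Pbr", "Pso", "Pse")
  res <- dollo_losses(pap, carriers)
  nts <- ape::Ntip(pap)
  origin <- res$origin
  clade_tips <- ape::extract.clade(pap, origin)$tip.label
  below <- function(v) if (v <= nts) pap$tip.label[v] else
    ape::extract.clade(pap, v)$tip.label
  all_nodes <- seq_len(nts + pap$Nnode)[-origin]
  k <- length(res$loss_branches)
  smaller <- utils::combn(all_nodes, k - 1, simplify = FALSE)
  explains <- vapply(smaller, function(losses) {
    pres <- setdiff(clade_tips, unlist(lapply(losses, below)))
    setequal(pres, carriers)
  }, logical(1))
  expect_false(any(explains))
})

test_that("fusion brackets read the chronogram as specified", {
  ch <- papaver_chronogram()
  single <- bracket_fusion(ch, "Pca")
  expect_equal(single$lower_my, 0)
  expect_equal(single$upper_my, 16.8)
  carriers <- c("Pca", "Par", "Pbr", "Pso", "Pse")
  br <- bracket_fusion(ch, carriers,
                       list(monophyletic = TRUE, support = 1))
  expect_equal(br$lower_my, 16.8)
  expect_equal(br$upper_my, 24.1)
  # refusal without monophyly
  ref <- bracket_fusion(ch, carriers,
                        list(monophyletic = FALSE, support = 0.3))
  expect_true(ref$refused)
  expect_match(ref$reason, "multiple origins")
  # monotonicity: adding a carrier never lowers the upper bound
  br2 <- bracket_fusion(ch, c(carriers, "Prh"))
  expect_gte(br2$upper_my, br$upper_my)
  expect_error(bracket_fusion(ch, c("Pca", "Zz")), "not in chronogram")
})

test_that("noise-free simulated brackets always contain the true time", {
  ch <- papaver_chronogram()
  for (s in 1:3) {
    b <- simulate_gene_family(ch, seed = s,
                              clock = clock_model(rate = 3.4e-9))
    fused <- unique(b$genes$species[b$genes$fused])
    br <- bracket_fusion(ch, fused)
    t_true <- b$events$time_my[b$events$kind == "fusion"]
    expect_lte(br$lower_my, t_true)
    expect_gte(br$upper_my, t_true)
  }
})

test_that("event histories are ordered and flag contradictions", {
  empty <- assemble_event_history(list())
  expect_equal(nrow(empty), 0)
  hist <- assemble_event_history(list(
    list(kind = "loss", branch = "Pat", age_my = 6, evidence = "x"),
    list(kind = "fusion", branch = "stem", bracket_my = c(16.8, 24.1),
         evidence = "y"),
    list(kind = "pairing", branch = "deep", bracket_my = c(24.1, 77),
         evidence = "z"),
    list(kind = "cluster_formation", branch = "cl",
         bracket_my = c(9.7, 16.8), evidence = "w")))
  expect_equal(hist$kind, c("pairing", "fusion", "cluster_formation",
                            "loss"))
  expect_equal(length(attr(hist, "conflicts")), 0)
  # a pairing entirely below the fusion bracket is contradictory
  bad <- assemble_event_history(list(
    list(kind = "fusion", branch = "s", bracket_my = c(16.8, 24.1),
         evidence = "y"),
    list(kind = "pairing", branch = "d", bracket_my = c(2, 5),
         evidence = "z")))
  expect_equal(length(attr(bad, "conflicts")), 1)
})
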