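make_panel <- function(seed = 1, p450_codons = 200, oxre_codons = 120) {
  set.seed(seed)
  module_panel(P450 = rand_coding(p450_codons),
               oxidoreductase = rand_coding(oxre_codons))
}

linker_nt <- function(naa, seed = 2) {
  set.seed(seed)
  substr(rand_coding(naa + 1), 4, (naa + 1) * 3)  # drop the ATG
}

test_that("constructed full fusions are classified with the right linker", {
  pn <- make_panel()
  lk <- linker_nt(11)
  fused <- paste0(pn$P450[[1]], lk, pn$oxidoreductase[[1]])
  call <- scan_sequence(fused, pn, id = "construct")
  expect_equal(call$class, "full_fusion")
  expect_equal(call$linker_aa, 11)
  expect_equal(call$strand, "+")
  hits <- call$hits
  expect_equal(hits$start[hits$role == "P450"], 0)
  expect_equal(hits$end[hits$role == "P450"], 600)
  expect_equal(hits$start[hits$role == "oxidoreductase"], 633)
})

test_that("a linker plus 13 oxidoreductase codons before a stop is a
           truncated fusion", {
  pn <- make_panel()
  lk <- linker_nt(11)
  remnant <- substr(pn$oxidoreductase[[1]], 1, 39)
  seq <- paste0(pn$P450[[1]], lk, remnant, "TAA",
                paste(rep("C", 60), collapse = ""))
  call <- scan_sequence(seq, pn, id = "trunc")
  expect_equal(call$class, "truncated_fusion")
  expect_equal(call$diagnostics$remnant_codons, 13L)
})

test_that("single modules and short sequences fall through cleanly", {
  pn <- make_panel()
  alone <- scan_sequence(pn$P450[[1]], pn)
  expect_equal(alone$class, "single_module")
  short <- scan_sequence("ACGTACGT", pn)
  expect_equal(short$class, "none")
  expect_match(short$diagnostics$reason, "shorter")
})

test_that("scanning the reverse complement flips only the strand", {
  pn <- make_panel()
  fused <- paste0(pn$P450[[1]], linker_nt(10), pn$oxidoreductase[[1]])
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fused)))
  fwd <- scan_sequence(fused, pn)
  rev <- scan_sequence(rc, pn)
  expect_equal(rev$class, fwd$class)
  expect_equal(rev$linker_aa, fwd$linker_aa)
  expect_equal(rev$linker, fwd$linker)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  # intervals come back in forward coordinates of the scanned sequence
  L <- nchar(fused)
  fh <- fwd$hits[fwd$hits$role == "P450", ]
  rh <- rev$hits[rev$hits$role == "P450", ]
  expect_equal(c(rh$start, rh$end), c(L - fh$end, L - fh$start))
})

test_that("out-of-bounds linkers are never classified full_fusion", {
  pn <- make_panel()
  for (naa in c(5L, 20L)) {
    fused <- paste0(pn$P450[[1]], linker_nt(naa), pn$oxidoreductase[[1]])
    call <- scan_sequence(fused, pn)
    expect_false(call$class == "full_fusion")
  }
})

test_that("pseudogene diagnostics catch stops and frameshifts", {
  set.seed(5)
  clean <- rand_coding(80)
  res <- pseudogene_check(clean)
  expect_true(res$clean)
  # single inserted nucleotide mid-ORF
  fs <- paste0(substr(clean, 1, 120), "G", substr(clean, 121, nchar(clean)))
  expect_true(pseudogene_check(fs)$frameshift)
  expect_true(pseudogene_check(fs, reference = clean)$frameshift)
  # premature stop at a known codon
  stopped <- paste0(substr(clean, 1, 90), "TGA",
                    substr(clean, 94, nchar(clean)))
  expect_equal(pseudogene_check(stopped)$premature_stop_codon, 31L)
})

test_that("layout scanning pairs nearby complementary single modules", {
  pn <- make_panel()
  seqs <- c(g1 = pn$P450[[1]], g2 = pn$oxidoreductase[[1]])
  lay <- data.frame(contig = "c1",
                    start = c(0L, nchar(seqs[1]) + 1000L),
                    end = c(nchar(seqs[1]),
                            nchar(seqs[1]) + 1000L + nchar(seqs[2])),
                    strand = "+", gene_id = c("g1", "g2"),
                    stringsAsFactors = FALSE)
  calls <- scan_layout(lay, seqs, pn)
  pair <- calls[["pair:g1:g2"]]
  expect_equal(pair$class, "unfused_pair")
  expect_equal(pair$distance_bp, 1000)
  expect_equal(pair$order, "P450-first")
  # 10 kb apart with D = 5 kb: two singles, no pair
  lay2 <- lay
  lay2$start[2] <- lay$end[1] + 10000L
  lay2$end[2] <- lay2$start[2] + nchar(seqs[2])
  calls2 <- scan_layout(lay2, seqs, pn)
  expect_null(calls2[["pair:g1:g2"]])
  expect_equal(calls2[["g1"]]$class, "single_module")
  # both genes on the minus strand: order flag recomputed consistently
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  seqs3 <- c(g1 = rc(pn$oxidoreductase[[1]]), g2 = rc(pn$P450[[1]]))
  lay3 <- lay
  lay3$strand <- "-"
  calls3 <- scan_layout(lay3, seqs3, pn)
  expect_equal(calls3[["pair:g1:g2"]]$order, "P450-first")
})

test_that("fusion-call classes reproduce simulator truth exactly", {
  ch <- papaver_chronogram()
  plan <- c(study_event_plan(linker_aa = 11),
            list(gf_event("pseudogenization", "Pat", 3, label = "La",
                          target = "La")))
  b <- simulate_gene_family(ch, events = plan,
                            clock = clock_model(rate = 3.4e-9), seed = 9)
  pn <- module_panel(b$panel$P450, b$panel$oxidoreductase)
  calls <- scan_layout(b$layouts, b$sequences, pn)
  cl <- vapply(calls, `[[`, character(1), "class")
  truth_fused <- b$genes$gene_id[b$genes$fused]
  expect_setequal(names(cl)[cl == "full_fusion"], truth_fused)
  # every co-located unfused pair is recovered as an unfused_pair call
  # (pseudogene status does not remove a module from the layout)
  by_sp <- split(b$genes, b$genes$species)
  expected_pairs <- sum(vapply(by_sp, function(g)
    sum(!g$fused) %/% 2L, integer(1)))
  expect_equal(sum(cl == "unfused_pair"), expected_pairs)
  # pseudogenized gene diagnosed; truth labels matched
  ps <- b$genes[b$genes$pseudo, ]
  expect_equal(nrow(ps), 1)
  diag <- pseudogene_check(b$sequences[[ps$gene_id]],
                           reference = if (ps$role == "P450")
                             b$panel$P450 else b$panel$oxidoreductase)
  expect_true(diag$frameshift || !is.na(diag$premature_stop_codon))
})
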