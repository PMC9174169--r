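NT <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strict molecular clock model
#'
#' Jukes-Cantor (JC69) clock used by the simulator and by Ks dating. The
#' default rate, 1.396e-8 substitutions/site/year, is the published
#' LTR-insertion dating rate for these genomes; it is a documented default,
#' not a biological claim about these loci.
#'
#' @param rate substitutions per site per year (> 0).
#' @param model substitution model id; only `"JC69"` is supported.
#' @param length sequence length in nucleotides.
#' @return a `clock_model` list.
#' @export
clock_model <- function(rate = 1.396e-8, model = "JC69", length = 2000L) {
  stopifnot(rate > 0, identical(model, "JC69"), length >= 1)
  structure(list(rate = rate, model = model, length = as.integer(length)),
            class = "clock_model")
}

#' Simulate a chronogram
#'
#' Two modes. Explicit: `topology` is a Newick string (or phylo) whose
#' branch lengths are durations in MY; it is validated (ultrametric, rooted)
#' and returned, so the requested node ages are reproduced exactly.
#' Birth-death: draw a random ultrametric tree with `tips` extant species
#' under a constant-rate birth-death process.
#'
#' @param topology Newick string or `phylo` with branch lengths in MY
#'   (explicit mode).
#' @param tips,birth,death number of extant tips and per-lineage rates
#'   (birth-death mode; `birth > death >= 0`).
#' @param seed RNG seed (mandatory in birth-death mode).
#' @return a chronogram.
#' @export
simulate_chronogram <- function(topology = NULL, tips = NULL, birth = 0.2,
                                death = 0, seed = NULL) {
  if (!is.null(topology)) {
    phy <- if (inherits(topology, "phylo")) topology
           else ape::read.tree(text = topology)
    return(as_chronogram(phy))
  }
  stopifnot(!is.null(tips), tips >= 2, birth > 0, birth > death, death >= 0)
  if (is.null(seed)) stop("birth-death mode requires a seed")
  set.seed(seed)
  phy <- ape::rphylo(tips, birth = birth, death = death)
  as_chronogram(phy)
}

# Random nucleotide sequence as a character vector of "A","C","G","T".
random_sequence <- function(length) sample(NT, length, replace = TRUE)

# Random coding sequence: ATG followed by sense codons (no stops), as a
# split character vector.
random_coding_sequence <- function(ncodons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(NT, NT, NT), 1, paste0, collapse = "")
  sense <- setdiff(codons, stops)
  cds <- c("ATG", sample(sense, ncodons - 1L, replace = TRUE))
  unlist(strsplit(cds, ""), use.names = FALSE)
}

#' Evolve a sequence under the JC69 clock
#'
#' Each site changes to a specific other base with probability
#' `(1 - exp(-4 d / 3)) / 4` where `d = rate * years` is the expected
#' number of substitutions per site. No indels.
#'
#' @param seq character vector of bases (split sequence).
#' @param years elapsed time in years.
#' @param rate substitutions/site/year.
#' @return the evolved sequence (same length).
#' @export
evolve_jc69 <- function(seq, years, rate) {
  d <- rate * years
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- runif(length(seq)) < p_change
  if (any(hit)) {
    idx <- which(hit)
    offs <- sample.int(3L, length(idx), replace = TRUE)
    pos <- match(seq[idx], NT)
    seq[idx] <- NT[((pos - 1L + offs) %% 4L) + 1L]
  }
  seq
}

#' Simulate a clock-like alignment on a chronogram
#'
#' Evolves a random ancestral sequence down every branch of the chronogram
#' under JC69; because there are no indels the tip sequences are
#' positionally aligned.
#'
#' @param chron a chronogram (branch lengths MY).
#' @param clock a [clock_model()].
#' @param seed RNG seed.
#' @return named character vector of tip sequences (an alignment).
#' @export
simulate_alignment <- function(chron, clock = clock_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(chron)
  root <- ntip + 1L
  ord <- ape::reorder.phylo(chron, "cladewise")
  seqs <- vector("list", ntip + chron$Nnode)
  seqs[[root]] <- random_sequence(clock$length)
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    seqs[[ch]] <- evolve_jc69(seqs[[p]], ord$edge.length[i] * 1e6, clock$rate)
  }
  out <- vapply(seq_len(ntip), function(i) paste0(seqs[[i]], collapse = ""),
                character(1))
  names(out) <- chron$tip.label
  out
}

## ---- gene family simulation --------------------------------------------

# Species-tree branch named by the node at its child end: a tip label, or
# the leaf set whose MRCA it is.
resolve_branch_node <- function(chron, branch) {
  if (length(branch) == 1L && branch %in% chron$tip.label)
    return(match(branch, chron$tip.label))
  miss <- setdiff(branch, chron$tip.label)
  if (length(miss)) stop("unknown species in branch spec: ",
                         paste(miss, collapse = ", "))
  ape::getMRCA(chron, branch)
}

#' Define a gene-family event
#'
#' Events sit on a species-tree branch (named by the node at its child end)
#' at an absolute age in MY strictly inside that branch's age interval.
#'
#' @param kind one of `"pairing"`, `"segmental_duplication"`, `"fusion"`,
#'   `"loss"`, `"pseudogenization"`, `"rearrangement"`.
#' @param branch tip label or character vector of tip labels (MRCA).
#' @param time_my event age, MY.
#' @param label subgroup label: the pair created (pairing), the new copy
#'   (segmental_duplication), the fused gene (fusion), or the affected
#'   subgroup (loss/pseudogenization/rearrangement).
#' @param target for fusion/pseudogenization: label of the pair/gene acted
#'   on (fusion defaults to the most recently created unfused pair).
#' @param relabel for segmental_duplication: new label for the source pair
#'   from this point on (NULL keeps its label).
#' @param linker_aa fusion linker length in amino acids (NULL draws
#'   uniformly from 9-13 aa).
#' @param pair_bp genomic distance between paired genes (pairing only).
#' @return an event list.
#' @export
gf_event <- function(kind, branch, time_my, label = NULL, target = NULL,
                     relabel = NULL, linker_aa = NULL, pair_bp = 1000L) {
  kinds <- c("pairing", "segmental_duplication", "fusion", "loss",
             "pseudogenization", "rearrangement")
  kind <- match.arg(kind, kinds)
  if (!is.null(linker_aa) && linker_aa < 1) stop("linker length < 1")
  list(kind = kind, branch = branch, time_my = time_my, label = label,
       target = target, relabel = relabel, linker_aa = linker_aa,
       pair_bp = pair_bp)
}

#' The default gene-family event plan of the study scenario
#'
#' Pairing of a P450-like / oxidoreductase-like gene pair on the Papaver
#' stem (so P. nudicaule inherits the ancestral "Ln" pair about 1 kb
#' apart), a segmental duplication on the Clade 2 stem that creates the
#' pair destined to fuse while the source pair continues as "La", the
#' single fusion event ("STORR") on the same stem, lineage-specific losses
#' of the fusion gene in P. atlanticum and P. rhoeas, and a pair-order
#' rearrangement in P. armeniacum.
#'
#' @param linker_aa fusion linker length (aa); NULL draws from 9-13.
#' @return list of [gf_event()]s.
#' @export
study_event_plan <- function(linker_aa = 11L) {
  clade2 <- c("Pca", "Prh", "Pat", "Par", "Pbr", "Pso", "Pse")
  papaver <- c("Pnu", clade2)
  list(
    gf_event("pairing", papaver, 30, label = "Ln", pair_bp = 1000L),
    gf_event("segmental_duplication", clade2, 20.5, label = "Lpre",
             relabel = "La"),
    gf_event("fusion", clade2, 19, label = "STORR", target = "Lpre",
             linker_aa = linker_aa),
    gf_event("loss", "Pat", 6, label = "STORR"),
    gf_event("loss", "Prh", 7, label = "STORR"),
    gf_event("rearrangement", "Par", 5, label = "La")
  )
}

new_gene <- function(label, role, seq, fused = FALSE, pair_id = NA_character_,
                     pseudo = FALSE, frameshift = FALSE) {
  list(label = label, role = role, seq = seq, fused = fused,
       pair_id = pair_id, pseudo = pseudo, frameshift = frameshift,
       rearranged = FALSE, linker_aa = NA_integer_, module_bp = NULL)
}

#' Simulate a gene family with known history on a chronogram
#'
#' Walks the species tree from the root towards the tips carrying a set of
#' gene copies; events fire on their configured branch at their configured
#' age. Pairing creates a linked pair of P450-like and oxidoreductase-like
#' genes; segmental duplication copies a pair under a new subgroup label;
#' fusion concatenates the two module sequences of a pair in frame with a
#' fresh linker; loss removes a subgroup's lineage below that branch;
#' pseudogenization inserts one nucleotide (frameshift) or a premature stop
#' codon; rearrangement flips the genomic order of a pair. Sequences evolve
#' under the JC69 clock with no indels, so module sequences of a subgroup
#' stay positionally aligned.
#'
#' @param chron chronogram; the family exists only below the pairing branch.
#' @param events list of [gf_event()]s; see [study_event_plan()].
#' @param clock a [clock_model()] (its `length` field is unused here).
#' @param module_bp nt lengths of the P450-like and oxidoreductase-like
#'   modules (each divisible by 3).
#' @param seed mandatory RNG seed.
#' @return a `synthetic_bundle`: list with `genes` (truth table, one row
#'   per extant gene copy), `sequences` (named nt strings), `layouts`
#'   (BED-like data.frame: contig, start, end, strand, gene_id, label,
#'   role; 0-based half-open), `chronogram`, `events` (realized plan),
#'   `panel` (ancestral module reference sequences for scanning),
#'   `module_bp` (per fused gene, its module segment lengths), `clock`,
#'   and `seed`.
#' @export
simulate_gene_family <- function(chron, events = study_event_plan(),
                                 clock = clock_model(),
                                 module_bp = c(900L, 600L), seed) {
  stopifnot(!missing(seed))
  stopifnot(length(module_bp) == 2, all(module_bp %% 3 == 0))
  set.seed(seed)
  ages <- node_ages(chron)
  ntip <- ape::Ntip(chron)
  root <- ntip + 1L

  ev_node <- vapply(events, function(e) resolve_branch_node(chron, e$branch),
                    integer(1))
  for (i in seq_along(events)) {
    v <- ev_node[i]
    pa <- if (v == root) Inf
          else ages[chron$edge[match(v, chron$edge[, 2]), 1]]
    t <- events[[i]]$time_my
    if (!(t > ages[v] && t < pa))
      stop("event '", events[[i]]$kind, "' at ", t,
           " MY lies outside its branch age interval (", ages[v], ", ",
           if (is.finite(pa)) pa else "Inf", ")")
  }

  pairing_i <- which(vapply(events, function(e) e$kind == "pairing",
                            logical(1)))
  if (length(pairing_i) != 1L)
    stop("the event plan must contain exactly one pairing event")
  pairing <- events[[pairing_i]]
  pairing_node <- ev_node[pairing_i]
  pair_bp <- pairing$pair_bp

  anc_p450 <- random_coding_sequence(module_bp[1] / 3L)
  anc_oxre <- random_coding_sequence(module_bp[2] / 3L)
  panel <- list(P450 = paste0(anc_p450, collapse = ""),
                oxidoreductase = paste0(anc_oxre, collapse = ""))

  rate <- clock$rate
  realized <- list()
  genes_out <- list()
  layout_rows <- list()

  evolve_set <- function(genes, dt_my) {
    if (dt_my <= 0 || !length(genes)) return(genes)
    lapply(genes, function(g) {
      g$seq <- evolve_jc69(g$seq, dt_my * 1e6, rate)
      g
    })
  }

  make_linker <- function(naa) {
    if (is.null(naa)) naa <- sample(9:13, 1)
    random_coding_sequence(naa + 1L)[-(1:3)]   # drop the leading ATG
  }

  rename_pair <- function(genes, old, new) {
    ids_old <- paste0(old, c(".P450", ".oxre"))
    ids_new <- paste0(new, c(".P450", ".oxre"))
    for (k in 1:2) {
      g <- genes[[ids_old[k]]]
      g$label <- new
      g$pair_id <- ids_new[3 - k]
      genes[[ids_new[k]]] <- g
    }
    genes[setdiff(names(genes), ids_old)]
  }

  apply_event <- function(genes, e) {
    kind <- e$kind
    if (kind == "pairing") {
      lab <- e$label %||% "L0"
      genes[[paste0(lab, ".P450")]] <-
        new_gene(lab, "P450", anc_p450, pair_id = paste0(lab, ".oxre"))
      genes[[paste0(lab, ".oxre")]] <-
        new_gene(lab, "oxidoreductase", anc_oxre,
                 pair_id = paste0(lab, ".P450"))
    } else if (kind == "segmental_duplication") {
      unfused_labs <- unique(vapply(
        Filter(function(g) !g$fused && !g$pseudo, genes),
        `[[`, character(1), "label"))
      if (!length(unfused_labs)) stop("no unfused pair to duplicate")
      src_lab <- e$target %||% unfused_labs[length(unfused_labs)]
      lab <- e$label
      for (role in c("P450", "oxre")) {
        donor <- genes[[paste0(src_lab, ".", role)]]
        id <- paste0(lab, ".", role)
        partner <- paste0(lab, ".", setdiff(c("P450", "oxre"), role))
        g <- donor
        g$label <- lab
        g$pair_id <- partner
        genes[[id]] <- g
      }
      if (!is.null(e$relabel))
        genes <- rename_pair(genes, src_lab, e$relabel)
    } else if (kind == "fusion") {
      unfused_labs <- unique(vapply(
        Filter(function(g) !g$fused, genes), `[[`, character(1), "label"))
      if (!length(unfused_labs)) stop("fusion event but no unfused pair")
      tgt <- e$target %||% unfused_labs[length(unfused_labs)]
      p450 <- genes[[paste0(tgt, ".P450")]]
      oxre <- genes[[paste0(tgt, ".oxre")]]
      linker <- make_linker(e$linker_aa)
      lab <- e$label %||% "fused"
      g <- new_gene(lab, "fused", c(p450$seq, linker, oxre$seq),
                    fused = TRUE)
      g$linker_aa <- length(linker) / 3L
      g$module_bp <- c(length(p450$seq), length(oxre$seq))
      genes <- genes[setdiff(names(genes),
                             paste0(tgt, c(".P450", ".oxre")))]
      genes[[lab]] <- g
    } else if (kind == "loss") {
      genes <- Filter(function(g) g$label != e$label, genes)
    } else if (kind == "pseudogenization") {
      tgt <- e$target %||% e$label
      idx <- which(vapply(genes, function(g) g$label == tgt, logical(1)))
      if (length(idx)) {
        i <- idx[1]
        g <- genes[[i]]
        if (runif(1) < 0.5) {
          pos <- floor(length(g$seq) / 2)
          g$seq <- append(g$seq, sample(NT, 1), after = pos)
          g$frameshift <- TRUE
        } else {
          cpos <- floor(length(g$seq) / 6) * 3L + 1L
          g$seq[cpos:(cpos + 2L)] <- c("T", "A", "A")
        }
        g$pseudo <- TRUE
        genes[[i]] <- g
      }
    } else if (kind == "rearrangement") {
      for (i in seq_along(genes))
        if (genes[[i]]$label == e$label) genes[[i]]$rearranged <- TRUE
    }
    genes
  }

  place_tip <- function(node, genes) {
    sp <- chron$tip.label[node]
    pos <- 1L
    prev_local <- NA_character_
    local_ids <- names(genes)
    for (j in seq_along(genes)) {
      id <- local_ids[j]
      g <- genes[[j]]
      gid <- paste0(sp, "_", id)
      glen <- length(g$seq)
      gap <- if (!is.na(g$pair_id) && identical(g$pair_id, prev_local))
        pair_bp else 10000L
      start <- pos + gap
      genes_out[[gid]] <<- list(
        gene_id = gid, species = sp, subgroup = g$label, role = g$role,
        fused = g$fused, pseudo = g$pseudo, frameshift = g$frameshift,
        rearranged = g$rearranged, linker_aa = g$linker_aa,
        module_bp = g$module_bp, seq = paste0(g$seq, collapse = ""))
      layout_rows[[gid]] <<- data.frame(
        contig = paste0("ctg_", sp), start = start - 1L,
        end = start - 1L + glen, strand = "+", gene_id = gid,
        label = if (g$fused) g$label else
          paste0(g$label, "_", if (g$role == "P450") "P450" else "COR"),
        role = g$role, stringsAsFactors = FALSE)
      pos <- start + glen
      prev_local <- id
    }
    # rearrangement: swap the two members of flagged pairs on the contig
    re_labs <- unique(vapply(Filter(function(g)
      isTRUE(g$rearranged) && !g$fused, genes), `[[`, character(1), "label"))
    for (lab in re_labs) {
      ids <- paste0(sp, "_", lab, c(".P450", ".oxre"))
      if (!all(ids %in% names(layout_rows))) next
      r1 <- layout_rows[[ids[1]]]; r2 <- layout_rows[[ids[2]]]
      w1 <- r1$end - r1$start; w2 <- r2$end - r2$start
      lo <- min(r1$start, r2$start); hi <- max(r1$end, r2$end)
      gapbp <- (hi - lo) - w1 - w2
      # oxre first, then P450
      layout_rows[[ids[2]]]$start <<- lo
      layout_rows[[ids[2]]]$end <<- lo + w2
      layout_rows[[ids[1]]]$start <<- lo + w2 + gapbp
      layout_rows[[ids[1]]]$end <<- hi
    }
    invisible(NULL)
  }

  descend <- function(node, genes, from_age) {
    here <- which(ev_node == node)
    here <- here[order(-vapply(here, function(i) events[[i]]$time_my,
                               numeric(1)))]
    t_cur <- from_age
    for (i in here) {
      e <- events[[i]]
      genes <- evolve_set(genes, t_cur - e$time_my)
      genes <- apply_event(genes, e)
      realized[[length(realized) + 1L]] <<- data.frame(
        kind = e$kind, node = node, time_my = e$time_my,
        label = e$label %||% NA_character_, stringsAsFactors = FALSE)
      t_cur <- e$time_my
    }
    genes <- evolve_set(genes, t_cur - ages[node])
    if (node <= ntip) {
      if (length(genes)) place_tip(node, genes)
      return(invisible(NULL))
    }
    for (k in chron$edge[chron$edge[, 1] == node, 2])
      descend(k, genes, ages[node])
    invisible(NULL)
  }

  start_age <- if (pairing_node == root) pairing$time_my + 1 else
    ages[chron$edge[match(pairing_node, chron$edge[, 2]), 1]]
  descend(pairing_node, list(), start_age)

  genes_df <- do.call(rbind, lapply(genes_out, function(g)
    data.frame(gene_id = g$gene_id, species = g$species,
               subgroup = g$subgroup, role = g$role, fused = g$fused,
               pseudo = g$pseudo, frameshift = g$frameshift,
               rearranged = g$rearranged, linker_aa = g$linker_aa,
               stringsAsFactors = FALSE)))
  rownames(genes_df) <- NULL
  seqs <- vapply(genes_out, `[[`, character(1), "seq")
  layouts <- do.call(rbind, layout_rows)
  layouts <- layouts[order(layouts$contig, layouts$start), ]
  rownames(layouts) <- NULL
  realized_df <- if (length(realized)) do.call(rbind, realized) else
    data.frame(kind = character(), node = integer(), time_my = numeric(),
               label = character())
  module_bp_map <- lapply(genes_out, `[[`, "module_bp")

  structure(list(genes = genes_df, sequences = seqs, layouts = layouts,
                 chronogram = chron, events = realized_df, panel = panel,
                 module_bp = module_bp_map, clock = clock, seed = seed),
            class = "synthetic_bundle")
}

#' Extract positionally aligned module sequences from a bundle
#'
#' For one module role, returns the module sub-sequence of every extant
#' gene carrying it: unfused genes of that role contribute their full
#' sequence, fused genes the corresponding module segment. Pseudogenes are
#' excluded (not full-length coding sequences). No indels are simulated, so
#' the result is an alignment.
#'
#' @param bundle a `synthetic_bundle`.
#' @param role `"P450"` or `"oxidoreductase"`.
#' @return named character vector (alignment); names are gene ids.
#' @export
module_alignment <- function(bundle, role = c("P450", "oxidoreductase")) {
  role <- match.arg(role)
  out <- character(0)
  for (i in seq_len(nrow(bundle$genes))) {
    g <- bundle$genes[i, ]
    if (g$pseudo) next
    s <- bundle$sequences[[g$gene_id]]
    if (g$role == role) {
      out[g$gene_id] <- s
    } else if (g$fused) {
      mb <- bundle$module_bp[[g$gene_id]]
      if (role == "P450") out[g$gene_id] <- substr(s, 1, mb[1])
      else out[g$gene_id] <- substr(s, nchar(s) - mb[2] + 1, nchar(s))
    }
  }
  out
}

#' Write a synthetic bundle to plain-text files
#'
#' FASTA for sequences, BED-like TSV for layouts, Newick plus node-age TSV
#' for the chronogram, JSON for the truth tables. Regenerating with the
#' same seed and configuration and rewriting gives byte-identical files.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(bundle$sequences)
  Biostrings::writeXStringSet(ss, filepath = file.path(dir, "genes.fasta"))
  utils::write.table(bundle$layouts, file.path(dir, "layouts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_chronogram(bundle$chronogram, file.path(dir, "chronogram.nwk"),
                   file.path(dir, "node_ages.tsv"))
  truth <- list(genes = bundle$genes, events = bundle$events,
                panel = bundle$panel, seed = bundle$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

## ---- synonymous-only paralog divergence ---------------------------------

#' Simulate a paralog pair diverging by synonymous substitutions only
#'
#' Starting from one random coding sequence, each of the two descendant
#' lineages accumulates mutations for `time_my` under a JC69 proposal
#' process in which non-synonymous (or stop-creating) proposals are
#' rejected. Each specific nucleotide change is proposed at rate/3 per
#' site-year, so synonymous substitutions accrue at `rate` per
#' Nei-Gojobori synonymous site and the pair's expected Ks is
#' `2 * rate * time`.
#'
#' @param ncodons coding length in codons.
#' @param time_my divergence time of each lineage from the ancestor (MY).
#' @param rate substitutions/site/year.
#' @param seed RNG seed.
#' @return list with elements `a` and `b` (coding nt strings).
#' @export
simulate_synonymous_pair <- function(ncodons = 500L, time_my = 20,
                                     rate = 1.396e-8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- random_coding_sequence(ncodons)
  code <- Biostrings::GENETIC_CODE
  evolve_syn <- function(seq, years) {
    L <- length(seq)
    n_prop <- stats::rpois(1, L * rate * years)
    if (n_prop == 0) return(seq)
    sites <- sample.int(L, n_prop, replace = TRUE)
    offs <- sample.int(3L, n_prop, replace = TRUE)
    for (k in seq_len(n_prop)) {
      i <- sites[k]
      new_nt <- NT[((match(seq[i], NT) - 1L + offs[k]) %% 4L) + 1L]
      c0 <- (i - 1L) %/% 3L
      cod <- seq[(c0 * 3L + 1L):(c0 * 3L + 3L)]
      aa_old <- code[[paste0(cod, collapse = "")]]
      cod[((i - 1L) %% 3L) + 1L] <- new_nt
      aa_new <- code[[paste0(cod, collapse = "")]]
      if (identical(aa_old, aa_new) && aa_new != "*") seq[i] <- new_nt
    }
    seq
  }
  years <- time_my * 1e6
  list(a = paste0(evolve_syn(anc, years), collapse = ""),
       b = paste0(evolve_syn(anc, years), collapse = ""))
}

## ---- dilution series ----------------------------------------------------

#' Simulate a calibration dilution series and sample peak areas
#'
#' Linear instrument response `area = intercept + slope * conc` with
#' Gaussian noise on the calibration points. Sample peaks are generated at
#' configured multiples of the true limit of detection
#' `LOD = 3.3 * noise_sd / slope`.
#'
#' @param concentrations numeric vector (at least 3 points, e.g. a 20-point
#'   serial dilution).
#' @param slope,intercept line parameters (slope > 0).
#' @param noise_sd Gaussian response noise sd (>= 0).
#' @param sample_multiples named numeric vector: sample id -> multiple of
#'   the true LOD at which its concentration sits.
#' @param seed RNG seed.
#' @return list with `calibration` (data.frame conc, response), `samples`
#'   (data.frame sample, conc, response or NULL), and `true_lod`.
#' @export
simulate_dilution_series <- function(concentrations, slope = 1,
                                     intercept = 0, noise_sd = 0,
                                     sample_multiples = NULL, seed = NULL) {
  if (length(concentrations) < 3) stop("need at least 3 concentration points")
  stopifnot(noise_sd >= 0, slope > 0)
  if (!is.null(seed)) set.seed(seed)
  resp <- intercept + slope * concentrations +
    rnorm(length(concentrations), 0, noise_sd)
  cal <- data.frame(conc = concentrations, response = resp)
  true_lod <- 3.3 * noise_sd / slope
  samples <- NULL
  if (!is.null(sample_multiples)) {
    conc <- true_lod * sample_multiples
    samples <- data.frame(sample = names(sample_multiples), conc = conc,
                          response = intercept + slope * conc,
                          stringsAsFactors = FALSE)
  }
  list(calibration = cal, samples = samples, true_lod = true_lod)
}
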