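#' Reference module panel for fusion scanning
#'
#' Reference coding sequences for the two modules of the bi-modular fusion
#' protein: a cytochrome P450 and an oxidoreductase. Multiple references
#' per role are allowed (named vectors); ids must be unique.
#'
#' @param P450,oxidoreductase character vectors of nt reference sequences.
#' @return a `module_panel` list.
#' @export
module_panel <- function(P450, oxidoreductase) {
  p <- as.character(P450)
  o <- as.character(oxidoreductase)
  if (!length(p) || !length(o)) stop("both module roles must be represented")
  if (is.null(names(p))) names(p) <- paste0("P450_ref", seq_along(p))
  if (is.null(names(o))) names(o) <- paste0("oxre_ref", seq_along(o))
  if (anyDuplicated(c(names(p), names(o)))) stop("duplicate panel ids")
  structure(list(P450 = p, oxidoreductase = o), class = "module_panel")
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

translate_nt <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
  aa <- Biostrings::GENETIC_CODE[cods]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# best panel hit for one role on the (already oriented) sequence
best_role_hit <- function(seq, refs, match, mismatch, gap) {
  best <- NULL
  for (id in names(refs)) {
    h <- smith_waterman(refs[[id]], seq, match = match, mismatch = mismatch,
                        gap = gap, both_strands = FALSE)
    if (is.null(best) || h$score > best$score) {
      best <- h
      best$ref <- id
      best$ref_len <- nchar(refs[[id]])
    }
  }
  if (best$empty) return(NULL)
  qlen <- best$query_interval[2] - best$query_interval[1]
  best$coverage <- qlen / best$ref_len
  # project the full module interval onto the target
  L <- nchar(seq)
  best$proj <- c(max(0L, best$target_interval[1] - best$query_interval[1]),
                 min(L, best$target_interval[2] +
                        (best$ref_len - best$query_interval[2])))
  best
}

empty_call <- function(id, reason) {
  structure(list(sequence_id = id, class = "none", hits = NULL,
                 linker = NA_character_, linker_aa = NA_integer_,
                 strand = NA_character_, diagnostics = list(reason = reason)),
            class = "fusion_call")
}

#' Scan a sequence for a bi-modular P450-oxidoreductase fusion
#'
#' Locates the best non-overlapping hit per module role by local alignment
#' against the panel, checks module order, strand, reading frame and linker
#' length, and classifies the sequence as `full_fusion` (both modules at
#' `min_coverage`, same strand and frame, P450 before oxidoreductase,
#' translated linker length within `linker_bounds`), `truncated_fusion`
#' (full P450 plus conserved linker, then a short oxidoreductase remnant
#' ending at a premature stop), `single_module`, or `none`. The linker is
#' the translated segment strictly between the projected end of the P450
#' module and the projected start of the oxidoreductase module.
#'
#' @param seq nucleotide string.
#' @param panel a [module_panel()].
#' @param id sequence id carried into the call.
#' @param min_coverage minimum aligned fraction of the panel reference for
#'   a "full length" module (default 0.8).
#' @param linker_bounds allowed translated linker length in aa (default
#'   9-13).
#' @param match,mismatch,gap local-alignment scores.
#' @return a `fusion_call`: `sequence_id`, `class`, `hits` (data.frame with
#'   role, start, end, strand, frame, score, coverage, ref), `linker`,
#'   `linker_aa`, `strand`, `diagnostics`.
#' @export
scan_sequence <- function(seq, panel, id = "query", min_coverage = 0.8,
                          linker_bounds = c(9L, 13L), match = 2,
                          mismatch = -3, gap = -5) {
  stopifnot(inherits(panel, "module_panel"))
  if (nchar(seq) < min(nchar(unlist(panel))))
    return(empty_call(id,
      "sequence shorter than the smallest panel module"))
  # choose orientation by the best overall hit
  probe <- smith_waterman(panel$P450[[1]], seq, match = match,
                          mismatch = mismatch, gap = gap)
  probe2 <- smith_waterman(panel$oxidoreductase[[1]], seq, match = match,
                           mismatch = mismatch, gap = gap)
  strand <- if (probe2$score > probe$score) probe2$strand else probe$strand
  oseq <- if (strand == "-") revcomp(seq) else seq
  L <- nchar(seq)

  hp <- best_role_hit(oseq, panel$P450, match, mismatch, gap)
  ho <- best_role_hit(oseq, panel$oxidoreductase, match, mismatch, gap)

  back_map <- function(iv) {
    if (strand == "-") c(L - iv[2], L - iv[1]) else iv
  }
  hit_row <- function(h, role) {
    iv <- back_map(h$proj)
    data.frame(role = role, start = iv[1], end = iv[2], strand = strand,
               frame = h$proj[1] %% 3, score = h$score,
               coverage = h$coverage, ref = h$ref,
               stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(
    if (!is.null(hp)) list(hit_row(hp, "P450")),
    if (!is.null(ho)) list(hit_row(ho, "oxidoreductase"))))

  if (is.null(hp) && is.null(ho))
    return(empty_call(id, "no module hit"))

  mk <- function(class, linker = NA_character_, linker_aa = NA_integer_,
                 diagnostics = list()) {
    structure(list(sequence_id = id, class = class, hits = hits,
                   linker = linker, linker_aa = linker_aa, strand = strand,
                   diagnostics = diagnostics), class = "fusion_call")
  }

  covA <- if (!is.null(hp)) hp$coverage else 0
  covB <- if (!is.null(ho)) ho$coverage else 0
  if (is.null(hp) || covA < min_coverage) {
    if (covB >= min_coverage) return(mk("single_module"))
    return(mk("none", diagnostics = list(reason = "no full-length module")))
  }
  if (is.null(ho)) return(mk("single_module"))

  # both present on the oriented sequence; require P450 upstream
  gap_nt <- ho$proj[1] - hp$proj[2]
  in_frame <- gap_nt >= 0 && gap_nt %% 3 == 0
  linker_nt <- if (gap_nt > 0)
    substr(oseq, hp$proj[2] + 1, ho$proj[1]) else ""
  linker_aa <- if (in_frame) gap_nt %/% 3 else NA_integer_
  linker <- if (in_frame && gap_nt > 0) translate_nt(linker_nt)
            else NA_character_
  ordered <- ho$proj[1] >= hp$proj[2]

  if (covB >= min_coverage) {
    if (ordered && in_frame && !is.na(linker_aa) &&
        linker_aa >= linker_bounds[1] && linker_aa <= linker_bounds[2]) {
      diag <- if (!is.na(linker) && grepl("*", linker, fixed = TRUE))
        list(linker_stop = TRUE) else list()
      return(mk("full_fusion", linker, linker_aa, diagnostics = diag))
    }
    return(mk("unclassified_two_modules", linker, linker_aa,
              diagnostics = list(ordered = ordered, in_frame = in_frame,
                                 linker_aa = linker_aa)))
  }

  # oxidoreductase remnant: look for a premature stop after the linker
  if (ordered && in_frame && !is.na(linker_aa) &&
      linker_aa >= linker_bounds[1] && linker_aa <= linker_bounds[2]) {
    tail_nt <- substr(oseq, ho$proj[1] + 1, nchar(oseq))
    aa <- translate_nt(tail_nt)
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0) {
      return(mk("truncated_fusion", linker, linker_aa,
                diagnostics = list(
                  premature_stop_codon = as.integer(stop_at),
                  remnant_codons = as.integer(stop_at) - 1L)))
    }
  }
  mk("single_module")
}

#' Check a coding sequence for pseudogene features
#'
#' Reports the first in-frame premature stop codon and frameshift evidence:
#' a length not divisible by 3, or (when a reference is given) a length
#' difference from the reference that is not a multiple of 3.
#'
#' @param seq nucleotide string.
#' @param reference optional intact reference coding sequence.
#' @return list: `premature_stop_codon` (codon index or NA), `frameshift`
#'   (logical), `clean` (logical).
#' @export
pseudogene_check <- function(seq, reference = NULL) {
  fs <- if (!is.null(reference))
    (nchar(seq) - nchar(reference)) %% 3 != 0
  else nchar(seq) %% 3 != 0
  aa <- translate_nt(seq)
  ncod <- nchar(aa)
  stop_at <- regexpr("*", substr(aa, 1, max(0, ncod - 1)), fixed = TRUE)
  premature <- if (stop_at > 0) as.integer(stop_at) else NA_integer_
  list(premature_stop_codon = premature, frameshift = fs,
       clean = !fs && is.na(premature))
}

#' Scan a contig layout for fusions and unfused module pairs
#'
#' Scans every gene sequence with [scan_sequence()], then pairs
#' single-module genes of complementary roles lying within `pair_distance`
#' bp on the same contig into `unfused_pair` calls carrying the inter-gene
#' distance and the orientation-normalized gene order (`"P450-first"` or
#' `"COR-first"`). Overlapping gene intervals are flagged but both genes
#' are retained.
#'
#' @param layout BED-like data.frame: contig, start, end, strand, gene_id
#'   (0-based half-open).
#' @param sequences named character vector of gene sequences.
#' @param panel a [module_panel()].
#' @param pair_distance maximum inter-gene distance D in bp (default 5000).
#' @param ... passed to [scan_sequence()].
#' @return named list of `fusion_call`s (per gene, plus one per unfused
#'   pair under "pair:<idA>:<idB>").
#' @export
scan_layout <- function(layout, sequences, panel, pair_distance = 5000,
                        ...) {
  stopifnot(pair_distance > 0)
  calls <- list()
  for (i in seq_len(nrow(layout))) {
    gid <- layout$gene_id[i]
    calls[[gid]] <- scan_sequence(sequences[[gid]], panel, id = gid, ...)
  }
  for (ctg in unique(layout$contig)) {
    rows <- layout[layout$contig == ctg, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1) {
      ov <- which(rows$start[-1] < rows$end[-nrow(rows)])
      for (k in ov) {
        calls[[rows$gene_id[k]]]$diagnostics$overlaps <-
          rows$gene_id[k + 1]
        calls[[rows$gene_id[k + 1]]]$diagnostics$overlaps <-
          rows$gene_id[k]
      }
    }
    singles <- rows[vapply(rows$gene_id, function(g)
      calls[[g]]$class == "single_module", logical(1)), , drop = FALSE]
    if (nrow(singles) < 2) next
    role_of <- vapply(singles$gene_id, function(g) {
      h <- calls[[g]]$hits
      h$role[which.max(h$coverage)]
    }, character(1))
    used <- character(0)
    for (i in seq_len(nrow(singles) - 1)) {
      a <- singles$gene_id[i]; b <- singles$gene_id[i + 1]
      if (a %in% used || b %in% used) next
      if (role_of[[a]] == role_of[[b]]) next
      dist_bp <- singles$start[i + 1] - singles$end[i]
      if (dist_bp > pair_distance) next
      minus <- singles$strand[i] == "-" && singles$strand[i + 1] == "-"
      first_role <- if (minus) role_of[[b]] else role_of[[a]]
      ord <- if (first_role == "P450") "P450-first" else "COR-first"
      calls[[paste0("pair:", a, ":", b)]] <- structure(list(
        sequence_id = paste0(a, "+", b), class = "unfused_pair",
        members = c(a, b), distance_bp = dist_bp, order = ord,
        contig = ctg, diagnostics = list()), class = "fusion_call")
      used <- c(used, a, b)
    }
  }
  calls
}
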