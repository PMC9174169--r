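## Microsynteny: reciprocal best hits, cluster presence, pair order.

#' Reciprocal best hits between two gene sets
#'
#' Scores every cross pair by local alignment and keeps (a, b) when b is
#' a's best hit, a is b's best hit, and the normalized score -- the raw
#' local score divided by the smaller self-alignment score -- is at least
#' `min_norm_score`. The normalized self-score ratio replaces a raw
#' E-value cutoff, which depends on database size and is not reproducible
#' in a library setting.
#'
#' @param a,b named character vectors of nt sequences.
#' @param min_norm_score q in `[0, 1]` (default 0.9).
#' @param match,mismatch,gap alignment scores.
#' @return data.frame: gene_a, gene_b, norm_score (each gene in at most
#'   one pair).
#' @export
reciprocal_best_hits <- function(a, b, min_norm_score = 0.9, match = 2,
                                 mismatch = -3, gap = -5) {
  stopifnot(length(a) >= 1, length(b) >= 1,
            min_norm_score >= 0, min_norm_score <= 1)
  self <- function(s) match * nchar(s)
  score <- matrix(0, length(a), length(b),
                  dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    h <- smith_waterman(a[[i]], b[[j]], match = match, mismatch = mismatch,
                        gap = gap)
    score[i, j] <- h$score / min(self(a[[i]]), self(b[[j]]))
  }
  best_ab <- apply(score, 1, which.max)
  best_ba <- apply(score, 2, which.max)
  keep <- which(vapply(seq_along(a), function(i) {
    j <- best_ab[i]
    best_ba[j] == i && score[i, j] >= min_norm_score
  }, logical(1)))
  data.frame(gene_a = names(a)[keep], gene_b = names(b)[best_ab[keep]],
             norm_score = score[cbind(keep, best_ab[keep])],
             stringsAsFactors = FALSE)
}

#' Score presence of the fusion-plus-promorphinan gene cluster
#'
#' Reports, per contig, which of the required gene labels co-occur within
#' `max_span_bp`, whether the cluster is complete, and any extra (tandem)
#' copies of required labels. Labels are matched as prefixes so subgroup
#' suffixes on layout labels do not hide a cluster member.
#'
#' @param layout BED-like data.frame with columns contig, start, end,
#'   label.
#' @param required cluster member labels (default the fusion gene STORR
#'   plus the four promorphinan genes SALSYN, SALR, SALAT, THS).
#' @param max_span_bp maximum cluster span (default 1.2 Mb, the largest
#'   relevant contig size).
#' @return list: `complete`, `present`, `missing`, `extras` (labels with
#'   more than one copy), `contig`, `span_bp`.
#' @export
cluster_presence <- function(layout,
                             required = c("STORR", "SALSYN", "SALR",
                                          "SALAT", "THS"),
                             max_span_bp = 1.2e6) {
  best <- list(complete = FALSE, present = character(0),
               missing = required, extras = character(0),
               contig = NA_character_, span_bp = NA_real_)
  label_hits <- function(lab, labels)
    labels == lab | startsWith(labels, paste0(lab, "_"))
  for (ctg in unique(layout$contig)) {
    rows <- layout[layout$contig == ctg, , drop = FALSE]
    hit_rows <- rows[Reduce(`|`, lapply(required, label_hits,
                                        labels = rows$label)), ,
                     drop = FALSE]
    if (!nrow(hit_rows)) next
    span <- max(hit_rows$end) - min(hit_rows$start)
    if (span > max_span_bp) next
    lab_of <- vapply(hit_rows$label, function(l)
      required[label_hits_any(l, required)][1], character(1))
    present <- unique(lab_of)
    extras <- unique(lab_of[duplicated(lab_of)])
    if (length(present) > length(best$present)) {
      best <- list(complete = setequal(present, required),
                   present = present,
                   missing = setdiff(required, present), extras = extras,
                   contig = ctg, span_bp = span)
    }
  }
  best
}

label_hits_any <- function(label, required)
  vapply(required, function(r)
    label == r || startsWith(label, paste0(r, "_")), logical(1))

#' Orientation-normalized order of a paralog gene pair
#'
#' For each candidate adjacent pair of complementary module roles on a
#' contig, reports whether the P450 gene precedes the oxidoreductase gene
#' once coordinates are normalized for strand (a pair carried entirely on
#' the minus strand is read right-to-left).
#'
#' @param layout BED-like data.frame with columns contig, start, end,
#'   strand, gene_id, role (role in "P450"/"oxidoreductase").
#' @param max_distance_bp maximum inter-gene distance for a candidate pair.
#' @return data.frame: contig, gene_p450, gene_oxre, order
#'   ("P450-first"/"COR-first"), distance_bp.
#' @export
pair_order <- function(layout, max_distance_bp = 5000) {
  if (!all(c("role", "strand") %in% names(layout)))
    stop("layout needs 'role' and 'strand' columns")
  out <- list()
  for (ctg in unique(layout$contig)) {
    rows <- layout[layout$contig == ctg &
                     layout$role %in% c("P450", "oxidoreductase"), ,
                   drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) < 2) next
    for (i in seq_len(nrow(rows) - 1)) {
      r1 <- rows[i, ]; r2 <- rows[i + 1, ]
      if (r1$role == r2$role) next
      d <- r2$start - r1$end
      if (d > max_distance_bp) next
      minus <- r1$strand == "-" && r2$strand == "-"
      first_role <- if (minus) r2$role else r1$role
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg,
        gene_p450 = if (r1$role == "P450") r1$gene_id else r2$gene_id,
        gene_oxre = if (r1$role == "P450") r2$gene_id else r1$gene_id,
        order = if (first_role == "P450") "P450-first" else "COR-first",
        distance_bp = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    stop("no candidate pair of complementary roles found")
  do.call(rbind, out)
}
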