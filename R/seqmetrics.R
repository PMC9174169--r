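## Alignments are named character vectors of equal-length sequence strings
## (gaps "-"); helper checks shared by the module.

check_alignment <- function(aln) {
  if (length(aln) < 1) stop("empty alignment")
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment records need unique names")
  L <- nchar(aln)
  if (length(unique(L)) != 1)
    stop("alignment sequences differ in length")
  invisible(nchar(aln[[1]]))
}

aln_matrix <- function(aln) {
  check_alignment(aln)
  do.call(rbind, strsplit(toupper(aln), ""))
}

#' Jukes-Cantor distance between two aligned nucleotide sequences
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` where `p` is the proportion of
#' differing ungapped columns. A p-distance at or beyond 0.75 is reported
#' as a saturation error rather than a (non-finite) number.
#'
#' @param a,b equal-length nucleotide strings (may contain "-").
#' @return distance in substitutions/site.
#' @export
jc69_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  if (nchar(a) == 0) stop("empty sequences")
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x != "-" & y != "-"
  if (!any(ok)) stop("no ungapped overlap between sequences")
  p <- mean(x[ok] != y[ok])
  if (p >= 0.75)
    stop("saturated pair: p-distance ", format(p), " >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' JC69 distance matrix for an alignment
#'
#' @param aln named character vector of aligned nt sequences.
#' @return symmetric matrix (subs/site) with zero diagonal and attribute
#'   `model = "JC69"`.
#' @export
jc69_distance_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    p <- mean(m[i, ok] != m[j, ok])
    if (p >= 0.75)
      stop("saturated pair: ", names(aln)[i], " vs ", names(aln)[j])
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  attr(d, "model") <- "JC69"
  # corrected distances can violate the triangle inequality; report, never fix
  viol <- 0L
  if (n >= 3) {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i != j && j != k && i != k &&
          d[i, k] > d[i, j] + d[j, k] + 1e-12) viol <- viol + 1L
    }
  }
  attr(d, "triangle_violations") <- viol
  if (viol > 0)
    warning(viol, " triangle-inequality violation(s) among JC distances")
  d
}

#' Pairwise percent-identity matrix
#'
#' Identity is computed over aligned columns where neither sequence has a
#' gap (EMBOSS-style pairwise identity). A pair with no ungapped overlap is
#' flagged as NA, never silently 0.
#'
#' @param aln named character vector of aligned sequences (nt or aa).
#' @return symmetric percent matrix, diagonal 100.
#' @export
identity_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 records")
  out <- matrix(100, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) {
      out[i, j] <- out[j, i] <- NA_real_
      warning("no ungapped overlap: ", names(aln)[i], " vs ", names(aln)[j])
    } else {
      out[i, j] <- out[j, i] <- 100 * mean(m[i, ok] == m[j, ok])
    }
  }
  out
}

#' Optimal local alignment (Smith-Waterman scoring)
#'
#' Best local alignment between `query` and `target` under simple
#' match/mismatch/linear-gap scores, computed on both target strands for
#' nucleotide input. Intervals are 0-based half-open; minus-strand hits are
#' reported in forward target coordinates. If no positive-scoring alignment
#' exists, an empty hit with score 0 is returned.
#'
#' @param query,target sequence strings.
#' @param match,mismatch,gap scores (gap is the penalty per gapped
#'   position, must be negative).
#' @param both_strands also try the reverse complement of `target`.
#' @return list: `score`, `query_interval`, `target_interval`, `strand`,
#'   `pident`, `empty`.
#' @export
smith_waterman <- function(query, target, match = 2, mismatch = -3,
                           gap = -5, both_strands = TRUE) {
  if (nchar(query) == 0 || nchar(target) == 0) stop("empty sequence")
  if (gap >= 0) stop("gap penalty must be negative")
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  one <- function(tg) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = query, subject = tg, type = "local",
      substitutionMatrix = sub, gapOpening = 0, gapExtension = -gap)
    list(score = Biostrings::score(pa),
         q = c(Biostrings::start(Biostrings::pattern(pa)) - 1L,
               Biostrings::end(Biostrings::pattern(pa))),
         t = c(Biostrings::start(Biostrings::subject(pa)) - 1L,
               Biostrings::end(Biostrings::subject(pa))),
         pid = Biostrings::pid(pa))
  }
  fwd <- one(target)
  best <- fwd; strand <- "+"
  if (both_strands && grepl("^[ACGTNacgtn]+$", target)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(target)))
    rev <- one(rc)
    if (rev$score > best$score) {
      L <- nchar(target)
      rev$t <- c(L - rev$t[2], L - rev$t[1])
      best <- rev; strand <- "-"
    }
  }
  if (best$score <= 0) {
    return(list(score = 0, query_interval = c(0L, 0L),
                target_interval = c(0L, 0L), strand = "+", pident = NA_real_,
                empty = TRUE))
  }
  list(score = best$score, query_interval = as.integer(best$q),
       target_interval = as.integer(best$t), strand = strand,
       pident = best$pid, empty = FALSE)
}

#' Keep conserved, gap-poor alignment columns
#'
#' A column is kept when its gap fraction is at most `max_gap_fraction` and
#' its majority residue (among non-gap characters) has frequency at least
#' `min_conservation`. Column order is preserved; the operation is
#' idempotent. If everything is removed, a zero-length alignment with
#' attribute `empty = TRUE` is returned with a warning.
#'
#' @param aln named character vector of aligned sequences.
#' @param max_gap_fraction g in `[0, 1]` (default 0).
#' @param min_conservation c in `(0, 1]` (default 0.5).
#' @return trimmed alignment; attribute `kept` holds the retained column
#'   indices.
#' @export
trim_conserved_blocks <- function(aln, max_gap_fraction = 0,
                                  min_conservation = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_conservation > 0, min_conservation <= 1)
  m <- aln_matrix(aln)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gapf <- mean(col == "-")
    if (gapf > max_gap_fraction) return(FALSE)
    res <- col[col != "-"]
    if (!length(res)) return(FALSE)
    max(table(res)) / length(res) >= min_conservation
  }, logical(1))
  out <- apply(m[, keep, drop = FALSE], 1, paste0, collapse = "")
  names(out) <- names(aln)
  if (!any(keep)) {
    warning("all columns removed by conservation trimming")
    attr(out, "empty") <- TRUE
  }
  attr(out, "kept") <- which(keep)
  out
}

#' Concatenate per-gene alignments over the same taxa
#'
#' @param alignments named list of alignments with identical taxon sets.
#' @return one alignment (taxa ordered as in the first element) with
#'   attribute `map`: data.frame(gene, start, end) of 1-based column spans.
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  taxa <- names(alignments[[1]])
  for (k in seq_along(alignments)) {
    tk <- names(alignments[[k]])
    miss <- c(setdiff(taxa, tk), setdiff(tk, taxa))
    if (length(miss))
      stop("taxon sets differ (alignment ", k, "): ",
           paste(unique(miss), collapse = ", "))
  }
  pieces <- lapply(alignments, function(a) a[taxa])
  lens <- vapply(pieces, function(a) nchar(a[[1]]), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  gene_names <- names(alignments) %||% paste0("gene", seq_along(alignments))
  out <- do.call(paste0, pieces)
  names(out) <- taxa
  attr(out, "map") <- data.frame(gene = gene_names, start = starts,
                                 end = ends, stringsAsFactors = FALSE)
  out
}
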