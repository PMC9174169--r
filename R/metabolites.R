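## Calibration fits, limits of detection, presence matrices.

#' Compound classes of the presence matrix
#'
#' Reticuline (the pathway branch point), the promorphinans (salutaridine,
#' salutaridinol, salutaridinol-7-O-acetate) and the morphinans (thebaine,
#' oripavine, codeine, morphine).
#'
#' @return named list of compound character vectors.
#' @export
compound_classes <- function() {
  list(
    reticuline = "reticuline",
    promorphinan = c("salutaridine", "salutaridinol",
                     "salutaridinol_7_O_acetate"),
    morphinan = c("thebaine", "oripavine", "codeine", "morphine")
  )
}

#' Fit a calibration line and compute the limit of detection
#'
#' Ordinary least squares of response on concentration; the limit of
#' detection is `LOD = 3.3 * Sy / S` where `Sy` is the residual standard
#' deviation of the response and `S` the slope.
#'
#' @param conc,response numeric vectors (>= 3 points, non-constant
#'   concentrations).
#' @return a `calibration_fit`: `slope`, `intercept`, `sy`, `lod`.
#' @export
fit_lod <- function(conc, response) {
  if (length(conc) < 3 || length(response) != length(conc))
    stop("need at least 3 matched concentration/response points")
  if (length(unique(conc)) < 2) stop("concentrations are constant")
  fit <- lm(response ~ conc)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("invalid fit: non-positive slope")
  # summary.lm warns on perfect fits; a zero residual sd is legitimate here
  sy <- suppressWarnings(summary(fit)$sigma)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 sy = sy, lod = 3.3 * sy / slope),
            class = "calibration_fit")
}

#' Call compound presence from peak areas
#'
#' Back-calculates each peak's concentration through the fitted calibration
#' line (intercept retained) and calls `detected` when the concentration is
#' at least `multiplier` times that compound's LOD, else `ND`. The boundary
#' is inclusive: exactly `multiplier * LOD` counts as detected.
#'
#' @param peaks data.frame: species, compound, area.
#' @param fits named list of `calibration_fit`s, one per compound present
#'   in `peaks`.
#' @param multiplier detection multiple of the LOD (default 10).
#' @return a `presence_matrix`: species x compound character matrix with
#'   values "detected"/"ND".
#' @export
call_presence <- function(peaks, fits, multiplier = 10) {
  stopifnot(all(c("species", "compound", "area") %in% names(peaks)))
  miss <- setdiff(unique(peaks$compound), names(fits))
  if (length(miss)) stop("missing calibration fit for: ",
                         paste(miss, collapse = ", "))
  species <- unique(peaks$species)
  compounds <- unique(peaks$compound)
  m <- matrix("ND", length(species), length(compounds),
              dimnames = list(species, compounds))
  for (i in seq_len(nrow(peaks))) {
    f <- fits[[peaks$compound[i]]]
    conc <- (peaks$area[i] - f$intercept) / f$slope
    thr <- multiplier * f$lod
    if (conc >= thr) m[peaks$species[i], peaks$compound[i]] <- "detected"
  }
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Per-class species counts from a presence matrix
#'
#' For each compound class, the number of species with at least one
#' detected compound of that class.
#'
#' @param m a `presence_matrix` (species x compound, "detected"/"ND").
#' @param classes compound classes (default [compound_classes()]).
#' @return named integer vector, one count per class.
#' @export
summarize_matrix <- function(m, classes = compound_classes()) {
  vapply(classes, function(cmp) {
    cols <- intersect(cmp, colnames(m))
    if (!length(cols)) return(0L)
    sum(apply(m[, cols, drop = FALSE] == "detected", 1, any))
  }, integer(1))
}

#' The published 12-species presence matrix
#'
#' Loads the printed species-by-compound detection table bundled with the
#' package (values "+" for quantified at >= 10x LOD, "ND" otherwise) and
#' recodes it as a `presence_matrix`.
#'
#' @param path CSV path; defaults to the bundled copy.
#' @return a `presence_matrix`.
#' @export
papaver_presence <- function(path = system.file("extdata",
                                                "papaver_presence.csv",
                                                package = "fusionclock")) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m[m == "+"] <- "detected"
  class(m) <- c("presence_matrix", class(m))
  m
}
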