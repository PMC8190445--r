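#' @import methods
#' @importFrom stats rbinom rgamma rnorm rpois runif plogis qnorm sd
#'   setNames approx update reformulate binomial vcov
#' @importFrom utils read.delim write.table
#' @useDynLib rohload, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GeneticMap: per-chromosome anchors from physical to genetic coordinates
#'
#' Holds the linkage-map anchors used to interpolate centimorgan positions
#' for markers that were not themselves linkage-mapped. Each chromosome
#' carries at least two anchors, ordered by physical position, with
#' non-decreasing genetic positions.
#'
#' @slot anchors data.frame with columns \code{chromosome}, \code{bp}
#'   (1-based physical position), \code{cm} (genetic position in
#'   centimorgan), sorted by chromosome then bp.
#'
#' @seealso [GeneticMap()], [interpolatePositions()], [totalMapLength()]
#' @export
setClass("GeneticMap", representation(anchors = "data.frame"))

setValidity("GeneticMap", function(object) {
  a <- object@anchors
  if (!all(c("chromosome", "bp", "cm") %in% names(a)))
    return("anchors must have columns chromosome, bp, cm")
  if (nrow(a) == 0L) return("map has no anchors")
  if (any(a$bp <= 0)) return("anchor bp must be positive")
  if (any(a$cm < 0)) return("anchor cm must be non-negative")
  for (chr in unique(a$chromosome)) {
    ai <- a[a$chromosome == chr, ]
    if (nrow(ai) < 2L)
      return(sprintf("chromosome %s has fewer than 2 anchors", chr))
    if (is.unsorted(ai$bp, strictly = TRUE))
      return(sprintf("chromosome %s anchors not strictly sorted by bp", chr))
    if (is.unsorted(ai$cm))
      return(sprintf("chromosome %s has decreasing cm", chr))
  }
  TRUE
})

#' Construct a GeneticMap
#'
#' @param anchors data.frame with columns \code{chromosome}, \code{bp},
#'   \code{cm}. Rows are sorted internally.
#' @return A [GeneticMap-class] object.
#' @examples
#' gm <- GeneticMap(data.frame(chromosome = "1", bp = c(100, 300), cm = c(3, 4)))
#' totalMapLength(gm)
#' @export
GeneticMap <- function(anchors) {
  anchors <- as.data.frame(anchors)
  anchors$chromosome <- as.character(anchors$chromosome)
  anchors <- anchors[order(anchors$chromosome, anchors$bp), , drop = FALSE]
  rownames(anchors) <- NULL
  new("GeneticMap", anchors = anchors)
}

setMethod("show", "GeneticMap", function(object) {
  a <- object@anchors
  cat("GeneticMap with", length(unique(a$chromosome)), "chromosome(s),",
      nrow(a), "anchors,", format(totalMapLength(object)), "cM total\n")
})

#' GenotypeMatrix: diploid calls over a cM-annotated marker table
#'
#' Genotypes are coded as allele dosage of the alternate (or derived)
#' allele: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, NA = missing. Markers are sorted by chromosome then cm.
#'
#' @slot calls integer matrix, individuals in rows, markers in columns.
#' @slot markers data.frame with columns \code{marker_id},
#'   \code{chromosome}, \code{bp}, \code{cm}.
#' @slot individuals character vector of individual ids (row order).
#'
#' @seealso [GenotypeMatrix()], [callRoh()]
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix", markers = "data.frame",
                        individuals = "character"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@markers
  if (!all(c("marker_id", "chromosome", "bp", "cm") %in% names(m)))
    return("markers must have columns marker_id, chromosome, bp, cm")
  if (ncol(object@calls) != nrow(m))
    return("ncol(calls) != nrow(markers)")
  if (nrow(object@calls) != length(object@individuals))
    return("nrow(calls) != length(individuals)")
  ok <- object@calls %in% c(0L, 1L, 2L) | is.na(object@calls)
  if (!all(ok)) return("calls must be 0, 1, 2 or NA")
  for (chr in unique(m$chromosome)) {
    if (is.unsorted(m$cm[m$chromosome == chr]))
      return(sprintf("markers on chromosome %s not sorted by cm", chr))
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls numeric/integer matrix (individuals x markers) with values
#'   0/1/2/NA.
#' @param markers data.frame with columns \code{marker_id},
#'   \code{chromosome}, \code{bp}, \code{cm}, one row per column of
#'   \code{calls}, sorted by chromosome then cm.
#' @param individuals character ids; defaults to rownames of \code{calls}
#'   or \code{ind_1 ... ind_n}.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, markers, individuals = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individuals)) {
    individuals <- rownames(calls)
    if (is.null(individuals)) individuals <- paste0("ind_", seq_len(nrow(calls)))
  }
  markers <- as.data.frame(markers)
  markers$chromosome <- as.character(markers$chromosome)
  rownames(markers) <- NULL
  new("GenotypeMatrix", calls = calls, markers = markers,
      individuals = as.character(individuals))
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", length(object@individuals), "individuals x",
      nrow(object@markers), "markers on",
      length(unique(object@markers$chromosome)), "chromosome(s)\n")
})

#' @describeIn GenotypeMatrix-class number of individuals and markers
#' @param x a GenotypeMatrix
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@calls))

#' Accessors for GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class]
#' @return \code{genotypeCalls}: the integer dosage matrix;
#'   \code{markerTable}: the marker data.frame; \code{individualIds}: the
#'   id vector.
#' @export
genotypeCalls <- function(x) x@calls

#' @rdname genotypeCalls
#' @export
markerTable <- function(x) x@markers

#' @rdname genotypeCalls
#' @export
individualIds <- function(x) x@individuals

#' SimResult: output of a forward Wright-Fisher simulation
#'
#' @slot genotypes a [GenotypeMatrix-class] of the final generation over
#'   segregating sites (dosage of the derived allele).
#' @slot mutations data.frame: \code{id}, \code{position_bp}, \code{s},
#'   \code{h}, \code{kind} ("neutral"/"deleterious"),
#'   \code{origin_generation}, \code{frequency} (population frequency in
#'   the final generation).
#' @slot trace integer vector of realized diploid population sizes, one
#'   per generation.
#' @slot seed the seed the run was started from.
#' @export
setClass("SimResult",
         representation(genotypes = "GenotypeMatrix", mutations = "data.frame",
                        trace = "integer", seed = "numeric"))

setValidity("SimResult", function(object) {
  mt <- object@mutations
  need <- c("id", "position_bp", "s", "h", "kind", "origin_generation",
            "frequency")
  if (!all(need %in% names(mt)))
    return(paste("mutations must have columns", paste(need, collapse = ", ")))
  if (nrow(mt) > 0) {
    if (any(mt$frequency <= 0 | mt$frequency >= 1))
      return("segregating frequencies must lie in (0,1)")
    if (any(mt$kind == "deleterious" & mt$s >= 0))
      return("deleterious mutations must have s < 0")
  }
  TRUE
})

setMethod("show", "SimResult", function(object) {
  mt <- object@mutations
  cat("SimResult:", nrow(object@genotypes@calls), "individuals,",
      nrow(mt), "segregating sites (",
      sum(mt$kind == "deleterious"), "deleterious ),",
      length(object@trace), "generations simulated\n")
})

#' @rdname genotypeCalls
#' @export
mutationTable <- function(x) x@mutations

#' @rdname genotypeCalls
#' @export
demographyTrace <- function(x) x@trace

#' SurvivalFit: fitted survival mixed model
#'
#' @slot coefficients data.frame with one row per fixed effect:
#'   \code{term}, \code{estimate} (log-odds scale), \code{lower},
#'   \code{upper} (95\% interval), \code{or}, \code{or_lower},
#'   \code{or_upper}, and \code{rhat} (NA for the likelihood backend).
#' @slot ranef_sd named numeric: group-level intercept SDs.
#' @slot backend "mcmc" or "glmer".
#' @slot converged logical; for MCMC, all Gelman-Rubin statistics < 1.1.
#' @slot n number of records used.
#' @export
setClass("SurvivalFit",
         representation(coefficients = "data.frame", ranef_sd = "numeric",
                        backend = "character", converged = "logical",
                        n = "integer"))

setMethod("show", "SurvivalFit", function(object) {
  cat("SurvivalFit (", object@backend, " backend, n = ", object@n,
      if (!object@converged) ", NOT CONVERGED" else "", ")\n", sep = "")
  print(object@coefficients, digits = 3, row.names = FALSE)
  cat("Group-level SDs:",
      paste(names(object@ranef_sd), round(object@ranef_sd, 3),
            sep = " = ", collapse = ", "), "\n")
})

#' @rdname genotypeCalls
#' @export
fixedEffects <- function(x) x@coefficients

#' @rdname genotypeCalls
#' @export
groupSd <- function(x) x@ranef_sd
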