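#' Read a linkage map from TSV
#'
#' Expects a tab-separated file with header columns \code{marker_id},
#' \code{chromosome}, \code{bp}, \code{cM} (case-insensitive for cM).
#'
#' @param path file path.
#' @return A [GeneticMap-class].
#' @export
readLinkageMap <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("chromosome", "bp", "cm") %in% names(tab)))
    stop("linkage map must have columns chromosome, bp, cM")
  GeneticMap(tab[, c("chromosome", "bp", "cm")])
}

#' Read marker positions from a PLINK .bim file
#'
#' @param path path to a text .bim file (chrom, marker_id, cm, bp,
#'   allele1, allele2; no header).
#' @return data.frame with columns \code{marker_id}, \code{chromosome},
#'   \code{bp}, \code{cm} (cm as stored, possibly 0 before
#'   interpolation), sorted by chromosome then bp.
#' @export
readBim <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop(".bim file must have at least 4 columns")
  out <- data.frame(marker_id = as.character(tab[[2]]),
                    chromosome = as.character(tab[[1]]),
                    bp = as.integer(tab[[4]]),
                    cm = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpolate genetic positions for unmapped markers
#'
#' Markers between two anchors get the linear interpolation (in bp) of the
#' flanking anchors' cM positions, i.e. a constant recombination rate is
#' assumed between anchors. Markers before the first anchor of a
#' chromosome get 0 cM; markers after the last anchor get the last
#' anchor's cM; markers between two anchors with equal cM get that cM; a
#' marker exactly at an anchor bp takes the anchor cM.
#'
#' @param map a [GeneticMap-class].
#' @param markers data.frame with columns \code{marker_id},
#'   \code{chromosome}, \code{bp} (a \code{cm} column, if present, is
#'   overwritten), sorted by chromosome then bp.
#' @return \code{markers} with the \code{cm} column filled.
#' @examples
#' gm <- GeneticMap(data.frame(chromosome = "1", bp = c(100, 300), cm = c(3, 4)))
#' mk <- data.frame(marker_id = "m1", chromosome = "1", bp = 200)
#' interpolatePositions(gm, mk)$cm  # 3.5
#' @export
interpolatePositions <- function(map, markers) {
  stopifnot(is(map, "GeneticMap"))
  markers <- as.data.frame(markers)
  markers$chromosome <- as.character(markers$chromosome)
  a <- map@anchors
  bad <- setdiff(unique(markers$chromosome), unique(a$chromosome))
  if (length(bad))
    stop("marker chromosome(s) absent from the map: ",
         paste(bad, collapse = ", "))
  cm <- numeric(nrow(markers))
  for (chr in unique(markers$chromosome)) {
    sel <- markers$chromosome == chr
    ai <- a[a$chromosome == chr, ]
    bp <- markers$bp[sel]
    # approx() with rule 2 carries the terminal cm beyond the last anchor;
    # positions before the first anchor are reset to 0 by convention.
    cmi <- approx(ai$bp, ai$cm, xout = bp, method = "linear",
                  ties = "ordered", rule = 2)$y
    cmi[bp < ai$bp[1L]] <- 0
    cm[sel] <- cmi
  }
  markers$cm <- cm
  markers
}

#' Expected ROH genetic length for a haplotype age
#'
#' An IBD segment whose underlying haplotypes coalesce \code{g}
#' generations ago has expected genetic length L = 100/(2g) cM, the basis
#' for the long/medium/short class boundaries (12.5 cM at g = 4, 1.5625 cM
#' at g = 32, 0.390625 cM at g = 128).
#'
#' @param g generations to the most recent common ancestor (> 0).
#' @return Expected length in cM.
#' @examples
#' expectedRohLength(25)  # 2 cM
#' @export
expectedRohLength <- function(g) {
  if (any(!is.finite(g)) || any(g <= 0)) stop("g must be positive")
  100 / (2 * g)
}

#' Expected time to MRCA for an ROH genetic length
#'
#' Inverse of [expectedRohLength()]: g = 100/(2L).
#'
#' @param length_cm segment genetic length in cM (> 0).
#' @return Expected generations to the MRCA.
#' @examples
#' expectedMrcaGenerations(0.390625)  # 128 generations
#' @export
expectedMrcaGenerations <- function(length_cm) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0))
    stop("length_cm must be positive")
  100 / (2 * length_cm)
}

#' Total genetic map length
#'
#' Sum over chromosomes of the terminal anchor cM. For the sex-averaged
#' autosomal map used throughout, this is 3146 cM.
#'
#' @param map a [GeneticMap-class].
#' @return Total length in cM.
#' @export
totalMapLength <- function(map) {
  stopifnot(is(map, "GeneticMap"))
  a <- map@anchors
  if (nrow(a) == 0L) stop("empty map")
  sum(tapply(a$cm, a$chromosome, max))
}

#' The autosomal genetic map length constant (cM)
#'
#' Total sex-averaged autosomal map length used as the F_ROH denominator.
#' @export
SOAY_MAP_LENGTH_CM <- 3146
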