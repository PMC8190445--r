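#' ROH detection parameters
#'
#' Defaults mirror a PLINK `--homozyg` run on cM-scaled coordinates
#' (cM x 1e6, so that 0.39 cM corresponds to the 390 "kb" threshold):
#' 25-SNP windows, at most 2 heterozygous and 2 missing calls per window,
#' at most 2 heterozygous calls per reported segment, minimum 25 SNPs and
#' 0.39 cM per segment, maximum gap 0.25 cM between adjacent markers, and
#' a maximum average spacing of 0.1 cM per SNP. `window_hit_threshold` is
#' the minimum fraction of windows covering a marker that must pass the
#' per-window limits for the marker to be part of a run (the detection
#' tool's default, 0.05).
#'
#' @param window_snps,min_snps,min_length_cm,max_gap_cm,max_avg_spacing_cm_per_snp,window_het,window_missing,segment_het,window_hit_threshold
#'   see Description.
#' @return A named list of class \code{RohParams}.
#' @export
rohParams <- function(window_snps = 25L, min_snps = 25L,
                      min_length_cm = 0.39, max_gap_cm = 0.25,
                      max_avg_spacing_cm_per_snp = 0.1,
                      window_het = 2L, window_missing = 2L,
                      segment_het = 2L, window_hit_threshold = 0.05) {
  p <- list(window_snps = as.integer(window_snps),
            min_snps = as.integer(min_snps),
            min_length_cm = min_length_cm, max_gap_cm = max_gap_cm,
            max_avg_spacing_cm_per_snp = max_avg_spacing_cm_per_snp,
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            segment_het = as.integer(segment_het),
            window_hit_threshold = window_hit_threshold)
  stopifnot(all(unlist(p) > 0 | c(rep(FALSE, 5), TRUE, TRUE, TRUE, FALSE)),
            p$window_hit_threshold > 0, p$window_hit_threshold <= 1)
  class(p) <- "RohParams"
  p
}

#' ROH length-class boundaries (cM)
#'
#' Class bounds follow the expected-length/haplotype-age correspondence
#' L = 100/(2g): short = [0.39, 1.56) cM (MRCA 32-128 generations),
#' medium = [1.56, 12.5] cM (4-32 generations), long = (12.5, Inf)
#' (up to 4 generations, i.e. recent close inbreeding).
#'
#' @param short_min_cm,medium_min_cm,long_min_cm strictly increasing
#'   boundaries.
#' @return Named list of class \code{RohClassBounds}.
#' @export
rohClassBounds <- function(short_min_cm = 0.39, medium_min_cm = 1.56,
                           long_min_cm = 12.5) {
  stopifnot(short_min_cm < medium_min_cm, medium_min_cm < long_min_cm)
  structure(list(short_min_cm = short_min_cm, medium_min_cm = medium_min_cm,
                 long_min_cm = long_min_cm), class = "RohClassBounds")
}

#' Scale cM positions to integer pseudo-coordinates
#'
#' All length/gap/density arithmetic in the caller runs on
#' \code{round(cm * 1e6)} so that thresholds expressed in cM map exactly
#' onto the kb-scale parameters of a physical-coordinate run.
#'
#' @param cm numeric vector of genetic positions.
#' @return integer-valued numeric vector of pseudo-positions.
#' @examples
#' scaleCmCoordinates(c(0.39, 0.25, 0))  # 390000 250000 0
#' @export
scaleCmCoordinates <- function(cm) round(cm * 1e6)

## Per-chromosome windowed detection on one call vector.
## g: integer dosage codes (0/1/2/NA) sorted by pos; pos: integer pseudo-cM.
.callRohChrom <- function(g, pos, p) {
  m <- length(g)
  W <- p$window_snps
  if (m < W) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  nW <- m - W + 1L
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  hit <- (cs_het[(W + 1L):(m + 1L)] - cs_het[1:nW]) <= p$window_het &
         (cs_mis[(W + 1L):(m + 1L)] - cs_mis[1:nW]) <= p$window_missing
  cs_hit <- c(0L, cumsum(hit))
  i <- seq_len(m)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, nW)
  hits_i <- cs_hit[hi + 1L] - cs_hit[lo]
  eligible <- hits_i / (hi - lo + 1L) >= p$window_hit_threshold - 1e-12

  min_len <- round(p$min_length_cm * 1e6)
  max_gap <- round(p$max_gap_cm * 1e6)
  max_density <- p$max_avg_spacing_cm_per_snp * 1e6

  segs <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    gap_brk <- if (length(run) > 1L) which(diff(pos[run]) > max_gap) else integer()
    sub_starts <- c(1L, gap_brk + 1L)
    sub_ends <- c(gap_brk, length(run))
    for (s in seq_along(sub_starts)) {
      idx <- run[sub_starts[s]:sub_ends[s]]
      segs <- c(segs, .trimAndFilter(idx, g, pos, p, min_len, max_density))
    }
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

## Edge-trim a marker-index interval so first/last calls are homozygous
## non-missing; returns NULL if none remain.
.edgeTrim <- function(idx, g) {
  hom <- which(!is.na(g[idx]) & g[idx] != 1L)
  if (!length(hom)) return(NULL)
  idx[hom[1L]:hom[length(hom)]]
}

## Split a run at every excess heterozygous call: walking left to right,
## the call that would be the (segment_het + 1)-th heterozygote closes
## the current piece just before it and opens the next just after it.
.splitAtExcessHets <- function(idx, g, k) {
  pieces <- list()
  cnt <- 0L
  start <- 1L
  for (j in seq_along(idx)) {
    if (!is.na(g[idx[j]]) && g[idx[j]] == 1L) {
      cnt <- cnt + 1L
      if (cnt > k) {
        if (start <= j - 1L)
          pieces[[length(pieces) + 1L]] <- idx[start:(j - 1L)]
        start <- j + 1L
        cnt <- 0L
      }
    }
  }
  if (start <= length(idx))
    pieces[[length(pieces) + 1L]] <- idx[start:length(idx)]
  pieces
}

## Apply the segment-level het allowance, edge-trim each piece to
## homozygous calls and apply the min-SNP / min-length / density filters.
.trimAndFilter <- function(idx, g, pos, p, min_len, max_density) {
  pieces <- .splitAtExcessHets(idx, g, p$segment_het)
  pieces <- lapply(pieces, .edgeTrim, g = g)
  pieces <- Filter(Negate(is.null), pieces)
  out <- list()
  for (ii in pieces) {
    n_snps <- length(ii)
    L <- pos[ii[n_snps]] - pos[ii[1L]]
    if (n_snps < p$min_snps) next
    if (L < min_len) next
    if (L / n_snps > max_density) next
    out[[length(out) + 1L]] <- data.frame(
      first = ii[1L], last = ii[n_snps], n_snps = n_snps,
      n_het = sum(!is.na(g[ii]) & g[ii] == 1L))
  }
  out
}

#' Call runs of homozygosity on genetic-map coordinates
#'
#' Windowed detection per individual and chromosome: every run of
#' \code{window_snps} consecutive markers forms a window; a window is a
#' hit if it contains at most \code{window_het} heterozygous and
#' \code{window_missing} missing calls; a marker is eligible when at least
#' a fraction \code{window_hit_threshold} of the windows covering it are
#' hits. Maximal runs of eligible markers are split at inter-marker gaps
#' larger than \code{max_gap_cm}, reduced (by splitting at excess
#' heterozygous calls) until at most \code{segment_het} heterozygous calls
#' remain per segment, edge-trimmed to homozygous calls, and finally
#' filtered on \code{min_snps}, \code{min_length_cm} and the average
#' marker spacing. Spans are measured first-to-last marker on integer
#' pseudo-coordinates (see [scaleCmCoordinates()]).
#'
#' @param genotypes a [GenotypeMatrix-class] with cm filled.
#' @param params a [rohParams()] list.
#' @return data.frame of segments: \code{individual}, \code{chromosome},
#'   \code{start_cm}, \code{end_cm}, \code{length_cm}, \code{n_snps},
#'   \code{n_het}, \code{snp1}, \code{snp2}; zero rows if none found.
#' @export
callRoh <- function(genotypes, params = rohParams()) {
  stopifnot(is(genotypes, "GenotypeMatrix"), inherits(params, "RohParams"))
  mk <- genotypes@markers
  calls <- genotypes@calls
  res <- list()
  for (chr in unique(mk$chromosome)) {
    sel <- which(mk$chromosome == chr)
    cmv <- mk$cm[sel]
    if (is.unsorted(cmv)) stop("markers not sorted by cm on chromosome ", chr)
    pos <- scaleCmCoordinates(cmv)
    for (r in seq_len(nrow(calls))) {
      segs <- .callRohChrom(calls[r, sel], pos, params)
      if (is.null(segs)) next
      res[[length(res) + 1L]] <- data.frame(
        individual = genotypes@individuals[r],
        chromosome = chr,
        start_cm = pos[segs$first] / 1e6,
        end_cm = pos[segs$last] / 1e6,
        length_cm = (pos[segs$last] - pos[segs$first]) / 1e6,
        n_snps = segs$n_snps, n_het = segs$n_het,
        snp1 = mk$marker_id[sel[segs$first]],
        snp2 = mk$marker_id[sel[segs$last]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(individual = character(), chromosome = character(),
                      start_cm = numeric(), end_cm = numeric(),
                      length_cm = numeric(), n_snps = integer(),
                      n_het = integer(), snp1 = character(),
                      snp2 = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$individual, out$chromosome, out$start_cm), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign length classes to ROH segments
#'
#' Boundary convention: short = [0.39, 1.56) cM, medium = [1.56, 12.5] cM,
#' long = (12.5, Inf) cM, so every segment has exactly one class.
#'
#' @param segments data.frame from [callRoh()].
#' @param bounds a [rohClassBounds()] list.
#' @return \code{segments} with a \code{length_class} factor column
#'   (levels short, medium, long).
#' @export
classifySegments <- function(segments, bounds = rohClassBounds()) {
  if (nrow(segments) &&
      any(segments$length_cm < bounds$short_min_cm - 1e-9))
    stop("segment shorter than the minimum class boundary")
  cls <- ifelse(segments$length_cm > bounds$long_min_cm, "long",
                ifelse(segments$length_cm >= bounds$medium_min_cm,
                       "medium", "short"))
  segments$length_class <- factor(cls, levels = c("short", "medium", "long"))
  segments
}

#' Per-individual length-class inbreeding coefficients F_ROH
#'
#' F for a class is the summed genetic length of that individual's
#' segments in the class divided by the total autosomal map length
#' (default 3146 cM); \code{f_total} uses all segments. Individuals with
#' no segments get F = 0 and a missing mean length.
#'
#' @param segments classified segments (see [classifySegments()]).
#' @param total_map_cm denominator in cM.
#' @param individuals optional character vector of ids to report (so that
#'   segment-free individuals appear with zero F); defaults to the ids
#'   present in \code{segments}.
#' @return data.frame: \code{individual}, \code{f_long}, \code{f_medium},
#'   \code{f_short}, \code{f_total}, \code{mean_roh_length_cm}.
#' @export
computeFroh <- function(segments, total_map_cm = SOAY_MAP_LENGTH_CM,
                        individuals = NULL) {
  stopifnot(total_map_cm > 0)
  if (nrow(segments) && any(segments$length_cm < 0))
    stop("negative segment length")
  if (nrow(segments) && is.null(segments$length_class))
    stop("segments must be classified first")
  if (is.null(individuals)) individuals <- unique(segments$individual)
  sumClass <- function(id, cls) {
    s <- segments$individual == id & segments$length_class == cls
    sum(segments$length_cm[s])
  }
  out <- data.frame(individual = individuals, stringsAsFactors = FALSE)
  out$f_long <- vapply(individuals, sumClass, 0, cls = "long") / total_map_cm
  out$f_medium <- vapply(individuals, sumClass, 0, cls = "medium") / total_map_cm
  out$f_short <- vapply(individuals, sumClass, 0, cls = "short") / total_map_cm
  out$f_total <- out$f_long + out$f_medium + out$f_short
  out$mean_roh_length_cm <- vapply(individuals, function(id) {
    s <- segments$length_cm[segments$individual == id]
    if (length(s)) mean(s) else NA_real_
  }, 0)
  rownames(out) <- NULL
  out
}

#' Write / read ROH segment tables
#'
#' The TSV layout follows the PLINK .hom convention (IID, CHR, SNP1, SNP2,
#' POS1, POS2, KB, NSNP, NHET) with positions in pseudo-bp (cM x 1e6), KB
#' = cM x 1000, plus a \code{length_class} column when present.
#'
#' @param segments segment data.frame.
#' @param path file path.
#' @return \code{readRohTable} returns the segment data.frame.
#' @export
writeRohTable <- function(segments, path) {
  tab <- data.frame(IID = segments$individual, CHR = segments$chromosome,
                    SNP1 = segments$snp1, SNP2 = segments$snp2,
                    POS1 = scaleCmCoordinates(segments$start_cm),
                    POS2 = scaleCmCoordinates(segments$end_cm),
                    KB = segments$length_cm * 1000,
                    NSNP = segments$n_snps, NHET = segments$n_het)
  if (!is.null(segments$length_class))
    tab$length_class <- as.character(segments$length_class)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRohTable
#' @export
readRohTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(individual = as.character(tab$IID),
                    chromosome = as.character(tab$CHR),
                    start_cm = tab$POS1 / 1e6, end_cm = tab$POS2 / 1e6,
                    length_cm = (tab$POS2 - tab$POS1) / 1e6,
                    n_snps = tab$NSNP, n_het = tab$NHET,
                    snp1 = as.character(tab$SNP1),
                    snp2 = as.character(tab$SNP2),
                    stringsAsFactors = FALSE)
  if (!is.null(tab$length_class))
    out$length_class <- factor(tab$length_class,
                               levels = c("short", "medium", "long"))
  out
}
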