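#' Deleterious mutations falling inside ROH segments
#'
#' For every called segment, finds the deleterious mutations whose
#' position lies within the segment span (closed interval) and for which
#' the individual is homozygous for the deleterious allele. ROH are taken
#' as IBD tracts, so heterozygous deleterious calls inside a segment are
#' not counted by default; set \code{homozygous_only = FALSE} to count any
#' carried copy instead. Segment coordinates are cM, mutation positions
#' bp; the two are matched through the 1 Mb = 1 cM pseudo-coordinate map
#' (cm x 1e6).
#'
#' @param genotypes a [GenotypeMatrix-class] (dosage of the derived
#'   allele) covering the mutation positions.
#' @param segments classified segment data.frame from
#'   [classifySegments()].
#' @param mutations mutation table (see [SimResult-class]).
#' @param homozygous_only count only dosage-2 mutations (default TRUE).
#' @return data.frame with one row per (segment, mutation) hit:
#'   \code{individual}, \code{length_class}, \code{segment_row},
#'   \code{mutation_id}, \code{s}, \code{frequency}.
#' @export
mutationsInRoh <- function(genotypes, segments, mutations,
                           homozygous_only = TRUE) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  if (nrow(segments) && is.null(segments$length_class))
    stop("segments must be classified first")
  del <- mutations[mutations$kind == "deleterious", , drop = FALSE]
  mk <- genotypes@markers
  col_of <- match(del$position_bp, mk$bp)
  if (nrow(del) && anyNA(col_of))
    stop("mutation positions absent from the genotype marker table; ",
         "coordinate spaces do not match")
  out <- list()
  start_pp <- scaleCmCoordinates(segments$start_cm)
  end_pp <- scaleCmCoordinates(segments$end_cm)
  for (k in seq_len(nrow(segments))) {
    ind <- segments$individual[k]
    r <- match(ind, genotypes@individuals)
    if (is.na(r)) stop("segment individual not in genotype matrix: ", ind)
    inside <- del$position_bp >= start_pp[k] & del$position_bp <= end_pp[k]
    if (!any(inside)) next
    dos <- genotypes@calls[r, col_of[inside]]
    keep <- if (homozygous_only) !is.na(dos) & dos == 2L else
      !is.na(dos) & dos >= 1L
    if (!any(keep)) next
    hit <- del[inside, , drop = FALSE][keep, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      individual = ind, length_class = as.character(segments$length_class[k]),
      segment_row = k, mutation_id = hit$id, s = hit$s,
      frequency = hit$frequency, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(individual = character(), length_class = character(),
                      segment_row = integer(), mutation_id = integer(),
                      s = numeric(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-individual, per-class mutation-load statistics
#'
#' For each individual and ROH length class with at least one segment:
#' \describe{
#'   \item{load_per_cm}{sum of selection coefficients of the counted
#'     deleterious mutations in that class divided by the summed cM
#'     length of the class's segments (the expected fitness decline per
#'     cM of ROH, <= 0);}
#'   \item{count_per_cm}{number of counted mutations per cM;}
#'   \item{mean_allele_frequency}{unweighted mean population frequency of
#'     the counted mutations (each counted once per
#'     individual-occurrence), missing when no mutations were counted.}
#' }
#' Individuals without segments of a class are omitted for that class
#' ("per cM of ROH" is undefined without ROH).
#'
#' @inheritParams mutationsInRoh
#' @return data.frame: \code{individual}, \code{length_class},
#'   \code{total_cm}, \code{n_mutations}, \code{load_per_cm},
#'   \code{count_per_cm}, \code{mean_allele_frequency}.
#' @export
rohLoadStats <- function(genotypes, segments, mutations,
                         homozygous_only = TRUE) {
  hits <- mutationsInRoh(genotypes, segments, mutations, homozygous_only)
  classes <- c("short", "medium", "long")
  out <- list()
  for (ind in unique(segments$individual)) {
    for (cls in classes) {
      sel <- segments$individual == ind & segments$length_class == cls
      tot <- sum(segments$length_cm[sel])
      if (tot <= 0) next
      hs <- hits[hits$individual == ind & hits$length_class == cls, ,
                 drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        individual = ind, length_class = cls, total_cm = tot,
        n_mutations = nrow(hs),
        load_per_cm = sum(hs$s) / tot,
        count_per_cm = nrow(hs) / tot,
        mean_allele_frequency = if (nrow(hs)) mean(hs$frequency) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(individual = character(), length_class = character(),
                      total_cm = numeric(), n_mutations = integer(),
                      load_per_cm = numeric(), count_per_cm = numeric(),
                      mean_allele_frequency = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$length_class <- factor(res$length_class, levels = classes)
  res
}

#' Replicate-level summary of load statistics
#'
#' Class means of the per-individual statistics (over individuals with a
#' defined value) plus percent contrasts against the long class:
#' contrast(A vs long) = 100 * (1 - mean_A / mean_long), for the load and
#' count statistics. Contrasts are missing when either class mean is
#' undefined.
#'
#' @param stats output of [rohLoadStats()].
#' @param replicate optional replicate identifier carried through.
#' @return one-row data.frame: per-class means
#'   (\code{load_<class>}, \code{count_<class>}, \code{freq_<class>}),
#'   \code{load_contrast_medium}, \code{load_contrast_short},
#'   \code{count_contrast_medium}, \code{count_contrast_short}.
#' @export
summarizeReplicate <- function(stats, replicate = NA) {
  classes <- c("short", "medium", "long")
  m <- function(col, cls) {
    v <- stats[[col]][stats$length_class == cls]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  load <- setNames(vapply(classes, m, 0, col = "load_per_cm"), classes)
  cnt <- setNames(vapply(classes, m, 0, col = "count_per_cm"), classes)
  frq <- setNames(vapply(classes, m, 0, col = "mean_allele_frequency"),
                  classes)
  contrast <- function(x, cls) {
    if (is.na(x[[cls]]) || is.na(x[["long"]]) || x[["long"]] == 0)
      return(NA_real_)
    100 * (1 - x[[cls]] / x[["long"]])
  }
  data.frame(replicate = replicate,
             load_short = load[["short"]], load_medium = load[["medium"]],
             load_long = load[["long"]],
             count_short = cnt[["short"]], count_medium = cnt[["medium"]],
             count_long = cnt[["long"]],
             freq_short = frq[["short"]], freq_medium = frq[["medium"]],
             freq_long = frq[["long"]],
             load_contrast_medium = contrast(load, "medium"),
             load_contrast_short = contrast(load, "short"),
             count_contrast_medium = contrast(cnt, "medium"),
             count_contrast_short = contrast(cnt, "short"))
}

#' Simulate, call ROH and summarize load, over replicates
#'
#' Convenience harness for the simulation study: runs
#' [runSimulation()] under the Soay demography for each replicate
#' sub-seed, calls ROH on the simulated genotypes with the standard
#' parameters, classifies segments, computes per-individual load
#' statistics and returns the per-replicate summaries.
#'
#' @param n_replicates number of replicates.
#' @param seed master seed; replicate r uses \code{seed + r - 1}.
#' @param dfe,genome,demography simulation configurations.
#' @param rescale rescaling factor Q (default 10 for desk-scale runs).
#' @param params,bounds ROH caller settings.
#' @param homozygous_only see [mutationsInRoh()].
#' @return data.frame of [summarizeReplicate()] rows, one per replicate.
#' @export
simulateLoadStudy <- function(n_replicates = 20, seed,
                              dfe = dfeConfig(), genome = genomeConfig(),
                              demography = soayDemography(), rescale = 10,
                              params = rohParams(),
                              bounds = rohClassBounds(),
                              homozygous_only = TRUE) {
  if (missing(seed)) stop("seed is required")
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- runSimulation(demography, dfe, genome, seed = seed + r - 1,
                         rescale = rescale)
    segs <- classifySegments(callRoh(sim@genotypes, params), bounds)
    st <- rohLoadStats(sim@genotypes, segs, sim@mutations, homozygous_only)
    out[[r]] <- summarizeReplicate(st, replicate = r)
  }
  do.call(rbind, out)
}
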