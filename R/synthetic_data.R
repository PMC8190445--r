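#' Generate a synthetic survival cohort with known effect sizes
#'
#' Draws per-individual length-class inbreeding coefficients with the
#' study-population means (f_long right-skewed and zero-inflated with
#' mean 0.013; f_medium and f_short truncated-normal with means 0.213 and
#' 0.107), assigns sex, twin status, birth year and mother (mothers
#' nested within years), draws Normal random intercepts per year and
#' mother, and generates Bernoulli survival from the logit model
#' b0 + 100 f_long b1 + 100 f_medium b2 + 100 f_short b3 + sex b4 +
#' twin b5 + a_year + a_mother. The default coefficients b1..b3 are the
#' logs of the odds ratios 0.876, 0.923 and 0.977 per 1% of genome; the
#' intercept default gives an overall first-year survival around 0.57.
#'
#' @param n cohort size (default 4879).
#' @param beta named numeric: \code{intercept}, \code{f_long},
#'   \code{f_medium}, \code{f_short} (per 1\% of genome), \code{sex},
#'   \code{twin}.
#' @param mean_f_long,mean_f_medium,mean_f_short target means.
#' @param zero_p_long zero-inflation probability of f_long.
#' @param shape_long gamma shape of non-zero f_long.
#' @param sd_f_medium,sd_f_short dispersion of the truncated normals.
#' @param sd_birth_year,sd_mother_id random-intercept SDs.
#' @param n_birth_years,mothers_per_year grouping structure (defaults 39
#'   years x 29 mothers, close to the study's 39 years and 1118 mothers).
#' @param twin_p,male_p Bernoulli probabilities for twin status and sex.
#' @param seed integer seed (required).
#' @return list with \code{records} (data.frame of survival records
#'   with id, survived, sex, twin, birth_year, mother_id, f_long,
#'   f_medium, f_short, f_total) and \code{truth} (the generating
#'   coefficients and latent intercept draws).
#' @export
generateCohort <- function(n = 4879,
                           beta = c(intercept = 2.6,
                                    f_long = log(0.876),
                                    f_medium = log(0.923),
                                    f_short = log(0.977),
                                    sex = -0.2, twin = -0.5),
                           mean_f_long = 0.013, mean_f_medium = 0.213,
                           mean_f_short = 0.107, zero_p_long = 0.3,
                           shape_long = 0.8, sd_f_medium = 0.035,
                           sd_f_short = 0.02, sd_birth_year = 0.3,
                           sd_mother_id = 0.3, n_birth_years = 39,
                           mothers_per_year = 29, twin_p = 0.15,
                           male_p = 0.5, seed) {
  if (missing(seed)) stop("seed is required")
  if (mean_f_long + mean_f_medium + mean_f_short > 1)
    stop("infeasible F means (sum > 1)")
  set.seed(seed)
  nz <- runif(n) >= zero_p_long
  f_long <- ifelse(nz,
    rgamma(n, shape = shape_long,
           scale = mean_f_long / (1 - zero_p_long) / shape_long), 0)
  f_medium <- pmax(0, rnorm(n, mean_f_medium, sd_f_medium))
  f_short <- pmax(0, rnorm(n, mean_f_short, sd_f_short))
  f_long <- pmin(f_long, 1)
  tot <- f_long + f_medium + f_short
  over <- tot > 1
  if (any(over)) {  # rare: renormalise so the classes cannot exceed the map
    f_long[over] <- f_long[over] / tot[over]
    f_medium[over] <- f_medium[over] / tot[over]
    f_short[over] <- f_short[over] / tot[over]
  }
  sex <- rbinom(n, 1, male_p)
  twin <- rbinom(n, 1, twin_p)
  birth_year <- sample.int(n_birth_years, n, replace = TRUE)
  mother_within <- sample.int(mothers_per_year, n, replace = TRUE)
  mother_id <- (birth_year - 1L) * mothers_per_year + mother_within
  a_year <- rnorm(n_birth_years, 0, sd_birth_year)
  a_mother <- rnorm(n_birth_years * mothers_per_year, 0, sd_mother_id)
  lp <- beta[["intercept"]] + 100 * f_long * beta[["f_long"]] +
    100 * f_medium * beta[["f_medium"]] + 100 * f_short * beta[["f_short"]] +
    sex * beta[["sex"]] + twin * beta[["twin"]] +
    a_year[birth_year] + a_mother[mother_id]
  survived <- rbinom(n, 1, plogis(lp))
  records <- data.frame(id = paste0("ind_", seq_len(n)), survived = survived,
                        sex = sex, twin = twin, birth_year = birth_year,
                        mother_id = mother_id, f_long = f_long,
                        f_medium = f_medium, f_short = f_short,
                        f_total = f_long + f_medium + f_short,
                        stringsAsFactors = FALSE)
  list(records = records,
       truth = list(beta = beta, a_year = a_year, a_mother = a_mother,
                    sd_birth_year = sd_birth_year,
                    sd_mother_id = sd_mother_id, seed = seed))
}

#' Generate a genotype fixture with planted homozygous segments
#'
#' Builds a single-chromosome marker map of equally spaced markers,
#' plants non-overlapping homozygous segments of known span per
#' individual (optionally contaminated with a fixed number of interior
#' heterozygous calls), and fills the background with random genotypes at
#' the given heterozygosity and missingness rates. The truth table
#' records every planted segment's exact marker range and cM span, so
#' caller sensitivity and span recovery can be scored exactly.
#'
#' @param n_individuals number of individuals.
#' @param n_markers markers on the chromosome.
#' @param spacing_cm inter-marker spacing in cM.
#' @param segments_per_individual planted segments per individual.
#' @param segment_markers markers per planted segment.
#' @param segment_het interior heterozygous contaminations per segment.
#' @param background_het background heterozygosity rate outside plants.
#' @param missing_rate missing-call rate outside plants.
#' @param seed integer seed (required).
#' @return list with \code{genotypes} (a [GenotypeMatrix-class]) and
#'   \code{truth} (data.frame: individual, chromosome, start_cm, end_cm,
#'   length_cm, n_markers, n_het).
#' @export
generateGenotypeFixture <- function(n_individuals = 10, n_markers = 1000,
                                    spacing_cm = 0.05,
                                    segments_per_individual = 1,
                                    segment_markers = 100, segment_het = 0,
                                    background_het = 0.5, missing_rate = 0,
                                    seed) {
  if (missing(seed)) stop("seed is required")
  if (segment_markers > n_markers)
    stop("planted segment exceeds the marker map span")
  set.seed(seed)
  cm <- (seq_len(n_markers) - 1L) * spacing_cm
  mk <- data.frame(marker_id = paste0("m_", seq_len(n_markers)),
                   chromosome = "1", bp = as.integer(round(cm * 1e6)) + 1L,
                   cm = cm, stringsAsFactors = FALSE)
  calls <- matrix(NA_integer_, n_individuals, n_markers)
  truth <- list()
  for (i in seq_len(n_individuals)) {
    g <- ifelse(runif(n_markers) < background_het, 1L,
                ifelse(runif(n_markers) < 0.5, 0L, 2L))
    if (missing_rate > 0)
      g[runif(n_markers) < missing_rate] <- NA_integer_
    taken <- rep(FALSE, n_markers)
    for (k in seq_len(segments_per_individual)) {
      ok <- FALSE
      for (try in 1:100) {
        st <- sample.int(n_markers - segment_markers + 1L, 1L)
        idx <- st:(st + segment_markers - 1L)
        if (!any(taken[idx])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place non-overlapping planted segments")
      taken[idx] <- TRUE
      g[idx] <- ifelse(runif(segment_markers) < 0.5, 0L, 2L)
      nhet <- min(segment_het, max(0L, segment_markers - 2L))
      if (nhet > 0) {
        hp <- sample(idx[-c(1L, length(idx))], nhet)
        g[hp] <- 1L
      }
      truth[[length(truth) + 1L]] <- data.frame(
        individual = paste0("ind_", i), chromosome = "1",
        start_cm = cm[idx[1L]], end_cm = cm[idx[length(idx)]],
        length_cm = cm[idx[length(idx)]] - cm[idx[1L]],
        n_markers = segment_markers, n_het = nhet,
        stringsAsFactors = FALSE)
    }
    calls[i, ] <- g
  }
  list(genotypes = GenotypeMatrix(calls, mk,
                                  paste0("ind_", seq_len(n_individuals))),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame())
}

#' Generate a random linkage-map fixture
#'
#' Anchors are placed at random physical positions with monotone
#' increasing cM (first anchor at 0 cM, last at \code{length_cm}), and a
#' denser set of unmapped markers is drawn for interpolation testing.
#'
#' @param n_chrom number of chromosomes.
#' @param length_cm genetic length per chromosome.
#' @param n_anchors anchors per chromosome (>= 2).
#' @param n_markers unmapped markers per chromosome.
#' @param span_bp physical span per chromosome.
#' @param seed integer seed (required).
#' @return list with \code{map} (a [GeneticMap-class]) and
#'   \code{markers} (data.frame marker_id, chromosome, bp).
#' @export
generateMapFixture <- function(n_chrom = 1, length_cm = 100, n_anchors = 20,
                               n_markers = 200, span_bp = 1e6, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_anchors >= 2, length_cm > 0, n_markers > 0)
  set.seed(seed)
  anchors <- list()
  markers <- list()
  for (ch in seq_len(n_chrom)) {
    bp <- sort(sample.int(span_bp, n_anchors))
    cmv <- c(0, sort(runif(n_anchors - 2L, 0, length_cm)), length_cm)
    anchors[[ch]] <- data.frame(chromosome = as.character(ch), bp = bp,
                                cm = cmv, stringsAsFactors = FALSE)
    mbp <- sort(sample.int(span_bp, n_markers))
    markers[[ch]] <- data.frame(
      marker_id = paste0("c", ch, "_m", seq_len(n_markers)),
      chromosome = as.character(ch), bp = mbp, stringsAsFactors = FALSE)
  }
  list(map = GeneticMap(do.call(rbind, anchors)),
       markers = do.call(rbind, markers))
}
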