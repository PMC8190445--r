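#' Demography, genome and DFE configurations
#'
#' `demographyConfig()` describes a stepwise history: constant-size
#' epochs, optionally followed by an instantaneous crash, an exponential
#' recovery, and a terminal constant phase. `soayDemography()` returns the
#' island history used throughout: an ancestral size of 1000 diploids for
#' 10,000 generations, 200 for 970 generations, a crash to 10 at
#' generation 10,970 (0-based), exponential recovery to 200 within 20
#' generations, and 200 until generation 10,999 (11,000 generations in
#' total).
#'
#' @param epochs data.frame with columns \code{n} (diploid size) and
#'   \code{duration} (generations).
#' @param size_at_crash,recovery_generations,recovered_size,post_generations
#'   optional terminal bottleneck-recovery phase: one generation at
#'   \code{size_at_crash}, then N(t) = round(crash * (recovered/crash)^
#'   (t/recovery_generations)) for t = 1..recovery_generations, then
#'   \code{post_generations} more generations at \code{recovered_size}.
#' @return list of class \code{DemographyConfig}.
#' @export
demographyConfig <- function(epochs, size_at_crash = NULL,
                             recovery_generations = NULL,
                             recovered_size = NULL, post_generations = 0L) {
  epochs <- as.data.frame(epochs)
  stopifnot(all(epochs$n >= 2), all(epochs$duration >= 1))
  cfg <- list(epochs = epochs, size_at_crash = size_at_crash,
              recovery_generations = recovery_generations,
              recovered_size = recovered_size,
              post_generations = as.integer(post_generations))
  class(cfg) <- "DemographyConfig"
  cfg
}

#' @rdname demographyConfig
#' @export
soayDemography <- function() {
  # the last recovery generation already sits at 200, so 9 further
  # generations complete the final 10 generations at the recovered size
  demographyConfig(data.frame(n = c(1000, 200), duration = c(10000, 970)),
                   size_at_crash = 10, recovery_generations = 20,
                   recovered_size = 200, post_generations = 9)
}

#' Realized population size per generation
#'
#' @param demography a [demographyConfig()].
#' @return integer vector of diploid sizes, one per generation
#'   (generation index 0-based: element \code{g + 1} is generation
#'   \code{g}).
#' @examples
#' tr <- demographySizes(soayDemography())
#' tr[10970]  # generation 10,969: 200
#' tr[10971]  # generation 10,970: crash to 10
#' tr[10991]  # generation 10,990: recovered to 200
#' @export
demographySizes <- function(demography) {
  stopifnot(inherits(demography, "DemographyConfig"))
  tr <- unlist(mapply(rep, demography$epochs$n, demography$epochs$duration,
                      SIMPLIFY = FALSE))
  if (!is.null(demography$size_at_crash)) {
    c0 <- demography$size_at_crash
    r <- demography$recovered_size
    rg <- demography$recovery_generations
    rec <- round(c0 * (r / c0)^(seq_len(rg) / rg))
    tr <- c(tr, c0, rec, rep(r, demography$post_generations))
  }
  as.integer(tr)
}

#' @rdname demographyConfig
#' @param length_bp,recombination_rate,mutation_rate genome length and
#'   per-bp per-generation rates. With the defaults (100 Mb, both rates
#'   1e-8) physical distance in Mb equals genetic distance in cM.
#' @export
genomeConfig <- function(length_bp = 1e8, recombination_rate = 1e-8,
                         mutation_rate = 1e-8) {
  stopifnot(length_bp > 0, recombination_rate > 0, mutation_rate > 0)
  structure(list(length_bp = length_bp,
                 recombination_rate = recombination_rate,
                 mutation_rate = mutation_rate), class = "GenomeConfig")
}

#' @rdname demographyConfig
#' @param mean_s mean selection coefficient of new deleterious mutations
#'   (negative); draws come from a gamma distribution with this mean and
#'   \code{shape}, negated.
#' @param shape gamma shape parameter.
#' @param h dominance coefficient of deleterious mutations (0 = fully
#'   recessive).
#' @param p_deleterious fraction of new mutations that are deleterious;
#'   the rest are neutral (s = 0).
#' @export
dfeConfig <- function(mean_s = -0.03, shape = 0.2, h = 0.05,
                      p_deleterious = 0.7) {
  stopifnot(mean_s < 0, shape > 0, h >= 0, h <= 1,
            p_deleterious >= 0, p_deleterious <= 1)
  structure(list(mean_s = mean_s, shape = shape, h = h,
                 p_deleterious = p_deleterious), class = "DFEConfig")
}

#' Draw selection coefficients from the deleterious DFE
#'
#' @param n number of draws.
#' @param dfe a [dfeConfig()].
#' @return numeric vector of n negative selection coefficients (gamma
#'   with mean \code{|mean_s|} and shape \code{shape}, negated).
#' @export
sampleDfe <- function(n, dfe = dfeConfig()) {
  stopifnot(inherits(dfe, "DFEConfig"), n >= 0)
  if (n == 0) return(numeric())
  -rgamma(n, shape = dfe$shape, scale = abs(dfe$mean_s) / dfe$shape)
}

#' Multiplicative relative fitness of a diploid genotype
#'
#' A mutation contributes a factor 1 + s when homozygous and 1 + h*s when
#' heterozygous; fitness is the product over loci, clamped below at 0.
#'
#' @param dosage integer vector of derived-allele dosages (0/1/2).
#' @param s,h selection and dominance coefficients per locus.
#' @return scalar relative fitness.
#' @examples
#' genomeFitness(2, -0.03, 0)        # 0.97
#' genomeFitness(1, -0.03, 0.05)     # 0.9985
#' @export
genomeFitness <- function(dosage, s, h) {
  stopifnot(length(s) == length(dosage), length(h) == length(dosage))
  f <- ifelse(dosage == 2, 1 + s, ifelse(dosage == 1, 1 + h * s, 1))
  # a non-positive factor is lethal regardless of the other loci
  if (any(f <= 0)) return(0)
  prod(f)
}

#' Rescale a simulation configuration by a factor Q
#'
#' Standard population rescaling for desk-scale runs: sizes N -> N/Q
#' (rounded, floor 2), epoch durations -> duration/Q (rounded up),
#' mutation and recombination rates -> rate * Q, and mean_s -> mean_s * Q,
#' so that the population-scaled products N*mu, N*r and N*s are preserved.
#'
#' @param demography,genome,dfe configurations to rescale.
#' @param Q scaling factor >= 1.
#' @return list with rescaled \code{demography}, \code{genome},
#'   \code{dfe}.
#' @export
rescaleConfig <- function(demography, genome, dfe, Q) {
  stopifnot(Q >= 1)
  if (Q == 1) return(list(demography = demography, genome = genome, dfe = dfe))
  ep <- demography$epochs
  ep$n <- pmax(2L, round(ep$n / Q))
  ep$duration <- ceiling(ep$duration / Q)
  d2 <- demography
  d2$epochs <- ep
  if (!is.null(d2$size_at_crash)) {
    d2$size_at_crash <- max(2L, round(d2$size_at_crash / Q))
    d2$recovered_size <- max(2L, round(d2$recovered_size / Q))
    d2$recovery_generations <- ceiling(d2$recovery_generations / Q)
    d2$post_generations <- as.integer(ceiling(d2$post_generations / Q))
  }
  g2 <- genome
  g2$mutation_rate <- genome$mutation_rate * Q
  g2$recombination_rate <- genome$recombination_rate * Q
  f2 <- dfe
  f2$mean_s <- dfe$mean_s * Q
  list(demography = d2, genome = g2, dfe = f2)
}

#' Run a forward Wright-Fisher simulation
#'
#' Each generation, offspring choose two parents with probability
#' proportional to multiplicative fitness (monoecious, selfing allowed);
#' each transmitted haplotype recombines with Poisson(r * L) crossovers at
#' uniform positions and acquires Poisson(mu * L) new mutations, each
#' deleterious with probability \code{p_deleterious} (s from the gamma
#' DFE, dominance \code{h}) and neutral otherwise. Fixed mutations are
#' dropped from the segregating set. The final generation is returned
#' over segregating sites only, with marker genetic positions assigned by
#' the unrescaled 1 Mb = 1 cM map (cm = bp * 1e-6).
#'
#' @param demography a [demographyConfig()] (default [soayDemography()]).
#' @param dfe a [dfeConfig()].
#' @param genome a [genomeConfig()].
#' @param seed integer seed (required; all randomness flows from it).
#' @param rescale optional rescaling factor Q (see [rescaleConfig()] and
#'   \code{rescale_mode}).
#' @param rescale_mode how Q is applied. \code{"ancestral"} (the default,
#'   staged rescaling) rescales only the first epoch — the deep burn-in,
#'   where rescaling is a good approximation — and runs the remaining
#'   epochs and the bottleneck-recovery phase at full size and rates; at
#'   the seam the standing selection coefficients are divided by Q
#'   (rescaling preserves N*s, so this hands over an equilibrium with the
#'   correct joint frequency/N*s structure). \code{"uniform"} rescales
#'   every epoch; note that uniform rescaling compresses the recent
#'   timescale, so haplotype ages below Q generations — and hence the
#'   longest ROH classes — cannot be represented.
#' @return A [SimResult-class].
#' @export
runSimulation <- function(demography = soayDemography(), dfe = dfeConfig(),
                          genome = genomeConfig(), seed, rescale = NULL,
                          rescale_mode = c("ancestral", "uniform")) {
  if (missing(seed)) stop("seed is required for reproducibility")
  rescale_mode <- match.arg(rescale_mode)
  Q <- if (is.null(rescale)) 1 else rescale
  stopifnot(Q >= 1)
  seam_gen <- 0L
  if (Q > 1 && rescale_mode == "uniform") {
    cfg <- rescaleConfig(demography, genome, dfe, Q)
    demography <- cfg$demography; genome <- cfg$genome; dfe <- cfg$dfe
    Q <- 1  # fully applied; per-generation rates are now constant
  }
  if (Q > 1) {  # staged: rescale the first (ancestral) epoch only
    ep <- demography$epochs
    anc_n <- max(2L, round(ep$n[1] / Q))
    anc_dur <- as.integer(ceiling(ep$duration[1] / Q))
    rest <- demography
    rest$epochs <- ep[-1, , drop = FALSE]
    rest_trace <- if (nrow(rest$epochs) || !is.null(rest$size_at_crash))
      demographySizes(rest) else integer()
    trace <- as.integer(c(rep(anc_n, anc_dur), rest_trace))
    nG <- length(trace)
    mu <- c(rep(genome$mutation_rate * Q, anc_dur),
            rep(genome$mutation_rate, nG - anc_dur))
    rec <- c(rep(genome$recombination_rate * Q, anc_dur),
             rep(genome$recombination_rate, nG - anc_dur))
    ms <- c(rep(abs(dfe$mean_s) * Q, anc_dur),
            rep(abs(dfe$mean_s), nG - anc_dur))
    seam_gen <- anc_dur + 1L
    s_seam <- 1 / Q
  } else {
    trace <- demographySizes(demography)
    nG <- length(trace)
    mu <- rep(genome$mutation_rate, nG)
    rec <- rep(genome$recombination_rate, nG)
    ms <- rep(abs(dfe$mean_s), nG)
    s_seam <- 1
  }
  set.seed(seed)
  raw <- wf_simulate_cpp(trace, genome$length_bp, mu, rec,
                         dfe$p_deleterious, ms, dfe$shape, dfe$h,
                         purge_every = 32L, seam_gen = seam_gen,
                         s_seam_factor = s_seam)
  S <- length(raw$position_bp)
  mut <- data.frame(id = seq_len(S), position_bp = raw$position_bp,
                    s = raw$s, h = raw$h,
                    kind = ifelse(raw$neutral, "neutral", "deleterious"),
                    origin_generation = raw$origin_generation,
                    frequency = raw$frequency, stringsAsFactors = FALSE)
  mk <- data.frame(marker_id = paste0("site_", raw$position_bp),
                   chromosome = "1", bp = raw$position_bp,
                   cm = raw$position_bp * 1e-6, stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(raw$genotypes, mk)
  res <- new("SimResult", genotypes = gm, mutations = mut,
             trace = trace, seed = as.numeric(seed))
  attr(res, "new_mutations_per_generation") <- raw$new_mutations_per_generation
  res
}

#' Nucleotide diversity of a simulated sample
#'
#' Mean pairwise diversity per site, computed from sample allele
#' frequencies with the standard small-sample correction
#' 2p(1-p) * 2n/(2n-1), summed over segregating sites and divided by the
#' genome length.
#'
#' @param result a [SimResult-class].
#' @param genome the [genomeConfig()] the run used (for the genome
#'   length).
#' @return per-site diversity (comparable to 4*N*mu under neutrality).
#' @export
pairwiseDiversity <- function(result, genome = genomeConfig()) {
  g <- result@genotypes@calls
  n2 <- 2 * nrow(g)
  p <- colSums(g) / n2
  sum(2 * p * (1 - p) * n2 / (n2 - 1)) / genome$length_bp
}

#' Export a simulation result as VCF (v4.2) plus a mutation TSV
#'
#' One contig, diploid GT fields, INFO fields S (selection coefficient),
#' H (dominance), KIND (neutral/deleterious), AF (population frequency).
#'
#' @param result a [SimResult-class].
#' @param path output VCF path; the companion mutation table is written
#'   to \code{sub("\\\\.vcf$", "_mutations.tsv", path)}.
#' @param contig_length contig length for the header.
#' @return invisibly, the VCF path.
#' @export
exportVcf <- function(result, path, contig_length = 1e8) {
  mut <- result@mutations
  g <- result@genotypes@calls
  ids <- result@genotypes@individuals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=1,length=%d>", as.integer(contig_length)),
    "##INFO=<ID=S,Number=1,Type=Float,Description=\"Selection coefficient\">",
    "##INFO=<ID=H,Number=1,Type=Float,Description=\"Dominance coefficient\">",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"neutral or deleterious\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  if (nrow(mut)) {
    gtcode <- c("0/0", "0/1", "1/1")
    rows <- vapply(seq_len(nrow(mut)), function(j) {
      info <- sprintf("S=%g;H=%g;KIND=%s;AF=%g", mut$s[j], mut$h[j],
                      mut$kind[j], mut$frequency[j])
      paste(c("1", mut$position_bp[j], paste0("mut_", mut$id[j]), "A", "T",
              ".", "PASS", info, "GT", gtcode[g[, j] + 1L]), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  writeMutationTable(mut, sub("\\.vcf$", "_mutations.tsv", path))
  invisible(path)
}

#' @rdname exportVcf
#' @param mutations a mutation data.frame.
#' @export
writeMutationTable <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-import an exported simulation VCF
#'
#' Reads the VCF with \pkg{vcfR} and reconstructs the genotype matrix and
#' mutation table.
#'
#' @param path VCF path.
#' @return list with \code{genotypes} (a [GenotypeMatrix-class]) and
#'   \code{mutations} (data.frame).
#' @export
readSimVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(v@fix) == 0L) {
    empty_mk <- data.frame(marker_id = character(), chromosome = character(),
                           bp = integer(), cm = numeric())
    return(list(genotypes = GenotypeMatrix(matrix(integer(), 0, 0), empty_mk),
                mutations = data.frame()))
  }
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  dos[] <- t((gt == "0/1" | gt == "1/0") * 1L + (gt == "1/1") * 2L)
  pos <- as.integer(v@fix[, "POS"])
  info <- v@fix[, "INFO"]
  getf <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    sub(paste0(key, "="), "", m)
  }
  mut <- data.frame(id = seq_along(pos), position_bp = pos,
                    s = as.numeric(getf("S")), h = as.numeric(getf("H")),
                    kind = getf("KIND"),
                    origin_generation = NA_integer_,
                    frequency = as.numeric(getf("AF")),
                    stringsAsFactors = FALSE)
  mk <- data.frame(marker_id = paste0("site_", pos), chromosome = "1",
                   bp = pos, cm = pos * 1e-6, stringsAsFactors = FALSE)
  list(genotypes = GenotypeMatrix(dos, mk, individuals = colnames(gt)),
       mutations = mut)
}
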