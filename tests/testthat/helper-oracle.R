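# Brute-force reference implementation of the windowed ROH semantics,
# written as explicit enumeration (no shared code with callRoh).
# g: vector of 0/1/2/NA codes, cm: sorted genetic positions, p: rohParams.

oracleEligible <- function(g, p) {
  m <- length(g)
  W <- p$window_snps
  sapply(seq_len(m), function(i) {
    total <- 0L
    hits <- 0L
    for (ws in seq_len(max(0L, m - W + 1L))) {
      we <- ws + W - 1L
      if (i < ws || i > we) next
      total <- total + 1L
      win <- g[ws:we]
      nhet <- sum(win == 1L, na.rm = TRUE)
      nmis <- sum(is.na(win))
      if (nhet <= p$window_het && nmis <= p$window_missing)
        hits <- hits + 1L
    }
    total > 0L && hits / total >= p$window_hit_threshold - 1e-12
  })
}

# maximal intervals of eligible markers with all adjacent gaps <= max_gap:
# enumerate every interval, keep those valid and not extendable
oracleRegions <- function(eligible, pos, p) {
  m <- length(eligible)
  gap <- round(p$max_gap_cm * 1e6)
  elig_cs <- cumsum(eligible)
  badgap <- c(diff(pos) > gap, FALSE)
  bad_cs <- cumsum(badgap)
  ok_pair <- function(a, b) {
    (elig_cs[b] - elig_cs[a] + eligible[a]) == (b - a + 1L) &&
      (a == b || (bad_cs[b - 1L] - bad_cs[a] + badgap[a]) == 0L)
  }
  regions <- list()
  for (a in seq_len(m)) {
    for (b in a:m) {
      if (!ok_pair(a, b)) next
      extendable <- (a > 1 && ok_pair(a - 1L, b)) ||
        (b < m && ok_pair(a, b + 1L))
      if (!extendable) regions[[length(regions) + 1L]] <- c(a, b)
    }
  }
  unique(regions)
}

# within a region, split at every heterozygous call that would exceed the
# per-segment allowance (left-to-right walk), then trim each piece so it
# starts and ends on a homozygous non-missing call
oracleCandidates <- function(a, b, g, p) {
  ishet <- function(i) !is.na(g[i]) && g[i] == 1L
  hom <- function(i) !is.na(g[i]) && g[i] != 1L
  pieces <- list()
  start <- a
  cnt <- 0L
  for (i in a:b) {
    if (ishet(i)) {
      cnt <- cnt + 1L
      if (cnt > p$segment_het) {
        if (start <= i - 1L) pieces[[length(pieces) + 1L]] <- c(start, i - 1L)
        start <- i + 1L
        cnt <- 0L
      }
    }
  }
  if (start <= b) pieces[[length(pieces) + 1L]] <- c(start, b)
  out <- list()
  for (xy in pieces) {
    homs <- (xy[1]:xy[2])[vapply(xy[1]:xy[2], hom, logical(1))]
    if (!length(homs)) next
    out[[length(out) + 1L]] <- c(min(homs), max(homs))
  }
  out
}

oracleCallRohChrom <- function(g, cm, p) {
  pos <- round(cm * 1e6)
  if (length(g) < p$window_snps) return(NULL)
  eligible <- oracleEligible(g, p)
  segs <- list()
  for (reg in oracleRegions(eligible, pos, p)) {
    cands <- oracleCandidates(reg[1], reg[2], g, p)
    for (xy in cands) {
      n <- xy[2] - xy[1] + 1L
      L <- pos[xy[2]] - pos[xy[1]]
      if (n < p$min_snps) next
      if (L < round(p$min_length_cm * 1e6)) next
      if (L / n > p$max_avg_spacing_cm_per_snp * 1e6) next
      segs[[length(segs) + 1L]] <- data.frame(
        first = xy[1], last = xy[2], n_snps = n,
        n_het = sum(g[xy[1]:xy[2]] == 1L, na.rm = TRUE))
    }
  }
  if (!length(segs)) return(NULL)
  out <- do.call(rbind, segs)
  out[order(out$first), , drop = FALSE]
}

# run both paths on a single-chromosome genotype vector and compare
oracleCompare <- function(g, cm, p = rohParams()) {
  mk <- data.frame(marker_id = paste0("m", seq_along(g)), chromosome = "1",
                   bp = seq_along(g), cm = cm)
  gm <- GenotypeMatrix(matrix(as.integer(g), nrow = 1), mk, "i1")
  impl <- callRoh(gm, p)
  orac <- oracleCallRohChrom(g, cm, p)
  if (is.null(orac)) return(nrow(impl) == 0L)
  pos <- round(cm * 1e6)
  oseg <- data.frame(start_cm = pos[orac$first] / 1e6,
                     end_cm = pos[orac$last] / 1e6,
                     n_snps = orac$n_snps, n_het = orac$n_het)
  iseg <- impl[, c("start_cm", "end_cm", "n_snps", "n_het")]
  rownames(iseg) <- rownames(oseg) <- NULL
  isTRUE(all.equal(iseg, oseg, tolerance = 1e-12))
}

# random single-chromosome genotype vector for fuzzing the caller:
# blocky alternation of mostly-homozygous tracts and noisy tracts
randomRohInstance <- function(m = 200) {
  # dense marker spacing with occasional large gaps to exercise splitting
  spacing <- ifelse(stats::runif(m) < 0.07,
                    stats::runif(m, 0.2, 0.4),
                    stats::runif(m, 0.004, 0.05))
  cm <- cumsum(spacing) - spacing[1]
  g <- integer(m)
  i <- 1L
  while (i <= m) {
    blk <- min(m, i + stats::rpois(1, 40))
    nb <- blk - i + 1L
    if (stats::runif(1) < 0.5) {
      gg <- ifelse(stats::runif(nb) < 0.03, 1L,
                   ifelse(stats::runif(nb) < 0.5, 0L, 2L))
    } else {
      gg <- sample(c(0L, 1L, 2L), nb, replace = TRUE)
    }
    g[i:blk] <- gg
    i <- blk + 1L
  }
  g[stats::runif(m) < 0.02] <- NA_integer_
  list(g = g, cm = cm)
}
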