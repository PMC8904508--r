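## Synthetic-data generator: every input the pipeline consumes can be
## simulated with known ground truth, under a single integer seed.

#' Simulate allele frequencies drifting along an admixture graph
#'
#' Root frequencies are drawn i.i.d. from Beta(a, b) (monomorphic draws are
#' redrawn). Along an edge with drift length `c`, the child frequency is
#' drawn from a Beta distribution with mean equal to the parent frequency
#' and variance `c * p * (1 - p)` (the Balding-Nichols model). When
#' `c >= 1`, the Beta-feasible variance is exceeded and the draw degenerates
#' to fixation at 0/1 with probability `1 - p` / `p`; such truncations, and
#' any draw landing exactly on the boundary, are counted in the `clipped`
#' slot. At an admixture node the two (drifted) parental frequencies are
#' mixed as `alpha * pA + (1 - alpha) * pB` before any further drift.
#'
#' @param graph An [AdmixtureGraph-class].
#' @param panel A [SNPPanel-class]; one frequency is drawn per SNP.
#' @param seed Integer seed; each node gets its own sub-stream.
#' @param rootShape Beta shape `c(a, b)` for root frequencies. The default
#'   Beta(0.46, 0.46) gives expected heterozygosity 2 E\[p(1-p)\] of about
#'   0.24, the scale on which duplicate/unrelated mismatch rates of roughly
#'   0.12/0.24 arise.
#' @return A [FreqTable-class] with one row per graph node (leaves included).
#' @export
simulateFrequencies <- function(graph, panel, seed = 1L,
                                rootShape = c(0.46, 0.46)) {
  stopifnot(is(graph, "AdmixtureGraph"), is(panel, "SNPPanel"))
  n <- nSnps(panel)
  if (n == 0) stop("panel is empty")
  ord <- .topoOrder(graph@edges)
  if (is.null(ord)) stop("graph contains a cycle")
  e <- graph@edges
  adm <- graph@admixture
  root <- graphRoot(graph)
  f <- matrix(NA_real_, nrow = length(ord), ncol = n,
              dimnames = list(ord, snpInfo(panel)$id))
  clipped <- 0L

  driftDraw <- function(p, c) {
    if (c == 0) return(p)
    out <- p
    mid <- p > 0 & p < 1
    if (c >= 1) {
      ## variance request exceeds Beta feasibility: fixation draw
      out[mid] <- as.numeric(runif(sum(mid)) < p[mid])
      clipped <<- clipped + sum(mid)
      return(out)
    }
    nu <- (1 - c) / c
    out[mid] <- rbeta(sum(mid), p[mid] * nu, (1 - p[mid]) * nu)
    hit <- mid & (out <= 0 | out >= 1)
    clipped <<- clipped + sum(hit)
    out
  }

  for (nd in ord) {
    s <- subSeed(seed, "freq", nd)
    if (nd == root) {
      f[nd, ] <- withSeed(s, {
        p <- rbeta(n, rootShape[1], rootShape[2])
        bad <- p <= 0 | p >= 1
        while (any(bad)) {
          p[bad] <- rbeta(sum(bad), rootShape[1], rootShape[2])
          bad <- p <= 0 | p >= 1
        }
        p
      })
    } else if (nd %in% adm$child) {
      i <- match(nd, adm$child)
      cA <- e$drift[e$parent == adm$parentA[i] & e$child == nd]
      cB <- e$drift[e$parent == adm$parentB[i] & e$child == nd]
      f[nd, ] <- withSeed(s, {
        dA <- driftDraw(f[adm$parentA[i], ], cA)
        dB <- driftDraw(f[adm$parentB[i], ], cB)
        adm$alpha[i] * dA + (1 - adm$alpha[i]) * dB
      })
    } else {
      par <- e$parent[e$child == nd]
      cc <- e$drift[e$child == nd]
      f[nd, ] <- withSeed(s, driftDraw(f[par, ], cc))
    }
  }
  new("FreqTable", freq = f, panel = panel,
      rootShape = as.numeric(rootShape), clipped = as.integer(clipped))
}

#' Specify a simulated cohort
#'
#' @param groups Named integer vector: diploid individuals per group label.
#'   Individuals are named `<group>_<i>`.
#' @param pedigree Optional `data.frame` with columns `indA`, `indB`,
#'   `relation` in `duplicate`, `parent_offspring`, `full_sib`,
#'   `second_degree`; both individuals must belong to the same group.
#' @param meanDepth Mean read depth per site (lambda of the Poisson), either
#'   a single value or named per individual.
#' @param libraryType `"double_strand"` or `"single_strand"`, single value
#'   or named per individual.
#' @param damageRate Terminal deamination probability delta in `[0, 1]`.
#' @return A list of class `CohortSpec`.
#' @export
CohortSpec <- function(groups, pedigree = NULL, meanDepth = 1,
                       libraryType = "double_strand", damageRate = 0) {
  stopifnot(!is.null(names(groups)), all(groups >= 1))
  inds <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%d", g, seq_len(groups[[g]]))), use.names = FALSE)
  group <- rep(names(groups), groups)
  names(group) <- inds
  if (is.null(pedigree))
    pedigree <- data.frame(indA = character(0), indB = character(0),
                           relation = character(0))
  ok <- c("duplicate", "parent_offspring", "full_sib", "second_degree")
  if (nrow(pedigree)) {
    stopifnot(all(pedigree$relation %in% ok),
              all(c(pedigree$indA, pedigree$indB) %in% inds))
    if (any(group[pedigree$indA] != group[pedigree$indB]))
      stop("pedigree links must stay within one group")
  }
  expand <- function(v) {
    if (length(v) == 1 && is.null(names(v))) return(setNames(rep(v, length(inds)), inds))
    out <- setNames(rep(v[[1]], length(inds)), inds)
    out[names(v)] <- v
    out
  }
  depth <- expand(meanDepth)
  if (any(!is.finite(depth)) || any(depth < 0)) stop("mean depth must be finite and >= 0")
  if (damageRate < 0 || damageRate > 1) stop("damage rate must lie in [0, 1]")
  structure(list(groups = groups, individuals = inds, group = group,
                 pedigree = pedigree, meanDepth = depth,
                 libraryType = expand(libraryType), damageRate = damageRate),
            class = "CohortSpec")
}

## offspring genotypes from two parental genotype vectors (dosage 0/1/2)
.offspring <- function(g1, g2) {
  rbinom(length(g1), 1, g1 / 2) + rbinom(length(g2), 1, g2 / 2)
}

#' Simulate diploid genotypes for a cohort, with pedigree relatives
#'
#' Unrelated individuals draw `Binomial(2, p)` genotypes per SNP
#' (Hardy-Weinberg). Pedigree links override: duplicates copy the genotype
#' vector; a parent-offspring pair transmits one allele from the parent and
#' draws the other from the population; full siblings share two simulated
#' parents; second-degree pairs are grandparent-grandchild via one
#' intervening simulated parent.
#'
#' @param freqs A [FreqTable-class] whose rows include every cohort group.
#' @param cohort A [CohortSpec].
#' @param seed Integer seed.
#' @return A diploid [CallMatrix-class] (ploidy 2).
#' @export
simulateGenotypes <- function(freqs, cohort, seed = 1L) {
  stopifnot(is(freqs, "FreqTable"), inherits(cohort, "CohortSpec"))
  missing <- setdiff(names(cohort$groups), rownames(freqs@freq))
  if (length(missing))
    stop("unknown group label(s): ", paste(missing, collapse = ", "))
  n <- nSnps(freqs)
  g <- matrix(NA_integer_, nrow = n, ncol = length(cohort$individuals),
              dimnames = list(snpInfo(freqs)$id, cohort$individuals))
  for (grp in names(cohort$groups)) {
    p <- freqs@freq[grp, ]
    members <- cohort$individuals[cohort$group[cohort$individuals] == grp]
    g[, members] <- withSeed(subSeed(seed, "geno", grp),
      matrix(rbinom(n * length(members), 2, p), nrow = n))
  }
  ped <- cohort$pedigree
  if (nrow(ped)) for (i in seq_len(nrow(ped))) {
    a <- ped$indA[i]; b <- ped$indB[i]
    p <- freqs@freq[cohort$group[a], ]
    withSeed(subSeed(seed, "ped", a, b, ped$relation[i]), {
      switch(ped$relation[i],
        duplicate = { g[, b] <- g[, a] },
        parent_offspring = {
          g[, b] <- rbinom(n, 1, g[, a] / 2) + rbinom(n, 1, p)
        },
        full_sib = {
          p1 <- rbinom(n, 2, p); p2 <- rbinom(n, 2, p)
          g[, a] <- .offspring(p1, p2)
          g[, b] <- .offspring(p1, p2)
        },
        second_degree = {
          mate1 <- rbinom(n, 2, p); mate2 <- rbinom(n, 2, p)
          mid <- .offspring(g[, a], mate1)
          g[, b] <- .offspring(mid, mate2)
        })
    })
  }
  CallMatrix(g, freqs@panel, ploidy = 2L)
}

#' Simulate a read pileup over a genotyped cohort
#'
#' Per individual and SNP, read depth is Poisson with the cohort's mean
#' depth; each read carries one of the individual's two alleles (uniformly),
#' a base quality, a mapping quality, a strand and a position within the
#' read. Post-mortem deamination is modelled on the terminal 5 bases: with
#' probability `damageRate`, a C carried by a plus-strand read is emitted as
#' T, and a G carried by a minus-strand read as A (the reference-orientation
#' image of C-to-T damage on the read's native strand).
#'
#' @param genotypes Diploid [CallMatrix-class] from [simulateGenotypes()].
#' @param cohort The [CohortSpec].
#' @param panel The [SNPPanel-class].
#' @param readLen Read length in bp (must exceed 10).
#' @param librariesPerIndividual Libraries sequenced per individual; each
#'   library draws its own Poisson depth.
#' @param seed Integer seed.
#' @return A pileup `data.frame` with columns `individual`, `library`,
#'   `chrom`, `position`, `base`, `base_quality`, `mapping_quality`,
#'   `strand`, `read_position`, `read_length`, `library_type`.
#' @export
simulatePileup <- function(genotypes, cohort, panel, readLen = 70L,
                           librariesPerIndividual = 1L, seed = 1L) {
  stopifnot(is(genotypes, "CallMatrix"), inherits(cohort, "CohortSpec"))
  if (readLen <= 10) stop("read length must exceed 10")
  s <- snpInfo(panel)
  out <- vector("list", 0)
  for (ind in individuals(genotypes)) {
    lambda <- cohort$meanDepth[[ind]]
    if (lambda < 0) stop("mean depth must be >= 0")
    ltype <- cohort$libraryType[[ind]]
    geno <- calls(genotypes)[, ind]
    for (lb in seq_len(librariesPerIndividual)) {
      lib <- sprintf("%s_L%d", ind, lb)
      rows <- withSeed(subSeed(seed, "pileup", ind, lib), {
        depth <- rpois(nrow(s), lambda)
        if (sum(depth) == 0) NULL else {
        idx <- rep.int(seq_len(nrow(s)), depth)
        nr <- length(idx)
        altRead <- rbinom(nr, 1, geno[idx] / 2)
        base <- ifelse(altRead == 1, s$alt[idx], s$ref[idx])
        strand <- ifelse(runif(nr) < 0.5, "+", "-")
        rp <- sample.int(readLen, nr, replace = TRUE)
        bq <- pmin(41L, pmax(2L, as.integer(round(rnorm(nr, 37, 4)))))
        mq <- sample(c(60L, 37L, 25L, 5L), nr, replace = TRUE,
                     prob = c(0.85, 0.07, 0.05, 0.03))
        terminal <- rp <= 5 | rp > readLen - 5
        dmg <- terminal & runif(nr) < cohort$damageRate
        base[dmg & strand == "+" & base == "C"] <- "T"
        base[dmg & strand == "-" & base == "G"] <- "A"
        data.frame(individual = ind, library = lib, chrom = s$chrom[idx],
                   position = s$pos[idx], base = base, base_quality = bq,
                   mapping_quality = mq, strand = strand, read_position = rp,
                   read_length = as.integer(readLen), library_type = ltype,
                   stringsAsFactors = FALSE)
        }
      })
      if (!is.null(rows)) out[[length(out) + 1]] <- rows
    }
  }
  if (!length(out))
    return(data.frame(individual = character(0), library = character(0),
                      chrom = character(0), position = integer(0),
                      base = character(0), base_quality = integer(0),
                      mapping_quality = integer(0), strand = character(0),
                      read_position = integer(0), read_length = integer(0),
                      library_type = character(0)))
  do.call(rbind, out)
}

#' Simulate admixed chromosomes with exponential ancestry tracts
#'
#' Each haplotype follows a Markov path over the two source ancestries
#' along the genetic map: the initial state is source 1 with probability
#' `alpha`, switch events arrive as a Poisson process of rate `g` per
#' Morgan, and the state after each switch is redrawn as source 1 with
#' probability `alpha`. Source-1 tracts therefore have mean length
#' `1 / ((1 - alpha) g)` Morgans. Alleles are drawn from the local
#' ancestry's source frequency.
#'
#' @param freqs A [FreqTable-class] containing both sources.
#' @param source1,source2 Row names of the two sources in `freqs`.
#' @param alpha Mixing proportion of `source1`.
#' @param g Generations since admixture (> 0); the tract-switch rate.
#' @param nInd Number of sampled diploid individuals.
#' @param seed Integer seed.
#' @return A list with elements `calls` (diploid [CallMatrix-class]),
#'   `ancestry` (SNPs x individuals dosage of source-1 ancestry, 0-2) and
#'   `tracts` (`data.frame` of per-haplotype segments in Morgans).
#' @export
simulateAdmixedGenotypes <- function(freqs, source1, source2, alpha, g,
                                     nInd, seed = 1L) {
  stopifnot(is(freqs, "FreqTable"))
  if (g <= 0) stop("admixture age g must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!all(c(source1, source2) %in% rownames(freqs@freq)))
    stop("both sources must be rows of the frequency table")
  s <- snpInfo(freqs)
  p1 <- freqs@freq[source1, ]; p2 <- freqs@freq[source2, ]
  n <- nrow(s)
  inds <- sprintf("adm_%d", seq_len(nInd))
  geno <- matrix(0L, n, nInd, dimnames = list(s$id, inds))
  anc <- matrix(0L, n, nInd, dimnames = list(s$id, inds))
  tracts <- vector("list", 0)
  chroms <- unique(s$chrom)
  for (ind in seq_len(nInd)) {
    for (hap in 1:2) {
      withSeed(subSeed(seed, "admix", ind, hap), {
        for (ch in chroms) {
          ix <- which(s$chrom == ch)
          g0 <- min(s$gpos[ix]); g1 <- max(s$gpos[ix])
          span <- g1 - g0
          k <- rpois(1, g * span)
          breaks <- sort(runif(k, g0, g1))
          states <- runif(k + 1) < alpha   # TRUE = source1
          seg <- findInterval(s$gpos[ix], breaks) + 1L
          st <- states[seg]
          p <- ifelse(st, p1[ix], p2[ix])
          geno[ix, ind] <- geno[ix, ind] + rbinom(length(ix), 1, p)
          anc[ix, ind] <- anc[ix, ind] + as.integer(st)
          ## a redrawn state equal to the previous one is not a tract
          ## boundary: merge consecutive same-state segments
          bnd <- c(g0, breaks, g1)
          run <- c(TRUE, states[-1] != states[-length(states)])
          st0 <- states[run]
          lo <- bnd[-length(bnd)][run]
          hi <- c(lo[-1], g1)
          tracts[[length(tracts) + 1]] <- data.frame(
            ind = inds[ind], hap = hap, chrom = ch,
            start = lo, end = hi,
            state = ifelse(st0, source1, source2))
        }
      })
    }
  }
  list(calls = CallMatrix(geno, freqs@panel, ploidy = 2L),
       ancestry = anc,
       tracts = do.call(rbind, tracts))
}
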