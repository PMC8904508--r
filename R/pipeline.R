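## End-to-end orchestration of the pipeline stages from a YAML config,
## with seeded reproducibility and a YAML run manifest.

.stageOrder <- c("simulate", "call", "relate", "fstat", "qpadm", "graph",
                 "dates", "scan", "yhap")

#' Run pipeline stages from a config
#'
#' Stages run in dependency order (simulate -> call -> relate ->
#' fstat/qpadm -> dates -> scan -> yhap); each stage reads the previous
#' stages' files from the output directory, so a stage whose upstream
#' artifact is missing fails with a dependency error naming it. Existing
#' stage outputs are not overwritten unless `force = TRUE`. All
#' randomness derives from the single `seed`, so rerunning an identical
#' config reproduces byte-identical outputs.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Top-level keys: `stages` (character vector), `seed`, `out`, plus one
#'   block of parameters per stage (see the bundled demo config in
#'   `system.file("extdata", "demo-config.yaml", package = "adnapipe")`).
#' @param seed Overrides the config seed.
#' @param outDir Overrides the config output directory.
#' @param force Rewrite outputs of requested stages.
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.yaml` in the output directory.
#' @export
runPipeline <- function(config, seed = NULL, outDir = NULL, force = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  if (is.null(outDir)) outDir <- if (!is.null(cfg$out)) cfg$out else "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- intersect(.stageOrder, cfg$stages)
  if (!length(stages)) stop("no known stage requested")
  manifest <- list(seed = as.integer(seed), stages = list())
  pth <- function(...) file.path(outDir, paste0(...))
  need <- function(f, stage, from) {
    if (!file.exists(f))
      stop(sprintf("stage '%s' needs '%s' from stage '%s'", stage, f, from))
    f
  }
  ## EIGENSTRAT prefixes: check for the .geno file, return the prefix
  needPrefix <- function(prefix, stage, from) {
    need(pth(prefix, ".geno"), stage, from)
    pth(prefix)
  }
  done <- function(...) all(file.exists(c(...)))

  for (st in stages) {
    summaryInfo <- switch(st,
      simulate = {
        outs <- c(pth("sim.geno"), pth("pileup.tsv"), pth("truth.yaml"))
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          sc <- cfg$simulate
          graph <- if (!is.null(sc$graph_file)) readGraph(sc$graph_file)
                   else readGraphList(sc$graph)
          panel <- simulatePanel(sc$n_snps, nChrom = sc$n_chrom %||% 1L,
                                 chromLengthMb = sc$chrom_length_mb %||% 100,
                                 seed = seed)
          freqs <- simulateFrequencies(graph, panel, seed = seed)
          cohort <- CohortSpec(unlist(sc$groups),
                               pedigree = if (!is.null(sc$pedigree))
                                 do.call(rbind, lapply(sc$pedigree, as.data.frame)),
                               meanDepth = sc$mean_depth %||% 1,
                               libraryType = sc$library_type %||% "double_strand",
                               damageRate = sc$damage_rate %||% 0)
          geno <- simulateGenotypes(freqs, cohort, seed = seed)
          pile <- simulatePileup(geno, cohort, panel,
                                 librariesPerIndividual = sc$libraries %||% 1L,
                                 seed = seed)
          writeEigenstrat(geno, pth("sim"), groups = cohort$group)
          writePileupTable(pile, pth("pileup.tsv"))
          ## ground-truth tables for recovery checks
          write.table(data.frame(individual = cohort$individuals,
                                 group = unname(cohort$group[cohort$individuals]),
                                 mean_depth = unname(cohort$meanDepth[cohort$individuals]),
                                 library_type = unname(cohort$libraryType[cohort$individuals])),
                      pth("truth-individuals.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          write.table(cohort$pedigree, pth("truth-pedigree.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          yaml::write_yaml(list(seed = as.integer(seed),
                                groups = as.list(unlist(sc$groups)),
                                damage_rate = cohort$damageRate,
                                graph = sc$graph %||% sc$graph_file),
                           pth("truth.yaml"))
          sprintf("%d SNPs, %d individuals, %d pileup rows",
                  nSnps(panel), length(cohort$individuals), nrow(pile))
        }
      },
      call = {
        outs <- pth("calls.geno")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          es <- readEigenstrat(needPrefix("sim", "call", "simulate"), ploidy = 2L)
          pile <- readPileupTable(need(pth("pileup.tsv"), "call", "simulate"))
          cc <- cfg$call
          cm <- callPseudohaploid(pile, es$panel,
                                  mode = cc$mode %||% "double_strand",
                                  minBaseQuality = cc$min_base_quality %||% 30L,
                                  minMapQuality = cc$min_map_quality %||% 30L,
                                  endTrim = cc$end_trim %||% 5L,
                                  seed = seed)
          writeEigenstrat(cm, pth("calls"),
                          groups = setNames(es$ind$group, es$ind$individual))
          sprintf("%d calls, %.1f%% missing", sum(!is.na(calls(cm))),
                  100 * mean(is.na(calls(cm))))
        }
      },
      relate = {
        outs <- pth("relatedness.tsv")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          es <- readEigenstrat(needPrefix("calls", "relate", "call"), ploidy = 1L)
          pm <- pairwiseMismatch(es$calls,
                                 minOverlap = cfg$relate$min_overlap %||% 3000L)
          B <- tryCatch(estimateBaseline(pm), error = function(e) NA)
          if (!is.na(B)) pm <- classifyPairs(pm, B)
          write.table(pm, pth("relatedness.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          sprintf("%d pairs, baseline %.4f", nrow(pm), B)
        }
      },
      fstat = {
        outs <- pth("fstats.tsv")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          es <- readEigenstrat(needPrefix("calls", "fstat", "call"), ploidy = 1L)
          ac <- alleleCounts(es$calls, setNames(es$ind$group, es$ind$individual))
          blocks <- assignBlocks(es$panel, cfg$fstat$block_cm %||% 5)
          tab <- fstatBatch(ac, do.call(rbind, lapply(cfg$fstat$pops, unlist)),
                            statistic = cfg$fstat$statistic %||% "f3",
                            blocks = blocks)
          write.table(tab, pth("fstats.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          sprintf("%d statistics", nrow(tab))
        }
      },
      qpadm = {
        outs <- pth("qpadm.tsv")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          es <- readEigenstrat(needPrefix("calls", "qpadm", "call"), ploidy = 1L)
          ac <- alleleCounts(es$calls, setNames(es$ind$group, es$ind$individual))
          blocks <- assignBlocks(es$panel, cfg$qpadm$block_cm %||% 5)
          qc <- cfg$qpadm
          fit <- qpAdm(ac, qc$target, unlist(qc$sources), unlist(qc$rights),
                       blocks, allsnps = qc$allsnps %||% TRUE)
          write.table(data.frame(source = fit$sources, weight = fit$weights,
                                 se = fit$se, p = fit$p,
                                 feasible = fit$feasible),
                      pth("qpadm.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          sprintf("p = %.3g, weights %s", fit$p,
                  paste(sprintf("%.3f", fit$weights), collapse = "/"))
        }
      },
      graph = {
        outs <- pth("graphfit.tsv")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          es <- readEigenstrat(needPrefix("calls", "graph", "call"), ploidy = 1L)
          gc2 <- cfg$graph
          topo <- if (!is.null(gc2$graph_file)) readGraph(gc2$graph_file)
                  else readGraphList(gc2)
          ac <- alleleCounts(es$calls, setNames(es$ind$group, es$ind$individual))
          blocks <- assignBlocks(es$panel, gc2$block_cm %||% 5)
          ft <- fitGraph(topo, ac, blocks, seed = seed)
          write.table(ft$fit, pth("graphfit.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          writeGraph(ft$graph, pth("graphfit.txt"))
          writeGraphDot(ft$graph, pth("graphfit.dot"))
          sprintf("score %d (of %d statistics)", ft$score, nrow(ft$fit))
        }
      },
      dates = {
        outs <- pth("dates.tsv")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          es <- readEigenstrat(needPrefix("sim", "dates", "simulate"), ploidy = 2L)
          dc <- cfg$dates
          grp <- setNames(es$ind$group, es$ind$individual)
          ac <- alleleCounts(es$calls, grp)
          tgt <- es$calls@calls[, grp == dc$target, drop = FALSE]
          tcm <- CallMatrix(tgt, es$panel, ploidy = 2L)
          p1 <- ac@x[dc$ref1, ] / pmax(ac@n[dc$ref1, ], 1)
          p2 <- ac@x[dc$ref2, ] / pmax(ac@n[dc$ref2, ], 1)
          curve <- ancestryCovariance(tcm, p1, p2,
                                      binsizeCM = dc$binsize_cm %||% 0.01,
                                      maxDistCM = dc$max_dist_cm %||% 1.0)
          ft <- fitDecay(curve, minDistCM = dc$min_dist_cm %||% 0.05)
          write.table(data.frame(bin_left_cM = curve$binLeftCM,
                                 covariance = curve$value,
                                 n_pairs = curve$nPairs),
                      pth("dates-curve.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          write.table(data.frame(A = ft$A, g = ft$g, c = ft$c, se = ft$se,
                                 converged = ft$converged),
                      pth("dates.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          sprintf("g = %.1f (SE %.1f)", ft$g, ft$se)
        }
      },
      scan = {
        outs <- pth("scan.tsv")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          es <- readEigenstrat(needPrefix("calls", "scan", "call"), ploidy = 1L)
          sc <- cfg$scan
          ac <- alleleCounts(es$calls, setNames(es$ind$group, es$ind$individual))
          spec <- windowSpec(sizeBp = sc$window_bp %||% 500000L,
                             stepBp = sc$step_bp %||% 10000L,
                             minSnps = sc$min_snps %||% 250L,
                             minAncientInd = sc$min_ancient %||% 15L)
          sw <- windowScan(ac, sc$target, sc$ancient, sc$outgroup, spec)
          blocks <- if (!is.null(sc$ld_blocks)) readBedIntervals(sc$ld_blocks)
                    else uniformLdBlocks(es$panel, sc$block_mb %||% 1)
          sw <- ldBlockZscores(sw, blocks, seed = seed)
          write.table(sw, pth("scan.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          cand <- callCandidates(sw, zThreshold = sc$z_threshold %||% 4)
          write.table(cand, pth("scan-candidates.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          sprintf("%d windows, %d candidate regions",
                  sum(!is.na(sw$normF3)), nrow(cand))
        }
      },
      yhap = {
        outs <- pth("yhap.tsv")
        if (done(outs) && !force) { "skipped (outputs exist)" } else {
          pile <- readPileupTable(need(pth("pileup.tsv"), "yhap", "simulate"))
          tree <- readMarkerTree(cfg$yhap$tree)
          rows <- lapply(unique(pile$individual), function(ind) {
            sup <- scoreBranches(pile[pile$individual == ind, ], tree)
            asg <- assignHaplogroup(sup, tree)
            data.frame(individual = ind, call = asg$call,
                       conflicts = paste(asg$conflicts, collapse = ","))
          })
          write.table(do.call(rbind, rows), pth("yhap.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          sprintf("%d individuals", length(rows))
        }
      })
    manifest$stages[[st]] <- summaryInfo
    message(sprintf("[%s] %s", st, summaryInfo))
  }
  files <- list.files(outDir, full.names = FALSE)
  manifest$outputs <- files[files != "manifest.yaml"]
  manifest$package_version <- as.character(utils::packageVersion("adnapipe"))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an AdmixtureGraph from a config list
#'
#' `edges` is a list/vector of "parent child drift" strings, `admixture`
#' of "child parentA parentB alpha" strings.
#'
#' @param spec A list with `edges` and optional `admixture`.
#' @return An [AdmixtureGraph-class].
#' @export
readGraphList <- function(spec) {
  tok <- strsplit(unlist(spec$edges), "[[:space:]]+")
  e <- do.call(rbind, lapply(tok, function(t)
    data.frame(parent = t[1], child = t[2], drift = as.numeric(t[3]))))
  a <- NULL
  if (!is.null(spec$admixture)) {
    tok <- strsplit(unlist(spec$admixture), "[[:space:]]+")
    a <- do.call(rbind, lapply(tok, function(t)
      data.frame(child = t[1], parentA = t[2], parentB = t[3],
                 alpha = as.numeric(t[4]))))
  }
  AdmixtureGraph(e, a)
}

#' Uniform LD blocks over a panel
#'
#' Partitions each chromosome into fixed-size physical blocks, a
#' stand-in when no curated LD-block map is supplied.
#'
#' @param panel A [SNPPanel-class].
#' @param sizeMb Block size in Mb (default 1).
#' @return A `data.frame` of 1-based inclusive intervals.
#' @export
uniformLdBlocks <- function(panel, sizeMb = 1) {
  s <- snpInfo(panel)
  out <- list()
  for (ch in unique(s$chrom)) {
    mx <- max(s$pos[s$chrom == ch])
    brk <- seq(0L, mx + sizeMb * 1e6, by = as.integer(sizeMb * 1e6))
    out[[ch]] <- data.frame(chrom = ch, start = head(brk, -1) + 1L,
                            end = tail(brk, -1))
  }
  res <- do.call(rbind, out)
  res$name <- sprintf("block%d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}
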