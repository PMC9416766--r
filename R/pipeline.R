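## Pipeline orchestration: simulate -> derived traits -> evaluation ->
## REML by birth-year period -> selection-index report -> GWAS, with a
## flat key-value configuration, per-stage logging and a deterministic
## manifest.

#' Default pipeline configuration
#'
#' A flat named list: a master `seed`, stage toggles, the traits to
#' analyze, three non-overlapping birth-year windows for the
#' period-wise variance-component analysis, and the population-size
#' knobs forwarded to [simConfig()]. Every stochastic stage draws from
#' the single seed, so a run is fully reproducible.
#'
#' @param seed Master seed.
#' @param stages Named logical vector over
#'   c(simulate, traits, evaluate, reml, index, gwas).
#' @param traits Traits simulated and analyzed.
#' @param periods List of c(firstYear, lastYear) birth-year windows.
#' @param nFounders,nGenerations,nHerds,nSnps Simulation sizes.
#' @return Configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(seed = 1L,
                           stages = c(simulate = TRUE, traits = TRUE,
                                      evaluate = TRUE, reml = TRUE,
                                      index = TRUE, gwas = TRUE),
                           traits = c("protein", "cs"),
                           periods = list(c(2000L, 2004L), c(2005L, 2008L),
                                          c(2009L, 2013L)),
                           nFounders = 120L, nGenerations = 3L,
                           nHerds = 8L, nSnps = 400L) {
  list(seed = as.integer(seed), stages = stages, traits = traits,
       periods = periods, nFounders = as.integer(nFounders),
       nGenerations = as.integer(nGenerations), nHerds = as.integer(nHerds),
       nSnps = as.integer(nSnps))
}

#' Validate a pipeline configuration
#'
#' Always returns (never throws): an empty character vector when the
#' configuration is executable, otherwise one message per issue naming
#' the offending field and constraint.
#'
#' @param config A configuration list (see [pipelineConfig()]).
#' @return Character vector of issues.
#' @export
validateConfig <- function(config) {
  issues <- character(0)
  need <- c("seed", "stages", "traits", "periods", "nFounders",
            "nGenerations", "nHerds", "nSnps")
  missing <- setdiff(need, names(config))
  if (length(missing))
    return(paste0("missing field(s): ", paste(missing, collapse = ", ")))
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed) || config$seed < 0)
    issues <- c(issues, "seed: must be a single non-negative integer")
  known <- c("simulate", "traits", "evaluate", "reml", "index", "gwas")
  if (is.null(names(config$stages)) ||
      !all(names(config$stages) %in% known))
    issues <- c(issues, paste0("stages: names must be among ",
                               paste(known, collapse = ", ")))
  if (!is.logical(config$stages))
    issues <- c(issues, "stages: toggles must be logical")
  for (f in c("nFounders", "nGenerations", "nHerds", "nSnps"))
    if (!is.numeric(config[[f]]) || config[[f]] < 0)
      issues <- c(issues, paste0(f, ": must be a non-negative count"))
  pr <- config$periods
  if (!is.list(pr) || !all(vapply(pr, length, 0L) == 2L)) {
    issues <- c(issues, "periods: each must be c(firstYear, lastYear)")
  } else {
    for (i in seq_along(pr)) {
      if (pr[[i]][1L] > pr[[i]][2L])
        issues <- c(issues, paste0("periods[", i, "]: start after end"))
      for (j in seq_along(pr)) {
        if (j <= i) next
        if (pr[[i]][1L] <= pr[[j]][2L] && pr[[j]][1L] <= pr[[i]][2L])
          issues <- c(issues,
                      paste0("periods ", i, " and ", j, " overlap"))
      }
    }
  }
  st <- config$stages
  if (isTRUE(st[["gwas"]]) && !isTRUE(st[["evaluate"]]))
    issues <- c(issues, "stages: gwas requires evaluate (response is EBV)")
  issues
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic population:
#' simulation, derived fertility traits, multi-trait BLUP evaluation
#' with realized genetic trends, period-wise REML parameter matrices
#' (heritabilities on the diagonal, genetic correlations above,
#' environmental correlations below), the selection-index gain report,
#' and a GWAS of the sire evaluations. All outputs are TSV/CSV under
#' `outDir`; `manifest.tsv` records the seed, package version and
#' per-stage row counts. A failing stage aborts with its name; outputs
#' of completed stages are preserved. Runs are byte-identical for a
#' fixed configuration and seed.
#'
#' @param config Configuration list (see [pipelineConfig()]).
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  issues <- validateConfig(config)
  if (length(issues))
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  on <- function(s) isTRUE(st[[s]])
  manifest <- list(seed = config$seed,
                   version = as.character(packageVersion("herdtrend")))
  results <- list()
  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cfg <- NULL; ped <- NULL; tv <- NULL; phen <- NULL; insem <- NULL
  if (on("simulate")) {
    runStage("simulate", function() {
      cfg <<- simConfig(traits = config$traits, nFounders = config$nFounders,
                        nGenerations = config$nGenerations,
                        nHerds = config$nHerds, nSnps = config$nSnps,
                        yearsSpanned = 12, seed = config$seed)
      ped <<- simulatePedigree(cfg)
      tv <<- simulateBreedingValues(ped, cfg@G, seed = config$seed)
      phen <<- simulatePhenotypes(ped, tv, cfg)
      insem <<- simulateInseminations(ped, tv, cfg)
      writePedigreeCsv(ped, file.path(outDir, "pedigree.csv"))
      writePhenotypesCsv(phen, file.path(outDir, "phenotypes.csv"))
      writeInseminationsCsv(insem, file.path(outDir, "inseminations.csv"))
      manifest$n_animals <<- length(ped@id)
      manifest$n_phenotype_rows <<- nrow(phen)
      manifest$n_insemination_rows <<- nrow(insem)
      results$pedigree <<- ped
    })
  }
  if (on("traits")) {
    runStage("traits", function() {
      if (is.null(insem)) stop("traits stage needs simulated inseminations")
      message("conception status: censored records imputed by the ",
              "geometric herd-year model (default)")
      cs <- conceptionStatus(insem, herds = ped)
      write.csv(cs, file.path(outDir, "conception_status.csv"),
                row.names = FALSE, quote = FALSE)
      manifest$n_cs_records <<- nrow(cs)
      results$conceptionStatus <<- cs
    })
  }
  evalRes <- NULL
  if (on("evaluate")) {
    runStage("evaluate", function() {
      if (is.null(phen)) stop("evaluate stage needs simulated phenotypes")
      covs <- traitCovariances(cfg@G, cfg@E)
      evalRes <<- blupEvaluate(phen, ped, covs,
                               fixed = c("hys", "parity"))
      ebvTab <- data.frame(animal = rep(rownames(ebv(evalRes)),
                                        ncol(ebv(evalRes))),
                           trait = rep(colnames(ebv(evalRes)),
                                       each = nrow(ebv(evalRes))),
                           ebv = as.vector(ebv(evalRes)),
                           stringsAsFactors = FALSE)
      ebvTab$birth <- ped@birth[match(ebvTab$animal, ped@id)]
      write.table(ebvTab, file.path(outDir, "ebv.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      trends <- realizedTrends(ebvTab)
      write.table(trends, file.path(outDir, "trends.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      manifest$n_evaluated <<- nrow(ebv(evalRes))
      results$evaluation <<- evalRes
      results$trends <<- trends
    })
  }
  if (on("reml")) {
    runStage("reml", function() {
      if (is.null(phen)) stop("reml stage needs simulated phenotypes")
      for (i in seq_along(config$periods)) {
        win <- config$periods[[i]]
        yrs <- as.integer(format(ped@birth, "%Y"))
        cows <- ped@id[yrs >= win[1L] & yrs <= win[2L]]
        sub <- phen[phen$animal %in% cows, ]
        if (!nrow(sub)) {
          manifest[[paste0("n_reml_period", i)]] <<- 0L
          next
        }
        fit <- remlFit(sub, ped, parities = 1L, fixed = "mean",
                       method = "em-then-ai", tol = 1e-5, maxIter = 60L)
        pm <- parameterMatrix(covariances(fit), below = "environmental")
        writeMatrixTsv(round(pm, 4),
                       file.path(outDir, paste0("parameters_period", i, ".tsv")))
        manifest[[paste0("n_reml_period", i)]] <<-
          length(unique(sub$animal))
        results$reml[[i]] <<- fit
      }
    })
  }
  if (on("index")) {
    runStage("index", function() {
      message("selection intensity calibrated against the realized ",
              "national total gain (default)")
      gains <- ilGainSummary()
      spec <- pd19IndexWeights()
      rep6 <- gainReport(spec, ilTraitCovariances(),
                         realized = setNames(gains$realized, gains$trait),
                         realizedSe = setNames(gains$realizedSe, gains$trait))
      out <- rep6
      out[, -1L] <- round(out[, -1L], 4)
      write.table(out, file.path(outDir, "gain_report.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      manifest$index_intensity <<- round(attr(rep6, "intensity"), 4)
      results$gainReport <<- rep6
    })
  }
  if (on("gwas")) {
    runStage("gwas", function() {
      if (is.null(evalRes)) stop("gwas stage needs the evaluation")
      gm <- simulateGenotypes(ped, cfg)
      bulls <- ped@id[ped@sex == "M"]
      gmB <- genotypeMatrix(dosages(gm)[bulls, , drop = FALSE],
                            map = snpMap(gm))
      tr <- config$traits
      scans <- lapply(tr, function(t)
        gwasScan(ebv(evalRes)[bulls, t], gmB, trait = t))
      names(scans) <- tr
      for (t in tr)
        write.table(gwasTable(scans[[t]]),
                    file.path(outDir, paste0("gwas_", t, ".tsv")),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      summ <- data.frame(trait = tr,
                         pseudoH2 = vapply(scans, function(s) s@h2, 0),
                         minP = vapply(scans, function(s)
                           min(gwasTable(s)$p, na.rm = TRUE), 0),
                         nSignif = vapply(scans, function(s)
                           nrow(bonferroni(s)), 0L))
      if (length(tr) >= 2L) {
        ct <- crossTraitEffects(scans[[1L]], scans[[2L]])
        summ$crossR2 <- c(ct$r2, rep(NA, length(tr) - 1L))
      }
      summ[, -1L] <- round(summ[, -1L], 6)
      write.table(summ, file.path(outDir, "gwas_summary.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      manifest$n_gwas_bulls <<- length(bulls)
      manifest$n_gwas_snps <<- nSnps(gmB)
      results$gwas <<- scans
    })
  }
  mf <- data.frame(key = names(manifest),
                   value = vapply(manifest, function(v)
                     format(v, scientific = FALSE), ""),
                   stringsAsFactors = FALSE)
  write.table(mf, file.path(outDir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  results$manifest <- manifest
  invisible(results)
}
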