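readEnergyTable <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  fields <- strsplit(first, "[\t,]")[[1L]]
  hasHeader <- length(fields) >= 3L &&
    is.na(suppressWarnings(as.numeric(fields[3L])))
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = hasHeader,
                          stringsAsFactors = FALSE, quote = "\"")
  names(df)[1:3] <- c("ligand", "receptor", "energy")
  df$energy <- as.numeric(df$energy)
  df[, c("ligand", "receptor", "energy")]
}

#' Read a per-node centrality table
#'
#' CSV/TSV with a `name` column and the six centrality columns produced by
#' [centralityTable()] (header matched case-insensitively).
#'
#' @param path path to the table.
#' @return data.frame in [centralityTable()] layout.
#' @export
readCentralityTable <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"")
  names(df) <- tolower(names(df))
  need <- c("name", CENTRALITY_MEASURES)
  if (!all(need %in% names(df))) {
    stopf("centrality table '%s' is missing column(s): %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df[, need]
}

hashConfig <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unname(tools::md5sum(tf))
}

cfgAsList <- function(cfg) {
  sl <- methods::slotNames(class(cfg))
  stats::setNames(lapply(sl, methods::slot, object = cfg), sl)
}

runStage <- function(stage, verbose, expr) {
  if (verbose) message(sprintf("[netpharm] stage '%s'", stage))
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  if (verbose) {
    message(sprintf("[netpharm] stage '%s' done in %.2fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run the full network-pharmacology screen
#'
#' Orchestrates ADMET screening, disease-source union and drug-disease
#' intersection, over-representation analysis, bipartite compound-target
#' and PPI network analysis with the median hub screen, and docking-energy
#' grading. Every intermediate artifact is written to `outDir` and a
#' machine-readable run summary (stage counts, seed, config hash) is
#' returned and written as `run_summary.json`.
#'
#' `config` is either a [SynthConfig-class] (fully synthetic run) or a list
#' / YAML / JSON file of input paths with optional elements:
#' \describe{
#'   \item{compounds}{compound table for [readCompoundTable()]}
#'   \item{diseaseSources}{character vector of gene-list paths}
#'   \item{drugTargets}{compound-target map for [readTargetMap()]}
#'   \item{gmt}{annotation sets for [readGmt()]}
#'   \item{universe}{optional gene-list path for the ORA universe}
#'   \item{ppiEdges}{edge list for [readEdgeList()]}
#'   \item{hubTable}{precomputed centrality table
#'     (see [readCentralityTable()]); its degree column is used to report
#'     the hub-subnetwork edge count when no PPI edge list is given}
#'   \item{docking}{ligand/receptor/energy TSV}
#'   \item{obMin, dlMin, qMax, rounds, topPairs}{scalar overrides}
#' }
#' An empty drug-disease intersection skips the downstream network stages
#' with a notice recorded in the summary.
#'
#' @param config a [SynthConfig-class], a list, or a path to a YAML/JSON
#'   config file.
#' @param outDir output directory (created if needed).
#' @param qMax ORA significance threshold (default 0.05).
#' @param rounds median-screen rounds (default 2).
#' @param topPairs docking pairs to keep in the ranked report (default 10).
#' @param verbose log stage progress to `message()`.
#' @return the run summary, invisibly (a named list).
#' @examples
#' \donttest{
#' cfg <- synthConfig(seed = 7, nCompounds = 50, nUniverse = 600,
#'                    sourceSizes = c(200L, 120L, 80L, 60L),
#'                    nTerms = 40L, ppiNodes = 60L, nHubs = 6L,
#'                    hubDegreeBoost = 12L)
#' summ <- runPipeline(cfg, outDir = tempfile("demo"), verbose = FALSE)
#' summ$counts
#' }
#' @export
runPipeline <- function(config, outDir, qMax = 0.05, rounds = 2L,
                        topPairs = 10L, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  synthetic <- is(config, "SynthConfig")
  if (!synthetic && is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!synthetic) {
    stopifnot(is.list(config))
    qMax <- config$qMax %||% qMax
    rounds <- config$rounds %||% rounds
    topPairs <- config$topPairs %||% topPairs
  }
  summary <- list(
    mode = if (synthetic) "synthetic" else "files",
    seed = if (synthetic) config@seed else NA,
    configHash = hashConfig(if (synthetic) cfgAsList(config) else config),
    counts = list(), notices = character())
  notice <- function(msg) {
    summary$notices <<- c(summary$notices, msg)
    if (verbose) message("[netpharm] notice: ", msg)
  }

  ## stage: compounds + ADMET
  compounds <- runStage("admet", verbose, {
    if (synthetic) genCompounds(config)
    else if (!is.null(config$compounds)) readCompoundTable(config$compounds)
    else NULL
  })
  kept <- NULL
  if (!is.null(compounds)) {
    obMin <- if (synthetic) OB_MIN_DEFAULT else config$obMin %||% OB_MIN_DEFAULT
    dlMin <- if (synthetic) DL_MIN_DEFAULT else config$dlMin %||% DL_MIN_DEFAULT
    kept <- screenCompounds(compounds, obMin, dlMin)
    writeResults(kept, file.path(outDir, "kept_compounds.csv"))
    summary$counts$compoundsTotal <- nrow(compounds)
    summary$counts$compoundsKept <- nrow(kept)
  } else notice("no compound table: ADMET stage skipped")

  ## stage: disease sources -> union, venn
  sources <- runStage("target_sets", verbose, {
    if (synthetic) genDiseaseSources(config)
    else if (length(config$diseaseSources)) lapply(config$diseaseSources, readGeneList)
    else list()
  })
  disease <- unionSources(if (length(sources)) sources else list(GeneSet()),
                          name = "disease-union")
  summary$counts$diseaseSources <- length(sources)
  summary$counts$diseaseUnion <- length(disease)
  writeResults(disease, file.path(outDir, "disease_union.txt"))
  if (length(sources) >= 2L && length(sources) <= 5L) {
    vr <- vennRegions(sources)
    writeResults(data.frame(region = names(vr), count = as.integer(vr),
                            stringsAsFactors = FALSE),
                 file.path(outDir, "venn_regions.csv"))
  }

  ## stage: drug targets -> intersection
  drugTargets <- runStage("drug_targets", verbose, {
    if (synthetic) {
      if (is.null(kept)) list() else genDrugTargets(config, kept, disease)
    } else if (!is.null(config$drugTargets)) readTargetMap(config$drugTargets)
    else list()
  })
  inter <- intersectDrugDisease(drugTargets, disease)
  summary$counts$drugTargetUnion <-
    length(unique(unlist(lapply(drugTargets, genes), use.names = FALSE)))
  summary$counts$intersection <- length(inter$intersection)
  writeResults(inter$intersection, file.path(outDir, "intersection.txt"))

  if (length(inter$intersection) == 0L) {
    notice("empty drug-disease intersection: enrichment and network stages skipped")
  } else {
    ## stage: enrichment
    runStage("enrichment", verbose, {
      ann <- if (synthetic) {
        genAnnotation(config, signalGenes = inter$intersection)
      } else if (!is.null(config$gmt)) {
        terms <- readGmt(config$gmt)
        list(terms = terms, planted = character(),
             categories = rep(NA_character_, length(terms)))
      } else NULL
      if (is.null(ann)) {
        notice("no annotation sets: enrichment stage skipped")
      } else {
        uniOra <- if (!synthetic && !is.null(config$universe)) {
          readGeneList(config$universe)
        } else if (synthetic) universeGenes(config) else NULL
        ora <- runOra(inter$intersection, ann$terms, universe = uniOra,
                      qMax = qMax, categories = ann$categories)
        writeResults(ora, file.path(outDir, "ora_results.csv"))
        summary$counts$termsTested <- nrow(ora)
        summary$counts$termsSignificant <- sum(ora$significant)
      }
      NULL
    })

    ## stage: bipartite compound-target network
    bip <- runStage("bipartite", verbose, buildBipartite(inter$perCompound))
    writeResults(bip, file.path(outDir, "bipartite_edges.tsv"))
    cdeg <- degreeCentrality(bip)[names(inter$perCompound)]
    cdeg <- sort(cdeg, decreasing = TRUE)
    writeResults(data.frame(compound = names(cdeg),
                            degree = as.integer(cdeg),
                            stringsAsFactors = FALSE),
                 file.path(outDir, "compound_degrees.csv"))
    summary$counts$bipartiteEdges <- igraph::ecount(bip)

    ## stage: PPI + median screen
    scr <- runStage("netanalysis", verbose, {
      ppi <- if (synthetic) {
        genPpi(config, nodes = inter$intersection)$graph
      } else if (!is.null(config$ppiEdges)) {
        readEdgeList(config$ppiEdges)
      } else NULL
      if (is.null(ppi) || igraph::vcount(ppi) == 0L) {
        notice("no PPI graph: hub screening skipped")
        NULL
      } else {
        writeResults(ppi, file.path(outDir, "ppi_edges.tsv"))
        s <- medianScreen(ppi, rounds = rounds)
        for (r in seq_len(nRounds(s))) {
          writeResults(centralityTable(hubSubgraph(s, r)),
                       file.path(outDir, sprintf("centrality_round%d.csv", r)))
        }
        writeResults(lapply(s@rounds, function(rr) as.list(rr@thresholds)),
                     file.path(outDir, "screen_thresholds.json"))
        writeResults(hubSubgraph(s), file.path(outDir, "hub_edges.tsv"))
        summary$counts$ppiNodes <- igraph::vcount(ppi)
        summary$counts$ppiEdges <- igraph::ecount(ppi)
        summary$counts$survivorsPerRound <-
          vapply(s@rounds, function(rr) length(rr@survivors), integer(1))
        summary$counts$hubSubnetworkEdges <-
          igraph::ecount(hubSubgraph(s))
        s
      }
    })

    ## stage: docking summary
    runStage("docking", verbose, {
      dock <- if (synthetic) {
        if (is.null(scr) || length(cdeg) == 0L) NULL
        else genDockingMatrix(config,
                              ligands = utils::head(names(cdeg), 5L),
                              receptors = survivors(scr))
      } else if (!is.null(config$docking)) {
        gradeEnergies(readEnergyTable(config$docking))
      } else NULL
      if (is.null(dock)) {
        notice("no docking energies: docking stage skipped")
      } else {
        writeResults(dock, file.path(outDir, "docking_graded.csv"))
        writeResults(rankPairs(dock, topPairs),
                     file.path(outDir, "docking_top_pairs.csv"))
        gc <- table(dock$grade)
        summary$counts$dockingGrades <-
          stats::setNames(as.list(as.integer(gc)), names(gc))
      }
      NULL
    })
  }

  ## file mode can report the hub-subnetwork edge count from a precomputed
  ## centrality table (degree sum / 2) when no PPI edge list is supplied
  if (!synthetic && !is.null(config$hubTable) &&
      is.null(summary$counts$hubSubnetworkEdges)) {
    tab <- readCentralityTable(config$hubTable)
    summary$counts$hubSubnetworkEdges <- sum(tab$degree) / 2
  }

  writeResults(summary, file.path(outDir, "run_summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Checks that require the study's supplementary target lists
#'
#' Two headline numbers of the original analysis - the size of the
#' drug-disease intersection and the top compound's degree in the
#' bipartite compound-target network - depend on full database exports
#' that are not redistributable at package scale. This helper runs both
#' computations when a directory supplies them and reports them as
#' unavailable otherwise. Expected layout: `compound_targets.tsv`
#' (two-column compound-target map, see [readTargetMap()]) and one or more
#' `disease_*.txt` gene lists (see [readGeneList()]).
#'
#' @param dir directory holding the supplementary files.
#' @return list with `available`; when `TRUE`, also `intersectionSize`,
#'   `topCompound` and `topDegree`.
#' @export
supplementaryChecks <- function(dir) {
  mapFile <- file.path(dir, "compound_targets.tsv")
  srcFiles <- if (dir.exists(dir)) {
    list.files(dir, pattern = "^disease_.*\\.txt$", full.names = TRUE)
  } else character()
  if (!file.exists(mapFile) || length(srcFiles) == 0L) {
    return(list(available = FALSE,
                missing = c(if (!file.exists(mapFile)) "compound_targets.tsv",
                            if (length(srcFiles) == 0L) "disease_*.txt")))
  }
  drugTargets <- readTargetMap(mapFile)
  disease <- unionSources(lapply(srcFiles, readGeneList), name = "disease")
  inter <- intersectDrugDisease(drugTargets, disease)
  bip <- buildBipartite(inter$perCompound)
  cdeg <- sort(degreeCentrality(bip)[names(inter$perCompound)],
               decreasing = TRUE)
  list(available = TRUE,
       intersectionSize = length(inter$intersection),
       topCompound = names(cdeg)[1L],
       topDegree = as.integer(cdeg[[1L]]))
}
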