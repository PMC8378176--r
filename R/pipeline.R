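#' Run the full essentiality-ranking pipeline
#'
#' Wires the stages end to end: read inputs, CoN-weight the network, NMTF
#' denoise/complete, build the transition matrix, compute annotation-based
#' initial scores, iterate the damped fixed point, sort, and (when a gold
#' list is supplied) evaluate. Writes a ranked score table
#' (`scores.tsv`: rank, protein, S_H, S_L, S_I, S_F), evaluation tables
#' when applicable (`topk_hits.tsv`, `pr_curve.csv`, `jackknife_curve.csv`)
#' and a JSON run manifest (effective configuration, seeds, package
#' versions, stage timings and stop reasons) into `outDir`. Any stage error
#' aborts with the stage name and removes partial outputs.
#'
#' @param edges path to the PPI edge list.
#' @param homology,localization annotation table paths (either may be
#'   `NULL`; missing annotations default to H = 0 / no compartments).
#' @param essential optional gold-standard list path; enables evaluation.
#' @param outDir output directory.
#' @param alpha,epsilon,rankMaxIter ranking parameters ([rankProteins()]).
#' @param k,nmtfSeed,nmtfMaxIter,relTol NMTF parameters ([nmtf()]).
#' @param rowRenormalize passed to [transitionMatrix()].
#' @param conDomain passed to [conMatrix()].
#' @param cutoffs top-k cutoffs for evaluation.
#' @return invisibly, a list with `scores` (data.frame), `report` (an
#'   [EvaluationReport-class] or `NULL`) and `manifest` (list).
#' @export
runPipeline <- function(edges, homology = NULL, localization = NULL,
                        essential = NULL, outDir,
                        alpha = 0.2, epsilon = 1e-6, rankMaxIter = 10000L,
                        k = 100L, nmtfSeed = 1L, nmtfMaxIter = 2000L,
                        relTol = 1e-6, rowRenormalize = TRUE,
                        conDomain = "all-pairs",
                        cutoffs = c(100L, 200L, 300L, 400L, 500L, 600L)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  timings <- list()
  stage <- "setup"
  out <- function(name) {
    p <- file.path(outDir, name)
    written <<- c(written, p)
    p
  }
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  tryCatch({
    net <- run_stage("read_inputs", readEdgeList(edges))
    ann <- run_stage("read_annotations",
                     readAnnotations(homology, localization, net))
    gold <- if (!is.null(essential))
      run_stage("read_gold", readEssentialList(essential, net)) else NULL

    con <- run_stage("con_weighting", conMatrix(net, domain = conDomain))
    fac <- run_stage("nmtf", nmtf(con, k = k, seed = nmtfSeed,
                                  maxIter = nmtfMaxIter, relTol = relTol))
    Pst <- run_stage("transition_matrix",
                     transitionMatrix(reconstruct(fac),
                                      rowRenormalize = rowRenormalize))
    sh <- run_stage("initial_scores", homologyScores(ann))
    sl <- localizationScores(ann)
    si <- initialScores(sh, sl)
    sf <- run_stage("ranking", rankProteins(Pst, si, alpha = alpha,
                                            epsilon = epsilon,
                                            maxIter = rankMaxIter))
    ranking <- run_stage("sort", topProteins(sf))

    ord <- match(ranking, proteinIds(net))
    scores <- data.frame(rank = seq_along(ranking), protein = ranking,
                         SH = unname(scoreValues(sh))[ord],
                         SL = unname(scoreValues(sl))[ord],
                         SI = unname(scoreValues(si))[ord],
                         SF = unname(scoreValues(sf))[ord])
    utils::write.table(scores, out("scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    report <- NULL
    if (!is.null(gold) && length(gold)) {
      report <- run_stage("evaluation", evaluateRanking(ranking, gold, cutoffs))
      utils::write.table(
        data.frame(K = names(report@topkHits), hits = report@topkHits),
        out("topk_hits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.csv(report@prPoints, out("pr_curve.csv"), row.names = FALSE)
      utils::write.csv(report@jackknifePoints, out("jackknife_curve.csv"),
                       row.names = FALSE)
    }

    manifest <- list(
      inputs = list(edges = edges, homology = homology,
                    localization = localization, essential = essential),
      config = list(alpha = alpha, epsilon = epsilon,
                    rankMaxIter = rankMaxIter, k = k, nmtfSeed = nmtfSeed,
                    nmtfMaxIter = nmtfMaxIter, relTol = relTol,
                    rowRenormalize = rowRenormalize, conDomain = conDomain,
                    cutoffs = cutoffs),
      network = list(nProteins = length(proteinIds(net)),
                     nEdges = sum(assocMatrix(net)) / 2),
      nmtf = list(iterations = fac@iterations, stopReason = fac@stopReason,
                  finalObjective = utils::tail(objectiveTrace(fac), 1L)),
      ranking = sf@metadata,
      stages = names(timings), timings = timings,
      versions = list(package = as.character(utils::packageVersion("ntmep")),
                      R = paste(R.version$major, R.version$minor, sep = ".")))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(scores = scores, report = report, manifest = manifest))
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
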