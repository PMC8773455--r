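#' Run the full analysis pipeline
#'
#' Chains the stages end to end and writes plain-text artifacts to
#' `outdir`: simulate (or load) control-region data, call and mask
#' variants, classify haplogroups, per-population diversity, p-distance
#' matrix, frequency PCA, classical MDS, haplotype-sharing matrices
#' (overall and per origin class), ancient-lineage tracing, plus a JSON
#' run manifest (package version, seed, parameters, output checksums) and
#' a `run.log` recording every dropped population with the reason.
#'
#' @param outdir output directory (created).
#' @param seed integer seed driving the simulation; mandatory when
#'   simulating.
#' @param fasta,popmap optional input FASTA and population-map paths; when
#'   `NULL` a synthetic dataset is generated from [demo_populations()].
#' @param sim_scale scale factor for the demo population sizes.
#' @param tree,reference,macro_table analysis resources (packaged
#'   defaults).
#' @param window_classify,window_diversity,window_sharing analysis windows
#'   (defaults: control region for classification, HVS1 for diversity,
#'   nps 16024-16569 for sharing and distances).
#' @param min_n minimum population size for frequency/distance analyses.
#' @param ancient ancient-records data frame (packaged synthetic default).
#' @param trace_lineages lineages to trace.
#' @param band,cutoff_ce,offset_range tracing parameters.
#' @return invisibly, a list with the computed objects and artifact paths.
#' @export
run_pipeline <- function(outdir, seed = NULL, fasta = NULL, popmap = NULL,
                         sim_scale = 1,
                         tree = load_packaged_tree(),
                         reference = packaged_reference(),
                         macro_table = load_macro_table(),
                         window_classify = standard_window("cr"),
                         window_diversity = standard_window("hvs1"),
                         window_sharing = standard_window("eurasian546"),
                         min_n = 30L,
                         ancient = load_packaged_ancient(),
                         trace_lineages = default_ancient_scenario()$lineages,
                         band = c(85, 125), cutoff_ce = -1000,
                         offset_range = c(20, 40)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) writeLines(sprintf(...), log_con)
  paths <- list(log = log_path)
  stage <- function(name, expr) {
    marker <- file.path(outdir, paste0(name, ".partial"))
    file.create(marker)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        logf("[%s] %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    unlink(marker)
    logf("[%s] done", name)
    res
  }

  # --- input stage: simulate or load ---------------------------------
  if (is.null(fasta)) {
    if (is.null(seed)) stop("simulating requires an explicit seed")
    sim <- stage("simulate", {
      cfg <- sim_config(demo_populations(tree, scale = sim_scale), seed = seed)
      s <- simulate_modern(cfg, tree, reference)
      p <- write_simulation(s, outdir)
      paths$fasta <- p$fasta; paths$popmap <- p$popmap; paths$truth <- p$truth
      s
    })
    seqs <- sim$sequences
    pops <- stats::setNames(sim$populations$population, sim$populations$sample_id)
  } else {
    sim <- NULL
    dat <- stage("load", parse_fasta(fasta, popmap,
                                     default_population = "unspecified"))
    seqs <- stats::setNames(dat$sequence, dat$sample_id)
    pops <- stats::setNames(dat$population, dat$sample_id)
  }

  # --- variant calling + masking -------------------------------------
  profiles <- stage("call_variants", {
    pr <- call_variants_many(seqs, reference, window_classify,
                             populations = pops)
    lapply(pr, mask_heteroplasmies)
  })

  # --- classification -------------------------------------------------
  classifications <- stage("classify", {
    cl <- classify_all(profiles, tree, macro_table)
    f <- file.path(outdir, "classifications.tsv")
    utils::write.table(cl, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$classifications <- f
    cl
  })

  # --- diversity ------------------------------------------------------
  diversity <- stage("diversity", {
    mat <- build_aligned_matrix(profiles, reference, window_diversity)
    ds <- diversity_summary(mat)
    f <- file.path(outdir, "diversity.tsv")
    utils::write.table(ds, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$diversity <- f
    ds
  })

  # --- distances + MDS ------------------------------------------------
  mat_share <- build_aligned_matrix(profiles, reference, window_sharing)
  distances <- stage("distance", {
    d <- build_distance_matrix(mat_share, min_n = min_n)
    f <- file.path(outdir, "distance_matrix.tsv")
    utils::write.table(cbind(population = rownames(d), as.data.frame(d)), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths$distance <- f
    d
  })
  mds <- stage("mds", {
    m <- classical_mds(distances, n_axes = min(2L, nrow(distances) - 1L))
    f <- file.path(outdir, "mds_coordinates.tsv")
    utils::write.table(cbind(population = rownames(m$coordinates),
                             as.data.frame(m$coordinates)),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$mds <- f
    m
  })

  # --- frequency PCA --------------------------------------------------
  pca <- stage("pca", {
    freq <- build_frequency_matrix(classifications, macro_table, min_n = min_n)
    fit <- pca_frequencies(freq, n_axes = min(2L, nrow(freq) - 1L, ncol(freq)))
    f <- file.path(outdir, "pca_coordinates.tsv")
    utils::write.table(cbind(population = rownames(fit$coordinates),
                             as.data.frame(fit$coordinates)),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    fe <- file.path(outdir, "pca_explained.tsv")
    utils::write.table(data.frame(axis = seq_along(fit$explained),
                                  explained = fit$explained),
                       fe, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$pca <- f; paths$pca_explained <- fe
    fit
  })

  # --- haplotype sharing ---------------------------------------------
  sharing <- stage("share", {
    out <- lapply(c(all = "all", EAs = "EAs", WEu = "WEu"), function(filt) {
      sets <- haplotype_sets(profiles, window_sharing, origin_filter = filt,
                             classifications = classifications)
      sets <- sets[lengths(sets) > 0L]
      if (length(sets) < 2L) {
        logf("[share] origin filter %s: fewer than 2 non-empty populations, skipped", filt)
        return(NULL)
      }
      sharing_matrix(sets, origin_filter = filt)
    })
    long <- do.call(rbind, lapply(out[!vapply(out, is.null, TRUE)],
                                  function(s) s$long))
    f <- file.path(outdir, "sharing.tsv")
    utils::write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$sharing <- f
    out
  })

  # --- ancient tracing ------------------------------------------------
  trace <- stage("trace", {
    tr <- trace_report(trace_lineages, ancient, band = band,
                       cutoff_ce = cutoff_ce, offset_range = offset_range)
    f <- file.path(outdir, "trace_results.tsv")
    utils::write.table(tr$results, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fs <- file.path(outdir, "trace_summary.json")
    jsonlite::write_json(tr$summary, fs, auto_unbox = TRUE)
    paths$trace <- f; paths$trace_summary <- fs
    tr
  })

  # --- manifest -------------------------------------------------------
  manifest <- stage("manifest", {
    arts <- unlist(paths[setdiff(names(paths), "log")])
    m <- list(
      package = "mtlineage",
      version = as.character(utils::packageVersion("mtlineage")),
      seed = seed,
      parameters = list(
        sim_scale = sim_scale, min_n = min_n,
        window_classify = c(window_classify$start, window_classify$end),
        window_diversity = c(window_diversity$start, window_diversity$end),
        window_sharing = c(window_sharing$start, window_sharing$end),
        band = band, cutoff_ce = cutoff_ce, offset_range = offset_range),
      outputs = as.list(stats::setNames(unname(tools::md5sum(arts)),
                                        basename(arts))))
    f <- file.path(outdir, "manifest.json")
    jsonlite::write_json(m, f, auto_unbox = TRUE, pretty = TRUE)
    paths$manifest <- f
    m
  })

  invisible(list(simulation = sim, profiles = profiles,
                 classifications = classifications, diversity = diversity,
                 distances = distances, mds = mds, pca = pca,
                 sharing = sharing, trace = trace, manifest = manifest,
                 paths = paths))
}
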