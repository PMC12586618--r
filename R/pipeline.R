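# End-to-end pipeline orchestration: simulate/ingest -> profiles -> gaps ->
# duration normalization -> functional regression -> dissimilarity clustering,
# with declarative configuration and a reproducibility manifest.

.defaultConfig <- function() {
  list(
    mode = "synthetic",
    out_dir = "artikin-run",
    seed = 1L,
    design = list(),            # overrides for cohortDesign()
    render = FALSE,             # synthetic mode: render phantom images and re-extract
    phantom = list(),           # overrides for phantomSpec()
    extraction = list(method = "raster", gmm_tol = 1e-8, gmm_max_iter = 500L),
    ingest = list(metadata_csv = NULL, landmarks_csv = NULL,
                  overrides_csv = NULL, spacing = 1.4, fps = 55),
    prep = list(min_reps = 1L, max_reps = 10L, drop_first = 0L),
    fosr = list(enabled = TRUE, sites = "all", reference = "FS",
                test = "wald", n_perm = 199L),
    cluster = list(linkage = "ward", k_range = 2:6, mode = "repetition",
                   newick = FALSE)
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
      .mergeConfig(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

.requireField <- function(cfg, path) {
  x <- cfg
  for (p in strsplit(path, "$", fixed = TRUE)[[1]]) x <- x[[p]]
  if (is.null(x))
    stop(sprintf("configuration error: required field '%s' is missing", path))
  x
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields override the documented defaults.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  .mergeConfig(.defaultConfig(), yaml::read_yaml(path))
}

# trial-level extraction: image sequence -> long width table
.extractTrial <- function(seq, grid, cfg_ex, subject, group, repetition,
                          overrides = NULL) {
  res <- extractWidths(seq, grid, method = cfg_ex$method, overrides = overrides,
                       gmm_tol = cfg_ex$gmm_tol,
                       gmm_max_iter = cfg_ex$gmm_max_iter)
  cbind(data.frame(subject = subject, group = group, repetition = repetition),
        res$widths)
}

#' Run the articulatory-kinematics pipeline end to end
#'
#' In synthetic mode a cohort is generated from the design (optionally
#' rendered to phantom images and re-extracted through the segmentation
#' chain); in ingest mode image stacks listed in the trial metadata are read
#' and extracted with per-trial grids. Trajectories are then normalized to the
#' cohort-median duration, modelled per site by function-on-scalar regression,
#' and clustered by energy distances between inter-site dissimilarity
#' profiles. All module outputs plus a manifest are written under
#' `config$out_dir`.
#'
#' @param config configuration list (see `artikin:::.defaultConfig()` for the
#'   fields and defaults) or path to a YAML file.
#' @return run report list (invisibly): `t_star`, `k`, `fisher_p`,
#'   `allocation_fraction`, `pc1_share`, `fosr` (per-site edf/p), `files`.
#' @export
#' @examples
#' \donttest{
#' cfg <- list(out_dir = tempfile(), seed = 7,
#'             design = list(n_subjects_per_group = c(FS = 4, AWS = 4),
#'                           n_repetitions = 3),
#'             fosr = list(enabled = FALSE))
#' rep <- runPipeline(cfg)
#' }
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- .mergeConfig(.defaultConfig(), config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(path) { files <<- c(files, path); path }

  if (cfg$mode == "synthetic") {
    design <- do.call(cohortDesign, c(cfg$design,
                                      if (is.null(cfg$design$seed))
                                        list(seed = cfg$seed)))
    bundle <- genTrajectories(design)
    if (isTRUE(cfg$render)) {
      spec <- do.call(phantomSpec, cfg$phantom)
      study <- renderPhantom(bundle, spec, seed = cfg$seed + 1L)
      grid <- study@grid
      traj <- do.call(rbind, lapply(names(phantomSequences(study)), function(id) {
        tru <- phantomTruth(study)
        key <- unique(tru[paste(tru$subject, tru$repetition, sep = "_r") == id,
                          c("subject", "group", "repetition")])
        .extractTrial(phantomSequences(study)[[id]], grid, cfg$extraction,
                      key$subject, key$group, key$repetition)
      }))
      traj$width <- traj$width_px
      .writeJson(list(landmarks = spec@landmarks,
                      lines = gridLines(grid)),
                 emit(file.path(out, "grid.json")))
    } else {
      traj <- bundleData(bundle)
    }
  } else if (cfg$mode == "ingest") {
    meta_csv <- .requireField(cfg, "ingest$metadata_csv")
    lm_csv <- .requireField(cfg, "ingest$landmarks_csv")
    meta <- utils::read.csv(meta_csv)
    lmt <- utils::read.csv(lm_csv)
    ovr <- if (!is.null(cfg$ingest$overrides_csv))
      utils::read.csv(cfg$ingest$overrides_csv) else NULL
    traj <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
      m <- meta[i, ]
      trial_id <- sprintf("%s_r%d", m$subject, m$repetition)
      seq <- readImageStack(m$path, spacing = cfg$ingest$spacing,
                            fps = cfg$ingest$fps)
      grid <- regridPerTrial(lmt, trial_id)
      ov <- if (!is.null(ovr)) ovr[ovr$trial == trial_id, , drop = FALSE] else NULL
      .extractTrial(seq, grid, cfg$extraction, m$subject, m$group,
                    m$repetition, overrides = ov)
    }))
    traj$width <- traj$width_px
  } else stop("configuration error: mode must be 'synthetic' or 'ingest'")

  .writeCsv(traj, emit(file.path(out, "trajectories.csv")))

  ts <- assembleTrajectories(traj, min_reps = cfg$prep$min_reps,
                             max_reps = cfg$prep$max_reps,
                             drop_first = cfg$prep$drop_first)
  ex <- exclusionLog(ts)
  .writeJson(list(t_star = tStar(ts), n_units = ncol(ts),
                  n_exclusions = if (is.null(ex)) 0L else nrow(ex)),
             emit(file.path(out, "provenance.json")))

  fosr_out <- list()
  if (isTRUE(cfg$fosr$enabled)) {
    sites <- if (identical(cfg$fosr$sites, "all")) .SITES else cfg$fosr$sites
    curves <- list()
    for (s in sites) {
      fit <- fitFosr(ts, s, fosrSpec(reference = cfg$fosr$reference))
      tst <- if (cfg$fosr$test == "permutation")
        testGroupEffect(fit, "permutation", n_perm = cfg$fosr$n_perm,
                        seed = cfg$seed + 2L)
      else testGroupEffect(fit, "wald")
      fosr_out[[s]] <- list(edf = as.list(fit@edf), statistic = tst$statistic,
                            p = tst$p)
      curves[[s]] <- rbind(predictCurves(fit, "group"),
                           predictCurves(fit, "subject"))
    }
    .writeJson(fosr_out, emit(file.path(out, "fosr_summary.json")))
    .writeCsv(do.call(rbind, curves), emit(file.path(out, "fosr_curves.csv")))
  }

  tab <- pairDissim(ts)
  .writeCsv(tab, emit(file.path(out, "pair_dissim.csv")))
  .writeCsv(subjectAverage(tab), emit(file.path(out, "subject_dissim.csv")))
  D <- subjectDistanceMatrix(tab, mode = cfg$cluster$mode)
  .writeCsv(as.data.frame(D), emit(file.path(out, "distance_matrix.csv")))
  res <- clusterReport(D, linkage = cfg$cluster$linkage,
                       k_range = cfg$cluster$k_range)
  pca <- pcaDissim(subjectAverage(tab))
  .writeJson(list(k = selectedK(res), linkage = res@linkage,
                  cindex = as.list(res@cindex_curve),
                  labels = stats::setNames(as.list(clusterLabels(res)),
                                           rownames(D)),
                  contingency = as.data.frame(res@contingency),
                  fisher_p = res@fisher_p,
                  allocation_fraction = res@allocation$fraction,
                  pca_shares = pca$shares),
             emit(file.path(out, "cluster_report.json")))
  .writeCsv(data.frame(merge1 = res@tree$merge[, 1],
                       merge2 = res@tree$merge[, 2],
                       height = res@tree$height),
            emit(file.path(out, "dendrogram.csv")))
  if (isTRUE(cfg$cluster$newick) && requireNamespace("ape", quietly = TRUE)) {
    tree <- res@tree; tree$labels <- rownames(D)
    ape::write.tree(ape::as.phylo(tree),
                    emit(file.path(out, "dendrogram.nwk")))
  }

  cfg_path <- .writeJson(cfg, emit(file.path(out, "config.json")))
  manifest <- list(
    package = "artikin",
    version = as.character(utils::packageVersion("artikin")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    t_star = tStar(ts),
    n_exclusions = if (is.null(ex)) 0L else nrow(ex),
    outputs = basename(files))
  .writeJson(manifest, file.path(out, "manifest.json"))

  invisible(list(t_star = tStar(ts), k = selectedK(res),
                 fisher_p = res@fisher_p,
                 allocation_fraction = res@allocation$fraction,
                 pc1_share = pca$shares[1], fosr = fosr_out,
                 files = c(files, file.path(out, "manifest.json"))))
}
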