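#' Pipeline run configuration
#'
#' Collects every stage parameter of an end-to-end run. Input is either a
#' simulation block (a [sim_config()]) or a directory of peak-list files
#' with a sample/group table. The configuration is validated up front and
#' serialized into the output directory so a run is reproducible from its
#' config alone.
#'
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param input_dir directory of `<sample>.txt` peak lists (used when
#'   `simulate` is `NULL`); must contain `samples.tsv` (sample, group).
#' @param out_dir output directory.
#' @param sn_threshold,mz_range S/N picking cutoff and recorded mass window.
#' @param calibration_ref reference m/z vector (default: built-in list).
#' @param align_window alignment window, ppm.
#' @param triplet_size replicates per group.
#' @param assign_tol assignment tolerance, ppm.
#' @param isotope_rel_tol isotopologue intensity tolerance.
#' @param remd_path optional REMD library file (default: built-in library).
#' @param class_map_path optional formula-to-class table.
#' @param contrast character pair `c(case_group, control_group)` for
#'   regulation labels.
#' @param fc_threshold,alpha regulation thresholds.
#' @param second_hits,control,acute dataset-splitting groups for PCA
#'   (`NULL` skips the split and analyzes all samples together).
#' @param seed RNG seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = sim_config(), input_dir = NULL,
                       out_dir = tempfile("mdinet_run_"),
                       sn_threshold = 4, mz_range = c(129, 1000),
                       calibration_ref = NULL, align_window = 1,
                       triplet_size = 3, assign_tol = 0.5,
                       isotope_rel_tol = 0.5, remd_path = NULL,
                       class_map_path = NULL,
                       contrast = c("virus_acute", "control"),
                       fc_threshold = 1.5, alpha = 0.05,
                       second_hits = "virus_np", control = "control",
                       acute = "virus_acute", seed = 1L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("config needs either a simulation block or an input directory")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir)
  if (!is.null(remd_path) && !file.exists(remd_path))
    stop("REMD library file does not exist: ", remd_path)
  if (!is.null(class_map_path) && !file.exists(class_map_path))
    stop("class map file does not exist: ", class_map_path)
  stopifnot(length(contrast) == 2, fc_threshold >= 1, align_window > 0)
  structure(list(simulate = simulate, input_dir = input_dir,
                 out_dir = out_dir, sn_threshold = sn_threshold,
                 mz_range = mz_range, calibration_ref = calibration_ref,
                 align_window = align_window, triplet_size = triplet_size,
                 assign_tol = assign_tol, isotope_rel_tol = isotope_rel_tol,
                 remd_path = remd_path, class_map_path = class_map_path,
                 contrast = contrast, fc_threshold = fc_threshold,
                 alpha = alpha, second_hits = second_hits, control = control,
                 acute = acute, seed = as.integer(seed)),
            class = "run_config")
}

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or read) peak lists -> S/N and mass-range filter ->
#' linear calibration -> ppm alignment -> replicate filter -> formula
#' assignment (combinatorial + isotope validation + network propagation) ->
#' IQR-Euclidean normalization -> regulation labels -> MDiN + MDEA + class
#' summary -> per-dataset Z-scaling, PCA and score group tests. All stage
#' outputs are written under the configured output directory together with a
#' JSON manifest (parameters, seed, per-stage record counts, file
#' checksums).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`fm_raw`,
#'   `fm_filtered`, `fm_norm`, `assignments`, `labels`, `net`, `enrichment`,
#'   `classes`, `pca`, `score_tests`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister")
  counts <- list()

  # --- input ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- tryCatch(simulate_metabolome(config$simulate),
                    error = function(e) stage_fail("simulate", e))
    peaklists <- sim$peaklists
    samples <- sim$samples
    write_simulation(sim, file.path(config$out_dir, "simulated"))
  } else {
    samples <- utils::read.table(file.path(config$input_dir, "samples.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    peaklists <- lapply(samples$sample, function(s)
      read_peak_list(file.path(config$input_dir, paste0(s, ".txt")),
                     sample = s))
    names(peaklists) <- samples$sample
    sim <- NULL
  }
  counts$peaks_in <- sum(vapply(peaklists, nrow, integer(1)))

  # --- S/N filter and calibration ---------------------------------------
  ref <- if (is.null(config$calibration_ref)) calibration_reference()
  else config$calibration_ref
  calres <- list()
  for (nm in names(peaklists)) {
    p <- tryCatch(sn_filter(peaklists[[nm]], config$sn_threshold,
                            config$mz_range),
                  error = function(e) stage_fail(paste0("sn_filter:", nm), e))
    cal <- tryCatch(calibrate(p, ref),
                    error = function(e) stage_fail(paste0("calibrate:", nm), e))
    peaklists[[nm]] <- cal$peaks
    calres[[nm]] <- cal$calibration
  }
  counts$peaks_after_sn <- sum(vapply(peaklists, nrow, integer(1)))

  # --- alignment and replicate filter ------------------------------------
  groups <- setNames(samples$group, samples$sample)
  fm_raw <- tryCatch(align(peaklists, window = config$align_window,
                           groups = groups),
                     error = function(e) stage_fail("align", e))
  counts$features_aligned <- length(fm_raw$mz)
  fm_filtered <- tryCatch(triplicate_filter(fm_raw, config$triplet_size),
                          error = function(e) stage_fail("triplicate_filter", e))
  counts$features_triplicate <- length(fm_filtered$mz)

  # --- formula assignment -------------------------------------------------
  remds <- tryCatch(load_remds(config$remd_path),
                    error = function(e) stage_fail("load_remds", e))
  ann <- tryCatch(assign_formulas(fm_filtered, tol = config$assign_tol,
                                  rel_tol = config$isotope_rel_tol,
                                  remds = remds),
                  error = function(e) stage_fail("assign_formulas", e))
  counts$formulas_assigned <-
    sum(ann$assignments$status != "unassigned")
  write_assignments(ann, file.path(config$out_dir, "assignments.tsv"))

  # --- normalization and regulation labels -------------------------------
  fm_norm <- tryCatch(iqr_euclidean_normalize(fm_filtered),
                      error = function(e) stage_fail("normalize", e))
  write_feature_matrix(fm_norm, file.path(config$out_dir,
                                          "feature_matrix_normalized.tsv"))
  labels <- tryCatch(
    select_nodes_of_interest(fm_norm, config$contrast[1], config$contrast[2],
                             fc_threshold = config$fc_threshold,
                             alpha = config$alpha),
    error = function(e) stage_fail("select_nodes_of_interest", e))
  labels$formula <- ann$assignments$formula
  counts$nodes_of_interest <- sum(labels$label != "unchanged")

  # --- MDiN, MDEA, class summary -----------------------------------------
  assigned <- ann$assignments[!is.na(ann$assignments$formula), ]
  net <- tryCatch(build_mdin(assigned, remds),
                  error = function(e) stage_fail("build_mdin", e))
  counts$mdin_nodes <- igraph::vcount(net)
  counts$mdin_edges <- igraph::ecount(net)
  interest <- unique(labels$formula[labels$label != "unchanged" &
                                      !is.na(labels$formula)])
  enrichment <- if (igraph::ecount(net) > 0) {
    mdea(net, interest)
  } else NULL
  classes <- if (!is.null(config$class_map_path)) {
    class_summary(labels, config$class_map_path)
  } else if (!is.null(sim)) {
    class_summary(labels, data.frame(formula = sim$truth$formula,
                                     class = sim$truth$class,
                                     stringsAsFactors = FALSE))
  } else class_summary(labels)
  write_mdin_edgelist(net, file.path(config$out_dir, "mdin_edges.tsv"),
                      labels = labels)
  write_mdin_graphml(net, file.path(config$out_dir, "mdin.graphml"))
  if (!is.null(enrichment)) {
    utils::write.table(enrichment, file.path(config$out_dir, "mdea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(classes, file.path(config$out_dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- multivariate -------------------------------------------------------
  datasets <- if (!is.null(config$second_hits)) {
    split_datasets(fm_norm, config$second_hits, config$control, config$acute)
  } else list(all = fm_norm)
  pca_res <- list(); score_tests <- list()
  for (nm in names(datasets)) {
    z <- suppressWarnings(ztransform(datasets[[nm]]))
    pr <- pca_features(z)
    pca_res[[nm]] <- pr
    st <- score_group_test(pr)
    st$dataset <- nm
    score_tests[[nm]] <- st
  }
  score_tests <- do.call(rbind, score_tests)
  utils::write.table(score_tests, file.path(config$out_dir,
                                            "pc_score_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mdinet")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("simulate", "calibration_ref"))],
    simulation = if (!is.null(config$simulate))
      config$simulate[setdiff(names(config$simulate), "effect_map")],
    remd_library = if (is.null(config$remd_path)) "built-in" else config$remd_path,
    calibration = calres,
    stage_counts = counts,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(list(fm_raw = fm_raw, fm_filtered = fm_filtered,
                 fm_norm = fm_norm, assignments = ann, labels = labels,
                 net = net, enrichment = enrichment, classes = classes,
                 pca = pca_res, score_tests = score_tests,
                 manifest = manifest, sim = sim, samples = samples))
}
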