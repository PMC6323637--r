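#' Read a directory of per-subject connectome matrices
#'
#' Reads every `*.tsv` file in `path` as a square numeric matrix (no
#' header, tab-separated), validates symmetry and equal dimensions, and
#' returns the matrices in lexicographic file order with the file stem as
#' subject id.
#'
#' @param path Directory of TSV matrices.
#' @param tol Symmetry tolerance (default 1e-8).
#' @return A list with `connectomes` (list of matrices) and `subject_ids`.
#' @export
read_connectome_dir <- function(path, tol = 1e-8) {
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) < 1L) stop("no .tsv files found in ", path)
  mats <- list()
  dim0 <- NULL
  for (f in files) {
    A <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    dimnames(A) <- NULL
    if (nrow(A) != ncol(A)) stop("matrix in '", basename(f), "' is not square")
    if (is.null(dim0)) dim0 <- nrow(A)
    if (nrow(A) != dim0) {
      stop("matrix in '", basename(f), "' has dimension ", nrow(A),
           ", expected ", dim0)
    }
    if (max(abs(A - t(A))) > tol) {
      stop("matrix in '", basename(f), "' is not symmetric (tolerance ", tol, ")")
    }
    mats[[length(mats) + 1L]] <- A
  }
  list(connectomes = mats,
       subject_ids = sub("\\.tsv$", "", basename(files)))
}

#' Write per-subject connectomes to a directory of TSV matrices
#'
#' The inverse of [read_connectome_dir()]; one headerless tab-separated
#' matrix per subject, named `<subject_id>.tsv`.
#'
#' @param tensor An `adjacency_tensor`, or a list of matrices.
#' @param path Output directory (created if missing).
#' @param subject_ids Subject ids; defaults to the tensor's.
#' @return Invisibly, the written file paths.
#' @export
write_connectome_dir <- function(tensor, path, subject_ids = NULL) {
  if (is.list(tensor)) {
    mats <- tensor
  } else {
    S <- dim(tensor)[3L]
    mats <- lapply(seq_len(S), function(s) tensor[, , s])
  }
  if (is.null(subject_ids)) subject_ids <- attr(tensor, "subject_ids")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_along(mats))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, paste0(subject_ids, ".tsv"))
  for (s in seq_along(mats)) {
    utils::write.table(format(mats[[s]], digits = 17, trim = TRUE),
                       files[s], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(files)
}

#' Read regional time series with a sidecar JSON giving the TR
#'
#' The series file is a headerless TSV, one row per region and one column
#' per timepoint; the sidecar `<stem>.json` must provide
#' `sampling_interval` (seconds). Returns the pieces
#' [connectome_from_timeseries()] expects.
#'
#' @param path Path to the `.tsv` series file.
#' @return A list with `values` (regions x timepoints matrix) and
#'   `sampling_interval`.
#' @export
read_timeseries <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  sidecar <- sub("\\.tsv$", ".json", path)
  if (!file.exists(sidecar)) {
    stop("sidecar JSON '", basename(sidecar), "' with the sampling interval is missing")
  }
  meta <- jsonlite::read_json(sidecar)
  tr <- meta$sampling_interval
  if (is.null(tr) || !is.numeric(tr) || tr <= 0) {
    stop("sidecar '", basename(sidecar), "' must contain a positive `sampling_interval`")
  }
  if (anyNA(values)) stop("time series in '", basename(path), "' contain missing values")
  list(values = values, sampling_interval = tr)
}

#' Read a parcellation table
#'
#' A parcellation maps every region to a named cognitive system. The file
#' is a TSV with a header containing at least `region_id` (1-based,
#' contiguous) and `system`.
#'
#' @param path TSV file path.
#' @return A data frame with columns `region_id` and `system` (plus any
#'   extra columns, e.g. coordinates).
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("region_id", "system") %in% names(tab))) {
    stop("parcellation needs `region_id` and `system` columns")
  }
  if (anyDuplicated(tab$region_id) ||
      !identical(sort(as.integer(tab$region_id)), seq_len(nrow(tab)))) {
    stop("`region_id` must be unique and contiguous from 1")
  }
  if (anyNA(tab$system) || any(tab$system == "")) {
    stop("every region needs a system label")
  }
  tab[order(tab$region_id), , drop = FALSE]
}

#' Run the full edge-hypergraph pipeline
#'
#' Orchestrates the analysis end to end: adjacency tensor -> retained edge
#' vectors -> thresholded edge-by-edge hypergraph -> Louvain partition ->
#' hyperedges -> archetype classification -> nodal scores -> connector
#' classification and enrichment -> star-vs-module cohesion comparison ->
#' developmental models. Stages that need optional inputs (a system map for
#' scores and cohesion, covariates for the developmental models) are run
#' when those inputs are present.
#'
#' @param tensor An `adjacency_tensor` (e.g. from [generate_cohort()] or
#'   [stack_connectomes()]).
#' @param covariates Optional data frame with `age` and `motion` aligned
#'   with the tensor's subjects.
#' @param system_map Optional character vector assigning every region to a
#'   system (enables nodal score normalization and the cohesion stage).
#' @param min_strength,alpha,gamma,n_restarts,min_size,tau,n_null,Q,fdr_q
#'   Stage parameters; see the stage functions.
#' @param enrichment Run the subtype-enrichment stage when connectors are
#'   assigned (default `TRUE`); the null-replicate loop is the pipeline's
#'   most expensive stage after community detection.
#' @param seed Master seed for all randomized stages.
#' @param output_dir Optional directory; when given, stage outputs are
#'   written as TSV/JSON files together with the resolved configuration.
#'
#' @return A list with the outputs of every stage that ran: `edge_index`,
#'   `W`, `H`, `partition`, `hyperedges`, `archetypes`, `labels`, `scores`,
#'   `bridges`, `modules`, `connectors`, `enrichment`, `cohesion`,
#'   `age_effects`, `development`, and the resolved `config`.
#' @export
run_pipeline <- function(tensor, covariates = NULL, system_map = NULL,
                         min_strength = 0.07, alpha = 0.05, gamma = 1,
                         n_restarts = 100L, min_size = 2L, tau = 0.9,
                         n_null = 10000L, Q = 0.05, fdr_q = 0.01,
                         enrichment = TRUE, seed = 1L, output_dir = NULL) {
  d <- dim(tensor)
  if (length(d) != 3L || d[1L] != d[2L]) {
    stop("stage input: `tensor` must be regions x regions x subjects")
  }
  if (!is.null(covariates)) {
    if (!all(c("age", "motion") %in% names(covariates))) {
      stop("stage development: covariates need `age` and `motion` columns")
    }
    if (nrow(covariates) != d[3L]) {
      stop("stage development: covariates rows (", nrow(covariates),
           ") do not match subjects (", d[3L], ")")
    }
  }
  if (!is.null(system_map) && length(system_map) != d[1L]) {
    stop("stage scores: `system_map` must label all ", d[1L], " regions")
  }
  config <- list(min_strength = min_strength, alpha = alpha, gamma = gamma,
                 n_restarts = n_restarts, min_size = min_size, tau = tau,
                 n_null = n_null, Q = Q, fdr_q = fdr_q, seed = seed,
                 n_regions = d[1L], n_subjects = d[3L],
                 package_version = as.character(utils::packageVersion("edgehyper")))
  out <- list(config = config)

  index <- build_edge_index(d[1L])
  W <- extract_edge_vectors(tensor, index, min_strength = min_strength)
  H <- build_hypergraph(W, alpha = alpha)
  partition <- louvain_partition(H, gamma = gamma, n_restarts = n_restarts,
                                 seed = seed)
  hyperedges <- extract_hyperedges(partition, min_size = min_size, H = H)
  archetypes <- lapply(hyperedges, classify_hyperedge, tau = tau)
  labels <- vapply(archetypes, `[[`, "", "label")
  out[c("edge_index", "W", "H", "partition", "hyperedges", "archetypes")] <-
    list(index, W, H, partition, hyperedges, archetypes)
  out$labels <- labels
  out$fraction_negative <- attr(H, "fraction_negative")

  out$scores <- nodal_scores(hyperedges, archetypes, d[1L], system_map)

  is_bridge <- labels == "bridge"
  out$modules <- fundamental_modules(hyperedges, archetypes)
  if (any(is_bridge) && length(out$modules) > 0L) {
    out$bridges <- lapply(archetypes[is_bridge], function(a) a$bipartition)
    # the analytic null keeps power under the joint BH family, whose size
    # scales with the number of recovered modules
    out$connectors <- classify_connectors(out$bridges, out$modules, d[1L],
                                          Q = Q, n_null = n_null,
                                          seed = seed, method = "exact")
    if (enrichment && any(out$connectors$calls$subtype != "unassigned")) {
      out$enrichment <- subtype_enrichment(out$connectors, out$bridges,
                                           out$modules, d[1L],
                                           n_null = n_null, seed = seed)
    }
  }

  if (!is.null(system_map)) {
    stars <- hyperedges[labels == "star"]
    cores <- lapply(archetypes[labels == "star"], `[[`, "core")
    systems <- unique(system_map)
    module_dists <- list()
    star_means <- list()
    for (sys in systems) {
      regions <- which(system_map == sys)
      dist <- tryCatch(module_edge_cohesion(W, regions, sys),
                       error = function(e) NULL)
      centered <- vapply(cores, function(cr) all(cr %in% regions), TRUE)
      module_dists[[sys]] <- dist
      star_means[[sys]] <- if (any(centered)) {
        star_cohesion(W, stars[centered])
      } else numeric(0)
    }
    out$cohesion <- compare_cohesion(module_dists, star_means, seed = seed)
  }

  if (!is.null(covariates) && length(hyperedges) > 0L) {
    out$age_effects <- lapply(hyperedges, function(h) {
      age_model(hyperedge_strength(tensor, h), covariates)
    })
    n_classes <- sum(table(labels) >= 2L)
    if (n_classes >= 2L) {
      out$development <- class_comparison(out$age_effects, labels,
                                          n_perm = n_null, seed = seed,
                                          fdr_q = fdr_q)
    }
  }

  if (!is.null(output_dir)) {
    .write_pipeline_outputs(out, output_dir)
  }
  out
}

.write_pipeline_outputs <- function(out, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- out$config
  cfg$config_hash <- sum(utils::head(
    utf8ToInt(paste(names(cfg), unlist(cfg), collapse = "|")), 10000))
  provenance <- sprintf("# config_hash=%s seed=%s edgehyper=%s",
                        cfg$config_hash, cfg$seed, cfg$package_version)
  wr <- function(df, name) {
    path <- file.path(output_dir, name)
    writeLines(provenance, path)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE)
    )
  }
  jsonlite::write_json(cfg, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  pairs <- out$partition$pairs
  wr(data.frame(edge = out$partition$edges,
                region_i = pairs[, 1L], region_j = pairs[, 2L],
                community = out$partition$labels), "partition.tsv")
  if (length(out$hyperedges) > 0L) {
    wr(data.frame(
      hyperedge = vapply(out$hyperedges, `[[`, 0L, "id"),
      label = out$labels,
      n_edges = vapply(out$hyperedges, `[[`, 0L, "size"),
      n_nodes = vapply(out$hyperedges, function(h) length(h$nodes), 0L),
      bipartivity = vapply(out$archetypes, function(a) a$bipartition$b, 0),
      core_regions = vapply(out$archetypes, function(a) {
        paste(a$core, collapse = ",")
      }, "")
    ), "hyperedges.tsv")
  }
  wr(out$scores$scores, "nodal_scores.tsv")
  if (!is.null(out$connectors)) wr(out$connectors$calls, "connectors.tsv")
  if (!is.null(out$enrichment)) {
    jsonlite::write_json(out$enrichment$table,
                         file.path(output_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$cohesion)) wr(out$cohesion, "cohesion.tsv")
  if (!is.null(out$development)) {
    wr(data.frame(
      hyperedge = vapply(out$hyperedges, `[[`, 0L, "id"),
      label = out$labels,
      partial_r = out$development$partial_r,
      partial_p = out$development$partial_p,
      q = out$development$q,
      significant = out$development$fdr_mask
    ), "age_effects.tsv")
    jsonlite::write_json(
      list(anova = out$development$anova,
           posthoc = out$development$posthoc,
           excluded_classes = out$development$excluded_classes),
      file.path(output_dir, "development.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(output_dir)
}
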