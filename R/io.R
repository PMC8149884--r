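#' Save / load a topology as JSON
#'
#' The JSON carries the signed adjacency (column-major), node names and
#' dimensions; round-trips losslessly.
#'
#' @param topo a `topology`.
#' @param path file path.
#' @return `path` invisibly for save; the `topology` for load.
#' @export
save_topology <- function(topo, path) {
  stopifnot(inherits(topo, "topology"))
  obj <- list(n_genes = topo$n_genes, n_inputs = topo$n_inputs,
              gene_names = topo$gene_names, input_names = topo$input_names,
              sign = as.numeric(topo$sign))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_topology
#' @export
load_topology <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed topology file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  sgn <- as.numeric(obj$sign)
  if (!all(sgn %in% c(-1, 0, 1))) {
    stop("malformed topology file '", path,
         "': sign entries must be in {-1, 0, +1}", call. = FALSE)
  }
  s <- matrix(sgn, obj$n_genes + obj$n_inputs, obj$n_genes)
  topology(s, n_genes = obj$n_genes, n_inputs = obj$n_inputs,
           gene_names = obj$gene_names,
           input_names = as.character(obj$input_names %||% character(0)))
}

#' Save / load a topology as a SIF-like edge list
#'
#' One line per link: `regulator  sign  target` with sign `+` or `-`,
#' tab-separated, for use with graph tools.  Loading needs the node sets
#' to reconstruct absent links.
#'
#' @param topo a `topology`.
#' @param path file path.
#' @param gene_names,input_names node sets for loading.
#' @return `path` invisibly for save; the `topology` for load.
#' @export
save_topology_sif <- function(topo, path) {
  stopifnot(inherits(topo, "topology"))
  idx <- which(topo$sign != 0, arr.ind = TRUE)
  lines <- sprintf("%s\t%s\t%s",
                   rownames(topo$sign)[idx[, 1]],
                   ifelse(topo$sign[idx] > 0, "+", "-"),
                   colnames(topo$sign)[idx[, 2]])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_topology_sif
#' @export
load_topology_sif <- function(path, gene_names, input_names = character(0)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  s <- matrix(0, length(gene_names) + length(input_names), length(gene_names),
              dimnames = list(c(gene_names, input_names), gene_names))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t")[[1]]
    if (length(parts) != 3 || !parts[2] %in% c("+", "-")) {
      stop("malformed SIF line ", k, ": '", lines[k], "'", call. = FALSE)
    }
    if (!parts[1] %in% rownames(s) || !parts[3] %in% colnames(s)) {
      stop("unknown node on SIF line ", k, ": '", lines[k], "'",
           call. = FALSE)
    }
    s[parts[1], parts[3]] <- if (parts[2] == "+") 1 else -1
  }
  topology(s, n_genes = length(gene_names), n_inputs = length(input_names),
           gene_names = gene_names, input_names = input_names)
}

# construct the task described by a config task block
config_task <- function(block) {
  if (is.null(block$kind)) stop("config error: task$kind is required",
                                call. = FALSE)
  args <- block
  args$kind <- NULL
  switch(block$kind,
         adaptation = do.call(make_adaptation_task, args),
         controlled_oscillation = do.call(make_controlled_oscillation_task,
                                          args),
         gap_gene = {
           prof <- synth_gap_gene_profiles(
             n_positions = args$n_positions %||% 40,
             seed = args$profile_seed %||% 1)
           merge_task_list(make_gap_gene_task(prof,
                                              N_T = args$N_T %||% 30))
         },
         stop("config error: unknown task kind '", block$kind, "'",
              call. = FALSE))
}

#' Run a train-and-distill experiment from a config
#'
#' Executes the standard pipeline -- build the task, train an ensemble of
#' restarts, distill each trained model into a signed topology, optionally
#' sparsify -- and writes all artifacts (model checkpoints, topology JSON,
#' per-restart metrics, a loss CSV, and a manifest recording the config,
#' derived seeds and package version) into `out_dir`.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   Required blocks: `seed` (integer) and `task` (with `kind`
#'   `"adaptation"`, `"controlled_oscillation"` or `"gap_gene"` plus
#'   constructor arguments).  Optional: `training`
#'   (`restarts`, `max_iter`, `lr`, `noise_sd`, `hidden`, `architecture`),
#'   `interrogation` (`lambda`, `cutoff`, `sparsify`).
#' @param out_dir output directory (created if missing).
#' @return The manifest list, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("seed", "task")) {
    if (is.null(config[[field]])) {
      stop("config error: missing required block '", field, "'",
           call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "topologies"), showWarnings = FALSE)

  task <- config_task(config$task)
  tr <- config$training %||% list()
  n_restarts <- tr$restarts %||% 1
  cfg <- train_config(lr = tr$lr %||% 1e-2,
                      max_iter = tr$max_iter %||% 3000,
                      noise_sd = tr$noise_sd %||% 0.01,
                      seed = config$seed)
  hidden <- tr$hidden %||% c(16, 16)
  arch <- tr$architecture %||% "per_gene"
  ens <- train_ensemble(task, n_restarts, base_seed = config$seed,
                        config = cfg, hidden_sizes = hidden,
                        architecture = arch)

  ig <- config$interrogation %||% list()
  lam <- ig$lambda %||% 0.95
  cutoff <- ig$cutoff %||% 0.2
  metrics <- NULL
  losses <- NULL
  for (k in seq_along(ens)) {
    res <- ens[[k]]
    save_synthesis(res$synth,
                   file.path(out_dir, "models",
                             sprintf("model_%02d.json", res$restart)))
    wt <- simulate_task(res$synth, task)
    topo <- extract_topology(delta_matrix(res$synth, wt, lam = lam), cutoff)
    save_topology(topo,
                  file.path(out_dir, "topologies",
                            sprintf("topology_%02d.json", res$restart)))
    pcond <- task$meta$phenotype_condition %||% length(wt)
    pm <- tryCatch(phenotype_metrics(wt[[pcond]], task),
                   error = function(e) NULL)
    metrics <- rbind(metrics, data.frame(
      restart = res$restart, seed = res$seed, loss = res$best_loss,
      n_links = sum(topo$sign != 0),
      sensitivity = pm$sensitivity %||% NA_real_,
      adaptation_error = pm$adaptation_error %||% NA_real_))
    losses <- rbind(losses, data.frame(restart = res$restart,
                                       iteration = seq_along(res$loss_history),
                                       loss = res$loss_history))
  }
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(losses, file.path(out_dir, "loss_history.csv"),
            row.names = FALSE)

  if (isTRUE(ig$sparsify)) {
    sp <- sparsify(task, config = cfg, hidden_sizes = hidden,
                   architecture = arch,
                   seed = derive_seed(config$seed, "sparsify"),
                   lam_score = lam, cutoff = cutoff)
    for (k in seq_along(sp)) {
      save_topology(sp[[k]]$topology,
                    file.path(out_dir, "topologies",
                              sprintf("sparsify_step_%02d.json", k - 1L)))
    }
  }

  manifest <- list(
    package = "netdistill",
    version = as.character(utils::packageVersion("netdistill")),
    config = config,
    seeds = list(base = config$seed,
                 restarts = vapply(seq_len(n_restarts), function(r)
                   derive_seed(config$seed, paste0("restart-", r)),
                   integer(1))),
    n_trained = length(ens),
    n_failed = length(attr(ens, "failures")),
    best_loss = min(metrics$loss))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
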