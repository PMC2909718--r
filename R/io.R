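## Delimited-text input/output. Numeric values are written with 15
## significant digits so write -> read round-trips are lossless at double
## precision for these magnitudes.

fmt_num <- function(x) sprintf("%.15g", x)

write_tsv_matrix <- function(m, path) {
  df <- as.data.frame(apply(m, 2, fmt_num), stringsAsFactors = FALSE)
  if (nrow(m) == 1L) df <- as.data.frame(t(df), stringsAsFactors = FALSE)
  colnames(df) <- colnames(m)
  df <- cbind(sample = rownames(m), df, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write an expression dataset as tab-separated text
#'
#' Produces four files under the given prefix: `<prefix>_X.tsv` and
#' `<prefix>_Y.tsv` (samples x features, header row of feature ids, first
#' column sample ids), `<prefix>_labels.tsv` (sample id, class) and
#' `<prefix>_truth.tsv` (feature id, role, delta, pattern).
#'
#' @param ds An [simulate_dataset()] result.
#' @param prefix Path prefix for the output files.
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "expression_dataset"))
  paths <- paste0(prefix, c("_X.tsv", "_Y.tsv", "_labels.tsv", "_truth.tsv"))
  write_tsv_matrix(ds$X, paths[1])
  write_tsv_matrix(ds$Y, paths[2])
  utils::write.table(data.frame(sample = rownames(ds$Y),
                                class = as.character(ds$labels)),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth$delta <- ifelse(is.na(truth$delta), "NA", fmt_num(truth$delta))
  utils::write.table(truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read an expression dataset written by [write_dataset()]
#'
#' @param prefix The path prefix used when writing.
#' @return An `"expression_dataset"` (without the generating config, which
#'   is not serialized).
#' @export
read_dataset <- function(prefix) {
  x <- read_tsv_matrix(paste0(prefix, "_X.tsv"))
  y <- read_tsv_matrix(paste0(prefix, "_Y.tsv"))
  lab <- utils::read.delim(paste0(prefix, "_labels.tsv"),
                           stringsAsFactors = FALSE)
  truth <- utils::read.delim(paste0(prefix, "_truth.tsv"),
                             stringsAsFactors = FALSE)
  truth$delta <- suppressWarnings(as.numeric(truth$delta))
  structure(list(X = x, Y = y,
                 labels = factor(lab$class, levels = c("A", "B")),
                 truth = truth, config = NULL),
            class = "expression_dataset")
}

#' Write / read a pool assignment as a two-column text table
#'
#' @param assignment A [assign_pools()] result.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_pool_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "pool_assignment"))
  utils::write.table(assignment$pools[, c("sample", "pool", "class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_assignment
#' @export
read_pool_assignment <- function(path) {
  pools <- utils::read.delim(path, stringsAsFactors = FALSE)
  m_p <- as.integer(table(pools$pool)[1])
  out <- list(m_p = m_p,
              n_pools_per_class = as.integer(min(table(pools$class)) %/% m_p),
              pools = pools[, c("pool", "class", "sample")])
  class(out) <- "pool_assignment"
  out
}

run_config_defaults <- function() {
  list(n_per_class = 30L, n_features = 1000L, n_de_genes = 10L,
       n_patterns = 10L, background_mean = 8, bio_sd = 0.2,
       de_delta_interval = c(0.1, 0.5), pattern_offset = 0.4,
       class_mean_interval = c(6, 10), shuffle_columns = FALSE,
       scenarios = c("DE_ONLY", "LINEAR_ONLY", "COMBINED"),
       noise_sds = c(0.2, 0.4), pool_sizes = c(1L, 2L, 3L, 5L),
       methods = METHOD_TAGS, n_reps = 500L, base_seed = 1L,
       out_dir = ".", bootstrap_level = 0.95, n_boot = 1000L)
}

#' Load a run configuration from a YAML file
#'
#' Reads a key-value (YAML) configuration selecting the simulation
#' parameters and experiment grid; omitted keys take the study defaults
#' (30 per class, 1000 features, pool sizes 1/2/3/5, noise sds 0.2 and 0.4,
#' all five methods, 500 repetitions). Unknown keys and invalid values are
#' errors.
#'
#' @param path Path to the YAML file. An empty file yields the full default
#'   grid.
#' @return A validated named list of class `"run_config"`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  bad_sc <- setdiff(cfg$scenarios, c("DE_ONLY", "LINEAR_ONLY", "COMBINED"))
  if (length(bad_sc))
    stop("invalid scenario tag(s): ", paste(bad_sc, collapse = ", "),
         call. = FALSE)
  bad_m <- setdiff(cfg$methods, METHOD_TAGS)
  if (length(bad_m))
    stop("invalid method tag(s): ", paste(bad_m, collapse = ", "),
         call. = FALSE)
  ## only an explicitly requested pool size is a load-time error; the
  ## effective grid (after command-line overrides) is validated at run time
  if (!is.null(user$pool_sizes))
    for (m_p in cfg$pool_sizes)
      if (cfg$n_per_class %% as.integer(m_p) != 0L)
        stop("pool_sizes: ", m_p, " does not divide n_per_class = ",
             cfg$n_per_class, call. = FALSE)
  if (cfg$n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  ## validate the simulation fields by constructing a sim_config
  as_sim_config(cfg, cfg$scenarios[1], cfg$noise_sds[1])
  structure(cfg, class = "run_config")
}

as_sim_config <- function(run_cfg, scenario, noise_sd) {
  sim_config(n_per_class = run_cfg$n_per_class,
             n_features = run_cfg$n_features,
             n_de_genes = run_cfg$n_de_genes,
             n_patterns = run_cfg$n_patterns,
             background_mean = run_cfg$background_mean,
             bio_sd = run_cfg$bio_sd,
             noise_sd = noise_sd,
             de_delta_interval = run_cfg$de_delta_interval,
             pattern_offset = run_cfg$pattern_offset,
             class_mean_interval = run_cfg$class_mean_interval,
             scenario = scenario,
             shuffle_columns = run_cfg$shuffle_columns)
}
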