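# File formats and run plumbing: observation CSV (rows = time points,
# columns = spatial series), YAML/JSON run configuration, long-format chain
# CSV, event-log CSV, and a JSON run manifest.

#' Read an observation CSV
#'
#' Header row of series names, one row per time point, one column per
#' spatial dimension (the common layout for multivariate log-return files).
#' Returned transposed to the package's `d x N` convention.
#'
#' @param path CSV file path.
#' @return `d x N` numeric matrix with series names as rownames.
#' @export
read_observation_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty observation CSV")
  num <- vapply(df, is.numeric, TRUE)
  if (!all(num)) stop("non-numeric observation columns: ",
                      paste(names(df)[!num], collapse = ", "))
  y <- t(as.matrix(df))
  if (any(!is.finite(y))) stop("observation CSV contains missing or non-finite values")
  y
}

#' Write an observation matrix as CSV
#'
#' @param y `d x N` matrix.
#' @param path output path.
#' @export
write_observation_csv <- function(y, path) {
  nm <- rownames(y)
  if (is.null(nm)) nm <- paste0("series", seq_len(nrow(y)))
  df <- as.data.frame(t(y))
  names(df) <- nm
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a discretized chain in long format
#'
#' Columns `time, k, n, value`: one row per (sample time, coordinate).
#'
#' @param chain a [bps_chain()].
#' @param path output path.
#' @export
write_chain_csv <- function(chain, path) {
  ns <- ncol(chain$samples)
  grid <- expand.grid(k = seq_len(chain$d), n = seq_len(chain$N))
  df <- data.frame(time = rep(chain$times, each = nrow(grid)),
                   k = rep(grid$k, ns), n = rep(grid$n, ns),
                   value = as.vector(chain$samples))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format chain CSV
#'
#' @param path CSV written by [write_chain_csv()].
#' @return a [bps_chain()].
#' @export
read_chain_csv <- function(path) {
  df <- utils::read.csv(path)
  d <- max(df$k); N <- max(df$n)
  times <- sort(unique(df$time))
  df <- df[order(df$time, df$n, df$k), ]
  samples <- matrix(df$value, d * N, length(times))
  delta <- if (length(times) > 1L) times[2L] - times[1L] else times[1L]
  bps_chain(samples, d, N, delta)
}

#' Write the event log of a run
#'
#' @param traj a `bps_trajectory`.
#' @param path output path.
#' @export
write_event_log <- function(traj, path) {
  utils::write.csv(traj$events, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Configuration, seed, model name, sampler, and event counters of a run.
#'
#' @param traj a `bps_trajectory`.
#' @param path output path.
#' @export
write_run_manifest <- function(traj, path) {
  cfg <- traj$config
  cfg$delta <- if (is.null(cfg$delta)) NA else cfg$delta
  obj <- list(model = traj$model, sampler = traj$sampler,
              d = traj$d, N = traj$N,
              config = unclass(cfg), counters = as.list(traj$counters))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' The file must contain a `model` block (`name` = `lgssm` or `sv`, `d`,
#' `N`, and model parameters) and may contain a `sampler` block
#' (`kind` = `global|local|blocked|even-odd`, `theta`, `gamma`, `horizon`,
#' `delta`, `width`, `overlap`, `seed`).
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config extension: ", ext))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$model))
    stop("config schema error: missing key 'model'")
  # YAML 1.1 resolves a bare `N` key to a boolean; map it back
  nm <- names(cfg$model)
  if (!"N" %in% nm && "FALSE" %in% nm)
    names(cfg$model)[nm == "FALSE"] <- "N"
  required <- c("name", "d", "N")
  missing <- setdiff(required, names(cfg$model))
  if (length(missing))
    stop("config schema error: missing model keys: ", paste(missing, collapse = ", "))
  if (!cfg$model$name %in% c("lgssm", "sv"))
    stop("config schema error: model$name must be 'lgssm' or 'sv'")
  cfg
}

config_model <- function(cfg, y = NULL, seed = NULL) {
  mc <- cfg$model
  if (mc$name == "lgssm") {
    params <- lgssm_params(mc$d, mc$N,
                           sigma2 = mc$sigma2 %||% 5, psi = mc$psi %||% 0.1)
    if (is.null(y)) y <- simulate_lgssm(params, seed = seed)$y
    list(model = lgssm_model(params, y), params = params, y = y)
  } else {
    params <- if (!is.null(mc$alpha)) {
      sv_params(mc$d, mc$N, alpha = mc$alpha,
                Sigma_eta = matrix(unlist(mc$Sigma_eta), mc$d, mc$d),
                Sigma_eps = matrix(unlist(mc$Sigma_eps), mc$d, mc$d),
                Sigma_rho = matrix(unlist(mc$Sigma_rho), mc$d, mc$d),
                nu = mc$nu %||% 10L)
    } else sv_default_params(mc$d, mc$N)
    sim <- simulate_sv(params, seed = seed)
    if (!is.null(y)) {
      data <- sv_dataset(y, sim$data$gamma)   # observed returns, simulated mixing
    } else data <- sim$data
    list(model = sv_model(params, data), params = params, y = data$y)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
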