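#' Table-1 default configuration values
#'
#' The benchmark defaults used when a configuration omits keys: 1000 users,
#' three M/M/1/10 servers with capacities \{100, 200, 400\} requests/s and
#' latencies \{10, 20, 30\} ms, a 100 ms timeout, workload 0.75, fixed
#' tolerance 5, adaptive parameters `T0 = 5`, `x0 = 0`, `beta = 0.1`.
#' @keywords internal
default_config_values <- function() {
  list(system = list(Nu = 1000, tau_ms = 100, rho = 0.75,
                     latency = "round-trip"),
       servers = list(list(mu = 100, c = 1, k = 10, d_ms = 10),
                      list(mu = 200, c = 1, k = 10, d_ms = 20),
                      list(mu = 400, c = 1, k = 10, d_ms = 30)),
       population = list(tolerance = 5),
       learning = list(T0 = 5, x0 = 0, beta = 0.1),
       run = list(mode = "fixed", duration = 1800, seed = 1, sample_dt = 1,
                  shift_rule = "uniform", smooth = 0.01, tail_fraction = 0.1,
                  scale = 1))
}

check_keys <- function(given, allowed, where) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown))
    stop(sprintf("unknown key '%s' in config section '%s'", unknown[1], where))
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration with flat sections `system`, `servers` (a
#' list of per-server maps), `population`, `learning` and `run`, fills
#' omitted keys with the Table-1-style defaults (see
#' [default_config_values()]), converts millisecond latencies/timeouts to
#' seconds, and resolves the workload (give `rho` *or* `lambda_u`, never
#' both). Unknown keys are errors, never silently ignored.
#'
#' @param path Path to a YAML config file; an empty file yields the full
#'   default system.
#' @return List of class `"wsls_config"` with the resolved `system`
#'   ([system_spec()]), the raw resolved `values`, and `run` settings.
#' @examples
#' f <- tempfile(fileext = ".yaml"); writeLines("", f)
#' cfg <- load_config(f)   # benchmark defaults
#' cfg$system$lambda_u
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop(sprintf("config file '%s' not found", path))
  if (is.null(raw)) raw <- list()
  check_keys(raw, c("system", "servers", "population", "learning", "run"), "(top level)")
  def <- default_config_values()

  sys_raw <- raw$system
  check_keys(sys_raw, c("Nu", "tau_ms", "rho", "lambda_u", "latency"), "system")
  if (!is.null(sys_raw$rho) && !is.null(sys_raw$lambda_u))
    stop("config conflict: give either system.rho or system.lambda_u, not both")
  sysv <- utils::modifyList(def$system, sys_raw %||% list())
  if (!is.null(sys_raw$lambda_u)) sysv$rho <- NULL

  servers <- raw$servers %||% def$servers
  servers <- lapply(seq_along(servers), function(i) {
    s <- servers[[i]]
    check_keys(s, c("mu", "c", "k", "d_ms"), sprintf("servers[%d]", i))
    utils::modifyList(list(c = 1, k = 10, d_ms = 0), s)
  })
  check_keys(raw$population, c("tolerance"), "population")
  popv <- utils::modifyList(def$population, raw$population %||% list())
  check_keys(raw$learning, c("T0", "x0", "beta"), "learning")
  lrnv <- utils::modifyList(def$learning, raw$learning %||% list())
  check_keys(raw$run, c("mode", "duration", "seed", "sample_dt", "shift_rule",
                        "smooth", "tail_fraction", "scale", "schedule"), "run")
  runv <- utils::modifyList(def$run, raw$run %||% list())

  values <- list(system = sysv, servers = servers, population = popv,
                 learning = lrnv, run = runv)
  structure(list(system = build_system(values), values = values,
                 run = runv, population = popv, learning = lrnv),
            class = "wsls_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_system <- function(values, scale = values$run$scale %||% 1) {
  goods <- lapply(values$servers, function(s)
    queue_server_spec(mu = s$mu * scale, c = s$c, k = s$k, d = s$d_ms / 1000))
  sysv <- values$system
  Nu <- max(1, round(sysv$Nu * scale))
  if (!is.null(sysv$rho))
    system_spec(goods, Nu = Nu, tau = sysv$tau_ms / 1000, rho = sysv$rho,
                latency_mode = sysv$latency)
  else
    system_spec(goods, Nu = Nu, tau = sysv$tau_ms / 1000,
                lambda_u = sysv$lambda_u, latency_mode = sysv$latency)
}

#' Write a configuration file
#'
#' Serializes the resolved values of a [load_config()] result (or a raw
#' values list) back to YAML, so that `load_config(write_config(x))`
#' round-trips.
#'
#' @param config A `"wsls_config"` or the `values` list of one.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  values <- if (inherits(config, "wsls_config")) config$values else config
  yaml::write_yaml(values, path)
  invisible(path)
}

#' Build a sim_config from a loaded configuration
#'
#' @param config A `"wsls_config"`.
#' @param scale Proportional scale factor on `Nu` and capacities (workload
#'   preserved); overrides `run.scale`.
#' @param seed Optional seed override.
#' @param duration Optional duration override (seconds).
#' @return A [sim_config()].
#' @export
config_to_sim <- function(config, scale = NULL, seed = NULL, duration = NULL) {
  stopifnot(inherits(config, "wsls_config"))
  v <- config$values
  scale <- scale %||% v$run$scale %||% 1
  system <- build_system(v, scale = scale)
  sched <- if (!is.null(v$run$schedule))
    do.call(rbind, lapply(v$run$schedule, as.data.frame))
  sim_config(system,
             duration = duration %||% v$run$duration,
             mode = v$run$mode,
             tolerance = unlist(v$population$tolerance),
             T0 = v$learning$T0, x0 = v$learning$x0, beta = v$learning$beta,
             shift_rule = v$run$shift_rule,
             schedule = sched,
             seed = seed %||% v$run$seed,
             sample_dt = v$run$sample_dt)
}

#' Experiment presets
#'
#' Named, fully resolved experiment configurations at benchmark scale:
#' \describe{
#'   \item{`wsls-basic`}{single-failure tolerance (WSLS in its purest form),
#'     constant workload 0.75, 1800 s.}
#'   \item{`adaptive`}{adaptive tolerance from `T0 = 5`, `beta = 0.1`,
#'     constant workload 0.75, 36000 s.}
#'   \item{`multi-seed`}{15 replicate runs at workload 0.5, fixed tolerance 5
#'     and adaptive variants, 12000 s each.}
#'   \item{`dynamic-load`}{workload switching every hour through
#'     0.75, 1.25, 0.75, 1.25, 0.75, 0.5, 0.25, 0.5, 0.75, 1; fixed-5 and
#'     adaptive variants, 36000 s.}
#' }
#'
#' @param name Preset name.
#' @param seed Base seed.
#' @param scale Proportional scale factor on `Nu` and capacities.
#' @return A list with elements `name`, `configs` (named list of
#'   [sim_config()] objects) and `values` (config echo).
#' @export
experiment_preset <- function(name = c("wsls-basic", "adaptive", "multi-seed",
                                       "dynamic-load"),
                              seed = 1L, scale = 1) {
  name <- match.arg(name)
  v <- default_config_values()
  v$run$scale <- scale
  mk <- function(patch_run = list(), patch_pop = list(), seed_i = seed) {
    v2 <- v
    v2$run <- utils::modifyList(v2$run, patch_run)
    v2$population <- utils::modifyList(v2$population, patch_pop)
    cfg <- structure(list(values = v2), class = "wsls_config")
    config_to_sim(cfg, scale = scale, seed = seed_i)
  }
  hourly <- data.frame(length = rep(3600, 10),
                       rho = c(0.75, 1.25, 0.75, 1.25, 0.75, 0.5, 0.25, 0.5,
                               0.75, 1))
  configs <- switch(
    name,
    "wsls-basic" = list(run = mk(list(mode = "fixed", duration = 1800),
                                 list(tolerance = 1))),
    "adaptive" = list(run = mk(list(mode = "adaptive", duration = 36000))),
    "multi-seed" = {
      reps <- list()
      for (r in 1:15) {
        v$system$rho <- 0.5
        reps[[sprintf("fixed_%02d", r)]] <-
          mk(list(mode = "fixed", duration = 12000), list(tolerance = 5),
             seed_i = seed + r - 1L)
        reps[[sprintf("adaptive_%02d", r)]] <-
          mk(list(mode = "adaptive", duration = 12000), seed_i = seed + r - 1L)
      }
      reps
    },
    "dynamic-load" = list(
      fixed = mk(list(mode = "fixed", duration = 36000,
                      schedule = lapply(seq_len(nrow(hourly)), function(i)
                        as.list(hourly[i, ]))),
                 list(tolerance = 5)),
      adaptive = mk(list(mode = "adaptive", duration = 36000,
                         schedule = lapply(seq_len(nrow(hourly)), function(i)
                           as.list(hourly[i, ]))))))
  if (name == "multi-seed") v$system$rho <- 0.5
  list(name = name, configs = configs, values = v, seed = seed, scale = scale)
}
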